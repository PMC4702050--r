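#' Predict minimum-free-energy secondary structures
#'
#' Folds one or more sequences and returns, for each, the dot-bracket
#' structure, the free energy and a pair table. The default engine is
#' ViennaRNA's `RNAfold` executable (thermodynamic MFE; sequences are passed
#' DNA-side, RNAfold treats T as U). A built-in Nussinov-style
#' base-pair-maximization engine is available as a dependency-free fallback;
#' its `mfe` slot is the negated pair count, a surrogate score rather than
#' kcal/mol, and it is intended for testing and for hosts without ViennaRNA.
#'
#' @param seqs character vector of sequences (ACGT, length >= 1 each).
#' @param engine `"auto"` (RNAfold if found on PATH, else nussinov),
#'   `"rnafold"` or `"nussinov"`.
#' @param ids optional sequence ids used in error messages.
#' @return list of fold results, each a list with `structure` (dot-bracket),
#'   `mfe` (<= 0) and `pair_table` (integer vector, 1-based partner or NA).
#' @export
rna_fold <- function(seqs, engine = c("auto", "rnafold", "nussinov"), ids = NULL) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (rnafold_available()) "rnafold" else "nussinov"
  }
  if (length(seqs) == 0L) return(list())
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  bad <- !grepl("^[ACGTU]+$", toupper(seqs))
  if (any(bad)) stop("fold error for ", ids[which(bad)[1]],
                     ": sequence contains non-ACGT characters")
  res <- switch(engine,
                rnafold  = fold_rnafold(toupper(seqs), ids),
                nussinov = lapply(toupper(rna2dna(seqs)), fold_nussinov))
  for (i in seq_along(res)) res[[i]]$pair_table <- pair_table(res[[i]]$structure)
  res
}

#' Is the RNAfold executable available?
#' @return logical scalar.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

fold_rnafold <- function(seqs, ids) {
  inp <- paste0(">s", seq_along(seqs), "\n", seqs)
  out <- tryCatch(
    system2("RNAfold", c("--noPS"), input = inp, stdout = TRUE, stderr = FALSE),
    error = function(e) stop("fold error: RNAfold invocation failed (",
                             conditionMessage(e), ")"))
  heads <- grep("^>", out)
  if (length(heads) != length(seqs)) {
    stop("fold error: RNAfold returned ", length(heads),
         " records for ", length(seqs), " sequences")
  }
  lapply(seq_along(heads), function(i) {
    line <- out[heads[i] + 2L]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3L) stop("fold error for ", ids[i],
                              ": unparseable RNAfold output '", line, "'")
    list(structure = m[2], mfe = as.numeric(m[3]))
  })
}

# base-pair maximization (Nussinov) with canonical + wobble pairs and a
# minimum hairpin loop of 3; nested traceback gives a valid dot-bracket.
fold_nussinov <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  if (n <= min_loop + 1L) {
    return(list(structure = strrep(".", n), mfe = 0))
  }
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      for (k in ks) {
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) M[i, k - 1L] else 0L
          v <- left + M[k + 1L, j - 1L] + 1L
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    done <- FALSE
    for (k in i:(j - min_loop - 1L)) {
      if (can_pair(s[k], s[j])) {
        left <- if (k > i) M[i, k - 1L] else 0L
        if (left + M[k + 1L, j - 1L] + 1L == M[i, j]) {
          db[k] <- "("; db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          done <- TRUE
          break
        }
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  npairs <- sum(db == "(")
  list(structure = paste(db, collapse = ""), mfe = -as.numeric(npairs))
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced `(`/`)`, `.` unpaired).
#' @return integer vector: `pt[i]` is the 1-based partner of position `i`,
#'   `NA` if unpaired. The table is an involution: `pt[pt[i]] == i`.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("invalid character in dot-bracket: ", ch[i])
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  pt
}
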