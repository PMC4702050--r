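#' Read a collapsed small-RNA / degradome library
#'
#' Collapsed libraries hold one record per distinct sequence together with its
#' raw read count. Two dialects are accepted, auto-detected from the first
#' non-empty line:
#'
#' * FASTA with the count encoded in the header, either `>id_count` or
#'   `>id-count` (the trailing integer field is the count);
#' * two-column TSV, `sequence<TAB>count`, no header.
#'
#' @param path file path.
#' @return data.frame with columns `seq` (character) and `count` (integer),
#'   untreated (see [pretreat_library()]).
#' @export
read_collapsed_reads <- function(path) {
  if (!file.exists(path)) stop("collapsed-read file not found: ", path)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (length(l <- readLines(con, n = 1L)) == 1L) {
    if (nzchar(trimws(l))) { first <- l; break }
  }
  close(con); on.exit()
  if (startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path)
    ids <- names(ss)
    counts <- suppressWarnings(as.integer(sub(".*[-_](\\d+)\\s*$", "\\1", ids)))
    if (anyNA(counts)) {
      stop("cannot parse read counts from FASTA headers in ", path,
           " (expected '>id_count' or '>id-count')")
    }
    data.frame(seq = as.character(ss), count = counts,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "integer"),
                            col.names = c("seq", "count"))
    df
  }
}

#' Write a collapsed library
#'
#' @param reads data.frame with `seq` and `count` (a `mir_library`'s `$reads`
#'   also works), or a `mir_library`.
#' @param path output path.
#' @param format `"tsv"` (sequence TAB count) or `"fasta"` (`>t<i>_<count>`).
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (inherits(reads, "mir_library")) reads <- reads$reads
  if (format == "tsv") {
    utils::write.table(reads[, c("seq", "count")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(paste0(">t", seq_len(nrow(reads)), "_", reads$count, "\n",
                      reads$seq), path)
  }
  invisible(path)
}

#' Pre-treat an HTS library and normalize to reads per million
#'
#' Discards records whose sequence contains `N` (any non-ACGT character after
#' U->T and case folding) and records with zero read count, then computes RPM
#' over the sum of raw counts of the *retained* records, so that library RPM
#' always sums to one million.
#'
#' @param reads a data.frame with `seq`/`count` columns, or a path accepted by
#'   [read_collapsed_reads()].
#' @param kind one of `"degradome"`, `"srna"`, `"ago"`, `"control"`.
#' @param name library identifier (defaults to the file basename or "library").
#' @return an object of class `mir_library`: a list with `name`, `kind`,
#'   `reads` (data.frame `seq`, `count`, `rpm`; unique uppercase DNA
#'   sequences) and `total_raw` (sum of retained raw counts).
#' @export
pretreat_library <- function(reads, kind = c("degradome", "srna", "ago", "control"),
                             name = NULL) {
  kind <- match.arg(kind)
  src <- NULL
  if (is.character(reads) && length(reads) == 1L) {
    src <- reads
    reads <- read_collapsed_reads(reads)
  }
  if (is.null(name)) name <- if (!is.null(src)) basename(src) else "library"
  stopifnot(is.data.frame(reads), all(c("seq", "count") %in% names(reads)))

  sq <- rna2dna(reads$seq)
  cnt <- as.integer(reads$count)
  keep <- grepl("^[ACGT]+$", sq) & !is.na(cnt) & cnt > 0L
  sq <- sq[keep]; cnt <- cnt[keep]
  if (length(sq) == 0L) {
    stop("library '", name, "' is empty after pre-treatment (N / zero-count filtering)")
  }
  # collapse duplicate sequences (counts add) to keep per-library uniqueness
  dt <- data.table(seq = sq, count = cnt)
  dt <- dt[, list(count = sum(count)), by = "seq"]
  total <- sum(dt$count)
  dt[, rpm := count / total * 1e6]
  structure(list(name = name, kind = kind,
                 reads = as.data.frame(dt), total_raw = total),
            class = "mir_library")
}

#' @export
print.mir_library <- function(x, ...) {
  cat(sprintf("<mir_library> %s (%s): %d distinct reads, %d raw counts\n",
              x$name, x$kind, nrow(x$reads), x$total_raw))
  invisible(x)
}

#' Split a genome into overlapping scanning fragments
#'
#' Chromosomes are subdivided into 10,000-nt fragments with 500-nt overlaps
#' (consecutive fragment starts 0, 9,500, 19,000, ...), so every genomic
#' position is covered and no feature shorter than the overlap is split
#' across all fragments containing it.
#'
#' @param genome path to a multi-record nucleotide FASTA, or a named
#'   [Biostrings::DNAStringSet].
#' @param fragment_len fragment length (default 10,000 nt).
#' @param overlap overlap between consecutive fragments (default 500 nt).
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open),
#'   `seq`, `is_last`.
#' @export
fragment_genome <- function(genome, fragment_len = 10000L, overlap = 500L) {
  stopifnot(fragment_len > overlap, overlap >= 0)
  gen <- load_genome(genome)
  step <- fragment_len - overlap
  out <- vector("list", length(gen))
  for (i in seq_along(gen)) {
    chrom <- names(gen)[i]
    len <- Biostrings::width(gen)[i]
    n_frag <- if (len <= fragment_len) 1L else
      as.integer(ceiling((len - fragment_len) / step)) + 1L
    starts <- seq.int(0L, by = step, length.out = n_frag)
    ends <- pmin(starts + fragment_len, len)
    seqs <- as.character(Biostrings::subseq(rep(gen[i], length(starts)),
                                            start = starts + 1L, end = ends))
    out[[i]] <- data.frame(chrom = chrom, start = starts, end = ends,
                           seq = unname(seqs),
                           is_last = seq_along(starts) == length(starts),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# read a genome FASTA (or pass a DNAStringSet through), checking IDs
load_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    gen <- tryCatch(Biostrings::readDNAStringSet(genome),
                    error = function(e) stop("unreadable genome FASTA: ",
                                             genome, " (", conditionMessage(e), ")"))
  } else if (inherits(genome, "DNAStringSet")) {
    gen <- genome
  } else stop("genome must be a FASTA path or a DNAStringSet")
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen))) stop("duplicate sequence IDs in genome FASTA")
  gen
}

#' Load miRBase-style hairpin and mature sets for one species
#'
#' Reads hairpin and mature FASTA files in the miRBase dialect (IDs like
#' `ath-mir-…` / `ath-miR-…`), keeps records whose ID starts with the species
#' prefix, maps U to T, and computes the length of the longest hairpin — the
#' window parameter L used for precursor candidate extraction.
#'
#' @param hairpin_fa,mature_fa FASTA paths (RNA or DNA alphabet).
#' @param prefix species prefix, e.g. `"ath"`; empty string keeps everything.
#' @return object of class `mirbase_set`: list with `hairpins`, `matures`
#'   (named character vectors, DNA alphabet) and `longest_hairpin_len` (L).
#' @export
load_mirbase <- function(hairpin_fa, mature_fa, prefix = "") {
  read_one <- function(path, what) {
    ss <- Biostrings::readBStringSet(path)
    names(ss) <- sub("\\s.*$", "", names(ss))
    v <- rna2dna(as.character(ss))
    names(v) <- names(ss)
    if (nzchar(prefix)) v <- v[startsWith(names(v), prefix)]
    if (length(v) == 0L) {
      stop("no ", what, " records for species prefix '", prefix, "' in ", path)
    }
    v
  }
  hp <- read_one(hairpin_fa, "hairpin")
  mat <- read_one(mature_fa, "mature")
  structure(list(hairpins = hp, matures = mat,
                 longest_hairpin_len = max(nchar(hp))),
            class = "mirbase_set")
}

#' @export
print.mirbase_set <- function(x, ...) {
  cat(sprintf("<mirbase_set> %d hairpins, %d matures, L = %d\n",
              length(x$hairpins), length(x$matures), x$longest_hairpin_len))
  invisible(x)
}
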