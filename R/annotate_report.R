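#' Annotate a duplex call against registered mature miRNAs
#'
#' Exact, U/T-insensitive sequence identity of the called mature or star to
#' any registered mature record; all matching names are listed (identical
#' sequences under several names all appear). An empty list marks the call
#' as novel.
#'
#' @param call a `mir_duplex`.
#' @param mirbase a `mirbase_set` from [load_mirbase()].
#' @return the call with `known_ids` (character vector, possibly empty).
#' @export
annotate_known <- function(call, mirbase) {
  mats <- rna2dna(mirbase$matures)
  hits <- names(mats)[mats == rna2dna(call$mature$seq) |
                      mats == rna2dna(call$star$seq)]
  call$known_ids <- unname(hits)
  call
}

#' Build the final report table from duplex calls
#'
#' One row per duplex, deterministically ordered by (chrom, start, strand).
#' Sequences are reported RNA-side; genomic and precursor-local coordinates
#' are 1-based inclusive. Columns:
#' `chrom`, `start`, `end`, `strand` — precursor locus;
#' `signatures` — degradome signature position(s) on the precursor (1-based,
#' comma-separated) with the source library in brackets;
#' `mature_seq`, `mature_span`, `mature_rpm`, `star_seq`, `star_span`,
#' `star_rpm` — the duplex (`*_span` within the precursor; `*_rpm` holds
#' `lib=rpm` pairs, one per sRNA library);
#' `star_mode`, `ago_status`, `known_ids` (comma-separated, empty = novel,
#' also flagged by `novel`), `mfe`, `precursor_seq`, `structure`.
#'
#' @param calls list of trimmed, annotated `mir_duplex` objects.
#' @return data.frame (0 rows allowed).
#' @export
build_report <- function(calls) {
  cols <- c("chrom", "start", "end", "strand", "signatures",
            "mature_seq", "mature_span", "mature_rpm",
            "star_seq", "star_span", "star_rpm",
            "star_mode", "ago_status", "known_ids", "novel",
            "mfe", "precursor_seq", "structure")
  if (length(calls) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(calls, function(x) {
    stopifnot(isTRUE(x$trimmed))
    sh <- x$precursor_local[1] - 1L
    rpm_str <- function(v) {
      if (is.null(v)) return("")
      paste(sprintf("%s=%.4f", names(v), v), collapse = ",")
    }
    known <- x$known_ids %||% character(0)
    data.frame(
      chrom = x$chrom,
      start = x$precursor_gstart + 1L,
      end = x$precursor_gend,
      strand = x$strand,
      signatures = sprintf("%d[%s]", x$anchor_local - sh, x$signal_library),
      mature_seq = dna2rna(x$mature$seq),
      mature_span = sprintf("%d-%d", x$mature_local[1], x$mature_local[2]),
      mature_rpm = rpm_str(x$mature_rpm_by_lib %||%
                             setNames(x$mature$rpm, x$srna_library %||% "srna")),
      star_seq = dna2rna(x$star$seq),
      star_span = sprintf("%d-%d", x$star_local[1], x$star_local[2]),
      star_rpm = rpm_str(x$star_rpm_by_lib %||%
                           setNames(x$star$rpm, x$srna_library %||% "srna")),
      star_mode = x$star_mode,
      ago_status = x$ago_status,
      known_ids = paste(known, collapse = ","),
      novel = if (length(known) == 0L) "yes" else "no",
      mfe = sprintf("%.2f", x$precursor_fold$mfe),
      precursor_seq = dna2rna(x$precursor_seq),
      structure = x$precursor_fold$structure,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

#' Write the report files
#'
#' Writes the master TSV and a text file of precursor sequence/structure
#' blocks, in deterministic (chrom, start, strand) order. With zero records a
#' headers-only TSV is produced.
#'
#' @param report data.frame from [build_report()].
#' @param tsv_path master table path.
#' @param blocks_path precursor block file path (optional, `NULL` skips).
#' @return `tsv_path`, invisibly.
#' @export
write_report <- function(report, tsv_path, blocks_path = NULL) {
  utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(blocks_path)) {
    con <- file(blocks_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(report))) {
      r <- report[i, ]
      writeLines(c(
        sprintf(">%s:%s-%s(%s)%s mature=%s star=%s %s",
                r$chrom, r$start, r$end, r$strand,
                if (r$novel == "yes") " novel" else "",
                r$mature_span, r$star_span,
                if (nzchar(r$known_ids)) r$known_ids else "-"),
        r$precursor_seq,
        sprintf("%s (%s)", r$structure, r$mfe)), con)
    }
  }
  invisible(tsv_path)
}

#' Read back a report TSV
#' @param path report TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE)
}

#' Degradome end-support profile over known precursors
#'
#' For every registered hairpin whose annotated mature can be located by
#' exact substring match, degradome tags are mapped to the hairpin (sense),
#' cleavage signals are called with the hairpin standing in for the genome
#' fragment (same two criteria), and each signal is classified by its nearest
#' duplex end with its signed offset in -3..+3. The four ends are the 5' and
#' 3' ends of the mature (ends 1 and 2) and of the star (ends 3 and 4); the
#' star span is taken from a registered star record when one matches the
#' hairpin, otherwise derived from the hairpin MFE fold by the 2-nt 3'
#' overhang rule. A 3'-end cut leaves its signature one position past the
#' arm, so end reference positions are mature_5', mature_3'+1, star_5',
#' star_3'+1. Signals equidistant from k ends contribute 1/k to each; signals
#' farther than 3 nt from every end are tallied in an `other` bucket so both
#' denominator choices remain computable.
#'
#' @param mirbase `mirbase_set`.
#' @param deg_libs list of pre-treated degradome libraries.
#' @inheritParams call_signals
#' @param engine folding engine for hairpins without a registered star.
#' @return list with `per_precursor` (named list of 4 x 7 count matrices,
#'   ends x offsets, plus an `other` attribute), `aggregate` (summed matrix),
#'   `other` (total off-end weight), `n_signals` (classified signal count),
#'   `n_profiled`, `n_skipped`.
#' @export
end_support_profile <- function(mirbase, deg_libs, flank_w = 50L, ratio = 5,
                                rank_k = 12L, engine = "auto") {
  if (inherits(deg_libs, "mir_library")) deg_libs <- list(deg_libs)
  idxs <- lapply(deg_libs, tag_index)
  offsets <- -3:3
  mk_mat <- function() matrix(0, nrow = 4, ncol = 7,
                              dimnames = list(c("mature_5p", "mature_3p",
                                                "star_5p", "star_3p"),
                                              as.character(offsets)))
  per <- list()
  agg <- mk_mat()
  other <- 0
  n_signals <- 0
  n_skipped <- 0L
  hp_by_prec <- match_matures_to_hairpins(mirbase)
  for (hid in names(mirbase$hairpins)) {
    hp <- mirbase$hairpins[[hid]]
    loc <- hp_by_prec[[hid]]
    if (is.null(loc)) {
      warning("cannot locate a registered mature on hairpin ", hid,
              "; record skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    m5 <- loc$mature[1]; m3 <- loc$mature[2]
    if (is.null(loc$star)) {
      pt <- rna_fold(hp, engine = engine)[[1]]$pair_table
      if (m3 - 2L < 1L || is.na(pt[m3 - 2L]) || is.na(pt[m5])) {
        n_skipped <- n_skipped + 1L; next
      }
      star <- c(pt[m3 - 2L], pt[m5] + 2L)
    } else star <- loc$star
    ref <- c(mature_5p = m5, mature_3p = m3 + 1L,
             star_5p = star[1], star_3p = star[2] + 1L)
    frag <- list(chrom = hid, start = 0L, seq = hp)
    mat <- mk_mat()
    oth <- 0
    for (li in seq_along(deg_libs)) {
      tg <- map_tags(frag, idxs[[li]])
      tg <- tg[tg$strand == "+", ]     # degradome tags are sense to the precursor
      if (nrow(tg) == 0L) next
      sg <- call_signals(tg, flank_w, ratio, rank_k,
                         library_name = deg_libs[[li]]$name)
      for (p in sg$pos) {
        d <- (p + 1L) - ref            # signal pos is 0-based, refs 1-based
        nearest <- which(abs(d) == min(abs(d)))
        if (min(abs(d)) > 3L) { oth <- oth + 1; next }
        w <- 1 / length(nearest)
        for (e in nearest) {
          mat[e, as.character(d[e])] <- mat[e, as.character(d[e])] + w
        }
      }
      n_signals <- n_signals + nrow(sg)
    }
    attr(mat, "other") <- oth
    per[[hid]] <- mat
    agg <- agg + mat
    other <- other + oth
  }
  list(per_precursor = per, aggregate = agg, other = other,
       n_signals = n_signals, n_profiled = length(per), n_skipped = n_skipped)
}

# locate each hairpin's mature (and star, if a second registered mature also
# matches) by exact substring search; NULL when no mature matches
match_matures_to_hairpins <- function(mirbase) {
  out <- list()
  for (hid in names(mirbase$hairpins)) {
    hp <- mirbase$hairpins[[hid]]
    spans <- list()
    for (mid in names(mirbase$matures)) {
      m <- mirbase$matures[[mid]]
      i <- regexpr(m, hp, fixed = TRUE)
      if (i > 0) spans[[mid]] <- c(as.integer(i), as.integer(i) + nchar(m) - 1L)
    }
    if (length(spans) == 0L) { out[hid] <- list(NULL); next }
    # the 5'-most match is the profiled mature; a second, disjoint match on
    # the other arm serves as the registered star
    ord <- order(vapply(spans, `[`, 0L, 1))
    mature <- spans[[ord[1]]]
    star <- NULL
    for (k in ord[-1]) {
      if (spans[[k]][1] > mature[2]) { star <- spans[[k]]; break }
    }
    out[[hid]] <- list(mature = mature, star = star,
                       mature_id = names(spans)[ord[1]])
  }
  out
}

#' Write end-support profiles as TSVs
#'
#' One aggregate frequency table (ends x offsets, plus the off-end bucket)
#' and one long-format per-precursor table.
#'
#' @param profile result of [end_support_profile()].
#' @param aggregate_path,per_precursor_path output paths (`NULL` skips).
#' @return invisibly, `aggregate_path`.
#' @export
write_end_support <- function(profile, aggregate_path,
                              per_precursor_path = NULL) {
  agg <- as.data.frame(profile$aggregate)
  agg <- cbind(end = rownames(agg), agg, stringsAsFactors = FALSE)
  utils::write.table(agg, aggregate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# other\t%g\n# n_signals\t%g\n", profile$other,
              profile$n_signals), file = aggregate_path, append = TRUE)
  if (!is.null(per_precursor_path)) {
    rows <- list()
    for (hid in names(profile$per_precursor)) {
      m <- profile$per_precursor[[hid]]
      df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
      names(df) <- c("end", "offset", "weight")
      df <- df[df$weight > 0, , drop = FALSE]
      if (nrow(df)) rows[[hid]] <- cbind(precursor = hid, df)
    }
    if (length(rows)) {
      utils::write.table(do.call(rbind, rows), per_precursor_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      writeLines("precursor\tend\toffset\tweight", per_precursor_path)
    }
  }
  invisible(aggregate_path)
}
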