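#' Precursor candidate windows around a cleavage signal
#'
#' Dicer cleavage sites sit at either end of the mature or star sequence, and
#' matures are shorter than 30 nt, so a precursor containing the signal must
#' lie either within the L nt downstream plus 30 nt upstream of the site
#' (3'-arm hypothesis) or within the L nt upstream plus 30 nt downstream
#' (5'-arm hypothesis). Both (30+L)-nt windows are emitted, in transcript
#' orientation (strand-adjusted). Windows truncated by a chromosome end are
#' kept if still >= 60 nt; windows containing N are dropped downstream when
#' the sequence is attached.
#'
#' @param sig one signal row (list/data.frame with `chrom`, `strand`, `pos`).
#' @param L window length parameter: length of the species' longest
#'   registered hairpin (must be >= 60).
#' @param chrom_len chromosome length.
#' @return data.frame of up to 2 candidate shells: `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic span), `arm_hypothesis`,
#'   `anchor_local` (1-based position of the cleavage site in the candidate
#'   sequence, transcript orientation), `anchor_pos` (genomic).
#' @export
candidate_windows <- function(sig, L, chrom_len) {
  stopifnot(L >= 60)
  pos <- as.integer(sig$pos)
  if (sig$strand == "+") {
    spans <- list(three_prime_arm = c(pos - 30L, pos + L),
                  five_prime_arm  = c(pos - L, pos + 30L))
  } else {
    spans <- list(three_prime_arm = c(pos - L + 1L, pos + 31L),
                  five_prime_arm  = c(pos - 29L, pos + L + 1L))
  }
  out <- list()
  for (hyp in names(spans)) {
    s <- max(0L, spans[[hyp]][1]); e <- min(as.integer(chrom_len), spans[[hyp]][2])
    if (e - s < 60L) next
    anchor_local <- if (sig$strand == "+") pos - s + 1L else e - pos
    if (anchor_local < 1L || anchor_local > e - s) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = sig$chrom, strand = sig$strand, start = s, end = e,
      arm_hypothesis = hyp, anchor_local = anchor_local, anchor_pos = pos,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# strand-adjusted candidate sequence from the chromosome string
candidate_sequence <- function(chrom_seq, start, end, strand) {
  s <- substr(chrom_seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Stem complementarity of the two 30-nt regions flanking the anchor
#'
#' The precursor's true ends are unknown, so instead of a global hairpin test
#' the two 30-nt regions abutting the cleavage site (one ending at it, one
#' starting at it, in candidate coordinates) are scored on the MFE structure:
#' the score of a region is the fraction of its positions base-paired to a
#' partner *outside* the region. Regions truncated by the candidate edge are
#' scored over their actual length.
#'
#' @param pair_table pair table of the candidate fold.
#' @param anchor_local 1-based anchor position (first nt after the cut).
#' @param region_len region length (default 30).
#' @return named numeric vector `c(upstream=, downstream=)` in `[0, 1]`.
#' @export
stem_complementarity <- function(pair_table, anchor_local, region_len = 30L) {
  n <- length(pair_table)
  if (anchor_local < 1L || anchor_local > n) {
    stop("anchor position lies outside the candidate")
  }
  score <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi < lo) return(0)
    idx <- lo:hi
    partners <- pair_table[idx]
    sum(!is.na(partners) & (partners < lo | partners > hi)) / length(idx)
  }
  c(upstream = score(anchor_local - region_len, anchor_local - 1L),
    downstream = score(anchor_local, anchor_local + region_len - 1L))
}

# does the region's outside pairing fall entirely on one side of the region?
# rejects pseudoknot-like scatter; a locally duplex-like ("classic stem")
# geometry has all partners either upstream or downstream of the region.
stem_one_sided <- function(pair_table, anchor_local, which = c("upstream", "downstream"),
                           region_len = 30L) {
  which <- match.arg(which)
  n <- length(pair_table)
  if (which == "upstream") {
    lo <- max(1L, anchor_local - region_len); hi <- anchor_local - 1L
  } else {
    lo <- anchor_local; hi <- min(n, anchor_local + region_len - 1L)
  }
  if (hi < lo) return(TRUE)
  partners <- pair_table[lo:hi]
  partners <- partners[!is.na(partners)]
  partners <- partners[partners < lo | partners > hi]
  length(partners) == 0L || all(partners < lo) || all(partners > hi)
}

#' Build folded, scored precursor candidates from cleavage signals
#'
#' For each signal (deduplicated to one row per chrom/strand/pos), both
#' candidate windows are extracted, candidates containing N are dropped,
#' all candidate sequences are folded in one batch, and the two stem
#' complementarity scores are attached.
#'
#' @param signals signal table ([scan_signals()] output).
#' @param genome FASTA path or DNAStringSet.
#' @param L window parameter (longest registered hairpin length).
#' @param engine folding engine, see [rna_fold()].
#' @return list of candidate objects (class `mir_candidate`), each a list
#'   with `chrom`, `strand`, `start`, `end`, `seq`, `arm_hypothesis`,
#'   `anchor_local`, `anchor_pos`, `signal_library`, `fold`
#'   (structure/mfe/pair_table), `stem_scores`, `passed` (set by
#'   [filter_candidates()]).
#' @export
build_candidates <- function(signals, genome, L, engine = "auto") {
  gen <- load_genome(genome)
  chrom_seqs <- setNames(as.character(gen), names(gen))
  sig <- data.table::as.data.table(signals)
  if (nrow(sig) == 0L) return(list())
  # one anchor per genomic key; per-library provenance collapsed to a list
  sig <- sig[, list(library = paste(sort(unique(library)), collapse = ",")),
             by = c("chrom", "strand", "pos")]
  shells <- list()
  for (i in seq_len(nrow(sig))) {
    s <- sig[i]
    cw <- candidate_windows(s, L, nchar(chrom_seqs[[s$chrom]]))
    if (is.null(cw)) next
    for (j in seq_len(nrow(cw))) {
      w <- cw[j, ]
      sq <- candidate_sequence(chrom_seqs[[w$chrom]], w$start, w$end, w$strand)
      if (grepl("[^ACGT]", sq)) next
      shells[[length(shells) + 1L]] <- list(
        chrom = w$chrom, strand = w$strand, start = w$start, end = w$end,
        seq = sq, arm_hypothesis = w$arm_hypothesis,
        anchor_local = w$anchor_local, anchor_pos = w$anchor_pos,
        signal_library = s$library)
    }
  }
  if (length(shells) == 0L) return(list())
  folds <- rna_fold(vapply(shells, `[[`, "", "seq"), engine = engine,
                    ids = vapply(shells, function(x)
                      sprintf("%s:%d-%d(%s)", x$chrom, x$start, x$end, x$strand), ""))
  for (i in seq_along(shells)) {
    shells[[i]]$fold <- folds[[i]]
    shells[[i]]$stem_scores <- stem_complementarity(folds[[i]]$pair_table,
                                                    shells[[i]]$anchor_local)
    class(shells[[i]]) <- "mir_candidate"
  }
  shells
}

#' Retain hairpin-plausible candidates
#'
#' A candidate passes when at least one of its two 30-nt stem regions has
#' complementarity strictly greater than `threshold` (default 0.70) *and*
#' that region's partners all fall on one side of it (classic stem-loop
#' geometry rather than pseudoknot-like scatter). Candidates identical in
#' (chrom, strand, genomic span) are deduplicated.
#'
#' @param cands list of candidates from [build_candidates()].
#' @param threshold complementarity threshold, strict inequality
#'   (default 0.70).
#' @return list of passing candidates, `passed = TRUE` set on each.
#' @export
filter_candidates <- function(cands, threshold = 0.70) {
  seen <- character(0)
  out <- list()
  for (cand in cands) {
    sc <- cand$stem_scores
    ok <- FALSE
    for (side in c("upstream", "downstream")) {
      if (sc[[side]] > threshold &&
          stem_one_sided(cand$fold$pair_table, cand$anchor_local, side)) {
        ok <- TRUE; break
      }
    }
    if (!ok) next
    key <- sprintf("%s:%d-%d:%s", cand$chrom, cand$start, cand$end, cand$strand)
    if (key %in% seen) next
    seen <- c(seen, key)
    cand$passed <- TRUE
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Dump candidates as a TSV
#'
#' Genomic span 1-based inclusive, strand, anchor position (1-based), both
#' stem scores, MFE and dot-bracket string.
#'
#' @param cands list of candidates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cands, path) {
  df <- data.frame(
    chrom = vapply(cands, `[[`, "", "chrom"),
    start = vapply(cands, function(x) x$start + 1L, 0L),
    end = vapply(cands, `[[`, 0L, "end"),
    strand = vapply(cands, `[[`, "", "strand"),
    anchor = vapply(cands, function(x) x$anchor_pos + 1L, 0L),
    arm_hypothesis = vapply(cands, `[[`, "", "arm_hypothesis"),
    stem_upstream = sprintf("%.4f", vapply(cands, function(x) x$stem_scores[["upstream"]], 0)),
    stem_downstream = sprintf("%.4f", vapply(cands, function(x) x$stem_scores[["downstream"]], 0)),
    mfe = sprintf("%.2f", vapply(cands, function(x) x$fold$mfe, 0)),
    structure = vapply(cands, function(x) x$fold$structure, ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
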