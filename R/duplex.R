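# sentinel for "no duplex could be called here", carrying the reason
no_call <- function(reason) structure(list(reason = reason), class = "mir_nocall")

#' Is an object a successful duplex call?
#' @param x object returned by [call_duplex()] or [trim_precursor()].
#' @return logical scalar.
#' @export
is_duplex_call <- function(x) inherits(x, "mir_duplex")

#' Map small-RNA reads onto a precursor candidate
#'
#' Exact, full-length placements of reads of miRNA-plausible length on the
#' sense strand of the candidate (candidates already carry the genomic
#' strand; antisense sRNAs are outside the biogenesis model).
#'
#' @param candidate a `mir_candidate` (needs `$seq`), or any list with `seq`.
#' @param lib pre-treated sRNA `mir_library`, or a prebuilt [srna_index()].
#' @param len_min,len_max read length bounds (defaults 18 and 25 nt).
#' @return data.table of placements: `seq`, `count`, `rpm`, `start`, `end`
#'   (1-based inclusive candidate-local coordinates).
#' @export
map_srna <- function(candidate, lib, len_min = 18L, len_max = 25L) {
  idx <- if (inherits(lib, "srna_index")) lib else srna_index(lib, len_min, len_max)
  subj <- Biostrings::DNAString(candidate$seq)
  res <- list()
  for (grp in idx$groups) {
    si <- Biostrings::startIndex(Biostrings::matchPDict(grp$pd, subj))
    nh <- lengths(si)
    if (sum(nh) == 0L) next
    which_pat <- rep(grp$idx, nh)
    wdt <- nchar(idx$reads$seq[grp$idx[1]])
    st <- unlist(si, use.names = FALSE)
    res[[length(res) + 1L]] <- data.table(
      seq = idx$reads$seq[which_pat],
      count = idx$reads$count[which_pat],
      rpm = idx$reads$rpm[which_pat],
      start = st,
      end = st + wdt - 1L)
  }
  if (length(res) == 0L) {
    return(data.table(seq = character(), count = integer(), rpm = numeric(),
                      start = integer(), end = integer()))
  }
  rbindlist(res)
}

#' Exact-match index for sRNA placements (sense strand, length-bounded)
#'
#' @inheritParams map_srna
#' @return opaque index object of class `srna_index`.
#' @export
srna_index <- function(lib, len_min = 18L, len_max = 25L) {
  stopifnot(inherits(lib, "mir_library"))
  reads <- lib$reads
  w <- nchar(reads$seq)
  keep <- which(w >= len_min & w <= len_max)
  groups <- lapply(split(keep, w[keep]), function(idx) {
    list(idx = idx, pd = Biostrings::PDict(Biostrings::DNAStringSet(reads$seq[idx])))
  })
  structure(list(lib_name = lib$name, reads = reads, groups = groups),
            class = "srna_index")
}

#' Cluster sRNA placements into isomiR clusters
#'
#' Single-linkage grouping of placements whose 5' ends differ by at most
#' `max_shift` nt and whose spans overlap — the cluster structure produced by
#' imprecise Dicer cropping. Clusters are sorted by total RPM descending;
#' members within a cluster by RPM descending.
#'
#' @param placements [map_srna()] output for one candidate.
#' @param max_shift maximum 5'-end difference linking two reads (default 3).
#' @return list of clusters, each a list with `reads` (data.table), `span`
#'   (`c(start, end)`, 1-based inclusive), `total_rpm`, `top_read` (list).
#' @export
cluster_reads <- function(placements, max_shift = 3L) {
  if (nrow(placements) == 0L) return(list())
  pl <- data.table::as.data.table(placements)
  setorder(pl, start, end)
  grp <- integer(nrow(pl))
  grp[1] <- 1L
  max_end <- pl$end[1]
  for (i in seq_len(nrow(pl))[-1]) {
    linked <- (pl$start[i] - pl$start[i - 1L] <= max_shift) &&
      (pl$start[i] <= max_end)   # overlaps some earlier member
    grp[i] <- if (linked) grp[i - 1L] else grp[i - 1L] + 1L
    max_end <- if (linked) max(max_end, pl$end[i]) else pl$end[i]
  }
  clusters <- lapply(split(seq_len(nrow(pl)), grp), function(idx) {
    reads <- pl[idx][order(-rpm, start, seq)]
    top <- as.list(reads[1])
    list(reads = reads, span = c(min(reads$start), max(reads$end)),
         total_rpm = sum(reads$rpm), top_read = top)
  })
  clusters[order(-vapply(clusters, `[[`, 0, "total_rpm"))]
}

#' Call a miRNA-miRNA* duplex on a candidate
#'
#' The most abundant isomiR cluster with an end within `anchor_window` nt of
#' the anchoring cleavage signal supplies the mature miRNA (its most abundant
#' read). The expected star is derived from the MFE pair table by the 2-nt 3'
#' overhang rule: `star_5' = pt[mature_3' - 2]`, `star_3' = pt[mature_5'] + 2`
#' (candidate-local 1-based coordinates, transcript orientation). If an sRNA
#' read occupies exactly those coordinates the call is `overhang` mode;
#' otherwise the top read of a cluster overlapping the expected star span is
#' taken as the star (`isomir_fallback`); otherwise there is no call. Both
#' mature and expected star must reside in mostly-paired stem (unpaired
#' fraction <= `max_unpaired`), and mature and star spans must be disjoint.
#'
#' @param candidate a folded `mir_candidate`.
#' @param clusters [cluster_reads()] output for the candidate.
#' @param placements the placements the clusters were built from (used to
#'   look up an exact star read); if `NULL` they are reconstructed from the
#'   clusters.
#' @param max_unpaired maximum unpaired fraction inside the mature/star span
#'   (default 0.5).
#' @param anchor_window mature-cluster anchoring window (default 3 nt),
#'   matching the observed up-to-3-nt migration of Dicer scars.
#' @return a `mir_duplex` list, or a `mir_nocall` object (with a `$reason`
#'   string) when no duplex can be called.
#' @export
call_duplex <- function(candidate, clusters, placements = NULL,
                        max_unpaired = 0.5, anchor_window = 3L) {
  if (length(clusters) == 0L) return(no_call("no_srna_cluster"))
  if (is.null(placements)) {
    placements <- rbindlist(lapply(clusters, `[[`, "reads"))
  }
  anchor <- candidate$anchor_local
  pt <- candidate$fold$pair_table
  n <- length(pt)
  # cleavage positions implied by a read: its 5' end and the position just
  # past its 3' end; the anchor must sit within the window of either
  eligible <- vapply(clusters, function(cl) {
    tr <- cl$top_read
    matched_end(tr$start, tr$end, anchor, anchor_window) != ""
  }, logical(1))
  if (!any(eligible)) return(no_call("no_cluster_at_anchor"))
  cl <- clusters[eligible][[1]]          # clusters are sorted by total_rpm
  mat <- cl$top_read
  m5 <- mat$start; m3 <- mat$end
  if (m3 - 2L < 1L || is.na(pt[m3 - 2L]) || is.na(pt[m5])) {
    return(no_call("mature_end_unpaired"))
  }
  s5 <- pt[m3 - 2L]
  s3 <- pt[m5] + 2L
  if (s5 > s3 || s5 < 1L || s3 > n) return(no_call("star_outside_candidate"))
  if (!(s5 > m3 || s3 < m5)) return(no_call("arms_overlap"))
  unp <- function(lo, hi) mean(is.na(pt[lo:hi]))
  if (unp(m5, m3) > max_unpaired || unp(s5, s3) > max_unpaired) {
    return(no_call("arm_not_stem_resident"))
  }
  exact <- placements[placements$start == s5 & placements$end == s3, ]
  if (nrow(exact) > 0L) {
    exact <- exact[order(-exact$rpm, exact$seq), ]
    star <- as.list(exact[1, ])
    star_mode <- "overhang"
  } else {
    overl <- vapply(clusters, function(x) {
      x$span[1] <= s3 && x$span[2] >= s5 &&
        (x$top_read$start > m3 || x$top_read$end < m5)
    }, logical(1))
    if (!any(overl)) return(no_call("no_star_evidence"))
    star <- clusters[overl][[1]]$top_read
    star_mode <- "isomir_fallback"
  }
  structure(list(
    chrom = candidate$chrom, strand = candidate$strand,
    cand_start = candidate$start, cand_end = candidate$end,
    seq = candidate$seq, fold = candidate$fold,
    anchor_local = anchor, anchor_pos = candidate$anchor_pos,
    signal_library = candidate$signal_library %||% "",
    matched_end = matched_end(m5, m3, anchor, anchor_window),
    mature = list(seq = mat$seq, start = m5, end = m3,
                  rpm = mat$rpm, count = mat$count),
    star = list(seq = star$seq, start = star$start, end = star$end,
                rpm = star$rpm, count = star$count),
    expected_star = c(s5, s3),
    star_mode = star_mode, ago_status = "not_tested",
    trimmed = FALSE), class = "mir_duplex")
}

# which end of a read (if any) explains the anchor cleavage position:
# "five_prime" if the cut sits at the read's 5' end, "three_prime" if just
# past its 3' end, "" otherwise
matched_end <- function(start, end, anchor, window = 3L) {
  if (abs(start - anchor) <= window) "five_prime"
  else if (abs(end + 1L - anchor) <= window) "three_prime"
  else ""
}

#' Trim a called precursor to the duplex plus 5-nt flanks
#'
#' The reported precursor spans the mature and star sequences plus 5
#' additional nt at both ends, clipped at the candidate boundary. The trimmed
#' sequence is refolded and the call retained only if the duplex geometry
#' still holds on the refold (exact 2-nt 3' overhangs for `overhang` calls;
#' expected-star agreement within 3 nt for fallback calls).
#'
#' @param call a `mir_duplex` from [call_duplex()].
#' @param engine folding engine, see [rna_fold()].
#' @param flank trimming flank (default 5 nt).
#' @return updated `mir_duplex` with `precursor_*` fields, or a `mir_nocall`
#'   object when the refold breaks the duplex.
#' @export
trim_precursor <- function(call, engine = "auto", flank = 5L) {
  n <- nchar(call$seq)
  m5 <- call$mature$start; m3 <- call$mature$end
  s5 <- call$star$start; s3 <- call$star$end
  tstart <- max(1L, min(m5, s5) - flank)
  tend <- min(n, max(m3, s3) + flank)
  tseq <- substr(call$seq, tstart, tend)
  fold <- rna_fold(tseq, engine = engine)[[1]]
  sh <- tstart - 1L
  m5t <- m5 - sh; m3t <- m3 - sh; s5t <- s5 - sh; s3t <- s3 - sh
  pt <- fold$pair_table
  nt <- length(pt)
  ok <- FALSE
  if (m3t - 2L >= 1L && m3t <= nt && !is.na(pt[m3t - 2L]) && !is.na(pt[m5t])) {
    e5 <- pt[m3t - 2L]; e3 <- pt[m5t] + 2L
    ok <- if (call$star_mode == "overhang") {
      e5 == s5t && e3 == s3t
    } else {
      abs(e5 - s5t) <= 3L && abs(e3 - s3t) <= 3L
    }
  }
  if (!ok) return(no_call("refold_broke_duplex"))
  # genomic span of the trimmed precursor (0-based half-open)
  if (call$strand == "+") {
    gspan <- c(call$cand_start + tstart - 1L, call$cand_start + tend)
  } else {
    gspan <- c(call$cand_end - tend, call$cand_end - tstart + 1L)
  }
  call$precursor_seq <- tseq
  call$precursor_fold <- fold
  call$precursor_gstart <- gspan[1]
  call$precursor_gend <- gspan[2]
  call$precursor_local <- c(tstart, tend)
  call$mature_local <- c(m5t, m3t)
  call$star_local <- c(s5t, s3t)
  call$trimmed <- TRUE
  call
}

# genomic 0-based half-open span of a candidate-local 1-based interval
local_to_genomic <- function(call, lo, hi) {
  if (call$strand == "+") {
    c(call$cand_start + lo - 1L, call$cand_start + hi)
  } else {
    c(call$cand_end - hi, call$cand_end - lo + 1L)
  }
}

#' AGO-enrichment filter
#'
#' A duplex passes when the mature or the star sequence is present in the
#' AGO-IP library above `min_rpm` (default 1 RPM) *and* its AGO abundance is
#' at least `fold` (default 3) times its abundance in the matched control
#' library (a sequence absent from the control passes the fold test).
#'
#' @param call a `mir_duplex`.
#' @param ago_lib,control_lib pre-treated `mir_library` objects; `NULL`
#'   `ago_lib` leaves the call `not_tested`.
#' @param min_rpm AGO abundance floor (default 1 RPM, strict >).
#' @param fold AGO/control enrichment factor (default 3, `>=`).
#' @return the call with `ago_status` set to `"enriched"`, `"rejected"` or
#'   `"not_tested"`.
#' @export
ago_filter <- function(call, ago_lib, control_lib = NULL,
                       min_rpm = 1.0, fold = 3.0) {
  if (is.null(ago_lib)) {
    call$ago_status <- "not_tested"
    return(call)
  }
  lookup <- function(lib, s) {
    if (is.null(lib)) return(0)
    i <- match(s, lib$reads$seq)
    if (is.na(i)) 0 else lib$reads$rpm[i]
  }
  passes <- function(s) {
    a <- lookup(ago_lib, s)
    ctl <- lookup(control_lib, s)
    a > min_rpm && a >= fold * ctl
  }
  call$ago_status <- if (passes(call$mature$seq) || passes(call$star$seq)) {
    "enriched"
  } else "rejected"
  call
}

#' Detect duplexes across all retained candidates and sRNA libraries
#'
#' Each sRNA library is processed independently and the resulting calls are
#' unioned, deduplicated by (chrom, strand, mature span, star span) with
#' per-library RPM columns retained.
#'
#' @param candidates list of passing candidates ([filter_candidates()]).
#' @param srna_libs list of pre-treated sRNA `mir_library` objects.
#' @param ago_lib,control_lib optional AGO-IP pair for [ago_filter()].
#' @param len_min,len_max sRNA length bounds.
#' @param max_unpaired stem-residency ceiling (default 0.5).
#' @param ago_min_rpm,ago_fold AGO filter parameters (defaults 1 RPM, 3x).
#' @param engine folding engine for the trim refold.
#' @param keep_rejected keep AGO-rejected calls in the result (flagged) or
#'   drop them (default drop when an AGO library is given).
#' @return list of `mir_duplex` calls; attribute `reasons` tabulates why
#'   candidates yielded no call.
#' @export
detect_duplexes <- function(candidates, srna_libs, ago_lib = NULL,
                            control_lib = NULL, len_min = 18L, len_max = 25L,
                            max_unpaired = 0.5, ago_min_rpm = 1.0,
                            ago_fold = 3.0, engine = "auto",
                            keep_rejected = FALSE) {
  if (inherits(srna_libs, "mir_library")) srna_libs <- list(srna_libs)
  idxs <- lapply(srna_libs, srna_index, len_min = len_min, len_max = len_max)
  calls <- list()
  reasons <- character(0)
  for (cand in candidates) {
    for (li in seq_along(srna_libs)) {
      pl <- map_srna(cand, idxs[[li]], len_min, len_max)
      cl <- cluster_reads(pl)
      call <- call_duplex(cand, cl, pl, max_unpaired = max_unpaired)
      if (!inherits(call, "mir_duplex")) { reasons <- c(reasons, call$reason); next }
      call <- trim_precursor(call, engine = engine)
      if (!inherits(call, "mir_duplex")) { reasons <- c(reasons, call$reason); next }
      call <- ago_filter(call, ago_lib, control_lib, ago_min_rpm, ago_fold)
      if (call$ago_status == "rejected" && !keep_rejected) {
        reasons <- c(reasons, "ago_rejected"); next
      }
      call$srna_library <- srna_libs[[li]]$name
      calls[[length(calls) + 1L]] <- call
    }
  }
  merged <- merge_duplex_calls(calls)
  attr(merged, "reasons") <- table(reasons)
  merged
}

# union calls across libraries/candidates; one record per genomic duplex,
# per-library RPMs kept as named vectors
merge_duplex_calls <- function(calls) {
  if (length(calls) == 0L) return(list())
  keys <- vapply(calls, function(x) {
    mg <- local_to_genomic(x, x$mature$start, x$mature$end)
    sg <- local_to_genomic(x, x$star$start, x$star$end)
    sprintf("%s:%s:%d-%d:%d-%d", x$chrom, x$strand, mg[1], mg[2], sg[1], sg[2])
  }, "")
  out <- list()
  for (k in unique(keys)) {
    grp <- calls[keys == k]
    call <- grp[[1]]
    libs <- vapply(grp, function(x) x$srna_library %||% "srna", "")
    mrpm <- setNames(vapply(grp, function(x) x$mature$rpm, 0), libs)
    srpm <- setNames(vapply(grp, function(x) x$star$rpm, 0), libs)
    keep <- !duplicated(libs)      # same duplex seen in overlapping fragments
    call$mature_rpm_by_lib <- mrpm[keep][order(names(mrpm[keep]))]
    call$star_rpm_by_lib <- srpm[keep][order(names(srpm[keep]))]
    if (any(vapply(grp, `[[`, "", "ago_status") == "enriched")) {
      call$ago_status <- "enriched"
    }
    out[[length(out) + 1L]] <- call
  }
  # deterministic genomic order
  ord <- order(vapply(out, `[[`, "", "chrom"),
               vapply(out, function(x) local_to_genomic(x, x$mature$start,
                                                        x$mature$end)[1], 0L),
               vapply(out, `[[`, "", "strand"))
  out[ord]
}
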