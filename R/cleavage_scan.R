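#' Build an exact-matching index for a pre-treated library
#'
#' Groups the library's distinct sequences by width and builds
#' [Biostrings::PDict] objects for the forward and reverse-complement
#' orientations, so that repeated [map_tags()] calls over many genome
#' fragments do not rebuild the dictionaries.
#'
#' @param lib a `mir_library`.
#' @return opaque index object (class `tag_index`).
#' @export
tag_index <- function(lib) {
  stopifnot(inherits(lib, "mir_library"))
  reads <- lib$reads
  w <- nchar(reads$seq)
  groups <- lapply(split(seq_len(nrow(reads)), w), function(idx) {
    fwd <- Biostrings::DNAStringSet(reads$seq[idx])
    list(idx = idx,
         fwd = Biostrings::PDict(fwd),
         rev = Biostrings::PDict(Biostrings::reverseComplement(fwd)))
  })
  structure(list(lib_name = lib$name, reads = reads, groups = groups),
            class = "tag_index")
}

#' Map library tags exactly onto a genome fragment (both strands)
#'
#' Every exact, full-length occurrence of every tag is reported; a tag mapping
#' to several positions keeps all of them. On the minus strand the tag's 5'
#' end is the highest genomic coordinate of its span.
#'
#' @param fragment one row of [fragment_genome()] output (or a list with
#'   `chrom`, `start`, `seq`).
#' @param lib a `mir_library`, or a prebuilt [tag_index()].
#' @return data.table with columns `seq`, `count`, `rpm`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic span) and `five_prime_pos`.
#' @export
map_tags <- function(fragment, lib) {
  idx <- if (inherits(lib, "tag_index")) lib else tag_index(lib)
  subj <- Biostrings::DNAString(fragment$seq)
  frag_start <- as.integer(fragment$start)
  res <- list()
  for (grp in idx$groups) {
    for (orient in c("+", "-")) {
      pd <- if (orient == "+") grp$fwd else grp$rev
      si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      nh <- lengths(si)
      if (sum(nh) == 0L) next
      which_pat <- rep(grp$idx, nh)
      wdt <- nchar(idx$reads$seq[grp$idx[1]])
      st <- unlist(si, use.names = FALSE) - 1L + frag_start
      en <- st + wdt
      res[[length(res) + 1L]] <- data.table(
        seq = idx$reads$seq[which_pat],
        count = idx$reads$count[which_pat],
        rpm = idx$reads$rpm[which_pat],
        chrom = fragment$chrom,
        strand = orient,
        start = st, end = en,
        five_prime_pos = if (orient == "+") st else en - 1L)
    }
  }
  if (length(res) == 0L) {
    return(data.table(seq = character(), count = integer(), rpm = numeric(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      five_prime_pos = integer()))
  }
  rbindlist(res)
}

#' Call degradome cleavage signals on one fragment
#'
#' A genomic position with at least one mapped tag 5' end is emitted as a
#' cleavage signal when it passes both extraction criteria:
#'
#' 1. *local dominance* — the averaged RPM of the distinct tags whose 5' ends
#'    map to the position is at least `ratio` (default 5) times the averaged
#'    RPM over the tag-bearing positions in the `flank_w`-nt regions on either
#'    side (positions carrying no tag do not enter the baseline; if no
#'    flanking position carries a tag the criterion passes vacuously);
#' 2. *fragment prominence* — the most abundant tag at the position ranks
#'    within the top `rank_k` (default 12) distinct tags mapped to the
#'    fragment on that strand, ranked by RPM descending with competition
#'    ranking for ties.
#'
#' @param tags output of [map_tags()] for one fragment and one library
#'   (both strands may be present; they are processed independently).
#' @param flank_w flank half-width in nt (default 50).
#' @param ratio local-dominance factor (default 5).
#' @param rank_k fragment-prominence rank cutoff (default 12).
#' @param stat how tag abundances at a position are combined: `"mean"`
#'   (averaged RPM per distinct tag, default) or `"sum"`.
#' @param library_name recorded in the `library` column (defaults to "").
#' @return data.table with `chrom`, `strand`, `pos`, `mean_rpm`, `peak_rank`,
#'   `n_tags`, `library`, ordered by strand then position.
#' @export
call_signals <- function(tags, flank_w = 50L, ratio = 5, rank_k = 12L,
                         stat = c("mean", "sum"), library_name = "") {
  stat <- match.arg(stat)
  if (flank_w <= 0L) stop("flank_w must be positive")
  if (ratio <= 0) stop("ratio must be positive")
  if (rank_k < 1L) stop("rank_k must be >= 1")
  empty <- data.table(chrom = character(), strand = character(),
                      pos = integer(), mean_rpm = numeric(),
                      peak_rank = integer(), n_tags = integer(),
                      library = character())
  if (nrow(tags) == 0L) return(empty)
  tags <- data.table::as.data.table(tags)
  out <- list()
  for (str in unique(tags$strand)) {
    st <- tags[strand == str]
    # distinct tags on this fragment+strand, competition-ranked by RPM:
    # rank(r) = 1 + #(distinct tags with rpm strictly greater than r)
    dtag_rpm_sorted <- sort(unique(st[, list(seq, rpm)])$rpm)
    nd <- length(dtag_rpm_sorted)
    pos_stats <- st[, list(
      mean_rpm = if (stat == "mean") mean(rpm) else sum(rpm),
      n_tags = .N,
      top_tag_rpm = max(rpm)), by = "five_prime_pos"]
    setorder(pos_stats, five_prime_pos)
    p <- pos_stats$five_prime_pos
    v <- pos_stats$mean_rpm
    cs <- c(0, cumsum(v))
    lo <- findInterval(p - flank_w - 0.5, p) + 1L
    hi <- findInterval(p + flank_w + 0.5, p)
    flank_n <- hi - lo              # window count minus the position itself
    flank_sum <- cs[hi + 1L] - cs[lo] - v
    # ">= ratio times" must pass at exact equality; integer read counts make
    # such ties common, so guard the comparison against floating-point
    # association order with a small relative tolerance
    baseline <- ratio * (flank_sum / pmax(flank_n, 1L))
    pass1 <- flank_n == 0L | v >= baseline * (1 - 1e-9)
    peak_rank <- nd - findInterval(pos_stats$top_tag_rpm, dtag_rpm_sorted) + 1L
    pass2 <- peak_rank <= rank_k
    keep <- pass1 & pass2
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.table(
      chrom = st$chrom[1], strand = str, pos = p[keep],
      mean_rpm = v[keep], peak_rank = peak_rank[keep],
      n_tags = pos_stats$n_tags[keep], library = library_name)
  }
  if (length(out) == 0L) return(empty)
  res <- rbindlist(out)
  setorder(res, strand, pos)
  res
}

#' Scan a whole genome for degradome cleavage signals
#'
#' Fragments the genome (10,000 nt / 500-nt overlap), maps each degradome
#' library onto every fragment on both strands, calls signals per
#' (fragment, strand, library), deduplicates signals re-discovered inside
#' fragment overlaps by their genomic key, and unions signals across
#' libraries keeping per-library evidence rows.
#'
#' @param genome FASTA path or DNAStringSet.
#' @param deg_libs list of pre-treated degradome `mir_library` objects.
#' @inheritParams call_signals
#' @param fragment_len,overlap fragment geometry (defaults 10,000/500).
#' @return data.table of signals (one row per chrom/strand/pos/library).
#' @export
scan_signals <- function(genome, deg_libs, flank_w = 50L, ratio = 5,
                         rank_k = 12L, stat = "mean",
                         fragment_len = 10000L, overlap = 500L) {
  if (inherits(deg_libs, "mir_library")) deg_libs <- list(deg_libs)
  frags <- fragment_genome(genome, fragment_len, overlap)
  idxs <- lapply(deg_libs, tag_index)
  sigs <- list()
  for (fi in seq_len(nrow(frags))) {
    frag <- frags[fi, ]
    for (li in seq_along(deg_libs)) {
      tg <- map_tags(frag, idxs[[li]])
      if (nrow(tg) == 0L) next
      s <- call_signals(tg, flank_w, ratio, rank_k, stat,
                        library_name = deg_libs[[li]]$name)
      if (nrow(s)) sigs[[length(sigs) + 1L]] <- s
    }
  }
  if (length(sigs) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), mean_rpm = numeric(),
                      peak_rank = integer(), n_tags = integer(),
                      library = character()))
  }
  res <- unique(rbindlist(sigs), by = c("chrom", "strand", "pos", "library"))
  setorder(res, chrom, strand, pos, library)
  res
}

#' Write signals as a BED-like TSV
#'
#' Columns: chrom, start, end (`pos`, `pos + 1`, 0-based half-open),
#' name = source library, score = mean RPM, strand.
#'
#' @param signals signal table from [call_signals()]/[scan_signals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signals_bed <- function(signals, path) {
  bed <- data.frame(chrom = signals$chrom, start = signals$pos,
                    end = signals$pos + 1L, name = signals$library,
                    score = sprintf("%.4f", signals$mean_rpm),
                    strand = signals$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
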