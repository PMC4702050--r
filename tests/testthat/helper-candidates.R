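# Construct a folded precursor candidate hosting a perfect inverted-repeat
# hairpin, with known mature/star duplex geometry, for duplex-calling tests.
#
# Layout (1-based local coordinates):
#   [flank_l][ arm (stem) ][ loop ][ revcomp(arm) ][flank_r]
# mature sits on the 5' arm at `offset` (0-based within the arm); the star
# implied by the 2-nt 3' overhang rule on a perfect stem is
# [n + 3 - m3, n + 3 - m5] relative to the hairpin, where n is hairpin length.
perfect_candidate <- function(stem = 30L, loop = 8L, flank_l = 15L,
                              flank_r = 15L, offset = 5L, mature_len = 21L,
                              seed = 101, anchor_at = c("mature_5p", "mature_3p")) {
  anchor_at <- match.arg(anchor_at)
  set.seed(seed)
  arm <- paste(sample(c("A", "C", "G", "T"), stem, replace = TRUE),
               collapse = "")
  lp <- paste(sample(c("A", "C", "G", "T"), loop, replace = TRUE),
              collapse = "")
  hairpin <- paste0(arm, lp, revcomp(arm))
  seqfl <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  cand_seq <- paste0(seqfl(flank_l), hairpin, seqfl(flank_r))
  n <- nchar(hairpin)
  m5 <- flank_l + offset + 1L
  m3 <- flank_l + offset + mature_len
  s5 <- flank_l + (n + 3L - (offset + mature_len))
  s3 <- flank_l + (n + 3L - (offset + 1L))
  anchor <- if (anchor_at == "mature_5p") m5 else m3 + 1L
  fold <- rna_fold(cand_seq)[[1]]
  cand <- structure(list(
    chrom = "chrT", strand = "+", start = 1000L,
    end = 1000L + nchar(cand_seq), seq = cand_seq,
    arm_hypothesis = "three_prime_arm", anchor_local = anchor,
    anchor_pos = 1000L + anchor - 1L, signal_library = "degT",
    fold = fold,
    stem_scores = stem_complementarity(fold$pair_table, anchor)),
    class = "mir_candidate")
  list(candidate = cand, m5 = m5, m3 = m3, s5 = s5, s3 = s3,
       mature_seq = substr(cand_seq, m5, m3),
       star_seq = substr(cand_seq, s5, s3))
}

# placements table in the shape map_srna() produces
placements_table <- function(cand_seq, spans, counts) {
  total <- sum(counts)
  data.table::data.table(
    seq = vapply(spans, function(sp) substr(cand_seq, sp[1], sp[2]), ""),
    count = as.integer(counts),
    rpm = counts / total * 1e6,
    start = vapply(spans, `[`, 0L, 1),
    end = vapply(spans, `[`, 0L, 2))
}

# small collapsed-read library object without file IO
library_from_df <- function(df, kind = "srna", name = "testlib") {
  pretreat_library(df, kind = kind, name = name)
}
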