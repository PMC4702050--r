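test_that("candidate windows follow the (30+L) rule on both strands", {
  sig <- list(chrom = "c", strand = "+", pos = 5000L)
  cw <- candidate_windows(sig, L = 350L, chrom_len = 100000L)
  expect_equal(nrow(cw), 2L)
  a <- cw[cw$arm_hypothesis == "three_prime_arm", ]
  b <- cw[cw$arm_hypothesis == "five_prime_arm", ]
  expect_equal(c(a$start, a$end), c(4970L, 5350L))
  expect_equal(c(b$start, b$end), c(4650L, 5030L))
  expect_equal(a$anchor_local, 31L)
  expect_equal(b$anchor_local, 351L)

  # near the chromosome start only the downstream window survives
  cw2 <- candidate_windows(list(chrom = "c", strand = "+", pos = 10L),
                           L = 350L, chrom_len = 100000L)
  expect_equal(nrow(cw2), 1L)
  expect_equal(cw2$arm_hypothesis, "three_prime_arm")
  expect_equal(c(cw2$start, cw2$end), c(0L, 360L))

  # minus strand: same two span lengths, mirrored
  cw3 <- candidate_windows(list(chrom = "c", strand = "-", pos = 5000L),
                           L = 350L, chrom_len = 100000L)
  expect_equal(sort(cw3$end - cw3$start), c(380L, 380L))
  a3 <- cw3[cw3$arm_hypothesis == "three_prime_arm", ]
  expect_equal(c(a3$start, a3$end), c(4651L, 5031L))
  expect_equal(a3$anchor_local, 31L)

  expect_error(candidate_windows(sig, L = 59L, chrom_len = 1e5), "L >= 60")
})

test_that("window algebra: both windows cover the anchor, length <= 30+L", {
  set.seed(51)
  for (rep in 1:40) {
    L <- sample(60:400, 1)
    chrom_len <- sample(1000:50000, 1)
    sig <- list(chrom = "c", strand = sample(c("+", "-"), 1),
                pos = sample(chrom_len, 1) - 1L)
    cw <- candidate_windows(sig, L, chrom_len)
    if (is.null(cw)) next
    expect_true(all(cw$end - cw$start <= 30L + L))
    expect_lte(sum(cw$end - cw$start), 2L * (30L + L))
    expect_true(all(cw$start <= sig$pos & sig$pos < cw$end))
    expect_true(all(cw$anchor_local >= 1L &
                    cw$anchor_local <= cw$end - cw$start))
  }
})

test_that("stem complementarity counts pairing out of the 30-nt region", {
  # synthetic pair table: 100-nt molecule, positions 31..60 fully paired
  # with 61..90 (partner outside the upstream region)
  pt <- rep(NA_integer_, 100)
  pt[31:60] <- 121L - (31:60)
  pt[61:90] <- 121L - (61:90)
  sc <- stem_complementarity(pt, anchor_local = 61L)
  expect_equal(unname(sc["upstream"]), 1.0)
  # downstream region [61, 90] pairs back into [31, 60]: also outside itself
  expect_equal(unname(sc["downstream"]), 1.0)

  # a region inside a loop scores zero
  sc2 <- stem_complementarity(rep(NA_integer_, 100), anchor_local = 50L)
  expect_equal(unname(sc2), c(0, 0))

  # 24 of 30 positions paired across the stem: 0.8, passes the 0.70 default
  pt3 <- rep(NA_integer_, 120)
  pt3[31:54] <- 151L - (31:54)
  pt3[97:120] <- 151L - (97:120)
  sc3 <- stem_complementarity(pt3, anchor_local = 61L)
  expect_equal(unname(sc3["upstream"]), 24 / 30)

  # pairs inside the region itself do not count
  pt4 <- rep(NA_integer_, 100)
  pt4[41:50] <- 101L - (41:50)  # 41..50 pairs 51..60, all inside [31,60]
  pt4[51:60] <- 101L - (51:60)
  expect_equal(unname(stem_complementarity(pt4, 61L)["upstream"]), 0)

  expect_error(stem_complementarity(pt, 500L), "outside")
})

test_that("the filter applies a strict threshold and deduplicates spans", {
  mk_cand <- function(up, down, start = 0L) {
    pt <- rep(NA_integer_, 120)
    n_up <- round(30 * up); n_down <- round(30 * down)
    if (n_up > 0) pt[31:(30 + n_up)] <- 120L - seq_len(n_up)
    if (n_down > 0) pt[61:(60 + n_down)] <- 20L - seq_len(n_down)
    structure(list(chrom = "c", strand = "+", start = start,
                   end = start + 120L, seq = strrep("A", 120),
                   arm_hypothesis = "three_prime_arm", anchor_local = 61L,
                   anchor_pos = start + 60L, signal_library = "d",
                   fold = list(structure = strrep(".", 120), mfe = 0,
                               pair_table = pt),
                   stem_scores = stem_complementarity(pt, 61L)),
              class = "mir_candidate")
  }
  c_hi <- mk_cand(0.9, 0.2)
  c_at <- mk_cand(0.7, 0.65, start = 200L)
  expect_equal(unname(c_at$stem_scores["upstream"]), 0.70)
  kept <- filter_candidates(list(c_hi, c_at), threshold = 0.70)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$start, 0L)

  # identical genomic spans collapse to one candidate
  expect_equal(length(filter_candidates(list(c_hi, c_hi))), 1L)
})

test_that("planted hairpins pass the 0.70 filter; shuffled sequences mostly fail", {
  set.seed(52)
  L <- 68L
  passes <- function(seqs, anchor) {
    folds <- rna_fold(seqs)
    vapply(seq_along(seqs), function(i) {
      sc <- stem_complementarity(folds[[i]]$pair_table, anchor)
      any(sc > 0.70)
    }, logical(1))
  }
  planted <- vapply(1:10, function(i) {
    arm <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    loop <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
    flank <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                   collapse = "")
    paste0(flank, arm, loop, revcomp(arm))   # anchor at hairpin start
  }, "")
  expect_true(all(passes(planted, anchor = 31L)))

  shuffled <- vapply(planted, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  shuffled <- c(shuffled, vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 98, replace = TRUE), collapse = ""), ""))
  expect_lt(mean(passes(shuffled, anchor = 31L)), 0.20)
})

test_that("candidate folds are involutions and respect genome identity", {
  set.seed(53)
  chrom <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
  p <- tempfile(fileext = ".fa"); writeLines(c(">c1", chrom), p)
  sig <- data.frame(chrom = "c1", strand = c("+", "-"), pos = c(1500L, 2000L),
                    library = "d")
  cands <- build_candidates(sig, p, L = 80L)
  expect_gt(length(cands), 0L)
  for (cand in cands) {
    pt <- cand$fold$pair_table
    paired <- which(!is.na(pt))
    expect_true(all(pt[pt[paired]] == paired))
    gseq <- substr(chrom, cand$start + 1L, cand$end)
    if (cand$strand == "-") gseq <- revcomp(gseq)
    expect_identical(cand$seq, gseq)
  }
})
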