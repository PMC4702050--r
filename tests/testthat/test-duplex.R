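test_that("sRNA mapping is sense-only, exact and length-bounded", {
  pc <- perfect_candidate()
  cand <- pc$candidate
  reads <- data.frame(
    seq = c(pc$mature_seq,                                  # 21 nt, sense
            substr(cand$seq, 40, 70),                       # 31 nt: too long
            revcomp(pc$mature_seq)),                        # antisense
    count = c(10L, 5L, 7L))
  lib <- library_from_df(reads, "srna")
  pl <- map_srna(cand, lib)
  expect_true(pc$mature_seq %in% pl$seq)
  expect_false(any(nchar(pl$seq) > 25L))
  expect_equal(pl$start[pl$seq == pc$mature_seq], pc$m5)
  expect_equal(pl$end[pl$seq == pc$mature_seq], pc$m3)
})

test_that("isomiR clustering is single-linkage over 5'-end shifts <= 3", {
  pl <- placements_table(strrep("ACGT", 60),
                         spans = list(c(100L, 120L), c(100L, 121L)),
                         counts = c(10, 5))
  expect_equal(length(cluster_reads(pl)), 1L)

  pl2 <- placements_table(strrep("ACGT", 60),
                          spans = list(c(100L, 120L), c(101L, 121L),
                                       c(103L, 123L), c(160L, 180L)),
                          counts = c(10, 5, 3, 8))
  cl <- cluster_reads(pl2)
  expect_equal(length(cl), 2L)
  spans5 <- sort(unname(vapply(cl, function(x) x$span[1], 0L)))
  expect_equal(spans5, c(100L, 160L))
  # clusters ordered by total RPM descending; members by RPM descending
  expect_gte(cl[[1]]$total_rpm, cl[[2]]$total_rpm)
  expect_equal(cl[[1]]$top_read$start, 100L)

  expect_equal(length(cluster_reads(pl2[0, ])), 0L)
})

test_that("duplexes are called by the 2-nt 3' overhang rule", {
  pc <- perfect_candidate()
  cand <- pc$candidate
  pl <- placements_table(cand$seq,
                         spans = list(c(pc$m5, pc$m3),          # mature
                                      c(pc$m5 + 1L, pc$m3 + 1L),
                                      c(pc$s5, pc$s3),          # exact star
                                      c(pc$s5 + 1L, pc$s3 + 1L)),
                         counts = c(100, 40, 25, 10))
  call <- call_duplex(cand, cluster_reads(pl), pl)
  expect_true(is_duplex_call(call))
  expect_equal(call$star_mode, "overhang")
  expect_equal(call$mature$seq, pc$mature_seq)
  expect_equal(call$star$seq, pc$star_seq)
  expect_equal(c(call$star$start, call$star$end), c(pc$s5, pc$s3))
  # both duplex ends show 2-nt 3' overhangs on the pair table
  pt <- cand$fold$pair_table
  expect_equal(pt[call$mature$end - 2L], call$star$start)
  expect_equal(pt[call$mature$start], call$star$end - 2L)
  # arms disjoint
  expect_true(call$star$start > call$mature$end ||
              call$star$end < call$mature$start)
})

test_that("removing the exact star read flips to the isomiR* fallback, mature unchanged", {
  pc <- perfect_candidate()
  cand <- pc$candidate
  pl_full <- placements_table(cand$seq,
                              spans = list(c(pc$m5, pc$m3),
                                           c(pc$s5, pc$s3),
                                           c(pc$s5 + 1L, pc$s3 + 1L)),
                              counts = c(100, 25, 10))
  pl_nostar <- pl_full[pl_full$start != pc$s5 | pl_full$end != pc$s3, ]
  call_full <- call_duplex(cand, cluster_reads(pl_full), pl_full)
  call_fb <- call_duplex(cand, cluster_reads(pl_nostar), pl_nostar)
  expect_equal(call_full$star_mode, "overhang")
  expect_equal(call_fb$star_mode, "isomir_fallback")
  expect_equal(call_fb$mature$seq, call_full$mature$seq)
  expect_equal(c(call_fb$star$start, call_fb$star$end),
               c(pc$s5 + 1L, pc$s3 + 1L))
})

test_that("reads only in the loop, or no star evidence, yield no call", {
  pc <- perfect_candidate(flank_l = 15L, stem = 30L, loop = 8L)
  cand <- pc$candidate
  loop_start <- 15L + 31L
  pl_loop <- placements_table(cand$seq,
                              spans = list(c(loop_start - 6L, loop_start + 14L)),
                              counts = 50)
  res <- call_duplex(cand, cluster_reads(pl_loop), pl_loop)
  expect_false(is_duplex_call(res))

  pl_mat <- placements_table(cand$seq, spans = list(c(pc$m5, pc$m3)),
                             counts = 100)
  res2 <- call_duplex(cand, cluster_reads(pl_mat), pl_mat)
  expect_false(is_duplex_call(res2))
  expect_equal(res2$reason, "no_star_evidence")
})

test_that("precursor trimming keeps the duplex plus 5-nt flanks and refolds", {
  pc <- perfect_candidate()
  cand <- pc$candidate
  pl <- placements_table(cand$seq,
                         spans = list(c(pc$m5, pc$m3), c(pc$s5, pc$s3)),
                         counts = c(100, 25))
  call <- call_duplex(cand, cluster_reads(pl), pl)
  trimmed <- trim_precursor(call)
  expect_true(is_duplex_call(trimmed))
  expect_equal(trimmed$precursor_local,
               c(min(pc$m5, pc$s5) - 5L, max(pc$m3, pc$s3) + 5L))
  expect_equal(nchar(trimmed$precursor_seq),
               diff(trimmed$precursor_local) + 1L)
  # duplex geometry holds on the refold
  ptt <- trimmed$precursor_fold$pair_table
  expect_equal(ptt[trimmed$mature_local[2] - 2L], trimmed$star_local[1])
  expect_equal(ptt[trimmed$mature_local[1]], trimmed$star_local[2] - 2L)
  # genomic span arithmetic (plus strand)
  expect_equal(trimmed$precursor_gstart,
               cand$start + trimmed$precursor_local[1] - 1L)
  expect_equal(trimmed$precursor_gend,
               cand$start + trimmed$precursor_local[2])
})

test_that("trimming clips at the candidate edge", {
  pc <- perfect_candidate(flank_l = 2L, offset = 2L)  # mature 5 nt from the edge
  cand <- pc$candidate
  pl <- placements_table(cand$seq,
                         spans = list(c(pc$m5, pc$m3), c(pc$s5, pc$s3)),
                         counts = c(100, 25))
  call <- call_duplex(cand, cluster_reads(pl), pl)
  trimmed <- trim_precursor(call)
  expect_true(is_duplex_call(trimmed))
  expect_equal(trimmed$precursor_local[1], 1L)   # clipped, not negative
})

test_that("AGO enrichment applies the 1 RPM floor and 3x control ratio", {
  pc <- perfect_candidate()
  cand <- pc$candidate
  pl <- placements_table(cand$seq,
                         spans = list(c(pc$m5, pc$m3), c(pc$s5, pc$s3)),
                         counts = c(100, 25))
  call <- call_duplex(cand, cluster_reads(pl), pl)
  mklib <- function(seqs, rpms, kind) {
    structure(list(name = kind, kind = kind,
                   reads = data.frame(seq = seqs, count = 1L, rpm = rpms),
                   total_raw = 1L), class = "mir_library")
  }
  # 9 RPM vs 3 RPM control: 9 >= 3*3 and 9 > 1 -> enriched
  c1 <- ago_filter(call, mklib(pc$mature_seq, 9, "ago"),
                   mklib(pc$mature_seq, 3, "control"))
  expect_equal(c1$ago_status, "enriched")
  # 0.5 RPM, absent from control: below the 1 RPM floor -> rejected
  c2 <- ago_filter(call, mklib(pc$mature_seq, 0.5, "ago"),
                   mklib("GGGG", 1, "control"))
  expect_equal(c2$ago_status, "rejected")
  # 9 RPM vs 4 RPM: fails the 3x ratio -> rejected
  c3 <- ago_filter(call, mklib(pc$mature_seq, 9, "ago"),
                   mklib(pc$mature_seq, 4, "control"))
  expect_equal(c3$ago_status, "rejected")
  # no AGO library
  c4 <- ago_filter(call, NULL, NULL)
  expect_equal(c4$ago_status, "not_tested")
})

test_that("detect_duplexes unions calls across libraries with per-library RPM", {
  pc <- perfect_candidate()
  reads <- data.frame(seq = c(pc$mature_seq, pc$star_seq), count = c(80L, 20L))
  libA <- pretreat_library(reads, "srna", name = "tissueA")
  libB <- pretreat_library(rbind(reads, data.frame(seq = "ACGTACGTACGTACGTACG",
                                                   count = 100L)),
                           "srna", name = "tissueB")
  calls <- detect_duplexes(list(pc$candidate), list(libA, libB))
  expect_equal(length(calls), 1L)
  expect_setequal(names(calls[[1]]$mature_rpm_by_lib), c("tissueA", "tissueB"))
  expect_equal(unname(calls[[1]]$mature_rpm_by_lib["tissueA"]), 8e5)
})
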