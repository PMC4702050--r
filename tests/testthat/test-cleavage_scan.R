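random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

test_that("tags map exactly on both strands with correct 5' end positions", {
  set.seed(41)
  frag_seq <- random_seq(1000)
  tag <- "ACGTACGTACGTACGTACGT"
  frag_seq <- paste0(substr(frag_seq, 1, 100), tag,
                     substr(frag_seq, 121, 200), revcomp(tag),
                     substr(frag_seq, 241, 1000))
  # tag now at offset 100 (+) and its reverse complement at offset 200
  frag <- list(chrom = "c1", start = 5000L, seq = frag_seq)
  lib <- library_from_df(data.frame(seq = tag, count = 4L), "degradome")
  tg <- map_tags(frag, lib)
  plus <- tg[tg$strand == "+", ]
  minus <- tg[tg$strand == "-", ]
  expect_true(5100L %in% plus$five_prime_pos)
  expect_true(5219L %in% minus$five_prime_pos)
  expect_equal(minus$five_prime_pos, minus$end - 1L)

  absent <- library_from_df(data.frame(seq = strrep("ACGT", 5), count = 1L),
                            "degradome")
  expect_equal(nrow(map_tags(list(chrom = "c1", start = 0L,
                                  seq = strrep("T", 500)), absent)), 0L)
})

test_that("multi-mapping tags report every locus", {
  set.seed(42)
  tag <- "GATTACAGATTACAGATTAC"
  frag_seq <- paste0(random_seq(50), tag, random_seq(80), tag, random_seq(50))
  frag <- list(chrom = "c1", start = 0L, seq = frag_seq)
  lib <- library_from_df(data.frame(seq = tag, count = 2L), "degradome")
  tg <- map_tags(frag, lib)
  expect_gte(sum(tg$strand == "+"), 2L)
})

test_that("local dominance and fragment rank criteria gate signal calls", {
  mk_tags <- function(rpms, positions) {
    data.table::data.table(
      seq = vapply(seq_along(rpms), function(i)
        paste0(strrep("A", 19), c("C", "G", "T", "A")[1 + i %% 4], i), ""),
      count = 1L, rpm = rpms, chrom = "c1", strand = "+",
      start = positions, end = positions + 20L, five_prime_pos = positions)
  }
  # single tagged position, empty flanks: vacuous pass, rank 1
  s1 <- call_signals(mk_tags(5, 100L))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$peak_rank, 1L)

  # mean 50 vs flanking means 5 and 15: flank mean 10, 50 >= 5*10 -> emitted
  s2 <- call_signals(mk_tags(c(50, 5, 15), c(500L, 470L, 530L)))
  expect_true(500L %in% s2$pos)
  # but 50 < 5 * mean(5, 25) = 75 -> rejected
  s3 <- call_signals(mk_tags(c(50, 5, 25), c(500L, 470L, 530L)))
  expect_false(500L %in% s3$pos)

  # 13 distinct tags, strictly decreasing abundance, positions far apart:
  # the weakest position carries rank 13 -> rejected; rank 12 survives
  tg <- mk_tags(seq(130, 10, by = -10), seq(0L, 2400L, by = 200L))
  s4 <- call_signals(tg)
  expect_false(2400L %in% s4$pos)
  expect_true(2200L %in% s4$pos)

  expect_error(call_signals(mk_tags(5, 100L), flank_w = 0L), "flank_w")
  expect_error(call_signals(mk_tags(5, 100L), ratio = -1), "ratio")
})

test_that("signal calling matches the brute-force oracle on random fixtures", {
  set.seed(43)
  for (rep in 1:20) {
    frag_seq <- random_seq(sample(500:2000, 1))
    n_tags <- sample(5:50, 1)
    starts <- sample(nchar(frag_seq) - 25L, n_tags, replace = TRUE)
    reads <- data.frame(
      seq = substring(frag_seq, starts, starts + sample(17:22, n_tags,
                                                        replace = TRUE)),
      count = sample(c(rep(1, 6), 5, 20, 60), n_tags, replace = TRUE))
    lib <- library_from_df(reads, "degradome")
    frag <- list(chrom = "cx", start = 0L, seq = frag_seq)
    tg <- map_tags(frag, lib)
    got <- call_signals(tg)
    want <- oracle_signals(oracle_map_tags(frag_seq, 0L, "cx", lib$reads))
    expect_equal(nrow(got), nrow(want))
    expect_equal(paste(got$strand, got$pos),
                 paste(want$strand, want$pos))
    expect_equal(got$mean_rpm, want$mean_rpm, tolerance = 1e-9)
    expect_equal(got$peak_rank, want$peak_rank)
  }
})

test_that("reverse-complementing fragment and tags mirrors the signals", {
  set.seed(44)
  frag_seq <- random_seq(800)
  starts <- sample(700, 12)
  reads <- data.frame(seq = substring(frag_seq, starts, starts + 19L),
                      count = sample(c(1, 1, 2, 30), 12, replace = TRUE))
  lib <- library_from_df(reads, "degradome")
  f_fwd <- list(chrom = "c", start = 0L, seq = frag_seq)
  f_rev <- list(chrom = "c", start = 0L, seq = revcomp(frag_seq))
  s_fwd <- call_signals(map_tags(f_fwd, lib))
  s_rev <- call_signals(map_tags(f_rev, lib))
  mirror <- function(s, len) {
    data.frame(strand = ifelse(s$strand == "+", "-", "+"),
               pos = (len - 1L) - s$pos)
  }
  m <- mirror(s_fwd, nchar(frag_seq))
  expect_setequal(paste(m$strand, m$pos), paste(s_rev$strand, s_rev$pos))
})

test_that("raising ratio or lowering rank_k never adds a signal", {
  set.seed(45)
  frag_seq <- random_seq(1500)
  starts <- sample(1400, 30)
  reads <- data.frame(seq = substring(frag_seq, starts, starts + 19L),
                      count = sample(c(1, 1, 1, 4, 15, 40), 30, replace = TRUE))
  lib <- library_from_df(reads, "degradome")
  tg <- map_tags(list(chrom = "c", start = 0L, seq = frag_seq), lib)
  key <- function(s) paste(s$strand, s$pos)
  base <- call_signals(tg, ratio = 5, rank_k = 12L)
  expect_true(all(key(call_signals(tg, ratio = 8, rank_k = 12L)) %in% key(base)))
  expect_true(all(key(call_signals(tg, ratio = 5, rank_k = 4L)) %in% key(base)))
  loose <- call_signals(tg, ratio = 2, rank_k = 30L)
  expect_true(all(key(base) %in% key(loose)))
})

test_that("whole-genome scan deduplicates signals found in fragment overlaps", {
  set.seed(46)
  chrom <- random_seq(12000)
  tag <- substr(chrom, 9701, 9720)     # inside the 500-nt overlap region
  lib <- library_from_df(data.frame(seq = tag, count = 50L), "degradome")
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", chrom), p)
  sg <- scan_signals(p, list(lib))
  expect_false(any(duplicated(sg[, c("chrom", "strand", "pos", "library")])))
  expect_true(9700L %in% sg$pos[sg$strand == "+"])
})
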