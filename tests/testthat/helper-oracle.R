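# Independent brute-force reimplementations used as oracles. These are kept
# deliberately naive (character operations and explicit loops) and share no
# code with the package paths they check.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# all exact occurrences of every read on both strands of a fragment
oracle_map_tags <- function(frag_seq, frag_start, chrom, reads) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    sq <- reads$seq[i]
    w <- nchar(sq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sq else oracle_revcomp(sq)
      hits <- gregexpr(pat, frag_seq, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      # gregexpr skips overlapping occurrences; rescan after each hit start
      all_hits <- integer(0)
      from <- 1L
      repeat {
        h <- regexpr(pat, substr(frag_seq, from, nchar(frag_seq)), fixed = TRUE)
        if (h < 0) break
        all_hits <- c(all_hits, from + h - 1L)
        from <- from + h
      }
      for (p1 in all_hits) {
        start0 <- frag_start + p1 - 1L
        out[[length(out) + 1L]] <- data.frame(
          seq = sq, count = reads$count[i], rpm = reads$rpm[i],
          chrom = chrom, strand = strand,
          start = start0, end = start0 + w,
          five_prime_pos = if (strand == "+") start0 else start0 + w - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq = character(), count = integer(), rpm = numeric(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      five_prime_pos = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# brute-force signal caller: explicit per-position loops
oracle_signals <- function(tags, flank_w = 50L, ratio = 5, rank_k = 12L) {
  res <- list()
  for (strand in unique(tags$strand)) {
    st <- tags[tags$strand == strand, , drop = FALSE]
    dt <- unique(st[, c("seq", "rpm")])
    means <- tapply(st$rpm, st$five_prime_pos, mean)
    tops <- tapply(st$rpm, st$five_prime_pos, max)
    positions <- sort(unique(st$five_prime_pos))
    key <- as.character(positions)
    for (p in positions) {
      v <- unname(means[[as.character(p)]])
      flank <- positions[positions != p & abs(positions - p) <= flank_w]
      # "ratio times or more": equality passes; same relative guard against
      # floating-point association order as the specification of the check
      pass1 <- if (length(flank) == 0L) TRUE else {
        v >= ratio * mean(means[as.character(flank)]) * (1 - 1e-9)
      }
      top <- unname(tops[[as.character(p)]])
      rnk <- 1L + sum(dt$rpm > top)
      if (pass1 && rnk <= rank_k) {
        res[[length(res) + 1L]] <- data.frame(
          strand = strand, pos = p, mean_rpm = v, peak_rank = rnk,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(strand = character(), pos = integer(),
                      mean_rpm = numeric(), peak_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df[order(df$strand, df$pos), , drop = FALSE]
}
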