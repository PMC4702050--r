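#' Specification for a synthetic miRNA-discovery test world
#'
#' Describes a random genome with planted canonical hairpin precursors, the
#' degradome library carrying Dicer-end scars over Poisson background, and
#' sRNA libraries with isomiR clouds over the planted arms. All generators
#' derive their randomness from `seed`, so a fixed spec reproduces
#' byte-identical fixtures.
#'
#' Planted hairpins are perfect inverted repeats: a `stem_len`-bp stem
#' hosting the mature on the 5' arm at offset `mature_offset`, a `loop_len`
#' loop, and the star on the 3' arm at exact 2-nt 3' overhang geometry.
#'
#' @param n_hairpins number of planted hairpins (default 20).
#' @param genome_len chromosome length in nt (default 500,000).
#' @param n_chrom number of chromosomes (default 1).
#' @param mature_len mature miRNA length (default 21).
#' @param stem_len perfect stem length in bp (default 30).
#' @param loop_len loop length (default 8).
#' @param mature_offset 0-based offset of the mature within the 5' arm
#'   (default 5; must leave the whole mature inside the stem).
#' @param scar_rpm_fold planted-scar abundance over the unit background
#'   count (default 10).
#' @param isomir_spread maximum 5'-end offset of generated isomiRs
#'   (default 2).
#' @param background_tag_rate distinct background degradome tags per kb per
#'   strand (default 600). Background tags are singletons (count 1) placed
#'   as a Poisson process; they carry the flanking baseline against which
#'   the 5x local-dominance criterion is measured. The density is chosen so
#'   that the 2-3 sibling scar positions of a planted duplex that fall
#'   inside a 50-nt flank are diluted by unit-count background: with m
#'   occupied flank slots the baseline is about (10k + m)/(m + k) for k
#'   sibling scars, which stays below scar_rpm_fold/5 = 2 with high
#'   probability once E[m] = 100(1 - exp(-0.6)) ~ 45.
#' @param srna_background_rate distinct background sRNA reads per kb
#'   (default 2).
#' @param seed integer RNG seed.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_hairpins = 20L, genome_len = 500000L, n_chrom = 1L,
                       mature_len = 21L, stem_len = 30L, loop_len = 8L,
                       mature_offset = 5L, scar_rpm_fold = 10,
                       isomir_spread = 2L, background_tag_rate = 600,
                       srna_background_rate = 2, seed = 1L) {
  stopifnot(n_hairpins >= 0, genome_len > 0, n_chrom >= 1,
            mature_len > 0, stem_len > 0, loop_len >= 3,
            mature_offset >= 2, scar_rpm_fold > 0, isomir_spread >= 0,
            background_tag_rate >= 0, srna_background_rate >= 0)
  if (mature_offset + mature_len > stem_len) {
    stop("mature (offset + length) must fit inside the stem arm")
  }
  hairpin_len <- 2L * stem_len + loop_len
  if (hairpin_len + 400L > genome_len) {
    stop("hairpin does not fit in the genome with placement margins")
  }
  structure(list(n_hairpins = as.integer(n_hairpins),
                 genome_len = as.integer(genome_len),
                 n_chrom = as.integer(n_chrom),
                 mature_len = as.integer(mature_len),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mature_offset = as.integer(mature_offset),
                 hairpin_len = hairpin_len,
                 scar_rpm_fold = scar_rpm_fold,
                 isomir_spread = as.integer(isomir_spread),
                 background_tag_rate = background_tag_rate,
                 srna_background_rate = srna_background_rate,
                 seed = as.integer(seed)), class = "plant_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the fixture genome with planted hairpins and its truth table
#'
#' Hairpins are placed one per equal-width genome bin (disjoint by
#' construction, margins away from chromosome ends), each on a random
#' strand. The truth table records, per hairpin, the genomic span, strand,
#' transcript-oriented hairpin/mature/star sequences, their genomic spans
#' (0-based half-open) and the four Dicer scar positions (0-based genomic
#' 5'-end positions of the expected degradome signatures).
#'
#' @param spec a [plant_spec()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `truth` (data.frame).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  chroms <- setNames(vapply(seq_len(spec$n_chrom),
                            function(i) random_dna(spec$genome_len), ""),
                     paste0("chr", seq_len(spec$n_chrom)))
  truth <- list()
  if (spec$n_hairpins > 0L) {
    per_chrom <- diff(round(seq(0, spec$n_hairpins, length.out = spec$n_chrom + 1)))
    hp_i <- 0L
    for (ci in seq_len(spec$n_chrom)) {
      nh <- per_chrom[ci]
      if (nh == 0L) next
      margin <- 200L
      bin <- (spec$genome_len - 2L * margin) %/% nh
      stopifnot(bin > spec$hairpin_len + 100L)
      for (k in seq_len(nh)) {
        hp_i <- hp_i + 1L
        arm <- random_dna(spec$stem_len)
        loop <- random_dna(spec$loop_len)
        hairpin <- paste0(arm, loop, revcomp(arm))
        strand <- sample(c("+", "-"), 1)
        start <- margin + (k - 1L) * bin +
          sample.int(bin - spec$hairpin_len - 100L, 1)
        end <- start + spec$hairpin_len          # 0-based half-open
        planted <- if (strand == "+") hairpin else revcomp(hairpin)
        chroms[ci] <- paste0(substr(chroms[ci], 1, start),
                             planted,
                             substr(chroms[ci], end + 1L, spec$genome_len))
        truth[[hp_i]] <- hairpin_truth_row(
          id = sprintf("hp%03d", hp_i), chrom = names(chroms)[ci],
          strand = strand, start = start, end = end, hairpin = hairpin,
          spec = spec)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  list(genome = chroms, truth = truth)
}

empty_truth <- function() {
  data.frame(id = character(), chrom = character(), strand = character(),
             hp_start = integer(), hp_end = integer(), hp_seq = character(),
             mature_seq = character(), star_seq = character(),
             mature_gstart = integer(), mature_gend = integer(),
             star_gstart = integer(), star_gend = integer(),
             scar_pos = character(), stringsAsFactors = FALSE)
}

# duplex geometry of a planted hairpin, all spans 0-based half-open genomic
hairpin_truth_row <- function(id, chrom, strand, start, end, hairpin, spec) {
  start <- as.integer(start); end <- as.integer(end)
  n <- spec$hairpin_len
  m5 <- spec$mature_offset + 1L                     # 1-based local
  m3 <- spec$mature_offset + spec$mature_len
  s5 <- n + 3L - m3                                 # pt[m3 - 2] on a perfect stem
  s3 <- n + 3L - m5                                 # pt[m5] + 2
  cuts <- c(m5, m3 + 1L, s5, s3 + 1L)               # 1-based local cut sites
  if (strand == "+") {
    to_g <- function(l) start + l - 1L              # local 1-based -> genomic 0-based
    mature_g <- c(to_g(m5), to_g(m3) + 1L)
    star_g <- c(to_g(s5), to_g(s3) + 1L)
  } else {
    to_g <- function(l) end - l                     # 5' end positions on minus
    mature_g <- c(end - m3, end - m5 + 1L)
    star_g <- c(end - s3, end - s5 + 1L)
  }
  data.frame(id = id, chrom = chrom, strand = strand,
             hp_start = start, hp_end = end, hp_seq = hairpin,
             mature_seq = substr(hairpin, m5, m3),
             star_seq = substr(hairpin, s5, s3),
             mature_gstart = mature_g[1], mature_gend = mature_g[2],
             star_gstart = star_g[1], star_gend = star_g[2],
             scar_pos = paste(vapply(cuts, to_g, 0L), collapse = ","),
             stringsAsFactors = FALSE)
}

# transcript-oriented tag sequence whose 5' end sits at local cut site l
# (1-based on the planted hairpin), extending downstream in transcript space
scar_tag_seq <- function(chrom_seq, row, l, tag_len = 20L) {
  if (row$strand == "+") {
    substr(chrom_seq, row$hp_start + l, row$hp_start + l + tag_len - 1L)
  } else {
    g <- row$hp_end - l                             # 0-based 5'-end position
    revcomp(substr(chrom_seq, g - tag_len + 2L, g + 1L))
  }
}

#' Generate a degradome library over the fixture genome
#'
#' For each planted duplex, one 20-nt tag per duplex end whose 5' end sits
#' exactly at the Dicer cut site, with raw count `scar_rpm_fold` (over the
#' unit background count); plus singleton background tags (count 1) at
#' Poisson-process positions on both strands, `background_tag_rate` tags per
#' kb per strand. All tags are 20 nt, the fixed signature length of
#' PARE-style degradome libraries — so two tags sharing a 5' end are the
#' same sequence and their counts collapse, as in real data.
#'
#' @param spec a [plant_spec()].
#' @param world result of [make_genome()] (genome + truth).
#' @return data.frame of collapsed reads (`seq`, `count`), un-pretreated.
#' @export
make_degradome <- function(spec, world) {
  set.seed(spec$seed + 1L)
  genome <- world$genome
  truth <- world$truth
  seqs <- character(0); counts <- integer(0)
  scar_count <- max(1L, as.integer(round(spec$scar_rpm_fold)))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    cuts_local <- duplex_cut_sites(spec)
    for (l in cuts_local) {
      s <- scar_tag_seq(genome[[row$chrom]], row, l)
      seqs <- c(seqs, s); counts <- c(counts, scar_count)
    }
  }
  for (ci in seq_along(genome)) {
    chrom_seq <- genome[[ci]]
    len <- nchar(chrom_seq)
    n_bg <- round(spec$background_tag_rate * len / 1000)
    if (n_bg == 0) next
    for (strand in c("+", "-")) {
      w <- 20L                                      # PARE signature length
      p <- sample.int(len - 30L, n_bg) + 3L         # 0-based 5'-end positions
      if (strand == "+") {
        s <- substring(chrom_seq, p + 1L, p + w)
      } else {
        p <- p + 25L
        s <- revcomp(substring(chrom_seq, p - w + 2L, p + 1L))
      }
      seqs <- c(seqs, s); counts <- c(counts, rep(1L, n_bg))
    }
  }
  data.frame(seq = seqs, count = counts, stringsAsFactors = FALSE)
}

# 1-based local cut sites of the planted duplex (mature 5', mature 3'+1,
# star 5', star 3'+1)
duplex_cut_sites <- function(spec) {
  n <- spec$hairpin_len
  m5 <- spec$mature_offset + 1L
  m3 <- spec$mature_offset + spec$mature_len
  s5 <- n + 3L - m3
  s3 <- n + 3L - m5
  c(m5, m3 + 1L, s5, s3 + 1L)
}

#' Generate sRNA libraries over the fixture genome
#'
#' The planted mature is the most abundant read over its hairpin (count 100),
#' flanked by isomiRs at 5'-offsets up to `isomir_spread` with geometrically
#' decaying counts (ratio 0.5). Star reads sit at the exact 2-nt 3' overhang
#' coordinates at lower abundance (count 30) with their own isomiR cloud.
#' Background reads (lengths 18-25, count 1 + Pois(0.3)) are scattered
#' uniformly. With `ago = TRUE` a matched AGO-IP / control pair is also
#' produced: the AGO library is mature-enriched (>= 3x the control in RPM),
#' the control is uniform.
#'
#' @param spec a [plant_spec()].
#' @param world result of [make_genome()].
#' @param ago also build the AGO/control pair (default TRUE).
#' @return list with `srna`, and when requested `ago` and `control`, each a
#'   data.frame of collapsed reads.
#' @export
make_srna <- function(spec, world, ago = TRUE) {
  set.seed(spec$seed + 2L)
  genome <- world$genome
  truth <- world$truth
  n <- spec$hairpin_len
  m5 <- spec$mature_offset + 1L
  m3 <- spec$mature_offset + spec$mature_len
  s5 <- n + 3L - m3
  s3 <- n + 3L - m5
  arm_reads <- function(row, lo, hi, base_count) {
    # canonical read plus 5'-shifted isomiRs, constant length
    offs <- if (spec$isomir_spread > 0) {
      c(0L, unlist(lapply(seq_len(spec$isomir_spread), function(d) c(-d, d))))
    } else 0L
    data.frame(
      seq = vapply(offs, function(d)
        local_subseq(genome[[row$chrom]], row, lo + d, hi + d), ""),
      count = as.integer(round(base_count * 0.5^abs(offs))),
      stringsAsFactors = FALSE)
  }
  planted <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    planted[[length(planted) + 1L]] <- arm_reads(row, m5, m3, 100)
    planted[[length(planted) + 1L]] <- arm_reads(row, s5, s3, 30)
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(seq = character(), count = integer(), stringsAsFactors = FALSE)
  bg <- srna_background(spec, genome)
  srna <- rbind(planted, bg)
  out <- list(srna = srna)
  if (ago) {
    mature_seqs <- truth$mature_seq
    star_seqs <- truth$star_seq
    ago_df <- rbind(
      data.frame(seq = mature_seqs, count = rep(50L, length(mature_seqs)),
                 stringsAsFactors = FALSE),
      data.frame(seq = star_seqs, count = rep(5L, length(star_seqs)),
                 stringsAsFactors = FALSE),
      srna_background(spec, genome, unit_counts = TRUE))
    control_df <- rbind(
      data.frame(seq = c(mature_seqs, star_seqs),
                 count = rep(1L, 2L * length(mature_seqs)),
                 stringsAsFactors = FALSE),
      srna_background(spec, genome, unit_counts = TRUE))
    out$ago <- ago_df
    out$control <- control_df
  }
  out
}

local_subseq <- function(chrom_seq, row, lo, hi) {
  if (row$strand == "+") {
    substr(chrom_seq, row$hp_start + lo, row$hp_start + hi)
  } else {
    revcomp(substr(chrom_seq, row$hp_end - hi + 1L, row$hp_end - lo + 1L))
  }
}

srna_background <- function(spec, genome, unit_counts = FALSE) {
  seqs <- character(0); counts <- integer(0)
  for (ci in seq_along(genome)) {
    chrom_seq <- genome[[ci]]
    len <- nchar(chrom_seq)
    n_bg <- round(spec$srna_background_rate * len / 1000)
    if (n_bg == 0) next
    w <- sample(18:25, n_bg, replace = TRUE)
    p <- sample.int(len - 30L, n_bg)
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    s <- substring(chrom_seq, p, p + w - 1L)
    flip <- strand == "-"
    if (any(flip)) s[flip] <- revcomp(s[flip])
    cnt <- if (unit_counts) rep(1L, n_bg) else 1L + stats::rpois(n_bg, 0.3)
    seqs <- c(seqs, s); counts <- c(counts, cnt)
  }
  data.frame(seq = seqs, count = counts, stringsAsFactors = FALSE)
}

#' Write a fixture miRBase-style hairpin/mature pair for the planted set
#'
#' Hairpins are written RNA-side under ids `<prefix>-mir-f###`; matures and
#' stars under `<prefix>-miR-f###-5p` / `-3p`. These are synthetic records
#' emulating the miRBase dialect for the planted hairpins, not database
#' content.
#'
#' @param truth truth table from [make_genome()].
#' @param hairpin_path,mature_path output FASTA paths.
#' @param prefix species prefix (default `"ath"`).
#' @param include row indices of hairpins to register (default all).
#' @return invisibly, a list with the two paths.
#' @export
make_mirbase_files <- function(truth, hairpin_path, mature_path,
                               prefix = "ath", include = seq_len(nrow(truth))) {
  truth <- truth[include, , drop = FALSE]
  ids <- sprintf("%s-mir-f%03d", prefix, seq_len(nrow(truth)))
  writeLines(paste0(">", ids, "\n", dna2rna(truth$hp_seq)), hairpin_path)
  mids <- c(sprintf("%s-miR-f%03d-5p", prefix, seq_len(nrow(truth))),
            sprintf("%s-miR-f%03d-3p", prefix, seq_len(nrow(truth))))
  mseqs <- c(truth$mature_seq, truth$star_seq)
  writeLines(paste0(">", mids, "\n", dna2rna(mseqs)), mature_path)
  invisible(list(hairpin = hairpin_path, mature = mature_path))
}

#' Write a complete fixture set to a directory
#'
#' Produces `genome.fa`, `degradome.tsv`, `srna.fa`, `ago.tsv`,
#' `control.tsv`, `hairpin.fa`, `mature.fa` and `truth.tsv` — the same
#' dialects the readers accept — and returns the paths plus the in-memory
#' truth table.
#'
#' @param spec a [plant_spec()].
#' @param dir output directory (created if needed).
#' @param ago write the AGO/control pair (default TRUE).
#' @return list of paths (`genome`, `degradome`, `srna`, `ago`, `control`,
#'   `hairpin`, `mature`, `truth_path`) plus `truth`.
#' @export
write_fixture_set <- function(spec, dir, ago = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  world <- make_genome(spec)
  deg <- make_degradome(spec, world)
  sr <- make_srna(spec, world, ago = ago)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    degradome = file.path(dir, "degradome.tsv"),
    srna = file.path(dir, "srna.fa"),
    hairpin = file.path(dir, "hairpin.fa"),
    mature = file.path(dir, "mature.fa"),
    truth_path = file.path(dir, "truth.tsv"))
  writeLines(paste0(">", names(world$genome), "\n", unname(world$genome)),
             paths$genome)
  write_collapsed_reads(deg, paths$degradome, format = "tsv")
  write_collapsed_reads(sr$srna, paths$srna, format = "fasta")
  if (ago) {
    paths$ago <- file.path(dir, "ago.tsv")
    paths$control <- file.path(dir, "control.tsv")
    write_collapsed_reads(sr$ago, paths$ago, format = "tsv")
    write_collapsed_reads(sr$control, paths$control, format = "tsv")
  }
  if (nrow(world$truth) > 0L) {
    make_mirbase_files(world$truth, paths$hairpin, paths$mature)
  } else {
    # background-only worlds still need an L parameter carrier: register a
    # synthetic 80-nt hairpin so the window length is defined
    set.seed(spec$seed + 3L)
    arm <- random_dna(36L)
    hp <- paste0(arm, random_dna(8L), revcomp(arm))
    writeLines(paste0(">ath-mir-fsyn\n", dna2rna(hp)), paths$hairpin)
    writeLines(paste0(">ath-miR-fsyn\n",
                      dna2rna(substr(hp, 6, 26))), paths$mature)
  }
  utils::write.table(world$truth, paths$truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(paths, list(truth = world$truth))
}
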