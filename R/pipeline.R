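#' Pipeline run configuration
#'
#' Bundles input paths and parameters. All defaults follow the published
#' extraction criteria: 5x local dominance, top-12 fragment rank, 70% stem
#' complementarity (strict), 18-25-nt sRNAs, 1 RPM / 3x AGO enrichment, and
#' the fixed 10,000-nt / 500-nt fragment geometry.
#'
#' @param genome genome FASTA path.
#' @param degradome character vector of degradome collapsed-read paths.
#' @param srna character vector of sRNA collapsed-read paths.
#' @param hairpin,mature miRBase-style FASTA paths (provide the species' L
#'   parameter and the known-miRNA annotation).
#' @param outdir output directory (created; holds checkpoints and reports).
#' @param ago,control optional AGO-IP and matched control library paths.
#' @param species_prefix miRBase species prefix filter (default keep all).
#' @param L override for the window parameter L; default is the longest
#'   registered hairpin length.
#' @param flank_w,ratio,rank_k signal-calling parameters (see
#'   [call_signals()]).
#' @param stem_threshold stem-complementarity cutoff, strict (default 0.70).
#' @param len_min,len_max sRNA length bounds (defaults 18, 25).
#' @param max_unpaired duplex stem-residency ceiling (default 0.5).
#' @param ago_min_rpm,ago_fold AGO filter parameters (defaults 1 RPM, 3x).
#' @param keep_rejected keep AGO-rejected duplexes in the report.
#' @param engine folding engine (see [rna_fold()]).
#' @param workers fragment-level worker processes (default 1).
#' @param fragment_len,overlap fragment geometry (fixed defaults
#'   10,000/500).
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, degradome, srna, hairpin, mature, outdir,
                       ago = NULL, control = NULL, species_prefix = "",
                       L = NULL, flank_w = 50L, ratio = 5, rank_k = 12L,
                       stem_threshold = 0.70, len_min = 18L, len_max = 25L,
                       max_unpaired = 0.5, ago_min_rpm = 1.0, ago_fold = 3.0,
                       keep_rejected = FALSE, engine = "auto", workers = 1L,
                       fragment_len = 10000L, overlap = 500L) {
  cfg <- list(genome = genome, degradome = degradome, srna = srna,
              hairpin = hairpin, mature = mature, outdir = outdir,
              ago = ago, control = control, species_prefix = species_prefix,
              L = L, flank_w = as.integer(flank_w), ratio = ratio,
              rank_k = as.integer(rank_k), stem_threshold = stem_threshold,
              len_min = as.integer(len_min), len_max = as.integer(len_max),
              max_unpaired = max_unpaired, ago_min_rpm = ago_min_rpm,
              ago_fold = ago_fold, keep_rejected = isTRUE(keep_rejected),
              engine = engine, workers = as.integer(workers),
              fragment_len = as.integer(fragment_len),
              overlap = as.integer(overlap))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full discovery pipeline
#'
#' Stages, in workflow order: pre-treat all libraries; load the miRBase set
#' (defines L); fragment the genome; per fragment, map degradome tags on both
#' strands, call cleavage signals, extract and fold the two (30+L)-nt
#' candidates per signal, apply the stem-complementarity filter, map and
#' cluster sRNA reads on passing candidates, call duplexes by the 2-nt 3'
#' overhang rule, trim precursors and apply the optional AGO filter. Per
#' fragment results are checkpointed as RDS files in `outdir/checkpoints`;
#' a rerun (or [resume_pipeline()]) recomputes only fragments without a
#' valid checkpoint, and the merged report is byte-identical to an
#' uninterrupted run. A manifest (parameters, input checksums, package
#' version) is written to `outdir/manifest.json`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @param .stop_after stop (simulating an interruption) after this many
#'   fragments have been processed; used to exercise resume semantics.
#' @return invisibly, a list with `report` (data.frame), `calls`, `signals`,
#'   `paths` (report/bed/manifest paths); `NULL` when interrupted via
#'   `.stop_after`.
#' @export
run_pipeline <- function(config, quiet = TRUE, .stop_after = Inf) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(config$outdir, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  write_manifest(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  deg_libs <- lapply(seq_along(config$degradome), function(i)
    pretreat_library(config$degradome[[i]], kind = "degradome"))
  srna_libs <- lapply(seq_along(config$srna), function(i)
    pretreat_library(config$srna[[i]], kind = "srna"))
  ago_lib <- if (!is.null(config$ago))
    pretreat_library(config$ago, kind = "ago") else NULL
  control_lib <- if (!is.null(config$control))
    pretreat_library(config$control, kind = "control") else NULL
  mirbase <- load_mirbase(config$hairpin, config$mature, config$species_prefix)
  L <- config$L %||% mirbase$longest_hairpin_len
  if (L < 60L) stop("window parameter L must be >= 60 (got ", L, ")")

  gen <- load_genome(config$genome)
  chrom_seqs <- setNames(as.character(gen), names(gen))
  frags <- fragment_genome(gen, config$fragment_len, config$overlap)
  say("fragments: %d; L = %d", nrow(frags), L)

  deg_idx <- lapply(deg_libs, tag_index)
  srna_idx <- lapply(srna_libs, srna_index,
                     len_min = config$len_min, len_max = config$len_max)

  ck_path <- function(fi) file.path(config$outdir, "checkpoints",
                                    sprintf("%s_%09d.rds", frags$chrom[fi],
                                            frags$start[fi]))
  todo <- seq_len(nrow(frags))
  done_mask <- vapply(todo, function(fi) {
    p <- ck_path(fi)
    if (!file.exists(p)) return(FALSE)
    ok <- tryCatch({ readRDS(p); TRUE }, error = function(e) FALSE)
    if (!ok) warning("corrupted checkpoint ", basename(p),
                     "; fragment will be reprocessed")
    ok
  }, logical(1))
  pending <- todo[!done_mask]
  if (is.finite(.stop_after)) pending <- utils::head(pending, .stop_after)

  worker <- function(fi) {
    frag <- frags[fi, ]
    res <- tryCatch(
      process_fragment(frag, chrom_seqs[[frag$chrom]], deg_libs, deg_idx,
                       srna_libs, srna_idx, ago_lib, control_lib, L, config),
      error = function(e) {
        warning("fragment ", frag$chrom, ":", frag$start, " failed: ",
                conditionMessage(e))
        list(signals = NULL, calls = list(), error = conditionMessage(e))
      })
    saveRDS(res, ck_path(fi))
    fi
  }
  if (length(pending)) {
    if (config$workers > 1L) {
      parallel::mclapply(pending, worker, mc.cores = config$workers)
    } else {
      lapply(pending, worker)
    }
  }
  if (is.finite(.stop_after) && any(!file.exists(vapply(todo, ck_path, "")))) {
    say("interrupted after %d fragments", .stop_after)
    return(invisible(NULL))
  }

  results <- lapply(todo, function(fi) readRDS(ck_path(fi)))
  signals <- rbindlist(Filter(Negate(is.null),
                              lapply(results, `[[`, "signals")))
  if (nrow(signals)) {
    signals <- unique(signals, by = c("chrom", "strand", "pos", "library"))
    setorder(signals, chrom, strand, pos, library)
  }
  calls <- merge_duplex_calls(do.call(c, lapply(results, `[[`, "calls")))
  calls <- lapply(calls, annotate_known, mirbase = mirbase)
  report <- build_report(calls)
  paths <- list(report = file.path(config$outdir, "report.tsv"),
                blocks = file.path(config$outdir, "precursors.txt"),
                bed = file.path(config$outdir, "signals.bed"),
                manifest = file.path(config$outdir, "manifest.json"))
  write_report(report, paths$report, paths$blocks)
  write_signals_bed(signals, paths$bed)
  say("calls: %d (report at %s)", nrow(report), paths$report)
  invisible(list(report = report, calls = calls, signals = signals,
                 paths = paths))
}

# all per-fragment work: signals -> candidates -> filter -> duplexes
process_fragment <- function(frag, chrom_seq, deg_libs, deg_idx,
                             srna_libs, srna_idx, ago_lib, control_lib,
                             L, config) {
  sigs <- list()
  for (li in seq_along(deg_libs)) {
    tg <- map_tags(frag, deg_idx[[li]])
    if (nrow(tg) == 0L) next
    s <- call_signals(tg, config$flank_w, config$ratio, config$rank_k,
                      library_name = deg_libs[[li]]$name)
    if (nrow(s)) sigs[[length(sigs) + 1L]] <- s
  }
  if (length(sigs) == 0L) return(list(signals = NULL, calls = list()))
  signals <- rbindlist(sigs)
  cands <- build_candidates_local(signals, chrom_seq, L, config$engine)
  cands <- filter_candidates(cands, config$stem_threshold)
  if (length(cands) == 0L) return(list(signals = signals, calls = list()))
  calls <- detect_duplexes(cands, srna_libs, ago_lib, control_lib,
                           len_min = config$len_min, len_max = config$len_max,
                           max_unpaired = config$max_unpaired,
                           ago_min_rpm = config$ago_min_rpm,
                           ago_fold = config$ago_fold,
                           engine = config$engine,
                           keep_rejected = config$keep_rejected)
  list(signals = signals, calls = calls)
}

# build_candidates against a single already-loaded chromosome string
build_candidates_local <- function(signals, chrom_seq, L, engine) {
  sig <- data.table::as.data.table(signals)
  if (nrow(sig) == 0L) return(list())
  sig <- sig[, list(library = paste(sort(unique(library)), collapse = ",")),
             by = c("chrom", "strand", "pos")]
  shells <- list()
  for (i in seq_len(nrow(sig))) {
    s <- sig[i]
    cw <- candidate_windows(s, L, nchar(chrom_seq))
    if (is.null(cw)) next
    for (j in seq_len(nrow(cw))) {
      w <- cw[j, ]
      sq <- candidate_sequence(chrom_seq, w$start, w$end, w$strand)
      if (grepl("[^ACGT]", sq)) next
      shells[[length(shells) + 1L]] <- list(
        chrom = w$chrom, strand = w$strand, start = w$start, end = w$end,
        seq = sq, arm_hypothesis = w$arm_hypothesis,
        anchor_local = w$anchor_local, anchor_pos = w$anchor_pos,
        signal_library = s$library)
    }
  }
  if (length(shells) == 0L) return(list())
  folds <- rna_fold(vapply(shells, `[[`, "", "seq"), engine = engine)
  for (i in seq_along(shells)) {
    shells[[i]]$fold <- folds[[i]]
    shells[[i]]$stem_scores <- stem_complementarity(folds[[i]]$pair_table,
                                                    shells[[i]]$anchor_local)
    class(shells[[i]]) <- "mir_candidate"
  }
  shells
}

write_manifest <- function(config) {
  inputs <- unlist(config[c("genome", "degradome", "srna", "hairpin",
                            "mature", "ago", "control")], use.names = FALSE)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  checks <- tryCatch(as.list(tools::md5sum(unlist(inputs))),
                     error = function(e) list())
  manifest <- list(
    package = "degradomir",
    version = as.character(utils::packageVersion("degradomir")),
    config = config[setdiff(names(config), "outdir")],
    outdir = config$outdir,
    input_md5 = checks)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Resume an interrupted pipeline run
#'
#' Reconstructs the configuration from `outdir/manifest.json` and reruns the
#' pipeline; fragments with a valid checkpoint are not recomputed, so a
#' resumed run finishes the pending fragments and rewrites the final report,
#' byte-identical to an uninterrupted run. On a completed output directory
#' this is a no-op apart from rewriting identical reports.
#'
#' @param outdir output directory of the interrupted run.
#' @param workers optional worker-count override.
#' @return see [run_pipeline()].
#' @export
resume_pipeline <- function(outdir, workers = NULL) {
  mpath <- file.path(outdir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", outdir,
                                "; nothing to resume")
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cfgl <- m$config
  cfg <- run_config(
    genome = cfgl$genome, degradome = unlist(cfgl$degradome),
    srna = unlist(cfgl$srna), hairpin = cfgl$hairpin, mature = cfgl$mature,
    outdir = outdir, ago = cfgl$ago, control = cfgl$control,
    species_prefix = cfgl$species_prefix %||% "", L = cfgl$L,
    flank_w = cfgl$flank_w, ratio = cfgl$ratio, rank_k = cfgl$rank_k,
    stem_threshold = cfgl$stem_threshold, len_min = cfgl$len_min,
    len_max = cfgl$len_max, max_unpaired = cfgl$max_unpaired,
    ago_min_rpm = cfgl$ago_min_rpm, ago_fold = cfgl$ago_fold,
    keep_rejected = cfgl$keep_rejected, engine = cfgl$engine,
    workers = workers %||% cfgl$workers,
    fragment_len = cfgl$fragment_len, overlap = cfgl$overlap)
  run_pipeline(cfg)
}
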