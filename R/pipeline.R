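pipeline_defaults <- function() {
  list(
    bb_table = NULL,           # path to the building-block CSV (required)
    out_dir = "delscreen_out",
    # library design
    max_mw = 200, banned_flags = character(),
    max_unassigned_stereocenters = 0L,
    codon_length = 8L, d_min = 3L,
    # screen simulation
    n_droplets = 1e5, droplet_rate = 800, bead_lambda = 0.06,
    neg_mu = 100, neg_sigma = 5,
    control_bead_fraction = 0.01, control_inhibition = 1,
    active_map = numeric(), detect_min_inhibition = 0.5,
    reads_per_bead = 20L, sub_error_rate = 0.01,
    # sorter
    k_sigma = 5, t_window = 30, f_bin = 7, min_events = 100L,
    # deconvolution
    max_mismatch = 1L, min_support = 0.5,
    sample_size = 1500L, n_samples = 3L, k_max = 10L,
    enrich_k_min = 3L,
    screen_id = "screen1",
    seed = 1L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (by extension), overlays it on the
#' package defaults, and validates every parameter. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or `NULL`
#'   to start from defaults.
#' @param ... Named overrides applied after the file (same keys).
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- pipeline_defaults()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  dots <- list(...)
  for (src in list(user, dots)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(src)] <- src
  }
  if (is.null(cfg$bb_table))
    stop("config must set `bb_table` (building-block CSV path)",
         call. = FALSE)
  if (length(cfg$active_map) && is.list(cfg$active_map))
    cfg$active_map <- unlist(cfg$active_map)
  # validate numerics before any stage runs
  for (nm in c("max_mw", "codon_length", "d_min", "n_droplets",
               "droplet_rate", "neg_sigma", "k_sigma", "t_window", "f_bin",
               "reads_per_bead", "sample_size", "n_samples", "k_max",
               "enrich_k_min"))
    check_pos(cfg[[nm]], nm)
  for (nm in c("bead_lambda", "max_unassigned_stereocenters", "min_events",
               "max_mismatch"))
    check_nonneg(cfg[[nm]], nm)
  for (nm in c("control_bead_fraction", "control_inhibition",
               "sub_error_rate", "min_support", "detect_min_inhibition"))
    check_frac(cfg[[nm]], nm)
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  log_stage(verbose, stage, "done in %.2f s", proc.time()[["elapsed"]] - t0)
  out
}

#' Run the full screen pipeline
#'
#' Executes design -> simulate -> sort -> decode -> analyze on one
#' configuration: enumerate and filter the library, build the codebook,
#' simulate the droplet screen, sort with the dynamic threshold, sequence
#' and decode the sorted beads, tabulate k classes, estimate the null FDR
#' matrix, and test building-block enrichment. All artifacts are written
#' under `config$out_dir` and a JSON run report is returned (and written).
#' Identical config and seed give identical artifacts; each stage draws its
#' randomness from a stage seed derived via [stage_seed()], so stages can
#' be re-run in isolation from their serialized inputs.
#'
#' @param config A [pipeline_config()] object.
#' @param verbose Emit per-stage progress messages (default TRUE).
#' @return The run report, invisibly: a list with `library_size`,
#'   `codebook`, `screen` (hit rates, Z', flags), `n_sorted_beads`,
#'   `bead_call_rate`, `kclass_top`, `fdr`, `enriched_bbs`, and the paths
#'   of all artifacts.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    codebook = file.path(config$out_dir, "codebook.tsv"),
    events = file.path(config$out_dir, "events.csv"),
    truth = file.path(config$out_dir, "ground_truth.json"),
    decisions = file.path(config$out_dir, "decisions.csv"),
    trace = file.path(config$out_dir, "threshold_trace.csv"),
    histogram = file.path(config$out_dir, "transient_histogram.tsv"),
    reads = file.path(config$out_dir, "hit_reads.fastq"),
    bead_calls = file.path(config$out_dir, "bead_calls.csv"),
    kclass = file.path(config$out_dir, "kclass.csv"),
    fdr = file.path(config$out_dir, "fdr_matrix.csv"),
    enrichment = file.path(config$out_dir, "enrichment.csv"),
    heatmap = file.path(config$out_dir, "heatmap.tsv"),
    report = file.path(config$out_dir, "report.json"))

  # -- design ---------------------------------------------------------------
  des <- run_stage("design", verbose, {
    bb <- read_building_blocks(config$bb_table)
    bb <- filter_building_blocks(
      bb, max_mw = config$max_mw, banned_flags = config$banned_flags,
      max_unassigned_stereocenters = config$max_unassigned_stereocenters)
    starters <- bb[bb$cycle == 1L, ]
    acids <- bb[bb$cycle == 2L, ]
    members <- enumerate_library(starters, acids)
    cb <- build_codebook(members, codon_length = config$codon_length,
                         d_min = config$d_min,
                         seed = stage_seed(config$seed, "design"))
    write_codebook(cb, paths$codebook)
    list(starters = starters, acids = acids, members = members,
         codebook = cb)
  })
  log_stage(verbose, "design", "library of %d members (%d x %d)",
            nrow(des$members), nrow(des$starters), nrow(des$acids))

  # -- simulate -------------------------------------------------------------
  sim <- run_stage("simulate", verbose, {
    par <- screen_params(
      n_droplets = config$n_droplets, droplet_rate = config$droplet_rate,
      bead_lambda = config$bead_lambda, neg_mu = config$neg_mu,
      neg_sigma = config$neg_sigma,
      control_bead_fraction = config$control_bead_fraction,
      control_inhibition = config$control_inhibition,
      active_map = config$active_map,
      detect_min_inhibition = config$detect_min_inhibition,
      seed = stage_seed(config$seed, "simulate"))
    s <- simulate_screen(par, des$members)
    write_events(s$events, paths$events)
    jsonlite::write_json(s$truth, paths$truth, dataframe = "columns",
                         digits = NA)
    s
  })

  # -- sort -----------------------------------------------------------------
  srt <- run_stage("sort", verbose, {
    res <- dynamic_threshold_sort(sim$events, k_sigma = config$k_sigma,
                                  t_window = config$t_window,
                                  min_events = config$min_events)
    utils::write.csv(res$decisions, paths$decisions, row.names = FALSE)
    utils::write.csv(res$trace, paths$trace, row.names = FALSE)
    write_histogram(bin_transient(sim$events, config$t_window, config$f_bin),
                    paths$histogram)
    res
  })
  qc <- screen_qc(srt, sim$events, sim$beads)
  log_stage(verbose, "sort", "%d hits / %d droplets, Z' = %.2f",
            sum(srt$decisions$is_hit), nrow(srt$decisions),
            qc$overall$zprime)

  # -- decode ---------------------------------------------------------------
  dec <- run_stage("decode", verbose, {
    hit_ids <- unlist(strsplit(
      sim$events$bead_ids[srt$decisions$is_hit], ";", fixed = TRUE))
    hit_beads <- sim$beads[sim$beads$bead_id %in% hit_ids, , drop = FALSE]
    reads <- generate_reads(hit_beads, des$codebook,
                            reads_per_bead = config$reads_per_bead,
                            sub_error_rate = config$sub_error_rate,
                            seed = stage_seed(config$seed, "decode"))
    write_fastq(reads, paths$reads)
    decoded <- decode_reads(reads, des$codebook,
                            max_mismatch = config$max_mismatch)
    calls <- call_beads(decoded, min_support = config$min_support)
    calls$screen_id <- config$screen_id
    utils::write.csv(calls, paths$bead_calls, row.names = FALSE)
    list(beads = hit_beads, calls = calls)
  })

  # -- analyze --------------------------------------------------------------
  ana <- run_stage("analyze", verbose, {
    called <- dec$calls[!is.na(dec$calls$call), ]
    kcl <- compute_kclass(data.frame(bead_id = called$bead_id,
                                     screen_id = called$screen_id,
                                     structure_id = called$call,
                                     stringsAsFactors = FALSE))
    utils::write.csv(as.data.frame(kcl), paths$kclass, row.names = FALSE)
    fdr <- estimate_fdr(des$members, sample_size = config$sample_size,
                        n_samples = config$n_samples, k_max = config$k_max,
                        seed = stage_seed(config$seed, "analyze"))
    utils::write.csv(as.data.frame(fdr), paths$fdr, row.names = FALSE)
    summed <- sum_kclass(kcl)
    hit_set <- summed$structure_id[summed$k >= config$enrich_k_min]
    enr <- if (length(hit_set))
      bb_enrichment(hit_set, des$members)
    else NULL
    if (!is.null(enr))
      utils::write.csv(as.data.frame(enr), paths$enrichment,
                       row.names = FALSE)
    hm <- export_heatmap(kcl, des$starters$bb_id, des$acids$bb_id,
                         des$members)
    utils::write.table(hm, paths$heatmap, sep = "\t", quote = FALSE,
                       col.names = NA)
    list(kclass = kcl, fdr = fdr, enrichment = enr, heatmap = hm)
  })

  summed <- sum_kclass(ana$kclass)
  report <- list(
    config = unclass(config),
    library_size = nrow(des$members),
    n_starters = nrow(des$starters),
    n_acids = nrow(des$acids),
    codebook = list(codon_length = des$codebook$codon_length,
                    d_min = des$codebook$d_min),
    screen = list(
      n_droplets = nrow(sim$events),
      n_beads = nrow(sim$beads),
      occupied_fraction = qc$overall$occupied_fraction,
      hit_rate = qc$overall$hit_rate,
      library_hit_rate = qc$overall$library_hit_rate,
      control_hit_rate = qc$overall$control_hit_rate,
      zprime = qc$overall$zprime,
      n_flagged_windows = nrow(qc$flags)),
    n_sorted_beads = nrow(dec$beads),
    bead_call_rate = if (nrow(dec$calls)) mean(!is.na(dec$calls$call))
                     else NA_real_,
    kclass_top = utils::head(summed, 10L),
    fdr = as.data.frame(ana$fdr)[c("k", "fdr_mean")],
    enriched_bbs = if (!is.null(ana$enrichment)) {
      e <- as.data.frame(ana$enrichment)
      e[e$p_adjusted < 0.05, c("bb_id", "cycle", "p", "p_adjusted")]
    } else NULL,
    paths = paths)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                       dataframe = "columns", digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
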