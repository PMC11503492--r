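#' Screen simulation parameters
#'
#' Bundles and validates the parameters of a simulated droplet screen. The
#' defaults emulate the published operating regime: ~90,000 beads across
#' ~1.5 million droplets gives a Poisson bead occupancy of
#' `bead_lambda = 0.06`; the negative (uninhibited) droplet population is
#' Gaussian in RFU, calibrated to `neg_mu = 100`, `neg_sigma = 5` so a
#' full-inhibition positive control yields Z' = 1 - 3(5+5)/100 = 0.70.
#'
#' @param n_droplets Number of droplets to generate.
#' @param droplet_rate Droplet generation rate (droplets/s); timestamps are
#'   evenly spaced at `1/droplet_rate`.
#' @param bead_lambda Mean beads per droplet (Poisson).
#' @param neg_mu,neg_sigma Mean and SD (RFU) of the negative population.
#' @param control_bead_fraction Fraction of beads that are positive-control
#'   beads (photocleavable nonselective inhibitor).
#' @param control_inhibition Inhibition fraction of a control bead (default
#'   1: full reporter suppression).
#' @param active_map Named numeric vector, structure_id -> inhibition
#'   fraction in \[0, 1\], for planted active library members. Structures
#'   not listed are inactive (0).
#' @param detect_min_inhibition Ground-truth detectability bound: a droplet
#'   is labelled an expected hit iff it contains a bead with inhibition
#'   above this value (default 0.5).
#' @param seed Integer seed; the simulation is fully reproducible given it.
#' @return A validated `screen_params` list.
#' @export
screen_params <- function(n_droplets = 1e5, droplet_rate = 800,
                          bead_lambda = 0.06, neg_mu = 100, neg_sigma = 5,
                          control_bead_fraction = 0.01,
                          control_inhibition = 1,
                          active_map = numeric(),
                          detect_min_inhibition = 0.5,
                          seed = 1L) {
  check_pos(n_droplets, "n_droplets")
  check_pos(droplet_rate, "droplet_rate")
  check_nonneg(bead_lambda, "bead_lambda")
  check_pos(neg_sigma, "neg_sigma")
  check_frac(control_bead_fraction, "control_bead_fraction")
  check_frac(control_inhibition, "control_inhibition")
  check_frac(detect_min_inhibition, "detect_min_inhibition")
  if (length(active_map)) {
    if (is.null(names(active_map)) || any(!nzchar(names(active_map))))
      stop("`active_map` must be named by structure_id", call. = FALSE)
    if (any(active_map < 0 | active_map > 1))
      stop("`active_map` inhibition fractions must be in [0, 1]",
           call. = FALSE)
  }
  structure(list(
    n_droplets = as.integer(n_droplets), droplet_rate = droplet_rate,
    bead_lambda = bead_lambda, neg_mu = neg_mu, neg_sigma = neg_sigma,
    control_bead_fraction = control_bead_fraction,
    control_inhibition = control_inhibition,
    active_map = active_map,
    detect_min_inhibition = detect_min_inhibition,
    seed = as.integer(seed)), class = "screen_params")
}

#' Simulate a droplet screen
#'
#' Generates a time-ordered droplet event stream with Poisson bead
#' occupancy and Gaussian reporter fluorescence, plus per-bead and
#' per-droplet ground truth for recovery testing. Bead counts per droplet
#' are `Poisson(bead_lambda)`; each bead is a positive-control bead with
#' probability `control_bead_fraction`, otherwise a library bead whose
#' structure is drawn uniformly from `library`. A droplet's expected
#' fluorescence is `neg_mu * (1 - max inhibition among its beads)` with SD
#' `neg_sigma`; beadless and all-inactive droplets sit at the negative
#' population. Fluorescence is not clipped at zero (the RFU offset is
#' arbitrary), so downstream code must tolerate small negative values.
#'
#' @param params A [screen_params()] object.
#' @param library Library `data.frame` from [enumerate_library()] (column
#'   `member_id` is the structure id).
#' @return A list of class `screen_sim`:
#'   \describe{
#'     \item{events}{`data.frame` with `t` (s, nondecreasing),
#'       `fluorescence` (RFU), `bead_ids` (`;`-joined, empty allowed).}
#'     \item{beads}{`data.frame` with `bead_id`, `kind`
#'       (`library`/`control_pos`), `structure_id`, `inhibition`, `droplet`.}
#'     \item{truth}{`data.frame` with per-droplet `droplet`, `n_beads`,
#'       `max_inhibition`, `expected_hit` (contains a bead with inhibition
#'       above the detectability bound).}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_screen <- function(params, library) {
  stopifnot(inherits(params, "screen_params"))
  if (length(params$active_map) &&
      !all(names(params$active_map) %in% library$member_id))
    stop("`active_map` keys must be library structure ids", call. = FALSE)
  n <- params$n_droplets
  with_seed(params$seed, {
    n_beads_per_drop <- stats::rpois(n, params$bead_lambda)
    total_beads <- sum(n_beads_per_drop)
    droplet_of_bead <- rep(seq_len(n), n_beads_per_drop)
    if (total_beads > 0L) {
      is_control <- stats::runif(total_beads) < params$control_bead_fraction
      structure_id <- rep("__control__", total_beads)
      n_lib <- sum(!is_control)
      if (n_lib > 0L)
        structure_id[!is_control] <-
          library$member_id[sample.int(nrow(library), n_lib, replace = TRUE)]
      inhibition <- ifelse(is_control, params$control_inhibition, 0)
      if (length(params$active_map)) {
        idx <- match(structure_id, names(params$active_map))
        hitable <- !is.na(idx) & !is_control
        inhibition[hitable] <- params$active_map[idx[hitable]]
      }
      beads <- data.frame(
        bead_id = sprintf("B%07d", seq_len(total_beads)),
        kind = ifelse(is_control, "control_pos", "library"),
        structure_id = structure_id,
        inhibition = inhibition,
        droplet = droplet_of_bead,
        stringsAsFactors = FALSE)
    } else {
      beads <- data.frame(bead_id = character(), kind = character(),
                          structure_id = character(), inhibition = numeric(),
                          droplet = integer(), stringsAsFactors = FALSE)
    }
    max_inh <- numeric(n)
    if (total_beads > 0L) {
      agg <- tapply(beads$inhibition, beads$droplet, max)
      max_inh[as.integer(names(agg))] <- agg
    }
    mu <- params$neg_mu * (1 - max_inh)
    f <- stats::rnorm(n, mean = mu, sd = params$neg_sigma)
    bead_ids <- character(n)
    if (total_beads > 0L) {
      joined <- tapply(beads$bead_id, beads$droplet,
                       paste, collapse = ";")
      bead_ids[as.integer(names(joined))] <- joined
    }
    events <- data.frame(
      t = (seq_len(n) - 1L) / params$droplet_rate,
      fluorescence = f,
      bead_ids = bead_ids,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      droplet = seq_len(n),
      n_beads = n_beads_per_drop,
      max_inhibition = max_inh,
      expected_hit = max_inh > params$detect_min_inhibition)
    structure(list(events = events, beads = beads, truth = truth,
                   params = params), class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(
    "screen_sim: %d droplets, %d beads (%.1f%% control), %.2f%% occupied\n",
    nrow(x$events), nrow(x$beads),
    100 * mean(x$beads$kind == "control_pos"),
    100 * mean(nzchar(x$events$bead_ids))))
  invisible(x)
}

#' Write / read a droplet event stream as CSV
#'
#' Columns `t,fluorescence,bead_ids`, with `bead_ids` `;`-joined (empty for
#' beadless droplets).
#'
#' @param events Event `data.frame`.
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   event `data.frame`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[c("t", "fluorescence", "bead_ids")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t = "numeric",
                                       fluorescence = "numeric",
                                       bead_ids = "character"))
  ev$bead_ids[is.na(ev$bead_ids)] <- ""
  ev
}
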