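#' Bin a droplet stream into a time x fluorescence transient histogram
#'
#' Two-dimensional binning of the event stream by time and fluorescence
#' (defaults 30 s and 7 RFU, the widths used for screen transient plots).
#' Bin indices are floor divisions, so negative fluorescence values bin
#' toward negative infinity; counts are conserved.
#'
#' @param events Event `data.frame` with `t` and `fluorescence`.
#' @param t_bin Time bin width in s (default 30).
#' @param f_bin Fluorescence bin width in RFU (default 7).
#' @return An object of class `transient_histogram`: a `data.frame` with
#'   `t_bin`, `f_bin` (integer bin indices) and `count`, plus attributes
#'   `t_bin_width`, `f_bin_width`, `total`.
#' @export
bin_transient <- function(events, t_bin = 30, f_bin = 7) {
  check_pos(t_bin, "t_bin")
  check_pos(f_bin, "f_bin")
  if (nrow(events) == 0L) {
    out <- data.frame(t_bin = integer(), f_bin = integer(),
                      count = integer())
  } else {
    ti <- floor(events$t / t_bin)
    fi <- floor(events$fluorescence / f_bin)
    tab <- table(t_bin = ti, f_bin = fi)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    out <- out[out$Freq > 0L, ]
    out <- data.frame(t_bin = as.integer(out$t_bin),
                      f_bin = as.integer(out$f_bin),
                      count = as.integer(out$Freq))
    out <- out[order(out$t_bin, out$f_bin), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("transient_histogram", "data.frame"),
            t_bin_width = t_bin, f_bin_width = f_bin,
            total = sum(out$count))
}

#' Write a transient histogram as a TSV matrix (time bins x fluorescence bins)
#' @param hist A `transient_histogram`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  if (nrow(hist) == 0L) {
    writeLines("", path)
    return(invisible(path))
  }
  tr <- range(hist$t_bin); fr <- range(hist$f_bin)
  m <- matrix(0L, nrow = tr[2] - tr[1] + 1L, ncol = fr[2] - fr[1] + 1L,
              dimnames = list(seq(tr[1], tr[2]), seq(fr[1], fr[2])))
  m[cbind(hist$t_bin - tr[1] + 1L, hist$f_bin - fr[1] + 1L)] <- hist$count
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Robust negative-population statistics for one time window
#'
#' Estimates the location and spread of the negative (uninhibited) droplet
#' population from all droplets in a window, using the median and the
#' scaled median absolute deviation (`1.4826 * MAD`, consistent for the SD
#' under normality). The robust pair is insensitive to the few-percent
#' low-fluorescence hit tail that would bias a mean/SD estimate — and hence
#' the sorting threshold — downward.
#'
#' @param f Numeric vector of fluorescence values (one window's events), or
#'   an event `data.frame` with a `fluorescence` column.
#' @return Named numeric vector `c(mu_hat = , sigma_hat = )`.
#' @export
estimate_negative_stats <- function(f) {
  if (is.data.frame(f)) f <- f$fluorescence
  if (length(f) == 0L) stop("empty window", call. = FALSE)
  c(mu_hat = stats::median(f), sigma_hat = stats::mad(f))
}

#' Dynamic-threshold droplet sorting
#'
#' Single-pass sorting of a time-ordered droplet stream. The stream is cut
#' into tumbling (non-overlapping) windows of `t_window` seconds; each
#' window's negative-population statistics come from
#' [estimate_negative_stats()] and set the sorting threshold
#' `mu_hat - k_sigma * sigma_hat`. A droplet is sorted as a hit iff its
#' fluorescence is strictly below its window's threshold (a droplet exactly
#' at the threshold is not a hit). Windows with fewer than `min_events`
#' droplets inherit the previous window's statistics with a warning; an
#' under-populated first window is an error.
#'
#' @param events Time-ordered event `data.frame` (`t` nondecreasing, else
#'   error).
#' @param k_sigma Threshold depth in robust SDs below the mean (default 5).
#' @param t_window Window length in s (default 30, matching the transient
#'   binning).
#' @param min_events Minimum droplets per window for a fresh estimate
#'   (default 100).
#' @return A list of class `sort_result`:
#'   \describe{
#'     \item{decisions}{`data.frame` `t`, `fluorescence`, `window`,
#'       `threshold`, `is_hit` — one row per droplet, input order.}
#'     \item{trace}{`data.frame` per window: `window`, `n_events`,
#'       `mu_hat`, `sigma_hat`, `threshold`, `carried` (statistics inherited
#'       from the previous window).}
#'   }
#' @export
dynamic_threshold_sort <- function(events, k_sigma = 5, t_window = 30,
                                   min_events = 100L) {
  check_pos(k_sigma, "k_sigma")
  check_pos(t_window, "t_window")
  if (is.unsorted(events$t))
    stop("event timestamps must be nondecreasing", call. = FALSE)
  win <- floor(events$t / t_window)
  uw <- sort(unique(win))
  trace <- data.frame(window = uw, n_events = 0L, mu_hat = NA_real_,
                      sigma_hat = NA_real_, threshold = NA_real_,
                      carried = FALSE)
  mu <- NA_real_; sg <- NA_real_
  for (i in seq_along(uw)) {
    f <- events$fluorescence[win == uw[i]]
    trace$n_events[i] <- length(f)
    if (length(f) >= min_events) {
      st <- estimate_negative_stats(f)
      mu <- st[["mu_hat"]]; sg <- st[["sigma_hat"]]
    } else if (i == 1L) {
      stop(sprintf(
        "first window has %d events (< min_events = %d); no threshold",
        length(f), min_events), call. = FALSE)
    } else {
      warning(sprintf(
        "window %d under-populated (%d events); carrying previous stats",
        uw[i], length(f)), call. = FALSE)
      trace$carried[i] <- TRUE
    }
    trace$mu_hat[i] <- mu
    trace$sigma_hat[i] <- sg
    trace$threshold[i] <- mu - k_sigma * sg
  }
  thr <- trace$threshold[match(win, trace$window)]
  decisions <- data.frame(
    t = events$t, fluorescence = events$fluorescence,
    window = win, threshold = thr,
    is_hit = events$fluorescence < thr)
  structure(list(decisions = decisions, trace = trace,
                 k_sigma = k_sigma, t_window = t_window),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf(
    "sort_result: %d droplets in %d windows, %d hits (%.3g%%), k_sigma = %g\n",
    nrow(x$decisions), nrow(x$trace), sum(x$decisions$is_hit),
    100 * mean(x$decisions$is_hit), x$k_sigma))
  invisible(x)
}

#' Z-prime assay quality statistic
#'
#' `Z' = 1 - 3 (sigma_pos + sigma_neg) / |mu_pos - mu_neg|` (the 3-sigma
#' screening-window convention). Z' is at most 1; values above 0.5 indicate
#' a screenable separation between the negative and positive-control
#' populations, and negative values (overlapping bands) are valid output
#' reported as failing QC. Equal means give an undefined separation and are
#' an error.
#'
#' @param neg,pos Numeric `c(mu, sigma)` for the negative and positive
#'   populations (sigmas must be non-negative).
#' @return The Z' value (a single number, <= 1).
#' @export
#' @examples
#' compute_zprime(c(100, 5), c(10, 5))  # 1 - 30/90 = 0.667
compute_zprime <- function(neg, pos) {
  stopifnot(length(neg) >= 2L, length(pos) >= 2L)
  if (neg[2] < 0 || pos[2] < 0)
    stop("sigmas must be non-negative", call. = FALSE)
  if (neg[1] == pos[1])
    stop("undefined separation: negative and positive means are equal",
         call. = FALSE)
  unname(1 - 3 * (pos[2] + neg[2]) / abs(pos[1] - neg[1]))
}

#' Per-window screen quality-control report
#'
#' Summarises sorting cadence: per window, the droplet count, the
#' bead-occupied droplet fraction, and the hit rates among library-bead and
#' control-bead droplets; whole-screen, the overall hit rate and (when bead
#' annotations are given) Z' of control-bead droplets against beadless
#' droplets. A window is flagged when its overall hit rate or its
#' control-occupancy fraction deviates from the screen-wide value by more
#' than `flag_k` binomial standard errors — drops in control occupancy are
#' the signature of a bead-introduction failure.
#'
#' @param sorted A [dynamic_threshold_sort()] result.
#' @param events The event `data.frame` that was sorted (for `bead_ids`).
#' @param beads Optional bead `data.frame` (`bead_id`, `kind`) to separate
#'   library from control beads and compute Z'.
#' @param flag_k Cadence flag threshold in binomial SEs (default 4).
#' @return A list of class `screen_qc`: `windows` (per-window
#'   `data.frame`), `overall` (named list with `n_droplets`, `hit_rate`,
#'   `occupied_fraction`, `library_hit_rate`, `control_hit_rate`,
#'   `zprime`), and `flags` (`data.frame` of flagged windows with reasons).
#' @export
screen_qc <- function(sorted, events, beads = NULL, flag_k = 4) {
  dec <- sorted$decisions
  if (nrow(dec) != nrow(events))
    stop("decisions must cover all events", call. = FALSE)
  occupied <- nzchar(events$bead_ids)
  has_lib <- has_ctrl <- rep(NA, nrow(events))
  if (!is.null(beads)) {
    ctrl_ids <- beads$bead_id[beads$kind == "control_pos"]
    per <- strsplit(events$bead_ids, ";", fixed = TRUE)
    n_ctrl <- vapply(per, function(b) sum(b %in% ctrl_ids), integer(1))
    n_all <- lengths(per) * nzchar(events$bead_ids)
    has_ctrl <- n_ctrl > 0L
    has_lib <- (n_all - n_ctrl) > 0L
  }
  win <- dec$window
  uw <- sort(unique(win))
  rate <- function(x, sel) if (sum(sel) == 0L) NA_real_ else mean(x[sel])
  windows <- do.call(rbind, lapply(uw, function(w) {
    s <- win == w
    data.frame(
      window = w,
      n_droplets = sum(s),
      occupied_fraction = mean(occupied[s]),
      hit_rate = mean(dec$is_hit[s]),
      control_fraction = if (is.null(beads)) NA_real_ else mean(has_ctrl[s]),
      library_hit_rate = if (is.null(beads)) NA_real_
                         else rate(dec$is_hit[s], has_lib[s]),
      control_hit_rate = if (is.null(beads)) NA_real_
                         else rate(dec$is_hit[s], has_ctrl[s]))
  }))
  zp <- NA_real_
  if (!is.null(beads) && any(has_ctrl) && any(!occupied)) {
    fn <- events$fluorescence[!occupied]
    fp <- events$fluorescence[has_ctrl]
    zp <- compute_zprime(c(mean(fn), stats::sd(fn)),
                         c(mean(fp), stats::sd(fp)))
  }
  overall <- list(
    n_droplets = nrow(dec),
    hit_rate = mean(dec$is_hit),
    occupied_fraction = mean(occupied),
    library_hit_rate = if (is.null(beads)) NA_real_
                       else rate(dec$is_hit, has_lib),
    control_hit_rate = if (is.null(beads)) NA_real_
                       else rate(dec$is_hit, has_ctrl),
    zprime = zp)
  # cadence flags: per-window binomial deviation from the screen-wide rate
  flags <- list()
  flag_metric <- function(metric, p0) {
    if (is.na(p0)) return()
    se <- sqrt(p0 * (1 - p0) / windows$n_droplets)
    dev <- abs(windows[[metric]] - p0)
    bad <- which(!is.na(dev) & se > 0 & dev > flag_k * se)
    for (w in bad)
      flags[[length(flags) + 1L]] <<- data.frame(
        window = windows$window[w], metric = metric,
        value = windows[[metric]][w], expected = p0)
  }
  flag_metric("hit_rate", overall$hit_rate)
  flag_metric("control_fraction",
              if (is.null(beads)) NA_real_ else mean(has_ctrl))
  flags <- if (length(flags)) do.call(rbind, flags)
           else data.frame(window = integer(), metric = character(),
                           value = numeric(), expected = numeric())
  structure(list(windows = windows, overall = overall, flags = flags,
                 flag_k = flag_k), class = "screen_qc")
}

#' @export
print.screen_qc <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "screen_qc: %d droplets, hit rate %.3g%%, occupied %.3g%%, Z' %s, %d flagged window(s)\n",
    o$n_droplets, 100 * o$hit_rate, 100 * o$occupied_fraction,
    if (is.na(o$zprime)) "NA" else sprintf("%.2f", o$zprime),
    nrow(x$flags)))
  invisible(x)
}
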