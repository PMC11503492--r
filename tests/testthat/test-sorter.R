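test_that("transient binning conserves counts and floors toward -Inf", {
  # hand-derived: floor(10/7) = 1, floor(20/7) = 2; t bins 0 and 1
  ev <- data.frame(t = c(1, 31, 31), fluorescence = c(10, 10, 20))
  h <- bin_transient(ev, t_bin = 30, f_bin = 7)
  expect_equal(h$t_bin, c(0L, 1L, 1L))
  expect_equal(h$f_bin, c(1L, 1L, 2L))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(attr(h, "total"), 3L)

  # empty stream
  h0 <- bin_transient(ev[0, ], 30, 7)
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "total"), 0L)

  # all in one bin
  ev1 <- data.frame(t = rep(2, 5), fluorescence = rep(3, 5))
  h1 <- bin_transient(ev1, 30, 7)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$count, 5L)

  # negative fluorescence bins by floor toward -infinity
  hn <- bin_transient(data.frame(t = 0, fluorescence = -0.5), 30, 7)
  expect_equal(hn$f_bin, -1L)

  # count conservation on a random stream
  set.seed(20)
  evr <- data.frame(t = sort(runif(500, 0, 300)),
                    fluorescence = rnorm(500, 100, 20))
  expect_equal(attr(bin_transient(evr), "total"), 500L)
})

test_that("robust negative statistics resist hit-tail contamination", {
  expect_equal(estimate_negative_stats(rep(100, 50)),
               c(mu_hat = 100, sigma_hat = 0))
  # median/MAD by hand: median = 100, MAD = 10, sigma = 1.4826 * 10
  expect_equal(estimate_negative_stats(c(90, 100, 110)),
               c(mu_hat = 100, sigma_hat = 1.4826 * 10))
  # Normal(100, 5) with 2% contamination at f = 10
  set.seed(21)
  f <- c(rnorm(9800, 100, 5), rep(10, 200))
  st <- estimate_negative_stats(f)
  expect_lt(abs(st[["mu_hat"]] - 100), 0.5)
  expect_lt(abs(st[["sigma_hat"]] - 5), 0.5)
  expect_error(estimate_negative_stats(numeric(0)), "empty")
})

test_that("dynamic sorting applies a strict per-window 5-sigma threshold", {
  set.seed(22)
  n <- 5000
  ev <- data.frame(t = seq(0, 29.99, length.out = n),
                   fluorescence = rnorm(n, 100, 5))
  # plant one clear hit and one droplet exactly at the realized threshold
  ev$fluorescence[100] <- 70
  res <- dynamic_threshold_sort(ev, k_sigma = 5, t_window = 30)
  thr <- res$trace$threshold[1]
  expect_equal(nrow(res$trace), 1L)
  expect_lt(abs(thr - 75), 1.5)       # ~ 100 - 5*5
  expect_true(res$decisions$is_hit[100])
  # strict inequality: a droplet exactly at the threshold is NOT a hit
  ev2 <- ev
  ev2$fluorescence[200] <- thr
  res2 <- dynamic_threshold_sort(ev2, k_sigma = 5, t_window = 30)
  expect_false(res2$decisions$is_hit[200])
  # count conservation
  expect_equal(nrow(res$decisions), n)

  # non-monotone timestamps rejected
  bad <- ev; bad$t[2] <- -1
  expect_error(dynamic_threshold_sort(bad), "nondecreasing")
})

test_that("under-populated windows inherit stats; empty first window errors", {
  set.seed(23)
  ev <- rbind(
    data.frame(t = seq(0, 29.9, length.out = 500),
               fluorescence = rnorm(500, 100, 5)),
    data.frame(t = seq(30, 59.9, length.out = 20),
               fluorescence = rnorm(20, 100, 5)))
  expect_warning(res <- dynamic_threshold_sort(ev, min_events = 100L),
                 "carrying")
  expect_true(res$trace$carried[2])
  expect_equal(res$trace$threshold[2], res$trace$threshold[1])
  expect_error(
    suppressWarnings(dynamic_threshold_sort(ev[501:520, ], min_events = 100L)),
    "first window")
})

test_that("null sort fraction matches the one-sided Gaussian tail", {
  # at desk scale the 5-sigma rate (~2.9e-7) is unobservable; verify the
  # scaled version at k_sigma in {2, 3} against pnorm(-k)
  n <- 1e5
  set.seed(24)
  ev <- data.frame(t = (seq_len(n) - 1) / 800,
                   fluorescence = rnorm(n, 100, 5))
  for (k in c(2, 3)) {
    res <- dynamic_threshold_sort(ev, k_sigma = k, t_window = 30)
    p <- pnorm(-k)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(res$decisions$is_hit) - p), 3 * se)
  }
})

test_that("sorting is invariant to histogram bin widths", {
  set.seed(25)
  ev <- data.frame(t = seq(0, 59.99, length.out = 2000),
                   fluorescence = rnorm(2000, 100, 5))
  res <- dynamic_threshold_sort(ev)
  # binning is visualization only: any f_bin choice leaves decisions alone
  h1 <- bin_transient(ev, 30, 7); h2 <- bin_transient(ev, 15, 2)
  res2 <- dynamic_threshold_sort(ev)
  expect_identical(res$decisions, res2$decisions)
  expect_equal(attr(h1, "total"), attr(h2, "total"))
})

test_that("Z-prime follows the 3-sigma screening-window formula", {
  # noiseless limit
  expect_equal(compute_zprime(c(100, 0), c(10, 0)), 1)
  # hand-computed: 1 - 3*(5+5)/90
  expect_equal(compute_zprime(c(100, 5), c(10, 5)), 1 - 30 / 90)
  # overlapping bands: negative Z' is valid output (fails QC downstream)
  expect_equal(compute_zprime(c(100, 20), c(10, 20)), 1 - 120 / 90)
  # undefined separation
  expect_error(compute_zprime(c(100, 5), c(100, 5)), "undefined")
  # monotone decrease in either sigma
  z <- vapply(seq(0, 10, by = 1),
              function(s) compute_zprime(c(100, s), c(10, 3)), numeric(1))
  expect_true(all(diff(z) < 0))
  z2 <- vapply(seq(0, 10, by = 1),
               function(s) compute_zprime(c(100, 3), c(10, s)), numeric(1))
  expect_true(all(diff(z2) < 0))
})

test_that("QC recovers a planted library-bead hit rate", {
  # plant actives on 17% of structures at full inhibition: the fraction of
  # occupied-bead droplets sorted as hits should recover ~0.17 (the planted
  # screen-outcome setting)
  lib <- toy_library(10, 10)
  active_ids <- lib$member_id[1:17]
  p <- screen_params(n_droplets = 1e5, bead_lambda = 0.06,
                     control_bead_fraction = 0,
                     active_map = setNames(rep(1, 17), active_ids),
                     seed = 26L)
  s <- simulate_screen(p, lib)
  res <- dynamic_threshold_sort(s$events)
  qc <- screen_qc(res, s$events, s$beads)
  occ <- nzchar(s$events$bead_ids)
  n_occ <- sum(occ)
  hit_rate_occ <- mean(res$decisions$is_hit[occ])
  se <- sqrt(0.17 * 0.83 / n_occ)
  expect_lt(abs(hit_rate_occ - 0.17), 3 * se)
  # rates land in [0,1] and window droplet counts conserve the stream
  expect_true(all(qc$windows$hit_rate >= 0 & qc$windows$hit_rate <= 1))
  expect_equal(sum(qc$windows$n_droplets), nrow(s$events))
})

test_that("QC cadence flags a window emptied of control beads", {
  lib <- toy_library()
  p <- screen_params(n_droplets = 6e4, bead_lambda = 0.2,
                     control_bead_fraction = 0.3, seed = 27L)
  s <- simulate_screen(p, lib)
  res <- dynamic_threshold_sort(s$events)
  qc0 <- screen_qc(res, s$events, s$beads)
  expect_equal(nrow(qc0$flags[qc0$flags$metric == "control_fraction", ]), 0L)

  # strip every control bead out of window 1 (30-60 s)
  ev <- s$events
  ctrl <- s$beads$bead_id[s$beads$kind == "control_pos"]
  w1 <- floor(ev$t / 30) == 1
  ev$bead_ids[w1] <- vapply(strsplit(ev$bead_ids[w1], ";", fixed = TRUE),
                            function(b) paste(setdiff(b, ctrl),
                                              collapse = ";"),
                            character(1))
  qc1 <- screen_qc(res, ev, s$beads)
  flagged <- qc1$flags[qc1$flags$metric == "control_fraction", ]
  expect_true(1 %in% flagged$window)

  # zero hits anywhere -> all rates 0, no hit-rate flags
  quiet <- data.frame(t = seq(0, 29.9, length.out = 1000),
                      fluorescence = rnorm(1000, 100, 5),
                      bead_ids = "")
  rq <- dynamic_threshold_sort(quiet)
  qq <- screen_qc(rq, quiet)
  if (sum(rq$decisions$is_hit) == 0) {
    expect_true(all(qq$windows$hit_rate == 0))
    expect_equal(nrow(qq$flags), 0L)
  }
})
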