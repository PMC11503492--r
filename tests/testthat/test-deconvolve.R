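test_that("decoder handles exact, corrected, ambiguous, control and fail reads", {
  cb <- manual_codebook(
    cycle1 = c(S1 = "AAAAAAAA", S2 = "CCCCAAAA"),
    cycle2 = c(A1 = "GGGGGGGG", A2 = "TTTTGGGG"),
    control = "TTTTTTTT", d_min = 4L)

  # error-free round trip
  r <- decode_read(make_amplicon(cb, "AAAAAAAA", "GGGGGGGG"), cb)
  expect_equal(r$status, "exact")
  expect_equal(r$codon1_id, "S1")
  expect_equal(r$codon2_id, "A1")
  expect_false(r$is_control)

  # one substitution in codon1 -> corrected to the right bb
  mut <- make_amplicon(cb, flip_base("AAAAAAAA", 3, "G"), "GGGGGGGG")
  rc <- decode_read(mut, cb, max_mismatch = 1L)
  expect_equal(rc$status, "corrected")
  expect_equal(rc$codon1_id, "S1")

  # equidistant tie in a d_min = 2 codebook -> ambiguous
  cb2 <- manual_codebook(cycle1 = c(S1 = "AAAA", S2 = "AACC"),
                         cycle2 = c(A1 = "GGGG"),
                         control = "TTTT", d_min = 2L)
  # "AACA" is Hamming-1 from both AAAA and AACC
  ra <- decode_read(make_amplicon(cb2, "AACA", "GGGG"), cb2,
                    max_mismatch = 1L)
  expect_equal(ra$status, "ambiguous")
  expect_true(is.na(ra$codon1_id))

  # control codon in slot 1 marks a control read
  rk <- decode_read(make_amplicon(cb, "TTTTTTTT", "TTTTTTTT"), cb)
  expect_true(rk$is_control)
  expect_equal(rk$status, "exact")

  # beyond max_mismatch, and wrong length: fail status, no exception
  rf <- decode_read(make_amplicon(cb, "GGAAAAAA", "GGGGGGGG"), cb,
                    max_mismatch = 1L)
  expect_equal(rf$status, "fail")
  rl <- decode_read("ACGT", cb)
  expect_equal(rl$status, "fail")
})

test_that("bead calling takes the supported plurality with a strict tie rule", {
  cb <- manual_codebook(
    cycle1 = c(S1 = "AAAAAAAA", S2 = "CCCCAAAA"),
    cycle2 = c(A1 = "GGGGGGGG", A2 = "TTTTGGGG"),
    control = "TTTTTTTT", d_min = 4L)
  amp <- function(s, a) make_amplicon(cb, cb$cycle1_codons[[s]],
                                      cb$cycle2_codons[[a]])
  reads_of <- function(bead, n1, n2 = 0L) {
    r <- c(rep(amp("S1", "A1"), n1), rep(amp("S2", "A2"), n2))
    setNames(r, paste0(bead, "/", seq_along(r)))
  }

  # unanimous
  d <- decode_reads(reads_of("B1", 20L), cb)
  c1 <- call_beads(d)
  expect_equal(c1$call, "S1-A1")
  expect_equal(c1$support, 1)

  # 12 vs 8 -> plurality at support 0.6 >= 0.5
  d2 <- decode_reads(reads_of("B2", 12L, 8L), cb)
  c2 <- call_beads(d2)
  expect_equal(c2$call, "S1-A1")
  expect_equal(c2$support, 0.6)

  # 10 vs 10 -> exact tie -> no-call
  d3 <- decode_reads(reads_of("B3", 10L, 10L), cb)
  expect_true(is.na(call_beads(d3)$call))

  # zero usable reads -> no-call
  d4 <- decode_reads(setNames(rep("ACGT", 3), paste0("B4/", 1:3)), cb)
  c4 <- call_beads(d4)
  expect_true(is.na(c4$call))
  expect_equal(c4$n_usable, 0L)

  # control beads are called "control"
  ctrl_amp <- make_amplicon(cb, "TTTTTTTT", "TTTTTTTT")
  d5 <- decode_reads(setNames(rep(ctrl_amp, 5), paste0("B5/", 1:5)), cb)
  expect_equal(call_beads(d5)$call, "control")
})

test_that("k-class tabulation counts distinct beads per structure and screen", {
  calls <- data.frame(
    bead_id = c("b1", "b2", "b3"), screen_id = "s1",
    structure_id = c("A", "A", "B"), stringsAsFactors = FALSE)
  k <- compute_kclass(calls)
  expect_equal(k$k[k$structure_id == "A"], 2L)
  expect_equal(k$k[k$structure_id == "B"], 1L)

  # summed-across-screens view
  two <- rbind(calls, data.frame(bead_id = c("c1", "c2"), screen_id = "s2",
                                 structure_id = "A"))
  summed <- sum_kclass(compute_kclass(two))
  expect_equal(summed$k[summed$structure_id == "A"], 4L)

  # conservation: sum of k equals called beads (controls/no-calls excluded)
  set.seed(30)
  n <- 1500
  big <- data.frame(bead_id = sprintf("b%04d", 1:n), screen_id = "s1",
                    structure_id = sample(sprintf("m%03d", 1:300), n,
                                          replace = TRUE))
  expect_equal(sum(compute_kclass(big)$k), n)

  # duplicate bead within a screen is an error
  dup <- calls; dup$bead_id[2] <- "b1"
  expect_error(compute_kclass(dup), "duplicate")
})

test_that("heat-map export projects summed k onto the starter x acid grid", {
  lib <- toy_library(3, 4)
  k <- compute_kclass(data.frame(
    bead_id = sprintf("b%d", 1:9), screen_id = "s1",
    structure_id = c(rep("S1-A2", 5), rep("S3-A4", 3), "S2-A1")))
  m <- export_heatmap(k, sprintf("S%d", 1:3), sprintf("A%d", 1:4), lib)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(m["S1", "A2"], 5L)
  expect_equal(m["S3", "A4"], 3L)
  expect_equal(m["S2", "A1"], 1L)
  expect_equal(sum(m), 9L)
  # row sums are per-starter totals
  expect_equal(unname(rowSums(m)), c(5, 1, 3))
  # unknown structure errors
  bad <- compute_kclass(data.frame(bead_id = "b1", screen_id = "s1",
                                   structure_id = "S9-A9"))
  expect_error(export_heatmap(bad, sprintf("S%d", 1:3), sprintf("A%d", 1:4),
                              lib), "unknown")
})

test_that("null FDR matrix has its structural invariants", {
  lib <- toy_library(10, 20)  # 200 members
  f <- estimate_fdr(lib, sample_size = 100L, n_samples = 5L, k_max = 6L,
                    seed = 31L)
  expect_equal(f$fdr_mean[1], 1)           # FDR(1) = 1 always
  expect_true(all(diff(f$fdr_mean) <= 0))  # nonincreasing in k
  expect_true(all(as.matrix(f[grep("rep", names(f))]) >= 0 &
                  as.matrix(f[grep("rep", names(f))]) <= 1))
  # reproducible given seed
  f2 <- estimate_fdr(lib, sample_size = 100L, n_samples = 5L, k_max = 6L,
                     seed = 31L)
  expect_identical(as.data.frame(f), as.data.frame(f2))

  # degenerate single-bead sample: only k = 1 occupied, flagged zeros above
  f1 <- estimate_fdr(lib, sample_size = 1L, n_samples = 2L, k_max = 3L,
                     seed = 32L)
  expect_equal(f1$fdr_mean, c(1, 0, 0))
  expect_equal(attr(f1, "degenerate"), c(2L, 3L))
})

test_that("resampled FDR agrees with the Poisson closed form", {
  s <- data.frame(bb_id = sprintf("S%02d", 1:14), cycle = 1L, mw = 150)
  a <- data.frame(bb_id = sprintf("A%03d", 1:382), cycle = 2L, mw = 120)
  lib <- enumerate_library(s, a)
  f <- estimate_fdr(lib, sample_size = 1500L, n_samples = 50L, k_max = 5L,
                    seed = 33L)
  reps <- as.matrix(as.data.frame(f)[grep("rep", names(f))])
  for (k in 2:4) {
    se <- sd(reps[k, ]) / sqrt(ncol(reps))
    expect_lt(abs(f$fdr_mean[k] - fdr_poisson_approx(k, 1500, nrow(lib))),
              3 * se + 1e-4)
  }
})

test_that("hypergeometric enrichment matches the exact oracle", {
  lib <- toy_library(3, 4)  # 12 members
  # hits = the 4 members of starter S1: p = 1 / choose(12, 4) = 1/495
  hits <- lib$member_id[lib$starter_id == "S1"]
  e <- bb_enrichment(hits, lib)
  expect_equal(e$p[e$bb_id == "S1"], 1 / choose(12, 4))
  expect_equal(e$n_hits_containing[e$bb_id == "S1"], 4L)
  # a BB absent from all hits is not enriched
  expect_equal(e$p[e$bb_id == "S2"], 1)
  # Bonferroni across all 7 BBs tested
  expect_equal(e$p_adjusted[e$bb_id == "S1"],
               min(1, 7 / choose(12, 4)))

  # hit set = entire library -> every BB saturated, p = 1
  efull <- bb_enrichment(lib$member_id, lib)
  expect_true(all(efull$p == 1))
  expect_true(all(efull$n_hits_containing == efull$n_lib_containing))

  # invariants: p in [0,1]; counts bounded
  expect_true(all(e$p >= 0 & e$p <= 1))
  expect_true(all(e$n_hits_containing <=
                  pmin(e$n_hits_total, e$n_lib_containing)))

  expect_warning(e0 <- bb_enrichment(character(0), lib), "empty")
  expect_equal(nrow(e0), 0L)
  expect_error(bb_enrichment("nope", lib), "library members")
})

test_that("null enrichment p-values are approximately uniform", {
  # permutation calibration at desk scale: uniform random hit sets should
  # not concentrate small p-values
  lib <- toy_library(8, 12)
  set.seed(34)
  pvals <- replicate(40, {
    hits <- sample(lib$member_id, 20)
    min(1, min(bb_enrichment(hits, lib)$p) * 20)  # Bonferroni on cycle-1
  })
  # under the null, conservatively adjusted minima should rarely be small
  expect_gt(mean(pvals > 0.05), 0.8)
})
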