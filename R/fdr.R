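#' Estimate the false discovery matrix by null resampling
#'
#' Emulates sequencing random (unsorted) bead samples: each replicate draws
#' `sample_size` beads uniformly with replacement over the library's
#' structures (a deep, uniformly represented bead pool), tabulates the
#' per-structure bead count, and computes, for each k threshold,
#' `FDR(k) = (# distinct structures with count >= k) /
#' (# distinct structures observed)` — the fraction of "called" structures
#' a k-threshold hit rule would accept from a null sample. FDR(1) is 1 by
#' construction and FDR is nonincreasing in k.
#'
#' Under this null the per-structure count is approximately
#' `Poisson(lambda = sample_size / |library|)`, so
#' `FDR(k) ~ P(X >= k) / P(X >= 1)` — a closed-form cross-check used in the
#' test suite.
#'
#' @param library Library `data.frame` (or anything with a `member_id`
#'   column), non-empty.
#' @param sample_size Beads per null sample (default 1500, the typical hit
#'   collection size).
#' @param n_samples Number of replicate samples (default 3).
#' @param k_max Largest k threshold tabulated (default 10).
#' @param seed Integer seed; reproducible given it.
#' @return An object of class `fdr_matrix`: a `data.frame` with `k`,
#'   `fdr_mean`, and one `fdr_rep<i>` column per replicate, plus attributes
#'   `sample_size`, `n_samples`, `seed`, and `degenerate` (k values with no
#'   support in any replicate, reported as 0).
#' @export
estimate_fdr <- function(library, sample_size = 1500L, n_samples = 3L,
                         k_max = 10L, seed = 1L) {
  check_pos(sample_size, "sample_size")
  check_pos(n_samples, "n_samples")
  check_pos(k_max, "k_max")
  n_lib <- if (is.data.frame(library)) nrow(library) else length(library)
  if (n_lib == 0L) stop("`library` must be non-empty", call. = FALSE)
  ks <- seq_len(k_max)
  reps <- with_seed(seed, {
    vapply(seq_len(n_samples), function(r) {
      counts <- tabulate(sample.int(n_lib, sample_size, replace = TRUE),
                         nbins = n_lib)
      observed <- sum(counts >= 1L)
      vapply(ks, function(k) sum(counts >= k) / observed, numeric(1))
    }, numeric(k_max))
  })
  reps <- matrix(reps, nrow = k_max)
  out <- data.frame(k = ks, fdr_mean = rowMeans(reps))
  for (r in seq_len(n_samples)) out[[paste0("fdr_rep", r)]] <- reps[, r]
  degenerate <- ks[rowSums(reps) == 0]
  structure(out, class = c("fdr_matrix", "data.frame"),
            sample_size = as.integer(sample_size),
            n_samples = as.integer(n_samples),
            seed = as.integer(seed),
            library_size = n_lib,
            degenerate = degenerate)
}

#' @export
print.fdr_matrix <- function(x, ...) {
  cat(sprintf(
    "fdr_matrix: %d x %d-bead null samples from a %d-structure library (seed %d)\n",
    attr(x, "n_samples"), attr(x, "sample_size"), attr(x, "library_size"),
    attr(x, "seed")))
  print.data.frame(x, digits = 4)
  if (length(attr(x, "degenerate")))
    cat("note: k in {", paste(attr(x, "degenerate"), collapse = ", "),
        "} had no support in any replicate (FDR reported as 0)\n")
  invisible(x)
}

#' Closed-form Poisson approximation to the null FDR
#'
#' `P(X >= k) / P(X >= 1)` for `X ~ Poisson(sample_size / library_size)`:
#' the expected fraction of observed structures reaching count k in a
#' uniform-with-replacement null sample.
#'
#' @param k K threshold (vectorised).
#' @param sample_size,library_size Null sample size and library size.
#' @return Numeric vector of approximate FDR values.
#' @export
fdr_poisson_approx <- function(k, sample_size, library_size) {
  lambda <- sample_size / library_size
  stats::ppois(k - 1, lambda, lower.tail = FALSE) /
    stats::ppois(0, lambda, lower.tail = FALSE)
}
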