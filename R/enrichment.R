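#' Building-block overrepresentation in the hit collection
#'
#' Tests, per building block, whether the distinct hit structures carry
#' that BB more often than a uniform draw from the library would. The test
#' is the one-sided hypergeometric tail: drawing `n_hits_total` distinct
#' structures from the `n_lib_total`-member library, the probability of
#' seeing at least `n_hits_containing` that contain the BB. P-values are
#' Bonferroni-adjusted across all BBs tested (both cycles).
#'
#' Using the distinct-structure hit set (typically k >= 3) rather than
#' bead-weighted counts avoids double-counting replicate beads of one
#' structure.
#'
#' @param hit_structures Character vector of hit structure ids (member
#'   ids); duplicates are collapsed. Must all be in the library.
#' @param library Library `data.frame` from [enumerate_library()].
#' @return A `data.frame` (class `enrichment_table`) with one row per BB:
#'   `bb_id`, `cycle`, `n_hits_containing`, `n_hits_total`,
#'   `n_lib_containing`, `n_lib_total`, `p`, `p_adjusted`; ordered by `p`.
#'   Empty hit set: empty result with a warning.
#' @export
bb_enrichment <- function(hit_structures, library) {
  hits <- unique(hit_structures)
  cols <- c("bb_id", "cycle", "n_hits_containing", "n_hits_total",
            "n_lib_containing", "n_lib_total", "p", "p_adjusted")
  if (length(hits) == 0L) {
    warning("empty hit set: no enrichment to test", call. = FALSE)
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(cols)), cols))
    return(structure(out, class = c("enrichment_table", "data.frame")))
  }
  if (!all(hits %in% library$member_id))
    stop("hit structures must be library members", call. = FALSE)
  n_lib <- nrow(library)
  n_hit <- length(hits)
  idx <- match(hits, library$member_id)
  test_bb <- function(bb_ids, lib_bb, hit_bb, cycle) {
    do.call(rbind, lapply(bb_ids, function(b) {
      m <- sum(lib_bb == b)
      q <- sum(hit_bb == b)
      p <- stats::phyper(q - 1, m, n_lib - m, n_hit, lower.tail = FALSE)
      data.frame(bb_id = b, cycle = cycle, n_hits_containing = q,
                 n_hits_total = n_hit, n_lib_containing = m,
                 n_lib_total = n_lib, p = p, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(
    test_bb(unique(library$starter_id), library$starter_id,
            library$starter_id[idx], 1L),
    test_bb(unique(library$acid_id), library$acid_id,
            library$acid_id[idx], 2L))
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out <- out[order(out$p, out$bb_id), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}
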