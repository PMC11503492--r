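#' Tabulate the k class of hit structures
#'
#' The k class of a structure is the number of distinct beads in a screen's
#' hit collection called as that structure — the replication evidence for a
#' hit. Control calls and no-calls are excluded from the table.
#'
#' @param bead_calls `data.frame` with `bead_id`, `screen_id`,
#'   `structure_id` (one row per called bead; `NA` structure = no-call;
#'   `"control"` = positive-control bead).
#' @return An object of class `kclass_table`: a `data.frame` with
#'   `structure_id`, `screen_id`, `k` (distinct beads, >= 1), ordered by
#'   decreasing k. Duplicate bead ids within a screen are an error.
#' @export
compute_kclass <- function(bead_calls) {
  need <- c("bead_id", "screen_id", "structure_id")
  if (!all(need %in% names(bead_calls)))
    stop("`bead_calls` needs columns bead_id, screen_id, structure_id",
         call. = FALSE)
  for (sc in unique(bead_calls$screen_id)) {
    ids <- bead_calls$bead_id[bead_calls$screen_id == sc]
    if (anyDuplicated(ids))
      stop(sprintf("duplicate bead_id within screen '%s'", sc),
           call. = FALSE)
  }
  keep <- !is.na(bead_calls$structure_id) &
    bead_calls$structure_id != "control"
  bc <- bead_calls[keep, ]
  if (nrow(bc) == 0L)
    return(structure(data.frame(structure_id = character(),
                                screen_id = character(), k = integer()),
                     class = c("kclass_table", "data.frame")))
  agg <- stats::aggregate(bead_id ~ structure_id + screen_id, data = bc,
                          FUN = length)
  names(agg)[3] <- "k"
  agg <- agg[order(-agg$k, agg$structure_id, agg$screen_id), ]
  rownames(agg) <- NULL
  structure(agg, class = c("kclass_table", "data.frame"))
}

#' Sum k classes across screens
#'
#' The cross-screen view used for the starter x acid heat map: per
#' structure, total k over all screens.
#'
#' @param kclass A [compute_kclass()] table.
#' @return A `data.frame` with `structure_id` and `k` (summed), ordered by
#'   decreasing k.
#' @export
sum_kclass <- function(kclass) {
  if (nrow(kclass) == 0L)
    return(data.frame(structure_id = character(), k = integer()))
  agg <- stats::aggregate(k ~ structure_id, data = as.data.frame(kclass),
                          FUN = sum)
  agg <- agg[order(-agg$k, agg$structure_id), ]
  rownames(agg) <- NULL
  agg
}

#' Export the starter x acid k-class heat-map matrix
#'
#' Projects the (cross-screen summed) k classes onto the library's
#' combinatorial axes: rows are cycle-1 starters, columns cycle-2 acids,
#' cells the summed k of the corresponding member (0 where never observed).
#'
#' @param kclass A [compute_kclass()] table.
#' @param starters,acids Character vectors of starter and acid bb_ids
#'   defining row and column order.
#' @param library Library `data.frame` mapping `member_id` to
#'   `starter_id`/`acid_id`. Structures in `kclass` absent from `library`
#'   are an error.
#' @return An integer matrix `length(starters) x length(acids)` with
#'   dimnames.
#' @export
export_heatmap <- function(kclass, starters, acids, library) {
  m <- matrix(0L, nrow = length(starters), ncol = length(acids),
              dimnames = list(starters, acids))
  summed <- sum_kclass(kclass)
  if (nrow(summed) == 0L) return(m)
  idx <- match(summed$structure_id, library$member_id)
  if (anyNA(idx))
    stop("unknown structure id(s): ",
         paste(summed$structure_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  st <- library$starter_id[idx]
  ac <- library$acid_id[idx]
  if (!all(st %in% starters) || !all(ac %in% acids))
    stop("structure resolves to a starter/acid outside the given axes",
         call. = FALSE)
  for (i in seq_len(nrow(summed)))
    m[st[i], ac[i]] <- m[st[i], ac[i]] + summed$k[i]
  m
}
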