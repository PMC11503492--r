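#' Enumerate the combinatorial library
#'
#' Forms the full cross product of cycle-1 starters and cycle-2 acids. Every
#' (starter, acid) pair becomes one library member with the deterministic,
#' human-readable id `"<starter_id>-<acid_id>"`.
#'
#' @param starters Building-block `data.frame`, all `cycle == 1`.
#' @param acids Building-block `data.frame`, all `cycle == 2`.
#' @return A `data.frame` with columns `member_id`, `starter_id`, `acid_id`;
#'   `nrow` equals `nrow(starters) * nrow(acids)`. Acids vary fastest within
#'   each starter.
#' @export
#' @examples
#' s <- data.frame(bb_id = c("s1", "s2"), cycle = 1L, mw = 150)
#' a <- data.frame(bb_id = c("a1", "a2", "a3"), cycle = 2L, mw = 120)
#' nrow(enumerate_library(s, a))  # 6
enumerate_library <- function(starters, acids) {
  starters <- validate_building_blocks(starters)
  acids <- validate_building_blocks(acids)
  if (!all(starters$cycle == 1L))
    stop("all `starters` must be cycle 1", call. = FALSE)
  if (!all(acids$cycle == 2L))
    stop("all `acids` must be cycle 2", call. = FALSE)
  if (anyDuplicated(starters$bb_id) || anyDuplicated(acids$bb_id))
    stop("duplicate bb_id within a cycle", call. = FALSE)
  grid <- expand.grid(acid_id = acids$bb_id, starter_id = starters$bb_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    member_id = paste(grid$starter_id, grid$acid_id, sep = "-"),
    starter_id = grid$starter_id,
    acid_id = grid$acid_id,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$member_id))
    stop("member ids collide; bb_ids must not themselves contain '-' parts ",
         "that alias other pairs", call. = FALSE)
  out
}
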