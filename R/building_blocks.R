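#' Read a building-block table
#'
#' Building blocks (BBs) are the monomers of the two-cycle combinatorial
#' library: cycle-1 "starters" and cycle-2 carboxylic-acid "tails". The
#' expected CSV header is
#' `bb_id,cycle,smiles,mw,n_unassigned_stereocenters,flags`, with `flags` a
#' `;`-separated list of structural-alert labels (may be empty).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per building block, columns
#'   `bb_id` (character), `cycle` (integer 1 or 2), `smiles` (character,
#'   possibly `NA`), `mw` (numeric, Da), `n_unassigned_stereocenters`
#'   (integer) and `flags` (character, `;`-separated).
#' @export
read_building_blocks <- function(path) {
  bb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bb_id = "character",
                                       smiles = "character",
                                       flags = "character"))
  validate_building_blocks(bb)
}

#' Validate a building-block table
#'
#' Checks the invariants of the building-block record: ids unique within a
#' cycle, cycle in \{1, 2\}, positive molecular weight, non-negative count
#' of unassigned stereocenters.
#'
#' @param bb A building-block `data.frame` (see [read_building_blocks()]).
#' @return The table, invisibly normalised (missing optional columns added).
#' @export
validate_building_blocks <- function(bb) {
  need <- c("bb_id", "cycle", "mw")
  miss <- setdiff(need, names(bb))
  if (length(miss))
    stop("building-block table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"smiles" %in% names(bb)) bb$smiles <- NA_character_
  if (!"n_unassigned_stereocenters" %in% names(bb))
    bb$n_unassigned_stereocenters <- 0L
  if (!"flags" %in% names(bb)) bb$flags <- ""
  bb$flags[is.na(bb$flags)] <- ""
  bb$cycle <- as.integer(bb$cycle)
  if (!all(bb$cycle %in% c(1L, 2L)))
    stop("`cycle` must be 1 or 2 for every building block", call. = FALSE)
  if (any(!is.finite(bb$mw) | bb$mw <= 0))
    stop("`mw` must be positive for every building block", call. = FALSE)
  if (any(bb$n_unassigned_stereocenters < 0))
    stop("`n_unassigned_stereocenters` must be >= 0", call. = FALSE)
  for (cy in unique(bb$cycle)) {
    ids <- bb$bb_id[bb$cycle == cy]
    if (anyDuplicated(ids))
      stop(sprintf("duplicate bb_id within cycle %d: %s", cy,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           call. = FALSE)
  }
  bb
}

# Split a `;`-separated flag string into a character vector (empty -> none).
parse_flags <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(f) f[nzchar(f)])
}

#' Filter building blocks by physicochemical and structural criteria
#'
#' Applies the library-design QC filters: a strict molecular-weight cutoff
#' (`mw < max_mw`; a BB at exactly the cutoff is excluded), a ban list of
#' structural-alert flags, and a cap on unassigned stereocenters. Input
#' order is preserved and the input is not modified.
#'
#' @param bbs Building-block `data.frame`.
#' @param max_mw Strict upper bound on molecular weight in Da (default 200).
#' @param banned_flags Character vector of banned structural-alert labels
#'   (default none); a BB carrying any banned flag is excluded.
#' @param max_unassigned_stereocenters Maximum number of unassigned
#'   stereocenters allowed (default 0).
#' @return The retained rows of `bbs`, in input order. Warns (does not
#'   error) if nothing is retained.
#' @export
#' @examples
#' bb <- data.frame(bb_id = c("a1", "a2"), cycle = 2L,
#'                  mw = c(150, 210), n_unassigned_stereocenters = 0L,
#'                  flags = "", stringsAsFactors = FALSE)
#' filter_building_blocks(bb, max_mw = 200)
filter_building_blocks <- function(bbs, max_mw = 200,
                                   banned_flags = character(),
                                   max_unassigned_stereocenters = 0L) {
  if (NROW(bbs) == 0L) stop("`bbs` must be non-empty", call. = FALSE)
  check_pos(max_mw, "max_mw")
  check_nonneg(max_unassigned_stereocenters, "max_unassigned_stereocenters")
  bbs <- validate_building_blocks(bbs)
  flag_ok <- vapply(parse_flags(bbs$flags),
                    function(f) !any(f %in% banned_flags), logical(1))
  keep <- bbs$mw < max_mw & flag_ok &
    bbs$n_unassigned_stereocenters <= max_unassigned_stereocenters
  out <- bbs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no building blocks pass the filters", call. = FALSE)
  out
}
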