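#' Tanimoto coefficient between two binary fingerprints
#'
#' Fingerprints are given as sets of "on" bit identifiers (integer or
#' character vectors). The Tanimoto (Jaccard) coefficient is the size of the
#' intersection over the size of the union; two empty fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b Vectors of on-bit identifiers.
#' @return A number in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Default fingerprint: the set of distinct ChemmineR atom-pair descriptors
# (binary presence fingerprint), via openbabel SMILES parsing (ChemmineOB).
chemmine_fingerprint <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the default fingerprint needs ChemmineR + ChemmineOB; ",
         "supply `fingerprint_fun` instead", call. = FALSE)
  # duplicate SMILES (e.g. the reference also being a member) are fine here;
  # ChemmineR only warns about its compound-id bookkeeping
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  apset <- ChemmineR::sdf2ap(sdf)
  lapply(ChemmineR::ap(apset), unique)
}

#' 2D fingerprint similarity of library members to a reference compound
#'
#' A two-dimensional structural similarity profile of the enumerated
#' library against a reference molecule, as Tanimoto similarity of binary
#' fingerprints. This is explicitly a 2D stand-in: it does not implement 3D
#' conformer shape/color overlap scoring, and its absolute values are not
#' comparable to 3D shape Tanimoto scores.
#'
#' Member SMILES are formed by joining the starter and acid SMILES with `.`
#' (an unreacted mixture record) unless `member_smiles` supplies assembled
#' product structures; either way the profile ranks members by shared 2D
#' features with the reference.
#'
#' @param members Library `data.frame` from [enumerate_library()].
#' @param bb_smiles Named character vector, bb_id -> SMILES, covering the
#'   starters and acids (used when `member_smiles` is absent).
#' @param reference_smiles SMILES of the reference compound.
#' @param member_smiles Optional named character vector, member_id -> SMILES
#'   of the assembled product.
#' @param fingerprint_fun Function mapping a character vector of SMILES to a
#'   list of on-bit vectors (one per molecule). Defaults to ChemmineR
#'   atom-pair 1024-bit fingerprints.
#' @return A `data.frame` with columns `member_id` and `tanimoto` (in
#'   \[0, 1\]). Members whose SMILES are missing or unparseable are skipped
#'   with a warning, not an error.
#' @export
similarity_profile <- function(members, bb_smiles = NULL, reference_smiles,
                               member_smiles = NULL,
                               fingerprint_fun = chemmine_fingerprint) {
  if (is.null(member_smiles)) {
    if (is.null(bb_smiles))
      stop("supply `bb_smiles` or `member_smiles`", call. = FALSE)
    member_smiles <- stats::setNames(
      paste(bb_smiles[members$starter_id], bb_smiles[members$acid_id],
            sep = "."),
      members$member_id)
    bad <- is.na(bb_smiles[members$starter_id]) |
      is.na(bb_smiles[members$acid_id])
    member_smiles[bad] <- NA_character_
  }
  smi <- member_smiles[members$member_id]
  usable <- !is.na(smi) & nzchar(smi)
  if (any(!usable))
    warning(sprintf("%d member(s) skipped: missing SMILES", sum(!usable)),
            call. = FALSE)
  fps <- tryCatch(
    fingerprint_fun(c(reference_smiles, unname(smi[usable]))),
    error = function(e) stop("fingerprinting failed: ", conditionMessage(e),
                             call. = FALSE))
  ref_fp <- fps[[1]]
  sims <- vapply(fps[-1], tanimoto, numeric(1), b = ref_fp)
  data.frame(member_id = members$member_id[usable],
             tanimoto = unname(sims),
             stringsAsFactors = FALSE)
}
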