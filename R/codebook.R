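DNA_ALPHABET <- c("A", "C", "G", "T")

# Pairwise Hamming distance between one codon and a set of codons, all the
# same length. Codons are plain character strings over ACGT.
hamming_to_set <- function(codon, set) {
  if (length(set) == 0L) return(integer(0))
  x <- strsplit(codon, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(set, "", fixed = TRUE)),
              nrow = length(x))
  colSums(m != x)
}

#' Pairwise Hamming distance between two equal-length DNA strings
#' @param a,b DNA strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Greedy random code construction: draw random codons, keep those at
# Hamming >= d_min from everything kept so far. Deterministic under seed.
grow_code <- function(n_needed, codon_length, d_min, avoid = character()) {
  # Singleton bound: a code of length L and minimum distance d has at most
  # 4^(L - d + 1) words; reject impossible requests up front.
  if (n_needed > 4^(codon_length - d_min + 1))
    stop(sprintf(
      "capacity error: cannot place %d codons of length %d at d_min = %d",
      n_needed, codon_length, d_min), call. = FALSE)
  code <- character(0)
  attempts <- 0L
  max_attempts <- max(10000L, 2000L * n_needed)
  while (length(code) < n_needed) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "capacity error: could not place %d codons (length %d, d_min %d) after %d attempts",
        n_needed, codon_length, d_min, max_attempts), call. = FALSE)
    cand <- paste(sample(DNA_ALPHABET, codon_length, replace = TRUE),
                  collapse = "")
    if (all(hamming_to_set(cand, code) >= d_min) &&
        all(hamming_to_set(cand, avoid) >= d_min))
      code <- c(code, cand)
  }
  code
}

#' Build a DNA codebook for a two-cycle library
#'
#' Assigns each cycle-1 and cycle-2 building block appearing in the library
#' a DNA codon such that, within each cycle, all codons are separated by at
#' least `d_min` substitutions (so up to `floor((d_min - 1) / 2)`
#' sequencing substitutions per codon are uniquely correctable). A reserved
#' control codon, at distance >= `d_min` from every cycle-1 codon, marks
#' positive-control beads. Construction is greedy random placement and is
#' deterministic given `seed`.
#'
#' @param members Library `data.frame` from [enumerate_library()].
#' @param codon_length Codon length in nt (default 8).
#' @param d_min Minimum within-cycle pairwise Hamming distance (default 3).
#' @param seed Integer seed for codon placement.
#' @param amplicon_layout Optional named list with constant segments
#'   `const5`, `spacer`, `const3` (DNA strings) flanking and separating the
#'   two codon slots; defaults are fixed stand-in sequences.
#' @return An object of class `codebook`: a list with `codon_length`,
#'   `cycle1_codons` and `cycle2_codons` (named character vectors,
#'   bb_id -> codon), `reserved_control_codon`, and `amplicon_layout`
#'   (ordered segments const5, codon1, spacer, codon2, const3).
#' @export
build_codebook <- function(members, codon_length = 8L, d_min = 3L, seed = 1L,
                           amplicon_layout = NULL) {
  check_pos(codon_length, "codon_length")
  if (d_min < 1L) stop("`d_min` must be >= 1", call. = FALSE)
  starters <- unique(members$starter_id)
  acids <- unique(members$acid_id)
  layout <- amplicon_layout %||%
    list(const5 = "TCAGCGTACG", spacer = "ACCTGG", const3 = "GTCGATCGAT")
  for (seg in c("const5", "spacer", "const3"))
    if (!grepl("^[ACGT]+$", layout[[seg]]))
      stop(sprintf("`amplicon_layout$%s` must be a non-empty ACGT string",
                   seg), call. = FALSE)
  with_seed(seed, {
    # control codon is grown with the cycle-1 code so the d_min guarantee
    # extends to it; it occupies the codon1 slot on control-bead amplicons
    c1 <- grow_code(length(starters) + 1L, codon_length, d_min)
    control <- c1[length(c1)]
    c1 <- c1[-length(c1)]
    c2 <- grow_code(length(acids), codon_length, d_min)
    structure(list(
      codon_length = as.integer(codon_length),
      d_min = as.integer(d_min),
      cycle1_codons = stats::setNames(c1, starters),
      cycle2_codons = stats::setNames(c2, acids),
      reserved_control_codon = control,
      amplicon_layout = list(
        const5 = layout$const5, codon1 = NA_character_,
        spacer = layout$spacer, codon2 = NA_character_,
        const3 = layout$const3)
    ), class = "codebook")
  })
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "codebook: %d cycle-1 + %d cycle-2 codons, length %d nt, d_min %d\n",
    length(x$cycle1_codons), length(x$cycle2_codons),
    x$codon_length, x$d_min))
  cat(sprintf("amplicon: %s-[codon1]-%s-[codon2]-%s (%d nt)\n",
              x$amplicon_layout$const5, x$amplicon_layout$spacer,
              x$amplicon_layout$const3, amplicon_length(x)))
  invisible(x)
}

# Total amplicon length implied by the codebook layout.
amplicon_length <- function(codebook) {
  nchar(codebook$amplicon_layout$const5) + 2L * codebook$codon_length +
    nchar(codebook$amplicon_layout$spacer) +
    nchar(codebook$amplicon_layout$const3)
}

# 1-based [start, end] of the two codon slots within the amplicon.
codon_slots <- function(codebook) {
  a <- nchar(codebook$amplicon_layout$const5)
  L <- codebook$codon_length
  s <- nchar(codebook$amplicon_layout$spacer)
  list(codon1 = c(a + 1L, a + L),
       codon2 = c(a + L + s + 1L, a + L + s + L))
}

#' Write / read a codebook's codon table as TSV
#'
#' The TSV holds the codon assignments (`cycle`, `bb_id`, `codon`, with the
#' reserved control codon under cycle 0); the amplicon layout travels in the
#' pipeline config.
#'
#' @param codebook A `codebook` object.
#' @param path Output TSV path.
#' @return `write_codebook` returns `path` invisibly.
#' @export
write_codebook <- function(codebook, path) {
  df <- rbind(
    data.frame(cycle = 0L, bb_id = "__control__",
               codon = codebook$reserved_control_codon),
    data.frame(cycle = 1L, bb_id = names(codebook$cycle1_codons),
               codon = unname(codebook$cycle1_codons)),
    data.frame(cycle = 2L, bb_id = names(codebook$cycle2_codons),
               codon = unname(codebook$cycle2_codons))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @param d_min,amplicon_layout Metadata not stored in the TSV, re-supplied
#'   on read (defaults match [build_codebook()]).
#' @return `read_codebook` returns a `codebook` object.
#' @export
read_codebook <- function(path, d_min = 3L, amplicon_layout = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "character"))
  layout <- amplicon_layout %||%
    list(const5 = "TCAGCGTACG", spacer = "ACCTGG", const3 = "GTCGATCGAT")
  c1 <- df[df$cycle == 1L, ]
  c2 <- df[df$cycle == 2L, ]
  structure(list(
    codon_length = nchar(df$codon[1]),
    d_min = as.integer(d_min),
    cycle1_codons = stats::setNames(c1$codon, c1$bb_id),
    cycle2_codons = stats::setNames(c2$codon, c2$bb_id),
    reserved_control_codon = df$codon[df$cycle == 0L][1],
    amplicon_layout = list(const5 = layout$const5, codon1 = NA_character_,
                           spacer = layout$spacer, codon2 = NA_character_,
                           const3 = layout$const3)
  ), class = "codebook")
}

#' Minimum pairwise Hamming distance within a set of codons
#'
#' Exhaustive all-pairs check, used to verify codebook invariants.
#'
#' @param codons Character vector of equal-length DNA strings.
#' @return The minimum pairwise distance (`Inf` for fewer than 2 codons).
#' @export
min_pairwise_hamming <- function(codons) {
  n <- length(codons)
  if (n < 2L) return(Inf)
  m <- matrix(unlist(strsplit(codons, "", fixed = TRUE)), ncol = n)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    best <- min(best, d)
  }
  best
}
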