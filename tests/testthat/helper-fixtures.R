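# Toy fixtures built in code; no files on disk.

toy_starters <- function(n = 3L) {
  data.frame(bb_id = sprintf("S%d", seq_len(n)), cycle = 1L,
             smiles = NA_character_, mw = 120 + seq_len(n),
             n_unassigned_stereocenters = 0L, flags = "",
             stringsAsFactors = FALSE)
}

toy_acids <- function(n = 4L) {
  data.frame(bb_id = sprintf("A%d", seq_len(n)), cycle = 2L,
             smiles = NA_character_, mw = 100 + seq_len(n),
             n_unassigned_stereocenters = 0L, flags = "",
             stringsAsFactors = FALSE)
}

toy_library <- function(ns = 3L, na = 4L) {
  enumerate_library(toy_starters(ns), toy_acids(na))
}

# A hand-written codebook (no RNG) for decoder unit tests.
manual_codebook <- function(cycle1, cycle2, control, d_min = 3L) {
  structure(list(
    codon_length = nchar(cycle1[[1]]),
    d_min = as.integer(d_min),
    cycle1_codons = cycle1,
    cycle2_codons = cycle2,
    reserved_control_codon = control,
    amplicon_layout = list(const5 = "TCAGCGTACG", codon1 = NA_character_,
                           spacer = "ACCTGG", codon2 = NA_character_,
                           const3 = "GTCGATCGAT")
  ), class = "codebook")
}

# Amplicon for a (codon1, codon2) pair under a codebook's layout.
make_amplicon <- function(codebook, c1, c2) {
  lay <- codebook$amplicon_layout
  paste0(lay$const5, c1, lay$spacer, c2, lay$const3)
}

# Substitute one base at position `pos` of `seq` to a different base.
flip_base <- function(seq, pos, to = NULL) {
  b <- substr(seq, pos, pos)
  repl <- to %||% setdiff(c("A", "C", "G", "T"), b)[1]
  paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
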