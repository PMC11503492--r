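#' Generate bead-barcode amplicon reads
#'
#' Emits `reads_per_bead` sequencing reads for every bead in the (typically
#' sorted) bead collection. A library bead's read is the amplicon
#' `const5 + codon1(starter) + spacer + codon2(acid) + const3`; a
#' positive-control bead carries the reserved control codon in both codon
#' slots. Substitution errors are applied i.i.d. per base at
#' `sub_error_rate` (substituted bases are drawn uniformly from the three
#' alternatives). Read ids encode the bead id as `"<bead_id>/<read#>"` —
#' simulation ground truth for recovery tests.
#'
#' @param beads Bead `data.frame` (needs `bead_id`, `kind`, `structure_id`;
#'   library structure ids must be `"<starter>-<acid>"` member ids covered
#'   by the codebook).
#' @param codebook A [build_codebook()] object.
#' @param reads_per_bead Reads to emit per bead (> 0).
#' @param sub_error_rate Per-base substitution probability in \[0, 1\].
#' @param seed Integer seed; output is byte-identical given it.
#' @return A named character vector of read sequences (names are read ids),
#'   of length `nrow(beads) * reads_per_bead`.
#' @export
generate_reads <- function(beads, codebook, reads_per_bead = 20L,
                           sub_error_rate = 0.01, seed = 1L) {
  if (!is.numeric(reads_per_bead) || reads_per_bead <= 0)
    stop("`reads_per_bead` must be > 0", call. = FALSE)
  check_frac(sub_error_rate, "sub_error_rate")
  if (nrow(beads) == 0L) return(stats::setNames(character(0), character(0)))
  is_ctrl <- beads$kind == "control_pos"
  starter <- sub("-.*$", "", beads$structure_id)
  acid <- sub("^[^-]*-", "", beads$structure_id)
  c1 <- ifelse(is_ctrl, codebook$reserved_control_codon,
               codebook$cycle1_codons[starter])
  c2 <- ifelse(is_ctrl, codebook$reserved_control_codon,
               codebook$cycle2_codons[acid])
  if (anyNA(c1) || anyNA(c2))
    stop("some bead structures have no codons in the codebook",
         call. = FALSE)
  lay <- codebook$amplicon_layout
  amplicon <- paste0(lay$const5, c1, lay$spacer, c2, lay$const3)
  reads <- rep(amplicon, each = reads_per_bead)
  ids <- paste0(rep(beads$bead_id, each = reads_per_bead), "/",
                rep(seq_len(reads_per_bead), times = nrow(beads)))
  with_seed(seed, {
    if (sub_error_rate > 0) {
      L <- nchar(reads[1])
      mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                    nrow = L)
      hit <- which(stats::runif(length(mat)) < sub_error_rate)
      if (length(hit)) {
        # uniform over the three non-identical bases
        cur <- mat[hit]
        repl <- vapply(cur, function(b)
          sample(setdiff(DNA_ALPHABET, b), 1L), character(1))
        mat[hit] <- repl
        reads <- apply(mat, 2, paste, collapse = "")
      }
    }
    stats::setNames(reads, ids)
  })
}

#' Write / read amplicon reads as FASTQ
#'
#' Standard 4-line FASTQ via Biostrings; qualities are uniform placeholders
#' (the decoder uses Hamming distance, not base qualities).
#'
#' @param reads Named character vector from [generate_reads()].
#' @param path FASTQ path.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` a named
#'   character vector of sequences.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(unname(reads))
  names(seqs) <- names(reads)
  quals <- Biostrings::BStringSet(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(seqs), names(seqs))
}
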