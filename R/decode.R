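# Match observed codons against a codon table within max_mismatch.
# Returns a data.frame with bb_id, dist, status for each observed codon.
# status: exact / corrected / ambiguous / fail.
match_codons <- function(obs, table_codons, control_codon, max_mismatch) {
  ids <- c(names(table_codons), "__control__")
  codons <- c(unname(table_codons), control_codon)
  L <- nchar(codons[1])
  uobs <- unique(obs)
  bad_len <- nchar(uobs) != L
  cm <- matrix(unlist(strsplit(codons, "", fixed = TRUE)), nrow = L)
  res_id <- character(length(uobs))
  res_status <- character(length(uobs))
  for (i in seq_along(uobs)) {
    if (bad_len[i]) { res_id[i] <- NA; res_status[i] <- "fail"; next }
    d <- colSums(cm != strsplit(uobs[i], "", fixed = TRUE)[[1]])
    dmin <- min(d)
    if (dmin == 0L) {
      res_id[i] <- ids[which.min(d)]; res_status[i] <- "exact"
    } else if (dmin <= max_mismatch) {
      cand <- which(d == dmin)
      if (length(cand) == 1L) {
        res_id[i] <- ids[cand]; res_status[i] <- "corrected"
      } else {
        res_id[i] <- NA; res_status[i] <- "ambiguous"
      }
    } else {
      res_id[i] <- NA; res_status[i] <- "fail"
    }
  }
  j <- match(obs, uobs)
  data.frame(bb_id = res_id[j], status = res_status[j],
             stringsAsFactors = FALSE)
}

#' Decode amplicon reads into building-block identities
#'
#' Extracts the two codon slots from each read at the fixed amplicon
#' offsets and matches each against its cycle's codon table. Per slot: an
#' exact match decodes directly; otherwise a unique codon within Hamming
#' distance `max_mismatch` is a correction; two or more equidistant
#' candidates are ambiguous; none within reach fails. The reserved control
#' codon in the codon-1 slot marks a control-bead read. Reads of the wrong
#' length get status `fail` (no exception).
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids, `"<bead_id>/<read#>"`).
#' @param codebook A [build_codebook()] object.
#' @param max_mismatch Maximum Hamming distance for codon correction
#'   (default 1, matching a d_min-3 codebook).
#' @return A `data.frame` with one row per read: `read_id`, `bead_id`,
#'   `codon1_id`, `codon2_id`, `status`
#'   (`exact`/`corrected`/`ambiguous`/`fail`) and `is_control`. The read
#'   status is the worse of the two slot statuses (`exact` < `corrected` <
#'   `ambiguous` < `fail`).
#' @export
decode_reads <- function(reads, codebook, max_mismatch = 1L) {
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), bead_id = character(),
                      codon1_id = character(), codon2_id = character(),
                      status = character(), is_control = logical(),
                      stringsAsFactors = FALSE))
  slots <- codon_slots(codebook)
  len_ok <- nchar(reads) == amplicon_length(codebook)
  obs1 <- ifelse(len_ok, substr(reads, slots$codon1[1], slots$codon1[2]), "")
  obs2 <- ifelse(len_ok, substr(reads, slots$codon2[1], slots$codon2[2]), "")
  m1 <- match_codons(obs1, codebook$cycle1_codons,
                     codebook$reserved_control_codon, max_mismatch)
  m2 <- match_codons(obs2, codebook$cycle2_codons,
                     codebook$reserved_control_codon, max_mismatch)
  is_control <- !is.na(m1$bb_id) & m1$bb_id == "__control__"
  rank <- c(exact = 1L, corrected = 2L, ambiguous = 3L, fail = 4L)
  worse <- pmax(rank[m1$status], rank[m2$status])
  status <- names(rank)[worse]
  # a control read only needs its codon-1 slot; codon 2 carries no identity
  status[is_control] <- m1$status[is_control]
  status[!len_ok] <- "fail"
  data.frame(
    read_id = names(reads),
    bead_id = sub("/[^/]*$", "", names(reads)),
    codon1_id = ifelse(is_control, NA_character_, m1$bb_id),
    codon2_id = ifelse(is_control, NA_character_, m2$bb_id),
    status = status,
    is_control = is_control,
    stringsAsFactors = FALSE)
}

#' @rdname decode_reads
#' @param seq A single read sequence.
#' @return `decode_read` returns a one-row `data.frame` of the same shape.
#' @export
decode_read <- function(seq, codebook, max_mismatch = 1L) {
  decode_reads(stats::setNames(seq, "read/1"), codebook, max_mismatch)
}

#' Call a per-bead structure from its decoded reads
#'
#' Among a bead's non-failed reads, the plurality (codon1, codon2) pair —
#' or control identity — wins if its support fraction among non-failed
#' reads reaches `min_support`; an exact tie for the plurality, an
#' under-supported winner, or zero usable reads yields a no-call.
#'
#' @param decoded Decoded-read `data.frame` from [decode_reads()] (may span
#'   many beads).
#' @param min_support Minimum support fraction among non-fail reads
#'   (default 0.5).
#' @return A `data.frame` with one row per bead: `bead_id`, `call`
#'   (structure id `"<starter>-<acid>"`, `"control"`, or `NA` for
#'   no-call), `support` (winning fraction), `n_reads`, `n_usable`.
#' @export
call_beads <- function(decoded, min_support = 0.5) {
  check_frac(min_support, "min_support")
  split_idx <- split(seq_len(nrow(decoded)), decoded$bead_id)
  rows <- lapply(names(split_idx), function(b) {
    d <- decoded[split_idx[[b]], ]
    usable <- d$status %in% c("exact", "corrected") &
      (d$is_control | (!is.na(d$codon1_id) & !is.na(d$codon2_id)))
    du <- d[usable, ]
    if (nrow(du) == 0L)
      return(data.frame(bead_id = b, call = NA_character_, support = 0,
                        n_reads = nrow(d), n_usable = 0L,
                        stringsAsFactors = FALSE))
    lab <- ifelse(du$is_control, "control",
                  paste(du$codon1_id, du$codon2_id, sep = "-"))
    tab <- sort(table(lab), decreasing = TRUE)
    top <- tab[1]
    tie <- length(tab) > 1L && tab[2] == top
    supp <- as.numeric(top) / nrow(du)
    call <- if (!tie && supp >= min_support) names(tab)[1] else NA_character_
    data.frame(bead_id = b, call = call, support = supp,
               n_reads = nrow(d), n_usable = nrow(du),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname call_beads
#' @export
call_bead <- function(decoded, min_support = 0.5) {
  call_beads(decoded, min_support)
}
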