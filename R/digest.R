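#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal to every K or R, including before proline.
#' Proline suppression is deliberately off by default: short fully cleaved
#' forms such as `D(pS)LQK` followed by P arise only under unconditional K/R
#' cleavage, and these are exactly the forms the short-peptide rescue logic
#' needs to see. Set `proline_rule = TRUE` for the classical suppressed rule.
#'
#' @param sequence protein sequence (uppercase one-letter residues), or a
#'   one-row protein entry as returned by [read_proteome_fasta()].
#' @param max_missed maximum number of missed cleavages, 0..2.
#' @param proline_rule if `TRUE`, suppress cleavage when the following residue
#'   is proline.
#' @return data.frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive protein coordinates), `missed_cleavages`, `length`, ordered by
#'   `start` then `missed_cleavages`.
#' @examples
#' digest("AKRDSLQKPGLEAPPRW", max_missed = 0)$sequence
#' @export
digest <- function(sequence, max_missed = 2L, proline_rule = FALSE) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  check_sequence(sequence, "protein sequence")
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L || max_missed > 2L) {
    stop("max_missed must be in 0..2", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  # cut points: after position i when chars[i] is K/R (and not before P if
  # the suppressed rule is requested); protein termini always cut
  is_site <- chars %in% c("K", "R")
  if (proline_rule && n > 1L) {
    is_site[seq_len(n - 1L)] <- is_site[seq_len(n - 1L)] &
      chars[seq.int(2L, n)] != "P"
  }
  is_site[n] <- FALSE                      # C-terminus is a boundary anyway
  cuts <- c(0L, which(is_site), n)         # boundaries after these positions
  nseg <- length(cuts) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      start <- cuts[i] + 1L
      end <- cuts[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, start, end),
        start = start, end = end,
        missed_cleavages = j - i,
        length = end - start + 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$missed_cleavages), , drop = FALSE]
}

#' Map a phosphosite onto digestion products
#'
#' Returns the candidate peptides whose coordinate window contains the site,
#' with the site's within-peptide offset recorded, sorted by missed cleavages
#' ascending (fully cleaved form first).
#'
#' @param position 1-based position of the phosphosite in the protein.
#' @param residue expected residue at that position (`"S"`, `"T"` or `"Y"`).
#' @param peptides digestion products from [digest()] of the same protein.
#' @param protein_sequence optional protein sequence for residue validation.
#' @return the matching rows of `peptides` with an added `phospho_offset`
#'   column (1-based position of the site within the peptide).
#' @export
map_site <- function(position, residue, peptides, protein_sequence = NULL) {
  position <- as.integer(position)
  residue <- match.arg(residue, c("S", "T", "Y"))
  if (!is.null(protein_sequence)) {
    if (position < 1L || position > nchar(protein_sequence)) {
      stop("site position ", position, " outside protein (length ",
           nchar(protein_sequence), ")", call. = FALSE)
    }
    found <- substr(protein_sequence, position, position)
    if (found != residue) {
      stop("residue mismatch at position ", position, ": expected ", residue,
           ", protein has ", found, call. = FALSE)
    }
  }
  hit <- peptides$start <= position & peptides$end >= position
  res <- peptides[hit, , drop = FALSE]
  if (nrow(res) == 0L) {
    res$phospho_offset <- integer(0)
    return(res)
  }
  res$phospho_offset <- position - res$start + 1L
  res <- res[order(res$missed_cleavages, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}
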