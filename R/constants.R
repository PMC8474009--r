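#' Monoisotopic mass constants
#'
#' Single authoritative table of monoisotopic residue masses and modification
#' deltas used throughout the package. All mass arithmetic (precursor m/z,
#' fragment m/z, heavy/light deltas) is derived from this one table so that
#' light and heavy forms, and all fragment series, stay mutually consistent.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{residues}{named numeric vector, monoisotopic residue (chain) masses
#'     in Da for the 20 standard amino acids}
#'   \item{proton}{proton mass, Da}
#'   \item{water}{water mass, Da (added once per peptide chain)}
#'   \item{mods}{named numeric vector of modification deltas in Da:
#'     \code{phospho} (+HPO3), and full 13C/15N substitutions
#'     \code{heavy_K}, \code{heavy_R}, \code{heavy_L}, \code{heavy_P}}
#' }
#' @export
mass_constants <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    proton = 1.0072765,
    water  = 18.0105646,
    mods = c(
      phospho = 79.9663305,
      heavy_K = 8.01420,
      heavy_R = 10.00827,
      heavy_L = 7.01723,
      heavy_P = 6.01385
    )
  )
}

#' @keywords internal
.AMINO_ACIDS <- names(mass_constants()$residues)

#' Check a peptide/protein sequence for standard residues
#'
#' @param sequence character scalar, uppercase one-letter amino acids.
#' @param what label used in the error message.
#' @return invisibly, the sequence.
#' @keywords internal
check_sequence <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop("non-standard residue '", bad[[1L]], "' in ", what, call. = FALSE)
  }
  invisible(sequence)
}
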