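#' Construct a modified peptide
#'
#' A light or heavy (stable-isotope-labeled, SIL) phosphopeptide with explicit
#' modification bookkeeping. Phosphorylation is only accepted on S/T/Y; the
#' heavy label must match its residue, and a heavy peptide carries exactly one
#' labeled residue (the synthesis convention for SIL internal standards).
#'
#' @param sequence peptide sequence, uppercase one-letter amino acids.
#' @param phospho integer vector of 1-based phosphorylated positions within
#'   the peptide (on S, T or Y).
#' @param heavy_pos 1-based position of the stable-isotope label, or `NULL`
#'   for a light peptide. The residue at this position must be K, R, L or P.
#' @param charge precursor charge state (>= 1).
#' @param label `"light"` or `"heavy"`; defaults to heavy when `heavy_pos`
#'   is given.
#' @return An object of class `modified_peptide`.
#' @examples
#' p <- modified_peptide("RDSLQKPGLEAPPR", phospho = 3, heavy_pos = 14)
#' monoisotopic_mass(p)
#' @export
modified_peptide <- function(sequence, phospho = integer(), heavy_pos = NULL,
                             charge = 2L,
                             label = if (is.null(heavy_pos)) "light" else "heavy") {
  check_sequence(sequence, "peptide sequence")
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  phospho <- as.integer(phospho)
  if (any(phospho < 1L | phospho > n)) {
    stop("phospho position outside peptide", call. = FALSE)
  }
  if (any(!chars[phospho] %in% c("S", "T", "Y"))) {
    stop("phospho only allowed on S/T/Y residues", call. = FALSE)
  }
  label <- match.arg(label, c("light", "heavy"))
  heavy_kind <- NULL
  if (!is.null(heavy_pos)) {
    heavy_pos <- as.integer(heavy_pos)
    stopifnot(length(heavy_pos) == 1L, heavy_pos >= 1L, heavy_pos <= n)
    res <- chars[heavy_pos]
    if (!res %in% c("K", "R", "L", "P")) {
      stop("heavy label supported on K/R/L/P, got '", res, "'", call. = FALSE)
    }
    heavy_kind <- paste0("heavy_", res)
    if (label != "heavy") {
      stop("a peptide with a heavy label must have label = 'heavy'",
           call. = FALSE)
    }
  } else if (label == "heavy") {
    stop("heavy peptide requires heavy_pos", call. = FALSE)
  }
  charge <- as.integer(charge)
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  structure(
    list(sequence = sequence, phospho = sort(phospho),
         heavy_pos = heavy_pos, heavy_kind = heavy_kind,
         charge = charge, label = label),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(modified_sequence(x), sprintf("(%d+, %s)\n", x$charge, x$label))
  invisible(x)
}

#' Render a peptide with phospho annotations
#'
#' Phosphorylated residues are wrapped as `(pS)`, `(pT)`, `(pY)` in the
#' field's usual notation, e.g. `"RD(pS)LQKPGLEAPPR"`.
#'
#' @param peptide a `modified_peptide`, or a plain sequence with `phospho`.
#' @param phospho phospho positions when `peptide` is a character sequence.
#' @return character scalar.
#' @export
modified_sequence <- function(peptide, phospho = integer()) {
  if (inherits(peptide, "modified_peptide")) {
    seq <- peptide$sequence
    phospho <- peptide$phospho
  } else {
    seq <- peptide
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(phospho) > 0L) {
    chars[phospho] <- paste0("(p", chars[phospho], ")")
  }
  paste(chars, collapse = "")
}

# per-residue mass vector including mods located at each position
.residue_masses <- function(peptide) {
  cst <- mass_constants()
  chars <- strsplit(peptide$sequence, "", fixed = TRUE)[[1L]]
  m <- unname(cst$residues[chars])
  if (length(peptide$phospho) > 0L) {
    m[peptide$phospho] <- m[peptide$phospho] + cst$mods[["phospho"]]
  }
  if (!is.null(peptide$heavy_pos)) {
    m[peptide$heavy_pos] <- m[peptide$heavy_pos] + cst$mods[[peptide$heavy_kind]]
  }
  m
}

#' Monoisotopic mass of a modified peptide
#'
#' Sum of residue chain masses plus one water, plus modification deltas
#' (+79.96633 Da per phosphate; 13C/15N label deltas for heavy residues).
#'
#' @param peptide a `modified_peptide`.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  sum(.residue_masses(peptide)) + mass_constants()$water
}

#' Precursor m/z
#'
#' `(M + z * proton) / z` for the peptide's charge state (or an explicit one).
#'
#' @param peptide a `modified_peptide`.
#' @param charge optional charge override (>= 1).
#' @return m/z in Th.
#' @export
precursor_mz <- function(peptide, charge = peptide$charge) {
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge < 1L) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  cst <- mass_constants()
  (monoisotopic_mass(peptide) + charge * cst$proton) / charge
}

#' Fragment ion m/z (b/y series)
#'
#' b_i covers residues 1..i (N-terminal), y_i covers the last i residues
#' (C-terminal, retains the water). Modifications within the fragment span are
#' included, so phospho-bearing fragments shift by +79.96633 Da.
#'
#' @param peptide a `modified_peptide`.
#' @param series `"b"` or `"y"`.
#' @param index fragment index, 1..(length-1).
#' @param charge fragment charge (>= 1).
#' @return m/z in Th.
#' @export
fragment_mz <- function(peptide, series, index, charge = 1L) {
  stopifnot(inherits(peptide, "modified_peptide"))
  series <- match.arg(series, c("b", "y"))
  n <- nchar(peptide$sequence)
  index <- as.integer(index)
  if (index < 1L || index > n - 1L) {
    stop("fragment index out of range (1..", n - 1L, ")", call. = FALSE)
  }
  charge <- as.integer(charge)
  if (charge < 1L) stop("fragment charge must be >= 1", call. = FALSE)
  cst <- mass_constants()
  m <- .residue_masses(peptide)
  neutral <- if (series == "b") {
    sum(m[seq_len(index)])
  } else {
    sum(m[seq.int(n - index + 1L, n)]) + cst$water
  }
  (neutral + charge * cst$proton) / charge
}
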