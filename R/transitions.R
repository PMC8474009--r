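#' Is a fragment site-determining?
#'
#' A fragment is site-determining when its residue span contains the
#' phosphorylated residue, or when the fragmentation boundary separates the
#' phosphosite from an alternative S/T/Y acceptor elsewhere in the peptide --
#' either way its mass discriminates positional phospho-isomers.
#'
#' @param peptide a `modified_peptide` with at least one phospho site.
#' @param series `"b"` or `"y"`.
#' @param index fragment index, 1..(length-1).
#' @return logical flag.
#' @export
site_determining <- function(peptide, series, index) {
  stopifnot(inherits(peptide, "modified_peptide"))
  series <- match.arg(series, c("b", "y"))
  n <- nchar(peptide$sequence)
  index <- as.integer(index)
  if (index < 1L || index > n - 1L) stop("fragment index out of range",
                                         call. = FALSE)
  if (length(peptide$phospho) == 0L) return(FALSE)
  chars <- strsplit(peptide$sequence, "", fixed = TRUE)[[1L]]
  cut <- if (series == "b") index else n - index  # boundary after `cut`
  span <- if (series == "b") seq_len(index) else seq.int(n - index + 1L, n)
  if (any(peptide$phospho %in% span)) return(TRUE)
  acceptors <- setdiff(which(chars %in% c("S", "T", "Y")), peptide$phospho)
  if (length(acceptors) == 0L) return(FALSE)
  any((peptide$phospho <= cut) != (acceptors <= cut))
}

#' Linear collision-energy formula
#'
#' The common triple-quadrupole parameterization `CE = slope * m/z +
#' intercept`, per precursor charge, rounded to 0.1 eV. Coefficients are
#' instrument-specific; the defaults are the widely used 2+/3+ values and
#' can be overridden via the configuration.
#'
#' @param precursor_mz precursor m/z in Th.
#' @param charge precursor charge.
#' @param coefficients named list of `list(slope=, intercept=)` keyed by
#'   charge as character (defaults from [default_config()]).
#' @return collision energy in eV.
#' @examples
#' calc_ce(500, 2)  # 19.3
#' @export
calc_ce <- function(precursor_mz, charge,
                    coefficients = default_config()$ce_coefficients) {
  key <- as.character(as.integer(charge))
  if (!key %in% names(coefficients)) {
    stop("no CE coefficients for charge ", key, call. = FALSE)
  }
  co <- coefficients[[key]]
  round(co$slope * precursor_mz + co$intercept, 1)
}

#' Collision-energy optimization schedule
#'
#' Eleven values centered on the calculated CE: five below and five above in
#' 2 eV increments, clipped at 0 eV from below (duplicate zeros retained; an
#' instrument export may de-duplicate).
#'
#' @param ce calculated collision energy, eV.
#' @param n_each steps on each side (default 5).
#' @param step increment, eV (default 2).
#' @return numeric vector of length `2 * n_each + 1`.
#' @examples
#' ce_schedule(20)  # 10, 12, ..., 30
#' @export
ce_schedule <- function(ce, n_each = 5L, step = 2) {
  pmax(ce + step * seq.int(-n_each, n_each), 0)
}

#' Rank transitions from a spectral library entry
#'
#' Deterministic replacement of the usual manual transition-picking step.
#' Fragments are tiered: (1) y-ions with product m/z above the precursor m/z;
#' (2) remaining site-determining ions of either series; (3) remaining
#' y-ions; (4) b-ions. Within a tier, fragments sort by library intensity
#' descending, ties broken by higher product m/z, then y before b, then lower
#' index. All of tiers 1--2 are taken up to `n_max`; when fewer than `n_min`
#' survive, tiers 3--4 pad the list to `n_min`.
#'
#' @param library_entry list with elements `peptide` (a `modified_peptide`)
#'   and `fragments` (data.frame: `series`, `index`, `charge`, `intensity`).
#' @param n_min,n_max transition count bounds (default 3 and 6).
#' @param ce_coefficients collision-energy coefficients for [calc_ce()].
#' @return data.frame of transitions: `series`, `index`, `charge`,
#'   `product_mz`, `precursor_mz`, `collision_energy`, `rank`,
#'   `site_determining`, `intensity`.
#' @export
rank_transitions <- function(library_entry, n_min = 3L, n_max = 6L,
                             ce_coefficients = default_config()$ce_coefficients) {
  pep <- library_entry$peptide
  fr <- library_entry$fragments
  if (is.null(fr) || nrow(fr) < 3L) {
    stop("spectral library entry needs at least 3 fragments", call. = FALSE)
  }
  stopifnot(inherits(pep, "modified_peptide"))
  pre_mz <- precursor_mz(pep)
  fr$product_mz <- vapply(seq_len(nrow(fr)), function(i)
    fragment_mz(pep, fr$series[i], fr$index[i], fr$charge[i]), numeric(1))
  fr$site_determining <- vapply(seq_len(nrow(fr)), function(i)
    site_determining(pep, fr$series[i], fr$index[i]), logical(1))
  tier <- ifelse(fr$series == "y" & fr$product_mz > pre_mz, 1L,
          ifelse(fr$site_determining, 2L,
          ifelse(fr$series == "y", 3L, 4L)))
  o <- order(tier, -fr$intensity, -fr$product_mz,
             match(fr$series, c("y", "b")), fr$index)
  fr <- fr[o, , drop = FALSE]
  tier <- tier[o]
  n_core <- min(sum(tier <= 2L), n_max)
  n_take <- max(n_core, min(n_min, nrow(fr)))
  out <- fr[seq_len(n_take), , drop = FALSE]
  out$precursor_mz <- pre_mz
  out$collision_energy <- calc_ce(pre_mz, pep$charge, ce_coefficients)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("series", "index", "charge", "product_mz", "precursor_mz",
          "collision_energy", "rank", "site_determining", "intensity")]
}

#' Default precursor charge for a peptide
#'
#' 2+ by default; 3+ is monitored in addition for peptides with two or more
#' basic residues (K/R/H) besides the C-terminus.
#'
#' @param sequence peptide sequence.
#' @return integer vector of charges to monitor.
#' @export
default_charges <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n_basic <- sum(chars[-length(chars)] %in% c("K", "R", "H"))
  if (n_basic >= 2L) c(2L, 3L) else 2L
}
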