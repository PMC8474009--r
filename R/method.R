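#' Route-specific LC-MRM method defaults
#'
#' IMAC runs on a 160-min gradient with a 3.0-s cycle; the pY-antibody route
#' on a 120-min gradient with a 1.5-s cycle. Both use Q1 0.4 / Q3 0.7 FWHM
#' and a 10-min retention-time scheduling window.
#'
#' @param route `"IMAC"` or `"pY"`.
#' @return list with `route`, `duration` (min), `rt_window` (min),
#'   `cycle_time` (s), `q1_resolution`, `q3_resolution`.
#' @export
method_config <- function(route = c("IMAC", "pY")) {
  route <- match.arg(route)
  if (route == "IMAC") {
    list(route = "IMAC", duration = 160, rt_window = 10, cycle_time = 3.0,
         q1_resolution = 0.4, q3_resolution = 0.7)
  } else {
    list(route = "pY", duration = 120, rt_window = 10, cycle_time = 1.5,
         q1_resolution = 0.4, q3_resolution = 0.7)
  }
}

#' Build a retention-time scheduled MRM method table
#'
#' One row per transition, each with an acquisition window of `rt_window`
#' minutes centered on the peptide's library retention time and clipped to
#' the gradient. Also reports the maximum number of concurrent transitions
#' over a 0.1-min sweep of the gradient as a schedule-feasibility diagnostic.
#'
#' @param transitions data.frame with at least `peptide_id` and the columns
#'   from [rank_transitions()].
#' @param library_rts named numeric vector of retention times (min) keyed by
#'   `peptide_id`.
#' @param config method configuration from [method_config()].
#' @return list with `table` (transitions plus `rt`, `rt_window_start`,
#'   `rt_window_end` and method metadata columns) and `max_concurrent`.
#' @export
build_method <- function(transitions, library_rts, config = method_config()) {
  stopifnot(nrow(transitions) > 0L)
  rt <- unname(library_rts[transitions$peptide_id])
  if (anyNA(rt)) {
    missing <- unique(transitions$peptide_id[is.na(rt)])
    stop("no library retention time for peptide ", missing[[1L]],
         call. = FALSE)
  }
  out_of_gradient <- rt < 0 | rt > config$duration
  if (any(out_of_gradient)) {
    bad <- unique(transitions$peptide_id[out_of_gradient])
    stop("retention time outside gradient for peptide ", bad[[1L]],
         call. = FALSE)
  }
  half <- config$rt_window / 2
  tab <- transitions
  tab$rt <- rt
  tab$rt_window_start <- pmax(rt - half, 0)
  tab$rt_window_end <- pmin(rt + half, config$duration)
  tab$cycle_time <- config$cycle_time
  tab$q1_resolution <- config$q1_resolution
  tab$q3_resolution <- config$q3_resolution
  grid <- seq(0, config$duration, by = 0.1)
  conc <- vapply(grid, function(t)
    sum(tab$rt_window_start <= t & t <= tab$rt_window_end), integer(1))
  list(table = tab, max_concurrent = max(conc))
}

# near-equal contiguous partition of n items into k parts
.partition_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

#' Assemble equimolar peptide mixtures
#'
#' Per enrichment route, panel entries are sorted alphabetically by gene
#' symbol and partitioned contiguously into the minimum number of mixtures
#' whose sizes all lie within the route's bounds, with sizes as equal as
#' possible (difference at most 1). The combined-route pool (IMACpY) is a
#' single mixture by construction. Infeasible bounds (too few peptides for
#' the lower bound) relax to a single mixture with a warning.
#'
#' @param panel data.frame of selected panel entries with columns `gene`,
#'   `modified_sequence`, `enrichment_route`.
#' @param bounds named list of `c(lower, upper)` per route; defaults
#'   IMAC `[43, 50]`, pY `[31, 40]`, IMACpY unbounded single mixture.
#' @param concentration equimolar concentration, pmol/ul (default 2).
#' @return data.frame with one row per peptide: `mixture_name`, `route`,
#'   `gene`, `modified_sequence`, `concentration_pmol_per_ul`.
#' @export
assemble_mixtures <- function(panel,
                              bounds = list(IMAC = c(43L, 50L),
                                            pY = c(31L, 40L),
                                            IMACpY = c(1L, .Machine$integer.max)),
                              concentration = 2) {
  stopifnot(nrow(panel) > 0L, all(nzchar(panel$enrichment_route)))
  out <- list()
  for (route in intersect(c("IMAC", "pY", "IMACpY"),
                          unique(panel$enrichment_route))) {
    members <- panel[panel$enrichment_route == route, , drop = FALSE]
    members <- members[order(members$gene, members$modified_sequence), ,
                       drop = FALSE]
    n <- nrow(members)
    b <- bounds[[route]]
    if (is.null(b)) b <- c(1L, n)
    k <- ceiling(n / b[[2L]])
    if (n < k * b[[1L]]) {
      if (n >= b[[1L]] && n <= b[[2L]]) {
        k <- 1L
      } else {
        warning("route ", route, ": ", n, " peptides infeasible for bounds [",
                b[[1L]], ",", b[[2L]], "]; using a single mixture")
        k <- 1L
      }
    }
    sizes <- .partition_sizes(n, k)
    members$mixture_name <- rep(sprintf("%s_%d", route, seq_len(k)),
                                times = sizes)
    members$route <- route
    members$concentration_pmol_per_ul <- concentration
    out[[route]] <- members[, c("mixture_name", "route", "gene",
                                "modified_sequence",
                                "concentration_pmol_per_ul")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
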