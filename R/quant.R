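#' Integrate a chromatographic peak
#'
#' Trapezoidal area over explicit boundaries with no baseline subtraction
#' (an optional linear baseline drawn between the boundary intensities can be
#' subtracted). Apex height is the maximum raw intensity inside the
#' boundaries.
#'
#' @param times numeric vector of retention times (min), strictly increasing.
#' @param intensities matching intensity vector (counts).
#' @param bounds numeric length-2 `c(start, end)` within the trace range.
#' @param baseline `"none"` (default) or `"linear"`.
#' @return list with `boundary_start`, `boundary_end`, `area` (counts*min),
#'   `apex_height` (counts).
#' @export
integrate_peak <- function(times, intensities, bounds, baseline = "none") {
  stopifnot(length(times) == length(intensities), length(times) >= 5L,
            all(diff(times) > 0))
  baseline <- match.arg(baseline, c("none", "linear"))
  if (bounds[[1L]] >= bounds[[2L]]) stop("invalid bounds", call. = FALSE)
  if (bounds[[1L]] < times[[1L]] || bounds[[2L]] > times[[length(times)]]) {
    stop("integration bounds outside trace time range", call. = FALSE)
  }
  # interpolated trace restricted to [start, end], boundary points included
  inside <- times > bounds[[1L]] & times < bounds[[2L]]
  tt <- c(bounds[[1L]], times[inside], bounds[[2L]])
  yy <- stats::approx(times, intensities, xout = tt)$y
  if (baseline == "linear") {
    base <- stats::approx(bounds, yy[c(1L, length(yy))], xout = tt)$y
    yy <- pmax(yy - base, 0)
  }
  area <- sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2)
  list(boundary_start = bounds[[1L]], boundary_end = bounds[[2L]],
       area = area, apex_height = max(yy))
}

#' Pick integration boundaries from the heavy-standard signal
#'
#' The spiked heavy peptide defines the elution window: the summed heavy
#' intensity profile's apex sets the center and its full width at half
#' maximum (FWHM, by linear interpolation of the half-max crossings) sets the
#' scale; boundaries are `apex +/- k * FWHM`, clipped to the trace range, and
#' the same window is applied to light and heavy traces.
#'
#' @param times shared time grid (min).
#' @param heavy_intensity_list list of heavy-transition intensity vectors on
#'   that grid.
#' @param k half-window in FWHM units (default 1.5).
#' @return numeric `c(start, end)`.
#' @export
pick_boundaries <- function(times, heavy_intensity_list, k = 1.5) {
  stopifnot(length(heavy_intensity_list) >= 1L)
  total <- Reduce(`+`, heavy_intensity_list)
  stopifnot(length(total) == length(times))
  if (all(total <= 0)) {
    stop("internal standard not detected (all-zero heavy signal)",
         call. = FALSE)
  }
  apex_i <- which.max(total)
  apex <- times[[apex_i]]
  half <- total[[apex_i]] / 2
  above <- total >= half
  if (all(above)) {
    warning("flat heavy signal; using full trace window")
    return(c(times[[1L]], times[[length(times)]]))
  }
  cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between grid points
    t0 <- times[[i0]]; t1 <- times[[i1]]
    y0 <- total[[i0]]; y1 <- total[[i1]]
    t0 + (half - y0) / (y1 - y0) * (t1 - t0)
  }
  left <- apex_i
  while (left > 1L && above[[left - 1L]]) left <- left - 1L
  lt <- if (left == 1L) times[[1L]] else cross(left - 1L, left)
  right <- apex_i
  while (right < length(total) && above[[right + 1L]]) right <- right + 1L
  rt <- if (right == length(total)) times[[length(times)]] else
    cross(right, right + 1L)
  fwhm <- rt - lt
  c(max(apex - k * fwhm, times[[1L]]),
    min(apex + k * fwhm, times[[length(times)]]))
}

#' Select the reporting transition
#'
#' For each transition the relative-contribution fraction (area over summed
#' area) is computed separately in the heavy and the light channel; matched
#' fragmentation patterns make these fractions agree. A transition whose
#' light fraction deviates from its heavy fraction by more than `cutoff` is
#' flagged as interfered. Among clean transitions the one with the largest
#' heavy area reports; if every transition is flagged, the least-deviating
#' one is used with a warning.
#'
#' @param areas data.frame with columns `transition`, `light_area`,
#'   `heavy_area`.
#' @param cutoff interference cutoff on the absolute fraction deviation
#'   (default 0.2).
#' @return list with `transition` (the reporting key), `interference`
#'   (logical vector named by transition), `all_flagged`.
#' @export
select_reporting_transition <- function(areas, cutoff = 0.2) {
  stopifnot(nrow(areas) >= 1L)
  if (nrow(areas) == 1L) {
    warning("single transition available; interference check not possible")
    return(list(transition = areas$transition[[1L]],
                interference = stats::setNames(FALSE, areas$transition),
                all_flagged = FALSE))
  }
  hsum <- sum(areas$heavy_area)
  lsum <- sum(areas$light_area)
  if (hsum <= 0) stop("no heavy signal across transitions", call. = FALSE)
  hfrac <- areas$heavy_area / hsum
  if (lsum <= 0) {
    # no endogenous signal at all: nothing to cross-check, report on the
    # strongest heavy transition
    pick <- which.max(areas$heavy_area)
    return(list(transition = areas$transition[[pick]],
                interference = stats::setNames(rep(FALSE, nrow(areas)),
                                               areas$transition),
                all_flagged = FALSE))
  }
  lfrac <- areas$light_area / lsum
  dev <- abs(lfrac - hfrac)
  flagged <- dev > cutoff
  names(flagged) <- areas$transition
  if (all(flagged)) {
    warning("all transitions interference-flagged; using least deviating")
    pick <- which.min(dev)
    return(list(transition = areas$transition[[pick]],
                interference = flagged, all_flagged = TRUE))
  }
  ok <- which(!flagged)
  pick <- ok[which.max(areas$heavy_area[ok])]
  list(transition = areas$transition[[pick]], interference = flagged,
       all_flagged = FALSE)
}

#' Route-specific light detection thresholds (counts)
#'
#' @param route `"pY"` or `"IMAC"`.
#' @param config run configuration (see [default_config()]).
#' @return apex-height threshold in counts (250 for pY-antibody samples,
#'   300 for IMAC).
#' @export
height_threshold <- function(route, config = default_config()) {
  switch(route,
         pY = config$py_height_threshold,
         IMAC = config$imac_height_threshold,
         stop("unknown enrichment route '", route, "'", call. = FALSE))
}

#' Detection flag and data category for a quantified peptide
#'
#' Detection of the endogenous (light) peptide requires signal on every
#' monitored transition plus a minimal apex height of the reporting
#' transition: category 1 (confident) when all light transitions have
#' nonzero area and the reporting light apex exceeds the route threshold;
#' category 2 (below threshold) when signal is present on all transitions but
#' the apex does not clear the threshold; category 3 (absent) when at least
#' one transition shows no light signal.
#'
#' @param light_areas per-transition light areas.
#' @param reporting_light_height apex height of the reporting transition's
#'   light trace (counts).
#' @param route `"pY"` or `"IMAC"`.
#' @param config run configuration.
#' @return list with `detected` (logical) and `category` (1, 2 or 3).
#' @export
detect_endogenous <- function(light_areas, reporting_light_height, route,
                              config = default_config()) {
  thr <- height_threshold(route, config)
  if (any(light_areas <= 0)) {
    return(list(detected = FALSE, category = 3L))
  }
  if (reporting_light_height > thr) {
    list(detected = TRUE, category = 1L)
  } else {
    list(detected = FALSE, category = 2L)
  }
}

#' Light/heavy peak-area ratio
#'
#' @param light_area light (endogenous) area on the reporting transition.
#' @param heavy_area heavy (SIL standard) area on the reporting transition.
#' @return the peak-area ratio (PAR), dimensionless.
#' @export
compute_par <- function(light_area, heavy_area) {
  if (heavy_area <= 0) {
    stop("heavy standard not detected (zero heavy area)", call. = FALSE)
  }
  light_area / heavy_area
}

#' Percent coefficient of variation
#'
#' @param values numeric vector of >= 2 replicate measurements with nonzero
#'   mean.
#' @return `100 * sd / mean`.
#' @examples
#' percent_cv(c(8, 10, 12))  # 20
#' @export
percent_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need >= 2 values for %CV", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; %CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Quantify MRM chromatograms into peak-area ratios
#'
#' Full per-sample, per-peptide quantification: the summed heavy signal sets
#' the integration window, every transition is integrated in both isotope
#' channels over that same window, a reporting transition is chosen by the
#' interference rule, and the light/heavy peak-area ratio, detection flag and
#' data category are derived.
#'
#' @param chromatograms long-format data.frame with columns `sample`,
#'   `peptide`, `transition`, `label` (`light`/`heavy`), `time`, `intensity`.
#' @param route `"pY"` or `"IMAC"` (sets the detection threshold).
#' @param config run configuration (interference cutoff, thresholds,
#'   boundary half-window).
#' @return data.frame with one row per sample x peptide: `sample`, `peptide`,
#'   `route`, `reporting_transition`, `light_area`, `heavy_area`,
#'   `light_height`, `par`, `detected`, `category`.
#' @export
quantify_chromatograms <- function(chromatograms, route,
                                   config = default_config()) {
  needed <- c("sample", "peptide", "transition", "label", "time", "intensity")
  missing_cols <- setdiff(needed, names(chromatograms))
  if (length(missing_cols) > 0L) {
    stop("chromatogram table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  height_threshold(route, config)  # validates the route early
  out <- list()
  for (smp in unique(chromatograms$sample)) {
    cs <- chromatograms[chromatograms$sample == smp, , drop = FALSE]
    for (pep in unique(cs$peptide)) {
      cp <- cs[cs$peptide == pep, , drop = FALSE]
      transitions <- sort(unique(cp$transition))
      times <- sort(unique(cp$time))
      grab <- function(tr, lab) {
        sel <- cp[cp$transition == tr & cp$label == lab, , drop = FALSE]
        sel <- sel[order(sel$time), , drop = FALSE]
        stopifnot(nrow(sel) == length(times))
        sel$intensity
      }
      heavy <- lapply(transitions, grab, lab = "heavy")
      bounds <- pick_boundaries(times, heavy, k = config$boundary_fwhm_k)
      rows <- lapply(seq_along(transitions), function(i) {
        hint <- integrate_peak(times, heavy[[i]], bounds)
        lint <- integrate_peak(times, grab(transitions[[i]], "light"), bounds)
        data.frame(transition = transitions[[i]],
                   light_area = lint$area, heavy_area = hint$area,
                   light_height = lint$apex_height,
                   stringsAsFactors = FALSE)
      })
      areas <- do.call(rbind, rows)
      rep_sel <- select_reporting_transition(areas,
                                             cutoff = config$interference_cutoff)
      ri <- match(rep_sel$transition, areas$transition)
      det <- detect_endogenous(areas$light_area, areas$light_height[ri],
                               route, config)
      par <- if (areas$heavy_area[ri] > 0)
        compute_par(areas$light_area[ri], areas$heavy_area[ri]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, peptide = pep, route = route,
        reporting_transition = rep_sel$transition,
        light_area = areas$light_area[ri],
        heavy_area = areas$heavy_area[ri],
        light_height = areas$light_height[ri],
        par = par, detected = det$detected, category = det$category,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
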