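#' Simulation design defaults
#'
#' Conditions for the synthetic-data generators, chosen to mirror the assay's
#' operating point: 30 fmol heavy spike per sample, heavy apex calibrated to
#' about 10,000 counts, Gaussian elution peaks of sd 0.1 min sampled on a
#' 0.05-min grid, additive normal noise at 5% of the heavy apex, and a light
#' censoring floor below which the endogenous signal is zeroed.
#'
#' @param n_proteins number of background proteins.
#' @param scenario named integer vector of embedded nomination scenarios:
#'   `plain`, `short_rescue`, `shared_peptide`, `too_long`, `pY`,
#'   `doubly_phospho`.
#' @param heavy_amount_fmol heavy spike per sample (fmol).
#' @param heavy_apex_counts calibrated heavy apex at the default spike.
#' @param peak_sigma_min Gaussian elution sd (min).
#' @param grid_step_min chromatographic sampling interval (min).
#' @param noise_sd_frac additive noise sd as a fraction of the heavy apex.
#' @param censor_light_frac light amount (as a fraction of heavy) below which
#'   the light signal is zeroed, emulating the detection limit.
#' @param gradient_min gradient length (min).
#' @param seed RNG seed (mandatory for every generator).
#' @return list of design parameters.
#' @export
simulation_design <- function(n_proteins = 12L,
                              scenario = c(plain = 4L, short_rescue = 1L,
                                           shared_peptide = 1L, too_long = 1L,
                                           pY = 2L, doubly_phospho = 1L),
                              heavy_amount_fmol = 30,
                              heavy_apex_counts = 10000,
                              peak_sigma_min = 0.1,
                              grid_step_min = 0.05,
                              noise_sd_frac = 0.05,
                              censor_light_frac = 0.005,
                              gradient_min = 60,
                              seed = 1L) {
  stopifnot(heavy_amount_fmol > 0, heavy_apex_counts > 0, peak_sigma_min > 0,
            grid_step_min > 0, noise_sd_frac >= 0, !is.null(seed))
  list(n_proteins = as.integer(n_proteins), scenario = scenario,
       heavy_amount_fmol = heavy_amount_fmol,
       heavy_apex_counts = heavy_apex_counts,
       peak_sigma_min = peak_sigma_min, grid_step_min = grid_step_min,
       noise_sd_frac = noise_sd_frac, censor_light_frac = censor_light_frac,
       gradient_min = gradient_min, seed = as.integer(seed))
}

.random_sequence <- function(n) {
  # tryptic-looking random protein: mostly non-basic residues with K/R
  # sprinkled to give peptides of realistic length
  aa <- setdiff(.AMINO_ACIDS, c("K", "R"))
  chars <- sample(aa, n, replace = TRUE)
  cut_every <- 10L
  pos <- seq.int(cut_every, n - 1L, by = cut_every)
  chars[pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic proteome with embedded nomination scenarios
#'
#' Builds a small proteome whose phosphosite nominations exercise every
#' selection rule: plain well-behaved sites, a short fully cleaved peptide
#' rescued by an observed missed-cleaved form, a peptide shared verbatim
#' between two genes, a site trapped in a >40-residue tryptic peptide, pY
#' sites (with and without dual-route evidence), and a site whose doubly
#' phosphorylated form dominates the evidence. All outputs are pure
#' functions of the design seed.
#'
#' @param design a [simulation_design()].
#' @return list with `proteome` (data.frame: `accession`, `gene_symbol`,
#'   `sequence`), `sites` (`gene_symbol`, `residue`, `position`, `source`),
#'   `evidence` (`modified_sequence`, `count`, `routes`), and
#'   `scenario_sites` (named list mapping scenario class to site labels).
#' @export
make_proteome <- function(design = simulation_design()) {
  sc <- design$scenario
  n_needed <- sum(sc) + sc[["shared_peptide"]]  # shared sites span 2 genes
  if (design$n_proteins < n_needed) {
    stop("n_proteins (", design$n_proteins, ") too small for ", n_needed,
         " scenario genes", call. = FALSE)
  }
  set.seed(design$seed)
  genes <- sprintf("GENE%02d", seq_len(design$n_proteins))
  seqs <- vapply(seq_len(design$n_proteins), function(i)
    .random_sequence(80L), character(1))
  sites <- list(); evid <- list(); scenario_sites <- list()
  gi <- 0L
  take_gene <- function() { gi <<- gi + 1L; gi }
  add_evidence <- function(mseq, count, routes) {
    evid[[length(evid) + 1L]] <<- data.frame(
      modified_sequence = mseq, count = as.integer(count), routes = routes,
      stringsAsFactors = FALSE)
  }
  add_site <- function(gene, residue, position, source = "nominated") {
    sites[[length(sites) + 1L]] <<- data.frame(
      gene_symbol = gene, residue = residue, position = position,
      source = source, stringsAsFactors = FALSE)
    sprintf("%s p%s%d", gene, residue, position)
  }
  embed <- function(i, motif, at) {
    s <- seqs[[i]]
    substr(s, at, at + nchar(motif) - 1L) <- motif
    seqs[[i]] <<- s
  }

  # plain sites: S embedded mid-peptide, observed under IMAC; one variable
  # residue keeps each motif unique to its gene
  plain_var <- c("G", "A", "V", "F", "N", "Q", "E", "M")
  for (k in seq_len(sc[["plain"]])) {
    i <- take_gene()
    embed(i, paste0("ADSVE", plain_var[[k]], "TLK"), 21L)
    lab <- add_site(genes[i], "S", 23L)
    pep <- map_site(23L, "S", digest(seqs[i], 0L), seqs[i])
    add_evidence(modified_sequence(pep$sequence[1L], pep$phospho_offset[1L]),
                 20L + k, "IMAC")
    scenario_sites$plain <- c(scenario_sites$plain, lab)
  }
  # short rescue: fully cleaved form < 6 residues; observed 2-missed form
  for (k in seq_len(sc[["short_rescue"]])) {
    i <- take_gene()
    embed(i, "RDSLQKPGLEAPPR", 21L)  # K/R-flanked: DSLQK fully cleaved
    lab <- add_site(genes[i], "S", 23L)
    cand <- map_site(23L, "S", digest(seqs[i], 2L), seqs[i])
    long <- cand[cand$length >= 6L & cand$length <= 40L &
                   cand$missed_cleavages == 2L, , drop = FALSE]
    add_evidence(modified_sequence(long$sequence[1L], long$phospho_offset[1L]),
                 12L, "IMAC")
    scenario_sites$short_rescue <- c(scenario_sites$short_rescue, lab)
  }
  # shared peptide: same tryptic window in two genes
  for (k in seq_len(sc[["shared_peptide"]])) {
    i <- take_gene(); j <- take_gene()
    embed(i, "KETIQTWFK", 30L)
    embed(j, "KETIQTWFK", 50L)
    lab <- add_site(genes[i], "T", 35L)   # the second T of ETIQTWFK
    pep <- map_site(35L, "T", digest(seqs[i], 0L), seqs[i])
    add_evidence(modified_sequence(pep$sequence[1L], pep$phospho_offset[1L]),
                 15L, "IMAC")
    scenario_sites$shared_peptide <- c(scenario_sites$shared_peptide, lab)
  }
  # too long: strip K/R from a 45-residue stretch around the site
  for (k in seq_len(sc[["too_long"]])) {
    i <- take_gene()
    s <- seqs[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    repl <- which(chars %in% c("K", "R") & seq_along(chars) > 12L &
                    seq_along(chars) < 68L)
    chars[repl] <- "A"
    chars[40L] <- "S"
    seqs[[i]] <- paste(chars, collapse = "")
    lab <- add_site(genes[i], "S", 40L)
    scenario_sites$too_long <- c(scenario_sites$too_long, lab)
  }
  # pY sites; the first gets dual-route evidence (IMACpY), the rest pY-only
  py_var <- c("V", "A", "L", "F", "N", "Q")
  for (k in seq_len(sc[["pY"]])) {
    i <- take_gene()
    embed(i, paste0("GDYEN", py_var[[k]], "GSR"), 41L)
    lab <- add_site(genes[i], "Y", 43L)
    pep <- map_site(43L, "Y", digest(seqs[i], 0L), seqs[i])
    routes <- if (k == 1L) "IMAC,pY" else "pY"
    add_evidence(modified_sequence(pep$sequence[1L], pep$phospho_offset[1L]),
                 8L + k, routes)
    scenario_sites$pY <- c(scenario_sites$pY, lab)
  }
  # doubly phosphorylated form much more prevalent than the singly form
  for (k in seq_len(sc[["doubly_phospho"]])) {
    i <- take_gene()
    embed(i, "FLTEYVATR", 51L)       # MAPK-style TEY activation loop motif
    lab <- add_site(genes[i], "T", 53L)
    pep <- map_site(53L, "T", digest(seqs[i], 0L), seqs[i])
    p1 <- pep$phospho_offset[1L]
    chars <- strsplit(pep$sequence[1L], "", fixed = TRUE)[[1L]]
    p2 <- setdiff(which(chars == "Y"), p1)[1L]
    add_evidence(modified_sequence(pep$sequence[1L], p1), 5L, "IMAC")
    add_evidence(modified_sequence(pep$sequence[1L], sort(c(p1, p2))),
                 40L, "IMAC")
    scenario_sites$doubly_phospho <- c(scenario_sites$doubly_phospho, lab)
  }

  proteome <- data.frame(
    accession = sprintf("SYN%04d", seq_len(design$n_proteins)),
    gene_symbol = genes, sequence = seqs, stringsAsFactors = FALSE)
  list(proteome = proteome,
       sites = do.call(rbind, sites),
       evidence = do.call(rbind, evid),
       scenario_sites = scenario_sites)
}

#' Simulate MRM chromatograms for a panel
#'
#' Gaussian elution peaks per transition and isotope label on a shared
#' regular time grid. The per-transition relative intensities are drawn once
#' per peptide and shared between light and heavy (matched fragmentation
#' patterns); the heavy apex is calibrated so the default spike yields
#' `heavy_apex_counts`; the light apex scales with the peptide's true
#' light/heavy ratio. Additive truncated-normal noise and a light censoring
#' floor emulate detector noise and the detection limit. Optionally a
#' co-eluting contaminant is added to one named light transition.
#'
#' @param peptide_ids character vector of peptide identifiers.
#' @param true_ratios named numeric vector of true light/heavy ratios (one
#'   per peptide).
#' @param design a [simulation_design()].
#' @param n_transitions transitions per peptide (default 3).
#' @param sample_id sample identifier stamped on the output (default "S1").
#' @param interference named list `list(peptide=, transition=, scale=)` to
#'   inject an off-pattern contaminant into one light transition, or `NULL`.
#' @param rts optional named vector of retention times (min); defaults to
#'   equally spaced across the middle of the gradient.
#' @return list with `chromatograms` (long-format data.frame: `sample`,
#'   `peptide`, `transition`, `label`, `time`, `intensity`) and `truth`
#'   (data.frame: `peptide`, `true_ratio`, `rt`, `censored`).
#' @export
simulate_chromatograms <- function(peptide_ids, true_ratios,
                                   design = simulation_design(),
                                   n_transitions = 3L, sample_id = "S1",
                                   interference = NULL, rts = NULL) {
  stopifnot(length(peptide_ids) >= 1L,
            all(peptide_ids %in% names(true_ratios)))
  set.seed(design$seed)
  if (is.null(rts)) {
    rts <- stats::setNames(
      seq(0.25 * design$gradient_min, 0.75 * design$gradient_min,
          length.out = length(peptide_ids)), peptide_ids)
  }
  bad_rt <- rts[peptide_ids] < 0 | rts[peptide_ids] > design$gradient_min
  if (any(bad_rt)) {
    stop("retention time outside gradient for peptide ",
         peptide_ids[bad_rt][[1L]], call. = FALSE)
  }
  chrom <- list(); truth <- list()
  for (pep in peptide_ids) {
    rt <- rts[[pep]]
    ratio <- true_ratios[[pep]]
    # local window around the peak keeps trace sizes manageable
    t0 <- max(0, rt - 1.5); t1 <- min(design$gradient_min, rt + 1.5)
    times <- seq(t0, t1, by = design$grid_step_min)
    rel <- sort(stats::runif(n_transitions, 0.3, 1), decreasing = TRUE)
    rel <- rel / max(rel)
    censored <- ratio < design$censor_light_frac
    for (k in seq_len(n_transitions)) {
      tr <- sprintf("y%d", k + 3L)
      shape <- exp(-(times - rt)^2 / (2 * design$peak_sigma_min^2))
      heavy_apex <- design$heavy_apex_counts * rel[k]
      light_apex <- heavy_apex * ratio
      noise_sd <- design$noise_sd_frac * design$heavy_apex_counts
      mk <- function(apex, contaminate = FALSE) {
        y <- apex * shape
        if (contaminate) {
          y <- y + interference$scale * design$heavy_apex_counts * shape
        }
        if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
        pmax(y, 0)
      }
      contaminate <- !is.null(interference) &&
        identical(interference$peptide, pep) &&
        identical(interference$transition, tr)
      # censored light signal drops to a flat zero baseline (below the
      # detection limit nothing is recorded, not even noise)
      light <- if (censored) rep(0, length(times)) else
        mk(light_apex, contaminate)
      chrom[[length(chrom) + 1L]] <- data.frame(
        sample = sample_id, peptide = pep, transition = tr,
        label = rep(c("heavy", "light"), each = length(times)),
        time = rep(times, 2L),
        intensity = c(mk(heavy_apex), light),
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = pep, true_ratio = ratio, rt = rt, censored = censored,
      stringsAsFactors = FALSE)
  }
  list(chromatograms = do.call(rbind, chrom),
       truth = do.call(rbind, truth))
}

#' Simulate a differential study at the ratio level
#'
#' Draws log2 light/heavy ratios for a peptides-by-samples design with two
#' or more groups: a stated fraction of rows carry a true group effect, the
#' rest are null. Cells in the lower `censor_quantile` of each column are
#' assigned category 3 (to be imputed), the next `cat2_quantile` category 2,
#' the rest category 1. Ground truth (which rows carry effects, the true
#' effect sizes) is returned alongside.
#'
#' @param n_rows number of peptides.
#' @param groups character vector, one group label per sample.
#' @param effect log2 effect added to the first group for affected rows.
#' @param frac_affected fraction of rows with a true effect.
#' @param within_sd within-group sd of log2 ratios.
#' @param baseline_mean,baseline_sd distribution of row baseline levels.
#' @param censor_quantile fraction of cells censored to category 3.
#' @param cat2_quantile additional fraction assigned category 2.
#' @param seed RNG seed.
#' @return list with `ratio_matrix` (a `ratio_matrix` as from
#'   [categorize_and_transform()]) and `truth` (data.frame: `row`,
#'   `affected`, `true_effect`).
#' @export
simulate_study <- function(n_rows = 200L, groups = c("A", "A", "B", "B"),
                           effect = 1.0, frac_affected = 0.1,
                           within_sd = 0.5, baseline_mean = -1,
                           baseline_sd = 1, censor_quantile = 0,
                           cat2_quantile = 0.1, seed = 1L) {
  set.seed(seed)
  n_col <- length(groups)
  first <- groups == groups[[1L]]
  affected <- seq_len(n_rows) <= round(frac_affected * n_rows)
  base <- stats::rnorm(n_rows, baseline_mean, baseline_sd)
  mat <- matrix(stats::rnorm(n_rows * n_col, 0, within_sd), n_rows, n_col)
  mat <- mat + base
  mat[affected, first] <- mat[affected, first] + effect
  rownames(mat) <- sprintf("pep%04d", seq_len(n_rows))
  colnames(mat) <- sprintf("%s_r%d", groups, stats::ave(
    seq_len(n_col), groups, FUN = seq_along))
  cat <- matrix(1L, n_rows, n_col, dimnames = dimnames(mat))
  if (censor_quantile > 0 || cat2_quantile > 0) {
    q3 <- stats::quantile(mat, censor_quantile)
    q2 <- stats::quantile(mat, censor_quantile + cat2_quantile)
    cat[mat <= q2] <- 2L
    cat[mat <= q3] <- 3L
    mat[cat == 3L] <- NA_real_
  }
  rm <- structure(list(log2_ratio = mat, category = cat),
                  class = "ratio_matrix")
  list(ratio_matrix = rm,
       truth = data.frame(row = rownames(mat), affected = affected,
                          true_effect = ifelse(affected, effect, 0),
                          stringsAsFactors = FALSE))
}
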