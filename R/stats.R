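#' Build a log2 ratio matrix from quantification records
#'
#' Light/heavy peak-area ratios are log2-transformed for categories 1
#' (confident) and 2 (below the minimal-signal threshold; these values are
#' kept as measured), while category-3 cells (no signal) become missing.
#'
#' @param records quantification table from [quantify_chromatograms()] (or
#'   the same columns read from file): `sample`, `peptide`, `par`,
#'   `category`.
#' @return list of class `ratio_matrix` with matrices `log2_ratio` and
#'   `category` (peptides x samples).
#' @export
categorize_and_transform <- function(records) {
  peptides <- sort(unique(records$peptide))
  samples <- sort(unique(records$sample))
  lmat <- matrix(NA_real_, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  cmat <- matrix(NA_integer_, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  for (i in seq_len(nrow(records))) {
    r <- records$peptide[i]; s <- records$sample[i]
    cat3 <- records$category[i] == 3L
    cmat[r, s] <- records$category[i]
    if (!cat3) {
      if (is.na(records$par[i]) || records$par[i] <= 0) {
        stop("non-positive peak-area ratio for quantified cell ",
             r, " / ", s, call. = FALSE)
      }
      lmat[r, s] <- log2(records$par[i])
    }
  }
  structure(list(log2_ratio = lmat, category = cmat),
            class = "ratio_matrix")
}

#' Left-censored imputation from the below-threshold distribution
#'
#' Category-3 cells (no signal) are replaced by independent draws from a
#' normal distribution whose parameters come from the category-2 cells (those
#' quantified but below the minimal-signal threshold): `mu` and `sd` are their
#' mean and standard deviation, and `mu` is shifted down by `shift * sd` so
#' the imputed values resemble ratios below the detection limit. Imputation
#' is intended to run separately per dataset and enrichment route; pass the
#' corresponding sub-matrix.
#'
#' @param rm a `ratio_matrix` from [categorize_and_transform()].
#' @param shift number of sd subtracted from `mu` (default 1).
#' @param seed RNG seed; re-running with the same seed is bit-identical.
#' @param mu,sd explicit parameters, overriding estimation (both required
#'   when no category-2 cells exist).
#' @return the `ratio_matrix` with category-3 cells filled in; imputation
#'   parameters are attached as attribute `imputation_params` and an audit
#'   table (cell, drawn value) as attribute `imputation_audit`.
#' @export
impute_missing <- function(rm, shift = 1, seed = 1L, mu = NULL, sd = NULL) {
  stopifnot(inherits(rm, "ratio_matrix"))
  cat2 <- rm$log2_ratio[which(rm$category == 2L)]
  cat2 <- cat2[!is.na(cat2)]
  if (is.null(mu) || is.null(sd)) {
    if (length(cat2) < 2L) {
      stop("fewer than 2 category-2 values; supply mu and sd explicitly",
           call. = FALSE)
    }
    mu <- mean(cat2)
    sd <- stats::sd(cat2)
  }
  idx <- which(rm$category == 3L & is.na(rm$log2_ratio))
  params <- list(mu = mu, sd = sd, shift = shift, seed = seed,
                 n_imputed = length(idx))
  attr(rm, "imputation_params") <- params
  if (length(idx) == 0L) {
    attr(rm, "imputation_audit") <- data.frame(row = character(0),
                                               col = character(0),
                                               value = numeric(0))
    return(rm)
  }
  set.seed(seed)
  draws <- stats::rnorm(length(idx), mean = mu - shift * sd, sd = sd)
  rm$log2_ratio[idx] <- draws
  rc <- arrayInd(idx, dim(rm$log2_ratio))
  attr(rm, "imputation_audit") <- data.frame(
    row = rownames(rm$log2_ratio)[rc[, 1L]],
    col = colnames(rm$log2_ratio)[rc[, 2L]],
    value = draws, stringsAsFactors = FALSE)
  attr(rm, "imputation_params") <- params
  rm
}

# Newton inversion of the trigamma function (solves trigamma(y) = x)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes scaled-F fit of residual variances
#'
#' Models per-row sample variances as s^2 ~ s0^2 * F(d, d0) and estimates the
#' prior degrees of freedom `d0` and prior variance `s0^2` by the method of
#' moments on log s^2 (mean and variance of log s^2 have closed forms in
#' digamma/trigamma; the trigamma inversion uses a few Newton steps).
#'
#' @param s2 per-row residual variances.
#' @param df per-row residual degrees of freedom (recycled).
#' @return list with `d0` (possibly `Inf`) and `s02`.
#' @export
fit_scaled_f <- function(s2, df) {
  ok <- !is.na(s2) & !is.na(df) & df > 0
  s2 <- s2[ok]; df <- rep_len(df, length(ok))[ok]
  if (length(s2) < 2L) stop("need >= 2 variances to fit the prior",
                            call. = FALSE)
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) -
    mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# posterior (squeezed) variances given the scaled-F prior
.squeeze_var <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
}

.moderated_finish <- function(res, d0, s02) {
  res$s2_post <- .squeeze_var(res$s2, res$df_residual, d0, s02)
  res$t_statistic <- res$effect / sqrt(res$s2_post * res$stderr_scale)
  res$df <- res$df_residual + d0
  res$p_value <- 2 * stats::pt(-abs(res$t_statistic), df = res$df)
  # rows with zero posterior variance and zero effect: t = 0, p = 1
  degenerate <- res$s2_post == 0
  res$t_statistic[degenerate & res$effect == 0] <- 0
  res$p_value[degenerate & res$effect == 0] <- 1
  res$adj_p_value <- bh_adjust(res$p_value)
  res$stderr_scale <- NULL
  res
}

#' Two-sample moderated t-test
#'
#' Row-wise comparison of two sample groups with empirical-Bayes variance
#' moderation: the pooled within-group variance of each row is squeezed
#' toward a prior estimated across rows ([fit_scaled_f()]), the t statistic
#' uses the squeezed variance, and its null distribution gains the prior
#' degrees of freedom. P-values are two-sided and Benjamini-Hochberg
#' adjusted.
#'
#' @param mat numeric matrix (rows = peptides, columns = samples), typically
#'   the `log2_ratio` slot of an imputed `ratio_matrix`.
#' @param groups character/factor of length `ncol(mat)` with exactly two
#'   levels; the effect is `mean(level1) - mean(level2)` in the order of
#'   `levels` (or of first appearance).
#' @param d0,s02 optional prior overrides (e.g. `d0 = 0` reproduces the
#'   ordinary Student t-test row by row).
#' @return data.frame: `row`, `effect`, `t_statistic`, `df`, `p_value`,
#'   `adj_p_value`, `n1`, `n2`, `skipped` (rows with fewer than 2 values in
#'   a group carry NA statistics and `skipped = TRUE`).
#' @export
moderated_t_two_sample <- function(mat, groups, d0 = NULL, s02 = NULL) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(mat), nlevels(groups) == 2L)
  g1 <- levels(groups)[[1L]]; g2 <- levels(groups)[[2L]]
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    x1 <- mat[i, groups == g1]; x1 <- x1[!is.na(x1)]
    x2 <- mat[i, groups == g2]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2L || n2 < 2L) {
      return(data.frame(row = rownames(mat)[i], effect = NA_real_,
                        s2 = NA_real_, df_residual = NA_real_,
                        stderr_scale = NA_real_, n1 = n1, n2 = n2,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    d <- n1 + n2 - 2L
    s2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / d
    data.frame(row = rownames(mat)[i], effect = mean(x1) - mean(x2),
               s2 = s2, df_residual = d, stderr_scale = 1 / n1 + 1 / n2,
               n1 = n1, n2 = n2, skipped = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  used <- !res$skipped
  if (!any(used)) stop("no testable rows (need >= 2 values per group)",
                       call. = FALSE)
  if (is.null(d0) || is.null(s02)) {
    fit <- fit_scaled_f(res$s2[used], res$df_residual[used])
    d0 <- if (is.null(d0)) fit$d0 else d0
    s02 <- if (is.null(s02)) fit$s02 else s02
  }
  out <- res[used, , drop = FALSE]
  out <- .moderated_finish(out, d0, s02)
  skipped <- res[!used, , drop = FALSE]
  if (nrow(skipped) > 0L) {
    skipped$s2_post <- NA_real_; skipped$t_statistic <- NA_real_
    skipped$df <- NA_real_; skipped$p_value <- NA_real_
    skipped$adj_p_value <- NA_real_; skipped$stderr_scale <- NULL
    out <- rbind(out, skipped)
  }
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  rownames(out) <- NULL
  out[match(rownames(mat)[rownames(mat) %in% out$row], out$row), ,
      drop = FALSE]
}

#' One-sample moderated t-test against mean zero
#'
#' Same empirical-Bayes machinery as [moderated_t_two_sample()], applied to
#' row means against a null of 0 -- the test used for drug/vehicle ratio-of-
#' ratio designs.
#'
#' @param mat numeric matrix of log2 ratios (or ratio-of-ratios).
#' @param d0,s02 optional prior overrides.
#' @return data.frame as in [moderated_t_two_sample()] with `n` per row.
#' @export
moderated_t_one_sample <- function(mat, d0 = NULL, s02 = NULL) {
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]; x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) {
      return(data.frame(row = rownames(mat)[i], effect = NA_real_,
                        s2 = NA_real_, df_residual = NA_real_,
                        stderr_scale = NA_real_, n = n, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(row = rownames(mat)[i], effect = mean(x), s2 = stats::var(x),
               df_residual = n - 1L, stderr_scale = 1 / n, n = n,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  used <- !res$skipped
  if (!any(used)) stop("no testable rows", call. = FALSE)
  if (is.null(d0) || is.null(s02)) {
    fit <- fit_scaled_f(res$s2[used], res$df_residual[used])
    d0 <- if (is.null(d0)) fit$d0 else d0
    s02 <- if (is.null(s02)) fit$s02 else s02
  }
  out <- .moderated_finish(res[used, , drop = FALSE], d0, s02)
  skipped <- res[!used, , drop = FALSE]
  if (nrow(skipped) > 0L) {
    skipped$s2_post <- NA_real_; skipped$t_statistic <- NA_real_
    skipped$df <- NA_real_; skipped$p_value <- NA_real_
    skipped$adj_p_value <- NA_real_; skipped$stderr_scale <- NULL
    out <- rbind(out, skipped)
  }
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  rownames(out) <- NULL
  out[match(rownames(mat)[rownames(mat) %in% out$row], out$row), ,
      drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Row-wise one-way ANOVA with Tukey pairwise comparisons
#'
#' Standard one-way ANOVA per row over >= 2 groups (groups with fewer than 2
#' non-missing values are dropped for that row and flagged), followed by
#' Tukey's honest significant difference for all group pairs. The Tukey
#' p-values are additionally Benjamini-Hochberg adjusted across all
#' comparisons of all rows.
#'
#' @param mat numeric matrix (rows x samples).
#' @param groups factor/character of length `ncol(mat)`.
#' @return list with `anova` (data.frame: `row`, `F`, `p_value`,
#'   `adj_p_value`, `n_groups`, `dropped_groups`) and `tukey` (data.frame:
#'   `row`, `comparison`, `diff`, `p_value`, `adj_p_value`).
#' @export
anova_tukey <- function(mat, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(mat))
  arows <- list(); trows <- list()
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    keep <- !is.na(x)
    tab <- table(groups[keep])
    good <- names(tab)[tab >= 2L]
    dropped <- setdiff(levels(droplevels(groups[keep])), good)
    sel <- keep & groups %in% good
    if (length(good) < 2L) next
    df <- data.frame(value = x[sel], group = droplevels(groups[sel]))
    if (stats::var(df$value) == 0) {
      arows[[length(arows) + 1L]] <- data.frame(
        row = rownames(mat)[i], F = 0, p_value = 1,
        n_groups = length(good),
        dropped_groups = paste(dropped, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1L]]
    arows[[length(arows) + 1L]] <- data.frame(
      row = rownames(mat)[i], F = an[["F value"]][[1L]],
      p_value = an[["Pr(>F)"]][[1L]], n_groups = length(good),
      dropped_groups = paste(dropped, collapse = ","),
      stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit)$group
    trows[[length(trows) + 1L]] <- data.frame(
      row = rownames(mat)[i], comparison = rownames(tk),
      diff = tk[, "diff"], p_value = tk[, "p adj"],
      stringsAsFactors = FALSE)
  }
  if (length(arows) == 0L) stop("no row with >= 2 groups of >= 2 values",
                                call. = FALSE)
  anova <- do.call(rbind, arows)
  anova$adj_p_value <- bh_adjust(anova$p_value)
  tukey <- if (length(trows) > 0L) do.call(rbind, trows) else
    data.frame(row = character(0), comparison = character(0),
               diff = numeric(0), p_value = numeric(0))
  if (nrow(tukey) > 0L) tukey$adj_p_value <- bh_adjust(tukey$p_value)
  rownames(anova) <- NULL; rownames(tukey) <- NULL
  list(anova = anova, tukey = tukey)
}

#' Robust median-MAD row normalization
#'
#' Per row: subtract the median and divide by the median absolute deviation.
#' The MAD is used without the 1.4826 normal-consistency factor (the robust
#' z-score convention of heat-map tools); set `constant` to change this.
#' Rows with MAD 0 become all zeros and are flagged.
#'
#' @param mat numeric matrix.
#' @param constant MAD scale factor (default 1).
#' @return list with `matrix` (normalized) and `zero_mad_rows` (row names).
#' @export
median_mad_normalize <- function(mat, constant = 1) {
  out <- mat
  flagged <- character(0)
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    med <- stats::median(x, na.rm = TRUE)
    mad <- stats::median(abs(x - med), na.rm = TRUE) * constant
    if (is.na(mad) || mad == 0) {
      out[i, ] <- ifelse(is.na(x), NA_real_, 0)
      flagged <- c(flagged, rownames(mat)[i])
    } else {
      out[i, ] <- (x - med) / mad
    }
  }
  list(matrix = out, zero_mad_rows = flagged)
}

#' Spearman-correlation distance between samples
#'
#' `1 - Spearman correlation` per column pair over pairwise-complete rows
#' (at least `min_shared` shared observations required).
#'
#' @param mat numeric matrix (rows x samples).
#' @param min_shared minimum pairwise-complete rows per pair (default 3).
#' @return a `dist` object over columns.
#' @export
spearman_distance <- function(mat, min_shared = 3L) {
  n <- ncol(mat)
  ids <- colnames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) < min_shared) {
        stop("fewer than ", min_shared, " shared observations between ",
             ids[i], " and ", ids[j], call. = FALSE)
      }
      if (stats::sd(mat[ok, i]) == 0 || stats::sd(mat[ok, j]) == 0) {
        bad <- if (stats::sd(mat[ok, i]) == 0) ids[i] else ids[j]
        stop("correlation undefined: sample ", bad, " is constant",
             call. = FALSE)
      }
      rho <- stats::cor(mat[ok, i], mat[ok, j], method = "spearman")
      d[i, j] <- d[j, i] <- 1 - rho
    }
  }
  stats::as.dist(d)
}

#' Cluster samples by Spearman-correlation distance
#'
#' Complete-linkage hierarchical clustering on the `1 - Spearman` distance.
#' Columns are ordered lexicographically first so that equal-distance merges
#' resolve deterministically.
#'
#' @param mat numeric matrix (rows x samples), >= 3 samples.
#' @param min_shared minimum pairwise-complete rows per sample pair.
#' @return an `hclust` object.
#' @export
cluster_samples <- function(mat, min_shared = 3L) {
  stopifnot(ncol(mat) >= 3L)
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  stats::hclust(spearman_distance(mat, min_shared), method = "complete")
}

#' Export a differential-results table for causal network analysis
#'
#' Flat table (gene, site, effect sign, BH-adjusted p) in the form consumed
#' by causal pathway inference tools; no network computation is performed
#' here.
#'
#' @param results data.frame with columns `gene`, `site`, `effect`,
#'   `adj_p_value`.
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
export_causalpath_table <- function(results, path) {
  cols <- c("gene", "site", "effect_sign", "adj_p_value")
  if (nrow(results) == 0L) {
    out <- data.frame(gene = character(0), site = character(0),
                      effect_sign = integer(0), adj_p_value = numeric(0))
  } else {
    out <- data.frame(gene = results$gene, site = results$site,
                      effect_sign = sign(results$effect),
                      adj_p_value = results$adj_p_value,
                      stringsAsFactors = FALSE)
    out <- out[order(out$adj_p_value), , drop = FALSE]
  }
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
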