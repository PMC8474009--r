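toy_records <- function() {
  data.frame(
    sample = rep(c("s1", "s2", "s3"), each = 3),
    peptide = rep(c("p1", "p2", "p3"), times = 3),
    par = c(1, 0.5, 2, 4, 0.25, NA, 1, 8, 0.125),
    category = c(1L, 2L, 1L, 1L, 2L, 3L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

test_that("log2 transform keeps category 1-2 values and masks category 3", {
  rm <- categorize_and_transform(toy_records())
  expect_equal(rm$log2_ratio["p1", "s1"], 0)
  expect_equal(rm$log2_ratio["p2", "s1"], -1)
  expect_equal(rm$log2_ratio["p1", "s2"], 2)
  expect_true(is.na(rm$log2_ratio["p3", "s2"]))
  expect_identical(rm$category["p3", "s2"], 3L)
  bad <- toy_records(); bad$par[1] <- 0
  expect_error(categorize_and_transform(bad), "non-positive")
})

test_that("imputation draws from the down-shifted category-2 normal", {
  # category-2 values {-2,-1,0}: mu = -1, sd = 1, draws ~ Normal(-2, 1)
  rm <- structure(list(
    log2_ratio = matrix(c(-2, -1, 0, rep(NA, 3)), 2, 3, byrow = TRUE,
                        dimnames = list(c("a", "b"), c("x", "y", "z"))),
    category = matrix(c(2L, 2L, 2L, 3L, 3L, 3L), 2, 3, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("x", "y", "z")))),
    class = "ratio_matrix")
  imp <- impute_missing(rm, seed = 99)
  pars <- attr(imp, "imputation_params")
  expect_equal(pars$mu, -1)
  expect_equal(pars$sd, 1)
  expect_false(anyNA(imp$log2_ratio))
  # category 1-2 cells untouched, identical re-run is bit-identical
  expect_identical(imp$log2_ratio["a", ], rm$log2_ratio["a", ])
  expect_identical(impute_missing(rm, seed = 99)$log2_ratio,
                   imp$log2_ratio)
  expect_error(impute_missing(structure(list(
    log2_ratio = matrix(NA_real_, 2, 2), category = matrix(3L, 2, 2)),
    class = "ratio_matrix")), "category-2")
})

test_that("imputed draws average to mu - shift*sd at large n", {
  st <- simulate_study(n_rows = 2500, groups = rep(c("A", "B"), each = 2),
                       censor_quantile = 0.5, cat2_quantile = 0.2, seed = 8)
  rm <- st$ratio_matrix
  imp <- impute_missing(rm, seed = 17)
  pars <- attr(imp, "imputation_params")
  audit <- attr(imp, "imputation_audit")
  expect_gte(nrow(audit), 4000)
  se <- pars$sd / sqrt(nrow(audit))
  expect_lt(abs(mean(audit$value) - (pars$mu - pars$sd)), 3 * se)
  expect_lt(abs(sd(audit$value) - pars$sd) / pars$sd, 0.05)
})

test_that("moderated t with d0 = 0 reduces to the ordinary Student t", {
  set.seed(2)
  mat <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(sprintf("r%02d", 1:40), NULL))
  colnames(mat) <- sprintf("s%d", 1:8)
  groups <- rep(c("A", "B"), each = 4)
  res <- moderated_t_two_sample(mat, groups, d0 = 0, s02 = 1)
  for (i in c(1, 17, 40)) {
    tt <- t.test(mat[i, 1:4], mat[i, 5:8], var.equal = TRUE)
    r <- res[res$row == rownames(mat)[i], ]
    expect_equal(r$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(r$effect, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("d0 -> Inf pools every row to the common prior variance", {
  set.seed(3)
  mat <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(sprintf("r%02d", 1:20), sprintf("s%d", 1:6)))
  res <- moderated_t_two_sample(mat, rep(c("A", "B"), each = 3),
                                d0 = Inf, s02 = 2)
  expect_true(all(abs(res$s2_post - 2) < 1e-12))
})

test_that("moderated machinery agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(4)
  mat <- matrix(rnorm(300 * 8, sd = rep(sqrt(rchisq(300, 4) / 4), 8)),
                300, 8, dimnames = list(sprintf("r%03d", 1:300),
                                        sprintf("s%d", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  ours <- moderated_t_two_sample(mat, groups)
  fit <- limma::lmFit(mat, stats::model.matrix(~ factor(groups)))
  fit <- limma::eBayes(fit)
  prior <- attr(ours, "prior")
  expect_equal(prior$d0, fit$df.prior, tolerance = 0.05)
  expect_equal(prior$s02, fit$s2.prior, tolerance = 0.02)
  expect_lt(max(abs(ours$p_value - fit$p.value[, 2])), 0.005)
})

test_that("identical group means give t = 0, p = 1", {
  mat <- matrix(rep(c(1, 2, 1, 2), 3), 3, 4, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  res <- moderated_t_two_sample(mat, c("A", "A", "B", "B"))
  expect_true(all(res$effect == 0))
  expect_true(all(res$t_statistic == 0))
  expect_true(all(res$p_value == 1))
})

test_that("one-sample moderated t handles zero-variance rows finitely", {
  mat <- rbind(r1 = c(0, 0, 0, 0), r2 = c(0.5, 0.5, 0.5, 0.5),
               r3 = c(1, 0.2, -0.4, 0.9), r4 = rnorm(4), r5 = rnorm(4))
  colnames(mat) <- sprintf("s%d", 1:4)
  res <- moderated_t_one_sample(mat)
  r1 <- res[res$row == "r1", ]; r2 <- res[res$row == "r2", ]
  expect_equal(r1$t_statistic, 0)
  expect_true(is.finite(r2$t_statistic))  # ordinary t would be infinite
  expect_gt(abs(r2$t_statistic), 0)
})

test_that("rows with too few observations are flagged and skipped", {
  mat <- rbind(ok = rnorm(6), thin = c(1, NA, NA, 2, 3, NA))
  colnames(mat) <- sprintf("s%d", 1:6)
  res <- moderated_t_two_sample(mat, rep(c("A", "B"), each = 3),
                                d0 = 1, s02 = 1)
  expect_true(res$skipped[res$row == "thin"])
  expect_true(is.na(res$p_value[res$row == "thin"]))
})

test_that("BH adjustment equals the naive step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(20); perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("row-wise ANOVA matches the textbook decomposition", {
  # hand-worked 3-group table: groups {1,2,3}, {2,3,4}, {6,7,8}
  mat <- matrix(c(1, 2, 3, 2, 3, 4, 6, 7, 8), 1, 9,
                dimnames = list("r1", sprintf("s%d", 1:9)))
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(mat, g)
  # SSB = 3*((2-4)^2+(3-4)^2+(7-4)^2) = 42, SSW = 6, F = (42/2)/(6/6) = 21
  expect_equal(res$anova$F, 21, tolerance = 1e-10)
  expect_identical(nrow(res$tukey), 3L)
  # two groups: F equals the squared pooled t
  mat2 <- matrix(rnorm(8), 1, 8, dimnames = list("r1", sprintf("s%d", 1:8)))
  g2 <- rep(c("a", "b"), each = 4)
  res2 <- anova_tukey(mat2, g2)
  tt <- t.test(mat2[1, 1:4], mat2[1, 5:8], var.equal = TRUE)
  expect_equal(res2$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # identical groups: F = 0
  mat3 <- matrix(rep(1, 9), 1, 9, dimnames = list("r1", sprintf("s%d", 1:9)))
  expect_equal(anova_tukey(mat3, g)$anova$F, 0)
})

test_that("median-MAD normalization is a robust row z-score", {
  mat <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(mat) <- c("x", "y", "z")
  res <- median_mad_normalize(mat)
  expect_equal(unname(res$matrix["a", ]), c(-1, 0, 1))
  expect_equal(unname(res$matrix["b", ]), c(0, 0, 0))
  expect_identical(res$zero_mad_rows, "b")
  # normalized rows have median 0 exactly
  set.seed(10)
  m <- matrix(rnorm(50), 5, 10, dimnames = list(letters[1:5], NULL))
  colnames(m) <- sprintf("s%d", 1:10)
  norm <- median_mad_normalize(m)$matrix
  expect_true(all(abs(apply(norm, 1, median)) < 1e-12))
})

test_that("duplicated samples merge first under Spearman-complete linkage", {
  set.seed(11)
  base <- matrix(rnorm(200), 50, 4)
  mat <- cbind(base, base + matrix(rnorm(200, sd = 0.01), 50, 4))
  colnames(mat) <- c(paste0("orig", 1:4), paste0("copy", 1:4))
  rownames(mat) <- sprintf("r%02d", 1:50)
  hc <- cluster_samples(mat)
  merged <- stats::cutree(hc, k = 4)
  for (i in 1:4) {
    expect_identical(merged[[paste0("orig", i)]],
                     merged[[paste0("copy", i)]])
  }
  # identical samples merge at height 0 first
  mat2 <- cbind(mat[, 1, drop = FALSE], mat[, 1, drop = FALSE], mat[, 2:3])
  colnames(mat2) <- c("dupA", "dupB", "c", "d")
  hc2 <- cluster_samples(mat2)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_error(cluster_samples(cbind(mat[, 1:2], const = rep(1, 50))),
               "constant")
})

test_that("linkage heights match a brute-force complete-linkage oracle", {
  set.seed(12)
  mat <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, letters[1:5]))
  rownames(mat) <- sprintf("r%02d", 1:20)
  d <- as.matrix(spearman_distance(mat))
  # naive agglomeration
  clusters <- as.list(colnames(mat))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  hc <- cluster_samples(mat)
  expect_equal(hc$height, heights, tolerance = 1e-12)
})

test_that("causal-input export writes a sorted, round-trippable table", {
  res <- data.frame(gene = c("AKT1", "EGFR", "TP53"),
                    site = c("pS473", "pY1068", "pS15"),
                    effect = c(1.2, -0.8, 0.3),
                    adj_p_value = c(0.04, 0.001, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_causalpath_table(res, path)
  expect_identical(out$gene[1], "EGFR")
  back <- read.delim(path)
  expect_equal(back$adj_p_value, sort(res$adj_p_value), tolerance = 1e-6)
  expect_identical(back$effect_sign, c(-1L, 1L, 1L))
  empty <- export_causalpath_table(res[0, ], path)
  expect_identical(nrow(read.delim(path)), 0L)
})

test_that("the moderated test separates true effects from nulls at the study design", {
  st <- simulate_study(n_rows = 500, groups = c("A", "A", "B", "B"),
                       effect = 1, frac_affected = 0.1, within_sd = 0.5,
                       censor_quantile = 0, cat2_quantile = 0, seed = 11)
  res <- moderated_t_two_sample(st$ratio_matrix$log2_ratio,
                                c("A", "A", "B", "B"))
  m <- merge(res, st$truth, by = "row")
  raw_power <- mean(m$p_value[m$affected] < 0.05)
  raw_fpr <- mean(m$p_value[!m$affected] < 0.05)
  expect_gt(raw_power, 0.3)
  expect_lt(raw_fpr, 0.1)
  # at a 2-fold-larger effect the test clears BH 0.05 for most true rows
  st2 <- simulate_study(n_rows = 500, groups = c("A", "A", "B", "B"),
                        effect = 2, frac_affected = 0.1, within_sd = 0.5,
                        censor_quantile = 0, cat2_quantile = 0, seed = 11)
  res2 <- moderated_t_two_sample(st2$ratio_matrix$log2_ratio,
                                 c("A", "A", "B", "B"))
  m2 <- merge(res2, st2$truth, by = "row")
  expect_gt(mean(m2$adj_p_value[m2$affected] < 0.05), 0.5)
})
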