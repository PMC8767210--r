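mk_summaries <- function(x) {
  # wrap a numeric matrix as a minimal trip-summary data.frame
  df <- as.data.frame(x)
  names(df) <- trip_summary_variables()[seq_len(ncol(x))]
  df$id <- sprintf("S%03d", seq_len(nrow(x)))
  df
}

test_that("matrix assembly passes complete data through and drops sparse rows", {
  set.seed(6)
  x <- matrix(rnorm(20 * 8), 20, 8)
  s <- mk_summaries(x)
  am <- assemble_matrix(s)
  expect_equal(unname(am$x), unname(x))
  expect_length(am$dropped, 0)
  # a row missing 20 of 31 variables is excluded
  x31 <- matrix(rnorm(12 * 31), 12, 31)
  s31 <- mk_summaries(x31)
  s31[3, trip_summary_variables()[1:20]] <- NA
  am31 <- assemble_matrix(s31)
  expect_equal(am31$dropped, "S003")
  expect_equal(nrow(am31$x), 11)
})

test_that("iterative PCA imputation fills a masked cell within the observed range", {
  set.seed(16)
  n <- 40
  z <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(runif(3 * 10, -1, 1), 3, 10)
  x <- z %*% load + matrix(rnorm(n * 10, 0, 0.1), n, 10)
  s <- mk_summaries(x)
  true_val <- x[5, 2]
  s[5, trip_summary_variables()[2]] <- NA
  am <- assemble_matrix(s)
  imputed <- am$x[5, 2]
  expect_gte(imputed, min(x[, 2])); expect_lte(imputed, max(x[, 2]))
  # low-rank structure makes the imputation close to truth
  expect_lt(abs(imputed - true_val), 2 * sd(x[, 2]))
})

test_that("correlation PCA has the closed-form spectrum for duplicated variables", {
  set.seed(23)
  v <- rnorm(30)
  x <- cbind(a = v, b = 2 * v + 5)   # correlation exactly 1
  p <- run_pca(x)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(sum(p$var_frac), 1)
  expect_equal(p$retained, 1L)       # eigenvalue rule and 10% rule both pass
})

test_that("PCA is rotation-invariant, reconstructs exactly, and applies the retention rule", {
  set.seed(29)
  x <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2.5, 1.5, 1, 0.5, 0.2))
  p <- run_pca(x)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  # spectrum matches an independent eigen-decomposition of the
  # correlation matrix
  expect_equal(p$eigenvalues, eigen(cor(x))$values, tolerance = 1e-9)
  # permuting variables leaves the correlation spectrum unchanged
  p2 <- run_pca(x[, c(3, 1, 6, 2, 5, 4)])
  expect_equal(p2$eigenvalues, p$eigenvalues, tolerance = 1e-9)
  # reconstruction with all components is exact
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  z <- scale(x)
  rec <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(rec - z)), 1e-10)
  # retention: eigenvalue >= 1 AND variance fraction >= 10%
  expect_equal(p$retained,
               which(p$eigenvalues >= 1 & p$var_frac >= 0.10))
  expect_error(run_pca(cbind(x, const = 1)), "zero-variance")
})

test_that("well-separated blobs are recovered at k = 3 with perfect agreement", {
  skip_if_not_installed("mclust")
  set.seed(37)
  ctr <- rbind(c(0, 0), c(12, 0), c(0, 12))
  truth <- rep(1:3, each = 20)
  sc <- ctr[truth, ] + matrix(rnorm(120, 0, 1), 60, 2)
  sol <- cluster_strategies(sc)
  expect_equal(sol$k, 3)
  expect_equal(mclust::adjustedRandIndex(sol$assignments, truth), 1)
})

test_that("duplicated points cluster identically and silhouette matches brute force", {
  set.seed(41)
  base <- rbind(matrix(rnorm(30, 0, 0.4), 15, 2),
                matrix(rnorm(30, 8, 0.4), 15, 2))
  dup <- rbind(base, base)
  sol <- cluster_strategies(dup)
  n <- nrow(base)
  expect_equal(sol$assignments[seq_len(n)], sol$assignments[n + seq_len(n)],
               ignore_attr = TRUE)
  # exhaustive silhouette evaluation agrees with the chosen k
  d <- dist(base)
  tree <- hclust(d, method = "ward.D2")
  sil <- vapply(2:8, function(k)
    mean(cluster::silhouette(cutree(tree, k), d)[, "sil_width"]), numeric(1))
  sol_b <- cluster_strategies(base)
  expect_equal(unname(sol_b$silhouette), sil, tolerance = 1e-12)
  expect_equal(sol_b$k, (2:8)[which.max(sil)])
})

test_that("Ward merge heights are monotone non-decreasing", {
  set.seed(43)
  sc <- matrix(rnorm(80), 40, 2)
  sol <- cluster_strategies(sc)
  expect_true(all(diff(sol$tree$height) >= -1e-12))
})

test_that("cluster discrimination reduces to textbook ANOVA and t-tests", {
  set.seed(47)
  # equal cluster means: the null model wins on AICc
  y0 <- rnorm(60)
  cl3 <- rep(1:3, each = 20)
  d0 <- discriminate(y0, cl3)
  expect_gt(d0$aicc, d0$null_aicc)
  # balanced 3-group data: the Wald chi-square is df x the one-way ANOVA F
  y <- rnorm(60) + c(0, 1.5, 3)[cl3]
  d1 <- discriminate(y, cl3)
  f_aov <- summary(aov(y ~ factor(cl3)))[[1]]$`F value`[1]
  expect_equal(d1$wald$Chisq[1], 2 * f_aov, tolerance = 1e-8)
  expect_lt(d1$aicc, d1$null_aicc)
  # two clusters: the Tukey-adjusted contrast equals a pooled t-test
  y2 <- rnorm(40) + rep(c(0, 1), each = 20)
  cl2 <- rep(1:2, each = 20)
  d2 <- discriminate(y2, cl2)
  tt <- t.test(y2 ~ cl2, var.equal = TRUE)
  expect_equal(d2$contrasts$p.value, tt$p.value, tolerance = 1e-8)
})

test_that("diel comparisons pick the right test and apply Bonferroni", {
  set.seed(53)
  a <- rnorm(30); b <- a
  expect_gt(diel_compare(a, b)$p, 0.9)
  # shifted normals: Welch statistic matches the closed form
  x <- rnorm(30); y <- rnorm(30) + 1
  dc <- diel_compare(x, y)
  expect_equal(dc$test, "welch")
  t_manual <- (mean(x) - mean(y)) / sqrt(var(x) / 30 + var(y) / 30)
  expect_equal(dc$statistic, t_manual, tolerance = 1e-10)
  # constant vectors force the nonparametric branch
  expect_equal(diel_compare(rep(1, 5), rep(2, 5))$test, "wilcoxon")
  # family correction: adjusted p = min(1, m * p)
  fam <- list(v1 = list(day = x, night = y),
              v2 = list(day = rnorm(20), night = rnorm(20)),
              v3 = list(day = rnorm(20), night = rnorm(20) + 3))
  out <- diel_compare_family(fam)
  expect_equal(out$p_adjusted, pmin(1, 3 * out$p))
})
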