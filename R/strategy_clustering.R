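# Behavioural-strategy clustering: assemble the 31-variable matrix with
# missing-data handling, correlation-matrix PCA with an
# eigenvalue/variance retention rule, Ward hierarchical clustering with
# silhouette-based k selection, per-variable GLM discrimination with AICc
# and Tukey contrasts, and diel day/night comparisons.

#' Assemble the trip-summary matrix for multivariate analysis
#'
#' Drops deployments missing more than half of the variables, then
#' imputes the remainder by regularized iterative PCA: repeatedly fit a
#' low-rank SVD to the standardized matrix and refill the missing cells
#' from the reconstruction until convergence.
#'
#' @param summaries data.frame of trip summaries (rows = deployments);
#'   only the canonical 31 variables are used.
#' @param rank rank of the imputation SVD.
#' @param max_iter,tol iteration controls.
#' @return list: `x` (complete numeric matrix, rownames = ids),
#'   `dropped` (ids excluded), `imputed` (logical matrix of filled cells).
#' @export
assemble_matrix <- function(summaries, rank = 3, max_iter = 100, tol = 1e-6) {
  stopifnot(nrow(summaries) >= 2)
  vars <- intersect(trip_summary_variables(), names(summaries))
  x <- as.matrix(summaries[, vars])
  mode(x) <- "numeric"
  rownames(x) <- summaries$id
  frac_missing <- rowMeans(is.na(x))
  dropped <- rownames(x)[frac_missing > 0.5]
  x <- x[frac_missing <= 0.5, , drop = FALSE]
  if (nrow(x) == 0) stop("all deployments were dropped as mostly missing")
  # drop zero-variance columns; they carry no clustering signal
  keep <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  x <- x[, keep, drop = FALSE]
  miss <- is.na(x)
  if (any(miss)) {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    z[miss] <- 0
    r <- min(rank, nrow(z) - 1, ncol(z) - 1)
    for (it in seq_len(max_iter)) {
      sv <- svd(z, nu = r, nv = r)
      # regularized reconstruction: shrink the retained singular values by
      # the mean discarded variance, damping overfit to imputed cells
      d <- sv$d[seq_len(r)]
      noise <- if (length(sv$d) > r) mean(sv$d[-seq_len(r)]^2) else 0
      dshrunk <- pmax(d - noise / pmax(d, 1e-12), 0)
      fit <- sv$u %*% (dshrunk * t(sv$v))
      delta <- max(abs(fit[miss] - z[miss]))
      z[miss] <- fit[miss]
      if (delta < tol) break
    }
    x[miss] <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")[miss]
  }
  list(x = x, dropped = dropped, imputed = miss)
}

#' Correlation-matrix PCA with the retention rule
#'
#' Variables are centred and scaled; components are retained when their
#' eigenvalue is at least 1 and they explain at least 10% of the
#' variance. Loadings follow a deterministic sign convention (the largest
#' absolute loading of each component is positive).
#'
#' @param x complete numeric matrix (rows = deployments).
#' @param eig_min,var_min retention thresholds.
#' @return list of class `pca_result`: `loadings`, `scores`,
#'   `eigenvalues`, `var_frac`, `retained`.
#' @export
run_pca <- function(x, eig_min = 1.0, var_min = 0.10) {
  stopifnot(nrow(x) >= 3, is.numeric(x))
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) stop("zero-variance column: ",
                          paste(colnames(x)[sdv == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- p$sdev^2
  vf <- eig / sum(eig)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(p$rotation, 2, flip, "*")
  sco <- sweep(p$x, 2, flip, "*")
  structure(list(loadings = rot, scores = sco, eigenvalues = eig,
                 var_frac = vf,
                 retained = which(eig >= eig_min & vf >= var_min)),
            class = "pca_result")
}

#' Ward hierarchical clustering with silhouette-selected k
#'
#' Euclidean dissimilarity of the retained PC scores, Ward.D2 linkage.
#' k is chosen to maximize the average silhouette width over `k_range`
#' (ties to the smaller k); within-cluster sums of squares are reported
#' for elbow inspection.
#'
#' @param scores numeric matrix (rows = deployments), typically the
#'   retained columns of a [run_pca()] result.
#' @param k_range candidate cluster counts.
#' @return list of class `cluster_solution`: `tree` (hclust), `k`,
#'   `assignments`, `silhouette` (named by k), `wss` (named by k).
#' @export
cluster_strategies <- function(scores, k_range = 2:8) {
  n <- nrow(scores)
  if (n < 3) stop("clustering needs at least 3 rows")
  k_range <- k_range[k_range < n]
  d <- stats::dist(scores)
  tree <- stats::hclust(d, method = "ward.D2")
  sil <- wss <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- stats::cutree(tree, k)
    sil[i] <- mean(cluster::silhouette(cl, d)[, "sil_width"])
    wss[i] <- sum(vapply(split(seq_len(n), cl), function(ix) {
      m <- scores[ix, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
  }
  k_best <- k_range[which.max(sil)]   # which.max takes the first = smallest k
  structure(list(tree = tree, k = k_best,
                 assignments = stats::cutree(tree, k_best),
                 silhouette = sil, wss = wss),
            class = "cluster_solution")
}

# AICc for a fitted (g)lm
aicc <- function(fit) {
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

#' Which variables discriminate among clusters
#'
#' Gaussian identity-link GLM of one variable on the cluster factor,
#' compared with the intercept-only null by likelihood-ratio test and
#' AICc; term importance by Type-II Wald ANOVA; post hoc Tukey-adjusted
#' pairwise contrasts of the estimated marginal (cluster) means.
#'
#' @param values numeric response (one trip variable).
#' @param assignments cluster labels.
#' @return list of class `discrimination_result`: `fit`, `aicc`,
#'   `null_aicc`, `lrt_p`, `wald` (car::Anova table), `contrasts`
#'   (emmeans pairs), `unstable` (TRUE when any cluster has < 2 members).
#' @export
discriminate <- function(values, assignments) {
  cl <- factor(assignments)
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  ok <- !is.na(values)
  dat <- data.frame(y = values[ok], cluster = cl[ok])
  if (sum(table(dat$cluster) >= 2) < 2)
    stop("need at least 2 clusters with at least 2 members")
  fit <- stats::glm(y ~ cluster, data = dat, family = stats::gaussian())
  null <- stats::glm(y ~ 1, data = dat, family = stats::gaussian())
  lrt <- stats::anova(null, fit, test = "LRT")
  wald <- car::Anova(fit, type = 2, test.statistic = "Wald")
  emm <- emmeans::emmeans(fit, "cluster")
  contrasts <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                               adjust = "tukey"))
  structure(list(fit = fit, aicc = aicc(fit), null_aicc = aicc(null),
                 lrt_p = lrt$`Pr(>Chi)`[2], wald = wald,
                 emmeans = as.data.frame(emm), contrasts = contrasts,
                 unstable = any(table(dat$cluster) < 2)),
            class = "discrimination_result")
}

#' Compare day vs night values of a dive variable
#'
#' Shapiro-Wilk on each side; when both look normal a Welch two-sample
#' t-test, otherwise a Mann-Whitney-Wilcoxon test. Run the whole family
#' through [diel_compare_family()] to get Bonferroni-adjusted p-values.
#'
#' @param day,night numeric vectors (>= 3 each).
#' @param shapiro_alpha normality cut for choosing the test.
#' @return list: `test` ("welch" or "wilcoxon"), `statistic`, `p`,
#'   `mean_day`, `mean_night`.
#' @export
diel_compare <- function(day, night, shapiro_alpha = 0.05) {
  stopifnot(length(day) >= 3, length(night) >= 3)
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)   # constant: force nonparametric
    stats::shapiro.test(v)$p.value >= shapiro_alpha
  }
  if (normal(day) && normal(night)) {
    tt <- stats::t.test(day, night)            # Welch by default
    out <- list(test = "welch", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- stats::wilcox.test(day, night, exact = FALSE)
    out <- list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
  }
  out$mean_day <- mean(day); out$mean_night <- mean(night)
  out
}

#' Bonferroni-corrected family of diel comparisons
#'
#' @param pairs named list of `list(day =, night =)` vectors.
#' @return data.frame: variable, test, statistic, p, p_adjusted.
#' @export
diel_compare_family <- function(pairs) {
  res <- lapply(pairs, function(p) diel_compare(p$day, p$night))
  out <- data.frame(variable = names(pairs),
                    test = vapply(res, `[[`, character(1), "test"),
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}
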