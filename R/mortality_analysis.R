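# Tag-fate attribution (mechanical failure vs at-sea death), last-known-
# location metrics, logistic mortality models with AIC ranking and
# Hosmer-Lemeshow fit, and between-sex comparison of death locations.

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test with the normal approximation and
#' tie correction. Used on the daily best-location-class rank of a
#' transmitter's final weeks: a significant decreasing trend indicates a
#' degrading tag.
#'
#' @param x numeric series in time order.
#' @param alternative `"decreasing"`, `"increasing"` or `"two.sided"`.
#' @return list: `S`, `z`, `p`.
#' @export
mann_kendall <- function(x, alternative = "decreasing") {
  n <- length(x)
  if (n < 4 || length(unique(x)) < 2) return(list(S = 0, z = 0, p = 1))
  S <- 0
  for (i in seq_len(n - 1))
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  vS <- (n * (n - 1) * (2 * n + 5) -
         sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(vS) else if (S < 0) (S + 1) / sqrt(vS) else 0
  p <- switch(alternative,
              decreasing = stats::pnorm(z),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(S = S, z = z, p = p)
}

#' Attribute a stopped tag to failure or death
#'
#' Decision order: (1) transmitted to the trip end -> survived;
#' (2) stopped at sea but the animal was resighted in a later season ->
#' tag failure; (3) stopped at sea, never resighted, but the location
#' quality degraded over the final `trend_window_days` (one-sided
#' Mann-Kendall, p < `alpha`) -> tag failure; (4) stopped at sea, never
#' resighted, quality trend-free -> presumed dead.
#'
#' @param transmissions data.frame `day`, `date`, `best_lc` (classes
#'   3,2,1,0,A,B), one row per transmitting day.
#' @param resights POSIXct vector of resight dates (may be empty).
#' @param trip_end POSIXct scheduled end of trip.
#' @param trend_window_days window for the quality-trend test.
#' @param alpha one-sided significance cut for "degrading".
#' @param return_tol_days slack for declaring a completed trip.
#' @return list of class `tag_fate`: `outcome` (`"survived_returned"`,
#'   `"tag_failure"`, `"died"`), `resighted`, `trend_p`, `last_date`.
#' @export
attribute_tag_fate <- function(transmissions, resights, trip_end,
                               trend_window_days = 30, alpha = 0.05,
                               return_tol_days = 3) {
  stopifnot(nrow(transmissions) >= 1)
  last <- max(transmissions$date)
  ranks <- lc_rank(as.character(transmissions$best_lc))
  w <- min(trend_window_days, length(ranks))
  tail_ranks <- ranks[seq(length(ranks) - w + 1, length(ranks))]
  mk <- mann_kendall(tail_ranks, "decreasing")
  resighted <- length(resights) > 0 && any(resights > last)
  outcome <- if (last >= trip_end - return_tol_days * 86400) "survived_returned"
    else if (resighted) "tag_failure"
    else if (mk$p < alpha) "tag_failure"
    else "died"
  structure(list(outcome = outcome, resighted = resighted,
                 trend_p = mk$p, trend_S = mk$S, last_date = last,
                 short_record = nrow(transmissions) < trend_window_days),
            class = "tag_fate")
}

#' Attribute fates across a cohort and build the model table
#'
#' @param fixture list with `table` (id, sex, trip, year, trip_days),
#'   `transmissions`, `resights`, `start` — e.g. from
#'   [make_cohort_fixture()] or assembled from a simulated cohort.
#' @param ... passed to [attribute_tag_fate()].
#' @return the table with `outcome` and `died` (0/1) columns.
#' @export
attribute_cohort_fates <- function(fixture, ...) {
  tab <- fixture$table
  tab$outcome <- vapply(seq_len(nrow(tab)), function(i) {
    id <- tab$id[i]
    trip_end <- fixture$start + tab$trip_days[i] * 86400
    attribute_tag_fate(fixture$transmissions[[id]], fixture$resights[[id]],
                       trip_end, ...)$outcome
  }, character(1))
  tab$died <- as.integer(tab$outcome == "died")
  tab
}

#' Metrics at the last known location
#'
#' The trip portion is `"outward"` before the track first reaches
#' `apex_frac` of its maximum colony distance, `"farthest point"` while
#' at or beyond it, and `"return"` once it has left the plateau moving
#' colony-ward.
#'
#' @param track hourly track (`time`, `lon`, `lat`, `speed_kmh`).
#' @param geometry study geometry ([make_geometry()]).
#' @param params [foraging_params()] (for the apex fraction and
#'   ecoregion rule).
#' @return one-row data.frame: `lon`, `lat`, `transit_rate_ms`,
#'   `shelf_distance_km`, `ecoregion`, `portion`.
#' @export
last_location_metrics <- function(track, geometry, params = foraging_params()) {
  stopifnot(nrow(track) >= 2)
  n <- nrow(track)
  d <- geosphere::distHaversine(cbind(track$lon, track$lat),
                                matrix(geometry$colony, nrow = 1)) / 1000
  apex <- d >= params$apex_frac * max(d)
  first_apex <- which(apex)[1]
  # the last observed position is either within the farthest-point
  # plateau, past it moving colony-ward, or (when the plateau was reached
  # and left early) still short of it
  portion <- if (apex[n]) "farthest point"
    else if (n > first_apex) "return"
    else "outward"
  regions <- vapply(geometry$ecoregions, function(p)
    points_in_polygon(track$lon[n], track$lat[n], p), logical(1))
  data.frame(lon = track$lon[n], lat = track$lat[n],
             transit_rate_ms = track$speed_kmh[n] / 3.6,
             shelf_distance_km = distance_to_shelf(track$lon[n], track$lat[n],
                                                   geometry$shelf),
             ecoregion = if (any(regions)) names(regions)[which(regions)[1]]
                         else "open/unassigned",
             portion = portion)
}

#' Fit and rank the candidate logistic mortality models
#'
#' Binomial logit GLMs of died (0/1) on all subsets of
#' {sex, trip, year} that contain sex, plus the intercept-only null for
#' reference. Models are ranked by AIC with a delta-AIC <= 7 shortlist;
#' the best model gets a likelihood-ratio test against the null, a
#' Hosmer-Lemeshow goodness-of-fit test and a Type-II Wald ANOVA.
#'
#' @param cohort data.frame: `died` (0/1), `sex`, `trip`, `year` (year is
#'   treated as a factor).
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return list of class `mortality_models`: `ranking` (formula, AIC,
#'   delta_aic, shortlisted), `fits`, `best`, `lrt_p`, `hosmer_lemeshow`,
#'   `wald`.
#' @export
fit_mortality_models <- function(cohort, hl_groups = 10) {
  stopifnot(all(c("died", "sex") %in% names(cohort)))
  if (length(unique(cohort$died)) < 2)
    stop("both outcome levels must be present")
  cohort$sex <- factor(cohort$sex)
  if ("trip" %in% names(cohort)) cohort$trip <- factor(cohort$trip)
  if ("year" %in% names(cohort)) cohort$year <- factor(cohort$year)
  extras <- intersect(c("trip", "year"), names(cohort))
  extras <- extras[vapply(extras, function(v) nlevels(cohort[[v]]) > 1, logical(1))]
  combos <- unlist(lapply(0:length(extras), function(k)
    utils::combn(extras, k, simplify = FALSE)), recursive = FALSE)
  forms <- vapply(combos, function(cc)
    trimws(paste("died ~ sex",
                 if (length(cc)) paste("+", paste(cc, collapse = " + "))
                 else "")), character(1))
  forms <- c(forms, "died ~ 1")
  fits <- lapply(forms, function(f)
    stats::glm(stats::as.formula(f), data = cohort, family = stats::binomial()))
  names(fits) <- forms
  sep <- vapply(fits, function(f)
    any(abs(stats::coef(f)) > 15, na.rm = TRUE), logical(1))
  if (any(sep)) warning("possible complete separation in: ",
                        paste(forms[sep], collapse = "; "))
  aics <- vapply(fits, stats::AIC, numeric(1))
  cand <- names(fits) != "died ~ 1"
  ranking <- data.frame(formula = forms, aic = aics,
                        delta_aic = aics - min(aics[cand]),
                        candidate = cand)
  ranking$shortlisted <- cand & ranking$delta_aic <= 7
  ranking <- ranking[order(!ranking$candidate, ranking$aic), ]
  best_f <- ranking$formula[1]
  best <- fits[[best_f]]
  lrt <- stats::anova(fits[["died ~ 1"]], best, test = "LRT")
  structure(list(ranking = ranking, fits = fits, best = best,
                 best_formula = best_f,
                 lrt_p = lrt$`Pr(>Chi)`[2],
                 hosmer_lemeshow = hosmer_lemeshow(cohort$died,
                                                   stats::fitted(best),
                                                   hl_groups),
                 wald = car::Anova(best, type = 2, test.statistic = "Wald")),
            class = "mortality_models")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk chi-squared on g groups, df = g - 2.
#'
#' @param y observed 0/1 outcomes.
#' @param p fitted probabilities.
#' @param g number of groups.
#' @return list: `statistic`, `df`, `p`.
#' @export
hosmer_lemeshow <- function(y, p, g = 10) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  grp <- cut(p, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  exp_g <- tapply(p, grp, sum)
  chi <- sum((obs - exp_g)^2 / (exp_g * (1 - exp_g / n_g)), na.rm = TRUE)
  df <- max(1, length(levels(droplevels(grp))) - 2)
  list(statistic = chi, df = df, p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Marginal mortality probability by sex
#'
#' Averages the predicted death probability over the levels of the other
#' model terms at each sex (estimated marginal mean on the response
#' scale); the Wald confidence interval is built on the link scale and
#' back-transformed.
#'
#' @param fit a binomial GLM containing `sex`.
#' @param level confidence level.
#' @return data.frame: `sex`, `probability`, `lower`, `upper`.
#' @export
mortality_probability <- function(fit, level = 0.95) {
  dat <- fit$model
  sexes <- levels(dat$sex)
  others <- setdiff(names(dat), c("died", "sex", "(weights)"))
  ref <- if (length(others)) {
    expand.grid(lapply(dat[others], function(v)
      if (is.factor(v)) levels(v) else unique(v)), stringsAsFactors = FALSE)
  } else data.frame(row.names = 1)
  names(ref) <- others
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(sexes, function(s) {
    nd <- ref; nd$sex <- s
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    # average on the link scale across the reference grid (one cell when
    # the model is sex-only), then back-transform
    eta <- mean(pr$fit)
    se <- sqrt(mean(pr$se.fit^2))
    data.frame(sex = s,
               probability = stats::plogis(eta),
               lower = stats::plogis(eta - z * se),
               upper = stats::plogis(eta + z * se))
  })
  do.call(rbind, out)
}

#' Compare movement metrics of dead males vs dead females
#'
#' Mann-Whitney-Wilcoxon per metric with Bonferroni correction over the
#' family.
#'
#' @param males,females data.frames of last-location metrics with the
#'   columns in `metrics`.
#' @param metrics which columns to compare.
#' @return data.frame: metric, W, p, p_adjusted, medians.
#' @export
compare_death_locations <- function(males, females,
                                    metrics = c("shelf_distance_km",
                                                "transit_rate_ms")) {
  stopifnot(nrow(males) >= 3, nrow(females) >= 3)
  res <- lapply(metrics, function(m) {
    wt <- stats::wilcox.test(males[[m]], females[[m]], exact = FALSE)
    data.frame(metric = m, W = unname(wt$statistic), p = wt$p.value,
               median_male = stats::median(males[[m]]),
               median_female = stats::median(females[[m]]))
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out
}
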