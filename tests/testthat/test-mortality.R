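mk_trans <- function(ranks, start = as.POSIXct("2010-03-15", tz = "UTC")) {
  cls <- c("B", "A", "0", "1", "2", "3")[ranks]
  data.frame(day = seq_along(ranks),
             date = start + (seq_along(ranks) - 1) * 86400,
             best_lc = cls)
}

no_resight <- as.POSIXct(character(0), tz = "UTC")

test_that("Mann-Kendall flags monotone decline and not a trend-free series", {
  mono <- mann_kendall(rep(6:1, each = 5), "decreasing")
  expect_lt(mono$p, 1e-4)
  flat <- mann_kendall(rep(c(3, 6, 1, 5, 2, 4), 5), "decreasing")
  expect_gt(flat$p, 0.2)
  expect_equal(mann_kendall(rep(2, 10))$p, 1)   # constant: no evidence
})

test_that("tag-fate attribution follows the decision order", {
  start <- as.POSIXct("2010-03-15", tz = "UTC")
  trip_end <- start + 100 * 86400
  # transmitted to trip end: survived regardless of quality
  f1 <- attribute_tag_fate(mk_trans(sample(1:6, 100, TRUE)), no_resight, trip_end)
  expect_equal(f1$outcome, "survived_returned")
  # stopped at sea, resighted next season: failure (animal alive)
  f2 <- attribute_tag_fate(mk_trans(rep(c(4, 2, 6, 1), 10)),
                           start + 300 * 86400, trip_end)
  expect_equal(f2$outcome, "tag_failure")
  expect_true(f2$resighted)
  # monotone class decline over the final month, no resight: failure
  f3 <- attribute_tag_fate(mk_trans(c(rep(5, 30), rep(6:1, each = 5))),
                           no_resight, trip_end)
  expect_equal(f3$outcome, "tag_failure")
  expect_lt(f3$trend_p, 0.05)
  # trend-free classes to the end, no resight: presumed dead
  f4 <- attribute_tag_fate(mk_trans(rep(c(3, 6, 1, 5, 2, 4), 10)),
                           no_resight, trip_end)
  expect_equal(f4$outcome, "died")
})

test_that("fate attribution is exhaustive and consistent on the packaged fixture", {
  fx <- make_cohort_fixture()
  tab <- attribute_cohort_fates(fx)
  expect_equal(nrow(tab), 217)
  expect_true(all(tab$outcome %in% c("survived_returned", "tag_failure", "died")))
  # attribution recovers the construction exactly
  expect_equal(unname(table(tab$true_fate, tab$outcome)["died", "died"]), 39)
  expect_true(all((tab$outcome == "died") == (tab$true_fate == "died")))
})

test_that("last-location metrics read the trip geometry", {
  geom <- make_geometry()
  t0 <- as.POSIXct("2010-03-15", tz = "UTC")
  # out-and-die-at-apex track
  xk <- c(seq(0, -300, length.out = 30), rep(-300, 5))
  ll <- unproject_aeqd(xk, seq(0, 350, length.out = 35), geom$colony)
  tr <- data.frame(time = t0 + (0:34) * 3600, lon = ll[, "lon"],
                   lat = ll[, "lat"])
  tr$speed_kmh <- transit_speeds(tr)
  m <- last_location_metrics(tr, geom)
  expect_equal(m$portion, "farthest point")
  expect_equal(m$transit_rate_ms, tr$speed_kmh[35] / 3.6)
  # final position on the isobath: distance ~ 0
  ll2 <- unproject_aeqd(c(-200, -100, geom$shelf_x_km), c(100, 100, 100),
                        geom$colony)
  tr2 <- data.frame(time = t0 + (0:2) * 3600, lon = ll2[, "lon"],
                    lat = ll2[, "lat"])
  tr2$speed_kmh <- transit_speeds(tr2)
  expect_lt(last_location_metrics(tr2, geom)$shelf_distance_km, 0.05)
})

test_that("near-shelf death fractions round-trip the generator's construction", {
  geom <- make_geometry()
  t0 <- as.POSIXct("2010-03-15", tz = "UTC")
  set.seed(83)
  # plant 20 deaths within 30 km of the shelf and 10 far offshore
  d_true <- c(runif(20, 0, 25), runif(10, 200, 600))
  near_frac <- vapply(d_true, function(d) {
    ll <- unproject_aeqd(c(0, geom$shelf_x_km - d), c(200, 200), geom$colony)
    tr <- data.frame(time = t0 + (0:1) * 3600, lon = ll[, "lon"],
                     lat = ll[, "lat"])
    tr$speed_kmh <- transit_speeds(tr)
    last_location_metrics(tr, geom)$shelf_distance_km
  }, numeric(1))
  expect_equal(mean(near_frac <= 30), 20 / 30, tolerance = 1e-9)
})

test_that("the sex-only logistic model reproduces group death fractions", {
  cohort <- data.frame(
    sex = rep(c("male", "female"), c(39, 178)),
    trip = "post-breeding",
    year = 2010,
    died = c(rep(1, 17), rep(0, 22), rep(1, 22), rep(0, 156)))
  fits <- fit_mortality_models(cohort)
  expect_s3_class(fits$best, "glm")
  pr <- mortality_probability(fits$best)
  expect_equal(pr$probability[pr$sex == "male"], 17 / 39, tolerance = 1e-6)
  expect_equal(pr$probability[pr$sex == "female"], 22 / 178, tolerance = 1e-6)
  expect_true(all(pr$probability > 0 & pr$probability < 1))
  expect_true(all(pr$lower < pr$probability & pr$probability < pr$upper))
  expect_lt(fits$lrt_p, 0.001)
  expect_true(is.finite(fits$hosmer_lemeshow$statistic))
  # single outcome level is an error
  expect_error(fit_mortality_models(transform(cohort, died = 0)), "outcome")
})

test_that("glm IRLS matches a brute-force likelihood grid on a 2-parameter model", {
  set.seed(89)
  x <- rep(c(0, 1), each = 60)
  p_true <- plogis(-1 + 1.2 * x)
  y <- rbinom(120, 1, p_true)
  fit <- glm(y ~ x, family = binomial())
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log1p(exp(b[1] + b[2] * x)))
  grid <- optim(c(0, 0), nll, method = "BFGS")
  expect_lt(max(abs(coef(fit) - grid$par)), 1e-4)
})

test_that("null-true cohorts keep the null competitive in AIC", {
  set.seed(97)
  hits <- 0
  for (r in 1:20) {
    cohort <- data.frame(sex = rep(c("male", "female"), each = 60),
                         died = rbinom(120, 1, 0.25))
    if (length(unique(cohort$died)) < 2) next
    f <- fit_mortality_models(cohort)
    null_aic <- f$ranking$aic[f$ranking$formula == "died ~ 1"]
    sex_aic <- f$ranking$aic[f$ranking$formula == "died ~ sex"]
    hits <- hits + (null_aic <= sex_aic + 2)
  }
  expect_gt(hits, 14)   # in most replicates
})

test_that("death-location comparison uses exact small-sample behaviour", {
  set.seed(101)
  same <- data.frame(shelf_distance_km = rnorm(20, 100, 10),
                     transit_rate_ms = rnorm(20, 0.5, 0.1))
  out_same <- compare_death_locations(same, same)
  expect_true(all(out_same$p > 0.9))
  # large separation: significant after Bonferroni
  males <- data.frame(shelf_distance_km = rnorm(17, 60, 10),
                      transit_rate_ms = rnorm(17, 0.5, 0.1))
  females <- data.frame(shelf_distance_km = rnorm(22, 470, 50),
                        transit_rate_ms = rnorm(22, 0.5, 0.1))
  out <- compare_death_locations(males, females)
  expect_lt(out$p_adjusted[out$metric == "shelf_distance_km"], 0.001)
  # U statistic on {1,2,3} vs {4,5,6}: W = 0, exact p = 2/choose(6,3)
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p.value, 2 / choose(6, 3), tolerance = 1e-12)
})

test_that("marginal probability CIs achieve nominal coverage under the model", {
  set.seed(103)
  p_true <- 0.3
  cover <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    cohort <- data.frame(sex = rep(c("male", "female"), each = 100),
                         died = rbinom(200, 1, p_true))
    if (length(unique(cohort$died)) < 2) { cover <- cover + 1; next }
    fit <- glm(died ~ sex, data = transform(cohort, sex = factor(sex)),
               family = binomial())
    pr <- mortality_probability(fit)
    row <- pr[pr$sex == "male", ]
    cover <- cover + (row$lower <= p_true && p_true <= row$upper)
  }
  expect_gt(cover / n_rep, 0.90)
  expect_lt(cover / n_rep, 0.99)
})
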