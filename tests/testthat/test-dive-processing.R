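t0 <- as.POSIXct("2010-03-01", tz = "UTC")

test_that("subsampling keeps every k-th sample and rejects non-divisors", {
  s8 <- data.frame(time = t0 + (0:99) * 8, depth_m = sin(1:100))
  expect_identical(subsample_depth(s8, 8), s8)
  s1 <- data.frame(time = t0 + 0:799, depth_m = sin((1:800) / 20))
  expect_equal(nrow(subsample_depth(s1, 8)), 100)
  s2 <- data.frame(time = t0 + (0:399) * 2, depth_m = sin((1:400) / 10))
  sub <- subsample_depth(s2, 8)
  expect_equal(sub$depth_m, s2$depth_m[seq(1, 400, by = 4)])
  s3 <- data.frame(time = t0 + (0:99) * 3, depth_m = numeric(100))
  expect_error(subsample_depth(s3, 8), "divide")
})

test_that("dive detection applies the printed retention thresholds", {
  expect_equal(nrow(detect_dives(data.frame(time = t0 + (0:99) * 8,
                                            depth_m = numeric(100)))), 0)
  # one V excursion to 20 m lasting ~60 s passes both thresholds
  d1 <- c(numeric(4), seq(4, 20, length.out = 4), seq(20, 4, length.out = 4),
          numeric(4))
  s1 <- data.frame(time = t0 + (seq_along(d1) - 1) * 8, depth_m = d1)
  expect_equal(nrow(detect_dives(s1)), 1)
  # 30 s at 20 m fails the duration rule; 300 s at 10 m fails the depth rule
  d2 <- c(numeric(3), 20, 20, 20, numeric(3),
          rep(10, 38), numeric(3))
  s2 <- data.frame(time = t0 + (seq_along(d2) - 1) * 8, depth_m = d2)
  expect_equal(nrow(detect_dives(s2)), 0)
})

test_that("post-dive interval is the surface gap to the next dive", {
  mk_dive <- function(depth, ns) c(numeric(2), rep(depth, ns), numeric(2))
  d <- c(mk_dive(50, 10), numeric(26), mk_dive(60, 10))
  s <- data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
  dv <- detect_dives(s)
  expect_equal(nrow(dv), 2)
  gap_s <- as.numeric(dv$start[2]) - as.numeric(dv$end[1])
  expect_equal(dv$postdive_interval_min[1], gap_s / 60)
  expect_true(is.na(dv$postdive_interval_min[2]))
})

test_that("square-wave dive metrics match the efficiency definition", {
  # 10 min at constant depth inside a 20 min submerged window
  n_bot <- 75                       # 10 min at 8 s
  n_leg <- 38                       # ~5 min shallow legs at 30 m
  d <- c(numeric(2), rep(30, n_leg), rep(100, n_bot), rep(30, n_leg),
         numeric(2))
  s <- data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
  dv <- detect_dives(s)
  dv <- dive_metrics(s, dv[1, ])
  expect_equal(dv$efficiency, dv$bottom_time_min / dv$duration_min)
  expect_equal(dv$bottom_time_min, 10, tolerance = 0.05)
  expect_equal(dv$efficiency, 10 / dv$duration_min, tolerance = 1e-9)
})

test_that("excursion counting matches a constructed oracle and the V limit", {
  # bottom profile with 3 reversals of 6 m amplitude at threshold 5 m
  bot <- 100 - 6 * abs(sin(pi * 3 * seq(0, 1, length.out = 200)))
  expect_equal(count_excursions(bot, 5), 3)
  expect_equal(count_excursions(bot, 7), 0)    # threshold above amplitude
  # pure V-dive: negligible bottom phase, efficiency ~ 0
  s <- v_dive_series(100)
  dv <- dive_metrics(s, detect_dives(s)[1, ])
  expect_lt(dv$efficiency, 0.1)
  expect_equal(dv$n_excursions, 0)
})

test_that("the classifier hierarchy resolves the four archetypes", {
  # V-dive with no wiggles: transit
  s <- v_dive_series(100)
  dv <- dive_metrics(s, detect_dives(s)[1, ])
  expect_equal(classify_dive(s, dv, 3000), "transit")

  # flat-bottom dive to 248 m over a 250 m seafloor: benthic
  d <- c(numeric(2), seq(0, 248, length.out = 40), rep(248, 80),
         seq(248, 0, length.out = 40), numeric(2))
  sb <- data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
  dvb <- dive_metrics(sb, detect_dives(sb)[1, ])
  expect_equal(classify_dive(sb, dvb, 250), "benthic")
  # the same dive without a seafloor reference cannot be benthic
  expect_false(classify_dive(sb, dvb, NA) == "benthic")

  # 550 m dive with 6 bottom wiggles over a 3000 m seafloor: pelagic
  bot <- 550 - 12 * abs(sin(pi * 6 * seq(0, 1, length.out = 90)))
  d <- c(numeric(2), seq(0, 550, length.out = 50), bot,
         seq(550, 0, length.out = 50), numeric(2))
  sp <- data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
  dvp <- dive_metrics(sp, detect_dives(sp)[1, ])
  expect_equal(dvp$n_excursions, 6)
  expect_equal(classify_dive(sp, dvp, 3000), "pelagic")

  # slow monotone mid-segment: drift
  d <- c(numeric(2), seq(0, 300, length.out = 30),
         seq(300, 360, length.out = 120),        # 0.0625 m/s over half the dive
         seq(360, 0, length.out = 30), numeric(2))
  sd_ <- data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
  dvd <- dive_metrics(sd_, detect_dives(sd_)[1, ])
  expect_equal(classify_dive(sd_, dvd, 3000), "drift")
})

test_that("zero-offset correction restores the 15 m retention rule under drift", {
  set.seed(3)
  spec <- dive_spec(depth_noise_sd = 0.5, surface_drift_m_per_day = 40)
  ds <- simulate_dive_series(c(transit = 1, pelagic = 0, benthic = 0, drift = 0),
                             duration_h = 6, spec = spec, seafloor_m = 3000)
  raw_min <- min(ds$series$depth_m[ds$series$depth_m > 0])
  corr <- zero_offset_correct(ds$series)
  # the corrected series has true surface intervals back near zero
  expect_lt(quantile(corr$depth_m, 0.05), 1.5)
  dv <- detect_dives(corr)
  expect_equal(nrow(dv), nrow(ds$truth))
})

test_that("noise-free archetypes are recovered perfectly; noisy recovery stays high", {
  run_recovery <- function(noise) {
    set.seed(19)
    spec <- dive_spec(depth_noise_sd = noise)
    ds <- simulate_dive_series(c(transit = .25, pelagic = .25, benthic = .25,
                                 drift = .25), duration_h = 10, spec = spec,
                               seafloor_m = 260)
    series <- subsample_depth(ds$series, 8)
    dv <- detect_dives(series)
    dv <- do.call(rbind, lapply(seq_len(nrow(dv)), function(i)
      dive_metrics(series, dv[i, ])))
    pred <- vapply(seq_len(nrow(dv)), function(i)
      classify_dive(series, dv[i, ], 260), character(1))
    truth <- vapply(seq_len(nrow(dv)), function(i) {
      j <- which.min(abs(as.numeric(ds$truth$start) - as.numeric(dv$start[i])))
      ds$truth$type[j]
    }, character(1))
    mean(pred == truth)
  }
  expect_equal(run_recovery(0), 1)
  acc1 <- run_recovery(1)
  expect_gt(acc1, 0.9)
  acc4 <- run_recovery(4)
  expect_gte(acc1, acc4 - 0.05)   # monotone (noisy estimate: small slack)
  expect_gt(acc4, 0.25)           # still above chance
})

test_that("diel assignment uses the dive midpoint zenith", {
  mk <- function(hh) {
    st <- as.POSIXct("2010-03-20", tz = "UTC") + hh * 3600 - 600
    data.frame(start = st, end = st + 1200, lat = 0, lon = 0)
  }
  expect_equal(assign_diel(mk(12)), "day")       # local solar noon
  expect_equal(assign_diel(mk(0)), "night")      # local solar midnight
  d <- mk(11); d$lat <- NA
  expect_error(assign_diel(d), "no position")
})

test_that("georeferencing interpolates linearly and flags out-of-span dives", {
  tr <- data.frame(time = t0 + (0:5) * 3600,
                   lon = seq(-130, -129.5, length.out = 6),
                   lat = seq(40, 40.25, length.out = 6))
  # dive centred exactly on an hourly timestamp
  dv <- data.frame(start = t0 + 2 * 3600 - 300, end = t0 + 2 * 3600 + 300)
  g <- georeference_dives(dv, tr)
  expect_equal(g$lon, tr$lon[3]); expect_equal(g$lat, tr$lat[3])
  # dive at 30 min between two positions lands at the midpoint
  dv2 <- data.frame(start = t0 + 90 * 60, end = t0 + 90 * 60)
  g2 <- georeference_dives(dv2, tr)
  expect_equal(g2$lon, mean(tr$lon[2:3])); expect_equal(g2$lat, mean(tr$lat[2:3]))
  # outside the track span: unplaced
  dv3 <- data.frame(start = t0 + 10 * 3600, end = t0 + 10 * 3600)
  expect_false(georeference_dives(dv3, tr)$placed)
  # hull property over random dives
  set.seed(5)
  mids <- sort(runif(40, 0, 5 * 3600))
  dv4 <- data.frame(start = t0 + mids, end = t0 + mids)
  g4 <- georeference_dives(dv4, tr)
  lo <- findInterval(mids / 3600, 0:5)
  expect_true(all(g4$lon >= pmin(tr$lon[lo], tr$lon[lo + 1]) - 1e-12))
  expect_true(all(g4$lon <= pmax(tr$lon[lo], tr$lon[lo + 1]) + 1e-12))
})

test_that("per-deployment dive-type proportions sum to one with valid efficiencies", {
  co <- small_cohort()
  for (id in co$deployments$id[1:4]) {
    dv <- process_dives(co$dives[[id]]$series, geometry = co$geometry)
    props <- prop.table(table(factor(dv$type, levels = c("transit", "pelagic",
                                                         "benthic", "drift"))))
    expect_equal(sum(props), 1)
    expect_true(all(dv$efficiency >= 0 & dv$efficiency <= 1))
    expect_true(all(dv$bottom_time_min <= dv$duration_min + 1e-9))
  }
})
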