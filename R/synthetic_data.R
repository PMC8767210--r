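# Seeded synthetic cohorts of satellite-tracked, TDR-instrumented seals.
# The generator emulates the statistical structure the downstream analysis
# assumes -- two-state movement, four dive archetypes, ARGOS class-dependent
# position error, onshore fasting, and a tag-fate process -- and retains all
# ground truth so recovery can be tested end to end.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B")

#' Default ARGOS position-error standard deviations (km) by location class
#' @export
argos_error_sd_default <- function() {
  c("3" = 0.25, "2" = 0.5, "1" = 1.5, "0" = 4, "A" = 6, "B" = 10)
}

#' Dive archetype parameters
#'
#' Depths are metres, durations minutes, rates m/s. `diel_offset_m` is how
#' much shallower a pelagic foraging dive is at night than by day, matching
#' the diel vertical migration of mesopelagic prey. Transit dives are
#' parameterized by vertical rate so their V shape stays steep at any
#' depth; drift dives contain one slow monotone segment.
#'
#' @param sampling_s depth sampling interval, seconds (1-8).
#' @param depth_noise_sd additive Gaussian depth noise, metres.
#' @param surface_drift_m_per_day slow linear offset of the zero-depth
#'   reading, exercising zero-offset correction. Default 0.
#' @return list of archetype specs used by [simulate_dive_series()].
#' @export
dive_spec <- function(sampling_s = 8, depth_noise_sd = 1,
                      surface_drift_m_per_day = 0) {
  list(
    sampling_s = sampling_s,
    depth_noise_sd = depth_noise_sd,
    surface_drift_m_per_day = surface_drift_m_per_day,
    surface_min = c(mean = 2.2, sd = 0.4),
    transit = list(depth = c(mean = 190, sd = 20), rate_ms = c(mean = 0.85, sd = 0.08)),
    pelagic = list(depth = c(mean = 560, sd = 40), duration_min = c(mean = 24, sd = 2),
                   bottom_frac = 0.45, wiggles = c(mean = 18, sd = 2),
                   wiggle_amp_m = 10, diel_offset_m = 80,
                   # mid-water dives keep clear of the seafloor: max depth
                   # clearance_frac * seafloor - clearance_m, at least
                   # min_depth_m, else the animal forages benthically
                   clearance_frac = 0.7, clearance_m = 130, min_depth_m = 100),
    benthic = list(duration_min = c(mean = 20, sd = 2.5), bottom_frac = 0.60,
                   wiggles = c(mean = 18, sd = 3), wiggle_amp_m = 8,
                   depth_frac_of_seafloor = 0.985,
                   # beyond this the bottom is out of reach: forage mid-water
                   max_seafloor_m = 600),
    drift   = list(depth = c(mean = 350, sd = 40), duration_min = c(mean = 20, sd = 2),
                   drift_frac = 0.5, drift_rate_ms = 0.12)
  )
}

#' Default movement/behaviour specs for the three foraging strategies
#'
#' Males: shelf-bound benthic foragers on biannual ~126-day trips.
#' Post-breeding females: ~76-day pelagic trips a few hundred km beyond
#' the shelf. Post-moult females: ~220-day pelagic trips ranging farther,
#' with several prey patches. Each entry carries trip duration, transit
#' and area-restricted-search speeds, destination and patch structure,
#' per-state dive-archetype mixes, body-composition parameters and the
#' strategy's pelagic dive depth.
#'
#' @return named list of per-strategy specs; edit and pass to
#'   [sim_config()] to plant custom strategies.
#' @export
strategy_defaults <- function() {
  list(
    male = list(
      trip_days = c(mean = 126, sd = 18),
      transit_speed_kmh = 4.0, ars_speed_kmh = 0.7,
      n_patches = 1, dest_km = c(x = -35, y = 800), dest_sd_km = c(30, 120),
      mix_transit = c(transit = 0.70, pelagic = 0.12, benthic = 0, drift = 0.18),
      mix_ars     = c(transit = 0.04, pelagic = 0.14, benthic = 0.72, drift = 0.10),
      departure_mass = c(mean = 1074, sd = 194), gain = c(mean = 458, sd = 160),
      adipose_frac = 0.41, pelagic_depth = c(mean = 410, sd = 60)
    ),
    female_pb = list(
      trip_days = c(mean = 76, sd = 13),
      transit_speed_kmh = 3.6, ars_speed_kmh = 0.8,
      n_patches = 2, dest_km = c(x = -530, y = 430), dest_sd_km = c(120, 260),
      mix_transit = c(transit = 0.62, pelagic = 0.22, benthic = 0, drift = 0.16),
      mix_ars     = c(transit = 0.05, pelagic = 0.80, benthic = 0.05, drift = 0.10),
      departure_mass = c(mean = 335, sd = 49), gain = c(mean = 76, sd = 31),
      adipose_frac = 0.46, pelagic_depth = c(mean = 560, sd = 45)
    ),
    female_pm = list(
      trip_days = c(mean = 220, sd = 20),
      transit_speed_kmh = 3.6, ars_speed_kmh = 0.8,
      n_patches = 4, dest_km = c(x = -660, y = 320), dest_sd_km = c(150, 340),
      mix_transit = c(transit = 0.62, pelagic = 0.22, benthic = 0, drift = 0.16),
      mix_ars     = c(transit = 0.06, pelagic = 0.78, benthic = 0.05, drift = 0.11),
      departure_mass = c(mean = 281, sd = 36), gain = c(mean = 233, sd = 53),
      adipose_frac = 0.36, pelagic_depth = c(mean = 545, sd = 45)
    )
  )
}

#' Synthetic study geometry
#'
#' A colony on the central California coast, a straight continental-shelf
#' isobath running parallel to the coast `shelf_offshore_km` west of it,
#' and three rectangular mesopelagic ecoregions (California Current,
#' Subarctic Pacific, North Central Pacific) in the colony-centred
#' azimuthal equidistant plane. Rectangles keep every containment and
#' distance checkable by hand.
#'
#' @param colony `c(lon, lat)` of the breeding colony.
#' @param shelf_offshore_km perpendicular distance from colony to the
#'   200 m isobath.
#' @return list with `colony`, `shelf` (lon/lat polyline), `ecoregions`
#'   (named list of lon/lat rings) and seafloor parameters.
#' @export
make_geometry <- function(colony = c(lon = -122.33, lat = 37.11),
                          shelf_offshore_km = 60) {
  sx <- -shelf_offshore_km
  shelf_xy <- cbind(x = rep(sx, 61), y = seq(-800, 2200, length.out = 61))
  shelf <- as.data.frame(unproject_aeqd(shelf_xy[, 1], shelf_xy[, 2], colony))
  rect <- function(x1, x2, y1, y2) {
    xy <- cbind(x = c(x1, x2, x2, x1, x1), y = c(y1, y1, y2, y2, y1))
    as.data.frame(unproject_aeqd(xy[, 1], xy[, 2], colony))
  }
  list(
    colony = colony,
    shelf = shelf,
    shelf_x_km = sx,
    ecoregions = list(
      california_current    = rect(-420,   80, -1400, 220),
      subarctic_pacific     = rect(-2600,  80,   220, 2400),
      north_central_pacific = rect(-2600, -420, -1400, 220)
    ),
    seafloor = list(shelf_x_km = sx, coast_depth_m = 30, shelf_edge_depth_m = 250,
                    slope_m_per_km = 45, abyss_m = 3900)
  )
}

#' Seafloor depth under a projected x (cross-shore) coordinate
#'
#' Piecewise-linear synthetic bathymetry: shoaling shelf inshore of the
#' isobath, a steep slope beyond it, flattening at abyssal depth.
#'
#' @param geometry output of [make_geometry()].
#' @param x_km cross-shore coordinate (km, negative = offshore).
#' @return seafloor depth in metres (positive down).
#' @export
seafloor_depth <- function(geometry, x_km) {
  sf <- geometry$seafloor
  sx <- sf$shelf_x_km
  on_shelf <- x_km >= sx
  d <- numeric(length(x_km))
  frac <- pmin(1, pmax(0, x_km / sx))
  d[on_shelf] <- sf$coast_depth_m +
    (sf$shelf_edge_depth_m - sf$coast_depth_m) * frac[on_shelf]
  d[!on_shelf] <- pmin(sf$abyss_m,
                       sf$shelf_edge_depth_m + sf$slope_m_per_km * (sx - x_km[!on_shelf]))
  d
}

#' Simulation configuration
#'
#' Bundles every tunable of the cohort generator. Defaults are set to the
#' field-realistic scales of an adult northern elephant seal study:
#' biannual trips of roughly 76/126/220 days, transit speeds near
#' 4 km/h with area-restricted search well under the 2 km/h foraging
#' threshold, ARGOS errors from hundreds of metres (class 3) to 10 km
#' (class B), and per-sex death/tag-failure probabilities of 0.44/0.21
#' (males) and 0.12/0.13 (females).
#'
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @param n_males,n_females deployment counts.
#' @param female_pm_fraction share of female deployments on the
#'   post-moult trip.
#' @param trip_scale multiplies every strategy's trip duration; < 1 gives
#'   desk-scale cohorts with unchanged per-hour behaviour.
#' @param strategies per-strategy movement/behaviour specs (see
#'   `strategy_defaults()` for the shape).
#' @param dive output of [dive_spec()].
#' @param argos list: `rate_per_h`, `class_probs`, `error_sd_km`,
#'   `outlier_rate`, `outlier_km` range.
#' @param fate list of per-sex probabilities `p_death`, `p_failure`, and
#'   `p_resight_after_failure`.
#' @param geometry output of [make_geometry()].
#' @param start_year first tagging year.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_males = 10L, n_females = 30L,
                       female_pm_fraction = 0.27,
                       trip_scale = 1,
                       strategies = strategy_defaults(),
                       dive = dive_spec(),
                       argos = list(rate_per_h = 1.2,
                                    class_probs = c("3" = 0.08, "2" = 0.15, "1" = 0.20,
                                                    "0" = 0.18, "A" = 0.20, "B" = 0.19),
                                    error_sd_km = argos_error_sd_default(),
                                    outlier_rate = 0.02,
                                    outlier_km = c(80, 300)),
                       fate = list(male   = c(p_death = 17 / 39, p_failure = 8 / 39,
                                              p_resight_after_failure = 0.5),
                                   female = c(p_death = 22 / 178, p_failure = 24 / 178,
                                              p_resight_after_failure = 0.5)),
                       geometry = make_geometry(),
                       start_year = 2006L) {
  stopifnot(n_males >= 0, n_females >= 0, n_males + n_females > 0,
            female_pm_fraction >= 0, female_pm_fraction <= 1,
            trip_scale > 0,
            argos$outlier_rate >= 0, argos$outlier_rate <= 1,
            all(argos$error_sd_km >= 0),
            all(unlist(fate) >= 0), all(unlist(fate) <= 1),
            fate$male[["p_death"]] + fate$male[["p_failure"]] <= 1,
            fate$female[["p_death"]] + fate$female[["p_failure"]] <= 1)
  for (s in strategies) {
    stopifnot(abs(sum(s$mix_transit) - 1) < 1e-9, abs(sum(s$mix_ars) - 1) < 1e-9)
  }
  structure(list(seed = as.integer(seed), n_males = as.integer(n_males),
                 n_females = as.integer(n_females),
                 female_pm_fraction = female_pm_fraction, trip_scale = trip_scale,
                 strategies = strategies, dive = dive, argos = argos,
                 fate = fate, geometry = geometry,
                 start_year = as.integer(start_year)),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# movement

# Hourly true path in the colony-centred plane: outbound transit to each
# foraging patch (correlated headings), area-restricted search dwell at
# the patch, then return. Returns one row per hour with behavioural state.
simulate_true_path <- function(strategy, days, geometry) {
  total_h <- max(48L, round(days * 24))
  dest <- c(strategy$dest_km[["x"]] + stats::rnorm(1, 0, strategy$dest_sd_km[1]),
            strategy$dest_km[["y"]] + stats::rnorm(1, 0, strategy$dest_sd_km[2]))
  np <- strategy$n_patches
  # patches strung along the route, the last at the destination
  fr <- if (np == 1) 1 else seq(0.45, 1, length.out = np)
  patches <- cbind(dest[1] * fr, dest[2] * fr)
  jit <- if (is.null(strategy$patch_jitter_km)) 25 else strategy$patch_jitter_km
  patches <- patches + matrix(stats::rnorm(2 * np, 0, jit), ncol = 2)

  leg_len <- sum(sqrt(rowSums(diff(rbind(c(0, 0), patches, c(0, 0)))^2)))
  travel_h <- leg_len / strategy$transit_speed_kmh * 1.15
  if (travel_h > 0.65 * total_h) {           # shrink route to fit trip budget
    sc <- 0.65 * total_h / travel_h
    patches <- patches * sc
    travel_h <- travel_h * sc
  }
  dwell_h <- pmax(6, rep((total_h - travel_h) / np, np))

  x <- y <- numeric(total_h)
  state <- character(total_h)
  pos <- c(0, 0); heading <- NULL
  phase <- "out"; patch_i <- 1; dwell_left <- dwell_h[1]
  for (h in seq_len(total_h)) {
    target <- if (phase == "return") c(0, 0) else patches[patch_i, ]
    if (phase %in% c("out", "return")) {
      bear <- atan2(target[2] - pos[2], target[1] - pos[1])
      heading <- bear + stats::rnorm(1, 0, 0.25)
      sp <- max(0.5, stats::rnorm(1, strategy$transit_speed_kmh, 0.5))
      pos <- pos + sp * c(cos(heading), sin(heading))
      state[h] <- "transit"
      d_t <- sqrt(sum((target - pos)^2))
      if (phase == "out" && d_t < sp) phase <- "forage"
      if (phase == "return" && d_t < sp) {
        x[h] <- pos[1]; y[h] <- pos[2]
        x <- x[1:h]; y <- y[1:h]; state <- state[1:h]
        break
      }
    } else {                                  # area-restricted search
      heading <- stats::runif(1, 0, 2 * pi)
      sp <- abs(stats::rnorm(1, strategy$ars_speed_kmh, 0.2))
      pos <- pos + sp * c(cos(heading), sin(heading))
      state[h] <- "ars"
      dwell_left <- dwell_left - 1
      if (dwell_left <= 0) {
        if (patch_i < nrow(patches)) {
          patch_i <- patch_i + 1; dwell_left <- dwell_h[patch_i]; phase <- "out"
        } else phase <- "return"
      }
    }
    x[h] <- pos[1]; y[h] <- pos[2]
  }
  n <- length(x)
  ll <- unproject_aeqd(x, y, geometry$colony)
  data.frame(hour = seq_len(n), x = x, y = y,
             lon = ll[, "lon"], lat = ll[, "lat"], state = state,
             seafloor_m = seafloor_depth(geometry, x))
}

# ARGOS sampling of a true path: Poisson fix times, class-dependent
# Gaussian error, occasional large outliers; the alternate (mirror)
# position carries ordinary class error so filter substitution has
# something sensible to fall back on.
simulate_argos <- function(path, start_time, argos, geometry) {
  total_h <- nrow(path)
  gaps <- stats::rexp(ceiling(total_h * argos$rate_per_h * 1.6), argos$rate_per_h)
  t_h <- cumsum(gaps)
  t_h <- t_h[t_h < total_h - 1]
  if (length(t_h) < 4) t_h <- seq(0.5, total_h - 1, length.out = 4)
  tx <- stats::approx(path$hour, path$x, xout = t_h + 1)$y
  ty <- stats::approx(path$hour, path$y, xout = t_h + 1)$y
  lc <- sample(ARGOS_CLASSES, length(t_h), replace = TRUE, prob = argos$class_probs)
  sd <- argos$error_sd_km[lc]
  ex <- tx + stats::rnorm(length(t_h), 0, sd)
  ey <- ty + stats::rnorm(length(t_h), 0, sd)
  ax <- tx + stats::rnorm(length(t_h), 0, sd)
  ay <- ty + stats::rnorm(length(t_h), 0, sd)
  out <- stats::runif(length(t_h)) < argos$outlier_rate
  if (any(out)) {
    r <- stats::runif(sum(out), argos$outlier_km[1], argos$outlier_km[2])
    th <- stats::runif(sum(out), 0, 2 * pi)
    ex[out] <- tx[out] + r * cos(th)
    ey[out] <- ty[out] + r * sin(th)
  }
  ll  <- unproject_aeqd(ex, ey, geometry$colony)
  all <- unproject_aeqd(ax, ay, geometry$colony)
  data.frame(time = start_time + t_h * 3600, lc = lc,
             lon = ll[, "lon"], lat = ll[, "lat"],
             alt_lon = all[, "lon"], alt_lat = all[, "lat"],
             outlier = out)
}

# ---------------------------------------------------------------------------
# dives

# Habitat-conditional archetype: benthic foraging needs a reachable
# bottom, pelagic foraging needs mid-water clearance above the seafloor.
resolve_dive_type <- function(type, seafloor_m, spec) {
  pel_cap <- spec$pelagic$clearance_frac * seafloor_m - spec$pelagic$clearance_m
  if (type == "benthic" && seafloor_m > spec$benthic$max_seafloor_m)
    type <- "pelagic"
  if (type == "pelagic" && pel_cap < spec$pelagic$min_depth_m)
    type <- "benthic"
  type
}

# One noise-free dive profile sampled at dt seconds. Returns depths (m).
dive_profile <- function(type, dt, spec, seafloor_m, night = FALSE) {
  if (type == "transit") {
    depth <- stats::rnorm(1, spec$transit$depth[["mean"]], spec$transit$depth[["sd"]])
    depth <- max(25, min(depth, 0.7 * seafloor_m))
    rate <- max(0.5, stats::rnorm(1, spec$transit$rate_ms[["mean"]],
                                  spec$transit$rate_ms[["sd"]]))
    dur <- 2 * depth / rate
    n <- max(5, round(dur / dt))
    tt <- seq_len(n) / (n + 1)
    # two-slope V: steady descent/ascent with a brief terminal spike, so
    # the apex is touched but under 10% of the dive sits in the deepest
    # fifth of the depth range, even at 8 s sampling
    s <- 1 - abs(2 * tt - 1)
    return(depth * ifelse(s < 0.94, 0.65 * s / 0.94,
                          0.65 + 0.35 * (s - 0.94) / 0.06))
  }
  if (type == "pelagic") {
    depth <- stats::rnorm(1, spec$pelagic$depth[["mean"]], spec$pelagic$depth[["sd"]])
    if (night) depth <- depth - spec$pelagic$diel_offset_m
    cap <- spec$pelagic$clearance_frac * seafloor_m - spec$pelagic$clearance_m
    depth <- max(60, min(depth, cap))
    dur <- max(120, stats::rnorm(1, spec$pelagic$duration_min[["mean"]],
                                 spec$pelagic$duration_min[["sd"]]) * 60)
    bf <- spec$pelagic$bottom_frac
    k <- max(1, round(stats::rnorm(1, spec$pelagic$wiggles[["mean"]],
                                   spec$pelagic$wiggles[["sd"]])))
    amp <- spec$pelagic$wiggle_amp_m
  } else if (type == "benthic") {
    depth <- spec$benthic$depth_frac_of_seafloor * seafloor_m
    dur <- max(120, stats::rnorm(1, spec$benthic$duration_min[["mean"]],
                                 spec$benthic$duration_min[["sd"]]) * 60)
    bf <- spec$benthic$bottom_frac
    k <- max(1, round(stats::rnorm(1, spec$benthic$wiggles[["mean"]],
                                   spec$benthic$wiggles[["sd"]])))
    amp <- spec$benthic$wiggle_amp_m
  } else if (type == "drift") {
    depth <- stats::rnorm(1, spec$drift$depth[["mean"]], spec$drift$depth[["sd"]])
    depth <- max(80, min(depth, 0.75 * seafloor_m))
    dur <- max(240, stats::rnorm(1, spec$drift$duration_min[["mean"]],
                                 spec$drift$duration_min[["sd"]]) * 60)
    fr <- spec$drift$drift_frac
    d0 <- max(0.35 * depth, depth - spec$drift$drift_rate_ms * fr * dur)
    n <- max(8, round(dur / dt))
    tt <- seq_len(n) / (n + 1)
    f1 <- (1 - fr) * 0.55; f2 <- f1 + fr
    d <- numeric(n)
    seg1 <- tt < f1; seg2 <- tt >= f1 & tt <= f2; seg3 <- tt > f2
    d[seg1] <- d0 * tt[seg1] / f1
    d[seg2] <- d0 + (depth - d0) * (tt[seg2] - f1) / fr
    d[seg3] <- depth * (1 - tt[seg3]) / (1 - f2)
    return(d)
  } else stop("unknown dive archetype: ", type)
  # foraging dives (pelagic / benthic): trapezoid with bottom wiggles
  n <- max(10, round(dur / dt))
  tt <- seq_len(n) / (n + 1)
  df <- (1 - bf) / 2
  d <- numeric(n)
  desc <- tt < df; asc <- tt > 1 - df; bot <- !desc & !asc
  d[desc] <- depth * tt[desc] / df
  d[asc]  <- depth * (1 - tt[asc]) / df
  s <- (tt[bot] - df) / bf
  d[bot] <- depth - amp * abs(sin(pi * k * s))
  d
}

#' Simulate a depth time series from an archetype mixture
#'
#' Draws dives from the four-archetype mixture back to back with surfacing
#' intervals until `duration_h` is filled. Ground-truth dive windows and
#' types are returned for recovery testing.
#'
#' @param mix named numeric weights over
#'   `c("transit","pelagic","benthic","drift")`; must sum to 1.
#' @param duration_h record length, hours.
#' @param interval_s sampling interval, seconds (1-8).
#' @param spec [dive_spec()] output.
#' @param seafloor_m seafloor depth below the animal, metres. A vector of
#'   length `duration_h` (one value per hour) or a scalar.
#' @param start_time POSIXct of the first sample (drives diel modulation).
#' @param lon,lat position used for the solar zenith (scalar or per-hour).
#' @param noise_sd depth noise sd (m); overrides `spec$depth_noise_sd`.
#' @return list with `series` (data.frame time, depth_m) and `truth`
#'   (data.frame start, end, type).
#' @export
simulate_dive_series <- function(mix, duration_h, interval_s = 8,
                                 spec = dive_spec(), seafloor_m = 3800,
                                 start_time = as.POSIXct("2010-03-01", tz = "UTC"),
                                 lon = -130, lat = 40, noise_sd = NULL) {
  stopifnot(interval_s >= 1, interval_s <= 8)
  if (abs(sum(mix) - 1) > 1e-8) stop("archetype weights must sum to 1")
  mix <- mix[c("transit", "pelagic", "benthic", "drift")]
  if (anyNA(mix)) stop("mix must name all four archetypes")
  if (is.null(noise_sd)) noise_sd <- spec$depth_noise_sd
  per_hour <- function(h, v) if (length(v) == 1) v else v[min(h, length(v))]

  total_s <- duration_h * 3600
  t_s <- 0
  depths <- list(); truth <- list(); i <- 0
  while (t_s < total_s - 60) {
    h <- floor(t_s / 3600) + 1
    type <- resolve_dive_type(sample(names(mix), 1, prob = mix),
                              per_hour(h, seafloor_m), spec)
    tm <- start_time + t_s
    zen <- solar_zenith(tm, per_hour(h, lat), per_hour(h, lon))
    prof <- dive_profile(type, interval_s, spec, per_hour(h, seafloor_m),
                         night = zen > 90)
    i <- i + 1
    truth[[i]] <- data.frame(start = tm, end = tm + length(prof) * interval_s,
                             type = type)
    surf_s <- max(30, stats::rnorm(1, spec$surface_min[["mean"]] * 60,
                                   spec$surface_min[["sd"]] * 60))
    depths[[i]] <- c(prof, numeric(max(1, round(surf_s / interval_s))))
    t_s <- t_s + (length(depths[[i]])) * interval_s
  }
  d <- unlist(depths)
  tim <- start_time + (seq_along(d) - 1) * interval_s
  if (noise_sd > 0) d <- d + stats::rnorm(length(d), 0, noise_sd)
  if (spec$surface_drift_m_per_day != 0)
    d <- d + spec$surface_drift_m_per_day * as.numeric(tim - start_time) / 86400
  d <- pmax(d, 0)
  truth <- do.call(rbind, truth)
  # relabel: a "pelagic" draw squeezed onto the shelf is what it looks
  # like -- its truth label stays pelagic; classification must cope.
  list(series = data.frame(time = tim, depth_m = d), truth = truth)
}

# ---------------------------------------------------------------------------
# body composition and fates

simulate_body <- function(id, strategy_name, strategy, trip_days, trip,
                          gain_scale = 1) {
  dep_mass <- max(80, stats::rnorm(1, strategy$departure_mass[["mean"]],
                                   strategy$departure_mass[["sd"]]))
  # gains accrue with time at sea, so they shrink with a shortened trip
  gain <- max(2, stats::rnorm(1, strategy$gain[["mean"]] * gain_scale,
                              strategy$gain[["sd"]] * gain_scale))
  days_ashore <- max(0, round(stats::rnorm(1, 3, 1)))
  pup_mass <- if (trip == "post-moult" && grepl("female", strategy_name))
    max(20, stats::rnorm(1, 35, 5)) else 0
  arrival_mass <- dep_mass + gain
  # the onshore correction defines the canonical daily loss recursion
  # (anchored at the census mass); the generator solves for the census
  # mass whose correction recovers the arrival mass exactly
  correction <- if (grepl("female", strategy_name)) {
    function(c) female_onshore_mass_change(c, days_ashore)
  } else {
    # haul-out phase on arrival: moult after the post-breeding trip,
    # breeding after the post-moult trip
    phase <- if (trip == "post-breeding") "moult" else "breeding"
    function(c) male_onshore_mass_change(c, phase, days_ashore)
  }
  m <- arrival_mass - pup_mass
  for (k in 1:25) m <- arrival_mass - pup_mass - correction(m + pup_mass)
  census_mass <- m
  data.frame(id = id, strategy = strategy_name, trip = trip,
             departure_mass_kg = dep_mass, true_gain_kg = gain,
             adipose_frac = strategy$adipose_frac,
             arrival_census_mass_kg = census_mass,
             days_ashore_arrival = days_ashore, pup_mass_kg = pup_mass,
             trip_days = trip_days)
}

lc_rank <- function(lc) match(lc, rev(ARGOS_CLASSES))  # B=1 ... 3=6

# Daily best-location-class record plus resight history for one
# deployment, given its true fate.
simulate_fate_records <- function(fate, trip_days, start_time, class_probs,
                                  p_resight_after_failure) {
  days <- max(10L, round(trip_days))
  stop_day <- if (fate == "survived") days else max(5L, round(stats::runif(1, 0.3, 0.9) * days))
  cls <- sample(ARGOS_CLASSES, stop_day, replace = TRUE, prob = class_probs)
  if (fate == "failure") {
    # progressive degradation towards the worst classes over the final month
    w <- min(30L, stop_day)
    idx <- seq(stop_day - w + 1, stop_day)
    target <- round(seq(6, 1, length.out = w))
    jitter <- pmin(6, pmax(1, target + sample(c(-1, 0, 0, 1), w, replace = TRUE)))
    cls[idx] <- ARGOS_CLASSES[7 - jitter]
  }
  resights <- if (fate == "survived") {
    start_time + (days + rdunif_int(1, 1, 20)) * 86400
  } else if (fate == "failure" && stats::runif(1) < p_resight_after_failure) {
    start_time + (days + rdunif_int(1, 60, 300)) * 86400
  } else as.POSIXct(character(0), tz = "UTC")
  list(transmissions = data.frame(day = seq_len(stop_day),
                                  date = start_time + (seq_len(stop_day) - 1) * 86400,
                                  best_lc = cls),
       resights = resights,
       stop_day = stop_day, trip_days = days)
}

# base R has no integer-uniform sampler under stats::; small shim, kept
# off the public surface
rdunif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Simulate a complete instrumented cohort
#'
#' One deployment per animal: true hourly path with behavioural state,
#' ARGOS fixes with class-dependent error, a depth time series with
#' ground-truth dive types, a body-composition record, and a tag-fate
#' record (transmission-quality series plus resight history). All truth is
#' retained so the processing chain can be validated by recovery.
#'
#' @param config a [sim_config()].
#' @param components which data streams to generate. The true path is
#'   always simulated; dropping `"dives"` (by far the heaviest stream)
#'   gives fast cohorts for demographic checks at large n.
#' @return object of class `seal_cohort`: list with `deployments`,
#'   `argos`, `paths`, `dives`, `body`, `fates`, `geometry`, `config`.
#' @export
simulate_cohort <- function(config,
                            components = c("tracks", "dives", "body", "fates")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_males + config$n_females
  sex <- c(rep("male", config$n_males), rep("female", config$n_females))
  strat <- ifelse(sex == "male", "male",
                  ifelse(stats::runif(n) < config$female_pm_fraction,
                         "female_pm", "female_pb"))
  trip <- ifelse(strat == "female_pm", "post-moult",
                 ifelse(strat == "female_pb", "post-breeding",
                        sample(c("post-breeding", "post-moult"), n, replace = TRUE)))
  year <- config$start_year + rdunif_int(n, 0, 9)
  ids <- sprintf("%s%03d", ifelse(sex == "male", "M", "F"), seq_len(n))

  deployments <- data.frame(id = ids, sex = sex, strategy = strat,
                            trip = trip, year = year)
  argos_all <- vector("list", n); paths <- vector("list", n)
  dives <- vector("list", n); body <- vector("list", n)
  trans <- vector("list", n); resights <- vector("list", n)
  fate_true <- character(n); trip_days_v <- numeric(n)
  starts <- as.POSIXct(rep(NA_real_, n), tz = "UTC", origin = "1970-01-01")

  for (i in seq_len(n)) {
    scfg <- config$strategies[[strat[i]]]
    td <- max(2, stats::rnorm(1, scfg$trip_days[["mean"]], scfg$trip_days[["sd"]])) *
      config$trip_scale
    start <- as.POSIXct(sprintf("%d-%02d-15 06:00:00", year[i],
                                if (trip[i] == "post-breeding") 3L else 6L),
                        tz = "UTC")
    path <- simulate_true_path(scfg, td, config$geometry)
    td_real <- nrow(path) / 24
    ar <- if ("tracks" %in% components)
      simulate_argos(path, start, config$argos, config$geometry) else NULL

    ds <- if ("dives" %in% components) {
      mix_h <- ifelse(path$state == "ars", "ars", "transit")
      # per-hour archetype mixes follow the behavioural state; seafloor
      # and position follow the true path
      simulate_deployment_dives(path, mix_h, scfg, config$dive, start,
                                config$geometry)
    } else NULL

    fate_probs <- config$fate[[sex[i]]]
    u <- stats::runif(1)
    fate_true[i] <- if (u < fate_probs[["p_death"]]) "died"
      else if (u < fate_probs[["p_death"]] + fate_probs[["p_failure"]]) "failure"
      else "survived"
    if ("fates" %in% components) {
      # fate evidence (daily quality records, resights) lives on the
      # nominal trip timeline, independent of any movement down-scaling
      td_nominal <- td_real / config$trip_scale
      fr <- simulate_fate_records(fate_true[i], td_nominal, start,
                                  config$argos$class_probs,
                                  fate_probs[["p_resight_after_failure"]])
      trans[[i]] <- fr$transmissions
      resights[[i]] <- fr$resights
    }

    if (!is.null(ar)) argos_all[[i]] <- cbind(id = ids[i], ar)
    paths[[i]] <- cbind(id = ids[i], path,
                        time = start + (path$hour - 1) * 3600)
    if (!is.null(ds)) dives[[i]] <- ds
    if ("body" %in% components)
      body[[i]] <- simulate_body(ids[i], strat[i], scfg, td_real, trip[i],
                                 gain_scale = config$trip_scale)
    trip_days_v[i] <- td_real
    starts[i] <- start
  }
  deployments$trip_days <- trip_days_v
  deployments$fate_trip_days <- trip_days_v / config$trip_scale
  deployments$start <- starts
  deployments$true_fate <- fate_true
  names(dives) <- ids; names(trans) <- ids; names(resights) <- ids

  structure(list(deployments = deployments,
                 argos = do.call(rbind, argos_all),
                 paths = do.call(rbind, paths),
                 dives = dives,
                 body = do.call(rbind, body),
                 fates = list(transmissions = trans, resights = resights),
                 geometry = config$geometry,
                 config = config),
            class = "seal_cohort")
}

# Per-deployment dive record: hour-by-hour archetype mix follows the
# behavioural state; seafloor and position follow the true path. The
# seafloor under a dive is evaluated at the dive's (estimated) midpoint
# position, the same georeferencing the analysis applies.
simulate_deployment_dives <- function(path, state_kind, scfg, dspec, start,
                                      geometry) {
  n_h <- nrow(path)
  mixes <- list(transit = scfg$mix_transit, ars = scfg$mix_ars)
  # per-strategy pelagic depth overrides the archetype default; a strategy
  # may also override any other archetype parameter
  dspec$pelagic$depth <- scfg$pelagic_depth
  if (!is.null(scfg$dive_overrides))
    dspec <- utils::modifyList(dspec, scfg$dive_overrides)
  # typical dive lengths, used only to centre the seafloor lookup
  mid_s <- c(transit = 230, pelagic = 720, benthic = 600, drift = 600)
  x_at <- function(t_s) stats::approx(path$hour, path$x,
                                      xout = pmin(pmax(t_s / 3600 + 1, 1), n_h),
                                      rule = 2)$y
  total_s <- n_h * 3600
  t_s <- 0; depths <- list(); truth <- list(); i <- 0
  dt <- dspec$sampling_s
  while (t_s < total_s - 120) {
    h <- min(n_h, floor(t_s / 3600) + 1)
    mix <- mixes[[state_kind[h]]]
    type0 <- sample(names(mix), 1, prob = mix)
    sf <- seafloor_depth(geometry, x_at(t_s + mid_s[[type0]]))
    type <- resolve_dive_type(type0, sf, dspec)
    if (type != type0) sf <- seafloor_depth(geometry, x_at(t_s + mid_s[[type]]))
    tm <- start + t_s
    zen <- solar_zenith(tm, path$lat[h], path$lon[h])
    prof <- dive_profile(type, dt, dspec, sf, night = zen > 90)
    i <- i + 1
    truth[[i]] <- data.frame(start = tm, end = tm + length(prof) * dt, type = type)
    surf_s <- max(30, stats::rnorm(1, dspec$surface_min[["mean"]] * 60,
                                   dspec$surface_min[["sd"]] * 60))
    depths[[i]] <- c(prof, numeric(max(1, round(surf_s / dt))))
    t_s <- t_s + length(depths[[i]]) * dt
  }
  d <- unlist(depths)
  tim <- start + (seq_along(d) - 1) * dt
  if (dspec$depth_noise_sd > 0) d <- d + stats::rnorm(length(d), 0, dspec$depth_noise_sd)
  if (dspec$surface_drift_m_per_day != 0)
    d <- d + dspec$surface_drift_m_per_day * as.numeric(tim - start) / 86400
  list(series = data.frame(time = tim, depth_m = pmax(d, 0)),
       truth = do.call(rbind, truth))
}

# ---------------------------------------------------------------------------
# fixed cohort fixture

#' Specification for the fixed tag-fate cohort fixture
#'
#' Per-sex deployment counts with the number of tags that stopped at sea,
#' split into mechanical failures and deaths. Defaults encode a 217-tag
#' cohort: 39 males (25 stopped = 8 failures + 17 deaths) and 178 females
#' (46 stopped = 24 failures + 22 deaths).
#'
#' @param males,females named integer vectors with elements `deployments`,
#'   `stopped`, `failures`, `deaths`.
#' @return object of class `cohort_fixture_spec`.
#' @export
cohort_fixture_spec <- function(males = c(deployments = 39, stopped = 25,
                                          failures = 8, deaths = 17),
                                females = c(deployments = 178, stopped = 46,
                                            failures = 24, deaths = 22)) {
  for (v in list(males, females)) {
    stopifnot(v[["failures"]] + v[["deaths"]] == v[["stopped"]],
              v[["stopped"]] <= v[["deployments"]])
  }
  structure(list(males = males, females = females), class = "cohort_fixture_spec")
}

#' Build the deterministic tag-fate cohort fixture
#'
#' Constructs per-deployment transmission-quality series and resight
#' histories such that [attribute_tag_fate()] reproduces the spec counts
#' exactly: survivors transmit to trip end and are resighted; failures
#' stop at sea with a monotone class degradation over the final month;
#' deaths stop at sea with a trend-free repeating class pattern and no
#' resight. Fully deterministic (no RNG).
#'
#' @param spec a [cohort_fixture_spec()].
#' @return list with `table` (id, sex, trip, year, true_fate, trip_days),
#'   `transmissions` and `resights` named per deployment.
#' @export
make_cohort_fixture <- function(spec = cohort_fixture_spec()) {
  stopifnot(inherits(spec, "cohort_fixture_spec"))
  start <- as.POSIXct("2010-03-15 00:00:00", tz = "UTC")
  build_sex <- function(sx, v, trip_days) {
    n <- v[["deployments"]]
    fate <- c(rep("died", v[["deaths"]]), rep("failure", v[["failures"]]),
              rep("survived", n - v[["stopped"]]))
    ids <- sprintf("%s%03d", toupper(substr(sx, 1, 1)), seq_len(n))
    trans <- vector("list", n); res <- vector("list", n)
    for (i in seq_len(n)) {
      stop_day <- if (fate[i] == "survived") trip_days else
        40 + (i %% 25)                      # spread stop days, deterministic
      base <- ARGOS_CLASSES[((seq_len(stop_day) * 5 + i) %% 6) + 1]  # trend-free
      if (fate[i] == "failure") {
        w <- min(30, stop_day)
        idx <- seq(stop_day - w + 1, stop_day)
        base[idx] <- ARGOS_CLASSES[7 - round(seq(6, 1, length.out = w))]
      }
      trans[[i]] <- data.frame(day = seq_len(stop_day),
                               date = start + (seq_len(stop_day) - 1) * 86400,
                               best_lc = base)
      res[[i]] <- if (fate[i] == "survived")
        start + (trip_days + 5) * 86400 else as.POSIXct(character(0), tz = "UTC")
    }
    names(trans) <- ids; names(res) <- ids
    list(table = data.frame(id = ids, sex = sx,
                            trip = rep(c("post-breeding", "post-moult"),
                                       length.out = n),
                            year = 2006 + (seq_len(n) %% 10),
                            true_fate = fate, trip_days = trip_days),
         transmissions = trans, resights = res)
  }
  m <- build_sex("male", spec$males, trip_days = 126)
  f <- build_sex("female", spec$females, trip_days = 76)
  list(table = rbind(m$table, f$table),
       transmissions = c(m$transmissions, f$transmissions),
       resights = c(m$resights, f$resights),
       start = start)
}
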