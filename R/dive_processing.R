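# Dive detection and classification from TDR depth series: subsampling,
# zero-offset correction, dive segmentation with duration/depth retention
# rules, per-dive metrics (bottom phase, efficiency, vertical excursions),
# a four-type hierarchical classifier, diel assignment from the solar
# zenith, and georeferencing against the smoothed track.

#' Dive detection parameters
#'
#' Dives are excursions below `surface_threshold_m`, retained only when
#' they exceed `min_duration_s` in duration and `min_depth_m` in depth.
#'
#' @param subsample_s target sampling interval (s).
#' @param min_duration_s,min_depth_m retention thresholds (32 s, 15 m).
#' @param surface_threshold_m depth below which the animal is submerged.
#' @param zero_offset_window_h window for the rolling zero-offset
#'   correction.
#' @return list of class `dive_detection_params`.
#' @export
dive_detection_params <- function(subsample_s = 8, min_duration_s = 32,
                                  min_depth_m = 15, surface_threshold_m = 2,
                                  zero_offset_window_h = 2) {
  stopifnot(min_duration_s > subsample_s, min_depth_m > 0,
            surface_threshold_m > 0, zero_offset_window_h > 0)
  structure(list(subsample_s = subsample_s, min_duration_s = min_duration_s,
                 min_depth_m = min_depth_m,
                 surface_threshold_m = surface_threshold_m,
                 zero_offset_window_h = zero_offset_window_h),
            class = "dive_detection_params")
}

#' Dive classifier parameters
#'
#' @param bottom_frac bottom phase = samples deeper than this fraction of
#'   max depth (0.80).
#' @param wiggle_amp_m minimum amplitude of a counted vertical excursion.
#' @param benthic_tol benthic when |max depth - seafloor| is within this
#'   fraction of seafloor depth.
#' @param drift_min_frac,drift_max_rate_ms a drift dive contains a
#'   contiguous monotone segment of at least this fraction of the dive at
#'   a vertical rate no faster than this.
#' @param drift_min_s the drift segment must also last at least this many
#'   seconds; passive drifts run for minutes, and the floor keeps short
#'   shallow V-dives from qualifying.
#' @param transit_max_bottom_frac dives with a bottom fraction below this
#'   and no excursions are transit V-dives.
#' @param smooth_window_s running-mean window applied before vertical-rate
#'   computations, to keep the drift test robust to sensor noise.
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(bottom_frac = 0.80, wiggle_amp_m = 5,
                              benthic_tol = 0.10, drift_min_frac = 0.4,
                              drift_max_rate_ms = 0.4, drift_min_s = 300,
                              transit_max_bottom_frac = 0.15,
                              smooth_window_s = 40) {
  stopifnot(bottom_frac > 0, bottom_frac < 1, wiggle_amp_m > 0,
            benthic_tol > 0, benthic_tol < 1,
            drift_min_frac > 0, drift_min_frac < 1, drift_max_rate_ms > 0,
            drift_min_s > 0,
            transit_max_bottom_frac > 0, transit_max_bottom_frac < 1)
  structure(list(bottom_frac = bottom_frac, wiggle_amp_m = wiggle_amp_m,
                 benthic_tol = benthic_tol, drift_min_frac = drift_min_frac,
                 drift_max_rate_ms = drift_max_rate_ms,
                 drift_min_s = drift_min_s,
                 transit_max_bottom_frac = transit_max_bottom_frac,
                 smooth_window_s = smooth_window_s),
            class = "classifier_params")
}

#' Subsample a depth series to a coarser interval
#'
#' Keeps every k-th sample; the source interval must divide the target.
#'
#' @param series data.frame `time`, `depth_m` at a regular interval.
#' @param target_s target interval in seconds.
#' @return the subsampled series.
#' @export
subsample_depth <- function(series, target_s = 8) {
  dt <- stats::median(diff(as.numeric(series$time)))
  if (abs(dt - target_s) < 1e-9) return(series)
  k <- target_s / dt
  if (abs(k - round(k)) > 1e-6)
    stop("source interval (", dt, " s) does not divide target (", target_s, " s)")
  series[seq(1, nrow(series), by = round(k)), , drop = FALSE]
}

#' Rolling zero-offset correction
#'
#' Pressure transducers drift slowly, shifting the apparent surface away
#' from zero and corrupting the 15 m retention rule. The correction
#' estimates the surface reading as a low quantile of depth within a
#' rolling window and subtracts it.
#'
#' @param series data.frame `time`, `depth_m`.
#' @param window_h window length in hours.
#' @param prob quantile treated as the surface (default 0.02).
#' @return the corrected series (depths clamped at >= 0).
#' @export
zero_offset_correct <- function(series, window_h = 2, prob = 0.02) {
  d <- series$depth_m
  t_s <- as.numeric(series$time) - as.numeric(series$time[1])
  wins <- floor(t_s / (window_h * 3600))
  offs <- tapply(d, wins, stats::quantile, probs = prob, names = FALSE)
  centre <- (as.numeric(names(offs)) + 0.5) * window_h * 3600
  off <- if (length(offs) == 1) rep(offs, length(d))
         else stats::approx(centre, offs, xout = t_s, rule = 2)$y
  series$depth_m <- pmax(d - off, 0)
  series
}

#' Detect dives in a depth series
#'
#' A dive is a maximal run of samples below the surface threshold; it is
#' retained only when it exceeds the duration and depth thresholds. The
#' post-dive interval is the surface time from each dive's end to the next
#' dive's start.
#'
#' @param series data.frame `time`, `depth_m` (regular sampling).
#' @param params a [dive_detection_params()].
#' @return data.frame, one row per retained dive: `start`, `end`,
#'   `i_start`, `i_end`, `max_depth_m`, `duration_min`,
#'   `postdive_interval_min` (NA for the last dive).
#' @export
detect_dives <- function(series, params = dive_detection_params()) {
  stopifnot(all(is.finite(series$depth_m)), !is.unsorted(as.numeric(series$time)))
  sub <- series$depth_m > params$surface_threshold_m
  if (!any(sub)) return(empty_dive_table())
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(i_start = starts[r$values], i_end = ends[r$values])
  dt <- stats::median(diff(as.numeric(series$time)))
  seg$duration_s <- (seg$i_end - seg$i_start + 1) * dt
  seg$max_depth_m <- vapply(seq_len(nrow(seg)), function(i)
    max(series$depth_m[seg$i_start[i]:seg$i_end[i]]), numeric(1))
  seg <- seg[seg$duration_s > params$min_duration_s &
             seg$max_depth_m > params$min_depth_m, , drop = FALSE]
  if (nrow(seg) == 0) return(empty_dive_table())
  seg$start <- series$time[seg$i_start]
  seg$end <- series$time[seg$i_end]
  seg$duration_min <- seg$duration_s / 60
  nd <- nrow(seg)
  seg$postdive_interval_min <-
    c(as.numeric(seg$start[-1]) - as.numeric(seg$end[-nd]), NA) / 60
  seg[, c("start", "end", "i_start", "i_end", "max_depth_m",
          "duration_min", "postdive_interval_min")]
}

empty_dive_table <- function() {
  data.frame(start = as.POSIXct(character(0), tz = "UTC"),
             end = as.POSIXct(character(0), tz = "UTC"),
             i_start = integer(0), i_end = integer(0),
             max_depth_m = numeric(0), duration_min = numeric(0),
             postdive_interval_min = numeric(0))
}

#' Count vertical excursions (wiggles) in a depth trace
#'
#' Prunes the local-extrema sequence until every remaining reversal has
#' amplitude at least `amp_m`, then counts the shallow-ward reversals
#' (local depth minima) strictly inside the trace. Each counted excursion
#' is one rise-and-return of at least the threshold amplitude, the
#' standard prey-capture-attempt proxy.
#'
#' @param depth numeric depth vector (m, positive down).
#' @param amp_m amplitude threshold (m).
#' @return integer count.
#' @export
count_excursions <- function(depth, amp_m = 5) {
  pts <- to_extrema(depth)
  repeat {
    if (length(pts) < 3) break
    amps <- abs(diff(pts))
    j <- which.min(amps)
    if (amps[j] >= amp_m) break
    if (j == 1) pts <- pts[-1]
    else if (j == length(amps)) pts <- pts[-length(pts)]
    else pts <- pts[-c(j, j + 1)]     # drop an interior reversal pair
    pts <- to_extrema(pts)
  }
  if (length(pts) < 3) return(0L)
  inner <- 2:(length(pts) - 1)
  sum(pts[inner] < pts[inner - 1] & pts[inner] < pts[inner + 1])
}

# collapse a numeric trace to its alternating local extrema (endpoints kept)
to_extrema <- function(x) {
  x <- x[c(TRUE, diff(x) != 0)]
  if (length(x) < 3) return(x)
  s <- sign(diff(x))
  keep <- c(TRUE, s[-length(s)] != s[-1], TRUE)
  x[keep]
}

#' Per-dive metrics
#'
#' Bottom phase = samples between the first and last crossing of
#' `bottom_frac * max depth`; bottom time is its span, efficiency is
#' bottom time over duration, and excursions are counted within the
#' bottom phase.
#'
#' @param series full depth series the dive indices refer to.
#' @param dive one row of [detect_dives()] output.
#' @param params a [classifier_params()].
#' @return the row with `bottom_time_min`, `efficiency`, `n_excursions`
#'   columns added.
#' @export
dive_metrics <- function(series, dive, params = classifier_params()) {
  idx <- dive$i_start:dive$i_end
  d <- series$depth_m[idx]
  dt <- stats::median(diff(as.numeric(series$time)))
  thr <- params$bottom_frac * dive$max_depth_m
  deep <- which(d >= thr)
  if (length(deep) == 0) {
    bt <- 0; nx <- 0L
  } else {
    span <- deep[1]:deep[length(deep)]
    bt <- length(span) * dt / 60
    nx <- count_excursions(d[span], params$wiggle_amp_m)
  }
  bt <- min(bt, dive$duration_min)
  dive$bottom_time_min <- bt
  dive$efficiency <- bt / dive$duration_min
  dive$n_excursions <- nx
  dive
}

running_mean <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  stats::filter(x, rep(1 / k, k), sides = 2) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; as.numeric(y) })()
}

#' Classify a dive into one of four types
#'
#' Hierarchical rules, evaluated in order:
#' 1. *drift*: a contiguous segment covering at least `drift_min_frac` of
#'    the dive with a monotone-signed vertical rate no faster than
#'    `drift_max_rate_ms` (rates from a noise-smoothed trace);
#' 2. *benthic foraging*: max depth within `benthic_tol` of the seafloor
#'    and a bottom fraction of at least `transit_max_bottom_frac`;
#' 3. *pelagic foraging*: at least one bottom excursion and a bottom
#'    fraction of at least `transit_max_bottom_frac`;
#' 4. otherwise *transit*.
#'
#' @param series full depth series.
#' @param dive a row from [dive_metrics()].
#' @param seafloor_m seafloor depth at the dive location (NA skips the
#'   benthic test).
#' @param params a [classifier_params()].
#' @return one of `"drift"`, `"benthic"`, `"pelagic"`, `"transit"`.
#' @export
classify_dive <- function(series, dive, seafloor_m = NA,
                          params = classifier_params()) {
  idx <- dive$i_start:dive$i_end
  d <- series$depth_m[idx]
  dt <- stats::median(diff(as.numeric(series$time)))
  k <- max(1L, round(params$smooth_window_s / dt))
  ds <- running_mean(d, k)
  rate <- diff(ds) / dt
  n <- length(rate)
  if (n >= 4) {
    slow <- abs(rate) <= params$drift_max_rate_ms
    sgn <- sign(rate)
    # longest run that is slow with one consistent sign
    best <- 0; cur <- 0; cur_sign <- 0
    for (i in seq_len(n)) {
      if (slow[i] && sgn[i] != 0 && (cur == 0 || sgn[i] == cur_sign)) {
        if (cur == 0) cur_sign <- sgn[i]
        cur <- cur + 1
      } else {
        best <- max(best, cur)
        cur <- if (slow[i] && sgn[i] != 0) 1 else 0
        cur_sign <- sgn[i]
      }
    }
    best <- max(best, cur)
    if (best / n >= params$drift_min_frac &&
        best * dt >= params$drift_min_s) return("drift")
  }
  bottom_frac_obs <- dive$bottom_time_min / dive$duration_min
  if (!is.na(seafloor_m) &&
      abs(dive$max_depth_m - seafloor_m) <= params$benthic_tol * seafloor_m &&
      bottom_frac_obs >= params$transit_max_bottom_frac) return("benthic")
  if (dive$n_excursions >= 1 &&
      bottom_frac_obs >= params$transit_max_bottom_frac) return("pelagic")
  "transit"
}

#' Assign day or night from the solar zenith angle
#'
#' Evaluated at the dive midpoint. Zenith at or below `day_zenith_deg`
#' means day. The default 90 is the geometric horizon; 96 gives a
#' civil-twilight definition.
#'
#' @param dive a dive row with `start`, `end`, `lat`, `lon`.
#' @param day_zenith_deg day/night cut (degrees).
#' @return `"day"` or `"night"`.
#' @export
assign_diel <- function(dive, day_zenith_deg = 90) {
  if (is.na(dive$lat) || is.na(dive$lon)) stop("dive has no position")
  mid <- dive$start + (as.numeric(dive$end) - as.numeric(dive$start)) / 2
  z <- solar_zenith(mid, dive$lat, dive$lon)
  if (z <= day_zenith_deg) "day" else "night"
}

#' Georeference dives against the hourly track
#'
#' Positions are linearly interpolated in time between the bracketing
#' hourly positions at each dive midpoint. Dives outside the track span
#' get NA coordinates and `placed = FALSE`.
#'
#' @param dives dive table with `start`, `end`.
#' @param track hourly track with `time`, `lon`, `lat`.
#' @return dives with `lon`, `lat`, `placed` columns.
#' @export
georeference_dives <- function(dives, track) {
  tt <- as.numeric(track$time)
  mid <- as.numeric(dives$start) +
    (as.numeric(dives$end) - as.numeric(dives$start)) / 2
  inside <- mid >= tt[1] & mid <= tt[length(tt)]
  dives$lon <- dives$lat <- NA_real_
  if (any(inside)) {
    dives$lon[inside] <- stats::approx(tt, track$lon, xout = mid[inside])$y
    dives$lat[inside] <- stats::approx(tt, track$lat, xout = mid[inside])$y
  }
  dives$placed <- inside
  dives
}

#' Run the full dive-processing chain for one deployment
#'
#' Subsamples to 8 s, applies zero-offset correction, detects dives,
#' computes metrics, georeferences against the track, classifies each
#' dive with the local seafloor depth and assigns day/night.
#'
#' @param series depth series data.frame `time`, `depth_m`.
#' @param track hourly track (may be NULL: dives stay unplaced and the
#'   benthic test is skipped).
#' @param geometry study geometry from [make_geometry()] used to look up
#'   seafloor depth (may be NULL).
#' @param det [dive_detection_params()].
#' @param cls [classifier_params()].
#' @param day_zenith_deg diel cut, degrees.
#' @return dive table with metrics, `type`, `diel`, positions.
#' @export
process_dives <- function(series, track = NULL, geometry = NULL,
                          det = dive_detection_params(),
                          cls = classifier_params(), day_zenith_deg = 90) {
  series <- subsample_depth(series, det$subsample_s)
  series <- zero_offset_correct(series, det$zero_offset_window_h)
  dives <- detect_dives(series, det)
  if (nrow(dives) == 0) {
    dives$type <- character(0); dives$diel <- character(0)
    dives$lon <- numeric(0); dives$lat <- numeric(0)
    dives$seafloor_m <- numeric(0)
    return(dives)
  }
  dives <- do.call(rbind, lapply(seq_len(nrow(dives)), function(i)
    dive_metrics(series, dives[i, ], cls)))
  if (!is.null(track)) {
    dives <- georeference_dives(dives, track)
  } else {
    dives$lon <- NA_real_; dives$lat <- NA_real_; dives$placed <- FALSE
  }
  dives$seafloor_m <- NA_real_
  if (!is.null(geometry) && any(dives$placed)) {
    xy <- project_aeqd(dives$lon[dives$placed], dives$lat[dives$placed],
                       geometry$colony)
    dives$seafloor_m[dives$placed] <- seafloor_depth(geometry, xy[, "x"])
  }
  dives$type <- vapply(seq_len(nrow(dives)), function(i)
    classify_dive(series, dives[i, ], dives$seafloor_m[i], cls), character(1))
  dives$diel <- NA_character_
  ok <- dives$placed
  dives$diel[ok] <- vapply(which(ok), function(i)
    assign_diel(dives[i, ], day_zenith_deg), character(1))
  dives
}
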