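# From raw ARGOS fixes to trip-truncated, outlier-filtered tracks and
# smoothed hourly positions. The smoother is a continuous-time correlated
# random walk (integrated Ornstein-Uhlenbeck velocity) Kalman
# filter/smoother fitted by maximum likelihood in a colony-centred planar
# projection, with class-dependent measurement error.

#' Speed-distance-angle filter parameters
#'
#' @param max_speed_kmh maximum plausible sustained speed (default 12).
#' @param min_angle_deg minimum inner turning angle; fixes forming a
#'   sharper spike than this are suspect (default 160).
#' @param use_alternate replace a rejected fix with its ARGOS mirror
#'   position when the mirror satisfies the criteria.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(max_speed_kmh = 12, min_angle_deg = 160,
                          use_alternate = TRUE) {
  stopifnot(max_speed_kmh > 0, min_angle_deg > 0, min_angle_deg <= 180)
  structure(list(max_speed_kmh = max_speed_kmh, min_angle_deg = min_angle_deg,
                 use_alternate = use_alternate), class = "filter_params")
}

#' Truncate a deployment's fixes to the at-sea trip window
#'
#' @param fixes data.frame with a POSIXct `time` column.
#' @param departure,arrival POSIXct trip bounds.
#' @return fixes with `departure <= time <= arrival`, original order.
#' @export
truncate_trip <- function(fixes, departure, arrival) {
  stopifnot(departure < arrival)
  out <- fixes[fixes$time >= departure & fixes$time <= arrival, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no fixes inside the trip window; malformed deployment")
  out
}

# speeds (km/h) between consecutive fixes
fix_speeds <- function(fixes) {
  d <- gc_step_km(fixes$lon, fixes$lat)
  dt <- diff(as.numeric(fixes$time)) / 3600
  d / pmax(dt, 1e-6)
}

#' Speed-distance-angle filter for ARGOS fixes
#'
#' Iteratively removes implausible fixes from one deployment. A fix is
#' removed when the implied great-circle speed to both neighbours exceeds
#' `max_speed_kmh`, or when it forms a spike: inner turning angle below
#' `min_angle_deg` with both adjacent displacements exceeding what the
#' animal can cover at the maximum speed. Before removal the ARGOS
#' alternate (mirror) position is substituted if it satisfies the
#' criteria. A final forward pass guarantees that no retained consecutive
#' pair implies a speed above the threshold.
#'
#' @param fixes data.frame: `time`, `lon`, `lat`, optionally `alt_lon`,
#'   `alt_lat`.
#' @param params a [filter_params()].
#' @return the retained (possibly substituted) fixes.
#' @export
sda_filter <- function(fixes, params = filter_params()) {
  if (nrow(fixes) < 3) stop("sda_filter needs at least 3 fixes")
  fixes <- fixes[order(fixes$time), , drop = FALSE]
  has_alt <- all(c("alt_lon", "alt_lat") %in% names(fixes)) && params$use_alternate
  vmax <- params$max_speed_kmh

  ok_at <- function(fx, i, lon, lat) {
    # would (lon, lat) at row i satisfy both criteria against neighbours?
    lo <- fx$lon; la <- fx$lat
    lo[i] <- lon; la[i] <- lat
    idx <- max(1, i - 1):min(nrow(fx), i + 1)
    sp <- gc_step_km(lo[idx], la[idx]) /
      pmax(diff(as.numeric(fx$time[idx])) / 3600, 1e-6)
    all(sp <= vmax)
  }

  repeat {
    n <- nrow(fixes)
    if (n < 3) break
    sp <- fix_speeds(fixes)                       # length n-1
    ang <- turning_angle_deg(fixes$lon, fixes$lat) # length n-2, at 2..n-1
    sp_prev <- sp[1:(n - 2)]; sp_next <- sp[2:(n - 1)]
    both_fast <- sp_prev > vmax & sp_next > vmax
    spike <- ang < params$min_angle_deg & both_fast
    bad <- which(both_fast | spike) + 1           # interior indices
    if (length(bad) == 0) break
    drop <- logical(n)
    for (i in bad) {
      if (has_alt && !is.na(fixes$alt_lon[i]) &&
          ok_at(fixes, i, fixes$alt_lon[i], fixes$alt_lat[i])) {
        fixes$lon[i] <- fixes$alt_lon[i]
        fixes$lat[i] <- fixes$alt_lat[i]
      } else drop[i] <- TRUE
    }
    if (!any(drop)) break
    fixes <- fixes[!drop, , drop = FALSE]
  }

  # forward pass: drop anything unreachable at vmax from the last kept fix
  keep <- rep(TRUE, nrow(fixes))
  last <- 1
  for (i in 2:nrow(fixes)) {
    d <- geosphere::distHaversine(c(fixes$lon[last], fixes$lat[last]),
                                  c(fixes$lon[i], fixes$lat[i])) / 1000
    dt <- (as.numeric(fixes$time[i]) - as.numeric(fixes$time[last])) / 3600
    if (d / max(dt, 1e-6) > vmax) keep[i] <- FALSE else last <- i
  }
  fixes[keep, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# CTCRW Kalman machinery. State per axis: (position, velocity); the
# velocity is Ornstein-Uhlenbeck with reversion beta (1/h) and diffusion
# sigma, integrated into position (Johnson et al.-style discretization).

ctcrw_mats <- function(dt, beta, sigma) {
  eb <- exp(-beta * dt)
  A <- matrix(c(1, 0, (1 - eb) / beta, eb), 2, 2)
  s2 <- sigma^2
  q_vv <- s2 / (2 * beta) * (1 - eb^2)
  q_xv <- s2 / (2 * beta^2) * (1 - 2 * eb + eb^2)
  q_xx <- s2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
  Q <- matrix(c(q_xx, q_xv, q_xv, q_vv), 2, 2)
  list(A = A, Q = Q)
}

# Kalman filter over irregular times; obs is n x 2 (x, y) with NA rows for
# prediction-only times; tau is the per-time measurement sd (km).
ctcrw_filter <- function(times_h, obs, tau, beta, sigma, smooth = FALSE) {
  n <- length(times_h)
  # independent x/y axes share parameters: run one 4-state filter as two
  # 2-state filters stacked
  m <- matrix(0, n, 4)          # filtered means (x, vx, y, vy)
  P <- array(0, c(n, 4, 4))
  mp <- matrix(0, n, 4); Pp <- array(0, c(n, 4, 4))
  first <- which(!is.na(obs[, 1]))[1]
  vstat <- sigma^2 / (2 * beta)
  mcur <- c(obs[first, 1], 0, obs[first, 2], 0)
  Pcur <- diag(c(tau[first]^2 + 1, vstat, tau[first]^2 + 1, vstat))
  ll <- 0
  for (k in seq_len(n)) {
    if (k > 1) {
      dt <- times_h[k] - times_h[k - 1]
      mats <- ctcrw_mats(max(dt, 1e-6), beta, sigma)
      A4 <- matrix(0, 4, 4); Q4 <- matrix(0, 4, 4)
      A4[1:2, 1:2] <- mats$A; A4[3:4, 3:4] <- mats$A
      Q4[1:2, 1:2] <- mats$Q; Q4[3:4, 3:4] <- mats$Q
      mcur <- drop(A4 %*% mcur)
      Pcur <- A4 %*% Pcur %*% t(A4) + Q4
    }
    mp[k, ] <- mcur; Pp[k, , ] <- Pcur
    if (!is.na(obs[k, 1]) && k >= first) {
      H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 3] <- 1
      R <- diag(rep(tau[k]^2, 2))
      S <- H %*% Pcur %*% t(H) + R
      v <- obs[k, ] - drop(H %*% mcur)
      Sc <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(Sc)) return(list(ll = -Inf))
      ll <- ll - sum(log(diag(Sc))) - 0.5 * sum(backsolve(Sc, v, transpose = TRUE)^2) -
        log(2 * pi)
      K <- Pcur %*% t(H) %*% chol2inv(Sc)
      mcur <- mcur + drop(K %*% v)
      Pcur <- (diag(4) - K %*% H) %*% Pcur
    }
    m[k, ] <- mcur; P[k, , ] <- Pcur
  }
  out <- list(ll = ll, m = m, P = P)
  if (smooth) {
    ms <- m; Ps <- P
    for (k in (n - 1):1) {
      dt <- times_h[k + 1] - times_h[k]
      mats <- ctcrw_mats(max(dt, 1e-6), beta, sigma)
      A4 <- matrix(0, 4, 4)
      A4[1:2, 1:2] <- mats$A; A4[3:4, 3:4] <- mats$A
      Ppk <- Pp[k + 1, , ]
      G <- P[k, , ] %*% t(A4) %*% tryCatch(solve(Ppk), error = function(e) MASS::ginv(Ppk))
      ms[k, ] <- m[k, ] + drop(G %*% (ms[k + 1, ] - mp[k + 1, ]))
      Ps[k, , ] <- P[k, , ] + G %*% (Ps[k + 1, , ] - Ppk) %*% t(G)
    }
    out$ms <- ms; out$Ps <- Ps
  }
  out
}

#' Smooth a filtered track to hourly positions
#'
#' Fits a continuous-time correlated random walk (integrated OU velocity)
#' by maximum likelihood via the Kalman filter in an azimuthal equidistant
#' plane centred on `origin`, then smooths (RTS) and predicts positions on
#' the hour with a positional standard deviation. Measurement error is set
#' per ARGOS location class. Falls back to piecewise-linear interpolation
#' with a warning when the likelihood fit fails.
#'
#' @param fixes filtered fixes: `time`, `lon`, `lat`, `lc`.
#' @param origin projection centre `c(lon, lat)` (the colony).
#' @param error_sd_km named per-class measurement sd; a single number
#'   applies to all classes.
#' @param step_h prediction step in hours.
#' @return data.frame of class `hourly_track`: `time`, `lon`, `lat`,
#'   `sd_km`, `speed_kmh` (speed to the next position; last row repeats
#'   the preceding value).
#' @export
smooth_track <- function(fixes, origin, error_sd_km = argos_error_sd_default(),
                         step_h = 1) {
  if (nrow(fixes) < 2) stop("smoothing needs at least 2 fixes")
  fixes <- fixes[order(fixes$time), , drop = FALSE]
  t0 <- as.numeric(fixes$time[1])
  th_obs <- (as.numeric(fixes$time) - t0) / 3600
  if (max(th_obs) < 2) stop("fixes must span at least 2 hours")
  # collapse duplicate timestamps
  keep <- c(TRUE, diff(th_obs) > 1e-9)
  fixes <- fixes[keep, , drop = FALSE]; th_obs <- th_obs[keep]

  xy <- project_aeqd(fixes$lon, fixes$lat, origin)
  tau_obs <- if (length(error_sd_km) == 1) rep(error_sd_km, nrow(fixes))
             else unname(error_sd_km[as.character(fixes$lc)])
  tau_obs[is.na(tau_obs)] <- max(error_sd_km)
  tau_obs <- pmax(tau_obs, 1e-6)

  grid <- seq(ceiling(th_obs[1]), floor(th_obs[length(th_obs)]), by = step_h)
  if (length(grid) < 2) stop("track too short for an hourly grid")
  times_all <- sort(unique(c(th_obs, grid)))
  oi <- match(th_obs, times_all)
  obs <- matrix(NA_real_, length(times_all), 2)
  obs[oi, ] <- xy
  tau <- rep(1, length(times_all)); tau[oi] <- tau_obs

  nll <- function(par) {
    f <- ctcrw_filter(times_all, obs, tau, exp(par[1]), exp(par[2]))
    if (!is.finite(f$ll)) 1e10 else -f$ll
  }
  fit <- tryCatch(
    stats::optim(c(log(0.5), log(3)), nll, method = "L-BFGS-B",
                 lower = c(log(1e-3), log(1e-4)), upper = c(log(50), log(500))),
    error = function(e) NULL)

  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
    warning("CTCRW fit failed; falling back to linear interpolation")
    gx <- stats::approx(th_obs, xy[, 1], xout = grid, rule = 2)$y
    gy <- stats::approx(th_obs, xy[, 2], xout = grid, rule = 2)$y
    sd_km <- rep(mean(tau_obs), length(grid))
  } else {
    f <- ctcrw_filter(times_all, obs, tau, exp(fit$par[1]), exp(fit$par[2]),
                      smooth = TRUE)
    gi <- match(grid, times_all)
    gx <- f$ms[gi, 1]; gy <- f$ms[gi, 3]
    sd_km <- sqrt(pmax(0, (f$Ps[cbind(gi, 1, 1)] + f$Ps[cbind(gi, 3, 3)]) / 2))
  }
  ll <- unproject_aeqd(gx, gy, origin)
  out <- data.frame(time = as.POSIXct(t0 + grid * 3600,
                                      origin = "1970-01-01", tz = "UTC"),
                    lon = ll[, "lon"], lat = ll[, "lat"], sd_km = sd_km)
  out$speed_kmh <- transit_speeds(out)
  class(out) <- c("hourly_track", class(out))
  out
}

#' Transit speed between successive hourly positions
#'
#' Great-circle distance divided by the elapsed time. The last position
#' carries the preceding speed so the vector matches the track length.
#'
#' @param track data.frame with `time`, `lon`, `lat`.
#' @return numeric vector of speeds (km/h), one per position.
#' @export
transit_speeds <- function(track) {
  if (nrow(track) < 2) stop("need at least 2 positions")
  d <- gc_step_km(track$lon, track$lat)
  dt <- diff(as.numeric(track$time)) / 3600
  sp <- d / pmax(dt, 1e-9)
  c(sp, sp[length(sp)])
}

#' Retain one deployment per female for repeat deployments
#'
#' The default keeps each animal's first trip deterministically; set
#' `random = TRUE` (with a seed) to drop repeats at random instead.
#'
#' @param deployments data.frame with `id`, `animal`, `start`.
#' @param random logical; sample the retained trip instead of taking the
#'   first.
#' @param seed RNG seed used when `random = TRUE`.
#' @return the retained subset of `deployments`.
#' @export
dedupe_deployments <- function(deployments, random = FALSE, seed = 1L) {
  stopifnot(all(c("animal", "start") %in% names(deployments)))
  sel <- unlist(lapply(split(seq_len(nrow(deployments)), deployments$animal),
                       function(ix) {
    if (length(ix) == 1) return(ix)
    if (random) {
      set.seed(seed + ix[1])
      sample(ix, 1)
    } else ix[order(deployments$start[ix])][1]
  }))
  deployments[sort(sel), , drop = FALSE]
}
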