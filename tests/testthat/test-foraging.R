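t0 <- as.POSIXct("2010-03-01", tz = "UTC")

mk_track <- function(speeds, lon = NULL, lat = NULL) {
  n <- length(speeds)
  data.frame(time = t0 + (0:(n - 1)) * 3600,
             lon = if (is.null(lon)) seq(-130, -129, length.out = n) else lon,
             lat = if (is.null(lat)) rep(40, n) else lat,
             speed_kmh = speeds)
}

mk_dive <- function(hour, type) {
  data.frame(start = t0 + hour * 3600 - 600, end = t0 + hour * 3600 + 600,
             type = type)
}

test_that("foraging needs both slow transit and a foraging dive", {
  tr <- mk_track(c(1, 1, 5, 1))
  dv <- rbind(mk_dive(0, "benthic"), mk_dive(1, "drift"),
              mk_dive(2, "pelagic"), mk_dive(3, "transit"))
  fl <- detect_foraging_locations(tr, dv)
  expect_equal(fl, c(TRUE, FALSE, FALSE, FALSE))
  # no foraging dives at all: no flags regardless of speed
  expect_false(any(detect_foraging_locations(tr, dv[dv$type == "drift", ])))
})

test_that("raising the speed threshold never reduces the feeding proportion", {
  set.seed(31)
  tr <- mk_track(runif(50, 0, 6))
  dv <- do.call(rbind, lapply(0:49, function(h) mk_dive(h, "pelagic")))
  p <- vapply(c(1, 2, 3, 5), function(v)
    proportion_time_feeding(detect_foraging_locations(tr, dv,
                                                      foraging_params(max_transit_kmh = v))),
    numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("proportion of time feeding matches its definition", {
  expect_equal(proportion_time_feeding(rep(TRUE, 10)), 1)
  expect_equal(proportion_time_feeding(rep(FALSE, 10)), 0)
  expect_equal(proportion_time_feeding(c(rep(TRUE, 53), rep(FALSE, 47))), 0.53)
})

test_that("trip typology follows the stray-count rule at its printed boundary", {
  colony <- c(-122.33, 37.11)
  # out-and-back track: apex at hours 20-30
  d_km <- c(seq(0, 500, length.out = 20), rep(500, 11),
            seq(500, 0, length.out = 20))
  ll <- unproject_aeqd(-d_km, rep(0, length(d_km)), colony)
  tr <- data.frame(time = t0 + (seq_along(d_km) - 1) * 3600,
                   lon = ll[, "lon"], lat = ll[, "lat"],
                   speed_kmh = 1)
  apex_flags <- logical(nrow(tr)); apex_flags[21:31] <- TRUE
  expect_equal(classify_trip_typology(tr, apex_flags, colony), "focused")
  # exactly 4 strays stays focused (< 5 rule); 6 strays is throughout
  f4 <- apex_flags; f4[2:5] <- TRUE
  expect_equal(classify_trip_typology(tr, f4, colony), "focused")
  f6 <- apex_flags; f6[2:7] <- TRUE
  expect_equal(classify_trip_typology(tr, f6, colony), "throughout")
  expect_equal(classify_trip_typology(tr, logical(nrow(tr)), colony), "none")
})

test_that("ecoregion assignment applies the majority rule inclusively", {
  geom <- make_geometry()
  pt <- function(region, n) {
    ctr <- colMeans(geom$ecoregions[[region]][1:4, ])
    cbind(rep(ctr[1], n), rep(ctr[2], n))
  }
  # 84% in one region
  xy <- rbind(pt("subarctic_pacific", 84), pt("california_current", 16))
  expect_equal(assign_ecoregion(xy[, 1], xy[, 2], geom$ecoregions),
               "subarctic_pacific")
  # 40/35/25: no majority
  xy2 <- rbind(pt("subarctic_pacific", 40), pt("california_current", 35),
               pt("north_central_pacific", 25))
  expect_equal(assign_ecoregion(xy2[, 1], xy2[, 2], geom$ecoregions), "multiple")
  # exactly 50% qualifies (greater-than-or-equal boundary)
  xy3 <- rbind(pt("subarctic_pacific", 50), pt("california_current", 25),
               pt("north_central_pacific", 25))
  expect_equal(assign_ecoregion(xy3[, 1], xy3[, 2], geom$ecoregions),
               "subarctic_pacific")
})

test_that("distance to the shelf edge matches plane geometry and a brute-force oracle", {
  geom <- make_geometry()
  # a point on the isobath
  on_line <- unproject_aeqd(geom$shelf_x_km, 400, geom$colony)
  expect_lt(distance_to_shelf(on_line[, "lon"], on_line[, "lat"], geom$shelf), 0.05)
  # 33.5 km inshore of the straight isobath
  p <- unproject_aeqd(geom$shelf_x_km + 33.5, 400, geom$colony)
  expect_equal(distance_to_shelf(p[, "lon"], p[, "lat"], geom$shelf), 33.5,
               tolerance = 0.01)
  # random points vs minimum over a densified vertex set
  set.seed(8)
  xy <- cbind(runif(15, -300, 100), runif(15, -200, 1000))
  ll <- unproject_aeqd(xy[, 1], xy[, 2], geom$colony)
  dense_y <- seq(-800, 2200, by = 1)
  dense <- unproject_aeqd(rep(geom$shelf_x_km, length(dense_y)), dense_y,
                          geom$colony)
  d_pkg <- distance_to_shelf(ll[, "lon"], ll[, "lat"], geom$shelf)
  d_brute <- vapply(seq_len(nrow(ll)), function(i)
    min(geosphere::distHaversine(ll[i, , drop = FALSE], dense)) / 1000,
    numeric(1))
  expect_lt(max(abs(d_pkg - d_brute) / pmax(d_brute, 1)), 0.001)
})

test_that("foraging area behaves like a 95% density region", {
  set.seed(12)
  # uniform disc of radius R: area within 15% of pi R^2 at large n
  R <- 60
  r <- R * sqrt(runif(3000)); th <- runif(3000, 0, 2 * pi)
  ctr <- c(-130, 42)
  ll <- unproject_aeqd(r * cos(th), r * sin(th) + 500, ctr)
  a <- foraging_area(ll[, "lon"], ll[, "lat"])
  expect_lt(abs(a - 0.95 * pi * R^2) / (0.95 * pi * R^2), 0.15)
  # widening the bandwidth cannot shrink the area
  a2 <- foraging_area(ll[, "lon"], ll[, "lat"], bw_scale = 2)
  expect_gte(a2, a * 0.999)
  # degenerate cluster: a small single-kernel footprint, still defined
  ll0 <- unproject_aeqd(rep(0, 12), rep(0, 12), ctr)
  a0 <- foraging_area(ll0[, "lon"], ll0[, "lat"])
  expect_true(is.finite(a0) && a0 < 500)
  # too few locations: undefined
  expect_true(is.na(foraging_area(ll[1:5, "lon"], ll[1:5, "lat"])))
})

test_that("habitat typing follows the near-shelf fraction bands", {
  expect_equal(habitat_type(rep(5, 20)), "coastal")
  expect_equal(habitat_type(rep(400, 20)), "open ocean")
  expect_equal(habitat_type(c(rep(5, 10), rep(400, 10))), "coastal/open ocean")
})

test_that("trip summaries are total with coherent proportions", {
  co <- small_cohort()
  id <- co$deployments$id[1]
  dv <- process_dives(co$dives[[id]]$series,
                      track = data.frame(time = co$paths$time[co$paths$id == id],
                                         lon = co$paths$lon[co$paths$id == id],
                                         lat = co$paths$lat[co$paths$id == id]),
                      geometry = co$geometry)
  tr <- data.frame(time = co$paths$time[co$paths$id == id],
                   lon = co$paths$lon[co$paths$id == id],
                   lat = co$paths$lat[co$paths$id == id])
  tr$speed_kmh <- transit_speeds(tr)
  s <- trip_summary(id, tr, dv, co$geometry,
                    meta = list(sex = co$deployments$sex[1]))
  expect_equal(ncol(s) - sum(names(s) %in% c("id", "ecoregion", "habitat",
                                             "typology", "sex")), 31)
  expect_equal(s$prop_transit + s$prop_pelagic + s$prop_drift + s$prop_benthic,
               1, tolerance = 1e-9)
  expect_true(s$prop_time_feeding >= 0 && s$prop_time_feeding <= 1)
  expect_true(all(trip_summary_variables() %in% names(s)))
})
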