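# Trip-level foraging variables: feeding detection from slow transit plus
# foraging dives, trip typology, ecoregion and habitat assignment,
# distance to the shelf edge, kernel foraging area, and assembly of the
# 31-variable behavioural profile per deployment.

#' Foraging-analysis parameters
#'
#' @param max_transit_kmh hourly positions slower than this can be
#'   foraging locations (default 2).
#' @param ecoregion_majority minimum fraction of foraging locations that
#'   must fall in one ecoregion to assign it (default 0.5).
#' @param focused_max_stray a trip is "focused" when fewer than this many
#'   foraging locations lie outside the farthest-point segment.
#' @param apex_frac hours whose distance from the colony is at least this
#'   fraction of the trip maximum form the farthest-point segment.
#' @param kde_cell_km KDE cell size for foraging area (2 km).
#' @param ud_level UD probability level defining the foraging area.
#' @param coastal_km distance to the shelf edge within which a location is
#'   on/near-shelf (30 km).
#' @param coastal_frac,ocean_frac habitat splits: coastal when at least
#'   `coastal_frac` of foraging locations are near-shelf, open ocean when
#'   at most `ocean_frac` are.
#' @param min_locations_kde minimum foraging locations for a defined
#'   foraging area.
#' @return list of class `foraging_params`.
#' @export
foraging_params <- function(max_transit_kmh = 2, ecoregion_majority = 0.5,
                            focused_max_stray = 5, apex_frac = 0.9,
                            kde_cell_km = 2, ud_level = 0.95,
                            coastal_km = 30, coastal_frac = 0.9,
                            ocean_frac = 0.1, min_locations_kde = 10) {
  stopifnot(max_transit_kmh > 0, ecoregion_majority > 0, ecoregion_majority <= 1,
            ud_level > 0, ud_level < 1)
  structure(as.list(environment()), class = "foraging_params")
}

#' Flag foraging locations on the hourly track
#'
#' A position is a foraging location iff its transit speed is below the
#' threshold AND at least one pelagic- or benthic-foraging dive is
#' georeferenced to that hour.
#'
#' @param track hourly track with `time`, `speed_kmh`.
#' @param dives classified, georeferenced dive table (`start`, `end`,
#'   `type`).
#' @param params a [foraging_params()].
#' @return logical vector, one flag per track row.
#' @export
detect_foraging_locations <- function(track, dives, params = foraging_params()) {
  slow <- track$speed_kmh < params$max_transit_kmh
  if (nrow(dives) == 0) return(slow & FALSE)
  fg <- dives[dives$type %in% c("pelagic", "benthic"), , drop = FALSE]
  if (nrow(fg) == 0) return(slow & FALSE)
  tt <- as.numeric(track$time)
  mid <- as.numeric(fg$start) + (as.numeric(fg$end) - as.numeric(fg$start)) / 2
  hr <- findInterval(mid, tt - 1800)        # dive midpoint rounded to track hour
  hr <- hr[hr >= 1 & hr <= length(tt)]
  has_dive <- logical(length(tt))
  has_dive[unique(hr)] <- TRUE
  slow & has_dive
}

#' Proportion of at-sea time spent feeding
#'
#' @param flags logical foraging flags over the hourly track.
#' @return foraging hours / total hours.
#' @export
proportion_time_feeding <- function(flags) {
  stopifnot(length(flags) >= 1)
  mean(flags)
}

#' Classify trip typology: focused vs throughout
#'
#' The farthest-point segment is the set of hours whose distance from the
#' colony is at least `apex_frac` of the trip maximum. A trip is
#' `"focused"` when fewer than `focused_max_stray` foraging locations fall
#' outside that segment, `"throughout"` otherwise, `"none"` when no
#' foraging location exists.
#'
#' @param track hourly track.
#' @param flags foraging flags from [detect_foraging_locations()].
#' @param colony `c(lon, lat)`.
#' @param params a [foraging_params()].
#' @return `"focused"`, `"throughout"` or `"none"`.
#' @export
classify_trip_typology <- function(track, flags, colony,
                                   params = foraging_params()) {
  if (!any(flags)) return("none")
  d <- geosphere::distHaversine(cbind(track$lon, track$lat),
                                matrix(colony, nrow = 1)) / 1000
  apex <- d >= params$apex_frac * max(d)
  stray <- sum(flags & !apex)
  if (stray < params$focused_max_stray) "focused" else "throughout"
}

#' Assign the trip to a mesopelagic ecoregion
#'
#' The region containing at least the majority fraction of foraging
#' locations; `"multiple"` when none qualifies. Locations in no polygon
#' count towards the denominator as open/unassigned.
#'
#' @param lon,lat foraging-location coordinates.
#' @param ecoregions named list of lon/lat polygon rings.
#' @param params a [foraging_params()].
#' @return region name or `"multiple"`.
#' @export
assign_ecoregion <- function(lon, lat, ecoregions, params = foraging_params()) {
  if (length(lon) == 0) return(NA_character_)
  counts <- vapply(ecoregions, function(p)
    sum(points_in_polygon(lon, lat, p)), numeric(1))
  frac <- counts / length(lon)
  hit <- which(frac >= params$ecoregion_majority)
  if (length(hit) == 0) "multiple" else names(ecoregions)[hit[which.max(frac[hit])]]
}

#' Geodesic distance to the continental shelf edge
#'
#' Distance from each point to the nearest point of the isobath polyline
#' (great-circle against each segment), in km; 0 on the line.
#'
#' @param lon,lat point coordinates.
#' @param shelf polyline data.frame `lon`, `lat`.
#' @return numeric vector of distances (km).
#' @export
distance_to_shelf <- function(lon, lat, shelf) {
  stopifnot(nrow(shelf) >= 2)
  d <- geosphere::dist2Line(cbind(lon, lat),
                            as.matrix(shelf[, c("lon", "lat")]))
  unname(d[, "distance"]) / 1000
}

#' Foraging area from a 2D kernel utilization distribution
#'
#' Gaussian KDE of the foraging locations in a locally projected plane
#' (azimuthal equidistant at the locations' centroid) on a `cell_km` grid
#' with Silverman reference bandwidths; the area is the total area of the
#' smallest set of highest-density cells holding `ud_level` of the mass.
#'
#' @param lon,lat foraging-location coordinates.
#' @param params a [foraging_params()].
#' @param bw_scale multiplies both bandwidths (for sensitivity checks).
#' @return area in km^2, or NA when fewer than `min_locations_kde`
#'   locations are available.
#' @export
foraging_area <- function(lon, lat, params = foraging_params(), bw_scale = 1) {
  n <- length(lon)
  if (n < params$min_locations_kde) return(NA_real_)
  ctr <- c(mean(lon), mean(lat))
  xy <- project_aeqd(lon, lat, ctr)
  bw <- c(stats::bw.nrd0(xy[, 1]), stats::bw.nrd0(xy[, 2])) * bw_scale
  bw <- pmax(bw, params$kde_cell_km / 2)    # degenerate clusters: one kernel
  cell <- params$kde_cell_km
  gx <- seq(min(xy[, 1]) - 3 * bw[1], max(xy[, 1]) + 3 * bw[1], by = cell)
  gy <- seq(min(xy[, 2]) - 3 * bw[2], max(xy[, 2]) + 3 * bw[2], by = cell)
  # MASS::kde2d takes full kernel widths = 4 * sd
  dens <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * bw, n = c(length(gx), length(gy)),
                      lims = c(range(gx), range(gy)))
  z <- dens$z / sum(dens$z)
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(z[ord])
  n_in <- which(cum >= params$ud_level)[1]
  n_in * cell^2
}

#' Habitat type from near-shelf fractions of foraging locations
#'
#' @param shelf_dist_km per-foraging-location distances to the shelf edge.
#' @param params a [foraging_params()].
#' @return `"coastal"`, `"coastal/open ocean"` or `"open ocean"`.
#' @export
habitat_type <- function(shelf_dist_km, params = foraging_params()) {
  if (length(shelf_dist_km) == 0) return(NA_character_)
  near <- mean(shelf_dist_km <= params$coastal_km)
  if (near >= params$coastal_frac) "coastal"
  else if (near <= params$ocean_frac) "open ocean"
  else "coastal/open ocean"
}

#' Canonical names of the 31 trip-summary behavioural variables
#'
#' Three spatial variables, four dive-type proportions, and six dive
#' metrics per dive type x diel cell.
#'
#' @return character vector of length 31.
#' @export
trip_summary_variables <- function() {
  metrics <- c("max_depth_m", "duration_min", "bottom_time_min",
               "postdive_interval_min", "n_excursions", "efficiency")
  cells <- as.vector(outer(metrics, c("pelagic_day", "pelagic_night",
                                      "benthic_day", "benthic_night"),
                           function(m, g) paste(g, m, sep = ".")))
  c("shelf_distance_km", "prop_time_feeding", "foraging_area_km2",
    "prop_transit", "prop_pelagic", "prop_drift", "prop_benthic", cells)
}

#' Assemble the 31-variable trip summary for one deployment
#'
#' Combines the hourly track, classified dives and study geometry into
#' one row: mean distance to the shelf edge over foraging locations,
#' proportion of time feeding, 95% UD foraging area, the four dive-type
#' proportions, and per dive-type x diel cell the mean max depth,
#' duration, bottom time, post-dive interval, excursion count and
#' efficiency — plus ecoregion, habitat and typology labels. Cells with
#' no dives are NA.
#'
#' @param id deployment id.
#' @param track hourly track with speeds.
#' @param dives classified, georeferenced dive table.
#' @param geometry study geometry ([make_geometry()]).
#' @param params a [foraging_params()].
#' @param meta optional named list (sex, trip, ...) appended as columns.
#' @return one-row data.frame with the 31 variables plus labels.
#' @export
trip_summary <- function(id, track, dives, geometry,
                         params = foraging_params(), meta = list()) {
  flags <- detect_foraging_locations(track, dives, params)
  f_lon <- track$lon[flags]; f_lat <- track$lat[flags]
  sd_km <- if (length(f_lon)) distance_to_shelf(f_lon, f_lat, geometry$shelf)
           else numeric(0)

  n_div <- nrow(dives)
  prop <- function(ty) if (n_div == 0) NA_real_ else mean(dives$type == ty)
  out <- data.frame(id = id,
                    shelf_distance_km = if (length(sd_km)) mean(sd_km) else NA_real_,
                    prop_time_feeding = proportion_time_feeding(flags),
                    foraging_area_km2 = foraging_area(f_lon, f_lat, params),
                    prop_transit = prop("transit"), prop_pelagic = prop("pelagic"),
                    prop_drift = prop("drift"), prop_benthic = prop("benthic"))
  metrics <- c("max_depth_m", "duration_min", "bottom_time_min",
               "postdive_interval_min", "n_excursions", "efficiency")
  for (ty in c("pelagic", "benthic")) for (dl in c("day", "night")) {
    sel <- dives$type == ty & !is.na(dives$diel) & dives$diel == dl
    for (mt in metrics) {
      col <- paste(paste(ty, dl, sep = "_"), mt, sep = ".")
      out[[col]] <- if (any(sel)) mean(dives[[mt]][sel], na.rm = TRUE) else NA_real_
    }
  }
  out$ecoregion <- assign_ecoregion(f_lon, f_lat, geometry$ecoregions, params)
  out$habitat <- habitat_type(sd_km, params)
  out$typology <- classify_trip_typology(track, flags, geometry$colony, params)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}
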