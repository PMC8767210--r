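# Orchestration: one reproducible run from simulation through mortality
# models, with serialized stage outputs (CSV/GeoJSON/JSON) so any stage
# can be re-run from its inputs alone.

#' Run configuration
#'
#' @param seed RNG seed, recorded in every output's metadata.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param filter [filter_params()].
#' @param detection [dive_detection_params()].
#' @param classifier [classifier_params()].
#' @param foraging [foraging_params()].
#' @param stages character vector of stages to run, in dependency order
#'   from `c("simulate","tracks","dives","forage","energy","cluster",
#'   "overlap","mortality")`.
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(seed = seed),
                       filter = filter_params(),
                       detection = dive_detection_params(),
                       classifier = classifier_params(),
                       foraging = foraging_params(),
                       stages = c("simulate", "tracks", "dives", "forage",
                                  "energy", "cluster", "overlap", "mortality"),
                       out_dir = tempfile("sealforage_run_")) {
  known <- c("simulate", "tracks", "dives", "forage", "energy", "cluster",
             "overlap", "mortality")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, filter = filter,
                 detection = detection, classifier = classifier,
                 foraging = foraging, stages = stages, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Only keys known to [run_config()] and its parameter blocks are
#' accepted; an unknown key is an error before any stage runs.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "stages", "n_males", "n_females",
             "trip_scale", "female_pm_fraction",
             "max_speed_kmh", "min_angle_deg", "max_transit_kmh",
             "kde_cell_km")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  seed <- if (!is.null(y$seed)) y$seed else 1L
  sim_args <- y[intersect(names(y), c("n_males", "n_females", "trip_scale",
                                      "female_pm_fraction"))]
  sim <- do.call(sim_config, c(list(seed = seed), sim_args))
  fp <- do.call(filter_params,
                y[intersect(names(y), c("max_speed_kmh", "min_angle_deg"))])
  fo <- do.call(foraging_params,
                y[intersect(names(y), c("max_transit_kmh", "kde_cell_km"))])
  args <- list(seed = seed, sim = sim, filter = fp, foraging = fo)
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, args)
}

write_geojson <- function(geometry, path) {
  ring <- function(df) list(lapply(seq_len(nrow(df)), function(i)
    c(df$lon[i], df$lat[i])))
  features <- c(
    list(list(type = "Feature",
              properties = list(name = "colony"),
              geometry = list(type = "Point",
                              coordinates = unname(geometry$colony))),
         list(type = "Feature",
              properties = list(name = "shelf_200m_isobath"),
              geometry = list(type = "LineString",
                              coordinates = lapply(seq_len(nrow(geometry$shelf)),
                                function(i) c(geometry$shelf$lon[i],
                                              geometry$shelf$lat[i]))))),
    lapply(names(geometry$ecoregions), function(nm)
      list(type = "Feature", properties = list(name = nm),
           geometry = list(type = "Polygon",
                           coordinates = ring(geometry$ecoregions[[nm]])))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order on a simulated
#' cohort, writing each stage's tables to `out_dir` along with a JSON
#' metadata sidecar carrying the seed and a configuration hash. Rerunning
#' with the same configuration reproduces the outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage progress messages.
#' @return invisible list with every stage result (`cohort`, `tracks`,
#'   `dives`, `summaries`, `budgets`, `clustering`, `overlap`,
#'   `mortality`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  res <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %-9s %6.1f s", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  geometry <- config$sim$geometry

  if ("simulate" %in% config$stages) {
    res$cohort <- stage("simulate", simulate_cohort(config$sim))
    utils::write.csv(res$cohort$argos,
                     file.path(config$out_dir, "argos_fixes.csv"),
                     row.names = FALSE)
    utils::write.csv(res$cohort$body,
                     file.path(config$out_dir, "body_records.csv"),
                     row.names = FALSE)
    write_geojson(geometry, file.path(config$out_dir, "geometry.geojson"))
  }
  cohort <- res$cohort
  ids <- cohort$deployments$id

  if ("tracks" %in% config$stages) {
    res$tracks <- stage("tracks", {
      lapply(stats::setNames(ids, ids), function(id) {
        fx <- cohort$argos[cohort$argos$id == id, ]
        dep <- cohort$deployments[cohort$deployments$id == id, ]
        fx <- truncate_trip(fx, dep$start, dep$start + dep$trip_days * 86400)
        fx <- sda_filter(fx, config$filter)
        smooth_track(fx, geometry$colony,
                     config$sim$argos$error_sd_km)
      })
    })
    all_tracks <- do.call(rbind, lapply(ids, function(id)
      cbind(id = id, as.data.frame(res$tracks[[id]]))))
    utils::write.csv(all_tracks, file.path(config$out_dir, "hourly_tracks.csv"),
                     row.names = FALSE)
  }

  if ("dives" %in% config$stages) {
    res$dives <- stage("dives", {
      lapply(stats::setNames(ids, ids), function(id)
        process_dives(cohort$dives[[id]]$series, res$tracks[[id]], geometry,
                      config$detection, config$classifier))
    })
    all_dives <- do.call(rbind, lapply(ids, function(id) {
      d <- res$dives[[id]]
      if (nrow(d)) cbind(id = id, d) else NULL
    }))
    utils::write.csv(all_dives, file.path(config$out_dir, "dives.csv"),
                     row.names = FALSE)
  }

  if ("forage" %in% config$stages) {
    res$summaries <- stage("forage", {
      do.call(rbind, lapply(ids, function(id) {
        dep <- cohort$deployments[cohort$deployments$id == id, ]
        trip_summary(id, res$tracks[[id]], res$dives[[id]], geometry,
                     config$foraging,
                     meta = list(sex = dep$sex, trip = dep$trip,
                                 strategy = dep$strategy))
      }))
    })
    utils::write.csv(res$summaries,
                     file.path(config$out_dir, "trip_summaries.csv"),
                     row.names = FALSE)
  }

  if ("energy" %in% config$stages) {
    res$budgets <- stage("energy", {
      do.call(rbind, lapply(ids, function(id) {
        body <- cohort$body[cohort$body$id == id, ]
        dep <- cohort$deployments[cohort$deployments$id == id, ]
        smry <- res$summaries[res$summaries$id == id, ]
        energy_budget(body, smry$prop_time_feeding * body$trip_days, dep$sex)
      }))
    })
    utils::write.csv(res$budgets,
                     file.path(config$out_dir, "energy_budgets.csv"),
                     row.names = FALSE)
  }

  if ("cluster" %in% config$stages) {
    res$clustering <- stage("cluster", {
      am <- assemble_matrix(res$summaries)
      pca <- run_pca(am$x)
      ret <- if (length(pca$retained)) pca$retained else 1:2
      sol <- cluster_strategies(pca$scores[, ret, drop = FALSE])
      list(matrix = am, pca = pca, solution = sol)
    })
    utils::write.csv(data.frame(id = rownames(res$clustering$matrix$x),
                                cluster = res$clustering$solution$assignments),
                     file.path(config$out_dir, "cluster_assignments.csv"),
                     row.names = FALSE)
  }

  if ("overlap" %in% config$stages) {
    res$overlap <- stage("overlap", {
      pts <- lapply(c(male = "male", female = "female"), function(sx) {
        sel_ids <- ids[cohort$deployments$sex == sx]
        do.call(rbind, lapply(sel_ids, function(id) {
          tr <- res$tracks[[id]]
          dv <- res$dives[[id]]
          fl <- detect_foraging_locations(tr, dv, config$foraging)
          if (!any(fl)) return(NULL)
          xy <- project_aeqd(tr$lon[fl], tr$lat[fl], geometry$colony)
          # deepest foraging dive per flagged hour, km, for the 3D axis
          depth <- vapply(which(fl), function(h) {
            mid <- as.numeric(dv$start) + (as.numeric(dv$end) -
                                             as.numeric(dv$start)) / 2
            sel <- dv$type %in% c("pelagic", "benthic") &
              abs(mid - as.numeric(tr$time[h])) <= 1800
            if (any(sel)) max(dv$max_depth_m[sel]) / 1000 else NA_real_
          }, numeric(1))
          cbind(xy, depth_km = depth)
        }))
      })
      if (is.null(pts$male) || is.null(pts$female) ||
          nrow(pts$male) < 10 || nrow(pts$female) < 10) {
        NULL
      } else {
        list(d2 = group_overlap(pts$male[, 1:2], pts$female[, 1:2],
                                cell_km = config$foraging$kde_cell_km),
             d3 = {
               m3 <- pts$male[!is.na(pts$male[, 3]), ]
               f3 <- pts$female[!is.na(pts$female[, 3]), ]
               if (nrow(m3) >= 10 && nrow(f3) >= 10)
                 group_overlap(m3, f3,
                               cell_km = c(rep(config$foraging$kde_cell_km, 2),
                                           0.05))
               else NULL
             })
      }
    })
  }

  if ("mortality" %in% config$stages) {
    res$mortality <- stage("mortality", {
      fixture <- list(table = cohort$deployments,
                      transmissions = cohort$fates$transmissions,
                      resights = cohort$fates$resights,
                      start = min(cohort$deployments$start))
      tab <- fixture$table
      tab$outcome <- vapply(seq_len(nrow(tab)), function(i) {
        attribute_tag_fate(fixture$transmissions[[tab$id[i]]],
                           fixture$resights[[tab$id[i]]],
                           tab$start[i] + tab$fate_trip_days[i] * 86400)$outcome
      }, character(1))
      tab$died <- as.integer(tab$outcome == "died")
      models <- if (length(unique(tab$died)) == 2)
        fit_mortality_models(tab) else NULL
      list(cohort_table = tab, models = models,
           probabilities = if (!is.null(models))
             mortality_probability(models$best) else NULL)
    })
    utils::write.csv(res$mortality$cohort_table,
                     file.path(config$out_dir, "cohort_fates.csv"),
                     row.names = FALSE)
  }

  meta <- list(seed = config$seed,
               config_hash = config_hash(config),
               stages = config$stages,
               elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                               units = "secs")))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

# stable hash of the configuration (structure + values; output path and
# environments excluded)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  raw <- serialize(rapply(x, function(v)
    if (is.numeric(v)) signif(v, 12) else v, how = "replace"),
    NULL, version = 2)
  sum(as.numeric(raw) * (seq_along(raw) %% 997)) %% 1e9
}
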