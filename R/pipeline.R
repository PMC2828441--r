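#' Default pipeline configuration
#'
#' A demo-scale configuration of the full study pipeline: a 200-area
#' synthetic city over a 15 x 15 road lattice with 12 candidate stations,
#' GA runs at a reduced generation budget. The paper-scale study profile
#' (2076 areas, 35 sites x 5 slots, 1500 generations) is available with
#' `profile = "study"`.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param profile `"demo"` (default) or `"study"`.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, profile = c("demo", "study")) {
  profile <- match.arg(profile)
  base <- list(
    seed = seed,
    stages = c("generate", "fit", "project", "distances",
               "optimize", "evaluate"),
    synthetic_city = list(
      n_rows = 15, n_cols = 15, spacing_m = 800,
      jitter_frac = 0.2, edge_removal_frac = 0.1,
      n_areas = 200, total_pop = 78000,
      n_sites = 12, slots_per_site = 2,
      target_r2 = 0.71
    ),
    regression = list(p_enter = 0.05, p_remove = 0.10),
    projection = list(horizon_year = 2040, n_admin = 8,
                      total_fertility_rate = 1.22),
    ga = list(n_values = c(4, 6), generations = 300,
              population_size = 60),
    evaluate = list(speed_kmh = 30, busy_prob = 0.322)
  )
  if (profile == "study") {
    base$synthetic_city <- utils::modifyList(base$synthetic_city, list(
      n_rows = 40, n_cols = 40, spacing_m = 600,
      n_areas = 2076, total_pop = 814000,
      n_sites = 35, slots_per_site = 5))
    base$projection$n_admin <- 38
    base$ga <- list(n_values = 27, generations = 1500,
                    population_size = 100)
  }
  base
}

#' Generate a complete synthetic city
#'
#' Convenience wrapper running the synthetic-city stages in order: road
#' graph, census areas, demographics, candidate sites, R-squared
#' calibrated case counts and scattered case points.
#'
#' @param cfg `synthetic_city` block of the configuration (see
#'   [default_config()]).
#' @param seed integer seed.
#' @param geometry if FALSE, skip case-point scattering (the polygons are
#'   still built; point scatter is only needed for point-in-polygon
#'   work).
#' @return list `graph, areas, sites, cases, noise_sd`.
#' @export
generate_city <- function(cfg, seed = 1L, geometry = TRUE) {
  graph <- generate_road_graph(cfg$n_rows, cfg$n_cols, cfg$spacing_m,
                               cfg$jitter_frac, cfg$edge_removal_frac,
                               seed = seed)
  areas <- generate_census_areas(graph, cfg$n_areas, seed = seed + 1L)
  areas <- populate_demographics(areas, cfg$total_pop, seed = seed + 2L)
  sites <- place_candidate_sites(graph, cfg$n_sites, cfg$slots_per_site,
                                 seed = seed + 3L)
  noise_sd <- calibrate_noise_to_r2(areas, target_r2 = cfg$target_r2)
  areas <- simulate_case_counts(areas, noise_sd = noise_sd,
                                seed = seed + 4L)
  cases <- if (geometry) scatter_case_points(areas, seed = seed + 5L) else NULL
  list(graph = graph, areas = areas, sites = sites, cases = cases,
       noise_sd = noise_sd)
}

#' Run the study pipeline
#'
#' Executes the requested stages in order: generate the synthetic city;
#' summarise cases per area and fit the stepwise demand model; project
#' populations and predict future per-area demand; build the OD matrix;
#' run the GA per requested fleet size n for the current and the peak
#' future period; evaluate and compare current vs optimised deployments.
#' All outputs are written under `out_dir` and listed, with content
#' hashes, in the returned (and saved) run manifest.
#'
#' @param config configuration list as from [default_config()], or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("emsloc_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  seed <- config$seed
  art <- list()        # in-memory artefacts passed between stages
  files <- character(0)
  t_start <- Sys.time()

  run_stage <- function(name, fn) {
    message(sprintf("[emsloc] stage %-10s ...", name), appendLF = FALSE)
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf(" done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  if ("generate" %in% stages) {
    art$city <- run_stage("generate", function() {
      city <- generate_city(config$synthetic_city, seed = seed)
      write_road_graph_csv(city$graph, file.path(out_dir, "nodes.csv"),
                           file.path(out_dir, "edges.csv"))
      write_areas_geojson(city$areas, file.path(out_dir, "areas.geojson"))
      utils::write.csv(city$areas$table, file.path(out_dir, "areas.csv"),
                       row.names = FALSE)
      utils::write.csv(city$sites, file.path(out_dir, "sites.csv"),
                       row.names = FALSE)
      if (!is.null(city$cases)) {
        utils::write.csv(city$cases, file.path(out_dir, "case_points.csv"),
                         row.names = FALSE)
      }
      city
    })
    files <- c(files, "nodes.csv", "edges.csv", "areas.geojson",
               "areas.csv", "sites.csv",
               if (!is.null(art$city$cases)) "case_points.csv")
  }

  if ("fit" %in% stages) {
    art$model <- run_stage("fit", function() {
      dat <- cbind(predictor_table(art$city$areas),
                   observed_cases = art$city$areas$table$observed_cases)
      m <- stepwise_select(dat, "observed_cases",
                           c("pop_0_4", "pop_15_64", "pop_80_over",
                             "companies_5plus"),
                           p_enter = config$regression$p_enter,
                           p_remove = config$regression$p_remove)
      write_demand_model(m, file.path(out_dir, "demand_model.json"))
      m
    })
    files <- c(files, "demand_model.json")
  }

  if ("project" %in% stages) {
    art$future <- run_stage("project", function() {
      areas <- art$city$areas
      membership <- make_admin_membership(areas, config$projection$n_admin,
                                          seed = seed + 10L)
      base <- areas_to_cohort_table(areas, membership)
      # emulate an earlier census by back-casting with mild ageing drift:
      # slightly larger young cohorts and smaller old cohorts 5 years ago
      earlier <- base
      drift <- seq(1.06, 0.94, length.out = length(age_bands()))
      earlier$count <- earlier$count *
        drift[match(as.character(earlier$band), age_bands())]
      params <- projection_params(
        cohort_change_ratios(earlier, base),
        total_fertility_rate = config$projection$total_fertility_rate)
      series <- project_series(earlier, base, params,
                               horizon_year = config$projection$horizon_year,
                               base_year = 2005)
      for (p in names(series)) {
        write_cohort_csv(series[[p]], p,
                         file.path(out_dir, sprintf("cohorts_%s.csv", p)))
      }
      predictors <- disaggregate_growth(series, base, areas, membership)
      demand <- lapply(predictors, function(pt) {
        data.frame(area_id = pt$area_id,
                   predicted_cases = predict_cases(art$model, pt))
      })
      utils::write.csv(
        data.frame(period = rep(names(demand), each = nrow(areas$table)),
                   do.call(rbind, demand)),
        file.path(out_dir, "predicted_demand.csv"), row.names = FALSE)
      list(membership = membership, series = series,
           predictors = predictors, demand = demand)
    })
    files <- c(files, sprintf("cohorts_%s.csv", names(art$future$series)),
               "predicted_demand.csv")
  }

  if ("distances" %in% stages) {
    art$od <- run_stage("distances", function() {
      areas <- art$city$areas
      od <- od_matrix(art$city$graph,
                      areas$table[, c("centroid_x", "centroid_y")],
                      art$city$sites[, c("x", "y")],
                      origin_ids = areas$table$area_id,
                      destination_ids = art$city$sites$site_id)
      write_od_csv(od, dense_path = file.path(out_dir, "od.csv"))
      od
    })
    files <- c(files, "od.csv")
  }

  if ("optimize" %in% stages) {
    art$ga <- run_stage("optimize", function() {
      slots <- candidate_slots(art$city$sites)
      weights_now <- art$city$areas$table$observed_cases
      peak <- peak_period(art$future)
      weights_future <- if (is.null(peak)) NULL else
        art$future$demand[[peak]]$predicted_cases
      res <- list()
      for (n in config$ga$n_values) {
        cfg_ga <- ga_config(n, population_size = config$ga$population_size,
                            generations = config$ga$generations,
                            seed = seed + 20L + n)
        res[[paste0("current_n", n)]] <-
          evolve_locations(cfg_ga, art$od, weights_now, slots)
        if (!is.null(weights_future)) {
          res[[paste0("future_n", n)]] <-
            evolve_locations(cfg_ga, art$od, weights_future, slots)
        }
      }
      jsonlite::write_json(
        lapply(res, function(r) list(slots = r$best, sites = r$best_sites,
                                     fitness = r$best_fitness,
                                     history = r$history)),
        file.path(out_dir, "ga_results.json"), digits = NA)
      res
    })
    files <- c(files, "ga_results.json")
  }

  if ("evaluate" %in% stages) {
    art$eval <- run_stage("evaluate", function() {
      slots <- candidate_slots(art$city$sites)
      weights <- art$city$areas$table$observed_cases
      n_eval <- config$ga$n_values[1]
      # "current" scenario: historically grown locations, i.e. a seeded
      # random placement of the same fleet size
      set.seed(seed + 30L)
      s_current <- sort(sample(slots$slot_id, n_eval))
      s_opt <- art$ga[[paste0("current_n", n_eval)]]$best
      cases <- if (!is.null(art$city$cases)) art$city$cases else
        data.frame(area_id = rep(art$city$areas$table$area_id, weights))
      cmp <- compare_scenarios(s_current, s_opt, cases, art$od, weights,
                               slots, busy_prob = config$evaluate$busy_prob,
                               speed_kmh = config$evaluate$speed_kmh,
                               seed = seed + 31L)
      jsonlite::write_json(
        list(n = n_eval,
             current = cmp$current[c("mean_response_time_s", "pct_rank1")],
             alternative = cmp$alternative[c("mean_response_time_s", "pct_rank1")],
             delta_mean_time_s = cmp$delta_mean_time_s,
             delta_pct_rank1 = cmp$delta_pct_rank1),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(cmp$busyness_alternative,
                       file.path(out_dir, "busyness.csv"), row.names = FALSE)
      cmp
    })
    files <- c(files, "evaluation.json", "busyness.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("emsloc")),
    seed = seed,
    stages = stages,
    config = config,
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"),
    outputs = lapply(stats::setNames(nm = files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest[c("package_version", "seed", "stages",
                                  "config", "outputs")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(manifest, list(out_dir = out_dir, artefacts = art)))
}

# Period of peak predicted demand, or NULL if projection was skipped.
peak_period <- function(future) {
  if (is.null(future)) return(NULL)
  tot <- vapply(future$demand, function(d) sum(d$predicted_cases), numeric(1))
  names(tot)[which.max(tot)]
}

#' Best fitness as a function of fleet size n
#'
#' Runs the GA for each requested n and tabulates the best fitness.
#' The table should be non-increasing in n (serving demand with more
#' ambulances can only shorten nearest distances); any increase is
#' flagged as a GA shortfall in the `monotone` column.
#'
#' @param od,weights,slots evaluation context.
#' @param n_values fleet sizes to sweep (the study swept 2..50).
#' @param generations,population_size GA budget per run.
#' @param seed master seed; run i uses `seed + i`.
#' @param use_oracle if TRUE, use exhaustive enumeration instead of the
#'   GA (only for small instances).
#' @return data.frame `n, fitness, monotone`.
#' @export
sweep_n <- function(od, weights, slots, n_values,
                    generations = 300, population_size = 60, seed = 1L,
                    use_oracle = FALSE) {
  n_values <- sort(n_values)
  fitness <- numeric(length(n_values))
  for (i in seq_along(n_values)) {
    fitness[i] <- if (use_oracle) {
      brute_force_optimum(od, weights, n_values[i])$fitness
    } else {
      cfg <- ga_config(n_values[i], population_size = population_size,
                       generations = generations, seed = seed + i)
      evolve_locations(cfg, od, weights, slots)$best_fitness
    }
  }
  monotone <- c(TRUE, diff(fitness) <= 1e-9 * pmax(1, fitness[-1]))
  if (any(!monotone)) {
    warning("sweep_n: fitness increased with n at n = ",
            paste(n_values[!monotone], collapse = ", "),
            " (GA shortfall)")
  }
  data.frame(n = n_values, fitness = fitness, monotone = monotone)
}
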