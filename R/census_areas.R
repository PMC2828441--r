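#' Partition a city into census small areas
#'
#' Tiles the road graph's bounding box with `k` non-overlapping convex
#' polygons: the Voronoi cells of `k` uniformly seeded points, clipped to
#' the box. Centroids follow the bounding-envelope convention
#' (see [envelope_centroid()]), not the area centroid.
#'
#' @param graph a `road_graph` defining the spatial extent.
#' @param k number of census areas, at least 1.
#' @param seed integer RNG seed.
#' @return an object of class `census_areas`: list with `table`
#'   (data.frame `area_id, centroid_x, centroid_y, area_m2`), `polygons`
#'   (list of vertex matrices, in `area_id` order) and `bbox`.
#' @export
generate_census_areas <- function(graph, k, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(graph$nodes) == 0L) stop("graph is empty")
  bbox <- graph_bbox(graph)
  set.seed(seed)
  seeds <- cbind(stats::runif(k, bbox["xmin"], bbox["xmax"]),
                 stats::runif(k, bbox["ymin"], bbox["ymax"]))
  if (nrow(unique(seeds)) < k) {
    stop("could not place k distinct seed points")
  }
  polys <- voronoi_cells(seeds, bbox)
  cent <- t(vapply(polys, envelope_centroid, numeric(2)))
  tab <- data.frame(
    area_id = seq_len(k),
    centroid_x = cent[, 1], centroid_y = cent[, 2],
    area_m2 = vapply(polys, polygon_area, numeric(1))
  )
  structure(list(table = tab, polygons = polys, bbox = bbox),
            class = "census_areas")
}

#' @export
print.census_areas <- function(x, ...) {
  cat(sprintf("<census_areas> %d areas over %.1f km2\n",
              nrow(x$table), sum(x$table$area_m2) / 1e6))
  if (!is.null(x$table$pop_total)) {
    cat(sprintf("  population %d, companies %d",
                sum(x$table$pop_total), sum(x$table$companies_5plus)))
    if (!is.null(x$table$observed_cases)) {
      cat(sprintf(", observed cases %d", sum(x$table$observed_cases)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Five-year age band labels (0-4 ... 85+)
#' @return character vector of 18 band labels.
#' @export
age_bands <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

#' Default city age-sex profile
#'
#' Population shares by 5-year age band and sex for an ageing regional
#' Japanese city (working-age share ~64%, 80+ share ~7%). Shares sum to 1
#' over the whole matrix. The male fraction declines with age, reflecting
#' differential longevity.
#'
#' @return 18 x 2 matrix (rows [age_bands()], columns `male`, `female`).
#' @export
default_age_profile <- function() {
  total <- c(0.045, 0.045, 0.047, 0.050, 0.058, 0.063, 0.070, 0.065,
             0.061, 0.062, 0.070, 0.078, 0.063, 0.057, 0.052, 0.044,
             0.037, 0.033)
  male_frac <- c(rep(0.512, 8), rep(0.50, 4), 0.48, 0.46, 0.44, 0.42,
                 0.39, 0.35)
  prof <- cbind(male = total * male_frac, female = total * (1 - male_frac))
  rownames(prof) <- age_bands()
  prof / sum(prof)
}

#' Populate census areas with demographics
#'
#' Allocates a city-wide population across areas and a sex-by-age
#' structure within each area, then scatters company counts with a
#' separate, steeper central gradient. Design choices emulate how real
#' census small areas behave: area populations are moderately dispersed
#' (delineation targets roughly equal populations), the centre of the city
#' is denser, and small-area age composition is strongly heterogeneous
#' (new estates vs ageing districts), which is what gives the young-age
#' predictor identifiable variation.
#'
#' @param areas a `census_areas` object.
#' @param total_pop total city population (>= 0).
#' @param age_profile 18 x 2 matrix of shares summing to 1
#'   (default [default_age_profile()]).
#' @param company_intensity mean companies (>5 employees) per area; the
#'   citywide total is `round(company_intensity * k)`.
#' @param urban_gradient strength of the centre-weighted residential
#'   density gradient (0 = flat); the centre-to-edge expected density
#'   ratio is `exp(urban_gradient)`. The default is mild because census
#'   small areas are delineated to hold roughly comparable populations.
#' @param seed integer RNG seed.
#' @param share_concentration Dirichlet concentration for per-area
#'   age-share heterogeneity (smaller = more heterogeneous).
#' @param size_sdlog lognormal spread of idiosyncratic area size weights.
#' @param company_gradient central gradient for companies; steeper than
#'   the residential one so the covariate is not collinear with population.
#' @param youth_sdlog,ageing_sdlog lognormal spread of per-area
#'   multipliers on the child (0-9) and elderly (65+) profile blocks,
#'   emulating young-family estates and ageing districts.
#' @return the `census_areas` object with demographic columns
#'   (`pop_total, pop_0_4, pop_15_64, pop_65_over, pop_80_over,
#'   companies_5plus`) added to `$table` and an `$age_sex` count array
#'   (area x band x sex).
#' @export
populate_demographics <- function(areas, total_pop,
                                  age_profile = default_age_profile(),
                                  company_intensity = 6.5,
                                  urban_gradient = 0.4,
                                  seed = 1L,
                                  share_concentration = 60,
                                  size_sdlog = 0.2,
                                  company_gradient = 1.5,
                                  youth_sdlog = 0.5,
                                  ageing_sdlog = 0.25) {
  if (total_pop < 0) stop("total_pop must be non-negative")
  if (abs(sum(age_profile) - 1) > 1e-9) {
    stop("age_profile proportions must sum to 1")
  }
  set.seed(seed)
  tab <- areas$table
  k <- nrow(tab)
  cx <- mean(areas$bbox[c("xmin", "xmax")])
  cy <- mean(areas$bbox[c("ymin", "ymax")])
  r <- sqrt((tab$centroid_x - cx)^2 + (tab$centroid_y - cy)^2)
  rs <- if (max(r) > 0) r / max(r) else r
  w <- exp(stats::rnorm(k, 0, size_sdlog) + urban_gradient * (1 - rs))
  pop <- as.integer(stats::rmultinom(1, total_pop, w))

  bands <- age_bands()
  alpha0 <- share_concentration * age_profile        # 18 x 2, mean = profile
  young <- bands %in% c("0-4", "5-9")
  old <- bands %in% c("65-69", "70-74", "75-79", "80-84", "85+")
  youth_mult <- exp(stats::rnorm(k, 0, youth_sdlog))
  ageing_mult <- exp(stats::rnorm(k, 0, ageing_sdlog))
  age_sex <- array(0L, dim = c(k, 18L, 2L),
                   dimnames = list(NULL, bands, c("male", "female")))
  for (i in seq_len(k)) {
    a <- alpha0
    a[young, ] <- a[young, ] * youth_mult[i]
    a[old, ] <- a[old, ] * ageing_mult[i]
    g <- stats::rgamma(36L, shape = as.vector(a))
    if (sum(g) == 0) g <- as.vector(a)
    age_sex[i, , ] <- stats::rmultinom(1, pop[i], g / sum(g))
  }
  band_tot <- age_sex[, , 1L, drop = FALSE][, , 1L] +
    age_sex[, , 2L, drop = FALSE][, , 1L]
  if (k == 1L) band_tot <- matrix(band_tot, nrow = 1L)
  i1564 <- which(bands %in% c("15-19", "20-24", "25-29", "30-34", "35-39",
                              "40-44", "45-49", "50-54", "55-59", "60-64"))
  i65 <- which(bands %in% c("65-69", "70-74", "75-79", "80-84", "85+"))
  i80 <- which(bands %in% c("80-84", "85+"))
  tab$pop_total <- pop
  tab$pop_0_4 <- as.integer(band_tot[, 1L])
  tab$pop_15_64 <- as.integer(rowSums(band_tot[, i1564, drop = FALSE]))
  tab$pop_65_over <- as.integer(rowSums(band_tot[, i65, drop = FALSE]))
  tab$pop_80_over <- as.integer(rowSums(band_tot[, i80, drop = FALSE]))

  total_companies <- round(company_intensity * k)
  wc <- exp(stats::rnorm(k, 0, 0.4) + company_gradient * (1 - rs))
  tab$companies_5plus <- as.integer(stats::rmultinom(1, total_companies, wc))

  areas$table <- tab
  areas$age_sex <- age_sex
  areas
}

#' Predictor table for the demand regression
#'
#' Extracts the four demand predictors per census area: population aged
#' 0-4 (`pop_0_4`), 15-64 (`pop_15_64`), 80 and over (`pop_80_over`) and
#' companies with more than five employees (`companies_5plus`).
#'
#' @param areas a populated `census_areas` object (or a data.frame that
#'   already has the predictor columns).
#' @return data.frame keyed by `area_id`.
#' @export
predictor_table <- function(areas) {
  tab <- if (inherits(areas, "census_areas")) areas$table else areas
  need <- c("pop_0_4", "pop_15_64", "pop_80_over", "companies_5plus")
  if (!all(need %in% names(tab))) {
    stop("areas are not populated: run populate_demographics() first")
  }
  tab[, c("area_id", need)]
}

#' Simulate observed EMS case counts per census area
#'
#' Case counts are generated around the linear demand model's mean:
#' `observed = round(max(0, mu + eps))` with Gaussian noise
#' `eps ~ N(0, noise_sd)`. Negative means (possible in tiny areas because
#' the model intercept is negative) are clipped at zero before rounding,
#' since counts cannot be negative. A Poisson alternative
#' (`family = "poisson"`, rate `max(0, mu)`) is available; the Gaussian
#' default matches the least-squares generating assumption, which gives
#' the R-squared noise calibration a closed form.
#'
#' @param areas a populated `census_areas` object.
#' @param model a `demand_model` (default: the published coefficients,
#'   [niigata_demand_model()]).
#' @param noise_sd Gaussian noise standard deviation (>= 0); typically
#'   from [calibrate_noise_to_r2()].
#' @param seed integer RNG seed.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return the `census_areas` object with an `observed_cases` column; the
#'   latent means are kept in `$table$case_mean`.
#' @export
simulate_case_counts <- function(areas, model = niigata_demand_model(),
                                 noise_sd, seed = 1L,
                                 family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- predict_cases(model, predictor_table(areas), clip_negative = FALSE)
  set.seed(seed)
  obs <- switch(family,
    gaussian = as.integer(round(pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd)))),
    poisson = as.integer(stats::rpois(length(mu), pmax(0, mu)))
  )
  areas$table$case_mean <- mu
  areas$table$observed_cases <- obs
  areas
}

#' Calibrate case-count noise to a target R-squared
#'
#' Under the Gaussian generating model the population R-squared is
#' `var(mu) / (var(mu) + noise_sd^2)`, so the noise level that attains a
#' target is `noise_sd = sd(mu) * sqrt(1/target_r2 - 1)`.
#'
#' @param areas a populated `census_areas` object.
#' @param model a `demand_model`.
#' @param target_r2 target coefficient of determination in (0, 1); the
#'   study value is 0.71.
#' @return noise standard deviation (cases).
#' @export
calibrate_noise_to_r2 <- function(areas, model = niigata_demand_model(),
                                  target_r2 = 0.71) {
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must lie in (0, 1)")
  mu <- predict_cases(model, predictor_table(areas), clip_negative = FALSE)
  s <- stats::sd(mu)
  if (!is.finite(s) || s == 0) {
    stop("calibration is degenerate: the model mean is constant across areas")
  }
  s * sqrt(1 / target_r2 - 1)
}

#' Scatter case points inside their census areas
#'
#' Places exactly `observed_cases` points uniformly at random inside each
#' area's polygon, tagged with the generating `area_id` so point-in-polygon
#' recounts can be verified round-trip.
#'
#' @param areas a `census_areas` object with `observed_cases` set.
#' @param seed integer RNG seed.
#' @return data.frame `case_id, x, y, area_id`.
#' @export
scatter_case_points <- function(areas, seed = 1L) {
  if (is.null(areas$table$observed_cases)) {
    stop("observed_cases not set: run simulate_case_counts() first")
  }
  set.seed(seed)
  out <- vector("list", nrow(areas$table))
  for (i in seq_len(nrow(areas$table))) {
    n <- areas$table$observed_cases[i]
    if (n == 0L) next
    pts <- sample_points_in_polygon(areas$polygons[[i]], n)
    out[[i]] <- data.frame(x = pts[, 1], y = pts[, 2],
                           area_id = areas$table$area_id[i])
  }
  pts <- do.call(rbind, out)
  if (is.null(pts)) {
    return(data.frame(case_id = integer(0), x = numeric(0),
                      y = numeric(0), area_id = integer(0)))
  }
  data.frame(case_id = seq_len(nrow(pts)), pts)
}

#' Place candidate ambulance stations on the road network
#'
#' Stations sit at distinct road-network nodes (in the study region,
#' ambulances operate from fire stations, which are network-adjacent);
#' each offers up to `slots_per_site` ambulance slots.
#'
#' @param graph a `road_graph`.
#' @param n_sites number of stations (<= number of nodes).
#' @param slots_per_site ambulance slots per station (default 5).
#' @param seed integer RNG seed.
#' @return data.frame `site_id, node_id, x, y, max_slots`.
#' @export
place_candidate_sites <- function(graph, n_sites, slots_per_site = 5,
                                  seed = 1L) {
  if (n_sites > nrow(graph$nodes)) {
    stop("n_sites exceeds the number of road-network nodes")
  }
  if (slots_per_site < 1) stop("slots_per_site must be >= 1")
  set.seed(seed)
  pick <- sort(sample(graph$nodes$id, n_sites))
  data.frame(
    site_id = seq_len(n_sites),
    node_id = pick,
    x = graph$nodes$x[match(pick, graph$nodes$id)],
    y = graph$nodes$y[match(pick, graph$nodes$id)],
    max_slots = slots_per_site
  )
}
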