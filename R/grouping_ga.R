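#' Enumerate candidate ambulance slots
#'
#' Expands candidate stations into individual ambulance slots: site j
#' with `max_slots` m contributes slots (j, 1) ... (j, m). With 35
#' stations of 5 slots this yields the 175-slot search space.
#'
#' @param sites data.frame from [place_candidate_sites()].
#' @return data.frame `slot_id, site_id, slot_index`.
#' @export
candidate_slots <- function(sites) {
  n <- rep(sites$site_id, sites$max_slots)
  idx <- unlist(lapply(sites$max_slots, seq_len))
  data.frame(slot_id = seq_along(n), site_id = n, slot_index = idx)
}

# Distinct site ids covered by a chromosome (vector of slot ids).
slot_sites <- function(slot_ids, slots) {
  sort(unique(slots$site_id[match(slot_ids, slots$slot_id)]))
}

# Weighted distance to the nearest of the given sites, per area.
nearest_site_dist <- function(od, site_ids) {
  cols <- match(as.character(site_ids), colnames(od))
  if (anyNA(cols)) stop("sites missing from the OD matrix: ",
                        paste(site_ids[is.na(cols)], collapse = ", "))
  d <- od[, cols[1]]
  for (j in cols[-1]) d <- pmin(d, od[, j])
  d
}

#' Fitness of a location set: total case-weighted network distance
#'
#' `F(s) = sum_i w_i * min_{j in sites(s)} d(i, j)` in person-metres,
#' the case-weighted p-median objective. Only the distinct sites of the
#' chromosome matter: a second slot at a station adds capacity, not
#' proximity, so duplicate slots leave the fitness unchanged.
#'
#' @param slot_ids integer vector of chosen slot ids (a chromosome).
#' @param od OD matrix (areas x sites, metres) with site-id colnames.
#' @param weights per-area case counts aligned with `od` rows.
#' @param slots slot table from [candidate_slots()].
#' @return fitness in person-metres.
#' @export
location_fitness <- function(slot_ids, od, weights, slots) {
  if (length(slot_ids) == 0L) stop("location set is empty")
  if (length(weights) != nrow(od)) {
    stop("weights must align with the OD matrix rows")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  sum(weights * nearest_site_dist(od, slot_sites(slot_ids, slots)))
}

#' GA configuration
#'
#' @param n number of ambulance slots to select.
#' @param population_size chromosomes per generation (>= 2).
#' @param generations number of GA cycles (the study ran 1500).
#' @param crossover_rate probability an offspring is bred by crossover
#'   rather than cloned from the better parent.
#' @param mutation_rate per-slot replacement probability.
#' @param elitism_count chromosomes carried over unchanged (>= 1, less
#'   than `population_size`); guarantees a non-increasing best fitness.
#' @param tournament_size parents are the best of this many uniform picks.
#' @param seed integer RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(n, population_size = 100, generations = 1500,
                      crossover_rate = 0.9, mutation_rate = 0.05,
                      elitism_count = 2, tournament_size = 3, seed = 1L) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (elitism_count < 1 || elitism_count >= population_size) {
    stop("need 1 <= elitism_count < population_size")
  }
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (n < 1) stop("n must be >= 1")
  structure(list(n = n, population_size = population_size,
                 generations = generations, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism_count = elitism_count,
                 tournament_size = tournament_size, seed = seed),
            class = "ga_config")
}

#' Initialise a GA population
#'
#' Uniform random n-subsets of the candidate slots, distinct where the
#' search space allows.
#'
#' @param config a `ga_config`.
#' @param slots slot table from [candidate_slots()].
#' @param seed optional seed (defaults to `config$seed`).
#' @return list of sorted integer slot-id vectors.
#' @export
init_population <- function(config, slots, seed = config$seed) {
  if (config$n > nrow(slots)) {
    stop("n exceeds the number of candidate slots")
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(config$population_size), function(i) {
    sort(sample(slots$slot_id, config$n))
  })
}

#' Grouping crossover: keep the intersection, fill greedily
#'
#' The child inherits every slot both parents share, then fills up to n
#' from the parents' symmetric difference, at each step adding the slot
#' with the best marginal fitness gain (largest reduction in case-weighted
#' distance). Ties break to the lowest site id, then slot index, making
#' the operator deterministic given its parents.
#'
#' @param p1,p2 parent chromosomes (equal length).
#' @param od,weights,slots fitness context as in [location_fitness()].
#' @param seed optional seed (unused by the deterministic fill; accepted
#'   for interface symmetry).
#' @return child chromosome (sorted slot ids).
#' @export
crossover_location_sets <- function(p1, p2, od, weights, slots, seed = NULL) {
  if (length(p1) != length(p2)) stop("parents must have equal length")
  if (!is.null(seed)) set.seed(seed)
  n <- length(p1)
  child <- intersect(p1, p2)
  pool <- setdiff(union(p1, p2), child)
  if (length(child) == n) return(sort(child))
  # order pool deterministically for tie-breaking
  pm <- slots[match(pool, slots$slot_id), ]
  pool <- pool[order(pm$site_id, pm$slot_index)]
  cur <- if (length(child)) {
    nearest_site_dist(od, slot_sites(child, slots))
  } else NULL
  while (length(child) < n) {
    best_f <- Inf; best_i <- 1L; best_d <- NULL
    for (i in seq_along(pool)) {
      scol <- as.character(slots$site_id[match(pool[i], slots$slot_id)])
      dcand <- if (is.null(cur)) od[, scol] else pmin(cur, od[, scol])
      f <- sum(weights * dcand)
      if (f < best_f) { best_f <- f; best_i <- i; best_d <- dcand }
    }
    child <- c(child, pool[best_i])
    pool <- pool[-best_i]
    cur <- best_d
  }
  sort(child)
}

#' Mutate a chromosome by uniform slot replacement
#'
#' Each slot is independently replaced with probability `rate` by a slot
#' drawn uniformly from those not currently in the chromosome; the
#' chromosome size is preserved. With no unused slot available the
#' chromosome is returned unchanged.
#'
#' @param slot_ids chromosome.
#' @param rate per-slot replacement probability in \[0, 1\].
#' @param slots slot table.
#' @param seed optional integer seed.
#' @return mutated chromosome (sorted slot ids).
#' @export
mutate_location_set <- function(slot_ids, rate, slots, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cur <- slot_ids
  hit <- stats::runif(length(cur)) < rate
  for (i in which(hit)) {
    unused <- setdiff(slots$slot_id, cur)
    if (length(unused) == 0L) break
    cur[i] <- if (length(unused) == 1L) unused else sample(unused, 1L)
  }
  sort(cur)
}

#' Run the grouping genetic algorithm
#'
#' Tournament selection, intersection-preserving greedy crossover,
#' uniform slot-replacement mutation and elitism, for a fixed number of
#' generations. Elitism makes the best-so-far fitness non-increasing
#' across the history. Fully reproducible given the config seed.
#'
#' @param config a `ga_config`.
#' @param od,weights OD matrix and case weights.
#' @param slots slot table from [candidate_slots()].
#' @return list of class `ga_result`: `best` (sorted slot ids),
#'   `best_sites`, `best_fitness` (person-metres), `history` (best
#'   fitness per generation), `evaluations`.
#' @export
evolve_locations <- function(config, od, weights, slots) {
  set.seed(config$seed)
  pop <- init_population(config, slots, seed = NULL)
  evals <- 0L
  fit <- vapply(pop, function(s) {
    location_fitness(s, od, weights, slots)
  }, numeric(1))
  evals <- evals + length(pop)
  history <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    elite_idx <- ord[seq_len(config$elitism_count)]
    newpop <- pop[elite_idx]
    newfit <- fit[elite_idx]
    while (length(newpop) < config$population_size) {
      pick <- function() {
        cand <- sample.int(length(pop), config$tournament_size, replace = TRUE)
        cand[which.min(fit[cand])]
      }
      i1 <- pick(); i2 <- pick()
      if (stats::runif(1) < config$crossover_rate) {
        child <- crossover_location_sets(pop[[i1]], pop[[i2]],
                                         od, weights, slots)
        evals <- evals + length(setdiff(union(pop[[i1]], pop[[i2]]),
                                        intersect(pop[[i1]], pop[[i2]])))
      } else {
        child <- if (fit[i1] <= fit[i2]) pop[[i1]] else pop[[i2]]
      }
      child <- mutate_location_set(child, config$mutation_rate, slots)
      newpop[[length(newpop) + 1L]] <- child
      newfit <- c(newfit, location_fitness(child, od, weights, slots))
      evals <- evals + 1L
    }
    pop <- newpop
    fit <- newfit
    history[gen] <- min(fit)
  }
  best <- which.min(fit)
  structure(list(best = pop[[best]],
                 best_sites = slot_sites(pop[[best]], slots),
                 best_fitness = fit[best],
                 history = history, evaluations = evals),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> best fitness %.1f person-km over %d generations (%d evaluations)\n",
    x$best_fitness / 1000, length(x$history), x$evaluations))
  cat("  sites:", paste(x$best_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Exact optimum by exhaustive enumeration
#'
#' Enumerates all n-subsets of distinct sites (duplicate slots cannot
#' lower the case-weighted distance, so enumeration over sites suffices)
#' and returns the minimiser; ties resolve to the lexicographically
#' smallest site set. Refuses instances with more than `max_subsets`
#' combinations.
#'
#' @param od OD matrix (areas x sites).
#' @param weights per-area case weights.
#' @param n subset size.
#' @param max_subsets refusal threshold (default 1e6).
#' @return list `sites` (sorted site ids), `fitness` (person-metres).
#' @export
brute_force_optimum <- function(od, weights, n, max_subsets = 1e6) {
  sites <- colnames(od)
  n_comb <- choose(length(sites), n)
  if (n_comb > max_subsets) {
    stop(sprintf("instance too large for enumeration: %.3g subsets", n_comb))
  }
  if (n > length(sites)) stop("n exceeds the number of sites")
  comb <- utils::combn(seq_along(sites), n)
  best_f <- Inf; best <- NULL
  for (j in seq_len(ncol(comb))) {
    d <- od[, comb[1, j]]
    for (c2 in comb[-1, j]) d <- pmin(d, od[, c2])
    f <- sum(weights * d)
    if (f < best_f) { best_f <- f; best <- comb[, j] }
  }
  list(sites = sites[best], fitness = best_f)
}
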