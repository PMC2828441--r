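test_that("fitness matches hand enumeration on the two-area instance", {
  h <- hand_instance()
  s12 <- c(1, 4)    # slot 1 of site 1, slot 1 of site 2
  expect_equal(location_fitness(s12, h$od, h$w, h$slots),
               2 * 1000 + 3 * 2000)   # = 8000
  expect_equal(location_fitness(s12, h$od, c(A = 0, B = 0), h$slots), 0)
  expect_error(location_fitness(integer(0), h$od, h$w, h$slots), "empty")
  expect_error(location_fitness(s12, h$od, c(-1, 1), h$slots),
               "non-negative")
})

test_that("duplicate slots at a site leave the fitness unchanged", {
  h <- hand_instance()
  one_slot <- location_fitness(c(1, 4), h$od, h$w, h$slots)
  many_slots <- location_fitness(c(1, 2, 3, 4), h$od, h$w, h$slots)
  expect_equal(one_slot, many_slots)
  sc <- small_city(seed = 21, n_sites = 6, slots_per_site = 3)
  set.seed(1)
  for (rep in 1:10) {
    sites_pick <- sample(sc$sites$site_id, 3)
    base <- sc$slots$slot_id[sc$slots$site_id %in% sites_pick &
                               sc$slots$slot_index == 1]
    extra <- sc$slots$slot_id[sc$slots$site_id == sites_pick[1] &
                                sc$slots$slot_index == 2]
    expect_equal(location_fitness(base, sc$od, sc$w, sc$slots),
                 location_fitness(c(base, extra), sc$od, sc$w, sc$slots))
  }
})

test_that("the full candidate set attains the nearest-site lower bound", {
  sc <- small_city(seed = 5)
  all_slots <- sc$slots$slot_id
  lb <- sum(sc$w * apply(sc$od, 1, min))
  expect_equal(location_fitness(all_slots, sc$od, sc$w, sc$slots), lb)
  # supermodular-style bound along random chains: more sites never hurt
  set.seed(7)
  for (rep in 1:20) {
    sizes <- sort(sample(1:nrow(sc$sites), 3))
    perm <- sample(all_slots)
    f <- vapply(sizes, function(n)
      location_fitness(perm[1:n], sc$od, sc$w, sc$slots), numeric(1))
    expect_true(all(diff(f) <= 1e-9))
    expect_true(all(f >= lb - 1e-9))
  }
})

test_that("population initialisation is valid, seeded and size-aware", {
  sc <- small_city(seed = 2, n_sites = 8, slots_per_site = 2)
  cfg <- ga_config(5, population_size = 40, generations = 10, seed = 3)
  p1 <- init_population(cfg, sc$slots)
  p2 <- init_population(cfg, sc$slots)
  expect_identical(p1, p2)
  expect_true(all(vapply(p1, length, integer(1)) == 5))
  expect_true(all(vapply(p1, anyDuplicated, integer(1)) == 0))
  expect_true(all(unlist(p1) %in% sc$slots$slot_id))
  # n equal to the slot count: every chromosome is the full set
  cfg_full <- ga_config(16, population_size = 5, generations = 1, seed = 1)
  pf <- init_population(cfg_full, sc$slots)
  expect_true(all(vapply(pf, function(s) identical(s, sort(sc$slots$slot_id)),
                         logical(1))))
  expect_error(init_population(ga_config(99, seed = 1), sc$slots), "exceeds")
})

test_that("crossover is idempotent and greedy on singletons", {
  h <- hand_instance()
  expect_equal(crossover_location_sets(c(1, 4), c(1, 4), h$od, h$w, h$slots),
               c(1, 4))
  # disjoint singleton parents: child is the better singleton
  f1 <- location_fitness(1, h$od, h$w, h$slots)  # site 1: 2*1000+3*5000
  f2 <- location_fitness(4, h$od, h$w, h$slots)  # site 2: 2*4000+3*2000
  expect_equal(f1, 17000); expect_equal(f2, 14000)
  expect_equal(crossover_location_sets(1, 4, h$od, h$w, h$slots), 4)
})

test_that("greedy crossover children are never worse than both parents", {
  sc <- small_city(seed = 31, n_sites = 10, slots_per_site = 1)
  set.seed(13)
  for (rep in 1:50) {
    p1 <- sort(sample(sc$slots$slot_id, 4))
    p2 <- sort(sample(sc$slots$slot_id, 4))
    ch <- crossover_location_sets(p1, p2, sc$od, sc$w, sc$slots)
    expect_length(ch, 4)
    expect_true(all(ch %in% union(p1, p2)))
    expect_true(all(intersect(p1, p2) %in% ch))
    fc <- location_fitness(ch, sc$od, sc$w, sc$slots)
    fmax <- max(location_fitness(p1, sc$od, sc$w, sc$slots),
                location_fitness(p2, sc$od, sc$w, sc$slots))
    expect_lte(fc, fmax + 1e-9)
  }
})

test_that("mutation preserves size, respects the rate and its limits", {
  sc <- small_city(seed = 41, n_sites = 30, slots_per_site = 2)
  s <- sort(sc$slots$slot_id[1:10])
  expect_identical(mutate_location_set(s, 0, sc$slots, seed = 1), s)
  # rate 1 with exactly one replacement available: deterministic swap at
  # the mutated position set
  small_slots <- sc$slots[1:11, ]
  m <- mutate_location_set(s, 1, small_slots, seed = 2)
  expect_length(m, 10)
  expect_true(all(m %in% small_slots$slot_id))
  # binomial expectation: mean replaced slots ~ n * rate
  set.seed(3)
  reps <- replicate(2000, {
    out <- mutate_location_set(s, 0.1, sc$slots)
    length(setdiff(out, s))
  })
  expect_equal(mean(reps), 10 * 0.1, tolerance = 0.05)
  expect_error(mutate_location_set(s, 1.5, sc$slots), "rate")
})

test_that("the GA finds the exact optimum on enumerable instances", {
  sc <- small_city(seed = 51, n_sites = 10, slots_per_site = 1)
  hits <- 0; n_inst <- 30
  for (i in seq_len(n_inst)) {
    set.seed(1000 + i)
    w <- stats::rpois(nrow(sc$od), 5)
    bf <- brute_force_optimum(sc$od, w, 3)           # C(10,3) = 120 subsets
    res <- evolve_locations(
      ga_config(3, population_size = 40, generations = 40,
                mutation_rate = 0.1, seed = i),
      sc$od, w, sc$slots)
    expect_gte(res$best_fitness, bf$fitness - 1e-9)  # never beats the oracle
    lb <- sum(w * apply(sc$od, 1, min))
    expect_gte(res$best_fitness, lb - 1e-9)          # never beats the bound
    if (abs(res$best_fitness - bf$fitness) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * n_inst))
})

test_that("GA history is non-increasing and runs reproduce bit-exactly", {
  sc <- small_city(seed = 61, n_sites = 8, slots_per_site = 2)
  cfg <- ga_config(5, population_size = 24, generations = 40, seed = 9)
  r1 <- evolve_locations(cfg, sc$od, sc$w, sc$slots)
  r2 <- evolve_locations(cfg, sc$od, sc$w, sc$slots)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 1e-9))
  expect_equal(r1$best_fitness, r1$history[length(r1$history)])
  # n = total slots: best fitness equals the full-set bound at once
  cfg_full <- ga_config(16, population_size = 4, generations = 2, seed = 1)
  rf <- evolve_locations(cfg_full, sc$od, sc$w, sc$slots)
  expect_equal(rf$best_fitness,
               sum(sc$w * apply(sc$od, 1, min)))
})

test_that("brute force enumerates exactly and refuses huge instances", {
  h <- hand_instance()
  b1 <- brute_force_optimum(h$od, h$w, 1)
  expect_equal(b1$sites, "2")             # 14000 beats 17000
  expect_equal(b1$fitness, 14000)
  b2 <- brute_force_optimum(h$od, h$w, 2)
  expect_equal(b2$fitness, 8000)
  sc <- small_city(seed = 71, n_sites = 10, slots_per_site = 1)
  expect_error(brute_force_optimum(sc$od, sc$w, 5, max_subsets = 100),
               "too large")
  # optimality: no enumerated subset beats the returned one
  b3 <- brute_force_optimum(sc$od, sc$w, 2)
  combs <- utils::combn(colnames(sc$od), 2)
  fits <- apply(combs, 2, function(s)
    sum(sc$w * pmin(sc$od[, s[1]], sc$od[, s[2]])))
  expect_equal(b3$fitness, min(fits))
})
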