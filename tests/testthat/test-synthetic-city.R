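test_that("unperturbed lattices have the expected node and edge counts", {
  g <- generate_road_graph(2, 2, 1000, 0, 0, seed = 1)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
  expect_true(all(abs(g$edges$length_m - 1000) < 1e-12))

  g <- generate_road_graph(5, 5, 500, 0, 0, seed = 1)
  expect_equal(nrow(g$nodes), 25)
  expect_equal(nrow(g$edges), 5 * 4 + 5 * 4)
})

test_that("edge removal thins the graph but never disconnects it", {
  for (seed in c(7, 8, 9)) {
    g <- generate_road_graph(10, 10, 500, 0.2, 0.1, seed = seed)
    expect_lte(nrow(g$edges), 180 - 0)          # never grows
    expect_gte(nrow(g$edges), 180 - 18)         # at most 10% removed
    expect_true(flood_fill_connected(g$nodes$id, g$edges))
    expect_true(all(g$edges$length_m > 0))
  }
})

test_that("generator arguments are validated", {
  expect_error(generate_road_graph(1, 5, 500), "n_rows")
  expect_error(generate_road_graph(5, 5, 500, jitter_frac = 0.5), "jitter")
  expect_error(generate_road_graph(5, 5, 500, edge_removal_frac = 0.3),
               "edge_removal_frac")
})

test_that("generators are pure functions of their seed", {
  g1 <- generate_road_graph(8, 8, 400, 0.2, 0.1, seed = 5)
  g2 <- generate_road_graph(8, 8, 400, 0.2, 0.1, seed = 5)
  expect_identical(g1, g2)
  a1 <- generate_census_areas(g1, 25, seed = 3)
  a2 <- generate_census_areas(g2, 25, seed = 3)
  expect_identical(a1, a2)
  d1 <- populate_demographics(a1, 10000, seed = 4)
  d2 <- populate_demographics(a2, 10000, seed = 4)
  expect_identical(d1, d2)
})

test_that("census areas partition the bounding box", {
  g <- generate_road_graph(6, 6, 600, 0.15, 0, seed = 2)
  bb <- graph_bbox(g)
  box_area <- (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])
  a1 <- generate_census_areas(g, 1, seed = 5)
  expect_equal(nrow(a1$table), 1)
  expect_equal(unname(a1$table$area_m2), unname(box_area))
  expect_equal(unname(a1$table$centroid_x),
               unname(mean(bb[c("xmin", "xmax")])))
  for (k in c(4, 50)) {
    a <- generate_census_areas(g, k, seed = k)
    expect_lt(abs(sum(a$table$area_m2) - box_area) / box_area, 1e-6)
    # envelope-centroid convention per polygon
    for (i in c(1L, k)) {
      expect_equal(unname(envelope_centroid(a$polygons[[i]])),
                   c(a$table$centroid_x[i], a$table$centroid_y[i]))
    }
  }
})

test_that("demographics conserve totals and nest age groups", {
  g <- generate_road_graph(5, 5, 800, 0.1, 0, seed = 1)
  a <- generate_census_areas(g, 1, seed = 1)
  a <- populate_demographics(a, 1000, seed = 1)
  expect_equal(sum(a$table$pop_total), 1000)

  a <- generate_census_areas(g, 40, seed = 2)
  a <- populate_demographics(a, 50000, seed = 2)
  expect_equal(sum(a$table$pop_total), 50000)
  expect_true(all(a$table$pop_80_over <= a$table$pop_65_over))
  expect_true(all(a$table$pop_total >= 0))
  # age-sex array agrees with the derived columns
  expect_equal(a$table$pop_total,
               as.integer(rowSums(a$age_sex[, , 1] + a$age_sex[, , 2])))
  expect_error(populate_demographics(a, -5), "non-negative")
  bad_profile <- default_age_profile() * 2
  expect_error(populate_demographics(a, 100, age_profile = bad_profile),
               "sum to 1")
})

test_that("study-scale area populations average city total over area count", {
  g <- generate_road_graph(20, 20, 1000, 0.2, 0.1, seed = 3)
  a <- generate_census_areas(g, 400, seed = 3)
  a <- populate_demographics(a, 814000 * 400 / 2076, seed = 3)
  expect_equal(mean(a$table$pop_total), 814000 / 2076, tolerance = 1e-6)
})

test_that("case counts follow the published model mean", {
  m <- niigata_demand_model()
  g <- generate_road_graph(4, 4, 500, 0, 0, seed = 1)
  a <- generate_census_areas(g, 2, seed = 1)
  a$table$pop_0_4 <- c(0, 100)
  a$table$pop_15_64 <- c(0, 1000)
  a$table$pop_80_over <- c(0, 50)
  a$table$companies_5plus <- c(0, 10)
  a <- simulate_case_counts(a, m, noise_sd = 0, seed = 1)
  # all-zero predictors: mean is the negative intercept, clipped to 0
  expect_equal(a$table$case_mean[1], -0.268)
  expect_equal(a$table$observed_cases[1], 0L)
  # direct evaluation: 0.6 + 21 + 5.1 + 4.33 - 0.268 = 30.762 -> 31
  expect_equal(a$table$case_mean[2], 30.762)
  expect_equal(a$table$observed_cases[2], 31L)
  b <- simulate_case_counts(a, m, noise_sd = 2, seed = 99)
  b2 <- simulate_case_counts(a, m, noise_sd = 2, seed = 99)
  expect_identical(b$table$observed_cases, b2$table$observed_cases)
  expect_true(all(b$table$observed_cases >= 0))
})

test_that("noise calibration has the closed form and the stated limits", {
  g <- generate_road_graph(5, 5, 700, 0.1, 0, seed = 4)
  a <- generate_census_areas(g, 30, seed = 4)
  a <- populate_demographics(a, 12000, seed = 4)
  m <- niigata_demand_model()
  mu <- predict_cases(m, predictor_table(a), clip_negative = FALSE)
  expect_equal(calibrate_noise_to_r2(a, m, 0.5), sd(mu))
  expect_lt(calibrate_noise_to_r2(a, m, 0.999), 0.05 * sd(mu))
  expect_error(calibrate_noise_to_r2(a, m, 1.2), "target_r2")
  # degenerate: identical predictors everywhere
  a$table$pop_0_4 <- 5; a$table$pop_15_64 <- 50
  a$table$pop_80_over <- 3; a$table$companies_5plus <- 2
  expect_error(calibrate_noise_to_r2(a, m, 0.7), "degenerate")
})

test_that("scattered case points are recovered exactly by point-in-polygon", {
  g <- generate_road_graph(6, 6, 500, 0.2, 0.05, seed = 6)
  a <- generate_census_areas(g, 50, seed = 9)
  a <- populate_demographics(a, 15000, seed = 6)
  m <- niigata_demand_model()
  a <- simulate_case_counts(a, m, calibrate_noise_to_r2(a, m, 0.71), seed = 7)
  expect_gt(sum(a$table$observed_cases), 0)
  pts <- scatter_case_points(a, seed = 8)
  expect_equal(nrow(pts), sum(a$table$observed_cases))
  counts <- count_points_in_polygons(pts, a)
  expect_equal(as.integer(counts), a$table$observed_cases)
  expect_equal(attr(counts, "unassigned"), 0L)
  # zero-case areas contribute no points
  zero <- a$table$area_id[a$table$observed_cases == 0]
  expect_false(any(pts$area_id %in% zero))
  expect_error(scatter_case_points(generate_census_areas(g, 3, 1)),
               "observed_cases")
})

test_that("candidate sites sit on network nodes with the full slot count", {
  g <- generate_road_graph(8, 8, 600, 0.2, 0.1, seed = 2)
  s <- place_candidate_sites(g, 35, 5, seed = 1)
  expect_equal(nrow(candidate_slots(s)), 175)
  s2 <- place_candidate_sites(g, 10, 2, seed = 3)
  expect_true(all(s2$node_id %in% g$nodes$id))
  expect_equal(s2$x, g$nodes$x[match(s2$node_id, g$nodes$id)])
  expect_equal(nrow(place_candidate_sites(g, 1, 1, seed = 1)), 1)
  expect_error(place_candidate_sites(g, 1000, 1, seed = 1), "exceeds")
})
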