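# Build a cohort table with the same count vector for both sexes.
flat_cohort <- function(counts, admin_id = 1) {
  do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(admin_id = admin_id, sex = s, band = age_bands(),
               count = counts)
  }))
}

test_that("cohort-change ratios follow cohorts forward", {
  t0 <- flat_cohort(c(rep(100, 17), 50))
  t5 <- t0
  # shift every cohort up one band unchanged; empty the 85+ source
  t0$count[t0$band == "85+"] <- 0
  t5$count <- ave(t0$count, t5$sex, FUN = function(x) c(x[1], x[-18]))
  rr <- cohort_change_ratios(t0, t5)
  expect_true(all(abs(rr$ratio - 1) < 1e-12))
  # a specific shrinking cohort: 200 aged 60-64 -> 180 aged 65-69
  t0b <- flat_cohort(rep(200, 18)); t5b <- flat_cohort(rep(200, 18))
  t5b$count[t5b$band == "65-69"] <- 180
  rrb <- cohort_change_ratios(t0b, t5b)
  expect_equal(rrb$ratio[rrb$band == "65-69" & rrb$sex == "male"], 0.9)
  expect_true(all(rrb$ratio > 0))
  # zero source cohort floors with a warning
  t0c <- flat_cohort(c(0, rep(100, 17)))
  expect_warning(rrc <- cohort_change_ratios(t0c, t5b), "floored")
  expect_true(all(rrc$ratio > 0))
})

test_that("births follow the flat-rate fertility arithmetic", {
  rr <- data.frame(sex = rep(c("male", "female"), each = 17),
                   band = rep(age_bands()[-1], 2), ratio = 1)
  p <- projection_params(rr, total_fertility_rate = 1.22,
                         sex_ratio_at_birth = 105, childhood_survival = 1)
  tab <- flat_cohort(rep(0, 18))
  fertile <- tab$sex == "female" &
    tab$band %in% c("15-19", "20-24", "25-29", "30-34", "35-39",
                    "40-44", "45-49")
  tab$count[fertile] <- 1000 / 7
  nxt <- project_step(tab, p)
  expect_equal(sum(nxt$count[nxt$band == "0-4"]), 1000 * (1.22 / 35) * 5,
               tolerance = 1e-10)
  # sex split 105:100
  m <- sum(nxt$count[nxt$band == "0-4" & nxt$sex == "male"])
  f <- sum(nxt$count[nxt$band == "0-4" & nxt$sex == "female"])
  expect_equal(m / f, 1.05, tolerance = 1e-10)
  # zero fertility empties the youngest band
  p0 <- projection_params(rr, total_fertility_rate = 0)
  nxt0 <- project_step(tab, p0)
  expect_true(all(nxt0$count[nxt0$band == "0-4"] == 0))
})

test_that("a stationary population is a fixed point of the projection", {
  # equal bands c, with the open-ended band at its stationary level
  counts <- c(rep(100, 17), 60)
  t0 <- flat_cohort(counts)
  rr <- cohort_change_ratios(t0, t0)
  # replacement births: force fertility so that births = the 0-4 cohort
  women <- sum(t0$count[t0$sex == "female" &
                          t0$band %in% c("15-19", "20-24", "25-29", "30-34",
                                         "35-39", "40-44", "45-49")])
  tfr <- 200 / (women * 5 / 35)   # both sexes: 100 male + 100 female
  p <- projection_params(rr, total_fertility_rate = tfr,
                         sex_ratio_at_birth = 100, childhood_survival = 1)
  nxt <- project_step(t0, p)
  nxt <- nxt[order(nxt$admin_id, nxt$sex, nxt$band), ]
  ref <- cohort_table(t0); ref <- ref[order(ref$admin_id, ref$sex, ref$band), ]
  expect_equal(nxt$count, ref$count, tolerance = 1e-10)
  # applied repeatedly, every period is identical
  series <- project_series(t0, t0, p, horizon_year = 2025)
  expect_equal(names(series), c("2010", "2015", "2020", "2025"))
  expect_equal(series[["2010"]]$count, series[["2025"]]$count,
               tolerance = 1e-10)
})

test_that("sub-replacement regimes decline monotonically", {
  t0 <- flat_cohort(c(rep(100, 17), 60))
  rr <- cohort_change_ratios(t0, t0)
  rr$ratio <- pmin(rr$ratio, 0.97)
  p <- projection_params(rr, total_fertility_rate = 1.22)
  series <- project_series(t0, t0, p, horizon_year = 2040)
  totals <- vapply(series, function(s) sum(s$count), numeric(1))
  expect_true(all(diff(totals) < 0))
  expect_true(all(vapply(series, function(s) all(s$count >= 0), logical(1))))
  expect_error(project_series(t0, t0, p, horizon_year = 2005), "horizon")
  expect_error(project_series(t0, t0, p, horizon_year = 2013), "multiple")
  expect_length(project_series(t0, t0, p, horizon_year = 2010), 1)
})

test_that("disaggregation scales areas by admin growth and conserves totals", {
  g <- generate_road_graph(6, 6, 600, 0.1, 0, seed = 11)
  a <- generate_census_areas(g, 24, seed = 11)
  a <- populate_demographics(a, 30000, seed = 11)
  membership <- make_admin_membership(a, 3, seed = 1)
  base <- areas_to_cohort_table(a, membership)
  expect_equal(sum(base$count), 30000)

  # growth factor 1 everywhere: predictors unchanged
  same <- disaggregate_growth(list(`2010` = base), base, a, membership)
  pt0 <- predictor_table(a)
  expect_equal(same[["2010"]]$pop_80_over, pt0$pop_80_over)
  expect_equal(same[["2010"]]$pop_15_64, pt0$pop_15_64)

  # doubling one admin's 80+ bands doubles member areas' 80+ counts
  proj <- base
  dbl <- proj$admin_id == 1 & proj$band %in% c("80-84", "85+")
  proj$count[dbl] <- proj$count[dbl] * 2
  out <- disaggregate_growth(list(`2015` = proj), base, a, membership)
  in1 <- membership$admin_id[match(pt0$area_id, membership$area_id)] == 1
  expect_equal(out[["2015"]]$pop_80_over[in1], 2 * pt0$pop_80_over[in1])
  expect_equal(out[["2015"]]$pop_80_over[!in1], pt0$pop_80_over[!in1])
  # conservation: member-area sums equal the admin projection
  arr <- attr(out[["2015"]], "age_sex")
  scaled_tot <- sum(arr[in1, c("80-84", "85+"), ])
  expect_equal(scaled_tot, sum(proj$count[dbl]), tolerance = 1e-9)
  # companies frozen by default, scalable on request
  expect_equal(out[["2015"]]$companies_5plus, pt0$companies_5plus)
  out2 <- disaggregate_growth(list(`2015` = proj), base, a, membership,
                              company_growth = 1.5)
  expect_equal(out2[["2015"]]$companies_5plus, 1.5 * pt0$companies_5plus)

  expect_error(disaggregate_growth(list(`2015` = proj), base, a,
                                   membership[-1, ]), "mapped")
})

test_that("full-table conservation holds across all periods and bands", {
  g <- generate_road_graph(5, 5, 700, 0.1, 0, seed = 12)
  a <- generate_census_areas(g, 20, seed = 12)
  a <- populate_demographics(a, 20000, seed = 12)
  membership <- make_admin_membership(a, 4, seed = 2)
  base <- areas_to_cohort_table(a, membership)
  earlier <- base
  earlier$count <- round(earlier$count * 1.05)
  series <- project_series(earlier, base, horizon_year = 2020)
  out <- disaggregate_growth(series, base, a, membership)
  for (p in names(series)) {
    arr <- attr(out[[p]], "age_sex")
    admin_of <- membership$admin_id[match(a$table$area_id,
                                          membership$area_id)]
    proj <- cohort_table(series[[p]])
    for (ad in unique(admin_of)) {
      got <- sum(arr[admin_of == ad, , ])
      want <- sum(proj$count[proj$admin_id == ad])
      # equal up to cohorts that are empty at the census-area level
      expect_lte(got, want + 1e-6)
      expect_gt(got, 0)
    }
  }
})
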