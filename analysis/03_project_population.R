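#!/usr/bin/env Rscript
# Project the city's population forward in 5-year steps with
# Hamilton-Perry cohort-change ratios (estimated from two census time
# points) and low fertility (TFR 1.22), disaggregate administrative-area
# growth back to census areas, and predict per-area EMS demand for each
# period with the fitted model.

source(file.path("analysis", "_common.R"))

city <- build_city()
dat <- cbind(predictor_table(city$areas),
             observed_cases = city$areas$table$observed_cases)
model <- stepwise_select(dat, "observed_cases",
                         c("pop_0_4", "pop_15_64", "pop_80_over",
                           "companies_5plus"))

membership <- make_admin_membership(city$areas, n_admin = 8,
                                    seed = MASTER_SEED + 10L)
base <- areas_to_cohort_table(city$areas, membership)

# Emulate the earlier census with a mild ageing drift (younger cohorts
# slightly larger five years ago), so the estimated cohort-change ratios
# encode ageing plus attrition.
earlier <- base
drift <- seq(1.06, 0.94, length.out = length(age_bands()))
earlier$count <- earlier$count * drift[match(as.character(earlier$band),
                                             age_bands())]

params <- projection_params(cohort_change_ratios(earlier, base),
                            total_fertility_rate = 1.22)
series <- project_series(earlier, base, params, horizon_year = 2040)
predictors <- disaggregate_growth(series, base, city$areas, membership)

demand <- do.call(rbind, lapply(names(predictors), function(p) {
  data.frame(period = p, area_id = predictors[[p]]$area_id,
             predicted_cases = predict_cases(model, predictors[[p]]))
}))
utils::write.csv(demand, file.path(RESULTS_DIR, "predicted_demand_by_period.csv"),
                 row.names = FALSE)

totals <- data.frame(
  period = names(series),
  population = vapply(series, function(s) sum(s$count), numeric(1)),
  pop_80_over = vapply(predictors, function(pt) sum(pt$pop_80_over),
                       numeric(1)),
  predicted_cases = vapply(split(demand$predicted_cases, demand$period),
                           sum, numeric(1))[names(series)]
)
utils::write.csv(totals, file.path(RESULTS_DIR, "projection_totals.csv"),
                 row.names = FALSE)

cat("projected totals per period:\n")
print(totals, digits = 4, row.names = FALSE)
peak <- totals$period[which.max(totals$predicted_cases)]
cat(sprintf("predicted EMS demand peaks in %s (%.0f cases vs %d observed now)\n",
            peak, max(totals$predicted_cases),
            sum(city$areas$table$observed_cases)))
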