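#' Validate a cohort table
#'
#' A cohort table is a long-format data.frame with columns
#' `admin_id, sex, band, count`: population by sex and 5-year age band
#' (`0-4` ... `85+`, the last open-ended) for each administrative area at
#' one census time point.
#'
#' @param tab data.frame to validate.
#' @return the table, with `band` as an ordered factor over [age_bands()].
#' @export
cohort_table <- function(tab) {
  need <- c("admin_id", "sex", "band", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$count < 0)) stop("cohort counts must be non-negative")
  if (!all(tab$band %in% age_bands())) {
    stop("unknown age bands: ",
         paste(setdiff(unique(tab$band), age_bands()), collapse = ", "))
  }
  tab$band <- factor(tab$band, levels = age_bands(), ordered = TRUE)
  tab$sex <- as.character(tab$sex)
  dup <- duplicated(tab[, c("admin_id", "sex", "band")])
  if (any(dup)) stop("duplicate admin_id x sex x band rows")
  tab
}

# Sum counts over admin areas -> matrix band x sex.
pool_cohorts <- function(tab) {
  tapply(tab$count, list(band = tab$band, sex = tab$sex), sum, default = 0)
}

#' Cohort-change ratios from two censuses five years apart
#'
#' Hamilton-Perry ratios: for each sex and band `b`, the ratio of the
#' cohort's size at the later census to the same cohort's size (band
#' `b - 1`) at the earlier census, pooled over administrative areas. The
#' ratios absorb mortality and net migration jointly. The open-ended 85+
#' band pools the two oldest source bands (80-84 and 85+). A zero
#' denominator yields the configurable `ratio_floor` with a warning.
#'
#' @param pop_t0,pop_t5 cohort tables five years apart.
#' @param ratio_floor value used when a source cohort is empty.
#' @return data.frame `sex, band, ratio` for bands `5-9` ... `85+`.
#' @export
cohort_change_ratios <- function(pop_t0, pop_t5, ratio_floor = 1e-6) {
  pop_t0 <- cohort_table(pop_t0); pop_t5 <- cohort_table(pop_t5)
  m0 <- pool_cohorts(pop_t0); m5 <- pool_cohorts(pop_t5)
  if (!identical(dimnames(m0), dimnames(m5))) {
    stop("the two censuses must cover the same sexes and bands")
  }
  bands <- age_bands()
  nb <- length(bands)
  out <- list()
  floored <- FALSE
  for (sx in colnames(m0)) {
    num <- m5[bands[-1], sx]
    den <- m0[bands[-nb], sx]
    # open-ended band: survivors of both 80-84 and 85+ end up in 85+
    den[nb - 1L] <- m0[bands[nb - 1L], sx] + m0[bands[nb], sx]
    ratio <- num / den
    bad <- !is.finite(ratio) | den == 0
    if (any(bad)) { floored <- TRUE; ratio[bad] <- ratio_floor }
    ratio <- pmax(ratio, ratio_floor)
    out[[sx]] <- data.frame(sex = sx, band = bands[-1], ratio = ratio,
                            row.names = NULL)
  }
  if (floored) warning("zero source cohorts: ratio floored at ", ratio_floor)
  do.call(rbind, out)
}

#' Projection parameters
#'
#' @param ratios data.frame from [cohort_change_ratios()].
#' @param total_fertility_rate lifetime births per woman; the study
#'   locality's value is 1.22.
#' @param sex_ratio_at_birth male births per 100 female births.
#' @param childhood_survival fraction of births surviving into the 0-4
#'   band at the end of the 5-year step.
#' @return list of class `projection_params`.
#' @export
projection_params <- function(ratios, total_fertility_rate = 1.22,
                              sex_ratio_at_birth = 105,
                              childhood_survival = 0.995) {
  if (any(ratios$ratio <= 0)) stop("cohort-change ratios must be positive")
  if (total_fertility_rate < 0) stop("total_fertility_rate must be >= 0")
  if (childhood_survival <= 0 || childhood_survival > 1) {
    stop("childhood_survival must lie in (0, 1]")
  }
  structure(list(ratios = ratios,
                 total_fertility_rate = total_fertility_rate,
                 sex_ratio_at_birth = sex_ratio_at_birth,
                 childhood_survival = childhood_survival),
            class = "projection_params")
}

#' Advance a cohort table by one 5-year step
#'
#' Each cohort moves up one band scaled by its sex-specific
#' cohort-change ratio; the 85+ band receives the survivors of both 80-84
#' and 85+. Births over the step are
#' `sum(women aged 15-49) * (TFR / 35) * 5` (a flat annual rate over the
#' 35 reproductive years, since only a single total fertility rate is
#' available), split by the sex ratio at birth and survived into 0-4.
#'
#' @param pop_t cohort table at time t.
#' @param params a `projection_params`.
#' @return cohort table at t + 5.
#' @export
project_step <- function(pop_t, params) {
  pop_t <- cohort_table(pop_t)
  bands <- age_bands(); nb <- length(bands)
  rmap <- params$ratios
  admins <- unique(pop_t$admin_id)
  sexes <- unique(pop_t$sex)
  fertile <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
  pr_m <- params$sex_ratio_at_birth / (params$sex_ratio_at_birth + 100)
  out <- list()
  for (ad in admins) {
    sub <- pop_t[pop_t$admin_id == ad, ]
    women <- sum(sub$count[sub$sex == "female" & sub$band %in% fertile])
    births <- women * (params$total_fertility_rate / 35) * 5
    for (sx in sexes) {
      cnt <- stats::setNames(rep(0, nb), bands)
      have <- sub[sub$sex == sx, ]
      cnt[as.character(have$band)] <- have$count
      rr <- rmap$ratio[rmap$sex == sx][match(bands[-1], rmap$band[rmap$sex == sx])]
      new <- stats::setNames(rep(0, nb), bands)
      new[bands[2:(nb - 1L)]] <- cnt[bands[1:(nb - 2L)]] * rr[1:(nb - 2L)]
      new[bands[nb]] <- (cnt[bands[nb - 1L]] + cnt[bands[nb]]) * rr[nb - 1L]
      sex_births <- births * if (sx == "male") pr_m else (1 - pr_m)
      new[bands[1L]] <- sex_births * params$childhood_survival
      out[[length(out) + 1L]] <- data.frame(
        admin_id = ad, sex = sx, band = bands, count = unname(new),
        row.names = NULL)
    }
  }
  cohort_table(do.call(rbind, out))
}

#' Project a population series in 5-year steps
#'
#' Estimates cohort-change ratios once from the two base censuses and
#' applies them repeatedly from the later census out to the horizon.
#'
#' @param pop_2000,pop_2005 cohort tables for the two base censuses.
#' @param params optional `projection_params`; if NULL, built from the
#'   two base tables with default fertility settings.
#' @param horizon_year last projected year; a multiple of 5, >= 2010.
#' @param base_year year of the later base census (default 2005).
#' @return named list of cohort tables, one per projected period
#'   ("2010", "2015", ...).
#' @export
project_series <- function(pop_2000, pop_2005, params = NULL,
                           horizon_year = 2040, base_year = 2005) {
  if (horizon_year < base_year + 5) {
    stop("horizon_year must be at least one 5-year step after the base")
  }
  if (horizon_year %% 5 != 0) stop("horizon_year must be a multiple of 5")
  if (is.null(params)) {
    params <- projection_params(cohort_change_ratios(pop_2000, pop_2005))
  }
  years <- seq(base_year + 5, horizon_year, by = 5)
  out <- vector("list", length(years))
  names(out) <- years
  cur <- pop_2005
  for (i in seq_along(years)) {
    cur <- project_step(cur, params)
    out[[i]] <- cur
  }
  out
}

#' Disaggregate administrative-area growth to census areas
#'
#' Scales each census area's sex-by-band counts by the band-specific
#' growth factor of the administrative area it belongs to (projected /
#' base count), then recomputes the demand-model predictors. Company
#' counts are held at baseline (socio-economic variables are kept
#' consistent across periods) unless a growth multiplier is given.
#'
#' @param admin_projection list of projected cohort tables from
#'   [project_series()].
#' @param admin_base the base-year cohort table the projection started
#'   from.
#' @param areas a populated `census_areas` object.
#' @param membership data.frame `area_id, admin_id` mapping every census
#'   area to exactly one administrative area.
#' @param company_growth multiplier applied to company counts per period
#'   (default 1 = frozen).
#' @return named list (per period) of predictor tables
#'   (`area_id, pop_0_4, pop_15_64, pop_80_over, companies_5plus`), each
#'   with the scaled area x band x sex array attached as attribute
#'   `"age_sex"`.
#' @export
disaggregate_growth <- function(admin_projection, admin_base, areas,
                                membership, company_growth = 1) {
  admin_base <- cohort_table(admin_base)
  tab <- areas$table
  if (!all(tab$area_id %in% membership$area_id)) {
    stop("every census area must be mapped to an administrative area")
  }
  admin_of <- membership$admin_id[match(tab$area_id, membership$area_id)]
  bands <- age_bands()
  sexes <- c("male", "female")
  base_arr <- admin_cohort_array(admin_base, bands, sexes)
  out <- vector("list", length(admin_projection))
  names(out) <- names(admin_projection)
  i1564 <- bands %in% c("15-19", "20-24", "25-29", "30-34", "35-39",
                        "40-44", "45-49", "50-54", "55-59", "60-64")
  i80 <- bands %in% c("80-84", "85+")
  for (p in names(admin_projection)) {
    proj_arr <- admin_cohort_array(cohort_table(admin_projection[[p]]),
                                   bands, sexes)
    growth <- proj_arr / base_arr
    growth[base_arr == 0] <- 1      # empty base cohorts carry no growth
    admin_idx <- match(as.character(admin_of), dimnames(growth)[[1]])
    if (anyNA(admin_idx)) {
      stop("membership refers to admin areas absent from the base census")
    }
    scaled <- areas$age_sex
    for (s in seq_along(sexes)) {
      g <- growth[admin_idx, , s]
      if (is.null(dim(g))) g <- matrix(g, nrow = length(admin_idx))
      scaled[, , s] <- areas$age_sex[, , s] * g
    }
    band_tot <- scaled[, , 1L] + scaled[, , 2L]
    if (is.null(dim(band_tot))) band_tot <- matrix(band_tot, nrow = 1L)
    pt <- data.frame(
      area_id = tab$area_id,
      pop_0_4 = band_tot[, 1L],
      pop_15_64 = rowSums(band_tot[, i1564, drop = FALSE]),
      pop_80_over = rowSums(band_tot[, i80, drop = FALSE]),
      companies_5plus = tab$companies_5plus * company_growth
    )
    attr(pt, "age_sex") <- scaled
    out[[p]] <- pt
  }
  out
}

# Cohort table -> array [admin, band, sex], admins in sorted order.
admin_cohort_array <- function(tab, bands, sexes) {
  admins <- sort(unique(tab$admin_id))
  arr <- array(0, dim = c(length(admins), length(bands), length(sexes)),
               dimnames = list(admins, bands, sexes))
  idx <- cbind(match(tab$admin_id, admins),
               match(as.character(tab$band), bands),
               match(tab$sex, sexes))
  arr[idx] <- tab$count
  arr
}

#' Assign census areas to administrative areas
#'
#' Partitions census areas into `n_admin` administrative areas by
#' k-means clustering of their centroids, a stand-in for the
#' administrative geography of a real city.
#'
#' @param areas a `census_areas` object.
#' @param n_admin number of administrative areas (the study city has 38).
#' @param seed integer RNG seed.
#' @return data.frame `area_id, admin_id`.
#' @export
make_admin_membership <- function(areas, n_admin = 38, seed = 1L) {
  set.seed(seed)
  xy <- cbind(areas$table$centroid_x, areas$table$centroid_y)
  n_admin <- min(n_admin, nrow(xy))
  km <- stats::kmeans(xy, centers = n_admin, nstart = 5)
  data.frame(area_id = areas$table$area_id, admin_id = km$cluster)
}

#' Aggregate census-area demographics into an administrative cohort table
#'
#' @param areas a populated `census_areas` object.
#' @param membership data.frame `area_id, admin_id`.
#' @return a cohort table (`admin_id, sex, band, count`).
#' @export
areas_to_cohort_table <- function(areas, membership) {
  admin_of <- membership$admin_id[match(areas$table$area_id,
                                        membership$area_id)]
  bands <- age_bands(); sexes <- c("male", "female")
  out <- list()
  for (s in seq_along(sexes)) {
    m <- rowsum(areas$age_sex[, , s], admin_of)
    for (b in seq_along(bands)) {
      out[[length(out) + 1L]] <- data.frame(
        admin_id = as.integer(rownames(m)), sex = sexes[s],
        band = bands[b], count = m[, b], row.names = NULL)
    }
  }
  cohort_table(do.call(rbind, out))
}
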