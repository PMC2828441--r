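#' Construct a demand model
#'
#' A linear model of per-area EMS case counts: intercept plus one
#' coefficient per selected predictor, with standard errors, p-values and
#' the coefficient of multiple determination.
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector of slopes.
#' @param standard_errors,p_values named numeric vectors aligned with
#'   `c("(Intercept)", names(coefficients))`.
#' @param r_squared coefficient of determination in \[0, 1\].
#' @param selected_predictors predictor names in selection order.
#' @param response_unit free-text note of what the response counts are
#'   (e.g. "cases per 9 months").
#' @return object of class `demand_model`.
#' @export
demand_model <- function(intercept, coefficients,
                         standard_errors = NULL, p_values = NULL,
                         r_squared = NA_real_,
                         selected_predictors = names(coefficients),
                         response_unit = "cases") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  full <- c("(Intercept)", names(coefficients))
  for (v in list(standard_errors, p_values)) {
    if (!is.null(v) && !identical(sort(names(v)), sort(full))) {
      stop("standard_errors and p_values need one entry per coefficient")
    }
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 standard_errors = standard_errors, p_values = p_values,
                 r_squared = r_squared,
                 selected_predictors = selected_predictors,
                 response_unit = response_unit),
            class = "demand_model")
}

#' @export
print.demand_model <- function(x, ...) {
  cat("<demand_model>  y =", format(x$intercept, digits = 4))
  for (nm in names(x$coefficients)) {
    cat(sprintf(" %+g*%s", x$coefficients[[nm]], nm))
  }
  cat(sprintf("\n  R^2 = %s; response: %s\n",
              format(x$r_squared, digits = 3), x$response_unit))
  invisible(x)
}

#' The published Niigata EMS demand model
#'
#' The stepwise-OLS fit reported for Niigata City's 2076 census small
#' areas (EMS cases, April-December 2007):
#' `y = 0.006*pop_0_4 + 0.021*pop_15_64 + 0.102*pop_80_over +
#' 0.433*companies_5plus - 0.268`, with R-squared 0.71. Used as the
#' generating mean of the synthetic-city case counts and as the reference
#' for parameter-recovery checks.
#'
#' @return a `demand_model`.
#' @export
niigata_demand_model <- function() {
  co <- c(pop_0_4 = 0.006, pop_15_64 = 0.021,
          pop_80_over = 0.102, companies_5plus = 0.433)
  se <- c("(Intercept)" = NA_real_, pop_0_4 = 0.001, pop_15_64 = 0.006,
          pop_80_over = 0.006, companies_5plus = 0.013)
  demand_model(intercept = -0.268, coefficients = co,
               standard_errors = se,
               r_squared = 0.71,
               response_unit = "cases per 9 months")
}

#' Ordinary least squares fit of the demand model
#'
#' Fits case counts on the given predictors with an intercept. Standard
#' errors and p-values are the usual normal-theory ones from
#' `sigma^2 (X'X)^{-1}`. A zero-variance response yields zero slopes and
#' R-squared defined as 0.
#'
#' @param data data.frame containing the response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @return a `demand_model` with the fitted `lm` attached as
#'   attribute `"fit"`.
#' @export
fit_ols <- function(data, response, predictors) {
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) < length(predictors) + 2L) {
    stop("need at least p + 2 rows to fit p predictors")
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(seq_len(ncol(X) + 1L), piv) - 1L
    stop("design matrix is rank deficient; collinear columns: ",
         paste(predictors[bad[bad > 0]], collapse = ", "))
  }
  fm <- stats::as.formula(paste(
    response, "~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- stats::lm(fm, data = data)
  # summary.lm warns on noiseless fits; perfect recovery is legitimate here
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  co <- cf[-1, 1]
  names(co) <- predictors
  se <- cf[, 2]; pv <- cf[, 4]
  names(se) <- names(pv) <- c("(Intercept)", predictors)
  r2 <- if (stats::var(data[[response]]) == 0) 0 else sm$r.squared
  m <- demand_model(intercept = unname(cf[1, 1]), coefficients = co,
                    standard_errors = se, p_values = pv, r_squared = r2)
  attr(m, "fit") <- fit
  m
}

# Partial-F p-value for adding `cand` to the model with `current`
# predictors: with a single added column this is the square of its t
# statistic, F(1, n - p - 1).
add_term_pvalue <- function(data, response, current, cand) {
  fit <- attr(fit_ols(data, response, c(current, cand)), "fit")
  cf <- summary(fit)$coefficients
  cf[nrow(cf), 4]
}

#' Stepwise predictor selection by partial F tests
#'
#' Forward-entry / backward-removal stepwise selection in the style of
#' classic statistical packages: at each cycle the candidate whose
#' partial-F p-value (given the current model) is smallest enters if it is
#' below `p_enter`; then any included predictor whose partial-F p-value
#' rises above `p_remove` is removed, worst first. The loop runs until no
#' change; the returned model is refitted on the final predictor set.
#'
#' @param data data.frame with response and candidate columns.
#' @param response response column name.
#' @param candidates character vector of candidate predictor names.
#' @param p_enter,p_remove entry/removal thresholds;
#'   `p_enter <= p_remove` is required to prevent cycling (defaults 0.05
#'   and 0.10).
#' @return a `demand_model`; `selected_predictors` records entry order.
#' @export
stepwise_select <- function(data, response, candidates,
                            p_enter = 0.05, p_remove = 0.10) {
  if (p_enter > p_remove) {
    stop("p_enter must be <= p_remove to prevent cycling")
  }
  current <- character(0)
  seen <- character(0)
  repeat {
    key <- paste(sort(current), collapse = "|")
    if (key %in% seen) {
      stop("stepwise selection revisited a predictor set: cycling detected")
    }
    seen <- c(seen, key)
    changed <- FALSE
    # forward entry
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      pv <- vapply(pool, function(cand)
        add_term_pvalue(data, response, current, cand), numeric(1))
      if (min(pv) < p_enter) {
        current <- c(current, pool[which.min(pv)])
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (length(current) == 0L) break
      fit <- attr(fit_ols(data, response, current), "fit")
      pv <- summary(fit)$coefficients[-1, 4]
      if (max(pv) > p_remove) {
        current <- current[-which.max(pv)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(current) == 0L) {
    y <- data[[response]]
    return(demand_model(intercept = mean(y),
                        coefficients = stats::setNames(numeric(0), character(0)),
                        r_squared = 0,
                        selected_predictors = character(0)))
  }
  m <- fit_ols(data, response, current)
  m$selected_predictors <- current
  m
}

#' Predict per-area case counts from a demand model
#'
#' Evaluates `y_hat = b0 + sum_j b_j x_j` for every row. For planning,
#' negative predictions are clipped at zero by default (the intercept is
#' negative, so near-empty areas can go below zero); the raw affine value
#' is kept in the `"raw"` attribute for diagnostics.
#'
#' @param model a `demand_model`.
#' @param table data.frame containing all selected predictor columns.
#' @param clip_negative clip predictions at 0 (default TRUE).
#' @return numeric vector of predictions, with attribute `"raw"`.
#' @export
predict_cases <- function(model, table, clip_negative = TRUE) {
  need <- names(model$coefficients)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("prediction table is missing predictor columns: ",
         paste(miss, collapse = ", "))
  }
  raw <- rep(model$intercept, nrow(table))
  for (nm in need) raw <- raw + model$coefficients[[nm]] * table[[nm]]
  out <- if (clip_negative) pmax(0, raw) else raw
  attr(out, "raw") <- raw
  out
}

#' Serialise a demand model to JSON
#' @param model a `demand_model`.
#' @param path file path to write.
#' @return the path, invisibly.
#' @export
write_demand_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         standard_errors = as.list(model$standard_errors),
         p_values = as.list(model$p_values),
         r_squared = model$r_squared,
         selected_predictors = model$selected_predictors,
         response_unit = model$response_unit),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
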