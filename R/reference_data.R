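#' Published demographic breakdown of the Niigata 2007 EMS cases
#'
#' The published age- and sex-group user counts and monthly users per
#' 1,000 population for the 21,211 geocoded pre-hospital emergency cases
#' attended in Niigata City between April and December 2007. Shipped as a
#' plain CSV in `extdata`; used to verify derived shares (e.g. the 85+
#' share of cases) and to illustrate the steep rise in case rates beyond
#' age 55.
#'
#' @return data.frame `category, group, users, monthly_users_per_1000`.
#' @export
niigata_case_demographics <- function() {
  utils::read.csv(system.file("extdata", "niigata_2007_case_demographics.csv",
                              package = "emsloc", mustWork = TRUE))
}

#' Share of cases in selected groups of a case-demographics table
#'
#' Computes each requested group's percentage of the total case count
#' (including unknown-group cases in the denominator, as published
#' percentages do).
#'
#' @param tbl table in the format of [niigata_case_demographics()].
#' @param category `"age"` or `"sex"`.
#' @param groups character vector of group labels to pool.
#' @return percentage (0-100) of total cases.
#' @export
case_share <- function(tbl, category, groups) {
  total <- sum(tbl$users[tbl$category == category])
  sel <- tbl$category == category & tbl$group %in% groups
  100 * sum(tbl$users[sel]) / total
}
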