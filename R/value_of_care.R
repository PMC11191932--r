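#' Observed and expected mortality for a cohort
#'
#' Observed mortality is the composite count of in-hospital deaths and
#' discharges to inpatient or outpatient hospice. Expected mortality is the
#' sum of model-predicted hospital-mortality probabilities over the cohort —
#' the standard risk-adjusted construction.
#'
#' @param cohort Non-empty admission table with `died_in_hospital`,
#'   `discharged_to_hospice` and (for the ratio) `risk_mortality`.
#' @return `observed_mortality()`: integer count. `expected_mortality()`:
#'   numeric sum of predicted probabilities.
#' @export
observed_mortality <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  sum(cohort$died_in_hospital | cohort$discharged_to_hospice)
}

#' @rdname observed_mortality
#' @export
expected_mortality <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  check_risk_domain(cohort$risk_mortality)
  sum(cohort$risk_mortality)
}

#' Observed-to-expected mortality ratio
#'
#' @inheritParams observed_mortality
#' @param continuity_correction Add 0.5 to both the observed and expected
#'   counts; use when a cohort has zero observed mortalities (the inverted
#'   ratio is otherwise undefined downstream).
#' @return Dimensionless O:E ratio.
#' @export
oe_ratio <- function(cohort, continuity_correction = FALSE) {
  o <- observed_mortality(cohort)
  e <- expected_mortality(cohort)
  if (continuity_correction) {
    o <- o + 0.5
    e <- e + 0.5
  }
  if (e <= 0) stop("expected mortality is zero; O:E ratio undefined",
                   call. = FALSE)
  o / e
}

#' Risk-adjusted value of care for a case cohort and its matched controls
#'
#' For each admission `i` in cohort `g`, the raw statistic is the inverted
#' cohort O:E mortality ratio divided by a cost denominator, and the
#' reported value is `C` times that, with a single constant `C` fitted so
#' the *pooled* case+control median value equals 1. By default the
#' denominator is the admission's own total cost (one point per admission);
#' `denominator = "median_cost"` divides by the cohort's median total cost
#' instead, making the value constant within each cohort.
#'
#' Multiplying all costs by any positive factor leaves the normalized values
#' unchanged (`C` absorbs the scale).
#'
#' @param cases,controls Non-empty admission tables with outcome flags,
#'   `risk_mortality` and `total_cost`.
#' @param denominator `"per_admission"` (default) or `"median_cost"`.
#' @param continuity_correction Passed to [oe_ratio()] for both cohorts;
#'   required when either cohort has zero observed mortalities.
#' @return Object of class `value_of_care_result`: per-cohort lists
#'   (`observed_deaths`, `expected_deaths`, `oe_ratio`, `values` — a vector
#'   named by admission id — and `median_value`), the shared
#'   `normalization_constant`, and `pooled_median` (always 1 up to floating
#'   point).
#' @export
value_of_care <- function(cases, controls,
                          denominator = c("per_admission", "median_cost"),
                          continuity_correction = FALSE) {
  denominator <- match.arg(denominator)
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  if (any(c(cases$total_cost, controls$total_cost) <= 0)) {
    stop("total_cost must be positive", call. = FALSE)
  }
  cohort_raw <- function(tbl) {
    oe <- oe_ratio(tbl, continuity_correction)
    if (oe == 0) {
      stop(paste("cohort O:E ratio is 0 (no observed mortalities);",
                 "rerun with continuity_correction = TRUE"), call. = FALSE)
    }
    denom <- switch(denominator,
                    per_admission = tbl$total_cost,
                    median_cost = rep(median(tbl$total_cost), nrow(tbl)))
    list(oe = oe, raw = setNames((1 / oe) / denom, tbl$id))
  }
  rc <- cohort_raw(cases)
  rk <- cohort_raw(controls)
  C <- 1 / median(c(rc$raw, rk$raw))
  make_result <- function(tbl, r) {
    list(observed_deaths = observed_mortality(tbl),
         expected_deaths = expected_mortality(tbl),
         oe_ratio = r$oe,
         values = r$raw * C,
         median_value = median(r$raw * C))
  }
  structure(list(
    cases = make_result(cases, rc),
    controls = make_result(controls, rk),
    normalization_constant = C,
    denominator = denominator,
    pooled_median = median(c(rc$raw, rk$raw) * C)
  ), class = "value_of_care_result")
}

#' @export
print.value_of_care_result <- function(x, ...) {
  cat(sprintf(
    paste0("Value of care (%s denominator)\n",
           "  cases:    O:E = %.3f (%d observed / %.1f expected), median value %.3f\n",
           "  controls: O:E = %.3f (%d observed / %.1f expected), median value %.3f\n",
           "  normalization constant C = %.4g; pooled median = %.6f\n"),
    x$denominator,
    x$cases$oe_ratio, x$cases$observed_deaths, x$cases$expected_deaths,
    x$cases$median_value,
    x$controls$oe_ratio, x$controls$observed_deaths,
    x$controls$expected_deaths, x$controls$median_value,
    x$normalization_constant, x$pooled_median))
  invisible(x)
}
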