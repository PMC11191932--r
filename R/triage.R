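#' Apply cohort exclusion rules
#'
#' Removes admissions that died during the index surgery, lasted less than
#' 24 hours (strictly: an admission of exactly 24 hours is kept), or are not
#' the first surgery of the admission. The union of kept and excluded rows
#' equals the input; the excluded table carries a machine-readable reason
#' (semicolon-joined when several rules apply).
#'
#' @param table Admission table containing `died_during_index_surgery`,
#'   `admission_hours`, and `surgery_sequence`.
#' @return A list with elements `kept` and `excluded`; `excluded` has an
#'   extra `exclusion_reason` column.
#' @export
apply_exclusions <- function(table) {
  required <- c("died_during_index_surgery", "admission_hours",
                "surgery_sequence")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  reasons <- character(nrow(table))
  add_reason <- function(reasons, hit, tag) {
    ifelse(hit, ifelse(reasons == "", tag, paste(reasons, tag, sep = ";")),
           reasons)
  }
  reasons <- add_reason(reasons, table$died_during_index_surgery,
                        "index_surgery_death")
  reasons <- add_reason(reasons, table$admission_hours < 24,
                        "admission_lt_24h")
  reasons <- add_reason(reasons, table$surgery_sequence != 1L,
                        "repeat_surgery")
  drop <- reasons != ""
  excluded <- table[drop, , drop = FALSE]
  excluded$exclusion_reason <- reasons[drop]
  list(kept = table[!drop, , drop = FALSE], excluded = excluded)
}

#' Compute acuity percentile thresholds
#'
#' The 75th and 50th empirical percentiles of each risk score over a
#' reference population, under the package-wide quantile convention (linear
#' interpolation between closest order statistics).
#'
#' @param reference Table with `risk_mortality` and `risk_prolonged_icu`,
#'   at least 4 rows.
#' @return Object of class `acuity_thresholds` with fields `q75_mortality`,
#'   `q75_prolonged_icu`, `q50_mortality`, `q50_prolonged_icu`,
#'   `n_reference`.
#' @export
compute_thresholds <- function(reference) {
  for (col in c("risk_mortality", "risk_prolonged_icu")) {
    if (!col %in% names(reference)) {
      stop(sprintf("missing required column: %s", col), call. = FALSE)
    }
  }
  if (nrow(reference) < 4) {
    stop("need at least 4 reference admissions to compute quartiles",
         call. = FALSE)
  }
  check_risk_domain(reference$risk_mortality)
  check_risk_domain(reference$risk_prolonged_icu)
  structure(list(
    q75_mortality = pct_quantile(reference$risk_mortality, 0.75),
    q75_prolonged_icu = pct_quantile(reference$risk_prolonged_icu, 0.75),
    q50_mortality = pct_quantile(reference$risk_mortality, 0.50),
    q50_prolonged_icu = pct_quantile(reference$risk_prolonged_icu, 0.50),
    n_reference = nrow(reference)
  ), class = "acuity_thresholds")
}

#' Fixed acuity thresholds
#'
#' Constructs an `acuity_thresholds` object from externally supplied values
#' (e.g. thresholds published from a separate training population) instead
#' of recomputing them from the analysis table.
#'
#' @param q75_mortality,q75_prolonged_icu Top-quartile cutoffs in \[0,1\].
#' @param q50_mortality,q50_prolonged_icu Median cutoffs in \[0,1\].
#' @return Object of class `acuity_thresholds`.
#' @export
fixed_thresholds <- function(q75_mortality, q75_prolonged_icu,
                             q50_mortality, q50_prolonged_icu) {
  vals <- c(q75_mortality, q75_prolonged_icu, q50_mortality,
            q50_prolonged_icu)
  if (any(vals < 0) || any(vals > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (q50_mortality > q75_mortality ||
      q50_prolonged_icu > q75_prolonged_icu) {
    stop("median thresholds cannot exceed top-quartile thresholds",
         call. = FALSE)
  }
  structure(list(
    q75_mortality = q75_mortality, q75_prolonged_icu = q75_prolonged_icu,
    q50_mortality = q50_mortality, q50_prolonged_icu = q50_prolonged_icu,
    n_reference = NA_integer_
  ), class = "acuity_thresholds")
}

check_risk_domain <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("risk scores must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# High acuity: either risk in the top quartile (inclusive, >= q75).
# Low acuity: both risks strictly below the median (< q50).
# The two cannot co-occur because q50 <= q75.
acuity_class <- function(risk_mortality, risk_prolonged_icu, thresholds) {
  check_risk_domain(risk_mortality)
  check_risk_domain(risk_prolonged_icu)
  high <- risk_mortality >= thresholds$q75_mortality |
    risk_prolonged_icu >= thresholds$q75_prolonged_icu
  low <- risk_mortality < thresholds$q50_mortality &
    risk_prolonged_icu < thresholds$q50_prolonged_icu
  ifelse(high, "high", ifelse(low, "low", "intermediate"))
}

#' Classify admissions as overtriaged, undertriaged, or appropriate
#'
#' High-acuity admissions (either risk score in the top quartile of the
#' reference population, inclusive) triaged to a general ward are
#' *undertriage*; low-acuity admissions (both risk scores strictly below the
#' reference median) triaged to an ICU are *overtriage*. All other ICU
#' admissions are `appropriate_icu`, all other ward admissions
#' `appropriate_ward`. Intermediate-acuity admissions (between the median
#' and top quartile on their worst score) are never a triage error by
#' construction.
#'
#' @param table Admission table with `risk_mortality`, `risk_prolonged_icu`,
#'   `location`; usually the `kept` output of [apply_exclusions()].
#' @param thresholds An `acuity_thresholds` object from
#'   [compute_thresholds()] or [fixed_thresholds()].
#' @return A tibble with columns `id` (when present in the input), `acuity`
#'   (`high`/`intermediate`/`low`), and `label` (`overtriage`,
#'   `undertriage`, `appropriate_icu`, `appropriate_ward`).
#' @export
classify_triage <- function(table, thresholds) {
  if (!inherits(thresholds, "acuity_thresholds")) {
    stop("`thresholds` must be an acuity_thresholds object", call. = FALSE)
  }
  if (!all(table$location %in% location_levels())) {
    stop("`location` must be 'ICU' or 'ward'", call. = FALSE)
  }
  acuity <- acuity_class(table$risk_mortality, table$risk_prolonged_icu,
                         thresholds)
  icu <- table$location == "ICU"
  label <- ifelse(acuity == "high" & !icu, "undertriage",
           ifelse(acuity == "low" & icu, "overtriage",
           ifelse(icu, "appropriate_icu", "appropriate_ward")))
  out <- tibble::tibble(acuity = acuity, label = label)
  if ("id" %in% names(table)) {
    out <- tibble::tibble(id = table$id, out)
  }
  out
}
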