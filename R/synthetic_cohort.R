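#' Specify a planted sociodemographic phenotype
#'
#' A phenotype is one component of the mixture from which the synthetic
#' cohort generator draws sociodemographics. Each admission is assigned to
#' exactly one phenotype; the assignment is recorded as hidden ground truth
#' (a sidecar, not a column of the admission table) so that clustering
#' recovery can be tested without leaking labels into the analysis path.
#'
#' @param name Label for the phenotype (e.g. `"older_medicare"`).
#' @param weight Mixture proportion; weights across phenotypes must sum to 1.
#' @param age_mean,age_sd Age distribution in years (normal, truncated at
#'   18 and 100).
#' @param sex_probs Named probability vector over `c("female", "male")`.
#' @param race_probs Named probability vector over the race categories used
#'   in the admission schema.
#' @param payer_probs Named probability vector over the payer categories.
#' @param adi_national_mean,adi_national_sd Area deprivation index national
#'   rank (1–100; draws are clipped to that range).
#' @param adi_state_mean,adi_state_sd Area deprivation index state rank
#'   (1–10, deciles; clipped).
#' @param svi_mean,svi_sd Social vulnerability index (0–1; clipped).
#' @param emergent_surgery_prob Probability the index surgery was emergent.
#' @param rural_prob Probability of rural residence.
#'
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, weight,
                           age_mean, age_sd,
                           sex_probs, race_probs, payer_probs,
                           adi_national_mean, adi_national_sd,
                           adi_state_mean, adi_state_sd,
                           svi_mean, svi_sd,
                           emergent_surgery_prob = 0.1,
                           rural_prob = 0.2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(weight), length(weight) == 1L, weight > 0,
            age_sd > 0, adi_national_sd > 0, adi_state_sd > 0, svi_sd > 0)
  check_prob_vector <- function(p, levels, what) {
    if (is.null(names(p)) || !all(names(p) %in% levels)) {
      stop(sprintf("`%s` must be named with known categories", what),
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("`%s` must sum to 1 (got %.12f)", what, sum(p)),
           call. = FALSE)
    }
    full <- setNames(numeric(length(levels)), levels)
    full[names(p)] <- p
    full
  }
  spec <- list(
    name = name, weight = weight,
    age_mean = age_mean, age_sd = age_sd,
    sex_probs = check_prob_vector(sex_probs, sex_levels(), "sex_probs"),
    race_probs = check_prob_vector(race_probs, race_levels(), "race_probs"),
    payer_probs = check_prob_vector(payer_probs, payer_levels(), "payer_probs"),
    adi_national_mean = adi_national_mean, adi_national_sd = adi_national_sd,
    adi_state_mean = adi_state_mean, adi_state_sd = adi_state_sd,
    svi_mean = svi_mean, svi_sd = svi_sd,
    emergent_surgery_prob = emergent_surgery_prob,
    rural_prob = rural_prob
  )
  if (emergent_surgery_prob < 0 || emergent_surgery_prob > 1 ||
      rural_prob < 0 || rural_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "phenotype_spec")
}

#' Default three-phenotype mixture
#'
#' Three well-separated sociodemographic phenotypes emulating the contrasts
#' reported for postoperative triage cohorts: a large older group dominated
#' by Medicare and Medicare HMO coverage living in deprived areas; a
#' socioeconomically advantaged, predominantly White group with low area
#' deprivation ranks; and a younger group with higher Black representation,
#' Medicaid/Medicaid HMO coverage, and more emergent surgery. Separation
#' between components (2.5+ within-component SDs on the continuous axes,
#' near-disjoint payer signatures) is chosen so the planted structure is
#' recoverable by K-means, mirroring how distinct the reported phenotypes
#' are from one another.
#'
#' @return A list of three [phenotype_spec()] objects.
#' @export
default_phenotypes <- function() {
  list(
    phenotype_spec(
      name = "older_medicare", weight = 0.42,
      age_mean = 69, age_sd = 7,
      sex_probs = c(female = 0.50, male = 0.50),
      race_probs = c("Black" = 0.33, "White" = 0.60, "Other/multiracial" = 0.05,
                     "Asian" = 0.01, "Unknown" = 0.01),
      payer_probs = c("Medicare" = 0.45, "Medicare HMO" = 0.32,
                      "Blue Cross Blue Shield" = 0.04, "Managed care" = 0.03,
                      "Medicaid" = 0.03, "Medicaid HMO" = 0.05,
                      "Self-pay" = 0.02, "Federal non-CMS" = 0.02,
                      "Commercial" = 0.02, "Other/unknown" = 0.02),
      adi_national_mean = 82, adi_national_sd = 9,
      adi_state_mean = 8.7, adi_state_sd = 1.1,
      svi_mean = 0.66, svi_sd = 0.09,
      emergent_surgery_prob = 0.12, rural_prob = 0.32
    ),
    phenotype_spec(
      name = "advantaged", weight = 0.35,
      age_mean = 63, age_sd = 9,
      sex_probs = c(female = 0.47, male = 0.53),
      race_probs = c("Black" = 0.11, "White" = 0.82, "Other/multiracial" = 0.04,
                     "Asian" = 0.02, "Unknown" = 0.01),
      payer_probs = c("Blue Cross Blue Shield" = 0.30, "Medicare" = 0.33,
                      "Medicare HMO" = 0.13, "Managed care" = 0.10,
                      "Commercial" = 0.05, "Federal non-CMS" = 0.04,
                      "Medicaid" = 0.01, "Medicaid HMO" = 0.01,
                      "Self-pay" = 0.01, "Other/unknown" = 0.02),
      adi_national_mean = 42, adi_national_sd = 10,
      adi_state_mean = 4.2, adi_state_sd = 1.4,
      svi_mean = 0.45, svi_sd = 0.09,
      emergent_surgery_prob = 0.08, rural_prob = 0.18
    ),
    phenotype_spec(
      name = "younger_medicaid", weight = 0.23,
      age_mean = 42, age_sd = 8,
      sex_probs = c(female = 0.52, male = 0.48),
      race_probs = c("Black" = 0.45, "White" = 0.46, "Other/multiracial" = 0.06,
                     "Asian" = 0.01, "Unknown" = 0.02),
      payer_probs = c("Medicaid" = 0.08, "Medicaid HMO" = 0.26,
                      "Self-pay" = 0.06, "Medicare" = 0.18,
                      "Medicare HMO" = 0.06, "Blue Cross Blue Shield" = 0.13,
                      "Managed care" = 0.07, "Commercial" = 0.03,
                      "Federal non-CMS" = 0.03, "Other/unknown" = 0.10),
      adi_national_mean = 83, adi_national_sd = 10,
      adi_state_mean = 8.6, adi_state_sd = 1.2,
      svi_mean = 0.65, svi_sd = 0.10,
      emergent_surgery_prob = 0.22, rural_prob = 0.20
    )
  )
}

#' Configure the synthetic cohort generator
#'
#' @param n_admissions Number of admissions to generate (>= 1).
#' @param seed Integer seed; identical config + seed gives an identical table.
#' @param triage_error_rates Length-2 probability vector
#'   `c(p_icu_given_low, p_ward_given_high)`: the probability that a
#'   low-acuity admission is (over)triaged to the ICU, and that a
#'   high-acuity admission is (under)triaged to a general ward.
#' @param phenotype_specs List of [phenotype_spec()]; weights must sum to 1.
#' @param mortality_calibration Scale factor linking the mortality risk score
#'   to the probability of the composite observed-mortality event (hospital
#'   death or discharge to hospice). At the default of 1 the risk score *is*
#'   the event probability, so cohort observed-to-expected ratios are
#'   centred on 1 by construction.
#' @param hospice_fraction Fraction of composite mortality events realised as
#'   hospice discharge rather than in-hospital death (single categorical
#'   draw, so the two flags can never both be set).
#' @param risk_beta Beta shape parameters for the two risk scores by latent
#'   acuity class: a list with elements `mort_low`, `mort_high`, `picu_low`,
#'   `picu_high`, each `c(shape1, shape2)`.
#' @param p_high_acuity Marginal probability of the latent high-acuity class.
#' @param icu_rate_intermediate Probability that an intermediate-acuity
#'   admission (between the 50th and 75th risk percentiles) is in the ICU.
#' @param cost_model List with `base` (currency units), `log_los` (additive
#'   effect of hospital length of stay on log cost per day), `log_icu`
#'   (additive ICU effect on log cost), `sdlog` (log-normal noise).
#' @param exclusion_rates Length-2 probability vector
#'   `c(p_index_surgery_death, p_admission_lt_24h)`.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_admissions = 6000,
                             seed = 20260927,
                             triage_error_rates = c(0.08, 0.33),
                             phenotype_specs = default_phenotypes(),
                             mortality_calibration = 1,
                             hospice_fraction = 0.5,
                             risk_beta = list(mort_low = c(1.2, 60),
                                              mort_high = c(2.5, 35),
                                              picu_low = c(1.5, 20),
                                              picu_high = c(4, 8)),
                             p_high_acuity = 0.35,
                             icu_rate_intermediate = 0.4,
                             cost_model = list(base = 11000, log_los = 0.09,
                                               log_icu = 0.35, sdlog = 0.5),
                             exclusion_rates = c(0.004, 0.03)) {
  if (!is.numeric(n_admissions) || length(n_admissions) != 1L ||
      n_admissions < 1 || n_admissions != floor(n_admissions)) {
    stop("`n_admissions` must be a positive integer", call. = FALSE)
  }
  probs <- c(triage_error_rates, mortality_calibration * 0, hospice_fraction,
             p_high_acuity, icu_rate_intermediate, exclusion_rates)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(triage_error_rates) != 2L || length(exclusion_rates) != 2L) {
    stop("`triage_error_rates` and `exclusion_rates` are probability pairs",
         call. = FALSE)
  }
  if (mortality_calibration < 0) {
    stop("`mortality_calibration` must be non-negative", call. = FALSE)
  }
  w <- vapply(phenotype_specs, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("phenotype mixture weights must sum to 1 (got %.12f)",
                 sum(w)), call. = FALSE)
  }
  structure(list(
    n_admissions = as.integer(n_admissions),
    seed = as.integer(seed),
    triage_error_rates = triage_error_rates,
    phenotype_specs = phenotype_specs,
    mortality_calibration = mortality_calibration,
    hospice_fraction = hospice_fraction,
    risk_beta = risk_beta,
    p_high_acuity = p_high_acuity,
    icu_rate_intermediate = icu_rate_intermediate,
    cost_model = cost_model,
    exclusion_rates = exclusion_rates
  ), class = "synthetic_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic postoperative admission cohort
#'
#' Draws an admission-level table with the statistical structure the triage
#' analysis assumes: two Beta-distributed risk scores conditioned on a latent
#' acuity class, ICU/ward location assigned from the percentile-rule acuity
#' (computed with the same thresholds and tie conventions the classifier
#' uses, on the subset that survives the exclusion rules) perturbed by the
#' configured triage error rates, sociodemographics from a planted phenotype
#' mixture, composite mortality outcomes driven by the mortality risk score,
#' and right-skewed log-normal costs increasing in length of stay and ICU
#' use.
#'
#' Hidden ground truth (planted phenotype and model-acuity class per
#' admission) is attached as the `"ground_truth"` attribute rather than as
#' table columns, so downstream stages cannot silently peek; retrieve it with
#' [ground_truth()].
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per admission.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be created by synthetic_config()", call. = FALSE)
  }
  n <- config$n_admissions
  specs <- config$phenotype_specs
  withr::with_seed(config$seed, {
    ## phenotype mixture and sociodemographics
    w <- vapply(specs, function(s) s$weight, numeric(1))
    ph_idx <- sample.int(length(specs), n, replace = TRUE, prob = w)
    ph_names <- vapply(specs, function(s) s$name, character(1))
    grab <- function(field) vapply(specs, function(s) s[[field]], numeric(1))
    age <- clip(rnorm(n, grab("age_mean")[ph_idx], grab("age_sd")[ph_idx]),
                18, 100)
    adi_national <- clip(rnorm(n, grab("adi_national_mean")[ph_idx],
                               grab("adi_national_sd")[ph_idx]), 1, 100)
    adi_state <- clip(rnorm(n, grab("adi_state_mean")[ph_idx],
                            grab("adi_state_sd")[ph_idx]), 1, 10)
    svi <- clip(rnorm(n, grab("svi_mean")[ph_idx], grab("svi_sd")[ph_idx]),
                0, 1)
    draw_cat <- function(field, levels) {
      out <- character(n)
      for (j in seq_along(specs)) {
        idx <- which(ph_idx == j)
        if (length(idx)) {
          out[idx] <- sample(levels, length(idx), replace = TRUE,
                             prob = specs[[j]][[field]])
        }
      }
      out
    }
    sex <- draw_cat("sex_probs", sex_levels())
    race <- draw_cat("race_probs", race_levels())
    payer <- draw_cat("payer_probs", payer_levels())
    rural <- rbinom(n, 1, grab("rural_prob")[ph_idx]) == 1
    emergent_surgery <- rbinom(n, 1, grab("emergent_surgery_prob")[ph_idx]) == 1

    ## latent acuity and risk scores
    high <- rbinom(n, 1, config$p_high_acuity) == 1
    rb <- config$risk_beta
    risk_mortality <- ifelse(
      high, rbeta(n, rb$mort_high[1], rb$mort_high[2]),
      rbeta(n, rb$mort_low[1], rb$mort_low[2]))
    risk_prolonged_icu <- ifelse(
      high, rbeta(n, rb$picu_high[1], rb$picu_high[2]),
      rbeta(n, rb$picu_low[1], rb$picu_low[2]))

    ## exclusion flags drawn before location so model-acuity thresholds can
    ## be computed on the analyzable subset exactly as the classifier will
    died_index <- rbinom(n, 1, config$exclusion_rates[1]) == 1
    short_stay <- !died_index & rbinom(n, 1, config$exclusion_rates[2]) == 1

    ## model-acuity by the percentile rule on the would-be-kept subset
    kept <- !died_index & !short_stay
    thr <- compute_thresholds(data.frame(
      risk_mortality = risk_mortality[kept],
      risk_prolonged_icu = risk_prolonged_icu[kept]))
    acuity <- acuity_class(risk_mortality, risk_prolonged_icu, thr)

    ## location from model-acuity perturbed by triage error rates
    err <- config$triage_error_rates
    u <- runif(n)
    location <- character(n)
    location[acuity == "high"] <- ifelse(u[acuity == "high"] < err[2],
                                         "ward", "ICU")
    location[acuity == "low"] <- ifelse(u[acuity == "low"] < err[1],
                                        "ICU", "ward")
    location[acuity == "intermediate"] <-
      ifelse(u[acuity == "intermediate"] < config$icu_rate_intermediate,
             "ICU", "ward")

    ## lengths of stay (fractional days)
    hospital_los <- rlnorm(n, meanlog = log(1.8) + 1.1 * risk_prolonged_icu +
                             0.25 * (location == "ICU"), sdlog = 0.55)
    admission_hours <- ifelse(short_stay, runif(n, 4, 23.9),
                              pmax(hospital_los, 1.01) * 24)
    hospital_los <- admission_hours / 24
    icu_los <- ifelse(location == "ICU",
                      pmin(hospital_los,
                           rlnorm(n, meanlog = log(1.1) +
                                    1.4 * risk_prolonged_icu, sdlog = 0.6)),
                      0)

    ## composite mortality as one categorical draw (no contradictory flags)
    p_event <- clip(config$mortality_calibration * risk_mortality, 0, 1)
    ev <- runif(n)
    event <- ev < p_event
    hospice <- event & (runif(n) < config$hospice_fraction)
    died <- event & !hospice
    died[died_index] <- TRUE
    hospice[died_index] <- FALSE

    ## costs: log-normal, multiplicative LOS and ICU effects
    cm <- config$cost_model
    total_cost <- rlnorm(n, meanlog = log(cm$base) +
                           cm$log_los * pmin(hospital_los, 30) +
                           cm$log_icu * (location == "ICU"),
                         sdlog = cm$sdlog)

    ## complication flags at Table-2-like magnitudes, increasing in acuity
    prolonged_icu_48h <- icu_los >= 2
    prolonged_vent_48h <- rbinom(n, 1, clip(0.004 + 0.04 * risk_prolonged_icu,
                                            0, 1)) == 1
    aki_u <- runif(n)
    p_aki <- clip(0.06 + 1.2 * risk_mortality, 0, 1)
    aki_category <- ifelse(aki_u < 0.55 * p_aki, "rapid_reversal",
                    ifelse(aki_u < 0.80 * p_aki, "persistent_recovered",
                    ifelse(aki_u < p_aki, "persistent_no_recovery", "none")))
    transfusion_postop <- rbinom(n, 1, clip(0.03 + 0.35 * risk_mortality,
                                            0, 1)) == 1
    transfusion_any <- transfusion_postop |
      rbinom(n, 1, clip(0.02 + 0.15 * risk_mortality, 0, 1)) == 1
    second_surgery <- rbinom(n, 1, clip(0.04 + 0.35 * risk_prolonged_icu,
                                        0, 1)) == 1

    tbl <- tibble::tibble(
      id = sprintf("A%06d", seq_len(n)),
      risk_mortality = risk_mortality,
      risk_prolonged_icu = risk_prolonged_icu,
      location = location,
      age = age,
      sex = sex,
      race = race,
      rural = rural,
      adi_state = adi_state,
      adi_national = adi_national,
      svi = svi,
      payer = payer,
      died_in_hospital = died,
      discharged_to_hospice = hospice,
      icu_los_days = icu_los,
      hospital_los_days = hospital_los,
      total_cost = total_cost,
      died_during_index_surgery = died_index,
      admission_hours = admission_hours,
      surgery_sequence = 1L,
      emergent_surgery = emergent_surgery,
      prolonged_icu_48h = prolonged_icu_48h,
      prolonged_vent_48h = prolonged_vent_48h,
      aki_category = aki_category,
      transfusion_postop = transfusion_postop,
      transfusion_any = transfusion_any,
      second_surgery = second_surgery
    )
    attr(tbl, "ground_truth") <- tibble::tibble(
      id = tbl$id,
      phenotype = ph_names[ph_idx],
      acuity = acuity
    )
    tbl
  })
}

#' Retrieve planted ground truth from a generated cohort
#'
#' Returns the hidden phenotype and model-acuity assignment attached by
#' [generate_cohort()]. Intended for tests and recovery experiments only;
#' the analysis pipeline never reads it.
#'
#' @param table A tibble produced by [generate_cohort()] (or read back with
#'   its sidecar via [read_cohort()]).
#' @return A tibble with columns `id`, `phenotype`, `acuity`.
#' @export
ground_truth <- function(table) {
  gt <- attr(table, "ground_truth", exact = TRUE)
  if (is.null(gt)) {
    stop("table carries no ground-truth sidecar; was it made by generate_cohort()?",
         call. = FALSE)
  }
  gt
}

#' Write / read a cohort table with its ground-truth sidecar
#'
#' The admission table is written as RFC 4180 CSV (UTF-8, header row, empty
#' fields for missing values). Ground truth, when present, goes to a separate
#' sidecar CSV so the analysis pipeline cannot silently peek at planted
#' labels.
#'
#' @param table Cohort tibble.
#' @param path Output CSV path for the admission table.
#' @param ground_truth_path Optional sidecar CSV path; defaults to
#'   `<path minus .csv>_ground_truth.csv` when the table carries ground truth.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, ground_truth_path = NULL) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  gt <- attr(table, "ground_truth", exact = TRUE)
  if (!is.null(gt)) {
    if (is.null(ground_truth_path)) {
      ground_truth_path <- sub("\\.csv$", "", path)
      ground_truth_path <- paste0(ground_truth_path, "_ground_truth.csv")
    }
    write.csv(as.data.frame(gt), ground_truth_path, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, ground_truth_path = NULL) {
  tbl <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
  tbl <- validate_schema(tbl, "admissions")
  if (!is.null(ground_truth_path) && file.exists(ground_truth_path)) {
    attr(tbl, "ground_truth") <-
      tibble::as_tibble(read.csv(ground_truth_path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"))
  }
  tbl
}
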