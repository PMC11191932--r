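voc_cohort <- function(id_prefix, risks, died, hospice, cost) {
  tibble::tibble(id = paste0(id_prefix, seq_along(risks)),
                 risk_mortality = risks, died_in_hospital = died,
                 discharged_to_hospice = hospice, total_cost = cost)
}

test_that("observed mortality is the death-or-hospice composite count", {
  coh <- voc_cohort("a", rep(0.1, 10),
                    died = c(TRUE, TRUE, rep(FALSE, 8)),
                    hospice = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
                    cost = rep(1000, 10))
  expect_equal(observed_mortality(coh), 3)
  coh0 <- voc_cohort("b", rep(0.1, 4), rep(FALSE, 4), rep(FALSE, 4),
                     rep(1000, 4))
  expect_equal(observed_mortality(coh0), 0)
  expect_error(observed_mortality(coh0[0, ]), "empty")
})

test_that("O:E ratio matches hand computation and boundary behavior", {
  # perfectly calibrated: risk 0.5 everywhere, half observed
  coh <- voc_cohort("a", rep(0.5, 10),
                    died = rep(c(TRUE, FALSE), 5),
                    hospice = rep(FALSE, 10), cost = rep(1, 10))
  expect_equal(oe_ratio(coh), 1.0)
  # 10 records, sum(risk) = 0.8, observed = 2 -> 2.5
  coh2 <- voc_cohort("b", rep(0.08, 10),
                     died = c(TRUE, TRUE, rep(FALSE, 8)),
                     hospice = rep(FALSE, 10), cost = rep(1, 10))
  expect_equal(oe_ratio(coh2), 2.5)
  # zero observed -> ratio 0 (downstream guard handles it)
  coh3 <- voc_cohort("c", rep(0.1, 5), rep(FALSE, 5), rep(FALSE, 5),
                     rep(1, 5))
  expect_equal(oe_ratio(coh3), 0)
  expect_gt(oe_ratio(coh3, continuity_correction = TRUE), 0)
  coh4 <- voc_cohort("d", rep(0, 3), rep(FALSE, 3), rep(FALSE, 3), rep(1, 3))
  expect_error(oe_ratio(coh4), "undefined")
})

test_that("value of care normalizes the pooled median to 1 and follows ratio algebra", {
  withr::with_seed(8, {
    cases <- voc_cohort("c", runif(40, 0.2, 0.6),
                        died = runif(40) < 0.4, hospice = rep(FALSE, 40),
                        cost = runif(40, 8000, 30000))
    controls <- voc_cohort("k", runif(60, 0.2, 0.6),
                           died = runif(60) < 0.4, hospice = rep(FALSE, 60),
                           cost = runif(60, 8000, 30000))
  })
  res <- value_of_care(cases, controls)
  expect_equal(res$pooled_median, 1, tolerance = 1e-12)
  expect_true(all(res$cases$values > 0))
  expect_true(all(res$controls$values > 0))
  # identical O:E and identical costs: both cohort medians are 1
  cases_sym <- voc_cohort("c", rep(0.5, 10), rep(c(TRUE, FALSE), 5),
                          rep(FALSE, 10), rep(c(1000, 2000), 5))
  controls_sym <- voc_cohort("k", rep(0.5, 10), rep(c(TRUE, FALSE), 5),
                             rep(FALSE, 10), rep(c(1000, 2000), 5))
  sym <- value_of_care(cases_sym, controls_sym)
  expect_equal(sym$cases$median_value, 1, tolerance = 1e-12)
  expect_equal(sym$controls$median_value, 1, tolerance = 1e-12)
  # control O:E half the case O:E, identical costs -> control median 2x case
  cases_h <- voc_cohort("c", rep(0.5, 10), rep(TRUE, 10), rep(FALSE, 10),
                        rep(c(1000, 2000), 5))       # O:E = 2
  controls_h <- voc_cohort("k", rep(0.5, 10), rep(c(TRUE, FALSE), 5),
                           rep(FALSE, 10), rep(c(1000, 2000), 5))  # O:E = 1
  h <- value_of_care(cases_h, controls_h)
  expect_equal(h$controls$median_value, 2 * h$cases$median_value,
               tolerance = 1e-12)
})

test_that("cost scale is absorbed by the normalization constant", {
  withr::with_seed(9, {
    cases <- voc_cohort("c", runif(30, 0.1, 0.5), runif(30) < 0.3,
                        rep(FALSE, 30), runif(30, 5000, 40000))
    controls <- voc_cohort("k", runif(30, 0.1, 0.5), runif(30) < 0.3,
                           rep(FALSE, 30), runif(30, 5000, 40000))
  })
  r1 <- value_of_care(cases, controls)
  cases2 <- dplyr::mutate(cases, total_cost = total_cost * 37.5)
  controls2 <- dplyr::mutate(controls, total_cost = total_cost * 37.5)
  r2 <- value_of_care(cases2, controls2)
  expect_equal(r2$cases$values, r1$cases$values, tolerance = 1e-12)
  expect_equal(r2$controls$values, r1$controls$values, tolerance = 1e-12)
})

test_that("zero-mortality cohorts demand the continuity correction", {
  dead <- voc_cohort("c", rep(0.3, 8), rep(c(TRUE, FALSE), 4),
                     rep(FALSE, 8), rep(1000, 8))
  alive <- voc_cohort("k", rep(0.3, 8), rep(FALSE, 8), rep(FALSE, 8),
                      rep(1000, 8))
  expect_error(value_of_care(dead, alive), "continuity_correction")
  res <- value_of_care(dead, alive, continuity_correction = TRUE)
  expect_equal(res$pooled_median, 1, tolerance = 1e-12)
})

test_that("median-cost denominator variant gives constant values within cohort", {
  withr::with_seed(10, {
    cases <- voc_cohort("c", runif(20, 0.2, 0.6), runif(20) < 0.4,
                        rep(FALSE, 20), runif(20, 5000, 30000))
    controls <- voc_cohort("k", runif(20, 0.2, 0.6), runif(20) < 0.4,
                           rep(FALSE, 20), runif(20, 5000, 30000))
  })
  res <- value_of_care(cases, controls, denominator = "median_cost")
  expect_equal(length(unique(round(res$cases$values, 12))), 1)
  expect_equal(length(unique(round(res$controls$values, 12))), 1)
  expect_equal(res$pooled_median, 1, tolerance = 1e-12)
})

test_that("synthetic outcomes drawn from the risk scores give O:E near 1", {
  tbl <- generate_cohort(synthetic_config(n_admissions = 50000, seed = 99))
  kept <- apply_exclusions(tbl)$kept
  oe <- oe_ratio(kept)
  mc_se <- sqrt(sum(kept$risk_mortality * (1 - kept$risk_mortality))) /
    sum(kept$risk_mortality)
  expect_lt(abs(oe - 1), 3 * mc_se)
})
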