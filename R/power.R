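#' Power and sample size for two-group designs with unequal allocation
#'
#' Closed-form power of the two-sided large-sample z comparison, with
#' `allocation_ratio` controls per case. For proportions this is the
#' classical pooled-variance (score-test) construction — null standard
#' error from the allocation-weighted pooled proportion, alternative
#' standard error unpooled — optionally with a continuity correction
#' subtracting `(1/n1 + 1/n2)/2` from the absolute difference. For means
#' the standard deviation is treated as a known planning value (classical
#' sample-size framing). `required_cases_*()` return the smallest case
#' count whose closed-form (or simulated) power reaches the target.
#'
#' @param n_cases Number of cases (group 1).
#' @param p1,p2 Event proportions in cases and controls, in (0, 1).
#' @param m1,m2 Group means; `sd` the common known standard deviation.
#' @param allocation_ratio Controls per case (> 0); the control group size
#'   is `ceiling(allocation_ratio * n_cases)`.
#' @param alpha Two-sided significance level.
#' @param method `"normal"` (default), `"continuity"` (proportions only),
#'   or `"simulation"` (Monte-Carlo search using the same test statistic).
#' @return Power functions: probability in \[0, 1\]. `required_cases_*()`:
#'   smallest case count (positive integer).
#' @name power_two_groups
NULL

#' @rdname power_two_groups
#' @export
power_two_proportions <- function(n_cases, p1, p2, allocation_ratio = 1,
                                  alpha = 0.05,
                                  method = c("normal", "continuity")) {
  method <- match.arg(method)
  n1 <- n_cases
  n2 <- ceiling(allocation_ratio * n_cases)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- abs(p1 - p2)
  if (method == "continuity") d <- max(0, d - (1 / n1 + 1 / n2) / 2)
  za <- qnorm(1 - alpha / 2)
  pnorm((d - za * se0) / se1) + pnorm((-d - za * se0) / se1)
}

#' @rdname power_two_groups
#' @export
power_two_means <- function(n_cases, m1, m2, sd, allocation_ratio = 1,
                            alpha = 0.05) {
  n1 <- n_cases
  n2 <- ceiling(allocation_ratio * n_cases)
  se <- sd * sqrt(1 / n1 + 1 / n2)
  d <- abs(m1 - m2)
  za <- qnorm(1 - alpha / 2)
  pnorm(d / se - za) + pnorm(-d / se - za)
}

search_smallest_n <- function(power_fn, target_power, n_start) {
  n <- max(2L, as.integer(floor(n_start)))
  # walk down while still powered, then up until powered: smallest n
  while (n > 2L && power_fn(n - 1L) >= target_power) n <- n - 1L
  while (power_fn(n) < target_power) n <- n + 1L
  n
}

#' @rdname power_two_groups
#' @param target_power Desired power in (0, 1).
#' @param nsim,seed Replicates and seed for `method = "simulation"`.
#' @export
required_cases_two_proportions <- function(p1, p2, allocation_ratio = 1,
                                           alpha = 0.05, target_power = 0.8,
                                           method = c("normal", "continuity",
                                                      "simulation"),
                                           nsim = 2000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            allocation_ratio > 0)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("proportions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (p1 == p2) stop("p1 = p2: no finite sample size", call. = FALSE)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(target_power)
  d <- abs(p1 - p2)
  r <- allocation_ratio
  pbar <- (p1 + r * p2) / (1 + r)
  n0 <- ((za * sqrt(pbar * (1 - pbar) * (1 + 1 / r)) +
            zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2) / r)) / d)^2
  if (method == "simulation") {
    fn <- function(n) mc_power_two_proportions(
      n, p1, p2, allocation_ratio, alpha, nsim = nsim,
      seed = seed + n)  # distinct stream per candidate n
  } else {
    fn <- function(n) power_two_proportions(n, p1, p2, allocation_ratio,
                                            alpha, method)
  }
  search_smallest_n(fn, target_power, n0)
}

#' @rdname power_two_groups
#' @export
required_cases_two_means <- function(m1, m2, sd, allocation_ratio = 1,
                                     alpha = 0.05, target_power = 0.8) {
  stopifnot(sd > 0, alpha > 0, alpha < 1, target_power > 0,
            target_power < 1, allocation_ratio > 0)
  if (m1 == m2) stop("m1 = m2: no finite sample size", call. = FALSE)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(target_power)
  n0 <- (za + zb)^2 * sd^2 * (1 + 1 / allocation_ratio) / (m1 - m2)^2
  search_smallest_n(
    function(n) power_two_means(n, m1, m2, sd, allocation_ratio, alpha),
    target_power, n0)
}

#' Monte-Carlo power of the same two-group z tests
#'
#' Simulates the rejection rate of the identical test statistic the
#' closed-form power functions describe: pooled-variance (score) z for
#' proportions (optionally continuity-corrected), known-sd z for means.
#' Used to verify self-consistency of the returned sample sizes.
#'
#' @inheritParams power_two_groups
#' @param nsim Number of simulated trials.
#' @param seed Seed for the simulation.
#' @return Estimated power (rejection fraction).
#' @export
mc_power_two_proportions <- function(n_cases, p1, p2, allocation_ratio = 1,
                                     alpha = 0.05, method = c("normal",
                                                              "continuity"),
                                     nsim = 10000, seed = 1L) {
  method <- match.arg(method)
  n1 <- n_cases
  n2 <- ceiling(allocation_ratio * n_cases)
  za <- qnorm(1 - alpha / 2)
  withr::with_seed(seed, {
    x1 <- rbinom(nsim, n1, p1)
    x2 <- rbinom(nsim, n2, p2)
    ph1 <- x1 / n1
    ph2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se0 <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    d <- abs(ph1 - ph2)
    if (method == "continuity") d <- pmax(0, d - (1 / n1 + 1 / n2) / 2)
    z <- ifelse(se0 == 0, ifelse(d == 0, 0, Inf), d / se0)
    mean(z > za)
  })
}

#' @rdname mc_power_two_proportions
#' @export
mc_power_two_means <- function(n_cases, m1, m2, sd, allocation_ratio = 1,
                               alpha = 0.05, nsim = 10000, seed = 1L) {
  n1 <- n_cases
  n2 <- ceiling(allocation_ratio * n_cases)
  za <- qnorm(1 - alpha / 2)
  se <- sd * sqrt(1 / n1 + 1 / n2)
  withr::with_seed(seed, {
    mbar1 <- rnorm(nsim, m1, sd / sqrt(n1))
    mbar2 <- rnorm(nsim, m2, sd / sqrt(n2))
    mean(abs(mbar1 - mbar2) / se > za)
  })
}
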