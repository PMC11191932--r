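# Independent brute-force oracles. These deliberately re-derive every rule
# from first principles (sort-and-interpolate quantiles, literal label
# definitions, full enumeration for exact tests) and never call the package
# functions they check.

# Linear-interpolation percentile between closest order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Literal triage labels from a table of risks + locations.
oracle_triage <- function(tbl) {
  q75m <- oracle_quantile(tbl$risk_mortality, 0.75)
  q75p <- oracle_quantile(tbl$risk_prolonged_icu, 0.75)
  q50m <- oracle_quantile(tbl$risk_mortality, 0.50)
  q50p <- oracle_quantile(tbl$risk_prolonged_icu, 0.50)
  out <- character(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    high <- tbl$risk_mortality[i] >= q75m || tbl$risk_prolonged_icu[i] >= q75p
    low <- tbl$risk_mortality[i] < q50m && tbl$risk_prolonged_icu[i] < q50p
    icu <- tbl$location[i] == "ICU"
    out[i] <- if (high && !icu) "undertriage"
      else if (low && icu) "overtriage"
      else if (icu) "appropriate_icu"
      else "appropriate_ward"
  }
  out
}

# k nearest pool members per case by brute force over all pairs; ties by
# lowest control id.
oracle_knn <- function(cases, pool, k, features, standardize = TRUE) {
  Xc <- as.matrix(cases[, features, drop = FALSE])
  Xp <- as.matrix(pool[, features, drop = FALSE])
  if (standardize) {
    both <- rbind(Xc, Xp)
    for (j in seq_len(ncol(both))) {
      mu <- mean(both[, j]); s <- sd(both[, j]); if (s == 0) s <- 1
      Xc[, j] <- (Xc[, j] - mu) / s
      Xp[, j] <- (Xp[, j] - mu) / s
    }
  }
  sel <- list()
  for (i in seq_len(nrow(Xc))) {
    d <- sqrt(rowSums((Xp - matrix(Xc[i, ], nrow(Xp), ncol(Xp),
                                   byrow = TRUE))^2))
    ord <- order(d, pool$id)
    sel[[cases$id[i]]] <- pool$id[ord[seq_len(min(k, nrow(pool)))]]
  }
  sel
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of P(table) over all tables with the same margins whose probability
# does not exceed that of the observed table.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group-A rank
# assignments (no ties).
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  n <- length(pooled)
  m <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(m)])
  combos <- combn(n, m)
  w_all <- apply(combos, 2, function(idx) sum(idx))
  mu <- m * (n + 1) / 2
  # two-sided: assignments at least as far from the mean as observed
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Small deterministic admission table for exclusion/classification tests.
make_toy_admissions <- function(n = 12, seed = 7) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("T%03d", seq_len(n)),
      risk_mortality = runif(n),
      risk_prolonged_icu = runif(n),
      location = sample(c("ICU", "ward"), n, replace = TRUE),
      died_in_hospital = FALSE,
      discharged_to_hospice = FALSE,
      total_cost = runif(n, 5000, 30000),
      died_during_index_surgery = FALSE,
      admission_hours = runif(n, 30, 200),
      surgery_sequence = 1L
    )
  })
}
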