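#' Build a risk-matched control cohort by K-nearest neighbors
#'
#' For each case, selects its `k` nearest members of the candidate pool
#' under Euclidean distance on the matching features (standardized to zero
#' mean / unit variance over cases and pool jointly, by default). The
#' deduplicated union of the per-case neighbor sets is the control cohort —
#' this is what makes the achieved control:case ratio data-dependent rather
#' than fixed. Distance ties are broken by lowest admission id so repeated
#' runs give identical cohorts.
#'
#' @param cases,pool Admission tables; `pool` holds the candidate controls
#'   and must be disjoint from `cases` by `id`.
#' @param k Neighbors per case (default 5); capped at the pool size with a
#'   warning if larger.
#' @param features Character vector of matching features (default: the two
#'   risk scores).
#' @param standardize Standardize features over cases and pool jointly
#'   before computing distances (default `TRUE`). Constant features
#'   contribute zero distance.
#' @param caliper Optional maximum distance; neighbors farther than this are
#'   not selected (default `NULL`, no caliper).
#' @return Object of class `matched_cohort`: `case_ids`, `control_ids`
#'   (deduplicated union), `pairs` (tibble of case id, control id, distance,
#'   neighbor rank), `ratio_achieved`, `feature_names`.
#' @export
match_controls <- function(cases, pool, k = 5,
                           features = c("risk_mortality",
                                        "risk_prolonged_icu"),
                           standardize = TRUE, caliper = NULL) {
  if (nrow(pool) == 0) stop("candidate pool is empty", call. = FALSE)
  if (nrow(cases) == 0) stop("case table is empty", call. = FALSE)
  if (k < 1 || k != floor(k)) stop("`k` must be a positive integer",
                                   call. = FALSE)
  for (f in features) {
    if (!f %in% names(cases) || !f %in% names(pool)) {
      stop(sprintf("matching feature `%s` missing from cases or pool", f),
           call. = FALSE)
    }
  }
  if (any(cases$id %in% pool$id)) {
    stop("cases and pool must be disjoint by id", call. = FALSE)
  }
  if (k > nrow(pool)) {
    warning(sprintf("k = %d exceeds pool size %d; capped", k, nrow(pool)))
    k <- nrow(pool)
  }
  Xc <- as.matrix(cases[, features, drop = FALSE])
  Xp <- as.matrix(pool[, features, drop = FALSE])
  if (standardize) {
    both <- rbind(Xc, Xp)
    mu <- colMeans(both)
    sdv <- apply(both, 2, sd)
    sdv[sdv == 0] <- 1  # constant feature: contributes nothing
    Xc <- sweep(sweep(Xc, 2, mu), 2, sdv, "/")
    Xp <- sweep(sweep(Xp, 2, mu), 2, sdv, "/")
  }
  # squared-distance matrix cases x pool
  d2 <- matrix(0, nrow(Xc), nrow(Xp))
  for (j in seq_along(features)) {
    d2 <- d2 + outer(Xc[, j], Xp[, j], "-")^2
  }
  dist_mat <- sqrt(pmax(d2, 0))
  pool_order_key <- order(pool$id)  # for deterministic tie-breaks

  pairs <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    di <- dist_mat[i, ]
    # order by distance then by admission id (lowest wins ties)
    ord <- order(di, match(seq_along(di), pool_order_key))
    sel <- ord[seq_len(k)]
    if (!is.null(caliper)) sel <- sel[di[sel] <= caliper]
    if (length(sel)) {
      pairs[[i]] <- tibble::tibble(
        case_id = cases$id[i],
        control_id = pool$id[sel],
        distance = di[sel],
        neighbor_rank = seq_along(sel)
      )
    }
  }
  empty_pairs <- tibble::tibble(case_id = character(0),
                                control_id = character(0),
                                distance = numeric(0),
                                neighbor_rank = integer(0))
  pairs <- dplyr::bind_rows(c(list(empty_pairs), pairs))
  control_ids <- unique(pairs$control_id)
  structure(list(
    case_ids = cases$id,
    control_ids = control_ids,
    pairs = pairs,
    ratio_achieved = length(control_ids) / nrow(cases),
    feature_names = features
  ), class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "Matched cohort: %d cases, %d unique controls (ratio %.2f:1) on [%s]\n",
    length(x$case_ids), length(x$control_ids), x$ratio_achieved,
    paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Covariate balance diagnostics for a matched cohort
#'
#' Standardized mean differences: (mean in cases − mean in controls) /
#' pooled SD, with pooled SD = sqrt((var_case + var_control) / 2). When the
#' pooled SD is zero the SMD is reported as 0 if the means are equal and
#' flagged undefined (NA + note) otherwise.
#'
#' @param cases,controls Non-empty admission tables.
#' @param features Numeric columns to diagnose.
#' @return Tibble with one row per feature: means, pooled SD, `smd`, `note`.
#' @export
balance_diagnostics <- function(cases, controls,
                                features = c("risk_mortality",
                                             "risk_prolonged_icu")) {
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  rows <- lapply(features, function(f) {
    xc <- cases[[f]]
    xt <- controls[[f]]
    pooled <- sqrt((var(xc) + var(xt)) / 2)
    dmean <- mean(xc) - mean(xt)
    if (is.na(pooled) || pooled == 0) {
      smd <- if (isTRUE(all.equal(dmean, 0))) 0 else NA_real_
      note <- if (is.na(smd)) "undefined: zero pooled SD, unequal means" else
        "zero pooled SD, equal means"
    } else {
      smd <- dmean / pooled
      note <- ""
    }
    tibble::tibble(feature = f, mean_case = mean(xc), mean_control = mean(xt),
                   pooled_sd = pooled, smd = smd, note = note)
  })
  dplyr::bind_rows(rows)
}
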