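#' Winsorize a numeric vector
#'
#' Treats the top and bottom `tail` fraction of the distribution as
#' outliers: the `floor(n * tail)` smallest observations are raised to the
#' nearest retained order statistic and the `floor(n * tail)` largest are
#' lowered to it. Because the replacement limits are themselves data values,
#' the transform is exactly idempotent. Length and order are preserved;
#' `tail = 0` is the identity.
#'
#' @param values Numeric vector.
#' @param tail Fraction in \[0, 0.5) trimmed from each end (default 0.01,
#'   i.e. the top and bottom 1% are treated as outliers).
#' @return Winsorized vector.
#' @export
winsorize <- function(values, tail = 0.01) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (tail < 0 || tail >= 0.5) stop("`tail` must lie in [0, 0.5)",
                                    call. = FALSE)
  if (tail == 0 || length(values) == 0) return(values)
  lims <- winsor_limits(values, tail)
  clip(values, lims[1], lims[2])
}

# Rank-based winsorization limits: the (k+1)-th smallest and largest order
# statistics with k = floor(n * tail); chosen over interpolated quantiles so
# that reapplication is a no-op.
winsor_limits <- function(values, tail) {
  s <- sort(values)
  n <- length(s)
  k <- floor(n * tail)
  c(s[k + 1], s[n - k])
}

#' Encode mixed sociodemographic features for clustering
#'
#' Categorical features are one-hot encoded (one indicator column per
#' observed level); continuous features are winsorized then standardized to
#' zero mean / unit variance. Row order matches the input. The returned
#' encoding spec (levels, winsorization limits, centers, scales) can be
#' passed back to encode new data consistently; an unseen category at that
#' point is an error naming the offending category.
#'
#' @param cohort Admission table.
#' @param continuous,categorical Feature names. The default clustering
#'   feature set is age, the two area deprivation index ranks, sex, race and
#'   payer; the social vulnerability index can be added via `continuous`.
#' @param tail Winsorization tail fraction.
#' @param spec Optional encoding spec from a previous call (transform mode).
#' @return List with `X` (numeric matrix) and `spec`.
#' @export
encode_features <- function(cohort,
                            continuous = c("age", "adi_state",
                                           "adi_national"),
                            categorical = c("sex", "race", "payer"),
                            tail = 0.01, spec = NULL) {
  for (f in c(continuous, categorical)) {
    if (!f %in% names(cohort)) {
      stop(sprintf("feature `%s` not found in cohort", f), call. = FALSE)
    }
  }
  fit_mode <- is.null(spec)
  if (fit_mode) {
    spec <- list(continuous = continuous, categorical = categorical,
                 tail = tail, winsor_limits = list(), center = c(),
                 scale = c(), levels = list())
  }
  blocks <- list()
  for (f in spec$continuous) {
    x <- as.numeric(cohort[[f]])
    if (fit_mode) {
      if (spec$tail > 0 && length(x) > 0) {
        spec$winsor_limits[[f]] <- winsor_limits(x, spec$tail)
      } else {
        spec$winsor_limits[[f]] <- range(x)
      }
      xw <- clip(x, spec$winsor_limits[[f]][1], spec$winsor_limits[[f]][2])
      spec$center[f] <- mean(xw)
      s <- sd(xw)
      spec$scale[f] <- if (is.na(s) || s == 0) 1 else s
    } else {
      xw <- clip(x, spec$winsor_limits[[f]][1], spec$winsor_limits[[f]][2])
    }
    blocks[[f]] <- matrix((xw - spec$center[f]) / spec$scale[f],
                          ncol = 1, dimnames = list(NULL, f))
  }
  for (f in spec$categorical) {
    x <- as.character(cohort[[f]])
    if (fit_mode) {
      spec$levels[[f]] <- sort(unique(x))
    } else {
      unseen <- setdiff(unique(x), spec$levels[[f]])
      if (length(unseen)) {
        stop(sprintf("unseen category in `%s`: %s", f,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
    }
    lv <- spec$levels[[f]]
    m <- matrix(0, nrow(cohort), length(lv),
                dimnames = list(NULL, paste(f, lv, sep = "=")))
    m[cbind(seq_len(nrow(cohort)), match(x, lv))] <- 1
    blocks[[f]] <- m
  }
  X <- do.call(cbind, blocks[c(spec$continuous, spec$categorical)])
  list(X = X, spec = spec)
}

#' K-means with seeded restarts and canonical cluster indices
#'
#' Lloyd-style alternation from `restarts` random initializations (distinct
#' data rows as starting centers), keeping the fit with the lowest
#' within-cluster sum of squares. Cluster indices are canonicalized by
#' descending cluster size, then by the first centroid coordinate, so labels
#' are stable across runs and row permutations.
#'
#' @param X Numeric matrix (rows = admissions).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed Integer seed.
#' @param restarts Random initializations (default 10).
#' @return List with `centroids` (k x d), `labels` (integer vector),
#'   `wcss` (total within-cluster sum of squares), `k`.
#' @export
fit_kmeans <- function(X, k, seed = 1L, restarts = 10) {
  X <- as.matrix(X)
  if (k < 1 || k > nrow(X)) {
    stop("`k` must lie between 1 and the number of rows", call. = FALSE)
  }
  if (k == 1) {
    ctr <- matrix(colMeans(X), 1, ncol(X),
                  dimnames = list(NULL, colnames(X)))
    wcss <- sum(sweep(X, 2, ctr[1, ])^2)
    return(list(centroids = ctr, labels = rep(1L, nrow(X)), wcss = wcss,
                k = 1L))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- X[sample.int(nrow(X), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(kmeans(X, centers = init, iter.max = 200,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) {
        # degenerate start (duplicate rows / emptied cluster): fall back to
        # the default algorithm for this restart
        fit <- tryCatch(
          suppressWarnings(kmeans(X, centers = k, iter.max = 200)),
          error = function(e) NULL)
      }
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
  canonicalize_clusters(best$centers, best$cluster, best$tot.withinss, k)
}

canonicalize_clusters <- function(centroids, labels, wcss, k) {
  sizes <- tabulate(labels, nbins = k)
  ord <- order(-sizes, centroids[, 1])
  relabel <- match(seq_len(k), ord)
  list(centroids = centroids[ord, , drop = FALSE],
       labels = as.integer(relabel[labels]),
       wcss = wcss, k = as.integer(k))
}

#' Select the elbow of a within-cluster sum-of-squares curve
#'
#' Both axes are min-max normalized to \[0, 1\] and the selected k is the
#' one maximizing perpendicular distance to the chord joining the curve's
#' endpoints (a "kneedle"-style criterion). An exactly linear curve has no
#' elbow and returns k = 1; ties go to the smallest k.
#'
#' @param wcss_curve Numeric vector of WCSS values for k = 1, 2, ...,
#'   non-increasing.
#' @return Selected k (integer).
#' @export
select_elbow <- function(wcss_curve) {
  kmax <- length(wcss_curve)
  if (kmax < 1) stop("empty WCSS curve", call. = FALSE)
  if (any(diff(wcss_curve) > 1e-8 * max(abs(wcss_curve), 1))) {
    stop("WCSS curve must be non-increasing in k", call. = FALSE)
  }
  if (kmax <= 2) return(1L)
  ks <- seq_len(kmax)
  x <- (ks - 1) / (kmax - 1)
  rngw <- wcss_curve[1] - wcss_curve[kmax]
  if (rngw <= 0) return(1L)  # flat curve
  y <- (wcss_curve - wcss_curve[kmax]) / rngw
  # chord from (0, 1) to (1, 0); distance to line x + y - 1 = 0
  d <- abs(x + y - 1) / sqrt(2)
  if (max(d) < 1e-12) return(1L)  # exactly linear: no elbow
  as.integer(which.max(d))
}

#' Discover sociodemographic phenotypes in a cohort
#'
#' Encodes the clustering features ([encode_features()]), fits K-means for
#' each k in `k_range` with seeded restarts, selects k at the elbow of the
#' WCSS curve ([select_elbow()]), and returns the selected model with
#' canonical cluster labels.
#'
#' @param cohort Admission table (typically one triage cohort).
#' @param k_range Candidate cluster counts (default 1:9, consecutive from 1).
#' @param seed,restarts Passed to [fit_kmeans()].
#' @inheritParams encode_features
#' @return Object of class `phenotype_model`: `feature_names`,
#'   `encoding_spec`, `wcss_curve` (named by k), `selected_k`, `centroids`,
#'   `labels` (named by admission id when available), `seed`.
#' @export
fit_phenotypes <- function(cohort, k_range = 1:9, seed = 1L, restarts = 10,
                           continuous = c("age", "adi_state",
                                          "adi_national"),
                           categorical = c("sex", "race", "payer"),
                           tail = 0.01) {
  if (!identical(as.integer(k_range), seq.int(1L, length(k_range)))) {
    stop("`k_range` must be consecutive integers starting at 1",
         call. = FALSE)
  }
  k_range <- k_range[k_range <= nrow(cohort)]
  enc <- encode_features(cohort, continuous = continuous,
                         categorical = categorical, tail = tail)
  fits <- lapply(k_range, function(k) {
    fit_kmeans(enc$X, k, seed = seed + k, restarts = restarts)
  })
  wcss <- vapply(fits, `[[`, numeric(1), "wcss")
  # enforce nesting: with finitely many restarts a larger k can land in a
  # worse local optimum; fall back to the best smaller-k fit in that case
  for (i in seq_along(wcss)[-1]) {
    if (wcss[i] > wcss[i - 1]) {
      fits[[i]] <- fits[[i - 1]]
      wcss[i] <- wcss[i - 1]
    }
  }
  names(wcss) <- k_range
  selected <- select_elbow(wcss)
  chosen <- fits[[selected]]
  labels <- chosen$labels
  if ("id" %in% names(cohort)) names(labels) <- cohort$id
  structure(list(
    feature_names = colnames(enc$X),
    encoding_spec = enc$spec,
    wcss_curve = wcss,
    selected_k = chosen$k,
    centroids = chosen$centroids,
    labels = labels,
    seed = seed
  ), class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("Phenotype model: k = %d selected from k = 1..%d (n = %d)\n",
              x$selected_k, length(x$wcss_curve), length(x$labels)))
  cat("WCSS curve:", paste(sprintf("%.1f", x$wcss_curve), collapse = ", "),
      "\n")
  invisible(x)
}

#' Summarize clusters sociodemographically
#'
#' Per cluster: n, counts and percentages for categorical variables, and
#' median \[IQR\] for continuous variables — the structure of a phenotype
#' characteristics table.
#'
#' @param cohort Admission table.
#' @param labels Integer cluster labels covering the table (e.g.
#'   `fit_phenotypes(cohort)$labels`).
#' @inheritParams encode_features
#' @return Tibble with columns `cluster`, `n`, `variable`, `level`,
#'   `count`, `percent`, `median`, `q1`, `q3`, `formatted`.
#' @export
summarize_clusters <- function(cohort,
                               labels,
                               continuous = c("age", "adi_state",
                                              "adi_national", "svi"),
                               categorical = c("sex", "race", "payer")) {
  if (length(labels) != nrow(cohort)) {
    stop("labels must cover the table", call. = FALSE)
  }
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  out <- list()
  for (cl in sort(unique(labels))) {
    sub <- cohort[labels == cl, , drop = FALSE]
    n <- nrow(sub)
    for (f in categorical) {
      tab <- table(factor(sub[[f]]))
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster = cl, n = n, variable = f, level = names(tab),
        count = as.integer(tab), percent = 100 * as.integer(tab) / n,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        formatted = sprintf("%d (%s)", as.integer(tab),
                            format_percent(as.integer(tab), n)))
    }
    for (f in continuous) {
      q <- pct_quantile(sub[[f]], c(0.25, 0.5, 0.75))
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster = cl, n = n, variable = f, level = NA_character_,
        count = NA_integer_, percent = NA_real_,
        median = q[2], q1 = q[1], q3 = q[3],
        formatted = sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3]))
    }
  }
  dplyr::bind_rows(out)
}
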