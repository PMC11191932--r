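test_that("winsorization clamps tails under the declared rank convention", {
  x <- withr::with_seed(2, sample(as.numeric(1:100)))
  w <- winsorize(x, 0.01)
  # independent oracle: floor(100 * 0.01) = 1 value replaced at each end,
  # by the 2nd smallest / 2nd largest order statistics
  s <- sort(x)
  expect_equal(min(w), s[2])
  expect_equal(max(w), s[99])
  expect_equal(sort(w)[2:99], s[2:99])
  expect_equal(length(w), 100)
  expect_true(all((w >= s[2]) & (w <= s[99])))
  # idempotence, identity at tail = 0, degenerate input
  expect_equal(winsorize(w, 0.01), w)
  expect_equal(winsorize(x, 0), x)
  expect_equal(winsorize(rep(3, 7)), rep(3, 7))
  expect_error(winsorize(letters), "numeric")
  expect_error(winsorize(x, 0.5), "0.5")
})

test_that("feature encoding one-hot partitions and standardizes", {
  tbl <- tibble::tibble(
    age = c(30, 50, 70), adi_state = c(2, 5, 9), adi_national = c(10, 50, 90),
    sex = c("female", "male", "female"),
    race = c("White", "Black", "White"),
    payer = c("Medicare", "Medicaid", "Medicare"))
  enc <- encode_features(tbl)
  X <- enc$X
  # one row per admission; one-hot blocks sum to 1
  expect_equal(nrow(X), 3)
  sex_cols <- grep("^sex=", colnames(X))
  expect_equal(unname(rowSums(X[, sex_cols, drop = FALSE])), rep(1, 3))
  expect_equal(unname(rowSums(X[, grep("^race=", colnames(X)), drop = FALSE])),
               rep(1, 3))
  # standardized continuous columns: mean 0, variance 1
  expect_equal(mean(X[, "age"]), 0, tolerance = 1e-12)
  expect_equal(var(X[, "age"]), 1, tolerance = 1e-12)
  # two admissions identical except sex differ only in the two sex columns
  t2 <- tbl[c(1, 1), ]
  t2$sex <- c("female", "male")
  e2 <- encode_features(t2)
  diffcols <- which(e2$X[1, ] != e2$X[2, ])
  expect_setequal(colnames(e2$X)[diffcols], c("sex=female", "sex=male"))
  # transform mode rejects unseen categories by name
  expect_error(encode_features(dplyr::mutate(tbl, payer = "Commercial"),
                               spec = enc$spec), "Commercial")
  # single admission still encodes
  e1 <- encode_features(tbl[1, ])
  expect_equal(nrow(e1$X), 1)
})

test_that("k-means recovers planted blobs and satisfies closed forms", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(60, 0), ncol = 2),
               matrix(rnorm(60, 20), ncol = 2))
  })
  truth <- rep(1:2, each = 30)
  # k = 1: centroid is the column means, wcss the total SS
  f1 <- fit_kmeans(X, 1)
  expect_equal(unname(f1$centroids[1, ]), unname(colMeans(X)))
  expect_equal(f1$wcss, sum(sweep(X, 2, colMeans(X))^2))
  # k = 2 with >= 10 SD separation: exact recovery up to permutation
  f2 <- fit_kmeans(X, 2, seed = 3)
  expect_equal(length(unique(paste(f2$labels, truth))), 2)
  # wcss non-increasing in k
  wcss <- vapply(1:5, function(k) fit_kmeans(X, k, seed = k)$wcss,
                 numeric(1))
  expect_true(all(diff(wcss) <= 1e-8))
  expect_error(fit_kmeans(X, nrow(X) + 1), "between 1")
  # determinism under a fixed seed
  expect_identical(fit_kmeans(X, 3, seed = 11, restarts = 5)$labels,
                   fit_kmeans(X, 3, seed = 11, restarts = 5)$labels)
})

test_that("elbow selection follows the chord-distance criterion", {
  # sharp breakpoint at k = 3
  curve <- c(100, 60, 20, 18, 16, 14, 12, 10, 8)
  expect_equal(select_elbow(curve), 3)
  # exactly linear curve: no elbow, k = 1
  expect_equal(select_elbow(seq(100, 20, length.out = 9)), 1)
  # flat curve
  expect_equal(select_elbow(rep(5, 9)), 1)
  expect_error(select_elbow(c(10, 12, 8)), "non-increasing")
  # geometric hand construction: piecewise linear, elbow at planted k
  for (kstar in c(2, 4, 6)) {
    y <- c(seq(100, 30, length.out = kstar),
           seq(30, 25, length.out = 9 - kstar + 1)[-1])
    expect_equal(select_elbow(y), kstar)
  }
})

test_that("planted three-phenotype structure is recovered with k = 3", {
  hits_k <- 0
  hits_ari <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    tbl <- generate_cohort(synthetic_config(n_admissions = 700,
                                            seed = 5000 + i))
    gt <- ground_truth(tbl)
    ph <- fit_phenotypes(tbl, seed = 300 + i)
    hits_k <- hits_k + (ph$selected_k == 3)
    hits_ari <- hits_ari +
      (mclust::adjustedRandIndex(ph$labels, gt$phenotype) >= 0.9)
  }
  expect_gte(hits_k, ceiling(0.95 * reps))
  expect_gte(hits_ari, ceiling(0.95 * reps))
})

test_that("labels are stable under row permutation after canonicalization", {
  tbl <- generate_cohort(synthetic_config(n_admissions = 400, seed = 77))
  ph <- fit_phenotypes(tbl, k_range = 1:4, seed = 9)
  perm <- withr::with_seed(1, sample(nrow(tbl)))
  ph_p <- fit_phenotypes(tbl[perm, ], k_range = 1:4, seed = 9)
  expect_equal(unname(ph_p$labels), unname(ph$labels[perm]))
})

test_that("cluster summaries match hand tabulation", {
  tbl <- tibble::tibble(
    age = c(30, 40, 50, 60, 70, 80),
    sex = c("female", "female", "male", "male", "male", "female"),
    svi = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  s <- summarize_clusters(tbl, labels, continuous = c("age", "svi"),
                          categorical = "sex")
  f1 <- s[s$cluster == 1 & s$variable == "sex" & s$level == "female", ]
  expect_equal(f1$count, 2)
  expect_equal(f1$percent, 100 * 2 / 3)
  a2 <- s[s$cluster == 2 & s$variable == "age", ]
  expect_equal(a2$median, 70)
  # one cluster holding all rows equals the whole-cohort summary
  s_all <- summarize_clusters(tbl, rep(1L, 6), continuous = "age",
                              categorical = "sex")
  expect_equal(s_all$n[1], 6)
  expect_equal(s_all[s_all$variable == "age", ]$median, median(tbl$age))
  expect_error(summarize_clusters(tbl, labels[1:3]), "cover")
})

test_that("planted phenotype age ordering survives clustering summaries", {
  tbl <- generate_cohort(synthetic_config(n_admissions = 700, seed = 123))
  ph <- fit_phenotypes(tbl, seed = 4)
  s <- summarize_clusters(tbl, ph$labels, continuous = "age",
                          categorical = character(0))
  med_age <- s$median[s$variable == "age"][order(s$cluster[s$variable == "age"])]
  # default mixture: largest cluster oldest, smallest youngest
  expect_equal(length(med_age), 3)
  expect_gt(max(med_age), 60)
  expect_lt(min(med_age), 50)
})
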