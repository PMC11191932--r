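test_that("categorical test routing and exact enumeration agree", {
  # balanced table: no association, p = 1
  even <- rbind(c(10, 10), c(10, 10))
  res <- compare_categorical(even)
  expect_equal(res$p_value, 1)
  # small table switches to the exact test and matches the hypergeometric
  # enumeration oracle
  tab <- rbind(c(1, 9), c(8, 2))
  res2 <- compare_categorical(tab)
  expect_equal(res2$test_used, "fisher_exact")
  expect_equal(res2$p_value, oracle_fisher_2x2(tab), tolerance = 1e-9)
  # large-count table uses chi-square
  big <- rbind(c(371, 289), c(1327, 1750))
  res3 <- compare_categorical(big)
  expect_equal(res3$test_used, "chi_square")
  expect_lt(res3$p_value, 0.001)
  expect_error(compare_categorical(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(compare_categorical(rbind(c(1.5, 2), c(3, 4))), "integers")
})

test_that("exact categorical test equals enumeration for all small 2x2 tables", {
  for (n in c(8, 12, 20, 40)) {
    for (rep in 1:6) {
      tab <- withr::with_seed(n * 100 + rep, {
        repeat {
          cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
          m <- matrix(cells, 2, 2)
          if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
        }
        m
      })
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        expect_equal(compare_categorical(tab)$p_value,
                     oracle_fisher_2x2(tab), tolerance = 1e-9,
                     info = paste(tab, collapse = ","))
      }
    }
  }
})

test_that("rank-sum test matches the permutation enumeration oracle", {
  # separated groups: 2 of 20 orderings as extreme
  expect_equal(compare_continuous(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_equal(oracle_ranksum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # random small instances without ties
  withr::with_seed(33, {
    for (rep in 1:10) {
      m <- sample(2:8, 1); n <- sample(2:8, 1)
      x <- sample(seq_len(100), m + n)
      a <- x[seq_len(m)]; b <- x[-seq_len(m)]
      expect_equal(compare_continuous(a, b)$p_value, oracle_ranksum(a, b),
                   tolerance = 1e-9)
    }
  })
  # symmetric groups: p = 1
  expect_equal(compare_continuous(c(1, 4), c(2, 3))$p_value, 1)
  expect_error(compare_continuous(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum detects a 1 SD shift at n = 200 per group", {
  hits <- 0
  for (i in 1:20) {
    withr::with_seed(800 + i, {
      a <- rnorm(200)
      b <- rnorm(200, 1)
    })
    hits <- hits + (compare_continuous(a, b)$p_value < 0.001)
  }
  expect_gte(hits, 20 * 0.99)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(14, {
    for (rep in 1:50) {
      p <- runif(sample(1:20, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("table formatter reproduces printed one-decimal percentages", {
  expect_equal(format_percent(148, 660), "22.4")
  expect_equal(format_percent(36, 2335), "1.5")
  expect_equal(format_percent(663, 2335), "28.4")
  expect_equal(format_percent(371, 660), "56.2")
  expect_equal(format_percent(870, 2335), "37.3")
  expect_equal(format_percent(51, 2335), "2.2")
  expect_equal(format_pvalue(c(0.0004, 0.995, 0.042)),
               c("<0.001", ">0.99", "0.042"))
})

test_that("comparison tables assemble, route, and adjust", {
  withr::with_seed(6, {
    tbl <- tibble::tibble(
      grp = rep(c("case", "control"), each = 60),
      sex = sample(c("female", "male"), 120, replace = TRUE),
      age = c(rnorm(60, 50, 8), rnorm(60, 60, 8)))
  })
  vars <- tibble::tibble(variable = c("sex", "age"),
                         type = c("categorical", "continuous"))
  out <- build_comparison_table(tbl, "grp", vars)
  # one row per sex level plus one age row
  expect_equal(nrow(out), length(unique(tbl$sex)) + 1)
  expect_true(all(out$p_adjusted >= out$p_raw - 1e-12))
  expect_true(all(out$p_adjusted >= 0 & out$p_adjusted <= 1))
  out_raw <- build_comparison_table(tbl, "grp", vars, adjust = FALSE)
  expect_equal(out_raw$p_adjusted, out_raw$p_raw)
  expect_error(build_comparison_table(tbl, "missing", vars), "not found")
  expect_error(
    build_comparison_table(tbl, "grp",
                           tibble::tibble(variable = "age", type = "odd")),
    "unknown variable type")
})

test_that("permuted group labels give roughly uniform adjusted p-values", {
  withr::with_seed(91, {
    tbl <- tibble::tibble(
      x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
    vars <- tibble::tibble(variable = c("x1", "x2", "x3"),
                           type = "continuous")
    p_raw <- replicate(60, {
      tbl$grp <- sample(rep(c("a", "b"), each = 100))
      min(build_comparison_table(tbl, "grp", vars, adjust = FALSE)$p_raw)
    })
  })
  # under the null the minimum of 3 raw p-values exceeds 0.05 most of the time
  expect_gt(mean(p_raw > 0.05), 0.7)
})
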