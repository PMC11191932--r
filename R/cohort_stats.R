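#' Format a percentage to one decimal, as printed in cohort tables
#'
#' @param count,total Non-negative counts.
#' @return Character, e.g. `"22.4"` for 148 of 660.
#' @export
format_percent <- function(count, total) {
  sprintf("%.1f", 100 * count / total)
}

#' Format a p-value for table display
#'
#' `"<0.001"` below 0.001, `">0.99"` above 0.99, otherwise 2 significant
#' digits.
#'
#' @param p Probability in \[0, 1\].
#' @return Character.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<0.001")
    if (pi > 0.99) return(">0.99")
    format(signif(pi, 2), scientific = FALSE)
  }, character(1))
}

#' Two-group test for a categorical variable
#'
#' Pearson chi-square test of independence (without continuity correction)
#' by default, switching to the exact conditional test (Fisher) when any
#' expected cell count is below 5.
#'
#' @param counts 2 x c matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `p_value` and `test_used`
#'   (`"chi_square"`/`"fisher_exact"`).
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    p <- fisher.test(counts)$p.value
    list(p_value = min(p, 1), test_used = "fisher_exact")
  } else {
    p <- suppressWarnings(chisq.test(counts, correct = FALSE)$p.value)
    list(p_value = p, test_used = "chi_square")
  }
}

#' Two-group test for a continuous variable
#'
#' Two-sided Wilcoxon rank-sum (Mann–Whitney) test: exact when both groups
#' have at most 20 observations and there are no ties, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `p_value` and `test_used` (`"rank_sum"`).
#' @export
compare_continuous <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- length(group_a) <= 20 && length(group_b) <= 20 &&
    !any(duplicated(c(group_a, group_b)))
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value)
  list(p_value = min(p, 1), test_used = "rank_sum")
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over one family of p-values
#' (one comparison table), returned in the original order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the raw ones.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Build a two-group comparison table
#'
#' Assembles a Table-1/Table-2-style comparison: for each categorical
#' variable, one row per level with a level-vs-rest 2x2 test
#' ([compare_categorical()]); for each continuous variable, one
#' median-\[IQR\] row with a rank-sum test ([compare_continuous()]).
#' Benjamini–Hochberg adjustment is applied across all rows of the table
#' (the table is the family), switchable off per the convention of tables
#' whose footnotes do not mention adjustment.
#'
#' @param cohort Admission table containing `group_col` and the variables.
#' @param group_col Name of a column with exactly 2 levels.
#' @param variables Data frame / tibble with columns `variable` and `type`
#'   (`"categorical"` or `"continuous"`).
#' @param adjust Apply BH adjustment across rows (default `TRUE`).
#' @return Tibble of comparison rows: `variable`, `level`,
#'   per-group formatted summaries, `test_used`, `p_raw`, `p_adjusted`,
#'   `p_display`.
#' @export
build_comparison_table <- function(cohort, group_col, variables,
                                   adjust = TRUE) {
  if (!group_col %in% names(cohort)) {
    stop(sprintf("group column `%s` not found", group_col), call. = FALSE)
  }
  g <- as.character(cohort[[group_col]])
  glev <- sort(unique(g))
  if (length(glev) != 2) {
    stop("group column must have exactly 2 levels", call. = FALSE)
  }
  a <- cohort[g == glev[1], , drop = FALSE]
  b <- cohort[g == glev[2], , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(variables))) {
    v <- variables$variable[i]
    ty <- variables$type[i]
    if (!v %in% names(cohort)) {
      stop(sprintf("variable `%s` not found", v), call. = FALSE)
    }
    if (ty == "categorical") {
      x <- as.character(cohort[[v]])
      for (lv in sort(unique(x))) {
        na_ <- sum(a[[v]] == lv)
        nb_ <- sum(b[[v]] == lv)
        tab <- rbind(c(na_, nrow(a) - na_), c(nb_, nrow(b) - nb_))
        if (na_ + nb_ == 0 || na_ + nb_ == nrow(a) + nrow(b)) {
          # level absent or universal: no contrast to test
          tst <- list(p_value = NA_real_, test_used = "none")
        } else {
          tst <- compare_categorical(tab)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = v, level = lv,
          summary_a = sprintf("%d (%s)", na_, format_percent(na_, nrow(a))),
          summary_b = sprintf("%d (%s)", nb_, format_percent(nb_, nrow(b))),
          test_used = tst$test_used, p_raw = tst$p_value)
      }
    } else if (ty == "continuous") {
      fmt <- function(x) {
        q <- pct_quantile(x, c(0.25, 0.5, 0.75))
        sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
      }
      tst <- compare_continuous(a[[v]], b[[v]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = NA_character_,
        summary_a = fmt(a[[v]]), summary_b = fmt(b[[v]]),
        test_used = tst$test_used, p_raw = tst$p_value)
    } else {
      stop(sprintf("unknown variable type `%s` for `%s`", ty, v),
           call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- out$p_raw
  testable <- !is.na(out$p_raw)
  if (adjust && any(testable)) {
    out$p_adjusted[testable] <- bh_adjust(out$p_raw[testable])
  }
  out$p_display <- format_pvalue(out$p_adjusted)
  names(out)[names(out) == "summary_a"] <- paste0("summary_", glev[1])
  names(out)[names(out) == "summary_b"] <- paste0("summary_", glev[2])
  out
}
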