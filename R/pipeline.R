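#' Configure an end-to-end triage-equity analysis run
#'
#' Either `input` (path to an admission CSV) or `simulate` (a
#' [synthetic_config()]) must be given, not both. All blocks have working
#' defaults matching the package's documented conventions. A config can
#' also be loaded from YAML with [read_pipeline_config()].
#'
#' @param input Optional path to an admission CSV (validated against the
#'   admissions schema).
#' @param simulate Optional [synthetic_config()] used to generate the input.
#' @param thresholds `"compute"` (empirical percentiles of the
#'   post-exclusion population) or a [fixed_thresholds()] object.
#' @param matching List: `k`, `features`, `standardize`, `caliper`.
#' @param voc List: `denominator`, `continuity_correction`.
#' @param phenotype List: `k_max`, `restarts`, `continuous`, `categorical`.
#' @param stats List: `adjust` (BH adjustment on/off).
#' @param seed Integer seed for seeded stages (clustering restarts).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            thresholds = "compute",
                            matching = list(), voc = list(),
                            phenotype = list(), stats = list(),
                            seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of `input` and `simulate` must be given",
         call. = FALSE)
  }
  matching <- utils::modifyList(
    list(k = 5, features = c("risk_mortality", "risk_prolonged_icu"),
         standardize = TRUE, caliper = NULL), matching)
  voc <- utils::modifyList(
    list(denominator = "per_admission", continuity_correction = FALSE), voc)
  phenotype <- utils::modifyList(
    list(k_max = 9, restarts = 10,
         continuous = c("age", "adi_state", "adi_national"),
         categorical = c("sex", "race", "payer")), phenotype)
  stats <- utils::modifyList(list(adjust = TRUE), stats)
  if (phenotype$k_max < 1 || phenotype$k_max > 9) {
    stop("phenotype k range must lie within [1, 9]", call. = FALSE)
  }
  structure(list(input = input, simulate = simulate,
                 thresholds = thresholds, matching = matching, voc = voc,
                 phenotype = phenotype, stats = stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()`: a `pipeline_config`;
#'   `write_pipeline_config()`: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    sim <- do.call(synthetic_config, raw$simulate[
      setdiff(names(raw$simulate), "phenotype_specs")])
  }
  thresholds <- raw$thresholds %||% "compute"
  if (is.list(thresholds)) thresholds <- do.call(fixed_thresholds, thresholds)
  pipeline_config(input = raw$input, simulate = sim,
                  thresholds = thresholds,
                  matching = raw$matching %||% list(),
                  voc = raw$voc %||% list(),
                  phenotype = raw$phenotype %||% list(),
                  stats = raw$stats %||% list(),
                  seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  ser <- list(input = config$input, thresholds = config$thresholds,
              matching = config$matching, voc = config$voc,
              phenotype = config$phenotype, stats = config$stats,
              seed = config$seed)
  if (!is.null(config$simulate)) {
    ser$simulate <- list(n_admissions = config$simulate$n_admissions,
                         seed = config$simulate$seed,
                         triage_error_rates =
                           config$simulate$triage_error_rates)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_comparison_variables <- function() {
  tibble::tibble(
    variable = c("sex", "race", "payer", "age", "adi_state", "adi_national",
                 "svi", "icu_los_days", "hospital_los_days", "total_cost",
                 "prolonged_icu_48h", "died_in_hospital",
                 "discharged_to_hospice"),
    type = c("categorical", "categorical", "categorical", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "categorical", "categorical",
             "categorical")
  )
}

#' Run the full triage-equity pipeline
#'
#' Executes: simulate or load → exclusions → acuity thresholds →
#' triage classification → risk matching (overtriage vs low-acuity ward
#' controls; undertriage vs high-acuity ICU controls) → value of care per
#' analysis → phenotyping per case cohort → BH-adjusted comparison tables.
#' All tabular outputs are written as CSV under `output_dir`, plus a JSON
#' manifest recording the seed, per-stage row counts, and an MD5 content
#' hash per output file. If classification finds no overtriage and no
#' undertriage cases, the pipeline stops gracefully after writing labels and
#' records a `"no cases"` notice in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(output_dir, name)
    write.csv(as.data.frame(tbl), path, row.names = FALSE, na = "",
              fileEncoding = "UTF-8")
    files <<- c(files, path)
    path
  }

  stage <- "input"
  res <- tryCatch({
    admissions <- if (!is.null(config$simulate)) {
      generate_cohort(config$simulate)
    } else {
      read_cohort(config$input)
    }

    stage <- "exclusions"
    exc <- apply_exclusions(admissions)
    emit(exc$excluded[, c("id", "exclusion_reason")], "exclusions.csv")

    stage <- "thresholds"
    thr <- if (identical(config$thresholds, "compute")) {
      compute_thresholds(exc$kept)
    } else config$thresholds

    stage <- "classify"
    labels <- classify_triage(exc$kept, thr)
    emit(labels, "triage_labels.csv")
    kept <- dplyr::left_join(exc$kept, labels, by = "id")
    counts <- table(labels$label)

    analyses <- list()
    n_over <- sum(labels$label == "overtriage")
    n_under <- sum(labels$label == "undertriage")
    if (n_over == 0 && n_under == 0) {
      notice <- "no cases: zero overtriage and zero undertriage admissions"
      message("run_pipeline: ", notice)
      manifest <- build_manifest(config, files, counts, notice, output_dir)
      return(list(admissions = admissions, exclusions = exc,
                  thresholds = thr, labels = labels, analyses = analyses,
                  manifest = manifest))
    }

    specs <- list(
      overtriage = list(case_label = "overtriage",
                        pool = kept$label == "appropriate_ward" &
                          kept$acuity == "low"),
      undertriage = list(case_label = "undertriage",
                         pool = kept$label == "appropriate_icu" &
                           kept$acuity == "high"))
    for (an in names(specs)) {
      stage <- paste0("match_", an)
      cases <- kept[kept$label == specs[[an]]$case_label, , drop = FALSE]
      pool <- kept[specs[[an]]$pool, , drop = FALSE]
      if (nrow(cases) == 0 || nrow(pool) == 0) next
      mc <- match_controls(cases, pool, k = config$matching$k,
                           features = config$matching$features,
                           standardize = config$matching$standardize,
                           caliper = config$matching$caliper)
      controls <- kept[match(mc$control_ids, kept$id), , drop = FALSE]
      emit(tibble::tibble(
        id = c(mc$case_ids, mc$control_ids),
        role = c(rep("case", length(mc$case_ids)),
                 rep("control", length(mc$control_ids))),
        analysis = an), paste0("cohort_", an, ".csv"))
      emit(balance_diagnostics(cases, controls, config$matching$features),
           paste0("balance_", an, ".csv"))

      stage <- paste0("voc_", an)
      voc <- value_of_care(cases, controls,
                           denominator = config$voc$denominator,
                           continuity_correction =
                             config$voc$continuity_correction)
      emit(tibble::tibble(
        id = c(names(voc$cases$values), names(voc$controls$values)),
        role = c(rep("case", length(voc$cases$values)),
                 rep("control", length(voc$controls$values))),
        value = unname(c(voc$cases$values, voc$controls$values))),
        paste0("value_of_care_", an, ".csv"))

      stage <- paste0("phenotype_", an)
      ph <- fit_phenotypes(cases, k_range = seq_len(config$phenotype$k_max),
                           seed = config$seed,
                           restarts = config$phenotype$restarts,
                           continuous = config$phenotype$continuous,
                           categorical = config$phenotype$categorical)
      emit(tibble::tibble(id = names(ph$labels), cluster = ph$labels),
           paste0("phenotype_labels_", an, ".csv"))
      emit(tibble::tibble(k = as.integer(names(ph$wcss_curve)),
                          wcss = unname(ph$wcss_curve)),
           paste0("wcss_curve_", an, ".csv"))
      emit(summarize_clusters(cases, ph$labels),
           paste0("phenotype_summary_", an, ".csv"))

      stage <- paste0("compare_", an)
      both <- dplyr::bind_rows(
        dplyr::mutate(cases, .group = "case"),
        dplyr::mutate(controls, .group = "control"))
      comparison <- build_comparison_table(
        both, ".group",
        default_comparison_variables()[
          default_comparison_variables()$variable %in% names(both), ,
          drop = FALSE],
        adjust = config$stats$adjust)
      emit(comparison, paste0("comparison_", an, ".csv"))

      analyses[[an]] <- list(matched = mc, value_of_care = voc,
                             phenotypes = ph, comparison = comparison)
    }

    manifest <- build_manifest(config, files, counts, NULL, output_dir)
    list(admissions = admissions, exclusions = exc, thresholds = thr,
         labels = labels, analyses = analyses, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

build_manifest <- function(config, files, label_counts, notice,
                           output_dir) {
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("postriage")),
    label_counts = as.list(label_counts),
    notice = notice,
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
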