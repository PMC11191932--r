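admissions_schema <- function() {
  list(
    id = list(type = "character", required = TRUE),
    risk_mortality = list(type = "numeric", required = TRUE, min = 0,
                          max = 1),
    risk_prolonged_icu = list(type = "numeric", required = TRUE, min = 0,
                              max = 1),
    location = list(type = "character", required = TRUE,
                    levels = location_levels()),
    age = list(type = "numeric", required = TRUE, min = 0, max = 130),
    sex = list(type = "character", required = TRUE, levels = sex_levels()),
    race = list(type = "character", required = TRUE,
                levels = race_levels()),
    rural = list(type = "logical", required = FALSE),
    adi_state = list(type = "numeric", required = FALSE, min = 1, max = 10),
    adi_national = list(type = "numeric", required = FALSE, min = 1,
                        max = 100),
    svi = list(type = "numeric", required = FALSE, min = 0, max = 1),
    payer = list(type = "character", required = TRUE,
                 levels = payer_levels()),
    died_in_hospital = list(type = "logical", required = TRUE),
    discharged_to_hospice = list(type = "logical", required = TRUE),
    icu_los_days = list(type = "numeric", required = TRUE, min = 0),
    hospital_los_days = list(type = "numeric", required = TRUE, min = 0),
    total_cost = list(type = "numeric", required = TRUE, min = 1e-9),
    died_during_index_surgery = list(type = "logical", required = TRUE),
    admission_hours = list(type = "numeric", required = TRUE, min = 0),
    surgery_sequence = list(type = "integer", required = TRUE, min = 1)
  )
}

#' Validate and coerce a table against a named schema
#'
#' Coerces column types, checks enumerations and bounds, and applies the
#' missing-value policy: rows with missing values in *required* fields are
#' dropped (and counted in a message), mirroring exclusion of admissions
#' with missing data. Impossible values (e.g. a risk score above 1 or a
#' negative length of stay) are a validation error reporting the offending
#' row numbers.
#'
#' @param table Data frame to validate.
#' @param schema Schema name; currently `"admissions"`.
#' @param quiet Suppress the dropped-row message.
#' @return The validated tibble (rows with missing required fields
#'   removed), with a `"n_dropped_missing"` attribute.
#' @export
validate_schema <- function(table, schema = "admissions", quiet = FALSE) {
  sch <- switch(schema,
                admissions = admissions_schema(),
                stop(sprintf("unknown schema `%s`", schema), call. = FALSE))
  present <- intersect(names(sch), names(table))
  required <- names(sch)[vapply(sch, `[[`, logical(1), "required")]
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop(sprintf("malformed table: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in present) {
    rule <- sch[[col]]
    table[[col]] <- switch(rule$type,
                           numeric = as.numeric(table[[col]]),
                           integer = as.integer(table[[col]]),
                           logical = as.logical(table[[col]]),
                           character = as.character(table[[col]]))
    if (rule$type == "character" && !is.null(rule$levels)) {
      # empty string = missing for categoricals
      table[[col]][table[[col]] == ""] <- NA_character_
      bad <- which(!is.na(table[[col]]) & !table[[col]] %in% rule$levels)
      if (length(bad)) {
        stop(sprintf("invalid value(s) in `%s` at row(s) %s", col,
                     paste(head(bad, 10), collapse = ", ")), call. = FALSE)
      }
    }
  }
  # impossible values are an error, not silently dropped
  for (col in present) {
    rule <- sch[[col]]
    x <- table[[col]]
    bad <- integer(0)
    if (!is.null(rule$min)) bad <- c(bad, which(!is.na(x) & x < rule$min))
    if (!is.null(rule$max)) bad <- c(bad, which(!is.na(x) & x > rule$max))
    if (length(bad)) {
      stop(sprintf("impossible value(s) in `%s` at row(s) %s", col,
                   paste(head(sort(unique(bad)), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(table))
  for (col in required) keep <- keep & !is.na(table[[col]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    message(sprintf("validate_schema: dropped %d row(s) with missing required fields",
                    n_dropped))
  }
  out <- tibble::as_tibble(table[keep, , drop = FALSE])
  attr(out, "n_dropped_missing") <- n_dropped
  out
}
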