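#' Read a measurement table from delimited text
#'
#' Expects a UTF-8 comma-separated file with a header row and columns
#' `index`, `temperature_C`, `time_days`, `value`, `unit` and optionally
#' `replicate`. Rows are grouped into one series per (index, temperature);
#' unit consistency within a series is enforced, and parse errors name the
#' offending row.
#'
#' @param path Path to the CSV file.
#' @return Tidy tibble of measurements (columns `index_id`,
#'   `temperature_C`, `time_days`, `value`, `unit`, `replicate`), validated
#'   via [split_series()].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Measurement file not found: ", path),
          class = "oliveASLT_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("index", "temperature_C", "time_days", "value", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "oliveASLT_parse_error")
  }
  numeric_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) || anyNA(raw[[col]])) {
      row <- c(bad, which(is.na(raw[[col]])))[1]
      abort(paste0("Non-numeric or missing `", col, "` in ", path,
                   " at data row ", row, " (value: '",
                   raw[[col]][row], "')."),
            class = "oliveASLT_parse_error")
    }
    v
  }
  out <- tibble(
    index_id = raw$index,
    temperature_C = numeric_col("temperature_C"),
    time_days = numeric_col("time_days"),
    value = numeric_col("value"),
    unit = raw$unit,
    replicate = if ("replicate" %in% names(raw)) raw$replicate
                else NA_character_
  )
  split_series(out)  # validates grouping, units, finiteness
  out
}

#' Write a measurement table to delimited text
#'
#' Emits the same format [read_measurements()] reads, so synthetic studies
#' round-trip exactly (values at full precision).
#'
#' @param measurements Tidy measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- tibble(index = measurements$index_id,
                temperature_C = measurements$temperature_C,
                time_days = measurements$time_days,
                value = format(measurements$value, digits = 17, trim = TRUE,
                               scientific = FALSE),
                unit = measurements$unit,
                replicate = measurements$replicate)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Serialize zero-order fits to JSON
#'
#' One record per (index, temperature) with all fit fields at full
#' precision.
#'
#' @param fits Tibble from [fit_rate_constants()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  jsonlite::write_json(fits, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize Arrhenius models to JSON
#'
#' @param models An `arrhenius_model` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  if (inherits(models, "arrhenius_model")) models <- list(models)
  recs <- lapply(models, function(m) {
    list(index = m$index_id, Ea_kJ_mol = m$Ea / 1000, k_ref = m$k_ref,
         T_ref_K = m$T_ref, k0 = m$k0, r2 = m$r2, fit_space = m$fit_space,
         method = m$method, gas_constant = m$gas_constant,
         covariance = m$covariance)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
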