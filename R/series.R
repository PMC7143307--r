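#' Construct a single quality-index measurement series
#'
#' A measurement series holds the observations of one quality index (for
#' example K270 or hexanal) at one storage temperature. It is the unit of
#' work for zero-order rate estimation: observations are sorted by storage
#' time on construction, and replicate determinations at the same time point
#' are kept as separate rows.
#'
#' @param index_id Character scalar naming the index (e.g. `"K270"`, `"PV"`,
#'   `"CT"`, `"HEXANAL"`, `"PPP"`, `"K232"`, `"PHENOLS"`, `"TOCOPHEROLS"`,
#'   or any user-defined label).
#' @param temperature_C Storage temperature in degrees Celsius (scalar).
#' @param time_days Numeric vector of storage times in days, one per
#'   observation; finite and non-negative.
#' @param value Numeric vector of measured index values, same length as
#'   `time_days`; finite. Units are index-specific (absorbance for
#'   K270/K232, meq O2/kg for PV, mg/kg for CT and hexanal, percent for
#'   pyropheophytin a).
#' @param unit Unit label (character scalar).
#' @param replicate Optional replicate identifier per observation; recycled
#'   if scalar.
#'
#' @return A tibble of class `aslt_series` with columns `index_id`,
#'   `temperature_C`, `time_days`, `value`, `unit`, `replicate`, sorted by
#'   `time_days` (ties keep input order).
#' @examples
#' measurement_series("K270", 25, c(0, 30, 60), c(0.15, 0.16, 0.17), "abs")
#' @export
measurement_series <- function(index_id, temperature_C, time_days, value,
                               unit = "unknown", replicate = NA_character_) {
  if (!is.character(index_id) || length(index_id) != 1L || is.na(index_id)) {
    abort("`index_id` must be a single non-missing string.",
          class = "oliveASLT_validation_error")
  }
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      !is.finite(temperature_C)) {
    abort("`temperature_C` must be a single finite number.",
          class = "oliveASLT_validation_error")
  }
  n <- length(time_days)
  if (length(value) != n) {
    abort("`time_days` and `value` must have equal length.",
          class = "oliveASLT_validation_error")
  }
  if (!is.numeric(time_days) || anyNA(time_days) || any(!is.finite(time_days))) {
    abort("`time_days` must be finite and non-missing.",
          class = "oliveASLT_validation_error")
  }
  if (any(time_days < 0)) {
    abort("`time_days` must be non-negative.",
          class = "oliveASLT_validation_error")
  }
  if (!is.numeric(value) || anyNA(value) || any(!is.finite(value))) {
    abort("`value` must be finite and non-missing.",
          class = "oliveASLT_validation_error")
  }
  replicate <- as.character(replicate)
  if (length(replicate) == 1L) replicate <- rep(replicate, n)
  if (length(replicate) != n) {
    abort("`replicate` must be scalar or one value per observation.",
          class = "oliveASLT_validation_error")
  }
  ord <- order(time_days)
  out <- tibble(
    index_id = index_id,
    temperature_C = temperature_C,
    time_days = time_days[ord],
    value = value[ord],
    unit = unit,
    replicate = replicate[ord]
  )
  class(out) <- c("aslt_series", class(out))
  out
}

#' Split a tidy measurement table into per-series objects
#'
#' @param measurements A tibble with columns `index_id`, `temperature_C`,
#'   `time_days`, `value`, `unit` and optionally `replicate` (one row per
#'   observation, possibly many indices and temperatures).
#' @return A named list of [measurement_series()] objects, one per
#'   (index, temperature) combination, named `"<index>@<temperature>C"`.
#' @export
split_series <- function(measurements) {
  required <- c("index_id", "temperature_C", "time_days", "value", "unit")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("Measurement table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "oliveASLT_validation_error")
  }
  if (!"replicate" %in% names(measurements)) {
    measurements$replicate <- NA_character_
  }
  keys <- paste0(measurements$index_id, "@", measurements$temperature_C, "C")
  groups <- split(seq_len(nrow(measurements)), keys)
  out <- lapply(groups, function(idx) {
    block <- measurements[idx, ]
    if (length(unique(block$unit)) > 1L) {
      abort(paste0("Series ", block$index_id[1], " at ", block$temperature_C[1],
                   " °C mixes units: ",
                   paste(unique(block$unit), collapse = ", ")),
            class = "oliveASLT_validation_error")
    }
    measurement_series(block$index_id[1], block$temperature_C[1],
                       block$time_days, block$value, block$unit[1],
                       block$replicate)
  })
  out[order(names(out))]
}
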