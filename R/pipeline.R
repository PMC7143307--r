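#' Configure the ASLT analysis pipeline
#'
#' @param measurements Tidy measurement tibble (e.g. from
#'   [read_measurements()] or [generate_series()]), or `NULL` when
#'   supplying `rates` directly.
#' @param rates Optional rate-constant table (columns `index_id`,
#'   `temperature_C`, `k`, optionally `se_k`, `unit`) to skip the
#'   zero-order stage - the natural input when raw trajectories exist only
#'   as published fitted rates.
#' @param limits Named list of [acceptability_limit()] objects; defaults to
#'   the EVOO registry [evoo_limits()]. Indices without a limit are fitted
#'   but excluded from shelf-life prediction.
#' @param prediction_temperatures Temperatures (degrees Celsius) at which
#'   shelf-life is predicted. Values outside -20 to 80 are rejected; values
#'   outside the calibrated 25-60 span trigger a warning.
#' @param T_ref Reference temperature, K.
#' @param gas_constant Molar gas constant, J/(K mol).
#' @param method `"two-step"` (default) or `"one-step"`.
#' @param fit_space Fit space for the two-step route.
#' @param min_points Minimum observations per fitted segment.
#' @param alpha Significance level for responsiveness classification.
#' @param ci_method,n_boot Confidence-interval settings for
#'   [predict_shelf_life()].
#' @param seed Seed for any stochastic step (bootstrap).
#' @param output_dir Optional directory; when set, rate, model and
#'   shelf-life tables are written there (CSV + JSON).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(measurements = NULL, rates = NULL,
                            limits = evoo_limits(),
                            prediction_temperatures = c(25, 40, 50, 60),
                            T_ref = 318.15, gas_constant = 8.31,
                            method = c("two-step", "one-step"),
                            fit_space = c("log-linear", "nonlinear"),
                            min_points = 4L, alpha = 0.05,
                            ci_method = c("delta", "bootstrap"),
                            n_boot = 1000L, seed = 1L,
                            output_dir = NULL) {
  method <- match.arg(method)
  fit_space <- match.arg(fit_space)
  ci_method <- match.arg(ci_method)
  if (is.null(measurements) && is.null(rates)) {
    abort("Provide `measurements`, `rates`, or both.",
          class = "oliveASLT_validation_error")
  }
  if (any(prediction_temperatures < -20 | prediction_temperatures > 80)) {
    abort("Prediction temperatures must lie within -20 to 80 °C.",
          class = "oliveASLT_validation_error")
  }
  if (any(prediction_temperatures < 25 | prediction_temperatures > 60)) {
    warn("Some prediction temperatures fall outside the calibrated 25-60 °C span; extrapolation is less reliable.")
  }
  structure(list(measurements = measurements, rates = rates, limits = limits,
                 prediction_temperatures = prediction_temperatures,
                 T_ref = T_ref, gas_constant = gas_constant, method = method,
                 fit_space = fit_space, min_points = as.integer(min_points),
                 alpha = alpha, ci_method = ci_method,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full accelerated shelf-life analysis
#'
#' Executes the staged analysis: zero-order rate estimation per (index,
#' temperature), responsiveness classification, Arrhenius
#' temperature-dependence fitting for responsive indices, shelf-life
#' prediction against the configured acceptability limits, and shelf-life
#' plot fitting. When the input is a rate-constant table the first stage is
#' skipped and every supplied index is treated as responsive.
#'
#' @param config A [pipeline_config()].
#' @return List of class `aslt_report` with elements `rates` (per-index,
#'   per-temperature zero-order fits or the supplied rates),
#'   `responsiveness`, `models` (named list of `arrhenius_model`),
#'   `model_table`, `shelf_life` (tibble across indices and temperatures),
#'   `plots` (named list of `shelf_life_plot_model`), and `warnings`.
#' @examples
#' cfg <- pipeline_config(rates = evoo_rate_constants(),
#'                        prediction_temperatures = c(25, 40, 50, 60))
#' rep <- run_pipeline(cfg)
#' rep$shelf_life
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character(0)

  # Stage 1: apparent zero-order rates
  if (!is.null(config$measurements)) {
    fits <- fit_rate_constants(config$measurements,
                               min_points = config$min_points)
    responsiveness <- classify_responsiveness(fits, alpha = config$alpha)
    rates_tbl <- fits
  } else {
    rates_tbl <- as_tibble(config$rates)
    if (!"se_k" %in% names(rates_tbl)) rates_tbl$se_k <- NA_real_
    if (!"unit" %in% names(rates_tbl)) rates_tbl$unit <- "index-units/day"
    responsiveness <- tibble(index_id = unique(rates_tbl$index_id),
                             deciding_temperature_C = NA_real_,
                             k = NA_real_, p_slope = NA_real_,
                             responsive = TRUE, label = "responsive")
  }

  responsive_ids <- responsiveness$index_id[responsiveness$responsive]
  if (!length(responsive_ids)) {
    warn("No responsive index found: no shelf-life can be computed.")
    notes <- c(notes, "no responsive index; shelf-life stage skipped")
  }

  # Stage 2: Arrhenius temperature dependence
  models <- list()
  for (id in responsive_ids) {
    sub <- rates_tbl[rates_tbl$index_id == id, ]
    if (length(unique(sub$temperature_C)) < 2L) {
      notes <- c(notes, paste0(id, ": fewer than 2 temperatures, skipped"))
      next
    }
    fitted <- tryCatch({
      if (config$method == "one-step" && !is.null(config$measurements)) {
        ms <- config$measurements
        fit_arrhenius_onestep(ms[ms$index_id == id, ], T_ref = config$T_ref,
                              gas_constant = config$gas_constant,
                              min_points = config$min_points)
      } else {
        fit_arrhenius_twostep(
          rate_constant_set(id, sub$temperature_C, sub$k, sub$se_k,
                            unit = sub$unit[1]),
          T_ref = config$T_ref, gas_constant = config$gas_constant,
          fit_space = config$fit_space)
      }
    }, error = function(e) {
      notes <<- c(notes, paste0(id, ": Arrhenius stage skipped (",
                                conditionMessage(e), ")"))
      NULL
    })
    if (!is.null(fitted)) models[[id]] <- fitted
  }

  # Stage 3: shelf-life prediction and shelf-life plots
  sl_rows <- list()
  plots <- list()
  for (id in names(models)) {
    limit <- config$limits[[id]]
    if (is.null(limit)) {
      notes <- c(notes, paste0(id, ": no acceptability limit configured, ",
                               "shelf-life not predicted"))
      next
    }
    sl <- predict_shelf_life(models[[id]], limit,
                             config$prediction_temperatures,
                             ci_method = config$ci_method,
                             n_boot = config$n_boot, seed = config$seed)
    sl_rows[[id]] <- sl
    if (length(unique(sl$temperature_C)) >= 3L) {
      plots[[id]] <- fit_shelf_life_plot(sl)
    }
  }
  shelf_life <- if (length(sl_rows)) dplyr::bind_rows(sl_rows) else
    tibble(index_id = character(), temperature_C = numeric(),
           k_T = numeric(), SL_days = numeric(), SL_days_floor = numeric(),
           ci_low = numeric(), ci_high = numeric())

  report <- structure(
    list(rates = rates_tbl, responsiveness = responsiveness,
         models = models, model_table = if (length(models))
           arrhenius_table(models) else tibble(),
         shelf_life = shelf_life, plots = plots, warnings = notes),
    class = "aslt_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(rates_tbl,
                     file.path(config$output_dir, "rate_constants.csv"),
                     progress = FALSE)
    if (length(models)) {
      write_models_json(models,
                        file.path(config$output_dir, "arrhenius_models.json"))
    }
    readr::write_csv(shelf_life,
                     file.path(config$output_dir, "shelf_life.csv"),
                     progress = FALSE)
  }
  report
}

#' @export
print.aslt_report <- function(x, ...) {
  cat("ASLT analysis report\n")
  cat("  Indices fitted:", length(unique(x$rates$index_id)), "\n")
  cat("  Responsive:",
      paste(x$responsiveness$index_id[x$responsiveness$responsive],
            collapse = ", "), "\n")
  if (nrow(x$shelf_life)) {
    cat("  Shelf-life (whole days):\n")
    wide <- tidyr::pivot_wider(
      x$shelf_life[, c("index_id", "temperature_C", "SL_days_floor")],
      names_from = "index_id", values_from = "SL_days_floor")
    print(as.data.frame(wide), row.names = FALSE)
  }
  if (length(x$warnings)) cat("  Notes:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
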