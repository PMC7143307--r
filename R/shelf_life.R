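#' Define an acceptability limit for a quality index
#'
#' Shelf-life ends when an index crosses its acceptability limit; for an
#' upper limit the shelf-life under zero-order kinetics is
#' \eqn{SL = (I_{lim} - I_0) / k_T}.
#'
#' @param index_id Index name.
#' @param I0 Initial index value, index units.
#' @param I_lim Threshold value, index units; must differ from `I0` and
#'   exceed it for an upper limit.
#' @param source Provenance label, e.g. `"EU Reg 2568/91"` or `"user"`.
#' @return A list of class `acceptability_limit`.
#' @examples
#' acceptability_limit("K270", I0 = 0.15, I_lim = 0.22,
#'                     source = "EU Reg 2568/91")
#' @export
acceptability_limit <- function(index_id, I0, I_lim, source = "user") {
  stopifnot(is.numeric(I0), is.numeric(I_lim), length(I0) == 1L,
            length(I_lim) == 1L, is.finite(I0), is.finite(I_lim))
  if (I_lim == I0) {
    warn("`I_lim` equals `I0`: shelf-life will be zero at any temperature.")
  }
  structure(list(index_id = index_id, I0 = I0, I_lim = I_lim,
                 source = source),
            class = "acceptability_limit")
}

#' Built-in acceptability limits for extra-virgin olive oil
#'
#' Regulatory thresholds commonly used for EVOO quality: the EU/IOC legal
#' limits for peroxide value (20.0 meq O2/kg), K232 (2.50) and K270 (0.22),
#' and the Australian-standard pyropheophytin a limit (17%). Initial values
#' default to a reference fresh EVOO composition (K270 0.15, PV 5.7,
#' K232 1.81) and should be overridden with the measured initial value of
#' the product under study when available.
#'
#' @return Named list of [acceptability_limit()] objects for `K270`, `PV`,
#'   `K232` and `PPP`.
#' @export
evoo_limits <- function() {
  list(
    K270 = acceptability_limit("K270", I0 = 0.15, I_lim = 0.22,
                               source = "EU Reg 2568/91 / IOC"),
    PV   = acceptability_limit("PV", I0 = 5.7, I_lim = 20.0,
                               source = "EU Reg 2568/91 / IOC"),
    K232 = acceptability_limit("K232", I0 = 1.81, I_lim = 2.50,
                               source = "EU Reg 2568/91 / IOC"),
    PPP  = acceptability_limit("PPP", I0 = 1.0, I_lim = 17.0,
                               source = "Australian Standard AS 5264-2011")
  )
}

#' Predict shelf-life at a storage temperature
#'
#' Combines an Arrhenius model with an acceptability limit:
#' \eqn{SL = (I_{lim} - I_0) / k_T} with \eqn{k_T} from [predict_rate()].
#' Reported whole days use floor, so a product is never credited with a day
#' it does not complete. Confidence intervals come from the delta method on
#' \eqn{\ln k_T} (using the model covariance of \eqn{(\ln k_{ref}, E_a)}),
#' or from a parametric bootstrap of those two parameters.
#'
#' @param model An `arrhenius_model`.
#' @param limit An [acceptability_limit()] for the same index.
#' @param temperature_C Storage temperature(s) in degrees Celsius.
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap draws when `ci_method = "bootstrap"`.
#' @param seed Optional seed for the bootstrap.
#' @return Tibble of class `shelf_life_prediction`: one row per temperature
#'   with `index_id`, `temperature_C`, `k_T`, `SL_days`, `SL_days_floor`,
#'   `ci_low`, `ci_high`.
#' @examples
#' rs <- rate_constant_set("K270", c(25, 40, 50, 60),
#'                         c(0.18, 0.62, 1.07, 2.20) * 1e-3)
#' m <- fit_arrhenius_twostep(rs)
#' predict_shelf_life(m, evoo_limits()$K270, c(25, 40, 50, 60))
#' @export
predict_shelf_life <- function(model, limit, temperature_C,
                               ci_method = c("delta", "bootstrap"),
                               level = 0.95, n_boot = 1000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(model, "arrhenius_model"),
            inherits(limit, "acceptability_limit"))
  if (!identical(limit$index_id, model$index_id)) {
    abort(paste0("Limit is for ", limit$index_id, " but model is for ",
                 model$index_id, "."),
          class = "oliveASLT_validation_error")
  }
  k_T <- predict_rate(model, temperature_C)
  if (any(k_T <= 0)) {
    abort(paste0("Predicted rate for ", model$index_id,
                 " is non-positive: the index does not degrade and its ",
                 "shelf-life is undefined (effectively unlimited)."),
          class = "oliveASLT_non_degrading_error")
  }
  span <- limit$I_lim - limit$I0
  if (span < 0) {
    abort("`I_lim` below `I0` is not supported for an upper limit.",
          class = "oliveASLT_domain_error")
  }
  SL <- span / k_T

  x <- 1 / celsius_to_kelvin(temperature_C) - 1 / model$T_ref
  V <- model$covariance
  have_cov <- is.matrix(V) && !anyNA(V)
  z <- qnorm(1 - (1 - level) / 2)
  if (span == 0 || !have_cov) {
    ci_low <- ci_high <- rep(NA_real_, length(SL))
    if (span == 0) ci_low <- ci_high <- rep(0, length(SL))
  } else if (ci_method == "delta") {
    # ln SL = ln span - ln k_T; grad of ln k_T wrt (ln k_ref, Ea) = (1, -x/R)
    se_lnk <- vapply(x, function(xi) {
      g <- c(1, -xi / model$gas_constant)
      sqrt(max(0, drop(t(g) %*% V %*% g)))
    }, numeric(1))
    ci_low <- SL * exp(-z * se_lnk)
    ci_high <- SL * exp(z * se_lnk)
  } else {
    if (!is.null(seed)) set.seed(seed)
    L <- chol(V + diag(1e-30, 2))
    draws <- matrix(rnorm(2 * n_boot), ncol = 2) %*% L
    lnk_ref_b <- log(model$k_ref) + draws[, 1]
    Ea_b <- model$Ea + draws[, 2]
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qs <- vapply(x, function(xi) {
      SL_b <- span / exp(lnk_ref_b - Ea_b * xi / model$gas_constant)
      stats::quantile(SL_b, probs, names = FALSE)
    }, numeric(2))
    ci_low <- qs[1, ]
    ci_high <- qs[2, ]
  }

  out <- tibble(index_id = model$index_id, temperature_C = temperature_C,
                k_T = k_T, SL_days = SL, SL_days_floor = floor(SL),
                ci_low = ci_low, ci_high = ci_high)
  class(out) <- c("shelf_life_prediction", class(out))
  out
}

#' Fit a shelf-life plot (ln SL versus temperature)
#'
#' The shelf-life plot regresses the natural log of predicted shelf-life on
#' storage temperature in degrees Celsius; its straight line is the usual
#' extrapolation tool for temperatures outside the tested range. An
#' Arrhenius-consistent variant regressing on inverse absolute temperature
#' is available via `x_axis = "inv_kelvin"`.
#'
#' @param predictions A [predict_shelf_life()] table (or any tibble with
#'   `temperature_C` and `SL_days`) covering at least 3 distinct
#'   temperatures with positive shelf-lives.
#' @param x_axis `"celsius"` (default) or `"inv_kelvin"`.
#' @return List of class `shelf_life_plot_model` with `slope`, `intercept`
#'   (ln days), `r2`, and `x_axis`.
#' @export
fit_shelf_life_plot <- function(predictions,
                                x_axis = c("celsius", "inv_kelvin")) {
  x_axis <- match.arg(x_axis)
  tc <- predictions$temperature_C
  SL <- predictions$SL_days
  if (length(unique(tc)) < 3L) {
    abort("At least 3 distinct temperatures are required for a shelf-life plot.",
          class = "oliveASLT_insufficient_design_error")
  }
  if (any(SL <= 0)) {
    abort("All shelf-lives must be positive to fit ln(SL).",
          class = "oliveASLT_domain_error")
  }
  xv <- if (x_axis == "celsius") tc else 1 / celsius_to_kelvin(tc)
  f <- ols_line(xv, log(SL))
  structure(list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
                 x_axis = x_axis, n = length(SL)),
            class = "shelf_life_plot_model")
}

#' Predict shelf-life from a fitted shelf-life plot
#'
#' @param plot_model A [fit_shelf_life_plot()] result.
#' @param temperature_C Temperature(s) in degrees Celsius.
#' @return Shelf-life in days: `exp(intercept + slope * x)` where x is the
#'   plot's abscissa (Celsius or 1/K).
#' @export
predict_from_plot <- function(plot_model, temperature_C) {
  stopifnot(inherits(plot_model, "shelf_life_plot_model"))
  xv <- if (plot_model$x_axis == "celsius") temperature_C
        else 1 / celsius_to_kelvin(temperature_C)
  exp(plot_model$intercept + plot_model$slope * xv)
}

#' Acceleration factor between two storage temperatures
#'
#' Ratio of the predicted degradation rate at a test temperature to that at
#' a market temperature. Under a shared acceptability limit it equals the
#' inverse ratio of shelf-lives, i.e. how many days of market storage one
#' day of accelerated testing stands for.
#'
#' @param model An `arrhenius_model`.
#' @param test_temperature_C Accelerated-test temperature, degrees Celsius.
#' @param market_temperature_C Market/storage temperature, degrees Celsius.
#' @return Dimensionless ratio `k(test) / k(market)`.
#' @examples
#' rs <- rate_constant_set("K270", c(25, 40, 50, 60),
#'                         c(0.18, 0.62, 1.07, 2.20) * 1e-3)
#' acceleration_factor(fit_arrhenius_twostep(rs), 60, 25)
#' @export
acceleration_factor <- function(model, test_temperature_C,
                                market_temperature_C) {
  predict_rate(model, test_temperature_C) /
    predict_rate(model, market_temperature_C)
}

#' @export
print.shelf_life_plot_model <- function(x, ...) {
  cat(sprintf(
    "Shelf-life plot model: ln(SL) = %.4f %+.4g * %s  (r2 = %.3f, n = %d)\n",
    x$intercept, x$slope,
    if (x$x_axis == "celsius") "T[degC]" else "1/T[K]", x$r2, x$n))
  invisible(x)
}
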