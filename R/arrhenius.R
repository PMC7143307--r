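#' Assemble a rate-constant set for Arrhenius modelling
#'
#' @param index_id Index name (character scalar).
#' @param temperature_C Storage temperatures in degrees Celsius.
#' @param k Apparent zero-order rate constants, index-units per day; same
#'   length as `temperature_C`, all finite.
#' @param se_k Optional standard errors of `k`.
#' @param unit Unit label for `k` (per day).
#' @return A tibble of class `rate_constant_set`.
#' @examples
#' rate_constant_set("K270", c(25, 40, 50, 60),
#'                   c(0.18, 0.62, 1.07, 2.20) * 1e-3)
#' @export
rate_constant_set <- function(index_id, temperature_C, k, se_k = NA_real_,
                              unit = "index-units/day") {
  if (length(k) != length(temperature_C)) {
    abort("`k` and `temperature_C` must have equal length.",
          class = "oliveASLT_validation_error")
  }
  if (anyNA(k) || any(!is.finite(k))) {
    abort("All rate constants must be finite.",
          class = "oliveASLT_validation_error")
  }
  if (length(unique(temperature_C)) < 2L) {
    abort("At least 2 distinct temperatures are required.",
          class = "oliveASLT_insufficient_design_error")
  }
  if (length(se_k) == 1L) se_k <- rep(se_k, length(k))
  out <- tibble(index_id = index_id, temperature_C = temperature_C,
                k = k, se_k = se_k, unit = unit)
  class(out) <- c("rate_constant_set", class(out))
  out
}

new_arrhenius_model <- function(index_id, Ea, k_ref, T_ref, gas_constant,
                                r2, covariance, fit_space, method,
                                unit = "index-units/day", extra = list()) {
  model <- c(list(
    index_id = index_id,
    Ea = Ea,                       # J/mol
    k_ref = k_ref,                 # index-units/day at T_ref
    T_ref = T_ref,                 # K
    k0 = exp(log(k_ref) + Ea / (gas_constant * T_ref)),
    gas_constant = gas_constant,   # J/(K mol)
    r2 = r2,
    covariance = covariance,       # 2x2 of (ln k_ref, Ea)
    fit_space = fit_space,
    method = method,
    unit = unit
  ), extra)
  structure(model, class = "arrhenius_model")
}

#' Fit the reparametrized Arrhenius equation to rate constants (two-step)
#'
#' Models the temperature dependence of apparent rate constants as
#' \deqn{\ln k = \ln k_{ref} - \frac{E_a}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\right)}
#' where the reference temperature, chosen near the middle of the tested
#' range, decorrelates the two parameters. In the default log-linear space
#' this is ordinary least squares of \eqn{\ln k} on
#' \eqn{(1/T - 1/T_{ref})}; the nonlinear space refits k itself by
#' Levenberg-Marquardt least squares initialized from the log-linear
#' solution. The pre-exponential (frequency) factor is recovered as
#' \eqn{k_0 = \exp(\ln k_{ref} + E_a/(R\,T_{ref}))}.
#'
#' @param rates A [rate_constant_set()], or a tibble with columns
#'   `temperature_C` and `k` (and optionally `index_id`, `unit`).
#' @param T_ref Reference absolute temperature in K (default 318.15, i.e.
#'   45 degrees Celsius, the midpoint of a 25-60 degree design).
#' @param gas_constant Molar gas constant in J/(K mol); default 8.31.
#' @param fit_space `"log-linear"` (default) or `"nonlinear"`.
#' @return An `arrhenius_model`: list with `Ea` (J/mol), `k_ref`, `T_ref`,
#'   `k0`, `gas_constant`, `r2` (in the fitted space), `covariance` (2x2 of
#'   `(ln k_ref, Ea)`), `fit_space`, `method = "two-step"`.
#' @examples
#' rs <- rate_constant_set("K270", c(25, 40, 50, 60),
#'                         c(0.18, 0.62, 1.07, 2.20) * 1e-3)
#' m <- fit_arrhenius_twostep(rs)
#' m$Ea / 1000  # activation energy in kJ/mol
#' @export
fit_arrhenius_twostep <- function(rates, T_ref = 318.15, gas_constant = 8.31,
                                  fit_space = c("log-linear", "nonlinear")) {
  fit_space <- match.arg(fit_space)
  stopifnot(T_ref > 0, gas_constant > 0)
  temperature_C <- rates$temperature_C
  k <- rates$k
  index_id <- if ("index_id" %in% names(rates)) rates$index_id[1] else "index"
  unit <- if ("unit" %in% names(rates)) rates$unit[1] else "index-units/day"
  if (length(unique(temperature_C)) < 2L) {
    abort("At least 2 distinct temperatures are required.",
          class = "oliveASLT_insufficient_design_error")
  }
  if (any(k <= 0)) {
    bad <- which(k <= 0)[1]
    abort(paste0("Non-positive rate constant for ", index_id, " at ",
                 temperature_C[bad], " °C: log-linear Arrhenius fitting ",
                 "requires k > 0."),
          class = "oliveASLT_domain_error")
  }
  x <- 1 / celsius_to_kelvin(temperature_C) - 1 / T_ref
  log_fit <- lm(log(k) ~ x)
  slope <- unname(coef(log_fit)[2L])
  intercept <- unname(coef(log_fit)[1L])
  Ea <- -slope * gas_constant
  k_ref <- exp(intercept)
  n <- length(k)
  # covariance of (ln k_ref, Ea) = J V J' with J = diag(1, -R)
  V <- if (n > 2L) suppressWarnings(vcov(log_fit)) else matrix(0, 2, 2)
  J <- diag(c(1, -gas_constant))
  covariance <- J %*% V %*% t(J)
  dimnames(covariance) <- list(c("ln_k_ref", "Ea"), c("ln_k_ref", "Ea"))
  rss <- sum(resid(log_fit)^2)
  tss <- sum((log(k) - mean(log(k)))^2)
  r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))

  if (fit_space == "nonlinear") {
    nl <- minpack.lm::nlsLM(
      k ~ kr * exp(-Ea_p / gas_constant * x),
      data = data.frame(k = k, x = x),
      start = list(kr = k_ref, Ea_p = Ea),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12))
    k_ref <- unname(coef(nl)["kr"])
    Ea <- unname(coef(nl)["Ea_p"])
    V_nl <- tryCatch(vcov(nl), error = function(e) matrix(NA_real_, 2, 2))
    # transform cov of (k_ref, Ea) to (ln k_ref, Ea)
    J_nl <- diag(c(1 / k_ref, 1))
    covariance <- J_nl %*% V_nl %*% t(J_nl)
    dimnames(covariance) <- list(c("ln_k_ref", "Ea"), c("ln_k_ref", "Ea"))
    rss <- sum(resid(nl)^2)
    tss <- sum((k - mean(k))^2)
    r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))
  }

  new_arrhenius_model(index_id, Ea, k_ref, T_ref, gas_constant, r2,
                      covariance, fit_space, method = "two-step",
                      unit = unit, extra = list(n_rates = n))
}

#' One-step Arrhenius fit over all storage observations
#'
#' Instead of condensing each temperature into a fitted rate first, the
#' one-step fit regresses every retained observation jointly on the model
#' \deqn{I(t, T) = I_{0,T} + k_{ref}\,
#'   e^{-\frac{E_a}{R}(\frac{1}{T}-\frac{1}{T_{ref}})}\, t}
#' with a shared activation energy and reference rate and (by default) one
#' intercept per temperature. Increasing segments are selected per series
#' before fitting, exactly as in the two-step route. Levenberg-Marquardt
#' least squares, initialized from the two-step solution.
#'
#' @param series_list List of [measurement_series()] (or a tidy measurement
#'   table) covering one index at two or more temperatures.
#' @inheritParams fit_arrhenius_twostep
#' @param min_points Passed to the per-series segment selection.
#' @param intercepts `"per_temperature"` (default) or `"shared"`.
#' @param max_iter Maximum optimizer iterations.
#' @return An `arrhenius_model` with `method = "one-step"`, plus elements
#'   `intercepts_fit` (named per-temperature intercepts), `convergence`
#'   (optimizer message) and `n_obs`.
#' @export
fit_arrhenius_onestep <- function(series_list, T_ref = 318.15,
                                  gas_constant = 8.31, min_points = 4L,
                                  intercepts = c("per_temperature", "shared"),
                                  max_iter = 1000L) {
  intercepts <- match.arg(intercepts)
  if (is_tibble(series_list) || is.data.frame(series_list)) {
    series_list <- split_series(series_list)
  }
  temps <- vapply(series_list, function(s) s$temperature_C[1], numeric(1))
  if (length(unique(temps)) < 2L) {
    abort("At least 2 distinct temperatures are required.",
          class = "oliveASLT_insufficient_design_error")
  }
  index_id <- series_list[[1]]$index_id[1]
  unit <- series_list[[1]]$unit[1]

  # per-series truncation to the increasing segment, then pooled data
  fits <- lapply(series_list, fit_zero_order, min_points = min_points)
  pooled <- dplyr::bind_rows(lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    m <- fits[[i]]$truncated_at
    tibble(time = s$time_days[1:m], value = s$value[1:m],
           temperature_C = s$temperature_C[1])
  }))
  pooled$grp <- as.integer(factor(pooled$temperature_C))
  pooled$x <- 1 / celsius_to_kelvin(pooled$temperature_C) - 1 / T_ref
  n_grp <- max(pooled$grp)

  # initialize from the two-step route
  start_rates <- rate_constant_set(
    index_id,
    vapply(fits, function(f) f$temperature_C, numeric(1)),
    pmax(vapply(fits, function(f) f$k, numeric(1)), 1e-12))
  init <- fit_arrhenius_twostep(start_rates, T_ref, gas_constant)
  init_I0 <- vapply(fits, function(f) f$intercept, numeric(1))
  grp_of_temp <- as.integer(factor(vapply(fits, function(f) f$temperature_C,
                                          numeric(1))))
  I0_start <- vapply(seq_len(n_grp),
                     function(g) mean(init_I0[grp_of_temp == g]), numeric(1))

  fml <- if (intercepts == "per_temperature") {
    value ~ I0[grp] + kr * exp(-Ea_p / gas_constant * x) * time
  } else {
    value ~ I0 + kr * exp(-Ea_p / gas_constant * x) * time
  }
  start <- list(I0 = if (intercepts == "per_temperature") I0_start
                     else mean(I0_start),
                kr = init$k_ref, Ea_p = init$Ea)
  nl <- tryCatch(
    stats::nls(fml, data = pooled, start = start, algorithm = "port",
               control = stats::nls.control(maxiter = max_iter,
                                            tol = 1e-10, warnOnly = FALSE)),
    error = function(e) {
      abort(paste0("One-step Arrhenius fit for ", index_id,
                   " failed to converge: ", conditionMessage(e)),
            class = "oliveASLT_estimation_failure")
    })
  cf <- coef(nl)
  k_ref <- unname(cf["kr"])
  Ea <- unname(cf["Ea_p"])
  V_all <- tryCatch(suppressWarnings(vcov(nl)), error = function(e) NULL)
  covariance <- matrix(NA_real_, 2, 2,
                       dimnames = list(c("ln_k_ref", "Ea"),
                                       c("ln_k_ref", "Ea")))
  if (!is.null(V_all)) {
    idx <- match(c("kr", "Ea_p"), rownames(V_all))
    V2 <- V_all[idx, idx]
    J <- diag(c(1 / k_ref, 1))
    covariance <- J %*% V2 %*% t(J)
    dimnames(covariance) <- list(c("ln_k_ref", "Ea"), c("ln_k_ref", "Ea"))
  }
  rss <- sum(resid(nl)^2)
  tss <- sum((pooled$value - mean(pooled$value))^2)
  r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))
  I0_hat <- cf[startsWith(names(cf), "I0")]
  names(I0_hat) <- paste0(sort(unique(pooled$temperature_C)), "C")[
    seq_along(I0_hat)]

  new_arrhenius_model(
    index_id, Ea, k_ref, T_ref, gas_constant, r2, covariance,
    fit_space = "nonlinear", method = "one-step", unit = unit,
    extra = list(intercepts_fit = I0_hat,
                 convergence = nl$convInfo$stopMessage,
                 n_obs = nrow(pooled)))
}

#' Pre-exponential factor from a fitted Arrhenius model
#'
#' Evaluates \eqn{k_0 = \exp(\ln k_{ref} + E_a / (R\,T_{ref}))}, the rate
#' the model extrapolates to infinite temperature, in the same units as
#' `k_ref`.
#'
#' @param model An `arrhenius_model`.
#' @return `k0` in index-units per day.
#' @export
compute_k0 <- function(model) {
  stopifnot(inherits(model, "arrhenius_model"))
  exp(log(model$k_ref) + model$Ea / (model$gas_constant * model$T_ref))
}

#' Predict the degradation rate at a storage temperature
#'
#' @param model An `arrhenius_model`.
#' @param temperature_C Temperature(s) in degrees Celsius (above absolute
#'   zero).
#' @return Predicted rate constant(s) k in index-units per day; equals
#'   `k_ref` exactly when the temperature matches `T_ref`.
#' @examples
#' rs <- rate_constant_set("K270", c(25, 40, 50, 60),
#'                         c(0.18, 0.62, 1.07, 2.20) * 1e-3)
#' predict_rate(fit_arrhenius_twostep(rs), 25)
#' @export
predict_rate <- function(model, temperature_C) {
  stopifnot(inherits(model, "arrhenius_model"))
  T_K <- celsius_to_kelvin(temperature_C)
  model$k_ref * exp(-model$Ea / model$gas_constant * (1 / T_K - 1 / model$T_ref))
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat(sprintf(
    "Arrhenius model (%s, %s %s)\n  Ea = %.2f kJ/mol, k_ref = %.4g %s at T_ref = %.2f K\n  k0 = %.3g, r2 = %.3f (R = %g J/K/mol)\n",
    x$index_id, x$method, x$fit_space, x$Ea / 1000, x$k_ref, x$unit,
    x$T_ref, x$k0, x$r2, x$gas_constant))
  invisible(x)
}

#' Tidy one or more Arrhenius models into a table
#'
#' @param models An `arrhenius_model` or list of them.
#' @return Tibble with one row per model: index, Ea in kJ/mol, k_ref, T_ref,
#'   k0, r2, fit space and method.
#' @export
arrhenius_table <- function(models) {
  if (inherits(models, "arrhenius_model")) models <- list(models)
  dplyr::bind_rows(lapply(models, function(m) {
    tibble(index_id = m$index_id, Ea_kJ_mol = m$Ea / 1000, k_ref = m$k_ref,
           T_ref_K = m$T_ref, k0 = m$k0, r2 = m$r2,
           fit_space = m$fit_space, method = m$method,
           gas_constant = m$gas_constant)
  }))
}
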