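#' @section Zero-order kinetics:
#' Under apparent zero-order kinetics an index I grows linearly with storage
#' time, I(t) = I0 + k t, and the rate constant k is the slope of the
#' ordinary least-squares line of value on time. Only the increasing part of
#' a trajectory is informative about k when the index later saturates, so
#' fitting is preceded by an increasing-segment search.
#' @name kinetics
#' @keywords internal
NULL

# Closed-form OLS of value on time with the diagnostics the kinetics
# report needs (normal equations; called thousands of times by the prefix
# search, so no lm() overhead). r2 is clamped to [0, 1] and defined as 0
# for a constant response (zero total sum of squares); slope is NA on a
# degenerate design (all times equal).
ols_line <- function(time_days, value) {
  n <- length(time_days)
  tbar <- mean(time_days)
  vbar <- mean(value)
  sxx <- sum((time_days - tbar)^2)
  if (sxx <= 0) {
    return(list(slope = NA_real_, intercept = vbar, se_slope = NA_real_,
                r2 = 0, p_slope = NA_real_, rmse = sqrt(mean((value - vbar)^2)),
                residuals = value - vbar, n = n))
  }
  slope <- sum((time_days - tbar) * (value - vbar)) / sxx
  intercept <- vbar - slope * tbar
  res <- value - intercept - slope * time_days
  rss <- sum(res^2)
  tss <- sum((value - vbar)^2)
  r2 <- if (tss <= 0) 0 else max(0, min(1, 1 - rss / tss))
  df <- n - 2L
  sigma2 <- if (df > 0) rss / df else 0
  se_slope <- sqrt(sigma2 / sxx)
  p_slope <- if (df > 0 && is.finite(se_slope) && se_slope > 0) {
    2 * pt(-abs(slope / se_slope), df = df)
  } else if (isTRUE(all.equal(slope, 0))) {
    1
  } else {
    0  # exact non-zero slope: infinitely strong evidence
  }
  list(slope = slope, intercept = intercept, se_slope = se_slope,
       r2 = r2, p_slope = p_slope, rmse = sqrt(mean(res^2)),
       residuals = res, n = n)
}

#' Select the increasing segment of a storage trajectory
#'
#' Several indices (notably pyropheophytin a at high temperature) rise
#' linearly and then saturate at a plateau; only the rising part carries the
#' zero-order rate. All prefix lengths from `min_points` to the full series
#' are searched exhaustively and the positive-slope prefix with the highest
#' coefficient of determination wins, ties broken toward the longest
#' prefix. To keep chance collinearity in a short noisy prefix from
#' truncating a genuinely linear series, a prefix shorter than the full
#' series is only eligible when the excluded tail departs downward from the
#' extrapolated prefix line beyond prediction noise (mean standardized tail
#' deviation below -2, with the full-series RMSE as the noise scale) - the
#' signature of plateau onset. If no prefix has a
#' positive slope the full series is returned so that the downstream fit
#' reports the (non-positive) slope unchanged.
#'
#' @param series A [measurement_series()].
#' @param min_points Minimum number of observations in the fitted segment
#'   (default 4; at least 3).
#' @return Integer prefix length m, `min_points <= m <= nrow(series)`.
#' @examples
#' s <- measurement_series("K270", 25, 0:9, 0.15 + 0.002 * 0:9, "abs")
#' select_increasing_segment(s)  # full length: no plateau
#' @export
select_increasing_segment <- function(series, min_points = 4L) {
  min_points <- as.integer(min_points)
  if (min_points < 3L) {
    abort("`min_points` must be at least 3.",
          class = "oliveASLT_precondition_error")
  }
  n <- nrow(series)
  if (n < min_points) {
    abort(paste0("Series ", series$index_id[1], " at ", series$temperature_C[1],
                 " °C has ", n, " observations; at least ", min_points,
                 " are required."),
          class = "oliveASLT_precondition_error")
  }
  tt <- series$time_days
  vv <- series$value
  full <- ols_line(tt, vv)
  noise_scale <- max(full$rmse, .Machine$double.eps)
  best_m <- NA_integer_
  best_r2 <- -Inf
  for (m in min_points:n) {
    f <- ols_line(tt[1:m], vv[1:m])
    if (!is.finite(f$slope) || f$slope <= 0) next
    if (m < n) {
      # a shorter prefix is eligible only when the excluded tail departs
      # downward from the extrapolated prefix line beyond prediction noise
      tail_idx <- (m + 1L):n
      pred <- f$intercept + f$slope * tt[tail_idx]
      sxx_m <- sum((tt[1:m] - mean(tt[1:m]))^2)
      se_pred <- noise_scale *
        sqrt(1 + 1 / m + (tt[tail_idx] - mean(tt[1:m]))^2 / sxx_m)
      z_tail <- mean((vv[tail_idx] - pred) / se_pred)
      if (z_tail >= -2) next
    }
    if (f$r2 >= best_r2) {  # >= breaks ties toward the longest prefix
      best_r2 <- f$r2
      best_m <- m
    }
  }
  if (is.na(best_m)) n else best_m
}

#' Flag a possible lag phase before the linear rise
#'
#' Advisory check for a lag (induction) period: the flag is raised when the
#' earliest observation sits more than two root-mean-square residuals below
#' the fitted zero-order line and dropping it improves the coefficient of
#' determination. The flag never alters the fitted rate.
#'
#' @param series A [measurement_series()].
#' @param fit A [fit_zero_order()] result computed on `series`.
#' @return Logical; `TRUE` when a lag phase is suspected. Degenerate
#'   zero-residual fits return `FALSE`.
#' @export
detect_lag <- function(series, fit) {
  m <- fit$truncated_at
  t_seg <- series$time_days[1:m]
  v_seg <- series$value[1:m]
  f <- ols_line(t_seg, v_seg)
  if (!is.finite(f$slope) || f$rmse <= 0) return(FALSE)
  first_resid <- v_seg[1] - (f$intercept + f$slope * t_seg[1])
  if (first_resid >= -2 * f$rmse) return(FALSE)
  if (m - 1L < 3L) return(FALSE)
  f_drop <- ols_line(t_seg[-1], v_seg[-1])
  f_drop$r2 > f$r2
}

#' Fit an apparent zero-order rate constant to one series
#'
#' Ordinary least squares of index value on storage time over the increasing
#' segment chosen by [select_increasing_segment()]. The slope is the
#' apparent zero-order rate constant k in index-units per day.
#'
#' @inheritParams select_increasing_segment
#' @param average_replicates If `TRUE`, replicate determinations at the same
#'   time point are averaged before regression; by default they enter as
#'   separate observations.
#' @return A list of class `zero_order_fit` with elements `index_id`,
#'   `temperature_C`, `unit`, `k` (slope, index-units/day), `intercept`
#'   (fitted initial value), `se_k`, `r2`, `p_slope` (two-sided t test on
#'   the slope, `n_used - 2` degrees of freedom), `n_used`, `truncated_at`
#'   (index of the last observation retained) and `lag_flag`.
#' @examples
#' s <- measurement_series("K270", 25, seq(0, 300, 30),
#'                         0.15 + 2e-4 * seq(0, 300, 30), "abs")
#' fit_zero_order(s)$k
#' @export
fit_zero_order <- function(series, min_points = 4L,
                           average_replicates = FALSE) {
  if (average_replicates) {
    agg <- stats::aggregate(value ~ time_days, data = series, FUN = mean)
    series <- measurement_series(series$index_id[1], series$temperature_C[1],
                                 agg$time_days, agg$value, series$unit[1])
  }
  if (length(unique(series$time_days)) < 2L) {
    abort(paste0("Series ", series$index_id[1], " at ", series$temperature_C[1],
                 " °C has all observations at the same time; ",
                 "the regression design is degenerate."),
          class = "oliveASLT_degenerate_design_error")
  }
  m <- select_increasing_segment(series, min_points)
  f <- ols_line(series$time_days[1:m], series$value[1:m])
  out <- structure(
    list(index_id = series$index_id[1],
         temperature_C = series$temperature_C[1],
         unit = series$unit[1],
         k = f$slope,
         intercept = f$intercept,
         se_k = f$se_slope,
         r2 = f$r2,
         p_slope = f$p_slope,
         n_used = m,
         truncated_at = m,
         lag_flag = FALSE),
    class = "zero_order_fit")
  out$lag_flag <- detect_lag(series, out)
  out
}

#' @export
print.zero_order_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-order fit: %s at %g degC\n  k = %.4g %s/day (SE %.3g), r2 = %.3f, p = %.3g\n  n used = %d of segment end %d%s\n",
    x$index_id, x$temperature_C, x$k, x$unit, x$se_k, x$r2, x$p_slope,
    x$n_used, x$truncated_at,
    if (x$lag_flag) " [possible lag phase]" else ""))
  invisible(x)
}

#' Fit zero-order rate constants for every series in a measurement table
#'
#' @param measurements Tidy measurement table (see [split_series()]) or a
#'   list of [measurement_series()] objects.
#' @inheritParams fit_zero_order
#' @return A tibble with one row per (index, temperature): all
#'   `zero_order_fit` fields as columns, sorted by index then temperature.
#' @export
fit_rate_constants <- function(measurements, min_points = 4L,
                               average_replicates = FALSE) {
  series_list <- if (is_tibble(measurements) || is.data.frame(measurements)) {
    split_series(measurements)
  } else {
    measurements
  }
  fits <- lapply(series_list, fit_zero_order, min_points = min_points,
                 average_replicates = average_replicates)
  out <- dplyr::bind_rows(lapply(fits, function(f) as_tibble(unclass(f))))
  dplyr::arrange(out, .data$index_id, .data$temperature_C)
}

#' Classify indices as responsive or non-responsive
#'
#' An index is a usable shelf-life indicator only if it changes measurably
#' during storage. Following standard ASLT practice the call is made at the
#' highest tested temperature, where any real response is fastest: the index
#' is labelled `"responsive"` when its slope there is positive with
#' `p_slope < alpha`, otherwise `"non-responsive"`. The label is advisory
#' and never blocks fitting.
#'
#' @param fits Tibble of zero-order fits as returned by
#'   [fit_rate_constants()].
#' @param alpha Significance level for the slope test (default 0.05).
#' @return Tibble with columns `index_id`, `responsive` (logical), `label`,
#'   plus the slope and p-value at the deciding temperature.
#' @export
classify_responsiveness <- function(fits, alpha = 0.05) {
  stopifnot(nrow(fits) >= 1L)
  fits |>
    dplyr::group_by(.data$index_id) |>
    dplyr::slice_max(.data$temperature_C, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$index_id,
      deciding_temperature_C = .data$temperature_C,
      k = .data$k,
      p_slope = .data$p_slope,
      responsive = .data$k > 0 & .data$p_slope < alpha,
      label = ifelse(.data$responsive, "responsive", "non-responsive")
    )
}
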