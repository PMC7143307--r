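test_that("index specs and study configs validate their fields", {
  expect_error(synthetic_index_spec("X", I0 = 1, sigma = -1),
               class = "oliveASLT_validation_error")
  expect_error(synthetic_index_spec("X", I0 = 5, plateau = 4),
               class = "oliveASLT_validation_error")
  expect_error(synthetic_index_spec("X", I0 = 1, lag_days = -3),
               class = "oliveASLT_validation_error")
  expect_error(synthetic_study_config(temperatures = 25),
               class = "oliveASLT_validation_error")
  expect_error(synthetic_study_config(sampling_days = c(5, 10)),
               class = "oliveASLT_validation_error")
  err <- tryCatch(synthetic_study_config(temperatures = 25,
                                         sampling_days = c(5, 1)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "temperatures")
  expect_match(err, "sorted")
})

test_that("the default study emulates the accelerated EVOO design", {
  cfg <- default_study_config()
  expect_equal(cfg$temperatures, c(25, 40, 50, 60))
  expect_length(cfg$sampling_days, 15)
  expect_equal(range(cfg$sampling_days), c(0, 300))
  expect_equal(cfg$replicates_per_time, 2L)
  specs <- setNames(cfg$indices,
                    vapply(cfg$indices, `[[`, "", "index_id"))
  expect_equal(specs$K270$I0, 0.15)
  expect_equal(specs$K270$Ea, 58.39e3)
  expect_false(specs$PV$responsive)
  expect_false(specs$TOCOPHEROLS$responsive)
  expect_equal(specs$PPP$plateau, 26)
})

test_that("identical configuration and seed reproduce bit-identical output", {
  a <- generate_series(default_study_config(seed = 11))
  b <- generate_series(default_study_config(seed = 11))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$manifest, b$manifest)
  c <- generate_series(default_study_config(seed = 12))
  expect_false(identical(a$measurements$value, c$measurements$value))
})

test_that("noise-free generation lies exactly on the generating line", {
  spec <- synthetic_index_spec("K270", I0 = 0.15, Ea = 58.39e3,
                               k_ref = 8.1e-4, sigma = 0)
  cfg <- synthetic_study_config(indices = list(spec), seed = 5)
  sim <- generate_series(cfg)
  ms <- sim$measurements
  for (tc in cfg$temperatures) {
    sub <- ms[ms$temperature_C == tc, ]
    k_T <- 8.1e-4 * exp(-58.39e3 / 8.31 * (1 / (tc + 273.15) - 1 / 318.15))
    expect_equal(sub$value, 0.15 + k_T * sub$time_days, tolerance = 1e-12)
  }
})

test_that("noise-free generation plus the full pipeline returns the generating parameters", {
  spec <- synthetic_index_spec("K270", I0 = 0.15, Ea = 58.39e3,
                               k_ref = 8.1e-4, sigma = 0,
                               unit = "absorbance")
  sim <- generate_series(synthetic_study_config(indices = list(spec),
                                                seed = 5))
  fits <- fit_rate_constants(sim$measurements)
  expect_equal(fits$r2, rep(1, 4))
  m <- fit_arrhenius_twostep(rate_constant_set("K270", fits$temperature_C,
                                               fits$k))
  expect_equal(m$Ea, 58.39e3, tolerance = 1e-9)
  expect_equal(m$k_ref, 8.1e-4, tolerance = 1e-12)
})

test_that("lag and plateau shape the noiseless trajectory as specified", {
  spec <- synthetic_index_spec("PPP", I0 = 1, Ea = 0, k_ref = 0.5,
                               plateau = 11, lag_days = 10, sigma = 0,
                               unit = "percent")
  cfg <- synthetic_study_config(temperatures = c(25, 60),
                                sampling_days = c(0, 5, 10, 20, 30, 40, 60),
                                replicates_per_time = 1L,
                                indices = list(spec), seed = 2)
  ms <- generate_series(cfg)$measurements
  sub <- ms[ms$temperature_C == 25, ]
  expect_equal(sub$value,
               pmin(1 + 0.5 * pmax(0, sub$time_days - 10), 11),
               tolerance = 1e-12)
  expect_equal(sub$value[1:3], c(1, 1, 1))       # within the lag
  expect_equal(max(sub$value), 11)               # capped at the plateau
})

test_that("plateau-truncated fitting recovers the generating rate within two standard errors", {
  set.seed(42)
  kref_60 <- 0.4
  spec <- synthetic_index_spec("PPP", I0 = 1, Ea = 0, k_ref = kref_60,
                               plateau = 26, sigma = 0.3, unit = "percent")
  cfg <- synthetic_study_config(
    temperatures = c(50, 60),
    sampling_days = c(0, 6, 12, 18, 24, 30, 36, 42, 48, 60, 90, 120, 180,
                      240, 300),
    indices = list(spec), seed = 42)
  ms <- generate_series(cfg)$measurements
  s60 <- split_series(ms[ms$temperature_C == 60, ])[[1]]
  f <- fit_zero_order(s60)
  expect_lt(f$truncated_at, nrow(s60))                 # plateau cut away
  expect_lt(abs(f$k - kref_60), 2 * f$se_k)            # unbiased slope
  expect_identical(f$truncated_at,
                   prefix_oracle(s60$time_days, s60$value, 4L))
})

test_that("empirical noise converges to the configured standard deviation", {
  spec <- synthetic_index_spec("FLAT", I0 = 0, sigma = 1, responsive = FALSE)
  cfg <- synthetic_study_config(temperatures = c(25, 40),
                                replicates_per_time = 340L,
                                indices = list(spec), seed = 31)
  ms <- generate_series(cfg)$measurements
  expect_gte(nrow(ms), 1e4)
  expect_lt(abs(sd(ms$value) - 1), 0.03)
})

test_that("multiplicative noise and zero-clipping options apply", {
  spec <- synthetic_index_spec("X", I0 = 10, sigma = 0.01, responsive = FALSE)
  cfg <- synthetic_study_config(temperatures = c(25, 40),
                                indices = list(spec), seed = 3,
                                noise = "multiplicative")
  ms <- generate_series(cfg)$measurements
  expect_lt(abs(sd(ms$value / 10) - 0.01) / 0.01, 0.5)
  spec2 <- synthetic_index_spec("Y", I0 = 0.01, sigma = 1, responsive = FALSE)
  cfg2 <- synthetic_study_config(temperatures = c(25, 40),
                                 indices = list(spec2), seed = 3,
                                 clip_zero = TRUE)
  expect_gte(min(generate_series(cfg2)$measurements$value), 0)
})

test_that("the manifest records every generating parameter", {
  cfg <- default_study_config(seed = 9)
  man <- generate_series(cfg)$manifest
  expect_equal(man$seed, 9L)
  expect_equal(man$temperatures, cfg$temperatures)
  expect_equal(man$sampling_days, cfg$sampling_days)
  expect_length(man$indices, length(cfg$indices))
  expect_equal(man$indices[[1]]$Ea, cfg$indices[[1]]$Ea)
})
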