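fs_paper <- 1 / 0.3

test_that("an artifact-free series passes through motion correction unchanged", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 2, seed = 31)
  x <- simulate_rest_series(cfg)$values
  out <- mara_correct(x, fs_paper)
  expect_identical(out$values, x)
  expect_equal(nrow(out$segments), 0)
})

test_that("an injected spike is detected and its energy removed", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 2, seed = 32)
  x <- simulate_rest_series(cfg)$values
  inj <- inject_motion_artifacts(x,
    artifact_spec(n_spikes = 1, spike_amplitude = 10 * sd(x)), seed = 6)
  out <- mara_correct(inj$values, fs_paper)
  f <- which(inj$mask)
  expect_true(any(out$segments$start <= f & out$segments$end >= f))
  expect_lt(abs(sd(out$values) - sd(x)) / sd(x), 0.20)
})

test_that("an injected baseline shift is reduced by at least 80%", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 2, seed = 33)
  x <- simulate_rest_series(cfg)$values
  shift_amp <- 10 * sd(x)
  f <- 600
  inj <- inject_motion_artifacts(x, artifact_spec(n_shifts = 1,
                                                  shift_amplitude = shift_amp),
                                 seed = 1, frames = list(shifts = f))
  out <- mara_correct(inj$values, fs_paper)
  step_before <- mean(inj$values[(f + 30):(f + 200)]) -
    mean(inj$values[(f - 200):(f - 30)])
  step_after <- mean(out$values[(f + 30):(f + 200)]) -
    mean(out$values[(f - 200):(f - 30)])
  raw_step <- mean(x[(f + 30):(f + 200)]) - mean(x[(f - 200):(f - 30)])
  expect_lt(abs(step_after - raw_step), 0.2 * abs(step_before - raw_step))
})

test_that("band-stop attenuates the physiological bands and preserves the task band", {
  n <- 1100
  t <- (0:(n - 1)) * 0.3
  for (f in c(0.1, 0.2, 1.0)) {
    x <- sin(2 * pi * f * t)
    y <- bandstop_filter(x, fs_paper)
    expect_lt(fitted_amplitude(y, f, fs_paper), 0.10)  # >= 20 dB
  }
  x <- sin(2 * pi * (1 / 60) * t)
  y <- bandstop_filter(x, fs_paper)
  expect_equal(fitted_amplitude(y, 1 / 60, fs_paper), 1, tolerance = 0.01)
})

test_that("band-stop passes DC and rejects bands beyond Nyquist", {
  x <- rep(4.2, 600)
  expect_equal(bandstop_filter(x, fs_paper), x, tolerance = 1e-6)
  expect_error(bandstop_filter(x, fs_paper,
                               filter_spec(stop_band_hz = c(0.08, 2))),
               "Nyquist")
})

test_that("detrending removes polynomial drifts and preserves sinusoids", {
  n <- 1100
  t <- (0:(n - 1)) * 0.3
  ramp <- 0.02 * t + 3
  expect_lt(max(abs(detrend_series(ramp))), 1e-9)
  s <- sin(2 * pi * 0.05 * t)
  y <- detrend_series(ramp + s)
  expect_equal(fitted_amplitude(y, 0.05, fs_paper, trim = 0), 1,
               tolerance = 0.01)
  expect_equal(as.numeric(detrend_series(rep(0, 50))), rep(0, 50))
  expect_lt(abs(mean(detrend_series(ramp + s))), 1e-9)
})

test_that("filtering and detrending are linear operators", {
  set.seed(77)
  x1 <- rnorm(800); x2 <- rnorm(800)
  lin <- function(x) detrend_series(bandstop_filter(x, fs_paper), 1)
  expect_equal(lin(x1 + x2), lin(x1) + lin(x2), tolerance = 1e-8)
  expect_equal(lin(3 * x1), 3 * lin(x1), tolerance = 1e-8)
})

test_that("the conditioning chain preserves the five-cycle activation structure", {
  d <- paper_design()
  reg <- task_regressor(d)
  cfg <- signal_sim_config(design = d, seed = 71)  # default amplitudes/noise
  s <- simulate_activation_series(cfg)
  out <- preprocess_series(s$values, fs_paper)
  # < 0.05 degradation versus the unfiltered noiseless correlation of 1.0
  expect_gt(cor(out$values, reg), 0.95)
  expect_named(out$report, c("mara", "filter", "detrend"))
})

test_that("stage parameters are validated", {
  expect_error(mara_spec(threshold_factor = 0))
  expect_error(filter_spec(stop_band_hz = c(0.5, 0.1)))
  expect_error(mara_correct(rnorm(5), fs_paper), "window")
})
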