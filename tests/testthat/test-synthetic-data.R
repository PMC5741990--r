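test_that("rest-series variance matches the sinusoid-plus-noise closed form", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 2, seed = 11)
  s <- simulate_rest_series(cfg)
  expected <- 2^2 + sum(c(1, 1, 1)^2 / 2)   # sigma^2 + sum(a_i^2)/2
  expect_equal(var(s$values), expected, tolerance = 0.10)
})

test_that("the three physiological frequencies dominate the rest spectrum", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 0.3, seed = 5)
  s <- simulate_rest_series(cfg)
  n <- length(s$values)
  fs <- 1 / 0.3
  spec <- Mod(fft(s$values - mean(s$values)))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) * fs / n
  top3 <- sort(freqs[order(spec, decreasing = TRUE)[1:3]])
  expect_equal(top3, c(0.1, 0.2, 1.0), tolerance = 0.02)
})

test_that("degenerate configurations reduce to pure noise or a single tone", {
  cfg <- signal_sim_config(design = paper_design(),
                           physio_amplitudes = c(0, 0, 0), noise_sd = 1,
                           seed = 3)
  s <- simulate_rest_series(cfg)
  expect_lt(abs(mean(s$values)), 3 / sqrt(1100))
  cfg2 <- signal_sim_config(design = paper_design(),
                            physio_amplitudes = c(0, 0, 1), noise_sd = 0,
                            random_phases = FALSE)
  s2 <- simulate_rest_series(cfg2)
  n <- length(s2$values); fs <- 1 / 0.3
  spec <- Mod(fft(s2$values))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) * fs / n
  expect_equal(freqs[which.max(spec)], 1.0, tolerance = 0.02)
})

test_that("empirical noise SD converges to the configured value", {
  d <- block_design(30, 5, 300, 300, 0.3)  # ~10^4 frames
  cfg <- signal_sim_config(design = d, physio_amplitudes = c(0, 0, 0),
                           noise_sd = 3, seed = 9)
  s <- simulate_rest_series(cfg)
  expect_equal(sd(s$values), 3, tolerance = 0.05)
})

test_that("the reference corpus has 100 balanced, reproducible data sets", {
  c1 <- generate_training_corpus(seed = 7)
  expect_length(c1$series, 100)
  expect_equal(as.vector(table(c1$labels)), c(50, 50))
  expect_true(all(c1$noise_sd >= 1 & c1$noise_sd <= 10))
  c2 <- generate_training_corpus(seed = 7)
  expect_identical(lapply(c1$series, `[[`, "values"),
                   lapply(c2$series, `[[`, "values"))
  c3 <- generate_training_corpus(seed = 8)
  expect_false(identical(c1$series[[1]]$values, c3$series[[1]]$values))
})

test_that("leaving the reference noise regime is flagged", {
  expect_warning(generate_training_corpus(n_per_class = 2,
                                          noise_range = c(0.1, 0.5)),
                 "reference")
})

test_that("artifact injection reports exactly the corrupted frames", {
  cfg <- signal_sim_config(design = paper_design(), noise_sd = 2, seed = 21)
  x <- simulate_rest_series(cfg)$values
  none <- inject_motion_artifacts(x, artifact_spec(), seed = 1)
  expect_identical(none$values, x)
  expect_false(any(none$mask))

  spiked <- inject_motion_artifacts(x,
    artifact_spec(n_spikes = 1, spike_amplitude = 10 * sd(x)), seed = 2)
  expect_equal(sum(spiked$mask), 1)
  f <- which(spiked$mask)
  expect_equal(abs(spiked$values[f] - x[f]), 10 * sd(x))
  expect_identical(spiked$values[-f], x[-f])

  a <- inject_motion_artifacts(x, artifact_spec(n_shifts = 5,
                                                shift_amplitude = 3), seed = 4)
  b <- inject_motion_artifacts(x, artifact_spec(n_shifts = 5,
                                                shift_amplitude = 3), seed = 4)
  expect_identical(a, b)
  expect_length(a$shift_frames, 5)
})
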