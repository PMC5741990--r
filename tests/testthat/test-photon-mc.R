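# Light-weight transport checks; the 10^6-photon physics validation lives in
# the acceptance suite.

test_that("photon tracing is reproducible and geometrically sane", {
  st <- homogeneous_stack()
  p1 <- cached_paths(st, 1e5, 101, "homog_small")
  p2 <- run_photon_mc(st, 1e5, seed = 101)
  expect_identical(p1$paths_cm, p2$paths_cm)
  expect_true(all(p1$exit_r_cm >= 2.5 & p1$exit_r_cm <= 3.5))
  expect_true(all(p1$times_ns > 0.1))  # 3 cm at c/n takes > 0.14 ns
  expect_equal(ncol(p1$paths_cm), 10)
  p3 <- run_photon_mc(st, 1e5, seed = 102)
  expect_false(identical(p1$paths_cm, p3$paths_cm))
})

test_that("raising absorption shortens the mean time-of-flight", {
  p <- cached_paths(homogeneous_stack(), 1e5, 101, "homog_small")
  m_lo <- mc_moments(p, rep(0.15, 10))
  m_hi <- mc_moments(p, rep(0.25, 10))
  expect_lt(m_hi$mean_tof_ps, m_lo$mean_tof_ps)
  # deep-layer (brain) absorption increase alone also shortens <t>
  mua <- rep(0.15, 10); mua[5:10] <- 0.17
  expect_lt(mc_moments(p, mua)$mean_tof_ps, m_lo$mean_tof_ps)
})

test_that("the homogeneous DTOF matches the diffusion closed form in shape", {
  p <- cached_paths(homogeneous_stack(), 3e5, 55, "homog_shape")
  h <- mc_dtof(p, bin_ps = 128)
  tb <- (seq_along(h$counts) - 0.5) * 128 / 1e3  # bin centres, ns
  # annulus-integrated oracle, matching the detector ring of the MC
  rho <- seq(2.5, 3.5, length.out = 21)
  th <- as.vector(vapply(rho, function(r)
    td_diffusion_reflectance(r, tb, 0.15, 10), numeric(length(tb))) %*%
      (2 * pi * rho))
  keep <- th > 0.05 * max(th)
  a <- h$counts[keep] / sum(h$counts[keep])
  b <- th[keep] / sum(th[keep])
  expect_gt(cor(a, b), 0.98)
  expect_lt(max(abs(a - b) / max(b)), 0.15)
})

test_that("simulated frame counts are Poisson-distributed", {
  tl <- build_timeline(short_design())   # 500 frames
  cfg <- dtof_sim_config(photons_per_frame = 2000, n_photons_mc = 5e4,
                         wavelengths_nm = 830,
                         stacks = head_model()["830"], seed = 12)
  rec <- simulate_dtof_recording(cfg, tl, rep(0, 500), rep(0, 500))
  totals <- rowSums(rec$counts[["830"]])
  # dispersion-index test: (n-1) s^2 / mean ~ chi-square(n-1) for Poisson
  n <- length(totals)
  stat <- (n - 1) * var(totals) / mean(totals)
  expect_gt(stat, qchisq(0.005, n - 1))
  expect_lt(stat, qchisq(0.995, n - 1))
  # null recording: frame-to-frame <t> scatter is shot-noise level, no drift
  ms <- moments_from_recording(rec)
  dm <- delta_mean_tof(ms$mean_tof_ps, baseline_frames = 1:100)
  expect_lt(abs(mean(dm[401:500])), 4 * sd(dm) / 10)
})

test_that("an oxyhemoglobin step in the brain layers lowers <t> at 830 nm", {
  tl <- build_timeline(tiny_design())
  dHbO <- c(rep(0, 10), rep(8, 10), rep(0, 10))
  cfg <- dtof_sim_config(photons_per_frame = 5e5, n_photons_mc = 1e5,
                         wavelengths_nm = 830,
                         stacks = head_model()["830"], seed = 13)
  rec <- simulate_dtof_recording(cfg, tl, dHbO, rep(0, 30))
  ms <- moments_from_recording(rec)
  dm <- delta_mean_tof(ms$mean_tof_ps, baseline_frames = 1:10)
  expect_lt(mean(dm[11:20]), 0)
  expect_lt(mean(dm[11:20]), mean(dm[21:30]) - 1e-6)
})

test_that("chromophore course must align with the timeline", {
  tl <- build_timeline(tiny_design())
  cfg <- dtof_sim_config(photons_per_frame = 1e3, n_photons_mc = 5e4,
                         wavelengths_nm = 830,
                         stacks = head_model()["830"], seed = 14)
  expect_error(simulate_dtof_recording(cfg, tl, rep(0, 29), rep(0, 29)),
               "length")
})
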