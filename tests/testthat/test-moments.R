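test_that("moment examples: single bin, symmetric triangle, direct sum", {
  m1 <- compute_moments(dtof(c(0, 1, 0)))
  expect_equal(m1$N, 1)
  expect_equal(m1$mean_tof_ps, 16)
  expect_equal(m1$var_ps2, 0)

  m2 <- compute_moments(dtof(c(1, 2, 1)))
  expect_equal(m2$mean_tof_ps, 16)

  m3 <- compute_moments(dtof(c(3, 5, 2)))
  expect_equal(m3$N, 10)
  expect_equal(m3$mean_tof_ps, 14.4)
  o <- oracle_moments(c(3, 5, 2), 16)
  expect_equal(m3$var_ps2, o$var_ps2)
})

test_that("moments equal the brute-force direct-sum oracle on 1000 random DTOFs", {
  set.seed(123)
  for (i in 1:1000) {
    nb <- sample(5:60, 1)
    counts <- rpois(nb, sample(c(0.5, 3, 20), 1))
    if (all(counts == 0)) counts[sample(nb, 1)] <- 1
    bw <- sample(c(8, 16, 32), 1)
    m <- compute_moments(dtof(counts, bin_width_ps = bw),
                         peak_fraction = 0, background_fraction = 0)
    o <- oracle_moments(counts, bw)
    expect_identical(m$N, o$N)
    expect_identical(m$mean_tof_ps, o$mean_tof_ps)
    expect_equal(m$var_ps2, max(o$var_ps2, 0))
  }
})

test_that("mean time-of-flight is count-scale invariant while N scales linearly", {
  set.seed(4)
  for (i in 1:20) {
    counts <- rpois(40, 5) + 1
    k <- sample(2:7, 1)
    m1 <- compute_moments(dtof(counts), peak_fraction = 0,
                          background_fraction = 0)
    m2 <- compute_moments(dtof(k * counts), peak_fraction = 0,
                          background_fraction = 0)
    expect_equal(m2$mean_tof_ps, m1$mean_tof_ps)
    expect_equal(m2$var_ps2, m1$var_ps2)
    expect_equal(m2$N, k * m1$N)
  }
})

test_that("adding counts later than <t> strictly increases <t>", {
  set.seed(9)
  for (i in 1:20) {
    counts <- c(rpois(30, 4) + 1, rep(0, 10))
    m <- compute_moments(dtof(counts), peak_fraction = 0,
                         background_fraction = 0)
    late_bin <- ceiling(m$mean_tof_ps / 16) + 1 + sample(0:8, 1)
    counts2 <- counts
    counts2[min(late_bin + 1, length(counts2))] <- counts2[min(late_bin + 1, length(counts2))] + 5
    m2 <- compute_moments(dtof(counts2), peak_fraction = 0,
                          background_fraction = 0)
    expect_gt(m2$mean_tof_ps, m$mean_tof_ps)
  }
})

test_that("degenerate DTOFs are rejected", {
  expect_error(compute_moments(dtof(c(0, 0, 0))), "undefined")
  expect_error(dtof(c(-1, 2)), "counts")
  expect_error(dtof(numeric(0)))
})

test_that("the fraction-of-peak window excludes a flat background tail", {
  # strong peak plus a 1-count noise floor far out: the window must stop
  # before the floor when the threshold exceeds the floor level
  counts <- c(rep(0, 20), 0, 5, 800, 400, 100, 30, rep(0, 30), rep(1, 5))
  m <- compute_moments(dtof(counts), peak_fraction = 0.01,
                       background_fraction = 0)
  expect_lte(m$window[2], 26 + 8)
})

test_that("delta mean time-of-flight is referenced to the baseline window", {
  x <- c(rep(5, 10), rep(8, 10))
  d <- delta_mean_tof(x, baseline_frames = 1:10)
  expect_equal(d, c(rep(0, 10), rep(3, 10)))
  expect_equal(delta_mean_tof(rep(2, 20), baseline_frames = 1:5), rep(0, 20))
  expect_error(delta_mean_tof(x, baseline_frames = 15:25), "baseline")
  tl <- build_timeline(paper_design())
  y <- seq_len(1100)
  expect_equal(delta_mean_tof(y, timeline = tl), y - mean(y[1:100]))
})
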