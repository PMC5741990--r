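# Shared fixtures: small designs, cached Monte Carlo path sets, and
# brute-force oracles used across test files.

paper_design <- function() block_design(30, 5, 30, 30, 0.3)

tiny_design <- function() block_design(10, 1, 10, 10, 1.0)

# ~500-frame design for shot-noise statistics at desk scale
short_design <- function() block_design(30, 2, 30, 30, 0.3)

homogeneous_stack <- function(mua = 0.15, musp = 10)
  optical_layer_stack(rep(mua, 10), rep(musp, 10))

# photon path sets are expensive; compute each (key, n, seed) once per run
.mc_cache <- new.env(parent = emptyenv())
cached_paths <- function(stack, n_photons, seed, key) {
  id <- paste(key, n_photons, seed, sep = "_")
  if (is.null(.mc_cache[[id]]))
    .mc_cache[[id]] <- run_photon_mc(stack, n_photons = n_photons, seed = seed)
  .mc_cache[[id]]
}

.model_cache <- new.env(parent = emptyenv())
cached_model <- function(seed = 1) {
  id <- paste0("model_", seed)
  if (is.null(.model_cache[[id]])) {
    corpus <- generate_training_corpus(seed = seed)
    .model_cache[[id]] <- train_activation_classifier(corpus)
  }
  .model_cache[[id]]
}

# brute-force DTOF moment oracle: plain loops over all bins, no windowing
oracle_moments <- function(counts, bin_ps, t0 = 0) {
  N <- 0; s1 <- 0; s2 <- 0
  for (i in seq_along(counts)) {
    t <- t0 + (i - 1) * bin_ps
    N <- N + counts[i]
    s1 <- s1 + t * counts[i]
    s2 <- s2 + t * t * counts[i]
  }
  m <- s1 / N
  list(N = N, mean_tof_ps = m, var_ps2 = s2 / N - m * m)
}

# brute-force CNR oracle built from raw frame masks
oracle_cnr <- function(values, indicator) {
  ti <- which(indicator == 1); ri <- which(indicator == 0)
  (mean(values[ti]) - mean(values[ri])) / sd(values[ri])
}

# amplitude of a sinusoid of known frequency in a series (central section,
# least squares on sin/cos pair), for filter attenuation measurements
fitted_amplitude <- function(x, f, fs, trim = 0.2) {
  n <- length(x)
  keep <- seq(floor(trim * n) + 1, ceiling((1 - trim) * n))
  t <- (keep - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  b <- coef(lm(x[keep] ~ X - 1))
  sqrt(sum(b^2))
}
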