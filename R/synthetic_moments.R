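#' Configuration for moment-level signal simulation
#'
#' Simulated series combine (optionally) a block activation response, three
#' physiological sinusoids and additive Gaussian noise, sampled at the frame
#' rate of the instrument. The default sinusoid frequencies are 0.1 Hz
#' (Mayer waves), 0.2 Hz (respiration) and 1 Hz (cardiac); all amplitudes
#' are in the same arbitrary units as `noise_sd`.
#'
#' @param design A `block_design`.
#' @param activation_amplitude Peak amplitude of the activation response
#'   (boxcar convolved with the HRF, unit peak) in signal units.
#' @param physio_amplitudes Amplitudes of the (Mayer, respiration, cardiac)
#'   sinusoids.
#' @param physio_freqs_hz Frequencies of the three sinusoids, Hz.
#' @param noise_sd Standard deviation of additive Gaussian noise. The
#'   reference training corpus draws this from \[1, 10\].
#' @param random_phases If `TRUE` (default) each sinusoid gets a random
#'   phase per draw; if `FALSE` all phases are zero.
#' @param seed Optional integer seed; a given seed reproduces the draw.
#' @return An object of class `signal_sim_config`.
#' @export
signal_sim_config <- function(design = block_design(),
                              activation_amplitude = 5,
                              physio_amplitudes = c(1, 1, 1),
                              physio_freqs_hz = c(0.1, 0.2, 1.0),
                              noise_sd = 1,
                              random_phases = TRUE,
                              seed = NULL) {
  stopifnot(inherits(design, "block_design"),
            length(physio_amplitudes) == 3, all(physio_amplitudes >= 0),
            length(physio_freqs_hz) == 3, all(physio_freqs_hz > 0),
            is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0)
  structure(list(design = design,
                 activation_amplitude = activation_amplitude,
                 physio_amplitudes = physio_amplitudes,
                 physio_freqs_hz = physio_freqs_hz,
                 noise_sd = noise_sd,
                 random_phases = isTRUE(random_phases),
                 seed = seed),
            class = "signal_sim_config")
}

#' @noRd
.simulate_series <- function(cfg, hrf, with_activation) {
  tl <- build_timeline(cfg$design)
  t <- tl$times
  reg <- if (with_activation && cfg$activation_amplitude != 0)
    task_regressor(cfg$design, hrf) else numeric(length(t))
  with_seed(cfg$seed, {
    ph <- if (cfg$random_phases) runif(3, 0, 2 * pi) else c(0, 0, 0)
    physio <- Reduce(`+`, lapply(1:3, function(i) {
      cfg$physio_amplitudes[i] * sin(2 * pi * cfg$physio_freqs_hz[i] * t + ph[i])
    }))
    noise <- if (cfg$noise_sd > 0) rnorm(length(t), 0, cfg$noise_sd)
             else numeric(length(t))
    amp <- if (with_activation) cfg$activation_amplitude else 0
    values <- amp * reg + physio + noise
    structure(list(times = t, values = values, timeline = tl,
                   regressor = reg, label = if (with_activation) "activation" else "rest",
                   noise_sd = cfg$noise_sd, seed = cfg$seed),
              class = "sim_series")
  })
}

#' Simulate a moment-level activation series
#'
#' Activation amplitude times the unit-peak boxcar-convolved-with-HRF model,
#' plus the three physiological sinusoids and Gaussian noise.
#'
#' @param cfg A `signal_sim_config`.
#' @param hrf An `hrf_model`.
#' @return A `sim_series` with fields `times`, `values`, `timeline`,
#'   `regressor`, `label`, `noise_sd`, `seed`.
#' @export
simulate_activation_series <- function(cfg, hrf = hrf_model()) {
  .simulate_series(cfg, hrf, with_activation = TRUE)
}

#' Simulate a moment-level rest series
#'
#' Physiological sinusoids plus Gaussian noise only (activation amplitude 0).
#'
#' @inheritParams simulate_activation_series
#' @return A `sim_series`.
#' @export
simulate_rest_series <- function(cfg, hrf = hrf_model()) {
  .simulate_series(cfg, hrf, with_activation = FALSE)
}

#' Generate the labelled simulated training corpus
#'
#' The reference corpus holds `n_per_class` activation and `n_per_class`
#' rest series (default 50 + 50 = 100 data sets) whose noise standard
#' deviation is drawn uniformly from `noise_range` per data set. Per-item
#' seeds are derived from `seed` and recorded, so a corpus is exactly
#' reproducible.
#'
#' @param n_per_class Number of data sets per class (>= 1).
#' @param noise_range Range the per-set noise SD is drawn from; values
#'   outside \[1, 10\] trigger a warning because they leave the reference
#'   regime.
#' @param design,hrf Paradigm and HRF used for every set.
#' @param activation_amplitude,physio_amplitudes Signal amplitudes shared by
#'   all sets.
#' @param seed Master seed.
#' @return An object of class `training_corpus`: list with `series` (list of
#'   `sim_series`), `labels` (factor), `noise_sd`, `seeds`, and a `manifest`
#'   describing the generation parameters.
#' @export
generate_training_corpus <- function(n_per_class = 50,
                                     noise_range = c(1, 10),
                                     design = block_design(),
                                     hrf = hrf_model(),
                                     activation_amplitude = 5,
                                     physio_amplitudes = c(1, 1, 1),
                                     seed = 1L) {
  stopifnot(n_per_class >= 1, length(noise_range) == 2,
            noise_range[1] <= noise_range[2], noise_range[1] >= 0)
  if (noise_range[1] < 1 || noise_range[2] > 10)
    warning("noise_range outside [1, 10]: not the reference corpus regime")
  n <- 2L * as.integer(n_per_class)
  labels <- factor(rep(c("activation", "rest"), each = n_per_class),
                   levels = c("activation", "rest"))
  noise_sd <- with_seed(seed, runif(n, noise_range[1], noise_range[2]))
  seeds <- vapply(seq_len(n), function(k) derive_seed(seed, k), numeric(1))
  series <- lapply(seq_len(n), function(k) {
    cfg <- signal_sim_config(design = design,
                             activation_amplitude = activation_amplitude,
                             physio_amplitudes = physio_amplitudes,
                             noise_sd = noise_sd[k], seed = seeds[k])
    if (labels[k] == "activation") simulate_activation_series(cfg, hrf)
    else simulate_rest_series(cfg, hrf)
  })
  manifest <- list(n_per_class = n_per_class, noise_range = noise_range,
                   activation_amplitude = activation_amplitude,
                   physio_amplitudes = physio_amplitudes,
                   design = unclass(design), seed = seed)
  structure(list(series = series, labels = labels, noise_sd = noise_sd,
                 seeds = seeds, manifest = manifest),
            class = "training_corpus")
}

#' @export
print.training_corpus <- function(x, ...) {
  cat(sprintf("Training corpus: %d data sets (%d activation, %d rest)\n",
              length(x$series), sum(x$labels == "activation"),
              sum(x$labels == "rest")))
  cat(sprintf("  noise SD in [%.2f, %.2f], master seed %s\n",
              min(x$noise_sd), max(x$noise_sd), format(x$manifest$seed)))
  invisible(x)
}

#' Motion-artifact specification
#'
#' @param n_spikes Number of single-frame spikes.
#' @param spike_amplitude Spike amplitude in signal units (a single frame is
#'   displaced by this amount).
#' @param n_shifts Number of persistent baseline shifts.
#' @param shift_amplitude Step height of each baseline shift.
#' @return An `artifact_spec`.
#' @export
artifact_spec <- function(n_spikes = 0, spike_amplitude = 0,
                          n_shifts = 0, shift_amplitude = 0) {
  stopifnot(n_spikes >= 0, n_shifts >= 0)
  structure(list(n_spikes = n_spikes, spike_amplitude = spike_amplitude,
                 n_shifts = n_shifts, shift_amplitude = shift_amplitude),
            class = "artifact_spec")
}

#' Inject motion artifacts into a series
#'
#' Adds single-frame spikes and/or persistent baseline shifts at random
#' frames (reproducible given `seed`) and returns the exact ground-truth
#' mask of modified frames, for testing motion-artifact correction.
#'
#' @param values Numeric series.
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @param frames Optional explicit frames (list with `spikes` and `shifts`
#'   integer vectors) overriding random placement.
#' @return List with `values` (corrupted series), `mask` (logical, frames
#'   whose value was modified), `spike_frames`, `shift_frames`.
#' @export
inject_motion_artifacts <- function(values, spec, seed = NULL, frames = NULL) {
  stopifnot(inherits(spec, "artifact_spec"), is.numeric(values))
  n <- length(values)
  out <- values
  mask <- rep(FALSE, n)
  pick <- with_seed(seed, {
    list(spikes = if (is.null(frames$spikes) && spec$n_spikes > 0)
                    sample(seq(2, n - 1), spec$n_spikes) else frames$spikes,
         shifts = if (is.null(frames$shifts) && spec$n_shifts > 0)
                    sample(seq(2, n - 1), spec$n_shifts) else frames$shifts,
         signs = sample(c(-1, 1), spec$n_spikes + spec$n_shifts, replace = TRUE))
  })
  s_idx <- 0
  for (f in pick$spikes) {
    s_idx <- s_idx + 1
    out[f] <- out[f] + pick$signs[s_idx] * spec$spike_amplitude
    mask[f] <- TRUE
  }
  for (f in pick$shifts) {
    s_idx <- s_idx + 1
    out[f:n] <- out[f:n] + pick$signs[s_idx] * spec$shift_amplitude
    mask[f:n] <- TRUE
  }
  list(values = out, mask = mask,
       spike_frames = sort(as.integer(pick$spikes %||% integer(0))),
       shift_frames = sort(as.integer(pick$shifts %||% integer(0))))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
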