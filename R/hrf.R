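#' Hemodynamic response function model
#'
#' The default is the canonical double-gamma shape: a positive gamma
#' response peaking about 5-6 s after stimulus onset minus a smaller,
#' delayed gamma undershoot (peak near 15-16 s), with a 1:6
#' response-to-undershoot amplitude ratio. All shape parameters are
#' configurable.
#'
#' @param family Currently only `"double_gamma"`.
#' @param peak_delay_s Shape of the response gamma (seconds; gamma shape
#'   parameter with unit scale, mode at `peak_delay_s - 1`).
#' @param undershoot_delay_s Shape of the undershoot gamma.
#' @param dispersion_s Scale of both gammas, seconds.
#' @param undershoot_ratio Undershoot amplitude relative to the response.
#' @param duration_s Kernel support; the kernel is zero for `t < 0` (causal)
#'   and truncated at `duration_s`.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(family = "double_gamma", peak_delay_s = 6,
                      undershoot_delay_s = 16, dispersion_s = 1,
                      undershoot_ratio = 1 / 6, duration_s = 32) {
  family <- match.arg(family, "double_gamma")
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0, dispersion_s > 0,
            undershoot_ratio >= 0, duration_s > 0)
  structure(list(family = family, peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 dispersion_s = dispersion_s,
                 undershoot_ratio = undershoot_ratio,
                 duration_s = duration_s),
            class = "hrf_model")
}

#' Sampled HRF kernel
#'
#' @param hrf An `hrf_model`.
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of kernel samples at `t = 0, dt, 2 dt, ...` up to
#'   `duration_s`. The kernel integrates to a finite positive value.
#' @export
hrf_kernel <- function(hrf, dt) {
  stopifnot(inherits(hrf, "hrf_model"), dt > 0)
  t <- seq(0, hrf$duration_s, by = dt)
  k <- dgamma(t, shape = hrf$peak_delay_s / hrf$dispersion_s,
              scale = hrf$dispersion_s) -
    hrf$undershoot_ratio *
      dgamma(t, shape = hrf$undershoot_delay_s / hrf$dispersion_s,
             scale = hrf$dispersion_s)
  if (sum(k) * dt <= 0) stop("HRF kernel does not integrate to a positive value")
  k
}

#' Theoretical activation model for a block design
#'
#' Convolves the task boxcar with the hemodynamic response function and
#' rescales to unit peak. This is the "theoretical model" against which the
#' classifier's correlation feature is computed, and the shape used for the
#' simulated activation class.
#'
#' @param design A `block_design`.
#' @param hrf An `hrf_model`.
#' @return Numeric regressor with one entry per frame, peak value 1.
#' @export
task_regressor <- function(design, hrf = hrf_model()) {
  box <- boxcar_regressor(design)
  k <- hrf_kernel(hrf, design$frame_interval_s)
  n <- length(box)
  y <- convolve(c(box, rep(0, length(k))), rev(k), type = "open")
  y <- y[seq_len(n)]
  pk <- max(abs(y))
  if (pk == 0) stop("degenerate regressor: zero response")
  y / pk
}
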