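#' DTOF histogram object
#'
#' One distribution of time-of-flight of photons: a histogram of photon
#' arrival times for one channel, wavelength and frame.
#'
#' @param counts Non-negative, finite bin counts.
#' @param bin_width_ps Bin width, ps.
#' @param t0_offset_ps Arrival time of the first bin, ps.
#' @return A `dtof` object.
#' @export
dtof <- function(counts, bin_width_ps = 16, t0_offset_ps = 0) {
  stopifnot(is.numeric(counts), length(counts) >= 1, all(is.finite(counts)),
            all(counts >= 0), bin_width_ps > 0)
  structure(list(counts = as.numeric(counts), bin_width_ps = bin_width_ps,
                 t0_offset_ps = t0_offset_ps),
            class = "dtof")
}

#' Statistical moments of a DTOF
#'
#' Computes the photon count N, the mean time-of-flight `<t>` and the
#' variance V of a DTOF over an integration window. The window is resolved
#' with a fraction-of-peak rule after constant-background subtraction:
#' the background is estimated as the mean of the leading
#' `background_fraction` of bins, subtracted and floored at zero, and the
#' window runs from the first to the last bin whose corrected count reaches
#' `peak_fraction` of the corrected peak. Bin `i` is located at
#' `t0_offset_ps + (i - 1) * bin_width_ps`.
#'
#' @param d A [dtof()].
#' @param peak_fraction Fraction-of-peak integration threshold (default 1%).
#' @param background_fraction Leading fraction of bins eligible for the
#'   constant-background estimate; only bins before the DTOF onset (first
#'   bin reaching `peak_fraction` of the raw peak) are used, so the
#'   background never includes the pulse itself. 0 disables background
#'   subtraction.
#' @return A `moment_frame`: list with `N`, `mean_tof_ps`, `var_ps2`,
#'   `window` (first and last bin index used) and `background`.
#' @examples
#' compute_moments(dtof(c(3, 5, 2)))  # <t> = 14.4 ps
#' @export
compute_moments <- function(d, peak_fraction = 0.01,
                            background_fraction = 0.1) {
  stopifnot(inherits(d, "dtof"), peak_fraction >= 0, peak_fraction < 1,
            background_fraction >= 0, background_fraction < 1)
  cts <- d$counts
  nb <- length(cts)
  bg <- 0
  if (background_fraction > 0 && nb >= 10) {
    onset <- which(cts >= peak_fraction * max(cts))[1]
    lead <- seq_len(min(floor(background_fraction * nb), max(onset - 2L, 0L)))
    if (length(lead)) {
      bg <- mean(cts[lead])
      cts <- pmax(cts - bg, 0)
    }
  }
  pk <- max(cts)
  if (pk <= 0) stop("undefined moments: DTOF is empty after background correction")
  inwin <- which(cts >= peak_fraction * pk)
  i1 <- inwin[1]; i2 <- inwin[length(inwin)]
  w <- i1:i2
  tt <- d$t0_offset_ps + (w - 1) * d$bin_width_ps
  N <- sum(cts[w])
  if (N <= 0) stop("undefined moments: empty integration window")
  m <- sum(tt * cts[w]) / N
  v <- sum(tt^2 * cts[w]) / N - m^2
  structure(list(N = N, mean_tof_ps = m, var_ps2 = max(v, 0),
                 window = c(i1, i2), background = bg),
            class = "moment_frame")
}

#' Moment time series of a DTOF recording
#'
#' Applies [compute_moments()] to every frame and wavelength of a
#' [simulate_dtof_recording()] output (or a recording read from file).
#'
#' @param rec A `dtof_recording`.
#' @param ... Passed to [compute_moments()].
#' @return A `moment_series` data frame with columns `time_s`, `channel`,
#'   `wavelength_nm`, `N`, `mean_tof_ps`, `var_ps2`, and attributes
#'   `frame_interval_s` and `timeline`.
#' @export
moments_from_recording <- function(rec, ...) {
  stopifnot(inherits(rec, "dtof_recording"))
  out <- do.call(rbind, lapply(as.character(rec$wavelengths_nm), function(w) {
    M <- rec$counts[[w]]
    res <- t(vapply(seq_len(nrow(M)), function(f) {
      mf <- compute_moments(dtof(M[f, ], bin_width_ps = rec$bin_ps), ...)
      c(mf$N, mf$mean_tof_ps, mf$var_ps2)
    }, numeric(3)))
    data.frame(time_s = rec$frame_times_s, channel = rec$channel,
               wavelength_nm = as.numeric(w), N = res[, 1],
               mean_tof_ps = res[, 2], var_ps2 = res[, 3])
  }))
  rownames(out) <- NULL
  attr(out, "frame_interval_s") <- rec$timeline$design$frame_interval_s
  class(out) <- c("moment_series", "data.frame")
  out
}

#' Change in mean time-of-flight relative to a baseline window
#'
#' `Delta<t>(t) = <t>(t) - mean(<t> over the baseline window)`. The default
#' baseline is the lead-in rest period when a timeline is supplied.
#'
#' @param mean_tof_ps Numeric `<t>` series (one channel, one wavelength).
#' @param baseline_frames Integer indices of the baseline window; defaults
#'   to the lead-in rest frames of `timeline` if given, else the first 10%
#'   of frames.
#' @param timeline Optional `timeline` used to derive the default baseline.
#' @return Numeric `Delta<t>` series, ps.
#' @export
delta_mean_tof <- function(mean_tof_ps, baseline_frames = NULL,
                           timeline = NULL) {
  n <- length(mean_tof_ps)
  if (is.null(baseline_frames)) {
    if (!is.null(timeline)) {
      d <- timeline$design
      baseline_frames <- seq_len(round(d$lead_in_rest_s / d$frame_interval_s))
    } else {
      baseline_frames <- seq_len(max(1L, floor(0.1 * n)))
    }
  }
  if (length(baseline_frames) == 0 || any(baseline_frames < 1) ||
      any(baseline_frames > n))
    stop("baseline window outside the run")
  mean_tof_ps - mean(mean_tof_ps[baseline_frames])
}
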