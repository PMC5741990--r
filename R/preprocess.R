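#' Band-stop filter specification
#'
#' Butterworth band-stop applied forward-backward (zero-phase) so block
#' timing is not shifted. The default stop band 0.08-1.5 Hz removes the
#' Mayer-wave, respiratory and cardiac bands while preserving the task
#' fundamental (1/60 Hz for 30 s blocks). Order 5 is the default: it is the
#' lowest order whose two-pass attenuation reaches 20 dB at 0.1 Hz with the
#' 0.08 Hz lower edge.
#'
#' @param stop_band_hz Lower and upper stop-band edges, Hz.
#' @param order Butterworth prototype order per edge.
#' @param zero_phase Apply forward-backward (default) or single-pass.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(stop_band_hz = c(0.08, 1.5), order = 5,
                        zero_phase = TRUE) {
  stopifnot(length(stop_band_hz) == 2, stop_band_hz[1] > 0,
            stop_band_hz[1] < stop_band_hz[2], order >= 1)
  structure(list(stop_band_hz = stop_band_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Motion-artifact correction specification
#'
#' Parameters of the moving-standard-deviation artifact detector and
#' smoothing-spline corrector.
#'
#' @param moving_window_s Moving-SD window length, seconds.
#' @param threshold_factor Segments whose moving SD exceeds
#'   `threshold_factor` times the run-median moving SD are marked.
#' @param smoothing_parameter Smoothing-spline stiffness (`spar` of
#'   [stats::smooth.spline()]), in (0, 1\].
#' @return A `mara_spec`.
#' @export
mara_spec <- function(moving_window_s = 2, threshold_factor = 3,
                      smoothing_parameter = 0.6) {
  stopifnot(moving_window_s > 0, threshold_factor > 0,
            smoothing_parameter > 0, smoothing_parameter <= 1)
  structure(list(moving_window_s = moving_window_s,
                 threshold_factor = threshold_factor,
                 smoothing_parameter = smoothing_parameter),
            class = "mara_spec")
}

#' Centered moving standard deviation
#' @noRd
.moving_sd <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  i1 <- pmax(seq_len(n) - half, 1L)
  i2 <- pmin(seq_len(n) + half, n)
  m <- i2 - i1 + 1
  s <- cs[i2 + 1] - cs[i1]
  s2 <- cs2[i2 + 1] - cs2[i1]
  v <- pmax((s2 - s^2 / m) / pmax(m - 1, 1), 0)
  sqrt(v)
}

#' Motion-artifact reduction (moving-SD detection + spline correction)
#'
#' Frames whose moving standard deviation exceeds `threshold_factor` times
#' the run-median moving SD are grouped into artifact segments. Within each
#' segment a smoothing-spline trend is subtracted (flattening spikes and
#' steps), and the series is reassembled segment by segment with constant
#' offsets chosen so boundary means match, removing the discontinuities a
#' baseline shift would otherwise leave. An artifact-free series is
#' returned unchanged. Clean segments keep their shape exactly; those after
#' a corrected baseline shift may be re-leveled by a constant, which is
#' inconsequential for the detrended, baseline-referenced signals used
#' downstream.
#'
#' @param values Numeric series.
#' @param fs Sampling rate, Hz.
#' @param spec A [mara_spec()].
#' @return List with `values` (corrected series), `segments` (data frame of
#'   detected artifact segments: `start`, `end` frame indices) and
#'   `detected` (logical mask).
#' @export
mara_correct <- function(values, fs, spec = mara_spec()) {
  stopifnot(inherits(spec, "mara_spec"), is.numeric(values), fs > 0)
  n <- length(values)
  win <- max(3L, round(spec$moving_window_s * fs))
  if (n < 2 * win) stop("series shorter than twice the moving window")
  half <- max(1L, win %/% 2L)
  msd <- .moving_sd(values, half)
  bad <- msd > spec$threshold_factor * median(msd)
  if (!any(bad)) {
    return(list(values = values,
                segments = data.frame(start = integer(0), end = integer(0)),
                detected = bad))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg_df <- data.frame(start = starts[r$values], end = ends[r$values])
  # piecewise reassembly with boundary-mean matching
  k_match <- 3L
  rebuilt <- numeric(0)
  for (i in seq_along(r$lengths)) {
    idx <- starts[i]:ends[i]
    seg <- values[idx]
    if (r$values[i]) {
      if (length(idx) >= 4) {
        sp <- smooth.spline(idx, seg, spar = spec$smoothing_parameter)
        trend <- predict(sp, idx)$y
      } else {
        trend <- rep(mean(seg), length(seg))
      }
      seg <- seg - trend + mean(trend)
    }
    if (length(rebuilt) == 0) {
      rebuilt <- seg
    } else {
      k <- min(k_match, length(seg), length(rebuilt))
      off <- mean(tail(rebuilt, k)) - mean(head(seg, k))
      rebuilt <- c(rebuilt, seg + off)
    }
  }
  list(values = rebuilt, segments = seg_df, detected = bad)
}

#' Zero-phase Butterworth band-stop filter
#'
#' Applies the band-stop of a [filter_spec()] with reflective padding of
#' about two periods of the lower stop-band edge on both ends (trimmed
#' afterwards) to suppress filter edge transients.
#'
#' @param values Numeric series.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length.
#' @export
bandstop_filter <- function(values, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  nyq <- fs / 2
  if (spec$stop_band_hz[2] > nyq)
    stop(sprintf("stop band upper edge %g Hz exceeds the Nyquist frequency %g Hz",
                 spec$stop_band_hz[2], nyq))
  n <- length(values)
  bf <- signal::butter(spec$order, spec$stop_band_hz / nyq, type = "stop")
  # demean (band-stop passes DC exactly), reflect-pad, filter, trim, restore
  mu <- mean(values)
  v <- values - mu
  pad <- min(n - 1L, ceiling(2 * fs / spec$stop_band_hz[1]))
  x <- c(2 * v[1] - rev(v[seq(2, pad + 1)]),
         v,
         2 * v[n] - rev(v[seq(n - pad, n - 1)]))
  y <- if (spec$zero_phase) signal::filtfilt(bf, x)
       else as.numeric(signal::filter(bf, x))
  y[seq(pad + 1, pad + n)] + mu
}

#' Polynomial detrending
#'
#' Removes the least-squares polynomial trend (default linear, for slow
#' signal drifts). The output has zero mean.
#'
#' @param values Numeric series of length >= 2.
#' @param order Polynomial order, 1 (default) to 3.
#' @return Detrended series.
#' @export
detrend_series <- function(values, order = 1) {
  stopifnot(length(values) >= 2, order >= 1, order <= 3)
  i <- seq_along(values)
  X <- outer(i - mean(i), seq_len(order), `^`)
  residuals(lm(values ~ X))
}

#' Full signal-conditioning chain
#'
#' Fixed stage order: motion-artifact reduction, band-stop filtering,
#' detrending. Each stage's parameters are recorded in the returned report.
#'
#' @param values Numeric series (one channel, one wavelength).
#' @param fs Sampling rate, Hz.
#' @param mara A [mara_spec()], or `NULL` to skip.
#' @param filter A [filter_spec()], or `NULL` to skip.
#' @param detrend_order Polynomial order for detrending, or `NULL` to skip.
#' @return List with `values` and `report` (per-stage parameters and the
#'   motion-artifact segment table).
#' @export
preprocess_series <- function(values, fs, mara = mara_spec(),
                              filter = filter_spec(), detrend_order = 1) {
  report <- list()
  if (!is.null(mara)) {
    mc <- mara_correct(values, fs, mara)
    values <- mc$values
    report$mara <- list(spec = unclass(mara), segments = mc$segments)
  }
  if (!is.null(filter)) {
    values <- bandstop_filter(values, fs, filter)
    report$filter <- unclass(filter)
  }
  if (!is.null(detrend_order)) {
    values <- as.numeric(detrend_series(values, detrend_order))
    report$detrend <- list(order = detrend_order)
  }
  list(values = as.numeric(values), report = report)
}
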