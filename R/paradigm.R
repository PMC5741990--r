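#' Block-design motor-imagery paradigm
#'
#' Describes the question protocol: a lead-in rest period followed by
#' `n_cycles` alternating task/rest blocks. The default reproduces the
#' communication protocol used throughout this package: 30 s rest, then five
#' cycles of 30 s motor imagery and 30 s rest, sampled every 300 ms, for a
#' total of 330 s (5:30 min) per question.
#'
#' @param lead_in_rest_s Lead-in rest duration in seconds.
#' @param n_cycles Number of task/rest cycles (>= 1).
#' @param task_s Task (motor imagery) block duration in seconds.
#' @param cycle_rest_s Rest block duration within each cycle, seconds.
#' @param frame_interval_s Sampling interval of the instrument, seconds.
#' @return An object of class `block_design`.
#' @examples
#' d <- block_design()
#' total_duration(d)   # 330 s
#' @export
block_design <- function(lead_in_rest_s = 30, n_cycles = 5, task_s = 30,
                         cycle_rest_s = 30, frame_interval_s = 0.3) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("n_cycles must be an integer >= 1")
  n_cycles <- as.integer(round(n_cycles))
  for (nm in c("lead_in_rest_s", "task_s", "cycle_rest_s", "frame_interval_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a positive finite scalar", nm))
  }
  for (nm in c("lead_in_rest_s", "task_s", "cycle_rest_s")) {
    v <- get(nm)
    k <- v / frame_interval_s
    if (abs(k - round(k)) > 1e-9)
      stop(sprintf("%s (%g s) is not an integer multiple of frame_interval_s (%g s)",
                   nm, v, frame_interval_s))
  }
  structure(list(lead_in_rest_s = lead_in_rest_s, n_cycles = n_cycles,
                 task_s = task_s, cycle_rest_s = cycle_rest_s,
                 frame_interval_s = frame_interval_s),
            class = "block_design")
}

#' Total duration of a block design
#' @param design A `block_design`.
#' @return Total protocol duration in seconds.
#' @export
total_duration <- function(design) {
  stopifnot(inherits(design, "block_design"))
  design$lead_in_rest_s + design$n_cycles * (design$task_s + design$cycle_rest_s)
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("Block design: %g s lead-in rest + %d x (%g s task / %g s rest)\n",
              x$lead_in_rest_s, x$n_cycles, x$task_s, x$cycle_rest_s))
  cat(sprintf("  frame interval %g s, total %g s (%d frames)\n",
              x$frame_interval_s, total_duration(x),
              as.integer(round(total_duration(x) / x$frame_interval_s))))
  invisible(x)
}

#' Frame-level timeline of a block design
#'
#' Expands a design into per-frame timestamps and a binary task indicator.
#' Block boundaries are half-open `[start, end)`, so each frame belongs to
#' exactly one block and no frame is double-counted.
#'
#' @param design A `block_design`.
#' @return An object of class `timeline` with fields `times` (seconds,
#'   starting at 0), `task_indicator` (0/1 integer vector) and `design`.
#' @examples
#' tl <- build_timeline(block_design())
#' length(tl$times)          # 1100 frames
#' sum(tl$task_indicator)    # 500 task frames
#' @export
build_timeline <- function(design) {
  stopifnot(inherits(design, "block_design"))
  dt <- design$frame_interval_s
  li <- as.integer(round(design$lead_in_rest_s / dt))
  ti <- as.integer(round(design$task_s / dt))
  ri <- as.integer(round(design$cycle_rest_s / dt))
  indicator <- c(rep(0L, li), rep(c(rep(1L, ti), rep(0L, ri)), design$n_cycles))
  times <- (seq_along(indicator) - 1) * dt
  structure(list(times = times, task_indicator = indicator, design = design),
            class = "timeline")
}

#' Task boxcar regressor
#'
#' The task indicator of [build_timeline()] as a real-valued 0/1 vector,
#' i.e. the rectangular (boxcar) task regressor before hemodynamic
#' convolution.
#'
#' @param design A `block_design`.
#' @return Numeric vector with one entry per frame.
#' @export
boxcar_regressor <- function(design) {
  as.numeric(build_timeline(design)$task_indicator)
}
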