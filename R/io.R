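#' Write a moment series to tab-separated text
#'
#' Columnar dialect: one header line, tab separation, columns `time_s`,
#' `channel`, `wavelength_nm`, `N`, `mean_tof_ps`, `var_ps2`.
#'
#' @param ms A `moment_series` data frame (or any data frame with those
#'   columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_moment_series <- function(ms, path) {
  cols <- c("time_s", "channel", "wavelength_nm", "N", "mean_tof_ps", "var_ps2")
  missing_cols <- setdiff(cols, names(ms))
  if (length(missing_cols))
    stop("moment series lacks column(s): ", paste(missing_cols, collapse = ", "))
  write.table(ms[, cols], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a moment series from tab-separated text
#'
#' @param path File written by [write_moment_series()].
#' @return A `moment_series` data frame.
#' @export
read_moment_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cols <- c("time_s", "channel", "wavelength_nm", "N", "mean_tof_ps", "var_ps2")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("malformed moment file %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  num <- setdiff(cols, "channel")
  for (cc in num) if (!is.numeric(df[[cc]]))
    stop(sprintf("malformed moment file %s: column %s is not numeric", path, cc))
  if (any(df$N < 0)) stop("malformed moment file: negative photon count")
  class(df) <- c("moment_series", "data.frame")
  df
}

#' Write a DTOF recording as columnar histogram text
#'
#' One row per frame and wavelength: `frame_time_s`, `channel`,
#' `wavelength_nm`, then one column per bin (`b0001`, `b0002`, ...).
#'
#' @param rec A `dtof_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dtof_recording <- function(rec, path) {
  stopifnot(inherits(rec, "dtof_recording"))
  nb <- ncol(rec$counts[[1]])
  rows <- do.call(rbind, lapply(as.character(rec$wavelengths_nm), function(w) {
    M <- rec$counts[[w]]
    cbind(data.frame(frame_time_s = rec$frame_times_s, channel = rec$channel,
                     wavelength_nm = as.numeric(w)),
          as.data.frame(M))
  }))
  names(rows)[-(1:3)] <- sprintf("b%04d", seq_len(nb))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_ps=%g", rec$bin_ps), con)
  write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DTOF recording from columnar histogram text
#'
#' @param path File written by [write_dtof_recording()].
#' @param timeline Optional `timeline` to attach (needed by
#'   [process_recording()] for the baseline and frame rate).
#' @return A `dtof_recording` (without ground truth or photon paths).
#' @export
read_dtof_recording <- function(path, timeline = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1)
  if (!grepl("^# bin_ps=", hdr)) stop("malformed DTOF file: missing bin_ps header")
  bin_ps <- as.numeric(sub("^# bin_ps=", "", hdr))
  df <- read.delim(path, sep = "\t", skip = 1, stringsAsFactors = FALSE)
  need <- c("frame_time_s", "channel", "wavelength_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed DTOF file: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bins <- grep("^b\\d+$", names(df), value = TRUE)
  if (!length(bins)) stop("malformed DTOF file: no bin columns")
  counts_all <- as.matrix(df[, bins])
  if (any(counts_all < 0)) stop("malformed DTOF file: negative count")
  wls <- sort(unique(df$wavelength_nm))
  counts <- lapply(wls, function(w)
    unname(counts_all[df$wavelength_nm == w, , drop = FALSE]))
  names(counts) <- as.character(wls)
  structure(list(counts = counts, wavelengths_nm = wls, bin_ps = bin_ps,
                 frame_times_s = df$frame_time_s[df$wavelength_nm == wls[1]],
                 channel = df$channel[1], cfg = NULL, timeline = timeline,
                 truth = NULL, paths = NULL),
            class = "dtof_recording")
}

#' Write a DTOF recording in a SNIRF-convention JSON container
#'
#' Mirrors the group layout of the shared near-infrared spectroscopy format
#' (SNIRF) time-domain convention -- `formatVersion`, `nirs/data`,
#' `nirs/probe`, a measurement list entry per wavelength -- as a JSON text
#' document rather than an HDF5 binary.
#'
#' @param rec A `dtof_recording`.
#' @param path Output file (suggested extension: `.snirf.json`).
#' @return `path`, invisibly.
#' @export
write_snirf_json <- function(rec, path) {
  stopifnot(inherits(rec, "dtof_recording"))
  doc <- list(
    formatVersion = "1.1-json",
    nirs = list(
      metaDataTags = list(TimeUnit = "s", LengthUnit = "cm",
                          MomentOrders = "histogram"),
      probe = list(wavelengths = rec$wavelengths_nm,
                   timeDelayWidth_ps = rec$bin_ps),
      data = lapply(as.character(rec$wavelengths_nm), function(w) {
        list(wavelength_nm = as.numeric(w),
             sourceLabel = "S1", detectorLabel = rec$channel,
             time = rec$frame_times_s,
             dataTimeSeries = rec$counts[[w]])
      })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DTOF recording from the SNIRF-convention JSON container
#'
#' @param path File written by [write_snirf_json()].
#' @param timeline Optional `timeline` to attach.
#' @return A `dtof_recording`.
#' @export
read_snirf_json <- function(path, timeline = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$nirs$data)) stop("malformed SNIRF-JSON file: no nirs/data group")
  dat <- doc$nirs$data
  wls <- dat$wavelength_nm
  counts <- lapply(seq_along(wls), function(i) {
    M <- dat$dataTimeSeries[[i]]
    if (any(M < 0)) stop("malformed SNIRF-JSON file: negative count")
    M
  })
  names(counts) <- as.character(wls)
  structure(list(counts = counts, wavelengths_nm = wls,
                 bin_ps = doc$nirs$probe$timeDelayWidth_ps,
                 frame_times_s = dat$time[[1]],
                 channel = dat$detectorLabel[[1]], cfg = NULL,
                 timeline = timeline, truth = NULL, paths = NULL),
            class = "dtof_recording")
}

#' Read a run configuration from key/value text
#'
#' Lines of the form `key=value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop(sprintf("malformed config line %d: '%s'", which(bad)[1],
                 lines[bad][1]))
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- trimws(vapply(kv, `[`, character(1), 1))
  out
}

#' Write a run configuration as key/value text
#'
#' @param cfg Named list of scalar values.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(is.list(cfg), !is.null(names(cfg)))
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 15),
                            character(1))),
             path)
  invisible(path)
}

#' Block design from a run configuration
#' @param cfg Named list (e.g. from [read_run_config()]).
#' @return A `block_design` built from the paradigm keys, with defaults for
#'   any key not present.
#' @export
design_from_config <- function(cfg) {
  d <- formals(block_design)
  block_design(
    lead_in_rest_s = cfg$lead_in_rest_s %||% eval(d$lead_in_rest_s),
    n_cycles = cfg$n_cycles %||% eval(d$n_cycles),
    task_s = cfg$task_s %||% eval(d$task_s),
    cycle_rest_s = cfg$cycle_rest_s %||% eval(d$cycle_rest_s),
    frame_interval_s = cfg$frame_interval_s %||% eval(d$frame_interval_s))
}

#' Stable hash of a configuration object
#'
#' MD5 of the deparsed object, used to stamp every artifact with the
#' configuration that produced it.
#'
#' @param obj Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj, control = c("exact")), f)
  unname(tools::md5sum(f))
}

#' Append a stage record to a run log
#'
#' Line-oriented, append-only log: timestamp, stage name, `key=value`
#' parameters.
#'
#' @param path Log file (created if absent).
#' @param stage Stage name.
#' @param params Named list of scalar parameters.
#' @return `path`, invisibly.
#' @export
log_stage <- function(path, stage, params = list()) {
  kv <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) format(v, digits = 10),
                         character(1))), collapse = " ")
  else ""
  cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage, kv),
      file = path, append = TRUE)
  invisible(path)
}
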