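#' Hemoglobin time courses from a DTOF recording
#'
#' The full measurement chain for one channel: per-frame DTOF moments,
#' change in mean time-of-flight relative to the lead-in rest baseline,
#' signal conditioning (motion-artifact reduction, band-stop, detrend),
#' conversion to absorption changes with the intracerebral sensitivity
#' factor per wavelength, and inversion of the extinction matrix to
#' oxy-/deoxyhemoglobin.
#'
#' @param rec A `dtof_recording`.
#' @param sf_by_wavelength Named numeric vector of intracerebral sensitivity
#'   factors (ps per cm^-1), names = wavelengths; typically
#'   `intracerebral_sf()` of a [run_sensitivity_mc()] profile per
#'   wavelength.
#' @param ext Extinction table.
#' @param mara,filter,detrend_order Signal-conditioning settings (see
#'   [preprocess_series()]).
#' @return List with `dHbO_uM`, `dHbR_uM`, `delta_tof_ps` (per wavelength),
#'   `times_s` and the conditioning reports.
#' @export
process_recording <- function(rec, sf_by_wavelength,
                              ext = extinction_table(rec$wavelengths_nm),
                              mara = mara_spec(), filter = filter_spec(),
                              detrend_order = 1) {
  stopifnot(inherits(rec, "dtof_recording"))
  wl <- as.character(rec$wavelengths_nm)
  stopifnot(all(wl %in% names(sf_by_wavelength)))
  ms <- moments_from_recording(rec)
  fs <- 1 / rec$timeline$design$frame_interval_s
  dmua <- list(); dtof_ps <- list(); reports <- list()
  for (w in wl) {
    mt <- ms$mean_tof_ps[ms$wavelength_nm == as.numeric(w)]
    dtf <- delta_mean_tof(mt, timeline = rec$timeline)
    pp <- preprocess_series(dtf, fs, mara = mara, filter = filter,
                            detrend_order = detrend_order)
    dtof_ps[[w]] <- pp$values
    reports[[w]] <- pp$report
    dmua[[w]] <- delta_mua_from_dtof(pp$values, sf_by_wavelength[[w]])
  }
  hb <- hemoglobin_from_mua(dmua[[wl[1]]], dmua[[wl[2]]], ext)
  list(dHbO_uM = hb$dHbO_uM, dHbR_uM = hb$dHbR_uM,
       delta_tof_ps = dtof_ps, times_s = rec$frame_times_s,
       channel = rec$channel, reports = reports)
}

#' Decode one question from per-channel oxyhemoglobin series
#'
#' Classifies every channel and applies the yes/no rule (any activated
#' channel means "yes").
#'
#' @param channel_series Named list of per-channel oxyhemoglobin series.
#' @param model An `activation_model`.
#' @param question_id Question identifier.
#' @param preprocess Condition each series before feature extraction.
#' @return An `answer`.
#' @export
answer_question <- function(channel_series, model, question_id = "Q1",
                            preprocess = model$preprocess) {
  stopifnot(length(channel_series) >= 1)
  ids <- names(channel_series) %||% paste0("ch", seq_along(channel_series))
  decisions <- lapply(seq_along(channel_series), function(i)
    classify_channel(channel_series[[i]], model, channel = ids[i],
                     preprocess = preprocess))
  decide_answer(decisions, question_id)
}

#' Synthetic end-to-end decoding evaluation
#'
#' Simulates seeded synthetic question runs (four channels each; "yes" runs
#' carry the activation response on every channel, "no" runs are rest
#' only), decodes each with [answer_question()], and reports the fraction
#' of correct "yes" and "no" answers.
#'
#' @param model An `activation_model`.
#' @param n_runs Number of question runs (alternating yes/no truth).
#' @param noise_range Per-channel noise SD range (drawn uniformly).
#' @param n_channels Channels per run.
#' @param activation_amplitude Activation amplitude of "yes" runs.
#' @param design,hrf Paradigm and HRF.
#' @param seed Master seed.
#' @return List with `yes_accuracy`, `no_accuracy`, `n_yes`, `n_no` and the
#'   per-run table `runs`.
#' @export
evaluate_decoding <- function(model, n_runs = 100, noise_range = c(1, 5),
                              n_channels = 4, activation_amplitude = 5,
                              design = block_design(), hrf = hrf_model(),
                              seed = 1L) {
  truth <- rep(c("yes", "no"), length.out = n_runs)
  res <- vapply(seq_len(n_runs), function(i) {
    chans <- lapply(seq_len(n_channels), function(j) {
      s <- derive_seed(seed, i * 37 + j)
      nsd <- with_seed(s, runif(1, noise_range[1], noise_range[2]))
      cfg <- signal_sim_config(design = design,
                               activation_amplitude = activation_amplitude,
                               noise_sd = nsd, seed = derive_seed(s, 1))
      if (truth[i] == "yes") simulate_activation_series(cfg, hrf)$values
      else simulate_rest_series(cfg, hrf)$values
    })
    ans <- answer_question(chans, model, question_id = paste0("run", i))
    ans$response
  }, character(1))
  runs <- data.frame(run = seq_len(n_runs), truth = truth, decoded = res)
  list(yes_accuracy = mean(res[truth == "yes"] == "yes"),
       no_accuracy = mean(res[truth == "no"] == "no"),
       n_yes = sum(truth == "yes"), n_no = sum(truth == "no"),
       runs = runs)
}
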