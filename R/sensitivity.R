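#' Monte Carlo sensitivity factors of the mean time-of-flight
#'
#' For every layer k the sensitivity factor `SF_k = -d<t>/dmua_k` (ps per
#' cm^-1) is estimated at the baseline absorption of the stack by
#' reweighting the shared photon path set with `exp(-dmua * L_k)` at
#' `+/- delta_mua` and central differencing. Because both evaluations reuse
#' the same photon packets the estimator is strongly correlated and the
#' Monte Carlo noise of the difference is small; its standard error is
#' reported per layer via a per-photon influence-function linearization.
#' `SF_k` is positive: an absorption increase removes late (deep) photons
#' and shortens `<t>`.
#'
#' @param stack An `optical_layer_stack`, or a precomputed `photon_paths`
#'   object (in which case no new photons are traced).
#' @param n_photons Photons to launch (>= 1e5).
#' @param source_detector_cm,annulus_halfwidth_cm Detector geometry, cm.
#' @param delta_mua Central-difference step, 1/cm.
#' @param integration `NULL` for moments over the full photon times, or a
#'   [moment_integration()] rule. When converting measured `Delta<t>` series
#'   the sensitivity factors must be evaluated under the SAME integration
#'   rule applied to the measured DTOFs, otherwise the fraction-of-peak
#'   window truncates the depth-sensitive late tail on the measurement side
#'   only and the recovered absorption changes are biased low. With a rule
#'   given, photon times are binned and the baseline fraction-of-peak
#'   window (held fixed across the +/- perturbations) restricts the
#'   moments.
#' @param seed Integer seed (required unless `stack` is a `photon_paths`).
#' @return A `sensitivity_profile`: `sf_per_layer` and `se_per_layer`
#'   (ps per cm^-1), `sf_global` and `se_global` (all layers perturbed
#'   together), baseline `mean_tof_ps`, `n_detected`, `n_launched`,
#'   `delta_mua`, `stack`, `seed`.
#' @export
run_sensitivity_mc <- function(stack, n_photons = 1e6,
                               source_detector_cm = 3,
                               annulus_halfwidth_cm = 0.5,
                               delta_mua = 0.005, integration = NULL,
                               seed = NULL) {
  if (inherits(stack, "photon_paths")) {
    paths <- stack
    stack <- paths$stack
  } else {
    stopifnot(inherits(stack, "optical_layer_stack"))
    if (n_photons < 1e5) stop("n_photons must be at least 1e5")
    paths <- run_photon_mc(stack, n_photons = n_photons,
                           source_detector_cm = source_detector_cm,
                           annulus_halfwidth_cm = annulus_halfwidth_cm,
                           seed = seed)
  }
  nl <- stack$n_layers
  t_ps <- paths$times_ns * 1e3
  sel <- NULL
  if (!is.null(integration)) {
    stopifnot(inherits(integration, "moment_integration"))
    d0 <- mc_dtof(paths, stack$mua, bin_ps = integration$bin_ps,
                  window_ns = integration$window_ns)
    mf <- compute_moments(dtof(d0$counts, integration$bin_ps),
                          peak_fraction = integration$peak_fraction,
                          background_fraction = integration$background_fraction)
    bin <- pmin(floor(t_ps / integration$bin_ps) + 1,
                length(d0$counts))
    sel <- bin >= mf$window[1] & bin <= mf$window[2]
    t_ps <- (bin - 1) * integration$bin_ps   # binned times, measurement grid
  }

  diff_est <- function(layers) {
    dm <- numeric(nl); dm[layers] <- delta_mua
    wp <- .mc_weights(paths, stack$mua + dm)
    wm <- .mc_weights(paths, stack$mua - dm)
    if (!is.null(sel)) { wp <- wp * sel; wm <- wm * sel }
    mp <- sum(wp * t_ps) / sum(wp)
    mm <- sum(wm * t_ps) / sum(wm)
    # influence-function SE of the correlated difference of ratio estimators
    u <- wp * (t_ps - mp) / mean(wp) - wm * (t_ps - mm) / mean(wm)
    nph <- length(t_ps)
    c(sf = -(mp - mm) / (2 * delta_mua),
      se = sd(u) / sqrt(nph) / (2 * delta_mua))
  }

  per_layer <- vapply(seq_len(nl), function(k) diff_est(k), numeric(2))
  glob <- diff_est(seq_len(nl))
  m0 <- mc_moments(paths)
  structure(list(sf_per_layer = unname(per_layer["sf", ]),
                 se_per_layer = unname(per_layer["se", ]),
                 sf_global = unname(glob["sf"]),
                 se_global = unname(glob["se"]),
                 mean_tof_ps = m0$mean_tof_ps,
                 var_ps2 = m0$var_ps2,
                 n_detected = paths$n_detected,
                 n_launched = paths$n_launched,
                 delta_mua = delta_mua, integration = integration,
                 stack = stack, seed = paths$seed),
            class = "sensitivity_profile")
}

#' DTOF moment-integration rule
#'
#' Bundles the histogram binning and fraction-of-peak windowing used when
#' computing moments of measured DTOFs, so sensitivity factors can be
#' evaluated under the identical rule (see [run_sensitivity_mc()]).
#'
#' @param bin_ps Histogram bin width, ps.
#' @param window_ns Histogram window (laser repetition period), ns.
#' @param peak_fraction,background_fraction As in [compute_moments()].
#' @return A `moment_integration` object.
#' @export
moment_integration <- function(bin_ps = 16, window_ns = 12.5,
                               peak_fraction = 0.01,
                               background_fraction = 0.1) {
  stopifnot(bin_ps > 0, window_ns > 0)
  structure(list(bin_ps = bin_ps, window_ns = window_ns,
                 peak_fraction = peak_fraction,
                 background_fraction = background_fraction),
            class = "moment_integration")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("Sensitivity profile: %d layers, %d detected photons\n",
              x$stack$n_layers, x$n_detected))
  cat(sprintf("  baseline <t> = %.0f ps; SF per layer (ps/cm^-1):\n",
              x$mean_tof_ps))
  print(round(x$sf_per_layer, 1))
  invisible(x)
}

#' Intracerebral sensitivity factor
#'
#' Sum of the per-layer sensitivity factors over the intracerebral layers
#' (default layers 5 to 10 of the reference 10-layer stack, i.e. depths of
#' 0.8 cm and below; layer 1 is at the surface).
#'
#' @param profile A `sensitivity_profile` with at least `max(layers)`
#'   layers.
#' @param layers Layer indices to sum, 1-based from the surface.
#' @return Scalar intracerebral SF, ps per cm^-1.
#' @export
intracerebral_sf <- function(profile, layers = 5:10) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  if (length(profile$sf_per_layer) < max(layers))
    stop(sprintf("profile has %d layers; need at least %d",
                 length(profile$sf_per_layer), max(layers)))
  sum(profile$sf_per_layer[layers])
}

#' Absorption change from a mean time-of-flight change
#'
#' `dmua(t) = -Delta<t>(t) / SF`, with the sign convention that an
#' absorption increase shortens `<t>` (SF > 0).
#'
#' @param delta_tof_ps `Delta<t>` series, ps.
#' @param sf Intracerebral sensitivity factor, ps per cm^-1 (must be > 0).
#' @return `dmua` series, 1/cm.
#' @export
delta_mua_from_dtof <- function(delta_tof_ps, sf) {
  if (!is.numeric(sf) || length(sf) != 1 || !is.finite(sf) || sf <= 0)
    stop("sensitivity factor must be a positive scalar")
  -delta_tof_ps / sf
}

#' Hemoglobin concentration changes from two-wavelength absorption changes
#'
#' Inverts the extinction matrix per frame:
#' `[dHbO; dHbR] = E^-1 [dmua(760); dmua(830)]`.
#'
#' @param dmua_760,dmua_830 Absorption-change series at the two
#'   wavelengths, 1/cm (equal length).
#' @param ext Extinction table from [extinction_table()] (cm^-1 per uM).
#' @return List with `dHbO_uM` and `dHbR_uM` series (micromolar).
#' @export
hemoglobin_from_mua <- function(dmua_760, dmua_830,
                                ext = extinction_table()) {
  stopifnot(length(dmua_760) == length(dmua_830), nrow(ext) == 2,
            ncol(ext) == 2)
  if (abs(det(ext)) < .Machine$double.eps * 100)
    stop("singular extinction matrix")
  Einv <- solve(ext)
  hb <- Einv %*% rbind(dmua_760, dmua_830)
  list(dHbO_uM = as.numeric(hb[1, ]), dHbR_uM = as.numeric(hb[2, ]))
}
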