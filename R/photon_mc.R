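#' Trace photon paths through a layered head model
#'
#' Runs the layered-slab Monte Carlo: photons are launched normally into the
#' surface at the origin, scattered isotropically with the per-layer reduced
#' scattering coefficient (similarity relation), and recorded when they exit
#' the top surface within an annular detector at the source-detector
#' distance. Absorption is not applied during tracking; detected packets
#' carry their per-layer path lengths, so any absorption vector can be
#' applied afterwards by reweighting with `exp(-sum(mua * L))`. One photon
#' set therefore serves the DTOF simulator, the sensitivity-factor
#' estimator, and every absorption time course.
#'
#' @param stack An `optical_layer_stack`.
#' @param n_photons Number of photons to launch (>= 1e5 recommended for
#'   sensitivity estimates).
#' @param source_detector_cm Nominal source-detector distance, cm.
#' @param annulus_halfwidth_cm Detector annulus half-width, cm.
#' @param max_time_ns Paths longer than this flight time are abandoned.
#'   At baseline head absorption the photon weight at 8 ns is below 1e-10,
#'   so the default truncation is inconsequential for any moment.
#' @param seed Integer seed (mandatory; the tracker uses its own counter-
#'   based generator so results are independent of R's RNG state).
#' @return A `photon_paths` object: `paths_cm` (matrix, detected photons x
#'   layers, path length per layer including the semi-infinite extension of
#'   the deepest layer), `times_ns`, `exit_r_cm`, `n_launched`, `stack`,
#'   geometry and seed.
#' @export
run_photon_mc <- function(stack, n_photons = 1e6, source_detector_cm = 3,
                          annulus_halfwidth_cm = 0.5, max_time_ns = 8,
                          seed) {
  stopifnot(inherits(stack, "optical_layer_stack"), n_photons >= 1,
            source_detector_cm > 0,
            annulus_halfwidth_cm > 0, annulus_halfwidth_cm < source_detector_cm)
  if (missing(seed) || is.null(seed)) stop("run_photon_mc requires a seed")
  v <- .C_CM_PER_NS / stack$refractive_index
  res <- .mc_layered_paths(as.numeric(n_photons), stack$musp,
                           stack$thickness_cm,
                           source_detector_cm - annulus_halfwidth_cm,
                           source_detector_cm + annulus_halfwidth_cm,
                           max_time_ns * v, as.numeric(seed))
  if (nrow(res$paths_cm) == 0)
    stop("no photons detected: check geometry and photon budget")
  structure(list(paths_cm = res$paths_cm,
                 times_ns = rowSums(res$paths_cm) / v,
                 exit_r_cm = res$exit_r_cm,
                 n_launched = res$n_launched,
                 n_detected = nrow(res$paths_cm),
                 stack = stack,
                 source_detector_cm = source_detector_cm,
                 annulus_halfwidth_cm = annulus_halfwidth_cm,
                 max_time_ns = max_time_ns,
                 seed = seed),
            class = "photon_paths")
}

#' @export
print.photon_paths <- function(x, ...) {
  cat(sprintf(
    "Photon path set: %d detected / %g launched, rho = %g +/- %g cm, seed %s\n",
    x$n_detected, x$n_launched, x$source_detector_cm,
    x$annulus_halfwidth_cm, format(x$seed)))
  invisible(x)
}

#' Absorption weights for a photon path set
#' @noRd
.mc_weights <- function(paths, mua) {
  stopifnot(length(mua) == ncol(paths$paths_cm))
  as.vector(exp(-(paths$paths_cm %*% mua)))
}

#' Weighted DTOF moments of a photon path set
#'
#' Mean time-of-flight and variance of the detected-photon arrival times
#' under a given per-layer absorption vector (applied by reweighting).
#'
#' @param paths A `photon_paths` object.
#' @param mua Per-layer absorption vector, 1/cm; defaults to the baseline
#'   absorption of the stack the paths were traced in.
#' @return List with `mean_tof_ps`, `var_ps2`, `sum_weight`.
#' @export
mc_moments <- function(paths, mua = paths$stack$mua) {
  w <- .mc_weights(paths, mua)
  W <- sum(w)
  m <- sum(w * paths$times_ns) / W
  v <- sum(w * paths$times_ns^2) / W - m^2
  list(mean_tof_ps = m * 1e3, var_ps2 = v * 1e6, sum_weight = W)
}

#' Noiseless DTOF histogram of a photon path set
#'
#' @param paths A `photon_paths`.
#' @param mua Per-layer absorption vector, 1/cm.
#' @param bin_ps Histogram bin width, ps.
#' @param window_ns Histogram extent (laser repetition window), ns.
#' @return List with `counts` (expected weight per bin, unnormalized),
#'   `bin_ps`, `t0_offset_ps = 0`.
#' @export
mc_dtof <- function(paths, mua = paths$stack$mua, bin_ps = 16,
                    window_ns = 12.5) {
  w <- .mc_weights(paths, mua)
  nb <- floor(window_ns * 1e3 / bin_ps)
  bin <- pmin(floor(paths$times_ns * 1e3 / bin_ps) + 1, nb)
  counts <- numeric(nb)
  agg <- rowsum(w, bin)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  list(counts = counts, bin_ps = bin_ps, t0_offset_ps = 0)
}

#' Configuration for DTOF-level recording simulation
#'
#' Instrument constants default to the reference system: 3 cm
#' source-detector distance, 760/830 nm, 80 MHz pulse train (12.5 ns
#' window), 16 ps bins, one DTOF per channel every frame.
#'
#' @param stacks Named list of `optical_layer_stack` per wavelength, e.g.
#'   from [head_model()].
#' @param source_detector_cm Source-detector distance, cm.
#' @param wavelengths_nm Wavelength pair.
#' @param bin_ps DTOF bin width, ps.
#' @param rep_rate_mhz Laser repetition rate, MHz (sets the histogram
#'   window `1e3 / rep_rate_mhz` ns).
#' @param photons_per_frame Expected detected photon count per frame.
#' @param n_photons_mc Photons launched to build the path set per
#'   wavelength.
#' @param brain_layers Indices of the layers driven by the chromophore time
#'   course (1-based from the surface).
#' @param annulus_halfwidth_cm Detector annulus half-width, cm.
#' @param seed Integer seed.
#' @return A `dtof_sim_config`.
#' @export
dtof_sim_config <- function(stacks = head_model(),
                            source_detector_cm = 3,
                            wavelengths_nm = c(760, 830),
                            bin_ps = 16,
                            rep_rate_mhz = 80,
                            photons_per_frame = 1e6,
                            n_photons_mc = 1e6,
                            brain_layers = 5:10,
                            annulus_halfwidth_cm = 0.5,
                            seed = 1L) {
  stopifnot(all(as.character(wavelengths_nm) %in% names(stacks)),
            bin_ps > 0, rep_rate_mhz > 0, photons_per_frame > 0)
  structure(list(stacks = stacks, source_detector_cm = source_detector_cm,
                 wavelengths_nm = wavelengths_nm, bin_ps = bin_ps,
                 rep_rate_mhz = rep_rate_mhz,
                 photons_per_frame = photons_per_frame,
                 n_photons_mc = n_photons_mc, brain_layers = brain_layers,
                 annulus_halfwidth_cm = annulus_halfwidth_cm, seed = seed),
            class = "dtof_sim_config")
}

#' Simulate a DTOF-level recording
#'
#' Produces one DTOF histogram per frame and wavelength for a single
#' channel. Per frame, the brain-layer absorption is the stack baseline
#' plus the extinction-weighted hemoglobin changes; the frame's noiseless
#' DTOF is obtained by reweighting a shared photon path set, scaled so the
#' baseline frame expects `photons_per_frame` counts, and Poisson shot
#' noise is drawn per bin.
#'
#' @param cfg A [dtof_sim_config()].
#' @param timeline A `timeline` from [build_timeline()].
#' @param dHbO_uM,dHbR_uM Chromophore concentration-change time courses
#'   (micromolar), one value per frame, driving the brain-layer absorption.
#' @param ext Extinction table from [extinction_table()].
#' @param channel Channel identifier stored with the recording.
#' @param paths Optional named list of precomputed `photon_paths` per
#'   wavelength (reused when simulating several channels).
#' @return A `dtof_recording`: per wavelength an integer matrix of counts
#'   (frames x bins), plus frame times, configuration and the ground-truth
#'   chromophore course.
#' @export
simulate_dtof_recording <- function(cfg, timeline, dHbO_uM, dHbR_uM,
                                    ext = extinction_table(cfg$wavelengths_nm),
                                    channel = "ch1", paths = NULL) {
  stopifnot(inherits(cfg, "dtof_sim_config"), inherits(timeline, "timeline"))
  nf <- length(timeline$times)
  if (length(dHbO_uM) != nf || length(dHbR_uM) != nf)
    stop("chromophore time course length does not match the timeline")
  window_ns <- 1e3 / cfg$rep_rate_mhz
  nb <- floor(window_ns * 1e3 / cfg$bin_ps)
  wl <- as.character(cfg$wavelengths_nm)
  counts <- vector("list", length(wl)); names(counts) <- wl
  used_paths <- vector("list", length(wl)); names(used_paths) <- wl
  for (iw in seq_along(wl)) {
    w <- wl[iw]
    stack <- cfg$stacks[[w]]
    p <- paths[[w]] %||% run_photon_mc(
      stack, n_photons = cfg$n_photons_mc,
      source_detector_cm = cfg$source_detector_cm,
      annulus_halfwidth_cm = cfg$annulus_halfwidth_cm,
      seed = derive_seed(cfg$seed, iw))
    used_paths[[w]] <- p
    w0 <- .mc_weights(p, stack$mua)
    Lbrain <- rowSums(p$paths_cm[, cfg$brain_layers, drop = FALSE])
    bin <- pmin(floor(p$times_ns * 1e3 / cfg$bin_ps) + 1, nb)
    # extinction-weighted brain-layer absorption change per frame
    dmua <- ext[w, "HbO"] * dHbO_uM + ext[w, "HbR"] * dHbR_uM
    scale0 <- cfg$photons_per_frame / sum(w0)
    M <- matrix(0L, nrow = nf, ncol = nb)
    with_seed(derive_seed(cfg$seed, 100 + iw), {
      for (f in seq_len(nf)) {
        wf <- w0 * exp(-dmua[f] * Lbrain)
        expected <- numeric(nb)
        agg <- rowsum(wf, bin)
        expected[as.integer(rownames(agg))] <- agg[, 1]
        M[f, ] <- rpois(nb, expected * scale0)
      }
    })
    counts[[w]] <- M
  }
  structure(list(counts = counts, wavelengths_nm = cfg$wavelengths_nm,
                 bin_ps = cfg$bin_ps, frame_times_s = timeline$times,
                 channel = channel, cfg = cfg, timeline = timeline,
                 truth = list(dHbO_uM = dHbO_uM, dHbR_uM = dHbR_uM),
                 paths = used_paths),
            class = "dtof_recording")
}

#' @export
print.dtof_recording <- function(x, ...) {
  cat(sprintf("DTOF recording: channel %s, %d frames x %d bins at %g ps, %s nm\n",
              x$channel, nrow(x$counts[[1]]), ncol(x$counts[[1]]), x$bin_ps,
              paste(x$wavelengths_nm, collapse = "/")))
  invisible(x)
}
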