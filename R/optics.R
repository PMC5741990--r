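#' Layered optical head model
#'
#' A slab of `n_layers` horizontal layers. The reference head model has
#' 10 layers of 0.2 cm each (2 cm total); the deepest layer is treated as
#' semi-infinite below its upper boundary. Layer 1 is at the surface;
#' layers 5-10 (depths 0.8-2.0 cm) are the intracerebral compartment.
#'
#' @param mua Per-layer absorption coefficients, 1/cm.
#' @param musp Per-layer reduced scattering coefficients, 1/cm.
#' @param thickness_cm Per-layer thickness (scalar recycled or vector), cm.
#' @param refractive_index Medium refractive index (uniform; boundaries are
#'   treated as index-matched).
#' @return An `optical_layer_stack`.
#' @export
optical_layer_stack <- function(mua, musp, thickness_cm = 0.2,
                                refractive_index = 1.4) {
  n <- length(mua)
  stopifnot(n >= 1, length(musp) == n, all(mua > 0), all(musp > 0),
            refractive_index >= 1)
  th <- rep_len(thickness_cm, n)
  stopifnot(all(th > 0))
  structure(list(mua = as.numeric(mua), musp = as.numeric(musp),
                 thickness_cm = th, refractive_index = refractive_index,
                 n_layers = n),
            class = "optical_layer_stack")
}

#' Reference two-wavelength head model
#'
#' Ten 0.2 cm layers grouped as scalp (layers 1-2), skull (3-4) and brain
#' (5-10), with literature-typical baseline optical properties at 760 and
#' 830 nm (absorption about 0.1-0.2 /cm, reduced scattering about
#' 8-11 /cm). All values are declared here, not buried in the transport
#' code, and can be overridden per wavelength.
#'
#' @param wavelengths_nm Wavelength pair, nm.
#' @param mua,musp Optional named lists (names = wavelengths as character)
#'   of per-layer coefficient vectors overriding the defaults.
#' @return Named list of `optical_layer_stack`, one per wavelength.
#' @export
head_model <- function(wavelengths_nm = c(760, 830), mua = NULL, musp = NULL) {
  defaults_mua <- list(
    "760" = c(rep(0.17, 2), rep(0.12, 2), rep(0.19, 6)),
    "830" = c(rep(0.16, 2), rep(0.11, 2), rep(0.18, 6)))
  defaults_musp <- list(
    "760" = c(rep(8, 2), rep(10, 2), rep(11, 6)),
    "830" = c(rep(7.4, 2), rep(9.3, 2), rep(10.2, 6)))
  out <- lapply(as.character(wavelengths_nm), function(w) {
    ma <- (mua[[w]] %||% defaults_mua[[w]]) %||%
      stop("no default optical properties for wavelength ", w, " nm")
    ms <- (musp[[w]] %||% defaults_musp[[w]]) %||%
      stop("no default optical properties for wavelength ", w, " nm")
    optical_layer_stack(ma, ms)
  })
  names(out) <- as.character(wavelengths_nm)
  out
}

#' Hemoglobin extinction coefficient table
#'
#' Effective extinction coefficients of oxy- and deoxyhemoglobin at the two
#' instrument wavelengths, expressed as absorption per unit concentration
#' (cm^-1 per micromolar, natural-log convention, i.e. molar decadic
#' coefficients times ln 10). Values follow the widely used compiled
#' tabulation of hemoglobin spectra (source recorded in the attribute
#' `source`).
#'
#' @param wavelengths_nm Wavelength pair; 760 and 830 nm are tabulated.
#' @return A 2x2 numeric matrix, rows = wavelengths, columns = c("HbO",
#'   "HbR"), with attributes `units`, `source` and `condition_number`.
#' @export
extinction_table <- function(wavelengths_nm = c(760, 830)) {
  # molar decadic extinction, cm^-1 / M (compiled hemoglobin spectra)
  eps_molar <- rbind("760" = c(HbO = 586.00, HbR = 1548.52),
                     "830" = c(HbO = 974.00, HbR = 693.04))
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(eps_molar)))
    stop("extinction coefficients tabulated only at 760 and 830 nm")
  E <- eps_molar[key, , drop = FALSE] * log(10) * 1e-6  # cm^-1 per uM
  cn <- kappa(E, exact = TRUE)
  if (!is.finite(cn)) stop("singular extinction matrix")
  attr(E, "units") <- "cm^-1 per uM (ln convention)"
  attr(E, "source") <- "compiled-hemoglobin-spectra (Prahl tabulation)"
  attr(E, "condition_number") <- cn
  E
}
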