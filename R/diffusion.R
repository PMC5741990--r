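#' Time-domain diffuse reflectance of a semi-infinite medium
#'
#' Closed-form diffusion-theory reflectance from a homogeneous semi-infinite
#' medium, using the extrapolated-boundary dipole solution: an isotropic
#' source at depth `z0 = 1/musp` and a negative image source mirrored about
#' the extrapolated boundary at `-zb`, `zb = 2 A D`. Serves as the analytic
#' reference the layered Monte Carlo is validated against.
#'
#' @param rho_cm Source-detector distance(s), cm.
#' @param t_ns Photon arrival time(s), ns (vectorized over `t_ns`).
#' @param mua Absorption coefficient, 1/cm.
#' @param musp Reduced scattering coefficient, 1/cm.
#' @param refractive_index Medium refractive index (sets the speed of light
#'   in the medium).
#' @param A Boundary-mismatch factor; 1 for index-matched boundaries.
#' @return Reflectance (photons per cm^2 per ns, arbitrary source
#'   normalization), same length as `t_ns`.
#' @export
td_diffusion_reflectance <- function(rho_cm, t_ns, mua, musp,
                                     refractive_index = 1.4, A = 1) {
  stopifnot(mua >= 0, musp > 0, all(t_ns > 0))
  v <- .C_CM_PER_NS / refractive_index      # cm/ns
  D <- 1 / (3 * musp)                       # cm
  z0 <- 1 / musp
  zb <- 2 * A * D
  fourDvt <- 4 * D * v * t_ns
  pref <- 0.5 * (pi * fourDvt)^(-3 / 2) * t_ns^(-1) * v *
    exp(-mua * v * t_ns - rho_cm^2 / fourDvt)
  pref * (z0 * exp(-z0^2 / fourDvt) +
            (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / fourDvt))
}

#' Diffusion-theory DTOF moments over a detector annulus
#'
#' Numerically integrates the closed-form time-domain reflectance over an
#' annular detector (the same geometry the Monte Carlo uses) and returns
#' the DTOF moments and the absorption derivative of the mean
#' time-of-flight.
#'
#' @param mua,musp Optical coefficients, 1/cm.
#' @param rho_cm Nominal source-detector distance, cm.
#' @param annulus_halfwidth_cm Detector annulus half-width, cm.
#' @param refractive_index Medium refractive index.
#' @param t_max_ns,nt Time-integration grid extent and size.
#' @param delta_mua Central-difference step for the derivative, 1/cm.
#' @return List with `mean_tof_ps`, `var_ps2`, and `dmean_dmua_ps_cm`
#'   (= d<t>/d mua, ps per cm^-1; negative: absorption shortens <t>).
#' @export
td_diffusion_moments <- function(mua, musp, rho_cm = 3,
                                 annulus_halfwidth_cm = 0.5,
                                 refractive_index = 1.4,
                                 t_max_ns = 12, nt = 6000,
                                 delta_mua = 0.005) {
  t <- seq(t_max_ns / nt, t_max_ns, length.out = nt)
  rho <- seq(rho_cm - annulus_halfwidth_cm, rho_cm + annulus_halfwidth_cm,
             length.out = 41)
  w_rho <- 2 * pi * rho                     # annulus area weighting
  curve_at <- function(ma) {
    R <- vapply(rho, function(r)
      td_diffusion_reflectance(r, t, ma, musp, refractive_index), numeric(nt))
    as.vector(R %*% w_rho)
  }
  mom <- function(ma) {
    Rt <- curve_at(ma)
    m0 <- sum(Rt); m1 <- sum(Rt * t); m2 <- sum(Rt * t^2)
    mt <- m1 / m0
    c(mean = mt, var = m2 / m0 - mt^2)
  }
  m <- mom(mua)
  d <- (mom(mua + delta_mua)["mean"] - mom(mua - delta_mua)["mean"]) /
    (2 * delta_mua)
  list(mean_tof_ps = unname(m["mean"]) * 1e3,
       var_ps2 = unname(m["var"]) * 1e6,
       dmean_dmua_ps_cm = unname(d) * 1e3)
}
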