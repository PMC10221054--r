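#' Sun/view geometry
#'
#' Illumination and viewing configuration of a canopy scene.  The default
#' reproduces the simulation setup used throughout the package: solar
#' zenith 30 degrees, nadir view, relative azimuth 0, direct-beam-only
#' illumination.
#'
#' @param solar_zenith_deg Solar zenith angle in degrees, \[0, 90).
#' @param view_zenith_deg View zenith angle in degrees, \[0, 90).
#' @param relative_azimuth_deg Sun-view relative azimuth in degrees.
#' @param direct_fraction Fraction of incident irradiance arriving as the
#'   direct solar beam, in \[0, 1\]; the remainder enters as isotropic
#'   diffuse sky radiation.
#' @return An object of class `"geometry"`.
#' @export
#' @examples
#' geometry()                      # solar zenith 30, nadir view
geometry <- function(solar_zenith_deg = 30, view_zenith_deg = 0,
                     relative_azimuth_deg = 0, direct_fraction = 1) {
  if (solar_zenith_deg < 0 || solar_zenith_deg >= 90) {
    stop("solar_zenith_deg must lie in [0, 90)")
  }
  if (view_zenith_deg < 0 || view_zenith_deg >= 90) {
    stop("view_zenith_deg must lie in [0, 90)")
  }
  if (direct_fraction < 0 || direct_fraction > 1) {
    stop("direct_fraction must lie in [0, 1]")
  }
  structure(list(solar_zenith_deg = solar_zenith_deg,
                 view_zenith_deg = view_zenith_deg,
                 relative_azimuth_deg = relative_azimuth_deg,
                 direct_fraction = direct_fraction),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf(
    "Geometry: solar zenith %g deg, view zenith %g deg, rel. azimuth %g deg, direct fraction %g\n",
    x$solar_zenith_deg, x$view_zenith_deg, x$relative_azimuth_deg,
    x$direct_fraction))
  invisible(x)
}

#' Four-stream SAIL coefficients for one component
#'
#' Per-wavelength coefficients of the four-stream differential equations
#' for a homogeneous layer of one component: extinction of the direct beam
#' (`k`) and of the viewer-direction flux (`K`), diffuse attenuation `a`
#' and backscatter `sigma`, direct-to-diffuse scattering down (`s`) and up
#' (`s_prime`), and the viewer-direction source weights `u` (from upward
#' diffuse), `v` (from downward diffuse) and `w` (bidirectional, from the
#' direct beam).  All scattering coefficients are linear in the component's
#' reflectance and transmittance; `k` and `K` depend only on the
#' inclination distribution and the geometry.
#'
#' @param optics A [component_optics()] object.
#' @param lidf `"spherical"` or `"planophile"`.
#' @param geom A [geometry()] object.
#' @return List of per-wavelength numeric vectors `k`, `K`, `a`, `sigma`,
#'   `s`, `s_prime`, `u`, `v`, `w` plus the wavelength grid.
#' @export
sail_coefficients <- function(optics, lidf, geom) {
  stopifnot(inherits(optics, "component_optics"), inherits(geom, "geometry"))
  lidf <- match.arg(lidf, .lidf_names)
  tts <- geom$solar_zenith_deg * pi / 180
  tto <- geom$view_zenith_deg * pi / 180
  psi <- abs(geom$relative_azimuth_deg) %% 360
  psi <- min(psi, 360 - psi) * pi / 180

  ks <- g_projection(lidf, geom$solar_zenith_deg) / cos(tts)
  ko <- g_projection(lidf, geom$view_zenith_deg) / cos(tto)
  bf <- lidf_cos2_moment(lidf)

  sdb <- 0.5 * (ks + bf); sdf <- 0.5 * (ks - bf)
  ddb <- 0.5 * (1 + bf);  ddf <- 0.5 * (1 - bf)
  dob <- 0.5 * (ko + bf); dof <- 0.5 * (ko - bf)
  bi <- lidf_bidirectional(lidf, tts, tto, psi)

  rho <- optics$reflectance
  tau <- optics$transmittance
  nw <- length(rho)

  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  list(wavelength = optics$wavelength,
       k = rep(ks, nw), K = rep(ko, nw),
       a = 1 - sigf, sigma = sigb,
       s = sdf * rho + sdb * tau,        # forward-scattered beam -> E-
       s_prime = sdb * rho + sdf * tau,  # back-scattered beam -> E+
       u = dof * rho + dob * tau,        # E+ -> viewer
       v = dob * rho + dof * tau,        # E- -> viewer
       w = bi$sob * rho + bi$sof * tau)  # beam -> viewer
}
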