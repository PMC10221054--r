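# Leaf inclination distribution functions and projection geometry -------
#
# Inclination densities over leaf zenith angle theta_l in [0, pi/2]:
#   spherical   g(t) = sin t            (orientation-uniform)
#   planophile  g(t) = (2/pi)(1 + cos 2t)  (mostly horizontal)
# Both integrate to 1 over [0, pi/2].

.lidf_names <- c("spherical", "planophile")

lidf_density <- function(lidf) {
  lidf <- match.arg(lidf, .lidf_names)
  switch(lidf,
         spherical  = function(t) sin(t),
         planophile = function(t) (2 / pi) * (1 + cos(2 * t)))
}

# Mean projection of a facet of inclination theta_l onto the plane normal
# to a beam at zenith `theta` (azimuth-averaged).  Standard transition-
# angle form: cos(theta) cos(theta_l) when the facet never turns its edge
# to the beam, otherwise the two-branch expression.
.chi_projection <- function(theta, theta_l) {
  cs <- cos(theta_l) * cos(theta)
  ss <- sin(theta_l) * sin(theta)
  out <- cs
  tr <- ss > 1e-12 & abs(cs / pmax(ss, 1e-300)) < 1
  if (any(tr)) {
    bts <- acos(-cs[tr] / ss[tr])
    out[tr] <- (2 / pi) * ((bts - pi / 2) * cs[tr] + sin(bts) * ss[tr])
  }
  out
}

#' Mean projection (G-function) of a leaf inclination distribution
#'
#' The mean projection of unit one-sided component area onto the plane
#' perpendicular to a beam at the given zenith angle.  Divided by the
#' cosine of the zenith it gives the extinction coefficient per unit area
#' index.  For the spherical distribution the projection is exactly 1/2 in
#' every direction; the planophile value is obtained by quadrature over
#' the inclination density.
#'
#' @param lidf `"spherical"` or `"planophile"`.
#' @param zenith_deg Beam zenith angle in degrees, in \[0, 90).
#' @return Scalar projection in (0, 1\].
#' @export
#' @examples
#' g_projection("spherical", 37)   # exactly 0.5
#' g_projection("planophile", 0)   # 8 / (3 * pi)
g_projection <- function(lidf, zenith_deg) {
  lidf <- match.arg(lidf, .lidf_names)
  if (zenith_deg < 0 || zenith_deg >= 90) {
    stop("zenith angle must lie in [0, 90) degrees")
  }
  if (lidf == "spherical") return(0.5)
  theta <- zenith_deg * pi / 180
  dens <- lidf_density(lidf)
  f <- function(tl) dens(tl) * .chi_projection(theta, tl)
  # split at the kink where facets begin to self-shadow
  split <- pi / 2 - theta
  if (split <= 0 || split >= pi / 2) {
    stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
  } else {
    stats::integrate(f, 0, split, rel.tol = 1e-10)$value +
      stats::integrate(f, split, pi / 2, rel.tol = 1e-10)$value
  }
}

# Second moment of cos(theta_l): closed forms for the two densities.
lidf_cos2_moment <- function(lidf) {
  lidf <- match.arg(lidf, .lidf_names)
  switch(lidf, spherical = 1 / 3, planophile = 3 / 4)
}

# Azimuthally resolved single-scattering geometry (classical SAIL volume
# scattering): for one leaf inclination return the bidirectional
# sun-to-view scattering factors frho (reflectance side) and ftau
# (transmittance side), plus the two beam projections.  Angles in radians;
# psi is the relative azimuth.
.volscatt <- function(tts, tto, psi, ttl) {
  cts <- cos(tts); cto <- cos(tto)
  sts <- sin(tts); sto <- sin(tto)
  costl <- cos(ttl); sintl <- sin(ttl)
  cs <- costl * cts; co <- costl * cto
  ss <- sintl * sts; so <- sintl * sto

  cosbts <- ifelse(abs(ss) > 1e-6, -cs / ss, 5)
  cosbto <- ifelse(abs(so) > 1e-6, -co / so, 5)

  bts <- ifelse(abs(cosbts) < 1, acos(pmax(pmin(cosbts, 1), -1)), pi)
  ds  <- ifelse(abs(cosbts) < 1, ss, cs)
  chi_s <- (2 / pi) * ((bts - pi / 2) * cs + sin(bts) * ss)

  bto <- ifelse(abs(cosbto) < 1, acos(pmax(pmin(cosbto, 1), -1)),
                ifelse(tto < pi / 2, pi, 0))
  doo <- ifelse(abs(cosbto) < 1, so, ifelse(tto < pi / 2, co, -co))
  chi_o <- (2 / pi) * ((bto - pi / 2) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  bt1 <- ifelse(psi <= btran1, psi, btran1)
  bt2 <- ifelse(psi <= btran1, btran1, pmin(psi, btran2))
  bt3 <- ifelse(psi <= btran2, btran2, psi)

  t1 <- 2 * cs * co + ss * so * cos(psi)
  t2 <- ifelse(bt2 > 0,
               sin(bt2) * (2 * ds * doo + ss * so * cos(bt1) * cos(bt3)),
               0)
  denom <- 2 * pi^2
  frho <- pmax(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- pmax((-bt2 * t1 + t2) / denom, 0)
  list(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

# LIDF-averaged bidirectional scattering factors sob (reflectance weight)
# and sof (transmittance weight) for the viewer-direction source term.
# Midpoint quadrature over the inclination density.
lidf_bidirectional <- function(lidf, tts, tto, psi, n = 1201L) {
  dens <- lidf_density(lidf)
  tl <- (seq_len(n) - 0.5) * (pi / 2) / n
  w <- dens(tl) * (pi / 2) / n
  vs <- .volscatt(tts, tto, psi, tl)
  cts <- cos(tts); cto <- cos(tto)
  list(sob = sum(w * vs$frho) * pi / (cts * cto),
       sof = sum(w * vs$ftau) * pi / (cts * cto))
}
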