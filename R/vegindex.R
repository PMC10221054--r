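#' Vegetation-index configuration
#'
#' Band windows (closed intervals, nm) for the blue, red and NIR bands and
#' the SAVI soil-adjustment factor `L`.  Defaults are MODIS-like: blue
#' 459--479 nm, red 620--670 nm, NIR 841--876 nm, `L = 0.5`.
#'
#' @param blue_band,red_band,nir_band Numeric length-2 `(min, max)` nm.
#' @param savi_L Canopy background adjustment factor of SAVI.
#' @return An object of class `"vi_config"`.
#' @export
vi_config <- function(blue_band = c(459, 479), red_band = c(620, 670),
                      nir_band = c(841, 876), savi_L = 0.5) {
  bands <- list(blue_band = blue_band, red_band = red_band,
                nir_band = nir_band)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] >= b[2]) {
      stop(sprintf("%s must be an increasing (min, max) pair", nm))
    }
  }
  ord <- bands[order(vapply(bands, `[`, numeric(1), 1))]
  for (i in seq_len(length(ord) - 1L)) {
    if (ord[[i]][2] >= ord[[i + 1L]][1]) stop("band windows must be disjoint")
  }
  structure(list(blue_band = blue_band, red_band = red_band,
                 nir_band = nir_band, savi_L = savi_L),
            class = "vi_config")
}

#' Mean reflectance within a band window
#'
#' Flat (unweighted) mean of all samples with `band[1] <= wavelength <=
#' band[2]`.
#'
#' @param reflectance A [spectral_curve()] (or a `"flux_profile"`, whose
#'   nadir reflectance factor is used).
#' @param band Numeric `(min, max)` window in nm, inside the curve range.
#' @return Scalar band reflectance.
#' @export
band_average <- function(reflectance, band) {
  if (inherits(reflectance, "flux_profile")) {
    reflectance <- spectral_curve(reflectance$wavelength,
                                  reflectance$reflectance)
  }
  stopifnot(inherits(reflectance, "spectral_curve"))
  if (band[1] < min(reflectance$wavelength) - 1e-9 ||
      band[2] > max(reflectance$wavelength) + 1e-9) {
    stop(sprintf("band [%g, %g] nm lies outside the curve range", band[1], band[2]))
  }
  idx <- reflectance$wavelength >= band[1] - 1e-9 &
    reflectance$wavelength <= band[2] + 1e-9
  if (!any(idx)) {
    stop(sprintf("no grid samples inside band [%g, %g] nm", band[1], band[2]))
  }
  mean(reflectance$value[idx])
}

#' Band reflectances of a simulated canopy
#'
#' Convolves a nadir reflectance spectrum into the blue/red/NIR windows of
#' a [vi_config()].
#'
#' @param reflectance Spectral curve or `"flux_profile"`.
#' @param cfg A [vi_config()].
#' @return List with `r_blue`, `r_red`, `r_nir`.
#' @export
band_reflectance <- function(reflectance, cfg = vi_config()) {
  stopifnot(inherits(cfg, "vi_config"))
  list(r_blue = band_average(reflectance, cfg$blue_band),
       r_red = band_average(reflectance, cfg$red_band),
       r_nir = band_average(reflectance, cfg$nir_band))
}

#' Vegetation indices from band reflectances
#'
#' Computes, with `N`, `R`, `B` the NIR, red and blue band reflectances and
#' `L` the SAVI adjustment factor:
#' \deqn{NDVI = (N - R)/(N + R)}
#' \deqn{EVI = 2.5 (N - R)/(N + 6R - 7.5B + 1)}
#' \deqn{EVI2 = (N - R)/(N + 2.4R + 1)}
#' \deqn{SAVI = (1 + L)(N - R)/(N + R + L)}
#'
#' @param bands List with `r_blue`, `r_red`, `r_nir` (see
#'   [band_reflectance()]).
#' @param cfg A [vi_config()] (supplies `L`).
#' @return List of class `"vi_record"` with `ndvi`, `evi`, `evi2`, `savi`.
#' @export
#' @examples
#' compute_indices(list(r_blue = 0.03, r_red = 0.05, r_nir = 0.5))
compute_indices <- function(bands, cfg = vi_config()) {
  stopifnot(inherits(cfg, "vi_config"))
  N <- bands$r_nir; R <- bands$r_red; B <- bands$r_blue
  if (any(!is.finite(c(N, R, B)))) stop("band reflectances must be finite")
  L <- cfg$savi_L
  dens <- c(ndvi = N + R, evi = N + 6 * R - 7.5 * B + 1,
            evi2 = N + 2.4 * R + 1, savi = N + R + L)
  zero <- abs(dens) < 1e-12
  if (any(zero)) {
    stop(sprintf("zero denominator for index %s",
                 paste(names(dens)[zero], collapse = ", ")))
  }
  structure(list(ndvi = (N - R) / dens[["ndvi"]],
                 evi = 2.5 * (N - R) / dens[["evi"]],
                 evi2 = (N - R) / dens[["evi2"]],
                 savi = (1 + L) * (N - R) / dens[["savi"]]),
            class = "vi_record")
}

#' @export
print.vi_record <- function(x, ...) {
  cat(sprintf("NDVI %.4f | EVI %.4f | EVI2 %.4f | SAVI %.4f\n",
              x$ndvi, x$evi, x$evi2, x$savi))
  invisible(x)
}
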