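#' Canonical wavelength grid
#'
#' The default wavelength grid used throughout the package: 400--1000 nm in
#' 5 nm steps (121 samples).  It covers the photosynthetically active
#' radiation (PAR) window 400--700 nm and all vegetation-index bands.
#'
#' @return Numeric vector of wavelengths in nanometres.
#' @export
#' @examples
#' range(canonical_grid())
canonical_grid <- function() seq(400, 1000, by = 5)

#' Construct a spectral curve
#'
#' A spectral curve is a set of values sampled on a strictly increasing
#' wavelength grid (nm).  Reflectance, transmittance and absorptance curves
#' must lie in \[0, 1\]; set `unit_interval = TRUE` to enforce that.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of the same length; all values finite.
#' @param unit_interval Logical; require values in \[0, 1\].
#' @return An object of class `"spectral_curve"` with fields `wavelength`
#'   and `value`.
#' @export
#' @examples
#' sc <- spectral_curve(c(400, 500, 600), c(0.1, 0.2, 0.15))
spectral_curve <- function(wavelength, value, unit_interval = FALSE) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length")
  }
  if (length(wavelength) < 1L) stop("empty spectral curve")
  if (!all(is.finite(wavelength)) || !all(is.finite(value))) {
    stop("spectral curve contains non-finite entries")
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (unit_interval && (any(value < -1e-12) || any(value > 1 + 1e-12))) {
    stop("curve values must lie in [0, 1]")
  }
  structure(list(wavelength = wavelength, value = value),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("Spectral curve: %d samples, %g-%g nm, values in [%.4g, %.4g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' Construct component optical properties
#'
#' Bundles the reflectance and transmittance spectra of a canopy component
#' (green leaf, woody branch) or of the soil background on a shared
#' wavelength grid.  Branches and soil are opaque: they absorb and reflect
#' but do not transmit, so their transmittance is identically zero.
#'
#' @param kind One of `"leaf"`, `"branch"`, `"soil"`.
#' @param wavelength Strictly increasing wavelengths in nm.
#' @param reflectance Reflectance in \[0, 1\], same length as `wavelength`.
#' @param transmittance Transmittance in \[0, 1\]; may be omitted for
#'   `branch`/`soil` (filled with zeros).  `reflectance + transmittance`
#'   must not exceed 1 at any wavelength.
#' @param label Free-text label (e.g. a species name).
#' @return An object of class `"component_optics"`.
#' @export
#' @examples
#' co <- component_optics("leaf", c(400, 550, 700),
#'                        reflectance = c(0.05, 0.10, 0.06),
#'                        transmittance = c(0.02, 0.05, 0.03))
component_optics <- function(kind = c("leaf", "branch", "soil"),
                             wavelength, reflectance, transmittance = NULL,
                             label = "") {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  if (is.null(transmittance)) {
    if (kind == "leaf") stop("leaf optics require a transmittance spectrum")
    transmittance <- numeric(length(wavelength))
  }
  transmittance <- as.numeric(transmittance)
  spectral_curve(wavelength, reflectance, unit_interval = TRUE)
  spectral_curve(wavelength, transmittance, unit_interval = TRUE)
  if (length(transmittance) != length(wavelength)) {
    stop("transmittance length does not match the wavelength grid")
  }
  bad <- which(reflectance + transmittance > 1 + 1e-9)
  if (length(bad)) {
    stop(sprintf(
      "reflectance + transmittance > 1 at row %d (wavelength %g nm)",
      bad[1L], wavelength[bad[1L]]))
  }
  if (kind != "leaf" && any(transmittance > 1e-12)) {
    stop(sprintf("%s components are opaque: transmittance must be zero", kind))
  }
  structure(list(kind = kind, label = label, wavelength = wavelength,
                 reflectance = reflectance, transmittance = transmittance),
            class = "component_optics")
}

#' @export
print.component_optics <- function(x, ...) {
  cat(sprintf("Component optics [%s]%s: %d samples, %g-%g nm\n",
              x$kind, if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  mean reflectance %.3f, mean transmittance %.3f\n",
              mean(x$reflectance), mean(x$transmittance)))
  invisible(x)
}

#' Read component optics from CSV
#'
#' Expects a header with columns `wavelength_nm`, `reflectance` and
#' (optionally, for branch/soil) `transmittance`.  Rows are sorted by
#' wavelength; all `component_optics` invariants are enforced with
#' row-level error messages.
#'
#' @param path Path to a CSV file (UTF-8, '.' decimal separator).
#' @param kind Component kind, see [component_optics()].
#' @param label Label stored on the result; defaults to the file name.
#' @return A validated [component_optics()] object on the file's grid.
#' @export
read_optics_csv <- function(path, kind = c("leaf", "branch", "soil"),
                            label = basename(path)) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "reflectance")
  if (kind == "leaf") need <- c(need, "transmittance")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  if (anyDuplicated(df$wavelength_nm)) {
    stop(sprintf("%s: duplicated wavelength at row %d", path,
                 anyDuplicated(df$wavelength_nm)))
  }
  tau <- if ("transmittance" %in% names(df)) df$transmittance else NULL
  component_optics(kind, df$wavelength_nm, df$reflectance, tau, label = label)
}

#' Write component optics to CSV
#'
#' Inverse of [read_optics_csv()]: columns `wavelength_nm`, `reflectance`,
#' `transmittance`.
#'
#' @param optics A [component_optics()] object.
#' @param path Output file path.
#' @param digits Significant digits written (default 10, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_optics_csv <- function(optics, path, digits = 10) {
  stopifnot(inherits(optics, "component_optics"))
  df <- data.frame(wavelength_nm = optics$wavelength,
                   reflectance = signif(optics$reflectance, digits),
                   transmittance = signif(optics$transmittance, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample component optics onto a new wavelength grid
#'
#' Linear interpolation of reflectance and transmittance.  Extrapolation is
#' refused: the requested grid must lie within the source range.
#'
#' @param optics A [component_optics()] object.
#' @param grid Target wavelengths (nm), within the source range.
#' @return A [component_optics()] object on `grid`.
#' @export
resample_optics <- function(optics, grid) {
  stopifnot(inherits(optics, "component_optics"))
  grid <- as.numeric(grid)
  if (min(grid) < min(optics$wavelength) - 1e-9 ||
      max(grid) > max(optics$wavelength) + 1e-9) {
    stop(sprintf("requested grid [%g, %g] nm extends beyond source range [%g, %g] nm",
                 min(grid), max(grid),
                 min(optics$wavelength), max(optics$wavelength)))
  }
  rho <- stats::approx(optics$wavelength, optics$reflectance, xout = grid)$y
  tau <- stats::approx(optics$wavelength, optics$transmittance, xout = grid)$y
  component_optics(optics$kind, grid, rho, tau, label = optics$label)
}

# Interpolate an optional weighting curve onto sample wavelengths and
# normalise it to unit sum; NULL means uniform weights.
.par_weights <- function(wl, weighting) {
  if (is.null(weighting)) {
    w <- rep(1, length(wl))
  } else {
    stopifnot(inherits(weighting, "spectral_curve"))
    w <- stats::approx(weighting$wavelength, weighting$value, xout = wl,
                       rule = 2)$y
    if (any(w < 0)) stop("weighting must be non-negative")
    if (sum(w) <= 0) stop("weighting sums to zero over the PAR window")
  }
  w / sum(w)
}

#' Mean PAR absorptance of a component
#'
#' Weighted mean of `1 - reflectance - transmittance` over the
#' photosynthetically active window 400--700 nm.  The default weighting is
#' uniform; a solar irradiance spectrum may be supplied.
#'
#' @param optics A [component_optics()] object whose grid covers
#'   400--700 nm.
#' @param weighting Optional [spectral_curve()] of spectral weights.
#' @return Scalar absorptance in \[0, 1\].
#' @export
par_absorptance <- function(optics, weighting = NULL) {
  stopifnot(inherits(optics, "component_optics"))
  wl <- optics$wavelength
  if (min(wl) > 400 + 1e-9 || max(wl) < 700 - 1e-9) {
    stop("optics grid does not cover the PAR window 400-700 nm")
  }
  idx <- wl >= 400 - 1e-9 & wl <= 700 + 1e-9
  a <- 1 - optics$reflectance[idx] - optics$transmittance[idx]
  sum(a * .par_weights(wl[idx], weighting))
}
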