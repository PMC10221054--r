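#' Per-layer absorbed fraction spectrum
#'
#' Flux balance of one layer: at every wavelength the absorbed fraction is
#' the net flux entering through the layer top minus the net flux leaving
#' through its bottom, normalised by the incident top-of-canopy
#' irradiance, i.e. `([Es + E- - E+] at boundary i) - (same at boundary
#' i+1)` divided by the incident.
#'
#' @param profile A `"flux_profile"` from [solve_stack()] or
#'   [fd_oracle_solve()].
#' @param layer_index Layer number, 1 = top layer.
#' @return A [spectral_curve()] of absorbed fractions.
#' @export
layer_absorbed_fraction <- function(profile, layer_index) {
  stopifnot(inherits(profile, "flux_profile"))
  N <- length(profile$layer_area)
  if (layer_index < 1 || layer_index > N) {
    stop(sprintf("layer_index must lie in 1..%d", N))
  }
  net <- profile$Es + profile$E_minus - profile$E_plus
  absd <- net[, layer_index] - net[, layer_index + 1L]
  frac <- ifelse(profile$incident > 0, absd / profile$incident, 0)
  spectral_curve(profile$wavelength, frac)
}

#' Spectrally integrated FPAR from an absorption spectrum
#'
#' FPAR is the weighted mean of the absorbed fraction over the
#' photosynthetically active window 400--700 nm.  The default weighting is
#' uniform; an irradiance spectrum may be supplied.
#'
#' @param absorption A [spectral_curve()] whose grid covers 400--700 nm.
#' @param weighting Optional [spectral_curve()] of spectral weights.
#' @return Scalar FPAR.
#' @export
fpar_from_absorption <- function(absorption, weighting = NULL) {
  stopifnot(inherits(absorption, "spectral_curve"))
  wl <- absorption$wavelength
  if (min(wl) > 400 + 1e-9 || max(wl) < 700 - 1e-9) {
    stop("absorption grid does not cover the PAR window 400-700 nm")
  }
  idx <- wl >= 400 - 1e-9 & wl <= 700 + 1e-9
  sum(absorption$value[idx] * .par_weights(wl[idx], weighting))
}

#' Partition canopy FPAR into green and non-green components
#'
#' Sums per-layer FPAR over leaf layers (green FPAR, absorbed by
#' photosynthetic vegetation) and over branch layers (non-photosynthetic
#' FPAR).  Soil absorption is background, not canopy, and is excluded.
#'
#' @param profile A `"flux_profile"` computed from `stack`.
#' @param stack The [canopy_stack()] the profile was computed from.
#' @param weighting Optional PAR weighting, see [fpar_from_absorption()].
#' @return An object of class `"fpar_result"`: list with `fpar_total`,
#'   `fpar_pav` (green) and `fpar_npv` fractions.
#' @export
partition_canopy_fpar <- function(profile, stack, weighting = NULL) {
  stopifnot(inherits(profile, "flux_profile"),
            inherits(stack, "canopy_stack"))
  N <- length(stack$layers)
  if (length(profile$layer_area) != N ||
      !isTRUE(all.equal(profile$wavelength, stack$soil$wavelength))) {
    stop("flux profile does not match the canopy stack")
  }
  pav <- 0; npv <- 0
  for (i in seq_len(N)) {
    fi <- fpar_from_absorption(layer_absorbed_fraction(profile, i), weighting)
    if (stack$layers[[i]]$component$kind == "leaf") pav <- pav + fi
    else npv <- npv + fi
  }
  structure(list(fpar_total = pav + npv, fpar_pav = pav, fpar_npv = npv),
            class = "fpar_result")
}

#' @export
print.fpar_result <- function(x, ...) {
  cat(sprintf("FPAR: total %.4f | green (PAV) %.4f | non-green (NPV) %.4f\n",
              x$fpar_total, x$fpar_pav, x$fpar_npv))
  invisible(x)
}
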