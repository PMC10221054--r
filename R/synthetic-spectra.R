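# Synthetic component spectra -------------------------------------------
#
# Stand-ins for laboratory leaf/branch spectra: a smooth scattering
# baseline with two Gaussian absorption wells in the blue (~450 nm) and red
# (~670 nm), a logistic red edge rising to a near-infrared scattering
# plateau, and a small seeded smooth perturbation so that different seeds
# give different but physically valid curves.

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's
# RNG state afterwards so package functions never disturb global
# reproducibility.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth zero-mean pseudo-random perturbation: a few sinusoids with seeded
# periods/phases.  Deterministic given (lam, amp, seed).
.smooth_noise <- function(lam, amp, seed) {
  if (amp <= 0) return(numeric(length(lam)))
  with_seed(seed, {
    per <- stats::runif(3, 90, 260)
    ph <- stats::runif(3, 0, 2 * pi)
    cf <- stats::rnorm(3)
    z <- rowSums(vapply(1:3, function(j) cf[j] * sin(2 * pi * lam / per[j] + ph[j]),
                        numeric(length(lam))))
    amp * z / sqrt(3)
  })
}

#' Built-in species leaf profiles
#'
#' Six leaf profiles named after common North American forest species, with
#' PAR-absorptance targets ordered oak > alder > (aspen, spruce, hemlock) >
#' juniper.  Broadleaf species: alder, oak, aspen; needleleaf: hemlock,
#' juniper, spruce.
#'
#' @return Named list of leaf profile parameter lists (see
#'   [generate_component_optics()]).
#' @export
#' @examples
#' names(species_profiles())
species_profiles <- function() {
  mk <- function(par_abs, nir_scatter = 0.93, red_edge_nm = 718) {
    list(par_absorptance = par_abs, nir_scatter = nir_scatter,
         red_edge_nm = red_edge_nm, red_edge_width = 13,
         refl_fraction = 0.52, noise_amp = 0.004)
  }
  list(
    oak     = mk(0.880),
    alder   = mk(0.868),
    aspen   = mk(0.860, nir_scatter = 0.94),
    spruce  = mk(0.862, nir_scatter = 0.90, red_edge_nm = 714),
    hemlock = mk(0.858, nir_scatter = 0.91, red_edge_nm = 715),
    juniper = mk(0.842, nir_scatter = 0.89, red_edge_nm = 712)
  )
}

#' Default branch and soil profiles
#'
#' Branch bark reflectance is a moderate ramp rising towards the NIR with
#' zero transmittance; the default soil background is a dry-soil linear
#' ramp from 0.05 (400 nm) to 0.25 (1000 nm).
#'
#' @param type `"broadleaf"`, `"needleleaf"` (branch profiles) or
#'   `"soil"`.
#' @return A profile parameter list.
#' @export
default_profile <- function(type = c("broadleaf", "needleleaf", "soil")) {
  type <- match.arg(type)
  switch(type,
    broadleaf  = list(refl_400 = 0.12, refl_1000 = 0.38, noise_amp = 0.004),
    needleleaf = list(refl_400 = 0.10, refl_1000 = 0.34, noise_amp = 0.004),
    soil       = list(refl_400 = 0.05, refl_1000 = 0.25, noise_amp = 0))
}

#' Generate synthetic component optical spectra
#'
#' Deterministic for a fixed `(kind, profile, grid, seed)` triple.  Leaf
#' curves are built from a visible absorptance shape (blue and red Gaussian
#' wells over a baseline) calibrated so that the mean 400--700 nm
#' absorptance matches `profile$par_absorptance`, joined through a logistic
#' red edge to an NIR scattering plateau of `profile$nir_scatter`
#' (reflectance + transmittance).  Branch and soil curves are linear
#' reflectance ramps with zero transmittance.
#'
#' @param kind `"leaf"`, `"branch"` or `"soil"`.
#' @param profile Profile parameter list, or for leaves the name of a
#'   built-in species profile (see [species_profiles()],
#'   [default_profile()]).
#' @param grid Wavelength grid (nm); must cover 400--700 nm for leaves.
#' @param seed Integer seed for the smooth perturbation.
#' @return A [component_optics()] object.
#' @export
#' @examples
#' oak <- generate_component_optics("leaf", "oak", seed = 1)
#' par_absorptance(oak)
generate_component_optics <- function(kind = c("leaf", "branch", "soil"),
                                      profile, grid = canonical_grid(),
                                      seed = 1L) {
  kind <- match.arg(kind)
  lam <- as.numeric(grid)
  if (is.character(profile)) {
    if (kind != "leaf") stop("named profiles exist only for leaves")
    sp <- species_profiles()
    if (!profile %in% names(sp)) {
      stop(sprintf("unknown species profile '%s'", profile))
    }
    label <- profile
    profile <- sp[[profile]]
  } else {
    label <- sprintf("synthetic-%s", kind)
  }

  if (kind == "leaf") {
    if (min(lam) > 400 || max(lam) < 700) {
      stop("leaf generation requires a grid covering 400-700 nm")
    }
    target <- profile$par_absorptance
    if (is.null(target) || target <= 0 || target >= 1) {
      stop("profile$par_absorptance must lie in (0, 1)")
    }
    a_nir <- 1 - profile$nir_scatter
    if (a_nir < 0 || a_nir > 1) stop("profile$nir_scatter must lie in [0, 1]")
    edge <- 1 / (1 + exp((lam - profile$red_edge_nm) / profile$red_edge_width))
    shape <- 0.78 + 0.19 * exp(-((lam - 450) / 45)^2) +
      0.19 * exp(-((lam - 672) / 50)^2)
    par_idx <- lam >= 400 & lam <= 700
    cc <- (target - a_nir * mean(1 - edge[par_idx])) /
      mean((edge * shape)[par_idx])
    if (cc * max(shape) > 1 || cc <= 0) {
      stop(sprintf(
        "PAR absorptance target %.3f incompatible with reflectance + transmittance <= 1",
        target))
    }
    absorptance <- a_nir * (1 - edge) + cc * shape * edge
    absorptance <- absorptance + .smooth_noise(lam, profile$noise_amp, seed)
    absorptance <- pmin(pmax(absorptance, 0.005), 0.995)
    scat <- 1 - absorptance
    rho <- profile$refl_fraction * scat
    tau <- scat - rho
    return(component_optics("leaf", lam, rho, tau, label = label))
  }

  # branch / soil: opaque reflectance ramp
  r0 <- profile$refl_400
  r1 <- profile$refl_1000
  if (is.null(r0) || is.null(r1)) stop("profile must give refl_400 and refl_1000")
  rho <- r0 + (r1 - r0) * (lam - 400) / 600
  rho <- rho + .smooth_noise(lam, profile$noise_amp %||% 0, seed)
  rho <- pmin(pmax(rho, 0.01), 0.95)
  component_optics(kind, lam, rho, NULL, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic forest component optics
#'
#' Returns the leaf, branch and soil optics used by the simulation grids.
#' The leaf spectrum of a forest type is the average of its three species
#' spectra (broadleaf: alder, oak, aspen; needleleaf: hemlock, juniper,
#' spruce), mirroring the practice of averaging species measurements into
#' one broadleaf and one needleleaf input set.
#'
#' @param forest_type `"DBF"` (deciduous broadleaf) or `"ENF"` (evergreen
#'   needleleaf).
#' @param grid Wavelength grid (nm).
#' @param seed Integer seed.
#' @return List with elements `leaf`, `branch`, `soil`
#'   ([component_optics()] objects).
#' @export
synthetic_forest_optics <- function(forest_type = c("DBF", "ENF"),
                                    grid = canonical_grid(), seed = 1L) {
  forest_type <- match.arg(forest_type)
  species <- if (forest_type == "DBF") c("alder", "oak", "aspen")
             else c("hemlock", "juniper", "spruce")
  leaves <- lapply(seq_along(species), function(i) {
    generate_component_optics("leaf", species[i], grid, seed + i)
  })
  rho <- rowMeans(vapply(leaves, `[[`, numeric(length(grid)), "reflectance"))
  tau <- rowMeans(vapply(leaves, `[[`, numeric(length(grid)), "transmittance"))
  leaf <- component_optics("leaf", grid, rho, tau,
                           label = sprintf("%s mean leaf", forest_type))
  branch_profile <- default_profile(
    if (forest_type == "DBF") "broadleaf" else "needleleaf")
  branch <- generate_component_optics("branch", branch_profile, grid,
                                      seed + 10L)
  soil <- generate_component_optics("soil", default_profile("soil"), grid,
                                    seed + 20L)
  soil$label <- "default soil ramp"
  list(leaf = leaf, branch = branch, soil = soil)
}
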