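# Shared fixtures, all built in code.

par_grid <- function(step = 50) seq(400, 700, by = step)

# spectrally flat component
flat_optics <- function(kind, rho, tau = 0, grid = par_grid()) {
  component_optics(kind, grid, rep(rho, length(grid)),
                   if (kind == "leaf") rep(tau, length(grid)) else NULL)
}

black_leaf <- function(grid = par_grid()) flat_optics("leaf", 0, 0, grid)
black_soil <- function(grid = par_grid()) flat_optics("soil", 0, grid = grid)

# cache expensive shared objects across test files
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

forest_optics <- function(ft) {
  cached(paste0("optics_", ft), synthetic_forest_optics(ft, seed = 1))
}

full_grid_sim <- function(ft) {
  cached(paste0("grid_", ft), {
    opt <- forest_optics(ft)
    run_scenario_grid(scenario_config(ft, opt$leaf, opt$branch, opt$soil))
  })
}

inversion_sim <- function(ft) {
  cached(paste0("inv_", ft), {
    opt <- forest_optics(ft)
    run_inversion_scenario(scenario_config(ft, opt$leaf, opt$branch,
                                           opt$soil))
  })
}

# random physically valid stack on a small wavelength grid
random_stack <- function(rng_seed, max_layers = 4) {
  set.seed(rng_seed)
  grid <- sort(sample(seq(400, 1000, 50), 3))
  n <- sample.int(max_layers, 1)
  layers <- lapply(seq_len(n), function(i) {
    kind <- sample(c("leaf", "branch"), 1)
    rho <- runif(length(grid), 0.02, 0.5)
    tau <- if (kind == "leaf") runif(length(grid), 0, 0.95 - rho) else NULL
    canopy_layer(
      component_optics(kind, grid, rho, tau),
      area_index = runif(1, 0.1, 2.5),
      lidf = sample(c("spherical", "planophile"), 1))
  })
  soil <- component_optics("soil", grid, runif(length(grid), 0, 0.4))
  canopy_stack(layers, soil)
}

random_geometry <- function() {
  geometry(solar_zenith_deg = runif(1, 5, 70),
           view_zenith_deg = runif(1, 0, 40),
           relative_azimuth_deg = runif(1, 0, 180),
           direct_fraction = sample(c(1, runif(1, 0.3, 1)), 1))
}
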