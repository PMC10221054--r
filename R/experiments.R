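# Simulation grids and green-FPAR ~ vegetation-index experiments --------

#' Build a two-component canopy stack
#'
#' Splits a total plant area index between leaves and branches at a given
#' green proportion and arranges them vertically.  `"blocks"` (default)
#' places one leaf block above one branch block -- leaves occupy the top of
#' real forest canopies, and woody material sits beneath them.
#' `"interleaved"` alternates `n_pairs` thin (leaf, branch) sub-layer
#' pairs, approximating a well-mixed canopy.  Zero-area layers are not
#' emitted.
#'
#' @param pai Total plant area index (> 0).
#' @param green_proportion Leaf share of the total area, in (0, 1\].
#' @param leaf_optics,branch_optics,soil_optics [component_optics()]
#'   objects on one wavelength grid.
#' @param arrangement `"blocks"` or `"interleaved"`.
#' @param n_pairs Number of leaf/branch pairs in interleaved mode.
#' @param leaf_lidf,branch_lidf Inclination distributions (defaults:
#'   spherical leaves, planophile branches).
#' @return A [canopy_stack()].
#' @export
build_stack <- function(pai, green_proportion, leaf_optics, branch_optics,
                        soil_optics,
                        arrangement = c("blocks", "interleaved"),
                        n_pairs = 10L,
                        leaf_lidf = "spherical", branch_lidf = "planophile") {
  arrangement <- match.arg(arrangement)
  if (pai <= 0) stop("pai must be positive")
  if (green_proportion <= 0 || green_proportion > 1) {
    stop("green_proportion must lie in (0, 1]")
  }
  leaf_area <- pai * green_proportion
  branch_area <- pai * (1 - green_proportion)
  layers <- list()
  if (arrangement == "blocks") {
    if (leaf_area > 0) {
      layers <- c(layers, list(canopy_layer(leaf_optics, leaf_area, leaf_lidf)))
    }
    if (branch_area > 0) {
      layers <- c(layers,
                  list(canopy_layer(branch_optics, branch_area, branch_lidf)))
    }
  } else {
    for (i in seq_len(n_pairs)) {
      if (leaf_area > 0) {
        layers <- c(layers, list(
          canopy_layer(leaf_optics, leaf_area / n_pairs, leaf_lidf)))
      }
      if (branch_area > 0) {
        layers <- c(layers, list(
          canopy_layer(branch_optics, branch_area / n_pairs, branch_lidf)))
      }
    }
  }
  canopy_stack(layers, soil_optics)
}

#' Scenario configuration for a simulation grid
#'
#' Bundles the component optics, the plant-area-index and green-proportion
#' grids, the sun/view geometry, the layer arrangement and the
#' vegetation-index configuration for one forest type.  Defaults reproduce
#' the study conditions: PAI in \{0.1, 0.5, 1, ..., 7\}, green proportion
#' in \{0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.98\}, solar zenith 30 degrees,
#' nadir view, direct-beam illumination.
#'
#' @param forest_type `"DBF"` or `"ENF"`.
#' @param leaf_optics,branch_optics,soil_optics [component_optics()]
#'   objects; defaults are synthesised with [synthetic_forest_optics()].
#' @param pai_values Positive plant-area-index grid.
#' @param green_proportions Green-proportion grid in (0, 1\].
#' @param geometry A [geometry()].
#' @param arrangement,n_pairs See [build_stack()].
#' @param vi_config A [vi_config()].
#' @param seed Seed used only when optics are synthesised here.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(forest_type = c("DBF", "ENF"),
                            leaf_optics = NULL, branch_optics = NULL,
                            soil_optics = NULL,
                            pai_values = c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7),
                            green_proportions = c(0.5, 0.6, 0.7, 0.8, 0.9,
                                                  0.95, 0.98),
                            geometry = greensail::geometry(),
                            arrangement = c("blocks", "interleaved"),
                            n_pairs = 10L,
                            vi_config = greensail::vi_config(),
                            seed = 1L) {
  forest_type <- match.arg(forest_type)
  arrangement <- match.arg(arrangement)
  if (any(pai_values <= 0)) stop("pai_values must be positive")
  if (any(green_proportions <= 0 | green_proportions > 1)) {
    stop("green_proportions must lie in (0, 1]")
  }
  if (is.null(leaf_optics) || is.null(branch_optics) || is.null(soil_optics)) {
    opt <- synthetic_forest_optics(forest_type, seed = seed)
    leaf_optics <- leaf_optics %||% opt$leaf
    branch_optics <- branch_optics %||% opt$branch
    soil_optics <- soil_optics %||% opt$soil
  }
  structure(list(forest_type = forest_type, leaf_optics = leaf_optics,
                 branch_optics = branch_optics, soil_optics = soil_optics,
                 pai_values = pai_values,
                 green_proportions = green_proportions,
                 geometry = geometry, arrangement = arrangement,
                 n_pairs = n_pairs, vi_config = vi_config),
            class = "scenario_config")
}

# simulate one (pai, proportion) cell -> one-row data.frame
.simulate_cell <- function(cfg, pai, gp) {
  st <- build_stack(pai, gp, cfg$leaf_optics, cfg$branch_optics,
                    cfg$soil_optics, cfg$arrangement, cfg$n_pairs)
  prof <- solve_stack(st, cfg$geometry)
  fp <- partition_canopy_fpar(prof, st)
  bands <- band_reflectance(prof, cfg$vi_config)
  vi <- compute_indices(bands, cfg$vi_config)
  data.frame(forest_type = cfg$forest_type, pai = pai, green_proportion = gp,
             fpar_total = fp$fpar_total, fpar_pav = fp$fpar_pav,
             fpar_npv = fp$fpar_npv,
             ndvi = vi$ndvi, evi = vi$evi, evi2 = vi$evi2, savi = vi$savi,
             r_blue = bands$r_blue, r_red = bands$r_red, r_nir = bands$r_nir,
             stringsAsFactors = FALSE)
}

#' Run the full simulation grid of a scenario
#'
#' One row per (plant area index, green proportion) combination.  The
#' computation is deterministic given the configuration.
#'
#' @param cfg A [scenario_config()].
#' @param verbose Emit per-scenario progress on standard error.
#' @return A data frame with FPAR partition, band reflectances and
#'   vegetation indices per row.
#' @export
run_scenario_grid <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  grid <- expand.grid(gp = cfg$green_proportions, pai = cfg$pai_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    if (verbose) {
      message(sprintf("[%s] PAI %.2f proportion %.2f", cfg$forest_type,
                      grid$pai[i], grid$gp[i]))
    }
    .simulate_cell(cfg, grid$pai[i], grid$gp[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$pai, out$green_proportion), , drop = FALSE]
}

#' Re-simulation scenario for the inversion models
#'
#' Deciduous broadleaf forests (DBF) keep a fixed woody (NPV) area index --
#' winter canopies carry only branches, whose area changes little through
#' the year -- so the leaf area is `PAI - npv_area_index` and the green
#' proportion varies with PAI.  Evergreen needleleaf forests (ENF) keep a
#' fixed green proportion (field campaigns place it near 90%).
#'
#' @param cfg A [scenario_config()] (its PAI/proportion grids are ignored).
#' @param pai_values PAI grid, default integers 1..7.
#' @param npv_area_index Fixed branch area index for DBF (default 0.5).
#' @param green_proportion Fixed green proportion for ENF (default 0.90).
#' @return Data frame as [run_scenario_grid()], one row per PAI.
#' @export
run_inversion_scenario <- function(cfg, pai_values = 1:7,
                                   npv_area_index = 0.5,
                                   green_proportion = 0.90) {
  stopifnot(inherits(cfg, "scenario_config"))
  rows <- lapply(pai_values, function(pai) {
    if (cfg$forest_type == "DBF") {
      if (pai <= npv_area_index) {
        stop(sprintf("PAI %g does not exceed the fixed NPV area index %g",
                     pai, npv_area_index))
      }
      gp <- (pai - npv_area_index) / pai
    } else {
      gp <- green_proportion
    }
    .simulate_cell(cfg, pai, gp)
  })
  do.call(rbind, rows)
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation of two equally long sequences.
#'
#' @param xs,ys Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return Scalar correlation in \[-1, 1\].
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("at least 3 observations are required")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("degenerate input: zero variance")
  }
  stats::cor(xs, ys)
}

#' Correlation table between FPAR components and vegetation indices
#'
#' Pearson correlations over the pooled rows of a simulation table for
#' every (FPAR column, vegetation-index column) pair, optionally
#' stratified by green proportion.
#'
#' @param simtable Data frame from [run_scenario_grid()] or
#'   [run_inversion_scenario()].
#' @param fpar_columns,vi_columns Column names to correlate.
#' @param by_proportion Also stratify by `green_proportion`.
#' @return Long data frame with columns `fpar`, `vi`, `r` (and
#'   `green_proportion` when stratified).
#' @export
correlation_table <- function(simtable,
                              fpar_columns = c("fpar_total", "fpar_pav",
                                               "fpar_npv"),
                              vi_columns = c("ndvi", "evi", "evi2", "savi"),
                              by_proportion = FALSE) {
  stopifnot(all(c(fpar_columns, vi_columns) %in% names(simtable)))
  one <- function(df, gp = NA_real_) {
    combos <- expand.grid(fpar = fpar_columns, vi = vi_columns,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    combos$r <- mapply(function(f, v) pearson_r(df[[f]], df[[v]]),
                       combos$fpar, combos$vi)
    if (!is.na(gp)) combos$green_proportion <- gp
    combos
  }
  if (!by_proportion) return(one(simtable))
  do.call(rbind, lapply(split(simtable, simtable$green_proportion),
                        function(df) one(df, df$green_proportion[1])))
}

#' Fit a linear green-FPAR ~ vegetation-index inversion model
#'
#' Ordinary least squares of green FPAR (`fpar_pav`) on one vegetation
#' index, with the error metrics evaluated on the fitted rows: mean error
#' is the mean absolute residual and the error rate is the mean error as a
#' percentage of the mean simulated green FPAR.
#'
#' @param simtable Simulation table with at least 3 rows.
#' @param vi_name One of the vegetation-index columns (default `"evi"`).
#' @return An object of class `"fpar_vi_fit"` with fields `vi_name`,
#'   `slope`, `intercept`, `pearson_r`, `mean_error`,
#'   `error_rate_percent`, `n`.
#' @export
fit_green_fpar_vi <- function(simtable, vi_name = "evi") {
  stopifnot(vi_name %in% names(simtable), "fpar_pav" %in% names(simtable))
  if (nrow(simtable) < 3L) stop("at least 3 rows are required")
  x <- simtable[[vi_name]]
  y <- simtable$fpar_pav
  if (stats::sd(x) == 0) stop("degenerate design: constant vegetation index")
  fit <- stats::lm(y ~ x)
  mean_error <- mean(abs(stats::residuals(fit)))
  structure(list(vi_name = vi_name,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = pearson_r(x, y),
                 mean_error = mean_error,
                 error_rate_percent = 100 * mean_error / mean(y),
                 n = length(x), model = fit),
            class = "fpar_vi_fit")
}

#' @export
print.fpar_vi_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Green FPAR ~ %s (n = %d):\n", toupper(x$vi_name), x$n))
  cat(sprintf("  fpar_pav = %.*f x %s %+.*f\n", digits, x$slope,
              toupper(x$vi_name), digits, x$intercept))
  cat(sprintf("  Pearson r %.4f | mean error %.4f | error rate %.2f%%\n",
              x$pearson_r, x$mean_error, x$error_rate_percent))
  invisible(x)
}

#' @export
coef.fpar_vi_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.fpar_vi_fit <- function(object, vi, ...) {
  object$intercept + object$slope * vi
}

#' Green FPAR of individual species under fixed scenarios
#'
#' Simulates green FPAR for each species' leaf optics under a small grid of
#' plant area index and green proportion, all other conditions equal.
#'
#' @param species_optics Named list of leaf [component_optics()].
#' @param branch_optics,soil_optics Shared branch and soil optics.
#' @param pai_values PAI values (default 1, 4, 7).
#' @param proportions Green proportions (default 0.98, 0.50).
#' @param geometry A [geometry()].
#' @param arrangement,n_pairs See [build_stack()].
#' @return Long data frame: `species`, `green_proportion`, `pai`,
#'   `fpar_pav`.
#' @export
species_fpar_table <- function(species_optics, branch_optics, soil_optics,
                               pai_values = c(1, 4, 7),
                               proportions = c(0.98, 0.50),
                               geometry = greensail::geometry(),
                               arrangement = "blocks", n_pairs = 10L) {
  stopifnot(length(names(species_optics)) == length(species_optics))
  rows <- list()
  for (sp in names(species_optics)) {
    for (gp in proportions) {
      for (pai in pai_values) {
        st <- build_stack(pai, gp, species_optics[[sp]], branch_optics,
                          soil_optics, arrangement, n_pairs)
        fp <- partition_canopy_fpar(solve_stack(st, geometry), st)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, green_proportion = gp, pai = pai,
          fpar_pav = fp$fpar_pav, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
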