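# Run configuration, table and fit writers ------------------------------

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing one simulation run: the forest
#' type, spectra (either CSV paths or names of built-in synthetic
#' profiles plus a seed), the PAI and green-proportion grids, geometry,
#' layer arrangement and vegetation-index bands.  Missing fields receive
#' the package defaults (solar zenith 30, nadir view, azimuth 0, direct
#' fraction 1).  Validation failures report the offending field.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()] with the extra attribute `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  bad <- function(field, msg) stop(sprintf("config field '%s': %s", field, msg))

  forest_type <- cfg$forest_type %||% "DBF"
  if (!forest_type %in% c("DBF", "ENF")) {
    bad("forest_type", "must be 'DBF' or 'ENF'")
  }
  seed <- cfg$seed %||% 1L
  if (!is.numeric(seed)) bad("seed", "must be an integer")

  g <- cfg$geometry %||% list()
  for (f in c("solar_zenith_deg", "view_zenith_deg")) {
    if (!is.null(g[[f]]) && (g[[f]] < 0 || g[[f]] >= 90)) {
      bad(paste0("geometry.", f), "must lie in [0, 90)")
    }
  }
  if (!is.null(g$direct_fraction) &&
      (g$direct_fraction < 0 || g$direct_fraction > 1)) {
    bad("geometry.direct_fraction", "must lie in [0, 1]")
  }
  geom <- geometry(solar_zenith_deg = g$solar_zenith_deg %||% 30,
                   view_zenith_deg = g$view_zenith_deg %||% 0,
                   relative_azimuth_deg = g$relative_azimuth_deg %||% 0,
                   direct_fraction = g$direct_fraction %||% 1)

  sp <- cfg$spectra %||% list()
  grid <- canonical_grid()
  read_or_generate <- function(entry, kind, default_profile_name) {
    if (is.null(entry)) {
      if (kind == "leaf") {
        return(NULL)  # synthesised by scenario_config
      }
      return(NULL)
    }
    if (file.exists(entry)) {
      return(resample_optics(read_optics_csv(entry, kind), grid))
    }
    if (kind == "leaf") {
      return(generate_component_optics("leaf", entry, grid, seed))
    }
    bad(paste0("spectra.", kind), sprintf("file '%s' not found", entry))
  }
  leaf <- read_or_generate(sp$leaf, "leaf")
  branch <- if (!is.null(sp$branch) && file.exists(sp$branch)) {
    resample_optics(read_optics_csv(sp$branch, "branch"), grid)
  } else if (!is.null(sp$branch)) {
    bad("spectra.branch", sprintf("file '%s' not found", sp$branch))
  } else NULL
  soil <- if (!is.null(sp$soil) && file.exists(sp$soil)) {
    resample_optics(read_optics_csv(sp$soil, "soil"), grid)
  } else if (!is.null(sp$soil)) {
    bad("spectra.soil", sprintf("file '%s' not found", sp$soil))
  } else NULL

  pai_values <- cfg$pai_values %||% c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7)
  if (any(pai_values <= 0)) bad("pai_values", "must be positive")
  props <- cfg$green_proportions %||% c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.98)
  if (any(props <= 0 | props > 1)) {
    bad("green_proportions", "must lie in (0, 1]")
  }

  vic <- cfg$vi %||% list()
  vcfg <- vi_config(blue_band = unlist(vic$blue_band) %||% c(459, 479),
                    red_band = unlist(vic$red_band) %||% c(620, 670),
                    nir_band = unlist(vic$nir_band) %||% c(841, 876),
                    savi_L = vic$savi_L %||% 0.5)

  out <- scenario_config(forest_type = forest_type, leaf_optics = leaf,
                         branch_optics = branch, soil_optics = soil,
                         pai_values = pai_values, green_proportions = props,
                         geometry = geom,
                         arrangement = cfg$arrangement %||% "blocks",
                         n_pairs = cfg$n_pairs %||% 10L,
                         vi_config = vcfg, seed = seed)
  attr(out, "seed") <- seed
  out
}

#' Write a simulation table to CSV
#'
#' Fixed column order, 6 significant digits; reloading with
#' [read_sim_table()] reproduces values to the written precision.
#'
#' @param simtable Data frame from [run_scenario_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(simtable, path) {
  num <- vapply(simtable, is.numeric, logical(1))
  simtable[num] <- lapply(simtable[num], signif, digits = 6)
  utils::write.csv(simtable, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_table
#' @export
read_sim_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a regression fit to JSON
#'
#' Serialises exactly the fields of an `"fpar_vi_fit"` object (slope,
#' intercept, correlation, error metrics).
#'
#' @param fit An `"fpar_vi_fit"` from [fit_green_fpar_vi()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fpar_vi_fit"))
  out <- fit[c("vi_name", "slope", "intercept", "pearson_r", "mean_error",
               "error_rate_percent", "n")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
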