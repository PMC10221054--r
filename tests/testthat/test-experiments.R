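test_that("build_stack splits area between leaves and branches", {
  opt <- forest_optics("DBF")
  st <- build_stack(2, 0.5, opt$leaf, opt$branch, opt$soil,
                    arrangement = "interleaved", n_pairs = 10)
  expect_length(st$layers, 20)
  areas <- vapply(st$layers, `[[`, numeric(1), "area_index")
  expect_equal(areas, rep(0.1, 20))
  kinds <- vapply(st$layers, function(l) l$component$kind, character(1))
  leaf_area <- sum(areas[kinds == "leaf"])
  expect_equal(leaf_area, 1.0)

  blocks <- build_stack(2, 0.5, opt$leaf, opt$branch, opt$soil)
  expect_length(blocks$layers, 2)
  expect_identical(blocks$layers[[1]]$component$kind, "leaf")
  expect_identical(blocks$layers[[2]]$component$kind, "branch")
  expect_identical(blocks$layers[[1]]$lidf, "spherical")
  expect_identical(blocks$layers[[2]]$lidf, "planophile")

  pure <- build_stack(2, 1.0, opt$leaf, opt$branch, opt$soil,
                      arrangement = "interleaved")
  expect_length(pure$layers, 10)
  expect_true(all(vapply(pure$layers, function(l) l$component$kind,
                         character(1)) == "leaf"))
  expect_error(build_stack(0, 0.5, opt$leaf, opt$branch, opt$soil),
               "positive")
  expect_error(build_stack(2, 0, opt$leaf, opt$branch, opt$soil),
               "\\(0, 1\\]")
})

test_that("interleaving converges with the number of sublayer pairs", {
  opt <- forest_optics("DBF")
  fp10 <- {
    st <- build_stack(3, 0.6, opt$leaf, opt$branch, opt$soil,
                      "interleaved", n_pairs = 10)
    partition_canopy_fpar(solve_stack(st, geometry()), st)
  }
  fp40 <- {
    st <- build_stack(3, 0.6, opt$leaf, opt$branch, opt$soil,
                      "interleaved", n_pairs = 40)
    partition_canopy_fpar(solve_stack(st, geometry()), st)
  }
  expect_lt(abs(fp10$fpar_total - fp40$fpar_total), 0.005)
})

test_that("the scenario grid enumerates PAI x proportion deterministically", {
  sim <- full_grid_sim("DBF")
  expect_equal(nrow(sim), 9 * 7)
  expect_setequal(unique(sim$pai), c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7))
  expect_setequal(unique(sim$green_proportion),
                  c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.98))
  # maximum green FPAR at the densest, greenest canopy
  top <- sim[which.max(sim$fpar_pav), ]
  expect_equal(top$pai, 7)
  expect_equal(top$green_proportion, 0.98)
  # re-running yields an identical table
  opt <- forest_optics("DBF")
  again <- run_scenario_grid(scenario_config("DBF", opt$leaf, opt$branch,
                                             opt$soil))
  expect_identical(sim, again)
})

test_that("FPAR responds to canopy structure as expected", {
  sim <- full_grid_sim("DBF")
  for (gp in unique(sim$green_proportion)) {
    s <- sim[sim$green_proportion == gp, ]
    s <- s[order(s$pai), ]
    expect_true(all(diff(s$fpar_total) > 0))
    expect_true(all(diff(s$fpar_pav) > 0))
    # indices rise with PAI too
    for (vi in c("ndvi", "evi", "evi2", "savi")) {
      expect_true(all(diff(s[[vi]]) > 0))
    }
  }
  for (pai in unique(sim$pai)) {
    s <- sim[sim$pai == pai, ]
    s <- s[order(s$green_proportion), ]
    expect_true(all(diff(s$fpar_pav) > 0))
    expect_true(all(diff(s$fpar_npv) < 0))
  }
  # NDVI dominates SAVI wherever the red-NIR contrast is positive
  expect_true(all(sim$ndvi > sim$savi))
})

test_that("non-green FPAR peaks at intermediate PAI", {
  sim <- full_grid_sim("DBF")
  s <- sim[sim$green_proportion == 0.5, ]
  s <- s[order(s$pai), ]
  peak <- which.max(s$fpar_npv)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(s))
  expect_gte(s$pai[peak], 1)
  expect_lte(s$pai[peak], 3)
})

test_that("pearson_r reproduces hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8, tolerance = 1e-9)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("correlation table separates green from non-green FPAR", {
  sim <- full_grid_sim("DBF")
  ct <- correlation_table(sim)
  expect_equal(nrow(ct), 12)
  pav <- ct$r[ct$fpar == "fpar_pav"]
  npv <- abs(ct$r[ct$fpar == "fpar_npv"])
  expect_true(all(pav > 0.9))
  expect_true(all(npv < 0.5))
  expect_true(all(npv < pav))
  strat <- correlation_table(sim, by_proportion = TRUE)
  expect_equal(nrow(strat), 12 * 7)
  sim$const <- 1
  expect_error(correlation_table(sim, fpar_columns = "const"),
               "zero variance")
})

test_that("inversion scenarios fix the stated component", {
  inv <- inversion_sim("DBF")
  expect_equal(nrow(inv), 7)
  expect_equal(inv$pai, 1:7)
  # branch area fixed at 0.5: green proportion = (PAI - 0.5)/PAI
  expect_equal(inv$green_proportion, (1:7 - 0.5) / (1:7))
  expect_equal(inv$green_proportion[1], 0.5)

  invE <- inversion_sim("ENF")
  expect_equal(invE$green_proportion, rep(0.9, 7))
  # ENF at PAI 4: leaf area 3.6, branch area 0.4
  expect_equal(4 * invE$green_proportion[4], 3.6)

  opt <- forest_optics("DBF")
  cfg <- scenario_config("DBF", opt$leaf, opt$branch, opt$soil)
  expect_error(run_inversion_scenario(cfg, pai_values = c(0.5, 1:7)),
               "NPV area index")
})

test_that("OLS inversion recovers exact and noisy linear relations", {
  # exact line
  vi <- seq(0.2, 0.8, length.out = 10)
  tab <- data.frame(fpar_pav = 2 * vi - 0.5, evi = vi)
  fit <- fit_green_fpar_vi(tab, "evi")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.5, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$mean_error, 0, tolerance = 1e-12)
  expect_equal(coef(fit), c(intercept = -0.5, slope = 2), tolerance = 1e-12)
  expect_equal(predict(fit, 0.5), 0.5, tolerance = 1e-12)

  # parameter recovery under seeded noise
  set.seed(123)
  slopes <- replicate(20, {
    x <- runif(50, 0.1, 0.9)
    y <- 1.8 * x - 0.3 + rnorm(50, sd = 0.01)
    fit_green_fpar_vi(data.frame(fpar_pav = y, evi = x), "evi")$slope
  })
  expect_true(all(abs(slopes - 1.8) < 0.05))
  expect_lt(abs(mean(slopes) - 1.8), 0.01)
  expect_error(fit_green_fpar_vi(data.frame(fpar_pav = 1:5,
                                            evi = rep(1, 5)), "evi"),
               "degenerate")
})

test_that("species green FPAR ranks by PAR absorptance and grows with PAI", {
  tab <- cached("species_tab", {
    sp <- lapply(stats::setNames(nm = names(species_profiles())),
                 function(s) generate_component_optics("leaf", s, seed = 1))
    br <- generate_component_optics("branch", default_profile("broadleaf"),
                                    seed = 11)
    so <- generate_component_optics("soil", default_profile("soil"),
                                    seed = 21)
    species_fpar_table(sp, br, so)
  })
  expect_equal(nrow(tab), 6 * 3 * 2)
  for (gp in unique(tab$green_proportion)) {
    for (pai in unique(tab$pai)) {
      cell <- tab[tab$green_proportion == gp & tab$pai == pai, ]
      expect_identical(cell$species[which.max(cell$fpar_pav)], "oak")
    }
  }
  for (sp in unique(tab$species)) {
    for (gp in unique(tab$green_proportion)) {
      s <- tab[tab$species == sp & tab$green_proportion == gp, ]
      s <- s[order(s$pai), ]
      expect_true(all(diff(s$fpar_pav) > 0))
    }
  }
})
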