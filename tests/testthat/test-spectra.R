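test_that("optics CSV reading parses, validates and fills defaults", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance,transmittance",
               "400,0.05,0.02", "550,0.10,0.05", "700,0.06,0.03"), f)
  co <- read_optics_csv(f, "leaf")
  expect_s3_class(co, "component_optics")
  expect_length(co$wavelength, 3)
  expect_equal(co$reflectance, c(0.05, 0.10, 0.06))

  # rows out of order are sorted
  writeLines(c("wavelength_nm,reflectance,transmittance",
               "700,0.06,0.03", "400,0.05,0.02", "550,0.10,0.05"), f)
  expect_equal(read_optics_csv(f, "leaf")$wavelength, c(400, 550, 700))

  # rho + tau > 1 rejected with a row-level message
  writeLines(c("wavelength_nm,reflectance,transmittance",
               "400,0.05,0.02", "550,0.7,0.5"), f)
  expect_error(read_optics_csv(f, "leaf"), "row 2")

  # branch without a transmittance column gets zeros
  writeLines(c("wavelength_nm,reflectance",
               "400,0.1", "700,0.2"), f)
  br <- read_optics_csv(f, "branch")
  expect_identical(br$transmittance, c(0, 0))

  writeLines(c("wavelength_nm,rho", "400,0.1"), f)
  expect_error(read_optics_csv(f, "leaf"), "missing column")
})

test_that("write/read CSV round-trips optics on the stored grid", {
  opt <- generate_component_optics("leaf", "oak", seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_optics_csv(opt, f)
  back <- read_optics_csv(f, "leaf")
  expect_equal(back$wavelength, opt$wavelength)
  expect_equal(back$reflectance, opt$reflectance, tolerance = 1e-8)
  expect_equal(back$transmittance, opt$transmittance, tolerance = 1e-8)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  two <- component_optics("branch", c(400, 500), c(0, 1))
  expect_equal(resample_optics(two, 450)$reflectance, 0.5)

  src <- generate_component_optics("leaf", "aspen", seed = 2)
  same <- resample_optics(src, src$wavelength)
  expect_equal(same$reflectance, src$reflectance)
  expect_equal(same$transmittance, src$transmittance)
  expect_error(resample_optics(src, 350), "beyond source range")
})

test_that("component invariants are enforced", {
  expect_error(component_optics("leaf", c(400, 500), c(0.7, 0.1),
                                c(0.5, 0.1)), "reflectance \\+ transmittance")
  expect_error(component_optics("branch", c(400, 500), c(0.1, 0.1),
                                c(0.05, 0)), "opaque")
  expect_error(spectral_curve(c(500, 400), c(0, 0)), "strictly increasing")
  expect_error(spectral_curve(c(400, 500), c(0, NA)), "non-finite")
})

test_that("par_absorptance integrates 1 - rho - tau over the PAR window", {
  expect_equal(par_absorptance(black_leaf()), 1)
  expect_equal(par_absorptance(flat_optics("leaf", 0.5, 0.5)), 0)
  expect_equal(par_absorptance(flat_optics("leaf", 0.1, 0.1)), 0.8)
  # weighting concentrated at one wavelength picks out that sample
  g <- par_grid(10)
  opt <- flat_optics("leaf", 0.3, 0, g)
  spike <- spectral_curve(g, as.numeric(g == 550))
  expect_equal(par_absorptance(opt, spike), 0.7)
  narrow <- component_optics("leaf", seq(450, 650, 50),
                             rep(0.1, 5), rep(0.1, 5))
  expect_error(par_absorptance(narrow), "PAR window")
})

test_that("synthetic generation is deterministic and respects kind", {
  a <- generate_component_optics("leaf", "oak", seed = 3)
  b <- generate_component_optics("leaf", "oak", seed = 3)
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$transmittance, b$transmittance)
  c <- generate_component_optics("leaf", "oak", seed = 4)
  expect_false(identical(a$reflectance, c$reflectance))

  br <- generate_component_optics("branch", default_profile("broadleaf"),
                                  seed = 3)
  expect_true(all(br$transmittance == 0))
  so <- generate_component_optics("soil", default_profile("soil"), seed = 1)
  expect_true(all(so$transmittance == 0))
})

test_that("leaf generator hits its PAR-absorptance target and NIR plateau", {
  for (sp in names(species_profiles())) {
    prof <- species_profiles()[[sp]]
    leaf <- generate_component_optics("leaf", sp, seed = 11)
    expect_lt(abs(par_absorptance(leaf) - prof$par_absorptance), 0.02)
    nir <- leaf$wavelength >= 800 & leaf$wavelength <= 900
    scat <- leaf$reflectance[nir] + leaf$transmittance[nir]
    expect_true(all(scat >= 0.7 * prof$nir_scatter))
  }
  # oak-like absorbs more PAR than juniper-like
  oak <- generate_component_optics("leaf", "oak", seed = 5)
  juniper <- generate_component_optics("leaf", "juniper", seed = 5)
  expect_gt(par_absorptance(oak), par_absorptance(juniper))
  # incompatible target
  prof <- species_profiles()$oak
  prof$par_absorptance <- 0.999
  expect_error(generate_component_optics("leaf", prof, seed = 1),
               "incompatible")
})

test_that("raising the PAR target never decreases generated absorptance", {
  targets <- seq(0.70, 0.88, by = 0.01)
  prof <- species_profiles()$aspen
  vals <- vapply(targets, function(t) {
    prof$par_absorptance <- t
    par_absorptance(generate_component_optics("leaf", prof, seed = 9))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("generated curves satisfy optics invariants across many seeds", {
  kinds <- c("leaf", "branch", "soil")
  profs <- list(species_profiles()$spruce, default_profile("needleleaf"),
                default_profile("soil"))
  for (s in 1:1000) {
    i <- (s %% 3) + 1
    opt <- generate_component_optics(kinds[i], profs[[i]], seed = s)
    expect_true(all(opt$reflectance >= 0 & opt$reflectance <= 1))
    expect_true(all(opt$transmittance >= 0 & opt$transmittance <= 1))
    expect_true(all(opt$reflectance + opt$transmittance <= 1 + 1e-12))
  }
})

test_that("forest optics average the species of their type", {
  opt <- forest_optics("DBF")
  expect_identical(opt$leaf$kind, "leaf")
  expect_identical(opt$branch$kind, "branch")
  expect_identical(opt$soil$kind, "soil")
  sp <- lapply(seq_along(c("alder", "oak", "aspen")), function(i) {
    generate_component_optics("leaf", c("alder", "oak", "aspen")[i],
                              seed = 1 + i)
  })
  expect_equal(opt$leaf$reflectance,
               rowMeans(vapply(sp, `[[`, numeric(121), "reflectance")))
})
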