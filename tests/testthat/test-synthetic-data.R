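test_that("recipe arithmetic conserves volume and recovers the target", {
  r <- compute_recipe(2500, 0.4, 5)
  expect_equal(r$il_volume_ul + r$ink_volume_ul + r$contrast_volume_ul +
                 r$ddw_volume_ul, r$total_volume_ul)
  expect_equal(r$il_volume_ul, 0.10 * 2500)
  expect_equal(r$ink_volume_ul, 0.03 * 2500)
  # concentration recomputed from volumes returns the target exactly
  expect_equal(r$contrast_volume_ul * 5 / r$total_volume_ul, 0.4)
  expect_equal(r$agarose_mg, 25)  # 1 g per 100 mL
})

test_that("recipe boundary and infeasibility behave as specified", {
  # contrast exactly 87% of total: DDW = 0, still valid
  r <- compute_recipe(1000, 0.87, 1)
  expect_equal(r$contrast_volume_ul, 870)
  expect_equal(r$ddw_volume_ul, 0)
  expect_error(compute_recipe(1000, 0.9, 1), "infeasible")
  expect_error(compute_recipe(1000, 2, 1), "stock_conc")
  expect_error(compute_recipe(1000, -1, 1), "stock_conc")
})

test_that("simulated DR profiles are reproducible and wavelength-checked", {
  spec <- phantom_spec(decay_model(1, 3.74),
                       optical = default_phantom_optics(au_mg_ml = 0.1),
                       seed = 21L)
  a <- simulate_dr_profile(spec, "650")
  b <- simulate_dr_profile(spec, "650")
  expect_identical(a$gamma, b$gamma)
  c <- simulate_dr_profile(spec, "650", seed = 99L)
  expect_false(identical(a$gamma, c$gamma))
  expect_error(simulate_dr_profile(spec, "999"), "wavelength")
})

test_that("high-count DR simulation recovers the slope within 1%", {
  op <- optical_properties(0.5^2 / 3, 1.0)  # mu_eff = 0.5
  spec <- phantom_spec(decay_model(1, 3.74), optical = list("650" = op),
                       seed = 30L)
  hats <- vapply(1:50, function(r) {
    prof <- simulate_dr_profile(spec, "650", counts_at_rho1 = 1e8,
                                seed = 3000L + r)
    fit_dr_slope(prof)$mu_eff_hat
  }, numeric(1))
  expect_lt(abs(mean(hats) - 0.5) / 0.5, 0.01)
})

test_that("strong absorption at a short counts budget hits the detection limit", {
  optics <- default_phantom_optics(au_mg_ml = 0)
  strong <- lapply(optics, function(op)
    optical_properties(op$mu_a * 10 + 1.5, op$mu_s_prime, op$wavelength))
  spec <- phantom_spec(decay_model(1, 3.74), optical = strong, seed = 8L)
  prof <- simulate_dr_profile(spec, "650", counts_at_rho1 = 50,
                              noise_floor = 30)
  f <- try_fit_dr_slope(prof)
  expect_s3_class(f, "dr_fit_failure")
})

test_that("homogeneous FLIM simulation matches its expectation", {
  st <- default_settings(counts = 1e4, n_bins = 64)
  spec <- phantom_spec(decay_model(1, 3.92), heterogeneity_cv = 0,
                       grid = c(12, 12), seed = 61L)
  img <- simulate_flim_image(spec, st)
  totals <- apply(img$counts, c(1, 2), sum)
  se <- sqrt(1e4 / length(totals))
  expect_lt(abs(mean(totals) - 1e4), 3 * se)
  # per-bin aggregate within counting-noise bounds of the expectation
  pooled <- apply(img$counts, 3, sum)
  expected <- length(totals) * expected_bin_counts(spec$truth_decay, st)$counts
  big <- expected > 500
  expect_true(all(abs(pooled[big] - expected[big]) / expected[big] <
                    5 / sqrt(expected[big])))
})

test_that("heterogeneity field delivers the configured total-count CV", {
  st <- default_settings(counts = 1e4, n_bins = 32)
  spec <- phantom_spec(decay_model(1, 3.92), heterogeneity_cv = 0.3,
                       grid = c(64, 64), seed = 62L)
  img <- simulate_flim_image(spec, st)
  totals <- as.numeric(apply(img$counts, c(1, 2), sum))
  cv <- stats::sd(totals) / mean(totals)
  expect_gte(cv, 0.25)
  expect_lte(cv, 0.35)
  # field mean ~ 1: expected total intensity is CV-invariant
  expect_lt(abs(mean(totals) - 1e4) / 1e4, 2 * cv / sqrt(length(totals)) + 0.01)
})

test_that("FLIM simulation is seed-reproducible", {
  st <- default_settings(counts = 1e3, n_bins = 32)
  spec <- phantom_spec(decay_model(1, 2.0), heterogeneity_cv = 0.2,
                       grid = c(6, 6), seed = 63L)
  expect_identical(simulate_flim_image(spec, st)$counts,
                   simulate_flim_image(spec, st)$counts)
})

test_that("fixture suite writes the full campaign with a faithful manifest", {
  out <- withr::local_tempdir()
  st <- default_settings(counts = 2e3, n_bins = 64)
  man <- make_fixture_suite(out, settings = st, grid = c(4, 4),
                            dr_counts = 1e5, seed = 777L)
  expect_length(man$images, 2 + 6 + 18)   # free-dye + solutions + phantom areas
  expect_length(man$dr_profiles, 12)      # six Au levels x two wavelengths
  expect_true(file.exists(file.path(out, "manifest.json")))
  # every file re-readable by the analysis modules
  for (f in names(man$images))
    expect_s3_class(read_flim_image(file.path(out, f)), "flim_image")
  for (f in names(man$dr_profiles))
    expect_s3_class(read_reflectance_profile(file.path(out, f)),
                    "reflectance_profile")
  # determinism: regenerating with the master seed gives identical data
  out2 <- withr::local_tempdir()
  make_fixture_suite(out2, settings = st, grid = c(4, 4),
                     dr_counts = 1e5, seed = 777L)
  f1 <- read_flim_image(file.path(out, "solution_01.tif"))
  f2 <- read_flim_image(file.path(out2, "solution_01.tif"))
  expect_identical(f1$counts, f2$counts)
  p1 <- read_reflectance_profile(file.path(out, "dr_au0.10_650nm.tsv"))
  p2 <- read_reflectance_profile(file.path(out2, "dr_au0.10_650nm.tsv"))
  expect_identical(p1$gamma, p2$gamma)
})
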