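test_that("mono fit recovers the lifetime from a noiseless curve", {
  st <- default_settings()
  curve <- expected_bin_counts(decay_model(1, 3.92), st)
  fit <- fit_pixel_mono(curve, st)
  expect_true(fit$converged)
  expect_equal(fit$tau1, 3.92, tolerance = 1e-4)
  expect_equal(fit$mean_flt, fit$tau1)
  expect_equal(fit$a1_pct, 100)
})

test_that("mono fit on a Poisson pixel lands close to truth", {
  st <- default_settings(counts = 1e4)
  curve <- poisson_curve(decay_model(1, 3.92), st, seed = 101)
  fit <- fit_pixel_mono(curve, st)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau1 - 3.92), 0.05 * 3.92)
})

test_that("pixels below the counts threshold are excluded, not errors", {
  st <- default_settings(counts = 1e4)
  zero <- decay_curve(expected_bin_counts(decay_model(1, 1), st)$bin_times,
                      rep(0, st$n_bins))
  fit <- fit_pixel_mono(zero, st)
  expect_false(fit$included)
  expect_true(is.na(fit$tau1))
})

test_that("bi-exponential fit with pure fast component gives a1 near 100", {
  st <- default_settings(counts = 1e4)
  curve <- poisson_curve(decay_model(1, 1.0), st, seed = 55)
  fit <- fit_pixel_biexp_fixed(curve, st, tau2_fixed = 3.92)
  expect_true(fit$converged)
  expect_gte(fit$a1_pct, 99)
  expect_equal(fit$tau1, 1.0, tolerance = 0.05)
})

test_that("bi-exponential fit recovers benchmark conjugate parameters", {
  st <- default_settings(counts = 1e4)
  truth <- decay_model(c(0.8116, 0.1884), c(1.15, 3.92))
  fits <- lapply(1:8, function(s)
    fit_pixel_biexp_fixed(poisson_curve(truth, st, seed = 200 + s), st, 3.92))
  tau1s <- vapply(fits, `[[`, numeric(1), "tau1")
  # within twice the benchmark pixel STD (0.24 ns) of the true 1.15 ns
  expect_lt(abs(mean(tau1s) - 1.15), 2 * 0.24)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  # amplitude-weighted lifetime lies between the two component lifetimes
  mf <- vapply(fits, `[[`, numeric(1), "mean_flt")
  expect_true(all(mf > tau1s & mf < 3.92))
})

test_that("lifetimes colliding with the fixed component are flagged", {
  # near-coincident components: fits scatter around the fixed lifetime;
  # the flag must mirror the |tau1 - tau2| < 0.05 ns condition on every
  # pixel and fire on collisions instead of erroring
  st <- default_settings(counts = 1e4)
  truth <- decay_model(c(0.3, 0.7), c(3.8, 3.92))
  fits <- lapply(8:12, function(s)
    fit_pixel_biexp_fixed(poisson_curve(truth, st, seed = s), st, 3.92))
  flags <- vapply(fits, `[[`, logical(1), "identifiability_flag")
  tau1s <- vapply(fits, `[[`, numeric(1), "tau1")
  expect_identical(flags, abs(tau1s - 3.92) < 0.05)
  expect_true(any(flags))   # seed 10 collides
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("tau2 echoes the fixed value and component labels never swap", {
  # free lifetime above the fixed one: stays labelled tau1
  st <- default_settings(counts = 2e4)
  truth <- decay_model(c(0.6, 0.4), c(6.0, 3.74))
  fit <- fit_pixel_biexp_fixed(poisson_curve(truth, st, seed = 31), st, 3.74)
  expect_equal(fit$tau2, 3.74)
  expect_gt(fit$tau1, 3.74)
})

test_that("whole-image fit handles masks, dead pixels and aggregation", {
  st <- default_settings(counts = 1e4, n_bins = 128)
  spec <- phantom_spec(decay_model(1, 3.92), grid = c(8, 8), seed = 5L)
  img <- simulate_flim_image(spec, st)
  # two dead pixels
  img$counts[1, 1, ] <- 0
  img$counts[3, 5, ] <- 0
  res <- fit_image(img, "mono")
  expect_equal(nrow(res), 64)
  expect_equal(sum(!res$included), 2)
  expect_true(all(res$converged[res$included]))
  sm <- summarize_image(res)
  expect_equal(sm$n_pixels_included, 62)
  expect_equal(sm$n_pixels_excluded, 2)
  expect_equal(sm$mean$tau1, 3.92, tolerance = 0.05)
  # histogram counts account for every included pixel
  expect_equal(sum(sm$tau1_hist$counts), 62)
  # mask errors
  img$mask <- matrix(FALSE, 8, 8)
  expect_error(fit_image(img, "mono"), "empty mask")
})

test_that("summaries are exact on constant result grids", {
  res <- tibble::tibble(
    row = rep(1:2, 2), col = rep(1:2, each = 2),
    tau1 = 2.0, tau2 = 2.0, a1_pct = 100, mean_flt = 2.0, chi2 = 1.0,
    chi2_flag = FALSE, converged = TRUE, identifiability_flag = FALSE,
    total_counts = 1e4, background = 0, included = TRUE)
  sm <- summarize_image(res)
  expect_equal(sm$mean$tau1, 2.0)
  expect_equal(sm$sd$tau1, 0)
  expect_error(summarize_image(res[res$tau1 > 3, ]), "zero converged")
})

test_that("model misspecification inflates chi-square", {
  st <- default_settings(counts = 3e4, n_bins = 128)
  bi_truth <- decay_model(c(0.7, 0.3), c(0.6, 3.92))
  mono_truth <- decay_model(1, 2.0)
  chi_mis <- vapply(1:6, function(s)
    fit_pixel_mono(poisson_curve(bi_truth, st, seed = 400 + s), st)$chi2,
    numeric(1))
  chi_ok <- vapply(1:6, function(s)
    fit_pixel_mono(poisson_curve(mono_truth, st, seed = 500 + s), st)$chi2,
    numeric(1))
  expect_gt(mean(chi_mis), mean(chi_ok))
  expect_gt(mean(chi_mis), 1.5)
})

test_that("recovery does not improve when the photon budget drops", {
  truth <- decay_model(1, 3.92)
  rmse_at <- function(counts) {
    st <- default_settings(counts = counts, n_bins = 128)
    errs <- vapply(1:10, function(s)
      fit_pixel_mono(poisson_curve(truth, st, seed = 600 + s), st)$tau1 - 3.92,
      numeric(1))
    sqrt(mean(errs^2))
  }
  expect_gte(rmse_at(1e3), rmse_at(1e4))
})

test_that("neyman-weighted least squares is available as an option", {
  st <- default_settings(counts = 1e5)
  curve <- poisson_curve(decay_model(1, 3.92), st, seed = 8)
  f_wls <- fit_pixel_mono(curve, st, objective = "wls")
  f_mle <- fit_pixel_mono(curve, st, objective = "mle")
  expect_true(f_wls$converged && f_mle$converged)
  expect_equal(f_wls$tau1, f_mle$tau1, tolerance = 0.05)
})

test_that("interface images show the boundary in region statistics", {
  st <- default_settings(counts = 1e4, n_bins = 128)
  img <- simulate_interface_image(decay_model(1, 3.74),
                                  decay_model(c(0.8, 0.2), c(0.9, 3.74)),
                                  st, grid = c(10, 10), seed = 9L)
  res <- fit_image(img, "mono")
  b <- attr(img, "boundary_col")
  left <- res$tau1[res$col <= b]
  right <- res$tau1[res$col > b]
  pooled_se <- sqrt(stats::var(left) / length(left) +
                    stats::var(right) / length(right))
  expect_gt(abs(mean(left) - mean(right)), 5 * pooled_se)
})

test_that("lifetime maps render with excluded pixels as background", {
  st <- default_settings(counts = 1e4, n_bins = 64)
  spec <- phantom_spec(decay_model(1, 2.0), grid = c(4, 4), seed = 2L)
  img <- simulate_flim_image(spec, st)
  res <- fit_image(img, "mono")
  p <- render_flim_image(res)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  render_flim_image(res, value = "mean_flt", color_range = c(1, 3), path = path)
  expect_true(file.exists(path))
})

test_that("image stacks round-trip through multi-page TIFF", {
  st <- default_settings(counts = 1e4, n_bins = 64)
  spec <- phantom_spec(decay_model(1, 2.0), grid = c(5, 6), seed = 3L)
  img <- simulate_flim_image(spec, st)
  path <- withr::local_tempfile(fileext = ".tif")
  write_flim_image(img, path)
  back <- read_flim_image(path)
  expect_equal(dim(back$counts), dim(img$counts))
  expect_true(all(back$counts == img$counts))
  expect_equal(back$settings$rep_rate_mhz, st$rep_rate_mhz)
})
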