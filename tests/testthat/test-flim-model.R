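test_that("decay intensity evaluates the sum of exponentials", {
  m <- decay_model(c(0.4, 0.6), c(1, 4))
  expect_equal(decay_intensity(m, 0), 1.0)             # sum of amplitudes
  mono <- decay_model(1, 2)
  expect_equal(decay_intensity(mono, 2), exp(-1))
  bi <- decay_model(c(0.8, 0.2), c(1, 4))
  expect_equal(decay_intensity(bi, 2), 0.8 * exp(-2) + 0.2 * exp(-0.5))
  expect_equal(decay_intensity(bi, 2), 0.22957436, tolerance = 1e-7)
  expect_error(decay_intensity(mono, -1), "t")
})

test_that("amplitude-weighted lifetime averages normalised fractions", {
  expect_equal(amplitude_weighted_flt(decay_model(1, 3.92)), 3.92)
  expect_equal(amplitude_weighted_flt(decay_model(c(1, 1), c(1, 3))), 2.0)
  # benchmark conjugate-solution parameters: 0.8116*1.15 + 0.1884*3.92
  m <- decay_model(c(81.16, 18.84), c(1.15, 3.92))
  expect_equal(amplitude_weighted_flt(m), 1.671868, tolerance = 1e-6)
  # invariant to common rescaling of amplitudes
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(amplitude_weighted_flt(decay_model(k * c(0.3, 0.7), c(0.5, 3))),
                 amplitude_weighted_flt(decay_model(c(0.3, 0.7), c(0.5, 3))))
  }
  expect_error(decay_model(c(0, 0), c(1, 2)), "amplitude")
})

test_that("decay model constructor enforces invariants", {
  expect_error(decay_model(1, c(1, 2)), "equal length")
  expect_error(decay_model(c(0.5, 0.5), c(1, -2)), "lifetimes")
  expect_error(decay_model(c(-0.5, 1), c(1, 2)), "amplitudes")
})

test_that("acquisition settings derive period and bin width", {
  s <- acquisition_settings(50, 256)
  expect_equal(s$period_ns, 20)
  expect_equal(s$bin_width_ns, 20 / 256)
  expect_equal(acquisition_settings(20)$period_ns, 50)
  expect_equal(acquisition_settings(80)$period_ns, 12.5)
  expect_error(acquisition_settings(50, n_bins = 3), "n_bins")
  expect_error(acquisition_settings(0), "rep_rate")
  expect_error(acquisition_settings(50, irf_fwhm_ps = 5000), "period")
})

test_that("expected bin counts match the brute-force pulse-train oracle", {
  st <- default_settings(counts = 1e4, n_bins = 64)
  cases <- list(
    list(model = decay_model(1, 3.92), fr = 1, taus = 3.92),
    list(model = decay_model(c(0.8116, 0.1884), c(1.15, 3.92)),
         fr = c(0.8116, 0.1884), taus = c(1.15, 3.92)),
    list(model = decay_model(c(0.66, 0.34), c(2.72, 3.92)),
         fr = c(0.66, 0.34), taus = c(2.72, 3.92)))
  for (cs in cases) {
    got <- expected_bin_counts(cs$model, st)$counts
    want <- 1e4 * oracle_pattern(cs$taus, cs$fr, st)
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("bin counts sum exactly to the photon budget and decrease", {
  st <- default_settings(counts = 5e3)
  m <- decay_model(c(0.7, 0.3), c(0.8, 3.92))
  counts <- expected_bin_counts(m, st)$counts
  expect_equal(sum(counts), 5e3)
  expect_true(all(diff(counts) < 0))
})

test_that("wrap correction vanishes for lifetimes much shorter than the period", {
  st <- default_settings(counts = 1e4)     # 20 ns period
  m <- decay_model(1, 0.1)                 # tau << period
  wrapped <- expected_bin_counts(m, st, wrap = TRUE)$counts
  plain <- expected_bin_counts(m, st, wrap = FALSE)$counts
  expect_equal(wrapped, plain, tolerance = 1e-6)
})

test_that("wrap correction matters at tau = 3.92 ns and 50 MHz", {
  st <- default_settings()
  # for one component the pile-up factor 1/(1 - exp(-T/tau)) is a pure
  # scale, cancelled by normalisation; the wrapped shape must therefore
  # equal the pulse-train oracle exactly
  wrapped_mono <- expected_bin_counts(decay_model(1, 3.92), st, wrap = TRUE)$counts
  expect_equal(wrapped_mono, st$counts_target * oracle_pattern(3.92, 1, st),
               tolerance = 1e-7)
  # for a mixture the two components carry different pile-up factors
  # (1.0061 at tau = 3.92 vs ~1 at tau = 1.15), so the normalised shape
  # itself shifts measurably
  m <- decay_model(c(0.8116, 0.1884), c(1.15, 3.92))
  wrapped <- expected_bin_counts(m, st, wrap = TRUE)$counts
  plain <- expected_bin_counts(m, st, wrap = FALSE)$counts
  expect_gt(max(abs(wrapped - plain) / plain), 1e-3)
})

test_that("Gaussian IRF smearing conserves counts and delays the peak", {
  st0 <- default_settings(counts = 1e4)
  st_irf <- acquisition_settings(50, 256, irf_fwhm_ps = 100, counts_target = 1e4)
  m <- decay_model(1, 1.0)
  plain <- expected_bin_counts(m, st0)$counts
  smeared <- expected_bin_counts(m, st_irf, irf_t0_ns = 1.0)$counts
  expect_equal(sum(smeared), 1e4)
  expect_gt(which.max(smeared), which.max(plain))
})

test_that("decay curves round-trip through delimited text", {
  st <- default_settings(n_bins = 32)
  curve <- expected_bin_counts(decay_model(1, 2.5), st)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decay_curve(curve, path)
  back <- read_decay_curve(path)
  expect_equal(back$bin_times, curve$bin_times)
  expect_equal(back$counts, curve$counts)
})
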