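# Shared fixtures and independent oracles. The oracles recompute
# expected quantities by brute force (numeric quadrature, explicit
# pulse-train summation, grid search) so they share no code path with
# the package implementation.

default_settings <- function(counts = 1e4, n_bins = 256, rep = 50, irf = 0) {
  acquisition_settings(rep_rate_mhz = rep, n_bins = n_bins,
                       irf_fwhm_ps = irf, counts_target = counts)
}

# Expected per-bin photon fractions by brute force: sum the decay over
# `n_periods` earlier excitation pulses and integrate each bin with
# stats::integrate. No geometric-series closed form.
oracle_pattern <- function(lifetimes, fractions, settings, n_periods = 80) {
  T <- settings$period_ns
  edges <- seq(0, T, length.out = settings$n_bins + 1)
  intensity <- function(t) {
    out <- 0
    for (i in seq_along(lifetimes)) {
      for (k in 0:n_periods) out <- out + fractions[i] * exp(-(t + k * T) / lifetimes[i])
    }
    out
  }
  p <- vapply(seq_len(settings$n_bins), function(b) {
    stats::integrate(intensity, edges[b], edges[b + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  p / sum(p)
}

# Grid-search fit oracle on a noiseless curve: exhaustive search over
# tau1 (0.05-ns steps) and the amplitude percentage (1% steps), with
# the overall scale solved by linear least squares at each grid point
# (background known to be zero for noiseless synthetic curves).
# Patterns come from explicit pulse-train summation, independently of
# the package's geometric-series closed form.
oracle_grid_fit <- function(curve, settings, mode, tau2_fixed = NULL,
                            tau_grid = seq(0.05, 15, by = 0.05),
                            a1_grid = seq(0, 100, by = 1)) {
  y <- curve$counts
  T <- settings$period_ns
  edges <- seq(0, T, length.out = settings$n_bins + 1)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  comp <- function(tau, n_periods = 80) {
    p <- numeric(settings$n_bins)
    for (k in 0:n_periods)
      p <- p + tau * (exp(-(lo + k * T) / tau) - exp(-(hi + k * T) / tau))
    p
  }
  B <- vapply(tau_grid, comp, numeric(settings$n_bins))  # bins x taus
  best_rss <- function(P) {
    # per-column least-squares scale, then residual sum of squares
    A <- colSums(P * y) / colSums(P * P)
    sum(y^2) - A * colSums(P * y)
  }
  if (mode == "mono") {
    rss <- best_rss(B)
    list(tau1 = tau_grid[which.min(rss)], a1_pct = 100)
  } else {
    b2 <- comp(tau2_fixed)
    best <- c(Inf, NA, NA)
    for (a1 in a1_grid) {
      f <- a1 / 100
      rss <- best_rss(f * B + (1 - f) * b2)
      j <- which.min(rss)
      if (rss[j] < best[1]) best <- c(rss[j], tau_grid[j], a1)
    }
    list(tau1 = best[2], a1_pct = best[3])
  }
}

# Simulate one Poisson decay curve from ground truth via the package's
# expected pattern (the data-generating route under test elsewhere).
poisson_curve <- function(model, settings, seed) {
  exp_curve <- expected_bin_counts(model, settings)
  withr::with_seed(seed,
    decay_curve(exp_curve$bin_times, stats::rpois(length(exp_curve$counts),
                                                  exp_curve$counts)))
}
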