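# Synthetic measurement generator: phantom recipes, shot-noise
# diffuse-reflectance profiles, and FLIM image stacks with spatial
# concentration heterogeneity. Every stage of the analysis pipeline can
# be exercised end-to-end on these simulations, with known ground truth.

#' Phantom specification for simulation
#'
#' Ground truth for one simulated phantom (or solution): optical
#' properties per wavelength, the true fluorescence decay, the spatial
#' heterogeneity of the per-pixel probe concentration, grid size and
#' seed.
#'
#' The heterogeneity field emulates the concentration gradients that
#' arise when a phantom solidifies — areas of higher and lower probe
#' concentration — as a smoothed log-normal per-pixel intensity
#' multiplier with mean 1 and the given coefficient of variation.
#'
#' @param truth_decay A [decay_model()] giving the true decay.
#' @param optical Named list of [optical_properties()], keyed by
#'   wavelength label (defaults cover 650 and 780 nm with
#'   Intralipid-like scattering and ink-dominated absorption; the
#'   values are literature-plausible placeholders, configurable).
#' @param heterogeneity_cv Coefficient of variation of the per-pixel
#'   concentration multiplier (>= 0; 0 = homogeneous).
#' @param grid `c(rows, cols)` pixel grid, each >= 1.
#' @param seed Integer seed for every stochastic draw of this phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(truth_decay,
                         optical = default_phantom_optics(),
                         heterogeneity_cv = 0, grid = c(64, 64),
                         seed = 1L) {
  stopifnot(inherits(truth_decay, "decay_model"),
            is.numeric(heterogeneity_cv), heterogeneity_cv >= 0,
            length(grid) == 2L, all(grid >= 1))
  stopifnot(is.list(optical), length(optical) >= 1L,
            all(vapply(optical, inherits, logical(1), "optical_properties")))
  structure(
    list(truth_decay = truth_decay, optical = optical,
         heterogeneity_cv = heterogeneity_cv,
         grid = as.integer(grid), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom optical properties
#'
#' Baseline Intralipid/India-ink phantom optics: reduced scattering
#' 1.0 mm^-1 at both wavelengths, ink-only absorption 0.005 mm^-1, plus
#' a per-(mg/mL Au) absorption increment that is larger at 650 nm than
#' at 780 nm (gold nanorods of this geometry absorb more strongly at
#' 650 nm). These are plausible placeholder coefficients, not measured
#' values, and are fully configurable.
#'
#' @param au_mg_ml Gold concentration in mg/mL (default 0).
#' @param mu_s_prime Reduced scattering, mm^-1 (default 1.0).
#' @param mu_a_base Ink-only absorption, mm^-1 (default 0.005).
#' @param au_increment Named vector: absorption increment per mg/mL Au
#'   at each wavelength, mm^-1.
#' @return Named list of [optical_properties()] keyed by wavelength.
#' @export
default_phantom_optics <- function(au_mg_ml = 0, mu_s_prime = 1.0,
                                   mu_a_base = 0.005,
                                   au_increment = c("650" = 0.60, "780" = 0.15)) {
  out <- lapply(names(au_increment), function(wl) {
    optical_properties(mu_a = mu_a_base + au_mg_ml * au_increment[[wl]],
                       mu_s_prime = mu_s_prime, wavelength = as.numeric(wl))
  })
  names(out) <- names(au_increment)
  out
}

# ---- phantom recipe arithmetic --------------------------------------------

#' Compute an Intralipid/ink/agarose phantom recipe
#'
#' Component volumes for a solid tissue-like phantom: Intralipid is 10%
#' of the total volume (scattering), diluted India ink 3% (absorption),
#' the contrast solution `total * target_conc / stock_conc`, double
#' distilled water the remainder, and agarose 1% weight-per-volume
#' (1 g per 100 mL). Volumes always sum exactly to the total. The
#' contrast solution may occupy at most the 87% of the volume not taken
#' by Intralipid and ink.
#'
#' @param total_volume_ul Total phantom volume in microlitres (> 0).
#' @param target_conc Desired contrast-agent concentration in the
#'   phantom (any unit, same as `stock_conc`).
#' @param stock_conc Concentration of the contrast stock solution
#'   (> `target_conc`).
#' @return An object of class `phantom_recipe` with fields
#'   `total_volume_ul`, `il_volume_ul`, `ink_volume_ul`,
#'   `contrast_volume_ul`, `ddw_volume_ul`, `agarose_mg`.
#' @examples
#' # a 4-mL free-fluorescein phantom at 0.33 uM from a 10 uM stock
#' compute_recipe(4000, 0.33, 10)
#' @export
compute_recipe <- function(total_volume_ul, target_conc, stock_conc) {
  stopifnot(is.numeric(total_volume_ul), total_volume_ul > 0,
            is.numeric(target_conc), is.numeric(stock_conc))
  if (!(stock_conc > target_conc && target_conc > 0))
    stop("need stock_conc > target_conc > 0")
  contrast <- total_volume_ul * target_conc / stock_conc
  if (contrast > 0.87 * total_volume_ul)
    stop("infeasible recipe: contrast solution would exceed 87% of the total volume")
  il <- 0.10 * total_volume_ul
  ink <- 0.03 * total_volume_ul
  ddw <- total_volume_ul - il - ink - contrast
  structure(
    list(total_volume_ul = total_volume_ul, il_volume_ul = il,
         ink_volume_ul = ink, contrast_volume_ul = contrast,
         ddw_volume_ul = ddw,
         agarose_mg = 10 * total_volume_ul / 1000),  # 1 g per 100 mL
    class = "phantom_recipe"
  )
}

#' @export
print.phantom_recipe <- function(x, ...) {
  cat(sprintf("<phantom_recipe> total %g uL\n", x$total_volume_ul))
  cat(sprintf("  Intralipid      %g uL\n", x$il_volume_ul))
  cat(sprintf("  India ink 0.1%%  %g uL\n", x$ink_volume_ul))
  cat(sprintf("  contrast stock  %g uL\n", x$contrast_volume_ul))
  cat(sprintf("  DDW             %g uL\n", x$ddw_volume_ul))
  cat(sprintf("  agarose         %g mg\n", x$agarose_mg))
  invisible(x)
}

# ---- diffuse-reflectance simulation ---------------------------------------

#' Simulate a shot-noise diffuse-reflectance profile
#'
#' Evaluates the forward diffusion model at the requested separations,
#' scales so the expected photon count at the nearest separation equals
#' `counts_at_rho1`, draws per-sample Poisson counts, and attaches a
#' dark-count detection floor. Strongly absorbing phantoms at a short
#' counts budget lose most samples below the floor — the
#' detection-limit regime in which slope fitting fails.
#'
#' @param spec A [phantom_spec()].
#' @param wavelength Wavelength label; must match a key of
#'   `spec$optical`.
#' @param rho Source-detector separations, mm (default 1-6 mm in
#'   0.25-mm steps, spanning the diffusive regime).
#' @param counts_at_rho1 Expected photon count at the nearest
#'   separation (default 1e6).
#' @param noise_floor Dark-count detection floor in counts (default 10).
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A [reflectance_profile()] with Poisson counts.
#' @export
simulate_dr_profile <- function(spec, wavelength, rho = seq(1, 6, by = 0.25),
                                counts_at_rho1 = 1e6, noise_floor = 10,
                                seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  wl <- as.character(wavelength)
  if (!wl %in% names(spec$optical))
    stop("no optical properties for wavelength ", wl, " in this phantom spec")
  if (is.null(seed)) seed <- spec$seed
  model <- forward_reflectance(1, spec$optical[[wl]], rho)
  expected <- model$gamma * counts_at_rho1 / model$gamma[1]
  counts <- withr::with_seed(seed, stats::rpois(length(expected), expected))
  reflectance_profile(rho, counts, noise_floor = noise_floor)
}

# ---- FLIM image simulation -------------------------------------------------

# Smoothed log-normal concentration multiplier field, mean 1, marginal
# coefficient of variation cv. White Gaussian noise is smoothed by
# circular convolution with a Gaussian kernel (stationary, so every
# pixel keeps the same marginal variance) and re-standardised, so the
# configured CV survives the smoothing.
.heterogeneity_field <- function(rows, cols, cv, corr_length = 4) {
  if (cv <= 0) return(matrix(1, rows, cols))
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (corr_length > 0 && rows * cols > 1) {
    circ_dist <- function(n) {
      d <- 0:(n - 1)
      ifelse(d <= n / 2, d, d - n)
    }
    kern <- outer(stats::dnorm(circ_dist(rows), sd = corr_length),
                  stats::dnorm(circ_dist(cols), sd = corr_length))
    kern <- kern / sum(kern)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (rows * cols)
    sdz <- stats::sd(as.numeric(z))
    if (sdz > 0) z <- (z - mean(z)) / sdz
  }
  sigma2 <- log(1 + cv^2)
  exp(sqrt(sigma2) * z - sigma2 / 2)
}

#' Simulate a FLIM image stack
#'
#' Per-pixel expected bin counts come from [expected_bin_counts()] of
#' the phantom's true decay, scaled by a smoothed log-normal per-pixel
#' concentration multiplier (mean 1, CV `spec$heterogeneity_cv`,
#' correlation length `corr_length` pixels); measured counts are drawn
#' Poisson per bin. Fully reproducible from the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param settings An [acquisition_settings()]; `counts_target` is the
#'   expected total photons per pixel before the heterogeneity
#'   multiplier.
#' @param corr_length Correlation length of the heterogeneity field in
#'   pixels (default 4).
#' @param background_rate Expected dark counts per bin (default 0, so
#'   the pure sum-of-exponentials model is exactly recoverable).
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A [flim_image()].
#' @export
simulate_flim_image <- function(spec, settings, corr_length = 4,
                                background_rate = 0, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(settings, "acquisition_settings"))
  if (is.null(seed)) seed <- spec$seed
  rows <- spec$grid[1]; cols <- spec$grid[2]
  expected <- expected_bin_counts(spec$truth_decay, settings)$counts
  counts <- withr::with_seed(seed, {
    mult <- .heterogeneity_field(rows, cols, spec$heterogeneity_cv, corr_length)
    lam <- outer(as.numeric(mult), expected) + background_rate
    array(stats::rpois(length(lam), lam), dim = c(rows, cols, settings$n_bins))
  })
  flim_image(counts, settings)
}

#' Simulate a two-region interface image
#'
#' Left half of the grid follows one decay model, right half another —
#' the interface geometry used to image a free-dye phantom butted
#' against a conjugate phantom. Heterogeneity and Poisson noise as in
#' [simulate_flim_image()].
#'
#' @param left,right [decay_model()] ground truths for the two halves.
#' @param settings An [acquisition_settings()].
#' @param grid `c(rows, cols)`.
#' @param heterogeneity_cv Concentration-field CV applied to both sides.
#' @param seed Integer seed.
#' @return A [flim_image()]; the boundary column index is
#'   `attr(, "boundary_col")`.
#' @export
simulate_interface_image <- function(left, right, settings, grid = c(32, 32),
                                     heterogeneity_cv = 0, seed = 1L) {
  stopifnot(inherits(left, "decay_model"), inherits(right, "decay_model"))
  rows <- grid[1]; cols <- grid[2]
  split_at <- cols %/% 2
  e_left <- expected_bin_counts(left, settings)$counts
  e_right <- expected_bin_counts(right, settings)$counts
  counts <- withr::with_seed(seed, {
    mult <- .heterogeneity_field(rows, cols, heterogeneity_cv)
    lam <- array(0, dim = c(rows, cols, settings$n_bins))
    for (j in seq_len(cols)) {
      e <- if (j <= split_at) e_left else e_right
      lam[, j, ] <- outer(mult[, j], e)
    }
    array(stats::rpois(length(lam), lam), dim = dim(lam))
  })
  img <- flim_image(counts, settings)
  attr(img, "boundary_col") <- split_at
  img
}

# ---- full fixture suite ----------------------------------------------------

#' Generate the full benchmark fixture suite
#'
#' Writes a complete simulated measurement campaign to `out_dir`:
#' one bi-exponential solution image per linker in
#' [gnr_solution_table()] (slow component 3.92 ns), one image per
#' (linker, area) row of [gnr_phantom_table()] (slow component 3.74 ns,
#' heterogeneity on), mono-exponential free-fluorescein solution and
#' phantom images, and diffuse-reflectance profiles for six Au
#' concentrations (0.05-0.3 mg/mL) at 650 and 780 nm. A JSON manifest
#' maps every file to its ground-truth parameters.
#'
#' @param out_dir Output directory (created if missing).
#' @param settings An [acquisition_settings()] shared by all images.
#' @param grid Pixel grid for the images (default `c(16, 16)` to keep
#'   the suite light; raise for full-scale runs).
#' @param heterogeneity_cv Concentration-field CV for phantom images
#'   (default 0.1).
#' @param dr_counts Expected DR photon count at the nearest separation
#'   (default 1e6).
#' @param seed Master seed; every file derives its own sub-seed.
#' @return The manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir,
                               settings = acquisition_settings(),
                               grid = c(16, 16), heterogeneity_cv = 0.1,
                               dr_counts = 1e6, seed = 20160926L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anchors <- reference_lifetimes()
  manifest <- list(seed = seed, images = list(), dr_profiles = list())
  sub_seed <- function(k) (seed + 7919L * k) %% .Machine$integer.max
  k <- 0L

  add_image <- function(fname, model, cv, truth) {
    k <<- k + 1L
    spec <- phantom_spec(model, heterogeneity_cv = cv, grid = grid,
                         seed = sub_seed(k))
    img <- simulate_flim_image(spec, settings)
    path <- file.path(out_dir, fname)
    write_flim_image(img, path)
    manifest$images[[fname]] <<- c(truth, list(seed = sub_seed(k)))
  }

  # free-dye anchors: mono-exponential
  add_image("solution_free_fluorescein.tif",
            decay_model(1, anchors$solution_flt), 0,
            list(kind = "solution_free", mode = "mono",
                 tau = anchors$solution_flt))
  add_image("phantom_free_fluorescein.tif",
            decay_model(1, anchors$phantom_flt), heterogeneity_cv,
            list(kind = "phantom_free", mode = "mono",
                 tau = anchors$phantom_flt))

  # conjugate solutions: bi-exponential, slow component at the solution anchor
  sol <- gnr_solution_table()
  for (i in seq_len(nrow(sol))) {
    f1 <- sol$a1_pct[i] / 100
    add_image(sprintf("solution_%02d.tif", i),
              decay_model(c(f1, 1 - f1), c(sol$tau1[i], anchors$solution_flt),
                          fixed = c(FALSE, TRUE)),
              0,
              list(kind = "solution_conjugate", mode = "biexp_fixed",
                   label = sol$label[i], tau1 = sol$tau1[i],
                   a1_pct = sol$a1_pct[i], tau2 = anchors$solution_flt))
  }

  # conjugate phantom areas: bi-exponential, slow component at the phantom anchor
  ph <- gnr_phantom_table()
  for (i in seq_len(nrow(ph))) {
    f1 <- ph$a1_pct[i] / 100
    add_image(sprintf("phantom_%02d_area%d.tif", (i - 1L) %/% 3L + 1L, ph$area[i]),
              decay_model(c(f1, 1 - f1), c(ph$tau1[i], anchors$phantom_flt),
                          fixed = c(FALSE, TRUE)),
              heterogeneity_cv,
              list(kind = "phantom_conjugate", mode = "biexp_fixed",
                   label = ph$label[i], area = ph$area[i], tau1 = ph$tau1[i],
                   a1_pct = ph$a1_pct[i], tau2 = anchors$phantom_flt))
  }

  # DR concentration ladder: six Au levels x two wavelengths
  au_levels <- seq(0.05, 0.3, by = 0.05)
  for (au in au_levels) {
    for (wl in c("650", "780")) {
      k <- k + 1L
      optics <- default_phantom_optics(au_mg_ml = au)
      spec <- phantom_spec(decay_model(1, anchors$phantom_flt),
                           optical = optics, grid = c(1, 1),
                           seed = sub_seed(k))
      prof <- simulate_dr_profile(spec, wl, counts_at_rho1 = dr_counts)
      fname <- sprintf("dr_au%.2f_%snm.tsv", au, wl)
      write_reflectance_profile(prof, file.path(out_dir, fname))
      manifest$dr_profiles[[fname]] <- list(
        au_mg_ml = au, wavelength = as.numeric(wl),
        mu_a = optics[[wl]]$mu_a, mu_s_prime = optics[[wl]]$mu_s_prime,
        mu_eff = effective_attenuation(optics[[wl]]), seed = sub_seed(k))
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
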