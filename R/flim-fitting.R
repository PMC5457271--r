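# Per-pixel TCSPC decay fitting: mono-exponential, and bi-exponential
# with the slow component's lifetime held fixed (the free-dye anchor).
# Image-level application, aggregation and rendering.

.TAU_BOUNDS <- c(0.05, 15)  # ns; typical FLT range 0.1-10 ns, padded

#' FLIM image stack
#'
#' A scanned pixel grid of photon-arrival histograms: a 3-D array
#' (row x col x time-bin) of non-negative counts plus the acquisition
#' settings and an optional inclusion mask.
#'
#' @param counts 3-D numeric array, `dim = c(rows, cols, n_bins)`, with
#'   `n_bins` matching `settings$n_bins`.
#' @param settings An [acquisition_settings()].
#' @param mask Optional logical matrix (`rows x cols`); `FALSE` pixels
#'   are skipped by [fit_image()].
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(counts, settings, mask = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L,
            inherits(settings, "acquisition_settings"))
  if (dim(counts)[3] != settings$n_bins)
    stop("third dimension of `counts` must equal `settings$n_bins`")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(counts)[1:2]))
  }
  structure(list(counts = counts, settings = settings, mask = mask),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_image> %d x %d pixels, %d time bins, %g MHz, %.3g total counts\n",
              d[1], d[2], d[3], x$settings$rep_rate_mhz, sum(x$counts)))
  invisible(x)
}

# ---- core single-curve fit -------------------------------------------------

# Signed square-root Poisson deviance residuals; minimising their sum of
# squares through Levenberg-Marquardt is equivalent to Poisson MLE.
.deviance_residuals <- function(y, m) {
  m <- pmax(m, 1e-12)
  d <- 2 * (m - y + ifelse(y > 0, y * log(y / m), 0))
  sign(y - m) * sqrt(pmax(d, 0))
}

# Neyman reduced chi-square: conventional TCSPC fit-quality statistic.
.reduced_chi2 <- function(y, m, n_par) {
  sum((y - m)^2 / pmax(y, 1)) / (length(y) - n_par)
}

# Deterministic initial values: lifetime from the log-linear slope of the
# first decade of background-subtracted counts, background from the tail
# bins. No random starts, so fits are reproducible without a seed.
.init_decay_fit <- function(y, settings, tau_bounds) {
  n <- length(y)
  mids <- (seq_len(n) - 0.5) * settings$bin_width_ns
  bg0 <- mean(utils::tail(y, max(2L, n %/% 20L)))
  ysub <- y - bg0
  top <- max(ysub)
  tau0 <- settings$period_ns / 4
  if (top > 0) {
    idx <- which(ysub > max(top / 10, 1e-3))
    if (length(idx) >= 2L) {
      sl <- stats::coef(stats::lm(log(ysub[idx]) ~ mids[idx]))[2]
      if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
    }
  }
  tau0 <- min(max(tau0, tau_bounds[1] * 1.5), tau_bounds[2] / 1.5)
  A0 <- max(sum(y) - n * bg0, 1)
  list(A = A0, tau = tau0, bg = bg0)
}

# Fit one histogram. mode "mono": free amplitude, lifetime, background.
# mode "biexp_fixed": free total amplitude, amplitude fraction f of the
# free component, free tau1, background; tau2 held at tau2_fixed.
.fit_decay <- function(y, settings, mode = c("mono", "biexp_fixed"),
                       tau2_fixed = NULL, objective = c("mle", "wls"),
                       wrap = TRUE, tau_bounds = .TAU_BOUNDS) {
  mode <- match.arg(mode); objective <- match.arg(objective)
  n <- length(y)
  stopifnot(n == settings$n_bins)
  if (mode == "biexp_fixed") {
    if (is.null(tau2_fixed) || !is.numeric(tau2_fixed) || tau2_fixed <= 0)
      stop("`tau2_fixed` (ns, > 0) is required for the bi-exponential fit")
  }
  init <- .init_decay_fit(y, settings, tau_bounds)

  model_fun <- if (mode == "mono") {
    function(p) p[1] * .decay_pattern(p[2], 1, settings, wrap) + p[3]
  } else {
    function(p) p[1] * .decay_pattern(c(p[3], tau2_fixed), c(p[2], 1 - p[2]),
                                      settings, wrap) + p[4]
  }
  resid_fun <- if (objective == "mle") {
    function(p) .deviance_residuals(y, model_fun(p))
  } else {
    w <- 1 / sqrt(pmax(y, 1))
    function(p) w * (model_fun(p) - y)
  }

  if (mode == "mono") {
    par0 <- c(init$A, init$tau, init$bg)
    lower <- c(1e-9, tau_bounds[1], 0); upper <- c(Inf, tau_bounds[2], Inf)
  } else {
    par0 <- c(init$A, 0.7, init$tau, init$bg)
    lower <- c(1e-9, 0, tau_bounds[1], 0); upper <- c(Inf, 1, tau_bounds[2], Inf)
  }
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 150))
  p <- fit$par
  m <- model_fun(p)
  n_par <- length(par0)
  chi2 <- .reduced_chi2(y, m, n_par)
  converged <- fit$info %in% 1:4

  if (mode == "mono") {
    tau1 <- p[2]; tau2 <- p[2]; a1_pct <- 100; mean_flt <- p[2]
    identifiability_flag <- FALSE
  } else {
    tau1 <- p[3]; tau2 <- tau2_fixed; f <- p[2]
    a1_pct <- 100 * f
    mean_flt <- f * tau1 + (1 - f) * tau2
    identifiability_flag <- abs(tau1 - tau2) < 0.05
  }
  list(tau1 = tau1, tau2 = tau2, a1_pct = a1_pct, mean_flt = mean_flt,
       chi2 = chi2, chi2_flag = chi2 > 1.5, converged = converged,
       identifiability_flag = identifiability_flag,
       total_counts = sum(y), background = p[length(p)],
       amplitude = p[1], n_iter = fit$niter, info = fit$info)
}

# ---- public per-pixel fits -------------------------------------------------

#' Fit a single pixel's decay with a mono-exponential model
#'
#' Least-deviance (Poisson maximum-likelihood, default) or
#' Neyman-weighted least-squares fit of the wrap-corrected
#' single-exponential expected-count model with free amplitude, lifetime
#' and constant background. Lifetimes are bounded to `[0.05, 15]` ns.
#' The reduced \eqn{\chi^2} is always reported with Neyman weights
#' `max(count, 1)`, the conventional TCSPC quality statistic.
#'
#' Pixels whose total counts fall below `min_counts` are excluded, not
#' errors: the returned result has `included = FALSE` and `NA`
#' parameters.
#'
#' @param curve A [decay_curve()] with measured counts.
#' @param settings An [acquisition_settings()].
#' @param objective `"mle"` (Poisson deviance, default) or `"wls"`
#'   (Neyman-weighted least squares).
#' @param wrap Apply the incomplete-decay correction in the fitted model
#'   (default `TRUE`).
#' @param min_counts Minimum total photons for a fittable pixel
#'   (default 100).
#' @return An object of class `pixel_fit`: tau1, tau2, a1_pct, mean_flt,
#'   chi2 (+ flag), convergence and bookkeeping fields.
#' @export
fit_pixel_mono <- function(curve, settings, objective = c("mle", "wls"),
                           wrap = TRUE, min_counts = 100) {
  stopifnot(inherits(curve, "decay_curve"))
  y <- curve$counts
  if (sum(y) < min_counts) return(.excluded_pixel(sum(y)))
  out <- .fit_decay(y, settings, "mono", objective = match.arg(objective),
                    wrap = wrap)
  structure(c(out, list(included = TRUE, mode = "mono")), class = "pixel_fit")
}

#' Fit a single pixel's decay with a fixed-slow-component bi-exponential
#'
#' Bi-exponential fit where the slow (free-dye) lifetime \eqn{\tau_2} is
#' held at a previously measured reference value and the fast
#' (quenched) component's lifetime \eqn{\tau_1}, the amplitude fraction
#' and the background are free. Component 1 is by definition the free
#' lifetime — components are never reordered by value, so \eqn{\tau_1}
#' may exceed \eqn{\tau_2}. `a1_pct` is the amplitude fraction
#' \eqn{100\,\alpha_1/(\alpha_1+\alpha_2)} and `mean_flt` the
#' amplitude-weighted lifetime. Fits where \eqn{|\tau_1 - \tau_2| <
#' 0.05} ns are flagged for weak identifiability but not rejected.
#'
#' @inheritParams fit_pixel_mono
#' @param tau2_fixed The fixed slow lifetime in ns (> 0).
#' @return A `pixel_fit` object (see [fit_pixel_mono()]).
#' @export
fit_pixel_biexp_fixed <- function(curve, settings, tau2_fixed,
                                  objective = c("mle", "wls"), wrap = TRUE,
                                  min_counts = 100) {
  stopifnot(inherits(curve, "decay_curve"))
  y <- curve$counts
  if (sum(y) < min_counts) return(.excluded_pixel(sum(y)))
  out <- .fit_decay(y, settings, "biexp_fixed", tau2_fixed = tau2_fixed,
                    objective = match.arg(objective), wrap = wrap)
  structure(c(out, list(included = TRUE, mode = "biexp_fixed")),
            class = "pixel_fit")
}

.excluded_pixel <- function(total) {
  structure(list(tau1 = NA_real_, tau2 = NA_real_, a1_pct = NA_real_,
                 mean_flt = NA_real_, chi2 = NA_real_, chi2_flag = NA,
                 converged = NA, identifiability_flag = NA,
                 total_counts = total, background = NA_real_,
                 amplitude = NA_real_, n_iter = 0L, info = NA_integer_,
                 included = FALSE, mode = NA_character_),
            class = "pixel_fit")
}

#' @export
print.pixel_fit <- function(x, ...) {
  if (!isTRUE(x$included)) {
    cat(sprintf("<pixel_fit> excluded (%g counts below threshold)\n", x$total_counts))
    return(invisible(x))
  }
  cat(sprintf("<pixel_fit> [%s] tau1 = %.3f ns, tau2 = %.3f ns, a1 = %.1f%%, <tau> = %.3f ns, chi2 = %.3f%s\n",
              x$mode, x$tau1, x$tau2, x$a1_pct, x$mean_flt, x$chi2,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

# ---- whole-image fitting ---------------------------------------------------

#' Fit every pixel of a FLIM image
#'
#' Applies [fit_pixel_mono()] or [fit_pixel_biexp_fixed()] over the
#' image mask. Initialisation is deterministic, so the result depends
#' only on the image itself.
#'
#' @param image A [flim_image()].
#' @param mode `"mono"` or `"biexp_fixed"`.
#' @param tau2_fixed Fixed slow lifetime in ns; required when
#'   `mode = "biexp_fixed"`.
#' @inheritParams fit_pixel_mono
#' @return A [tibble::tibble()] with one row per masked pixel: `row`,
#'   `col`, `tau1`, `tau2`, `a1_pct`, `mean_flt`, `chi2`, `chi2_flag`,
#'   `converged`, `identifiability_flag`, `total_counts`, `background`,
#'   `included`.
#' @export
fit_image <- function(image, mode = c("mono", "biexp_fixed"),
                      tau2_fixed = NULL, objective = c("mle", "wls"),
                      wrap = TRUE, min_counts = 100) {
  stopifnot(inherits(image, "flim_image"))
  mode <- match.arg(mode); objective <- match.arg(objective)
  if (mode == "biexp_fixed" && is.null(tau2_fixed))
    stop("`tau2_fixed` is required when mode = \"biexp_fixed\"")
  d <- dim(image$counts)
  mask <- if (is.null(image$mask)) matrix(TRUE, d[1], d[2]) else image$mask
  if (!any(mask)) stop("empty mask: no pixels to fit")
  idx <- which(mask, arr.ind = TRUE)
  n_px <- nrow(idx)
  cols <- list(
    row = idx[, 1], col = idx[, 2],
    tau1 = numeric(n_px), tau2 = numeric(n_px), a1_pct = numeric(n_px),
    mean_flt = numeric(n_px), chi2 = numeric(n_px), chi2_flag = logical(n_px),
    converged = logical(n_px), identifiability_flag = logical(n_px),
    total_counts = numeric(n_px), background = numeric(n_px),
    included = logical(n_px))
  for (k in seq_len(n_px)) {
    y <- image$counts[idx[k, 1], idx[k, 2], ]
    if (sum(y) < min_counts) {
      res <- .excluded_pixel(sum(y))
      res$included <- FALSE
    } else {
      res <- .fit_decay(y, image$settings, mode, tau2_fixed = tau2_fixed,
                        objective = objective, wrap = wrap)
      res$included <- TRUE
    }
    cols$tau1[k] <- res$tau1; cols$tau2[k] <- res$tau2
    cols$a1_pct[k] <- res$a1_pct; cols$mean_flt[k] <- res$mean_flt
    cols$chi2[k] <- res$chi2
    cols$chi2_flag[k] <- isTRUE(res$chi2_flag)
    cols$converged[k] <- isTRUE(res$converged)
    cols$identifiability_flag[k] <- isTRUE(res$identifiability_flag)
    cols$total_counts[k] <- res$total_counts
    cols$background[k] <- res$background
    cols$included[k] <- res$included
  }
  out <- tibble::as_tibble(cols)
  attr(out, "mode") <- mode
  attr(out, "tau2_fixed") <- tau2_fixed
  attr(out, "grid") <- d[1:2]
  out
}

#' Summarise a fitted FLIM image
#'
#' Image-level means and standard deviations of `tau1`, `a1_pct`,
#' `mean_flt` and `chi2` over converged, included pixels, plus a `tau1`
#' histogram.
#'
#' @param results Per-pixel result table from [fit_image()].
#' @param hist_binwidth Width of the `tau1` histogram bins in ns
#'   (default 0.05).
#' @return An object of class `image_summary`: per-quantity `mean` and
#'   `sd`, histogram (`breaks`, `counts`), `n_pixels_included`,
#'   `n_pixels_excluded`.
#' @export
summarize_image <- function(results, hist_binwidth = 0.05) {
  ok <- results$included & results$converged
  if (!any(ok)) stop("empty summary: zero converged pixels")
  sub <- results[ok, , drop = FALSE]
  qty <- c("tau1", "a1_pct", "mean_flt", "chi2")
  means <- vapply(qty, function(q) mean(sub[[q]]), numeric(1))
  sds <- vapply(qty, function(q) stats::sd(sub[[q]]), numeric(1))
  lo <- floor(min(sub$tau1) / hist_binwidth) * hist_binwidth
  hi <- ceiling(max(sub$tau1) / hist_binwidth) * hist_binwidth
  if (hi <= lo) hi <- lo + hist_binwidth
  breaks <- seq(lo, hi, by = hist_binwidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(sub$tau1, breaks = breaks, plot = FALSE)
  structure(
    list(mean = as.list(means), sd = as.list(sds),
         tau1_hist = list(breaks = h$breaks, counts = h$counts),
         n_pixels_included = sum(ok),
         n_pixels_excluded = nrow(results) - sum(ok)),
    class = "image_summary"
  )
}

#' @export
print.image_summary <- function(x, ...) {
  cat("<image_summary>\n")
  cat(sprintf("  tau1     = %.3f +/- %.3f ns\n", x$mean$tau1, x$sd$tau1))
  cat(sprintf("  a1%%      = %.2f +/- %.2f\n", x$mean$a1_pct, x$sd$a1_pct))
  cat(sprintf("  <tau>    = %.3f +/- %.3f ns\n", x$mean$mean_flt, x$sd$mean_flt))
  cat(sprintf("  chi2     = %.3f +/- %.3f\n", x$mean$chi2, x$sd$chi2))
  cat(sprintf("  pixels   = %d included, %d excluded\n",
              x$n_pixels_included, x$n_pixels_excluded))
  invisible(x)
}

#' One-row summary table in the linker-report column order
#'
#' Flattens an [summarize_image()] result to the standard report schema:
#' label, a1% mean/STD, tau1 mean/STD, chi2 mean/STD.
#'
#' @param summary An `image_summary`.
#' @param label Row label (e.g. linker name and area).
#' @return A one-row [tibble::tibble()].
#' @export
summary_row <- function(summary, label) {
  stopifnot(inherits(summary, "image_summary"))
  tibble::tibble(
    label = label,
    a1_pct_mean = summary$mean$a1_pct, a1_pct_sd = summary$sd$a1_pct,
    tau1_mean = summary$mean$tau1, tau1_sd = summary$sd$tau1,
    chi2_mean = summary$mean$chi2, chi2_sd = summary$sd$chi2,
    n_pixels = summary$n_pixels_included)
}

#' Render a fitted FLIM image as a colour map
#'
#' 2-D colour-mapped image of a per-pixel quantity (default the fitted
#' lifetime); excluded or non-converged pixels render as background.
#'
#' @param results Per-pixel result table from [fit_image()].
#' @param value Which quantity to map: `"tau1"` or `"mean_flt"`.
#' @param color_range Optional `c(lo, hi)` ns limits for the colour
#'   scale.
#' @param path Optional png output path; if `NULL`, the ggplot object is
#'   returned.
#' @return The ggplot object, invisibly if written to file.
#' @export
render_flim_image <- function(results, value = c("tau1", "mean_flt"),
                              color_range = NULL, path = NULL) {
  value <- match.arg(value)
  tab <- results
  tab$val <- ifelse(tab$included & tab$converged, tab[[value]], NA_real_)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$col, y = .data$row,
                                         fill = .data$val)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = color_range, na.value = "grey20",
                                  name = paste0(value, " [ns]")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 5, height = 4.5, dpi = 150)
  invisible(p)
}
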