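# Recovery of optical coefficients from measured diffuse-reflectance
# profiles: ordinary least squares on the ln(rho^2 Gamma) line.

#' Fit the diffuse-reflectance attenuation slope
#'
#' Ordinary least-squares line through the linearised samples
#' \eqn{\ln(\rho^2\Gamma)} vs \eqn{\rho}. The estimated effective
#' attenuation coefficient is minus the slope; the intercept estimates
#' \eqn{\ln c_1}. The fit is deliberately unweighted: it reproduces the
#' standard slope calculation, nothing fancier.
#'
#' @param profile A [reflectance_profile()].
#' @param rho_window Optional `c(min, max)` in mm restricting the fitted
#'   separations; default uses the full profile.
#' @return An object of class `dr_fit`: a list with `slope`, `intercept`,
#'   `mu_eff_hat` (= -slope), `r_squared`, `n_used`, `n_excluded`.
#' @export
fit_dr_slope <- function(profile, rho_window = NULL) {
  pts <- log_rho2_transform(profile)
  n_excluded <- attr(pts, "n_excluded")
  if (!is.null(rho_window)) {
    stopifnot(length(rho_window) == 2L, rho_window[1] < rho_window[2])
    pts <- pts[pts$rho >= rho_window[1] & pts$rho <= rho_window[2], , drop = FALSE]
    if (nrow(pts) < 2L)
      stop("insufficient data: fewer than 2 samples inside `rho_window`")
  }
  if (length(unique(pts$rho)) < 2L)
    stop("degenerate profile: all separations identical")
  fit <- stats::lm(y ~ rho, data = pts)
  cf <- stats::coef(fit)
  tss <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         mu_eff_hat = -unname(cf[2]), r_squared = r2,
         n_used = nrow(pts), n_excluded = n_excluded),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit> slope = %.4g mm^-1 (mu_eff = %.4g), R^2 = %.4f, n = %d (%d excluded)\n",
              x$slope, x$mu_eff_hat, x$r_squared, x$n_used, x$n_excluded))
  invisible(x)
}

#' Invert the effective attenuation for the absorption coefficient
#'
#' Given an estimated \eqn{\mu_{eff}} and a known reduced scattering
#' coefficient, returns \eqn{\mu_a = \mu_{eff}^2 / (3 \mu_s')} — the
#' algebraic inverse of [effective_attenuation()].
#'
#' @param mu_eff_hat Estimated effective attenuation, mm^-1, >= 0.
#' @param mu_s_prime_known Known reduced scattering coefficient, mm^-1, > 0.
#' @return Absorption coefficient in mm^-1.
#' @export
invert_absorption <- function(mu_eff_hat, mu_s_prime_known) {
  if (!is.numeric(mu_s_prime_known) || mu_s_prime_known <= 0)
    stop("`mu_s_prime_known` must be > 0")
  if (!is.numeric(mu_eff_hat) || any(mu_eff_hat < 0))
    stop("`mu_eff_hat` must be >= 0")
  mu_eff_hat^2 / (3 * mu_s_prime_known)
}

#' Tabulate and compare attenuation slopes across phantoms
#'
#' Collects per-phantom slope fits into one table, mirroring a
#' bar-plot-of-slopes comparison across a concentration ladder. Profiles
#' whose fit failed (too few samples above the noise floor — the
#' detection-limit regime of strongly absorbing phantoms) appear as rows
#' flagged `detected = FALSE` rather than aborting the analysis.
#'
#' @param fits A named list whose elements are `dr_fit` objects or
#'   `try`-style failures (anything not a `dr_fit` counts as a failed,
#'   undetected measurement). Names are the phantom labels.
#' @param sort_by Column to sort by: `"label"` (default), `"slope"`, or
#'   `"mu_eff_hat"`.
#' @return A [tibble::tibble()] with columns `label`, `slope`,
#'   `mu_eff_hat`, `r_squared`, `n_used`, `n_excluded`, `detected`.
#' @export
compare_slopes <- function(fits, sort_by = c("label", "slope", "mu_eff_hat")) {
  sort_by <- match.arg(sort_by)
  if (length(fits) == 0L) stop("`fits` must be a non-empty list")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("`fits` must be a named list (names are phantom labels)")
  rows <- lapply(names(fits), function(lbl) {
    f <- fits[[lbl]]
    if (inherits(f, "dr_fit")) {
      tibble::tibble(label = lbl, slope = f$slope, mu_eff_hat = f$mu_eff_hat,
                     r_squared = f$r_squared, n_used = f$n_used,
                     n_excluded = f$n_excluded, detected = TRUE)
    } else {
      tibble::tibble(label = lbl, slope = NA_real_, mu_eff_hat = NA_real_,
                     r_squared = NA_real_, n_used = 0L, n_excluded = NA_integer_,
                     detected = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (sort_by != "label") out <- out[order(out[[sort_by]]), , drop = FALSE]
  out
}

#' Fit a reflectance profile, reporting failure instead of erroring
#'
#' Wrapper around [fit_dr_slope()] that converts the insufficient-data
#' error (all light absorbed, detection-limit regime) into a value
#' [compare_slopes()] understands.
#'
#' @inheritParams fit_dr_slope
#' @return A `dr_fit`, or a `dr_fit_failure` object carrying the message.
#' @export
try_fit_dr_slope <- function(profile, rho_window = NULL) {
  tryCatch(fit_dr_slope(profile, rho_window),
           error = function(e) structure(list(message = conditionMessage(e)),
                                         class = "dr_fit_failure"))
}

#' Bar plot of attenuation slopes across phantoms
#'
#' Renders the [compare_slopes()] table as a bar chart of |slope| per
#' phantom label, optionally grouped/filled by a wavelength column the
#' caller adds. Undetected phantoms are drawn as empty slots.
#'
#' @param slope_table Output of [compare_slopes()], optionally with an
#'   extra `wavelength` column for grouping.
#' @param path Optional output image path (png); if `NULL` the ggplot
#'   object is returned without writing.
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_dr_slopes <- function(slope_table, path = NULL) {
  tab <- slope_table
  tab$magnitude <- abs(tab$slope)
  has_wl <- "wavelength" %in% names(tab)
  if (has_wl) tab$wavelength <- factor(tab$wavelength)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$magnitude)) +
    (if (has_wl)
      ggplot2::geom_col(ggplot2::aes(fill = .data$wavelength),
                        position = ggplot2::position_dodge())
     else ggplot2::geom_col()) +
    ggplot2::labs(x = NULL, y = "|slope| of ln(rho^2 * Gamma)  [mm^-1]",
                  fill = "wavelength [nm]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
  invisible(p)
}
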