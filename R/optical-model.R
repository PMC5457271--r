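# Diffusion-reflectance forward model and optical-coefficient algebra.
#
# Units are fixed package-wide: all lengths in mm, all attenuation
# coefficients in mm^-1, lifetimes in ns. This is the single place where
# the unit convention is stated and enforced.

#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient \eqn{\mu_a} and the reduced scattering
#' coefficient \eqn{\mu_s'} of a turbid medium (phantom, tissue), both in
#' mm\eqn{^{-1}}, with an optional wavelength tag. The derived effective
#' attenuation coefficient \eqn{\mu_{eff} = \sqrt{3 \mu_a \mu_s'}} is
#' computed on demand by [effective_attenuation()], never stored.
#'
#' @param mu_a Absorption coefficient, mm^-1, must be >= 0.
#' @param mu_s_prime Reduced scattering coefficient, mm^-1, must be > 0.
#' @param wavelength Optional wavelength in nm (metadata only).
#' @return An object of class `optical_properties`.
#' @examples
#' op <- optical_properties(mu_a = 0.01, mu_s_prime = 1.0, wavelength = 650)
#' effective_attenuation(op)
#' @export
optical_properties <- function(mu_a, mu_s_prime, wavelength = NA_real_) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L)
  if (is.na(mu_a) || mu_a < 0)
    stop("`mu_a` must be a non-negative absorption coefficient (mm^-1)")
  if (is.na(mu_s_prime) || mu_s_prime <= 0)
    stop("`mu_s_prime` must be a positive reduced scattering coefficient (mm^-1)")
  structure(
    list(mu_a = as.numeric(mu_a), mu_s_prime = as.numeric(mu_s_prime),
         wavelength = as.numeric(wavelength)),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mu_a = %g mm^-1, mu_s' = %g mm^-1, mu_eff = %g mm^-1",
              x$mu_a, x$mu_s_prime, effective_attenuation(x)))
  if (!is.na(x$wavelength)) cat(sprintf(" @ %g nm", x$wavelength))
  cat("\n")
  invisible(x)
}

#' Effective attenuation coefficient
#'
#' Computes \eqn{\mu_{eff} = \sqrt{3 \mu_a \mu_s'}}, the decay constant of
#' diffuse light far from a pencil-beam source in the diffusion
#' approximation. Zero if and only if the medium does not absorb.
#'
#' @param optical An [optical_properties()] object, or a plain list with
#'   `mu_a` and `mu_s_prime` fields.
#' @return Effective attenuation coefficient in mm^-1.
#' @export
effective_attenuation <- function(optical) {
  if (!inherits(optical, "optical_properties"))
    optical <- optical_properties(optical$mu_a, optical$mu_s_prime)
  sqrt(3 * optical$mu_a * optical$mu_s_prime)
}

#' Diffuse reflectance profile
#'
#' An ordered set of (source-detector separation, reflected intensity)
#' samples from one diffusion-reflectance scan of a turbid surface.
#'
#' @param rho Source-detector separations in mm; strictly increasing, all > 0.
#' @param gamma Reflected intensities (photon counts or arbitrary units),
#'   non-negative, same length as `rho`.
#' @param noise_floor Intensity below which a sample counts as undetected
#'   (same units as `gamma`); `NA` disables the floor.
#' @return An object of class `reflectance_profile`.
#' @export
reflectance_profile <- function(rho, gamma, noise_floor = NA_real_) {
  rho <- as.numeric(rho); gamma <- as.numeric(gamma)
  if (length(rho) != length(gamma))
    stop("`rho` and `gamma` must have the same length")
  if (length(rho) < 2L)
    stop("a reflectance profile needs at least 2 samples")
  if (any(rho <= 0) || any(diff(rho) <= 0))
    stop("`rho` must be strictly increasing and positive (mm)")
  if (any(gamma < 0))
    stop("`gamma` intensities must be non-negative")
  structure(list(rho = rho, gamma = gamma, noise_floor = as.numeric(noise_floor)),
            class = "reflectance_profile")
}

#' @export
print.reflectance_profile <- function(x, ...) {
  cat(sprintf("<reflectance_profile> %d samples, rho %g-%g mm", length(x$rho),
              min(x$rho), max(x$rho)))
  if (!is.na(x$noise_floor)) cat(sprintf(", noise floor %g", x$noise_floor))
  cat("\n")
  invisible(x)
}

#' Forward diffusion-reflectance model
#'
#' Evaluates the semi-infinite-medium diffuse reflectance
#' \deqn{\Gamma(\rho) = \frac{c_1}{\rho^2} e^{-\mu_{eff}\,\rho}}
#' at the requested separations. The intercept constant \eqn{c_2} of the
#' linearised form is always `log(c1)`, computed on demand.
#'
#' @param c1 Positive amplitude constant (arbitrary intensity units).
#' @param optical An [optical_properties()] object.
#' @param rho Source-detector separations in mm, all > 0 (the model
#'   diverges at the origin).
#' @return A [reflectance_profile()] with the model intensities.
#' @export
forward_reflectance <- function(c1, optical, rho) {
  if (!is.numeric(c1) || length(c1) != 1L || c1 <= 0)
    stop("`c1` must be a positive scalar")
  rho <- as.numeric(rho)
  if (any(rho <= 0)) stop("all `rho` must be > 0 (model diverges at the origin)")
  mu <- effective_attenuation(optical)
  reflectance_profile(rho, c1 / rho^2 * exp(-mu * rho))
}

#' Linearising transform of a reflectance profile
#'
#' Maps each valid sample to \eqn{(\rho,\; y = \ln(\rho^2 \Gamma(\rho)))}.
#' On model-conforming data y is linear in rho with slope
#' \eqn{-\mu_{eff}} and intercept \eqn{\ln c_1}. Samples with
#' \eqn{\Gamma \le 0} or at/below the profile's noise floor are dropped
#' (not clipped: clipping would bias the slope) and their count reported.
#'
#' @param profile A [reflectance_profile()].
#' @return A data frame with columns `rho` and `y`, plus attribute
#'   `n_excluded` giving the number of dropped samples.
#' @export
log_rho2_transform <- function(profile) {
  stopifnot(inherits(profile, "reflectance_profile"))
  floor_ <- if (is.na(profile$noise_floor)) 0 else profile$noise_floor
  keep <- profile$gamma > 0 & profile$gamma > floor_
  n_excluded <- sum(!keep)
  if (sum(keep) < 2L)
    stop("insufficient data: fewer than 2 samples above the noise floor (",
         n_excluded, " excluded)")
  out <- data.frame(rho = profile$rho[keep],
                    y = log(profile$rho[keep]^2 * profile$gamma[keep]))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read / write a reflectance profile as delimited text
#'
#' Two-column tab-separated text with header `rho_mm`, `intensity`;
#' lines starting with `#` are comments. A `# noise_floor:` comment line
#' round-trips the detection floor.
#'
#' @param profile A [reflectance_profile()].
#' @param path File path.
#' @return `write_reflectance_profile()` returns `path` invisibly;
#'   `read_reflectance_profile()` returns a [reflectance_profile()].
#' @export
write_reflectance_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reflectance_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(profile$noise_floor))
    writeLines(sprintf("# noise_floor: %.17g", profile$noise_floor), con)
  writeLines("rho_mm\tintensity", con)
  writeLines(sprintf("%.17g\t%.17g", profile$rho, profile$gamma), con)
  invisible(path)
}

#' @rdname write_reflectance_profile
#' @export
read_reflectance_profile <- function(path) {
  lines <- readLines(path)
  floor_ <- NA_real_
  fl <- grep("^#\\s*noise_floor:", lines, value = TRUE)
  if (length(fl)) floor_ <- as.numeric(sub("^#\\s*noise_floor:\\s*", "", fl[1]))
  tab <- utils::read.delim(text = lines, comment.char = "#")
  reflectance_profile(tab$rho_mm, tab$intensity, noise_floor = floor_)
}
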