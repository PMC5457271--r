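# Sum-of-exponentials fluorescence decay under periodic pulsed excitation:
# model evaluation, amplitude-weighted mean lifetime, and expected TCSPC
# bin counts with incomplete-decay (wrap-around) correction.

#' Sum-of-exponentials decay model
#'
#' Describes a fluorescence decay \eqn{I(t) = \sum_i \alpha_i e^{-t/\tau_i}}
#' by its component amplitudes and lifetimes. Amplitudes are stored as
#' given; normalised amplitude fractions are computed where needed, so a
#' model is invariant to rescaling all amplitudes by a common factor.
#'
#' @param amplitudes Component amplitudes \eqn{\alpha_i \ge 0}, at least
#'   one positive (dimensionless).
#' @param lifetimes Component lifetimes \eqn{\tau_i} in ns, all > 0, same
#'   length as `amplitudes`.
#' @param fixed Logical vector flagging lifetimes held constant during
#'   fitting (metadata; default all free).
#' @return An object of class `decay_model`.
#' @examples
#' m <- decay_model(c(0.8, 0.2), c(1.15, 3.92), fixed = c(FALSE, TRUE))
#' amplitude_weighted_flt(m)
#' @export
decay_model <- function(amplitudes, lifetimes, fixed = NULL) {
  amplitudes <- as.numeric(amplitudes); lifetimes <- as.numeric(lifetimes)
  if (length(amplitudes) != length(lifetimes) || length(amplitudes) < 1L)
    stop("`amplitudes` and `lifetimes` must have equal length >= 1")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (all(amplitudes == 0)) stop("at least one amplitude must be > 0")
  if (any(lifetimes <= 0)) stop("all lifetimes must be > 0 (ns)")
  if (is.null(fixed)) fixed <- rep(FALSE, length(lifetimes))
  stopifnot(is.logical(fixed), length(fixed) == length(lifetimes))
  structure(list(amplitudes = amplitudes, lifetimes = lifetimes, fixed = fixed),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  fr <- x$amplitudes / sum(x$amplitudes)
  cat("<decay_model>\n")
  for (i in seq_along(fr))
    cat(sprintf("  component %d: tau = %g ns, amplitude fraction = %.4f%s\n",
                i, x$lifetimes[i], fr[i], if (x$fixed[i]) " [fixed]" else ""))
  cat(sprintf("  amplitude-weighted <tau> = %.4g ns\n", amplitude_weighted_flt(x)))
  invisible(x)
}

#' Evaluate the decay intensity
#'
#' \eqn{I(t) = \sum_i \alpha_i e^{-t/\tau_i}} for `t >= 0` (ns).
#'
#' @param model A [decay_model()].
#' @param t Times in ns, all >= 0 (vectorised).
#' @return Intensities (arbitrary units), same length as `t`.
#' @export
decay_intensity <- function(model, t) {
  stopifnot(inherits(model, "decay_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be >= 0")
  vapply(t, function(ti) sum(model$amplitudes * exp(-ti / model$lifetimes)),
         numeric(1))
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' \eqn{\langle\tau\rangle = \sum_i f_i \tau_i} with amplitude fractions
#' \eqn{f_i = \alpha_i / \sum_j \alpha_j}. Amplitudes are normalised
#' before weighting so the result is well defined for unnormalised fits
#' and always lies in `[min(tau), max(tau)]`.
#'
#' @param model A [decay_model()].
#' @return Mean lifetime in ns.
#' @export
amplitude_weighted_flt <- function(model) {
  stopifnot(inherits(model, "decay_model"))
  fr <- model$amplitudes / sum(model$amplitudes)
  sum(fr * model$lifetimes)
}

#' TCSPC acquisition settings
#'
#' Pulse repetition rate, histogram binning, instrument response width
#' and target photon budget of a time-correlated single-photon-counting
#' acquisition. The excitation period is `1000 / rep_rate_mhz` ns.
#'
#' @param rep_rate_mhz Pulse repetition frequency in MHz (> 0; typical
#'   scanner settings are 20, 50 or 80).
#' @param n_bins Number of time bins per period (integer >= 4; default
#'   256, a typical TCSPC histogram resolution).
#' @param irf_fwhm_ps Full width at half maximum of the Gaussian
#'   instrument response, ps, >= 0; 0 means ideal delta excitation.
#'   Must be much shorter than the period.
#' @param counts_target Expected total photons per pixel (> 0).
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(rep_rate_mhz = 50, n_bins = 256,
                                 irf_fwhm_ps = 0, counts_target = 1e4) {
  if (!is.numeric(rep_rate_mhz) || rep_rate_mhz <= 0)
    stop("`rep_rate_mhz` must be > 0")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 4L) stop("`n_bins` must be an integer >= 4")
  if (!is.numeric(irf_fwhm_ps) || irf_fwhm_ps < 0)
    stop("`irf_fwhm_ps` must be >= 0")
  period_ns <- 1000 / rep_rate_mhz
  if (irf_fwhm_ps / 1000 > period_ns / 10)
    stop("`irf_fwhm_ps` must be much shorter than the excitation period")
  if (!is.numeric(counts_target) || counts_target <= 0)
    stop("`counts_target` must be > 0")
  structure(
    list(rep_rate_mhz = rep_rate_mhz, n_bins = n_bins,
         irf_fwhm_ps = irf_fwhm_ps, counts_target = counts_target,
         period_ns = period_ns, bin_width_ns = period_ns / n_bins),
    class = "acquisition_settings"
  )
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat(sprintf(
    "<acquisition_settings> %g MHz (period %g ns), %d bins of %g ns, IRF FWHM %g ps, %g counts/pixel\n",
    x$rep_rate_mhz, x$period_ns, x$n_bins, x$bin_width_ns, x$irf_fwhm_ps,
    x$counts_target))
  invisible(x)
}

#' A binned decay curve
#'
#' One pixel's photon-arrival histogram over a single excitation period:
#' bin-centre times (ns) plus measured (integer) or expected (real)
#' counts.
#'
#' @param bin_times Bin-centre times in ns, strictly increasing within
#'   `[0, period)`.
#' @param counts Non-negative counts per bin, same length.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(bin_times, counts) {
  bin_times <- as.numeric(bin_times); counts <- as.numeric(counts)
  if (length(bin_times) != length(counts))
    stop("`bin_times` and `counts` must have the same length")
  if (any(diff(bin_times) <= 0)) stop("`bin_times` must be strictly increasing")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  structure(list(bin_times = bin_times, counts = counts), class = "decay_curve")
}

# Per-bin integral of the periodised decay for one component with unit
# amplitude: integral over [t0,t1) of exp(-t/tau)/(1 - exp(-T/tau)) dt.
# The geometric-series wrap factor accounts for photons excited by all
# earlier pulses (incomplete decay).
.bin_integral <- function(tau, edges, period_ns, wrap = TRUE) {
  lo <- edges[-length(edges)]; hi <- edges[-1]
  base <- tau * (exp(-lo / tau) - exp(-hi / tau))
  if (wrap) base / (1 - exp(-period_ns / tau)) else base
}

# Circular Gaussian smearing of a per-bin pattern (IRF); conserves totals.
.irf_smear <- function(pattern, settings, t0_ns = 0) {
  sigma_ns <- settings$irf_fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
  if (sigma_ns <= 0 && t0_ns == 0) return(pattern)
  n <- length(pattern)
  shift_bins <- t0_ns / settings$bin_width_ns
  # kernel indexed by circular delay o = 0..n-1, signed as o or o - n
  o <- 0:(n - 1)
  signed <- ifelse(o < n / 2, o, o - n)
  kern <- if (sigma_ns > 0) {
    stats::dnorm(signed - shift_bins, sd = sigma_ns / settings$bin_width_ns)
  } else {
    out <- numeric(n); out[which.min(abs(signed - shift_bins))] <- 1; out
  }
  kern <- kern / sum(kern)
  # circular convolution via FFT; wrap-around is physical under periodic excitation
  conv <- Re(stats::fft(stats::fft(pattern) * stats::fft(kern), inverse = TRUE)) / n
  pmax(conv, 0)
}

# Normalised per-bin pattern (sums to 1) for a decay model under given
# acquisition settings. Workhorse shared by simulation and fitting.
.decay_pattern <- function(lifetimes, fractions, settings, wrap = TRUE,
                           irf_t0_ns = 0) {
  edges <- seq(0, settings$period_ns, length.out = settings$n_bins + 1L)
  contrib <- vapply(seq_along(lifetimes),
                    function(i) fractions[i] *
                      .bin_integral(lifetimes[i], edges, settings$period_ns, wrap),
                    numeric(settings$n_bins))
  p <- if (is.matrix(contrib)) rowSums(contrib) else contrib
  p <- .irf_smear(p, settings, irf_t0_ns)
  p / sum(p)
}

#' Expected TCSPC bin counts for a decay model
#'
#' Integrates the periodised decay over each time bin. Under pulsed
#' excitation with period \eqn{T}, photons from all previous pulses pile
#' into the current period; per component the geometric series closes to
#' \eqn{e^{-t/\tau} / (1 - e^{-T/\tau})} (incomplete-decay wrap
#' correction, on by default). If `irf_fwhm_ps > 0` the pattern is
#' convolved (circularly) with a Gaussian instrument response. The
#' result is scaled so the bins sum exactly to `counts_target`.
#'
#' @param model A [decay_model()].
#' @param settings An [acquisition_settings()].
#' @param wrap Apply the incomplete-decay correction (default `TRUE`).
#' @param irf_t0_ns Centre of the Gaussian IRF in ns (default 0).
#' @return A [decay_curve()] with real-valued expected counts.
#' @export
expected_bin_counts <- function(model, settings, wrap = TRUE, irf_t0_ns = 0) {
  stopifnot(inherits(model, "decay_model"),
            inherits(settings, "acquisition_settings"))
  fr <- model$amplitudes / sum(model$amplitudes)
  p <- .decay_pattern(model$lifetimes, fr, settings, wrap, irf_t0_ns)
  edges <- seq(0, settings$period_ns, length.out = settings$n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  decay_curve(mids, settings$counts_target * p)
}

#' Read / write a decay curve as delimited text
#'
#' Two-column tab-separated text with header `time_ns`, `counts`.
#'
#' @param curve A [decay_curve()].
#' @param path File path.
#' @return `write_decay_curve()` returns `path` invisibly;
#'   `read_decay_curve()` returns a [decay_curve()].
#' @export
write_decay_curve <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  utils::write.table(
    data.frame(time_ns = curve$bin_times, counts = curve$counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay_curve
#' @export
read_decay_curve <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  decay_curve(tab$time_ns, tab$counts)
}
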