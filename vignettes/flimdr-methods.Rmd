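---
title: "Models and methods in flimdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in flimdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimdr)
```

`flimdr` analyses two complementary optical measurements of tissue-like
phantoms carrying fluorescent nano-probes: diffuse reflectance (DR), which
senses the bulk absorption and scattering of the medium, and fluorescence
lifetime imaging (FLIM), which senses the nanoscale environment of the
fluorophore — in particular the lifetime shortening induced by a nearby
gold nanorod. This vignette describes the models, the numerical choices
behind the fits, and what the synthetic-data generator does and does not
emulate.

## The diffuse-reflectance model

For a pencil beam entering a semi-infinite turbid medium, the diffusion
approximation gives the reflected intensity at source–detector separation
$\rho$ as

$$\Gamma(\rho) = \frac{c_1}{\rho^2}\, e^{-\mu_{\mathrm{eff}}\rho},
\qquad \mu_{\mathrm{eff}} = \sqrt{3\,\mu_a\,\mu_s'},$$

with $\mu_a$ the absorption and $\mu_s'$ the reduced scattering
coefficient. All lengths in the package are millimetres and all
coefficients mm$^{-1}$ — the natural scale for separations of a few mm.
Taking logs linearises the model:

$$\ln\!\big(\rho^2\,\Gamma(\rho)\big) = \ln c_1 - \mu_{\mathrm{eff}}\,\rho,$$

so an ordinary least-squares line through the transformed samples
estimates $\mu_{\mathrm{eff}}$ as minus the slope. We deliberately fit an
*unweighted* line: the quantity practitioners compare across phantoms is
this plain slope, and re-weighting would change what is being reported.
Given one coefficient from an independent measurement, the other follows
algebraically (`invert_absorption()`).

Samples at or below the detection floor are **dropped, never clipped** —
clipping a censored intensity to the floor biases the slope downward. When
fewer than two samples survive, the fit reports an insufficient-data
failure; `compare_slopes()` carries such phantoms as "not detected" rows
so a concentration-ladder analysis continues without them. This mirrors
what strongly absorbing phantoms actually do to a DR instrument: past a
concentration limit, essentially all photons are absorbed and the profile
disappears into the dark counts.

There is no windowing by default; `rho_window` exists because real rigs
sometimes exclude the shortest separations where the diffusion
approximation is weakest, but any sub-window of noiseless model data gives
the identical slope, which the tests verify.

## The decay model and the amplitude-weighted lifetime

Fluorescence decays are modelled as sums of exponentials,

$$I(t) = \sum_i \alpha_i\, e^{-t/\tau_i},$$

and summarised by the amplitude-weighted mean lifetime
$\langle\tau\rangle = \sum_i f_i \tau_i$ with $f_i = \alpha_i / \sum_j
\alpha_j$. Amplitudes are normalised *before* weighting so that
$\langle\tau\rangle$ is well defined for unnormalised fit outputs and is
invariant to rescaling all amplitudes by a common factor. The reported
`a1_pct` is the **amplitude fraction** $100\,\alpha_1/(\alpha_1+\alpha_2)$,
not the intensity fraction $\alpha_1\tau_1/\sum_j \alpha_j\tau_j$; the
amplitude convention is the one under which the percentage and
$\langle\tau\rangle$ are mutually consistent.

### Binned expected counts under periodic excitation

A TCSPC histogram records arrivals within one excitation period
$T = 1000/\text{rep rate (MHz)}$ ns. When $\tau$ is not much smaller than
$T$, photons excited by *earlier* pulses still arrive in the current
period; summing the pulse train gives the closed form

$$I_{\mathrm{wrapped}}(t) = \sum_{k \ge 0} e^{-(t + kT)/\tau}
 = \frac{e^{-t/\tau}}{1 - e^{-T/\tau}}.$$

At 50 MHz and $\tau = 3.92$ ns the pile-up factor is
$1/(1-e^{-20/3.92}) \approx 1.0061$ — per component a pure scale, but for
a mixture the components carry *different* factors, so the incomplete-decay
correction genuinely changes the fitted shape. It is always on in the
simulator and on by default in fitting. Expected counts integrate this
wrapped decay exactly over each bin (no midpoint approximation) and are
normalised so the bins sum to the photon budget. The tests check the
pattern against a brute-force pulse-train/quadrature oracle.

Defaults: 256 bins per period (a typical TCSPC histogram width), and a
Gaussian instrument response of configurable FWHM applied by circular
convolution (circularity is physical under periodic excitation). The
default IRF width is 0: excitation pulses of tens of ps are one to two
orders of magnitude shorter than the shortest lifetime of interest
(~0.35 ns), so the delta approximation changes fitted lifetimes by far
less than the photon noise while keeping the model identifiable.

## Per-pixel fitting

Two models are offered, matching the standard free-dye / conjugate
protocol:

* **mono**: free amplitude, lifetime, constant background — for free-dye
  samples;
* **biexp_fixed**: free total amplitude, amplitude fraction, fast
  lifetime, background, with the slow lifetime **fixed** at the free-dye
  reference (3.92 ns for solutions, 3.74 ns for phantoms in the bundled
  benchmarks). Component 1 is *by definition* the free lifetime;
  components are never reordered by value, so $\tau_1$ may legitimately
  exceed $\tau_2$.

### Objective function

The default objective is **Poisson maximum likelihood**, implemented as
signed square-root deviance residuals passed to a Levenberg–Marquardt
minimiser, so the same bounded-LM machinery serves both objectives.
Neyman-weighted least squares (weights $1/\max(y,1)$) is available via
`objective = "wls"`.

MLE is the default for a quantitative reason. At realistic per-pixel
budgets ($10^4$ photons over 256 bins) the late-decay bins hold only a few
counts each; Neyman weighting over-weights downward count fluctuations and
biases mono-exponential lifetimes low by about 0.15 ns at
$\tau = 3.92$ ns — several times the per-pixel statistical scatter, and a
bias that does not average away over an image. The Poisson deviance
objective reduces this to ~0.01 ns. The reduced $\chi^2$ reported with
every fit nevertheless uses the conventional Neyman form
$\sum (y-m)^2/\max(y,1)/(n-p)$, because that is the fit-quality statistic
practitioners expect to read; values above 1.5 are flagged.

### Initialisation, bounds, degeneracies

Fits are deterministically initialised — no random restarts, so a fitted
image is a pure function of its data: the background starts at the mean of
the last 5% of bins, the lifetime at the log-linear slope of the first
decade of background-subtracted counts, and the amplitude fraction at 0.7.
Lifetimes are bounded to $[0.05, 15]$ ns (the typical 0.1–10 ns FLT range,
padded so genuine values never sit on a bound). A constant background term
is always present even though the pure decay model omits it — real TCSPC
has dark counts — and the simulator's default background of zero keeps the
idealised model exactly recoverable.

Two degeneracies are reported rather than hidden. When the true fast
fraction is small or $\tau_1 \approx \tau_2$, the likelihood has a flat
ridge: amplitude can trade against lifetime almost freely. Fits whose
$|\tau_1-\tau_2| < 0.05$ ns carry an identifiability flag. Pixels with
fewer than 100 total photons are excluded from fitting entirely (a
bi-exponential fit on fewer counts is numerology), and exclusion is a
reported state, not an error.

### Aggregation

`summarize_image()` averages $\tau_1$, `a1_pct`, $\langle\tau\rangle$ and
$\chi^2$ over converged, included pixels and builds a $\tau_1$ histogram
(default 0.05-ns bins) — the per-image schema used in linker-comparison
reports, which `summary_row()` flattens to the standard column order.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be validated
by parameter recovery with no external data. It emulates:

* **Photon statistics**: independent Poisson counts per time bin and per
  DR sample — correct for TCSPC and photodiode counting.
* **Incomplete decay**: via the wrapped expected pattern above.
* **Spatial concentration heterogeneity**: phantoms solidify unevenly,
  leaving areas of higher and lower probe concentration. This is emulated
  as a per-pixel intensity multiplier: white Gaussian noise smoothed by
  circular FFT convolution with a Gaussian kernel (correlation length 4
  pixels by default), standardised, then exponentiated to a log-normal
  field with mean 1 and configurable CV. Smoothing is circular
  deliberately: a stationary field keeps the same marginal variance at
  every pixel, so the configured CV is actually realised (edge-padded
  smoothing does not, and distorts the field's tail behaviour after
  exponentiation). Log-normality reflects that concentration gradients
  act multiplicatively and smoothly, not blockwise.
* **DR detection limits**: profiles are scaled to an expected photon
  count at the nearest separation, Poisson-sampled, and carry a
  dark-count floor, so the high-absorption failure mode arises naturally.

Default DR separations are 1–6 mm in 0.25-mm steps — the diffusive regime
for a fibre-based rig. Baseline optics are Intralipid-like
($\mu_s' = 1.0$ mm$^{-1}$) with ink-dominated absorption
(0.005 mm$^{-1}$) plus a per-(mg/mL Au) increment larger at 650 nm than
780 nm, reflecting the nanorods' stronger absorption at 650 nm. **These
optical coefficients are literature-plausible placeholders, not measured
values**, and everything is configurable.

What the generator does *not* emulate: instrument afterpulsing and dead
time, measured (non-Gaussian) IRFs, scan-optics blur, fluorophore
photobleaching, and any electrodynamic model of the lifetime-shortening
mechanism itself — ground-truth lifetimes are inputs, not predictions.
Passing recovery tests therefore demonstrates that the *analysis* is
correct and unbiased under ideal counting statistics, not that any
particular physical probe behaves as modelled.

## Benchmarks and problem sizes

The bundled reference tables (`reference_lifetimes()`,
`gnr_solution_table()`, `gnr_phantom_table()`) provide measured anchor
values: free fluorescein at 3.92 ± 0.04 ns in solution and 3.74 ± 0.06 ns
in a phantom, and per-linker conjugate rows ($\tau_1$, a1%, $\chi^2$, with
pixel STDs). The acceptance benchmark (`scripts/acceptance.R` and the
full-scale test file) simulates 64×64-pixel images at 50 MHz, 256 bins and
~$10^4$ photons per pixel — the full measurement scale — and requires the
recovered image means to land within twice the reference pixel STD of the
ground truth. Unit tests use smaller grids (4×4 to 16×16) and fewer bins,
chosen so the whole suite exercises every code path at interactive speed;
grid size only changes the standard error of image means, not the
per-pixel estimator being tested.

## Known limitations

* The bi-exponential model is limited to two components with one fixed;
  no global (image-wide) fitting, no phasor analysis, no measured-IRF
  deconvolution.
* $\chi^2$ is reported, and flagged above 1.5, but the package does not
  reinterpret elevated $\chi^2$ — on real data it may reflect IRF
  mismatch, afterpulsing or heterogeneity within a pixel, none of which
  the fit can distinguish.
* A single DR profile cannot yield both $\mu_a$ and $\mu_s'$ — the
  inversion is deliberately one-coefficient-given-the-other.
* The DR slope comparison is unitless-relative: absolute slopes depend on
  the (placeholder) optics configuration.
```{r}
sessionInfo()
```
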