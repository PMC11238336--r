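---
title: "Methods: fractional Kelvin-Voigt fitting, scaling analysis and pore morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional Kelvin-Voigt fitting, scaling analysis and pore morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracRheo)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the tunable parameters with their defaults
and rationale, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open.

## The fractional Kelvin-Voigt model

Soft biological hydrogels such as mucin gels relax over a broad spectrum
of time scales; their oscillatory spectra cannot be captured by a single
relaxation time. The fractional Kelvin-Voigt model (FKVM) replaces the
dashpot of the classical Kelvin-Voigt element with a *spring-pot*, a
fractional element whose constitutive law interpolates between a spring
(order $\alpha = 0$) and a dashpot ($\alpha = 1$). A spring of modulus
$G$ (Pa) in parallel with a spring-pot of quasi-property $\eta_\alpha$
(Pa s$^\alpha$) has the complex modulus

$$G^*(\omega) = G + \eta_\alpha (i\omega)^\alpha,$$

taken on the principal branch, so that

$$G'(\omega) = G + \eta_\alpha \omega^\alpha \cos(\pi\alpha/2), \qquad
  G''(\omega) = \eta_\alpha \omega^\alpha \sin(\pi\alpha/2).$$

The implementation commits to this closed form and then *asserts* its
defining limits in the test suite rather than assuming them: the
low-frequency plateau $G'(\omega \to 0) \to G$, the high-frequency
power law with log-log slope $\alpha$ in both moduli, the loss-tangent
limit $G''/G' \to \tan(\pi\alpha/2)$, and the exact degeneracies at
$\alpha = 0$ (two parallel springs, $G'' \equiv 0$) and $\alpha = 1$
(classical Kelvin-Voigt, $G' = G$, $G'' = \eta_\alpha\omega$). The
forward model admits the endpoints $\alpha \in \{0, 1\}$ so those limits
can be tested; the fit bounds exclude them (below).

Derived quantities use the standard definitions $\tan\delta = G''/G'$
(reported in degrees, 0 purely elastic, 90 purely viscous, 45 at the
elastic/viscous boundary) and $\eta^* = |G^*|/\omega$ (Pa s).

## Fitting procedure

Both moduli are fitted **simultaneously**: the residual vector stacks

$$r = \big[\ln(G'_\mathrm{model}/G'_\mathrm{data}),\;
           \ln(G''_\mathrm{model}/G''_\mathrm{data})\big]$$

and the minimised quantity is $\|r\|^2$. The log form is what makes
simultaneous fitting meaningful for moduli spanning decades: every data
point contributes on the same relative scale. A plain-residual objective
would be dominated by the highest-frequency points. A relative-residual
alternative ($(\mathrm{model}-\mathrm{data})/\mathrm{data}$) is available
behind `objective = "relative"` for sensitivity checks; on well-behaved
data the two agree closely in $\alpha$.

Tunable parameters of `fitFKVM()`:

* `cutoff` (rad/s, default **50**). Points at or above the cutoff are
  excluded from the fit entirely, never down-weighted: high-frequency
  oscillatory data on weak gels are contaminated by sample and
  instrument inertia, and a contaminated point carries no usable
  information about the material. The default corresponds to 7.96 Hz.
  `FitResult` reports `nUsed`/`nExcluded` (counting both moduli) so the
  bookkeeping is visible.
* `bounds`: $G \in [0,\infty)$, $\eta_\alpha \in (0,\infty)$,
  $\alpha \in (0.01, 0.99)$ by default. The interior $\alpha$ box keeps
  the optimiser away from the degenerate endpoints where the model loses
  identifiability ($\alpha = 0$ makes $G$ and $\eta_\alpha$ collinear).
* `nRestarts` (default 5) and `seed`. Optimisation runs in transformed
  coordinates $(\ln G, \ln\eta_\alpha, \mathrm{logit}\,\alpha)$ so the
  box constraints are smooth, via bounded Levenberg-Marquardt
  (`minpack.lm::nls.lm`). The first start is asymptote-based:
  $\alpha_0$ from the log-log slope of $G''$ over the top included
  decade, $\eta_{\alpha,0}$ from $G''$ at the highest included
  frequency, $G_0$ from $G'$ at the lowest frequency minus the
  spring-pot contribution (floored at a small positive value). Each
  parameter dominates a distinct asymptote, which makes this start
  reliable; the remaining restarts jitter it with seeded Gaussian noise
  as insurance against local minima. Fits are deterministic given the
  seed.

Standard errors come from the Jacobian-based covariance of the
log-residual fit, propagated to the natural parameters by the delta
method, and are reported as $\pm 1\sigma$. When a parameter sits on a
bound the covariance can be singular; standard errors are then `NA`
rather than a fabricated number.

Replicate handling is deliberately left to the caller: `fitFKVM()` fits
one sweep, `fitSeries()` fits a list with shared settings (failures
flagged per entry, never aborting the batch), and `mergeUpDown()`
combines bidirectional sweeps by the pointwise *geometric* mean —
the natural mean for quantities analysed on log scales — reporting the
maximum relative discrepancy and flagging hysteresis above `rtol`
(default 10 %). Fitting mean spectra and fitting per-replicate sweeps
are therefore both one line.

### Covariance properties

Two exact invariances of the log objective are asserted to tight
tolerances in the tests, because they are the properties a user
implicitly relies on when comparing fits across instruments and unit
conventions: scaling all moduli by $c$ scales $\hat G$ and
$\hat\eta_\alpha$ by $c$ and leaves $\hat\alpha$ unchanged ($10^{-8}$);
scaling frequency by $k$ (with the cutoff rescaled accordingly) leaves
$\hat G$ and $\hat\alpha$ unchanged and scales $\hat\eta_\alpha$ by
$k^{-\hat\alpha}$ ($10^{-6}$).

## Data model and I/O

All frequencies are angular (rad/s) internally; Hz exists only at I/O
boundaries, converted exactly by $\omega = 2\pi f$. Rheometer text
exports differ mainly in column names, frequency unit, separator and
decimal mark, so a single small *dialect* (`sweepDialect()`, optionally
loaded from YAML) is the only configuration mechanism — there are no
per-vendor parsers. Loaders are total: malformed input produces a typed
error, never a partially constructed object. Rows with non-positive
moduli are instrument artifacts incompatible with log residuals; they
are dropped at load with a logged count, not imputed. Containers
validate on construction (minimum three points, strictly positive finite
moduli, strictly monotone frequency grid consistent with the declared
sweep direction; flow curves enforce $\sigma = \eta\dot\gamma$).

## Scaling analysis

`powerLawFit()` is ordinary least squares of $\ln y$ on $\ln x$,
optionally windowed. It is exact on noiseless power-law data and exactly
unit-covariant. Representative-point scaling of a dose series uses $G'$
and $G''$ at 1 Hz and $\eta$ at 1.0 s$^{-1}$ by default — the standard
reporting convention for concentration series of weak gels.
Shear-thinning exponents are reported as the magnitude of the (negative)
log-log slope of $\eta(\dot\gamma)$ inside an **explicit, mandatory**
window: thinning exponents depend strongly on the window, so the package
refuses to guess one.

`yieldStressEstimate()` defaults to a Herschel-Bulkley fit
$\sigma(\dot\gamma) = \sigma_y + K\dot\gamma^n$ on the low-shear half of
the curve (log-stress residuals, bounded Levenberg-Marquardt,
$n \in (0, 1]$), because it is transparent and testable against
generated ground truth; a non-parametric low-shear stress-plateau median
is available as `method = "stress-plateau"`. The yield stress of a weak
mucin-like gel (mPa scale) is only identifiable if the curve reaches
shear rates where $\sigma_y$ is a non-negligible fraction of the total
stress — around $10^{-4}$ s$^{-1}$ and below for mPa-scale $\sigma_y$
with $K$ of order 0.3 Pa s$^n$. When the fitted $\sigma_y$ is
indistinguishable from zero (standard error at least as large as the
value, or collapse onto the bound) the estimate is flagged
`noPlateau` instead of being reported as a finite yield stress.

The linear viscoelastic region is detected from an amplitude sweep as
the first strain at which $G'$ departs from its low-strain plateau
(mean of the lowest-strain third) by more than 10 % — the tolerance is a
package decision, configurable, since no universal numeric criterion
exists. Monotonically decaying sweeps with no resolvable plateau are
flagged low-confidence rather than silently summarised.

Grid alignment between sweeps (for `sweepRatios()`) uses linear
interpolation in ln-ln space only, consistent with the log-scale
analysis everywhere else.

## Pore morphometry

The micrograph pipeline is: Gaussian smoothing (sampled kernel,
$\sigma = 1$ px default, radius $4\sigma$, reflective boundaries —
total intensity conserved to well under 0.1 %) → Otsu binarisation →
connected-component labelling → Feret diameters → distribution
statistics. Conventions, each configurable:

* **Pore class = dark pixels**, fiber network = bright; an `invert`
  flag covers other imaging modalities.
* **Otsu**: 256-bin equal-width histogram over the intensity range;
  the returned threshold is the bin edge maximising the between-class
  variance. The test suite asserts *oracle equality* with an exhaustive
  search computed directly from raw pixel values, and agreement with an
  independent library implementation in achieved between-class variance
  (the argmax itself is non-unique when the histogram has an empty gap
  between modes).
* **8-connectivity** for pore labelling (the common particle-analyzer
  default), switchable to 4.
* **Edge exclusion**: any component touching the image border is
  flagged and excluded from all statistics — a partially imaged pore has
  an unknowable Feret diameter.
* **Minimum area floor** (default 4 px): a size floor standing in for
  the manual verification step of interactive particle analysis.
* **Feret diameters on pixel-corner points**: each pixel is a unit
  square and the convex hull is taken over the four corners. The
  maximum Feret is the hull diameter; the minimum Feret is the smallest
  width over orientations via rotating calipers (the minimum is always
  attained flush against a hull edge). The corner convention makes the
  axis-aligned $s \times s$ square exact ($s$ and $s\sqrt 2$) and
  biases curved shapes upward by at most 1 px per axis; a digital disk
  of radius $r$ measures between $2r$ and $2r + \sqrt 2$ px.
* **Calibration (`nmPerPx`) must be supplied explicitly** — the
  magnification-to-scale mapping is instrument-specific and is never
  inferred. All nm quantities scale exactly linearly in it (areas
  quadratically), which the tests assert.

An image with no interior pores raises a typed empty-statistics error
rather than returning a misleading zero-row summary. The standard
deviation of a single pore is reported `NA`, not 0.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class the pipeline consumes, with
ground truth stored alongside, and are pure functions of their seed
(they also restore the caller's RNG state). Defaults are chosen once to
represent the regime of weak mucin-type gels:

* `generateSweep()`: FKVM spectra with $G = 2$ Pa,
  $\eta_\alpha = 1.5$ Pa s$^\alpha$, $\alpha = 0.70$ on a log grid over
  0.3-300 rad/s — moduli of a few Pa with $G'' > G'$ over most of the
  window, the typical weak-gel picture.
* `generateConcentrationSeries()`: doses 10, 20, 60, 100, 140 g/L with
  moduli scaling exponent 2.0 and viscosity exponent 2.2 — the scaling
  regime of entangled-polymer hydrogels. Both $G$ and $\eta_\alpha$
  scale with the same exponent so the representative-point moduli scale
  *exactly*, making noiseless closure tests sharp; $\alpha$ is constant
  across doses.
* `generateFlowCurve()`: Herschel-Bulkley with $\sigma_y = 1$ mPa,
  $K = 0.3$ Pa s$^n$, $n = 0.75$ over 0.1-1000 s$^{-1}$ (the standard
  steady-shear protocol window; yield-stress studies extend the lower
  end as discussed above).
* `generatePorePhantom()`: dark elliptical pores on a bright
  background, 512 px at 2 nm/px, lognormal minimum Feret diameters
  (median 35 nm, log-sd 0.4 — mainly 10-80 nm). Ellipses are used
  deliberately: their Feret diameters have closed forms (minor/major
  axis), so the truth table is analytic. Placement is rejection
  sampling with non-overlapping bounding circles; impossible densities
  raise an error instead of degrading silently. Intensities are
  quantised to the 8-bit grid so images round-trip losslessly through
  PNG.

Noise is multiplicative lognormal everywhere (rheometer and detector
errors scale with signal), parameterised by its coefficient of
variation and calibrated to unit mean.

What the generators do **not** emulate — and hence what passing tests do
not demonstrate about real data: amplitude-dependent nonlinearity
(LAOS), drift and aging during a sweep, correlated point-to-point
instrument noise, inertia artifacts (the generator is clean above the
cutoff where real data are not), evaporation, wall slip, cryo-preparation
artifacts in micrographs, non-elliptical and overlapping pores, and
uneven illumination. Recovery results on synthetic data bound what the
estimators can do under their own assumptions; they do not certify those
assumptions for any particular instrument.

## Problem sizes and numerical tolerances

The shipped test suite uses the sizes at which the methods' guarantees
are sharp but cheap: 30-point sweeps for fit recovery (200 Monte-Carlo
replicates at 5 % noise; median relative error below 5 % and
$|\bar{\hat\alpha} - 0.70| < 0.01$), 500 replicates for scaling-exponent
bias at 10 % noise (mean within 0.05), 512-px phantoms for the image
pipeline (pore count recovered exactly at zero noise, mean min-Feret
within 10 % of the analytic truth), 100 images for Otsu oracle equality
and 200 random convex pixel clouds for the Feret oracle (equality within
$10^{-6}$ against a dense-projection oracle augmented with flush-edge
orientations; a uniform angle grid alone converges only first-order at
the minimum because the width function has a kink there). Noiseless
recoveries are asserted at $10^{-6}$ relative (fit) and $10^{-10}$
(scaling exponents); the classical-limit identities at $10^{-12}$.

## Known limitations

* The FKVM cannot represent a terminal-flow crossover ($G'' \sim \omega$
  with $G' \sim \omega^2$) or multiple distinct relaxation processes;
  fractional Maxwell/Zener variants are out of scope (extension point
  only). Model selection between fractional models is likewise out of
  scope.
* Two-regime concentration scaling with automatic breakpoint detection
  is not provided; a fixed user-supplied window is.
* `lveRegion()` assumes the sweep actually enters the linear regime at
  its lowest strains.
* Pore analysis is strictly 2-D and descriptive; no stereological
  correction, fiber-thickness metrics, or significance testing between
  samples.
* Proprietary rheometer binary formats are not read; export to
  delimited text first.
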