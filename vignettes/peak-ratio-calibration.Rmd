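---
title: "Peak-height-ratio calibration of a binary drug film: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-height-ratio calibration of a binary drug film}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrquant)
```

## The measurement model

A film of a piperacillin/tazobactam (PIP/TAZ) mixture deposited on an ATR
crystal produces an absorbance spectrum that is, to first order, a
Beer–Lambert superposition of the two pure-component responses scaled by
the deposited mass:

$$A(\nu) \approx g \cdot \frac{C_\mathrm{PIP} R_\mathrm{PIP}(\nu) +
  C_\mathrm{TAZ} R_\mathrm{TAZ}(\nu)}{100}$$

The film scale $g$ is uncontrolled: droplet spreading and particle
distribution vary between depositions. Any single peak height is therefore
useless for quantification, but the *ratio* of two heights read from the
same film cancels $g$ exactly. The package's statistic is
$r = I(873)/I(890)$: the 890 cm⁻¹ band is an aromatic CH wagging mode of
PIP with no TAZ counterpart, while at 873 cm⁻¹ the TAZ response is strong
and grows visibly with TAZ content.

Both heights are read above a single straight baseline through the
spectrum's values at 862 and 905 cm⁻¹. Because the same line serves both
peaks, any affine contribution to the absorbance — offset drift, a gentle
linear slope — is removed exactly; this is a tested invariant, not an
approximation.

With the binary closure $C_\mathrm{PIP} + C_\mathrm{TAZ} = 100$ % w/w,
writing the mixture heights as linear combinations of the component
responses and dividing numerator and denominator by $C_\mathrm{PIP}$ shows
the ratio is (up to band overlap, below) linear in
$x = 100 / C_\mathrm{PIP}$. One ordinary least-squares line $r = a + bx$
therefore calibrates *both* components at once, and inversion is closed
form:

$$C_\mathrm{PIP} = \frac{100\,b}{\bar r - a}, \qquad
  C_\mathrm{TAZ} = 100 - C_\mathrm{PIP}.$$

The closure also forces the two recovered contents to share one standard
deviation — an error in one component is exactly the opposite error in the
other.

## Reading a height: tunable parameters

* **Peak positions** (`numeratorPosition` 873, `denominatorPosition`
  890 cm⁻¹) and **baseline anchors** (`baselineLeft` 862, `baselineRight`
  905 cm⁻¹): the published band pair and its bracketing window.
* **Apex half-width** (`apexHalfwidth`, 4 cm⁻¹): the height is the maximum
  baseline-corrected absorbance within ±4 cm⁻¹ of the nominal position,
  4 cm⁻¹ being a typical mid-IR instrument resolution. Reading at the
  local apex is robust to small calibration shifts of the wavenumber axis;
  the apex actually used is reported alongside each height so an audit can
  spot a window that captured the wrong feature. A `fixed` mode reads
  exactly at the nominal wavenumber instead — both are supported because
  peak-reading conventions differ between processing programs, and apex is
  the default.
* Anchors falling between grid points are linearly interpolated; windows
  are closed intervals in cm⁻¹; descending-wavenumber input (common in
  infrared exports) is normalised to ascending on read.
* A window whose corrected signal never rises above zero is a
  *non-detected* peak: it warns and reports the value rather than clipping
  to zero, except as a ratio denominator, where a height below $10^{-12}$
  is an error — a ratio against an absent band is meaningless.

## Calibration, inversion, uncertainty

`fitCalibration()` is unweighted OLS (via `lm`) in two modes:
`on_replicates` (default, every film is a point) and `on_means` (one point
per standard). The mean mode exists because published standards tables
often print only per-standard means; fitting printed means is then the
faithful recomputation. With only two points the line is exact and the
standard errors are reported as `NA` markers rather than invented.

Uncertainty on an inverted composition defaults to the replicate-only
delta method, $\mathrm{sd}(C_\mathrm{PIP}) = \frac{100\,b}{(\bar r -
a)^2}\,\mathrm{se}(\bar r)$: it reproduces the scale of a replicate-based
± without asserting how any particular published ± was derived. An
`extended` mode adds the calibration-parameter variances
($\mathrm{se}(a)$, $\mathrm{se}(b)$, covariance neglected) in quadrature
for users who want the calibration's own contribution folded in.

Compositions are recovered even outside the calibrated 5–50 % w/w TAZ
range, but flagged: a ratio below the pure-PIP point implies
$C_\mathrm{PIP} > 100$ and is reported as extrapolation rather than
silently clipped. A ratio at or below the intercept has no positive
solution and errors.

## Detection limits

Blanks here are pure-PIP films — the relevant null hypothesis is "no TAZ",
not "no sample". The decision ratio is $\bar y_b + k\,s_b$ with $k = 3$;
mapped through the line it gives the largest $C_\mathrm{PIP}$
distinguishable from pure PIP, whose complement is the TAZ LOD. The
default LOQ convention is the factor rule $\mathrm{LOQ} = 3 \times
\mathrm{LOD}$, chosen because the published LOD/LOQ pair for this
formulation (1.618 and 4.854 % w/w) sits in exactly that 1:3 proportion;
an ICH-style rule ($k_Q = 10$ decision ratio) is available as `ratio`
mode. The blank statistics behind the published limits were never
tabulated, so `referenceBlankStats()` is an explicitly labelled synthetic
reconstruction: mean at the model's pure-PIP ratio, sd chosen for
consistency with the published LOD.

## What the simulator emulates — and what it does not

`generatorConfig()` builds spectra as sums of pseudo-Voigt bands
($\eta L + (1-\eta)G$, default $\eta = 0.7$, FWHM 6 cm⁻¹) at the
published characteristic positions of both APIs, then applies the noise
structure the analysis assumes:

* **Film scale** $g \sim$ lognormal(0, 0.2): multiplicative, shared by all
  wavenumbers of one film. The ratio must cancel it exactly — a tested
  invariant.
* **Drift**: a random straight line (slope $\pm 2\times10^{-5}$ a.u./cm⁻¹,
  offset $\pm 0.02$ a.u.). Straight by design: the anchored baseline
  removes it exactly, and that exactness is itself under test.
* **Additive noise**: i.i.d. Gaussian, default sd 0.011 a.u., fixed by a
  one-off calibration loop so the mean 3-replicate ratio RSD at the 10:90
  composition is ≈ 2.8 % — the centre of the published replicate RSD range
  (1.90–3.89 %).

The four anchor amplitudes (PIP/TAZ at 873/890) are not free: under the
mixing algebra, a generator with $T_{873} = b$, $P_{873} = a + b$,
$P_{890} = 1$, $T_{890} = 0$ reproduces the line $r = a + bx$ exactly at
the anchor bands, so ground truth is known. All other band amplitudes are
documented arbitrary constants — relative band intensities are not
tabulated in the source material — which makes the synthetic spectra
*structurally* faithful (positions, overlap topology, noise structure) but
not spectroscopically faithful. Passing tests therefore demonstrate the
statistics, not instrument physics: no penetration-depth dispersion, no
water bands, no pressure effects, no polymorph shifts.

Two numerical choices deserve note:

* **Grid step 1 cm⁻¹** (600–4000). The apex height is a maximum over
  discrete grid points; on a grid whose points straddle a band centre an
  odd-centred band (873) reads ~9 % below its amplitude while an
  even-centred one (890) reads exactly, which would silently corrupt the
  anchor calibration. A 1 cm⁻¹ grid samples every integer band centre
  exactly. This mirrors practice: quoted peak positions *are* grid points
  of the instrument's sampled spectrum.
* **Band FWHM 6 cm⁻¹** keeps the 873/890 pair resolved (17 cm⁻¹ apart) but
  leaves real Lorentzian tail overlap; noiseless pipeline ratios
  reproduce the encoded line only to about 0.04 absolute. That residual
  is why noiseless checks carry a 0.05 tolerance rather than exactness —
  and why calibrating and quantifying *through the same pipeline* largely
  cancels it.

* **Seeding**: every replicate draws from a private RNG stream derived
  from (master seed, role, composition, replicate index); the caller's
  RNG state is untouched and identical configurations yield bit-identical
  spectra.

## Qualitative identification

TAZ has no unoverlapped band in the formulation, so identification uses
(i) matching detected local maxima — prominence at least 3× a noise scale
estimated as the median absolute successive difference — against the
reference position table within ±4 cm⁻¹, and (ii) the ratio statistic
itself against a decision threshold (default 0.27 ≈ pure-PIP ratio 0.22
plus a 3σ blank margin). The 1135 cm⁻¹ TAZ shoulder is kept only as a
table position; shoulder detection on a flank is a visual judgement this
package does not attempt to formalise.

## Problem sizes used in the shipped checks

The test suite and acceptance script run six standards × 3 replicate
films, 20 blanks and one 3-replicate unknown per simulated study, three
studies (seeds) per run — the same design as the original experiment, at
which scale the full suite completes in seconds. Brute-force oracle
comparisons (explicit-loop baseline/heights, closed-form OLS) run on 100
randomized small instances at $10^{-10}$ tolerance.

## Known limitations

* Univariate by construction: one band pair, two components, closure. No
  PLS/PCR, no three-component formulations.
* Unweighted OLS; the visible heteroscedasticity of ratio noise across
  the composition range is ignored, as in the original method.
* The delta-method ± ignores slope–intercept covariance in extended mode
  and all calibration error in replicate mode.
* JCAMP-DX support is a deliberate subset: affine `(X++(Y..Y))` records
  only; compressed encodings are rejected loudly rather than guessed at.
* The LOD reconstruction is a consistency argument, not recovered data;
  with different (unpublished) blank statistics the k = 3 chain would
  give different limits.
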