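---
title: "Deconvolving DNA-content histograms for genome size estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving DNA-content histograms for genome size estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyfit)
```

## The problem

Flow cytometry estimates plant genome size by staining nuclei with a
DNA-selective fluorochrome and recording per-nucleus fluorescence. A sample is
co-chopped with an internal standard of known DNA content; the ratio of the
two G1 peak positions, times the standard's genome size, gives the sample's
DNA content in pg/2C. The traditional analysis — drawing a gate around each
peak by eye — is subjective: narrowing a gate deflates the CV used for quality
control, and background debris under a peak inflates nuclei counts.

ploidyfit instead fits a parametric model of the whole histogram by nonlinear
least squares. Debris, S-phase nuclei and doublet aggregates are explicit
model components, so their contribution is separated from the G1/G2 peaks
rather than gated away by hand.

## The histogram model

Events from one fluorescence channel are binned into N equal-width bins over
`[0, range_max)`; all components are evaluated on the 1-based bin index
$x = 1, \dots, N$ against the observed counts $H(j)$. The fitted curve is a
sum of:

* **G1 peaks** (sample and standard): Gaussians
  $A\,e^{-(x-\mu)^2/2\sigma^2}$ with height $A$, position $\mu$ and width
  $\sigma$ (bins). The reported CV is $100\,\sigma/\mu$ and the modeled
  nuclei count is the Gaussian area $A\sigma\sqrt{2\pi}$.
* **G2 peaks**: Gaussians linked to their G1 parent by the linearity $L$:
  mean $L\mu$, width $L\sigma$, with only the height free. $L$ is fixed at
  the physical value 2.0 by default; *variable linearity* mode fits
  $L \in [1.90, 2.10]$ to absorb amplifier nonlinearity.
* **Debris**: cut nuclear fragments accumulate below the peaks. The
  *single-cut* form is the $\sqrt{j}$-weighted tail sum
  $SC(x) = a \sum_{j>x} \sqrt{j}\, H(j)$; the *multi-cut* form is the
  exponentially damped tail sum $MC(x) = a\,e^{-kx} \sum_{j>x} H(j)$.
  Both are computed from the **observed** histogram, which makes each a fixed
  shape scaled linearly by its amplitude — the fitting loop precomputes the
  unit shapes once (`model_bases()`). The damping was placed on the
  evaluation position $x$ (not on the fragment origin) so debris mass
  concentrates at low channels, which is how multiply-cut fragments behave.
* **S phase**: a broadened rectangle spanning the sample G1 and G2 positions,
  $BR(x) = \tfrac{A_s}{2}\left[\mathrm{erf}\frac{x-x_1}{\sqrt2\,\sigma_s} -
  \mathrm{erf}\frac{x-x_2}{\sqrt2\,\sigma_s}\right]$ with $x_1 = \mu_{G1}$,
  $x_2 = L\mu_{G1}$ tied to the sample peaks and a free edge width
  $\sigma_s$.
* **Aggregates**: doublets register the summed fluorescence of two nuclei, so
  the aggregate curve is the weighted self-convolution of the observed
  histogram over unordered bin pairs,
  $Agg(x) = a \sum_{j=1}^{\lfloor x/2 \rfloor} \sqrt{j(x-j)}\,H(j)H(x-j)$.
  Only pairwise aggregation is modeled; triplets are rare at normal event
  rates and would be absorbed by the amplitude.

## Fitting

Initial estimates come from peak detection: counts are smoothed with a 5-bin
centered moving average, local maxima at ≥10% of the (above-floor) smoothed
maximum are kept, candidates within 2 windows of a stronger one are
suppressed, and anything inside the debris-exclusion floor (the lowest 10 of
256 bins, scaled proportionally to the resolution) is ignored. Peak positions
and smoothed heights seed $\mu$ and $A$; $\sigma$ starts at a 5% CV; the
debris amplitude starts from the mean counts in the lowest quartile of fitted
bins divided by the unit debris curve there; the S-phase plateau starts at 1%
of the sample G1 height.

The model is fitted by unweighted least squares with the Levenberg–Marquardt
implementation in `minpack.lm::nls.lm`, using its native box constraints:
positions within ±10% of their initial estimate, widths within CV 0.5–15%,
non-negative heights and amplitudes, $k \in [0, 1]$. The bounds prevent label
switching between the two G1 peaks and collapse onto spikes. The default
convergence tolerance is a relative objective change of 1e-8 within at most
1024 iterations. Fitting is deterministic — there are no random restarts —
and non-convergence is reported as a flag on the result, never as an error,
so directory-scale batches always complete.

Goodness of fit is summarized by the residual chi-square
$\mathrm{RCS} = \frac{1}{n-p}\sum_{j} \frac{(H(j)-F(j))^2}{\max(F(j), 1)}$
over the fitted bins: residuals scaled by a Poisson-like variance (the fitted
count, floored at one count) per residual degree of freedom. Values near 1
mean residuals at counting-noise scale. It is a rough diagnostic; no pass /
fail cutoff is imposed. The fit itself is unweighted, matching standard
practice for this model family, so RCS serves purely as the scale check.
The fit mask excludes the debris-floor bins and the top bin (where clipped
events pile up on some instruments).

Initial-estimate robustness is a design property, not luck: with the peaks
seeded within a few bins and heights within ±20%, the converged estimates
agree to better than 0.1% (tested). When detection does fail — e.g. a
shoulder mistaken for a peak — `refit_with_overrides()` re-runs the fit from
user-supplied starting values, re-centering the position bounds around the
override; in batch runs the same mechanism is driven by per-file `overrides`
in the YAML configuration.

## Choices where the design was open

* **Histogram resolution.** 256 bins by default (a common cytometer
  resolution); the range ceiling comes from the channel's `$PnR` keyword,
  falling back to the smallest power of two covering the data. Analyses that
  must keep G2 and doublets of a bright sample on scale should raise
  `n_bins` at fixed bin width, as the examples do (1024 bins over 4096).
* **Role assignment.** With two detected peaks and no hint, the lower
  position is label A and the config says which label is the standard
  (default: A, the common case of a smaller-genome standard). A numeric
  position hint instead picks the nearest candidate as the standard.
* **G2 width linkage.** The G2 width is tied as $L\sigma_{G1}$ (constant CV)
  rather than fitted freely: G2 peaks are often small, and a free width
  invites collapse onto noise.
* **Standard G2 off by default.** Standards are usually G1-dominant, and
  whenever the sample/standard ratio is close to an integer the standard's G2
  is nearly collinear with the sample G1 component, which would make the fit
  degenerate.
* **Gating.** Gates are polygons supplied in the configuration, applied with
  the even-odd rule and boundary points retained — deterministic and
  reproducible, unlike interactive gating. Gating is a last resort; the model
  exists precisely to make most gating unnecessary.
* **Counting convention.** `total_nuclei` sums Gaussian areas only (G1 + G2,
  both roles). S-phase, debris and aggregate areas are never counted as
  nuclei, but the per-component parameters are reported so a user can add
  the S-phase contribution if their QC convention includes it.

## The event simulator

Because public FCS repositories rarely carry ground truth, the package ships
a generative twin of the model (`simulate_events()`): events draw a class
(G1/G2/S per population, debris, doublet) from specified fractions, then a
fluorescence value — Gaussians for G1/G2, a broadened uniform for S phase,
$\sqrt{U}\times$ (a fresh nucleus) for fragments, and the sum of two
independent nuclei for doublets. The $\sqrt{U}$ fragment size is deliberately
*not* identical to the single-cut fitting form: debris models are
approximations of fragment physics, and recovery tests against an exactly
matching generator would be circular. `standard_fixture()` freezes the
reference conditions used throughout the tests: 20,000 events, standard G1 at
400 and sample G1 at 800 intensity units (bins 100 and 200 at bin width 4),
3% CVs, 40% standard nuclei, 5% G2 and 5% S phase, 15% debris, 2% doublets,
linearity 2.0, seed 1. The generator pins the RNG algorithm
(Mersenne-Twister / inversion / rejection sampling) so fixtures are bitwise
reproducible across platforms and R versions.

What the simulator does *not* emulate: instrument drift, carry-over,
spectral spillover, log-amplified channels, and non-Gaussian peak asymmetry.
Passing recovery tests therefore demonstrates correctness of the estimator
under clean acquisition, not robustness to every instrument artifact; on
real data the RCS and the fit plot remain the operator's diagnostics.

Test and validation problem sizes were chosen to exercise the estimator at
realistic scale while staying quick: 20,000-event simulations for recovery
(50 replicate seeds for stability), 64-bin histograms for the brute-force
component oracles (100 random cases), and 5-file directories for the batch
contract.

## Known limitations

* Linear-domain data only; log-amplified channels must be decoded upstream.
* Debris beyond the single/multi-cut family (e.g. sliced-nucleus models) and
  higher-order aggregates are not modeled.
* The sample/standard assignment assumes the two dominant peaks are the two
  G1 populations; heavily endopolyploid tissue needs manual overrides.
* Approximate standard errors come from the Jacobian at the optimum and are
  reported as NA for parameters pinned at a bound.
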