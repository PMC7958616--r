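---
title: "Decomposing the Water Association Band: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the Water Association Band: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wabdecomp)
```

## The problem

Dry amorphous sugar matrices — trehalose, sucrose, maltose, lactose,
raffinose — are widely used to preserve proteins at very low hydration.
The little water that remains after drying is not homogeneous: it lives in
hydrogen-bond environments that range from strongly disordered (chaotropic,
e.g. at the protein surface) to ice-like (kosmotropic, in sugar-water
domains). The Water Association Band (WAB), a weak and very broad infrared
combination band between roughly 2000 and 2500 cm⁻¹, probes exactly this:
its sub-structure shifts from low-frequency to high-frequency components as
the hydrogen-bond network orders.

`wabdecomp` implements the full analysis chain for WAB spectra of
myoglobin–sugar films prepared across a range of sugar/protein ratios
(S/P, counted in monosaccharide units per protein molecule: disaccharides
contribute 2 units, the trisaccharide raffinose 3):

1. background subtraction (constant plus a Gaussian tail),
2. area normalization over the WAB window,
3. constrained Gaussian sub-band decomposition with parsimonious model
   selection,
4. fractional populations and replicate aggregation,
5. cross-composition trend analysis (two-family clustering, population
   interconversion, red/blue peak shifts),
6. formulation arithmetic (S/P and water/sugar ratios),

together with a synthetic-spectrum generator that plants known ground
truth, so every stage is testable without access to raw instrument data.

## Signal model

A measured spectrum is modeled as

$$ A(\nu) = B(\nu) + \sum_{k} a_k
   \exp\!\left[-4\ln 2\,\frac{(\nu - c_k)^2}{w_k^2}\right] + \varepsilon(\nu), $$

where $B(\nu) = b_0 + a_B \exp[-4\ln 2\,(\nu - c_B)^2 / w_B^2]$ is the
background (a constant plus the low-frequency wing of the very strong
CH-stretching bands at 2800–3000 cm⁻¹), each sub-band is a Gaussian
parameterized by center $c_k$, full width at half maximum $w_k$ and peak
amplitude $a_k$, and $\varepsilon$ is additive measurement noise. Gaussian
(not Lorentzian or Voigt) component shapes reflect the strong inhomogeneity
of the band: each sub-band stands for a blurred family of hydrogen-bond
configurations, not a single oscillator.

The observable of interest is the *fractional population* of each sub-band:
its analytic area $a_k\, (w_k / 2.3548)\sqrt{2\pi}$ divided by the summed
area of all fitted components. Normalization makes this meaningful — the
raw WAB area tracks water content only roughly, but the *relative* weight
of the sub-bands tracks the hydrogen-bond populations.

### The sub-band taxonomy

Seven classes are admitted, each confined to a fixed frequency window:

```{r}
subband_classes()
```

Five of them (W0b, W1, W2a, W3, W4) occur in every sample and are always
fitted. W0a and W2b are duplications — splittings of the W0 and W2 bands —
that are only admitted when the data demand them (see *Model selection*).
The W4 window contains the cubic-ice maximum at 2255 cm⁻¹, which anchors
its ice-like attribution.

## Background fitting

The background is fitted by bounded least squares over an *anchor region*
(default 2400–2600 cm⁻¹), the high-wavenumber side of the WAB where the
CH-stretch wing dominates and the sub-band wings are negligible (< 10⁻³ of
their peaks). The tail center is constrained to 2700–3100 cm⁻¹, bracketing
the CH-stretch region with margin.

An option (`n_edge`) adds the lowest-wavenumber points of the WAB window to
the fit support. It is off by default: the strongly-destructured sub-bands
W0a (2000–2010 cm⁻¹) and W0b (2015–2035 cm⁻¹) sit directly at that edge,
and whenever they are populated — which is precisely the protein-rich
regime — those points ride on sub-band signal, not background. Including
them biases the fitted offset upward by the local sub-band amplitude
(several 10⁻³ absorbance in our synthetic studies), which distorts all
populations after normalization and can mask genuine duplications during
model selection. The anchor region alone identifies both the offset and
the tail: the wing rises from ~10⁻³ to ~6 × 10⁻² across it, enough
curvature to separate the two terms.

Whether the constant is fitted jointly with the tail or beforehand is a
free choice; we fit jointly (one bounded Levenberg–Marquardt problem).

## Sub-band fitting

For a chosen class set, the decomposition is a bounded nonlinear
least-squares problem over $(c_k, w_k, a_k)$: centers are box-constrained
to their class windows (half-open at the shared 2120 cm⁻¹ edge, which
belongs to W2a by convention; the W4 window is closed), amplitudes are
non-negative, and widths lie in `fwhm_bounds` (default 20–200 cm⁻¹ — the
whole band is only ~300 cm⁻¹ wide, so no single component may approach
that scale, and the lower bound excludes spike-fitting of noise).

Initialization is deterministic: centers at the window midpoints, widths at
the canonical class widths (`canonical_fwhm()`, 50–90 cm⁻¹), amplitudes
read off the spectrum at the initial centers and rescaled so the implied
total analytic area matches the observed band area (overlapping neighbors
otherwise inflate the read-off heights roughly three-fold).

### Why the fit is regularized

Adjacent sub-bands overlap heavily: the W0a–W0b separation (~20 cm⁻¹) and
the W2a–W2b separation (~40 cm⁻¹) are well below the component widths.
This has a hard statistical consequence that we measured directly on
synthetic data: with all 21 parameters free, distinct parameter vectors
whose populations differ by ±0.1–0.25 reproduce the same spectrum to
within a residual far below any realistic noise floor. An unregularized
fit started *at the planted truth* of a seven-component spectrum with 0.3%
noise drifts to population errors of 0.03–0.25 while the residual sits at
the noise floor — the data genuinely do not determine the populations.
Worse for parsimony-based selection, a five-band model can absorb a real
W0a or W2b duplication entirely by broadening its neighbors, again at no
residual cost.

The estimator therefore adds a mild Tikhonov penalty toward the taxonomy
shape, appended to the residual vector:

$$ r_{\text{pen}} = \left\{ \kappa_c \hat\sigma\, \frac{c_k - m_k}{h_k},\;
   \kappa_w \hat\sigma\, \log\frac{w_k}{w_k^{0}} \right\}_k $$

with $m_k$ the window midpoint, $h_k$ the window half-width, $w_k^0$ the
canonical class width, $\kappa_c = 15$ (centers) and $\kappa_w = 200$
(widths). Two properties matter:

* **The penalty is scaled by the estimated noise** $\hat\sigma$, obtained
  from the residual of an unpenalized pilot fit ($\hat\sigma^2 =
  \mathrm{RSS}/(n - 3k)$). For noiseless data the penalty vanishes, so
  exact recovery of well-separated components is untouched (our tests
  verify recovery to ~10⁻¹⁵ in populations and < 0.1 cm⁻¹ in centers). A
  pilot residual below 0.01% of the signal rms is treated as numerical
  rather than measurement noise and disables the penalty outright.
* **Widths are held much more firmly than centers.** Peak positions are
  physical observables reported per sample (red/blue shifts across
  compositions are part of the analysis), so their prior is weak — under
  0.3% noise it permits shifts of several cm⁻¹ where the data support
  them. Widths, by contrast, are treated as class properties: nothing in
  the analysis interprets per-sample width changes, and leaving them
  effectively free is exactly what destroys identifiability.

With this estimator, seven planted populations at 0.3% noise are recovered
within ±0.03 (median maximum error ≈ 0.003), and selection distinguishes
five- from seven-band truths reliably.

### Optimization

Each fit uses Levenberg–Marquardt (`minpack.lm::nls.lm`) with an analytic
Jacobian and box constraints; convergence at relative RSS change < 10⁻¹²
or parameter step < 10⁻¹⁰, with an iteration budget of 2000 (restarting
the damping after each 1024-iteration leg). Because the unpenalized
surface is multimodal, the pilot runs two deterministic routes — a staged
descent (centers frozen at their starting values first, then everything
free; the frozen stage is solved in a reduced parameterization) and a
direct descent — and keeps the better one. No randomness is involved; the
decomposition is bit-reproducible given (spectrum, classes, config). An
optional multistart (`multistart > 0`) perturbs the initialization using
the config seed, off by default.

## Model selection

The band profile is described with the fewest Gaussian components that the
data justify. The five mandatory classes are always fitted; the candidates
{+W0a}, {+W2b}, {+both} are then fitted — each warm-started from the
accepted smaller model (which guarantees the nested-model RSS never
increases) and also from the default initialization, keeping the better —
and a candidate is accepted only if it improves the BIC,

$$ \mathrm{BIC} = n \log(\mathrm{RSS}/n) + 3k \log n , $$

by at least `selection_threshold` (default 10, a strong-evidence
convention). Candidates are examined in order of increasing size, so ties
resolve to the fewest components. The BIC uses the data residual only
(never the penalty terms), and the noise level entering the penalty is
estimated once per spectrum, from the richest candidate's unpenalized
residual, so all candidates are penalized on the same scale and their BICs
are comparable.

## Replicate aggregation

Samples are measured in replicate (3–8 films per formulation in the study
design this package emulates). Populations and peak frequencies are
reported as means over replicates with sample (n−1) standard deviations. A
class absent from one replicate's accepted model contributes population 0
to the population statistics, but its center statistics are computed only
over the replicates where it is present. Instrumental-resolution
uncertainty (~0.3 cm⁻¹) is *not* folded into the SDs.

## Cross-composition trends

* **Two-family clustering.** WAB profiles ordered by S/P are compared by
  L2 distance between consecutive area-normalized profiles; the transition
  is placed at the S/P immediately *below* the largest consecutive gap
  (matching the convention that labels the last low-family member as the
  transition ratio), and the separation score — largest gap over the mean
  of the others — flags reliability (threshold 2.0). The profiles are
  re-normalized internally, so the split is invariant to common rescaling
  and to input order.
* **Population trends.** Spearman rank correlation of population against
  log₂(S/P) (the designs double S/P at every step); |ρ| ≥ 0.7 calls a
  direction, otherwise the trend is flat. Constant populations define
  ρ = 0.
* **Peak shifts.** The endpoint centers (lowest vs highest S/P) are
  compared; a shift is declared only when |Δc| exceeds the combined
  standard deviation $\sqrt{s_1^2 + s_2^2}$. Red = frequency decreases
  with S/P, blue = increases.

The ρ threshold, the separation-score threshold and the combined-SD rule
are this package's operationalizations of qualitative statements; they are
declared conventions, configurable in `wab_config()`.

## Formulation arithmetic

Solutions are prepared at equal monosaccharide-unit concentration rather
than equal nominal molarity, so di- and trisaccharides are comparable:
0.8 M units ≡ 0.40 M disaccharide ≡ 0.27 M raffinose. `sp_ratio()`
recomputes S/P from the preparation molarities; the disaccharide
formulation rows reproduce their nominal labels exactly, while the
raffinose rows imply slightly different ratios (18.75, 38.6, 78, 160, 315
against labels 20–320) — the package reports the computed values alongside
the labels without reconciliation, since the rounding convention behind
the labels is unknown. Water/sugar ratios convert between molar and mass
units with 18.015 g/mol for water and anhydrous sugar masses (342.30 g/mol
for the disaccharides, 504.42 g/mol for raffinose); the bundled
residual-water reference (`ws_reference()`) has its minimum at S/P = 80
for every sugar. Where a protein mass is needed, horse myoglobin is taken
as 16,950 g/mol (configurable); note that with these constants S/P = 80
corresponds to a protein:sugar mass ratio of ≈1.24, not exactly 1:1.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the analysis
assumes, with planted ground truth for every spectrum:

* **Composition dependence.** Per sugar, populations blend from a
  protein-dominated vector (low-frequency heavy: W0a/W0b present, W2a
  dominant, no W2b) to a sugar-dominated vector (W2b/W3/W4 heavy) through
  a logistic in log₂(S/P) centered at S/P = 110 — between the last
  low-family design point (80) and the first high-family point (160), so
  the labeled transition of a generated study is 80. Steepness encodes the
  sugars' characters: trehalose smooth (1.5), sucrose abrupt (6), maltose
  2.5, lactose 3 (with W2b weight already at low S/P), raffinose 5 with no
  W2b in either regime. Protein-free samples return the sugar-dominated
  vector with W0a forced to zero. These vectors are qualitative encodings
  chosen once for this package; they are not measured values.
* **Spectra.** Sub-band Gaussians at the window midpoints with canonical
  widths (50–90 cm⁻¹, so the composite approaches the ~300 cm⁻¹ full-band
  width), areas proportional to populations with total WAB area 25
  absorbance·cm⁻¹; a background (offset 0.02, tail at 2900 cm⁻¹, FWHM
  300 cm⁻¹, amplitude 1.0) whose wing reaches ~0.06 at 2600 cm⁻¹ so that
  background fitting is genuinely exercised; i.i.d. Gaussian noise with SD
  0.3% of the maximum signal, on a 1 cm⁻¹ grid over 2000–2600 cm⁻¹.
* **Replicates.** Populations jitter by a Dirichlet perturbation
  (concentration 400, giving population SDs of a few percent, the scale of
  real replicate scatter); centers jitter by a truncated normal (SD
  2 cm⁻¹) inside their windows; every spectrum gets fresh noise. All
  randomness derives from one master seed through per-(sugar, S/P,
  replicate) hashed substreams, so adding a sugar to a design never
  changes the other sugars' draws, and the manifest is seed-independent.

What the generator does **not** emulate: physical line-shape theory
(anharmonic coupling, librational combination structure), correlated or
multiplicative instrument noise, atmospheric interference, crystallization
(peak duplication/opacity), or temperature dependence. Passing tests on
synthetic data therefore demonstrate that the *pipeline* is correct and
stable under the stated statistical assumptions — not that real spectra
satisfy those assumptions.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature everywhere (areas agree with the closed-form
  Gaussian area within 0.1% for FWHM ≥ 20 cm⁻¹ on a 1 cm⁻¹ grid); region
  integrals interpolate the exact endpoints so areas are well defined on
  any grid.
* Negative post-subtraction values are kept, not clipped; normalization
  uses the signed area and raises a data error when it is ≤ 0 (empty or
  negative band).
* A flat spectrum yields a degenerate background (offset = the constant,
  zero tail amplitude) without invoking the optimizer.
* Centers falling in inter-window gaps are assigned to the nearest class
  (flagged as out-of-window); equidistant ties go to the lower-frequency
  class.
* Replicate SDs are sample standard deviations, defined as 0 for a single
  replicate.
* Spectra are written with 17 significant digits; read–write round trips
  are exact to 10⁻¹².

## Problem sizes in the test-suite and validation runs

The stochastic suites use 100 seeds per condition: five- and seven-band
selection accuracy, seven-band population recovery (±0.03), and
family-transition recovery on the abrupt preset (noise SD 0.3% of max
throughout, one 601-point spectrum per seed). The simulated studies in
`analysis/` use four replicates per sample and five to six S/P points per
sugar. These sizes were chosen to estimate the relevant rates to a few
percent while keeping a full run in the minutes range on a single core.

## Known limitations

* The shape prior biases noisy fits toward the canonical widths and window
  midpoints. This is deliberate — the alternative is statistical
  non-identifiability — but it means that, on real data whose component
  widths deviate strongly from the canonical values, the populations
  inherit that prior. The canonical widths are themselves placeholders:
  per-sub-band widths have not been published for these systems.
* Model selection only arbitrates the two known duplications (W0a, W2b);
  it does not search for additional unknown components.
* The water-content band area (`band_area()` around 5200 cm⁻¹) supports
  drying-stabilization monitoring only; no calibration to absolute water
  content is attempted.
* JCAMP-DX support is limited to single-block XYDATA/XYPOINTS tables.
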