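---
title: "Models and methods in loopchap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in loopchap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopchap)
```

`loopchap` implements the quantitative machinery behind a common
experimental programme in chaperone biochemistry: relating the
hydrophobicity of short loop motifs in an ATP-independent chaperone domain
(the BRICHOS family is the motivating case) to its ability to prevent
amorphous protein aggregation, and separately asking — via global kinetic
fitting — which microscopic step of amyloid fibril formation the chaperone
inhibits. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## 1. Motif hydropathy

A variant is described by three short loop motifs (tripeptides in the wild
type, possibly empty in deletion variants) plus the anchor residue at loop
position 206. Its score is the **sum** of per-residue scale values over all
residues of the three motifs plus the anchor:

* Sum rather than mean: for fixed-length tripeptides the two are affine
  equivalents and the downstream regression is invariant to affine
  recoding, but the sum extends without reweighting to deletion variants
  (score contribution 0) and to the single anchor residue.
* Two scales ship with the package: the Kyte–Doolittle index, and the
  "biological" translocon scale — the apparent free energy of membrane
  insertion through Sec61, in kcal/mol, where *smaller* published values
  mean more hydrophobic. Both are exposed on a common working orientation
  (larger = more hydrophobic; the biological scale is negated, its raw
  values retained), and the orientation is always declared, never inferred
  from the numbers.

Because the regression downstream is invariant to affine recoding of its
x-axis, the choice of sum vs mean and of sign convention does not affect
R², p-values or predicted activities — only the printed axis values. This
also means results can be compared against plots using either convention
without refitting.

## 2. Aggregation mass from turbidity kinetics

Anti-amorphous activity is quantified from plate-reader turbidity traces
(absorbance at 360 nm of a heat-destabilized substrate such as citrate
synthase, cycled nominally every 90 s) as the **aggregation mass**: the
trapezoidal area under the baseline-corrected trace over the time window
common to sample and control, normalized to the substrate-alone control
and expressed in percent.

Numerical and design choices:

* **Trapezoids on actual timestamps.** Plate cycles can have gaps;
  integrating the recorded grid avoids resampling artifacts. AUC is linear
  in the signal, so a common rescaling of sample and control cancels
  exactly.
* **Baseline correction** subtracts the mean of the first 3 points
  (configurable) from both sample and control. Raw offsets otherwise bias
  the AUC ratio; negative corrected values are kept, not clipped, so that
  baseline noise remains zero-mean under the integral.
* **Replicates**: AUC is computed per replicate first, then averaged;
  the dispersion is `100 · sd(AUC)/mean(control AUC)`. This matches the
  usual "mean ± sd of per-replicate quantities" reporting.
* The control against itself is exactly 100% by construction, for any
  positive trace — a property the test suite asserts.

## 3. The hydropathy–activity regression

Across a panel of variants measured at one substrate:chaperone molar ratio
(always on a monomer-subunit basis), aggregation mass is regressed on
combined hydropathy by ordinary least squares, one point per variant
(per-variant means, not pooled replicates — panels of this kind plot one
point per variant). The object stores the sufficient statistics
(`n`, `x_mean`, centred `x_sumsq`, residual sd) so that confidence bands
can be reconstructed without the training data.

Predictions for new variants (e.g. a BRICHOS domain from another protein,
or a chimera carrying motifs from an unrelated small heat-shock protein)
use the **confidence interval of the mean response**,

$$\hat y(x) \pm t_{1-\alpha/2,\,n-2}\; s\sqrt{\tfrac1n +
  \tfrac{(x-\bar x)^2}{S_{xx}}},$$

not the wider prediction interval: the quantity being predicted is the
expected activity of a variant given its hydropathy — what the regression
line and its confidence band display — and the narrow published intervals
for such predictions are mean-response bands. Optionally, point and bounds
are clamped to the physically meaningful [0, 100]%.

`correlate()` exposes the same R²/p machinery for auxiliary correlations
(e.g. oligomer subunit count vs activity) and is tested to agree exactly
with the regression statistics.

## 4. Amyloid kinetics

### 4.1 The empirical sigmoid

Thioflavin-T traces are summarized by
$$F(t) = F_0 + A\,/\,(1 + \exp[r_{\max}(\tau_{1/2} - t)]),$$
fitted by Levenberg–Marquardt from a data-driven deterministic start
(baseline/plateau from signal quantiles, half-rise crossing for
$\tau_{1/2}$, steepest slope for $r_{\max}$) with a fixed fallback start
grid; no randomness is involved, so refits are bit-reproducible. Fits with
non-positive amplitude or growth rate are rejected, and a fitted
$\tau_{1/2}$ outside the observed span is flagged. Replicates are
normalized to [0, 1] through their own fitted $(F_0, A)$ and averaged
pointwise; if any replicate cannot be fitted, all replicates fall back to
min/max normalization and the result carries a fallback flag (both
conventions are in use; the flag records which one produced the curve).

### 4.2 The integrated rate law

Fibril mass growth by primary nucleation (rate constant $k_n$, order
$n_C$), elongation ($k_+$) and fibril-surface secondary nucleation ($k_2$,
order $n_2$) admits a closed-form solution for the normalized fibril mass
$M(t)/M(\infty)$ in terms of two identifiable combinations
$$\lambda = \sqrt{2 k_+ k_n m_0^{n_C}}, \qquad
  \kappa = \sqrt{2 k_+ k_2 m_0^{n_2+1}},$$
with coefficients $C_\pm = \pm\lambda^2/2\kappa^2$,
$k_\infty = \sqrt{2\kappa^2/(n_2(n_2+1)) + 2\lambda^2/n_C}$,
$\bar k_\infty = \sqrt{k_\infty^2 - 4C_+C_-\kappa^2}$,
$B_\pm = (k_\infty \pm \bar k_\infty)/2\kappa$.

Numerical safety is part of the contract:

* every $\exp(\kappa t)$ is folded into log space via
  $\log(B + C_+e^{\kappa t}) = \kappa t + \log(C_+ + B e^{-\kappa t})$, so
  the curve is finite at arbitrary $t$;
* $\bar k_\infty$ is evaluated as $\sqrt{k_\infty^2 + \lambda^4/\kappa^2}$
  and $B_-$ in the rationalized form
  $-(\lambda^4/\kappa^2)/(2\kappa(k_\infty + \bar k_\infty))$, both
  algebraically identical to the definitions but free of the catastrophic
  cancellation that the naive forms suffer when $\lambda \gg \kappa$;
* $t = 0$ maps to exactly 0, and outputs are confined to [0, 1];
* limit branches: $\lambda = 0$ (no primary nucleation, unseeded) returns
  the zero curve; $\kappa = 0$ (no secondary nucleation) uses the limit
  $M/M_\infty = 1 - (1 + \lambda^2 t/k_\infty)^{2/n_C} e^{-k_\infty t}$
  with $k_\infty = \lambda\sqrt{2/n_C}$.

Reaction orders default to $n_C = n_2 = 2$ and $m_0$ to 3 µmol/L — the
conventional choices for this substrate at the concentration the assays
use — and are configurable, not fitted.

**Validity.** The closed form is a linearized self-consistent solution.
Against direct numerical integration of the moment equations
($\mathrm{d}P/\mathrm{d}t = k_n m^{n_C} + k_2 m^{n_2} M$,
$\mathrm{d}M/\mathrm{d}t = 2k_+ m P$, $m = m_0 - M$) its half-time error
is about 0.2% at $\lambda/\kappa = 0.01$, 1.5% at $0.1$, 7% at $0.3$ and
21% at $\lambda = \kappa$. It is therefore quantitatively reliable where
secondary nucleation dominates proliferation ($\lambda \lesssim
0.1\kappa$, which covers the substrate this machinery is aimed at) and
should be treated as qualitative outside that regime. The test suite and
the acceptance script measure this curve; the package does not hide it.

### 4.3 Constrained global fitting

To identify the microscopic step a chaperone inhibits, curves recorded at
several chaperone:substrate ratios (0% control, then e.g. 10/50/100%) are
fitted **globally**: all parameters shared across conditions except a
per-condition multiplicative factor on exactly one rate constant (the
control factor pinned at 1). Repeating the fit with each of $k_n$, $k_+$,
$k_2$ as the free constant and ranking by pooled residual sum of squares
selects the best-supported mechanism.

Because only $\lambda$ and $\kappa$ are identifiable from mass curves,
optimization runs in $\log(\lambda, \kappa)$ space and the free-constant
constraint acts on the combinations: a $k_n$ factor scales $\lambda^2$, a
$k_2$ factor scales $\kappa^2$, and a $k_+$ factor scales both (since
$k_+$ enters both products linearly). Reported rate constants are the
products $k_+k_n$ and $k_+k_2$; individual constants are deliberately not
reported.

Optimization is Nelder–Mead polished by BFGS, multi-started from a seeded
Latin hypercube spanning ±3 decades around a data-driven guess
($\kappa_0 = 2 r_{\max}$ of the control curve's sigmoid fit). The default
is 16 starts; the simulation studies in the tests and the acceptance
script use 4, which the data-driven initialization makes sufficient there
and keeps 3 candidate fits × 100 simulated panels tractable. A panel whose
conditions are all essentially the same curve makes free and shared
parameters indistinguishable; such panels are flagged `degenerate`, not
silently fitted.

## 5. QC computations

* **SEC oligomer size**: peak maximum and full width at half maximum
  (linear interpolation at the half-height crossings) are converted to
  molecular weight via a user-supplied log-linear column calibration
  (standard SEC practice) and divided by the monomer molecular weight.
  Counts are reported as rounded integers with the unrounded MW ratio
  retained; the FWHM range brackets the peak estimate, and later elution
  can never increase the count (negative calibration slope).
* **CD**: mean residue ellipticity
  $\mathrm{MRE} = \theta_{\mathrm{mdeg}} / (10\, l\, c\, (N-1))$ with the
  peptide-bond count $N-1$ as divisor (configurable to $N$, since
  conventions differ).
* **Trp fluorescence**: emission maximum as the argmax of a
  moving-average-smoothed spectrum, to 1 nm — enough to resolve the ~7 nm
  red shift that distinguishes a solvent-exposed from a buried reporter.

## 6. Synthetic data: what it emulates, and what it does not

All pipeline inputs can be generated with known ground truth from a seeded
`generator_config()`; every generator is deterministic given the config
and restores the caller's RNG state.

* **Variant panels**: random tripeptide motifs spanning the full
  hydropathy range, always including a hydrophobic wild-type-like variant,
  an all-EGR polar variant, a Ser/Ala-softened variant and an anchor
  Thr→Trp swap. True activity is `clamp(40 − 3·score + noise, 0, 100)` on
  the oriented biological scale by default — chosen so the panel spans
  roughly 40–100% aggregation mass, the dynamic range such experiments
  occupy — with 5% Gaussian noise as a realistic between-variant assay sd.
* **Turbidity plates**: the control is a logistic absorbance curve (the
  analysis uses only the AUC, so any saturating shape with controllable
  area serves); variant traces are the control shape scaled by
  activity/100, making the expected AUC ratio the activity by
  construction; additive Gaussian noise (0.01 AU), 3 replicates, 90 s
  cadence, 90 min span.
* **Thioflavin-T panels**: closed-form curves at ratios 0/10/50/100% with
  one rate constant suppressed per ratio (default $k_2$ at factors
  1/0.5/0.2/0.1 — a monotone dose response of the kind a
  secondary-nucleation-blocking chaperone produces), baseline λ = 4·10⁻⁵
  s⁻¹ and κ = 1.2·10⁻³ s⁻¹ (half-time ≈ 1.8 h at 3 µmol/L, typical for
  this substrate), multiplicative 2% noise (fluorescence-like), 4
  replicates, 12 h span.
* **SEC**: piecewise-Gaussian peaks constructed so the maximum and both
  half-height crossings land exactly on configured subunit counts, on an
  exactly log-linear calibration.

What passing on these fixtures does **not** show about real data: real
turbidity traces need not share a shape across variants (only the AUC is
modelled); real ThT panels contain pipetting-level concentration errors,
drift and plateau decay that the multiplicative-noise model omits; real
SEC peaks overlap and tail. The generators validate the estimators'
correctness and identifiability under the stated noise, not instrument
physics.

## 7. Orchestration and reproducibility

`run_amorphous()` and `run_amyloid()` compose the stages from a single
YAML/JSON config in which every default is surfaced (`baseline_n = 3`,
`scale = "biological"`, `ci_level = 0.95`, `m0 = 3e-6`, `n_C = n_2 = 2`,
all three candidate free constants, `seed = 1`). Outputs are plain
TSV/JSON plus a manifest listing an md5 for every file, the seed and the
package version; with fixed inputs and seed, all outputs except the
manifest timestamp are byte-identical across reruns. Errors are prefixed
with the failing stage's name.

## 8. Known limitations

* The closed-form rate law's accuracy degrades outside the
  secondary-nucleation-dominated regime (Section 4.2); the moment-ODE
  integrator `ode_mass_fraction()` is provided for cross-checking.
* Individual rate constants are not identifiable from mass curves; only
  $k_+k_n$ and $k_+k_2$ are reported, and a chaperone acting on two steps
  at once violates the single-free-constant design by construction (the
  ranking then reports the best single-step approximation).
* Published per-variant wet-lab panels are not redistributed with the
  package; checks against published regression numbers require supplying
  those tables (see `tests/testthat/test-acceptance.R` for the expected
  file formats).
* Seeded-aggregation and fragmentation mechanisms, overlapping-SEC-peak
  deconvolution and CD secondary-structure estimation are out of scope.

## 9. Problem sizes used in the checks

The test suite and acceptance script run entirely on generated data at
desk scale: 1,000 parameter draws for boundary identities, 100 draws for
the ODE comparison, 100 simulations each for sigmoid recovery and for
global-fit model selection (4 ratios × 4 replicates, 61 time points), and
panels of 10–12 variants × 3 replicates for the regression round trips.
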