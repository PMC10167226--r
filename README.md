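# loopchap

Quantitative analysis of chaperone loop-motif hydropathy, anti-aggregation
activity, and amyloid formation kinetics.

ATP-independent molecular chaperones such as BRICHOS domains prevent
amorphous aggregation of destabilized proteins, and their efficiency can be
traced to a handful of short hydrophobic loop motifs. `loopchap` implements
the analysis pipeline for the two experimental axes of that programme:

1. **Amorphous aggregation.** Turbidity kinetics (A360 of heat-destabilized
   substrates like citrate synthase) are reduced to the *aggregation mass*
   — the area under the baseline-corrected curve as a percentage of the
   substrate-alone control — and regressed by OLS on the combined motif
   hydropathy

   *mass%* = β₀ + β₁ · Σᵣ h(r),

   where h is a residue hydropathy scale (Kyte–Doolittle, or the
   "biological" translocon ΔG<sub>app</sub> scale in kcal/mol) summed over
   the three loop motifs plus the position-206 anchor residue. The fitted
   line predicts activities of new variants with mean-response confidence
   bands.

2. **Amyloid formation.** Thioflavin-T traces of fibril formation are
   fitted with the empirical sigmoid
   F(t) = F₀ + A/(1 + exp[r_max(τ₁/₂ − t)]), and panels recorded at several
   chaperone molar ratios are fitted globally with the integrated rate law
   of nucleation–elongation–secondary nucleation,

   M(t)/M(∞) = 1 − [ (B₊+C₊)/(B₊+C₊e^{κt}) · (B₋+C₊e^{κt})/(B₋+C₊) ]^{k∞²/(κ·k̃∞)} · e^{−k∞t},

   with λ = √(2k₊kₙm₀^{n_C}), κ = √(2k₊k₂m₀^{n₂+1}), under the constraint
   that exactly one of kₙ, k₊, k₂ varies across ratios. Ranking the three
   constrained fits by residual sum of squares identifies which microscopic
   step the chaperone inhibits.

Supporting modules cover SEC-based oligomer subunit estimation (peak + FWHM
through a log-linear calibration), CD mean-residue-ellipticity conversion,
Trp emission-maximum detection, seeded synthetic-data generators for every
input, and a config-driven orchestration layer (`run_amorphous()`,
`run_amyloid()`) that writes TSV/JSON outputs with a hashed manifest.

## Worked example

Score a synthetic variant panel, quantify activities from a generated
turbidity plate, fit the hydropathy–activity line and predict a new
variant:

```r
library(loopchap)
bio <- load_scale("biological")

cfg    <- generator_config(seed = 11, n_variants = 12)
vp     <- gen_variant_panel(cfg, bio)                 # motifs + ground truth
tp     <- gen_turbidity_panel(cfg, vp$truth)          # plate + well map
masses <- aggregation_mass_panel(traces_from_plate(tp$plate, tp$map))
scores <- score_panel(vp$motifs, bio)

model <- fit_activity_regression(scores, masses)
model
#> Hydropathy-activity regression (aggregation mass % ~ combined hydropathy)
#>   hydropathy scale: biological
#>   substrate:chaperone ratio: 1:1
#>   n = 12 variants | slope = -3.023 %/unit | intercept = 40.32 %
#>   R^2 = 0.948 | p(slope) = 9.47e-08 | residual sd = 5.15 %

new <- motif_set("candidate", "LIF", "AVI", "MLV", "T")
predict(model, motif_hydropathy(new, bio), clamp = TRUE)
#>   variant_id combined   fit   lwr   upr
#> 1  candidate     2.71 32.12 25.62 38.63
```

Reading: the panel was generated with true slope −3%/unit and intercept
40% plus 5% noise, and the fit recovers both (−3.02, 40.3) with R² = 0.95.
The strongly hydrophobic candidate motifs (combined score +2.7 kcal/mol on
the oriented biological scale) are predicted to leave only 32% of the
control aggregation mass, i.e. to suppress about two thirds of substrate
aggregation, with a 95% mean-response interval of 26–39%.

For the amyloid side, `gen_tht_panel()` → `normalize_panel()` →
`global_fit(panel, "all")` returns the three candidate mechanism fits
ranked by residual sum of squares; on panels generated with secondary
nucleation suppressed, the k₂-free model ranks first and recovers the
per-ratio suppression factors. See the methods vignette
(`vignettes/loopchap-methods.Rmd`) for the models, parameterization and
validity limits.

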