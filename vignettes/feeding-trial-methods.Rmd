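---
title: "Methods: quantifying dietary protein quality in fishmeal-replacement trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dietary protein quality in fishmeal-replacement trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquatrial)
```

## The problem

Fishmeal is the reference protein for aquafeeds, but supply is capped, so
trials routinely test blends of alternative proteins as substitutes. The
statistical question such a trial poses is not just "did the fish grow" but
*which property of the diet predicts growth*. Chemical amino-acid
composition alone often fails to discriminate: blends are deliberately
formulated so that all diets carry nearly the same essential amino acid
(EAA) pattern. What differs between blends is how digestible those amino
acids are. This package implements the analysis chain that makes that
argument quantitative: formulate the diets, measure digestibility with an
inert marker, score protein quality on a digestible basis, and regress
growth on the score to estimate the quality threshold that saturates growth.

The packaged example is a gibel carp (*Carassius gibelio*) trial: one 15%
fishmeal control plus three blends of *Tenebrio molitor* meal, *Chlorella*
meal, *Clostridium autoethanogenum* protein (CAP) and cottonseed protein
concentrate (CPC), at ratio parts 1:1:8:2 (A), 1:1:6:4 (B) and 1:1:4:6 (C),
each replacing 1/3, 2/3 or all of the fishmeal — ten diets, three cages of
70 fish per diet, 56 days.

## Diet formulation

Replacement is isonitrogenous: the blend mass substituting fishmeal mass
`m` is `m × f`, where the protein-equivalence factor
`f = CP_fishmeal / CP_blend` and `CP_blend` is the ratio-weighted mean crude
protein of the blend components. The blend mass is split across components
proportionally to their ratio parts, and a cellulose filler closes the
formulation to 100% of dry matter. Replacement levels printed as 33% and
67% are treated as exactly 1/3 and 2/3, which is what the published
inclusion table implies (fishmeal 10.00 and 5.00 from a 15.00 base).

The original trial report never states its equivalence factors. Back-deriving
them from the published inclusion columns gives 0.912, 0.96 and 1.008 for
blends A, B and C, and those constants ship as `trial_blend_factors()`;
with them the formulation engine reproduces every published blend-ingredient
cell to 2 decimals. `equivalence_factor()` derives factors from ingredient
crude-protein values instead, which keeps the engine general — the packaged
synthetic ingredient profiles give factors of 0.88–0.97, close to but not
equal to the back-derived constants, confirming that the exact rule behind
the published numbers is not recoverable from crude protein alone.

Dietary amino-acid composition is linear mixing:
`content_aa = Σ_i inclusion_i/100 × content_{i,aa}`. Oil and energy
balancing are out of scope; per-diet oil inclusions are accepted as given.

## Marker-based digestibility

With an indigestible marker (yttrium trioxide, 0.10% DM) the apparent
digestibility coefficient of any substance is

    ADC (%) = 100 × [1 − (feces_conc / diet_conc) × (marker_diet / marker_feces)]

For dry matter both concentrations are 100, so
`ADC_DM = 100 × (1 − marker_diet/marker_feces)`. Two design choices matter:

* **Negative ADCs are kept, flagged, never clamped.** They are
  mathematically possible under assay noise, and clamping would bias pooled
  statistics.
* **Pooled ADCs ("total EAA", "total NEAA") apply the formula to summed
  concentrations**, not to the mean of the individual ADCs. The mean-of-ADCs
  alternative weights trace and abundant amino acids equally and is not the
  marker-ratio formula applied to the total; the pooled value always lies
  between the component extremes.

## Protein-quality indices

The essential amino acid index over the nine EAAs (lysine, methionine,
threonine, arginine, leucine, isoleucine, valine, phenylalanine, histidine)
is

    EAAI (%) = 100 × ( ∏_i content_i / requirement_i )^(1/9)

and the digestible index substitutes digestible contents:

    DEAAI (%) = 100 × ( ∏_i (content_i × ADC_i/100) / requirement_i )^(1/9)

Numerical and semantic choices:

* **Ratios are not capped at 1.** The classic Oser index caps each ratio;
  the published control value (95.83) only reproduces uncapped, and capping
  would destroy the monotonicity in ADC that the dose-response analysis
  relies on.
* **Exactly nine EAAs.** Tryptophan is excluded from the canonical set —
  it is destroyed by acid hydrolysis and absent from the available
  requirement sets — so `n = 9` is fixed, and the requirement set type
  enforces exactly nine strictly positive entries. The default set for gibel
  carp is lysine 3.30, methionine 0.89, threonine 1.70, arginine 1.50,
  leucine 1.80, isoleucine 1.30, valine 1.70, phenylalanine 1.10, histidine
  0.80 (% DM), injectable via `requirement_set()`.
* **Log-space evaluation.** The geometric mean is computed as
  `exp(mean(log(ratios)))`, which agrees with the direct product to 1e-12
  and cannot overflow.
* **The asparagine row is pooled Asx** (Asn + Asp) as printed; the cysteine
  row behaves irregularly across diets in the original tables and is ingested
  as printed, without correction.

Recomputing the indices from the packaged 2-dp tables reproduces 9 of the
10 published DEAAI cells to ±0.05. The B100 cell does not recompute
(published 83.75; the 2-dp inputs give 83.18) and its EAAI shows the same
pattern (97.50 vs 96.84); these cells were evidently computed from unrounded
laboratory values, so they are documented here rather than "fixed".

## Growth and feed-utilization indices

All footnote formulas are implemented on cage records: SGR =
`100 × (ln fbw − ln ibw)/days`; survival; feeding rate on mean biomass;
feed efficiency crediting dead-fish weight; PER and PRE on protein intake.
The cage is the unit of analysis (three cages per diet). Weights and intakes
must share a basis (per fish or per cage) — SGR is invariant to the choice,
the ratio indices are not, so `cage_record()` carries an explicit basis
flag. Published FE/PER/PRE cannot be recomputed from published group means
(per-cage intakes and dead-fish weights are unpublished); they are exercised
on synthetic records instead.

## The linear-plateau model

Nutrient-requirement thresholds are estimated with the continuous broken-line
model

    y = plateau − slope × max(0, b − x),   slope ≥ 0

For fixed breakpoint `b` the two linear parameters are closed-form least
squares on the regressor `z = max(0, b − x)`, so the breakpoint is profiled:
RSS is evaluated on a 512-point grid spanning `[min x, max x]`, and the best
candidate is refined by golden-section search between its grid neighbours.
The search is fully deterministic — no random restarts — so a fit is exactly
reproducible. When the sign constraint binds (no rising limb), the fit
degenerates to the flat model with `slope = 0`, `plateau = mean(y)`,
breakpoint reported at `min(x)` and an `all_plateau` flag. A
quadratic-plateau variant (`y = plateau − k(b − x)²`) is provided as a
sensitivity check, and on the packaged data it moves the SGR threshold by
less than 0.4 DEAAI units.

The model family was chosen deliberately: the original trial report names only
"nonlinear regression", and the one-breakpoint linear-plateau model is the
standard nutrient-requirement estimator in fish nutrition. On the ten
(DEAAI, SGR) per-diet means the fitted breakpoint is 79.46% DEAAI with
plateau 2.46 %/d — the dietary digestible-quality threshold for maximum
growth. Secondary fits (FE and PRE against DEAAI, crude-protein ADC against
dry-matter ADC) use the same estimator without asserting exact reproduction
of descriptive thresholds. Per-diet means (n = 10) are used rather than
per-cage values, since that is the resolution at which the published
indices exist.

## Group statistics

Duncan's multiple range test is the step-down range procedure on sorted
means: a span of `p` adjacent means is non-significant when its range is
below `R_p = q(1 − α_p, p, df_error) × sqrt(MSE/n_h)`, with protection
level `α_p = 1 − (1 − α)^(p−1)`, studentized-range quantiles computed
numerically (`qtukey`, no lookup tables), and `n_h` the harmonic mean group
size (Kramer adjustment; the packaged trial is balanced so it only matters
for general use). Wider spans shield the comparisons they contain, which is
what makes the letters contiguous over the sorted means. With two groups the
procedure reduces exactly to the pooled two-sample t-test, which the test
suite verifies decision-by-decision. No pre-installed package provides
Duncan's test, so it is implemented here and cross-checked against that
reduction.

The homogeneity check is Levene's test (median-centered, via `car`); it is
reported but does not gate the ANOVA, since the original trial report does not
state a remedy on failure. qPCR relative expression normalizes
`E^(−Ct_target)` by the geometric mean of `E^(−Ct_ref)` over reference
genes and rescales so the calibrator group mean is 1; amplification
efficiency defaults to 2.0 (none is published) and is settable per analysis.

## The synthetic-trial generator

`trial_config()` defaults encode the study conditions: 10 diets × 3 cages ×
70 fish, 56 days, initial weight 15.18 g, feeding rate 3 %BW/d, survival
probability 0.96, dietary crude protein 34.2% DM, marker 0.10% DM. True
amino-acid compositions default to the packaged diet table and true ADCs to
the packaged digestibility table, so the simulated DEAAI span (78.7–83.8)
is the observed one; growth responds through the linear-plateau curve with
breakpoint 79.5, plateau 2.46 %/d and slope 0.25, with cage-mean SGR noise
sd 0.03 %/d. Feces are generated by marker mass balance —
`feces_conc = diet_conc × (1 − ADC/100) / (1 − ADC_DM/100)` with the marker
concentrated by `1/(1 − ADC_DM/100)` — so in noiseless mode the pipeline
returns the true ADCs and DEAAI to 1e-9, a property the tests assert.

Noise models: multiplicative lognormal on assay concentrations (keeps
positivity; CV 2% by default, mean-one parameterization), additive normal on
cage-mean SGR, additive normal on the Ct scale (sd 0.2 cycles). One seed
fixes the dataset; each table type draws from its own derived substream so
adding a table type never perturbs existing draws. `target_deaai` rescales
each diet's EAA ADCs by a common factor to place true DEAAI exactly at a
requested value, which the simulation study uses to span 76–85.

What the generator does **not** emulate: individual-fish growth variance
within cages, fecal leaching or collection losses (marker recovery is
complete up to assay noise), correlations between amino-acid assays, tank
effects, or time dynamics within the trial. Passing tests therefore
demonstrate that the estimators are correct and well-calibrated under the
stated noise models — not that real fecal assays are unbiased.

## Problem sizes and numerical conventions

The test suite and the simulation script use 200 replicates for breakpoint
recovery (median absolute error ~0.035 DEAAI units at 3 cages/diet, noise sd
0.02, 100% of replicates within 0.5) and 400 replicates for the ANOVA
null-uniformity check; both run in seconds. All compositions are stored and
computed at full double precision; 2-decimal rounding happens only at report
rendering, matching how the published tables print. Table I/O is plain
TSV/CSV with full-precision round-tripping (`%.17g`).

## Known limitations

* The published FE/PER/PRE values and the fecal compositions behind the
  published ADC table are not recoverable from printed summaries; those
  paths are validated on synthetic data only.
* The equivalence factors are back-derived constants; the rule that produced
  them (crude-protein matching or otherwise) is not stated in the original trial report.
* The linear-plateau breakpoint has no closed-form standard error here;
  uncertainty beyond the fit diagnostics requires resampling, which is out
  of scope.
* Duncan's test controls the per-comparison protected error rate, not the
  familywise rate; with ten equal groups some letter splitting is expected
  by construction, and the suite records (without asserting) that frequency.
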