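---
title: "The A-MSS: scoring model, validation statistics, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The A-MSS: scoring model, validation statistics, and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amss)
```

## The scoring model

The Adapted Murine Sepsis Score treats sepsis severity in mice as a sum
of ten ordinal items, each 0–4. Seven are rater-assigned observational
items (the established MSS: appearance, consciousness, activity,
stimulus response, eyes, respiration rate, respiration quality; subtotal
0–28). Three are quantitative measurements binned onto the same scale —
rectal temperature, glycemia, and percent body-weight loss from the
animal's earliest observation — giving a 0–40 total. The additive form
assumes the items are exchangeable severity indicators; no item is
weighted, which keeps the score computable at the cage side.

### Bin-edge conventions

Printed band edges for the quantitative items overlap at several points,
so the package fixes explicit conventions, always resolving an ambiguity
toward the *lower* (healthier) score:

* **Temperature**: the 36–38 °C band is closed on both sides
  (hyperthermia is strict, `> 38`, and scores only 1 — the scale is
  deliberately non-monotone above 38 °C, since early hyperthermia is a
  milder sign than hypothermia); the hypothermia bands are
  `[35, 36) → 2`, `[34, 35) → 3`, `< 34 → 4`.
* **Glycemia**: 148 mg/dL belongs to the 0 band (`≥ 148 → 0`), the
  overlap being resolved conservatively; then `[122, 148) → 1`,
  `[58, 122) → 2`, `(40, 58) → 3`, `≤ 40 → 4`.
* **Weight loss**: bands share printed endpoints, resolved
  left-open/right-closed — the only convention consistent with the
  strict `> 20` top band. Exactly 5% scores 0 and exactly 20% scores 3;
  any weight gain scores 0.

Each scorer is a total function: a fine-grid sweep in the test suite
asserts the five bands partition the domain exactly.

### Missing data

Missing inputs are first-class and never imputed. A row missing any of
the ten items is flagged `complete = FALSE` with an `NA` A-MSS total,
because a partial sum is not comparable on the 0–40 scale; the MSS
subtotal is still reported when all seven observational items are
present. The weight-loss item is undefined whenever the baseline or the
current weight is missing. The baseline is each animal's earliest
observation (time zero in the intended design); comparing to the
previous timepoint instead would make the item depend on sampling
frequency.

### Classification

`classify()` calls an animal septic when its A-MSS total is strictly
above the cutoff (default 3.5, the reference 4 h operating point of the score). With
integer totals and half-integer cutoffs the strictness convention is
unobservable; it is documented for non-integer extensions.

## Hematological indices

`derive_indices()` computes NLR (`neut/lymph`), PLR (`plt/lymph`),
MPV/PC (`mpv/plt`, in fL per 10³ cells/µL), and the baseline-relative
platelet count (`100 · plt / baseline plt`). "Relative platelet count"
is interpreted as percent of the animal's own baseline; a composition
measure (platelet fraction of all cells) would be an alternative
reading, and the implementation isolates the choice in one place so it
can be swapped. A zero denominator yields an `NA` with an explicit
`undefined_*` flag, distinct from plain missingness. Counts are assumed
already dilution-corrected.

## Validation statistics

**ROC.** Candidate cutoffs are midpoints between adjacent distinct
observed scores, with infinite sentinels; sensitivity at a cutoff is the
fraction of diseased scores strictly above it. The AUC is the
trapezoidal area under the ROC polyline, which equals the Mann–Whitney
concordance with ties counted ½ (the test suite asserts this
equivalence against an exhaustive pairwise oracle). The operating cutoff
maximises Youden's J, ties broken toward higher specificity and then the
lower threshold. When the two arms' score supports are adjacent (as in
a cohort where the chosen cutoff 3.5 lies between observed 3s and
4s) the midpoint is a half-integer; when a gap of even width separates
the supports the midpoint is an integer — e.g. positives {4,5,6} vs
negatives {0,1,2} give 3.0. Both are correct outputs of the same rule.

**Correlation.** Pearson's r by the product-moment formula; Spearman's
rho is Pearson on midranks. Two-sided p-values use
t = r·√((n−2)/(1−r²)) on n−2 df, with p = 0 at |r| = 1. The method is
caller-chosen; the package deliberately does not auto-select by a
normality screen.

**Two-way ANOVA.** Treatment × time is a fixed-effects factorial. With
unequal arm sizes (7 vs 8) the design is unbalanced, so sums of squares
use unweighted cell means scaled by the harmonic mean cell size
(Type-III-like); on balanced designs this reduces to the classical
partition, which is how it is cross-checked against `aov()` in the
tests. F ratios use the pooled within-cell mean square. Post-tests
compare the arms within each time level by a pooled-variance t,
Bonferroni-adjusted by the number of time levels (4 on the default
grid), matching the per-timepoint asterisk structure such figures carry.
A design with zero within-cell variance raises a degenerate-data error
rather than returning infinite F values.

`validate_score()` chains these: ROC of the 4 h A-MSS against group
membership, correlations of the early score with the 24 h hematological
severity markers, correlations of both score totals with 24 h glycemia,
temperature, and body weight, and the factorial ANOVA of the total.
Correlations against *body weight* are reported with negative sign in
septic cohorts; the correlation against *loss percent* is its mirror
image and is reported alongside, since figures of this kind
sometimes plot the signed weight change instead.

## The cohort simulator

`generate_cohort()` emulates a two-arm fecal-peritonitis study: 7
control and 8 sepsis animals observed at 0/4/12/24 h. Each variable
follows a trajectory — baseline distribution across animals, per-hour
control drift (0 by default), additive sepsis deviations anchored at the
study grid and linearly interpolated elsewhere, residual noise, and
physiological truncation bounds. The default deviations encode the
qualitative dynamics of this model: glycemia falling from the
normoglycemic band (~160 mg/dL) into severe hypoglycemia (≤ 40 by
24 h), temperature below 34 °C at 24 h, ~16% weight loss at 24 h,
platelet decline, a 12 h neutrophil peak returning toward baseline by
24 h, and 24 h lymphopenia/monocytopenia. The white-cell count is built
as neutrophils + lymphocytes + monocytes + a small unclassified
component, so the differential can never exceed the total.

Observational items follow a latent-severity model: each sepsis animal
has a severity curve (0 at baseline, rising to a plateau), and each item
is `clamp(round(severity + item offset + noise), 0, 4)` with
round-half-away-from-zero (avoiding R's banker's rounding so noise-free
cohorts are exactly reproducible). The shared latent severity induces
the inter-item correlation an additive score assumes. A per-animal
severity factor (normal, mean 1, SD 0.25, truncated at 0.3) scales both
the severity curve and every physiological deviation, so a weak
responder is weak everywhere — this is what produces occasional
sub-cutoff sepsis animals, mirroring the reference sensitivity of 87.5%
(one of eight animals below the 3.5 cutoff at 4 h).

The 4 h calibration deserves note: defaults were chosen so that the
simulated 4 h score distributions reproduce the reference operating
point — controls reaching ~3, sepsis animals starting adjacent, median
ROC cutoff 3.5, specificity near 100% and sensitivity in the 90s —
rather than maximising separation, which would be easy but unfaithful.

Randomness is split per stream (`animal/variable`) from the single
config seed by a deterministic string hash, so adding a variable to the
generator does not perturb the draws of the others, identical
configurations are byte-identical on disk, and the caller's RNG state
is untouched. `effect_scale = 0` yields a null cohort (both arms
identically distributed; the 4 h AUC then averages 0.5 across seeds,
which the tests verify over 200 seeds), and `noise_scale = 0` yields a
noise-free deterministic cohort (all control totals 0, sepsis totals
strictly increasing over the grid).

What the simulator does *not* model: pathophysiological mechanism (no
LPS/cytokine dynamics — the trajectories are descriptive Gaussians with
truncation), mortality or censoring (none occurred within the 24 h
window being emulated), circadian structure, or rater bias in the
observational items. Passing tests on synthetic cohorts therefore
demonstrate that the scoring and validation machinery recovers
differences that exist by construction; they are not evidence about any
particular real cohort.

```{r pipeline}
cohort <- generate_cohort(default_config(seed = 42))
v <- validate_score(cohort)
glance(v)
```

## Problem sizes and numerical choices

The test suite and the acceptance script use the study-sized cohort (15
animals × 4 timepoints), 100 seeds for recovery-rate estimates, and 200
seeds for null calibration — large enough for stable fractions at the
asserted margins while keeping a full run in minutes. Oracle-equivalence
checks (AUC vs concordance, factorial ANOVA vs the linear-model fit,
Spearman vs Pearson-on-midranks) run on hundreds of small random
instances (n ≤ 30), where exhaustive enumeration is exact. Band
boundaries are compared with plain floating-point comparisons — scores
are defined on measured quantities, so values epsilon-close to a bin
edge take the side the comparison lands on; no snapping is applied.

## Limitations

* The rubric's observational items remain subjective; the package
  validates their range, not their assignment.
* The unweighted-means ANOVA is one of several defensible unbalanced
  decompositions; sequential (Type-I) sums of squares would differ.
* AUC confidence intervals (e.g. DeLong) and repeated-measures or
  mixed-effects longitudinal models are out of scope.
* Simulator defaults are tuned to band-relevant ranges of the rubric and
  the reference operating point, not to any raw animal data, which are
  not public.
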