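---
title: "Models and methods: pain-sensitivity classes, psychophysics, and brain–rating dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic test bed does and
does not establish about real data.

## 1. The generative rating model

A trial's noiseless rating follows Stevens' power law on the
baseline-offset scale,

$$\text{rating} = e^{\,b\,\ln \Delta + c}, \qquad
\Delta = |\,\text{level} - \text{baseline}\,|,$$

clipped to the VAS range [0, 10], with the rating at or below baseline
defined as 0. All logarithms are natural: the class coefficient pairs the
generator uses (e.g. b = 2.93, c = −5.49 for the high-sensitivity intensity
curve) produce plausible VAS values at 48 °C only under ln — under log10 the
same pair yields ≈ 0.006 — so ln is adopted throughout, in the generator and
in every fit.

Trial noise is placed on the log-response scale,
$\exp(\ln(\mu + \varepsilon) + \mathcal N(0, \sigma^2)) - \varepsilon$ with
$\varepsilon = 0.01$, then clipped. A multiplicative error structure keeps
the model exactly recoverable by regression in double-log space and makes
the 35 °C baseline emit near-zero ratings without a special case. The noise
law of real VAS ratings is unknown; the log-normal choice is a modelling
convention, not an inference about any study.

Default study conditions: 101 participants in three latent classes
(High/Moderate/Low, deterministic largest-remainder allocation 23/41/37);
familiarization 8 temperatures (35, 43–49 °C) × 4 repetitions; scanner tasks
heat 17 × 48 °C / 4 × 47 °C, cold 4 × 0.5 °C / 1 × 3 °C, auditory
5 × 90 dB / 2 × 80 dB; trial noise sd 0.15 (log scale); 28 participants
missing the cold task and 4 the auditory task. Cold uses the reversed
gradient Δ = 35 − level; auditory uses a 70 dB quiet baseline.

**Participant heterogeneity.** The latent-class model treats the class curve
as the participant's curve, so the heat generator adds no per-participant
effect beyond trial noise — a shared per-participant shift of $c$ would
induce within-class feature correlations that the diagonal-covariance
mixture (Section 2) cannot represent, confounding a test of the selection
logic with deliberate model misspecification. Cold (sd 0.3) and auditory
(sd 1.0) *do* carry per-participant log-constant shifts, shared between the
two measures of a modality: wide interindividual variation in loudness
ratings is what makes the auditory covariate analysis informative, and
neither modality feeds the heat-only class features. The auditory defaults
produce high-intensity ratings averaging ≈ 1 VAS with a long right tail,
the shape typical of loudness ratings in a non-noxious control condition.

## 2. Sensitivity classes

Features are the per-participant mean intensity and unpleasantness ratings
at 43–49 °C (14 features; 35 °C is excluded everywhere). Mixtures with
k = 1…5 Gaussian components are fitted by EM with:

* **diagonal covariances** — with ~100 observations in 14 dimensions a full
  covariance per class is ill-conditioned; diagonal structure is the
  standard latent-profile convention;
* variance ridge floor 10⁻⁶; convergence at relative log-likelihood change
  ≤ 10⁻⁸, at most 500 iterations;
* 20 kmeans++-style restarts per k, best log-likelihood kept, seeded for
  reproducibility;
* BIC = −2 log L + p log n with p = (k − 1) + 2kd counted explicitly
  (weights, means, diagonal variances) because model comparison depends on
  the count;
* hard assignment by maximum responsibility, ties to the lowest index.

Selection applies two rules in order: models whose smallest class holds
≤ 10 % of participants are *spurious* (over-extraction) and eliminated;
among survivors the lowest BIC wins. On default synthetic cohorts the 4- and
5-class fits reliably produce spurious classes — the penalized likelihood
happily isolates a handful of participants — so the rule, not BIC, is what
disqualifies them; this is the intended behaviour of the procedure. Classes
are then labelled Low/Moderate/High by the grand mean of their mean feature
vector. Absolute BIC values depend on the software's parameterization and
are not comparable across implementations; the selection *logic* is the
contract, and tests verify it (plus agreement of the EM itself with an
independent mixture implementation on clean data).

## 3. Power-function fits

Per class and measure, the class mean rating (mean over participants of
per-participant means — whether pooled or averaged log-ratings were used in
comparable analyses is typically unstated; averaging-then-logging is this
package's declared convention) is regressed in double-log space:
b = slope, c = intercept, F on (1, n−2) df for the slope. Points with mean
rating ≤ 0 are dropped with a warning rather than offset — an additive
offset would bias b, and no principled offset exists. The noiseless
generator is inverted exactly (machine precision); under trial noise sd
0.15 at the 7 × 4 design the median exponent error stays below 0.3.
The characteristic ordering — unpleasantness exponents above intensity
exponents, constants below — holds in the generator defaults and is
verified by `compare_exponents()`.

## 4. Discrimination thresholds

Binarization is strict (`>` reference mean ascending, `<` descending; ties
0), with the reference rating defined as the participant's *mean* rating at
the reference temperature (a per-trial reference would be equally
consistent with the verbal definition; the mean is the declared
convention). The descending comparison set is 43–48 °C: the innocuous
baseline is excluded from noxious-range analyses. The logistic predictor is
absolute temperature in °C, so −intercept/slope is itself a temperature on
the reporting scale of the 43.5/48.5 edge values.

Degenerate patterns:

* all indicators 1 → edge value (43.5/48.5 °C), no fit — discrimination
  finer than the 1 °C grid;
* all indicators 0 → censored half a degree past the farthest comparison
  temperature (49.5/42.5 °C), flagged; the source procedure defines only
  the all-discriminated case, so the censoring mirror is this package's
  choice;
* perfect separation (MLE undefined) → midpoint between the highest all-0
  and lowest all-1 temperature, flagged;
* fitted thresholds clamped into [43.5, 49.5] (ascending) and [42.5, 48.5]
  (descending) so the reported scale matches the attainable range.

Low trial noise relative to the 1 °C steps makes many synthetic
participants hit the all-discriminated edge — the very situation the edge
rule exists for. Class comparisons use Kruskal–Wallis plus Dunn post-hoc z
from pooled rank sums with the same tie correction; the adjustment method
behind published "adjusted p" values is typically unnamed, so Bonferroni
over the three pairwise tests is the default, selectable via
`p.adjust.methods`.

## 5. Mass-univariate brain analyses

The package starts from per-subject contrast maps (a subjects × in-mask
voxel matrix tied to a 3-D grid); no time-series modelling is attempted.
Group models are ordinary least squares — mixed-effects weighting of
first-level variances is not reproducible from contrast maps alone.

* **Paired contrast**: one-sample t on high − low differences, df n − 1.
* **Covariate GLM**: per-voxel OLS on the mean-centered rating, df n − 2.
  Centering makes slopes invariant to constant rating shifts (verified).
* t (or one-sided F) statistics map to z by the normal-quantile transform,
  capped at |z| = 40 where tail probabilities underflow.
* **Cluster inference**: 6-connectivity components of |z| ≥ 3.1 (the most
  conservative standard neighbourhood, stated for reproducibility);
  positive and negative clusters are reported separately. The max-cluster-
  size null is built by sign-flipping (paired) or covariate permutation
  (GLM) — exact under exchangeability, with corrected
  p = (1 + #{null ≥ obs}) / (n_perm + 1); Gaussian-random-field correction
  is deliberately not used, since smoothness estimation is undefined on
  synthetic grids. Defaults z = 3.1, α = 0.05, 1000 permutations.

**Calibration and discreteness.** On unsmoothed i.i.d. noise the
suprathreshold voxels at z ≥ 3.1 are isolated specks; the max-cluster-size
statistic then takes only 2–3 integer values and the permutation test,
while valid, is far more conservative than nominal. Cluster-extent
inference presumes spatially smooth fields — as real z-maps are — so the
type-I calibration study in the test suite draws subject maps smoothed with
a Gaussian kernel (σ = 1.5 voxels, FWHM ≈ 3.5 voxels, the scale of common
fMRI smoothing) and forms clusters at z = 2.3, where the null spreads over
many sizes; there the empirical FWE sits in the nominal band. The
generator's planted-effect maps are left unsmoothed: their effects are
block-shaped and far above threshold, where discreteness is irrelevant.

## 6. Signature expression and LASSO-PCR

Signature expression is the dot product of a beta map with a voxel-weight
pattern, restricted to the signature's own mask; linearity is exact and
tested to machine precision. No published weight map ships with the
package: `synthetic_signature()` builds a synthetic pattern aligned with
the generator's planted blob, which suffices for the structural claims
(positive expression in every subject under aligned planting, paired-t df
n − 1, correlation df n − 2).

LASSO-PCR per outer fold: center training maps → full-rank PCA
(min(n_train − 1, voxels) components; the L1 penalty does the selection) →
lasso on component scores with λ minimizing inner 5-fold CV MSE over a
50-point path down to 10⁻³·λ_max → predict held-out subjects; 5 outer folds
× 5 repeats, every subject tested once per repeat. Cross-validation error
is RMSE in VAS units, with MAE alongside (which of the two a given "CV
error in VAS units" denotes is often unstated; RMSE is the declared
primary).

**The prediction r.** Pooling held-out predictions across folds and
correlating with the observed ratings is biased *negative* under the null:
when the inner CV selects the empty model, each fold's prediction is its
training mean, which anti-correlates with the held-out fold's ratings by
construction (≈ −1/√(fold size) ≈ −0.22 at n = 101, k = 5). The package
therefore reports `r` as the mean within-test-fold correlation (constant
predictions contribute 0), which is centred at zero under the null and
approaches 1 under strong coupling, and keeps the pooled value as
`r_pooled` for comparability.

Bootstrap weight inference resamples subjects with replacement and refits
the PCA + lasso pipeline per sample with λ fixed at the full-data
CV-selected value (re-running the inner CV 5000 times adds cost, not
validity, to a weight-stability z); z = mean/sd of each voxel's weight
across samples. The default 5000 samples can be scaled down for desk-scale
work; tests verify a few hundred samples already rank planted voxels above
noise and correlate > 0.9 with a larger run.

## 7. The dissociation regimes

`generate_beta_maps()` plants a 4×4×4 effect blob inside an ellipsoidal
mask on a 16³ grid (≈ 1100 in-mask voxels — small enough for desk-scale
permutation studies) with amplitude gain_cond · s_p, gain_high > gain_low:

* **coupled**: s_p is the participant's true mean high-intensity rating —
  activation tracks perception between individuals;
* **dissociated**: s_p is a constant (4 VAS, a typical cohort mean) — the
  within-individual stimulus effect survives, the between-individual
  rating relationship is absent.

Under defaults (gains 0.5/0.25 contrast units per VAS unit, voxel noise sd
1) the paired high-vs-low contrast is detected in both regimes, while the
covariate GLM and LASSO-PCR find a rating relationship only under
coupling — the dissociation pattern the pipeline's `findings.json` asserts
per modality (heat and cold dissociated, auditory coupled, overridable).

## 8. Problem sizes and limitations

The simulation studies in the test suite use: 50 cohorts of n = 101 for
class recovery; 50 seeds per regime (300-permutation cluster nulls, 2-repeat
LASSO-PCR) for the dissociation contrast; 1000 null replicates each for the
Kruskal–Wallis and Pearson calibrations and 400 for the cluster FWE; these
sizes put binomial uncertainty well inside the asserted bands while keeping
the default test run desk-scale.

What passing tests show — and what they do not: the synthetic generator
emulates rating structure, class separation, missingness and the two
coupling regimes, but not hemodynamic time series, spatially structured
physiological noise, motion, session-order effects, or rating-scale usage
idiosyncrasies (end-aversion, anchoring). Recovery and calibration results
therefore validate the *procedures* under their stated assumptions; they do
not certify effect sizes or error rates on real cohorts. Absolute BIC
values are implementation-specific; only selection behaviour transfers.
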