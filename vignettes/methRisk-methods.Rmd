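---
title: "Methods: methylation-based risk classification from systemic epigenetic variation"
author: "methRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-based risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and rationale

DNA methylation in whole blood is cell-type-specific, which makes
blood-based epigenetic classifiers of brain disorders fragile: a signal
may reflect leukocyte composition or exposures rather than anything
shared with the brain. `methRisk` builds case-control classifiers on
two feature families chosen to sidestep this problem:

* **CoRSIV regions** — genomic regions of correlated, systemic
  interindividual variation, where one person's methylation is similar
  across tissues. Probes within a region are averaged into a single
  variable, since their values are mutually correlated.
* **High range 2-98% probes** — probes ranked by the difference between
  the 98th and 2nd percentile of their beta values across samples.
  Unlike variance, this inter-percentile range rewards bi- and
  trimodal probes with well-separated modes ("epiallele-like"
  behaviour), which empirically also show blood-brain concordance.

Known smoking-associated probes are excluded before any selection or
fitting, and cell-composition estimates plus a methylation-derived
smoking score enter as explicit covariates so that their contribution
is visible in the variable importance ranking rather than hidden in
the probes.

## The sparse PLS-DA core

The classifier is a two-component sparse partial least squares
discriminant analysis. The design matrix `X` (samples x variables) is
centered and scaled to unit variance, as is the two-column dummy
encoding `Y` of the class labels. Per component `h`:

1. initialise the Y-side weight from the dominant right singular
   direction of `X_h' Y_h`;
2. iterate: `a <- X_h' Y_h b`; soft-threshold `a` with the
   `(keep+1)`-th largest absolute entry as the threshold, so exactly
   `keep[h]` entries remain nonzero; normalise `a`; `t <- X_h a`;
   `b <- Y_h' t / ||Y_h' t||`; stop when the weight vector changes by
   less than `tol` (default `1e-6`) in the max norm, or after
   `maxIter` (500) iterations — non-convergence is flagged on the
   model, never silent;
3. store the score `t_h` and loading `c_h = X_h' t_h / t_h' t_h`;
   deflate both blocks by regression on `t_h`.

Numerical conventions, all recorded in the serialized model:

* sign of each component fixed by making the largest-magnitude weight
  entry positive (removes the inherent sign ambiguity);
* explained variance of component `h` is
  `||t_h c_h'||^2_F / ||X_1||^2_F` on the scaled matrix;
* zero-variance columns are dropped with a warning before scaling;
* missing values are imputed by *training* column means, stored in the
  model so that test-time imputation reuses them — test data never
  influence any training statistic;
* two-column dummy coding (one per class) with regression deflation of
  `Y`; with two classes this spans the same score subspace as a single
  contrast column, and the sign rule removes the remaining rotation
  ambiguity.

With `keep` equal to the number of variables the iteration reduces to
dense PLS-DA, and the first weight vector coincides with the first
left singular vector of the scaled cross-covariance — this dense limit
is exercised as an oracle test, and an independent implementation
(mixOmics) is used as a cross-check of the sparse selection in the
test suite.

## Risk distance and PPV evaluation

The fitted 2-D scores are projected onto the unit vector along
`(v1, v2)`, the per-component explained variances: components that
capture more variance contribute proportionally more to the risk
axis. The projection is **signed** — an unsigned Euclidean norm cannot
distinguish case-like from control-like samples, and controls are
expected to sit at negative values. The orientation sign is chosen so
training cases have the larger mean. "Risk distance" of a new sample
is this signed scalar projection, computed from the stored model
parameters (imputation means, centering, scaling, rotation).

Evaluation anchors cutoffs on the *training controls*: a sample is
called positive when its risk distance strictly exceeds
`control_mean + m * control_sd` (SD with divisor n-1) for SD multiples
`m` in `{1, 1.5, 2, 2.5, 3}`. Per cutoff the table reports positives,
true and false positives, and PPV (`NA`, never a NaN, when nobody is
called positive). The smallest `m` achieving a target PPV (default
80%) is found by piecewise-linear interpolation between adjacent grid
points; when no interval brackets the target the quantity is flagged
undefined rather than extrapolated. Both the number of positives and
the number of true positives at the interpolated cutoff are reported,
since "individuals classified" can reasonably mean either. Strict
inequality at the cutoff is a determinism choice; ties on a continuous
score are measure-zero.

AUROC is the Mann-Whitney rank statistic with midranks for ties.
Cross-validated AUROC uses stratified folds; held-out samples are
scored by the signed first-axis projection, oriented on the training
fold.

## The synthetic cohort generator

Real HM450 cohorts cannot ship with a package, so the generator
produces cohorts with the statistical structure the method relies on,
plus ground truth (`SimTruth`) for recovery tests.

**Epiallele mixture.** Each CoRSIV region draws, per individual, a
latent methylation level from a 3-state mixture with means
`(0.15, 0.50, 0.85)` and probabilities `(0.25, 0.50, 0.25)` —
reproducing the tri/bimodal beta-value histograms seen at systemic
probes. All probes of a region share the latent; observed betas add
Beta-distributed noise with concentration `precisionBlood` (default
50, giving within-region correlation ~0.9 and per-probe SD ~0.07 at
mid-range, typical of array replicates).

**Disease model.** Case status follows a liability threshold:
`L = w_g * PRS + w_m * D + e`, `e ~ N(0,1)`, case when `L > 0`, with
`D` the mean latent deviation of the informative regions. Individuals
are rejection-sampled to the case/control quotas, since the cohorts
emulated are case-control designs, not population samples. The
PRS-methylation coupling tilts informative-region state probabilities
exponentially by `kappa * PRS` (`p_k(theta)` proportional to
`p_k exp(theta mu_k)`), so part of any PRS effect on liability flows
through methylation — an mQTL-like channel. Because the tilt is an
exponential family, the mean latent responds to the tilt with slope
`Var(mu)`, giving a closed-form **generative mediated fraction**
`w_m c / (w_g + w_m c)` with `c` the PRS-averaged slope; the inverse
helper `liabilityWeightsForFraction()` solves for weights achieving a
target fraction.

**Planted case effect.** Informative regions additionally receive a
case-specific tilt solved (by 1-D root finding on the PRS-averaged
mean) so that the expected case-minus-control difference equals
`deltaBeta` exactly. Implementing the effect as a state-probability
tilt rather than a mean shift preserves bimodality under the effect.
When `deltaBeta = 0` no re-draw happens and the liability pathway is
exactly as specified — the configuration used for mediation recovery.

**Nuisance structure.** Designated smoking probes are hypomethylated
by 0.15 in smokers; smoking status is drawn per label with a
configurable case odds ratio (default 3, reflecting heavier smoking
among cases); the smoking-score covariate is a fixed weighted sum of
hypomethylation at those probes. Cell-composition probes are linear in
Dirichlet-distributed leukocyte fractions (default concentration
dominated by granulocytes, as in whole blood). Remaining probes are
unimodal noise.

**Determinism and streams.** All randomness derives from `seed`
through fixed sub-streams per component (samples, informative latents,
covariates, probe noise), so adding probes never perturbs sample
labels, and identical seeds give bit-identical cohorts. Per-probe
array constants (noise/smoking/cell baselines) are drawn from a
separate `arraySeed` (default fixed) so cohorts simulated with
different `seed`s share the same synthetic "array" — without this,
training and testing cohorts would disagree on probe baselines in a
way no real array does.

**Calibration choices.** The coupling default `kappa = 0.1` was chosen
once so that the correlation between test-set risk distance and PRS in
the flagship scenario lands near the weakly-positive value reported
for real cohorts (~0.3); across seeds the realised correlation centers
in the 0.25-0.45 range. It is a qualitative match, not a calibration
to any cohort. Mediation-recovery scenarios use a stronger coupling
(`kappa = 1`) and a total liability effect of 2 so that the
exposure-mediator-outcome path is well identified at n = 5000; with
weaker, literature-scale effects the proportion-mediated estimator's
sampling error at that n would swamp the quantity being recovered.

**What the generator does not emulate.** No batch or dye-bias
artifacts, no genotypes (PRS is a scalar), no probe-level annotation
errors, no missingness unless configured, and no unknown
smoking-responsive CpGs outside the designated set. Passing recovery
tests therefore demonstrates correctness of the pipeline's machinery
under the assumed generative structure, not performance on real
arrays.

## Multi-tissue panels

`simulateMultiTissue()` emulates matched multi-tissue designs (blood
plus brain regions from the same individuals): a configurable fraction
of probes shares the per-individual latent across tissues (systemic),
the rest draw independent latents per tissue. Cross-tissue screening
computes per-probe Pearson correlations between a reference tissue and
every other tissue over matched individuals; zero-variance probes are
flagged rather than producing undefined numbers. At 67 individuals the
null correlation SD is about `1/sqrt(64) = 0.125`, which motivates the
0.2 bound used for tissue-specific probes in the checks.

## Mediation analysis

`mediation()` asks how much of a continuous exposure's association
with a binary outcome flows through a continuous mediator. Exposure
and mediator are standardized. Two estimators are reported because
they answer subtly different questions:

* `prop_mediated_diff = 1 - beta_direct / beta_total` from the two
  logistic fits — simple, but biased on the odds-ratio scale because
  logistic coefficients rescale when a correlated covariate enters;
* `prop_mediated_acme = ACME / (ACME + ADE)` — the counterfactual
  estimator: predicted-probability contrasts for a 1-SD exposure
  change, integrating the mediator's error distribution by
  Gauss-Hermite quadrature (21 nodes; deterministic, so the bootstrap
  is the only stochastic element). This is the estimator that recovers
  the generative mediated fraction in simulation and should be treated
  as the primary quantity.

Confidence intervals are percentile bootstrap over samples. Logistic
fits are checked for separation (fitted probabilities of 0/1, runaway
coefficients, non-convergence) and fail loudly naming the fit; a total
effect indistinguishable from zero flags the proportions as unstable
rather than reporting a meaningless ratio. The two estimators agree in
the rare-outcome, small-effect limit, which is asserted by simulation
in the test suite.

## Colocalization enrichment

`proximityEnrichment()` tests whether a model's probes sit closer to
trait-associated SNPs than an equally sized random draw from the probe
background. Drawing the null from the *probe background* (not from
genome-wide positions) respects the array's design constraints. The
statistic is the count of model probes whose interval, extended by
`windowBp` (default 50 kb, configurable) on both sides, overlaps at
least one SNP; the empirical P gets the add-one correction
`(1 + #{null >= obs}) / (n_perm + 1)` and so is never zero.
Coordinates are 0-based half-open throughout; the GRanges conversion
shifts starts by one at the boundary.

## Problem sizes used in the checks

The test suite exercises the full pipeline at 400/400 training and
350/320 testing samples on a 2000-probe array with 200 three-probe
CoRSIV regions and 100 informative regions at `deltaBeta = 0.10`; the
acceptance script uses 414/433 and 353/322. Mediation recovery runs at
n = 5000 with 200 bootstrap replicates; enrichment calibration uses
200 replicates of 700 SNPs against a 1000-probe background with 499
permutations each. The label-permuted null is summarised by the median
over five permutations: a single permuted run's PPV curve can touch
any target by small-count noise (two or three chance positives), and
its AUROC inherits a ~0.06 SD from chance alignment with the planted
axis, so the median is the right summary of the qualitative claim that
a null model classifies nobody.

## Known limitations

* Two classes only; no multiclass discrimination or O-PLS variants.
* `keep` is user-set (default 50 per component); no internal tuning
  loop is run, though the union of selected variables is reported so
  users can match a target model size.
* The importance score (`sum_h |W[v,h]| * explainedVariance[h]`) is a
  declared convention; other weightings exist.
* Enrichment ignores linkage disequilibrium among SNPs.
* PPV evaluation is within-cohort; no recalibration to population
  prevalence is attempted.
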