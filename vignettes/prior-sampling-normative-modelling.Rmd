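---
title: "Prior-sampling cVAE normative modelling: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-sampling cVAE normative modelling: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorcvae)
```

## The problem

A normative model is a statistical reference for what a brain measure is
*expected* to be, given a person's covariates.  Individuals are then scored by
how far their observed measures deviate from that covariate-specific norm.
`priorcvae` implements a multivariate normative model for tabular
imaging-derived phenotypes (IDPs) — regional cortical thickness, cortical and
subcortical volumes, and white matter hyperintensity (WMH) lesion loads —
conditioned on seven covariates: age, sex, intracranial volume (ICV), and four
binary vascular risk factors (diabetes, hypercholesterolaemia, obesity,
smoking).

The core model is a conditional variational autoencoder (cVAE) with a
probabilistic Gaussian decoder, trained on a healthy (normotensive) reference
cohort.  The defining choice of this package is the **inference strategy**:
predictions are generated by **prior sampling** — latent vectors drawn from the
standard-normal prior, decoded together with the covariates, with the observed
brain measures never consulted.  This preserves the normative-modelling
contract (a pure covariate-based norm) that the conventional
**posterior-sampling** strategy, which encodes the observations before
decoding, violates.  Posterior sampling is also implemented, deliberately, as
the comparison method.

## Model and training objective

All features are z-scored on the training set; WMH volumes, which are heavily
right-skewed with many exact zeros, are first mapped through
`log(raw + offset)` with `offset = 1` mm³ (so a zero lesion load maps to zero;
the offset is configurable because no canonical choice exists).  Age and ICV
are z-scored; binary covariates pass through as 0/1 (sex: male = 1).  SDs use
the sample (n − 1) convention throughout so test expectations are exact.

The encoder maps `[Y, X]` through ReLU hidden layers (default: one layer of
512 units) to the mean and log-variance of a Gaussian posterior over a latent
`z` (default 64 dimensions); the decoder maps `[z, X]` to the mean and
log-variance of a Gaussian over `Y`.  Training minimises the negative evidence
lower bound

    loss = mean over batch [ KL( N(mu_z, s_z^2) || N(0, I) ) + NLL(Y | mu_Y, s_Y^2) ]

with the KL in closed form summed over latent dimensions and the Gaussian
negative log-likelihood summed over features.  Summing (rather than averaging)
over features keeps the two terms on the scale the bound implies; losses are
therefore comparable only at fixed F, which is documented here on purpose.
Both log-variance heads are clamped to [−10, 10] for numerical stability, a
choice the objective itself does not dictate.  Optimisation uses Adam
(default learning rate 1e−3, batch 256), a seeded uniform 10% validation
split (no stratification), early stopping with patience 20 epochs, and
restoration of the best-validation-epoch parameters.  A seeded random-search
tuner with k-fold cross-validation (`tune_hyperparameters()`) stands in for a
full Bayesian hyperparameter study; trials that diverge are scored `Inf`
rather than aborting the search.

The network, its analytic gradients, and Adam are implemented directly in
matrix code; the gradient implementation is verified against central finite
differences in the test suite (tolerance 1e−4 relative on a pencil-sized
network).

## Prior-sampling inference and the law of total variance

For each of `K` Monte-Carlo iterations (default 1000, comfortably above the
~400 needed for stable 95% interval estimates), a latent draw is decoded with
the covariates into a per-iteration Gaussian `(mu_k, s_k^2)`.  These are
aggregated into one predictive distribution per subject and feature:

    mu*    = mean_k mu_k
    s*^2   = mean_k s_k^2              (within-iteration variance)
           + mean_k (mu_k - mu*)^2     (between-iteration variance)

The identity `s*^2 = within + between` holds exactly by construction and is
asserted to 1e−12 in the tests, alongside an empirical check against brute-
force sampling from the K-component mixture.  Both variance components mix
aleatoric and epistemic uncertainty; the package does not attempt to
disentangle them.

One design choice deserves a note: a single latent draw per iteration is
shared across all subjects, rather than maintaining per-subject random
streams.  Because latents are independent of covariates, each subject's draws
are still marginally i.i.d. standard normal, and the scheme makes predictions
invariant to subject order and subsetting (to BLAS rounding, ~1e−16) while
keeping the decoder call fully vectorised.  Subjects with identical covariates
receive bitwise-identical predictions under a shared seed.

Deviation scores are `z = (Y − mu*) / s*` on the standardised (for WMH:
log-standardised) scale, with |z| > 2.58 — the outer ~1% of a standard
normal — flagged as an extreme deviation.  Raw-scale reporting of `mu*` is
available via `destandardise()`; a raw-scale `s*` for log-transformed features
is not defined and deliberately not provided.

## The synthetic cohort generator

Restricted cohort data cannot ship with a package, so `generator_spec()` /
`simulate_cohort()` produce cohorts with the statistical structure the method
is designed for, plus exact ground truth for every subject's conditional mean
and SD.  Defaults describe a mid-to-late-life population: age 60.76 ± 7.20
years truncated to [45, 84] (the parent-normal location is solved so the
truncated mean equals the target — naive truncation would bias it upward by
~0.25 years), 30.8% male, prevalences 1.8% / 7.4% / 8.5% / 33.8% for
diabetes / hypercholesterolaemia / obesity / smoking, ICV 1.55e6 ± 1.5e5 mm³.
Blood pressure is bivariate normal (SBP 135 ± 18, DBP 82 ± 10 mmHg,
correlation 0.7) — chosen so that all four hypertension grades (0–3, graded by
the standard SBP/DBP thresholds: 130/85, 140/90, 160/100) arise in realistic
proportions (roughly a third of subjects normotensive).

Features follow a linear model on the transformed scale: intercept plus
effects of the standardised covariates, plus an additive per-level pathology
shift, plus Gaussian noise (optionally age-heteroscedastic).  Category-level
defaults (for example: age −0.06 mm per SD on thickness with noise SD 0.12;
age +0.55 per SD on log-WMH with noise SD 1.2; ICV strongly positive on
volumes) give covariate effects up to ~0.5 noise SDs, varied deterministically
across features within a category.  WMH features are mapped to the raw scale
by `exp(.) − 1`, clipped at zero — the clipping is what produces the requested
zero inflation, and it mildly censors the latent Gaussian left tail.  Default
hypertension shifts on log-WMH are 0 / 0.6 / 1.2 / 2.0 for levels 0–3, strong
enough that graded pathology is detectable at a few thousand subjects (the
matching real-data effects are far smaller but rest on tens of thousands of
subjects); morphometric shifts are small and negative.

What the generator deliberately does *not* emulate: spatial covariance between
regions beyond what shared covariate effects induce (residual noise is
independent across features), longitudinal structure, and site effects.  The
first omission matters for interpretation and is discussed below.

## What the validation battery shows — and what it cannot

* **Parameter recovery.** On a 2,000-subject, 20-feature linear-Gaussian
  cohort, prior-sampling predictive means correlate > 0.9 per feature with the
  generating conditional means (typically > 0.95), and the median relative
  error of `s*` against the generating SD is well under 25% (typically ~4%).
* **Calibration.** The ground-truth oracle's expected calibration error (ECE,
  10 confidence levels from 0.05 to 0.95) stays below 0.02 at n = 5,000, which
  bounds the Monte-Carlo floor of the metric; trained-model ECEs land close to
  it.  A tenfold SD inflation follows the analytic coverage curve
  `2*pnorm(10*qnorm((1+a)/2)) − 1`; note that its ECE (≈ 0.44) approaches the
  often-quoted `mean(1 − a)` = 0.5 only in the infinite-inflation limit.
* **Test machinery.** The median-based permutation test (pooled re-partition,
  empirical p floored at 1/n_perm; exhaustive enumeration whenever the
  partition count fits the permutation budget) holds its nominal size within
  [0.03, 0.07] over 500 null replicates and agrees exactly with full
  enumeration at |A| = |B| = 4.  Cliff's delta, the four accuracy metrics and
  Benjamini–Hochberg FDR match brute-force reimplementations to 1e−10.
  Spearman's coefficient uses Pearson-on-midranks, the standard
  generalisation under ties.
* **Clinical direction.** Level-graded WMH pathology produces positive
  z-versus-level Spearman correlations surviving FDR for all affected
  features, and extreme-positive rates that rise monotonically across levels
  0 → 3 (from under 1% to over 20% under the default shifts).
* **Sensitivity direction.** Perturbing age by +1 training SD moves
  prior-sampling predictions in the generating direction, and a paired
  Wilcoxon test on per-(subject, feature) absolute effects shows posterior
  sampling to be significantly *less* responsive (rank-biserial effect size
  negative, p far below 0.01).  The pairing granularity — (subject, feature)
  cells — and the matched-pairs rank-biserial estimator are package choices;
  other conventions exist.

A caveat the reader should carry: because the generator's residual noise is
independent across features, the encoder posterior gains little information
from the observations beyond what covariates supply, and partially collapses
to the prior.  The posterior-versus-prior contrasts above are therefore
directionally correct but much weaker in magnitude than what correlated,
real-world IDPs produce, where a low-dimensional latent can absorb the
observations almost entirely (making posterior sampling both excellent at
reconstruction and nearly blind to covariate perturbation and pathology —
exactly why it is unsuitable as a normative reference).  Passing these tests
validates the machinery, not the magnitude of real-data contrasts.

## Numerical and design details worth knowing

* Multiple-testing families: FDR is applied within each analysis table
  (one covariate-independence table, one clinical table, one family per
  permutation comparison set), not globally.
* Degenerate inputs: zero-variance features abort standardisation by name;
  constant covariates yield missing correlations with a warning; empty groups
  yield missing extreme rates with a warning; a constant observed vector makes
  Spearman undefined (missing, with a warning) and explained variance an
  error.
* `K < 2` is rejected (between-iteration variance undefined); the
  between-variance accumulator is clamped at zero against catastrophic
  cancellation.
* Checkpoints are a single JSON file (version field included) holding config,
  standardisation state and parameters at full precision.
* Problem sizes in the test-suite and acceptance runs (20 features, cohorts of
  2,000–6,000, latent 8, hidden 64, K = 300–1,000) are desk-scale choices that
  keep the full battery to a couple of minutes while preserving every
  statistical property being asserted; the architecture defaults
  (latent 64, hidden 512) reflect the full-scale setting.

## Known limitations

Regions with sparse pathology (near-zero lesion loads) are poorly served by a
Gaussian likelihood even after the log transform; real analyses should expect
inflated calibration error there.  The model estimates total predictive
uncertainty only.  Fractional-polynomial model selection, GAMLSS- and
HBR-style references are out of scope; the two-stage polynomial baseline
(`fit_baseline()`) exists so the comparison machinery is exercisable, and any
external model can be plugged in through the `predict_normative()` contract
(covariates in, `mu`/`sigma` out, observations never consulted).
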