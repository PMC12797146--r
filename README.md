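# priorcvae

Multivariate normative modelling of brain imaging-derived phenotypes (IDPs)
with a **prior-sampling conditional variational autoencoder**.

A normative model estimates the distribution of a measure expected for a
person's covariates — here age, sex, intracranial volume and four vascular
risk factors — so that individuals can be scored by how far they deviate from
that covariate-specific norm.  `priorcvae` trains a conditional VAE with a
probabilistic Gaussian decoder on a healthy reference cohort and then, at
inference time, never looks at a subject's observed brain measures: latent
vectors are sampled from the standard-normal prior, decoded with the
covariates, and aggregated over K Monte-Carlo iterations by the law of total
variance,

    mu* = mean_k mu_k,      sigma*^2 = mean_k sigma_k^2 + mean_k (mu_k - mu*)^2 ,

into a predictive mean and SD per subject and feature.  Deviation scores
`z = (Y - mu*) / sigma*` flag extreme deviations at |z| > 2.58 (the outer ~1%
of a standard normal).  The conventional **posterior-sampling** strategy —
encoding the observations before decoding — is also implemented, as the
comparison method whose bias towards the observations the prior-sampling
design avoids.

The package also provides:

* a seeded **synthetic cohort generator** with known per-subject ground truth:
  truncated-normal age, Bernoulli risk factors, correlated bivariate blood
  pressure graded into four hypertension levels, linear covariate effects,
  zero-inflated log-normal WMH volumes, and level-graded additive pathology;
* a full **evaluation battery**: median absolute error, RMSE, Spearman's rho,
  explained variance; median-based permutation tests with Cliff's delta and
  Benjamini–Hochberg FDR; expected calibration error over central-interval
  coverage; covariate-perturbation sensitivity analysis (prior vs posterior);
  covariate-independence and clinical deviation analyses;
* a **two-stage polynomial baseline** (least-squares mean + residual-RMSE SD)
  behind a pluggable covariate-only model interface (`predict_normative()`);
* an end-to-end **pipeline** (`run_pipeline()`, with a thin CLI at
  `inst/cli/priorcvae.R`) covering simulate → train → predict → deviations →
  evaluate/calibrate/sensitivity/independence/clinical.

The network, its analytic gradients and the Adam optimiser are implemented
directly in matrix code and verified against finite differences in the tests.

## Worked example

Simulate a cohort, train on its normotensive subjects, and score everyone
against the covariate-only norm:

```r
library(priorcvae)

spec  <- generator_spec(n_subjects = 3000, seed = 42)
sim   <- simulate_cohort(spec)
train <- subset_cohort(sim$cohort, sim$cohort$hypertension_level == 0)

cfg   <- cvae_config(n_features = 20, latent_dim = 8, hidden_dim = 64,
                     batch_size = 128, max_epochs = 150, seed = 1)
model <- train_cvae(train, cfg)
#> <trained_cvae> F=20 latent=8 hidden=1x64; best epoch 147 (val loss 26.5146)

std  <- standardise(model$state, sim$cohort)
norm <- prior_predict(model, std$Xstd, K = 500, seed = 1)
dev  <- deviation_scores(norm, std$Ystd)

clin <- clinical_association(dev, sim$cohort$hypertension_level)
head(clin[order(-clin$r), ], 5)
#>    feature     r         p     p_fdr
#> 20  wmh_05 0.572 7.65e-260 1.53e-258
#> 19  wmh_04 0.555 5.65e-242 5.65e-241
#> 18  wmh_03 0.503 1.55e-192 1.04e-191
#> 17  wmh_02 0.372  2.92e-99  1.46e-98
#> 16  wmh_01 0.329  1.64e-76  6.57e-76
```

The five WMH features — the ones the generator endows with level-graded
pathology — top the table: their deviation scores correlate positively with
hypertension level and survive FDR correction, while morphometric features
(small injected effects) sit far below.  The same gradient shows up as
extreme-deviation rates per level for a single WMH feature:

```r
subset(extreme_rates(dev, sim$cohort$hypertension_level),
       feature == "wmh_03")[, c("group", "pct_pos", "n")]
#>    group pct_pos    n
#> 18     0   0.869 1036
#> 38     1   1.742  689
#> 58     2   6.879 1003
#> 78     3  26.471  272
```

Under 1% of normotensive subjects exceed z = 2.58 (the calibrated healthy
rate), rising monotonically to ~26% at hypertension level 3.

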