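#' @name synthetic_cohort
#' @title Synthetic cohort generation with known ground truth
#'
#' @description
#' A seeded generator producing cohorts with the statistical structure of a
#' large ageing-population imaging study: truncated-normal age, Bernoulli
#' vascular risk factors, normal intracranial volume, correlated bivariate
#' blood pressure from which a four-grade hypertension level is derived,
#' linear covariate effects on the (possibly log) transformed feature scale,
#' log-normal zero-inflated WMH volumes, and additive level-graded
#' hypertension pathology.  The generator records every subject's true
#' conditional mean and SD on the transformed scale, so parameter-recovery
#' and calibration tests have an exact oracle.
NULL

#' Default feature counts for the full-scale preset
#'
#' 62 cortical thickness, 65 cortical volume, 38 subcortical volume and 30
#' WMH features; test-scale cohorts default to 5 per category.
#' @export
full_feature_counts <- c(cortical_thickness = 62L, cortical_volume = 65L,
                         subcortical_volume = 38L, wmh = 30L)

default_category_params <- function() {
  # intercept, covariate effects (per SD of age/ICV, per unit for binaries)
  # and noise SD, all on the transformed feature scale.
  list(
    cortical_thickness = list(intercept = 2.5,
                              effects = c(age = -0.06, sex = 0.02, icv = 0.02,
                                          diabetes = -0.01, hyperchol = -0.01,
                                          obesity = 0, smoking = -0.01),
                              s = 0.12,
                              delta = c(0, -0.01, -0.02, -0.04)),
    cortical_volume = list(intercept = 5000,
                           effects = c(age = -120, sex = 80, icv = 220,
                                       diabetes = -20, hyperchol = -15,
                                       obesity = 0, smoking = -10),
                           s = 450,
                           delta = c(0, -30, -60, -120)),
    subcortical_volume = list(intercept = 4000,
                              effects = c(age = -100, sex = 60, icv = 180,
                                          diabetes = -15, hyperchol = -10,
                                          obesity = 0, smoking = -10),
                              s = 380,
                              delta = c(0, -20, -45, -90)),
    wmh = list(intercept = 2.0,
               effects = c(age = 0.55, sex = 0.05, icv = 0.05,
                           diabetes = 0.10, hyperchol = 0.10,
                           obesity = 0.05, smoking = 0.05),
               s = 1.2,
               delta = c(0, 0.6, 1.2, 2.0))
  )
}

build_default_effects <- function(counts) {
  pars <- default_category_params()
  F <- sum(counts)
  B <- matrix(0, nrow = 8, ncol = F,
              dimnames = list(c("intercept", COVARIATE_NAMES), NULL))
  s <- numeric(F)
  delta <- matrix(0, nrow = 4, ncol = F)
  names_ <- character(F)
  cats <- character(F)
  j <- 0L
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0) next
    p <- pars[[cat]]
    # deterministic per-feature scaling so features within a category differ
    scl <- seq(0.6, 1.4, length.out = k)
    for (i in seq_len(k)) {
      j <- j + 1L
      B["intercept", j] <- p$intercept
      B[c("age_years", "sex", "icv_mm3", "diabetes", "hyperchol",
          "obesity", "smoking"), j] <- p$effects * scl[i]
      s[j] <- p$s
      delta[, j] <- p$delta * scl[i]
      names_[j] <- sprintf("%s_%02d", cat, i)
      cats[j] <- cat
    }
  }
  list(B = B, s = s, delta = delta,
       meta = feature_meta(names_, cats))
}

#' Specify a synthetic cohort generator
#'
#' Defaults emulate the demographics of a mid-to-late-life population cohort:
#' age 60.76 +/- 7.20 years truncated to \[45, 84\], 30.8% male, and risk
#' factor prevalences of 1.8% (diabetes), 7.4% (hypercholesterolaemia),
#' 8.5% (obesity) and 33.8% (smoking).  Blood pressure is bivariate normal
#' (SBP 135 +/- 18, DBP 82 +/- 10, correlation 0.7 mmHg), which yields all
#' four hypertension grades in realistic proportions.
#'
#' @param n_subjects number of subjects to generate.
#' @param counts named integer vector of feature counts per category; the
#'   default gives a 20-feature desk-scale cohort, [full_feature_counts] the
#'   195-feature preset.
#' @param seed master seed; all generator randomness derives from it.
#' @param age_mean,age_sd,age_range age marginal (years).
#' @param sex_prev,diabetes_prev,hyperchol_prev,obesity_prev,smoking_prev
#'   Bernoulli prevalences in `(0, 1)` (0 or 1 allowed for degenerate
#'   columns in tests).
#' @param icv_mean,icv_sd intracranial volume marginal (mm^3).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,bp_cor blood pressure model.
#' @param B effect matrix `8 x F` (intercept row plus one row per covariate)
#'   on the transformed feature scale, applied to standardised age/ICV and
#'   raw 0/1 binaries.
#' @param s positive noise SD vector (length F) on the transformed scale.
#' @param delta `4 x F` additive pathology shifts per hypertension level on
#'   the transformed scale; the level-0 row must be zero.
#' @param meta feature metadata matching `B`/`s`/`delta` columns.
#' @param het_age_slope relative increase of noise SD per SD of age
#'   (0 = homoscedastic).
#' @param wmh_offset offset used when mapping WMH features from the log to
#'   the raw scale.
#' @return a `generator_spec` object.
#' @export
generator_spec <- function(n_subjects = 2000L,
                           counts = c(cortical_thickness = 5L,
                                      cortical_volume = 5L,
                                      subcortical_volume = 5L,
                                      wmh = 5L),
                           seed = 1L,
                           age_mean = 60.76, age_sd = 7.20,
                           age_range = c(45, 84),
                           sex_prev = 0.308, diabetes_prev = 0.018,
                           hyperchol_prev = 0.074, obesity_prev = 0.085,
                           smoking_prev = 0.338,
                           icv_mean = 1.55e6, icv_sd = 1.5e5,
                           sbp_mean = 135, sbp_sd = 18,
                           dbp_mean = 82, dbp_sd = 10, bp_cor = 0.7,
                           B = NULL, s = NULL, delta = NULL, meta = NULL,
                           het_age_slope = 0, wmh_offset = 1) {
  if (n_subjects < 1) stopf("`n_subjects` must be at least 1")
  prev <- c(sex_prev, diabetes_prev, hyperchol_prev, obesity_prev, smoking_prev)
  if (any(prev < 0 | prev > 1)) stopf("prevalences must lie in [0, 1]")
  def <- build_default_effects(counts)
  B <- B %||% def$B
  s <- s %||% def$s
  delta <- delta %||% def$delta
  meta <- meta %||% def$meta
  F <- nrow(meta)
  if (!identical(dim(B), c(8L, as.integer(F)))) stopf("`B` must be 8 x F")
  if (length(s) != F || any(s < 0)) stopf("`s` must be a non-negative vector of length F")
  if (!identical(dim(delta), c(4L, as.integer(F)))) stopf("`delta` must be 4 x F")
  if (any(delta[1, ] != 0)) stopf("level-0 pathology shifts must be zero")
  structure(list(n_subjects = as.integer(n_subjects), counts = counts,
                 seed = seed,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 sex_prev = sex_prev, diabetes_prev = diabetes_prev,
                 hyperchol_prev = hyperchol_prev, obesity_prev = obesity_prev,
                 smoking_prev = smoking_prev,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 sbp_mean = sbp_mean, sbp_sd = sbp_sd,
                 dbp_mean = dbp_mean, dbp_sd = dbp_sd, bp_cor = bp_cor,
                 B = B, s = s, delta = delta, meta = meta,
                 het_age_slope = het_age_slope, wmh_offset = wmh_offset),
            class = "generator_spec")
}

truncnorm_location <- function(target_mean, sd, lo, hi) {
  f <- function(m) {
    a <- (lo - m) / sd
    b <- (hi - m) / sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    m + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z - target_mean
  }
  stats::uniroot(f, c(target_mean - 5 * sd, target_mean + 5 * sd),
                 tol = 1e-10)$root
}

#' Sample covariates and blood pressure
#'
#' Age is drawn from a truncated normal (inverse-CDF method), the binaries
#' from independent Bernoullis, ICV from a normal, and (SBP, DBP) from a
#' correlated bivariate normal.
#'
#' @param spec a [generator_spec()].
#' @return list with `X` (`n x 7` raw covariate matrix), `sbp`, `dbp`.
#' @export
sample_covariates <- function(spec) {
  n <- spec$n_subjects
  # location of the parent normal chosen so the *truncated* mean equals the
  # specified marginal mean (truncation alone would bias it upward)
  loc <- truncnorm_location(spec$age_mean, spec$age_sd,
                            spec$age_range[1], spec$age_range[2])
  with_seed(derive_seed(spec$seed, "covariates"), {
    p_lo <- stats::pnorm((spec$age_range[1] - loc) / spec$age_sd)
    p_hi <- stats::pnorm((spec$age_range[2] - loc) / spec$age_sd)
    age <- loc + spec$age_sd *
      stats::qnorm(stats::runif(n, p_lo, p_hi))
    sex <- stats::rbinom(n, 1, spec$sex_prev)
    icv <- stats::rnorm(n, spec$icv_mean, spec$icv_sd)
    dia <- stats::rbinom(n, 1, spec$diabetes_prev)
    chol <- stats::rbinom(n, 1, spec$hyperchol_prev)
    obes <- stats::rbinom(n, 1, spec$obesity_prev)
    smok <- stats::rbinom(n, 1, spec$smoking_prev)
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    sbp <- spec$sbp_mean + spec$sbp_sd * e1
    dbp <- spec$dbp_mean + spec$dbp_sd *
      (spec$bp_cor * e1 + sqrt(1 - spec$bp_cor^2) * e2)
    X <- cbind(age_years = age, sex = sex, icv_mm3 = icv, diabetes = dia,
               hyperchol = chol, obesity = obes, smoking = smok)
    list(X = X, sbp = sbp, dbp = dbp)
  })
}

#' Grade hypertension from blood pressure
#'
#' Four-level grading: level 0 (normotensive) requires SBP < 130 and
#' DBP < 85 mmHg; level 1 is SBP 130-139 or DBP 85-89; level 2 is
#' SBP 140-159 or DBP 90-99; level 3 is SBP >= 160 or DBP >= 100.  A
#' subject is assigned the highest grade reached by either pressure.
#'
#' @param sbp,dbp systolic / diastolic blood pressure in mmHg.
#' @return integer vector of levels in `0:3`.
#' @export
classify_hypertension <- function(sbp, dbp) {
  if (any(sbp <= 0) || any(dbp <= 0)) stopf("blood pressures must be positive")
  lvl_s <- ifelse(sbp >= 160, 3L, ifelse(sbp >= 140, 2L, ifelse(sbp >= 130, 1L, 0L)))
  lvl_d <- ifelse(dbp >= 100, 3L, ifelse(dbp >= 90, 2L, ifelse(dbp >= 85, 1L, 0L)))
  pmax(lvl_s, lvl_d)
}

#' Sample features given covariates and hypertension levels
#'
#' On the transformed scale each feature is
#' `intercept + B %*% x_std + delta[level] + s * eps`, with `eps` standard
#' normal and `x_std` the covariates standardised by the spec's marginal
#' parameters (binaries passed through).  WMH features are mapped to the raw
#' scale by `exp(.) - wmh_offset`, clipped at zero; other categories are
#' already in raw units.
#'
#' @param spec a [generator_spec()].
#' @param covariates output of [sample_covariates()] (or a compatible list).
#' @param levels integer hypertension levels in `0:3`, one per subject.
#' @param seed optional seed overriding the spec-derived feature stream.
#' @return list with `cohort` (a [cohort_table()]) and `truth` (list of
#'   `mean`, `sd` matrices on the transformed scale plus `level`).
#' @export
sample_features <- function(spec, covariates, levels, seed = NULL) {
  X <- covariates$X
  n <- nrow(X)
  if (length(levels) != n) stopf("`levels` must have one entry per subject")
  F <- nrow(spec$meta)
  age_std <- (X[, "age_years"] - spec$age_mean) / spec$age_sd
  icv_std <- (X[, "icv_mm3"] - spec$icv_mean) / spec$icv_sd
  design <- cbind(1, age_std, X[, "sex"], icv_std, X[, "diabetes"],
                  X[, "hyperchol"], X[, "obesity"], X[, "smoking"])
  mean_t <- design %*% spec$B + spec$delta[levels + 1L, , drop = FALSE]
  sd_t <- matrix(spec$s, n, F, byrow = TRUE) *
    (1 + spec$het_age_slope * age_std)
  if (any(sd_t < 0)) stopf("heteroscedasticity slope drives noise SD negative")
  seed <- seed %||% derive_seed(spec$seed, "features")
  eps <- with_seed(seed, matrix(stats::rnorm(n * F), n, F))
  Yt <- mean_t + sd_t * eps
  Y <- Yt
  lg <- spec$meta$log_transform
  if (any(lg)) Y[, lg] <- pmax(exp(Yt[, lg, drop = FALSE]) - spec$wmh_offset, 0)
  cohort <- cohort_table(sprintf("S%06d", seq_len(n)), X, Y, spec$meta,
                         sbp_mmHg = covariates$sbp, dbp_mmHg = covariates$dbp,
                         hypertension_level = levels)
  list(cohort = cohort,
       truth = list(mean = mean_t, sd = sd_t, level = levels))
}

#' Simulate a complete cohort
#'
#' Covariates, blood pressure, hypertension grading and features in one
#' seeded call.
#'
#' @param spec a [generator_spec()].
#' @param normotensive_only if `TRUE`, keep only level-0 subjects (the
#'   training condition of a normative model built on healthy references).
#' @return list with `cohort`, `truth` and the echoed `spec`.
#' @export
simulate_cohort <- function(spec, normotensive_only = FALSE) {
  cov <- sample_covariates(spec)
  levels <- classify_hypertension(cov$sbp, cov$dbp)
  out <- sample_features(spec, cov, levels)
  if (normotensive_only) {
    keep <- levels == 0L
    out$cohort <- subset_cohort(out$cohort, keep)
    out$truth$mean <- out$truth$mean[keep, , drop = FALSE]
    out$truth$sd <- out$truth$sd[keep, , drop = FALSE]
    out$truth$level <- out$truth$level[keep]
  }
  list(cohort = out$cohort, truth = out$truth, spec = spec)
}
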