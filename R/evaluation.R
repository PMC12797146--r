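#' @name evaluation
#' @title Accuracy metrics, permutation tests, calibration and deviation analyses
#'
#' @description
#' Four per-feature accuracy metrics (median absolute error, RMSE,
#' Spearman's rho, explained variance), a median-based permutation test with
#' Cliff's delta for comparing per-feature metric vectors between models,
#' Benjamini-Hochberg FDR correction, expected calibration error over a grid
#' of central confidence intervals, covariate-perturbation sensitivity
#' analysis contrasting prior- and posterior-sampling inference, and the
#' covariate-independence and clinical deviation analyses.
NULL

check_pair <- function(y, mu) {
  if (length(y) != length(mu)) stopf("vectors must have equal length")
  if (length(y) < 1) stopf("empty input")
}

#' Median absolute error
#' @param y observed values.
#' @param mu predicted means.
#' @return `median(|y - mu|)`; 0 for a perfect prediction.
#' @export
median_ae <- function(y, mu) {
  check_pair(y, mu)
  stats::median(abs(y - mu))
}

#' Root mean squared error
#' @param y observed values.
#' @param mu predicted means.
#' @return `sqrt(mean((y - mu)^2))`.
#' @export
rmse <- function(y, mu) {
  check_pair(y, mu)
  sqrt(mean((y - mu)^2))
}

#' Spearman's rank correlation
#'
#' Rank correlation with average (mid) ranks for ties; a constant input
#' yields `NA` with a warning.
#'
#' @param y observed values.
#' @param mu predicted means.
#' @return rho in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
spearman_rho <- function(y, mu) {
  check_pair(y, mu)
  if (length(y) < 2) stopf("need at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(mu) == 0) {
    warnf("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(y, mu, method = "spearman")
}

#' Explained variance
#'
#' `1 - sum((y - mu)^2) / sum((y - mean(y))^2)`; 1 for a perfect
#' prediction, 0 for the constant-mean predictor, negative when worse than
#' predicting the mean.
#'
#' @param y observed values (non-constant).
#' @param mu predicted means.
#' @return scalar in `(-Inf, 1]`.
#' @export
explained_variance <- function(y, mu) {
  check_pair(y, mu)
  if (length(y) < 2) stopf("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("observed values have zero variance")
  1 - sum((y - mu)^2) / ss_tot
}

#' Per-feature metric table
#'
#' @param Y observed feature matrix `subjects x F`.
#' @param mu predicted mean matrix of the same shape.
#' @param model_label label recorded in the table.
#' @return data.frame with one row per feature: `feature`, `model`,
#'   `median_ae`, `rmse`, `spearman`, `explained_var`.
#' @export
metric_table <- function(Y, mu, model_label = "model") {
  assert_matrix(Y, "Y")
  if (!identical(dim(Y), dim(mu))) stopf("Y and mu shapes differ")
  feats <- colnames(Y) %||% paste0("f", seq_len(ncol(Y)))
  data.frame(
    feature = feats, model = model_label,
    median_ae = vapply(seq_len(ncol(Y)), function(j) median_ae(Y[, j], mu[, j]), 0),
    rmse = vapply(seq_len(ncol(Y)), function(j) rmse(Y[, j], mu[, j]), 0),
    spearman = vapply(seq_len(ncol(Y)), function(j) spearman_rho(Y[, j], mu[, j]), 0),
    explained_var = vapply(seq_len(ncol(Y)), function(j)
      explained_variance(Y[, j], mu[, j]), 0),
    row.names = NULL)
}

#' Cliff's delta effect size
#'
#' `(#\{a > b\} - #\{a < b\}) / (|A| |B|)` over all cross pairs: the
#' difference between the probabilities that a value from `A` exceeds one
#' from `B` and vice versa.
#'
#' @param a,b numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stopf("empty input")
  # rank-based O((n+m) log(n+m)) count of concordant/discordant pairs
  r <- rank(c(a, b), ties.method = "average")
  ra <- r[seq_along(a)]
  # sum of midranks of A minus its internal contribution gives the pair counts
  gt <- sum(ra) - length(a) * (length(a) + 1) / 2   # #{a>b} + 0.5 #ties
  (2 * gt - length(a) * length(b)) / (length(a) * length(b))
}

#' Median-based permutation test
#'
#' Tests whether the median of per-feature scores differs between two
#' models.  The observed statistic is `median(A) - median(B)`; the null
#' distribution pools both score vectors and randomly re-partitions them
#' into groups of the original sizes.  The empirical p-value is the
#' proportion of null statistics whose absolute value reaches the observed
#' one, floored at `1 / n_perm`.  When the number of distinct partitions is
#' at most `n_perm`, all partitions are enumerated and the p-value is
#' exact.
#'
#' @param scores_a,scores_b per-feature score vectors.
#' @param n_perm number of permutations (default 10000).
#' @param seed seed for the re-partitions.
#' @param label comparison label carried into the result.
#' @return a `permutation_result` list: `label`, `observed` (median
#'   difference), `delta` (Cliff's delta), `n_perm`, `p_value`, `exact`.
#' @export
permutation_median_test <- function(scores_a, scores_b, n_perm = 10000L,
                                    seed = 1L, label = "A vs B") {
  if (length(scores_a) < 1 || length(scores_b) < 1) stopf("empty score vector")
  if (n_perm < 100) warnf("n_perm < 100 gives a very coarse p-value")
  observed <- stats::median(scores_a) - stats::median(scores_b)
  pooled <- c(scores_a, scores_b)
  n_a <- length(scores_a)
  n_tot <- length(pooled)
  n_part <- suppressWarnings(choose(n_tot, n_a))
  exact <- is.finite(n_part) && n_part <= n_perm
  if (exact) {
    combs <- utils::combn(n_tot, n_a)
    null_diff <- apply(combs, 2, function(idx) {
      stats::median(pooled[idx]) - stats::median(pooled[-idx])
    })
  } else {
    null_diff <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n_tot, n_a)
        stats::median(pooled[idx]) - stats::median(pooled[-idx])
      }, 0)
    })
  }
  p <- mean(abs(null_diff) >= abs(observed) - 1e-12)
  p <- max(p, 1 / length(null_diff))
  structure(list(label = label, observed = observed,
                 delta = cliffs_delta(scores_a, scores_b),
                 n_perm = length(null_diff), p_value = p, exact = exact),
            class = "permutation_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction; monotone and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Expected calibration error for one feature
#'
#' For each confidence level `alpha` the central interval
#' `mu +/- z_{(1+alpha)/2} * sigma` is formed and its observed coverage
#' (fraction of observations inside) compared with `alpha`; the ECE is the
#' mean absolute gap over levels.
#'
#' @param mu,sigma predictive mean and SD vectors.
#' @param y observed values.
#' @param levels confidence levels (default 0.05 to 0.95 in steps of 0.1,
#'   i.e. 10 bins).
#' @return list with `ece` and a `coverage` data.frame of
#'   `(level, observed)`.
#' @export
expected_calibration_error <- function(mu, sigma, y,
                                       levels = seq(0.05, 0.95, by = 0.1)) {
  if (length(levels) == 0) stopf("`levels` must be non-empty")
  if (any(sigma <= 0)) stopf("predictive SDs must be positive")
  check_pair(y, mu)
  cover <- vapply(levels, function(a) {
    zq <- stats::qnorm((1 + a) / 2)
    mean(y >= mu - zq * sigma & y <= mu + zq * sigma)
  }, 0)
  list(ece = mean(abs(cover - levels)),
       coverage = data.frame(level = levels, observed = cover))
}

#' Per-feature ECE table
#'
#' @param dist a `predictive_distribution` (or any list with `mu`, `sigma`
#'   matrices).
#' @param Ystd observed standardised features.
#' @param levels confidence levels.
#' @return data.frame with `feature` and `ece` columns.
#' @export
ece_table <- function(dist, Ystd, levels = seq(0.05, 0.95, by = 0.1)) {
  feats <- colnames(Ystd) %||% paste0("f", seq_len(ncol(Ystd)))
  data.frame(
    feature = feats,
    ece = vapply(seq_len(ncol(Ystd)), function(j) {
      expected_calibration_error(dist$mu[, j], dist$sigma[, j], Ystd[, j],
                                 levels)$ece
    }, 0),
    row.names = NULL)
}

#' Covariate-perturbation sensitivity analysis
#'
#' Each subject's chosen continuous covariate (default age) is shifted by
#' one training-set SD while all other covariates are held fixed.
#' Predictions for the original and perturbed covariates are generated with
#' matched seeds under both prior- and posterior-sampling inference.
#' Regionally, the shift is the difference of per-feature prediction
#' medians (perturbed minus original); globally, the absolute
#' per-(subject, feature) perturbation effects of the two inference modes
#' are compared with a paired Wilcoxon signed-rank test and a matched-pairs
#' rank-biserial effect size.
#'
#' @param model a `trained_cvae`.
#' @param holdout a `cohort_table` to perturb.
#' @param covariate covariate name, `"age_years"` or `"icv_mm3"`.
#' @param delta_sd shift in training-set SDs of the covariate (default +1).
#' @param K Monte-Carlo iterations per prediction.
#' @param seed matched seed for all four prediction runs.
#' @return a `sensitivity_result` list: `regional` (per feature and mode,
#'   original/perturbed medians and shift), `effects` (per-mode
#'   distributions of absolute effects), `wilcoxon` (statistic, p-value,
#'   rank-biserial effect size), `pct_smaller` (percent by which the median
#'   posterior effect is smaller than the prior one).
#' @export
covariate_sensitivity <- function(model, holdout, covariate = "age_years",
                                  delta_sd = 1, K = 1000L, seed = 1L) {
  if (!covariate %in% c("age_years", "icv_mm3")) {
    stopf("`covariate` must be a continuous covariate ('age_years' or 'icv_mm3')")
  }
  state <- model$state
  sd_raw <- if (covariate == "age_years") state$age_sd else state$icv_sd
  std <- standardise(state, holdout)
  X_pert <- holdout$X
  X_pert[, covariate] <- X_pert[, covariate] + delta_sd * sd_raw
  Xstd_pert <- standardise_covariates(state, X_pert)

  pred <- list(
    prior_orig = prior_predict(model, std$Xstd, K, seed),
    prior_pert = prior_predict(model, Xstd_pert, K, seed),
    post_orig = posterior_predict(model, std$Ystd, std$Xstd, K, seed),
    post_pert = posterior_predict(model, std$Ystd, Xstd_pert, K, seed))

  feats <- state$feature_names
  regional <- do.call(rbind, lapply(c("prior", "posterior"), function(mode) {
    o <- if (mode == "prior") pred$prior_orig$mu else pred$post_orig$mu
    p <- if (mode == "prior") pred$prior_pert$mu else pred$post_pert$mu
    data.frame(feature = feats, mode = mode,
               median_original = apply(o, 2, stats::median),
               median_perturbed = apply(p, 2, stats::median),
               shift = apply(p, 2, stats::median) - apply(o, 2, stats::median),
               row.names = NULL)
  }))

  eff_prior <- as.vector(abs(pred$prior_pert$mu - pred$prior_orig$mu))
  eff_post <- as.vector(abs(pred$post_pert$mu - pred$post_orig$mu))
  d <- eff_post - eff_prior
  if (all(d == 0)) {
    wil <- list(statistic = NA_real_, p_value = NA_real_,
                rank_biserial = 0, note = "no difference between modes")
  } else {
    wt <- stats::wilcox.test(eff_post, eff_prior, paired = TRUE, exact = FALSE)
    nz <- d[d != 0]
    r <- rank(abs(nz))
    w_pos <- sum(r[nz > 0])
    w_neg <- sum(r[nz < 0])
    wil <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                rank_biserial = (w_pos - w_neg) / (w_pos + w_neg))
  }
  pct_smaller <- if (stats::median(eff_prior) > 0) {
    100 * (1 - stats::median(eff_post) / stats::median(eff_prior))
  } else {
    NA_real_
  }
  structure(list(covariate = covariate, delta_sd = delta_sd,
                 regional = regional,
                 effects = list(prior = eff_prior, posterior = eff_post),
                 wilcoxon = wil, pct_smaller = pct_smaller),
            class = "sensitivity_result")
}

#' Covariate-independence of deviation scores
#'
#' Correlates each covariate with the deviation z-scores of every feature:
#' Spearman for continuous covariates (age, ICV), point-biserial (Pearson
#' against the 0/1 indicator) for binaries.  P-values are FDR-adjusted
#' within the table.
#'
#' @param dev a `deviation_matrix`.
#' @param X raw covariate matrix `subjects x 7`.
#' @return data.frame with `feature`, `covariate`, `r`, `p`, `p_fdr`.
#' @export
covariate_independence <- function(dev, X) {
  assert_matrix(X, "X", ncol = 7L, nrow = nrow(dev$z))
  colnames(X) <- COVARIATE_NAMES
  continuous <- c("age_years", "icv_mm3")
  feats <- colnames(dev$z) %||% paste0("f", seq_len(ncol(dev$z)))
  rows <- list()
  for (cv in COVARIATE_NAMES) {
    x <- X[, cv]
    if (stats::sd(x) == 0) {
      warnf("covariate '%s' is constant; correlations reported as missing", cv)
      rows[[cv]] <- data.frame(feature = feats, covariate = cv,
                               r = NA_real_, p = NA_real_, row.names = NULL)
      next
    }
    method <- if (cv %in% continuous) "spearman" else "pearson"
    res <- lapply(seq_len(ncol(dev$z)), function(j) {
      ct <- suppressWarnings(
        stats::cor.test(x, dev$z[, j], method = method, exact = FALSE))
      c(r = unname(ct$estimate), p = ct$p.value)
    })
    rows[[cv]] <- data.frame(feature = feats, covariate = cv,
                             r = vapply(res, `[[`, 0, "r"),
                             p = vapply(res, `[[`, 0, "p"), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_fdr <- fdr_adjust(out$p)
  out
}

#' Association between deviation scores and hypertension level
#'
#' Per feature, Spearman correlation between z-scores and the ordinal
#' hypertension level (0-3), FDR-adjusted within the table.
#'
#' @param dev a `deviation_matrix`.
#' @param levels integer hypertension levels in `0:3`, one per subject.
#' @return data.frame with `feature`, `r`, `p`, `p_fdr`.
#' @export
clinical_association <- function(dev, levels) {
  if (length(levels) != nrow(dev$z)) stopf("`levels` must match subjects")
  if (!all(levels %in% 0:3)) stopf("levels must lie in 0:3")
  if (length(unique(levels)) < 2) {
    stopf("need at least two distinct hypertension levels")
  }
  feats <- colnames(dev$z) %||% paste0("f", seq_len(ncol(dev$z)))
  res <- lapply(seq_len(ncol(dev$z)), function(j) {
    ct <- suppressWarnings(
      stats::cor.test(levels, dev$z[, j], method = "spearman", exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(feature = feats,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"), row.names = NULL)
  out$p_fdr <- fdr_adjust(out$p)
  out
}

#' Bland-Altman-style per-feature difference table
#'
#' For two per-feature score vectors, the per-feature mean and difference
#' used in Bland-Altman comparison plots, emitted as data.
#'
#' @param scores_a,scores_b named per-feature score vectors.
#' @param labels character pair naming the models.
#' @return data.frame with `feature`, `mean_score`, `difference`.
#' @export
bland_altman_table <- function(scores_a, scores_b, labels = c("A", "B")) {
  if (length(scores_a) != length(scores_b)) stopf("score vectors differ in length")
  feats <- names(scores_a) %||% paste0("f", seq_along(scores_a))
  data.frame(feature = feats,
             mean_score = (scores_a + scores_b) / 2,
             difference = scores_a - scores_b,
             comparison = paste(labels, collapse = " vs "),
             row.names = NULL)
}
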