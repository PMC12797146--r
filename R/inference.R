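#' @name inference
#' @title Prior- and posterior-sampling predictive distributions
#'
#' @description
#' Prior-sampling inference is the covariate-only prediction strategy: for
#' each Monte-Carlo iteration a latent vector is drawn from the standard
#' normal prior, decoded together with the covariates, and the resulting
#' per-iteration Gaussians are aggregated by the law of total variance into
#' a single predictive mean and SD per subject and feature.  The observed
#' features are never consulted, so the prediction is a true covariate-based
#' norm.  Posterior-sampling inference is the conventional alternative that
#' first encodes the observed features together with the covariates and
#' samples latents from the approximate posterior; it is provided for
#' comparison.  Deviation z-scores standardise observed values against the
#' predictive distribution, with |z| > 2.58 (the 99th percentile band of a
#' standard normal) flagged as extreme.
NULL

aggregate_draws <- function(model, Xstd, K, draw_z, mode) {
  if (K < 2) stopf("K must be >= 2 (between-draw variance undefined)")
  n <- nrow(Xstd)
  F <- model$config$n_features
  clamp_range <- model$config$logvar_clamp
  sum_mu <- matrix(0, n, F)
  sum_mu2 <- matrix(0, n, F)
  sum_var <- matrix(0, n, F)
  for (k in seq_len(K)) {
    z <- draw_z(k)
    dec <- decode(model$params, z, Xstd, clamp_range)
    sum_mu <- sum_mu + dec$mu
    sum_mu2 <- sum_mu2 + dec$mu^2
    sum_var <- sum_var + exp(dec$logvar)
  }
  mu_star <- sum_mu / K
  between <- pmax(sum_mu2 / K - mu_star^2, 0)
  within <- sum_var / K
  structure(list(mu = mu_star, sigma = sqrt(within + between),
                 within_var = within, between_var = between,
                 K = K, mode = mode),
            class = "predictive_distribution")
}

#' @export
print.predictive_distribution <- function(x, ...) {
  cat(sprintf("<predictive_distribution> mode=%s, %d x %d, K=%d draws\n",
              x$mode, nrow(x$mu), ncol(x$mu), x$K))
  invisible(x)
}

#' Prior-sampling (covariate-only) prediction
#'
#' For each of `K` iterations a latent vector is drawn from `N(0, I)` and
#' decoded with the covariates; the predictive mean is the average of the
#' per-iteration means and the predictive variance decomposes by the law of
#' total variance into the mean within-iteration variance plus the variance
#' of the iteration means.  One latent draw per iteration is shared across
#' subjects (latents are independent of covariates), which makes the result
#' invariant to subject order and subsetting under a fixed seed.
#'
#' @param model a `trained_cvae`.
#' @param Xstd standardised covariates `subjects x C` (see
#'   [standardise_covariates()]).
#' @param K number of Monte-Carlo iterations (default 1000).
#' @param seed seed for the latent draws.
#' @return a `predictive_distribution` with `mu`, `sigma`, `within_var`,
#'   `between_var` on the standardised scale.
#' @export
prior_predict <- function(model, Xstd, K = 1000L, seed = 1L) {
  assert_matrix(Xstd, "Xstd", ncol = model$config$n_covariates)
  L <- model$config$latent_dim
  n <- nrow(Xstd)
  eps <- with_seed(seed, matrix(stats::rnorm(K * L), K, L))
  aggregate_draws(model, Xstd, K,
                  function(k) matrix(eps[k, ], n, L, byrow = TRUE),
                  mode = "prior")
}

#' Posterior-sampling (dual-input) prediction
#'
#' Latents are sampled from the encoder's approximate posterior
#' `N(mu_z(Y, X), sigma_z^2(Y, X))` via the reparameterisation; aggregation
#' is identical to [prior_predict()].  Because observed features enter the
#' inference, the result is biased towards the observations and is provided
#' as the conventional comparison method, not as a normative reference.
#'
#' @param model a `trained_cvae`.
#' @param Ystd standardised observed features.
#' @param Xstd standardised covariates.
#' @param K number of Monte-Carlo iterations.
#' @param seed seed for the noise draws (matched with [prior_predict()]
#'   when equal: the same `eps` stream is used).
#' @return a `predictive_distribution` with `mode = "posterior"`.
#' @export
posterior_predict <- function(model, Ystd, Xstd, K = 1000L, seed = 1L) {
  assert_matrix(Xstd, "Xstd", ncol = model$config$n_covariates)
  assert_matrix(Ystd, "Ystd", ncol = model$config$n_features, nrow = nrow(Xstd))
  L <- model$config$latent_dim
  n <- nrow(Xstd)
  post <- encode(model$params, Ystd, Xstd, model$config$logvar_clamp)
  sd_z <- exp(post$logvar / 2)
  eps <- with_seed(seed, matrix(stats::rnorm(K * L), K, L))
  aggregate_draws(model, Xstd, K,
                  function(k) post$mu + sd_z * matrix(eps[k, ], n, L, byrow = TRUE),
                  mode = "posterior")
}

#' Deviation z-scores against a predictive distribution
#'
#' `z = (Y - mu*) / sigma*` per subject and feature, with extreme flags at
#' the configurable threshold (default 2.58, i.e. roughly the outer 1% of a
#' standard normal).
#'
#' @param dist a `predictive_distribution`.
#' @param Ystd observed features on the same (standardised) scale.
#' @param threshold extreme-deviation threshold.
#' @return a `deviation_matrix` with `z`, `extreme_pos`, `extreme_neg`.
#' @export
deviation_scores <- function(dist, Ystd, threshold = 2.58) {
  assert_matrix(Ystd, "Ystd")
  if (!identical(dim(Ystd), dim(dist$mu))) {
    stopf("Ystd shape does not match the predictive distribution")
  }
  if (any(dist$sigma <= 0)) stopf("predictive SDs must be positive")
  z <- (Ystd - dist$mu) / dist$sigma
  structure(list(z = z, threshold = threshold,
                 extreme_pos = z > threshold, extreme_neg = z < -threshold),
            class = "deviation_matrix")
}

#' Extreme-deviation percentages by group
#'
#' Percentage of subjects with an extreme positive / negative deviation, per
#' feature and per group (e.g. hypertension level).
#'
#' @param dev a `deviation_matrix`.
#' @param groups grouping vector, one value per subject.
#' @return data.frame with columns `group`, `feature`, `pct_pos`, `pct_neg`,
#'   `n`; empty groups yield `NA` rates with a warning.
#' @export
extreme_rates <- function(dev, groups) {
  if (length(groups) != nrow(dev$z)) {
    stopf("`groups` must have one value per subject")
  }
  lev <- sort(unique(groups))
  feats <- colnames(dev$z) %||% paste0("f", seq_len(ncol(dev$z)))
  out <- list()
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) == 0) {
      warnf("group '%s' is empty; rates reported as missing", g)
      pos <- neg <- rep(NA_real_, length(feats))
    } else {
      pos <- 100 * colMeans(dev$extreme_pos[idx, , drop = FALSE])
      neg <- 100 * colMeans(dev$extreme_neg[idx, , drop = FALSE])
    }
    out[[length(out) + 1L]] <-
      data.frame(group = g, feature = feats, pct_pos = pos, pct_neg = neg,
                 n = length(idx), row.names = NULL)
  }
  do.call(rbind, out)
}
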