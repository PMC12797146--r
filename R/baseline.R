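#' @name baseline_models
#' @title Covariate-only two-stage baseline normative model
#'
#' @description
#' A reference normative model in the two-stage style used by regression
#' approaches that estimate only the conditional mean: stage one fits a
#' per-feature least-squares regression on a covariate design (polynomial in
#' standardised age, linear in the other covariates) of the standardised
#' features; stage two takes the RMSE of the stage-one residuals as a
#' constant per-feature estimate of the residual SD.  The model satisfies
#' the same predict contract as prior-sampling cVAE inference (covariates
#' in, predictive mean and SD out; observed features never consulted), so
#' the entire evaluation battery runs on it unchanged.
NULL

baseline_design <- function(Xstd, age_degree) {
  cols <- list(intercept = rep(1, nrow(Xstd)))
  for (d in seq_len(age_degree)) {
    cols[[paste0("age", if (d > 1) paste0("^", d) else "")]] <-
      Xstd[, "age_years"]^d
  }
  for (cv in setdiff(COVARIATE_NAMES, "age_years")) cols[[cv]] <- Xstd[, cv]
  do.call(cbind, cols)
}

#' Fit the two-stage baseline
#'
#' @param train a training `cohort_table`.
#' @param age_degree polynomial degree for the age term (default 2).
#' @param wmh_offset offset for the WMH log transform.
#' @return a `two_stage_baseline` with per-feature coefficients and residual
#'   RMSE on the standardised scale, plus the frozen standardisation state.
#' @export
fit_baseline <- function(train, age_degree = 2L, wmh_offset = 1) {
  state <- fit_standardisation(train, wmh_offset = wmh_offset)
  std <- standardise(state, train)
  D <- baseline_design(std$Xstd, age_degree)
  if (nrow(D) <= ncol(D)) {
    stopf("need more subjects (%d) than design columns (%d)", nrow(D), ncol(D))
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrD, std$Ystd)
  resid <- std$Ystd - D %*% coefs
  sigma <- sqrt(colMeans(resid^2))
  structure(list(coefficients = coefs, sigma = sigma,
                 age_degree = as.integer(age_degree), state = state,
                 label = "two_stage_baseline"),
            class = "two_stage_baseline")
}

#' Predict from the two-stage baseline
#'
#' @param model a fitted `two_stage_baseline`.
#' @param Xstd standardised covariate matrix `subjects x 7`.
#' @return list with `mu` (`subjects x F`) and `sigma` (`subjects x F`,
#'   constant down each column).
#' @export
predict_baseline <- function(model, Xstd) {
  assert_matrix(Xstd, "Xstd", ncol = 7L)
  colnames(Xstd) <- COVARIATE_NAMES
  D <- baseline_design(Xstd, model$age_degree)
  if (ncol(D) != nrow(model$coefficients)) {
    stopf("design width %d does not match fitted coefficients (%d)",
          ncol(D), nrow(model$coefficients))
  }
  mu <- D %*% model$coefficients
  sigma <- matrix(model$sigma, nrow(mu), ncol(mu), byrow = TRUE)
  colnames(mu) <- colnames(sigma) <- model$state$feature_names
  list(mu = mu, sigma = sigma)
}

#' Covariate-only normative prediction (generic)
#'
#' The common contract every normative model in the package satisfies:
#' given covariates only, return a predictive mean and SD per subject and
#' feature on the standardised scale.  Methods exist for `trained_cvae`
#' (prior-sampling inference) and `two_stage_baseline`.
#'
#' @param model a fitted normative model.
#' @param Xstd standardised covariate matrix.
#' @param ... method-specific arguments (e.g. `K`, `seed` for the cVAE).
#' @return list with matrices `mu` and `sigma`.
#' @export
predict_normative <- function(model, Xstd, ...) UseMethod("predict_normative")

#' @rdname predict_normative
#' @export
predict_normative.trained_cvae <- function(model, Xstd, ...) {
  p <- prior_predict(model, Xstd, ...)
  list(mu = p$mu, sigma = p$sigma)
}

#' @rdname predict_normative
#' @export
predict_normative.two_stage_baseline <- function(model, Xstd, ...) {
  predict_baseline(model, Xstd)
}

#' Model label for reports
#' @param model a fitted normative model.
#' @return character scalar.
#' @export
model_label <- function(model) {
  if (inherits(model, "trained_cvae")) "prior_cvae" else model$label
}
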