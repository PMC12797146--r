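test_that("accuracy metrics hit their analytic anchor values", {
  y <- c(2.3, -1, 4, 0.5)
  expect_equal(median_ae(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(median_ae(c(-1, 0, 3), c(0, 0, 0)), 1)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(spearman_rho(y, exp(y)), 1)       # increasing transform
  expect_equal(spearman_rho(y, -y^3), -1)        # decreasing transform
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(mean(y), 4)), 0)
  expect_lt(explained_variance(y, -y), 0)        # worse than the mean
  expect_warning(sp <- spearman_rho(y, rep(1, 4)), "constant")
  expect_true(is.na(sp))
  expect_error(explained_variance(rep(1, 4), y), "zero variance")
})

test_that("metrics agree with brute-force reimplementations on random vectors", {
  set.seed(50)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    y <- rnorm(n)
    mu <- rnorm(n)
    if (i %% 3 == 0) {  # inject ties
      y <- round(y, 1); mu <- round(mu, 1)
    }
    expect_equal(median_ae(y, mu), oracle_median_ae(y, mu), tolerance = 1e-10)
    expect_equal(rmse(y, mu), oracle_rmse(y, mu), tolerance = 1e-10)
    if (sd(y) > 0 && sd(mu) > 0) {
      expect_equal(spearman_rho(y, mu), oracle_spearman(y, mu),
                   tolerance = 1e-10)
    }
    if (sd(y) > 0) {
      expect_equal(explained_variance(y, mu),
                   oracle_explained_variance(y, mu), tolerance = 1e-10)
    }
  }
})

test_that("Cliff's delta equals the O(n^2) pair count", {
  expect_equal(cliffs_delta(rep(1, 5), rep(1, 7)), 0)
  expect_equal(cliffs_delta(11:15, 1:5), 1)
  expect_equal(cliffs_delta(1:5, 11:15), -1)
  set.seed(51)
  for (i in 1:50) {
    a <- round(rnorm(sample(2:30, 1)), 1)
    b <- round(rnorm(sample(2:30, 1)), 1)
    expect_equal(cliffs_delta(a, b), oracle_cliffs_delta(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the median permutation test behaves at the extremes and matches enumeration", {
  a <- rnorm(30)
  r_same <- permutation_median_test(a, a, n_perm = 500, seed = 1)
  expect_equal(r_same$observed, 0)
  expect_gt(r_same$p_value, 0.9)

  r_sep <- permutation_median_test(a + 100, a, n_perm = 1000, seed = 2)
  expect_lte(r_sep$p_value, 2 / 1000)
  expect_equal(r_sep$delta, 1)

  # |A| = |B| = 4: the implementation enumerates, and must agree with an
  # independently coded exhaustive oracle
  set.seed(52)
  for (i in 1:10) {
    a4 <- rnorm(4); b4 <- rnorm(4, mean = 0.5)
    r <- permutation_median_test(a4, b4, n_perm = 10000, seed = 3)
    expect_true(r$exact)
    expect_equal(r$p_value, max(oracle_exhaustive_perm_p(a4, b4), 1 / r$n_perm))
  }

  expect_warning(permutation_median_test(a, a, n_perm = 50, seed = 4), "coarse")
})

test_that("FDR adjustment reproduces the hand-worked step-up and p.adjust oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  # hand computation: p_(i) * n / i = 0.04 for every i, monotone already
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(53)
  p <- runif(25)
  expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  # order equivariance
  o <- sample(25)
  expect_equal(fdr_adjust(p[o]), fdr_adjust(p)[o])
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("ECE is near zero for calibrated predictions and follows the inflation closed form", {
  n <- 1e5
  set.seed(54)
  mu <- rnorm(n)
  sigma <- runif(n, 0.5, 2)
  y <- rnorm(n, mu, sigma)
  cal <- expected_calibration_error(mu, sigma, y)
  expect_lt(cal$ece, 0.01)
  expect_equal(nrow(cal$coverage), 10)  # default level grid

  # inflating sigma tenfold: coverage at level a becomes 2*pnorm(10*z_a)-1
  infl <- expected_calibration_error(mu, 10 * sigma, y)
  levels <- seq(0.05, 0.95, by = 0.1)
  analytic <- 2 * pnorm(10 * qnorm((1 + levels) / 2)) - 1
  expect_equal(infl$coverage$observed, analytic, tolerance = 0.01)
  expect_equal(infl$ece, mean(abs(analytic - levels)), tolerance = 0.01)
  expect_true(all(infl$coverage$observed[levels >= 0.25] > 0.99))
  expect_error(expected_calibration_error(mu, sigma, y, levels = numeric(0)),
               "non-empty")
})

test_that("perturbation sensitivity separates prior from posterior inference", {
  setup <- pathology_setup()
  normo <- which(setup$levels == 0L)[1:300]
  holdout <- subset_cohort(setup$sim$cohort, normo)

  sens0 <- covariate_sensitivity(setup$model, holdout, delta_sd = 0,
                                 K = 50, seed = 60)
  expect_equal(sens0$regional$shift, rep(0, nrow(sens0$regional)))
  expect_equal(sens0$wilcoxon$rank_biserial, 0)

  sens <- covariate_sensitivity(setup$model, holdout, delta_sd = 1,
                                K = 200, seed = 61)
  # ageing shifts the WMH norm upward under prior sampling (positive
  # generating age effect), and prior effects dominate posterior ones
  wmh <- grepl("^wmh", sens$regional$feature)
  prior_rows <- sens$regional$mode == "prior"
  expect_true(all(sens$regional$shift[wmh & prior_rows] > 0))
  expect_lt(sens$wilcoxon$p_value, 0.01)
  expect_lt(sens$wilcoxon$rank_biserial, 0)  # posterior effects smaller
  expect_lt(median(sens$effects$posterior), median(sens$effects$prior))
  expect_error(covariate_sensitivity(setup$model, holdout, covariate = "sex"),
               "continuous")
})

test_that("deviation scores decorrelate from covariates, with exact rank oracle", {
  set.seed(62)
  n <- 2000
  X <- cbind(age_years = rnorm(n, 60, 7), sex = rbinom(n, 1, 0.4),
             icv_mm3 = rnorm(n, 1.5e6, 1e5), diabetes = rbinom(n, 1, 0.1),
             hyperchol = rbinom(n, 1, 0.1), obesity = rbinom(n, 1, 0.1),
             smoking = rbinom(n, 1, 0.3))
  z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  dev <- structure(list(z = z), class = "deviation_matrix")
  tab <- covariate_independence(dev, X)
  expect_lt(max(abs(tab$r)), 0.1)
  expect_equal(nrow(tab), 3 * 7)

  # a z-score equal to age correlates perfectly
  z2 <- z; z2[, 1] <- X[, "age_years"]
  tab2 <- covariate_independence(structure(list(z = z2),
                                           class = "deviation_matrix"), X)
  expect_equal(tab2$r[tab2$feature == "a" & tab2$covariate == "age_years"], 1)

  # oracle: midrank Pearson reproduces the reported Spearman coefficient
  r_pkg <- tab$r[tab$feature == "b" & tab$covariate == "age_years"]
  expect_equal(r_pkg, oracle_spearman(X[, "age_years"], z[, 2]),
               tolerance = 1e-10)
})

test_that("clinical association detects level-graded pathology via rank correlation", {
  # hand-built 8-subject example against the rank oracle
  lv <- c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L)
  z <- matrix(c(-1, 0, 0.2, 0.1, 0.8, 1.1, 1.9, 2.5), 8, 1,
              dimnames = list(NULL, "wmh_01"))
  dev <- structure(list(z = z), class = "deviation_matrix")
  tab <- clinical_association(dev, lv)
  expect_equal(tab$r, oracle_spearman(lv, z[, 1]), tolerance = 1e-10)
  expect_error(clinical_association(dev, rep(1L, 8)), "distinct")

  # no pathology: independent z-scores show no FDR-surviving association
  set.seed(63)
  z0 <- matrix(rnorm(2000 * 5), 2000, 5)
  lv0 <- sample(0:3, 2000, replace = TRUE)
  tab0 <- clinical_association(structure(list(z = z0),
                                         class = "deviation_matrix"), lv0)
  expect_gt(min(tab0$p_fdr), 0.05)
})

test_that("metric and Bland-Altman tables carry per-feature results", {
  set.seed(64)
  Y <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("x", "y", "z")))
  mu <- Y + matrix(rnorm(300, sd = 0.3), 100, 3)
  tab <- metric_table(Y, mu, "demo")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rmse[1], rmse(Y[, 1], mu[, 1]))
  ba <- bland_altman_table(setNames(tab$rmse, tab$feature),
                          setNames(tab$rmse * 1.1, tab$feature))
  expect_equal(ba$difference, tab$rmse - tab$rmse * 1.1)
})
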