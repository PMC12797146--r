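tiny_config <- function() {
  cvae_config(n_features = 2L, n_covariates = 1L, latent_dim = 1L,
              hidden_dim = 2L, seed = 1L)
}

test_that("encoder and decoder forward passes are deterministic affine+ReLU maps", {
  cfg <- tiny_config()
  p0 <- zero_params(cfg)
  Y <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  X <- matrix(c(1, -1), 2, 1)
  enc <- encode(p0, Y, X)
  expect_equal(enc$mu, matrix(0, 2, 1))
  expect_equal(enc$logvar, matrix(0, 2, 1))
  dec <- decode(p0, matrix(0, 2, 1), X)
  expect_equal(dec$mu, matrix(0, 2, 2))

  # identical rows give identical outputs
  cfg2 <- cvae_config(n_features = 3L, latent_dim = 2L, hidden_dim = 8L, seed = 2L)
  p <- init_cvae_params(cfg2)
  Yr <- matrix(rnorm(3), 1, 3)[c(1, 1), , drop = FALSE]
  Xr <- matrix(rnorm(7), 1, 7)[c(1, 1), , drop = FALSE]
  enc2 <- encode(p, Yr, Xr)
  expect_identical(enc2$mu[1, ], enc2$mu[2, ])

  # width mismatch errors
  expect_error(encode(p, Yr[, 1:2, drop = FALSE], Xr), "width")
})

test_that("a pencil-sized network matches the hand-computed composition", {
  cfg <- tiny_config()
  p <- zero_params(cfg)
  # encoder: input (y1, y2, x); hidden 2 units; latent 1
  p$encoder$hidden[[1]]$W <- matrix(c(1, 0,
                                      0, 1,
                                      1, -1), 3, 2, byrow = TRUE)
  p$encoder$hidden[[1]]$b <- c(0.5, -0.5)
  p$encoder$mu$W <- matrix(c(2, -1), 2, 1)
  p$encoder$mu$b <- 0.25
  p$encoder$lv$W <- matrix(c(1, 1), 2, 1)
  p$encoder$lv$b <- -1
  y <- c(1, 2); x <- 3
  # hand computation: h = relu(c(1*1 + 3*1 + 0.5, 1*2 + 3*(-1) - 0.5))
  h <- pmax(c(1 + 3 + 0.5, 2 - 3 - 0.5), 0)          # c(4.5, 0)
  mu_hand <- 2 * h[1] - 1 * h[2] + 0.25               # 9.25
  lv_hand <- h[1] + h[2] - 1                          # 3.5
  enc <- encode(p, matrix(y, 1, 2), matrix(x, 1, 1))
  expect_equal(enc$mu[1, 1], mu_hand)
  expect_equal(enc$logvar[1, 1], lv_hand)

  # decoder: input (z, x)
  p$decoder$hidden[[1]]$W <- matrix(c(1, -1,
                                      0.5, 0.5), 2, 2, byrow = TRUE)
  p$decoder$hidden[[1]]$b <- c(0, 1)
  p$decoder$mu$W <- matrix(c(1, 2, 3, 4), 2, 2)
  p$decoder$mu$b <- c(-1, 1)
  z <- 0.4
  hd <- pmax(c(z * 1 + x * 0.5, z * (-1) + x * 0.5 + 1), 0)  # c(1.9, 2.1)
  mu_y_hand <- c(1 * hd[1] + 2 * hd[2] - 1, 3 * hd[1] + 4 * hd[2] + 1)
  dec <- decode(p, matrix(z, 1, 1), matrix(x, 1, 1))
  expect_equal(dec$mu[1, ], mu_y_hand)
  # clamped log-variance head (weights zero) stays at its bias 0
  expect_equal(dec$logvar[1, ], c(0, 0))
})

test_that("reparameterisation has the right limits, moments and determinism", {
  mu <- matrix(1.5, 1, 1)
  expect_equal(reparameterise(mu, matrix(-100, 1, 1), seed = 1)[1, 1], 1.5)

  z <- reparameterise(matrix(0, 1e5, 1), matrix(0, 1e5, 1), seed = 2)
  expect_lt(abs(mean(z)), 3 / sqrt(1e5))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / 1e5))

  z1 <- reparameterise(matrix(0, 10, 3), matrix(0.3, 10, 3), seed = 7)
  z2 <- reparameterise(matrix(0, 10, 3), matrix(0.3, 10, 3), seed = 7)
  expect_identical(z1, z2)
})

test_that("the loss equals its closed forms and a density oracle", {
  n <- 4; F <- 3; L <- 2
  Y <- matrix(rnorm(n * F), n, F)
  zero <- matrix(0, n, L)
  # KL of the prior against itself is zero
  l0 <- elbo_loss(Y, Y, matrix(0, n, F), zero, zero)
  expect_equal(l0$kl, 0)
  # perfect mean with unit variance: NLL per feature is log(2*pi)/2
  expect_equal(l0$recon, F * log(2 * pi) / 2)

  set.seed(3)
  mu_y <- matrix(rnorm(n * F), n, F)
  lv_y <- matrix(rnorm(n * F, sd = 0.5), n, F)
  mu_z <- matrix(rnorm(n * L), n, L)
  lv_z <- matrix(rnorm(n * L, sd = 0.5), n, L)
  l <- elbo_loss(Y, mu_y, lv_y, mu_z, lv_z)
  # NLL by direct density evaluation
  nll_direct <- mean(rowSums(-dnorm(Y, mu_y, exp(lv_y / 2), log = TRUE)))
  expect_equal(l$recon, nll_direct, tolerance = 1e-10)
  # KL by numerical integration of q log(q/p), dimension by dimension
  kl_num <- mean(sapply(seq_len(n), function(i) {
    sum(sapply(seq_len(L), function(d) {
      m <- mu_z[i, d]; s <- exp(lv_z[i, d] / 2)
      integrate(function(t) {
        q <- dnorm(t, m, s)
        ifelse(q > 0, q * (dnorm(t, m, s, log = TRUE) - dnorm(t, log = TRUE)), 0)
      }, m - 12 * s, m + 12 * s, rel.tol = 1e-10)$value
    }))
  }))
  expect_equal(l$kl, kl_num, tolerance = 1e-6)
  # KL is non-negative for random inputs
  expect_gte(l$kl, 0)
  expect_error(elbo_loss(Y, mu_y * Inf, lv_y, mu_z, lv_z), "non-finite")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- tiny_config()
  p <- init_cvae_params(cfg, seed = 5)
  set.seed(6)
  Y <- matrix(rnorm(8), 4, 2)
  X <- matrix(rnorm(4), 4, 1)
  eps <- matrix(rnorm(4), 4, 1)
  res <- priorcvae:::cvae_grad(p, Y, X, eps, c(-10, 10))

  loss_at <- function(pp) priorcvae:::cvae_grad(pp, Y, X, eps, c(-10, 10))$loss$loss
  h <- 1e-6
  check_block <- function(getter, setter, grad) {
    W <- getter(p)
    for (idx in seq_along(W)) {
      Wp <- W; Wp[idx] <- W[idx] + h
      Wm <- W; Wm[idx] <- W[idx] - h
      fd <- (loss_at(setter(p, Wp)) - loss_at(setter(p, Wm))) / (2 * h)
      expect_equal(grad[idx], fd, tolerance = 1e-4)
    }
  }
  check_block(function(p) p$encoder$hidden[[1]]$W,
              function(p, W) { p$encoder$hidden[[1]]$W <- W; p },
              res$grads$encoder$hidden[[1]]$W)
  check_block(function(p) p$encoder$mu$W,
              function(p, W) { p$encoder$mu$W <- W; p },
              res$grads$encoder$mu$W)
  check_block(function(p) p$encoder$lv$W,
              function(p, W) { p$encoder$lv$W <- W; p },
              res$grads$encoder$lv$W)
  check_block(function(p) p$decoder$hidden[[1]]$W,
              function(p, W) { p$decoder$hidden[[1]]$W <- W; p },
              res$grads$decoder$hidden[[1]]$W)
  check_block(function(p) p$decoder$mu$b,
              function(p, b) { p$decoder$mu$b <- b; p },
              res$grads$decoder$mu$b)
  check_block(function(p) p$decoder$lv$W,
              function(p, W) { p$decoder$lv$W <- W; p },
              res$grads$decoder$lv$W)
})

test_that("training selects the best validation epoch and is reproducible", {
  sim <- simulate_cohort(generator_spec(n_subjects = 400L, seed = 20L))
  cfg <- cvae_config(n_features = 20L, latent_dim = 4L, hidden_dim = 32L,
                     batch_size = 64L, max_epochs = 40L, patience = 10L,
                     seed = 21L)
  m <- train_cvae(sim$cohort, cfg)
  expect_s3_class(m, "trained_cvae")
  expect_lte(m$history$val_loss[m$best_epoch], m$history$val_loss[1])
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss))

  m2 <- train_cvae(sim$cohort, cfg)
  expect_identical(m$history, m2$history)
  expect_equal(m$params$decoder$mu$W, m2$params$decoder$mu$W)
})

test_that("a trained model assigns matched covariates far higher likelihood than shuffled ones", {
  spec <- generator_spec(n_subjects = 800L, seed = 22L,
                         s = rep(0.05, 20) * c(rep(1, 15), rep(4, 5)),
                         delta = matrix(0, 4, 20))
  sim <- simulate_cohort(spec)
  cfg <- cvae_config(n_features = 20L, latent_dim = 4L, hidden_dim = 48L,
                     batch_size = 128L, max_epochs = 120L, patience = 20L,
                     seed = 23L)
  m <- train_cvae(sim$cohort, cfg)
  std <- standardise(m$state, sim$cohort)
  pp <- prior_predict(m, std$Xstd, K = 200L, seed = 24L)
  nll <- function(y, mu, sd_) mean(-dnorm(y, mu, sd_, log = TRUE))
  matched <- nll(std$Ystd, pp$mu, pp$sigma)
  shuf <- sample(nrow(std$Ystd))
  shuffled <- nll(std$Ystd[shuf, ], pp$mu, pp$sigma)
  expect_lt(matched, shuffled - 0.5)
})

test_that("the seeded tuner books trials correctly and avoids divergent configs", {
  sim <- simulate_cohort(generator_spec(n_subjects = 200L, seed = 30L))
  base <- cvae_config(n_features = 20L, latent_dim = 4L, hidden_dim = 16L,
                      batch_size = 64L, max_epochs = 8L, patience = 8L,
                      seed = 31L)
  expect_error(tune_hyperparameters(sim$cohort, base, list(), 2L, 2L),
               "empty")

  one <- tune_hyperparameters(sim$cohort, base,
                              list(latent_dim = 6L), n_trials = 1L,
                              n_folds = 2L, seed = 32L)
  expect_equal(one$best_config$latent_dim, 6L)
  expect_equal(nrow(one$trials), 1L * 2L)

  two <- tune_hyperparameters(sim$cohort, base,
                              list(learning_rate = c(1e-3, 10)),
                              n_trials = 4L, n_folds = 2L, seed = 33L)
  expect_equal(nrow(two$trials), 8L)
  expect_equal(two$best_config$learning_rate, 1e-3)
})

test_that("checkpoints round-trip through JSON", {
  setup <- recovery_setup()
  path <- withr::local_tempfile(fileext = ".json")
  save_cvae(setup$model, path)
  m2 <- load_cvae(path)
  expect_equal(m2$config$latent_dim, setup$model$config$latent_dim)
  expect_equal(m2$params$decoder$mu$W, setup$model$params$decoder$mu$W)
  expect_equal(unname(m2$state$feature_sd),
               unname(setup$model$state$feature_sd))
  p1 <- prior_predict(setup$model, setup$std$Xstd[1:20, ], K = 50, seed = 5)
  p2 <- prior_predict(m2, setup$std$Xstd[1:20, ], K = 50, seed = 5)
  expect_equal(p1$mu, p2$mu)
  expect_equal(p1$sigma, p2$sigma)
})
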