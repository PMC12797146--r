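#' @name cvae_core
#' @title Conditional variational autoencoder for tabular phenotypes
#'
#' @description
#' The model is a conditional VAE over standardised features `Y` given
#' covariates `X`.  The encoder maps `[Y, X]` through ReLU hidden layers to
#' the mean and log-variance of a Gaussian approximate posterior over a
#' latent vector `z`; the decoder maps `[z, X]` through ReLU hidden layers
#' to the mean and log-variance of a Gaussian over `Y` (a probabilistic
#' decoder, so every reconstruction is a full distribution, not a point).
#' Training minimises the negative evidence lower bound: the closed-form KL
#' divergence of the posterior from the standard-normal prior (summed over
#' latent dimensions) plus the Gaussian negative log-likelihood of `Y`
#' (summed over features), averaged over the batch, with the Adam optimiser
#' and early stopping on a held-out validation split.
NULL

LOG2PI <- log(2 * pi)

#' Configure a conditional VAE
#'
#' @param n_features number of features `F`.
#' @param n_covariates number of conditioning covariates (7 for the standard
#'   covariate set).
#' @param latent_dim latent dimensionality (default 64).
#' @param hidden_dim units per hidden layer (default 512).
#' @param n_hidden_layers ReLU hidden layers in encoder and decoder.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience in epochs (default 20).
#' @param validation_fraction fraction of the training cohort held out to
#'   monitor validation loss (default 0.10).
#' @param seed master seed controlling split, initialisation and sampling.
#' @param logvar_clamp two-element range to which both log-variance heads
#'   are clamped for numerical stability.
#' @return a `cvae_config` object.
#' @export
cvae_config <- function(n_features, n_covariates = 7L, latent_dim = 64L,
                        hidden_dim = 512L, n_hidden_layers = 1L,
                        learning_rate = 1e-3, batch_size = 256L,
                        max_epochs = 500L, patience = 20L,
                        validation_fraction = 0.10, seed = 1L,
                        logvar_clamp = c(-10, 10)) {
  if (latent_dim < 1) stopf("`latent_dim` must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stopf("`validation_fraction` must lie in (0, 1)")
  }
  if (patience < 1) stopf("`patience` must be >= 1")
  structure(list(n_features = as.integer(n_features),
                 n_covariates = as.integer(n_covariates),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = seed,
                 logvar_clamp = as.numeric(logvar_clamp)),
            class = "cvae_config")
}

init_linear <- function(n_in, n_out, scale) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

init_half <- function(n_in, hidden, layers, n_out) {
  hid <- vector("list", layers)
  d <- n_in
  for (l in seq_len(layers)) {
    hid[[l]] <- init_linear(d, hidden, sqrt(2 / d))  # He init for ReLU
    d <- hidden
  }
  list(hidden = hid,
       mu = init_linear(d, n_out, sqrt(1 / d)),
       lv = init_linear(d, n_out, sqrt(1 / d)))
}

#' Initialise cVAE parameters
#'
#' He-initialised hidden layers, smaller Gaussian heads, zero biases.
#'
#' @param config a [cvae_config()].
#' @param seed seed for the initialisation draw (defaults to the config
#'   seed).
#' @return a `cvae_params` list with `encoder` and `decoder` halves.
#' @export
init_cvae_params <- function(config, seed = config$seed) {
  with_seed(seed, {
    p <- list(
      encoder = init_half(config$n_features + config$n_covariates,
                          config$hidden_dim, config$n_hidden_layers,
                          config$latent_dim),
      decoder = init_half(config$latent_dim + config$n_covariates,
                          config$hidden_dim, config$n_hidden_layers,
                          config$n_features))
    class(p) <- "cvae_params"
    p
  })
}

half_forward <- function(half, input, clamp_range) {
  dimnames(input) <- NULL
  H <- input
  acts <- vector("list", length(half$hidden) + 1L)
  acts[[1]] <- H
  for (l in seq_along(half$hidden)) {
    A <- H %*% half$hidden[[l]]$W
    A <- sweep(A, 2, half$hidden[[l]]$b, "+")
    H <- pmax(A, 0)
    acts[[l + 1L]] <- H
  }
  mu <- sweep(H %*% half$mu$W, 2, half$mu$b, "+")
  lv_raw <- sweep(H %*% half$lv$W, 2, half$lv$b, "+")
  lv <- clamp(lv_raw, clamp_range[1], clamp_range[2])
  list(mu = mu, logvar = lv,
       lv_mask = (lv_raw > clamp_range[1]) & (lv_raw < clamp_range[2]),
       acts = acts)
}

# Backward pass through one encoder/decoder half.  d_mu / d_lv are gradients
# wrt the head outputs (d_lv already clamp-masked).  Returns gradients
# mirroring the parameter structure plus the gradient wrt the input.
half_backward <- function(half, cache, d_mu, d_lv) {
  H_last <- cache$acts[[length(cache$acts)]]
  g <- list(hidden = vector("list", length(half$hidden)),
            mu = list(W = crossprod(H_last, d_mu), b = colSums(d_mu)),
            lv = list(W = crossprod(H_last, d_lv), b = colSums(d_lv)))
  dH <- tcrossprod(d_mu, half$mu$W) + tcrossprod(d_lv, half$lv$W)
  for (l in rev(seq_along(half$hidden))) {
    dA <- dH * (cache$acts[[l + 1L]] > 0)
    g$hidden[[l]] <- list(W = crossprod(cache$acts[[l]], dA), b = colSums(dA))
    dH <- tcrossprod(dA, half$hidden[[l]]$W)
  }
  list(grads = g, d_input = dH)
}

#' Encoder forward pass
#'
#' Deterministic map from standardised features and covariates to the
#' approximate-posterior mean and (clamped) log-variance.
#'
#' @param params a `cvae_params` object.
#' @param Ystd standardised features `subjects x F`.
#' @param Xstd standardised covariates `subjects x C`.
#' @param logvar_clamp clamp range for the log-variance head.
#' @return list with `mu` and `logvar`, each `subjects x latent_dim`.
#' @export
encode <- function(params, Ystd, Xstd, logvar_clamp = c(-10, 10)) {
  enc_in <- ncol(params$encoder$hidden[[1]]$W)  # hidden width
  expect_in <- nrow(params$encoder$hidden[[1]]$W)
  if (ncol(Ystd) + ncol(Xstd) != expect_in) {
    stopf("encoder expects input width %d, got %d", expect_in,
          ncol(Ystd) + ncol(Xstd))
  }
  if (nrow(Ystd) != nrow(Xstd)) stopf("Ystd and Xstd must have equal rows")
  out <- half_forward(params$encoder, cbind(Ystd, Xstd), logvar_clamp)
  list(mu = out$mu, logvar = out$logvar)
}

#' Decoder forward pass
#'
#' Deterministic map from a latent vector and covariates to the parameters
#' of the predicted feature distribution `Y ~ N(mu, exp(logvar))`.
#'
#' @param params a `cvae_params` object.
#' @param z latent matrix `subjects x latent_dim`.
#' @param Xstd standardised covariates `subjects x C`.
#' @param logvar_clamp clamp range for the log-variance head.
#' @return list with `mu` and `logvar`, each `subjects x F`.
#' @export
decode <- function(params, z, Xstd, logvar_clamp = c(-10, 10)) {
  expect_in <- nrow(params$decoder$hidden[[1]]$W)
  if (ncol(z) + ncol(Xstd) != expect_in) {
    stopf("decoder expects input width %d, got %d", expect_in,
          ncol(z) + ncol(Xstd))
  }
  if (nrow(z) != nrow(Xstd)) stopf("z and Xstd must have equal rows")
  out <- half_forward(params$decoder, cbind(z, Xstd), logvar_clamp)
  list(mu = out$mu, logvar = out$logvar)
}

#' Reparameterised latent sample
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, 1)`, so sampling is a
#' deterministic function of `(mu, logvar, eps)` and gradients can flow
#' through it.
#'
#' @param mu,logvar matrices of matching shape.
#' @param seed optional seed for the noise draw.
#' @param eps optional pre-drawn noise matrix (overrides `seed`).
#' @return matrix `z` of the same shape.
#' @export
reparameterise <- function(mu, logvar, seed = NULL, eps = NULL) {
  if (!identical(dim(mu), dim(logvar))) stopf("mu and logvar shapes differ")
  if (is.null(eps)) {
    eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  }
  mu + exp(logvar / 2) * eps
}

#' Negative evidence lower bound
#'
#' `loss = mean_batch[ KL(N(mu_z, s_z^2) || N(0, I)) + Gaussian NLL of Y ]`
#' with the KL summed over latent dimensions in closed form
#' `0.5 * sum(mu^2 + s^2 - 1 - log s^2)` and the NLL summed over features.
#' Minimising this loss maximises the evidence lower bound.
#'
#' @param Ystd observed standardised features.
#' @param mu_y,logvar_y decoder outputs.
#' @param mu_z,logvar_z encoder outputs.
#' @return list with `loss`, `kl`, `recon` (all scalars, batch means).
#' @export
elbo_loss <- function(Ystd, mu_y, logvar_y, mu_z, logvar_z) {
  for (nm in c("Ystd", "mu_y", "logvar_y", "mu_z", "logvar_z")) {
    assert_finite(get(nm), nm)
  }
  kl_i <- 0.5 * rowSums(mu_z^2 + exp(logvar_z) - 1 - logvar_z)
  nll_i <- 0.5 * rowSums(LOG2PI + logvar_y + (Ystd - mu_y)^2 / exp(logvar_y))
  list(loss = mean(kl_i + nll_i), kl = mean(kl_i), recon = mean(nll_i))
}

# One full forward + analytic backward pass; returns loss components and
# gradients mirroring the parameter structure.
cvae_grad <- function(params, Ystd, Xstd, eps, clamp_range) {
  dimnames(Ystd) <- NULL
  dimnames(Xstd) <- NULL
  B <- nrow(Ystd)
  enc <- half_forward(params$encoder, cbind(Ystd, Xstd), clamp_range)
  z <- enc$mu + exp(enc$logvar / 2) * eps
  dec <- half_forward(params$decoder, cbind(z, Xstd), clamp_range)
  loss <- elbo_loss(Ystd, dec$mu, dec$logvar, enc$mu, enc$logvar)

  var_y <- exp(dec$logvar)
  d_mu_y <- (dec$mu - Ystd) / var_y / B
  d_lv_y <- (0.5 * (1 - (Ystd - dec$mu)^2 / var_y) / B) * dec$lv_mask
  bw_dec <- half_backward(params$decoder, dec, d_mu_y, d_lv_y)
  d_z <- bw_dec$d_input[, seq_len(ncol(z)), drop = FALSE]

  d_mu_z <- enc$mu / B + d_z
  d_lv_z <- (0.5 * (exp(enc$logvar) - 1) / B +
               d_z * eps * 0.5 * exp(enc$logvar / 2)) * enc$lv_mask
  bw_enc <- half_backward(params$encoder, enc, d_mu_z, d_lv_z)

  list(loss = loss,
       grads = list(encoder = bw_enc$grads, decoder = bw_dec$grads))
}

# --- Adam over the nested parameter structure -------------------------------

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  cls <- class(params)
  out <- walk(unclass(params), grads, state$m, state$v)
  params <- out$p
  class(params) <- cls
  list(params = params, state = list(m = out$m, v = out$v))
}

cvae_eval_loss <- function(params, Ystd, Xstd, clamp_range) {
  enc <- half_forward(params$encoder, cbind(Ystd, Xstd), clamp_range)
  eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
  z <- enc$mu + exp(enc$logvar / 2) * eps
  dec <- half_forward(params$decoder, cbind(z, Xstd), clamp_range)
  elbo_loss(Ystd, dec$mu, dec$logvar, enc$mu, enc$logvar)$loss
}

#' Train a conditional VAE on a cohort
#'
#' Splits off a seeded uniform validation fraction, fits the feature and
#' covariate standardisation on the remaining training split only, then
#' optimises the negative ELBO with Adam.  Early stopping monitors the
#' validation loss with the configured patience; the parameters from the
#' best validation epoch are restored.
#'
#' @param train a training `cohort_table` (>= 20 subjects).
#' @param config a [cvae_config()] whose `n_features` matches the cohort.
#' @param wmh_offset offset for the WMH log transform.
#' @return a `trained_cvae` with elements `config`, `params`, `state`
#'   (standardisation), `history` (per-epoch train/val loss), `best_epoch`.
#' @export
train_cvae <- function(train, config, wmh_offset = 1) {
  n <- n_subjects(train)
  if (n < 20) stopf("need at least 20 subjects to train")
  if (config$n_features != ncol(train$Y)) {
    stopf("config expects %d features, cohort has %d",
          config$n_features, ncol(train$Y))
  }
  with_seed(config$seed, {
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr <- subset_cohort(train, tr_idx)
    va <- subset_cohort(train, val_idx)
    state <- fit_standardisation(tr, wmh_offset = wmh_offset)
    std_tr <- standardise(state, tr)
    std_va <- standardise(state, va)

    params <- init_cvae_params(config, seed = NULL)  # use ambient stream
    opt <- list(m = zeros_like(unclass(params)), v = zeros_like(unclass(params)))
    clamp_range <- config$logvar_clamp
    hist_tr <- hist_va <- numeric(0)
    best_loss <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    t_step <- 0L
    n_tr <- length(tr_idx)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      batch_losses <- numeric(0)
      for (start in seq(1, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        Yb <- std_tr$Ystd[idx, , drop = FALSE]
        Xb <- std_tr$Xstd[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * config$latent_dim),
                      length(idx), config$latent_dim)
        res <- cvae_grad(params, Yb, Xb, eps, clamp_range)
        if (!is.finite(res$loss$loss)) {
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, res$grads, opt, config$learning_rate, t_step)
        params <- upd$params
        opt <- upd$state
        batch_losses <- c(batch_losses, res$loss$loss)
      }
      val_loss <- cvae_eval_loss(params, std_va$Ystd, std_va$Xstd, clamp_range)
      if (!is.finite(val_loss)) {
        stopf("training diverged (non-finite validation loss) at epoch %d", epoch)
      }
      hist_tr <- c(hist_tr, mean(batch_losses))
      hist_va <- c(hist_va, val_loss)
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(config = config, params = best_params, state = state,
                   history = data.frame(epoch = seq_along(hist_tr),
                                        train_loss = hist_tr,
                                        val_loss = hist_va),
                   best_epoch = best_epoch),
              class = "trained_cvae")
  })
}

#' @export
print.trained_cvae <- function(x, ...) {
  cat(sprintf("<trained_cvae> F=%d latent=%d hidden=%dx%d; best epoch %d (val loss %.4f)\n",
              x$config$n_features, x$config$latent_dim, x$config$n_hidden_layers,
              x$config$hidden_dim, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Seeded hyperparameter search with k-fold cross-validation
#'
#' A simplified random search: each trial draws one value per hyperparameter
#' from `search_space`, trains on each of `n_folds` folds' complements and
#' records the fold-held-out loss; the configuration with the lowest mean
#' cross-validation loss wins.  Trials whose training diverges score `Inf`.
#'
#' @param train a training `cohort_table`.
#' @param base_config a [cvae_config()] supplying fixed settings.
#' @param search_space named list of candidate value vectors, e.g.
#'   `list(latent_dim = c(8, 16), learning_rate = c(1e-3, 1e-2))`.
#' @param n_trials number of sampled configurations.
#' @param n_folds number of CV folds (>= 2).
#' @param seed seed for trial sampling and fold assignment.
#' @return list with `best_config` and a `trials` data.frame of
#'   `n_trials * n_folds` rows.
#' @export
tune_hyperparameters <- function(train, base_config, search_space,
                                 n_trials = 10L, n_folds = 5L, seed = 1L) {
  if (length(search_space) == 0) stopf("empty hyperparameter search space")
  if (n_folds < 2) stopf("`n_folds` must be >= 2")
  n <- n_subjects(train)
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(n_folds), n))
    rows <- list()
    mean_losses <- numeric(n_trials)
    configs <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      draw <- lapply(search_space, function(v) v[[sample.int(length(v), 1L)]])
      cfg <- base_config
      cfg[names(draw)] <- draw
      class(cfg) <- "cvae_config"
      configs[[t]] <- cfg
      fold_losses <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        fit_cohort <- subset_cohort(train, folds != f)
        held <- subset_cohort(train, folds == f)
        loss <- tryCatch({
          model <- train_cvae(fit_cohort, cfg)
          std <- standardise(model$state, held)
          cvae_eval_loss(model$params, std$Ystd, std$Xstd, cfg$logvar_clamp)
        }, error = function(e) Inf)
        fold_losses[f] <- loss
        rows[[length(rows) + 1L]] <-
          data.frame(trial = t, fold = f, loss = loss,
                     as.data.frame(draw, stringsAsFactors = FALSE))
      }
      mean_losses[t] <- mean(fold_losses)
    }
    list(best_config = configs[[which.min(mean_losses)]],
         mean_losses = mean_losses,
         trials = do.call(rbind, rows))
  })
}

# --- Checkpointing -----------------------------------------------------------

pack_array <- function(x) {
  if (is.list(x)) lapply(x, pack_array)
  else list(dim = dim(x) %||% length(x), data = as.vector(x))
}

unpack_array <- function(x) {
  if (!is.null(x$data)) {
    if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2]) else as.numeric(x$data)
  } else {
    lapply(x, unpack_array)
  }
}

#' Save a trained cVAE checkpoint
#'
#' Single JSON file holding a format version, the config, the
#' standardisation state and all network parameters at full precision.
#'
#' @param model a `trained_cvae`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_cvae <- function(model, path) {
  obj <- list(format = "priorcvae-checkpoint", version = 1L,
              config = unclass(model$config),
              state = unclass(model$state),
              best_epoch = model$best_epoch,
              history = model$history,
              params = pack_array(unclass(model$params)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a trained cVAE checkpoint
#' @param path file written by [save_cvae()].
#' @return a `trained_cvae`.
#' @export
load_cvae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$format, "priorcvae-checkpoint")) {
    stopf("not a priorcvae checkpoint: %s", path)
  }
  config <- obj$config
  class(config) <- "cvae_config"
  state <- obj$state
  state$feature_mean <- as.numeric(state$feature_mean)
  state$feature_sd <- as.numeric(state$feature_sd)
  class(state) <- "standardisation_state"
  params <- unpack_array(obj$params)
  class(params) <- "cvae_params"
  structure(list(config = config, params = params, state = state,
                 history = as.data.frame(lapply(obj$history, unlist)),
                 best_epoch = obj$best_epoch),
            class = "trained_cvae")
}
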