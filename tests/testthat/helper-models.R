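# Shared synthetic cohorts and trained models, built once per test session.

test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = test_cache)) assign(key, build(), envir = test_cache)
  get(key, envir = test_cache)
}

small_cvae_config <- function(F, seed = 11L) {
  cvae_config(n_features = F, latent_dim = 8L, hidden_dim = 64L,
              learning_rate = 1e-3, batch_size = 128L, max_epochs = 150L,
              patience = 20L, seed = seed)
}

# zero out every weight and bias of an initialised parameter set
zero_params <- function(config) {
  p <- init_cvae_params(config, seed = 1L)
  rapply(unclass(p), function(x) x * 0, how = "replace") -> p0
  class(p0) <- "cvae_params"
  p0
}

# linear-Gaussian parameter-recovery setup: n = 2000, F = 20, no pathology
recovery_setup <- function() cache_get("recovery", function() {
  spec <- generator_spec(n_subjects = 2000L, seed = 101L,
                         delta = matrix(0, 4, 20))
  sim <- simulate_cohort(spec)
  model <- train_cvae(sim$cohort, small_cvae_config(20L, seed = 11L))
  std <- standardise(model$state, sim$cohort)
  truth_mu_std <- sweep(sweep(sim$truth$mean, 2, model$state$feature_mean),
                        2, model$state$feature_sd, "/")
  truth_sd_std <- sweep(sim$truth$sd, 2, model$state$feature_sd, "/")
  prior <- prior_predict(model, std$Xstd, K = 500L, seed = 21L)
  list(spec = spec, sim = sim, model = model, std = std,
       truth_mu_std = truth_mu_std, truth_sd_std = truth_sd_std,
       prior = prior)
})

# graded-pathology setup: train on normotensive subjects only, evaluate all
pathology_setup <- function() cache_get("pathology", function() {
  spec <- generator_spec(n_subjects = 6000L, seed = 202L)
  sim <- simulate_cohort(spec)
  lv <- sim$cohort$hypertension_level
  train <- subset_cohort(sim$cohort, lv == 0L)
  model <- train_cvae(train, small_cvae_config(20L, seed = 12L))
  std <- standardise(model$state, sim$cohort)
  prior <- prior_predict(model, std$Xstd, K = 300L, seed = 31L)
  post <- posterior_predict(model, std$Ystd, std$Xstd, K = 300L, seed = 31L)
  list(spec = spec, sim = sim, model = model, std = std, levels = lv,
       prior = prior, posterior = post,
       dev_prior = deviation_scores(prior, std$Ystd),
       dev_post = deviation_scores(post, std$Ystd))
})

# write a tiny 3-subject cohort fixture to a temp dir; returns file paths
write_toy_cohort_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cov <- data.frame(subject_id = c("s1", "s2", "s3"),
                    age_years = c(50, 60, 70), sex = c(0, 1, 0),
                    icv_mm3 = c(1.4e6, 1.5e6, 1.6e6),
                    diabetes = c(0, 0, 1), hyperchol = c(0, 1, 0),
                    obesity = c(0, 0, 0), smoking = c(1, 0, 0))
  feat <- data.frame(subject_id = c("s1", "s2", "s3"),
                     thick_a = c(2.5, 2.4, 2.3),
                     vol_a = c(5000, 5100, 4900),
                     sub_a = c(4000, 3900, 4100),
                     wmh_a = c(0, 12.5, 430))
  meta <- data.frame(name = c("thick_a", "vol_a", "sub_a", "wmh_a"),
                     category = c("cortical_thickness", "cortical_volume",
                                  "subcortical_volume", "wmh"))
  paths <- file.path(dir, c("cov.csv", "feat.csv", "meta.csv"))
  write.csv(cov, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(feat, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(meta, paths[3], row.names = FALSE, quote = FALSE)
  paths
}
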