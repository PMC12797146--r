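#' @name cli_app
#' @title End-to-end pipeline
#'
#' @description
#' Orchestrates the full workflow on synthetic or user-supplied data:
#' simulate a cohort, split it into a healthy (normotensive) training set
#' and an evaluation set, train the cVAE, generate prior- and
#' posterior-sampling predictions, compute deviation scores, and run the
#' evaluation battery (metrics + permutation comparison against the
#' two-stage baseline, calibration, sensitivity, covariate-independence and
#' clinical analyses).  Every report embeds the master seed and a hash of
#' the fully-resolved configuration.  A thin command-line wrapper lives at
#' `inst/cli/priorcvae.R`.
NULL

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return nested configuration list; any element can be overridden before
#'   passing to [run_pipeline()].
#' @export
default_run_config <- function(out_dir = "priorcvae_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = c("simulate", "train", "predict", "deviations", "evaluate",
               "calibrate", "sensitivity", "independence", "clinical"),
    simulate = list(n_subjects = 3000L, preset = "desk"),
    train_fraction = 0.8,
    model = list(latent_dim = 16L, hidden_dim = 64L, n_hidden_layers = 1L,
                 learning_rate = 1e-3, batch_size = 128L, max_epochs = 200L,
                 patience = 20L),
    inference = list(K = 300L, threshold = 2.58),
    baseline = list(age_degree = 2L)
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

write_matrix_csv <- function(m, ids, path) {
  df <- data.frame(subject_id = ids, signif(m, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' Stages execute in the fixed order simulate, train, predict, deviations,
#' evaluate, calibrate, sensitivity, independence, clinical; requesting a
#' stage whose prerequisites are not requested is an error.  All numeric
#' reports are deterministic functions of the configuration.
#'
#' @param config a configuration list as from [default_run_config()], or a
#'   path to a YAML file holding one.
#' @return invisibly, a list with the in-memory artefacts (cohorts, model,
#'   predictions, report tables) and the paths written.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  for (nm in names(base)) config[[nm]] <- config[[nm]] %||% base[[nm]]
  stages <- config$stages
  order_ <- base$stages
  stages <- order_[order_ %in% stages]
  deps <- list(train = "simulate", predict = "train", deviations = "predict",
               evaluate = "predict", calibrate = "predict",
               sensitivity = "train", independence = "deviations",
               clinical = "deviations")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      stopf("stage '%s' requires stage '%s'", s, need)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- list(config_hash = hash, seed = config$seed,
               package_version = as.character(utils::packageVersion("priorcvae")))
  arte <- list(config = config, meta = meta)
  paths <- character(0)
  emit_json <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(c(meta, obj), p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <<- c(paths, p)
  }
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, 6)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }

  run_stage <- function(s, fn) {
    tryCatch(fn(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", s, conditionMessage(e))
    })
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    pipeline_log("simulate", sprintf("n=%d", config$simulate$n_subjects))
    counts <- if (identical(config$simulate$preset, "full")) {
      full_feature_counts
    } else {
      c(cortical_thickness = 5L, cortical_volume = 5L,
        subcortical_volume = 5L, wmh = 5L)
    }
    spec <- generator_spec(n_subjects = config$simulate$n_subjects,
                           counts = counts,
                           seed = derive_seed(config$seed, "simulate"))
    sim <- simulate_cohort(spec)
    # normotensive-only training split; remainder + all hypertensives evaluate
    lv <- sim$cohort$hypertension_level
    normo <- which(lv == 0L)
    n_tr <- round(config$train_fraction * length(normo))
    tr_idx <- with_seed(derive_seed(config$seed, "split"),
                        sample(normo, n_tr))
    arte$sim <<- sim
    arte$train <<- subset_cohort(sim$cohort, tr_idx)
    ev_idx <- setdiff(seq_len(n_subjects(sim$cohort)), tr_idx)
    arte$eval <<- subset_cohort(sim$cohort, ev_idx)
    arte$eval_truth <<- list(mean = sim$truth$mean[ev_idx, , drop = FALSE],
                             sd = sim$truth$sd[ev_idx, , drop = FALSE],
                             level = sim$truth$level[ev_idx])
    write_cohort(sim$cohort,
                 file.path(config$out_dir, "covariates.csv"),
                 file.path(config$out_dir, "features.csv"),
                 file.path(config$out_dir, "feature_meta.csv"))
    emit_json(list(spec_echo = list(n_subjects = spec$n_subjects,
                                    counts = as.list(spec$counts),
                                    seed = spec$seed)),
              "simulation.json")
  })

  if ("train" %in% stages) run_stage("train", function() {
    m <- config$model
    cfg <- cvae_config(n_features = ncol(arte$train$Y),
                       latent_dim = m$latent_dim, hidden_dim = m$hidden_dim,
                       n_hidden_layers = m$n_hidden_layers,
                       learning_rate = m$learning_rate,
                       batch_size = m$batch_size, max_epochs = m$max_epochs,
                       patience = m$patience,
                       seed = derive_seed(config$seed, "train"))
    pipeline_log("train", sprintf("n=%d, F=%d", n_subjects(arte$train),
                                  cfg$n_features))
    arte$model <<- train_cvae(arte$train, cfg)
    arte$baseline <<- fit_baseline(arte$train,
                                   age_degree = config$baseline$age_degree)
    save_cvae(arte$model, file.path(config$out_dir, "model_checkpoint.json"))
    paths <<- c(paths, file.path(config$out_dir, "model_checkpoint.json"))
  })

  if ("predict" %in% stages) run_stage("predict", function() {
    pipeline_log("predict", sprintf("K=%d", config$inference$K))
    std <- standardise(arte$model$state, arte$eval)
    arte$eval_std <<- std
    arte$prior <<- prior_predict(arte$model, std$Xstd, config$inference$K,
                                 seed = derive_seed(config$seed, "prior"))
    arte$posterior <<- posterior_predict(arte$model, std$Ystd, std$Xstd,
                                         config$inference$K,
                                         seed = derive_seed(config$seed, "post"))
    arte$base_pred <<- predict_normative(arte$baseline, std$Xstd)
    write_matrix_csv(arte$prior$mu, arte$eval$subject_ids,
                     file.path(config$out_dir, "prior_mu.csv"))
    write_matrix_csv(arte$prior$sigma, arte$eval$subject_ids,
                     file.path(config$out_dir, "prior_sigma.csv"))
  })

  if ("deviations" %in% stages) run_stage("deviations", function() {
    arte$dev_prior <<- deviation_scores(arte$prior, arte$eval_std$Ystd,
                                        threshold = config$inference$threshold)
    arte$dev_post <<- deviation_scores(arte$posterior, arte$eval_std$Ystd,
                                       threshold = config$inference$threshold)
    write_matrix_csv(arte$dev_prior$z, arte$eval$subject_ids,
                     file.path(config$out_dir, "z_prior.csv"))
    rates <- extreme_rates(arte$dev_prior, arte$eval$hypertension_level)
    emit_csv(rates, "extreme_rates_prior.csv")
    emit_json(list(threshold = config$inference$threshold,
                   overall_pct_extreme =
                     100 * mean(abs(arte$dev_prior$z) > config$inference$threshold)),
              "deviations.json")
  })

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    Y <- arte$eval_std$Ystd
    tabs <- rbind(metric_table(Y, arte$prior$mu, "prior_cvae"),
                  metric_table(Y, arte$posterior$mu, "posterior_cvae"),
                  metric_table(Y, arte$base_pred$mu, "two_stage_baseline"))
    arte$metrics <<- tabs
    emit_csv(tabs, "metrics.csv")
    comps <- list()
    for (metric in c("median_ae", "rmse", "spearman", "explained_var")) {
      a <- tabs[tabs$model == "prior_cvae", metric]
      b <- tabs[tabs$model == "two_stage_baseline", metric]
      r <- permutation_median_test(a, b, n_perm = 10000L,
                                   seed = derive_seed(config$seed, metric),
                                   label = sprintf("prior_cvae vs baseline (%s)",
                                                   metric))
      comps[[metric]] <- list(observed = r$observed, delta = r$delta,
                              p_value = r$p_value)
    }
    ps <- vapply(comps, `[[`, 0, "p_value")
    p_fdr <- fdr_adjust(ps)
    for (i in seq_along(comps)) comps[[i]]$p_fdr <- p_fdr[i]
    arte$comparisons <<- comps
    emit_json(list(permutation_tests = comps), "model_comparison.json")
  })

  if ("calibrate" %in% stages) run_stage("calibrate", function() {
    tab <- ece_table(arte$prior, arte$eval_std$Ystd)
    tab$model <- "prior_cvae"
    tab2 <- ece_table(arte$base_pred, arte$eval_std$Ystd)
    tab2$model <- "two_stage_baseline"
    arte$ece <<- rbind(tab, tab2)
    emit_csv(arte$ece, "ece.csv")
  })

  if ("sensitivity" %in% stages) run_stage("sensitivity", function() {
    holdout <- arte$eval
    normo <- which(holdout$hypertension_level == 0L)
    if (length(normo) >= 20) holdout <- subset_cohort(holdout, normo)
    sens <- covariate_sensitivity(arte$model, holdout,
                                  K = config$inference$K,
                                  seed = derive_seed(config$seed, "sens"))
    arte$sensitivity <<- sens
    emit_csv(sens$regional, "sensitivity_regional.csv")
    emit_json(list(wilcoxon = sens$wilcoxon, pct_smaller = sens$pct_smaller),
              "sensitivity_global.json")
  })

  if ("independence" %in% stages) run_stage("independence", function() {
    normo <- which(arte$eval$hypertension_level == 0L)
    dev0 <- deviation_scores(
      list(mu = arte$prior$mu[normo, , drop = FALSE],
           sigma = arte$prior$sigma[normo, , drop = FALSE]),
      arte$eval_std$Ystd[normo, , drop = FALSE],
      threshold = config$inference$threshold)
    tab <- covariate_independence(dev0, arte$eval$X[normo, , drop = FALSE])
    arte$independence <<- tab
    emit_csv(tab, "covariate_independence.csv")
  })

  if ("clinical" %in% stages) run_stage("clinical", function() {
    tab <- clinical_association(arte$dev_prior, arte$eval$hypertension_level)
    arte$clinical <<- tab
    emit_csv(tab, "clinical_association.csv")
  })

  arte$paths <- paths
  invisible(arte)
}
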