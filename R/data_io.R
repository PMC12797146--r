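#' @name data_io
#' @title Cohort containers and standardisation
#'
#' @description
#' A cohort couples a covariate table (age, sex, intracranial volume and four
#' binary vascular risk factors), a matrix of continuous imaging-derived
#' phenotypes (IDPs) in raw units, and per-feature metadata assigning each IDP
#' to one of four categories: cortical thickness, cortical volume, subcortical
#' volume or white matter hyperintensity (WMH) volume.  WMH volumes are
#' heavily right-skewed with many exact zeros, so they are log-transformed
#' (with a small positive offset) before z-scoring; all other features are
#' z-scored directly.  The standardisation state is always fitted on training
#' data only and frozen, so held-out and clinical cohorts are mapped onto the
#' training scale.
NULL

COVARIATE_NAMES <- c("age_years", "sex", "icv_mm3", "diabetes", "hyperchol",
                     "obesity", "smoking")
FEATURE_CATEGORIES <- c("cortical_thickness", "cortical_volume",
                        "subcortical_volume", "wmh")

#' Construct feature metadata
#'
#' @param name character vector of unique feature names.
#' @param category character vector of categories, each one of
#'   `"cortical_thickness"`, `"cortical_volume"`, `"subcortical_volume"`,
#'   `"wmh"`.
#' @param log_transform optional logical vector; defaults to
#'   `category == "wmh"`.
#' @return a `data.frame` with columns `name`, `category`, `log_transform`.
#' @export
feature_meta <- function(name, category, log_transform = NULL) {
  name <- as.character(name)
  category <- as.character(category)
  if (length(name) != length(category)) {
    stopf("`name` and `category` must have equal length")
  }
  if (anyDuplicated(name)) {
    stopf("duplicate feature names: %s",
          paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- setdiff(unique(category), FEATURE_CATEGORIES)
  if (length(bad)) stopf("unknown feature category: %s", paste(bad, collapse = ", "))
  if (is.null(log_transform)) log_transform <- category == "wmh"
  data.frame(name = name, category = category,
             log_transform = as.logical(log_transform),
             stringsAsFactors = FALSE)
}

#' Construct a cohort table
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param X numeric matrix `subjects x 7`, columns ordered `age_years, sex,
#'   icv_mm3, diabetes, hyperchol, obesity, smoking` (binaries coded 0/1,
#'   sex: male = 1).
#' @param Y numeric matrix `subjects x F` of features in raw units.
#' @param meta feature metadata from [feature_meta()], one row per column of
#'   `Y`.
#' @param sbp_mmHg,dbp_mmHg optional systolic / diastolic blood pressure.
#' @param hypertension_level optional integer vector in `0:3`.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(subject_ids, X, Y, meta,
                         sbp_mmHg = NULL, dbp_mmHg = NULL,
                         hypertension_level = NULL) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stopf("subject ids must be unique")
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  assert_matrix(X, "X", ncol = 7L, nrow = n)
  assert_matrix(Y, "Y", nrow = n)
  if (nrow(meta) != ncol(Y)) {
    stopf("feature metadata has %d rows but Y has %d columns", nrow(meta), ncol(Y))
  }
  if (anyNA(X)) stopf("covariate matrix contains missing values")
  if (anyNA(Y)) stopf("feature matrix contains missing values")
  wmh <- meta$log_transform
  if (any(wmh) && any(Y[, wmh, drop = FALSE] < 0)) {
    stopf("negative raw WMH volumes are not allowed")
  }
  dimnames(X) <- list(NULL, COVARIATE_NAMES)
  dimnames(Y) <- list(NULL, meta$name)
  for (v in c("sbp_mmHg", "dbp_mmHg", "hypertension_level")) {
    val <- get(v)
    if (!is.null(val) && length(val) != n) {
      stopf("`%s` must have one value per subject", v)
    }
  }
  structure(list(subject_ids = subject_ids, X = X, Y = Y, meta = meta,
                 sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
                 hypertension_level = hypertension_level),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d features (%s)\n",
              length(x$subject_ids), ncol(x$Y),
              paste(sprintf("%s: %d", names(table(x$meta$category)),
                            as.integer(table(x$meta$category))), collapse = ", ")))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `cohort_table`.
#' @return integer subject count.
#' @export
n_subjects <- function(cohort) length(cohort$subject_ids)

#' Subset a cohort by subject index
#' @param cohort a `cohort_table`.
#' @param idx integer or logical index over subjects.
#' @return the subset `cohort_table`, rows aligned.
#' @export
subset_cohort <- function(cohort, idx) {
  cohort_table(cohort$subject_ids[idx],
               cohort$X[idx, , drop = FALSE],
               cohort$Y[idx, , drop = FALSE],
               cohort$meta,
               sbp_mmHg = cohort$sbp_mmHg[idx],
               dbp_mmHg = cohort$dbp_mmHg[idx],
               hypertension_level = cohort$hypertension_level[idx])
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

check_no_missing <- function(df, label) {
  if (anyNA(df)) {
    idx <- which(is.na(df), arr.ind = TRUE)[1, ]
    stopf("missing value in %s file at row %d, column '%s'",
          label, idx[1], colnames(df)[idx[2]])
  }
}

#' Load a cohort from delimited text files
#'
#' Reads a covariate file (columns `subject_id` plus the seven covariates), a
#' feature file (`subject_id` plus one column per feature) and a feature-meta
#' file (`name,category`).  Files may be comma- or tab-delimited; the
#' delimiter is detected from the header line.  Rows are aligned on
#' `subject_id`, following the covariate-file order; incomplete rows are
#' rejected rather than imputed.
#'
#' @param covariate_path,feature_path,meta_path file paths.
#' @return a [cohort_table()].
#' @export
load_cohort <- function(covariate_path, feature_path, meta_path) {
  cov <- read_delim_auto(covariate_path)
  feat <- read_delim_auto(feature_path)
  meta_df <- read_delim_auto(meta_path)
  for (need in c("subject_id", COVARIATE_NAMES)) {
    if (!need %in% colnames(cov)) stopf("covariate file lacks column '%s'", need)
  }
  if (!"subject_id" %in% colnames(feat)) stopf("feature file lacks column 'subject_id'")
  if (!all(c("name", "category") %in% colnames(meta_df))) {
    stopf("feature-meta file must have columns 'name' and 'category'")
  }
  check_no_missing(cov, "covariate")
  check_no_missing(feat, "feature")
  ids <- as.character(cov$subject_id)
  fids <- as.character(feat$subject_id)
  if (!setequal(ids, fids) || length(ids) != length(fids)) {
    stopf("subject ids do not match between covariate and feature files")
  }
  feat <- feat[match(ids, fids), , drop = FALSE]
  meta <- feature_meta(meta_df$name, meta_df$category,
                       log_transform = meta_df$log_transform)
  missing_feats <- setdiff(meta$name, colnames(feat))
  if (length(missing_feats)) {
    stopf("feature file lacks columns: %s", paste(missing_feats, collapse = ", "))
  }
  Y <- as.matrix(feat[, meta$name, drop = FALSE])
  opt <- function(col) if (col %in% colnames(cov)) cov[[col]] else NULL
  cohort_table(ids,
               as.matrix(cov[, COVARIATE_NAMES, drop = FALSE]),
               Y, meta,
               sbp_mmHg = opt("sbp_mmHg"), dbp_mmHg = opt("dbp_mmHg"),
               hypertension_level = opt("hypertension_level"))
}

#' Write a cohort to delimited text files
#'
#' Inverse of [load_cohort()]: emits covariate, feature and feature-meta
#' files with numeric values at 6 significant digits.
#'
#' @param cohort a `cohort_table`.
#' @param covariate_path,feature_path,meta_path output paths.
#' @return invisibly, the three paths.
#' @export
write_cohort <- function(cohort, covariate_path, feature_path, meta_path) {
  fmt <- function(x) {
    if (is.numeric(x)) signif(x, 6) else x
  }
  cov <- data.frame(subject_id = cohort$subject_ids,
                    as.data.frame(cohort$X), check.names = FALSE)
  if (!is.null(cohort$sbp_mmHg)) cov$sbp_mmHg <- cohort$sbp_mmHg
  if (!is.null(cohort$dbp_mmHg)) cov$dbp_mmHg <- cohort$dbp_mmHg
  if (!is.null(cohort$hypertension_level)) {
    cov$hypertension_level <- cohort$hypertension_level
  }
  cov[] <- lapply(cov, fmt)
  feat <- data.frame(subject_id = cohort$subject_ids,
                     as.data.frame(cohort$Y), check.names = FALSE)
  feat[] <- lapply(feat, fmt)
  utils::write.csv(cov, covariate_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(feat, feature_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(covariate_path, feature_path, meta_path))
}

#' Fit the standardisation transform on a training cohort
#'
#' Per-feature means and sample standard deviations (denominator `n - 1`) are
#' computed on log-transformed values (`log(raw + wmh_offset)`) for WMH
#' features and on raw values otherwise.  Age and intracranial volume means
#' and SDs are stored so continuous covariates can be mapped to the standard
#' normal scale; binary covariates pass through as 0/1.
#'
#' @param train a training `cohort_table` with at least 2 subjects.
#' @param wmh_offset positive offset added to WMH volumes before `log`;
#'   the default `1` (mm^3) maps a zero lesion load to zero.
#' @return a `standardisation_state` object.
#' @export
fit_standardisation <- function(train, wmh_offset = 1) {
  if (n_subjects(train) < 2) stopf("need at least 2 subjects to fit standardisation")
  if (wmh_offset <= 0) stopf("`wmh_offset` must be positive")
  Yt <- transform_features(train$Y, train$meta, wmh_offset)
  mu <- colMeans(Yt)
  sd_ <- apply(Yt, 2, stats::sd)
  if (any(sd_ <= 0 | !is.finite(sd_))) {
    stopf("zero-variance feature(s) after transform: %s",
          paste(train$meta$name[sd_ <= 0 | !is.finite(sd_)], collapse = ", "))
  }
  age <- train$X[, "age_years"]
  icv <- train$X[, "icv_mm3"]
  structure(list(feature_names = train$meta$name,
                 log_transform = train$meta$log_transform,
                 feature_mean = mu, feature_sd = sd_,
                 age_mean = mean(age), age_sd = stats::sd(age),
                 icv_mean = mean(icv), icv_sd = stats::sd(icv),
                 wmh_offset = wmh_offset),
            class = "standardisation_state")
}

transform_features <- function(Y, meta, offset) {
  Yt <- Y
  lg <- meta$log_transform
  if (any(lg)) Yt[, lg] <- log(Y[, lg, drop = FALSE] + offset)
  Yt
}

#' Standardise a cohort onto the training scale
#'
#' @param state a `standardisation_state` from [fit_standardisation()].
#' @param cohort a `cohort_table` whose features match the state.
#' @return list with `Ystd` (`subjects x F`) and `Xstd` (`subjects x 7`; age
#'   and ICV z-scored, binaries untouched).
#' @export
standardise <- function(state, cohort) {
  if (!identical(cohort$meta$name, state$feature_names)) {
    stopf("cohort features do not match standardisation state")
  }
  Yt <- transform_features(cohort$Y, cohort$meta, state$wmh_offset)
  Ystd <- sweep(sweep(Yt, 2, state$feature_mean), 2, state$feature_sd, "/")
  Xstd <- cohort$X
  Xstd[, "age_years"] <- (Xstd[, "age_years"] - state$age_mean) / state$age_sd
  Xstd[, "icv_mm3"] <- (Xstd[, "icv_mm3"] - state$icv_mean) / state$icv_sd
  list(Ystd = Ystd, Xstd = Xstd)
}

#' Map standardised features back to raw units
#'
#' Exact inverse of the feature part of [standardise()]: rescale, then for
#' WMH features exponentiate and subtract the offset.
#'
#' @param state a `standardisation_state`.
#' @param Ystd standardised feature matrix `subjects x F`.
#' @return matrix in raw units.
#' @export
destandardise <- function(state, Ystd) {
  assert_matrix(Ystd, "Ystd", ncol = length(state$feature_names))
  Yt <- sweep(sweep(Ystd, 2, state$feature_sd, "*"), 2, state$feature_mean, "+")
  lg <- state$log_transform
  if (any(lg)) Yt[, lg] <- exp(Yt[, lg, drop = FALSE]) - state$wmh_offset
  colnames(Yt) <- state$feature_names
  Yt
}

#' Standardise only covariates (no features required)
#' @param state a `standardisation_state`.
#' @param X covariate matrix `subjects x 7` in raw units.
#' @return standardised covariate matrix.
#' @export
standardise_covariates <- function(state, X) {
  assert_matrix(X, "X", ncol = 7L)
  colnames(X) <- COVARIATE_NAMES
  X[, "age_years"] <- (X[, "age_years"] - state$age_mean) / state$age_sd
  X[, "icv_mm3"] <- (X[, "icv_mm3"] - state$icv_mean) / state$icv_sd
  X
}
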