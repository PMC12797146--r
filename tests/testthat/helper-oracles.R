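# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately use naive algorithms (loops, sorting,
# full enumeration) and never call the functions they verify.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_median_ae <- function(y, mu) oracle_median(abs(y - mu))

oracle_rmse <- function(y, mu) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - mu[i])^2
  sqrt(acc / length(y))
}

# midranks computed by hand, then the plain Pearson formula
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_spearman <- function(y, mu) {
  oracle_pearson(oracle_midrank(y), oracle_midrank(mu))
}

oracle_explained_variance <- function(y, mu) {
  1 - sum((y - mu)^2) / sum((y - mean(y))^2)
}

oracle_cliffs_delta <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# Benjamini-Hochberg step-up written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in rev(seq_len(n))) {
    val <- p[ord[i]] * n / i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# exhaustive two-sample median permutation p-value
oracle_exhaustive_perm_p <- function(a, b) {
  pooled <- c(a, b)
  obs <- oracle_median(a) - oracle_median(b)
  combs <- utils::combn(length(pooled), length(a))
  nulls <- apply(combs, 2, function(idx) {
    oracle_median(pooled[idx]) - oracle_median(pooled[-idx])
  })
  mean(abs(nulls) >= abs(obs) - 1e-12)
}

# hypertension grading re-encoded from the clinical band definitions,
# written as explicit interval tests rather than a highest-grade scan
oracle_hypertension <- function(sbp, dbp) {
  mapply(function(s, d) {
    if (s >= 160 || d >= 100) return(3L)
    if ((s >= 140 && s < 160) || (d >= 90 && d < 100)) return(2L)
    if ((s >= 130 && s < 140) || (d >= 85 && d < 90)) return(1L)
    0L
  }, sbp, dbp)
}
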