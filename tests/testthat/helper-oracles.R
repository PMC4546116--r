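# Independent oracles used across test files. These deliberately avoid the
# code paths they check.

# Benjamini-Hochberg step-up by explicit min-over-suffix loop.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Spearman rho from the rank definition (average ranks for ties), computed
# as the Pearson correlation of the rank vectors.
spearman_brute <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mean((rx - mean(rx)) * (ry - mean(ry))) / (stats::sd(rx) * stats::sd(ry)) *
    length(rx) / (length(rx) - 1)
}

# One-sided Fisher/hypergeometric tail by exhaustive enumeration:
# P(overlap >= q) when drawing k genes from a universe of N containing m
# targets.
hyper_tail_brute <- function(q, m, N, k) {
  sum(vapply(q:min(m, k), function(x) {
    choose(m, x) * choose(N - m, k - x) / choose(N, k)
  }, numeric(1)))
}

# Quantile normalization by the order-statistic definition, ties receiving
# the mean of the row means over their rank range.
quantile_normalize_brute <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    # interpolate mean-of-means for tied (fractional) ranks
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

# Small focused gene panel used for the Monte-Carlo power / FDR / rho
# studies: 40 genes, 12 monotone with top-dose effects spanning 0.8-2.4 log2
# (all at least 4x the 0.2 noise SD), remainder null.
power_panel <- function(noise_sd = 0.2, n_monotone = 12, n_genes = 40,
                        top_dose = 54) {
  top_effects <- seq(0.8, 2.4, length.out = n_monotone)
  slopes <- top_effects / top_dose
  ids <- c(sprintf("mono%02d", seq_len(n_monotone)),
           sprintf("null%02d", seq_len(n_genes - n_monotone)))
  classes <- stats::setNames(
    c(rep("monotone_dose", n_monotone),
      rep("null", n_genes - n_monotone)), ids)
  effects <- stats::setNames(lapply(slopes, effect_linear),
                             ids[seq_len(n_monotone)])
  effect_model(classes, effects, noise_sd = noise_sd)
}

# One-tissue design used by the Monte-Carlo studies (halves the compute of
# the default two-tissue design without changing the per-group statistics).
cortex_design <- function() {
  study_design(tissues = "cortex")
}
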