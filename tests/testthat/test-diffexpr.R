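# Differential-expression stage: normalization, filtering, Welch tests, BH,
# and the dual significance threshold.

test_that("quantile normalization matches the order-statistic definition", {
  # two samples (1,2,3) and (4,5,6): both become the means of order stats
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2,
               ignore_attr = TRUE)

  # tie-free data: columns end up with identical distributions
  set.seed(42)
  m3 <- matrix(rnorm(120), nrow = 20)
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  for (j in 2:ncol(sorted)) {
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  }
  expect_equal(qn3, quantile_normalize_brute(m3), ignore_attr = TRUE,
               tolerance = 1e-12)

  # tied data: matches the hand-rolled tie rule (mean of means over the
  # tied rank range); tied columns then need not be identical
  m4 <- matrix(sample(1:40, 120, replace = TRUE), nrow = 20)
  expect_equal(quantile_normalize(m4), quantile_normalize_brute(m4),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("variance filter removes the stated fraction and edge cases", {
  set.seed(1)
  m <- matrix(rnorm(600), nrow = 100)
  expect_identical(variance_filter(m, 0), m)
  kept <- variance_filter(m, 0.2)
  expect_equal(nrow(kept), 80)
  v <- apply(m, 1, var)
  expect_true(min(apply(kept, 1, var)) >= quantile(v, 0.2))
  const <- matrix(3, nrow = 5, ncol = 4)
  expect_warning(out <- variance_filter(const, 0.2), "removed all genes")
  expect_equal(nrow(out), 0)
})

test_that("Welch statistics match the hand formula and t.test", {
  es <- structure(list(
    exprs = rbind(g1 = c(3, 4, 5, 1, 2, 3)),
    samples = data.frame(
      tissue = "cortex", timepoint_months = 12,
      activity_MBq = c(150, 150, 150, 0, 0, 0),
      is_control = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      replicate = c(1:3, 1:3),
      sample_id = paste0("s", 1:6)),
    tissue = "cortex"), class = "expr_set")
  de <- de_table(es, 12, 150)
  expect_equal(de$log2_ratio, 2.0)
  expect_equal(de$t, 2.449, tolerance = 1e-3)   # 2 / sqrt(2/3)
  tt <- t.test(c(3, 4, 5), c(1, 2, 3))
  expect_equal(de$p, tt$p.value, tolerance = 1e-12)

  # group identical to control: zero ratio
  es$exprs <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  expect_equal(de_table(es, 12, 150)$log2_ratio, 0)

  # zero variance in both groups: documented convention
  es$exprs <- rbind(g1 = c(2, 2, 2, 2, 2, 2), g2 = c(3, 3, 3, 1, 1, 1))
  de <- de_table(es, 12, 150)
  expect_equal(de$p, c(1, 0))
})

test_that("de_table requires an age-matched control set", {
  d <- study_design(timepoints_months = c(4, 8))
  eff <- power_panel()
  st <- gen_expression_set(d, eff, seed = 1)
  es <- st$cortex
  es$samples$is_control[es$samples$timepoint_months == 8] <- FALSE
  expect_error(de_table(es, 8, 150), "pairing error")
})

test_that("BH adjustment matches the examples and brute force", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("dual significance threshold is strict on both sides", {
  de <- data.frame(q = c(0.005, 0.005, 0.02, 0.005),
                   log2_ratio = c(0.60, 0.58, 3.0, -0.70))
  out <- call_significant(de)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("up", NA, NA, "down"))
})

test_that("significant-call counts are invariant under gene permutation", {
  d <- cortex_design()
  st <- gen_expression_set(d, power_panel(), seed = 11)
  es <- st$cortex
  de1 <- de_all_groups(list(cortex = es), variance_quantile = 0)
  perm <- sample(nrow(es$exprs))
  es2 <- es
  es2$exprs <- es$exprs[perm, ]
  de2 <- de_all_groups(list(cortex = es2), variance_quantile = 0)
  n1 <- aggregate(significant ~ timepoint_months + activity_MBq, de1, sum)
  n2 <- aggregate(significant ~ timepoint_months + activity_MBq, de2, sum)
  expect_equal(n1, n2)
})

test_that("per-group log2-ratio estimates are unbiased", {
  # planted Cdkn1a-like profile: estimated group ratios average to the
  # truth over 200 seeds (simulated data is calibrated by construction, so
  # the estimator is tested without cross-sample renormalization)
  d <- cortex_design()
  eff <- default_effect_model(n_genes = 40, design = d, seed = 3)
  truth <- vapply(d$doses_Gy, function(dd) {
    gene_effect(eff, "Cdkn1a_like", dd, 12)
  }, numeric(1))
  est <- matrix(0, 200, length(truth))
  for (s in 1:200) {
    st <- gen_expression_set(d, eff, seed = 1000 + s)
    de <- de_all_groups(st, variance_quantile = 0, normalize = FALSE)
    sub <- de[de$gene == "Cdkn1a_like" & de$timepoint_months == 12, ]
    est[s, ] <- sub$log2_ratio[order(sub$activity_MBq)]
  }
  bias <- colMeans(est) - truth
  expect_true(all(abs(bias) < 0.05))
})

test_that("expression sets round-trip through TSV + JSON", {
  d <- study_design(timepoints_months = 4, tissues = "cortex")
  st <- gen_expression_set(d, power_panel(), seed = 5)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_expression_set(st$cortex, tsv, js)
  back <- read_expression_set(tsv, js)
  expect_equal(back$exprs, st$cortex$exprs, tolerance = 1e-10)
  expect_equal(back$samples$activity_MBq, st$cortex$samples$activity_MBq)
  expect_equal(back$tissue, "cortex")
})
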