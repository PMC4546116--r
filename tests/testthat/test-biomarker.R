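# Recurrence, catalogue overlap, dose-response, regulator enrichment.

test_that("the packaged marker panel reproduces the published counts", {
  markers <- load_marker_catalogue()
  mc <- recurrence_from_catalogue(markers, "cortex")
  mm <- recurrence_from_catalogue(markers, "medulla")
  expect_equal(ncol(mc), 15)
  expect_equal(ncol(mm), 15)
  expect_equal(marker_overlap(mc, marker_catalogue_genes(markers, "cortex"))$unique_count, 34)
  expect_equal(marker_overlap(mm, marker_catalogue_genes(markers, "medulla"))$unique_count, 32)
  expect_equal(recurrence_count(mc, "Cdkn1a"), 12)
  expect_equal(recurrence_count(mm, "Cdkn1a"), 13)
  expect_equal(recurrence_count(mc, "NotAGene"), 0)
  # filled-cell pattern: every fixture row maps to exactly one filled cell
  expect_equal(sum(!is.na(mc)), sum(markers$tissue == "cortex"))
  expect_equal(sum(!is.na(mm)), sum(markers$tissue == "medulla"))
  # and the Cdkn1a 12-month profile carries the printed values
  expect_equal(unname(dose_profile(mc, "Cdkn1a", 12)),
               c(1.3, 1.0, 1.6, 1.4, 2.0))
})

test_that("build_recurrence is order-invariant and validates completeness", {
  markers <- load_marker_catalogue()
  m1 <- recurrence_from_catalogue(markers, "cortex")
  shuffled <- markers[rev(seq_len(nrow(markers))), ]
  m2 <- recurrence_from_catalogue(shuffled, "cortex")
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])

  # missing group cell -> incomplete-design error naming the cell
  de <- data.frame(gene = "g1", tissue = "cortex", timepoint_months = 4,
                   activity_MBq = 30, log2_ratio = 1, significant = TRUE)
  expect_error(
    build_recurrence(de, "cortex", timepoints_months = c(4, 8),
                     activities_MBq = c(30, 60)),
    "incomplete design.*8mo_30MBq")

  # no significant calls: empty gene axis, full group axis
  de0 <- data.frame(gene = "g1", tissue = "cortex",
                    timepoint_months = c(4, 8), activity_MBq = 30,
                    log2_ratio = 0.1, significant = FALSE)
  m0 <- build_recurrence(de0, "cortex", timepoints_months = c(4, 8),
                         activities_MBq = 30)
  expect_equal(nrow(m0), 0)
  expect_equal(ncol(m0), 2)
})

test_that("recurrence counts sum to the number of filled cells", {
  markers <- load_marker_catalogue()
  m <- recurrence_from_catalogue(markers, "medulla")
  total <- sum(vapply(rownames(m), function(g) recurrence_count(m, g),
                      integer(1)))
  expect_equal(total, sum(!is.na(m)))
})

test_that("dose_response_score matches hand ranks and brute force", {
  # published Cdkn1a cortex 12-month profile vs dose: rho = 0.8
  sc <- dose_response_score(c(1.3, 1.0, 1.6, 1.4, 2.0),
                            c(16, 29, 40, 48, 54))
  expect_equal(sc$rho, 0.8)
  expect_false(sc$monotone)
  expect_equal(dose_response_score(c(1, 2, 3), c(1, 2, 3)),
               list(rho = 1.0, monotone = TRUE, n = 3, insufficient = FALSE))
  expect_equal(dose_response_score(c(3, 2, 1))$rho, -1.0)
  # fewer than 3 values: insufficient-data signal, not an error
  ins <- dose_response_score(c(1, NA, NA, 2, NA))
  expect_true(ins$insufficient)
  expect_true(is.na(ins$rho))

  set.seed(5)
  i <- 0
  while (i < 1000) {
    n <- sample(3:12, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- round(rnorm(n), 1)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next  # rho undefined
    i <- i + 1
    expect_equal(dose_response_score(y, x)$rho, spearman_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("planted monotone genes score high dose-response rho", {
  # slope 0.02 log2/Gy, noise 0.2: median rho across 200 seeds >= 0.7
  d <- cortex_design()
  cls <- c(mono = "monotone_dose",
           setNames(rep("null", 19), sprintf("n%02d", 1:19)))
  eff <- effect_model(cls, list(mono = effect_linear(0.02)), noise_sd = 0.2)
  rhos <- vapply(1:200, function(s) {
    st <- gen_expression_set(d, eff, seed = s)
    de <- de_all_groups(st, variance_quantile = 0, normalize = FALSE)
    sub <- de[de$gene == "mono" & de$timepoint_months == 12, ]
    dose_response_score(sub$log2_ratio[order(sub$activity_MBq)],
                        d$doses_Gy)$rho
  }, numeric(1))
  expect_gte(median(rhos), 0.7)
})

test_that("regulator enrichment reproduces the published Ifng overlap", {
  regmap <- load_regulator_map()
  cortex_map <- regmap[regmap$tissue == "cortex", ]
  # the recurrent cortex set: marker-panel genes plus the mapped targets
  markers <- load_marker_catalogue()
  m <- recurrence_from_catalogue(markers, "cortex")
  rec <- union(rownames(m), unique(cortex_map$target))
  out <- regulator_enrichment(rec, cortex_map, universe_size = 20000)
  ifng <- out[out$regulator == "Ifng", ]
  expect_equal(strsplit(ifng$overlap_genes, ",")[[1]],
               c("Actb", "Adipoq", "C3", "Cdkn1a", "Dbp", "Hspb1", "Nupr1"))
  # ranked by overlap desc, then p, then name
  expect_true(all(diff(out$overlap) <= 0))
  expect_error(regulator_enrichment("A", cortex_map[0, ], 100), "empty")
})

test_that("enrichment p-values equal exhaustive hypergeometric tails", {
  map <- data.frame(regulator = "R",
                    target = c("t1", "t2", "t3", "t4", "t5"))
  gs <- c("t1", "t2", "t3", sprintf("x%d", 1:7))  # overlap 3 of 5, set 10
  out <- regulator_enrichment(gs, map, universe_size = 100)
  expect_equal(out$overlap, 3)
  expect_equal(out$p, hyper_tail_brute(3, 5, 100, 10), tolerance = 1e-12)
  # empty gene set: overlap 0, p = 1
  out0 <- regulator_enrichment(character(0), map, universe_size = 100)
  expect_equal(out0$overlap, 0)
  expect_equal(out0$p, 1)
})

test_that("marker_overlap ignores duplicates and case", {
  markers <- load_marker_catalogue()
  m <- recurrence_from_catalogue(markers, "cortex")
  cat1 <- marker_catalogue_genes(markers, "cortex")
  cat_dup <- rbind(cat1, transform(cat1, gene = toupper(gene)))
  expect_equal(marker_overlap(m, cat_dup)$unique_count, 34)
})
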