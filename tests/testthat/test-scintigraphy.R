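# Planar frame simulation, ROI segmentation, calibrated quantification,
# renograms, DMSA normalization, paired tests.

geom <- scinti_geometry()

test_that("geometry rejects overlapping objects", {
  expect_error(
    scinti_geometry(kidney_centers = list(c(100, 96), c(100, 110))),
    "geometry error")
})

test_that("zero activity and zero background give all-zero frames", {
  kin <- renal_kinetics(injected_MBq = 1e-12)
  fr <- gen_scintigraphy_series(kin, geom, seed = 1, background_cpm = 0,
                                syringe_activity_MBq = 1e-12)
  expect_true(all(vapply(fr, function(f) sum(f$counts), numeric(1)) < 1e-6))
})

test_that("expected object counts follow sensitivity x activity x duration", {
  # static DMSA-style frame, noise-free: exact expectation
  f <- gen_dmsa_frame(10, geom, injected_MBq = 40, time_h = 3,
                      duration_min = 3, sensitivity = 2000,
                      background_cpm = 0, noise = FALSE)
  decay <- 2^(-3 / 6.007)
  expect_equal(sum(f$counts[geom$masks$left_kidney]),
               0.05 * 40 * decay * 2000 * 3, tolerance = 1e-9)
  # Poisson mean identity over 100 seeds within 1%
  lambda <- f$counts
  set.seed(1)
  tot <- replicate(100, sum(rpois(length(lambda), lambda)))
  expect_equal(mean(tot), sum(lambda), tolerance = 0.01)
})

test_that("fractional-max segmentation matches a brute-force pixel scan", {
  # all activity in the kidneys: two isolated Gaussian blobs, no body pool
  f <- gen_dmsa_frame(100, geom, background_cpm = 0, noise = FALSE)
  f$counts <- round(f$counts)
  seed_px <- geom$seeds$left_kidney
  roi <- segment_roi(f, seed_px, 0.10)
  # brute force: all pixels >= 0.1 * local max around this isolated blob
  h <- 30
  rows <- (seed_px[1] - h):(seed_px[1] + h)
  cols <- (seed_px[2] - h):(seed_px[2] + h)
  thr <- 0.1 * max(f$counts[rows, cols])
  brute <- matrix(FALSE, 256, 256)
  brute[rows, cols] <- f$counts[rows, cols] >= thr
  expect_equal(sum(roi), sum(brute))
  expect_true(all(which(roi) %in% which(brute)))
  # excludes the well-separated contralateral kidney
  expect_false(any(roi & geom$masks$right_kidney))
  # uniform positive image: mask spans the whole window
  fu <- f; fu$counts <- matrix(7, 256, 256)
  roi_u <- segment_roi(fu, c(128, 128), 0.10, window = 21)
  expect_equal(sum(roi_u), 21 * 21)
  # cold seed with a hot object in the window errors
  expect_error(segment_roi(f, c(100, 70), 0.10), "empty ROI")
})

test_that("segmentation is idempotent and monotone in the threshold", {
  kin <- renal_kinetics()
  fr <- gen_scintigraphy_series(kin, geom, seed = 4)
  f <- fr[[3]]
  roi10 <- segment_roi(f, geom$seeds$left_kidney, 0.10)
  # idempotent: masking out everything else and re-running returns the mask
  f2 <- f
  f2$counts[!roi10] <- 0
  roi_again <- segment_roi(f2, geom$seeds$left_kidney, 0.10)
  expect_equal(unclass(roi_again)[, ], unclass(roi10)[, ])
  # higher threshold gives a subset
  roi30 <- segment_roi(f, geom$seeds$left_kidney, 0.30)
  expect_true(all(which(roi30) %in% which(roi10)))
  expect_lt(sum(roi30), sum(roi10))
})

test_that("syringe calibration identity and empty-ROI conventions hold", {
  f <- gen_dmsa_frame(10, geom, noise = FALSE, background_cpm = 0)
  syr <- geom$masks$syringe
  q <- quantify_frame(f, syr, syr)
  expect_equal(q$activity_MBq, f$syringe_activity_MBq, tolerance = 1e-12)
  empty <- matrix(FALSE, 256, 256)
  q0 <- quantify_frame(f, empty, syr)
  expect_equal(q0$activity_MBq, 0)
  expect_equal(q0$percent_IA, 0)
  fz <- f; fz$counts <- matrix(0, 256, 256)
  expect_error(quantify_frame(fz, syr, syr), "calibration error")
})

test_that("quantification with truth masks is unbiased (500 Poisson seeds)", {
  kin <- renal_kinetics()
  fr_nf <- gen_scintigraphy_series(kin, geom, frame_times_min = 12.5,
                                   seed = 1, noise = FALSE,
                                   background_cpm = 0)
  lambda <- fr_nf[[1]]$counts
  truth <- attr(fr_nf, "truth")
  masks <- attr(fr_nf, "geometry")$masks
  kid_mask <- masks$left_kidney | masks$right_kidney
  set.seed(2024)
  n <- 500
  est <- matrix(NA_real_, n, 3)
  f <- fr_nf[[1]]
  for (i in seq_len(n)) {
    f$counts <- matrix(rpois(length(lambda), lambda), 256, 256)
    syr <- masks$syringe
    est[i, 1] <- quantify_frame(f, kid_mask, syr)$percent_IA
    est[i, 2] <- quantify_frame(f, masks$bladder, syr)$percent_IA
    est[i, 3] <- quantify_frame(f, syr, syr)$activity_MBq
  }
  true_vals <- c(100 * truth$kidney, 100 * truth$bladder,
                 f$syringe_activity_MBq)
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(n)
    expect_lt(abs(mean(est[, j]) - true_vals[j]), 3 * se + 1e-9)
  }
})

test_that("renograms mirror normal and obstructed kinetics", {
  # normal excretion: kidney %IA falls over the last four frames,
  # bladder %IA rises
  kin <- renal_kinetics(impairment_factor = 1)
  fr <- gen_scintigraphy_series(kin, geom, seed = 6)
  rg <- build_renogram(fr, kidney_seeds = geom$seeds[1:2],
                       bladder_seed = geom$seeds$bladder,
                       syringe_seed = geom$seeds$syringe)
  last4 <- rg$kidney_pct[rg$time_min >= 17.5]
  expect_true(all(diff(last4) < 0))
  # segmented bladder ROI is meaningful once the bladder outshines the body
  # pool; the first frame (2.5 min, ~2% IA) is checked with truth masks
  expect_true(all(diff(rg$bladder_pct[rg$time_min >= 7.5]) > 0))
  rg_truth <- build_renogram(fr, kidney_seeds = geom$seeds[1:2],
                             bladder_seed = geom$seeds$bladder,
                             syringe_seed = geom$seeds$syringe,
                             masks = attr(fr, "geometry")$masks)
  expect_true(all(diff(rg_truth$bladder_pct) > 0))
  expect_gt(bladder_at_27_5(rg), 10)

  # full obstruction: kidney %IA non-decreasing, bladder ~ 0 at 27.5 min
  kin0 <- renal_kinetics(impairment_factor = 0)
  fr0 <- gen_scintigraphy_series(kin0, geom, seed = 7)
  rg0 <- build_renogram(fr0, kidney_seeds = geom$seeds[1:2],
                        bladder_seed = geom$seeds$bladder,
                        syringe_seed = geom$seeds$syringe)
  expect_true(all(diff(rg0$kidney_pct) > -0.5))  # Poisson jitter allowance
  expect_lt(bladder_at_27_5(rg0), 1)

  # protocol check: 27.5-min frame required
  expect_error(
    build_renogram(fr[-6], kidney_seeds = geom$seeds[1:2],
                   bladder_seed = geom$seeds$bladder,
                   syringe_seed = geom$seeds$syringe),
    "protocol error")
})

test_that("renograms conserve mass balance in noise-free mode", {
  kin <- renal_kinetics()
  fr <- gen_scintigraphy_series(kin, geom, seed = 1, noise = FALSE,
                                background_cpm = 0)
  masks <- attr(fr, "geometry")$masks
  whole <- masks$left_kidney | masks$right_kidney | masks$bladder |
    masks$remainder
  for (f in fr[c(1, 4, 7)]) {
    tot <- quantify_frame(f, whole, masks$syringe)$percent_IA
    expect_equal(tot, 100, tolerance = 0.02)
  }
})

test_that("DMSA uptake normalizes to controls", {
  # truth ratio planted at 1.4 (the published 4-month 30 MBq DMSA cell)
  ctl_pct <- 15
  f <- gen_dmsa_frame(1.4 * ctl_pct, geom, seed = 8)
  masks <- geom$masks
  out <- dmsa_uptake(f, kidney_seeds = geom$seeds[1:2],
                     syringe_seed = geom$seeds$syringe,
                     control_percent_ias = rep(ctl_pct, 4),
                     masks = masks)
  expect_equal(out$percent_of_control, 140, tolerance = 0.05 * 140)
  # subject equal to control mean -> 100%
  f2 <- gen_dmsa_frame(ctl_pct, geom, seed = 9, noise = FALSE,
                       background_cpm = 0)
  out2 <- dmsa_uptake(f2, geom$seeds[1:2], geom$seeds$syringe,
                      control_percent_ias = ctl_pct, masks = masks)
  expect_equal(out2$percent_of_control, 100, tolerance = 1e-9)
  expect_error(dmsa_uptake(f2, geom$seeds[1:2], geom$seeds$syringe,
                           control_percent_ias = numeric(0)),
               "non-empty")
  expect_error(dmsa_uptake(f2, geom$seeds[1:2], geom$seeds$syringe,
                           control_percent_ias = 0, masks = masks),
               "normalization error")
})

test_that("normalized control DMSA uptakes average 100%", {
  ctl_truth <- c(14, 15, 16, 15)
  pct <- vapply(seq_along(ctl_truth), function(i) {
    f <- gen_dmsa_frame(ctl_truth[i], geom, seed = 20 + i, noise = FALSE,
                        background_cpm = 0)
    dmsa_uptake(f, geom$seeds[1:2], geom$seeds$syringe,
                control_percent_ias = 1, masks = geom$masks)$percent_IA
  }, numeric(1))
  normalized <- 100 * pct / mean(pct)
  expect_equal(mean(normalized), 100, tolerance = 1e-9)
})

test_that("paired t comparison matches the hand formula and conventions", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2, p = 1, significant = FALSE,
                    degenerate = TRUE))
  out <- compare_groups(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(out$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(round(out$p, 4), 0.0742)
  expect_false(out$significant)
  deg <- compare_groups(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(deg$significant)
  expect_equal(deg$p, 0)
  expect_error(compare_groups(1:3, 1:4), "equal length")
})

test_that("frame series round-trip through multi-page TIFF + JSON", {
  kin <- renal_kinetics()
  fr <- gen_scintigraphy_series(kin, geom, frame_times_min = c(2.5, 7.5),
                                seed = 3)
  tif <- tempfile(fileext = ".tif"); js <- tempfile(fileext = ".json")
  write_frame_series(fr, tif, js)
  back <- read_frame_series(tif, js)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$counts, round(fr[[1]]$counts), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(back[[2]]$frame_time_min, 7.5)
  expect_equal(back[[1]]$syringe_activity_MBq, 5)
  expect_equal(back[[1]]$injected_MBq, 55)
})
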