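#' Fractional-max ROI segmentation
#'
#' Outlines a region of interest the way the published image analysis did:
#' all pixels at or above 10% of the maximal pixel count, taken as the
#' 8-connected component containing a seed pixel. The maximum is computed
#' within a square window centred on the seed (the object's local maximum,
#' not the frame maximum, which would be the calibration syringe), and the
#' component is grown within that window. Deterministic.
#'
#' @param frame A `planar_frame`.
#' @param seed_pixel (row, col) inside the intended object.
#' @param threshold_frac Fraction of the local maximum, in (0, 1);
#'   default 0.10.
#' @param window Odd window side length (pixels) around the seed.
#' @param label Optional ROI label.
#' @return A logical matrix of class `roi_mask` with attributes `label` and
#'   `threshold` (absolute counts).
#' @export
segment_roi <- function(frame, seed_pixel, threshold_frac = 0.10,
                        window = 61, label = NA_character_) {
  stopifnot(inherits(frame, "planar_frame"), length(seed_pixel) == 2)
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("threshold_frac must be in (0, 1)")
  }
  counts <- frame$counts
  nr <- nrow(counts); nc <- ncol(counts)
  r0 <- seed_pixel[1]; c0 <- seed_pixel[2]
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc) {
    stop("seed pixel outside the image")
  }
  h <- (window - 1) %/% 2
  rows <- max(1, r0 - h):min(nr, r0 + h)
  cols <- max(1, c0 - h):min(nc, c0 + h)
  thr <- threshold_frac * max(counts[rows, cols])
  if (counts[r0, c0] < thr) {
    stop("empty ROI: seed pixel below the threshold")
  }
  above <- matrix(FALSE, nr, nc)
  above[rows, cols] <- counts[rows, cols] >= thr
  # 8-connected flood fill from the seed
  mask <- matrix(FALSE, nr, nc)
  queue <- matrix(c(r0, c0), ncol = 2)
  mask[r0, c0] <- TRUE
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  while (nrow(queue) > 0) {
    cur <- queue
    queue <- matrix(numeric(0), ncol = 2)
    cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
      cbind(cur[, 1] + off[k, 1], cur[, 2] + off[k, 2])
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[ok, , drop = FALSE]
    idx <- cand[, 1] + (cand[, 2] - 1) * nr
    keep <- above[idx] & !mask[idx]
    idx <- unique(idx[keep])
    if (length(idx) > 0) {
      mask[idx] <- TRUE
      queue <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
    }
  }
  structure(mask, label = label, threshold = thr,
            class = c("roi_mask", "matrix"))
}

#' Calibrated activity and percent injected activity of an ROI
#'
#' Converts ROI counts to activity with the calibration syringe imaged in
#' the same frame (assuming similar attenuation for the organ and the
#' syringe): `activity = roi_counts * syringe_activity / syringe_counts`.
#' The result is decay-corrected back to injection time with the 99mTc
#' half-life (6.007 h) and expressed as percent of the injected activity.
#'
#' @param frame A `planar_frame`.
#' @param roi Logical ROI mask (organ).
#' @param syringe_roi Logical ROI mask of the calibration syringe.
#' @return A list: `activity_MBq` (at frame time), `activity_MBq_t0`
#'   (decay-corrected), `percent_IA`, `roi_counts`, `syringe_counts`.
#' @export
quantify_frame <- function(frame, roi, syringe_roi) {
  stopifnot(inherits(frame, "planar_frame"))
  syr <- sum(frame$counts[syringe_roi])
  if (syr <= 0) stop("calibration error: zero syringe counts")
  cnt <- sum(frame$counts[roi])
  act <- cnt * frame$syringe_activity_MBq / syr
  corr <- act * 2^(frame$frame_time_min / (.TC99M_HALF_LIFE_H * 60))
  list(activity_MBq = act,
       activity_MBq_t0 = corr,
       percent_IA = 100 * corr / frame$injected_MBq,
       roi_counts = cnt,
       syringe_counts = syr)
}

#' Renogram from a DTPA frame series
#'
#' Quantifies kidney (left + right) and bladder percent injected activity in
#' every frame and reads the bladder content at 27.5 min. ROIs are outlined
#' per frame with the fractional-max rule from the supplied seed pixels, or
#' taken from `masks` when given (e.g. the generator's truth masks). A
#' bladder whose counts are too low to segment (seed below threshold, as
#' under full obstruction) is recorded as 0 %IA and flagged.
#'
#' @param frames A `frame_series` or list of `planar_frame`s.
#' @param kidney_seeds List of two (row, col) seeds.
#' @param bladder_seed,syringe_seed (row, col) seeds.
#' @param threshold_frac Fractional-max threshold.
#' @param masks Optional named list of logical masks (`left_kidney`,
#'   `right_kidney`, `bladder`, `syringe`) used for every frame instead of
#'   segmentation.
#' @param protocol If `TRUE`, require the seven protocol frame times
#'   (2.5--32.5 min) including the 27.5-min frame.
#' @return A `renogram` data.frame (`time_min`, `kidney_pct`, `left_pct`,
#'   `right_pct`, `bladder_pct`, `bladder_segmented`) with attribute
#'   `bladder_at_27_5`.
#' @export
build_renogram <- function(frames, kidney_seeds, bladder_seed, syringe_seed,
                           threshold_frac = 0.10, masks = NULL,
                           protocol = TRUE) {
  times <- vapply(frames, `[[`, numeric(1), "frame_time_min")
  if (protocol) {
    need <- dtpa_protocol_times()
    if (!all(need %in% times)) {
      stop("protocol error: missing frame(s) at ",
           paste(setdiff(need, times), collapse = ", "), " min")
    }
  }
  rows <- lapply(frames, function(f) {
    get_mask <- function(name, seed) {
      if (!is.null(masks)) return(masks[[name]])
      segment_roi(f, seed, threshold_frac, label = name)
    }
    syr <- get_mask("syringe", syringe_seed)
    lk <- quantify_frame(f, get_mask("left_kidney", kidney_seeds[[1]]), syr)
    rk <- quantify_frame(f, get_mask("right_kidney", kidney_seeds[[2]]), syr)
    bl_ok <- TRUE
    bl <- tryCatch(
      quantify_frame(f, get_mask("bladder", bladder_seed), syr),
      error = function(e) {
        if (!grepl("empty ROI", conditionMessage(e))) stop(e)
        bl_ok <<- FALSE
        list(percent_IA = 0)
      })
    data.frame(time_min = f$frame_time_min,
               kidney_pct = lk$percent_IA + rk$percent_IA,
               left_pct = lk$percent_IA, right_pct = rk$percent_IA,
               bladder_pct = bl$percent_IA, bladder_segmented = bl_ok)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$time_min), , drop = FALSE]
  i275 <- match(27.5, out$time_min)
  attr(out, "bladder_at_27_5") <- if (is.na(i275)) NA_real_ else
    out$bladder_pct[i275]
  class(out) <- c("renogram", "data.frame")
  out
}

#' Bladder content at 27.5 minutes
#'
#' @param renogram A [build_renogram()] result.
#' @return Percent injected activity in the bladder at 27.5 min.
#' @export
bladder_at_27_5 <- function(renogram) attr(renogram, "bladder_at_27_5")

#' DMSA uptake as percent of controls
#'
#' Quantifies the subject's kidney percent injected activity on the static
#' 3-h frame and normalizes it to the mean of the control %IA values.
#'
#' @param frame A `planar_frame` (3-h DMSA image).
#' @param kidney_seeds List of two (row, col) seeds.
#' @param syringe_seed (row, col) seed of the calibration syringe.
#' @param control_percent_ias Non-empty numeric vector of control kidney %IA.
#' @param threshold_frac Fractional-max threshold.
#' @param masks Optional named mask list, as in [build_renogram()].
#' @return A list: `percent_IA` (subject), `percent_of_control`.
#' @export
dmsa_uptake <- function(frame, kidney_seeds, syringe_seed,
                        control_percent_ias, threshold_frac = 0.10,
                        masks = NULL) {
  if (length(control_percent_ias) == 0) {
    stop("control list must be non-empty")
  }
  ctl <- mean(control_percent_ias)
  if (ctl == 0) stop("normalization error: zero control mean")
  get_mask <- function(name, seed) {
    if (!is.null(masks)) return(masks[[name]])
    segment_roi(frame, seed, threshold_frac, label = name)
  }
  syr <- get_mask("syringe", syringe_seed)
  lk <- quantify_frame(frame, get_mask("left_kidney", kidney_seeds[[1]]), syr)
  rk <- quantify_frame(frame, get_mask("right_kidney", kidney_seeds[[2]]), syr)
  pct <- lk$percent_IA + rk$percent_IA
  list(percent_IA = pct, percent_of_control = 100 * pct / ctl)
}

#' Paired Student t-test between matched groups
#'
#' Classical paired two-sided t-test on the per-subject differences, with
#' significance at p < `alpha` (strict). Degenerate inputs follow a
#' documented convention: all differences zero gives t = 0, p = 1; zero
#' variance with a nonzero mean difference gives p = 0 and is flagged.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A list: `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1, p = 1, significant = FALSE,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                significant = TRUE, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE)
}
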