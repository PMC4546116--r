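# Planar gamma-camera frame simulator: two Gaussian-blob kidneys, a disc
# bladder, a rectangular calibration syringe, and a uniform remainder-of-body
# ellipse, rendered as Poisson count images on a 256x256 grid.

.TC99M_HALF_LIFE_H <- 6.007

#' Planar scintigraphy phantom geometry
#'
#' Places the imaged objects on the pixel grid: the two kidneys as 2D
#' Gaussian blobs (truncated at 3 sigma and renormalized, so each kidney's
#' expected counts are exact), the bladder as a uniform disc, the calibration
#' syringe as a uniform rectangle in a corner outside the body, and the
#' remainder-of-body activity spread uniformly over a body ellipse excluding
#' the kidney and bladder regions. Object masks must not overlap.
#'
#' @param nx,ny Image size in pixels.
#' @param kidney_centers List of two (row, col) centers.
#' @param kidney_sigma Gaussian sigma in pixels.
#' @param bladder_center (row, col) center of the bladder disc.
#' @param bladder_radius Disc radius (pixels).
#' @param syringe_rows,syringe_cols Pixel index ranges of the syringe.
#' @param body_center,body_semiaxes Body ellipse ((row, col), (a_row, a_col)).
#' @return An object of class `scinti_geometry` carrying the object masks and
#'   normalized intensity maps.
#' @export
scinti_geometry <- function(nx = 256, ny = 256,
                            kidney_centers = list(c(100, 96), c(100, 160)),
                            kidney_sigma = 6,
                            bladder_center = c(190, 128),
                            bladder_radius = 10,
                            syringe_rows = 8:23, syringe_cols = 232:239,
                            body_center = c(140, 128),
                            body_semiaxes = c(100, 60)) {
  row <- matrix(seq_len(nx), nx, ny)
  col <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  kid_maps <- list(); kid_masks <- list()
  for (i in seq_along(kidney_centers)) {
    c0 <- kidney_centers[[i]]
    d2 <- (row - c0[1])^2 + (col - c0[2])^2
    mask <- d2 <= (3 * kidney_sigma)^2
    map <- exp(-d2 / (2 * kidney_sigma^2)) * mask
    kid_maps[[i]] <- map / sum(map)
    kid_masks[[i]] <- mask
  }
  bl_mask <- (row - bladder_center[1])^2 + (col - bladder_center[2])^2 <=
    bladder_radius^2
  sy_mask <- matrix(FALSE, nx, ny)
  sy_mask[syringe_rows, syringe_cols] <- TRUE
  body_mask <- ((row - body_center[1]) / body_semiaxes[1])^2 +
    ((col - body_center[2]) / body_semiaxes[2])^2 <= 1
  masks <- list(left_kidney = kid_masks[[1]], right_kidney = kid_masks[[2]],
                bladder = bl_mask, syringe = sy_mask)
  pairs <- utils::combn(names(masks), 2)
  for (j in seq_len(ncol(pairs))) {
    if (any(masks[[pairs[1, j]]] & masks[[pairs[2, j]]])) {
      stop("geometry error: object masks overlap (",
           pairs[1, j], " / ", pairs[2, j], ")")
    }
  }
  if (any(sy_mask & body_mask)) {
    stop("geometry error: syringe overlaps the body")
  }
  rem_mask <- body_mask & !kid_masks[[1]] & !kid_masks[[2]] & !bl_mask
  structure(list(
    nx = nx, ny = ny,
    masks = c(masks, list(body = body_mask, remainder = rem_mask)),
    maps = list(
      left_kidney = kid_maps[[1]],
      right_kidney = kid_maps[[2]],
      bladder = bl_mask / sum(bl_mask),
      syringe = sy_mask / sum(sy_mask),
      remainder = rem_mask / sum(rem_mask)),
    seeds = list(left_kidney = kidney_centers[[1]],
                 right_kidney = kidney_centers[[2]],
                 bladder = bladder_center,
                 syringe = c(syringe_rows[1], syringe_cols[1]))),
    class = "scinti_geometry")
}

# Render one frame: object activities (MBq, at frame time) -> expected counts
# or a Poisson realization thereof.
.render_frame <- function(geometry, activities_MBq, duration_min, sensitivity,
                          background_cpm, noise) {
  lambda <- matrix(0, geometry$nx, geometry$ny)
  for (obj in names(activities_MBq)) {
    a <- activities_MBq[[obj]]
    if (a > 0) lambda <- lambda + geometry$maps[[obj]] * a
  }
  lambda <- lambda * sensitivity * duration_min +
    background_cpm * duration_min
  if (noise) {
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     geometry$nx, geometry$ny)
  } else {
    counts <- lambda
  }
  counts
}

#' Simulate a series of planar scintigraphy frames
#'
#' Runs the renal kinetic model, applies 99mTc physical decay at each frame
#' midpoint, distributes the kidney fraction equally over the two kidneys,
#' and renders Poisson count images (or exact expectations in noise-free
#' mode). The calibration syringe is rendered at its stated constant
#' activity; the known value is recorded in every frame's metadata.
#'
#' @param kinetics A [renal_kinetics()].
#' @param geometry A [scinti_geometry()].
#' @param frame_times_min Frame midpoints (minutes post injection).
#' @param seed Integer seed for the Poisson noise.
#' @param duration_min Acquisition duration per frame.
#' @param sensitivity Counts per MBq per minute.
#' @param syringe_activity_MBq Known calibration activity.
#' @param background_cpm Background count rate per pixel per minute.
#' @param noise `FALSE` returns expected counts instead of Poisson draws.
#' @return A `frame_series`: list of `planar_frame` objects (fields `counts`,
#'   `frame_time_min`, `duration_min`, `syringe_activity_MBq`,
#'   `injected_MBq`) with attributes `geometry`, `truth` (kinetic fractions
#'   per frame), `sensitivity`, `background_cpm`.
#' @export
gen_scintigraphy_series <- function(kinetics, geometry,
                                    frame_times_min = dtpa_protocol_times(),
                                    seed = 1, duration_min = 1,
                                    sensitivity = 2000,
                                    syringe_activity_MBq = 5,
                                    background_cpm = 0.02,
                                    noise = TRUE) {
  stopifnot(inherits(kinetics, "renal_kinetics"),
            inherits(geometry, "scinti_geometry"))
  if (any(frame_times_min <= 0)) {
    stop("frame times must be positive minutes post injection")
  }
  frac <- solve_renal_kinetics(kinetics, frame_times_min)
  decay <- 2^(-frame_times_min / (.TC99M_HALF_LIFE_H * 60))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- lapply(seq_along(frame_times_min), function(i) {
    ia <- kinetics$injected_MBq * decay[i]
    acts <- list(left_kidney = frac$kidney[i] * ia / 2,
                 right_kidney = frac$kidney[i] * ia / 2,
                 bladder = frac$bladder[i] * ia,
                 remainder = frac$remainder[i] * ia,
                 syringe = syringe_activity_MBq)
    counts <- .render_frame(geometry, acts, duration_min, sensitivity,
                            background_cpm, noise)
    structure(list(counts = counts,
                   frame_time_min = frame_times_min[i],
                   duration_min = duration_min,
                   syringe_activity_MBq = syringe_activity_MBq,
                   injected_MBq = kinetics$injected_MBq),
              class = "planar_frame")
  })
  structure(frames, class = "frame_series", geometry = geometry,
            truth = frac, sensitivity = sensitivity,
            background_cpm = background_cpm)
}

#' DTPA renography protocol frame times
#'
#' One-minute posterior images every fifth minute between 2.5 and 32.5
#' minutes after tracer injection (frame midpoints).
#'
#' @return Numeric vector of 7 frame times (min).
#' @export
dtpa_protocol_times <- function() seq(2.5, 32.5, by = 5)

#' Simulate a static DMSA frame
#'
#' A 3-minute posterior image 3 h after tracer injection, with a fixed
#' fraction of the injected activity retained in the kidneys (split equally)
#' and the rest in the body pool.
#'
#' @param kidney_percent_ia Percent of injected activity in both kidneys.
#' @param geometry A [scinti_geometry()].
#' @param injected_MBq Injected tracer activity (MBq).
#' @param time_h Imaging time (h post injection).
#' @param duration_min Acquisition duration.
#' @param seed,sensitivity,syringe_activity_MBq,background_cpm,noise As in
#'   [gen_scintigraphy_series()].
#' @return A `planar_frame`.
#' @export
gen_dmsa_frame <- function(kidney_percent_ia, geometry, injected_MBq = 40,
                           time_h = 3, duration_min = 3, seed = 1,
                           sensitivity = 2000, syringe_activity_MBq = 5,
                           background_cpm = 0.02, noise = TRUE) {
  stopifnot(kidney_percent_ia >= 0, kidney_percent_ia <= 100)
  k <- kidney_percent_ia / 100
  decay <- 2^(-time_h / .TC99M_HALF_LIFE_H)
  ia <- injected_MBq * decay
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  acts <- list(left_kidney = k * ia / 2, right_kidney = k * ia / 2,
               bladder = 0, remainder = (1 - k) * ia,
               syringe = syringe_activity_MBq)
  counts <- .render_frame(geometry, acts, duration_min, sensitivity,
                          background_cpm, noise)
  structure(list(counts = counts, frame_time_min = time_h * 60,
                 duration_min = duration_min,
                 syringe_activity_MBq = syringe_activity_MBq,
                 injected_MBq = injected_MBq),
            class = "planar_frame")
}

#' Write and read a frame series as multi-page TIFF plus JSON metadata
#'
#' Counts are stored as 16-bit unsigned integers (one TIFF page per frame);
#' frame times, durations, syringe activity and injected activity go to a
#' JSON sidecar.
#'
#' @param frames A `frame_series` or list of `planar_frame`s.
#' @param tif,json File paths.
#' @return `read_frame_series()` returns a list of `planar_frame`s;
#'   `write_frame_series()` the paths, invisibly.
#' @export
write_frame_series <- function(frames, tif, json) {
  mx <- 65535
  pages <- lapply(frames, function(f) {
    if (max(f$counts) > mx) stop("counts exceed 16-bit range")
    round(f$counts) / mx
  })
  tiff::writeTIFF(pages, tif, bits.per.sample = 16)
  meta <- list(
    frame_time_min = vapply(frames, `[[`, numeric(1), "frame_time_min"),
    duration_min = vapply(frames, `[[`, numeric(1), "duration_min"),
    syringe_activity_MBq = vapply(frames, `[[`, numeric(1),
                                  "syringe_activity_MBq"),
    injected_MBq = vapply(frames, `[[`, numeric(1), "injected_MBq"))
  jsonlite::write_json(meta, json, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(c(tif = tif, json = json))
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(tif, json) {
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  lapply(seq_along(pages), function(i) {
    structure(list(counts = pages[[i]],
                   frame_time_min = meta$frame_time_min[i],
                   duration_min = meta$duration_min[i],
                   syringe_activity_MBq = meta$syringe_activity_MBq[i],
                   injected_MBq = meta$injected_MBq[i]),
              class = "planar_frame")
  })
}
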