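#' Saturable kidney uptake model
#'
#' The fraction of injected activity reaching the kidney uptake plateau
#' follows a one-site saturation curve, u(A) = u0 * k_sat / (k_sat + A):
#' at vanishing injected activity the uptake fraction approaches `u0`, and it
#' declines as receptor-mediated uptake saturates with increasing injected
#' activity. This is the simplest form reproducing the decreasing Gy/MBq in
#' the published dose table. Retention in the kidney is biexponential
#' (fast + slow biological components) on top of physical decay.
#'
#' @param u0 Zero-activity uptake fraction (0 < u0 <= 1).
#' @param k_sat_MBq Saturation constant (MBq, > 0).
#' @param half_life_fast_h,half_life_slow_h Biological clearance half-lives
#'   (h, > 0).
#' @param fraction_fast Fraction of retained activity clearing with the fast
#'   component, in [0, 1].
#' @return An object of class `uptake_model`.
#' @export
uptake_model <- function(u0, k_sat_MBq, half_life_fast_h = 12,
                         half_life_slow_h = 120, fraction_fast = 0.9) {
  if (!is.numeric(u0) || u0 <= 0 || u0 > 1) {
    stop("invalid parameter: u0 must be in (0, 1]")
  }
  if (k_sat_MBq <= 0) stop("invalid parameter: k_sat_MBq must be > 0")
  if (half_life_fast_h <= 0 || half_life_slow_h <= 0) {
    stop("invalid parameter: half-lives must be > 0")
  }
  if (fraction_fast < 0 || fraction_fast > 1) {
    stop("invalid parameter: fraction_fast must be in [0, 1]")
  }
  structure(
    list(u0 = u0, k_sat_MBq = k_sat_MBq,
         half_life_fast_h = half_life_fast_h,
         half_life_slow_h = half_life_slow_h,
         fraction_fast = fraction_fast),
    class = "uptake_model"
  )
}

#' Uptake fraction at a given injected activity
#'
#' @param model An [uptake_model()].
#' @param injected_MBq Injected activity (MBq, >= 0).
#' @return Fraction of injected activity at the uptake plateau.
#' @export
uptake_fraction <- function(model, injected_MBq) {
  stopifnot(inherits(model, "uptake_model"), all(injected_MBq >= 0))
  model$u0 * model$k_sat_MBq / (model$k_sat_MBq + injected_MBq)
}

#' Simulate a kidney time-activity curve
#'
#' The kidney activity at time t (hours post injection) is
#' `u(A) * A * (f * 2^(-t/Tf) + (1-f) * 2^(-t/Ts)) * 2^(-t/Tp)`,
#' i.e. instantaneous plateau uptake followed by biexponential biological
#' clearance multiplied by 177Lu physical decay (Tp = 159.528 h). The curve
#' is deterministic unless `noise_cv` is set, in which case each sample gets
#' independent multiplicative log-normal noise.
#'
#' @param injected_MBq Injected activity (MBq, >= 0).
#' @param model An [uptake_model()].
#' @param grid_h Strictly increasing sample times (h), all > 0.
#' @param phys_half_life_h Physical half-life (h).
#' @param noise_cv Optional coefficient of variation for multiplicative
#'   noise; `NULL` (default) for a noise-free curve.
#' @param seed Seed used only when `noise_cv` is set.
#' @return A `tac` object: data.frame with columns `time_h`, `activity_MBq`
#'   and attribute `organ = "kidney"`.
#' @export
gen_biodistribution <- function(injected_MBq, model, grid_h,
                                phys_half_life_h = 159.528,
                                noise_cv = NULL, seed = 1) {
  stopifnot(inherits(model, "uptake_model"))
  if (injected_MBq < 0) stop("injected_MBq must be >= 0")
  if (length(grid_h) == 0) stop("input error: empty time grid")
  if (any(grid_h <= 0) || any(diff(grid_h) <= 0)) {
    stop("grid_h must be strictly increasing and > 0")
  }
  u <- uptake_fraction(model, injected_MBq)
  retention <- model$fraction_fast * 2^(-grid_h / model$half_life_fast_h) +
    (1 - model$fraction_fast) * 2^(-grid_h / model$half_life_slow_h)
  act <- u * injected_MBq * retention * 2^(-grid_h / phys_half_life_h)
  if (!is.null(noise_cv)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    act <- act * stats::rlnorm(length(act), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
  }
  tac <- data.frame(time_h = grid_h, activity_MBq = act)
  attr(tac, "organ") <- "kidney"
  class(tac) <- c("tac", "data.frame")
  tac
}

#' Read and write a time-activity curve as two-column CSV
#'
#' @param tac A `tac` data.frame (`time_h`, `activity_MBq`).
#' @param path CSV file path.
#' @return `read_tac()` returns a `tac`; `write_tac()` the path, invisibly.
#' @export
write_tac <- function(tac, path) {
  utils::write.csv(tac[, c("time_h", "activity_MBq")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "activity_MBq") %in% names(df)))
  class(df) <- c("tac", "data.frame")
  attr(df, "organ") <- "kidney"
  df
}
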