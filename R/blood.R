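# Blood-marker derivation: test/control ratios, reduction factors, and
# fold increases for WBC, RBC, urea, and creatinine panels.

.BLOOD_BASELINES <- c(wbc = 8, rbc = 9, urea = 8, creatinine = 20)
# units: WBC 1e9/L, RBC 1e12/L, urea mmol/L, creatinine umol/L
.DOSE_ANCHORS_GY <- c(16, 29, 40, 48, 54)
.ACTIVITY_ANCHORS_MBQ <- c(30, 60, 90, 120, 150)

#' Simulate a blood panel
#'
#' Draws one animal's panel (WBC, RBC, urea, creatinine) whose expected
#' test/control ratio equals the ratio-table cell for the nearest (dose,
#' time) condition, with multiplicative log-normal noise. Dose 0 is a
#' control panel (expected ratio 1 for every analyte). The absorbed dose is
#' mapped to the nearest published activity level (16/29/40/48/54 Gy
#' correspond to 30--150 MBq); a missing cell falls back to the nearest
#' available time point for that analyte and activity.
#'
#' @param dose_Gy Kidney absorbed dose (Gy, >= 0).
#' @param timepoint_months Time point (months).
#' @param effect_table Ratio table (see [load_blood_ratio_table()]).
#' @param seed Integer seed; fixed seed gives a bitwise-identical panel.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @return A `blood_panel` data.frame (`analyte`, `value`) with attributes
#'   `dose_Gy`, `timepoint_months`, `is_control`.
#' @export
gen_blood_panel <- function(dose_Gy, timepoint_months, effect_table,
                            seed = 1, cv = 0.1) {
  if (dose_Gy < 0) stop("input error: negative dose")
  analytes <- names(.BLOOD_BASELINES)
  ratios <- stats::setNames(rep(1, length(analytes)), analytes)
  if (dose_Gy > 0) {
    act <- .ACTIVITY_ANCHORS_MBQ[which.min(abs(.DOSE_ANCHORS_GY - dose_Gy))]
    for (an in analytes) {
      sub <- effect_table[effect_table$analyte == an &
                            effect_table$activity_MBq == act, , drop = FALSE]
      if (nrow(sub) == 0) {
        stop("effect table has no cells for analyte ", an,
             " at ", act, " MBq")
      }
      i <- which.min(abs(sub$timepoint_months - timepoint_months))
      ratios[[an]] <- sub$percent_of_control[i] / 100
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- stats::rlnorm(length(analytes), meanlog = -sdlog^2 / 2,
                         sdlog = sdlog)
  panel <- data.frame(analyte = analytes,
                      value = unname(.BLOOD_BASELINES * ratios * noise),
                      stringsAsFactors = FALSE)
  structure(panel, dose_Gy = dose_Gy, timepoint_months = timepoint_months,
            is_control = dose_Gy == 0,
            class = c("blood_panel", "data.frame"))
}

#' Test/control ratios, reduction factors, and fold increases
#'
#' Summarizes groups of blood panels the way the published table reports
#' them: per analyte, percent of control = 100 x mean(test) / mean(control);
#' the reduction factor is 100/percent rounded to one decimal (used for
#' counts that fall, e.g. "reduced by a factor 2.0"); the fold increase is
#' percent/100, also reported rounded to the nearest integer for "n-fold"
#' phrasing.
#'
#' @param test_panels,control_panels Non-empty lists of `blood_panel`s (or
#'   data.frames with `analyte`, `value`) over the same analytes.
#' @return A data.frame: `analyte`, `percent_of_control`,
#'   `reduction_factor`, `fold_increase`, `fold_nearest`.
#' @export
derive_ratios <- function(test_panels, control_panels) {
  if (length(test_panels) == 0 || length(control_panels) == 0) {
    stop("both panel lists must be non-empty")
  }
  pool <- function(panels) {
    df <- do.call(rbind, lapply(panels, function(p) p[, c("analyte", "value")]))
    tapply(df$value, df$analyte, mean)
  }
  test <- pool(test_panels)
  ctl <- pool(control_panels)
  analytes <- sort(names(test))
  if (!setequal(analytes, names(ctl))) {
    stop("test and control panels must share the same analytes")
  }
  if (any(ctl[analytes] == 0)) {
    stop("undefined ratio: zero control mean")
  }
  percent <- 100 * unname(test[analytes]) / unname(ctl[analytes])
  data.frame(analyte = analytes,
             percent_of_control = percent,
             reduction_factor = round(100 / percent, 1),
             fold_increase = percent / 100,
             fold_nearest = round(percent / 100),
             stringsAsFactors = FALSE)
}

#' Summary statistics straight from the published ratio table
#'
#' Applies the reduction-factor and fold-increase arithmetic to the fixture
#' percentages themselves (the table stores test/control as percent).
#'
#' @param effect_table Ratio table (see [load_blood_ratio_table()]).
#' @return The table with `reduction_factor`, `fold_increase`, and
#'   `fold_nearest` columns appended.
#' @export
blood_summary_from_fixture <- function(effect_table) {
  p <- effect_table$percent_of_control
  effect_table$reduction_factor <- round(100 / p, 1)
  effect_table$fold_increase <- p / 100
  effect_table$fold_nearest <- round(p / 100)
  effect_table
}
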