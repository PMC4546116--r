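#' Study design for a dose-by-time kidney expression experiment
#'
#' Describes the layout of the animal study the simulator emulates: a set of
#' injected activities plus saline controls, three late time points, two
#' kidney tissues, and a small number of replicates per group. The default
#' arguments reproduce the published design: 30--150 MBq in five steps,
#' 4/8/12 months, cortex and medulla, n = 3 exposed animals per group and
#' three age-matched controls per time point.
#'
#' @param activities_MBq Strictly increasing positive injected activities
#'   (MBq), excluding the control (0 MBq is implicit).
#' @param doses_Gy Kidney absorbed dose (Gy) corresponding to each activity;
#'   used by effect models, which are expressed on the absorbed-dose scale.
#' @param timepoints_months Time points after administration (months).
#' @param tissues Tissue labels.
#' @param replicates_per_group Exposed animals per activity-by-time group.
#' @param controls_per_timepoint Age-matched control animals per time point.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(activities_MBq = c(30, 60, 90, 120, 150),
                         doses_Gy = c(16, 29, 40, 48, 54),
                         timepoints_months = c(4, 8, 12),
                         tissues = c("cortex", "medulla"),
                         replicates_per_group = 3,
                         controls_per_timepoint = 3) {
  if (length(activities_MBq) == 0 || any(activities_MBq <= 0)) {
    stop("activities_MBq must be positive (the 0 MBq control is implicit)")
  }
  if (any(diff(activities_MBq) <= 0)) {
    stop("activities_MBq must be strictly increasing")
  }
  if (length(doses_Gy) != length(activities_MBq) || any(doses_Gy < 0)) {
    stop("doses_Gy must be non-negative and aligned with activities_MBq")
  }
  if (replicates_per_group < 2) stop("replicates_per_group must be >= 2")
  if (controls_per_timepoint < 2) stop("controls_per_timepoint must be >= 2")
  if (length(timepoints_months) == 0 || length(tissues) == 0) {
    stop("timepoints_months and tissues must be non-empty")
  }
  design <- structure(
    list(
      activities_MBq = activities_MBq,
      doses_Gy = doses_Gy,
      timepoints_months = timepoints_months,
      tissues = tissues,
      replicates_per_group = replicates_per_group,
      controls_per_timepoint = controls_per_timepoint
    ),
    class = "study_design"
  )
  design
}

#' Number of exposure groups per tissue in a design
#'
#' One group per (activity, time point) pair; 15 for the default design.
#'
#' @param design A `study_design`.
#' @return Integer group count.
#' @export
n_groups <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$activities_MBq) * length(design$timepoints_months)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:",
      length(x$activities_MBq), "activities x",
      length(x$timepoints_months), "timepoints x",
      length(x$tissues), "tissues,",
      x$replicates_per_group, "replicates/group,",
      x$controls_per_timepoint, "controls/timepoint\n")
  cat("  activities (MBq):", paste(x$activities_MBq, collapse = ", "), "\n")
  cat("  doses (Gy):      ", paste(x$doses_Gy, collapse = ", "), "\n")
  invisible(x)
}
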