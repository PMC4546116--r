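#' Packaged fixtures transcribed from the published tables
#'
#' Three plain-text tables ship with the package under `extdata/`:
#' \describe{
#'   \item{table1_markers.tsv}{per-tissue panel of previously proposed
#'     kidney-injury / radiation marker genes with their printed log2 ratios
#'     per (time point, activity) cell, the marker category, and a flag for
#'     genes also proposed as protein-level biodosimeters.}
#'   \item{table2_regulators.tsv}{upstream regulator to target-gene map per
#'     tissue (one row per regulator-target pair).}
#'   \item{table3_ratios.tsv}{blood, body-weight, and scintigraphy summary
#'     ratios versus control (percent), per (time point, activity, analyte);
#'     cells the study could not measure are absent.}
#' }
#' Values are stored exactly as printed; they are inputs, never recomputed.
#'
#' @param path Optional override path to the TSV (used in tests); by default
#'   the installed fixture is read.
#' @return A data.frame.
#' @name fixtures
NULL

.fixture_path <- function(file, path = NULL) {
  if (!is.null(path)) return(path)
  p <- system.file("extdata", file, package = "renaltox")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' @rdname fixtures
#' @export
load_marker_catalogue <- function(path = NULL) {
  df <- utils::read.delim(.fixture_path("table1_markers.tsv", path),
                          stringsAsFactors = FALSE)
  needed <- c("tissue", "timepoint_months", "activity_MBq", "gene",
              "log2_ratio", "category", "protein_flag")
  stopifnot(all(needed %in% names(df)))
  df$protein_flag <- as.logical(df$protein_flag)
  df
}

#' @rdname fixtures
#' @export
load_regulator_map <- function(path = NULL) {
  df <- utils::read.delim(.fixture_path("table2_regulators.tsv", path),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("tissue", "regulator", "target") %in% names(df)))
  if (any(!nzchar(df$target))) stop("regulator map contains empty targets")
  df
}

#' @rdname fixtures
#' @export
load_blood_ratio_table <- function(path = NULL) {
  df <- utils::read.delim(.fixture_path("table3_ratios.tsv", path),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("timepoint_months", "activity_MBq", "analyte",
                  "percent_of_control") %in% names(df)))
  df
}

#' Recurrence matrix from the packaged marker panel
#'
#' Builds the per-tissue [build_recurrence()] matrix directly from the
#' marker-panel fixture: every printed cell is a significant call of the
#' published analysis (printed values are rounded, so the dual threshold is
#' not re-applied here), and the group axis is the full published design
#' (4/8/12 months x 30--150 MBq, 15 groups).
#'
#' @param markers The [load_marker_catalogue()] data.frame.
#' @param tissue `"cortex"` or `"medulla"`.
#' @param timepoints_months,activities_MBq Full group axes.
#' @return A `recurrence_matrix`.
#' @export
recurrence_from_catalogue <- function(markers, tissue,
                                      timepoints_months = c(4, 8, 12),
                                      activities_MBq = c(30, 60, 90, 120, 150)) {
  sub <- markers[markers$tissue == tissue, , drop = FALSE]
  sub$significant <- TRUE
  # ensure every group cell is represented so the axis is complete
  axis <- expand.grid(activity_MBq = activities_MBq,
                      timepoint_months = timepoints_months,
                      KEEP.OUT.ATTRS = FALSE)
  pad <- data.frame(gene = NA_character_, tissue = tissue,
                    timepoint_months = axis$timepoint_months,
                    activity_MBq = axis$activity_MBq,
                    log2_ratio = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  sig_rows <- sub[, c("gene", "tissue", "timepoint_months", "activity_MBq",
                      "log2_ratio")]
  sig_rows$significant <- TRUE
  de_like <- rbind(sig_rows, pad)
  build_recurrence(de_like, tissue,
                   timepoints_months = timepoints_months,
                   activities_MBq = activities_MBq)
}

#' Unique marker catalogue per tissue
#'
#' Collapses the marker panel to one row per gene (category and protein
#' flag), for use as the annotation catalogue in [marker_overlap()].
#'
#' @param markers The [load_marker_catalogue()] data.frame.
#' @param tissue Tissue to extract.
#' @return A data.frame `gene`, `category`, `protein_flag`.
#' @export
marker_catalogue_genes <- function(markers, tissue) {
  sub <- markers[markers$tissue == tissue,
                 c("gene", "category", "protein_flag")]
  sub <- sub[!duplicated(sub$gene), , drop = FALSE]
  sub <- sub[order(sub$gene), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Extract a gene's dose profile from a recurrence matrix
#'
#' Returns the log2 ratios of one gene at one time point, ordered by
#' increasing activity (NA where the gene was not significant).
#'
#' @param m A `recurrence_matrix`.
#' @param gene Gene symbol.
#' @param timepoint_months Time point to extract.
#' @return Named numeric vector ordered by activity.
#' @export
dose_profile <- function(m, gene, timepoint_months) {
  stopifnot(inherits(m, "recurrence_matrix"))
  groups <- attr(m, "groups")
  sel <- which(groups$timepoint_months == timepoint_months)
  sel <- sel[order(groups$activity_MBq[sel])]
  i <- match(.norm_symbol(gene), .norm_symbol(rownames(m)))
  if (is.na(i)) return(stats::setNames(rep(NA_real_, length(sel)),
                                       groups$group[sel]))
  stats::setNames(m[i, sel], groups$group[sel])
}
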