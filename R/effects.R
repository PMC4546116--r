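#' Per-gene effect model for the expression simulator
#'
#' Assigns every simulated gene a class and a true-effect function mapping
#' (absorbed dose in Gy, time point in months) to the expected log2 ratio
#' versus age-matched controls. Measurement noise is Gaussian on the log2
#' scale with a common standard deviation, which keeps the downstream Welch
#' tests' assumptions transparent.
#'
#' Classes:
#' \describe{
#'   \item{null}{identically zero effect at all doses and times.}
#'   \item{monotone_dose}{effect non-decreasing in dose at every fixed time.}
#'   \item{late_responder}{effect appears only from an onset time point.}
#'   \item{recurrent_marker}{tabulated effect per (dose, time) cell, e.g. a
#'     Cdkn1a-like profile.}
#' }
#'
#' @param classes Named character vector, gene id -> class.
#' @param effects Named list of `function(dose_Gy, timepoint_months)` for
#'   every non-null gene. Null genes need no entry.
#' @param noise_sd Standard deviation of the Gaussian log2 noise (> 0).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(classes, effects = list(), noise_sd = 0.2) {
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stop("classes must be a named vector (names are gene ids)")
  }
  if (anyDuplicated(names(classes))) stop("duplicate gene identifiers")
  allowed <- c("null", "monotone_dose", "late_responder", "recurrent_marker")
  if (!all(classes %in% allowed)) {
    stop("unknown gene class; allowed: ", paste(allowed, collapse = ", "))
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0) {
    stop("invalid parameter: noise_sd must be a single positive number")
  }
  non_null <- names(classes)[classes != "null"]
  missing <- setdiff(non_null, names(effects))
  if (length(missing) > 0) {
    stop("non-null genes without an effect function: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(
    list(classes = classes, effects = effects, noise_sd = noise_sd),
    class = "effect_model"
  )
}

#' True log2 effect of one gene at one condition
#'
#' @param model An `effect_model`.
#' @param gene Gene id.
#' @param dose_Gy Absorbed dose (Gy).
#' @param timepoint_months Time point (months).
#' @return Numeric expected log2 ratio (0 for null genes).
#' @export
gene_effect <- function(model, gene, dose_Gy, timepoint_months) {
  stopifnot(inherits(model, "effect_model"))
  cls <- model$classes[[gene]]
  if (is.null(cls)) stop("unknown gene: ", gene)
  if (cls == "null") return(0)
  model$effects[[gene]](dose_Gy, timepoint_months)
}

#' Effect-shape constructors
#'
#' Helpers returning `function(dose_Gy, timepoint_months)` closures for use
#' in [effect_model()].
#'
#' * `effect_linear()`: log2 ratio grows linearly with absorbed dose.
#' * `effect_late()`: linear-in-dose effect switched on from an onset time.
#' * `effect_table()`: exact lookup of a (dose x time) table of log2 ratios,
#'   used to plant marker-like profiles (doses/times outside the table error).
#'
#' @param slope_per_Gy log2 ratio per Gy.
#' @param amplitude log2 ratio at `dose_ref` after onset.
#' @param onset_months first time point at which the effect is present.
#' @param dose_ref reference dose (Gy) at which `amplitude` applies.
#' @param values numeric matrix of log2 ratios, doses in rows, times in
#'   columns.
#' @param doses_Gy,timepoints_months axes of `values`.
#' @return A function of (dose_Gy, timepoint_months).
#' @name effect_shapes
NULL

#' @rdname effect_shapes
#' @export
effect_linear <- function(slope_per_Gy) {
  force(slope_per_Gy)
  function(dose_Gy, timepoint_months) slope_per_Gy * dose_Gy
}

#' @rdname effect_shapes
#' @export
effect_late <- function(amplitude, onset_months = 12, dose_ref = 54) {
  force(amplitude); force(onset_months); force(dose_ref)
  function(dose_Gy, timepoint_months) {
    if (timepoint_months >= onset_months) amplitude * dose_Gy / dose_ref else 0
  }
}

#' @rdname effect_shapes
#' @export
effect_table <- function(values, doses_Gy, timepoints_months) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(doses_Gy),
            ncol(values) == length(timepoints_months))
  function(dose_Gy, timepoint_months) {
    i <- match(dose_Gy, doses_Gy)
    j <- match(timepoint_months, timepoints_months)
    if (is.na(i) || is.na(j)) {
      stop("effect table has no cell for dose ", dose_Gy,
           " Gy at ", timepoint_months, " months")
    }
    values[i, j]
  }
}

#' Default effect model emulating the study's transcriptional structure
#'
#' Builds a scaled-down array of `n_genes` genes: one Cdkn1a-like recurrent
#' marker carrying the published cortex log2 profile, a block of
#' monotone dose-response genes with slopes spanning weak to strong
#' regulation, a few late responders visible only at 12 months, and null
#' genes for the remainder. Gene ids are `g0001 ...`; the marker gene is
#' named `Cdkn1a_like`.
#'
#' @param n_genes Total gene count (>= 30).
#' @param design A [study_design()]; supplies the dose/time axes for the
#'   tabulated marker profile.
#' @param noise_sd Gaussian log2 noise SD.
#' @param n_monotone,n_late Numbers of planted monotone and late genes.
#' @param seed Seed used to draw the monotone slopes reproducibly.
#' @return An `effect_model`.
#' @export
default_effect_model <- function(n_genes = 1000, design = study_design(),
                                 noise_sd = 0.2, n_monotone = 20,
                                 n_late = 5, seed = 1) {
  stopifnot(n_genes >= 30)
  # Published Cdkn1a cortex profile: rows = doses, cols = 4/8/12 months.
  # 4-month cells below the reporting threshold are kept small but non-zero.
  cdkn1a <- cbind(
    c(0.3, 0.5, 1.2, 1.49, 2.0),
    c(0.5, 0.87, 1.1, 1.5, 1.8),
    c(1.3, 1.0, 1.6, 1.4, 2.0)
  )
  marker_fun <- effect_table(cdkn1a, design$doses_Gy,
                             design$timepoints_months)
  n_null <- n_genes - 1 - n_monotone - n_late
  ids <- sprintf("g%04d", seq_len(n_genes - 1))
  genes <- c("Cdkn1a_like", ids)
  classes <- c(
    "recurrent_marker",
    rep("monotone_dose", n_monotone),
    rep("late_responder", n_late),
    rep("null", n_null)
  )
  names(classes) <- genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  slopes <- stats::runif(n_monotone, 0.015, 0.05)
  effects <- c(
    list(Cdkn1a_like = marker_fun),
    stats::setNames(lapply(slopes, effect_linear),
                    genes[2:(1 + n_monotone)]),
    stats::setNames(
      lapply(seq_len(n_late), function(i) effect_late(1 + 0.2 * i)),
      genes[(2 + n_monotone):(1 + n_monotone + n_late)]
    )
  )
  effect_model(classes, effects, noise_sd = noise_sd)
}

# Save/restore the global RNG state so constructors with internal draws do
# not perturb caller-level reproducibility.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
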