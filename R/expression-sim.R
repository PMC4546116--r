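#' Simulate a dose-by-time kidney expression study
#'
#' Generates one genes-by-samples log2-intensity matrix per tissue under the
#' given design and effect model. Each gene receives a fixed baseline
#' log2 intensity (drawn once per tissue), exposed samples add the gene's
#' true effect at their (dose, time) cell, and every measurement adds
#' independent Gaussian log2 noise. Controls are drawn per time point
#' (age-matched) and shared across activities at that time point, as in the
#' animal study.
#'
#' Monotone-dose genes are validated against the design's dose grid at
#' construction time: a `monotone_dose` effect that decreases anywhere on the
#' grid is an error.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()]; every gene must have a class.
#' @param seed Integer seed; fixed seed gives a bitwise-identical study.
#' @return An object of class `expr_study`: a named list (one element per
#'   tissue) of `expr_set` objects, each with elements `exprs` (matrix,
#'   genes x samples), `samples` (data.frame of sample metadata) and
#'   `tissue`.
#' @export
gen_expression_set <- function(design, effects, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_model"))
  genes <- names(effects$classes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (effects$noise_sd <= 0) stop("invalid parameter: noise_sd must be > 0")
  .check_monotone(design, effects)

  # Precompute true effects per gene x (activity, timepoint) cell.
  cells <- expand.grid(activity = design$activities_MBq,
                       timepoint = design$timepoints_months,
                       KEEP.OUT.ATTRS = FALSE)
  cells$dose <- design$doses_Gy[match(cells$activity, design$activities_MBq)]
  eff_mat <- matrix(0, nrow = length(genes), ncol = nrow(cells),
                    dimnames = list(genes, NULL))
  for (g in genes) {
    if (effects$classes[[g]] == "null") next
    f <- effects$effects[[g]]
    eff_mat[g, ] <- mapply(f, cells$dose, cells$timepoint)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  study <- lapply(design$tissues, function(tissue) {
    baseline <- stats::rnorm(length(genes), mean = 8, sd = 1.5)
    meta <- .sample_sheet(design, tissue)
    mat <- matrix(NA_real_, nrow = length(genes), ncol = nrow(meta),
                  dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- baseline
      if (!meta$is_control[j]) {
        cell <- which(cells$activity == meta$activity_MBq[j] &
                        cells$timepoint == meta$timepoint_months[j])
        mu <- mu + eff_mat[, cell]
      }
      mat[, j] <- mu + stats::rnorm(length(genes), sd = effects$noise_sd)
    }
    structure(list(exprs = mat, samples = meta, tissue = tissue),
              class = "expr_set")
  })
  names(study) <- design$tissues
  structure(study, class = "expr_study", design = design)
}

.sample_sheet <- function(design, tissue) {
  rows <- list()
  for (tp in design$timepoints_months) {
    for (r in seq_len(design$controls_per_timepoint)) {
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tissue, timepoint_months = tp, activity_MBq = 0,
        is_control = TRUE, replicate = r,
        stringsAsFactors = FALSE)
    }
    for (a in design$activities_MBq) {
      for (r in seq_len(design$replicates_per_group)) {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tissue, timepoint_months = tp, activity_MBq = a,
          is_control = FALSE, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf(
    "%s_%dmo_%s_r%d", substr(meta$tissue, 1, 3), meta$timepoint_months,
    ifelse(meta$is_control, "ctl", paste0(meta$activity_MBq, "MBq")),
    meta$replicate)
  meta
}

.check_monotone <- function(design, effects) {
  mono <- names(effects$classes)[effects$classes == "monotone_dose"]
  for (g in mono) {
    f <- effects$effects[[g]]
    for (tp in design$timepoints_months) {
      vals <- vapply(design$doses_Gy, f, numeric(1), tp)
      if (any(diff(vals) < 0)) {
        stop("monotone_dose gene '", g,
             "' decreases with dose at ", tp, " months")
      }
    }
  }
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", x$tissue, "-", nrow(x$exprs), "genes x",
      ncol(x$exprs), "samples\n")
  invisible(x)
}

#' Read and write expression sets as TSV plus JSON metadata
#'
#' The matrix is written as a tab-separated table (genes in rows, samples in
#' columns, first column `gene`), the sample sheet as a JSON sidecar.
#'
#' @param es An `expr_set`.
#' @param tsv,json File paths.
#' @return `read_expression_set()` returns an `expr_set`;
#'   `write_expression_set()` returns the paths invisibly.
#' @export
write_expression_set <- function(es, tsv, json) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(gene = rownames(es$exprs), es$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tissue = es$tissue, samples = es$samples),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_expression_set
#' @export
read_expression_set <- function(tsv, json) {
  df <- utils::read.delim(tsv, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  samples <- as.data.frame(meta$samples, stringsAsFactors = FALSE)
  structure(list(exprs = mat, samples = samples, tissue = meta$tissue),
            class = "expr_set")
}
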