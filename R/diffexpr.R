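#' Quantile-normalize a log2 expression matrix
#'
#' Each column's sorted values are replaced by the across-sample mean of the
#' order statistics; tied values receive the mean of the means over their
#' tied rank range. Delegates to `limma::normalizeQuantiles(ties = TRUE)`,
#' which implements exactly this rule.
#'
#' @param mat Numeric matrix, genes x samples.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (!all(is.finite(mat))) stop("input error: matrix must be finite")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Remove low-variance genes
#'
#' Drops genes whose cross-sample variance falls strictly below the
#' `variance_quantile` of all gene variances. With `variance_quantile = 0`
#' nothing is removed. Genes with exactly zero variance carry no usable
#' signal and are always dropped when the filter is active; a completely
#' constant matrix therefore filters to zero genes, with a warning rather
#' than an error.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param variance_quantile Fraction in [0, 1) of lowest-variance genes to
#'   remove.
#' @return The filtered matrix.
#' @export
variance_filter <- function(mat, variance_quantile = 0.2) {
  stopifnot(is.matrix(mat))
  if (variance_quantile < 0 || variance_quantile >= 1) {
    stop("variance_quantile must be in [0, 1)")
  }
  if (variance_quantile == 0) return(mat)
  v <- apply(mat, 1, stats::var)
  thr <- stats::quantile(v, variance_quantile, names = FALSE)
  keep <- v >= thr & v > 0
  if (!any(keep)) {
    warning("variance filter removed all genes")
  }
  mat[keep, , drop = FALSE]
}

#' Preprocess an expression set: quantile normalization then variance filter
#'
#' @param es An `expr_set`.
#' @param variance_quantile Passed to [variance_filter()]; default removes
#'   the lowest 20% variance genes.
#' @return The preprocessed `expr_set`.
#' @export
preprocess <- function(es, variance_quantile = 0.2) {
  stopifnot(inherits(es, "expr_set"))
  mat <- quantile_normalize(es$exprs)
  es$exprs <- variance_filter(mat, variance_quantile)
  es
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`):
#' q_(i) = min over j >= i of n * p_(j) / j, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("input error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised two-sided Welch t-test across genes (rows). Zero variance in
# both groups: p = 1 when the means are equal, p = 0 otherwise (documented
# convention for degenerate, noise-free inputs).
.welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (mx == my)
    p[degenerate] <- 0
    p[eq] <- 1
    tstat[degenerate] <- sign(mx - my)[degenerate] * Inf
    tstat[eq] <- 0
  }
  list(log2_ratio = mx - my, t = tstat, df = df, p = p)
}

#' Differential expression of one exposure group versus matched controls
#'
#' Computes, per gene, the log2 ratio (group mean minus age-matched control
#' mean on the log2 scale), a two-sided Welch t-test p-value, the
#' Benjamini-Hochberg q-value across genes within this group, and the
#' significance call under the dual threshold (q < `q_max` and
#' |log2 ratio| > `lfc_min`, both strict).
#'
#' @param es An `expr_set` (typically after [preprocess()]).
#' @param timepoint_months,activity_MBq Group selector.
#' @param q_max,lfc_min Significance thresholds; defaults FDR 0.01 and
#'   log2 ratio 0.58 (= log2 1.5 to two decimals).
#' @return A data.frame with columns `gene`, `tissue`, `timepoint_months`,
#'   `activity_MBq`, `log2_ratio`, `t`, `p`, `q`, `significant`, `direction`.
#' @export
de_table <- function(es, timepoint_months, activity_MBq,
                     q_max = 0.01, lfc_min = 0.58) {
  stopifnot(inherits(es, "expr_set"))
  s <- es$samples
  grp <- which(!s$is_control & s$timepoint_months == timepoint_months &
                 s$activity_MBq == activity_MBq)
  ctl <- which(s$is_control & s$timepoint_months == timepoint_months)
  if (length(grp) < 2) {
    stop("pairing error: exposure group ", activity_MBq, " MBq at ",
         timepoint_months, " months has fewer than 2 replicates")
  }
  if (length(ctl) < 2) {
    stop("pairing error: no age-matched control set (>= 2 replicates) at ",
         timepoint_months, " months for tissue ", es$tissue)
  }
  w <- .welch_rows(es$exprs[, grp, drop = FALSE],
                   es$exprs[, ctl, drop = FALSE])
  out <- data.frame(
    gene = rownames(es$exprs),
    tissue = es$tissue,
    timepoint_months = timepoint_months,
    activity_MBq = activity_MBq,
    log2_ratio = w$log2_ratio,
    t = w$t,
    p = w$p,
    q = bh_adjust(w$p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  call_significant(out, q_max = q_max, lfc_min = lfc_min)
}

#' Apply the dual significance threshold to a DE table
#'
#' A gene is significant iff `q < q_max` and `|log2_ratio| > lfc_min`, both
#' strict: boundary values are not significant. `direction` is `"up"` or
#' `"down"` for significant genes, `NA` otherwise.
#'
#' @param de A data.frame with columns `q` and `log2_ratio`.
#' @param q_max,lfc_min Strict thresholds.
#' @return `de` with `significant` and `direction` columns (re)computed.
#' @export
call_significant <- function(de, q_max = 0.01, lfc_min = 0.58) {
  stopifnot(all(c("q", "log2_ratio") %in% names(de)))
  de$significant <- de$q < q_max & abs(de$log2_ratio) > lfc_min
  de$direction <- ifelse(de$significant,
                         ifelse(de$log2_ratio > 0, "up", "down"),
                         NA_character_)
  de
}

#' Differential expression for every group of a study
#'
#' Runs [preprocess()] and [de_table()] for every (tissue, time point,
#' activity) cell of the design and row-binds the results.
#'
#' @param study An `expr_study` from [gen_expression_set()], or a named list
#'   of `expr_set` objects.
#' @param variance_quantile Passed to [preprocess()].
#' @param q_max,lfc_min Significance thresholds.
#' @param normalize Apply quantile normalization (default). Disable for data
#'   that is already calibrated across samples, e.g. small simulated panels
#'   where normalization's mostly-null assumption does not hold.
#' @return One long data.frame of per-gene, per-group results.
#' @export
de_all_groups <- function(study, variance_quantile = 0.2,
                          q_max = 0.01, lfc_min = 0.58, normalize = TRUE) {
  out <- list()
  for (es in study) {
    if (!inherits(es, "expr_set")) next
    pe <- if (normalize) {
      preprocess(es, variance_quantile)
    } else {
      es$exprs <- variance_filter(es$exprs, variance_quantile)
      es
    }
    tps <- sort(unique(pe$samples$timepoint_months))
    acts <- sort(unique(pe$samples$activity_MBq[!pe$samples$is_control]))
    for (tp in tps) {
      for (a in acts) {
        out[[length(out) + 1]] <-
          de_table(pe, tp, a, q_max = q_max, lfc_min = lfc_min)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write per-group DE tables as TSV
#'
#' @param de A DE data.frame (e.g. from [de_all_groups()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
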