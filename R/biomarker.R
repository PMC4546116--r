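#' Recurrence matrix of significant calls across dose-by-time groups
#'
#' Collects, for one tissue, the log2 ratio of every significant call into a
#' genes x groups matrix (group = time point x activity; 15 groups for the
#' default design). Cells without a significant call are `NA`. The gene axis
#' is the lexicographically sorted union of significant genes; the group axis
#' always covers the full design, so an empty result is a 0-row matrix with
#' all group columns.
#'
#' @param de A per-gene, per-group DE data.frame with columns `gene`,
#'   `tissue`, `timepoint_months`, `activity_MBq`, `log2_ratio`,
#'   `significant` (e.g. from [de_all_groups()] or
#'   [recurrence_from_catalogue()] input).
#' @param tissue Tissue to extract.
#' @param timepoints_months,activities_MBq The full group axes; defaults are
#'   taken from the rows present for this tissue. Every (time, activity)
#'   cell must be represented by at least one row (significant or not),
#'   otherwise an incomplete-design error lists the missing cells.
#' @return A `recurrence_matrix`: numeric matrix with attributes `tissue` and
#'   `groups` (data.frame of the group axis).
#' @export
build_recurrence <- function(de, tissue,
                             timepoints_months = NULL,
                             activities_MBq = NULL) {
  stopifnot(all(c("gene", "tissue", "timepoint_months", "activity_MBq",
                  "log2_ratio", "significant") %in% names(de)))
  de <- de[de$tissue == tissue, , drop = FALSE]
  if (is.null(timepoints_months)) {
    timepoints_months <- sort(unique(de$timepoint_months))
  }
  if (is.null(activities_MBq)) {
    activities_MBq <- sort(unique(de$activity_MBq))
  }
  groups <- expand.grid(activity_MBq = activities_MBq,
                        timepoint_months = timepoints_months,
                        KEEP.OUT.ATTRS = FALSE)
  groups <- groups[, c("timepoint_months", "activity_MBq")]
  key <- function(tp, a) paste0(tp, "mo_", a, "MBq")
  groups$group <- key(groups$timepoint_months, groups$activity_MBq)
  have <- unique(key(de$timepoint_months, de$activity_MBq))
  missing <- setdiff(groups$group, have)
  if (length(missing) > 0) {
    stop("incomplete design: no DE results for group(s) ",
         paste(missing, collapse = ", "))
  }
  sig <- de[de$significant, , drop = FALSE]
  genes <- sort(unique(sig$gene))
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(groups),
              dimnames = list(genes, groups$group))
  if (nrow(sig) > 0) {
    idx <- cbind(match(sig$gene, genes),
                 match(key(sig$timepoint_months, sig$activity_MBq),
                       groups$group))
    m[idx] <- sig$log2_ratio
  }
  structure(m, tissue = tissue, groups = groups,
            class = c("recurrence_matrix", "matrix"))
}

#' Number of groups in which a gene recurs
#'
#' Counts the dose-by-time groups (within the matrix's tissue) where the gene
#' carries a significant call. A gene absent from the matrix counts 0.
#'
#' @param m A `recurrence_matrix`.
#' @param gene Gene symbol (matched case-insensitively after trimming).
#' @return Integer count.
#' @export
recurrence_count <- function(m, gene) {
  stopifnot(inherits(m, "recurrence_matrix"))
  i <- match(.norm_symbol(gene), .norm_symbol(rownames(m)))
  if (is.na(i)) return(0L)
  sum(!is.na(m[i, ]))
}

.norm_symbol <- function(x) toupper(trimws(x))

#' Overlap of recurrence results with the marker catalogue
#'
#' Annotates the genes significant in at least one group of the tissue with
#' their catalogue category (kidney-injury marker, radiation marker, or
#' both) and protein-biodosimeter flag, and reports the number of distinct
#' catalogue genes hit. Symbols are matched case-insensitively; duplicate
#' calls across groups do not inflate the count.
#'
#' @param m A `recurrence_matrix`.
#' @param catalogue A marker catalogue data.frame with columns `gene`,
#'   `category`, `protein_flag` (see [load_marker_catalogue()]).
#' @return A list: `genes` (annotated data.frame with per-gene recurrence
#'   counts) and `unique_count`.
#' @export
marker_overlap <- function(m, catalogue) {
  stopifnot(inherits(m, "recurrence_matrix"),
            all(c("gene", "category", "protein_flag") %in% names(catalogue)))
  cat_u <- unique(catalogue[, c("gene", "category", "protein_flag")])
  sig_genes <- rownames(m)[rowSums(!is.na(m)) > 0]
  hit <- cat_u[.norm_symbol(cat_u$gene) %in% .norm_symbol(sig_genes), ,
               drop = FALSE]
  hit <- hit[!duplicated(.norm_symbol(hit$gene)), , drop = FALSE]
  hit <- hit[order(hit$gene), , drop = FALSE]
  hit$recurrence <- vapply(hit$gene, function(g) recurrence_count(m, g),
                           integer(1))
  rownames(hit) <- NULL
  list(genes = hit, unique_count = nrow(hit))
}

#' Dose-response score of a gene's log2 ratios
#'
#' Spearman rank correlation between log2 ratios and absorbed dose (ties get
#' average ranks; missing cells are excluded pairwise), plus a flag for a
#' strictly increasing profile. Fewer than 3 complete pairs is signalled as
#' insufficient data, not an error.
#'
#' @param lfc_by_dose log2 ratios ordered by increasing dose (may contain
#'   `NA` for non-significant cells).
#' @param doses_Gy The corresponding doses; defaults to the rank order.
#' @return A list: `rho`, `monotone`, `n` (complete pairs), `insufficient`.
#' @export
dose_response_score <- function(lfc_by_dose,
                                doses_Gy = seq_along(lfc_by_dose)) {
  stopifnot(length(lfc_by_dose) == length(doses_Gy))
  ok <- !is.na(lfc_by_dose) & !is.na(doses_Gy)
  n <- sum(ok)
  if (n < 3) {
    return(list(rho = NA_real_, monotone = NA, n = n, insufficient = TRUE))
  }
  x <- doses_Gy[ok]; y <- lfc_by_dose[ok]
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, monotone = all(diff(y[order(x)]) > 0), n = n,
       insufficient = FALSE)
}

#' Upstream-regulator overlap and enrichment
#'
#' For each regulator in the map, intersects its target set with the query
#' gene set (case-insensitive symbols) and computes a one-sided Fisher exact
#' p-value (hypergeometric upper tail) for the overlap given the gene
#' universe. This is a transparent overlap/enrichment computation; it does
#' not reproduce any proprietary causal-network score. Regulators are ranked
#' by overlap (descending), then p (ascending), then name.
#'
#' @param gene_set Character vector of query genes (e.g. recurrent genes of
#'   one tissue).
#' @param reg_map Data.frame with columns `regulator`, `target` (one row per
#'   pair; see [load_regulator_map()]).
#' @param universe_size Number of genes in the testing universe; must be at
#'   least the size of the union of the query set and all targets.
#' @return A data.frame ranked as described, with columns `regulator`,
#'   `n_targets`, `overlap`, `p`, `overlap_genes` (comma-separated).
#' @export
regulator_enrichment <- function(gene_set, reg_map, universe_size) {
  stopifnot(all(c("regulator", "target") %in% names(reg_map)))
  if (nrow(reg_map) == 0) stop("input error: empty regulator map")
  gs <- unique(.norm_symbol(gene_set))
  all_targets <- unique(.norm_symbol(reg_map$target))
  if (universe_size < length(union(gs, all_targets))) {
    stop("universe_size smaller than the union of gene set and targets")
  }
  regs <- sort(unique(reg_map$regulator))
  rows <- lapply(regs, function(r) {
    targets <- reg_map$target[reg_map$regulator == r]
    tn <- unique(.norm_symbol(targets))
    hit_n <- intersect(tn, gs)
    # report symbols as stored in the map, sorted
    hits <- sort(unique(targets[.norm_symbol(targets) %in% hit_n]))
    q <- length(hit_n); mm <- length(tn); k <- length(gs)
    p <- stats::phyper(q - 1, mm, universe_size - mm, k, lower.tail = FALSE)
    data.frame(regulator = r, n_targets = mm, overlap = q, p = p,
               overlap_genes = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$overlap, out$p, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene biomarker report for one tissue
#'
#' Combines recurrence counts, catalogue annotation, and the dose-response
#' score at a chosen time point into one table. A gene is flagged
#' `recurrent` when significant in at least `min_groups` groups (default 2).
#'
#' @param m A `recurrence_matrix`.
#' @param catalogue Marker catalogue data.frame (may be `NULL`).
#' @param score_timepoint Time point (months) whose dose profile is scored.
#' @param doses_Gy Dose axis for the scored profile.
#' @param min_groups Recurrence threshold defining "recurrent".
#' @return A data.frame: `gene`, `tissue`, `recurrence_count`, `recurrent`,
#'   `category`, `rho`, `monotone`.
#' @export
biomarker_report <- function(m, catalogue = NULL, score_timepoint = 12,
                             doses_Gy = c(16, 29, 40, 48, 54),
                             min_groups = 2) {
  stopifnot(inherits(m, "recurrence_matrix"))
  groups <- attr(m, "groups")
  sel <- groups$timepoint_months == score_timepoint
  genes <- rownames(m)
  rows <- lapply(genes, function(g) {
    rc <- recurrence_count(m, g)
    prof <- m[g, sel]
    sc <- dose_response_score(prof, doses_Gy[seq_along(prof)])
    cat_g <- NA_character_
    if (!is.null(catalogue)) {
      i <- match(.norm_symbol(g), .norm_symbol(catalogue$gene))
      if (!is.na(i)) cat_g <- catalogue$category[i]
    }
    data.frame(gene = g, tissue = attr(m, "tissue"), recurrence_count = rc,
               recurrent = rc >= min_groups, category = cat_g,
               rho = sc$rho, monotone = sc$monotone,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene = character(), tissue = character(),
                      recurrence_count = integer(), recurrent = logical(),
                      category = character(), rho = numeric(),
                      monotone = logical())
  }
  out
}
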