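#' Compute Log2Ex expression levels from a Ct matrix
#'
#' Expression level is defined as `Log2Ex = LoD - Ct` against the
#' per-gene limit-of-detection Ct (default 24).  Cells with missing Ct
#' or Ct at/above the LoD are non-expressing and their Log2Ex is
#' clamped to 0; a cell expresses a gene iff its Log2Ex is > 0.
#'
#' @param ct a `ct_matrix` (see [ct_matrix()]).
#' @param lod optional per-gene LoD overriding `ct$lod`, e.g. from
#'   [adjust_lod()].
#' @return object of class `log2ex_matrix`: list with `log2ex`
#'   (cells x genes), logical `expressed`, `lod`, `control_genes`,
#'   `cell_labels`.
#' @export
compute_log2ex <- function(ct, lod = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  lodv <- ct$lod
  if (!is.null(lod)) {
    lod <- rep_len(lod, ncol(ct$ct))
    if (is.null(names(lod))) names(lod) <- colnames(ct$ct)
    lodv[names(lod)] <- lod
  }
  if (any(is.na(lodv))) stop_input("LoD must be set for every gene")
  l2e <- sweep(-ct$ct, 2, lodv[colnames(ct$ct)], "+")
  l2e[is.na(l2e) | l2e < 0] <- 0
  structure(list(log2ex = l2e, expressed = l2e > 0, lod = lodv,
                 control_genes = ct$control_genes,
                 cell_labels = ct$cell_labels),
            class = "log2ex_matrix")
}

#' @export
print.log2ex_matrix <- function(x, ...) {
  cat("Log2Ex matrix:", nrow(x$log2ex), "cells x", ncol(x$log2ex),
      "genes;", sum(x$expressed), "expressed calls\n")
  invisible(x)
}

#' Adjust per-gene limits of detection from the Ct distribution
#'
#' For genes whose detected-Ct distribution is bimodal (an expressing
#' mode at low Ct and a noise mode near the default LoD), the LoD is
#' lowered to the valley between the two modes so that only noise-free
#' data count as expression.  Genes with a unimodal distribution, or
#' with fewer than `min_cells` detected values, keep the default.  The
#' adjusted LoD never exceeds the default.
#'
#' @param ct a `ct_matrix`.
#' @param default_lod default LoD Ct (24).
#' @param min_cells minimum detected Ct values required to attempt an
#'   adjustment (20).
#' @param bw smoothing bandwidth passed to [stats::density()].
#' @param overrides optional named vector of explicit per-gene LoDs
#'   that take precedence over the heuristic.
#' @return named per-gene LoD vector.
#' @export
adjust_lod <- function(ct, default_lod = 24, min_cells = 20, bw = "nrd0",
                       overrides = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  lod <- stats::setNames(rep(default_lod, ncol(ct$ct)), colnames(ct$ct))
  for (g in colnames(ct$ct)) {
    v <- ct$ct[, g]
    v <- v[!is.na(v)]
    if (length(v) < min_cells) next
    valley <- density_valley(v, bw = bw)
    if (!is.na(valley)) lod[g] <- min(valley, default_lod)
  }
  if (!is.null(overrides)) lod[names(overrides)] <- overrides
  lod
}

#' Filter cells on control genes and genes on expressing-cell count
#'
#' Removes cells in which either control assay (B2M or Spike1) is
#' non-expressed, then removes genes expressed in fewer than
#' `min_cells` of the remaining cells.  The control columns themselves
#' are dropped from the analysis matrix.  If the control columns are
#' absent (e.g. on an already-filtered matrix) the cell filter is
#' skipped, which makes the operation idempotent.
#'
#' @param l2e a `log2ex_matrix`.
#' @param min_cells minimum number of expressing cells for a gene to be
#'   retained (default 10; genes expressed by fewer cells are
#'   excluded).
#' @return list with `log2ex` (the filtered `log2ex_matrix`) and
#'   `report` (character vectors `cells_removed`, `genes_removed`).
#' @export
filter_matrix <- function(l2e, min_cells = 10) {
  stopifnot(inherits(l2e, "log2ex_matrix"))
  ctrl <- intersect(l2e$control_genes, colnames(l2e$log2ex))
  if (length(ctrl) > 0) {
    ok <- rowSums(!l2e$expressed[, ctrl, drop = FALSE]) == 0
  } else {
    ok <- rep(TRUE, nrow(l2e$log2ex))
  }
  cells_removed <- rownames(l2e$log2ex)[!ok]
  if (!any(ok)) stop_input("all cells removed by the control-gene filter")
  keep_genes <- setdiff(colnames(l2e$log2ex), l2e$control_genes)
  expr_counts <- colSums(l2e$expressed[ok, keep_genes, drop = FALSE])
  genes_removed <- keep_genes[expr_counts < min_cells]
  keep_genes <- setdiff(keep_genes, genes_removed)
  out <- structure(list(
    log2ex = l2e$log2ex[ok, keep_genes, drop = FALSE],
    expressed = l2e$expressed[ok, keep_genes, drop = FALSE],
    lod = l2e$lod[keep_genes],
    control_genes = l2e$control_genes,
    cell_labels = if (!is.null(l2e$cell_labels)) l2e$cell_labels[ok]),
    class = "log2ex_matrix")
  list(log2ex = out,
       report = list(cells_removed = cells_removed,
                     genes_removed = genes_removed))
}

#' Hierarchically cluster cells and genes (Ward / Euclidean)
#'
#' Agglomerative clustering of cells and of genes on Euclidean
#' distances over the continuous Log2Ex values, Ward linkage.  The
#' binary expressed/non-expressed matrix is returned in the clustered
#' order for heatmap rendering.  Rows are sorted lexicographically by
#' cell identifier before clustering so the result does not depend on
#' input record order.
#'
#' @param l2e a `log2ex_matrix` with at least 2 cells and 2 genes.
#' @return list with `cell_hclust`, `gene_hclust` (hclust objects),
#'   `cell_order`, `gene_order` (identifiers in dendrogram order) and
#'   `expressed` (logical matrix reordered accordingly).
#' @export
cluster_binary <- function(l2e) {
  stopifnot(inherits(l2e, "log2ex_matrix"))
  m <- l2e$log2ex
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_input("need at least 2 cells and 2 genes to cluster")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  ch <- stats::hclust(stats::dist(m), method = "ward.D2")
  gh <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  cell_order <- rownames(m)[ch$order]
  gene_order <- colnames(m)[gh$order]
  list(cell_hclust = ch, gene_hclust = gh,
       cell_order = cell_order, gene_order = gene_order,
       expressed = l2e$expressed[cell_order, gene_order, drop = FALSE])
}

#' Per-subset fractions of expressing cells
#'
#' @param expressed logical cells x genes matrix (e.g.
#'   `l2e$expressed`).
#' @param labels subset label per cell; every cell must be labeled.
#' @return numeric subsets x genes matrix of expressing fractions.
#' @export
expressing_fraction <- function(expressed, labels) {
  bad <- which(is.na(labels) | labels == "")
  if (length(bad))
    stop_input("unlabeled cell(s): %s",
               paste(rownames(expressed)[bad] %||% bad, collapse = ", "))
  if (length(labels) != nrow(expressed))
    stop_input("one label per cell required")
  groups <- sort(unique(labels))
  out <- t(vapply(groups, function(g)
    colMeans(expressed[labels == g, , drop = FALSE]),
    numeric(ncol(expressed))))
  rownames(out) <- groups
  out
}
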