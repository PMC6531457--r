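#' Quantile-normalize a bulk expression matrix
#'
#' Forces every sample's value distribution onto the cross-sample mean
#' of order statistics; ties within a sample receive the mean of the
#' normalized values they span.  Delegates to
#' [limma::normalizeQuantiles()] on the transposed (genes x samples)
#' matrix.
#'
#' @param x a `bulk_matrix` or a samples x genes numeric matrix.
#' @param labels subset per sample (required when `x` is a bare
#'   matrix).
#' @return a `bulk_matrix` with normalized `expr`.
#' @export
quantile_normalize <- function(x, labels = NULL) {
  b <- as_bulk(x, labels)
  if (any(colSums(!is.na(t(b$expr))) == 0))
    stop_input("sample with no observed values")
  norm <- t(limma::normalizeQuantiles(t(b$expr), ties = TRUE))
  dimnames(norm) <- dimnames(b$expr)
  structure(list(expr = norm, labels = b$labels), class = "bulk_matrix")
}

as_bulk <- function(x, labels = NULL) {
  if (inherits(x, "bulk_matrix")) return(x)
  if (is.null(labels)) stop_input("sample labels required")
  if (length(labels) != nrow(x)) stop_input("one label per sample required")
  structure(list(expr = as.matrix(x), labels = as.character(labels)),
            class = "bulk_matrix")
}

#' Per-gene two-sample t-tests between two subsets
#'
#' For every gene, a two-sample t-test (Welch by default) between the
#' samples of `group_a` and `group_b`, plus the linear-scale fold
#' change `2^(mean_a - mean_b)` of group a over group b (the input is
#' log2-scale).  Genes that are constant in both groups get p = 1 when
#' the group means are equal and p = 0 otherwise.
#'
#' @param x a `bulk_matrix` (log2 scale, ideally quantile-normalized).
#' @param group_a,group_b subset labels; each needs >= 2 samples.
#' @param var_equal FALSE (Welch, default) or TRUE (Student).
#' @return data.frame with columns `gene`, `fold`, `p`, and the
#'   comparison recorded in attribute `comparison` as
#'   `"group_a_vs_group_b"`.
#' @export
pairwise_tests <- function(x, group_a, group_b, var_equal = FALSE) {
  b <- as_bulk(x)
  ia <- b$labels == group_a
  ib <- b$labels == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop_input("need >= 2 replicates per side (%s: %d, %s: %d)",
               group_a, sum(ia), group_b, sum(ib))
  res <- apply(b$expr, 2, function(v) {
    a <- v[ia]; bb <- v[ib]
    d <- mean(a) - mean(bb)
    p <- tryCatch(
      stats::t.test(a, bb, var.equal = var_equal)$p.value,
      error = function(e) if (abs(d) < .Machine$double.eps^0.5) 1 else 0)
    c(fold = 2^d, p = p)
  })
  out <- data.frame(gene = colnames(b$expr), fold = res["fold", ],
                    p = res["p", ], row.names = NULL)
  attr(out, "comparison") <- paste0(group_a, "_vs_", group_b)
  out
}

check_comparisons <- function(results, needed) {
  have <- vapply(results, attr, character(1), "comparison")
  names(results) <- have
  missing <- setdiff(needed, have)
  if (length(missing))
    stop_input("missing comparison(s): %s", paste(missing, collapse = ", "))
  results
}

intersect_de <- function(results, needed, fold_threshold, alpha,
                         adjust = "none") {
  results <- check_comparisons(results, needed)
  genes <- results[[needed[1]]]$gene
  keep <- rep(TRUE, length(genes))
  for (cmp in needed) {
    r <- results[[cmp]]
    if (!identical(as.character(r$gene), as.character(genes)))
      stop_input("comparisons cover different gene sets")
    p <- if (adjust == "none") r$p else stats::p.adjust(r$p, method = adjust)
    keep <- keep & r$fold >= fold_threshold & p < alpha
  }
  as.character(genes[keep])
}

#' Genes specifically upregulated in T_EMRA
#'
#' Intersection analysis: a gene is included iff it shows at least
#' `fold_threshold`-fold upregulation with p < `alpha` in every one of
#' the three comparisons T_EMRA vs T_N, T_EMRA vs T_CM and T_EMRA vs
#' T_EM.
#'
#' @param results list of [pairwise_tests()] results containing the
#'   three required comparisons (order free).
#' @param fold_threshold minimum fold change (default 2, inclusive).
#' @param alpha p-value cutoff (default 0.05, exclusive).
#' @param adjust multiple-testing adjustment applied per comparison
#'   before thresholding; `"none"` (default, raw p-values) or a
#'   [stats::p.adjust()] method such as `"BH"`.
#' @return character vector of included genes.
#' @export
intersect_temra <- function(results, fold_threshold = 2, alpha = 0.05,
                            adjust = "none") {
  intersect_de(results,
               c("T_EMRA_vs_T_N", "T_EMRA_vs_T_CM", "T_EMRA_vs_T_EM"),
               fold_threshold, alpha, adjust)
}

#' Genes upregulated in both T_EM and T_EMRA
#'
#' Intersection analysis over four comparisons: T_EMRA vs T_N, T_EMRA
#' vs T_CM, T_EM vs T_N and T_EM vs T_CM; a gene is included iff it is
#' at least `fold_threshold`-fold up with p < `alpha` in all four.
#'
#' @inheritParams intersect_temra
#' @export
intersect_tem_temra <- function(results, fold_threshold = 2, alpha = 0.05,
                                adjust = "none") {
  intersect_de(results,
               c("T_EMRA_vs_T_N", "T_EMRA_vs_T_CM",
                 "T_EM_vs_T_N", "T_EM_vs_T_CM"),
               fold_threshold, alpha, adjust)
}

#' Restrict a gene set to the cell surfaceome
#'
#' Case-insensitive intersection of gene symbols with a surfaceome
#' list (one symbol per line when a path is given).
#'
#' @param genes character vector of gene symbols.
#' @param surfaceome character vector of surfaceome symbols or path to
#'   a plain-text list.
#' @return list with `genes` (matched input symbols, original casing)
#'   and `unmatched` (input symbols not on the list).
#' @export
surfaceome_filter <- function(genes, surfaceome) {
  if (is.character(surfaceome) && length(surfaceome) == 1 &&
      file.exists(surfaceome))
    surfaceome <- read_gene_list(surfaceome)
  surfaceome <- trimws(surfaceome)
  surfaceome <- surfaceome[nzchar(surfaceome)]
  if (length(surfaceome) == 0) {
    warning("empty surfaceome list")
    return(list(genes = character(0), unmatched = as.character(genes)))
  }
  hit <- toupper(genes) %in% toupper(surfaceome)
  list(genes = as.character(genes[hit]),
       unmatched = as.character(genes[!hit]))
}
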