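#' Construct a clonotype table
#'
#' A clonotype is identified by the triple (V-beta gene, J-beta gene,
#' CDR3 amino-acid sequence); `count` holds the number of reads
#' supporting it.  Proportions are always derived as count / total, see
#' [clone_proportions()].
#'
#' @param x data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`,
#'   `count` (positive integers).
#' @param population optional label for the population of origin.
#' @return object of class `clonotype_table` (a data.frame).
#' @export
clonotype_table <- function(x, population = NULL) {
  x <- as.data.frame(x)
  req <- c("v_gene", "j_gene", "cdr3_aa", "count")
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop_input("clonotype table lacks column(s): %s",
               paste(missing, collapse = ", "))
  if (nrow(x) == 0) stop_input("empty clonotype table")
  if (any(x$count <= 0) || any(x$count != round(x$count)))
    stop_input("clonotype counts must be positive integers")
  key <- clone_key(x)
  if (anyDuplicated(key))
    stop_input("duplicated clonotype identities (V, J, CDR3aa)")
  x <- x[req]
  rownames(x) <- NULL
  structure(x, class = c("clonotype_table", "data.frame"),
            population = population)
}

clone_key <- function(tbl) paste(tbl$v_gene, tbl$j_gene, tbl$cdr3_aa,
                                 sep = "\r")

#' Clonotype proportions
#'
#' @param tbl a `clonotype_table`.
#' @return numeric vector `count / sum(count)`, parallel to the rows.
#' @export
clone_proportions <- function(tbl) tbl$count / sum(tbl$count)

#' @export
print.clonotype_table <- function(x, ...) {
  cat("Clonotype table", if (!is.null(attr(x, "population")))
        paste0("[", attr(x, "population"), "]") else "",
      ": ", nrow(x), " clonotypes, ", sum(x$count), " reads; top clone ",
      sprintf("%.1f%%", 100 * max(clone_proportions(x))), "\n", sep = "")
  invisible(x)
}

# deterministic top-k ordering: count desc, then V, J, CDR3aa
head_clones <- function(tbl, k) {
  ord <- order(-tbl$count, tbl$v_gene, tbl$j_gene, tbl$cdr3_aa,
               method = "radix")
  tbl[ord[seq_len(min(k, nrow(tbl)))], , drop = FALSE]
}

#' Select the top expanded clones of a repertoire
#'
#' Returns the `n` clonotypes with the largest read counts (all of them
#' if fewer exist).  Ties at the boundary are broken deterministically
#' by (count desc, V gene, J gene, CDR3aa), so the selection does not
#' depend on input record order.  Proportions derived from the result
#' refer to the retained set only.
#'
#' @param tbl a `clonotype_table`.
#' @param n number of clones to keep (default 100).
#' @return a `clonotype_table` with at most `n` rows.
#' @export
top_clones <- function(tbl, n = 100) {
  clonotype_table(head_clones(tbl, n), population = attr(tbl, "population"))
}

#' Filter reads on mean Phred quality
#'
#' Retains reads whose average base quality is at least
#' `min_avg_quality` (default 30); reads below the threshold are
#' excluded.  Accepts either a per-read data.frame (columns `v_gene`,
#' `j_gene`, `cdr3_aa`, `avg_quality`) or a path to a FASTQ file whose
#' read names carry the clonotype annotation as
#' `id|V|J|CDR3` (see [write_reads_fastq()]).
#'
#' @param reads data.frame of reads or FASTQ path.
#' @param min_avg_quality retention threshold on the mean Phred score.
#' @return list with `reads` (retained rows) and `report`
#'   (n_input, n_retained, n_excluded).
#' @export
filter_reads <- function(reads, min_avg_quality = 30) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_reads(reads)
  if (!is.data.frame(reads) || !"avg_quality" %in% names(reads))
    stop_input("reads must be a data.frame with an avg_quality column or a FASTQ path")
  keep <- reads$avg_quality >= min_avg_quality
  list(reads = reads[keep, , drop = FALSE],
       report = list(n_input = nrow(reads), n_retained = sum(keep),
                     n_excluded = sum(!keep)))
}

#' Aggregate reads into a clonotype table
#'
#' @param reads data.frame with `v_gene`, `j_gene`, `cdr3_aa` (one row
#'   per read, e.g. the retained reads from [filter_reads()]).
#' @param population optional population label.
#' @return a `clonotype_table` with per-clonotype read counts.
#' @export
clonotypes_from_reads <- function(reads, population = NULL) {
  if (nrow(reads) == 0) stop_input("no reads to aggregate")
  key <- paste(reads$v_gene, reads$j_gene, reads$cdr3_aa, sep = "\r")
  cnt <- table(key)
  first <- !duplicated(key)
  ids <- reads[first, c("v_gene", "j_gene", "cdr3_aa")]
  ids$count <- as.integer(cnt[key[first]])
  clonotype_table(ids, population = population)
}

#' Morisita-Horn similarity of two repertoires
#'
#' Abundance-weighted similarity over the union of clonotype
#' identities, ranging from 0 (disjoint repertoires) to 1 (identical
#' composition).  Computed both from raw counts `x_i`, `y_i` with totals
#' `X`, `Y` as
#' `2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' and from proportions `p_i`, `q_i` as
#' `2 * sum(p_i q_i) / (sum(p_i^2) + sum(q_i^2))`; the two algebraically
#' equivalent forms are asserted equal before the value is returned.
#'
#' @param P,Q `clonotype_table`s.
#' @return similarity in \[0, 1\].
#' @export
morisita_horn <- function(P, Q) {
  if (nrow(P) == 0 || nrow(Q) == 0) stop_input("empty clonotype table")
  keys <- union(clone_key(P), clone_key(Q))
  x <- stats::setNames(numeric(length(keys)), keys)
  y <- x
  x[clone_key(P)] <- P$count
  y[clone_key(Q)] <- Q$count
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop_input("totals must be positive")
  s_counts <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  p <- x / X; q <- y / Y
  s_props <- 2 * sum(p * q) / (sum(p^2) + sum(q^2))
  stopifnot(abs(s_counts - s_props) < 1e-9)
  s_props
}

#' Default alpha grid for Renyi diversity profiles
#' @return numeric vector 0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf.
#' @export
default_alpha_grid <- function() c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf)

#' Renyi diversity profile of a repertoire
#'
#' Computes the Renyi entropy `H_a = ln(sum(p_i^a)) / (1 - a)` (natural
#' log) on the clone proportions, with the standard limit cases: at
#' `a = 0` the log of richness, at `a = 1` the Shannon entropy
#' `-sum(p_i ln p_i)`, at `a = 2` the log of the reciprocal Simpson
#' index, and at `a = Inf` the Berger-Parker reading
#' `-ln(max p_i)`.  `H_a` is non-increasing in `a`.
#'
#' @param tbl a `clonotype_table`.
#' @param alphas non-negative scaling parameters (may include `Inf`).
#' @return data.frame of class `diversity_profile` with columns `alpha`
#'   and `H`; the population label is carried over as an attribute.
#' @export
renyi_profile <- function(tbl, alphas = default_alpha_grid()) {
  if (any(alphas < 0)) stop_input("alpha must be non-negative")
  p <- clone_proportions(tbl)
  p <- p[p > 0]
  m <- max(p)
  H <- vapply(alphas, function(a) {
    if (a == 0) return(log(length(p)))
    if (a == 1) return(-sum(p * log(p)))
    if (is.infinite(a)) return(-log(m))
    # scaled by the largest proportion for numerical stability at large a
    (a * log(m) + log(sum((p / m)^a))) / (1 - a)
  }, numeric(1))
  structure(data.frame(alpha = alphas, H = H),
            class = c("diversity_profile", "data.frame"),
            population = attr(tbl, "population"))
}

#' Rank repertoires by their diversity profiles
#'
#' A repertoire is more diverse than another iff its profile is at
#' least as high at every alpha on the common grid and strictly higher
#' somewhere; profiles that cross cannot be ranked.
#'
#' @param profiles named list of `diversity_profile`s on a common alpha
#'   grid.
#' @param tol numerical tolerance for treating two values as equal.
#' @return data.frame with one row per ordered pair: columns `a`, `b`,
#'   `relation` in more_diverse / less_diverse / tied / not_rankable
#'   (relation of `a` relative to `b`).
#' @export
compare_profiles <- function(profiles, tol = 1e-9) {
  stopifnot(length(profiles) >= 2)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  grid <- profiles[[1]]$alpha
  for (pr in profiles)
    if (length(pr$alpha) != length(grid) || any(pr$alpha != grid))
      stop_input("profiles are not on a common alpha grid")
  pairs <- utils::combn(names(profiles), 2)
  res <- data.frame(a = character(0), b = character(0),
                    relation = character(0))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- profiles[[a]]$H - profiles[[b]]$H
    up <- any(d > tol); down <- any(d < -tol)
    rel <- if (up && down) "not_rankable"
           else if (up) "more_diverse"
           else if (down) "less_diverse"
           else "tied"
    res <- rbind(res, data.frame(a = a, b = b, relation = rel))
  }
  res
}

#' Count dominant source clonotypes found in target repertoires
#'
#' Takes the `top_k` most expanded clonotypes of a source population
#' and counts how many of their identities occur in each target
#' repertoire.
#'
#' @param source a `clonotype_table`.
#' @param targets named list of `clonotype_table`s.
#' @param top_k number of dominant source clones to track (all clones
#'   if the source has fewer).
#' @return named integer vector of per-target counts.
#' @export
shared_dominant_clones <- function(source, targets, top_k = 100) {
  dom <- clone_key(head_clones(source, top_k))
  vapply(targets, function(tb) sum(dom %in% clone_key(tb)), integer(1))
}

#' Clonal space occupied by clone-rank bins
#'
#' Fraction of all reads carried by the clones in each rank range
#' (ranks by decreasing count, deterministic tie-breaking).
#'
#' @param tbl a `clonotype_table`.
#' @param bins list of `c(lo, hi)` rank ranges (1-based, inclusive; use
#'   `Inf` for an open upper end); must be non-overlapping and ordered.
#' @return named numeric vector of summed proportions per bin.
#' @export
clonal_space <- function(tbl,
                         bins = list(c(1, 10), c(11, 100), c(101, Inf))) {
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(lo > hi) || any(lo[-1] <= hi[-length(hi)]))
    stop_input("rank bins must be ordered and non-overlapping")
  ordered <- head_clones(tbl, nrow(tbl))
  p <- ordered$count / sum(ordered$count)
  out <- vapply(seq_along(bins), function(i) {
    r <- seq.int(lo[i], min(hi[i], length(p)))
    if (lo[i] > length(p)) 0 else sum(p[r])
  }, numeric(1))
  names(out) <- vapply(bins, function(b)
    paste0(b[1], "-", ifelse(is.infinite(b[2]), "end", b[2])), character(1))
  out
}
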