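#' Locate the valley between the two dominant modes of a distribution
#'
#' Smooths `x` with a Gaussian kernel density estimate, finds its local
#' maxima, and returns the position of the minimum between the two
#' highest maxima.  Used both for adjusting qPCR limits of detection and
#' for automatic positivity thresholds on fluorescence channels.
#'
#' @param x numeric vector.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @param n grid size for the density estimate.
#' @return the valley location, or `NA_real_` if the smoothed
#'   distribution has fewer than two modes.
#' @export
density_valley <- function(x, bw = "nrd0", n = 512) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || length(unique(x)) < 2) return(NA_real_)
  d <- stats::density(x, bw = bw, n = n)
  y <- d$y
  # interior local maxima of the density grid
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2) return(NA_real_)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  d$x[seg[which.min(y[seg])]]
}

#' Robust per-column scaling (median / MAD)
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; columns with zero MAD fall back to
#'   sd, and constant columns are returned centred at 0.
#' @keywords internal
robust_scale <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, function(v) {
    m <- stats::median(v)
    s <- stats::mad(v)
    if (!is.finite(s) || s == 0) s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(v - m)
    (v - m) / s
  })
}

#' k-nearest-neighbour search
#'
#' Thin wrapper around [RANN::nn2()] returning neighbour indices and
#' distances, excluding each point itself when `query` is omitted.
#'
#' @param data numeric matrix of points (rows).
#' @param k number of neighbours.
#' @param query optional query matrix; defaults to `data`.
#' @return list with integer matrix `idx` and numeric matrix `dist`,
#'   each `nrow(query)` x `k`.
#' @keywords internal
knn_search <- function(data, k, query = NULL) {
  data <- as.matrix(data)
  self_query <- is.null(query)
  if (self_query) query <- data
  kk <- min(if (self_query) k + 1L else k, nrow(data))
  res <- RANN::nn2(data, query, k = kk)
  if (self_query) {
    # drop the self-match in column 1 (nn2 returns it first at distance 0)
    list(idx = res$nn.idx[, -1, drop = FALSE],
         dist = res$nn.dists[, -1, drop = FALSE])
  } else {
    list(idx = res$nn.idx, dist = res$nn.dists)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
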