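#' Density-dependent downsampling of cytometry events
#'
#' Equalizes local event density before trajectory analysis.  Local
#' density is estimated as the inverse mean distance to the
#' `k_density` nearest neighbours on the (scaled) trajectory channels;
#' events are retained with probability `min(1, c / density)` where the
#' constant `c` is found by bisection so that the expected retained
#' count equals `target_total`.  A final uniform trim or top-up
#' enforces an exact output size of `min(target_total, nrow(events))`.
#' Only observed events are returned (no synthetic points).
#'
#' @param events event data.frame.
#' @param target_total output size budget (default 50,000 cells).
#' @param k_density neighbours for the density estimate.
#' @param channels channels defining the density space; defaults to
#'   the trajectory channel set present in `events`.
#' @param seed integer seed.
#' @return the retained subset of `events` (rows of the input).
#' @export
density_downsample <- function(events, target_total = 50000,
                               k_density = 15, channels = NULL, seed = 1) {
  if (target_total <= 0) stop_input("target_total must be positive")
  n <- nrow(events)
  if (n <= target_total) {
    if (n < target_total)
      warning(sprintf("only %d events available for a %d budget; all retained",
                      n, target_total))
    return(events)
  }
  channels <- channels %||% intersect(TRAJECTORY_CHANNELS, names(events))
  x <- robust_scale(log1p(as.matrix(events[channels])))
  set.seed(seed)
  nn <- knn_search(x, k_density)
  dens <- 1 / (rowMeans(nn$dist) + 1e-12)

  expected <- function(c) sum(pmin(1, c / dens))
  lo <- 0; hi <- max(dens)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target_total) lo <- mid else hi <- mid
  }
  keep <- stats::runif(n) < pmin(1, hi / dens)
  excess <- sum(keep) - target_total
  if (excess > 0) {
    keep[sample(which(keep), excess)] <- FALSE
  } else if (excess < 0) {
    keep[sample(which(!keep), -excess)] <- TRUE
  }
  events[keep, , drop = FALSE]
}

#' Graph-based pseudotime anchored at naive initiator cells
#'
#' Builds a k-nearest-neighbour graph on the robust-scaled
#' log-intensities of the trajectory channels, then estimates each
#' event's position along the differentiation trajectory by an
#' ensemble of waypoint-refined shortest-path distances: per repeat, a
#' random initiator event is the origin, geodesic distances seed the
#' ordering, and randomly sampled waypoints iteratively refine each
#' event's position as the average of the waypoint perspectives
#' `t_w +/- d(w, i)` (sign by whether the event lies beyond the
#' waypoint).  Repeats are averaged and min-max scaled to \[0, 1\].
#' Disconnected graph components are joined through their nearest
#' inter-component event pair, with a warning.
#'
#' @param events event data.frame.
#' @param initiator_mask logical per-event vector marking the
#'   CD45RA+CCR7+ initiator (naive) cells; if NULL, the
#'   `init_fraction` of events with the highest CCR7 x CD45RA product
#'   is used.
#' @param channels trajectory channels (default: CCR7, CD45RA, KLRB1,
#'   KLRG1, KLRF1, GPR56, TNF, IFNg, as present).
#' @param k_graph neighbours in the graph.
#' @param n_waypoints waypoints per repeat.
#' @param n_repeats ensemble size.
#' @param n_refine refinement passes per repeat.
#' @param init_fraction fallback initiator fraction when no mask is
#'   given.
#' @param seed integer seed; fixed seeds give identical results.
#' @return object of class `pseudotime_result`: list with
#'   `pseudotime` (per event, in \[0, 1\]), `channels`,
#'   `initiator_mask`.
#' @export
pseudotime <- function(events, initiator_mask = NULL, channels = NULL,
                       k_graph = 15, n_waypoints = 60, n_repeats = 5,
                       n_refine = 2, init_fraction = 0.05, seed = 1) {
  channels <- channels %||% intersect(TRAJECTORY_CHANNELS, names(events))
  n <- nrow(events)
  x <- robust_scale(log1p(as.matrix(events[channels])))
  if (is.null(initiator_mask)) {
    score <- events[["CCR7"]] * events[["CD45RA"]]
    initiator_mask <- rank(-score, ties.method = "first") <=
      max(1, round(init_fraction * n))
  }
  if (!any(initiator_mask)) stop_input("initiator_mask selects no events")
  set.seed(seed)

  nn <- knn_search(x, k_graph)
  edges <- data.frame(
    from = rep(seq_len(n), ncol(nn$idx)),
    to = as.vector(nn$idx),
    weight = pmax(as.vector(nn$dist), 1e-12))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(id = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning(sprintf("kNN graph has %d components; joining via nearest pairs",
                    comp$no))
    main <- which(comp$membership == which.max(comp$csize))
    for (cc in setdiff(seq_len(comp$no), which.max(comp$csize))) {
      other <- which(comp$membership == cc)
      hit <- RANN::nn2(x[main, , drop = FALSE], x[other, , drop = FALSE],
                       k = 1)
      j <- which.min(hit$nn.dists[, 1])
      g <- igraph::add_edges(g, c(other[j], main[hit$nn.idx[j, 1]]),
                             weight = max(hit$nn.dists[j, 1], 1e-12))
    }
  }

  initiators <- which(initiator_mask)
  acc <- numeric(n)
  for (r in seq_len(n_repeats)) {
    start <- initiators[sample.int(length(initiators), 1)]
    wp <- unique(c(start, sample.int(n, min(n_waypoints, n))))
    D <- igraph::distances(g, v = wp, weights = igraph::E(g)$weight)
    t_i <- D[1, ]                      # geodesic distance from the origin
    t_i <- t_i / max(t_i)
    Dn <- D / max(D[is.finite(D)])
    for (it in seq_len(n_refine)) {
      t_w <- t_i[wp]
      beyond <- outer(t_w, t_i, function(a, b) b >= a)  # waypoints x events
      persp <- t_w + Dn * (2 * beyond - 1)
      t_i <- colMeans(persp)
      t_i <- t_i - min(t_i)
    }
    acc <- acc + (t_i - min(t_i)) / (max(t_i) - min(t_i))
  }
  pt <- acc / n_repeats
  pt <- (pt - min(pt)) / (max(pt) - min(pt))
  structure(list(pseudotime = pt, channels = channels,
                 initiator_mask = initiator_mask),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat("Pseudotime over", length(x$pseudotime), "events;",
      sum(x$initiator_mask), "initiators; channels:",
      paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Binned relative marker curves and the marker acquisition order
#'
#' Bins events by pseudotime quantiles, takes the per-bin median
#' intensity of every trajectory channel, min-max normalizes each
#' channel's curve to \[0, 1\], and derives the acquisition order as
#' the order in which the curves first cross 0.5 (linear interpolation
#' between bins).  Constant channels yield a flat curve and are
#' excluded from the ordering.
#'
#' @param result a `pseudotime_result`.
#' @param events the event data.frame the result was computed on.
#' @param n_bins number of quantile bins (>= 5); bins collapsed by
#'   massive ties are merged into their neighbour.
#' @param threshold crossing level on the normalized curves.
#' @return list with `curves` (bins x channels, normalized),
#'   `medians` (raw per-bin medians), `bin_centers` (mean pseudotime
#'   per bin) and `acquisition` (named crossing positions, sorted; NA
#'   channels excluded).
#' @export
binned_curves <- function(result, events, n_bins = 20, threshold = 0.5) {
  if (n_bins < 5) stop_input("n_bins must be >= 5")
  pt <- result$pseudotime
  breaks <- unique(stats::quantile(pt, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) stop_input("pseudotime too degenerate to bin")
  bin <- cut(pt, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- max(bin)
  med <- vapply(result$channels, function(ch)
    vapply(seq_len(nb), function(b)
      stats::median(events[[ch]][bin == b]), numeric(1)),
    numeric(nb))
  curves <- apply(med, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(NA_real_, length(v)) else (v - rng[1]) / diff(rng)
  })
  crossing <- vapply(colnames(curves), function(ch) {
    v <- curves[, ch]
    if (anyNA(v)) return(NA_real_)
    i <- which(v >= threshold)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(1)
    i - 1 + (threshold - v[i - 1]) / (v[i] - v[i - 1])
  }, numeric(1))
  acq <- sort(crossing[!is.na(crossing)])
  list(curves = curves, medians = med,
       bin_centers = tapply(pt, bin, mean),
       acquisition = acq)
}
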