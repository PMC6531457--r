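# Independent brute-force oracles used across tests.

# Ward clustering by direct minimization of the increase in within-cluster
# error sum of squares; heights follow the sqrt(2 * dESS) convention.
ward_oracle_heights <- function(points) {
  ess <- function(idx) {
    m <- points[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(points)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# Welch two-sample t-test from the closed-form expressions.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Quantile normalization by explicit order statistics (no ties handling
# needed for the fixtures that use it).
quantile_oracle <- function(mat_samples_by_genes) {
  sorted <- apply(mat_samples_by_genes, 1, sort)   # genes x samples
  target <- rowMeans(sorted)
  out <- mat_samples_by_genes
  for (i in seq_len(nrow(out))) out[i, ] <- target[rank(out[i, ])]
  out
}

# Histogram-based valley search: running-mean smoothed counts, minimum
# between the two tallest local maxima.
hist_valley_oracle <- function(x, binwidth = 0.5) {
  br <- seq(floor(min(x)) - 1, ceiling(max(x)) + 1, by = binwidth)
  h <- hist(x, breaks = br, plot = FALSE)
  y <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
  y[is.na(y)] <- 0
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  low <- seg[y[seg] == min(y[seg])]       # centre of the minimal plateau
  h$mids[low[ceiling(length(low) / 2)]]
}

# Renyi entropy straight from its defining formula (naive evaluation).
renyi_oracle <- function(counts, alpha) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  if (alpha == 0) log(length(p))
  else if (alpha == 1) -sum(p * log(p))
  else if (is.infinite(alpha)) -log(max(p))
  else log(sum(p^alpha)) / (1 - alpha)
}

# Small clonotype-table builder: counts named by CDR3 identity.
make_clono <- function(counts, population = NULL) {
  clonotype_table(data.frame(
    v_gene = "TRBV9", j_gene = "TRBJ2-1",
    cdr3_aa = names(counts), count = unname(counts)),
    population = population)
}

# Event rows with explicit intensities around a threshold of 100:
# "+" -> 200, "-" -> 50.
make_events <- function(...) {
  spec <- list(...)
  as.data.frame(lapply(spec, function(s) ifelse(s == "+", 200, 50)))
}

unit_thresholds <- function(channels = c("CCR7", "CD45RA", "CD25", "CD127",
                                         "KLRB1", "KLRG1", "GPR56", "KLRF1",
                                         "TNF", "IFNg")) {
  stats::setNames(rep(100, length(channels)), channels)
}

fake_de <- function(genes, fold, p, comparison) {
  out <- data.frame(gene = genes, fold = fold, p = p)
  attr(out, "comparison") <- comparison
  out
}
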