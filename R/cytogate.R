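#' Estimate per-channel positivity thresholds
#'
#' Automatic threshold at the valley of the two-component intensity
#' distribution on the log scale (the negative and positive stained
#' populations); falls back to the midpoint between the two k-means
#' centres when the smoothed log-density is unimodal.
#'
#' @param events event data.frame (see [gen_events()]).
#' @param channels channels to threshold; defaults to all phenotype,
#'   KLR and cytokine channels present.
#' @return named numeric vector of thresholds on the intensity scale.
#' @export
estimate_thresholds <- function(events, channels = NULL) {
  channels <- channels %||% intersect(ALL_CHANNELS, names(events))
  vapply(channels, function(ch) {
    lx <- log(pmax(events[[ch]], .Machine$double.eps))
    v <- density_valley(lx)
    if (is.na(v)) {
      km <- stats::kmeans(lx, centers = range(lx))
      v <- mean(km$centers)
    }
    exp(v)
  }, numeric(1))
}

check_channels <- function(events, needed) {
  missing <- setdiff(needed, names(events))
  if (length(missing))
    stop_input("missing channel(s): %s", paste(missing, collapse = ", "))
}

# positivity uses strict inequality: events exactly at threshold are negative
is_pos <- function(events, ch, thresholds) events[[ch]] > thresholds[[ch]]

#' Classic CD45RA/CCR7 subsets and the Treg gate
#'
#' Regulatory T cells are gated CD25-high and CD127-low and labeled
#' `Treg` (to be excluded from conventional analyses); the remaining
#' events are labeled by their CD45RA x CCR7 quadrant: T_N
#' (CD45RA+CCR7+), T_CM (CD45RA-CCR7+), T_EM (CD45RA-CCR7-) and T_EMRA
#' (CD45RA+CCR7-).
#'
#' @param events event data.frame with CD45RA, CCR7, CD25, CD127
#'   channels.
#' @param thresholds named per-channel positivity thresholds (e.g.
#'   [estimate_thresholds()]); CD25 acts as the "high" and CD127 as the
#'   "low" boundary of the Treg gate.
#' @return factor with levels T_N, T_CM, T_EM, T_EMRA, Treg.
#' @export
gate_classic <- function(events, thresholds) {
  check_channels(events, c("CD45RA", "CCR7", "CD25", "CD127"))
  ra <- is_pos(events, "CD45RA", thresholds)
  c7 <- is_pos(events, "CCR7", thresholds)
  treg <- is_pos(events, "CD25", thresholds) &
    !is_pos(events, "CD127", thresholds)
  lab <- ifelse(ra & c7, "T_N",
         ifelse(!ra & c7, "T_CM",
         ifelse(!ra & !c7, "T_EM", "T_EMRA")))
  lab[treg] <- "Treg"
  factor(lab, levels = c(CLASSIC_SUBSETS, "Treg"))
}

klr_pattern <- function(pos) {
  paste0("B1", ifelse(pos[, "KLRB1"], "+", "-"),
         "G1", ifelse(pos[, "KLRG1"], "+", "-"),
         "G56", ifelse(pos[, "GPR56"], "+", "-"),
         "F1", ifelse(pos[, "KLRF1"], "+", "-"))
}

CANONICAL_PATTERNS <- c(
  P1 = "B1-G1-G56-F1-", P2 = "B1+G1-G56-F1-", P3 = "B1+G1+G56-F1-",
  P4 = "B1+G1+G56+F1-", P5 = "B1+G1+G56+F1+")
B1NEG_PATTERNS <- c(P3_B1neg = "B1-G1+G56-F1-", P4_B1neg = "B1-G1+G56+F1-")

#' Progressive KLR/GPR56 population labels
#'
#' Maps each event's 4-bit (KLRB1, KLRG1, GPR56, KLRF1) positivity
#' pattern to the five canonical progressive populations: P1 all
#' negative, P2 KLRB1+ only, P3 KLRB1+KLRG1+, P4 KLRB1+KLRG1+GPR56+,
#' P5 all four positive.  Every other pattern is labeled
#' `off_path(<pattern>)` with the pattern retained.  With
#' `scheme = "extended"` the KLRB1-negative analogues of P3 and P4
#' (KLRG1+ without KLRB1) get their own labels `P3_B1neg` /
#' `P4_B1neg`, giving the 8-way composition used for tissue
#' comparisons.
#'
#' @param events event data.frame with the four KLR/GPR56 channels.
#' @param thresholds named per-channel positivity thresholds.
#' @param scheme `"progressive"` (default, 5 populations + off-path)
#'   or `"extended"`.
#' @return character vector of population labels (partition of the
#'   events: labels always cover every event exactly once).
#' @export
gate_klr <- function(events, thresholds,
                     scheme = c("progressive", "extended")) {
  scheme <- match.arg(scheme)
  check_channels(events, KLR_MARKERS)
  pos <- vapply(KLR_MARKERS, function(ch) is_pos(events, ch, thresholds),
                logical(nrow(events)))
  if (nrow(events) == 1) pos <- matrix(pos, 1, dimnames = list(NULL, KLR_MARKERS))
  pat <- klr_pattern(pos)
  map <- CANONICAL_PATTERNS
  if (scheme == "extended") map <- c(map, B1NEG_PATTERNS)
  lab <- names(map)[match(pat, map)]
  off <- is.na(lab)
  lab[off] <- sprintf("off_path(%s)", pat[off])
  lab
}

#' Cytokine producer frequencies per group
#'
#' Percent of TNF single-positive, IFN-gamma single-positive,
#' TNF+IFN-gamma co-producing, and any-producing events per group.
#' Empty groups yield NA frequencies rather than an error.
#'
#' @param events event data.frame with TNF and IFNg channels.
#' @param groups grouping label per event (e.g. [gate_klr()] output).
#' @param thresholds named per-channel positivity thresholds.
#' @return data.frame with one row per group: `group`, `n`, `pct_tnf`,
#'   `pct_ifng`, `pct_co` (percentages of the group size).
#' @export
coproducer_frequency <- function(events, groups, thresholds) {
  check_channels(events, CYTOKINE_CHANNELS)
  tnf <- is_pos(events, "TNF", thresholds)
  ifng <- is_pos(events, "IFNg", thresholds)
  lev <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  rows <- lapply(lev, function(g) {
    i <- which(groups == g)
    n <- length(i)
    pct <- function(x) if (n == 0) NA_real_ else 100 * sum(x[i]) / n
    data.frame(group = g, n = n, pct_tnf = pct(tnf), pct_ifng = pct(ifng),
               pct_co = pct(tnf & ifng))
  })
  do.call(rbind, rows)
}

#' KLR/GPR56 population composition within classic subsets
#'
#' For each requested classic subset, the fraction of its events in
#' each progressive population; all off-path patterns are pooled into
#' one `off_path` bin.  Fractions sum to 1 within a non-empty subset;
#' empty subsets return an empty composition.
#'
#' @param classic classic subset label per event ([gate_classic()]).
#' @param klr KLR population label per event ([gate_klr()]).
#' @param within classic subsets to report (default T_EM and T_EMRA).
#' @return named list: subset -> named fraction vector.
#' @export
subset_composition <- function(classic, klr,
                               within = c("T_EM", "T_EMRA")) {
  klr_pooled <- ifelse(startsWith(klr, "off_path"), "off_path", klr)
  out <- lapply(within, function(s) {
    x <- klr_pooled[classic == s & !is.na(classic)]
    if (length(x) == 0) return(numeric(0))
    tab <- table(factor(x, levels = unique(c(KLR_STAGES, sort(unique(x))))))
    tab <- tab[tab > 0 | names(tab) %in% KLR_STAGES]
    as.vector(tab) / length(x) -> fr
    stats::setNames(fr, names(tab))
  })
  names(out) <- within
  out
}

dunn_pairs <- function(rbar, se_fun, groups, p_adjust) {
  pairs <- utils::combn(groups, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z[i] <- (rbar[a] - rbar[b]) / se_fun(a, b)
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p = p, p_adj = stats::p.adjust(p, method = p_adjust))
}

#' Nonparametric comparison of three or more groups with Dunn post-hoc
#'
#' Matched (per-donor) measurements are compared with Friedman's
#' rank-sum test followed by Dunn's pairwise z-tests on the mean
#' within-block ranks; unmatched samples use the Kruskal-Wallis test
#' with Dunn's z-tests on mean pooled ranks (tie-corrected).  Pairwise
#' p-values are adjusted over all tested pairs (Bonferroni by
#' default, configurable).
#'
#' @param values matched: numeric donors x groups matrix/data.frame
#'   with complete blocks; unmatched: named list of numeric vectors.
#' @param matched TRUE for the matched (Friedman) design.
#' @param p_adjust adjustment method for [stats::p.adjust()].
#' @return list with `omnibus` (`statistic`, `df`, `p`, `method`) and
#'   `pairwise` (data.frame with z and adjusted p per group pair).
#' @export
compare_groups <- function(values, matched = TRUE, p_adjust = "bonferroni") {
  if (matched) {
    m <- as.matrix(values)
    if (ncol(m) < 3) stop_input("need >= 3 groups")
    if (nrow(m) < 3) stop_input("need >= 3 donors")
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)
      stop_input("incomplete blocks: %s",
                 paste(sprintf("donor %s / group %s",
                               rownames(m)[idx[, 1]] %||% idx[, 1],
                               colnames(m)[idx[, 2]] %||% idx[, 2]),
                       collapse = "; "))
    }
    if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
    ft <- stats::friedman.test(m)
    # fully tied blocks leave the tie-corrected statistic undefined (0/0);
    # there is no evidence against the null then
    if (!is.finite(ft$statistic)) {
      ft$statistic <- 0
      ft$p.value <- 1
    }
    n <- nrow(m); k <- ncol(m)
    ranks <- t(apply(m, 1, rank))
    rbar <- colMeans(ranks)
    se <- function(a, b) sqrt(k * (k + 1) / (6 * n))
    pairwise <- dunn_pairs(rbar, se, colnames(m), p_adjust)
    omnibus <- list(statistic = unname(ft$statistic),
                    df = unname(ft$parameter), p = ft$p.value,
                    method = "Friedman")
  } else {
    stopifnot(is.list(values))
    if (length(values) < 3) stop_input("need >= 3 groups")
    if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
    kt <- stats::kruskal.test(values)
    x <- unlist(values, use.names = FALSE)
    g <- rep(names(values), lengths(values))
    r <- rank(x)
    N <- length(x)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    rbar <- tapply(r, g, mean)
    ns <- lengths(values)
    se <- function(a, b)
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    pairwise <- dunn_pairs(rbar, se, names(values), p_adjust)
    omnibus <- list(statistic = unname(kt$statistic),
                    df = unname(kt$parameter), p = kt$p.value,
                    method = "Kruskal-Wallis")
  }
  list(omnibus = omnibus, pairwise = pairwise)
}
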