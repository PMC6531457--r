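#' Generate a synthetic cytometry event table
#'
#' Draws `n_cells` events from a [default_stage_model()]-style mixture.
#' Each event gets a hidden stage, per-channel boolean states drawn from
#' the stage's positivity probabilities, a cytokine production category
#' (none / TNF only / IFN-gamma only / co-producer), and continuous
#' intensities drawn from the channel's two-component log-normal.
#' Hidden truth is emitted in columns prefixed `truth_` so downstream
#' modules can be run blinded and evaluated afterwards.
#'
#' @param model a `stage_model`; see [default_stage_model()].
#' @param n_cells number of events to draw (> 0).
#' @param seed integer seed; identical `(model, n_cells, seed)` calls
#'   return identical tables.
#' @return data.frame with one row per event: intensity columns CCR7,
#'   CD45RA, CD25, CD127, KLRB1, KLRG1, GPR56, KLRF1, TNF, IFNg, plus
#'   `truth_stage` and logical `truth_<channel>` state columns.
#' @export
gen_events <- function(model = default_stage_model(), n_cells, seed) {
  if (n_cells <= 0) stop_input("n_cells must be positive")
  validate_stage_model(model)
  set.seed(seed)

  support <- names(model$stage_mix)[model$stage_mix > 0]
  flat <- rownames(model$marker_on_prob)[
    rowSums(model$marker_on_prob) == 0 &
    rowSums(model$cytokine_prob) == 0]
  if (length(intersect(flat, support)))
    warning("non-stochastic stage(s) in mixture: ",
            paste(intersect(flat, support), collapse = ", "))

  stage <- sample(model$stages, n_cells, replace = TRUE,
                  prob = model$stage_mix[model$stages])

  state <- matrix(FALSE, n_cells, length(ALL_CHANNELS),
                  dimnames = list(NULL, ALL_CHANNELS))
  for (ch in PHENO_CHANNELS)
    state[, ch] <- stats::runif(n_cells) < model$pheno_on_prob[stage, ch]
  for (ch in KLR_MARKERS)
    state[, ch] <- stats::runif(n_cells) < model$marker_on_prob[stage, ch]

  cp <- model$cytokine_prob[stage, , drop = FALSE]
  u <- stats::runif(n_cells)
  co <- u < cp[, "co"]
  tnf_only <- !co & u < cp[, "co"] + cp[, "tnf_only"]
  ifng_only <- !co & !tnf_only &
    u < cp[, "co"] + cp[, "tnf_only"] + cp[, "ifng_only"]
  state[, "TNF"] <- co | tnf_only
  state[, "IFNg"] <- co | ifng_only

  ip <- model$intensity_params
  intens <- matrix(NA_real_, n_cells, length(ALL_CHANNELS),
                   dimnames = list(NULL, ALL_CHANNELS))
  for (ch in ALL_CHANNELS) {
    on <- state[, ch]
    mu <- ifelse(on, ip[ch, "pos_meanlog"], ip[ch, "neg_meanlog"])
    sdl <- ifelse(on, ip[ch, "pos_sdlog"], ip[ch, "neg_sdlog"])
    intens[, ch] <- exp(stats::rnorm(n_cells, mu, sdl))
  }

  out <- as.data.frame(intens)
  out$truth_stage <- stage
  for (ch in ALL_CHANNELS) out[[paste0("truth_", ch)]] <- state[, ch]
  out
}

#' Construct a single-cell qRT-PCR Ct matrix object
#'
#' @param ct numeric cells x genes matrix of cycle-threshold values
#'   (NA = undetected).  Positive where present.
#' @param control_genes names of the control assays (default B2M and
#'   Spike1); must be columns of `ct` when cell filtering is intended.
#' @param lod per-gene limit-of-detection Ct; a scalar is recycled.
#'   Defaults to Ct 24.
#' @param cell_labels optional subset label per cell.
#' @return object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, control_genes = c("B2M", "Spike1"), lod = 24,
                      cell_labels = NULL) {
  ct <- as.matrix(ct)
  if (is.null(colnames(ct))) stop_input("ct matrix needs gene column names")
  bad <- which(!is.na(ct) & ct <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("non-positive Ct for cell '%s', gene '%s'",
               rownames(ct)[bad[1, 1]] %||% bad[1, 1],
               colnames(ct)[bad[1, 2]])
  if (is.null(rownames(ct))) rownames(ct) <- paste0("cell", seq_len(nrow(ct)))
  lod <- rep_len(lod, ncol(ct))
  names(lod) <- colnames(ct)
  structure(list(ct = ct, control_genes = control_genes, lod = lod,
                 cell_labels = cell_labels),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("Ct matrix:", nrow(x$ct), "cells x", ncol(x$ct), "genes; LoD range",
      paste(range(x$lod), collapse = "-"), "\n")
  invisible(x)
}

#' Generate a synthetic single-cell qRT-PCR Ct matrix
#'
#' Emulates a Fluidigm-style cells x genes Ct export.  Each subset has a
#' per-gene expressing fraction; expressing cells draw a Ct below the
#' gene's LoD, non-expressing cells are either missing or fall at/above
#' the LoD.  A configurable fraction of cells fails the B2M/Spike1
#' controls (both undetected), to exercise the cell filter.
#'
#' @param subset_profiles named list: subset -> named vector of
#'   expressing fractions per gene (all genes must agree across
#'   subsets).
#' @param n_cells cells per subset (scalar or per-subset vector).
#' @param seed integer seed.
#' @param lod limit-of-detection Ct (default 24).
#' @param control_fail_rate fraction of cells with failed controls.
#' @return a `ct_matrix` with `cell_labels` set to the subset of origin.
#' @export
gen_ct_matrix <- function(subset_profiles, n_cells, seed, lod = 24,
                          control_fail_rate = 0.02) {
  stopifnot(length(subset_profiles) >= 1)
  fracs <- do.call(rbind, subset_profiles)
  if (any(fracs < 0 | fracs > 1))
    stop_input("expressing fractions must lie in [0, 1]")
  genes <- colnames(fracs)
  set.seed(seed)
  n_cells <- rep_len(n_cells, length(subset_profiles))
  labels <- rep(names(subset_profiles), n_cells)
  n <- length(labels)

  draw_gene <- function(frac_per_cell) {
    expressing <- stats::runif(n) < frac_per_cell
    ct <- rep(NA_real_, n)
    ne <- which(!expressing)
    detected_noise <- ne[stats::runif(length(ne)) < 0.4]
    ct[detected_noise] <- stats::runif(length(detected_noise), lod, lod + 4)
    ex <- which(expressing)
    ct[ex] <- pmin(pmax(stats::rnorm(length(ex), lod - 7, 1.8), 5), lod - 0.1)
    ct
  }
  ct <- vapply(genes, function(g) draw_gene(fracs[labels, g]), numeric(n))

  # controls: strong, always-on assays except in failed cells
  b2m <- pmax(stats::rnorm(n, 14, 1), 5)
  spike <- pmax(stats::rnorm(n, 13, 1), 5)
  failed <- stats::runif(n) < control_fail_rate
  b2m[failed] <- NA
  spike[failed] <- NA
  ct <- cbind(ct, B2M = b2m, Spike1 = spike)
  rownames(ct) <- sprintf("%s_c%04d", labels, seq_len(n))
  ct_matrix(ct, control_genes = c("B2M", "Spike1"), lod = lod,
            cell_labels = labels)
}

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
V_GENES <- sprintf("TRBV%d", c(2, 4, 5, 6, 7, 9, 10, 11, 12, 13, 14, 15,
                               18, 19, 20, 24, 25, 27, 28, 29, 30))
J_GENES <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))

# unique CDR3 amino-acid strings: 3 random residues plus a base-20
# encoding of a running index, framed by canonical CASS...F anchors
make_clone_ids <- function(n, offset) {
  if (n == 0)
    return(data.frame(v_gene = character(0), j_gene = character(0),
                      cdr3_aa = character(0)))
  encode <- function(i) {
    s <- character(0)
    i <- i - 1
    repeat {
      s <- c(AA[i %% 20 + 1], s)
      i <- i %/% 20
      if (i == 0) break
    }
    paste(s, collapse = "")
  }
  idx <- offset + seq_len(n)
  data.frame(
    v_gene = sample(V_GENES, n, replace = TRUE),
    j_gene = sample(J_GENES, n, replace = TRUE),
    cdr3_aa = paste0(
      "CASS",
      vapply(seq_len(n), function(i)
        paste(sample(AA, 3, replace = TRUE), collapse = ""), character(1)),
      vapply(idx, encode, character(1)), "F"))
}

#' Generate synthetic TCR-beta repertoires for the five stages
#'
#' One clonotype table per progressive stage P1..P5.  Counts follow a
#' power-law rank-frequency distribution with the model's
#' stage-specific exponent; the top clones of the late stages (P4, P5)
#' are seeded into earlier repertoires with the model's sharing
#' probabilities, at random rank positions.  Every listed clone
#' receives at least one read, so seeded clones are guaranteed present.
#'
#' @param model a `repertoire_model`; see [default_repertoire_model()].
#' @param seed integer seed.
#' @param emit_reads if TRUE, also return per-read records (one row per
#'   read with clonotype identity and a mean Phred quality drawn from
#'   the model's quality distribution) for exercising the Q30 filter.
#' @return named list of `clonotype_table`s (P1..P5); with
#'   `emit_reads`, a list with elements `tables` and `reads`.
#' @export
gen_repertoires <- function(model = default_repertoire_model(), seed,
                            emit_reads = FALSE) {
  if (any(model$n_clones < 1)) stop_input("n_clones must be >= 1 per stage")
  set.seed(seed)
  stages_late_first <- rev(KLR_STAGES)
  clones <- list()   # per stage: data.frame of clone identities
  tables <- list()
  offset <- 0

  for (s in stages_late_first) {
    n_s <- model$n_clones[[s]]
    inject <- NULL
    for (src in c("P5", "P4")) {
      if (src == s || !src %in% names(tables)) next
      pr <- model$sharing[src, s]
      if (pr <= 0) next
      top <- head_clones(tables[[src]], model$top_k_shared)
      keep <- stats::runif(nrow(top)) < pr
      inject <- rbind(inject, top[keep, c("v_gene", "j_gene", "cdr3_aa")])
    }
    if (!is.null(inject))
      inject <- unique(inject)
    n_inject <- if (is.null(inject)) 0 else min(nrow(inject), n_s)
    if (n_inject > 0) inject <- inject[seq_len(n_inject), , drop = FALSE]
    n_fresh <- n_s - n_inject
    fresh <- make_clone_ids(n_fresh, offset)
    offset <- offset + n_fresh
    ids <- rbind(inject, fresh)
    ids <- ids[sample(nrow(ids)), , drop = FALSE]   # random rank placement

    p <- seq_len(n_s)^(-model$expansion[[s]])
    p <- p / sum(p)
    depth <- model$read_depth[[s]]
    extra <- if (depth > n_s) as.vector(stats::rmultinom(1, depth - n_s, p))
             else 0
    ids$count <- 1 + extra
    tables[[s]] <- clonotype_table(ids, population = s)
  }
  tables <- tables[KLR_STAGES]

  if (!emit_reads) return(tables)
  reads <- lapply(tables, function(tb) {
    idx <- rep(seq_len(nrow(tb)), tb$count)
    q <- pmin(pmax(stats::rnorm(length(idx), model$quality_mean,
                                model$quality_sd), 2), 41)
    data.frame(read_id = sprintf("%s_r%06d", attr(tb, "population"),
                                 seq_along(idx)),
               v_gene = tb$v_gene[idx], j_gene = tb$j_gene[idx],
               cdr3_aa = tb$cdr3_aa[idx], avg_quality = q)
  })
  list(tables = tables, reads = reads)
}

#' Generate a synthetic bulk expression matrix
#'
#' Log2-scale samples x genes matrix for the four classic subsets (T_N,
#' T_CM, T_EM, T_EMRA) with planted signature genes: each signature
#' gene is shifted up by `log2(fold)` in the subsets named in its
#' `up_in` field, on top of a per-gene baseline plus Gaussian noise.
#'
#' @param signature NULL or data.frame with columns `gene`, `fold`
#'   (linear fold change, > 0) and `up_in` (comma-separated subset
#'   names).
#' @param n_replicates samples per subset.
#' @param n_background number of unaffected background genes.
#' @param noise_sd per-measurement Gaussian noise, log2 units.
#' @param seed integer seed.
#' @return object of class `bulk_matrix`: list with `expr`
#'   (samples x genes, log2) and `labels` (subset per sample).
#' @export
gen_bulk <- function(signature = NULL, n_replicates = 6, n_background = 300,
                     noise_sd = 0.25, seed = 1) {
  if (!is.null(signature) && any(signature$fold <= 0))
    stop_input("signature folds must be > 0")
  set.seed(seed)
  genes <- sprintf("BG%04d", seq_len(n_background))
  if (!is.null(signature)) genes <- c(as.character(signature$gene), genes)
  labels <- rep(CLASSIC_SUBSETS, each = n_replicates)
  n <- length(labels)
  base <- stats::runif(length(genes), 6, 12)
  expr <- matrix(stats::rnorm(n * length(genes), sd = noise_sd), n,
                 dimnames = list(sprintf("%s_s%02d", labels, seq_len(n)),
                                 genes))
  expr <- sweep(expr, 2, base, "+")
  if (!is.null(signature)) {
    for (i in seq_len(nrow(signature))) {
      ups <- trimws(strsplit(as.character(signature$up_in[i]), ",")[[1]])
      expr[labels %in% ups, as.character(signature$gene[i])] <-
        expr[labels %in% ups, as.character(signature$gene[i])] +
        log2(signature$fold[i])
    }
  }
  structure(list(expr = expr, labels = labels), class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat("Bulk matrix:", nrow(x$expr), "samples x", ncol(x$expr), "genes (",
      paste(unique(x$labels), collapse = ", "), ")\n")
  invisible(x)
}
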