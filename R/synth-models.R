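#' Default generative model of progressive marker acquisition
#'
#' Describes the cell populations a stimulated CD4+ T-cell sample is
#' assumed to contain: naive cells, regulatory T cells, the five
#' canonical progressive KLR/GPR56 stages P1..P5 (from
#' KLRB1-KLRG1-GPR56-KLRF1- to all four positive), and a low-frequency
#' off-path pattern (KLRB1-KLRG1+) that is observed in real samples.
#' For each stage the model holds per-channel positivity probabilities,
#' cytokine production probabilities (TNF only, IFN-gamma only, and
#' TNF/IFN-gamma co-production), and two-component log-normal intensity
#' parameters per channel.
#'
#' The defaults encode the assumed biology: marker positivity is
#' monotone non-decreasing along P1 to P5 for each of KLRB1, KLRG1,
#' GPR56 and KLRF1 (progressive acquisition), and TNF/IFN-gamma
#' co-production is unimodal along the path — low in P1, maximal around
#' P3/P4, and reduced again in the terminally differentiated P5
#' ("exhausted") stage.
#'
#' @param separation difference between positive and negative component
#'   means on the log-intensity scale; the default gives well-separated
#'   components (about 6.7 component standard deviations).
#' @return an object of class `stage_model`.
#' @export
default_stage_model <- function(separation = log(1000) - log(50)) {
  stages <- c("naive", "treg", KLR_STAGES, "offpath_B1nG1p")
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(stages, NULL)
    m
  }
  hi <- 0.995; lo <- 0.005
  marker_on_prob <- mk(
    #        KLRB1 KLRG1 GPR56 KLRF1
    naive = c(lo,   lo,   lo,   lo),
    treg  = c(0.05, lo,   lo,   lo),
    P1    = c(lo,   lo,   lo,   lo),
    P2    = c(hi,   lo,   lo,   lo),
    P3    = c(hi,   hi,   lo,   lo),
    P4    = c(hi,   hi,   hi,   lo),
    P5    = c(hi,   hi,   hi,   hi),
    offpath_B1nG1p = c(lo, hi,  lo,   lo))
  colnames(marker_on_prob) <- KLR_MARKERS

  pheno_on_prob <- mk(
    #        CCR7  CD45RA CD25  CD127
    naive = c(0.98, 0.98, 0.05, 0.90),
    treg  = c(0.60, 0.10, 0.97, 0.04),
    P1    = c(0.70, 0.08, 0.10, 0.85),
    P2    = c(0.50, 0.08, 0.10, 0.85),
    P3    = c(0.30, 0.15, 0.10, 0.85),
    P4    = c(0.12, 0.35, 0.10, 0.85),
    P5    = c(0.05, 0.80, 0.10, 0.85),
    offpath_B1nG1p = c(0.30, 0.15, 0.10, 0.85))
  colnames(pheno_on_prob) <- PHENO_CHANNELS

  cytokine_prob <- mk(
    #        tnf_only ifng_only co
    naive = c(0.05, 0.01, 0.01),
    treg  = c(0.03, 0.01, 0.01),
    P1    = c(0.08, 0.02, 0.02),
    P2    = c(0.25, 0.05, 0.15),
    P3    = c(0.28, 0.12, 0.45),
    P4    = c(0.24, 0.15, 0.42),
    P5    = c(0.10, 0.08, 0.12),
    offpath_B1nG1p = c(0.25, 0.08, 0.20))
  colnames(cytokine_prob) <- c("tnf_only", "ifng_only", "co")

  stage_mix <- c(naive = 0.20, treg = 0.05, P1 = 0.20, P2 = 0.17,
                 P3 = 0.15, P4 = 0.12, P5 = 0.08, offpath_B1nG1p = 0.03)

  intensity_params <- data.frame(
    channel = ALL_CHANNELS,
    neg_meanlog = log(50), neg_sdlog = 0.45,
    pos_meanlog = log(50) + separation, pos_sdlog = 0.45,
    row.names = ALL_CHANNELS)

  model <- structure(
    list(stages = stages, stage_mix = stage_mix,
         marker_on_prob = marker_on_prob, pheno_on_prob = pheno_on_prob,
         cytokine_prob = cytokine_prob, intensity_params = intensity_params),
    class = "stage_model")
  validate_stage_model(model)
  model
}

#' Validate a stage model
#'
#' Checks probability ranges and the structural assumptions of the
#' progressive path: monotone marker acquisition along P1..P5 and a
#' unimodal co-production profile peaking at P3 or P4 and declining in
#' P5.
#'
#' @param model a `stage_model`.
#' @return the model, invisibly; errors describe the violated property.
#' @export
validate_stage_model <- function(model) {
  probs <- c(model$marker_on_prob, model$pheno_on_prob,
             model$cytokine_prob, model$stage_mix)
  if (any(probs < 0 | probs > 1))
    stop_input("stage model probabilities must lie in [0, 1]")
  if (abs(sum(model$stage_mix) - 1) > 1e-8)
    stop_input("stage_mix must sum to 1")
  mp <- model$marker_on_prob[KLR_STAGES, , drop = FALSE]
  if (any(apply(mp, 2, function(p) any(diff(p) < 0))))
    stop_input("marker_on_prob must be monotone non-decreasing along P1..P5")
  co <- model$cytokine_prob[KLR_STAGES, "co"]
  peak <- which.max(co)
  if (!peak %in% c(3L, 4L) || co[5] >= max(co[3:4]) || co[1] >= co[peak])
    stop_input("co-production must rise to a P3/P4 maximum and decline at P5")
  invisible(model)
}

#' Default generative model of clonally expanded TCR-beta repertoires
#'
#' One repertoire per progressive stage P1..P5.  Rank-frequency follows
#' a power law with a stage-specific exponent that increases along the
#' path (progressive clonal expansion), while clone richness decreases;
#' both drive the expected Renyi diversity down from P1 to P5.  Dominant
#' (top `top_k_shared`) clones of the late stages P4 and P5 are seeded
#' into earlier repertoires with probabilities from `sharing`, with
#' adjacent late stages sharing more than distal pairs.
#'
#' @return an object of class `repertoire_model`.
#' @export
default_repertoire_model <- function() {
  sharing <- matrix(0, 5, 5, dimnames = list(KLR_STAGES, KLR_STAGES))
  sharing["P5", c("P1", "P2", "P3", "P4")] <- c(0.10, 0.25, 0.40, 0.80)
  sharing["P4", c("P1", "P2", "P3")] <- c(0.12, 0.30, 0.50)
  structure(
    list(
      n_clones = c(P1 = 3000, P2 = 2000, P3 = 1200, P4 = 500, P5 = 80),
      expansion = c(P1 = 0.30, P2 = 0.60, P3 = 0.90, P4 = 1.20, P5 = 1.50),
      read_depth = c(P1 = 20000, P2 = 20000, P3 = 20000, P4 = 20000,
                     P5 = 20000),
      sharing = sharing,
      top_k_shared = 100,
      quality_mean = 36, quality_sd = 3),
    class = "repertoire_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("Stage model:", length(x$stages), "stages\n")
  cat("mixture:", paste(sprintf("%s=%.2f", names(x$stage_mix), x$stage_mix),
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
print.repertoire_model <- function(x, ...) {
  cat("Repertoire model: stages", paste(names(x$n_clones), collapse = " "),
      "\n  clones:", paste(x$n_clones, collapse = " "),
      "\n  power-law exponents:", paste(x$expansion, collapse = " "), "\n")
  invisible(x)
}
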