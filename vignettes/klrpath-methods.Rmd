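---
title: "Methods: models, parameters and design choices in klrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in klrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klrpath)
```

# Scope

`klrpath` analyses human CD4+ memory T-cell differentiation through a
progressive surface-marker classification: cells acquire KLRB1, then
KLRG1, then GPR56, and finally KLRF1, giving five canonical populations
P1 (all four negative) through P5 (all four positive). The package
covers the five analysis stages around that idea — single-cell qRT-PCR
preprocessing, bulk intersection differential expression, cytometry
gating with cytokine quantification, TCRβ repertoire statistics, and a
pseudotime trajectory — together with synthetic-data generators that
emulate every input kind. This vignette records the models, the
defaults, and the choices made where the design was genuinely open.

# Single-cell qRT-PCR (`scqpcr`)

Expression is defined as `Log2Ex = LoD − Ct`: one cycle below the
limit of detection equals one log2 unit of expression. Missing Ct or
Ct at/above the LoD is non-expression, with `Log2Ex` clamped at 0, so
`expressed ⇔ Log2Ex > 0`. The default LoD is Ct 24 for every gene.

**LoD adjustment.** Some assays produce a low-level noise mode below
the default LoD. `adjust_lod()` treats a gene's detected-Ct
distribution as a two-component mixture: it smooths the values with a
Gaussian kernel (`stats::density`, bandwidth `nrd0` by default,
configurable) and, when two or more modes exist, lowers the LoD to the
valley between the two highest modes. This is a heuristic — the
underlying idea is only "include noise-free data" — so it requires at
least 20 detected values, never raises the LoD above the default, and
can be overridden per gene with an explicit table (`overrides=`).

**Filtering.** Cells with undetectable B2M or Spike1 are removed
first; genes expressed in fewer than 10 of the remaining cells are
removed second; the control columns are then dropped from the analysis
matrix. Because the controls are gone after the first pass, the filter
is idempotent. Removing every cell is an explicit error, not an empty
result.

**Clustering.** Cells and genes are clustered on Euclidean distances
over the *continuous* `Log2Ex` values with Ward linkage
(`hclust(method = "ward.D2")`, i.e. heights are the square root of
twice the increase in within-cluster error sum of squares; the test
suite checks this against a direct ESS-minimizing implementation). The
binary expressed/non-expressed matrix is presentation only: it is
returned reordered for heatmap rendering but never drives the linkage.
Rows are sorted lexicographically by cell identifier before clustering
so that record order cannot change the dendrogram.

# Bulk intersection differential expression (`bulkde`)

Samples are quantile-normalized (delegated to
`limma::normalizeQuantiles(ties = TRUE)`, so tied values receive the
mean of the order statistics they span), then per-gene two-sample
t-tests compare subset pairs. Welch's unequal-variance test is the
default because the equal-variance assumption buys nothing here;
Student's form is available via `var_equal = TRUE`. Fold changes are
linear-scale, `2^(mean difference)` of the log2 values, matching the
"twofold upregulation" phrasing.

The intersections are strict conjunctions: `intersect_temra()` keeps a
gene iff fold ≥ 2 **and** p < 0.05 in *each* of T_EMRA vs T_N, T_CM
and T_EM; `intersect_tem_temra()` requires the same in all four of
T_EMRA/T_EM vs T_N/T_CM. The fold boundary is inclusive ("at least
twofold") and the p boundary exclusive. No multiple-testing correction
is applied inside the intersection by default — the procedure is a raw
per-comparison p < 0.05 rule — but `adjust = "BH"` switches every
comparison to FDR-adjusted p-values. Surfaceome restriction is a
case-insensitive symbol intersection with a report of unmatched
symbols. Probe-to-gene collapsing is out of scope: inputs are
gene-level matrices.

# Gating and group comparisons (`cytogate`)

Positivity is strict (`intensity > threshold`); an event exactly at a
threshold is negative, which keeps gating deterministic. Thresholds
are supplied per channel; `estimate_thresholds()` automates the manual
gate by placing each channel's threshold at the valley of the
two-component log-intensity distribution (k-means midpoint as the
unimodal fallback). Tregs are CD25-high and CD127-low and are excluded
from conventional analyses; the remaining events are labeled by the
CD45RA × CCR7 quadrant. `gate_klr()` maps the 4-bit
(KLRB1, KLRG1, GPR56, KLRF1) pattern to P1..P5; the other 11 patterns
are never discarded but labeled `off_path(<pattern>)`, so the labels
always partition the events. `scheme = "extended"` additionally names
the KLRB1-negative analogues of P3/P4 (`P3_B1neg`, `P4_B1neg`), the
8-way composition used when comparing blood and tissue.

Matched per-donor comparisons of ≥ 3 groups use Friedman's test with
Dunn's post-hoc z-tests on mean within-block ranks,
`z = (R̄ᵢ − R̄ⱼ) / sqrt(k(k+1)/(6n))`; unmatched comparisons use
Kruskal–Wallis with tie-corrected Dunn z-tests. Which family the
pairwise adjustment controls is not canonical, so it is configurable;
the default is Bonferroni over all tested pairs, the convention of the
common graphing software. Fully tied blocks make the tie-corrected
Friedman statistic 0/0; the package reports statistic 0, p = 1.

# TCRβ repertoire statistics (`repertoire`)

A clonotype is the triple (Vβ gene, Jβ gene, CDR3 amino-acid
sequence). Reads with mean Phred quality below 30 are excluded (the
boundary read at exactly 30 is retained); similarity and diversity are
computed on the top 100 expanded clones, with boundary ties broken by
(count desc, V, J, CDR3) so selection is permutation-invariant.

**Morisita–Horn.** The published formula divides Σpᵢ and Σqᵢ by P² and
Q², which reads ambiguously depending on whether pᵢ, qᵢ are counts or
proportions. The two readings are algebraically the same index, and
`morisita_horn()` computes both — the counts form
`2Σxᵢyᵢ / ((Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y)` and the proportions form
`2Σpᵢqᵢ / (Σpᵢ² + Σqᵢ²)` — and asserts their equality to 1e−9 before
returning. Self-similarity is exactly 1, disjoint repertoires exactly 0.

**Rényi profiles.** `H_α = ln(Σpᵢ^α)/(1−α)` in natural-log units, with
the limit cases ln(richness) at α = 0, Shannon at α = 1, ln(1/Simpson)
at α = 2 and −ln(max pᵢ) at α = ∞. Large α is evaluated in the
numerically stable form `(α·ln m + ln Σ(pᵢ/m)^α)/(1−α)` with
`m = max pᵢ` so that α = 64 does not underflow. The default grid is
0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, ∞ — the named readouts plus
geometric padding. Profile ranking is dominance: higher everywhere
(strictly somewhere) means more diverse; any crossing means no ranking
(`not_rankable`); numerically identical profiles are `tied`.

# Trajectory (`trajectory`)

**Density-dependent downsampling.** Local density is the inverse mean
distance to the `k_density` (default 15) nearest neighbours on the
robust-scaled log trajectory channels. Events are retained with
probability `min(1, c/density)`, with `c` found by bisection so the
expected retained count equals the budget (default 50,000 cells), and
a final uniform trim/top-up makes the size exact. Only observed events
are ever returned.

**Pseudotime.** The trajectory channels are CCR7, CD45RA, the four KLR
markers, TNF and IFN-γ, each robust-scaled (median/MAD of
log-intensities) because fluorophore scales differ. A k-nearest-
neighbour graph (`k_graph = 15`) is built; disconnected components are
joined through their nearest inter-component event pair with a
warning. Per repeat, one randomly chosen CD45RA+CCR7+ initiator is the
origin, its geodesic distances seed the ordering, and `n_waypoints`
(60) random waypoints refine each event's position as the mean of the
waypoint perspectives `t_w ± d(w, i)` — plus when the event lies
beyond the waypoint, minus otherwise — for `n_refine` (2) passes.
Repeats (`n_repeats = 5`) are min–max scaled and averaged. This is a
waypoint shortest-path ensemble in the spirit of the published
graph-trajectory tools for cytometry; its acceptance surface is
ordering recovery (stage means increase, acquisition order correct),
not numeric identity with any specific implementation, and every
parameter is exposed. When no initiator gate is supplied, the top 5%
of events by CCR7 × CD45RA product serve as initiators.

**Curves.** Events are binned by pseudotime quantiles (20 bins by
default; bins collapsed by ties merge into their neighbour), per-bin
channel medians are min–max normalized to [0, 1], and the acquisition
order is the order of first crossing of 0.5 — a scale-free threshold on
normalized curves, with linear interpolation between bins. Constant
channels stay flat and are excluded from the ordering.

# The synthetic-data generators (`synth`)

The generators define the study conditions the tests run under; they
are fixtures in code, not dials.

* **Events.** A mixture of naive, Treg, P1..P5 and one low-frequency
  off-path pattern (KLRB1−KLRG1+, 3%) — off-path cells are included
  because real samples contain them. Default mixture: 20% naive, 5%
  Treg, 20/17/15/12/8% P1..P5. Marker states are Bernoulli with
  probability 0.995 (on) / 0.005 (off) for the stage's canonical
  pattern — high-fidelity but not deterministic; intensities are
  two-component log-normal per channel, meanlog log(50) vs log(1000),
  sdlog 0.45 (≈ 6.7 SD separation, i.e. "well-separated" gating
  difficulty; the separation is a single argument of
  `default_stage_model()` so tests can tune difficulty). Cytokine
  co-production rises 2% → 45% from P1 to P3, stays comparable at P4
  and collapses to 12% at P5 — the low → high → exhausted profile.
  CCR7 decays and CD45RA re-appears along the path, so the classic
  quadrants correlate with the stages as expected.
* **Ct matrices.** Expressing cells draw Ct ~ N(LoD − 7, 1.8) truncated
  below the LoD; non-expressing cells are missing (60%) or uniform in
  [LoD, LoD + 4]; 2% of cells fail both controls.
* **Repertoires.** Rank-frequency is a power law with exponent rising
  0.3 → 1.5 from P1 to P5 (one parameter reproduces progressive clonal
  expansion), clone richness falling 3000 → 80, depth 20,000 reads.
  The top-100 clones of P4 and P5 are seeded into earlier stages with
  probabilities 0.8 (P5→P4) down to 0.10 (P5→P1), at random rank
  positions, and every listed clone keeps at least one read so seeded
  presence is exact. P5's richness of 80 is deliberately below the
  top-100 cutoff: the most differentiated sorted population is tiny,
  and its profile then sits below P1's at *every* α including the
  α = 0 richness limit.
* **Bulk.** Gene baselines uniform in log2 [6, 12], Gaussian noise
  (default SD 0.25), signature genes shifted by log2(fold) in their
  subsets.

What passing on these data does *not* show: the generators have no
spectral spillover, no instrument drift, no doublets, no per-donor
heterogeneity (variation between repertoires comes only from sampling
noise), and log-normal intensity components are an idealization of
stained-population shapes. Recovery results are statements about the
pipeline's correctness under its own assumptions, not about any
donor's biology.

# Problem sizes and determinism

Every generator and every stochastic algorithm takes an explicit
integer seed, and identical calls are byte-identical. The shipped
tests use 50,000 events for moment-matching checks, 20,000 events for
gating recovery, 12,000 events downsampled to 4,000 for trajectory
recovery, and 1,000 random tables for the Rényi limit checks — sizes
at which the binomial 3-SE tolerances are meaningful while the whole
suite stays quick on one CPU. The acceptance script downsamples
200,000 events to the default 50,000-cell budget.

# Known limitations

* FCS binary parsing, compensation and spillover handling are out of
  scope; event tables arrive as TSV/CSV exports.
* V(D)J rearrangement extraction from raw reads is out of scope; the
  repertoire module consumes clonotype-annotated records (AIRR-style
  TSV, or FASTQ whose read names carry the annotation).
* t-SNE/viSNE map generation is not reimplemented.
* The pseudotime is one trajectory with one origin; branching fates
  are not modelled.
* `adjust_lod()` assumes at most two meaningful modes per gene; assays
  with more structure should use explicit per-gene overrides.
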