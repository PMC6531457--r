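# Shared fixtures used by both the unit suites and the acceptance suite.

# 12 cells, one assay gene expressed in n_expr_gene of them, controls on
# for all but the last cell (failed B2M).
filtered_fixture <- function(n_expr_gene) {
  n <- 12
  ct <- matrix(NA_real_, n, 3,
               dimnames = list(paste0("c", seq_len(n)),
                               c("GENEA", "B2M", "Spike1")))
  ct[seq_len(n_expr_gene), "GENEA"] <- 18
  ct[, "B2M"] <- 14
  ct[, "Spike1"] <- 14
  ct[n, "B2M"] <- NA
  compute_log2ex(ct_matrix(ct))
}

# three T_EMRA comparisons for one gene, with the T_EMRA-vs-T_EM fold
# and p left configurable
temra_results <- function(fold3, p3) {
  list(fake_de("G1", 3, 0.01, "T_EMRA_vs_T_N"),
       fake_de("G1", 2.5, 0.02, "T_EMRA_vs_T_CM"),
       fake_de("G1", fold3, p3, "T_EMRA_vs_T_EM"))
}
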