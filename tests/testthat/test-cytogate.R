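test_that("classic gating maps quadrants and excludes Tregs", {
  th <- unit_thresholds()
  ev <- make_events(CD45RA = c("+", "-", "-", "+", "+"),
                    CCR7   = c("+", "+", "-", "-", "+"),
                    CD25   = c("-", "-", "-", "-", "+"),
                    CD127  = c("+", "+", "+", "+", "-"))
  lab <- gate_classic(ev, th)
  expect_equal(as.character(lab), c("T_N", "T_CM", "T_EM", "T_EMRA", "Treg"))
  expect_error(gate_classic(ev[, -1], th), "CD45RA")
})

test_that("events exactly at threshold count as negative", {
  th <- unit_thresholds()
  ev <- data.frame(CD45RA = 100, CCR7 = 100, CD25 = 50, CD127 = 200)
  expect_equal(as.character(gate_classic(ev, th)), "T_EM")
})

test_that("the KLR scheme maps canonical patterns and keeps off-path ones", {
  th <- unit_thresholds()
  ev <- make_events(KLRB1 = c("-", "+", "+", "+", "+", "-"),
                    KLRG1 = c("-", "-", "+", "+", "+", "+"),
                    GPR56 = c("-", "-", "-", "+", "+", "-"),
                    KLRF1 = c("-", "-", "-", "-", "+", "-"))
  lab <- gate_klr(ev, th)
  expect_equal(lab, c("P1", "P2", "P3", "P4", "P5",
                      "off_path(B1-G1+G56-F1-)"))
  ext <- gate_klr(ev, th, scheme = "extended")
  expect_equal(ext[6], c("P3_B1neg"))
  expect_error(gate_klr(ev[, -2], th), "KLRG1")
})

test_that("klr labels partition random events", {
  ev <- gen_events(default_stage_model(), 3000, seed = 20)
  th <- estimate_thresholds(ev)
  lab <- gate_klr(ev, th)
  expect_equal(length(lab), nrow(ev))
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), nrow(ev))
  # threshold monotonicity: raising the KLRB1 threshold never increases
  # the KLRB1-positive count
  pos_count <- function(t) {
    th2 <- th; th2["KLRB1"] <- t
    sum(ev$KLRB1 > th2["KLRB1"])
  }
  ts <- quantile(ev$KLRB1, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_true(all(diff(vapply(ts, pos_count, numeric(1))) <= 0))
})

test_that("hidden stages are recovered from intensities by gating", {
  ev <- gen_events(default_stage_model(), 20000, seed = 21)
  th <- estimate_thresholds(ev)
  lab <- gate_klr(ev, th)
  on_path <- ev$truth_stage %in% c("P1", "P2", "P3", "P4", "P5")
  acc <- mean(lab[on_path] == ev$truth_stage[on_path])
  expect_gte(acc, 0.95)
  # the classic gate also recovers naive and Treg events well
  cl <- gate_classic(ev, th)
  expect_gt(mean(cl[ev$truth_stage == "naive"] == "T_N"), 0.9)
  expect_gt(mean(cl[ev$truth_stage == "treg"] == "Treg"), 0.85)
})

test_that("co-producer frequencies are percentages with NA for empty groups", {
  th <- unit_thresholds()
  ev <- make_events(TNF = c("+", "+", "-"), IFNg = c("+", "+", "-"))
  f <- coproducer_frequency(ev, groups = c("a", "a", "b"), th)
  expect_equal(f$pct_co[f$group == "a"], 100)
  expect_equal(f$pct_co[f$group == "b"], 0)
  f2 <- coproducer_frequency(ev, factor(c("a", "a", "a"),
                                        levels = c("a", "z")), th)
  expect_true(is.na(f2$pct_co[f2$group == "z"]))
})

test_that("co-production follows the low-high-exhausted profile by stage", {
  ev <- gen_events(default_stage_model(), 30000, seed = 22)
  th <- estimate_thresholds(ev)
  f <- coproducer_frequency(ev, ev$truth_stage, th)
  pct <- setNames(f$pct_co, f$group)
  expect_lt(pct["P1"], pct["P2"])
  expect_lt(pct["P2"], pct["P3"])
  expect_lt(abs(pct["P3"] - pct["P4"]), 10)    # P3 and P4 comparable
  expect_gt(pct["P4"], pct["P5"])              # exhausted late stage
})

test_that("subset composition sums to one with off-path pooled", {
  classic <- c("T_EMRA", "T_EMRA", "T_EM", "T_EM", "T_EM")
  klr <- c("P5", "P5", "P3", "P4", "off_path(B1-G1+G56-F1-)")
  comp <- subset_composition(classic, klr)
  expect_equal(unname(comp$T_EMRA["P5"]), 1)
  expect_equal(sum(comp$T_EM), 1)
  expect_equal(unname(comp$T_EM["off_path"]), 1 / 3)
  expect_length(subset_composition(classic, klr, within = "T_N")$T_N, 0)
})

test_that("matched comparisons match the closed-form Friedman statistic", {
  # 3 donors x 3 groups, strictly ordered within every donor:
  # rank sums 3, 6, 9 -> chi-square = 6
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1.5, 2.5, 3.5))
  dimnames(m) <- list(paste0("d", 1:3), c("g1", "g2", "g3"))
  res <- compare_groups(m, matched = TRUE)
  expect_equal(res$omnibus$statistic, 6)
  expect_equal(res$omnibus$p, stats::pchisq(6, 2, lower.tail = FALSE))
  # Dunn z for the extreme pair: (3 - 1) / sqrt(k(k+1)/(6n)) with k=n=3
  z13 <- subset(res$pairwise, group_a == "g1" & group_b == "g3")$z
  expect_equal(abs(z13), 2 / sqrt(12 / 18), tolerance = 1e-12)

  # identical columns -> statistic 0, p = 1
  m0 <- matrix(rep(c(5, 7, 9), 3), 3, byrow = FALSE,
               dimnames = list(paste0("d", 1:3), c("g1", "g2", "g3")))
  expect_equal(compare_groups(m0)$omnibus$statistic, 0)
  expect_equal(compare_groups(m0)$omnibus$p, 1)

  # joint relabeling leaves p unchanged
  perm <- c(3, 1, 2)
  mp <- m[, perm]
  colnames(mp) <- paste0("g", 1:3)
  expect_equal(compare_groups(mp)$omnibus$p, res$omnibus$p)

  m[2, 3] <- NA
  expect_error(compare_groups(m), "d2 / group g3")
  expect_error(compare_groups(m[, 1:2]), ">= 3 groups")
})

test_that("unmatched comparisons use Kruskal-Wallis with tie-corrected Dunn", {
  vals <- list(a = c(1, 2, 3, 4), b = c(3, 5, 6, 7), c = c(8, 9, 10, 11))
  res <- compare_groups(vals, matched = FALSE)
  expect_equal(res$omnibus$p, stats::kruskal.test(vals)$p.value)
  # hand-computed Dunn z for pair (a, c): pooled ranks
  r <- rank(unlist(vals))
  rbar <- tapply(r, rep(names(vals), lengths(vals)), mean)
  N <- 12
  ties <- table(unlist(vals))
  sigma <- sqrt((N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
                (1 / 4 + 1 / 4))
  zac <- (rbar["a"] - rbar["c"]) / sigma
  got <- subset(res$pairwise, group_a == "a" & group_b == "c")$z
  expect_equal(got, unname(zac), tolerance = 1e-12)
})
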