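test_that("clonotype tables validate identity and counts", {
  tb <- make_clono(c(A = 3, B = 1))
  expect_s3_class(tb, "clonotype_table")
  expect_equal(sum(clone_proportions(tb)), 1)
  expect_error(make_clono(c(A = 3, A = 1)), "duplicated")
  expect_error(make_clono(c(A = 0)), "positive integers")
  expect_error(make_clono(c(A = 1.5)), "positive integers")
  expect_error(clonotype_table(data.frame(v_gene = "V")), "lacks column")
})

test_that("the Q30 read filter keeps the boundary read", {
  reads <- data.frame(read_id = paste0("r", 1:4),
                      v_gene = "TRBV9", j_gene = "TRBJ2-1",
                      cdr3_aa = c("CASSA", "CASSA", "CASSB", "CASSB"),
                      avg_quality = c(29.9, 30.0, 40, 12))
  f <- filter_reads(reads)
  expect_equal(f$report$n_input, 4)
  expect_equal(f$report$n_retained, 2)
  expect_equal(f$reads$read_id, c("r2", "r3"))
  all40 <- filter_reads(transform(reads, avg_quality = 40))
  expect_equal(all40$report$n_excluded, 0)
  tb <- clonotypes_from_reads(f$reads)
  expect_equal(sort(tb$count), c(1, 1))
})

test_that("FASTQ reads round-trip with mean qualities and clonotype names", {
  reads <- data.frame(read_id = paste0("r", 1:3),
                      v_gene = c("TRBV9", "TRBV9", "TRBV7"),
                      j_gene = "TRBJ2-1",
                      cdr3_aa = c("CASSA", "CASSB", "CASSC"),
                      avg_quality = c(29, 31, 40))
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq)
  back <- read_fastq_reads(fq)
  expect_equal(back$avg_quality, reads$avg_quality)
  expect_equal(back$cdr3_aa, reads$cdr3_aa)
  f <- filter_reads(fq)
  expect_equal(f$report$n_retained, 2)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1|V|J|C", "ACGT", "+", "IIII",
               "r2 broken", "ACGT", "+", "IIII"), bad)
  expect_error(read_fastq_reads(bad), "record 2")
})

test_that("top-clone selection is size-bounded and order-invariant", {
  set.seed(10)
  counts <- sample(1000, 500)          # distinct counts
  names(counts) <- sprintf("CASS%04dF", seq_along(counts))
  tb <- make_clono(counts)
  top <- top_clones(tb)
  expect_equal(nrow(top), 100)
  expect_equal(sort(top$count, decreasing = TRUE),
               unname(sort(counts, decreasing = TRUE)[1:100]))
  small <- top_clones(make_clono(counts[1:40]))
  expect_equal(nrow(small), 40)

  # ties spanning the boundary: deterministic, permutation-invariant
  tied <- c(stats::setNames(rep(5, 150), sprintf("CASSTIE%03dF", 1:150)),
            c(BIG1 = 50, BIG2 = 40))
  tt <- make_clono(tied)
  sel1 <- top_clones(tt)
  sel2 <- top_clones(make_clono(tied[sample(length(tied))]))
  expect_equal(sel1$cdr3_aa, sel2$cdr3_aa)
  expect_equal(nrow(sel1), 100)
})

test_that("Morisita-Horn matches hand values and vegan on random tables", {
  p <- make_clono(c(A = 3, B = 1))
  q <- make_clono(c(A = 1, B = 3))
  expect_equal(morisita_horn(p, q), 0.6)
  expect_equal(morisita_horn(p, p), 1)
  expect_equal(morisita_horn(p, make_clono(c(C = 2, D = 2))), 0)
  expect_equal(morisita_horn(p, q), morisita_horn(q, p))
  expect_error(morisita_horn(p, make_clono(c(A = 1))[0, ]), "empty")

  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    shared <- sprintf("CASSS%02dF", seq_len(n))
    x <- sample(50, n, replace = TRUE)
    y <- sample(50, n, replace = TRUE)
    y[sample(n, n %/% 3)] <- 0
    keep <- y > 0
    P <- make_clono(stats::setNames(x, shared))
    Q <- make_clono(stats::setNames(y[keep], shared[keep]))
    yy <- y
    veg <- 1 - vegan::vegdist(rbind(x, yy), method = "horn")[1]
    expect_equal(morisita_horn(P, Q), unname(veg), tolerance = 1e-10)
  }
})

test_that("Renyi profiles honour the limit cases and monotonicity", {
  uni <- make_clono(stats::setNames(rep(5, 4), c("A", "B", "C", "D")))
  expect_equal(renyi_profile(uni, 2)$H, log(4))
  expect_equal(renyi_profile(uni, c(0, 1, 7, Inf))$H, rep(log(4), 4))
  one <- make_clono(c(A = 10))
  expect_equal(renyi_profile(one)$H, rep(0, 11))
  expect_error(renyi_profile(uni, -1), "non-negative")

  set.seed(12)
  for (i in 1:10) {
    counts <- sample(200, sample(3:40, 1), replace = TRUE)
    names(counts) <- sprintf("CASSR%02dF", seq_along(counts))
    tb <- make_clono(counts)
    pr <- renyi_profile(tb)
    expect_true(all(diff(pr$H) <= 1e-10))
    expect_equal(pr$H[pr$alpha == 0], log(nrow(tb)))
    p <- clone_proportions(tb)
    expect_equal(pr$H[pr$alpha == 1], -sum(p * log(p)))
    expect_equal(pr$H[pr$alpha == 2], log(1 / sum(p^2)))
    expect_equal(pr$H[is.infinite(pr$alpha)], -log(max(p)))
    for (a in c(0.5, 2, 8)) {
      expect_equal(pr$H[pr$alpha == a], renyi_oracle(counts, a))
    }
  }

  skip_if_not_installed("vegan")
  counts <- c(A = 40, B = 10, C = 5, D = 1)
  got <- renyi_profile(make_clono(counts), c(0, 0.5, 1, 2, 16, Inf))$H
  veg <- as.numeric(vegan::renyi(counts / sum(counts),
                                 scales = c(0, 0.5, 1, 2, 16, Inf)))
  expect_equal(got, veg, tolerance = 1e-8)
})

test_that("profile ranking detects dominance, ties and crossings", {
  a <- renyi_profile(make_clono(stats::setNames(rep(4, 8), LETTERS[1:8])))
  b <- renyi_profile(make_clono(c(A = 50, B = 3, C = 2, D = 1)))
  r <- compare_profiles(list(hi = a, lo = b))
  expect_equal(r$relation, "more_diverse")
  expect_equal(compare_profiles(list(x = a, y = a))$relation, "tied")
  # crossing: richer but more skewed vs poorer but even
  skew <- renyi_profile(make_clono(
    c(stats::setNames(rep(1, 19), paste0("S", 1:19)), BIG = 300)))
  even <- renyi_profile(make_clono(stats::setNames(rep(5, 6), paste0("E", 1:6))))
  expect_true(skew$H[skew$alpha == 0] > even$H[even$alpha == 0])
  expect_true(max(skew$H) > max(even$H) && min(skew$H) < min(even$H))
  expect_equal(compare_profiles(list(s = skew, e = even))$relation,
               "not_rankable")
  short <- renyi_profile(make_clono(c(A = 1, B = 1)), c(0, 1, 2))
  expect_error(compare_profiles(list(a, short)), "common alpha grid")
})

test_that("dominant-clone sharing counts identities in targets", {
  src <- make_clono(stats::setNames(51:60, paste0("D", 1:10)))
  expect_equal(unname(shared_dominant_clones(src, list(self = src),
                                             top_k = 10)), 10)
  disj <- make_clono(stats::setNames(rep(3, 5), paste0("X", 1:5)))
  expect_equal(unname(shared_dominant_clones(src, list(d = disj), 10)), 0)

  # binomial oracle on generated repertoires: only P5 seeds earlier stages
  m <- default_repertoire_model()
  m$sharing[] <- 0
  m$sharing["P5", "P2"] <- 0.3
  m$n_clones <- c(P1 = 500, P2 = 400, P3 = 300, P4 = 200, P5 = 100)
  m$read_depth <- stats::setNames(rep(5000, 5), names(m$n_clones))
  reps <- gen_repertoires(m, seed = 13)
  got <- shared_dominant_clones(reps$P5, reps["P2"], top_k = 100)
  expect_lt(abs(got[["P2"]] - 30), 3 * sqrt(100 * 0.3 * 0.7))
})

test_that("clonal space fractions follow the rank bins", {
  expect_equal(unname(clonal_space(make_clono(c(A = 7)),
                                   list(c(1, 10)))), 1)
  uni <- make_clono(stats::setNames(rep(2, 100), sprintf("U%03d", 1:100)))
  cs <- clonal_space(uni, list(c(1, 10), c(11, 100)))
  expect_equal(unname(cs), c(0.1, 0.9))
  expect_error(clonal_space(uni, list(c(1, 10), c(5, 20))),
               "non-overlapping")

  # a steeper expansion law concentrates more mass in the top bin
  share_top <- function(gamma) {
    counts <- round(1000 * seq_len(200)^(-gamma)) + 1
    names(counts) <- sprintf("PL%03d", seq_along(counts))
    clonal_space(make_clono(counts), list(c(1, 10), c(11, Inf)))[1]
  }
  expect_lt(share_top(0.3), share_top(1.5))
})

test_that("record order never changes top-clone diversity results", {
  reps <- gen_repertoires(seed = 14)
  tb <- reps$P3
  shuf <- clonotype_table(tb[sample(nrow(tb)), ], population = "P3")
  expect_equal(renyi_profile(top_clones(tb))$H,
               renyi_profile(top_clones(shuf))$H)
})
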