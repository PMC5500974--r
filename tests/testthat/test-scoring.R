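test_that("tabulate_counts counts exactly and validates indices", {
  d <- tiny_separating_dataset()
  ct <- tabulate_counts(d, 1)
  expect_identical(unname(ct$counts[1, "control"]), 2L)
  expect_identical(unname(ct$counts[3, "case"]), 2L)
  expect_identical(sum(ct$counts), 4L)
  expect_identical(ct$row_sums, rowSums(ct$counts))
  expect_error(tabulate_counts(d, c(1, 1)), "distinct")
  expect_error(tabulate_counts(d, 5), "range")
})

test_that("tabulate_counts matches a naive per-sample loop on random pairs", {
  d <- simulate_dataset(builtin_model(1), 80, 80, 12, seed = 3)
  naive <- function(d, snps) {
    K <- length(snps)
    out <- matrix(0L, 3^K, 2)
    for (i in seq_len(nrow(d$genotypes))) {
      row <- 1L
      for (s in snps) row <- (row - 1L) * 3L + d$genotypes[i, s] + 1L
      out[row, d$phenotype[i] + 1L] <- out[row, d$phenotype[i] + 1L] + 1L
    }
    out
  }
  set.seed(5)
  for (rep in 1:10) {
    snps <- sort(sample.int(12, 2))
    expect_identical(unname(tabulate_counts(d, snps)$counts), naive(d, snps))
  }
  # and a 3-way combination
  snps <- c(2L, 5L, 9L)
  expect_identical(unname(tabulate_counts(d, snps)$counts), naive(d, snps))
})

test_that("mutual information reproduces hand-derived values", {
  # perfectly separating genotype: MI = H(Y) = ln 2
  expect_equal(mutual_information(tabulate_counts(tiny_separating_dataset(), 1)),
               log(2), tolerance = 1e-12)
  # constant phenotype: MI = 0 exactly
  d0 <- genotype_dataset(matrix(c(0L, 1L, 2L, 1L), ncol = 1), rep(0L, 4))
  expect_identical(mutual_information(tabulate_counts(d0, 1)), 0)
  # hand-computed 2x2-style example: genotypes (0,0,0,2), phenotype (0,1,0,1)
  # p(s): (3/4, 1/4); p(y): (1/2, 1/2); joint: (2/4, 1/4, 0, 1/4)
  ct <- counts_1snp(matrix(c(2L, 0L, 0L, 1L, 0L, 1L), ncol = 2))
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mutual_information(ct),
               h(c(3, 1) / 4) + h(c(2, 2) / 4) - h(c(2, 1, 1) / 4),
               tolerance = 1e-12)
})

test_that("mutual information respects its information bounds", {
  set.seed(11)
  for (rep in 1:50) {
    ct <- random_counts(rows = sample(3:9, 1), n = sample(5:60, 1))
    mi <- mutual_information(ct)
    h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
    hs <- h(ct$row_sums[ct$row_sums > 0] / ct$n)
    hy <- h(colSums(ct$counts)[colSums(ct$counts) > 0] / ct$n)
    expect_gte(mi, 0)
    expect_lte(mi, min(hs, hy) + 1e-12)
  }
})

test_that("mutual information is invariant to genotype relabeling and SNP order", {
  d <- simulate_dataset(builtin_model(3), 100, 100, 6, seed = 21)
  mi_a <- mutual_information(tabulate_counts(d, c(2, 5)))
  mi_b <- mutual_information(tabulate_counts(d, c(5, 2)))
  expect_identical(mi_a, mi_b)
  # relabel genotype classes of SNP 2 (2 <-> 0): rows permute, MI unchanged
  d2 <- d
  d2$genotypes[, 2] <- 2L - d2$genotypes[, 2]
  expect_equal(mutual_information(tabulate_counts(d2, c(2, 5))), mi_a,
               tolerance = 1e-12)
})

test_that("K2 log-score reproduces exact factorial values", {
  # one occupied row, r = 2 split 1/1: K2 factor 1!1!/3! = 1/6
  expect_equal(k2_log(counts_1snp(matrix(c(1L, 0L, 0L, 1L, 0L, 0L), ncol = 2))),
               log(6), tolerance = 1e-12)
  # one occupied row, r = 2 split 2/0: 2!0!/3! = 1/3
  expect_equal(k2_log(counts_1snp(matrix(c(2L, 0L, 0L, 0L, 0L, 0L), ncol = 2))),
               log(3), tolerance = 1e-12)
  # all-zero table scores exactly 0
  expect_identical(k2_log(counts_1snp(matrix(0L, 3, 2))), 0)
})

test_that("K2 log-score agrees with the exact-arithmetic oracle on n <= 20", {
  set.seed(17)
  worst <- 0
  for (rep in 1:10000) {
    ct <- random_counts(rows = sample(c(3L, 9L), 1), n = sample.int(20, 1))
    worst <- max(worst, abs(k2_log(ct) - k2_log_oracle(ct)))
  }
  expect_lt(worst, 1e-9)
})

test_that("Svalue composes MI and K2 as hand-derived", {
  ct <- tabulate_counts(tiny_separating_dataset(), 1)
  # two occupied rows each r=2 split 2/0 -> K2 log = 2 ln 3; MI = ln 2
  expect_equal(svalue(ct), log(2) / (2 * log(3)), tolerance = 1e-12)
  # zero MI forces Svalue 0 regardless of the denominator
  d0 <- genotype_dataset(matrix(c(0L, 1L, 2L, 1L), ncol = 1), rep(0L, 4))
  expect_identical(svalue(tabulate_counts(d0, 1)), 0)
})

test_that("scores are pure functions of the contingency counts", {
  d <- simulate_dataset(builtin_model(1), 60, 60, 8, seed = 13)
  ct <- tabulate_counts(d, c(3, 7))
  rebuilt <- contingency_counts(ct$counts)
  expect_identical(mutual_information(ct), mutual_information(rebuilt))
  expect_identical(k2_log(ct), k2_log(rebuilt))
  expect_identical(svalue(ct), svalue(rebuilt))
})

test_that("the true pair outscores (true, background) pairs on Model 1 data", {
  d <- simulate_dataset(builtin_model(1), 2000, 2000, 20, seed = 77)
  tr <- d$truth[[1]]
  s_true <- svalue(tabulate_counts(d, tr))
  for (bg in setdiff(seq_len(20), tr)) {
    expect_gt(s_true, svalue(tabulate_counts(d, c(tr[1], bg))))
    expect_gt(s_true, svalue(tabulate_counts(d, c(tr[2], bg))))
  }
})

test_that("chi-square test matches hand evaluation and conventions", {
  # identical case/control distributions: statistic 0, p 1
  ct <- counts_1snp(matrix(c(5L, 5L, 5L, 5L, 5L, 5L), ncol = 2))
  res <- chi2_association(ct)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # diagonal 2x2 table ((10,0),(0,10)): statistic 20, df 1
  ct <- contingency_counts(matrix(c(10L, 0L, 0L, 10L), ncol = 2))
  res <- chi2_association(ct)
  expect_equal(res$statistic, 20)
  expect_identical(res$df, 1L)
  # single occupied row: p 1 by convention
  ct <- counts_1snp(matrix(c(4L, 0L, 0L, 3L, 0L, 0L), ncol = 2))
  expect_equal(chi2_association(ct)$p_value, 1)
})

test_that("chi-square p-values are null-uniform over simulated replicates", {
  set.seed(29)
  pvals <- replicate(500, {
    g <- rbinom(200, 2, 0.3)
    y <- rbinom(200, 1, 0.5)
    d <- genotype_dataset(matrix(as.integer(g), ncol = 1), as.integer(y))
    chi2_association(tabulate_counts(d, 1))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("deterministic mapping attains the MI maximum over same-margin tables", {
  # brute force over all 3x2 tables with row margins (2,2,0) and n=4:
  # the separating table must maximize MI and Svalue
  best_mi <- -1; best_sv <- -1
  for (a in 0:2) for (b in 0:2) {
    tab <- matrix(c(a, b, 0L, 2L - a, 2L - b, 0L), ncol = 2)
    ct <- contingency_counts(tab)
    best_mi <- max(best_mi, mutual_information(ct))
    best_sv <- max(best_sv, svalue(ct))
  }
  sep <- contingency_counts(matrix(c(2L, 0L, 0L, 0L, 2L, 0L), ncol = 2))
  expect_equal(mutual_information(sep), best_mi, tolerance = 1e-12)
  expect_equal(mutual_information(sep), log(2), tolerance = 1e-12)  # = H(Y)
  expect_equal(svalue(sep), best_sv, tolerance = 1e-12)
})
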