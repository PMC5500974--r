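# Small shared fixtures, all built in code.

# a 3x3 penetrance matrix with constant risk
constant_model <- function(c = 0.1, maf = c(0.3, 0.2)) {
  epistasis_model(maf, matrix(c, 3, 3), label = sprintf("constant %.2f", c))
}

# four samples, one SNP, genotypes perfectly separating the phenotype:
# MI = ln 2, K2 log = 2 ln 3
tiny_separating_dataset <- function() {
  genotype_dataset(matrix(c(0L, 0L, 2L, 2L), ncol = 1),
                   c(0L, 0L, 1L, 1L))
}

# contingency_counts for a single-SNP table given as a 3x2 matrix
counts_1snp <- function(mat) contingency_counts(mat)

# random contingency table over r rows with n total samples
random_counts <- function(rows, n) {
  cells <- sample.int(rows * 2L, n, replace = TRUE)
  contingency_counts(matrix(tabulate(cells, rows * 2L), ncol = 2L))
}

# exact-arithmetic oracle for the K2 log-score: each occupied row's
# marginal-likelihood factor is r_i1! r_i2! / (r_i + 1)!, which equals
# 1 / ((r_i + 1) * choose(r_i, r_i1)) with exact integer choose() for
# the table sizes used in tests; summed in log space.
k2_log_oracle <- function(counts) {
  tab <- counts$counts
  r <- rowSums(tab)
  sum(log((r + 1) * choose(r, tab[, 1])))
}
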