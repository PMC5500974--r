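#' Contingency counts for a SNP combination against the phenotype
#'
#' Cross-tabulates the joint genotypes of a K-SNP combination against the
#' binary phenotype.  Rows follow the canonical cell order: mixed-radix
#' expansion of the genotype codes with the last SNP fastest, so for K = 2
#' row `i` holds genotypes `(g1, g2)` with `i = 1 + 3*g1 + g2`.
#'
#' @param dataset a [genotype_dataset()].
#' @param snps integer vector of K distinct SNP column indices.
#' @return an object of class `contingency_counts`: list with `counts`
#'   (3^K x 2 integer matrix, columns control/case), `row_sums`, `n` and
#'   the sorted `snps`.
#' @export
tabulate_counts <- function(dataset, snps) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  snps <- as.integer(snps)
  if (anyNA(snps) || any(snps < 1L | snps > ncol(dataset$genotypes)))
    stop("SNP indices out of range")
  if (anyDuplicated(snps)) stop("SNP indices must be distinct")
  snps <- sort(snps)
  cnt <- count_cells(dataset$genotypes, dataset$phenotype, snps)
  contingency_counts(matrix(cnt, ncol = 2L, byrow = TRUE,
                            dimnames = list(NULL, c("control", "case"))),
                     snps = snps)
}

#' @rdname tabulate_counts
#' @param counts a 3^K x 2 matrix of non-negative counts (columns
#'   control/case) in canonical row order.
#' @export
contingency_counts <- function(counts, snps = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (ncol(counts) != 2L) stop("'counts' must have two columns")
  if (any(counts < 0L)) stop("counts must be non-negative")
  structure(list(counts = counts, row_sums = rowSums(counts),
                 n = sum(counts), snps = snps),
            class = "contingency_counts")
}

## Interleaved cell counts (control, case per genotype row) via one tabulate()
## pass: index = 2 * (mixed-radix genotype row) + phenotype + 1.
count_cells <- function(G, y, snps) {
  row <- 0L
  for (s in snps) row <- row * 3L + G[, s]
  tabulate(row * 2L + y + 1L, nbins = 2L * 3L^length(snps))
}

#' Mutual information between a SNP combination and the phenotype
#'
#' Plug-in estimate MI(S; Y) = H(S) + H(Y) - H(S, Y) from the contingency
#' counts, in nats (natural logarithm), with the convention 0 log 0 = 0.
#' Larger values indicate stronger association.
#'
#' @param counts a [contingency_counts()] (or the output of
#'   [tabulate_counts()]).
#' @return mutual information in nats, >= 0.
#' @export
mutual_information <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (counts$n == 0L) stop("empty contingency table")
  mi_from_counts(as.vector(t(counts$counts)), counts$n)
}

## cnt is the interleaved vector (control, case alternating per row).
mi_from_counts <- function(cnt, n) {
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x / n * log(x / n))
  }
  rows <- cnt[c(TRUE, FALSE)] + cnt[c(FALSE, TRUE)]
  cols <- c(sum(cnt[c(TRUE, FALSE)]), sum(cnt[c(FALSE, TRUE)]))
  mi <- ent(rows) + ent(cols) - ent(cnt)
  max(mi, 0)  # clamp float round-off on independent tables
}

#' Logarithmic K2 score of a SNP combination
#'
#' The negated log of the K2 Bayesian-network marginal likelihood of the
#' phenotype node with the SNP combination as parents (uniform Dirichlet
#' prior):
#' `sum_i ( sum_{b=1}^{r_i + 1} log b  -  sum_j sum_{d=1}^{r_ij} log d )`,
#' computed via log-gamma.  Natural logarithm; a *lower* score means a
#' stronger association.  Empty rows contribute zero, and an all-zero table
#' scores exactly 0.
#'
#' @inheritParams mutual_information
#' @return the logarithmic K2 score, >= 0.
#' @export
k2_log <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  k2_from_counts(as.vector(t(counts$counts)))
}

k2_from_counts <- function(cnt) {
  rows <- cnt[c(TRUE, FALSE)] + cnt[c(FALSE, TRUE)]
  sum(lgamma(rows + 2)) - sum(lgamma(cnt + 1))
}

#' Svalue fitness of a SNP combination
#'
#' The ratio of the mutual information to the logarithmic K2 score.  Both
#' numerator and denominator grade association strength (higher MI, lower K2
#' log-score), so higher Svalue means stronger association.  If the K2
#' log-score is below `1e-12` (only possible for near-empty tables) the
#' Svalue is defined as 0 when MI = 0 and MI / 1e-12 otherwise, preserving
#' ordering on degenerate inputs.
#'
#' @inheritParams mutual_information
#' @return the Svalue, >= 0.
#' @export
svalue <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (counts$n == 0L) return(0)
  cnt <- as.vector(t(counts$counts))
  svalue_from(mi_from_counts(cnt, counts$n), k2_from_counts(cnt))
}

svalue_from <- function(mi, k2) {
  if (k2 < 1e-12) {
    if (mi == 0) 0 else mi / 1e-12
  } else mi / k2
}

#' Pearson chi-square association test on a genotype-by-phenotype table
#'
#' Computes the Pearson statistic over the *occupied* genotype rows only
#' (rows with zero samples are dropped, so expected counts are always
#' defined), with degrees of freedom (number of occupied rows - 1) x 1.
#' A table with a single occupied row returns statistic 0 and p = 1 by
#' convention.
#'
#' @inheritParams mutual_information
#' @return list with `statistic`, `df` and `p_value` (upper tail).
#' @export
chi2_association <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (counts$n == 0L) stop("empty contingency table")
  tab <- counts$counts[counts$row_sums > 0L, , drop = FALSE]
  df <- (nrow(tab) - 1L) * 1L
  if (df == 0L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- expected > 0
  stat <- sum((tab[keep] - expected[keep])^2 / expected[keep])
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Score one SNP combination
#'
#' Convenience wrapper producing the full score breakdown used in search
#' results and report files.
#'
#' @param dataset a [genotype_dataset()].
#' @param snps integer vector of K distinct SNP column indices.
#' @param chi2 also compute the chi-square test (default TRUE).
#' @return an object of class `combination_score`: list with `snps` (sorted),
#'   `mi`, `k2_log`, `svalue` and (optionally) `chi2_stat`, `chi2_p`.
#' @export
score_combination <- function(dataset, snps, chi2 = TRUE) {
  counts <- tabulate_counts(dataset, snps)
  cnt <- as.vector(t(counts$counts))
  mi <- mi_from_counts(cnt, counts$n)
  k2 <- k2_from_counts(cnt)
  out <- list(snps = counts$snps, mi = mi, k2_log = k2,
              svalue = svalue_from(mi, k2))
  if (chi2) {
    ct <- chi2_association(counts)
    out$chi2_stat <- ct$statistic
    out$chi2_p <- ct$p_value
  }
  structure(out, class = "combination_score")
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("<combination_score> SNPs (%s): Svalue %.6g (MI %.6g / K2log %.6g)",
              paste(x$snps, collapse = ", "), x$svalue, x$mi, x$k2_log))
  if (!is.null(x$chi2_p))
    cat(sprintf(", chi-square p %.3g", x$chi2_p))
  cat("\n")
  invisible(x)
}
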