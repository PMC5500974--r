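#' Construct a case-control genotype dataset
#'
#' The canonical container for a case-control study: an integer genotype
#' matrix coded 0 = homozygous common, 1 = heterozygous, 2 = homozygous
#' minor, and a binary phenotype (0 = control, 1 = case).
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns, values
#'   in {0, 1, 2}.
#' @param phenotype integer vector of 0/1, length `nrow(genotypes)`.
#' @param snp_names character vector of SNP identifiers, length
#'   `ncol(genotypes)`; defaults to `SNP1..SNPp`.
#' @param truth optional list of integer vectors: ground-truth disease SNP
#'   column indices (1-based), one vector per embedded interaction.
#' @param background_maf optional numeric vector of the simulated per-SNP
#'   minor allele frequencies (NA at disease SNP positions).
#'
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_names = NULL,
                             truth = NULL, background_maf = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (nrow(genotypes) != length(phenotype))
    stop("phenotype length must equal the number of genotype rows")
  if (length(genotypes) && !all(genotypes %in% 0:2))
    stop("genotype values must be 0, 1 or 2")
  if (length(phenotype) && !all(phenotype %in% 0:1))
    stop("phenotype values must be 0 (control) or 1 (case)")
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  snp_names <- as.character(snp_names)
  if (length(snp_names) != ncol(genotypes))
    stop("snp_names length must equal the number of SNPs")
  if (!is.null(truth)) {
    truth <- lapply(truth, function(v) sort(as.integer(v)))
    bad <- vapply(truth, function(v)
      any(v < 1L | v > ncol(genotypes)) || anyDuplicated(v) > 0L, logical(1))
    if (any(bad)) stop("truth indices out of range or duplicated")
  }
  colnames(genotypes) <- snp_names
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_names = snp_names, truth = truth,
                 background_maf = background_maf),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples (%d cases / %d controls), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (!is.null(x$truth))
    cat("  truth:", paste(vapply(x$truth, function(v)
      paste0("(", paste(x$snp_names[v], collapse = ", "), ")"),
      character(1)), collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Simulate a case-control dataset with one embedded interaction
#'
#' Disease-SNP genotypes are drawn exactly from
#' [genotype_distribution_given_status()] according to each sample's
#' case/control status (exact Bayes inversion of the penetrance model, not
#' rejection sampling).  Background SNPs are independent of the phenotype and
#' follow Hardy-Weinberg genotype frequencies with per-SNP minor allele
#' frequencies drawn uniformly from `background_maf_range`.  The disease SNPs
#' are placed at random column positions, recorded in the `truth` field.
#'
#' @param model an [epistasis_model()].
#' @param n_cases,n_controls sample counts (default 2000 each, the customary
#'   benchmark design).
#' @param n_snps total number of SNPs, at least K (default 100).
#' @param background_maf_range interval the background MAFs are drawn from
#'   (default `c(0.05, 0.5)`).
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   bit for bit.
#' @return a [genotype_dataset()] with controls first (phenotype 0) then
#'   cases (phenotype 1).
#' @export
#' @examples
#' d <- simulate_dataset(builtin_model(1), n_cases = 100, n_controls = 100,
#'                       n_snps = 20, seed = 1)
#' d$truth
simulate_dataset <- function(model, n_cases = 2000, n_controls = 2000,
                             n_snps = 100,
                             background_maf_range = c(0.05, 0.5),
                             seed = NULL) {
  stopifnot(inherits(model, "epistasis_model"))
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  n_snps <- as.integer(n_snps)
  K <- length(model$maf)
  if (n_cases < 1L || n_controls < 1L) stop("sample counts must be positive")
  if (n_snps < K) stop("'n_snps' must be at least ", K)
  if (length(background_maf_range) != 2L ||
      background_maf_range[1] > background_maf_range[2] ||
      background_maf_range[1] <= 0 || background_maf_range[2] > 0.5)
    stop("'background_maf_range' must be an interval within (0, 0.5]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  # conditional cell distributions (errors here if the model is degenerate)
  p_case <- flatten_cells(genotype_distribution_given_status(model, 1L))
  p_ctrl <- flatten_cells(genotype_distribution_given_status(model, 0L))

  n <- n_cases + n_controls
  phenotype <- rep(c(0L, 1L), c(n_controls, n_cases))
  pos <- sort(sample.int(n_snps, K))
  maf_bg <- stats::runif(n_snps, background_maf_range[1], background_maf_range[2])

  # background: HWE genotypes = minor-allele counts out of 2 draws
  genotypes <- matrix(stats::rbinom(n * n_snps, 2L, rep(maf_bg, each = n)),
                      nrow = n, ncol = n_snps)
  storage.mode(genotypes) <- "integer"

  cells <- integer(n)
  cells[phenotype == 0L] <- sample.int(3L^K, n_controls, replace = TRUE,
                                       prob = p_ctrl)
  cells[phenotype == 1L] <- sample.int(3L^K, n_cases, replace = TRUE,
                                       prob = p_case)
  genotypes[, pos] <- decode_cells(cells, K)
  maf_bg[pos] <- NA_real_

  genotype_dataset(genotypes, phenotype, truth = list(pos),
                   background_maf = maf_bg)
}

#' Simulate an unascertained cohort from a penetrance model
#'
#' Draws the disease-SNP genotypes of `n` individuals from the joint
#' Hardy-Weinberg distribution and assigns disease status by a Bernoulli draw
#' from the penetrance of each genotype.  Unlike [simulate_dataset()] there is
#' no case/control ascertainment: the empirical case fraction estimates the
#' model prevalence and the per-cell case fraction estimates the penetrance.
#'
#' @inheritParams simulate_dataset
#' @param n cohort size.
#' @return a [genotype_dataset()] with K SNP columns and no background SNPs.
#' @export
simulate_cohort <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "epistasis_model"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- length(model$maf)
  p_joint <- flatten_cells(joint_genotype_freq(model))
  pen <- flatten_cells(model$penetrance)
  cells <- sample.int(3L^K, n, replace = TRUE, prob = p_joint)
  phenotype <- stats::rbinom(n, 1L, pen[cells])
  genotype_dataset(decode_cells(cells, K), phenotype,
                   truth = list(seq_len(K)))
}
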