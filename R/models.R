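#' Define a K-locus penetrance disease model
#'
#' An epistasis model couples per-SNP minor allele frequencies (MAFs) with a
#' penetrance table: the probability of disease for each joint genotype of the
#' K disease SNPs.  Genotypes along every axis are ordered homozygous common,
#' heterozygous, homozygous minor.
#'
#' @param maf numeric vector of minor allele frequencies, one per disease SNP,
#'   each in (0, 0.5].
#' @param penetrance numeric array (or matrix for K = 2) with dimensions
#'   `rep(3, K)`; entry `[g1+1, ..., gK+1]` is P(disease | genotypes g), where
#'   g counts minor alleles (0, 1 or 2).  All entries must lie in [0, 1].
#' @param label free-text model name.
#'
#' @return An object of class `epistasis_model`.
#' @seealso [builtin_models()], [model_prevalence()], [simulate_dataset()]
#' @export
#' @examples
#' # a null model: disease risk 0.1 regardless of genotype
#' m <- epistasis_model(c(0.3, 0.2), matrix(0.1, 3, 3), "null")
#' model_prevalence(m)
epistasis_model <- function(maf, penetrance, label = "custom") {
  maf <- as.numeric(maf)
  if (length(maf) < 1L || anyNA(maf) || any(maf <= 0 | maf > 0.5))
    stop("'maf' entries must lie in (0, 0.5]")
  K <- length(maf)
  if (!is.array(penetrance) || !identical(dim(penetrance), rep(3L, K)))
    stop("'penetrance' must be an array with dimensions rep(3, ", K, ")")
  penetrance <- array(as.numeric(penetrance), dim = rep(3L, K))
  if (anyNA(penetrance) || any(penetrance < 0 | penetrance > 1))
    stop("'penetrance' entries must lie in [0, 1]")
  structure(list(maf = maf, penetrance = penetrance,
                 label = as.character(label)[1L]),
            class = "epistasis_model")
}

#' @export
print.epistasis_model <- function(x, ...) {
  K <- length(x$maf)
  cat(sprintf("<epistasis_model> %s (%d-locus)\n", x$label, K))
  cat("  MAF:       ", paste(format(x$maf), collapse = ", "), "\n")
  cat("  prevalence:", format(model_prevalence(x)), "\n")
  if (K == 2L) {
    tab <- matrix(x$penetrance, 3, 3,
                  dimnames = list(A = c("AA", "Aa", "aa"),
                                  B = c("BB", "Bb", "bb")))
    print(tab)
  }
  invisible(x)
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param p minor allele frequency.
#' @return numeric vector `c((1-p)^2, 2p(1-p), p^2)` for the homozygous
#'   common, heterozygous and homozygous minor genotypes.
#' @export
hwe_genotype_freq <- function(p) {
  if (any(p < 0 | p > 1)) stop("allele frequency must lie in [0, 1]")
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

## Joint HWE genotype probability array for the model's disease SNPs,
## same layout as the penetrance table.
joint_genotype_freq <- function(model) {
  freqs <- lapply(model$maf, hwe_genotype_freq)
  Reduce(function(a, b) outer(a, b), freqs)
}

#' Population disease prevalence implied by a model
#'
#' Sums penetrance over the joint Hardy-Weinberg genotype distribution of the
#' disease SNPs: prevalence = sum_g P(g) * P(disease | g).
#'
#' @param model an [epistasis_model()].
#' @return the prevalence, a probability.
#' @export
#' @examples
#' model_prevalence(builtin_model(1))  # ~0.100
model_prevalence <- function(model) {
  stopifnot(inherits(model, "epistasis_model"))
  sum(joint_genotype_freq(model) * model$penetrance)
}

#' Genotype distribution of the disease SNPs given case/control status
#'
#' Bayes inversion of the penetrance model: P(g | status) is proportional to
#' P(g) * penetrance(g) for cases and P(g) * (1 - penetrance(g)) for controls,
#' with P(g) the joint Hardy-Weinberg distribution.  This is the exact
#' conditional distribution the simulator samples from.
#'
#' @param model an [epistasis_model()].
#' @param status 1 (case) or 0 (control).
#' @return numeric array with dimensions `rep(3, K)` summing to 1, laid out
#'   like the penetrance table.
#' @export
genotype_distribution_given_status <- function(model, status) {
  stopifnot(inherits(model, "epistasis_model"))
  status <- as.integer(status)
  if (!status %in% c(0L, 1L)) stop("'status' must be 0 (control) or 1 (case)")
  prev <- model_prevalence(model)
  if (prev <= 0 && status == 1L)
    stop("model prevalence is 0: cannot sample case genotypes")
  if (prev >= 1 && status == 0L)
    stop("model prevalence is 1: cannot sample control genotypes")
  joint <- joint_genotype_freq(model)
  w <- if (status == 1L) joint * model$penetrance
       else joint * (1 - model$penetrance)
  w / sum(w)
}

## Flatten an array over genotype combinations into the canonical cell order:
## mixed-radix expansion of the genotype codes with the LAST SNP fastest,
## i.e. cell index = 1 + sum_k g_k * 3^(K-k).
flatten_cells <- function(a) {
  d <- dim(a)
  if (is.null(d)) return(as.vector(a))
  as.vector(aperm(a, rev(seq_along(d))))
}

## Decode canonical cell indices (1-based) into a matrix of genotype codes,
## one column per SNP, first SNP most significant.
decode_cells <- function(cells, K) {
  g <- matrix(0L, length(cells), K)
  r <- cells - 1L
  for (k in K:1) {
    g[, k] <- as.integer(r %% 3L)
    r <- r %/% 3L
  }
  g
}

#' Benchmark two-locus disease models
#'
#' Five widely used two-SNP benchmark penetrance models.  Models 1 and 2
#' display marginal effects in addition to the interaction (ME models);
#' Models 3-5 display interaction effects only (NME models).  For Models 1, 3
#' and 4 the prevalence implied by Hardy-Weinberg genotype frequencies matches
#' the commonly quoted values (0.100, 0.300, 0.171).  The customary printed
#' tables for Models 2 and 5 are internally inconsistent (their quoted
#' prevalences, 0.050 and 0.010, do not follow from the penetrance entries);
#' the penetrance tables are taken as authoritative here.
#'
#' @return `builtin_models()`: a named list of five [epistasis_model()]
#'   objects.  `builtin_model(i)`: the i-th of them.
#' @export
builtin_models <- function() {
  list(
    model1 = epistasis_model(
      c(0.300, 0.200),
      matrix(c(0.087, 0.087, 0.087,
               0.087, 0.146, 0.190,
               0.087, 0.190, 0.247), 3, 3, byrow = TRUE),
      "Model 1"),
    model2 = epistasis_model(
      c(0.400, 0.400),
      matrix(c(0.042, 0.042, 0.042,
               0.240, 0.270, 0.420,
               0.240, 0.440, 0.090), 3, 3, byrow = TRUE),
      "Model 2"),
    model3 = epistasis_model(
      c(0.500, 0.500),
      matrix(c(0.470, 0.230, 0.270,
               0.240, 0.270, 0.420,
               0.240, 0.440, 0.090), 3, 3, byrow = TRUE),
      "Model 3"),
    model4 = epistasis_model(
      c(0.400, 0.400),
      matrix(c(0.068, 0.299, 0.017,
               0.289, 0.044, 0.285,
               0.048, 0.262, 0.174), 3, 3, byrow = TRUE),
      "Model 4"),
    model5 = epistasis_model(
      c(0.500, 0.500),
      matrix(c(0.000, 0.000, 0.100,
               0.000, 0.050, 0.000,
               0.100, 0.000, 0.000), 3, 3, byrow = TRUE),
      "Model 5")
  )
}

#' @rdname builtin_models
#' @param i model number, 1 to 5.
#' @export
builtin_model <- function(i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > 5L) stop("'i' must be 1..5")
  builtin_models()[[i]]
}

#' Read a disease model from a YAML file
#'
#' The file must contain `maf` (list of K frequencies) and `penetrance`
#' (a list of 3 rows of 3 values for K = 2, or a flat list of 3^K values in
#' canonical cell order for general K), and may contain `label`.
#'
#' @param path file path.
#' @return an [epistasis_model()].
#' @export
read_model_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$maf) || is.null(cfg$penetrance))
    stop("model file must define 'maf' and 'penetrance'")
  maf <- as.numeric(unlist(cfg$maf))
  K <- length(maf)
  pv <- unlist(cfg$penetrance)
  if (length(pv) != 3^K)
    stop("penetrance must have ", 3^K, " entries for ", K, " SNPs")
  if (K == 2L && is.list(cfg$penetrance) && length(cfg$penetrance) == 3L) {
    pen <- matrix(pv, 3, 3, byrow = TRUE)  # rows are first-SNP genotypes
  } else {
    # flat vector in canonical order, last SNP fastest
    pen <- aperm(array(pv, rep(3L, K)), rev(seq_len(K)))
  }
  epistasis_model(maf, array(pen, rep(3L, K)),
                  label = if (is.null(cfg$label)) basename(path) else cfg$label)
}
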