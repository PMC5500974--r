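#' Read a case-control genotype file
#'
#' Parses the delimited case-control dialect used by BOOST/BEAM-style tools:
#' a header row of SNP names with a final `Class` column, then one row per
#' sample holding the genotype codes and the 0/1 phenotype.  Genotypes may be
#' coded `{0,1,2}` or `{1,2,3}` (both meaning homozygous common,
#' heterozygous, homozygous minor); the coding is auto-detected from the
#' values present or forced with `dialect`.  The delimiter (tab or comma) is
#' auto-detected from the header unless `sep` is given.  If a sidecar
#' metadata file `<path>.meta.json` exists, ground-truth indices recorded by
#' [write_genotypes()] are restored.  Missing genotypes are not supported:
#' any value outside the coding is a parse error naming the offending line.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"012"` or `"123"` genotype coding.
#' @param sep field delimiter, `NULL` to auto-detect tab or comma.
#' @return a [genotype_dataset()] in the canonical 0/1/2 coding.
#' @export
read_genotypes <- function(path, dialect = c("auto", "012", "123"),
                           sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "integer")
  if (ncol(tab) < 2L)
    stop("expected at least one SNP column and a final class column")
  cls_col <- ncol(tab)
  if (tolower(colnames(tab)[cls_col]) != "class")
    stop("last header field must be 'Class', found '",
         colnames(tab)[cls_col], "'")
  pheno <- tab[[cls_col]]
  bad <- which(!pheno %in% 0:1)
  if (length(bad))
    stop("invalid phenotype value ", pheno[bad[1]], " on line ", bad[1] + 1L,
         " (must be 0 or 1)")
  geno <- as.matrix(tab[, -cls_col, drop = FALSE])
  vals <- sort(unique(as.vector(geno)))
  if (dialect == "auto") {
    if (any(vals < 0L) || any(vals > 3L))
      stop("invalid genotype value ", vals[vals < 0L | vals > 3L][1],
           " on line ",
           which(apply(geno < 0L | geno > 3L, 1L, any))[1] + 1L)
    dialect <- if (length(vals) == 0L) "012"  # no samples: coding irrelevant
               else if (0L %in% vals) "012"
               else if (3L %in% vals) "123"
               else stop("genotype coding ambiguous (only values ",
                         paste(vals, collapse = ", "),
                         " present); set 'dialect' explicitly")
  }
  allowed <- if (dialect == "012") 0:2 else 1:3
  bad_row <- which(apply(!matrix(geno %in% allowed, nrow(geno)), 1L, any))
  if (length(bad_row)) {
    bad_val <- geno[bad_row[1], !geno[bad_row[1], ] %in% allowed][1]
    stop("invalid genotype value ", bad_val, " on line ", bad_row[1] + 1L,
         " for coding {", paste(allowed, collapse = ","), "}")
  }
  if (dialect == "123") geno <- geno - 1L
  truth <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
    if (!is.null(meta$truth))
      truth <- lapply(meta$truth, function(v) as.integer(unlist(v)))
  }
  genotype_dataset(geno, pheno, snp_names = colnames(tab)[-cls_col],
                   truth = truth)
}

#' Write a case-control genotype file
#'
#' Emits the delimited dialect read by [read_genotypes()]: header of SNP
#' names plus a final `Class` column, one row per sample.  Output bytes are
#' deterministic for a fixed dataset and dialect.  Ground-truth disease SNP
#' indices, when present, are written to a sidecar `<path>.meta.json`.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param dialect `"012"` (default) or `"123"` genotype coding.
#' @param sep field delimiter (default tab).
#' @param truth_sidecar write the metadata sidecar when truth is available
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, dialect = c("012", "123"),
                            sep = "\t", truth_sidecar = TRUE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  dialect <- match.arg(dialect)
  geno <- dataset$genotypes
  if (dialect == "123") geno <- geno + 1L
  out <- cbind(geno, Class = dataset$phenotype)
  colnames(out) <- c(dataset$snp_names, "Class")
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (truth_sidecar && !is.null(dataset$truth)) {
    meta <- list(truth = dataset$truth,
                 truth_names = lapply(dataset$truth,
                                      function(v) dataset$snp_names[v]))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE)
  }
  invisible(path)
}

#' Write a ranked search result with its run metadata
#'
#' Writes a tab-separated report of the final candidate memory (rank, SNP
#' names, 1-based column indices, mutual information, K2 log-score, Svalue,
#' chi-square statistic and p-value) plus a `<path>.meta.json` sidecar with
#' the run parameters, seed and per-iteration history, so any run can be
#' reconstructed from its outputs.
#'
#' @param result an `epiaco_result` (see [run_epiaco()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "epiaco_result"))
  mem <- result$candidates
  df <- data.frame(
    rank = seq_along(mem$key),
    snp_names = vapply(mem$snps, function(s)
      paste(result$snp_names[s], collapse = ","), character(1)),
    snp_indices = mem$key,
    mi = mem$mi,
    k2_log = mem$k2_log,
    svalue = mem$svalue,
    chi2_stat = if (is.null(mem$chi2_stat)) NA_real_ else mem$chi2_stat,
    chi2_p = if (is.null(mem$chi2_p)) NA_real_ else mem$chi2_p,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(method = result$method, seed = result$seed,
               params = unclass(result$params),
               history = result$history)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read and write run configuration files
#'
#' A run configuration is a YAML file holding search parameters (any
#' [aco_params()] field), I/O paths, the genotype coding dialect and the
#' detection-call mode.  Configurations round-trip losslessly.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a named list with an `aco_params` object in
#'   `$params` plus any other fields.  `write_run_config()`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  par_fields <- c("n_ants", "n_iterations", "order", "alpha", "beta",
                  "rho", "xi", "tau0", "seed", "q_mode")
  given <- cfg[names(cfg) %in% par_fields]
  cfg <- cfg[!names(cfg) %in% par_fields]
  cfg$params <- do.call(aco_params, given)
  cfg
}

#' @rdname read_run_config
#' @param config a named list as returned by `read_run_config()` (a `params`
#'   entry is flattened into its fields).
#' @export
write_run_config <- function(config, path) {
  if (!is.null(config$params)) {
    p <- unclass(config$params)
    config$params <- NULL
    config <- c(config, p[!vapply(p, is.null, logical(1))])
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
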