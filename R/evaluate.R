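#' Did a search detect the ground-truth interaction?
#'
#' Two detection calls are supported.  `"top1"` (the strict default, matching
#' the convention that an interaction is perfectly identified with no false
#' positives): the single top-ranked combination equals the truth set.
#' `"candidates"`: the truth set is present in the candidate memory and every
#' reported candidate overlaps the truth.
#'
#' @param result an `epiaco_result` (see [run_epiaco()]).
#' @param truth integer vector of the ground-truth disease SNP indices.
#' @param mode `"top1"` or `"candidates"`.
#' @return logical.
#' @export
detection_success <- function(result, truth, mode = c("top1", "candidates")) {
  mode <- match.arg(mode)
  truth <- sort(as.integer(truth))
  if (length(truth) == 0L) stop("'truth' must be non-empty")
  top <- top_combination(result)
  if (is.null(top)) return(FALSE)
  if (mode == "top1") return(identical(top, truth))
  mem <- result$candidates
  key <- combo_key(truth)
  (key %in% mem$key) &&
    all(vapply(mem$snps, function(s) any(s %in% truth), logical(1)))
}

#' Define a detection-power experiment
#'
#' A power experiment simulates `n_datasets` case-control datasets from one
#' disease model, runs the search `runs_per_dataset` times on each with
#' deterministically derived seeds, and reports the percentage of datasets in
#' which the embedded interaction was detected (Power = 100 R / G).
#'
#' @param model an [epistasis_model()].
#' @param params an [aco_params()].
#' @param n_datasets number of simulated datasets G (default 20).
#' @param runs_per_dataset search repetitions per dataset (default 1).
#' @param n_cases,n_controls,n_snps,background_maf_range dataset design,
#'   passed to [simulate_dataset()].
#' @param seed master seed; dataset and run seeds are derived from it.
#' @return an object of class `power_experiment`.
#' @export
power_experiment <- function(model, params = aco_params(), n_datasets = 20,
                             runs_per_dataset = 1, n_cases = 2000,
                             n_controls = 2000, n_snps = 100,
                             background_maf_range = c(0.05, 0.5),
                             seed = 1) {
  stopifnot(inherits(model, "epistasis_model"),
            inherits(params, "aco_params"))
  n_datasets <- as.integer(n_datasets)
  runs_per_dataset <- as.integer(runs_per_dataset)
  if (n_datasets < 1L || runs_per_dataset < 1L)
    stop("'n_datasets' and 'runs_per_dataset' must be positive")
  structure(list(model = model, params = params, n_datasets = n_datasets,
                 runs_per_dataset = runs_per_dataset, n_cases = n_cases,
                 n_controls = n_controls, n_snps = n_snps,
                 background_maf_range = background_maf_range,
                 seed = as.integer(seed)),
            class = "power_experiment")
}

#' Run a detection-power experiment
#'
#' For each dataset, the per-run success flags are aggregated into a
#' per-dataset detection call: `"majority"` (default) marks a dataset
#' detected when more than half of its runs succeed; `"mean"` instead
#' averages all run successes directly.  The result's `dispersion` is the
#' standard deviation of the per-run power across run replicates (NA for a
#' single run).
#'
#' @param experiment a [power_experiment()].
#' @param aggregate `"majority"` or `"mean"` per-dataset aggregation.
#' @param mode detection call passed to [detection_success()].
#' @param method `"epiaco"` or `"random"` (pure random search at the same
#'   evaluation budget, m ants x T iterations).
#' @param verbose print per-dataset progress.
#' @return an object of class `power_result`: list with `power` (percentage
#'   in [0, 100]), `detected` (per-dataset flags), `successes`
#'   (dataset x run logical matrix) and `dispersion`.
#' @export
detection_power <- function(experiment, aggregate = c("majority", "mean"),
                            mode = c("top1", "candidates"),
                            method = c("epiaco", "random"),
                            verbose = FALSE) {
  stopifnot(inherits(experiment, "power_experiment"))
  aggregate <- match.arg(aggregate)
  mode <- match.arg(mode)
  method <- match.arg(method)
  G <- experiment$n_datasets
  R <- experiment$runs_per_dataset
  params <- experiment$params

  set.seed(experiment$seed)
  ds_seeds <- sample.int(.Machine$integer.max - 1L, G)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L, G * R), G, R)

  successes <- matrix(NA, G, R)
  for (g in seq_len(G)) {
    ds <- simulate_dataset(experiment$model, experiment$n_cases,
                           experiment$n_controls, experiment$n_snps,
                           experiment$background_maf_range,
                           seed = ds_seeds[g])
    truth <- ds$truth[[1L]]
    for (r in seq_len(R)) {
      res <- if (method == "epiaco") {
        p <- params
        p$seed <- run_seeds[g, r]
        run_epiaco(ds, p)
      } else {
        run_random_search(ds, n_evals = params$n_ants * params$n_iterations,
                          order = params$order, seed = run_seeds[g, r])
      }
      successes[g, r] <- detection_success(res, truth, mode)
    }
    if (verbose)
      message(sprintf("dataset %d/%d: %d/%d run(s) detected",
                      g, G, sum(successes[g, ]), R))
  }

  detected <- rowMeans(successes) > 0.5
  power <- if (aggregate == "majority") 100 * mean(detected)
           else 100 * mean(successes)
  per_run_power <- 100 * colMeans(successes)
  structure(list(power = power, detected = detected, successes = successes,
                 dispersion = if (R > 1L) stats::sd(per_run_power) else NA_real_,
                 aggregate = aggregate, mode = mode, method = method,
                 experiment = experiment),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> %s: power %.2f%% (%d/%d datasets, %d run(s) each",
              x$method, x$power, sum(x$detected), length(x$detected),
              ncol(x$successes)))
  if (!is.na(x$dispersion)) cat(sprintf(", run sd %.2f", x$dispersion))
  cat(")\n")
  invisible(x)
}
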