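## ---- combination keys -------------------------------------------------

#' Canonical key of a SNP combination
#'
#' @param snps integer vector of SNP indices.
#' @return a string, the sorted indices joined by commas.
#' @export
combo_key <- function(snps) paste(sort(as.integer(snps)), collapse = ",")

## zero-padded variant used for deterministic tie-breaking by ascending tuple
sort_key_of <- function(snps) {
  paste(sprintf("%08d", sort(as.integer(snps))), collapse = ",")
}

## ---- candidate memory -------------------------------------------------

#' Candidate-solution memory
#'
#' High-scoring SNP combinations retained across iterations.  Entries are
#' unique by combination and kept sorted by descending Svalue, ties broken by
#' ascending index tuple.  `empty_memory()` creates an empty one.
#'
#' @return an object of class `candidate_memory`: parallel fields `key`,
#'   `snps` (list of integer vectors), `svalue`, `mi`, `k2_log`.
#' @export
empty_memory <- function() {
  structure(list(key = character(), snps = list(), svalue = numeric(),
                 mi = numeric(), k2_log = numeric(), sort_key = character()),
            class = "candidate_memory")
}

memory_from <- function(key, snps, svalue, mi, k2_log,
                        sort_key = vapply(snps, sort_key_of, character(1))) {
  structure(list(key = key, snps = snps, svalue = svalue, mi = mi,
                 k2_log = k2_log, sort_key = sort_key),
            class = "candidate_memory")
}

memory_subset <- function(mem, idx) {
  memory_from(mem$key[idx], mem$snps[idx], mem$svalue[idx], mem$mi[idx],
              mem$k2_log[idx], mem$sort_key[idx])
}

memory_concat <- function(a, b) {
  memory_from(c(a$key, b$key), c(a$snps, b$snps), c(a$svalue, b$svalue),
              c(a$mi, b$mi), c(a$k2_log, b$k2_log),
              c(a$sort_key, b$sort_key))
}

## dedupe by key (first occurrence wins) and sort by descending svalue,
## ties by ascending index tuple
memory_rank <- function(mem) {
  mem <- memory_subset(mem, !duplicated(mem$key))
  memory_subset(mem, order(-mem$svalue, mem$sort_key))
}

#' @export
length.candidate_memory <- function(x) length(x$key)

#' @export
print.candidate_memory <- function(x, n = 10L, ...) {
  cat(sprintf("<candidate_memory> %d combination(s)\n", length(x)))
  if (length(x))
    print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
as.data.frame.candidate_memory <- function(x, ...) {
  df <- data.frame(rank = seq_along(x$key), snps = x$key, mi = x$mi,
                   k2_log = x$k2_log, svalue = x$svalue,
                   stringsAsFactors = FALSE)
  if (!is.null(x$chi2_stat)) {
    df$chi2_stat <- x$chi2_stat
    df$chi2_p <- x$chi2_p
  }
  df
}

## ---- inflection point -------------------------------------------------

#' Inflection point of a descending score list
#'
#' Given Svalue scores sorted in descending order (1-based ranks), returns
#' the rank `f` maximizing the second difference
#' `(s_g - s_{g-1}) - (s_{g-1} - s_{g-2})` over `g = 3..m`; ties take the
#' smallest `g`.  The top-`f` scores are treated as candidate solutions.
#' Lists with fewer than 3 scores return their length; an empty list
#' returns 0.
#'
#' @param scores numeric vector sorted in descending order.
#' @return the cut rank `f`.
#' @export
#' @examples
#' find_inflection(c(10, 9.8, 4, 3.9, 3.8))  # 4
find_inflection <- function(scores) {
  m <- length(scores)
  if (m == 0L) return(0L)
  if (any(diff(scores) > 1e-9)) stop("'scores' must be sorted descending")
  if (m < 3L) return(m)
  d2 <- scores[3:m] - 2 * scores[2:(m - 1L)] + scores[1:(m - 2L)]
  2L + which.max(d2)  # which.max returns the first maximum: smallest g
}

## ---- memory update ----------------------------------------------------

#' Merge an iteration's solutions into the candidate memory
#'
#' The iteration's solutions are deduplicated, ranked by descending Svalue
#' and cut at their inflection point; the survivors are merged (union) with
#' the previous memory, the merged list is re-ranked, and a second
#' inflection-point cut yields the new memory.  Good solutions from earlier
#' iterations are never lost: the best Svalue in memory is non-decreasing.
#'
#' @param memory a `candidate_memory` (see [empty_memory()]).
#' @param iteration_solutions either a `candidate_memory`-like structure or a
#'   list of [score_combination()] results for the current iteration.
#' @param capacity optional hard cap on memory size (default unbounded; the
#'   inflection point self-limits).
#' @return the updated `candidate_memory`.
#' @export
update_memory <- function(memory, iteration_solutions, capacity = Inf) {
  if (!inherits(iteration_solutions, "candidate_memory"))
    iteration_solutions <- solutions_to_memory(iteration_solutions)
  sol <- memory_rank(iteration_solutions)
  f1 <- find_inflection(sol$svalue)
  sol <- memory_subset(sol, seq_len(f1))
  merged <- memory_rank(memory_concat(memory, sol))
  f2 <- find_inflection(merged$svalue)
  merged <- memory_subset(merged, seq_len(min(f2, capacity)))
  merged
}

solutions_to_memory <- function(solutions) {
  if (inherits(solutions, "combination_score")) solutions <- list(solutions)
  snps <- lapply(solutions, function(s) sort(as.integer(s$snps)))
  memory_from(vapply(snps, combo_key, character(1)), snps,
              vapply(solutions, function(s) s$svalue, numeric(1)),
              vapply(solutions, function(s) s$mi, numeric(1)),
              vapply(solutions, function(s) s$k2_log, numeric(1)))
}

## ---- main search ------------------------------------------------------

#' Ant colony search for epistatic interactions
#'
#' Runs the full search: pheromones are initialized at `tau0` and the
#' heuristic at 1; in each of T iterations every one of the m ants constructs
#' a K-SNP combination (probabilistic or stochastic path selection governed
#' by q0 = t/T), combinations are scored by the Svalue fitness, the candidate
#' memory is updated via the inflection-point rule, and pheromones evaporate
#' and receive per-ant deposits with the xi-scaled candidate reward.
#' Duplicate combinations within an iteration enter the memory once but every
#' ant deposits pheromone.  Scores are cached per combination, so repeated
#' evaluations of the same pair are free.
#'
#' @param dataset a [genotype_dataset()].
#' @param params an [aco_params()]; `params$seed` makes the run reproducible.
#' @param eta optional positive heuristic vector (defaults to all 1).
#' @param memory_capacity optional cap on the candidate memory size.
#' @param verbose print per-iteration progress (iteration, best Svalue,
#'   memory size).
#' @return an object of class `epiaco_result`: list with `candidates` (final
#'   ranked [candidate_memory][empty_memory()] including chi-square tests),
#'   `history` (per-iteration best Svalue, memory size, selection-strategy
#'   counts), `params`, `seed`, `snp_names` and `method`.
#' @seealso [brute_force_scan()], [run_random_search()], [detection_power()]
#' @export
run_epiaco <- function(dataset, params = aco_params(), eta = NULL,
                       memory_capacity = Inf, verbose = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(params, "aco_params"))
  G <- dataset$genotypes
  y <- dataset$phenotype
  n <- ncol(G)
  K <- params$order
  m <- params$n_ants
  total <- params$n_iterations
  if (n < K) stop("dataset has fewer SNPs than the order K")
  if (!is.null(params$seed)) set.seed(params$seed)

  n_samp <- nrow(G)
  nbins <- 2L * 3L^K
  cache <- new.env(hash = TRUE, parent = emptyenv())
  score_of <- function(key, snps) {
    val <- cache[[key]]
    if (is.null(val)) {
      cnt <- count_cells(G, y, snps)
      mi <- mi_from_counts(cnt, n_samp)
      k2 <- k2_from_counts(cnt)
      val <- c(mi, k2, svalue_from(mi, k2))
      cache[[key]] <- val
    }
    val
  }

  memory <- empty_memory()
  per_choice <- params$q_mode == "per_choice"
  history <- data.frame(iteration = seq_len(total), best_svalue = NA_real_,
                        n_candidates = NA_integer_,
                        n_probabilistic = NA_integer_,
                        n_stochastic = NA_integer_)

  tau <- rep(params$tau0, n)
  for (t in seq_len(total)) {
    q0 <- t / total
    w <- state_weights(params, tau = tau, eta = eta, n = n)
    V <- pheromone_lower_half(tau)
    combos <- matrix(0L, m, K)
    n_stoch <- 0L
    for (a in seq_len(m)) {
      chosen <- integer(K)
      q <- stats::runif(1)
      for (k in seq_len(K)) {
        if (per_choice && k > 1L) q <- stats::runif(1)
        prior <- chosen[seq_len(k - 1L)]
        if (q <= q0) {
          if (k == 1L) {
            i <- sample.int(n, 1L, prob = w)
          } else {
            w2 <- w
            w2[prior] <- 0
            i <- sample.int(n, 1L, prob = w2)
          }
        } else {
          n_stoch <- n_stoch + 1L
          v <- if (k == 1L) V else V[!(V %in% prior)]
          if (length(v) == 0L) v <- setdiff(seq_len(n), prior)
          i <- if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
        }
        chosen[k] <- i
      }
      combos[a, ] <- sort.int(chosen)
    }

    keys <- apply(combos, 1L, paste, collapse = ",")
    sv <- numeric(m); miv <- numeric(m); k2v <- numeric(m)
    for (a in seq_len(m)) {
      val <- score_of(keys[a], combos[a, ])
      miv[a] <- val[1L]; k2v[a] <- val[2L]; sv[a] <- val[3L]
    }

    first <- !duplicated(keys)
    memory <- update_memory(
      memory,
      memory_from(keys[first],
                  lapply(which(first), function(a) combos[a, ]),
                  sv[first], miv[first], k2v[first]),
      capacity = memory_capacity)

    # evaporation + per-ant deposits, candidate combinations earn xi extra
    deposit <- sv * (1 + params$xi * (keys %in% memory$key))
    delta <- numeric(n)
    agg <- rowsum(rep(deposit, times = K), as.vector(combos))
    delta[as.integer(rownames(agg))] <- agg
    tau <- (1 - params$rho) * tau + delta

    history$best_svalue[t] <- if (length(memory)) memory$svalue[1L] else NA_real_
    history$n_candidates[t] <- length(memory)
    history$n_stochastic[t] <- n_stoch
    history$n_probabilistic[t] <- m * K - n_stoch
    if (verbose)
      message(sprintf("iteration %d/%d: best Svalue %.6g, memory %d",
                      t, total, history$best_svalue[t], length(memory)))
  }

  # chi-square breakdown for the final report
  chi2_stat <- chi2_p <- rep(NA_real_, length(memory))
  for (i in seq_along(memory$key)) {
    ct <- chi2_association(tabulate_counts(dataset, memory$snps[[i]]))
    chi2_stat[i] <- ct$statistic
    chi2_p[i] <- ct$p_value
  }
  memory$chi2_stat <- chi2_stat
  memory$chi2_p <- chi2_p

  structure(list(candidates = memory, history = history, params = params,
                 seed = params$seed, snp_names = dataset$snp_names,
                 method = "epiaco"),
            class = "epiaco_result")
}

## weights of the probabilistic rule for the current pheromone state
state_weights <- function(params, tau, eta, n) {
  e <- if (is.null(eta)) rep(1, n) else eta
  tau^params$alpha * e^params$beta
}

#' @export
print.epiaco_result <- function(x, ...) {
  cat(sprintf("<epiaco_result> %s search, %d candidate combination(s)\n",
              x$method, length(x$candidates)))
  if (length(x$candidates)) {
    df <- as.data.frame(x$candidates)
    df$snp_names <- vapply(x$candidates$snps, function(s)
      paste(x$snp_names[s], collapse = ","), character(1))
    print(utils::head(df, 10L))
  }
  invisible(x)
}

#' Top-ranked combination of a search result
#'
#' @param result an `epiaco_result` (from [run_epiaco()],
#'   [run_random_search()]) or a scan from [brute_force_scan()].
#' @return sorted integer vector of the best-scoring combination's SNP
#'   indices, or NULL for an empty result.
#' @export
top_combination <- function(result) {
  if (inherits(result, "epiaco_result")) {
    if (!length(result$candidates)) return(NULL)
    return(result$candidates$snps[[1L]])
  }
  if (inherits(result, "candidate_memory")) {
    if (!length(result)) return(NULL)
    return(result$snps[[1L]])
  }
  stop("unsupported result type")
}

## ---- oracles ----------------------------------------------------------

#' Exhaustive Svalue scan over all K-combinations
#'
#' Scores every K-SNP combination and returns the full descending ranking.
#' Intended as a verification oracle and for small data sets; errors if the
#' number of combinations exceeds `cap`.
#'
#' @param dataset a [genotype_dataset()].
#' @param order combination order K (default 2).
#' @param cap maximum number of combinations to enumerate (default 2e5).
#' @return a `candidate_memory` holding the complete ranking.
#' @export
brute_force_scan <- function(dataset, order = 2L, cap = 2e5) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  K <- as.integer(order)
  n <- ncol(dataset$genotypes)
  if (n < K) stop("dataset has fewer SNPs than the order K")
  if (choose(n, K) > cap)
    stop("choose(", n, ", ", K, ") combinations exceed the cap of ", cap)
  combos <- utils::combn(n, K)
  nc <- ncol(combos)
  G <- dataset$genotypes; y <- dataset$phenotype; n_samp <- nrow(G)
  mi <- k2 <- sv <- numeric(nc)
  for (j in seq_len(nc)) {
    cnt <- count_cells(G, y, combos[, j])
    mi[j] <- mi_from_counts(cnt, n_samp)
    k2[j] <- k2_from_counts(cnt)
    sv[j] <- svalue_from(mi[j], k2[j])
  }
  snps <- lapply(seq_len(nc), function(j) combos[, j])
  memory_rank(memory_from(vapply(snps, combo_key, character(1)), snps,
                          sv, mi, k2))
}

#' Pure random search baseline
#'
#' Samples `n_evals` K-combinations uniformly at random (with replacement
#' across draws), scores each by the Svalue fitness, and returns the ranking
#' of the distinct combinations seen.  This is the no-pheromone baseline the
#' ant colony search is compared against at an equal evaluation budget.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_evals number of combinations to draw.
#' @param order combination order K (default 2).
#' @param seed optional integer seed.
#' @return an `epiaco_result` with `method = "random"`.
#' @export
run_random_search <- function(dataset, n_evals, order = 2L, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  K <- as.integer(order)
  n <- ncol(dataset$genotypes)
  if (n < K) stop("dataset has fewer SNPs than the order K")
  if (!is.null(seed)) set.seed(as.integer(seed))
  G <- dataset$genotypes; y <- dataset$phenotype; n_samp <- nrow(G)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  keys <- character(n_evals)
  snps_list <- vector("list", n_evals)
  for (e in seq_len(n_evals)) {
    snps <- sort.int(sample.int(n, K))
    key <- paste(snps, collapse = ",")
    keys[e] <- key
    snps_list[[e]] <- snps
    if (is.null(cache[[key]])) {
      cnt <- count_cells(G, y, snps)
      mi <- mi_from_counts(cnt, n_samp)
      k2 <- k2_from_counts(cnt)
      cache[[key]] <- c(mi, k2, svalue_from(mi, k2))
    }
  }
  first <- !duplicated(keys)
  vals <- vapply(keys[first], function(k) cache[[k]], numeric(3))
  memory <- memory_rank(memory_from(keys[first], snps_list[first],
                                    vals[3L, ], vals[1L, ], vals[2L, ]))
  structure(list(candidates = memory, history = NULL, params = NULL,
                 seed = seed, snp_names = dataset$snp_names,
                 method = "random"),
            class = "epiaco_result")
}
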