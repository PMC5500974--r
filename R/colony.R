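#' Ant colony search parameters
#'
#' Bundles and validates the tunables of the ant colony search.  Defaults
#' follow the benchmark settings used throughout the package's validation:
#' m = 25 ants, T = 200 iterations, pheromone/heuristic exponents
#' alpha = beta = 1, evaporation rho = 0.2, candidate reward xi = 0.3
#' (recommended range 0.2-0.5), initial pheromone tau0 = 1, pair order
#' K = 2.  The ant/iteration split matters beyond the m x T evaluation
#' budget: pheromone deposits are on the Svalue scale (about 1e-5 for
#' 4000-sample datasets), so the tau0 baseline must evaporate through that
#' scale — at rho = 0.2 roughly 60 iterations — before path selection can
#' respond to the accumulated deposits.  Runs with too few iterations never
#' leave the near-uniform regime regardless of how many ants they use.
#'
#' @param n_ants number of ants m (>= 3: the inflection-point rule needs at
#'   least three ranked solutions).
#' @param n_iterations total iterations T.
#' @param order combination order K (>= 2).
#' @param alpha,beta exponents weighting pheromone and heuristic information
#'   in the probabilistic selection rule.
#' @param rho pheromone evaporation coefficient in [0, 1).
#' @param xi candidate-solution reward factor in [0, 1].
#' @param tau0 initial pheromone level (> 0).
#' @param seed optional integer seed for a search run.
#' @param q_mode draw the exploration/exploitation uniform `q` once per SNP
#'   choice (`"per_choice"`, default) or once per ant (`"per_ant"`).
#' @return an object of class `aco_params`.
#' @export
aco_params <- function(n_ants = 25, n_iterations = 200, order = 2,
                       alpha = 1, beta = 1, rho = 0.2, xi = 0.3,
                       tau0 = 1, seed = NULL,
                       q_mode = c("per_choice", "per_ant")) {
  q_mode <- match.arg(q_mode)
  n_ants <- as.integer(n_ants); n_iterations <- as.integer(n_iterations)
  order <- as.integer(order)
  if (n_ants < 3L) stop("'n_ants' must be at least 3")
  if (n_iterations < 1L) stop("'n_iterations' must be at least 1")
  if (order < 2L) stop("'order' must be at least 2")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (xi < 0 || xi > 1) stop("'xi' must lie in [0, 1]")
  if (tau0 <= 0) stop("'tau0' must be positive")
  structure(list(n_ants = n_ants, n_iterations = n_iterations, order = order,
                 alpha = alpha, beta = beta, rho = rho, xi = xi, tau0 = tau0,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 q_mode = q_mode),
            class = "aco_params")
}

#' @export
print.aco_params <- function(x, ...) {
  cat(sprintf(paste0("<aco_params> m=%d ants, T=%d iterations, K=%d, ",
                     "alpha=%g beta=%g rho=%g xi=%g tau0=%g, q per %s\n"),
              x$n_ants, x$n_iterations, x$order, x$alpha, x$beta, x$rho,
              x$xi, x$tau0, sub("per_", "", x$q_mode)))
  invisible(x)
}

#' Colony state: pheromone and heuristic vectors
#'
#' Pheromone and heuristic information are attached to single SNPs (node
#' pheromones, not edges).  The heuristic vector defaults to 1 everywhere and
#' is kept as a hook for injecting prior knowledge.
#'
#' @param n_snps number of SNPs.
#' @param params an [aco_params()].
#' @param eta optional positive heuristic vector of length `n_snps`.
#' @return an object of class `colony_state` with fields `tau`, `eta`,
#'   `params`, `iteration` (1-based) and `total_iterations`.
#' @export
colony_state <- function(n_snps, params = aco_params(), eta = NULL) {
  n_snps <- as.integer(n_snps)
  if (n_snps < params$order) stop("'n_snps' must be at least the order K")
  if (is.null(eta)) eta <- rep(1, n_snps)
  if (length(eta) != n_snps || any(eta <= 0))
    stop("'eta' must be a strictly positive vector of length n_snps")
  structure(list(tau = rep(params$tau0, n_snps), eta = as.numeric(eta),
                 params = params, iteration = 1L,
                 total_iterations = params$n_iterations),
            class = "colony_state")
}

#' Exploration/exploitation threshold q0
#'
#' The ratio of the current iteration to the total iteration count.  A fresh
#' uniform draw q <= q0 routes a SNP choice to the probabilistic selection
#' rule, q > q0 to the stochastic rule, so early iterations explore widely
#' and the final iteration (q0 = 1) is fully probabilistic.
#'
#' @param iteration current iteration t (1-based).
#' @param total total iterations T.
#' @return t / T.
#' @export
q_threshold <- function(iteration, total) {
  if (iteration < 1L || iteration > total)
    stop("'iteration' must lie in 1..total")
  iteration / total
}

#' Probabilistic path selection
#'
#' Samples a SNP from `available` with probability proportional to
#' `tau_i^alpha * eta_i^beta`.
#'
#' @param state a [colony_state()].
#' @param available non-empty integer vector of selectable SNP indices.
#' @return one SNP index.
#' @export
select_probabilistic <- function(state, available) {
  if (length(available) == 0L) stop("no SNPs available for selection")
  if (length(available) == 1L) return(available)
  w <- state$tau[available]^state$params$alpha *
       state$eta[available]^state$params$beta
  available[sample.int(length(available), 1L, prob = w)]
}

## Indices of the floor(n/2) SNPs with the lowest pheromones: the latter half
## of a descending-pheromone sort, ties broken by ascending SNP index.
pheromone_lower_half <- function(tau) {
  n <- length(tau)
  ord <- order(tau, decreasing = TRUE)  # stable: ties stay in index order
  ord[seq.int(n - n %/% 2L + 1L, length.out = n %/% 2L)]
}

#' Stochastic path selection
#'
#' Ranks all SNPs by descending pheromone and samples uniformly from the
#' latter half (the `floor(n/2)` lowest-pheromone SNPs, ties broken by
#' ascending index) intersected with `available`; if that intersection is
#' empty it falls back to a uniform draw over `available`.
#'
#' @inheritParams select_probabilistic
#' @return one SNP index.
#' @export
select_stochastic <- function(state, available) {
  if (length(available) == 0L) stop("no SNPs available for selection")
  v <- pheromone_lower_half(state$tau)
  v <- v[v %in% available]
  if (length(v) == 0L) v <- available
  if (length(v) == 1L) return(v)
  v[sample.int(length(v), 1L)]
}

#' Construct one ant's K-SNP combination
#'
#' Chooses K distinct SNPs sequentially.  For each choice a uniform `q` is
#' drawn (or one per ant, see [aco_params()] `q_mode`) and compared with
#' q0 = t/T: `q <= q0` routes to [select_probabilistic()], otherwise to
#' [select_stochastic()].  Already chosen SNPs are removed from the
#' available set.
#'
#' @param state a [colony_state()].
#' @return sorted integer vector of K distinct SNP indices, with attribute
#'   `n_stochastic`: how many of the K choices used the stochastic rule.
#' @export
construct_combination <- function(state) {
  K <- state$params$order
  n <- length(state$tau)
  if (n < K) stop("not enough SNPs for order ", K)
  q0 <- q_threshold(state$iteration, state$total_iterations)
  available <- seq_len(n)
  chosen <- integer(K)
  n_stoch <- 0L
  q <- stats::runif(1)  # per-ant draw; redrawn per choice below if configured
  for (k in seq_len(K)) {
    if (state$params$q_mode == "per_choice" && k > 1L) q <- stats::runif(1)
    if (q <= q0) {
      chosen[k] <- select_probabilistic(state, available)
    } else {
      chosen[k] <- select_stochastic(state, available)
      n_stoch <- n_stoch + 1L
    }
    available <- available[available != chosen[k]]
  }
  structure(sort(chosen), n_stochastic = n_stoch)
}

#' Pheromone update with candidate-solution reward
#'
#' Applies evaporation and per-ant deposits:
#' `tau_i(t+1) = (1 - rho) tau_i(t) + sum_k Svalue(A_k) [i in A_k]
#'  + sum_k xi Svalue(A_k) [i in A_k, A_k a candidate]`.
#' Every ant deposits (duplicated combinations deposit once per ant), and
#' combinations present in the candidate memory earn the additional
#' xi-scaled reward.
#'
#' @param state a [colony_state()].
#' @param ant_solutions list with one element per ant, each a list with
#'   `snps` (integer vector) and `svalue`.
#' @param candidates a [candidate_memory()] (or character vector of
#'   combination keys) defining which combinations earn the extra reward.
#' @return the updated `colony_state` (iteration counter advanced).
#' @export
update_pheromones <- function(state, ant_solutions, candidates = NULL) {
  keys <- if (inherits(candidates, "candidate_memory")) candidates$key
          else as.character(candidates)
  tau <- (1 - state$params$rho) * state$tau
  for (sol in ant_solutions) {
    inc <- sol$svalue
    if (combo_key(sol$snps) %in% keys)
      inc <- inc + state$params$xi * sol$svalue
    tau[sol$snps] <- tau[sol$snps] + inc
  }
  state$tau <- tau
  state$iteration <- min(state$iteration + 1L, state$total_iterations)
  state
}
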