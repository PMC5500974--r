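test_that("parameter validation enforces the documented ranges", {
  expect_error(aco_params(n_ants = 2), "at least 3")
  expect_error(aco_params(order = 1), "at least 2")
  expect_error(aco_params(rho = 1), "\\[0, 1\\)")
  expect_error(aco_params(xi = 1.5), "\\[0, 1\\]")
  expect_error(aco_params(tau0 = 0), "positive")
  p <- aco_params(seed = 4L)
  expect_identical(p$seed, 4L)
})

test_that("q threshold is the iteration ratio with its boundary behavior", {
  expect_equal(q_threshold(1, 25), 0.04)
  expect_equal(q_threshold(13, 25), 0.52)
  expect_equal(q_threshold(25, 25), 1)
  expect_error(q_threshold(0, 25))
  expect_error(q_threshold(26, 25))
})

test_that("probabilistic selection follows the pheromone-heuristic weights", {
  p <- aco_params(n_ants = 10, n_iterations = 5)
  st <- colony_state(4, p)
  # uniform tau and eta: each index near 1/4 (chi-square goodness of fit)
  set.seed(1)
  draws <- replicate(10000, select_probabilistic(st, 1:4))
  gof <- chisq.test(tabulate(draws, 4))
  expect_gt(gof$p.value, 0.01)
  # tau = (3,1), eta = 1: probabilities (0.75, 0.25)
  st2 <- colony_state(2, p)
  st2$tau <- c(3, 1)
  draws2 <- replicate(10000, select_probabilistic(st2, 1:2))
  expect_lt(abs(mean(draws2 == 1L) - 0.75), 0.02)
  # single available SNP is always selected
  expect_identical(select_probabilistic(st, 3L), 3L)
  expect_error(select_probabilistic(st, integer(0)), "available")
})

test_that("stochastic selection draws from the lower pheromone half", {
  p <- aco_params(n_ants = 10, n_iterations = 5)
  st <- colony_state(4, p)
  st$tau <- c(4, 3, 2, 1)
  set.seed(2)
  draws <- replicate(2000, select_stochastic(st, 1:4))
  expect_setequal(unique(draws), c(3L, 4L))  # pheromones {2, 1}
  expect_lt(abs(mean(draws == 3L) - 0.5), 0.05)
  # equal pheromones: tie-break gives the latter half by ascending index
  st$tau <- rep(1, 4)
  draws <- unique(replicate(500, select_stochastic(st, 1:4)))
  expect_setequal(draws, c(3L, 4L))
  # available disjoint from the lower half: uniform fallback over available
  st$tau <- c(4, 3, 2, 1)
  draws <- unique(replicate(500, select_stochastic(st, 1:2)))
  expect_setequal(draws, c(1L, 2L))
})

test_that("combination construction yields distinct sorted SNPs", {
  p <- aco_params(n_ants = 10, n_iterations = 5, order = 2)
  st <- colony_state(6, p)
  set.seed(3)
  for (rep in 1:50) {
    cmb <- construct_combination(st)
    expect_length(cmb, 2L)
    expect_identical(anyDuplicated(cmb), 0L)
    expect_identical(as.integer(cmb), sort(as.integer(cmb)))
  }
  # with K = n_snps the whole SNP set is exhausted
  p_full <- aco_params(n_ants = 10, n_iterations = 5, order = 6)
  st_full <- colony_state(6, p_full)
  expect_identical(as.integer(construct_combination(st_full)), 1:6)
})

test_that("at the final iteration every choice is probabilistic", {
  p <- aco_params(n_ants = 10, n_iterations = 7)
  st <- colony_state(10, p)
  st$iteration <- 7L
  set.seed(4)
  for (rep in 1:40)
    expect_identical(attr(construct_combination(st), "n_stochastic"), 0L)
})

test_that("construction with a fixed seed is reproducible", {
  p <- aco_params(n_ants = 10, n_iterations = 5)
  st <- colony_state(30, p)
  set.seed(9); a <- replicate(20, construct_combination(st))
  set.seed(9); b <- replicate(20, construct_combination(st))
  expect_identical(a, b)
})

test_that("pheromone update applies evaporation, deposits and candidate reward", {
  p <- aco_params(n_ants = 3, n_iterations = 10, rho = 0.2, xi = 0.3)
  st <- colony_state(4, p)
  s <- 0.05
  sol <- list(list(snps = c(1L, 2L), svalue = s))
  cand <- combo_key(c(1L, 2L))
  st2 <- update_pheromones(st, sol, cand)
  expect_equal(st2$tau[1:2], rep(0.8 + s + 0.3 * s, 2), tolerance = 1e-12)
  expect_equal(st2$tau[3:4], rep(0.8, 2), tolerance = 1e-12)  # pure evaporation
  # two ants on the same combination double the increments
  st3 <- update_pheromones(st, c(sol, sol), cand)
  expect_equal(st3$tau[1:2], rep(0.8 + 2 * (s + 0.3 * s), 2), tolerance = 1e-12)
  # non-candidate combination earns no extra reward
  st4 <- update_pheromones(st, sol, character(0))
  expect_equal(st4$tau[1:2], rep(0.8 + s, 2), tolerance = 1e-12)
})

test_that("with xi = 0 the candidate term vanishes identically", {
  p0 <- aco_params(n_ants = 3, n_iterations = 10, rho = 0.2, xi = 0)
  st <- colony_state(4, p0)
  sol <- list(list(snps = c(1L, 3L), svalue = 0.07))
  with_cand <- update_pheromones(st, sol, combo_key(c(1L, 3L)))
  without <- update_pheromones(st, sol, character(0))
  expect_identical(with_cand$tau, without$tau)
})

test_that("pheromones stay strictly positive throughout a run", {
  p <- aco_params(n_ants = 5, n_iterations = 30, rho = 0.2)
  st <- colony_state(8, p)
  set.seed(6)
  for (t in 1:30) {
    sols <- lapply(1:5, function(a)
      list(snps = sort(sample.int(8, 2)), svalue = runif(1, 0, 1e-4)))
    st <- update_pheromones(st, sols, character(0))
    expect_true(all(st$tau > 0))
  }
})

test_that("stochastic selection fraction tracks 1 - t/T across a run", {
  d <- simulate_dataset(builtin_model(1), 200, 200, 30, seed = 15)
  res <- run_epiaco(d, aco_params(n_ants = 60, n_iterations = 20, seed = 2))
  frac <- res$history$n_stochastic /
    (res$history$n_stochastic + res$history$n_probabilistic)
  expected <- 1 - res$history$iteration / 20
  # binomial noise on 120 choices per iteration: allow 4 sd plus tie effects
  tol <- 4 * sqrt(expected * (1 - expected) / 120) + 0.01
  expect_true(all(abs(frac - expected) <= tol))
  # and the fraction trends downward overall
  expect_lt(mean(frac[11:20]), mean(frac[1:10]))
})
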