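test_that("sign activation maps zero upward and rejects non-finite input", {
  expect_identical(sgn(c(-0.1, 0, 2.5)), c(-1L, 1L, 1L))
  expect_error(sgn(NaN), "finite")
  expect_error(sgn(Inf), "finite")
})

test_that("Hebbian storage gives symmetric zero-diagonal outer products", {
  W <- hebbian_weights(rbind(c(1, -1, 1)))
  expect_equal(W, rbind(c(0, -1, 1), c(-1, 0, -1), c(1, -1, 0)) / 3)

  # two orthogonal-in-sign patterns cancel off-diagonal
  W2 <- hebbian_weights(rbind(c(1, 1), c(1, -1)))
  expect_equal(W2, matrix(0, 2, 2))

  expect_equal(hebbian_weights(list(c(1, -1, 1))),
               hebbian_weights(rbind(c(1, -1, 1))))
  expect_error(hebbian_weights(list()), "at least one")
  expect_error(hebbian_weights(list(c(1, -1), c(1, -1, 1))), "same length")
  expect_error(hebbian_weights(rbind(c(1, 0, -1))), "bipolar")
})

test_that("a single stored pattern is a fixed point at zero threshold", {
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(3:15, 1)
    xi <- sample(c(-1L, 1L), n, replace = TRUE)
    W <- hebbian_weights(rbind(xi))
    res <- run_to_convergence(W, xi, config = fit_config(threshold_scale = 0))
    expect_true(res$converged)
    expect_equal(res$sweeps, 1L)
    expect_identical(res$state, xi)
  }
})

test_that("the energy function matches its closed form", {
  expect_equal(hopfield_energy(matrix(0, 3, 3), c(1, -1, 1), lambda = 0), 0)
  W <- rbind(c(0, 1), c(1, 0))
  expect_equal(hopfield_energy(W, c(1, 1), lambda = 0), -1)
  expect_equal(hopfield_energy(W, c(1, 1), thresholds = c(0.5, 0.5), lambda = 1), 0)
  expect_error(hopfield_energy(W, c(1, 1, 1)), "disagree")
})

test_that("a deterministic sweep follows the net-input rule step by step", {
  W <- rbind(c(0, 1), c(1, 0))
  res <- update_sweep(W, c(1, -1))
  # neuron 1 sees net -1 and flips; neuron 2 then sees net -1 and stays -1
  expect_identical(res$state, c(-1L, -1L))
  expect_equal(res$trace$net, c(-1, -1))
  expect_equal(res$flips, 1L)

  # a fixed point passes through unchanged with zero flips
  res2 <- update_sweep(W, c(1, 1))
  expect_identical(res2$state, c(1L, 1L))
  expect_equal(res2$flips, 0L)
})

test_that("stochastic dynamics are reproducible under a seed", {
  set.seed(2)
  W <- hebbian_weights(rbind(sample(c(-1L, 1L), 8, TRUE)))
  x0 <- sample(c(-1L, 1L), 8, TRUE)
  cfg <- fit_config(update_mode = "stochastic", seed = 99,
                    neuron_order = "shuffled")
  a <- update_sweep(W, x0, thresholds = rep(0.6, 8), config = cfg)
  b <- update_sweep(W, x0, thresholds = rep(0.6, 8), config = cfg)
  expect_identical(a, b)
  ra <- run_to_convergence(W, x0, thresholds = rep(0.6, 8), config = cfg)
  rb <- run_to_convergence(W, x0, thresholds = rep(0.6, 8), config = cfg)
  expect_identical(ra, rb)
})

test_that("deterministic updates never increase the energy", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    W <- matrix(rnorm(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    thresholds <- runif(n)
    x <- sample(c(-1L, 1L), n, replace = TRUE)
    e_prev <- hopfield_energy(W, x, thresholds, 1)
    for (s in 1:5) {
      res <- update_sweep(W, x, thresholds, fit_config())
      expect_true(all(diff(c(e_prev, res$trace$energy)) <= 1e-12))
      e_prev <- res$trace$energy[length(res$trace$energy)]
      x <- res$state
    }
  }
})

test_that("random symmetric zero-diagonal nets always reach a fixed point", {
  set.seed(4)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    W <- matrix(rnorm(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    thresholds <- runif(n)
    for (start in 1:5) {
      x0 <- sample(c(-1L, 1L), n, replace = TRUE)
      res <- run_to_convergence(W, x0, thresholds,
                                fit_config(j_max = 2^n))
      expect_true(res$converged)
      # the final state really is stable: one more sweep changes nothing
      again <- update_sweep(W, res$state, thresholds, fit_config())
      expect_equal(again$flips, 0L)
    }
  }
})

test_that("reachable fixed points match brute-force stability (n <= 4)", {
  set.seed(5)
  for (n in 2:4) {
    W <- matrix(rnorm(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    thresholds <- runif(n)
    for (lambda in c(0, 1)) {
      cfg <- fit_config(threshold_scale = lambda, j_max = 2^n + 2)
      starts <- all_states(n)
      reached <- unique(t(apply(starts, 1, function(x0)
        run_to_convergence(W, x0, thresholds, cfg)$state)))
      expected <- stable_states_bruteforce(W, thresholds, lambda)
      key <- function(M) sort(apply(M, 1, paste, collapse = ","))
      expect_identical(key(reached), key(expected))
    }
  }
})

test_that("stored patterns are recalled from nearby states (capacity regime)", {
  set.seed(6)
  n <- 20
  hits <- 0L; total <- 0L
  for (rep in 1:10) {
    p <- sample(1:2, 1)
    patterns <- matrix(sample(c(-1L, 1L), p * n, replace = TRUE), p, n)
    W <- hebbian_weights(patterns)
    cfg <- fit_config(threshold_scale = 0)
    for (probe in 1:20) {
      target <- patterns[sample(p, 1), ]
      x0 <- target
      flip <- sample(n, 1)
      x0[flip] <- -x0[flip]
      final <- run_to_convergence(W, x0, config = cfg)$state
      hits <- hits + identical(final, target)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
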