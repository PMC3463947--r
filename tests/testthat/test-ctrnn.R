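test_that("sigmoid matches the logistic function and its symmetries", {
  expect_identical(sigmoid(0), 0.5)
  # frozen from a 30-digit arbitrary-precision evaluation of 1/(1+e^-2)
  expect_equal(sigmoid(2), 0.880797077977882444, tolerance = 1e-15)
  expect_lt(abs(sigmoid(40) - 1), 1e-15)
  expect_lt(sigmoid(-40), 1e-15)
  x <- seq(-10, 10, by = 0.37)
  expect_equal(sigmoid(-x), 1 - sigmoid(x), tolerance = 1e-12)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_error(sigmoid(c(1, NaN)), "non-finite")
  expect_error(sigmoid(Inf), "non-finite")
})

test_that("parameter and state constructors enforce the model invariants", {
  expect_error(ctrnn_params(n = 2, tau = c(1, -1)), "tau")
  expect_error(ctrnn_params(n = 2, g = c(1, 2)), "fixed at 1")
  expect_error(ctrnn_params(n = 2, w = matrix(0, 3, 3)), "matrix")
  p <- single_neuron()
  st <- ctrnn_state(p, 0.3)
  expect_equal(st$o, sigmoid(0.3))
  expect_error(ctrnn_state(p, c(1, 2)), "length")
})

test_that("the origin is an exact fixed point of the uncoupled network", {
  p <- ctrnn_params(n = 4, tau = rep(2, 4))
  st <- ctrnn_state(p)
  for (i in 1:10) st <- ctrnn_step(p, st, h = 0.1)
  expect_identical(st$s, rep(0, 4))
})

test_that("Euler integration matches the single-neuron closed form", {
  # s(t) = I (1 - e^(-t/tau)) for tau ds/dt = -s + I from s(0) = 0
  p <- single_neuron(tau = 1)
  closed <- function(t, I = 1, tau = 1) I * (1 - exp(-t / tau))
  run_to <- function(h, t_end) {
    st <- ctrnn_state(p)
    for (i in seq_len(round(t_end / h))) st <- ctrnn_step(p, st, input = 1,
                                                          h = h)
    st$s
  }
  # within 5e-3 of the closed form across t in [0, 10] at h = 0.01
  st <- ctrnn_state(p)
  worst <- 0
  for (i in seq_len(1000)) {
    st <- ctrnn_step(p, st, input = 1, h = 0.01)
    worst <- max(worst, abs(st$s - closed(i * 0.01)))
  }
  expect_lt(worst, 5e-3)
  # first-order convergence: halving h roughly halves the error at t = 1
  e1 <- abs(run_to(0.02, 1) - closed(1))
  e2 <- abs(run_to(0.01, 1) - closed(1))
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("outputs stay in [0, 1] for arbitrary parameters and horizons", {
  for (seed in 1:5) {
    p <- random_params(seed)
    st <- ctrnn_state(p, runif(8, -30, 30))
    for (i in 1:200) {
      st <- ctrnn_step(p, st, input = c(p$r, rep(0, 7)) * (i %% 2), h = 0.1)
      expect_true(all(st$o >= 0 & st$o <= 1))
    }
  }
})

test_that("a diverging state errors with the offending neuron", {
  p <- ctrnn_params(n = 2, tau = c(0.01, 1))
  st <- ctrnn_state(p, c(1, 0))
  expect_error({
    for (i in 1:500) st <- ctrnn_step(p, st, h = 10)
  }, "blow-up")
})

test_that("find_equilibria recovers the trivial and forced fixed points", {
  p <- ctrnn_params(n = 3, tau = rep(1, 3))
  eq <- find_equilibria(p, n_starts = 20, seed = 1)
  expect_true(eq$converged)
  expect_equal(nrow(eq$equilibria), 1L)
  expect_equal(as.numeric(eq$equilibria[1, ]), rep(0, 3), tolerance = 1e-6)
  expect_equal(eq$fraction, 1)
  expect_true(all(eq$residual < 1e-8))

  # self-exciting neuron w11 = 10, theta = -5: s = 5 solves s = 10*sigma(s-5)
  p2 <- single_neuron(w11 = 10, theta = -5)
  f <- function(s) -s + 10 * sigmoid(s - 5)
  expect_equal(f(5), 0)
})

test_that("attractor count matches a dense 1-D root-bracketing oracle", {
  p <- single_neuron(w11 = 10, theta = -5)
  # oracle: bracket all roots of f(s) = -s + 10*sigma(s-5), keep stable ones
  f <- function(s) -s + 10 * sigmoid(s - 5)
  grid <- seq(-20, 30, by = 0.01)
  fg <- f(grid)
  idx <- which(fg[-1] * fg[-length(fg)] <= 0 & fg[-1] != 0)
  roots <- vapply(idx, function(i)
    uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1))
  stable <- roots[vapply(roots, function(s) f(s + 1e-6) < f(s - 1e-6) &&
                           f(s - 1e-6) > 0, logical(1))]
  expect_equal(length(roots), 3L)   # bistable: two attractors, one repellor
  expect_equal(length(stable), 2L)

  eq <- find_equilibria(p, n_starts = 50, seed = 7, start_range = c(-20, 30))
  expect_true(eq$converged)
  expect_equal(nrow(eq$equilibria), 2L)
  expect_equal(sort(as.numeric(eq$equilibria)), sort(stable),
               tolerance = 1e-6)
  expect_equal(sum(eq$fraction), 1)
})

test_that("equilibrium search is deterministic and preserves caller RNG", {
  p <- random_params(3)
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- find_equilibria(p, n_starts = 10, seed = 5, max_steps = 2e4)
  also <- runif(1)
  b <- find_equilibria(p, n_starts = 10, seed = 5, max_steps = 2e4)
  expect_identical(a$equilibria, b$equilibria)
  expect_identical(before, also)
})

test_that("attractor_scan separates clamped input conditions", {
  # decoupled network: neuron 1 settles at exactly the clamped input value
  p <- ctrnn_params(n = 4, tau = rep(1, 4))
  sc <- attractor_scan(p, input_values = c(0, 1), n_starts = 10, seed = 2)
  expect_length(sc$inventories, 2L)
  expect_equal(as.numeric(sc$inventories[[1]]$equilibria[1, ]), rep(0, 4),
               tolerance = 1e-6)
  expect_equal(as.numeric(sc$inventories[[2]]$equilibria[1, ]),
               c(1, 0, 0, 0), tolerance = 1e-6)
  expect_equal(attractor_shift(sc), 1, tolerance = 1e-6)
  # degenerate scan of one input value
  sc1 <- attractor_scan(p, input_values = 0, n_starts = 5, seed = 2)
  expect_length(sc1$inventories, 1L)
})
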