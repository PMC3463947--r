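#' Continuous-time recurrent neural network parameters
#'
#' Bundles the parameters of a CTRNN of `n` fully interconnected neurons
#' (self-connections allowed) with leaky-integrator dynamics
#' \deqn{\tau_i \dot s_i = -s_i + \sum_j w_{ji}\,\sigma(g_j(s_j+\theta_j)) + I_i}
#' where \eqn{\sigma(x) = 1/(1+e^{-x})} is the logistic output function.
#' The per-neuron output gains `g` are fixed at 1 in this model. Two kinds of
#' embodiment gains are carried along with the network: a receptor gain `r`
#' that scales the binary contact input to neuron 1, and effector gains `e`
#' for the movement neuron (2) and the left/right button neurons (3, 4).
#'
#' @param n neuron count (>= 1; the embodied model uses 8).
#' @param tau time constants, length-`n` positive vector (time units).
#' @param w `n x n` weight matrix; `w[j, i]` is the connection from neuron
#'   `j` to neuron `i`.
#' @param theta biases, length-`n` vector.
#' @param g output gains, fixed at 1 (validated).
#' @param r receptor input gain applied to neuron 1's binary input.
#' @param e effector gains `c(move, left, right)`: movement velocity range
#'   (space/time) and link-adjustment step per click (space units).
#' @return An object of class `ctrnn_params`.
#' @seealso [ctrnn_step()], [find_equilibria()], [decode_genotype()]
#' @export
ctrnn_params <- function(n = 8L, tau = rep(1, n), w = matrix(0, n, n),
                         theta = rep(0, n), g = rep(1, n), r = 1,
                         e = c(move = 1, left = 0.5, right = 0.5)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  tau <- as.numeric(tau); theta <- as.numeric(theta); g <- as.numeric(g)
  if (length(tau) != n || any(!is.finite(tau)) || any(tau <= 0))
    stop("tau must be ", n, " finite positive time constants")
  if (!is.matrix(w) || any(dim(w) != n) || any(!is.finite(w)))
    stop("w must be a finite ", n, "x", n, " matrix")
  if (length(theta) != n || any(!is.finite(theta)))
    stop("theta must be a finite length-", n, " vector")
  if (length(g) != n || any(g != 1))
    stop("output gains g are fixed at 1 in this model")
  if (length(r) != 1L || !is.finite(r)) stop("r must be a finite scalar")
  e <- as.numeric(e)
  if (length(e) != 3L || any(!is.finite(e)) || any(e < 0))
    stop("e must be three non-negative effector gains (move, left, right)")
  structure(list(n = n, tau = tau, w = w, theta = theta, g = g, r = r,
                 e = setNames(e, c("move", "left", "right"))),
            class = "ctrnn_params")
}

#' @export
print.ctrnn_params <- function(x, ...) {
  cat("CTRNN parameters: ", x$n, " neurons\n", sep = "")
  cat("  tau in [", round(min(x$tau), 3), ", ", round(max(x$tau), 3),
      "]; |w| max ", round(max(abs(x$w)), 3), "\n", sep = "")
  cat("  receptor gain r = ", round(x$r, 3), "; effector gains e = (",
      paste(round(x$e, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Logistic activation function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the standard CTRNN output nonlinearity.
#' Strictly increasing with `sigmoid(-x) = 1 - sigmoid(x)`.
#'
#' @param x finite numeric vector.
#' @return Values in `[0, 1]`.
#' @export
sigmoid <- function(x) {
  if (any(!is.finite(x))) stop("sigmoid: non-finite input")
  1 / (1 + exp(-x))
}

#' CTRNN outputs for a given state
#'
#' @param params a [ctrnn_params()] object.
#' @param s state vector.
#' @return Output vector `o = sigmoid(g * (s + theta))`, each in `[0, 1]`.
#' @export
ctrnn_outputs <- function(params, s) sigmoid(params$g * (s + params$theta))

#' CTRNN state
#'
#' A state vector `s` together with its outputs `o`, which are always a pure
#' function of `s` and the parameters.
#'
#' @param params a [ctrnn_params()] object.
#' @param s state vector (defaults to all zeros, the trial initialization).
#' @return An object of class `ctrnn_state` with elements `s` and `o`.
#' @export
ctrnn_state <- function(params, s = rep(0, params$n)) {
  s <- as.numeric(s)
  if (length(s) != params$n || any(!is.finite(s)))
    stop("s must be a finite length-", params$n, " vector")
  structure(list(s = s, o = ctrnn_outputs(params, s)), class = "ctrnn_state")
}

#' One explicit-Euler CTRNN update
#'
#' Advances the network state by one step of size `h`:
#' `s <- s + (h / tau) * (-s + t(w) %*% o + input)`, with outputs recomputed
#' from the new state. Deterministic given its arguments.
#'
#' @param params a [ctrnn_params()] object.
#' @param state a [ctrnn_state()] object.
#' @param input length-`n` external input vector (in the embodied model only
#'   neuron 1 receives nonzero input, already multiplied by the receptor
#'   gain).
#' @param h Euler step size (> 0, time units; default 0.1). One model "time
#'   step" is one Euler update.
#' @return The updated `ctrnn_state`.
#' @export
ctrnn_step <- function(params, state, input = rep(0, params$n), h = 0.1) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a positive scalar")
  input <- as.numeric(input)
  if (length(input) != params$n) stop("input must have length ", params$n)
  s <- state$s +
    (h / params$tau) * (-state$s + drop(crossprod(params$w, state$o)) + input)
  if (any(!is.finite(s)))
    stop("numerical blow-up in ctrnn_step (neuron ",
         which(!is.finite(s))[1L], ")")
  ctrnn_state(params, s)
}

# time derivative s-dot at state s under a constant input vector
ctrnn_deriv <- function(params, s, input) {
  o <- ctrnn_outputs(params, s)
  (-s + drop(crossprod(params$w, o)) + input) / params$tau
}

# Newton refinement of a root of -s + t(w) o(s) + I = 0, analytic Jacobian.
# Returns the refined point, or the starting point if Newton leaves the
# basin (step diverges or the Jacobian is singular).
ctrnn_newton <- function(params, s, input, tol = 1e-12, max_iter = 50L) {
  n <- params$n
  for (it in seq_len(max_iter)) {
    o <- ctrnn_outputs(params, s)
    f <- -s + drop(crossprod(params$w, o)) + input
    if (max(abs(f)) < tol) break
    J <- -diag(n) + t(params$w) * rep(o * (1 - o), each = n)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || max(abs(step)) > 1e6)
      return(s)
    s <- s - step
  }
  s
}

#' Numerically locate the equilibria of a clamped CTRNN
#'
#' Integrates the network from `n_starts` random initial states under a
#' constant input vector until the sup-norm of the state derivative falls
#' below `tol` (or the step budget runs out), merges nearby endpoints, and
#' polishes each distinct endpoint by Newton root-finding on the equilibrium
#' condition. The fraction of starts attracted to each equilibrium estimates
#' its basin size; a single equilibrium capturing all starts is the
#' single-globally-attracting-fixed-point signature reported for evolved
#' controllers of this model.
#'
#' @param params a [ctrnn_params()] object.
#' @param input clamped constant input vector (length `n`); the embodied
#'   analysis clamps neuron 1 to a post-gain value in `{0, r}`.
#' @param n_starts number of random initial states (default 100).
#' @param tol convergence tolerance on `max(abs(s-dot))` (default 1e-8).
#' @param merge_radius sup-norm radius within which endpoints are considered
#'   the same equilibrium (default 1e-4).
#' @param max_steps Euler step budget per start (default 1e6).
#' @param h Euler step size (default 0.1).
#' @param seed optional RNG seed for the random starts; the caller's RNG
#'   state is preserved.
#' @param start_range range from which initial states are drawn uniformly.
#' @return An object of class `ctrnn_equilibria`: list with `equilibria`
#'   (k x n matrix), `fraction` (share of starts per equilibrium),
#'   `residual` (sup-norm of s-dot at each), `converged` (did any start
#'   settle; `FALSE` flags a limit cycle or slow dynamics, not an error),
#'   `n_starts`, and `input`.
#' @export
find_equilibria <- function(params, input = rep(0, params$n), n_starts = 100L,
                            tol = 1e-8, merge_radius = 1e-4, max_steps = 1e6,
                            h = 0.1, seed = NULL, start_range = c(-10, 10)) {
  stopifnot(n_starts >= 1L, tol > 0, merge_radius > 0, h > 0)
  input <- as.numeric(input)
  if (length(input) != params$n || any(!is.finite(input)))
    stop("input must be a finite length-", params$n, " vector")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- params$n
  ends <- list()
  for (k in seq_len(n_starts)) {
    s0 <- runif(n, start_range[1], start_range[2])
    res <- ctrnn_settle(s0, params$tau, params$w, params$theta, input,
                        h, tol, max_steps)
    if (res$converged) ends[[length(ends) + 1L]] <- res$s
  }
  if (length(ends) == 0L) {
    return(structure(list(equilibria = matrix(numeric(0), 0L, n),
                          fraction = numeric(0), residual = numeric(0),
                          converged = FALSE, n_starts = n_starts,
                          input = input),
                     class = "ctrnn_equilibria"))
  }
  # greedy sup-norm clustering of endpoints
  centers <- list(); counts <- integer(0)
  for (s in ends) {
    hit <- 0L
    for (i in seq_along(centers)) {
      if (max(abs(s - centers[[i]])) <= merge_radius) { hit <- i; break }
    }
    if (hit > 0L) counts[hit] <- counts[hit] + 1L
    else { centers[[length(centers) + 1L]] <- s; counts <- c(counts, 1L) }
  }
  eq <- do.call(rbind, lapply(centers, function(s)
    ctrnn_newton(params, s, input)))
  resid <- vapply(seq_len(nrow(eq)), function(i)
    max(abs(ctrnn_deriv(params, eq[i, ], input))), numeric(1))
  structure(list(equilibria = eq, fraction = counts / n_starts,
                 residual = resid, converged = TRUE, n_starts = n_starts,
                 input = input),
            class = "ctrnn_equilibria")
}

#' @export
print.ctrnn_equilibria <- function(x, ...) {
  if (!x$converged) {
    cat("No start converged within budget (limit cycle or slow dynamics?)\n")
    return(invisible(x))
  }
  cat(nrow(x$equilibria), "equilibrium point(s) from", x$n_starts,
      "starts\n")
  for (i in seq_len(nrow(x$equilibria))) {
    cat(sprintf("  #%d  basin %.0f%%  residual %.2e  s = (%s)\n", i,
                100 * x$fraction[i], x$residual[i],
                paste(sprintf("%.3f", x$equilibria[i, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Equilibrium inventory as a function of clamped input
#'
#' Runs [find_equilibria()] for each clamped receptor-input value and tabulates
#' the per-input equilibrium sets. For an evolved controller the inventory
#' shifts in state space between the no-contact (0) and contact (`r`) clamp,
#' which is how a single-attractor network can still separate the two input
#' conditions: the attractor's pull, not a repertoire of attractors, encodes
#' the sensory state.
#'
#' @param params a [ctrnn_params()] object.
#' @param input_values clamped post-gain input values applied to neuron 1
#'   (default `c(0, params$r)`, the two conditions of the binary-contact
#'   model).
#' @param ... passed to [find_equilibria()].
#' @return An object of class `attractor_scan`: list with `input_values` and
#'   `inventories` (one `ctrnn_equilibria` per input value).
#' @export
attractor_scan <- function(params, input_values = c(0, params$r), ...) {
  input_values <- as.numeric(input_values)
  if (any(!is.finite(input_values))) stop("input values must be finite")
  inv <- lapply(input_values, function(v) {
    input <- rep(0, params$n); input[1L] <- v
    find_equilibria(params, input = input, ...)
  })
  structure(list(input_values = input_values, inventories = inv),
            class = "attractor_scan")
}

#' Shift of the dominant attractor between two input conditions
#'
#' Euclidean distance in state space between the largest-basin equilibria of
#' the first two input conditions of an [attractor_scan()]. `NA` if either
#' condition did not converge.
#'
#' @param scan an `attractor_scan` object.
#' @return A single distance (space of neuron states), or `NA`.
#' @export
attractor_shift <- function(scan) {
  if (length(scan$inventories) < 2L) return(NA_real_)
  a <- scan$inventories[[1L]]; b <- scan$inventories[[2L]]
  if (!a$converged || !b$converged) return(NA_real_)
  pa <- a$equilibria[which.max(a$fraction), ]
  pb <- b$equilibria[which.max(b$fraction), ]
  sqrt(sum((pa - pb)^2))
}

# RNG bookkeeping: preserve the caller's stream around seeded sections.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
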