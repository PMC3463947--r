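#' Configuration of one two-agent trial
#'
#' Encodes the trial protocol: agent 1's RF starts at `rf1_base + u1` and its
#' link at `d1_base + u2`, with `u1`, `u2` drawn once per trial from a
#' uniform distribution on `[-perturb_range, perturb_range]` (each
#' perturbation can be disabled); agent 2 starts exactly at `rf2_0` with link
#' `d2_0`. The nominal values (RFs at +10/-10, links at -20/+20) put each
#' agent's RF directly on the other's BO with body offset 0, so perturbations
#' are what make the task non-trivial. Neuron states always start at 0.
#'
#' @param steps number of time steps (>= 1, default 3000). One time step is
#'   one Euler update of size `h`.
#' @param h Euler step size (default 0.1 time units).
#' @param rf1_base,rf2_0 initial RF positions before perturbation (10, -10).
#' @param d1_base,d2_0 initial link distances before perturbation (-20, 20).
#' @param perturb_rf1,perturb_d1 apply the uniform perturbation to RF1 / D1?
#' @param perturb_range half-width of the uniform perturbation (1.5).
#' @param noise_sd standard deviation of the Gaussian movement noise added
#'   to the mapped motor output each step (default 0.05; 0 disables).
#' @param threshold button activation threshold (0.75).
#' @param contact_radius contact rule radius (0.5, inclusive).
#' @param seed optional RNG seed; a seeded trial is fully reproducible and
#'   leaves the caller's RNG state untouched.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(steps = 3000L, h = 0.1, rf1_base = 10, rf2_0 = -10,
                         d1_base = -20, d2_0 = 20, perturb_rf1 = TRUE,
                         perturb_d1 = TRUE, perturb_range = 1.5,
                         noise_sd = 0.05, threshold = 0.75,
                         contact_radius = 0.5, seed = NULL) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be >= 1")
  if (h <= 0) stop("h must be positive")
  if (perturb_range < 0) stop("perturb_range must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(steps = steps, h = h, rf1_base = rf1_base, rf2_0 = rf2_0,
                 d1_base = d1_base, d2_0 = d2_0,
                 perturb_rf1 = isTRUE(perturb_rf1),
                 perturb_d1 = isTRUE(perturb_d1),
                 perturb_range = perturb_range, noise_sd = noise_sd,
                 threshold = threshold, contact_radius = contact_radius,
                 seed = seed),
            class = "trial_config")
}

#' Initialize a trial: two clonal agents and their world
#'
#' Draws the enabled initial-condition perturbations (`u1` for RF1, `u2` for
#' D1) from the current RNG stream and builds agent 1 (mirror +1) and
#' agent 2 (mirror -1) sharing one decoded parameter set, neuron states
#' zeroed.
#'
#' @param config a [trial_config()].
#' @param params a [ctrnn_params()] (>= 4 neurons).
#' @return List with `agents` (list of two [agent_controller()]s), `world`
#'   (a [world_config()]) and `u = c(u1, u2)` (the realized perturbations,
#'   0 where disabled).
#' @export
init_trial <- function(config, params) {
  if (!inherits(config, "trial_config")) stop("config must be a trial_config")
  u1 <- if (config$perturb_rf1)
    runif(1, -config$perturb_range, config$perturb_range) else 0
  u2 <- if (config$perturb_d1)
    runif(1, -config$perturb_range, config$perturb_range) else 0
  a1 <- agent_controller(params, mirror = 1, rf_pos = config$rf1_base + u1,
                         d = config$d1_base + u2,
                         threshold = config$threshold)
  a2 <- agent_controller(params, mirror = -1, rf_pos = config$rf2_0,
                         d = config$d2_0, threshold = config$threshold)
  list(agents = list(a1, a2),
       world = world_config(contact_radius = config$contact_radius),
       u = c(u1 = u1, u2 = u2))
}

#' Run one coupled two-agent episode
#'
#' Synchronous loop, per step: (1) both agents sense contact on the previous
#' step's positions (the initial positions before the first network update);
#' (2) both controllers take one Euler step; (3) both motions and click
#' adjustments are applied; everything is recorded. Identical seeds give
#' bit-identical records.
#'
#' The `"cpp"` engine (default) runs the loop in compiled code; `"r"` runs
#' the same loop through the R-level operations ([agent_step()],
#' [apply_motion()], [click_to_body()]). Both consume the RNG identically
#' (two movement-noise draws per step, agent 1 first) and agree to numerical
#' round-off.
#'
#' @param config a [trial_config()].
#' @param params a [ctrnn_params()].
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `trial_record`: list with `series` (one row
#'   per step: positions, link distances, body offset, contact flags, all
#'   neuron outputs of both agents, click events), `init` (realized initial
#'   conditions), `config` and `seed`.
#' @export
run_trial <- function(config, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(config$seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(config$seed)
  }
  init <- init_trial(config, params)
  rf1_0 <- init$agents[[1L]]$body$rf_pos
  rf2_0 <- init$agents[[2L]]$body$rf_pos
  d1_0 <- init$agents[[1L]]$body$d
  d2_0 <- init$agents[[2L]]$body$d
  n <- params$n

  if (engine == "cpp") {
    res <- run_trial_core(config$steps, config$h, params$tau, params$w,
                          params$theta, params$r, params$e[["move"]],
                          params$e[["left"]], params$e[["right"]],
                          rf1_0, rf2_0, d1_0, d2_0, config$noise_sd,
                          config$threshold, config$contact_radius)
    o1 <- res$o_agent1; o2 <- res$o_agent2
    series <- data.frame(step = seq_len(config$steps), rf1 = res$rf1,
                         bo1 = res$rf1 + res$d1, d1 = res$d1, rf2 = res$rf2,
                         bo2 = res$rf2 + res$d2, d2 = res$d2,
                         offset = res$d1 + res$d2, contact1 = res$contact1,
                         contact2 = res$contact2)
    colnames(o1) <- paste0("o", seq_len(n), "_agent1")
    colnames(o2) <- paste0("o", seq_len(n), "_agent2")
    series <- cbind(series, as.data.frame(o1), as.data.frame(o2),
                    data.frame(clickL1 = res$clickL1, clickR1 = res$clickR1,
                               clickL2 = res$clickL2, clickR2 = res$clickR2))
  } else {
    series <- run_trial_r_engine(config, init)
  }
  structure(list(series = series, config = config, seed = config$seed,
                 init = list(rf1_0 = rf1_0, rf2_0 = rf2_0, d1_0 = d1_0,
                             d2_0 = d2_0, u = init$u)),
            class = "trial_record")
}

# Reference R implementation of the trial loop, built from the module-level
# operations; slow, used for cross-checking the compiled core.
run_trial_r_engine <- function(config, init) {
  a1 <- init$agents[[1L]]; a2 <- init$agents[[2L]]; world <- init$world
  n <- a1$params$n; steps <- config$steps
  num <- function() numeric(steps); int <- function() integer(steps)
  rf1 <- num(); rf2 <- num(); d1 <- num(); d2 <- num()
  c1 <- int(); c2 <- int()
  o1 <- matrix(0, steps, n); o2 <- matrix(0, steps, n)
  clL1 <- int(); clR1 <- int(); clL2 <- int(); clR2 <- int()
  for (t in seq_len(steps)) {
    c1[t] <- sense_contact(a1$body, a2$body, world)
    c2[t] <- sense_contact(a2$body, a1$body, world)
    z <- rnorm(2L)
    s1 <- agent_step(a1, c1[t], config$h, config$noise_sd * z[1L])
    s2 <- agent_step(a2, c2[t], config$h, config$noise_sd * z[2L])
    a1 <- s1$agent; a2 <- s2$agent
    a1$body <- apply_motion(a1$body, s1$velocity, config$h)
    a2$body <- apply_motion(a2$body, s2$velocity, config$h)
    a1 <- click_to_body(a1, s1$clicks)
    a2 <- click_to_body(a2, s2$clicks)
    rf1[t] <- a1$body$rf_pos; rf2[t] <- a2$body$rf_pos
    d1[t] <- a1$body$d; d2[t] <- a2$body$d
    o1[t, ] <- a1$state$o; o2[t, ] <- a2$state$o
    clL1[t] <- "left" %in% s1$clicks; clR1[t] <- "right" %in% s1$clicks
    clL2[t] <- "left" %in% s2$clicks; clR2[t] <- "right" %in% s2$clicks
  }
  colnames(o1) <- paste0("o", seq_len(n), "_agent1")
  colnames(o2) <- paste0("o", seq_len(n), "_agent2")
  cbind(data.frame(step = seq_len(steps), rf1 = rf1, bo1 = rf1 + d1,
                   d1 = d1, rf2 = rf2, bo2 = rf2 + d2, d2 = d2,
                   offset = d1 + d2, contact1 = c1, contact2 = c2),
        as.data.frame(o1), as.data.frame(o2),
        data.frame(clickL1 = clL1, clickR1 = clR1, clickL2 = clL2,
                   clickR2 = clR2))
}

#' @export
print.trial_record <- function(x, ...) {
  s <- x$series
  cat(sprintf("trial: %d steps (h = %g), initial offset %.3f\n",
              nrow(s), x$config$h, x$init$d1_0 + x$init$d2_0))
  cat(sprintf("  final offset %.3f; contact fraction %.2f/%.2f;",
              s$offset[nrow(s)], mean(s$contact1), mean(s$contact2)))
  cat(sprintf(" clicks L/R: agent1 %d/%d, agent2 %d/%d\n",
              sum(s$clickL1), sum(s$clickR1), sum(s$clickL2),
              sum(s$clickR2)))
  invisible(x)
}

#' Fitness components of one trial
#'
#' `C` is the fraction of steps in the trial's last `contact_frac` with at
#' least one contact flag on (did the agents establish and maintain an
#' interaction); `M = max(0, 1 - mean|offset| / offset_norm)` over the last
#' `offset_frac` of steps (did they match their configurations, normalized
#' by the largest initial offset). The trial's fitness is the even blend
#' `0.5 * C + 0.5 * M`, in `[0, 1]`.
#'
#' @param record a [run_trial()] record.
#' @param offset_norm normalizer for the offset term (default 1.5, the
#'   largest initial offset of the trial protocol).
#' @param contact_frac fraction of the trial, taken from the end, over which
#'   contact is scored (default 0.5, the second half).
#' @param offset_frac fraction of the trial, taken from the end, over which
#'   the offset mismatch is scored (default 0.5; matching is typically
#'   achieved well before mid-trial, so scoring the whole second half
#'   rewards matching early and holding it, not just ending well).
#' @return Named vector `c(C, M, fitness)`.
#' @export
fitness_components <- function(record, offset_norm = 1.5,
                               contact_frac = 0.5, offset_frac = 0.5) {
  s <- record$series
  steps <- nrow(s)
  cwin <- seq.int(steps - ceiling(contact_frac * steps) + 1L, steps)
  owin <- seq.int(steps - ceiling(offset_frac * steps) + 1L, steps)
  C <- mean(s$contact1[cwin] | s$contact2[cwin])
  M <- max(0, 1 - mean(abs(s$offset[owin])) / offset_norm)
  c(C = C, M = M, fitness = 0.5 * C + 0.5 * M)
}
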