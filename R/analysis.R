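#' The 7-trial body-offset sweep
#'
#' Systematically varies the initial D1 perturbation over a grid (default
#' `-1.5` to `1.5` by `0.5`, so the initial body offset equals the grid
#' value) with the RF-position perturbation disabled, and runs one trial per
#' grid value. This is the protocol behind the headline offset-convergence
#' result: a successful controller pulls every nonzero initial offset into
#' the mutual-contact window and keeps the offset-0 trial there.
#'
#' @param params a [ctrnn_params()].
#' @param base_config a [trial_config()]; its perturbations are forced off
#'   (the grid drives D1 deterministically). Default: 3000 steps, noise on.
#' @param grid initial-offset grid (added to the nominal D1 of -20).
#' @param seed optional base seed; trial `i` runs with `seed + i` (movement
#'   noise only, since perturbations are off).
#' @return An object of class `sweep_result`: list with `grid`, `records`
#'   (one [run_trial()] record per grid value) and `base_config`.
#' @export
run_sweep <- function(params, base_config = NULL,
                      grid = seq(-1.5, 1.5, by = 0.5), seed = NULL) {
  if (is.null(base_config)) base_config <- trial_config()
  base_config$perturb_rf1 <- FALSE
  base_config$perturb_d1 <- FALSE
  records <- lapply(seq_along(grid), function(i) {
    cfg <- base_config
    cfg$d1_base <- base_config$d1_base + grid[i]
    if (!is.null(seed)) cfg$seed <- seed + i
    tryCatch(run_trial(cfg, params),
             error = function(e) stop("sweep trial at grid value ", grid[i],
                                      " failed: ", conditionMessage(e),
                                      call. = FALSE))
  })
  structure(list(grid = grid, records = records, base_config = base_config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep of", length(x$records), "trials, initial offsets:",
      paste(x$grid, collapse = ", "), "\n")
  print(sweep_convergence(x))
  invisible(x)
}

#' Offset-convergence summary of a sweep
#'
#' For each trial: the initial and final body offset, the first step at
#' which `|offset|` enters the mutual-contact window, and whether it stayed
#' inside throughout.
#'
#' @param sweep a [run_sweep()] result.
#' @param window half-width of the mutual-contact window (default 1).
#' @return Data frame with one row per trial: `grid`, `init_offset`,
#'   `final_offset`, `first_in_window` (NA if never), `always_in_window`.
#' @export
sweep_convergence <- function(sweep, window = 1) {
  rows <- lapply(seq_along(sweep$records), function(i) {
    rec <- sweep$records[[i]]
    off <- rec$series$offset
    inside <- abs(off) <= window
    data.frame(grid = sweep$grid[i],
               init_offset = rec$init$d1_0 + rec$init$d2_0,
               final_offset = off[length(off)],
               first_in_window = if (any(inside)) which(inside)[1L]
                                 else NA_integer_,
               always_in_window = all(inside))
  })
  do.call(rbind, rows)
}

as_record_list <- function(records) {
  if (inherits(records, "sweep_result")) return(records$records)
  if (inherits(records, "trial_record")) return(list(records))
  records
}

#' Growth of link-distance diversity across trials
#'
#' At each step, pools the link distances of all trials, sign-aligned so
#' that the two agents are commensurable under mimicry: the pool is
#' `{D1 of each trial} + {-D2 of each trial}` (when offset is 0,
#' `D1 = -D2`). The per-step standard deviation of this pool measures how
#' diverse the realized body configurations are, and an ordinary
#' least-squares fit of sd against step gives the long-run trend; with
#' movement noise on, identically initialized trials spread apart and the
#' slope is positive.
#'
#' @param records a list of equal-length trial records (>= 2) or a
#'   `sweep_result`.
#' @return An object of class `link_diversity`: `step`, `sd` (per-step
#'   pooled sd), `slope`, `intercept` (OLS of sd on step), `n_trials`.
#' @export
link_diversity <- function(records) {
  records <- as_record_list(records)
  if (length(records) < 2L) stop("need at least 2 trial records")
  lens <- vapply(records, function(r) nrow(r$series), integer(1))
  if (length(unique(lens)) != 1L)
    stop("records must have identical lengths")
  pool <- cbind(vapply(records, function(r) r$series$d1, numeric(lens[1])),
                vapply(records, function(r) -r$series$d2, numeric(lens[1])))
  m <- ncol(pool)
  mu <- rowMeans(pool)
  sdser <- sqrt(rowSums((pool - mu)^2) / (m - 1))
  step <- seq_len(lens[1])
  fit <- lm(sdser ~ step)
  structure(list(step = step, sd = sdser,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_trials = length(records)),
            class = "link_diversity")
}

#' @export
print.link_diversity <- function(x, ...) {
  cat(sprintf(
    "link diversity over %d trials x %d steps: slope %.3e per step\n",
    x$n_trials, length(x$step), x$slope))
  invisible(x)
}

#' Clicking-role differentiation within a trial
#'
#' First-click step per agent (any button) and a role-division flag: roles
#' are divided when exactly one agent clicks within the first `window`
#' steps, or when both click but their first clicks are more than `window`
#' steps apart. Trials started with a nonzero body offset typically show
#' one agent (the one whose click direction corrects the offset) clicking
#' early while the other holds off until mutual contact is established.
#'
#' @param record a trial record.
#' @param window role-division window in steps (default 500).
#' @return List with `first_click` (named vector, NA = never clicked),
#'   `role_division` (logical), `clicker` (`"agent1"`, `"agent2"` or NA)
#'   and `window`.
#' @export
role_latency <- function(record, window = 500L) {
  s <- record$series
  first_of <- function(v) if (any(v > 0)) which(v > 0)[1L] else NA_integer_
  f1 <- first_of(s$clickL1 + s$clickR1)
  f2 <- first_of(s$clickL2 + s$clickR2)
  in1 <- !is.na(f1) && f1 <= window
  in2 <- !is.na(f2) && f2 <= window
  division <- xor(in1, in2) ||
    (!is.na(f1) && !is.na(f2) && abs(f1 - f2) > window)
  clicker <- NA_character_
  if (division) {
    if (is.na(f2) || (!is.na(f1) && f1 < f2)) clicker <- "agent1"
    else if (is.na(f1) || f2 < f1) clicker <- "agent2"
    else division <- FALSE  # simultaneous first clicks: no division
  }
  list(first_click = c(agent1 = f1, agent2 = f2),
       role_division = division, clicker = clicker, window = window)
}

#' Button-use counts
#'
#' Exact click-event counts per agent and side. Evolved solutions of this
#' model tend to adopt a left-button-only strategy (each agent only ever
#' grows `|D|`, relying on the partner to click when the offset requires
#' the opposite correction), which shows up as a zero right-button column.
#'
#' @param record a trial record.
#' @return List with `counts` (2 x 2 matrix, agents x sides) and
#'   `single_button` (TRUE when all clicks across both agents fall on one
#'   side).
#' @export
button_usage <- function(record) {
  s <- record$series
  counts <- matrix(c(sum(s$clickL1), sum(s$clickR1),
                     sum(s$clickL2), sum(s$clickR2)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c("agent1", "agent2"),
                                   c("left", "right")))
  side_tot <- colSums(counts)
  list(counts = counts,
       single_button = sum(side_tot > 0) == 1L)
}

spearman_safe <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(estimate = NA_real_, degenerate = TRUE, n = length(x)))
  list(estimate = suppressWarnings(cor(x, y, method = "spearman")),
       degenerate = FALSE, n = length(x))
}

#' Correlations between body offset and interaction properties
#'
#' Windows each trial (non-overlapping blocks of `window` steps) and
#' computes, per window, the mean `|offset|`, the contact frequency
#' (fraction of steps with at least one contact flag on), and the drift
#' (mean step-to-step velocity of the midpoint between RF1 and BO2 over the
#' window's contact steps; NA when the window has no contact). Pools the
#' windows of all records and reports Spearman rank correlations of
#' `|offset|` with contact frequency (expected negative: a smaller offset
#' lets contacts happen more often) and with `|drift|` (expected positive:
#' mismatched configurations make the interaction's locus drift sideways).
#'
#' @param records a trial record, list of records, or `sweep_result`.
#' @param window window length in steps (default 200; must not exceed the
#'   record length).
#' @return List with `table` (one row per window), `cor_offset_contact`,
#'   `cor_offset_drift` (each a list `estimate`/`degenerate`/`n`; a
#'   zero-variance pool is flagged degenerate, not an error).
#' @export
interaction_correlations <- function(records, window = 200L) {
  records <- as_record_list(records)
  if (length(records) < 1L) stop("need at least one record")
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  tabs <- lapply(seq_along(records), function(k) {
    s <- records[[k]]$series
    h <- records[[k]]$config$h
    steps <- nrow(s)
    if (window > steps) stop("window (", window,
                             ") longer than record (", steps, " steps)")
    nw <- floor(steps / window)
    mid <- (s$rf1 + s$bo2) / 2
    vel <- c(NA, diff(mid)) / h
    anyc <- (s$contact1 | s$contact2)
    do.call(rbind, lapply(seq_len(nw), function(i) {
      idx <- seq.int((i - 1L) * window + 1L, i * window)
      cidx <- idx[anyc[idx] & is.finite(vel[idx])]
      data.frame(record = k, window = i,
                 mean_abs_offset = mean(abs(s$offset[idx])),
                 contact_freq = mean(anyc[idx]),
                 drift = if (length(cidx) > 0) mean(vel[cidx]) else NA_real_)
    }))
  })
  tab <- do.call(rbind, tabs)
  list(table = tab,
       cor_offset_contact = spearman_safe(tab$mean_abs_offset,
                                          tab$contact_freq),
       cor_offset_drift = spearman_safe(tab$mean_abs_offset,
                                        abs(tab$drift)))
}

#' Sliding-window synchrony of the two agents' movement
#'
#' Pearson correlation, over a sliding window, between agent 1's mapped
#' movement output `2 * o2 - 1` and agent 2's mirrored one
#' `-(2 * o2 - 1)` (the mirror sign makes equal allocentric motion
#' correlate at +1). Values near 1 late in a trial are the model's
#' signature of behavioral and neural synchronization once mimicry is
#' established. Zero-variance windows yield NA (flagged, not an error).
#'
#' @param record a trial record.
#' @param window window length in steps (>= 2, default 200).
#' @return List with `series` (length = steps; entry `t` is the correlation
#'   over the window ending at `t`, NA for the first `window - 1` steps and
#'   for degenerate windows), `window`, and `rms_per_neuron` (RMS
#'   output difference per neuron between the agents over the whole trial).
#' @export
synchrony_index <- function(record, window = 200L) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  s <- record$series
  steps <- nrow(s)
  if (window > steps) stop("window longer than record")
  x <- 2 * s$o2_agent1 - 1
  y <- -(2 * s$o2_agent2 - 1)
  cs <- function(v) c(0, cumsum(v))
  wsum <- function(v) { c0 <- cs(v); c0[(window + 1L):(steps + 1L)] -
                          c0[1:(steps - window + 1L)] }
  Sx <- wsum(x); Sy <- wsum(y); Sxx <- wsum(x * x); Syy <- wsum(y * y)
  Sxy <- wsum(x * y)
  num <- window * Sxy - Sx * Sy
  dx <- pmax(window * Sxx - Sx^2, 0)
  dy <- pmax(window * Syy - Sy^2, 0)
  den <- sqrt(dx * dy)
  r <- ifelse(den < 1e-10, NA_real_, pmin(pmax(num / den, -1), 1))
  series <- c(rep(NA_real_, window - 1L), r)
  n <- record$config$steps
  o1 <- as.matrix(s[paste0("o", 1:8, "_agent1")])
  o2 <- as.matrix(s[paste0("o", 1:8, "_agent2")])
  rms <- sqrt(colMeans((o1 - o2)^2))
  names(rms) <- paste0("o", 1:8)
  list(series = series, window = window, rms_per_neuron = rms)
}

#' @describeIn run_sweep Plot the body-offset series of all sweep trials.
#' @param x a `sweep_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, ...) {
  off <- vapply(x$records, function(r) r$series$offset,
                numeric(nrow(x$records[[1]]$series)))
  graphics::matplot(off, type = "l", lty = 1, xlab = "time step",
                    ylab = "body offset (D1 + D2)", ...)
  graphics::abline(h = c(-1, 0, 1), lty = c(2, 1, 2), col = "grey50")
  invisible(x)
}

#' @describeIn link_diversity Plot the pooled sd series with its OLS trend.
#' @param x a `link_diversity` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.link_diversity <- function(x, ...) {
  graphics::plot(x$step, x$sd, type = "l", xlab = "time step",
                 ylab = "sd of pooled link distances", ...)
  graphics::abline(x$intercept, x$slope, col = "red", lwd = 2)
  invisible(x)
}
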