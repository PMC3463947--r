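#' Genotype of a clonal controller
#'
#' A unit-interval vector of 84 genes encoding, in order: the 64 connection
#' weights (column-major, `w[j, i]` = weight from j to i), 8 biases, 8 time
#' constants, the receptor gain, and the three effector gains (move, left,
#' right). Both agents of every evaluation decode the same genotype, so the
#' embodiment gains evolve together with the network.
#'
#' @param genes numeric vector, length 84, all in `[0, 1]`.
#' @return An object of class `genotype`.
#' @export
genotype <- function(genes) {
  genes <- as.numeric(genes)
  if (length(genes) != 84L)
    stop("genotype must have exactly 84 genes, got ", length(genes))
  bad <- which(!is.finite(genes) | genes < 0 | genes > 1)
  if (length(bad) > 0L)
    stop("gene ", bad[1L], " outside [0, 1]: ", genes[bad[1L]])
  structure(genes, class = "genotype")
}

#' Decoding ranges for each gene class
#'
#' Affine decoding targets: weights and biases in `[-8, 8]`, time constants
#' in `[1, 30]`, receptor gain in `[0, 10]`, effector gains in `[0, 1]`.
#'
#' @param w,theta,tau,r,e two-element `c(lo, hi)` ranges.
#' @return A list of ranges of class `gene_ranges`.
#' @export
gene_ranges <- function(w = c(-8, 8), theta = c(-8, 8), tau = c(1, 30),
                        r = c(0, 10), e = c(0, 1)) {
  rng <- list(w = w, theta = theta, tau = tau, r = r, e = e)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] >= v[2])
      stop("range for ", nm, " must be c(lo, hi) with lo < hi")
  }
  structure(rng, class = "gene_ranges")
}

#' Decode a genotype into CTRNN parameters
#'
#' Total, deterministic affine map per gene class; see [genotype()] for the
#' gene layout and [gene_ranges()] for the targets.
#'
#' @param geno a [genotype()] (or plain numeric vector of 84 unit-interval
#'   genes, validated).
#' @param ranges a [gene_ranges()].
#' @return A [ctrnn_params()] for an 8-neuron controller.
#' @export
decode_genotype <- function(geno, ranges = gene_ranges()) {
  g <- unclass(genotype(geno))
  aff <- function(x, r) r[1] + x * (r[2] - r[1])
  ctrnn_params(n = 8L,
               tau = aff(g[73:80], ranges$tau),
               w = matrix(aff(g[1:64], ranges$w), 8L, 8L),
               theta = aff(g[65:72], ranges$theta),
               r = aff(g[81], ranges$r),
               e = aff(g[82:84], ranges$e))
}

#' Encode CTRNN parameters back into a genotype
#'
#' Inverse of [decode_genotype()]; errors if any parameter lies outside its
#' decoding range.
#'
#' @param params a [ctrnn_params()] with 8 neurons.
#' @param ranges a [gene_ranges()].
#' @return A [genotype()].
#' @export
encode_params <- function(params, ranges = gene_ranges()) {
  if (params$n != 8L) stop("encoding is defined for 8-neuron controllers")
  inv <- function(x, r, what) {
    g <- (x - r[1]) / (r[2] - r[1])
    if (any(g < -1e-12 | g > 1 + 1e-12))
      stop(what, " outside decoding range [", r[1], ", ", r[2], "]")
    pmin(pmax(g, 0), 1)
  }
  genotype(c(inv(as.vector(params$w), ranges$w, "weight"),
             inv(params$theta, ranges$theta, "bias"),
             inv(params$tau, ranges$tau, "time constant"),
             inv(params$r, ranges$r, "receptor gain"),
             inv(unname(params$e), ranges$e, "effector gain")))
}

#' Genetic-algorithm configuration
#'
#' Generational GA with elitism, tournament selection, uniform crossover and
#' Gaussian creep mutation reflected at the `[0, 1]` gene bounds. Evaluation
#' runs `trials_per_eval` trials of `trial_steps` steps with initial-
#' condition perturbations enabled (without them an inert pair at the
#' nominal initialization already scores perfectly). Per-trial seeds are
#' held fixed within a generation and, by default, resampled across
#' generations (`fixed_eval_seeds = TRUE` freezes them for the whole run,
#' making the best-of-generation series non-decreasing under elitism).
#'
#' @param pop_size population size (>= 2, default 96).
#' @param generations number of generations (default 200).
#' @param elitism number of top genotypes copied unchanged (>= 1).
#' @param tournament tournament size for parent selection (default 3).
#' @param mutation_sd per-gene Gaussian mutation sd (default 0.05).
#' @param reset_rate per-gene probability of a uniform reset mutation
#'   applied after the Gaussian creep (default 0, i.e. creep only).
#' @param crossover_rate probability of uniform crossover (default 0.5).
#' @param trials_per_eval trials per fitness evaluation (default 15).
#' @param trial_steps steps per trial (default 3000).
#' @param champion_trials,champion_steps the run's champion is selected by
#'   re-evaluating every distinct generation leader (hall of fame) on this
#'   many fresh trials of this length (defaults 15 and 3000, the full
#'   evaluation protocol) and taking the argmax; per-generation evaluation
#'   can then be scaled down without the noisy final generation deciding
#'   which controller the run returns. `champion_trials = 0` returns the
#'   final generation's best instead.
#' @param h Euler step size (default 0.1).
#' @param noise_sd movement-noise sd during evaluation (default 0.05).
#' @param perturb_range initial-condition perturbation half-width (1.5).
#' @param offset_norm,contact_frac,offset_frac fitness-shape parameters,
#'   passed to [fitness_components()].
#' @param fixed_eval_seeds keep one set of trial seeds for all generations?
#' @param seed master RNG seed for the run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 96L, generations = 200L, elitism = 1L,
                      tournament = 3L, mutation_sd = 0.05,
                      reset_rate = 0, crossover_rate = 0.5,
                      trials_per_eval = 15L,
                      trial_steps = 3000L, champion_trials = 15L,
                      champion_steps = 3000L, h = 0.1, noise_sd = 0.05,
                      perturb_range = 1.5, offset_norm = 1.5,
                      contact_frac = 0.5, offset_frac = 0.5,
                      fixed_eval_seeds = FALSE, seed = NULL) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L) stop("pop_size must be >= 2")
  if (elitism < 1L || elitism >= pop_size)
    stop("elitism must be in [1, pop_size)")
  if (tournament < 1L || tournament > pop_size)
    stop("tournament size must be in [1, pop_size]")
  if (trials_per_eval < 1L) stop("trials_per_eval must be >= 1")
  if (mutation_sd < 0 || crossover_rate < 0 || crossover_rate > 1)
    stop("invalid operator rates")
  structure(list(pop_size = pop_size,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 tournament = as.integer(tournament),
                 mutation_sd = mutation_sd, reset_rate = reset_rate,
                 crossover_rate = crossover_rate,
                 trials_per_eval = as.integer(trials_per_eval),
                 trial_steps = as.integer(trial_steps),
                 champion_trials = as.integer(champion_trials),
                 champion_steps = as.integer(champion_steps), h = h,
                 noise_sd = noise_sd, perturb_range = perturb_range,
                 offset_norm = offset_norm, contact_frac = contact_frac,
                 offset_frac = offset_frac,
                 fixed_eval_seeds = isTRUE(fixed_eval_seeds), seed = seed),
            class = "ga_config")
}

# Trial configuration used during evolution: perturbations on.
eval_trial_config <- function(ga, seed) {
  trial_config(steps = ga$trial_steps, h = ga$h, noise_sd = ga$noise_sd,
               perturb_range = ga$perturb_range, seed = seed)
}

#' Evaluate a genotype against the trial protocol
#'
#' Decodes the genotype and runs one trial per seed in `trial_seeds`
#' (perturbed initial conditions, movement noise on), scoring each with
#' [fitness_components()]; the genotype's fitness is the mean over trials.
#' A trial that blows up numerically scores 0 with a warning.
#'
#' @param geno a [genotype()] or 84-gene vector.
#' @param ga a [ga_config()].
#' @param trial_seeds integer seeds, one per trial (default derived from
#'   the current RNG stream).
#' @param ranges a [gene_ranges()].
#' @return Scalar fitness in `[0, 1]` with attribute `per_trial` (matrix of
#'   per-trial `C`, `M`, `fitness`).
#' @export
evaluate_genotype <- function(geno, ga,
                              trial_seeds = sample.int(2147483646L,
                                                       ga$trials_per_eval),
                              ranges = gene_ranges()) {
  params <- decode_genotype(geno, ranges)
  per <- vapply(trial_seeds, function(s) {
    rec <- tryCatch(run_trial(eval_trial_config(ga, s), params),
                    error = function(e) {
                      warning("trial (seed ", s, ") failed: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(rec)) c(C = 0, M = 0, fitness = 0)
    else fitness_components(rec, offset_norm = ga$offset_norm,
                            contact_frac = ga$contact_frac,
                            offset_frac = ga$offset_frac)
  }, numeric(3L))
  structure(mean(per["fitness", ]), per_trial = per)
}

# one generational turnover: elitism + tournament selection + uniform
# crossover + Gaussian creep mutation reflected at the gene bounds
reproduce <- function(pop, fit, ga) {
  n_genes <- ncol(pop)
  ord <- order(fit, decreasing = TRUE)
  nxt <- matrix(0, ga$pop_size, n_genes)
  nxt[seq_len(ga$elitism), ] <- pop[ord[seq_len(ga$elitism)], ,
                                    drop = FALSE]
  pick <- function() {
    cand <- sample.int(ga$pop_size, ga$tournament, replace = FALSE)
    cand[which.max(fit[cand])]
  }
  for (i in seq.int(ga$elitism + 1L, ga$pop_size)) {
    p1 <- pop[pick(), ]
    child <- if (runif(1) < ga$crossover_rate) {
      p2 <- pop[pick(), ]
      mask <- runif(n_genes) < 0.5
      ifelse(mask, p1, p2)
    } else p1
    child <- reflect_unit(child + rnorm(n_genes, 0, ga$mutation_sd))
    if (ga$reset_rate > 0) {
      hit <- runif(n_genes) < ga$reset_rate
      child[hit] <- runif(sum(hit))
    }
    nxt[i, ] <- child
  }
  nxt
}

reflect_unit <- function(x) {
  for (i in 1:3) {
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > 1, 2 - x, x)
  }
  pmin(pmax(x, 0), 1)
}

#' Evolve a clonal controller
#'
#' Generational GA over [genotype()] vectors. Fully reproducible from
#' `ga$seed`; all randomness (population init, operator draws, per-trial
#' seeds) flows from that one stream. With `fixed_eval_seeds = TRUE` and
#' elitism the best-of-generation fitness series is non-decreasing.
#'
#' @param ga a [ga_config()].
#' @param ranges a [gene_ranges()].
#' @param checkpoint_path optional JSON path written after every generation;
#'   an interrupted run restarts from it with `resume = TRUE` and reproduces
#'   the uninterrupted run.
#' @param resume resume from `checkpoint_path` if it exists?
#' @param progress print per-generation summaries?
#' @return An object of class `evolution_result`: `best_genotype` (the
#'   run's champion, see `champion_trials`), `best_fitness` (the champion's
#'   re-evaluated fitness), `stats` (data frame
#'   gen/best/mean/sd), `hall_of_fame` (best genotype per generation),
#'   `eval_seeds` (final generation's trial seeds), `ga`, `ranges`.
#' @export
evolve <- function(ga, ranges = gene_ranges(), checkpoint_path = NULL,
                   resume = FALSE, progress = FALSE) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  if (!is.null(ga$seed)) set.seed(ga$seed)
  n_genes <- 84L
  gen_start <- 1L
  stats <- data.frame(gen = integer(0), best = numeric(0),
                      mean = numeric(0), sd = numeric(0))
  hof <- list()
  pop <- matrix(runif(ga$pop_size * n_genes), ga$pop_size, n_genes)
  eval_seeds <- NULL

  fit <- NULL
  if (resume && !is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    ck <- jsonlite::read_json(checkpoint_path, simplifyVector = TRUE)
    # genes and fitnesses are stored as C99 hex-float strings so the
    # restored run is bit-identical to the uninterrupted one
    pop <- matrix(as.numeric(ck$pop), nrow = nrow(ck$pop))
    fit <- as.numeric(ck$fit)
    gen_start <- ck$gen + 1L
    stats <- as.data.frame(ck$stats)
    hof <- lapply(seq_len(nrow(ck$hof)), function(i)
      as.numeric(ck$hof[i, ]))
    eval_seeds <- as.integer(ck$eval_seeds)
    assign(".Random.seed", as.integer(ck$rng), envir = globalenv())
    if (gen_start > ga$generations)
      stop("checkpoint already covers all ", ga$generations, " generations")
  }

  for (gen in seq.int(gen_start, ga$generations)) {
    if (gen > 1L) pop <- reproduce(pop, fit, ga)
    if (is.null(eval_seeds) || !ga$fixed_eval_seeds)
      eval_seeds <- sample.int(2147483646L, ga$trials_per_eval)
    fit <- apply(pop, 1L, function(g)
      as.numeric(evaluate_genotype(g, ga, eval_seeds, ranges)))
    stats <- rbind(stats, data.frame(gen = gen, best = max(fit),
                                     mean = mean(fit), sd = sd(fit)))
    hof[[gen]] <- pop[which.max(fit), ]
    if (progress)
      message(sprintf("gen %3d  best %.4f  mean %.4f", gen, max(fit),
                      mean(fit)))
    if (!is.null(checkpoint_path)) {
      hex <- function(x) if (is.matrix(x)) matrix(sprintf("%a", x), nrow(x))
                         else sprintf("%a", x)
      jsonlite::write_json(
        list(gen = gen, pop = hex(pop), fit = hex(fit), stats = stats,
             hof = hex(do.call(rbind, hof)), eval_seeds = eval_seeds,
             rng = get_rng_state()),
        checkpoint_path, auto_unbox = TRUE, digits = NA)
    }
  }

  best <- which.max(fit)
  best_geno <- pop[best, ]
  best_fit <- fit[best]
  if (ga$champion_trials > 0L) {
    cands <- unique(hof)
    champ_ga <- ga
    champ_ga$trials_per_eval <- ga$champion_trials
    champ_ga$trial_steps <- ga$champion_steps
    champ_seeds <- sample.int(2147483646L, ga$champion_trials)
    refit <- vapply(cands, function(g)
      as.numeric(evaluate_genotype(g, champ_ga, champ_seeds, ranges)),
      numeric(1))
    best_geno <- cands[[which.max(refit)]]
    best_fit <- max(refit)
  }
  structure(list(best_genotype = genotype(best_geno),
                 best_fitness = best_fit, stats = stats,
                 hall_of_fame = lapply(hof, genotype),
                 eval_seeds = eval_seeds, ga = ga, ranges = ranges),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("GA run: %d generations, population %d\n",
              nrow(x$stats), x$ga$pop_size))
  if (x$ga$champion_trials > 0L)
    cat(sprintf("  champion fitness %.4f (re-evaluated on %d x %d-step trials)\n",
                x$best_fitness, x$ga$champion_trials, x$ga$champion_steps))
  else
    cat(sprintf("  best fitness %.4f (final generation's %d eval trials)\n",
                x$best_fitness, x$ga$trials_per_eval))
  invisible(x)
}
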