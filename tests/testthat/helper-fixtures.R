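# Small fixtures shared across test files; everything is built in code.

# inert clonal controller: zero weights, zero biases, movement output pinned
# at 0.5 so velocity is 0 and no button ever reaches threshold
inert_params <- function() decode_genotype(rep(0.5, 84))

# single leaky integrator, no coupling: closed form s(t) = I (1 - e^(-t/tau))
single_neuron <- function(tau = 1, w11 = 0, theta = 0) {
  ctrnn_params(n = 1L, tau = tau, w = matrix(w11, 1, 1), theta = theta,
               g = 1, r = 1, e = c(1, 0, 0))
}

# random (but seeded) full controller via the genotype decoder
random_params <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  decode_genotype(runif(84))
}

# seeded random genotype vector (unit interval genes)
random_params_genes <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  runif(84)
}

# a genotype biased toward visible behavior: moving (theta2 > 0) and
# clicking (strong receptor-to-left-button weight, slow-ish button neuron)
busy_genes <- function() {
  g <- rep(0.5, 84)
  g[66] <- 0.60                 # theta2: movement output above 0.5
  g[1 + 8 * 2] <- 1.0           # w[1,3]: receptor drives left button
  g[67] <- 0.70                 # theta3: left button near threshold
  g[73:80] <- 0.05              # fast time constants
  g[81] <- 0.8                  # receptor gain
  g
}

# synthetic trial record for analysis-metric unit tests; any column can be
# overridden, everything else defaults to an inert trace
fake_record <- function(n, d1 = rep(-20, n), d2 = rep(20, n),
                        contact1 = rep(0L, n), contact2 = rep(0L, n),
                        rf1 = rep(10, n), rf2 = rep(-10, n),
                        o2_1 = rep(0.5, n), o2_2 = rep(0.5, n),
                        clickL1 = rep(0L, n), clickR1 = rep(0L, n),
                        clickL2 = rep(0L, n), clickR2 = rep(0L, n),
                        h = 0.1) {
  series <- data.frame(step = seq_len(n), rf1 = rf1, bo1 = rf1 + d1,
                       d1 = d1, rf2 = rf2, bo2 = rf2 + d2, d2 = d2,
                       offset = d1 + d2, contact1 = contact1,
                       contact2 = contact2)
  outs <- matrix(0.5, n, 16)
  colnames(outs) <- c(paste0("o", 1:8, "_agent1"),
                      paste0("o", 1:8, "_agent2"))
  outs[, "o2_agent1"] <- o2_1
  outs[, "o2_agent2"] <- o2_2
  series <- cbind(series, as.data.frame(outs),
                  data.frame(clickL1 = clickL1, clickR1 = clickR1,
                             clickL2 = clickL2, clickR2 = clickR2))
  structure(list(series = series,
                 config = trial_config(steps = n, h = h),
                 seed = NULL,
                 init = list(rf1_0 = rf1[1], rf2_0 = rf2[1],
                             d1_0 = d1[1], d2_0 = d2[1])),
            class = "trial_record")
}
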