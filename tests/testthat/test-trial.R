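test_that("initialization follows the trial protocol", {
  p <- inert_params()
  cfg <- trial_config(perturb_rf1 = FALSE, perturb_d1 = FALSE)
  init <- init_trial(cfg, p)
  expect_identical(init$agents[[1]]$body$rf_pos, 10)
  expect_identical(init$agents[[2]]$body$rf_pos, -10)
  expect_identical(init$agents[[1]]$body$d, -20)
  expect_identical(init$agents[[2]]$body$d, 20)
  expect_identical(body_offset(init$agents[[1]]$body,
                               init$agents[[2]]$body), 0)
  expect_identical(init$agents[[1]]$body$mirror, 1)
  expect_identical(init$agents[[2]]$body$mirror, -1)
  expect_identical(init$agents[[1]]$state$s, rep(0, 8))

  # a -1.5 D1 shift reproduces the representative-trial initial offset
  cfg2 <- trial_config(d1_base = -21.5, perturb_rf1 = FALSE,
                       perturb_d1 = FALSE)
  init2 <- init_trial(cfg2, p)
  expect_identical(body_offset(init2$agents[[1]]$body,
                               init2$agents[[2]]$body), -1.5)

  # perturbations are drawn from the seeded stream, within range
  cfg3 <- trial_config()
  set.seed(21); a <- init_trial(cfg3, p)
  set.seed(21); b <- init_trial(cfg3, p)
  expect_identical(a$u, b$u)
  expect_true(all(abs(a$u) <= 1.5))
})

test_that("nominal start puts both agents in contact at step one", {
  p <- inert_params()
  cfg <- trial_config(steps = 5, perturb_rf1 = FALSE, perturb_d1 = FALSE,
                      noise_sd = 0, seed = 1)
  rec <- run_trial(cfg, p)
  expect_identical(rec$series$contact1[1], 1L)
  expect_identical(rec$series$contact2[1], 1L)
})

test_that("inert controllers leave the world constant", {
  p <- inert_params()
  p$e[] <- 0
  cfg <- trial_config(steps = 200, seed = 8)
  rec <- run_trial(cfg, p)
  s <- rec$series
  expect_true(all(s$rf1 == s$rf1[1]))
  expect_true(all(s$d1 == s$d1[1]))
  expect_true(all(s$offset == s$offset[1]))
  expect_true(all(s$clickL1 == 0 & s$clickR2 == 0))
})

test_that("identical seeds give bit-identical records", {
  p <- random_params(9)
  cfg <- trial_config(steps = 300, seed = 123)
  r1 <- run_trial(cfg, p)
  r2 <- run_trial(cfg, p)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$init, r2$init)
})

test_that("the compiled engine reproduces the R-level operations", {
  for (gen in list(busy_genes(), runif(84))) {
    p <- decode_genotype(gen)
    cfg <- trial_config(steps = 150, seed = 77)
    a <- run_trial(cfg, p, engine = "cpp")
    b <- run_trial(cfg, p, engine = "r")
    expect_equal(as.matrix(a$series), as.matrix(b$series),
                 tolerance = 1e-12)
    # the busy genotype must actually exercise the click path
  }
  p <- decode_genotype(busy_genes())
  rec <- run_trial(trial_config(steps = 400, seed = 3), p)
  expect_gt(sum(rec$series$clickL1 + rec$series$clickL2), 0)
})

test_that("the record is internally consistent (rigid link, schema)", {
  p <- decode_genotype(busy_genes())
  rec <- run_trial(trial_config(steps = 250, seed = 5), p)
  s <- rec$series
  expect_identical(nrow(s), 250L)
  expect_equal(s$bo1, s$rf1 + s$d1)
  expect_equal(s$bo2, s$rf2 + s$d2)
  expect_equal(s$offset, s$d1 + s$d2)
  expect_true(all(c(paste0("o", 1:8, "_agent1"),
                    paste0("o", 1:8, "_agent2"),
                    "clickL1", "clickR1", "clickL2", "clickR2")
                  %in% names(s)))
})

test_that("offset changes only at click events, by the effector steps", {
  p <- decode_genotype(busy_genes())
  rec <- run_trial(trial_config(steps = 500, seed = 6), p)
  s <- rec$series
  d_off <- diff(c(rec$init$d1_0 + rec$init$d2_0, s$offset))
  eL <- p$e[["left"]]; eR <- p$e[["right"]]
  expected <- -eL * s$clickL1 + eR * s$clickR1 +
    eL * s$clickL2 - eR * s$clickR2
  expect_equal(d_off, expected, tolerance = 1e-10)
})

test_that("noiseless unperturbed trials are seed-independent", {
  p <- random_params(2)
  cfg1 <- trial_config(steps = 200, noise_sd = 0, perturb_rf1 = FALSE,
                       perturb_d1 = FALSE, seed = 1)
  cfg2 <- cfg1; cfg2$seed <- 999
  expect_identical(run_trial(cfg1, p)$series, run_trial(cfg2, p)$series)
})

test_that("relabeling the agents and negating the axis mirrors the trial", {
  # clonal controllers: agent 1 perturbed by (a, b) maps onto a trial with
  # agent 2 started at the negated positions; offset series negates
  p <- decode_genotype(busy_genes())
  a <- 0.7; b <- -1.1
  cfgA <- trial_config(steps = 300, noise_sd = 0, perturb_rf1 = FALSE,
                       perturb_d1 = FALSE, rf1_base = 10 + a,
                       d1_base = -20 + b, seed = 1)
  cfgB <- trial_config(steps = 300, noise_sd = 0, perturb_rf1 = FALSE,
                       perturb_d1 = FALSE, rf2_0 = -10 - a,
                       d2_0 = 20 - b, seed = 1)
  A <- run_trial(cfgA, p)$series
  B <- run_trial(cfgB, p)$series
  expect_equal(B$rf2, -A$rf1, tolerance = 1e-12)
  expect_equal(B$rf1, -A$rf2, tolerance = 1e-12)
  expect_equal(B$d1, -A$d2, tolerance = 1e-12)
  expect_equal(B$d2, -A$d1, tolerance = 1e-12)
  expect_equal(B$offset, -A$offset, tolerance = 1e-12)
  expect_identical(B$contact1, A$contact2)
  expect_identical(B$contact2, A$contact1)
})

test_that("fitness components score the two halves of the task", {
  p <- inert_params()
  cfg <- trial_config(steps = 100, perturb_rf1 = FALSE, perturb_d1 = FALSE,
                      noise_sd = 0, seed = 1)
  f <- fitness_components(run_trial(cfg, p))
  # inert pair at the exact nominal start: permanent contact, zero offset
  expect_identical(unname(f), c(1, 1, 1))
  # never in contact and offset held beyond the normalizer scores zero
  rec <- fake_record(100, d1 = rep(-20, 100), d2 = rep(22, 100))
  expect_identical(unname(fitness_components(rec)), c(0, 0, 0))
})
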