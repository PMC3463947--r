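test_that("the offset sweep covers the grid exactly", {
  p <- inert_params()
  base <- trial_config(steps = 40, noise_sd = 0)
  sw <- run_sweep(p, base, seed = 1)
  expect_length(sw$records, 7L)
  expect_identical(sw$grid, seq(-1.5, 1.5, by = 0.5))
  cv <- sweep_convergence(sw)
  expect_identical(cv$init_offset, sw$grid)
  # inert controller: every offset series constant at its initial value
  expect_identical(cv$final_offset, cv$init_offset)
  # degenerate single-value grid
  sw0 <- run_sweep(p, base, grid = 0, seed = 1)
  expect_length(sw0$records, 1L)
  expect_identical(sweep_convergence(sw0)$init_offset, 0)
})

test_that("link diversity is zero for identical or shifted trials", {
  n <- 100
  base <- fake_record(n)
  ld <- link_diversity(list(base, base, base))
  expect_identical(max(abs(ld$sd)), 0)
  expect_equal(ld$slope, 0)
  # trials differing by a constant d1 shift: constant sd, zero slope
  shifted <- lapply(c(0, 0.5, 1), function(s) fake_record(n, d1 = rep(-20 + s, n)))
  ld2 <- link_diversity(shifted)
  expect_equal(ld2$sd, rep(ld2$sd[1], n))
  expect_equal(ld2$slope, 0, tolerance = 1e-12)
  expect_error(link_diversity(list(base)), "at least 2")
  expect_error(link_diversity(list(base, fake_record(50))), "identical")
})

test_that("noisy evolved-style trials show growing link diversity", {
  # a hand-built random-walk surrogate: occasional complementary click
  # drift makes trials diverge, the pooled sd must trend upward
  set.seed(42)
  n <- 2000
  recs <- lapply(1:7, function(i) {
    clicks <- rbinom(n, 1, 0.01)
    d1 <- -20 - cumsum(clicks * 0.25)
    fake_record(n, d1 = d1, d2 = rep(20, n))
  })
  expect_gt(link_diversity(recs)$slope, 0)
})

test_that("role division is flagged from first-click asymmetry", {
  n <- 2000
  only_a2 <- fake_record(n, clickL2 = as.integer(seq_len(n) %in% c(100, 300)))
  rl <- role_latency(only_a2, window = 1000)
  expect_true(rl$role_division)
  expect_identical(rl$clicker, "agent2")
  expect_identical(unname(rl$first_click), c(NA_integer_, 100L))

  neither <- fake_record(n)
  rl2 <- role_latency(neither)
  expect_false(rl2$role_division)
  expect_true(all(is.na(rl2$first_click)))

  simultaneous <- fake_record(n, clickL1 = as.integer(seq_len(n) == 50),
                              clickL2 = as.integer(seq_len(n) == 50))
  rl3 <- role_latency(simultaneous, window = 500)
  expect_false(rl3$role_division)

  # both click early but far apart: division by latency difference
  spread <- fake_record(n, clickL1 = as.integer(seq_len(n) == 10),
                        clickL2 = as.integer(seq_len(n) == 1500))
  rl4 <- role_latency(spread, window = 500)
  expect_true(rl4$role_division)
  expect_identical(rl4$clicker, "agent1")
})

test_that("button usage counts events and detects one-button strategies", {
  n <- 500
  rec <- fake_record(n,
                     clickL1 = as.integer(seq_len(n) %in% c(3, 9, 40, 60, 90)),
                     clickL2 = as.integer(seq_len(n) %in% c(10, 20)))
  bu <- button_usage(rec)
  expect_identical(bu$counts["agent1", "left"], 5L)
  expect_identical(bu$counts["agent1", "right"], 0L)
  expect_identical(bu$counts["agent2", "left"], 2L)
  expect_true(bu$single_button)
  bu2 <- button_usage(fake_record(n))
  expect_identical(sum(bu2$counts), 0L)
  expect_false(button_usage(
    fake_record(n, clickL1 = as.integer(seq_len(n) == 1),
                clickR2 = as.integer(seq_len(n) == 2)))$single_button)
})

test_that("offset-contact correlation recovers a constructed dependency", {
  # 10 windows of 100 steps: |offset| falls exactly as contact rises
  n <- 1000; w <- 100
  offs <- rep(seq(1.0, 0.1, by = -0.1), each = w)
  dens <- rep(seq(0.05, 0.95, by = 0.1), each = w)
  contact1 <- as.integer((seq_len(n) %% w) < dens * w)
  rec <- fake_record(n, d1 = offs - 20, d2 = rep(20, n),
                     contact1 = contact1)
  ic <- interaction_correlations(rec, window = w)
  expect_equal(ic$cor_offset_contact$estimate, -1)
  expect_false(ic$cor_offset_contact$degenerate)

  # constant offset and contact: both correlations degenerate, flagged
  flat <- fake_record(n, contact1 = rep(1L, n))
  ic2 <- interaction_correlations(flat, window = w)
  expect_true(ic2$cor_offset_contact$degenerate)
  expect_true(is.na(ic2$cor_offset_contact$estimate))

  expect_error(interaction_correlations(fake_record(50), window = 100),
               "longer than record")
})

test_that("drift correlates with offset in a constructed record", {
  # midpoint velocity magnitude rises with |offset| across windows
  n <- 1000; w <- 100
  offs <- rep(seq(0.1, 1.0, by = 0.1), each = w)
  vel <- rep(seq(0.02, 0.2, by = 0.02), each = w)   # per-step drift
  rf1 <- cumsum(vel)
  rec <- fake_record(n, d1 = offs - 20, d2 = rep(20, n), rf1 = rf1,
                     contact1 = rep(1L, n))
  ic <- interaction_correlations(rec, window = w)
  expect_equal(ic$cor_offset_drift$estimate, 1)
})

test_that("synchrony is +1 for mirrored-equal movement, -1 for opposed", {
  n <- 600
  x <- 0.5 + 0.3 * sin(seq_len(n) / 10)
  same <- fake_record(n, o2_1 = x, o2_2 = 1 - x)   # mirrored equal
  s1 <- synchrony_index(same, window = 100)
  expect_true(all(is.na(s1$series[1:99])))
  expect_equal(unique(round(s1$series[-(1:99)], 10)), 1)
  opposed <- fake_record(n, o2_1 = x, o2_2 = x)    # allocentrically opposed
  s2 <- synchrony_index(opposed, window = 100)
  expect_equal(unique(round(s2$series[-(1:99)], 10)), -1)
  # zero-variance windows flagged as NA, not an error
  flat <- fake_record(n)
  s3 <- synchrony_index(flat, window = 100)
  expect_true(all(is.na(s3$series)))
  expect_named(s3$rms_per_neuron, paste0("o", 1:8))
})

test_that("analysis functions never re-simulate (pure functions of records)", {
  p <- decode_genotype(busy_genes())
  rec <- run_trial(trial_config(steps = 300, seed = 2), p)
  a <- role_latency(rec)
  b <- role_latency(rec)
  expect_identical(a, b)
  expect_identical(button_usage(rec), button_usage(rec))
})
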