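# Population model: labelling-index formula, simulator, and the
# differential exposure time estimators.

test_that("expected labelling index follows the random-phase model", {
  expect_equal(expected_labelling_index(3, 0, 12), 0.25)
  expect_equal(expected_labelling_index(3, 9, 12), 1)
  expect_equal(expected_labelling_index(2, 1, 10, 0.5), 0.15)
  # saturation: T_S + T_exp beyond T_C cannot exceed GF
  expect_equal(expected_labelling_index(3, 30, 12, 0.8), 0.8)
  expect_error(expected_labelling_index(3, 1, 0), "positive")
  expect_error(expected_labelling_index(3, 1, -2), "positive")
})

test_that("expected labelling index is monotone in its arguments", {
  ts <- seq(0.5, 6, by = 0.5)
  te <- seq(0, 8, by = 0.5)
  tc <- seq(9, 40, by = 1)
  expect_true(all(diff(expected_labelling_index(ts, 2, 12)) >= 0))
  expect_true(all(diff(expected_labelling_index(3, te, 12)) >= 0))
  expect_true(all(diff(expected_labelling_index(3, 2, tc)) <= 0))
})

test_that("exposure schedules must be nested and positive", {
  s <- exposure_schedule(4, 1)
  expect_equal(s$delta_t_h, 3)
  expect_error(exposure_schedule(1, 4), "nested")
  expect_error(exposure_schedule(4, 0), "nested")
  expect_error(exposure_schedule(4, 4), "nested")
})

test_that("simulated labelled fractions match the closed form", {
  # T_C = 24, T_S = 6, exposures 4/1: expected long fraction 10/24
  sched <- exposure_schedule(4, 1)
  pop <- simulate_population(
    population_params(24, 6, n_cells = 500, seed = 7), sched)
  p <- 10 / 24
  ci <- qnorm(0.995) * sqrt(p * (1 - p) / 500)
  expect_lt(abs(mean(pop$labelled_long) - p), ci + 1 / 500)
  # closed-form agreement within 4 binomial SEs at n = 10,000, several regimes
  for (par in list(c(8, 3, 1), c(40, 8, 1), c(24, 6, 0.6))) {
    pp <- population_params(par[1], par[2], par[3], n_cells = 10000, seed = 11)
    pop <- simulate_population(pp, sched)
    for (ch in c("long", "short")) {
      te <- if (ch == "long") 4 else 1
      p <- expected_labelling_index(par[2], te, par[1], par[3])
      se <- sqrt(p * (1 - p) / 10000)
      expect_lt(abs(mean(pop[[paste0("labelled_", ch)]]) - p), 4 * se)
    }
  }
})

test_that("simulation respects nesting, growth fraction and seeding", {
  sched <- exposure_schedule(4, 1)
  pop <- simulate_population(population_params(12, 3, n_cells = 2000, seed = 3),
                             sched)
  expect_true(all(pop$labelled_long[pop$labelled_short]))
  none <- simulate_population(
    population_params(12, 3, growth_fraction = 0, n_cells = 500, seed = 3),
    sched)
  expect_equal(sum(none$labelled_long), 0)
  expect_equal(sum(none$labelled_short), 0)
  a <- simulate_population(population_params(12, 3, n_cells = 100, seed = 42), sched)
  b <- simulate_population(population_params(12, 3, n_cells = 100, seed = 42), sched)
  expect_identical(a, b)
  expect_warning(
    simulate_population(population_params(3, 1, n_cells = 10, seed = 1),
                        exposure_schedule(4, 1)),
    "exceeds the cycle length")
})

test_that("cycle-length estimator inverts the labelling difference", {
  est <- estimate_cycle_length(0.5, 0.125, delta_t_h = 3)
  expect_equal(est$t_c_h, 8)
  expect_false(est$censored)
  # zero information censors at the cap
  est0 <- estimate_cycle_length(0.2, 0.2, delta_t_h = 3, max_cycle_h = 32)
  expect_true(est0$censored)
  expect_equal(est0$t_c_h, 32)
  # exact boundary dF = delta_t / max_cycle is censored ("> 32 h")
  estb <- estimate_cycle_length(0.2, 0.2 - 3 / 32, delta_t_h = 3, max_cycle_h = 32)
  expect_true(estb$censored)
  # just inside the boundary resolves
  esti <- estimate_cycle_length(0.2, 0.2 - 3 / 31, delta_t_h = 3, max_cycle_h = 32)
  expect_false(esti$censored)
  expect_equal(esti$t_c_h, 31)
  # growth fraction rescales: with GF the estimate is true T_C, without it
  # the population doubling time
  expect_equal(estimate_cycle_length(0.5, 0.125, 3, growth_fraction = 0.5)$t_c_h, 4)
  expect_error(estimate_cycle_length(0.1, 0.3, 3), "inconsistent")
  expect_error(estimate_cycle_length(1.2, 0.1, 3), "\\[0, 1\\]")
})

test_that("S-phase estimator inverts the short index and clamps at zero", {
  expect_equal(estimate_s_phase(0.5, 8, 1)$t_s_h, 3)
  expect_equal(estimate_s_phase(1 / 8, 8, 1)$t_s_h, 0)  # f_short T_C = T_exp
  expect_warning(res <- estimate_s_phase(0.05, 8, 1), "clamped")
  expect_equal(res$t_s_h, 0)
  cens <- estimate_s_phase(0.3, 32, 1, censored = TRUE)
  expect_true(cens$censored)
  expect_equal(format_cycle_length(32, TRUE), "> 32 h")
})

test_that("replicated experiments recover the cycle length with small bias", {
  sched <- exposure_schedule(4, 1)
  sim <- simulate_cycle_experiment(
    population_params(8, 3, n_cells = 2000, seed = 19), sched,
    replicates = 100)
  expect_equal(nrow(sim), 100)
  # round-trip relative bias below 2% averaged over replicates
  expect_lt(abs(mean(sim$t_c_h) - 8) / 8, 0.02)
  expect_true(all(sim$f_long >= sim$f_short))
  g <- glance(sim)
  expect_equal(g$replicates, 100)
  expect_lt(abs(g$bias_h), 0.2)
  # same seed reproduces the whole experiment
  sim2 <- simulate_cycle_experiment(
    population_params(8, 3, n_cells = 2000, seed = 19), sched,
    replicates = 100)
  expect_equal(sim$t_c_h, sim2$t_c_h)
})
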