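test_that("dilution renormalizes the final biomass to rho0", {
  env <- env2n(c0 = 1)
  s <- strategy_set(rbind(c(0.4, 0.6), c(0.8, 0.2)))
  res <- run_batch(c(4e-4, 6e-4), s, env)
  inoc <- dilute(res, 1e-3)
  expect_equal(sum(inoc), 1e-3)
  expect_equal(inoc / sum(inoc), res$rho_final / sum(res$rho_final))

  fake <- res
  fake$rho_final <- c(0.6, 0.4)
  expect_equal(dilute(fake, 1e-3), c(6e-4, 4e-4))
})

test_that("a monoculture is at steady state after a single batch", {
  env <- env2n(c0 = 1)
  s <- strategy_set(matrix(c(0.5, 0.5), 1))
  ss <- run_to_steady_state(1, s, env)
  expect_true(ss$converged)
  expect_equal(ss$batches_used, 1L)
  expect_equal(ss$rho_star, 1e-3)
  expect_true(ss$survivors)
  expect_equal(ss$diversity$m_e, 1)
})

test_that("equal inocula under balanced supply are already the steady state", {
  s <- equally_spaced_strategies(21)
  env <- env2n(c0 = 1)
  ss <- run_to_steady_state(rep(1, 21), s, env)
  expect_true(ss$converged)
  expect_equal(ss$rho_star, rep(1e-3 / 21, 21), tolerance = 1e-8)
  expect_true(all(ss$survivors))
  expect_equal(sum(ss$rho_star), 1e-3, tolerance = 1e-12)
})

test_that("the steady state satisfies the dilution scaling relation", {
  s <- equally_spaced_strategies(7)
  env <- env2n(c0 = 0.5, supply = c(0.35, 0.65))
  ss <- run_to_steady_state(rep(1, 7), s, env,
                            control = protocol_control(max_batches = 5000,
                                                       steady_state_tol = 1e-8))
  expect_true(ss$converged)
  expect_true(is.finite(ss$convergence_rate) && ss$convergence_rate < 1)
  fold <- (env$rho0 + env$c0) / env$rho0
  expect_equal(ss$last_batch$rho_final, fold * ss$rho_star,
               tolerance = 1e-6)
})

test_that("supply outside the strategy hull leaves one survivor", {
  set.seed(99)
  s <- random_two_nutrient_community(4)
  # supply to the left of all strategies, small bolus (chemostat-like)
  x <- min(s$alpha[, 1]) - 0.1
  env <- env2n(c0 = 1e-4, supply = c(x, 1 - x))
  ss <- run_to_steady_state(rep(1, 4), s, env,
                            control = protocol_control(max_batches = 4000))
  expect_equal(sum(ss$survivors), 1L)
  expect_equal(which(ss$survivors), which.min(s$alpha[, 1]))
})

test_that("bottleneck sampling keeps exact cell bookkeeping", {
  env <- env2n(c0 = 1)
  s <- equally_spaced_strategies(5)
  res <- run_batch(rep(2e-4, 5), s, env)
  pool <- rep(1 / 5, 5)
  cfg <- bottleneck_config(1008, 50, pool, seed = 1)
  for (k in 1:20) {
    counts <- bottleneck_sample(res, cfg, seed = k)
    expect_equal(sum(counts), 1008L)
    expect_true(all(counts >= 0))
  }
  # without spike-in, a monoculture always gets every cell
  s1 <- strategy_set(matrix(c(0.5, 0.5), 1))
  res1 <- run_batch(1e-3, s1, env)
  c1 <- bottleneck_sample(res1, bottleneck_config(1008), seed = 2)
  expect_identical(c1, 1008L)

  # same seed, same draw
  a <- bottleneck_sample(res, cfg, seed = 7)
  b <- bottleneck_sample(res, cfg, seed = 7)
  expect_identical(a, b)
})

test_that("sampling a population smaller than the bottleneck errors", {
  env <- env2n(c0 = 1)
  s1 <- strategy_set(matrix(c(0.5, 0.5), 1))
  # stop the batch almost immediately: biomass ~ rho0, only ~1008 cells,
  # then ask for more resident cells than exist
  res <- run_batch(1e-4, s1, env,
                   batch_control(mode = "fixed_time", t_batch = 1e-6))
  expect_error(bottleneck_sample(res, bottleneck_config(1008), seed = 1),
               "too small")
})

test_that("stochastic runs are reproducible and conserve cell counts", {
  env <- env2n(c0 = 1e-2)
  s <- equally_spaced_strategies(5)
  cfg <- bottleneck_config(200, 20, rep(1 / 5, 5), seed = 31)
  r1 <- run_stochastic(rep(1, 5), s, env, cfg, n_batches = 30)
  r2 <- run_stochastic(rep(1, 5), s, env, cfg, n_batches = 30)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == 200L))

  cfg2 <- bottleneck_config(200, 20, rep(1 / 5, 5), seed = 32)
  r3 <- run_stochastic(rep(1, 5), s, env, cfg2, n_batches = 30)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("pure migration reproduces the pool composition", {
  env <- env2n(c0 = 1e-2)
  s <- equally_spaced_strategies(5)
  pool <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  cfg <- bottleneck_config(500, 500, pool, seed = 8)
  r <- run_stochastic(rep(1, 5), s, env, cfg, n_batches = 60)
  # inoculum is a fresh multinomial pool draw every batch
  se <- sqrt(pool * (1 - pool) / (500 * 30))
  expect_true(all(abs(r$mean_fractions - pool) < 4 * se + 1e-12))
})

test_that("bolus schedules produce the configured supply sequences", {
  env <- env2n(c0 = 1, supply = c(0.5, 0.5))
  mx <- bolus_schedule(env, "mixed")
  expect_equal(mx$supply(1), c(0.5, 0.5))
  expect_equal(mx$supply(17), c(0.5, 0.5))

  alt <- bolus_schedule(env, "alternating", cycle_length = 2)
  expect_equal(alt$period, 2L)
  expect_equal(alt$supply(1), c(1, 0))
  expect_equal(alt$supply(2), c(0, 1))
  expect_equal(alt$supply(3), c(1, 0))

  env37 <- env2n(supply = c(0.25, 0.75))
  sch4 <- bolus_schedule(env37, "alternating", cycle_length = 4)
  expect_equal(sapply(1:4, function(b) sch4$supply(b)[1]), c(1, 0, 0, 0))

  expect_error(bolus_schedule(env, "alternating", cycle_length = 3),
               "not representable")
})

test_that("alternating single-nutrient boluses support less diversity than mixed", {
  s <- equally_spaced_strategies(11)
  env <- env2n(c0 = 1)
  ctrl <- protocol_control(max_batches = 3000, steady_state_tol = 1e-8)
  mixed <- run_to_steady_state(rep(1, 11), s, env, control = ctrl)
  alt <- run_to_steady_state(rep(1, 11), s, env, control = ctrl,
                             schedule = bolus_schedule(env, "alternating",
                                                       cycle_length = 2))
  expect_equal(mixed$diversity$m_e, 11, tolerance = 1e-6)
  expect_lt(alt$diversity$m_e, mixed$diversity$m_e - 1)
})
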