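test_that("the chemostat balance holds identically for trivial communities", {
  # single species: sum_i alpha_i c_i / (alpha_i rho0) = c0/rho0 exactly
  s <- strategy_set(matrix(c(0.3, 0.7), 1))
  env <- env2n(c0 = 1e-4, supply = c(0.6, 0.4))
  cv <- chemostat_residual(1e-3, s, env)
  expect_equal(cv$residuals, 0)

  # two specialists with abundances matched to the supply
  sp <- strategy_set(rbind(c(1, 0), c(0, 1)))
  env3 <- env2n(c0 = 1e-4, supply = c(0.3, 0.7))
  cv2 <- chemostat_residual(c(0.3, 0.7) * 1e-3, sp, env3)
  expect_equal(cv2$residuals, c(0, 0))

  # supplied nutrient that nobody can eat
  one <- strategy_set(matrix(c(1, 0), 1))
  expect_error(chemostat_residual(1e-3, one, env3), "zero total enzyme")
})

test_that("delta_tilde ties the supply rates to the batch duration", {
  s <- strategy_set(matrix(c(0.5, 0.5), 1))
  env <- env2n(c0 = 1e-4)
  b <- run_batch(1e-3, s, env)
  cv <- chemostat_residual(1e-3, s, env, batch = b)
  expect_equal(cv$s, env$c0 * env$supply_fraction / b$t_f)
  expect_equal(cv$delta_tilde, sum(cv$s) / 1e-3, tolerance = 1e-12)
})

test_that("a resident's own strategy invades neutrally at steady state", {
  env <- env2n(c0 = 1, supply = c(0.35, 0.65))
  res <- run_to_steady_state(1, strategy_set(matrix(c(0.4, 0.6), 1)), env)
  inv <- invasion_fold(res$last_batch, c(0.4, 0.6), env)
  expect_equal(inv$fold, inv$resident_fold, tolerance = 1e-9)
  expect_equal(inv$resident_fold, (1e-3 + 1) / 1e-3, tolerance = 1e-8)
})

test_that("a batch away from steady state is rejected as stale", {
  env <- env2n(c0 = 1, supply = c(0.2, 0.8))
  s <- strategy_set(rbind(c(0.3, 0.7), c(0.8, 0.2)))
  b <- run_batch(c(5e-4, 5e-4), s, env)   # folds differ: not steady
  expect_error(invasion_fold(b, c(0.5, 0.5), env), "stale")
})

test_that("every unit-budget strategy is neutral at the remapped boundary", {
  env <- env2n(c0 = 1)
  strat <- c(0.3, 0.7)
  b <- remapped_boundary(strat, env)
  envb <- env; envb$supply_fraction <- b$boundary
  res <- run_batch(1e-3, strategy_set(matrix(strat, 1)), envb)
  for (inv in list(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1))) {
    f <- invasion_fold(res, inv, envb)
    expect_equal(f$fold, f$resident_fold, tolerance = 1e-6)
  }
})

test_that("at saturating bolus any strategy nearer the supply invades", {
  env <- env2n(c0 = 1e4, supply = c(0.3, 0.7))
  res <- run_to_steady_state(1, strategy_set(matrix(c(0.6, 0.4), 1)), env)
  b <- res$last_batch
  expect_true(invasion_fold(b, c(0.5, 0.5), env)$can_invade)
  expect_true(invasion_fold(b, c(0.2, 0.8), env)$can_invade)
  expect_false(invasion_fold(b, c(0.8, 0.2), env)$can_invade)
})

test_that("the invader fold matches brute-force co-simulation", {
  env <- env2n(c0 = 1, supply = c(0.35, 0.65))
  resident <- c(0.4, 0.6)
  res <- run_to_steady_state(1, strategy_set(matrix(resident, 1)), env)
  invader <- c(0.25, 0.75)
  pred <- invasion_fold(res$last_batch, invader, env)$fold
  both <- strategy_set(rbind(resident, invader))
  co <- run_batch(c(res$rho_star, 1e-9 * env$rho0), both, env)
  observed <- co$rho_final[2] / co$inoculum[2]
  expect_equal(log(pred), log(observed), tolerance = 1e-6)
})

test_that("specialists and the perfect generalist are never remapped", {
  for (c0 in c(1e-3, 1, 1e3)) {
    env <- env2n(c0 = c0)
    expect_equal(remapped_boundary(c(0.5, 0.5), env)$boundary,
                 c(0.5, 0.5), tolerance = 1e-6)
    expect_equal(remapped_boundary(c(1, 0), env)$boundary, c(1, 0))
    expect_equal(remapped_boundary(c(0, 1), env)$boundary, c(0, 1))
  }
})

test_that("remapping pulls interior strategies toward the simplex center", {
  env <- env2n(c0 = 1)        # c0 = K, rho0 << K: strongest remapping
  b <- remapped_boundary(c(0.2, 0.8), env)
  expect_true(b$converged)
  expect_gt(b$boundary[1], 0.2)
  expect_lt(b$boundary[1], 0.5)
  expect_lt(abs(b$residual), 1e-8)

  # large inoculum: remapping vanishes
  env_big <- env2n(c0 = 1, rho0 = 1e2)
  b2 <- remapped_boundary(c(0.2, 0.8), env_big)
  expect_lt(abs(b2$boundary[1] - 0.2), 1e-3)
})

test_that("the mutual-invasibility window is bracketed by the remapped boundaries", {
  A <- c(0.3, 0.7); B <- c(0.7, 0.3)

  # chemostat limit: window is essentially [A, B]
  env_lo <- env2n(c0 = 1e-4, rho0 = 1e-2)
  w_lo <- coexistence_window(A, B, env_lo)
  expect_equal(w_lo$lower, 0.3, tolerance = 5e-3)
  expect_equal(w_lo$upper, 0.7, tolerance = 5e-3)
  expect_false(w_lo$empty)

  # c0 = K: strictly inside [A, B]
  env_mid <- env2n(c0 = 1)
  w_mid <- coexistence_window(A, B, env_mid)
  expect_gt(w_mid$lower, 0.3)
  expect_lt(w_mid$upper, 0.7)
  expect_false(w_mid$empty)

  expect_error(coexistence_window(A, A, env_mid), "degenerate")
  expect_error(coexistence_window(B, A, env_mid), "strategyA")
})

test_that("serial dilution confirms the coexistence window verdicts", {
  A <- c(0.3, 0.7); B <- c(0.7, 0.3)
  env <- env2n(c0 = 1)
  w <- coexistence_window(A, B, env)
  s <- strategy_set(rbind(A, B))
  ctrl <- protocol_control(max_batches = 4000, steady_state_tol = 1e-8)

  inside <- (w$lower + w$upper) / 2
  env_in <- env; env_in$supply_fraction <- c(inside, 1 - inside)
  ss_in <- run_to_steady_state(c(1, 1), s, env_in, control = ctrl)
  expect_equal(sum(ss_in$survivors), 2L)

  outside <- (0.3 + w$lower) / 2    # between A and the window edge
  env_out <- env; env_out$supply_fraction <- c(outside, 1 - outside)
  ss_out <- run_to_steady_state(c(1, 1), s, env_out, control = ctrl)
  expect_equal(sum(ss_out$survivors), 1L)
})

test_that("convex-hull membership produces valid barycentric weights", {
  h <- convex_hull_contains(rbind(c(0, 1), c(1, 0)), c(0.3, 0.7))
  expect_true(h$contains)
  expect_equal(h$weights, c(0.7, 0.3))   # weight on (0,1) then (1,0)
  expect_equal(h$margin, 0.3)

  # supply equal to a hull point: contained with zero margin
  pts <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  hb <- convex_hull_contains(pts, c(0.2, 0.8))
  expect_true(hb$contains)
  expect_equal(hb$margin, 0)

  ho <- convex_hull_contains(pts, c(0.8, 0.2))
  expect_false(ho$contains)
  expect_lt(ho$margin, 0)

  # three nutrients: centroid of three near-vertex strategies
  pts3 <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05),
                c(0.05, 0.05, 0.9))
  h3 <- convex_hull_contains(pts3, rep(1 / 3, 3))
  expect_true(h3$contains)
  expect_equal(h3$weights, rep(1 / 3, 3), tolerance = 1e-9)
  expect_gt(h3$margin, 0)

  expect_error(convex_hull_contains(pts, c(0.2, 0.3, 0.5)), "disagree")
})

test_that("hull verdicts agree with the interval test on random communities", {
  set.seed(7)
  for (k in 1:25) {
    pts <- random_two_nutrient_community(sample(2:6, 1))$alpha
    x <- runif(1)
    h <- convex_hull_contains(pts, c(x, 1 - x))
    in_interval <- x >= min(pts[, 1]) - 1e-12 && x <= max(pts[, 1]) + 1e-12
    expect_identical(h$contains, in_interval)
    if (h$contains) {
      expect_equal(drop(t(pts) %*% h$weights), c(x, 1 - x),
                   tolerance = 1e-9)
      expect_equal(sum(h$weights), 1, tolerance = 1e-9)
      expect_true(all(h$weights >= -1e-12))
    }
  }
})
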