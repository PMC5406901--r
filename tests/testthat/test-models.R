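test_that("daughter-pair probabilities reproduce the transition table", {
  m <- branching_model(theta1 = 0.6, theta2 = 0.1, theta3 = 0.1,
                       theta4 = 0.05)
  expect_equal(unname(daughter_type_probs("OFF", m)), c(0.6, 0.1, 0.1, 0.2))
  expect_equal(unname(daughter_type_probs("ON", m)), c(0.1, 0.05, 0.05, 0.8))
  # degenerate simplex corner
  expect_equal(unname(daughter_type_probs(0, list(theta1 = 1, theta2 = 0,
                                                  theta3 = 0.5, theta4 = 0.25))),
               c(1, 0, 0, 0))
  expect_error(daughter_type_probs(0, list(theta1 = 0.8, theta2 = 0.2,
                                           theta3 = 0, theta4 = 0)),
               "<= 1")
})

test_that("pair probabilities close to one over a grid of valid rows", {
  for (t1 in seq(0, 1, by = 0.25)) {
    for (t2 in seq(0, (1 - t1) / 2, length.out = 3)) {
      v <- daughter_type_probs(0, list(theta1 = t1, theta2 = t2,
                                       theta3 = t1, theta4 = t2))
      expect_equal(sum(v), 1, tolerance = 1e-12)
      expect_equal(v[[2]], v[[3]])
      expect_true(all(v >= 0))
    }
  }
})

test_that("branching division kernel: empirical pair frequencies and carry-over", {
  set.seed(42)
  m <- branching_model()
  n <- 1e5
  st <- list(type = rep(0L, n), D = runif(n), F = runif(n))
  pair <- sample_daughter_pairs(m, st)
  # concentrations pass to both daughters unchanged
  expect_identical(pair$d1$D, st$D)
  expect_identical(pair$d2$F, st$F)
  counts <- table(factor(2 * pair$d1$type + pair$d2$type, levels = 0:3))
  probs <- daughter_type_probs("OFF", m)
  for (j in 1:4) {
    se <- sqrt(probs[[j]] * (1 - probs[[j]]) / n)
    expect_lt(abs(counts[[j]] / n - probs[[j]]), 3 * se + 1e-12)
  }
  # degenerate: theta1 = 1 forces OFF/OFF
  md <- branching_model(theta1 = 1, theta2 = 0)
  pd <- sample_daughter_pairs(md, st)
  expect_true(all(pd$d1$type == 0L) && all(pd$d2$type == 0L))
})

test_that("ctmc daughters inherit the type and redraw production rates", {
  set.seed(7)
  m <- ctmc_model()
  st <- sample_root_states(m, 500)
  pair <- sample_daughter_pairs(m, st)
  expect_identical(pair$d1$type, st$type)
  expect_identical(pair$d2$type, st$type)
  expect_identical(pair$d1$D, st$D)
  # fresh extrinsic draws, independent between daughters
  expect_gt(mean(pair$d1$alpha_on != pair$d2$alpha_on), 0.99)
})

test_that("ctmc path sampler obeys the exponential holding-time law", {
  set.seed(11)
  # no switching when both rates vanish
  pth <- sample_ctmc_path(1, 0, 0, 30)
  expect_length(pth$switch_times, 0)
  expect_equal(pth$types, 1L)
  # single possible switch when q2 = 0, frequency 1 - exp(-q1 T)
  n <- 1e5; q1 <- 0.03; T <- 20
  nsw <- replicate(n, length(sample_ctmc_path(0, q1, 0, T)$switch_times))
  expect_true(all(nsw <= 1))
  p_true <- 1 - exp(-q1 * T)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(nsw) - p_true), 3 * se)
})

test_that("ctmc occupancy approaches the stationary distribution", {
  set.seed(13)
  q1 <- 0.05; q2 <- 0.02
  m <- ctmc_model(q1 = q1, q2 = q2)
  st <- sample_root_states(m, 20000)
  out <- advance_states(m, st, 400)  # ~20 mean holding times
  p_on <- q1 / (q1 + q2)
  se <- sqrt(p_on * (1 - p_on) / 20000)
  expect_lt(abs(mean(out$type) - p_on), 4 * se)
})

test_that("extrinsic draws share one multiplier with the stated spread", {
  set.seed(17)
  d0 <- extrinsic_draw(2, 20, 0, n = 5)
  expect_equal(d0$alpha_on / d0$alpha_off, rep(10, 5))
  expect_equal(d0$z, rep(1, 5))
  d <- extrinsic_draw(2, 20, 0.3, n = 1e5)
  expect_equal(cor(log(d$alpha_off), log(d$alpha_on)), 1)
  expect_equal(sd(log(d$z)), 0.3, tolerance = 0.01)
  expect_equal(median(d$alpha_on), 20, tolerance = 0.1)
})

test_that("measurement model is a scaled Gaussian in F with variance floor", {
  # mode of the density over y sits at c*F
  ll <- measurement_loglik(seq(3.9, 4.1, by = 0.01), F = 2, c = 2, sigma2 = 1)
  expect_equal(which.max(ll), 11)
  # equals the explicit normal log-density formula
  y <- 3.7; F <- 2.3; cc <- 1.4; s2 <- 0.8
  byhand <- -0.5 * log(2 * pi * s2 * F) - (y - cc * F)^2 / (2 * s2 * F)
  expect_equal(measurement_loglik(y, F, cc, s2), byhand, tolerance = 1e-12)
  # dark cell stays finite through the variance floor
  expect_true(is.finite(measurement_loglik(0.1, 0, 1, 1)))
  expect_error(measurement_loglik(1, 1, 1, sigma2 = 0), "sigma2")
})

test_that("branching lifetime simulation matches the closed form", {
  m <- branching_model()
  traj <- simulate_lifetime(m, list(type = 1L, D = 0, F = 0), 30)
  st <- trajectory_state(traj, c(10, 30))
  ref10 <- propagate_reporter(0, 0, m$params$alpha_on, m$params$delta,
                              m$params$m, 10)
  expect_equal(st$F[1], ref10$F)
  expect_equal(st$type, c(1L, 1L))
})

test_that("switch-free ctmc reproduces the branching dynamics exactly", {
  m2 <- ctmc_model(q1 = 0, q2 = 0, sigma_ext = 0)
  m1 <- branching_model(alpha_off = m2$params$mu_alpha_off,
                        alpha_on = m2$params$mu_alpha_on)
  s0 <- list(type = 1L, D = 2, F = 1, alpha_off = 1, alpha_on = 10)
  t2 <- simulate_lifetime(m2, s0, 30)
  t1 <- simulate_lifetime(m1, s0, 30)
  for (t in c(0, 7.5, 30)) {
    expect_equal(trajectory_state(t2, t)$F, trajectory_state(t1, t)$F,
                 tolerance = 1e-12)
  }
})

test_that("ctmc lifetime simulation agrees with a fine-grid Euler oracle", {
  set.seed(19)
  m <- ctmc_model(q1 = 0.08, q2 = 0.06)
  s0 <- list(type = 0L, D = 1.5, F = 0.5, alpha_off = 0.9, alpha_on = 11)
  traj <- simulate_lifetime(m, s0, 30)
  alpha_fun <- approxfun(c(0, traj$breaks, 31),
                         c(traj$alpha, traj$alpha[length(traj$alpha)]),
                         method = "constant")
  oracle <- euler_reporter(1.5, 0.5, alpha_fun, m$params$delta, m$params$m,
                           30, h = 5e-5)
  st <- trajectory_state(traj, 30)
  expect_equal(st$F, oracle$F, tolerance = 1e-6)
  expect_equal(st$D, oracle$D, tolerance = 1e-6)
})

test_that("vectorized ctmc advance matches the path-based simulator in law", {
  set.seed(23)
  m <- ctmc_model(q1 = 0.04, q2 = 0.03)
  L <- 30000
  st <- sample_root_states(m, L)
  fast <- advance_states(m, st, 30)
  slow_F <- vapply(seq_len(2000), function(i) {
    s0 <- lapply(st, `[`, i)
    trajectory_state(simulate_lifetime(m, s0, 30), 30)$F
  }, 0)
  expect_lt(abs(mean(fast$F) - mean(slow_F)),
            3 * (sd(slow_F) / sqrt(2000) + sd(fast$F) / sqrt(L)))
})

test_that("update_params revalidates and rejects unknown names", {
  m <- branching_model()
  m2 <- update_params(m, c(theta1 = 0.3, theta2 = 0.2))
  expect_equal(m2$params$theta1, 0.3)
  expect_equal(m2$params$alpha_on, m$params$alpha_on)
  expect_error(update_params(m, c(nope = 1)), "unknown")
  expect_error(update_params(m, c(theta1 = 0.9, theta2 = 0.4)), "<= 1")
})
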