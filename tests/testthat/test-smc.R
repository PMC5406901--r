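test_that("resampling follows the weights", {
  set.seed(31)
  # equal weights, systematic: counts differ by at most one
  idx <- resample(rep(-3.2, 7), L = 21, scheme = "systematic")
  cnt <- table(factor(idx, levels = 1:7))
  expect_lte(diff(range(cnt)), 1)
  # overwhelming weight wins every draw
  lw <- c(0, -log(1e12), -log(1e12))
  expect_true(all(resample(lw, L = 50) == 1L))
  # multinomial counts match weights within 3 binomial SEs
  lw <- log(c(0.5, 0.3, 0.2))
  n <- 1e5
  idx <- resample(lw, L = n)
  for (j in 1:3) {
    p <- exp(lw[j])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(idx == j) - p), 3 * se)
  }
  expect_error(resample(c(-Inf, -Inf)), "zero")
})

test_that("deterministic single-cell likelihood is exact for any L", {
  m <- deterministic_branching(type_on = TRUE)
  tr <- single_cell_tree(obs_times = c(5, 10, 15), readouts = c(1, 2, 3))
  p <- m$params
  Fs <- vapply(c(5, 10, 15), function(t)
    propagate_reporter(0, 0, p$alpha_on, p$delta, p$m, t)$F, 0)
  exact <- sum(measurement_loglik(c(1, 2, 3), Fs, p$c, p$sigma2))
  for (L in c(1, 17)) {
    expect_equal(tree_loglik(tr, m, L)$value, exact, tolerance = 1e-12)
    expect_equal(tree_loglik_exact(tr, m, L)$value, exact, tolerance = 1e-12)
  }
})

test_that("triplet update handles empty daughters and single particles", {
  m <- branching_model()
  set.seed(33)
  states <- sample_root_states(m, 10)
  d_empty <- cell_record(1, 1, 30)
  up <- triplet_update(states, d_empty, cell_record(1, 2, 30), m)
  expect_equal(up$contrib, 0)  # empty product of measurement densities
  expect_length(up$d1$type, 10)
  # L = 1: contribution is the summed measurement loglik of the one draw
  set.seed(34)
  st1 <- sample_root_states(m, 1)
  d1 <- cell_record(1, 1, 30, c(10, 20), c(1.5, 2.5))
  d2 <- cell_record(1, 2, 30, c(10, 20), c(0.5, 1.0))
  set.seed(35)
  up1 <- triplet_update(st1, d1, d2, m)
  set.seed(35)
  pair <- sample_daughter_pairs(m, st1)
  r1 <- lineagesmc:::cell_weight(m, pair$d1, d1)
  r2 <- lineagesmc:::cell_weight(m, pair$d2, d2)
  expect_equal(up1$contrib, r1$log_weights + r2$log_weights)
})

test_that("smc estimators are unbiased on the observable-type model", {
  set.seed(37)
  dm <- discrete_model()
  tr <- simulate_tree(sim_config(dm, 2, lifetime = 30, dt = 15))
  exact <- discrete_tree_loglik_exact(tr, dm)
  est_t <- replicate(200, tree_loglik(tr, dm, 2000)$value)
  est_e <- replicate(200, tree_loglik_exact(tr, dm, 2000)$value)
  # exp(estimate) averaged over replicates approaches the exact likelihood
  expect_lt(abs(mean(exp(est_t)) / exp(exact) - 1), 0.05)
  expect_lt(abs(mean(exp(est_e)) / exp(exact) - 1), 0.05)
})

test_that("trajectory baseline: per-cell terms match per-cell enumeration", {
  set.seed(38)
  dm <- discrete_model(root = list(p_on = 0.5))
  tr <- simulate_tree(sim_config(dm, 2, lifetime = 30, dt = 15))
  # with an explicit balanced birth prior every cell contributes exactly
  # log P(type) = log(1/2), independent of ancestry
  half <- function(gen) list(type = rep(c(0L, 1L), length.out = 500))
  est <- trajectory_loglik(tr, dm, 500, init_prior = half)
  expect_equal(unname(est$per_triplet), rep(log(0.5), n_cells(tr)))
  # cells without readouts contribute nothing
  empty <- lineage_tree(list(cell_record(0, 1, 30),
                             cell_record(1, 1, 30),
                             cell_record(1, 2, 30)))
  expect_equal(trajectory_loglik(empty, dm, 50)$value, 0)
})

test_that("likelihood is additive over independent trees", {
  set.seed(39)
  m <- branching_model()
  trees <- list(make_example_dataset(1, seed = 101, n_generations = 2),
                make_example_dataset(1, seed = 102, n_generations = 2))
  tot <- vapply(trees, function(tr) tree_loglik(tr, m, 400)$value, 0)
  # additivity is by construction; check the estimate decomposition instead:
  # value = root contribution + per-triplet contributions
  est <- tree_loglik(trees[[1]], m, 400)
  expect_equal(est$value, est$root_loglik + sum(est$per_triplet))
  expect_length(est$per_triplet, nrow(lineagesmc:::tree_mothers(trees[[1]])))
  expect_true(all(is.finite(tot)))
})

test_that("daughter order does not shift the estimator's expectation", {
  set.seed(41)
  m <- branching_model()
  tr <- make_example_dataset(1, seed = 43, n_generations = 2)
  # swap the two daughters of the root, relabeling the subtrees
  swap <- function(tree) {
    cells <- lapply(tree$cells, function(cl) {
      if (cl$gen == 0L) return(cl)
      # flip the branch at generation 1: index i -> mirrored index
      path <- integer(cl$gen)
      idx <- cl$idx
      for (g in seq(cl$gen, 1)) {
        path[g] <- (idx - 1L) %% 2L
        idx <- (idx - 1L) %/% 2L + 1L
      }
      path[1] <- 1L - path[1]
      idx <- 1L
      for (g in seq_len(cl$gen)) idx <- 2L * (idx - 1L) + path[g] + 1L
      cell_record(cl$gen, idx, cl$lifetime, cl$obs_times, cl$readouts)
    })
    lineage_tree(unname(cells))
  }
  tr_sw <- swap(tr)
  a <- replicate(40, tree_loglik(tr, m, 400)$value)
  b <- replicate(40, tree_loglik(tr_sw, m, 400)$value)
  z <- (mean(a) - mean(b)) / sqrt(var(a) / 40 + var(b) / 40)
  expect_lt(abs(z), 4)
})

test_that("exact and triplet estimators agree on small reporter trees", {
  set.seed(47)
  m <- branching_model()
  tr <- make_example_dataset(1, seed = 48, n_generations = 3)
  a <- replicate(30, tree_loglik(tr, m, 800)$value)
  b <- replicate(30, tree_loglik_exact(tr, m, 800)$value)
  z <- (mean(a) - mean(b)) / sqrt(var(a) / 30 + var(b) / 30)
  expect_lt(abs(z), 4)
  expect_error(tree_loglik_exact(make_example_dataset(1, seed = 1,
                                                      n_generations = 6), m),
               "gated")
})

test_that("estimator convergence study: CV shrinks and the mean stabilizes", {
  set.seed(49)
  m <- branching_model()
  tr <- make_example_dataset(1, seed = 50, n_generations = 3)
  conv <- estimator_convergence(tr, m, particle_grid = c(25, 100, 400),
                                reps = 30)
  expect_equal(conv$L, c(25, 100, 400))
  expect_lt(conv$cv[3], conv$cv[1])
  # deterministic single-cell case: zero spread at any L
  trd <- single_cell_tree()
  md <- deterministic_branching()
  convd <- estimator_convergence(trd, md, particle_grid = c(10, 50), reps = 5)
  expect_equal(convd$cv, c(0, 0))
})
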