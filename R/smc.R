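# Sequential Monte Carlo machinery for lineage-tree likelihoods.
#
# All weight arithmetic is carried out in log space; per-set normalization
# subtracts the maximum log weight before exponentiating (the product of
# ~K Gaussian terms per daughter underflows quickly otherwise).

#' Resample particle indices from log weights
#'
#' @param log_weights particle log weights (need not be normalized; at least
#'   one must be finite).
#' @param L number of indices to draw (default: one per weight).
#' @param scheme `"multinomial"` (independent draws, the default) or
#'   `"systematic"` (stratified single-uniform scheme, lower variance).
#' @return integer vector of `L` indices; the expected count of index `l` is
#'   proportional to its normalized weight.
#' @export
resample <- function(log_weights, L = length(log_weights),
                     scheme = c("multinomial", "systematic")) {
  scheme <- match.arg(scheme)
  mx <- max(log_weights)
  if (!is.finite(mx)) stop("resample: all weights are zero")
  w <- exp(log_weights - mx)
  w <- w / sum(w)
  if (scheme == "multinomial") {
    sample.int(length(w), L, replace = TRUE, prob = w)
  } else {
    u <- (stats::runif(1) + seq_len(L) - 1) / L
    findInterval(u, cumsum(w), left.open = TRUE) + 1L
  }
}

# bootstrap particle filter over a single cell's readout series, with
# per-observation resampling; returns the cell's marginal log-likelihood and
# the (unweighted) particle set at division time
#' @keywords internal
#' @noRd
cell_filter <- function(model, states, cell, scheme = "multinomial") {
  ll <- 0
  t_prev <- 0
  for (k in seq_along(cell$obs_times)) {
    states <- advance_states(model, states, cell$obs_times[k] - t_prev)
    t_prev <- cell$obs_times[k]
    lw <- obs_loglik(model, states, cell$readouts[k])
    contrib <- logmeanexp(lw)
    if (!is.finite(contrib))
      return(list(loglik = -Inf, states = states))
    ll <- ll + contrib
    states <- subset_states(states, resample(lw, scheme = scheme))
  }
  states <- advance_states(model, states, cell$lifetime - t_prev)
  list(loglik = ll, states = states)
}

# whole-lifetime weighting of one cell: accumulate per-particle
# log-likelihoods over the readout series, no intermediate resampling;
# returns per-particle log weights and end states.  The default method
# advances sequentially between readouts; the reporter models override it
# with equivalent closed-form vectorized routines (the hot path of the SMC).
#' @keywords internal
#' @noRd
cell_weight <- function(model, states, cell) UseMethod("cell_weight")

#' @export
cell_weight.default <- function(model, states, cell) {
  L <- n_states(states)
  lw <- numeric(L)
  t_prev <- 0
  for (k in seq_along(cell$obs_times)) {
    states <- advance_states(model, states, cell$obs_times[k] - t_prev)
    t_prev <- cell$obs_times[k]
    lw <- lw + obs_loglik(model, states, cell$readouts[k])
  }
  states <- advance_states(model, states, cell$lifetime - t_prev)
  list(log_weights = lw, states = states)
}

# branching model: the type is fixed over the lifetime, so the reporter state
# at every readout time follows from the birth state in closed form
#' @export
cell_weight.branching_model <- function(model, states, cell) {
  p <- model$params
  L <- length(states$type)
  alpha <- p$alpha_off + (p$alpha_on - p$alpha_off) * (states$type == 1L)
  ts <- c(cell$obs_times, cell$lifetime)
  kn <- ode_kernels(p$delta, p$m, ts)  # vectors over ts
  K <- length(cell$obs_times)
  lw <- numeric(L)
  for (k in seq_len(K)) {
    Fk <- kn$phiFD[k] * states$D + kn$phiFF[k] * states$F + alpha * kn$HF[k]
    sd_k <- sqrt(p$sigma2 * pmax(Fk, model$var_floor))
    lw <- lw + stats::dnorm(cell$readouts[k], p$c * Fk, sd_k, log = TRUE)
  }
  iT <- K + 1L
  end <- list(type = states$type,
              D = kn$phiDD[iT] * states$D + alpha * kn$HD[iT],
              F = kn$phiFD[iT] * states$D + kn$phiFF[iT] * states$F +
                  alpha * kn$HF[iT])
  list(log_weights = lw, states = end)
}

# sample the CTMC segment structure of L particles over [0, T]; segments are
# returned in sampling rounds (round 1 holds every particle's first segment,
# round j the j-th segment of the particles still switching), which keeps the
# downstream kernel accumulation free of any grouping/sorting
#' @keywords internal
#' @noRd
ctmc_segments <- function(q1, q2, type0, T) {
  ty <- type0
  cur <- numeric(length(type0))
  active <- seq_along(type0)
  rounds <- list()
  while (length(active) > 0) {
    on <- ty[active] == 1L
    r <- q1 + (q2 - q1) * on
    hold <- rep(Inf, length(active))
    pos <- r > 0
    if (any(pos)) hold[pos] <- stats::rexp(sum(pos), r[pos])
    nxt <- cur[active] + hold
    rounds[[length(rounds) + 1L]] <-
      list(pid = active, u = cur[active], v = pmin(nxt, T), on = on)
    flip <- nxt < T
    ty[active[flip]] <- 1L - ty[active[flip]]
    cur[active] <- nxt
    active <- active[flip]
  }
  list(rounds = rounds, type_T = ty)
}

# CTMC model: sample each particle's switch structure once per lifetime and
# evaluate the affine reporter response at every readout time by summing the
# input-kernel integrals over the ON segments (see advance_states.ctmc_model)
#' @export
cell_weight.ctmc_model <- function(model, states, cell) {
  p <- model$params
  L <- length(states$type)
  k <- p$delta + p$m
  HD <- function(tau) if (k > 0) -expm1(-k * tau) / k else tau
  HFr <- function(tau) (if (p$delta > 0) -expm1(-p$delta * tau) / p$delta
                        else tau) - HD(tau)
  seg <- ctmc_segments(p$q1, p$q2, states$type, cell$lifetime)
  # particles that never switch are handled with scalar kernels; only the
  # switching minority needs the per-segment accumulation
  r1 <- seg$rounds[[1]]
  ns <- r1$v >= cell$lifetime
  ns_on <- which(ns & r1$on)
  on_rounds <- list()
  keep1 <- !ns & r1$on
  if (any(keep1))
    on_rounds[[1]] <- list(pid = r1$pid[keep1], u = r1$u[keep1],
                           v = r1$v[keep1])
  for (rd in seg$rounds[-1]) {
    if (!any(rd$on)) next
    on_rounds[[length(on_rounds) + 1L]] <-
      list(pid = rd$pid[rd$on], u = rd$u[rd$on], v = rd$v[rd$on])
  }
  da <- states$alpha_on - states$alpha_off
  state_at <- function(t) {
    SD <- numeric(L); SF <- numeric(L)
    SD[ns_on] <- HD(t)
    SF[ns_on] <- HFr(t)
    for (rd in on_rounds) {
      keep <- rd$u < t
      if (!any(keep)) next
      j <- rd$pid[keep]
      uu <- rd$u[keep]; vv <- pmin(rd$v[keep], t)
      SD[j] <- SD[j] + HD(t - uu) - HD(t - vv)
      SF[j] <- SF[j] + HFr(t - uu) - HFr(t - vv)
    }
    phiDD <- exp(-k * t); phiFF <- exp(-p$delta * t)
    list(D = phiDD * states$D + states$alpha_off * HD(t) + da * SD,
         F = (phiFF - phiDD) * states$D + phiFF * states$F +
             states$alpha_off * HFr(t) + da * SF)
  }
  lw <- numeric(L)
  for (m_ in seq_along(cell$obs_times)) {
    Fm <- state_at(cell$obs_times[m_])$F
    sd_m <- sqrt(p$sigma2 * pmax(Fm, model$var_floor))
    lw <- lw + stats::dnorm(cell$readouts[m_], p$c * Fm, sd_m, log = TRUE)
  }
  at_T <- state_at(cell$lifetime)
  list(log_weights = lw,
       states = list(type = seg$type_T, D = at_T$D, F = at_T$F,
                     alpha_off = states$alpha_off,
                     alpha_on = states$alpha_on))
}

#' One mother-daughter triplet update of the tree SMC
#'
#' The elementary step of the recursive tree-likelihood estimator.  Starting
#' from `L` unweighted particles approximating the mother's state posterior
#' at her division time, it (i) draws a pair of daughter birth states per
#' particle from the division kernel, (ii) simulates both daughters forward
#' to their own division times, (iii) weights particle `l` by the product of
#' the two daughters' full measurement likelihoods, and (iv) estimates the
#' triplet's marginal contribution as the log of the mean weight.  The
#' daughter particle sets are then resampled jointly -- the weight belongs to
#' the mother particle, so one index draw selects both daughters' simulated
#' end states -- and returned unweighted for the next generation.
#'
#' @param mother_states unweighted particle set (as produced by a previous
#'   update) at the mother's division time.
#' @param daughter1,daughter2 the two daughters' [cell_record()]s.
#' @param model a `lineage_model`.
#' @param scheme resampling scheme, see [resample()].
#' @return list with `contrib` (log marginal contribution of the triplet;
#'   `-Inf` when every particle has zero weight), and unweighted daughter
#'   particle sets `d1`, `d2` at their division times.
#' @export
triplet_update <- function(mother_states, daughter1, daughter2, model,
                           scheme = "multinomial") {
  pair <- sample_daughter_pairs(model, mother_states)
  r1 <- cell_weight(model, pair$d1, daughter1)
  r2 <- cell_weight(model, pair$d2, daughter2)
  lw <- r1$log_weights + r2$log_weights
  contrib <- logmeanexp(lw)
  if (!is.finite(contrib))
    return(list(contrib = -Inf, d1 = r1$states, d2 = r2$states))
  idx <- resample(lw, scheme = scheme)
  list(contrib = contrib,
       d1 = subset_states(r1$states, idx),
       d2 = subset_states(r2$states, idx))
}

loglik_estimate <- function(value, root_loglik, per_triplet, n_particles,
                            method) {
  structure(list(value = value, root_loglik = root_loglik,
                 per_triplet = per_triplet, n_particles = n_particles,
                 method = method),
            class = "loglik_estimate")
}

#' @export
print.loglik_estimate <- function(x, ...) {
  cat("tree log-likelihood estimate (", x$method, ", L = ", x$n_particles,
      "): ", format(x$value, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Recursive SMC estimate of the lineage-tree log-likelihood
#'
#' Estimates `log P(Y_tree | model)` by recursive filtering over the tree:
#' the root cell is handled by a classical bootstrap particle filter over its
#' own readouts, and every subsequent generation is processed one
#' mother-daughter triplet at a time via [triplet_update()].  Treating the
#' triplets of a generation independently rests on the branch-decoupling
#' approximation: the information a daughter pair's measurements carry back
#' about their mother's state is neglected, which is accurate when cells are
#' observed frequently enough that a mother's state is already well
#' constrained by her own and her ancestors' readouts.  Use
#' [tree_loglik_exact()] to audit this approximation on small trees.
#'
#' The returned value decomposes as the root-filter contribution plus one
#' term per triplet; `-Inf` (all particle weights zero somewhere) is
#' propagated and flagged, and callers should treat it as likelihood zero.
#'
#' @param tree a [lineage_tree()] (complete or pruned).
#' @param model a `lineage_model`.
#' @param n_particles number of particles `L >= 1`.
#' @param scheme resampling scheme, see [resample()].
#' @return a `"loglik_estimate"`: list with `value`, `root_loglik`,
#'   `per_triplet` (named per-triplet contributions), `n_particles`,
#'   `method`.
#' @export
tree_loglik <- function(tree, model, n_particles = 1000,
                        scheme = "multinomial") {
  stopifnot(n_particles >= 1)
  root <- tree$cells[["0.1"]]
  states <- sample_root_states(model, n_particles)
  rf <- cell_filter(model, states, root, scheme)
  state_sets <- list("0.1" = rf$states)
  per_triplet <- numeric(0)
  if (!is.finite(rf$loglik))
    return(loglik_estimate(-Inf, -Inf, per_triplet, n_particles, "triplet"))
  mothers <- tree_mothers(tree)
  for (r in seq_len(nrow(mothers))) {
    g <- mothers$gen[r]; i <- mothers$idx[r]
    k1 <- cell_key(g + 1L, 2L * i - 1L)
    k2 <- cell_key(g + 1L, 2L * i)
    up <- triplet_update(state_sets[[cell_key(g, i)]],
                         tree$cells[[k1]], tree$cells[[k2]], model, scheme)
    per_triplet[cell_key(g, i)] <- up$contrib
    state_sets[[cell_key(g, i)]] <- NULL  # mother no longer needed
    if (!is.finite(up$contrib))
      return(loglik_estimate(-Inf, rf$loglik, per_triplet, n_particles,
                             "triplet"))
    state_sets[[k1]] <- up$d1
    state_sets[[k2]] <- up$d2
  }
  loglik_estimate(rf$loglik + sum(per_triplet), rf$loglik, per_triplet,
                  n_particles, "triplet")
}

#' Exact joint SMC estimate of the lineage-tree log-likelihood
#'
#' Unbiased SMC estimator of the tree marginal likelihood without the
#' branch-decoupling approximation.  Each particle carries the *joint* state
#' of every live cell (mothers not yet divided plus daughters already
#' simulated); the daughter pairs of a generation are processed sequentially
#' and every resampling step acts on all live state sets together, so the
#' information a daughter pair's measurements carry about its mother -- and,
#' through her, about the sibling branches -- is propagated instead of being
#' dropped.  The joint particle degenerates as trees widen, so this
#' validation-grade estimator is gated to trees of at most 5 generations.
#'
#' @inheritParams tree_loglik
#' @return a `"loglik_estimate"`; `per_triplet` holds one contribution per
#'   mother-daughter triplet, as for [tree_loglik()].
#' @export
tree_loglik_exact <- function(tree, model, n_particles = 1000,
                              scheme = "multinomial") {
  stopifnot(n_particles >= 1)
  if (tree$n_generations > 5)
    stop("tree_loglik_exact is validation code, gated to <= 5 generations")
  root <- tree$cells[["0.1"]]
  rf <- cell_filter(model, sample_root_states(model, n_particles), root,
                    scheme)
  per_triplet <- numeric(0)
  if (!is.finite(rf$loglik))
    return(loglik_estimate(-Inf, -Inf, per_triplet, n_particles, "exact"))
  live <- list("0.1" = rf$states)  # all state sets share the particle index
  mothers <- tree_mothers(tree)
  for (r in seq_len(nrow(mothers))) {
    g <- mothers$gen[r]; i <- mothers$idx[r]
    k1 <- cell_key(g + 1L, 2L * i - 1L)
    k2 <- cell_key(g + 1L, 2L * i)
    pair <- sample_daughter_pairs(model, live[[cell_key(g, i)]])
    r1 <- cell_weight(model, pair$d1, tree$cells[[k1]])
    r2 <- cell_weight(model, pair$d2, tree$cells[[k2]])
    lw <- r1$log_weights + r2$log_weights
    contrib <- logmeanexp(lw)
    per_triplet[cell_key(g, i)] <- contrib
    live[[cell_key(g, i)]] <- NULL
    live[[k1]] <- r1$states
    live[[k2]] <- r2$states
    if (!is.finite(contrib))
      return(loglik_estimate(-Inf, rf$loglik, per_triplet, n_particles,
                             "exact"))
    idx <- resample(lw, scheme = scheme)
    live <- lapply(live, subset_states, idx = idx)
  }
  loglik_estimate(rf$loglik + sum(per_triplet), rf$loglik, per_triplet,
                  n_particles, "exact")
}

# prior-predictive birth-state pools per generation, by forward simulation of
# L independent single-cell lineages through the tree's generations
#' @keywords internal
#' @noRd
default_init_prior <- function(model, tree, n_particles) {
  gens <- vapply(tree$cells, `[[`, 0L, "gen")
  mean_lt <- vapply(0:tree$n_generations, function(g)
    mean(vapply(tree$cells[gens == g], `[[`, 0, "lifetime")), 0)
  pools <- vector("list", tree$n_generations + 1L)
  states <- sample_root_states(model, n_particles)
  pools[[1]] <- states
  if (tree$n_generations > 0) {
    for (g in seq_len(tree$n_generations)) {
      states <- advance_states(model, states, mean_lt[g])
      pair <- sample_daughter_pairs(model, states)
      pick <- stats::runif(n_particles) < 0.5
      states <- lapply(seq_along(pair$d1), function(f)
        ifelse(pick, pair$d1[[f]], pair$d2[[f]]))
      names(states) <- names(pair$d1)
      states$type <- as.integer(states$type)
      pools[[g + 1L]] <- states
    }
  }
  function(gen) pools[[gen + 1L]]
}

#' Trajectory-based (ancestry-free) log-likelihood baseline
#'
#' The conventional single-cell alternative: the tree is broken into
#' individual cell trajectories, each treated as an independent time series.
#' Every cell's particle filter is initialized from an assumed birth-state
#' prior instead of its mother's posterior, and the total is the sum of
#' per-cell log-likelihoods.  By default the birth prior of generation `g` is
#' the model's prior-predictive birth-state distribution at that generation,
#' approximated by forward simulation of independent lineages (recomputed for
#' the model supplied, since it depends on the parameters).
#'
#' @inheritParams tree_loglik
#' @param init_prior `NULL` for the default prior-predictive pools, or a
#'   function `function(gen)` returning a state set of `n_particles` birth
#'   states for generation `gen`.
#' @return a `"loglik_estimate"`; `per_triplet` holds one contribution per
#'   cell.
#' @export
trajectory_loglik <- function(tree, model, n_particles = 1000,
                              scheme = "multinomial", init_prior = NULL) {
  stopifnot(n_particles >= 1)
  if (is.null(init_prior))
    init_prior <- default_init_prior(model, tree, n_particles)
  per_cell <- numeric(0)
  total <- 0
  for (cl in tree$cells) {
    cf <- cell_filter(model, init_prior(cl$gen), cl, scheme)
    per_cell[cell_key(cl$gen, cl$idx)] <- cf$loglik
    total <- total + cf$loglik
    if (!is.finite(total))
      return(loglik_estimate(-Inf, NA_real_, per_cell, n_particles,
                             "trajectory"))
  }
  loglik_estimate(total, NA_real_, per_cell, n_particles, "trajectory")
}

#' Replicate study of the SMC estimator across particle counts
#'
#' Re-estimates the tree log-likelihood `reps` times at each particle count
#' and summarizes the mean, standard deviation and coefficient of variation
#' (standard deviation divided by the absolute mean, so the CV stays positive
#' for negative log-likelihoods) of the replicate estimates.  Used to size
#' the particle count: the CV drops as `L` grows and the mean stabilizes once
#' the estimator has converged.
#'
#' @inheritParams tree_loglik
#' @param particle_grid increasing vector of particle counts to test.
#' @param reps replicate estimates per particle count (>= 2).
#' @param estimator which estimator to study, `"triplet"` (default),
#'   `"exact"` or `"trajectory"`.
#' @return data.frame of class `"smc_convergence"` with columns `L`, `mean`,
#'   `sd`, `cv`, `se` (standard error of the mean).
#' @export
estimator_convergence <- function(tree, model,
                                  particle_grid = c(50, 100, 250, 500, 1000),
                                  reps = 100, estimator = "triplet",
                                  scheme = "multinomial") {
  stopifnot(reps >= 2)
  fn <- switch(estimator, triplet = tree_loglik, exact = tree_loglik_exact,
               trajectory = trajectory_loglik,
               stop("unknown estimator: ", estimator))
  rows <- lapply(particle_grid, function(L) {
    est <- vapply(seq_len(reps),
                  function(r) fn(tree, model, L, scheme = scheme)$value, 0)
    data.frame(L = L, mean = mean(est), sd = stats::sd(est),
               cv = stats::sd(est) / abs(mean(est)),
               se = stats::sd(est) / sqrt(reps))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("smc_convergence", "data.frame")
  out
}

#' @export
plot.smc_convergence <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$L, x$mean, type = "b", xlab = "particles L",
                 ylab = "mean log-likelihood", ...)
  graphics::arrows(x$L, x$mean - 2 * x$se, x$L, x$mean + 2 * x$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::plot(x$L, log10(x$cv), type = "b", xlab = "particles L",
                 ylab = "log10 CV", ...)
  invisible(x)
}

#' Exact log-likelihood of the reduced discrete model
#'
#' Closed-form oracle for [discrete_model()] trees: with the type directly
#' observed the likelihood is the root-prior mass of the observed root type
#' times the division-kernel mass of every observed daughter pair (readout
#' series within a lifetime are redundant observations of a constant type).
#'
#' @param tree a `lineage_tree` whose readouts are types (0/1).
#' @param model a [discrete_model()].
#' @return exact log-likelihood (scalar; `-Inf` if any cell's readouts are
#'   internally inconsistent).
#' @export
discrete_tree_loglik_exact <- function(tree, model) {
  stopifnot(inherits(model, "discrete_model"))
  type_of <- function(cl) {
    ys <- unique(cl$readouts)
    if (length(ys) > 1) return(NA_integer_)
    as.integer(ys)
  }
  root_ty <- type_of(tree$cells[["0.1"]])
  if (is.na(root_ty)) return(-Inf)
  ll <- log(if (root_ty == 1L) model$root$p_on else 1 - model$root$p_on)
  mothers <- tree_mothers(tree)
  for (r in seq_len(nrow(mothers))) {
    g <- mothers$gen[r]; i <- mothers$idx[r]
    mt <- type_of(tree$cells[[cell_key(g, i)]])
    t1 <- type_of(tree$cells[[cell_key(g + 1L, 2L * i - 1L)]])
    t2 <- type_of(tree$cells[[cell_key(g + 1L, 2L * i)]])
    if (any(is.na(c(mt, t1, t2)))) return(-Inf)
    pr <- daughter_type_probs(mt, model)
    ll <- ll + log(pr[[2L * t1 + t2 + 1L]])
  }
  ll
}
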