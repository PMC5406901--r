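# Model contract
#
# A model object is a list with class c("<family>", "lineage_model") carrying
# a validated parameter list in $params and a root-state prior in $root.
# Every family implements four generics operating on "state sets" -- plain
# lists of aligned vectors (one entry per particle), with components
#   type  : discrete phenotype, 0 = OFF, 1 = ON
#   D, F  : dark / mature reporter concentrations (reporter models)
#   alpha_off, alpha_on : per-cell production rates (CTMC model only)
#
# The generics:
#   sample_root_states(model, L)             draws L founder birth states
#   sample_daughter_pairs(model, states)     division kernel, both daughters
#   advance_states(model, states, dt)        exact forward sampling over dt
#   obs_loglik(model, states, y)             log f(y | state) per particle
#
# advance_states is causal and exactly distributed (no discretization), so
# composing it over sub-intervals is statistically identical to one call.

#' @keywords internal
#' @noRd
subset_states <- function(states, idx) lapply(states, function(v) v[idx])

#' @keywords internal
#' @noRd
n_states <- function(states) length(states[[1]])

#' Update free parameters of a model
#'
#' Returns a copy of `model` with the named entries of `values` replacing the
#' corresponding parameters, revalidated.  Used by the sampler to evaluate
#' proposed parameter vectors.
#'
#' @param model a `lineage_model`.
#' @param values named numeric vector of parameter values.
#' @return the updated model.
#' @export
update_params <- function(model, values) {
  UseMethod("update_params")
}

#' @export
update_params.lineage_model <- function(model, values) {
  p <- model$params
  unknown <- setdiff(names(values), names(p))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(values)] <- as.list(as.numeric(values))
  do.call(model$constructor, c(p, list(root = model$root)))
}

#' @export
print.lineage_model <- function(x, ...) {
  cat(x$label, "\n  parameters: ",
      paste(names(x$params),
            vapply(x$params, function(v) format(v, digits = 4), ""),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname model_contract
#' @export
sample_root_states <- function(model, L) UseMethod("sample_root_states")

#' @rdname model_contract
#' @export
sample_daughter_pairs <- function(model, states)
  UseMethod("sample_daughter_pairs")

#' @rdname model_contract
#' @export
advance_states <- function(model, states, dt) UseMethod("advance_states")

#' @rdname model_contract
#' @export
obs_loglik <- function(model, states, y) UseMethod("obs_loglik")

#' Model contract generics
#'
#' Low-level generics every model family implements: sampling founder birth
#' states, the mother-to-daughters division kernel, exact forward sampling of
#' the within-lifetime dynamics, and the per-readout measurement density.
#' These are the only operations the SMC machinery needs, so new model
#' families plug in by providing methods.
#'
#' @param model a `lineage_model` object.
#' @param L number of particles to draw.
#' @param states a state set (list of aligned per-particle vectors).
#' @param dt interval to advance by (minutes).
#' @param y a single readout value.
#' @name model_contract
NULL

.check_simplex_row <- function(a, b, what) {
  if (a < 0 || a > 1 || b < 0 || b > 1 || a + 2 * b > 1 + 1e-12)
    stop(what, ": need both in [0,1] and first + 2*second <= 1")
}

#' Two-type branching-process model with reporter readouts
#'
#' The cell phenotype (OFF/ON) is fixed during a lifetime and can change only
#' at division: the pair of daughter types is drawn from a row of the
#' transition table selected by the mother's type (see
#' [daughter_type_probs()]).  The phenotype sets the production rate of a
#' two-stage fluorescent reporter (dark pool `D` maturing into fluorescent
#' pool `F`, both diluted), whose mature pool is observed at discrete times
#' with signal-proportional Gaussian noise
#' `y ~ N(c * F, sigma2 * F)` (see [measurement_loglik()]).  Reporter
#' concentrations pass from mother to daughters unchanged.
#'
#' Default reporter constants correspond to dilution by growth with a 30 min
#' doubling time (`delta = log(2)/30`), a 15 min maturation half-time
#' (`m = log(2)/15`), and a ten-fold ON/OFF induction ratio.
#'
#' @param theta1 P(both daughters OFF | mother OFF).
#' @param theta2 P(first OFF, second ON | mother OFF); by symmetry also the
#'   probability of the mirrored pair, so `theta1 + 2*theta2 <= 1`.
#' @param theta3 P(both daughters OFF | mother ON).
#' @param theta4 P(first OFF, second ON | mother ON); `theta3 + 2*theta4 <= 1`.
#' @param alpha_off,alpha_on reporter production rates (conc/min) of OFF and
#'   ON cells, `alpha_on > alpha_off`.
#' @param delta dilution rate (1/min).
#' @param m maturation rate (1/min).
#' @param c fluorescence per concentration unit of mature reporter.
#' @param sigma2 measurement variance per concentration unit.
#' @param root root-cell prior: list with `p_on` (probability the founder is
#'   ON) and `D0`, `F0` (founder birth concentrations).
#' @param var_floor variance floor (concentration units) used as
#'   `sigma2 * max(F, var_floor)` so the likelihood stays finite for fully
#'   dark cells.
#' @return a `lineage_model` of class `"branching_model"`.
#' @export
branching_model <- function(theta1 = 0.6, theta2 = 0.1,
                            theta3 = 0.1, theta4 = 0.05,
                            alpha_off = 1, alpha_on = 10,
                            delta = log(2) / 30, m = log(2) / 15,
                            c = 1, sigma2 = 1,
                            root = list(p_on = 0.5, D0 = 0, F0 = 0),
                            var_floor = 1e-6) {
  .check_simplex_row(theta1, theta2, "theta1/theta2")
  .check_simplex_row(theta3, theta4, "theta3/theta4")
  if (alpha_off < 0 || alpha_on < 0) stop("production rates must be >= 0")
  if (delta < 0 || m < 0) stop("delta and m must be >= 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  params <- list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 theta4 = theta4, alpha_off = alpha_off, alpha_on = alpha_on,
                 delta = delta, m = m, c = c, sigma2 = sigma2)
  structure(list(params = params, root = root, var_floor = var_floor,
                 constructor = branching_model,
                 label = "two-type branching process with reporter readouts"),
            class = c("branching_model", "lineage_model"))
}

#' Two-state switching model with extrinsic production-rate noise
#'
#' The phenotype follows a two-state continuous-time Markov chain during each
#' lifetime, with switching rates `q1` (OFF to ON) and `q2` (ON to OFF); at
#' division both daughters inherit the mother's current type and reporter
#' concentrations.  Each newborn cell draws its own pair of production rates
#' in a perfectly correlated way: a single lognormal multiplier `z` with
#' `log z ~ N(log_location, sigma_ext^2)` scales both location parameters
#' (see [extrinsic_draw()]).  Reporter dynamics and measurement noise are as
#' in [branching_model()].
#'
#' Default switching rates put the model in the slow regime (mean holding
#' times of 100 min, beyond a 30 min lifetime) in which ancestry carries most
#' of the information about a cell's state.
#'
#' @param q1 OFF-to-ON switching rate (1/min).
#' @param q2 ON-to-OFF switching rate (1/min).
#' @param mu_alpha_off,mu_alpha_on production-rate scale (median) parameters.
#' @param sigma_ext extrinsic-noise log standard deviation (>= 0).
#' @param log_location location of `log z`; 0 (the default) makes
#'   `mu_alpha_*` the median production rates.
#' @inheritParams branching_model
#' @return a `lineage_model` of class `"ctmc_model"`.
#' @export
ctmc_model <- function(q1 = 0.01, q2 = 0.01,
                       mu_alpha_off = 1, mu_alpha_on = 10,
                       sigma_ext = 0.3, delta = log(2) / 30, m = log(2) / 15,
                       c = 1, sigma2 = 9, log_location = 0,
                       root = list(p_on = 0.5, D0 = 0, F0 = 0),
                       var_floor = 1e-6) {
  if (q1 < 0 || q2 < 0) stop("switching rates must be >= 0")
  if (sigma_ext < 0) stop("sigma_ext must be >= 0")
  if (mu_alpha_off < 0 || mu_alpha_on < 0) stop("rate scales must be >= 0")
  if (delta < 0 || m < 0) stop("delta and m must be >= 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  params <- list(q1 = q1, q2 = q2, mu_alpha_off = mu_alpha_off,
                 mu_alpha_on = mu_alpha_on, sigma_ext = sigma_ext,
                 delta = delta, m = m, c = c, sigma2 = sigma2,
                 log_location = log_location)
  structure(list(params = params, root = root, var_floor = var_floor,
                 constructor = ctmc_model,
                 label = "two-state CTMC switching with extrinsic noise"),
            class = c("ctmc_model", "lineage_model"))
}

#' Reduced discrete model with directly observable types
#'
#' A stripped-down branching process used for validation: the state is the
#' phenotype alone (no reporter), the type is constant within a lifetime, and
#' each readout observes the type exactly (log-likelihood 0 on a match,
#' `-Inf` otherwise).  Because the state is fully observed the tree
#' likelihood has a closed form -- the product of the root prior mass and the
#' division-kernel mass of every observed daughter pair -- which makes this
#' model an exact oracle for the SMC estimators.
#'
#' @inheritParams branching_model
#' @param root list with `p_on`, the root-type prior.
#' @return a `lineage_model` of class `"discrete_model"`.
#' @seealso [discrete_tree_loglik_exact()]
#' @export
discrete_model <- function(theta1 = 0.6, theta2 = 0.1,
                           theta3 = 0.1, theta4 = 0.05,
                           root = list(p_on = 0.5)) {
  .check_simplex_row(theta1, theta2, "theta1/theta2")
  .check_simplex_row(theta3, theta4, "theta3/theta4")
  params <- list(theta1 = theta1, theta2 = theta2,
                 theta3 = theta3, theta4 = theta4)
  structure(list(params = params, root = root,
                 constructor = discrete_model,
                 label = "reduced branching process, types observable"),
            class = c("discrete_model", "lineage_model"))
}

#' Daughter-pair type probabilities of the branching process
#'
#' The division kernel of the two-type branching process as a probability
#' vector over the ordered daughter pairs (OFF,OFF), (OFF,ON), (ON,OFF),
#' (ON,ON).  The two mixed entries are equal by symmetry and each row closes
#' to one, so an OFF mother yields
#' `(theta1, theta2, theta2, 1 - theta1 - 2*theta2)` and an ON mother
#' `(theta3, theta4, theta4, 1 - theta3 - 2*theta4)`.
#'
#' @param mother_type `"OFF"`/`"ON"` or 0/1.
#' @param params a [branching_model()], [discrete_model()], or a named list
#'   with `theta1..theta4`.
#' @return named numeric vector of the four pair probabilities.
#' @examples
#' daughter_type_probs("OFF", branching_model())
#' @export
daughter_type_probs <- function(mother_type, params) {
  p <- if (inherits(params, "lineage_model")) params$params else params
  .check_simplex_row(p$theta1, p$theta2, "theta1/theta2")
  .check_simplex_row(p$theta3, p$theta4, "theta3/theta4")
  ty <- if (is.character(mother_type)) {
    match.arg(toupper(mother_type), c("OFF", "ON")) == "ON"
  } else as.logical(mother_type)
  v <- if (ty) c(p$theta3, p$theta4, p$theta4, 1 - p$theta3 - 2 * p$theta4)
       else    c(p$theta1, p$theta2, p$theta2, 1 - p$theta1 - 2 * p$theta2)
  stats::setNames(pmax(v, 0), c("OFF.OFF", "OFF.ON", "ON.OFF", "ON.ON"))
}

# vectorized draw of daughter-pair categories; returns list(t1, t2) of 0/1
#' @keywords internal
#' @noRd
draw_pair_types <- function(mother_type, p) {
  row_off <- c(p$theta1, p$theta2, p$theta2, 1 - p$theta1 - 2 * p$theta2)
  row_on <- c(p$theta3, p$theta4, p$theta4, 1 - p$theta3 - 2 * p$theta4)
  on <- mother_type == 1L
  c1 <- row_off[1] + (row_on[1] - row_off[1]) * on
  c2 <- c1 + row_off[2] + (row_on[2] - row_off[2]) * on
  c3 <- c2 + row_off[3] + (row_on[3] - row_off[3]) * on
  u <- stats::runif(length(mother_type))
  cat <- 1L + (u > c1) + (u > c2) + (u > c3)
  list(t1 = as.integer(cat >= 3L), t2 = as.integer(cat == 2L | cat == 4L))
}

#' Draw correlated extrinsic production rates
#'
#' Newborn cells receive their own OFF/ON production-rate pair by scaling the
#' population location parameters with one shared lognormal multiplier
#' `z = exp(log_location + sigma_ext * eps)`, `eps ~ N(0,1)`:
#' `alpha_off = mu_alpha_off * z`, `alpha_on = mu_alpha_on * z`.  The shared
#' multiplier makes the two log-rates perfectly correlated across cells, and
#' `sigma_ext = 0` removes the extrinsic variability.
#'
#' @param mu_alpha_off,mu_alpha_on location (median, when `log_location = 0`)
#'   parameters of the two rates.
#' @param sigma_ext log standard deviation of the multiplier (>= 0).
#' @param n number of cells to draw for.
#' @param log_location location of `log z` (default 0).
#' @return list with vectors `alpha_off`, `alpha_on`, `z`.
#' @export
extrinsic_draw <- function(mu_alpha_off, mu_alpha_on, sigma_ext, n = 1,
                           log_location = 0) {
  if (sigma_ext < 0) stop("sigma_ext must be >= 0")
  z <- exp(log_location + sigma_ext * stats::rnorm(n))
  list(alpha_off = mu_alpha_off * z, alpha_on = mu_alpha_on * z, z = z)
}

#' Measurement log-density of a fluorescence readout
#'
#' The readout of a cell with mature-reporter concentration `F` is modeled as
#' `y ~ N(c * F, sigma2 * F)`: each concentration unit emits fluorescence
#' with mean `c` and variance `sigma2`, so both the mean and the variance of
#' the total signal scale with `F`.  Since the stated variance degenerates at
#' `F = 0`, the implementation uses `sigma2 * max(F, var_floor)`, keeping the
#' density finite for dark cells.
#'
#' @param y readout value (arbitrary fluorescence units).
#' @param F mature reporter concentration (>= 0), vectorized.
#' @param c fluorescence scale per concentration unit.
#' @param sigma2 variance per concentration unit (> 0).
#' @param var_floor variance floor in concentration units.
#' @return log density, vectorized over `F` (and `y`).
#' @export
measurement_loglik <- function(y, F, c = 1, sigma2 = 1, var_floor = 1e-6) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (any(F < 0)) stop("F must be >= 0")
  stats::dnorm(y, mean = c * F, sd = sqrt(sigma2 * pmax(F, var_floor)),
               log = TRUE)
}

#' Sample a two-state CTMC type path
#'
#' Forward-simulates the phenotype of one cell over its lifetime: exponential
#' holding times with rate `q1` while OFF and `q2` while ON, alternating
#' types starting from `x0`.
#'
#' @param x0 initial type (0 = OFF, 1 = ON).
#' @param q1 OFF-to-ON rate (1/min).
#' @param q2 ON-to-OFF rate (1/min).
#' @param T lifetime (min, > 0).
#' @return list with `switch_times` (strictly increasing, in `(0, T)`),
#'   `types` (type on each inter-switch segment, starting with `x0`),
#'   `x0` and `T`.
#' @export
sample_ctmc_path <- function(x0, q1, q2, T) {
  if (T <= 0) stop("T must be > 0")
  if (q1 < 0 || q2 < 0) stop("rates must be >= 0")
  ty <- as.integer(x0)
  t <- 0
  sw <- numeric(0)
  types <- ty
  repeat {
    r <- if (ty == 1L) q2 else q1
    if (r <= 0) break
    t <- t + stats::rexp(1, r)
    if (t >= T) break
    sw <- c(sw, t)
    ty <- 1L - ty
    types <- c(types, ty)
  }
  list(switch_times = sw, types = types, x0 = as.integer(x0), T = T)
}

# ---- branching model methods -------------------------------------------

#' @export
sample_root_states.branching_model <- function(model, L) {
  list(type = as.integer(stats::runif(L) < model$root$p_on),
       D = rep(as.numeric(model$root$D0), L),
       F = rep(as.numeric(model$root$F0), L))
}

#' @export
sample_daughter_pairs.branching_model <- function(model, states) {
  tt <- draw_pair_types(states$type, model$params)
  list(d1 = list(type = tt$t1, D = states$D, F = states$F),
       d2 = list(type = tt$t2, D = states$D, F = states$F))
}

#' @export
advance_states.branching_model <- function(model, states, dt) {
  p <- model$params
  alpha <- p$alpha_off + (p$alpha_on - p$alpha_off) * (states$type == 1L)
  out <- propagate_reporter(states$D, states$F, alpha, p$delta, p$m, dt)
  list(type = states$type, D = out$D, F = out$F)
}

#' @export
obs_loglik.branching_model <- function(model, states, y) {
  p <- model$params
  measurement_loglik(y, states$F, p$c, p$sigma2, model$var_floor)
}

# ---- CTMC model methods -------------------------------------------------

#' @export
sample_root_states.ctmc_model <- function(model, L) {
  p <- model$params
  a <- extrinsic_draw(p$mu_alpha_off, p$mu_alpha_on, p$sigma_ext, L,
                      p$log_location)
  list(type = as.integer(stats::runif(L) < model$root$p_on),
       D = rep(as.numeric(model$root$D0), L),
       F = rep(as.numeric(model$root$F0), L),
       alpha_off = a$alpha_off, alpha_on = a$alpha_on)
}

#' @export
sample_daughter_pairs.ctmc_model <- function(model, states) {
  p <- model$params
  L <- n_states(states)
  mk <- function() {
    a <- extrinsic_draw(p$mu_alpha_off, p$mu_alpha_on, p$sigma_ext, L,
                        p$log_location)
    list(type = states$type, D = states$D, F = states$F,
         alpha_off = a$alpha_off, alpha_on = a$alpha_on)
  }
  list(d1 = mk(), d2 = mk())
}

# Exact vectorized advance: per particle, sample the CTMC switch structure on
# [0, dt] and accumulate the input-kernel integrals over the ON segments.
# Because the reporter ODE is affine, the end state is
#   D(dt) = PhiDD D0 + alpha_off H_D(dt) + (alpha_on - alpha_off) S_D
#   F(dt) = PhiFD D0 + PhiFF F0 + alpha_off H_F(dt) + (alpha_on - alpha_off) S_F
# with S = sum over ON segments [u,v] of H(dt - u) - H(dt - v).
#' @export
advance_states.ctmc_model <- function(model, states, dt) {
  p <- model$params
  L <- n_states(states)
  k <- p$delta + p$m
  if (dt <= 0) return(states)
  ty <- states$type
  cur <- numeric(L)
  SD <- numeric(L)
  SF <- numeric(L)
  active <- rep(TRUE, L)
  HD <- function(tau) if (k > 0) -expm1(-k * tau) / k else tau
  HFr <- function(tau) (if (p$delta > 0) -expm1(-p$delta * tau) / p$delta
                        else tau) - HD(tau)
  while (any(active)) {
    idx <- which(active)
    rate <- ifelse(ty[idx] == 1L, p$q2, p$q1)
    hold <- ifelse(rate > 0, stats::rexp(length(idx), pmax(rate, 1e-300)), Inf)
    nxt <- cur[idx] + hold
    seg_end <- pmin(nxt, dt)
    on <- ty[idx] == 1L
    if (any(on)) {
      j <- idx[on]
      u <- cur[j]
      v <- seg_end[on]
      SD[j] <- SD[j] + HD(dt - u) - HD(dt - v)
      SF[j] <- SF[j] + HFr(dt - u) - HFr(dt - v)
    }
    flips <- nxt < dt
    ty[idx[flips]] <- 1L - ty[idx[flips]]
    cur[idx] <- nxt
    active[idx] <- flips
  }
  phiDD <- exp(-k * dt)
  phiFF <- exp(-p$delta * dt)
  phiFD <- phiFF - phiDD
  da <- states$alpha_on - states$alpha_off
  list(type = ty,
       D = phiDD * states$D + states$alpha_off * HD(dt) + da * SD,
       F = phiFD * states$D + phiFF * states$F +
           states$alpha_off * HFr(dt) + da * SF,
       alpha_off = states$alpha_off, alpha_on = states$alpha_on)
}

#' @export
obs_loglik.ctmc_model <- function(model, states, y) {
  p <- model$params
  measurement_loglik(y, states$F, p$c, p$sigma2, model$var_floor)
}

# ---- reduced discrete model methods ------------------------------------

#' @export
sample_root_states.discrete_model <- function(model, L) {
  list(type = as.integer(stats::runif(L) < model$root$p_on))
}

#' @export
sample_daughter_pairs.discrete_model <- function(model, states) {
  tt <- draw_pair_types(states$type, model$params)
  list(d1 = list(type = tt$t1), d2 = list(type = tt$t2))
}

#' @export
advance_states.discrete_model <- function(model, states, dt) states

#' @export
obs_loglik.discrete_model <- function(model, states, y) {
  ifelse(states$type == as.integer(y), 0, -Inf)
}

# ---- whole-lifetime simulation -----------------------------------------

#' Simulate one cell's latent trajectory over its lifetime
#'
#' Draws a complete latent trajectory for a single cell: the type path (a
#' single constant segment for the branching model, a sampled CTMC path for
#' the switching model) together with the piecewise closed-form reporter
#' dynamics, which make the trajectory evaluable at any time in
#' `[0, lifetime]` via [trajectory_state()].
#'
#' @param model a `lineage_model`.
#' @param state0 birth state: list with `type`, `D`, `F` (and, for the CTMC
#'   model, `alpha_off`, `alpha_on`; missing rates are drawn fresh).
#' @param lifetime lifetime in minutes.
#' @return an object of class `"cell_trajectory"`.
#' @export
simulate_lifetime <- function(model, state0, lifetime) {
  UseMethod("simulate_lifetime")
}

#' @export
simulate_lifetime.branching_model <- function(model, state0, lifetime) {
  p <- model$params
  alpha <- if (state0$type == 1L) p$alpha_on else p$alpha_off
  structure(list(breaks = numeric(0), types = state0$type,
                 alpha = alpha, delta = p$delta, m = p$m,
                 D0 = state0$D, F0 = state0$F, lifetime = lifetime),
            class = "cell_trajectory")
}

#' @export
simulate_lifetime.ctmc_model <- function(model, state0, lifetime) {
  p <- model$params
  if (is.null(state0$alpha_off)) {
    a <- extrinsic_draw(p$mu_alpha_off, p$mu_alpha_on, p$sigma_ext, 1,
                        p$log_location)
    state0$alpha_off <- a$alpha_off
    state0$alpha_on <- a$alpha_on
  }
  path <- sample_ctmc_path(state0$type, p$q1, p$q2, lifetime)
  alpha <- ifelse(path$types == 1L, state0$alpha_on, state0$alpha_off)
  structure(list(breaks = path$switch_times, types = path$types,
                 alpha = alpha, delta = p$delta, m = p$m,
                 D0 = state0$D, F0 = state0$F, lifetime = lifetime,
                 alpha_off = state0$alpha_off, alpha_on = state0$alpha_on),
            class = "cell_trajectory")
}

#' Evaluate a simulated cell trajectory
#'
#' @param traj a `"cell_trajectory"` from [simulate_lifetime()].
#' @param t time(s) in `[0, lifetime]` on the cell-local clock.
#' @return list with vectors `type`, `D`, `F` at the requested times.
#' @export
trajectory_state <- function(traj, t) {
  if (any(t < 0 | t > traj$lifetime + 1e-9))
    stop("t must lie in [0, lifetime]")
  bounds <- c(0, traj$breaks, traj$lifetime)
  out_type <- integer(length(t))
  out_D <- numeric(length(t))
  out_F <- numeric(length(t))
  for (i in seq_along(t)) {
    D <- traj$D0; F <- traj$F0
    ti <- t[i]
    seg <- 1L
    while (seg <= length(traj$types) && bounds[seg] < ti) {
      dt <- min(bounds[seg + 1L], ti) - bounds[seg]
      pr <- propagate_reporter(D, F, traj$alpha[seg], traj$delta, traj$m, dt)
      D <- pr$D; F <- pr$F
      seg <- seg + 1L
    }
    out_type[i] <- traj$types[min(max(findInterval(ti, bounds, left.open = TRUE),
                                      1L), length(traj$types))]
    out_D[i] <- D; out_F[i] <- F
  }
  list(type = out_type, D = out_D, F = out_F)
}
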