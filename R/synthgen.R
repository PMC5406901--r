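# Forward simulation of complete lineage-tree datasets.

#' Simulation configuration
#'
#' Bundles everything the forward simulator needs: the generative model, the
#' tree depth, the lifetime rule and the measurement interval.  Readouts are
#' placed at multiples of `dt` excluding birth (`t = 0`) and including the
#' division time when it is a multiple -- a 30 min lifetime sampled every
#' 5 min yields 6 readouts per cell.
#'
#' @param model a `lineage_model` used for data generation.
#' @param n_generations final generation `N >= 0`; the complete tree has
#'   `2^(N+1) - 1` cells.
#' @param lifetime constant lifetime in minutes, or a function
#'   `function(gen, idx)` returning a per-cell lifetime.
#' @param dt measurement interval in minutes (`dt <= lifetime`).
#' @param latent attach the latent truth (type path, division-time
#'   concentrations) to every cell?
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(model, n_generations, lifetime = 30, dt = 5,
                       latent = FALSE) {
  stopifnot(n_generations >= 0)
  if (is.numeric(lifetime) && any(dt > lifetime))
    stop("dt must not exceed the lifetime")
  structure(list(model = model, n_generations = as.integer(n_generations),
                 lifetime = lifetime, dt = dt, latent = latent),
            class = "sim_config")
}

#' @keywords internal
#' @noRd
scalar_state <- function(states, l = 1L) lapply(states, `[`, l)

#' Simulate a complete lineage tree
#'
#' Draws the founder's birth state from the model's root prior and generates
#' the full binary tree depth-first: each cell's latent trajectory is sampled
#' over its lifetime ([simulate_lifetime()]), noisy readouts are drawn from
#' the measurement model at the configured observation times, and the two
#' daughters' birth states are drawn from the division kernel at the
#' division time.
#'
#' For reporter models the readout at time `t` is drawn from
#' `N(c * F(t), sigma2 * max(F(t), var_floor))`; for the reduced discrete
#' model the readout is the type itself.
#'
#' @param config a [sim_config()].
#' @return a [lineage_tree()]; with `latent = TRUE` each cell carries its
#'   type path, division-time concentrations `D_div`/`F_div`, birth state and
#'   noise-free fluorescence `F_obs`.
#' @export
simulate_tree <- function(config) {
  model <- config$model
  lt_of <- if (is.function(config$lifetime)) config$lifetime
           else function(gen, idx) config$lifetime
  discrete <- inherits(model, "discrete_model")
  cells <- list()
  rec <- function(gen, idx, state0) {
    T <- lt_of(gen, idx)
    obs <- seq(config$dt, T + 1e-9, by = config$dt)
    obs <- obs[obs <= T + 1e-9]
    if (discrete) {
      y <- rep(as.numeric(state0$type), length(obs))
      end <- state0
      latent <- if (config$latent)
        list(type_path = cbind(time = 0, type = state0$type),
             D_div = NA_real_, F_div = NA_real_)
    } else {
      p <- model$params
      traj <- simulate_lifetime(model, state0, T)
      st <- trajectory_state(traj, obs)
      y <- stats::rnorm(length(obs), p$c * st$F,
                        sqrt(p$sigma2 * pmax(st$F, model$var_floor)))
      at_T <- trajectory_state(traj, T)
      end <- list(type = at_T$type, D = at_T$D, F = at_T$F)
      if (!is.null(traj$alpha_off)) {
        end$alpha_off <- traj$alpha_off
        end$alpha_on <- traj$alpha_on
      }
      latent <- if (config$latent)
        list(type_path = cbind(time = c(0, traj$breaks), type = traj$types),
             D_div = at_T$D, F_div = at_T$F,
             D0 = state0$D, F0 = state0$F, F_obs = st$F)
    }
    cells[[length(cells) + 1L]] <<-
      cell_record(gen, idx, T, obs, y,
                  latent = if (config$latent) latent)
    if (gen < config$n_generations) {
      pair <- sample_daughter_pairs(model, end)
      rec(gen + 1L, 2L * idx - 1L, scalar_state(pair$d1))
      rec(gen + 1L, 2L * idx, scalar_state(pair$d2))
    }
  }
  rec(0L, 1L, scalar_state(sample_root_states(model, 1L)))
  lineage_tree(cells)
}

#' Example datasets at the documented generation settings
#'
#' Convenience wrappers reproducing the two study designs.  Example 1: one
#' branching-process tree, seven generations (255 cells), 30 min lifetimes,
#' readouts every 5 min (6 per cell), division kernel
#' `theta = (0.6, 0.1, 0.1, 0.05)`.  Example 2: one CTMC-switching tree with
#' extrinsic noise `sigma_ext = 0.3`, five generations by default, same
#' lifetime and sampling.  The reporter constants are the model defaults.
#'
#' @param example 1 (branching process) or 2 (CTMC switching).
#' @param seed integer seed for reproducibility.
#' @param n_generations tree depth override (default 7 for Example 1, 5 for
#'   Example 2).
#' @param latent attach latent truth?
#' @return a [lineage_tree()].
#' @export
make_example_dataset <- function(example = 1, seed = 1,
                                 n_generations = NULL, latent = FALSE) {
  set.seed(seed)
  if (example == 1) {
    n <- if (is.null(n_generations)) 7L else n_generations
    simulate_tree(sim_config(branching_model(), n, lifetime = 30, dt = 5,
                             latent = latent))
  } else if (example == 2) {
    n <- if (is.null(n_generations)) 5L else n_generations
    simulate_tree(sim_config(ctmc_model(), n, lifetime = 30, dt = 5,
                             latent = latent))
  } else stop("example must be 1 or 2")
}
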