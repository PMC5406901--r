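# Pseudo-marginal Metropolis-Hastings over model parameters.
#
# The sampler substitutes the SMC estimate of the tree log-likelihood for the
# intractable exact value.  Because the (exponentiated) estimate is unbiased,
# the chain still targets the exact posterior provided the incumbent's
# estimate is stored and reused, never refreshed -- which is how the
# bookkeeping below works.

# ---- priors -------------------------------------------------------------

#' Prior specifications for scalar parameters
#'
#' Three prior families cover the parameters of the shipped models: a flat
#' prior on `[0, 1]` (used for the branching-process transition
#' probabilities), a uniform prior on an interval, and a log-uniform prior on
#' a positive interval (density proportional to `1/x`).  Each returns a spec
#' holding the support and a log-density function.
#'
#' @param lo,hi support bounds (`lo < hi`; positive for `prior_log_uniform`).
#' @return a list of class `"prior_spec"` with `logd(x)` and `support`.
#' @name priors
NULL

prior_spec <- function(logd, support, label) {
  structure(list(logd = logd, support = support, label = label),
            class = "prior_spec")
}

#' @rdname priors
#' @export
prior_flat01 <- function() {
  prior_spec(function(x) ifelse(x >= 0 & x <= 1, 0, -Inf), c(0, 1),
             "flat on [0,1]")
}

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(lo < hi)
  prior_spec(function(x) stats::dunif(x, lo, hi, log = TRUE), c(lo, hi),
             sprintf("uniform(%g, %g)", lo, hi))
}

#' @rdname priors
#' @export
prior_log_uniform <- function(lo, hi) {
  stopifnot(lo > 0, lo < hi)
  lz <- log(log(hi) - log(lo))
  prior_spec(function(x) ifelse(x >= lo & x <= hi, -log(x) - lz, -Inf),
             c(lo, hi), sprintf("log-uniform(%g, %g)", lo, hi))
}

# ---- proposals ----------------------------------------------------------

#' @keywords internal
#' @noRd
ldirichlet <- function(x, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' @keywords internal
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# constrained pair (a, b) with a + 2b <= 1  <->  simplex point (a, 2b, rest)
#' @keywords internal
#' @noRd
pair_to_simplex <- function(ab, eps) {
  p <- c(ab[1], 2 * ab[2], 1 - ab[1] - 2 * ab[2])
  p <- pmax(p, eps)
  p / sum(p)
}

#' Dirichlet proposal for a constrained transition-probability pair
#'
#' Proposes a new value of a pair `(a, b)` subject to `a, b >= 0` and
#' `a + 2b <= 1` (one row of the branching-process transition table, where
#' `b` is the probability of each of the two mirrored mixed pairs).  The pair
#' is mapped to the 3-simplex point `(a, 2b, 1 - a - 2b)` and a Dirichlet
#' draw with that mean and concentration `kappa` is mapped back; large
#' `kappa` concentrates the proposal at the current value.  The returned log
#' Hastings ratio `log q(x | x') - log q(x' | x)` accounts for the asymmetry
#' of the kernel (the constant Jacobian of the `2b` reparameterization
#' cancels between the two directions).  Components at the simplex boundary
#' are jittered by `eps` so the reverse density stays positive.
#'
#' @param current numeric pair `(a, b)` satisfying the constraint.
#' @param kappa Dirichlet concentration (> 0).
#' @param eps boundary jitter.
#' @return list with `value` (the proposed pair) and `log_hr`.
#' @export
propose_simplex_pair <- function(current, kappa = 100, eps = 1e-6) {
  stopifnot(kappa > 0)
  p <- pair_to_simplex(current, eps)
  x <- rdirichlet1(kappa * p)
  prop <- c(x[1], x[2] / 2)
  q <- pair_to_simplex(prop, eps)
  log_hr <- ldirichlet(p, kappa * q) - ldirichlet(x, kappa * p)
  list(value = prop, log_hr = log_hr)
}

#' Lognormal random-walk proposal for a positive scalar
#'
#' Multiplicative random walk `x' = x * exp(step * eps)`, `eps ~ N(0, 1)`.
#' The log Hastings ratio of this kernel is `log(x'/x)`.
#'
#' @param current current value (> 0).
#' @param step log-scale step size (> 0).
#' @return list with `value` and `log_hr`.
#' @export
propose_positive <- function(current, step = 0.1) {
  stopifnot(current > 0, step >= 0)
  prop <- current * exp(step * stats::rnorm(1))
  list(value = prop, log_hr = log(prop / current))
}

#' Proposal blocks for the sampler
#'
#' The sampler's proposal is a list of blocks, proposed jointly each
#' iteration with a single accept/reject decision.  `proposal_simplex()`
#' declares a Dirichlet block over a constrained transition-probability pair
#' (see [propose_simplex_pair()]); `proposal_lognorm()` a lognormal
#' random-walk block for one positive scalar (see [propose_positive()]).
#'
#' @param params character pair of parameter names, e.g.
#'   `c("theta1", "theta2")`.
#' @param param single parameter name.
#' @param kappa Dirichlet concentration.
#' @param step lognormal step size.
#' @param eps simplex boundary jitter.
#' @return a proposal block for [pmmh()].
#' @name proposals
NULL

#' @rdname proposals
#' @export
proposal_simplex <- function(params, kappa = 100, eps = 1e-6) {
  stopifnot(length(params) == 2)
  structure(list(type = "simplex", params = params, kappa = kappa,
                 eps = eps), class = "proposal_block")
}

#' @rdname proposals
#' @export
proposal_lognorm <- function(param, step = 0.1) {
  stopifnot(length(param) == 1)
  structure(list(type = "lognorm", params = param, step = step),
            class = "proposal_block")
}

#' @keywords internal
#' @noRd
propose_all <- function(blocks, current) {
  prop <- current
  log_hr <- 0
  for (b in blocks) {
    if (b$type == "simplex") {
      pr <- propose_simplex_pair(current[b$params], b$kappa, b$eps)
    } else {
      pr <- propose_positive(current[b$params], b$step)
    }
    prop[b$params] <- pr$value
    log_hr <- log_hr + pr$log_hr
  }
  list(value = prop, log_hr = log_hr)
}

# ---- the sampler --------------------------------------------------------

#' Pseudo-marginal Metropolis-Hastings over lineage-tree data
#'
#' Fits a lineage model to one or more observed trees by pseudo-marginal
#' MCMC: at each iteration all free parameters are proposed jointly from the
#' declared proposal blocks, the marginal log-likelihood of the proposal is
#' estimated by the recursive tree SMC ([tree_loglik()]; summed over trees),
#' and the move is accepted with the Metropolis-Hastings probability computed
#' from the *estimated* log-likelihoods, the prior, and the Hastings
#' correction.  The incumbent's estimate is stored and reused, never
#' recomputed, which is what makes the noisy-likelihood chain target the
#' exact posterior.
#'
#' Reproducibility: all randomness is derived from `seed` through three
#' per-iteration counter-based streams (proposal, SMC, accept), so a run is
#' reproducible given `(seed, n_iter, n_particles)`.
#'
#' @param data a [lineage_tree()] or a list of trees (independent, their
#'   log-likelihoods add).
#' @param model a `lineage_model` carrying the fixed parameters and starting
#'   values for the free ones.
#' @param proposal list of proposal blocks ([proposal_simplex()],
#'   [proposal_lognorm()]).
#' @param prior named list of prior specs ([prior_flat01()] etc.), one per
#'   free parameter.
#' @param init named numeric vector of starting values for the free
#'   parameters (its names define the free-parameter set).
#' @param n_iter number of MCMC iterations.
#' @param n_particles SMC particle count per likelihood evaluation.
#' @param likelihood `"tree"` for the recursive tree SMC (default),
#'   `"trajectory"` for the ancestry-free baseline
#'   ([trajectory_loglik()]).
#' @param loglik optional plug-in replacing the SMC estimate: a function
#'   `function(params, model)` returning a log-likelihood.  With an exact
#'   plug-in the sampler is a standard Metropolis-Hastings chain.
#' @param seed integer master seed (optional).
#' @param scheme SMC resampling scheme, see [resample()].
#' @param verbose print progress every 500 iterations.
#' @return an object of class `"pmmh_fit"`: list with `draws` (n_iter x p
#'   matrix), `loglik` (stored estimate per iteration), `accepted` (logical),
#'   `init`, `acceptance_rate`, `n_particles`, `seed`, `burn_in` (0 for a raw
#'   chain), `thin` (1).
#' @seealso [thin_chain()], [posterior_summary()], [summary.pmmh_fit()]
#' @examples
#' \donttest{
#' set.seed(1)
#' tree <- simulate_tree(sim_config(branching_model(), n_generations = 3))
#' fit <- pmmh(tree, branching_model(),
#'             proposal = list(proposal_simplex(c("theta1", "theta2")),
#'                             proposal_simplex(c("theta3", "theta4"))),
#'             prior = list(theta1 = prior_flat01(), theta2 = prior_flat01(),
#'                          theta3 = prior_flat01(), theta4 = prior_flat01()),
#'             init = c(theta1 = 0.25, theta2 = 0.25,
#'                      theta3 = 0.25, theta4 = 0.25),
#'             n_iter = 50, n_particles = 50, seed = 1)
#' coef(fit)
#' }
#' @export
pmmh <- function(data, model, proposal, prior, init, n_iter,
                 n_particles = 1000, likelihood = c("tree", "trajectory"),
                 loglik = NULL, seed = NULL, scheme = "multinomial",
                 verbose = FALSE) {
  likelihood <- match.arg(likelihood)
  stopifnot(n_iter >= 1, n_particles >= 1)
  if (is.null(names(init)) || any(names(init) == ""))
    stop("init must be a fully named numeric vector")
  free <- names(init)
  if (!setequal(free, names(prior)))
    stop("prior must name exactly the free parameters: ",
         paste(free, collapse = ", "))
  prop_pars <- unlist(lapply(proposal, `[[`, "params"))
  if (!setequal(prop_pars, free) || anyDuplicated(prop_pars))
    stop("proposal blocks must cover each free parameter exactly once")
  trees <- if (inherits(data, "lineage_tree")) list(data) else data
  if (is.null(loglik)) {
    est_fn <- if (likelihood == "tree") tree_loglik else trajectory_loglik
    loglik <- function(params, mdl)
      sum(vapply(trees,
                 function(tr) est_fn(tr, mdl, n_particles,
                                     scheme = scheme)$value, 0))
  }
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  s_prop <- seed_stream(seed, n_iter + 1L, salt = 1L)
  s_smc <- seed_stream(seed, n_iter + 1L, salt = 2L)
  s_acc <- seed_stream(seed, n_iter + 1L, salt = 3L)

  logprior <- function(v)
    sum(vapply(free, function(nm) prior[[nm]]$logd(v[[nm]]), 0))
  cur <- init
  lp_cur <- logprior(cur)
  if (!is.finite(lp_cur)) stop("init is outside the prior support")
  cur_model <- if (is.null(model)) NULL else update_params(model, cur)
  set.seed(s_smc[n_iter + 1L])
  ll_cur <- loglik(cur, cur_model)
  if (!is.finite(ll_cur))
    stop("log-likelihood estimate at init is -Inf; choose another init")

  p <- length(free)
  draws <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, free))
  ll_trace <- numeric(n_iter)
  acc <- logical(n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(s_prop[it])
    pr <- propose_all(proposal, cur)
    lp_prop <- logprior(pr$value)
    if (is.finite(lp_prop)) {
      prop_model <- if (is.null(model)) NULL else
        tryCatch(update_params(model, pr$value), error = function(e) NULL)
      if (is.null(prop_model) && !is.null(model)) {
        ll_prop <- -Inf
      } else {
        set.seed(s_smc[it])
        ll_prop <- loglik(pr$value, prop_model)
      }
      set.seed(s_acc[it])
      log_alpha <- (ll_prop + lp_prop) - (ll_cur + lp_cur) + pr$log_hr
      if (is.finite(ll_prop) && log(stats::runif(1)) < log_alpha) {
        cur <- pr$value
        ll_cur <- ll_prop
        lp_cur <- lp_prop
        acc[it] <- TRUE
      }
    }
    draws[it, ] <- cur
    ll_trace[it] <- ll_cur
    if (verbose && it %% 500 == 0)
      message("iter ", it, "  loglik ", format(ll_cur, digits = 6),
              "  acc ", format(mean(acc[seq_len(it)]), digits = 3))
  }
  structure(list(draws = draws, loglik = ll_trace, accepted = acc,
                 init = init, acceptance_rate = mean(acc),
                 n_particles = n_particles, likelihood = likelihood,
                 seed = seed, burn_in = 0L, thin = 1L),
            class = "pmmh_fit")
}

#' Discard burn-in and thin a chain
#'
#' @param fit a `"pmmh_fit"`.
#' @param burn_in iterations to discard from the front (default 1000).
#' @param stride keep every `stride`-th remaining draw (default 10).
#' @return the thinned `"pmmh_fit"`.
#' @export
thin_chain <- function(fit, burn_in = 1000, stride = 10) {
  n <- nrow(fit$draws)
  if (burn_in + stride > n) stop("burn_in + stride exceeds the chain length")
  keep <- seq(burn_in + stride, n, by = stride)
  fit$draws <- fit$draws[keep, , drop = FALSE]
  fit$loglik <- fit$loglik[keep]
  fit$accepted <- fit$accepted[keep]
  fit$burn_in <- fit$burn_in + as.integer(burn_in)
  fit$thin <- fit$thin * as.integer(stride)
  fit
}

#' @export
print.pmmh_fit <- function(x, ...) {
  cat("pseudo-marginal MH chain: ", nrow(x$draws), " draws x ",
      ncol(x$draws), " parameters (", x$likelihood, " likelihood, L = ",
      x$n_particles, ")\n", sep = "")
  cat("acceptance rate: ", format(x$acceptance_rate, digits = 3), "\n",
      sep = "")
  if (x$burn_in > 0 || x$thin > 1)
    cat("burn-in ", x$burn_in, ", thinning ", x$thin, "\n", sep = "")
  cat("posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' @export
coef.pmmh_fit <- function(object, ...) colMeans(object$draws)

#' @export
as.data.frame.pmmh_fit <- function(x, ...) {
  data.frame(iteration = seq_len(nrow(x$draws)), x$draws,
             loglik = x$loglik, accepted = x$accepted)
}

#' Posterior summary of a fitted chain
#'
#' @param object a `"pmmh_fit"`.
#' @param level credible-interval level (default 0.9).
#' @param ... unused.
#' @return data.frame (one row per parameter) with mean, variance, median and
#'   equal-tailed credible bounds; printed with the acceptance rate.
#' @export
summary.pmmh_fit <- function(object, level = 0.9, ...) {
  tab <- do.call(rbind, lapply(colnames(object$draws), function(nm)
    posterior_summary(object, nm, level = level)))
  structure(list(table = tab, acceptance_rate = object$acceptance_rate,
                 n = nrow(object$draws), level = level),
            class = "summary.pmmh_fit")
}

#' @export
print.summary.pmmh_fit <- function(x, ...) {
  cat("posterior summaries (", x$n, " draws, ",
      round(100 * x$level), "% equal-tailed intervals):\n", sep = "")
  print(x$table, digits = 4)
  cat("acceptance rate: ", format(x$acceptance_rate, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Trace and posterior-density plots of a chain
#'
#' @param x a `"pmmh_fit"`.
#' @param params parameters to plot (default: all).
#' @param truth optional named vector of generating values to mark.
#' @param ... passed to the underlying plot calls.
#' @export
plot.pmmh_fit <- function(x, params = colnames(x$draws), truth = NULL, ...) {
  np <- length(params)
  op <- graphics::par(mfrow = c(np, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in params) {
    v <- x$draws[, nm]
    graphics::plot(v, type = "l", xlab = "iteration", ylab = nm, ...)
    graphics::plot(stats::density(v), main = "", xlab = nm, ...)
    graphics::abline(v = mean(v), lty = 2)
    if (!is.null(truth) && nm %in% names(truth))
      graphics::abline(v = truth[[nm]], col = 2)
  }
  invisible(x)
}
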