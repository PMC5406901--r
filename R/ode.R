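# Closed-form propagation of the linear reporter maturation system
#
#   dD/dt = alpha - (delta + m) D        (immature, dark pool)
#   dF/dt = m D - delta F                (mature, fluorescent pool)
#
# With constant production alpha over an interval the system is affine and
# the flow is available in closed form.  Writing k = delta + m, the impulse
# responses are
#   Phi_DD(t) = exp(-k t)
#   Phi_FD(t) = exp(-delta t) - exp(-k t)     (F response to initial D)
#   Phi_FF(t) = exp(-delta t)
# and the integrated input kernels (response to unit constant alpha)
#   H_D(t) = (1 - exp(-k t)) / k
#   H_F(t) = (1 - exp(-delta t)) / delta - H_D(t).
# The delta -> 0 and k -> 0 limits are handled with expm1 so no special-case
# branching is needed down to exactly-zero rates.

# (1 - exp(-r t)) / r, stable for r >= 0 including r = 0
#' @keywords internal
#' @noRd
.h1 <- function(r, t) {
  if (r <= 0) return(t)
  -expm1(-r * t) / r
}

#' @keywords internal
#' @noRd
ode_kernels <- function(delta, m, t) {
  k <- delta + m
  list(phiDD = exp(-k * t),
       phiFD = exp(-delta * t) - exp(-k * t),
       phiFF = exp(-delta * t),
       HD = .h1(k, t),
       HF = .h1(delta, t) - .h1(k, t))
}

#' Propagate the reporter concentrations over an interval
#'
#' Advances the dark (immature) and fluorescent (mature) reporter pools by
#' `dt` minutes under constant production rate `alpha`, dilution rate `delta`
#' and maturation rate `m`, using the exact solution of the linear ODE pair.
#' Callers with a time-varying production rate split the interval at the
#' switch points.  All arguments are vectorized.
#'
#' @param D0,F0 initial concentrations (>= 0).
#' @param alpha production rate of the dark species (concentration/min).
#' @param delta dilution rate (1/min).
#' @param m maturation rate (1/min).
#' @param dt interval length (min, >= 0).
#' @return a list with components `D` and `F`, the concentrations after `dt`.
#' @examples
#' # steady state: D -> alpha/(delta+m), F -> m*alpha/(delta*(delta+m))
#' propagate_reporter(0, 0, alpha = 10, delta = 0.02, m = 0.05, dt = 1e6)
#' @export
propagate_reporter <- function(D0, F0, alpha, delta, m, dt) {
  if (any(D0 < 0) || any(F0 < 0) || any(alpha < 0) || any(delta < 0) ||
      any(m < 0) || any(dt < 0))
    stop("propagate_reporter: all arguments must be nonnegative")
  n <- max(length(D0), length(F0), length(alpha), length(dt))
  if (length(dt) == 1L) {
    kn <- ode_kernels(delta, m, dt)
  } else {
    k <- delta + m
    kn <- list(phiDD = exp(-k * dt), phiFD = exp(-delta * dt) - exp(-k * dt),
               phiFF = exp(-delta * dt),
               HD = if (k > 0) -expm1(-k * dt) / k else dt,
               HF = (if (delta > 0) -expm1(-delta * dt) / delta else dt) -
                    (if (k > 0) -expm1(-k * dt) / k else dt))
  }
  list(D = kn$phiDD * D0 + alpha * kn$HD,
       F = kn$phiFD * D0 + kn$phiFF * F0 + alpha * kn$HF)
}
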