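#' Model parameters
#'
#' Single source of truth for every constant of the coupled agent--matrix
#' model.  Defaults are the homeostatic reference parameterisation used
#' throughout: a spring of unit cross-sectional area (\code{A0 = 1}) sitting
#' at its target strain (\code{eps_s = 1}), a fibrotic threshold area an
#' order of magnitude above homeostasis (\code{At = 10}), a steep stiffness
#' Hill function (\code{beta = 3}) against a shallow strain Hill function
#' (\code{gamma = 1}), and an agent memory of one half (\code{r = 0.5}).
#'
#' Two quantities are derived and cached on construction:
#' \describe{
#'   \item{\code{c}}{the homeostatic offset that makes total activation zero
#'     at \code{(eps = eps_s, A = A0)}; see
#'     \code{\link{steady_state_constant}}.  Approximately 0.5 whenever
#'     \code{A0 << At}.}
#'   \item{\code{a_fib}}{the maximal fibrotic activation \code{w2 - c},
#'     attained in the limit of an infinitely stiff spring carrying no
#'     strain.  The proliferation and apoptosis ramps are scaled by it;
#'     for \code{w2 <= c} it is non-positive and fibrotic proliferation is
#'     impossible (the model can then only heal).}
#' }
#'
#' @param w1 strain-signal weight (dimensionless, >= 0).
#' @param w2 stiffness-signal weight (dimensionless, >= 0); the propensity
#'   for fibrosis.  1--3 is the physiological range explored.
#' @param A0 initial spring cross-sectional area (> 0).
#' @param At fibrotic threshold area (> A0).
#' @param eps0 initial (prestress) spring strain.
#' @param eps_s target homeostatic strain (> 0).
#' @param gamma steepness of the strain Hill function (> 0).
#' @param beta steepness of the stiffness Hill function (> 0).
#' @param r agent activation memory in [0, 1]; 1 is memoryless.
#' @param P matrix production/digestion scaling constant (> 0).
#' @param p1 per-node probability of a new agent appearing per iteration.
#' @param p3_max division-probability scale in [0, 1].
#' @param D0 initial agent density (agents per spring).
#' @param Dmax maximum agent density (carrying capacity).
#' @param E Young's modulus (uniform; stiffness varies only through A).
#' @param n_iterations default number of iterations for simulations.
#' @param seed default RNG seed for stochastic components.
#' @param ns_ratio node-to-spring count ratio used by the lumped
#'   single-element model in the density influx term (2/3 is the generic
#'   planar Voronoi value: degree-3 vertices).
#'
#' @return An object of class \code{model_params}: a named list with all
#'   arguments plus the derived fields \code{c}, \code{a_fib}.
#' @examples
#' p <- model_params(w2 = 2)
#' p$c          # homeostatic offset, ~0.5
#' p$a_fib      # maximal fibrotic activation
#' @export
model_params <- function(w1 = 1, w2 = 1, A0 = 1, At = 10,
                         eps0 = 1, eps_s = 1, gamma = 1, beta = 3,
                         r = 0.5, P = 0.2, p1 = 0.01, p3_max = 0.02,
                         D0 = 0.3, Dmax = 3, E = 1,
                         n_iterations = 2000L, seed = 1L,
                         ns_ratio = 2 / 3) {
  stopifnot(w1 >= 0, w2 >= 0, A0 > 0, At > A0, eps_s > 0, gamma > 0,
            beta > 0, r >= 0, r <= 1, P > 0,
            p1 >= 0, p1 <= 1, p3_max >= 0, p3_max <= 1,
            D0 >= 0, Dmax > 0, D0 <= Dmax, E > 0,
            n_iterations >= 1, ns_ratio > 0)
  if (eps0 <= -1) stop("eps0 must exceed -1 (springs cannot invert)")
  p <- list(w1 = w1, w2 = w2, A0 = A0, At = At, eps0 = eps0,
            eps_s = eps_s, gamma = gamma, beta = beta, r = r, P = P,
            p1 = p1, p3_max = p3_max, D0 = D0, Dmax = Dmax, E = E,
            n_iterations = as.integer(n_iterations),
            seed = as.integer(seed), ns_ratio = ns_ratio)
  class(p) <- "model_params"
  p$c <- steady_state_constant(p)
  p$a_fib <- p$w2 - p$c
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (fibrosis spring-network model)\n")
  cat(sprintf("  signal weights   w1 = %g (strain), w2 = %g (stiffness)\n",
              x$w1, x$w2))
  cat(sprintf("  areas            A0 = %g, At = %g (fibrotic threshold)\n",
              x$A0, x$At))
  cat(sprintf("  strain           eps0 = %g, eps_s = %g\n", x$eps0, x$eps_s))
  cat(sprintf("  Hill steepness   gamma = %g (strain), beta = %g (stiffness)\n",
              x$gamma, x$beta))
  cat(sprintf("  agent memory r = %g, production P = %g\n", x$r, x$P))
  cat(sprintf("  population       p1 = %g, p3_max = %g, D0 = %g, Dmax = %g\n",
              x$p1, x$p3_max, x$D0, x$Dmax))
  cat(sprintf("  derived          c = %.6f, a_fib = %.6f\n", x$c, x$a_fib))
  invisible(x)
}

#' Rebuild parameters with some fields changed
#'
#' Returns a new \code{model_params} with the given fields replaced and the
#' derived constants (\code{c}, \code{a_fib}) recomputed.
#'
#' @param params a \code{model_params} object.
#' @param ... fields to override, by name.
#' @return a new \code{model_params}.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  upd <- list(...)
  keep <- setdiff(names(formals(model_params)), names(upd))
  do.call(model_params, c(params[keep], upd))
}

## --- activation-dependent population rates -------------------------------
## Division ramps linearly from 0 (a <= 0) to p3_max at the fully fibrotic
## activation a_fib; apoptosis declines over the same ramp so that both the
## homeostatic state (a = 0, D = D0) and the fully fibrotic state
## (a = a_fib, D = Dmax) are exact fixed points of the density map.

#' Per-agent division probability
#'
#' Linear ramp in activation: zero for non-positive activation, reaching
#' \code{p3_max} at the maximal fibrotic activation \code{a_fib}.  When
#' \code{a_fib <= 0} (stiffness weight at or below its critical value) the
#' ramp degenerates and division is impossible; this is the instability
#' boundary of the model.
#'
#' @param a activation value(s).
#' @param params a \code{model_params}.
#' @return probability vector, same length as \code{a}.
#' @export
division_prob <- function(a, params) {
  if (params$a_fib <= 0) return(rep(0, length(a)))
  params$p3_max * pmin(pmax(a, 0), params$a_fib) / params$a_fib
}

#' Per-agent death probability
#'
#' Baseline apoptosis \code{p2_0} for unactivated agents, declining linearly
#' with activation so that highly activated (myofibroblast-like) agents
#' resist apoptosis: at \code{a = a_fib} the rate is
#' \code{p2_0 * D0 / Dmax}, which balances the constant influx exactly at
#' the carrying capacity.
#'
#' @param a activation value(s).
#' @param params a \code{model_params}.
#' @param p2_0 baseline death probability, normally
#'   \code{p1 * (n/s) / D0} from the homeostatic balance of the density map.
#' @return probability vector, same length as \code{a}.
#' @export
death_prob <- function(a, params, p2_0) {
  frac <- if (params$a_fib <= 0) 0 else
    pmin(pmax(a, 0), params$a_fib) / params$a_fib
  p2_0 * (1 - (1 - params$D0 / params$Dmax) * frac)
}
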