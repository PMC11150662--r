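## Lumped single-element difference-equation system: Hill activations,
## constant-force strain, activation memory, matrix and density updates,
## fixed points, thresholds and phase classification.

#' Stiffness contribution to agent activation
#'
#' Hill function of spring cross-sectional area,
#' \eqn{a_K = (A/A_t)^\beta / ((A/A_t)^\beta + 1)}.  Because stiffness
#' \eqn{K = EA/L_0} varies only through \eqn{A} (uniform \eqn{E} and a
#' cell-scale perceived \eqn{L_0}), the area stands in for stiffness.
#' Self-limited: strictly increasing in \code{A}, bounded in [0, 1).
#'
#' @param A cross-sectional area(s), >= 0.
#' @param params a \code{\link{model_params}}.
#' @return activation contribution(s) in [0, 1).
#' @examples
#' p <- model_params()
#' stiffness_activation(p$At, p)   # half saturation: 0.5
#' @export
stiffness_activation <- function(A, params) {
  if (any(A < 0)) stop("cross-sectional area must be non-negative")
  x <- (A / params$At)^params$beta
  ifelse(is.infinite(x), 1, x / (x + 1))
}

#' Strain contribution to agent activation
#'
#' Hill function of spring strain,
#' \eqn{a_\varepsilon = (\varepsilon/\varepsilon_s)^\gamma /
#' ((\varepsilon/\varepsilon_s)^\gamma + 1)}, representing stretch-mediated
#' signalling (latent TGF-beta release, stretch-gated channels).  Half
#' maximal at the target strain \code{eps_s}.
#'
#' @param eps strain value(s), >= 0.
#' @param params a \code{\link{model_params}}.
#' @return activation contribution(s) in [0, 1).
#' @export
strain_activation <- function(eps, params) {
  if (any(eps < 0)) stop("strain must be non-negative")
  x <- (eps / params$eps_s)^params$gamma
  ifelse(is.infinite(x), 1, x / (x + 1))
}

#' Homeostatic offset constant
#'
#' The constant \eqn{c = w_1/2 + w_2 (A_0/A_t)^\beta/((A_0/A_t)^\beta + 1)}
#' that zeroes total activation at homeostasis
#' (\eqn{\varepsilon = \varepsilon_s}, \eqn{A = A_0}).  With the default
#' parameters the second term is tiny (\eqn{A_0 \ll A_t}) and
#' \eqn{c \approx 0.5}.
#'
#' @param params a \code{\link{model_params}} (or plain list holding
#'   \code{w1, w2, A0, At, beta}).
#' @return the scalar constant c.
#' @export
steady_state_constant <- function(params) {
  ## written so the homeostatic cancellation in total_activation() is exact
  ## in floating point: same products, same Hill evaluation.
  params$w1 * 0.5 + params$w2 * stiffness_activation(params$A0, params)
}

#' Total activation from the two mechanical signals
#'
#' Weighted sum \eqn{a = w_1 a_\varepsilon + w_2 a_K - c}; zero at
#' homeostasis by construction of \code{c}, negative when the strain signal
#' is weak (driving digestion), positive when the stiffness signal
#' dominates (driving deposition).
#'
#' @param a_eps strain activation contribution(s) in [0, 1).
#' @param a_K stiffness activation contribution(s) in [0, 1).
#' @param params a \code{\link{model_params}}.
#' @return signed activation(s) in (-c, w1 + w2 - c].
#' @export
total_activation <- function(a_eps, a_K, params) {
  params$w1 * a_eps + params$w2 * a_K - params$c
}

#' Activation memory update
#'
#' First-order low-pass of the instantaneous signal:
#' \eqn{a \leftarrow a(1-r) + r (w_1 a_\varepsilon + w_2 a_K - c)}.
#' \code{r = 1} is memoryless, \code{r = 0} freezes the activation.
#'
#' @param a current activation(s).
#' @param a_eps strain activation contribution(s).
#' @param a_K stiffness activation contribution(s).
#' @param params a \code{\link{model_params}}.
#' @return updated activation(s).
#' @export
update_activation <- function(a, a_eps, a_K, params) {
  a * (1 - params$r) + params$r * total_activation(a_eps, a_K, params)
}

#' Matrix deposition/digestion update
#'
#' \eqn{A \leftarrow A + P D a}.  The result may be non-positive, which
#' signals rupture to the caller; it is deliberately not clamped here.
#'
#' @param A cross-sectional area(s), >= 0.
#' @param D agent density, >= 0.
#' @param a activation(s).
#' @param params a \code{\link{model_params}}.
#' @return updated area(s).
#' @export
update_area <- function(A, D, a, params) {
  if (any(A < 0)) stop("cross-sectional area must be non-negative")
  if (any(D < 0)) stop("agent density must be non-negative")
  A + params$P * D * a
}

#' Strain of a single element under constant external force
#'
#' For a Hookean spring held by a constant force, strain is inversely
#' proportional to cross-sectional area: \eqn{\varepsilon = \varepsilon_s
#' A_0 / A}.  The product \eqn{\varepsilon A} is invariant, equal to
#' \eqn{\varepsilon_s A_0}; strain drops toward zero as the element
#' stiffens without bound.
#'
#' @param A cross-sectional area(s), > 0.
#' @param params a \code{\link{model_params}}.
#' @return strain value(s).
#' @export
constant_force_strain <- function(A, params) {
  if (any(A <= 0))
    stop("element ruptured: cross-sectional area is non-positive",
         call. = FALSE)
  params$eps_s * params$A0 / A
}

#' Agent density update (mean-field)
#'
#' \eqn{D \leftarrow D + p_1 n/s + p_3(a) D (1 - D/D_{max}) - p_2(a) D},
#' clamped to \eqn{[0, D_{max}]}.  Influx is constant (migration from
#' outside the tissue), division carries a logistic carrying-capacity
#' factor, and apoptosis declines with activation
#' (see \code{\link{death_prob}}).  At \code{a = 0} the map converges
#' exponentially to \code{D0}; at \code{a = a_fib} it converges to
#' \code{Dmax}.
#'
#' @param D agent density (agents per spring).
#' @param a activation driving proliferation/death.
#' @param n_nodes number of nodes in the network.
#' @param n_springs number of springs in the network.
#' @param params a \code{\link{model_params}}.
#' @return updated density, in [0, Dmax].
#' @export
update_density <- function(D, a, n_nodes, n_springs, params) {
  if (any(D < 0)) stop("agent density must be non-negative")
  update_density_ratio(D, a, n_nodes / n_springs, params)
}

## influx written as p2_0 * D0 (identical real number to p1 * n/s by the
## homeostatic balance) so the fixed point at D = D0 is exact in floating
## point.
update_density_ratio <- function(D, a, ns_ratio, params) {
  p2_0 <- params$p1 * ns_ratio / params$D0
  dD <- p2_0 * params$D0 +
    division_prob(a, params) * D * (1 - D / params$Dmax) -
    death_prob(a, params, p2_0) * D
  pmin(pmax(D + dD, 0), params$Dmax)
}

## --- the coupled map engine ----------------------------------------------
## Vectorised over elements: used scalar (with recording) by
## simulate_element() and in bulk (no recording) by threshold scans and
## phase diagrams.  Order per iteration: strain -> Hill activations ->
## activation memory -> area -> density.
element_map_run <- function(params, A_init, eps_init = NULL,
                            n_iterations = params$n_iterations,
                            record = FALSE) {
  n <- length(A_init)
  A <- as.numeric(A_init)
  if (any(A <= 0)) stop("initial area must be positive")
  a <- rep(0, n)
  D <- rep(params$D0, n)
  eps <- if (is.null(eps_init)) constant_force_strain(A, params)
         else as.numeric(eps_init)
  frozen <- rep(FALSE, n)      # overflowed or ruptured elements
  overflow <- rep(FALSE, n)
  ruptured <- rep(FALSE, n)
  A_cap <- 1e9 * params$At
  A_init <- A
  maxA <- A
  inc_last <- rep(TRUE, n)     # A strictly increasing over last 10%?
  dec_last <- rep(TRUE, n)     # A strictly decreasing over last 10%?
  last10 <- floor(0.9 * n_iterations)
  traj <- NULL
  if (record) {
    traj <- matrix(NA_real_, n_iterations + 1L, 4L,
                   dimnames = list(NULL, c("A", "eps", "a", "D")))
    traj[1L, ] <- c(A, eps, a, D)
  }
  for (j in seq_len(n_iterations)) {
    live <- !frozen
    if (!any(live)) {
      if (record) traj[j + 1L, ] <- traj[j, ]
      next
    }
    e <- eps
    if (!(j == 1L && !is.null(eps_init)))
      e[live] <- params$eps_s * params$A0 / A[live]
    a_eps <- strain_activation(pmax(e, 0), params)
    a_K <- stiffness_activation(A, params)
    a_new <- update_activation(a, a_eps, a_K, params)
    A_new <- update_area(A, D, a_new, params)
    bad_hi <- live & (!is.finite(A_new) | A_new > A_cap)
    bad_lo <- live & !bad_hi & (A_new <= 0)
    upd <- live & !bad_hi & !bad_lo
    if (j > last10) {
      inc_last[upd] <- inc_last[upd] & (A_new[upd] > A[upd])
      dec_last[upd] <- dec_last[upd] & (A_new[upd] < A[upd])
    }
    if (any(bad_hi)) inc_last[bad_hi] <- TRUE
    a[upd] <- a_new[upd]; A[upd] <- A_new[upd]
    D[upd] <- update_density_ratio(D[upd], a_new[upd], params$ns_ratio,
                                   params)
    ## recorded state carries the instantaneous constant-force strain of
    ## the updated area (eps * A = eps_s * A0 exactly along a trajectory)
    eps[upd] <- params$eps_s * params$A0 / A[upd]
    overflow <- overflow | bad_hi
    ruptured <- ruptured | bad_lo
    frozen <- frozen | bad_hi | bad_lo
    maxA <- pmax(maxA, A)
    if (record) {
      traj[j + 1L, ] <- c(A, eps, a, D)
      if (frozen[1L]) { traj <- traj[seq_len(j + 1L), , drop = FALSE]; break }
    }
  }
  list(A = A, eps = eps, a = a, D = D, A_init = A_init, maxA = maxA,
       inc_last = inc_last, dec_last = dec_last,
       overflow = overflow, ruptured = ruptured, traj = traj)
}

## Outcome rules.  Healing: either settled within tolerance of homeostasis,
## or still strictly descending toward it from above with negative
## activation (the element is then inside the healing basin: digestion is
## monotone down to A0, where activation changes sign).  Fibrotic: area
## overflowed, grew past the divergence cap, or is strictly increasing
## above homeostasis with positive activation.  The cap test compares
## against the post-injury starting area so a large insult that is being
## digested is not mistaken for runaway growth.
classify_summary <- function(A, a, D, A_init, maxA, inc_last, dec_last,
                             overflow, ruptured, params,
                             tol_A = 0.01 * params$A0, tol_a = 1e-3) {
  out <- rep("undecided", length(A))
  out[!is.finite(D)] <- "unstable"
  out[ruptured] <- "unstable"
  out[overflow] <- "fibrotic"
  und <- out == "undecided"
  healed <- und & ((abs(A - params$A0) < tol_A & abs(a) < tol_a) |
                     (A > params$A0 & dec_last & a < 0))
  out[healed] <- "healing"
  fib <- out == "undecided" &
    ((maxA > 10 * params$At & maxA > A_init) |
       (inc_last & a > 0 & A > params$A0))
  out[fib] <- "fibrotic"
  out
}

#' Simulate the lumped single-element model
#'
#' Iterates the coupled map (constant-force strain, Hill activations,
#' activation memory, matrix update, density update) from homeostasis after
#' a single multiplicative insult to the cross-sectional area at iteration
#' 0.  Deterministic; no random numbers are consumed.
#'
#' @param params a \code{\link{model_params}}.
#' @param injury_multiplier multiplicative insult applied to \code{A0} at
#'   iteration 0 (> 0; < 1 softening, > 1 stiffening).
#' @param n_iterations number of iterations (default from \code{params}).
#' @return an \code{element_trajectory}: a data.frame with columns
#'   \code{iteration, A, eps, a, D} and attributes \code{outcome}
#'   (\code{"healing"}, \code{"fibrotic"}, \code{"unstable"} or
#'   \code{"undecided"}) and \code{params}.  The trajectory is truncated if
#'   the area overflows (outcome \code{"fibrotic"}).
#' @examples
#' p <- model_params(w2 = 2)
#' tr <- simulate_element(p, injury_multiplier = 8)
#' attr(tr, "outcome")
#' @export
simulate_element <- function(params, injury_multiplier = 1,
                             n_iterations = params$n_iterations) {
  stopifnot(injury_multiplier > 0)
  res <- element_map_run(params, params$A0 * injury_multiplier,
                         n_iterations = n_iterations, record = TRUE)
  traj <- data.frame(iteration = seq_len(nrow(res$traj)) - 1L, res$traj)
  outcome <- classify_summary(res$A, res$a, res$D, res$A_init, res$maxA,
                              res$inc_last, res$dec_last,
                              res$overflow, res$ruptured, params)
  structure(traj, outcome = outcome, params = params,
            truncated = nrow(res$traj) < n_iterations + 1L,
            class = c("element_trajectory", "data.frame"))
}

#' Classify the outcome of an element trajectory
#'
#' Labels a trajectory \code{"healing"} when the final state has returned to
#' homeostasis (\code{|A - A0| < tol_A} and \code{|a| < tol_a}),
#' \code{"fibrotic"} when the area ever exceeded \code{10 At}, overflowed,
#' or is strictly increasing with positive activation over the last 10\% of
#' iterations, \code{"unstable"} when the element ruptured or the density
#' lost finiteness, and \code{"undecided"} otherwise.
#'
#' @param traj an \code{element_trajectory} from
#'   \code{\link{simulate_element}}.
#' @param params a \code{\link{model_params}} (defaults to the trajectory's
#'   own).
#' @param tol_A absolute area tolerance for healing.
#' @param tol_a absolute activation tolerance for healing.
#' @return one of \code{"healing"}, \code{"fibrotic"}, \code{"unstable"},
#'   \code{"undecided"}.
#' @export
classify_outcome <- function(traj, params = attr(traj, "params"),
                             tol_A = 0.01 * params$A0, tol_a = 1e-3) {
  if (is.null(traj) || nrow(traj) == 0L)
    stop("empty trajectory cannot be classified")
  n <- nrow(traj)
  fin <- traj[n, ]
  last10 <- traj$A[traj$iteration > floor(0.9 * max(traj$iteration))]
  inc <- length(last10) < 2L || all(diff(last10) > 0)
  dec <- length(last10) >= 2L && all(diff(last10) < 0)
  overflow <- isTRUE(attr(traj, "truncated")) && fin$A > 0
  ruptured <- isTRUE(attr(traj, "truncated")) && fin$A <= 0
  classify_summary(fin$A, fin$a, fin$D, traj$A[1L], max(traj$A), inc, dec,
                   overflow, ruptured, params, tol_A, tol_a)
}

## Vectorised outcome of the element model over a set of multipliers.
element_outcomes <- function(params, multipliers,
                             n_iterations = params$n_iterations) {
  res <- element_map_run(params, params$A0 * multipliers,
                         n_iterations = n_iterations)
  classify_summary(res$A, res$a, res$D, res$A_init, res$maxA,
                   res$inc_last, res$dec_last,
                   res$overflow, res$ruptured, params)
}

#' Critical injury multiplier for fibrosis
#'
#' Finds the threshold stiffening insult above which the single-element
#' model fails to heal, by a geometric coarse scan (ratio 1.1) followed by
#' bisection.  Returns \code{Inf} when no insult in the bracket produces a
#' fibrotic outcome (always the case for \code{w2 <= 0.5 w1}: the fibrotic
#' positive feedback is then always weaker than the strain-driven healing).
#' The threshold strictly decreases as the stiffness weight \code{w2}
#' grows.
#'
#' @param params a \code{\link{model_params}}.
#' @param tol bisection tolerance on the multiplier.
#' @param mult_max upper end of the scanned multiplier range.
#' @param n_iterations iterations per trial simulation.
#' @return the critical multiplier, or \code{Inf} if the model always
#'   heals.
#' @export
find_fibrotic_threshold <- function(params, tol = 1e-3,
                                    mult_max = 100 * params$At / params$A0,
                                    n_iterations = params$n_iterations) {
  if (params$w2 <= 0.5 * params$w1) return(Inf)
  grid <- exp(seq(0, log(mult_max), by = log(1.1)))
  out <- element_outcomes(params, grid, n_iterations)
  fib <- out == "fibrotic"
  if (!any(fib)) return(Inf)
  i <- which(fib)[1L]
  if (any(out[seq(i, length(out))] == "healing"))
    stop("non-monotone outcome classification across the injury scan; ",
         "first fibrotic multiplier ", signif(grid[i], 6),
         ", later healing multiplier ",
         signif(grid[seq(i, length(grid))][
       which(out[seq(i, length(out))] == "healing")[1L]], 6))
  if (i == 1L) return(grid[1L])
  lo <- grid[i - 1L]; hi <- grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (element_outcomes(params, mid, n_iterations) == "fibrotic")
      hi <- mid else lo <- mid
  }
  hi
}

#' Critical stiffness weight admitting fibrosis
#'
#' Bisects the stiffness weight \code{w2} on the predicate "some stiffening
#' insult produces a fibrotic outcome" (finite
#' \code{\link{find_fibrotic_threshold}}), returning the infimum weight at
#' which a fibrotic response first becomes possible.  Analytically this is
#' the weight where the fully fibrotic activation \code{w2 - c} changes
#' sign, i.e. just above \code{0.5 w1}.
#'
#' @param params a \code{\link{model_params}}; \code{w1} is held fixed.
#' @param tol bisection tolerance on the weight.
#' @param n_iterations iterations per trial simulation.
#' @return the critical stiffness weight.
#' @export
find_critical_weight <- function(params, tol = 1e-3,
                                 n_iterations = params$n_iterations) {
  admits <- function(w2) {
    is.finite(find_fibrotic_threshold(update_params(params, w2 = w2),
                                      n_iterations = n_iterations))
  }
  lo <- 0.4 * params$w1
  hi <- max(params$w1, 0.8 * params$w1)
  if (admits(lo)) stop("fibrosis already possible at w2 = 0.4 w1")
  while (!admits(hi)) hi <- hi * 1.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (admits(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Phase diagram of the single-element model
#'
#' Classifies a grid of initial states \code{(eps, A)} by running the
#' element map from each: the given strain is used for the first iteration,
#' after which strain is slaved to the constant-force relation.  Grid cells
#' whose 4-neighbourhood contains both healing and fibrotic outcomes are
#' relabelled \code{"mixed"} (the boundary band).  The homeostatic steady
#' state sits at \code{(eps_s, A0)}, i.e. (1, 1) at defaults.
#'
#' @param params a \code{\link{model_params}}.
#' @param eps_grid vector of initial strains (> 0).
#' @param A_grid vector of initial areas (> 0).
#' @param n_iterations iterations per grid point.
#' @return a \code{phase_diagram} object: list with \code{eps}, \code{A}
#'   and a character matrix \code{label} (\code{length(eps)} rows by
#'   \code{length(A)} columns).
#' @export
phase_diagram <- function(params, eps_grid, A_grid,
                          n_iterations = params$n_iterations) {
  stopifnot(all(eps_grid > 0), all(A_grid > 0))
  g <- expand.grid(eps = eps_grid, A = A_grid)
  out <- element_map_run(params, g$A, eps_init = g$eps,
                         n_iterations = n_iterations)
  lab <- classify_summary(out$A, out$a, out$D, out$A_init, out$maxA,
                          out$inc_last, out$dec_last,
                          out$overflow, out$ruptured, params)
  lab <- matrix(lab, length(eps_grid), length(A_grid))
  base <- lab
  ne <- length(eps_grid); na <- length(A_grid)
  for (i in seq_len(ne)) for (j in seq_len(na)) {
    nb <- c(if (i > 1) base[i - 1, j], if (i < ne) base[i + 1, j],
            if (j > 1) base[i, j - 1], if (j < na) base[i, j + 1],
            base[i, j])
    if (any(nb == "healing") && any(nb == "fibrotic"))
      lab[i, j] <- "mixed"
  }
  structure(list(eps = eps_grid, A = A_grid, label = lab, params = params),
            class = "phase_diagram")
}
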