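## Elastic equilibrium under fixed boundary forces, per-spring strain
## extraction, rupture pruning, and the strain-energy stiffness assay.

#' Hookean spring constant
#'
#' \eqn{K = E A / L_0}: stiffness proportional to cross-sectional area at
#' uniform modulus, as for a strip of tissue probed over a fixed
#' (cell-scale) length.
#'
#' @param E Young's modulus (> 0).
#' @param A cross-sectional area (> 0).
#' @param L0 rest length (> 0).
#' @return spring constant(s).
#' @export
spring_constant <- function(E, A, L0) {
  if (any(E <= 0) || any(A <= 0) || any(L0 <= 0))
    stop("E, A and L0 must all be positive")
  E * A / L0
}

net_arrays <- function(net, coords = NULL) {
  nd <- net$nodes; sp <- net$springs
  list(coords = if (is.null(coords)) cbind(nd$x, nd$y) else coords,
       edges = cbind(match(sp$node_i, nd$id), match(sp$node_j, nd$id)) - 1L,
       L0 = sp$L0,
       k = spring_constant(sp$E, sp$A, sp$L0),
       fext = cbind(nd$fx, nd$fy))
}

#' Total elastic energy of a configuration
#'
#' Sum of spring strain energies \eqn{\frac12 K (L - L_0)^2}, minus the
#' work of the constant boundary forces when
#' \code{include_external = TRUE} (the potential that
#' \code{\link{equilibrate}} minimizes).
#'
#' @param net a \code{spring_network}.
#' @param coords optional n-by-2 coordinate matrix overriding the stored
#'   positions.
#' @param include_external subtract the boundary-force work term.
#' @return scalar energy.
#' @export
network_energy <- function(net, coords = NULL, include_external = TRUE) {
  a <- net_arrays(net, coords)
  net_energy_cpp(a$coords, a$edges, a$L0, a$k, a$fext, include_external)
}

#' Relax the network to elastic equilibrium
#'
#' Minimizes total elastic energy minus the work of the constant boundary
#' forces until the net force on every free node falls below \code{tol}.
#' Two engines are available: \code{"relax"}, a deterministic inertial
#' descent (FIRE) used everywhere by default, and \code{"anneal"}, a
#' greedy random-displacement schedule with progressively decreasing step
#' sizes, retained as a fidelity check (both must land on the same
#' equilibrium).  \code{"anneal"} consumes random numbers from the R
#' stream.
#'
#' @param net a \code{spring_network} with boundary forces set.
#' @param mode \code{"relax"} (default) or \code{"anneal"}.
#' @param tol convergence tolerance on the maximum residual node force, in
#'   force units of \code{E A0} (so 1e-6 of the homeostatic tension scale).
#' @param max_iter iteration (or sweep) cap; exceeding it returns
#'   \code{converged = FALSE} rather than failing.
#' @param pinned logical vector over nodes: pinned nodes do not move
#'   (default: none; boundary nodes are held by their forces, not pinned).
#' @param coords optional starting coordinates (warm start).
#' @return an \code{equilibrium_result}: list with \code{coords} (n by 2),
#'   \code{residual}, \code{iterations}, \code{converged}.
#' @export
equilibrate <- function(net, mode = c("relax", "anneal"), tol = 1e-6,
                        max_iter = 50000L, pinned = NULL, coords = NULL) {
  mode <- match.arg(mode)
  a <- net_arrays(net, coords)
  free <- if (is.null(pinned)) rep(TRUE, nrow(a$coords)) else !pinned
  res <- if (mode == "relax") {
    ## Newton-Krylov first (a few steps from a warm start), inertial
    ## descent (FIRE) as the robust fallback
    r1 <- relax_newton_cpp(a$coords, a$edges, a$L0, a$k, a$fext, free, tol,
                           50L, 400L)
    if (r1$converged) r1
    else relax_fire_cpp(r1$coords, a$edges, a$L0, a$k, a$fext, free, tol,
                        as.integer(max_iter))
  } else {
    relax_anneal_cpp(a$coords, a$edges, a$L0, a$k, a$fext, free,
                     step0 = 0.25 * mean(a$L0), shrink = 0.7, tol = tol,
                     max_sweeps = as.integer(max_iter))
  }
  structure(res, class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium: %s after %d iterations (residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

set_coords <- function(net, coords) {
  net$nodes$x <- coords[, 1]
  net$nodes$y <- coords[, 2]
  net
}

#' Per-spring strains
#'
#' \eqn{\varepsilon = (L - L_0)/L_0} for every spring at the given (or
#' stored) coordinates.  Negative values indicate compression; springs
#' carry force by the same Hookean law in both directions.
#'
#' @param net a \code{spring_network}.
#' @param coords optional coordinate matrix.
#' @return numeric vector of strains, one per spring.
#' @export
spring_strains <- function(net, coords = NULL) {
  L <- current_lengths(net, coords)
  (L - net$springs$L0) / net$springs$L0
}

#' Remove ruptured and stranded material
#'
#' Removes springs whose area has been digested to zero or below
#' (rupture), then isolated springs (springs both of whose endpoints
#' connect to nothing else), then nodes left without any spring.  Agents
#' sitting on removed nodes are stranded and removed from the population.
#' When removal takes away loaded boundary nodes the remaining boundary
#' forces are re-centred to zero sum, so an equilibrium continues to
#' exist.  Idempotent.
#'
#' @param net a \code{spring_network} (possibly with A <= 0 springs).
#' @param pop optional \code{agent_population} to strand against.
#' @return list with elements \code{net}, \code{removed_springs},
#'   \code{removed_nodes}, \code{stranded_agents} (ids), and \code{pop}
#'   (the surviving population, if one was given).
#' @export
prune_ruptured <- function(net, pop = NULL) {
  sp <- net$springs; nd <- net$nodes
  dead <- sp$A <= 0
  sp2 <- sp[!dead, , drop = FALSE]
  deg <- tabulate(match(c(sp2$node_i, sp2$node_j), nd$id), nbins = nrow(nd))
  iso <- deg[match(sp2$node_i, nd$id)] == 1L &
    deg[match(sp2$node_j, nd$id)] == 1L
  removed_springs <- c(sp$id[dead], sp2$id[iso])
  sp2 <- sp2[!iso, , drop = FALSE]
  live_nodes <- unique(c(sp2$node_i, sp2$node_j))
  removed_nodes <- setdiff(nd$id, live_nodes)
  nd2 <- nd[nd$id %in% live_nodes, , drop = FALSE]
  ## keep the frozen boundary forces summing to zero
  if (any(nd2$is_boundary) &&
      length(removed_nodes) > 0L &&
      (abs(sum(nd2$fx)) > 0 || abs(sum(nd2$fy)) > 0)) {
    nb <- sum(nd2$is_boundary)
    nd2$fx[nd2$is_boundary] <- nd2$fx[nd2$is_boundary] - sum(nd2$fx) / nb
    nd2$fy[nd2$is_boundary] <- nd2$fy[nd2$is_boundary] - sum(nd2$fy) / nb
  }
  stranded <- integer(0)
  if (!is.null(pop) && nrow(pop) > 0L) {
    gone <- !(pop$node %in% nd2$id)
    stranded <- pop$id[gone]
    pop <- pop[!gone, , drop = FALSE]
  }
  net$nodes <- nd2
  net$springs <- sp2
  list(net = net, removed_springs = removed_springs,
       removed_nodes = removed_nodes, stranded_agents = stranded,
       pop = pop)
}

#' Strain-energy stiffness assay
#'
#' Measures whole-network stiffness the way a tissue strip would be
#' tested: the boundary is stretched isotropically about its centroid in
#' five accumulating steps of 2\% strain; after each step the interior is
#' re-equilibrated with the boundary held at its stretched positions and
#' the spring strain energies are summed.  A second-order polynomial is
#' fit to energy versus cumulative strain (including the unstretched
#' point) and its quadratic coefficient is the stiffness.  Run-level
#' metrics divide this by the value at iteration 0 ("normalized
#' stiffness").  The assay works on a copy; the run state is untouched.
#'
#' @param net an equilibrated \code{spring_network}.
#' @param n_steps number of accumulating stretches.
#' @param step_strain strain increment per stretch.
#' @param tol equilibrium tolerance for the interior relaxations.
#' @param max_iter relaxation iteration cap.
#' @return list with \code{stiffness} (the quadratic coefficient),
#'   \code{residual} (relative root-mean-square residual of the fit),
#'   \code{strain} and \code{energy} vectors.
#' @export
stiffness_assay <- function(net, n_steps = 5L, step_strain = 0.02,
                            tol = 1e-9, max_iter = 100000L) {
  a <- net_arrays(net)
  b <- net$nodes$is_boundary
  if (!any(b)) stop("network has no boundary nodes to stretch")
  ctr <- colMeans(a$coords[b, , drop = FALSE])
  strain <- c(0, step_strain * seq_len(n_steps))
  energy <- numeric(length(strain))
  energy[1] <- net_energy_cpp(a$coords, a$edges, a$L0, a$k, a$fext, FALSE)
  coords <- a$coords
  zero_f <- matrix(0, nrow(coords), 2)   # boundary is pinned, not pulled
  for (s in seq_len(n_steps)) {
    coords[b, 1] <- ctr[1] + (1 + strain[s + 1]) * (a$coords[b, 1] - ctr[1])
    coords[b, 2] <- ctr[2] + (1 + strain[s + 1]) * (a$coords[b, 2] - ctr[2])
    res <- relax_fire_cpp(coords, a$edges, a$L0, a$k, zero_f, !b, tol,
                          as.integer(max_iter))
    coords <- res$coords
    energy[s + 1] <- net_energy_cpp(coords, a$edges, a$L0, a$k, zero_f,
                                    FALSE)
  }
  fit <- lm(energy ~ strain + I(strain^2))
  list(stiffness = unname(coef(fit)[3]),
       residual = sqrt(mean(fit$residuals^2)) / max(abs(energy)),
       strain = strain, energy = energy)
}
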