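## Discrete agents on the network: random migration, mechanosensing with
## memory, matrix deposition/digestion, spontaneous appearance, death and
## division.  All randomness flows through R's RNG in a fixed draw order
## (migration picks, then births, then deaths, then divisions), and agents
## are processed in id order, so a single set.seed() makes a whole run
## bit-reproducible.

#' Initialise the agent population
#'
#' Places \code{round(D0 * n_springs)} unactivated agents on uniformly
#' random nodes of the network.
#'
#' @param net a \code{spring_network}.
#' @param D0 target initial density (agents per spring).
#' @return an \code{agent_population}: data.frame with columns \code{id},
#'   \code{node}, \code{a}, sorted by id, carrying a \code{next_id}
#'   attribute.
#' @export
init_agents <- function(net, D0 = 0.3) {
  n <- round(D0 * nrow(net$springs))
  pop <- data.frame(id = seq_len(n),
                    node = if (n > 0)
                      net$nodes$id[sample.int(nrow(net$nodes), n,
                                              replace = TRUE)]
                    else integer(0),
                    a = numeric(n))
  structure(pop, next_id = n + 1L,
            class = c("agent_population", "data.frame"))
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("Agent population: %d agents, mean activation %.4f\n",
              nrow(x), if (nrow(x)) mean(x$a) else NA_real_))
  invisible(x)
}

## flat incidence structure: for node index v, incident spring rows are
## flat[(offset[v]+1):(offset[v]+deg[v])]
node_incidence <- function(net) {
  n <- nrow(net$nodes)
  ends <- match(c(net$springs$node_i, net$springs$node_j), net$nodes$id)
  sid <- rep(seq_len(nrow(net$springs)), 2L)
  ord <- order(ends)
  deg <- tabulate(ends, nbins = n)
  list(flat = sid[ord], offset = cumsum(c(0L, deg))[seq_len(n)], deg = deg)
}

#' One migration/mechanosensing/deposition step
#'
#' Every agent picks one spring incident to its node uniformly at random,
#' traverses it to the opposite node, reads that spring's stiffness (via
#' its area) and strain, updates its activation with memory, and deposits
#' or digests matrix on the crossed spring: \code{A <- A + P a}.  Agent
#' density enters the network model through the number of crossings, so
#' the per-crossing increment carries no explicit density factor.
#' Compressive (negative) strains contribute zero strain activation.
#' Agents on isolated nodes are removed.
#'
#' @param pop an \code{agent_population}.
#' @param net a \code{spring_network}.
#' @param strains per-spring strain vector from the current equilibrium
#'   (see \code{\link{spring_strains}}).
#' @param params a \code{\link{model_params}}.
#' @return list with updated \code{pop}, \code{net} (areas modified;
#'   possibly now containing A <= 0 springs awaiting pruning), and
#'   \code{visits}, a data.frame of (node, a) pairs for the activation
#'   accumulation map.
#' @export
step_migration <- function(pop, net, strains, params) {
  if (nrow(pop) == 0L)
    return(list(pop = pop, net = net,
                visits = data.frame(node = integer(0), a = numeric(0))))
  inc <- node_incidence(net)
  nidx <- match(pop$node, net$nodes$id)
  deg <- inc$deg[nidx]
  keep <- deg > 0L
  pop <- pop[keep, , drop = FALSE]
  if (nrow(pop) == 0L)
    return(list(pop = pop, net = net,
                visits = data.frame(node = integer(0), a = numeric(0))))
  nidx <- nidx[keep]; deg <- deg[keep]
  u <- runif(nrow(pop))
  pick <- inc$offset[nidx] + pmax(1L, ceiling(u * deg))
  sid <- inc$flat[pick]
  sp <- net$springs
  across <- ifelse(sp$node_i[sid] == pop$node, sp$node_j[sid],
                   sp$node_i[sid])
  a_K <- stiffness_activation(sp$A[sid], params)
  a_eps <- strain_activation(pmax(strains[sid], 0), params)
  pop$a <- update_activation(pop$a, a_eps, a_K, params)
  pop$node <- across
  dA <- rowsum(params$P * pop$a, sid)
  rows <- as.integer(rownames(dA))
  net$springs$A[rows] <- net$springs$A[rows] + dA[, 1]
  list(pop = pop, net = net,
       visits = data.frame(node = across, a = pop$a))
}

#' One birth/death/division step
#'
#' Each node spawns a fresh unactivated agent with probability \code{p1}
#' (migration into the tissue); each agent dies with the
#' activation-dependent probability \code{\link{death_prob}}; each
#' survivor divides with probability
#' \code{\link{division_prob}(a) * (1 - D/Dmax)} (logistic crowding),
#' placing an unactivated daughter on its own node.  Death is evaluated
#' before division.  The expected density change matches the mean-field
#' density map \code{\link{update_density}}.
#'
#' @param pop an \code{agent_population}.
#' @param net a \code{spring_network}.
#' @param params a \code{\link{model_params}}.
#' @param p2_0 baseline death probability (frozen at run start from the
#'   initial node/spring ratio: \code{p1 (n/s) / D0}).
#' @return the updated population, with an \code{events} attribute
#'   (births, deaths, divisions counts).
#' @export
step_birth_death_division <- function(pop, net, params, p2_0) {
  n_springs <- nrow(net$springs)
  D <- nrow(pop) / n_springs
  next_id <- attr(pop, "next_id")
  born <- net$nodes$id[runif(nrow(net$nodes)) < params$p1]
  dies <- runif(nrow(pop)) < death_prob(pop$a, params, p2_0)
  surv <- pop[!dies, , drop = FALSE]
  crowd <- max(0, 1 - D / params$Dmax)
  divides <- runif(nrow(surv)) < division_prob(surv$a, params) * crowd
  new_nodes <- c(born, surv$node[divides])
  if (length(new_nodes) > 0L) {
    kids <- data.frame(id = seq(next_id, length.out = length(new_nodes)),
                       node = new_nodes, a = 0)
    next_id <- next_id + length(new_nodes)
    surv <- rbind(surv, kids)
  }
  structure(surv, next_id = next_id,
            events = c(births = length(born), deaths = sum(dies),
                       divisions = sum(divides)),
            class = c("agent_population", "data.frame"))
}

#' Histogram of agent activations
#'
#' Bins the current activation levels; agents near zero are
#' fibroblast-like, agents near the maximal fibrotic activation
#' myofibroblast-like, with the transition visible as a second mode as
#' disease progresses.
#'
#' @param pop an \code{agent_population}.
#' @param breaks bin breaks covering the attainable activation range
#'   \code{(-c, w1 + w2 - c]}; either a count or a vector of break
#'   points (as for \code{\link[graphics]{hist}}).
#' @param params a \code{\link{model_params}} used for the default range.
#' @return list with \code{breaks}, \code{counts}, \code{mids}.
#' @export
activation_histogram <- function(pop, breaks = 40L,
                                 params = model_params()) {
  if (length(breaks) == 1L)
    breaks <- seq(-params$c, params$w1 + params$w2 - params$c,
                  length.out = breaks + 1L)
  h <- graphics::hist(pmin(pmax(pop$a, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Accumulated local activation map
#'
#' Per-node running sum of the activation of every agent that visited it,
#' a proxy for locally accumulated alpha-smooth-muscle actin.  Built from
#' the visit log a simulation keeps (see \code{\link{run_simulation}}).
#'
#' @param visits data.frame with columns \code{node}, \code{a}
#'   (concatenated visit logs), or a \code{fibrosis_run} object.
#' @param node_ids nodes to report (default: all visited).
#' @return named numeric vector of accumulated activation per node id.
#' @export
local_activation_map <- function(visits, node_ids = NULL) {
  if (inherits(visits, "fibrosis_run")) visits <- visits$visits
  acc <- if (nrow(visits) == 0L) numeric(0)
  else {
    s <- rowsum(visits$a, visits$node)
    setNames(s[, 1], rownames(s))
  }
  if (is.null(node_ids)) return(acc)
  out <- setNames(numeric(length(node_ids)), node_ids)
  out[names(acc)[names(acc) %in% names(out)]] <-
    acc[names(acc) %in% names(out)]
  out
}
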