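## Injury protocols, the full network-simulation driver, replicate
## orchestration and run-level metrics (normalized stiffness, percent
## ruptured springs, agent density, activation histograms, network area).

#' Injury specification
#'
#' A single insult: a fraction of springs has its cross-sectional area
#' multiplied by a common factor (softening < 1, stiffening > 1).
#'
#' @param fraction fraction of springs to perturb, in [0, 1].
#' @param multiplier multiplicative area factor (> 0).
#' @param seed RNG seed for spring selection, or \code{NULL} to draw from
#'   the current stream.
#' @param clustered select a spatially contiguous patch (grown over the
#'   spring adjacency) instead of uniformly random springs.  Off by
#'   default; the baseline protocol scatters the injury.
#' @return an \code{injury_spec}.
#' @export
injury_spec <- function(fraction, multiplier, seed = NULL,
                        clustered = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (multiplier <= 0) stop("injury multiplier must be positive")
  structure(list(fraction = fraction, multiplier = multiplier,
                 seed = seed, clustered = clustered),
            class = "injury_spec")
}

#' Apply an injury to a network
#'
#' Multiplies the area of the selected springs and re-equilibrates.
#'
#' @param net a \code{spring_network}.
#' @param spec an \code{\link{injury_spec}}.
#' @param tol re-equilibration tolerance.
#' @return the injured, re-equilibrated network, with the chosen spring
#'   ids in attribute \code{injured_springs}.
#' @export
apply_injury <- function(net, spec, tol = 1e-6) {
  m <- nrow(net$springs)
  count <- round(spec$fraction * m)
  if (spec$fraction > 0 && count < 1L)
    stop("injury fraction selects no springs on this network")
  if (count == 0L) return(structure(net, injured_springs = integer(0)))
  chosen <- with_seed(spec$seed, {
    if (!spec$clustered) {
      sample.int(m, count)
    } else {
      ## grow a patch over spring adjacency (springs sharing a node)
      start <- sample.int(m, 1L)
      sel <- start
      frontier <- start
      while (length(sel) < count && length(frontier) > 0L) {
        nodes <- unique(c(net$springs$node_i[frontier],
                          net$springs$node_j[frontier]))
        nb <- which(net$springs$node_i %in% nodes |
                      net$springs$node_j %in% nodes)
        frontier <- setdiff(nb, sel)
        sel <- unique(c(sel, frontier))
      }
      sel[seq_len(min(count, length(sel)))]
    }
  })
  net$springs$A[chosen] <- net$springs$A[chosen] * spec$multiplier
  res <- equilibrate(net, tol = tol)
  net <- set_coords(net, res$coords)
  structure(net, injured_springs = net$springs$id[chosen])
}

hull_area <- function(net) {
  x <- net$nodes$x; y <- net$nodes$y
  if (length(x) < 3L) return(0)
  h <- chull(x, y)
  x <- x[h]; y <- y[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Run the full agent/network simulation
#'
#' The complete loop: agents migrate over the current equilibrium strains
#' and remodel the springs they cross; ruptured material is pruned; the
#' population turns over (birth, death, division); the network is
#' re-equilibrated from a warm start.  The stiffness assay runs every
#' \code{assay_stride} iterations.  Iteration 0 is the pre-injury state
#' (so normalized stiffness starts at exactly 1); the injury, if any, is
#' applied between iterations 0 and 1.  A single \code{set.seed(seed)}
#' governs network generation, agent placement, injury selection and all
#' population events, so equal seeds give bit-identical runs.
#'
#' @param params a \code{\link{model_params}}.
#' @param injury an \code{\link{injury_spec}} or \code{NULL}.
#' @param domain a \code{\link{domain_spec}} used when \code{net} is not
#'   supplied; its \code{seed} field is ignored in favour of \code{seed}.
#' @param net optional pre-built network (skips generation).
#' @param n_iterations iterations to run.
#' @param assay_stride iterations between stiffness assays (the costly
#'   metric; curves are step functions between assays).
#' @param seed integer seed for the whole run, or \code{NULL} to use the
#'   current RNG state.
#' @param tol equilibrium tolerance during the run.
#' @param snapshot_at iterations at which to store network + population
#'   snapshots (0 is pre-injury, 1 is just after injury).
#' @param keep_visits retain the per-iteration visit log for
#'   \code{\link{local_activation_map}}.
#' @return a \code{fibrosis_run}: list with \code{metrics} (per-iteration
#'   data.frame), \code{assays}, \code{outcome}, \code{snapshots},
#'   \code{visits}, \code{final_net}, \code{final_pop}, \code{histograms},
#'   \code{params}, \code{injury}, \code{seed}.
#' @export
run_simulation <- function(params, injury = NULL, domain = domain_spec(),
                           net = NULL, n_iterations = 500L,
                           assay_stride = 50L, seed = 1L, tol = 1e-6,
                           snapshot_at = c(0L, 1L,
                                           floor(n_iterations / 2L),
                                           n_iterations),
                           keep_visits = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) {
    domain$seed <- NULL
    net <- generate_network(domain, params)
  }
  n_init <- nrow(net$springs)
  ns_ratio0 <- nrow(net$nodes) / n_init
  p2_0 <- params$p1 * ns_ratio0 / params$D0
  base <- stiffness_assay(net)
  pop <- init_agents(net, params$D0)
  snaps <- list()
  take_snap <- function(label, j) {
    snaps[[label]] <<- list(iteration = j, net = net, pop = pop)
  }
  if (0L %in% snapshot_at) take_snap("iter0", 0L)
  metrics <- data.frame(iteration = 0L, n_springs = n_init,
                        n_agents = nrow(pop),
                        density = nrow(pop) / n_init,
                        pct_ruptured = 0, mean_abs_a = 0,
                        area = hull_area(net), stiffness = 1)
  injured_ids <- integer(0)
  if (!is.null(injury)) {
    net <- apply_injury(net, injury, tol = tol)
    injured_ids <- attr(net, "injured_springs")
  }
  if (1L %in% snapshot_at) take_snap("injury", 1L)
  visits <- vector("list", if (keep_visits) n_iterations else 0L)
  hists <- list()
  norm_st <- 1
  rows <- vector("list", n_iterations)
  disintegrated <- FALSE
  for (j in seq_len(n_iterations)) {
    strains <- spring_strains(net)
    mig <- step_migration(pop, net, strains, params)
    if (keep_visits) visits[[j]] <- mig$visits
    pr <- prune_ruptured(mig$net, mig$pop)
    net <- pr$net
    if (nrow(net$springs) == 0L) { disintegrated <- TRUE; break }
    pop <- step_birth_death_division(pr$pop, net, params, p2_0)
    res <- equilibrate(net, tol = tol)
    net <- set_coords(net, res$coords)
    if (j %% assay_stride == 0L || j == n_iterations) {
      norm_st <- stiffness_assay(net)$stiffness / base$stiffness
      hists[[as.character(j)]] <- activation_histogram(pop, params = params)
    }
    rows[[j]] <- data.frame(
      iteration = j, n_springs = nrow(net$springs), n_agents = nrow(pop),
      density = nrow(pop) / nrow(net$springs),
      pct_ruptured = 100 * (n_init - nrow(net$springs)) / n_init,
      mean_abs_a = if (nrow(pop)) mean(abs(pop$a)) else 0,
      area = hull_area(net), stiffness = norm_st)
    if (j %in% snapshot_at && j > 1L)
      take_snap(paste0("iter", j), j)
  }
  metrics <- rbind(metrics, do.call(rbind, rows[!vapply(rows, is.null,
                                                        logical(1))]))
  assays <- metrics[metrics$iteration %in%
                      unique(c(0L, seq(assay_stride, n_iterations,
                                       by = assay_stride), n_iterations)),
                    c("iteration", "stiffness")]
  outcome <- if (disintegrated) "unstable"
  else classify_run_outcome(assays$stiffness)
  structure(list(metrics = metrics, assays = assays, outcome = outcome,
                 snapshots = snaps,
                 visits = if (keep_visits)
                   do.call(rbind, visits[!vapply(visits, is.null,
                                                 logical(1))])
                 else NULL,
                 histograms = hists, final_net = net, final_pop = pop,
                 injured_springs = injured_ids, params = params,
                 injury = injury, seed = seed),
            class = "fibrosis_run")
}

#' @export
print.fibrosis_run <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("Fibrosis run: %d iterations, outcome \"%s\"\n",
                     "  final normalized stiffness %.3f, %.1f%% springs ",
                     "ruptured, density %.2f\n"),
              m$iteration, x$outcome, m$stiffness, m$pct_ruptured,
              m$density))
  invisible(x)
}

## Network-level outcome from the normalized-stiffness assay series,
## mirroring how stiffness trajectories are read in replicate plots:
## healing when stiffness has returned to within 20% of baseline and is
## not still climbing; fibrotic when stiffness has doubled or is strictly
## climbing away from the healing band at the end.  Agent activation is
## reported as its own metric (histograms, mean |a|) rather than folded
## into the outcome: a healed network can retain a small activated focus.
classify_run_outcome <- function(norm_stiffness, heal_band = c(0.8, 1.2),
                                 fibrotic_factor = 2) {
  n <- length(norm_stiffness)
  fin <- norm_stiffness[n]
  tail_n <- max(2L, ceiling(0.1 * n)) + 1L
  tail_v <- norm_stiffness[seq(max(1L, n - tail_n + 1L), n)]
  ## a trend needs both monotonicity and a material rise (>2%), so that
  ## assay jitter around a stationary value is not read as progression
  climbing <- length(tail_v) >= 2L && all(diff(tail_v) > 0) &&
    tail_v[length(tail_v)] / tail_v[1] > 1.02
  if (fin > fibrotic_factor || (climbing && fin > heal_band[2]))
    return("fibrotic")
  if (fin >= heal_band[1] && fin <= heal_band[2] && !climbing)
    return("healing")
  "undecided"
}

#' Replicate study of one injury condition
#'
#' Runs independent replicates (fresh network, agents and event stream
#' per replicate; seeds derived from \code{seed}) and collects the final
#' distribution of normalized stiffness, percent ruptured springs and
#' agent density --- the raw material of box-plot comparisons across
#' stiffness weights.
#'
#' @param params a \code{\link{model_params}}.
#' @param injury an \code{\link{injury_spec}} or \code{NULL}.
#' @param n_replicates number of replicates (>= 1; 9 mirrors the study
#'   design of at least nine networks per condition).
#' @param seed master seed from which replicate seeds are derived.
#' @param ... passed to \code{\link{run_simulation}}.
#' @return a \code{replicate_study}: list with \code{runs} (the
#'   individual \code{fibrosis_run}s) and \code{summary} (one row per
#'   replicate).
#' @export
replicate_study <- function(params, injury = NULL, n_replicates = 9L,
                            seed = 1L, ...) {
  stopifnot(n_replicates >= 1L)
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max, n_replicates))
  runs <- lapply(seq_len(n_replicates), function(i) {
    run_simulation(params, injury, seed = seeds[i], ...)
  })
  summary <- do.call(rbind, lapply(seq_along(runs), function(i) {
    m <- runs[[i]]$metrics[nrow(runs[[i]]$metrics), ]
    data.frame(replicate = i, seed = seeds[i],
               final_stiffness = m$stiffness,
               pct_ruptured = m$pct_ruptured, density = m$density,
               outcome = runs[[i]]$outcome)
  }))
  structure(list(runs = runs, summary = summary, params = params,
                 injury = injury, seed = seed),
            class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, ...) {
  cat(sprintf("Replicate study: %d runs (w2 = %g)\n", nrow(x$summary),
              x$params$w2))
  print(table(x$summary$outcome))
  invisible(x)
}

#' Sensitivity-ablation experiment
#'
#' Reruns the standard experiment with one mechanosensitive pathway
#' removed: \code{"no_strain"} sets the strain weight \code{w1} to zero
#' (stiffness-only agents; the system loses its healing response) and
#' \code{"no_stiffness"} sets \code{w2} to zero (strain-only agents; the
#' fibrotic positive feedback disappears).  The homeostatic offset
#' \code{c} is recomputed for the ablated weights.
#'
#' @param params a \code{\link{model_params}} (the unablated baseline).
#' @param mode \code{"no_strain"} or \code{"no_stiffness"}.
#' @param injury an \code{\link{injury_spec}} or \code{NULL}.
#' @param ... passed to \code{\link{run_simulation}}.
#' @return a \code{fibrosis_run}.
#' @export
ablation <- function(params, mode = c("no_strain", "no_stiffness"),
                     injury = NULL, ...) {
  mode <- match.arg(mode)
  ab <- if (mode == "no_strain") update_params(params, w1 = 0)
  else update_params(params, w2 = 0)
  run_simulation(ab, injury, ...)
}
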