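## Configuration files, CSV metric tables, figure-style rendering
## (synthetic histology, phase diagrams) and the command-line interface.
## Config keys mirror the model's own symbol names (w1, w2, A0, At, ...)
## so a parameter table reads directly as documentation.  All quantitative
## outputs are CSV; images are a convenience and never parsed by tests.

#' Read a run configuration
#'
#' Flat key--value YAML with up to four sections: \code{params} (model
#' constants, by symbol name), \code{domain} (side, radius, seed),
#' \code{injury} (fraction, multiplier, seed, clustered) and \code{run}
#' (n_iterations, assay_stride, seed, replicates, out_dir).  Missing
#' sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return a \code{run_config}: list with \code{params}
#'   (\code{\link{model_params}}), \code{domain}
#'   (\code{\link{domain_spec}}), \code{injury}
#'   (\code{\link{injury_spec}} or NULL) and \code{run} (plain list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- list(
    params = do.call(model_params, raw$params %||% list()),
    domain = do.call(domain_spec, raw$domain %||% list()),
    injury = if (!is.null(raw$injury))
      do.call(injury_spec, raw$injury) else NULL,
    run = utils::modifyList(list(n_iterations = 500L, assay_stride = 50L,
                                 seed = 1L, replicates = 1L,
                                 out_dir = "."),
                            raw$run %||% list()))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration
#'
#' Inverse of \code{\link{read_run_config}}; numeric values keep full
#' precision so the round trip is lossless.
#'
#' @param cfg a \code{run_config}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  p <- cfg$params
  out <- list(
    params = p[setdiff(names(formals(model_params)), character(0))],
    domain = cfg$domain[c("side", "radius", "seed")],
    injury = if (!is.null(cfg$injury))
      cfg$injury[c("fraction", "multiplier", "seed", "clustered")],
    run = cfg$run)
  drop_null <- function(x) if (is.list(x)) lapply(Filter(Negate(is.null), x),
                                                  drop_null) else x
  writeLines(yaml::as.yaml(drop_null(out), precision = 17L), path)
  invisible(path)
}

#' Write an element trajectory as CSV
#'
#' Columns \code{iteration, A, eps, a, D, outcome}.
#'
#' @param traj an \code{element_trajectory}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$outcome <- attr(traj, "outcome")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write run metrics as tidy CSV
#'
#' Long format: \code{iteration, replicate, metric, value}, suitable for
#' downstream statistics.
#'
#' @param runs a \code{fibrosis_run}, or a \code{replicate_study}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(runs, path) {
  one <- function(run, rep) {
    m <- run$metrics
    cols <- setdiff(names(m), "iteration")
    do.call(rbind, lapply(cols, function(cl)
      data.frame(iteration = m$iteration, replicate = rep, metric = cl,
                 value = m[[cl]])))
  }
  df <- if (inherits(runs, "replicate_study"))
    do.call(rbind, lapply(seq_along(runs$runs),
                          function(i) one(runs$runs[[i]], i)))
  else one(runs, 1L)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a synthetic histology image
#'
#' Draws the network with line widths proportional to spring
#' cross-sectional area, the way stained collagen reads in a section:
#' thickened strands around fibrotic foci, voids where springs have
#' ruptured.
#'
#' @param net a \code{spring_network}.
#' @param path output PNG path.
#' @param width_per_A line width per unit area (proportionality constant).
#' @param max_lwd clamp on line width.
#' @param px image size in pixels.
#' @return \code{path}, invisibly.
#' @export
render_histology <- function(net, path, width_per_A = 1.5, max_lwd = 20,
                             px = 800L) {
  png(path, width = px, height = px)
  on.exit(dev.off())
  op <- par(mar = c(0, 0, 0, 0))
  on.exit(par(op), add = TRUE)
  if (nrow(net$springs) == 0L) {
    warning("rendering an empty network")
    plot.new()
    return(invisible(path))
  }
  nd <- net$nodes
  i <- match(net$springs$node_i, nd$id)
  j <- match(net$springs$node_j, nd$id)
  plot(NA, xlim = range(nd$x), ylim = range(nd$y), asp = 1, axes = FALSE,
       xlab = "", ylab = "")
  segments(nd$x[i], nd$y[i], nd$x[j], nd$y[j],
           lwd = pmin(width_per_A * net$springs$A, max_lwd),
           col = "#7a1f3d", lend = 1)
  invisible(path)
}

#' Render a phase diagram
#'
#' Healing, fibrotic and mixed regions of the single-element model in
#' strain--area coordinates, optionally overlaid with the per-spring
#' states of a network and the constant-force trajectory of the lumped
#' element.
#'
#' @param phase a \code{\link{phase_diagram}} object.
#' @param path output PNG path.
#' @param spring_states optional data.frame/matrix with columns
#'   \code{eps}, \code{A}: per-spring states to overlay.
#' @param trajectory optional \code{element_trajectory} to overlay.
#' @param px image size in pixels.
#' @return \code{path}, invisibly.
#' @export
render_phase_diagram <- function(phase, path, spring_states = NULL,
                                 trajectory = NULL, px = 800L) {
  stopifnot(inherits(phase, "phase_diagram"))
  cols <- c(healing = "#9be09b", fibrotic = "#f2a6c8",
            mixed = "#f5e663", undecided = "#d9d9d9",
            unstable = "#bdbdbd")
  labs <- sort(unique(as.vector(phase$label)))
  z <- matrix(match(phase$label, labs), nrow(phase$label))
  png(path, width = px, height = px)
  on.exit(dev.off())
  image(phase$eps, phase$A, z, col = cols[labs], xlab = "strain",
        ylab = "cross-sectional area")
  if (!is.null(spring_states))
    points(spring_states[, "eps"], spring_states[, "A"], pch = 8,
           col = "red", cex = 0.6)
  if (!is.null(trajectory))
    lines(trajectory$eps, trajectory$A, lwd = 2)
  points(phase$params$eps_s, phase$params$A0, pch = 19)
  legend("topright", legend = labs, fill = cols[labs], bg = "white")
  invisible(path)
}

#' Command-line interface
#'
#' Thin argument-parsing layer over the package functions, used by the
#' \code{exec/fibronet} script.  Subcommands: \code{element} (lumped
#' single-element trajectory and thresholds), \code{phase} (phase
#' diagram), \code{generate} (network snapshot), \code{simulate} (full
#' run or replicate study, with optional ablation), \code{assay}
#' (stiffness of a snapshot), \code{render} (histology image of a
#' snapshot).  Outputs are CSVs, network snapshots and PNGs next to a
#' \code{manifest.yaml} recording the exact parameters and seeds.
#'
#' @param args character vector of command-line arguments, e.g.
#'   \code{c("element", "--w2", "2", "--injury-multiplier", "8")}.
#' @return integer exit code (0 on success), invisibly.
#' @export
fibronet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fibronet <element|phase|generate|simulate|assay|render>",
    "[--config FILE] [--seed N] [--w2 X] [--injury-fraction X]",
    "[--injury-multiplier X] [--iterations N] [--replicates N]",
    "[--ablate no_strain|no_stiffness] [--network FILE] [--out DIR]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  rc <- tryCatch({
    opt <- parse_cli_flags(args[-1L])
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
    else list(params = model_params(), domain = domain_spec(),
              injury = NULL,
              run = list(n_iterations = 500L, assay_stride = 50L,
                         seed = 1L, replicates = 1L, out_dir = "."))
    if (!is.null(opt$w2)) cfg$params <- update_params(cfg$params,
                                                      w2 = opt$w2)
    if (!is.null(opt$seed)) cfg$run$seed <- opt$seed
    if (!is.null(opt$iterations)) cfg$run$n_iterations <- opt$iterations
    if (!is.null(opt$replicates)) cfg$run$replicates <- opt$replicates
    if (!is.null(opt$out)) cfg$run$out_dir <- opt$out
    if (!is.null(opt[["injury-fraction"]]) ||
        !is.null(opt[["injury-multiplier"]]))
      cfg$injury <- injury_spec(opt[["injury-fraction"]] %||% 0.1,
                                opt[["injury-multiplier"]] %||% 10)
    dir.create(cfg$run$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$run$out_dir, f)
    writeLines(yaml::as.yaml(list(command = cmd, args = args,
                                  seed = cfg$run$seed,
                                  w1 = cfg$params$w1, w2 = cfg$params$w2)),
               out("manifest.yaml"))
    switch(cmd,
      element = {
        mult <- if (!is.null(cfg$injury)) cfg$injury$multiplier else 1
        tr <- simulate_element(cfg$params, mult,
                               n_iterations = cfg$run$n_iterations)
        write_trajectory(tr, out("element_trajectory.csv"))
        thr <- find_fibrotic_threshold(cfg$params)
        message(sprintf("outcome: %s; fibrotic threshold multiplier: %s",
                        attr(tr, "outcome"), format(thr)))
      },
      phase = {
        ph <- phase_diagram(cfg$params,
                            eps_grid = exp(seq(log(0.05), log(5),
                                               length.out = 25)),
                            A_grid = exp(seq(log(0.2), log(50),
                                             length.out = 25)),
                            n_iterations = cfg$run$n_iterations)
        render_phase_diagram(ph, out("phase_diagram.png"))
        write.csv(data.frame(eps = rep(ph$eps, length(ph$A)),
                             A = rep(ph$A, each = length(ph$eps)),
                             label = as.vector(ph$label)),
                  out("phase_labels.csv"), row.names = FALSE)
      },
      generate = {
        set.seed(cfg$run$seed)
        cfg$domain$seed <- NULL
        net <- generate_network(cfg$domain, cfg$params)
        write_network(net, out("network.txt"))
      },
      simulate = {
        run_one <- function(p) {
          if (cfg$run$replicates > 1L) {
            st <- replicate_study(p, cfg$injury,
                                  n_replicates = cfg$run$replicates,
                                  seed = cfg$run$seed,
                                  domain = cfg$domain,
                                  n_iterations = cfg$run$n_iterations,
                                  assay_stride = cfg$run$assay_stride)
            write_metrics(st, out("metrics.csv"))
            write.csv(st$summary, out("summary.csv"), row.names = FALSE)
          } else {
            r <- run_simulation(p, cfg$injury, domain = cfg$domain,
                                n_iterations = cfg$run$n_iterations,
                                assay_stride = cfg$run$assay_stride,
                                seed = cfg$run$seed)
            write_metrics(r, out("metrics.csv"))
            write_network(r$final_net, out("final_network.txt"))
            message("outcome: ", r$outcome)
          }
        }
        p <- cfg$params
        if (!is.null(opt$ablate))
          p <- if (opt$ablate == "no_strain") update_params(p, w1 = 0)
          else update_params(p, w2 = 0)
        run_one(p)
      },
      assay = {
        if (is.null(opt$network)) stop("assay needs --network FILE")
        net <- read_network(opt$network)
        as <- stiffness_assay(net)
        message(sprintf("stiffness (quadratic coefficient): %.8g",
                        as$stiffness))
      },
      render = {
        if (is.null(opt$network)) stop("render needs --network FILE")
        net <- read_network(opt$network)
        render_histology(net, out("histology.png"))
      },
      stop("unknown subcommand: ", cmd, "\n", usage))
    0L
  }, error = function(e) {
    message("fibronet error [", cmd, "]: ", conditionMessage(e))
    1L
  })
  invisible(rc)
}

parse_cli_flags <- function(args) {
  flags <- c("config", "seed", "w2", "injury-fraction",
             "injury-multiplier", "iterations", "replicates", "ablate",
             "network", "out")
  numeric_flags <- c("seed", "w2", "injury-fraction", "injury-multiplier",
                     "iterations", "replicates")
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || !(key %in% flags))
      stop("unknown flag: ", args[i])
    if (i == length(args)) stop("flag ", args[i], " needs a value")
    val <- args[i + 1L]
    opt[[key]] <- if (key %in% numeric_flags) as.numeric(val) else val
    i <- i + 2L
  }
  opt
}
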