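## Procedural generation of the spring networks representing lung
## parenchyma: Poisson-disk seeded Voronoi tessellations (non-uniform, the
## production geometry) and honeycomb lattices (deterministic fixture),
## plus prestress and reaction-force boundary conditions.

#' Square simulation domain
#'
#' @param side side length of the square domain (dimensionless length).
#' @param radius Poisson-disk exclusion radius; must be < side/4 so the
#'   domain holds enough interior cells.  The default pair yields a network
#'   of roughly 300--600 springs.
#' @param seed RNG seed for sampling, or \code{NULL} to draw from the
#'   current RNG stream (used by the experiment drivers, which seed once
#'   per run).
#' @return a \code{domain_spec} object.
#' @export
domain_spec <- function(side = 1, radius = 0.07, seed = NULL) {
  stopifnot(side > 0, radius > 0)
  if (radius >= side / 4)
    stop("radius must be below side/4 for a usable tessellation")
  structure(list(side = side, radius = radius, seed = seed),
            class = "domain_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Poisson-disk point sample of the domain (Bridson dart throwing)
#'
#' Produces a maximal blue-noise point set: all pairwise distances are at
#' least \code{radius}, and no disk of radius \code{2 radius} fits inside
#' the domain without containing a point.  Up to 30 candidate darts are
#' thrown per active point.  Deterministic for a fixed seed.
#'
#' @param domain a \code{\link{domain_spec}}.
#' @return a two-column matrix of point coordinates.
#' @export
poisson_disk_sample <- function(domain) {
  stopifnot(inherits(domain, "domain_spec"))
  with_seed(domain$seed, {
    side <- domain$side; r <- domain$radius; k <- 30L
    cell <- r / sqrt(2)
    ng <- ceiling(side / cell)
    grid <- matrix(NA_integer_, ng, ng)   # index of point in each cell
    pts <- matrix(NA_real_, 4096L, 2L)
    npts <- 0L
    gidx <- function(p) pmin(pmax(floor(p / cell) + 1L, 1L), ng)
    ok <- function(p) {
      g <- gidx(p)
      for (gi in max(1L, g[1] - 2L):min(ng, g[1] + 2L))
        for (gj in max(1L, g[2] - 2L):min(ng, g[2] + 2L)) {
          q <- grid[gi, gj]
          if (!is.na(q) && sum((pts[q, ] - p)^2) < r^2) return(FALSE)
        }
      TRUE
    }
    push <- function(p) {
      npts <<- npts + 1L
      if (npts > nrow(pts)) pts <<- rbind(pts, matrix(NA_real_, nrow(pts), 2L))
      pts[npts, ] <<- p
      g <- gidx(p)
      grid[g[1], g[2]] <<- npts
      npts
    }
    active <- push(runif(2) * side)
    while (length(active) > 0L) {
      ai <- sample.int(length(active), 1L)
      centre <- pts[active[ai], ]
      placed <- FALSE
      for (trial in seq_len(k)) {
        rho <- r * sqrt(runif(1, 1, 4))    # uniform over the [r, 2r] annulus
        th <- runif(1, 0, 2 * pi)
        p <- centre + rho * c(cos(th), sin(th))
        if (all(p >= 0) && all(p <= side) && ok(p)) {
          active <- c(active, push(p))
          placed <- TRUE
          break
        }
      }
      if (!placed) active <- active[-ai]
    }
    pts[seq_len(npts), , drop = FALSE]
  })
}

## ---- Delaunay triangulation (Bowyer-Watson) -----------------------------
## O(n^2); adequate for the point counts a desk-scale domain produces.
circumcircle <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c3 <- P[tri[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c3[, 2]) + b[, 1] * (c3[, 2] - a[, 2]) +
              c3[, 1] * (a[, 2] - b[, 2]))
  if (any(abs(d) < 1e-300))
    stop("degenerate (collinear) triangle in triangulation")
  a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c3^2)
  ux <- (a2 * (b[, 2] - c3[, 2]) + b2 * (c3[, 2] - a[, 2]) +
           c2 * (a[, 2] - b[, 2])) / d
  uy <- (a2 * (c3[, 1] - b[, 1]) + b2 * (a[, 1] - c3[, 1]) +
           c2 * (b[, 1] - a[, 1])) / d
  cbind(ux, uy, (ux - a[, 1])^2 + (uy - a[, 2])^2)
}

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3L)
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2]))) + 1
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  P <- rbind(pts,
             c(cx - 30 * span, cy - 20 * span),
             c(cx + 30 * span, cy - 20 * span),
             c(cx, cy + 30 * span))
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1L)
  cc <- circumcircle(P, tri)
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 < cc[, 3]
    if (!any(bad)) stop("point outside all circumcircles; corrupt state")
    badtri <- tri[bad, , drop = FALSE]
    edges <- rbind(badtri[, c(1, 2)], badtri[, c(2, 3)], badtri[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])   # polygon boundary edges
    poly <- edges[keep, , drop = FALSE]
    newtri <- cbind(poly, ip)
    tri <- rbind(tri[!bad, , drop = FALSE], newtri)
    cc <- rbind(cc[!bad, , drop = FALSE], circumcircle(P, newtri))
  }
  real <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  list(points = pts, triangles = tri[real, , drop = FALSE],
       circumcenters = cc[real, 1:2, drop = FALSE])
}

## Liang-Barsky clip of segment p->q to [0, side]^2; NULL if fully outside.
clip_segment <- function(p, q, side) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (ax in 1:2) for (sgn in c(-1, 1)) {
    pr <- if (sgn < 0) -d[ax] else d[ax]
    qr <- if (sgn < 0) p[ax] - 0 else side - p[ax]
    if (pr == 0) { if (qr < 0) return(NULL) }
    else {
      t <- qr / pr
      if (pr < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
      else        { if (t < t0) return(NULL); if (t < t1) t1 <- t }
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

#' Build a Voronoi spring network from a point set
#'
#' The Voronoi diagram of the points is computed (via its dual Delaunay
#' triangulation); Voronoi vertices become network nodes and finite Voronoi
#' edges become springs with uniform cross-sectional area and modulus.
#' Edges crossing the domain boundary are truncated at the boundary and the
#' cut endpoint becomes a boundary node; edges shorter than
#' \code{1e-6 side} are contracted.  Rest lengths are set to the current
#' edge lengths (zero strain) until \code{\link{apply_prestress}} is
#' applied.  Only the largest connected component is kept.
#'
#' @param points two-column coordinate matrix (>= 10 points).
#' @param domain a \code{\link{domain_spec}}.
#' @param A uniform initial cross-sectional area.
#' @param E uniform Young's modulus.
#' @return a \code{spring_network}.
#' @export
build_voronoi_network <- function(points, domain, A = 1, E = 1) {
  stopifnot(nrow(points) >= 10L)
  side <- domain$side
  dt <- delaunay_triangulate(points)
  tri <- dt$triangles; cc <- dt$circumcenters
  ## map each Delaunay edge to the triangles sharing it
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  all_e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  tidx <- rep(seq_len(nrow(tri)), 3L)
  keys <- ekey(all_e[, 1], all_e[, 2])
  byk <- split(tidx, keys)
  epts <- split(seq_len(nrow(all_e)), keys)
  segs <- vector("list", length(byk))
  for (q in seq_along(byk)) {
    ts <- byk[[q]]
    if (length(ts) == 2L) {
      segs[[q]] <- clip_segment(cc[ts[1], ], cc[ts[2], ], side)
    } else {
      ## hull edge: Voronoi ray along the outward normal of the edge
      er <- all_e[epts[[q]][1], ]
      t1 <- tri[ts[1], ]
      third <- setdiff(t1, er)
      pi_ <- dt$points[er[1], ]; pj <- dt$points[er[2], ]
      pk <- dt$points[third, ]
      mid <- (pi_ + pj) / 2
      dvec <- c(-(pj[2] - pi_[2]), pj[1] - pi_[1])
      if (sum(dvec * (mid - pk)) < 0) dvec <- -dvec
      dvec <- dvec / sqrt(sum(dvec^2))
      segs[[q]] <- clip_segment(cc[ts[1], ], cc[ts[1], ] + dvec * 10 * side,
                                side)
    }
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < 3L) stop("tessellation produced too few edges")
  ends <- do.call(rbind, segs)               # 2 rows per segment
  ## merge coincident endpoints
  tol <- 1e-9 * side
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  uid <- match(key, unique(key))
  xy <- ends[!duplicated(uid), , drop = FALSE]
  ei <- matrix(uid, ncol = 2L, byrow = TRUE)
  ## contract short edges by unioning endpoints
  len <- sqrt(rowSums((xy[ei[, 1], , drop = FALSE] -
                         xy[ei[, 2], , drop = FALSE])^2))
  parent <- seq_len(nrow(xy))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in which(len < 1e-6 * side))
    parent[find(ei[s, 1])] <- find(ei[s, 2])
  root <- vapply(seq_len(nrow(xy)), find, integer(1))
  ei <- cbind(root[ei[, 1]], root[ei[, 2]])
  keep_e <- ei[, 1] != ei[, 2]
  ei <- ei[keep_e, , drop = FALSE]
  dup <- duplicated(paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2])))
  ei <- ei[!dup, , drop = FALSE]
  ## largest connected component
  g <- igraph::graph_from_edgelist(ei, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  in_big <- comp$membership[ei[, 1]] == big
  ei <- ei[in_big, , drop = FALSE]
  used <- sort(unique(as.vector(ei)))
  remap <- match(seq_len(max(used)), used)
  nodes_xy <- xy[used, , drop = FALSE]
  ei <- cbind(remap[ei[, 1]], remap[ei[, 2]])
  btol <- 1e-7 * side
  on_bnd <- nodes_xy[, 1] < btol | nodes_xy[, 1] > side - btol |
    nodes_xy[, 2] < btol | nodes_xy[, 2] > side - btol
  nodes <- data.frame(id = seq_len(nrow(nodes_xy)),
                      x = nodes_xy[, 1], y = nodes_xy[, 2],
                      is_boundary = on_bnd, fx = 0, fy = 0)
  L <- sqrt((nodes$x[ei[, 1]] - nodes$x[ei[, 2]])^2 +
              (nodes$y[ei[, 1]] - nodes$y[ei[, 2]])^2)
  springs <- data.frame(id = seq_len(nrow(ei)),
                        node_i = ei[, 1], node_j = ei[, 2],
                        L0 = L, A = A, E = E)
  new_spring_network(nodes, springs, domain)
}

new_spring_network <- function(nodes, springs, domain = NULL) {
  net <- structure(list(nodes = nodes, springs = springs, domain = domain),
                   class = "spring_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  nd <- net$nodes; sp <- net$springs
  stopifnot(!anyDuplicated(nd$id))
  if (!all(sp$node_i %in% nd$id) || !all(sp$node_j %in% nd$id))
    stop("spring endpoint references a missing node")
  if (any(sp$node_i == sp$node_j)) stop("self-loop spring")
  key <- paste(pmin(sp$node_i, sp$node_j), pmax(sp$node_i, sp$node_j))
  if (anyDuplicated(key)) stop("duplicate spring")
  if (any(sp$A <= 0))
    stop("spring with non-positive area present; prune before use")
  invisible(net)
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("Spring network: %d nodes (%d boundary), %d springs\n",
              nrow(x$nodes), sum(x$nodes$is_boundary), nrow(x$springs)))
  invisible(x)
}

#' Honeycomb lattice fixture network
#'
#' A regular hexagonal (honeycomb) network with uniform edge length: the
#' deterministic fixture geometry.  Every vertex has degree at most 3;
#' vertices of degree below 3 form the outer rim and are marked as
#' boundary.
#'
#' @param n_rings number of rings of hexagonal cells (1 = a single
#'   hexagon: 6 nodes, 6 springs).
#' @param edge edge length.
#' @param A uniform cross-sectional area.
#' @param E uniform Young's modulus.
#' @return a \code{spring_network}.
#' @export
hexagonal_network <- function(n_rings, edge = 1, A = 1, E = 1) {
  stopifnot(n_rings >= 1)
  k <- n_rings - 1L
  centres <- NULL
  for (q in -k:k) for (r in -k:k)
    if (abs(q + r) <= k)
      centres <- rbind(centres,
                       c(sqrt(3) * edge * (q + r / 2), 1.5 * edge * r))
  ang <- pi / 6 + (0:5) * pi / 3
  vx <- as.vector(outer(edge * cos(ang), centres[, 1], `+`))
  vy <- as.vector(outer(edge * sin(ang), centres[, 2], `+`))
  tol <- 1e-6 * edge
  key <- paste(round(vx / tol), round(vy / tol))
  uid <- match(key, unique(key))
  keep <- !duplicated(uid)
  nodes_xy <- cbind(vx[keep], vy[keep])
  v1 <- uid[rep(seq(0, nrow(centres) - 1) * 6, each = 6) + rep(1:6, nrow(centres))]
  v2 <- uid[rep(seq(0, nrow(centres) - 1) * 6, each = 6) + rep(c(2:6, 1), nrow(centres))]
  ei <- cbind(pmin(v1, v2), pmax(v1, v2))
  ei <- ei[!duplicated(paste(ei[, 1], ei[, 2])), , drop = FALSE]
  deg <- tabulate(as.vector(ei), nbins = nrow(nodes_xy))
  nodes <- data.frame(id = seq_len(nrow(nodes_xy)),
                      x = nodes_xy[, 1], y = nodes_xy[, 2],
                      is_boundary = deg < 3L, fx = 0, fy = 0)
  L <- sqrt((nodes$x[ei[, 1]] - nodes$x[ei[, 2]])^2 +
              (nodes$y[ei[, 1]] - nodes$y[ei[, 2]])^2)
  springs <- data.frame(id = seq_len(nrow(ei)),
                        node_i = ei[, 1], node_j = ei[, 2],
                        L0 = L, A = A, E = E)
  new_spring_network(nodes, springs)
}

#' Prestress the network to a uniform strain
#'
#' Sets every spring's rest length to \code{current length / (1 + eps0)} so
#' that the as-generated configuration carries strain exactly \code{eps0}
#' on every spring, mimicking inflated parenchyma.
#'
#' @param net a \code{spring_network}.
#' @param eps0 uniform prestrain (> -1).
#' @return the prestressed network.
#' @export
apply_prestress <- function(net, eps0) {
  if (eps0 <= -1) stop("prestrain must exceed -1")
  L <- current_lengths(net)
  net$springs$L0 <- L / (1 + eps0)
  net
}

current_lengths <- function(net, coords = NULL) {
  nd <- net$nodes
  if (is.null(coords)) coords <- cbind(nd$x, nd$y)
  i <- match(net$springs$node_i, nd$id)
  j <- match(net$springs$node_j, nd$id)
  sqrt((coords[i, 1] - coords[j, 1])^2 + (coords[i, 2] - coords[j, 2])^2)
}

## net internal spring force on every node (n x 2), current configuration
internal_forces <- function(net) {
  nd <- net$nodes; sp <- net$springs
  i <- match(sp$node_i, nd$id); j <- match(sp$node_j, nd$id)
  dx <- nd$x[j] - nd$x[i]; dy <- nd$y[j] - nd$y[i]
  L <- sqrt(dx^2 + dy^2)
  t <- spring_constant(sp$E, sp$A, sp$L0) * (L - sp$L0) / L
  fx <- rowsum(c(t * dx, -t * dx), c(i, j))
  fy <- rowsum(c(t * dy, -t * dy), c(i, j))
  F <- matrix(0, nrow(nd), 2)
  idx <- as.integer(rownames(fx))
  F[idx, 1] <- fx; F[idx, 2] <- fy
  F
}

#' Freeze reaction forces on the boundary
#'
#' Stores, on every boundary node, the external force equal to minus the
#' net internal spring force acting on it in the current configuration ---
#' the reaction the prestressed network exerts on its surroundings.  With
#' these forces applied the boundary is in equilibrium; interior nodes are
#' in equilibrium too once they have been relaxed (see
#' \code{\link{generate_network}}).  The forces remain constant for the
#' rest of a simulation, which lets the network contract as fibrosis
#' stiffens it.
#'
#' @param net a \code{spring_network} (normally prestressed).
#' @return the network with \code{fx, fy} filled on boundary nodes.
#' @export
compute_boundary_forces <- function(net) {
  F <- internal_forces(net)
  b <- net$nodes$is_boundary
  net$nodes$fx <- ifelse(b, -F[, 1], 0)
  net$nodes$fy <- ifelse(b, -F[, 2], 0)
  net
}

#' Generate a ready-to-run prestressed Voronoi network
#'
#' Full pipeline: Poisson-disk sample, Voronoi tessellation, uniform
#' prestress, interior settling (the uniform-strain configuration is not an
#' interior force balance, so interior nodes are relaxed with the boundary
#' pinned), and freezing of the boundary reaction forces.  The returned
#' network is an equilibrium of its own boundary forces to within
#' \code{tol}.
#'
#' @param domain a \code{\link{domain_spec}}.
#' @param params a \code{\link{model_params}} supplying \code{A0},
#'   \code{E} and \code{eps0}.
#' @param settle relax interior nodes before freezing reactions (skip only
#'   for geometries that are already balanced, e.g. honeycombs).
#' @param tol residual force tolerance for settling.
#' @return an equilibrated, prestressed \code{spring_network}.
#' @export
generate_network <- function(domain = domain_spec(), params = model_params(),
                             settle = TRUE, tol = 1e-10) {
  pts <- poisson_disk_sample(domain)
  net <- build_voronoi_network(pts, domain, A = params$A0, E = params$E)
  net <- apply_prestress(net, params$eps0)
  if (settle) {
    res <- equilibrate(net, pinned = net$nodes$is_boundary, tol = tol)
    net$nodes$x <- res$coords[, 1]
    net$nodes$y <- res$coords[, 2]
  }
  compute_boundary_forces(net)
}

#' Serialize a spring network to a plain-text snapshot
#'
#' Node and edge tables in one CSV-sectioned text file; numeric fields are
#' written with 17 significant digits so the round trip through
#' \code{\link{read_network}} is bit exact.
#'
#' @param net a \code{spring_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  fmt <- function(x) sprintf("%.17g", x)
  nd <- net$nodes; sp <- net$springs
  lines <- c(
    "# fibronet spring network v1",
    "# nodes",
    "id,x,y,is_boundary,fx,fy",
    paste(nd$id, fmt(nd$x), fmt(nd$y), as.integer(nd$is_boundary),
          fmt(nd$fx), fmt(nd$fy), sep = ","),
    "# springs",
    "id,node_i,node_j,L0,A,E",
    paste(sp$id, sp$node_i, sp$node_j, fmt(sp$L0), fmt(sp$A), fmt(sp$E),
          sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spring network snapshot
#'
#' @param path file written by \code{\link{write_network}}.
#' @return a \code{spring_network}.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  isec <- which(startsWith(lines, "# "))
  nsec <- which(lines == "# nodes")
  ssec <- which(lines == "# springs")
  if (length(nsec) != 1L || length(ssec) != 1L)
    stop("not a fibronet network snapshot: ", path)
  nd <- read.csv(text = lines[(nsec + 1L):(ssec - 1L)])
  sp <- read.csv(text = lines[(ssec + 1L):length(lines)])
  nd$is_boundary <- as.logical(nd$is_boundary)
  for (cl in c("x", "y", "fx", "fy")) nd[[cl]] <- as.numeric(nd[[cl]])
  for (cl in c("L0", "A", "E")) sp[[cl]] <- as.numeric(sp[[cl]])
  new_spring_network(nd, sp)
}
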