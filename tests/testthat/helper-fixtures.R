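# Shared fixtures, generated in code.  The honeycomb is the deterministic
# mechanics fixture; the small Voronoi network is cached per test session
# because generation is the slow step.

default_params <- function(...) model_params(...)

# internal helpers exercised directly by tests
element_outcomes <- fibronet:::element_outcomes
set_coords <- fibronet:::set_coords
hull_area <- fibronet:::hull_area
node_incidence <- fibronet:::node_incidence
classify_run_outcome <- fibronet:::classify_run_outcome

# prestressed honeycomb with frozen boundary reactions (exact equilibrium)
hex_fixture <- function(n_rings = 3, eps0 = 1, A = 1, E = 1) {
  net <- hexagonal_network(n_rings, A = A, E = E)
  net <- apply_prestress(net, eps0)
  compute_boundary_forces(net)
}

local({
  cache <- new.env(parent = emptyenv())
  voronoi_fixture <<- function(seed = 42, radius = 0.09) {
    key <- paste0("net_", seed, "_", radius)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_network(
        domain_spec(1, radius, seed = seed), model_params(), tol = 1e-10)
    cache[[key]]
  }
})

# two-node, one-spring network under an axial force pair: the closed-form
# Hookean oracle (strain = F / (E A) at constant force)
single_spring_net <- function(E = 1, A = 1, L0 = 1, F = 0.1) {
  nodes <- data.frame(id = 1:2, x = c(0, L0), y = c(0, 0),
                      is_boundary = TRUE, fx = c(-F, F), fy = 0)
  springs <- data.frame(id = 1L, node_i = 1L, node_j = 2L,
                        L0 = L0, A = A, E = E)
  fibronet:::new_spring_network(nodes, springs)
}
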