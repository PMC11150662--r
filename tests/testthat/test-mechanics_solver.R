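# Equilibrium solver, strains, rupture pruning and the stiffness assay.

test_that("spring constant is E A / L0 with domain checks", {
  expect_equal(spring_constant(1, 1, 1), 1)
  expect_equal(spring_constant(1, 10, 0.5), 20)
  expect_equal(spring_constant(2, 3, 1.5), 2 * spring_constant(1, 3, 1.5))
  expect_error(spring_constant(0, 1, 1), "positive")
  expect_error(spring_constant(1, -2, 1), "positive")
})

test_that("single spring under constant force matches the Hookean oracle", {
  for (F in c(0.05, 0.3, 1)) {
    net <- single_spring_net(E = 1, A = 0.8, L0 = 1, F = F)
    res <- equilibrate(net, tol = 1e-12)
    eps <- spring_strains(net, res$coords)
    expect_equal(eps, F / (1 * 0.8), tolerance = 1e-8)
  }
})

test_that("relaxation never raises the energy and hits its tolerance", {
  net <- hex_fixture(3)
  set.seed(2)
  jig <- cbind(net$nodes$x, net$nodes$y) +
    matrix(rnorm(2 * nrow(net$nodes), 0, 0.05), ncol = 2)
  e_before <- network_energy(net, jig)
  res <- equilibrate(net, coords = jig, tol = 1e-9)
  expect_true(res$converged)
  expect_lte(res$residual, 1e-9)
  expect_lt(network_energy(net, res$coords), e_before)
})

test_that("relax and anneal engines agree on the equilibrium", {
  net <- hex_fixture(2)
  set.seed(4)
  jig <- cbind(net$nodes$x, net$nodes$y) +
    matrix(rnorm(2 * nrow(net$nodes), 0, 0.04), ncol = 2)
  r1 <- equilibrate(net, mode = "relax", coords = jig, tol = 1e-9)
  set.seed(99)
  r2 <- equilibrate(net, mode = "anneal", coords = jig, tol = 1e-4,
                    max_iter = 20000)
  e1 <- network_energy(net, r1$coords)
  e2 <- network_energy(net, r2$coords)
  expect_lt(abs(e1 - e2) / abs(e1), 1e-4)
})

test_that("equilibrium is translation-consistent", {
  net <- voronoi_fixture()
  res <- equilibrate(net, tol = 1e-9)
  shifted <- res$coords + matrix(rep(c(0.3, -0.2), each = nrow(res$coords)),
                                 ncol = 2)
  res2 <- equilibrate(net, coords = shifted, tol = 1e-9)
  # forces depend on relative positions only; the shifted copy is already
  # an equilibrium and stays where it is
  expect_lt(max(abs(res2$coords - shifted)), 1e-8)
})

test_that("symmetric hexagon under symmetric load keeps its symmetry", {
  net <- hex_fixture(1)      # single hexagon, all nodes boundary
  res <- equilibrate(net, tol = 1e-11)
  # 6-fold symmetric reaction forces hold the regular hexagon: node radii
  # stay equal
  r <- sqrt(rowSums((res$coords - matrix(colMeans(res$coords),
                                         nrow(res$coords), 2,
                                         byrow = TRUE))^2))
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
})

test_that("strains read (L - L0)/L0 and respond to local stiffening", {
  net <- hex_fixture(3)
  expect_equal(spring_strains(net), rep(1, nrow(net$springs)),
               tolerance = 1e-12)
  # stiffen one interior spring 10x: its strain drops, neighbours pick up
  interior_nodes <- net$nodes$id[!net$nodes$is_boundary]
  s <- which(net$springs$node_i %in% interior_nodes &
               net$springs$node_j %in% interior_nodes)[1]
  net2 <- net
  net2$springs$A[s] <- 10 * net2$springs$A[s]
  res <- equilibrate(net2, tol = 1e-10)
  eps <- spring_strains(net2, res$coords)
  expect_lt(eps[s], 1)
  nb <- which(net$springs$node_i %in% c(net$springs$node_i[s],
                                        net$springs$node_j[s]) |
                net$springs$node_j %in% c(net$springs$node_i[s],
                                          net$springs$node_j[s]))
  nb <- setdiff(nb, s)
  expect_gt(max(eps[nb]), 1)
})

test_that("pruning removes ruptured, isolated and stranded material", {
  net <- hex_fixture(2)
  # no-op on a healthy network
  pr0 <- prune_ruptured(net)
  expect_equal(nrow(pr0$net$springs), nrow(net$springs))
  expect_length(pr0$removed_springs, 0)
  # rupture all springs around one interior node: node goes away
  nd <- net$nodes$id[!net$nodes$is_boundary][1]
  hit <- net$springs$node_i == nd | net$springs$node_j == nd
  net$springs$A[hit] <- 0
  pop <- structure(data.frame(id = 1:2,
                              node = c(nd,
                                       net$nodes$id[net$nodes$is_boundary][1]),
                              a = 0),
                   next_id = 3L,
                   class = c("agent_population", "data.frame"))
  pr <- prune_ruptured(net, pop)
  expect_true(nd %in% pr$removed_nodes)
  expect_identical(pr$stranded_agents, 1L)
  expect_equal(nrow(pr$pop), 1L)
  # idempotent
  pr2 <- prune_ruptured(pr$net, pr$pop)
  expect_identical(pr2$net$springs$id, pr$net$springs$id)
  expect_length(pr2$removed_springs, 0)
})

test_that("pruning drops isolated two-node components", {
  nodes <- data.frame(id = 1:5, x = c(0, 1, 2, 5, 6), y = 0,
                      is_boundary = FALSE, fx = 0, fy = 0)
  springs <- data.frame(id = 1:3, node_i = c(1, 2, 4), node_j = c(2, 3, 5),
                        L0 = 1, A = 1, E = 1)
  net <- fibronet:::new_spring_network(nodes, springs)
  pr <- prune_ruptured(net)
  expect_identical(sort(pr$removed_springs), 3L)   # the stranded pair
  expect_true(all(c(4L, 5L) %in% pr$removed_nodes))
})

test_that("stiffness assay matches the single-spring closed form", {
  # stretching an unstrained spring of stiffness K about its centre:
  # E(s) = 1/2 K (L0 s)^2, so the quadratic coefficient is K L0^2 / 2
  K <- 2.5; L0 <- 1.4
  nodes <- data.frame(id = 1:2, x = c(0, L0), y = 0, is_boundary = TRUE,
                      fx = 0, fy = 0)
  springs <- data.frame(id = 1L, node_i = 1L, node_j = 2L, L0 = L0,
                        A = K * L0, E = 1)   # E A / L0 = K
  net <- fibronet:::new_spring_network(nodes, springs)
  as <- stiffness_assay(net)
  expect_equal(as$stiffness, 0.5 * K * L0^2, tolerance = 1e-8)
  expect_lt(as$residual, 1e-10)
})

test_that("assay scales linearly in area and never drops when stiffened", {
  net <- voronoi_fixture()
  a1 <- stiffness_assay(net)
  net2 <- net
  net2$springs$A <- 2 * net2$springs$A
  a2 <- stiffness_assay(net2)
  expect_equal(a2$stiffness / a1$stiffness, 2, tolerance = 1e-6)
  # raising a single spring's area cannot soften the network
  net3 <- net
  net3$springs$A[5] <- 4 * net3$springs$A[5]
  a3 <- stiffness_assay(net3)
  expect_gte(a3$stiffness, a1$stiffness * (1 - 1e-9))
})

test_that("assay on a healthy network self-normalizes to 1 cleanly", {
  net <- voronoi_fixture()
  as <- stiffness_assay(net)
  expect_equal(as$stiffness / as$stiffness, 1)
  expect_lt(as$residual, 1e-6)
  expect_equal(as$strain, c(0, 0.02, 0.04, 0.06, 0.08, 0.10))
  expect_true(all(diff(as$energy) > 0))
})
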