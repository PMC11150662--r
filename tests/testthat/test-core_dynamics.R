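# Lumped single-element difference-equation system.

test_that("Hill activations match direct arithmetic and saturate", {
  p <- default_params()
  # half saturation and zero
  expect_equal(stiffness_activation(p$At, p), 0.5)
  expect_equal(stiffness_activation(0, p), 0)
  expect_equal(strain_activation(p$eps_s, p), 0.5)
  expect_equal(strain_activation(0, p), 0)
  # frozen arithmetic at the defaults: (1/10)^3 / ((1/10)^3 + 1)
  expect_equal(stiffness_activation(1, p), 0.001 / 1.001, tolerance = 1e-12)
  # gamma = 1, eps = 3: 3 / 4
  expect_equal(strain_activation(3, p), 0.75)
  expect_error(stiffness_activation(-1, p), "non-negative")
  expect_error(strain_activation(-0.5, p), "non-negative")
})

test_that("Hill activations are bounded and strictly monotone", {
  set.seed(7)
  for (rep in 1:25) {
    p <- model_params(At = runif(1, 2, 50), beta = runif(1, 0.5, 6),
                      eps_s = runif(1, 0.2, 4), gamma = runif(1, 0.5, 4))
    x <- sort(c(0, exp(runif(20, -4, 6))))
    aK <- stiffness_activation(x, p)
    ae <- strain_activation(x, p)
    expect_true(all(aK >= 0 & aK < 1))
    expect_true(all(ae >= 0 & ae < 1))
    expect_true(all(diff(aK) > 0))
    expect_true(all(diff(ae) > 0))
  }
  # limit: saturation at 1 from below
  expect_equal(stiffness_activation(1e150, default_params()), 1)
})

test_that("homeostatic offset constant matches independent arithmetic", {
  # independent evaluation, written out digit by digit
  cofw <- function(w1, w2, A0, At, beta)
    w1 / 2 + w2 * (A0 / At)^beta / ((A0 / At)^beta + 1)
  expect_equal(model_params()$c, cofw(1, 1, 1, 10, 3), tolerance = 1e-15)
  expect_equal(model_params()$c, 0.500999, tolerance = 1e-6)
  expect_equal(model_params(w2 = 2)$c, 0.501998, tolerance = 1e-6)
  expect_equal(model_params(w2 = 0)$c, 0.5)
  # cache coherence
  p <- model_params(w2 = 2.4, beta = 2, At = 7)
  expect_identical(p$c, steady_state_constant(p))
})

test_that("total activation is zero at homeostasis and bounded", {
  p <- default_params()
  a0 <- total_activation(strain_activation(p$eps_s, p),
                         stiffness_activation(p$A0, p), p)
  expect_identical(a0, 0)       # exact cancellation by construction of c
  expect_equal(total_activation(0, 0, p), -p$c)
  expect_equal(total_activation(1, 1, p), p$w1 + p$w2 - p$c)
})

test_that("activation memory update follows the low-pass form", {
  p <- default_params()
  # memoryless at the fixed point
  p1 <- update_params(p, r = 1)
  expect_equal(update_activation(0.7, 0.5, stiffness_activation(1, p1), p1),
               0)
  # full memory freezes a
  p0 <- update_params(p, r = 0)
  expect_equal(update_activation(0.3, 0.9, 0.9, p0), 0.3)
  # frozen arithmetic: r = 0.5, a = 0, inputs as evaluated at A=1, eps=3
  expect_equal(update_activation(0, 0.75, 0.001 / 1.001, p),
               0.5 * (0.75 + 0.001 / 1.001 - p$c), tolerance = 1e-12)
  expect_equal(update_activation(0, 0.75, 9.99001e-4, p), 0.125,
               tolerance = 1e-4)
})

test_that("area update is linear in P, D, a and can signal rupture", {
  p <- default_params()
  expect_equal(update_area(2.5, 1.3, 0, p), 2.5)
  expect_equal(update_area(1, 0.3, 0.5, p), 1.03)
  expect_equal(update_area(0.01, 1, -0.5, p), -0.09)   # rupture condition
})

test_that("constant-force strain keeps eps * A invariant", {
  p <- default_params()
  expect_equal(constant_force_strain(p$A0, p), p$eps_s)
  expect_equal(constant_force_strain(2 * p$A0, p), p$eps_s / 2)
  A <- exp(seq(-2, 8, length.out = 40))
  expect_equal(constant_force_strain(A, p) * A,
               rep(p$eps_s * p$A0, 40), tolerance = 1e-12)
  expect_error(constant_force_strain(0, p), "ruptured")
})

test_that("density map has its two fixed points and is clamped", {
  p <- default_params()
  expect_equal(update_density(p$D0, 0, 2, 3, p), p$D0)     # homeostasis
  expect_equal(update_density(p$Dmax, p$a_fib, 2, 3, p), p$Dmax)
  expect_equal(update_density(0, 0, 2, 3, p), p$p1 * 2 / 3,
               tolerance = 1e-12)
  expect_true(update_density(p$Dmax, 10, 2, 3, p) <= p$Dmax)
  # convergence to D0 from both sides at a = 0
  D <- 1.7
  for (i in 1:4000) D <- update_density(D, 0, 2, 3, p)
  expect_equal(D, p$D0, tolerance = 1e-6)
  # convergence to Dmax under sustained fibrotic activation
  D <- 1
  for (i in 1:9000) D <- update_density(D, p$a_fib, 2, 3, p)
  expect_equal(D, p$Dmax, tolerance = 1e-3)
})

test_that("the coupled map holds the homeostatic fixed point exactly", {
  for (w2 in c(1, 1.7, 3)) {
    p <- model_params(w2 = w2)
    tr <- simulate_element(p, injury_multiplier = 1, n_iterations = 300)
    expect_true(all(tr$A == p$A0))
    expect_true(all(tr$a == 0))
    expect_true(all(tr$eps == p$eps_s))
    expect_true(all(tr$D == p$D0))
    expect_identical(attr(tr, "outcome"), "healing")
  }
})

test_that("single-element trajectories keep the constant-force invariant", {
  p <- model_params(w2 = 1.5)
  tr <- simulate_element(p, injury_multiplier = 3, n_iterations = 500)
  expect_equal(tr$eps * tr$A, rep(p$eps_s * p$A0, nrow(tr)),
               tolerance = 1e-9)
})

test_that("element simulation is bit-reproducible", {
  p <- model_params(w2 = 2)
  t1 <- simulate_element(p, 4.5, n_iterations = 400)
  t2 <- simulate_element(p, 4.5, n_iterations = 400)
  expect_identical(t1, t2)
})

test_that("softening injuries heal; extreme stiffening turns fibrotic", {
  expect_identical(attr(simulate_element(model_params(w2 = 1.5), 0.5),
                        "outcome"), "healing")
  soft <- element_outcomes(model_params(w2 = 2), seq(0.05, 0.95, 0.05),
                           n_iterations = 2000)
  expect_true(all(soft == "healing"))
  tr <- simulate_element(model_params(w2 = 2), 50)
  expect_identical(attr(tr, "outcome"), "fibrotic")
  # runaway growth: strain collapses toward zero as area grows
  expect_lt(tr$eps[nrow(tr)], 0.1)
  expect_gt(tr$A[nrow(tr)], tr$A[2])
})

test_that("outcome is monotone in the injury multiplier (healing interval)", {
  for (w2 in c(1, 1.5, 2, 2.5, 3)) {
    m <- seq(1, 15, by = 0.05)
    out <- element_outcomes(model_params(w2 = w2), m)
    fib <- out == "fibrotic"
    expect_true(all(diff(fib) >= 0))       # fibrotic region is an interval up
    expect_true(all(out[!fib] == "healing"))
  }
})

test_that("fibrotic threshold agrees with a brute-force scan", {
  p <- model_params(w2 = 1.5)
  thr <- find_fibrotic_threshold(p)
  m <- seq(floor(thr) - 1, ceiling(thr) + 1, by = 0.01)
  out <- element_outcomes(p, m)
  scan_thr <- m[which(out == "fibrotic")[1]]
  expect_lt(abs(thr - scan_thr), 0.01 + 1e-3)
})

test_that("threshold decreases with stiffness weight; sentinel below 0.5", {
  thr <- vapply(c(1, 1.5, 2, 2.5, 3), function(w2)
    find_fibrotic_threshold(model_params(w2 = w2)), numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_identical(find_fibrotic_threshold(model_params(w2 = 0.4)), Inf)
  expect_identical(find_fibrotic_threshold(model_params(w2 = 0.5)), Inf)
})

test_that("critical stiffness weight sits at half the strain weight", {
  cw <- find_critical_weight(model_params(), n_iterations = 1000)
  expect_equal(cw, 0.5, tolerance = 2e-3)
  # joint rescaling symmetry: doubling w1 doubles the critical weight
  cw2 <- find_critical_weight(model_params(w1 = 2), n_iterations = 1000)
  expect_equal(cw2, 1, tolerance = 4e-3)
})

test_that("a saturating elevated-area state exists just below w2 = 0.5", {
  # the closed-form condition w2 > w1/2 considers only unbounded growth;
  # the full Hill system also has a stable elevated-area fixed point
  # reachable slightly below it, where the strain signal (decaying ~1/A)
  # still tops up the stiffness deficit (decaying ~1/A^3)
  p <- model_params(w2 = 0.49)
  tr <- simulate_element(p, 30, n_iterations = 3000)
  expect_identical(attr(tr, "outcome"), "fibrotic")
  expect_gt(tr$A[nrow(tr)], 10 * p$A0)          # elevated, not healing
  expect_lt(tr$A[nrow(tr)], 100 * p$A0)         # saturating, not runaway
})

test_that("phase diagram: homeostasis heals, far-field is fibrotic", {
  p <- model_params(w2 = 2)
  ph <- phase_diagram(p, eps_grid = c(0.5, 1, 2), A_grid = c(0.5, 1, 2),
                      n_iterations = 1500)
  expect_identical(ph$label[2, 2], "healing")             # (eps=1, A=1)
  far <- phase_diagram(p, eps_grid = c(0.02, 0.05), A_grid = c(30, 60),
                       n_iterations = 1500)
  expect_true(all(far$label == "fibrotic"))               # low eps, A >> At
  # a grid straddling the basin boundary gets a mixed band
  wide <- phase_diagram(p, eps_grid = c(0.1, 1), A_grid = c(1, 30),
                        n_iterations = 1500)
  expect_true(any(wide$label == "mixed"))
  expect_true(all(wide$label %in%
                    c("healing", "fibrotic", "mixed", "undecided",
                      "unstable")))
})

test_that("phase boundary is consistent with the injury threshold", {
  # along the constant-force curve eps * A = 1 the phase flip happens at
  # the threshold multiplier found independently by bisection
  p <- model_params(w2 = 2)
  thr <- find_fibrotic_threshold(p)
  below <- 0.95 * thr; above <- 1.05 * thr
  ph_b <- phase_diagram(p, eps_grid = 1 / below, A_grid = below,
                        n_iterations = 2000)
  ph_a <- phase_diagram(p, eps_grid = 1 / above, A_grid = above,
                        n_iterations = 2000)
  expect_identical(as.vector(ph_b$label), "healing")
  expect_identical(as.vector(ph_a$label), "fibrotic")
})
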