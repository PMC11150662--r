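// Elastic equilibrium of a 2D Hookean spring network under constant
// external (boundary) forces.  Two engines:
//   - FIRE (fast inertial relaxation engine): deterministic default.
//   - greedy random-displacement descent with a shrinking step schedule:
//     fidelity check mirroring the annealing the model was conceived with.
// Energy: sum_s 1/2 k_s (L_s - L0_s)^2  -  sum_i F_i . x_i
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void spring_forces(const NumericMatrix& x, const IntegerMatrix& e,
                          const NumericVector& L0, const NumericVector& k,
                          const NumericMatrix& fext, NumericMatrix& F) {
  const int n = x.nrow(), m = e.nrow();
  for (int i = 0; i < n; ++i) { F(i, 0) = fext(i, 0); F(i, 1) = fext(i, 1); }
  for (int s = 0; s < m; ++s) {
    const int i = e(s, 0), j = e(s, 1);
    const double dx = x(j, 0) - x(i, 0), dy = x(j, 1) - x(i, 1);
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0) continue;                  // degenerate: no defined direction
    const double t = k[s] * (L - L0[s]) / L;   // tension / length
    F(i, 0) += t * dx; F(i, 1) += t * dy;
    F(j, 0) -= t * dx; F(j, 1) -= t * dy;
  }
}

// [[Rcpp::export]]
NumericMatrix net_forces_cpp(NumericMatrix coords, IntegerMatrix edges,
                             NumericVector L0, NumericVector k,
                             NumericMatrix fext) {
  NumericMatrix F(coords.nrow(), 2);
  spring_forces(coords, edges, L0, k, fext, F);
  return F;
}

// [[Rcpp::export]]
double net_energy_cpp(NumericMatrix coords, IntegerMatrix edges,
                      NumericVector L0, NumericVector k,
                      NumericMatrix fext, bool include_external) {
  const int n = coords.nrow(), m = edges.nrow();
  double E = 0.0;
  for (int s = 0; s < m; ++s) {
    const int i = edges(s, 0), j = edges(s, 1);
    const double dx = coords(j, 0) - coords(i, 0);
    const double dy = coords(j, 1) - coords(i, 1);
    const double L = std::sqrt(dx * dx + dy * dy);
    const double d = L - L0[s];
    E += 0.5 * k[s] * d * d;
  }
  if (include_external)
    for (int i = 0; i < n; ++i)
      E -= fext(i, 0) * coords(i, 0) + fext(i, 1) * coords(i, 1);
  return E;
}

// [[Rcpp::export]]
List relax_fire_cpp(NumericMatrix coords, IntegerMatrix edges,
                    NumericVector L0, NumericVector k, NumericMatrix fext,
                    LogicalVector free_node, double tol, int max_iter) {
  const int n = coords.nrow(), m = edges.nrow();
  NumericMatrix x = clone(coords);
  NumericMatrix F(n, 2), v(n, 2);
  double kmax = 1e-12;
  for (int s = 0; s < m; ++s) if (k[s] > kmax) kmax = k[s];
  const double dt_max = 0.8 / std::sqrt(kmax);
  double dt = 0.1 * dt_max, alpha = 0.1;
  int npos = 0, it = 0;
  double fmax = R_PosInf;
  for (it = 0; it < max_iter; ++it) {
    spring_forces(x, edges, L0, k, fext, F);
    fmax = 0.0;
    double P = 0.0, vn2 = 0.0, fn2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!free_node[i]) { F(i, 0) = 0; F(i, 1) = 0; continue; }
      const double fi = std::sqrt(F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1));
      if (fi > fmax) fmax = fi;
      P += F(i, 0) * v(i, 0) + F(i, 1) * v(i, 1);
      vn2 += v(i, 0) * v(i, 0) + v(i, 1) * v(i, 1);
      fn2 += F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1);
    }
    if (fmax <= tol) break;
    if (P > 0) {
      if (++npos > 5) { dt = std::min(dt * 1.1, dt_max); alpha *= 0.99; }
      const double mix = (fn2 > 0) ? alpha * std::sqrt(vn2 / fn2) : 0.0;
      for (int i = 0; i < n; ++i) {
        if (!free_node[i]) continue;
        v(i, 0) = (1 - alpha) * v(i, 0) + mix * F(i, 0);
        v(i, 1) = (1 - alpha) * v(i, 1) + mix * F(i, 1);
      }
    } else {
      for (int i = 0; i < n; ++i) { v(i, 0) = 0; v(i, 1) = 0; }
      dt *= 0.5; alpha = 0.1; npos = 0;
    }
    for (int i = 0; i < n; ++i) {
      if (!free_node[i]) continue;
      v(i, 0) += dt * F(i, 0); v(i, 1) += dt * F(i, 1);
      x(i, 0) += dt * v(i, 0); x(i, 1) += dt * v(i, 1);
    }
  }
  return List::create(_["coords"] = x, _["residual"] = fmax,
                      _["iterations"] = it, _["converged"] = fmax <= tol);
}

// Newton-Krylov relaxation: Newton iterations with a matrix-free conjugate
// gradient solve of the spring-network Hessian (per-spring 2x2 blocks
// k u u^T + (t/L)(I - u u^T)), a backtracking line search on the energy,
// and early CG exit on negative curvature (possible under compression).
// Converges in a handful of Newton steps from the warm starts a running
// simulation provides; the caller falls back to FIRE if it stalls.
// [[Rcpp::export]]
List relax_newton_cpp(NumericMatrix coords, IntegerMatrix edges,
                      NumericVector L0, NumericVector k, NumericMatrix fext,
                      LogicalVector free_node, double tol, int max_newton,
                      int max_cg) {
  const int n = coords.nrow(), m = edges.nrow();
  NumericMatrix x = clone(coords);
  NumericMatrix F(n, 2);
  std::vector<double> Bxx(m), Bxy(m), Byy(m);
  std::vector<double> d(2 * n, 0.0), r(2 * n), p(2 * n), Hp(2 * n);
  auto energy = [&]() {
    double E = 0.0;
    for (int s = 0; s < m; ++s) {
      const int i = edges(s, 0), j = edges(s, 1);
      const double dx = x(j, 0) - x(i, 0), dy = x(j, 1) - x(i, 1);
      const double dl = std::sqrt(dx * dx + dy * dy) - L0[s];
      E += 0.5 * k[s] * dl * dl;
    }
    for (int i = 0; i < n; ++i)
      E -= fext(i, 0) * x(i, 0) + fext(i, 1) * x(i, 1);
    return E;
  };
  auto hessian_blocks = [&]() {
    for (int s = 0; s < m; ++s) {
      const int i = edges(s, 0), j = edges(s, 1);
      const double dx = x(j, 0) - x(i, 0), dy = x(j, 1) - x(i, 1);
      const double L = std::sqrt(dx * dx + dy * dy);
      if (L <= 0) { Bxx[s] = Byy[s] = k[s]; Bxy[s] = 0; continue; }
      const double ux = dx / L, uy = dy / L;
      const double tL = k[s] * (L - L0[s]) / L;
      Bxx[s] = k[s] * ux * ux + tL * (1 - ux * ux);
      Bxy[s] = (k[s] - tL) * ux * uy;
      Byy[s] = k[s] * uy * uy + tL * (1 - uy * uy);
    }
  };
  auto hess_vec = [&](const std::vector<double>& v, std::vector<double>& out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int s = 0; s < m; ++s) {
      const int i = edges(s, 0), j = edges(s, 1);
      const double ex = v[2 * i] - v[2 * j], ey = v[2 * i + 1] - v[2 * j + 1];
      const double wx = Bxx[s] * ex + Bxy[s] * ey;
      const double wy = Bxy[s] * ex + Byy[s] * ey;
      out[2 * i] += wx;     out[2 * i + 1] += wy;
      out[2 * j] -= wx;     out[2 * j + 1] -= wy;
    }
    for (int i = 0; i < n; ++i)
      if (!free_node[i]) { out[2 * i] = v[2 * i]; out[2 * i + 1] = v[2 * i + 1]; }
  };
  double fmax = R_PosInf;
  int it = 0;
  bool ok = true;
  for (it = 0; it < max_newton; ++it) {
    spring_forces(x, edges, L0, k, fext, F);
    fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!free_node[i]) continue;
      const double fi = std::sqrt(F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1));
      if (fi > fmax) fmax = fi;
    }
    if (fmax <= tol) break;
    hessian_blocks();
    // CG solve H d = F (gradient is -F); d starts at 0
    std::fill(d.begin(), d.end(), 0.0);
    double rr = 0.0;
    for (int i = 0; i < n; ++i) {
      r[2 * i] = free_node[i] ? F(i, 0) : 0.0;
      r[2 * i + 1] = free_node[i] ? F(i, 1) : 0.0;
      rr += r[2 * i] * r[2 * i] + r[2 * i + 1] * r[2 * i + 1];
    }
    p = r;
    const double rr0 = rr;
    for (int cg = 0; cg < max_cg && rr > 1e-4 * rr0 && rr > 1e-30; ++cg) {
      hess_vec(p, Hp);
      double pHp = 0.0;
      for (size_t q = 0; q < p.size(); ++q) pHp += p[q] * Hp[q];
      if (pHp <= 0) { if (cg == 0) d = r; break; }  // negative curvature
      const double alpha = rr / pHp;
      double rr_new = 0.0;
      for (size_t q = 0; q < p.size(); ++q) {
        d[q] += alpha * p[q];
        r[q] -= alpha * Hp[q];
        rr_new += r[q] * r[q];
      }
      const double beta = rr_new / rr;
      rr = rr_new;
      for (size_t q = 0; q < p.size(); ++q) p[q] = r[q] + beta * p[q];
    }
    // backtracking line search on the energy along d
    const double E0 = energy();
    double step = 1.0;
    bool accepted = false;
    for (int ls = 0; ls < 12; ++ls) {
      for (int i = 0; i < n; ++i) {
        if (!free_node[i]) continue;
        x(i, 0) += step * d[2 * i];
        x(i, 1) += step * d[2 * i + 1];
      }
      if (energy() <= E0 + 1e-12 * std::abs(E0)) { accepted = true; break; }
      for (int i = 0; i < n; ++i) {
        if (!free_node[i]) continue;
        x(i, 0) -= step * d[2 * i];
        x(i, 1) -= step * d[2 * i + 1];
      }
      step *= 0.5;
    }
    if (!accepted) { ok = false; break; }
  }
  return List::create(_["coords"] = x, _["residual"] = fmax,
                      _["iterations"] = it,
                      _["converged"] = ok && fmax <= tol);
}

// Greedy zero-temperature random-displacement descent: per sweep each free
// node proposes one move drawn uniformly from a square of half-width
// `step`; the move is kept only if it lowers the energy.  The step shrinks
// when little is accepted, mimicking "progressively decreasing amounts".
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List relax_anneal_cpp(NumericMatrix coords, IntegerMatrix edges,
                      NumericVector L0, NumericVector k, NumericMatrix fext,
                      LogicalVector free_node, double step0, double shrink,
                      double tol, int max_sweeps) {
  const int n = coords.nrow(), m = edges.nrow();
  NumericMatrix x = clone(coords);
  // incidence lists
  std::vector< std::vector<int> > inc(n);
  for (int s = 0; s < m; ++s) { inc[edges(s, 0)].push_back(s);
                                inc[edges(s, 1)].push_back(s); }
  RNGScope scope;
  double step = step0, fmax = R_PosInf;
  int sweep = 0;
  NumericMatrix F(n, 2);
  auto local_energy = [&](int node) {
    double E = -(fext(node, 0) * x(node, 0) + fext(node, 1) * x(node, 1));
    for (size_t q = 0; q < inc[node].size(); ++q) {
      const int s = inc[node][q];
      const int i = edges(s, 0), j = edges(s, 1);
      const double dx = x(j, 0) - x(i, 0), dy = x(j, 1) - x(i, 1);
      const double d = std::sqrt(dx * dx + dy * dy) - L0[s];
      E += 0.5 * k[s] * d * d;
    }
    return E;
  };
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    int accepted = 0, nfree = 0;
    for (int i = 0; i < n; ++i) {
      if (!free_node[i]) continue;
      ++nfree;
      const double e0 = local_energy(i);
      const double ox = x(i, 0), oy = x(i, 1);
      x(i, 0) = ox + step * (2.0 * R::runif(0, 1) - 1.0);
      x(i, 1) = oy + step * (2.0 * R::runif(0, 1) - 1.0);
      if (local_energy(i) < e0) ++accepted;
      else { x(i, 0) = ox; x(i, 1) = oy; }
    }
    if (nfree == 0) break;
    if (accepted < 0.25 * nfree) step *= shrink;
    if (sweep % 10 == 9 || step < 1e-14) {
      spring_forces(x, edges, L0, k, fext, F);
      fmax = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!free_node[i]) continue;
        const double fi = std::sqrt(F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1));
        if (fi > fmax) fmax = fi;
      }
      if (fmax <= tol || step < 1e-14) break;
    }
  }
  spring_forces(x, edges, L0, k, fext, F);
  fmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!free_node[i]) continue;
    const double fi = std::sqrt(F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1));
    if (fi > fmax) fmax = fi;
  }
  return List::create(_["coords"] = x, _["residual"] = fmax,
                      _["iterations"] = sweep, _["converged"] = fmax <= tol);
}
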