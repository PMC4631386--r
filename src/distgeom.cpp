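// Distance-geometry inner loops: triangle-inequality bound smoothing,
// random metrization with bound propagation, and gradient descent /
// steepest-descent+conjugate-gradient minimization of the restraint
// penalty.  Kept in C++ because the bound matrices are dense O(N^2)
// objects updated O(N) times per structure.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Floyd-Warshall on the upper matrix; inverse triangle inequality on the
// lower matrix (iterated to a fixed point).  Returns -1 on success or the
// flattened index of an inconsistent pair.
static int smooth_inplace(NumericMatrix L, NumericMatrix U) {
  const int n = L.nrow();
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      const double uik = U(i, k);
      if (!R_finite(uik)) continue;
      for (int j = 0; j < n; ++j) {
        const double v = uik + U(k, j);
        if (v < U(i, j)) { U(i, j) = v; }
      }
    }
  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= n) {
    changed = false;
    for (int k = 0; k < n; ++k)
      for (int i = 0; i < n; ++i) {
        const double lik = L(i, k), uik = U(i, k);
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double lo = lik - U(k, j);
          const double l2 = L(k, j) - uik;
          if (l2 > lo) lo = l2;
          if (lo > L(i, j) + 1e-12) { L(i, j) = lo; changed = true; }
        }
      }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (L(i, j) > U(i, j) + 1e-9) return i * n + j;
  return -1;
}

// [[Rcpp::export]]
List cpp_smooth_bounds(NumericMatrix lower, NumericMatrix upper) {
  NumericMatrix L = clone(lower), U = clone(upper);
  int bad = smooth_inplace(L, U);
  return List::create(_["lower"] = L, _["upper"] = U, _["bad"] = bad);
}

// Propagate bounds after fixing pair (i, j) at distance d: one incremental
// Floyd-Warshall pass through the two affected atoms.
static void propagate_fix(NumericMatrix L, NumericMatrix U, int i, int j) {
  const int n = L.nrow();
  const int ks[2] = { i, j };
  for (int t = 0; t < 2; ++t) {
    const int k = ks[t];
    for (int a = 0; a < n; ++a) {
      const double uak = U(a, k), lak = L(a, k);
      for (int b = 0; b < n; ++b) {
        if (b == a) continue;
        const double uu = uak + U(k, b);
        if (uu < U(a, b)) U(a, b) = uu;
        double lo = lak - U(k, b);
        const double l2 = L(k, b) - uak;
        if (l2 > lo) lo = l2;
        if (lo > L(a, b)) L(a, b) = lo;
      }
    }
  }
}

// Partial random metrization: pairs listed in `fix` (0-based, in the order
// given) are drawn uniformly within their current bounds and propagated;
// all remaining pairs are then sampled independently within the final
// bounds.  Uses the R RNG (seed with set.seed()).
// [[Rcpp::export]]
List cpp_metrize(NumericMatrix lower, NumericMatrix upper,
                 IntegerMatrix fix) {
  NumericMatrix L = clone(lower), U = clone(upper);
  const int n = L.nrow();
  for (int r = 0; r < fix.nrow(); ++r) {
    const int i = fix(r, 0), j = fix(r, 1);
    double lo = L(i, j), hi = U(i, j);
    if (lo > hi + 1e-9)
      return List::create(_["ok"] = false, _["bad"] = i * n + j);
    double d = (hi > lo) ? R::runif(lo, hi) : lo;
    L(i, j) = L(j, i) = U(i, j) = U(j, i) = d;
    propagate_fix(L, U, i, j);
  }
  // consistency check + independent sampling of the rest
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double lo = L(i, j), hi = U(i, j);
      if (lo > hi + 1e-9)
        return List::create(_["ok"] = false, _["bad"] = i * n + j);
      double d = (hi > lo) ? R::runif(lo, hi) : lo;
      D(i, j) = D(j, i) = d;
    }
  return List::create(_["ok"] = true, _["dist"] = D);
}

// Restraint-penalty energy and gradient.
// X: n x dim coordinates; bounds L/U with per-pair weights W (experimental
// restraints are typically weighted above the generic soft-sphere bounds);
// w4 penalizes the 4th coordinate; quads: m x 4 (0-based) rows
// (CA, C, N, CB) with target positive chiral volume; penalty
// wchir * max(0, vmin - V)^2 on the first three coordinates.
static double energy_grad(const NumericMatrix& X, const NumericMatrix& L,
                          const NumericMatrix& U, const NumericMatrix& W,
                          double w4, const IntegerMatrix& quads,
                          double wchir, double vmin, NumericMatrix& G) {
  const int n = X.nrow(), dim = X.ncol();
  std::fill(G.begin(), G.end(), 0.0);
  double E = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < dim; ++c) {
        const double t = X(i, c) - X(j, c);
        d2 += t * t;
      }
      const double d = std::sqrt(d2);
      double viol = 0.0;
      if (d > U(i, j)) viol = d - U(i, j);
      else if (d < L(i, j)) viol = d - L(i, j);  // negative
      if (viol != 0.0) {
        const double w = W(i, j);
        E += w * viol * viol;
        const double f = 2.0 * w * viol / (d > 1e-9 ? d : 1e-9);
        for (int c = 0; c < dim; ++c) {
          const double t = f * (X(i, c) - X(j, c));
          G(i, c) += t;
          G(j, c) -= t;
        }
      }
    }
  if (dim == 4 && w4 > 0.0) {
    for (int i = 0; i < n; ++i) {
      E += w4 * X(i, 3) * X(i, 3);
      G(i, 3) += 2.0 * w4 * X(i, 3);
    }
  }
  if (wchir > 0.0 && quads.nrow() > 0) {
    for (int q = 0; q < quads.nrow(); ++q) {
      const int ca = quads(q, 0), cc = quads(q, 1), nn = quads(q, 2),
                cb = quads(q, 3);
      double a[3], b[3], c[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = X(cc, k) - X(ca, k);
        b[k] = X(nn, k) - X(ca, k);
        c[k] = X(cb, k) - X(ca, k);
      }
      const double cx = a[1] * b[2] - a[2] * b[1];
      const double cy = a[2] * b[0] - a[0] * b[2];
      const double cz = a[0] * b[1] - a[1] * b[0];
      const double V = (cx * c[0] + cy * c[1] + cz * c[2]) / 6.0;
      if (V < vmin) {
        const double def = vmin - V;
        E += wchir * def * def;
        const double f = -2.0 * wchir * def / 6.0;  // dE/dV * dV/d(...)
        // dV/dc = cross(a,b); dV/da = cross(b,c); dV/db = cross(c,a)
        const double dax = b[1] * c[2] - b[2] * c[1];
        const double day = b[2] * c[0] - b[0] * c[2];
        const double daz = b[0] * c[1] - b[1] * c[0];
        const double dbx = c[1] * a[2] - c[2] * a[1];
        const double dby = c[2] * a[0] - c[0] * a[2];
        const double dbz = c[0] * a[1] - c[1] * a[0];
        G(cc, 0) += f * dax; G(cc, 1) += f * day; G(cc, 2) += f * daz;
        G(nn, 0) += f * dbx; G(nn, 1) += f * dby; G(nn, 2) += f * dbz;
        G(cb, 0) += f * cx;  G(cb, 1) += f * cy;  G(cb, 2) += f * cz;
        G(ca, 0) -= f * (dax + dbx + cx);
        G(ca, 1) -= f * (day + dby + cy);
        G(ca, 2) -= f * (daz + dbz + cz);
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix X, NumericMatrix L, NumericMatrix U,
                NumericMatrix W, double w4, IntegerMatrix quads,
                double wchir, double vmin) {
  NumericMatrix G(X.nrow(), X.ncol());
  double E = energy_grad(X, L, U, W, w4, quads, wchir, vmin, G);
  return List::create(_["energy"] = E, _["grad"] = G);
}

// Fixed-schedule minimization: `sd_steps` steepest-descent steps followed
// by `cg_steps` Polak-Ribiere conjugate-gradient steps, each displacing no
// atom by more than `max_disp`; steps that would raise the energy are
// shrunk and skipped if no improvement is possible, so the energy is
// non-increasing across the run.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix X0, NumericMatrix L, NumericMatrix U,
                  NumericMatrix W, IntegerMatrix quads, double wchir,
                  double vmin, int sd_steps, int cg_steps,
                  double max_disp) {
  NumericMatrix X = clone(X0);
  const int n = X.nrow(), dim = X.ncol();
  NumericMatrix G(n, dim), Xt(n, dim), Gprev(n, dim), Dir(n, dim);
  double E = energy_grad(X, L, U, W, 0.0, quads, wchir, vmin, G);

  auto try_step = [&](const NumericMatrix& D) -> bool {
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < dim; ++c) d2 += D(i, c) * D(i, c);
      if (d2 > dmax) dmax = d2;
    }
    dmax = std::sqrt(dmax);
    if (dmax < 1e-14) return false;
    double scale = max_disp / dmax;
    for (int h = 0; h < 8; ++h) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < dim; ++c)
          Xt(i, c) = X(i, c) + scale * D(i, c);
      NumericMatrix Gt(n, dim);
      const double Et = energy_grad(Xt, L, U, W, 0.0, quads, wchir, vmin, Gt);
      if (Et <= E) {
        X = clone(Xt); E = Et;
        Gprev = clone(G); G = Gt;
        return true;
      }
      scale *= 0.5;
    }
    return false;
  };

  for (int it = 0; it < sd_steps; ++it) {
    if (E <= 1e-14) break;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < dim; ++c) Dir(i, c) = -G(i, c);
    if (!try_step(Dir)) break;
  }
  // conjugate gradient (Polak-Ribiere, restarted if the direction is uphill)
  std::fill(Gprev.begin(), Gprev.end(), 0.0);
  NumericMatrix H(n, dim);
  bool have_h = false;
  for (int it = 0; it < cg_steps; ++it) {
    if (E <= 1e-14) break;
    double beta = 0.0;
    if (have_h) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < dim; ++c) {
          num += G(i, c) * (G(i, c) - Gprev(i, c));
          den += Gprev(i, c) * Gprev(i, c);
        }
      beta = (den > 1e-20) ? std::max(0.0, num / den) : 0.0;
    }
    double downhill = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < dim; ++c) {
        H(i, c) = -G(i, c) + beta * H(i, c);
        downhill += -H(i, c) * G(i, c);
      }
    if (downhill >= 0.0) {  // uphill direction: restart with -G
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < dim; ++c) H(i, c) = -G(i, c);
    }
    have_h = true;
    if (!try_step(H)) break;
  }
  return List::create(_["X"] = X, _["energy"] = E);
}
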