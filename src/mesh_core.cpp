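// Core numerical routines for the two-cell surface-energy model:
// patch areas / body volumes and their gradients, the projected-gradient
// energy minimizer with volume constraints and a one-sided ellipsoid
// constraint, mesh-quality passes (tangential smoothing, equiangulation),
// nearest-point projection onto an ellipsoid, marker-based 3D watershed,
// brute-force nearest neighbours and ray-casting point-in-body tests.
//
// Patch codes used throughout: 1 = AB outer, 2 = P1 outer, 3 = contact.
// Contact triangles are stored once, oriented outward from AB (normal
// pointing into P1); the P1 body uses them with reversed sense.

#include <RcppArmadillo.h>
#include <queue>
#include <map>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::rowvec3 crossr(const arma::rowvec3& a, const arma::rowvec3& b) {
  arma::rowvec3 c;
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
  return c;
}

// ---------------------------------------------------------------------------
// areas / volumes / gradients
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_patch_areas(const arma::mat& V, const arma::imat& F, const arma::ivec& patch) {
  arma::vec A(3, arma::fill::zeros);
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    arma::rowvec3 a = V.row(F(t, 0)), b = V.row(F(t, 1)), c = V.row(F(t, 2));
    A[patch[t] - 1] += 0.5 * arma::norm(crossr(b - a, c - a), 2);
  }
  return A;
}

// Signed divergence-theorem volumes of the two bodies.
// [[Rcpp::export]]
arma::vec cpp_body_volumes(const arma::mat& V, const arma::imat& F, const arma::ivec& patch) {
  double vA = 0.0, vP = 0.0;
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    arma::rowvec3 a = V.row(F(t, 0)), b = V.row(F(t, 1)), c = V.row(F(t, 2));
    double det = arma::dot(a, crossr(b, c)) / 6.0;
    int p = patch[t];
    if (p == 1) vA += det;
    else if (p == 2) vP += det;
    else { vA += det; vP -= det; }
  }
  arma::vec out(2);
  out[0] = vA; out[1] = vP;
  return out;
}

static double energy_and_grad(const arma::mat& V, const arma::imat& F,
                              const arma::ivec& patch, const arma::vec& gamma,
                              arma::mat& G) {
  G.zeros(V.n_rows, 3);
  double E = 0.0;
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    arma::rowvec3 a = V.row(ia), b = V.row(ib), c = V.row(ic);
    arma::rowvec3 N = crossr(b - a, c - a);
    double nn = arma::norm(N, 2);
    if (nn < 1e-300) continue;
    double g = gamma[patch[t] - 1];
    E += 0.5 * g * nn;
    arma::rowvec3 nh = N / nn;
    G.row(ia) += 0.5 * g * crossr(nh, c - b);
    G.row(ib) += 0.5 * g * crossr(nh, a - c);
    G.row(ic) += 0.5 * g * crossr(nh, b - a);
  }
  return E;
}

static void volume_grads(const arma::mat& V, const arma::imat& F, const arma::ivec& patch,
                         arma::mat& GA, arma::mat& GP) {
  GA.zeros(V.n_rows, 3);
  GP.zeros(V.n_rows, 3);
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    arma::rowvec3 a = V.row(ia), b = V.row(ib), c = V.row(ic);
    arma::rowvec3 ga = crossr(b, c) / 6.0, gb = crossr(c, a) / 6.0, gc = crossr(a, b) / 6.0;
    int p = patch[t];
    if (p == 1) { GA.row(ia) += ga; GA.row(ib) += gb; GA.row(ic) += gc; }
    else if (p == 2) { GP.row(ia) += ga; GP.row(ib) += gb; GP.row(ic) += gc; }
    else {
      GA.row(ia) += ga; GA.row(ib) += gb; GA.row(ic) += gc;
      GP.row(ia) -= ga; GP.row(ib) -= gb; GP.row(ic) -= gc;
    }
  }
}

// [[Rcpp::export]]
List cpp_energy_grad(const arma::mat& V, const arma::imat& F, const arma::ivec& patch,
                     const arma::vec& gamma) {
  arma::mat G;
  double E = energy_and_grad(V, F, patch, gamma, G);
  return List::create(_["energy"] = E, _["grad"] = G);
}

// [[Rcpp::export]]
List cpp_volume_grads(const arma::mat& V, const arma::imat& F, const arma::ivec& patch) {
  arma::mat GA, GP;
  volume_grads(V, F, patch, GA, GP);
  return List::create(_["gradAB"] = GA, _["gradP1"] = GP);
}

// ---------------------------------------------------------------------------
// ellipsoid projection (axis-aligned, centered frame)
// ---------------------------------------------------------------------------

// Nearest point on the ellipsoid x^2/s1^2 + y^2/s2^2 + z^2/s3^2 = 1.
// Lagrange condition gives p_i = x_i s_i^2 / (s_i^2 + t); t solves
// f(t) = sum x_i^2 s_i^2 / (s_i^2 + t)^2 = 1 (f is strictly decreasing).
static arma::rowvec3 project_pt(const arma::rowvec3& x, const arma::vec& s) {
  double smin2 = s.min() * s.min();
  double r = arma::norm(x, 2);
  if (r < 1e-12 * s.max()) {            // degenerate center point
    arma::uword k = s.index_min();
    arma::rowvec3 p(arma::fill::zeros);
    p[k] = s[k];
    return p;
  }
  double w2 = 0.0;
  for (int i = 0; i < 3; ++i) w2 += x[i] * x[i] * s[i] * s[i];
  double g = x[0] * x[0] / (s[0] * s[0]) + x[1] * x[1] / (s[1] * s[1]) + x[2] * x[2] / (s[2] * s[2]);
  double lo, hi;
  if (g >= 1.0) { lo = 0.0; hi = std::sqrt(w2); }      // exterior: t in [0, sqrt(w2)]
  else { lo = -smin2; hi = 0.0; }                       // interior
  // hybrid Newton / bisection
  double t = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double f = 0.0, fp = 0.0;
    for (int i = 0; i < 3; ++i) {
      double d = s[i] * s[i] + t;
      if (d <= 0) { f = 1e30; fp = -1e30; break; }
      double q = x[i] * s[i] / d;
      f += q * q;                          // x_i^2 s_i^2 / d^2
      fp += -2.0 * x[i] * x[i] * s[i] * s[i] / (d * d * d);
    }
    double resid = f - 1.0;
    if (std::fabs(resid) < 1e-13) break;
    if (resid > 0) lo = t; else hi = t;
    double tn = t - resid / fp;
    t = (tn > lo && tn < hi) ? tn : 0.5 * (lo + hi);
  }
  arma::rowvec3 p;
  for (int i = 0; i < 3; ++i) p[i] = x[i] * s[i] * s[i] / (s[i] * s[i] + t);
  return p;
}

// [[Rcpp::export]]
arma::mat cpp_project_ellipsoid(const arma::mat& X, const arma::vec& axes) {
  arma::mat P(X.n_rows, 3);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    P.row(i) = project_pt(X.row(i), axes);
  return P;
}

static inline double ell_implicit(const arma::rowvec3& x, const arma::vec& s) {
  return x[0] * x[0] / (s[0] * s[0]) + x[1] * x[1] / (s[1] * s[1]) + x[2] * x[2] / (s[2] * s[2]);
}

// clamp vertices outside the ellipsoid back onto its surface; returns #clamped
static int clamp_outside(arma::mat& V, const arma::vec& s) {
  int n = 0;
  for (arma::uword i = 0; i < V.n_rows; ++i) {
    arma::rowvec3 x = V.row(i);
    if (ell_implicit(x, s) > 1.0 + 1e-12) {
      V.row(i) = project_pt(x, s);
      ++n;
    }
  }
  return n;
}

// ---------------------------------------------------------------------------
// volume restoration (projected constraint): Newton on the two multipliers
// ---------------------------------------------------------------------------

static bool restore_volumes(arma::mat& V, const arma::imat& F, const arma::ivec& patch,
                            double VAt, double VPt, bool hasP1,
                            const arma::vec* axes, double cap, int maxit) {
  arma::mat GA, GP;
  for (int it = 0; it < maxit; ++it) {
    arma::vec vol = cpp_body_volumes(V, F, patch);
    double rA = VAt - vol[0];
    double rP = hasP1 ? (VPt - vol[1]) : 0.0;
    double rel = std::fabs(rA) / VAt + (hasP1 ? std::fabs(rP) / VPt : 0.0);
    if (rel < 1e-11) return true;
    volume_grads(V, F, patch, GA, GP);
    if (axes) {
      // shell-pressed vertices stay put: correcting through them only
      // fights the clamp; route the correction through free vertices
      int nfree = 0;
      for (arma::uword i = 0; i < V.n_rows; ++i) {
        if (ell_implicit(V.row(i), *axes) > 1.0 - 1e-9) {
          GA.row(i).zeros();
          GP.row(i).zeros();
        } else ++nfree;
      }
      if (nfree < 4) volume_grads(V, F, patch, GA, GP);  // fallback
    }
    double lamA, lamP = 0.0;
    if (hasP1) {
      double aa = arma::accu(GA % GA), ap = arma::accu(GA % GP), pp = arma::accu(GP % GP);
      double det = aa * pp - ap * ap;
      if (std::fabs(det) < 1e-30) return false;
      lamA = (pp * rA - ap * rP) / det;
      lamP = (aa * rP - ap * rA) / det;
    } else {
      double aa = arma::accu(GA % GA);
      if (aa < 1e-30) return false;
      lamA = rA / aa;
    }
    arma::mat disp = lamA * GA + (hasP1 ? lamP * GP : arma::mat(V.n_rows, 3, arma::fill::zeros));
    double mx = std::sqrt(arma::max(arma::sum(disp % disp, 1)));
    if (mx > cap) disp *= cap / mx;
    V += disp;
    if (axes) clamp_outside(V, *axes);
  }
  arma::vec vol = cpp_body_volumes(V, F, patch);
  double rel = std::fabs(VAt - vol[0]) / VAt + (hasP1 ? std::fabs(VPt - vol[1]) / VPt : 0.0);
  return rel < 1e-6;
}

// [[Rcpp::export]]
List cpp_restore_volumes(arma::mat V, const arma::imat& F, const arma::ivec& patch,
                         double VAt, double VPt, bool hasP1,
                         Nullable<NumericVector> axes_, double cap, int maxit) {
  arma::vec ax;
  const arma::vec* axp = nullptr;
  if (axes_.isNotNull()) { ax = as<arma::vec>(axes_.get()); axp = &ax; }
  bool ok = restore_volumes(V, F, patch, VAt, VPt, hasP1, axp, cap, maxit);
  return List::create(_["vertices"] = V, _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// least-squares pressure multipliers over shell-free vertices
// ---------------------------------------------------------------------------

// Least-squares multipliers of grad E = pA grad V_AB + pP grad V_P1.
// Vertices pressed against the shell also carry an unknown normal
// reaction; their rows are projected onto the shell tangent plane so
// they contribute only the reaction-free tangential balance.
static arma::vec pressures_ls(const arma::mat& V, const arma::imat& F, const arma::ivec& patch,
                              const arma::vec& gamma, bool hasP1, const arma::vec* axes) {
  arma::mat G, GA, GP;
  energy_and_grad(V, F, patch, gamma, G);
  volume_grads(V, F, patch, GA, GP);
  double aa = 0, ap = 0, pp = 0, ae = 0, pe = 0;
  for (arma::uword i = 0; i < V.n_rows; ++i) {
    arma::rowvec3 g = G.row(i), ga = GA.row(i), gp = GP.row(i);
    if (axes && ell_implicit(V.row(i), *axes) > 1.0 - 1e-3) {
      arma::rowvec3 nrm;
      for (int k = 0; k < 3; ++k) nrm[k] = 2.0 * V(i, k) / ((*axes)[k] * (*axes)[k]);
      double nn = arma::norm(nrm, 2);
      if (nn > 0) {
        nrm /= nn;
        g -= arma::dot(g, nrm) * nrm;
        ga -= arma::dot(ga, nrm) * nrm;
        gp -= arma::dot(gp, nrm) * nrm;
      }
    }
    aa += arma::dot(ga, ga);
    ap += arma::dot(ga, gp);
    pp += arma::dot(gp, gp);
    ae += arma::dot(ga, g);
    pe += arma::dot(gp, g);
  }
  arma::vec out(2);
  if (hasP1) {
    double det = aa * pp - ap * ap;
    out[0] = (pp * ae - ap * pe) / det;
    out[1] = (aa * pe - ap * ae) / det;
  } else {
    out[0] = ae / aa;
    out[1] = NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_pressures(const arma::mat& V, const arma::imat& F, const arma::ivec& patch,
                        const arma::vec& gamma, bool hasP1, Nullable<NumericVector> axes_) {
  arma::vec ax;
  const arma::vec* axp = nullptr;
  if (axes_.isNotNull()) { ax = as<arma::vec>(axes_.get()); axp = &ax; }
  return pressures_ls(V, F, patch, gamma, hasP1, axp);
}

// ---------------------------------------------------------------------------
// projected-gradient minimizer with backtracking line search
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_minimize(arma::mat V, const arma::imat& F, const arma::ivec& patch,
                  const arma::vec& gamma, double VAt, double VPt, bool hasP1,
                  Nullable<NumericVector> axes_, int maxit, double tolE, int window,
                  double stepFrac) {
  arma::vec ax;
  const arma::vec* axes = nullptr;
  if (axes_.isNotNull()) { ax = as<arma::vec>(axes_.get()); axes = &ax; }

  // mean edge length sets the displacement scale
  double h = 0.0;
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    h += arma::norm(V.row(F(t, 0)) - V.row(F(t, 1)), 2);
    h += arma::norm(V.row(F(t, 1)) - V.row(F(t, 2)), 2);
    h += arma::norm(V.row(F(t, 2)) - V.row(F(t, 0)), 2);
  }
  h /= (3.0 * F.n_rows);

  if (axes) clamp_outside(V, *axes);
  restore_volumes(V, F, patch, VAt, VPt, hasP1, axes, 0.5 * h, 400);

  arma::mat G;
  double E = energy_and_grad(V, F, patch, gamma, G);
  std::vector<double> hist;
  hist.reserve(maxit + 1);
  hist.push_back(E);
  double eta = -1.0;
  int fails = 0, accepted = 0;
  bool converged = false;

  arma::mat GA, GP;
  for (int it = 0; it < maxit; ++it) {
    // project the gradient onto the volume-constraint tangent space:
    // d = -(grad E - pA grad V_AB - pP grad V_P1) with least-squares
    // multipliers, so steps are not immediately undone by the volume
    // restoration
    volume_grads(V, F, patch, GA, GP);
    arma::mat d = -G;
    {
      double aa = arma::accu(GA % GA), pp = arma::accu(GP % GP);
      if (hasP1) {
        double ap = arma::accu(GA % GP);
        double ae = arma::accu(GA % G), pe = arma::accu(GP % G);
        double det = aa * pp - ap * ap;
        if (std::fabs(det) > 1e-30) {
          double pA = (pp * ae - ap * pe) / det;
          double pP = (aa * pe - ap * ae) / det;
          d = -(G - pA * GA - pP * GP);
        }
      } else if (aa > 1e-30) {
        d = -(G - (arma::accu(GA % G) / aa) * GA);
      }
    }
    if (axes) {
      // active one-sided constraint: strip the outward normal component
      for (arma::uword i = 0; i < V.n_rows; ++i) {
        arma::rowvec3 x = V.row(i);
        if (ell_implicit(x, *axes) > 1.0 - 1e-6) {
          arma::rowvec3 nrm;
          for (int k = 0; k < 3; ++k) nrm[k] = 2.0 * x[k] / ((*axes)[k] * (*axes)[k]);
          double nn = arma::norm(nrm, 2);
          if (nn > 0) {
            nrm /= nn;
            double dn = arma::dot(d.row(i), nrm);
            if (dn > 0) d.row(i) -= dn * nrm;
          }
        }
      }
    }
    double gd = -arma::accu(d % d);          // descent rate along d
    double dmax = std::sqrt(arma::max(arma::sum(d % d, 1)));
    if (dmax < 1e-300) { converged = true; break; }
    double etaMax = stepFrac * h / dmax;
    if (eta < 0 || eta > etaMax) eta = etaMax;
    bool ok = false;
    for (int k = 0; k < 40; ++k) {
      arma::mat Vt = V + eta * d;
      if (axes) clamp_outside(Vt, *axes);
      if (!restore_volumes(Vt, F, patch, VAt, VPt, hasP1, axes, 0.5 * h, 200)) { eta *= 0.5; continue; }
      double Et = energy_and_grad(Vt, F, patch, gamma, G); // G overwritten; recomputed below on accept
      if (Et <= E + 1e-4 * eta * gd) {
        V = Vt; E = Et; ok = true; ++accepted;
        break;
      }
      eta *= 0.5;
    }
    if (!ok) {
      ++fails;
      E = energy_and_grad(V, F, patch, gamma, G);
      if (fails >= 3) { converged = true; break; }
      eta = -1.0;
      continue;
    }
    fails = 0;
    E = energy_and_grad(V, F, patch, gamma, G); // gradient at accepted iterate
    hist.push_back(E);
    eta = std::min(2.0 * eta, etaMax);
    int nh = hist.size();
    if (nh > window) {
      double drop = hist[nh - 1 - window] - hist[nh - 1];
      if (drop < tolE * std::fabs(hist[nh - 1])) { converged = true; break; }
    }
  }

  arma::vec vol = cpp_body_volumes(V, F, patch);
  arma::vec P = pressures_ls(V, F, patch, gamma, hasP1, axes);
  int nactive = 0;
  if (axes)
    for (arma::uword i = 0; i < V.n_rows; ++i)
      if (ell_implicit(V.row(i), *axes) > 1.0 - 1e-6) ++nactive;

  return List::create(_["vertices"] = V, _["energy"] = E,
                      _["volumes"] = vol, _["pressures"] = P,
                      _["iterations"] = accepted, _["converged"] = converged,
                      _["nActive"] = nactive,
                      _["energyTrace"] = NumericVector(hist.begin(), hist.end()));
}

// ---------------------------------------------------------------------------
// mesh quality: tangential smoothing and equiangulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_smooth(arma::mat V, const arma::imat& F, const arma::ivec& patch,
                     Nullable<NumericVector> axes_, double omega, int npass) {
  arma::vec ax;
  const arma::vec* axes = nullptr;
  if (axes_.isNotNull()) { ax = as<arma::vec>(axes_.get()); axes = &ax; }
  int n = V.n_rows;
  // vertex patch incidence and neighbours
  std::vector<std::set<int>> vpatch(n);
  std::vector<std::set<int>> nbr(n);
  std::map<std::pair<int,int>, std::set<int>> edgePatch;
  for (arma::uword t = 0; t < F.n_rows; ++t) {
    int idx[3] = {(int)F(t,0), (int)F(t,1), (int)F(t,2)};
    for (int k = 0; k < 3; ++k) {
      vpatch[idx[k]].insert(patch[t]);
      int a = idx[k], b = idx[(k+1)%3];
      nbr[a].insert(b); nbr[b].insert(a);
      std::pair<int,int> key(std::min(a, b), std::max(a, b));
      edgePatch[key].insert(patch[t]);
    }
  }
  // triple-line neighbours: edges whose incident triangles span >= 2 patches
  std::vector<std::vector<int>> tnbr(n);
  for (auto& kv : edgePatch) {
    if (kv.second.size() >= 2) {
      tnbr[kv.first.first].push_back(kv.first.second);
      tnbr[kv.first.second].push_back(kv.first.first);
    }
  }
  for (int pass = 0; pass < npass; ++pass) {
    // vertex normals from stored orientation
    arma::mat N(n, 3, arma::fill::zeros);
    for (arma::uword t = 0; t < F.n_rows; ++t) {
      arma::rowvec3 a = V.row(F(t,0)), b = V.row(F(t,1)), c = V.row(F(t,2));
      arma::rowvec3 tn = crossr(b - a, c - a);
      N.row(F(t,0)) += tn; N.row(F(t,1)) += tn; N.row(F(t,2)) += tn;
    }
    arma::mat Vnew = V;
    for (int i = 0; i < n; ++i) {
      bool onTriple = vpatch[i].size() >= 2;
      if (onTriple) {
        if (tnbr[i].size() != 2) continue;      // junction or defect: leave in place
        arma::rowvec3 p = 0.5 * (V.row(tnbr[i][0]) + V.row(tnbr[i][1]));
        arma::rowvec3 tang = V.row(tnbr[i][1]) - V.row(tnbr[i][0]);
        double tl = arma::norm(tang, 2);
        if (tl < 1e-300) continue;
        tang /= tl;
        arma::rowvec3 d = p - V.row(i);
        Vnew.row(i) = V.row(i) + omega * arma::dot(d, tang) * tang;
      } else {
        if (nbr[i].empty()) continue;
        arma::rowvec3 cen(arma::fill::zeros);
        for (int j : nbr[i]) cen += V.row(j);
        cen /= (double)nbr[i].size();
        arma::rowvec3 d = cen - V.row(i);
        arma::rowvec3 nh = N.row(i);
        double nn = arma::norm(nh, 2);
        if (nn > 0) { nh /= nn; d -= arma::dot(d, nh) * nh; }
        Vnew.row(i) = V.row(i) + omega * d;
      }
      if (axes) {
        bool wasActive = ell_implicit(V.row(i), *axes) > 1.0 - 1e-6;
        arma::rowvec3 x = Vnew.row(i);
        if (wasActive || ell_implicit(x, *axes) > 1.0 + 1e-12)
          Vnew.row(i) = project_pt(x, *axes);
      }
    }
    V = Vnew;
  }
  return V;
}

static inline double tri_min_angle(const arma::rowvec3& a, const arma::rowvec3& b,
                                   const arma::rowvec3& c) {
  double la = arma::norm(b - c, 2), lb = arma::norm(a - c, 2), lc = arma::norm(a - b, 2);
  double A2 = arma::norm(crossr(b - a, c - a), 2);
  if (la * lb * lc < 1e-300) return 0.0;
  double sa = A2 / (lb * lc), sb = A2 / (la * lc), sc = A2 / (la * lb);
  double s = std::min(1.0, std::min(sa, std::min(sb, sc)));
  return std::asin(std::max(0.0, s));
}

// Same-patch interior edge flips that improve the local minimum angle.
// Patch-boundary (triple line) edges are never flipped.
// [[Rcpp::export]]
List cpp_equiangulate(const arma::mat& V, arma::imat F, arma::ivec patch, int maxpass) {
  int nflip_total = 0;
  for (int pass = 0; pass < maxpass; ++pass) {
    std::map<std::pair<int,int>, std::vector<int>> etri;
    std::set<std::pair<int,int>> edges;
    for (arma::uword t = 0; t < F.n_rows; ++t)
      for (int k = 0; k < 3; ++k) {
        int u = F(t,k), w = F(t,(k+1)%3);
        std::pair<int,int> key(std::min(u, w), std::max(u, w));
        etri[key].push_back(t);
        edges.insert(key);
      }
    int nflip = 0;
    std::set<int> touched;
    for (auto& kv : etri) {
      if (kv.second.size() != 2) continue;
      int t1 = kv.second[0], t2 = kv.second[1];
      if (patch[t1] != patch[t2]) continue;
      if (touched.count(t1) || touched.count(t2)) continue;
      int a = kv.first.first, b = kv.first.second;
      auto opp = [&](int t) {
        for (int k = 0; k < 3; ++k) {
          int v = F(t,k);
          if (v != a && v != b) return v;
        }
        return -1;
      };
      int c = opp(t1), d = opp(t2);
      if (c < 0 || d < 0 || c == d) continue;
      std::pair<int,int> keycd(std::min(c, d), std::max(c, d));
      if (edges.count(keycd)) continue;  // flipped edge already exists
      arma::rowvec3 pa = V.row(a), pb = V.row(b), pc = V.row(c), pd = V.row(d);
      double before = std::min(tri_min_angle(pa, pb, pc), tri_min_angle(pa, pb, pd));
      double after  = std::min(tri_min_angle(pa, pd, pc), tri_min_angle(pd, pb, pc));
      double a1 = arma::norm(crossr(pd - pa, pc - pa), 2);
      double a2 = arma::norm(crossr(pb - pd, pc - pd), 2);
      if (after > before + 1e-10 && a1 > 1e-12 && a2 > 1e-12) {
        // consistent orientation: one triangle traverses a->b, the other b->a.
        // Arrange so that t1 traverses a->b (swap a,b if needed), then
        // (a,b,c) + (b,a,d) flips to (a,d,c) + (d,b,c).
        bool t1_ab = false;
        for (int k = 0; k < 3; ++k)
          if (F(t1,k) == a && F(t1,(k+1)%3) == b) t1_ab = true;
        if (!t1_ab) std::swap(a, b);
        F(t1,0) = a; F(t1,1) = d; F(t1,2) = c;
        F(t2,0) = d; F(t2,1) = b; F(t2,2) = c;
        touched.insert(t1); touched.insert(t2);
        ++nflip;
      }
    }
    nflip_total += nflip;
    if (nflip == 0) break;
  }
  return List::create(_["triangles"] = F, _["patch"] = patch, _["nflips"] = nflip_total);
}

// ---------------------------------------------------------------------------
// closedness / orientation check: directed edges of a body's bounding set
// must each appear exactly once, undirected edges exactly twice
// [[Rcpp::export]]
LogicalVector cpp_check_closed(const arma::imat& F) {
  std::map<std::pair<int,int>, int> dir;
  for (arma::uword t = 0; t < F.n_rows; ++t)
    for (int k = 0; k < 3; ++k) {
      int a = F(t,k), b = F(t,(k+1)%3);
      dir[{a,b}]++;
    }
  bool closed = true, oriented = true;
  for (auto& kv : dir) {
    if (kv.second != 1) oriented = false;
    auto rev = dir.find({kv.first.second, kv.first.first});
    if (rev == dir.end()) closed = false;
  }
  return LogicalVector::create(_["closed"] = closed, _["oriented"] = oriented && closed);
}

// ---------------------------------------------------------------------------
// marker-based 3D watershed (Meyer flooding), 6-connectivity
// labels: >0 marker regions, -1 watershed line
// ---------------------------------------------------------------------------

struct QE {
  double val;
  long order;
  long idx;
};
struct QEcmp {
  bool operator()(const QE& a, const QE& b) const {
    if (a.val != b.val) return a.val > b.val;   // min-heap on value
    return a.order > b.order;                   // FIFO tie-break
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(IntegerVector dims, NumericVector img,
                            IntegerVector markerIdx, IntegerVector markerLab) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::priority_queue<QE, std::vector<QE>, QEcmp> pq;
  long order = 0;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  auto push_nbrs = [&](long idx) {
    long rem = idx;
    int x = rem % nx; rem /= nx;
    int y = rem % ny; rem /= ny;
    int z = rem;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      long j = (long)xx + nx * ((long)yy + (long)ny * zz);
      if (lab[j] == 0) pq.push({img[j], order++, j});
    }
  };
  for (int i = 0; i < markerIdx.size(); ++i) {
    long idx = markerIdx[i];
    lab[idx] = markerLab[i];
  }
  for (int i = 0; i < markerIdx.size(); ++i) push_nbrs(markerIdx[i]);
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    long idx = e.idx;
    if (lab[idx] != 0) continue;
    long rem = idx;
    int x = rem % nx; rem /= nx;
    int y = rem % ny; rem /= ny;
    int z = rem;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      long j = (long)xx + nx * ((long)yy + (long)ny * zz);
      if (lab[j] > 0) {
        if (found == 0) found = lab[j];
        else if (lab[j] != found) conflict = true;
      }
    }
    if (conflict) lab[idx] = -1;
    else if (found > 0) {
      lab[idx] = found;
      push_nbrs(idx);
    }
  }
  for (long i = 0; i < n; ++i) if (lab[i] == 0) lab[i] = -1;
  return IntegerVector(lab.begin(), lab.end());
}

// ---------------------------------------------------------------------------
// brute-force nearest neighbours (query rows -> nearest ref row)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nn(const arma::mat& query, const arma::mat& ref) {
  arma::uword nq = query.n_rows, nr = ref.n_rows;
  arma::ivec idx(nq);
  arma::vec d2(nq);
  for (arma::uword i = 0; i < nq; ++i) {
    double best = arma::datum::inf;
    arma::uword bj = 0;
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    for (arma::uword j = 0; j < nr; ++j) {
      double a = qx - ref(j,0), b = qy - ref(j,1), c = qz - ref(j,2);
      double dd = a*a + b*b + c*c;
      if (dd < best) { best = dd; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist"] = arma::sqrt(d2));
}

// ---------------------------------------------------------------------------
// ray-casting point-in-closed-mesh test (ray along a fixed skew direction)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_points_inside(const arma::mat& V, const arma::imat& F,
                                const arma::mat& pts) {
  arma::rowvec3 dir;
  dir[0] = 1.23e-4; dir[1] = 2.17e-4; dir[2] = 1.0;   // fixed skew ray dodges edges
  dir /= arma::norm(dir, 2);
  arma::uword np = pts.n_rows, nt = F.n_rows;
  LogicalVector inside(np);
  // precompute triangle data
  arma::mat A(nt,3), E1(nt,3), E2(nt,3);
  for (arma::uword t = 0; t < nt; ++t) {
    A.row(t) = V.row(F(t,0));
    E1.row(t) = V.row(F(t,1)) - V.row(F(t,0));
    E2.row(t) = V.row(F(t,2)) - V.row(F(t,0));
  }
  for (arma::uword i = 0; i < np; ++i) {
    arma::rowvec3 o = pts.row(i);
    int cross = 0;
    for (arma::uword t = 0; t < nt; ++t) {
      arma::rowvec3 e1 = E1.row(t), e2 = E2.row(t);
      arma::rowvec3 pvec = crossr(dir, e2);
      double det = arma::dot(e1, pvec);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      arma::rowvec3 tvec = o - A.row(t);
      double u = arma::dot(tvec, pvec) * inv;
      if (u < 0.0 || u > 1.0) continue;
      arma::rowvec3 qvec = crossr(tvec, e1);
      double v = arma::dot(dir, qvec) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double tt = arma::dot(e2, qvec) * inv;
      if (tt > 0.0) ++cross;
    }
    inside[i] = (cross % 2) == 1;
  }
  return inside;
}
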