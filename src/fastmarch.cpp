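// Multifront fast-marching engine on anisotropic triangular surface meshes.
//
// The eikonal equation  c * sqrt(grad(t)' G grad(t)) = 1  with
// G = k f f' + (I - f f')  (k >= 1, f = unit fiber direction) is equivalent
// to front propagation under the Riemannian metric M = G^{-1} / c^2: the
// travel time of a straight segment v inside a triangle is
//   tau(v) = sqrt(v'v - (1 - 1/k) (f.v)^2) / c .
// The solver performs the classical two-point within-triangle update
// (linear interpolation of the arrival time along the known edge, exact
// minimisation over the interpolation parameter) with a one-point edge
// fallback, on a priority-ordered narrow band.
//
// The same engine runs in two modes:
//  * static: every node activates once (activation map, predecessors,
//    activation vectors, front ids);
//  * dynamic: nodes re-activate subject to ERP(BCL) restitution; refractory
//    arrivals are deferred to last_activation + ERP and only survive if the
//    driving node is still within its source-viability window (a proxy for
//    the limited time an eikonal front can drive a blocked neighbour).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Ev {
  double t;
  int node;
  int pred;
  int fid;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.node > b.node; // lowest node index wins on ties
  }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// exponential restitution value A - B exp(-bcl/C), bcl clamped to range
inline double resti(double A, double B, double C, double bcl,
                    double lo, double hi) {
  bcl = clampd(bcl, lo, hi);
  return A - B * std::exp(-bcl / C);
}

// anisotropic squared length under G^{-1}: |v|^2 - kk (f.v)^2, kk = 1 - 1/k
inline double m2(const double* v, const double* f, double kk) {
  double fv = f[0] * v[0] + f[1] * v[1] + f[2] * v[2];
  double vv = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  double q = vv - kk * fv * fv;
  return q > 0 ? q : 0.0;
}
inline double mdot(const double* p, const double* q, const double* f,
                   double kk) {
  double fp = f[0] * p[0] + f[1] * p[1] + f[2] * p[2];
  double fq = f[0] * q[0] + f[1] * q[1] + f[2] * q[2];
  return p[0] * q[0] + p[1] * q[1] + p[2] * q[2] - kk * fp * fq;
}

// Two-point update: known vertices A (time TA) and B (time TB), target X,
// speed c (mm/ms), metric (f, kk). Returns arrival time; lam in [0,1]
// (1 = arrival from A) via out-parameter.
double tri_update(double TA, double TB, const double* A, const double* B,
                  const double* X, const double* f, double kk, double c,
                  double& lam) {
  double u[3] = {A[0] - B[0], A[1] - B[1], A[2] - B[2]};
  double w[3] = {X[0] - B[0], X[1] - B[1], X[2] - B[2]};
  double xa[3] = {X[0] - A[0], X[1] - A[1], X[2] - A[2]};
  double a = m2(u, f, kk);
  double b = mdot(u, w, f, kk);
  double d = m2(w, f, kk);
  double tA = TA + std::sqrt(m2(xa, f, kk)) / c; // lam = 1
  double tB = TB + std::sqrt(d) / c;             // lam = 0
  double best;
  if (tA <= tB) { best = tA; lam = 1.0; } else { best = tB; lam = 0.0; }
  if (a <= 1e-300) return best;
  double D = TA - TB;
  double D2 = D * D * c * c;
  // stationarity: a*l - b = -D*c*sqrt(q(l)), q(l) = a l^2 - 2 b l + d
  double alpha = a * (a - D2);
  double beta = -2.0 * b * (a - D2);
  double gamma = b * b - D2 * d;
  double roots[2];
  int nr = 0;
  if (std::fabs(alpha) < 1e-14 * a * a) {
    if (std::fabs(beta) > 1e-300) roots[nr++] = -gamma / beta;
  } else {
    double disc = beta * beta - 4.0 * alpha * gamma;
    if (disc >= 0) {
      double sq = std::sqrt(disc);
      roots[nr++] = (-beta + sq) / (2.0 * alpha);
      roots[nr++] = (-beta - sq) / (2.0 * alpha);
    }
  }
  for (int r = 0; r < nr; ++r) {
    double l = roots[r];
    if (l <= 0.0 || l >= 1.0) continue;
    double q = a * l * l - 2.0 * b * l + d;
    if (q <= 0) continue;
    if ((a * l - b) * D > 0) continue; // wrong branch
    double t = TB + l * D + std::sqrt(q) / c;
    if (t < best) { best = t; lam = l; }
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
List fm_engine_cpp(NumericMatrix P, IntegerMatrix TRI, NumericMatrix FIB,
                   NumericVector ktri, LogicalVector cond,
                   IntegerVector regtri, NumericMatrix cvp, NumericMatrix erpp,
                   bool use_erp, double bclmin, double bclmax,
                   NumericVector init_last, LogicalVector has_init,
                   NumericVector init_bcl, IntegerVector stim_nodes,
                   NumericVector stim_times, IntegerVector stim_fid,
                   IntegerVector seed_nodes, double duration, bool dynamic,
                   double source_window, bool record_events,
                   double max_events) {
  const int nN = P.nrow(), nT = TRI.nrow();
  // node -> incident triangles
  std::vector<std::vector<int> > inc(nN);
  for (int t = 0; t < nT; ++t)
    for (int v = 0; v < 3; ++v) inc[TRI(t, v)].push_back(t);

  std::vector<double> last(nN, 0.0);
  std::vector<char> haslast(nN, 0);
  std::vector<int> nact(nN, 0);
  std::vector<double> ta(nN, R_PosInf);
  std::vector<int> pred(nN, -1), fid(nN, -1);
  std::vector<double> besttent(nN, R_PosInf);

  for (int i = 0; i < nN; ++i) {
    if (has_init[i]) { last[i] = init_last[i]; haslast[i] = 1; }
  }

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
  std::vector<int> ev_node;
  std::vector<double> ev_time;
  std::vector<int> ev_fid;
  bool truncated = false;

  const double* Pp = REAL(P);
  auto pos = [&](int i, double* out) {
    out[0] = Pp[i]; out[1] = Pp[i + nN]; out[2] = Pp[i + 2 * nN];
  };

  auto cv_mmms = [&](int reg, double bcl) {
    return resti(cvp(reg, 0), cvp(reg, 1), cvp(reg, 2), bcl, bclmin, bclmax) /
           1000.0;
  };
  auto erp_ms = [&](int reg, double bcl) {
    return resti(erpp(reg, 0), erpp(reg, 1), erpp(reg, 2), bcl, bclmin,
                 bclmax);
  };
  // node region: region of lowest-index incident conductive triangle
  std::vector<int> nreg(nN, 0);
  for (int i = 0; i < nN; ++i) {
    int r = -1;
    for (size_t s = 0; s < inc[i].size(); ++s) {
      int t = inc[i][s];
      if (cond[t]) { r = regtri[t]; break; }
    }
    nreg[i] = r < 0 ? 0 : r;
  }

  // push tentative arrivals for all neighbours of node i activated at time t
  auto push_updates = [&](int i, double t, int fi) {
    double Pi[3]; pos(i, Pi);
    for (size_t s = 0; s < inc[i].size(); ++s) {
      int tr = inc[i][s];
      if (!cond[tr]) continue;
      int a = TRI(tr, 0), b = TRI(tr, 1), cdx = TRI(tr, 2);
      int oth[2];
      if (a == i) { oth[0] = b; oth[1] = cdx; }
      else if (b == i) { oth[0] = a; oth[1] = cdx; }
      else { oth[0] = a; oth[1] = b; }
      double fdir[3] = {FIB(tr, 0), FIB(tr, 1), FIB(tr, 2)};
      double kk = 1.0 - 1.0 / ktri[tr];
      int reg = regtri[tr];
      for (int m = 0; m < 2; ++m) {
        int j = oth[m], o = oth[1 - m];
        if (!dynamic && nact[j] > 0) continue;
        double Pj[3], Po[3];
        pos(j, Pj); pos(o, Po);
        // BCL (and hence CV) of the node being activated
        double bcl_j = (dynamic && haslast[j]) ? (t - last[j]) : init_bcl[j];
        double c = cv_mmms(reg, bcl_j);
        if (c <= 0) continue;
        // companion usable if on the same wavefront pass
        bool ouse;
        double To = 0;
        if (!dynamic) {
          ouse = nact[o] > 0;
          To = ta[o];
        } else {
          ouse = haslast[o] != 0;
          To = last[o];
          if (ouse) {
            double io[3] = {Po[0] - Pi[0], Po[1] - Pi[1], Po[2] - Pi[2]};
            double chord =
                std::sqrt(io[0] * io[0] + io[1] * io[1] + io[2] * io[2]);
            double cslow = cv_mmms(reg, bclmin);
            double win = source_window * chord / std::max(cslow, 1e-9);
            if (t - To > win) ouse = false;
          }
        }
        double lam = 1.0, tj;
        int pj = i;
        if (ouse && To <= t + 1e-12) {
          tj = tri_update(t, To, Pi, Po, Pj, fdir, kk, c, lam);
          pj = (lam >= 0.5) ? i : o;
        } else {
          double v[3] = {Pj[0] - Pi[0], Pj[1] - Pi[1], Pj[2] - Pi[2]};
          tj = t + std::sqrt(m2(v, fdir, kk)) / c;
        }
        if (dynamic && haslast[j]) {
          // refine CV at the self-consistent BCL of the tentative arrival
          double c2 = cv_mmms(reg, tj - last[j]);
          if (std::fabs(c2 - c) > 1e-12 && c2 > 0) {
            if (ouse && To <= t + 1e-12) {
              tj = tri_update(t, To, Pi, Po, Pj, fdir, kk, c2, lam);
              pj = (lam >= 0.5) ? i : o;
            } else {
              double v[3] = {Pj[0] - Pi[0], Pj[1] - Pi[1], Pj[2] - Pi[2]};
              tj = t + std::sqrt(m2(v, fdir, kk)) / c2;
            }
          }
        }
        if (!R_finite(tj)) continue;
        if (tj > duration) continue;
        if (!dynamic) {
          if (tj >= besttent[j] - 1e-15) continue;
          besttent[j] = tj;
        } else {
          if (haslast[j] && tj - last[j] < 1e-9) continue;
        }
        pq.push(Ev{tj, j, pj, fi});
      }
    }
  };

  // initial stimuli
  for (int s = 0; s < stim_nodes.size(); ++s)
    pq.push(Ev{stim_times[s], stim_nodes[s], -1, stim_fid[s]});
  // seeds: nodes considered just-activated at their init_last time
  for (int s = 0; s < seed_nodes.size(); ++s) {
    int i = seed_nodes[s];
    nact[i] = 1;
    ta[i] = last[i];
    push_updates(i, last[i], 0);
  }

  while (!pq.empty()) {
    Ev ev = pq.top();
    pq.pop();
    double t = ev.t;
    int i = ev.node;
    if (t > duration) break;
    if (!dynamic && nact[i] > 0) continue;
    if (dynamic && haslast[i]) {
      double since = t - last[i];
      if (since < 1e-9) continue;
      double erpv = use_erp ? erp_ms(nreg[i], since) : 0.0;
      if (since < erpv - 1e-9) {
        // head-of-line deferral to last + ERP(BCL) fixed point
        double s2 = last[i] + erpv;
        for (int it = 0; it < 50; ++it) {
          double nxt = last[i] + erp_ms(nreg[i], s2 - last[i]);
          if (std::fabs(nxt - s2) < 1e-6) { s2 = nxt; break; }
          s2 = nxt;
        }
        // survive only while the driver can still source the junction
        int p = ev.pred;
        bool viable = false;
        if (p >= 0 && haslast[p]) {
          double Pi[3], Pp2[3];
          pos(i, Pi); pos(p, Pp2);
          double dx = Pi[0] - Pp2[0], dy = Pi[1] - Pp2[1],
                 dz = Pi[2] - Pp2[2];
          double chord = std::sqrt(dx * dx + dy * dy + dz * dz);
          double cslow = cv_mmms(nreg[i], bclmin);
          double win = source_window * chord / std::max(cslow, 1e-9);
          viable = (s2 - last[p]) <= win;
        }
        if (viable && s2 <= duration) pq.push(Ev{s2, i, ev.pred, ev.fid});
        continue;
      }
    }
    // activate
    if (nact[i] == 0) {
      ta[i] = t;
      pred[i] = ev.pred;
      fid[i] = ev.fid;
    }
    if (dynamic) {
      last[i] = t;
      haslast[i] = 1;
    } else {
      ta[i] = t;
      pred[i] = ev.pred;
      fid[i] = ev.fid;
    }
    nact[i]++;
    if (record_events) {
      ev_node.push_back(i + 1);
      ev_time.push_back(t);
      ev_fid.push_back(ev.fid);
      if ((double)ev_node.size() >= max_events) { truncated = true; break; }
    }
    push_updates(i, t, ev.fid);
  }

  return List::create(
      _["ta"] = NumericVector(ta.begin(), ta.end()),
      _["pred"] = IntegerVector(pred.begin(), pred.end()),
      _["front_id"] = IntegerVector(fid.begin(), fid.end()),
      _["n_act"] = IntegerVector(nact.begin(), nact.end()),
      _["last"] = NumericVector(last.begin(), last.end()),
      _["event_node"] = IntegerVector(ev_node.begin(), ev_node.end()),
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["event_front"] = IntegerVector(ev_fid.begin(), ev_fid.end()),
      _["truncated"] = truncated);
}

// Gauss-Seidel circular-mean relaxation of a phase field anchored on loop
// nodes (Dirichlet). Adjacency in CSR form (0-based). Sweeps run in
// breadth-first order from the anchors; initial values are the phase of the
// nearest anchor. Returns the per-sweep maximum circular update trace.
// [[Rcpp::export]]
List phase_relax_cpp(IntegerVector adj_off, IntegerVector adj_idx,
                     IntegerVector anchor_idx, NumericVector anchor_phase,
                     double tol, int maxit) {
  const int n = adj_off.size() - 1;
  const double TWOPI = 2.0 * M_PI;
  std::vector<double> phi(n, 0.0);
  std::vector<char> fixed(n, 0), seen(n, 0);
  std::vector<int> order;
  order.reserve(n);
  std::queue<int> bfs;
  for (int s = 0; s < anchor_idx.size(); ++s) {
    int i = anchor_idx[s];
    phi[i] = anchor_phase[s];
    fixed[i] = 1;
    if (!seen[i]) { seen[i] = 1; bfs.push(i); }
  }
  while (!bfs.empty()) {
    int i = bfs.front();
    bfs.pop();
    if (!fixed[i]) order.push_back(i);
    for (int s = adj_off[i]; s < adj_off[i + 1]; ++s) {
      int j = adj_idx[s];
      if (!seen[j]) {
        seen[j] = 1;
        phi[j] = phi[i]; // nearest-anchor initialisation via BFS tree
        bfs.push(j);
      }
    }
  }
  std::vector<double> trace;
  bool conv = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double mx = 0.0;
    for (size_t s = 0; s < order.size(); ++s) {
      int i = order[s];
      double S = 0, C = 0;
      int deg = 0;
      for (int e = adj_off[i]; e < adj_off[i + 1]; ++e) {
        int j = adj_idx[e];
        S += std::sin(phi[j]);
        C += std::cos(phi[j]);
        ++deg;
      }
      if (deg == 0) continue;
      if (S * S + C * C < 1e-24) continue; // undefined mean, keep value
      double nw = std::atan2(S, C);
      if (nw < 0) nw += TWOPI;
      double d = std::fabs(nw - phi[i]);
      if (d > M_PI) d = TWOPI - d;
      if (d > mx) mx = d;
      phi[i] = nw;
    }
    trace.push_back(mx);
    if (mx < tol) { conv = true; ++it; break; }
  }
  for (int i = 0; i < n; ++i) {
    phi[i] -= TWOPI * std::floor(phi[i] / TWOPI);
    if (phi[i] >= TWOPI) phi[i] = 0.0;
  }
  return List::create(_["phase"] = NumericVector(phi.begin(), phi.end()),
                      _["iterations"] = it,
                      _["converged"] = conv,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
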