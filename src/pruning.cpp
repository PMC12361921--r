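#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// P(t) = U diag(exp(ev * t)) Uinv for a reversible Q, column-major 4x4.
static inline void pmat4(const double* U, const double* ev, const double* Uinv,
                         double tr, double* P) {
  double E[4];
  for (int k = 0; k < 4; ++k) E[k] = std::exp(ev[k] * tr);
  for (int j = 0; j < 4; ++j)
    for (int i = 0; i < 4; ++i) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += U[i + 4 * k] * E[k] * Uinv[k + 4 * j];
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
}

// Felsenstein pruning over a postorder edge list with per-node rescaling.
//
// edge: (E x 2) postorder edge matrix, 1-based ape numbering (tips 1..ntip,
//   root ntip+1).  len: branch lengths per edge row.  tipp: tip partial
//   indicators, dim (4, P, ntip).  U/ev/Uinv: eigen system of Q.  rates,
//   catw: discrete-gamma category rates and weights.  freqs: stationary
//   frequencies.  patw: pattern weights.  want: edge row indices (1-based)
//   for which the edge environment (partials on both sides of the edge,
//   excluding the edge's own P matrix) is returned, so R code can cheaply
//   re-evaluate the likelihood as a function of that edge's length.
//
// Returns list(loglik, and for each wanted edge: ux/uxs (parent-side
// partial and its log-scaler) and dn/dns (child-side)).
// [[Rcpp::export]]
List prune_env(IntegerMatrix edge, int ntip, NumericVector len,
               NumericVector tipp, NumericMatrix U, NumericVector ev,
               NumericMatrix Uinv, NumericVector rates, NumericVector catw,
               NumericVector freqs, NumericVector patw, IntegerVector want,
               bool arrays = false) {
  const int E = edge.nrow();
  const int P = patw.size();
  const int K = rates.size();
  const int nint = E + 1 - ntip;          // internal nodes
  const int root = ntip + 1;
  const bool env = want.size() > 0 || arrays;
  const double* pU = U.begin();
  const double* pEv = ev.begin();
  const double* pUi = Uinv.begin();
  const size_t blk = (size_t)4 * P * K;    // one node's partial block

  std::vector<double> down(blk * nint);
  std::vector<double> dscale((size_t)P * nint, 0.0);
  std::vector<double> z;                   // per-edge child contribution
  if (env) z.resize(blk * E);
  std::vector<int> remaining(nint, 0), touched(nint, 0);
  std::vector<std::vector<int> > childedges(nint);
  for (int e = 0; e < E; ++e) {
    int u = edge(e, 0) - root;             // internal index of parent
    remaining[u]++;
    childedges[u].push_back(e);
  }

  std::vector<double> Pk((size_t)16 * K), tmp(blk);

  for (int e = 0; e < E; ++e) {
    const int u = edge(e, 0) - root;
    const int v = edge(e, 1);
    for (int k = 0; k < K; ++k)
      pmat4(pU, pEv, pUi, len[e] * rates[k], &Pk[16 * k]);
    const bool vtip = v <= ntip;
    const double* dv = vtip ? &tipp[(size_t)4 * P * (v - 1)]
                            : &down[blk * (v - root)];
    // tmp = P_e %*% down[v]  (per category)
    for (int k = 0; k < K; ++k) {
      const double* Pm = &Pk[16 * k];
      const double* src = vtip ? dv : dv + (size_t)4 * P * k;
      double* out = &tmp[(size_t)4 * P * k];
      for (int p = 0; p < P; ++p) {
        const double* s = src + 4 * p;
        double* o = out + 4 * p;
        for (int i = 0; i < 4; ++i)
          o[i] = Pm[i] * s[0] + Pm[i + 4] * s[1] + Pm[i + 8] * s[2] +
                 Pm[i + 12] * s[3];
      }
    }
    if (env) std::copy(tmp.begin(), tmp.end(), z.begin() + blk * e);
    double* du = &down[blk * u];
    if (!touched[u]) {
      std::copy(tmp.begin(), tmp.end(), du);
      touched[u] = 1;
    } else {
      for (size_t i = 0; i < blk; ++i) du[i] *= tmp[i];
    }
    if (!vtip) {
      const double* sv = &dscale[(size_t)P * (v - root)];
      double* su = &dscale[(size_t)P * u];
      for (int p = 0; p < P; ++p) su[p] += sv[p];
    }
    if (--remaining[u] == 0) {
      // rescale node u per pattern to prevent underflow
      double* su = &dscale[(size_t)P * u];
      for (int p = 0; p < P; ++p) {
        double m = 0.0;
        for (int k = 0; k < K; ++k) {
          const double* o = du + (size_t)4 * P * k + 4 * p;
          for (int i = 0; i < 4; ++i) if (o[i] > m) m = o[i];
        }
        if (m > 0.0 && m != 1.0) {
          const double inv = 1.0 / m;
          for (int k = 0; k < K; ++k) {
            double* o = du + (size_t)4 * P * k + 4 * p;
            for (int i = 0; i < 4; ++i) o[i] *= inv;
          }
          su[p] += std::log(m);
        }
      }
    }
  }

  // log-likelihood at the root
  double ll = 0.0;
  {
    const double* dr = &down[0];
    const double* sr = &dscale[0];
    for (int p = 0; p < P; ++p) {
      double L = 0.0;
      for (int k = 0; k < K; ++k) {
        const double* o = dr + (size_t)4 * P * k + 4 * p;
        double s = freqs[0] * o[0] + freqs[1] * o[1] + freqs[2] * o[2] +
                   freqs[3] * o[3];
        L += catw[k] * s;
      }
      if (L < 1e-300) L = 1e-300;
      ll += patw[p] * (std::log(L) + sr[p]);
    }
  }

  List res = List::create(Named("loglik") = ll);
  if (!env) return res;

  // preorder pass: parent-side partials per edge.  Only the ancestor
  // chain of each wanted edge needs an up-partial, so everything off
  // those paths is skipped.
  const int W = want.size();
  std::vector<int> slot(E, -1);
  for (int w = 0; w < W; ++w) slot[want[w] - 1] = w;
  std::vector<int> parent_of(nint, -1);       // parent internal node
  for (int e = 0; e < E; ++e)
    if (edge(e, 1) > ntip)
      parent_of[edge(e, 1) - root] = edge(e, 0) - root;
  std::vector<char> need_up(nint, arrays ? 1 : 0);
  need_up[0] = 1;                             // root
  for (int w = 0; w < W; ++w) {
    int u = edge(want[w] - 1, 0) - root;
    while (u >= 0 && !need_up[u]) { need_up[u] = 1; u = parent_of[u]; }
  }

  std::vector<double> up(blk * nint), uscale((size_t)P * nint, 0.0);
  for (int k = 0; k < K; ++k)
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < 4; ++i)
        up[(size_t)4 * P * k + 4 * p + i] = freqs[i];

  NumericVector ux(Dimension(4, P, K * W)), dn(Dimension(4, P, K * W));
  NumericMatrix uxs(P, W), dns(P, W);
  std::vector<double> x(blk);

  for (int e = E - 1; e >= 0; --e) {
    const int u = edge(e, 0) - root;
    const int v = edge(e, 1);
    const bool want_e = slot[e] >= 0;
    const bool need_v = v > ntip && need_up[v - root];
    if (!want_e && !need_v) continue;
    // x = up[u] * prod of sibling edge contributions
    std::copy(up.begin() + blk * u, up.begin() + blk * (u + 1), x.begin());
    double xs_extra = 0.0;                  // pattern-independent part none;
    std::vector<const double*> sibscale;
    for (size_t ci = 0; ci < childedges[u].size(); ++ci) {
      int s = childedges[u][ci];
      if (s == e) continue;
      const double* zs = &z[blk * s];
      for (size_t i = 0; i < blk; ++i) x[i] *= zs[i];
      int sv = edge(s, 1);
      if (sv > ntip) sibscale.push_back(&dscale[(size_t)P * (sv - root)]);
    }
    (void)xs_extra;
    // per-pattern log-scaler of x
    std::vector<double> xscale(P);
    {
      const double* us = &uscale[(size_t)P * u];
      for (int p = 0; p < P; ++p) {
        double s = us[p];
        for (size_t q = 0; q < sibscale.size(); ++q) s += sibscale[q][p];
        xscale[p] = s;
      }
    }
    const int w = slot[e];
    if (w >= 0) {
      const bool vtip = v <= ntip;
      const double* dv = vtip ? &tipp[(size_t)4 * P * (v - 1)]
                              : &down[blk * (v - root)];
      const double* sv = vtip ? NULL : &dscale[(size_t)P * (v - root)];
      for (int k = 0; k < K; ++k) {
        double* uxk = &ux[(size_t)4 * P * ((size_t)K * w + k)];
        double* dnk = &dn[(size_t)4 * P * ((size_t)K * w + k)];
        const double* xk = &x[(size_t)4 * P * k];
        const double* dvk = vtip ? dv : dv + (size_t)4 * P * k;
        std::copy(xk, xk + (size_t)4 * P, uxk);
        std::copy(dvk, dvk + (size_t)4 * P, dnk);
      }
      for (int p = 0; p < P; ++p) {
        uxs(p, w) = xscale[p];
        dns(p, w) = vtip ? 0.0 : sv[p];
      }
    }
    if (need_v) {
      // up[v] = t(P_e) %*% x, then rescale
      for (int k = 0; k < K; ++k)
        pmat4(pU, pEv, pUi, len[e] * rates[k], &Pk[16 * k]);
      double* uv = &up[blk * (v - root)];
      for (int k = 0; k < K; ++k) {
        const double* Pm = &Pk[16 * k];
        const double* xk = &x[(size_t)4 * P * k];
        double* o = uv + (size_t)4 * P * k;
        for (int p = 0; p < P; ++p) {
          const double* xp = xk + 4 * p;
          double* op = o + 4 * p;
          for (int j = 0; j < 4; ++j)
            op[j] = Pm[j * 4 + 0] * xp[0] + Pm[j * 4 + 1] * xp[1] +
                    Pm[j * 4 + 2] * xp[2] + Pm[j * 4 + 3] * xp[3];
        }
      }
      double* us = &uscale[(size_t)P * (v - root)];
      for (int p = 0; p < P; ++p) {
        double m = 0.0;
        for (int k = 0; k < K; ++k) {
          double* op = uv + (size_t)4 * P * k + 4 * p;
          for (int j = 0; j < 4; ++j) if (op[j] > m) m = op[j];
        }
        us[p] = xscale[p];
        if (m > 0.0 && m != 1.0) {
          const double inv = 1.0 / m;
          for (int k = 0; k < K; ++k) {
            double* op = uv + (size_t)4 * P * k + 4 * p;
            for (int j = 0; j < 4; ++j) op[j] *= inv;
          }
          us[p] += std::log(m);
        }
      }
    }
  }

  res["ux"] = ux;
  res["uxs"] = uxs;
  res["dn"] = dn;
  res["dns"] = dns;
  res["want"] = want;
  if (arrays) {
    // per-edge child contributions and per-internal-node parent-side
    // partials, for local (quartet) rescoring of NNI resolutions
    NumericVector zout(Dimension(4, P, K * E));
    std::copy(z.begin(), z.end(), zout.begin());
    NumericVector upout(Dimension(4, P, K * nint));
    std::copy(up.begin(), up.end(), upout.begin());
    res["z"] = zout;
    res["up"] = upout;
  }
  return res;
}

// One Gauss-Seidel sweep of branch-length optimization over a partitioned
// dataset, entirely in C++: a postorder pass computes child-side partials
// per region, then a preorder traversal maintains parent-side partials and
// optimizes every edge in place by guarded Newton on the analytic
// derivatives (summed over regions, each with its own rate multiplier).
// Parent-side partials below an updated edge use the new length; sibling
// contributions within a sweep may be one update stale, which the next
// sweep absorbs.  Returns the updated lengths.
//
// regions: list of list(tipp, patw, U, ev, Uinv, rates, catw, freqs, rate)
// [[Rcpp::export]]
NumericVector gs_sweep(IntegerMatrix edge, int ntip, NumericVector len_in,
                       List regions, double bl_max) {
  NumericVector len = clone(len_in);
  const int E = edge.nrow();
  const int nint = E + 1 - ntip;
  const int root = ntip + 1;
  const int R = regions.size();

  struct Reg {
    const double *tipp, *U, *ev, *Ui, *rates, *catw, *freqs, *patw;
    int P, K;
    double rate;
    std::vector<double> down, z, up;
  };
  std::vector<Reg> rg(R);
  for (int r = 0; r < R; ++r) {
    List L = regions[r];
    NumericVector tipp = L["tipp"], patw = L["patw"], ev = L["ev"],
        rates = L["rates"], catw = L["catw"], freqs = L["freqs"];
    NumericMatrix U = L["U"], Ui = L["Uinv"];
    rg[r].tipp = tipp.begin(); rg[r].patw = patw.begin();
    rg[r].U = U.begin(); rg[r].ev = ev.begin(); rg[r].Ui = Ui.begin();
    rg[r].rates = rates.begin(); rg[r].catw = catw.begin();
    rg[r].freqs = freqs.begin();
    rg[r].P = patw.size(); rg[r].K = rates.size();
    rg[r].rate = as<double>(L["rate"]);
    size_t blk = (size_t)4 * rg[r].P * rg[r].K;
    rg[r].down.assign(blk * nint, 0.0);
    rg[r].z.assign(blk * E, 0.0);
    rg[r].up.assign(blk * nint, 0.0);
  }

  std::vector<int> remaining(nint, 0);
  std::vector<std::vector<int> > childedges(nint);
  for (int e = 0; e < E; ++e) {
    childedges[edge(e, 0) - root].push_back(e);
    remaining[edge(e, 0) - root]++;
  }

  std::vector<double> Pk(16 * 8), tmp;
  // postorder: down partials and per-edge contributions z
  for (int r = 0; r < R; ++r) {
    Reg& g = rg[r];
    const size_t blk = (size_t)4 * g.P * g.K;
    std::vector<int> rem = remaining;
    std::vector<char> touched(nint, 0);
    tmp.resize(blk);
    for (int e = 0; e < E; ++e) {
      const int u = edge(e, 0) - root;
      const int v = edge(e, 1);
      for (int k = 0; k < g.K; ++k)
        pmat4(g.U, g.ev, g.Ui, len[e] * g.rate * g.rates[k], &Pk[16 * k]);
      const bool vtip = v <= ntip;
      const double* dv = vtip ? g.tipp + (size_t)4 * g.P * (v - 1)
                              : &g.down[blk * (v - root)];
      for (int k = 0; k < g.K; ++k) {
        const double* Pm = &Pk[16 * k];
        const double* src = vtip ? dv : dv + (size_t)4 * g.P * k;
        double* out = &tmp[(size_t)4 * g.P * k];
        for (int p = 0; p < g.P; ++p) {
          const double* s = src + 4 * p;
          double* o = out + 4 * p;
          for (int i = 0; i < 4; ++i)
            o[i] = Pm[i] * s[0] + Pm[i + 4] * s[1] + Pm[i + 8] * s[2] +
                   Pm[i + 12] * s[3];
        }
      }
      std::copy(tmp.begin(), tmp.end(), g.z.begin() + blk * e);
      double* du = &g.down[blk * u];
      if (!touched[u]) { std::copy(tmp.begin(), tmp.end(), du); touched[u] = 1; }
      else for (size_t i = 0; i < blk; ++i) du[i] *= tmp[i];
      if (--rem[u] == 0) {
        for (int p = 0; p < g.P; ++p) {
          double m = 0.0;
          for (int k = 0; k < g.K; ++k) {
            double* o = du + (size_t)4 * g.P * k + 4 * p;
            for (int i = 0; i < 4; ++i) if (o[i] > m) m = o[i];
          }
          if (m > 0.0 && m != 1.0) {
            const double inv = 1.0 / m;
            for (int k = 0; k < g.K; ++k) {
              double* o = du + (size_t)4 * g.P * k + 4 * p;
              for (int i = 0; i < 4; ++i) o[i] *= inv;
            }
          }
        }
      }
    }
    // root up = freqs
    double* uv = &g.up[0];
    for (int k = 0; k < g.K; ++k)
      for (int p = 0; p < g.P; ++p)
        for (int i = 0; i < 4; ++i)
          uv[(size_t)4 * g.P * k + 4 * p + i] = g.freqs[i];
  }

  // per-edge objective: value + derivatives at t, summed over regions,
  // using x (parent side, stored per region in xbuf) and down[v]
  std::vector<std::vector<double> > xbuf(R);
  for (int r = 0; r < R; ++r)
    xbuf[r].resize((size_t)4 * rg[r].P * rg[r].K);

  for (int e = E - 1; e >= 0; --e) {
    const int u = edge(e, 0) - root;
    const int v = edge(e, 1);
    const bool vtip = v <= ntip;
    // x = up[u] * sibling z's, per region
    for (int r = 0; r < R; ++r) {
      Reg& g = rg[r];
      const size_t blk = (size_t)4 * g.P * g.K;
      std::copy(g.up.begin() + blk * u, g.up.begin() + blk * (u + 1),
                xbuf[r].begin());
      for (size_t ci = 0; ci < childedges[u].size(); ++ci) {
        int s = childedges[u][ci];
        if (s == e) continue;
        const double* zs = &g.z[blk * s];
        for (size_t i = 0; i < blk; ++i) xbuf[r][i] *= zs[i];
      }
      // rescale x per pattern for stability
      for (int p = 0; p < g.P; ++p) {
        double m = 0.0;
        for (int k = 0; k < g.K; ++k) {
          double* xp = &xbuf[r][(size_t)4 * g.P * k + 4 * p];
          for (int i = 0; i < 4; ++i) if (xp[i] > m) m = xp[i];
        }
        if (m > 0.0 && m != 1.0) {
          const double inv = 1.0 / m;
          for (int k = 0; k < g.K; ++k) {
            double* xp = &xbuf[r][(size_t)4 * g.P * k + 4 * p];
            for (int i = 0; i < 4; ++i) xp[i] *= inv;
          }
        }
      }
    }
    // f(t), f'(t), f''(t)
    std::vector<double> Pv(16 * 8), P1(16 * 8), P2(16 * 8);
    auto eval = [&](double t, double* d1out, double* d2out) -> double {
      double ll = 0.0, D1 = 0.0, D2 = 0.0;
      for (int r = 0; r < R; ++r) {
        Reg& g = rg[r];
        const double rr = g.rate;
        for (int k = 0; k < g.K; ++k) {
          double Ee[4], E1[4], E2[4];
          const double tr = t * rr * g.rates[k];
          const double cr = rr * g.rates[k];
          for (int q = 0; q < 4; ++q) {
            Ee[q] = std::exp(g.ev[q] * tr);
            E1[q] = g.ev[q] * cr * Ee[q];
            E2[q] = g.ev[q] * cr * E1[q];
          }
          for (int j = 0; j < 4; ++j)
            for (int i = 0; i < 4; ++i) {
              double s = 0, s1 = 0, s2 = 0;
              for (int q = 0; q < 4; ++q) {
                const double uu = g.U[i + 4 * q] * g.Ui[q + 4 * j];
                s += uu * Ee[q]; s1 += uu * E1[q]; s2 += uu * E2[q];
              }
              Pv[16 * k + i + 4 * j] = s > 0.0 ? s : 0.0;
              P1[16 * k + i + 4 * j] = s1;
              P2[16 * k + i + 4 * j] = s2;
            }
        }
        const double* dvb = vtip ? g.tipp + (size_t)4 * g.P * (v - 1)
                                 : &g.down[(size_t)4 * g.P * g.K * (v - root)];
        for (int p = 0; p < g.P; ++p) {
          double Lp = 0, La = 0, Lb = 0;
          for (int k = 0; k < g.K; ++k) {
            const double* Pm = &Pv[16 * k];
            const double* Pa = &P1[16 * k];
            const double* Pb = &P2[16 * k];
            const double* xk = &xbuf[r][(size_t)4 * g.P * k + 4 * p];
            const double* dk = vtip ? dvb + 4 * p
                                    : dvb + (size_t)4 * g.P * k + 4 * p;
            double s = 0, sa = 0, sb = 0;
            for (int i = 0; i < 4; ++i) {
              double pi = 0, pa = 0, pb = 0;
              for (int j = 0; j < 4; ++j) {
                pi += Pm[i + 4 * j] * dk[j];
                pa += Pa[i + 4 * j] * dk[j];
                pb += Pb[i + 4 * j] * dk[j];
              }
              s += xk[i] * pi; sa += xk[i] * pa; sb += xk[i] * pb;
            }
            Lp += g.catw[k] * s; La += g.catw[k] * sa; Lb += g.catw[k] * sb;
          }
          if (Lp < 1e-300) Lp = 1e-300;
          ll += g.patw[p] * std::log(Lp);
          const double r1 = La / Lp;
          D1 += g.patw[p] * r1;
          D2 += g.patw[p] * (Lb / Lp - r1 * r1);
        }
      }
      if (d1out) *d1out = D1;
      if (d2out) *d2out = D2;
      return ll;
    };
    // guarded Newton on [0, bl_max]
    double t = len[e];
    double d1, d2;
    double best_ll = eval(t, &d1, &d2), best_t = t;
    for (int it = 0; it < 12; ++it) {
      if (!std::isfinite(d1) || std::fabs(d1) < 1e-10) break;
      double step = (std::isfinite(d2) && d2 < 0) ? -d1 / d2
                    : (d1 > 0 ? 1.0 : -1.0) * 0.5 * (std::fabs(t) + 0.05);
      double tn = t + step;
      if (tn < 0) tn = 0;
      if (tn > bl_max) tn = bl_max;
      double lln = eval(tn, &d1, &d2);
      int tries = 0;
      while ((!std::isfinite(lln) || lln < best_ll - 1e-12) && tries < 8) {
        tn = (tn + t) / 2;
        lln = eval(tn, &d1, &d2);
        ++tries;
      }
      if (std::isfinite(lln) && lln > best_ll) { best_ll = lln; best_t = tn; }
      if (std::fabs(tn - t) < 1e-8) { t = tn; break; }
      t = tn;
    }
    if (best_t > 0 && best_t < 1e-4) {
      double ll0 = eval(0.0, NULL, NULL);
      if (ll0 >= best_ll) best_t = 0.0;
    }
    len[e] = best_t;
    // descend: up[v] with the new length
    if (!vtip) {
      for (int r = 0; r < R; ++r) {
        Reg& g = rg[r];
        const size_t blk = (size_t)4 * g.P * g.K;
        for (int k = 0; k < g.K; ++k)
          pmat4(g.U, g.ev, g.Ui, len[e] * g.rate * g.rates[k], &Pk[16 * k]);
        double* uv = &g.up[blk * (v - root)];
        for (int k = 0; k < g.K; ++k) {
          const double* Pm = &Pk[16 * k];
          const double* xk = &xbuf[r][(size_t)4 * g.P * k];
          double* o = uv + (size_t)4 * g.P * k;
          for (int p = 0; p < g.P; ++p) {
            const double* xp = xk + 4 * p;
            double* op = o + 4 * p;
            for (int j = 0; j < 4; ++j)
              op[j] = Pm[j * 4 + 0] * xp[0] + Pm[j * 4 + 1] * xp[1] +
                      Pm[j * 4 + 2] * xp[2] + Pm[j * 4 + 3] * xp[3];
          }
        }
        // rescale up[v]
        for (int p = 0; p < g.P; ++p) {
          double m = 0.0;
          for (int k = 0; k < g.K; ++k) {
            double* op = uv + (size_t)4 * g.P * k + 4 * p;
            for (int j = 0; j < 4; ++j) if (op[j] > m) m = op[j];
          }
          if (m > 0.0 && m != 1.0) {
            const double inv = 1.0 / m;
            for (int k = 0; k < g.K; ++k) {
              double* op = uv + (size_t)4 * g.P * k + 4 * p;
              for (int j = 0; j < 4; ++j) op[j] *= inv;
            }
          }
        }
      }
    }
  }
  return len;
}

// As env_loglik below, but also returns the first and second derivatives
// of the log-likelihood with respect to t (used by the guarded-Newton
// branch-length optimizer).
// [[Rcpp::export]]
NumericVector env_dloglik(NumericVector ux, NumericVector uxs,
                          NumericVector dn, NumericVector dns, int w, int P,
                          int K, double t, NumericMatrix U, NumericVector ev,
                          NumericMatrix Uinv, NumericVector rates,
                          NumericVector catw, NumericVector patw) {
  std::vector<double> Pk((size_t)16 * K), P1((size_t)16 * K),
      P2((size_t)16 * K);
  for (int k = 0; k < K; ++k) {
    double E[4], E1[4], E2[4];
    const double r = rates[k];
    for (int q = 0; q < 4; ++q) {
      E[q] = std::exp(ev[q] * t * r);
      E1[q] = ev[q] * r * E[q];
      E2[q] = ev[q] * r * E1[q];
    }
    for (int j = 0; j < 4; ++j)
      for (int i = 0; i < 4; ++i) {
        double s = 0, s1 = 0, s2 = 0;
        for (int q = 0; q < 4; ++q) {
          const double uu = U(i, q) * Uinv(q, j);
          s += uu * E[q]; s1 += uu * E1[q]; s2 += uu * E2[q];
        }
        Pk[16 * k + i + 4 * j] = s > 0.0 ? s : 0.0;
        P1[16 * k + i + 4 * j] = s1;
        P2[16 * k + i + 4 * j] = s2;
      }
  }
  double ll = 0.0, d1 = 0.0, d2 = 0.0;
  const double* puxs = uxs.begin() + (size_t)P * (w - 1);
  const double* pdns = dns.begin() + (size_t)P * (w - 1);
  for (int p = 0; p < P; ++p) {
    double L = 0.0, La = 0.0, Lb = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* Pm = &Pk[16 * k];
      const double* Pa = &P1[16 * k];
      const double* Pb = &P2[16 * k];
      const double* u = ux.begin() + (size_t)4 * P * ((size_t)K * (w - 1) + k) + 4 * p;
      const double* d = dn.begin() + (size_t)4 * P * ((size_t)K * (w - 1) + k) + 4 * p;
      double s = 0, sa = 0, sb = 0;
      for (int i = 0; i < 4; ++i) {
        double pi = 0, pa = 0, pb = 0;
        for (int j = 0; j < 4; ++j) {
          pi += Pm[i + 4 * j] * d[j];
          pa += Pa[i + 4 * j] * d[j];
          pb += Pb[i + 4 * j] * d[j];
        }
        s += u[i] * pi; sa += u[i] * pa; sb += u[i] * pb;
      }
      L += catw[k] * s; La += catw[k] * sa; Lb += catw[k] * sb;
    }
    if (L < 1e-300) L = 1e-300;
    ll += patw[p] * (std::log(L) + puxs[p] + pdns[p]);
    const double r1 = La / L;
    d1 += patw[p] * r1;
    d2 += patw[p] * (Lb / L - r1 * r1);
  }
  return NumericVector::create(ll, d1, d2);
}

// Likelihood of attaching one extra edge of length t between the stored
// parent-side and child-side partials of an edge environment (used by the
// R-side branch-length optimizer; kept in C++ for the inner loop).
// [[Rcpp::export]]
double env_loglik(NumericVector ux, NumericVector uxs, NumericVector dn,
                  NumericVector dns, int w, int P, int K, double t,
                  NumericMatrix U, NumericVector ev, NumericMatrix Uinv,
                  NumericVector rates, NumericVector catw,
                  NumericVector patw) {
  std::vector<double> Pk((size_t)16 * K);
  for (int k = 0; k < K; ++k)
    pmat4(U.begin(), ev.begin(), Uinv.begin(), t * rates[k], &Pk[16 * k]);
  double ll = 0.0;
  const double* puxs = uxs.begin() + (size_t)P * (w - 1);
  const double* pdns = dns.begin() + (size_t)P * (w - 1);
  for (int p = 0; p < P; ++p) {
    double L = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* Pm = &Pk[16 * k];
      const double* u = ux.begin() + (size_t)4 * P * ((size_t)K * (w - 1) + k) + 4 * p;
      const double* d = dn.begin() + (size_t)4 * P * ((size_t)K * (w - 1) + k) + 4 * p;
      double s = 0.0;
      for (int i = 0; i < 4; ++i) {
        double pi = Pm[i] * d[0] + Pm[i + 4] * d[1] + Pm[i + 8] * d[2] +
                    Pm[i + 12] * d[3];
        s += u[i] * pi;
      }
      L += catw[k] * s;
    }
    if (L < 1e-300) L = 1e-300;
    ll += patw[p] * (std::log(L) + puxs[p] + pdns[p]);
  }
  return ll;
}
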