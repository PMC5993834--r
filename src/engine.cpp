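// Simulation engine: parallel Hopfield sweeps, activity-driven edge dynamics,
// and the one-step master equation for the decoupled (topological) limit.
// All randomness goes through R's RNG so that set.seed() controls every run.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int N;
  std::vector<std::vector<int> > adj;
  long E;
  Net(int N_) : N(N_), adj(N_), E(0) {}
  bool has_edge(int i, int j) const {
    const std::vector<int>& a = adj[i].size() <= adj[j].size() ? adj[i] : adj[j];
    int tgt = adj[i].size() <= adj[j].size() ? j : i;
    return std::find(a.begin(), a.end(), tgt) != a.end();
  }
  void add_edge(int i, int j) {
    adj[i].push_back(j);
    adj[j].push_back(i);
    ++E;
  }
  // remove the pos-th incident edge of i (and its mirror entry)
  void remove_incident(int i, int pos) {
    int j = adj[i][pos];
    adj[i][pos] = adj[i].back(); adj[i].pop_back();
    std::vector<int>& aj = adj[j];
    std::vector<int>::iterator it = std::find(aj.begin(), aj.end(), i);
    *it = aj.back(); aj.pop_back();
    --E;
  }
};

Net net_from_edges(const IntegerMatrix& edges, int N) {
  Net net(N);
  for (int e = 0; e < edges.nrow(); ++e)
    net.add_edge(edges(e, 0) - 1, edges(e, 1) - 1);
  return net;
}

IntegerMatrix edges_of(const Net& net) {
  IntegerMatrix out((int)net.E, 2);
  int r = 0;
  for (int i = 0; i < net.N; ++i)
    for (size_t q = 0; q < net.adj[i].size(); ++q) {
      int j = net.adj[i][q];
      if (i < j) { out(r, 0) = i + 1; out(r, 1) = j + 1; ++r; }
    }
  return out;
}

inline double pow_fast(double x, double a) {
  if (a == 1.0) return x;
  if (a == 0.0) return 1.0;
  if (a == 2.0) return x * x;
  return std::pow(x, a);
}

int sample_cum(const std::vector<double>& cum) {
  double total = cum.back();
  double r = unif_rand() * total;
  int idx = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
  if (idx >= (int)cum.size()) idx = (int)cum.size() - 1;
  return idx;
}

// Node-selection weights for the MC scheme: the clipped local probabilities
// pi(I_i) and eta(I_i, k_i) of the model (renormalised after clipping).
// The random-partner (1/N) and random-neighbour (k/kappa N) channels are NOT
// part of these weights -- they arise from the uniform partner / uniform
// incident-edge choices of the structural step, which is what makes the
// effective per-node rates pi~ = (pi + 1/N)/2 and eta~ = (eta + k/(kappa N))/2.
void local_weights(const std::vector<double>& I, const std::vector<int>& deg,
                   long E, double alpha, double gam, bool eta_approx,
                   std::vector<double>& pi_sel, std::vector<double>& eta_sel) {
  int N = (int)I.size();
  pi_sel.assign(N, 0.0);
  eta_sel.assign(N, 0.0);
  double sIa = 0.0, sIg = 0.0;
  std::vector<double> Ia(N), Ig(N);
  for (int i = 0; i < N; ++i) {
    Ia[i] = I[i] > 0 ? pow_fast(I[i], alpha) : 0.0;
    Ig[i] = I[i] > 0 ? pow_fast(I[i], gam) : 0.0;
    sIa += Ia[i]; sIg += Ig[i];
  }
  double invN = 1.0 / N;
  if (sIa > 0) {
    for (int i = 0; i < N; ++i)
      pi_sel[i] = std::max(2.0 * Ia[i] / sIa - invN, 0.0);
  }
  double sp = 0.0;
  for (int i = 0; i < N; ++i) sp += pi_sel[i];
  if (sp > 0) for (int i = 0; i < N; ++i) pi_sel[i] /= sp;
  else for (int i = 0; i < N; ++i) pi_sel[i] = invN;  // fully silent: uniform

  double ktot = 2.0 * (double)E;  // = kappa * N
  if (eta_approx && sIg > 0) {
    for (int i = 0; i < N; ++i) eta_sel[i] = Ig[i] / sIg;
  } else if (sIg > 0 && ktot > 0) {
    for (int i = 0; i < N; ++i)
      eta_sel[i] = std::max(2.0 * Ig[i] / sIg - deg[i] / ktot, 0.0);
  }
  double se = 0.0;
  for (int i = 0; i < N; ++i) se += eta_sel[i];
  if (se > 0) for (int i = 0; i < N; ++i) eta_sel[i] /= se;
  else if (ktot > 0)  // silent network: losses fall back to degree-proportional
    for (int i = 0; i < N; ++i) eta_sel[i] = deg[i] / ktot;
}

struct StepReport { int added, removed, skip_gain, skip_loss; };

// One structural update: Poisson numbers of gains/losses executed in random
// interleaved order, nodes selected by cumulative weights (BKL style).
StepReport structural_step(Net& net, const std::vector<double>& pi_t,
                           const std::vector<double>& eta_t, double u, double d) {
  int N = net.N;
  StepReport rep; rep.added = rep.removed = rep.skip_gain = rep.skip_loss = 0;
  int G = (int)R::rpois(N * u);
  int L = (int)R::rpois(N * d);
  if (G + L == 0) return rep;
  std::vector<int> deg(N);
  std::vector<double> cpi(N), ceta(N);
  double accp = 0.0, acce = 0.0;
  for (int i = 0; i < N; ++i) {
    accp += pi_t[i]; cpi[i] = accp;
    acce += eta_t[i]; ceta[i] = acce;
  }
  std::vector<char> ev(G + L);
  std::fill(ev.begin(), ev.begin() + G, 1);
  // Fisher-Yates with R's RNG
  for (int i = (int)ev.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ev[i], ev[j]);
  }
  const int MAXTRY = 200;
  for (size_t e = 0; e < ev.size(); ++e) {
    if (ev[e]) {  // gain: node by pi~, partner uniform among non-neighbours
      bool done = false;
      for (int tr = 0; tr < MAXTRY && !done; ++tr) {
        if (cpi.back() <= 0) break;
        int i = sample_cum(cpi);
        if ((int)net.adj[i].size() >= N - 1) continue;
        for (int tr2 = 0; tr2 < MAXTRY; ++tr2) {
          int j = (int)(unif_rand() * N);
          if (j >= N) j = N - 1;
          if (j == i || net.has_edge(i, j)) continue;
          net.add_edge(i, j);
          ++rep.added; done = true;
          break;
        }
      }
      if (!done) ++rep.skip_gain;
    } else {      // loss: node by eta~, victim edge uniform among incident
      bool done = false;
      for (int tr = 0; tr < MAXTRY && !done; ++tr) {
        if (ceta.back() <= 0) break;
        int j = sample_cum(ceta);
        int kj = (int)net.adj[j].size();
        if (kj == 0) continue;
        int pos = (int)(unif_rand() * kj);
        if (pos >= kj) pos = kj - 1;
        net.remove_incident(j, pos);
        ++rep.removed; done = true;
      }
      if (!done) ++rep.skip_loss;
    }
  }
  return rep;
}

// degree-based observables
void degree_stats(const Net& net, double& kappa, double& g, double& r) {
  int N = net.N;
  double s1 = 0, s2 = 0, s3 = 0;
  for (int i = 0; i < N; ++i) {
    double k = (double)net.adj[i].size();
    s1 += k; s2 += k * k; s3 += k * k * k;
  }
  kappa = s1 / N;
  if (kappa > 0) {
    double var = s2 / N - kappa * kappa;
    g = std::exp(-var / (kappa * kappa));
  } else g = NA_REAL;
  // edge Pearson r over ordered edge ends
  double spr = 0.0;
  for (int i = 0; i < N; ++i)
    for (size_t q = 0; q < net.adj[i].size(); ++q)
      spr += (double)net.adj[i].size() * (double)net.adj[net.adj[i][q]].size();
  double twoE = s1;
  if (twoE > 0) {
    double mx = s2 / twoE;            // mean degree over edge ends
    double mx2 = s3 / twoE;           // mean squared degree over edge ends
    double mxy = spr / twoE;
    double den = mx2 - mx * mx;
    r = den > 1e-14 ? (mxy - mx * mx) / den : NA_REAL;
  } else r = NA_REAL;
}

// one synchronous Hopfield sweep on an adjacency-list network
void sweep_adj(const Net& net, const NumericMatrix& W, std::vector<int>& s,
               std::vector<double>& h, const std::vector<double>& theta,
               double beta, bool zeroT) {
  int N = net.N;
  for (int i = 0; i < N; ++i) {
    double hi = 0.0;
    const std::vector<int>& ai = net.adj[i];
    for (size_t q = 0; q < ai.size(); ++q) {
      int j = ai[q];
      if (s[j]) hi += W(j, i);
    }
    h[i] = hi;
  }
  for (int i = 0; i < N; ++i) {
    double x = h[i] - theta[i];
    int si;
    if (zeroT) {
      si = x > 0 ? 1 : (x < 0 ? 0 : (unif_rand() < 0.5 ? 1 : 0));
    } else {
      double p = 0.5 * (1.0 + std::tanh(beta * x));
      si = unif_rand() < p ? 1 : 0;
    }
    s[i] = si;  // safe: h already computed from old states
  }
}

void thresholds_adj(const Net& net, const NumericMatrix& W, std::vector<double>& theta) {
  int N = net.N;
  for (int i = 0; i < N; ++i) {
    double th = 0.0;
    const std::vector<int>& ai = net.adj[i];
    for (size_t q = 0; q < ai.size(); ++q) th += W(ai[q], i);
    theta[i] = 0.5 * th;
  }
}

// single-pattern fast path: w_ij = x_i x_j with x_i = (xi_i - a0)/sqrt(c),
// so fields need only the two small vectors (no N x N matrix traffic)
void thresholds_adj_p1(const Net& net, const std::vector<double>& x,
                       std::vector<double>& theta) {
  int N = net.N;
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    const std::vector<int>& ai = net.adj[i];
    for (size_t q = 0; q < ai.size(); ++q) acc += x[ai[q]];
    theta[i] = 0.5 * x[i] * acc;
  }
}

void sweep_adj_p1(const Net& net, const std::vector<double>& x,
                  std::vector<int>& s, std::vector<double>& h,
                  const std::vector<double>& theta, double beta, bool zeroT) {
  int N = net.N;
  static std::vector<double> y;  // y_j = s_j x_j, branchless gather source
  y.resize(N);
  for (int j = 0; j < N; ++j) y[j] = s[j] ? x[j] : 0.0;
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    const std::vector<int>& ai = net.adj[i];
    for (size_t q = 0; q < ai.size(); ++q) acc += y[ai[q]];
    h[i] = x[i] * acc;
  }
  for (int i = 0; i < N; ++i) {
    double xv = h[i] - theta[i];
    s[i] = zeroT ? (xv > 0 ? 1 : (xv < 0 ? 0 : (unif_rand() < 0.5 ? 1 : 0)))
                 : (unif_rand() < 0.5 * (1.0 + std::tanh(beta * xv)) ? 1 : 0);
  }
}

double overlap_of(const std::vector<int>& s, const NumericMatrix& xi, int mu, double a0) {
  int N = (int)s.size();
  double acc = 0.0;
  for (int i = 0; i < N; ++i) acc += (xi(i, mu) - a0) * s[i];
  return acc / (N * a0 * (1.0 - a0));
}

} // namespace

// [[Rcpp::export]]
List cpp_local_weights(NumericVector I, IntegerVector deg, double E,
                       double alpha, double gam, bool eta_approx) {
  std::vector<double> Iv(I.begin(), I.end()), pi_t, eta_t;
  std::vector<int> dv(deg.begin(), deg.end());
  local_weights(Iv, dv, (long)E, alpha, gam, eta_approx, pi_t, eta_t);
  return List::create(_["pi_sel"] = NumericVector(pi_t.begin(), pi_t.end()),
                      _["eta_sel"] = NumericVector(eta_t.begin(), eta_t.end()));
}

// [[Rcpp::export]]
List cpp_structural_step(IntegerMatrix edges, int N, NumericVector pi_sel,
                         NumericVector eta_sel, double u, double d) {
  Net net = net_from_edges(edges, N);
  std::vector<double> pv(pi_sel.begin(), pi_sel.end());
  std::vector<double> ev(eta_sel.begin(), eta_sel.end());
  StepReport rep = structural_step(net, pv, ev, u, d);
  return List::create(_["edges"] = edges_of(net),
                      _["added"] = rep.added, _["removed"] = rep.removed,
                      _["skipped_gains"] = rep.skip_gain,
                      _["skipped_losses"] = rep.skip_loss);
}

// [[Rcpp::export]]
List cpp_hopfield(NumericMatrix W, Nullable<IntegerMatrix> edges, int N,
                  IntegerVector s0, double T, int n_sweeps,
                  NumericMatrix xi, double a0) {
  int P = xi.ncol();
  bool complete = edges.isNull();
  Net net(complete ? 1 : N);
  if (!complete) net = net_from_edges(edges.get(), N);
  std::vector<int> s(s0.begin(), s0.end());
  std::vector<double> h(N, 0.0), theta(N, 0.0);
  bool zeroT = (T == 0.0);
  // +/-1 heat-bath convention: the spin field is 2(h - theta), so the
  // reference fully connected model orders at T = 1
  double beta = zeroT ? 0.0 : 2.0 / T;

  // pattern-factored couplings: w_ij = sum_mu x_i^mu x_j^mu (zero diagonal),
  // with x_i^mu = (xi_i^mu - a0) / sqrt(kappa_scale); the scale is recovered
  // from the supplied Hebbian matrix so the factorisation stays exact
  std::vector<double> x1;
  bool p1 = (P == 1) && !complete;
  double c_scale = 1.0;  // 1/(kappa_inf a0 (1-a0))
  if (p1 || complete) {
    // recover the Hebbian scale from an off-diagonal entry whose pattern
    // inner product does not vanish (always exists for 0/1 patterns)
    for (int j = 1; j < N; ++j) {
      double acc = 0.0;
      for (int mu = 0; mu < P; ++mu) acc += (xi(0, mu) - a0) * (xi(j, mu) - a0);
      if (std::fabs(acc) > 1e-10) { c_scale = W(j, 0) / acc; break; }
    }
  }
  std::vector<std::vector<double> > xf;  // x[mu][i] for the complete graph
  if (p1) {
    double rt = std::sqrt(c_scale);
    x1.resize(N);
    for (int i = 0; i < N; ++i) x1[i] = (xi(i, 0) - a0) * rt;
  } else if (complete) {
    double rt = std::sqrt(c_scale);
    xf.assign(P, std::vector<double>(N));
    for (int mu = 0; mu < P; ++mu)
      for (int i = 0; i < N; ++i) xf[mu][i] = (xi(i, mu) - a0) * rt;
  }

  if (complete) {
    // theta_i = 1/2 sum_j w_ij = 1/2 (x_i sum_j x_j - x_i^2) summed over mu
    std::vector<double> Sx(P, 0.0);
    for (int mu = 0; mu < P; ++mu)
      for (int j = 0; j < N; ++j) Sx[mu] += xf[mu][j];
    for (int i = 0; i < N; ++i) {
      double th = 0.0;
      for (int mu = 0; mu < P; ++mu)
        th += xf[mu][i] * (Sx[mu] - xf[mu][i]);
      theta[i] = 0.5 * th;
    }
  } else if (p1) thresholds_adj_p1(net, x1, theta);
  else thresholds_adj(net, W, theta);

  NumericMatrix m_rec(n_sweeps, P);
  NumericVector M_rec(n_sweeps);
  for (int sw = 0; sw < n_sweeps; ++sw) {
    if (complete) {
      // h_i = sum_mu x_i (S_mu - x_i s_i), with S_mu = sum_{j firing} x_j
      std::vector<double> Sa(P, 0.0);
      for (int mu = 0; mu < P; ++mu) {
        const std::vector<double>& xm = xf[mu];
        double acc = 0.0;
        for (int j = 0; j < N; ++j) if (s[j]) acc += xm[j];
        Sa[mu] = acc;
      }
      for (int i = 0; i < N; ++i) {
        double hi = 0.0;
        for (int mu = 0; mu < P; ++mu)
          hi += xf[mu][i] * (Sa[mu] - xf[mu][i] * s[i]);
        h[i] = hi;
      }
      for (int i = 0; i < N; ++i) {
        double x = h[i] - theta[i];
        s[i] = zeroT ? (x > 0 ? 1 : (x < 0 ? 0 : (unif_rand() < 0.5 ? 1 : 0)))
                     : (unif_rand() < 0.5 * (1.0 + std::tanh(beta * x)) ? 1 : 0);
      }
    } else if (p1) {
      sweep_adj_p1(net, x1, s, h, theta, beta, zeroT);
    } else {
      sweep_adj(net, W, s, h, theta, beta, zeroT);
    }
    double M = 0.0;
    for (int i = 0; i < N; ++i) M += s[i];
    M_rec[sw] = M / N;
    for (int mu = 0; mu < P; ++mu) m_rec(sw, mu) = overlap_of(s, xi, mu, a0);
  }
  return List::create(_["m"] = m_rec, _["M"] = M_rec,
                      _["states"] = IntegerVector(s.begin(), s.end()),
                      _["fields"] = NumericVector(h.begin(), h.end()),
                      _["thresholds"] = NumericVector(theta.begin(), theta.end()));
}

// [[Rcpp::export]]
List cpp_coevolve(IntegerMatrix edges, int N, NumericMatrix W, NumericMatrix xi,
                  double a0, IntegerVector s0, double T, double alpha, double gam,
                  double n_edges, double kappa_inf, double growth_a, double growth_tau,
                  int h_s, int t_max, bool topological, bool eta_approx,
                  bool window_avg_currents, int record_every, int avg_start) {
  Net net = net_from_edges(edges, N);
  int P = xi.ncol();
  std::vector<int> s(s0.begin(), s0.end());
  std::vector<double> h(N, 0.0), theta(N, 0.0), I(N, 0.0), Iacc(N, 0.0);
  bool zeroT = (T == 0.0);
  double beta = zeroT ? 0.0 : 2.0 / T;  // +/-1 heat-bath convention, see cpp_hopfield

  // single-pattern factorisation w_ij = x_i x_j (see cpp_hopfield)
  bool p1 = (P == 1) && !topological && N > 1;
  std::vector<double> x1;
  if (p1) {
    double acc = (xi(0, 0) - a0) * (xi(1, 0) - a0);
    double c_scale = std::fabs(acc) > 1e-300 ? W(1, 0) / acc : 1.0;
    double rt = std::sqrt(c_scale);
    x1.resize(N);
    for (int i = 0; i < N; ++i) x1[i] = (xi(i, 0) - a0) * rt;
  }

  int n_rec = t_max / record_every;
  NumericVector t_rec(n_rec), kap_rec(n_rec), M_rec(n_rec), g_rec(n_rec), r_rec(n_rec);
  NumericMatrix m_rec(n_rec, P);
  NumericVector deg_hist(N);          // pooled degree counts over the averaging window
  NumericVector knn_sum(N), knn_cnt(N);
  long skip_gain = 0, skip_loss = 0;
  std::vector<double> pi_t, eta_t;
  std::vector<int> deg(N);

  for (int t = 1; t <= t_max; ++t) {
    if (!topological) {
      if (p1) thresholds_adj_p1(net, x1, theta);
      else thresholds_adj(net, W, theta);
      if (window_avg_currents) std::fill(Iacc.begin(), Iacc.end(), 0.0);
      for (int sw = 0; sw < h_s; ++sw) {
        if (p1) sweep_adj_p1(net, x1, s, h, theta, beta, zeroT);
        else sweep_adj(net, W, s, h, theta, beta, zeroT);
        if (window_avg_currents)
          for (int i = 0; i < N; ++i) Iacc[i] += std::fabs(h[i] - theta[i]);
      }
      if (window_avg_currents)
        for (int i = 0; i < N; ++i) I[i] = Iacc[i] / h_s;
      else
        for (int i = 0; i < N; ++i) I[i] = std::fabs(h[i] - theta[i]);
    } else {
      for (int i = 0; i < N; ++i) I[i] = (double)net.adj[i].size();
    }
    for (int i = 0; i < N; ++i) deg[i] = (int)net.adj[i].size();
    double kappa = 2.0 * (double)net.E / N;
    double u = (n_edges / N) * (1.0 - kappa / (2.0 * kappa_inf));
    if (growth_a > 0) u += growth_a * std::exp(-(double)t / growth_tau);
    if (u < 0) u = 0;
    double d = (n_edges / N) * kappa / (2.0 * kappa_inf);
    local_weights(I, deg, net.E, alpha, gam, eta_approx, pi_t, eta_t);
    StepReport rep = structural_step(net, pi_t, eta_t, u, d);
    skip_gain += rep.skip_gain; skip_loss += rep.skip_loss;

    if (t % record_every == 0) {
      int idx = t / record_every - 1;
      double kap, g, r;
      degree_stats(net, kap, g, r);
      t_rec[idx] = t; kap_rec[idx] = kap; g_rec[idx] = g; r_rec[idx] = r;
      if (!topological) {
        double M = 0.0;
        for (int i = 0; i < N; ++i) M += s[i];
        M_rec[idx] = M / N;
        for (int mu = 0; mu < P; ++mu) m_rec(idx, mu) = overlap_of(s, xi, mu, a0);
      } else {
        M_rec[idx] = NA_REAL;
        for (int mu = 0; mu < P; ++mu) m_rec(idx, mu) = NA_REAL;
      }
      if (t >= avg_start) {
        for (int i = 0; i < N; ++i) {
          int k = (int)net.adj[i].size();
          deg_hist[k] += 1.0;
          if (k > 0) {
            double acc = 0.0;
            for (size_t q = 0; q < net.adj[i].size(); ++q)
              acc += (double)net.adj[net.adj[i][q]].size();
            knn_sum[k] += acc / k;
            knn_cnt[k] += 1.0;
          }
        }
      }
    }
  }
  if (!topological) {
    if (p1) {
      thresholds_adj_p1(net, x1, theta);
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (size_t q = 0; q < net.adj[i].size(); ++q)
          if (s[net.adj[i][q]]) acc += x1[net.adj[i][q]];
        h[i] = x1[i] * acc;
        I[i] = std::fabs(h[i] - theta[i]);
      }
    } else {
      thresholds_adj(net, W, theta);
      for (int i = 0; i < N; ++i) {
        double hi = 0.0;
        for (size_t q = 0; q < net.adj[i].size(); ++q)
          if (s[net.adj[i][q]]) hi += W(net.adj[i][q], i);
        h[i] = hi;
        I[i] = std::fabs(h[i] - theta[i]);
      }
    }
  } else {
    for (int i = 0; i < N; ++i) I[i] = (double)net.adj[i].size();
  }
  return List::create(_["t"] = t_rec, _["kappa"] = kap_rec, _["M"] = M_rec,
                      _["g"] = g_rec, _["r"] = r_rec, _["m"] = m_rec,
                      _["edges"] = edges_of(net),
                      _["states"] = IntegerVector(s.begin(), s.end()),
                      _["currents"] = NumericVector(I.begin(), I.end()),
                      _["deg_hist"] = deg_hist,
                      _["knn_sum"] = knn_sum, _["knn_cnt"] = knn_cnt,
                      _["skipped_gains"] = (double)skip_gain,
                      _["skipped_losses"] = (double)skip_loss);
}

// Explicit Euler with adaptive step for the one-step master equation of the
// topological limit. Time unit: one structural update of the whole network.
// [[Rcpp::export]]
List cpp_master(NumericVector p0, double kappa_inf, double n_edges, double alpha,
                double gam, double t_end, double tol, double safety,
                double max_iter, int sample_every, bool mc_rates) {
  int N = p0.size();
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> a(N), b(N), dp(N), pi_t(N), eta_t(N);
  double t = 0.0, l1 = R_PosInf;
  double iter = 0;
  std::vector<double> ts, ks;
  bool converged = false;

  while (t < t_end && iter < max_iter) {
    double kappa = 0.0, mka = 0.0, mkg = 0.0;
    for (int k = 0; k < N; ++k) {
      kappa += (double)k * p[k];
      mka += pow_fast((double)k, alpha) * p[k];
      mkg += pow_fast((double)k, gam) * p[k];
    }
    if (((long)iter) % sample_every == 0) { ts.push_back(t); ks.push_back(kappa); }
    double invN = 1.0 / N;
    double u = (n_edges / N) * (1.0 - kappa / (2.0 * kappa_inf));
    if (u < 0) u = 0;
    double d = (n_edges / N) * kappa / (2.0 * kappa_inf);
    double maxrate = 0.0;
    if (!mc_rates) {
      // literal one-step rates of the model's master equation: effective
      // weights proportional to k^alpha (gains) and k^gamma (losses), with
      // the uniform random-partner channel as a floor so that low-degree
      // (and isolated) nodes keep gaining edges
      for (int k = 0; k < N; ++k) {
        double ka = pow_fast((double)k, alpha);
        double kg = pow_fast((double)k, gam);
        a[k] = mka > 0 ? std::max(2.0 * u * ka / mka, u) : u;
        b[k] = mkg > 0 ? 2.0 * d * kg / mkg : 0.0;
        double tot = a[k] + b[k];
        if (tot > maxrate) maxrate = tot;
      }
    } else {
      // MC-faithful mean field: clipped selection weights renormalised as in
      // the simulation (S = N sum_k p(k) w(k) plays the role of sum_i w_i);
      // saturated nodes (k = N-1) are resampled by the MC when drawn for a
      // gain or as a partner, so they are excluded from the normalisations.
      double S_pi = 0.0, S_eta = 0.0;
      for (int k = 0; k < N; ++k) {
        double ka = pow_fast((double)k, alpha);
        pi_t[k] = mka > 0 ? std::max(2.0 * ka / (mka * N) - invN, 0.0) : 0.0;
        if (k < N - 1) S_pi += p[k] * pi_t[k];
        double kg = pow_fast((double)k, gam);
        double kk = kappa > 0 ? (double)k / (kappa * N) : 0.0;
        eta_t[k] = mkg > 0 ? std::max(2.0 * kg / (mkg * N) - kk, 0.0) : 0.0;
        S_eta += p[k] * eta_t[k];
      }
      S_pi *= N; S_eta *= N;
      double p_sat = p[N - 1];
      // per-node rates: selected-node channel + random-partner (gains) or
      // random-neighbour (losses, probability k/kappa N per event) channel;
      // total degree-increment rate 2Nu reproduces tau_p = N kappa_inf/(2n)
      double u_partner = p_sat < 1.0 ? u / (1.0 - p_sat) : 0.0;
      for (int k = 0; k < N; ++k) {
        double gain_sel = S_pi > 0 ? N * u * pi_t[k] / S_pi : u_partner;
        a[k] = gain_sel + u_partner;
        double loss_nbr = kappa > 0 ? d * (double)k / kappa : 0.0;
        double loss_sel = S_eta > 0 ? N * d * eta_t[k] / S_eta : loss_nbr;
        b[k] = loss_sel + loss_nbr;
        double tot = a[k] + b[k];
        if (tot > maxrate) maxrate = tot;
      }
    }
    a[N - 1] = 0.0;  // reflecting boundaries
    b[0] = 0.0;
    if (maxrate <= 0) { converged = true; l1 = 0.0; break; }

    l1 = 0.0;
    for (int k = 0; k < N; ++k) {
      double in_gain = k > 0 ? a[k - 1] * p[k - 1] : 0.0;
      double in_loss = k < N - 1 ? b[k + 1] * p[k + 1] : 0.0;
      dp[k] = in_gain + in_loss - (a[k] + b[k]) * p[k];
      l1 += std::fabs(dp[k]);
    }
    if (l1 < tol) { converged = true; break; }
    double dt = safety / maxrate;
    if (t + dt > t_end) dt = t_end - t;
    // guard: halve dt until no probability goes negative (cannot loop forever
    // since dt*maxrate < 1 already guarantees positivity for a birth-death step)
    int halvings = 0;
    for (;;) {
      bool ok = true;
      for (int k = 0; k < N; ++k)
        if (p[k] + dt * dp[k] < -1e-15) { ok = false; break; }
      if (ok) break;
      dt *= 0.5;
      if (++halvings > 60) stop("master equation: step size underflow");
    }
    for (int k = 0; k < N; ++k) {
      p[k] += dt * dp[k];
      if (p[k] < 0) p[k] = 0;  // clip FP dust
    }
    t += dt;
    iter += 1;
    if (((long)iter) % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  ts.push_back(t);
  double kap_fin = 0.0;
  for (int k = 0; k < N; ++k) kap_fin += (double)k * p[k];
  ks.push_back(kap_fin);
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["t"] = t, _["l1"] = l1, _["converged"] = converged,
                      _["iterations"] = iter,
                      _["t_samples"] = NumericVector(ts.begin(), ts.end()),
                      _["kappa_samples"] = NumericVector(ks.begin(), ks.end()));
}
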