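#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sparse column-compressed copy of a dense flux-operator matrix.
// Column sums are ~0 and off-diagonals >= 0 by construction upstream.
struct SpOp {
  int n;
  std::vector<int> ptr, row;
  std::vector<double> val;
  std::vector<double> diag;   // diagonal (outflow) per column
  std::vector<double> fire;   // threshold-crossing fraction per column

  void init(const NumericMatrix &M, const NumericVector &f) {
    n = M.nrow();
    ptr.assign(n + 1, 0);
    diag.assign(n, 0.0);
    fire.assign(f.begin(), f.end());
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i)
        if (M(i, j) != 0.0) ptr[j + 1]++;
      diag[j] = M(j, j);
    }
    for (int j = 0; j < n; ++j) ptr[j + 1] += ptr[j];
    row.resize(ptr[n]);
    val.resize(ptr[n]);
    std::vector<int> pos(ptr.begin(), ptr.end() - 1);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (M(i, j) != 0.0) { row[pos[j]] = i; val[pos[j]] = M(i, j); ++pos[j]; }
  }

  // y += scale * (M p)
  void apply(const std::vector<double> &p, double scale,
             std::vector<double> &y) const {
    for (int j = 0; j < n; ++j) {
      double pj = p[j] * scale;
      if (pj == 0.0) continue;
      for (int k = ptr[j]; k < ptr[j + 1]; ++k) y[row[k]] += val[k] * pj;
    }
  }

  double fire_dot(const std::vector<double> &p) const {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += fire[j] * p[j];
    return s;
  }
};

struct Pop {
  SpOp L;
  std::vector<SpOp> S;
  std::vector<double> p, f1, y1, f2;
  double max_leak_out = 0.0;
  std::vector<double> max_syn_out;  // per operator, max(-diag)
};

// [[Rcpp::export]]
List dipde_run_cpp(List pops, IntegerVector c_target, IntegerVector c_op,
                   IntegerVector c_srctype, IntegerVector c_source,
                   NumericVector c_indeg, IntegerVector c_delay,
                   NumericMatrix ext_rates, NumericVector init_rates,
                   double dt, int n_steps, double courant) {
  const int npop = pops.size();
  const int nconn = c_target.size();
  std::vector<Pop> P(npop);
  for (int q = 0; q < npop; ++q) {
    List pl = pops[q];
    NumericMatrix L = pl["L"];
    List Ss = pl["S"];
    List Fs = pl["F"];
    NumericVector p0 = pl["p0"];
    NumericVector zero(L.nrow());
    P[q].L.init(L, zero);
    P[q].S.resize(Ss.size());
    P[q].max_syn_out.resize(Ss.size());
    for (int s = 0; s < Ss.size(); ++s) {
      P[q].S[s].init(as<NumericMatrix>(Ss[s]), as<NumericVector>(Fs[s]));
      double m = 0.0;
      for (double d : P[q].S[s].diag) m = std::max(m, -d);
      P[q].max_syn_out[s] = m;
    }
    for (double d : P[q].L.diag) P[q].max_leak_out = std::max(P[q].max_leak_out, -d);
    P[q].p.assign(p0.begin(), p0.end());
    P[q].f1.assign(p0.size(), 0.0);
    P[q].y1.assign(p0.size(), 0.0);
    P[q].f2.assign(p0.size(), 0.0);
  }

  NumericMatrix rate_hist(n_steps, npop);       // Hz
  std::vector<std::vector<double> > lambda(npop);
  for (int q = 0; q < npop; ++q) lambda[q].assign(P[q].S.size(), 0.0);

  for (int k = 0; k < n_steps; ++k) {
    // read all delayed source rates first (Jacobi update)
    for (int q = 0; q < npop; ++q)
      std::fill(lambda[q].begin(), lambda[q].end(), 0.0);
    for (int c = 0; c < nconn; ++c) {
      double r;
      if (c_srctype[c] == 0) {               // internal: rates known up to k-1
        int idx = k - std::max(c_delay[c], 1);
        // delay buffers pre-filled with the source's initial rate
        r = (idx >= 0) ? rate_hist(idx, c_source[c]) : init_rates[c_source[c]];
      } else {                               // external: prescribed signal
        int idx = k - c_delay[c];
        if (idx < 0) idx = 0;                // buffer pre-filled with t=0 rate
        r = ext_rates(idx, c_source[c]);
      }
      lambda[c_target[c]][c_op[c]] += c_indeg[c] * r * 1e-3;  // events/ms
    }

    for (int q = 0; q < npop; ++q) {
      Pop &pp = P[q];
      double maxout = pp.max_leak_out;
      for (size_t s = 0; s < pp.S.size(); ++s)
        maxout += lambda[q][s] * pp.max_syn_out[s];
      int n_sub = std::max(1, (int)std::ceil(dt * maxout / courant));
      double h = dt / n_sub;
      double spike = 0.0;
      const int nb = (int)pp.p.size();
      // Heun (explicit trapezoid) sub-steps: second order, conservative,
      // and positivity-preserving for h * max outflow <= 1
      for (int sub = 0; sub < n_sub; ++sub) {
        std::fill(pp.f1.begin(), pp.f1.end(), 0.0);
        pp.L.apply(pp.p, 1.0, pp.f1);
        double fire_p = 0.0;
        for (size_t s = 0; s < pp.S.size(); ++s) {
          if (lambda[q][s] == 0.0) continue;
          pp.S[s].apply(pp.p, lambda[q][s], pp.f1);
          fire_p += lambda[q][s] * pp.S[s].fire_dot(pp.p);
        }
        for (int i = 0; i < nb; ++i) pp.y1[i] = pp.p[i] + h * pp.f1[i];
        std::fill(pp.f2.begin(), pp.f2.end(), 0.0);
        pp.L.apply(pp.y1, 1.0, pp.f2);
        double fire_y = 0.0;
        for (size_t s = 0; s < pp.S.size(); ++s) {
          if (lambda[q][s] == 0.0) continue;
          pp.S[s].apply(pp.y1, lambda[q][s], pp.f2);
          fire_y += lambda[q][s] * pp.S[s].fire_dot(pp.y1);
        }
        for (int i = 0; i < nb; ++i)
          pp.p[i] += 0.5 * h * (pp.f1[i] + pp.f2[i]);
        spike += 0.5 * h * (fire_p + fire_y);
      }
      for (double v : pp.p)
        if (v < -1e-12)
          stop("numerical scheme failure: negative probability mass");
      rate_hist(k, q) = 1000.0 * spike / dt;
    }
  }

  List finals(npop);
  for (int q = 0; q < npop; ++q)
    finals[q] = NumericVector(P[q].p.begin(), P[q].p.end());
  return List::create(_["rates"] = rate_hist, _["final"] = finals);
}
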