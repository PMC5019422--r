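#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One trial of a spiking leaky integrate-and-fire network with
// current-jump (shot-noise) synapses, exact exponential decay between
// grid times, Poisson background/stimulus event counts per step, and a
// fresh Bernoulli/in-degree connectivity realization.
//
// sizes      : neurons per population
// indeg      : target x source mean in-degree (each target neuron samples
//              round(indeg) sources uniformly with replacement)
// wmat       : target x source synaptic jump (mV)
// dmean, dsd : target x source delay mean / sd (ms); per-synapse delays
//              are drawn from a normal truncated below at one step
// bg_rate    : per-neuron effective background event rate (Hz) per pop
// stim_rate  : n_steps x npop per-neuron stimulus event rate (Hz)
// Uses the R RNG; seed with set.seed() before each trial.
// [[Rcpp::export]]
List lif_trial_cpp(IntegerVector sizes, NumericMatrix indeg,
                   NumericMatrix wmat, NumericMatrix dmean,
                   NumericMatrix dsd,
                   double tau_m, double v_theta, double v_reset,
                   NumericVector bg_rate, double bg_w,
                   NumericMatrix stim_rate, double stim_w,
                   double dt, int n_steps, double init_mean,
                   double init_sd, int bin_steps, int t_ref_steps) {
  const int npop = sizes.size();
  std::vector<int> offset(npop + 1, 0);
  for (int q = 0; q < npop; ++q) {
    if (sizes[q] < 1) stop("every population needs at least one neuron");
    offset[q + 1] = offset[q] + sizes[q];
  }
  const int N = offset[npop];
  std::vector<unsigned char> pop_of(N);
  for (int q = 0; q < npop; ++q)
    for (int i = offset[q]; i < offset[q + 1]; ++i) pop_of[i] = (unsigned char)q;

  // --- ring length covers the delay distribution support
  int max_d = 1;
  for (int t = 0; t < npop; ++t)
    for (int s = 0; s < npop; ++s) {
      int d = (int)std::ceil((dmean(t, s) + 4.0 * dsd(t, s)) / dt);
      max_d = std::max(max_d, d + 1);
    }
  const int ring = max_d;
  if (ring > 255) stop("delay distribution support exceeds 255 time steps");

  // --- connectivity realization: sample in-partners and per-synapse
  //     delays, store out-adjacency
  std::vector<int> syn_src, syn_tgt;
  std::vector<unsigned char> syn_d;
  {
    long total = 0;
    for (int t = 0; t < npop; ++t)
      for (int s = 0; s < npop; ++s)
        total += (long)sizes[t] * (long)std::lround(indeg(t, s));
    syn_src.reserve(total);
    syn_tgt.reserve(total);
    syn_d.reserve(total);
    for (int t = 0; t < npop; ++t)
      for (int s = 0; s < npop; ++s) {
        int K = (int)std::lround(indeg(t, s));
        if (K <= 0) continue;
        const double dm = dmean(t, s), ds = dsd(t, s);
        for (int n = offset[t]; n < offset[t + 1]; ++n)
          for (int k = 0; k < K; ++k) {
            int src = offset[s] + (int)(unif_rand() * sizes[s]);
            if (src >= offset[s + 1]) src = offset[s + 1] - 1;
            double d_ms = ds > 0 ? dm + ds * norm_rand() : dm;
            int d = (int)std::lround(d_ms / dt);
            if (d < 1) d = 1;
            if (d > ring - 1) d = ring - 1;
            syn_src.push_back(src);
            syn_tgt.push_back(n);
            syn_d.push_back((unsigned char)d);
          }
      }
  }
  const long nsyn = (long)syn_src.size();
  std::vector<long> out_ptr(N + 1, 0);
  for (long k = 0; k < nsyn; ++k) out_ptr[syn_src[k] + 1]++;
  for (int i = 0; i < N; ++i) out_ptr[i + 1] += out_ptr[i];
  std::vector<int> out_tgt(nsyn);
  std::vector<unsigned char> out_d(nsyn);
  {
    std::vector<long> pos(out_ptr.begin(), out_ptr.end() - 1);
    for (long k = 0; k < nsyn; ++k) {
      long p = pos[syn_src[k]]++;
      out_tgt[p] = syn_tgt[k];
      out_d[p] = syn_d[k];
    }
  }
  std::vector<int>().swap(syn_src);
  std::vector<int>().swap(syn_tgt);
  std::vector<unsigned char>().swap(syn_d);
  std::vector<double> v(N), pending((size_t)N * ring, 0.0);
  std::vector<int> refr(N, 0);
  for (int i = 0; i < N; ++i) v[i] = init_mean + init_sd * norm_rand();

  const double decay = std::exp(-dt / tau_m);
  const int n_bins = (n_steps + bin_steps - 1) / bin_steps;
  IntegerMatrix counts(n_bins, npop);
  std::vector<double> bg_mean(npop), stim_col(npop);
  for (int q = 0; q < npop; ++q) bg_mean[q] = bg_rate[q] * dt * 1e-3;

  int cur = 0;
  for (int k = 0; k < n_steps; ++k) {
    const int bin = k / bin_steps;
    for (int q = 0; q < npop; ++q)
      stim_col[q] = stim_rate(k, q) * dt * 1e-3;
    for (int i = 0; i < N; ++i) {
      const int q = pop_of[i];
      double *pend = &pending[(size_t)i * ring];
      double inj = pend[cur];
      pend[cur] = 0.0;
      if (refr[i] > 0) { refr[i]--; v[i] = v_reset; continue; }
      double vi = v[i] * decay + inj;
      if (bg_mean[q] > 0) vi += bg_w * R::rpois(bg_mean[q]);
      if (stim_col[q] > 0) vi += stim_w * R::rpois(stim_col[q]);
      if (vi >= v_theta) {
        counts(bin, q)++;
        vi = v_reset;
        refr[i] = t_ref_steps;
        for (long s = out_ptr[i]; s < out_ptr[i + 1]; ++s) {
          int tgt = out_tgt[s];
          int tq = pop_of[tgt];
          pending[(size_t)tgt * ring + (cur + out_d[s]) % ring] += wmat(tq, q);
        }
      }
      v[i] = vi;
    }
    cur = (cur + 1) % ring;
  }

  // rates in Hz: spikes / (neurons * bin width in s)
  NumericMatrix rates(n_bins, npop);
  const double bin_s = bin_steps * dt * 1e-3;
  for (int q = 0; q < npop; ++q)
    for (int b = 0; b < n_bins; ++b)
      rates(b, q) = counts(b, q) / (sizes[q] * bin_s);
  return List::create(_["rates"] = rates, _["counts"] = counts,
                      _["n_synapses"] = (double)nsyn);
}
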