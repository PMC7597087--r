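// GrowCut / Band-Based GrowCut cellular-automaton core.
//
// Fully synchronous attack-and-capture updates over a 2D or 3D grid held as
// an R column-major array. Every attack evaluation reads the pre-step state;
// for each defending cell the strongest successful local attacker is found
// first, then the strongest successful sampled remote attacker; the remote
// attacker captures only if strictly stronger than both the defence and the
// best local attack (ties go local). Tie among equal local attackers: first
// in the deterministic offset order supplied from R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int d;
  int dims[3];
  long stride[3];
  long n;
  void init(const IntegerVector &dv) {
    d = dv.size();
    n = 1;
    for (int j = 0; j < d; ++j) {
      dims[j] = dv[j];
      stride[j] = n;
      n *= dims[j];
    }
  }
  void coords(long idx, int *c) const {
    for (int j = d - 1; j >= 0; --j) {
      c[j] = (int)(idx / stride[j]);
      idx -= (long)c[j] * stride[j];
    }
  }
  // neighbour linear index, or -1 when the offset leaves the grid
  long shift(const int *c, const int *off) const {
    long idx = 0;
    for (int j = 0; j < d; ++j) {
      int cj = c[j] + off[j];
      if (cj < 0 || cj >= dims[j]) return -1;
      idx += (long)cj * stride[j];
    }
    return idx;
  }
};

inline double attack(double cp, double cq, double sq) {
  return (1.0 - std::fabs(cp - cq)) * sq;  // g(x) = 1 - x on [0,1] features
}

// k distinct in-grid band neighbours of cell c, uniform without replacement.
// Rejection sampling against the full offset table (uniform over the clipped
// subset), with a full-enumeration fallback for heavily clipped cells.
inline int sample_band(const Grid &g, const int *c, const IntegerMatrix &off,
                       int k, long *out, std::vector<long> &scratch) {
  const int m = off.nrow();
  int got = 0;
  const int cap = std::max(64, 16 * k);
  int tries = 0;
  int o[3];
  while (got < k && tries < cap) {
    ++tries;
    int j = (int)(unif_rand() * m);
    if (j >= m) j = m - 1;
    for (int a = 0; a < g.d; ++a) o[a] = off(j, a);
    long q = g.shift(c, o);
    if (q < 0) continue;
    bool dup = false;
    for (int t = 0; t < got; ++t)
      if (out[t] == q) { dup = true; break; }
    if (!dup) out[got++] = q;
  }
  if (got == k) return got;
  // fallback: enumerate the clipped band, excluding cells already drawn
  scratch.clear();
  for (int j = 0; j < m; ++j) {
    for (int a = 0; a < g.d; ++a) o[a] = off(j, a);
    long q = g.shift(c, o);
    if (q < 0) continue;
    bool dup = false;
    for (int t = 0; t < got; ++t)
      if (out[t] == q) { dup = true; break; }
    if (!dup) scratch.push_back(q);
  }
  int remaining = k - got;
  int avail = (int)scratch.size();
  if (avail <= remaining) {
    for (int t = 0; t < avail; ++t) out[got++] = scratch[t];
    return got;
  }
  // partial Fisher-Yates draw of `remaining` from scratch
  for (int t = 0; t < remaining; ++t) {
    int j = t + (int)(unif_rand() * (avail - t));
    if (j >= avail) j = avail - 1;
    std::swap(scratch[t], scratch[j]);
    out[got++] = scratch[t];
  }
  return got;
}

}  // namespace

// [[Rcpp::export]]
List bbg_run_cpp(NumericVector image, IntegerVector dims,
                 IntegerVector labels0, NumericVector strengths0,
                 IntegerMatrix local_off, IntegerMatrix band_off,
                 int k, int max_iter,
                 bool record_samples, bool record_history) {
  Grid g;
  g.init(dims);
  const bool has_band = band_off.nrow() > 0 && k > 0;
  const int n_local = local_off.nrow();

  IntegerVector lab_old = clone(labels0);
  NumericVector sig_old = clone(strengths0);
  IntegerVector lab_new(g.n);
  NumericVector sig_new(g.n);

  double n_local_wins = 0, n_remote_wins = 0, n_overrides = 0;
  int iterations = 0;
  bool converged = false;

  std::vector<long> ksamp(has_band ? k : 1);
  std::vector<long> scratch;
  std::vector<std::vector<int> > sample_log;  // per-iteration (cell,q) pairs
  List history(record_history ? max_iter : 0);

  int c[3], o[3];

  for (int t = 1; t <= max_iter; ++t) {
    long captures = 0;
    std::vector<int> iter_samples;
    for (long p = 0; p < g.n; ++p) {
      g.coords(p, c);
      const double cp = image[p];
      const double defense = sig_old[p];

      double best_local = -1.0;
      long best_local_q = -1;
      for (int j = 0; j < n_local; ++j) {
        for (int a = 0; a < g.d; ++a) o[a] = local_off(j, a);
        long q = g.shift(c, o);
        if (q < 0) continue;
        double att = attack(cp, image[q], sig_old[q]);
        if (att > best_local) { best_local = att; best_local_q = q; }
      }

      double best_remote = -1.0;
      long best_remote_q = -1;
      if (has_band) {
        int got = sample_band(g, c, band_off, k, ksamp.data(), scratch);
        for (int t2 = 0; t2 < got; ++t2) {
          long q = ksamp[t2];
          if (record_samples) {
            iter_samples.push_back((int)(p + 1));
            iter_samples.push_back((int)(q + 1));
          }
          double att = attack(cp, image[q], sig_old[q]);
          if (att > best_remote) { best_remote = att; best_remote_q = q; }
        }
      }

      const bool local_ok = best_local_q >= 0 && best_local > defense;
      const bool remote_ok = best_remote_q >= 0 && best_remote > defense;

      long winner = -1;
      double win_att = 0.0;
      if (remote_ok && (!local_ok || best_remote > best_local)) {
        winner = best_remote_q;
        win_att = best_remote;
        if (local_ok) n_overrides += 1; else n_remote_wins += 1;
      } else if (local_ok) {
        winner = best_local_q;
        win_att = best_local;
        n_local_wins += 1;
      }

      if (winner >= 0) {
        lab_new[p] = lab_old[winner];
        sig_new[p] = win_att;
        ++captures;
      } else {
        lab_new[p] = lab_old[p];
        sig_new[p] = defense;
      }
    }

    std::swap(lab_old, lab_new);
    std::swap(sig_old, sig_new);
    iterations = t;
    if (record_samples) sample_log.push_back(iter_samples);
    if (record_history) history[t - 1] = clone(lab_old);
    if (captures == 0) { converged = true; break; }
  }

  List samples;
  if (record_samples) {
    samples = List(sample_log.size());
    for (size_t i = 0; i < sample_log.size(); ++i) {
      const std::vector<int> &v = sample_log[i];
      IntegerMatrix m(v.size() / 2, 2);
      for (size_t r = 0; r < v.size() / 2; ++r) {
        m(r, 0) = v[2 * r];
        m(r, 1) = v[2 * r + 1];
      }
      samples[i] = m;
    }
  }
  if (record_history && iterations < max_iter) {
    List trimmed(iterations);
    for (int i = 0; i < iterations; ++i) trimmed[i] = history[i];
    history = trimmed;
  }

  return List::create(
      _["labels"] = lab_old, _["strengths"] = sig_old,
      _["iterations"] = iterations, _["converged"] = converged,
      _["local_wins"] = n_local_wins, _["remote_wins"] = n_remote_wins,
      _["remote_overrides"] = n_overrides,
      _["samples"] = samples, _["history"] = history);
}
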