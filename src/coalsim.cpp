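#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Piecewise male effective size looking backwards in time (generations):
//   [0, g_end)            : end_n                  (post-expansion, constant)
//   [g_end, g_end + g_dur): end_n * exp(-beta * (t - g_end))
//                           beta = log(end_n / start_n) / g_dur
//   [g_end + g_dur, Inf)  : start_n                (ancestral, constant)
// Continuous at both epoch boundaries.
struct SizeModel {
  double end_n, start_n, g_end, g_dur, beta;
};

static SizeModel make_model(double start_n, double end_n,
                            double g_end, double g_dur) {
  SizeModel m;
  m.start_n = start_n;
  m.end_n = end_n;
  m.g_end = g_end;
  m.g_dur = g_dur;
  m.beta = (g_dur > 0.0) ? std::log(end_n / start_n) / g_dur : 0.0;
  return m;
}

// Time s >= 0 such that the pair-coalescence hazard integral
//   int_{t0}^{t0+s} c / N(t) dt  equals H,
// with c = k(k-1)/2 for k lineages (haploid scaling: rate 1/N per pair per
// generation). Closed-form inversion within each epoch; residual hazard is
// carried across epoch boundaries.
static double wait_time(const SizeModel &m, double c, double t0, double H) {
  double t = t0;
  if (t < m.g_end) {
    double rate = c / m.end_n;
    double h_full = rate * (m.g_end - t);
    if (H <= h_full) return t + H / rate - t0;
    H -= h_full;
    t = m.g_end;
  }
  double b2 = m.g_end + m.g_dur;
  if (t < b2) {
    if (std::fabs(m.beta) < 1e-14) {
      double rate = c / m.end_n;
      double h_full = rate * (b2 - t);
      if (H <= h_full) return t + H / rate - t0;
      H -= h_full;
    } else {
      double e0 = std::exp(m.beta * (t - m.g_end));
      double eb = std::exp(m.beta * (b2 - m.g_end));
      double h_full = c / (m.end_n * m.beta) * (eb - e0);
      if (H <= h_full) {
        double s = std::log(e0 + H * m.end_n * m.beta / c) / m.beta -
                   (t - m.g_end);
        return t + s - t0;
      }
      H -= h_full;
    }
    t = b2;
  }
  return t + H * m.start_n / c - t0;
}

// One replicate: simulate the genealogy of n tips and accumulate the three
// tree statistics without materialising the tree. Cluster bookkeeping:
//   size     - number of tips in the cluster
//   rtime    - coalescent time (generations) of the cluster's root node
//   sumd     - sum over tips of the path length (current length units:
//              generations, or SNPs in mutate mode) from cluster root to tip
//   sumsq    - sum of squared root-to-tip path lengths
//   intsum   - total internal-branch length strictly inside the cluster
// RNG draws per coalescence, in order: waiting-time uniform, pair-choice
// uniform, then (mutate mode only) two Poisson branch-length draws.
static void sim_one(int n, const SizeModel &m, bool mutate, double mu_len,
                    double *out) {
  std::vector<int> size(n, 1);
  std::vector<double> rtime(n, 0.0), sumd(n, 0.0), sumsq(n, 0.0),
      intsum(n, 0.0);
  double t = 0.0, TER = 0.0, S1 = 0.0, S2 = 0.0, W1 = 0.0, W2 = 0.0;

  for (int k = n; k >= 2; --k) {
    double c = 0.5 * k * (k - 1);
    double u = unif_rand();
    while (u <= 0.0 || u >= 1.0) u = unif_rand();
    t += wait_time(m, c, t, -std::log(u));

    int npairs = k * (k - 1) / 2;
    int idx = (int)(unif_rand() * npairs);
    if (idx >= npairs) idx = npairs - 1;
    int i = 0, j = -1;
    for (;; ++i) {
      int cnt = k - 1 - i;
      if (idx < cnt) { j = i + 1 + idx; break; }
      idx -= cnt;
    }

    double lenA = t - rtime[i], lenB = t - rtime[j];
    if (mutate) {
      lenA = R::rpois(lenA * mu_len);
      lenB = R::rpois(lenB * mu_len);
    }
    int nA = size[i], nB = size[j];
    if (nA == 1) TER += lenA; else { S1 += lenA; S2 += lenA * intsum[i]; }
    if (nB == 1) TER += lenB; else { S1 += lenB; S2 += lenB * intsum[j]; }

    double SdA = sumd[i] + nA * lenA;
    double SqA = sumsq[i] + 2.0 * lenA * sumd[i] + nA * lenA * lenA;
    double SdB = sumd[j] + nB * lenB;
    double SqB = sumsq[j] + 2.0 * lenB * sumd[j] + nB * lenB * lenB;
    // pairs split by this node: depth of pair (a in A, b in B) is the mean
    // of the two root-to-tip path lengths from the new node
    W1 += 0.5 * (nB * SdA + nA * SdB);
    W2 += 0.25 * (nB * SqA + 2.0 * SdA * SdB + nA * SqB);

    intsum[i] += intsum[j] + (nA >= 2 ? lenA : 0.0) + (nB >= 2 ? lenB : 0.0);
    sumd[i] = SdA + SdB;
    sumsq[i] = SqA + SqB;
    size[i] = nA + nB;
    rtime[i] = t;
    int last = k - 1;
    if (j != last) {
      size[j] = size[last]; rtime[j] = rtime[last]; sumd[j] = sumd[last];
      sumsq[j] = sumsq[last]; intsum[j] = intsum[last];
    }
  }

  double L = TER + S1;
  double P = 0.5 * n * (n - 1);
  out[3] = t;      // TMRCA in generations
  out[4] = L;      // total branch length (generations or SNPs)
  if (L <= 0.0) {  // possible in mutate mode only: no variants at all
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL;
    return;
  }
  out[0] = (S1 > 0.0) ? (TER / L) / (S1 / L + S2 / (L * L)) : R_PosInf;
  double mval = W1 / (P * L);
  double var = W2 / (P * L * L) - mval * mval;
  out[1] = mval;
  out[2] = std::sqrt(var > 0.0 ? var : 0.0);
}

// Simulate `reps` genealogies of `n_tips` samples under the expansion model
// (times in generations) and return per-replicate statistics computed on
// trees normalised to total length 1: columns r, tmrca_mean, tmrca_sd,
// tmrca_gen (unnormalised), total_len (unnormalised). In mutate mode branch
// lengths are replaced by Poisson(length * mu_len) variant counts before the
// statistics are taken; replicates with no variants at all give NA rows.
// [[Rcpp::export]]
NumericMatrix cpp_scenario_stats(int n_tips, double start_n, double end_n,
                                 double g_end, double g_dur, int reps,
                                 bool mutate, double mu_len) {
  if (n_tips < 2) stop("need at least 2 tips");
  if (start_n < 1.0 || end_n < 1.0) stop("population sizes must be >= 1");
  if (g_end < 0.0 || g_dur < 0.0) stop("epoch times must be non-negative");
  SizeModel m = make_model(start_n, end_n, g_end, g_dur);
  NumericMatrix out(reps, 5);
  double row[5];
  for (int r = 0; r < reps; ++r) {
    sim_one(n_tips, m, mutate, mu_len, row);
    for (int c = 0; c < 5; ++c) out(r, c) = row[c];
  }
  colnames(out) = CharacterVector::create("r", "tmrca_mean", "tmrca_sd",
                                          "tmrca_gen", "total_len");
  return out;
}
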