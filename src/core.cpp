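// Compiled inner loops: context-dependent rate tensor, dinucleotide
// composition derivative, equilibrium solver, and the Gillespie sequence
// evolution simulator. Nucleotides are coded 0..3 = A,C,G,T throughout;
// dinucleotide proportions are 4x4 column-major [first, second].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int mut_index(int j, int l) {
  // 12 ordered substitutions (from, to) lexicographic: A>C=0, A>G, A>T, C>A, ...
  return j * 3 + (l - (l > j ? 1 : 0));
}

static inline double q_entry(int j, int l, double theta, double kappa) {
  // HKY-style default rate: theta toward C/G, (1-theta) toward A/T,
  // times kappa for transitions (A<->G, C<->T, i.e. |j-l| == 2).
  double base = (l == 1 || l == 2) ? theta : 1.0 - theta;
  return (std::abs(j - l) == 2) ? kappa * base : base;
}

// rates[i + 4j + 16l + 64k] = f_up(i, j->l) * Q_jl * f_down(j->l, k), 0 if j==l
// [[Rcpp::export]]
NumericVector dc_rate_array(NumericMatrix up, NumericMatrix down,
                            double kappa, double theta) {
  NumericVector rates(256);
  for (int j = 0; j < 4; ++j)
    for (int l = 0; l < 4; ++l) {
      if (l == j) continue;
      int m = mut_index(j, l);
      double q = q_entry(j, l, theta, kappa);
      for (int i = 0; i < 4; ++i)
        for (int k = 0; k < 4; ++k)
          rates[i + 4 * j + 16 * l + 64 * k] = up(i, m) * q * down(m, k);
    }
  return rates;
}

static void deriv_core(const double* d, const double* rates, double* dd) {
  double m[4];
  for (int j = 0; j < 4; ++j) {
    m[j] = 0.0;
    for (int i = 0; i < 4; ++i) m[j] += d[i + 4 * j];
  }
  for (int x = 0; x < 16; ++x) dd[x] = 0.0;
  for (int j = 0; j < 4; ++j) {
    if (m[j] < 1e-14) continue;  // removable singularity of d_ij d_jk / m_j
    for (int i = 0; i < 4; ++i) {
      double dij = d[i + 4 * j];
      if (dij == 0.0) continue;
      for (int k = 0; k < 4; ++k) {
        double t = dij * d[j + 4 * k] / m[j];
        if (t == 0.0) continue;
        for (int l = 0; l < 4; ++l) {
          if (l == j) continue;
          double phi = t * rates[i + 4 * j + 16 * l + 64 * k];
          if (phi == 0.0) continue;
          dd[i + 4 * l] += phi;
          dd[l + 4 * k] += phi;
          dd[i + 4 * j] -= phi;
          dd[j + 4 * k] -= phi;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector dc_deriv(NumericVector d, NumericVector rates) {
  NumericVector dd(16);
  deriv_core(d.begin(), rates.begin(), dd.begin());
  return dd;
}

static double max_abs(const double* v, int n) {
  double r = 0.0;
  for (int i = 0; i < n; ++i) r = std::max(r, std::abs(v[i]));
  return r;
}

static void rk4_step(double* d, const double* rates, double dt) {
  double k1[16], k2[16], k3[16], k4[16], tmp[16];
  deriv_core(d, rates, k1);
  for (int i = 0; i < 16; ++i) tmp[i] = d[i] + 0.5 * dt * k1[i];
  deriv_core(tmp, rates, k2);
  for (int i = 0; i < 16; ++i) tmp[i] = d[i] + 0.5 * dt * k2[i];
  deriv_core(tmp, rates, k3);
  for (int i = 0; i < 16; ++i) tmp[i] = d[i] + dt * k3[i];
  deriv_core(tmp, rates, k4);
  for (int i = 0; i < 16; ++i)
    d[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Relaxation (RK4, step bounded by the fastest total event rate) down to a
// loose residual, then a damped least-squares Newton polish on the
// stationarity system augmented with the conserved linear invariants
// (total probability and the three independent margin differences), which
// make the raw 16x16 Jacobian singular.
// [[Rcpp::export]]
List dc_equilibrium(NumericVector rates, NumericVector d0,
                    double tol = 1e-10, double polish_tol = 1e-13,
                    double u_max = 4000.0) {
  const double* Rt = rates.begin();
  double d[16];
  double s0 = 0.0;
  for (int i = 0; i < 16; ++i) s0 += d0[i];
  for (int i = 0; i < 16; ++i) d[i] = d0[i] / s0;

  // max total exit rate over trinucleotide contexts bounds the stiffness
  double rmax = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 4; ++k) {
        double s = 0.0;
        for (int l = 0; l < 4; ++l)
          if (l != j) s += Rt[i + 4 * j + 16 * l + 64 * k];
        rmax = std::max(rmax, s);
      }
  if (rmax <= 0.0) stop("all substitution rates are zero");
  double dt = 0.25 / rmax;

  double F[16];
  deriv_core(d, Rt, F);
  double res = max_abs(F, 16);
  double u = 0.0;
  int n_steps = 0;

  // phase 1: relax until the Newton basin (or a still-loose residual)
  while (res > 1e-5 && u < u_max) {
    for (int s = 0; s < 25; ++s) { rk4_step(d, Rt, dt); u += dt; }
    n_steps += 25;
    double sum = 0.0;
    for (int i = 0; i < 16; ++i) { if (d[i] < 0.0) d[i] = 0.0; sum += d[i]; }
    for (int i = 0; i < 16; ++i) d[i] /= sum;
    deriv_core(d, Rt, F);
    res = max_abs(F, 16);
  }

  // phase 2: Newton polish
  int newton_iter = 0;
  bool stalled = false;
  for (; newton_iter < 80; ++newton_iter) {
    deriv_core(d, Rt, F);
    res = max_abs(F, 16);
    if (res < polish_tol) break;
    arma::mat J(20, 16, arma::fill::zeros);
    arma::vec Fa(20, arma::fill::zeros);
    for (int i = 0; i < 16; ++i) Fa(i) = F[i];
    double dp[16], Fp[16];
    for (int c = 0; c < 16; ++c) {
      double h = 1e-7 * (std::abs(d[c]) + 1e-7);
      std::copy(d, d + 16, dp);
      dp[c] += h;
      deriv_core(dp, Rt, Fp);
      for (int r = 0; r < 16; ++r) J(r, c) = (Fp[r] - F[r]) / h;
    }
    double sum = 0.0;
    for (int i = 0; i < 16; ++i) sum += d[i];
    Fa(16) = sum - 1.0;
    for (int c = 0; c < 16; ++c) J(16, c) = 1.0;
    for (int j = 0; j < 3; ++j) {       // margin differences for A, C, G
      double g = 0.0;
      for (int i = 0; i < 4; ++i) g += d[i + 4 * j] - d[j + 4 * i];
      Fa(17 + j) = g;
      for (int i = 0; i < 4; ++i) {
        if (i == j) continue;
        J(17 + j, i + 4 * j) += 1.0;
        J(17 + j, j + 4 * i) -= 1.0;
      }
    }
    arma::vec step;
    bool ok = arma::solve(step, J, Fa, arma::solve_opts::fast);
    if (!ok) { stalled = true; break; }
    double lambda = 1.0;
    bool accepted = false;
    for (int t = 0; t < 40; ++t) {
      double dn[16], mn = 0.0;
      for (int i = 0; i < 16; ++i) { dn[i] = d[i] - lambda * step(i); mn = std::min(mn, dn[i]); }
      deriv_core(dn, Rt, Fp);
      double rn = max_abs(Fp, 16);
      if (mn > -1e-12 && rn < res * (1.0 - 1e-6 * lambda)) {
        for (int i = 0; i < 16; ++i) d[i] = std::max(dn[i], 0.0);
        accepted = true;
        break;
      }
      lambda *= 0.5;
    }
    if (!accepted) {
      // leave the stall by further relaxation, then retry
      if (u >= u_max) { stalled = true; break; }
      for (int s = 0; s < 200; ++s) { rk4_step(d, Rt, dt); u += dt; }
      n_steps += 200;
    }
  }
  deriv_core(d, Rt, F);
  res = max_abs(F, 16);

  NumericVector out(16);
  for (int i = 0; i < 16; ++i) out[i] = d[i];
  return List::create(_["d"] = out, _["residual"] = res,
                      _["converged"] = (res < tol) && !stalled,
                      _["u"] = u, _["rk4_steps"] = n_steps,
                      _["newton_iterations"] = newton_iter);
}

// ---- Gillespie simulator -------------------------------------------------

struct Fenwick {
  int n;
  std::vector<double> t;
  explicit Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double delta) { for (++i; i <= n; i += i & -i) t[i] += delta; }
  double total() const {
    double s = 0.0;
    for (int i = n; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // largest index with prefix sum < x
  int search(double x) const {
    int pos = 0, log = 1;
    while ((1 << log) <= n) ++log;
    for (int pw = 1 << (log - 1); pw > 0; pw >>= 1)
      if (pos + pw <= n && t[pos + pw] < x) { pos += pw; x -= t[pos]; }
    return std::min(pos, n - 1);
  }
};

static inline double site_rate(const std::vector<int>& seq, int pos,
                               const double* rates, bool circular) {
  int n = seq.size();
  if (!circular && (pos == 0 || pos == n - 1)) return 0.0;  // fixed ends
  int i = seq[(pos - 1 + n) % n], j = seq[pos], k = seq[(pos + 1) % n];
  double s = 0.0;
  for (int l = 0; l < 4; ++l)
    if (l != j) s += rates[i + 4 * j + 16 * l + 64 * k];
  return s;
}

// Evolves seq0 for n_events substitutions under r(i, j->l, k); events with
// index >= record_start (0-based) are returned as (ref, alt, five, three)
// rows. Uses R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export]]
List dc_evolve(IntegerVector seq0, NumericVector rates, double n_events,
               bool circular = true, double record_start = -1.0) {
  int n = seq0.size();
  if (n < 3) stop("sequence too short to evolve");
  std::vector<int> seq(seq0.begin(), seq0.end());
  for (int p = 0; p < n; ++p)
    if (seq[p] < 0 || seq[p] > 3) stop("sequence codes must be in 0..3");
  const double* R = rates.begin();

  std::vector<double> srate(n);            // shadow of per-site exit rates
  Fenwick fen(n);
  for (int p = 0; p < n; ++p) {
    srate[p] = site_rate(seq, p, R, circular);
    fen.add(p, srate[p]);
  }
  double total = fen.total();
  if (total <= 0.0) stop("total substitution rate is zero");

  std::vector<int> rec_ref, rec_alt, rec_five, rec_three;
  NumericVector type_counts(12);
  long long nev = (long long)n_events;
  const long long rebuild_every = 1 << 20;

  for (long long e = 0; e < nev; ++e) {
    if (e > 0 && e % rebuild_every == 0) {  // control float drift
      std::fill(fen.t.begin(), fen.t.end(), 0.0);
      for (int p = 0; p < n; ++p) {
        srate[p] = site_rate(seq, p, R, circular);
        fen.add(p, srate[p]);
      }
      total = fen.total();
    }
    double u = unif_rand() * total;
    int pos = fen.search(u);
    int i = seq[(pos - 1 + n) % n], j = seq[pos], k = seq[(pos + 1) % n];
    double rs[4], cum = 0.0;
    for (int l = 0; l < 4; ++l) {
      rs[l] = (l == j) ? 0.0 : R[i + 4 * j + 16 * l + 64 * k];
      cum += rs[l];
    }
    if (cum <= 0.0) { --e; continue; }   // zero-rate site hit by drift; resample
    double v = unif_rand() * cum;
    int l = 0;
    double acc = rs[0];
    while (l < 3 && v >= acc) acc += rs[++l];
    type_counts[mut_index(j, l)] += 1.0;
    if (record_start >= 0.0 && (double)e >= record_start) {
      rec_ref.push_back(j); rec_alt.push_back(l);
      rec_five.push_back(i); rec_three.push_back(k);
    }
    seq[pos] = l;
    for (int p = pos - 1; p <= pos + 1; ++p) {
      if (!circular && (p < 0 || p >= n)) continue;
      int pp = (p + n) % n;
      double newr = site_rate(seq, pp, R, circular);
      fen.add(pp, newr - srate[pp]);
      total += newr - srate[pp];
      srate[pp] = newr;
    }
  }

  IntegerMatrix rec(rec_ref.size(), 4);
  for (size_t r = 0; r < rec_ref.size(); ++r) {
    rec(r, 0) = rec_ref[r]; rec(r, 1) = rec_alt[r];
    rec(r, 2) = rec_five[r]; rec(r, 3) = rec_three[r];
  }
  IntegerVector seq_out(seq.begin(), seq.end());
  return List::create(_["seq"] = seq_out, _["type_counts"] = type_counts,
                      _["records"] = rec);
}
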