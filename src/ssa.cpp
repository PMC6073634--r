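// Gillespie direct-method kernels for GARD dynamics.
//
// All kernels draw from R's RNG stream (unif_rand), so every simulation is a
// pure function of (state, parameters, set.seed()).  Per SSA step exactly two
// uniforms are consumed: one for the waiting time, one for channel selection.
// The catalytic load s_i = sum_j beta(i,j) n_j is maintained incrementally,
// giving O(N_G) work per event instead of O(N_G^2).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct GardState {
  int ng;
  std::vector<int> n;      // counts per type
  long long N;             // total count
  std::vector<double> s;   // catalytic load per target type
  const double *beta;      // column-major ng x ng

  void init(const IntegerVector &counts, const NumericMatrix &b) {
    ng = b.nrow();
    beta = b.begin();
    n.assign(counts.begin(), counts.end());
    N = 0;
    for (int i = 0; i < ng; ++i) N += n[i];
    s.assign(ng, 0.0);
    for (int j = 0; j < ng; ++j) {
      if (n[j] == 0) continue;
      const double *col_j = beta + (size_t)j * ng; // beta(i,j) over i
      for (int i = 0; i < ng; ++i) s[i] += col_j[i] * n[j];
    }
  }

  void add(int t) {
    n[t] += 1; N += 1;
    const double *col = beta + (size_t)t * ng;
    for (int i = 0; i < ng; ++i) s[i] += col[i];
  }

  void remove(int t) {
    n[t] -= 1; N -= 1;
    const double *col = beta + (size_t)t * ng;
    for (int i = 0; i < ng; ++i) s[i] -= col[i];
  }
};

// One SSA step over the 2*ng entry/exit channels.  rho may be scaled by a
// finite-supply budget (budget == NULL means infinite supply).  Returns the
// elapsed time; *event gets the channel (0..ng-1 entry, ng..2ng-1 exit).
// Exits are disabled at N == 1 so the assembly never empties.
double gard_step(GardState &st, const double *kf, const double *kb,
                 const double *rho, const double *budget_scale,
                 int *event) {
  const int ng = st.ng;
  const double N = (double)st.N;
  std::vector<double> fwd(ng), bwd(ng);
  double total = 0.0;
  for (int i = 0; i < ng; ++i) {
    const double C = 1.0 + st.s[i] / N;
    double r = rho[i];
    if (budget_scale) r *= budget_scale[i];
    fwd[i] = kf[i] * r * N * C;
    total += fwd[i];
  }
  for (int i = 0; i < ng; ++i) {
    const double C = 1.0 + st.s[i] / N;
    bwd[i] = (st.N > 1) ? kb[i] * st.n[i] * C : 0.0;
    total += bwd[i];
  }
  if (!(total > 0.0)) stop("all propensities are zero: stalled system");
  const double dt = -std::log(unif_rand()) / total;
  const double u = unif_rand() * total;
  double acc = 0.0;
  int ev = -1;
  for (int i = 0; i < ng && ev < 0; ++i) {
    acc += fwd[i];
    if (u < acc) ev = i;
  }
  for (int i = 0; i < ng && ev < 0; ++i) {
    acc += bwd[i];
    if (u < acc) ev = ng + i;
  }
  if (ev < 0) { // numerical edge: pick last positive channel
    for (int i = 2 * ng - 1; i >= 0 && ev < 0; --i) {
      double p = (i < ng) ? fwd[i] : bwd[i - ng];
      if (p > 0.0) ev = i;
    }
  }
  *event = ev;
  return dt;
}

void apply_event(GardState &st, int ev) {
  if (ev < st.ng) st.add(ev); else st.remove(ev - st.ng);
}

std::vector<int> seed_counts(int ng, int n_min) {
  std::vector<int> n(ng, 0);
  for (int k = 0; k < n_min; ++k) {
    int t = (int)(unif_rand() * ng);
    if (t >= ng) t = ng - 1;
    n[t] += 1;
  }
  return n;
}

// Partition an expanded molecule list into exact halves by partial
// Fisher-Yates: N/2 uniform draws, multivariate hypergeometric by symmetry.
void split_counts(const std::vector<int> &n, int ng,
                  std::vector<int> &p1, std::vector<int> &p2) {
  std::vector<int> mol;
  for (int i = 0; i < ng; ++i)
    for (int k = 0; k < n[i]; ++k) mol.push_back(i);
  const int N = (int)mol.size();
  const int half = N / 2;
  p1.assign(ng, 0); p2.assign(ng, 0);
  for (int k = 0; k < half; ++k) {
    int j = k + (int)(unif_rand() * (N - k));
    if (j >= N) j = N - 1;
    std::swap(mol[k], mol[j]);
    p1[mol[k]] += 1;
  }
  for (int k = half; k < N; ++k) p2[mol[k]] += 1;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_seed_assembly(int n_types, int n_min) {
  std::vector<int> n = seed_counts(n_types, n_min);
  return IntegerVector(n.begin(), n.end());
}

// [[Rcpp::export]]
List cpp_step(IntegerVector counts, NumericMatrix beta, NumericVector kf,
              NumericVector kb, NumericVector rho) {
  GardState st; st.init(counts, beta);
  if (st.N < 1) stop("empty assembly");
  int ev = -1;
  double dt = gard_step(st, kf.begin(), kb.begin(), rho.begin(), nullptr, &ev);
  apply_event(st, ev);
  return List::create(_["counts"] = IntegerVector(st.n.begin(), st.n.end()),
                      _["dt"] = dt,
                      _["event"] = ev + 1); // 1-based channel id for R
}

// [[Rcpp::export]]
List cpp_grow(IntegerVector counts, NumericMatrix beta, NumericVector kf,
              NumericVector kb, NumericVector rho, int n_max,
              double max_steps) {
  GardState st; st.init(counts, beta);
  if (st.N < 1) stop("empty assembly");
  if (st.N > n_max) stop("assembly larger than n_max");
  double t = 0.0, steps = 0.0;
  while (st.N < n_max) {
    if (++steps > max_steps) stop("stalled growth: step budget exceeded");
    int ev = -1;
    t += gard_step(st, kf.begin(), kb.begin(), rho.begin(), nullptr, &ev);
    apply_event(st, ev);
  }
  return List::create(_["counts"] = IntegerVector(st.n.begin(), st.n.end()),
                      _["time"] = t, _["steps"] = steps);
}

// [[Rcpp::export]]
List cpp_split(IntegerVector counts) {
  int ng = counts.size();
  std::vector<int> n(counts.begin(), counts.end()), p1, p2;
  long long N = 0; for (int i = 0; i < ng; ++i) N += n[i];
  if (N % 2 != 0) stop("split requires an even total count");
  split_counts(n, ng, p1, p2);
  return List::create(_["first"] = IntegerVector(p1.begin(), p1.end()),
                      _["second"] = IntegerVector(p2.begin(), p2.end()));
}

// Trace mode: seed -> (grow to n_max, record, split, keep one progeny) x n_gen.
// [[Rcpp::export]]
List cpp_run_trace(NumericMatrix beta, NumericVector kf, NumericVector kb,
                   NumericVector rho, int n_max, int n_min, int n_gen,
                   double max_steps, IntegerVector init) {
  const int ng = beta.nrow();
  std::vector<int> n;
  if (init.size() == 0) n = seed_counts(ng, n_min);
  else n.assign(init.begin(), init.end());

  IntegerMatrix comp(n_gen, ng);
  NumericVector times(n_gen);
  double t = 0.0;

  GardState st;
  for (int g = 0; g < n_gen; ++g) {
    st.init(IntegerVector(n.begin(), n.end()), beta);
    double steps = 0.0;
    while (st.N < n_max) {
      if (++steps > max_steps) stop("stalled growth: step budget exceeded");
      int ev = -1;
      t += gard_step(st, kf.begin(), kb.begin(), rho.begin(), nullptr, &ev);
      apply_event(st, ev);
    }
    for (int i = 0; i < ng; ++i) comp(g, i) = st.n[i];
    times[g] = t;
    std::vector<int> p1, p2;
    split_counts(st.n, ng, p1, p2);
    n = (unif_rand() < 0.5) ? p1 : p2;
  }
  return List::create(_["composition"] = comp, _["time"] = times);
}

// Finite-supply, no-fission run: rho_i(t) = conc_per_unit * budget_i(t);
// the external budget is decremented on entry and restored on exit.
// [[Rcpp::export]]
List cpp_run_equilibrium(NumericMatrix beta, NumericVector kf,
                         NumericVector kb, NumericVector budget,
                         double conc_per_unit, IntegerVector init,
                         double max_steps, int record_every) {
  const int ng = beta.nrow();
  GardState st; st.init(init, beta);
  if (st.N < 1) stop("empty assembly");
  double tot_budget = 0.0;
  for (int i = 0; i < ng; ++i) tot_budget += budget[i];
  if (!(tot_budget > 0.0)) stop("zero external budget");

  std::vector<double> b(budget.begin(), budget.end());
  std::vector<double> rho(ng, conc_per_unit);

  std::vector<double> rec_t;
  std::vector<int> rec_n;
  std::vector<long long> rec_N;
  double t = 0.0, steps = 0.0;
  int since_rec = 0;
  auto record = [&](void) {
    rec_t.push_back(t);
    rec_N.push_back(st.N);
    for (int i = 0; i < ng; ++i) rec_n.push_back(st.n[i]);
    since_rec = 0;
  };
  record();
  while (steps < max_steps) {
    steps += 1.0;
    int ev = -1;
    t += gard_step(st, kf.begin(), kb.begin(), rho.data(), b.data(), &ev);
    if (ev < ng) b[ev] -= 1.0; else b[ev - ng] += 1.0;
    apply_event(st, ev);
    if (++since_rec == record_every) record();
  }
  if (since_rec > 0) record();
  const int nrec = (int)rec_t.size();
  IntegerMatrix comp(nrec, ng);
  NumericVector tt(nrec), NN(nrec);
  for (int r = 0; r < nrec; ++r) {
    tt[r] = rec_t[r];
    NN[r] = (double)rec_N[r];
    for (int i = 0; i < ng; ++i) comp(r, i) = rec_n[(size_t)r * ng + i];
  }
  return List::create(_["composition"] = comp, _["time"] = tt,
                      _["size"] = NN,
                      _["budget"] = NumericVector(b.begin(), b.end()));
}

// ---------------------------------------------------------------------------
// Dimer-level polymer GARD (P-GARD).
//
// Species: ng monomers + ng*ng ordered dimers (i,j).  N counts monomer
// equivalents (free monomers + 2 per dimer).  Channel layout per step:
//   [0, ng)        monomer entry
//   [ng, 2ng)      monomer exit
//   [2ng, 2ng+ng2) dimerization of (i,j), row-major
//   [.., +ng2)     cleavage of (i,j), row-major
// Catalytic enhancements are additive over sub-sites and computed on the fly:
//   monomer a on entry/exit of i:      beta(i,a)
//   dimer (a,b) on entry/exit of i:    (beta(i,a) + beta(i,b)) / 2
//   monomer a on dimerization (i,j):   (beta(i,a) + beta(j,a)) / 2
//   dimer (a,b) on dimerization (i,j): (beta(i,a) + beta(j,b)) / 2
// With zero dimer rates and no dimers present this consumes the identical
// RNG stream as cpp_run_trace (degeneracy contract).
// [[Rcpp::export]]
List cpp_run_pgard(NumericMatrix beta, NumericVector kf, NumericVector kb,
                   NumericVector rho, double k_dim, double k_cleave,
                   int n_max, int n_min, int n_gen, double max_steps,
                   IntegerVector init) {
  const int ng = beta.nrow();
  const int ng2 = ng * ng;
  const double *B = beta.begin(); // column-major: B[i + j*ng] = beta(i,j)

  std::vector<int> mono;
  if (init.size() == 0) mono = seed_counts(ng, n_min);
  else mono.assign(init.begin(), init.end());
  std::vector<int> dim(ng2, 0); // dim[i*ng + j], row-major ordered pair (i,j)

  // incremental sums
  std::vector<double> s(ng, 0.0);   // sum_a beta(i,a) mono_a
  std::vector<double> d1(ng, 0.0);  // sum_a beta(i,a) u_a, u_a = first-slot dimer count
  std::vector<double> d2(ng, 0.0);  // sum_a beta(i,a) w_a, w_a = second-slot count
  long long N = 0;
  for (int a = 0; a < ng; ++a) {
    N += mono[a];
    if (mono[a] > 0)
      for (int i = 0; i < ng; ++i) s[i] += B[i + (size_t)a * ng] * mono[a];
  }

  auto add_mono = [&](int t) {
    mono[t] += 1; N += 1;
    for (int i = 0; i < ng; ++i) s[i] += B[i + (size_t)t * ng];
  };
  auto rm_mono = [&](int t) {
    mono[t] -= 1; N -= 1;
    for (int i = 0; i < ng; ++i) s[i] -= B[i + (size_t)t * ng];
  };
  auto form_dimer = [&](int i, int j) {
    mono[i] -= 1; mono[j] -= 1; dim[i * ng + j] += 1;
    for (int x = 0; x < ng; ++x) {
      s[x] -= B[x + (size_t)i * ng] + B[x + (size_t)j * ng];
      d1[x] += B[x + (size_t)i * ng];
      d2[x] += B[x + (size_t)j * ng];
    }
  };
  auto cleave_dimer = [&](int i, int j) {
    mono[i] += 1; mono[j] += 1; dim[i * ng + j] -= 1;
    for (int x = 0; x < ng; ++x) {
      s[x] += B[x + (size_t)i * ng] + B[x + (size_t)j * ng];
      d1[x] -= B[x + (size_t)i * ng];
      d2[x] -= B[x + (size_t)j * ng];
    }
  };

  const bool dimers_possible = (k_dim > 0.0) || (k_cleave > 0.0);
  long long n_dim_total = 0;

  IntegerMatrix mono_out(n_gen, ng);
  IntegerMatrix dim_out(n_gen, ng2);
  NumericVector times(n_gen), dimer_frac(n_gen);
  double t = 0.0;

  std::vector<double> fwd(ng), bwd(ng), pdim, pclv;
  if (dimers_possible) { pdim.assign(ng2, 0.0); pclv.assign(ng2, 0.0); }

  for (int g = 0; g < n_gen; ++g) {
    double steps = 0.0;
    while (N < n_max) {
      if (++steps > max_steps) stop("stalled growth: step budget exceeded");
      const double Nd = (double)N;
      double total = 0.0;
      for (int i = 0; i < ng; ++i) {
        const double C = 1.0 + (s[i] + 0.5 * (d1[i] + d2[i])) / Nd;
        fwd[i] = kf[i] * rho[i] * Nd * C;
        total += fwd[i];
      }
      for (int i = 0; i < ng; ++i) {
        const double C = 1.0 + (s[i] + 0.5 * (d1[i] + d2[i])) / Nd;
        bwd[i] = (N > 1) ? kb[i] * mono[i] * C : 0.0;
        total += bwd[i];
      }
      const bool any_dim_now = dimers_possible && (k_dim > 0.0 || n_dim_total > 0);
      if (any_dim_now) {
        for (int i = 0; i < ng; ++i) {
          for (int j = 0; j < ng; ++j) {
            const int idx = i * ng + j;
            const double E = 0.5 * (s[i] + s[j]) + 0.5 * (d1[i] + d2[j]);
            const double fac = 1.0 + E / Nd;
            const double pairs =
                (double)mono[i] * (double)(mono[j] - (i == j ? 1 : 0));
            pdim[idx] = (k_dim > 0.0 && pairs > 0.0) ? k_dim * pairs * fac : 0.0;
            pclv[idx] = (k_cleave > 0.0 && dim[idx] > 0)
                            ? k_cleave * dim[idx] * fac : 0.0;
            total += pdim[idx] + pclv[idx];
          }
        }
      }
      if (!(total > 0.0)) stop("all propensities are zero: stalled system");
      t += -std::log(unif_rand()) / total;
      const double u = unif_rand() * total;
      double acc = 0.0;
      int ev = -1;
      for (int i = 0; i < ng && ev < 0; ++i) { acc += fwd[i]; if (u < acc) ev = i; }
      for (int i = 0; i < ng && ev < 0; ++i) { acc += bwd[i]; if (u < acc) ev = ng + i; }
      if (any_dim_now) {
        for (int k = 0; k < ng2 && ev < 0; ++k) { acc += pdim[k]; if (u < acc) ev = 2 * ng + k; }
        for (int k = 0; k < ng2 && ev < 0; ++k) { acc += pclv[k]; if (u < acc) ev = 2 * ng + ng2 + k; }
      }
      if (ev < 0) { // numerical fallback: last positive channel
        for (int i = ng - 1; i >= 0 && ev < 0; --i)
          if (bwd[i] > 0.0) ev = ng + i;
        for (int i = ng - 1; i >= 0 && ev < 0; --i)
          if (fwd[i] > 0.0) ev = i;
      }
      if (ev < ng) add_mono(ev);
      else if (ev < 2 * ng) rm_mono(ev - ng);
      else if (ev < 2 * ng + ng2) {
        int k = ev - 2 * ng; form_dimer(k / ng, k % ng); n_dim_total += 1;
      } else {
        int k = ev - 2 * ng - ng2; cleave_dimer(k / ng, k % ng); n_dim_total -= 1;
      }
    }

    for (int i = 0; i < ng; ++i) mono_out(g, i) = mono[i];
    for (int k = 0; k < ng2; ++k) dim_out(g, k) = dim[k];
    times[g] = t;
    dimer_frac[g] = 2.0 * (double)n_dim_total / (double)N;

    // split: particles are free monomers (1 equivalent) and dimers (2);
    // draw particles uniformly without replacement until progeny 1 holds
    // at least N/2 monomer equivalents; dimers are indivisible.
    std::vector<int> ptype; // 0..ng-1 monomer, ng + i*ng + j dimer
    for (int i = 0; i < ng; ++i)
      for (int c = 0; c < mono[i]; ++c) ptype.push_back(i);
    for (int k = 0; k < ng2; ++k)
      for (int c = 0; c < dim[k]; ++c) ptype.push_back(ng + k);
    const int M = (int)ptype.size();
    const long long half = N / 2;
    std::vector<int> m1(ng, 0), dd1(ng2, 0);
    long long acc_eq = 0;
    int kpick = 0;
    while (acc_eq < half && kpick < M) {
      int j = kpick + (int)(unif_rand() * (M - kpick));
      if (j >= M) j = M - 1;
      std::swap(ptype[kpick], ptype[j]);
      const int p = ptype[kpick];
      if (p < ng) { m1[p] += 1; acc_eq += 1; }
      else { dd1[p - ng] += 1; acc_eq += 2; }
      ++kpick;
    }
    std::vector<int> m2(ng, 0), dd2v(ng2, 0);
    for (int k = kpick; k < M; ++k) {
      const int p = ptype[k];
      if (p < ng) m2[p] += 1; else dd2v[p - ng] += 1;
    }
    const bool keep_first = (unif_rand() < 0.5);
    const std::vector<int> &km = keep_first ? m1 : m2;
    const std::vector<int> &kd = keep_first ? dd1 : dd2v;

    // rebuild state from kept progeny
    mono = km; dim = kd;
    std::fill(s.begin(), s.end(), 0.0);
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(d2.begin(), d2.end(), 0.0);
    N = 0; n_dim_total = 0;
    for (int a = 0; a < ng; ++a) {
      N += mono[a];
      if (mono[a] > 0)
        for (int i = 0; i < ng; ++i) s[i] += B[i + (size_t)a * ng] * mono[a];
    }
    for (int i = 0; i < ng; ++i)
      for (int j = 0; j < ng; ++j) {
        const int c = dim[i * ng + j];
        if (c == 0) continue;
        n_dim_total += c; N += 2LL * c;
        for (int x = 0; x < ng; ++x) {
          d1[x] += B[x + (size_t)i * ng] * c;
          d2[x] += B[x + (size_t)j * ng] * c;
        }
      }
  }
  return List::create(_["monomers"] = mono_out, _["dimers"] = dim_out,
                      _["time"] = times, _["dimer_fraction"] = dimer_frac);
}
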