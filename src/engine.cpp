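// Hybrid stochastic-deterministic simulator for the her1/7 segmentation
// clock.  Continuous species (mRNA, protein) evolve by explicit Euler
// integration of delay differential equations on a fixed grid; the occupancy
// of the four her1/7 gene copies per cell evolves by an exact delayed
// direct-method Gillespie sampler whose propensities vary continuously
// between regulatory events.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xorshift128+ with splitmix64 seeding.  One master seed; independent
// streams are derived as stream(seed, id) so that adding cells does not
// reshuffle the draws of existing streams.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xrng {
  uint64_t s0, s1;
  Xrng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform on the open interval (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Ring buffer over the integration grid for one delayed quantity across all
// cells.  Values for t <= 0 fall back to the initial state (pre-history).
struct Ring {
  int cap, n;
  std::vector<double> v;     // cap * n
  std::vector<double> init;  // n
  void setup(int cap_, int n_, double init_val) {
    cap = cap_;
    n = n_;
    v.assign((size_t)cap * n, init_val);
    init.assign(n, init_val);
  }
  inline void set_init(int cell, double val) { init[cell] = val; }
  inline void store(long step, int cell, double val) {
    v[(size_t)(step % cap) * n + cell] = val;
  }
  inline double at_step(long step, int cell) const {
    if (step <= 0) return init[cell];
    return v[(size_t)(step % cap) * n + cell];
  }
  // linear interpolation at time t = s * dt (s in step units)
  inline double at(double s, int cell) const {
    if (s <= 0.0) return init[cell];
    long i0 = (long)std::floor(s);
    double f = s - i0;
    double a = at_step(i0, cell);
    if (f == 0.0) return a;
    return a + f * (at_step(i0 + 1, cell) - a);
  }
};

// Piecewise-constant per-cell record of active gene-copy counts, with a
// moving read pointer (delayed queries are monotone in t within a cell).
struct GeneHist {
  std::vector<double> t;
  std::vector<unsigned char> g1, g7;
  size_t ptr = 0;
  void push(double time, int a1, int a7) {
    t.push_back(time);
    g1.push_back((unsigned char)a1);
    g7.push_back((unsigned char)a7);
  }
  inline void lookup(double tq, int &a1, int &a7) {
    while (ptr + 1 < t.size() && t[ptr + 1] <= tq) ++ptr;
    // ptr may have advanced past earlier queries of other delays; rewind if
    // needed (only occurs when two delayed consumers share the buffer)
    while (ptr > 0 && t[ptr] > tq) --ptr;
    a1 = g1[ptr];
    a7 = g7[ptr];
  }
};

// occupancy codes
enum { FREE = 0, REP_H1 = 1, REP_H7 = 2, NICD_BOUND = 3 };
static inline bool is_active(int occ) { return occ == FREE || occ == NICD_BOUND; }

struct PerCell {
  // continuous state
  double m1, m7, p1, p7, md, pd, pN;
  // gene copies: 0,1 her1; 2,3 her7
  int occ[4];
  int n_free, n_bound;
  inline void recount() {
    n_free = 0;
    for (int c = 0; c < 4; ++c)
      if (occ[c] == FREE) ++n_free;
    n_bound = 4 - n_free;
    // NICD-bound copies count as bound for dissociation purposes
    int nicd = 0;
    for (int c = 0; c < 4; ++c)
      if (occ[c] == NICD_BOUND) ++nicd;
    (void)nicd;
  }
  inline int active_h1() const {
    return (is_active(occ[0]) ? 1 : 0) + (is_active(occ[1]) ? 1 : 0);
  }
  inline int active_h7() const {
    return (is_active(occ[2]) ? 1 : 0) + (is_active(occ[3]) ? 1 : 0);
  }
  // bitmask of per-copy activity (bit 0 = first copy, bit 1 = second)
  inline int mask_h1() const {
    return (is_active(occ[0]) ? 1 : 0) | (is_active(occ[1]) ? 2 : 0);
  }
  inline int mask_h7() const {
    return (is_active(occ[2]) ? 1 : 0) | (is_active(occ[3]) ? 2 : 0);
  }
};

struct ParVec {
  std::vector<double> v;
  inline double operator[](int i) const { return v[i]; }
};

static ParVec get_par(const List &pars, const char *name, int n) {
  if (!pars.containsElementNamed(name))
    stop("parameter '%s' missing", name);
  NumericVector x = pars[name];
  ParVec out;
  out.v.resize(n);
  if (x.size() == 1)
    std::fill(out.v.begin(), out.v.end(), x[0]);
  else if ((int)x.size() == n)
    std::copy(x.begin(), x.end(), out.v.begin());
  else
    stop("parameter '%s' must have length 1 or n_cells", name);
  return out;
}

// repression factor shared by the deterministic her1/7 variant and the
// delta promoter in both variants
static inline double Ffac(double p1, double p7, double P01, double P07,
                          double ph6, double ph6ref) {
  double a = p1 / P01;
  double b = (p7 * ph6) / (P07 * ph6ref);
  return 1.0 / (1.0 + a * a + b * b);
}

// Solve A + integral_0^tau of linear hazard (a_s -> a_e over h) = r for tau.
// Returns a value > h when no crossing occurs within the interval.
static inline double hazard_crossing(double A, double r, double a_s,
                                     double a_e, double h) {
  double need = r - A;
  double slope = (a_e - a_s) / h;
  if (std::fabs(slope) < 1e-14) {
    if (a_s <= 0.0) return h * 2.0;
    return need / a_s;
  }
  // 0.5*slope*tau^2 + a_s*tau - need = 0
  double disc = a_s * a_s + 2.0 * slope * need;
  if (disc < 0.0) return h * 2.0;
  double tau = (-a_s + std::sqrt(disc)) / slope;
  if (tau < 0.0) return h * 2.0;
  return tau;
}

// [[Rcpp::export]]
List cpp_simulate(List pars, int n_cells, int hybrid, int notch,
                  IntegerMatrix neighbours, double t_end, double dt,
                  double record_dt, int init_random,
                  IntegerVector init_occupancy, NumericVector init_state,
                  int seed, int record_all, int record_genes,
                  int return_events) {
  if (n_cells < 1) stop("n_cells must be >= 1");
  if (t_end <= 0) stop("t_end must be positive");
  if (dt <= 0) stop("dt must be positive");

  const int n = n_cells;
  ParVec alpha_h1 = get_par(pars, "alpha_h1", n),
         alpha_h7 = get_par(pars, "alpha_h7", n),
         beta_h1 = get_par(pars, "beta_h1", n),
         beta_h7 = get_par(pars, "beta_h7", n),
         lambda_mh = get_par(pars, "lambda_mh", n),
         lambda_ph = get_par(pars, "lambda_ph", n),
         tau_mh = get_par(pars, "tau_mh", n),
         tau_ph1 = get_par(pars, "tau_ph1", n),
         tau_ph7 = get_par(pars, "tau_ph7", n),
         p_h6 = get_par(pars, "p_h6", n),
         P0_h1 = get_par(pars, "P0_h1", n),
         P0_h7 = get_par(pars, "P0_h7", n),
         p_h6_ref = get_par(pars, "p_h6_ref", n);

  ParVec koff, kon_rep, kon_nicd;
  if (hybrid) {
    koff = get_par(pars, "koff", n);
    kon_rep = get_par(pars, "kon_rep", n);
    kon_nicd = notch ? get_par(pars, "kon_nicd", n) : ParVec();
  }
  ParVec alpha_d, beta_d, lambda_md, lambda_pd, tau_md, tau_pd, k_N, lambda_N,
      tau_pN;
  if (notch) {
    alpha_d = get_par(pars, "alpha_d", n);
    beta_d = get_par(pars, "beta_d", n);
    lambda_md = get_par(pars, "lambda_md", n);
    lambda_pd = get_par(pars, "lambda_pd", n);
    tau_md = get_par(pars, "tau_md", n);
    tau_pd = get_par(pars, "tau_pd", n);
    k_N = get_par(pars, "k_N", n);
    lambda_N = get_par(pars, "lambda_N", n);
    tau_pN = get_par(pars, "tau_pN", n);
    if (neighbours.nrow() != n || neighbours.ncol() != 6)
      stop("notch mode requires an n_cells x 6 neighbour table");
  }

  double max_delay = 0.0, min_delay = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double ds[6];
    int nd = 3;
    ds[0] = tau_mh[i];
    ds[1] = tau_ph1[i];
    ds[2] = tau_ph7[i];
    if (notch) {
      ds[3] = tau_md[i];
      ds[4] = tau_pd[i];
      ds[5] = tau_pN[i];
      nd = 6;
    }
    for (int k = 0; k < nd; ++k) {
      if (ds[k] < 0) stop("delays must be non-negative");
      if (ds[k] > max_delay) max_delay = ds[k];
      if (ds[k] > 0 && ds[k] < min_delay) min_delay = ds[k];
    }
  }
  if (R_finite(min_delay) && dt > min_delay)
    stop("dt must not exceed the smallest positive delay");

  const long nsteps = (long)std::ceil(t_end / dt - 1e-9);
  const int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  const int nrec = (int)(nsteps / rec_every) + 1;
  const int cap = (int)std::ceil(max_delay / dt) + 3;

  // rings for the delayed reads
  Ring r_m1, r_m7, r_p1, r_p7, r_md, r_pd;
  r_m1.setup(cap, n, 0.0);
  r_m7.setup(cap, n, 0.0);
  r_p1.setup(cap, n, 0.0);
  r_p7.setup(cap, n, 0.0);
  if (notch) {
    r_md.setup(cap, n, 0.0);
    r_pd.setup(cap, n, 0.0);
  }

  std::vector<PerCell> cell(n);
  std::vector<GeneHist> ghist(hybrid ? n : 0);

  // --- initialisation ---------------------------------------------------
  for (int i = 0; i < n; ++i) {
    PerCell &c = cell[i];
    if (init_random) {
      Xrng rg((uint64_t)seed, 1000 + (uint64_t)i);
      c.m1 = 60.0 * rg.unif();
      c.m7 = 60.0 * rg.unif();
      c.p1 = 1500.0 * rg.unif();
      c.p7 = 1500.0 * rg.unif();
      c.md = 60.0 * rg.unif();
      c.pd = 1500.0 * rg.unif();
      c.pN = 800.0 * rg.unif();
      for (int k = 0; k < 4; ++k) {
        double u = rg.unif();
        int nstates = (hybrid && notch) ? 4 : (hybrid ? 3 : 1);
        int s = (int)(u * nstates);
        if (s >= nstates) s = nstates - 1;
        c.occ[k] = hybrid ? s : FREE;
      }
    } else {
      c.m1 = c.m7 = c.p1 = c.p7 = c.md = c.pd = c.pN = 0.0;
      if (init_state.size() == 7) {
        c.m1 = init_state[0];
        c.m7 = init_state[1];
        c.p1 = init_state[2];
        c.p7 = init_state[3];
        c.md = init_state[4];
        c.pd = init_state[5];
        c.pN = init_state[6];
      }
      for (int k = 0; k < 4; ++k)
        c.occ[k] = (init_occupancy.size() == 4) ? init_occupancy[k] : FREE;
    }
    c.recount();
    r_m1.set_init(i, c.m1);
    r_m7.set_init(i, c.m7);
    r_p1.set_init(i, c.p1);
    r_p7.set_init(i, c.p7);
    if (notch) {
      r_md.set_init(i, c.md);
      r_pd.set_init(i, c.pd);
    }
    r_m1.store(0, i, c.m1);
    r_m7.store(0, i, c.m7);
    r_p1.store(0, i, c.p1);
    r_p7.store(0, i, c.p7);
    if (notch) {
      r_md.store(0, i, c.md);
      r_pd.store(0, i, c.pd);
    }
    if (hybrid) ghist[i].push(-1e30, c.active_h1(), c.active_h7());
  }

  Xrng ev_rng((uint64_t)seed, 1);

  // recording buffers
  NumericVector rec_time(nrec);
  NumericMatrix rec_p1(nrec, n);
  NumericMatrix rec_m1, rec_m7, rec_p7, rec_md, rec_pd, rec_pN;
  if (record_all) {
    rec_m1 = NumericMatrix(nrec, n);
    rec_m7 = NumericMatrix(nrec, n);
    rec_p7 = NumericMatrix(nrec, n);
    if (notch) {
      rec_md = NumericMatrix(nrec, n);
      rec_pd = NumericMatrix(nrec, n);
      rec_pN = NumericMatrix(nrec, n);
    }
  }
  IntegerMatrix rec_g1, rec_g7;
  if (record_genes && hybrid) {
    rec_g1 = IntegerMatrix(nrec, n);
    rec_g7 = IntegerMatrix(nrec, n);
  }
  std::vector<double> ev_time;
  std::vector<int> ev_cell, ev_copy, ev_from, ev_to;

  auto record_row = [&](int row, double t) {
    rec_time[row] = t;
    for (int i = 0; i < n; ++i) {
      rec_p1(row, i) = cell[i].p1;
      if (record_all) {
        rec_m1(row, i) = cell[i].m1;
        rec_m7(row, i) = cell[i].m7;
        rec_p7(row, i) = cell[i].p7;
        if (notch) {
          rec_md(row, i) = cell[i].md;
          rec_pd(row, i) = cell[i].pd;
          rec_pN(row, i) = cell[i].pN;
        }
      }
      if (record_genes && hybrid) {
        rec_g1(row, i) = cell[i].mask_h1();
        rec_g7(row, i) = cell[i].mask_h7();
      }
    }
  };
  record_row(0, 0.0);
  int rec_row = 1;

  // per-cell association rates from (possibly interpolated) protein levels
  auto assoc_rates = [&](int i, double p1, double p7, double pN, double &r1,
                         double &r7, double &rN) {
    r1 = kon_rep[i] * p1 * p1;
    double het = p7 * p_h6[i] / p_h6_ref[i];
    r7 = kon_rep[i] * het * het;
    rN = (notch) ? kon_nicd[i] * pN * pN : 0.0;
  };

  auto cell_hazard = [&](int i, double p1, double p7, double pN) {
    double r1, r7, rN;
    assoc_rates(i, p1, p7, pN, r1, r7, rN);
    return cell[i].n_free * (r1 + r7 + rN) + cell[i].n_bound * koff[i];
  };

  // state at the endpoints of the current step, for interpolation
  std::vector<double> p1_s(n), p7_s(n), pN_s(n), p1_e(n), p7_e(n), pN_e(n);

  double r_target = hybrid ? -std::log(ev_rng.unif()) : 0.0;
  double A_accum = 0.0;

  for (long k = 0; k < nsteps; ++k) {
    const double t = k * dt;
    // -- Euler step of the DDEs over [t, t+dt]; gene-activity production
    //    terms read delayed history, so within-step regulatory events do
    //    not alter this update
    for (int i = 0; i < n; ++i) {
      PerCell &c = cell[i];
      p1_s[i] = c.p1;
      p7_s[i] = c.p7;
      pN_s[i] = c.pN;
      // production terms read only delayed history (delays >= dt), so both
      // Heun stages share them
      auto production = [&](double tq, double &prod_m1, double &prod_m7,
                            double &prod_md, double &prod_pN) {
        if (hybrid) {
          int a1, a7;
          ghist[i].lookup(tq - tau_mh[i], a1, a7);
          prod_m1 = alpha_h1[i] * a1 / 2.0;
          prod_m7 = alpha_h7[i] * a7 / 2.0;
        } else {
          double dp1 = r_p1.at((tq - tau_mh[i]) / dt, i);
          double dp7 = r_p7.at((tq - tau_mh[i]) / dt, i);
          double F = Ffac(dp1, dp7, P0_h1[i], P0_h7[i], p_h6[i], p_h6_ref[i]);
          prod_m1 = alpha_h1[i] * F;
          prod_m7 = alpha_h7[i] * F;
        }
        prod_md = 0.0;
        prod_pN = 0.0;
        if (notch) {
          double dq1 = r_p1.at((tq - tau_md[i]) / dt, i);
          double dq7 = r_p7.at((tq - tau_md[i]) / dt, i);
          double Fd = Ffac(dq1, dq7, P0_h1[i], P0_h7[i], p_h6[i], p_h6_ref[i]);
          prod_md = alpha_d[i] * Fd;
          double sum_d = 0.0;
          double sq = (tq - tau_pN[i]) / dt;
          for (int j = 0; j < 6; ++j)
            sum_d += r_pd.at(sq, neighbours(i, j) - 1);
          prod_pN = k_N[i] * (sum_d / 6.0);
        }
      };
      double pm1a, pm7a, pmda, ppNa, pm1b, pm7b, pmdb, ppNb;
      production(t, pm1a, pm7a, pmda, ppNa);
      production(t + dt, pm1b, pm7b, pmdb, ppNb);
      double bm1a = beta_h1[i] * r_m1.at((t - tau_ph1[i]) / dt, i);
      double bm1b = beta_h1[i] * r_m1.at((t + dt - tau_ph1[i]) / dt, i);
      double bm7a = beta_h7[i] * r_m7.at((t - tau_ph7[i]) / dt, i);
      double bm7b = beta_h7[i] * r_m7.at((t + dt - tau_ph7[i]) / dt, i);
      double bpda = 0, bpdb = 0;
      if (notch) {
        bpda = beta_d[i] * r_md.at((t - tau_pd[i]) / dt, i);
        bpdb = beta_d[i] * r_md.at((t + dt - tau_pd[i]) / dt, i);
      }
      // Heun (explicit trapezoidal): predictor at t+dt, then average slopes
      auto heun = [&](double y, double prod_a, double prod_b, double lam) {
        double f1 = prod_a - lam * y;
        double ystar = y + dt * f1;
        double f2 = prod_b - lam * ystar;
        return std::max(0.0, y + 0.5 * dt * (f1 + f2));
      };
      c.m1 = heun(c.m1, pm1a, pm1b, lambda_mh[i]);
      c.m7 = heun(c.m7, pm7a, pm7b, lambda_mh[i]);
      c.p1 = heun(c.p1, bm1a, bm1b, lambda_ph[i]);
      c.p7 = heun(c.p7, bm7a, bm7b, lambda_ph[i]);
      if (notch) {
        c.md = heun(c.md, pmda, pmdb, lambda_md[i]);
        c.pd = heun(c.pd, bpda, bpdb, lambda_pd[i]);
        c.pN = heun(c.pN, ppNa, ppNb, lambda_N[i]);
      }
      r_m1.store(k + 1, i, c.m1);
      r_m7.store(k + 1, i, c.m7);
      r_p1.store(k + 1, i, c.p1);
      r_p7.store(k + 1, i, c.p7);
      if (notch) {
        r_md.store(k + 1, i, c.md);
        r_pd.store(k + 1, i, c.pd);
      }
      p1_e[i] = c.p1;
      p7_e[i] = c.p7;
      pN_e[i] = c.pN;
    }

    // -- delayed direct-method Gillespie over (t, t+dt] ------------------
    if (hybrid) {
      double tau_cur = 0.0;
      double a_s = 0.0, a_e = 0.0;
      for (int i = 0; i < n; ++i) {
        a_s += cell_hazard(i, p1_s[i], p7_s[i], pN_s[i]);
        a_e += cell_hazard(i, p1_e[i], p7_e[i], pN_e[i]);
      }
      for (;;) {
        double h = dt - tau_cur;
        if (h <= 0.0) break;
        double seg = 0.5 * h * (a_s + a_e);
        if (A_accum + seg < r_target) {
          A_accum += seg;
          break;
        }
        double tau_rel = hazard_crossing(A_accum, r_target, a_s, a_e, h);
        if (tau_rel > h) {  // numerical guard: treat as no crossing
          A_accum += seg;
          break;
        }
        double tau_star = tau_cur + tau_rel;
        double f = tau_star / dt;
        // select the cell by its hazard at the event time
        double tot = 0.0;
        std::vector<double> az(n);
        for (int i = 0; i < n; ++i) {
          double p1 = p1_s[i] + f * (p1_e[i] - p1_s[i]);
          double p7 = p7_s[i] + f * (p7_e[i] - p7_s[i]);
          double pN = pN_s[i] + f * (pN_e[i] - pN_s[i]);
          az[i] = cell_hazard(i, p1, p7, pN);
          tot += az[i];
        }
        if (tot <= 0.0) {  // hazard vanished; no event in this step
          A_accum = 0.0;
          r_target = -std::log(ev_rng.unif());
          break;
        }
        double u = ev_rng.unif() * tot;
        int ic = 0;
        double cum = 0.0;
        for (; ic < n - 1; ++ic) {
          cum += az[ic];
          if (u <= cum) break;
        }
        PerCell &c = cell[ic];
        double p1 = p1_s[ic] + f * (p1_e[ic] - p1_s[ic]);
        double p7 = p7_s[ic] + f * (p7_e[ic] - p7_s[ic]);
        double pN = pN_s[ic] + f * (pN_e[ic] - pN_s[ic]);
        double r1, r7, rN;
        assoc_rates(ic, p1, p7, pN, r1, r7, rN);
        double w_assoc1 = c.n_free * r1, w_assoc7 = c.n_free * r7,
               w_assocN = c.n_free * rN, w_diss = c.n_bound * koff[ic];
        double wtot = w_assoc1 + w_assoc7 + w_assocN + w_diss;
        double u2 = ev_rng.unif() * wtot;
        int new_occ, old_occ, copy = -1;
        if (u2 < w_assoc1 || u2 < w_assoc1 + w_assoc7 ||
            u2 < w_assoc1 + w_assoc7 + w_assocN) {
          new_occ = (u2 < w_assoc1) ? REP_H1
                    : (u2 < w_assoc1 + w_assoc7) ? REP_H7
                                                 : NICD_BOUND;
          // uniform among FREE copies
          int pick = (int)(ev_rng.unif() * c.n_free);
          if (pick >= c.n_free) pick = c.n_free - 1;
          for (int cc = 0, cnt = 0; cc < 4; ++cc)
            if (c.occ[cc] == FREE && cnt++ == pick) {
              copy = cc;
              break;
            }
        } else {
          new_occ = FREE;
          int pick = (int)(ev_rng.unif() * c.n_bound);
          if (pick >= c.n_bound) pick = c.n_bound - 1;
          for (int cc = 0, cnt = 0; cc < 4; ++cc)
            if (c.occ[cc] != FREE && cnt++ == pick) {
              copy = cc;
              break;
            }
        }
        old_occ = c.occ[copy];
        c.occ[copy] = new_occ;
        c.recount();
        double t_ev = t + tau_star;
        ghist[ic].push(t_ev, c.active_h1(), c.active_h7());
        if (return_events) {
          ev_time.push_back(t_ev);
          ev_cell.push_back(ic + 1);
          ev_copy.push_back(copy + 1);
          ev_from.push_back(old_occ);
          ev_to.push_back(new_occ);
        }
        // restart accumulation from the event time
        r_target = -std::log(ev_rng.unif());
        A_accum = 0.0;
        tau_cur = tau_star;
        a_s = a_e = 0.0;
        double f2 = tau_cur / dt;
        for (int i = 0; i < n; ++i) {
          double q1 = p1_s[i] + f2 * (p1_e[i] - p1_s[i]);
          double q7 = p7_s[i] + f2 * (p7_e[i] - p7_s[i]);
          double qN = pN_s[i] + f2 * (pN_e[i] - pN_s[i]);
          a_s += cell_hazard(i, q1, q7, qN);
          a_e += cell_hazard(i, p1_e[i], p7_e[i], pN_e[i]);
        }
      }
    }

    if ((k + 1) % rec_every == 0 && rec_row < nrec)
      record_row(rec_row++, (k + 1) * dt);
  }

  List out = List::create(
      _["time"] = rec_time, _["p_h1"] = rec_p1);
  if (record_all) {
    out["m_h1"] = rec_m1;
    out["m_h7"] = rec_m7;
    out["p_h7"] = rec_p7;
    if (notch) {
      out["m_d"] = rec_md;
      out["p_d"] = rec_pd;
      out["p_N"] = rec_pN;
    }
  }
  if (record_genes && hybrid) {
    out["g_h1"] = rec_g1;
    out["g_h7"] = rec_g7;
  }
  if (return_events) {
    out["events"] = List::create(
        _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
        _["cell"] = IntegerVector(ev_cell.begin(), ev_cell.end()),
        _["copy"] = IntegerVector(ev_copy.begin(), ev_copy.end()),
        _["from"] = IntegerVector(ev_from.begin(), ev_from.end()),
        _["to"] = IntegerVector(ev_to.begin(), ev_to.end()));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stand-alone event-time sampler over a piecewise-linear total hazard,
// using the same cumulative-hazard inversion as the engine.  Each draw is an
// independent first-event time measured from times[0].
// [[Rcpp::export]]
NumericVector cpp_sample_event_times(NumericVector times, NumericVector a0,
                                     int n, int seed) {
  if (times.size() != a0.size() || times.size() < 2)
    stop("times and a0 must have equal length >= 2");
  Xrng rg((uint64_t)seed, 7);
  NumericVector out(n);
  int m = times.size();
  for (int d = 0; d < n; ++d) {
    double r = -std::log(rg.unif());
    double A = 0.0;
    double tev = R_PosInf;
    for (int k = 0; k + 1 < m; ++k) {
      double h = times[k + 1] - times[k];
      if (h <= 0) stop("times must be strictly increasing");
      double seg = 0.5 * h * (a0[k] + a0[k + 1]);
      if (A + seg >= r) {
        double tau = hazard_crossing(A, r, a0[k], a0[k + 1], h);
        if (tau <= h) {
          tev = times[k] + tau;
          break;
        }
      }
      A += seg;
    }
    out[d] = tev;
  }
  return out;
}
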