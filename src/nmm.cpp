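#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Parameter order is fixed and must match nmm_param_names() on the R side.
enum Par {
  QMAX_E, QMAX_I, THETA_E, THETA_I, SIGMA_E, SIGMA_I,
  GAMMA_E, GAMMA_I,
  N_EE, N_EI, N_IE, N_II,
  TAU_E, TAU_I, C_E, C_I,
  G_AMPA, G_GABA, G_L_E, G_L_I, G_KNA,
  E_AMPA, E_GABA, E_L_E, E_L_I, E_K,
  ALPHA_NA, TAU_NA, R_PUMP, NA_EQ,
  PHI_MEAN, PHI_SD,
  NPAR
};

// Deterministic normal generator (mt19937_64 + Box-Muller) so trajectories
// are bit-identical across platforms/compilers for a given seed.
struct Gauss {
  std::mt19937_64 gen;
  bool have = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : gen(seed) {}
  double unif() { return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    if (have) { have = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

static inline double sigm(double V, double Qmax, double theta, double sigma) {
  const double C = M_PI / std::sqrt(3.0);
  return Qmax / (1.0 + std::exp(-C * (V - theta) / sigma));
}

static inline double kna_w(double Na) {
  // 0.37 / (1 + (38.7/Na)^3.5); x^3.5 = x^3 * sqrt(x), avoiding pow()
  double r = 38.7 / Na;
  return 0.37 / (1.0 + r * r * r * std::sqrt(r));
}

static inline double cube(double x) { return x * x * x; }

// [[Rcpp::export(name = ".nmm_simulate_cpp")]]
List nmm_simulate_cpp(NumericVector p, double duration, double burn_in,
                      double dt, int fs_out, double seed) {
  if (p.size() != NPAR) stop("parameter vector must have length 32");
  const double Qmax_e = p[QMAX_E], Qmax_i = p[QMAX_I];
  const double th_e = p[THETA_E], th_i = p[THETA_I];
  const double sg_e = p[SIGMA_E], sg_i = p[SIGMA_I];
  const double ge = p[GAMMA_E], gi = p[GAMMA_I];
  const double Nee = p[N_EE], Nei = p[N_EI], Nie = p[N_IE], Nii = p[N_II];
  const double tau_e = p[TAU_E], tau_i = p[TAU_I];
  const double Ce = p[C_E], Ci = p[C_I];
  const double gA = p[G_AMPA], gG = p[G_GABA];
  const double gLe = p[G_L_E], gLi = p[G_L_I], gK = p[G_KNA];
  const double Ee = p[E_AMPA], Ei = p[E_GABA];
  const double ELe = p[E_L_E], ELi = p[E_L_I], EK = p[E_K];
  const double aNa = p[ALPHA_NA], tNa = p[TAU_NA];
  const double Rp = p[R_PUMP], Naeq = p[NA_EQ];
  const double phi_m = p[PHI_MEAN], phi_s = p[PHI_SD];

  const long n_steps = (long)std::llround((burn_in + duration) / dt);
  const int n_out = (int)std::lround(duration * fs_out);
  const double sqdt = std::sqrt(dt);
  const double ge2 = ge * ge, gi2 = gi * gi;
  const double pump_eq = cube(Naeq) / (cube(Naeq) + 3375.0);

  Gauss rng((uint64_t)seed);

  // state
  double Ve = ELe, Vi = ELi;
  double see = phi_m, dsee = 0, sei = phi_m, dsei = 0;
  double sie = 0, dsie = 0, sii = 0, dsii = 0;
  double Na = Naeq;

  NumericVector o_Ve(n_out), o_Vi(n_out), o_Qe(n_out), o_Qi(n_out),
      o_see(n_out), o_sei(n_out), o_sie(n_out), o_sii(n_out), o_Na(n_out);

  // exact post-burn-in time averages (accumulated every integration step)
  double mQe = 0, mQi = 0, mIexc_e = 0, mIinh_e = 0, mIleak_e = 0,
         mIkna_e = 0, mIexc_i = 0, mIinh_i = 0, mIleak_i = 0;
  long n_acc = 0;

  bool blown = false;
  int out_idx = 0;
  long next_out = (long)std::llround(burn_in / dt);  // first sample at t = burn_in

  for (long k = 0; k < n_steps; ++k) {
    double Qe = sigm(Ve, Qmax_e, th_e, sg_e);
    double Qi = sigm(Vi, Qmax_i, th_i, sg_i);
    double w = kna_w(Na);

    // signed currents, depolarizing positive
    double Iexc_e = -gA * see * (Ve - Ee);
    double Iinh_e = -gG * sie * (Ve - Ei);
    double Ileak_e = -gLe * (Ve - ELe);
    double Ikna_e = -gK * w * (Ve - EK);
    double Iexc_i = -gA * sei * (Vi - Ee);
    double Iinh_i = -gG * sii * (Vi - Ei);
    double Ileak_i = -gLi * (Vi - ELi);

    if (k * dt >= burn_in) {
      mQe += Qe; mQi += Qi;
      mIexc_e += Iexc_e; mIinh_e += Iinh_e; mIleak_e += Ileak_e;
      mIkna_e += Ikna_e; mIexc_i += Iexc_i; mIinh_i += Iinh_i;
      mIleak_i += Ileak_i;
      ++n_acc;
    }

    if (out_idx < n_out && k == next_out) {
      o_Ve[out_idx] = Ve; o_Vi[out_idx] = Vi;
      o_Qe[out_idx] = Qe; o_Qi[out_idx] = Qi;
      o_see[out_idx] = see; o_sei[out_idx] = sei;
      o_sie[out_idx] = sie; o_sii[out_idx] = sii;
      o_Na[out_idx] = Na;
      ++out_idx;
      next_out = (long)std::llround((burn_in + out_idx / (double)fs_out) / dt);
    }

    // derivatives
    double dVe = (Ileak_e + (Iexc_e + Iinh_e + Ikna_e) / Ce) / tau_e;
    double dVi = (Ileak_i + (Iexc_i + Iinh_i) / Ci) / tau_i;
    double pump = Rp * (cube(Na) / (cube(Na) + 3375.0) - pump_eq);
    double dNa = (aNa * Qe - pump) / tNa;

    // Euler-Maruyama update; afferent noise drives both excitatory synapses
    double xi1 = (phi_s > 0) ? rng() : 0.0;
    double xi2 = (phi_s > 0) ? rng() : 0.0;
    double ndsee = dsee + dt * (ge2 * (Nee * Qe + phi_m - see) - 2 * ge * dsee) +
                   ge2 * phi_s * sqdt * xi1;
    double ndsei = dsei + dt * (ge2 * (Nei * Qe + phi_m - sei) - 2 * ge * dsei) +
                   ge2 * phi_s * sqdt * xi2;
    double ndsie = dsie + dt * (gi2 * (Nie * Qi - sie) - 2 * gi * dsie);
    double ndsii = dsii + dt * (gi2 * (Nii * Qi - sii) - 2 * gi * dsii);

    see += dt * dsee; sei += dt * dsei; sie += dt * dsie; sii += dt * dsii;
    dsee = ndsee; dsei = ndsei; dsie = ndsie; dsii = ndsii;
    Ve += dt * dVe; Vi += dt * dVi; Na += dt * dNa;
    if (Na < 1e-6) Na = 1e-6;

    if (!std::isfinite(Ve) || !std::isfinite(Vi) || !std::isfinite(Na) ||
        std::fabs(Ve) > 200.0 || std::fabs(Vi) > 200.0) {
      blown = true;
      break;
    }
  }

  if (n_acc == 0) n_acc = 1;
  NumericVector means = NumericVector::create(
      _["mean_Q_e"] = mQe / n_acc, _["mean_Q_i"] = mQi / n_acc,
      _["I_exc_e"] = mIexc_e / n_acc, _["I_inh_e"] = mIinh_e / n_acc,
      _["I_leak_e"] = mIleak_e / n_acc, _["I_KNa_e"] = mIkna_e / n_acc,
      _["I_exc_i"] = mIexc_i / n_acc, _["I_inh_i"] = mIinh_i / n_acc,
      _["I_leak_i"] = mIleak_i / n_acc);

  return List::create(
      _["V_e"] = o_Ve, _["V_i"] = o_Vi, _["Q_e"] = o_Qe, _["Q_i"] = o_Qi,
      _["s_ee"] = o_see, _["s_ei"] = o_sei, _["s_ie"] = o_sie,
      _["s_ii"] = o_sii, _["Na"] = o_Na, _["blown_up"] = blown,
      _["n_out_filled"] = out_idx, _["means"] = means);
}

// Weighted horizontal visibility graph degrees, O(n) stack construction.
// Edge (i, j), i < j, iff x_k < min(x_i, x_j) for all i < k < j (strict;
// ties block visibility beyond the tied pair). Weight = |atan(slope)| with
// slope in units per second.
// [[Rcpp::export(name = ".hvg_degrees_cpp")]]
List hvg_degrees_cpp(NumericVector x, double fs) {
  int n = x.size();
  if (n < 2) stop("series must have length >= 2");
  IntegerVector deg(n, 0);
  NumericVector wdeg(n, 0.0);
  std::vector<int> st;
  st.reserve(n);
  st.push_back(0);
  for (int j = 1; j < n; ++j) {
    while (!st.empty() && x[st.back()] < x[j]) {
      int i = st.back();
      double w = std::fabs(std::atan((x[j] - x[i]) * fs / (double)(j - i)));
      deg[i]++; deg[j]++; wdeg[i] += w; wdeg[j] += w;
      st.pop_back();
    }
    if (!st.empty()) {
      int i = st.back();
      double w = std::fabs(std::atan((x[j] - x[i]) * fs / (double)(j - i)));
      deg[i]++; deg[j]++; wdeg[i] += w; wdeg[j] += w;
      if (x[i] == x[j]) st.pop_back();
    }
    st.push_back(j);
  }
  return List::create(_["degree"] = deg, _["wdegree"] = wdeg);
}
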