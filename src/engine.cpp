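// Tissue-scale right-hand side and time integration for gap-junction coupled
// EC/SMC populations.
//
// State layout: EC block first (4 doubles per EC: ca, store, v, ip3), then
// SMC block (5 doubles per SMC: ca, store, v, w, ip3), cell-major.
//
// The integrator is an adaptive Dormand-Prince 5(4) pair advancing each
// computational domain independently inside one communication interval while
// neighbour cells owned by other domains are held at their
// start-of-interval ("frozen ghost") values; edge states are refreshed at
// interval boundaries. A single-domain system degenerates to a monolithic
// adaptive solve.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct System {
  int n_ec, n_smc;
  // CSR homocellular adjacency (0-based)
  IntegerVector ec_ptr, ec_idx, smc_ptr, smc_idx;
  // heterocellular pairs, CSR from the EC side and its transpose
  IntegerVector het_ptr, het_smc, hetT_ptr, hetT_ec;
  NumericVector het_w, hetT_w;
  // effective coupling rates (flag * rate), order:
  // ec_v, ec_ca, ec_ip3, smc_v, smc_ca, smc_ip3, het_v, het_ca, het_ip3
  NumericVector rates;
  NumericVector agonist;       // per-EC j_plc (uM/s)
  NumericVector ps, pe;        // SMC / EC parameter vectors (fixed order)
  // domain ownership and local ODE offsets
  IntegerVector dom_ec, dom_smc;   // cell -> domain id (0-based)
  std::vector<int> loc_ec, loc_smc; // cell -> offset of its block in the
                                    // domain-local ODE vector
  std::vector<std::vector<int>> dom_ecs, dom_smcs; // domain -> owned cells
  int n_dom;

  explicit System(const List& s)
      : n_ec(as<int>(s["n_ec"])), n_smc(as<int>(s["n_smc"])),
        ec_ptr(s["ec_ptr"]), ec_idx(s["ec_idx"]),
        smc_ptr(s["smc_ptr"]), smc_idx(s["smc_idx"]),
        het_ptr(s["het_ptr"]), het_smc(s["het_smc"]),
        hetT_ptr(s["hetT_ptr"]), hetT_ec(s["hetT_ec"]),
        het_w(s["het_w"]), hetT_w(s["hetT_w"]),
        rates(s["rates"]), agonist(s["agonist"]),
        ps(s["p_smc"]), pe(s["p_ec"]),
        dom_ec(s["dom_ec"]), dom_smc(s["dom_smc"]) {
    n_dom = 0;
    for (int i = 0; i < n_ec; ++i) n_dom = std::max(n_dom, dom_ec[i] + 1);
    for (int i = 0; i < n_smc; ++i) n_dom = std::max(n_dom, dom_smc[i] + 1);
    dom_ecs.assign(n_dom, {});
    dom_smcs.assign(n_dom, {});
    loc_ec.assign(n_ec, -1);
    loc_smc.assign(n_smc, -1);
    std::vector<int> off(n_dom, 0);
    for (int i = 0; i < n_ec; ++i) {
      int d = dom_ec[i];
      dom_ecs[d].push_back(i);
      loc_ec[i] = off[d];
      off[d] += 4;
    }
    for (int i = 0; i < n_smc; ++i) {
      int d = dom_smc[i];
      dom_smcs[d].push_back(i);
      loc_smc[i] = off[d];
      off[d] += 5;
    }
  }

  int n_state() const { return 4 * n_ec + 5 * n_smc; }
  int dom_size(int d) const {
    return 4 * (int)dom_ecs[d].size() + 5 * (int)dom_smcs[d].size();
  }
};

// SMC parameter indices (order fixed in R/params.R)
enum {
  F_i, Kr_i, B_i, cb_i, C_i, sc_i, cc_i, D_i, vd_i, Rd_i, L_i, G_Ca, v_Ca1,
  v_Ca2, R_Ca, G_NaCa, c_NaCa, v_NaCa, F_NaK, G_Cl, v_Cl, G_K, v_K, lambda_i,
  c_w, beta_i, v_Ca3, R_K, gamma_i, k_i
};
// EC parameter indices
enum {
  F_j, Kr_j, B_j, cb_j, C_j, sc_j, cc_j, D_j, L_j, G_cat, E_Ca, m3_cat,
  m4_cat, J0_j, C_m, G_tot, v_K_j, a1_j, a2_j, b_j, c0_j, m3b_j, m4b_j,
  m3s_j, m4s_j, G_R, v_rest_j, k_j
};

inline void ec_deriv(const double* y, const double* p, double j_plc,
                     double in_ca, double in_ip3, double in_v, double* dy) {
  const double ca = y[0], er = y[1], v = y[2], ip3 = y[3];
  const double j_ip3 = p[F_j] * ip3 * ip3 / (p[Kr_j] * p[Kr_j] + ip3 * ip3);
  const double j_eru = p[B_j] * ca * ca / (p[cb_j] * p[cb_j] + ca * ca);
  const double ca4 = ca * ca * ca * ca;
  const double cc4 = p[cc_j] * p[cc_j] * p[cc_j] * p[cc_j];
  const double j_cicr =
      p[C_j] * er * er / (p[sc_j] * p[sc_j] + er * er) * ca4 / (cc4 + ca4);
  const double j_extr = p[D_j] * ca;
  const double j_leak = p[L_j] * er;
  const double lca = std::log10(ca);
  const double j_cat = p[G_cat] * (p[E_Ca] - v) * 0.5 *
                       (1.0 + std::tanh((lca - p[m3_cat]) / p[m4_cat]));
  const double dv_b = v + p[a2_j] * (lca - p[c0_j]) - p[b_j];
  const double p_bk = 0.2 * (1.0 + std::tanh(
      ((lca - p[c0_j]) * (v - p[b_j]) - p[a1_j]) /
      (p[m3b_j] * dv_b * dv_b + p[m4b_j])));
  const double p_sk =
      0.3 * (1.0 + std::tanh((lca - p[m3s_j]) / p[m4s_j]));
  const double i_k = p[G_tot] * (v - p[v_K_j]) * (p_bk + p_sk);
  const double i_r = p[G_R] * (v - p[v_rest_j]);

  dy[0] = j_ip3 - j_eru + j_cicr - j_extr + j_leak + j_cat + p[J0_j] + in_ca;
  dy[1] = j_eru - j_cicr - j_leak;
  dy[2] = -(i_k + i_r) / p[C_m] + in_v;
  dy[3] = j_plc - p[k_j] * ip3 + in_ip3;
}

inline void smc_deriv(const double* y, const double* p,
                      double in_ca, double in_ip3, double in_v, double* dy) {
  const double ca = y[0], sr = y[1], v = y[2], w = y[3], ip3 = y[4];
  const double j_ip3 = p[F_i] * ip3 * ip3 / (p[Kr_i] * p[Kr_i] + ip3 * ip3);
  const double j_sru = p[B_i] * ca * ca / (p[cb_i] * p[cb_i] + ca * ca);
  const double ca4 = ca * ca * ca * ca;
  const double cc4 = p[cc_i] * p[cc_i] * p[cc_i] * p[cc_i];
  const double j_cicr =
      p[C_i] * sr * sr / (p[sc_i] * p[sc_i] + sr * sr) * ca4 / (cc4 + ca4);
  const double j_extr = p[D_i] * ca * (1.0 + (v - p[vd_i]) / p[Rd_i]);
  const double j_leak = p[L_i] * sr;
  const double j_vocc = p[G_Ca] * (v - p[v_Ca1]) /
                        (1.0 + std::exp(-(v - p[v_Ca2]) / p[R_Ca]));
  const double j_naca =
      p[G_NaCa] * ca / (ca + p[c_NaCa]) * (v - p[v_NaCa]);
  const double j_cl = p[G_Cl] * (v - p[v_Cl]);
  const double j_k = p[G_K] * w * (v - p[v_K]);
  const double cw = ca + p[c_w];
  const double k_act =
      cw * cw / (cw * cw + p[beta_i] * std::exp(-(v - p[v_Ca3]) / p[R_K]));

  dy[0] = j_ip3 - j_sru + j_cicr - j_extr + j_leak - j_vocc + j_naca + in_ca;
  dy[1] = j_sru - j_cicr - j_leak;
  dy[2] = p[gamma_i] * (-p[F_NaK] - j_cl - 2.0 * j_vocc - j_naca - j_k) + in_v;
  dy[3] = p[lambda_i] * (k_act - w);
  dy[4] = -p[k_i] * ip3 + in_ip3;
}

// Derivatives for the cells of one domain. `yloc` is the domain-local
// state, `frozen` the full-length global state providing out-of-domain
// neighbour values. With d < 0 all cells are treated as owned (monolithic).
void domain_deriv(const System& S, int d, const double* yloc,
                  const double* frozen, double* dyloc) {
  const double r_ec_v = S.rates[0], r_ec_ca = S.rates[1], r_ec_ip = S.rates[2];
  const double r_sm_v = S.rates[3], r_sm_ca = S.rates[4], r_sm_ip = S.rates[5];
  const double r_h_v = S.rates[6], r_h_ca = S.rates[7], r_h_ip = S.rates[8];
  const bool mono = d < 0;
  static const std::vector<int> empty;

  const std::vector<int>& ecs = mono ? empty : S.dom_ecs[d];
  int necs = mono ? S.n_ec : (int)ecs.size();

  auto ec_at = [&](int j, int comp) -> double {
    if (mono) return yloc[4 * j + comp];
    if (S.dom_ec[j] == d) return yloc[S.loc_ec[j] + comp];
    return frozen[4 * j + comp];
  };
  auto smc_at = [&](int j, int comp) -> double {
    if (mono) return yloc[4 * S.n_ec + 5 * j + comp];
    if (S.dom_smc[j] == d) return yloc[S.loc_smc[j] + comp];
    return frozen[4 * S.n_ec + 5 * j + comp];
  };

  for (int a = 0; a < necs; ++a) {
    const int i = mono ? a : ecs[a];
    const int off = mono ? 4 * i : S.loc_ec[i];
    const double ca = yloc[off], v = yloc[off + 2], ip = yloc[off + 3];
    double in_ca = 0.0, in_ip = 0.0, in_v = 0.0;
    for (int k = S.ec_ptr[i]; k < S.ec_ptr[i + 1]; ++k) {
      const int j = S.ec_idx[k];
      in_ca += r_ec_ca * (ec_at(j, 0) - ca);
      in_v += r_ec_v * (ec_at(j, 2) - v);
      in_ip += r_ec_ip * (ec_at(j, 3) - ip);
    }
    for (int k = S.het_ptr[i]; k < S.het_ptr[i + 1]; ++k) {
      const int m = S.het_smc[k];
      const double w = S.het_w[k];
      in_ca += r_h_ca * w * (smc_at(m, 0) - ca);
      in_v += r_h_v * w * (smc_at(m, 2) - v);
      in_ip += r_h_ip * w * (smc_at(m, 4) - ip);
    }
    ec_deriv(yloc + off, REAL(S.pe), S.agonist[i], in_ca, in_ip, in_v,
             dyloc + off);
  }

  const std::vector<int>& smcs = mono ? empty : S.dom_smcs[d];
  int nsmcs = mono ? S.n_smc : (int)smcs.size();
  for (int a = 0; a < nsmcs; ++a) {
    const int i = mono ? a : smcs[a];
    const int off = mono ? 4 * S.n_ec + 5 * i : S.loc_smc[i];
    const double ca = yloc[off], v = yloc[off + 2], ip = yloc[off + 4];
    double in_ca = 0.0, in_ip = 0.0, in_v = 0.0;
    for (int k = S.smc_ptr[i]; k < S.smc_ptr[i + 1]; ++k) {
      const int j = S.smc_idx[k];
      in_ca += r_sm_ca * (smc_at(j, 0) - ca);
      in_v += r_sm_v * (smc_at(j, 2) - v);
      in_ip += r_sm_ip * (smc_at(j, 4) - ip);
    }
    for (int k = S.hetT_ptr[i]; k < S.hetT_ptr[i + 1]; ++k) {
      const int e = S.hetT_ec[k];
      const double w = S.hetT_w[k];
      in_ca += r_h_ca * w * (ec_at(e, 0) - ca);
      in_v += r_h_v * w * (ec_at(e, 2) - v);
      in_ip += r_h_ip * w * (ec_at(e, 3) - ip);
    }
    smc_deriv(yloc + off, REAL(S.ps), in_ca, in_ip, in_v, dyloc + off);
  }
}

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

struct Stepper {
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp, ynew;
  void resize(int n) {
    k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); k5.resize(n);
    k6.resize(n); k7.resize(n); ytmp.resize(n); ynew.resize(n);
  }
};

// Advance one domain from t0 to t1 with adaptive DP45; y is the
// domain-local vector (modified in place); returns the final step size.
double advance_adaptive(const System& S, int d, std::vector<double>& y,
                        const double* frozen, double t0, double t1,
                        double rtol, double atol, double h0, Stepper& W) {
  const int n = (int)y.size();
  W.resize(n);
  double t = t0;
  double h = (h0 > 0) ? std::min(h0, t1 - t0) : (t1 - t0) / 100.0;
  domain_deriv(S, d, y.data(), frozen, W.k1.data());
  long n_steps = 0;
  const long max_steps = 100000000L;
  while (t < t1) {
    if (h < 1e-12 * std::max(1.0, std::abs(t))) {
      stop("integrator step size underflow in domain %d at t = %g", d + 1, t);
    }
    if (++n_steps > max_steps) {
      stop("integrator exceeded maximum step count in domain %d at t = %g",
           d + 1, t);
    }
    if (t + h > t1) h = t1 - t;

    for (int i = 0; i < n; ++i) W.ytmp[i] = y[i] + h * a21 * W.k1[i];
    domain_deriv(S, d, W.ytmp.data(), frozen, W.k2.data());
    for (int i = 0; i < n; ++i)
      W.ytmp[i] = y[i] + h * (a31 * W.k1[i] + a32 * W.k2[i]);
    domain_deriv(S, d, W.ytmp.data(), frozen, W.k3.data());
    for (int i = 0; i < n; ++i)
      W.ytmp[i] = y[i] + h * (a41 * W.k1[i] + a42 * W.k2[i] + a43 * W.k3[i]);
    domain_deriv(S, d, W.ytmp.data(), frozen, W.k4.data());
    for (int i = 0; i < n; ++i)
      W.ytmp[i] = y[i] + h * (a51 * W.k1[i] + a52 * W.k2[i] + a53 * W.k3[i] +
                              a54 * W.k4[i]);
    domain_deriv(S, d, W.ytmp.data(), frozen, W.k5.data());
    for (int i = 0; i < n; ++i)
      W.ytmp[i] = y[i] + h * (a61 * W.k1[i] + a62 * W.k2[i] + a63 * W.k3[i] +
                              a64 * W.k4[i] + a65 * W.k5[i]);
    domain_deriv(S, d, W.ytmp.data(), frozen, W.k6.data());
    for (int i = 0; i < n; ++i)
      W.ynew[i] = y[i] + h * (b1 * W.k1[i] + b3 * W.k3[i] + b4 * W.k4[i] +
                              b5 * W.k5[i] + b6 * W.k6[i]);
    domain_deriv(S, d, W.ynew.data(), frozen, W.k7.data());

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double e = h * (e1 * W.k1[i] + e3 * W.k3[i] + e4 * W.k4[i] +
                            e5 * W.k5[i] + e6 * W.k6[i] + e7 * W.k7[i]);
      const double sc =
          atol + rtol * std::max(std::abs(y[i]), std::abs(W.ynew[i]));
      err += (e / sc) * (e / sc);
    }
    err = std::sqrt(err / n);

    if (err <= 1.0 || h <= 1e-12) {
      t += h;
      y.swap(W.ynew);
      W.k1.swap(W.k7); // FSAL
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
  }
  return h;
}

void gather_domain(const System& S, int d, const double* g,
                   std::vector<double>& y) {
  y.resize(S.dom_size(d));
  for (int i : S.dom_ecs[d])
    for (int c = 0; c < 4; ++c) y[S.loc_ec[i] + c] = g[4 * i + c];
  for (int i : S.dom_smcs[d])
    for (int c = 0; c < 5; ++c)
      y[S.loc_smc[i] + c] = g[4 * S.n_ec + 5 * i + c];
}

void scatter_domain(const System& S, int d, const std::vector<double>& y,
                    double* g) {
  for (int i : S.dom_ecs[d])
    for (int c = 0; c < 4; ++c) g[4 * i + c] = y[S.loc_ec[i] + c];
  for (int i : S.dom_smcs[d])
    for (int c = 0; c < 5; ++c)
      g[4 * S.n_ec + 5 * i + c] = y[S.loc_smc[i] + c];
}

} // namespace

// [[Rcpp::export]]
NumericVector tissue_deriv_cpp(NumericVector state, List sys) {
  System S(sys);
  if ((int)state.size() != S.n_state()) {
    stop("state length %d does not match 4*n_ec + 5*n_smc = %d",
         (int)state.size(), S.n_state());
  }
  std::vector<double> y(state.begin(), state.end()), dy(y.size());
  domain_deriv(S, -1, y.data(), nullptr, dy.data());
  return NumericVector(dy.begin(), dy.end());
}

// Serial reference backend: loops communication intervals, advancing every
// domain against the interval's frozen state; records snapshots at the
// requested output times (which must lie on interval boundaries).
// [[Rcpp::export]]
NumericMatrix integrate_tissue_cpp(NumericVector y0, NumericVector out_times,
                                   double comm_interval, List sys,
                                   double rtol, double atol) {
  System S(sys);
  if ((int)y0.size() != S.n_state()) stop("initial state length mismatch");
  const int n = S.n_state();
  NumericMatrix snaps(out_times.size(), n);

  std::vector<double> g(y0.begin(), y0.end()), frozen(n);
  std::vector<double> h_last(S.n_dom, -1.0);
  std::vector<double> yloc;
  Stepper W;

  double t = out_times[0];
  for (int c = 0; c < n; ++c) snaps(0, c) = g[c];

  int next_out = 1;
  const double t_end = out_times[out_times.size() - 1];
  const double eps = 1e-9 * std::max(1.0, std::abs(t_end));
  while (t < t_end - eps) {
    double t1 = std::min(t + comm_interval, t_end);
    if (S.n_dom == 1) {
      gather_domain(S, 0, g.data(), yloc);
      h_last[0] = advance_adaptive(S, 0, yloc, nullptr, t, t1, rtol, atol,
                                   h_last[0], W);
      scatter_domain(S, 0, yloc, g.data());
    } else {
      frozen = g;
      for (int d = 0; d < S.n_dom; ++d) {
        gather_domain(S, d, frozen.data(), yloc);
        h_last[d] = advance_adaptive(S, d, yloc, frozen.data(), t, t1, rtol,
                                     atol, h_last[d], W);
        scatter_domain(S, d, yloc, g.data());
      }
    }
    t = t1;
    if (next_out < (int)out_times.size() &&
        std::abs(t - out_times[next_out]) < eps) {
      for (int c = 0; c < n; ++c) snaps(next_out, c) = g[c];
      ++next_out;
    }
    Rcpp::checkUserInterrupt();
  }
  if (next_out != (int)out_times.size()) {
    stop("output times must be multiples of the communication interval");
  }
  return snaps;
}

// Advance a subset of domains over one communication interval against a
// common frozen state; used by the parallel backend. Returns the full-length
// state with only the subset's entries updated, plus final step sizes.
// [[Rcpp::export]]
List advance_domains_cpp(NumericVector y_frozen, IntegerVector domains,
                         double t0, double t1, List sys, double rtol,
                         double atol, NumericVector h_init) {
  System S(sys);
  std::vector<double> frozen(y_frozen.begin(), y_frozen.end());
  std::vector<double> g(frozen);
  NumericVector h_out(domains.size());
  std::vector<double> yloc;
  Stepper W;
  for (int k = 0; k < (int)domains.size(); ++k) {
    const int d = domains[k];
    gather_domain(S, d, frozen.data(), yloc);
    h_out[k] = advance_adaptive(S, d, yloc, frozen.data(), t0, t1, rtol, atol,
                                h_init[k], W);
    scatter_domain(S, d, yloc, g.data());
  }
  return List::create(_["state"] = NumericVector(g.begin(), g.end()),
                      _["h_last"] = h_out);
}
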