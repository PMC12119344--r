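// Compiled cores for the multiscale simulators.
//
// Unit conventions throughout: time ms, voltage mV, conductance nS,
// capacitance pF (pF/nS = ms), current pA (pA/nS = mV), rates passed in Hz
// and converted to 1/ms internally where needed. All randomness goes through
// R's RNG (set.seed() on the R side controls every simulator).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Semi-analytic transfer function
// ---------------------------------------------------------------------------

struct TFSpec {
  // single-cell constants
  double cm, gl, el;
  // synapse constants
  double qe, qi, taue, taui, ee, ei;
  // synaptic in-degrees
  double ke, ki;
  // effective-threshold polynomial (P0, Pmu, Psig, Ptau, Pmumu, Pmusig,
  // Pmutau, Psigsig, Psigtau, Ptautau)
  double P[10];
  // fiducial normalisation of the fluctuation variables
  double muv0, dmuv0, sv0, dsv0, tvn0, dtvn0;
};

static TFSpec tf_from_list(const List& x) {
  TFSpec tf;
  List neuron = x["neuron"], syn = x["synapse"];
  tf.cm = as<double>(neuron["c_m"]);
  tf.gl = as<double>(neuron["g_L"]);
  tf.el = as<double>(neuron["E_L"]);
  tf.qe = as<double>(syn["Q_e"]);
  tf.qi = as<double>(syn["Q_i"]);
  tf.taue = as<double>(syn["tau_e"]);
  tf.taui = as<double>(syn["tau_i"]);
  tf.ee = as<double>(syn["E_e"]);
  tf.ei = as<double>(syn["E_i"]);
  tf.ke = as<double>(x["K_e"]);
  tf.ki = as<double>(x["K_i"]);
  NumericVector p = x["coefficients"];
  if (p.size() != 10) stop("transfer-function coefficient vector must have length 10");
  for (int i = 0; i < 10; ++i) tf.P[i] = p[i];
  NumericVector fid = x["fiducials"];
  if (fid.size() != 6) stop("fiducial vector must have length 6");
  tf.muv0 = fid[0]; tf.dmuv0 = fid[1];
  tf.sv0 = fid[2];  tf.dsv0 = fid[3];
  tf.tvn0 = fid[4]; tf.dtvn0 = fid[5];
  return tf;
}

// Membrane fluctuation statistics under Poissonian shot-noise input.
// Rates in Hz, w in pA. Outputs muv (mV), sv (mV), tauv (ms).
static inline void tf_stats(const TFSpec& tf, double nue, double nui, double w,
                            double& muv, double& sv, double& tauv) {
  if (nue < 0) nue = 0;
  if (nui < 0) nui = 0;
  const double nue_ms = nue * 1e-3, nui_ms = nui * 1e-3;
  const double muge = nue_ms * tf.ke * tf.taue * tf.qe;
  const double mugi = nui_ms * tf.ki * tf.taui * tf.qi;
  const double mug = muge + mugi + tf.gl;
  const double tm = tf.cm / mug;
  muv = (muge * tf.ee + mugi * tf.ei + tf.gl * tf.el - w) / mug;
  const double ue = (tf.qe / mug) * (tf.ee - muv);
  const double ui = (tf.qi / mug) * (tf.ei - muv);
  const double ae = tf.ke * nue_ms * ue * ue * tf.taue * tf.taue;
  const double ai = tf.ki * nui_ms * ui * ui * tf.taui * tf.taui;
  const double se2 = ae / (2.0 * (tm + tf.taue)) + ai / (2.0 * (tm + tf.taui));
  sv = std::sqrt(se2 > 0 ? se2 : 0.0);
  const double den = ae / (tm + tf.taue) + ai / (tm + tf.taui);
  tauv = (den > 0) ? (ae + ai) / den : tm;
}

// Output firing rate in Hz given input rates (Hz) and adaptation w (pA).
static inline double tf_rate(const TFSpec& tf, double nue, double nui, double w) {
  double muv, sv, tauv;
  tf_stats(tf, nue, nui, w, muv, sv, tauv);
  if (!(sv > 1e-10)) return 0.0;      // zero-fluctuation limit: subthreshold
  const double tvn = tauv * tf.gl / tf.cm;
  const double x1 = (muv - tf.muv0) / tf.dmuv0;
  const double x2 = (sv - tf.sv0) / tf.dsv0;
  const double x3 = (tvn - tf.tvn0) / tf.dtvn0;
  const double veff = tf.P[0] + tf.P[1] * x1 + tf.P[2] * x2 + tf.P[3] * x3 +
                      tf.P[4] * x1 * x1 + tf.P[5] * x1 * x2 + tf.P[6] * x1 * x3 +
                      tf.P[7] * x2 * x2 + tf.P[8] * x2 * x3 + tf.P[9] * x3 * x3;
  const double z = (veff - muv) / (M_SQRT2 * sv);
  double rate_ms = 0.5 / tauv * std::erfc(z);
  if (rate_ms < 0) rate_ms = 0;
  return rate_ms * 1e3;
}

// [[Rcpp::export]]
NumericVector cpp_tf_rate(List tf_, NumericVector nu_e, NumericVector nu_i,
                          NumericVector w) {
  TFSpec tf = tf_from_list(tf_);
  const int n = nu_e.size();
  if (nu_i.size() != n || w.size() != n)
    stop("nu_e, nu_i and w must have equal length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tf_rate(tf, nu_e[i], nu_i[i], w[i]);
  return out;
}

// Fluctuation statistics of the compiled transfer-function path, exposed so
// the R implementation can be cross-checked against it.
// [[Rcpp::export]]
NumericMatrix cpp_tf_stats(List tf_, NumericVector nu_e, NumericVector nu_i,
                           NumericVector w) {
  TFSpec tf = tf_from_list(tf_);
  const int n = nu_e.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("mu_V", "sigma_V", "tau_V");
  for (int i = 0; i < n; ++i) {
    double muv, sv, tauv;
    tf_stats(tf, nu_e[i], nu_i[i], w[i], muv, sv, tauv);
    out(i, 0) = muv; out(i, 1) = sv; out(i, 2) = tauv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Single AdEx neuron under Poissonian conductance bombardment
// ---------------------------------------------------------------------------

struct Cell {
  double cm, gl, el, delta, vthr, vrest, trefr, a, b, tauw;
};

static Cell cell_from_list(const List& x) {
  Cell c;
  c.cm = as<double>(x["c_m"]);   c.gl = as<double>(x["g_L"]);
  c.el = as<double>(x["E_L"]);   c.delta = as<double>(x["delta"]);
  c.vthr = as<double>(x["v_thr"]); c.vrest = as<double>(x["v_rest"]);
  c.trefr = as<double>(x["t_refr"]); c.a = as<double>(x["a"]);
  c.b = as<double>(x["b"]);      c.tauw = as<double>(x["tau_w"]);
  return c;
}

struct Syn {
  double qe, qi, taue, taui, ee, ei;
};

static Syn syn_from_list(const List& x) {
  Syn s;
  s.qe = as<double>(x["Q_e"]); s.qi = as<double>(x["Q_i"]);
  s.taue = as<double>(x["tau_e"]); s.taui = as<double>(x["tau_i"]);
  s.ee = as<double>(x["E_e"]); s.ei = as<double>(x["E_i"]);
  return s;
}

static const double V_SPIKE = 0.0;   // numerical spike-detection ceiling (mV)
static const double EXP_CAP = 30.0;  // cap on the exponential argument

// Membrane-equation right-hand side (dv/dt, mV/ms)
static inline double dvdt(const Cell& c, double v, double w, double ge,
                          double gi, double ee, double ei) {
  double ex = (v - c.vthr) / c.delta;
  if (ex > EXP_CAP) ex = EXP_CAP;
  const double isyn = ge * (ee - v) + gi * (ei - v);
  return (c.gl * (c.el - v) + c.gl * c.delta * std::exp(ex) - w + isyn) / c.cm;
}

// Simulates one neuron receiving independent excitatory/inhibitory Poisson
// spike trains with total arrival rates rate_e/rate_i (Hz). Returns the
// output rate and subthreshold voltage moments measured after `discard` ms.
// When clamp_w is true the adaptation current is held at w_init (it enters
// the membrane equation like a constant hyperpolarising current), which is
// how the transfer function is sampled along its adaptation axis.
// [[Rcpp::export]]
List cpp_single_neuron(List cell_, List syn_, double rate_e, double rate_i,
                       double duration, double dt, double discard,
                       double w_init = 0.0, bool clamp_w = false) {
  Cell c = cell_from_list(cell_);
  Syn s = syn_from_list(syn_);
  const double dece = std::exp(-dt / s.taue), deci = std::exp(-dt / s.taui);
  const double lam_e = rate_e * dt * 1e-3, lam_i = rate_i * dt * 1e-3;
  const int nstep = (int)std::ceil(duration / dt);
  double v = c.el, w = w_init, ge = 0.0, gi = 0.0, refr_until = -1.0;
  long nspk = 0;
  double sv1 = 0.0, sv2 = 0.0;
  long nsamp = 0;
  RNGScope scope;
  for (int k = 0; k < nstep; ++k) {
    const double t = k * dt;
    ge = ge * dece + s.qe * R::rpois(lam_e);
    gi = gi * deci + s.qi * R::rpois(lam_i);
    if (t < refr_until) {
      v = c.vrest;
      if (!clamp_w) w += dt * (c.a * (v - c.el) - w) / c.tauw;
      continue;
    }
    const double dv = dvdt(c, v, w, ge, gi, s.ee, s.ei);
    v += dt * dv;
    if (!clamp_w) w += dt * (c.a * (v - c.el) - w) / c.tauw;
    if (v >= V_SPIKE) {
      v = c.vrest;
      if (!clamp_w) w += c.b;
      refr_until = t + dt + c.trefr;
      if (t >= discard) ++nspk;
    } else if (t >= discard) {
      sv1 += v; sv2 += v * v; ++nsamp;
    }
  }
  const double tmeas = (duration - discard) * 1e-3; // s
  const double mu = nsamp > 0 ? sv1 / nsamp : NA_REAL;
  const double var = nsamp > 1 ? (sv2 / nsamp - mu * mu) : NA_REAL;
  return List::create(_["rate"] = nspk / tmeas,
                      _["n_spikes"] = (double)nspk,
                      _["mu_V"] = mu,
                      _["sigma_V"] = var > 0 ? std::sqrt(var) : 0.0);
}

// ---------------------------------------------------------------------------
// Two-population AdEx spiking network
// ---------------------------------------------------------------------------

// targets/ptr: CSR adjacency over presynaptic neurons (0-based targets;
// neuron j projects to targets[ptr[j] .. ptr[j+1]-1]).
// is_inh: population label per neuron. ext_rate: afferent rate nu_aff(t) in
// Hz, one value per integration step (each neuron receives an independent
// Poisson train of total rate nu_aff * k_ext).
// [[Rcpp::export]]
List cpp_simulate_network(IntegerVector targets, IntegerVector ptr,
                          LogicalVector is_inh, List cell_e_, List cell_i_,
                          List syn_, NumericVector ext_rate, double k_ext,
                          double dt, double rate_bin, bool init_uniform,
                          bool record_w) {
  const int n = is_inh.size();
  if (ptr.size() != n + 1) stop("adjacency pointer has wrong length");
  Cell ce = cell_from_list(cell_e_), ci = cell_from_list(cell_i_);
  Syn s = syn_from_list(syn_);
  const double dece = std::exp(-dt / s.taue), deci = std::exp(-dt / s.taui);
  const int nstep = ext_rate.size();
  const double duration = nstep * dt;

  std::vector<double> v(n), w(n, 0.0), ge(n, 0.0), gi(n, 0.0),
      refr_until(n, -1.0);
  RNGScope scope;
  int ne_count = 0, ni_count = 0;
  for (int i = 0; i < n; ++i) {
    const Cell& c = is_inh[i] ? ci : ce;
    v[i] = init_uniform ? R::runif(c.el, c.vthr) : c.el;
    if (is_inh[i]) ++ni_count; else ++ne_count;
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spikers;
  spikers.reserve(256);

  const int nbin = (int)std::ceil(duration / rate_bin);
  std::vector<double> cnt_e(nbin, 0.0), cnt_i(nbin, 0.0);
  const int wstride = std::max(1, (int)std::floor(1.0 / dt)); // 1-ms samples
  std::vector<double> wtrace;
  if (record_w) wtrace.reserve(nstep / wstride + 1);

  for (int k = 0; k < nstep; ++k) {
    const double t = k * dt;
    const double lam = ext_rate[k] * k_ext * dt * 1e-3;
    spikers.clear();
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const Cell& c = is_inh[i] ? ci : ce;
      ge[i] = ge[i] * dece + (lam > 0 ? s.qe * R::rpois(lam) : 0.0);
      gi[i] *= deci;
      if (t < refr_until[i]) {
        v[i] = c.vrest;
        w[i] += dt * (c.a * (v[i] - c.el) - w[i]) / c.tauw;
      } else {
        v[i] += dt * dvdt(c, v[i], w[i], ge[i], gi[i], s.ee, s.ei);
        w[i] += dt * (c.a * (v[i] - c.el) - w[i]) / c.tauw;
        if (v[i] >= V_SPIKE) {
          v[i] = c.vrest;
          w[i] += c.b;
          refr_until[i] = t + dt + c.trefr;
          spikers.push_back(i);
        }
      }
      if (record_w && !is_inh[i]) wsum += w[i];
    }
    // propagate spikes (arrive on the next step's conductances)
    const int ib = (int)(t / rate_bin);
    for (size_t m = 0; m < spikers.size(); ++m) {
      const int j = spikers[m];
      spike_t.push_back(t);
      spike_id.push_back(j);
      if (is_inh[j]) cnt_i[ib] += 1.0; else cnt_e[ib] += 1.0;
      const double q = is_inh[j] ? s.qi : s.qe;
      if (is_inh[j]) {
        for (int e = ptr[j]; e < ptr[j + 1]; ++e) gi[targets[e]] += q;
      } else {
        for (int e = ptr[j]; e < ptr[j + 1]; ++e) ge[targets[e]] += q;
      }
    }
    if (record_w && (k % wstride == 0)) wtrace.push_back(wsum / ne_count);
    if (k % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector re(nbin), ri(nbin);
  for (int b = 0; b < nbin; ++b) {
    re[b] = cnt_e[b] / (ne_count * rate_bin * 1e-3); // Hz per neuron
    ri[b] = cnt_i[b] / (ni_count * rate_bin * 1e-3);
  }
  return List::create(_["spike_times"] = wrap(spike_t),
                      _["spike_ids"] = wrap(spike_id),
                      _["rate_e"] = re, _["rate_i"] = ri,
                      _["rate_bin"] = rate_bin,
                      _["w_trace"] = record_w ? wrap(wtrace) : R_NilValue,
                      _["n_e"] = ne_count, _["n_i"] = ni_count);
}

// ---------------------------------------------------------------------------
// Mean-field integrators
// ---------------------------------------------------------------------------

// OU increment helper: Wiener process with unit amplitude, time in seconds.
static inline double ou_step(double xi, double dt_ms, double tau_ou_ms) {
  const double dt_s = dt_ms * 1e-3;
  return xi - xi * (dt_ms / tau_ou_ms) + std::sqrt(dt_s) * norm_rand();
}

// First- or second-order mean-field for one excitatory/inhibitory module.
// be/ae/tauw/el_e: adaptation parameters of the excitatory population.
// Returns trajectories sampled every record_every steps.
// [[Rcpp::export]]
List cpp_simulate_mean_field(List tfe_, List tfi_, double be, double ae,
                             double tauw, double el_e, double Tmf,
                             double duration, double dt, double nu_drive,
                             double sigma, double tau_ou, int order,
                             double n_e, double n_i, int record_every,
                             double nu_e0, double nu_i0, double w0,
                             double rate_cap) {
  TFSpec tfe = tf_from_list(tfe_), tfi = tf_from_list(tfi_);
  const int nstep = (int)std::ceil(duration / dt);
  const int nrec = nstep / record_every + 1;
  NumericVector t_out(nrec), nue_out(nrec), nui_out(nrec), w_out(nrec),
      aff_out(nrec);
  NumericVector cee_out, cei_out, cii_out;
  if (order == 2) {
    cee_out = NumericVector(nrec);
    cei_out = NumericVector(nrec);
    cii_out = NumericVector(nrec);
  }
  double nue = nu_e0, nui = nu_i0, w = w0, xi = 0.0;
  double cee = 0.0, cei = 0.0, cii = 0.0;
  const double h = 1e-2; // finite-difference step, Hz
  RNGScope scope;
  int ir = 0;
  bool diverged = false;
  for (int k = 0; k <= nstep; ++k) {
    const double t = k * dt;
    double nuaff = nu_drive + sigma * xi;
    if (nuaff < 0) nuaff = 0;
    if (k % record_every == 0 && ir < nrec) {
      t_out[ir] = t; nue_out[ir] = nue; nui_out[ir] = nui; w_out[ir] = w;
      aff_out[ir] = nuaff;
      if (order == 2) { cee_out[ir] = cee; cei_out[ir] = cei; cii_out[ir] = cii; }
      ++ir;
    }
    if (k == nstep) break;

    const double xe = nue + nuaff; // excitatory input rate seen by both TFs
    const double fe = tf_rate(tfe, xe, nui, w);
    const double fi = tf_rate(tfi, xe, nui, 0.0);
    double dnue = (fe - nue), dnui = (fi - nui);

    if (order == 2) {
      // first and second derivatives of both TFs wrt (nu_e, nu_i)
      double fe_ep = tf_rate(tfe, xe + h, nui, w), fe_em = tf_rate(tfe, xe - h, nui, w);
      double fe_ip = tf_rate(tfe, xe, nui + h, w), fe_im = tf_rate(tfe, xe, nui - h, w);
      double fi_ep = tf_rate(tfi, xe + h, nui, 0), fi_em = tf_rate(tfi, xe - h, nui, 0);
      double fi_ip = tf_rate(tfi, xe, nui + h, 0), fi_im = tf_rate(tfi, xe, nui - h, 0);
      const double dfe_e = (fe_ep - fe_em) / (2 * h), dfe_i = (fe_ip - fe_im) / (2 * h);
      const double dfi_e = (fi_ep - fi_em) / (2 * h), dfi_i = (fi_ip - fi_im) / (2 * h);
      const double d2fe_ee = (fe_ep - 2 * fe + fe_em) / (h * h);
      const double d2fe_ii = (fe_ip - 2 * fe + fe_im) / (h * h);
      const double d2fi_ee = (fi_ep - 2 * fi + fi_em) / (h * h);
      const double d2fi_ii = (fi_ip - 2 * fi + fi_im) / (h * h);
      const double d2fe_ei = (tf_rate(tfe, xe + h, nui + h, w) - fe_ep - fe_ip + fe) / (h * h);
      const double d2fi_ei = (tf_rate(tfi, xe + h, nui + h, 0) - fi_ep - fi_ip + fi) / (h * h);
      dnue += 0.5 * (cee * d2fe_ee + 2 * cei * d2fe_ei + cii * d2fe_ii);
      dnui += 0.5 * (cee * d2fi_ee + 2 * cei * d2fi_ei + cii * d2fi_ii);
      const double invT = 1e3 / Tmf; // Hz
      const double dcee = fe * (invT - fe) / n_e + (fe - nue) * (fe - nue) +
                          2 * (dfe_e * cee + dfe_i * cei) - 2 * cee;
      const double dcii = fi * (invT - fi) / n_i + (fi - nui) * (fi - nui) +
                          2 * (dfi_e * cei + dfi_i * cii) - 2 * cii;
      const double dcei = (fe - nue) * (fi - nui) +
                          dfe_e * cei + dfe_i * cii +
                          dfi_e * cee + dfi_i * cei - 2 * cei;
      cee += dt / Tmf * dcee;
      cii += dt / Tmf * dcii;
      cei += dt / Tmf * dcei;
      if (cee < 0) cee = 0;
      if (cii < 0) cii = 0;
    }

    nue += dt / Tmf * dnue;
    nui += dt / Tmf * dnui;
    if (nue < 0) nue = 0;
    if (nui < 0) nui = 0;
    double muv, sv, tauv;
    tf_stats(tfe, xe, nui, w, muv, sv, tauv);
    w += dt * (-w / tauw + be * nue * 1e-3 + (ae / tauw) * (muv - el_e));
    xi = ou_step(xi, dt, tau_ou);
    if (nue > rate_cap || nui > rate_cap || !std::isfinite(nue) ||
        !std::isfinite(nui) || !std::isfinite(w)) {
      diverged = true;
      break;
    }
    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["time"] = t_out, _["nu_e"] = nue_out,
                          _["nu_i"] = nui_out, _["W"] = w_out,
                          _["nu_aff"] = aff_out, _["diverged"] = diverged,
                          _["n_recorded"] = ir);
  if (order == 2) {
    out["c_ee"] = cee_out; out["c_ei"] = cei_out; out["c_ii"] = cii_out;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Whole-brain network of first-order mean-field nodes with delays
// ---------------------------------------------------------------------------

// edge list (0-based): src, dst, weight (already G-scaled, diagonal excluded),
// delay in integration steps. Each node has an independent OU drive.
// [[Rcpp::export]]
List cpp_simulate_whole_brain(List tfe_, List tfi_, int n_nodes,
                              IntegerVector e_src, IntegerVector e_dst,
                              NumericVector e_w, IntegerVector e_delay,
                              double be, double ae, double tauw, double el_e,
                              double Tmf, double duration, double dt,
                              double nu_drive, double sigma, double tau_ou,
                              int stim_node, double stim_onset,
                              double stim_dur, double stim_amp,
                              int record_every, double nu_e0, double nu_i0,
                              double rate_cap) {
  TFSpec tfe = tf_from_list(tfe_), tfi = tf_from_list(tfi_);
  const int nstep = (int)std::ceil(duration / dt);
  const int nedge = e_src.size();
  int maxd = 0;
  for (int e = 0; e < nedge; ++e) if (e_delay[e] > maxd) maxd = e_delay[e];
  const int hlen = maxd + 1;

  std::vector<double> nue(n_nodes, nu_e0), nui(n_nodes, nu_i0),
      w(n_nodes, 0.0), xi(n_nodes, 0.0), coup(n_nodes, 0.0),
      nue_new(n_nodes), nui_new(n_nodes);
  // ring buffer of nu_e history: hist[(k % hlen) * n_nodes + node]
  std::vector<double> hist((size_t)hlen * n_nodes, nu_e0);

  const int nrec = nstep / record_every + 1;
  NumericMatrix rec_e(nrec, n_nodes), rec_i(nrec, n_nodes), rec_w(nrec, n_nodes);
  NumericVector t_out(nrec);
  RNGScope scope;
  int ir = 0;
  bool diverged = false;
  for (int k = 0; k <= nstep; ++k) {
    const double t = k * dt;
    if (k % record_every == 0 && ir < nrec) {
      t_out[ir] = t;
      for (int m = 0; m < n_nodes; ++m) {
        rec_e(ir, m) = nue[m]; rec_i(ir, m) = nui[m]; rec_w(ir, m) = w[m];
      }
      ++ir;
    }
    if (k == nstep) break;

    std::fill(coup.begin(), coup.end(), 0.0);
    for (int e = 0; e < nedge; ++e) {
      const int kk = k - e_delay[e];
      const double past = (kk >= 0) ? hist[(size_t)(kk % hlen) * n_nodes + e_src[e]]
                                    : nu_e0;
      coup[e_dst[e]] += e_w[e] * past;
    }
    const bool stim_on = stim_node >= 0 && t >= stim_onset &&
                         t < stim_onset + stim_dur;
    for (int m = 0; m < n_nodes; ++m) {
      double nuaff = nu_drive + sigma * xi[m];
      if (nuaff < 0) nuaff = 0;
      double xin = nue[m] + nuaff + coup[m];
      if (stim_on && m == stim_node) xin += stim_amp;
      const double fe = tf_rate(tfe, xin, nui[m], w[m]);
      const double fi = tf_rate(tfi, xin, nui[m], 0.0);
      nue_new[m] = nue[m] + dt / Tmf * (fe - nue[m]);
      nui_new[m] = nui[m] + dt / Tmf * (fi - nui[m]);
      if (nue_new[m] < 0) nue_new[m] = 0;
      if (nui_new[m] < 0) nui_new[m] = 0;
      double muv, sv, tauv;
      tf_stats(tfe, xin, nui[m], w[m], muv, sv, tauv);
      w[m] += dt * (-w[m] / tauw + be * nue[m] * 1e-3 + (ae / tauw) * (muv - el_e));
      xi[m] = ou_step(xi[m], dt, tau_ou);
      if (nue_new[m] > rate_cap || !std::isfinite(nue_new[m]) ||
          !std::isfinite(w[m])) diverged = true;
    }
    for (int m = 0; m < n_nodes; ++m) {
      nue[m] = nue_new[m];
      nui[m] = nui_new[m];
      hist[(size_t)((k + 1) % hlen) * n_nodes + m] = nue[m];
    }
    if (diverged) break;
    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = t_out, _["nu_e"] = rec_e, _["nu_i"] = rec_i,
                      _["W"] = rec_w, _["diverged"] = diverged,
                      _["n_recorded"] = ir);
}

// ---------------------------------------------------------------------------
// Lempel-Ziv (LZ76) complexity
// ---------------------------------------------------------------------------

// Kaspar-Schuster counting of the LZ76 exhaustive-history phrases.
// [[Rcpp::export]]
int cpp_lz76(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
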