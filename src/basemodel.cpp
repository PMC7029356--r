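// Core right-hand side and fixed-step integrator for the cardiomyocyte
// base model: membrane potential, 13 membrane currents, five intracellular
// Ca2+ compartments with first-order buffers, SERCA uptake, inter-compartment
// diffusion and availability-limited RyR release.
//
// Units package-wide: ms, mV, mM, A/F; fluxes in mmol/ms; volumes in L.
// Gating kinetics follow Hodgkin-Huxley style formulations adapted from the
// ten Tusscher (2004) and Grandi (2010) adult ventricular models and the
// Paci (2013) hiPSC-CM model (funny current); see the package vignette.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- parameter indexing (kept in sync with .param_names in R/parameters.R)
enum Par {
  P_gNa = 0, P_gNaL, P_gCaL, P_gto, P_gKr, P_gKs, P_gK1, P_gNaK, P_gNaCa,
  P_gpCa, P_gbCa, P_gbCl, P_gf,
  P_aRyR, P_bRyR, P_gammaRyR, P_etaRyR, P_kappaRyR,
  P_gSERCA, P_kSERCA,
  P_Bd, P_Bsl, P_Bc, P_Bs,
  P_kond, P_konsl, P_konc, P_kons,
  P_koffd, P_koffsl, P_koffc, P_koffs,
  P_adc, P_aslc, P_ans,
  P_Vcell, P_chi, P_Cm,
  P_fracd, P_fracsl, P_fracc, P_fracs, P_fracn,
  P_Nai, P_Ki, P_Nao, P_Ko, P_Cao,
  P_Ef, P_ECl, P_kfCa,
  NPAR
};

// ---- state indexing (kept in sync with .state_names in R/parameters.R)
enum St {
  S_v = 0,
  S_m, S_h, S_j, S_mL, S_hL, S_d, S_f, S_fCa,
  S_r_to, S_s_to, S_xr1, S_xr2, S_xs, S_xf,
  S_cd, S_csl, S_cc, S_cs, S_cn,
  S_bd, S_bsl, S_bc, S_bs,
  S_rRyR,
  NSTATE
};

static const int NGATE = 14;              // states S_m .. S_xf
static const int NCUR = 14;               // 13 currents + stimulus
static const int NFLUX = 12;

static const double FARADAY = 96485.0;    // C/mol
static const double RTF = 26.712832;      // RT/F at 310 K, mV

static inline double time_in_cycle(double t, double period) {
  return t - period * std::floor(t / period);
}

// gate steady states and time constants; gates are states S_m..S_xf in order
static void gate_rates(double v, double cd, double kfca,
                       double *ginf, double *gtau) {
  // I_Na m, h, j (ten Tusscher 2004)
  double am = 1.0 / (1.0 + exp((-60.0 - v) / 5.0));
  double bm = 0.1 / (1.0 + exp((v + 35.0) / 5.0)) +
              0.1 / (1.0 + exp((v - 50.0) / 200.0));
  double minf = 1.0 / (1.0 + exp((-56.86 - v) / 9.03));
  ginf[0] = minf * minf;
  gtau[0] = am * bm;

  double hinf = 1.0 / (1.0 + exp((v + 71.55) / 7.43));
  ginf[1] = hinf * hinf;
  double ah, bh;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp(-(v + 10.66) / 11.1)));
  } else {
    ah = 0.057 * exp(-(v + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v);
  }
  gtau[1] = 1.0 / (ah + bh);

  ginf[2] = ginf[1];
  double aj, bj;
  if (v >= -40.0) {
    aj = 0.0;
    bj = 0.6 * exp(0.057 * v) / (1.0 + exp(-0.1 * (v + 32.0)));
  } else {
    aj = (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + exp(0.311 * (v + 79.23)));
    bj = 0.02424 * exp(-0.01052 * v) / (1.0 + exp(-0.1378 * (v + 40.14)));
  }
  gtau[2] = 1.0 / (aj + bj);

  // I_NaL mL, hL (late sodium; mL shares the fast-Na activation time scale)
  ginf[3] = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
  gtau[3] = gtau[0];
  ginf[4] = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
  gtau[4] = 200.0;

  // I_CaL d, f, fCa
  double dinf = 1.0 / (1.0 + exp((-5.0 - v) / 7.5));
  double ad = 1.4 / (1.0 + exp((-35.0 - v) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + exp((v + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + exp((50.0 - v) / 20.0));
  ginf[5] = dinf;
  gtau[5] = ad * bd + gd;

  ginf[6] = 1.0 / (1.0 + exp((v + 20.0) / 7.0));
  gtau[6] = 2.0 * (1125.0 * exp(-(v + 27.0) * (v + 27.0) / 240.0) + 80.0 +
                   165.0 / (1.0 + exp((25.0 - v) / 10.0)));

  // Ca-dependent inactivation driven by dyadic Ca2+ (smooth formulation)
  double cr = cd / kfca;
  ginf[7] = 0.02 + 0.98 / (1.0 + cr * cr);
  gtau[7] = 5.0;

  // I_to r (activation), s (inactivation); epicardial kinetics
  ginf[8] = 1.0 / (1.0 + exp((20.0 - v) / 6.0));
  gtau[8] = 9.5 * exp(-(v + 40.0) * (v + 40.0) / 1800.0) + 0.8;
  ginf[9] = 1.0 / (1.0 + exp((v + 20.0) / 5.0));
  gtau[9] = 85.0 * exp(-(v + 45.0) * (v + 45.0) / 320.0) +
            5.0 / (1.0 + exp((v - 20.0) / 5.0)) + 3.0;

  // I_Kr xr1, xr2
  ginf[10] = 1.0 / (1.0 + exp((-26.0 - v) / 7.0));
  gtau[10] = 450.0 / (1.0 + exp((-45.0 - v) / 10.0)) *
             6.0 / (1.0 + exp((v + 30.0) / 11.5));
  // fast hERG-like rectification: suppressed at depolarized plateau,
  // resurgent during repolarization
  ginf[11] = 1.0 / (1.0 + exp((v + 20.0) / 15.0));
  gtau[11] = 4.0;

  // I_Ks xs
  ginf[12] = 1.0 / (1.0 + exp((-5.0 - v) / 14.0));
  gtau[12] = 140.0 / sqrt(1.0 + exp((-10.0 - v) / 6.0)) *
             1.0 / (1.0 + exp((v - 60.0) / 20.0));

  // I_f xf (hyperpolarization-activated funny current, Paci 2013 kinetics)
  ginf[13] = 1.0 / (1.0 + exp((v + 77.85) / 5.0));
  gtau[13] = 1900.0 / (1.0 + exp((v + 15.0) / 10.0));
}

// currents (A/F) and fluxes (mmol/ms) for a given state
static void currents_fluxes(const double *y, const double *p, double istim,
                            double *I, double *J) {
  double v = y[S_v];
  double ENa = RTF * log(p[P_Nao] / p[P_Nai]);
  double EK = RTF * log(p[P_Ko] / p[P_Ki]);
  double EKs = RTF * log((p[P_Ko] + 0.03 * p[P_Nao]) /
                         (p[P_Ki] + 0.03 * p[P_Nai]));
  double csl = y[S_csl];
  double ECa = 0.5 * RTF * log(p[P_Cao] / (csl > 1e-8 ? csl : 1e-8));

  I[0] = p[P_gNa] * y[S_m] * y[S_m] * y[S_m] * y[S_h] * y[S_j] * (v - ENa);
  I[1] = p[P_gNaL] * y[S_mL] * y[S_hL] * (v - ENa);

  // L-type Ca current: GHK-type driving force with dyadic Ca2+ inside
  double vf = v / RTF;
  double e2 = exp(2.0 * vf);
  double drive;
  if (fabs(v) < 1e-4) {
    drive = 2.0 * FARADAY * (y[S_cd] - 0.341 * p[P_Cao]);
  } else {
    drive = 4.0 * v * (FARADAY / RTF) *
            (y[S_cd] * e2 - 0.341 * p[P_Cao]) / (e2 - 1.0);
  }
  I[2] = p[P_gCaL] * y[S_d] * y[S_f] * y[S_fCa] * drive;

  I[3] = p[P_gto] * y[S_r_to] * y[S_s_to] * (v - EK);
  double sqko = sqrt(p[P_Ko] / 5.4);
  I[4] = p[P_gKr] * sqko * y[S_xr1] * y[S_xr2] * (v - EK);
  I[5] = p[P_gKs] * y[S_xs] * y[S_xs] * (v - EKs);

  double dvk = v - EK;
  double aK1 = 0.1 / (1.0 + exp(0.06 * (dvk - 200.0)));
  double bK1 = (3.0 * exp(0.0002 * (dvk + 100.0)) + exp(0.1 * (dvk - 10.0))) /
               (1.0 + exp(-0.5 * dvk));
  I[6] = p[P_gK1] * sqko * (aK1 / (aK1 + bK1)) * dvk;

  I[7] = p[P_gNaK] * (p[P_Ko] / (p[P_Ko] + 1.0)) *
         (p[P_Nai] / (p[P_Nai] + 40.0)) /
         (1.0 + 0.1245 * exp(-0.1 * vf) + 0.0353 * exp(-vf));

  double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
  double na3 = p[P_Nai] * p[P_Nai] * p[P_Nai];
  double nao3 = p[P_Nao] * p[P_Nao] * p[P_Nao];
  I[8] = p[P_gNaCa] *
         (exp(gam * vf) * na3 * p[P_Cao] -
          exp((gam - 1.0) * vf) * nao3 * csl * alp) /
         ((KmNai * KmNai * KmNai + nao3) * (KmCa + p[P_Cao]) *
          (1.0 + ksat * exp((gam - 1.0) * vf)));

  I[9] = p[P_gpCa] * csl / (csl + 0.0005);
  I[10] = p[P_gbCa] * (v - ECa);
  I[11] = p[P_gbCl] * (v - p[P_ECl]);
  I[12] = p[P_gf] * y[S_xf] * (v - p[P_Ef]);
  I[13] = istim;

  // membrane Ca2+ flux conversion: A/F -> mmol/ms through total capacitance
  double Acap = p[P_chi] * p[P_Vcell] * 1e15;          // um^2
  double Ctot = p[P_Cm] * Acap * 1e-12;                // F
  double conv = Ctot / (2.0 * FARADAY);                // mmol/ms per A/F

  J[0] = -I[2] * conv;                                  // J_CaL (into dyad)
  J[1] = -(I[10] + I[9] - 2.0 * I[8]) * conv;           // J_esl (into SL)
  J[2] = p[P_adc] * (y[S_cd] - y[S_cc]);                // J_dc
  J[3] = p[P_aslc] * (y[S_csl] - y[S_cc]);              // J_slc
  J[4] = p[P_ans] * (y[S_cn] - y[S_cs]);                // J_ns

  double cd3 = y[S_cd] * y[S_cd] * y[S_cd];
  double k3 = p[P_kappaRyR] * p[P_kappaRyR] * p[P_kappaRyR];
  double popen = cd3 / (cd3 + k3);
  double grad = y[S_cs] - y[S_csl];
  J[5] = popen * y[S_rRyR] * p[P_aRyR] * grad;          // J_RyR
  J[6] = p[P_gammaRyR] * p[P_aRyR] * grad;              // J_leak
  double cc2 = y[S_cc] * y[S_cc];
  J[7] = p[P_gSERCA] * cc2 / (cc2 + p[P_kSERCA] * p[P_kSERCA]);  // J_SERCA

  double Vd = p[P_fracd] * p[P_Vcell];
  double Vsl = p[P_fracsl] * p[P_Vcell];
  double Vc = p[P_fracc] * p[P_Vcell];
  double Vs = p[P_fracs] * p[P_Vcell];
  J[8] = Vd * (p[P_kond] * y[S_cd] * (p[P_Bd] - y[S_bd]) -
               p[P_koffd] * y[S_bd]);                   // J_db
  J[9] = Vsl * (p[P_konsl] * y[S_csl] * (p[P_Bsl] - y[S_bsl]) -
                p[P_koffsl] * y[S_bsl]);                // J_slb
  J[10] = Vc * (p[P_konc] * y[S_cc] * (p[P_Bc] - y[S_bc]) -
                p[P_koffc] * y[S_bc]);                  // J_cb
  J[11] = Vs * (p[P_kons] * y[S_cs] * (p[P_Bs] - y[S_bs]) -
                p[P_koffs] * y[S_bs]);                  // J_sb
}

// full derivative vector; clampv: if true dv/dt = 0
static void derivs(const double *y, const double *p, double istim,
                   bool clampv, double *dy) {
  double I[NCUR], J[NFLUX];
  double ginf[NGATE], gtau[NGATE];
  currents_fluxes(y, p, istim, I, J);
  gate_rates(y[S_v], y[S_cd], p[P_kfCa], ginf, gtau);

  double isum = 0.0;
  for (int k = 0; k < NCUR; ++k) isum += I[k];
  dy[S_v] = clampv ? 0.0 : -isum;

  for (int g = 0; g < NGATE; ++g)
    dy[S_m + g] = (ginf[g] - y[S_m + g]) / gtau[g];

  double Vd = p[P_fracd] * p[P_Vcell];
  double Vsl = p[P_fracsl] * p[P_Vcell];
  double Vc = p[P_fracc] * p[P_Vcell];
  double Vs = p[P_fracs] * p[P_Vcell];
  double Vn = p[P_fracn] * p[P_Vcell];
  double Jssl = J[5] + J[6];

  dy[S_cd] = (J[0] - J[8] - J[2]) / Vd;
  dy[S_csl] = (J[1] - J[3] - J[9] + Jssl) / Vsl;
  dy[S_cc] = (J[3] + J[2] - J[7] - J[10]) / Vc;
  dy[S_cs] = (J[4] - Jssl - J[11]) / Vs;
  dy[S_cn] = (J[7] - J[4]) / Vn;
  dy[S_bd] = J[8] / Vd;
  dy[S_bsl] = J[9] / Vsl;
  dy[S_bc] = J[10] / Vc;
  dy[S_bs] = J[11] / Vs;

  double cd3 = y[S_cd] * y[S_cd] * y[S_cd];
  double k3 = p[P_kappaRyR] * p[P_kappaRyR] * p[P_kappaRyR];
  double popen = cd3 / (cd3 + k3);
  dy[S_rRyR] = -J[5] / p[P_bRyR] + p[P_etaRyR] * popen * (1.0 - y[S_rRyR]);
}

// [[Rcpp::export(name = ".bm_derivs")]]
List bm_derivs(NumericVector state, NumericVector params, double istim,
               bool clampv) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  double I[NCUR], J[NFLUX], dy[NSTATE];
  currents_fluxes(REAL(state), REAL(params), istim, I, J);
  derivs(REAL(state), REAL(params), istim, clampv, dy);
  return List::create(
    _["deriv"] = NumericVector(dy, dy + NSTATE),
    _["currents"] = NumericVector(I, I + NCUR),
    _["fluxes"] = NumericVector(J, J + NFLUX));
}

// One fixed time step: Rush-Larsen for gates and RyR availability,
// forward Euler for potential, concentrations and buffers.
static inline void step_rl(double *y, const double *p, double istim,
                           bool clampv, double clampval, double dt) {
  double I[NCUR], J[NFLUX];
  double ginf[NGATE], gtau[NGATE];
  currents_fluxes(y, p, istim, I, J);
  gate_rates(y[S_v], y[S_cd], p[P_kfCa], ginf, gtau);

  double isum = 0.0;
  for (int k = 0; k < NCUR; ++k) isum += I[k];

  double Vd = p[P_fracd] * p[P_Vcell];
  double Vsl = p[P_fracsl] * p[P_Vcell];
  double Vc = p[P_fracc] * p[P_Vcell];
  double Vs = p[P_fracs] * p[P_Vcell];
  double Vn = p[P_fracn] * p[P_Vcell];
  double Jssl = J[5] + J[6];

  double dcd = (J[0] - J[8] - J[2]) / Vd;
  double dcsl = (J[1] - J[3] - J[9] + Jssl) / Vsl;
  double dcc = (J[3] + J[2] - J[7] - J[10]) / Vc;
  double dcs = (J[4] - Jssl - J[11]) / Vs;
  double dcn = (J[7] - J[4]) / Vn;

  // RyR availability: linear in r at frozen concentrations -> exact update
  double cd3 = y[S_cd] * y[S_cd] * y[S_cd];
  double k3 = p[P_kappaRyR] * p[P_kappaRyR] * p[P_kappaRyR];
  double popen = cd3 / (cd3 + k3);
  double grad = y[S_cs] - y[S_csl];
  double brate = popen * (p[P_aRyR] * grad / p[P_bRyR] + p[P_etaRyR]);
  double arate = p[P_etaRyR] * popen;

  for (int g = 0; g < NGATE; ++g) {
    double e = exp(-dt / gtau[g]);
    y[S_m + g] = ginf[g] + (y[S_m + g] - ginf[g]) * e;
  }
  if (brate > 1e-12) {
    double req = arate / brate;
    y[S_rRyR] = req + (y[S_rRyR] - req) * exp(-brate * dt);
  } else {
    y[S_rRyR] += dt * (arate - brate * y[S_rRyR]);
  }
  if (y[S_rRyR] < 0.0) y[S_rRyR] = 0.0;
  if (y[S_rRyR] > 1.0) y[S_rRyR] = 1.0;

  y[S_v] = clampv ? clampval : y[S_v] - dt * isum;
  y[S_cd] += dt * dcd;
  y[S_csl] += dt * dcsl;
  y[S_cc] += dt * dcc;
  y[S_cs] += dt * dcs;
  y[S_cn] += dt * dcn;
  y[S_bd] += dt * J[8] / Vd;
  y[S_bsl] += dt * J[9] / Vsl;
  y[S_bc] += dt * J[10] / Vc;
  y[S_bs] += dt * J[11] / Vs;
  for (int k = S_cd; k <= S_bs; ++k)
    if (y[k] < 1e-12) y[k] = 1e-12;
}


// ---- voltage lookup table ------------------------------------------------
// The integrator spends nearly all of its time in exp() calls whose
// argument depends only on v (gate steady states / time constants and the
// voltage-dependent factors of I_CaL, I_K1, I_NaK and I_NaCa). They are
// tabulated on a fine v-grid per integration run (the Rush-Larsen
// exponential also folds in the fixed step size) and linearly
// interpolated. The Ca2+-dependent fCa gate is evaluated analytically.
static const int LUT_NGATE = 13;           // all gates except fCa
static const int LUT_NCOL = 2 * LUT_NGATE + 6;
static const int LC_GHK_A = 2 * LUT_NGATE;
static const int LC_GHK_B = LC_GHK_A + 1;
static const int LC_K1 = LC_GHK_A + 2;
static const int LC_NAK = LC_GHK_A + 3;
static const int LC_NCX_A = LC_GHK_A + 4;
static const int LC_NCX_B = LC_GHK_A + 5;

struct VLut {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> tab;   // row-major [i * LUT_NCOL + c]
};

// gate index (0..13, state S_m + g) for each LUT gate slot
static const int LUT_GATE[LUT_NGATE] = {0, 1, 2, 3, 4, 5, 6, 8, 9, 10, 11,
                                        12, 13};

static void build_vlut(const double *p, double dt, VLut &L) {
  L.vmin = -150.0;
  L.dv = 0.05;
  L.inv_dv = 1.0 / L.dv;
  L.n = (int)((150.0 - L.vmin) / L.dv) + 1;
  L.tab.assign((size_t)L.n * LUT_NCOL, 0.0);

  double EK = RTF * log(p[P_Ko] / p[P_Ki]);
  double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
  double na3 = p[P_Nai] * p[P_Nai] * p[P_Nai];
  double nao3 = p[P_Nao] * p[P_Nao] * p[P_Nao];

  double ginf[NGATE], gtau[NGATE];
  for (int i = 0; i < L.n; ++i) {
    double v = L.vmin + i * L.dv;
    double *row = &L.tab[(size_t)i * LUT_NCOL];
    gate_rates(v, 1e-4, p[P_kfCa], ginf, gtau);
    for (int g = 0; g < LUT_NGATE; ++g) {
      row[g] = ginf[LUT_GATE[g]];
      row[LUT_NGATE + g] = exp(-dt / gtau[LUT_GATE[g]]);
    }
    double vf = v / RTF;
    double e2 = exp(2.0 * vf);
    double pref;
    if (fabs(v) < 1e-4) {
      // limit of 4 v (F/RTF) e2/(e2-1) etc. as v -> 0
      row[LC_GHK_A] = 2.0 * FARADAY;
      row[LC_GHK_B] = 2.0 * FARADAY * 0.341 * p[P_Cao];
    } else {
      pref = 4.0 * v * (FARADAY / RTF) / (e2 - 1.0);
      row[LC_GHK_A] = pref * e2;
      row[LC_GHK_B] = pref * 0.341 * p[P_Cao];
    }
    double dvk = v - EK;
    double aK1 = 0.1 / (1.0 + exp(0.06 * (dvk - 200.0)));
    double bK1 = (3.0 * exp(0.0002 * (dvk + 100.0)) +
                  exp(0.1 * (dvk - 10.0))) / (1.0 + exp(-0.5 * dvk));
    row[LC_K1] = (aK1 / (aK1 + bK1)) * dvk;
    row[LC_NAK] = 1.0 / (1.0 + 0.1245 * exp(-0.1 * vf) +
                         0.0353 * exp(-vf));
    double den = (KmNai * KmNai * KmNai + nao3) * (KmCa + p[P_Cao]) *
                 (1.0 + ksat * exp((gam - 1.0) * vf));
    row[LC_NCX_A] = exp(gam * vf) * na3 * p[P_Cao] / den;
    row[LC_NCX_B] = exp((gam - 1.0) * vf) * nao3 * alp / den;
  }
}

// fixed per-run constants reused every step
struct RunConsts {
  double ENa, EK, EKs, sqko, conv;
  double Vd, Vsl, Vc, Vs, Vn;
  double k3, efca;
};

static void build_consts(const double *p, double dt, RunConsts &C) {
  C.ENa = RTF * log(p[P_Nao] / p[P_Nai]);
  C.EK = RTF * log(p[P_Ko] / p[P_Ki]);
  C.EKs = RTF * log((p[P_Ko] + 0.03 * p[P_Nao]) /
                    (p[P_Ki] + 0.03 * p[P_Nai]));
  C.sqko = sqrt(p[P_Ko] / 5.4);
  double Acap = p[P_chi] * p[P_Vcell] * 1e15;
  C.conv = p[P_Cm] * Acap * 1e-12 / (2.0 * FARADAY);
  C.Vd = p[P_fracd] * p[P_Vcell];
  C.Vsl = p[P_fracsl] * p[P_Vcell];
  C.Vc = p[P_fracc] * p[P_Vcell];
  C.Vs = p[P_fracs] * p[P_Vcell];
  C.Vn = p[P_fracn] * p[P_Vcell];
  C.k3 = p[P_kappaRyR] * p[P_kappaRyR] * p[P_kappaRyR];
  C.efca = exp(-dt / 5.0);
}

// one fixed step through the lookup table
static inline void step_rl_lut(double *y, const double *p, const VLut &L,
                               const RunConsts &C, double istim,
                               bool clampv, double clampval, double dt) {
  double v = y[S_v];
  double x = (v - L.vmin) * L.inv_dv;
  if (x < 0.0) x = 0.0;
  if (x > L.n - 2.0) x = L.n - 2.0;
  int i = (int)x;
  double w = x - i;
  const double *r0 = &L.tab[(size_t)i * LUT_NCOL];
  const double *r1 = r0 + LUT_NCOL;
  double row[LUT_NCOL];
  for (int c = 0; c < LUT_NCOL; ++c) row[c] = r0[c] + w * (r1[c] - r0[c]);

  double csl = y[S_csl];
  double I_Na = p[P_gNa] * y[S_m] * y[S_m] * y[S_m] * y[S_h] * y[S_j] *
                (v - C.ENa);
  double I_NaL = p[P_gNaL] * y[S_mL] * y[S_hL] * (v - C.ENa);
  double I_CaL = p[P_gCaL] * y[S_d] * y[S_f] * y[S_fCa] *
                 (row[LC_GHK_A] * y[S_cd] - row[LC_GHK_B]);
  double I_to = p[P_gto] * y[S_r_to] * y[S_s_to] * (v - C.EK);
  double I_Kr = p[P_gKr] * C.sqko * y[S_xr1] * y[S_xr2] * (v - C.EK);
  double I_Ks = p[P_gKs] * y[S_xs] * y[S_xs] * (v - C.EKs);
  double I_K1 = p[P_gK1] * C.sqko * row[LC_K1];
  double I_NaK = p[P_gNaK] * (p[P_Ko] / (p[P_Ko] + 1.0)) *
                 (p[P_Nai] / (p[P_Nai] + 40.0)) * row[LC_NAK];
  double I_NaCa = p[P_gNaCa] * (row[LC_NCX_A] - row[LC_NCX_B] * csl);
  double I_pCa = p[P_gpCa] * csl / (csl + 0.0005);
  double csl_c = csl > 1e-8 ? csl : 1e-8;
  double I_bCa = p[P_gbCa] * (v - 0.5 * RTF * log(p[P_Cao] / csl_c));
  double I_bCl = p[P_gbCl] * (v - p[P_ECl]);
  double I_f = p[P_gf] * y[S_xf] * (v - p[P_Ef]);

  double isum = I_Na + I_NaL + I_CaL + I_to + I_Kr + I_Ks + I_K1 + I_NaK +
                I_NaCa + I_pCa + I_bCa + I_bCl + I_f + istim;

  double J_CaL = -I_CaL * C.conv;
  double J_esl = -(I_bCa + I_pCa - 2.0 * I_NaCa) * C.conv;
  double J_dc = p[P_adc] * (y[S_cd] - y[S_cc]);
  double J_slc = p[P_aslc] * (csl - y[S_cc]);
  double J_ns = p[P_ans] * (y[S_cn] - y[S_cs]);
  double cd3 = y[S_cd] * y[S_cd] * y[S_cd];
  double popen = cd3 / (cd3 + C.k3);
  double grad = y[S_cs] - csl;
  double J_RyR = popen * y[S_rRyR] * p[P_aRyR] * grad;
  double J_leak = p[P_gammaRyR] * p[P_aRyR] * grad;
  double cc2 = y[S_cc] * y[S_cc];
  double J_SERCA = p[P_gSERCA] * cc2 /
                   (cc2 + p[P_kSERCA] * p[P_kSERCA]);
  double J_db = C.Vd * (p[P_kond] * y[S_cd] * (p[P_Bd] - y[S_bd]) -
                        p[P_koffd] * y[S_bd]);
  double J_slb = C.Vsl * (p[P_konsl] * csl * (p[P_Bsl] - y[S_bsl]) -
                          p[P_koffsl] * y[S_bsl]);
  double J_cb = C.Vc * (p[P_konc] * y[S_cc] * (p[P_Bc] - y[S_bc]) -
                        p[P_koffc] * y[S_bc]);
  double J_sb = C.Vs * (p[P_kons] * y[S_cs] * (p[P_Bs] - y[S_bs]) -
                        p[P_koffs] * y[S_bs]);
  double Jssl = J_RyR + J_leak;

  double dcd = (J_CaL - J_db - J_dc) / C.Vd;
  double dcsl = (J_esl - J_slc - J_slb + Jssl) / C.Vsl;
  double dcc = (J_slc + J_dc - J_SERCA - J_cb) / C.Vc;
  double dcs = (J_ns - Jssl - J_sb) / C.Vs;
  double dcn = (J_SERCA - J_ns) / C.Vn;

  double brate = popen * (p[P_aRyR] * grad / p[P_bRyR] + p[P_etaRyR]);
  double arate = p[P_etaRyR] * popen;

  for (int g = 0; g < LUT_NGATE; ++g) {
    int s = S_m + LUT_GATE[g];
    y[s] = row[g] + (y[s] - row[g]) * row[LUT_NGATE + g];
  }
  double cr = y[S_cd] / p[P_kfCa];
  double fcainf = 0.02 + 0.98 / (1.0 + cr * cr);
  y[S_fCa] = fcainf + (y[S_fCa] - fcainf) * C.efca;

  if (brate > 1e-12) {
    double req = arate / brate;
    y[S_rRyR] = req + (y[S_rRyR] - req) * exp(-brate * dt);
  } else {
    y[S_rRyR] += dt * (arate - brate * y[S_rRyR]);
  }
  if (y[S_rRyR] < 0.0) y[S_rRyR] = 0.0;
  if (y[S_rRyR] > 1.0) y[S_rRyR] = 1.0;

  y[S_v] = clampv ? clampval : v - dt * isum;
  y[S_cd] += dt * dcd;
  y[S_csl] += dt * dcsl;
  y[S_cc] += dt * dcc;
  y[S_cs] += dt * dcs;
  y[S_cn] += dt * dcn;
  y[S_bd] += dt * J_db / C.Vd;
  y[S_bsl] += dt * J_slb / C.Vsl;
  y[S_bc] += dt * J_cb / C.Vc;
  y[S_bs] += dt * J_sb / C.Vs;
  for (int k = S_cd; k <= S_bs; ++k)
    if (y[k] < 1e-12) y[k] = 1e-12;
}

// Integrate the model. mode: 0 = paced, 1 = voltage clamp, 2 = free running.
// Returns the sampled trace (columns: t, states, then optionally currents
// and fluxes) plus a status flag (0 ok, 1 solver failure at time t_fail).
// [[Rcpp::export(name = ".bm_integrate")]]
List bm_integrate(NumericVector params, NumericVector state0, int mode,
                  double duration, double period, double stim_amp,
                  double stim_dur, double clamp_v, double record_dt,
                  double dt, bool record_extra) {
  if (state0.size() != NSTATE) stop("state0 must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  const double *p = REAL(params);
  double y[NSTATE];
  for (int k = 0; k < NSTATE; ++k) y[k] = state0[k];

  int nsub = (int)std::max(1.0, std::round(record_dt / dt));
  double dts = record_dt / nsub;
  VLut lut;
  RunConsts consts;
  build_vlut(p, dts, lut);
  build_consts(p, dts, consts);
  int nrec = (int)std::floor(duration / record_dt + 1e-9) + 1;
  int ncol = 1 + NSTATE + (record_extra ? (NCUR + NFLUX) : 0);
  NumericMatrix out(nrec, ncol);

  int status = 0;
  double tfail = NA_REAL;
  int irec = 0;
  double t = 0.0;
  for (irec = 0; irec < nrec; ++irec) {
    t = irec * record_dt;
    bool clampv = (mode == 1);
    double istim = 0.0;
    if (mode == 0) {
      double tb = time_in_cycle(t, period);
      if (tb < stim_dur) istim = stim_amp;
    }
    out(irec, 0) = t;
    for (int k = 0; k < NSTATE; ++k) out(irec, 1 + k) = y[k];
    if (record_extra) {
      double I[NCUR], J[NFLUX];
      currents_fluxes(y, p, istim, I, J);
      for (int k = 0; k < NCUR; ++k) out(irec, 1 + NSTATE + k) = I[k];
      for (int k = 0; k < NFLUX; ++k) out(irec, 1 + NSTATE + NCUR + k) = J[k];
    }
    if (irec == nrec - 1) break;
    for (int s = 0; s < nsub; ++s) {
      double ts = t + s * dts;
      double is = 0.0;
      if (mode == 0) {
        double tb = time_in_cycle(ts, period);
        if (tb < stim_dur) is = stim_amp;
      }
      step_rl_lut(y, p, lut, consts, is, clampv, clamp_v, dts);
      if (!std::isfinite(y[S_v]) || fabs(y[S_v]) > 500.0) {
        status = 1;
        tfail = ts;
        break;
      }
    }
    if (status != 0) { ++irec; break; }
  }
  if (status != 0 && irec < nrec) {
    out = out(Range(0, std::max(irec - 1, 0)), _);
  }
  return List::create(_["trace"] = out, _["status"] = status,
                      _["t_fail"] = tfail);
}
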