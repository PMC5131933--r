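#ifndef SPIRALPS_CRN_MODEL_H
#define SPIRALPS_CRN_MODEL_H

#include <cmath>
#include <vector>

// Courtemanche-Ramirez-Nattel human atrial action potential model.
// Units: V in mV, time in ms, concentrations in mM, currents in pA/pF.
// State layout (21):
//   0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai,
//   19 Caup, 20 Carel

namespace crn {

const int NSTATE = 21;

// physical constants
const double Rgas = 8.3143;       // J/(K mol)
const double Temp = 310.0;        // K
const double Frdy = 96.4867;      // C/mmol
const double RTF  = Rgas * Temp / Frdy;  // ~26.71 mV
const double Cm   = 100.0;        // pF (whole-cell capacitance)
const double Vi   = 13668.0;      // um^3 intracellular volume
const double Vup  = 1109.52;      // um^3 SR uptake compartment
const double Vrel = 96.48;        // um^3 SR release compartment
const double Ko   = 5.4;          // mM
const double Nao  = 140.0;        // mM
const double Cao  = 1.8;          // mM

// maximal conductances / fluxes, possibly rescaled by a remodeling scenario
struct CellConst {
  double gNa, gK1, gto, gKur_scale, gKr, gKs, gCaL, gbCa, gbNa;
  double inak_max, inaca_max, ipca_max, iup_max, krel, leak_scale;
};

inline CellConst default_consts() {
  CellConst p;
  p.gNa = 7.8;          p.gK1 = 0.09;      p.gto = 0.1652;
  p.gKur_scale = 1.0;   p.gKr = 0.029411765; p.gKs = 0.12941176;
  p.gCaL = 0.12375;     p.gbCa = 0.001131; p.gbNa = 0.0006744375;
  p.inak_max = 0.59933874; p.inaca_max = 1600.0; p.ipca_max = 0.275;
  p.iup_max = 0.005;    p.krel = 30.0;     p.leak_scale = 1.0;
  return p;
}

// published resting steady state
inline void rest_state(double* s) {
  s[0] = -81.18;     s[1] = 2.908e-3;  s[2] = 9.649e-1;  s[3] = 9.775e-1;
  s[4] = 3.043e-2;   s[5] = 9.992e-1;  s[6] = 4.966e-3;  s[7] = 9.986e-1;
  s[8] = 3.296e-5;   s[9] = 1.869e-2;  s[10] = 1.367e-4; s[11] = 9.996e-1;
  s[12] = 7.755e-1;  s[13] = 0.0;      s[14] = 1.0;      s[15] = 9.992e-1;
  s[16] = 1.117e1;   s[17] = 1.39e2;   s[18] = 1.013e-4; s[19] = 1.488;
  s[20] = 1.488;
}

inline double sigm(double x) {            // 1/(1+exp(x)) overflow-safe
  if (x > 80.0) return 0.0;
  if (x < -80.0) return 1.0;
  return 1.0 / (1.0 + std::exp(x));
}

// steady state and time constant for the 12 voltage-dependent gates,
// order: m h j oa oi ua ui xr xs d f w
inline void gate_inf_tau(double V, double* inf, double* tau) {
  double a, b;
  // m
  a = (std::fabs(V + 47.13) < 1e-9) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  inf[0] = a / (a + b); tau[0] = 1.0 / (a + b);
  // h
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  inf[1] = a / (a + b); tau[1] = 1.0 / (a + b);
  // j
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[2] = a / (a + b); tau[2] = 1.0 / (a + b);
  // oa (Kq10 = 3)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[3] = sigm(-(V + 20.47) / 17.54); tau[3] = 1.0 / ((a + b) * 3.0);
  // oi
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  inf[4] = sigm((V + 43.1) / 5.3); tau[4] = 1.0 / ((a + b) * 3.0);
  // ua (same alpha/beta as oa)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[5] = sigm(-(V + 30.3) / 9.6); tau[5] = 1.0 / ((a + b) * 3.0);
  // ui
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  inf[6] = sigm((V - 99.45) / 27.48); tau[6] = 1.0 / ((a + b) * 3.0);
  // xr
  a = (std::fabs(V + 14.1) < 1e-9) ? 0.0015
      : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  b = (std::fabs(V - 3.3328) < 1e-9) ? 3.7836118e-4
      : 0.000073898 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  inf[7] = sigm(-(V + 14.1) / 6.5); tau[7] = 1.0 / (a + b);
  // xs
  a = (std::fabs(V - 19.9) < 1e-9) ? 0.00068
      : 0.00004 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  b = (std::fabs(V - 19.9) < 1e-9) ? 0.000315
      : 0.000035 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  inf[8] = std::pow(1.0 + std::exp(-(V - 19.9) / 12.7), -0.5);
  tau[8] = 0.5 / (a + b);
  // d
  inf[9] = sigm(-(V + 10.0) / 8.0);
  if (std::fabs(V + 10.0) < 1e-9) {
    tau[9] = 1.0 / (0.035 * 6.24 * 2.0);
  } else {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau[9] = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  // f
  inf[10] = sigm((V + 28.0) / 6.9);
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  // w
  inf[11] = 1.0 - sigm(-(V - 40.0) / 17.0);
  if (std::fabs(V - 7.9) < 1e-9) {
    tau[11] = 6.0 / (5.0 * 1.3);
  } else {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau[11] = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
}

const int NGATE = 12;
// state index of each tabulated gate (m h j oa oi ua ui xr xs d f w);
// fca, u, v occupy slots 12-14, so w sits at 15
const int GATE_IDX[NGATE] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
// table row: inf[12] | efac_sub[12] | efac_full[12] | ik1c gkur ikrc fnak expg expg1
const int ROWLEN = NGATE * 3 + 6;
const double TAB_VMIN = -120.0, TAB_VMAX = 80.0, TAB_STEP = 0.05;

struct Table {
  int n;
  double dt_sub, dt_full;
  double efca_sub, efca_full, eu_sub, eu_full;
  std::vector<double> rows;  // n * ROWLEN
  void build(double dt_sub_, double dt_full_) {
    dt_sub = dt_sub_; dt_full = dt_full_;
    efca_sub  = std::exp(-dt_sub / 2.0);  efca_full = std::exp(-dt_full / 2.0);
    eu_sub    = std::exp(-dt_sub / 8.0);  eu_full   = std::exp(-dt_full / 8.0);
    n = (int)std::floor((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 1;
    rows.assign((size_t)n * ROWLEN, 0.0);
    double inf[NGATE], tau[NGATE];
    double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < n; ++i) {
      double V = TAB_VMIN + i * TAB_STEP;
      double* r = &rows[(size_t)i * ROWLEN];
      gate_inf_tau(V, inf, tau);
      for (int g = 0; g < NGATE; ++g) {
        r[g] = inf[g];
        r[NGATE + g] = std::exp(-dt_sub / tau[g]);
        r[2 * NGATE + g] = std::exp(-dt_full / tau[g]);
      }
      double* c = r + 3 * NGATE;
      c[0] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));        // IK1 voltage factor
      c[1] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0)); // gKur(V)
      c[2] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));        // IKr rectification
      c[3] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                    0.0365 * sigma * std::exp(-V / RTF));      // fNaK
      c[4] = std::exp(0.35 * V / RTF);                         // NaCa forward
      c[5] = std::exp(-0.65 * V / RTF);                        // NaCa reverse
    }
  }
};

// one evaluation of the ionic model at the current state
struct Eval {
  double inf[NGATE];
  const double* r0; const double* r1; double w0, w1;
  double Iion, dVdt;
  double INaK, INaCa, INa, IK1, Ito, IKur, IKr, IKs, ICaL, IbNa, IbCa, IpCa;
  double Irel, Itr, Iup, Iupleak, u_inf, v_inf, tau_v, fca_inf;
};

const double NACA_DENOM = (87.5 * 87.5 * 87.5 + 140.0 * 140.0 * 140.0) * (1.38 + 1.8);

inline void eval_cell(const double* s, double Istim, double lap,
                      const CellConst& P, const Table& T, Eval& e) {
  double V = s[0];
  double Vc = V;
  // NaN-safe clamp: a non-finite V must not index outside the table
  if (!(Vc >= TAB_VMIN)) Vc = TAB_VMIN;
  if (Vc > TAB_VMAX - TAB_STEP) Vc = TAB_VMAX - TAB_STEP;
  double x = (Vc - TAB_VMIN) / TAB_STEP;
  int i0 = (int)x;
  e.w1 = x - i0; e.w0 = 1.0 - e.w1;
  e.r0 = &T.rows[(size_t)i0 * ROWLEN];
  e.r1 = e.r0 + ROWLEN;
  for (int g = 0; g < NGATE; ++g)
    e.inf[g] = e.w0 * e.r0[g] + e.w1 * e.r1[g];
  const double* c0 = e.r0 + 3 * NGATE;
  const double* c1 = e.r1 + 3 * NGATE;
  double ik1c = e.w0 * c0[0] + e.w1 * c1[0];
  double gkur = e.w0 * c0[1] + e.w1 * c1[1];
  double ikrc = e.w0 * c0[2] + e.w1 * c1[2];
  double fnak = e.w0 * c0[3] + e.w1 * c1[3];
  double expg = e.w0 * c0[4] + e.w1 * c1[4];
  double expg1 = e.w0 * c0[5] + e.w1 * c1[5];

  double Nai = s[16], Ki = s[17], Cai = s[18], Caup = s[19], Carel = s[20];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  double m = s[1], h = s[2], j = s[3];
  e.INa  = P.gNa * m * m * m * h * j * (V - ENa);
  e.IK1  = P.gK1 * ik1c * (V - EK);
  e.Ito  = P.gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
  e.IKur = P.gKur_scale * gkur * s[6] * s[6] * s[6] * s[7] * (V - EK);
  e.IKr  = P.gKr * ikrc * s[8] * (V - EK);
  e.IKs  = P.gKs * s[9] * s[9] * (V - EK);
  e.ICaL = P.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  e.IpCa = P.ipca_max * Cai / (0.0005 + Cai);
  e.INaK = P.inak_max * fnak * (Ko / (Ko + 1.5)) /
           (1.0 + std::pow(10.0 / Nai, 1.5));
  e.INaCa = P.inaca_max *
            (expg * Nai * Nai * Nai * Cao - expg1 * Nao * Nao * Nao * Cai) /
            (NACA_DENOM * (1.0 + 0.1 * expg1));
  e.IbNa = P.gbNa * (V - ENa);
  e.IbCa = P.gbCa * (V - ECa);
  e.Iion = e.INa + e.IK1 + e.Ito + e.IKur + e.IKr + e.IKs + e.ICaL +
           e.IpCa + e.INaK + e.INaCa + e.IbNa + e.IbCa;
  e.dVdt = -(e.Iion + Istim) + lap;

  e.Irel = P.krel * s[13] * s[13] * s[14] * s[15] * (Carel - Cai);
  e.Itr  = (Caup - Carel) / 180.0;
  e.Iup  = P.iup_max / (1.0 + 0.00092 / Cai);
  e.Iupleak = P.leak_scale * P.iup_max * Caup / 15.0;
  double Fn = 1e-12 * Vrel * e.Irel -
              (5e-13 / Frdy) * (0.5 * e.ICaL - 0.2 * e.INaCa) * Cm;
  e.u_inf = sigm(-(Fn - 3.4175e-13) / 13.67e-16);
  e.v_inf = 1.0 - sigm(-(Fn - 6.835e-14) / 13.67e-16);
  e.tau_v = 1.91 + 2.09 * sigm(-(Fn - 3.4175e-13) / 13.67e-16);
  e.fca_inf = 1.0 / (1.0 + Cai / 0.00035);
}

// commit a step of length dt using the evaluation e.
// which = 0: dt_sub tables; 1: dt_full tables.
inline void commit_cell(double* s, const Eval& e, const Table& T, int which) {
  double dt = which ? T.dt_full : T.dt_sub;
  int off = which ? 2 * NGATE : NGATE;
  for (int g = 0; g < NGATE; ++g) {
    double ef = e.w0 * e.r0[off + g] + e.w1 * e.r1[off + g];
    int gi = GATE_IDX[g];
    s[gi] = e.inf[g] + (s[gi] - e.inf[g]) * ef;
  }
  double efca = which ? T.efca_full : T.efca_sub;
  double eu   = which ? T.eu_full : T.eu_sub;
  s[12] = e.fca_inf + (s[12] - e.fca_inf) * efca;
  s[13] = e.u_inf + (s[13] - e.u_inf) * eu;
  s[14] += dt * (e.v_inf - s[14]) / e.tau_v;

  double f1 = Cm / (Frdy * Vi);
  s[16] += dt * (-3.0 * e.INaK - 3.0 * e.INaCa - e.IbNa - e.INa) * f1;
  s[17] += dt * (2.0 * e.INaK - e.IK1 - e.Ito - e.IKur - e.IKr - e.IKs) * f1;
  double Cai = s[18], Carel = s[20];
  double B1 = (2.0 * e.INaCa - e.IpCa - e.ICaL - e.IbCa) * Cm /
                  (2.0 * Frdy * Vi) +
              (Vup * (e.Iupleak - e.Iup) + e.Irel * Vrel) / Vi;
  double t1 = 0.07 * 0.0005 / ((Cai + 0.0005) * (Cai + 0.0005));
  double t2 = 0.05 * 0.00238 / ((Cai + 0.00238) * (Cai + 0.00238));
  s[18] += dt * B1 / (1.0 + t1 + t2);
  s[19] += dt * (e.Iup - e.Iupleak - e.Itr * Vrel / Vup);
  double csqn = 10.0 * 0.8 / ((Carel + 0.8) * (Carel + 0.8));
  s[20] += dt * (e.Itr - e.Irel) / (1.0 + csqn);
  s[0] += dt * e.dVdt;
}

// advance one cell over a full macro step with local sub-stepping:
// a single dt_full step if the predicted |dV| is below dv_max, otherwise
// n_sub steps of dt_sub. lap (diffusion + stimulus contribution to dV/dt)
// is held fixed over the macro step.
inline void step_cell(double* s, double Istim, double lap, double dv_max,
                      int n_sub, const CellConst& P, const Table& T, Eval& e) {
  eval_cell(s, Istim, lap, P, T, e);
  if (std::fabs(e.dVdt) * T.dt_full <= dv_max) {
    commit_cell(s, e, T, 1);
  } else {
    commit_cell(s, e, T, 0);
    for (int k = 1; k < n_sub; ++k) {
      eval_cell(s, Istim, lap, P, T, e);
      commit_cell(s, e, T, 0);
    }
  }
}

}  // namespace crn

#endif
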