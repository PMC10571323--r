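// Ionic model kernels: right-hand sides and the IMEX update of the cellular
// layer, vectorised over nodes.  All models run in their native units
// (mV or dimensionless potential, milliseconds); unit conversion to the SI
// tissue layer happens in R.
//
// Per model, eval() fills for every ionic variable k either
//   kind[k] = 1 (gate, dynamics affine in the gate):  winf[k], tau[k]
//   kind[k] = 0 (explicit variable):                  only H[k]
// together with H[k] for gates too (H = (winf - w)/tau) and the ionic
// current I_ion such that du/dt + I_ion = I_app.
//
// The BDF-sigma IMEX step then reads, with r = dt:
//   gates     w_{n+1} = (w_BDF + r winf/tau) / (alpha + r/tau)   (closed form)
//   explicit  w_{n+1} = (w_BDF + r H(u_EXT, w_EXT)) / alpha
// which is the direct inversion of the time-discrete ionic equations.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Aliev-Panfilov (1 ionic variable: recovery v).  Dimensionless u in [0,1];
// the native time unit is mapped to milliseconds through p[5] (ms per unit).
// params: k, a, eps0, mu1, mu2, tscale_ms
// ---------------------------------------------------------------------------
static const int APF_M = 1;
static void apf_eval(double u, const double* w, const double* p,
                     double* Iion, double* H, double* winf, double* tau,
                     int* kind, bool only_current) {
  const double k = p[0], a = p[1], eps0 = p[2], mu1 = p[3], mu2 = p[4],
               ts = p[5];
  const double v = w[0];
  *Iion = (k * u * (u - a) * (u - 1.0) + u * v) / ts;
  if (only_current) return;
  kind[0] = 0;
  const double eps = eps0 + mu1 * v / (u + mu2);
  H[0] = eps * (-v - k * u * (u - a - 1.0)) / ts;
  winf[0] = 0.0; tau[0] = 1.0;
}

// ---------------------------------------------------------------------------
// Bueno-Orovio minimal ventricular model (3 gates: v, w, s), epicardial
// parameter set by default.  Dimensionless u, time in ms.
// params (28): u_o,u_u,th_v,th_w,th_vm,th_o,tau_v1m,tau_v2m,tau_vp,
//   tau_w1m,tau_w2m,k_wm,u_wm,tau_wp,tau_fi,tau_o1,tau_o2,tau_so1,tau_so2,
//   k_so,u_so,tau_s1,tau_s2,k_s,u_s,tau_si,tau_winf,w_infstar
// ---------------------------------------------------------------------------
static const int BO_M = 3;
static void bo_eval(double u, const double* w, const double* p,
                    double* Iion, double* H, double* winf, double* tau,
                    int* kind, bool only_current) {
  const double u_o = p[0], u_u = p[1], th_v = p[2], th_w = p[3], th_vm = p[4],
    th_o = p[5], tau_v1m = p[6], tau_v2m = p[7], tau_vp = p[8],
    tau_w1m = p[9], tau_w2m = p[10], k_wm = p[11], u_wm = p[12],
    tau_wp = p[13], tau_fi = p[14], tau_o1 = p[15], tau_o2 = p[16],
    tau_so1 = p[17], tau_so2 = p[18], k_so = p[19], u_so = p[20],
    tau_s1 = p[21], tau_s2 = p[22], k_s = p[23], u_s = p[24],
    tau_si = p[25], tau_winf = p[26], w_infstar = p[27];
  const double v = w[0], ww = w[1], s = w[2];
  const double Hv = (u >= th_v) ? 1.0 : 0.0;
  const double Hw = (u >= th_w) ? 1.0 : 0.0;
  const double Ho = (u >= th_o) ? 1.0 : 0.0;
  const double tau_o  = (1.0 - Ho) * tau_o1 + Ho * tau_o2;
  const double tau_so = tau_so1 + (tau_so2 - tau_so1) *
    (1.0 + std::tanh(k_so * (u - u_so))) / 2.0;
  const double Jfi = -v * Hv * (u - th_v) * (u_u - u) / tau_fi;
  const double Jso = (u - u_o) * (1.0 - Hw) / tau_o + Hw / tau_so;
  const double Jsi = -Hw * ww * s / tau_si;
  *Iion = Jfi + Jso + Jsi;
  if (only_current) return;
  const double tau_vm = (u >= th_vm) ? tau_v2m : tau_v1m;
  const double tau_wm = tau_w1m + (tau_w2m - tau_w1m) *
    (1.0 + std::tanh(k_wm * (u - u_wm))) / 2.0;
  const double tau_s = (1.0 - Hw) * tau_s1 + Hw * tau_s2;
  const double v_inf = (u < th_vm) ? 1.0 : 0.0;
  const double w_inf = (1.0 - Ho) * (1.0 - u / tau_winf) + Ho * w_infstar;
  // gate dynamics written as (A - g)/T, piecewise in u
  kind[0] = kind[1] = kind[2] = 1;
  if (Hv < 0.5) { winf[0] = v_inf; tau[0] = tau_vm; }
  else          { winf[0] = 0.0;   tau[0] = tau_vp; }
  if (Hw < 0.5) { winf[1] = w_inf; tau[1] = tau_wm; }
  else          { winf[1] = 0.0;   tau[1] = tau_wp; }
  winf[2] = (1.0 + std::tanh(k_s * (u - u_s))) / 2.0; tau[2] = tau_s;
  for (int g = 0; g < 3; ++g) H[g] = (winf[g] - w[g]) / tau[g];
}

// ---------------------------------------------------------------------------
// ten Tusscher-Panfilov 2006 ventricular model.  18 ionic variables:
//  0 Cai  1 CaSR  2 Cass  3 Nai  4 Ki            (explicit, mM)
//  5 m  6 h  7 j  8 xr1  9 xr2  10 xs  11 r  12 s  13 d  14 f  15 f2
//  16 fCass  17 Rbar                              (implicit gates)
// params (24): GNa,GCaL,Gto,Gkr,Gks,GK1,GpCa,GpK,GbNa,GbCa,knak,knaca,
//   Ko,Nao,Cao,Vmaxup,Vrel,Vleak,Vxfer,k1p,k2p,k3,k4,cell_type(0 epi,
//   1 endo, 2 M)
// ---------------------------------------------------------------------------
static const int TTP_M = 18;
static void ttp06_eval(double V, const double* w, const double* p,
                       double* Iion, double* H, double* winf, double* tau,
                       int* kind, bool only_current) {
  const double GNa = p[0], GCaL = p[1], Gto = p[2], Gkr = p[3], Gks = p[4],
    GK1 = p[5], GpCa = p[6], GpK = p[7], GbNa = p[8], GbCa = p[9],
    knak = p[10], knaca = p[11], Ko = p[12], Nao = p[13], Cao = p[14],
    Vmaxup = p[15], Vrel = p[16], Vleak = p[17], Vxfer = p[18],
    k1p = p[19], k2p = p[20], k3 = p[21], k4 = p[22];
  const int cell = (int)p[23];

  const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
  const double RTONF = Rgas * Temp / Frdy;             // 26.7137... mV
  const double Cm = 0.185, Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
  const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
               Bufss = 0.4, Kbufss = 0.00025;
  const double Kup = 0.00025, maxsr = 2.5, minsr = 1.0, EC = 1.5;
  const double pKNa = 0.03, KmK = 1.0, KmNa = 40.0;
  const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, n_gamma = 0.35,
               alpha_naca = 2.5;
  const double KpCa = 0.0005;

  const double Cai = w[0], CaSR = w[1], Cass = w[2], Nai = w[3], Ki = w[4];
  const double m = w[5], h = w[6], j = w[7], xr1 = w[8], xr2 = w[9],
    xs = w[10], r = w[11], s = w[12], d = w[13], f = w[14], f2 = w[15],
    fCass = w[16], Rbar = w[17];

  const double Ek  = RTONF * std::log(Ko / Ki);
  const double ENa = RTONF * std::log(Nao / Nai);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTONF * std::log(Cao / Cai);

  const double INa = GNa * m * m * m * h * j * (V - ENa);
  double ICaL;
  {
    const double z = 2.0 * (V - 15.0) * Frdy / (Rgas * Temp);
    const double pref = GCaL * d * f * f2 * fCass * 4.0 * Frdy / (Rgas * Temp)
      * Frdy;
    if (std::fabs(z) < 1e-7) {
      // removable singularity at V = 15 mV: (V-15)/(e^z - 1) -> RT/(2F)
      ICaL = GCaL * d * f * f2 * fCass * 2.0 * Frdy * (0.25 * Cass - Cao);
    } else {
      ICaL = pref * (V - 15.0) *
        (0.25 * Cass * std::exp(z) - Cao) / (std::exp(z) - 1.0);
    }
  }
  const double Ito = Gto * r * s * (V - Ek);
  const double IKr = Gkr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - Ek);
  const double IKs = Gks * xs * xs * (V - EKs);
  double IK1;
  {
    const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
    const double bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                        std::exp(0.1 * (V - Ek - 10.0))) /
                       (1.0 + std::exp(-0.5 * (V - Ek)));
    IK1 = GK1 * std::sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - Ek);
  }
  const double vfrt = V * Frdy / (Rgas * Temp);
  const double INaCa = knaca *
    (std::exp(n_gamma * vfrt) * Nai * Nai * Nai * Cao -
     std::exp((n_gamma - 1.0) * vfrt) * Nao * Nao * Nao * Cai * alpha_naca) /
    ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
     (1.0 + ksat * std::exp((n_gamma - 1.0) * vfrt)));
  const double INaK = knak * Ko * Nai /
    ((Ko + KmK) * (Nai + KmNa) *
     (1.0 + 0.1245 * std::exp(-0.1 * vfrt) + 0.0353 * std::exp(-vfrt)));
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - ENa);
  const double IbCa = GbCa * (V - ECa);

  *Iion = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa + INaK + INaCa +
          IpCa + IpK;                                    // mV/ms
  if (only_current) return;

  // calcium subsystem
  const double kCasr = maxsr - (maxsr - minsr) /
    (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kCasr;
  const double k2 = k2p * kCasr;
  const double O = k1 * Cass * Cass * Rbar / (k3 + k1 * Cass * Cass);
  const double Irel = Vrel * O * (CaSR - Cass);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + Kup * Kup / (Cai * Cai));
  const double Ixfer = Vxfer * (Cass - Cai);

  const double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  const double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr /
                              ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  const double bufss = 1.0 / (1.0 + Bufss * Kbufss /
                              ((Cass + Kbufss) * (Cass + Kbufss)));
  for (int kk = 0; kk < 5; ++kk) kind[kk] = 0;
  H[0] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                 (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frdy));
  H[1] = bufsr * (Iup - Irel - Ileak);
  H[2] = bufss * (-ICaL * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
                  Ixfer * Vc / Vss);
  H[3] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frdy);
  H[4] = -(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * Cm / (Vc * Frdy);

  // gates
  for (int kk = 5; kk < TTP_M; ++kk) kind[kk] = 1;
  {
    const double inf = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                              (1.0 + std::exp((-56.86 - V) / 9.03)));
    const double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                     0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    winf[5] = inf; tau[5] = a * b;
  }
  {
    const double inf = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                              (1.0 + std::exp((V + 71.55) / 7.43)));
    double a, b;
    if (V >= -40.0) { a = 0.0; b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1))); }
    else { a = 0.057 * std::exp(-(V + 80.0) / 6.8);
           b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V); }
    winf[6] = inf; tau[6] = 1.0 / (a + b);
    double aj, bj;
    if (V >= -40.0) { aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0))); }
    else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    winf[7] = inf; tau[7] = 1.0 / (aj + bj);
  }
  {
    winf[8] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    tau[8] = a * b;
    winf[9] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double a2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double b2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    tau[9] = a2 * b2;
    winf[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double a3 = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double b3 = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    tau[10] = a3 * b3 + 80.0;
  }
  {
    winf[11] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    tau[11] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    if (cell == 1) {  // endocardial s gate
      winf[12] = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      tau[12] = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    } else {
      winf[12] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      tau[12] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }
  }
  {
    winf[13] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    const double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    tau[13] = a * b + c;
    winf[14] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    tau[14] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
              200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
              180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    winf[15] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    tau[15] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
              31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
              80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    const double cs = (Cass / 0.05) * (Cass / 0.05);
    winf[16] = 0.6 / (1.0 + cs) + 0.4;
    tau[16] = 80.0 / (1.0 + cs) + 2.0;
  }
  {
    // Rbar: dR/dt = k4 (1 - R) - k2 Cass R, affine in R
    const double rate = k2 * Cass + k4;
    winf[17] = k4 / rate; tau[17] = 1.0 / rate;
  }
  for (int kk = 5; kk < TTP_M; ++kk) H[kk] = (winf[kk] - w[kk]) / tau[kk];
}

// ---------------------------------------------------------------------------
// Courtemanche-Ramirez-Nattel 1998 human atrial model.  20 ionic variables:
//  0 Nai  1 Ki  2 Cai  3 Caup  4 Carel            (explicit, mM)
//  5 m 6 h 7 j 8 oa 9 oi 10 ua 11 ui 12 xr 13 xs 14 d 15 f 16 fca
//  17 u 18 v 19 wg                                 (implicit gates)
// params (14): gNa,gK1,gto,gKur_fix,gKur_var,gKr,gKs,gCaL,INaK_max,
//   INaCa_max,IpCa_max,gbNa,gbCa,krel
// ---------------------------------------------------------------------------
static const int CRN_M = 20;
static void crn_eval(double V, const double* w, const double* p,
                     double* Iion, double* H, double* winf, double* tau,
                     int* kind, bool only_current) {
  const double gNa = p[0], gK1 = p[1], gto = p[2], gKur_fix = p[3],
    gKur_var = p[4], gKr = p[5], gKs = p[6], gCaL = p[7], INaK_max = p[8],
    INaCa_max = p[9], IpCa_max = p[10], gbNa = p[11], gbCa = p[12],
    krel = p[13];

  const double Rgas = 8.3143, Temp = 310.0, Frdy = 96.4867;
  const double RTONF = Rgas * Temp / Frdy;            // mV
  const double Cm = 100.0;                            // pF
  const double Vi = 13668.0, Vup = 1109.52, Vrel_ = 96.48;
  const double Nao = 140.0, Ko = 5.4, Cao = 1.8;
  const double KQ10 = 3.0;
  const double KmNai = 10.0, KmKo = 1.5;
  const double KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35;
  const double Iup_max = 0.005, Kup = 0.00092, Caup_max = 15.0, tau_tr = 180.0;
  const double TRPN_max = 0.07, KmTRPN = 0.0005, CMDN_max = 0.05,
               KmCMDN = 0.00238, CSQN_max = 10.0, KmCSQN = 0.8;

  const double Nai = w[0], Ki = w[1], Cai = w[2], Caup = w[3], Carel = w[4];
  const double m = w[5], h = w[6], j = w[7], oa = w[8], oi = w[9],
    ua = w[10], ui = w[11], xr = w[12], xs = w[13], d = w[14], f = w[15],
    fca = w[16], uu = w[17], vv = w[18], wg = w[19];

  const double ENa = RTONF * std::log(Nao / Nai);
  const double EK  = RTONF * std::log(Ko / Ki);
  const double ECa = 0.5 * RTONF * std::log(Cao / Cai);
  const double vfrt = V * Frdy / (Rgas * Temp);

  const double INa = Cm * gNa * m * m * m * h * j * (V - ENa);
  const double IK1 = Cm * gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double Ito = Cm * gto * oa * oa * oa * oi * (V - EK);
  const double gKur = gKur_fix + gKur_var / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double IKur = Cm * gKur * ua * ua * ua * ui * (V - EK);
  const double IKr = Cm * gKr * xr * (V - EK) /
                     (1.0 + std::exp((V + 15.0) / 22.4));
  const double IKs = Cm * gKs * xs * xs * (V - EK);
  const double ICaL = Cm * gCaL * d * f * fca * (V - 65.0);
  const double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                             0.0365 * sig * std::exp(-vfrt));
  const double INaK = Cm * INaK_max * fNaK * Ko /
    ((1.0 + std::pow(KmNai / Nai, 1.5)) * (Ko + KmKo));
  const double INaCa = Cm * INaCa_max *
    (std::exp(gam * vfrt) * Nai * Nai * Nai * Cao -
     std::exp((gam - 1.0) * vfrt) * Nao * Nao * Nao * Cai) /
    ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
     (1.0 + ksat * std::exp((gam - 1.0) * vfrt)));
  const double IpCa = Cm * IpCa_max * Cai / (0.0005 + Cai);
  const double IbNa = Cm * gbNa * (V - ENa);
  const double IbCa = Cm * gbCa * (V - ECa);

  *Iion = (INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK + INaCa +
           IbNa + IbCa) / Cm;                           // mV/ms
  if (only_current) return;

  const double Irel = krel * uu * uu * vv * wg * (Carel - Cai);
  const double Itr = (Caup - Carel) / tau_tr;
  const double Iup = Iup_max / (1.0 + Kup / Cai);
  const double Iup_leak = Iup_max * Caup / Caup_max;

  for (int kk = 0; kk < 5; ++kk) kind[kk] = 0;
  H[0] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) / (Frdy * Vi);
  H[1] = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) / (Frdy * Vi);
  {
    const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) / (2.0 * Frdy * Vi) +
      (Vup * (Iup_leak - Iup) + Irel * Vrel_) / Vi;
    const double B2 = 1.0 +
      TRPN_max * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
      CMDN_max * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
    H[2] = B1 / B2;
  }
  H[3] = Iup - Iup_leak - Itr * Vrel_ / Vup;
  H[4] = (Itr - Irel) /
    (1.0 + CSQN_max * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));

  for (int kk = 5; kk < CRN_M; ++kk) kind[kk] = 1;
  {
    double am;
    if (std::fabs(V + 47.13) < 1e-10) am = 3.2;
    else am = 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
    const double bm = 0.08 * std::exp(-V / 11.0);
    winf[5] = am / (am + bm); tau[5] = 1.0 / (am + bm);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0; bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0; bj = 0.3 * std::exp(-2.535e-7 * V) /
                     (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
      aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    winf[6] = ah / (ah + bh); tau[6] = 1.0 / (ah + bh);
    winf[7] = aj / (aj + bj); tau[7] = 1.0 / (aj + bj);
  }
  {
    const double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                             std::exp(-(V - 30.0) / 59.0));
    const double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    tau[8] = 1.0 / ((a + b) * KQ10);
    winf[8] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
    const double a2 = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
    const double b2 = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
    tau[9] = 1.0 / ((a2 + b2) * KQ10);
    winf[9] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
    tau[10] = tau[8] * 1.0;  // same alpha/beta as oa
    winf[10] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
    const double a4 = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
    const double b4 = std::exp((V - 158.0) / 16.0);
    tau[11] = 1.0 / ((a4 + b4) * KQ10);
    winf[11] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  }
  {
    double axr, bxr;
    if (std::fabs(V + 14.1) < 1e-10) axr = 0.0015;
    else axr = 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
    if (std::fabs(V - 3.3328) < 1e-10) bxr = 3.7836118e-4;
    else bxr = 7.3898e-5 * (V - 3.3328) /
               (std::exp((V - 3.3328) / 5.1237) - 1.0);
    tau[12] = 1.0 / (axr + bxr);
    winf[12] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
    double axs, bxs;
    if (std::fabs(V - 19.9) < 1e-10) { axs = 0.00068; bxs = 0.000315; }
    else {
      axs = 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
      bxs = 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
    }
    tau[13] = 0.5 / (axs + bxs);
    winf[13] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  }
  {
    double td;
    if (std::fabs(V + 10.0) < 1e-10) td = 4.579 / (1.0 + std::exp(-(V + 10.0) / 6.24));
    else td = (1.0 - std::exp(-(V + 10.0) / 6.24)) /
              (0.035 * (V + 10.0) * (1.0 + std::exp(-(V + 10.0) / 6.24)));
    tau[14] = td;
    winf[14] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
    tau[15] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
    winf[15] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
    winf[16] = 1.0 / (1.0 + Cai / 0.00035); tau[16] = 2.0;
  }
  {
    const double Fn = 1e-12 * Vrel_ * Irel -
      (5e-13 / Frdy) * (0.5 * ICaL - 0.2 * INaCa);
    winf[17] = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    tau[17] = 8.0;
    winf[18] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
    tau[18] = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    winf[19] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
    if (std::fabs(V - 7.9) < 1e-10) {
      tau[19] = 6.0 * 0.2 / 1.3;
    } else {
      tau[19] = 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
        ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));
    }
  }
  for (int kk = 5; kk < CRN_M; ++kk) H[kk] = (winf[kk] - w[kk]) / tau[kk];
}

// ---------------------------------------------------------------------------

typedef void (*eval_fn)(double, const double*, const double*, double*,
                        double*, double*, double*, int*, bool);

static eval_fn get_model(int id, int* M) {
  switch (id) {
    case 1: *M = APF_M; return apf_eval;
    case 2: *M = BO_M;  return bo_eval;
    case 3: *M = TTP_M; return ttp06_eval;
    case 4: *M = CRN_M; return crn_eval;
  }
  stop("unknown ionic model id");
  return nullptr;  // not reached
}

// [[Rcpp::export]]
List ionic_rhs_cpp(int model_id, NumericVector u, NumericMatrix w,
                   NumericVector params) {
  int M;
  eval_fn f = get_model(model_id, &M);
  const int n = u.size();
  if (w.nrow() != n || w.ncol() != M) stop("w must be n x M");
  NumericVector Iion(n);
  NumericMatrix H(n, M);
  std::vector<double> wk(M), Hk(M), winf(M), tau(M);
  std::vector<int> kind(M);
  const double* p = params.begin();
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < M; ++k) wk[k] = w(i, k);
    double I;
    f(u[i], wk.data(), p, &I, Hk.data(), winf.data(), tau.data(),
      kind.data(), false);
    Iion[i] = I;
    for (int k = 0; k < M; ++k) H(i, k) = Hk[k];
  }
  return List::create(_["Iion"] = Iion, _["H"] = H);
}

// [[Rcpp::export]]
NumericVector ionic_current_cpp(int model_id, NumericVector u,
                                NumericMatrix w, NumericVector params) {
  int M;
  eval_fn f = get_model(model_id, &M);
  const int n = u.size();
  if (w.nrow() != n || w.ncol() != M) stop("w must be n x M");
  NumericVector Iion(n);
  std::vector<double> wk(M), Hk(M), winf(M), tau(M);
  std::vector<int> kind(M);
  const double* p = params.begin();
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < M; ++k) wk[k] = w(i, k);
    double I;
    f(u[i], wk.data(), p, &I, Hk.data(), winf.data(), tau.data(),
      kind.data(), true);
    Iion[i] = I;
  }
  return Iion;
}

// One IMEX ionic update: gates closed-form implicit, the rest explicit,
// all coefficients evaluated at the extrapolated state.  dt in model time
// units (ms).  Gates are clamped to [0,1]; the clamp count is returned as
// an attribute.
// [[Rcpp::export]]
NumericMatrix ionic_step_cpp(int model_id, NumericVector u_ext,
                             NumericMatrix w_bdf, NumericMatrix w_ext,
                             double dt, double alpha, NumericVector params) {
  int M;
  eval_fn f = get_model(model_id, &M);
  const int n = u_ext.size();
  if (w_bdf.nrow() != n || w_bdf.ncol() != M) stop("w_bdf must be n x M");
  if (w_ext.nrow() != n || w_ext.ncol() != M) stop("w_ext must be n x M");
  if (dt <= 0) stop("dt must be positive");
  NumericMatrix out(n, M);
  std::vector<double> wk(M), Hk(M), winf(M), tau(M);
  std::vector<int> kind(M);
  const double* p = params.begin();
  int clamped = 0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < M; ++k) wk[k] = w_ext(i, k);
    double I;
    f(u_ext[i], wk.data(), p, &I, Hk.data(), winf.data(), tau.data(),
      kind.data(), false);
    for (int k = 0; k < M; ++k) {
      double wn;
      if (kind[k] == 1) {
        wn = (w_bdf(i, k) + dt * winf[k] / tau[k]) / (alpha + dt / tau[k]);
        if (wn < 0.0) { wn = 0.0; ++clamped; }
        else if (wn > 1.0) { wn = 1.0; ++clamped; }
      } else {
        wn = (w_bdf(i, k) + dt * Hk[k]) / alpha;
      }
      out(i, k) = wn;
    }
  }
  out.attr("clamped") = clamped;
  return out;
}
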