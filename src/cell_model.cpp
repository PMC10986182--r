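// Human ventricular myocyte membrane kinetics: ten Tusscher & Panfilov (2006)
// formulation with the O'Hara-Rudy late sodium current added to the total
// membrane current. Integration is Rush-Larsen for the Hodgkin-Huxley gates
// and forward Euler for voltage and concentrations; calsequestrin/calmodulin
// buffering is handled with the usual instantaneous-buffer quadratic update.
//
// Two evaluation paths are provided: a direct path computing all rate
// constants with exp(), and a lookup-table path (0.05 mV grid with linear
// interpolation) used by tissue simulations. Both paths share the same rate
// functions so they cannot drift apart.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "cell_model.h"

using namespace Rcpp;

// ---- physical constants ----------------------------------------------------
static const double Rgas = 8314.472;   // mJ/(mol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96485.3415; // C/mol
static const double RTONF = Rgas * Temp / Frdy; // ~26.71 mV
static const double inverseVcF2 = 1.0 / (2.0 * 0.016404 * Frdy);
static const double inverseVcF = 1.0 / (0.016404 * Frdy);
static const double inversevssF2 = 1.0 / (2.0 * 0.00005468 * Frdy);
static const double CAPACITANCE = 0.185;

// ---- fixed model parameters ------------------------------------------------
static const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
static const double Vsr = 0.001094, Vss = 0.00005468, Vc = 0.016404;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double pKNa = 0.03;
static const double Gna = 14.838, Gbna = 0.00029, GCaL = 0.0000398,
                    Gbca = 0.000592, Gkr = 0.153, GK1 = 5.405,
                    GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    nab = 0.35; // NCX voltage-dependence exponent

static inline double Gto_of(int variant) {
  return variant == FS_ENDO ? 0.073 : 0.294;
}
static inline double Gks_of(int variant) {
  return variant == FS_MCELL ? 0.098 : 0.392;
}

// ---- gate rate functions ---------------------------------------------------
// inf/tau for the 13 Rush-Larsen gates, order:
// m h j xr1 xr2 xs r s d f f2 mL hL
static void gate_rates(double V, int variant, double *inf, double *tau) {
  // m
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  inf[0] = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                  (1.0 + std::exp((-56.86 - V) / 9.03)));
  tau[0] = am * bm;
  // h
  inf[1] = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                  (1.0 + std::exp((V + 71.55) / 7.43)));
  double ah, bh;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
  }
  tau[1] = 1.0 / (ah + bh);
  // j
  inf[2] = inf[1];
  double aj, bj;
  if (V >= -40.0) {
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    aj = (-25428.0 * std::exp(0.2444 * V) -
          0.000006948 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  tau[2] = 1.0 / (aj + bj);
  // xr1
  inf[3] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  tau[3] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
           (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
  // xr2
  inf[4] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  tau[4] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
           (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
  // xs
  inf[5] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  tau[5] = (1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0))) *
               (1.0 / (1.0 + std::exp((V - 35.0) / 15.0))) + 80.0;
  // r
  inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // s (transmural-variant dependent)
  if (variant == FS_ENDO) {
    inf[7] = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    tau[7] = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {
    inf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  // d
  inf[8] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  tau[8] = ad * bd + gd;
  // f
  inf[9] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  tau[9] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
           200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
           180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  // f2
  inf[10] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  tau[10] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
            31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
            80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  // mL (late sodium activation; O'Hara-Rudy kinetics)
  inf[11] = 1.0 / (1.0 + std::exp(-(V + 42.85) / 5.264));
  tau[11] = 1.0 / (6.765 * std::exp((V + 11.64) / 34.77) +
                   8.552 * std::exp(-(V + 77.42) / 5.955));
  // hL (late sodium inactivation)
  inf[12] = 1.0 / (1.0 + std::exp((V + 87.61) / 7.488));
  tau[12] = 200.0;
}

// Voltage-only current factors shared by direct and LUT paths, order:
// 0 exp(2(V-15)F/RT); 1 (V-15)/(e1-1) (limit value at the singularity);
// 2 exp(nab*V*F/RT); 3 NCX denominator 1/(1+ksat*exp((nab-1)VF/RT));
// 4 exp((nab-1)VF/RT); 5 NaK rectification; 6 IpK rectification
#define FS_NVFAC 7
static void volt_factors(double V, double *fac) {
  double z = 2.0 * (V - 15.0) / RTONF;
  double e1 = std::exp(z);
  fac[0] = e1;
  fac[1] = (std::fabs(z) < 1e-7) ? RTONF / 2.0 : (V - 15.0) / (e1 - 1.0);
  fac[2] = std::exp(nab * V / RTONF);
  double em1 = std::exp((nab - 1.0) * V / RTONF);
  fac[4] = em1;
  fac[3] = 1.0 / (1.0 + ksat * em1);
  fac[5] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                  0.0353 * std::exp(-V / RTONF));
  fac[6] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
}

// Inward-rectifier open fraction as a function of x = V - EK.
static double k1_rect(double x) {
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (x - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (x + 100.0)) +
                std::exp(0.1 * (x - 10.0))) /
               (1.0 + std::exp(-0.5 * x));
  return ak1 / (ak1 + bk1);
}

// ---- lookup tables ---------------------------------------------------------
// One fused row per voltage bin (gate targets, gate exponentials, current
// factors) so a cell step touches two contiguous cache lines instead of 33
// scattered arrays.
#define FS_NLVAL (2 * FS_NGATE + FS_NVFAC)
struct CellLUT {
  double vmin, vmax, dv, inv_dv;
  int n;
  std::vector<double> tab; // n rows of FS_NLVAL values
  double xmin, xmax, inv_dx;
  int nx;
  std::vector<double> rk1;
  bool built;
  CellLUT() : built(false) {}

  void build(double dt, int variant) {
    vmin = -150.0; vmax = 100.0; dv = 0.02; inv_dv = 1.0 / dv;
    n = (int)std::floor((vmax - vmin) / dv) + 2;
    tab.resize((size_t)n * FS_NLVAL);
    double inf[FS_NGATE], tau[FS_NGATE], fac[FS_NVFAC];
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_rates(V, variant, inf, tau);
      volt_factors(V, fac);
      double *row = &tab[(size_t)i * FS_NLVAL];
      for (int g = 0; g < FS_NGATE; ++g) {
        row[g] = inf[g];
        row[FS_NGATE + g] = std::exp(-dt / tau[g]);
      }
      for (int f = 0; f < FS_NVFAC; ++f) row[2 * FS_NGATE + f] = fac[f];
    }
    xmin = -150.0; xmax = 300.0;
    double dx = 0.02; inv_dx = 1.0 / dx;
    nx = (int)std::floor((xmax - xmin) / dx) + 2;
    rk1.resize(nx);
    for (int i = 0; i < nx; ++i) rk1[i] = k1_rect(xmin + i * dx);
    built = true;
  }
};

// ---- one integration step --------------------------------------------------
// S: state vector (modified in place). scales: 8 ionic scale factors.
// Iext: external current in pA/pF, positive depolarizing (stimulus +
// diffusion). Returns the membrane voltage after the step.
// rev: optional 4-slot cache (Ek, Ena, Eks, Eca) refreshed by the caller;
// pass nullptr to recompute from concentrations every step.
static inline void fill_reversals(const double *S, double *rev) {
  rev[0] = RTONF * std::log(Ko / S[FS_KI]);
  rev[1] = RTONF * std::log(Nao / S[FS_NAI]);
  rev[2] = RTONF * std::log((Ko + pKNa * Nao) /
                            (S[FS_KI] + pKNa * S[FS_NAI]));
  rev[3] = 0.5 * RTONF * std::log(Cao / S[FS_CAI]);
}

static inline double step_cell_core(double *S, const double *scales,
                                    double gNaL, int variant, double dt,
                                    double Iext, const CellLUT *lut,
                                    const double *rev = nullptr) {
  const double V = S[FS_V];
  double inf[FS_NGATE], tau[FS_NGATE], fac[FS_NVFAC];
  double gexp[FS_NGATE];
  if (lut) {
    double u = (V - lut->vmin) * lut->inv_dv;
    if (u < 0.0) u = 0.0;
    if (u > lut->n - 2.0) u = lut->n - 2.0;
    int i0 = (int)u;
    double w = u - i0;
    const double *r0 = &lut->tab[(size_t)i0 * FS_NLVAL];
    const double *r1 = r0 + FS_NLVAL;
    for (int g = 0; g < FS_NGATE; ++g) {
      inf[g] = r0[g] + w * (r1[g] - r0[g]);
      gexp[g] = r0[FS_NGATE + g] + w * (r1[FS_NGATE + g] - r0[FS_NGATE + g]);
    }
    for (int f = 0; f < FS_NVFAC; ++f) {
      const int k = 2 * FS_NGATE + f;
      fac[f] = r0[k] + w * (r1[k] - r0[k]);
    }
  } else {
    gate_rates(V, variant, inf, tau);
    for (int g = 0; g < FS_NGATE; ++g) gexp[g] = std::exp(-dt / tau[g]);
    volt_factors(V, fac);
  }

  // reversal potentials (cached between refreshes in tissue runs)
  double revloc[4];
  if (!rev) { fill_reversals(S, revloc); rev = revloc; }
  const double Ek = rev[0], Ena = rev[1], Eks = rev[2], Eca = rev[3];

  // currents
  const double INa = Gna * S[FS_M] * S[FS_M] * S[FS_M] * S[FS_H] * S[FS_J] *
                     (V - Ena);
  const double INaL = scales[FS_S_NAL] * gNaL * S[FS_ML] * S[FS_HL] * (V - Ena);
  const double ICaL = scales[FS_S_CAL] * GCaL * S[FS_D] * S[FS_F] * S[FS_F2] *
                      S[FS_FCASS] * 4.0 * fac[1] * (Frdy / RTONF) *
                      (0.25 * S[FS_CASS] * fac[0] - Cao);
  const double Ito = scales[FS_S_TO] * Gto_of(variant) * S[FS_R] * S[FS_S] *
                     (V - Ek);
  const double IKr = scales[FS_S_KR] * Gkr * std::sqrt(Ko / 5.4) * S[FS_XR1] *
                     S[FS_XR2] * (V - Ek);
  const double IKs = scales[FS_S_KS] * Gks_of(variant) * S[FS_XS] * S[FS_XS] *
                     (V - Eks);
  double rk1v;
  if (lut) {
    double x = V - Ek;
    double u = (x - lut->xmin) * lut->inv_dx;
    if (u < 0.0) u = 0.0;
    if (u > lut->nx - 2.0) u = lut->nx - 2.0;
    int i0 = (int)u;
    double w = u - i0;
    rk1v = lut->rk1[i0] + w * (lut->rk1[i0 + 1] - lut->rk1[i0]);
  } else {
    rk1v = k1_rect(V - Ek);
  }
  const double IK1 = scales[FS_S_K1] * GK1 * std::sqrt(Ko / 5.4) * rk1v *
                     (V - Ek);
  const double INaCa =
      scales[FS_S_NCX] * knaca *
      (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) * fac[3] *
      (fac[2] * S[FS_NAI] * S[FS_NAI] * S[FS_NAI] * Cao -
       fac[4] * Nao * Nao * Nao * S[FS_CAI] * 2.5);
  const double INaK = knak * (Ko / (Ko + KmK)) *
                      (S[FS_NAI] / (S[FS_NAI] + KmNa)) * fac[5];
  const double IpCa = GpCa * S[FS_CAI] / (KpCa + S[FS_CAI]);
  const double IpK = GpK * fac[6] * (V - Ek);
  const double IbNa = Gbna * (V - Ena);
  const double IbCa = Gbca * (V - Eca);

  const double Itot = INa + INaL + ICaL + Ito + IKr + IKs + IK1 + INaCa +
                      INaK + IpCa + IpK + IbNa + IbCa;

  // calcium subsystem
  const double kCaSR =
      maxsr - (maxsr - minsr) / (1.0 + (EC / S[FS_CASR]) * (EC / S[FS_CASR]));
  const double k1 = k1p / kCaSR;
  const double k2 = k2p * kCaSR;
  S[FS_RR] += dt * (k4 * (1.0 - S[FS_RR]) - k2 * S[FS_CASS] * S[FS_RR]);
  const double OO = k1 * S[FS_CASS] * S[FS_CASS] * S[FS_RR] /
                    (k3 + k1 * S[FS_CASS] * S[FS_CASS]);
  const double Irel = Vrel * OO * (S[FS_CASR] - S[FS_CASS]);
  const double Ileak = Vleak * (S[FS_CASR] - S[FS_CAI]);
  const double Iup = scales[FS_S_SERCA] * Vmaxup /
                     (1.0 + Kup * Kup / (S[FS_CAI] * S[FS_CAI]));
  const double Ixfer = Vxfer * (S[FS_CASS] - S[FS_CAI]);

  {
    const double CaCSQN = Bufsr * S[FS_CASR] / (S[FS_CASR] + Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double b = Bufsr - CaCSQN - dCaSR - S[FS_CASR] + Kbufsr;
    const double c = Kbufsr * (CaCSQN + dCaSR + S[FS_CASR]);
    S[FS_CASR] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  {
    const double CaSSBuf = Bufss * S[FS_CASS] / (S[FS_CASS] + Kbufss);
    const double dCaSS =
        dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
              (-ICaL * inversevssF2 * CAPACITANCE));
    const double b = Bufss - CaSSBuf - dCaSS - S[FS_CASS] + Kbufss;
    const double c = Kbufss * (CaSSBuf + dCaSS + S[FS_CASS]);
    S[FS_CASS] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  {
    const double CaBuf = Bufc * S[FS_CAI] / (S[FS_CAI] + Kbufc);
    const double dCai =
        dt * ((-(IbCa + IpCa - 2.0 * INaCa) * inverseVcF2 * CAPACITANCE) -
              (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double b = Bufc - CaBuf - dCai - S[FS_CAI] + Kbufc;
    const double c = Kbufc * (CaBuf + dCai + S[FS_CAI]);
    S[FS_CAI] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }

  S[FS_NAI] += dt * (-(INa + INaL + IbNa + 3.0 * INaK + 3.0 * INaCa) *
                     inverseVcF * CAPACITANCE);
  S[FS_KI] += dt * (-(-Iext + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                    inverseVcF * CAPACITANCE);

  // Rush-Larsen gate updates
  static const int gate_state[FS_NGATE] = {FS_M, FS_H, FS_J, FS_XR1, FS_XR2,
                                           FS_XS, FS_R, FS_S, FS_D, FS_F,
                                           FS_F2, FS_ML, FS_HL};
  for (int g = 0; g < FS_NGATE; ++g) {
    const int k = gate_state[g];
    S[k] = inf[g] - (inf[g] - S[k]) * gexp[g];
  }
  // fcass depends on subspace calcium, not voltage
  {
    const double cass = S[FS_CASS];
    const double q = 1.0 / (1.0 + (cass / 0.05) * (cass / 0.05));
    const double finf = 0.6 * q + 0.4;
    const double ftau = 80.0 * q + 2.0;
    S[FS_FCASS] = finf - (finf - S[FS_FCASS]) * std::exp(-dt / ftau);
  }

  S[FS_V] = V + dt * (-Itot + Iext);
  return S[FS_V];
}

// default initial conditions (resting state before any pre-pacing)
static void init_state(double *S) {
  S[FS_V] = -86.2; S[FS_M] = 0.0; S[FS_H] = 0.75; S[FS_J] = 0.75;
  S[FS_XR1] = 0.0; S[FS_XR2] = 1.0; S[FS_XS] = 0.0; S[FS_R] = 0.0;
  S[FS_S] = 1.0; S[FS_D] = 0.0; S[FS_F] = 1.0; S[FS_F2] = 1.0;
  S[FS_FCASS] = 1.0; S[FS_RR] = 1.0; S[FS_CAI] = 0.00007; S[FS_CASR] = 1.3;
  S[FS_CASS] = 0.00007; S[FS_NAI] = 7.67; S[FS_KI] = 138.3;
  S[FS_ML] = 0.0; S[FS_HL] = 0.6;
}

static void check_state_finite(const double *S, double t) {
  static const char *nm[FS_NSTATE] = {
      "V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
      "fcass", "rr", "Cai", "CaSR", "CaSS", "Nai", "Ki", "mL", "hL"};
  for (int k = 0; k < FS_NSTATE; ++k) {
    if (!std::isfinite(S[k])) {
      stop("numerical blow-up at t = %.3f ms: state variable '%s' is not "
           "finite", t, nm[k]);
    }
  }
}

// [[Rcpp::export(name = ".fs_default_state")]]
NumericVector fs_default_state() {
  NumericVector out(FS_NSTATE);
  init_state(REAL(out));
  return out;
}

// [[Rcpp::export(name = ".fs_step_cell")]]
NumericVector fs_step_cell(NumericVector state, NumericVector scales,
                           double g_nal, int variant, double dt,
                           double i_stim) {
  if (state.size() != FS_NSTATE) stop("state must have %d entries", FS_NSTATE);
  if (scales.size() != FS_NSCALE) stop("scales must have %d entries", FS_NSCALE);
  NumericVector out = clone(state);
  step_cell_core(REAL(out), REAL(scales), g_nal, variant, dt, i_stim, nullptr);
  check_state_finite(REAL(out), dt);
  return out;
}

// APD90 of a single beat stored as V at uniform dt: time from maximum
// upstroke velocity to the first downward crossing of
// vrest + 0.1 * (vpeak - vrest), linearly interpolated.
static double apd90_of_beat(const std::vector<double> &v, double dt) {
  const int n = (int)v.size();
  if (n < 3) return NA_REAL;
  const double vrest = v[0];
  int i_up = 1, i_peak = 0;
  double max_dvdt = -1e300, vpeak = v[0];
  for (int i = 1; i < n; ++i) {
    const double dvdt = v[i] - v[i - 1];
    if (dvdt > max_dvdt) { max_dvdt = dvdt; i_up = i; }
    if (v[i] > vpeak) { vpeak = v[i]; i_peak = i; }
  }
  if (vpeak < 0.0) return NA_REAL; // no action potential elicited
  const double v90 = vrest + 0.1 * (vpeak - vrest);
  for (int i = i_peak + 1; i < n; ++i) {
    if (v[i] <= v90 && v[i - 1] > v90) {
      const double w = (v[i - 1] - v90) / (v[i - 1] - v[i]);
      return (i - 1 + w) * dt - i_up * dt;
    }
  }
  return NA_REAL; // did not repolarize within the cycle
}

// Single-cell pacing with per-beat APD90 bookkeeping and an optional
// steady-state early stop (|APD90[b] - APD90[b - ss_window]| < ss_tol).
// Returns list(time, v, apd90, beats_run, converged, state).
// [[Rcpp::export(name = ".fs_pace_cell")]]
List fs_pace_cell(NumericVector scales, double g_nal, int variant, double bcl,
                  int n_beats, double dt, double stim_amp, double stim_dur,
                  double record_dt, double ss_tol, int ss_window,
                  Nullable<NumericVector> state0, bool use_lut) {
  if (scales.size() != FS_NSCALE) stop("scales must have %d entries", FS_NSCALE);
  if (n_beats < 1) stop("n_beats must be >= 1");
  std::vector<double> S(FS_NSTATE);
  if (state0.isNotNull()) {
    NumericVector s0(state0);
    if (s0.size() != FS_NSTATE) stop("state0 must have %d entries", FS_NSTATE);
    for (int k = 0; k < FS_NSTATE; ++k) S[k] = s0[k];
  } else {
    init_state(S.data());
  }
  CellLUT lut;
  if (use_lut) lut.build(dt, variant);
  const CellLUT *lp = use_lut ? &lut : nullptr;

  const int steps_per_beat = (int)std::llround(bcl / dt);
  std::vector<double> apd;
  apd.reserve(n_beats);
  std::vector<double> beat_v(steps_per_beat + 1);
  bool converged = false;
  int beats_run = 0;

  for (int b = 0; b < n_beats; ++b) {
    for (int i = 0; i < steps_per_beat; ++i) {
      const double t = i * dt;
      const double istim = (t < stim_dur) ? stim_amp : 0.0;
      beat_v[i] = S[FS_V];
      const double vnew = step_cell_core(S.data(), REAL(scales), g_nal,
                                         variant, dt, istim, lp);
      if (!std::isfinite(vnew)) check_state_finite(S.data(), b * bcl + t);
    }
    beat_v[steps_per_beat] = S[FS_V];
    apd.push_back(apd90_of_beat(beat_v, dt));
    beats_run = b + 1;
    if (ss_tol > 0.0 && beats_run > ss_window) {
      const double a1 = apd[beats_run - 1];
      const double a0 = apd[beats_run - 1 - ss_window];
      if (R_finite(a1) && R_finite(a0) && std::fabs(a1 - a0) < ss_tol) {
        converged = true;
        break;
      }
    }
  }

  // down-sample the final beat's trace to record_dt
  const int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  std::vector<double> rec_t, rec_v;
  for (int i = 0; i <= steps_per_beat; i += rec_stride) {
    rec_t.push_back(i * dt);
    rec_v.push_back(beat_v[i]);
  }
  return List::create(_["time"] = rec_t, _["v"] = rec_v,
                      _["apd90"] = NumericVector(apd.begin(), apd.end()),
                      _["beats_run"] = beats_run, _["converged"] = converged,
                      _["state"] = NumericVector(S.begin(), S.end()));
}

// ---- monodomain tissue integrator ------------------------------------------
// Collocated lattice discretization: one membrane-model node per element
// center. The diffusion operator is supplied from R as a CSR adjacency with
// edge weights already scaled to 1/ms, so that
//   dV_i/dt += sum_j w_ij * (V_j - V_i).
// Stimuli are transmembrane currents (pA/pF) over explicit element sets.
// Activation times are upward crossings of v_thresh, linearly interpolated.
// [[Rcpp::export(name = ".fs_simulate")]]
List fs_simulate(IntegerVector csr_ptr, IntegerVector csr_idx,
                 NumericVector csr_w, IntegerVector region,
                 NumericMatrix region_scales, NumericVector region_gnal,
                 int variant, NumericVector stim_onset,
                 NumericVector stim_dur, NumericVector stim_amp,
                 IntegerVector stim_ptr, IntegerVector stim_cells, double dt,
                 double duration, double out_interval, double v_thresh,
                 bool record_frames, Nullable<NumericMatrix> state0,
                 bool use_lut, bool stop_when_quiet, double quiet_v,
                 double quiet_after) {
  const int n = region.size();
  if (csr_ptr.size() != n + 1) stop("csr_ptr length must be n + 1");
  const int nregion = region_scales.nrow();
  if (region_scales.ncol() != FS_NSCALE)
    stop("region_scales must have %d columns", FS_NSCALE);
  if (region_gnal.size() != nregion)
    stop("region_gnal length must match region_scales rows");
  const int nstim = stim_onset.size();
  if (stim_ptr.size() != nstim + 1) stop("stim_ptr length must be nstim + 1");

  // states, cell-major
  std::vector<double> S((size_t)n * FS_NSTATE);
  if (state0.isNotNull()) {
    NumericMatrix s0(state0);
    if (s0.nrow() != n || s0.ncol() != FS_NSTATE)
      stop("state0 must be n x %d", FS_NSTATE);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < FS_NSTATE; ++k)
        S[(size_t)i * FS_NSTATE + k] = s0(i, k);
  } else {
    double s0[FS_NSTATE];
    init_state(s0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < FS_NSTATE; ++k)
        S[(size_t)i * FS_NSTATE + k] = s0[k];
  }

  // per-region scale pointers
  std::vector<double> scl((size_t)nregion * FS_NSCALE);
  for (int r = 0; r < nregion; ++r)
    for (int k = 0; k < FS_NSCALE; ++k)
      scl[(size_t)r * FS_NSCALE + k] = region_scales(r, k);
  for (int i = 0; i < n; ++i)
    if (region[i] < 0 || region[i] >= nregion)
      stop("region id out of range for element %d", i + 1);

  CellLUT lut;
  if (use_lut) lut.build(dt, variant);
  const CellLUT *lp = use_lut ? &lut : nullptr;

  const long nsteps = (long)std::llround(duration / dt);
  const long frame_stride = std::max(1L, (long)std::llround(out_interval / dt));
  const long check_stride = std::max(1L, (long)std::llround(25.0 / dt));

  std::vector<double> V(n), Iext(n);
  for (int i = 0; i < n; ++i) V[i] = S[(size_t)i * FS_NSTATE + FS_V];

  // reversal-potential cache: intracellular concentrations move on second
  // timescales, so Nernst potentials are refreshed every 0.5 ms
  const long rev_stride = std::max(1L, (long)std::llround(0.5 / dt));
  std::vector<double> rev((size_t)n * 4);
  for (int i = 0; i < n; ++i)
    fill_reversals(&S[(size_t)i * FS_NSTATE], &rev[(size_t)i * 4]);

  std::vector<std::vector<double>> act(n);
  std::vector<double> frames; // column-major n x nframes
  std::vector<double> frame_times;
  bool stopped_early = false;
  double t_end = 0.0;

  for (long s = 0; s <= nsteps; ++s) {
    const double t = s * dt;
    if (record_frames && s % frame_stride == 0) {
      frames.insert(frames.end(), V.begin(), V.end());
      frame_times.push_back(t);
    }
    if (s == nsteps) { t_end = t; break; }

    // external currents: diffusion + stimuli
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const double vi = V[i];
      for (int p = csr_ptr[i]; p < csr_ptr[i + 1]; ++p)
        acc += csr_w[p] * (V[csr_idx[p]] - vi);
      Iext[i] = acc;
    }
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onset[q] && t < stim_onset[q] + stim_dur[q]) {
        for (int p = stim_ptr[q]; p < stim_ptr[q + 1]; ++p)
          Iext[stim_cells[p]] += stim_amp[q];
      }
    }

    // advance membrane model
    const bool refresh = (s % rev_stride == 0);
    for (int i = 0; i < n; ++i) {
      double *Si = &S[(size_t)i * FS_NSTATE];
      if (refresh) fill_reversals(Si, &rev[(size_t)i * 4]);
      const double vold = V[i];
      const double vnew = step_cell_core(
          Si, &scl[(size_t)region[i] * FS_NSCALE], region_gnal[region[i]],
          variant, dt, Iext[i], lp, &rev[(size_t)i * 4]);
      if (vold < v_thresh && vnew >= v_thresh) {
        const double w = (v_thresh - vold) / (vnew - vold);
        act[i].push_back(t + w * dt);
      }
      V[i] = vnew;
    }

    if (s % check_stride == 0) {
      double vmax = -1e300;
      for (int i = 0; i < n; ++i) vmax = std::max(vmax, V[i]);
      if (!std::isfinite(vmax)) {
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(V[i]))
            stop("numerical blow-up at t = %.3f ms in element %d", t + dt,
                 i + 1);
      }
      if (stop_when_quiet && t > quiet_after && vmax < quiet_v) {
        stopped_early = true;
        t_end = t + dt;
        break;
      }
      Rcpp::checkUserInterrupt();
    }
    t_end = t + dt;
  }

  // pack activations into a long table
  size_t ntot = 0;
  for (int i = 0; i < n; ++i) ntot += act[i].size();
  IntegerVector a_cell(ntot), a_index(ntot);
  NumericVector a_time(ntot);
  size_t pos = 0;
  for (int i = 0; i < n; ++i) {
    for (size_t k = 0; k < act[i].size(); ++k) {
      a_cell[pos] = i + 1;
      a_index[pos] = (int)k + 1;
      a_time[pos] = act[i][k];
      ++pos;
    }
  }

  NumericMatrix state_out(n, FS_NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < FS_NSTATE; ++k)
      state_out(i, k) = S[(size_t)i * FS_NSTATE + k];

  List out = List::create(
      _["activation"] = DataFrame::create(_["element"] = a_cell,
                                          _["index"] = a_index,
                                          _["time_ms"] = a_time),
      _["state"] = state_out, _["t_end"] = t_end,
      _["stopped_early"] = stopped_early);
  if (record_frames) {
    NumericMatrix fm(n, (int)frame_times.size());
    std::copy(frames.begin(), frames.end(), fm.begin());
    out["frames"] = fm;
    out["frame_times"] = NumericVector(frame_times.begin(), frame_times.end());
  }
  return out;
}
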