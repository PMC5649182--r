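// Core numerics: human ventricular myocyte (O'Hara-Rudy lineage, Luo-Rudy
// fast INa), Markov chain IKr with drug-bound open/inactivated states,
// guarded-receptor INa block, explicit-Euler monodomain solvers (1D strand,
// 2D sheet), and a frozen-gate voltage-clamp integrator for the Na block
// model. Voltage-dependent quantities are tabulated once per run (0.02 mV
// grid, linear interpolation); Hodgkin-Huxley gates advance by Rush-Larsen,
// Markov occupancies and concentrations by forward Euler.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// physical constants and cell geometry (cm, ms, mV, mM, uA/uF)
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Lcell = 0.01, rad = 0.0011;
static const double pi_ = 3.14;
static const double vcell = 1000.0 * pi_ * rad * rad * Lcell;
static const double Ageo = 2.0 * pi_ * rad * rad + 2.0 * pi_ * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

// CaMK
static const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
static const double CaMKo = 0.05, KmCaM = 0.0015;

// state vector layout (V stored separately in tissue arrays; single-cell
// state vectors are c(V, S) of length NS+1)
enum {
  s_nai = 0, s_nass, s_ki, s_kss, s_cai, s_cass, s_cansr, s_cajsr,
  s_m, s_h, s_j,
  s_mL, s_hL, s_hLp,
  s_a, s_iF, s_iS, s_ap, s_iFp, s_iSp,
  s_d, s_ff, s_fs, s_fcaf, s_fcas, s_jca, s_nca, s_ffp, s_fcafp,
  s_xs1, s_xs2, s_xk1,
  s_Jrelnp, s_Jrelp, s_CaMKt,
  s_mk1,              // 7 Markov occupancies population 1: C1,C2,C3,O,I,O*,I*
  s_mk2 = s_mk1 + 7,  // population 2
  s_bA = s_mk2 + 7, s_bI, s_bR,
  NS
};

// parameter vector layout (assembled in R by build_pvec)
enum {
  p_celltype = 0,       // 0 ENDO, 1 MCELL, 2 EPI
  p_sNa, p_sNaL, p_sto, p_sCaL, p_sKr, p_sKs, p_sK1, p_sNaCa, p_sNaK, p_sKb,
  p_sKsM,               // extra I_Ks multiplier for MCELL (heterogeneity)
  p_sCaLM, p_sNaKM,     // MCELL I_CaL / INaK heterogeneity multipliers
  p_sCaLE,              // EPI I_CaL heterogeneity multiplier
  p_wmut,               // weight of Markov population 2 (mutant)
  p_gKrReg,             // transmural IKr multiplier
  p_D,                  // drug concentration (uM)
  p_hkA1, p_hlA1, p_hkI1, p_hlI1,   // hERG binding, population 1
  p_hkA2, p_hlA2, p_hkI2, p_hlI2,   // hERG binding, population 2
  p_nkA, p_nkI, p_nkR, p_nlA, p_nlI, p_nlR,  // guarded-receptor Na binding
  p_mk1p,               // 16 Markov rate params population 1 (P,Q per rate)
  p_mk2p = p_mk1p + 16, // 16 for population 2
  NPAR = p_mk2p + 16
};

// voltage table columns
enum {
  c_minf = 0, c_mer, c_hinf, c_her, c_jinf, c_jer,
  c_mLinf, c_mLer, c_hLinf, c_hLer, c_hLpinf, c_hLper,
  c_ainf, c_aer, c_iFinf, c_iFer, c_iSer, c_apinf, c_aper, c_iFper, c_iSper,
  c_AiF,
  c_dinf, c_der, c_finf, c_ffer, c_fser,
  c_fcafer, c_fcaser, c_jcaer, c_Afcaf, c_ffper, c_fcafper,
  c_xs1inf, c_xs1er, c_xs2er,
  c_xk1inf, c_xk1er, c_rk1, c_xkb,
  c_e1, c_e2, c_G1, c_G2, c_hca, c_hna, c_Knai, c_Knao,
  c_mk1r,                // 9 Markov rates pop 1: a,b,a1,b1,a2,b2,ai,bi,mu
  c_mk2r = c_mk1r + 9,
  NCOL = c_mk2r + 9
};

static const double Vmin = -150.0, Vmax = 100.0, dV = 0.02;
static const int NV = (int)((Vmax - Vmin) / dV) + 1;
static const double RATE_CAP = 25.0;  // ms^-1 cap on Markov rates at extreme V

static inline double safe_exp_ratio(double x) {
  // x / (exp(x) - 1), smooth through x = 0
  if (std::fabs(x) < 1e-7) return 1.0 - x / 2.0;
  return x / (std::exp(x) - 1.0);
}

static void markov_rates(double V, const double* P, double* out) {
  // P: 16 values (P,Q) for a,b,a1,b1,a2,b2,ai,bi ; rate = P*exp(Q*V)
  for (int k = 0; k < 8; ++k) {
    double r = P[2 * k] * std::exp(P[2 * k + 1] * V);
    if (r > RATE_CAP) r = RATE_CAP;
    out[k] = r;
  }
  // mu from microscopic reversibility of the C3-O-I loop: mu = ai*b2/bi
  double mu = (out[7] > 1e-12) ? out[6] * out[5] / out[7] : 0.0;
  if (mu > RATE_CAP) mu = RATE_CAP;
  out[8] = mu;
}

// build the voltage table for one cell type / parameter set / dt
static void build_table(std::vector<double>& tab, const double* pv, double dt) {
  tab.assign((size_t)NV * NCOL, 0.0);
  int celltype = (int)pv[p_celltype];
  for (int i = 0; i < NV; ++i) {
    double V = Vmin + i * dV;
    double* r = &tab[(size_t)i * NCOL];
    // --- Luo-Rudy INa gates ---
    double am = (std::fabs(V + 47.13) < 1e-6) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
    double bm = 0.08 * std::exp(-V / 11.0);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.135 * std::exp((80.0 + V) / -6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
      aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tj = 1.0 / (aj + bj);
    r[c_minf] = am * tm; r[c_mer] = std::exp(-dt / tm);
    r[c_hinf] = ah * th; r[c_her] = std::exp(-dt / th);
    r[c_jinf] = aj * tj; r[c_jer] = std::exp(-dt / tj);
    // --- INaL ---
    double tmO = 1.0 / (6.765 * std::exp((V + 11.64) / 34.77)
                        + 8.552 * std::exp(-(V + 77.42) / 5.955));
    r[c_mLinf] = 1.0 / (1.0 + std::exp(-(V + 42.85) / 5.264));
    r[c_mLer] = std::exp(-dt / tmO);
    double thL = 200.0;
    r[c_hLinf] = 1.0 / (1.0 + std::exp((V + 87.61) / 7.488));
    r[c_hLer] = std::exp(-dt / thL);
    r[c_hLpinf] = 1.0 / (1.0 + std::exp((V + 93.81) / 7.488));
    r[c_hLper] = std::exp(-dt / (3.0 * thL));
    // --- Ito ---
    double ass = 1.0 / (1.0 + std::exp(-(V - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(V - 18.41) / 29.38)))
                          + 3.5 / (1.0 + std::exp((V + 100.0) / 29.38)));
    r[c_ainf] = ass; r[c_aer] = std::exp(-dt / ta);
    double iss = 1.0 / (1.0 + std::exp((V + 43.94) / 5.711));
    double delta_epi = (celltype == 2)
      ? 1.0 - 0.95 / (1.0 + std::exp((V + 70.0) / 5.0)) : 1.0;
    double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(V + 100.0) / 100.0)
                                + 0.08004 * std::exp((V + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(V + 96.52) / 59.05)
                                + 1.780e-8 * std::exp((V + 114.1) / 8.079));
    tiF *= delta_epi; tiS *= delta_epi;
    r[c_iFinf] = iss;
    r[c_iFer] = std::exp(-dt / tiF);
    r[c_iSer] = std::exp(-dt / tiS);
    r[c_AiF] = 1.0 / (1.0 + std::exp((V - 213.6) / 151.2));
    r[c_apinf] = 1.0 / (1.0 + std::exp(-(V - 24.34) / 14.82));
    r[c_aper] = std::exp(-dt / ta);
    double dti_dev = 1.354 + 1e-4 / (std::exp((V - 167.4) / 15.89)
                                     + std::exp(-(V - 12.23) / 0.2154));
    double dti_rec = 1.0 - 0.5 / (1.0 + std::exp((V + 70.0) / 20.0));
    r[c_iFper] = std::exp(-dt / (dti_dev * dti_rec * tiF));
    r[c_iSper] = std::exp(-dt / (dti_dev * dti_rec * tiS));
    // --- ICaL gates ---
    r[c_dinf] = 1.0 / (1.0 + std::exp(-(V + 3.94) / 4.23));
    double td = 0.6 + 1.0 / (std::exp(-0.05 * (V + 6.0)) + std::exp(0.09 * (V + 14.0)));
    r[c_der] = std::exp(-dt / td);
    double fss = 1.0 / (1.0 + std::exp((V + 19.58) / 3.696));
    r[c_finf] = fss;
    double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(V + 20.0) / 10.0)
                              + 0.0045 * std::exp((V + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (3.5e-5 * std::exp(-(V + 5.0) / 4.0)
                                 + 3.5e-5 * std::exp((V + 5.0) / 6.0));
    r[c_ffer] = std::exp(-dt / tff);
    r[c_fser] = std::exp(-dt / tfs);
    double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(V - 4.0) / 7.0)
                                + 0.04 * std::exp((V - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (1.2e-4 * std::exp(-V / 3.0)
                                  + 1.2e-4 * std::exp(V / 7.0));
    r[c_fcafer] = std::exp(-dt / tfcaf);
    r[c_fcaser] = std::exp(-dt / tfcas);
    r[c_jcaer] = std::exp(-dt / 75.0);
    r[c_Afcaf] = 0.3 + 0.6 / (1.0 + std::exp((V - 10.0) / 10.0));
    r[c_ffper] = std::exp(-dt / (2.5 * tff));
    r[c_fcafper] = std::exp(-dt / (2.5 * tfcaf));
    // --- IKs ---
    double xs1ss = 1.0 / (1.0 + std::exp(-(V + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((V + 48.28) / 17.80)
                                 + 0.001292 * std::exp(-(V + 210.0) / 230.0));
    double txs2 = 1.0 / (0.01 * std::exp((V - 50.0) / 20.0)
                         + 0.0193 * std::exp(-(V + 66.54) / 31.0));
    r[c_xs1inf] = xs1ss;
    r[c_xs1er] = std::exp(-dt / txs1);
    r[c_xs2er] = std::exp(-dt / txs2);
    // --- IK1 ---
    double xk1ss = 1.0 / (1.0 + std::exp(-(V + 2.5538 * ko + 144.59)
                                         / (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (std::exp(-(V + 127.2) / 20.36)
                           + std::exp((V + 236.8) / 69.33));
    r[c_xk1inf] = xk1ss;
    r[c_xk1er] = std::exp(-dt / txk1);
    r[c_rk1] = 1.0 / (1.0 + std::exp((V + 105.8 - 2.6 * ko) / 9.493));
    r[c_xkb] = 1.0 / (1.0 + std::exp(-(V - 14.48) / 18.34));
    // --- electro-diffusion helpers ---
    double vfrt = V * Frdy / (Rgas * Temp);
    double vffrt = V * Frdy * Frdy / (Rgas * Temp);
    r[c_e1] = std::exp(vfrt);
    r[c_e2] = std::exp(2.0 * vfrt);
    r[c_G1] = Frdy * safe_exp_ratio(vfrt);              // = vffrt/(e1-1)
    r[c_G2] = 0.5 * Frdy * safe_exp_ratio(2.0 * vfrt);  // = vffrt/(e2-1)
    (void)vffrt;
    r[c_hca] = std::exp(0.167 * vfrt);
    r[c_hna] = std::exp(0.5224 * vfrt);
    r[c_Knai] = 9.073 * std::exp(-0.155 * vfrt / 3.0);
    r[c_Knao] = 27.78 * std::exp((1.0 + 0.155) * vfrt / 3.0);
    // --- Markov IKr rates, two parameter sets ---
    markov_rates(V, pv + p_mk1p, r + c_mk1r);
    markov_rates(V, pv + p_mk2p, r + c_mk2r);
  }
}

struct CellConsts {
  int celltype;
  double gNa, GNaL, Gto, PCa, gKr, GKs, GK1, Gncx, Pnak, GKb;
  double JrelScale, upScale;
  double D;                      // drug concentration
  double hkA[2], hlA[2], hkI[2], hlI[2];
  double nkA, nkI, nkR, nlA, nlI, nlR;
  double wmut;
};

static void decode_consts(const double* pv, CellConsts& c) {
  int ct = (int)pv[p_celltype];
  c.celltype = ct;
  c.gNa = 23.0 * pv[p_sNa];
  c.GNaL = 0.0075 * pv[p_sNaL] * (ct == 2 ? 0.6 : 1.0);
  c.Gto = 0.02 * pv[p_sto] * (ct == 0 ? 1.0 : 4.0);
  c.PCa = 0.0001 * pv[p_sCaL]
          * (ct == 1 ? 2.5 * pv[p_sCaLM]
                     : (ct == 2 ? 1.2 * pv[p_sCaLE] : 1.0));
  c.gKr = 0.046 * std::sqrt(ko / 5.4) * pv[p_sKr] * pv[p_gKrReg];
  c.GKs = 0.0034 * pv[p_sKs]
          * (ct == 2 ? 1.4 : (ct == 1 ? pv[p_sKsM] : 1.0));
  c.GK1 = 0.1908 * std::sqrt(ko / 5.4) * pv[p_sK1]
          * (ct == 1 ? 1.3 : (ct == 2 ? 1.2 : 1.0));
  c.Gncx = 0.0008 * pv[p_sNaCa] * (ct == 1 ? 1.4 : (ct == 2 ? 1.1 : 1.0));
  c.Pnak = 30.0 * pv[p_sNaK]
           * (ct == 1 ? 0.7 * pv[p_sNaKM] : (ct == 2 ? 0.9 : 1.0));
  c.GKb = 0.003 * pv[p_sKb] * (ct == 2 ? 0.6 : 1.0);
  c.JrelScale = (ct == 1 ? 1.7 : 1.0);
  c.upScale = (ct == 2 ? 1.3 : 1.0);
  c.D = pv[p_D];
  c.hkA[0] = pv[p_hkA1]; c.hlA[0] = pv[p_hlA1];
  c.hkI[0] = pv[p_hkI1]; c.hlI[0] = pv[p_hlI1];
  c.hkA[1] = pv[p_hkA2]; c.hlA[1] = pv[p_hlA2];
  c.hkI[1] = pv[p_hkI2]; c.hlI[1] = pv[p_hlI2];
  c.nkA = pv[p_nkA]; c.nkI = pv[p_nkI]; c.nkR = pv[p_nkR];
  c.nlA = pv[p_nlA]; c.nlI = pv[p_nlI]; c.nlR = pv[p_nlR];
  c.wmut = pv[p_wmut];
}

// advance one cell by dt; returns total ionic current (uA/uF) evaluated at
// entry state, and updates gating/concentration states in place.
// cur (optional, length>=5): IKr, INa, ICaL, fbKr, fbNa
static inline double cell_step(double& V, double* S, const CellConsts& cc,
                               const std::vector<double>& tab, double dt,
                               double* cur) {
  // table lookup
  double fidx = (V - Vmin) / dV;
  if (fidx < 0) fidx = 0;
  if (fidx > NV - 2) fidx = NV - 2;
  int iv = (int)fidx;
  double w = fidx - iv;
  const double* r0 = &tab[(size_t)iv * NCOL];
  const double* r1 = r0 + NCOL;
  double R[NCOL];
  for (int k = 0; k < NCOL; ++k) R[k] = r0[k] * (1.0 - w) + r1[k] * w;

  double nai = S[s_nai], nass = S[s_nass], ki = S[s_ki], kss = S[s_kss];
  double cai = S[s_cai], cass = S[s_cass], cansr = S[s_cansr], cajsr = S[s_cajsr];

  double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  double EK = (Rgas * Temp / Frdy) * std::log(ko / ki);
  double EKs = (Rgas * Temp / Frdy)
               * std::log((ko + 0.01833 * nao) / (ki + 0.01833 * nai));

  double CaMKb = CaMKo * (1.0 - S[s_CaMKt]) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + S[s_CaMKt];
  double fp = 1.0 / (1.0 + KmCaMK / CaMKa);

  // fast Na (Luo-Rudy gating) with guarded-receptor block
  double m = S[s_m], h = S[s_h], j = S[s_j];
  double bsum = S[s_bA] + S[s_bI] + S[s_bR];
  double unb = 1.0 - bsum;
  double m3hj = m * m * m * h * j;
  double INa = cc.gNa * unb * m3hj * (V - ENa);

  double INaL = cc.GNaL * (V - ENa) * S[s_mL]
                * ((1.0 - fp) * S[s_hL] + fp * S[s_hLp]);

  double AiF = R[c_AiF];
  double ito_i = AiF * S[s_iF] + (1.0 - AiF) * S[s_iS];
  double ito_ip = AiF * S[s_iFp] + (1.0 - AiF) * S[s_iSp];
  double Ito = cc.Gto * (V - EK)
               * ((1.0 - fp) * S[s_a] * ito_i + fp * S[s_ap] * ito_ip);

  // ICaL / ICaNa / ICaK
  double f = 0.6 * S[s_ff] + 0.4 * S[s_fs];
  double fpg = 0.6 * S[s_ffp] + 0.4 * S[s_fs];
  double Afcaf = R[c_Afcaf];
  double fca = Afcaf * S[s_fcaf] + (1.0 - Afcaf) * S[s_fcas];
  double fcap = Afcaf * S[s_fcafp] + (1.0 - Afcaf) * S[s_fcas];
  double e1 = R[c_e1], e2 = R[c_e2], G1 = R[c_G1], G2 = R[c_G2];
  double PhiCaL = 4.0 * G2 * (cass * e2 - 0.341 * cao);
  double PhiCaNa = G1 * (0.75 * nass * e1 - 0.75 * nao);
  double PhiCaK = G1 * (0.75 * kss * e1 - 0.75 * ko);
  double d = S[s_d], nca = S[s_nca], jca = S[s_jca];
  double gweight = (1.0 - fp) * (f * (1.0 - nca) + jca * fca * nca)
                   + fp * 1.1 * (fpg * (1.0 - nca) + jca * fcap * nca);
  double ICaL = cc.PCa * PhiCaL * d * gweight;
  double ICaNa = 0.00125 * cc.PCa * PhiCaNa * d * gweight;
  double ICaK = 3.574e-4 * cc.PCa * PhiCaK * d * gweight;

  // Markov IKr, two populations
  double Oeff = (1.0 - cc.wmut) * S[s_mk1 + 3] + cc.wmut * S[s_mk2 + 3];
  double IKr = cc.gKr * Oeff * (V - EK);

  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double IKs = cc.GKs * KsCa * S[s_xs1] * S[s_xs2] * (V - EKs);
  double IK1 = cc.GK1 * R[c_rk1] * S[s_xk1] * (V - EK);

  // INaCa (myoplasmic and subspace components)
  double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  double kcaon = 1.5e6, kcaoff = 5.0e3, KmCaAct = 150.0e-6;
  double hca = R[c_hca], hna = R[c_hna];
  double INaCa_i, INaCa_ss;
  {
    double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    double h2 = (nai * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    double h5 = nai * nai / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cai * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double ra = KmCaAct / cai;
    double allo = 1.0 / (1.0 + ra * ra);
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * cc.Gncx * allo * (JncxNa + 2.0 * JncxCa);
  }
  {
    double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    double h2 = (nass * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    double h5 = nass * nass / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cass * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double ra = KmCaAct / cass;
    double allo = 1.0 / (1.0 + ra * ra);
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * cc.Gncx * allo * (JncxNa + 2.0 * JncxCa);
  }

  // INaK
  double INaK;
  {
    double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    double Kmgatp = 1.698e-7, Hp = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
    double Knap = 224.0, Kxkur = 292.0;
    double Knai = R[c_Knai], Knao = R[c_Knao];
    double P = eP / (1.0 + Hp / Khp + nai / Knap + ki / Kxkur);
    double rni = nai / Knai, rno = nao / Knao, rki = ki / Kki, rko = ko / Kko;
    double rni3 = rni * rni * rni, rno3 = rno * rno * rno;
    double oni = 1.0 + rni, ono = 1.0 + rno, oki = 1.0 + rki, oko = 1.0 + rko;
    double oni3 = oni * oni * oni, ono3 = ono * ono * ono;
    double oki2 = oki * oki, oko2 = oko * oko;
    double den_i = oni3 + oki2 - 1.0, den_o = ono3 + oko2 - 1.0;
    double a1 = (k1p * rni3) / den_i;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = (k2m * rno3) / den_o;
    double a3 = (k3p * rko * rko) / den_o;
    double b3 = (k3m * P * Hp) / (1.0 + MgATP / Kmgatp);
    double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    double b4 = (k4m * rki * rki) / den_i;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    INaK = cc.Pnak * (JnakNa + JnakK);
  }

  double IKb = cc.GKb * R[c_xkb] * (V - EK);
  double INab = 3.75e-10 * G1 * (nai * e1 - nao);
  double ICab = 2.5e-8 * 4.0 * G2 * (cai * e2 - 0.341 * cao);
  double IpCa = 0.0005 * cai / (0.0005 + cai);

  double Iion = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1
                + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab;

  if (cur) {
    cur[0] = IKr; cur[1] = INa; cur[2] = ICaL;
    cur[3] = (1.0 - cc.wmut) * (S[s_mk1 + 5] + S[s_mk1 + 6])
             + cc.wmut * (S[s_mk2 + 5] + S[s_mk2 + 6]);
    cur[4] = bsum;
  }

  // ---- state updates ----
  // Rush-Larsen HH gates
  S[s_m] = R[c_minf] + (m - R[c_minf]) * R[c_mer];
  S[s_h] = R[c_hinf] + (h - R[c_hinf]) * R[c_her];
  S[s_j] = R[c_jinf] + (j - R[c_jinf]) * R[c_jer];
  S[s_mL] = R[c_mLinf] + (S[s_mL] - R[c_mLinf]) * R[c_mLer];
  S[s_hL] = R[c_hLinf] + (S[s_hL] - R[c_hLinf]) * R[c_hLer];
  S[s_hLp] = R[c_hLpinf] + (S[s_hLp] - R[c_hLpinf]) * R[c_hLper];
  S[s_a] = R[c_ainf] + (S[s_a] - R[c_ainf]) * R[c_aer];
  S[s_iF] = R[c_iFinf] + (S[s_iF] - R[c_iFinf]) * R[c_iFer];
  S[s_iS] = R[c_iFinf] + (S[s_iS] - R[c_iFinf]) * R[c_iSer];
  S[s_ap] = R[c_apinf] + (S[s_ap] - R[c_apinf]) * R[c_aper];
  S[s_iFp] = R[c_iFinf] + (S[s_iFp] - R[c_iFinf]) * R[c_iFper];
  S[s_iSp] = R[c_iFinf] + (S[s_iSp] - R[c_iFinf]) * R[c_iSper];
  S[s_d] = R[c_dinf] + (S[s_d] - R[c_dinf]) * R[c_der];
  S[s_ff] = R[c_finf] + (S[s_ff] - R[c_finf]) * R[c_ffer];
  S[s_fs] = R[c_finf] + (S[s_fs] - R[c_finf]) * R[c_fser];
  S[s_fcaf] = R[c_finf] + (S[s_fcaf] - R[c_finf]) * R[c_fcafer];
  S[s_fcas] = R[c_finf] + (S[s_fcas] - R[c_finf]) * R[c_fcaser];
  S[s_jca] = R[c_finf] + (S[s_jca] - R[c_finf]) * R[c_jcaer];
  S[s_ffp] = R[c_finf] + (S[s_ffp] - R[c_finf]) * R[c_ffper];
  S[s_fcafp] = R[c_finf] + (S[s_fcafp] - R[c_finf]) * R[c_fcafper];
  S[s_xs1] = R[c_xs1inf] + (S[s_xs1] - R[c_xs1inf]) * R[c_xs1er];
  S[s_xs2] = R[c_xs1inf] + (S[s_xs2] - R[c_xs1inf]) * R[c_xs2er];
  S[s_xk1] = R[c_xk1inf] + (S[s_xk1] - R[c_xk1inf]) * R[c_xk1er];
  // nca
  {
    double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double onc = 1.0 + Kmn / cass;
    double onc2 = onc * onc;
    double anca = 1.0 / (k2n / km2n + onc2 * onc2);
    S[s_nca] = nca + dt * (anca * k2n - nca * km2n);
  }
  // Markov populations (forward Euler; conservative by construction)
  for (int p = 0; p < 2; ++p) {
    double* M = S + (p == 0 ? s_mk1 : s_mk2);
    const double* mr = R + (p == 0 ? c_mk1r : c_mk2r);
    double a = mr[0], b = mr[1], a1 = mr[2], b1 = mr[3];
    double a2 = mr[4], b2 = mr[5], ai = mr[6], bi = mr[7], mu = mr[8];
    double kAD = cc.hkA[p] * cc.D, kID = cc.hkI[p] * cc.D;
    double lA = cc.hlA[p], lI = cc.hlI[p];
    double C1 = M[0], C2 = M[1], C3 = M[2], O = M[3], I = M[4];
    double Os = M[5], Is = M[6];
    double dC1 = b * C2 - a * C1;
    double dC2 = a * C1 + b1 * C3 - (b + a1) * C2;
    double dC3 = a1 * C2 + b2 * O + mu * I - (b1 + 2.0 * a2) * C3;
    double dO = a2 * C3 + ai * I + lA * Os - (b2 + bi + kAD) * O;
    double dI = a2 * C3 + bi * O + lI * Is - (mu + ai + kID) * I;
    double dOs = kAD * O - lA * Os;
    double dIs = kID * I - lI * Is;
    M[0] = C1 + dt * dC1; M[1] = C2 + dt * dC2; M[2] = C3 + dt * dC3;
    M[3] = O + dt * dO; M[4] = I + dt * dI;
    M[5] = Os + dt * dOs; M[6] = Is + dt * dIs;
  }
  // guarded-receptor Na block
  {
    double gA = m3hj;
    double gI = 1.0 - h * j;
    double gR = (1.0 - m * m * m) * h * j;
    double Dd = cc.D;
    double bA = S[s_bA], bI = S[s_bI], bR = S[s_bR];
    S[s_bA] = bA + dt * (cc.nkA * Dd * gA * unb - cc.nlA * bA);
    S[s_bI] = bI + dt * (cc.nkI * Dd * gI * unb - cc.nlI * bI);
    S[s_bR] = bR + dt * (cc.nkR * Dd * gR * unb - cc.nlR * bR);
  }
  // SR fluxes and concentrations
  {
    double bt = 4.75, a_rel = 0.5 * bt;
    double rj = 1.5 / cajsr; double rj2 = rj * rj; double rj4 = rj2 * rj2;
    double rj8 = rj4 * rj4;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + rj8);
    if (cc.celltype == 1) Jrel_inf *= 1.7;
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    S[s_Jrelnp] = Jrel_inf + (S[s_Jrelnp] - Jrel_inf) * std::exp(-dt / tau_rel);
    double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrelp_inf = a_relp * (-ICaL) / (1.0 + rj8);
    if (cc.celltype == 1) Jrelp_inf *= 1.7;
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    S[s_Jrelp] = Jrelp_inf + (S[s_Jrelp] - Jrelp_inf) * std::exp(-dt / tau_relp);
    double fJrelp = fp;
    double Jrel = (1.0 - fJrelp) * S[s_Jrelnp] + fJrelp * S[s_Jrelp];

    double Jupnp = cc.upScale * 0.004375 * cai / (cai + 0.00092);
    double Jupp = cc.upScale * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fp) * Jupnp + fp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    S[s_CaMKt] += dt * (aCaMK * CaMKb * (CaMKb + S[s_CaMKt]) - bCaMK * S[s_CaMKt]);

    S[s_nai] = nai + dt * (-(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab)
                           * Acap / (Frdy * vmyo) + JdiffNa * vss / vmyo);
    S[s_nass] = nass + dt * (-(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss)
                             - JdiffNa);
    S[s_ki] = ki + dt * (-(Ito + IKr + IKs + IK1 + IKb - 2.0 * INaK)
                         * Acap / (Frdy * vmyo) + JdiffK * vss / vmyo);
    S[s_kss] = kss + dt * (-ICaK * Acap / (Frdy * vss) - JdiffK);

    double q1 = 0.00238 + cai, q2 = 0.0005 + cai;
    double Bcai = 1.0 / (1.0 + 0.05 * (cc.celltype == 2 ? 1.3 : 1.0) * 0.00238
                         / (q1 * q1) + 0.07 * 0.0005 / (q2 * q2));
    S[s_cai] = cai + dt * (Bcai * (-(IpCa + ICab - 2.0 * INaCa_i)
                                   * Acap / (2.0 * Frdy * vmyo)
                                   - Jup * vnsr / vmyo + Jdiff * vss / vmyo));
    double q3 = 0.00087 + cass, q4 = 0.0087 + cass;
    double Bcass = 1.0 / (1.0 + 0.047 * 0.00087 / (q3 * q3)
                          + 1.124 * 0.0087 / (q4 * q4));
    S[s_cass] = cass + dt * (Bcass * (-(ICaL - 2.0 * INaCa_ss)
                                      * Acap / (2.0 * Frdy * vss)
                                      + Jrel * vjsr / vss - Jdiff));
    S[s_cansr] = cansr + dt * (Jup - Jtr * vjsr / vnsr);
    double q5 = 0.8 + cajsr;
    double Bcajsr = 1.0 / (1.0 + 10.0 * 0.8 / (q5 * q5));
    S[s_cajsr] = cajsr + dt * (Bcajsr * (Jtr - Jrel));
  }

  return Iion;
}

// [[Rcpp::export(name = ".cpp_state_length")]]
int cpp_state_length() { return NS + 1; }

// [[Rcpp::export(name = ".cpp_init_state")]]
NumericVector cpp_init_state(NumericVector pvec) {
  // quiescent initial condition: gates at steady state for V0, Markov chain
  // fully in C1, no block
  double V0 = -87.8;
  NumericVector out(NS + 1);
  out[0] = V0;
  double* S = &out[1];
  S[s_nai] = 7.268; S[s_nass] = 7.268;
  S[s_ki] = 144.65; S[s_kss] = 144.65;
  S[s_cai] = 8.6e-5; S[s_cass] = 8.49e-5;
  S[s_cansr] = 1.61; S[s_cajsr] = 1.57;
  std::vector<double> tab;
  std::vector<double> pv(pvec.begin(), pvec.end());
  build_table(tab, pv.data(), 0.005);
  int iv = (int)((V0 - Vmin) / dV);
  const double* R = &tab[(size_t)iv * NCOL];
  S[s_m] = R[c_minf]; S[s_h] = R[c_hinf]; S[s_j] = R[c_jinf];
  S[s_mL] = R[c_mLinf]; S[s_hL] = R[c_hLinf]; S[s_hLp] = R[c_hLpinf];
  S[s_a] = R[c_ainf]; S[s_iF] = R[c_iFinf]; S[s_iS] = R[c_iFinf];
  S[s_ap] = R[c_apinf]; S[s_iFp] = R[c_iFinf]; S[s_iSp] = R[c_iFinf];
  S[s_d] = R[c_dinf]; S[s_ff] = R[c_finf]; S[s_fs] = R[c_finf];
  S[s_fcaf] = R[c_finf]; S[s_fcas] = R[c_finf]; S[s_jca] = R[c_finf];
  S[s_nca] = 0.0; S[s_ffp] = R[c_finf]; S[s_fcafp] = R[c_finf];
  S[s_xs1] = R[c_xs1inf]; S[s_xs2] = R[c_xs1inf]; S[s_xk1] = R[c_xk1inf];
  S[s_Jrelnp] = 0.0; S[s_Jrelp] = 0.0; S[s_CaMKt] = 0.0;
  S[s_mk1] = 1.0; S[s_mk2] = 1.0;  // all occupancy in C1
  return out;
}

// [[Rcpp::export(name = ".cpp_markov_matrix")]]
NumericMatrix cpp_markov_matrix(double V, NumericVector rateP,
                                NumericVector binding, double D) {
  // 7x7 generator matrix A with ds/dt = A s; state order C1,C2,C3,O,I,O*,I*
  double r[9];
  markov_rates(V, &rateP[0], r);
  double a = r[0], b = r[1], a1 = r[2], b1 = r[3], a2 = r[4], b2 = r[5];
  double ai = r[6], bi = r[7], mu = r[8];
  double kAD = binding[0] * D, lA = binding[1];
  double kID = binding[2] * D, lI = binding[3];
  NumericMatrix A(7, 7);
  // C1
  A(0, 0) = -a; A(0, 1) = b;
  // C2
  A(1, 0) = a; A(1, 1) = -(b + a1); A(1, 2) = b1;
  // C3
  A(2, 1) = a1; A(2, 2) = -(b1 + 2.0 * a2); A(2, 3) = b2; A(2, 4) = mu;
  // O
  A(3, 2) = a2; A(3, 3) = -(b2 + bi + kAD); A(3, 4) = ai; A(3, 5) = lA;
  // I
  A(4, 2) = a2; A(4, 3) = bi; A(4, 4) = -(mu + ai + kID); A(4, 6) = lI;
  // O*
  A(5, 3) = kAD; A(5, 5) = -lA;
  // I*
  A(6, 4) = kID; A(6, 6) = -lI;
  return A;
}

// [[Rcpp::export(name = ".cpp_cell_run")]]
List cpp_cell_run(NumericVector state, NumericVector pvec, double dt,
                  double t_end, double stim_amp, double stim_dur,
                  double stim_period, double stim_start, double out_every) {
  std::vector<double> pv(pvec.begin(), pvec.end());
  CellConsts cc;
  decode_consts(pv.data(), cc);
  std::vector<double> tab;
  build_table(tab, pv.data(), dt);

  double V = state[0];
  std::vector<double> S(state.begin() + 1, state.end());
  long nstep = (long)std::llround(t_end / dt);
  int every = out_every > 0 ? (int)std::llround(out_every / dt) : 0;
  long nout = every > 0 ? nstep / every + 1 : 0;

  NumericVector tv(nout), Vv(nout), ikr(nout), ina(nout), ical(nout),
    fbkr(nout), fbna(nout);
  double cur[5];
  long io = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    double Istim = 0.0;
    if (stim_amp != 0.0 && t >= stim_start) {
      double tp = t - stim_start; tp -= stim_period * std::floor(tp / stim_period);
      if (tp < stim_dur) Istim = stim_amp;
    }
    if (every > 0 && k % every == 0) {
      double Iion = cell_step(V, S.data(), cc, tab, dt, cur);
      tv[io] = t; Vv[io] = V; ikr[io] = cur[0]; ina[io] = cur[1];
      ical[io] = cur[2]; fbkr[io] = cur[3]; fbna[io] = cur[4];
      ++io;
      V += dt * (-(Iion + Istim));
    } else {
      double Iion = cell_step(V, S.data(), cc, tab, dt, NULL);
      V += dt * (-(Iion + Istim));
    }
    if (!(V > -200.0 && V < 200.0) || !std::isfinite(V))
      stop("integration unstable at t = %f ms (V = %f)", t, V);
  }
  NumericVector fin(NS + 1);
  fin[0] = V;
  for (int k = 0; k < NS; ++k) fin[k + 1] = S[k];
  if (every > 0) {
    tv = head(tv, io); Vv = head(Vv, io); ikr = head(ikr, io);
    ina = head(ina, io); ical = head(ical, io);
    fbkr = head(fbkr, io); fbna = head(fbna, io);
  }
  return List::create(_["time"] = tv, _["V"] = Vv, _["IKr"] = ikr,
                      _["INa"] = ina, _["ICaL"] = ical, _["fbKr"] = fbkr,
                      _["fbNa"] = fbna, _["state"] = fin);
}

// [[Rcpp::export(name = ".cpp_cell_record")]]
NumericMatrix cpp_cell_record(NumericVector state, NumericVector pvec,
                              double dt, double t_end, double stim_amp,
                              double stim_dur, double stim_period,
                              double stim_start, double out_every) {
  // record the FULL state vector (V + S) every out_every ms; used to build
  // the reference AP cycle for phase-distribution re-entry initiation
  std::vector<double> pv(pvec.begin(), pvec.end());
  CellConsts cc;
  decode_consts(pv.data(), cc);
  std::vector<double> tab;
  build_table(tab, pv.data(), dt);
  double V = state[0];
  std::vector<double> S(state.begin() + 1, state.end());
  long nstep = (long)std::llround(t_end / dt);
  int every = (int)std::llround(out_every / dt);
  long nout = nstep / every;
  NumericMatrix out(NS + 1, nout);
  long io = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    if (k % every == 0 && io < nout) {
      out(0, io) = V;
      for (int q = 0; q < NS; ++q) out(q + 1, io) = S[q];
      ++io;
    }
    double Istim = 0.0;
    if (stim_amp != 0.0 && t >= stim_start) {
      double tp = t - stim_start; tp -= stim_period * std::floor(tp / stim_period);
      if (tp < stim_dur) Istim = stim_amp;
    }
    double Iion = cell_step(V, S.data(), cc, tab, dt, NULL);
    V += dt * (-(Iion + Istim));
    if (!(V > -200.0 && V < 200.0)) stop("integration unstable");
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_strand_run")]]
List cpp_strand_run(NumericMatrix state0, IntegerVector region,
                    NumericMatrix pmat, NumericVector gkrmult,
                    NumericVector Dhalf, double dx, double dt, double t_end,
                    NumericVector stim1_times, double stim1_dur,
                    double stim1_amp, int stim1_lo, int stim1_hi,
                    NumericVector stim2_times, double stim2_dur,
                    double stim2_amp, int stim2_lo, int stim2_hi,
                    double out_every) {
  // state0: ncell x (NS+1), column 1 = V. region: per-cell index into pmat
  // rows (0-based). pmat: nregion x NPAR. gkrmult: per-cell extra IKr factor.
  // Dhalf: ncell-1 interface diffusion coefficients (cm^2/ms).
  int ncell = state0.nrow();
  int nregion = pmat.nrow();
  std::vector<std::vector<double> > tabs(nregion);
  std::vector<CellConsts> ccs((size_t)nregion);
  for (int g = 0; g < nregion; ++g) {
    std::vector<double> pv(NPAR);
    for (int k = 0; k < NPAR; ++k) pv[k] = pmat(g, k);
    build_table(tabs[g], pv.data(), dt);
    decode_consts(pv.data(), ccs[g]);
  }
  std::vector<double> V(ncell), S((size_t)ncell * NS);
  for (int i = 0; i < ncell; ++i) {
    V[i] = state0(i, 0);
    for (int k = 0; k < NS; ++k) S[(size_t)i * NS + k] = state0(i, k + 1);
  }
  long nstep = (long)std::llround(t_end / dt);
  int every = (int)std::llround(out_every / dt);
  long nout = nstep / every + 1;
  NumericMatrix Vout(ncell, nout);
  NumericVector tout(nout);
  std::vector<double> dVdiff(ncell);
  double rdx2 = 1.0 / (dx * dx);
  long io = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    if (k % every == 0 && io < nout) {
      tout[io] = t;
      for (int i = 0; i < ncell; ++i) Vout(i, io) = V[i];
      ++io;
    }
    // diffusion (no-flux boundaries)
    for (int i = 0; i < ncell; ++i) {
      double fl = (i > 0) ? Dhalf[i - 1] * (V[i - 1] - V[i]) : 0.0;
      double fr = (i < ncell - 1) ? Dhalf[i] * (V[i + 1] - V[i]) : 0.0;
      dVdiff[i] = (fl + fr) * rdx2;
    }
    bool s1 = false, s2 = false;
    for (int q = 0; q < stim1_times.size(); ++q)
      if (t >= stim1_times[q] && t < stim1_times[q] + stim1_dur) { s1 = true; break; }
    for (int q = 0; q < stim2_times.size(); ++q)
      if (t >= stim2_times[q] && t < stim2_times[q] + stim2_dur) { s2 = true; break; }
    for (int i = 0; i < ncell; ++i) {
      int g = region[i];
      CellConsts cc = ccs[g];
      cc.gKr *= gkrmult[i];
      double Istim = 0.0;
      if (s1 && i >= stim1_lo && i <= stim1_hi) Istim += stim1_amp;
      if (s2 && i >= stim2_lo && i <= stim2_hi) Istim += stim2_amp;
      double Iion = cell_step(V[i], &S[(size_t)i * NS], cc, tabs[g], dt, NULL);
      V[i] += dt * (dVdiff[i] - Iion - Istim);
      if (!(V[i] > -200.0 && V[i] < 200.0) || !std::isfinite(V[i]))
        stop("strand integration unstable at t = %f ms, cell %d", t, i + 1);
    }
  }
  if (io < nout) { tout = head(tout, io); Vout = Vout(_, Range(0, io - 1)); }
  NumericMatrix fin(ncell, NS + 1);
  for (int i = 0; i < ncell; ++i) {
    fin(i, 0) = V[i];
    for (int k = 0; k < NS; ++k) fin(i, k + 1) = S[(size_t)i * NS + k];
  }
  return List::create(_["time"] = tout, _["V"] = Vout, _["state"] = fin);
}

// [[Rcpp::export(name = ".cpp_sheet_run")]]
List cpp_sheet_run(NumericMatrix state0, NumericVector pvec, int nx, int ny,
                   double Dcoef, double dx, double dt, double t_end,
                   NumericVector electrode, NumericMatrix probes,
                   double out_every, double snap_every) {
  // homogeneous 2D sheet; state0: (nx*ny) x (NS+1); electrode: (x,y,z) cm;
  // probes: npts x 2 of 0-based (ix, iy); pECG and probe V sampled every
  // out_every ms; V snapshots every snap_every ms (0 = none).
  int ncell = nx * ny;
  if (state0.nrow() != ncell) stop("state0 dimension mismatch");
  std::vector<double> pv(pvec.begin(), pvec.end());
  CellConsts cc;
  decode_consts(pv.data(), cc);
  std::vector<double> tab;
  build_table(tab, pv.data(), dt);
  std::vector<double> V(ncell), S((size_t)ncell * NS), Vnew(ncell);
  for (int i = 0; i < ncell; ++i) {
    V[i] = state0(i, 0);
    for (int k = 0; k < NS; ++k) S[(size_t)i * NS + k] = state0(i, k + 1);
  }
  long nstep = (long)std::llround(t_end / dt);
  int every = (int)std::llround(out_every / dt);
  long nout = nstep / every + 1;
  int nsnap_every = snap_every > 0 ? (int)std::llround(snap_every / dt) : 0;
  long nsnap = nsnap_every > 0 ? nstep / nsnap_every + 1 : 0;
  int npr = probes.nrow();
  NumericVector tout(nout), pecg(nout), vmax(nout);
  NumericMatrix vprobe(npr, nout);
  NumericMatrix snaps(nsnap > 0 ? ncell : 1, nsnap > 0 ? nsnap : 1);
  NumericVector snap_t(nsnap > 0 ? nsnap : 1);
  // precompute pECG kernel gradient of 1/r at each node
  double ex = electrode[0], ey = electrode[1], ez = electrode[2];
  std::vector<double> kx(ncell), kyv(ncell);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      double x = ix * dx, y = iy * dx;
      double rx = x - ex, ry = y - ey, rz = -ez;
      double r = std::sqrt(rx * rx + ry * ry + rz * rz);
      double r3 = r * r * r;
      // grad_source(1/r) = -(rvec)/r^3 with rvec = source - electrode
      kx[iy * nx + ix] = -rx / r3;
      kyv[iy * nx + ix] = -ry / r3;
    }
  double rdx2 = Dcoef / (dx * dx);
  long io = 0, is = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    bool rec = (k % every == 0 && io < nout);
    if (rec) {
      tout[io] = t;
      double mx = -1e9;
      for (int i = 0; i < ncell; ++i) if (V[i] > mx) mx = V[i];
      vmax[io] = mx;
      for (int q = 0; q < npr; ++q)
        vprobe(q, io) = V[(int)probes(q, 1) * nx + (int)probes(q, 0)];
      // pECG: sum over nodes of -grad V . grad(1/r) dA
      double phi = 0.0;
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          int id = iy * nx + ix;
          double gvx = ((ix < nx - 1 ? V[id + 1] : V[id])
                        - (ix > 0 ? V[id - 1] : V[id]))
                       / ((ix > 0 && ix < nx - 1) ? 2.0 * dx : dx);
          double gvy = ((iy < ny - 1 ? V[id + nx] : V[id])
                        - (iy > 0 ? V[id - nx] : V[id]))
                       / ((iy > 0 && iy < ny - 1) ? 2.0 * dx : dx);
          phi += -(gvx * kx[id] + gvy * kyv[id]);
        }
      pecg[io] = phi * dx * dx;
      ++io;
    }
    if (nsnap_every > 0 && k % nsnap_every == 0 && is < nsnap) {
      snap_t[is] = t;
      for (int i = 0; i < ncell; ++i) snaps(i, is) = V[i];
      ++is;
    }
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int id = iy * nx + ix;
        double vl = ix > 0 ? V[id - 1] : V[id];
        double vr = ix < nx - 1 ? V[id + 1] : V[id];
        double vd = iy > 0 ? V[id - nx] : V[id];
        double vu = iy < ny - 1 ? V[id + nx] : V[id];
        double lap = rdx2 * (vl + vr + vd + vu - 4.0 * V[id]);
        double Iion = cell_step(V[id], &S[(size_t)id * NS], cc, tab, dt, NULL);
        Vnew[id] = V[id] + dt * (lap - Iion);
        if (!(Vnew[id] > -200.0 && Vnew[id] < 200.0) || !std::isfinite(Vnew[id]))
          stop("sheet integration unstable at t = %f ms", t);
      }
    std::swap(V, Vnew);
  }
  if (io < nout) {
    tout = head(tout, io); pecg = head(pecg, io); vmax = head(vmax, io);
    vprobe = vprobe(_, Range(0, io - 1));
  }
  List out = List::create(_["time"] = tout, _["pecg"] = pecg,
                          _["vmax"] = vmax, _["vprobe"] = vprobe);
  if (nsnap_every > 0) {
    out["snap_t"] = head(snap_t, is);
    out["snapshots"] = snaps(_, Range(0, is - 1));
  }
  NumericMatrix fin(ncell, NS + 1);
  for (int i = 0; i < ncell; ++i) {
    fin(i, 0) = V[i];
    for (int k = 0; k < NS; ++k) fin(i, k + 1) = S[(size_t)i * NS + k];
  }
  out["state"] = fin;
  return out;
}

// [[Rcpp::export(name = ".cpp_na_clamp")]]
List cpp_na_clamp(NumericMatrix segments, int nrep, NumericVector binding,
                  double D, double dt) {
  // guarded-receptor block under a piecewise-constant voltage clamp with
  // Luo-Rudy gate dynamics. segments: nseg x 2 (V, duration ms) repeated
  // nrep times. binding: kA,kI,kR,lA,lI,lR. Returns per-repetition block
  // state at the end of each segment-1 (test pulse) and the minimum
  // unblocked availability during that segment.
  int nseg = segments.nrow();
  double kA = binding[0], kI = binding[1], kR = binding[2];
  double lA = binding[3], lI = binding[4], lR = binding[5];
  // build a tiny rate table per segment
  std::vector<double> minf(nseg), mer(nseg), hinf(nseg), her(nseg),
    jinf(nseg), jer(nseg);
  for (int sgi = 0; sgi < nseg; ++sgi) {
    double V = segments(sgi, 0);
    double am = (std::fabs(V + 47.13) < 1e-6) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
    double bm = 0.08 * std::exp(-V / 11.0);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.135 * std::exp((80.0 + V) / -6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
      aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tj = 1.0 / (aj + bj);
    minf[sgi] = am * tm; mer[sgi] = std::exp(-dt / tm);
    hinf[sgi] = ah * th; her[sgi] = std::exp(-dt / th);
    jinf[sgi] = aj * tj; jer[sgi] = std::exp(-dt / tj);
  }
  // start from steady state of segment 0 (holding)
  double m = minf[0], h = hinf[0], j = jinf[0];
  double bA = 0.0, bI = 0.0, bR = 0.0;
  NumericMatrix rec(nrep, 4);  // bA,bI,bR at end of test segment, min unblocked
  for (int rep = 0; rep < nrep; ++rep) {
    for (int sgi = 0; sgi < nseg; ++sgi) {
      long ns = (long)std::llround(segments(sgi, 1) / dt);
      double gAmax = -1.0, uPeak = 1.0;
      for (long k = 0; k < ns; ++k) {
        double m3hj = m * m * m * h * j;
        double gA = m3hj, gI = 1.0 - h * j, gR = (1.0 - m * m * m) * h * j;
        double u = 1.0 - bA - bI - bR;
        // availability at the instant of peak activation = the fraction of
        // peak current preserved (the experimentally reported measure)
        if (gA > gAmax) { gAmax = gA; uPeak = u; }
        bA += dt * (kA * D * gA * u - lA * bA);
        bI += dt * (kI * D * gI * u - lI * bI);
        bR += dt * (kR * D * gR * u - lR * bR);
        m = minf[sgi] + (m - minf[sgi]) * mer[sgi];
        h = hinf[sgi] + (h - hinf[sgi]) * her[sgi];
        j = jinf[sgi] + (j - jinf[sgi]) * jer[sgi];
      }
      if (sgi == 1 || nseg == 1) {
        rec(rep, 0) = bA; rec(rep, 1) = bI; rec(rep, 2) = bR;
        rec(rep, 3) = uPeak;
      }
    }
  }
  return List::create(_["pulse"] = rec,
                      _["final"] = NumericVector::create(bA, bI, bR, m, h, j));
}
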