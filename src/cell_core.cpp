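// Compiled core: ionic currents, L-type Ca channel Markov chain, stochastic
// spark recruitment, compartmental Ca cycling, and the cell/tissue integrator
// (operator-split monodomain with adaptive time step).
//
// State vector layout per cell (NSTATE doubles):
//   0  V                      membrane voltage (mV)
//   1-3  m, h, j              INa gates
//   4    xkr                  IKr activation
//   5-6  xs1, xs2             IKs activation
//   7-8  xtos, ytos           slow Ito gates
//   9-10 xtof, ytof           fast Ito gates
//   11-14 cb, ci, csrb, csri  Ca concentrations (uM)
//   15  spark state: nb (count, stochastic) or pb (fraction, deterministic)
//   16-25 LCC occupancies: C1,C2,O,I1,I2 (spark off), CS1,CS2,OS,IS1,IS2
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NSTATE = 26;
enum { IV = 0, IM = 1, IH = 2, IJ = 3, IXKR = 4, IXS1 = 5, IXS2 = 6,
       IXTOS = 7, IYTOS = 8, IXTOF = 9, IYTOF = 10,
       ICB = 11, ICI = 12, ICSRB = 13, ICSRI = 14, ISPK = 15, ILCC = 16 };

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------
struct Params {
  // external/internal ion concentrations and physics
  double frt, Cm, Ko, Nao, Cao, Nai, Ki;
  // ionic conductances
  double gna, gkr, gks, gk1, gtos, gtof, gnak, gnaca, ksat, eta, xkmna, xkmca;
  // LCC
  double gca, cth, ACa, a24o, a34o, tauD, vAct, sAct, kOpen, kClose;
  double r42, v42, s42, a45, r54, v54, s54, caSparkLocal;
  // spark recruitment
  double Nb, betaB, gAlpha, Ksr, nSr;
  // Ca cycling
  double gb, gri, criTh, vb, vi, vsrb, vsri, vup, cup, gdc, gdsr, gsrleak,
         gcab, wca, Bcyt, Kbuf, betaSR, csrMax;
  // tissue / integration / stimulus
  double jSpeed, xs2TauScale;
  double DV, dx, dtFast, dtSlow, dvdtFast, postStimFast, stimAmp, stimDur;
  double eadDelay, eadJump;
  // derived
  double ek, ena, eks, signak, inakbar;
};

static double getp(const NumericVector& p, const std::vector<std::string>& nm,
                   const char* key) {
  for (R_xlen_t i = 0; i < p.size(); ++i)
    if (nm[i] == key) return p[i];
  stop("parameter '%s' missing from bundle", key);
  return NA_REAL;
}

static Params parseParams(const NumericVector& p) {
  std::vector<std::string> nm = as<std::vector<std::string> >(p.names());
  Params q;
  q.frt = getp(p, nm, "frt");  q.Cm = getp(p, nm, "Cm");
  q.Ko = getp(p, nm, "Ko");    q.Nao = getp(p, nm, "Nao");
  q.Cao = getp(p, nm, "Cao");  q.Nai = getp(p, nm, "Nai");
  q.Ki = getp(p, nm, "Ki");
  q.gna = getp(p, nm, "gna");  q.gkr = getp(p, nm, "gkr");
  q.gks = getp(p, nm, "gks");  q.gk1 = getp(p, nm, "gk1");
  q.gtos = getp(p, nm, "gtos"); q.gtof = getp(p, nm, "gtof");
  q.gnak = getp(p, nm, "gnak"); q.gnaca = getp(p, nm, "gnaca");
  q.ksat = getp(p, nm, "ksat"); q.eta = getp(p, nm, "eta");
  q.xkmna = getp(p, nm, "xkmna"); q.xkmca = getp(p, nm, "xkmca");
  q.gca = getp(p, nm, "gca");  q.cth = getp(p, nm, "cth");
  q.ACa = getp(p, nm, "ACa");  q.a24o = getp(p, nm, "a24o");
  q.a34o = getp(p, nm, "a34o"); q.tauD = getp(p, nm, "tauD");
  q.vAct = getp(p, nm, "vAct"); q.sAct = getp(p, nm, "sAct");
  q.kOpen = getp(p, nm, "kOpen"); q.kClose = getp(p, nm, "kClose");
  q.r42 = getp(p, nm, "r42");  q.v42 = getp(p, nm, "v42");
  q.s42 = getp(p, nm, "s42");  q.a45 = getp(p, nm, "a45");
  q.r54 = getp(p, nm, "r54");  q.v54 = getp(p, nm, "v54");
  q.s54 = getp(p, nm, "s54");  q.caSparkLocal = getp(p, nm, "caSparkLocal");
  q.Nb = getp(p, nm, "Nb");    q.betaB = getp(p, nm, "betaB");
  q.gAlpha = getp(p, nm, "gAlpha"); q.Ksr = getp(p, nm, "Ksr");
  q.nSr = getp(p, nm, "nSr");
  q.gb = getp(p, nm, "gb");    q.gri = getp(p, nm, "gri");
  q.criTh = getp(p, nm, "criTh");
  q.vb = getp(p, nm, "vb");    q.vi = getp(p, nm, "vi");
  q.vsrb = getp(p, nm, "vsrb"); q.vsri = getp(p, nm, "vsri");
  q.vup = getp(p, nm, "vup");  q.cup = getp(p, nm, "cup");
  q.gdc = getp(p, nm, "gdc");  q.gdsr = getp(p, nm, "gdsr");
  q.gsrleak = getp(p, nm, "gsrleak"); q.gcab = getp(p, nm, "gcab");
  q.wca = getp(p, nm, "wca");  q.Bcyt = getp(p, nm, "Bcyt");
  q.Kbuf = getp(p, nm, "Kbuf"); q.betaSR = getp(p, nm, "betaSR");
  q.csrMax = getp(p, nm, "csrMax");
  q.jSpeed = getp(p, nm, "jSpeed");
  q.xs2TauScale = getp(p, nm, "xs2TauScale");
  q.DV = getp(p, nm, "DV");    q.dx = getp(p, nm, "dx");
  q.dtFast = getp(p, nm, "dtFast"); q.dtSlow = getp(p, nm, "dtSlow");
  q.dvdtFast = getp(p, nm, "dvdtFast");
  q.postStimFast = getp(p, nm, "postStimFast");
  q.stimAmp = getp(p, nm, "stimAmp"); q.stimDur = getp(p, nm, "stimDur");
  q.eadDelay = getp(p, nm, "eadDelay"); q.eadJump = getp(p, nm, "eadJump");
  // derived reversal potentials (fixed internal Na/K)
  q.ek  = (1.0 / q.frt) * std::log(q.Ko / q.Ki);
  q.ena = (1.0 / q.frt) * std::log(q.Nao / q.Nai);
  const double prnak = 0.01833;
  q.eks = (1.0 / q.frt) *
          std::log((q.Ko + prnak * q.Nao) / (q.Ki + prnak * q.Nai));
  q.signak = (std::exp(q.Nao / 67.3) - 1.0) / 7.0;
  q.inakbar = q.gnak * (q.Ko / (q.Ko + 1.5)) * (q.Nai / (q.Nai + 12.0));
  return q;
}

// ---------------------------------------------------------------------------
// Per-cell RNG: PCG32 streams keyed by (run seed, cell index)
// ---------------------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t s, uint64_t cell) {
    // splitmix64 scramble of (seed, cell) so streams are decorrelated
    uint64_t z = s + 0x9E3779B97F4A7C15ULL * (cell + 1ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    state = z ^ (z >> 31);
    inc = (2ULL * cell + 1ULL) | 1ULL;
    next(); next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() {  // (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  // binomial sample by geometric waiting-time jumps; exact, O(successes)
  int rbinom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    double log1mp = std::log1p(-p);
    int count = 0;
    double i = 0.0;
    for (;;) {
      double g = std::floor(std::log(unif()) / log1mp);
      i += g + 1.0;
      if (i > n) break;
      ++count;
    }
    return count;
  }
};

// ---------------------------------------------------------------------------
// Gate kinetics (rabbit ventricular formulations)
// ---------------------------------------------------------------------------
struct GateK { double inf, tau; };

static inline GateK gate_m(double V) {
  double x = V + 47.13;
  double am = (std::fabs(x) < 1e-6) ? 3.2 : 0.32 * x / (1.0 - std::exp(-0.1 * x));
  double bm = 0.08 * std::exp(-V / 11.0);
  GateK g; g.inf = am / (am + bm); g.tau = 1.0 / (am + bm); return g;
}
static inline void gates_hj(double V, GateK& h, GateK& j) {
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(80.0 + V) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  h.inf = ah / (ah + bh); h.tau = 1.0 / (ah + bh);
  j.inf = aj / (aj + bj); j.tau = 1.0 / (aj + bj);
}
static inline GateK gate_xkr(double V) {
  GateK g;
  g.inf = 1.0 / (1.0 + std::exp(-(V + 50.0) / 7.5));
  double a = (std::fabs(V + 7.0) < 1e-6) ? 0.00138 / 0.123
           : 0.00138 * (V + 7.0) / (1.0 - std::exp(-0.123 * (V + 7.0)));
  double b = (std::fabs(V + 10.0) < 1e-6) ? 0.00061 / 0.145
           : 0.00061 * (V + 10.0) / (std::exp(0.145 * (V + 10.0)) - 1.0);
  g.tau = 1.0 / (a + b);
  return g;
}
static inline GateK gate_xs1(double V) {
  GateK g;
  g.inf = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
  double a = (std::fabs(V + 30.0) < 1e-6) ? 7.19e-5 / 0.148
           : 7.19e-5 * (V + 30.0) / (1.0 - std::exp(-0.148 * (V + 30.0)));
  double b = (std::fabs(V + 30.0) < 1e-6) ? 1.31e-4 / 0.0687
           : 1.31e-4 * (V + 30.0) / (std::exp(0.0687 * (V + 30.0)) - 1.0);
  g.tau = 1.0 / (a + b);
  return g;
}
static inline void gates_to(double V, GateK& xtos, GateK& ytos,
                            GateK& xtof, GateK& ytof) {
  double xinf = 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0));
  double yinf = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
  xtos.inf = xinf; xtos.tau = 9.0 / (1.0 + std::exp((V + 3.0) / 15.0)) + 0.5;
  ytos.inf = yinf; ytos.tau = 3000.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 30.0;
  xtof.inf = xinf; xtof.tau = 3.5 * std::exp(-(V / 30.0) * (V / 30.0)) + 1.5;
  ytof.inf = yinf; ytof.tau = 20.0 / (1.0 + std::exp((V + 33.5) / 10.0)) + 20.0;
}

// ---------------------------------------------------------------------------
// Currents (outward positive)
// ---------------------------------------------------------------------------
static inline double fca_gate(double cb, double cth) {
  if (cb <= 0.0) return 0.0;
  double r = cth / cb;
  return 1.0 / (1.0 + r * r);
}

// GHK-like driving term for the LCC; negative (inward) below the Ca
// reversal potential.  cb in uM.
static inline double lcc_drive(double V, double cb, const Params& q) {
  double za = 2.0 * V * q.frt;
  double cbm = cb * 1e-3;  // mM
  double f = (std::fabs(za) < 1e-4) ? (1.0 - za / 2.0)
                                    : za / (std::exp(za) - 1.0);
  return (cbm * std::exp(za) - 0.341 * q.Cao) * f;
}

// NCX turnover, returned as Ca extrusion flux (uM/ms, whole cell, positive
// = Ca leaves the J cytosolic compartment); cb in uM.
static inline double ncx_extrusion(double V, double cb, const Params& q) {
  double cbm = cb * 1e-3;
  double e1 = std::exp(q.eta * V * q.frt);
  double e2 = std::exp((q.eta - 1.0) * V * q.frt);
  double na3 = q.Nai * q.Nai * q.Nai;
  double nao3 = q.Nao * q.Nao * q.Nao;
  double num = e2 * nao3 * cbm - e1 * na3 * q.Cao;
  double den = (q.xkmna * q.xkmna * q.xkmna + nao3) * (q.xkmca + q.Cao) *
               (1.0 + q.ksat * e2);
  // Ca-dependent allosteric activation of the exchanger
  double allo = cb * cb / (cb * cb + 0.09);  // Km,act = 0.3 uM
  return q.gnaca * allo * num / den;
}

struct Currents {
  double ina, ikr, iks, ik1, itos, itof, inak, inaca, ica, itot;
  double jca, jnaca;  // Ca fluxes, positive into the J cytosolic space
};

static inline Currents membrane_currents(const double* s, const Params& q) {
  Currents c;
  double V = s[IV], cb = s[ICB];
  c.ina = q.gna * s[IM] * s[IM] * s[IM] * s[IH] * s[IJ] * (V - q.ena);
  double rkr = 1.0 / (1.0 + std::exp((V + 33.0) / 22.4));
  c.ikr = q.gkr * std::sqrt(q.Ko / 5.4) * s[IXKR] * rkr * (V - q.ek);
  c.iks = q.gks * s[IXS1] * s[IXS2] * (V - q.eks);
  double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (V - q.ek - 59.215)));
  double bk1 = (0.49124 * std::exp(0.08032 * (V - q.ek + 5.476)) +
                std::exp(0.06175 * (V - q.ek - 594.31))) /
               (1.0 + std::exp(-0.5143 * (V - q.ek + 4.753)));
  c.ik1 = q.gk1 * std::sqrt(q.Ko / 5.4) * ak1 / (ak1 + bk1) * (V - q.ek);
  double rs = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
  c.itos = q.gtos * s[IXTOS] * (s[IYTOS] + 0.5 * rs) * (V - q.ek);
  c.itof = q.gtof * s[IXTOF] * s[IYTOF] * (V - q.ek);
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * q.frt) +
                       0.0365 * q.signak * std::exp(-V * q.frt));
  c.inak = q.inakbar * fnak;
  double jx = ncx_extrusion(V, cb, q);
  c.jnaca = -jx;                       // Ca entry into J space
  c.inaca = -0.5 * jx / q.wca;         // 3Na:1Ca -> net charge = half the Ca flux
  double po = s[ILCC + 2] + s[ILCC + 7];  // O + OS
  c.ica = q.gca * po * lcc_drive(V, cb, q);
  c.jca = -q.wca * c.ica;
  double icab = q.gcab * (V - 0.5 / q.frt * std::log(q.Cao / (cb * 1e-3)));
  c.itot = c.ina + c.ikr + c.iks + c.ik1 + c.itos + c.itof + c.inak +
           c.inaca + c.ica + icab;
  return c;
}

// ---------------------------------------------------------------------------
// LCC Markov generator.  States within a group: C1,C2,O,I1,I2.
// Only open channels exchange between groups (O <-> OS) at alpha_b/beta_b.
// ---------------------------------------------------------------------------
static void lcc_rates_group(double V, double ca, const Params& q,
                            double* a /* a12,a21,a23,a32,a24,a42,a34,a45,a54 */) {
  double dinf = 1.0 / (1.0 + std::exp(-(V - q.vAct) / q.sAct));
  a[0] = dinf / q.tauD;              // C1 -> C2 (voltage activation)
  a[1] = (1.0 - dinf) / q.tauD;      // C2 -> C1
  a[2] = q.kOpen;                    // C2 -> O
  a[3] = q.kClose;                   // O  -> C2
  double fca = fca_gate(ca, q.cth);
  a[4] = q.a24o + q.ACa * fca;       // C2 -> I1 (Ca-dependent inactivation)
  a[5] = q.r42 / (1.0 + std::exp((V - q.v42) / q.s42));  // I1 -> C2 recovery
  a[6] = q.a34o + q.ACa * fca;       // O  -> I1
  a[7] = q.a45;                      // I1 -> I2 (deep inactivation)
  a[8] = q.r54 / (1.0 + std::exp((V - q.v54) / q.s54));  // I2 -> I1 recovery
}

// Fill the 10x10 generator Q (Q[i][j] = rate i->j) at given V, cb, spark rates.
static void lcc_generator(double V, double cb, double alphaB, double betaB,
                          const Params& q, double Q[10][10]) {
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) Q[i][j] = 0.0;
  double aoff[9], aon[9];
  lcc_rates_group(V, cb, q, aoff);
  lcc_rates_group(V, q.caSparkLocal, q, aon);
  const int C1 = 0, C2 = 1, O = 2, I1 = 3, I2 = 4;
  for (int grp = 0; grp < 2; ++grp) {
    const double* a = (grp == 0) ? aoff : aon;
    int o = 5 * grp;
    Q[o + C1][o + C2] = a[0]; Q[o + C2][o + C1] = a[1];
    Q[o + C2][o + O]  = a[2]; Q[o + O][o + C2]  = a[3];
    Q[o + C2][o + I1] = a[4]; Q[o + I1][o + C2] = a[5];
    Q[o + O][o + I1]  = a[6];
    Q[o + I1][o + I2] = a[7]; Q[o + I2][o + I1] = a[8];
  }
  Q[O][5 + O] = alphaB;   // O -> OS, with the spark recruitment rate
  Q[5 + O][O] = betaB;    // OS -> O, with the spark extinction rate
}

// ---------------------------------------------------------------------------
// Ca fluxes (whole-cell uM/ms; positive in the direction named in the model
// topology: J -> NJ for the diffusive terms, SR -> cytosol for release,
// cytosol -> SR for uptake, extracellular -> J cytosol for JCa/JNaCa)
// ---------------------------------------------------------------------------
struct CaFlux {
  double jrb, jri, jupb, jupi, jdsr, jdc, jca, jnaca, jleakb, jleaki;
};

static inline CaFlux ca_fluxes(const double* s, double pb, double jca,
                               double jnaca, const Params& q) {
  CaFlux f;
  double cb = s[ICB], ci = s[ICI], csrb = s[ICSRB], csri = s[ICSRI];
  f.jrb = q.gb * csrb * pb;
  // NJ release: threshold-activated, zero by default (gri = 0)
  f.jri = (ci > q.criTh) ? q.gri * csri * (ci - q.criTh) : 0.0;
  double fb = q.vb / (q.vb + q.vi), fi = q.vi / (q.vb + q.vi);
  f.jupb = q.vup * fb * cb * cb / (cb * cb + q.cup * q.cup);
  f.jupi = q.vup * fi * ci * ci / (ci * ci + q.cup * q.cup);
  f.jdsr = q.gdsr * (csrb - csri);
  f.jdc = q.gdc * (cb - ci);
  f.jleakb = q.gsrleak * (csrb - cb);
  f.jleaki = q.gsrleak * (csri - ci);
  f.jca = jca;
  f.jnaca = jnaca;
  return f;
}

// instantaneous buffering: total w = c + Bcyt*c/(Kbuf+c); inverting the
// total after each step conserves Ca exactly under Euler stepping
static inline double buf_total(double c, const Params& q) {
  return c + q.Bcyt * c / (q.Kbuf + c);
}
static inline double buf_invert(double w, const Params& q) {
  double b = q.Kbuf + q.Bcyt - w;
  return 0.5 * (-b + std::sqrt(b * b + 4.0 * q.Kbuf * w));
}

// ---------------------------------------------------------------------------
// One reaction step for a single cell.  Returns dV/dt (before diffusion).
// Updates s in place.  All sub-steps read beginning-of-step values, in the
// fixed order gates -> LCC -> sparks -> Ca -> currents -> V.
// ---------------------------------------------------------------------------
static double cell_reaction_step(double* s, const Params& q, double dt,
                                 double istim, bool stochastic, Pcg32* rng,
                                 int cellIndex) {
  double V = s[IV], cb = s[ICB];
  if (!R_finite(V) || !R_finite(cb))
    stop("integration failure: non-finite voltage or Ca in cell %d", cellIndex + 1);

  // spark rates from beginning-of-step LCC openings and SR load
  double openOff = s[ILCC + 2];
  double lr = std::pow(s[ICSRB] / q.Ksr, q.nSr);
  double load = lr / (1.0 + lr);
  double alphaB = q.gAlpha * openOff * load;
  double betaB = q.betaB;

  // --- gates (Rush-Larsen, unconditionally stable)
  GateK gm = gate_m(V), gh, gj;
  gates_hj(V, gh, gj);
  GateK gxkr = gate_xkr(V), gxs1 = gate_xs1(V);
  GateK gxtos, gytos, gxtof, gytof;
  gates_to(V, gxtos, gytos, gxtof, gytof);
  // currents must see beginning-of-step gates: compute before updating
  Currents cur = membrane_currents(s, q);

  s[IM]    += (gm.inf - s[IM]) * (1.0 - std::exp(-dt / gm.tau));
  s[IH]    += (gh.inf - s[IH]) * (1.0 - std::exp(-dt / gh.tau));
  s[IJ]    += (gj.inf - s[IJ]) * (1.0 - std::exp(-dt * q.jSpeed / gj.tau));
  s[IXKR]  += (gxkr.inf - s[IXKR]) * (1.0 - std::exp(-dt / gxkr.tau));
  s[IXS1]  += (gxs1.inf - s[IXS1]) * (1.0 - std::exp(-dt / gxs1.tau));
  s[IXS2]  += (gxs1.inf - s[IXS2]) *
              (1.0 - std::exp(-dt / (q.xs2TauScale * gxs1.tau)));
  s[IXTOS] += (gxtos.inf - s[IXTOS]) * (1.0 - std::exp(-dt / gxtos.tau));
  s[IYTOS] += (gytos.inf - s[IYTOS]) * (1.0 - std::exp(-dt / gytos.tau));
  s[IXTOF] += (gxtof.inf - s[IXTOF]) * (1.0 - std::exp(-dt / gxtof.tau));
  s[IYTOF] += (gytof.inf - s[IYTOF]) * (1.0 - std::exp(-dt / gytof.tau));

  // --- LCC Markov (population fractions, explicit Euler)
  double Q[10][10];
  lcc_generator(V, cb, alphaB, betaB, q, Q);
  double y[10], dy[10];
  for (int i = 0; i < 10; ++i) { y[i] = s[ILCC + i]; dy[i] = 0.0; }
  for (int i = 0; i < 10; ++i) {
    double out = 0.0;
    for (int j = 0; j < 10; ++j) {
      if (i == j) continue;
      out += Q[i][j];
      dy[j] += Q[i][j] * y[i];
    }
    if (out * dt >= 1.0)
      stop("LCC step too large: exit probability %.3f >= 1 in cell %d; reduce dt",
           out * dt, cellIndex + 1);
    dy[i] -= out * y[i];
  }
  for (int i = 0; i < 10; ++i) s[ILCC + i] = y[i] + dt * dy[i];

  // --- sparks
  double pb;
  if (stochastic) {
    double nb = s[ISPK];
    double pUp = alphaB * dt, pDn = betaB * dt;
    if (pUp > 1.0 || pDn > 1.0)
      stop("spark rate overflow: alpha*dt or beta*dt exceeds 1; reduce dt");
    int navail = (int)std::lround(q.Nb - nb);
    int non = (int)std::lround(nb);
    int up = rng->rbinom(navail, pUp);
    int dn = rng->rbinom(non, pDn);
    pb = nb / q.Nb;  // beginning-of-step value drives the fluxes
    s[ISPK] = nb + up - dn;
  } else {
    pb = s[ISPK];
    s[ISPK] = pb + dt * (alphaB * (1.0 - pb) - betaB * pb);
    if (s[ISPK] < 0.0) s[ISPK] = 0.0;
    if (s[ISPK] > 1.0) s[ISPK] = 1.0;
  }

  // --- Ca concentrations
  CaFlux f = ca_fluxes(s, pb, cur.jca, cur.jnaca, q);
  double dcb = (f.jrb + f.jca + f.jnaca + f.jleakb - f.jupb - f.jdc) / q.vb;
  double dci = (f.jri + f.jdc + f.jleaki - f.jupi) / q.vi;
  double dcsrb = (f.jupb - f.jrb - f.jleakb - f.jdsr) / q.vsrb;
  double dcsri = (f.jupi + f.jdsr - f.jri - f.jleaki) / q.vsri;
  s[ICB]   = buf_invert(buf_total(s[ICB], q) + dt * dcb, q);
  s[ICI]   = buf_invert(buf_total(s[ICI], q) + dt * dci, q);
  s[ICSRB] += dt * q.betaSR * dcsrb;
  s[ICSRI] += dt * q.betaSR * dcsri;
  if (s[ICB] < 0.0 || s[ICI] < 0.0 || s[ICSRB] < 0.0 || s[ICSRI] < 0.0)
    stop("Ca concentration went negative in cell %d: reduce dt", cellIndex + 1);

  // --- voltage
  double dvdt = -(cur.itot - istim) / q.Cm;
  s[IV] = V + dt * dvdt;
  return dvdt;
}

// ---------------------------------------------------------------------------
// Online per-beat APD detector (mirrors the analysis-module conventions:
// upstroke and APD at the fixed -40 mV crossing, APD90 from the per-beat
// rest/peak, linear interpolation of crossings, capping at CL).
// ---------------------------------------------------------------------------
struct BeatDetector {
  double vc;           // fixed threshold (-40 mV)
  double eadDelay, eadJump;
  // per-beat state
  double tStim, cl, rest, peak, tPeak, tUp, tDown40, tDown90, vminSince;
  bool haveUp, ead;
  double prevV, prevT;
  double lastDown40;   // from previous beat, for DI
  void resetRun() {
    lastDown40 = NA_REAL;
    prevV = NA_REAL; prevT = NA_REAL;
    haveUp = false;
  }
  void startBeat(double t, double cl_, double v) {
    tStim = t; cl = cl_; rest = v; peak = v; tPeak = t;
    tUp = NA_REAL; tDown40 = NA_REAL; tDown90 = NA_REAL;
    vminSince = 1e9; haveUp = false; ead = false;
  }
  static double interp(double t0, double v0, double t1, double v1, double lvl) {
    if (v1 == v0) return t1;
    return t0 + (lvl - v0) * (t1 - t0) / (v1 - v0);
  }
  void observe(double t, double v) {
    if (R_finite(prevT)) {
      if (!haveUp) {
        if (prevV < vc && v >= vc && t > tStim) {
          tUp = interp(prevT, prevV, t, v, vc);
          haveUp = true;
        }
      } else {
        if (v > peak) { peak = v; tPeak = t; }
        if (!R_finite(tDown40) && prevV >= vc && v < vc)
          tDown40 = interp(prevT, prevV, t, v, vc);
        double lvl90 = rest + 0.1 * (peak - rest);
        if (!R_finite(tDown90) && prevV >= lvl90 && v < lvl90 && t > tPeak)
          tDown90 = interp(prevT, prevV, t, v, lvl90);
        // EAD: secondary depolarization >= eadJump above a local minimum,
        // above the -40 mV line, in the repolarization phase
        if (t > tUp + eadDelay && v > vc && !R_finite(tDown40)) {
          if (v < vminSince) vminSince = v;
          else if (v > vminSince + eadJump) ead = true;
        }
      }
    }
    prevV = v; prevT = t;
  }
  // close the beat at the next stimulus (or end of run); fills one record
  void finishBeat(double* rec) {
    double apd40, apd90;
    bool capped = false;
    double di = NA_REAL;
    if (!haveUp) {
      apd40 = NA_REAL; apd90 = NA_REAL;
    } else {
      if (R_finite(lastDown40)) di = tUp - lastDown40;
      if (R_finite(tDown40)) apd40 = tDown40 - tUp;
      else { apd40 = cl; capped = true; }
      if (R_finite(tDown90)) apd90 = tDown90 - tUp;
      else { apd90 = cl; capped = true; }
      lastDown40 = R_finite(tDown40) ? tDown40 : (tUp + cl);
    }
    rec[0] = tStim; rec[1] = cl; rec[2] = haveUp ? tUp : NA_REAL;
    rec[3] = apd90; rec[4] = apd40; rec[5] = di;
    rec[6] = peak; rec[7] = rest; rec[8] = capped ? 1.0 : 0.0;
    rec[9] = ead ? 1.0 : 0.0;
  }
};

// ---------------------------------------------------------------------------
// The engine: nx*ny grid (1x1 = single cell), operator splitting, global
// adaptive dt, per-beat records for selected cells, optional trace and
// voltage snapshots.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector params, NumericMatrix state0, int nx, int ny,
                NumericVector stim_times, NumericVector cls,
                NumericVector stim_mask, bool stochastic, double seed,
                IntegerVector record_cells, double trace_dt,
                NumericVector snapshot_times, double t_end,
                bool record_maps) {
  Params q = parseParams(params);
  int ncell = nx * ny;
  if (state0.nrow() != NSTATE)
    stop("state matrix must have %d rows", NSTATE);
  if (state0.ncol() != ncell && state0.ncol() != 1)
    stop("state matrix must have 1 or nx*ny columns");
  if ((int)stim_mask.size() != ncell)
    stop("stim_mask length must equal nx*ny");
  int nbeat = stim_times.size();
  if ((int)cls.size() != nbeat) stop("cls must match stim_times");
  // diffusion stability check (explicit 5-point scheme)
  double ndim = (nx > 1) + (ny > 1);
  if (ncell > 1 && q.dtSlow > q.dx * q.dx / (2.0 * ndim * q.DV) + 1e-12)
    stop("diffusion stability bound violated: dtSlow > dx^2/(%g*DV)", 2.0 * ndim);

  std::vector<double> S((size_t)NSTATE * ncell);
  for (int c = 0; c < ncell; ++c) {
    int src = (state0.ncol() == 1) ? 0 : c;
    for (int k = 0; k < NSTATE; ++k) S[(size_t)c * NSTATE + k] = state0(k, src);
  }
  std::vector<Pcg32> rng(ncell);
  for (int c = 0; c < ncell; ++c) rng[c].seed((uint64_t)seed, (uint64_t)c);

  int nrec = record_cells.size();
  std::vector<BeatDetector> det(nrec);
  for (int r = 0; r < nrec; ++r) {
    det[r].vc = -40.0; det[r].eadDelay = q.eadDelay; det[r].eadJump = q.eadJump;
    det[r].resetRun();
  }
  // per-beat output for recorded cells: 10 fields per record
  std::vector<double> beats((size_t)nrec * nbeat * 10, NA_REAL);
  // whole-grid activation/repolarization maps per beat
  std::vector<double> actMap, repMap;
  std::vector<double> prevVall;
  if (record_maps) {
    actMap.assign((size_t)nbeat * ncell, NA_REAL);
    repMap.assign((size_t)nbeat * ncell, NA_REAL);
    prevVall.assign(ncell, NA_REAL);
  }
  // trace buffers
  std::vector<double> trT, trV, trCb, trCsrb, trPb, trCi, trCsri;
  std::vector<double> trIca, trIkr, trIks, trInaca, trOpen, trAvail;
  double nextTrace = 0.0;
  // snapshots
  int nsnap = snapshot_times.size();
  NumericMatrix snaps(nsnap > 0 ? ncell : 0, nsnap);
  int snapIdx = 0;

  std::vector<double> lap(ncell, 0.0);
  double t = 0.0;
  int beatIdx = -1;            // index of current beat window
  double lastStim = -1e9;
  double maxAbsDvdt = 0.0;
  double ddx2 = q.DV / (q.dx * q.dx);

  auto cellV = [&](int c) { return S[(size_t)c * NSTATE + IV]; };

  while (t < t_end - 1e-9) {
    // start new beat windows
    while (beatIdx + 1 < nbeat && t >= stim_times[beatIdx + 1] - 1e-9) {
      // close previous beat for recorded cells
      if (beatIdx >= 0)
        for (int r = 0; r < nrec; ++r)
          det[r].finishBeat(&beats[((size_t)r * nbeat + beatIdx) * 10]);
      ++beatIdx;
      lastStim = stim_times[beatIdx];
      for (int r = 0; r < nrec; ++r)
        det[r].startBeat(lastStim, cls[beatIdx], cellV(record_cells[r]));
      if (record_maps)
        for (int c = 0; c < ncell; ++c) prevVall[c] = cellV(c);
    }
    // adaptive dt
    bool fast = (t - lastStim < q.stimDur + q.postStimFast) ||
                (maxAbsDvdt > q.dvdtFast);
    double dt = fast ? q.dtFast : q.dtSlow;
    // land exactly on events
    double nextEvent = t_end;
    if (beatIdx + 1 < nbeat) nextEvent = std::min(nextEvent, stim_times[beatIdx + 1]);
    if (beatIdx >= 0 && t < stim_times[beatIdx] + q.stimDur)
      nextEvent = std::min(nextEvent, stim_times[beatIdx] + q.stimDur);
    if (snapIdx < nsnap) nextEvent = std::min(nextEvent, snapshot_times[snapIdx]);
    if (t + dt > nextEvent) dt = nextEvent - t;
    if (dt < 1e-12) { t = nextEvent; continue; }

    bool stimOn = beatIdx >= 0 && t >= stim_times[beatIdx] - 1e-9 &&
                  t < stim_times[beatIdx] + q.stimDur - 1e-9;

    // reaction substep
    double mx = 0.0;
    for (int c = 0; c < ncell; ++c) {
      double istim = (stimOn && stim_mask[c] > 0.0) ? q.stimAmp : 0.0;
      double dvdt = cell_reaction_step(&S[(size_t)c * NSTATE], q, dt, istim,
                                       stochastic, &rng[c], c);
      double a = std::fabs(dvdt);
      if (a > mx) mx = a;
    }
    // diffusion substep (5-point Laplacian, no-flux via mirrored ghosts)
    if (ncell > 1) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix) {
          int c = iy * nx + ix;
          double v = cellV(c);
          double vl = (ix > 0) ? cellV(c - 1) : v;
          double vr = (ix < nx - 1) ? cellV(c + 1) : v;
          double vd = (iy > 0) ? cellV(c - nx) : v;
          double vu = (iy < ny - 1) ? cellV(c + nx) : v;
          lap[c] = (vl + vr - 2.0 * v) + (vu + vd - 2.0 * v);
        }
      }
      for (int c = 0; c < ncell; ++c)
        S[(size_t)c * NSTATE + IV] += dt * ddx2 * lap[c];
    }
    maxAbsDvdt = mx;
    t += dt;

    // observations
    for (int r = 0; r < nrec; ++r) {
      int c = record_cells[r];
      if (beatIdx >= 0) det[r].observe(t, cellV(c));
    }
    if (record_maps && beatIdx >= 0) {
      for (int c = 0; c < ncell; ++c) {
        double v = cellV(c);
        size_t k = (size_t)beatIdx * ncell + c;
        if (!R_finite(actMap[k]) && prevVall[c] < -40.0 && v >= -40.0)
          actMap[k] = BeatDetector::interp(t - dt, prevVall[c], t, v, -40.0);
        if (R_finite(actMap[k]) && !R_finite(repMap[k]) &&
            prevVall[c] >= -40.0 && v < -40.0)
          repMap[k] = BeatDetector::interp(t - dt, prevVall[c], t, v, -40.0);
        prevVall[c] = v;
      }
    }
    if (trace_dt > 0.0 && t >= nextTrace - 1e-9) {
      int c = nrec > 0 ? record_cells[0] : 0;
      const double* s = &S[(size_t)c * NSTATE];
      trT.push_back(t); trV.push_back(s[IV]);
      trCb.push_back(s[ICB]); trCi.push_back(s[ICI]);
      trCsrb.push_back(s[ICSRB]); trCsri.push_back(s[ICSRI]);
      trPb.push_back(stochastic ? s[ISPK] / q.Nb : s[ISPK]);
      Currents cc = membrane_currents(s, q);
      trIca.push_back(cc.ica); trIkr.push_back(cc.ikr);
      trIks.push_back(cc.iks); trInaca.push_back(cc.inaca);
      trOpen.push_back(s[ILCC + 2] + s[ILCC + 7]);
      trAvail.push_back(1.0 - s[ILCC + 3] - s[ILCC + 4] - s[ILCC + 8] -
                        s[ILCC + 9]);
      nextTrace += trace_dt;
    }
    while (snapIdx < nsnap && t >= snapshot_times[snapIdx] - 1e-9) {
      for (int c = 0; c < ncell; ++c) snaps(c, snapIdx) = cellV(c);
      ++snapIdx;
    }
  }
  if (beatIdx >= 0)
    for (int r = 0; r < nrec; ++r)
      det[r].finishBeat(&beats[((size_t)r * nbeat + beatIdx) * 10]);

  // assemble outputs
  List beatList(nrec);
  for (int r = 0; r < nrec; ++r) {
    NumericVector tStim(nbeat), cl(nbeat), tUp(nbeat), apd90(nbeat),
        apd40(nbeat), di40(nbeat), peak(nbeat), rest(nbeat);
    LogicalVector capped(nbeat), ead(nbeat);
    for (int b = 0; b < nbeat; ++b) {
      const double* rc = &beats[((size_t)r * nbeat + b) * 10];
      tStim[b] = rc[0]; cl[b] = rc[1]; tUp[b] = rc[2]; apd90[b] = rc[3];
      apd40[b] = rc[4]; di40[b] = rc[5]; peak[b] = rc[6]; rest[b] = rc[7];
      capped[b] = R_finite(rc[8]) ? rc[8] > 0.5 : NA_LOGICAL;
      ead[b] = R_finite(rc[9]) ? rc[9] > 0.5 : NA_LOGICAL;
    }
    beatList[r] = DataFrame::create(
        _["beat"] = seq_len(nbeat), _["tStim"] = tStim, _["cl"] = cl,
        _["tUp"] = tUp, _["apd90"] = apd90, _["apd40"] = apd40,
        _["di40"] = di40, _["peak"] = peak, _["rest"] = rest,
        _["capped"] = capped, _["ead"] = ead);
  }
  NumericMatrix finalS(NSTATE, ncell);
  for (int c = 0; c < ncell; ++c)
    for (int k = 0; k < NSTATE; ++k) finalS(k, c) = S[(size_t)c * NSTATE + k];

  List out = List::create(
      _["beats"] = beatList, _["finalState"] = finalS,
      _["snapshots"] = snaps, _["snapshotTimes"] = snapshot_times);
  if (trace_dt > 0.0) {
    out["trace"] = DataFrame::create(
        _["t"] = wrap(trT), _["V"] = wrap(trV), _["cb"] = wrap(trCb),
        _["ci"] = wrap(trCi), _["csrb"] = wrap(trCsrb),
        _["csri"] = wrap(trCsri), _["pb"] = wrap(trPb),
        _["ica"] = wrap(trIca), _["ikr"] = wrap(trIkr),
        _["iks"] = wrap(trIks), _["inaca"] = wrap(trInaca),
        _["lccOpen"] = wrap(trOpen), _["lccAvail"] = wrap(trAvail));
  }
  if (record_maps) {
    NumericMatrix am(nbeat, ncell), rm(nbeat, ncell);
    for (int b = 0; b < nbeat; ++b)
      for (int c = 0; c < ncell; ++c) {
        am(b, c) = actMap[(size_t)b * ncell + c];
        rm(b, c) = repMap[(size_t)b * ncell + c];
      }
    out["activation"] = am;
    out["repolarization"] = rm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fine-grained exports for the module-level operations
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fca_cpp")]]
double fca_cpp(double cb, double cth) { return fca_gate(cb, cth); }

// [[Rcpp::export(name = ".lcc_inact_rates_cpp")]]
NumericVector lcc_inact_rates_cpp(double cb, NumericVector params, bool sparkOn) {
  Params q = parseParams(params);
  double fca = sparkOn ? fca_gate(q.caSparkLocal, q.cth) : fca_gate(cb, q.cth);
  return NumericVector::create(_["a24"] = q.a24o + q.ACa * fca,
                               _["a34"] = q.a34o + q.ACa * fca);
}

// [[Rcpp::export(name = ".lcc_generator_cpp")]]
NumericMatrix lcc_generator_cpp(double V, double cb, double alphaB,
                                double betaB, NumericVector params) {
  Params q = parseParams(params);
  double Q[10][10];
  lcc_generator(V, cb, alphaB, betaB, q, Q);
  NumericMatrix M(10, 10);
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) M(i, j) = Q[i][j];
  CharacterVector st = CharacterVector::create("C1", "C2", "O", "I1", "I2",
                                               "CS1", "CS2", "OS", "IS1", "IS2");
  M.attr("dimnames") = List::create(st, st);
  return M;
}

// [[Rcpp::export(name = ".membrane_currents_cpp")]]
NumericVector membrane_currents_cpp(NumericVector state, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Params q = parseParams(params);
  Currents c = membrane_currents(REAL(state), q);
  return NumericVector::create(
      _["ina"] = c.ina, _["ikr"] = c.ikr, _["iks"] = c.iks, _["ik1"] = c.ik1,
      _["itos"] = c.itos, _["itof"] = c.itof, _["inak"] = c.inak,
      _["inaca"] = c.inaca, _["ica"] = c.ica, _["itot"] = c.itot,
      _["jca"] = c.jca, _["jnaca"] = c.jnaca);
}

// [[Rcpp::export(name = ".ca_fluxes_cpp")]]
NumericVector ca_fluxes_cpp(NumericVector state, double pb, double jca,
                            double jnaca, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Params q = parseParams(params);
  CaFlux f = ca_fluxes(REAL(state), pb, jca, jnaca, q);
  return NumericVector::create(
      _["Jrb"] = f.jrb, _["Jri"] = f.jri, _["Jupb"] = f.jupb,
      _["Jupi"] = f.jupi, _["Jdsr"] = f.jdsr, _["Jdc"] = f.jdc,
      _["JCa"] = f.jca, _["JNaCa"] = f.jnaca,
      _["Jleakb"] = f.jleakb, _["Jleaki"] = f.jleaki);
}

// [[Rcpp::export(name = ".cell_step_cpp")]]
List cell_step_cpp(NumericVector state, NumericVector params, double dt,
                   double istim, bool stochastic, double seed) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Params q = parseParams(params);
  NumericVector s = clone(state);
  Pcg32 rng; rng.seed((uint64_t)seed, 0);
  double dvdt = cell_reaction_step(REAL(s), q, dt, istim, stochastic, &rng, 0);
  return List::create(_["state"] = s, _["dvdt"] = dvdt);
}

// [[Rcpp::export(name = ".gate_steady_cpp")]]
NumericVector gate_steady_cpp(double V) {
  GateK gm = gate_m(V), gh, gj;
  gates_hj(V, gh, gj);
  GateK gxkr = gate_xkr(V), gxs1 = gate_xs1(V);
  GateK gxtos, gytos, gxtof, gytof;
  gates_to(V, gxtos, gytos, gxtof, gytof);
  return NumericVector::create(
      _["m"] = gm.inf, _["h"] = gh.inf, _["j"] = gj.inf, _["xkr"] = gxkr.inf,
      _["xs1"] = gxs1.inf, _["xs2"] = gxs1.inf, _["xtos"] = gxtos.inf,
      _["ytos"] = gytos.inf, _["xtof"] = gxtof.inf, _["ytof"] = gytof.inf);
}
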