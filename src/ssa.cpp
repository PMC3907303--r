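// Exact stochastic (Gillespie direct-method) counterpart of the kinetic
// model.  Concentrations map to copy numbers through the system size omega:
// zero-order syntheses scale by omega, bimolecular rate constants by
// 1/omega, and the saturating (Michaelian / Goldbeter-Koshland) processes
// are lumped channels whose propensity is omega times the deterministic rate
// law evaluated at count/omega.  Parameter and species orders match
// R/parameters.R and R/state.R.

#include <Rcpp.h>
using namespace Rcpp;

enum {
  i_kAA1NFKB, i_kAA2NFKB, i_kAA3NFKB, i_KIPTEN, i_VDNFKB,
  i_KANFKB, i_KINFKB, i_NFKBT,
  i_VSLIN28, i_KA1NF, i_kDLIN28,
  i_VSLET7, i_KILET7, i_k1, i_k2, i_k3, i_k4, i_k5, i_k6, i_kDLET7,
  i_VS1MIL6, i_VS2MIL6, i_KA2NF, i_kDMIL6, i_kDILLET, i_kSIL6, i_kDIL6,
  i_VSMRAS, i_kDMRAS, i_kDRASLET, i_kSRAS, i_kDRAS,
  i_VSSTAT, i_KAIL6, i_kDSTAT, i_VSMIR21, i_KASTAT, i_kDMIR21,
  i_VSMPTEN, i_kDMPTEN, i_kDMIRMP, i_kSPTEN, i_kDPTEN,
  i_VSCERNA, i_k7, i_k8, i_kDCERNA, i_kDCELET7,
  i_VSMPTEN1, i_k9, i_k10, i_kDMPTEN1, i_kDMIRMP1,
  i_Src, NPAR
};

enum {
  s_NFKB, s_Lin28, s_Let7, s_mIL6, s_mIL6Let7, s_IL6, s_mRas, s_mRasLet7,
  s_Ras, s_STAT3, s_miR21, s_mPTEN, s_miRmpten, s_PTEN,
  s_ceRNA, s_ceRNAlet7, s_mPTEN1, s_miRmpten1, NSPEC
};

#define NCHAN 42
#define MAXCHG 3

// stoichiometry: per channel up to MAXCHG (species, delta) pairs, -1 = unused
static const int STOICH[NCHAN][MAXCHG][2] = {
  /* 0 NFKB activation   */ {{s_NFKB, +1}, {-1, 0}, {-1, 0}},
  /* 1 NFKB inactivation */ {{s_NFKB, -1}, {-1, 0}, {-1, 0}},
  /* 2 Lin28 synthesis   */ {{s_Lin28, +1}, {-1, 0}, {-1, 0}},
  /* 3 Lin28 degradation */ {{s_Lin28, -1}, {-1, 0}, {-1, 0}},
  /* 4 Let7 synthesis    */ {{s_Let7, +1}, {-1, 0}, {-1, 0}},
  /* 5 Let7 degradation  */ {{s_Let7, -1}, {-1, 0}, {-1, 0}},
  /* 6 Let7+mIL6 binding */ {{s_Let7, -1}, {s_mIL6, -1}, {s_mIL6Let7, +1}},
  /* 7 complex dissoc.   */ {{s_Let7, +1}, {s_mIL6, +1}, {s_mIL6Let7, -1}},
  /* 8 mIL6 basal syn.   */ {{s_mIL6, +1}, {-1, 0}, {-1, 0}},
  /* 9 mIL6 NFKB syn.    */ {{s_mIL6, +1}, {-1, 0}, {-1, 0}},
  /*10 mIL6 degradation  */ {{s_mIL6, -1}, {-1, 0}, {-1, 0}},
  /*11 mIL6Let7 degr.    */ {{s_mIL6Let7, -1}, {-1, 0}, {-1, 0}},
  /*12 IL6 synthesis     */ {{s_IL6, +1}, {-1, 0}, {-1, 0}},
  /*13 IL6 degradation   */ {{s_IL6, -1}, {-1, 0}, {-1, 0}},
  /*14 mRas synthesis    */ {{s_mRas, +1}, {-1, 0}, {-1, 0}},
  /*15 Let7+mRas binding */ {{s_Let7, -1}, {s_mRas, -1}, {s_mRasLet7, +1}},
  /*16 complex dissoc.   */ {{s_Let7, +1}, {s_mRas, +1}, {s_mRasLet7, -1}},
  /*17 mRas degradation  */ {{s_mRas, -1}, {-1, 0}, {-1, 0}},
  /*18 mRasLet7 degr.    */ {{s_mRasLet7, -1}, {-1, 0}, {-1, 0}},
  /*19 Ras synthesis     */ {{s_Ras, +1}, {-1, 0}, {-1, 0}},
  /*20 Ras degradation   */ {{s_Ras, -1}, {-1, 0}, {-1, 0}},
  /*21 STAT3 synthesis   */ {{s_STAT3, +1}, {-1, 0}, {-1, 0}},
  /*22 STAT3 degradation */ {{s_STAT3, -1}, {-1, 0}, {-1, 0}},
  /*23 miR21 synthesis   */ {{s_miR21, +1}, {-1, 0}, {-1, 0}},
  /*24 miR21 degradation */ {{s_miR21, -1}, {-1, 0}, {-1, 0}},
  /*25 miR21+mPTEN bind  */ {{s_miR21, -1}, {s_mPTEN, -1}, {s_miRmpten, +1}},
  /*26 complex dissoc.   */ {{s_miR21, +1}, {s_mPTEN, +1}, {s_miRmpten, -1}},
  /*27 mPTEN synthesis   */ {{s_mPTEN, +1}, {-1, 0}, {-1, 0}},
  /*28 mPTEN degradation */ {{s_mPTEN, -1}, {-1, 0}, {-1, 0}},
  /*29 miRmpten degr.    */ {{s_miRmpten, -1}, {-1, 0}, {-1, 0}},
  /*30 PTEN synthesis    */ {{s_PTEN, +1}, {-1, 0}, {-1, 0}},
  /*31 PTEN degradation  */ {{s_PTEN, -1}, {-1, 0}, {-1, 0}},
  /*32 ceRNA synthesis   */ {{s_ceRNA, +1}, {-1, 0}, {-1, 0}},
  /*33 Let7+ceRNA bind   */ {{s_Let7, -1}, {s_ceRNA, -1}, {s_ceRNAlet7, +1}},
  /*34 complex dissoc.   */ {{s_Let7, +1}, {s_ceRNA, +1}, {s_ceRNAlet7, -1}},
  /*35 ceRNA degradation */ {{s_ceRNA, -1}, {-1, 0}, {-1, 0}},
  /*36 ceRNAlet7 degr.   */ {{s_ceRNAlet7, -1}, {-1, 0}, {-1, 0}},
  /*37 mPTEN1 synthesis  */ {{s_mPTEN1, +1}, {-1, 0}, {-1, 0}},
  /*38 miR21+mPTEN1 bind */ {{s_miR21, -1}, {s_mPTEN1, -1}, {s_miRmpten1, +1}},
  /*39 complex dissoc.   */ {{s_miR21, +1}, {s_mPTEN1, +1}, {s_miRmpten1, -1}},
  /*40 mPTEN1 degr.      */ {{s_mPTEN1, -1}, {-1, 0}, {-1, 0}},
  /*41 miRmpten1 degr.   */ {{s_miRmpten1, -1}, {-1, 0}, {-1, 0}}
};

static double propensity(int c, const double *n, const double *p,
                         double omega) {
  switch (c) {
  case 0: {
    double inact_pool = p[i_NFKBT] - n[s_NFKB] / omega;
    if (inact_pool <= 0) return 0.0;
    double drive = (p[i_kAA1NFKB] * p[i_Src] +
                    p[i_kAA2NFKB] * n[s_IL6] / omega +
                    p[i_kAA3NFKB] * n[s_Ras] / omega) *
      p[i_KIPTEN] / (p[i_KIPTEN] + n[s_PTEN] / omega);
    return omega * drive * inact_pool / (p[i_KANFKB] + inact_pool);
  }
  case 1: return omega * p[i_VDNFKB] * (n[s_NFKB] / omega) /
      (p[i_KINFKB] + n[s_NFKB] / omega);
  case 2: return omega * p[i_VSLIN28] * (n[s_NFKB] / omega) /
      (p[i_KA1NF] + n[s_NFKB] / omega);
  case 3: return p[i_kDLIN28] * n[s_Lin28];
  case 4: return omega * p[i_VSLET7] * p[i_KILET7] /
      (p[i_KILET7] + n[s_Lin28] / omega);
  case 5: return p[i_kDLET7] * n[s_Let7];
  case 6: return p[i_k1] / omega * n[s_Let7] * n[s_mIL6];
  case 7: return p[i_k2] * n[s_mIL6Let7];
  case 8: return omega * p[i_VS1MIL6];
  case 9: return omega * p[i_VS2MIL6] * (n[s_NFKB] / omega) /
      (p[i_KA2NF] + n[s_NFKB] / omega);
  case 10: return p[i_kDMIL6] * n[s_mIL6];
  case 11: return p[i_kDILLET] * n[s_mIL6Let7];
  case 12: return p[i_kSIL6] * n[s_mIL6];
  case 13: return p[i_kDIL6] * n[s_IL6];
  case 14: return omega * p[i_VSMRAS];
  case 15: return p[i_k3] / omega * n[s_Let7] * n[s_mRas];
  case 16: return p[i_k4] * n[s_mRasLet7];
  case 17: return p[i_kDMRAS] * n[s_mRas];
  case 18: return p[i_kDRASLET] * n[s_mRasLet7];
  case 19: return p[i_kSRAS] * n[s_mRas];
  case 20: return p[i_kDRAS] * n[s_Ras];
  case 21: return omega * p[i_VSSTAT] * (n[s_IL6] / omega) /
      (p[i_KAIL6] + n[s_IL6] / omega);
  case 22: return p[i_kDSTAT] * n[s_STAT3];
  case 23: return omega * p[i_VSMIR21] * (n[s_STAT3] / omega) /
      (p[i_KASTAT] + n[s_STAT3] / omega);
  case 24: return p[i_kDMIR21] * n[s_miR21];
  case 25: return p[i_k5] / omega * n[s_miR21] * n[s_mPTEN];
  case 26: return p[i_k6] * n[s_miRmpten];
  case 27: return omega * p[i_VSMPTEN];
  case 28: return p[i_kDMPTEN] * n[s_mPTEN];
  case 29: return p[i_kDMIRMP] * n[s_miRmpten];
  case 30: return p[i_kSPTEN] * n[s_mPTEN];
  case 31: return p[i_kDPTEN] * n[s_PTEN];
  case 32: return omega * p[i_VSCERNA];
  case 33: return p[i_k7] / omega * n[s_Let7] * n[s_ceRNA];
  case 34: return p[i_k8] * n[s_ceRNAlet7];
  case 35: return p[i_kDCERNA] * n[s_ceRNA];
  case 36: return p[i_kDCELET7] * n[s_ceRNAlet7];
  case 37: return omega * p[i_VSMPTEN1];
  case 38: return p[i_k9] / omega * n[s_miR21] * n[s_mPTEN1];
  case 39: return p[i_k10] * n[s_miRmpten1];
  case 40: return p[i_kDMPTEN1] * n[s_mPTEN1];
  case 41: return p[i_kDMIRMP1] * n[s_miRmpten1];
  }
  return 0.0;
}

// channels whose propensity depends on each species (for partial updates)
static void buildDeps(std::vector< std::vector<int> > &dep) {
  dep.assign(NSPEC, std::vector<int>());
  const int depends[NCHAN][4] = {
    {s_NFKB, s_IL6, s_Ras, s_PTEN}, {s_NFKB, -1, -1, -1},
    {s_NFKB, -1, -1, -1}, {s_Lin28, -1, -1, -1},
    {s_Lin28, -1, -1, -1}, {s_Let7, -1, -1, -1},
    {s_Let7, s_mIL6, -1, -1}, {s_mIL6Let7, -1, -1, -1},
    {-1, -1, -1, -1}, {s_NFKB, -1, -1, -1},
    {s_mIL6, -1, -1, -1}, {s_mIL6Let7, -1, -1, -1},
    {s_mIL6, -1, -1, -1}, {s_IL6, -1, -1, -1},
    {-1, -1, -1, -1}, {s_Let7, s_mRas, -1, -1},
    {s_mRasLet7, -1, -1, -1}, {s_mRas, -1, -1, -1},
    {s_mRasLet7, -1, -1, -1}, {s_mRas, -1, -1, -1},
    {s_Ras, -1, -1, -1}, {s_IL6, -1, -1, -1},
    {s_STAT3, -1, -1, -1}, {s_STAT3, -1, -1, -1},
    {s_miR21, -1, -1, -1}, {s_miR21, s_mPTEN, -1, -1},
    {s_miRmpten, -1, -1, -1}, {-1, -1, -1, -1},
    {s_mPTEN, -1, -1, -1}, {s_miRmpten, -1, -1, -1},
    {s_mPTEN, -1, -1, -1}, {s_PTEN, -1, -1, -1},
    {-1, -1, -1, -1}, {s_Let7, s_ceRNA, -1, -1},
    {s_ceRNAlet7, -1, -1, -1}, {s_ceRNA, -1, -1, -1},
    {s_ceRNAlet7, -1, -1, -1}, {-1, -1, -1, -1},
    {s_miR21, s_mPTEN1, -1, -1}, {s_miRmpten1, -1, -1, -1},
    {s_mPTEN1, -1, -1, -1}, {s_miRmpten1, -1, -1, -1}
  };
  for (int c = 0; c < NCHAN; ++c)
    for (int k = 0; k < 4; ++k)
      if (depends[c][k] >= 0) dep[depends[c][k]].push_back(c);
}

static NumericVector ssaPropensities(NumericVector counts,
                                     NumericVector params, double omega) {
  if (counts.size() != NSPEC) stop("state must have %d species", NSPEC);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  NumericVector a(NCHAN);
  for (int c = 0; c < NCHAN; ++c)
    a[c] = propensity(c, counts.begin(), params.begin(), omega);
  return a;
}

static List ssaRunC(NumericVector initCounts, NumericVector params,
                    double omega, double tEndMin, double recordDtMin,
                    bool recordEvents, double maxEvents) {
  if (initCounts.size() != NSPEC) stop("state must have %d species", NSPEC);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);

  double n[NSPEC];
  for (int i = 0; i < NSPEC; ++i) {
    n[i] = std::floor(initCounts[i] + 0.5);
    if (n[i] < 0) stop("initial counts must be non-negative");
  }
  const double *p = params.begin();

  std::vector< std::vector<int> > dep;
  buildDeps(dep);

  double a[NCHAN], aTot = 0.0;
  for (int c = 0; c < NCHAN; ++c) { a[c] = propensity(c, n, p, omega); aTot += a[c]; }

  int nRec = (int) std::floor(tEndMin / recordDtMin + 1e-9) + 1;
  NumericMatrix snap(nRec, NSPEC);
  NumericVector snapT(nRec);
  int iRec = 0;

  std::vector<double> evT;
  std::vector<int> evC;

  RNGScope scope;
  double t = 0.0;
  double nEvents = 0.0;

  while (true) {
    double tau = (aTot > 0.0) ? ::Rf_rexp(1.0 / aTot) : R_PosInf;
    double tNext = t + tau;
    while (iRec < nRec && iRec * recordDtMin <= tNext + 1e-12) {
      if (iRec * recordDtMin > tEndMin + 1e-9) break;
      snapT[iRec] = iRec * recordDtMin;
      for (int i = 0; i < NSPEC; ++i) snap(iRec, i) = n[i];
      ++iRec;
    }
    if (tNext > tEndMin || aTot <= 0.0) break;
    t = tNext;

    double r = ::unif_rand() * aTot;
    int c = 0;
    double cum = 0.0;
    for (; c < NCHAN - 1; ++c) { cum += a[c]; if (r < cum) break; }

    for (int k = 0; k < MAXCHG; ++k) {
      int sp = STOICH[c][k][0];
      if (sp < 0) break;
      n[sp] += STOICH[c][k][1];
      if (n[sp] < 0)
        stop("negative copy number for species %d (channel %d)", sp, c);
    }
    for (int k = 0; k < MAXCHG; ++k) {
      int sp = STOICH[c][k][0];
      if (sp < 0) break;
      for (size_t j = 0; j < dep[sp].size(); ++j) {
        int cc = dep[sp][j];
        aTot -= a[cc];
        a[cc] = propensity(cc, n, p, omega);
        if (a[cc] < 0) stop("negative propensity in channel %d", cc);
        aTot += a[cc];
      }
    }
    if (aTot < 0) { // guard against drift of the cached total
      aTot = 0.0;
      for (int cc = 0; cc < NCHAN; ++cc) aTot += a[cc];
    }

    if (recordEvents) { evT.push_back(t); evC.push_back(c + 1); }
    if (++nEvents >= maxEvents)
      stop("event budget exceeded (%.0f events); raise maxEvents", maxEvents);
    if (((long long) nEvents) % 100000 == 0) {
      // refresh the cached total to keep rounding drift bounded
      aTot = 0.0;
      for (int cc = 0; cc < NCHAN; ++cc) aTot += a[cc];
      Rcpp::checkUserInterrupt();
    }
  }

  // fill any remaining grid points with the final state
  for (; iRec < nRec; ++iRec) {
    snapT[iRec] = iRec * recordDtMin;
    for (int i = 0; i < NSPEC; ++i) snap(iRec, i) = n[i];
  }

  NumericVector finalCounts(NSPEC);
  for (int i = 0; i < NSPEC; ++i) finalCounts[i] = n[i];

  List out = List::create(_["timesMin"] = snapT, _["counts"] = snap,
                          _["finalCounts"] = finalCounts,
                          _["nEvents"] = nEvents);
  if (recordEvents) {
    out["eventTimesMin"] = wrap(evT);
    out["eventChannel"] = wrap(evC);
  }
  return out;
}

extern "C" SEXP episwitch_ssa_propensities(SEXP counts, SEXP params,
                                           SEXP omega) {
  BEGIN_RCPP
  return wrap(ssaPropensities(NumericVector(counts), NumericVector(params),
                              as<double>(omega)));
  END_RCPP
}

extern "C" SEXP episwitch_ssa_run(SEXP initCounts, SEXP params, SEXP omega,
                                  SEXP tEndMin, SEXP recordDtMin,
                                  SEXP recordEvents, SEXP maxEvents) {
  BEGIN_RCPP
  return wrap(ssaRunC(NumericVector(initCounts), NumericVector(params),
                      as<double>(omega), as<double>(tEndMin),
                      as<double>(recordDtMin), as<bool>(recordEvents),
                      as<double>(maxEvents)));
  END_RCPP
}
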