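/* Compiled right-hand side for deSolve.  Parameter layout must match
 * .paramOrder in R/parameters.R (54 entries, Src last); state layout must
 * match .stateOrder in R/state.R (18 species).  The R function switchRHS()
 * is the readable reference; the two are asserted equal in the test suite.
 */
#include <R.h>

#define NPAR 54
static double p[NPAR];

/* parameter indices (canonical order) */
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
  i_Src
};

void episwitch_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

void episwitch_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
  const double NFKB = y[0], Lin28 = y[1], Let7 = y[2], mIL6 = y[3],
    mIL6Let7 = y[4], IL6 = y[5], mRas = y[6], mRasLet7 = y[7], Ras = y[8],
    STAT3 = y[9], miR21 = y[10], mPTEN = y[11], miRmpten = y[12],
    PTEN = y[13], ceRNA = y[14], ceRNAlet7 = y[15], mPTEN1 = y[16],
    miRmpten1 = y[17];

  const double drive = (p[i_kAA1NFKB] * p[i_Src] + p[i_kAA2NFKB] * IL6 +
                        p[i_kAA3NFKB] * Ras) *
    p[i_KIPTEN] / (p[i_KIPTEN] + PTEN);
  const double inactive = p[i_NFKBT] - NFKB;
  const double act = drive * inactive / (p[i_KANFKB] + inactive);
  const double inact = p[i_VDNFKB] * NFKB / (p[i_KINFKB] + NFKB);

  const double bIL6 = p[i_k1] * Let7 * mIL6 - p[i_k2] * mIL6Let7;
  const double bRas = p[i_k3] * Let7 * mRas - p[i_k4] * mRasLet7;
  const double bPt  = p[i_k5] * miR21 * mPTEN - p[i_k6] * miRmpten;
  const double bCe  = p[i_k7] * Let7 * ceRNA - p[i_k8] * ceRNAlet7;
  const double bPt1 = p[i_k9] * miR21 * mPTEN1 - p[i_k10] * miRmpten1;

  ydot[0] = act - inact;
  ydot[1] = p[i_VSLIN28] * NFKB / (p[i_KA1NF] + NFKB) - p[i_kDLIN28] * Lin28;
  ydot[2] = p[i_VSLET7] * p[i_KILET7] / (p[i_KILET7] + Lin28) -
    bIL6 - bRas - bCe - p[i_kDLET7] * Let7;
  ydot[3] = p[i_VS1MIL6] + p[i_VS2MIL6] * NFKB / (p[i_KA2NF] + NFKB) -
    bIL6 - p[i_kDMIL6] * mIL6;
  ydot[4] = bIL6 - p[i_kDILLET] * mIL6Let7;
  ydot[5] = p[i_kSIL6] * mIL6 - p[i_kDIL6] * IL6;
  ydot[6] = p[i_VSMRAS] - bRas - p[i_kDMRAS] * mRas;
  ydot[7] = bRas - p[i_kDRASLET] * mRasLet7;
  ydot[8] = p[i_kSRAS] * mRas - p[i_kDRAS] * Ras;
  ydot[9] = p[i_VSSTAT] * IL6 / (p[i_KAIL6] + IL6) - p[i_kDSTAT] * STAT3;
  ydot[10] = p[i_VSMIR21] * STAT3 / (p[i_KASTAT] + STAT3) -
    bPt - bPt1 - p[i_kDMIR21] * miR21;
  ydot[11] = p[i_VSMPTEN] - bPt - p[i_kDMPTEN] * mPTEN;
  ydot[12] = bPt - p[i_kDMIRMP] * miRmpten;
  ydot[13] = p[i_kSPTEN] * mPTEN - p[i_kDPTEN] * PTEN;
  ydot[14] = p[i_VSCERNA] - bCe - p[i_kDCERNA] * ceRNA;
  ydot[15] = bCe - p[i_kDCELET7] * ceRNAlet7;
  ydot[16] = p[i_VSMPTEN1] - bPt1 - p[i_kDMPTEN1] * mPTEN1;
  ydot[17] = bPt1 - p[i_kDMIRMP1] * miRmpten1;
}
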