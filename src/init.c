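#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* model_rhs.c (deSolve compiled interface) */
void episwitch_initmod(void (*odeparms)(int *, double *));
void episwitch_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip);

/* ssa.cpp */
SEXP episwitch_ssa_propensities(SEXP counts, SEXP params, SEXP omega);
SEXP episwitch_ssa_run(SEXP initCounts, SEXP params, SEXP omega, SEXP tEndMin,
                       SEXP recordDtMin, SEXP recordEvents, SEXP maxEvents);

static const R_CallMethodDef CallEntries[] = {
  {"episwitch_ssa_propensities", (DL_FUNC) &episwitch_ssa_propensities, 3},
  {"episwitch_ssa_run",          (DL_FUNC) &episwitch_ssa_run,          7},
  {NULL, NULL, 0}
};

/* registered so deSolve's getNativeSymbolInfo() can resolve them */
static const R_CMethodDef CEntries[] = {
  {"episwitch_initmod", (DL_FUNC) &episwitch_initmod, 0},
  {"episwitch_derivs",  (DL_FUNC) &episwitch_derivs,  0},
  {NULL, NULL, 0}
};

void R_init_episwitch(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
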