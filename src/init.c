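#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void pd1_initmod(void (*odeparms)(int *, double *));
void pd1_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
SEXP C_pd1_deriv(SEXP y, SEXP p);

static const R_CallMethodDef call_entries[] = {
  {"C_pd1_deriv", (DL_FUNC) &C_pd1_deriv, 2},
  {NULL, NULL, 0}
};

/* registered so deSolve can look them up by name in this DLL */
static const R_CMethodDef c_entries[] = {
  {"pd1_initmod", (DL_FUNC) &pd1_initmod, 1},
  {"pd1_derivs",  (DL_FUNC) &pd1_derivs,  6},
  {NULL, NULL, 0}
};

void R_init_pd1sig(DllInfo *dll)
{
  R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
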