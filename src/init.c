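#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP hc_set_network(SEXP lst);
SEXP hc_set_influx(SEXP val);
SEXP hc_rhs(SEXP y);
void hc_initmod(void (*odeparms)(int *, double *));
void hc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);

static const R_CallMethodDef CallEntries[] = {
    {"hc_set_network", (DL_FUNC) &hc_set_network, 1},
    {"hc_set_influx",  (DL_FUNC) &hc_set_influx,  1},
    {"hc_rhs",         (DL_FUNC) &hc_rhs,         1},
    {NULL, NULL, 0}
};

void R_init_hemicam(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up hc_derivs by name */
}
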