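#include <R.h>
#include <R_ext/Rdynload.h>

void batch_set_np(int *n);
void batch_initmod(void (*odeparms)(int *, double *));
void batch_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);
void batch_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip);

static const R_CMethodDef CEntries[] = {
    {"batch_set_np", (DL_FUNC) &batch_set_np, 1},
    {NULL, NULL, 0}
};

void R_init_serialdil(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks up batch_derivs / batch_initmod / batch_root by name */
    R_useDynamicSymbols(dll, TRUE);
}
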