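#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void warburgsim_init(void (*odeparms)(int *, double *));
void warburgsim_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"warburgsim_init",   (DL_FUNC) &warburgsim_init,   1},
    {"warburgsim_derivs", (DL_FUNC) &warburgsim_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_warburgsim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
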