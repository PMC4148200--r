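#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP dl_rhs_c(SEXP ys, SEXP ps);
SEXP dl_jac_c(SEXP ys, SEXP ps);

static const R_CallMethodDef CallEntries[] = {
    {"dl_rhs_c", (DL_FUNC) &dl_rhs_c, 2},
    {"dl_jac_c", (DL_FUNC) &dl_jac_c, 2},
    {NULL, NULL, 0}
};

void R_init_dlgradient(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
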