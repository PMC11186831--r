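#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_top_eigen(SEXP A_, SEXP k_);
SEXP C_slot_gather(SEXP values, SEXP idx, SEXP n_);

static const R_CallMethodDef callMethods[] = {
    {"C_top_eigen", (DL_FUNC) &C_top_eigen, 2},
    {"C_slot_gather", (DL_FUNC) &C_slot_gather, 3},
    {NULL, NULL, 0}
};

void R_init_divergene(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
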