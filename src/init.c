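#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call entry points (defined in ibm.cpp with C linkage) */
extern SEXP C_mutate_traits(SEXP, SEXP, SEXP);
extern SEXP C_forage_patch(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_run_sim(SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_mutate_traits", (DL_FUNC) &C_mutate_traits, 3},
    {"C_forage_patch",  (DL_FUNC) &C_forage_patch,  6},
    {"C_run_sim",       (DL_FUNC) &C_run_sim,       4},
    {NULL, NULL, 0}
};

void R_init_rangexp(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* keep dynamic lookup enabled: deSolve resolves the compiled
       ODE right-hand side (derivs_cr / initmod_cr) by symbol name */
    R_useDynamicSymbols(dll, TRUE);
}
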