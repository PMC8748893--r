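#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void R_init_mbode(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    /* deSolve looks the rhs/init routines up by name */
    R_useDynamicSymbols(dll, TRUE);
}
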