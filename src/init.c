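#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_svb_encode(SEXP values);
SEXP C_svb_decode(SEXP control, SEXP data, SEXP count);
SEXP C_zstd_compress(SEXP payload, SEXP level);
SEXP C_zstd_decompress(SEXP payload);
SEXP C_fnv1a64(SEXP payload);

static const R_CallMethodDef callMethods[] = {
    {"C_svb_encode",      (DL_FUNC) &C_svb_encode,      1},
    {"C_svb_decode",      (DL_FUNC) &C_svb_decode,      3},
    {"C_zstd_compress",   (DL_FUNC) &C_zstd_compress,   2},
    {"C_zstd_decompress", (DL_FUNC) &C_zstd_decompress, 1},
    {"C_fnv1a64",         (DL_FUNC) &C_fnv1a64,         1},
    {NULL, NULL, 0}
};

void R_init_slowfive(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
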