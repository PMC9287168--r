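#include <R.h>
#include <Rinternals.h>
#include <zstd.h>

SEXP C_zstd_compress(SEXP payload, SEXP level)
{
    size_t srcSize = (size_t) XLENGTH(payload);
    int lvl = asInteger(level);
    size_t bound = ZSTD_compressBound(srcSize);

    SEXP buf = PROTECT(allocVector(RAWSXP, (R_xlen_t) bound));
    size_t got = ZSTD_compress(RAW(buf), bound, RAW(payload), srcSize, lvl);
    if (ZSTD_isError(got)) {
        UNPROTECT(1);
        error("zstd compression failed: %s", ZSTD_getErrorName(got));
    }
    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) got));
    memcpy(RAW(out), RAW(buf), got);
    UNPROTECT(2);
    return out;
}

SEXP C_zstd_decompress(SEXP payload)
{
    size_t srcSize = (size_t) XLENGTH(payload);
    unsigned long long content =
        ZSTD_getFrameContentSize(RAW(payload), srcSize);
    if (content == ZSTD_CONTENTSIZE_ERROR || content == ZSTD_CONTENTSIZE_UNKNOWN)
        error("zstd decode error: not a complete zstd frame");

    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) content));
    size_t got = ZSTD_decompress(RAW(out), (size_t) content, RAW(payload), srcSize);
    if (ZSTD_isError(got)) {
        UNPROTECT(1);
        error("zstd decode error: %s", ZSTD_getErrorName(got));
    }
    UNPROTECT(1);
    return out;
}
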