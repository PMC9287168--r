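/* StreamVByte-style codec specialised to 16-bit values: one control bit per
 * value (LSB-first within each control byte), 0 = one data byte, 1 = two
 * data bytes little-endian.  Values must lie in [0, 65535]. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>

SEXP C_svb_encode(SEXP values)
{
    R_xlen_t n = XLENGTH(values);
    const int *v = INTEGER(values);
    R_xlen_t ncontrol = (n + 7) / 8;

    SEXP control = PROTECT(allocVector(RAWSXP, ncontrol));
    unsigned char *ctl = RAW(control);
    memset(ctl, 0, (size_t) ncontrol);

    /* first pass: control bits and data size */
    R_xlen_t ndata = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        int x = v[i];
        if (x == NA_INTEGER || x < 0 || x > 65535) {
            UNPROTECT(1);
            error("svb width error: value at position %lld is outside [0, 65535]",
                  (long long) (i + 1));
        }
        if (x > 255) {
            ctl[i >> 3] |= (unsigned char) (1u << (i & 7));
            ndata += 2;
        } else {
            ndata += 1;
        }
    }

    SEXP data = PROTECT(allocVector(RAWSXP, ndata));
    unsigned char *d = RAW(data);
    R_xlen_t k = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        unsigned int x = (unsigned int) v[i];
        d[k++] = (unsigned char) (x & 0xFF);
        if (x > 255)
            d[k++] = (unsigned char) ((x >> 8) & 0xFF);
    }

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, control);
    SET_VECTOR_ELT(out, 1, data);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("control"));
    SET_STRING_ELT(nms, 1, mkChar("data"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(4);
    return out;
}

SEXP C_svb_decode(SEXP control, SEXP data, SEXP count)
{
    R_xlen_t n = (R_xlen_t) asReal(count);
    R_xlen_t ncontrol = XLENGTH(control);
    R_xlen_t ndata = XLENGTH(data);
    const unsigned char *ctl = RAW(control);
    const unsigned char *d = RAW(data);

    if (ncontrol < (n + 7) / 8)
        error("svb decode error: control stream truncated at byte %lld",
              (long long) ncontrol);

    SEXP out = PROTECT(allocVector(INTSXP, n));
    int *v = INTEGER(out);
    R_xlen_t k = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        int two = (ctl[i >> 3] >> (i & 7)) & 1;
        if (k + 1 + two > ndata) {
            UNPROTECT(1);
            error("svb decode error: data stream truncated at byte %lld",
                  (long long) k);
        }
        unsigned int x = d[k++];
        if (two)
            x |= ((unsigned int) d[k++]) << 8;
        v[i] = (int) x;
    }
    if (k != ndata) {
        UNPROTECT(1);
        error("svb decode error: %lld trailing data bytes after value %lld",
              (long long) (ndata - k), (long long) n);
    }
    UNPROTECT(1);
    return out;
}
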