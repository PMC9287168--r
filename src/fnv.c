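/* FNV-1a 64-bit hash, returned as 8 little-endian bytes.  Used for index
 * staleness detection and order-invariant record-set checksums. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>

SEXP C_fnv1a64(SEXP payload)
{
    const unsigned char *p = RAW(payload);
    R_xlen_t n = XLENGTH(payload);
    uint64_t h = 1469598103934665603ULL;
    for (R_xlen_t i = 0; i < n; i++) {
        h ^= p[i];
        h *= 1099511628211ULL;
    }
    SEXP out = PROTECT(allocVector(RAWSXP, 8));
    unsigned char *o = RAW(out);
    for (int j = 0; j < 8; j++)
        o[j] = (unsigned char) ((h >> (8 * j)) & 0xFF);
    UNPROTECT(1);
    return out;
}
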