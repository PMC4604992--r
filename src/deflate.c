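/* DEFLATE size measurement against system zlib.
 *
 * R's memCompress() does not expose the compression level or a raw-stream
 * container, both of which the compressor contract here requires, so the
 * stream is driven directly.  The gzip header is pinned (mtime = 0, os = 3,
 * no name/comment) so byte counts are identical across machines. */

#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <zlib.h>

/* windowBits: 15 + 16 selects a gzip wrapper, -15 a raw DEFLATE stream */
SEXP C_deflate_size(SEXP data, SEXP level, SEXP gzip)
{
    int lv = Rf_asInteger(level);
    int gz = Rf_asLogical(gzip);
    uLong n = (uLong) XLENGTH(data);
    z_stream s;
    gz_header hd;
    int ret;

    if (lv < 1 || lv > 9)
        Rf_error("compression level must be in 1..9");

    memset(&s, 0, sizeof s);
    ret = deflateInit2(&s, lv, Z_DEFLATED, gz ? 15 + 16 : -15, 8,
                       Z_DEFAULT_STRATEGY);
    if (ret != Z_OK)
        Rf_error("deflateInit2 failed (%d)", ret);

    if (gz) {
        memset(&hd, 0, sizeof hd);
        hd.time = 0;
        hd.os = 3;              /* fixed: unix */
        deflateSetHeader(&s, &hd);
    }

    uLong bound = deflateBound(&s, n) + 32; /* +32: header slack */
    Bytef *out = (Bytef *) R_alloc(bound, 1);

    s.next_in = (Bytef *) RAW(data);
    s.avail_in = (uInt) n;
    s.next_out = out;
    s.avail_out = (uInt) bound;

    ret = deflate(&s, Z_FINISH);
    if (ret != Z_STREAM_END) {
        deflateEnd(&s);
        Rf_error("deflate failed (%d)", ret);
    }
    uLong size = s.total_out;
    deflateEnd(&s);

    return Rf_ScalarInteger((int) size);
}

static const R_CallMethodDef CallEntries[] = {
    {"C_deflate_size", (DL_FUNC) &C_deflate_size, 3},
    {NULL, NULL, 0}
};

void R_init_comprel(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
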