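#include <R.h>
#include <Rinternals.h>

/* Gather a sample x variable matrix from per-slot values.
 *
 * values: numeric vector (a flattened S x m per-slot value matrix)
 * idx:    integer vector of 1-based flat indices into values, one per
 *         output cell, laid out column-major for an n x m result
 * n:      number of output rows
 *
 * Equivalent to matrix(values[idx], n, length(idx)/n) but with a single
 * pass and no intermediate allocation; this sits in the inner loop of
 * the permutation engine.
 */
SEXP C_slot_gather(SEXP values, SEXP idx, SEXP n_)
{
    R_xlen_t N = XLENGTH(idx);
    int n = asInteger(n_);
    if (n <= 0 || N % n != 0)
        error("index length is not a multiple of the row count");
    SEXP out = PROTECT(allocMatrix(REALSXP, n, (int)(N / n)));
    double *x = REAL(out);
    const double *v = REAL(values);
    const int *id = INTEGER(idx);
    for (R_xlen_t i = 0; i < N; i++)
        x[i] = v[id[i] - 1];
    UNPROTECT(1);
    return out;
}
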