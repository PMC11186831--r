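#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>

/* Top-k eigenpairs of a dense symmetric matrix via LAPACK dsyevr
 * (range = "I").  Returns list(values, vectors) with eigenvalues in
 * decreasing order and vectors in matching columns.  Only the requested
 * k eigenvectors are back-transformed, which is substantially cheaper
 * than eigen() when k << n (the permutation engine refits PCA thousands
 * of times). */
SEXP C_top_eigen(SEXP A_, SEXP k_)
{
    int n = Rf_nrows(A_);
    int k = Rf_asInteger(k_);
    if (k < 1 || k > n)
        Rf_error("k must be in [1, nrow(A)]");
    if (Rf_ncols(A_) != n)
        Rf_error("A must be square");

    /* dsyevr destroys its input */
    SEXP Ac = PROTECT(Rf_duplicate(A_));
    double *A = REAL(Ac);

    int il = n - k + 1, iu = n, m_out = 0, info = 0;
    double vl = 0.0, vu = 0.0, abstol = 0.0;

    SEXP w_ = PROTECT(Rf_allocVector(REALSXP, n));
    SEXP z_ = PROTECT(Rf_allocMatrix(REALSXP, n, k));
    int *isuppz = (int *) R_alloc(2 * (size_t) k, sizeof(int));

    /* workspace query */
    double wkopt = 0;
    int iwkopt = 0, lwork = -1, liwork = -1;
    F77_CALL(dsyevr)("V", "I", "U", &n, A, &n, &vl, &vu, &il, &iu,
                     &abstol, &m_out, REAL(w_), REAL(z_), &n, isuppz,
                     &wkopt, &lwork, &iwkopt, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0)
        Rf_error("dsyevr workspace query failed (info = %d)", info);
    lwork = (int) wkopt;
    liwork = iwkopt;
    double *work = (double *) R_alloc((size_t) lwork, sizeof(double));
    int *iwork = (int *) R_alloc((size_t) liwork, sizeof(int));

    F77_CALL(dsyevr)("V", "I", "U", &n, A, &n, &vl, &vu, &il, &iu,
                     &abstol, &m_out, REAL(w_), REAL(z_), &n, isuppz,
                     work, &lwork, iwork, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0)
        Rf_error("dsyevr failed (info = %d)", info);
    if (m_out != k)
        Rf_error("dsyevr returned %d of %d requested eigenpairs", m_out, k);

    /* dsyevr returns ascending order; reverse to decreasing */
    SEXP vals = PROTECT(Rf_allocVector(REALSXP, k));
    SEXP vecs = PROTECT(Rf_allocMatrix(REALSXP, n, k));
    double *w = REAL(w_), *z = REAL(z_);
    double *rv = REAL(vals), *rz = REAL(vecs);
    for (int j = 0; j < k; j++) {
        rv[j] = w[k - 1 - j];
        double *src = z + (size_t) (k - 1 - j) * n;
        double *dst = rz + (size_t) j * n;
        for (int i = 0; i < n; i++)
            dst[i] = src[i];
    }

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, vals);
    SET_VECTOR_ELT(out, 1, vecs);
    SEXP nms = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, Rf_mkChar("values"));
    SET_STRING_ELT(nms, 1, Rf_mkChar("vectors"));
    Rf_setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(7);
    return out;
}
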