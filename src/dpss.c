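#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Number of eigenvalues of the symmetric tridiagonal matrix (diagonal d,
   off-diagonal e) strictly below each shift x, by Sturm sequence count. */
static SEXP sturm_count(SEXP d_, SEXP e_, SEXP x_)
{
    int n = LENGTH(d_), m = LENGTH(x_);
    double *d = REAL(d_), *e = REAL(e_), *x = REAL(x_);
    SEXP out = PROTECT(allocVector(INTSXP, m));
    int *cnt = INTEGER(out);
    for (int j = 0; j < m; j++) {
        double q = d[0] - x[j];
        int c = q < 0;
        for (int i = 1; i < n; i++) {
            double den = q;
            if (den == 0.0) den = 1e-300;
            q = (d[i] - x[j]) - e[i - 1] * e[i - 1] / den;
            if (q < 0) c++;
        }
        cnt[j] = c;
    }
    UNPROTECT(1);
    return out;
}

/* Solve (T - shift I) y = b for tridiagonal T by the Thomas algorithm,
   with a small diagonal guard so near-singular shifts remain usable for
   inverse iteration. */
static SEXP tridiag_solve_shifted(SEXP d_, SEXP e_, SEXP b_, SEXP shift_,
                                  SEXP guard_)
{
    int n = LENGTH(d_);
    double *d = REAL(d_), *e = REAL(e_), *b = REAL(b_);
    double shift = REAL(shift_)[0], guard = REAL(guard_)[0];
    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(out);
    double *cp = (double *) R_alloc(n, sizeof(double));
    double *bp = (double *) R_alloc(n, sizeof(double));
    double den = d[0] - shift;
    if (den > -guard && den < guard) den = guard;
    cp[0] = e[0] / den;
    bp[0] = b[0] / den;
    for (int i = 1; i < n; i++) {
        den = (d[i] - shift) - e[i - 1] * cp[i - 1];
        if (den > -guard && den < guard) den = guard;
        if (i < n - 1) cp[i] = e[i] / den;
        bp[i] = (b[i] - e[i - 1] * bp[i - 1]) / den;
    }
    y[n - 1] = bp[n - 1];
    for (int i = n - 2; i >= 0; i--) y[i] = bp[i] - cp[i] * y[i + 1];
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"c_sturm_count", (DL_FUNC) &sturm_count, 3},
    {"c_tridiag_solve_shifted", (DL_FUNC) &tridiag_solve_shifted, 5},
    {NULL, NULL, 0}
};

void R_init_sasseeg(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
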