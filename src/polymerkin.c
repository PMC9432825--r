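/* Compiled kernels: ODE right-hand sides for the two polymerization
 * schemes (deSolve compiled-model interface) and an exact stochastic
 * simulation algorithm used as an independent oracle for the mean-field
 * equations.
 *
 * State layout
 *   scheme 1: y[0..n-1]            = [A_1] .. [A_n]
 *   scheme 2: y[0..n-1]            = [A_1] .. [A_n]
 *             y[n..2n-3]           = [A'_3] .. [A'_n]
 *
 * Parameter vector (initmod): scheme, n, k1..k4, km1..km4, ktrans
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

static double pk_parms[11];

void pk_initmod(void (*odeparms)(int *, double *))
{
    int N = 11;
    odeparms(&N, pk_parms);
}

/* scheme 1: stepwise association k1,k2,k3,k4 (k4 from the tetramer up),
 * dissociation km1,km2,km3,km4; species n is absorbing (no flux to n+1) */
static void deriv_scheme1(int n, const double *y, double *ydot,
                          double k1, double k2, double k3, double k4,
                          double km1, double km2, double km3, double km4)
{
    double A = y[0];
    double dA;
    int i;

    /* forward flux f_i: A_i + A -> A_{i+1}; backward b_i: reverse */
    double f1 = k1 * A * A;
    double b1 = km1 * y[1];

    for (i = 0; i < n; i++) ydot[i] = 0.0;

    dA = -2.0 * f1 + 2.0 * b1;
    ydot[1] += f1 - b1;

    for (i = 2; i <= n - 1; i++) {       /* step i -> i+1, 1-based species i */
        double kon  = (i == 2) ? k2 : (i == 3) ? k3 : k4;
        double koff = (i == 2) ? km2 : (i == 3) ? km3 : km4;
        double f = kon * y[i - 1] * A;
        double b = koff * y[i];
        dA += -f + b;
        ydot[i - 1] += -f + b;
        ydot[i]     +=  f - b;
    }
    ydot[0] += dA;
}

/* scheme 2: unprimed pathway k1/km1, k2/km2 then k3/km3 for every step
 * above the trimer; primed pathway k4/km4; irreversible transition
 * A_i -> A'_i at ktrans for i >= 3; A'_3 dissociates to A_2 + A at km4 */
static void deriv_scheme2(int n, const double *y, double *ydot,
                          double k1, double k2, double k3, double k4,
                          double km1, double km2, double km3, double km4,
                          double ktrans)
{
    double A = y[0];
    const double *yp = y + n;    /* yp[j] = [A'_{j+3}], j = 0..n-3 */
    double *dp = ydot + n;
    double dA;
    int i;

    for (i = 0; i < 2 * n - 2; i++) ydot[i] = 0.0;

    double f1 = k1 * A * A;
    double b1 = km1 * y[1];
    dA = -2.0 * f1 + 2.0 * b1;
    ydot[1] += f1 - b1;

    for (i = 2; i <= n - 1; i++) {
        double kon  = (i == 2) ? k2 : k3;
        double koff = (i == 2) ? km2 : km3;
        double f = kon * y[i - 1] * A;
        double b = koff * y[i];
        dA += -f + b;
        ydot[i - 1] += -f + b;
        ydot[i]     +=  f - b;
    }

    /* transitions into the primed state */
    for (i = 3; i <= n; i++) {
        double tr = ktrans * y[i - 1];
        ydot[i - 1] -= tr;
        dp[i - 3]   += tr;
    }

    /* primed trimer dissociation A'_3 -> A_2 + A */
    {
        double r = km4 * yp[0];
        dp[0]   -= r;
        ydot[1] += r;
        dA      += r;
    }

    /* primed (dis)association A'_i + A <-> A'_{i+1}, i = 3..n-1 */
    for (i = 3; i <= n - 1; i++) {
        double f = k4 * yp[i - 3] * A;
        double b = km4 * yp[i - 2];
        dA += -f + b;
        dp[i - 3] += -f + b;
        dp[i - 2] +=  f - b;
    }

    ydot[0] += dA;
}

void pk_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    int scheme = (int) pk_parms[0];
    int n = (int) pk_parms[1];
    double k1 = pk_parms[2], k2 = pk_parms[3], k3 = pk_parms[4],
           k4 = pk_parms[5];
    double km1 = pk_parms[6], km2 = pk_parms[7], km3 = pk_parms[8],
           km4 = pk_parms[9];
    double ktrans = pk_parms[10];

    if (scheme == 1)
        deriv_scheme1(n, y, ydot, k1, k2, k3, k4, km1, km2, km3, km4);
    else
        deriv_scheme2(n, y, ydot, k1, k2, k3, k4, km1, km2, km3, km4,
                      ktrans);
}

/* ---------------------------------------------------------------------- */
/* Exact SSA over the same reaction networks.  Bimolecular propensities use
 * the macroscopic constants divided by omega (molecules per uM); the
 * dimerization propensity is (k1/omega) * nA * (nA - 1), consistent with
 * d[A]/dt = -2 k1 [A]^2. */

SEXP C_ssa(SEXP scheme_, SEXP n_, SEXP rates_, SEXP y0_, SEXP omega_,
           SEXP tgrid_, SEXP max_events_)
{
    int scheme = asInteger(scheme_);
    int n = asInteger(n_);
    double *rates = REAL(rates_);
    double k1 = rates[0], k2 = rates[1], k3 = rates[2], k4 = rates[3];
    double km1 = rates[4], km2 = rates[5], km3 = rates[6], km4 = rates[7];
    double ktrans = rates[8];
    double omega = asReal(omega_);
    double R_max_events = asReal(max_events_);

    int nstate = (scheme == 1) ? n : 2 * n - 2;
    int ngrid = LENGTH(tgrid_);
    double *tgrid = REAL(tgrid_);

    SEXP counts_ = PROTECT(allocMatrix(REALSXP, ngrid, nstate));
    double *counts = REAL(counts_);

    double *x = (double *) R_alloc(nstate, sizeof(double));
    for (int i = 0; i < nstate; i++) x[i] = REAL(y0_)[i];

    /* propensity slots: [0] dimerization, [1..n-2] association steps
     * i=2..n-1, [n-1..2n-3] dissociation of species 2..n, then for scheme 2:
     * primed association (n-3 slots), primed dissociation incl. trimer
     * (n-2 slots), transitions (n-2 slots) */
    int nprop = (scheme == 1) ? (2 * n - 2)
                              : (2 * n - 2) + (n - 3) + (n - 2) + (n - 2);
    double *a = (double *) R_alloc(nprop, sizeof(double));

    GetRNGstate();

    double t = 0.0;
    double nev = 0.0;
    double t_first = NA_REAL;
    int gi = 0;

    for (;;) {
        /* record grid points passed */
        while (gi < ngrid && tgrid[gi] <= t) {
            for (int s = 0; s < nstate; s++)
                counts[gi + ngrid * s] = x[s];
            gi++;
        }
        if (gi >= ngrid) break;
        if (nev >= R_max_events) {
            UNPROTECT(1);
            PutRNGstate();
            error("SSA exceeded the configured event cap (%g events)",
                  R_max_events);
        }

        double A = x[0];
        double atot = 0.0;
        int ip = 0;
        a[ip++] = (k1 / omega) * A * (A - 1.0);                /* dimer */
        for (int i = 2; i <= n - 1; i++) {                     /* assoc */
            double kon = (scheme == 1)
                ? ((i == 2) ? k2 : (i == 3) ? k3 : k4)
                : ((i == 2) ? k2 : k3);
            a[ip++] = (kon / omega) * x[i - 1] * A;
        }
        for (int i = 2; i <= n; i++) {                         /* dissoc */
            double koff = (scheme == 1)
                ? ((i == 2) ? km1 : (i == 3) ? km2 : (i == 4) ? km3 : km4)
                : ((i == 2) ? km1 : (i == 3) ? km2 : km3);
            a[ip++] = koff * x[i - 1];
        }
        if (scheme == 2) {
            for (int i = 3; i <= n - 1; i++)                   /* primed on */
                a[ip++] = (k4 / omega) * x[n + i - 3] * A;
            for (int i = 3; i <= n; i++)                       /* primed off */
                a[ip++] = km4 * x[n + i - 3];
            for (int i = 3; i <= n; i++)                       /* transition */
                a[ip++] = ktrans * x[i - 1];
        }
        for (int j = 0; j < nprop; j++) atot += a[j];

        if (atot <= 0.0) {         /* frozen system: fill remaining grid */
            for (; gi < ngrid; gi++)
                for (int s = 0; s < nstate; s++)
                    counts[gi + ngrid * s] = x[s];
            break;
        }

        double tau = exp_rand() / atot;
        double u = unif_rand() * atot;
        int r = 0;
        double acc = a[0];
        while (acc < u && r < nprop - 1) { r++; acc += a[r]; }

        double tnew = t + tau;
        while (gi < ngrid && tgrid[gi] <= tnew) {
            for (int s = 0; s < nstate; s++)
                counts[gi + ngrid * s] = x[s];
            gi++;
        }
        t = tnew;
        if (gi >= ngrid) break;
        if (ISNA(t_first)) t_first = t;
        nev += 1.0;

        /* apply the chosen reaction */
        int base_assoc = 1;
        int base_diss = base_assoc + (n - 2);
        if (r == 0) {                              /* 2A -> A2 */
            x[0] -= 2.0; x[1] += 1.0;
        } else if (r < base_diss) {                /* A_i + A -> A_{i+1} */
            int i = 2 + (r - base_assoc);
            x[0] -= 1.0; x[i - 1] -= 1.0; x[i] += 1.0;
        } else if (r < base_diss + (n - 1)) {      /* A_i -> A_{i-1} + A */
            int i = 2 + (r - base_diss);
            if (i == 2) { x[1] -= 1.0; x[0] += 2.0; }
            else { x[i - 1] -= 1.0; x[i - 2] += 1.0; x[0] += 1.0; }
        } else {
            int rr = r - (base_diss + (n - 1));
            if (rr < n - 3) {                      /* A'_i + A -> A'_{i+1} */
                int i = 3 + rr;
                x[0] -= 1.0; x[n + i - 3] -= 1.0; x[n + i - 2] += 1.0;
            } else if (rr < (n - 3) + (n - 2)) {   /* primed dissociation */
                int i = 3 + (rr - (n - 3));
                if (i == 3) { x[n] -= 1.0; x[1] += 1.0; x[0] += 1.0; }
                else {
                    x[n + i - 3] -= 1.0; x[n + i - 4] += 1.0; x[0] += 1.0;
                }
            } else {                               /* A_i -> A'_i */
                int i = 3 + (rr - (n - 3) - (n - 2));
                x[i - 1] -= 1.0; x[n + i - 3] += 1.0;
            }
        }
    }

    PutRNGstate();

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, counts_);
    SET_VECTOR_ELT(out, 1, ScalarReal(nev));
    SET_VECTOR_ELT(out, 2, ScalarReal(t_first));
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("counts"));
    SET_STRING_ELT(nm, 1, mkChar("n_events"));
    SET_STRING_ELT(nm, 2, mkChar("first_event_time"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(3);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_ssa", (DL_FUNC) &C_ssa, 7},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"pk_deriv", (DL_FUNC) &pk_deriv, 6},
    {"pk_initmod", (DL_FUNC) &pk_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_polymerkin(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
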