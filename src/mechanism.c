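/* Right-hand sides for the RAS-cleavage mechanism, in the form expected by
 * deSolve's compiled-model interface (initializer + derivative routines).
 *
 * Rapid-equilibrium model (2 states):
 *   y[0] = Rt  total intact RAS (free R + bound RP), molar
 *   y[1] = S   uncleaved reporter, molar
 * parms_re = {Ptot, ras_total, r1_init, KS, k2, KP, krep}
 *
 * Mass-action model (8 states):
 *   y = {R, P, RP, Pr1, S, r1, r2, AMC}
 * parms_ma = {KS, k2, KP, krep, kon}
 * Off-rates are kon*KS and kon*KP so the equilibria match the
 * rapid-equilibrium reduction as kon grows.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double parms_re[7];
static double parms_ma[5];

void rascleave_init_re(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms_re);
}

void rascleave_init_ma(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms_ma);
}

/* Free protease from the conservation equation
 *   P * (1 + Rt/(KS + P) + r1t/(KP + P)) = Ptot
 * by safeguarded Newton iteration on the monotone residual.
 */
double rascleave_free_p(double Ptot, double Rt, double r1t,
                        double KS, double KP)
{
    double lo, hi, P, f, df, Pn;
    int i;

    if (Ptot <= 0.0)
        return 0.0;
    if (Rt < 0.0) Rt = 0.0;
    if (r1t < 0.0) r1t = 0.0;

    lo = 0.0;
    hi = Ptot;
    P = Ptot / (1.0 + Rt / KS + r1t / KP); /* exact when P << KS, KP */
    if (P <= lo || P >= hi)
        P = 0.5 * Ptot;

    for (i = 0; i < 200; i++) {
        f = P * (1.0 + Rt / (KS + P) + r1t / (KP + P)) - Ptot;
        if (f > 0.0)
            hi = P;
        else
            lo = P;
        df = 1.0 + Rt * KS / ((KS + P) * (KS + P))
                 + r1t * KP / ((KP + P) * (KP + P));
        Pn = P - f / df;
        if (!(Pn > lo && Pn < hi))
            Pn = 0.5 * (lo + hi);
        if (fabs(Pn - P) <= 1e-15 * Ptot) {
            P = Pn;
            break;
        }
        P = Pn;
    }
    return P;
}

void rascleave_derivs_re(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double Ptot = parms_re[0], ras_total = parms_re[1], r1_init = parms_re[2];
    double KS = parms_re[3], k2 = parms_re[4], KP = parms_re[5],
           krep = parms_re[6];
    double Rt = y[0], S = y[1];
    double r1t, P, RP;

    if (Rt < 0.0) Rt = 0.0;
    if (S < 0.0) S = 0.0;
    r1t = ras_total + r1_init - Rt;
    P = rascleave_free_p(Ptot, Rt, r1t, KS, KP);
    RP = Rt * P / (KS + P);

    ydot[0] = -k2 * RP;
    ydot[1] = -krep * P * S;
}

void rascleave_derivs_ma(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double KS = parms_ma[0], k2 = parms_ma[1], KP = parms_ma[2],
           krep = parms_ma[3], kon = parms_ma[4];
    double R = y[0], P = y[1], RP = y[2], Pr1 = y[3], S = y[4], r1 = y[5];
    double bindS, bindP, acyl, rep;

    bindS = kon * R * P - kon * KS * RP;   /* R + P <-> RP   */
    bindP = kon * r1 * P - kon * KP * Pr1; /* r1 + P <-> Pr1 */
    acyl = k2 * RP;                        /* RP -> Pr1 + r2 */
    rep = krep * P * S;                    /* reporter turnover */

    ydot[0] = -bindS;              /* R   */
    ydot[1] = -bindS - bindP;      /* P   */
    ydot[2] = bindS - acyl;        /* RP  */
    ydot[3] = acyl + bindP;        /* Pr1 */
    ydot[4] = -rep;                /* S   */
    ydot[5] = -bindP;              /* r1  */
    ydot[6] = acyl;                /* r2  */
    ydot[7] = rep;                 /* AMC */
}

/* .Call wrapper so the R-level free_protease() shares the C root finder. */
SEXP rascleave_free_p_call(SEXP Ptot, SEXP Rt, SEXP r1t, SEXP KS, SEXP KP)
{
    SEXP ans = PROTECT(allocVector(REALSXP, 1));
    REAL(ans)[0] = rascleave_free_p(asReal(Ptot), asReal(Rt), asReal(r1t),
                                    asReal(KS), asReal(KP));
    UNPROTECT(1);
    return ans;
}

static const R_CallMethodDef call_entries[] = {
    {"rascleave_free_p_call", (DL_FUNC) &rascleave_free_p_call, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"rascleave_init_re", (DL_FUNC) &rascleave_init_re, 1},
    {"rascleave_init_ma", (DL_FUNC) &rascleave_init_ma, 1},
    {"rascleave_derivs_re", (DL_FUNC) &rascleave_derivs_re, 6},
    {"rascleave_derivs_ma", (DL_FUNC) &rascleave_derivs_ma, 6},
    {NULL, NULL, 0}
};

void R_init_rascleave(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
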