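/* Compiled right-hand side for the generated reaction network.
 *
 * The network (mass-action index arrays plus the non-mass-action layer:
 * calcium leak/pump/influx, surrogate-modulated CaMKII autophosphorylation
 * and pooled Michaelis-Menten dephosphorylation) is uploaded once per run
 * via hc_set_network(); deSolve then calls hc_derivs() through its
 * compiled-code interface. The spike influx is a plain zero-order rate
 * switched between integration segments via hc_set_influx(), so a segment
 * always sees a constant input and the solver restarts exactly at the
 * window edges.
 */
#include <R.h>
#include <Rinternals.h>
#include <stdlib.h>
#include <string.h>

static int ns = 0;
static int nm = 0;
static int *r1 = NULL, *r2 = NULL, *p1 = NULL, *p2 = NULL;
static double *kk = NULL;

static int ica = -1;
static double leak = 0.0, pump_vmax = 0.0, pump_km = 1.0, influx = 0.0;

static double k_autop = 0.0;
static int n_auto = 0;
static int *auto_src = NULL, *auto_dst = NULL;
static int n_act = 0;
static int *act_idx = NULL;
static double tot_monomer = 1.0;
static double poly5[6];

static double kcat_dep = 0.0, km_dep = 1.0;
static int n_enz = 0, n_dep = 0;
static int *enz_idx = NULL, *dep_src = NULL, *dep_dst = NULL;

static void free_all(void)
{
    free(r1); free(r2); free(p1); free(p2); free(kk);
    free(auto_src); free(auto_dst); free(act_idx);
    free(enz_idx); free(dep_src); free(dep_dst);
    r1 = r2 = p1 = p2 = NULL; kk = NULL;
    auto_src = auto_dst = act_idx = NULL;
    enz_idx = dep_src = dep_dst = NULL;
    nm = n_auto = n_act = n_enz = n_dep = 0;
}

static int *copy_int(SEXP el, int *n)
{
    SEXP iv = PROTECT(coerceVector(el, INTSXP));
    *n = LENGTH(iv);
    int *out = NULL;
    if (*n > 0) {
        out = (int *) malloc((size_t)(*n) * sizeof(int));
        if (!out) { UNPROTECT(1); error("hemicam: allocation failure"); }
        memcpy(out, INTEGER(iv), (size_t)(*n) * sizeof(int));
    }
    UNPROTECT(1);
    return out;
}

static double *copy_dbl(SEXP el, int *n)
{
    SEXP dv = PROTECT(coerceVector(el, REALSXP));
    *n = LENGTH(dv);
    double *out = NULL;
    if (*n > 0) {
        out = (double *) malloc((size_t)(*n) * sizeof(double));
        if (!out) { UNPROTECT(1); error("hemicam: allocation failure"); }
        memcpy(out, REAL(dv), (size_t)(*n) * sizeof(double));
    }
    UNPROTECT(1);
    return out;
}

static SEXP get_el(SEXP lst, const char *name)
{
    SEXP names = getAttrib(lst, R_NamesSymbol);
    for (int i = 0; i < LENGTH(lst); i++)
        if (strcmp(CHAR(STRING_ELT(names, i)), name) == 0)
            return VECTOR_ELT(lst, i);
    error("hemicam: missing network element '%s'", name);
    return R_NilValue;
}

SEXP hc_set_network(SEXP lst)
{
    int n, i;
    free_all();
    ns = asInteger(get_el(lst, "ns"));
    r1 = copy_int(get_el(lst, "r1"), &nm);
    r2 = copy_int(get_el(lst, "r2"), &n);
    p1 = copy_int(get_el(lst, "p1"), &n);
    p2 = copy_int(get_el(lst, "p2"), &n);
    kk = copy_dbl(get_el(lst, "k"), &n);
    if (n != nm) error("hemicam: inconsistent reaction arrays");
    ica = asInteger(get_el(lst, "ica"));
    leak = asReal(get_el(lst, "leak"));
    pump_vmax = asReal(get_el(lst, "pump_vmax"));
    pump_km = asReal(get_el(lst, "pump_km"));
    influx = asReal(get_el(lst, "influx"));
    k_autop = asReal(get_el(lst, "k_autop"));
    auto_src = copy_int(get_el(lst, "auto_src"), &n_auto);
    auto_dst = copy_int(get_el(lst, "auto_dst"), &n);
    act_idx = copy_int(get_el(lst, "active_idx"), &n_act);
    tot_monomer = asReal(get_el(lst, "total_monomer"));
    if (tot_monomer <= 0) tot_monomer = 1.0;
    SEXP pol = PROTECT(coerceVector(get_el(lst, "poly"), REALSXP));
    for (i = 0; i < 6; i++)
        poly5[i] = (i < LENGTH(pol)) ? REAL(pol)[i] : 0.0;
    UNPROTECT(1);
    kcat_dep = asReal(get_el(lst, "kcat_dep"));
    km_dep = asReal(get_el(lst, "km_dep"));
    if (km_dep <= 0) km_dep = 1.0;
    enz_idx = copy_int(get_el(lst, "enz_idx"), &n_enz);
    dep_src = copy_int(get_el(lst, "dep_src"), &n_dep);
    dep_dst = copy_int(get_el(lst, "dep_dst"), &n);
    return ScalarInteger(ns);
}

SEXP hc_set_influx(SEXP val)
{
    influx = asReal(val);
    return R_NilValue;
}

static void rhs(double *y, double *ydot)
{
    int i, j;
    double a, b, rate;
    for (i = 0; i < ns; i++) ydot[i] = 0.0;
    /* no clamping of small negative excursions: mass action is
     * self-correcting (rate ~ k*y pulls y back to zero) and clamping puts a
     * derivative kink exactly at y = 0, which defeats the BDF error test
     * whenever trace species ride the axis */
    for (j = 0; j < nm; j++) {
        a = y[r1[j]];
        if (r2[j] >= 0) { b = y[r2[j]]; rate = kk[j] * a * b; }
        else rate = kk[j] * a;
        ydot[r1[j]] -= rate;
        if (r2[j] >= 0) ydot[r2[j]] -= rate;
        if (p1[j] >= 0) ydot[p1[j]] += rate;
        if (p2[j] >= 0) ydot[p2[j]] += rate;
    }
    if (ica >= 0) {
        double ca = y[ica];
        ydot[ica] += leak + influx - pump_vmax * ca / (pump_km + ca);
    }
    if (k_autop > 0 && n_auto > 0) {
        double act = 0.0, frac, coef;
        for (i = 0; i < n_act; i++) act += y[act_idx[i]];
        frac = act / tot_monomer;
        coef = poly5[0] + frac * (poly5[1] + frac * (poly5[2] +
               frac * (poly5[3] + frac * (poly5[4] + frac * poly5[5]))));
        if (coef < 0) coef = 0; if (coef > 1) coef = 1;
        for (i = 0; i < n_auto; i++) {
            a = y[auto_src[i]];
            rate = k_autop * coef * a;
            ydot[auto_src[i]] -= rate;
            ydot[auto_dst[i]] += rate;
        }
    }
    if (kcat_dep > 0 && n_dep > 0) {
        double E = 0.0, S = 0.0, f;
        for (i = 0; i < n_enz; i++) E += y[enz_idx[i]];
        for (i = 0; i < n_dep; i++) S += y[dep_src[i]];
        f = kcat_dep * E / (km_dep + S);
        for (i = 0; i < n_dep; i++) {
            a = y[dep_src[i]];
            rate = f * a;
            ydot[dep_src[i]] -= rate;
            ydot[dep_dst[i]] += rate;
        }
    }
}

/* deSolve compiled-model entry points */
void hc_initmod(void (*odeparms)(int *, double *))
{
    int N = 0;
    double dummy = 0.0;
    odeparms(&N, &dummy);
}

void hc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    if (*neq != ns) error("hemicam: state length %d != network size %d",
                          *neq, ns);
    rhs(y, ydot);
}

/* direct evaluation from R, for cross-checking against the reference
 * R implementation of the same rate laws */
SEXP hc_rhs(SEXP ySEXP)
{
    SEXP yv = PROTECT(coerceVector(ySEXP, REALSXP));
    if (LENGTH(yv) != ns) {
        UNPROTECT(1);
        error("hemicam: state length %d != network size %d", LENGTH(yv), ns);
    }
    SEXP out = PROTECT(allocVector(REALSXP, ns));
    rhs(REAL(yv), REAL(out));
    UNPROTECT(2);
    return out;
}
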