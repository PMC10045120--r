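/* Compiled right-hand side for the data-driven reaction network.
 *
 * The R side precompiles the network into flat arrays (rate constants,
 * up-to-three participant indices per reaction with index n+1 meaning a
 * constant 1, gradient-permeation index pairs, and a dense stoichiometry
 * matrix with volume division and clamping folded in).  rx_set_network()
 * stashes those arrays in static storage; deSolve then calls rx_derivs()
 * directly, avoiding the R evaluation overhead per solver step.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAX_RX 4096

static SEXP net_ref = NULL;
static int n_sp = 0, n_rx = 0, n_gp = 0;
static double *K = NULL, *S = NULL;
static int *I1 = NULL, *I2 = NULL, *I3 = NULL;
static int *GP = NULL, *GOUT = NULL, *GIN = NULL;
static double vbuf[MAX_RX];

SEXP rx_set_network(SEXP net)
{
    if (net_ref != NULL) R_ReleaseObject(net_ref);
    net_ref = net;
    R_PreserveObject(net_ref);

    SEXP k  = VECTOR_ELT(net, 0);
    SEXP i1 = VECTOR_ELT(net, 1);
    SEXP i2 = VECTOR_ELT(net, 2);
    SEXP i3 = VECTOR_ELT(net, 3);
    SEXP s  = VECTOR_ELT(net, 4);
    SEXP gp = VECTOR_ELT(net, 5);
    SEXP go = VECTOR_ELT(net, 6);
    SEXP gi = VECTOR_ELT(net, 7);

    n_rx = LENGTH(k);
    if (n_rx > MAX_RX) error("too many reactions for compiled RHS");
    n_sp = Rf_nrows(s);
    n_gp = LENGTH(gp);
    K = REAL(k); S = REAL(s);
    I1 = INTEGER(i1); I2 = INTEGER(i2); I3 = INTEGER(i3);
    GP = INTEGER(gp); GOUT = INTEGER(go); GIN = INTEGER(gi);
    return R_NilValue;
}

void rx_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int n = n_sp, m = n_rx;
    for (int j = 0; j < m; j++) {
        double a = (I1[j] <= n) ? y[I1[j] - 1] : 1.0;
        double b = (I2[j] <= n) ? y[I2[j] - 1] : 1.0;
        double c = (I3[j] <= n) ? y[I3[j] - 1] : 1.0;
        vbuf[j] = K[j] * a * b * c;
    }
    for (int g = 0; g < n_gp; g++) {
        int j = GP[g] - 1;
        vbuf[j] = K[j] * (y[GOUT[g] - 1] - y[GIN[g] - 1]);
    }
    for (int s = 0; s < n; s++) ydot[s] = 0.0;
    for (int j = 0; j < m; j++) {
        const double vj = vbuf[j];
        if (vj == 0.0) continue;
        const double *col = S + (size_t) j * n;
        for (int s = 0; s < n; s++) ydot[s] += col[s] * vj;
    }
}

static const R_CallMethodDef call_entries[] = {
    {"rx_set_network", (DL_FUNC) &rx_set_network, 1},
    {NULL, NULL, 0}
};

void R_init_redoxcell(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
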