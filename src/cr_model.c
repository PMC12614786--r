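/* Compiled right-hand side of the consumer-resource system with byproduct
 * leakage, in the deSolve compiled-model convention:
 *
 *   dN_i/dt = N_i [ (1-l) sum_a C[i,a] R_a - m_i ]
 *   dR_a/dt = K_a - R_a (gamma + cons_a) + l sum_b D[a,b] R_b cons_b,
 *             cons_b = sum_i C[i,b] N_i
 *
 * State layout: y = [N_1..N_S, R_1..R_M]. Parameters are staged from R via
 * the .Call routine cr_set_parms as the flat vector
 * [S, M, l, gamma, m (S), K (M), C (S*M, column-major), D (M*M,
 * column-major)], so the integrator can be re-dimensioned per community
 * without re-loading the DLL. The dynamics are stiff (resource turnover is
 * orders of magnitude faster than population change), hence a stiff
 * solver with internally generated difference-quotient Jacobians.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>
#include <string.h>

static double *P = NULL;     /* staged parameter vector */
static double *consbuf = NULL; /* per-resource consumption pressure */
static double *rcbuf = NULL;   /* R_b * cons_b */
static R_xlen_t Pcap = 0;
static int Mcap = 0;
static int gS = 0, gM = 0;

SEXP cr_set_parms(SEXP parms)
{
    R_xlen_t n = XLENGTH(parms);
    double *x = REAL(parms);
    int S, M;

    if (n < 4) error("parameter vector too short");
    S = (int) x[0];
    M = (int) x[1];
    if (S < 0 || M < 1) error("invalid dimensions in parameter vector");
    if (n != 4 + S + M + (R_xlen_t) S * M + (R_xlen_t) M * M)
        error("parameter vector length does not match S=%d, M=%d", S, M);

    if (n > Pcap) {
        free(P);
        P = (double *) malloc(n * sizeof(double));
        if (!P) { Pcap = 0; error("allocation failure"); }
        Pcap = n;
    }
    if (M > Mcap) {
        free(consbuf); free(rcbuf);
        consbuf = (double *) malloc(M * sizeof(double));
        rcbuf = (double *) malloc(M * sizeof(double));
        if (!consbuf || !rcbuf) { Mcap = 0; error("allocation failure"); }
        Mcap = M;
    }
    memcpy(P, x, n * sizeof(double));
    gS = S;
    gM = M;
    return R_NilValue;
}

void cr_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int S = gS, M = gM;
    const double l = P[2], gamma = P[3];
    const double *m = P + 4, *K = m + S, *C = K + M, *D = C + (size_t) S * M;
    const double *N = y, *R = y + S;
    int i, a, b;

    for (i = 0; i < S; i++) {
        double g = 0.0;
        for (a = 0; a < M; a++) g += C[i + (size_t) S * a] * R[a];
        ydot[i] = N[i] * ((1.0 - l) * g - m[i]);
    }
    for (a = 0; a < M; a++) {
        double cons = 0.0;
        for (i = 0; i < S; i++) cons += C[i + (size_t) S * a] * N[i];
        consbuf[a] = cons;
        rcbuf[a] = R[a] * cons;
        ydot[S + a] = K[a] - R[a] * (gamma + cons);
    }
    if (l > 0.0) {
        for (a = 0; a < M; a++) {
            double acc = 0.0;
            for (b = 0; b < M; b++) acc += D[a + (size_t) M * b] * rcbuf[b];
            ydot[S + a] += l * acc;
        }
    }
}

static const R_CallMethodDef call_entries[] = {
    {"cr_set_parms", (DL_FUNC) &cr_set_parms, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"cr_derivs", (DL_FUNC) &cr_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_crinvade(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
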