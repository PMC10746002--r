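/* Compiled right-hand sides for the memristive Hindmarsh-Rose model,
 * consumed by deSolve's compiled-code interface.
 *
 * Parameter vector (set via memhr_init, order fixed on the R side):
 *   a, b, c, d, k, alpha, beta, A1, f1, A2, f2
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[11];
#define P_a     parms[0]
#define P_b     parms[1]
#define P_c     parms[2]
#define P_d     parms[3]
#define P_k     parms[4]
#define P_alpha parms[5]
#define P_beta  parms[6]
#define P_A1    parms[7]
#define P_f1    parms[8]
#define P_A2    parms[9]
#define P_f2    parms[10]

void memhr_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

static double drive(double t)
{
    return P_A1 * sin(2.0 * M_PI * P_f1 * t) + P_A2 * sin(2.0 * M_PI * P_f2 * t);
}

static void model_rhs(double t, const double *y, double *ydot)
{
    double x = y[0], yy = y[1], phi = y[2];
    double W = P_alpha + P_beta * phi * phi;
    ydot[0] = yy + P_a * x * x - P_b * x * x * x + P_k * W * x + drive(t);
    ydot[1] = P_c - P_d * x * x - yy;
    ydot[2] = x - phi;
}

/* state (x, y, phi) */
void memhr_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    model_rhs(*t, y, ydot);
}

/* state + 3x3 tangent matrix, column-major in y[3..11] */
void memhr_var_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    model_rhs(*t, y, ydot);
    double x = y[0], phi = y[2];
    double j11 = 2.0 * P_a * x - 3.0 * P_b * x * x
        + P_k * (P_alpha + P_beta * phi * phi);
    double j13 = 2.0 * P_k * P_beta * phi * x;
    double j21 = -2.0 * P_d * x;
    for (int col = 0; col < 3; col++) {
        double v1 = y[3 + 3 * col];
        double v2 = y[4 + 3 * col];
        double v3 = y[5 + 3 * col];
        ydot[3 + 3 * col] = j11 * v1 + v2 + j13 * v3;
        ydot[4 + 3 * col] = j21 * v1 - v2;
        ydot[5 + 3 * col] = v1 - v3;
    }
}

/* two independent copies with a shared drive (Benettin two-trajectory LE) */
void memhr_pair_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    model_rhs(*t, y, ydot);
    model_rhs(*t, y + 3, ydot + 3);
}

static const R_CMethodDef CEntries[] = {
    {"memhr_init",        (DL_FUNC) &memhr_init,        1},
    {"memhr_derivs",      (DL_FUNC) &memhr_derivs,      6},
    {"memhr_var_derivs",  (DL_FUNC) &memhr_var_derivs,  6},
    {"memhr_pair_derivs", (DL_FUNC) &memhr_pair_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_memhr(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
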