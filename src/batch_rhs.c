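/* Right-hand side of the within-batch dynamics, compiled for speed.
 *
 * State vector (length m + 4p):
 *   y[0 .. m-1]        rho_sigma   biomass densities (active species only)
 *   y[m .. m+p-1]      c_i         nutrient concentrations
 *   y[m+p .. m+2p-1]   I_i         Monod integrals  int c_i/(K_i+c_i) dt
 *   y[m+2p .. m+3p-1]  cons_i      cumulative consumption of nutrient i
 *   y[m+3p .. m+4p-1]  prod_i      cumulative byproduct production of i
 *
 * Parameter block (copied in through deSolve's initfunc):
 *   [0] m, [1] p, [2] thresh (absolute depletion threshold),
 *   [3 .. 3+p-1]              K_i
 *   [3+p .. 3+2p-1]           Y_i
 *   [3+2p .. 3+2p+p*p-1]      Gamma, column-major; Gamma[i,i'] converts
 *                             consumption of i' into production of i
 *   [.. + m*p]                alpha, column-major (species x nutrient)
 *   [.. + p]                  consumable flags (0/1), used by the root fn
 *
 * The block length varies with m and p, and deSolve's initfunc has no way
 * to learn it, so the R wrapper announces the length first via a .C call.
 */

#include <R.h>

#define MAXPARMS 200000
#define MAXNUT 64

static double parms[MAXPARMS];
static int n_parms = 0;

void batch_set_np(int *n)
{
    if (*n > MAXPARMS)
        error("parameter block too large (%d > %d)", *n, MAXPARMS);
    n_parms = *n;
}

void batch_initmod(void (*odeparms)(int *, double *))
{
    odeparms(&n_parms, parms);
}

void batch_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int m = (int) parms[0];
    int p = (int) parms[1];
    const double *K = parms + 3;
    const double *Y = parms + 3 + p;
    const double *G = parms + 3 + 2 * p;
    const double *A = parms + 3 + 2 * p + p * p;
    const double *rho = y;
    const double *c = y + m;
    double monod[MAXNUT], totup[MAXNUT];
    int i, ii, s;

    for (i = 0; i < p; i++) {
        double ci = c[i] > 0.0 ? c[i] : 0.0;
        monod[i] = ci / (K[i] + ci);
    }

    /* total consumption rate of each nutrient */
    for (i = 0; i < p; i++) {
        double tot = 0.0;
        const double *Ai = A + (size_t) m * i;
        for (s = 0; s < m; s++)
            tot += rho[s] * Ai[s];
        totup[i] = monod[i] * tot;
    }

    /* biomass growth: d rho / dt = rho * sum_i Y_i alpha_i monod_i */
    for (s = 0; s < m; s++) {
        double g = 0.0;
        for (i = 0; i < p; i++)
            g += Y[i] * A[s + (size_t) m * i] * monod[i];
        ydot[s] = rho[s] * g;
    }

    for (i = 0; i < p; i++) {
        double prod = 0.0;
        for (ii = 0; ii < p; ii++)
            prod += G[i + p * ii] * totup[ii];
        ydot[m + i] = -totup[i] + prod;
        ydot[m + p + i] = monod[i];
        ydot[m + 2 * p + i] = totup[i];
        ydot[m + 3 * p + i] = prod;
    }
}

/* Terminal event: total remaining consumable nutrient hits the threshold. */
void batch_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    int m = (int) parms[0];
    int p = (int) parms[1];
    double thresh = parms[2];
    const double *cons_flag = parms + 3 + 2 * p + p * p + (size_t) m * p;
    const double *c = y + m;
    double tot = 0.0;
    int i;

    for (i = 0; i < p; i++)
        if (cons_flag[i] > 0.5)
            tot += (c[i] > 0.0 ? c[i] : 0.0);
    gout[0] = tot - thresh;
}
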