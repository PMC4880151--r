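/* Compiled right-hand sides for the two niche-competition models,
 * in the form deSolve expects for its dllname interface.
 *
 * Parameter vector layout (must match .pack_parms() in R/dynamics.R):
 *   0 rho_S  1 delta_S  2 rho_A  3 delta_A  4 rho_L  5 delta_L
 *   6 mu_D   7 mu_T     8 K1     9 K2      10 convergence_norm_tol
 *
 * State ordering is (S, A, D, L, T) throughout the package.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double parms[11];

void hscniche_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

/* model = 1: mass-action A -> D flux delta_A * A
 * model = 2: flux damped by differentiated-cell feedback, delta_A * A / (1 + D)
 */
static void niche_rhs(int model, const double *y, double *ydot)
{
    const double S = y[0], A = y[1], D = y[2], L = y[3], T = y[4];
    const double Z2 = A + L;
    const double flux = (model == 2) ? parms[3] * A / (1.0 + D) : parms[3] * A;

    ydot[0] = parms[0] * S * (parms[8] - S) - parms[1] * S;
    ydot[1] = parms[1] * S + parms[2] * A * (parms[9] - Z2) - flux;
    ydot[2] = flux - parms[6] * D;
    ydot[3] = parms[4] * L * (parms[9] - Z2) - parms[5] * L;
    ydot[4] = parms[5] * L - parms[7] * T;
}

void hscniche_derivs1(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    niche_rhs(1, y, ydot);
}

void hscniche_derivs2(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    niche_rhs(2, y, ydot);
}

/* Root functions: max-norm of the right-hand side minus the convergence
 * tolerance.  lsodar stops the integration when this crosses zero, i.e.
 * at the first instant the trajectory satisfies the steady-state
 * criterion ||f(x)||_inf < tol. */
static double resid_root(int model, const double *y)
{
    double f[5], m = 0.0;
    int i;
    niche_rhs(model, y, f);
    for (i = 0; i < 5; i++)
        if (fabs(f[i]) > m) m = fabs(f[i]);
    return m - parms[10];
}

void hscniche_root1(int *neq, double *t, double *y, int *ng,
                    double *gout, double *out, int *ip)
{
    gout[0] = resid_root(1, y);
}

void hscniche_root2(int *neq, double *t, double *y, int *ng,
                    double *gout, double *out, int *ip)
{
    gout[0] = resid_root(2, y);
}
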