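/* Compiled right-hand side of the TRT + CAR-T tumor model for deSolve.
 *
 * State y = (N_T, N_R, N_C):
 *   dN_T/dt = rho*N_T - kRxT*N_T - k1*N_T*N_C
 *   dN_R/dt = kRxT*N_T - k1*N_R*N_C - kcl*N_R
 *   dN_C/dt = k2*(N_T+N_R)*N_C - kRxC*N_C - theta*N_C
 *
 * kRx_i sums the decaying dose-rate kill term of every TRT administration
 * already delivered (the R caller restarts integration at administration
 * times, so only events with day <= segment start are passed as active):
 *   kRx_i = alpha_i*R0*exp(-lam*dt)
 *         + 2*beta_i*R0^2*(exp(-2*lam*dt) - exp(-(lam+gamma)*dt))/(gamma-lam)
 * with dt = t - t_TRT and R0 = eta * activity(uCi) resolved by the caller.
 *
 * Parameter vector layout (0-based):
 *   0 rho, 1 k1, 2 k2, 3 theta, 4 kcl, 5 alphaT, 6 alphaC, 7 lam,
 *   8 betaT, 9 betaC, 10 gamma, 11 n_trt (active administrations),
 *   12..27 TRT days, 28..43 TRT R0 (Gy/day), 44 root threshold on burden
 *   (<= 0 disables the root function).
 */

#include <R.h>
#include <math.h>

#define CARTRT_NMAX 16
#define CARTRT_NPAR (12 + 2 * CARTRT_NMAX + 1)

static double parms[CARTRT_NPAR];

void cartrt_initmod(void (*odeparms)(int *, double *))
{
    int N = CARTRT_NPAR;
    odeparms(&N, parms);
}

static void kill_rates(double t, double *kT, double *kC)
{
    const double lam = parms[7], gamma = parms[10];
    const int n = (int)(parms[11] + 0.5);
    double sum_lin = 0.0, sum_quad = 0.0;
    int i;

    for (i = 0; i < n && i < CARTRT_NMAX; i++) {
        double dt = t - parms[12 + i];
        double R0 = parms[28 + i];
        if (dt < 0.0 || R0 <= 0.0)
            continue;
        sum_lin += R0 * exp(-lam * dt);
        if ((parms[8] > 0.0 || parms[9] > 0.0) && gamma != lam)
            sum_quad += 2.0 * R0 * R0 *
                (exp(-2.0 * lam * dt) - exp(-(lam + gamma) * dt)) /
                (gamma - lam);
    }
    *kT = parms[5] * sum_lin + parms[8] * sum_quad;
    *kC = parms[6] * sum_lin + parms[9] * sum_quad;
}

void cartrt_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double rho = parms[0], k1 = parms[1], k2 = parms[2];
    const double theta = parms[3], kcl = parms[4];
    double kT, kC;

    kill_rates(*t, &kT, &kC);
    ydot[0] = rho * y[0] - kT * y[0] - k1 * y[0] * y[2];
    ydot[1] = kT * y[0] - k1 * y[1] * y[2] - kcl * y[1];
    ydot[2] = k2 * (y[0] + y[1]) * y[2] - kC * y[2] - theta * y[2];
}

/* Root: total burden N_T + N_R hits the configured threshold. */
void cartrt_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = y[0] + y[1] - parms[44];
}
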