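/* Compiled right-hand side of the consumer-resource system for deSolve.
 * State y = (T, N); parms = (e, a, b, d_T, r0, K_N). */
#include <R.h>

static double cr_parms[6];

void initmod_cr(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, cr_parms);
}

void derivs_cr(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double e = cr_parms[0], a = cr_parms[1], b = cr_parms[2];
    double dT = cr_parms[3], r0 = cr_parms[4], KN = cr_parms[5];
    double T = y[0], N = y[1];
    double fr = a * N / (N + b); /* type II functional response */
    ydot[0] = e * fr * T - dT * T;
    ydot[1] = r0 * N * (1.0 - N / KN) - fr * T;
}
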