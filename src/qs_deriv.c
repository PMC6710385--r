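/* Right-hand sides of the AI-2 quorum-sensing ODEs, compiled for deSolve.
 *
 * State y = (A, L): extracellular AI-2 activity and lsr operon expression.
 * Cell density X(t) is the closed-form Gompertz curve, never integrated.
 *
 * Parameter vectors are filled from R via the deSolve initfunc protocol;
 * the orderings here must match the ones built in R/simulate.R.
 */
#include <math.h>
#include <R.h>

/* ---- single culture: parms = X0 C B M kA km1 n1 kXA km2 n2 kLA Xdelta kL km3 n3 kAL kR ---- */

static double sp[17];

void qsdyn_init(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, sp);
}

static double hill(double x, double n, double km)
{
    double xn = pow(x, n);
    return xn / (xn + pow(km, n));
}

void qsdyn_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double X0 = sp[0], C = sp[1], B = sp[2], M = sp[3];
    double kA = sp[4], km1 = sp[5], n1 = sp[6];
    double kXA = sp[7], km2 = sp[8], n2 = sp[9];
    double kLA = sp[10], Xd = sp[11];
    double kL = sp[12], km3 = sp[13], n3 = sp[14];
    double kAL = sp[15], kR = sp[16];

    double X = X0 + C * exp(-exp(-B * (*t - M)));
    double A = y[0], L = y[1];

    double muA  = kA * hill(X, n1, km1);
    double muXA = kXA * hill(X, n2, km2) * A;
    double muLA = kLA * (X / Xd) * A * L;
    double muL  = kL * hill(X, n3, km3) * A;
    double muAL = kAL * (X / Xd) * A * L;
    double muR  = kR * L;

    ydot[0] = muA - muXA - muLA;
    ydot[1] = muL + muAL - muR;
}

/* ---- co-culture: parms = X0 B M Cw Cko koBase kA km1 n1 kXA km2 n2 kLA Xdelta kL km3 n3 kAL kR
 *
 * Wild strain:     Xw(t)  = X0 + Cw * g(t)
 * LuxS- knockout:  Xko(t) = koBase + Cko * g(t),  g(t) = exp(-exp(-B(t-M)))
 * koBase carries the pre-cultured inoculum (X0 when there is no pre-culture).
 * The knockout produces no AI-2 but consumes it through PTS and LsrACDB;
 * operon expression tracks the wild strain only.
 */

static double cp[19];

void qsdyn_cocult_init(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, cp);
}

void qsdyn_cocult_derivs(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double X0 = cp[0], B = cp[1], M = cp[2];
    double Cw = cp[3], Cko = cp[4], koBase = cp[5];
    double kA = cp[6], km1 = cp[7], n1 = cp[8];
    double kXA = cp[9], km2 = cp[10], n2 = cp[11];
    double kLA = cp[12], Xd = cp[13];
    double kL = cp[14], km3 = cp[15], n3 = cp[16];
    double kAL = cp[17], kR = cp[18];

    double g = exp(-exp(-B * (*t - M)));
    double Xw = X0 + Cw * g;
    double Xko = koBase + Cko * g;
    double A = y[0], L = y[1];

    double muA    = kA * hill(Xw, n1, km1);
    double muXA   = kXA * hill(Xw, n2, km2) * A;
    double muXAko = kXA * hill(Xko, n2, km2) * A;
    double muLA   = kLA * (Xw / Xd) * A * L;
    double muLAko = kLA * (Xko / Xd) * A * L;
    double muL    = kL * hill(Xw, n3, km3) * A;
    double muAL   = kAL * (Xw / Xd) * A * L;
    double muR    = kR * L;

    ydot[0] = muA - (muXA + muXAko + muLA + muLAko);
    ydot[1] = muL + muAL - muR;
}
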