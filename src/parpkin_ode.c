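/* Mass-action right-hand side for the PARP1-DNA binding schemes,
 * in the deSolve compiled-model convention.
 *
 * State (nM):  y0 P      free protein
 *              y1 Dstar  free labeled DNA
 *              y2 D      free unlabeled competitor DNA (site units)
 *              y3 PDstar binary complex with labeled DNA
 *              y4 PD     binary complex with competitor DNA
 *              y5 T      ternary complex Dstar.P.D
 *
 * Parameters (nM^-1 s^-1 or s^-1): a generic 8-vector that encodes all
 * three schemes; unused steps carry zero rate constants.
 *   p0 k1    P + Dstar -> PDstar        p1 km1  PDstar -> P + Dstar
 *   p2 k1p   P + D     -> PD            p3 km1p PD     -> P + D
 *   p4 k2    PDstar + D -> T            p5 km2  T -> PDstar + D
 *   p6 k3    T -> PD + Dstar            p7 km3  PD + Dstar -> T
 */
#include <R.h>

static double parms[8];

void pk_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void pk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double P = y[0], Ds = y[1], D = y[2], PDs = y[3], PD = y[4], T = y[5];
    double v1 = parms[0] * P * Ds - parms[1] * PDs;
    double v2 = parms[2] * P * D - parms[3] * PD;
    double v3 = parms[4] * PDs * D - parms[5] * T;
    double v4 = parms[7] * PD * Ds - parms[6] * T;

    ydot[0] = -v1 - v2;
    ydot[1] = -v1 - v4;
    ydot[2] = -v2 - v3;
    ydot[3] =  v1 - v3;
    ydot[4] =  v2 - v4;
    ydot[5] =  v3 + v4;
}
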