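/* 20-state mass-action kinetics of tetramer oxygen binding with a single
 * quaternary-selective drug site.
 *
 * State layout (0-based): y[0..4] = R0..R4, y[5..9] = T0..T4,
 * y[10..14] = R0X..R4X, y[15..19] = T0X..T4X (trailing X = drug bound,
 * digit = oxygens bound).
 *
 * Parameters (31):
 *   0 kbR  1 kdR  2 kbT  3 kdT        per-heme oxygen rates
 *   4 kRbX 5 kRdX 6 kTbX 7 kTdX       drug rates
 *   8..12  kRT[i]   13..17 kTR[i]     quaternary, drug-free, i = ligation
 *   18..22 kRTX[i]  23..27 kTRX[i]    quaternary, drug-bound
 *   28 X_parm  29 vf  30 mass_balance flag
 *
 * One forcing: free oxygen x(t), mM. Free drug is either X_parm directly
 * (mass_balance = 0) or X_parm - vf * sum(drug-bound species).
 */
#include <R.h>

static double parms[31];
static double forc[1];

#define kbR   parms[0]
#define kdR   parms[1]
#define kbT   parms[2]
#define kdT   parms[3]
#define kRbX  parms[4]
#define kRdX  parms[5]
#define kTbX  parms[6]
#define kTdX  parms[7]
#define kRT(i)  parms[8 + (i)]
#define kTR(i)  parms[13 + (i)]
#define kRTX(i) parms[18 + (i)]
#define kTRX(i) parms[23 + (i)]
#define XPARM parms[28]
#define VF    parms[29]
#define MBAL  parms[30]
#define XO2   forc[0]

void mwc_initmod(void (*odeparms)(int *, double *))
{
    int n = 31;
    odeparms(&n, parms);
}

void mwc_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void mwc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double x = XO2;
    double X = XPARM;
    int i, c;

    if (MBAL > 0.5) {
        double bound = 0.0;
        for (i = 10; i < 20; i++) bound += y[i];
        X = XPARM - VF * bound;
    }

    for (i = 0; i < 20; i++) ydot[i] = 0.0;

    /* oxygen ladder within each of the four conformational columns;
     * statistical factor (4 - i) for binding to an i-ligated state,
     * i for dissociation from it */
    for (c = 0; c < 4; c++) {
        int off = 5 * c;
        double kb = (c % 2 == 0) ? kbR : kbT;
        double kd = (c % 2 == 0) ? kdR : kdT;
        for (i = 0; i < 4; i++) {
            double flow = (4 - i) * kb * y[off + i] * x
                        - (i + 1) * kd * y[off + i + 1];
            ydot[off + i]     -= flow;
            ydot[off + i + 1] += flow;
        }
    }

    /* quaternary exchange, same ligation and drug occupancy */
    for (i = 0; i < 5; i++) {
        double flow = kRT(i) * y[i] - kTR(i) * y[5 + i];
        ydot[i]     -= flow;
        ydot[5 + i] += flow;
        double flowX = kRTX(i) * y[10 + i] - kTRX(i) * y[15 + i];
        ydot[10 + i] -= flowX;
        ydot[15 + i] += flowX;
    }

    /* drug binding / dissociation, bimolecular in free drug */
    for (i = 0; i < 5; i++) {
        double bR = kRbX * y[i] * X - kRdX * y[10 + i];
        ydot[i]      -= bR;
        ydot[10 + i] += bR;
        double bT = kTbX * y[5 + i] * X - kTdX * y[15 + i];
        ydot[5 + i]  -= bT;
        ydot[15 + i] += bT;
    }
}
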