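/* Compiled right-hand side of the two-compartment CA3 neuron with
 * extracellular resistive coupling, in the deSolve compiled-model
 * interface. State ordering: Vs, Vd, h, n, s, c, q, Ca, Si, Wi.
 * Voltages are in the model frame (reference -60 mV); time in ms.
 */
#include <R.h>
#include <math.h>

static double parms[26];
#define P_SOMA  parms[0]
#define CM      parms[1]
#define GC      parms[2]
#define GL      parms[3]
#define GNA     parms[4]
#define GKDR    parms[5]
#define GCA     parms[6]
#define GKAHP   parms[7]
#define GKC     parms[8]
#define GNMDA   parms[9]
#define GAMPA   parms[10]
#define VNA     parms[11]
#define VCA     parms[12]
#define VK      parms[13]
#define VL      parms[14]
#define VSYN    parms[15]
#define IS      parms[16]
#define ID      parms[17]
#define RIN     parms[18]
#define ROUT    parms[19]
#define RTD     parms[20]
#define RSG     parms[21]
#define AMP     parms[22]
#define FREQ    parms[23]
#define SYNSELF parms[24]
#define FLDSOMA parms[25]   /* 1: VDSout drives the somatic coupling term
                               only; 0: symmetric (both compartments) */

void prfield_init(void (*odeparms)(int *, double *))
{
    int n = 26;
    odeparms(&n, parms);
}

/* k*(x)/(exp(x/b)-1) with its analytic limit k*b at x = 0 */
static double vtrap(double k, double x, double b)
{
    double u = x / b;
    if (fabs(u) < 1e-7)
        return k * b * (1.0 - 0.5 * u);
    return k * b * u / expm1(u);
}

void prfield_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double Vs = y[0], Vd = y[1], h = y[2], n = y[3], s = y[4];
    double c = y[5], q = y[6], Ca = y[7], Si = y[8], Wi = y[9];

    /* field source and quasi-static extracellular voltage: closed form of
     * the two-loop Kirchhoff system with source-loop access resistance
     * S = RTD + RSG */
    double Ve = AMP * sin(2.0 * M_PI * FREQ * (*t) / 1000.0);
    double S = RTD + RSG;
    double VDSout = ROUT * (S * (Vs - Vd) + RIN * Ve) /
        ((RIN + ROUT) * (S + ROUT) - ROUT * ROUT);

    /* gating rates */
    double am = vtrap(0.32, 13.1 - Vs, 4.0);
    double bm = vtrap(0.28, Vs - 40.1, 5.0);
    double ah = 0.128 * exp((17.0 - Vs) / 18.0);
    double bh = 4.0 / (1.0 + exp((40.0 - Vs) / 5.0));
    double an = vtrap(0.016, 35.1 - Vs, 5.0);
    double bn = 0.25 * exp(0.5 - 0.025 * Vs);
    double as = 1.6 / (1.0 + exp(-0.072 * (Vd - 65.0)));
    double bs = vtrap(0.02, Vd - 51.1, 5.0);
    double ac, bc;
    if (Vd <= 50.0) {
        ac = exp((Vd - 10.0) / 11.0 - (Vd - 6.5) / 27.0) / 18.975;
        bc = 2.0 * exp((6.5 - Vd) / 27.0) - ac;
        if (bc < 0.0) bc = 0.0;  /* clamp: keeps c within [0,1] near the split */
    } else {
        ac = 2.0 * exp((6.5 - Vd) / 27.0);
        bc = 0.0;
    }
    double aq = 0.00002 * Ca;
    if (aq > 0.01) aq = 0.01;
    double bq = 0.001;

    double minf = am / (am + bm);
    double chi = Ca / 250.0;
    if (chi > 1.0) chi = 1.0;

    /* currents (uA/cm^2) */
    double Isleak = GL * (Vs - VL);
    double Idleak = GL * (Vd - VL);
    double INa    = GNA * minf * minf * h * (Vs - VNA);
    double IKDR   = GKDR * n * (Vs - VK);
    double ICa    = GCA * s * s * (Vd - VCA);
    double IKAHP  = GKAHP * q * (Vd - VK);
    double IKC    = GKC * c * chi * (Vd - VK);
    double Isyn   = 0.0;
    if (SYNSELF > 0.5) {
        double INMDA = GNMDA * Si /
            (1.0 + 0.28 * exp(-0.062 * (Vd - 60.0))) * (Vd - VSYN);
        double IAMPA = GAMPA * Wi * (Vd - VSYN);
        Isyn = INMDA + IAMPA;
    }
    double IDSin_s = GC * (Vd + VDSout - Vs);
    double IDSin_d = (FLDSOMA > 0.5) ? GC * (Vd - Vs) : IDSin_s;

    ydot[0] = (-Isleak - INa - IKDR + IDSin_s / P_SOMA + IS / P_SOMA) / CM;
    ydot[1] = (-Idleak - ICa - IKAHP - IKC - Isyn
               - IDSin_d / (1.0 - P_SOMA) + ID / (1.0 - P_SOMA)) / CM;
    ydot[2] = ah * (1.0 - h) - bh * h;
    ydot[3] = an * (1.0 - n) - bn * n;
    ydot[4] = as * (1.0 - s) - bs * s;
    ydot[5] = ac * (1.0 - c) - bc * c;
    ydot[6] = aq * (1.0 - q) - bq * q;
    ydot[7] = -0.13 * ICa - 0.075 * Ca;
    if (SYNSELF > 0.5) {
        ydot[8] = (Vs >= 10.0 ? 1.0 : 0.0) - Si / 150.0;
        ydot[9] = (Vs >= 20.0 ? 1.0 : 0.0) - Wi / 2.0;
    } else {
        ydot[8] = -Si / 150.0;
        ydot[9] = -Wi / 2.0;
    }
}
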