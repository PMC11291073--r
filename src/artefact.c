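/* Coupled cell + pipette + amplifier derivatives for the voltage-clamp
 * artefact model, in the deSolve compiled-model calling convention.
 *
 * Units: mV, ms, MOhm, nF, nA, uS (MOhm * nF = ms; nF * mV/ms = nA).
 *
 * Parameter vector layout (see .vc_parms() on the R side, kept in lock-step):
 *   0 alpha_R    1 alpha_P    2 Rs_est     3 Cm_est(nF)  4 Cp_est(nF)
 *   5 tau_sum    6 tau_clamp  7 tau_z      8 Rs          9 Cm(nF)
 *  10 Cp(nF)    11 gleak     12 Eleak     13 Voff       14 Vcmd
 *  15 model id (0 = model cell, 1 = HH INa, 2 = none)
 *  16.. ionic model parameters:
 *    model cell: 16 Rk, 17 Ck(nF), 18 Rm
 *    HH INa:     16 g_max, 17 E_Na, 18 act_vhalf, 19 act_slope,
 *                20 inact_vhalf, 21 inact_slope,
 *                22-25 tau_m (min, amp, vmid, sigma),
 *                26-29 tau_h, 30-33 tau_j
 *
 * State vector: 0 Vm, 1 Vp, 2 Vclamp, 3 Vest, 4 Iout, 5.. ionic states
 * (model cell: 5 Ik; HH INa: 5 m, 6 h, 7 j).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 34

static double p[N_PARMS];

void vc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double bell_tau(double v, const double *q)
{
    /* q = (min, amp, vmid, sigma); amp scales a sech-type bell */
    double z = (v - q[2]) / q[3];
    return q[0] + q[1] / (exp(z) + exp(-z));
}

void vc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double aR = p[0], aP = p[1], Rse = p[2], Cme = p[3], Cpe = p[4];
    double tsum = p[5], tclamp = p[6], tz = p[7];
    double Rs = p[8], Cm = p[9], Cp = p[10];
    double gleak = p[11], Eleak = p[12], Voff = p[13], Vcmd = p[14];
    int model = (int) p[15];

    double Vm = y[0], Vp = y[1], Vclamp = y[2], Vest = y[3], Iout = y[4];

    /* supercharging estimate of the membrane potential */
    double dVest = (Vcmd - Vest) / ((1.0 - aP) * Rse * Cme);

    /* series-resistance compensation + supercharging feed-forward */
    double Vcmd_p = Vcmd + Rse * (aR * Iout + aP * Cme * dVest);

    double dVclamp = (Vcmd_p - Vclamp) / tsum;
    double dVp = (Vclamp - Vp) / tclamp;

    double Iion;
    if (model == 0) {
        Iion = y[5] + Vm / p[18];
    } else if (model == 1) {
        double m = y[5], h = y[6], j = y[7];
        Iion = p[16] * m * m * m * h * j * (Vm - p[17]);
    } else {
        Iion = 0.0;
    }

    double Ileak = gleak * (Vm - Eleak);
    double dVm = (Vp + Voff - Vm) / (Rs * Cm) - (Iion + Ileak) / Cm;

    /* pipette/membrane capacitive currents minus the machine's estimates */
    double Iin = Iion + Ileak
        + Cp * dVp - Cpe * dVclamp
        + Cm * dVm - Cme * dVest;

    ydot[0] = dVm;
    ydot[1] = dVp;
    ydot[2] = dVclamp;
    ydot[3] = dVest;
    ydot[4] = (Iin - Iout) / tz;

    if (model == 0) {
        /* series RC branch; needs dVm/dt from the same evaluation */
        ydot[5] = (p[17] * dVm - y[5]) / (p[16] * p[17]);
    } else if (model == 1) {
        double minf = 1.0 / (1.0 + exp(-(Vm - p[18]) / p[19]));
        double hinf = 1.0 / (1.0 + exp((Vm - p[20]) / p[21]));
        ydot[5] = (minf - y[5]) / bell_tau(Vm, p + 22);
        ydot[6] = (hinf - y[6]) / bell_tau(Vm, p + 26);
        ydot[7] = (hinf - y[7]) / bell_tau(Vm, p + 30);
    }

    if (ip[0] >= 2) {
        yout[0] = Iion;
        yout[1] = Iin;
    }
}
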