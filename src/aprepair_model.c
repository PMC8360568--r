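/* Surrogate ventricular action-potential model: Hodgkin-Huxley style gates,
 * fixed intracellular Na+/K+, and a two-compartment (cytosol/SR) calcium
 * subsystem. Each membrane current I_i = rho_i * J_i enters through a single
 * effective conductance geff_i = rho_i * g0_i * F_i supplied from R, where
 * F_i is the multiplicative drug combination factor (1 without drugs).
 *
 * deSolve compiled-model interface: aprep_initmod() receives the parameter
 * vector, aprep_derivs() evaluates the RHS and reports the 12 instantaneous
 * currents (A/F) as auxiliary outputs.
 *
 * State layout (must match R side):
 *  0 v     membrane potential (mV)
 *  1 m     I_Na activation
 *  2 h     I_Na fast inactivation
 *  3 j     I_Na slow inactivation
 *  4 hL    I_NaL inactivation
 *  5 d     I_CaL activation
 *  6 f     I_CaL voltage inactivation
 *  7 xr1   I_Kr activation (inactivation xKr2 is instantaneous)
 *  8 xs    I_Ks activation
 *  9 s     I_to inactivation (activation instantaneous)
 * 10 y     I_f activation
 * 11 cai   cytosolic Ca2+ (mM)
 * 12 casr  SR Ca2+ (mM)
 *
 * Parameter layout (see model_parms() on the R side):
 *  0 stim_amp  1 stim_start  2 stim_dur  3 xkr2_vshift  4 xkr2_slope
 *  5..16 geff: Na NaL CaL Kr Ks K1 to f NaCa NaK bCl bCa
 * 17 E_Na 18 E_K 19 E_CaL 20 E_f 21 E_Cl
 * 22 naca_a 23 ksat 24 kCa
 * 25 Vmaxup 26 Kup 27 krel 28 kleak 29 vc_vsr
 * 30 Bufc 31 Kbufc 32 Bufsr 33 Kbufsr 34 fca_k 35 cao
 */

#include <math.h>

#define NPARMS 36
static double parms[NPARMS];

#define stim_amp    parms[0]
#define stim_start  parms[1]
#define stim_dur    parms[2]
#define xkr2_vshift parms[3]
#define xkr2_slope  parms[4]
#define g_Na        parms[5]
#define g_NaL       parms[6]
#define g_CaL       parms[7]
#define g_Kr        parms[8]
#define g_Ks        parms[9]
#define g_K1        parms[10]
#define g_to        parms[11]
#define g_f         parms[12]
#define g_NaCa      parms[13]
#define g_NaK       parms[14]
#define g_bCl       parms[15]
#define g_bCa       parms[16]
#define E_Na        parms[17]
#define E_K         parms[18]
#define E_CaL       parms[19]
#define E_f         parms[20]
#define E_Cl        parms[21]
#define naca_a      parms[22]
#define ksat        parms[23]
#define kCa         parms[24]
#define Vmaxup      parms[25]
#define Kup         parms[26]
#define krel        parms[27]
#define kleak       parms[28]
#define vc_vsr      parms[29]
#define Bufc        parms[30]
#define Kbufc       parms[31]
#define Bufsr       parms[32]
#define Kbufsr      parms[33]
#define fca_k       parms[34]
#define cao         parms[35]

static const double VT = 26.7; /* RT/F at 37C, mV */

void aprep_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double sig(double x) { return 1.0 / (1.0 + exp(x)); }

void aprep_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double v = y[0], m = y[1], h = y[2], j = y[3], hL = y[4];
    double d = y[5], f = y[6], xr1 = y[7], xs = y[8], s = y[9], yf = y[10];
    double cai = y[11], casr = y[12];
    if (cai < 1e-7) cai = 1e-7;
    if (casr < 1e-5) casr = 1e-5;

    /* instantaneous gates */
    double mL_inf  = sig(-(v + 42.0) / 5.0);
    double xkr2    = sig((v + 70.0 - xkr2_vshift) / xkr2_slope);
    double r_inf   = sig(-(v - 5.0) / 9.0);
    double k1_inf  = sig((v - E_K - 10.0) / 12.0);
    double fca     = 1.0 / (1.0 + (cai / fca_k) * (cai / fca_k));
    double E_Ca    = 0.5 * VT * log(cao / cai);

    /* membrane currents (A/F, outward positive) */
    double I_Na   = g_Na  * m * m * m * h * j * (v - E_Na);
    double I_NaL  = g_NaL * mL_inf * hL * (v - E_Na);
    double I_CaL  = g_CaL * d * f * fca * (v - E_CaL);
    double I_Kr   = g_Kr  * xr1 * xkr2 * (v - E_K);
    double I_Ks   = g_Ks  * xs * xs * (v - E_K);
    double I_K1   = g_K1  * k1_inf * (v - E_K);
    double I_to   = g_to  * r_inf * s * (v - E_K);
    double I_f    = g_f   * yf * (v - E_f);
    double e1     = exp(0.35 * v / VT), e2 = exp(-0.65 * v / VT);
    double I_NaCa = g_NaCa * (e1 * naca_a - e2 * cai) / (1.0 + ksat * e2);
    double I_NaK  = g_NaK / (1.0 + 0.1245 * exp(-0.1 * v / VT)
                                 + 0.0353 * exp(-v / VT));
    double I_bCl  = g_bCl * (v - E_Cl);
    double I_bCa  = g_bCa * (v - E_Ca);

    double I_sum = I_Na + I_NaL + I_CaL + I_Kr + I_Ks + I_K1 + I_to + I_f
                 + I_NaCa + I_NaK + I_bCl + I_bCa;

    double I_stim = 0.0;
    if (*t >= stim_start && *t < stim_start + stim_dur) I_stim = stim_amp;

    ydot[0] = -I_sum + I_stim;

    /* HH gate kinetics: dy/dt = (y_inf - y)/tau(v) */
    double m_inf  = sig(-(v + 40.0) / 6.0);
    double tau_m  = 0.05 + 0.15 * sig((v + 35.0) / 6.0);
    double h_inf  = sig((v + 70.0) / 6.0);
    double tau_h  = 0.25 + 8.0 * sig((v + 55.0) / 7.0);
    double tau_j  = 2.0 + 80.0 * sig((v + 55.0) / 7.0);
    double hL_inf = sig((v + 91.0) / 6.1);
    double d_inf  = sig(-(v + 8.0) / 6.5);
    double vd     = (v + 10.0) / 30.0;
    double tau_d  = 0.5 + 2.5 * exp(-vd * vd);
    double f_inf  = sig((v + 24.0) / 5.5);
    double vf     = (v + 30.0) / 25.0;
    double tau_f  = 25.0 + 300.0 * exp(-vf * vf);
    double x1_inf = sig(-(v + 15.0) / 7.0);
    double vx     = (v + 30.0) / 30.0;
    double tau_x1 = 50.0 + 350.0 * exp(-vx * vx);
    double xs_inf = sig(-(v - 5.0) / 14.0);
    double vs     = (v + 10.0) / 60.0;
    double tau_xs = 300.0 + 700.0 * exp(-vs * vs);
    double s_inf  = sig((v + 38.0) / 6.0);
    double vss    = (v + 45.0) / 20.0;
    double tau_s  = 20.0 + 80.0 * exp(-vss * vss);
    double y_inf  = sig((v + 85.0) / 9.0);
    double tau_y  = 700.0;

    ydot[1]  = (m_inf - m) / tau_m;
    ydot[2]  = (h_inf - h) / tau_h;
    ydot[3]  = (h_inf - j) / tau_j;
    ydot[4]  = (hL_inf - hL) / 200.0;
    ydot[5]  = (d_inf - d) / tau_d;
    ydot[6]  = (f_inf - f) / tau_f;
    ydot[7]  = (x1_inf - xr1) / tau_x1;
    ydot[8]  = (xs_inf - xs) / tau_xs;
    ydot[9]  = (s_inf - s) / tau_s;
    ydot[10] = (y_inf - yf) / tau_y;

    /* calcium subsystem (mM, instantaneous buffering) */
    double J_up   = Vmaxup / (1.0 + (Kup / cai) * (Kup / cai));
    double J_rel  = krel * d * f * (casr - cai);
    double J_leak = kleak * (casr - cai);
    double bufc   = 1.0 / (1.0 + Bufc * Kbufc / ((cai + Kbufc) * (cai + Kbufc)));
    double bufsr  = 1.0 / (1.0 + Bufsr * Kbufsr / ((casr + Kbufsr) * (casr + Kbufsr)));

    ydot[11] = bufc * (-(I_CaL + I_bCa - 2.0 * I_NaCa) * kCa
                       + J_rel + J_leak - J_up);
    ydot[12] = bufsr * vc_vsr * (J_up - J_rel - J_leak);

    if (ip[0] >= 12) {
        yout[0] = I_Na;  yout[1] = I_NaL;  yout[2] = I_CaL;  yout[3] = I_Kr;
        yout[4] = I_Ks;  yout[5] = I_K1;   yout[6] = I_to;   yout[7] = I_f;
        yout[8] = I_NaCa; yout[9] = I_NaK; yout[10] = I_bCl; yout[11] = I_bCa;
    }
}
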