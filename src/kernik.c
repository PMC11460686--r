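/* Conductance-scalable iPSC-CM right-hand side (Kernik 2019 formulation).
 *
 * 22 states, units: t ms, V mV, concentrations mM, currents pA/pF.
 * State order (must match STATE_NAMES on the R side):
 *   0 V, 1 Ca_SR, 2 Cai, 3 Nai, 4 Ki,
 *   5 d, 6 f, 7 fCa,            (I_CaL gates)
 *   8 Xr1, 9 Xr2,               (I_Kr)
 *  10 Xs,                       (I_Ks)
 *  11 h, 12 j, 13 m,            (I_Na)
 *  14 Xf,                       (I_f)
 *  15 s, 16 r,                  (I_to)
 *  17 dCaT, 18 fCaT,            (I_CaT)
 *  19 R_ryr, 20 O_ryr, 21 I_ryr (SR release)
 *
 * Parameters (20 doubles, set through deSolve's initfunc):
 *   0..15 dimensionless multipliers on the 16 maximal conductances/fluxes,
 *         order: g_Na, g_f, g_CaL, g_CaT, g_to, g_Kr, g_Ks, g_K1,
 *                g_NaK, g_NaCa, g_PCa, g_bNa, g_bCa, g_up, g_leak, g_rel
 *   16 Nao (mM), 17 Cao (mM), 18 Ko (mM), 19 stimulus amplitude (pA/pF,
 *      applied as an inward current while nonzero; pulse windows are
 *      handled by piecewise integration on the R side).
 *
 * Optional outputs (nout = 16): the 16 scaled currents/fluxes in the
 * registry order I_Na, I_f, I_CaL, I_CaT, I_to, I_Kr, I_Ks, I_K1, I_NaK,
 * I_NaCa, I_PCa, I_bNa, I_bCa, J_up, J_leak, J_rel.
 */

#include <R.h>
#include <math.h>

static double parms[20];

#define S_NA    parms[0]
#define S_F     parms[1]
#define S_CAL   parms[2]
#define S_CAT   parms[3]
#define S_TO    parms[4]
#define S_KR    parms[5]
#define S_KS    parms[6]
#define S_K1    parms[7]
#define S_NAK   parms[8]
#define S_NACA  parms[9]
#define S_PCA   parms[10]
#define S_BNA   parms[11]
#define S_BCA   parms[12]
#define S_UP    parms[13]
#define S_LEAK  parms[14]
#define S_REL   parms[15]
#define P_NAO   parms[16]
#define P_CAO   parms[17]
#define P_KO    parms[18]
#define P_STIM  parms[19]

void kernik_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

/* generalized two-exponential gate: alpha = x1*exp(V/x2),
 * beta = (x5*x1)*exp(V/x4) with x4 = 1/(1/x2 + 1/x6);
 * inf = a/(a+b), tau = 1/(a+b) + offset */
static void gate_ab(double V, double x1, double x2, double x5, double x6,
                    double off, double *inf, double *tau)
{
    double x3 = x5 * x1;
    double x4 = 1.0 / (1.0 / x2 + 1.0 / x6);
    double a = x1 * exp(V / x2);
    double b = x3 * exp(V / x4);
    *inf = a / (a + b);
    *tau = 1.0 / (a + b) + off;
}

void kernik_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    /* physical constants and cell geometry */
    const double F    = 96.4853415;           /* C/mmol */
    const double Rg   = 8.314472;             /* J/(mol K) */
    const double T    = 310.0;                /* K */
    const double RTF  = Rg * T / F;           /* 26.712 mV */
    const double FRT  = 1.0 / RTF;
    const double Cm   = 60.0;                 /* pF */
    const double Vtot = 3960.0;               /* um^3 */
    const double Vc   = Vtot * (16404.0 / 17498.0);
    const double Vsr  = Vtot * (1094.0 / 17498.0);

    const double Nao = P_NAO, Cao = P_CAO, Ko = P_KO;

    double V    = y[0];
    double CaSR = y[1];
    double Cai  = y[2];
    double Nai  = y[3];
    double Ki   = y[4];
    double d    = y[5],  f    = y[6],  fCa  = y[7];
    double Xr1  = y[8],  Xr2  = y[9];
    double Xs   = y[10];
    double h    = y[11], j    = y[12], m    = y[13];
    double Xf   = y[14];
    double s    = y[15], r    = y[16];
    double dCaT = y[17], fCaT = y[18];
    double Rr   = y[19], Or   = y[20], Ir   = y[21];

    /* guard concentrations against transient non-physical excursions */
    if (Cai  < 1e-9) Cai  = 1e-9;
    if (CaSR < 1e-9) CaSR = 1e-9;

    double E_Na = RTF * log(Nao / Nai);
    double E_K  = RTF * log(Ko / Ki);
    double E_Ca = 0.5 * RTF * log(Cao / Cai);

    /* ---- I_K1 (time independent) ------------------------------------ */
    double aK1 = 0.477994972217041 * exp((V + 4.92502331781412) / 27.2427558793487);
    double bK1 = exp((V + 56.6361974998244) / 8.72223760006882);
    double i_K1 = S_K1 * 0.133785777797606 * sqrt(Ko / 5.4) *
                  (aK1 / (aK1 + bK1)) * (V - E_K);

    /* ---- I_Kr -------------------------------------------------------- */
    double xr1_inf, xr1_tau, xr2_inf, xr2_tau;
    gate_ab(V, 0.00574885237435, 13.6234926362576, 0.047630571181836,
            -7.06808742912608, 50.0, &xr1_inf, &xr1_tau);
    gate_ab(V, 0.012456640526827, -25.9944581644377, 37.3426331501041,
            22.0919642353902, 0.0, &xr2_inf, &xr2_tau);
    double i_Kr = S_KR * 0.218025 * sqrt(Ko / 5.4) * Xr1 * Xr2 * (V - E_K);

    /* ---- I_Ks -------------------------------------------------------- */
    double xs_inf, xs_tau;
    gate_ab(V, 0.00116558448, 66726.8386749, 0.280458908250097,
            -18.8666056755475, 4.74115e-06, &xs_inf, &xs_tau);
    double i_Ks = S_KS * 0.0077 * Xs * Xs * (V - E_K);

    /* ---- I_to -------------------------------------------------------- */
    double s_inf, s_tau, r_inf, r_tau;
    gate_ab(V, 0.000344230860846030, -17.6344722898096, 186.760536909695,
            8.18093387332270, 11.2244577239469, &s_inf, &s_tau);
    gate_ab(V, 0.0553614181712909, 11.6842023429669, 3.98918108037750,
            -11.0471393012032, 0.696758421171499, &r_inf, &r_tau);
    double i_to = S_TO * 0.117833333333333 * s * r * (V - E_K);

    /* ---- I_CaL (multi-ion, Shannon permeability split) --------------- */
    double d_inf, d_tau, f_inf, f_tau;
    gate_ab(V, 12.9663370456754, 7.07914596471100, 0.044909415846086,
            -6.90988036924199, 1.65824694683855, &d_inf, &d_tau);
    gate_ab(V, 0.000512589826103388, -49.5057120337527, 1931.21122351432,
            5.73002749969900, 100.462559171103, &f_inf, &f_tau);

    double aCa = 1.0 / (1.0 + pow(Cai / 0.0006, 8.0));
    double bCa = 0.1 / (1.0 + exp((Cai - 0.0009) / 0.0001));
    double cCa = 0.3 / (1.0 + exp((Cai - 0.00075) / 0.0008));
    double fCa_inf = (aCa + bCa + cCa) / 1.3156;
    double k_fca = (fCa_inf > fCa && V > -60.0) ? 0.0 : 1.0;

    double Veff = (fabs(V) < 1e-6) ? 1e-6 : V;
    double e2v = exp(2.0 * Veff * FRT);
    double e1v = exp(Veff * FRT);
    double pCaL = S_CAL * 0.308027691379868;
    const double pCa_sh = 5.4e-4, pNa_sh = 1.5e-8, pK_sh = 2.7e-7;
    const double pTot = pCa_sh + pNa_sh + pK_sh;
    double ibarca = (pCa_sh / pTot) * 4.0 * Veff * F * FRT *
                    (0.341 * Cai * e2v - 0.341 * Cao) / (e2v - 1.0);
    double ibarna = (pNa_sh / pTot) * Veff * F * FRT *
                    (0.75 * Nai * e1v - 0.75 * Nao) / (e1v - 1.0);
    double ibark  = (pK_sh / pTot) * Veff * F * FRT *
                    (0.75 * Ki * e1v - 0.75 * Ko) / (e1v - 1.0);
    double gates_CaL = d * f * fCa * pCaL;
    double i_CaL_Ca = ibarca * gates_CaL;
    double i_CaL_Na = ibarna * gates_CaL;
    double i_CaL_K  = ibark  * gates_CaL;
    double i_CaL = i_CaL_Ca + i_CaL_Na + i_CaL_K;

    /* ---- I_CaT ------------------------------------------------------- */
    double dcat_inf = 1.0 / (1.0 + exp(-(V + 26.3) / 6.0));
    double dcat_tau = 1.0 / (1.068 * exp((V + 26.3) / 30.0) +
                             1.068 * exp(-(V + 26.3) / 30.0));
    double fcat_inf = 1.0 / (1.0 + exp((V + 61.7) / 5.6));
    double fcat_tau = 1.0 / (0.0153 * exp(-(V + 61.7) / 83.3) +
                             0.015 * exp((V + 61.7) / 15.38));
    double i_CaT = S_CAT * 0.185 * dCaT * fCaT * (V - E_Ca);

    /* ---- I_Na -------------------------------------------------------- */
    double m_inf, m_tau, h_inf, h_tau, j_inf, j_tau;
    gate_ab(V, 108.045846384818, 13.107015733941, 0.002326914367,
            -7.917726289513, 0.031977580384, &m_inf, &m_tau);
    gate_ab(V, 0.003626598864, -19.839358860026, 9663.29497711474,
            7.395503564613, 0.167331502516, &h_inf, &h_tau);
    /* j shares h's steady state (x5, x6 taken from h) */
    {
        double j1 = 0.000512257182000000, j2 = -66.583755502652;
        double j3 = 9663.29497711474 * j1;
        double j4 = 1.0 / (1.0 / j2 + 1.0 / 7.395503564613);
        double a = j1 * exp(V / j2);
        double b = j3 * exp(V / j4);
        j_inf = a / (a + b);
        j_tau = 1.0 / (a + b) + 0.951088724962;
    }
    double i_Na = S_NA * 9.720613409241 * m * m * m * h * j * (V - E_Na);

    /* ---- I_f (Na/K split) -------------------------------------------- */
    double xf_inf, xf_tau;
    gate_ab(V, 5.79734480361287e-07, -14.5898121702056, 20086.6502378723,
            10.20235284528164, 43.8498855413015, &xf_inf, &xf_tau);
    double na_frac = 0.491 / (0.491 + 1.0);
    double g_f = S_F * 0.0435;
    double i_fNa = na_frac * g_f * Xf * (V - E_Na);
    double i_fK  = (1.0 - na_frac) * g_f * Xf * (V - E_K);
    double i_f = i_fNa + i_fK;

    /* ---- I_NaCa ------------------------------------------------------ */
    const double KmCa = 1.38, KmNai = 87.5, Ksat = 0.1;
    const double gam = 0.35 * 2.0, alp = 2.5 * 1.1;
    double egv  = exp(gam * V * FRT);
    double egv1 = exp((gam - 1.0) * V * FRT);
    double i_NaCa = S_NACA * 1100.0 *
        (egv * Nai * Nai * Nai * Cao - egv1 * Nao * Nao * Nao * Cai * alp) /
        ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + Ksat * egv1));

    /* ---- I_NaK ------------------------------------------------------- */
    double i_NaK = S_NAK * 2.4761 * Ko * Nai /
        ((Ko + 1.0) * (Nai + 40.0) *
         (1.0 + 0.1245 * exp(-0.1 * V * FRT) + 0.0353 * exp(-V * FRT)));

    /* ---- sarcolemmal Ca pump and background currents ------------------ */
    double i_PCa = S_PCA * 0.2625 * Cai / (Cai + 0.0005);
    double i_bNa = S_BNA * 0.00029 * (V - E_Na);
    double i_bCa = S_BCA * 0.000367 * (V - E_Ca);

    /* ---- SR fluxes (mM/ms, cytosolic reference volume) ---------------- */
    const double Kup = 0.00025 * 0.702;
    double j_up = S_UP * (0.000425 * 0.26) / (1.0 + (Kup * Kup) / (Cai * Cai));
    double j_leak = S_LEAK * 8.0e-5 * (CaSR - Cai);

    const double ks = 12.5, ec50SR = 0.45, MaxSR = 15.0, MinSR = 1.0;
    const double koCa = 56320.0 * 11.43025;
    const double kiCa = 54.0 * 0.3425;
    const double kom  = 1.5 * 0.1429;
    const double kim  = 0.001 * 0.5571;
    double kCaSR = MaxSR - (MaxSR - MinSR) / (1.0 + pow(ec50SR / CaSR, 2.5));
    double koSRCa = koCa / kCaSR;
    double kiSRCa = kiCa * kCaSR;
    double RI = 1.0 - Rr - Or - Ir;
    double j_rel = S_REL * ks * Or * (CaSR - Cai) * (Vsr / Vc);

    /* ---- stimulus (inward while P_STIM > 0) --------------------------- */
    double i_stim = -P_STIM;

    /* ---- membrane potential ------------------------------------------ */
    double i_tot = i_K1 + i_Kr + i_Ks + i_to + i_CaL + i_CaT + i_Na + i_f +
                   i_NaCa + i_NaK + i_PCa + i_bNa + i_bCa;
    ydot[0] = -(i_tot + i_stim);

    /* ---- ion concentrations ------------------------------------------ */
    double conv = Cm / (F * Vc);     /* (pA/pF) -> mM/ms */
    double BufSR = 10.0 * 1.2, KbufSR = 0.3;
    double BufC = 0.06, KbufC = 0.0006;
    double bSR = 1.0 / (1.0 + BufSR * KbufSR / ((CaSR + KbufSR) * (CaSR + KbufSR)));
    double bC  = 1.0 / (1.0 + BufC * KbufC / ((Cai + KbufC) * (Cai + KbufC)));

    ydot[1] = bSR * (Vc / Vsr) * (j_up - j_rel - j_leak);
    ydot[2] = bC * (j_leak - j_up + j_rel -
                    (i_CaL_Ca + i_CaT + i_bCa + i_PCa - 2.0 * i_NaCa) * conv / 2.0);
    ydot[3] = -(i_Na + i_bNa + i_fNa + 3.0 * i_NaK + 3.0 * i_NaCa + i_CaL_Na) * conv;
    ydot[4] = -(i_K1 + i_to + i_Kr + i_Ks + i_fK - 2.0 * i_NaK + i_CaL_K + i_stim) * conv;

    /* ---- gates -------------------------------------------------------- */
    ydot[5]  = (d_inf - d) / d_tau;
    ydot[6]  = (f_inf - f) / f_tau;
    ydot[7]  = k_fca * (fCa_inf - fCa) / 2.0;
    ydot[8]  = (xr1_inf - Xr1) / xr1_tau;
    ydot[9]  = (xr2_inf - Xr2) / xr2_tau;
    ydot[10] = (xs_inf - Xs) / xs_tau;
    ydot[11] = (h_inf - h) / h_tau;
    ydot[12] = (j_inf - j) / j_tau;
    ydot[13] = (m_inf - m) / m_tau;
    ydot[14] = (xf_inf - Xf) / xf_tau;
    ydot[15] = (s_inf - s) / s_tau;
    ydot[16] = (r_inf - r) / r_tau;
    ydot[17] = (dcat_inf - dCaT) / dcat_tau;
    ydot[18] = (fcat_inf - fCaT) / fcat_tau;

    /* ---- SR release gating (Shannon-type 3-state + implicit RI) ------- */
    double RtoO = koSRCa * Cai * Cai * Rr - kom * Or;
    double OtoI = kiSRCa * Cai * Or - kim * Ir;
    double RtoRI = kiSRCa * Cai * Rr - kim * RI;
    double ItoRI = kom * Ir - koSRCa * Cai * Cai * RI;
    ydot[19] = -RtoO - RtoRI;
    ydot[20] = RtoO - OtoI;
    ydot[21] = OtoI - ItoRI;

    if (ip[0] >= 16) {
        yout[0] = i_Na;   yout[1] = i_f;    yout[2] = i_CaL;  yout[3] = i_CaT;
        yout[4] = i_to;   yout[5] = i_Kr;   yout[6] = i_Ks;   yout[7] = i_K1;
        yout[8] = i_NaK;  yout[9] = i_NaCa; yout[10] = i_PCa; yout[11] = i_bNa;
        yout[12] = i_bCa; yout[13] = j_up;  yout[14] = j_leak; yout[15] = j_rel;
    }
}
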