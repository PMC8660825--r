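/* Compiled right-hand side of the 34-ODE cell-cycle / G2/M checkpoint
 * model, in the deSolve compiled-code convention.  Mirrors the R reference
 * implementation rhs_full(); the two are cross-checked in the test suite.
 * Parameter order matches param_symbols() (tau last).  The damage signal
 * is recomputed from the instantaneous Mad2:Cdc20P value on every call;
 * the Cdc20-reset arrest event is handled at the R level via the root
 * function g2m_root (Mad2:Cdc20P crossing 0.6).
 */
#include <R.h>
#include <math.h>

static double p[138];

#define K_S1         p[0]
#define K_S5         p[1]
#define K_S8         p[2]
#define K_S9         p[3]
#define K_S12        p[4]
#define K_S13        p[5]
#define K_S15        p[6]
#define K_S17        p[7]
#define K_S20        p[8]
#define K_S24        p[9]
#define K_S27        p[10]
#define K_S28        p[11]
#define K_S31        p[12]
#define K_S32        p[13]
#define K_S33        p[14]
#define K_S31_1      p[15]
#define K_S32_1      p[16]
#define K_F1         p[17]
#define K_R1         p[18]
#define K_F2         p[19]
#define K_F2_1       p[20]
#define K_R2         p[21]
#define K_R2_1       p[22]
#define K_F3         p[23]
#define K_R3         p[24]
#define K_F4         p[25]
#define K_R4         p[26]
#define K_R4_1       p[27]
#define K_F5         p[28]
#define K_R5         p[29]
#define K_F6P        p[30]
#define K_R6         p[31]
#define K_F7         p[32]
#define K_R7         p[33]
#define K_F8         p[34]
#define K_R8         p[35]
#define K_F9         p[36]
#define K_R9         p[37]
#define K_F10        p[38]
#define K_R10        p[39]
#define K_R10_1      p[40]
#define K_F11        p[41]
#define K_R11        p[42]
#define K_F12        p[43]
#define K_R12        p[44]
#define K_R12_1      p[45]
#define K_R12_2      p[46]
#define K_F13        p[47]
#define K_R13        p[48]
#define K_F14        p[49]
#define K_R14        p[50]
#define K_F16        p[51]
#define K_R16        p[52]
#define K_F17        p[53]
#define K_R17        p[54]
#define K_F18        p[55]
#define K_R18P       p[56]
#define K_F19        p[57]
#define K_D1         p[58]
#define K_D1_2       p[59]
#define K_D1_3       p[60]
#define K_D2_2       p[61]
#define K_D3_2       p[62]
#define K_D4_2       p[63]
#define K_D5         p[64]
#define K_D6_1       p[65]
#define K_D6_3       p[66]
#define K_D7_1       p[67]
#define K_D8_1       p[68]
#define K_D8_3       p[69]
#define K_D9_1       p[70]
#define K_D9_3       p[71]
#define K_D10        p[72]
#define K_D11_1      p[73]
#define K_D11_3      p[74]
#define K_D12        p[75]
#define K_D12_3      p[76]
#define K_D13        p[77]
#define K_D15        p[78]
#define K_D17_1      p[79]
#define K_D17_3      p[80]
#define K_D18_1      p[81]
#define K_D18_3      p[82]
#define K_D19_3      p[83]
#define K_D20        p[84]
#define K_D21        p[85]
#define K_D24_1      p[86]
#define K_D24_2      p[87]
#define K_D25_2      p[88]
#define K_D27        p[89]
#define K_D27_1      p[90]
#define K_D28        p[91]
#define K_D28_1      p[92]
#define K_D29        p[93]
#define K_D29_1      p[94]
#define K_D30_1      p[95]
#define K_D31        p[96]
#define K_D31_1      p[97]
#define K_D32        p[98]
#define K_D33        p[99]
#define K_P53        p[100]
#define K_A1         p[101]
#define K_A2         p[102]
#define K_A3         p[103]
#define K_CDC25P1    p[104]
#define K_CDC25P2    p[105]
#define K_CDC25      p[106]
#define K_WEE1       p[107]
#define K_WEE1P      p[108]
#define K_PLK1P1     p[109]
#define K_PLK1P2     p[110]
#define K_PLK1       p[111]
#define K_CDC20P1    p[112]
#define K_CDC20P2    p[113]
#define K_CDC20      p[114]
#define K_CYCB1      p[115]
#define K_CYCB2      p[116]
#define K_MPF        p[117]
#define K_PREMPF     p[118]
#define K_P21MPF     p[119]
#define K_APC20      p[120]
#define K_PTTG1      p[121]
#define K_PTSEP      p[122]
#define K_EMI1       p[123]
#define K_WEE1F      p[124]
#define K_APC        p[125]
#define K_APP        p[126]
#define K_CDH1       p[127]
#define K_APCH       p[128]
#define K_CDH1P      p[129]
#define K_SEP        p[130]
#define K_WIP1       p[131]
#define K_MCD        p[132]
#define K_DDS        p[133]
#define EPS_MCD      p[134]
#define EMI1_TOT     p[135]
#define SEP_TOT      p[136]
#define TAU          p[137]

void g2m_init(void (*odeparms)(int *, double *))
{
    int n = 138;
    odeparms(&n, p);
}

/* species indices */
#define iCB     0
#define iMPF    1
#define iPMPF   2
#define iP21MPF 3
#define iP21    4
#define iC25P   5
#define iW1P    6
#define iC25    7
#define iW1     8
#define iPPP    9
#define iPLP   10
#define iPL    11
#define iPP    12
#define iEM    13
#define iAP    14
#define iAPP   15
#define iC20   16
#define iC20P  17
#define iAPC20 18
#define iCH    19
#define iCHP   20
#define iAPCH  21
#define iSEP   22
#define iPT    23
#define iPTSEP 24
#define iEMP   25
#define iAT    26
#define iP53   27
#define iP53P  28
#define iP53PL 29
#define iMD    30
#define iWIP   31
#define iM2    32
#define iMC    33

void g2m_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double CB = y[iCB], MPF = y[iMPF], pMPF = y[iPMPF],
        p21MPF = y[iP21MPF], p21 = y[iP21], C25P = y[iC25P], W1P = y[iW1P],
        C25 = y[iC25], W1 = y[iW1], PPP = y[iPPP], PLP = y[iPLP],
        PL = y[iPL], PP = y[iPP], EM = y[iEM], AP = y[iAP], APP = y[iAPP],
        C20 = y[iC20], C20P = y[iC20P], APC20 = y[iAPC20], CH = y[iCH],
        CHP = y[iCHP], APCH = y[iAPCH], SEP = y[iSEP], PT = y[iPT],
        PTSEP = y[iPTSEP], EMP = y[iEMP], AT = y[iAT], P53 = y[iP53],
        P53P = y[iP53P], P53PL = y[iP53PL], MD = y[iMD], WIP = y[iWIP],
        M2 = y[iM2], MC = y[iMC];

    const double CDK1f = 1.0 - MPF - pMPF - p21MPF;

    /* damage signal: piecewise linear in Mad2:Cdc20P, decaying in time */
    double dds;
    if (MC < 0.36)      dds = 0.0;
    else if (MC <= 0.6) dds = 200.0 * (MC - 0.36);
    else                dds = 200.0 * (MC - 0.6);
    const double Sig = dds * exp(-1e-8 * (*t));

    const double mcd  = 1.0 + p21 / K_MCD + EPS_MCD * PLP / K_MCD;
    const double phiE = pow(K_EMI1, 4.0) / (pow(K_EMI1, 4.0) + pow(EM, 4.0));

    const double v1   = K_F1 * CB * CDK1f - K_R1 * MPF;
    const double vW   = (K_F2 * W1 + K_F2_1) * MPF;
    const double vC   = (K_R2 * C25P + K_R2_1) * pMPF;
    const double v3   = K_F3 * C25;
    const double v3r  = K_R3 * C25P / (K_CDC25P1 + C25P);
    const double v4   = K_F4 * MPF * W1 / (K_WEE1F + W1);
    const double v4r  = (K_R4 * PP + K_R4_1) * W1P / (K_WEE1P + W1P);
    const double v5   = K_R5 * MPF * p21 * p21 * p21 - K_F5 * p21MPF;
    const double v6   = K_F6P * PL * MPF * K_A1 / (K_A1 + AT);
    const double v6r  = K_R6 * PLP / (K_PLK1P1 + PLP);
    const double v7   = K_F7 * MPF * PP - K_R7 * PPP;
    const double v8   = K_F8 * PLP * EM - K_R8 * EMP;
    const double v9   = K_R9 * C20;
    const double v9r  = K_F9 * C20P / (K_CDC20P1 + C20P);
    const double v10  = K_F10 * MPF * AP / (K_APC + AP)
                      - (K_R10 * PP + K_R10_1) * APP / (K_APP + APP);
    const double v11  = K_F11 * APP * C20 * phiE;
    const double v11r = (K_R9 + K_R11) * APC20;
    const double v12  = K_F12 * MPF * CH / (K_CDH1 + CH)
                      - (K_R12 * PP + K_R12_1 + K_R12_2 * SEP / (K_SEP + SEP))
                        * CHP / (K_CDH1P + CHP);
    const double v13  = K_F13 * AP * CH - K_R13 * APCH;
    const double v14  = K_F14 * PT * SEP - K_R14 * PTSEP;
    const double v16  = K_F16 * P53 - K_R16 * P53P;
    const double v17  = K_F17 * P53P * PLP - K_R17 * P53PL;
    const double v18  = K_F18 * M2 * C20P - K_R18P * mcd * MC;
    const double v19  = K_F19 * MPF * APCH / (K_APCH + APCH);
    const double vPTS = K_D25_2 * APC20 * PTSEP / (K_PTSEP + PTSEP);

    double d[34];
    d[iCB] = K_S1 - v1 - (K_D1 + K_D1_2 * APC20 / (K_CYCB1 + CB)
                          + K_D1_3 * APCH / (K_CYCB2 + CB)) * CB;
    d[iMPF] = v1 - vW + vC - v5 - K_D2_2 * APC20 * MPF / (K_MPF + MPF);
    d[iPMPF] = vW - vC - K_D3_2 * APC20 * pMPF / (K_PREMPF + pMPF);
    d[iP21MPF] = v5 - K_D4_2 * APC20 * p21MPF / (K_P21MPF + p21MPF);
    d[iP21] = K_S5 * (1.0 + P53 / K_P53)
            + 3.0 * (K_F5 * p21MPF - K_R5 * MPF * p21 * p21 * p21)
            - K_D5 * p21;
    d[iC25P] = v3 - v3r - (K_D6_1 + K_D6_3 * APCH / (K_CDC25P2 + C25P)) * C25P;
    d[iW1P] = v4 - v4r - K_D7_1 * W1P;
    d[iC25] = K_S8 * K_A2 / (K_A2 + AT) - v3 + v3r
            - (K_D8_1 + K_D8_3 * APCH / (K_CDC25 + C25)) * C25;
    d[iW1] = K_S9 - v4 + v4r - (K_D9_1 + K_D9_3 * APCH / (K_WEE1 + W1)) * W1;
    d[iPPP] = v7 - K_D10 * PPP;
    d[iPLP] = v6 - v6r - (K_D11_1 + K_D11_3 * APCH / (K_PLK1P2 + PLP)) * PLP
            - K_F17 * P53P * PLP + K_R17 * P53PL;
    d[iPL] = K_S12 - v6 + v6r - (K_D12 + K_D12_3 * APCH / (K_PLK1 + PL)) * PL;
    d[iPP] = K_S13 - v7 - K_D13 * PP;
    d[iEM] = -v8;
    d[iAP] = K_S15 - v10 - v13 + v19 - K_D15 * AP;
    d[iAPP] = v10 - v11 + v11r;
    d[iC20] = K_S17 - v9 + v9r - v11
            - (K_D17_1 + K_D17_3 * APCH / (K_CDC20 + C20)) * C20;
    d[iC20P] = v9 - v9r + K_R9 * APC20 - K_F18 * M2 * C20P
             + K_R18P * mcd * MC
             - (K_D18_1 + K_D18_3 * APCH / (K_CDC20P2 + C20P)) * C20P;
    d[iAPC20] = v11 - v11r - K_D19_3 * APCH * APC20 / (K_APC20 + APC20);
    d[iCH] = K_S20 - v12 - v13 - K_D20 * CH;
    d[iCHP] = v12 + v19 - K_D21 * CHP;
    d[iAPCH] = v13 - v19;
    d[iSEP] = -v14 + vPTS;
    d[iPT] = K_S24 - v14 - (K_D24_1 + K_D24_2 * APC20 / (K_PTTG1 + PT)) * PT;
    d[iPTSEP] = v14 - vPTS;
    d[iEMP] = v8;
    d[iAT] = K_S27 * (1.0 + K_DDS * Sig)
           - K_D27_1 * AT * pow(WIP, 4.0) / (pow(K_WIP1, 4.0) + pow(WIP, 4.0))
           - K_D27 * AT;
    d[iP53] = K_S28 * (1.0 + AT / K_A3) - v16 - K_D28_1 * P53 * MD
            - K_D28 * P53;
    d[iP53P] = v16 - v17 - K_D29_1 * P53P * MD - K_D29 * P53P;
    d[iP53PL] = v17 - K_D30_1 * MD * P53PL;
    d[iMD] = K_S31 + K_S31_1 * P53P - K_D31_1 * AT * MD - K_D31 * MD;
    d[iWIP] = K_S32 + K_S32_1 * P53P - K_D32 * WIP;
    d[iM2] = K_S33 - K_F18 * M2 * C20P + K_R18P * mcd * MC - K_D33 * M2;
    d[iMC] = v18;

    for (int i = 0; i < 34; i++) ydot[i] = TAU * d[i];
}

/* root function: Mad2:Cdc20P crossing the 0.6 arrest threshold */
void g2m_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    gout[0] = y[iMC] - 0.6;
}
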