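/* Combined drug / bile acid / hepatotoxicity ODE right-hand side.
 *
 * Mirrors the R reference implementation (make_rhs_r); the parameter
 * vector layout is produced by flatten_model() and the state layout is
 * documented in R/model.R. A test asserts equality of the two routes.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NP 135
static double p[NP];

void dili_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

#define P_VLIV   p[0]
#define P_VPORT  p[1]
#define P_VSYS   p[2]
#define P_QH     p[3]
#define P_SYN    p[4]
#define P_KTRANS p[5]
#define P_FLOSS  p[6]
#define P_KCONV  p[7]
#define P_KCONJ  p[8]
#define P_KSULF  p[9]
#define P_CLHYD  p[10]
#define P_ATP0   p[11]
#define TR_VMAX(T,s) p[12 + ((T)*5 + (s))*2]
#define TR_KM(T,s)   p[13 + ((T)*5 + (s))*2]
#define TOX(c,k) p[42 + (c)*4 + (k)]   /* k: 0 vmax_s, 1 km_s, 2 H, 3 tau */
#define P_KATP   p[50]
#define IJ(k)    p[51 + (k)]  /* thr, k_nec, hill, alt_content, k_altc, k_bilic, k_regen */
#define P_FOLDMAX p[58]
#define P_KIND    p[59]
#define P_INDU    p[60]
#define P_INDM    p[61]
#define P_NENT    p[62]
#define EN(e,k)   p[63 + (e)*24 + (k)]

/* state indices (0-based) */
#define S_BA(s,c) ((s)*5 + (c))      /* c: 0 liver, 1 gb, 2 gut, 3 portal, 4 sys */
#define S_DELAY(s) (25 + (s))
#define S_FECAL 30
#define S_HYD   31
#define S_ATP   32
#define S_VIAB  33
#define S_ALT   34
#define S_BILI  35
#define S_IND   36
#define S_ENT(e,k) (37 + (e)*9 + (k)) /* k: 0 gut,1 portal,2 blood,3 liver,4 periph,5 fecal,6 renal,7 biliary,8 conv */

static const int cls[5] = {0, 0, 1, 1, 1};

void dili_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int s, T, e, j;
    int n_ent = (int) P_NENT;
    double fcomp[3] = {1, 1, 1}, fnoncomp[3] = {1, 1, 1}, etc = 1;
    double cl_ent[3] = {0, 0, 0};
    double met[2] = {0, 0};

    for (j = 0; j < *neq; j++) ydot[j] = 0;

    for (e = 0; e < n_ent; e++) {
        double ki, mode, fac;
        cl_ent[e] = y[S_ENT(e, 3)] / P_VLIV;
        for (T = 0; T < 3; T++) {
            ki = EN(e, 15 + 2 * T);
            mode = EN(e, 16 + 2 * T);
            if (ki > 0 && mode > 0) {
                fac = 1 + cl_ent[e] / ki;
                if (mode == 1) fcomp[T] *= fac; else fnoncomp[T] *= fac;
            }
        }
        ki = EN(e, 21);
        if (ki > 0 && EN(e, 22) > 0) etc /= (1 + cl_ent[e] / ki);
    }

    /* drug entities */
    if (n_ent > 0) {
        double ind = y[S_IND];
        double ind_u = (P_INDU > 0) ? ind : 1;
        double ind_m = (P_INDM > 0) ? ind : 1;
        double ka = EN(0, 1), fab = EN(0, 2), VC = EN(0, 3), VT = EN(0, 4);
        double qp = EN(0, 5), CLp = EN(0, 6), ren = EN(0, 7), bil = EN(0, 8);
        double vmu = EN(0, 9), kmu = EN(0, 10);
        double Gd = y[S_ENT(0, 0)], Pd = y[S_ENT(0, 1)], Bd = y[S_ENT(0, 2)];
        double Ld = y[S_ENT(0, 3)], Td = y[S_ENT(0, 4)];
        double C_Pd = Pd / P_VPORT, C_Bd = Bd / VC, C_Ld = Ld / P_VLIV;
        double C_Td = (VT > 0) ? Td / VT : 0;
        double upt = ind_u * vmu * C_Pd / (kmu + C_Pd) + CLp * C_Pd;
        double met_sum = 0;
        for (j = 0; j < n_ent - 1; j++) {
            double vmf = ind_m * EN(0, 11 + j * 2);
            double kmf = EN(0, 12 + j * 2);
            met[j] = vmf * C_Ld / (kmf + C_Ld);
            met_sum += met[j];
        }
        ydot[S_ENT(0, 0)] = -ka * Gd;
        ydot[S_ENT(0, 1)] = ka * fab * Gd + P_QH * (C_Bd - C_Pd) - upt;
        ydot[S_ENT(0, 2)] = P_QH * (C_Pd - C_Bd) + CLp * C_Ld -
            ren * C_Bd - qp * (C_Bd - C_Td);
        ydot[S_ENT(0, 3)] = upt - CLp * C_Ld - bil * C_Ld - met_sum;
        ydot[S_ENT(0, 4)] = qp * (C_Bd - C_Td);
        ydot[S_ENT(0, 5)] = ka * (1 - fab) * Gd;
        ydot[S_ENT(0, 6)] = ren * C_Bd;
        ydot[S_ENT(0, 7)] = bil * C_Ld;
        ydot[S_ENT(0, 8)] = met_sum;
        for (j = 0; j < n_ent - 1; j++) {
            e = j + 1;
            double CLpM = EN(e, 6), renM = EN(e, 7), bilM = EN(e, 8);
            double VCM = EN(e, 3);
            double LdM = y[S_ENT(e, 3)], BdM = y[S_ENT(e, 2)];
            double C_LM = LdM / P_VLIV, C_BM = BdM / VCM;
            double exch = CLpM * (C_LM - C_BM);
            ydot[S_ENT(e, 3)] = met[j] - bilM * C_LM - exch;
            ydot[S_ENT(e, 2)] = exch - renM * C_BM;
            ydot[S_ENT(e, 6)] = renM * C_BM;
            ydot[S_ENT(e, 7)] = bilM * C_LM;
            ydot[S_ENT(e, 8)] = met[j];
        }
        ydot[S_IND] = P_KIND * (P_FOLDMAX - ind);
    }

    /* bile acids */
    {
        double C_L[5], C_P[5], C_B[5], J_N[5], J_B[5], J_Bl[5];
        double gut_out[5];
        double J_conv, J_hyd;
        for (s = 0; s < 5; s++) {
            C_L[s] = y[S_BA(s, 0)] / P_VLIV;
            C_P[s] = y[S_BA(s, 3)] / P_VPORT;
            C_B[s] = y[S_BA(s, 4)] / P_VSYS;
            J_N[s] = (TR_VMAX(0, s) / fnoncomp[0]) * C_P[s] /
                (TR_KM(0, s) * fcomp[0] + C_P[s]);
            J_B[s] = (TR_VMAX(1, s) / fnoncomp[1]) * C_L[s] /
                (TR_KM(1, s) * fcomp[1] + C_L[s]);
            J_Bl[s] = (TR_VMAX(2, s) / fnoncomp[2]) * C_L[s] /
                (TR_KM(2, s) * fcomp[2] + C_L[s]);
            gut_out[s] = P_KTRANS * y[S_BA(s, 2)];
        }
        J_conv = P_KCONV * y[S_BA(0, 2)];
        J_hyd = P_CLHYD * C_L[2];

        for (s = 0; s < 5; s++) {
            ydot[S_BA(s, 0)] = J_N[s] - J_B[s] - J_Bl[s];
            ydot[S_BA(s, 1)] = J_B[s];
            ydot[S_BA(s, 2)] = -gut_out[s];
            ydot[S_BA(s, 3)] = (1 - P_FLOSS) * gut_out[s] - J_N[s] +
                P_QH * (C_B[s] - C_P[s]);
            ydot[S_BA(s, 4)] = J_Bl[s] - P_QH * (C_B[s] - C_P[s]);
        }
        ydot[S_BA(0, 0)] += P_SYN - P_KCONJ * y[S_BA(0, 0)];
        ydot[S_BA(1, 0)] += P_KCONJ * y[S_BA(0, 0)];
        ydot[S_BA(2, 0)] += -(P_KCONJ + P_KSULF) * y[S_BA(2, 0)] - J_hyd;
        ydot[S_BA(3, 0)] += P_KCONJ * y[S_BA(2, 0)];
        ydot[S_BA(4, 0)] += P_KSULF * y[S_BA(2, 0)];
        ydot[S_BA(0, 2)] += -J_conv;
        ydot[S_BA(2, 2)] += J_conv;
        ydot[S_FECAL] = P_FLOSS * (gut_out[0] + gut_out[1] + gut_out[2] +
                                   gut_out[3] + gut_out[4]);
        ydot[S_HYD] = J_hyd;

        /* delayed concentrations and toxicity */
        {
            double X[2] = {0, 0};
            double S_sig = 1, atp, deficit, hz, v, v_eff;
            for (s = 0; s < 5; s++) {
                double tau = TOX(cls[s], 3);
                ydot[S_DELAY(s)] = tau * (C_L[s] - y[S_DELAY(s)]);
                X[cls[s]] += y[S_DELAY(s)];
            }
            for (j = 0; j < 2; j++) {
                double x = X[j] > 0 ? X[j] : 0;
                double H = TOX(j, 2), km = TOX(j, 1);
                double frac = x > 0 ?
                    pow(x, H) / (pow(km, H) + pow(x, H)) : 0;
                S_sig *= 1 / (1 + TOX(j, 0) * frac);
            }
            atp = y[S_ATP] > 0 ? y[S_ATP] : 0;
            ydot[S_ATP] = P_KATP * S_sig * etc - P_KATP * atp / P_ATP0;
            deficit = (IJ(0) - atp) / IJ(0);
            if (deficit < 0) deficit = 0;
            hz = IJ(1) * pow(deficit, IJ(2));
            v = y[S_VIAB];
            ydot[S_VIAB] = -hz * v + IJ(6) * v * (1 - v);
            ydot[S_ALT] = IJ(4) * (1 - y[S_ALT]) + IJ(3) * hz * v;
            v_eff = v > 0.05 ? v : 0.05;
            ydot[S_BILI] = IJ(5) * (1 / v_eff - y[S_BILI]);
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"dili_init",   (DL_FUNC) &dili_init,   1},
    {"dili_derivs", (DL_FUNC) &dili_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_biletox(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
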