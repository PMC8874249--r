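/* Flow-limited PBK model for BPA + BPAG + BPAS solved as a delay
 * differential system (deSolve::dede compiled interface).
 *
 * Amounts in ug, concentrations in ug/L, time in h.  Two fixed-lag terms:
 * biliary transit (liver -> small intestine, default 4 h) for all three
 * analytes, and the lymphatic lag (lymph -> venous blood) for BPA.
 *
 * Parameter vector layout (see pbk_parms_vector() on the R side, which is
 * the single source of truth for the ordering).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 79

static double parms[NPARMS];

/* physiological (derived on the R side: absolute volumes L, flows L/h) */
#define Vli    parms[0]
#define Vst    parms[1]
#define Vgu    parms[2]
#define Vki    parms[3]
#define Vfa    parms[4]
#define Vspd   parms[5]
#define Vrpd   parms[6]
#define Vbld   parms[7]
#define Qhep   parms[8]
#define Qst    parms[9]
#define Qgu    parms[10]
#define Qki    parms[11]
#define Qfa    parms[12]
#define Qspd   parms[13]
#define Qrpd   parms[14]
/* uptake */
#define FracHep   parms[15]
#define FracLym   parms[16]
#define DRINKTIME parms[17]
/* binding */
#define FB_A   parms[18]
#define FB_G   parms[19]
#define FB_S   parms[20]
/* permeability + emptying */
#define BELLYPERM      parms[21]
#define GIPERM         parms[22]
#define BELLYPERMLYM   parms[23]
#define GIPERMLYM      parms[24]
#define KEMAX          parms[25]
#define KEMIN          parms[26]
/* first-order rates: gut (faecal), liver->bile, urine, bound->unbound */
#define KGUT_A   parms[27]
#define KGUT_G   parms[28]
#define KGUT_S   parms[29]
#define KLIV_A   parms[30]
#define KLIV_G   parms[31]
#define KLIV_S   parms[32]
#define KURN_A   parms[33]
#define KURN_G   parms[34]
#define KURN_S   parms[35]
#define KREM_A   parms[36]
#define KREM_G   parms[37]
#define KREM_S   parms[38]
#define K1LYMPH  parms[39]
#define LYMPHLAG parms[40]
/* whole-organ metabolic constants (ug/h, ug/L) */
#define VMAX_LI_G parms[41]
#define KM_LI_G   parms[42]
#define VMAX_LI_S parms[43]
#define KM_LI_S   parms[44]
#define VMAX_GU_G parms[45]
#define KM_GU_G   parms[46]
#define VMAX_GU_S parms[47]
#define KM_GU_S   parms[48]
/* partition coefficients tissue:blood, per analyte */
#define PLI_A  parms[49]
#define PKI_A  parms[50]
#define PFA_A  parms[51]
#define PGU_A  parms[52]
#define PST_A  parms[53]
#define PRPD_A parms[54]
#define PSPD_A parms[55]
#define PLI_G  parms[56]
#define PKI_G  parms[57]
#define PFA_G  parms[58]
#define PGU_G  parms[59]
#define PST_G  parms[60]
#define PRPD_G parms[61]
#define PSPD_G parms[62]
#define PLI_S  parms[63]
#define PKI_S  parms[64]
#define PFA_S  parms[65]
#define PGU_S  parms[66]
#define PST_S  parms[67]
#define PRPD_S parms[68]
#define PSPD_S parms[69]
/* dosing + lags + bookkeeping */
#define DOSE_TOTAL parms[70]   /* ug */
#define DOSE_START parms[71]   /* h */
#define DOSE_DUR   parms[72]   /* h */
#define BILE_LAG   parms[73]   /* h */
#define MWRATIO_G  parms[74]   /* MW_BPAG / MW_BPA */
#define MWRATIO_S  parms[75]   /* MW_BPAS / MW_BPA */
#define GUTLOSSALL parms[76]   /* 1: K1_x_GUT acts on all lumen pools   */
#define METAB_ON   parms[77]   /* 0 disables gut+liver metabolism       */
#define T0         parms[78]   /* integration start time                */

/* state indices */
#define iAST_HEP 0
#define iAGI_HEP 1
#define iAST_LYM 2
#define iAGI_LYM 3
#define iAST_UN  4
#define iAGI_UN  5
#define iALYMPH  6
#define iALYMTR  7   /* lymph transit (between exit and arrival in blood) */
/* per-analyte block, offsets from base: BPA base 8, BPAG base 21, BPAS 34 */
#define oRC    0   /* recirculated gut lumen      */
#define oBILE  1   /* biliary transit pool        */
#define oGU    2   /* gut tissue                  */
#define oST    3   /* stomach tissue              */
#define oLI    4   /* liver                       */
#define oKI    5   /* kidney                      */
#define oFA    6   /* fat                         */
#define oSPD   7   /* slowly perfused             */
#define oRPD   8   /* rapidly perfused            */
#define oBLDU  9   /* blood, unbound              */
#define oBLDB 10   /* blood, bound                */
#define oURN  11   /* urine, cumulative           */
#define oFEC  12   /* faeces, cumulative          */
#define BASE_A 8
#define BASE_G 21
#define BASE_S 34
#define NSTATE 47

void qivive_pbk_init(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, parms);
}

static void lagvalue(double T, int *nr, int N, double *ytau) {
  static void (*fun)(double, int *, int, double *) = NULL;
  if (fun == NULL)
    fun = (void (*)(double, int *, int, double *))
      R_GetCCallable("deSolve", "lagvalue");
  fun(T, nr, N, ytau);
}

/* lagged value of one state; history (t <= T0) is the zero initial state */
static double lagstate(double t, double lag, int idx) {
  if (t - lag <= T0 + 1e-12) return 0.0;
  double ytau[1];
  int nr = idx;
  lagvalue(t - lag, &nr, 1, ytau);
  return ytau[0];
}

/* one analyte's distribution/elimination block; returns nothing, fills ydot.
 * uptake_gu: mass flow (ug/h) appearing in gut tissue (absorption and/or
 * metabolite formation); uptake_li: mass flow formed in liver;
 * extra_blood_in: mass flow entering venous blood directly (lymph).      */
static void analyte_block(double t, const double *y, double *ydot, int base,
                          double Pli, double Pki, double Pfa, double Pgu,
                          double Pst, double Prpd, double Pspd,
                          double FB, double krem, double kliv, double kgut,
                          double kurn, double uptake_gu, double uptake_li,
                          double extra_blood_in, double met_gu,
                          double met_li) {
  const double *s = y + base;
  double Ca   = s[oBLDU] / Vbld;
  double Cvgu = s[oGU] / (Vgu * Pgu);
  double Cvst = s[oST] / (Vst * Pst);
  double Cvli = s[oLI] / (Vli * Pli);
  double Cvki = s[oKI] / (Vki * Pki);
  double Cvfa = s[oFA] / (Vfa * Pfa);
  double Cvsp = s[oSPD] / (Vspd * Pspd);
  double Cvrp = s[oRPD] / (Vrpd * Prpd);
  double Qliv = Qhep + Qgu + Qst;

  double bile_out = kliv * lagstate(t, BILE_LAG, base + oLI);
  double reabs = GIPERM * s[oRC];

  double *d = ydot + base;
  d[oRC]   = bile_out - reabs - kgut * s[oRC];
  d[oBILE] = kliv * s[oLI] - bile_out;
  d[oGU]   = Qgu * (Ca - Cvgu) + uptake_gu + reabs - met_gu;
  d[oST]   = Qst * (Ca - Cvst);
  d[oLI]   = Qhep * Ca + Qgu * Cvgu + Qst * Cvst + uptake_li
             - Qliv * Cvli - met_li - kliv * s[oLI];
  d[oKI]   = Qki * (Ca - Cvki) - kurn * s[oKI];
  d[oFA]   = Qfa * (Ca - Cvfa);
  d[oSPD]  = Qspd * (Ca - Cvsp);
  d[oRPD]  = Qrpd * (Ca - Cvrp);

  double inflow = Qliv * Cvli + Qki * Cvki + Qfa * Cvfa + Qspd * Cvsp +
                  Qrpd * Cvrp + extra_blood_in;
  double QC = Qliv + Qki + Qfa + Qspd + Qrpd;
  d[oBLDB] = FB * inflow - krem * s[oBLDB];
  d[oBLDU] = (1.0 - FB) * inflow + krem * s[oBLDB] - QC * Ca;
  d[oURN]  = kurn * s[oKI];
  d[oFEC]  = kgut * s[oRC];
}

void qivive_pbk_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip) {
  double tt = *t;

  /* zero-order ingestion over [DOSE_START, DOSE_START + DOSE_DUR) */
  double rin = 0.0;
  if (DOSE_DUR > 0 && tt >= DOSE_START && tt < DOSE_START + DOSE_DUR)
    rin = DOSE_TOTAL / DOSE_DUR;

  /* stomach emptying declines from KEMAX towards KEMIN as the meal clears */
  double te = tt - DOSE_START;
  if (te < 0) te = 0;
  double kem = KEMIN + (KEMAX - KEMIN) * exp(-te / DRINKTIME);

  double lossall = GUTLOSSALL > 0.5 ? KGUT_A : 0.0;

  ydot[iAST_HEP] = rin * FracHep - (kem + BELLYPERM) * y[iAST_HEP];
  ydot[iAGI_HEP] = kem * y[iAST_HEP] - (GIPERM + lossall) * y[iAGI_HEP];
  ydot[iAST_LYM] = rin * FracLym - (kem + BELLYPERMLYM) * y[iAST_LYM];
  ydot[iAGI_LYM] = kem * y[iAST_LYM] - (GIPERMLYM + lossall) * y[iAGI_LYM];
  ydot[iAST_UN]  = rin * (1.0 - FracHep - FracLym) - kem * y[iAST_UN];
  ydot[iAGI_UN]  = kem * y[iAST_UN] - KGUT_A * y[iAGI_UN];

  /* first-order exit from lymph; arrival in venous blood is delayed by
   * LYMPHLAG, with the in-transit mass held in a transit pool */
  double lymph_exit = K1LYMPH * y[iALYMPH];
  double lymph_lagged = K1LYMPH * lagstate(tt, LYMPHLAG, iALYMPH);
  ydot[iALYMPH] = BELLYPERMLYM * y[iAST_LYM] + GIPERMLYM * y[iAGI_LYM]
                  - lymph_exit;
  ydot[iALYMTR] = lymph_exit - lymph_lagged;

  /* Michaelis-Menten metabolism of BPA in gut and liver tissue */
  double Cgu_t = y[BASE_A + oGU] / Vgu;
  double Cli_t = y[BASE_A + oLI] / Vli;
  double met_gu_G = 0, met_gu_S = 0, met_li_G = 0, met_li_S = 0;
  if (METAB_ON > 0.5) {
    met_gu_G = VMAX_GU_G * Cgu_t / (KM_GU_G + Cgu_t);
    met_gu_S = VMAX_GU_S * Cgu_t / (KM_GU_S + Cgu_t);
    met_li_G = VMAX_LI_G * Cli_t / (KM_LI_G + Cli_t);
    met_li_S = VMAX_LI_S * Cli_t / (KM_LI_S + Cli_t);
  }

  /* BPA: absorbed mass enters gut tissue (gut lumen routes) or goes to the
   * portal vein collected in liver (stomach route), plus lymphatic input  */
  analyte_block(tt, y, ydot, BASE_A,
                PLI_A, PKI_A, PFA_A, PGU_A, PST_A, PRPD_A, PSPD_A,
                FB_A, KREM_A, KLIV_A, KGUT_A, KURN_A,
                /* uptake_gu   */ GIPERM * y[iAGI_HEP] +
                                  GIPERMLYM * 0.0,
                /* uptake_li   */ BELLYPERM * y[iAST_HEP],
                /* blood in    */ lymph_lagged,
                met_gu_G + met_gu_S, met_li_G + met_li_S);
  /* the lymph-route lumen mass goes to lymph, not to gut tissue */

  /* conjugates formed in gut and liver tissue (molar-corrected) */
  analyte_block(tt, y, ydot, BASE_G,
                PLI_G, PKI_G, PFA_G, PGU_G, PST_G, PRPD_G, PSPD_G,
                FB_G, KREM_G, KLIV_G, KGUT_G, KURN_G,
                met_gu_G * MWRATIO_G, met_li_G * MWRATIO_G, 0.0, 0.0, 0.0);
  analyte_block(tt, y, ydot, BASE_S,
                PLI_S, PKI_S, PFA_S, PGU_S, PST_S, PRPD_S, PSPD_S,
                FB_S, KREM_S, KLIV_S, KGUT_S, KURN_S,
                met_gu_S * MWRATIO_S, met_li_S * MWRATIO_S, 0.0, 0.0, 0.0);

  /* faeces also collects the unabsorbed transit pool (and, with the
   * all-lumen switch, losses from the absorbable lumen pools) */
  ydot[BASE_A + oFEC] += KGUT_A * y[iAGI_UN] +
                         lossall * (y[iAGI_HEP] + y[iAGI_LYM]);
}
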