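/* Right-hand side of the PD-1 / TCR / CD28 proximal signaling model.
 *
 * 20 species, 36 rate parameters, 10 conserved totals.  Free pools
 * (unphosphorylated receptor, free Zap70, free PI3K, free Lck_i, free LAT,
 * free Gads, free Slp76) are computed algebraically from the conservation
 * relations at every evaluation, so their totals are conserved by
 * construction.  Michaelis-Menten kinetics for receptor and PD-1
 * (de)phosphorylation, mass action elsewhere.  Only the PD-1-bound Shp2
 * complexes CP1/CP2 carry phosphatase activity; free Shp2 is inert.
 *
 * Compiled-model interface for deSolve: pd1_initmod receives the parameter
 * vector (36 rates + 10 totals + clamp flag/value = 48 values, in the order
 * fixed on the R side), pd1_derivs is the derivative function.  C_pd1_deriv
 * is a .Call entry point evaluating the same code at a single state.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 48
#define N_SPECIES 20

static double parms[N_PARMS];

/* species indices */
enum {
  I_CD3A, I_CD28A, I_PD1, I_PD1P1, I_PD1P2, I_SHP2, I_CP1, I_CP2,
  I_LCK_YIYA, I_LCK_YI, I_LCK_YA, I_LCK_PI,
  I_ZAP70I, I_ZAP70A1, I_ZAP70A2,
  I_LATA, I_SLP76I, I_SLP76A, I_GADSA, I_PI3KB
};

/* parameter indices (rates in Table-2 order, then totals, then CP2 clamp) */
enum {
  P_K_DPA_YIYA, P_K_DPI_YI, P_K_DPI_YIYA, P_K_DPA_YA, P_K_DPA_PI,
  P_K_A_ZAP, P_K_P1_ZAP, P_K_P2_ZAP, P_K_P_LAT, P_K_A_SLP, P_K_P_SLP,
  P_K_A_GADS, P_K_A_PI3K, P_K_A_SHP,
  P_K_PI_I, P_K_PI_YA, P_K_PA_I, P_K_PA_YI,
  P_K_P_CD3, P_K_DP_CD3, P_K_D_ZAP, P_K_D_SLP, P_K_D_GADS,
  P_K_P_CD28, P_K_DP_CD28, P_K_D_PI3K, P_K_P_PD1,
  P_K_D1_SHP, P_K_DP_CP2, P_K_D2_SHP,
  P_KM_P_CD3, P_KM_DP_CD3, P_KM_P_CD28, P_KM_DP_CD28, P_KM_P_PD1,
  P_K_CORR,
  P_CD3T, P_CD28T, P_ZAP70T, P_PI3KT, P_LCKT, P_LATT, P_GADST, P_SLP76T,
  P_SHP2T, P_PD1T,
  P_CLAMP_ON, P_CLAMP_VAL
};

static double pos(double x) { return x > 0.0 ? x : 0.0; }

static void compute_derivs(const double *p, const double *yin, double *ydot)
{
  double y[N_SPECIES];
  int i;

  /* soft-clip integrator under-shoot */
  for (i = 0; i < N_SPECIES; i++) y[i] = pos(yin[i]);

  int clamp = p[P_CLAMP_ON] != 0.0;
  double cp2 = clamp ? p[P_CLAMP_VAL] : y[I_CP2];

  double lck_active = y[I_LCK_YIYA] + y[I_LCK_YA];
  double cp_active  = y[I_CP1] + cp2;

  double cd3_free  = pos(p[P_CD3T] - (y[I_CD3A] + y[I_ZAP70I] +
                                      y[I_ZAP70A1] + y[I_ZAP70A2]));
  double cd28_free = pos(p[P_CD28T] - (y[I_CD28A] + y[I_PI3KB]));
  double zap_free  = pos(p[P_ZAP70T] - (y[I_ZAP70I] + y[I_ZAP70A1] +
                                        y[I_ZAP70A2]));
  double pi3k_free = pos(p[P_PI3KT] - y[I_PI3KB]);
  double lck_i     = pos(p[P_LCKT] - (y[I_LCK_YIYA] + y[I_LCK_YI] +
                                      y[I_LCK_YA] + y[I_LCK_PI]));
  double lat_free  = pos(p[P_LATT] - (y[I_LATA] + y[I_GADSA] +
                                      y[I_SLP76I] + y[I_SLP76A]));
  double gads_free = pos(p[P_GADST] - (y[I_GADSA] + y[I_SLP76I] +
                                       y[I_SLP76A]));
  double slp_free  = pos(p[P_SLP76T] - (y[I_SLP76I] + y[I_SLP76A]));

  /* saturating correction on the first PD-1 phosphorylation step only */
  double corr = 0.0;
  if (p[P_LCKT] > 0.0)
    corr = pos(1.0 - (y[I_PD1P1] + y[I_PD1P2]) / (p[P_LCKT] * p[P_K_CORR]));

  double v_pd1_1 = p[P_K_P_PD1] * lck_active * y[I_PD1] /
                   (p[P_KM_P_PD1] + y[I_PD1]) * corr;
  double v_pd1_2 = p[P_K_P_PD1] * y[I_PD1P1] * lck_active /
                   (p[P_KM_P_PD1] + y[I_PD1P1]);

  /* CP2 exchange fluxes, all disabled when CP2 is clamped (constant
   * catalytic pool emulating membrane-anchored Shp2) */
  double f_bind2 = clamp ? 0.0 : p[P_K_A_SHP] * y[I_PD1P2] * y[I_SHP2];
  double f_d1_2  = clamp ? 0.0 : p[P_K_D1_SHP] * cp2;
  double f_d2_2  = clamp ? 0.0 : p[P_K_D2_SHP] * cp2;
  double f_dp2   = clamp ? 0.0 : p[P_K_DP_CP2] * cp2;

  ydot[I_CD3A] =
    p[P_K_P_CD3] * lck_active * cd3_free / (p[P_KM_P_CD3] + cd3_free) -
    p[P_K_DP_CD3] * cp_active * y[I_CD3A] / (p[P_KM_DP_CD3] + y[I_CD3A]) +
    p[P_K_D_ZAP] * y[I_ZAP70I] - p[P_K_A_ZAP] * y[I_CD3A] * zap_free;

  ydot[I_CD28A] =
    p[P_K_P_CD28] * lck_active * cd28_free / (p[P_KM_P_CD28] + cd28_free) -
    p[P_K_DP_CD28] * cp_active * y[I_CD28A] / (p[P_KM_DP_CD28] + y[I_CD28A]) +
    p[P_K_D_PI3K] * y[I_PI3KB] - p[P_K_A_PI3K] * y[I_CD28A] * pi3k_free;

  ydot[I_PD1] = -v_pd1_1 + p[P_K_D2_SHP] * y[I_CP1];

  ydot[I_PD1P1] = v_pd1_1 - v_pd1_2 -
    p[P_K_A_SHP] * y[I_PD1P1] * y[I_SHP2] +
    p[P_K_D1_SHP] * y[I_CP1] + f_d2_2;

  ydot[I_PD1P2] = v_pd1_2 - f_bind2 + f_d1_2;

  ydot[I_SHP2] =
    -p[P_K_A_SHP] * y[I_SHP2] * y[I_PD1P1] - f_bind2 +
    (p[P_K_D1_SHP] + p[P_K_D2_SHP]) * y[I_CP1] + f_d1_2 + f_d2_2;

  ydot[I_CP1] = f_dp2 + p[P_K_A_SHP] * y[I_PD1P1] * y[I_SHP2] -
    (p[P_K_D1_SHP] + p[P_K_D2_SHP]) * y[I_CP1];

  ydot[I_CP2] = clamp ? 0.0 : (-f_dp2 + f_bind2 - f_d1_2 - f_d2_2);

  ydot[I_LCK_YIYA] =
    -p[P_K_DPA_YIYA] * cp_active * y[I_LCK_YIYA] -
    p[P_K_DPI_YIYA] * cp_active * y[I_LCK_YIYA] +
    p[P_K_PI_YA] * y[I_LCK_YA];

  ydot[I_LCK_YI] =
    p[P_K_DPA_YIYA] * cp_active * y[I_LCK_YIYA] -
    p[P_K_DPI_YI] * cp_active * y[I_LCK_YI] +
    p[P_K_PI_I] * lck_i - p[P_K_PA_YI] * y[I_LCK_YI] +
    p[P_K_DPA_PI] * cp_active * y[I_LCK_PI];

  ydot[I_LCK_YA] =
    p[P_K_DPI_YIYA] * cp_active * y[I_LCK_YIYA] -
    p[P_K_PI_YA] * y[I_LCK_YA] -
    p[P_K_DPA_YA] * cp_active * y[I_LCK_YA] +
    p[P_K_PA_I] * lck_i;

  ydot[I_LCK_PI] =
    -p[P_K_DPA_PI] * cp_active * y[I_LCK_PI] + p[P_K_PA_YI] * y[I_LCK_YI];

  ydot[I_ZAP70I] =
    p[P_K_A_ZAP] * y[I_CD3A] * zap_free - p[P_K_D_ZAP] * y[I_ZAP70I] -
    p[P_K_P1_ZAP] * lck_active * y[I_ZAP70I];

  ydot[I_ZAP70A1] =
    p[P_K_P1_ZAP] * lck_active * y[I_ZAP70I] -
    p[P_K_P2_ZAP] * lck_active * y[I_ZAP70A1];

  ydot[I_ZAP70A2] = p[P_K_P2_ZAP] * lck_active * y[I_ZAP70A1];

  ydot[I_LATA] =
    p[P_K_P_LAT] * y[I_ZAP70A2] * lat_free -
    p[P_K_A_GADS] * y[I_LATA] * gads_free + p[P_K_D_GADS] * y[I_GADSA];

  ydot[I_SLP76I] =
    p[P_K_A_SLP] * y[I_GADSA] * slp_free - p[P_K_D_SLP] * y[I_SLP76I] -
    p[P_K_P_SLP] * y[I_SLP76I] * y[I_ZAP70A2];

  ydot[I_SLP76A] = p[P_K_P_SLP] * y[I_SLP76I] * y[I_ZAP70A2];

  ydot[I_GADSA] =
    p[P_K_A_GADS] * y[I_LATA] * gads_free - p[P_K_D_GADS] * y[I_GADSA] -
    p[P_K_A_SLP] * y[I_GADSA] * slp_free + p[P_K_D_SLP] * y[I_SLP76I];

  ydot[I_PI3KB] =
    p[P_K_A_PI3K] * y[I_CD28A] * pi3k_free - p[P_K_D_PI3K] * y[I_PI3KB];
}

void pd1_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

void pd1_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  compute_derivs(parms, y, ydot);
}

SEXP C_pd1_deriv(SEXP y, SEXP p)
{
  if (LENGTH(y) != N_SPECIES)
    error("state vector must have %d elements", N_SPECIES);
  if (LENGTH(p) != N_PARMS)
    error("parameter vector must have %d elements", N_PARMS);
  SEXP out = PROTECT(allocVector(REALSXP, N_SPECIES));
  compute_derivs(REAL(p), REAL(y), REAL(out));
  UNPROTECT(1);
  return out;
}
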