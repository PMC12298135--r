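/* Compiled right-hand side of the three-pore model ODE, used through
 * deSolve's compiled-model interface. The fitting drivers evaluate the
 * model thousands of times per session, so the derivative is implemented
 * in C; the R-level pore_fluxes() keeps an independent implementation of
 * the same flux algebra that the test suite compares against.
 *
 * Parameters are staged into a static buffer by tpm_set_pars() immediately
 * before each integration (single-threaded use only, as with R's solvers).
 *
 * Layout of the parameter vector:
 *   [0]  ns               number of solutes
 *   [1]  nk               number of plasma knots (>= 1)
 *   [2]  track            1 = integrate cumulative net solute inflow states
 *   [3]  L                lymphatic absorption, mL/min
 *   [4..6]   alpha_i * LpS      (ultrasmall, small, large)
 *   [7..9]   sigma_protein_i    (ultrasmall, small, large)
 *   [10] dP   [11] pi_p   [12] RT
 *   then per-solute blocks, each of length ns:
 *     sig_s, sig_l, ps_s, ps_l
 *   then plasma knot times (nk) and knot values (nk * ns, solute-major)
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define TPM_MAXP 256
static double P[TPM_MAXP];

void tpm_set_pars(double *p, int *n)
{
    int i;
    if (*n > TPM_MAXP)
        error("tpm_set_pars: parameter vector too long (%d)", *n);
    if (*n > 0 && p[0] > 32)
        error("tpm_set_pars: at most 32 solutes supported");
    for (i = 0; i < *n; i++) P[i] = p[i];
}

/* Patlak convection-diffusion flux through one pathway (into the cavity). */
static double patlak(double jv, double sigma, double ps, double cp, double cd)
{
    double conv = jv * (1.0 - sigma), pe;
    if (sigma >= 1.0) return 0.0;
    if (ps <= 0.0) {
        if (conv == 0.0) return 0.0;
        return conv * (conv > 0.0 ? cp : cd);
    }
    pe = conv / ps;
    if (fabs(pe) < 1e-6)           /* series expansion avoids 0/0 */
        return ps * (cp - cd) + conv * (cp + cd) / 2.0;
    if (pe > 50.0)  return conv * cp;
    if (pe < -50.0) return conv * cd;
    {
        double em = exp(-pe);
        return conv * (cp - cd * em) / (1.0 - em);
    }
}

void tpm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int ns = (int) P[0], nk = (int) P[1], track = (int) P[2];
    double L = P[3];
    const double *aLpS = P + 4, *sp = P + 7;
    double dP = P[10], pi_p = P[11], RT = P[12];
    const double *sig_s = P + 13, *sig_l = P + 13 + ns;
    const double *ps_s = P + 13 + 2 * ns, *ps_l = P + 13 + 3 * ns;
    const double *kt = P + 13 + 4 * ns;      /* plasma knot times  */
    const double *kv = kt + nk;              /* knot values, solute-major */
    double V = y[0];
    const double *cd = y + 1;
    double cp[32];
    double osm_u = 0.0, osm_s = 0.0, osm_l = 0.0;
    double jv_u, jv_s, jv_l, dV;
    int s;

    /* plasma at time t: piecewise linear between knots, clamped */
    if (nk == 1) {
        for (s = 0; s < ns; s++) cp[s] = kv[s];
    } else {
        int k = 0;
        double w;
        while (k < nk - 2 && *t > kt[k + 1]) k++;
        w = (*t - kt[k]) / (kt[k + 1] - kt[k]);
        if (w < 0.0) w = 0.0;
        if (w > 1.0) w = 1.0;
        for (s = 0; s < ns; s++)
            cp[s] = (1.0 - w) * kv[s * nk + k] + w * kv[s * nk + k + 1];
    }

    for (s = 0; s < ns; s++) {
        double dc = cd[s] - cp[s];
        osm_u += dc;                  /* sigma = 1 at the water-only pore */
        osm_s += sig_s[s] * dc;
        osm_l += sig_l[s] * dc;
    }
    jv_u = aLpS[0] * (dP - sp[0] * pi_p + RT * osm_u);
    jv_s = aLpS[1] * (dP - sp[1] * pi_p + RT * osm_s);
    jv_l = aLpS[2] * (dP - sp[2] * pi_p + RT * osm_l);
    dV = jv_u + jv_s + jv_l - L;
    ydot[0] = dV;

    for (s = 0; s < ns; s++) {
        double js = patlak(jv_s, sig_s[s], ps_s[s], cp[s], cd[s]) +
                    patlak(jv_l, sig_l[s], ps_l[s], cp[s], cd[s]);
        double net = js - L * cd[s];
        ydot[1 + s] = (net - cd[s] * dV) / V;
        if (track) ydot[1 + ns + s] = net;
    }
}

/* Lumped diffusion-convection solute model on a prescribed volume profile:
 *   d(V cd)/dt = MTAC (cp - cd) + SiCo dV/dt [(1-w) cp + w cd]
 * Parameter layout (lump_set_pars):
 *   [0] MTAC  [1] SiCo  [2] w  [3] nvk  [4] npk
 *   then volume knot times (nvk), volume knot values (nvk),
 *   then plasma knot times (npk), plasma knot values (npk)
 * V is the piecewise-linear interpolant of the knots (clamped), its slope
 * the per-segment constant; plasma is piecewise linear, clamped.
 */
#define LUMP_MAXP 128
static double Q[LUMP_MAXP];

void lump_set_pars(double *p, int *n)
{
    int i;
    if (*n > LUMP_MAXP)
        error("lump_set_pars: parameter vector too long (%d)", *n);
    for (i = 0; i < *n; i++) Q[i] = p[i];
}

static double interp1(const double *xt, const double *xv, int n, double t,
                      double *slope)
{
    int k = 0;
    double w;
    if (n == 1) { *slope = 0.0; return xv[0]; }
    while (k < n - 2 && t > xt[k + 1]) k++;
    *slope = (xv[k + 1] - xv[k]) / (xt[k + 1] - xt[k]);
    w = (t - xt[k]) / (xt[k + 1] - xt[k]);
    if (w < 0.0) { w = 0.0; *slope = 0.0; }
    if (w > 1.0) { w = 1.0; *slope = 0.0; }
    return (1.0 - w) * xv[k] + w * xv[k + 1];
}

void lump_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double mtac = Q[0], sico = Q[1], w = Q[2];
    int nvk = (int) Q[3], npk = (int) Q[4];
    const double *vkt = Q + 5, *vkv = Q + 5 + nvk;
    const double *pkt = Q + 5 + 2 * nvk, *pkv = Q + 5 + 2 * nvk + npk;
    double dV, dum, V, cp, cd = y[0], dM;

    V = interp1(vkt, vkv, nvk, *t, &dV);
    cp = interp1(pkt, pkv, npk, *t, &dum);
    dM = mtac * (cp - cd) + sico * dV * ((1.0 - w) * cp + w * cd);
    ydot[0] = (dM - cd * dV) / V;
}

/* terminate integration when the cavity runs dry */
void tpm_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *rpar, int *ipar)
{
    gout[0] = y[0] - 1.0;
}

static const R_CMethodDef CEntries[] = {
    {"tpm_set_pars", (DL_FUNC) &tpm_set_pars, 2},
    {"lump_set_pars", (DL_FUNC) &lump_set_pars, 2},
    {NULL, NULL, 0}
};

void R_init_pdwell(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks tpm_derivs/tpm_root up by name */
}
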