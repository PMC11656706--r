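/* Compiled right-hand sides for the GUTS model variants, called by
 * deSolve::lsoda via the dllname/initfunc interface.  Parameter vectors
 * are passed by position; the R wrappers in R/simulator.R own the layout
 * and keep it in one place (see .gp_parms_*).  The external concentration
 * C_e is constant within one integration segment; time-varying exposure
 * is handled by segment-wise restarts on the R side.
 */
#include <R.h>
#include <math.h>

/* ---- GUTS-RNA-pulse ----------------------------------------------------
 * states y = (C_i, R, P*, H)
 * parms  p = (k_i, k_m, z_ci, v_rt, r_rt, k_rd, k_p, z, k_k, h_b,
 *             C_i_max, R_0, C_e)
 */
static double p_pulse[13];

void gp_init_pulse(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, p_pulse);
}

void gp_derivs_pulse(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double k_i = p_pulse[0], k_m = p_pulse[1], z_ci = p_pulse[2],
                 v_rt = p_pulse[3], r_rt = p_pulse[4], k_rd = p_pulse[5],
                 k_p = p_pulse[6], z = p_pulse[7], k_k = p_pulse[8],
                 h_b = p_pulse[9], cimax = p_pulse[10], r0 = p_pulse[11],
                 c_e = p_pulse[12];
    const double C_i = y[0], R = y[1], P = y[2];
    const double act = 1.0 / (1.0 + exp(-v_rt * (C_i / cimax - z_ci)));

    ydot[0] = k_i * c_e - k_m * P * C_i;
    ydot[1] = r_rt * act - k_rd * fmax(0.0, R - r0);
    ydot[2] = k_p * (R - P);
    ydot[3] = k_k * fmax(0.0, R - z) + h_b;
}

/* ---- GUTS-RNA ----------------------------------------------------------
 * states y = (C_i, D, H);  D is the nrf2 fold-change damage state
 * parms  p = (k_i, k_e, k_a, k_r, z, k_k, h_b, D_0, C_e)
 */
static double p_rna[9];

void gp_init_rna(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, p_rna);
}

void gp_derivs_rna(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double k_i = p_rna[0], k_e = p_rna[1], k_a = p_rna[2],
                 k_r = p_rna[3], z = p_rna[4], k_k = p_rna[5],
                 h_b = p_rna[6], d0 = p_rna[7], c_e = p_rna[8];
    const double C_i = y[0], D = y[1];

    ydot[0] = k_i * c_e - k_e * C_i;
    ydot[1] = k_a * C_i - k_r * (D - d0);
    ydot[2] = k_k * fmax(0.0, D - z) + h_b;
}

/* ---- GUTS-scaled-damage ------------------------------------------------
 * states y = (C_i, D, H)
 * parms  p = (k_i, k_e, k_d, z, k_k, h_b, C_e)
 */
static double p_sd[7];

void gp_init_sd(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, p_sd);
}

void gp_derivs_sd(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double k_i = p_sd[0], k_e = p_sd[1], k_d = p_sd[2],
                 z = p_sd[3], k_k = p_sd[4], h_b = p_sd[5], c_e = p_sd[6];
    const double C_i = y[0], D = y[1];

    ydot[0] = k_i * c_e - k_e * C_i;
    ydot[1] = k_d * (C_i - D);
    ydot[2] = k_k * fmax(0.0, D - z) + h_b;
}

/* ---- GUTS-reduced ------------------------------------------------------
 * states y = (D, H)
 * parms  p = (k_d, z, k_k, h_b, C_e)
 */
static double p_red[5];

void gp_init_red(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, p_red);
}

void gp_derivs_red(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double k_d = p_red[0], z = p_red[1], k_k = p_red[2],
                 h_b = p_red[3], c_e = p_red[4];
    const double D = y[0];

    ydot[0] = k_d * (c_e - D);
    ydot[1] = k_k * fmax(0.0, D - z) + h_b;
}

/* ---- stacked systems ---------------------------------------------------
 * One lsoda call integrates every treatment of a fit at once: n systems
 * with identical structure but per-treatment parameters and exposure.
 * parms layout: [n, shared..., then per-system blocks]; states are
 * consecutive per-system blocks.  Sized for several hundred treatments.
 */
#define GP_MAXP 8192
static double p_pulse_n[GP_MAXP];

void gp_init_pulse_n(void (*odeparms)(int *, double *))
{
    int n = GP_MAXP;
    odeparms(&n, p_pulse_n);
}

/* parms: [n, cimax, r0, (k_i,k_m,z_ci,v_rt,r_rt,k_rd,k_p,z,k_k,h_b,Ce) x n]
 * states: (C_i, R, P*, H) x n
 */
void gp_derivs_pulse_n(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const int n = (int) p_pulse_n[0];
    const double cimax = p_pulse_n[1], r0 = p_pulse_n[2];
    for (int j = 0; j < n; j++) {
        const double *p = p_pulse_n + 3 + 11 * j;
        const double *yj = y + 4 * j;
        double *dj = ydot + 4 * j;
        const double act = 1.0 / (1.0 + exp(-p[3] * (yj[0] / cimax - p[2])));
        dj[0] = p[0] * p[10] - p[1] * yj[2] * yj[0];
        dj[1] = p[4] * act - p[5] * fmax(0.0, yj[1] - r0);
        dj[2] = p[6] * (yj[1] - yj[2]);
        dj[3] = p[8] * fmax(0.0, yj[1] - p[7]) + p[9];
    }
}

static double p_rna_n[GP_MAXP];

void gp_init_rna_n(void (*odeparms)(int *, double *))
{
    int n = GP_MAXP;
    odeparms(&n, p_rna_n);
}

/* parms: [n, d0, (k_i,k_e,k_a,k_r,z,k_k,h_b,Ce) x n]; states (C_i,D,H) x n */
void gp_derivs_rna_n(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int n = (int) p_rna_n[0];
    const double d0 = p_rna_n[1];
    for (int j = 0; j < n; j++) {
        const double *p = p_rna_n + 2 + 8 * j;
        const double *yj = y + 3 * j;
        double *dj = ydot + 3 * j;
        dj[0] = p[0] * p[7] - p[1] * yj[0];
        dj[1] = p[2] * yj[0] - p[3] * (yj[1] - d0);
        dj[2] = p[5] * fmax(0.0, yj[1] - p[4]) + p[6];
    }
}

static double p_sd_n[GP_MAXP];

void gp_init_sd_n(void (*odeparms)(int *, double *))
{
    int n = GP_MAXP;
    odeparms(&n, p_sd_n);
}

/* parms: [n, (k_i,k_e,k_d,z,k_k,h_b,Ce) x n]; states (C_i,D,H) x n */
void gp_derivs_sd_n(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int n = (int) p_sd_n[0];
    for (int j = 0; j < n; j++) {
        const double *p = p_sd_n + 1 + 7 * j;
        const double *yj = y + 3 * j;
        double *dj = ydot + 3 * j;
        dj[0] = p[0] * p[6] - p[1] * yj[0];
        dj[1] = p[2] * (yj[0] - yj[1]);
        dj[2] = p[4] * fmax(0.0, yj[1] - p[3]) + p[5];
    }
}

static double p_red_n[GP_MAXP];

void gp_init_red_n(void (*odeparms)(int *, double *))
{
    int n = GP_MAXP;
    odeparms(&n, p_red_n);
}

/* parms: [n, (k_d,z,k_k,h_b,Ce) x n]; states (D,H) x n */
void gp_derivs_red_n(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int n = (int) p_red_n[0];
    for (int j = 0; j < n; j++) {
        const double *p = p_red_n + 1 + 5 * j;
        const double *yj = y + 2 * j;
        double *dj = ydot + 2 * j;
        dj[0] = p[0] * (p[4] - yj[0]);
        dj[1] = p[2] * fmax(0.0, yj[0] - p[1]) + p[3];
    }
}
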