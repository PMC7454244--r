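/* Tumor-immune QSP right-hand side, deSolve compiled-model convention.
 *
 * States (counts unless noted):
 *  0 C     cancer cells (tumor)
 *  1 D     dying cancer cells (tumor)
 *  2 A     released tumor antigen (arbitrary amount units)
 *  3 APCi  immature APCs (tumor)
 *  4 APCt  mature APCs (tumor)
 *  5 APCl  mature APCs (tumor-draining lymph node)
 *  6 Tn    naive T cells (central)
 *  7 Ta    activated T cells (TdLN)
 *  8 Tec   effector T cells (central)
 *  9 Tep   effector T cells (peripheral)
 * 10 Tet   effector T cells (tumor)
 * 11 Rl    regulatory T cells (TdLN)
 * 12 Rc    regulatory T cells (central)
 * 13 Rt    regulatory T cells (tumor)
 *
 * Forcings (precomputed from the binding equilibria + PK closed form):
 *  0 Hsyn  checkpoint Hill factor at the tumor synapse
 *  1 Hln   checkpoint Hill factor at the TdLN priming synapse
 *  2 Htce  TCE trimer Hill factor at the tumor synapse
 */
#include <R.h>
#include <math.h>

static double parms[45];
static double forc[3];

#define k_growth       parms[0]
#define c_max          parms[1]
#define k_kill_tcr     parms[2]
#define k_kill_tce     parms[3]
#define h_clone        parms[4]
#define k_treg_sup     parms[5]
#define k_clear        parms[6]
#define k_release      parms[7]
#define k_uptake       parms[8]
#define k_deg          parms[9]
#define s_apc          parms[10]
#define k_d_apc        parms[11]
#define k_mat          parms[12]
#define k_ant_half     parms[13]
#define k_mig          parms[14]
#define k_d_apc_ln     parms[15]
#define k_apc_half     parms[16]
#define k_act          parms[17]
#define n_clones       parms[18]
#define s_naive        parms[19]
#define d_naive        parms[20]
#define k_pro          parms[21]
#define n_div          parms[22]
#define q_in           parms[23]
#define q_out          parms[24]
#define k_death_teff   parms[25]
#define q_per          parms[26]
#define q_per_back     parms[27]
#define d_teff_c       parms[28]
#define k_act_treg     parms[29]
#define s_treg         parms[30]
#define k_pro_treg     parms[31]
#define n_div_treg     parms[32]
#define q_in_treg      parms[33]
#define q_out_treg     parms[34]
#define k_death_treg   parms[35]
#define d_treg_c       parms[36]
#define eps_cells      parms[37]
#define vol_cell       parms[38]
#define packing        parms[39]
#define d_target       parms[40]
#define k_apo          parms[41]
#define f_tce          parms[42]
#define beta_tce       parms[43]
#define c_ref          parms[44]

#define Hsyn forc[0]
#define Hln  forc[1]
#define Htce forc[2]

void init_qsp(void (*odeparms)(int *, double *))
{
    int n = 45;
    odeparms(&n, parms);
}

void forc_qsp(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forc);
}

void derivs_qsp(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double C    = fmax(y[0], 0.0);
    double D    = fmax(y[1], 0.0);
    double A    = fmax(y[2], 0.0);
    double APCi = fmax(y[3], 0.0);
    double APCt = fmax(y[4], 0.0);
    double APCl = fmax(y[5], 0.0);
    double Tn   = fmax(y[6], 0.0);
    double Ta   = fmax(y[7], 0.0);
    double Tec  = fmax(y[8], 0.0);
    double Tep  = fmax(y[9], 0.0);
    double Tet  = fmax(y[10], 0.0);
    double Rl   = fmax(y[11], 0.0);
    double Rc   = fmax(y[12], 0.0);
    double Rt   = fmax(y[13], 0.0);

    /* tumor killing: native-TCR and TCE-synapse routes share the effector
     * contact fraction, checkpoint derepression and Treg suppression */
    double rel_teff = Tet / (C + Tet + eps_cells);
    /* TCE-engaged killing is serial and saturates at a much lower
     * effector:target ratio than the native TCR route */
    double rel_tce  = Tet / (f_tce * C + Tet + eps_cells);
    double h_treg   = Rt / (Rt + Tet + 1.0);
    double suppress = 1.0 / (1.0 + k_treg_sup * h_treg);
    /* the TCE synapse is only partially checkpoint-sensitive (CD3
     * crosslinking partly bypasses PD-1 proximal inhibition) */
    double k_tot = (k_kill_tcr * h_clone * rel_teff * (1.0 - Hsyn) +
                    k_kill_tce * Htce * rel_tce * (1.0 - beta_tce * Hsyn)) *
                   suppress;

    ydot[0] = k_growth * C * (1.0 - C / c_max) - k_tot * C;
    ydot[1] = k_tot * C + k_apo * C - k_clear * D;

    /* antigen release, uptake and degradation */
    ydot[2] = k_release * D - k_uptake * A * APCi - k_deg * A;

    /* APC maturation in tumor, migration to TdLN */
    double h_ant = A / (A + k_ant_half);
    ydot[3] = s_apc - k_mat * h_ant * APCi - k_d_apc * APCi;
    ydot[4] = k_mat * h_ant * APCi - k_mig * APCt - k_d_apc * APCt;
    ydot[5] = k_mig * APCt - k_d_apc_ln * APCl;

    /* clonal T cell activation in TdLN; PD-L1 on APCs cuts the effective
     * number of division rounds during priming (amp = 2^(n_div*(1-Hln))) */
    double h_apc = APCl / (APCl + k_apc_half);
    double act   = k_act * n_clones * h_apc * Tn;
    double amp   = pow(2.0, n_div * (1.0 - Hln));
    ydot[6] = s_naive - d_naive * Tn - act;
    ydot[7] = act - k_pro * Ta;

    /* effector trafficking: perfusion scales with tumor surface area */
    double surf = pow(C / c_ref, 2.0 / 3.0);
    double infl = q_in * surf;
    ydot[8]  = amp * k_pro * Ta - infl * Tec - q_per * Tec +
               q_per_back * Tep - d_teff_c * Tec;
    ydot[9]  = q_per * Tec - q_per_back * Tep;
    ydot[10] = infl * Tec - q_out * Tet - k_death_teff * Tet;

    /* Treg mirror: activation from a fixed naive pool, no killing role */
    double act_r = k_act_treg * h_apc * s_treg;
    ydot[11] = act_r - k_pro_treg * Rl;
    ydot[12] = pow(2.0, n_div_treg) * k_pro_treg * Rl -
               q_in_treg * surf * Rc - d_treg_c * Rc;
    ydot[13] = q_in_treg * surf * Rc - q_out_treg * Rt - k_death_treg * Rt;

    if (ip[0] >= 1) {
        /* tumor diameter (cm) from the sphere-equivalent volume map */
        double vol = C * vol_cell / packing;
        yout[0] = cbrt(6.0 * vol / M_PI);
    }
}

/* stop pre-treatment initialization when the tumor reaches its target
 * diameter: root of diameter(C) - d_target */
void root_qsp(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    double vol = fmax(y[0], 0.0) * vol_cell / packing;
    gout[0] = cbrt(6.0 * vol / M_PI) - d_target;
}
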