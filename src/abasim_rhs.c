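/* Compiled right-hand sides for the three ODE models, in deSolve's
 * dllname/initfunc convention. These mirror the documented R-level RHS
 * functions exactly; the R versions remain the reference definitions
 * (used by the fixed-step RK4 oracle), so adaptive-vs-oracle tests also
 * cross-check the two implementations against each other.
 *
 * States and parameters use the package convention: concentrations in
 * micromolar, time in seconds, luminescence in RLU.
 */
#include <R.h>
#include <math.h>

/* Hill occupancy with the ligand clamped at zero: the literal signaling
 * equations may drive concentrations negative, and a fractional Hill
 * coefficient is undefined there. */
static double hill_occ(double C, double K, double n)
{
    double r;
    if (C <= 0.0) return 0.0;
    r = pow(C / K, n);
    if (!R_FINITE(r)) return 1.0;
    return r / (1.0 + r);
}

/* ---- signaling models --------------------------------------------- */
/* parms: k_synthesis, K1, K2, K3, k_iS, k_iP, k_iM, K_half, n          */
static double sig_p[9];

void abasim_init_signaling(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, sig_p);
}

/* state: C_ABA, SNRK2, PP2C, MAPK */
void abasim_rhs_signaling_aba(int *neq, double *t, double *y,
                              double *ydot, double *yout, int *ip)
{
    double occ = hill_occ(y[0], sig_p[7], sig_p[8]);
    ydot[0] = sig_p[0] - sig_p[1] * y[0];
    ydot[1] = sig_p[2] * occ;
    ydot[2] = sig_p[4] * y[1] - sig_p[5] * y[2];
    ydot[3] = -sig_p[4] * y[1] + sig_p[6] * y[2] + sig_p[3] * y[0];
}

void abasim_rhs_signaling_noaba(int *neq, double *t, double *y,
                                double *ydot, double *yout, int *ip)
{
    ydot[0] = 0.0;
    ydot[1] = -sig_p[6] * y[2];
    ydot[2] = sig_p[4] * y[1] - sig_p[5] * y[2];
    ydot[3] = -sig_p[4] * y[1] + sig_p[6] * y[2];
}

/* ---- biosensor model ---------------------------------------------- */
/* parms: k_prod, k_deg, kon, koff, k_trans, k_tran_deg, k_tran_syn,
 *        k_deg_prot, k_response, K_half, K_half_response, n,
 *        mode (1 = mass_action, 0 = literal)                           */
static double bio_p[13];

void abasim_init_biosensor(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, bio_p);
}

/* state: C_ABA, mRNA, Protein, Complex, I_biolum */
void abasim_rhs_biosensor(int *neq, double *t, double *y,
                          double *ydot, double *yout, int *ip)
{
    double C = y[0], m = y[1], P = y[2], X = y[3];
    double occ_tr = hill_occ(C, bio_p[9], bio_p[11]);
    double occ_rs = hill_occ(X, bio_p[10], bio_p[11]);

    ydot[1] = bio_p[4] * occ_tr - bio_p[5] * m;
    ydot[4] = bio_p[8] * occ_rs;
    if (bio_p[12] > 0.5) {          /* mass action */
        double assoc = bio_p[2] * C * P;
        double dissoc = bio_p[3] * X;
        ydot[0] = bio_p[0] - bio_p[1] * C - assoc + dissoc;
        ydot[2] = bio_p[6] * m - bio_p[7] * P - assoc + dissoc;
        ydot[3] = assoc - dissoc;
    } else {                        /* literal printed equations */
        ydot[0] = bio_p[0] - bio_p[1] * C - bio_p[2] * X + bio_p[3] * X;
        ydot[2] = bio_p[6] * m - bio_p[7] * P;
        ydot[3] = (bio_p[2] - bio_p[3]) * X;
    }
}
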