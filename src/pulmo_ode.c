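/* Structural ODE system for the pulmonary PK model, in the deSolve
 * compiled-model convention (initfunc + derivs looked up by name).
 *
 * State vector layout (0-based):
 *   y[0 .. ntr-1]  transit compartments (mg)       [absent when ntr == 0]
 *   y[ntr]         absorption (depot) compartment (mg)
 *   y[ntr+1]       central compartment amount (mg)
 *   y[ntr+2]       enzyme pool (dimensionless, baseline 1)
 *   y[ntr+3]       ELF effect-compartment concentration (mg/L)
 *   y[ntr+4]       AC  effect-compartment concentration (mg/L)
 *
 * Doses are bolus events into y[0] (or the depot when ntr == 0),
 * handled by the integrator's event mechanism, not here.
 */
#include <R.h>

static double parms[12];
#define NTRANSIT parms[0]  /* number of transit compartments (integer-valued) */
#define KTR      parms[1]  /* transit rate (N+1)/MTT, 1/h                     */
#define KA       parms[2]  /* depot -> central absorption rate, 1/h           */
#define CL_I     parms[3]  /* individual pre-induced oral clearance, L/h      */
#define VC_I     parms[4]  /* individual apparent central volume, L           */
#define EMAX     parms[5]  /* maximal fold-increase of enzyme production      */
#define EC50     parms[6]  /* plasma conc. at half-maximal induction, mg/L    */
#define KENZ     parms[7]  /* enzyme turn-over rate, 1/h                      */
#define KELF     parms[8]  /* plasma -> ELF equilibration rate, 1/h           */
#define KAC      parms[9]  /* plasma -> AC equilibration rate, 1/h            */
#define RELF     parms[10] /* pseudo-steady-state ELF/plasma ratio            */
#define RAC      parms[11] /* pseudo-steady-state AC/plasma ratio             */

void pulmo_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void pulmo_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int ntr = (int) (NTRANSIT + 0.5);
    double depot = y[ntr], central = y[ntr + 1], enz = y[ntr + 2];
    double cp = central / VC_I;
    /* clamp transient solver-induced negative concentrations out of the
     * saturable induction term */
    double cpp = (cp > 0.0) ? cp : 0.0;
    double stim = 1.0 + EMAX * cpp / (EC50 + cpp);
    int i;

    if (ntr > 0) {
        ydot[0] = -KTR * y[0];
        for (i = 1; i < ntr; i++)
            ydot[i] = KTR * (y[i - 1] - y[i]);
        ydot[ntr] = KTR * y[ntr - 1] - KA * depot;
    } else {
        ydot[ntr] = -KA * depot;
    }
    ydot[ntr + 1] = KA * depot - (CL_I * enz / VC_I) * central;
    ydot[ntr + 2] = KENZ * stim - KENZ * enz;
    ydot[ntr + 3] = KELF * (RELF * cp - y[ntr + 3]);
    ydot[ntr + 4] = KAC  * (RAC  * cp - y[ntr + 4]);
}

/* Stacked variant: M independent copies of the system sharing all
 * parameters except the individual clearance and central volume, laid out
 * block-wise in the state vector.  Blocks do not interact, so the Jacobian
 * is block diagonal and the system can be integrated with a banded
 * approximation (band width = block size - 1).  Used by the estimator to
 * amortize integrator overhead over a whole study population.
 */
#define PULMO_MAX_STACK 512

static double mparms[11 + 2 * PULMO_MAX_STACK];
#define M_NTRANSIT mparms[0]
#define M_KTR      mparms[1]
#define M_KA       mparms[2]
#define M_EMAX     mparms[3]
#define M_EC50     mparms[4]
#define M_KENZ     mparms[5]
#define M_KELF     mparms[6]
#define M_KAC      mparms[7]
#define M_RELF     mparms[8]
#define M_RAC      mparms[9]
#define M_M        mparms[10]
/* mparms[11 .. 11+M-1]      individual clearances
 * mparms[11+M .. 11+2M-1]   individual central volumes */

void pulmo_initmod_multi(void (*odeparms)(int *, double *))
{
    int n = 11 + 2 * PULMO_MAX_STACK;
    odeparms(&n, mparms);
}

void pulmo_derivs_multi(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    int ntr = (int) (M_NTRANSIT + 0.5);
    int m = (int) (M_M + 0.5);
    int blk = ntr + 5, b, i;

    for (b = 0; b < m; b++) {
        double *yb = y + b * blk, *db = ydot + b * blk;
        double cl = mparms[11 + b], vc = mparms[11 + m + b];
        double depot = yb[ntr], central = yb[ntr + 1], enz = yb[ntr + 2];
        double cp = central / vc;
        double cpp = (cp > 0.0) ? cp : 0.0;
        double stim = 1.0 + M_EMAX * cpp / (M_EC50 + cpp);

        if (ntr > 0) {
            db[0] = -M_KTR * yb[0];
            for (i = 1; i < ntr; i++)
                db[i] = M_KTR * (yb[i - 1] - yb[i]);
            db[ntr] = M_KTR * yb[ntr - 1] - M_KA * depot;
        } else {
            db[ntr] = -M_KA * depot;
        }
        db[ntr + 1] = M_KA * depot - (cl * enz / vc) * central;
        db[ntr + 2] = M_KENZ * stim - M_KENZ * enz;
        db[ntr + 3] = M_KELF * (M_RELF * cp - yb[ntr + 3]);
        db[ntr + 4] = M_KAC  * (M_RAC  * cp - yb[ntr + 4]);
    }
}

/* Reduced stacked variant for the estimator: only the non-stiff plasma
 * subsystem (transit chain, depot, central, enzyme) is integrated; the ELF
 * and AC effect compartments equilibrate within ~1 minute and are
 * reconstructed analytically from Cp and its derivatives outside the
 * solver.  Shares the parameter block of the full stacked variant.
 */
void pulmo_derivs_plasma_multi(int *neq, double *t, double *y, double *ydot,
                               double *yout, int *ip)
{
    int ntr = (int) (M_NTRANSIT + 0.5);
    int m = (int) (M_M + 0.5);
    int blk = ntr + 3, b, i;

    for (b = 0; b < m; b++) {
        double *yb = y + b * blk, *db = ydot + b * blk;
        double cl = mparms[11 + b], vc = mparms[11 + m + b];
        double depot = yb[ntr], central = yb[ntr + 1], enz = yb[ntr + 2];
        double cp = central / vc;
        double cpp = (cp > 0.0) ? cp : 0.0;
        double stim = 1.0 + M_EMAX * cpp / (M_EC50 + cpp);

        if (ntr > 0) {
            db[0] = -M_KTR * yb[0];
            for (i = 1; i < ntr; i++)
                db[i] = M_KTR * (yb[i - 1] - yb[i]);
            db[ntr] = M_KTR * yb[ntr - 1] - M_KA * depot;
        } else {
            db[ntr] = -M_KA * depot;
        }
        db[ntr + 1] = M_KA * depot - (cl * enz / vc) * central;
        db[ntr + 2] = M_KENZ * stim - M_KENZ * enz;
    }
}
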