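/* Native right-hand sides for the built-in phosphorylation-cascade model
 * family, in the deSolve compiled-model calling convention.
 *
 * States per layer i (i = 1..L): b_i (inactive), a_i (active), interleaved as
 * (b_1, a_1, b_2, a_2, ...). Layer 1 is activated by the stimulus dose, each
 * downstream layer by the active species of the layer above:
 *
 *   rate_i = (kb_i + ka_i * s_i) * b_i - kd_i * a_i,   s_1 = dose, s_i = a_{i-1}
 *   da_i/dt = rate_i,  db_i/dt = -rate_i
 *
 * Estimated parameters, linear scale, ordered (ka_1..ka_L, kd_1..kd_L,
 * kb_1..kb_L). The sensitivity variant integrates the forward variational
 * system with analytic Jacobians; its state vector is (x, S[,1], ..,
 * S[,n_theta]) with S = dx/dtheta stored column-wise.
 *
 * Parameter vector passed from R (fixed length MBODE_PARMS_LEN, padded):
 *   parms[0] = L, parms[1] = dose, parms[2 + 0..L-1] = ka,
 *   parms[2 + L..2L-1] = kd, parms[2 + 2L..3L-1] = kb.
 */

#include <R.h>

#define MBODE_MAX_LAYERS 20
#define MBODE_PARMS_LEN (2 + 3 * MBODE_MAX_LAYERS)

static double parms[MBODE_PARMS_LEN];

void mbode_cascade_init(void (*odeparms)(int *, double *))
{
    int N = MBODE_PARMS_LEN;
    odeparms(&N, parms);
}

#define PAR_L    ((int) parms[0])
#define PAR_DOSE (parms[1])
#define PAR_KA(i) (parms[2 + (i)])
#define PAR_KD(i) (parms[2 + PAR_L + (i)])
#define PAR_KB(i) (parms[2 + 2 * PAR_L + (i)])

/* plain dynamics: neq = 2 L */
void mbode_cascade_derivs(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    int L = PAR_L;
    double s = PAR_DOSE;
    for (int i = 0; i < L; i++) {
        double b = y[2 * i], a = y[2 * i + 1];
        double rate = (PAR_KB(i) + PAR_KA(i) * s) * b - PAR_KD(i) * a;
        ydot[2 * i] = -rate;
        ydot[2 * i + 1] = rate;
        s = a; /* stimulus for the next layer */
    }
}

/* forward variational system: neq = 2 L * (1 + 3 L) */
void mbode_cascade_sens_derivs(int *neq, double *t, double *y, double *ydot,
                               double *yout, int *ip)
{
    int L = PAR_L;
    int nx = 2 * L, ntheta = 3 * L;

    mbode_cascade_derivs(&nx, t, y, ydot, yout, ip);

    for (int j = 0; j < ntheta; j++) {
        double *S = y + nx * (1 + j);
        double *Sdot = ydot + nx * (1 + j);
        /* which layer and which rate constant parameter j refers to */
        int kind = j / L;      /* 0 = ka, 1 = kd, 2 = kb */
        int lay = j % L;
        double s = PAR_DOSE;
        for (int i = 0; i < L; i++) {
            double b = y[2 * i], a = y[2 * i + 1];
            /* J_x %*% S column: d(rate_i)/db_i, /da_i, /da_{i-1} */
            double drate = (PAR_KB(i) + PAR_KA(i) * s) * S[2 * i]
                - PAR_KD(i) * S[2 * i + 1];
            if (i > 0)
                drate += PAR_KA(i) * b * S[2 * i - 1];
            /* J_theta column: nonzero only in the layer parameter j acts on */
            if (lay == i) {
                if (kind == 0)      drate += s * b;  /* ka_i */
                else if (kind == 1) drate += -a;     /* kd_i */
                else                drate += b;      /* kb_i */
            }
            Sdot[2 * i] = -drate;
            Sdot[2 * i + 1] = drate;
            s = a;
        }
    }
}
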