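/* Method-of-lines right-hand side for the modified expansion-repression
 * circuit on a uniform 1D grid with zero-flux boundaries.
 *
 *   dM/dt = DM M'' - k M / (1 + E/xi) + nuM * theta(wM - x)
 *   dE/dt = DE E'' - mu E / (1 + E/zeta) + nuE * m^h / (m^h + M^h)
 *
 * State is interleaved (M_1, E_1, M_2, E_2, ...) so the Jacobian is
 * banded with half-bandwidth 2 (deSolve lsode, jactype = "bandint").
 * The source indicator is discretised by control-volume overlap so the
 * total production varies continuously as wM crosses grid nodes; in
 * boundary_flux mode the distributed source is off and a flux j0 enters
 * the half control volume at x = 0.
 */

#include <R.h>
#include <math.h>
#include <stdlib.h>

static double parms[18];
#define P_DM    parms[0]
#define P_DE    parms[1]
#define P_K     parms[2]
#define P_MU    parms[3]
#define P_NUM   parms[4]
#define P_NUE   parms[5]
#define P_XI    parms[6]
#define P_ZETA  parms[7]
#define P_M0    parms[8]
#define P_H     parms[9]
#define P_DX    parms[10]
#define P_NX    parms[11]
#define P_WM    parms[12]
#define P_J0    parms[13]
#define P_FLUX  parms[14]
#define P_SSTOL parms[15]
#define P_ATOL  parms[16]
#define P_OVER  parms[17]

void er_initmod(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms);
}

void er_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int nx = (int) P_NX;
    const double dx = P_DX;
    const double dx2 = dx * dx;
    const double L = (nx - 1) * dx;
    const double mh = pow(P_M0, P_H);
    int i;

    for (i = 0; i < nx; i++) {
        const double M = y[2 * i];
        const double E = y[2 * i + 1];
        double lapM, lapE;

        if (i == 0) {                       /* ghost reflection, x = 0 */
            lapM = 2.0 * (y[2] - M) / dx2;
            lapE = 2.0 * (y[3] - E) / dx2;
        } else if (i == nx - 1) {           /* ghost reflection, x = L */
            lapM = 2.0 * (y[2 * i - 2] - M) / dx2;
            lapE = 2.0 * (y[2 * i - 1] - E) / dx2;
        } else {
            lapM = (y[2 * i - 2] - 2.0 * M + y[2 * i + 2]) / dx2;
            lapE = (y[2 * i - 1] - 2.0 * E + y[2 * i + 3]) / dx2;
        }

        /* fractional overlap of this node's control volume with the
         * source region [0, wM] */
        double xl = i * dx - 0.5 * dx;
        double xr = i * dx + 0.5 * dx;
        if (xl < 0.0) xl = 0.0;
        if (xr > L) xr = L;
        double ov = fmin(xr, P_WM) - xl;
        if (ov < 0.0) ov = 0.0;
        const double w = ov / (xr - xl);

        const double prodM = (P_FLUX > 0.5) ? 0.0 : P_NUM * w;
        const double degM = P_K * M / (1.0 + E / P_XI);
        const double Mh = pow(fmax(M, 0.0), P_H);
        const double prodE = P_NUE * mh / (mh + Mh);
        const double degE = P_MU * E / (1.0 + E / P_ZETA);

        ydot[2 * i] = P_DM * lapM - degM + prodM;
        ydot[2 * i + 1] = P_DE * lapE - degE + prodE;
    }

    if (P_FLUX > 0.5)
        ydot[0] += P_J0 / (0.5 * dx);
}

/* Root functions for lsodar: g[0] crosses zero when the normalised
 * residual max|dC/dt|/(max C + atol) of both species falls below the
 * steady-state tolerance; g[1] crosses zero on concentration overflow
 * (blow-up guard). */
void er_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    const int nx = (int) P_NX;
    static double *ydot = NULL;
    static int ydot_len = 0;
    double maxM = 0.0, maxE = 0.0, maxdM = 0.0, maxdE = 0.0, maxy = 0.0;
    int i;

    if (ydot_len < *neq) {          /* reusable scratch, grown as needed */
        if (ydot != NULL) free(ydot);
        ydot = (double *) malloc(*neq * sizeof(double));
        ydot_len = *neq;
    }

    er_derivs(neq, t, y, ydot, out, ip);
    for (i = 0; i < nx; i++) {
        const double M = y[2 * i], E = y[2 * i + 1];
        if (M > maxM) maxM = M;
        if (E > maxE) maxE = E;
        if (fabs(y[2 * i]) > maxy) maxy = fabs(y[2 * i]);
        if (fabs(y[2 * i + 1]) > maxy) maxy = fabs(y[2 * i + 1]);
        if (fabs(ydot[2 * i]) > maxdM) maxdM = fabs(ydot[2 * i]);
        if (fabs(ydot[2 * i + 1]) > maxdE) maxdE = fabs(ydot[2 * i + 1]);
    }
    const double resM = maxdM / (maxM + P_ATOL);
    const double resE = maxdE / (maxE + P_ATOL);
    gout[0] = fmax(resM, resE) / P_SSTOL - 1.0;
    gout[1] = 1.0 - maxy / P_OVER;
}
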