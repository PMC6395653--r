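/* Compiled right-hand side of the tumor dynamical system (deSolve interface).
 *
 * Parameters arrive as one packed double vector (padded to PMAX), laid out
 * by the R side (see pack_parms() in R/dynamics.R):
 *   dims: nC, nm, nr, nf, nv, ne
 *   vmax[nr], vrev[nr]
 *   fwd triplets: species idx, reaction idx (0-based), km   (nf each)
 *   rev triplets: species idx, reaction idx, km             (nv each)
 *   effects: reaction idx, species idx, inhibit flag, k_half (ne each)
 *   growth_j, mu_max, mode_flux, vg
 *   eps_m[nm]
 *   iNAD, iNADH
 *   kd, hill_n, k_ratio
 *   C0[nC], F_in, F_out, mu_blood, v_cell
 *   Sc[nC*nr] column-major, Sm[nm*nr] column-major
 * State: y = (C[nC], m[nm], X, V_blood, V_tumor).
 */
#include <R.h>
#include <math.h>

#define PMAX 4096
#define RMAX 128

static double p[PMAX];

void warburgsim_init(void (*odeparms)(int *, double *))
{
    int N = PMAX;
    odeparms(&N, p);
}

void warburgsim_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    int k = 0;
    const int nC = (int) p[k++];
    const int nm = (int) p[k++];
    const int nr = (int) p[k++];
    const int nf = (int) p[k++];
    const int nv = (int) p[k++];
    const int ne = (int) p[k++];
    const double *vmax = p + k; k += nr;
    const double *vrev = p + k; k += nr;
    const double *fsp = p + k; k += nf;
    const double *frx = p + k; k += nf;
    const double *fkm = p + k; k += nf;
    const double *rsp = p + k; k += nv;
    const double *rrx = p + k; k += nv;
    const double *rkm = p + k; k += nv;
    const double *erx = p + k; k += ne;
    const double *esp = p + k; k += ne;
    const double *einh = p + k; k += ne;
    const double *ek = p + k; k += ne;
    const int gj = (int) p[k++];
    const double mu_max = p[k++];
    const int mode_flux = (int) p[k++];
    const double vg = p[k++];
    const double *eps_m = p + k; k += nm;
    const int iNAD = (int) p[k++];
    const int iNADH = (int) p[k++];
    const double kd = p[k++];
    const double hn = p[k++];
    const double kr = p[k++];
    const double *C0 = p + k; k += nC;
    const double F_in = p[k++];
    const double F_out = p[k++];
    const double mu_blood = p[k++];
    const double v_cell = p[k++];
    const double *Sc = p + k; k += nC * nr;
    const double *Sm = p + k; /* k += nm * nr; */

    const int ns = nC + nm;
    double conc[256];
    double pf[RMAX], pr[RMAX], v[RMAX];
    int i, j;

    for (i = 0; i < ns; i++) conc[i] = y[i] > 0 ? y[i] : 0.0;
    for (j = 0; j < nr; j++) { pf[j] = 1.0; pr[j] = 1.0; }
    for (i = 0; i < nf; i++) {
        double c = conc[(int) fsp[i]];
        pf[(int) frx[i]] *= c / (fkm[i] + c);
    }
    for (i = 0; i < nv; i++) {
        double c = conc[(int) rsp[i]];
        pr[(int) rrx[i]] *= c / (rkm[i] + c);
    }
    for (j = 0; j < nr; j++) v[j] = vmax[j] * pf[j] - vrev[j] * pr[j];
    for (i = 0; i < ne; i++) {
        double d = conc[(int) esp[i]];
        double fac = einh[i] > 0.5 ? ek[i] / (ek[i] + d) : 1.0 + d / (ek[i] + d);
        v[(int) erx[i]] *= fac;
    }

    double mu = mode_flux ? (vg > 0 ? mu_max * v[gj] / vg : 0.0) : mu_max;
    double nadh = conc[iNADH] > 1e-12 ? conc[iNADH] : 1e-12;
    double rho = conc[iNAD] / nadh;
    double rhon = pow(rho, hn);
    double dth = kd * (1.0 - rhon) / (pow(kr, hn) + rhon);

    double X = y[ns] > 0 ? y[ns] : 0.0;
    double Vb = y[ns + 1];

    for (i = 0; i < nC; i++) {
        double s = 0.0;
        for (j = 0; j < nr; j++) s += Sc[i + nC * j] * v[j];
        ydot[i] = s * X / Vb + (C0[i] * F_in - conc[i] * F_out) / Vb
                  - mu_blood * conc[i];
    }
    for (i = 0; i < nm; i++) {
        double s = 0.0;
        for (j = 0; j < nr; j++) s += Sm[i + nm * j] * v[j];
        ydot[nC + i] = s - (eps_m[i] + conc[nC + i]) * mu;
    }
    double dX = (mu - dth) * X;
    double dVb = mu_blood * Vb;
    ydot[ns] = dX;
    ydot[ns + 1] = dVb;
    ydot[ns + 2] = dX * 1e6 * v_cell + dVb * 1000.0;
}
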