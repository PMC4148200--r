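/* Compartmental reaction-transport right-hand side for the Dorsal-gradient
 * model, plus its analytic Jacobian. State vector y = (d, c, dc, dn), each
 * block of length n (compartments on a periodic ring):
 *   d  - cytoplasmic free Dl          c  - cytoplasmic free Cact
 *   dc - cytoplasmic Dl-Cact complex  dn - nuclear Dl
 *
 * Parameter vector p:
 *   p[0] = n, p[1] = Gamma, p[2] = k_i, p[3] = k_e, p[4] = P_Cact,
 *   p[5] = k_Deg, p[6] = k_b, p[7] = A_nuc, p[8] = V_nuc, p[9] = V_cyt,
 *   p[10 .. 10+n-1] = k_D(theta_j)
 */
#include <string.h>
#include <R.h>
#include <Rinternals.h>

SEXP dl_rhs_c(SEXP ys, SEXP ps)
{
    double *p = REAL(ps);
    int n = (int) p[0];
    double Gamma = p[1], k_i = p[2], k_e = p[3], P_Cact = p[4],
           k_Deg = p[5], k_b = p[6], A_nuc = p[7], V_nuc = p[8],
           V_cyt = p[9];
    double *kD = p + 10;
    double *y = REAL(ys);
    double *d = y, *c = y + n, *dc = y + 2 * n, *dn = y + 3 * n;

    SEXP out = PROTECT(allocVector(REALSXP, 4 * n));
    double *dy = REAL(out);

    for (int j = 0; j < n; j++) {
        int jm = (j == 0) ? n - 1 : j - 1;
        int jp = (j == n - 1) ? 0 : j + 1;
        double B = k_b * d[j] * c[j] - kD[j] * dc[j];
        double N = k_i * A_nuc * d[j] - k_e * A_nuc * dn[j];
        dy[j]         = -B - N / V_cyt + Gamma * (d[jm] - 2 * d[j] + d[jp]);
        dy[n + j]     = -B + P_Cact - k_Deg * c[j]
                        + Gamma * (c[jm] - 2 * c[j] + c[jp]);
        dy[2 * n + j] =  B + Gamma * (dc[jm] - 2 * dc[j] + dc[jp]);
        dy[3 * n + j] =  N / V_nuc;
    }
    UNPROTECT(1);
    return out;
}

/* Full (4n x 4n) Jacobian, column-major, for deSolve's jacfunc. */
SEXP dl_jac_c(SEXP ys, SEXP ps)
{
    double *p = REAL(ps);
    int n = (int) p[0];
    double Gamma = p[1], k_i = p[2], k_e = p[3],
           k_Deg = p[5], k_b = p[6], A_nuc = p[7], V_nuc = p[8],
           V_cyt = p[9];
    double *kD = p + 10;
    double *y = REAL(ys);
    double *d = y, *c = y + n;

    int m = 4 * n;
    SEXP out = PROTECT(allocMatrix(REALSXP, m, m));
    double *J = REAL(out);
    memset(J, 0, (size_t) m * m * sizeof(double));

#define EL(r, cc) J[(size_t)(cc) * m + (r)]
    for (int j = 0; j < n; j++) {
        int jm = (j == 0) ? n - 1 : j - 1;
        int jp = (j == n - 1) ? 0 : j + 1;
        double bd = k_b * d[j];   /* dB/dc  */
        double bc = k_b * c[j];   /* dB/dd  */

        /* row j: d'_j */
        EL(j, j)          = -bc - k_i * A_nuc / V_cyt - 2 * Gamma;
        EL(j, jm)        += Gamma;
        EL(j, jp)        += Gamma;
        EL(j, n + j)      = -bd;
        EL(j, 2 * n + j)  =  kD[j];
        EL(j, 3 * n + j)  =  k_e * A_nuc / V_cyt;

        /* row n+j: c'_j */
        EL(n + j, j)          = -bc;
        EL(n + j, n + j)      = -bd - k_Deg - 2 * Gamma;
        EL(n + j, n + jm)    += Gamma;
        EL(n + j, n + jp)    += Gamma;
        EL(n + j, 2 * n + j)  = kD[j];

        /* row 2n+j: dc'_j */
        EL(2 * n + j, j)           = bc;
        EL(2 * n + j, n + j)       = bd;
        EL(2 * n + j, 2 * n + j)   = -kD[j] - 2 * Gamma;
        EL(2 * n + j, 2 * n + jm) += Gamma;
        EL(2 * n + j, 2 * n + jp) += Gamma;

        /* row 3n+j: dn'_j */
        EL(3 * n + j, j)         = k_i * A_nuc / V_nuc;
        EL(3 * n + j, 3 * n + j) = -k_e * A_nuc / V_nuc;
    }
#undef EL
    UNPROTECT(1);
    return out;
}
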