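/* Core numerics for the meshless membrane + crescent-rod model.
 *
 * Particles carry a position r_i and a unit orientation u_i.  Membrane and
 * rod-backbone particles interact through
 *   U = U_rep + U_att + U_bend + U_tilt  (+ rod bonds, hook anchors, LJ)
 * with
 *   U_rep  = eps_rep * sum_{i<j} exp(-b(r-1)) f12(r/s_rep)
 *   U_att  = eps_att * sum_i [ 0.25 ln(1+exp(-4(rho_i - rho*))) - c0 ],
 *            rho_i = sum_j f12(r_ij/s_rho)
 *   U_bend = sum_{i<j} (k/2) |u_i - u_j - Cbd rhat|^2 w_cv(r)
 *   U_tilt = sum_{i<j} (k/2) [(u_i.rhat)^2 + (u_j.rhat)^2] w_cv(r)
 * where f12 is a smooth compact cutoff and w_cv a Gaussian-like compact
 * weight.  Hook particles are excluded-volume only.  Lengths in sigma,
 * energies in kBT.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>
#include <stdint.h>

enum {
  P_EPS_REP, P_B_REP, P_SREP_CUT, P_A_REP,
  P_EPS_ATT, P_RHO_STAR, P_A_RHO, P_SRHO_CUT,
  P_KBEND_MEM, P_KTILT_MEM, P_ALPHA_CV, P_R_GA, P_R_CC,
  P_KBEND_ROD, P_KTILT_ROD, P_CBD_ROD,
  P_SITE_K, P_EPS_SS, P_LJ_CUT, P_LJ_ON, P_KT, P_MASS, P_INERTIA,
  P_ATT_SHARP, P_ZCONF,
  NPAR
};

/* energy components (zconf = flat-plane restraint used by the edge-tension
   measurement scaffold) */
enum { E_REP, E_ATT, E_BEND, E_TILT, E_BOND, E_LJ, E_ZCONF, NE };

#define F_REP  1
#define F_ATT  2
#define F_BT   4
#define F_BOND 8
#define F_LJ   16
#define F_RODBEND 32  /* bend energy of intra-rod pairs only (REMD dU) */
#define F_ALL (F_REP|F_ATT|F_BT|F_BOND|F_LJ)

typedef struct {
  int n;
  double *x, *u;            /* 3*i + d layout */
  int *kind, *rod, *seg, *att;
  double L[3];
  int per[3];
  const double *par;
  int nb; int *bi, *bj; double *bk, *bl0;
  int ns; int *sh, *sa1, *sa2; double *scl, *scu;
} Sys;

typedef struct { int i, j; double d[3]; double r2; } Pair;

typedef struct {
  Pair *p; int np; int cap;
  int *head, *next, *cix;   /* cell list workspace */
  int ncell_cap;
  double *rho, *dgatt;
} Work;

/* ---------- smooth cutoff functions ---------- */

/* f(s) = exp[A (1 + 1/(s^12 - 1))], s < 1 (s scaled by cutoff), else 0 */
static inline double f12(double s, double A, double *df_ds) {
  if (s >= 1.0) { if (df_ds) *df_ds = 0.0; return 0.0; }
  double s2 = s * s, s4 = s2 * s2, s12 = s4 * s4 * s4;
  double den = s12 - 1.0;          /* in (-1, 0) */
  double val = exp(A * (1.0 + 1.0 / den));
  if (df_ds) *df_ds = val * A * (-12.0 * s12 / s) / (den * den);
  return val;
}

/* w_cv(r) = alpha * exp[(r/rga)^2 / ((r/rcc)^12 - 1)], r < rcc */
static inline double wcv(double r, double alpha, double rga, double rcc,
                         double *dw_dr) {
  double s = r / rcc;
  if (s >= 1.0) { if (dw_dr) *dw_dr = 0.0; return 0.0; }
  double g = (r / rga) * (r / rga);
  double s2 = s * s, s4 = s2 * s2, s12 = s4 * s4 * s4;
  double den = s12 - 1.0;
  double val = alpha * exp(g / den);
  if (dw_dr) {
    double dg = 2.0 * r / (rga * rga);
    double dden = 12.0 * s12 / r;
    *dw_dr = val * (dg / den - g * dden / (den * den));
  }
  return val;
}

static inline double att_g(double rho, double rho_star, double c0, double s) {
  /* (1/s)*ln(1+exp(-s(rho-rho*))) - c0: slope -1 below rho*, saturating
     above, with knee curvature proportional to s; stable for large |arg| */
  double a = -s * (rho - rho_star);
  double v = (a > 30.0) ? a / s : log1p(exp(a)) / s;
  return v - c0;
}

static inline double att_gprime(double rho, double rho_star, double s) {
  /* d/drho = -1/(1+exp(s(rho-rho*))) */
  double a = s * (rho - rho_star);
  if (a > 30.0) return -exp(-a);
  return -1.0 / (1.0 + exp(a));
}

static inline double minimg(double d, double L, int per) {
  if (per) d -= L * nearbyint(d / L);
  return d;
}

/* ---------- pair list ---------- */

static void add_pair(Work *w, int i, int j, const double d[3], double r2) {
  if (w->np >= w->cap)
    error("pair buffer overflow (%d pairs): configuration has collapsed", w->cap);
  Pair *p = &w->p[w->np++];
  p->i = i; p->j = j;
  p->d[0] = d[0]; p->d[1] = d[1]; p->d[2] = d[2];
  p->r2 = r2;
}

static void build_pairs(const Sys *S, Work *w, double rc) {
  const int n = S->n;
  const double rc2 = rc * rc;
  w->np = 0;
  double lo[3], hi[3], cl[3];
  int nc[3];
  int use_cells = (n > 192);
  for (int d = 0; d < 3 && use_cells; d++) {
    if (S->per[d]) { lo[d] = 0.0; hi[d] = S->L[d]; }
    else {
      lo[d] = hi[d] = S->x[d];
      for (int i = 1; i < n; i++) {
        double v = S->x[3 * i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
      hi[d] += 1e-9; lo[d] -= 1e-9;
    }
    double span = hi[d] - lo[d];
    nc[d] = (int)floor(span / rc);
    if (nc[d] < 1) nc[d] = 1;
    if (S->per[d] && nc[d] < 3) use_cells = 0;  /* avoid double counting */
    cl[d] = span / nc[d];
  }
  if (!use_cells) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; k++) {
          d[k] = minimg(S->x[3 * i + k] - S->x[3 * j + k], S->L[k], S->per[k]);
          r2 += d[k] * d[k];
        }
        if (r2 < rc2) add_pair(w, i, j, d, r2);
      }
    return;
  }
  int ntot = nc[0] * nc[1] * nc[2];
  if (ntot > w->ncell_cap) {
    /* very dilute system: the grid would dwarf the particle count */
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; k++) {
          d[k] = minimg(S->x[3 * i + k] - S->x[3 * j + k], S->L[k], S->per[k]);
          r2 += d[k] * d[k];
        }
        if (r2 < rc2) add_pair(w, i, j, d, r2);
      }
    return;
  }
  int *head = w->head, *next = w->next, *cix = w->cix;
  for (int c = 0; c < ntot; c++) head[c] = -1;
  for (int i = 0; i < n; i++) {
    int ic[3];
    for (int d = 0; d < 3; d++) {
      double v = S->x[3 * i + d];
      if (S->per[d]) { v -= S->L[d] * floor(v / S->L[d]); }
      int c = (int)((v - lo[d]) / cl[d]);
      if (c < 0) c = 0;
      if (c >= nc[d]) c = nc[d] - 1;
      ic[d] = c;
    }
    int c = (ic[2] * nc[1] + ic[1]) * nc[0] + ic[0];
    cix[i] = c;
    next[i] = head[c];
    head[c] = i;
  }
  for (int cz = 0; cz < nc[2]; cz++)
  for (int cy = 0; cy < nc[1]; cy++)
  for (int cx = 0; cx < nc[0]; cx++) {
    int c = (cz * nc[1] + cy) * nc[0] + cx;
    for (int oz = -1; oz <= 1; oz++)
    for (int oy = -1; oy <= 1; oy++)
    for (int ox = -1; ox <= 1; ox++) {
      int jx = cx + ox, jy = cy + oy, jz = cz + oz;
      if (S->per[0]) jx = (jx + nc[0]) % nc[0]; else if (jx < 0 || jx >= nc[0]) continue;
      if (S->per[1]) jy = (jy + nc[1]) % nc[1]; else if (jy < 0 || jy >= nc[1]) continue;
      if (S->per[2]) jz = (jz + nc[2]) % nc[2]; else if (jz < 0 || jz >= nc[2]) continue;
      int c2 = (jz * nc[1] + jy) * nc[0] + jx;
      if (c2 < c) continue;
      for (int i = head[c]; i >= 0; i = next[i]) {
        int jstart = (c2 == c) ? next[i] : head[c2];
        for (int j = jstart; j >= 0; j = next[j]) {
          double d[3], r2 = 0.0;
          for (int k = 0; k < 3; k++) {
            d[k] = minimg(S->x[3 * i + k] - S->x[3 * j + k], S->L[k], S->per[k]);
            r2 += d[k] * d[k];
          }
          if (r2 < rc2) add_pair(w, i, j, d, r2);
        }
      }
    }
  }
}

/* ---------- force / energy evaluation ---------- */

static double max_cutoff(const double *par) {
  double rc = par[P_SREP_CUT];
  if (par[P_SRHO_CUT] > rc) rc = par[P_SRHO_CUT];
  if (par[P_R_CC] > rc) rc = par[P_R_CC];
  if (par[P_EPS_SS] > 0.0 && par[P_LJ_CUT] > rc) rc = par[P_LJ_CUT];
  return rc;
}

/* quintic smoothstep switch: 1 below on, 0 above cut */
static inline double ljswitch(double r, double on, double cut, double *ds) {
  if (r <= on) { if (ds) *ds = 0.0; return 1.0; }
  if (r >= cut) { if (ds) *ds = 0.0; return 0.0; }
  double t = (r - on) / (cut - on);
  double s = 1.0 - t * t * t * (10.0 - 15.0 * t + 6.0 * t * t);
  if (ds) *ds = -30.0 * t * t * (1.0 - t) * (1.0 - t) / (cut - on);
  return s;
}

static void compute_forces(const Sys *S, Work *w, int flags,
                           double E[NE], double *f, double *gu, double W[3]) {
  const int n = S->n;
  const double *par = S->par;
  const double kT = par[P_KT];
  for (int k = 0; k < NE; k++) E[k] = 0.0;
  for (int k = 0; k < 3; k++) W[k] = 0.0;
  memset(f, 0, sizeof(double) * 3 * n);
  memset(gu, 0, sizeof(double) * 3 * n);

  if (flags & F_RODBEND) {
    /* intra-rod bend energy only (cheap REMD dU path), no forces */
    build_pairs(S, w, par[P_R_CC]);
    double cbd = par[P_CBD_ROD], kb = par[P_KBEND_ROD];
    for (int q = 0; q < w->np; q++) {
      Pair *p = &w->p[q];
      int i = p->i, j = p->j;
      if (S->rod[i] < 0 || S->rod[i] != S->rod[j]) continue;
      if (S->kind[i] != 1 || S->kind[j] != 1) continue;
      double r = sqrt(p->r2);
      double wv = wcv(r, par[P_ALPHA_CV], par[P_R_GA], par[P_R_CC], NULL);
      if (wv == 0.0) continue;
      double v[3], vv = 0.0;
      for (int k = 0; k < 3; k++) {
        double rh = p->d[k] / r;
        v[k] = S->u[3 * i + k] - S->u[3 * j + k] - cbd * rh;
        vv += v[k] * v[k];
      }
      E[E_BEND] += 0.5 * kb * vv * wv;
    }
    return;
  }

  double rc = max_cutoff(par);
  build_pairs(S, w, rc);

  /* pass 1: local densities (membrane + backbone only) */
  const double srho = par[P_SRHO_CUT], Arho = par[P_A_RHO];
  double *rho = w->rho, *dgatt = w->dgatt;
  memset(rho, 0, sizeof(double) * n);
  if (flags & F_ATT) {
    for (int q = 0; q < w->np; q++) {
      Pair *p = &w->p[q];
      if (S->kind[p->i] > 1 || S->kind[p->j] > 1) continue;
      if (p->r2 >= srho * srho) continue;
      double r = sqrt(p->r2);
      double fr = f12(r / srho, Arho, NULL);
      rho[p->i] += fr; rho[p->j] += fr;
    }
    double rho_star = par[P_RHO_STAR];
    double sharp = par[P_ATT_SHARP] > 0 ? par[P_ATT_SHARP] : 4.0;
    double sr = sharp * rho_star;
    double c0 = (sr > 30.0 ? sr : log1p(exp(sr))) / sharp;
    double eatt = par[P_EPS_ATT];
    for (int i = 0; i < n; i++) {
      if (S->kind[i] > 1) { dgatt[i] = 0.0; continue; }
      E[E_ATT] += eatt * att_g(rho[i], rho_star, c0, sharp);
      dgatt[i] = eatt * att_gprime(rho[i], rho_star, sharp);
    }
  }

  const double erep = par[P_EPS_REP], brep = par[P_B_REP];
  const double srep = par[P_SREP_CUT], Arep = par[P_A_REP];
  const double alpha = par[P_ALPHA_CV], rga = par[P_R_GA], rcc = par[P_R_CC];
  const double eps_ss = par[P_EPS_SS], ljcut = par[P_LJ_CUT], ljon = par[P_LJ_ON];
  const double cbd_rod = par[P_CBD_ROD];

  for (int q = 0; q < w->np; q++) {
    Pair *p = &w->p[q];
    const int i = p->i, j = p->j;
    const double r2 = p->r2;
    const double r = sqrt(r2);
    if (r < 1e-8) error("particles %d and %d coincide", i + 1, j + 1);
    const double *d = p->d;
    double fpair = 0.0;    /* radial force magnitude on i along +d */

    int isLJ = 0;
    if (eps_ss > 0.0 && S->att[i] && S->att[j] &&
        S->rod[i] >= 0 && S->rod[j] >= 0 && S->rod[i] != S->rod[j])
      isLJ = 1;

    if ((flags & F_REP) && !isLJ && r < srep) {
      double dfr;
      double fr = f12(r / srep, Arep, &dfr);
      double ex = exp(-brep * (r - 1.0));
      double e = erep * ex * fr;
      E[E_REP] += e;
      fpair += -(erep * (-brep * ex * fr + ex * dfr / srep));
    }

    if ((flags & F_LJ) && isLJ && r < ljcut) {
      double x2 = 1.0 / r2, x6 = x2 * x2 * x2, x12 = x6 * x6;
      double ds, sw = ljswitch(r, ljon, ljcut, &ds);
      double ulj = 4.0 * eps_ss * (x12 - x6);
      double dulj = 4.0 * eps_ss * (-12.0 * x12 + 6.0 * x6) / r;
      E[E_LJ] += ulj * sw;
      fpair += -(dulj * sw + ulj * ds);
    }

    if ((flags & F_ATT) && S->kind[i] <= 1 && S->kind[j] <= 1 && r < srho) {
      double dfr;
      f12(r / srho, Arho, &dfr);
      double gsum = dgatt[i] + dgatt[j];
      fpair += -(gsum * dfr / srho);
    }

    if ((flags & F_BT) && S->kind[i] <= 1 && S->kind[j] <= 1 && r < rcc) {
      double dwv;
      double wv = wcv(r, alpha, rga, rcc, &dwv);
      if (wv != 0.0) {
        double kb, kt, cbd;
        if (S->rod[i] >= 0 && S->rod[i] == S->rod[j]) {
          kb = par[P_KBEND_ROD]; kt = par[P_KTILT_ROD]; cbd = cbd_rod;
        } else {
          kb = par[P_KBEND_MEM]; kt = par[P_KTILT_MEM]; cbd = 0.0;
        }
        double rh[3];
        for (int k = 0; k < 3; k++) rh[k] = d[k] / r;
        const double *ui = &S->u[3 * i], *uj = &S->u[3 * j];
        double v[3], vv = 0.0, vdotrh = 0.0;
        for (int k = 0; k < 3; k++) {
          v[k] = ui[k] - uj[k] - cbd * rh[k];
          vv += v[k] * v[k];
          vdotrh += v[k] * rh[k];
        }
        double uir = ui[0] * rh[0] + ui[1] * rh[1] + ui[2] * rh[2];
        double ujr = uj[0] * rh[0] + uj[1] * rh[1] + uj[2] * rh[2];
        E[E_BEND] += 0.5 * kb * vv * wv;
        E[E_TILT] += 0.5 * kt * (uir * uir + ujr * ujr) * wv;
        /* radial parts through w'(r) */
        fpair += -(0.5 * kb * vv + 0.5 * kt * (uir * uir + ujr * ujr)) * dwv;
        /* non-radial position gradient via d rhat / d r_i */
        /* bend: -kb*cbd*wv*(v - (v.rh) rh)/r ; tilt: kt*wv*(uir*(ui-uir*rh)+ujr*(uj-ujr*rh))/r */
        for (int k = 0; k < 3; k++) {
          double gpos = 0.0;
          gpos += -kb * cbd * wv * (v[k] - vdotrh * rh[k]) / r;
          gpos += kt * wv * (uir * (ui[k] - uir * rh[k]) +
                             ujr * (uj[k] - ujr * rh[k])) / r;
          /* gpos is dU/dr_i excluding radial part; force on i is -gpos */
          f[3 * i + k] -= gpos;
          f[3 * j + k] += gpos;
          W[k] += d[k] * (-gpos);
          /* orientation gradients */
          gu[3 * i + k] += kb * wv * v[k] + kt * wv * uir * rh[k];
          gu[3 * j + k] += -kb * wv * v[k] + kt * wv * ujr * rh[k];
        }
      }
    }

    if (fpair != 0.0) {
      for (int k = 0; k < 3; k++) {
        double fk = fpair * d[k] / r;
        f[3 * i + k] += fk;
        f[3 * j + k] -= fk;
        W[k] += d[k] * fk;
      }
    }
  }

  /* bonds */
  if (flags & F_BOND) {
    for (int b = 0; b < S->nb; b++) {
      int i = S->bi[b], j = S->bj[b];
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; k++) {
        d[k] = minimg(S->x[3 * i + k] - S->x[3 * j + k], S->L[k], S->per[k]);
        r2 += d[k] * d[k];
      }
      double r = sqrt(r2);
      double dr = r - S->bl0[b];
      E[E_BOND] += 0.5 * S->bk[b] * dr * dr;
      double fmag = -S->bk[b] * dr;       /* along +d on i */
      for (int k = 0; k < 3; k++) {
        double fk = fmag * d[k] / r;
        f[3 * i + k] += fk;
        f[3 * j + k] -= fk;
        W[k] += d[k] * fk;
      }
    }
    /* hook site restraints: U = (ks/2) |r_h - p*|^2,
       p* = m + cl*(that x ubar) + cu*ubar */
    double ks = par[P_SITE_K];
    for (int s = 0; s < S->ns; s++) {
      int h = S->sh[s], a1 = S->sa1[s], a2 = S->sa2[s];
      double cl = S->scl[s], cu = S->scu[s];
      double t[3], dm[3], r2t = 0.0;
      for (int k = 0; k < 3; k++) {
        t[k] = minimg(S->x[3 * a2 + k] - S->x[3 * a1 + k], S->L[k], S->per[k]);
        r2t += t[k] * t[k];
      }
      double Lt = sqrt(r2t);
      double that[3];
      for (int k = 0; k < 3; k++) that[k] = t[k] / Lt;
      double vsum[3];
      for (int k = 0; k < 3; k++) vsum[k] = S->u[3 * a1 + k] + S->u[3 * a2 + k];
      double nv = sqrt(vsum[0] * vsum[0] + vsum[1] * vsum[1] + vsum[2] * vsum[2]);
      double ub[3];
      for (int k = 0; k < 3; k++) ub[k] = vsum[k] / nv;
      double bb[3] = { that[1] * ub[2] - that[2] * ub[1],
                       that[2] * ub[0] - that[0] * ub[2],
                       that[0] * ub[1] - that[1] * ub[0] };
      /* hook offset relative to anchor midpoint, minimum image */
      for (int k = 0; k < 3; k++) {
        double mid_rel = 0.5 * t[k];           /* midpoint - a1 */
        double dh = minimg(S->x[3 * h + k] - S->x[3 * a1 + k], S->L[k], S->per[k]);
        dm[k] = dh - mid_rel - cl * bb[k] - cu * ub[k];   /* r_h - p* */
      }
      double e = 0.5 * ks * (dm[0] * dm[0] + dm[1] * dm[1] + dm[2] * dm[2]);
      E[E_BOND] += e;
      double g[3];  /* ks * (r_h - p*) = dU/dr_h */
      for (int k = 0; k < 3; k++) g[k] = ks * dm[k];
      /* force on hook */
      for (int k = 0; k < 3; k++) f[3 * h + k] -= g[k];
      /* dpstar/da1: I/2 + (cl/Lt) [ub]_x (I - that thatT) ; da2: I/2 - same */
      double Pg[3]; /* (I - that thatT) g */
      double tg = that[0] * g[0] + that[1] * g[1] + that[2] * g[2];
      for (int k = 0; k < 3; k++) Pg[k] = g[k] - tg * that[k];
      /* M^T g where M = (cl/Lt) [ub]_x (I-tt): compute (I-tt)^T [ub]_x^T g
         [ub]_x^T = -[ub]_x, so M^T g = -(cl/Lt)(I-tt)(ub x g) */
      double uxg[3] = { ub[1] * g[2] - ub[2] * g[1],
                        ub[2] * g[0] - ub[0] * g[2],
                        ub[0] * g[1] - ub[1] * g[0] };
      double tuxg = that[0] * uxg[0] + that[1] * uxg[1] + that[2] * uxg[2];
      double MTg[3];
      for (int k = 0; k < 3; k++)
        MTg[k] = -(cl / Lt) * (uxg[k] - tuxg * that[k]);
      /* dU/dra = -(dpstar/dra)^T g  =>  F_a = (dpstar/dra)^T g */
      for (int k = 0; k < 3; k++) {
        double Fa1 = 0.5 * g[k] + MTg[k];
        double Fa2 = 0.5 * g[k] - MTg[k];
        f[3 * a1 + k] += Fa1;
        f[3 * a2 + k] += Fa2;
      }
      /* virial: group-relative, ref = a1 position; forces: h gets -g, a1,a2 above */
      for (int k = 0; k < 3; k++) {
        double dh = minimg(S->x[3 * h + k] - S->x[3 * a1 + k], S->L[k], S->per[k]);
        W[k] += dh * (-g[k]) + t[k] * (0.5 * g[k] - MTg[k]);
      }
      /* orientation gradients:
         dU/dpstar = -g ; dpstar/dub = cl [that]_x + cu I so
         (dpstar/dub)^T g = -cl (that x g) + cu g =: q2 ; dU/dub = -q2 ;
         dU/du_a = (I - ub ubT)/nv dU/dub, the same for both anchors */
      double txg[3] = { that[1] * g[2] - that[2] * g[1],
                        that[2] * g[0] - that[0] * g[2],
                        that[0] * g[1] - that[1] * g[0] };
      double q2[3];
      for (int k = 0; k < 3; k++) q2[k] = -cl * txg[k] + cu * g[k];
      double ubq = ub[0] * q2[0] + ub[1] * q2[1] + ub[2] * q2[2];
      for (int k = 0; k < 3; k++) {
        double dUdua = -(q2[k] - ubq * ub[k]) / nv;
        gu[3 * a1 + k] += dUdua;
        gu[3 * a2 + k] += dUdua;
      }
    }
  }

  /* optional flat-plane confinement (z spring); no in-plane virial */
  if (par[P_ZCONF] > 0.0) {
    double kz = par[P_ZCONF];
    for (int i = 0; i < n; i++) {
      double z = S->x[3 * i + 2];
      E[E_ZCONF] += 0.5 * kz * z * z;
      f[3 * i + 2] -= kz * z;
      W[2] += z * (-kz * z);
    }
  }

  (void)kT;
  /* project orientation gradients tangent to the unit sphere */
  for (int i = 0; i < n; i++) {
    double *g = &gu[3 * i];
    const double *ui = &S->u[3 * i];
    double dot = g[0] * ui[0] + g[1] * ui[1] + g[2] * ui[2];
    for (int k = 0; k < 3; k++) g[k] -= dot * ui[k];
  }
}

/* ---------- RNG: xoshiro256** with splitmix64 seeding ---------- */

typedef struct { uint64_t s[4]; double spare; int has_spare; } Rng;

static uint64_t splitmix64(uint64_t *x) {
  uint64_t z = (*x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static void rng_seed(Rng *r, uint64_t seed) {
  uint64_t x = seed;
  for (int i = 0; i < 4; i++) r->s[i] = splitmix64(&x);
  r->has_spare = 0; r->spare = 0.0;
}

static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

static inline uint64_t rng_next(Rng *r) {
  uint64_t *s = r->s;
  uint64_t result = rotl(s[1] * 5, 7) * 9;
  uint64_t t = s[1] << 17;
  s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
  s[2] ^= t; s[3] = rotl(s[3], 45);
  return result;
}

static inline double rng_unif(Rng *r) {
  return (rng_next(r) >> 11) * (1.0 / 9007199254740992.0);
}

static double rng_norm(Rng *r) {
  if (r->has_spare) { r->has_spare = 0; return r->spare; }
  double u, v, s;
  do {
    u = 2.0 * rng_unif(r) - 1.0;
    v = 2.0 * rng_unif(r) - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double m = sqrt(-2.0 * log(s) / s);
  r->spare = v * m; r->has_spare = 1;
  return u * m;
}

/* ---------- helpers for SEXP unpacking ---------- */

static SEXP getel(SEXP list, const char *name) {
  SEXP names = getAttrib(list, R_NamesSymbol);
  for (int i = 0; i < length(list); i++)
    if (strcmp(CHAR(STRING_ELT(names, i)), name) == 0)
      return VECTOR_ELT(list, i);
  return R_NilValue;
}

static double opt_num(SEXP opts, const char *name, double def) {
  SEXP e = getel(opts, name);
  if (e == R_NilValue || length(e) == 0) return def;
  return asReal(e);
}

/* transpose Nx3 R matrix into contiguous 3*i+d */
static double *unpack_mat(SEXP m, int n) {
  double *out = (double *) R_alloc((size_t)3 * n, sizeof(double));
  double *src = REAL(m);
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++)
      out[3 * i + d] = src[i + (size_t)n * d];
  return out;
}

static SEXP pack_mat(const double *x, int n) {
  SEXP m = PROTECT(allocMatrix(REALSXP, n, 3));
  double *dst = REAL(m);
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++)
      dst[i + (size_t)n * d] = x[3 * i + d];
  UNPROTECT(1);
  return m;
}

static int *unpack_int(SEXP v, int n) {
  int *out = (int *) R_alloc(n, sizeof(int));
  memcpy(out, INTEGER(v), sizeof(int) * n);
  return out;
}

static void setup_sys(Sys *S, SEXP sys, SEXP par) {
  SEXP x = getel(sys, "pos");
  S->n = nrows(x);
  S->x = unpack_mat(x, S->n);
  S->u = unpack_mat(getel(sys, "orient"), S->n);
  S->kind = unpack_int(getel(sys, "kind"), S->n);
  S->rod = unpack_int(getel(sys, "rod"), S->n);
  S->seg = unpack_int(getel(sys, "seg"), S->n);
  S->att = unpack_int(getel(sys, "att"), S->n);
  double *L = REAL(getel(sys, "L"));
  int *per = INTEGER(getel(sys, "per"));
  for (int d = 0; d < 3; d++) { S->L[d] = L[d]; S->per[d] = per[d]; }
  S->par = REAL(par);
  SEXP bonds = getel(sys, "bonds");
  S->nb = (bonds == R_NilValue) ? 0 : length(getel(bonds, "i"));
  if (S->nb > 0) {
    S->bi = unpack_int(getel(bonds, "i"), S->nb);
    S->bj = unpack_int(getel(bonds, "j"), S->nb);
    S->bk = REAL(getel(bonds, "k"));
    S->bl0 = REAL(getel(bonds, "l0"));
    for (int b = 0; b < S->nb; b++) { S->bi[b]--; S->bj[b]--; }
  }
  SEXP sites = getel(sys, "sites");
  S->ns = (sites == R_NilValue) ? 0 : length(getel(sites, "hook"));
  if (S->ns > 0) {
    S->sh = unpack_int(getel(sites, "hook"), S->ns);
    S->sa1 = unpack_int(getel(sites, "a1"), S->ns);
    S->sa2 = unpack_int(getel(sites, "a2"), S->ns);
    S->scl = REAL(getel(sites, "clat"));
    S->scu = REAL(getel(sites, "cup"));
    for (int s = 0; s < S->ns; s++) { S->sh[s]--; S->sa1[s]--; S->sa2[s]--; }
  }
}

static Work *setup_work(const Sys *S) {
  Work *w = (Work *) R_alloc(1, sizeof(Work));
  w->cap = 80 * S->n + 1024;
  w->p = (Pair *) R_alloc(w->cap, sizeof(Pair));
  w->ncell_cap = 4 * S->n + 64;
  w->head = (int *) R_alloc(w->ncell_cap, sizeof(int));
  w->next = (int *) R_alloc(S->n, sizeof(int));
  w->cix = (int *) R_alloc(S->n, sizeof(int));
  w->rho = (double *) R_alloc(S->n, sizeof(double));
  w->dgatt = (double *) R_alloc(S->n, sizeof(double));
  w->np = 0;
  return w;
}

/* ---------- .Call: single force/energy evaluation ---------- */

SEXP C_forces(SEXP sys, SEXP par, SEXP flags_) {
  Sys S; setup_sys(&S, sys, par);
  Work *w = setup_work(&S);
  int flags = asInteger(flags_);
  double E[NE], W[3];
  double *f = (double *) R_alloc((size_t)3 * S.n, sizeof(double));
  double *gu = (double *) R_alloc((size_t)3 * S.n, sizeof(double));
  compute_forces(&S, w, flags, E, f, gu, W);
  SEXP out = PROTECT(allocVector(VECSXP, 5));
  SEXP nm = PROTECT(allocVector(STRSXP, 5));
  const char *nms[5] = {"energy", "force", "ugrad", "virial", "rho"};
  for (int i = 0; i < 5; i++) SET_STRING_ELT(nm, i, mkChar(nms[i]));
  setAttrib(out, R_NamesSymbol, nm);
  SEXP Ee = PROTECT(allocVector(REALSXP, NE));
  memcpy(REAL(Ee), E, sizeof(double) * NE);
  SET_VECTOR_ELT(out, 0, Ee);
  SET_VECTOR_ELT(out, 1, pack_mat(f, S.n));
  SET_VECTOR_ELT(out, 2, pack_mat(gu, S.n));
  SEXP Wv = PROTECT(allocVector(REALSXP, 3));
  memcpy(REAL(Wv), W, sizeof(double) * 3);
  SET_VECTOR_ELT(out, 3, Wv);
  SEXP Rv = PROTECT(allocVector(REALSXP, S.n));
  memcpy(REAL(Rv), w->rho, sizeof(double) * S.n);
  SET_VECTOR_ELT(out, 4, Rv);
  UNPROTECT(5);
  return out;
}

/* ---------- Langevin dynamics ---------- */

static void rotate_u(double *u, const double *om, double h) {
  double a = sqrt(om[0] * om[0] + om[1] * om[1] + om[2] * om[2]) * h;
  if (a < 1e-14) return;
  double k[3] = { om[0], om[1], om[2] };
  double nk = a / h;
  for (int d = 0; d < 3; d++) k[d] /= nk;
  double c = cos(a), s = sin(a);
  double kxu[3] = { k[1] * u[2] - k[2] * u[1],
                    k[2] * u[0] - k[0] * u[2],
                    k[0] * u[1] - k[1] * u[0] };
  double kdu = k[0] * u[0] + k[1] * u[1] + k[2] * u[2];
  for (int d = 0; d < 3; d++)
    u[d] = u[d] * c + kxu[d] * s + k[d] * kdu * (1.0 - c);
  double nrm = sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int d = 0; d < 3; d++) u[d] /= nrm;
}

#define NSCOL 22

SEXP C_run(SEXP sys, SEXP par_, SEXP opts) {
  Sys S; setup_sys(&S, sys, par_);
  const int n = S.n;
  /* copy par: C_rod switching handled R-side; MC moves may need it mutable */
  double *par = (double *) R_alloc(NPAR, sizeof(double));
  memcpy(par, REAL(par_), sizeof(double) * NPAR);
  S.par = par;
  Work *w = setup_work(&S);

  double *v = unpack_mat(getel(sys, "vel"), n);
  double *om = unpack_mat(getel(sys, "avel"), n);

  const long nsteps = (long) opt_num(opts, "nsteps", 0);
  const double dt = opt_num(opts, "dt", 0.005);
  const double gt = opt_num(opts, "gammaT", 1.0);
  const double gr = opt_num(opts, "gammaR", 1.0);
  const int thermo = (int) opt_num(opts, "thermostat", 1);
  const double kT = par[P_KT];
  const double mass = par[P_MASS], inert = par[P_INERTIA];
  const long sample_every = (long) opt_num(opts, "sampleEvery", 100);
  const long frame_every = (long) opt_num(opts, "frameEvery", 0);
  const long mc_every = (long) opt_num(opts, "mcEvery", 0);
  const double mc_delta = opt_num(opts, "mcDelta", 0.001);
  const double t0 = opt_num(opts, "t0", 0.0);
  const double maxstep_len = opt_num(opts, "maxMove", 0.5);

  Rng rng;
  SEXP rst = getel(opts, "rngState");
  if (rst != R_NilValue && length(rst) == 32) {
    memcpy(rng.s, RAW(rst), 32);
    rng.has_spare = 0; rng.spare = 0.0;
  } else {
    rng_seed(&rng, (uint64_t)(int64_t) opt_num(opts, "seed", 1));
  }

  /* spectrum q list (integer mode pairs) */
  SEXP qm = getel(opts, "qmodes");
  int nq = (qm == R_NilValue) ? 0 : nrows(qm);
  int *qnx = NULL, *qny = NULL;
  double *spec = NULL;
  long spec_count = 0;
  if (nq > 0) {
    qnx = (int *) R_alloc(nq, sizeof(int));
    qny = (int *) R_alloc(nq, sizeof(int));
    for (int q = 0; q < nq; q++) {
      qnx[q] = INTEGER(qm)[q];
      qny[q] = INTEGER(qm)[q + nq];
    }
    spec = (double *) R_alloc(nq, sizeof(double));
    memset(spec, 0, sizeof(double) * nq);
  }

  long nsamp = nsteps / sample_every + 1;
  SEXP samples = PROTECT(allocMatrix(REALSXP, nsamp, NSCOL));
  double *smp = REAL(samples);
  long isamp = 0;
  long nf = frame_every > 0 ? nsteps / frame_every : 0;
  SEXP fx = R_NilValue, fu = R_NilValue, ftime = R_NilValue, fL = R_NilValue;
  int nprot = 1;
  double *pfx = NULL, *pfu = NULL, *pft = NULL, *pfL = NULL;
  if (nf > 0) {
    fx = PROTECT(alloc3DArray(REALSXP, n, 3, (int)nf)); nprot++;
    fu = PROTECT(alloc3DArray(REALSXP, n, 3, (int)nf)); nprot++;
    ftime = PROTECT(allocVector(REALSXP, nf)); nprot++;
    fL = PROTECT(allocMatrix(REALSXP, 3, (int)nf)); nprot++;
    pfx = REAL(fx); pfu = REAL(fu); pft = REAL(ftime); pfL = REAL(fL);
  }
  long iframe = 0;

  /* unwrapped displacement accumulators for MSD */
  double *disp = (double *) R_alloc((size_t)3 * n, sizeof(double));
  memset(disp, 0, sizeof(double) * 3 * n);

  double E[NE], W[3];
  double *f = (double *) R_alloc((size_t)3 * n, sizeof(double));
  double *gu = (double *) R_alloc((size_t)3 * n, sizeof(double));
  compute_forces(&S, w, F_ALL, E, f, gu, W);

  const double c1t = thermo ? exp(-gt * dt) : 1.0;
  const double c2t = thermo ? sqrt((1.0 - c1t * c1t) * kT / mass) : 0.0;
  const double c1r = thermo ? exp(-gr * dt) : 1.0;
  const double c2r = thermo ? sqrt((1.0 - c1r * c1r) * kT / inert) : 0.0;

  long mc_try = 0, mc_acc = 0;
  double *xs = (double *) R_alloc((size_t)3 * n, sizeof(double));

  /* sampling macro body as function-like block */
#define DO_SAMPLE(step) do {                                            \
    double Kt = 0.0, Kr = 0.0, m2 = 0.0, m3 = 0.0, kx = 0.0, ky = 0.0;  \
    for (int i = 0; i < n; i++) {                                       \
      double vx = v[3*i], vy = v[3*i+1], vz = v[3*i+2];                 \
      Kt += 0.5 * mass * (vx*vx + vy*vy + vz*vz);                       \
      kx += mass * vx * vx; ky += mass * vy * vy;                       \
      Kr += 0.5 * inert * (om[3*i]*om[3*i] + om[3*i+1]*om[3*i+1] + om[3*i+2]*om[3*i+2]); \
      double dx = disp[3*i], dy = disp[3*i+1], dz = disp[3*i+2];        \
      m2 += dx*dx + dy*dy; m3 += dx*dx + dy*dy + dz*dz;                 \
    }                                                                   \
    double A = S.L[0] * S.L[1];                                         \
    double Upot = 0.0;                                                  \
    for (int c = 0; c < NE; c++) Upot += E[c];                          \
    double row[NSCOL] = { (double)(step), t0 + (step)*dt,               \
      E[0], E[1], E[2], E[3], E[4], E[5], Upot, Kt, Kr,                 \
      S.L[0], S.L[1], S.L[2], A,                                        \
      W[0], W[1],                                                       \
      -(kx + ky + W[0] + W[1]) / (2.0 * A),                             \
      -(kx + W[0]) / S.L[0],                                            \
      m2 / n, m3 / n,                                                   \
      mc_try > 0 ? (double) mc_acc / mc_try : NA_REAL };                \
    for (int c = 0; c < NSCOL; c++) smp[isamp + nsamp * c] = row[c];    \
    isamp++;                                                            \
    if (nq > 0) {                                                       \
      double zbar = 0.0; int nz = 0;                                    \
      for (int i = 0; i < n; i++) if (S.kind[i] <= 1) { zbar += S.x[3*i+2]; nz++; } \
      zbar /= nz;                                                       \
      for (int q = 0; q < nq; q++) {                                    \
        double qx = 2.0 * M_PI * qnx[q] / S.L[0];                       \
        double qy = 2.0 * M_PI * qny[q] / S.L[1];                       \
        double re = 0.0, im = 0.0;                                      \
        for (int i = 0; i < n; i++) {                                   \
          if (S.kind[i] > 1) continue;                                  \
          double ph = qx * S.x[3*i] + qy * S.x[3*i+1];                  \
          double zz = S.x[3*i+2] - zbar;                                \
          re += zz * cos(ph); im -= zz * sin(ph);                       \
        }                                                               \
        spec[q] += re * re + im * im;                                   \
      }                                                                 \
      spec_count++;                                                     \
    }                                                                   \
  } while (0)

  DO_SAMPLE(0L);

  for (long step = 1; step <= nsteps; step++) {
    /* B */
    for (int i = 0; i < n; i++) {
      for (int d = 0; d < 3; d++)
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] / mass;
      /* torque tau = u x (-gu) */
      const double *ui = &S.u[3 * i];
      double *g = &gu[3 * i];
      double tq[3] = { ui[1] * (-g[2]) - ui[2] * (-g[1]),
                       ui[2] * (-g[0]) - ui[0] * (-g[2]),
                       ui[0] * (-g[1]) - ui[1] * (-g[0]) };
      for (int d = 0; d < 3; d++) om[3 * i + d] += 0.5 * dt * tq[d] / inert;
    }
    /* A */
    for (int i = 0; i < n; i++) {
      for (int d = 0; d < 3; d++) {
        double dx = 0.5 * dt * v[3 * i + d];
        S.x[3 * i + d] += dx;
        disp[3 * i + d] += dx;
      }
      rotate_u(&S.u[3 * i], &om[3 * i], 0.5 * dt);
    }
    /* O */
    if (thermo) {
      for (int i = 0; i < n; i++) {
        for (int d = 0; d < 3; d++)
          v[3 * i + d] = c1t * v[3 * i + d] + c2t * rng_norm(&rng);
        double *o = &om[3 * i];
        for (int d = 0; d < 3; d++)
          o[d] = c1r * o[d] + c2r * rng_norm(&rng);
        const double *ui = &S.u[3 * i];
        double dot = o[0] * ui[0] + o[1] * ui[1] + o[2] * ui[2];
        for (int d = 0; d < 3; d++) o[d] -= dot * ui[d];
      }
    }
    /* A */
    for (int i = 0; i < n; i++) {
      for (int d = 0; d < 3; d++) {
        double dx = 0.5 * dt * v[3 * i + d];
        S.x[3 * i + d] += dx;
        disp[3 * i + d] += dx;
      }
      rotate_u(&S.u[3 * i], &om[3 * i], 0.5 * dt);
    }
    /* wrap periodic coordinates */
    for (int i = 0; i < n; i++)
      for (int d = 0; d < 3; d++)
        if (S.per[d]) {
          double Ld = S.L[d];
          S.x[3 * i + d] -= Ld * floor(S.x[3 * i + d] / Ld);
        }
    /* B with new forces */
    compute_forces(&S, w, F_ALL, E, f, gu, W);
    double fmax2 = 0.0;
    for (int i = 0; i < 3 * n; i++)
      if (f[i] * f[i] > fmax2) fmax2 = f[i] * f[i];
    if (sqrt(fmax2) * dt * dt / mass > maxstep_len)
      error("force overflow at step %ld (|F|dt^2/m = %g sigma): particles overlap catastrophically; reduce dt or fix the initial configuration",
            step, sqrt(fmax2) * dt * dt / mass);
    for (int i = 0; i < n; i++) {
      for (int d = 0; d < 3; d++)
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] / mass;
      const double *ui = &S.u[3 * i];
      double *g = &gu[3 * i];
      double tq[3] = { ui[1] * (-g[2]) - ui[2] * (-g[1]),
                       ui[2] * (-g[0]) - ui[0] * (-g[2]),
                       ui[0] * (-g[1]) - ui[1] * (-g[0]) };
      double *o = &om[3 * i];
      for (int d = 0; d < 3; d++) o[d] += 0.5 * dt * tq[d] / inert;
      double dot = o[0] * ui[0] + o[1] * ui[1] + o[2] * ui[2];
      for (int d = 0; d < 3; d++) o[d] -= dot * ui[d];
    }

    /* MC area move (zero-tension ensemble), flat topology only */
    if (mc_every > 0 && step % mc_every == 0) {
      mc_try++;
      double lns = mc_delta * (2.0 * rng_unif(&rng) - 1.0);
      double s = exp(lns);
      double Uold = 0.0;
      for (int c = 0; c < NE; c++) Uold += E[c];
      memcpy(xs, S.x, sizeof(double) * 3 * n);
      double Lold0 = S.L[0], Lold1 = S.L[1];
      for (int i = 0; i < n; i++) { S.x[3 * i] *= s; S.x[3 * i + 1] *= s; }
      S.L[0] *= s; S.L[1] *= s;
      double E2[NE], W2[3];
      compute_forces(&S, w, F_ALL, E2, f, gu, W2);
      double Unew = 0.0;
      for (int c = 0; c < NE; c++) Unew += E2[c];
      double lnacc = -(Unew - Uold) / kT + 2.0 * n * lns;
      if (lnacc >= 0.0 || log(rng_unif(&rng)) < lnacc) {
        mc_acc++;
        memcpy(E, E2, sizeof(E));
        W[0] = W2[0]; W[1] = W2[1]; W[2] = W2[2];
      } else {
        memcpy(S.x, xs, sizeof(double) * 3 * n);
        S.L[0] = Lold0; S.L[1] = Lold1;
        compute_forces(&S, w, F_ALL, E, f, gu, W);
      }
    }

    if (step % sample_every == 0 && isamp < nsamp) DO_SAMPLE(step);
    if (frame_every > 0 && step % frame_every == 0 && iframe < nf) {
      for (int i = 0; i < n; i++)
        for (int d = 0; d < 3; d++) {
          pfx[i + (size_t)n * d + (size_t)3 * n * iframe] = S.x[3 * i + d];
          pfu[i + (size_t)n * d + (size_t)3 * n * iframe] = S.u[3 * i + d];
        }
      pft[iframe] = t0 + step * dt;
      pfL[3 * iframe] = S.L[0]; pfL[3 * iframe + 1] = S.L[1]; pfL[3 * iframe + 2] = S.L[2];
      iframe++;
    }
    if (step % 2048 == 0) R_CheckUserInterrupt();
  }

  SEXP out = PROTECT(allocVector(VECSXP, 12)); nprot++;
  SEXP nm = PROTECT(allocVector(STRSXP, 12)); nprot++;
  const char *nms[12] = {"pos", "orient", "vel", "avel", "L", "samples",
                         "framesPos", "framesOrient", "frameTime", "frameL",
                         "spec", "rngState"};
  for (int i = 0; i < 12; i++) SET_STRING_ELT(nm, i, mkChar(nms[i]));
  setAttrib(out, R_NamesSymbol, nm);
  SET_VECTOR_ELT(out, 0, pack_mat(S.x, n));
  SET_VECTOR_ELT(out, 1, pack_mat(S.u, n));
  SET_VECTOR_ELT(out, 2, pack_mat(v, n));
  SET_VECTOR_ELT(out, 3, pack_mat(om, n));
  SEXP Lv = PROTECT(allocVector(REALSXP, 3)); nprot++;
  memcpy(REAL(Lv), S.L, sizeof(double) * 3);
  SET_VECTOR_ELT(out, 4, Lv);
  SET_VECTOR_ELT(out, 5, samples);
  SET_VECTOR_ELT(out, 6, fx);
  SET_VECTOR_ELT(out, 7, fu);
  SET_VECTOR_ELT(out, 8, ftime);
  SET_VECTOR_ELT(out, 9, fL);
  if (nq > 0) {
    SEXP sp = PROTECT(allocVector(REALSXP, nq)); nprot++;
    for (int q = 0; q < nq; q++)
      REAL(sp)[q] = spec_count > 0 ? spec[q] / spec_count : NA_REAL;
    SET_VECTOR_ELT(out, 10, sp);
  } else SET_VECTOR_ELT(out, 10, R_NilValue);
  SEXP rs = PROTECT(allocVector(RAWSXP, 32)); nprot++;
  memcpy(RAW(rs), rng.s, 32);
  SET_VECTOR_ELT(out, 11, rs);
  UNPROTECT(nprot);
  return out;
}
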