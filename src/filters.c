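/* Per-pixel 3x3 neighborhood kernels used in the image pipeline hot path.
 * Borders are replicated. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

#define SWAP(a, b) do { double t = (a); if ((b) < (a)) { (a) = (b); (b) = t; } } while (0)

/* exact median of 9 via a 19-exchange sorting network */
static inline double med9(double *p) {
  SWAP(p[1], p[2]); SWAP(p[4], p[5]); SWAP(p[7], p[8]);
  SWAP(p[0], p[1]); SWAP(p[3], p[4]); SWAP(p[6], p[7]);
  SWAP(p[1], p[2]); SWAP(p[4], p[5]); SWAP(p[7], p[8]);
  SWAP(p[0], p[3]); SWAP(p[5], p[8]); SWAP(p[4], p[7]);
  SWAP(p[3], p[6]); SWAP(p[1], p[4]); SWAP(p[2], p[5]);
  SWAP(p[4], p[7]); SWAP(p[4], p[2]); SWAP(p[6], p[4]);
  SWAP(p[4], p[2]);
  return p[4];
}

SEXP C_median3x3(SEXP x) {
  SEXP dim = getAttrib(x, R_DimSymbol);
  int h = INTEGER(dim)[0], w = INTEGER(dim)[1];
  SEXP out = PROTECT(allocMatrix(REALSXP, h, w));
  double *xs = REAL(x), *o = REAL(out);
  double buf[9];
  for (int j = 0; j < w; j++) {
    int jm = clampi(j - 1, 0, w - 1), jp = clampi(j + 1, 0, w - 1);
    const double *cm = xs + (R_xlen_t) jm * h;
    const double *c0 = xs + (R_xlen_t) j * h;
    const double *cp = xs + (R_xlen_t) jp * h;
    for (int i = 0; i < h; i++) {
      int im = clampi(i - 1, 0, h - 1), ip = clampi(i + 1, 0, h - 1);
      buf[0] = cm[im]; buf[1] = cm[i]; buf[2] = cm[ip];
      buf[3] = c0[im]; buf[4] = c0[i]; buf[5] = c0[ip];
      buf[6] = cp[im]; buf[7] = cp[i]; buf[8] = cp[ip];
      o[(R_xlen_t) j * h + i] = med9(buf);
    }
  }
  UNPROTECT(1);
  return out;
}

/* max over the 8 neighbors (center excluded), replicated borders */
SEXP C_max8(SEXP x) {
  SEXP dim = getAttrib(x, R_DimSymbol);
  int h = INTEGER(dim)[0], w = INTEGER(dim)[1];
  SEXP out = PROTECT(allocMatrix(REALSXP, h, w));
  double *xs = REAL(x), *o = REAL(out);
  for (int j = 0; j < w; j++) {
    int jm = clampi(j - 1, 0, w - 1), jp = clampi(j + 1, 0, w - 1);
    const double *cm = xs + (R_xlen_t) jm * h;
    const double *c0 = xs + (R_xlen_t) j * h;
    const double *cp = xs + (R_xlen_t) jp * h;
    for (int i = 0; i < h; i++) {
      int im = clampi(i - 1, 0, h - 1), ip = clampi(i + 1, 0, h - 1);
      double m = cm[im];
      if (cm[i] > m) m = cm[i];
      if (cm[ip] > m) m = cm[ip];
      if (c0[im] > m) m = c0[im];
      if (c0[ip] > m) m = c0[ip];
      if (cp[im] > m) m = cp[im];
      if (cp[i] > m) m = cp[i];
      if (cp[ip] > m) m = cp[ip];
      o[(R_xlen_t) j * h + i] = m;
    }
  }
  UNPROTECT(1);
  return out;
}

/* Marching-squares contour length per label: each 2x2 block contributes
 * the iso-contour segment length of the block's binary pattern for every
 * label present in it. labels: integer matrix (0 = background), K: number
 * of labels. Returns double[K]. */
SEXP C_perimLabel(SEXP labels, SEXP K_) {
  SEXP dim = getAttrib(labels, R_DimSymbol);
  int h = INTEGER(dim)[0], w = INTEGER(dim)[1];
  int K = asInteger(K_);
  SEXP out = PROTECT(allocVector(REALSXP, K));
  double *P = REAL(out);
  for (int k = 0; k < K; k++) P[k] = 0.0;
  int *L = INTEGER(labels);
  /* Iso-contour segments weighted Vossepoel-Smeulders style: a straight
   * unit segment counts 0.948, a half-diagonal segment 1.340/2, which
   * debiases the staircase overestimate on smooth boundaries. */
  const double D = 0.670;   /* half-diagonal segment */
  const double S = 0.948;   /* straight unit segment */
  for (int j = -1; j < w; j++) {
    for (int i = -1; i < h; i++) {
      int a = (i >= 0 && j >= 0) ? L[(R_xlen_t) j * h + i] : 0;          /* TL */
      int b = (i + 1 < h && j >= 0) ? L[(R_xlen_t) j * h + i + 1] : 0;   /* BL */
      int c = (i >= 0 && j + 1 < w) ? L[(R_xlen_t) (j + 1) * h + i] : 0; /* TR */
      int d = (i + 1 < h && j + 1 < w) ? L[(R_xlen_t) (j + 1) * h + i + 1] : 0; /* BR */
      if (!(a | b | c | d)) continue;
      /* up to 4 distinct labels in the block */
      int seen[4]; int ns = 0;
      int vals[4] = {a, b, c, d};
      for (int q = 0; q < 4; q++) {
        int v = vals[q];
        if (v == 0) continue;
        int dup = 0;
        for (int s = 0; s < ns; s++) if (seen[s] == v) { dup = 1; break; }
        if (!dup) seen[ns++] = v;
      }
      for (int s = 0; s < ns; s++) {
        int v = seen[s];
        if (v > K) continue;
        int ia = (a == v), ib = (b == v), ic = (c == v), id = (d == v);
        int n = ia + ib + ic + id;
        double add = 0.0;
        if (n == 1 || n == 3) add = D;
        else if (n == 2) add = ((ia && id) || (ib && ic)) ? 2.0 * D : S;
        P[v - 1] += add;
      }
    }
  }
  UNPROTECT(1);
  return out;
}

static const R_CallMethodDef callMethods[] = {
  {"C_median3x3",  (DL_FUNC) &C_median3x3,  1},
  {"C_max8",       (DL_FUNC) &C_max8,       1},
  {"C_perimLabel", (DL_FUNC) &C_perimLabel, 2},
  {NULL, NULL, 0}
};

void R_init_ctcflow(DllInfo *info) {
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, FALSE);
  R_forceSymbols(info, TRUE);
}
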