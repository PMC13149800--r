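#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>

using namespace Rcpp;

// Kaiser-Bessel interpolation kernel, tabulated once per call.
// c(u) = I0(beta * sqrt(1 - (2u/W)^2)) for |u| <= W/2, else 0.
static std::vector<double> kb_table(double W, double beta, int ntab) {
  std::vector<double> tab(ntab + 1);
  double half = W / 2.0;
  for (int i = 0; i <= ntab; ++i) {
    double u = half * i / ntab;
    double t = 1.0 - (2.0 * u / W) * (2.0 * u / W);
    tab[i] = (t > 0.0) ? ::Rf_bessel_i(beta * std::sqrt(t), 0.0, 1.0)
                       : ((t == 0.0) ? 1.0 : 0.0);
  }
  return tab;
}

static inline double kb_eval(const std::vector<double>& tab, int ntab,
                             double half, double u) {
  double a = std::fabs(u);
  if (a >= half) return 0.0;
  double x = a / half * ntab;
  int i = (int)x;
  if (i >= ntab) return tab[ntab];
  double f = x - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// Per-point, per-axis tap weights and pre-wrapped array indices:
// taps g = g0 .. g0+W-1 with g0 = ceil(kappa - W/2), offsets
// u = kappa - g in (-W/2, W/2]. Centered coordinate g maps to array index
// (g + G/2) mod G (fftshifted layout).
struct Taps {
  std::vector<double> w;
  std::vector<int> idx;
};

static inline void make_taps(double kappa, int W, int G, double half,
                             const std::vector<double>& tab, int ntab,
                             Taps& t) {
  // plain wrapped (DFT) layout: centered coordinate g -> index g mod G
  int g0 = (int)std::ceil(kappa - half);
  int base = g0 % G;
  if (base < 0) base += G;
  for (int j = 0; j < W; ++j) {
    t.w[j] = kb_eval(tab, ntab, half, kappa - (g0 + j));
    int id = base + j;
    if (id >= G) id -= G;
    t.idx[j] = id;
  }
}

// Interpolate (type-2 step): sample a centered oversampled spectrum at
// off-grid locations kappa (units of oversampled grid cells, centered).
// [[Rcpp::export]]
ComplexVector kb_interp3(ComplexVector grid, int G, NumericMatrix kappa,
                         int W, double beta) {
  if (grid.size() != (R_xlen_t)G * G * G)
    stop("grid length does not match G^3");
  int M = kappa.nrow();
  const int ntab = 4096;
  std::vector<double> tab = kb_table((double)W, beta, ntab);
  double half = W / 2.0;
  ComplexVector out(M);
  Taps tx, ty, tz;
  tx.w.resize(W); tx.idx.resize(W);
  ty.w.resize(W); ty.idx.resize(W);
  tz.w.resize(W); tz.idx.resize(W);
  const Rcomplex* g = grid.begin();
  for (int m = 0; m < M; ++m) {
    make_taps(kappa(m, 0), W, G, half, tab, ntab, tx);
    make_taps(kappa(m, 1), W, G, half, tab, ntab, ty);
    make_taps(kappa(m, 2), W, G, half, tab, ntab, tz);
    double accr = 0.0, acci = 0.0;
    for (int c = 0; c < W; ++c) {
      double wz = tz.w[c];
      R_xlen_t oz = (R_xlen_t)tz.idx[c] * G * G;
      for (int b = 0; b < W; ++b) {
        double wyz = ty.w[b] * wz;
        const Rcomplex* row = g + oz + (R_xlen_t)ty.idx[b] * G;
        double rr = 0.0, ri = 0.0;
        for (int a = 0; a < W; ++a) {
          double w = tx.w[a];
          const Rcomplex& v = row[tx.idx[a]];
          rr += w * v.r;
          ri += w * v.i;
        }
        accr += wyz * rr;
        acci += wyz * ri;
      }
    }
    out[m].r = accr;
    out[m].i = acci;
  }
  return out;
}

// Spread (type-1 step): exact transpose of kb_interp3.
// [[Rcpp::export]]
ComplexVector kb_spread3(ComplexVector y, int G, NumericMatrix kappa,
                         int W, double beta) {
  int M = kappa.nrow();
  if (y.size() != M) stop("y length does not match kappa rows");
  const int ntab = 4096;
  std::vector<double> tab = kb_table((double)W, beta, ntab);
  double half = W / 2.0;
  ComplexVector out((R_xlen_t)G * G * G);
  Rcomplex* g = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) { g[i].r = 0.0; g[i].i = 0.0; }
  Taps tx, ty, tz;
  tx.w.resize(W); tx.idx.resize(W);
  ty.w.resize(W); ty.idx.resize(W);
  tz.w.resize(W); tz.idx.resize(W);
  for (int m = 0; m < M; ++m) {
    make_taps(kappa(m, 0), W, G, half, tab, ntab, tx);
    make_taps(kappa(m, 1), W, G, half, tab, ntab, ty);
    make_taps(kappa(m, 2), W, G, half, tab, ntab, tz);
    double vr = y[m].r, vi = y[m].i;
    for (int c = 0; c < W; ++c) {
      double wz = tz.w[c];
      R_xlen_t oz = (R_xlen_t)tz.idx[c] * G * G;
      for (int b = 0; b < W; ++b) {
        double wyz = ty.w[b] * wz;
        Rcomplex* row = g + oz + (R_xlen_t)ty.idx[b] * G;
        double pr = wyz * vr, pi = wyz * vi;
        for (int a = 0; a < W; ++a) {
          double w = tx.w[a];
          Rcomplex& t = row[tx.idx[a]];
          t.r += w * pr;
          t.i += w * pi;
        }
      }
    }
  }
  return out;
}

// Exact non-uniform DFT by direct summation:
// y_m = sum_n x(n) exp(-2*pi*i * k_m . (n - N/2)), n voxel indices 0..N-1
// per axis, k in cycles per voxel spacing. O(M * N^3); oracle / honest
// simulation mode for small grids only.
// [[Rcpp::export]]
ComplexVector dft_forward3(ComplexVector x, int N, NumericMatrix k) {
  if (x.size() != (R_xlen_t)N * N * N) stop("x length does not match N^3");
  int M = k.nrow();
  ComplexVector out(M);
  std::vector<std::complex<double> > ax(N), ay(N), az(N);
  const Rcomplex* xp = x.begin();
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      double c = n - N / 2.0;
      double px = -2.0 * M_PI * k(m, 0) * c;
      double py = -2.0 * M_PI * k(m, 1) * c;
      double pz = -2.0 * M_PI * k(m, 2) * c;
      ax[n] = std::complex<double>(std::cos(px), std::sin(px));
      ay[n] = std::complex<double>(std::cos(py), std::sin(py));
      az[n] = std::complex<double>(std::cos(pz), std::sin(pz));
    }
    std::complex<double> acc(0.0, 0.0);
    R_xlen_t idx = 0;
    for (int c = 0; c < N; ++c) {
      for (int b = 0; b < N; ++b) {
        std::complex<double> pyz = az[c] * ay[b];
        std::complex<double> row(0.0, 0.0);
        for (int a = 0; a < N; ++a, ++idx) {
          row += std::complex<double>(xp[idx].r, xp[idx].i) * ax[a];
        }
        acc += row * pyz;
      }
    }
    out[m].r = acc.real();
    out[m].i = acc.imag();
  }
  return out;
}

// Adjoint of dft_forward3 (conjugate transpose), same exact convention.
// [[Rcpp::export]]
ComplexVector dft_adjoint3(ComplexVector y, int N, NumericMatrix k) {
  int M = k.nrow();
  if (y.size() != M) stop("y length does not match k rows");
  ComplexVector out((R_xlen_t)N * N * N);
  Rcomplex* op = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) { op[i].r = 0.0; op[i].i = 0.0; }
  std::vector<std::complex<double> > ax(N), ay(N), az(N);
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      double c = n - N / 2.0;
      double px = 2.0 * M_PI * k(m, 0) * c;
      double py = 2.0 * M_PI * k(m, 1) * c;
      double pz = 2.0 * M_PI * k(m, 2) * c;
      ax[n] = std::complex<double>(std::cos(px), std::sin(px));
      ay[n] = std::complex<double>(std::cos(py), std::sin(py));
      az[n] = std::complex<double>(std::cos(pz), std::sin(pz));
    }
    std::complex<double> v(y[m].r, y[m].i);
    R_xlen_t idx = 0;
    for (int c = 0; c < N; ++c) {
      for (int b = 0; b < N; ++b) {
        std::complex<double> vyz = v * az[c] * ay[b];
        for (int a = 0; a < N; ++a, ++idx) {
          std::complex<double> t = vyz * ax[a];
          op[idx].r += t.real();
          op[idx].i += t.imag();
        }
      }
    }
  }
  return out;
}
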