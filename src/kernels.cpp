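#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Gaussian-modulated cosine pulse evaluated at time t (s) relative to its
// center; sigma_t is the envelope standard deviation in seconds.
static inline double pulse_val(double t, double fc, double sigma_t) {
  return std::exp(-0.5 * t * t / (sigma_t * sigma_t)) *
         std::cos(2.0 * M_PI * fc * t);
}

// Accumulate band-limited pulses from point sources into an RF matrix.
// Sources at (sx, sy, sz) with strengths amp and per-source extra delay
// t_extra (zero for one-way PA; transmit path delay for pulse-echo US).
// Spherical spreading 1/r; elements given as an n_elem x 3 matrix.
// Returns n_elem x n_time matrix; time axis starts at t0, sampled at fs.
// [[Rcpp::export]]
NumericMatrix cpp_rf_sim(NumericVector sx, NumericVector sy, NumericVector sz,
                         NumericVector amp, NumericVector t_extra,
                         NumericMatrix elem, double c, double fs, int n_time,
                         double t0, double fc, double sigma_t) {
  const int ns = sx.size();
  const int ne = elem.nrow();
  NumericMatrix rf(ne, n_time);
  const double support = 4.0 * sigma_t;
  const double r_min = 1e-4;  // clamp 1/r blow-up near an element
  // 16x-oversampled pulse lookup table (linear interpolation below): the
  // exp/cos per sample would otherwise dominate the whole simulation
  const int os = 16;
  const double dt_tab = 1.0 / (fs * os);
  const int half_tab = (int)std::ceil(support / dt_tab) + 1;
  std::vector<double> tab(2 * half_tab + 1);
  for (int k = -half_tab; k <= half_tab; ++k)
    tab[k + half_tab] = pulse_val(k * dt_tab, fc, sigma_t);
  double* rfp = REAL(rf);
  for (int i = 0; i < ns; ++i) {
    const double a0 = amp[i];
    if (a0 == 0.0) continue;
    const double six = sx[i], siy = sy[i], siz = sz[i], tei = t_extra[i];
    for (int e = 0; e < ne; ++e) {
      const double dx = six - elem(e, 0);
      const double dy = siy - elem(e, 1);
      const double dz = siz - elem(e, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double tt = r / c + tei;
      if (r < r_min) r = r_min;
      const double a = a0 / r;
      int n_lo = (int)std::ceil((tt - support - t0) * fs);
      int n_hi = (int)std::floor((tt + support - t0) * fs);
      if (n_lo < 0) n_lo = 0;
      if (n_hi > n_time - 1) n_hi = n_time - 1;
      for (int n = n_lo; n <= n_hi; ++n) {
        const double u = (t0 + n / fs - tt) / dt_tab + half_tab;
        const int k0 = (int)u;
        const double w = u - k0;
        rfp[e + (R_xlen_t)n * ne] +=
            a * ((1.0 - w) * tab[k0] + w * tab[k0 + 1]);
      }
    }
  }
  return rf;
}

// Delay-and-sum gather of (analytic) RF onto arbitrary pixel positions.
// rf_re/rf_im: n_elem x n_time real and imaginary parts of the analytic
// signal. Pixels at (px, 0, pz). One-way delays for photoacoustics;
// two_way adds the plane-wave transmit path z/c. Linear interpolation in
// time; samples outside the record contribute zero.
// [[Rcpp::export]]
List cpp_das(NumericMatrix rf_re, NumericMatrix rf_im, NumericMatrix elem,
             NumericVector px, NumericVector pz, double c, double fs,
             double t0, bool two_way, double fnum) {
  const int np = px.size();
  const int ne = elem.nrow();
  const int nt = rf_re.ncol();
  NumericVector out_re(np), out_im(np);
  for (int p = 0; p < np; ++p) {
    double acc_re = 0.0, acc_im = 0.0;
    const double tx = two_way ? pz[p] / c : 0.0;
    const double half_ap = fnum > 0 ? pz[p] / (2.0 * fnum) : 0.0;
    for (int e = 0; e < ne; ++e) {
      const double dx = px[p] - elem(e, 0);
      if (fnum > 0 && std::fabs(dx) > half_ap) continue;
      const double dy = -elem(e, 1);
      const double dz = pz[p] - elem(e, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double s = (tx + r / c - t0) * fs;
      const int i0 = (int)std::floor(s);
      if (i0 < 0 || i0 >= nt - 1) continue;
      const double w = s - i0;
      acc_re += (1.0 - w) * rf_re(e, i0) + w * rf_re(e, i0 + 1);
      acc_im += (1.0 - w) * rf_im(e, i0) + w * rf_im(e, i0 + 1);
    }
    out_re[p] = acc_re;
    out_im[p] = acc_im;
  }
  return List::create(Named("re") = out_re, Named("im") = out_im);
}

// ---- PatchMatch speckle tracking -----------------------------------------

// xorshift64* PRNG — deterministic across platforms, independent of R's RNG.
static inline uint64_t xs64(uint64_t* s) {
  uint64_t x = *s;
  x ^= x >> 12;
  x ^= x << 25;
  x ^= x >> 27;
  *s = x;
  return x * 2685821657736338717ULL;
}
static inline int rand_range(uint64_t* s, int lo, int hi) {  // inclusive
  return lo + (int)(xs64(s) % (uint64_t)(hi - lo + 1));
}

// NCC between the patch of `a` centered at (iz, ix) and the patch of `b`
// centered at (iz+dz, ix+dx); window clamped to the frame of `a`, candidate
// rejected (returns -2) if the displaced window leaves `b`.
static double patch_ncc(const NumericMatrix& a, const NumericMatrix& b,
                        int iz, int ix, int dz, int dx, int half) {
  const int nz = a.nrow(), nx = a.ncol();
  int z0 = iz - half, z1 = iz + half, x0 = ix - half, x1 = ix + half;
  if (z0 < 0) z0 = 0;
  if (x0 < 0) x0 = 0;
  if (z1 > nz - 1) z1 = nz - 1;
  if (x1 > nx - 1) x1 = nx - 1;
  if (z0 + dz < 0 || z1 + dz > nz - 1 || x0 + dx < 0 || x1 + dx > nx - 1)
    return -2.0;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  int n = 0;
  for (int x = x0; x <= x1; ++x) {
    for (int z = z0; z <= z1; ++z) {
      const double va = a(z, x);
      const double vb = b(z + dz, x + dx);
      sa += va; sb += vb;
      saa += va * va; sbb += vb * vb; sab += va * vb;
      ++n;
    }
  }
  const double ca = saa - sa * sa / n;
  const double cb = sbb - sb * sb / n;
  if (ca <= 0.0 || cb <= 0.0) return 0.0;
  return (sab - sa * sb / n) / std::sqrt(ca * cb);
}

// Randomized PatchMatch displacement field from frame a to frame b: for each
// pixel p of a, the integer displacement d maximizing patch NCC so that
// a(p) ~ b(p + d), refined to subpixel by a parabolic fit of the NCC surface.
// Alternating raster propagation + exponentially shrinking random search.
// [[Rcpp::export]]
List cpp_patchmatch(NumericMatrix a, NumericMatrix b, int half, int iters,
                    int radius0, double decay, int max_disp, double seed) {
  const int nz = a.nrow(), nx = a.ncol();
  IntegerMatrix dz(nz, nx), dx(nz, nx);
  NumericMatrix ncc(nz, nx);
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  // zero-displacement init (small inter-frame motion is the expected regime)
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z)
      ncc(z, x) = patch_ncc(a, b, z, x, 0, 0, half);

  for (int it = 0; it < iters; ++it) {
    const bool fwd = (it % 2 == 0);
    for (int xi = 0; xi < nx; ++xi) {
      const int x = fwd ? xi : nx - 1 - xi;
      for (int zi = 0; zi < nz; ++zi) {
        const int z = fwd ? zi : nz - 1 - zi;
        double best = ncc(z, x);
        int bdz = dz(z, x), bdx = dx(z, x);
        // propagation from already-visited neighbors
        const int pz1 = fwd ? z - 1 : z + 1;
        const int px1 = fwd ? x - 1 : x + 1;
        if (pz1 >= 0 && pz1 < nz) {
          const double v = patch_ncc(a, b, z, x, dz(pz1, x), dx(pz1, x), half);
          if (v > best) { best = v; bdz = dz(pz1, x); bdx = dx(pz1, x); }
        }
        if (px1 >= 0 && px1 < nx) {
          const double v = patch_ncc(a, b, z, x, dz(z, px1), dx(z, px1), half);
          if (v > best) { best = v; bdz = dz(z, px1); bdx = dx(z, px1); }
        }
        // random search around current best, radius halving
        int radius = radius0;
        while (radius >= 1) {
          int cz = bdz + rand_range(&rng, -radius, radius);
          int cx = bdx + rand_range(&rng, -radius, radius);
          if (cz > max_disp) cz = max_disp;
          if (cz < -max_disp) cz = -max_disp;
          if (cx > max_disp) cx = max_disp;
          if (cx < -max_disp) cx = -max_disp;
          const double v = patch_ncc(a, b, z, x, cz, cx, half);
          if (v > best) { best = v; bdz = cz; bdx = cx; }
          radius = (int)std::floor(radius * decay);
        }
        ncc(z, x) = best;
        dz(z, x) = bdz;
        dx(z, x) = bdx;
      }
    }
  }

  // parabolic subpixel refinement of the NCC surface around the optimum
  NumericMatrix fdz(nz, nx), fdx(nz, nx);
  for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) {
      double sz_ = 0.0, sx_ = 0.0;
      const int bdz = dz(z, x), bdx = dx(z, x);
      const double n0 = ncc(z, x);
      double nm = patch_ncc(a, b, z, x, bdz - 1, bdx, half);
      double np = patch_ncc(a, b, z, x, bdz + 1, bdx, half);
      if (nm > -1.5 && np > -1.5) {
        const double den = nm - 2.0 * n0 + np;
        if (den < -1e-12) {
          sz_ = 0.5 * (nm - np) / den;
          if (sz_ > 0.5) sz_ = 0.5;
          if (sz_ < -0.5) sz_ = -0.5;
        }
      }
      nm = patch_ncc(a, b, z, x, bdz, bdx - 1, half);
      np = patch_ncc(a, b, z, x, bdz, bdx + 1, half);
      if (nm > -1.5 && np > -1.5) {
        const double den = nm - 2.0 * n0 + np;
        if (den < -1e-12) {
          sx_ = 0.5 * (nm - np) / den;
          if (sx_ > 0.5) sx_ = 0.5;
          if (sx_ < -0.5) sx_ = -0.5;
        }
      }
      fdz(z, x) = bdz + sz_;
      fdx(z, x) = bdx + sx_;
    }
  }
  return List::create(Named("dz") = fdz, Named("dx") = fdx,
                      Named("ncc") = ncc);
}
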