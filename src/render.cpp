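#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian blur with replicate (nearest) border handling.
// Kernel truncated at `truncate` standard deviations and renormalized,
// so constant images are preserved exactly.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& x, double sigma,
                             double truncate = 4.0) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int h = (int)std::ceil(truncate * sigma);
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + h];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* xp = REAL(x);
  double* tp = REAL(tmp);
  double* op = REAL(out);
  const double* kp = k.data();
  // pass 1: along rows (within each column, contiguous in memory)
  for (int c = 0; c < nc; ++c) {
    const double* col = xp + (size_t)c * nr;
    double* tcol = tp + (size_t)c * nr;
    int lo = std::min(h, nr), hi = std::max(nr - h, lo);
    for (int r = 0; r < lo; ++r) {            // top border, clamped
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * kp[i + h];
      }
      tcol[r] = acc;
    }
    for (int r = lo; r < hi; ++r) {           // interior, branch-free
      double acc = 0.0;
      const double* p = col + r - h;
      for (int i = 0; i <= 2 * h; ++i) acc += p[i] * kp[i];
      tcol[r] = acc;
    }
    for (int r = hi; r < nr; ++r) {           // bottom border, clamped
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * kp[i + h];
      }
      tcol[r] = acc;
    }
  }
  // pass 2: along columns (axpy over contiguous column vectors)
  for (int c = 0; c < nc; ++c) {
    double* ocol = op + (size_t)c * nr;
    for (int i = -h; i <= h; ++i) {
      int cc = c + i;
      if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
      const double w = kp[i + h];
      const double* tcol = tp + (size_t)cc * nr;
      for (int r = 0; r < nr; ++r) ocol[r] += tcol[r] * w;
    }
  }
  return out;
}

static void blur_into(const double* xp, double* tp, double* op,
                      int nr, int nc, double sigma, double truncate) {
  if (sigma <= 0) {
    std::copy(xp, xp + (size_t)nr * nc, op);
    return;
  }
  int h = (int)std::ceil(truncate * sigma);
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + h];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  const double* kp = k.data();
  for (int c = 0; c < nc; ++c) {
    const double* col = xp + (size_t)c * nr;
    double* tcol = tp + (size_t)c * nr;
    int lo = std::min(h, nr), hi = std::max(nr - h, lo);
    for (int r = 0; r < lo; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * kp[i + h];
      }
      tcol[r] = acc;
    }
    for (int r = lo; r < hi; ++r) {
      double acc = 0.0;
      const double* p = col + r - h;
      for (int i = 0; i <= 2 * h; ++i) acc += p[i] * kp[i];
      tcol[r] = acc;
    }
    for (int r = hi; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * kp[i + h];
      }
      tcol[r] = acc;
    }
  }
  std::fill(op, op + (size_t)nr * nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    double* ocol = op + (size_t)c * nr;
    for (int i = -h; i <= h; ++i) {
      int cc = c + i;
      if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
      const double w = kp[i + h];
      const double* tcol = tp + (size_t)cc * nr;
      for (int r = 0; r < nr; ++r) ocol[r] += tcol[r] * w;
    }
  }
}

// Render a defocus z-stack from one in-focus scene: per slice, Gaussian
// blur of the given sigma, Gaussian camera noise (Box-Muller over R's
// uniform stream), clamping to the 16-bit range and integer quantization.
// [[Rcpp::export]]
NumericVector cpp_render_stack(const NumericMatrix& scene,
                               const NumericVector& sigmas,
                               double noise_sd, double truncate = 4.0) {
  int nr = scene.nrow(), nc = scene.ncol(), nz = sigmas.size();
  size_t npx = (size_t)nr * nc;
  NumericVector out(Dimension(nr, nc, nz));
  std::vector<double> tmp(npx), blurred(npx);
  double* op = REAL(out);
  RNGScope scope;
  double spare = 0.0; bool have_spare = false;
  for (int z = 0; z < nz; ++z) {
    blur_into(REAL(scene), tmp.data(), blurred.data(), nr, nc,
              sigmas[z], truncate);
    double* slice = op + npx * z;
    for (size_t i = 0; i < npx; ++i) {
      double v = blurred[i];
      if (noise_sd > 0) {
        double zn;
        if (have_spare) { zn = spare; have_spare = false; }
        else {
          double u1 = unif_rand(), u2 = unif_rand();
          if (u1 < 1e-300) u1 = 1e-300;
          double m = std::sqrt(-2.0 * std::log(u1));
          zn = m * std::cos(2.0 * M_PI * u2);
          spare = m * std::sin(2.0 * M_PI * u2);
          have_spare = true;
        }
        v += zn * noise_sd;
      }
      v = std::round(v);
      if (v < 0) v = 0; else if (v > 65535) v = 65535;
      slice[i] = v;
    }
  }
  return out;
}

// Add Gaussian camera noise (Box-Muller over R's uniform RNG stream, so
// set.seed applies), clamp to the 16-bit range and quantize to integer
// counts.
// [[Rcpp::export]]
NumericVector cpp_noise_quantize(const NumericVector& x, double sd) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* xp = REAL(x);
  double* op = REAL(out);
  RNGScope scope;
  if (sd > 0) {
    double spare = 0.0; bool have_spare = false;
    for (R_xlen_t i = 0; i < n; ++i) {
      double z;
      if (have_spare) { z = spare; have_spare = false; }
      else {
        double u1 = unif_rand(), u2 = unif_rand();
        if (u1 < 1e-300) u1 = 1e-300;
        double m = std::sqrt(-2.0 * std::log(u1));
        z = m * std::cos(2.0 * M_PI * u2);
        spare = m * std::sin(2.0 * M_PI * u2);
        have_spare = true;
      }
      double v = std::round(xp[i] + z * sd);
      if (v < 0) v = 0; else if (v > 65535) v = 65535;
      op[i] = v;
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = std::round(xp[i]);
      if (v < 0) v = 0; else if (v > 65535) v = 65535;
      op[i] = v;
    }
  }
  if (x.hasAttribute("dim")) out.attr("dim") = x.attr("dim");
  return out;
}
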