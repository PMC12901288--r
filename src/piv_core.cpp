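// Inner loops of the PIV engine: zero-mean normalized FFT cross-correlation
// per interrogation window, subpixel peak fitting, and the normalized median
// test used for vector validation. The surrounding grid bookkeeping lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Zero-mean normalized cross-correlation of two W x W windows, computed with
// zero padding to 2W (no circular wraparound within the valid displacement
// range). out(dr + W - 1, dc + W - 1) = sum_{r,c} a(r,c) b(r+dr, c+dc),
// normalized by ||a - mean(a)|| * ||b - mean(b)||.
static arma::mat xcorr_surface(const arma::mat& wa, const arma::mat& wb, bool& ok) {
  const int W = wa.n_rows;
  const double ma = arma::accu(wa) / (W * (double)W);
  const double mb = arma::accu(wb) / (W * (double)W);
  arma::mat az = wa - ma;
  arma::mat bz = wb - mb;
  const double sa = std::sqrt(arma::accu(arma::square(az)));
  const double sb = std::sqrt(arma::accu(arma::square(bz)));
  ok = (sa > 1e-12 && sb > 1e-12);
  if (!ok) return arma::mat();
  const int N = 2 * W;
  arma::mat Ar(N, N, arma::fill::zeros), Br(N, N, arma::fill::zeros);
  Ar.submat(0, 0, W - 1, W - 1) = az;
  Br.submat(0, 0, W - 1, W - 1) = bz;
  arma::cx_mat A(Ar, arma::mat(N, N, arma::fill::zeros));
  arma::cx_mat B(Br, arma::mat(N, N, arma::fill::zeros));
  arma::cx_mat R = arma::ifft2(arma::conj(arma::fft2(A)) % arma::fft2(B));
  // Unbiased overlap correction: with zero padding the raw correlation is
  // tapered by the shrinking window overlap (W - |d|) per axis, which biases
  // the subpixel fit toward zero. Divide it out, clamping at half-window
  // overlap so far lags are not blown up into spurious peaks.
  arma::mat out(2 * W - 1, 2 * W - 1);
  for (int dr = -(W - 1); dr <= W - 1; ++dr) {
    const double fr = std::max((double)(W - std::abs(dr)), W / 2.0) / W;
    for (int dc = -(W - 1); dc <= W - 1; ++dc) {
      const double fc = std::max((double)(W - std::abs(dc)), W / 2.0) / W;
      out(dr + W - 1, dc + W - 1) =
        R((dr + N) % N, (dc + N) % N).real() / (fr * fc);
    }
  }
  out /= (sa * sb);
  return out;
}

// Three-point Gaussian fit along one axis; parabolic fallback when any of
// the three correlation samples is non-positive or the log fit degenerates.
static double axis_offset(double cm, double c0, double cp,
                          bool force_parabolic = false) {
  if (!force_parabolic && cm > 0 && c0 > 0 && cp > 0) {
    const double lm = std::log(cm), l0 = std::log(c0), lp = std::log(cp);
    const double den = 2.0 * lm - 4.0 * l0 + 2.0 * lp;
    if (std::abs(den) > 1e-12) {
      const double d = (lm - lp) / den;
      if (std::abs(d) <= 1.0) return d;
    }
  }
  const double den = 2.0 * cm - 4.0 * c0 + 2.0 * cp;
  if (std::abs(den) > 1e-12) {
    const double d = (cm - cp) / den;
    if (std::abs(d) <= 1.0) return d;
  }
  return 0.0;
}

// Peak-to-second-peak ratio; the second peak must lie outside the first
// peak's neighbourhood (Chebyshev radius 2) so that the shoulder of a broad
// correlation peak - textured sheets correlate over a few pixels - does not
// count as a competitor.
static double peak_snr(const arma::mat& c, int pr, int pc) {
  const double cmax = c(pr, pc);
  if (cmax <= 0) return 0.0;
  double second = -arma::datum::inf;
  for (arma::uword i = 0; i < c.n_rows; ++i)
    for (arma::uword j = 0; j < c.n_cols; ++j) {
      if (std::abs((int)i - pr) <= 2 && std::abs((int)j - pc) <= 2) continue;
      if (c(i, j) > second) second = c(i, j);
    }
  if (!std::isfinite(second) || second <= 1e-12) return 1e6;
  return cmax / second;
}

// 2-D least-squares Gaussian fit: log-paraboloid over the (2r+1)^2
// neighbourhood of the integer peak. Averaging over 25 surface samples
// (r = 2) suppresses the texture-realization noise that limits the
// three-point fit on smooth (non-particle) images. Returns false when the
// neighbourhood leaves the surface, contains non-positive values, or the
// fitted extremum is not a nearby maximum; the caller then falls back to
// the axis-wise three-point fit.
static bool fit_gauss2d(const arma::mat& c, int pr, int pc, int rad,
                        double& dr, double& dc) {
  const int n = 2 * rad + 1;
  if (pr - rad < 0 || pc - rad < 0 ||
      pr + rad >= (int)c.n_rows || pc + rad >= (int)c.n_cols) return false;
  arma::mat X(n * n, 6);
  arma::vec y(n * n);
  int k = 0;
  for (int i = -rad; i <= rad; ++i)
    for (int j = -rad; j <= rad; ++j) {
      const double v = c(pr + i, pc + j);
      if (v <= 0) return false;
      X(k, 0) = 1; X(k, 1) = i; X(k, 2) = j;
      X(k, 3) = i * i; X(k, 4) = j * j; X(k, 5) = i * j;
      y(k) = std::log(v);
      ++k;
    }
  arma::vec b;
  if (!arma::solve(b, X.t() * X, X.t() * y)) return false;
  arma::mat A = { {2 * b(3), b(5)}, {b(5), 2 * b(4)} };
  // maximum requires negative-definite Hessian
  if (!(b(3) < 0 && 4 * b(3) * b(4) - b(5) * b(5) > 0)) return false;
  arma::vec d;
  if (!arma::solve(d, A, arma::vec({-b(1), -b(2)}))) return false;
  if (std::abs(d(0)) > 1.0 || std::abs(d(1)) > 1.0) return false;
  dr = d(0);
  dc = d(1);
  return true;
}

// [[Rcpp::export]]
List xcorr_core(const arma::mat& wa, const arma::mat& wb) {
  bool ok = false;
  arma::mat out = xcorr_surface(wa, wb, ok);
  return List::create(_["corr"] = out, _["valid"] = ok);
}

// One PIV pass over a fixed grid. off_r/off_c hold the integer predictor
// offset applied to the frame-b window at each grid node (clamped so the
// window stays inside the frame); the total displacement is the offset
// actually used plus the correlation-peak displacement.
// subpixel_method: 0 = gaussian2d (5x5 LS fit, 3-point fallback),
//                  1 = gaussian3 (axis-wise 3-point), 2 = parabolic-only.
// [[Rcpp::export]]
List piv_pass_core(const arma::mat& fa, const arma::mat& fb, int window, int step,
                   const arma::mat& off_r, const arma::mat& off_c, double snr_min,
                   int subpixel_method = 0) {
  const int rows = fa.n_rows, cols = fa.n_cols;
  const int nr = off_r.n_rows, nc = off_r.n_cols;
  const int W = window;
  arma::mat U(nr, nc), V(nr, nc), S(nr, nc);
  LogicalMatrix val(nr, nc);
  U.fill(NA_REAL); V.fill(NA_REAL); S.fill(NA_REAL);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const int r0 = i * step, c0 = j * step;
      int br = r0 + (int)off_r(i, j);
      int bc = c0 + (int)off_c(i, j);
      if (br < 0) br = 0;
      if (br > rows - W) br = rows - W;
      if (bc < 0) bc = 0;
      if (bc > cols - W) bc = cols - W;
      arma::mat wa = fa.submat(r0, c0, r0 + W - 1, c0 + W - 1);
      arma::mat wb = fb.submat(br, bc, br + W - 1, bc + W - 1);
      bool ok = false;
      arma::mat corr = xcorr_surface(wa, wb, ok);
      if (!ok) { val(i, j) = false; continue; }
      arma::uword pr_u, pc_u;
      corr.max(pr_u, pc_u);
      const int pr = (int)pr_u, pc = (int)pc_u;
      const int hi = 2 * W - 2;
      const bool border = (pr == 0 || pr == hi || pc == 0 || pc == hi);
      double dr = pr - (W - 1), dc = pc - (W - 1);
      if (!border) {
        double sr = 0, sc = 0;
        bool done = false;
        if (subpixel_method == 0) done = fit_gauss2d(corr, pr, pc, 2, sr, sc);
        if (!done) {
          const bool parab = (subpixel_method == 2);
          sr = axis_offset(corr(pr - 1, pc), corr(pr, pc), corr(pr + 1, pc), parab);
          sc = axis_offset(corr(pr, pc - 1), corr(pr, pc), corr(pr, pc + 1), parab);
        }
        dr += sr;
        dc += sc;
      }
      const double snr = peak_snr(corr, pr, pc);
      V(i, j) = dr + (br - r0);
      U(i, j) = dc + (bc - c0);
      S(i, j) = snr;
      val(i, j) = !border && corr(pr, pc) > 0 && snr >= snr_min;
    }
  }
  return List::create(_["u"] = U, _["v"] = V, _["snr"] = S, _["valid"] = val);
}

static double med_of(std::vector<double>& x) {
  const size_t n = x.size();
  std::sort(x.begin(), x.end());
  if (n % 2 == 1) return x[n / 2];
  return 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// Normalized median test (3x3 neighborhoods) on each velocity component,
// followed by replacement of failing vectors with the median of passing
// neighbors. residual r = |d - median(nbrs)| / (median(|nbrs - median|) + eps).
// [[Rcpp::export]]
List nmt_core(const arma::mat& u, const arma::mat& v, const LogicalMatrix& valid,
              double eps, double thresh) {
  const int nr = u.n_rows, nc = u.n_cols;
  LogicalMatrix pass(nr, nc), replaced(nr, nc);
  arma::mat uf = u, vf = v;
  arma::mat ru(nr, nc), rv(nr, nc);
  ru.fill(NA_REAL); rv.fill(NA_REAL);

  auto resid = [&](const arma::mat& m, int i, int j) -> double {
    std::vector<double> nb;
    nb.reserve(8);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        const int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (std::isfinite(m(ii, jj))) nb.push_back(m(ii, jj));
      }
    if (nb.size() < 3 || !std::isfinite(m(i, j))) return NA_REAL;
    const double mm = med_of(nb);
    std::vector<double> dev(nb.size());
    for (size_t k = 0; k < nb.size(); ++k) dev[k] = std::abs(nb[k] - mm);
    const double mdev = med_of(dev);
    return std::abs(m(i, j) - mm) / (mdev + eps);
  };

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      bool ok = valid(i, j) && std::isfinite(u(i, j)) && std::isfinite(v(i, j));
      if (ok) {
        const double r1 = resid(u, i, j);
        const double r2 = resid(v, i, j);
        ru(i, j) = r1; rv(i, j) = r2;
        if (std::isfinite(r1) && r1 > thresh) ok = false;
        if (std::isfinite(r2) && r2 > thresh) ok = false;
      }
      pass(i, j) = ok;
    }

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (pass(i, j)) continue;
      std::vector<double> nu, nv;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (pass(ii, jj)) { nu.push_back(u(ii, jj)); nv.push_back(v(ii, jj)); }
        }
      if (!nu.empty()) {
        uf(i, j) = med_of(nu);
        vf(i, j) = med_of(nv);
        replaced(i, j) = true;
      } else {
        uf(i, j) = NA_REAL;
        vf(i, j) = NA_REAL;
      }
    }

  return List::create(_["pass"] = pass, _["u"] = uf, _["v"] = vf,
                      _["replaced"] = replaced,
                      _["residual_u"] = ru, _["residual_v"] = rv);
}
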