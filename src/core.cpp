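#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Windowed autocovariance of every pixel trajectory, covaried against a
// centered model decay. traj: pixels x frames. model_c: centered model ACF
// values aligned with `lags` (0-based lag indices). Returns pixels x windows.
// [[Rcpp::export]]
NumericMatrix tc_transform_cpp(const NumericMatrix& traj,
                               const NumericVector& model_c,
                               const IntegerVector& lags,
                               int mw, int step, bool clip) {
  const int P = traj.nrow(), N = traj.ncol(), L = lags.size();
  const int n_out = (N - mw) / step + 1;
  if (n_out < 1) stop("movie shorter than one window");
  NumericMatrix out(P, n_out);
  std::vector<double> w(mw);
  for (int p = 0; p < P; ++p) {
    for (int iw = 0; iw < n_out; ++iw) {
      const int t0 = iw * step;
      double m = 0.0;
      for (int t = 0; t < mw; ++t) { w[t] = traj(p, t0 + t); m += w[t]; }
      m /= mw;
      for (int t = 0; t < mw; ++t) w[t] -= m;
      double v = 0.0;
      for (int li = 0; li < L; ++li) {
        const int k = lags[li];
        double s = 0.0;
        for (int t = 0; t + k < mw; ++t) s += w[t] * w[t + k];
        v += (s / (mw - k)) * model_c[li];
      }
      v /= L;
      out(p, iw) = (clip && v < 0.0) ? 0.0 : v;
    }
  }
  return out;
}

// Separable convolution with an odd symmetric kernel, holes of size
// `dilation` between taps, mirror boundary. Rows then columns.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(const NumericMatrix& img,
                           const NumericVector& kernel, int dilation) {
  const int H = img.nrow(), W = img.ncol(), K = kernel.size();
  const int half = (K - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  auto mirror = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int cc = mirror(c + (k - half) * dilation, W);
        s += kernel[k] * img(r, cc);
      }
      tmp(r, c) = s;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int rr = mirror(r + (k - half) * dilation, H);
        s += kernel[k] * tmp(rr, c);
      }
      out(r, c) = s;
    }
  return out;
}

// Strict local maxima over the 8-neighbourhood above `threshold`. A plateau
// yields only its first cell in raster (row, col) order: a candidate must be
// >= all neighbours and strictly > any neighbour earlier in raster order.
// Returns 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(const NumericMatrix& img, double threshold) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<int> rows, cols;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      const double v = img(r, c);
      if (!(v > threshold)) continue;
      bool ok = true;
      for (int dr = -1; dr <= 1 && ok; ++dr)
        for (int dc = -1; dc <= 1 && ok; ++dc) {
          if (dr == 0 && dc == 0) continue;
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          const double u = img(rr, cc);
          const bool earlier = (dr < 0) || (dr == 0 && dc < 0);
          if (earlier ? !(v > u) : !(v >= u)) ok = false;
        }
      if (ok) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}

// Levenberg-Marquardt least-squares fit of a symmetric 2-D Gaussian plus
// offset on a (2r+1)^2 window around each peak. Pixel coordinates are
// 0-based indices; the centre of pixel (0,0) is at (0,0) on this grid.
// Returns columns: x0, y0 (px), sigma (px), A, b, rss, converged(0/1).
static bool solve5(double M[5][5], double g[5], double d[5]) {
  int idx[5] = {0, 1, 2, 3, 4};
  for (int i = 0; i < 5; ++i) {
    int piv = i;
    for (int j = i + 1; j < 5; ++j)
      if (std::fabs(M[idx[j]][i]) > std::fabs(M[idx[piv]][i])) piv = j;
    std::swap(idx[i], idx[piv]);
    const double a = M[idx[i]][i];
    if (std::fabs(a) < 1e-14) return false;
    for (int j = i + 1; j < 5; ++j) {
      const double f = M[idx[j]][i] / a;
      for (int k = i; k < 5; ++k) M[idx[j]][k] -= f * M[idx[i]][k];
      g[idx[j]] -= f * g[idx[i]];
    }
  }
  for (int i = 4; i >= 0; --i) {
    double s = g[idx[i]];
    for (int k = i + 1; k < 5; ++k) s -= M[idx[i]][k] * d[k];
    d[i] = s / M[idx[i]][i];
  }
  return true;
}

// Integrated Gaussian model: pixel (r, c) covers [c-0.5, c+0.5] x
// [r-0.5, r+0.5] on the 0-based index grid, and the model value is
// N * DPhi_x * DPhi_y + b where DPhi is the Gaussian mass over the pixel
// extent. Proper for undersampled PSFs (sigma comparable to the pixel).
struct EdgeTerms { double dphi, d_dmu, d_ds; };

static inline EdgeTerms edge_terms(double u, double mu, double s) {
  // u: pixel centre coordinate; returns Gaussian mass over [u-.5, u+.5]
  const double zp = (u + 0.5 - mu) / s, zm = (u - 0.5 - mu) / s;
  const double pp = 0.5 * std::erf(zp / M_SQRT2),
               pm = 0.5 * std::erf(zm / M_SQRT2);
  const double dp = std::exp(-0.5 * zp * zp) / std::sqrt(2.0 * M_PI),
               dm = std::exp(-0.5 * zm * zm) / std::sqrt(2.0 * M_PI);
  EdgeTerms t;
  t.dphi = pp - pm;
  t.d_dmu = -(dp - dm) / s;
  t.d_ds = -(zp * dp - zm * dm) / s;
  return t;
}

// [[Rcpp::export]]
NumericMatrix fit_gaussians_cpp(const NumericMatrix& frame,
                                const IntegerMatrix& peaks,
                                int radius, double init_sigma,
                                int max_iter) {
  const int H = frame.nrow(), W = frame.ncol(), n = peaks.nrow();
  const int wlen = 2 * radius + 1;
  NumericMatrix out(n, 7);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < n; ++i) {
    const int pr = peaks(i, 0) - 1, pc = peaks(i, 1) - 1;
    const int r0 = std::max(0, pr - radius), r1 = std::min(H - 1, pr + radius);
    const int c0 = std::max(0, pc - radius), c1 = std::min(W - 1, pc + radius);
    if (r1 - r0 + 1 < wlen || c1 - c0 + 1 < wlen) { out(i, 6) = 0; continue; }
    double bmin = R_PosInf;
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c) bmin = std::min(bmin, frame(r, c));
    // parameters: N (volume), x0 (col), y0 (row), s, b
    const double peak0 = frame(pr, pc) - bmin;
    double th[5] = {std::max(peak0, 1e-6) * 2.0 * M_PI * init_sigma * init_sigma,
                    (double)pc, (double)pr, init_sigma, bmin};
    double lambda = 1e-3, rss = R_PosInf;
    bool conv = false;
    auto model_rss = [&](const double* p) {
      double acc = 0.0;
      for (int r = r0; r <= r1; ++r) {
        const EdgeTerms ty = edge_terms((double)r, p[2], p[3]);
        for (int c = c0; c <= c1; ++c) {
          const EdgeTerms tx = edge_terms((double)c, p[1], p[3]);
          const double res = p[0] * tx.dphi * ty.dphi + p[4] - frame(r, c);
          acc += res * res;
        }
      }
      return acc;
    };
    for (int it = 0; it < max_iter; ++it) {
      double M[5][5] = {{0}}, g[5] = {0};
      rss = 0.0;
      for (int r = r0; r <= r1; ++r) {
        const EdgeTerms ty = edge_terms((double)r, th[2], th[3]);
        for (int c = c0; c <= c1; ++c) {
          const EdgeTerms tx = edge_terms((double)c, th[1], th[3]);
          const double f = th[0] * tx.dphi * ty.dphi + th[4];
          const double res = f - frame(r, c);
          rss += res * res;
          const double J[5] = {tx.dphi * ty.dphi,
                               th[0] * tx.d_dmu * ty.dphi,
                               th[0] * tx.dphi * ty.d_dmu,
                               th[0] * (tx.d_ds * ty.dphi + tx.dphi * ty.d_ds),
                               1.0};
          for (int a = 0; a < 5; ++a) {
            g[a] -= J[a] * res;
            for (int b = a; b < 5; ++b) M[a][b] += J[a] * J[b];
          }
        }
      }
      for (int a = 0; a < 5; ++a)
        for (int b = 0; b < a; ++b) M[a][b] = M[b][a];
      double Md[5][5], gd[5], d[5];
      std::copy(&M[0][0], &M[0][0] + 25, &Md[0][0]);
      std::copy(g, g + 5, gd);
      for (int a = 0; a < 5; ++a) Md[a][a] *= (1.0 + lambda);
      if (!solve5(Md, gd, d)) break;
      double thn[5];
      for (int a = 0; a < 5; ++a) thn[a] = th[a] + d[a];
      if (thn[3] <= 0.05) thn[3] = 0.05;
      const double rssn = model_rss(thn);
      if (rssn < rss) {
        double stepsz = 0.0;
        for (int a = 0; a < 5; ++a) stepsz += d[a] * d[a];
        std::copy(thn, thn + 5, th);
        lambda = std::max(lambda * 0.3, 1e-9);
        if (std::sqrt(stepsz) < 1e-7) { conv = true; rss = rssn; break; }
        rss = rssn;
      } else {
        // no descent direction improves the fit: we are at a minimum
        lambda *= 10.0;
        if (lambda > 1e8) { conv = true; break; }
      }
      if (it == max_iter - 1) conv = true;
    }
    out(i, 0) = th[1]; out(i, 1) = th[2]; out(i, 2) = std::fabs(th[3]);
    out(i, 3) = th[0]; out(i, 4) = th[4]; out(i, 5) = rss;
    out(i, 6) = conv ? 1 : 0;
  }
  return out;
}

// Greedy temporal grouping of localizations into tracks. Input columns are
// sorted by frame. A row joins the first open track whose running
// intensity-weighted mean is within max_dist (nm) and whose last frame is at
// most off_frames + 1 behind. Returns a 1-based track id per row.
// [[Rcpp::export]]
IntegerVector merge_tracks_cpp(const IntegerVector& frame,
                               const NumericVector& x, const NumericVector& y,
                               const NumericVector& intensity,
                               double max_dist, int off_frames) {
  const int n = frame.size();
  IntegerVector id(n);
  std::vector<double> tx, ty, tw;   // running weighted means and weights
  std::vector<int> tlast, topen;    // last frame, open-track indices
  const double d2 = max_dist * max_dist;
  for (int i = 0; i < n; ++i) {
    // close expired tracks
    for (size_t j = 0; j < topen.size();) {
      if (frame[i] - tlast[topen[j]] > off_frames + 1)
        topen.erase(topen.begin() + j);
      else ++j;
    }
    int hit = -1;
    for (size_t j = 0; j < topen.size(); ++j) {
      const int t = topen[j];
      const double dx = x[i] - tx[t], dy = y[i] - ty[t];
      if (dx * dx + dy * dy <= d2) { hit = t; break; }
    }
    if (hit < 0) {
      hit = tx.size();
      tx.push_back(x[i]); ty.push_back(y[i]);
      tw.push_back(std::max(intensity[i], 1e-12));
      tlast.push_back(frame[i]); topen.push_back(hit);
    } else {
      const double w = std::max(intensity[i], 1e-12), W0 = tw[hit];
      tx[hit] = (tx[hit] * W0 + x[i] * w) / (W0 + w);
      ty[hit] = (ty[hit] * W0 + y[i] * w) / (W0 + w);
      tw[hit] = W0 + w;
      tlast[hit] = frame[i];
    }
    id[i] = hit + 1;
  }
  return id;
}

// Unit-mass Gaussian rendering of localizations onto a grid.
// x, y in nm; sigma per localization in nm; pixel in nm; H, W grid size.
// [[Rcpp::export]]
NumericMatrix render_gaussian_cpp(const NumericVector& x, const NumericVector& y,
                                  const NumericVector& sigma, double pixel,
                                  int H, int W) {
  NumericMatrix img(H, W);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    const double s = sigma[i], cx = x[i] / pixel, cy = y[i] / pixel;
    const double spx = s / pixel;
    const int rad = std::max(1, (int)std::ceil(4.0 * spx));
    const int c0 = std::max(0, (int)std::floor(cx) - rad);
    const int c1 = std::min(W - 1, (int)std::floor(cx) + rad);
    const int r0 = std::max(0, (int)std::floor(cy) - rad);
    const int r1 = std::min(H - 1, (int)std::floor(cy) + rad);
    if (c1 < c0 || r1 < r0) continue;
    // integrated Gaussian over pixel extents, mass 1 over the full plane
    for (int r = r0; r <= r1; ++r) {
      const double py = 0.5 * (std::erf((r + 1 - cy) / (spx * M_SQRT2)) -
                               std::erf((r - cy) / (spx * M_SQRT2)));
      for (int c = c0; c <= c1; ++c) {
        const double px = 0.5 * (std::erf((c + 1 - cx) / (spx * M_SQRT2)) -
                                 std::erf((c - cx) / (spx * M_SQRT2)));
        img(r, c) += px * py;
      }
    }
  }
  return img;
}
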