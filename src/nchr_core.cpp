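#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample) reflection of an index into [0, n).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    else i = 2 * n - 1 - i;
  }
  return i;
}

// Column-major padded copy, (H+2p) x (W+2p), symmetric reflection.
static std::vector<double> pad_reflect_mat(const NumericMatrix& img, int p) {
  int H = img.nrow(), W = img.ncol();
  int Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<double> P((size_t)Hp * Wp);
  for (int c = 0; c < Wp; ++c) {
    int cc = reflect_idx(c - p, W);
    double* col = &P[(size_t)c * Hp];
    for (int r = 0; r < Hp; ++r) col[r] = img(reflect_idx(r - p, H), cc);
  }
  return P;
}

// Vertical sliding-window sum, window 2*pr+1; valid rows [pr, Ha-pr).
static void box_vert(const std::vector<double>& A, int Ha, int Wa, int pr,
                     std::vector<double>& O) {
  for (int c = 0; c < Wa; ++c) {
    const double* a = &A[(size_t)c * Ha];
    double* o = &O[(size_t)c * Ha];
    double s = 0.0;
    for (int r = 0; r < 2 * pr; ++r) s += a[r];
    for (int r = pr; r < Ha - pr; ++r) {
      s += a[r + pr];
      o[r] = s;
      s -= a[r - pr];
    }
  }
}

// Horizontal sliding-window sum over rows [r0, r1); valid cols [pr, Wa-pr).
static void box_horiz(const std::vector<double>& A, int Ha, int Wa, int pr,
                      int r0, int r1, std::vector<double>& O) {
  for (int r = r0; r < r1; ++r) {
    double s = 0.0;
    for (int c = 0; c < 2 * pr; ++c) s += A[(size_t)c * Ha + r];
    for (int c = pr; c < Wa - pr; ++c) {
      s += A[(size_t)(c + pr) * Ha + r];
      O[(size_t)c * Ha + r] = s;
      s -= A[(size_t)(c - pr) * Ha + r];
    }
  }
}

// Patch-similarity weight field. Column j = (dc+nr)*neigh + (dr+nr) holds the
// weight w(x, x+(dr,dc)) for every image pixel x (column-major pixel order).
// The self-offset column (dr,dc) = (0,0) is identically zero. Patches are
// read through symmetric reflection of the image border; neighbor centers are
// taken in the same reflected coordinate system.
// [[Rcpp::export]]
NumericMatrix cpp_weight_field(NumericMatrix current, NumericMatrix noisy,
                               double sigma, int patch, int neigh,
                               bool modified, bool js_patch_count) {
  const int H = current.nrow(), W = current.ncol();
  const int pr = patch / 2, nr = neigh / 2, pad = pr + nr;
  const int Hp = H + 2 * pad;
  const int Hs = H + 2 * pr, Ws = W + 2 * pr;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int nOff = neigh * neigh;
  const size_t HW = (size_t)H * W;

  std::vector<double> P = pad_reflect_mat(current, pad);
  NumericMatrix out((int)HW, nOff); // zero-filled

  // James-Stein factor per center pixel (1.0 in conventional mode).
  std::vector<double> js(HW, 1.0);
  if (modified) {
    NumericMatrix resid(H, W);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        resid(r, c) = noisy(r, c) - current(r, c);
    std::vector<double> Q = pad_reflect_mat(resid, pr); // Hs x Ws
    for (size_t k = 0; k < Q.size(); ++k) Q[k] *= Q[k];
    std::vector<double> T1(Q.size()), T2(Q.size());
    box_vert(Q, Hs, Ws, pr, T1);
    box_horiz(T1, Hs, Ws, pr, pr, Hs - pr, T2);
    const int m = js_patch_count ? patch * patch : neigh * neigh;
    const double thr = (m - 2) * sigma * sigma;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double rn = T2[(size_t)(c + pr) * Hs + (r + pr)];
        double f = (rn > 0.0) ? 1.0 - thr / rn : 0.0;
        js[(size_t)c * H + r] = f > 0.0 ? f : 0.0;
      }
  }

  std::vector<double> S((size_t)Hs * Ws), T1(S.size()), D(S.size());
  double* outp = REAL(out);
  for (int dc = -nr; dc <= nr; ++dc) {
    for (int dr = -nr; dr <= nr; ++dr) {
      if (dr == 0 && dc == 0) continue;
      const int j = (dc + nr) * neigh + (dr + nr);
      // squared difference of the padded image against its shift by (dr,dc)
      for (int c = 0; c < Ws; ++c) {
        const double* p1 = &P[(size_t)(c + nr) * Hp + nr];
        const double* p2 = &P[(size_t)(c + nr + dc) * Hp + nr + dr];
        double* s = &S[(size_t)c * Hs];
        for (int r = 0; r < Hs; ++r) {
          double d = p1[r] - p2[r];
          s[r] = d * d;
        }
      }
      box_vert(S, Hs, Ws, pr, T1);
      box_horiz(T1, Hs, Ws, pr, pr, Hs - pr, D);
      double* o = outp + (size_t)j * HW;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          double jsv = js[(size_t)c * H + r];
          if (jsv <= 0.0) continue;
          double Dv = D[(size_t)(c + pr) * Hs + (r + pr)];
          o[(size_t)c * H + r] = jsv * std::exp(-Dv * inv2s2);
        }
    }
  }
  return out;
}

// Non-local penalty: sum over pixels x and offsets d of
// w(x,d) * ||patch(image, x) - patch(image, x+d)||^2 (Frobenius).
// [[Rcpp::export]]
double cpp_penalty(NumericMatrix image, NumericMatrix w, int patch, int neigh) {
  const int H = image.nrow(), W = image.ncol();
  const int pr = patch / 2, nr = neigh / 2, pad = pr + nr;
  const int Hp = H + 2 * pad;
  const int Hs = H + 2 * pr, Ws = W + 2 * pr;
  const size_t HW = (size_t)H * W;

  std::vector<double> P = pad_reflect_mat(image, pad);
  std::vector<double> S((size_t)Hs * Ws), T1(S.size()), D(S.size());
  const double* wp = REAL(w);
  double acc = 0.0;
  for (int dc = -nr; dc <= nr; ++dc) {
    for (int dr = -nr; dr <= nr; ++dr) {
      if (dr == 0 && dc == 0) continue;
      const int j = (dc + nr) * neigh + (dr + nr);
      const double* wj = wp + (size_t)j * HW;
      double mx = 0.0;
      for (size_t k = 0; k < HW; ++k) if (wj[k] > mx) mx = wj[k];
      if (mx == 0.0) continue;
      for (int c = 0; c < Ws; ++c) {
        const double* p1 = &P[(size_t)(c + nr) * Hp + nr];
        const double* p2 = &P[(size_t)(c + nr + dc) * Hp + nr + dr];
        double* s = &S[(size_t)c * Hs];
        for (int r = 0; r < Hs; ++r) {
          double d = p1[r] - p2[r];
          s[r] = d * d;
        }
      }
      box_vert(S, Hs, Ws, pr, T1);
      box_horiz(T1, Hs, Ws, pr, pr, Hs - pr, D);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          acc += wj[(size_t)c * H + r] * D[(size_t)(c + pr) * Hs + (r + pr)];
    }
  }
  return acc;
}

// Gradient of cpp_penalty with respect to the image, weights held frozen.
// Accumulated on the padded grid and folded back through the reflection map.
// [[Rcpp::export]]
NumericMatrix cpp_penalty_gradient(NumericMatrix image, NumericMatrix w,
                                   int patch, int neigh) {
  const int H = image.nrow(), W = image.ncol();
  const int pr = patch / 2, nr = neigh / 2, pad = pr + nr;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Hs = H + 2 * pr, Ws = W + 2 * pr;
  const int He = H + 4 * pr, We = W + 4 * pr;
  const size_t HW = (size_t)H * W;

  std::vector<double> P = pad_reflect_mat(image, pad);
  std::vector<double> G((size_t)Hp * Wp, 0.0);
  std::vector<double> Sg((size_t)Hs * Ws);
  std::vector<double> E((size_t)He * We), T1e(E.size()), WT(E.size());
  const double* wp = REAL(w);

  for (int dc = -nr; dc <= nr; ++dc) {
    for (int dr = -nr; dr <= nr; ++dr) {
      if (dr == 0 && dc == 0) continue;
      const int j = (dc + nr) * neigh + (dr + nr);
      const double* wj = wp + (size_t)j * HW;
      double mx = 0.0;
      for (size_t k = 0; k < HW; ++k) if (wj[k] > mx) mx = wj[k];
      if (mx == 0.0) continue;
      // signed difference field on the patch-extended grid
      for (int c = 0; c < Ws; ++c) {
        const double* p1 = &P[(size_t)(c + nr) * Hp + nr];
        const double* p2 = &P[(size_t)(c + nr + dc) * Hp + nr + dr];
        double* s = &Sg[(size_t)c * Hs];
        for (int r = 0; r < Hs; ++r) s[r] = p1[r] - p2[r];
      }
      // box-correlation of the weight plane: WT(t) = sum_{|u|<=pr} w(t-u)
      std::fill(E.begin(), E.end(), 0.0);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          E[(size_t)(c + 2 * pr) * He + (r + 2 * pr)] = wj[(size_t)c * H + r];
      box_vert(E, He, We, pr, T1e);
      box_horiz(T1e, He, We, pr, pr, He - pr, WT);
      for (int c = 0; c < Ws; ++c) {
        const double* wt = &WT[(size_t)(c + pr) * He + pr];
        const double* s = &Sg[(size_t)c * Hs];
        double* g1 = &G[(size_t)(c + nr) * Hp + nr];
        double* g2 = &G[(size_t)(c + nr + dc) * Hp + nr + dr];
        for (int r = 0; r < Hs; ++r) {
          double v = 2.0 * wt[r] * s[r];
          if (v != 0.0) {
            g1[r] += v;
            g2[r] -= v;
          }
        }
      }
    }
  }
  NumericMatrix grad(H, W);
  for (int c = 0; c < Wp; ++c) {
    int cc = reflect_idx(c - pad, W);
    for (int r = 0; r < Hp; ++r) {
      double v = G[(size_t)c * Hp + r];
      if (v != 0.0) grad(reflect_idx(r - pad, H), cc) += v;
    }
  }
  return grad;
}
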