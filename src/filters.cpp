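#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Border convention for grayscale neighborhood ops: edge replication
// (indices clamped to the image domain).
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& x, int k) {
  int H = x.nrow(), W = x.ncol(), h = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf(k * k);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      int m = 0;
      for (int di = -h; di <= h; ++di)
        for (int dj = -h; dj <= h; ++dj)
          buf[m++] = x(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        // even count (never hit for odd k, kept for completeness)
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// The eight 3x3 Kirsch compass kernels (+5/-3 pattern), applied as
// correlation; output is the maximum directional response (can be < 0
// only on pathological inputs since kernels are zero-sum).
// [[Rcpp::export]]
NumericMatrix cpp_kirsch(const NumericMatrix& x) {
  static const int K[8][9] = {
    { 5,  5,  5, -3,  0, -3, -3, -3, -3},  // N
    { 5,  5, -3,  5,  0, -3, -3, -3, -3},  // NW
    { 5, -3, -3,  5,  0, -3,  5, -3, -3},  // W
    {-3, -3, -3,  5,  0, -3,  5,  5, -3},  // SW
    {-3, -3, -3, -3,  0, -3,  5,  5,  5},  // S
    {-3, -3, -3, -3,  0,  5, -3,  5,  5},  // SE
    {-3, -3,  5, -3,  0,  5, -3, -3,  5},  // E
    {-3,  5,  5, -3,  0,  5, -3, -3, -3}   // NE
  };
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double best = R_NegInf;
      for (int d = 0; d < 8; ++d) {
        double acc = 0.0;
        int m = 0;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj)
            acc += K[d][m++] * x(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
        if (acc > best) best = acc;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Sobel pair: gx responds to horizontal (column-wise) intensity change,
// gy to vertical; correlation with edge replication.
// [[Rcpp::export]]
List cpp_sobel(const NumericMatrix& x) {
  static const int SX[9] = {-1, 0, 1, -2, 0, 2, -1, 0, 1};
  static const int SY[9] = {-1, -2, -1, 0, 0, 0, 1, 2, 1};
  int H = x.nrow(), W = x.ncol();
  NumericMatrix gx(H, W), gy(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double ax = 0.0, ay = 0.0;
      int m = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          double v = x(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
          ax += SX[m] * v;
          ay += SY[m] * v;
          ++m;
        }
      gx(i, j) = ax;
      gy(i, j) = ay;
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Separable convolution with a symmetric 1-D kernel, edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(const NumericMatrix& x, const NumericVector& kern) {
  int H = x.nrow(), W = x.ncol(), n = kern.size(), h = n / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int t = 0; t < n; ++t)
        acc += kern[t] * x(i, clampi(j + t - h, 0, W - 1));
      tmp(i, j) = acc;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int t = 0; t < n; ++t)
        acc += kern[t] * tmp(clampi(i + t - h, 0, H - 1), j);
      out(i, j) = acc;
    }
  return out;
}

// Binary morphology with the clipped-translate convention: offsets that
// fall outside the image domain are ignored, so erosion/dilation form an
// adjunction on the lattice of in-domain masks (opening/closing stay
// idempotent at borders).
// [[Rcpp::export]]
IntegerMatrix cpp_binary_erode(const IntegerMatrix& a,
                               const IntegerVector& dy, const IntegerVector& dx) {
  int H = a.nrow(), W = a.ncol(), n = dy.size();
  IntegerMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int v = 1;
      for (int t = 0; t < n && v; ++t) {
        int ii = i + dy[t], jj = j + dx[t];
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && a(ii, jj) == 0) v = 0;
      }
      out(i, j) = v;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_binary_dilate(const IntegerMatrix& a,
                                const IntegerVector& dy, const IntegerVector& dx) {
  int H = a.nrow(), W = a.ncol(), n = dy.size();
  IntegerMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int v = 0;
      for (int t = 0; t < n && !v; ++t) {
        int ii = i - dy[t], jj = j - dx[t];
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && a(ii, jj) == 1) v = 1;
      }
      out(i, j) = v;
    }
  return out;
}

// Grayscale dilation (f (+) b)(x) = sup_y [f(x - y) + b(y)] over the
// element support, with edge replication for out-of-domain f.
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& f,
                              const IntegerVector& dy, const IntegerVector& dx,
                              const NumericVector& bval) {
  int H = f.nrow(), W = f.ncol(), n = dy.size();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double best = R_NegInf;
      for (int t = 0; t < n; ++t) {
        double v = f(clampi(i - dy[t], 0, H - 1), clampi(j - dx[t], 0, W - 1)) + bval[t];
        if (v > best) best = v;
      }
      out(i, j) = best;
    }
  return out;
}

// Circular Hough accumulator. Edge pixels vote for centers at distance r
// along sampled angles; score is the supported fraction of the
// circumference. Ties broken by smaller radius, then row-major center.
// [[Rcpp::export]]
List cpp_hough_circle(const IntegerMatrix& edges, const IntegerVector& radii) {
  int H = edges.nrow(), W = edges.ncol(), nr = radii.size();
  std::vector<int> ey, ex;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (edges(i, j) == 1) { ey.push_back(i); ex.push_back(j); }
  double bestArc = -1.0, bestScore = -1.0;
  int bestR = -1, bestRow = -1, bestCol = -1;
  int nEdge = (int) ey.size();
  std::vector<int> acc((size_t) H * W);
  for (int t = 0; t < nr; ++t) {
    int r = radii[t];
    int na = std::max(16, (int) std::ceil(2.0 * M_PI * r));
    std::fill(acc.begin(), acc.end(), 0);
    // precompute circle offsets, deduplicated per angle step
    std::vector<int> oy(na), ox(na);
    for (int a = 0; a < na; ++a) {
      double th = 2.0 * M_PI * a / na;
      oy[a] = (int) std::lround(r * std::sin(th));
      ox[a] = (int) std::lround(r * std::cos(th));
    }
    for (int e = 0; e < nEdge; ++e) {
      for (int a = 0; a < na; ++a) {
        int ci = ey[e] - oy[a], cj = ex[e] - ox[a];
        if (ci >= 0 && ci < H && cj >= 0 && cj < W)
          acc[(size_t) ci * W + cj] += 1;
      }
    }
    // rank by supported arc length (completeness x circumference) so a
    // small but complete circle cannot outrank the disc; the stored score
    // stays the supported fraction of the circumference
    double arcPerVote = 2.0 * M_PI * r / na;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        double arc = acc[(size_t) i * W + j] * arcPerVote;
        if (arc > bestArc + 1e-9) {
          bestArc = arc;
          bestScore = (double) acc[(size_t) i * W + j] / na;
          bestR = r; bestRow = i; bestCol = j;
        }
      }
  }
  return List::create(_["row"] = bestRow, _["col"] = bestCol,
                      _["r"] = bestR, _["score"] = bestScore,
                      _["arc"] = bestArc);
}

// 8-connected component labeling (BFS), labels 1..n in row-major order
// of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) != 1 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W &&
                mask(ii, jj) == 1 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// Bilinear resize with the align-corners convention: source coordinate of
// output pixel t is t * (S - 1) / (T - 1) (source point itself when T = 1).
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(const NumericMatrix& x, int oh, int ow) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(oh, ow);
  for (int i = 0; i < oh; ++i) {
    double sy = (oh == 1) ? 0.0 : (double) i * (H - 1) / (oh - 1);
    int y0 = (int) std::floor(sy);
    int y1 = std::min(y0 + 1, H - 1);
    double fy = sy - y0;
    for (int j = 0; j < ow; ++j) {
      double sx = (ow == 1) ? 0.0 : (double) j * (W - 1) / (ow - 1);
      int x0 = (int) std::floor(sx);
      int x1 = std::min(x0 + 1, W - 1);
      double fx = sx - x0;
      out(i, j) = (1 - fy) * ((1 - fx) * x(y0, x0) + fx * x(y0, x1)) +
                  fy * ((1 - fx) * x(y1, x0) + fx * x(y1, x1));
    }
  }
  return out;
}
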