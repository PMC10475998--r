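#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat spherical (ball) structuring
// element, the primitive behind rolling-ball background estimation:
// background = dilate(erode(image)).  Out-of-bounds pixels are ignored
// (treated as neutral), which keeps the estimate defined at borders.

static NumericMatrix ball_transform(const NumericMatrix& img, double radius,
                                    bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  int r = (int)std::floor(radius);
  std::vector<int> dx, dy;
  std::vector<double> h;  // ball height <= 0 at offset
  for (int i = -r; i <= r; ++i)
    for (int j = -r; j <= r; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dx.push_back(i); dy.push_back(j);
        h.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  int K = (int)dx.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ri = rI + dx[k], ci = c + dy[k];
        if (ri < 0 || ri >= nr || ci < 0 || ci >= nc) continue;
        double v = erode ? img(ri, ci) - h[k] : img(ri, ci) + h[k];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(rI, c) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball_background(NumericMatrix img, double radius) {
  NumericMatrix er = ball_transform(img, radius, true);
  return ball_transform(er, radius, false);
}

// Connected-component labeling on a 2D/3D grid with face connectivity
// (4-connected in 2D, 6-connected in 3D).  fg is column-major.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, IntegerVector dims) {
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      int nnb = (nd == 3) ? 6 : 4;
      for (int k = 0; k < nnb; ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (fg[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// DBSCAN on 2D points with Euclidean metric and a grid spatial index.
// Deterministic: points are visited in row order and neighbor lists are
// sorted by index, so border points join the first-discovered core cluster.
// Returns cluster id per point, 0 = noise.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  int n = x.size();
  IntegerVector cl(n, 0);
  if (n == 0) return cl;
  double xmin = *std::min_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  std::unordered_map<long long, std::vector<int> > grid;
  auto cell = [&](double px, double py) -> long long {
    long long cx = (long long)std::floor((px - xmin) / eps);
    long long cy = (long long)std::floor((py - ymin) / eps);
    return cx * 2000003LL + cy;
  };
  for (int i = 0; i < n; ++i) grid[cell(x[i], y[i])].push_back(i);
  double e2 = eps * eps;
  auto region_query = [&](int i) {
    std::vector<int> nb;
    long long cx = (long long)std::floor((x[i] - xmin) / eps);
    long long cy = (long long)std::floor((y[i] - ymin) / eps);
    for (long long a = cx - 1; a <= cx + 1; ++a)
      for (long long b = cy - 1; b <= cy + 1; ++b) {
        auto it = grid.find(a * 2000003LL + b);
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= e2) nb.push_back(j);
        }
      }
    std::sort(nb.begin(), nb.end());
    return nb;
  };
  std::vector<char> visited(n, 0);
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    std::vector<int> nb = region_query(i);
    if ((int)nb.size() < min_pts) continue;  // noise unless claimed later
    ++cur;
    cl[i] = cur;
    std::deque<int> seeds(nb.begin(), nb.end());
    while (!seeds.empty()) {
      int j = seeds.front(); seeds.pop_front();
      if (cl[j] == 0) cl[j] = cur;
      if (visited[j]) continue;
      visited[j] = 1;
      std::vector<int> nb2 = region_query(j);
      if ((int)nb2.size() >= min_pts)
        for (int q : nb2) if (!visited[q] || cl[q] == 0) seeds.push_back(q);
    }
  }
  return cl;
}
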