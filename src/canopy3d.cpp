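#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
#include <unordered_map>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Semi-global block matching.
//
// Pixelwise cost: block-aggregated absolute intensity difference (box sum
// over block_size x block_size). Aggregation: 8-path semi-global dynamic
// programme with penalties P1 (|dd| = 1) and P2 (|dd| > 1). Winner-take-all
// with parabolic subpixel refinement, a uniqueness check, and a left-right
// consistency check computed from the same aggregated volume. Invalid
// pixels are NaN.
// ---------------------------------------------------------------------------

static inline float box_sum(const std::vector<double> &ii, int w1, int y0,
                            int x0, int y1, int x1) {
  // inclusive window on an (h+1)x(w+1) integral image with width w1 = w+1
  return (float)(ii[(y1 + 1) * w1 + (x1 + 1)] - ii[y0 * w1 + (x1 + 1)] -
                 ii[(y1 + 1) * w1 + x0] + ii[y0 * w1 + x0]);
}

// [[Rcpp::export]]
NumericMatrix sgbm_disparity_cpp(NumericMatrix left, NumericMatrix right,
                                 int min_disparity, int num_disparities,
                                 int block_size, double P1, double P2,
                                 int uniqueness_ratio, int lr_max_diff) {
  const int h = left.nrow(), w = left.ncol();
  const int D = num_disparities;
  const int r = block_size / 2;
  const float MAXCOST = 255.0f * block_size * block_size;

  // cost volume, index (y * w + x) * D + d
  std::vector<float> C((size_t)h * w * D, MAXCOST);
  std::vector<double> ii((size_t)(h + 1) * (w + 1), 0.0);
  const int w1 = w + 1;
  for (int d = 0; d < D; ++d) {
    const int disp = min_disparity + d;
    // integral image of |L(y,x) - R(y,x-disp)|
    for (int y = 0; y < h; ++y) {
      double rowsum = 0.0;
      for (int x = 0; x < w; ++x) {
        double ad = 0.0;
        int xr = x - disp;
        if (xr >= 0 && xr < w) ad = std::fabs(left(y, x) - right(y, xr));
        else ad = 255.0;
        rowsum += ad;
        ii[(y + 1) * w1 + (x + 1)] = ii[y * w1 + (x + 1)] + rowsum;
      }
    }
    for (int y = 0; y < h; ++y) {
      int y0 = std::max(0, y - r), y1 = std::min(h - 1, y + r);
      for (int x = 0; x < w; ++x) {
        int x0 = std::max(0, x - r), x1 = std::min(w - 1, x + r);
        float c = box_sum(ii, w1, y0, x0, y1, x1);
        // normalize by window area to the full block scale
        float area = (float)((y1 - y0 + 1) * (x1 - x0 + 1));
        C[((size_t)y * w + x) * D + d] =
            c * (block_size * block_size) / area;
      }
    }
  }

  std::vector<float> S((size_t)h * w * D, 0.0f);
  const int dirs[8][2] = {{0, 1},  {0, -1}, {1, 0},  {-1, 0},
                          {1, 1},  {1, -1}, {-1, 1}, {-1, -1}};
  std::vector<float> Lprev(D), Lcur(D);
  std::vector<float> rowbuf;  // previous-row L for vertical/diagonal paths

  for (int dir = 0; dir < 8; ++dir) {
    const int dy = dirs[dir][0], dx = dirs[dir][1];
    // iterate in an order such that p - (dy,dx) is already done
    const int ys = (dy >= 0) ? 0 : h - 1, ye = (dy >= 0) ? h : -1,
              yi = (dy >= 0) ? 1 : -1;
    const int xs = (dx >= 0) ? 0 : w - 1, xe = (dx >= 0) ? w : -1,
              xi = (dx >= 0) ? 1 : -1;
    rowbuf.assign((size_t)w * D, 0.0f);
    std::vector<float> rowmin(w, 0.0f);
    std::vector<float> currow((size_t)w * D, 0.0f);
    std::vector<float> curmin(w, 0.0f);
    for (int y = ys; y != ye; y += yi) {
      for (int x = xs; x != xe; x += xi) {
        const size_t base = ((size_t)y * w + x) * D;
        const int py = y - dy, px = x - dx;
        bool has_prev = (py >= 0 && py < h && px >= 0 && px < w);
        float pmin = 0.0f;
        const float *Lp = nullptr;
        if (has_prev) {
          if (dy == 0) {  // horizontal: previous pixel is in this row
            Lp = &currow[(size_t)px * D];
            pmin = curmin[px];
          } else {
            Lp = &rowbuf[(size_t)px * D];
            pmin = rowmin[px];
          }
        }
        float mn = std::numeric_limits<float>::max();
        float *Lc = &currow[(size_t)x * D];
        for (int d = 0; d < D; ++d) {
          float c = C[base + d];
          float v;
          if (!has_prev) {
            v = c;
          } else {
            float best = Lp[d];
            if (d > 0) best = std::min(best, Lp[d - 1] + (float)P1);
            if (d < D - 1) best = std::min(best, Lp[d + 1] + (float)P1);
            best = std::min(best, pmin + (float)P2);
            v = c + best - pmin;
          }
          Lc[d] = v;
          if (v < mn) mn = v;
          S[base + d] += v;
        }
        curmin[x] = mn;
      }
      if (dy != 0) {
        std::swap(rowbuf, currow);
        std::swap(rowmin, curmin);
      }
    }
  }

  NumericMatrix out(h, w);
  std::vector<double> dleft((size_t)h * w, -1.0);
  const double NaN = std::numeric_limits<double>::quiet_NaN();
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      const size_t base = ((size_t)y * w + x) * D;
      int bd = 0;
      float bs = S[base];
      for (int d = 1; d < D; ++d)
        if (S[base + d] < bs) { bs = S[base + d]; bd = d; }
      // uniqueness: best must beat every candidate farther than 1 level
      bool ok = true;
      if (uniqueness_ratio > 0) {
        for (int d = 0; d < D; ++d) {
          if (std::abs(d - bd) <= 1) continue;
          // <= so a flat (textureless) cost profile is ambiguous -> invalid
          if (S[base + d] * 100.0f <= bs * (100.0f + uniqueness_ratio)) {
            ok = false;
            break;
          }
        }
      }
      if (ok) {
        // texture check: a raw cost profile that is flat across the
        // disparity range carries no match evidence (textureless region)
        float cmin = C[base], cmax = C[base];
        for (int d = 1; d < D; ++d) {
          float c = C[base + d];
          if (c < cmin) cmin = c;
          if (c > cmax) cmax = c;
        }
        if (cmax - cmin <= (float)(block_size * block_size)) ok = false;
      }
      if (!ok) { out(y, x) = NaN; continue; }
      double disp = min_disparity + bd;
      if (bd > 0 && bd < D - 1) {
        double c0 = S[base + bd - 1], c1 = bs, c2 = S[base + bd + 1];
        double denom = c0 - 2.0 * c1 + c2;
        if (denom > 1e-9) disp += 0.5 * (c0 - c2) / denom;
      }
      out(y, x) = disp;
      dleft[(size_t)y * w + x] = disp;
    }
  }

  if (lr_max_diff >= 0) {
    // right disparity from the same aggregated volume:
    // S_R(y, xr, d) = S(y, xr + d, d)
    for (int y = 0; y < h; ++y) {
      std::vector<double> dr(w, -1.0);
      for (int xr = 0; xr < w; ++xr) {
        int bd = -1;
        float bs = std::numeric_limits<float>::max();
        for (int d = 0; d < D; ++d) {
          int xl = xr + min_disparity + d;
          if (xl < 0 || xl >= w) continue;
          float s = S[((size_t)y * w + xl) * D + d];
          if (s < bs) { bs = s; bd = d; }
        }
        if (bd >= 0) dr[xr] = min_disparity + bd;
      }
      for (int x = 0; x < w; ++x) {
        double dl = dleft[(size_t)y * w + x];
        if (dl < 0) continue;
        int xr = x - (int)std::lround(dl);
        if (xr < 0 || xr >= w || dr[xr] < 0 ||
            std::fabs(dl - dr[xr]) > lr_max_diff + 0.5) {
          out(y, x) = NaN;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Valid-aware median filter: each valid pixel becomes the median of the
// finite values in its window; invalid (NaN) pixels stay invalid.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix median_filter_valid_cpp(NumericMatrix m, int window) {
  const int h = m.nrow(), w = m.ncol(), r = window / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  const double NaN = std::numeric_limits<double>::quiet_NaN();
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!std::isfinite(m(y, x))) { out(y, x) = NaN; continue; }
      buf.clear();
      for (int i = std::max(0, y - r); i <= std::min(h - 1, y + r); ++i)
        for (int j = std::max(0, x - r); j <= std::min(w - 1, x + r); ++j)
          if (std::isfinite(m(i, j))) buf.push_back(m(i, j));
      size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        med = 0.5 * (med + lo);
      }
      out(y, x) = med;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact k-nearest-neighbour mean distances via a uniform voxel grid with
// ring expansion (correct for any point distribution; used by statistical
// outlier removal).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector knn_mean_dist_cpp(NumericVector x, NumericVector y,
                                NumericVector z, int k) {
  const int n = x.size();
  NumericVector out(n);
  if (n <= 1) return out;
  double minx = *std::min_element(x.begin(), x.end());
  double maxx = *std::max_element(x.begin(), x.end());
  double miny = *std::min_element(y.begin(), y.end());
  double maxy = *std::max_element(y.begin(), y.end());
  double minz = *std::min_element(z.begin(), z.end());
  double maxz = *std::max_element(z.begin(), z.end());
  // cell size from the non-degenerate extents only (planar / collinear
  // clouds would otherwise collapse the voxel volume)
  double ex = maxx - minx, ey = maxy - miny, ez = maxz - minz;
  double vol = 1.0;
  int ndim = 0;
  for (double e : {ex, ey, ez}) {
    if (e > 1e-9) { vol *= e; ++ndim; }
  }
  double cell = (ndim > 0)
                    ? std::pow(vol * std::max(1, k) / (double)n, 1.0 / ndim)
                    : 1.0;
  double max_extent = std::max({ex, ey, ez, 1e-9});
  cell = std::max(cell, max_extent / 256.0);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;

  auto key = [&](int ix, int iy, int iz) {
    return ((long long)ix << 42) ^ ((long long)iy << 21) ^ (long long)iz;
  };
  std::unordered_map<long long, std::vector<int>> grid;
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor((x[i] - minx) / cell);
    cy[i] = (int)std::floor((y[i] - miny) / cell);
    cz[i] = (int)std::floor((z[i] - minz) / cell);
    grid[key(cx[i], cy[i], cz[i])].push_back(i);
  }

  for (int i = 0; i < n; ++i) {
    // max-heap of squared distances, size <= k
    std::priority_queue<double> heap;
    int ring = 0;
    while (true) {
      // visit cells on the surface of the cube of radius `ring`
      for (int ix = cx[i] - ring; ix <= cx[i] + ring; ++ix) {
        for (int iy = cy[i] - ring; iy <= cy[i] + ring; ++iy) {
          for (int iz = cz[i] - ring; iz <= cz[i] + ring; ++iz) {
            if (std::max({std::abs(ix - cx[i]), std::abs(iy - cy[i]),
                          std::abs(iz - cz[i])}) != ring)
              continue;
            auto it = grid.find(key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              double d2 = dx * dx + dy * dy + dz * dz;
              if ((int)heap.size() < k) heap.push(d2);
              else if (d2 < heap.top()) { heap.pop(); heap.push(d2); }
            }
          }
        }
      }
      // all unvisited points lie beyond `ring * cell` from the query cell
      double guaranteed = (double)ring * cell;
      if ((int)heap.size() >= std::min(k, n - 1) &&
          std::sqrt(heap.top()) <= guaranteed)
        break;
      ++ring;
      if (ring > 1 + (int)(std::max({maxx - minx, maxy - miny, maxz - minz}) /
                           cell))
        break;  // scanned the whole extent
    }
    double s = 0.0;
    int m = heap.size();
    while (!heap.empty()) { s += std::sqrt(heap.top()); heap.pop(); }
    out[i] = (m > 0) ? s / m : 0.0;
  }
  return out;
}
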