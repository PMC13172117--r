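#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 90th percentile with linear interpolation (type-7): position 0.9*(n-1)
// between sorted order statistics.
static double p90_sorted(std::vector<double> &buf) {
  const int n = static_cast<int>(buf.size());
  if (n == 1) return buf[0];
  std::sort(buf.begin(), buf.end());
  const double pos = 0.9 * (n - 1);
  const int lo = static_cast<int>(std::floor(pos));
  const double frac = pos - lo;
  if (lo + 1 >= n) return buf[n - 1];
  return buf[lo] + frac * (buf[lo + 1] - buf[lo]);
}

// Multi-scale sliding-window probability map over one 3-D volume.
// Windows are 2-D, in-plane, stride 1, fully inside slice bounds; a window
// is valid when at least min_mask_fraction of its voxels are in the mask.
// Its feature is the p90 of the in-mask ADC values it contains, its
// probability the logistic model evaluated on that feature. Aggregation:
// cover = each in-mask voxel takes the max over all valid windows covering
// it; center = max over the valid windows centred on it.
// [[Rcpp::export]]
List cpp_sliding_window_map(NumericVector adc, LogicalVector mask,
                            IntegerVector grid_dim, IntegerVector window_sizes,
                            double min_mask_fraction, double intercept,
                            double slope, double std_mean, double std_sd,
                            bool cover) {
  const int nx = grid_dim[0], ny = grid_dim[1], nz = grid_dim[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector prob(nvox, NA_REAL);
  LogicalVector valid(nvox, false);

  std::vector<double> buf;
  buf.reserve(512);
  std::vector<int> integ((nx + 1) * (ny + 1), 0);
  const int stride = nx + 1;

  for (int z = 0; z < nz; ++z) {
    const R_xlen_t off = static_cast<R_xlen_t>(z) * nx * ny;
    // integral image of the mask slice: integ[y*stride + x] = count over
    // rows < y, cols < x (x fastest, matching R's column-major layout)
    for (int x = 0; x <= nx; ++x) integ[x] = 0;
    bool any_mask = false;
    for (int y = 1; y <= ny; ++y) {
      int rowsum = 0;
      integ[y * stride] = 0;
      for (int x = 1; x <= nx; ++x) {
        const bool m = mask[off + static_cast<R_xlen_t>(y - 1) * nx + (x - 1)];
        rowsum += m ? 1 : 0;
        any_mask = any_mask || m;
        integ[y * stride + x] = integ[(y - 1) * stride + x] + rowsum;
      }
    }
    if (!any_mask) continue;

    for (int wi = 0; wi < window_sizes.size(); ++wi) {
      const int w = window_sizes[wi];
      if (w > nx || w > ny) continue;
      const double need = min_mask_fraction * w * w - 1e-9;
      for (int y0 = 0; y0 + w <= ny; ++y0) {
        for (int x0 = 0; x0 + w <= nx; ++x0) {
          const int cnt = integ[(y0 + w) * stride + (x0 + w)] -
                          integ[y0 * stride + (x0 + w)] -
                          integ[(y0 + w) * stride + x0] +
                          integ[y0 * stride + x0];
          if (cnt < 1 || cnt < need) continue;
          buf.clear();
          for (int y = y0; y < y0 + w; ++y) {
            const R_xlen_t row = off + static_cast<R_xlen_t>(y) * nx;
            for (int x = x0; x < x0 + w; ++x) {
              if (mask[row + x]) buf.push_back(adc[row + x]);
            }
          }
          const double feat = (p90_sorted(buf) - std_mean) / std_sd;
          const double p = 1.0 / (1.0 + std::exp(-(intercept + slope * feat)));
          if (cover) {
            for (int y = y0; y < y0 + w; ++y) {
              const R_xlen_t row = off + static_cast<R_xlen_t>(y) * nx;
              for (int x = x0; x < x0 + w; ++x) {
                const R_xlen_t idx = row + x;
                if (!mask[idx]) continue;
                if (!valid[idx] || p > prob[idx]) {
                  prob[idx] = p;
                  valid[idx] = true;
                }
              }
            }
          } else {
            const R_xlen_t idx =
                off + static_cast<R_xlen_t>(y0 + w / 2) * nx + (x0 + w / 2);
            if (mask[idx] && (!valid[idx] || p > prob[idx])) {
              prob[idx] = p;
              valid[idx] = true;
            }
          }
        }
      }
    }
  }
  return List::create(Named("prob") = prob, Named("valid") = valid);
}
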