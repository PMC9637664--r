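#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Slice-wise 2D mask-aware median filter.
// For each in-mask voxel, takes the median of the in-mask values inside a
// size x size in-plane neighborhood; out-of-mask neighbors are excluded so
// extra-pulmonary zeros never bleed into the lung. Borders are handled by
// index reflection. Even-count neighborhoods use the mean of the two middle
// order statistics, matching R's median(). Out-of-mask voxels return 0.
// [[Rcpp::export(name = ".mask_median_filter_cpp")]]
NumericVector mask_median_filter_cpp(NumericVector vol, LogicalVector mask,
                                     IntegerVector dims, int size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int half = size / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve(size * size);
  for (int z = 0; z < nz; ++z) {
    const R_xlen_t zoff = (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t c = zoff + (R_xlen_t)y * nx + x;
        if (!mask[c]) { out[c] = 0.0; continue; }
        buf.clear();
        for (int dy = -half; dy <= half; ++dy) {
          int yy = y + dy;
          if (yy < 0) yy = -yy;                    // reflect
          if (yy >= ny) yy = 2 * ny - 2 - yy;
          for (int dx = -half; dx <= half; ++dx) {
            int xx = x + dx;
            if (xx < 0) xx = -xx;
            if (xx >= nx) xx = 2 * nx - 2 - xx;
            const R_xlen_t n = zoff + (R_xlen_t)yy * nx + xx;
            if (mask[n]) buf.push_back(vol[n]);
          }
        }
        const size_t m = buf.size();
        if (m == 0) { out[c] = vol[c]; continue; }
        const size_t mid = m / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = (med + lo) / 2.0;
        }
        out[c] = med;
      }
    }
  }
  return out;
}
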