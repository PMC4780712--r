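#include "cbct_common.h"
using namespace Rcpp;

// Voxel-driven distance-weighted backprojection over a circular orbit.
// `filt` holds ramp-filtered, cosine-weighted projections sampled on the
// virtual detector through the isocenter (pitch_iso). The caller applies
// the overall pi / n_views scan weighting.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector filt, int det_rows, int det_cols,
                                  double pitch_iso, double sad,
                                  NumericVector angles, int nx, int ny, int nz,
                                  double voxel, double ox, double oy, double oz) {
  const int nv = angles.size();
  NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
  const double* pf = filt.begin();
  double* pv = vol.begin();

  for (int iv = 0; iv < nv; ++iv) {
    const double cb = std::cos(angles[iv]);
    const double sb = std::sin(angles[iv]);
    const double* view = pf + static_cast<R_xlen_t>(det_rows) * det_cols * iv;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = (iz + 0.5 - nz / 2.0) * voxel + oz;
      for (int iy = 0; iy < ny; ++iy) {
        const double y = (iy + 0.5 - ny / 2.0) * voxel + oy;
        R_xlen_t base = static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
        for (int ix = 0; ix < nx; ++ix) {
          const double x = (ix + 0.5 - nx / 2.0) * voxel + ox;
          const double L = sad - (x * cb + y * sb);
          if (L < 1e-6) continue;
          const double mag = sad / L;
          const double u = (-x * sb + y * cb) * mag;
          const double v = z * mag;
          const double fc = u / pitch_iso + det_cols / 2.0 - 0.5;
          const double fr = v / pitch_iso + det_rows / 2.0 - 0.5;
          const int c0 = static_cast<int>(std::floor(fc));
          const int r0 = static_cast<int>(std::floor(fr));
          if (c0 < 0 || c0 + 1 >= det_cols || r0 < 0 || r0 + 1 >= det_rows)
            continue;
          const double wc = fc - c0, wr = fr - r0;
          const double* col0 = view + static_cast<R_xlen_t>(det_rows) * c0;
          const double* col1 = col0 + det_rows;
          const double val = (1 - wr) * ((1 - wc) * col0[r0] + wc * col1[r0]) +
                             wr * ((1 - wc) * col0[r0 + 1] + wc * col1[r0 + 1]);
          pv[base + ix] += mag * mag * val;
        }
      }
    }
  }
  return vol;
}
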