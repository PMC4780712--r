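#include "cbct_common.h"
using namespace Rcpp;

// chord length of segment src + t*dir, t in [0, tmax], inside cylinder i
static double clipped_chord(const Cyl& c, const Vec3& src, const Vec3& dir,
                            double tmax) {
  double t0, t1;
  if (!cyl_interval(c, src, dir, t0, t1)) return 0.0;
  t0 = std::max(t0, 0.0);
  t1 = std::min(t1, tmax);
  return (t1 > t0) ? (t1 - t0) : 0.0;
}

// Per-cylinder raw and net (innermost-wins) intersection lengths of the
// segment src -> dst.
// [[Rcpp::export]]
List cpp_ray_lengths(NumericMatrix cyl_m, NumericVector src, NumericVector dst) {
  std::vector<Cyl> cyls = parse_cylinders(cyl_m);
  Vec3 s = v3(src[0], src[1], src[2]);
  Vec3 d = v3(dst[0] - src[0], dst[1] - src[1], dst[2] - src[2]);
  double tmax = std::sqrt(dot(d, d));
  if (tmax < 1e-15) {
    NumericVector z(cyls.size());
    return List::create(_["raw"] = z, _["net"] = clone(z));
  }
  Vec3 u = v3(d.x / tmax, d.y / tmax, d.z / tmax);
  int n = cyls.size();
  NumericVector raw(n), net(n);
  for (int i = 0; i < n; ++i) raw[i] = clipped_chord(cyls[i], s, u, tmax);
  for (int i = 0; i < n; ++i) net[i] = raw[i];
  for (int i = 0; i < n; ++i)
    if (cyls[i].parent >= 0) net[cyls[i].parent] -= raw[i];
  for (int i = 0; i < n; ++i)
    if (net[i] < 0) net[i] = 0;
  return List::create(_["raw"] = raw, _["net"] = net);
}

// Analytic Beer-Lambert projector.
//
// i0 is the open-field value of a fully illuminated pixel; pixels partially
// covered by the collimated band are scaled by their axial coverage
// fraction. mu_tot is (ne x nmat) in 1/cm. det_mode 1 applies the
// scintillator absorption efficiency 1 - exp(-mu_csi * t / cos(theta)).
// [[Rcpp::export]]
NumericVector cpp_project_primary(double sad, double sdd, int det_rows,
                                  int det_cols, double pitch,
                                  NumericVector angles, double v_lo,
                                  double v_hi, NumericMatrix cyl_m,
                                  NumericMatrix mu_tot, double e0, double de,
                                  NumericVector spec_e, NumericVector spec_w,
                                  int det_mode, NumericVector csi_tot,
                                  double csi_t, double i0) {
  std::vector<Cyl> cyls = parse_cylinders(cyl_m);
  const int ne = mu_tot.nrow();
  const int nmat = mu_tot.ncol();
  const int nv = angles.size();
  const int nsp = spec_e.size();
  NumericVector out(static_cast<R_xlen_t>(det_rows) * det_cols * nv);
  const int ncyl = cyls.size();
  std::vector<double> raw(ncyl), lm(nmat);

  // pre-tabulated spectral attenuation per material per spectrum bin
  std::vector<double> mu_sp(nsp * nmat), csi_sp(nsp, 0.0);
  for (int m = 0; m < nmat; ++m)
    for (int k = 0; k < nsp; ++k)
      mu_sp[m * nsp + k] = grid_interp(&mu_tot(0, m), ne, e0, de, spec_e[k]);
  if (det_mode == 1)
    for (int k = 0; k < nsp; ++k)
      csi_sp[k] = grid_interp(&csi_tot[0], ne, e0, de, spec_e[k]);

  for (int iv = 0; iv < nv; ++iv) {
    ViewFrame fr = view_frame(sad, sdd, angles[iv]);
    for (int r = 0; r < det_rows; ++r) {
      double vc = (r + 0.5 - det_rows / 2.0) * pitch;
      double frac = (std::min(vc + pitch / 2.0, v_hi) -
                     std::max(vc - pitch / 2.0, v_lo)) / pitch;
      if (frac <= 0.0) continue;
      if (frac > 1.0) frac = 1.0;
      for (int c = 0; c < det_cols; ++c) {
        double uc = (c + 0.5 - det_cols / 2.0) * pitch;
        Vec3 p = fr.dcenter + uc * fr.eu + vc * fr.ev;
        Vec3 d = p - fr.src;
        double tmax = std::sqrt(dot(d, d));
        Vec3 u = v3(d.x / tmax, d.y / tmax, d.z / tmax);
        for (int m = 0; m < nmat; ++m) lm[m] = 0.0;
        for (int i = 0; i < ncyl; ++i) raw[i] = clipped_chord(cyls[i], fr.src, u, tmax);
        for (int i = 0; i < ncyl; ++i) {
          double net = raw[i];
          for (int j = 0; j < ncyl; ++j)
            if (cyls[j].parent == i) net -= raw[j];
          if (net > 0.0) lm[cyls[i].mat] += net;
        }
        double cosi = dot(u, fr.nrm);
        double T = 0.0;
        for (int k = 0; k < nsp; ++k) {
          double a = 0.0;
          for (int m = 0; m < nmat; ++m)
            if (lm[m] > 0.0) a += mu_sp[m * nsp + k] * lm[m];
          double eff = (det_mode == 1)
                           ? 1.0 - std::exp(-csi_sp[k] * csi_t / std::max(cosi, 0.05))
                           : 1.0;
          T += spec_w[k] * eff * std::exp(-a);
        }
        out[r + static_cast<R_xlen_t>(det_rows) * (c + static_cast<R_xlen_t>(det_cols) * iv)] =
            i0 * frac * T;
      }
    }
  }
  return out;
}
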