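#include "cbct_common.h"
using namespace Rcpp;

// Klein-Nishina sampling of the Compton energy ratio eps = E'/E for a
// free electron at rest (standard composition/rejection scheme).
static double sample_kn_eps(double E_keV, CbctRng& rng, double& cos_theta) {
  const double k = E_keV / 510.99895;
  const double eps0 = 1.0 / (1.0 + 2.0 * k);
  const double a1 = std::log(1.0 / eps0);
  const double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, t, g;
  do {
    if (rng.unif() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * rng.unif());
    } else {
      double u = rng.unif();
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * u);
    }
    t = (1.0 - eps) / (k * eps);
    double sin2 = t * (2.0 - t);
    g = 1.0 - eps * sin2 / (1.0 + eps * eps);
  } while (rng.unif() > g);
  cos_theta = 1.0 - t;
  return eps;
}

// Thomson angular sampling, pdf(mu) ~ (1 + mu^2), mu = cos(theta)
static double sample_thomson_mu(CbctRng& rng) {
  double mu;
  do {
    mu = 2.0 * rng.unif() - 1.0;
  } while (2.0 * rng.unif() > 1.0 + mu * mu);
  return mu;
}

static Vec3 rotate_direction(const Vec3& d, double cos_theta, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - cos_theta * cos_theta));
  Vec3 a = (std::fabs(d.x) < 0.9) ? v3(1, 0, 0) : v3(0, 1, 0);
  Vec3 t1 = normalize(cross(d, a));
  Vec3 t2 = cross(d, t1);
  Vec3 nd = cos_theta * d + (st * std::cos(phi)) * t1 + (st * std::sin(phi)) * t2;
  return normalize(nd);
}

// [[Rcpp::export]]
NumericVector cpp_sample_compton(double energy_keV, int n, int seed) {
  CbctRng rng(view_stream_seed(seed, 0));
  NumericVector out(n);
  double ct;
  for (int i = 0; i < n; ++i) out[i] = energy_keV * sample_kn_eps(energy_keV, rng, ct);
  return out;
}

// Monte Carlo transport of one projection view.
//
// Geometry in cm; energies in keV on a uniform grid (e0, de, ne).
// mu tables are (ne x nmat) linear attenuation coefficients in 1/cm.
// det_mode: 0 = ideal photon counter, 1 = scintillator slab.
// classify_mode: 0 = primary iff no phantom interaction,
//                1 = primary iff no phantom nor detector interaction.
// [[Rcpp::export]]
List cpp_simulate_view(double sad, double sdd, int det_rows, int det_cols,
                       double pitch, double angle, double v_lo, double v_hi,
                       NumericMatrix cyl_m, NumericMatrix mu_pe,
                       NumericMatrix mu_co, NumericMatrix mu_ra, double e0,
                       double de, NumericVector spec_e, NumericVector spec_w,
                       int det_mode, NumericVector csi_pe, NumericVector csi_co,
                       NumericVector csi_ra, double csi_t, double n_photons,
                       int seed, int view_index, bool energy_weighted,
                       int classify_mode, int record_cap) {
  const std::vector<Cyl> cyls = parse_cylinders(cyl_m);
  const int ne = mu_pe.nrow();
  const int nmat = mu_pe.ncol();
  const double E_CUT = 10.0;
  const int MAX_INTERACTIONS = 10000;
  const ViewFrame fr = view_frame(sad, sdd, angle);
  const double det_w = det_cols * pitch;

  // spectrum cdf
  const int nsp = spec_e.size();
  std::vector<double> cdf(nsp);
  double acc = 0.0;
  for (int i = 0; i < nsp; ++i) {
    acc += spec_w[i];
    cdf[i] = acc;
  }
  for (int i = 0; i < nsp; ++i) cdf[i] /= acc;

  // majorant over materials actually present
  std::vector<double> mu_tot(ne * nmat), majorant(ne, 0.0);
  for (int m = 0; m < nmat; ++m)
    for (int i = 0; i < ne; ++i) {
      double t = mu_pe(i, m) + mu_co(i, m) + mu_ra(i, m);
      mu_tot[m * ne + i] = t;
      if (t > majorant[i]) majorant[i] = t;
    }
  std::vector<double> csi_tot(det_mode == 1 ? ne : 0);
  for (size_t i = 0; i < csi_tot.size(); ++i)
    csi_tot[i] = csi_pe[i] + csi_co[i] + csi_ra[i];

  NumericMatrix tal_total(det_rows, det_cols), tal_primary(det_rows, det_cols),
      tal_scatter(det_rows, det_cols);
  NumericMatrix records(record_cap > 0 ? record_cap : 1, 7);
  int n_records = 0, n_runaway = 0;
  long long n_detected = 0;

  CbctRng rng(view_stream_seed(seed, view_index));
  const long long nph = static_cast<long long>(n_photons);

  for (long long ip = 0; ip < nph; ++ip) {
    // sample energy
    double u = rng.unif();
    int lo = 0, hi = nsp - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u)
        lo = mid + 1;
      else
        hi = mid;
    }
    double E = spec_e[lo];

    // aim at a uniform point in the illuminated detector band
    double ut = (rng.unif() - 0.5) * det_w;
    double vt = v_lo + rng.unif() * (v_hi - v_lo);
    Vec3 target = fr.dcenter + ut * fr.eu + vt * fr.ev;
    Vec3 pos = fr.src;
    Vec3 dir = normalize(target - fr.src);

    int ncp = 0, nrp = 0, ncd = 0, nrd = 0;
    bool alive = true;

    if (!cyls.empty()) {
      // transport within the body cylinder (convex); air gaps are vacuum
      double t0, t1;
      bool hit = cyl_interval(cyls[0], pos, dir, t0, t1);
      if (hit && t1 > 0.0) {
        if (t0 > 0.0) pos = pos + t0 * dir;  // advance to the entry point
        int n_int = 0;
        while (alive) {
          // segment bookkeeping: the exit distance and the energy-dependent
          // majorant stay valid until the direction or energy changes
          double t0s, t1s;
          if (!cyl_interval(cyls[0], pos, dir, t0s, t1s) || t1s <= 1e-12) break;
          double remaining = t1s;
          double mu_maj = grid_interp(majorant.data(), ne, e0, de, E);
          bool redirected = false;
          while (alive && !redirected) {
            double s = -std::log(rng.unif()) / mu_maj;
            if (s >= remaining) {
              pos = pos + (remaining + 1e-9) * dir;
              goto leaves_phantom;
            }
            pos = pos + s * dir;
            remaining -= s;
            int ic = material_at(cyls, pos);
            if (ic >= 0) {
              int m = cyls[ic].mat;
              double pe = grid_interp(&mu_pe(0, m), ne, e0, de, E);
              double co = grid_interp(&mu_co(0, m), ne, e0, de, E);
              double ra = grid_interp(&mu_ra(0, m), ne, e0, de, E);
              double x = rng.unif() * mu_maj;
              if (x < pe) {
                alive = false;  // photoelectric absorption
              } else if (x < pe + co) {
                double ct;
                double eps = sample_kn_eps(E, rng, ct);
                E *= eps;
                dir = rotate_direction(dir, ct, 2.0 * M_PI * rng.unif());
                ++ncp;
                redirected = true;
                if (E < E_CUT) alive = false;
              } else if (x < pe + co + ra) {
                double mu = sample_thomson_mu(rng);
                dir = rotate_direction(dir, mu, 2.0 * M_PI * rng.unif());
                ++nrp;
                redirected = true;
              }  // else: null (Woodcock) collision
            }
            if (++n_int > MAX_INTERACTIONS) {
              ++n_runaway;
              alive = false;
            }
          }
        }
      leaves_phantom:;
      }
    }
    if (!alive) continue;

    // propagate to the detector plane
    double dn = dot(dir, fr.nrm);
    if (dn <= 1e-9) continue;
    double t = dot(fr.dcenter - pos, fr.nrm) / dn;
    if (t < 0.0) continue;
    Vec3 p = pos + t * dir;
    double uu = dot(p - fr.dcenter, fr.eu);
    double vv = p.z;
    int col = static_cast<int>(std::floor(uu / pitch + det_cols / 2.0));
    int row = static_cast<int>(std::floor(vv / pitch + det_rows / 2.0));
    if (row < 0 || row >= det_rows || col < 0 || col >= det_cols) continue;

    bool detected = false;
    if (det_mode == 0) {
      detected = true;
    } else {
      // simplified slab scintillator: 1D depth transport along the ray
      double cosi = dn;  // incidence cosine on the panel
      double depth = 0.0;
      bool going = true;
      while (going) {
        double mt = grid_interp(csi_tot.data(), ne, e0, de, E);
        double step = -std::log(rng.unif()) / mt;
        depth += step * cosi;
        if (depth >= csi_t) break;  // escapes the scintillator
        double pe = grid_interp(&csi_pe[0], ne, e0, de, E);
        double co = grid_interp(&csi_co[0], ne, e0, de, E);
        double x = rng.unif() * mt;
        if (x < pe) {
          detected = true;
          going = false;
        } else if (x < pe + co) {
          double ct;
          E *= sample_kn_eps(E, rng, ct);
          ++ncd;
          if (E < E_CUT) {
            detected = true;  // locally absorbed
            going = false;
          }
        } else {
          ++nrd;
        }
      }
    }
    if (!detected) continue;

    bool primary = (classify_mode == 0) ? (ncp + nrp == 0)
                                        : (ncp + nrp + ncd + nrd == 0);
    double w = energy_weighted ? E : 1.0;
    tal_total(row, col) += w;
    if (primary)
      tal_primary(row, col) += w;
    else
      tal_scatter(row, col) += w;
    ++n_detected;

    if (record_cap > 0 && n_records < record_cap) {
      records(n_records, 0) = row + 1;
      records(n_records, 1) = col + 1;
      records(n_records, 2) = E;
      records(n_records, 3) = ncp;
      records(n_records, 4) = nrp;
      records(n_records, 5) = ncd;
      records(n_records, 6) = nrd;
      ++n_records;
    }
  }

  return List::create(
      _["total"] = tal_total, _["primary"] = tal_primary,
      _["scatter"] = tal_scatter, _["n_detected"] = static_cast<double>(n_detected),
      _["n_runaway"] = n_runaway, _["records"] = records,
      _["n_records"] = n_records);
}
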