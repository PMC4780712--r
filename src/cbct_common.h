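#ifndef CBCT_COMMON_H
#define CBCT_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

// Deterministic, platform-stable RNG: splitmix64-seeded mt19937_64 with
// manual conversion to doubles (std::uniform_real_distribution is not
// bit-stable across standard library implementations).
struct CbctRng {
  std::mt19937_64 gen;
  explicit CbctRng(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    gen.seed(z);
  }
  // open interval (0, 1)
  double unif() { return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

inline uint64_t view_stream_seed(int master_seed, int view_index) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(master_seed)) << 32) ^
         (0x5deece66dULL * static_cast<uint64_t>(view_index + 1));
}

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 normalize(Vec3 a) {
  double n = std::sqrt(dot(a, a));
  return v3(a.x / n, a.y / n, a.z / n);
}
inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// linear interpolation on a uniform energy grid, clamped at the ends
inline double grid_interp(const double* tab, int ne, double e0, double de, double E) {
  double x = (E - e0) / de;
  if (x <= 0.0) return tab[0];
  if (x >= ne - 1) return tab[ne - 1];
  int i = static_cast<int>(x);
  double f = x - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// Finite cylinder (axis || z): columns cx, cy, r, zmin, zmax, mat, depth, parent
struct Cyl {
  double cx, cy, r, zmin, zmax;
  int mat, depth, parent;
};

inline bool cyl_contains(const Cyl& c, const Vec3& p) {
  if (p.z < c.zmin || p.z > c.zmax) return false;
  double dx = p.x - c.cx, dy = p.y - c.cy;
  return dx * dx + dy * dy <= c.r * c.r;
}

// Intersection interval [t0, t1] of ray p + t d with the finite cylinder.
// Returns false when the ray misses.
inline bool cyl_interval(const Cyl& c, const Vec3& p, const Vec3& d,
                         double& t0, double& t1) {
  const double INF = 1e30;
  double ta = -INF, tb = INF;
  double a = d.x * d.x + d.y * d.y;
  double px = p.x - c.cx, py = p.y - c.cy;
  if (a > 1e-16) {
    double b = 2.0 * (px * d.x + py * d.y);
    double cc = px * px + py * py - c.r * c.r;
    double disc = b * b - 4.0 * a * cc;
    if (disc < 0.0) return false;
    double sq = std::sqrt(disc);
    ta = (-b - sq) / (2.0 * a);
    tb = (-b + sq) / (2.0 * a);
  } else {
    if (px * px + py * py > c.r * c.r) return false;
  }
  // z-slab
  double tz0, tz1;
  if (std::fabs(d.z) > 1e-16) {
    tz0 = (c.zmin - p.z) / d.z;
    tz1 = (c.zmax - p.z) / d.z;
    if (tz0 > tz1) std::swap(tz0, tz1);
  } else {
    if (p.z < c.zmin || p.z > c.zmax) return false;
    tz0 = -INF;
    tz1 = INF;
  }
  t0 = std::max(ta, tz0);
  t1 = std::min(tb, tz1);
  return t1 > t0;
}

inline std::vector<Cyl> parse_cylinders(const Rcpp::NumericMatrix& m) {
  std::vector<Cyl> out;
  out.reserve(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    Cyl c;
    c.cx = m(i, 0);
    c.cy = m(i, 1);
    c.r = m(i, 2);
    c.zmin = m(i, 3);
    c.zmax = m(i, 4);
    c.mat = static_cast<int>(m(i, 5));
    c.depth = static_cast<int>(m(i, 6));
    c.parent = static_cast<int>(m(i, 7));
    out.push_back(c);
  }
  return out;
}

// deepest cylinder containing p, or -1
inline int material_at(const std::vector<Cyl>& cyls, const Vec3& p) {
  int best = -1, bestd = -1;
  for (size_t i = 0; i < cyls.size(); ++i) {
    if (cyls[i].depth > bestd && cyl_contains(cyls[i], p)) {
      best = static_cast<int>(i);
      bestd = cyls[i].depth;
    }
  }
  return best;
}

struct ViewFrame {
  Vec3 src, dcenter, eu, ev, nrm;
};

inline ViewFrame view_frame(double sad, double sdd, double angle) {
  ViewFrame f;
  double cb = std::cos(angle), sb = std::sin(angle);
  f.src = v3(sad * cb, sad * sb, 0.0);
  f.dcenter = v3(-(sdd - sad) * cb, -(sdd - sad) * sb, 0.0);
  f.eu = v3(-sb, cb, 0.0);
  f.ev = v3(0.0, 0.0, 1.0);
  f.nrm = v3(-cb, -sb, 0.0);  // from source towards detector
  return f;
}

#endif
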