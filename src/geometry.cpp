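// Geometric kernels for covalent-loop piercing: centroid-fan triangulation of
// the closed loop, signed segment-triangle crossings (Moller-Trumbore), and a
// per-frame crossing trace for trajectories. Orientation convention: triangle
// normals follow the loop's vertex order (Newell area vector), so crossing
// signs are consistent along a trajectory while the loop stays connected.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }

// one round of Chaikin corner-cutting on a closed polygon
static std::vector<Vec3> chaikin_closed(const std::vector<Vec3>& p) {
  size_t n = p.size();
  std::vector<Vec3> out;
  out.reserve(2 * n);
  for (size_t i = 0; i < n; ++i) {
    const Vec3& a = p[i];
    const Vec3& b = p[(i + 1) % n];
    out.push_back(Vec3{0.75 * a.x + 0.25 * b.x, 0.75 * a.y + 0.25 * b.y,
                       0.75 * a.z + 0.25 * b.z});
    out.push_back(Vec3{0.25 * a.x + 0.75 * b.x, 0.25 * a.y + 0.75 * b.y,
                       0.25 * a.z + 0.75 * b.z});
  }
  return out;
}

struct Hit {
  int seg;     // 0-based segment index along the chain polyline
  int sign;    // +1 along fan orientation, -1 against
  Vec3 p;      // intersection point
};

// signed crossings of one segment with one triangle (Moller-Trumbore)
static bool seg_tri(const Vec3& o, const Vec3& d, const Vec3& v0, const Vec3& v1,
                    const Vec3& v2, double& t, int& sgn, Vec3& point) {
  Vec3 e1 = vsub(v1, v0), e2 = vsub(v2, v0);
  Vec3 pv = vcross(d, e2);
  double det = vdot(e1, pv);
  if (std::fabs(det) < 1e-14) return false;  // parallel (jitter upstream)
  double inv = 1.0 / det;
  Vec3 tv = vsub(o, v0);
  double u = vdot(tv, pv) * inv;
  if (u < 0.0 || u > 1.0) return false;
  Vec3 qv = vcross(tv, e1);
  double v = vdot(d, qv) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  t = vdot(e2, qv) * inv;
  if (t < 0.0 || t >= 1.0) return false;  // half-open: no double count at joints
  // +1 when the segment runs along the triangle normal (right-hand rule on
  // the vertex order): det = e1.(d x e2) is negative in that case
  sgn = det < 0 ? 1 : -1;
  point = Vec3{o.x + t * d.x, o.y + t * d.y, o.z + t * d.z};
  return true;
}

// all signed crossings of a polyline with the centroid fan of a closed curve;
// same-sign hits closer than tol are shared-edge double counts and are merged
static std::vector<Hit> fan_crossings(const std::vector<Vec3>& curve,
                                      const std::vector<Vec3>& chain,
                                      double tol) {
  size_t L = curve.size();
  Vec3 cen{0, 0, 0};
  for (size_t i = 0; i < L; ++i) {
    cen.x += curve[i].x;
    cen.y += curve[i].y;
    cen.z += curve[i].z;
  }
  cen.x /= L;
  cen.y /= L;
  cen.z /= L;

  std::vector<Hit> hits;
  for (size_t s = 0; s + 1 < chain.size(); ++s) {
    const Vec3& o = chain[s];
    Vec3 d = vsub(chain[s + 1], chain[s]);
    std::vector<Hit> seg_hits;
    for (size_t i = 0; i < L; ++i) {
      double t;
      int sgn;
      Vec3 pt;
      if (seg_tri(o, d, curve[i], curve[(i + 1) % L], cen, t, sgn, pt)) {
        bool dup = false;
        for (size_t h = 0; h < seg_hits.size(); ++h)
          if (seg_hits[h].sign == sgn && vnorm(vsub(seg_hits[h].p, pt)) < tol) {
            dup = true;
            break;
          }
        if (!dup) seg_hits.push_back(Hit{(int)s, sgn, pt});
      }
    }
    for (size_t h = 0; h < seg_hits.size(); ++h) hits.push_back(seg_hits[h]);
  }
  return hits;
}

// Newell area vector of a closed polygon (oriented; |A| = area for planar)
static Vec3 newell(const std::vector<Vec3>& p) {
  Vec3 a{0, 0, 0};
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    const Vec3& u = p[i];
    const Vec3& v = p[(i + 1) % n];
    a.x += (u.y - v.y) * (u.z + v.z);
    a.y += (u.z - v.z) * (u.x + v.x);
    a.z += (u.x - v.x) * (u.y + v.y);
  }
  a.x *= 0.5;
  a.y *= 0.5;
  a.z *= 0.5;
  return a;
}

static std::vector<Vec3> to_vecs(const NumericMatrix& m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3{m(i, 0), m(i, 1), m(i, 2)};
  return v;
}

// [[Rcpp::export]]
DataFrame cpp_fan_crossings(NumericMatrix curve, NumericMatrix chain,
                            int smooth_rounds, double merge_tol) {
  std::vector<Vec3> c = to_vecs(curve);
  for (int r = 0; r < smooth_rounds; ++r) c = chaikin_closed(c);
  std::vector<Hit> hits = fan_crossings(c, to_vecs(chain), merge_tol);
  int nh = hits.size();
  IntegerVector seg(nh), sgn(nh);
  NumericVector px(nh), py(nh), pz(nh);
  for (int i = 0; i < nh; ++i) {
    seg[i] = hits[i].seg + 1;
    sgn[i] = hits[i].sign;
    px[i] = hits[i].p.x;
    py[i] = hits[i].p.y;
    pz[i] = hits[i].p.z;
  }
  return DataFrame::create(_["segment"] = seg, _["sign"] = sgn, _["x"] = px,
                           _["y"] = py, _["z"] = pz);
}

// [[Rcpp::export]]
NumericMatrix cpp_chaikin(NumericMatrix curve, int rounds) {
  std::vector<Vec3> c = to_vecs(curve);
  for (int r = 0; r < rounds; ++r) c = chaikin_closed(c);
  NumericMatrix out(c.size(), 3);
  for (size_t i = 0; i < c.size(); ++i) {
    out(i, 0) = c[i].x;
    out(i, 1) = c[i].y;
    out(i, 2) = c[i].z;
  }
  return out;
}

// Per-frame crossing state of one tail against the instantaneous loop surface.
// frames: F x 3n flattened coords; loop_idx / tail_idx: 1-based residue
// indices, tail in walk order from the loop attachment outward (terminal
// residue last). A fixed small deterministic jitter is added to tail
// coordinates to avoid exact-coplanarity degeneracies.
// Returns F x 7: net, n_cross, term_side, tail_mean_side, first_pos, last_pos,
// degenerate (loop area below area_min).
// [[Rcpp::export]]
NumericMatrix cpp_crossing_trace(NumericMatrix frames, int n_res,
                                 IntegerVector loop_idx, IntegerVector tail_idx,
                                 int smooth_rounds, double merge_tol,
                                 double area_min, double jitter) {
  int F = frames.nrow();
  int nl = loop_idx.size(), nt = tail_idx.size();
  NumericMatrix out(F, 7);
  colnames(out) = CharacterVector::create("net", "n_cross", "term_side",
                                          "tail_mean_side", "first_pos",
                                          "last_pos", "degenerate");
  for (int f = 0; f < F; ++f) {
    std::vector<Vec3> loop(nl), tail(nt);
    for (int i = 0; i < nl; ++i) {
      int r = loop_idx[i] - 1;
      loop[i] = Vec3{frames(f, 3 * r), frames(f, 3 * r + 1), frames(f, 3 * r + 2)};
    }
    for (int i = 0; i < nt; ++i) {
      int r = tail_idx[i] - 1;
      tail[i] = Vec3{frames(f, 3 * r) + jitter * std::sin(137.0 * (i + 1)),
                     frames(f, 3 * r + 1) + jitter * std::cos(41.0 * (i + 1)),
                     frames(f, 3 * r + 2) + jitter * std::sin(89.0 * (i + 1))};
    }
    std::vector<Vec3> sm = loop;
    for (int r = 0; r < smooth_rounds; ++r) sm = chaikin_closed(sm);
    Vec3 area = newell(sm);
    double a = vnorm(area);
    if (a < area_min) {
      out(f, 6) = 1.0;
      out(f, 0) = NA_REAL;
      out(f, 1) = NA_REAL;
      out(f, 2) = NA_REAL;
      out(f, 3) = NA_REAL;
      out(f, 4) = NA_REAL;
      out(f, 5) = NA_REAL;
      continue;
    }
    Vec3 nh{area.x / a, area.y / a, area.z / a};
    Vec3 cen{0, 0, 0};
    for (int i = 0; i < nl; ++i) {
      cen.x += loop[i].x;
      cen.y += loop[i].y;
      cen.z += loop[i].z;
    }
    cen.x /= nl;
    cen.y /= nl;
    cen.z /= nl;

    std::vector<Hit> hits = fan_crossings(sm, tail, merge_tol);
    int net = 0;
    int first_pos = NA_INTEGER, last_pos = NA_INTEGER;
    for (size_t h = 0; h < hits.size(); ++h) {
      net += hits[h].sign;
      if (first_pos == NA_INTEGER || hits[h].seg + 1 < first_pos)
        first_pos = hits[h].seg + 1;
      if (last_pos == NA_INTEGER || hits[h].seg + 1 > last_pos)
        last_pos = hits[h].seg + 1;
    }
    double term_side = vdot(vsub(tail[nt - 1], cen), nh);
    double mean_side = 0.0;
    for (int i = 0; i < nt; ++i) mean_side += vdot(vsub(tail[i], cen), nh);
    mean_side /= nt;

    out(f, 0) = net;
    out(f, 1) = (double)hits.size();
    out(f, 2) = term_side;
    out(f, 3) = mean_side;
    out(f, 4) = first_pos == NA_INTEGER ? NA_REAL : (double)first_pos;
    out(f, 5) = last_pos == NA_INTEGER ? NA_REAL : (double)last_pos;
    out(f, 6) = 0.0;
  }
  return out;
}
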