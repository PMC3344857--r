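#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Average crossing number of polyline pairs via the analytic closed form
// for the Gauss double integral over a pair of straight segments
// (Klenin-Langowski construction).  The Gauss integral runs over ordered
// segment pairs, so each unordered pair contributes |Omega|/(2*pi), Omega
// the solid-angle sum
//   asin(n1.n2) + asin(n2.n3) + asin(n3.n4) + asin(n4.n1)
// with n1..n4 the unit normals of the tetrahedron spanned by the four
// endpoints.  Near-degenerate pairs (collinear endpoint triples) are
// resolved by recursive bisection of both segments.

namespace {

struct V3 {
  double x, y, z;
  V3 operator-(const V3& o) const { return {x-o.x, y-o.y, z-o.z}; }
  V3 operator+(const V3& o) const { return {x+o.x, y+o.y, z+o.z}; }
  V3 operator*(double s) const { return {x*s, y*s, z*s}; }
};
inline V3 cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dot(const V3& a, const V3& b) {
  return a.x*b.x + a.y*b.y + a.z*b.z;
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

inline double casin(double x) {
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  return std::asin(x);
}

const double DEG_EPS = 1e-12;

// |Gauss integral| for segment p1->p2 against p3->p4, in solid-angle units
// (divide by 4*pi outside).  depth limits degenerate-pair subdivision.
double seg_pair_abs_omega(const V3& p1, const V3& p2,
                          const V3& p3, const V3& p4, int depth) {
  V3 r13 = p3 - p1, r14 = p4 - p1, r23 = p3 - p2, r24 = p4 - p2;
  V3 n1 = cross(r13, r14), n2 = cross(r14, r24),
     n3 = cross(r24, r23), n4 = cross(r23, r13);
  double m1 = norm(n1), m2 = norm(n2), m3 = norm(n3), m4 = norm(n4);
  double scale = std::max(std::max(norm(r13), norm(r14)),
                          std::max(norm(r23), norm(r24)));
  double tol = DEG_EPS * scale * scale;
  if (m1 < tol || m2 < tol || m3 < tol || m4 < tol) {
    // some endpoint triple is (nearly) collinear; the asin form breaks.
    V3 e1 = p2 - p1, e2 = p4 - p3, d3 = p3 - p1, d4 = p4 - p1;
    double vol = std::fabs(dot(cross(e1, d3), d4));
    if (vol < DEG_EPS * scale * scale * scale) {
      // coplanar pair: zero unless the segments properly cross in their
      // plane (limiting value: seen crossed from half of all directions).
      V3 n = cross(e1, e2);
      if (norm(n) < tol) return 0.0;  // parallel in-plane: measure zero
      double o1 = dot(n, cross(d3, e1)), o2 = dot(n, cross(d4, e1));
      V3 d23 = p2 - p3;
      double o3 = dot(n, cross(e2, d3 * -1.0)), o4 = dot(n, cross(e2, d23));
      if (o1 * o2 < 0 && o3 * o4 < 0) return 2.0 * M_PI;
      return 0.0;
    }
    // genuinely 3D but touching: isolate the contact by bisection
    if (depth <= 0) return 0.0;
    V3 q12 = (p1 + p2) * 0.5, q34 = (p3 + p4) * 0.5;
    return seg_pair_abs_omega(p1, q12, p3, q34, depth - 1)
         + seg_pair_abs_omega(p1, q12, q34, p4, depth - 1)
         + seg_pair_abs_omega(q12, p2, p3, q34, depth - 1)
         + seg_pair_abs_omega(q12, p2, q34, p4, depth - 1);
  }
  double om = casin(dot(n1, n2) / (m1 * m2))
            + casin(dot(n2, n3) / (m2 * m3))
            + casin(dot(n3, n4) / (m3 * m4))
            + casin(dot(n4, n1) / (m4 * m1));
  return std::fabs(om);
}

inline V3 row(const NumericMatrix& m, int i) {
  return {m(i,0), m(i,1), m(i,2)};
}

} // namespace

// [[Rcpp::export]]
double acn_segments_cpp(NumericMatrix a, NumericMatrix b, bool intrachain) {
  int na = a.nrow() - 1, nb = b.nrow() - 1;
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    V3 p1 = row(a, i), p2 = row(a, i + 1);
    int jstart = intrachain ? i + 2 : 0;  // skip self and adjacent pairs
    for (int j = jstart; j < nb; ++j) {
      V3 p3 = row(b, j), p4 = row(b, j + 1);
      total += seg_pair_abs_omega(p1, p2, p3, p4, 8);
    }
  }
  return total / (2.0 * M_PI);
}

// Single segment pair (exposed for oracle comparisons in tests).
// [[Rcpp::export]]
double acn_segment_pair_cpp(NumericVector p1, NumericVector p2,
                            NumericVector p3, NumericVector p4) {
  V3 a = {p1[0], p1[1], p1[2]}, b = {p2[0], p2[1], p2[2]};
  V3 c = {p3[0], p3[1], p3[2]}, d = {p4[0], p4[1], p4[2]};
  return seg_pair_abs_omega(a, b, c, d, 8) / (2.0 * M_PI);
}
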