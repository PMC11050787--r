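#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Signed distance from query points to an oriented triangle mesh.
// Sign is resolved with angle-weighted pseudonormals (Baerentzen & Aanaes),
// which is robust when the closest feature is an edge or a vertex.
// Ties between faces at exactly equal distance resolve to the smallest
// face index (strict < while scanning in order), so results are deterministic.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }
inline Vec3 vunit(const Vec3 &a) {
  double n = vnorm(a);
  return n > 0 ? vscale(a, 1.0 / n) : Vec3{0, 0, 0};
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
// region: 0,1,2 = vertices a,b,c; 3 = edge ab; 4 = edge ac; 5 = edge bc; 6 = face.
Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c,
                         int &region) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { region = 0; return a; }

  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { region = 1; return b; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    region = 3;
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }

  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { region = 2; return c; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    region = 4;
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    region = 5;
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }

  region = 6;
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

inline long long edge_key(int i, int j, int nv) {
  int lo = i < j ? i : j, hi = i < j ? j : i;
  return (long long)lo * (long long)nv + (long long)hi;
}

} // namespace

// [[Rcpp::export]]
List mesh_signed_distance_cpp(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
  const int np = points.nrow(), nv = V.nrow(), nf = F.nrow();
  if (nf == 0 || nv == 0) stop("empty mesh");

  std::vector<Vec3> vert(nv);
  for (int i = 0; i < nv; ++i) vert[i] = {V(i, 0), V(i, 1), V(i, 2)};

  // Face normals (unnormalized keeps area weighting available; store unit too).
  std::vector<Vec3> fnorm(nf);
  for (int f = 0; f < nf; ++f) {
    const Vec3 &a = vert[F(f, 0)], &b = vert[F(f, 1)], &c = vert[F(f, 2)];
    fnorm[f] = vunit(vcross(vsub(b, a), vsub(c, a)));
  }

  // Angle-weighted vertex pseudonormals.
  std::vector<Vec3> vnorm_acc(nv, {0, 0, 0});
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int k = 0; k < 3; ++k) {
      const Vec3 &p0 = vert[idx[k]];
      const Vec3 &p1 = vert[idx[(k + 1) % 3]];
      const Vec3 &p2 = vert[idx[(k + 2) % 3]];
      Vec3 e1 = vunit(vsub(p1, p0)), e2 = vunit(vsub(p2, p0));
      double cang = vdot(e1, e2);
      cang = cang > 1 ? 1 : (cang < -1 ? -1 : cang);
      double ang = std::acos(cang);
      vnorm_acc[idx[k]] = vadd(vnorm_acc[idx[k]], vscale(fnorm[f], ang));
    }
  }

  // Edge pseudonormals: mean of adjacent face normals.
  std::unordered_map<long long, Vec3> enorm;
  enorm.reserve((size_t)nf * 3);
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int k = 0; k < 3; ++k) {
      long long key = edge_key(idx[k], idx[(k + 1) % 3], nv);
      auto it = enorm.find(key);
      if (it == enorm.end()) enorm[key] = fnorm[f];
      else it->second = vadd(it->second, fnorm[f]);
    }
  }

  NumericVector sd(np);
  NumericMatrix closest(np, 3);

  for (int i = 0; i < np; ++i) {
    Vec3 p = {points(i, 0), points(i, 1), points(i, 2)};
    double best_d2 = R_PosInf;
    Vec3 best_cp = {0, 0, 0};
    int best_f = -1, best_region = 6;
    for (int f = 0; f < nf; ++f) {
      int region;
      Vec3 cp = closest_on_triangle(p, vert[F(f, 0)], vert[F(f, 1)], vert[F(f, 2)], region);
      Vec3 d = vsub(p, cp);
      double d2 = vdot(d, d);
      if (d2 < best_d2) {
        best_d2 = d2;
        best_cp = cp;
        best_f = f;
        best_region = region;
      }
    }

    Vec3 n;
    int a = F(best_f, 0), b = F(best_f, 1), c = F(best_f, 2);
    switch (best_region) {
    case 0: n = vnorm_acc[a]; break;
    case 1: n = vnorm_acc[b]; break;
    case 2: n = vnorm_acc[c]; break;
    case 3: n = enorm[edge_key(a, b, nv)]; break;
    case 4: n = enorm[edge_key(a, c, nv)]; break;
    case 5: n = enorm[edge_key(b, c, nv)]; break;
    default: n = fnorm[best_f];
    }

    double dist = std::sqrt(best_d2);
    double s = vdot(vsub(p, best_cp), n);
    sd[i] = (s >= 0 ? 1.0 : -1.0) * dist;
    closest(i, 0) = best_cp.x;
    closest(i, 1) = best_cp.y;
    closest(i, 2) = best_cp.z;
  }

  return List::create(_["signed_distance"] = sd, _["closest"] = closest);
}
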