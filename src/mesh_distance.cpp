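// Exact signed point-to-mesh distance with a bounding-volume hierarchy.
// Sign convention: +1 outside (outward-normal side), -1 inside, decided by
// the angle-weighted pseudo-normal of the closest feature (face/edge/vertex).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
#include <algorithm>
#include <functional>
#include <cstdint>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalized(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : Vec3(0, 0, 0);
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
// bary receives barycentric coordinates (u on a, v on b, w on c).
static Vec3 closestPointTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                 const Vec3& c, double bary[3]) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { bary[0] = 1; bary[1] = 0; bary[2] = 0; return a; }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { bary[0] = 0; bary[1] = 1; bary[2] = 0; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { bary[0] = 0; bary[1] = 0; bary[2] = 1; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + ab * v + ac * w;
}

struct AABB {
  Vec3 lo, hi;
  AABB() {
    double inf = std::numeric_limits<double>::infinity();
    lo = Vec3(inf, inf, inf);
    hi = Vec3(-inf, -inf, -inf);
  }
  void grow(const Vec3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void grow(const AABB& b) { grow(b.lo); grow(b.hi); }
  double dist2(const Vec3& p) const {
    double d = 0, t;
    t = std::max({lo.x - p.x, 0.0, p.x - hi.x}); d += t * t;
    t = std::max({lo.y - p.y, 0.0, p.y - hi.y}); d += t * t;
    t = std::max({lo.z - p.z, 0.0, p.z - hi.z}); d += t * t;
    return d;
  }
};

struct BVHNode {
  AABB box;
  int left = -1, right = -1;  // child node indices; -1 for leaf
  int start = 0, count = 0;   // leaf: range into face index array
};

class MeshBVH {
public:
  std::vector<Vec3> V;
  std::vector<int> F;  // 3 * nface, 0-based
  std::vector<Vec3> faceNormal;    // unit
  std::vector<Vec3> vertexNormal;  // angle-weighted, unit
  std::map<std::pair<int, int>, Vec3> edgeNormal;  // summed face normals, unit
  std::vector<BVHNode> nodes;
  std::vector<int> order;  // face ids, permuted by build
  int nface = 0;

  MeshBVH(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    int nv = Vm.nrow();
    nface = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F.resize(3 * nface);
    for (int f = 0; f < nface; ++f)
      for (int k = 0; k < 3; ++k) F[3 * f + k] = Fm(f, k) - 1;
    buildNormals(nv);
    build();
  }

  void buildNormals(int nv) {
    faceNormal.resize(nface);
    vertexNormal.assign(nv, Vec3());
    for (int f = 0; f < nface; ++f) {
      int i0 = F[3 * f], i1 = F[3 * f + 1], i2 = F[3 * f + 2];
      Vec3 n = cross(V[i1] - V[i0], V[i2] - V[i0]);
      faceNormal[f] = normalized(n);
      // angle-weighted accumulation at each corner
      const int idx[3] = {i0, i1, i2};
      for (int k = 0; k < 3; ++k) {
        Vec3 e1 = V[idx[(k + 1) % 3]] - V[idx[k]];
        Vec3 e2 = V[idx[(k + 2) % 3]] - V[idx[k]];
        double c = dot(e1, e2) / (norm(e1) * norm(e2));
        c = std::max(-1.0, std::min(1.0, c));
        double ang = std::acos(c);
        vertexNormal[idx[k]] = vertexNormal[idx[k]] + faceNormal[f] * ang;
      }
      for (int k = 0; k < 3; ++k) {
        int a = idx[k], b = idx[(k + 1) % 3];
        auto key = std::minmax(a, b);
        edgeNormal[{key.first, key.second}] =
            edgeNormal[{key.first, key.second}] + faceNormal[f];
      }
    }
    for (auto& vn : vertexNormal) vn = normalized(vn);
    for (auto& kv : edgeNormal) kv.second = normalized(kv.second);
  }

  void build() {
    order.resize(nface);
    for (int f = 0; f < nface; ++f) order[f] = f;
    std::vector<Vec3> cent(nface);
    std::vector<AABB> fbox(nface);
    for (int f = 0; f < nface; ++f) {
      AABB b;
      for (int k = 0; k < 3; ++k) b.grow(V[F[3 * f + k]]);
      fbox[f] = b;
      cent[f] = (b.lo + b.hi) * 0.5;
    }
    nodes.reserve(2 * nface / 3 + 1);
    buildNode(0, nface, cent, fbox);
  }

  int buildNode(int start, int count, const std::vector<Vec3>& cent,
                const std::vector<AABB>& fbox) {
    int id = (int)nodes.size();
    nodes.push_back(BVHNode());
    AABB box;
    for (int i = start; i < start + count; ++i) box.grow(fbox[order[i]]);
    nodes[id].box = box;
    if (count <= 4) {
      nodes[id].start = start;
      nodes[id].count = count;
      return id;
    }
    Vec3 ext = box.hi - box.lo;
    int axis = 0;
    if (ext.y > ext.x) axis = 1;
    if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : axis == 1 ? cent[a].y : cent[a].z;
                       double cb = axis == 0 ? cent[b].x : axis == 1 ? cent[b].y : cent[b].z;
                       return ca < cb;
                     });
    int l = buildNode(start, mid - start, cent, fbox);
    int r = buildNode(mid, start + count - mid, cent, fbox);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void nearestInNode(int id, const Vec3& q, double& best2, int& bestFace,
                     Vec3& bestPoint, double bestBary[3]) const {
    const BVHNode& nd = nodes[id];
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int f = order[i];
        double bary[3];
        Vec3 c = closestPointTriangle(q, V[F[3 * f]], V[F[3 * f + 1]],
                                      V[F[3 * f + 2]], bary);
        Vec3 d = q - c;
        double d2 = dot(d, d);
        if (d2 < best2) {
          best2 = d2;
          bestFace = f;
          bestPoint = c;
          bestBary[0] = bary[0]; bestBary[1] = bary[1]; bestBary[2] = bary[2];
        }
      }
      return;
    }
    double dl = nodes[nd.left].box.dist2(q);
    double dr = nodes[nd.right].box.dist2(q);
    int first = nd.left, second = nd.right;
    if (dr < dl) { std::swap(first, second); std::swap(dl, dr); }
    if (dl < best2) nearestInNode(first, q, best2, bestFace, bestPoint, bestBary);
    if (dr < best2) nearestInNode(second, q, best2, bestFace, bestPoint, bestBary);
  }

  // returns signed distance; fills closest point and face id
  double query(const Vec3& q, Vec3& cp, int& face) const {
    double best2 = std::numeric_limits<double>::infinity();
    double bary[3] = {0, 0, 0};
    face = -1;
    nearestInNode(0, q, best2, face, cp, bary);
    double d = std::sqrt(best2);
    // classify closest feature by barycentrics
    const double eps = 1e-12;
    int zeros = (bary[0] <= eps) + (bary[1] <= eps) + (bary[2] <= eps);
    Vec3 n;
    if (zeros == 0) {
      n = faceNormal[face];
    } else if (zeros == 1) {
      int k = bary[0] <= eps ? 0 : (bary[1] <= eps ? 1 : 2);
      int a = F[3 * face + (k + 1) % 3], b = F[3 * face + (k + 2) % 3];
      auto key = std::minmax(a, b);
      auto it = edgeNormal.find({key.first, key.second});
      n = it != edgeNormal.end() ? it->second : faceNormal[face];
    } else {
      int k = bary[0] > eps ? 0 : (bary[1] > eps ? 1 : 2);
      n = vertexNormal[F[3 * face + k]];
    }
    double s = dot(q - cp, n);
    return s >= 0 ? d : -d;
  }
};

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshBVH> ptr(new MeshBVH(V, F), true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_bvh_query(SEXP bvh, NumericMatrix Q) {
  XPtr<MeshBVH> ptr(bvh);
  int n = Q.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 q(Q(i, 0), Q(i, 1), Q(i, 2)), cp;
    int f;
    dist[i] = ptr->query(q, cp, f);
    closest(i, 0) = cp.x; closest(i, 1) = cp.y; closest(i, 2) = cp.z;
    face[i] = f + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// Edge manifoldness / orientation audit.
// Returns counts of boundary edges (used once), non-manifold edges (used >2),
// and inconsistently oriented interior edges (same direction twice).
// [[Rcpp::export]]
List cpp_edge_audit(IntegerMatrix F, int nv) {
  std::map<std::pair<int, int>, std::pair<int, int>> cnt;  // (fwd, bwd)
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    for (int k = 0; k < 3; ++k) {
      int a = idx[k], b = idx[(k + 1) % 3];
      if (a < b) cnt[{a, b}].first++;
      else cnt[{b, a}].second++;
    }
  }
  int boundary = 0, nonmanifold = 0, inconsistent = 0, total = 0;
  for (auto& kv : cnt) {
    ++total;
    int u = kv.second.first + kv.second.second;
    if (u == 1) ++boundary;
    else if (u > 2) ++nonmanifold;
    else if (kv.second.first != 1) ++inconsistent;  // used twice, same direction
  }
  return List::create(_["n_edges"] = total, _["n_boundary"] = boundary,
                      _["n_nonmanifold"] = nonmanifold,
                      _["n_inconsistent"] = inconsistent);
}

// [[Rcpp::export]]
double cpp_signed_volume(NumericMatrix V, IntegerMatrix F) {
  double vol = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    Vec3 a(V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2));
    Vec3 b(V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2));
    Vec3 c(V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2));
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return vol;
}

// Connected components of faces via shared vertices (union-find).
// Returns 1-based component label per face.
// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nv) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = find(F(f, 0) - 1), b = find(F(f, 1) - 1), c = find(F(f, 2) - 1);
    parent[a] = b;
    parent[find(b)] = find(c);
  }
  std::map<int, int> relabel;
  IntegerVector comp(nf);
  for (int f = 0; f < nf; ++f) {
    int r = find(F(f, 0) - 1);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      int id = (int)relabel.size() + 1;
      relabel[r] = id;
      comp[f] = id;
    } else comp[f] = it->second;
  }
  return comp;
}
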