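// Incremental 3D convex hull (quickhull-style point insertion).
// No hull library ships with the environment, so the primitive is built
// here: triangle faces with outward orientation, visibility-driven horizon
// replacement, volume by signed tetrahedra and area by facet integration.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

struct Face {
  int a, b, c;     // vertex indices, outward-oriented
  double nx, ny, nz, d;  // plane: n . x = d, n outward (unnormalised)
  bool alive;
};

static inline void plane(const NumericMatrix& P, Face& f) {
  double ax = P(f.a,0), ay = P(f.a,1), az = P(f.a,2);
  double ux = P(f.b,0)-ax, uy = P(f.b,1)-ay, uz = P(f.b,2)-az;
  double vx = P(f.c,0)-ax, vy = P(f.c,1)-ay, vz = P(f.c,2)-az;
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.d = f.nx*ax + f.ny*ay + f.nz*az;
}

static inline double sdist(const NumericMatrix& P, const Face& f, int i) {
  return f.nx*P(i,0) + f.ny*P(i,1) + f.nz*P(i,2) - f.d;
}

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix P, double eps = 1e-10) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  // characteristic scale for the degeneracy tolerance
  double scale = 0.0;
  for (int j = 0; j < 3; ++j) {
    double lo = P(0,j), hi = P(0,j);
    for (int i = 1; i < n; ++i) { lo = std::min(lo,P(i,j)); hi = std::max(hi,P(i,j)); }
    scale = std::max(scale, hi - lo);
  }
  double tol = eps * std::max(scale*scale, 1.0) + 1e-300;

  // initial tetrahedron: extreme pair, then max-area, then max-volume point
  int i0 = 0, i1 = 1;
  {
    double best = -1;
    for (int j = 0; j < 3; ++j) {
      int lo = 0, hi = 0;
      for (int i = 1; i < n; ++i) {
        if (P(i,j) < P(lo,j)) lo = i;
        if (P(i,j) > P(hi,j)) hi = i;
      }
      double d = 0;
      for (int k = 0; k < 3; ++k) d += (P(hi,k)-P(lo,k))*(P(hi,k)-P(lo,k));
      if (d > best) { best = d; i0 = lo; i1 = hi; }
    }
    if (best <= tol) stop("degenerate point set (all points coincident)");
  }
  int i2 = -1;
  {
    double best = tol;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1) continue;
      double ux = P(i1,0)-P(i0,0), uy = P(i1,1)-P(i0,1), uz = P(i1,2)-P(i0,2);
      double vx = P(i,0)-P(i0,0), vy = P(i,1)-P(i0,1), vz = P(i,2)-P(i0,2);
      double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
      double a2 = cx*cx + cy*cy + cz*cz;
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (i2 < 0) stop("degenerate point set (collinear)");
  }
  int i3 = -1;
  {
    Face f0{i0, i1, i2, 0,0,0,0, true};
    plane(P, f0);
    double best = tol;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(sdist(P, f0, i));
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) stop("degenerate point set (coplanar)");
  }

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c, double ix, double iy, double iz) {
    Face f{a, b, c, 0,0,0,0, true};
    plane(P, f);
    // orient outward relative to interior point
    double d = f.nx*ix + f.ny*iy + f.nz*iz - f.d;
    if (d > 0) { std::swap(f.b, f.c); plane(P, f); }
    faces.push_back(f);
  };
  double ix = (P(i0,0)+P(i1,0)+P(i2,0)+P(i3,0))/4.0;
  double iy = (P(i0,1)+P(i1,1)+P(i2,1)+P(i3,1))/4.0;
  double iz = (P(i0,2)+P(i1,2)+P(i2,2)+P(i3,2))/4.0;
  add_face(i0,i1,i2, ix,iy,iz);
  add_face(i0,i1,i3, ix,iy,iz);
  add_face(i0,i2,i3, ix,iy,iz);
  add_face(i1,i2,i3, ix,iy,iz);

  std::vector<bool> used(n, false);
  used[i0]=used[i1]=used[i2]=used[i3]=true;

  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      if (sdist(P, faces[fi], i) > tol) vis.push_back((int)fi);
    }
    if (vis.empty()) continue;
    // horizon: edges of visible faces shared with exactly one visible face
    std::map<std::pair<int,int>, std::pair<int,int>> edge_count;
    for (int fi : vis) {
      const Face& f = faces[fi];
      int e[3][2] = {{f.a,f.b},{f.b,f.c},{f.c,f.a}};
      for (auto& ed : e) {
        auto key = std::make_pair(std::min(ed[0],ed[1]), std::max(ed[0],ed[1]));
        auto it = edge_count.find(key);
        if (it == edge_count.end())
          edge_count[key] = std::make_pair(ed[0], ed[1]);  // keep orientation
        else
          edge_count.erase(it);   // interior edge (shared by two visible)
      }
    }
    for (int fi : vis) faces[fi].alive = false;
    for (auto& kv : edge_count) {
      // new face: horizon edge (oriented as in the visible face) + new point
      // reversing keeps outward orientation
      add_face(kv.second.second, kv.second.first, i, ix, iy, iz);
      Face& nf = faces.back();
      // ensure outward: interior point must be on the negative side
      double d = nf.nx*ix + nf.ny*iy + nf.nz*iz - nf.d;
      if (d > tol) { std::swap(nf.b, nf.c); plane(P, nf); }
    }
    used[i] = true;
  }

  // collect alive faces; compute volume (divergence theorem) and area
  double vol = 0.0, area = 0.0;
  std::vector<int> fa, fb, fc;
  std::vector<bool> on_hull(n, false);
  for (const Face& f : faces) {
    if (!f.alive) continue;
    fa.push_back(f.a+1); fb.push_back(f.b+1); fc.push_back(f.c+1);
    on_hull[f.a] = on_hull[f.b] = on_hull[f.c] = true;
    double ax=P(f.a,0), ay=P(f.a,1), az=P(f.a,2);
    double bx=P(f.b,0), by=P(f.b,1), bz=P(f.b,2);
    double cx=P(f.c,0), cy=P(f.c,1), cz=P(f.c,2);
    vol += (ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx)) / 6.0;
    area += 0.5 * std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
  }
  IntegerVector vidx;
  for (int i = 0; i < n; ++i) if (on_hull[i]) vidx.push_back(i+1);
  IntegerMatrix F(fa.size(), 3);
  for (size_t i = 0; i < fa.size(); ++i) { F(i,0)=fa[i]; F(i,1)=fb[i]; F(i,2)=fc[i]; }
  return List::create(_["faces"] = F, _["vertices"] = vidx,
                      _["volume"] = std::fabs(vol), _["area"] = area);
}
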