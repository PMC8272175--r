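// Incremental Bowyer-Watson Delaunay triangulation.
//
// Used by the mesher: interface curves are sampled densely and interior
// filler points are kept away from them, so the Delaunay triangulation of
// the combined point set conforms to the tissue interfaces. Inputs are
// expected to carry a tiny symbolic jitter (applied on the R side) so that
// cocircular configurations -- ubiquitous for points sampled on circles --
// are broken before the floating-point incircle test sees them.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex indices, CCW
  int n[3];   // n[i] = neighbour across edge opposite v[i], -1 if none
  bool dead;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d strictly inside circumcircle of CCW triangle (a,b,c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

}  // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");

  std::vector<double> x(n + 3), y(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0);
    y[i] = pts(i, 1);
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set");

  // super-triangle vertices (indices n, n+1, n+2)
  const double M = 50.0 * span;
  x[n] = cx - M;     y[n] = cy - M;
  x[n + 1] = cx + M; y[n + 1] = cy - M;
  x[n + 2] = cx;     y[n + 2] = cy + M;

  std::vector<Tri> tris;
  tris.reserve(2 * n + 16);
  {
    Tri t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
    t0.n[0] = t0.n[1] = t0.n[2] = -1;
    t0.dead = false;
    tris.push_back(t0);
  }

  int last = 0;  // walk start

  std::vector<int> cavity, stack;
  std::vector<char> inCavity;
  std::vector<int> bedgeA, bedgeB, bedgeN;

  for (int ip = 0; ip < n; ++ip) {
    const double px = x[ip], py = y[ip];

    // ---- locate containing triangle by walking ----
    int cur = last;
    if (tris[cur].dead) {
      for (int k = (int)tris.size() - 1; k >= 0; --k)
        if (!tris[k].dead) { cur = k; break; }
    }
    int steps = 0, maxSteps = 4 * (int)tris.size() + 64;
    bool located = false;
    while (steps++ < maxSteps) {
      const Tri &t = tris[cur];
      double o0 = orient2d(x[t.v[1]], y[t.v[1]], x[t.v[2]], y[t.v[2]], px, py);
      double o1 = orient2d(x[t.v[2]], y[t.v[2]], x[t.v[0]], y[t.v[0]], px, py);
      double o2 = orient2d(x[t.v[0]], y[t.v[0]], x[t.v[1]], y[t.v[1]], px, py);
      int go = -1;
      if (o0 < 0) go = 0; else if (o1 < 0) go = 1; else if (o2 < 0) go = 2;
      if (go < 0) { located = true; break; }
      int nxt = t.n[go];
      if (nxt < 0) break;  // outside hull: cannot happen inside super-tri
      cur = nxt;
    }
    if (!located) {
      // fallback: exhaustive scan
      bool found = false;
      for (int k = 0; k < (int)tris.size() && !found; ++k) {
        if (tris[k].dead) continue;
        const Tri &t = tris[k];
        if (orient2d(x[t.v[1]], y[t.v[1]], x[t.v[2]], y[t.v[2]], px, py) >= 0 &&
            orient2d(x[t.v[2]], y[t.v[2]], x[t.v[0]], y[t.v[0]], px, py) >= 0 &&
            orient2d(x[t.v[0]], y[t.v[0]], x[t.v[1]], y[t.v[1]], px, py) >= 0) {
          cur = k; found = true;
        }
      }
      if (!found) stop("point location failed");
    }

    // ---- grow cavity of triangles whose circumcircle contains p ----
    cavity.clear(); stack.clear();
    if (inCavity.size() < tris.size()) inCavity.resize(tris.size() + 256, 0);
    stack.push_back(cur);
    inCavity[cur] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int e = 0; e < 3; ++e) {
        int nb = tris[t].n[e];
        if (nb < 0 || inCavity[nb]) continue;
        const Tri &tt = tris[nb];
        if (incircle(x[tt.v[0]], y[tt.v[0]], x[tt.v[1]], y[tt.v[1]],
                     x[tt.v[2]], y[tt.v[2]], px, py) > 0) {
          inCavity[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // ---- collect boundary edges of the cavity ----
    bedgeA.clear(); bedgeB.clear(); bedgeN.clear();
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      int t = cavity[ci];
      for (int e = 0; e < 3; ++e) {
        int nb = tris[t].n[e];
        if (nb >= 0 && inCavity[nb]) continue;
        // edge opposite v[e]: (v[e+1], v[e+2]) seen CCW from inside t
        bedgeA.push_back(tris[t].v[(e + 1) % 3]);
        bedgeB.push_back(tris[t].v[(e + 2) % 3]);
        bedgeN.push_back(nb);
      }
    }

    // ---- retriangulate: fan of (p, a, b) ----
    const int nNew = (int)bedgeA.size();
    std::vector<int> newIdx(nNew);
    for (int e = 0; e < nNew; ++e) {
      Tri t;
      t.v[0] = ip; t.v[1] = bedgeA[e]; t.v[2] = bedgeB[e];
      t.n[0] = bedgeN[e];  // across (a,b)
      t.n[1] = t.n[2] = -1;
      t.dead = false;
      int id;
      if (!cavity.empty()) {
        id = cavity.back(); cavity.pop_back();
        tris[id] = t;
      } else {
        id = (int)tris.size();
        tris.push_back(t);
        if (inCavity.size() < tris.size()) inCavity.resize(tris.size() + 256, 0);
      }
      newIdx[e] = id;
      // fix outer neighbour's back-link
      int nb = bedgeN[e];
      if (nb >= 0) {
        for (int k = 0; k < 3; ++k) {
          int a2 = tris[nb].v[(k + 1) % 3], b2 = tris[nb].v[(k + 2) % 3];
          if ((a2 == bedgeB[e] && b2 == bedgeA[e]) ||
              (a2 == bedgeA[e] && b2 == bedgeB[e])) {
            tris[nb].n[k] = id;
            break;
          }
        }
      }
    }
    // retire any leftover cavity slots
    for (size_t ci = 0; ci < cavity.size(); ++ci) tris[cavity[ci]].dead = true;
    for (size_t ci = 0; ci < cavity.size(); ++ci) inCavity[cavity[ci]] = 0;
    for (int e = 0; e < nNew; ++e) inCavity[newIdx[e]] = 0;

    // link new triangles to each other: edge (p, a) of one matches (b, p)
    // of the neighbour whose b == a
    {
      // map vertex a -> new tri with v[1] == a
      // (small loop; nNew is typically < 12)
      for (int e = 0; e < nNew; ++e) {
        for (int f = 0; f < nNew; ++f) {
          if (tris[newIdx[f]].v[2] == tris[newIdx[e]].v[1]) {
            // neighbour across edge (p, a_e) is tri f; that edge is
            // opposite v[2] in tri e
            tris[newIdx[e]].n[2] = newIdx[f];
            break;
          }
        }
      }
      for (int e = 0; e < nNew; ++e) {
        for (int f = 0; f < nNew; ++f) {
          if (tris[newIdx[f]].v[1] == tris[newIdx[e]].v[2]) {
            tris[newIdx[e]].n[1] = newIdx[f];
            break;
          }
        }
      }
    }
    last = newIdx.empty() ? last : newIdx[0];
  }

  // ---- export triangles not touching the super-triangle ----
  int m = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (tris[k].dead) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (tris[k].dead) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    out(r, 0) = tris[k].v[0] + 1;
    out(r, 1) = tris[k].v[1] + 1;
    out(r, 2) = tris[k].v[2] + 1;
    ++r;
  }
  return out;
}
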