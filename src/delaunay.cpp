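// Incremental Bowyer-Watson Delaunay triangulation.
//
// Used by the tissue mechanics to define spring neighbours; called once per
// time step, so it needs to be fast for a few thousand points. Points are
// inserted in a grid-snake spatial order with walk-based point location,
// giving near-linear expected behaviour. Degenerate inputs (duplicates,
// full collinearity) are handled by the R wrapper, not here.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <utility>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tri {
  int v[3];    // vertex ids, CCW
  int adj[3];  // adj[i] = triangle across edge opposite v[i], -1 if none
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p strictly inside circumcircle of CCW triangle (a,b,c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

class Delaunay {
public:
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int last = 0;  // walk start hint

  void addSuperTriangle() {
    const int n = static_cast<int>(px.size()) - 3;  // real points
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
    }
    const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double m = std::max(xmax - xmin, ymax - ymin);
    if (m <= 0) m = 1.0;
    const double s = 64.0 * m;
    px[n]     = cx - 2.0 * s; py[n]     = cy - s;
    px[n + 1] = cx + 2.0 * s; py[n + 1] = cy - s;
    px[n + 2] = cx;           py[n + 2] = cy + 2.0 * s;
    Tri t;
    t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2;
    t.adj[0] = t.adj[1] = t.adj[2] = -1;
    t.alive = true;
    tris.push_back(t);
    last = 0;
  }

  int locate(double x, double y) const {
    int t = last;
    if (t < 0 || t >= static_cast<int>(tris.size()) || !tris[t].alive) {
      t = -1;
      for (int i = static_cast<int>(tris.size()) - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
    }
    const int maxSteps = 4 * static_cast<int>(tris.size()) + 16;
    for (int step = 0; step < maxSteps; ++step) {
      const Tri& T = tris[t];
      int worst = -1; double worstVal = -1e-12;
      for (int i = 0; i < 3; ++i) {
        const int a = T.v[(i + 1) % 3], b = T.v[(i + 2) % 3];
        const double o = orient2d(px[a], py[a], px[b], py[b], x, y);
        if (o < worstVal) { worstVal = o; worst = i; }
      }
      if (worst < 0) return t;
      const int next = T.adj[worst];
      if (next < 0) return t;  // should not happen inside super triangle
      t = next;
    }
    // walk failed (numerical cycling): linear fallback
    for (int i = 0; i < static_cast<int>(tris.size()); ++i) {
      if (!tris[i].alive) continue;
      const Tri& T = tris[i];
      bool inside = true;
      for (int e = 0; e < 3 && inside; ++e) {
        const int a = T.v[(e + 1) % 3], b = T.v[(e + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < -1e-12) inside = false;
      }
      if (inside) return i;
    }
    return t;
  }

  void insert(int p) {
    const double x = px[p], y = py[p];
    const int t0 = locate(x, y);

    // grow cavity of triangles whose circumcircle contains p
    std::vector<int> bad;
    std::vector<char> inBad(tris.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    inBad[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      const Tri& T = tris[t];
      for (int i = 0; i < 3; ++i) {
        const int nb = T.adj[i];
        if (nb < 0 || inBad[nb]) continue;
        const Tri& N = tris[nb];
        if (incircle(px[N.v[0]], py[N.v[0]], px[N.v[1]], py[N.v[1]],
                     px[N.v[2]], py[N.v[2]], x, y) > 0) {
          inBad[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity, oriented CCW as seen from inside
    struct BEdge { int a, b, outer, ownerBad; };
    std::vector<BEdge> boundary;
    for (int t : bad) {
      const Tri& T = tris[t];
      for (int i = 0; i < 3; ++i) {
        const int nb = T.adj[i];
        if (nb >= 0 && inBad[nb]) continue;
        boundary.push_back({T.v[(i + 1) % 3], T.v[(i + 2) % 3], nb, t});
      }
    }
    for (int t : bad) tris[t].alive = false;

    // re-triangulate the star of p
    std::unordered_map<int, int> byStart, byEnd;
    std::vector<int> created;
    created.reserve(boundary.size());
    for (const BEdge& e : boundary) {
      Tri t;
      t.v[0] = e.a; t.v[1] = e.b; t.v[2] = p;
      t.adj[0] = -1; t.adj[1] = -1; t.adj[2] = e.outer;
      t.alive = true;
      const int id = static_cast<int>(tris.size());
      tris.push_back(t);
      created.push_back(id);
      byStart[e.a] = id;
      byEnd[e.b] = id;
      if (e.outer >= 0) {
        Tri& O = tris[e.outer];
        for (int i = 0; i < 3; ++i)
          if (O.adj[i] == e.ownerBad) O.adj[i] = id;
      }
    }
    for (size_t k = 0; k < created.size(); ++k) {
      const int id = created[k];
      Tri& T = tris[id];
      // edge (v[1], p) opposite v[0]: next triangle starts at v[1]
      auto itS = byStart.find(T.v[1]);
      if (itS != byStart.end()) T.adj[0] = itS->second;
      // edge (p, v[0]) opposite v[1]: previous triangle ends at v[0]
      auto itE = byEnd.find(T.v[0]);
      if (itE != byEnd.end()) T.adj[1] = itE->second;
    }
    if (!created.empty()) last = created.back();
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");

  Delaunay D;
  D.px.resize(n + 3);
  D.py.resize(n + 3);
  for (int i = 0; i < n; ++i) { D.px[i] = x[i]; D.py[i] = y[i]; }
  D.addSuperTriangle();

  // grid-snake insertion order for walk locality
  double xmin = x[0], xmax = x[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, static_cast<double>(x[i]));
    xmax = std::max(xmax, static_cast<double>(x[i]));
  }
  const int ncols = std::max(1, static_cast<int>(std::ceil(std::sqrt(
      static_cast<double>(n)))));
  const double w = (xmax > xmin) ? (xmax - xmin) : 1.0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ca = std::min(ncols - 1, static_cast<int>((x[a] - xmin) / w * ncols));
    int cb = std::min(ncols - 1, static_cast<int>((x[b] - xmin) / w * ncols));
    if (ca != cb) return ca < cb;
    const bool up = (ca % 2 == 0);
    return up ? (y[a] < y[b]) : (y[a] > y[b]);
  });

  for (int k = 0; k < n; ++k) D.insert(order[k]);

  // collect unique edges between real points
  std::vector<std::pair<int, int> > edges;
  for (const Tri& T : D.tris) {
    if (!T.alive) continue;
    for (int i = 0; i < 3; ++i) {
      int a = T.v[(i + 1) % 3], b = T.v[(i + 2) % 3];
      if (a >= n || b >= n) continue;
      if (a > b) std::swap(a, b);
      edges.push_back(std::make_pair(a, b));
    }
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());

  IntegerMatrix out(static_cast<int>(edges.size()), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = edges[i].first + 1;   // 1-based for R
    out(i, 1) = edges[i].second + 1;
  }
  return out;
}
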