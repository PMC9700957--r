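// Delaunay triangulation kernel.
//
// Lexicographic incremental construction (sweep over points sorted by x,
// then y, attaching each new point to the strictly visible convex-hull
// edges) followed by Lawson edge flips until the empty-circumcircle
// property holds. No super-triangle is used, so predicate evaluation only
// ever involves input points. Coordinates are internally rescaled to the
// unit box; near-cocircular quadruples within the predicate tolerance are
// left unflipped (any valid triangulation of a cocircular set is accepted).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <stack>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

typedef long double ld;

struct Tri {
  int a, b, c;
  bool alive;
};

inline ld orient(const std::vector<ld>& x, const std::vector<ld>& y,
                 int a, int b, int c) {
  return (x[b] - x[a]) * (y[c] - y[a]) - (y[b] - y[a]) * (x[c] - x[a]);
}

// > 0 iff d lies strictly inside the circumcircle of CCW triangle (a,b,c).
inline ld incircle(const std::vector<ld>& x, const std::vector<ld>& y,
                   int a, int b, int c, int d) {
  ld adx = x[a] - x[d], ady = y[a] - y[d];
  ld bdx = x[b] - x[d], bdy = y[b] - y[d];
  ld cdx = x[c] - x[d], cdy = y[c] - y[d];
  ld ad2 = adx * adx + ady * ady;
  ld bd2 = bdx * bdx + bdy * bdy;
  ld cd2 = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd2 - cdy * bd2)
       - ady * (bdx * cd2 - cdx * bd2)
       + ad2 * (bdx * cdy - cdx * bdy);
}

inline long long edge_key(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return (long long)u * (long long)n + (long long)v;
}

struct EdgeMap {
  std::unordered_map<long long, std::pair<int, int> > m;
  int n;
  explicit EdgeMap(int n_) : n(n_) {}
  void add(int u, int v, int tri) {
    long long k = edge_key(u, v, n);
    auto it = m.find(k);
    if (it == m.end()) {
      m[k] = std::make_pair(tri, -1);
    } else if (it->second.second == -1 && it->second.first != tri) {
      it->second.second = tri;
    } else {
      stop("internal triangulation error: edge shared by >2 triangles");
    }
  }
  void remove(int u, int v, int tri) {
    long long k = edge_key(u, v, n);
    auto it = m.find(k);
    if (it == m.end()) stop("internal triangulation error: missing edge");
    if (it->second.first == tri) it->second.first = it->second.second;
    else if (it->second.second != tri)
      stop("internal triangulation error: edge/triangle mismatch");
    it->second.second = -1;
    if (it->second.first == -1) m.erase(it);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("internal: cpp_delaunay requires >= 3 points");

  // Rescale into the unit box for well-conditioned predicates.
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (scale <= 0) scale = 1.0;
  std::vector<ld> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = (ld)((pts(i, 0) - xmin) / scale);
    y[i] = (ld)((pts(i, 1) - ymin) / scale);
  }
  const ld tol = 1e-13L;

  // Lexicographic order.
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<Tri> tris;
  tris.reserve(3 * n);
  EdgeMap edges(n);
  std::stack<std::pair<int, int> > pending;

  auto add_tri = [&](int a, int b, int c) {
    if (orient(x, y, a, b, c) < 0) std::swap(b, c);
    Tri t; t.a = a; t.b = b; t.c = c; t.alive = true;
    int id = (int)tris.size();
    tris.push_back(t);
    edges.add(a, b, id); edges.add(b, c, id); edges.add(c, a, id);
    pending.push(std::make_pair(a, b));
    pending.push(std::make_pair(b, c));
    pending.push(std::make_pair(c, a));
  };

  // Collinear prefix: ord[0..m-1] lie on one line, ord[m] breaks it.
  int m = 2;
  while (m < n && orient(x, y, ord[0], ord[1], ord[m]) == 0) ++m;
  if (m >= n) stop("internal: all points collinear (handled by caller)");

  const int q = ord[m];
  for (int i = 0; i + 1 < m; ++i) add_tri(ord[i], ord[i + 1], q);

  // Convex hull as a circular doubly-linked list (CCW).
  std::vector<int> nxt(n, -1), prv(n, -1);
  {
    std::vector<int> hull;
    if (orient(x, y, ord[0], ord[1], q) > 0) {
      for (int i = 0; i < m; ++i) hull.push_back(ord[i]);
      hull.push_back(q);
    } else {
      hull.push_back(ord[0]);
      hull.push_back(q);
      for (int i = m - 1; i >= 1; --i) hull.push_back(ord[i]);
    }
    int h = (int)hull.size();
    for (int i = 0; i < h; ++i) {
      nxt[hull[i]] = hull[(i + 1) % h];
      prv[hull[(i + 1) % h]] = hull[i];
    }
  }
  const int anchor = ord[0];  // lexicographic minimum stays on the hull

  for (int k = m + 1; k < n; ++k) {
    const int p = ord[k];
    // Find the contiguous arc of strictly visible hull edges.
    int arc_start = -1, arc_len = 0;
    int v = anchor;
    bool prev_vis = false, first_vis = false;
    int hull_size = 0;
    do {
      int w = nxt[v];
      bool vis = orient(x, y, v, w, p) < 0;
      if (vis && !prev_vis) arc_start = v;
      if (vis) ++arc_len;
      if (v == anchor) first_vis = vis;
      prev_vis = vis;
      v = w;
      ++hull_size;
      if (hull_size > n + 1) stop("internal: hull walk failed");
    } while (v != anchor);
    // If the arc wraps around the anchor, the true start is further back.
    if (first_vis && prev_vis) {
      arc_start = anchor;
      while (orient(x, y, prv[arc_start], arc_start, p) < 0)
        arc_start = prv[arc_start];
    }
    if (arc_len == 0 || arc_len >= hull_size)
      stop("internal: no visible hull edge (degenerate input?)");

    int u0 = arc_start;
    int ut = u0;
    for (int i = 0; i < arc_len; ++i) {
      add_tri(nxt[ut], ut, p);
      ut = nxt[ut];
    }
    // Replace the chain u0..ut by u0 -> p -> ut.
    nxt[u0] = p; prv[p] = u0;
    nxt[p] = ut; prv[ut] = p;
  }

  // Lawson flips to Delaunay.
  long long flips = 0, guard = 100LL * n * n + 1000;
  while (!pending.empty()) {
    std::pair<int, int> e = pending.top();
    pending.pop();
    auto it = edges.m.find(edge_key(e.first, e.second, n));
    if (it == edges.m.end()) continue;
    int t1 = it->second.first, t2 = it->second.second;
    if (t1 < 0 || t2 < 0) continue;  // hull edge
    const int u = e.first, vv = e.second;
    auto third = [&](const Tri& t) {
      if (t.a != u && t.a != vv) return t.a;
      if (t.b != u && t.b != vv) return t.b;
      return t.c;
    };
    int c = third(tris[t1]);
    int d = third(tris[t2]);
    // Orient (u, vv, c) CCW for the incircle test.
    int a = u, b = vv;
    if (orient(x, y, a, b, c) < 0) std::swap(a, b);
    if (incircle(x, y, a, b, c, d) > tol) {
      // Flip: replace triangles (a,b,c),(b,a,d) by (c,d,...) pair.
      tris[t1].alive = false;
      tris[t2].alive = false;
      edges.remove(a, b, t1); edges.remove(b, c, t1); edges.remove(c, a, t1);
      edges.remove(b, a, t2); edges.remove(a, d, t2); edges.remove(d, b, t2);
      add_tri(a, d, c);
      add_tri(d, b, c);
      if (++flips > guard) stop("internal: flip limit exceeded");
    }
  }

  // Collect unique edges of alive triangles.
  std::vector<std::pair<int, int> > out;
  out.reserve(3 * n);
  for (const Tri& t : tris) {
    if (!t.alive) continue;
    int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
    for (auto& ee : e) {
      int u = std::min(ee[0], ee[1]), w = std::max(ee[0], ee[1]);
      out.push_back(std::make_pair(u, w));
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());

  IntegerMatrix res((int)out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i].first + 1;   // 1-based for R
    res(i, 1) = out[i].second + 1;
  }
  return res;
}
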