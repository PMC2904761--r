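// Exact geometry predicates and crossing-delta kernels.
//
// All grid positions arrive as numeric (row, col) pairs; grid coordinates are
// integers well below 2^26, so double arithmetic in the orientation tests is
// exact there.  The same predicates are reused for the continuous spring
// baseline, where ordinary floating point is acceptable.
//
// The bulk and incremental kernels accumulate, for every candidate grid
// point q of a node, the crossing counts attributable to that node at q.
// Edge-edge terms sweep all q; node-edge terms exploit the integer lattice:
// the points lying on a segment, or the points q for which a fixed node sits
// inside segment q-a, form a 1-D lattice ray that is enumerated directly.
#include <Rcpp.h>
using namespace Rcpp;

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline int sgn(double x) { return (x > 0) - (x < 0); }

// Open-interior intersection of segments a-b and c-d: proper crossing, or
// collinear overlap of positive length.  Endpoint touchings (including
// T-junctions) return 0 -- a touching endpoint is a node and is charged to
// the node-edge counter instead.
static bool seg_cross(double ax, double ay, double bx, double by,
                      double cx, double cy, double dx, double dy) {
  if ((ax == bx && ay == by) || (cx == dx && cy == dy)) return false;
  int d1 = sgn(orient(cx, cy, dx, dy, ax, ay));
  int d2 = sgn(orient(cx, cy, dx, dy, bx, by));
  int d3 = sgn(orient(ax, ay, bx, by, cx, cy));
  int d4 = sgn(orient(ax, ay, bx, by, dx, dy));
  if (d1 * d2 < 0 && d3 * d4 < 0) return true;          // proper crossing
  if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {       // all collinear
    double alo, ahi, blo, bhi;
    if (std::abs(bx - ax) >= std::abs(by - ay)) {
      alo = std::min(ax, bx); ahi = std::max(ax, bx);
      blo = std::min(cx, dx); bhi = std::max(cx, dx);
    } else {
      alo = std::min(ay, by); ahi = std::max(ay, by);
      blo = std::min(cy, dy); bhi = std::max(cy, dy);
    }
    return std::max(alo, blo) < std::min(ahi, bhi);
  }
  return false;
}

// p strictly interior to segment a-b
static bool on_open(double px, double py, double ax, double ay,
                    double bx, double by) {
  if (ax == bx && ay == by) return false;
  if (orient(ax, ay, bx, by, px, py) != 0) return false;
  double dot1 = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
  double dot2 = (px - bx) * (ax - bx) + (py - by) * (ay - by);
  return dot1 > 0 && dot2 > 0;
}

static inline bool integral(double x) { return x == std::floor(x); }

static long igcd(long a, long b) {
  a = std::labs(a); b = std::labs(b);
  while (b) { long t = a % b; a = b; b = t; }
  return a;
}

// [[Rcpp::export]]
IntegerVector cpp_seg_cross_batch(NumericMatrix a1, NumericMatrix a2,
                                  NumericMatrix b1, NumericMatrix b2) {
  int n = a1.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = seg_cross(a1(i, 0), a1(i, 1), a2(i, 0), a2(i, 1),
                       b1(i, 0), b1(i, 1), b2(i, 0), b2(i, 1));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_on_segment_batch(NumericMatrix p, NumericMatrix a,
                                   NumericMatrix b) {
  int n = p.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = on_open(p(i, 0), p(i, 1), a(i, 0), a(i, 1), b(i, 0), b(i, 1));
  return out;
}

static inline bool share_endpoint(int a1, int a2, int b1, int b2) {
  return a1 == b1 || a1 == b2 || a2 == b1 || a2 == b2;
}

// Total (edge-edge, node-edge) crossing counts.  Edge pairs sharing a graph
// endpoint are never counted; a node is never counted against its own edges.
// [[Rcpp::export]]
IntegerVector cpp_count_crossings(NumericMatrix pos, IntegerMatrix edges) {
  int m = edges.nrow(), n = pos.nrow();
  long ee = 0, ne = 0;
  for (int i = 0; i < m; ++i) {
    int i1 = edges(i, 0), i2 = edges(i, 1);
    for (int j = i + 1; j < m; ++j) {
      int j1 = edges(j, 0), j2 = edges(j, 1);
      if (share_endpoint(i1, i2, j1, j2)) continue;
      ee += seg_cross(pos(i1, 0), pos(i1, 1), pos(i2, 0), pos(i2, 1),
                      pos(j1, 0), pos(j1, 1), pos(j2, 0), pos(j2, 1));
    }
    for (int u = 0; u < n; ++u) {
      if (u == i1 || u == i2) continue;
      ne += on_open(pos(u, 0), pos(u, 1), pos(i1, 0), pos(i1, 1),
                    pos(i2, 0), pos(i2, 1));
    }
  }
  return IntegerVector::create(_["ee"] = (int)ee, _["ne"] = (int)ne);
}

struct Scene {
  std::vector<double> pr, pc;   // node coordinates
  std::vector<int> e1, e2;      // 0-based edge endpoints
  int n, m, h, w;
  bool lattice;                 // all coordinates integral?
  Scene(NumericMatrix& pos, IntegerMatrix& edges, int h_, int w_) {
    n = pos.nrow(); m = edges.nrow(); h = h_; w = w_;
    pr.resize(n); pc.resize(n); e1.resize(m); e2.resize(m);
    lattice = true;
    for (int i = 0; i < n; ++i) {
      pr[i] = pos(i, 0); pc[i] = pos(i, 1);
      if (!integral(pr[i]) || !integral(pc[i])) lattice = false;
    }
    for (int e = 0; e < m; ++e) { e1[e] = edges(e, 0); e2[e] = edges(e, 1); }
  }
  std::vector<int> incident(int v) const {
    std::vector<int> ev;
    for (int e = 0; e < m; ++e)
      if (e1[e] == v || e2[e] == v) ev.push_back(e);
    return ev;
  }
};

// acc[q] += t for all lattice points q strictly inside segment a-b
static void add_on_segment(std::vector<int>& acc, int t,
                           double ar, double ac, double br, double bc,
                           int h, int w) {
  if (ar == br && ac == bc) return;
  if (!integral(ar) || !integral(ac) || !integral(br) || !integral(bc)) {
    for (int r = 0; r < h; ++r)
      for (int c = 0; c < w; ++c)
        if (on_open(r, c, ar, ac, br, bc)) acc[r * w + c] += t;
    return;
  }
  long dr = (long)br - (long)ar, dc = (long)bc - (long)ac;
  long g = igcd(dr, dc);
  if (g <= 1) return;
  long sr = dr / g, sc = dc / g;
  for (long k = 1; k < g; ++k) {
    long r = (long)ar + k * sr, c = (long)ac + k * sc;
    if (r >= 0 && r < h && c >= 0 && c < w) acc[r * w + c] += t;
  }
}

// acc[q] += t for all q such that node p lies strictly inside segment q-a:
// q walks the lattice ray from p away from a
static void add_on_ray(std::vector<int>& acc, int t,
                       double pr_, double pc_, double ar, double ac,
                       int h, int w) {
  if (pr_ == ar && pc_ == ac) return;
  if (!integral(pr_) || !integral(pc_) || !integral(ar) || !integral(ac)) {
    for (int r = 0; r < h; ++r)
      for (int c = 0; c < w; ++c)
        if (on_open(pr_, pc_, r, c, ar, ac)) acc[r * w + c] += t;
    return;
  }
  long dr = (long)pr_ - (long)ar, dc = (long)pc_ - (long)ac;
  long g = igcd(dr, dc);
  long sr = dr / g, sc = dc / g;
  long r = (long)pr_ + sr, c = (long)pc_ + sc;
  while (r >= 0 && r < h && c >= 0 && c < w) {
    acc[r * w + c] += t;
    r += sr; c += sc;
  }
}

// crossing counts attributable to node v as a function of its grid point:
// ee[q] = edge-edge crossings of E_v placed at q against fixed edges,
// ne[q] = v@q on fixed edges + fixed nodes on E_v@q.
static void v_candidate_counts(const Scene& S, int v,
                               std::vector<int>& ee, std::vector<int>& ne) {
  int hw = S.h * S.w;
  ee.assign(hw, 0); ne.assign(hw, 0);
  std::vector<int> ev = S.incident(v);
  for (size_t k = 0; k < ev.size(); ++k) {
    int e = ev[k];
    int a = S.e1[e] == v ? S.e2[e] : S.e1[e];
    double ar = S.pr[a], ac = S.pc[a];
    for (int f = 0; f < S.m; ++f) {
      int f1 = S.e1[f], f2 = S.e2[f];
      if (f1 == v || f2 == v) continue;       // within E_v: shares v
      if (a == f1 || a == f2) continue;       // shares the far endpoint
      double cr = S.pr[f1], cc = S.pc[f1], dr = S.pr[f2], dc = S.pc[f2];
      int q = 0;
      for (int r = 0; r < S.h; ++r)
        for (int c = 0; c < S.w; ++c, ++q)
          ee[q] += seg_cross(r, c, ar, ac, cr, cc, dr, dc);
    }
    for (int u = 0; u < S.n; ++u) {           // u inside segment q-a
      if (u == v || u == a) continue;
      add_on_ray(ne, 1, S.pr[u], S.pc[u], ar, ac, S.h, S.w);
    }
  }
  for (int f = 0; f < S.m; ++f) {             // v@q inside fixed edges
    int f1 = S.e1[f], f2 = S.e2[f];
    if (f1 == v || f2 == v) continue;
    add_on_segment(ne, 1, S.pr[f1], S.pc[f1], S.pr[f2], S.pc[f2], S.h, S.w);
  }
}

// For every grid point q, the change in (ee, ne) if node v moved to q.
// [[Rcpp::export]]
List cpp_bulk_deltas(int v, NumericMatrix pos, IntegerMatrix edges,
                     int h, int w) {
  Scene S(pos, edges, h, w);
  std::vector<int> ee, ne;
  v_candidate_counts(S, v, ee, ne);
  int cur = -1;
  if (integral(S.pr[v]) && integral(S.pc[v]) &&
      S.pr[v] >= 0 && S.pr[v] < h && S.pc[v] >= 0 && S.pc[v] < w)
    cur = (int)S.pr[v] * w + (int)S.pc[v];
  int base_ee = cur >= 0 ? ee[cur] : 0, base_ne = cur >= 0 ? ne[cur] : 0;
  IntegerVector dee(h * w), dne(h * w);
  for (int q = 0; q < h * w; ++q) {
    dee[q] = ee[q] - base_ee;
    dne[q] = ne[q] - base_ne;
  }
  return List::create(_["dee"] = dee, _["dne"] = dne);
}

// Incremental update of the per-(node, point) crossing-delta cache after
// node v moved from (old_r, old_c) to its current position in `pos`.
// Columns for v and its neighbours are recomputed outright; every other
// column is adjusted by exactly the terms that involve v's node or edges at
// the old versus new geometry.  Returns modified copies.
// [[Rcpp::export]]
List cpp_update_crossing_cache(IntegerMatrix dee_in, IntegerMatrix dne_in,
                               int v, double old_r, double old_c,
                               NumericMatrix pos, IntegerMatrix edges,
                               int h, int w) {
  IntegerMatrix dee = clone(dee_in), dne = clone(dne_in);
  Scene S(pos, edges, h, w);
  int hw = h * w;
  std::vector<int> ev = S.incident(v);
  std::vector<bool> is_nb(S.n, false);
  is_nb[v] = true;
  for (size_t k = 0; k < ev.size(); ++k) {
    is_nb[S.e1[ev[k]]] = true;
    is_nb[S.e2[ev[k]]] = true;
  }
  double new_r = S.pr[v], new_c = S.pc[v];
  std::vector<int> buf_ee, buf_ne, adj_ee(hw), adj_ne(hw);

  for (int u = 0; u < S.n; ++u) {
    if (is_nb[u]) {                           // full recompute
      v_candidate_counts(S, u, buf_ee, buf_ne);
      int cur = (int)S.pr[u] * w + (int)S.pc[u];
      int* pe = &dee(0, u); int* pn = &dne(0, u);
      for (int q = 0; q < hw; ++q) {
        pe[q] = buf_ee[q] - buf_ee[cur];
        pn[q] = buf_ne[q] - buf_ne[cur];
      }
      continue;
    }
    std::vector<int> eu = S.incident(u);
    std::fill(adj_ee.begin(), adj_ee.end(), 0);
    std::fill(adj_ne.begin(), adj_ne.end(), 0);
    bool any = false;
    for (size_t ke = 0; ke < eu.size(); ++ke) {
      int e = eu[ke];
      int a = S.e1[e] == u ? S.e2[e] : S.e1[e];
      double ar = S.pr[a], ac = S.pc[a];
      for (size_t kv = 0; kv < ev.size(); ++kv) {
        int f = ev[kv];
        int b = S.e1[f] == v ? S.e2[f] : S.e1[f];
        if (a == b || a == v) continue;       // shared endpoint: never counted
        double br = S.pr[b], bc = S.pc[b];
        any = true;
        int q = 0;
        for (int r = 0; r < h; ++r)
          for (int c = 0; c < w; ++c, ++q) {
            int t = seg_cross(r, c, ar, ac, new_r, new_c, br, bc) -
                    seg_cross(r, c, ar, ac, old_r, old_c, br, bc);
            adj_ee[q] += t;
          }
      }
      // v's node inside u's candidate edge q-a
      add_on_ray(adj_ne, +1, new_r, new_c, ar, ac, h, w);
      add_on_ray(adj_ne, -1, old_r, old_c, ar, ac, h, w);
      any = true;
    }
    // u@q inside v's edges
    for (size_t kv = 0; kv < ev.size(); ++kv) {
      int f = ev[kv];
      int b = S.e1[f] == v ? S.e2[f] : S.e1[f];
      double br = S.pr[b], bc = S.pc[b];
      add_on_segment(adj_ne, +1, new_r, new_c, br, bc, h, w);
      add_on_segment(adj_ne, -1, old_r, old_c, br, bc, h, w);
      any = true;
    }
    if (!any) continue;
    int cur = (int)S.pr[u] * w + (int)S.pc[u];
    int ce = adj_ee[cur], cn = adj_ne[cur];
    int* pe = &dee(0, u); int* pn = &dne(0, u);
    for (int q = 0; q < hw; ++q) {
      pe[q] += adj_ee[q] - ce;
      pn[q] += adj_ne[q] - cn;
    }
  }
  return List::create(_["dee"] = dee, _["dne"] = dne);
}
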