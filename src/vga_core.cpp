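// Visibility-graph core: line-of-sight tests against polygonal obstacles and
// breadth-first depth metrics.  Kept in C++ because a 1-vm grid over a
// city-block environment yields thousands of cells and O(n^2) sight lines.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double EPS = 1e-9;

// squared distance from point p to segment [a,b]
static double pt_seg_d2(double px, double py, double ax, double ay,
                        double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / l2;
    t = std::max(0.0, std::min(1.0, t));
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// point strictly inside a simple polygon ring (boundary counts as outside)
static bool in_ring_strict(double x, double y, const NumericMatrix &ring) {
  int n = ring.nrow();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    if (pt_seg_d2(x, y, ring(i, 0), ring(i, 1), ring(j, 0), ring(j, 1)) < EPS * EPS)
      return false;  // on boundary
  }
  bool inside = false;  // ray casting
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = ring(i, 0), yi = ring(i, 1), xj = ring(j, 0), yj = ring(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// parameters t in [0,1] where segment p->q crosses ring edges
static void ring_crossings(double px, double py, double qx, double qy,
                           const NumericMatrix &ring, std::vector<double> &ts) {
  int n = ring.nrow();
  double rx = qx - px, ry = qy - py;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double sx = ring(j, 0) - ring(i, 0), sy = ring(j, 1) - ring(i, 1);
    double denom = rx * sy - ry * sx;
    if (std::fabs(denom) < EPS) continue;  // parallel/collinear: boundary graze
    double wx = ring(i, 0) - px, wy = ring(i, 1) - py;
    double t = (wx * sy - wy * sx) / denom;
    double u = (wx * ry - wy * rx) / denom;
    if (t >= -EPS && t <= 1.0 + EPS && u >= -EPS && u <= 1.0 + EPS)
      ts.push_back(std::max(0.0, std::min(1.0, t)));
  }
}

// open segment p->q blocked by ring interior?  Split the segment at boundary
// crossings and test each sub-segment midpoint for strict interiority, so a
// sight line grazing along a wall stays visible.
static bool blocked_by_ring(double px, double py, double qx, double qy,
                            const NumericMatrix &ring) {
  std::vector<double> ts;
  ts.push_back(0.0);
  ts.push_back(1.0);
  ring_crossings(px, py, qx, qy, ring, ts);
  std::sort(ts.begin(), ts.end());
  for (size_t k = 0; k + 1 < ts.size(); ++k) {
    double tm = 0.5 * (ts[k] + ts[k + 1]);
    if (ts[k + 1] - ts[k] < EPS) continue;
    double mx = px + tm * (qx - px), my = py + tm * (qy - py);
    if (in_ring_strict(mx, my, ring)) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".cpp_point_in_obstacle")]]
LogicalVector cpp_point_in_obstacle(NumericVector x, NumericVector y,
                                    List rings) {
  int n = x.size(), m = rings.size();
  LogicalVector out(n, false);
  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < m; ++r) {
      NumericMatrix ring = rings[r];
      if (in_ring_strict(x[i], y[i], ring)) { out[i] = true; break; }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_segment_blocked")]]
LogicalVector cpp_segment_blocked(NumericVector px, NumericVector py,
                                  NumericVector qx, NumericVector qy,
                                  List rings) {
  int n = px.size(), m = rings.size();
  LogicalVector out(n, false);
  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < m; ++r) {
      NumericMatrix ring = rings[r];
      if (blocked_by_ring(px[i], py[i], qx[i], qy[i], ring)) {
        out[i] = true; break;
      }
    }
  }
  return out;
}

// is the ring an axis-aligned rectangle? (4 vertices, axis-parallel edges)
static bool ring_is_aa_rect(const NumericMatrix &ring) {
  if (ring.nrow() != 4) return false;
  for (int i = 0; i < 4; ++i) {
    int j = (i + 1) % 4;
    bool vx = std::fabs(ring(i, 0) - ring(j, 0)) < EPS;
    bool vy = std::fabs(ring(i, 1) - ring(j, 1)) < EPS;
    if (!vx && !vy) return false;
  }
  return true;
}

// Liang-Barsky clip of segment p->q against the OPEN box (x0,x1)x(y0,y1);
// blocked iff a sub-interval of positive length lies strictly inside, so a
// sight line grazing along a wall or corner stays visible.
static bool blocked_by_rect(double px, double py, double qx, double qy,
                            double x0, double x1, double y0, double y1) {
  double t0 = 0.0, t1 = 1.0;
  double d, lo, hi, ta, tb;
  // x slab
  d = qx - px;
  if (std::fabs(d) < EPS) {
    if (px <= x0 + EPS || px >= x1 - EPS) return false;
  } else {
    ta = (x0 - px) / d; tb = (x1 - px) / d;
    lo = std::min(ta, tb); hi = std::max(ta, tb);
    t0 = std::max(t0, lo); t1 = std::min(t1, hi);
  }
  // y slab
  d = qy - py;
  if (std::fabs(d) < EPS) {
    if (py <= y0 + EPS || py >= y1 - EPS) return false;
  } else {
    ta = (y0 - py) / d; tb = (y1 - py) / d;
    lo = std::min(ta, tb); hi = std::max(ta, tb);
    t0 = std::max(t0, lo); t1 = std::min(t1, hi);
  }
  return t1 - t0 > 1e-9;
}

// Pairwise mutual visibility between cell centers.  Returns a two-column
// integer matrix of 1-based edges (i < j).  Axis-aligned rectangular
// obstacles take an O(1) slab-clip path; arbitrary simple polygons fall
// back to the generic boundary-crossing test.
// [[Rcpp::export(name = ".cpp_visibility_edges")]]
IntegerMatrix cpp_visibility_edges(NumericVector x, NumericVector y,
                                   List rings) {
  int n = x.size(), m = rings.size();
  // obstacle bounding boxes for quick rejection + rectangle fast path
  std::vector<double> bx0(m), bx1(m), by0(m), by1(m);
  std::vector<char> is_rect(m);
  for (int r = 0; r < m; ++r) {
    NumericMatrix ring = rings[r];
    double x0 = ring(0, 0), x1 = x0, y0 = ring(0, 1), y1 = y0;
    for (int i = 1; i < ring.nrow(); ++i) {
      x0 = std::min(x0, ring(i, 0)); x1 = std::max(x1, ring(i, 0));
      y0 = std::min(y0, ring(i, 1)); y1 = std::max(y1, ring(i, 1));
    }
    bx0[r] = x0; bx1[r] = x1; by0[r] = y0; by1[r] = y1;
    is_rect[r] = ring_is_aa_rect(ring) ? 1 : 0;
  }
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    Rcpp::checkUserInterrupt();
    double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      bool blocked = false;
      double sx0 = std::min(xi, x[j]), sx1 = std::max(xi, x[j]);
      double sy0 = std::min(yi, y[j]), sy1 = std::max(yi, y[j]);
      for (int r = 0; r < m; ++r) {
        if (sx1 < bx0[r] - EPS || sx0 > bx1[r] + EPS ||
            sy1 < by0[r] - EPS || sy0 > by1[r] + EPS) continue;
        if (is_rect[r]) {
          if (blocked_by_rect(xi, yi, x[j], y[j],
                              bx0[r], bx1[r], by0[r], by1[r])) {
            blocked = true; break;
          }
        } else {
          NumericMatrix ring = rings[r];
          if (blocked_by_ring(xi, yi, x[j], y[j], ring)) {
            blocked = true; break;
          }
        }
      }
      if (!blocked) { ei.push_back(i + 1); ej.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) { out(k, 0) = ei[k]; out(k, 1) = ej[k]; }
  return out;
}

// All-sources BFS over an undirected edge list.  Returns per node:
// degree, sum of shortest-path steps to reached nodes, count reached
// (excluding self).
// [[Rcpp::export(name = ".cpp_bfs_depth_stats")]]
NumericMatrix cpp_bfs_depth_stats(int n, IntegerMatrix edges) {
  std::vector<std::vector<int> > adj(n);
  for (int k = 0; k < edges.nrow(); ++k) {
    int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  NumericMatrix out(n, 3);
  std::vector<int> depth(n);
  for (int s = 0; s < n; ++s) {
    Rcpp::checkUserInterrupt();
    std::fill(depth.begin(), depth.end(), -1);
    std::queue<int> q;
    depth[s] = 0; q.push(s);
    double dsum = 0.0; int reached = 0;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int w = adj[v][t];
        if (depth[w] < 0) {
          depth[w] = depth[v] + 1;
          dsum += depth[w];
          ++reached;
          q.push(w);
        }
      }
    }
    out(s, 0) = (double)adj[s].size();
    out(s, 1) = dsum;
    out(s, 2) = (double)reached;
  }
  return out;
}
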