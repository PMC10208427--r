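// Planar Voronoi diagrams by incremental half-plane clipping, with
// neighbor tracking, exact polygon moments, and Lloyd iteration support.
// Bounded mode clips cells to the domain rectangle; periodic mode tiles the
// seed set 3x3 and computes cells for the central copies, so cell polygons
// may extend past the domain while the diagram is a torus tessellation.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pt {
  double x, y;
};

// polygon with the owner of the edge leaving each vertex:
// owner >= 0 -> candidate seed index whose bisector carries the edge,
// owner < 0  -> domain wall (bounded) / initial box (periodic).
struct Poly {
  std::vector<Pt> v;
  std::vector<int> own;
};

inline double sq(double a) { return a * a; }

// clip poly to half-plane {x : u.(x - m) <= 0}; edges created get owner j
void clip_halfplane(Poly &p, double mx, double my, double ux, double uy,
                    int j) {
  const size_t m = p.v.size();
  if (m == 0) return;
  std::vector<double> f(m);
  bool any_out = false, any_in = false;
  for (size_t k = 0; k < m; ++k) {
    f[k] = ux * (p.v[k].x - mx) + uy * (p.v[k].y - my);
    if (f[k] > 0)
      any_out = true;
    else
      any_in = true;
  }
  if (!any_out) return;  // untouched
  Poly out;
  if (!any_in) {
    p.v.clear();
    p.own.clear();
    return;
  }
  out.v.reserve(m + 2);
  out.own.reserve(m + 2);
  for (size_t k = 0; k < m; ++k) {
    size_t k2 = (k + 1) % m;
    double fa = f[k], fb = f[k2];
    const Pt &a = p.v[k], &b = p.v[k2];
    if (fa <= 0) {
      if (fb <= 0) {
        out.v.push_back(a);
        out.own.push_back(p.own[k]);
      } else {
        // leaving: keep a, add intersection; edge from intersection runs
        // along the new bisector until the polygon re-enters
        out.v.push_back(a);
        out.own.push_back(p.own[k]);
        double t = fa / (fa - fb);
        out.v.push_back({a.x + t * (b.x - a.x), a.y + t * (b.y - a.y)});
        out.own.push_back(j);
      }
    } else if (fb <= 0) {
      // entering: intersection continues the original edge
      double t = fa / (fa - fb);
      out.v.push_back({a.x + t * (b.x - a.x), a.y + t * (b.y - a.y)});
      out.own.push_back(p.own[k]);
    }
  }
  p = std::move(out);
}

}  // namespace

// [[Rcpp::export]]
List cpp_voronoi(NumericMatrix seeds, double xmin, double xmax, double ymin,
                 double ymax, bool periodic) {
  const int n = seeds.nrow();
  const double Lx = xmax - xmin, Ly = ymax - ymin;

  // candidate seed list: originals, or 3x3 tiling in periodic mode
  std::vector<double> cx, cy;
  std::vector<int> cid;  // original seed id (0-based) of each candidate
  if (periodic) {
    cx.reserve(9 * n);
    cy.reserve(9 * n);
    cid.reserve(9 * n);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int i = 0; i < n; ++i) {
          cx.push_back(seeds(i, 0) + ox * Lx);
          cy.push_back(seeds(i, 1) + oy * Ly);
          cid.push_back(i);
        }
  } else {
    cx.resize(n);
    cy.resize(n);
    cid.resize(n);
    for (int i = 0; i < n; ++i) {
      cx[i] = seeds(i, 0);
      cy[i] = seeds(i, 1);
      cid[i] = i;
    }
  }
  const int nc = (int)cx.size();
  // central-tile copy index of seed i in the candidate list
  const int central_off = periodic ? 4 * n : 0;

  List cells(n), neigh(n);
  NumericVector area(n);
  NumericMatrix centroid(n, 2);
  double energy = 0.0;

  std::vector<std::pair<double, int>> cand(nc);

  for (int i = 0; i < n; ++i) {
    const double sx = seeds(i, 0), sy = seeds(i, 1);
    // start polygon: domain rectangle (bounded) or padded box (periodic)
    Poly p;
    double bx0 = xmin, bx1 = xmax, by0 = ymin, by1 = ymax;
    if (periodic) {
      bx0 -= Lx; bx1 += Lx; by0 -= Ly; by1 += Ly;
    }
    p.v = {{bx0, by0}, {bx1, by0}, {bx1, by1}, {bx0, by1}};
    p.own = {-1, -2, -3, -4};

    int me = central_off + i;
    int m = 0;
    for (int c = 0; c < nc; ++c) {
      if (c == me) continue;
      cand[m].first = sq(cx[c] - sx) + sq(cy[c] - sy);
      cand[m].second = c;
      ++m;
    }
    // only the nearest few dozen candidates can cut the cell; sort lazily
    int sorted_to = 0;
    int block = std::min(m, 48);
    std::nth_element(cand.begin(), cand.begin() + block - 1, cand.begin() + m);
    std::sort(cand.begin(), cand.begin() + block);
    sorted_to = block;

    double maxR2 = 0;
    for (auto &pt : p.v) maxR2 = std::max(maxR2, sq(pt.x - sx) + sq(pt.y - sy));

    for (int t = 0; t < m; ++t) {
      if (t == sorted_to) {  // rare: extend the sorted prefix
        std::sort(cand.begin() + sorted_to, cand.begin() + m);
        sorted_to = m;
      }
      int c = cand[t].second;
      double dd = cand[t].first;
      if (dd == 0.0) stop("coincident seeds");
      if (0.25 * dd > maxR2) break;  // sorted: no later seed can cut the cell
      clip_halfplane(p, 0.5 * (sx + cx[c]), 0.5 * (sy + cy[c]),
                     cx[c] - sx, cy[c] - sy, c);
      maxR2 = 0;
      for (auto &pt : p.v)
        maxR2 = std::max(maxR2, sq(pt.x - sx) + sq(pt.y - sy));
    }

    const size_t mv = p.v.size();
    if (mv < 3) stop("degenerate (empty) Voronoi cell");

    // moments: fan triangulation from the seed (cell is convex, contains seed)
    double A = 0, Cx = 0, Cy = 0, E = 0;
    for (size_t k = 0; k < mv; ++k) {
      size_t k2 = (k + 1) % mv;
      double d1x = p.v[k].x - sx, d1y = p.v[k].y - sy;
      double d2x = p.v[k2].x - sx, d2y = p.v[k2].y - sy;
      double At = 0.5 * (d1x * d2y - d1y * d2x);
      A += At;
      Cx += At * (sx + p.v[k].x + p.v[k2].x) / 3.0;
      Cy += At * (sy + p.v[k].y + p.v[k2].y) / 3.0;
      E += At / 6.0 *
           (d1x * d1x + d1y * d1y + d2x * d2x + d2y * d2y + d1x * d2x +
            d1y * d2y);
    }
    area[i] = A;
    centroid(i, 0) = Cx / A;
    centroid(i, 1) = Cy / A;
    energy += E;

    NumericMatrix ring(mv, 2);
    for (size_t k = 0; k < mv; ++k) {
      ring(k, 0) = p.v[k].x;
      ring(k, 1) = p.v[k].y;
    }
    cells[i] = ring;

    std::vector<int> nb;
    for (size_t k = 0; k < mv; ++k)
      if (p.own[k] >= 0) {
        int id = cid[p.own[k]];
        if (id != i) nb.push_back(id + 1);  // 1-based, drop self-images
      }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    neigh[i] = IntegerVector(nb.begin(), nb.end());
  }

  return List::create(_["cells"] = cells, _["neighbors"] = neigh,
                      _["areas"] = area, _["centroids"] = centroid,
                      _["energy"] = energy);
}
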