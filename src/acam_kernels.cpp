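#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Discrete energetics of a tissue of closed/open morphoelastic rods coupled
// by Hookean adhesion springs with saturation.
//
// Layout: all cortex nodes concatenated; loop l owns nodes
// [loop_off[l], loop_off[l+1]) (0-based). Segment j starts at node j and ends
// at the next node of the same loop (wrapping iff the loop is closed); its
// reference (stress-free) length is ell[j], already including the active
// contraction factor. Bending is penalised at every node with two incident
// segments: E_b = 1/2 kappa2 * theta^2 / a, a = (ell_prev + ell_next)/2,
// the turning-angle-per-reference-arc-length (discrete rods) convention.
// Stretching: E_s = 1/2 * (d/ell - 1)^2 * ell per segment.
// Springs: E_w = 1/2 k (delta-1)^2 for delta <= dmax, constant beyond
// (no force on the saturated branch). Spring endpoint b may be a fixed wall
// node (bwall = 1), which contributes no gradient.

static inline double seglen(const double* x, int i, int j) {
  double dx = x[2 * j] - x[2 * i], dy = x[2 * j + 1] - x[2 * i + 1];
  return std::sqrt(dx * dx + dy * dy);
}

// [[Rcpp::export]]
double acam_energy_cpp(NumericVector x, IntegerVector loop_off,
                       IntegerVector closed, NumericVector ell, double kappa2,
                       IntegerVector ba, IntegerVector bb, IntegerVector bwall,
                       NumericVector bk, double dmax, NumericMatrix wall) {
  const double* px = x.begin();
  double E = 0.0;
  int nl = loop_off.size() - 1;
  for (int l = 0; l < nl; ++l) {
    int s = loop_off[l], e = loop_off[l + 1], n = e - s;
    bool cl = closed[l] != 0;
    int nseg = cl ? n : n - 1;
    for (int k = 0; k < nseg; ++k) {
      int i = s + k, j = s + (k + 1) % n;
      double L = ell[i];
      double d = seglen(px, i, j);
      double eps = d / L - 1.0;
      E += 0.5 * eps * eps * L;
    }
    // bending at nodes with two incident segments
    int k0 = cl ? 0 : 1, k1 = cl ? n : n - 1;
    for (int k = k0; k < k1; ++k) {
      int j = s + k;
      int jm = s + (k - 1 + n) % n, jp = s + (k + 1) % n;
      double e1x = px[2 * j] - px[2 * jm], e1y = px[2 * j + 1] - px[2 * jm + 1];
      double e2x = px[2 * jp] - px[2 * j], e2y = px[2 * jp + 1] - px[2 * j + 1];
      double cr = e1x * e2y - e1y * e2x, dt = e1x * e2x + e1y * e2y;
      double th = std::atan2(cr, dt);
      double a = 0.5 * (ell[jm] + ell[j]);
      E += 0.5 * kappa2 * th * th / a;
    }
  }
  int nb = ba.size();
  for (int b = 0; b < nb; ++b) {
    int i = ba[b];
    double qx, qy;
    if (bwall[b]) {
      qx = wall(bb[b], 0); qy = wall(bb[b], 1);
    } else {
      qx = px[2 * bb[b]]; qy = px[2 * bb[b] + 1];
    }
    double dx = px[2 * i] - qx, dy = px[2 * i + 1] - qy;
    double del = std::sqrt(dx * dx + dy * dy);
    double u = (del <= dmax) ? (del - 1.0) : (dmax - 1.0);
    E += 0.5 * bk[b] * u * u;
  }
  return E;
}

// [[Rcpp::export]]
NumericVector acam_grad_cpp(NumericVector x, IntegerVector loop_off,
                            IntegerVector closed, NumericVector ell,
                            double kappa2, IntegerVector ba, IntegerVector bb,
                            IntegerVector bwall, NumericVector bk, double dmax,
                            NumericMatrix wall) {
  const double* px = x.begin();
  NumericVector g(x.size());
  double* pg = g.begin();
  int nl = loop_off.size() - 1;
  for (int l = 0; l < nl; ++l) {
    int s = loop_off[l], e = loop_off[l + 1], n = e - s;
    bool cl = closed[l] != 0;
    int nseg = cl ? n : n - 1;
    for (int k = 0; k < nseg; ++k) {
      int i = s + k, j = s + (k + 1) % n;
      double L = ell[i];
      double dx = px[2 * j] - px[2 * i], dy = px[2 * j + 1] - px[2 * i + 1];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d <= 0) continue;  // coincident nodes: no defined direction
      double f = (d / L - 1.0);  // dE/dd
      double ux = dx / d, uy = dy / d;
      pg[2 * j] += f * ux;     pg[2 * j + 1] += f * uy;
      pg[2 * i] -= f * ux;     pg[2 * i + 1] -= f * uy;
    }
    int k0 = cl ? 0 : 1, k1 = cl ? n : n - 1;
    for (int k = k0; k < k1; ++k) {
      int j = s + k;
      int jm = s + (k - 1 + n) % n, jp = s + (k + 1) % n;
      double e1x = px[2 * j] - px[2 * jm], e1y = px[2 * j + 1] - px[2 * jm + 1];
      double e2x = px[2 * jp] - px[2 * j], e2y = px[2 * jp + 1] - px[2 * j + 1];
      double n1 = e1x * e1x + e1y * e1y, n2 = e2x * e2x + e2y * e2y;
      if (n1 <= 0 || n2 <= 0) continue;
      double cr = e1x * e2y - e1y * e2x, dt = e1x * e2x + e1y * e2y;
      double th = std::atan2(cr, dt);
      double a = 0.5 * (ell[jm] + ell[j]);
      double dEdth = kappa2 * th / a;
      // d th / d e1 = -perp(e1)/|e1|^2 ; d th / d e2 = perp(e2)/|e2|^2
      double p1x = -e1y / n1, p1y = e1x / n1;
      double p2x = -e2y / n2, p2y = e2x / n2;
      // x_{jm}: de1 = -I  -> +perp(e1)/n1
      pg[2 * jm] += dEdth * p1x;      pg[2 * jm + 1] += dEdth * p1y;
      // x_j: de1 = +I, de2 = -I -> -p1 - p2
      pg[2 * j] += dEdth * (-p1x - p2x);
      pg[2 * j + 1] += dEdth * (-p1y - p2y);
      // x_{jp}: de2 = +I -> +p2
      pg[2 * jp] += dEdth * p2x;      pg[2 * jp + 1] += dEdth * p2y;
    }
  }
  int nb = ba.size();
  for (int b = 0; b < nb; ++b) {
    int i = ba[b];
    double qx, qy; bool fixedq = bwall[b] != 0;
    if (fixedq) { qx = wall(bb[b], 0); qy = wall(bb[b], 1); }
    else { qx = px[2 * bb[b]]; qy = px[2 * bb[b] + 1]; }
    double dx = px[2 * i] - qx, dy = px[2 * i + 1] - qy;
    double del = std::sqrt(dx * dx + dy * dy);
    if (del > dmax || del <= 0) continue;  // saturated: no force
    double f = bk[b] * (del - 1.0);
    double ux = dx / del, uy = dy / del;
    pg[2 * i] += f * ux; pg[2 * i + 1] += f * uy;
    if (!fixedq) { pg[2 * bb[b]] -= f * ux; pg[2 * bb[b] + 1] -= f * uy; }
  }
  return g;
}

// All cross-cell candidate pairs within `cutoff`, via a uniform grid hash.
// Tissue nodes carry positive cell ids; wall nodes (fixed) are a separate
// point set reported with wall = 1 and j indexing into the wall matrix.
// Tissue-tissue pairs are reported once (i < j).
// [[Rcpp::export]]
DataFrame neighbor_pairs_cpp(NumericMatrix pts, IntegerVector cell,
                             NumericMatrix wall, double cutoff) {
  int n = pts.nrow(), nw = wall.nrow(), ntot = n + nw;
  std::vector<double> X(ntot), Y(ntot);
  std::vector<int> C(ntot);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); C[i] = cell[i]; }
  for (int i = 0; i < nw; ++i) { X[n + i] = wall(i, 0); Y[n + i] = wall(i, 1); C[n + i] = 0; }
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(ntot * 2);
  const double h = cutoff;
  for (int i = 0; i < ntot; ++i) {
    long long ix = (long long)std::floor(X[i] / h);
    long long iy = (long long)std::floor(Y[i] / h);
    grid[(ix << 32) ^ (iy & 0xffffffffLL)].push_back(i);
  }
  std::vector<int> ia, ib, iw;
  std::vector<double> dd;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < ntot; ++i) {
    long long ix = (long long)std::floor(X[i] / h);
    long long iy = (long long)std::floor(Y[i] / h);
    for (long long gx = ix - 1; gx <= ix + 1; ++gx)
      for (long long gy = iy - 1; gy <= iy + 1; ++gy) {
        auto it = grid.find((gx << 32) ^ (gy & 0xffffffffLL));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          if (C[i] == C[j]) continue;
          if (C[i] == 0 && C[j] == 0) continue;
          double dx = X[i] - X[j], dy = Y[i] - Y[j];
          double d2 = dx * dx + dy * dy;
          if (d2 > c2) continue;
          // orient: tissue node first; wall partner flagged
          int a = i, b = j;
          if (C[a] == 0) std::swap(a, b);
          bool w = C[b] == 0;
          ia.push_back(a + 1);
          ib.push_back(w ? (b - n + 1) : (b + 1));
          iw.push_back(w ? 1 : 0);
          dd.push_back(std::sqrt(d2));
        }
      }
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ib, _["wall"] = iw,
                           _["d"] = dd);
}

// Minimum distance from each query point to a polyline (optionally closed).
// [[Rcpp::export]]
NumericVector dist_to_polyline_cpp(NumericMatrix q, NumericMatrix poly,
                                   bool closed) {
  int nq = q.nrow(), np = poly.nrow();
  NumericVector out(nq);
  int nseg = closed ? np : np - 1;
  for (int k = 0; k < nq; ++k) {
    double qx = q(k, 0), qy = q(k, 1);
    double best = R_PosInf;
    for (int s = 0; s < nseg; ++s) {
      int t = (s + 1) % np;
      double ax = poly(s, 0), ay = poly(s, 1);
      double bx = poly(t, 0), by = poly(t, 1);
      double ex = bx - ax, ey = by - ay;
      double L2 = ex * ex + ey * ey;
      double u = L2 > 0 ? ((qx - ax) * ex + (qy - ay) * ey) / L2 : 0.0;
      if (u < 0) u = 0; else if (u > 1) u = 1;
      double dx = qx - (ax + u * ex), dy = qy - (ay + u * ey);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}
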