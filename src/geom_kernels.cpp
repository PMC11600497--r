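#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-atom solvent-accessible surface area by probe-inflated sphere dot
// sampling. `sphere` is a fixed unit point set (deterministic, no RNG);
// accuracy is governed by its size, not by randomness.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, NumericMatrix sphere) {
  const int n = coords.nrow(), m = sphere.nrow();
  NumericVector area(n);
  std::vector<double> rx(n);
  for (int i = 0; i < n; ++i) rx[i] = radii[i] + probe;
  std::vector<int> nb; nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i,0), yi = coords(i,1), zi = coords(i,2);
    const double ri = rx[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j,0)-xi, dy = coords(j,1)-yi, dz = coords(j,2)-zi;
      const double lim = ri + rx[j];
      if (dx*dx + dy*dy + dz*dz < lim*lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri*sphere(k,0);
      const double py = yi + ri*sphere(k,1);
      const double pz = zi + ri*sphere(k,2);
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px-coords(j,0), dy = py-coords(j,1), dz = pz-coords(j,2);
        if (dx*dx + dy*dy + dz*dz < rx[j]*rx[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0*M_PI*ri*ri*((double)acc/(double)m);
  }
  return area;
}

// Accessible contact-surface dots: points on the van der Waals sphere of each
// atom whose probe-inflated image lies on the solvent-accessible surface.
// Returns position (at vdW radius), outward normal and the owning atom index.
// [[Rcpp::export]]
List cpp_surface_dots(NumericMatrix coords, NumericVector radii,
                      double probe, NumericMatrix sphere) {
  const int n = coords.nrow(), m = sphere.nrow();
  std::vector<double> rx(n);
  for (int i = 0; i < n; ++i) rx[i] = radii[i] + probe;
  std::vector<double> px, py, pz, nx, ny, nz;
  std::vector<int> owner;
  std::vector<int> nb; nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i,0), yi = coords(i,1), zi = coords(i,2);
    const double ri = rx[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j,0)-xi, dy = coords(j,1)-yi, dz = coords(j,2)-zi;
      const double lim = ri + rx[j];
      if (dx*dx + dy*dy + dz*dz < lim*lim) nb.push_back(j);
    }
    for (int k = 0; k < m; ++k) {
      const double sx = sphere(k,0), sy = sphere(k,1), sz = sphere(k,2);
      const double qx = xi + ri*sx, qy = yi + ri*sy, qz = zi + ri*sz;
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = qx-coords(j,0), dy = qy-coords(j,1), dz = qz-coords(j,2);
        if (dx*dx + dy*dy + dz*dz < rx[j]*rx[j]) { free_pt = false; break; }
      }
      if (free_pt) {
        px.push_back(xi + radii[i]*sx);
        py.push_back(yi + radii[i]*sy);
        pz.push_back(zi + radii[i]*sz);
        nx.push_back(sx); ny.push_back(sy); nz.push_back(sz);
        owner.push_back(i + 1);
      }
    }
  }
  const int np = px.size();
  NumericMatrix P(np, 3), N(np, 3);
  IntegerVector at(np);
  for (int i = 0; i < np; ++i) {
    P(i,0)=px[i]; P(i,1)=py[i]; P(i,2)=pz[i];
    N(i,0)=nx[i]; N(i,1)=ny[i]; N(i,2)=nz[i];
    at[i]=owner[i];
  }
  return List::create(_["points"]=P, _["normals"]=N, _["atom"]=at);
}

// Nearest neighbour in B for every row of A (brute force).
// [[Rcpp::export]]
List cpp_nn(NumericMatrix A, NumericMatrix B) {
  const int m = A.nrow(), n = B.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf; int bj = 0;
    const double xi = A(i,0), yi = A(i,1), zi = A(i,2);
    for (int j = 0; j < n; ++j) {
      const double dx = B(j,0)-xi, dy = B(j,1)-yi, dz = B(j,2)-zi;
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"]=idx, _["dist"]=dist);
}

// Minimum inter-set distance with early exit below `stop_below`.
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B, double stop_below) {
  double best = R_PosInf;
  const double s2 = stop_below*stop_below;
  for (int i = 0; i < A.nrow(); ++i) {
    const double xi = A(i,0), yi = A(i,1), zi = A(i,2);
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = B(j,0)-xi, dy = B(j,1)-yi, dz = B(j,2)-zi;
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) {
        best = d2;
        if (best < s2) return std::sqrt(best);
      }
    }
  }
  return std::sqrt(best);
}
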