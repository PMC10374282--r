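#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grid flood-fill for the accessible volume of a tethered label.
// Cells lie on a cubic grid centred at the anchor; a cell is free when it
// is within the linker length of the anchor and clears every bead by
// bead_radius + label_radius (the attachment bead never obstructs).
// Connectivity is 26-neighbour; seeds are the free cells within
// seed_radius of the anchor.
// [[Rcpp::export]]
NumericMatrix cpp_accessible_volume(NumericVector anchor, NumericMatrix beads,
                                    NumericVector radii, int exclude,
                                    double linker, double label_radius,
                                    double spacing, double seed_radius) {
  const int ng = (int)std::floor(linker / spacing);
  const int dim = 2 * ng + 1;
  const int ncell = dim * dim * dim;
  std::vector<char> state(ncell, 0); // 0 blocked/outside, 1 free, 2 reached
  const int nb = beads.nrow();
  const double L2 = linker * linker;

  for (int iz = 0; iz < dim; ++iz) {
    const double z = (iz - ng) * spacing;
    for (int iy = 0; iy < dim; ++iy) {
      const double y = (iy - ng) * spacing;
      for (int ix = 0; ix < dim; ++ix) {
        const double x = (ix - ng) * spacing;
        if (x * x + y * y + z * z > L2) continue;
        const double px = anchor[0] + x, py = anchor[1] + y, pz = anchor[2] + z;
        bool clash = false;
        for (int b = 0; b < nb; ++b) {
          if (b == exclude) continue;
          const double rc = radii[b] + label_radius;
          const double dx = px - beads(b, 0);
          const double dy = py - beads(b, 1);
          const double dz = pz - beads(b, 2);
          if (dx * dx + dy * dy + dz * dz <= rc * rc) { clash = true; break; }
        }
        if (!clash) state[ix + dim * (iy + dim * iz)] = 1;
      }
    }
  }

  std::queue<int> q;
  const double s2 = seed_radius * seed_radius;
  for (int iz = 0; iz < dim; ++iz)
    for (int iy = 0; iy < dim; ++iy)
      for (int ix = 0; ix < dim; ++ix) {
        const int id = ix + dim * (iy + dim * iz);
        if (state[id] != 1) continue;
        const double x = (ix - ng) * spacing, y = (iy - ng) * spacing,
                     z = (iz - ng) * spacing;
        if (x * x + y * y + z * z <= s2) { state[id] = 2; q.push(id); }
      }

  while (!q.empty()) {
    const int id = q.front(); q.pop();
    const int ix = id % dim, iy = (id / dim) % dim, iz = id / (dim * dim);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= dim || jy >= dim || jz >= dim)
            continue;
          const int jd = jx + dim * (jy + dim * jz);
          if (state[jd] == 1) { state[jd] = 2; q.push(jd); }
        }
  }

  int n = 0;
  for (int i = 0; i < ncell; ++i) if (state[i] == 2) ++n;
  NumericMatrix pts(n, 3);
  int k = 0;
  for (int iz = 0; iz < dim; ++iz)
    for (int iy = 0; iy < dim; ++iy)
      for (int ix = 0; ix < dim; ++ix)
        if (state[ix + dim * (iy + dim * iz)] == 2) {
          pts(k, 0) = anchor[0] + (ix - ng) * spacing;
          pts(k, 1) = anchor[1] + (iy - ng) * spacing;
          pts(k, 2) = anchor[2] + (iz - ng) * spacing;
          ++k;
        }
  return pts;
}

// Weighted pairwise-distance statistics between two point clouds:
// histogram over `breaks`, weighted sums of R and R^2, and the weighted sum
// of FRET efficiencies 1/(1+(R/R0)^6) (coincident points count E = 1).
// [[Rcpp::export]]
List cpp_pair_stats(NumericMatrix a, NumericVector wa,
                    NumericMatrix b, NumericVector wb,
                    double r0, NumericVector breaks) {
  const int na = a.nrow(), nb = b.nrow();
  const int nbin = breaks.size() - 1;
  const double lo = breaks[0], hi = breaks[nbin];
  const double bw = (hi - lo) / nbin;
  NumericVector hist(nbin);
  const double r02 = r0 * r0;
  double sw = 0, sr = 0, sr2 = 0, se = 0;
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2), wi = wa[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      const double w = wi * wb[j];
      sw += w; sr += w * r; sr2 += w * r2;
      const double s = r2 / r02;          // (r/r0)^6 = s^3
      se += (r <= 0.0) ? w : w / (1.0 + s * s * s);
      if (r >= lo && r < hi) {
        const int k = (int)((r - lo) / bw);
        if (k >= 0 && k < nbin) hist[k] += w;
      } else if (r == hi) {
        hist[nbin - 1] += w;
      }
    }
  }
  return List::create(_["hist"] = hist, _["sw"] = sw, _["sum_r"] = sr,
                      _["sum_r2"] = sr2, _["sum_e"] = se);
}

// Debye sum over precomputed pair distances: I(q) = sum_ij b_i b_j sinc(q r_ij).
// `d` are the n(n-1)/2 off-diagonal distances with pair weights `bp`;
// `self` is sum(b_i^2).
// [[Rcpp::export]]
NumericVector cpp_debye(NumericVector q, NumericVector d, NumericVector bp,
                        double self) {
  const int nq = q.size(), nd = d.size();
  NumericVector I(nq);
  for (int iq = 0; iq < nq; ++iq) {
    const double qq = q[iq];
    double s = self;
    if (qq <= 0) {
      for (int k = 0; k < nd; ++k) s += 2.0 * bp[k];
    } else {
      for (int k = 0; k < nd; ++k) {
        const double x = qq * d[k];
        s += 2.0 * bp[k] * ((x < 1e-8) ? 1.0 : std::sin(x) / x);
      }
    }
    I[iq] = s;
  }
  return I;
}
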