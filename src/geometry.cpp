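#include <Rcpp.h>
using namespace Rcpp;

// minimum-image component for an orthorhombic box
static inline double mi(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double mi_dist2(const double* xyz, int n, const double* box,
                              int i, int j) {
  double dx = mi(xyz[j] - xyz[i], box[0]);
  double dy = mi(xyz[j + n] - xyz[i + n], box[1]);
  double dz = mi(xyz[j + 2 * n] - xyz[i + 2 * n], box[2]);
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_min_image_distance(NumericMatrix xyz, NumericVector box,
                                     IntegerVector i, IntegerVector j) {
  int n = xyz.nrow(), np = i.size();
  NumericVector out(np);
  for (int k = 0; k < np; ++k)
    out[k] = std::sqrt(mi_dist2(xyz.begin(), n, box.begin(), i[k], j[k]));
  return out;
}

// For each atom in `from`, minimum-image distance to the nearest atom in `to`.
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericMatrix xyz, NumericVector box,
                                  IntegerVector from, IntegerVector to) {
  int n = xyz.nrow();
  NumericVector out(from.size());
  for (int f = 0; f < from.size(); ++f) {
    double best = R_PosInf;
    for (int t = 0; t < to.size(); ++t) {
      double d2 = mi_dist2(xyz.begin(), n, box.begin(), from[f], to[t]);
      if (d2 < best) best = d2;
    }
    out[f] = std::sqrt(best);
  }
  return out;
}

// Geometric hydrogen-bond detection: donor-acceptor distance cutoff plus
// hydrogen-donor-acceptor angle cutoff. dh holds 0-based (donor, hydrogen)
// columns, one row per covalent D-H pair; acc holds acceptor heavy atoms.
// [[Rcpp::export]]
IntegerMatrix cpp_hbonds(NumericMatrix xyz, NumericVector box,
                         IntegerMatrix dh, IntegerVector acc,
                         double rcut, double amax_deg) {
  int n = xyz.nrow();
  const double* p = xyz.begin();
  const double* b = box.begin();
  double cosmin = std::cos(amax_deg * M_PI / 180.0);
  double rcut2 = rcut * rcut;
  std::vector<int> vd, vh, va;
  for (int k = 0; k < dh.nrow(); ++k) {
    int d = dh(k, 0), h = dh(k, 1);
    double hx = mi(p[h] - p[d], b[0]);
    double hy = mi(p[h + n] - p[d + n], b[1]);
    double hz = mi(p[h + 2 * n] - p[d + 2 * n], b[2]);
    double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
    for (int m = 0; m < acc.size(); ++m) {
      int a = acc[m];
      if (a == d) continue;
      double ax = mi(p[a] - p[d], b[0]);
      double ay = mi(p[a + n] - p[d + n], b[1]);
      double az = mi(p[a + 2 * n] - p[d + 2 * n], b[2]);
      double r2 = ax * ax + ay * ay + az * az;
      if (r2 > rcut2 || r2 == 0.0) continue;
      double r = std::sqrt(r2);
      double c = (hx * ax + hy * ay + hz * az) / (hn * r);
      if (c >= cosmin) {
        vd.push_back(d); vh.push_back(h); va.push_back(a);
      }
    }
  }
  IntegerMatrix out(vd.size(), 3);
  for (size_t k = 0; k < vd.size(); ++k) {
    out(k, 0) = vd[k]; out(k, 1) = vh[k]; out(k, 2) = va[k];
  }
  return out;
}

// Water-oxygen -> protein-atom pair histogram, optionally accumulating the
// orientational order parameter 3cos^2(theta)-1 where theta is the angle
// between the O->atom vector and the water-plane normal (cross product of
// the two O-H bond vectors).
// [[Rcpp::export]]
List cpp_rdf_aniso(NumericMatrix xyz, NumericVector box,
                   IntegerVector oidx, IntegerVector h1idx,
                   IntegerVector h2idx, IntegerVector pidx,
                   double bw, double rmax, bool do_aniso) {
  int n = xyz.nrow();
  const double* p = xyz.begin();
  const double* b = box.begin();
  int nb = (int)std::ceil(rmax / bw - 1e-9);
  NumericVector counts(nb), s(nb);
  double rmax2 = rmax * rmax;
  for (int w = 0; w < oidx.size(); ++w) {
    int o = oidx[w];
    double nx = 0, ny = 0, nz = 0;
    if (do_aniso) {
      int h1 = h1idx[w], h2 = h2idx[w];
      double ax = mi(p[h1] - p[o], b[0]);
      double ay = mi(p[h1 + n] - p[o + n], b[1]);
      double az = mi(p[h1 + 2 * n] - p[o + 2 * n], b[2]);
      double cx = mi(p[h2] - p[o], b[0]);
      double cy = mi(p[h2 + n] - p[o + n], b[1]);
      double cz = mi(p[h2 + 2 * n] - p[o + 2 * n], b[2]);
      nx = ay * cz - az * cy;
      ny = az * cx - ax * cz;
      nz = ax * cy - ay * cx;
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nn < 1e-10)
        stop("degenerate water geometry: collinear O-H vectors");
      nx /= nn; ny /= nn; nz /= nn;
    }
    for (int m = 0; m < pidx.size(); ++m) {
      int a = pidx[m];
      double dx = mi(p[a] - p[o], b[0]);
      double dy = mi(p[a + n] - p[o + n], b[1]);
      double dz = mi(p[a + 2 * n] - p[o + 2 * n], b[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rmax2 || r2 == 0.0) continue;
      double r = std::sqrt(r2);
      int bin = (int)(r / bw);
      if (bin >= nb) bin = nb - 1;
      counts[bin] += 1.0;
      if (do_aniso) {
        double c = (dx * nx + dy * ny + dz * nz) / r;
        s[bin] += 3.0 * c * c - 1.0;
      }
    }
  }
  return List::create(_["counts"] = counts, _["s"] = s);
}

// Pairwise nonbonded decomposition: Lennard-Jones 12-6 with Lorentz-Berthelot
// combination and truncated Coulomb, split by segment pair into
// protein-protein / protein-water / water-water. Pairs within the same
// molecule id are excluded, and so are protein pairs in adjacent residues
// (covering bonded 1-2/1-3 neighbours across the peptide bond).
// segcode: 0 = protein, 1 = water, 2 = ion (grouped with water).
// [[Rcpp::export]]
NumericVector cpp_nonbonded_decompose(NumericMatrix xyz, NumericVector box,
                                      NumericVector sigma, NumericVector eps,
                                      NumericVector charge,
                                      IntegerVector segcode,
                                      IntegerVector molid, double cutoff) {
  const double FQQ = 138.935485;  // kJ nm mol^-1 e^-2
  int n = xyz.nrow();
  const double* p = xyz.begin();
  const double* b = box.begin();
  double cut2 = cutoff * cutoff;
  // 0: vdw_pp, 1: vdw_pw, 2: vdw_ww, 3: coul_pp, 4: coul_pw, 5: coul_ww
  NumericVector out(6);
  for (int i = 0; i < n - 1; ++i) {
    bool pi = segcode[i] == 0;
    for (int j = i + 1; j < n; ++j) {
      if (molid[i] == molid[j]) continue;
      if (segcode[i] == 0 && segcode[j] == 0 &&
          std::abs(molid[i] - molid[j]) <= 1) continue;
      double dx = mi(p[j] - p[i], b[0]);
      double dy = mi(p[j + n] - p[i + n], b[1]);
      double dz = mi(p[j + 2 * n] - p[i + 2 * n], b[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      if (r2 == 0.0) stop("zero interatomic distance in nonbonded pair");
      bool pj = segcode[j] == 0;
      int cat = pi && pj ? 0 : (pi || pj ? 1 : 2);
      double r = std::sqrt(r2);
      double sig = 0.5 * (sigma[i] + sigma[j]);
      double e = std::sqrt(eps[i] * eps[j]);
      if (e > 0.0 && sig > 0.0) {
        double sr2 = sig * sig / r2;
        double sr6 = sr2 * sr2 * sr2;
        out[cat] += 4.0 * e * (sr6 * sr6 - sr6);
      }
      if (charge[i] != 0.0 && charge[j] != 0.0)
        out[3 + cat] += FQQ * charge[i] * charge[j] / r;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nonbonded_pair(NumericMatrix xyz, NumericVector box,
                                 NumericVector sigma, NumericVector eps,
                                 NumericVector charge, int i, int j,
                                 double cutoff) {
  const double FQQ = 138.935485;
  int n = xyz.nrow();
  double r2 = mi_dist2(xyz.begin(), n, box.begin(), i, j);
  if (r2 == 0.0) stop("zero interatomic distance");
  NumericVector out(2);
  if (r2 > cutoff * cutoff) return out;
  double r = std::sqrt(r2);
  double sig = 0.5 * (sigma[i] + sigma[j]);
  double e = std::sqrt(eps[i] * eps[j]);
  if (e > 0.0 && sig > 0.0) {
    double sr6 = std::pow(sig * sig / r2, 3.0);
    out[0] = 4.0 * e * (sr6 * sr6 - sr6);
  }
  out[1] = FQQ * charge[i] * charge[j] / r;
  return out;
}
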