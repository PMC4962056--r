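#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Rigid-body Metropolis Monte Carlo for TIP4P/2005 water in the NVT
// ensemble. Lennard-Jones on oxygen, point charges on the two hydrogens and
// the in-plane M site; molecule-based spherical truncation on the O-O
// distance so that charge groups are never split by the cutoff, with a
// conducting-boundary reaction field (eps_rf -> infinity) accounting for
// the electrostatics beyond the cutoff.

namespace {

const double KB = 0.008314462618;   // kJ/mol/K
const double FQQ = 138.935485;      // kJ nm mol^-1 e^-2
const double SIG = 0.31589;         // nm
const double EPS = 0.7749;          // kJ/mol
const double QH = 0.5564;           // e
const double QM = -2.0 * QH;
const double DOM = 0.01546;         // nm, O->M along the HOH bisector

struct Vec { double x, y, z; };

inline double mi(double d, double L) { return d - L * std::round(d / L); }

struct WaterSystem {
  int n;
  std::vector<Vec> o, h1, h2, m;  // o absolute; h1/h2/m relative to o
  double bx, by, bz, rc2;
  double krf, crf;  // reaction-field constants: B/rc^3 and (1+B)/rc, B=1/2

  void set_m(int i) {
    double sx = h1[i].x + h2[i].x, sy = h1[i].y + h2[i].y,
           sz = h1[i].z + h2[i].z;
    double nn = std::sqrt(sx * sx + sy * sy + sz * sz);
    m[i] = {DOM * sx / nn, DOM * sy / nn, DOM * sz / nn};
  }

  // interaction energy of molecule i (at position oi with site set s) with j
  double pair_energy(const Vec& oi, const Vec& s1, const Vec& s2,
                     const Vec& sm, int j) const {
    double dx = mi(o[j].x - oi.x, bx);
    double dy = mi(o[j].y - oi.y, by);
    double dz = mi(o[j].z - oi.z, bz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) return 0.0;
    double sr2 = SIG * SIG / r2;
    double sr6 = sr2 * sr2 * sr2;
    double e = 4.0 * EPS * (sr6 * sr6 - sr6);
    const Vec* ai[3] = {&s1, &s2, &sm};
    const Vec* aj[3] = {&h1[j], &h2[j], &m[j]};
    const double qi[3] = {QH, QH, QM};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double ex = dx + aj[b]->x - ai[a]->x;
        double ey = dy + aj[b]->y - ai[a]->y;
        double ez = dz + aj[b]->z - ai[a]->z;
        double rr2 = ex * ex + ey * ey + ez * ez;
        e += FQQ * qi[a] * qi[b] *
             (1.0 / std::sqrt(rr2) + krf * rr2 - crf);
      }
    return e;
  }

  double mol_energy(const Vec& oi, const Vec& s1, const Vec& s2,
                    const Vec& sm, int skip) const {
    double e = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != skip) e += pair_energy(oi, s1, s2, sm, j);
    return e;
  }

  double total_energy() const {
    double e = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j)
        e += pair_energy(o[i], h1[i], h2[i], m[i], j);
    return e;
  }
};

inline Vec rodrigues(const Vec& v, const Vec& k, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  double dot = k.x * v.x + k.y * v.y + k.z * v.z;
  Vec cr = {k.y * v.z - k.z * v.y, k.z * v.x - k.x * v.z,
            k.x * v.y - k.y * v.x};
  return {v.x * c + cr.x * s + k.x * dot * (1 - c),
          v.y * c + cr.y * s + k.y * dot * (1 - c),
          v.z * c + cr.z * s + k.z * dot * (1 - c)};
}

}  // namespace

// o: n x 3 oxygen positions (nm); h1rel/h2rel: n x 3 O->H vectors.
// Returns sampled frames (each 3n x 3, atoms ordered O,H1,H2 per molecule),
// an energy trace (kJ/mol per molecule, one entry per sweep), and the
// production acceptance rate.
// [[Rcpp::export]]
List cpp_water_mc(NumericMatrix o, NumericMatrix h1rel, NumericMatrix h2rel,
                  NumericVector box, double tempK, double rc,
                  int n_equil, int n_prod, int sample_every, int seed,
                  double dt0, double dr0) {
  WaterSystem sys;
  sys.n = o.nrow();
  sys.bx = box[0]; sys.by = box[1]; sys.bz = box[2];
  sys.rc2 = rc * rc;
  sys.krf = 0.5 / (rc * rc * rc);
  sys.crf = 1.5 / rc;
  sys.o.resize(sys.n); sys.h1.resize(sys.n);
  sys.h2.resize(sys.n); sys.m.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) {
    sys.o[i] = {o(i, 0), o(i, 1), o(i, 2)};
    sys.h1[i] = {h1rel(i, 0), h1rel(i, 1), h1rel(i, 2)};
    sys.h2[i] = {h2rel(i, 0), h2rel(i, 1), h2rel(i, 2)};
    sys.set_m(i);
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  auto runif_s = [&](double a) { return a * (2.0 * U(rng) - 1.0); };
  auto rand_axis = [&]() {
    double x1, x2, s;
    do {
      x1 = 2.0 * U(rng) - 1.0; x2 = 2.0 * U(rng) - 1.0;
      s = x1 * x1 + x2 * x2;
    } while (s >= 1.0);
    double f = 2.0 * std::sqrt(1.0 - s);
    Vec v = {x1 * f, x2 * f, 1.0 - 2.0 * s};
    return v;
  };

  double beta = 1.0 / (KB * tempK);
  double dt = dt0, dr = dr0;
  long acc = 0, tot = 0;
  int n_sweeps = n_equil + n_prod;
  std::vector<double> etrace;
  etrace.reserve(n_sweeps / 10 + 1);
  List frames;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int mv = 0; mv < sys.n; ++mv) {
      int i = (int)(U(rng) * sys.n);
      if (i == sys.n) i = sys.n - 1;
      Vec no = sys.o[i], n1 = sys.h1[i], n2 = sys.h2[i], nm = sys.m[i];
      if (U(rng) < 0.5) {
        no.x += runif_s(dt); no.y += runif_s(dt); no.z += runif_s(dt);
      } else {
        Vec ax = rand_axis();
        double ang = runif_s(dr);
        n1 = rodrigues(n1, ax, ang);
        n2 = rodrigues(n2, ax, ang);
        nm = rodrigues(nm, ax, ang);
      }
      double e_old = sys.mol_energy(sys.o[i], sys.h1[i], sys.h2[i],
                                    sys.m[i], i);
      double e_new = sys.mol_energy(no, n1, n2, nm, i);
      double de = e_new - e_old;
      ++tot;
      if (de <= 0.0 || U(rng) < std::exp(-beta * de)) {
        sys.o[i] = no; sys.h1[i] = n1; sys.h2[i] = n2; sys.m[i] = nm;
        // keep oxygens wrapped into the primary box
        sys.o[i].x -= sys.bx * std::floor(sys.o[i].x / sys.bx);
        sys.o[i].y -= sys.by * std::floor(sys.o[i].y / sys.by);
        sys.o[i].z -= sys.bz * std::floor(sys.o[i].z / sys.bz);
        ++acc;
      }
    }
    // adapt move amplitudes over the first half of equilibration only,
    // targeting ~40% acceptance; frozen afterwards (detailed balance)
    if (sweep < n_equil / 2 && (sweep + 1) % 25 == 0) {
      double ar = (double)acc / (double)tot;
      double f = ar > 0.45 ? 1.1 : (ar < 0.35 ? 0.9 : 1.0);
      dt = std::min(0.15, std::max(0.002, dt * f));
      dr = std::min(1.5, std::max(0.02, dr * f));
      acc = 0; tot = 0;
    }
    if (sweep == n_equil - 1) { acc = 0; tot = 0; }
    if ((sweep + 1) % 10 == 0)
      etrace.push_back(sys.total_energy() / sys.n);
    if (sweep >= n_equil && (sweep - n_equil + 1) % sample_every == 0) {
      NumericMatrix fr(3 * sys.n, 3);
      for (int i = 0; i < sys.n; ++i) {
        fr(3 * i, 0) = sys.o[i].x;
        fr(3 * i, 1) = sys.o[i].y;
        fr(3 * i, 2) = sys.o[i].z;
        fr(3 * i + 1, 0) = sys.o[i].x + sys.h1[i].x;
        fr(3 * i + 1, 1) = sys.o[i].y + sys.h1[i].y;
        fr(3 * i + 1, 2) = sys.o[i].z + sys.h1[i].z;
        fr(3 * i + 2, 0) = sys.o[i].x + sys.h2[i].x;
        fr(3 * i + 2, 1) = sys.o[i].y + sys.h2[i].y;
        fr(3 * i + 2, 2) = sys.o[i].z + sys.h2[i].z;
      }
      frames.push_back(fr);
    }
  }
  double arate = tot > 0 ? (double)acc / (double)tot : NA_REAL;
  return List::create(_["frames"] = frames,
                      _["energy_trace"] = wrap(etrace),
                      _["acceptance"] = arate,
                      _["dt"] = dt, _["dr"] = dr);
}
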