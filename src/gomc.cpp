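#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Phi-restrained simulated annealing on a C-alpha Go-type model.
// Energy terms: harmonic bonds and angles toward native values, a
// 1-cos dihedral toward native, 12-10 wells on native residue-pair contacts
// (depth proportional to the native atom-pair count), r^-12 excluded volume
// on non-native pairs, plus a harmonic restraint on per-conformation
// per-residue Phi-values: E_phi = k * sum_valid (Phi_i - Phi_exp_i)^2.
// Inside the restraint the formed-ness of a contact is a smooth logistic
// switch centred on fq * native distance (width lambda), so intermediate
// Phi targets have a usable gradient; the reported Q and Phi use the hard
// cutoff. Every Monte Carlo move displaces a single bead (random
// displacement or crankshaft rotation about the neighbour axis), so energy
// changes are evaluated incrementally.

namespace {

const double KB = 0.008314462618;  // kJ/mol/K

struct Vec { double x, y, z; };

inline Vec sub(const Vec& a, const Vec& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline double norm(const Vec& a) {
  return std::sqrt(a.x * a.x + a.y * a.y + a.z * a.z);
}
inline double dot(const Vec& a, const Vec& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec cross(const Vec& a, const Vec& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}

double angle3(const Vec& a, const Vec& b, const Vec& c) {
  Vec u = sub(a, b), v = sub(c, b);
  double cs = dot(u, v) / (norm(u) * norm(v));
  cs = std::max(-1.0, std::min(1.0, cs));
  return std::acos(cs);
}

double torsion4(const Vec& a, const Vec& b, const Vec& c, const Vec& d) {
  Vec b1 = sub(b, a), b2 = sub(c, b), b3 = sub(d, c);
  Vec n1 = cross(b1, b2), n2 = cross(b2, b3);
  Vec m = cross(n1, b2);
  double nb2 = norm(b2);
  double x = dot(n1, n2), y = dot(m, n2) / nb2;
  return std::atan2(y, x);
}

struct GoModel {
  int n;
  std::vector<Vec> x;
  std::vector<double> r0, th0, ph0;        // native internal coordinates
  double kb, ka, kd, eps_rep, srep, fq, k_restr, lambda;
  // contacts
  std::vector<int> ci, cj;
  std::vector<double> crn, cw, ceps;
  std::vector<int> formed;                  // hard flags (reported Q/Phi)
  std::vector<double> qc;                   // smooth formed-ness (restraint)
  std::vector<double> fw, tw;               // per-residue smooth/total weight
  std::vector<double> phi_exp;              // NA -> not restrained
  std::vector<std::vector<int> > res_contacts;  // contact ids per residue
  std::vector<int> cid;                     // n*n lookup, -1 if none

  double bond_e(int i) const {  // bond between i and i+1
    double d = norm(sub(x[i + 1], x[i])) - r0[i];
    return kb * d * d;
  }
  double angle_e(int i) const {  // angle i, i+1, i+2
    double d = angle3(x[i], x[i + 1], x[i + 2]) - th0[i];
    return ka * d * d;
  }
  double dih_e(int i) const {  // dihedral i..i+3
    return kd * (1.0 - std::cos(torsion4(x[i], x[i + 1], x[i + 2],
                                         x[i + 3]) - ph0[i]));
  }

  // bonded terms involving bead b
  double bonded_local(int b) const {
    double e = 0.0;
    for (int i = std::max(0, b - 1); i <= std::min(n - 2, b); ++i)
      e += bond_e(i);
    for (int i = std::max(0, b - 2); i <= std::min(n - 3, b); ++i)
      e += angle_e(i);
    for (int i = std::max(0, b - 3); i <= std::min(n - 4, b); ++i)
      e += dih_e(i);
    return e;
  }

  double contact_e(int c, double r) const {
    double sr = crn[c] / r;
    double sr2 = sr * sr;
    double sr10 = sr2 * sr2 * sr2 * sr2 * sr2;
    return ceps[c] * (5.0 * sr10 * sr2 - 6.0 * sr10);
  }
  double rep_e(double r) const {
    double sr = srep / r;
    double sr6 = sr * sr * sr; sr6 *= sr6;
    return eps_rep * sr6 * sr6;
  }

  double smooth_q(int c, double r) const {
    return 1.0 / (1.0 + std::exp((r - fq * crn[c]) / lambda));
  }

  double phi_of(int i) const { return tw[i] > 0 ? fw[i] / tw[i] : 0.0; }
  double restraint_term(int i) const {
    if (ISNAN(phi_exp[i]) || tw[i] <= 0) return 0.0;
    double d = phi_of(i) - phi_exp[i];
    return k_restr * d * d;
  }

  double go_energy() const {
    double e = 0.0;
    for (int i = 0; i < n - 1; ++i) e += bond_e(i);
    for (int i = 0; i < n - 2; ++i) e += angle_e(i);
    for (int i = 0; i < n - 3; ++i) e += dih_e(i);
    for (int i = 0; i < n - 2; ++i)
      for (int j = i + 2; j < n; ++j) {
        double r = norm(sub(x[j], x[i]));
        int c = cid[i * n + j];
        e += c >= 0 ? contact_e(c, r) : rep_e(r);
      }
    return e;
  }

  double restraint_energy() const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) e += restraint_term(i);
    return e;
  }

  void recount_formed() {
    std::fill(fw.begin(), fw.end(), 0.0);
    for (size_t c = 0; c < ci.size(); ++c) {
      double r = norm(sub(x[cj[c]], x[ci[c]]));
      formed[c] = r <= fq * crn[c] ? 1 : 0;
      qc[c] = smooth_q(c, r);
      fw[ci[c]] += cw[c] * qc[c];
      fw[cj[c]] += cw[c] * qc[c];
    }
  }

  // per-residue hard-cutoff Phi for reporting
  double hard_phi(int i) const {
    if (tw[i] <= 0) return NA_REAL;
    double f = 0.0;
    for (size_t k = 0; k < res_contacts[i].size(); ++k) {
      int c = res_contacts[i][k];
      if (formed[c]) f += cw[c];
    }
    return f / tw[i];
  }

  double q_value() const {
    double f = 0.0, t = 0.0;
    for (size_t c = 0; c < ci.size(); ++c) {
      t += cw[c];
      if (formed[c]) f += cw[c];
    }
    return t > 0 ? f / t : NA_REAL;
  }
};

}  // namespace

static void init_go(GoModel& g, NumericMatrix native, IntegerMatrix contacts,
                    NumericVector contact_rnat, NumericVector contact_w,
                    List params) {
  g.n = native.nrow();
  g.x.resize(g.n);
  for (int i = 0; i < g.n; ++i)
    g.x[i] = {native(i, 0), native(i, 1), native(i, 2)};
  g.kb = as<double>(params["k_bond"]);
  g.ka = as<double>(params["k_angle"]);
  g.kd = as<double>(params["k_dihedral"]);
  double eps = as<double>(params["epsilon"]);
  g.eps_rep = as<double>(params["eps_rep"]);
  g.srep = as<double>(params["sigma_rep"]);
  g.fq = as<double>(params["formed_factor"]);
  g.k_restr = as<double>(params["k_phi"]);
  g.r0.resize(g.n - 1); g.th0.resize(std::max(0, g.n - 2));
  g.ph0.resize(std::max(0, g.n - 3));
  for (int i = 0; i < g.n - 1; ++i) g.r0[i] = norm(sub(g.x[i + 1], g.x[i]));
  for (int i = 0; i < g.n - 2; ++i)
    g.th0[i] = angle3(g.x[i], g.x[i + 1], g.x[i + 2]);
  for (int i = 0; i < g.n - 3; ++i)
    g.ph0[i] = torsion4(g.x[i], g.x[i + 1], g.x[i + 2], g.x[i + 3]);
  g.lambda = as<double>(params["lambda"]);
  int nc = contacts.nrow();
  g.ci.resize(nc); g.cj.resize(nc); g.crn.resize(nc);
  g.cw.resize(nc); g.ceps.resize(nc); g.formed.assign(nc, 0);
  g.qc.assign(nc, 0.0);
  g.cid.assign(g.n * g.n, -1);
  g.res_contacts.assign(g.n, std::vector<int>());
  g.fw.assign(g.n, 0.0); g.tw.assign(g.n, 0.0);
  for (int c = 0; c < nc; ++c) {
    int i = contacts(c, 0), j = contacts(c, 1);
    g.ci[c] = i; g.cj[c] = j;
    g.crn[c] = contact_rnat[c];
    g.cw[c] = contact_w[c];
    g.ceps[c] = eps * contact_w[c];
    g.cid[i * g.n + j] = c; g.cid[j * g.n + i] = c;
    g.res_contacts[i].push_back(c);
    g.res_contacts[j].push_back(c);
    g.tw[i] += contact_w[c]; g.tw[j] += contact_w[c];
  }
}

// [[Rcpp::export]]
double cpp_go_energy(NumericMatrix native, NumericMatrix coords,
                     IntegerMatrix contacts, NumericVector contact_rnat,
                     NumericVector contact_w, List params) {
  GoModel g;
  init_go(g, native, contacts, contact_rnat, contact_w, params);
  for (int i = 0; i < g.n; ++i)
    g.x[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
  return g.go_energy();
}

// [[Rcpp::export]]
List cpp_go_anneal(NumericMatrix coords, IntegerMatrix contacts,
                   NumericVector contact_rnat, NumericVector contact_w,
                   NumericVector phi_exp, List params, int n_cycles,
                   int steps_per_cycle, double t_low, double t_high,
                   int seed, bool restart_native) {
  GoModel g;
  init_go(g, coords, contacts, contact_rnat, contact_w, params);
  std::vector<Vec> native_x = g.x;
  double dd = as<double>(params["step_xyz"]);
  double crank = as<double>(params["step_crank"]);
  g.phi_exp.resize(g.n);
  for (int i = 0; i < g.n; ++i) g.phi_exp[i] = phi_exp[i];
  g.recount_formed();

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  List frames;
  NumericVector qv(n_cycles), e_go(n_cycles), e_phi(n_cycles);
  NumericMatrix phi_sim(n_cycles, g.n);
  long acc = 0, tot = 0;

  std::vector<int> changed_c;     // contacts touched by the proposal
  std::vector<double> prop_qc;    // their proposed smooth formed-ness
  std::vector<int> touched;       // residues whose phi changes

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    if (restart_native && cyc > 0) {
      g.x = native_x;
      g.recount_formed();
    }
    for (int sw = 0; sw < steps_per_cycle; ++sw) {
      double fr = steps_per_cycle > 1
                      ? (double)sw / (double)(steps_per_cycle - 1) : 1.0;
      double T = t_high + (t_low - t_high) * fr;
      double beta = 1.0 / (KB * T);
      for (int mv = 0; mv < g.n; ++mv) {
        int b = (int)(U(rng) * g.n);
        if (b == g.n) b = g.n - 1;
        Vec old = g.x[b], prop = old;
        if (b > 0 && b < g.n - 1 && U(rng) < 0.5) {
          // crankshaft: rotate bead b about the (b-1, b+1) axis
          Vec ax = sub(g.x[b + 1], g.x[b - 1]);
          double an = norm(ax);
          if (an > 1e-9) {
            ax = {ax.x / an, ax.y / an, ax.z / an};
            double ang = crank * (2.0 * U(rng) - 1.0);
            Vec v = sub(old, g.x[b - 1]);
            double c = std::cos(ang), s = std::sin(ang);
            double kd_ = dot(ax, v);
            Vec cr = cross(ax, v);
            prop = {g.x[b - 1].x + v.x * c + cr.x * s + ax.x * kd_ * (1 - c),
                    g.x[b - 1].y + v.y * c + cr.y * s + ax.y * kd_ * (1 - c),
                    g.x[b - 1].z + v.z * c + cr.z * s + ax.z * kd_ * (1 - c)};
          }
        } else {
          prop.x += dd * (2.0 * U(rng) - 1.0);
          prop.y += dd * (2.0 * U(rng) - 1.0);
          prop.z += dd * (2.0 * U(rng) - 1.0);
        }

        double de = 0.0;
        // bonded
        de -= g.bonded_local(b);
        // pairwise + smooth formed-ness changes of b's contacts
        changed_c.clear();
        prop_qc.clear();
        double pw_old = 0.0, pw_new = 0.0;
        for (int j = 0; j < g.n; ++j) {
          if (std::abs(j - b) < 2) continue;
          double r_old = norm(sub(g.x[j], old));
          double r_new = norm(sub(g.x[j], prop));
          int c = g.cid[b * g.n + j];
          if (c >= 0) {
            pw_old += g.contact_e(c, r_old);
            pw_new += g.contact_e(c, r_new);
            changed_c.push_back(c);
            prop_qc.push_back(g.smooth_q(c, r_new));
          } else {
            pw_old += g.rep_e(r_old);
            pw_new += g.rep_e(r_new);
          }
        }
        // restraint delta over the residues whose smooth Phi changes
        double rest_old = 0.0, rest_new = 0.0;
        if (!changed_c.empty() && g.k_restr != 0.0) {
          touched.clear();
          for (size_t k = 0; k < changed_c.size(); ++k) {
            int c = changed_c[k];
            touched.push_back(g.ci[c]);
            touched.push_back(g.cj[c]);
          }
          std::sort(touched.begin(), touched.end());
          touched.erase(std::unique(touched.begin(), touched.end()),
                        touched.end());
          for (size_t k = 0; k < touched.size(); ++k)
            rest_old += g.restraint_term(touched[k]);
          for (size_t k = 0; k < changed_c.size(); ++k) {
            int c = changed_c[k];
            double dw = g.cw[c] * (prop_qc[k] - g.qc[c]);
            g.fw[g.ci[c]] += dw; g.fw[g.cj[c]] += dw;
          }
          for (size_t k = 0; k < touched.size(); ++k)
            rest_new += g.restraint_term(touched[k]);
          // roll back; re-applied on acceptance
          for (size_t k = 0; k < changed_c.size(); ++k) {
            int c = changed_c[k];
            double dw = g.cw[c] * (g.qc[c] - prop_qc[k]);
            g.fw[g.ci[c]] += dw; g.fw[g.cj[c]] += dw;
          }
        }
        g.x[b] = prop;
        de += g.bonded_local(b);
        g.x[b] = old;
        de += pw_new - pw_old + rest_new - rest_old;

        ++tot;
        if (de <= 0.0 || U(rng) < std::exp(-beta * de)) {
          g.x[b] = prop;
          for (size_t k = 0; k < changed_c.size(); ++k) {
            int c = changed_c[k];
            double dw = g.cw[c] * (prop_qc[k] - g.qc[c]);
            g.fw[g.ci[c]] += dw; g.fw[g.cj[c]] += dw;
            g.qc[c] = prop_qc[k];
          }
          ++acc;
        }
      }
    }
    // cycle end: sampled at t_low; retain
    g.recount_formed();  // guard against any drift in the flags
    NumericMatrix fr(g.n, 3);
    for (int i = 0; i < g.n; ++i) {
      fr(i, 0) = g.x[i].x; fr(i, 1) = g.x[i].y; fr(i, 2) = g.x[i].z;
    }
    frames.push_back(fr);
    qv[cyc] = g.q_value();
    e_go[cyc] = g.go_energy();
    e_phi[cyc] = g.restraint_energy();
    for (int i = 0; i < g.n; ++i)
      phi_sim(cyc, i) = g.hard_phi(i);
  }

  return List::create(_["frames"] = frames, _["q"] = qv,
                      _["e_go"] = e_go, _["e_phi"] = e_phi,
                      _["phi_sim"] = phi_sim,
                      _["acceptance"] = (double)acc / (double)tot);
}
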