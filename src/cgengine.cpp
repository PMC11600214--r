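// Coarse-grained C-alpha engine: structure-based potential (bonds,
// angles, dihedrals, 12-10 native-contact wells, truncated r^-12
// excluded volume, flat-bottom distance restraints), Langevin (BAOAB)
// dynamics, and well-tempered metadynamics over the two RMSD
// collective variables.  Units: nm, kJ/mol, ps, K.

#include <RcppArmadillo.h>
#include <random>
#include "rmsdcv.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KB = 0.008314; // kJ mol^-1 K^-1

struct CgModel {
  arma::mat bonds;      // i j r0 k
  arma::mat angles;     // i j k th0 kang
  arma::mat dihedrals;  // i j k l phi0 kdih
  arma::mat contacts;   // i j r0 eps
  arma::imat repul;     // i j
  arma::mat restraints; // i j r0 k
  double sigma_rep = 0.4, rcut_rep = 0.75, flat_width = 0.05;
  int n = 0;
};

static arma::mat get_mat(const List& m, const char* name, int ncol) {
  if (!m.containsElementNamed(name)) return arma::mat(0, ncol);
  NumericMatrix x = m[name];
  if (x.nrow() == 0) return arma::mat(0, ncol);
  arma::mat out(x.begin(), x.nrow(), x.ncol());
  return out;
}

static CgModel parse_model(const List& m) {
  CgModel g;
  g.n = as<int>(m["n"]);
  g.bonds = get_mat(m, "bonds", 4);
  g.angles = get_mat(m, "angles", 5);
  g.dihedrals = get_mat(m, "dihedrals", 6);
  g.contacts = get_mat(m, "contacts", 4);
  arma::mat rp = get_mat(m, "repulsion", 2);
  g.repul = arma::conv_to<arma::imat>::from(rp);
  g.restraints = get_mat(m, "restraints", 4);
  if (m.containsElementNamed("sigma_rep"))
    g.sigma_rep = as<double>(m["sigma_rep"]);
  if (m.containsElementNamed("rcut_rep"))
    g.rcut_rep = as<double>(m["rcut_rep"]);
  if (m.containsElementNamed("flat_width"))
    g.flat_width = as<double>(m["flat_width"]);
  return g;
}

// Energy and forces; returns energy, fills F (n x 3).  Terms vector:
// bond, angle, dihedral, contact, repulsion, restraint.
static double cg_energy_forces(const CgModel& g, const arma::mat& X,
                               arma::mat& F, arma::vec& terms,
                               bool* overlap) {
  F.zeros(g.n, 3);
  terms.zeros(6);
  if (overlap) *overlap = false;

  // bonds
  for (arma::uword b = 0; b < g.bonds.n_rows; ++b) {
    int i = int(g.bonds(b, 0)), j = int(g.bonds(b, 1));
    double r0 = g.bonds(b, 2), k = g.bonds(b, 3);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    terms(0) += 0.5 * k * (r - r0) * (r - r0);
    arma::rowvec f = -k * (r - r0) / std::max(r, 1e-12) * d;
    F.row(i) += f;
    F.row(j) -= f;
  }

  // angles: harmonic in theta
  for (arma::uword a = 0; a < g.angles.n_rows; ++a) {
    int i = int(g.angles(a, 0)), j = int(g.angles(a, 1)),
        k = int(g.angles(a, 2));
    double th0 = g.angles(a, 3), ka = g.angles(a, 4);
    arma::rowvec u = X.row(i) - X.row(j);
    arma::rowvec v = X.row(k) - X.row(j);
    double nu = arma::norm(u), nv = arma::norm(v);
    double ct = arma::dot(u, v) / std::max(nu * nv, 1e-12);
    ct = std::min(1.0, std::max(-1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-8));
    double dV = ka * (th - th0);
    terms(1) += 0.5 * ka * (th - th0) * (th - th0);
    arma::rowvec dthdi = (ct * u / nu - v / nv) / (nu * st);
    arma::rowvec dthdk = (ct * v / nv - u / nu) / (nv * st);
    F.row(i) -= dV * dthdi;
    F.row(k) -= dV * dthdk;
    F.row(j) += dV * (dthdi + dthdk);
  }

  // dihedrals: k[1-cos(phi-phi0)] + k/2[1-cos(3(phi-phi0))]
  for (arma::uword d0 = 0; d0 < g.dihedrals.n_rows; ++d0) {
    int i = int(g.dihedrals(d0, 0)), j = int(g.dihedrals(d0, 1)),
        k = int(g.dihedrals(d0, 2)), l = int(g.dihedrals(d0, 3));
    double phi0 = g.dihedrals(d0, 4), kd = g.dihedrals(d0, 5);
    arma::rowvec b1 = X.row(j) - X.row(i);
    arma::rowvec b2 = X.row(k) - X.row(j);
    arma::rowvec b3 = X.row(l) - X.row(k);
    arma::rowvec n1 = arma::cross(b1, b2);
    arma::rowvec n2 = arma::cross(b2, b3);
    double nb2 = arma::norm(b2);
    double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
    if (n1sq < 1e-14 || n2sq < 1e-14) continue;
    double x = arma::dot(n1, n2);
    double y = arma::dot(arma::cross(n1, n2), b2) / nb2;
    double phi = std::atan2(y, x);
    double dphi = phi - phi0;
    terms(2) += kd * (1.0 - std::cos(dphi)) +
                0.5 * kd * (1.0 - std::cos(3.0 * dphi));
    double dV = kd * std::sin(dphi) + 1.5 * kd * std::sin(3.0 * dphi);
    arma::rowvec dpdi = -(nb2 / n1sq) * n1;
    arma::rowvec dpdl = (nb2 / n2sq) * n2;
    double c12 = arma::dot(b1, b2) / (nb2 * nb2);
    double c32 = arma::dot(b3, b2) / (nb2 * nb2);
    arma::rowvec dpdj = -(1.0 + c12) * dpdi + c32 * dpdl;
    arma::rowvec dpdk = c12 * dpdi - (1.0 + c32) * dpdl;
    F.row(i) -= dV * dpdi;
    F.row(j) -= dV * dpdj;
    F.row(k) -= dV * dpdk;
    F.row(l) -= dV * dpdl;
  }

  // 12-10 contacts: eps*(5(r0/r)^12 - 6(r0/r)^10), minimum -eps at r0
  for (arma::uword c = 0; c < g.contacts.n_rows; ++c) {
    int i = int(g.contacts(c, 0)), j = int(g.contacts(c, 1));
    double r0 = g.contacts(c, 2), eps = g.contacts(c, 3);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    if (r < 1e-6) { if (overlap) *overlap = true; r = 1e-6; }
    double q = r0 / r;
    double q2 = q * q, q4 = q2 * q2, q10 = q4 * q4 * q2, q12 = q10 * q2;
    terms(3) += eps * (5.0 * q12 - 6.0 * q10);
    double dVdr = eps * (-60.0 * q12 + 60.0 * q10) / r;
    arma::rowvec f = -dVdr / r * d;
    F.row(i) += f;
    F.row(j) -= f;
  }

  // truncated-shifted excluded volume
  {
    double s2 = g.sigma_rep * g.sigma_rep;
    double rc2 = g.rcut_rep * g.rcut_rep;
    double qc = s2 / rc2;
    double shift = qc * qc * qc * qc * qc * qc; // (sigma/rc)^12
    for (arma::uword p = 0; p < g.repul.n_rows; ++p) {
      int i = g.repul(p, 0), j = g.repul(p, 1);
      arma::rowvec d = X.row(i) - X.row(j);
      double r2 = arma::dot(d, d);
      if (r2 >= rc2) continue;
      if (r2 < 1e-12) { if (overlap) *overlap = true; r2 = 1e-12; }
      double q2 = s2 / r2;
      double q12 = q2 * q2 * q2;
      q12 = q12 * q12;
      terms(4) += q12 - shift;
      double dVdr_r = -12.0 * q12 / r2; // (dV/dr)/r
      arma::rowvec f = -dVdr_r * d;
      F.row(i) += f;
      F.row(j) -= f;
    }
  }

  // flat-bottom harmonic restraints
  for (arma::uword c = 0; c < g.restraints.n_rows; ++c) {
    int i = int(g.restraints(c, 0)), j = int(g.restraints(c, 1));
    double r0 = g.restraints(c, 2), k = g.restraints(c, 3);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    double ex = std::fabs(r - r0) - g.flat_width;
    if (ex <= 0.0) continue;
    double sgn = r > r0 ? 1.0 : -1.0;
    terms(5) += 0.5 * k * ex * ex;
    double dVdr = k * ex * sgn;
    arma::rowvec f = -dVdr / std::max(r, 1e-12) * d;
    F.row(i) += f;
    F.row(j) -= f;
  }

  return arma::accu(terms);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List model) {
  CgModel g = parse_model(model);
  arma::mat X(coords.begin(), coords.nrow(), 3);
  arma::mat F;
  arma::vec terms;
  bool overlap = false;
  double e = cg_energy_forces(g, X, F, terms, &overlap);
  if (overlap)
    stop("coincident particles: excluded-volume overflow");
  CharacterVector nm = CharacterVector::create(
      "bond", "angle", "dihedral", "contact", "repulsion", "restraint");
  NumericVector tv(terms.begin(), terms.end());
  tv.names() = nm;
  return List::create(_["energy"] = e, _["forces"] = wrap(F),
                      _["terms"] = tv);
}

// [[Rcpp::export]]
List cpp_rmsd_grad(NumericMatrix coords, NumericMatrix ref) {
  arma::mat X(coords.begin(), coords.nrow(), 3);
  arma::mat R(ref.begin(), ref.nrow(), 3);
  arma::mat gr;
  double r = kabsch_rmsd_grad(X, R, &gr);
  return List::create(_["rmsd"] = r, _["grad"] = wrap(gr));
}

struct MetadState {
  std::vector<double> c1, c2, h;
  double width = 0.05, kbdT = 1.0;
  bool well_tempered = true;

  double bias_and_grad(double s1, double s2, double* g1,
                       double* g2) const {
    double v = 0.0, d1 = 0.0, d2 = 0.0;
    double iw2 = 1.0 / (width * width);
    for (size_t k = 0; k < h.size(); ++k) {
      double u1 = s1 - c1[k], u2 = s2 - c2[k];
      double e = h[k] * std::exp(-0.5 * (u1 * u1 + u2 * u2) * iw2);
      v += e;
      d1 += -e * u1 * iw2;
      d2 += -e * u2 * iw2;
    }
    if (g1) *g1 = d1;
    if (g2) *g2 = d2;
    return v;
  }
};

// Shared BAOAB Langevin driver.  When t_end >= 0 the temperature is
// ramped linearly from t_start to t_end (simulated annealing);
// otherwise it is constant at t_start.  When gamma == 0 the O-step is
// the identity and the scheme reduces to velocity Verlet.  When metad
// is non-null, a well-tempered bias over (RMSD_A, RMSD_B) is applied
// and hills are deposited every `stride` steps.
static List run_dynamics(const CgModel& g, arma::mat X, int n_steps,
                         double dt, double t_start, double t_end,
                         double gamma, int seed, int save_stride,
                         MetadState* metad, const arma::mat* refA,
                         const arma::mat* refB, int stride, double h0,
                         double mass) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const int n = g.n;
  arma::mat Vel(n, 3), F, gradA, gradB;
  arma::vec terms;
  double T0 = t_start;
  // initial velocities from Maxwell-Boltzmann at the starting T
  double v0 = std::sqrt(KB * std::max(T0, 1e-10) / mass);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Vel(i, k) = v0 * gauss(rng);

  bool overlap = false;
  double epot = cg_energy_forces(g, X, F, terms, &overlap);
  double cv1 = 0.0, cv2 = 0.0;
  if (metad) {
    double g1, g2;
    cv1 = kabsch_rmsd_grad(X, *refA, &gradA);
    cv2 = kabsch_rmsd_grad(X, *refB, &gradB);
    double vb = metad->bias_and_grad(cv1, cv2, &g1, &g2);
    (void)vb;
    F -= g1 * gradA + g2 * gradB;
  }

  int n_save = n_steps / save_stride;
  arma::cube frames(n, 3, n_save);
  arma::mat cvs(n_save, 2);
  arma::vec epots(n_save), ekins(n_save), temps_out(n_save);
  std::vector<double> hill_step, hill_c1, hill_c2, hill_h;
  int isave = 0;
  bool blown = false;
  int blow_step = -1;

  for (int step = 1; step <= n_steps; ++step) {
    double T = (t_end >= 0.0)
        ? t_start + (t_end - t_start) * (double(step) / double(n_steps))
        : t_start;
    // B: half kick
    Vel += (0.5 * dt / mass) * F;
    // A: half drift
    X += 0.5 * dt * Vel;
    // O: Ornstein-Uhlenbeck
    if (gamma > 0.0) {
      double c1 = std::exp(-gamma * dt);
      double c2 = std::sqrt((1.0 - c1 * c1) * KB * T / mass);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          Vel(i, k) = c1 * Vel(i, k) + c2 * gauss(rng);
    }
    // A: half drift
    X += 0.5 * dt * Vel;
    if (!X.is_finite()) { blown = true; blow_step = step; break; }
    epot = cg_energy_forces(g, X, F, terms, &overlap);
    if (overlap || !std::isfinite(epot)) {
      blown = true; blow_step = step; break;
    }
    if (metad) {
      double g1, g2;
      cv1 = kabsch_rmsd_grad(X, *refA, &gradA);
      cv2 = kabsch_rmsd_grad(X, *refB, &gradB);
      if (step % stride == 0) {
        double vb = metad->bias_and_grad(cv1, cv2, nullptr, nullptr);
        double hh = metad->well_tempered
            ? h0 * std::exp(-vb / metad->kbdT) : h0;
        metad->c1.push_back(cv1);
        metad->c2.push_back(cv2);
        metad->h.push_back(hh);
        hill_step.push_back(step);
        hill_c1.push_back(cv1);
        hill_c2.push_back(cv2);
        hill_h.push_back(hh);
      }
      metad->bias_and_grad(cv1, cv2, &g1, &g2);
      F -= g1 * gradA + g2 * gradB;
    }
    // B: half kick
    Vel += (0.5 * dt / mass) * F;

    if (step % save_stride == 0 && isave < n_save) {
      frames.slice(isave) = X;
      cvs(isave, 0) = cv1;
      cvs(isave, 1) = cv2;
      epots(isave) = epot;
      ekins(isave) = 0.5 * mass * arma::accu(arma::square(Vel));
      temps_out(isave) = T;
      ++isave;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  arma::mat hills(hill_h.size(), 6);
  for (size_t k = 0; k < hill_h.size(); ++k) {
    hills(k, 0) = hill_step[k];
    hills(k, 1) = hill_c1[k];
    hills(k, 2) = hill_c2[k];
    hills(k, 3) = metad ? metad->width : 0.0;
    hills(k, 4) = metad ? metad->width : 0.0;
    hills(k, 5) = hill_h[k];
  }
  if (isave == 0) {
    frames.reset(); cvs.reset(); epots.reset(); ekins.reset();
    temps_out.reset();
  } else if (isave < n_save) {
    frames = frames.slices(0, isave - 1);
    cvs = cvs.rows(0, isave - 1);
    epots = epots.subvec(0, isave - 1);
    ekins = ekins.subvec(0, isave - 1);
    temps_out = temps_out.subvec(0, isave - 1);
  }
  return List::create(
      _["frames"] = wrap(frames), _["cvs"] = wrap(cvs),
      _["epot"] = wrap(epots), _["ekin"] = wrap(ekins),
      _["temperature"] = wrap(temps_out),
      _["hills"] = wrap(hills), _["final"] = wrap(X),
      _["blown_up"] = blown, _["blow_step"] = blow_step,
      _["n_saved"] = isave);
}

// [[Rcpp::export]]
List cpp_run_md(List model, NumericMatrix coords0, int n_steps, double dt,
                double t_start, double t_end, double gamma, int seed,
                int save_stride, double mass) {
  CgModel g = parse_model(model);
  arma::mat X(coords0.begin(), coords0.nrow(), 3);
  return run_dynamics(g, X, n_steps, dt, t_start, t_end, gamma, seed,
                      save_stride, nullptr, nullptr, nullptr, 0, 0.0,
                      mass);
}

// [[Rcpp::export]]
List cpp_run_metad(List model, NumericMatrix coords0, NumericMatrix refA,
                   NumericMatrix refB, int n_steps, double dt,
                   double temperature, double gamma, int seed,
                   int save_stride, int stride, double height0,
                   double width, double bias_factor, double mass,
                   bool well_tempered) {
  CgModel g = parse_model(model);
  arma::mat X(coords0.begin(), coords0.nrow(), 3);
  arma::mat RA(refA.begin(), refA.nrow(), 3);
  arma::mat RB(refB.begin(), refB.nrow(), 3);
  MetadState ms;
  ms.width = width;
  ms.well_tempered = well_tempered;
  ms.kbdT = KB * (bias_factor - 1.0) * temperature;
  return run_dynamics(g, X, n_steps, dt, temperature, -1.0, gamma, seed,
                      save_stride, &ms, &RA, &RB, stride, height0, mass);
}
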