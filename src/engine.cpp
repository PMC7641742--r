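// Compiled kernels for the restraint-driven annealing engine:
// flat-bottom restraint energies with analytic gradients, covalent terms,
// soft-sphere repulsion, velocity-Verlet dynamics with velocity-rescaling
// thermostat, and Floyd-style triangle smoothing of distance bounds.
//
// Units: length Angstrom, energy kcal/mol, mass amu, temperature K.
// Internal time unit sqrt(amu A^2 mol / kcal) = 48.8882 fs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TIME_UNIT_FS = 48.88821;
static const double KB = 0.0019872041; // kcal/mol/K

struct System {
  int n;
  arma::vec mass, vdw;
  arma::imat bonds;     arma::vec bond_r0;
  arma::imat angles;    arma::vec angle_th0;
  arma::imat impropers; arma::vec improper_phi0; arma::vec improper_k;
  double k_bond, k_angle, k_improper, k_rep, rep_scale;
  std::vector<std::vector<int>> excl_of;
};

struct Restraints {
  arma::ivec di, dj; arma::vec dlo, dup; arma::ivec dexch;
  arma::ivec t1, t2, t3, t4; arma::vec tcenter, thw;
  std::vector<arma::uvec> plan;
};

static System parse_system(const List& sys) {
  System s;
  s.n = as<int>(sys["n"]);
  s.mass = as<arma::vec>(sys["mass"]);
  s.vdw = as<arma::vec>(sys["vdw"]);
  s.bonds = as<arma::imat>(sys["bonds"]);
  s.bond_r0 = as<arma::vec>(sys["bond_r0"]);
  s.angles = as<arma::imat>(sys["angles"]);
  s.angle_th0 = as<arma::vec>(sys["angle_th0"]);
  s.impropers = as<arma::imat>(sys["impropers"]);
  s.improper_phi0 = as<arma::vec>(sys["improper_phi0"]);
  s.improper_k = as<arma::vec>(sys["improper_k"]);
  s.k_bond = as<double>(sys["k_bond"]);
  s.k_angle = as<double>(sys["k_angle"]);
  s.k_improper = as<double>(sys["k_improper"]);
  s.k_rep = as<double>(sys["k_rep"]);
  s.rep_scale = as<double>(sys["rep_scale"]);
  arma::imat ex = as<arma::imat>(sys["excl"]);
  s.excl_of.resize(s.n);
  for (arma::uword k = 0; k < ex.n_rows; ++k) {
    s.excl_of[ex(k, 0)].push_back(ex(k, 1));
    s.excl_of[ex(k, 1)].push_back(ex(k, 0));
  }
  for (auto& v : s.excl_of) std::sort(v.begin(), v.end());
  return s;
}

static Restraints parse_restraints(const List& restr) {
  Restraints r;
  List d = restr["dist"];
  r.di = as<arma::ivec>(d["i"]); r.dj = as<arma::ivec>(d["j"]);
  r.dlo = as<arma::vec>(d["lo"]); r.dup = as<arma::vec>(d["up"]);
  r.dexch = as<arma::ivec>(d["exch"]);
  List t = restr["dih"];
  r.t1 = as<arma::ivec>(t["i"]); r.t2 = as<arma::ivec>(t["j"]);
  r.t3 = as<arma::ivec>(t["k"]); r.t4 = as<arma::ivec>(t["l"]);
  r.tcenter = as<arma::vec>(t["center"]); r.thw = as<arma::vec>(t["halfwidth"]);
  List p = restr["plan"];
  for (int k = 0; k < p.size(); ++k)
    r.plan.push_back(arma::conv_to<arma::uvec>::from(as<arma::ivec>(p[k])));
  return r;
}

static bool is_excluded(const System& s, int i, int j) {
  const std::vector<int>& v = s.excl_of[i];
  return std::binary_search(v.begin(), v.end(), j);
}

// torsion angle and its gradient (Blondel-Karplus form)
static double torsion(const arma::mat& x, int i1, int i2, int i3, int i4,
                      arma::vec& g1, arma::vec& g2, arma::vec& g3,
                      arma::vec& g4) {
  arma::vec b1 = x.row(i2).t() - x.row(i1).t();
  arma::vec b2 = x.row(i3).t() - x.row(i2).t();
  arma::vec b3 = x.row(i4).t() - x.row(i3).t();
  arma::vec n1 = arma::cross(b1, b2);
  arma::vec n2 = arma::cross(b2, b3);
  double lb2 = arma::norm(b2);
  double phi = std::atan2(arma::dot(arma::cross(n1, b2 / lb2), n2),
                          arma::dot(n1, n2));
  double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
  if (n1sq < 1e-12 || n2sq < 1e-12) { // collinear: no defined gradient
    g1.zeros(3); g2.zeros(3); g3.zeros(3); g4.zeros(3);
    return phi;
  }
  g1 = (lb2 / n1sq) * n1;
  g4 = -(lb2 / n2sq) * n2;
  double f12 = arma::dot(b1, b2) / (lb2 * lb2);
  double f32 = arma::dot(b3, b2) / (lb2 * lb2);
  g2 = -g1 - f12 * g1 + f32 * g4;
  g3 = -g4 + f12 * g1 - f32 * g4;
  return phi;
}

static double wrap_pi(double a) {
  while (a > M_PI) a -= 2 * M_PI;
  while (a <= -M_PI) a += 2 * M_PI;
  return a;
}

struct EnergyParts {
  double bond = 0, angle = 0, improper = 0, nonbond = 0;
  double dist = 0, dihedral = 0, planarity = 0;
  double total() const {
    return bond + angle + improper + nonbond + dist + dihedral + planarity;
  }
};

// Adds forces (negative gradient of E) into f. Nonbonded pairs come from
// `pairs` when provided (MD neighbor list), otherwise from a full scan.
static EnergyParts compute_energy(const arma::mat& x, const System& s,
                                  const Restraints& r, double k_ne,
                                  double k_e, double k_dih, double k_plan,
                                  bool covalent, bool nonbonded,
                                  const std::vector<std::pair<int,int>>* pairs,
                                  arma::mat& grad) {
  EnergyParts ep;
  grad.zeros(s.n, 3);

  if (covalent) {
    for (arma::uword k = 0; k < s.bonds.n_rows; ++k) {
      int i = s.bonds(k, 0), j = s.bonds(k, 1);
      arma::vec d = x.row(i).t() - x.row(j).t();
      double rr = arma::norm(d);
      double dv = rr - s.bond_r0(k);
      ep.bond += s.k_bond * dv * dv;
      arma::vec g = 2 * s.k_bond * dv * d / rr;
      grad.row(i) += g.t(); grad.row(j) -= g.t();
    }
    for (arma::uword k = 0; k < s.angles.n_rows; ++k) {
      int i = s.angles(k, 0), j = s.angles(k, 1), l = s.angles(k, 2);
      arma::vec u = x.row(i).t() - x.row(j).t();
      arma::vec v = x.row(l).t() - x.row(j).t();
      double lu = arma::norm(u), lv = arma::norm(v);
      double ct = arma::dot(u, v) / (lu * lv);
      ct = std::min(1.0 - 1e-12, std::max(-1.0 + 1e-12, ct));
      double th = std::acos(ct), st = std::sqrt(1 - ct * ct);
      double dv2 = th - s.angle_th0(k);
      ep.angle += s.k_angle * dv2 * dv2;
      double pref = 2 * s.k_angle * dv2;
      arma::vec gi = (ct * u / lu - v / lv) / (lu * st);
      arma::vec gl = (ct * v / lv - u / lu) / (lv * st);
      grad.row(i) += (pref * gi).t();
      grad.row(l) += (pref * gl).t();
      grad.row(j) -= (pref * (gi + gl)).t();
    }
    arma::vec g1, g2, g3, g4;
    for (arma::uword k = 0; k < s.impropers.n_rows; ++k) {
      double phi = torsion(x, s.impropers(k, 0), s.impropers(k, 1),
                           s.impropers(k, 2), s.impropers(k, 3),
                           g1, g2, g3, g4);
      double dv2 = wrap_pi(phi - s.improper_phi0(k));
      ep.improper += s.improper_k(k) * dv2 * dv2;
      double pref = 2 * s.improper_k(k) * dv2;
      grad.row(s.impropers(k, 0)) += (pref * g1).t();
      grad.row(s.impropers(k, 1)) += (pref * g2).t();
      grad.row(s.impropers(k, 2)) += (pref * g3).t();
      grad.row(s.impropers(k, 3)) += (pref * g4).t();
    }
  }

  if (nonbonded) {
    auto nb_pair = [&](int i, int j) {
      double sij = s.rep_scale * (s.vdw(i) + s.vdw(j));
      arma::vec d = x.row(i).t() - x.row(j).t();
      double rr = arma::norm(d);
      if (rr < sij) {
        double dv = sij - rr;
        ep.nonbond += s.k_rep * dv * dv;
        arma::vec g = -2 * s.k_rep * dv * d / rr;
        grad.row(i) += g.t(); grad.row(j) -= g.t();
      }
    };
    if (pairs) {
      for (auto& pr : *pairs) nb_pair(pr.first, pr.second);
    } else {
      for (int i = 0; i < s.n; ++i)
        for (int j = i + 1; j < s.n; ++j)
          if (!is_excluded(s, i, j)) nb_pair(i, j);
    }
  }

  for (arma::uword k = 0; k < r.di.n_elem; ++k) {
    int i = r.di(k), j = r.dj(k);
    double kk = r.dexch(k) ? k_e : k_ne;
    arma::vec d = x.row(i).t() - x.row(j).t();
    double rr = arma::norm(d);
    double viol = 0;
    if (rr > r.dup(k)) viol = rr - r.dup(k);
    else if (rr < r.dlo(k)) viol = rr - r.dlo(k);
    if (viol != 0) {
      ep.dist += kk * viol * viol;
      arma::vec g = 2 * kk * viol * d / rr;
      grad.row(i) += g.t(); grad.row(j) -= g.t();
    }
  }

  {
    arma::vec g1, g2, g3, g4;
    for (arma::uword k = 0; k < r.t1.n_elem; ++k) {
      double phi = torsion(x, r.t1(k), r.t2(k), r.t3(k), r.t4(k),
                           g1, g2, g3, g4);
      double delta = wrap_pi(phi - r.tcenter(k));
      double ex = std::fabs(delta) - r.thw(k);
      if (ex > 0) {
        ep.dihedral += k_dih * ex * ex;
        double pref = 2 * k_dih * ex * (delta > 0 ? 1.0 : -1.0);
        grad.row(r.t1(k)) += (pref * g1).t();
        grad.row(r.t2(k)) += (pref * g2).t();
        grad.row(r.t3(k)) += (pref * g3).t();
        grad.row(r.t4(k)) += (pref * g4).t();
      }
    }
  }

  // planarity: sum of squared distances of member atoms to their common
  // best-fit plane equals the smallest eigenvalue of the scatter matrix;
  // the gradient (envelope theorem) is 2 k d_i n.
  for (const arma::uvec& u : r.plan) {
    arma::mat pts(u.n_elem, 3);
    for (arma::uword a = 0; a < u.n_elem; ++a) pts.row(a) = x.row(u(a));
    arma::rowvec c = arma::mean(pts, 0);
    pts.each_row() -= c;
    arma::mat S = pts.t() * pts;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, S);
    arma::vec nrm = evec.col(0);
    ep.planarity += k_plan * eval(0);
    for (arma::uword a = 0; a < u.n_elem; ++a) {
      double di = arma::dot(pts.row(a).t(), nrm);
      grad.row(u(a)) += (2 * k_plan * di * nrm).t();
    }
  }

  return ep;
}

// [[Rcpp::export]]
List qdh_energy_grad(const arma::mat& xyz, const List& sys, const List& restr,
                     double k_ne, double k_e, double k_dih, double k_plan,
                     bool covalent, bool nonbonded) {
  System s = parse_system(sys);
  Restraints r = parse_restraints(restr);
  arma::mat grad;
  EnergyParts ep = compute_energy(xyz, s, r, k_ne, k_e, k_dih, k_plan,
                                  covalent, nonbonded, nullptr, grad);
  return List::create(
    _["energy"] = ep.total(), _["grad"] = grad,
    _["components"] = NumericVector::create(
      _["bond"] = ep.bond, _["angle"] = ep.angle, _["improper"] = ep.improper,
      _["nonbond"] = ep.nonbond, _["distance"] = ep.dist,
      _["dihedral"] = ep.dihedral, _["planarity"] = ep.planarity));
}

static void build_pairs(const arma::mat& x, const System& s, double cutoff,
                        std::vector<std::pair<int,int>>& pairs) {
  pairs.clear();
  double c2 = cutoff * cutoff;
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      if (dx*dx + dy*dy + dz*dz < c2 && !is_excluded(s, i, j))
        pairs.emplace_back(i, j);
    }
  }
}

// One annealing stage of velocity-Verlet dynamics with a velocity-rescaling
// thermostat. Target temperature and the two distance-restraint force
// constants are interpolated linearly across the stage. Frames are
// accumulated (coordinate sums) every save_every steps once step >
// save_start; pass save_every = 0 to disable saving.
// [[Rcpp::export]]
List qdh_md_stage(const arma::mat& xyz, const arma::mat& vel,
                  const List& sys, const List& restr,
                  int nsteps, double dt_fs, double t_start, double t_end,
                  double k_ne_start, double k_ne_end,
                  double k_e_start, double k_e_end,
                  double k_dih, double k_plan,
                  int rescale_every, int nb_every,
                  int save_every, int save_start,
                  double rep_start, double rep_end) {
  System s = parse_system(sys);
  Restraints r = parse_restraints(restr);
  arma::mat x = xyz, v = vel, grad;
  double dt = dt_fs / TIME_UNIT_FS;
  double rep_max = std::max(rep_start, rep_end);
  double nb_cutoff = 2 * rep_max * s.vdw.max() + 1.5;
  s.rep_scale = rep_start;
  std::vector<std::pair<int,int>> pairs;
  build_pairs(x, s, nb_cutoff, pairs);

  arma::mat saved_sum(s.n, 3, arma::fill::zeros);
  int n_saved = 0;
  double frac, k_ne, k_e, t_target;
  EnergyParts ep = compute_energy(x, s, r, k_ne_start, k_e_start, k_dih,
                                  k_plan, true, true, &pairs, grad);
  arma::mat force = -grad;

  for (int step = 1; step <= nsteps; ++step) {
    frac = nsteps > 1 ? double(step - 1) / (nsteps - 1) : 1.0;
    k_ne = k_ne_start + frac * (k_ne_end - k_ne_start);
    k_e = k_e_start + frac * (k_e_end - k_e_start);
    t_target = t_start + frac * (t_end - t_start);
    s.rep_scale = rep_start + frac * (rep_end - rep_start);

    // velocity Verlet
    for (int i = 0; i < s.n; ++i)
      v.row(i) += 0.5 * dt * force.row(i) / s.mass(i);
    x += dt * v;
    if (nb_every > 0 && step % nb_every == 0)
      build_pairs(x, s, nb_cutoff, pairs);
    ep = compute_energy(x, s, r, k_ne, k_e, k_dih, k_plan, true, true,
                        &pairs, grad);
    force = -grad;
    for (int i = 0; i < s.n; ++i)
      v.row(i) += 0.5 * dt * force.row(i) / s.mass(i);

    if (rescale_every > 0 && step % rescale_every == 0) {
      double ke = 0;
      for (int i = 0; i < s.n; ++i)
        ke += 0.5 * s.mass(i) * arma::dot(v.row(i), v.row(i));
      double t_cur = 2 * ke / (3.0 * s.n * KB);
      if (t_cur > 1e-6) v *= std::sqrt(t_target / t_cur);
    }
    if (save_every > 0 && step > save_start &&
        (step - save_start) % save_every == 0) {
      saved_sum += x; ++n_saved;
    }
    if (step % 50 == 0 && !x.is_finite())
      return List::create(_["ok"] = false, _["step"] = step);
  }
  if (!x.is_finite())
    return List::create(_["ok"] = false, _["step"] = nsteps);
  return List::create(_["ok"] = true, _["xyz"] = x, _["vel"] = v,
                      _["saved_sum"] = saved_sum, _["n_saved"] = n_saved,
                      _["energy"] = ep.total());
}

// FIRE (fast inertial relaxation engine) minimization: force-only
// relaxation with adaptive timestep, far cheaper per step than quasi-Newton
// with R-level callbacks because the neighbor list is reused across steps.
// Returns the lowest-energy coordinates visited.
// [[Rcpp::export]]
List qdh_minimize(const arma::mat& xyz, const List& sys, const List& restr,
                  double k_ne, double k_e, double k_dih, double k_plan,
                  bool covalent, bool nonbonded, double min_rms_grad,
                  int max_iter, int nb_every) {
  System s = parse_system(sys);
  Restraints r = parse_restraints(restr);
  arma::mat x = xyz, grad;
  double nb_cutoff = 2 * s.rep_scale * s.vdw.max() + 1.5;
  std::vector<std::pair<int,int>> pairs;
  build_pairs(x, s, nb_cutoff, pairs);
  const std::vector<std::pair<int,int>>* plist =
    nonbonded ? &pairs : nullptr;

  EnergyParts ep = compute_energy(x, s, r, k_ne, k_e, k_dih, k_plan,
                                  covalent, nonbonded, plist, grad);
  double e = ep.total();
  arma::mat best_x = x;
  double best_e = e;
  arma::mat v(s.n, 3, arma::fill::zeros);
  double dt = 0.02, dt_max = 0.2, alpha = 0.1;
  int n_pos = 0, iter = 0;
  double rms = std::sqrt(arma::accu(grad % grad) / grad.n_elem);
  while (iter < max_iter && rms > min_rms_grad) {
    ++iter;
    arma::mat f = -grad;
    double p = arma::accu(f % v);
    if (p > 0) {
      double vn = std::sqrt(arma::accu(v % v));
      double fn = std::sqrt(arma::accu(f % f));
      if (fn > 1e-30)
        v = (1 - alpha) * v + alpha * vn * (f / fn);
      if (++n_pos > 5) {
        dt = std::min(dt * 1.1, dt_max);
        alpha *= 0.99;
      }
    } else {
      v.zeros();
      dt *= 0.5;
      alpha = 0.1;
      n_pos = 0;
    }
    v += dt * f;
    // cap per-step displacement at 0.2 A per atom
    double vmax = std::sqrt(arma::max(arma::sum(v % v, 1)));
    double step = vmax * dt;
    arma::mat dx = dt * v;
    if (step > 0.2) dx *= 0.2 / step;
    x += dx;
    if (nonbonded && nb_every > 0 && iter % nb_every == 0)
      build_pairs(x, s, nb_cutoff, pairs);
    ep = compute_energy(x, s, r, k_ne, k_e, k_dih, k_plan, covalent,
                        nonbonded, plist, grad);
    e = ep.total();
    rms = std::sqrt(arma::accu(grad % grad) / grad.n_elem);
    if (e < best_e) { best_e = e; best_x = x; }
    if (!x.is_finite()) break;
  }
  return List::create(_["xyz"] = best_x, _["energy"] = best_e,
                      _["rms_grad"] = rms, _["iterations"] = iter,
                      _["converged"] = rms <= min_rms_grad);
}

// Floyd-style triangle smoothing of a symmetric upper-bounds matrix,
// followed by one pass of inverse-triangle tightening of the lower bounds.
// [[Rcpp::export]]
List qdh_smooth_bounds(const arma::mat& lower, const arma::mat& upper) {
  arma::mat U = upper, L = lower;
  int n = U.n_rows;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        double s = uik + U(k, j);
        if (U(i, j) > s) U(i, j) = s;
      }
    }
  }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double s = L(i, k) - U(k, j);
        if (s > L(i, j)) L(i, j) = s;
      }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (L(i, j) > U(i, j)) L(i, j) = U(i, j);
  return List::create(_["lower"] = L, _["upper"] = U);
}
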