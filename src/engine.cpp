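// Coarse-grained bead-spring engine for 2D network self-assembly.
//
// Internal units: length nm, time ns, energy zJ (1e-21 J), mass 1e-21 kg.
// These are self-consistent: 1 zJ = 1 (1e-21 kg) nm^2 / ns^2.
// All conversions from user-facing units (J, N/m, us, Pa) happen in R.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static const double KB_ZJ = 1.380649e-2; // zJ / K

// bead type codes (must match R)
static const int T_HEAD = 1;
static const int T_BODY = 2;
static const int T_TANGLE = 3; // non-bonded behaviour identical to BODY

struct Params {
  double kl;       // zJ / nm^2
  double ktheta;   // zJ / rad^2
  double eps_hh, sig_hh, rc_hh; // zJ, nm, nm
  double eps_bb, sig_bb;        // zJ, nm (cutoff at sig_bb, purely repulsive)
};

struct EnergyBreakdown {
  double bond = 0, angle = 0, bb = 0, hh = 0, virial = 0;
  int n_overlap = 0;
  double total() const { return bond + angle + bb + hh; }
};

static inline double min_image(double d, double L) {
  // L <= 0 disables periodicity along that axis (not used in production)
  if (L > 0) d -= L * std::round(d / L);
  return d;
}

static inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

// Lennard-Jones energy/force factor. Returns energy; sets fr = (dU/dr)/r
// so that force on i is -fr * rij.
static inline double lj_pair(double r2, double eps, double sig,
                             double rc2, double &fr) {
  if (r2 >= rc2) { fr = 0.0; return 0.0; }
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  fr = -24.0 * eps * (2.0 * s12 - s6) / r2; // (dU/dr)/r
  return 4.0 * eps * (s12 - s6);
}

class System {
public:
  int n;
  std::vector<double> x, y, vx, vy;
  std::vector<int> type, mol;
  // topology
  std::vector<int> b_i, b_j; std::vector<double> b_rest;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_th0;
  std::unordered_set<long long> excl;
  double Lx, Ly;
  Params pp;
  double mass;

  // force accumulators
  std::vector<double> fx, fy;
  // reusable linked-cell arrays
  std::vector<int> cell_head, cell_next;
  // Verlet neighbour list (pairs within rc_max + skin at build time),
  // rebuilt when any bead has moved more than skin/2 since the build
  std::vector<int> nl_i, nl_j;
  std::vector<double> nlx0, nly0;
  double skin = 30.0;
  bool has_list = false;
  double list_Lx = 0, list_Ly = 0;

  System(NumericMatrix pos, NumericMatrix vel, IntegerVector typ,
         IntegerVector molv,
         IntegerMatrix bonds, NumericVector brest,
         IntegerMatrix angles, NumericVector ath0,
         IntegerMatrix exclm, NumericVector cell, List pars, double m) {
    n = pos.nrow();
    x.resize(n); y.resize(n); vx.resize(n); vy.resize(n);
    fx.resize(n); fy.resize(n);
    type.resize(n); mol.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = pos(i, 0); y[i] = pos(i, 1);
      vx[i] = vel(i, 0); vy[i] = vel(i, 1);
      type[i] = typ[i]; mol[i] = molv[i];
    }
    int nb = bonds.nrow();
    b_i.resize(nb); b_j.resize(nb); b_rest.resize(nb);
    for (int b = 0; b < nb; ++b) {
      b_i[b] = bonds(b, 0); b_j[b] = bonds(b, 1); b_rest[b] = brest[b];
    }
    int na = angles.nrow();
    a_i.resize(na); a_j.resize(na); a_k.resize(na); a_th0.resize(na);
    for (int a = 0; a < na; ++a) {
      a_i[a] = angles(a, 0); a_j[a] = angles(a, 1); a_k[a] = angles(a, 2);
      a_th0[a] = ath0[a];
    }
    for (int e = 0; e < exclm.nrow(); ++e)
      excl.insert(pair_key(exclm(e, 0), exclm(e, 1), n));
    Lx = cell[0]; Ly = cell[1];
    pp.kl = pars["kl"]; pp.ktheta = pars["ktheta"];
    pp.eps_hh = pars["eps_hh"]; pp.sig_hh = pars["sig_hh"];
    pp.rc_hh = pars["rc_hh"];
    pp.eps_bb = pars["eps_bb"]; pp.sig_bb = pars["sig_bb"];
    mass = m;
  }

  void wrap() {
    for (int i = 0; i < n; ++i) {
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
    }
  }

  double kinetic_T() const {
    double s = 0;
    for (int i = 0; i < n; ++i) s += vx[i] * vx[i] + vy[i] * vy[i];
    return mass * s / (2.0 * n * KB_ZJ);
  }

  // non-bonded pair interaction between listed beads i, j (type filtering
  // and intramolecular exclusions are applied when the list is built)
  inline void pair_force(int i, int j, EnergyBreakdown &eb) {
    bool ih = type[i] == T_HEAD;
    double rc = ih ? pp.rc_hh : pp.sig_bb;
    double dx = min_image(x[i] - x[j], Lx);
    double dy = min_image(y[i] - y[j], Ly);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rc * rc) return;
    // Overlap floor: below 0.7 sigma the 12-6 core is dynamically
    // unreachable (the barrier is ~256 eps >> kB T), so such separations
    // only occur in pathological initial states. Evaluate the pair at the
    // floor distance instead - this caps the force at a large finite value
    // that separates the beads without exploding the integrator.
    double sig = ih ? pp.sig_hh : pp.sig_bb;
    double rmin = 0.7 * sig;
    if (r2 < rmin * rmin) {
      eb.n_overlap++;
      double r = std::sqrt(r2);
      if (r < 1e-12) { dx = rmin; dy = 0.0; }
      else { dx *= rmin / r; dy *= rmin / r; }
      r2 = rmin * rmin;
    }
    double fr, u;
    if (ih) {
      u = lj_pair(r2, pp.eps_hh, pp.sig_hh, pp.rc_hh * pp.rc_hh, fr);
      eb.hh += u;
    } else {
      u = lj_pair(r2, pp.eps_bb, pp.sig_bb, pp.sig_bb * pp.sig_bb, fr);
      eb.bb += u;
    }
    double fxp = -fr * dx, fyp = -fr * dy; // force on i
    fx[i] += fxp; fy[i] += fyp;
    fx[j] -= fxp; fy[j] -= fyp;
    eb.virial += fxp * dx + fyp * dy;
  }

  EnergyBreakdown forces() {
    EnergyBreakdown eb;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // bonds
    for (size_t b = 0; b < b_i.size(); ++b) {
      int i = b_i[b], j = b_j[b];
      double dx = min_image(x[i] - x[j], Lx);
      double dy = min_image(y[i] - y[j], Ly);
      double r = std::sqrt(dx * dx + dy * dy);
      double dr = r - b_rest[b];
      eb.bond += 0.5 * pp.kl * dr * dr;
      double fr = r > 1e-12 ? -pp.kl * dr / r : 0.0;
      double fxp = fr * dx, fyp = fr * dy;
      fx[i] += fxp; fy[i] += fyp;
      fx[j] -= fxp; fy[j] -= fyp;
      eb.virial += fxp * dx + fyp * dy;
    }

    // angles (harmonic in theta; theta0 = pi is the straight-chain default)
    for (size_t a = 0; a < a_i.size(); ++a) {
      int i = a_i[a], j = a_j[a], k = a_k[a];
      double rijx = min_image(x[i] - x[j], Lx), rijy = min_image(y[i] - y[j], Ly);
      double rkjx = min_image(x[k] - x[j], Lx), rkjy = min_image(y[k] - y[j], Ly);
      double r1 = std::sqrt(rijx * rijx + rijy * rijy);
      double r2 = std::sqrt(rkjx * rkjx + rkjy * rkjy);
      if (r1 < 1e-12 || r2 < 1e-12) continue;
      double c = (rijx * rkjx + rijy * rkjy) / (r1 * r2);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double dth = th - a_th0[a];
      eb.angle += 0.5 * pp.ktheta * dth * dth;
      double s = std::sqrt(std::max(1.0 - c * c, 0.0));
      // factor = (dU/dtheta)/sin(theta). At the straight-chain rest state
      // (theta -> theta0 = pi) both dth and sin(theta) vanish together, so
      // clamping sin(theta) keeps the ratio at its finite limit.
      double factor = pp.ktheta * dth / std::max(s, 1e-8);
      // F_i = factor * d(cos th)/d r_i etc. (standard harmonic-angle forces)
      double fix = factor * (rkjx / (r1 * r2) - c * rijx / (r1 * r1));
      double fiy = factor * (rkjy / (r1 * r2) - c * rijy / (r1 * r1));
      double fkx = factor * (rijx / (r1 * r2) - c * rkjx / (r2 * r2));
      double fky = factor * (rijy / (r1 * r2) - c * rkjy / (r2 * r2));
      fx[i] += fix; fy[i] += fiy;
      fx[k] += fkx; fy[k] += fky;
      fx[j] -= fix + fkx; fy[j] -= fiy + fky;
      eb.virial += fix * rijx + fiy * rijy + fkx * rkjx + fky * rkjy;
    }

    // non-bonded pairs via Verlet list
    if (!has_list || list_Lx != Lx || list_Ly != Ly || moved_beyond_skin())
      build_pair_list();
    for (size_t p = 0; p < nl_i.size(); ++p)
      pair_force(nl_i[p], nl_j[p], eb);
    return eb;
  }

  bool moved_beyond_skin() {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = min_image(x[i] - nlx0[i], Lx);
      double dy = min_image(y[i] - nly0[i], Ly);
      if (dx * dx + dy * dy > lim2) return true;
    }
    return false;
  }

  // candidate pair filter applied once per list build: bead types must
  // interact (no head-body cross term) and intramolecular near neighbours
  // are excluded here, so the hot loop never consults the exclusion set
  inline void consider_pair(int i, int j, double rl2) {
    bool ih = type[i] == T_HEAD, jh = type[j] == T_HEAD;
    if (ih != jh) return;
    if (mol[i] == mol[j] && excl.count(pair_key(i, j, n))) return;
    double dx = min_image(x[i] - x[j], Lx);
    double dy = min_image(y[i] - y[j], Ly);
    if (dx * dx + dy * dy >= rl2) return;
    nl_i.push_back(i); nl_j.push_back(j);
  }

  void build_pair_list() {
    double rc = std::max(pp.rc_hh, pp.sig_bb) + skin;
    double rl2 = rc * rc;
    nl_i.clear(); nl_j.clear();
    int ncx = (int)std::floor(Lx / rc), ncy = (int)std::floor(Ly / rc);
    if (ncx >= 3 && ncy >= 3) {
      double cw = Lx / ncx, ch = Ly / ncy;
      size_t ncells = (size_t)ncx * ncy;
      cell_head.assign(ncells, -1);
      if ((int)cell_next.size() != n) cell_next.resize(n);
      for (int i = 0; i < n; ++i) {
        int cxi = (int)std::floor(x[i] / cw); if (cxi >= ncx) cxi = ncx - 1; if (cxi < 0) cxi = 0;
        int cyi = (int)std::floor(y[i] / ch); if (cyi >= ncy) cyi = ncy - 1; if (cyi < 0) cyi = 0;
        int c = cyi * ncx + cxi;
        cell_next[i] = cell_head[c];
        cell_head[c] = i;
      }
      // half-neighbour stencil: self, E, NE, N, NW
      static const int sten[5][2] = {{0,0},{1,0},{1,1},{0,1},{-1,1}};
      std::vector<int> xp(ncx), xm(ncx), yp(ncy);
      for (int c = 0; c < ncx; ++c) { xp[c] = (c + 1) % ncx; xm[c] = (c + ncx - 1) % ncx; }
      for (int c = 0; c < ncy; ++c) yp[c] = (c + 1) % ncy;
      for (int cyi = 0; cyi < ncy; ++cyi) {
        for (int cxi = 0; cxi < ncx; ++cxi) {
          int home = cyi * ncx + cxi;
          if (cell_head[home] < 0) continue;
          for (int sdx = 0; sdx < 5; ++sdx) {
            int ox = sten[sdx][0] == 0 ? cxi : (sten[sdx][0] == 1 ? xp[cxi] : xm[cxi]);
            int oy = sten[sdx][1] == 0 ? cyi : yp[cyi];
            int oc = oy * ncx + ox;
            if (cell_head[oc] < 0) continue;
            bool same = (sdx == 0);
            for (int i = cell_head[home]; i >= 0; i = cell_next[i]) {
              int j0 = same ? cell_next[i] : cell_head[oc];
              for (int j = j0; j >= 0; j = cell_next[j])
                consider_pair(i, j, rl2);
            }
          }
        }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          consider_pair(i, j, rl2);
    }
    nlx0.assign(x.begin(), x.end());
    nly0.assign(y.begin(), y.end());
    has_list = true;
    list_Lx = Lx; list_Ly = Ly;

  }
};

static List breakdown_list(const EnergyBreakdown &eb) {
  return List::create(
    _["bond"] = eb.bond, _["angle"] = eb.angle,
    _["body_body"] = eb.bb, _["head_head"] = eb.hh,
    _["total"] = eb.total(), _["virial"] = eb.virial,
    _["n_overlap"] = eb.n_overlap);
}

// [[Rcpp::export(name = ".cw_energy_forces")]]
List cw_energy_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                      IntegerVector mol,
                      IntegerMatrix bonds, NumericVector bond_rest,
                      IntegerMatrix angles, NumericVector angle_theta0,
                      IntegerMatrix excl, NumericVector cell, List pars,
                      double mass) {
  System sys(pos, vel, type, mol, bonds, bond_rest, angles, angle_theta0,
             excl, cell, pars, mass);
  EnergyBreakdown eb = sys.forces();
  NumericMatrix F(sys.n, 2);
  for (int i = 0; i < sys.n; ++i) { F(i, 0) = sys.fx[i]; F(i, 1) = sys.fy[i]; }
  return List::create(_["forces"] = F, _["energy"] = breakdown_list(eb));
}

// One stage of dynamics. Thermostat codes: 0 none (NVE), 1 Langevin,
// 2 deterministic velocity rescale (used during the NpT stage).
// The target temperature ramps linearly from T_start to T_end.
// [[Rcpp::export(name = ".cw_run_stage")]]
List cw_run_stage(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                  IntegerVector mol,
                  IntegerMatrix bonds, NumericVector bond_rest,
                  IntegerMatrix angles, NumericVector angle_theta0,
                  IntegerMatrix excl, NumericVector cell, List pars,
                  double mass, double dt, double gamma, int n_steps,
                  double T_start, double T_end, int thermostat,
                  double tau_T,
                  bool barostat, double p_target, double tau_p, double Lz0,
                  double scale_clamp,
                  double max_disp, int seed,
                  int sample_every, bool keep_snapshots) {
  System sys(pos, vel, type, mol, bonds, bond_rest, angles, angle_theta0,
             excl, cell, pars, mass);
  sys.wrap();
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double m = sys.mass;
  bool langevin = thermostat == 1 && std::isfinite(gamma) && gamma > 0;
  bool rescale = thermostat == 2;

  EnergyBreakdown eb = sys.forces();

  int n_samples = n_steps / std::max(sample_every, 1) + 2;
  NumericMatrix log(n_samples, 8);
  CharacterVector log_names = CharacterVector::create(
    "t_ns", "T_target", "T_kin", "U_total", "U_pair", "P", "Lx", "Ly");
  List snaps; int isnap = 0, ilog = 0;
  int total_overlap = 0;

  auto record = [&](int step) {
    double Tk = sys.kinetic_T();
    double Tt = n_steps > 0
      ? T_start + (T_end - T_start) * ((double)step / n_steps) : T_start;
    double vol = sys.Lx * sys.Ly * Lz0;
    double P = (sys.n * KB_ZJ * Tk + 0.5 * eb.virial) / vol;
    log(ilog, 0) = step * dt; log(ilog, 1) = Tt; log(ilog, 2) = Tk;
    log(ilog, 3) = eb.total(); log(ilog, 4) = eb.hh; log(ilog, 5) = P;
    log(ilog, 6) = sys.Lx; log(ilog, 7) = sys.Ly;
    ilog++;
    if (keep_snapshots) {
      NumericMatrix sp(sys.n, 2);
      for (int i = 0; i < sys.n; ++i) { sp(i, 0) = sys.x[i]; sp(i, 1) = sys.y[i]; }
      snaps.push_back(List::create(_["t_ns"] = step * dt, _["pos"] = sp));
      isnap++;
    }
  };
  record(0);

  // Langevin: velocity-Verlet (BAOAB) splitting. The friction -(m/gamma) v
  // and the fluctuation-dissipation-matched Brownian force act between the
  // two half-kicks as their exact Ornstein-Uhlenbeck map, which keeps the
  // stationary kinetic temperature at T even for stiff bonded modes.
  double c1 = langevin ? std::exp(-dt / gamma) : 1.0;
  double c2m = langevin ? std::sqrt(KB_ZJ / m * (1.0 - c1 * c1)) : 0.0;
  double half_cap = max_disp > 0 ? 0.5 * max_disp : 0.0;
  auto drift_half = [&](void) {
    for (int i = 0; i < sys.n; ++i) {
      double dx = 0.5 * dt * sys.vx[i], dy = 0.5 * dt * sys.vy[i];
      if (half_cap > 0) {
        double dr = std::sqrt(dx * dx + dy * dy);
        if (dr > half_cap) { dx *= half_cap / dr; dy *= half_cap / dr; }
      }
      sys.x[i] += dx; sys.y[i] += dy;
    }
  };

  for (int step = 1; step <= n_steps; ++step) {
    double frac = (double)step / n_steps;
    double T = T_start + (T_end - T_start) * frac;

    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] += 0.5 * dt * sys.fx[i] / m;
      sys.vy[i] += 0.5 * dt * sys.fy[i] / m;
    }
    drift_half();
    if (langevin) {
      double c2 = c2m * std::sqrt(T);
      for (int i = 0; i < sys.n; ++i) {
        sys.vx[i] = c1 * sys.vx[i] + c2 * gauss(rng);
        sys.vy[i] = c1 * sys.vy[i] + c2 * gauss(rng);
      }
    }
    drift_half();
    sys.wrap();

    eb = sys.forces();
    total_overlap += eb.n_overlap;

    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] += 0.5 * dt * sys.fx[i] / m;
      sys.vy[i] += 0.5 * dt * sys.fy[i] / m;
    }

    if (rescale) {
      double Tk = sys.kinetic_T();
      if (Tk > 1e-12) {
        double lam = std::sqrt(1.0 + (dt / tau_T) * (T / Tk - 1.0));
        lam = std::max(0.9, std::min(1.1, lam));
        for (int i = 0; i < sys.n; ++i) { sys.vx[i] *= lam; sys.vy[i] *= lam; }
      }
    }

    if (barostat) {
      double Tk = sys.kinetic_T();
      double vol = sys.Lx * sys.Ly * Lz0;
      double P = (sys.n * KB_ZJ * Tk + 0.5 * eb.virial) / vol;
      double dl = (dt / tau_p) * (P - p_target) / std::fabs(p_target);
      dl = std::max(-scale_clamp, std::min(scale_clamp, dl));
      double f = std::exp(dl);
      sys.Lx *= f; sys.Ly *= f;
      for (int i = 0; i < sys.n; ++i) { sys.x[i] *= f; sys.y[i] *= f; }
    }

    if (step % std::max(sample_every, 1) == 0 ||
        (step == n_steps && n_steps % std::max(sample_every, 1) != 0))
      record(step);

    if (step % 1000 == 0 || step == n_steps) {
      for (int i = 0; i < sys.n; ++i)
        if (!std::isfinite(sys.x[i]) || !std::isfinite(sys.vx[i]) ||
            !std::isfinite(sys.y[i]) || !std::isfinite(sys.vy[i]))
          stop("non-finite positions or velocities at step %d", step);
      if (barostat && sys.Lx * sys.Ly < 0.01 * cell[0] * cell[1])
        stop("cell collapse during barostat stage (area shrank > 10x)");
    }
  }

  NumericMatrix opos(sys.n, 2), ovel(sys.n, 2);
  for (int i = 0; i < sys.n; ++i) {
    opos(i, 0) = sys.x[i]; opos(i, 1) = sys.y[i];
    ovel(i, 0) = sys.vx[i]; ovel(i, 1) = sys.vy[i];
  }
  colnames(log) = log_names;
  NumericMatrix logt = log(Range(0, ilog - 1), Range(0, 7));
  colnames(logt) = log_names;
  return List::create(
    _["pos"] = opos, _["vel"] = ovel,
    _["cell"] = NumericVector::create(sys.Lx, sys.Ly),
    _["log"] = logt, _["snapshots"] = snaps,
    _["energy"] = breakdown_list(eb),
    _["n_overlap"] = total_overlap);
}
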