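// Core numerical engine: pair potentials, energy/forces under minimum-image
// periodic boundaries, BAOAB Langevin integration, neighbour/cell lists and
// trajectory contact counting. Units: nm, ps, kJ/mol, g/mol (so that
// 1 g/mol * (nm/ps)^2 == 1 kJ/mol), elementary charge e.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pair classes agreed with the R side (build_pair_tables)
enum PairClass { CLS_NONE = 0, CLS_HP = 1, CLS_CP = 2, CLS_EXCL = 3 };

struct FFPar {
  double sigma, eps_rep, kappa, Ss, z, rm, coulomb, cutoff, skin;
};

static FFPar read_ff(const List& ff) {
  FFPar p;
  p.sigma   = as<double>(ff["sigma"]);
  p.eps_rep = as<double>(ff["eps_rep"]);
  p.kappa   = as<double>(ff["kappa"]);
  p.Ss      = as<double>(ff["Ss"]);
  p.z       = as<double>(ff["z"]);
  p.rm      = as<double>(ff["rm_cp"]);
  p.coulomb = as<double>(ff["coulomb"]);
  p.cutoff  = as<double>(ff["cutoff"]);
  p.skin    = ff.containsElementNamed("skin") ? as<double>(ff["skin"]) : 0.3;
  return p;
}

static inline double min_image(double dx, double box) {
  return dx - box * std::nearbyint(dx / box);
}

// g(x) = x^2 / (4 sinh^2(x/2)) and its derivative; eps_r = Ss * (1 - g(r/z)).
// Series used at small x where the closed form cancels catastrophically.
static inline void diel_g(double x, double& g, double& gp) {
  if (x < 0.2) {
    double x2 = x * x;
    g  = 1.0 - x2 / 12.0 + x2 * x2 / 240.0 - x2 * x2 * x2 / 6048.0;
    gp = -x / 6.0 + x * x2 / 60.0 - x2 * x2 * x / 1008.0;
  } else {
    double s = std::sinh(0.5 * x), c = std::cosh(0.5 * x);
    g  = x * x / (4.0 * s * s);
    gp = (2.0 * x * s - x * x * c) / (4.0 * s * s * s);
  }
}

// [[Rcpp::export(name = ".eps_r_cpp")]]
NumericVector eps_r_cpp(NumericVector r, double Ss, double z) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double g, gp;
    diel_g(r[i] / z, g, gp);
    out[i] = Ss * (1.0 - g);
  }
  return out;
}

// phi_hp two-branch 8-6 potential; returns energy, derivative via dE.
static inline double hp_pair(double r, double sigma, double eps_rep,
                             double eps_ij, double& dE) {
  double s2 = sigma * sigma / (r * r);
  double s6 = s2 * s2 * s2;
  double s8 = s6 * s2;
  if (r <= sigma) {
    dE = (-8.0 * eps_rep * s8 + 8.0 * eps_ij * s6) / r;
    return eps_rep * s8 - eps_ij * ((4.0 / 3.0) * s6 - 1.0 / 3.0);
  } else {
    double E = (eps_rep - eps_ij) * s8;
    dE = -8.0 * E / r;
    return E;
  }
}

// cation-pi 8-6 with minimum -eps at r = rm
static inline double cp_pair(double r, double rm, double eps, double& dE) {
  double s2 = rm * rm / (r * r);
  double s6 = s2 * s2 * s2;
  double s8 = s6 * s2;
  dE = eps * (-24.0 * s8 + 24.0 * s6) / r;
  return eps * (3.0 * s8 - 4.0 * s6);
}

// screened Coulomb with distance-dependent dielectric, per unit qi*qj
static inline double elec_unit(double r, const FFPar& p, double& dE) {
  double g, gp;
  diel_g(r / p.z, g, gp);
  double epsr = p.Ss * (1.0 - g);
  double depsr = -p.Ss * gp / p.z;
  double E = p.coulomb * std::exp(-p.kappa * r) / (epsr * r);
  dE = E * (-p.kappa - 1.0 / r - depsr / epsr);
  return E;
}

struct System {
  int N;
  double box;
  const int* cls;        // N x N class matrix (column-major)
  const double* epsm;    // N x N epsilon matrix
  std::vector<double> q;
  std::vector<int> bi, bj;
  std::vector<double> b0;
  double kbond;
  FFPar ff;
  bool ideal;
  // precomputed energy shifts at the cutoff
  std::vector<double> shift; // per pair, same layout as cls (only class part)
  double elec_shift_unit;

  void precompute_shifts() {
    shift.assign((size_t)N * N, 0.0);
    double rc = ff.cutoff, d;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        int c = cls[i + (size_t)N * j];
        double e = epsm[i + (size_t)N * j];
        double s = 0.0;
        if (c == CLS_HP || c == CLS_EXCL) s = hp_pair(rc, ff.sigma, ff.eps_rep, e, d);
        else if (c == CLS_CP) s = cp_pair(rc, ff.rm, e, d);
        shift[i + (size_t)N * j] = s;
      }
    elec_shift_unit = elec_unit(rc, ff, d);
  }

  // energy and forces for one pair (i, j) at separation r along unit vector u
  inline void accum_pair(int i, int j, double r, double ux, double uy, double uz,
                         double& E, std::vector<double>& F) const {
    int c = cls[i + (size_t)N * j];
    if (c == CLS_NONE) return;
    double dE = 0.0, Ep = 0.0, d1;
    double e = epsm[i + (size_t)N * j];
    if (c == CLS_HP || c == CLS_EXCL)
      Ep = hp_pair(r, ff.sigma, ff.eps_rep, e, dE);
    else
      Ep = cp_pair(r, ff.rm, e, dE);
    Ep -= shift[i + (size_t)N * j];
    double qq = q[i] * q[j];
    if (qq != 0.0) {
      double Ee = elec_unit(r, ff, d1);
      Ep += qq * (Ee - elec_shift_unit);
      dE += qq * d1;
    }
    E += Ep;
    double f = -dE; // force magnitude along u (from i to j acts on j)
    F[3 * i + 0] -= f * ux; F[3 * i + 1] -= f * uy; F[3 * i + 2] -= f * uz;
    F[3 * j + 0] += f * ux; F[3 * j + 1] += f * uy; F[3 * j + 2] += f * uz;
  }

  double energy_forces(const std::vector<double>& x, std::vector<double>& F,
                       const std::vector<std::pair<int,int> >* nl) const {
    double E = 0.0;
    std::fill(F.begin(), F.end(), 0.0);
    double rc2 = ff.cutoff * ff.cutoff;
    if (!ideal) {
      if (nl) {
        for (size_t k = 0; k < nl->size(); ++k) {
          int i = (*nl)[k].first, j = (*nl)[k].second;
          double dx = min_image(x[3*j] - x[3*i], box);
          double dy = min_image(x[3*j+1] - x[3*i+1], box);
          double dz = min_image(x[3*j+2] - x[3*i+2], box);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 > rc2) continue;
          double r = std::sqrt(r2);
          if (r < 1e-6) stop("overlapping beads (pair %d, %d)", i + 1, j + 1);
          accum_pair(i, j, r, dx / r, dy / r, dz / r, E, F);
        }
      } else {
        for (int i = 0; i < N - 1; ++i)
          for (int j = i + 1; j < N; ++j) {
            double dx = min_image(x[3*j] - x[3*i], box);
            double dy = min_image(x[3*j+1] - x[3*i+1], box);
            double dz = min_image(x[3*j+2] - x[3*i+2], box);
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 > rc2) continue;
            if (cls[i + (size_t)N * j] == CLS_NONE) continue;
            double r = std::sqrt(r2);
            if (r < 1e-6) stop("overlapping beads (pair %d, %d)", i + 1, j + 1);
            accum_pair(i, j, r, dx / r, dy / r, dz / r, E, F);
          }
      }
    }
    // bonded terms (harmonic, never truncated, never shifted)
    for (size_t k = 0; k < bi.size(); ++k) {
      int i = bi[k], j = bj[k];
      double dx = min_image(x[3*j] - x[3*i], box);
      double dy = min_image(x[3*j+1] - x[3*i+1], box);
      double dz = min_image(x[3*j+2] - x[3*i+2], box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-9) stop("overlapping bonded beads (pair %d, %d)", i + 1, j + 1);
      double dr = r - b0[k];
      E += kbond * dr * dr;
      double f = -2.0 * kbond * dr;
      double ux = dx / r, uy = dy / r, uz = dz / r;
      F[3*i]   -= f * ux; F[3*i+1] -= f * uy; F[3*i+2] -= f * uz;
      F[3*j]   += f * ux; F[3*j+1] += f * uy; F[3*j+2] += f * uz;
    }
    return E;
  }

  void build_neighbors(const std::vector<double>& x,
                       std::vector<std::pair<int,int> >& nl) const {
    nl.clear();
    double rl = ff.cutoff + ff.skin, rl2 = rl * rl;
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (cls[i + (size_t)N * j] == CLS_NONE) continue;
        double dx = min_image(x[3*j] - x[3*i], box);
        double dy = min_image(x[3*j+1] - x[3*i+1], box);
        double dz = min_image(x[3*j+2] - x[3*i+2], box);
        if (dx*dx + dy*dy + dz*dz < rl2) nl.push_back(std::make_pair(i, j));
      }
  }
};

static System make_system(NumericMatrix pos, double box, IntegerMatrix cls,
                          NumericMatrix epsm, NumericVector charge,
                          IntegerMatrix bonds, NumericVector b0, double kbond,
                          List ff, bool ideal) {
  System s;
  s.N = pos.nrow();
  s.box = box;
  if (cls.nrow() != s.N || epsm.nrow() != s.N)
    stop("pair tables do not match the number of beads");
  s.cls = cls.begin();
  s.epsm = epsm.begin();
  s.q.assign(charge.begin(), charge.end());
  int nb = bonds.nrow();
  s.bi.resize(nb); s.bj.resize(nb);
  s.b0.assign(b0.begin(), b0.end());
  for (int k = 0; k < nb; ++k) { s.bi[k] = bonds(k, 0) - 1; s.bj[k] = bonds(k, 1) - 1; }
  s.kbond = kbond;
  s.ff = read_ff(ff);
  s.ideal = ideal;
  s.precompute_shifts();
  return s;
}

static std::vector<double> flatten(NumericMatrix pos) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i) {
    x[3*i] = pos(i, 0); x[3*i+1] = pos(i, 1); x[3*i+2] = pos(i, 2);
  }
  return x;
}

// [[Rcpp::export(name = ".ff_eval_cpp")]]
List ff_eval_cpp(NumericMatrix pos, double box, IntegerMatrix cls,
                 NumericMatrix epsm, NumericVector charge, IntegerMatrix bonds,
                 NumericVector b0, double kbond, List ff, bool ideal = false) {
  System s = make_system(pos, box, cls, epsm, charge, bonds, b0, kbond, ff, ideal);
  std::vector<double> x = flatten(pos);
  std::vector<double> F(3 * s.N);
  double E = s.energy_forces(x, F, NULL);
  NumericMatrix Fm(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    Fm(i, 0) = F[3*i]; Fm(i, 1) = F[3*i+1]; Fm(i, 2) = F[3*i+2];
  }
  return List::create(_["energy"] = E, _["forces"] = Fm);
}

// [[Rcpp::export(name = ".minimize_cpp")]]
NumericMatrix minimize_cpp(NumericMatrix pos, double box, IntegerMatrix cls,
                           NumericMatrix epsm, NumericVector charge,
                           IntegerMatrix bonds, NumericVector b0, double kbond,
                           List ff, LogicalVector movable, int n_iter = 200,
                           double max_step = 0.02) {
  System s = make_system(pos, box, cls, epsm, charge, bonds, b0, kbond, ff, false);
  std::vector<double> x = flatten(pos), F(3 * s.N);
  for (int it = 0; it < n_iter; ++it) {
    s.energy_forces(x, F, NULL);
    double fmax = 0.0;
    for (int i = 0; i < s.N; ++i) {
      if (!movable[i]) continue;
      for (int d = 0; d < 3; ++d) fmax = std::max(fmax, std::fabs(F[3*i+d]));
    }
    if (fmax < 1e-3) break;
    double alpha = max_step / fmax;
    for (int i = 0; i < s.N; ++i) {
      if (!movable[i]) continue;
      for (int d = 0; d < 3; ++d) x[3*i+d] += alpha * F[3*i+d];
    }
  }
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out(i, 0) = x[3*i]; out(i, 1) = x[3*i+1]; out(i, 2) = x[3*i+2];
  }
  return out;
}

// BAOAB Langevin / velocity-Verlet (gamma = 0) integrator.
// Uses R's RNG (norm_rand) so trajectories are reproducible via set.seed().
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix pos0, NumericMatrix vel0, double box,
                      IntegerMatrix cls, NumericMatrix epsm, NumericVector charge,
                      IntegerMatrix bonds, NumericVector b0, double kbond, List ff,
                      int n_steps, double dt, double gamma, double temp,
                      double mass, int save_every, bool ideal = false) {
  System s = make_system(pos0, box, cls, epsm, charge, bonds, b0, kbond, ff, ideal);
  const double kB = 0.008314462618;
  int N = s.N;
  std::vector<double> x = flatten(pos0), v = flatten(vel0), F(3 * N);
  std::vector<std::pair<int,int> > nl;
  std::vector<double> xref(x);
  const bool use_nl = !ideal;
  if (use_nl) s.build_neighbors(x, nl);
  double E = s.energy_forces(x, F, use_nl ? &nl : NULL);

  double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0.0) ? std::sqrt(kB * temp / mass * (1.0 - c1 * c1)) : 0.0;
  double halfdtm = 0.5 * dt / mass;

  int n_frames = n_steps / save_every + 1;
  NumericVector frames((size_t)N * 3 * n_frames);
  frames.attr("dim") = IntegerVector::create(N, 3, n_frames);
  NumericVector times(n_frames), pe(n_frames), ke(n_frames);
  int fidx = 0;
  double ke0 = 0.0;
  for (int i = 0; i < 3 * N; ++i) ke0 += v[i] * v[i];
  auto save_frame = [&](int step, double Epot) {
    for (int i = 0; i < N; ++i) {
      frames[(size_t)fidx * 3 * N + i]         = x[3*i];
      frames[(size_t)fidx * 3 * N + N + i]     = x[3*i+1];
      frames[(size_t)fidx * 3 * N + 2 * N + i] = x[3*i+2];
    }
    times[fidx] = step * dt;
    pe[fidx] = Epot;
    double k = 0.0;
    for (int i = 0; i < 3 * N; ++i) k += v[i] * v[i];
    ke[fidx] = 0.5 * mass * k;
    ++fidx;
  };
  save_frame(0, E);

  double skin_half2 = 0.25 * s.ff.skin * s.ff.skin;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * N; ++i) v[i] += halfdtm * F[i];      // B
    for (int i = 0; i < 3 * N; ++i) x[i] += 0.5 * dt * v[i];     // A
    if (gamma > 0.0)                                             // O
      for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * N; ++i) x[i] += 0.5 * dt * v[i];     // A
    if (use_nl) {
      double dmax2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double dx = x[3*i] - xref[3*i], dy = x[3*i+1] - xref[3*i+1],
               dz = x[3*i+2] - xref[3*i+2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 > dmax2) dmax2 = d2;
      }
      if (dmax2 > skin_half2) { s.build_neighbors(x, nl); xref = x; }
    }
    E = s.energy_forces(x, F, use_nl ? &nl : NULL);              // forces at t+dt
    for (int i = 0; i < 3 * N; ++i) v[i] += halfdtm * F[i];      // B
    double fmax = 0.0;
    for (int i = 0; i < 3 * N; ++i) fmax = std::max(fmax, std::fabs(F[i]));
    if (!std::isfinite(E) || fmax > 1e7)
      stop("numeric blow-up at step %d (|F|max = %g)", step, fmax);
    if (step % save_every == 0) save_frame(step, E);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix vout(N, 3);
  for (int i = 0; i < N; ++i) {
    vout(i, 0) = v[3*i]; vout(i, 1) = v[3*i+1]; vout(i, 2) = v[3*i+2];
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["pe"] = pe, _["ke"] = ke, _["final_vel"] = vout);
}

// Exact pair list within cutoff under minimum image (O(N^2)).
// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, double box, double cutoff) {
  int N = pos.nrow();
  double rc2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = min_image(pos(j,0) - pos(i,0), box);
      double dy = min_image(pos(j,1) - pos(i,1), box);
      double dz = min_image(pos(j,2) - pos(i,2), box);
      if (dx*dx + dy*dy + dz*dz <= rc2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// Contact statistics over trajectory frames via a periodic cell list.
// Returns per-frame pair counts and, per B bead, the number of frames in
// which at least one A bead lies within the cutoff.
// [[Rcpp::export(name = ".contacts_cpp")]]
List contacts_cpp(NumericVector frames, double box, IntegerVector idxA,
                  IntegerVector idxB, double cutoff) {
  IntegerVector dim = frames.attr("dim");
  int N = dim[0], F = dim[2];
  int nA = idxA.size(), nB = idxB.size();
  double rc2 = cutoff * cutoff;
  IntegerVector counts(F);
  IntegerVector bframes(nB);
  int nc = (int)std::floor(box / cutoff);
  if (nc > 32) nc = 32;
  bool use_cells = nc >= 3;
  double cell = box / std::max(nc, 1);
  std::vector<std::vector<int> > grid;
  if (use_cells) grid.resize((size_t)nc * nc * nc);

  for (int f = 0; f < F; ++f) {
    const double* X = &frames[(size_t)f * 3 * N];
    // coordinates of bead i in frame f: X[i], X[N+i], X[2N+i]
    int framecount = 0;
    std::vector<bool> btouch(nB, false);
    if (use_cells) {
      for (size_t c = 0; c < grid.size(); ++c) grid[c].clear();
      std::vector<double> wa(3 * nA);
      for (int a = 0; a < nA; ++a) {
        int i = idxA[a] - 1;
        double px = X[i], py = X[N + i], pz = X[2 * N + i];
        px -= box * std::floor(px / box);
        py -= box * std::floor(py / box);
        pz -= box * std::floor(pz / box);
        wa[3*a] = px; wa[3*a+1] = py; wa[3*a+2] = pz;
        int cx = std::min((int)(px / cell), nc - 1);
        int cy = std::min((int)(py / cell), nc - 1);
        int cz = std::min((int)(pz / cell), nc - 1);
        grid[(size_t)(cx * nc + cy) * nc + cz].push_back(a);
      }
      for (int bq = 0; bq < nB; ++bq) {
        int j = idxB[bq] - 1;
        double px = X[j], py = X[N + j], pz = X[2 * N + j];
        px -= box * std::floor(px / box);
        py -= box * std::floor(py / box);
        pz -= box * std::floor(pz / box);
        int cx = std::min((int)(px / cell), nc - 1);
        int cy = std::min((int)(py / cell), nc - 1);
        int cz = std::min((int)(pz / cell), nc - 1);
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              int gx = (cx + ox + nc) % nc, gy = (cy + oy + nc) % nc,
                  gz = (cz + oz + nc) % nc;
              const std::vector<int>& cellv = grid[(size_t)(gx * nc + gy) * nc + gz];
              for (size_t t = 0; t < cellv.size(); ++t) {
                int a = cellv[t];
                double dx = min_image(wa[3*a] - px, box);
                double dy = min_image(wa[3*a+1] - py, box);
                double dz = min_image(wa[3*a+2] - pz, box);
                if (dx*dx + dy*dy + dz*dz <= rc2) {
                  ++framecount;
                  btouch[bq] = true;
                }
              }
            }
      }
    } else {
      for (int bq = 0; bq < nB; ++bq) {
        int j = idxB[bq] - 1;
        for (int a = 0; a < nA; ++a) {
          int i = idxA[a] - 1;
          double dx = min_image(X[i] - X[j], box);
          double dy = min_image(X[N+i] - X[N+j], box);
          double dz = min_image(X[2*N+i] - X[2*N+j], box);
          if (dx*dx + dy*dy + dz*dz <= rc2) {
            ++framecount;
            btouch[bq] = true;
          }
        }
      }
    }
    counts[f] = framecount;
    for (int bq = 0; bq < nB; ++bq) if (btouch[bq]) ++bframes[bq];
  }
  return List::create(_["per_frame"] = counts, _["b_frames"] = bframes);
}
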