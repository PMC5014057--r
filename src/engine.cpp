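// Off-lattice crypt engine.
//
// Geometry: basal membrane = hemisphere (radius R, bottom pole at origin,
// centre at (0,0,R)) joined to a cylinder of the same radius for z >= R.
// Position metric P = geodesic meridian arc from the bottom pole, in cell
// radii (1 unit = 5 um).
//
// Lineage state codes used throughout:
//   1 SC, 2 EC_progenitor, 3 GC_progenitor, 4 PC_progenitor,
//   5 EC_terminal, 6 GC_terminal, 7 PC_terminal.
//
// All randomness draws from R's RNG so set.seed() on the R side makes every
// run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-12;

// ---------------------------------------------------------------- geometry

inline double axialP1(double x, double y, double z, double R) {
  if (z >= R) return R * M_PI / 2.0 + (z - R);
  double ux = x, uy = y, uz = z - R;
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (n < EPS) return 0.0; // degenerate cap centre -> pole
  double c = -uz / n;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return R * std::acos(c);
}

inline void project1(double x, double y, double z, double R,
                     double &ox, double &oy, double &oz) {
  if (z >= R) {
    double rho = std::sqrt(x * x + y * y);
    if (rho < EPS) { ox = R; oy = 0.0; oz = z; return; } // on-axis fallback: +x
    ox = x * R / rho; oy = y * R / rho; oz = z;
    return;
  }
  double ux = x, uy = y, uz = z - R;
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (n < EPS) { ox = 0.0; oy = 0.0; oz = 0.0; return; } // cap centre -> pole
  ox = ux * R / n; oy = uy * R / n; oz = R + uz * R / n;
}

// unit tangent along the meridian, pointing toward increasing P;
// zero vector at the bottom pole (direction undefined there).
inline void upTangent1(double x, double y, double z, double R,
                       double &tx, double &ty, double &tz) {
  if (z >= R) { tx = 0.0; ty = 0.0; tz = 1.0; return; }
  double rho = std::sqrt(x * x + y * y);
  if (rho < 1e-9) { tx = 0.0; ty = 0.0; tz = 0.0; return; }
  double uz = z - R;
  double n = std::sqrt(rho * rho + uz * uz);
  double st = rho / n, ct = -uz / n; // sin/cos of polar angle from bottom pole
  double cf = x / rho, sf = y / rho;
  tx = ct * cf; ty = ct * sf; tz = st;
}

// outward surface normal at (the projection of) a point
inline void normal1(double x, double y, double z, double R,
                    double &nx, double &ny, double &nz) {
  if (z >= R) {
    double rho = std::sqrt(x * x + y * y);
    if (rho < EPS) { nx = 1.0; ny = 0.0; nz = 0.0; return; }
    nx = x / rho; ny = y / rho; nz = 0.0;
    return;
  }
  double ux = x, uy = y, uz = z - R;
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (n < EPS) { nx = 0.0; ny = 0.0; nz = -1.0; return; }
  nx = ux / n; ny = uy / n; nz = uz / n;
}

inline double radiusOf(double vol) {
  return std::cbrt(3.0 * vol / (4.0 * M_PI));
}

// sphere-sphere intersection (lens) volume; d = centre distance
inline double lensVolume(double r1, double r2, double d) {
  if (d >= r1 + r2) return 0.0;
  double rs = std::min(r1, r2);
  if (d <= std::fabs(r1 - r2)) return 4.0 * M_PI * rs * rs * rs / 3.0;
  double a = r1 + r2 - d;
  return M_PI * a * a *
         (d * d + 2.0 * d * (r1 + r2) - 3.0 * (r1 - r2) * (r1 - r2)) /
         (12.0 * d);
}

// ------------------------------------------------------------- state codes

inline bool isPCstate(int s) { return s == 4 || s == 7; }
inline bool isGCstate(int s) { return s == 3 || s == 6; }
inline bool isTerminal(int s) { return s >= 5; }
inline bool isProlif(int s) { return s >= 1 && s <= 4; }

inline int fateDecision1(int s, int nPC, int nGC, double P,
                         double P1, double P2, int C1, int C2, int outside) {
  int wnt = outside ? 0 : (P < P1 ? 0 : (P < P2 ? 1 : 2));
  switch (s) {
  case 1: // SC
    if (wnt == 0) return (nPC >= C1) ? 1 : 4;
    if (wnt == 2) return 5;
    return (nGC >= C2) ? 2 : 3;
  case 2: // EC progenitor
    if (wnt == 2) return 5;
    if (wnt == 0 && nPC >= C1) return 1;
    return (nGC >= C2) ? 2 : 3;
  case 3: // GC progenitor
    if (nGC >= C2) return 2;
    if (wnt == 2) return 6;
    return 3;
  case 4: // PC progenitor
    if (wnt == 0 && nPC >= C1) return 1;
    return 4;
  default:
    return s;
  }
}

// fate-change trigger codes: 1 wnt, 2 notch, 3 terminal, 4 last_cycle
inline int triggerOf(int sOld, int sNew) {
  if (sNew == 7) return 4;
  if (sNew == 5 || sNew == 6) return 3;
  if ((sOld == 1 && sNew == 4) || (sOld == 2 && sNew == 3) ||
      (sOld == 4 && sNew == 1) || (sOld == 3 && sNew == 2)) return 2;
  return 1;
}

// --------------------------------------------------------------- exported
// granular operations (the same internals the engine loop uses)

// [[Rcpp::export(name = ".cpp_axial_position")]]
NumericVector cpp_axial_position(NumericMatrix pts, double R) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = axialP1(pts(i, 0), pts(i, 1), pts(i, 2), R);
  return out;
}

// [[Rcpp::export(name = ".cpp_project")]]
NumericMatrix cpp_project(NumericMatrix pts, double R) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double ox, oy, oz;
    project1(pts(i, 0), pts(i, 1), pts(i, 2), R, ox, oy, oz);
    out(i, 0) = ox; out(i, 1) = oy; out(i, 2) = oz;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_up_tangent")]]
NumericMatrix cpp_up_tangent(NumericMatrix pts, double R) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double tx, ty, tz;
    upTangent1(pts(i, 0), pts(i, 1), pts(i, 2), R, tx, ty, tz);
    out(i, 0) = tx; out(i, 1) = ty; out(i, 2) = tz;
  }
  return out;
}

// contact pairs (1-based indices, i < j)
// [[Rcpp::export(name = ".cpp_detect_contacts")]]
IntegerMatrix cpp_detect_contacts(NumericVector x, NumericVector y,
                                  NumericVector z, NumericVector r,
                                  double contact_factor) {
  int n = x.size();
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double cut = contact_factor * (r[i] + r[j]);
      if (dx * dx + dy * dy + dz * dz < cut * cut) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

inline void pairForce1(double dx, double dy, double dz, double ri, double rj,
                       double k_rep, double k_adh, double adh_range,
                       double &fx, double &fy, double &fz) {
  double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (dist < 1e-9) { // coincident centres: random separation direction
    double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (gn < EPS) { gx = 1.0; gy = 0.0; gz = 0.0; gn = 1.0; }
    double mag = k_rep * std::pow(ri + rj, 1.5);
    fx = mag * gx / gn; fy = mag * gy / gn; fz = mag * gz / gn;
    return;
  }
  double delta = (ri + rj) - dist;
  double mag = 0.0;
  if (delta > 0.0) mag = k_rep * std::pow(delta, 1.5);
  else if (-delta < adh_range) mag = -k_adh;
  fx = mag * dx / dist; fy = mag * dy / dist; fz = mag * dz / dist;
}

// force on cell i exerted by cell j (repulsion positive along i - j)
// [[Rcpp::export(name = ".cpp_pair_force")]]
NumericVector cpp_pair_force(NumericVector pi, double ri, NumericVector pj,
                             double rj, double k_rep, double k_adh,
                             double adh_range) {
  double fx, fy, fz;
  pairForce1(pi[0] - pj[0], pi[1] - pj[1], pi[2] - pj[2], ri, rj, k_rep,
             k_adh, adh_range, fx, fy, fz);
  return NumericVector::create(fx, fy, fz);
}

// ----------------------------------------------------------- force summing

struct Par {
  double R, exitP, k_rep, k_adh, adh_range, k_mem, friction;
  double bias_up, bias_down, dt, max_step, contact_factor, tol;
  double vp_frac, cgt_mean, cgt_cv, fate_dt, max_pc_wait;
  double tau_p, tau_cv, contact_thresh, t0;
  int contact_death, max_cells;
};

struct Pop {
  std::vector<double> x, y, z, vol, v0, age, cgt, pc_clock, pc_age, lifespan,
      pc_wait, vp_scale, cycle_delta;
  std::vector<int> id, state, founder, clone, inhibited, C1, C2, pc_bias,
      outside;
  size_t n() const { return x.size(); }
};

inline double biasMag(int s, int pc_bias, const Par &p) {
  if (s == 2 || s == 3 || s == 5 || s == 6) return p.bias_up;
  if ((s == 4 || s == 7) && pc_bias) return -p.bias_down;
  return 0.0;
}

static void sumForces(Pop &P_, const Par &par, std::vector<double> &fx,
                      std::vector<double> &fy, std::vector<double> &fz) {
  size_t n = P_.n();
  fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
  std::vector<double> rad(n);
  for (size_t i = 0; i < n; ++i) rad[i] = radiusOf(P_.vol[i]);
  for (size_t i = 0; i < n; ++i) {
    for (size_t j = i + 1; j < n; ++j) {
      double dx = P_.x[i] - P_.x[j], dy = P_.y[i] - P_.y[j],
             dz = P_.z[i] - P_.z[j];
      double cut = par.contact_factor * (rad[i] + rad[j]);
      if (dx * dx + dy * dy + dz * dz >= cut * cut) continue;
      double gx, gy, gz;
      pairForce1(dx, dy, dz, rad[i], rad[j], par.k_rep, par.k_adh,
                 par.adh_range, gx, gy, gz);
      fx[i] += gx; fy[i] += gy; fz[i] += gz;
      fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
    }
    // active migration bias along the meridian
    double bm = biasMag(P_.state[i], P_.pc_bias[i], par);
    if (bm != 0.0) {
      double tx, ty, tz;
      upTangent1(P_.x[i], P_.y[i], P_.z[i], par.R, tx, ty, tz);
      fx[i] += bm * tx; fy[i] += bm * ty; fz[i] += bm * tz;
    }
    // membrane attachment spring
    double ox, oy, oz;
    project1(P_.x[i], P_.y[i], P_.z[i], par.R, ox, oy, oz);
    fx[i] += par.k_mem * (ox - P_.x[i]);
    fy[i] += par.k_mem * (oy - P_.y[i]);
    fz[i] += par.k_mem * (oz - P_.z[i]);
  }
}

// The clamp diagnostic only counts settled cells (age >= 2 h): freshly
// placed daughters overlap by construction and their fast clamped
// separation is intended, not numerical instability.
static int mechSubstep(Pop &P_, const Par &par, long *clamped_settled,
                       long *moves_settled) {
  size_t n = P_.n();
  std::vector<double> fx, fy, fz;
  sumForces(P_, par, fx, fy, fz);
  int clamped = 0;
  for (size_t i = 0; i < n; ++i) {
    double dx = fx[i] / par.friction * par.dt;
    double dy = fy[i] / par.friction * par.dt;
    double dz = fz[i] / par.friction * par.dt;
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    bool settled = P_.age.empty() || P_.age[i] >= 2.0;
    if (moves_settled && settled) (*moves_settled)++;
    if (d > par.max_step) {
      double s = par.max_step / d;
      dx *= s; dy *= s; dz *= s;
      clamped++;
      if (clamped_settled && settled) (*clamped_settled)++;
    }
    P_.x[i] += dx; P_.y[i] += dy; P_.z[i] += dz;
  }
  return clamped;
}

// one mechanics substep on raw arrays (exported for unit tests)
// [[Rcpp::export(name = ".cpp_substep")]]
List cpp_substep(NumericVector x, NumericVector y, NumericVector z,
                 NumericVector vol, IntegerVector state,
                 IntegerVector pc_bias, List par) {
  Par p;
  p.R = par["cap_radius"]; p.k_rep = par["k_rep"]; p.k_adh = par["k_adh"];
  p.adh_range = par["adhesion_range"]; p.k_mem = par["k_mem"];
  p.friction = par["friction"]; p.bias_up = par["bias_up"];
  p.bias_down = par["bias_down"]; p.dt = par["dt"];
  p.max_step = par["max_step"]; p.contact_factor = par["contact_factor"];
  Pop q;
  int n = x.size();
  q.x.assign(x.begin(), x.end()); q.y.assign(y.begin(), y.end());
  q.z.assign(z.begin(), z.end()); q.vol.assign(vol.begin(), vol.end());
  q.state.assign(state.begin(), state.end());
  q.pc_bias.assign(pc_bias.begin(), pc_bias.end());
  int clamped = mechSubstep(q, p, NULL, NULL);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = q.x[i]; out(i, 1) = q.y[i]; out(i, 2) = q.z[i];
  }
  return List::create(_["pos"] = out, _["clamped"] = clamped);
}

// available (uncompressed) volume = own volume minus summed lens overlaps
// [[Rcpp::export(name = ".cpp_available_volume")]]
NumericVector cpp_available_volume(NumericVector x, NumericVector y,
                                   NumericVector z, NumericVector vol) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> rad(n);
  for (int i = 0; i < n; ++i) rad[i] = radiusOf(vol[i]);
  for (int i = 0; i < n; ++i) out[i] = vol[i];
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double lv = lensVolume(rad[i], rad[j], d);
      if (lv > 0.0) { out[i] -= lv; out[j] -= lv; }
    }
  for (int i = 0; i < n; ++i)
    if (out[i] < 0.0) out[i] = 0.0;
  return out;
}

// [[Rcpp::export(name = ".cpp_lens_volume")]]
double cpp_lens_volume(double r1, double r2, double d) {
  return lensVolume(r1, r2, d);
}

// [[Rcpp::export(name = ".cpp_fate_decision")]]
IntegerVector cpp_fate_decision(IntegerVector state, IntegerVector nPC,
                                IntegerVector nGC, NumericVector P,
                                double P1, double P2, IntegerVector C1,
                                IntegerVector C2, IntegerVector outside) {
  int n = state.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (isTerminal(state[i]))
      stop("update_fate called on a terminally differentiated cell");
    out[i] = fateDecision1(state[i], nPC[i], nGC[i], P[i], P1, P2, C1[i],
                           C2[i], outside[i]);
  }
  return out;
}

// daughter placement for a division (random tangential axis, projected)
// [[Rcpp::export(name = ".cpp_division_placement")]]
NumericMatrix cpp_division_placement(double x, double y, double z, double vol,
                                     double R) {
  double nx, ny, nz;
  normal1(x, y, z, R, nx, ny, nz);
  double tx = 0, ty = 0, tz = 0, tn = 0;
  do {
    double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
    double dot = gx * nx + gy * ny + gz * nz;
    tx = gx - dot * nx; ty = gy - dot * ny; tz = gz - dot * nz;
    tn = std::sqrt(tx * tx + ty * ty + tz * tz);
  } while (tn < 1e-8);
  tx /= tn; ty /= tn; tz /= tn;
  double off = 0.5 * radiusOf(vol);
  NumericMatrix out(2, 3);
  double ox, oy, oz;
  project1(x + off * tx, y + off * ty, z + off * tz, R, ox, oy, oz);
  out(0, 0) = ox; out(0, 1) = oy; out(0, 2) = oz;
  project1(x - off * tx, y - off * ty, z - off * tz, R, ox, oy, oz);
  out(1, 0) = ox; out(1, 1) = oy; out(1, 2) = oz;
  return out;
}

// ------------------------------------------------------------------ engine

struct EventLog {
  // time, type, id, founder, clone, P, s_old, s_new
  // types: 1 division, 2 anoikis, 3 exit, 4 death_intrinsic,
  //        5 death_contact, 6 fate_change
  std::vector<double> rows;
  void add(double t, int type, int id, int founder, int clone, double P,
           int sOld, int sNew) {
    rows.push_back(t); rows.push_back(type); rows.push_back(id);
    rows.push_back(founder); rows.push_back(clone); rows.push_back(P);
    rows.push_back(sOld); rows.push_back(sNew);
  }
};

struct DivLog {
  // time, mother, d1, d2, P, mother_state, founder, clone
  std::vector<double> rows;
  void add(double t, int m, int d1, int d2, double P, int ms, int f, int c) {
    rows.push_back(t); rows.push_back(m); rows.push_back(d1);
    rows.push_back(d2); rows.push_back(P); rows.push_back(ms);
    rows.push_back(f); rows.push_back(c);
  }
};

inline double drawCgt(double mean, double cv, double delta) {
  double m = mean + delta;
  if (m < 1.0) m = 1.0;
  if (cv <= 0.0) return m;
  double sdlog = std::sqrt(std::log(1.0 + cv * cv));
  double meanlog = std::log(m) - 0.5 * sdlog * sdlog;
  return std::exp(meanlog + sdlog * norm_rand());
}

inline double drawLifespan(double tau, double cv) {
  if (cv <= 0.0) return tau;
  double v;
  do { v = tau + cv * tau * norm_rand(); } while (v <= 0.0);
  return v;
}

static void removeCells(Pop &P_, const std::vector<char> &dead) {
  size_t k = 0;
  for (size_t i = 0; i < P_.n(); ++i) {
    if (dead[i]) continue;
    if (k != i) {
      P_.x[k] = P_.x[i]; P_.y[k] = P_.y[i]; P_.z[k] = P_.z[i];
      P_.vol[k] = P_.vol[i]; P_.v0[k] = P_.v0[i]; P_.age[k] = P_.age[i];
      P_.cgt[k] = P_.cgt[i]; P_.pc_clock[k] = P_.pc_clock[i];
      P_.pc_age[k] = P_.pc_age[i]; P_.lifespan[k] = P_.lifespan[i];
      P_.pc_wait[k] = P_.pc_wait[i]; P_.vp_scale[k] = P_.vp_scale[i];
      P_.cycle_delta[k] = P_.cycle_delta[i];
      P_.id[k] = P_.id[i]; P_.state[k] = P_.state[i];
      P_.founder[k] = P_.founder[i]; P_.clone[k] = P_.clone[i];
      P_.inhibited[k] = P_.inhibited[i]; P_.C1[k] = P_.C1[i];
      P_.C2[k] = P_.C2[i]; P_.pc_bias[k] = P_.pc_bias[i];
      P_.outside[k] = P_.outside[i];
    }
    ++k;
  }
  P_.x.resize(k); P_.y.resize(k); P_.z.resize(k); P_.vol.resize(k);
  P_.v0.resize(k); P_.age.resize(k); P_.cgt.resize(k); P_.pc_clock.resize(k);
  P_.pc_age.resize(k); P_.lifespan.resize(k); P_.pc_wait.resize(k);
  P_.vp_scale.resize(k); P_.cycle_delta.resize(k);
  P_.id.resize(k); P_.state.resize(k); P_.founder.resize(k);
  P_.clone.resize(k); P_.inhibited.resize(k); P_.C1.resize(k);
  P_.C2.resize(k); P_.pc_bias.resize(k); P_.outside.resize(k);
}

static void buildAdjacency(const Pop &P_, double contact_factor,
                           std::vector<std::vector<int> > &adj) {
  size_t n = P_.n();
  adj.assign(n, std::vector<int>());
  std::vector<double> rad(n);
  for (size_t i = 0; i < n; ++i) rad[i] = radiusOf(P_.vol[i]);
  for (size_t i = 0; i < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      double dx = P_.x[i] - P_.x[j], dy = P_.y[i] - P_.y[j],
             dz = P_.z[i] - P_.z[j];
      double cut = contact_factor * (rad[i] + rad[j]);
      if (dx * dx + dy * dy + dz * dz < cut * cut) {
        adj[i].push_back(j);
        adj[j].push_back(i);
      }
    }
}

// Fisher-Yates permutation using R's RNG
static std::vector<int> randPerm(int n) {
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// [[Rcpp::export(name = ".cpp_run_crypt")]]
List cpp_run_crypt(List pop, List par, double hours, int next_id,
                   bool stop_on_conversion, bool check_clone,
                   bool record_fate_events) {
  Par p;
  p.R = par["cap_radius"]; p.exitP = par["exit_position"];
  p.k_rep = par["k_rep"]; p.k_adh = par["k_adh"];
  p.adh_range = par["adhesion_range"]; p.k_mem = par["k_mem"];
  p.friction = par["friction"]; p.bias_up = par["bias_up"];
  p.bias_down = par["bias_down"]; p.dt = par["dt"];
  p.max_step = par["max_step"]; p.contact_factor = par["contact_factor"];
  p.tol = par["substrate_tolerance"]; p.vp_frac = par["vp_frac"];
  p.cgt_mean = par["cycle_growth_time"]; p.cgt_cv = par["cycle_cv"];
  p.fate_dt = par["fate_dt"]; p.max_pc_wait = par["max_pc_progenitor_wait"];
  p.tau_p = par["tau_p_hours"]; p.tau_cv = par["lifespan_cv"];
  p.contact_death = as<int>(par["contact_death"]);
  p.contact_thresh = par["contact_starvation_threshold"];
  p.t0 = par["t0"]; p.max_cells = as<int>(par["max_cells"]);
  double P1 = par["P1"], P2 = par["P2"];

  Pop q;
  {
    NumericVector x = pop["x"], y = pop["y"], z = pop["z"], vol = pop["volume"],
                  v0 = pop["v0"], age = pop["age"], cgt = pop["cycle_growth_time"],
                  pcc = pop["pc_clock"], pca = pop["pc_age"],
                  lf = pop["intrinsic_lifespan"], pw = pop["pc_wait"],
                  vs = pop["vp_scale"], cd = pop["cycle_delta"];
    IntegerVector id = pop["id"], st = pop["state"], fo = pop["founder"],
                  cl = pop["clone"], in = pop["inhibited"], c1 = pop["C1_eff"],
                  c2 = pop["C2_eff"], pb = pop["pc_bias"], ou = pop["outside_niche"];
    q.x.assign(x.begin(), x.end()); q.y.assign(y.begin(), y.end());
    q.z.assign(z.begin(), z.end()); q.vol.assign(vol.begin(), vol.end());
    q.v0.assign(v0.begin(), v0.end()); q.age.assign(age.begin(), age.end());
    q.cgt.assign(cgt.begin(), cgt.end());
    q.pc_clock.assign(pcc.begin(), pcc.end());
    q.pc_age.assign(pca.begin(), pca.end());
    q.lifespan.assign(lf.begin(), lf.end());
    q.pc_wait.assign(pw.begin(), pw.end());
    q.vp_scale.assign(vs.begin(), vs.end());
    q.cycle_delta.assign(cd.begin(), cd.end());
    q.id.assign(id.begin(), id.end()); q.state.assign(st.begin(), st.end());
    q.founder.assign(fo.begin(), fo.end());
    q.clone.assign(cl.begin(), cl.end());
    q.inhibited.assign(in.begin(), in.end());
    q.C1.assign(c1.begin(), c1.end()); q.C2.assign(c2.begin(), c2.end());
    q.pc_bias.assign(pb.begin(), pb.end());
    q.outside.assign(ou.begin(), ou.end());
  }

  EventLog ev;
  DivLog dv;
  int nsub = (int)std::lround(p.fate_dt / p.dt);
  int nticks = (int)std::lround(hours / p.fate_dt);
  long clamped = 0, moves = 0;
  double conv_time = -1.0, fix_time = -1.0, loss_time = -1.0;
  long n_births = 0, n_removals = 0;

  for (int tick = 1; tick <= nticks; ++tick) {
    // mechanics substeps
    for (int s = 0; s < nsub; ++s)
      mechSubstep(q, p, &clamped, &moves);
    double t = p.t0 + tick * p.fate_dt;
    size_t n = q.n();

    // growth & contact inhibition
    std::vector<std::vector<int> > adj;
    buildAdjacency(q, p.contact_factor, adj);
    {
      std::vector<double> rad(n);
      for (size_t i = 0; i < n; ++i) rad[i] = radiusOf(q.vol[i]);
      for (size_t i = 0; i < n; ++i) {
        if (!isProlif(q.state[i])) { q.inhibited[i] = 0; continue; }
        double avail = q.vol[i];
        for (size_t k = 0; k < adj[i].size(); ++k) {
          int j = adj[i][k];
          double dx = q.x[i] - q.x[j], dy = q.y[i] - q.y[j],
                 dz = q.z[i] - q.z[j];
          avail -= lensVolume(rad[i], rad[j],
                              std::sqrt(dx * dx + dy * dy + dz * dz));
        }
        if (avail < 0.0) avail = 0.0;
        double vp_eff = p.vp_frac * q.v0[i] * q.vp_scale[i];
        if (avail >= vp_eff) {
          q.vol[i] += q.v0[i] / q.cgt[i] * p.fate_dt;
          q.inhibited[i] = 0;
          if (q.state[i] == 4) q.pc_wait[i] = 0.0;
        } else {
          q.inhibited[i] = 1;
          if (q.state[i] == 4) q.pc_wait[i] += p.fate_dt;
        }
      }
    }

    // divisions (random order among the ready cells)
    {
      std::vector<int> ready;
      for (size_t i = 0; i < n; ++i)
        if (isProlif(q.state[i]) && q.vol[i] >= 2.0 * q.v0[i])
          ready.push_back(i);
      std::vector<int> perm = randPerm(ready.size());
      for (size_t k = 0; k < ready.size(); ++k) {
        int i = ready[perm[k]];
        double Pm = axialP1(q.x[i], q.y[i], q.z[i], p.R);
        NumericMatrix dpos =
            cpp_division_placement(q.x[i], q.y[i], q.z[i], q.vol[i], p.R);
        int mstate = q.state[i];
        int dstate = (mstate == 4) ? 7 : mstate; // PC last-cycle rule
        int id1 = next_id++, id2 = next_id++;
        dv.add(t, q.id[i], id1, id2, Pm, mstate, q.founder[i], q.clone[i]);
        ev.add(t, 1, q.id[i], q.founder[i], q.clone[i], Pm, mstate, mstate);
        // mother slot becomes daughter 1
        double mv0 = q.v0[i];
        q.x[i] = dpos(0, 0); q.y[i] = dpos(0, 1); q.z[i] = dpos(0, 2);
        q.vol[i] = mv0; q.age[i] = 0.0;
        q.cgt[i] = drawCgt(p.cgt_mean, p.cgt_cv, q.cycle_delta[i]);
        q.id[i] = id1; q.state[i] = dstate; q.pc_wait[i] = 0.0;
        // daughter 2 appended
        q.x.push_back(dpos(1, 0)); q.y.push_back(dpos(1, 1));
        q.z.push_back(dpos(1, 2)); q.vol.push_back(mv0);
        q.v0.push_back(mv0); q.age.push_back(0.0);
        q.cgt.push_back(drawCgt(p.cgt_mean, p.cgt_cv, q.cycle_delta[i]));
        q.pc_clock.push_back(0.0); q.pc_age.push_back(0.0);
        q.lifespan.push_back(NA_REAL); q.pc_wait.push_back(0.0);
        q.vp_scale.push_back(q.vp_scale[i]);
        q.cycle_delta.push_back(q.cycle_delta[i]);
        q.id.push_back(id2); q.state.push_back(dstate);
        q.founder.push_back(q.founder[i]); q.clone.push_back(q.clone[i]);
        q.inhibited.push_back(0); q.C1.push_back(q.C1[i]);
        q.C2.push_back(q.C2[i]); q.pc_bias.push_back(q.pc_bias[i]);
        q.outside.push_back(q.outside[i]);
        n_births += 2; // two daughters replace one mother
        n_removals += 1;
        if (dstate == 7) { // both daughters terminal PCs
          int slots[2] = { i, (int)q.n() - 1 };
          for (int u = 0; u < 2; ++u) {
            int s2 = slots[u];
            q.lifespan[s2] = drawLifespan(p.tau_p, p.tau_cv);
            q.pc_age[s2] = 0.0; q.pc_clock[s2] = 0.0;
            double Pd = axialP1(q.x[s2], q.y[s2], q.z[s2], p.R);
            if (record_fate_events)
              ev.add(t, 6, q.id[s2], q.founder[s2], q.clone[s2], Pd, 4, 7);
          }
        }
      }
      n = q.n();
      if ((int)n > p.max_cells)
        stop("population exceeded max_cells (%d): runaway growth", p.max_cells);
    }

    // fate updates (sequential, randomized order, current states)
    buildAdjacency(q, p.contact_factor, adj);
    {
      std::vector<int> perm = randPerm(n);
      for (size_t k = 0; k < n; ++k) {
        int i = perm[k];
        int s = q.state[i];
        if (isTerminal(s)) continue;
        int nPC = 0, nGC = 0;
        for (size_t u = 0; u < adj[i].size(); ++u) {
          int sj = q.state[adj[i][u]];
          if (isPCstate(sj)) nPC++;
          else if (isGCstate(sj)) nGC++;
        }
        double Pi = axialP1(q.x[i], q.y[i], q.z[i], p.R);
        int sNew = fateDecision1(s, nPC, nGC, Pi, P1, P2, q.C1[i], q.C2[i],
                                 q.outside[i]);
        // PC progenitor stuck under contact inhibition converts without
        // dividing after max_pc_progenitor_wait hours
        if (s == 4 && sNew == 4 && q.pc_wait[i] > p.max_pc_wait) {
          sNew = 7;
          q.lifespan[i] = drawLifespan(p.tau_p, p.tau_cv);
          q.pc_age[i] = 0.0; q.pc_clock[i] = 0.0;
        }
        if (sNew != s) {
          q.state[i] = sNew;
          q.pc_wait[i] = 0.0;
          if (sNew == 5 || sNew == 6) q.inhibited[i] = 0;
          if (record_fate_events)
            ev.add(t, 6, q.id[i], q.founder[i], q.clone[i], Pi, s, sNew);
        }
      }
    }

    // PC death checks + anoikis/exit (single removal pass)
    buildAdjacency(q, p.contact_factor, adj);
    {
      std::vector<char> dead(n, 0);
      for (size_t i = 0; i < n; ++i) {
        double Pi = axialP1(q.x[i], q.y[i], q.z[i], p.R);
        if (q.state[i] == 7) {
          bool scContact = false;
          for (size_t u = 0; u < adj[i].size(); ++u)
            if (q.state[adj[i][u]] == 1) { scContact = true; break; }
          if (scContact) q.pc_clock[i] = 0.0;
          else q.pc_clock[i] += p.fate_dt;
          q.pc_age[i] += p.fate_dt;
          if (p.contact_death && q.pc_clock[i] > p.contact_thresh) {
            dead[i] = 1;
            ev.add(t, 5, q.id[i], q.founder[i], q.clone[i], Pi, 7, 7);
            continue;
          }
          if (q.pc_age[i] > q.lifespan[i]) {
            dead[i] = 1;
            ev.add(t, 4, q.id[i], q.founder[i], q.clone[i], Pi, 7, 7);
            continue;
          }
        }
        // anoikis: centre further from the membrane than radius + tolerance
        double ox, oy, oz;
        project1(q.x[i], q.y[i], q.z[i], p.R, ox, oy, oz);
        double dx = q.x[i] - ox, dy = q.y[i] - oy, dz = q.z[i] - oz;
        double dsep = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dsep > radiusOf(q.vol[i]) + p.tol) {
          dead[i] = 1;
          ev.add(t, 2, q.id[i], q.founder[i], q.clone[i], Pi,
                 q.state[i], q.state[i]);
          continue;
        }
        if (Pi > p.exitP) {
          dead[i] = 1;
          ev.add(t, 3, q.id[i], q.founder[i], q.clone[i], Pi,
                 q.state[i], q.state[i]);
        }
      }
      size_t nd = 0;
      for (size_t i = 0; i < n; ++i) nd += dead[i];
      if (nd > 0) removeCells(q, dead);
      n_removals += nd;
      n = q.n();
    }

    for (size_t i = 0; i < n; ++i) q.age[i] += p.fate_dt;

    // monoclonal-conversion / clone-resolution checks
    if (conv_time < 0.0 || check_clone) {
      int nSC = 0, sameF = -1;
      bool mono = true;
      bool cloneAllSC = true;
      long nCloneCells = 0;
      for (size_t i = 0; i < n; ++i) {
        if (q.clone[i] == 1) nCloneCells++; // the tracked (mutant) clone
        if (q.state[i] == 1) {
          nSC++;
          if (sameF < 0) sameF = q.founder[i];
          else if (q.founder[i] != sameF) mono = false;
          if (q.clone[i] != 1) cloneAllSC = false;
        }
      }
      if (conv_time < 0.0 && nSC > 0 && mono) conv_time = t;
      if (check_clone) {
        if (fix_time < 0.0 && nSC > 0 && cloneAllSC && nCloneCells > 0)
          fix_time = t;
        if (loss_time < 0.0 && nCloneCells == 0) loss_time = t;
      }
    }
    bool resolved = stop_on_conversion &&
                    (conv_time >= 0.0 &&
                     (!check_clone || fix_time >= 0.0 || loss_time >= 0.0));
    if (!check_clone && stop_on_conversion && conv_time >= 0.0) resolved = true;
    if (check_clone && stop_on_conversion &&
        (fix_time >= 0.0 || loss_time >= 0.0))
      resolved = true;
    if (resolved) break;
  }

  // repackage population
  size_t n = q.n();
  List out_pop = List::create(
      _["id"] = IntegerVector(q.id.begin(), q.id.end()),
      _["x"] = NumericVector(q.x.begin(), q.x.end()),
      _["y"] = NumericVector(q.y.begin(), q.y.end()),
      _["z"] = NumericVector(q.z.begin(), q.z.end()),
      _["volume"] = NumericVector(q.vol.begin(), q.vol.end()),
      _["v0"] = NumericVector(q.v0.begin(), q.v0.end()),
      _["state"] = IntegerVector(q.state.begin(), q.state.end()),
      _["founder"] = IntegerVector(q.founder.begin(), q.founder.end()),
      _["clone"] = IntegerVector(q.clone.begin(), q.clone.end()),
      _["age"] = NumericVector(q.age.begin(), q.age.end()),
      _["cycle_growth_time"] = NumericVector(q.cgt.begin(), q.cgt.end()),
      _["pc_clock"] = NumericVector(q.pc_clock.begin(), q.pc_clock.end()),
      _["pc_age"] = NumericVector(q.pc_age.begin(), q.pc_age.end()),
      _["intrinsic_lifespan"] =
          NumericVector(q.lifespan.begin(), q.lifespan.end()),
      _["pc_wait"] = NumericVector(q.pc_wait.begin(), q.pc_wait.end()),
      _["inhibited"] = IntegerVector(q.inhibited.begin(), q.inhibited.end()),
      _["C1_eff"] = IntegerVector(q.C1.begin(), q.C1.end()),
      _["C2_eff"] = IntegerVector(q.C2.begin(), q.C2.end()),
      _["vp_scale"] = NumericVector(q.vp_scale.begin(), q.vp_scale.end()));
  // List::create is limited to 20 slots; add the rest directly
  out_pop["cycle_delta"] =
      NumericVector(q.cycle_delta.begin(), q.cycle_delta.end());
  out_pop["pc_bias"] = IntegerVector(q.pc_bias.begin(), q.pc_bias.end());
  out_pop["outside_niche"] = IntegerVector(q.outside.begin(), q.outside.end());

  int nev = ev.rows.size() / 8;
  NumericMatrix evm(nev, 8);
  for (int i = 0; i < nev; ++i)
    for (int j = 0; j < 8; ++j) evm(i, j) = ev.rows[i * 8 + j];
  int ndv = dv.rows.size() / 8;
  NumericMatrix dvm(ndv, 8);
  for (int i = 0; i < ndv; ++i)
    for (int j = 0; j < 8; ++j) dvm(i, j) = dv.rows[i * 8 + j];

  return List::create(
      _["pop"] = out_pop, _["events"] = evm, _["divisions"] = dvm,
      _["conversion_time"] = conv_time, _["fix_time"] = fix_time,
      _["loss_time"] = loss_time, _["next_id"] = next_id,
      _["n_cells"] = (int)n, _["clamp_fraction"] =
          moves > 0 ? (double)clamped / (double)moves : 0.0,
      _["n_births"] = (double)n_births, _["n_removals"] = (double)n_removals);
}
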