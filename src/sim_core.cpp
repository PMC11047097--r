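// Core engine for the corrugated-microwell biofilm model.
//
// Cells are spherocylinders confined to the XY plane: a centerline segment of
// length `len` (caps excluded) with hemispherical caps of radius `r`.
// Mechanics: Hertzian-like cell-cell repulsion F = k_cell * overlap^{3/2},
// linear wall repulsion F = k_wall * penetration, breakable extension-only
// adhesion springs to the walls, overdamped dynamics v = F/(gamma*len),
// omega = tau/(gamma_rot*len^3). Cells crossing the open top (y > height)
// are removed. Units: um, h, pN.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double PI2 = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// small counter-based RNG (splitmix64): compact state, reproducible across
// calls without serializing a mersenne twister.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------
struct Well {
  double width, height, T, A;
  bool flat;
  double h(double x) const {
    return flat ? 0.0 : 0.5 * A * (1.0 - std::cos(PI2 * x / T));
  }
  double hp(double x) const {  // dh/dx
    return flat ? 0.0 : 0.5 * A * (PI2 / T) * std::sin(PI2 * x / T);
  }
};

static Well well_from_list(const List& spec) {
  Well w;
  w.width  = as<double>(spec["width"]);
  w.height = as<double>(spec["height"]);
  w.flat   = as<bool>(spec["flat"]);
  w.T = w.flat ? R_PosInf : as<double>(spec["period_T"]);
  w.A = w.flat ? 0.0      : as<double>(spec["amplitude_A"]);
  return w;
}

// squared distance from (px,py) to the bottom curve at abscissa u
static inline double d2_curve(const Well& w, double px, double py, double u) {
  double dy = py - w.h(u);
  double dx = px - u;
  return dx * dx + dy * dy;
}

// Nearest point on the sine bottom: coarse scan over one period around px,
// then ternary refinement to ~1e-8 um. Returns foot abscissa.
// For points close to the curve (the only ones that matter for forces) a
// Newton fast path on the foot condition (x-u) + (y-h(u)) h'(u) = 0
// converges in a few iterations; the scan is the robust fallback.
static double bottom_foot_scan(const Well& w, double px, double py);

static double bottom_foot(const Well& w, double px, double py) {
  if (w.flat) return px;
  if (std::fabs(py - w.h(px)) < 2.0) {
    double u = px;
    const double wpi2 = PI2 / w.T;
    for (int it = 0; it < 10; ++it) {
      double s = std::sin(wpi2 * u), c = std::cos(wpi2 * u);
      double h = 0.5 * w.A * (1.0 - c);
      double hp = 0.5 * w.A * wpi2 * s;
      double hpp = 0.5 * w.A * wpi2 * wpi2 * c;
      double g = (px - u) + (py - h) * hp;
      double gp = -1.0 + (py - h) * hpp - hp * hp;
      if (std::fabs(gp) < 1e-12) break;
      double du = g / gp;
      u -= du;
      if (std::fabs(u - px) > 0.5 * w.T) break;  // left the basin: fallback
      if (std::fabs(du) < 1e-8) {
        // Accept only a true local minimum (gp < 0) that reports a close
        // contact: Newton can land on the wrong flank's minimum for points
        // deep inside a valley, but for those the reported distance is
        // large, and only near-contact distances matter to the caller.
        if (gp < 0.0) {
          double ddx = px - u, ddy = py - w.h(u);
          if (ddx * ddx + ddy * ddy < 1.0) return u;
        }
        break;
      }
    }
  }
  return bottom_foot_scan(w, px, py);
}

static double bottom_foot_scan(const Well& w, double px, double py) {
  double lo = px - 0.5 * w.T, hi = px + 0.5 * w.T;
  const int NS = 24;
  double best_u = lo, best_d = d2_curve(w, px, py, lo);
  for (int i = 1; i <= NS; ++i) {
    double u = lo + (hi - lo) * i / NS;
    double d = d2_curve(w, px, py, u);
    if (d < best_d) { best_d = d; best_u = u; }
  }
  double a = best_u - (hi - lo) / NS, b = best_u + (hi - lo) / NS;
  for (int it = 0; it < 80; ++it) {
    double m1 = a + (b - a) / 3.0, m2 = b - (b - a) / 3.0;
    if (d2_curve(w, px, py, m1) < d2_curve(w, px, py, m2)) b = m2; else a = m1;
    if (b - a < 1e-9) break;
  }
  return 0.5 * (a + b);
}

// Signed distance (negative = penetrating) and outward normal for one wall.
// wall: 0 = bottom, 1 = left, 2 = right.
// `cutoff`: distances above it need not be exact (the caller applies no
// force there). For the sine bottom this enables a one-evaluation Lipschitz
// lower bound (euclidean distance to a graph with slope bound L is at least
// vertical distance / sqrt(1 + L^2)) that skips the foot search for the
// bulk of the near-bottom band.
static void wall_dist(const Well& w, int wall, double px, double py,
                      double& dist, double& nx, double& ny,
                      double& footx, double& footy,
                      double cutoff = R_PosInf) {
  if (wall == 1) {        // left wall x = 0
    dist = px; nx = 1.0; ny = 0.0; footx = 0.0; footy = py;
  } else if (wall == 2) { // right wall x = width
    dist = w.width - px; nx = -1.0; ny = 0.0; footx = w.width; footy = py;
  } else {                // bottom
    if (w.flat) {
      dist = py; nx = 0.0; ny = 1.0; footx = px; footy = 0.0;
    } else {
      if (R_finite(cutoff)) {
        double v = py - w.h(px);
        double L = 0.5 * w.A * PI2 / w.T;
        double lb = v / std::sqrt(1.0 + L * L);
        if (v >= 0.0 && lb > cutoff) {
          dist = lb; nx = 0.0; ny = 1.0; footx = px; footy = w.h(px);
          return;
        }
      }
      double u = bottom_foot(w, px, py);
      double hx = w.h(u), hpx = w.hp(u);
      double nn = std::sqrt(1.0 + hpx * hpx);
      nx = -hpx / nn; ny = 1.0 / nn;
      // signed distance via projection on the normal at the foot point
      dist = (px - u) * nx + (py - hx) * ny;
      footx = u; footy = hx;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_wall_contact(List spec, double px, double py) {
  Well w = well_from_list(spec);
  double best = R_PosInf, bnx = 0, bny = 0, bfx = 0, bfy = 0;
  int bwall = 0;
  for (int wall = 0; wall < 3; ++wall) {
    double d, nx, ny, fx, fy;
    wall_dist(w, wall, px, py, d, nx, ny, fx, fy);
    if (d < best) { best = d; bnx = nx; bny = ny; bwall = wall; bfx = fx; bfy = fy; }
  }
  return NumericVector::create(_["distance"] = best, _["nx"] = bnx,
                               _["ny"] = bny, _["wall"] = (double)bwall,
                               _["foot_x"] = bfx, _["foot_y"] = bfy);
}

// ---------------------------------------------------------------------------
// segment-segment closest points (Ericson, Real-Time Collision Detection)
static double closest_segments_d2(double p1x, double p1y, double q1x, double q1y,
                                  double p2x, double p2y, double q2x, double q2y,
                                  double& s, double& t) {
  double d1x = q1x - p1x, d1y = q1y - p1y;
  double d2x = q2x - p2x, d2y = q2y - p2y;
  double rx = p1x - p2x, ry = p1y - p2y;
  double a = d1x * d1x + d1y * d1y;
  double e = d2x * d2x + d2y * d2y;
  double f = d2x * rx + d2y * ry;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1x * rx + d1y * ry;
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1x * d2x + d1y * d2y;
      double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double cx1 = p1x + d1x * s, cy1 = p1y + d1y * s;
  double cx2 = p2x + d2x * t, cy2 = p2y + d2y * t;
  double dx = cx1 - cx2, dy = cy1 - cy2;
  return dx * dx + dy * dy;
}

static inline double closest_segments(double p1x, double p1y, double q1x,
                                      double q1y, double p2x, double p2y,
                                      double q2x, double q2y,
                                      double& s, double& t) {
  return std::sqrt(closest_segments_d2(p1x, p1y, q1x, q1y,
                                       p2x, p2y, q2x, q2y, s, t));
}

// Contact parameters for the repulsive force. For near-parallel segments
// the minimum-distance point is an endpoint that switches sides
// discontinuously as the relative angle crosses zero, which makes stacked
// (nematically aligned) cells exchange alternating torques and pump
// energy. In that regime the force is applied at the midpoint of the
// overlapping span instead, which is continuous in the configuration.
static inline double contact_params(double p1x, double p1y, double q1x,
                                    double q1y, double p2x, double p2y,
                                    double q2x, double q2y,
                                    double& s, double& t) {
  double d2 = closest_segments_d2(p1x, p1y, q1x, q1y,
                                  p2x, p2y, q2x, q2y, s, t);
  double d1xv = q1x - p1x, d1yv = q1y - p1y;
  double d2xv = q2x - p2x, d2yv = q2y - p2y;
  double a = d1xv * d1xv + d1yv * d1yv;
  double e = d2xv * d2xv + d2yv * d2yv;
  if (a > 1e-12 && e > 1e-12) {
    double b = d1xv * d2xv + d1yv * d2yv;
    if (b * b > 0.995 * a * e) {  // within ~4 degrees of parallel
      double t0 = ((p2x - p1x) * d1xv + (p2y - p1y) * d1yv) / a;
      double t1 = ((q2x - p1x) * d1xv + (q2y - p1y) * d1yv) / a;
      double lo = std::max(0.0, std::min(t0, t1));
      double hi = std::min(1.0, std::max(t0, t1));
      if (hi >= lo) {
        double sm = 0.5 * (lo + hi);
        double cx = p1x + d1xv * sm, cy = p1y + d1yv * sm;
        double tm = ((cx - p2x) * d2xv + (cy - p2y) * d2yv) / e;
        tm = std::min(1.0, std::max(0.0, tm));
        double ex = p2x + d2xv * tm, ey = p2y + d2yv * tm;
        double dx = cx - ex, dy = cy - ey;
        s = sm; t = tm;
        return dx * dx + dy * dy;
      }
    }
  }
  return d2;
}

// [[Rcpp::export]]
List cpp_segment_closest(NumericVector segA, NumericVector segB) {
  double s, t;
  double d = closest_segments(segA[0], segA[1], segA[2], segA[3],
                              segB[0], segB[1], segB[2], segB[3], s, t);
  return List::create(_["distance"] = d, _["s"] = s, _["t"] = t);
}

// ---------------------------------------------------------------------------
struct Spring {
  bool active;
  double ax, ay;    // wall anchor
  double rest;      // rest length
  double tfrac;     // attach abscissa as fraction of half centerline [-1, 1]
};

struct Cell {
  double x, y, ang, len, r, gmult;
  int id, founder, genotype, strain;
  Spring spr[3];
};

static inline void endpoints(const Cell& c, double& ax, double& ay,
                             double& bx, double& by) {
  double ux = std::cos(c.ang), uy = std::sin(c.ang);
  double hl = 0.5 * c.len;
  ax = c.x - hl * ux; ay = c.y - hl * uy;
  bx = c.x + hl * ux; by = c.y + hl * uy;
}

struct Params {
  double k_cell, k_wall, k_adhesion, eps_max, gamma, gamma_rot;
  double dt, elongation_rate, l_div, l_min, radius, division_angle_noise;
  double sub_cap_frac, verlet_skin;
  bool adhesion_on;
};

static Params params_from_list(const List& p) {
  Params q;
  q.k_cell = as<double>(p["k_cell"]);
  q.k_wall = as<double>(p["k_wall"]);
  q.k_adhesion = as<double>(p["k_adhesion"]);
  q.eps_max = as<double>(p["epsilon_max"]);
  q.gamma = as<double>(p["gamma"]);
  q.gamma_rot = as<double>(p["gamma_rot"]);
  q.dt = as<double>(p["dt"]);
  q.elongation_rate = as<double>(p["elongation_rate"]);
  q.l_div = as<double>(p["l_div"]);
  q.l_min = as<double>(p["l_min"]);
  q.radius = as<double>(p["radius"]);
  q.division_angle_noise = as<double>(p["division_angle_noise"]);
  q.sub_cap_frac = p.containsElementNamed("sub_cap_frac") ?
      as<double>(p["sub_cap_frac"]) : 0.08;
  q.verlet_skin = p.containsElementNamed("verlet_skin") ?
      as<double>(p["verlet_skin"]) : 0.45;
  q.adhesion_on = q.k_adhesion > 0.0;
  return q;
}

// exponential-integrator stabilization for stiff one-sided contacts:
// scales a force whose linearized relaxation rate over dt is mu so that an
// explicit step cannot overshoot (exact for a single linear contact).
static inline double stab(double mu) {
  // Rational approximation of (1 - exp(-mu))/mu built from the Pade form
  // of exp(-mu): accurate for small mu and with the correct 1/mu asymptote
  // for stiff contacts, without an exp() in the innermost contact loop.
  double s = 1.0 + mu * (1.0 + mu * (0.5 + mu / 6.0));
  return (1.0 + mu * (0.5 + mu / 6.0)) / s;
}

// pairwise Hertzian force; raw = no stabilization (dt <= 0)
static bool pair_force(const Cell& A, const Cell& B, double k_cell,
                       double dt, double gamma,
                       double& fx, double& fy, double& tqA, double& tqB,
                       double* energy) {
  double a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y, s, t;
  endpoints(A, a1x, a1y, b1x, b1y);
  endpoints(B, a2x, a2y, b2x, b2y);
  double d = std::sqrt(contact_params(a1x, a1y, b1x, b1y,
                                      a2x, a2y, b2x, b2y, s, t));
  double o = A.r + B.r - d;
  if (o <= 0.0) return false;
  double pAx = a1x + (b1x - a1x) * s, pAy = a1y + (b1y - a1y) * s;
  double pBx = a2x + (b2x - a2x) * t, pBy = a2y + (b2y - a2y) * t;
  double nx, ny;
  if (d > 1e-9) { nx = (pAx - pBx) / d; ny = (pAy - pBy) / d; }
  else {
    // coincident centerlines: deterministic perpendicular from id hash
    uint64_t hsh = (uint64_t)(A.id * 2654435761u) ^ (uint64_t)(B.id * 40503u);
    double sgn = (hsh & 1u) ? 1.0 : -1.0;
    nx = -std::sin(A.ang) * sgn; ny = std::cos(A.ang) * sgn;
  }
  double F = k_cell * o * std::sqrt(o);
  if (dt > 0.0) {
    double lA = std::max(A.len, 0.5), lB = std::max(B.len, 0.5);
    double mu = dt * 4.5 * k_cell * std::sqrt(o) * (1.0 / (gamma * lA) + 1.0 / (gamma * lB));
    F *= stab(mu);
  }
  fx = F * nx; fy = F * ny;
  tqA = (pAx - A.x) * fy - (pAy - A.y) * fx;
  tqB = -((pBx - B.x) * fy - (pBy - B.y) * fx);
  if (energy) *energy += 0.4 * k_cell * o * o * std::sqrt(o);
  return true;
}

// [[Rcpp::export]]
List cpp_pair_repulsion(NumericVector cellA, NumericVector cellB, double k_cell) {
  // cell vectors: x, y, angle, length, radius, id
  Cell A{}, B{};
  A.x = cellA[0]; A.y = cellA[1]; A.ang = cellA[2]; A.len = cellA[3];
  A.r = cellA[4]; A.id = (int)cellA[5];
  B.x = cellB[0]; B.y = cellB[1]; B.ang = cellB[2]; B.len = cellB[3];
  B.r = cellB[4]; B.id = (int)cellB[5];
  double fx = 0, fy = 0, tqA = 0, tqB = 0;
  bool hit = pair_force(A, B, k_cell, -1.0, 1.0, fx, fy, tqA, tqB, nullptr);
  if (!hit) { fx = fy = tqA = tqB = 0.0; }
  return List::create(_["forceA"] = NumericVector::create(fx, fy),
                      _["forceB"] = NumericVector::create(-fx, -fy),
                      _["torqueA"] = tqA, _["torqueB"] = tqB);
}

// Per-cell stiffness accumulator for the implicit (backward-Euler)
// treatment of stiff wall and adhesion springs: translational 2x2 block
// plus a scalar rotational stiffness about the cell center. The
// translation-rotation coupling is dropped (block-diagonal approximation);
// the displacement-capped sub-stepping guards the residual coupled modes.
struct StiffAcc {
  double kxx = 0, kxy = 0, kyy = 0, krot = 0;
  void add(double k, double nx, double ny, double rx, double ry) {
    kxx += k * nx * nx; kxy += k * nx * ny; kyy += k * ny * ny;
    double lever = rx * ny - ry * nx;
    krot += k * lever * lever;
  }
};

// wall repulsion sampled at the two cap centers and the midpoint
static double pen_info[4];  // diagnostics: argmax wall penetration

// Wall contact sampling. Flat walls are linear, so the two cap centers and
// the midpoint sample penetration exactly (max at an endpoint). The sine
// bottom has curvature radius down to ~(T/2pi)^2*(2/A); a long cell pressed
// onto a convex ridge can penetrate *between* coarse samples (sagitta
// ~ spacing^2/8R), so corrugated wells use 9 equidistant centerline points,
// keeping the unsampled penetration below 0.04 um for division-length
// cells at the sharpest shipped corrugation.
static void wall_force_cell(const Cell& c, const Well& w, double k_wall,
                            double& fx, double& fy, double& tq,
                            double* energy, double* max_pen,
                            StiffAcc* acc) {
  double ax, ay, bx, by;
  endpoints(c, ax, ay, bx, by);
  int nsp = w.flat ? 3 : 9;
  double sx[9], sy[9];
  for (int i = 0; i < nsp; ++i) {
    double tf = (nsp == 3) ? (i - 1) * 1.0 : (i - 4) * 0.25;
    double lam = 0.5 * (1.0 + tf);
    sx[i] = ax + (bx - ax) * lam;
    sy[i] = ay + (by - ay) * lam;
  }
  for (int i = 0; i < nsp; ++i) {
    // skip bottom query when clearly far above the corrugation
    for (int wall = 0; wall < 3; ++wall) {
      if (wall == 0 && sy[i] > w.A + c.r + 0.5) continue;
      if (wall == 1 && sx[i] > c.r + 0.5) continue;
      if (wall == 2 && sx[i] < w.width - c.r - 0.5) continue;
      double d, nx, ny, fpx, fpy;
      wall_dist(w, wall, sx[i], sy[i], d, nx, ny, fpx, fpy, c.r + 0.01);
      double p = c.r - d;
      if (p <= 0.0) continue;
      double F = k_wall * p;
      fx += F * nx; fy += F * ny;
      tq += (sx[i] - c.x) * (F * ny) - (sy[i] - c.y) * (F * nx);
      if (energy) *energy += 0.5 * k_wall * p * p;
      if (max_pen && p > *max_pen) {
        *max_pen = p;
        pen_info[0] = sx[i]; pen_info[1] = sy[i];
        pen_info[2] = (double)wall; pen_info[3] = c.len;
      }
      if (acc) acc->add(k_wall, nx, ny, sx[i] - c.x, sy[i] - c.y);
    }
  }
}

// [[Rcpp::export]]
List cpp_wall_forces(NumericVector cell, List spec, double k_wall) {
  Well w = well_from_list(spec);
  Cell c{};
  c.x = cell[0]; c.y = cell[1]; c.ang = cell[2]; c.len = cell[3]; c.r = cell[4];
  double fx = 0, fy = 0, tq = 0;
  wall_force_cell(c, w, k_wall, fx, fy, tq, nullptr, nullptr, nullptr);
  return List::create(_["force"] = NumericVector::create(fx, fy),
                      _["torque"] = tq);
}

// adhesion spring bookkeeping + force for one cell
static void adhesion_cell(Cell& c, const Well& w, const Params& P,
                          double& fx, double& fy, double& tq, double* energy,
                          StiffAcc* acc) {
  double ax, ay, bx, by;
  endpoints(c, ax, ay, bx, by);
  double sx[3] = {ax, c.x, bx}, sy[3] = {ay, c.y, by};
  double tf[3] = {-1.0, 0.0, 1.0};
  for (int wall = 0; wall < 3; ++wall) {
    Spring& sp = c.spr[wall];
    if (!sp.active) {
      // create on first contact: nearest sample point within `radius`
      double bestd = R_PosInf, bfx = 0, bfy = 0, btf = 0;
      for (int i = 0; i < 3; ++i) {
        if (wall == 0 && sy[i] > w.A + c.r + 0.25) continue;
        if (wall == 1 && sx[i] > c.r + 0.25) continue;
        if (wall == 2 && sx[i] < w.width - c.r - 0.25) continue;
        double d, nx, ny, fpx, fpy;
        wall_dist(w, wall, sx[i], sy[i], d, nx, ny, fpx, fpy, c.r + 0.01);
        if (d < c.r && d < bestd) { bestd = d; bfx = fpx; bfy = fpy; btf = tf[i]; }
      }
      if (R_finite(bestd)) {
        sp.active = true;
        sp.ax = bfx; sp.ay = bfy;
        sp.rest = std::max(bestd, 0.05 * c.r);
        sp.tfrac = btf;
      }
      continue;
    }
    // attach point follows the centerline abscissa
    double ux = std::cos(c.ang), uy = std::sin(c.ang);
    double px = c.x + sp.tfrac * 0.5 * c.len * ux;
    double py = c.y + sp.tfrac * 0.5 * c.len * uy;
    double dx = sp.ax - px, dy = sp.ay - py;
    double L = std::sqrt(dx * dx + dy * dy);
    double e = L - sp.rest;
    if (e <= 0.0) continue;             // extension-only
    if (e > P.eps_max * sp.rest) {      // broken
      sp.active = false;
      continue;
    }
    double F = P.k_adhesion * e;
    double nx = dx / L, ny = dy / L;
    fx += F * nx; fy += F * ny;
    tq += (px - c.x) * (F * ny) - (py - c.y) * (F * nx);
    if (energy) *energy += 0.5 * P.k_adhesion * e * e;
    if (acc) acc->add(P.k_adhesion, nx, ny, px - c.x, py - c.y);
  }
}

// [[Rcpp::export]]
List cpp_adhesion_forces(NumericVector cell, DataFrame springs, List spec,
                         List params) {
  Well w = well_from_list(spec);
  Params P = params_from_list(params);
  Cell c{};
  c.x = cell[0]; c.y = cell[1]; c.ang = cell[2]; c.len = cell[3]; c.r = cell[4];
  for (int i = 0; i < 3; ++i) c.spr[i].active = false;
  IntegerVector swall = springs["wall"];
  NumericVector sax = springs["anchor_x"], say = springs["anchor_y"],
                srest = springs["rest_length"], stf = springs["attach_frac"];
  for (int j = 0; j < swall.size(); ++j) {
    Spring& sp = c.spr[swall[j]];
    sp.active = true; sp.ax = sax[j]; sp.ay = say[j];
    sp.rest = srest[j]; sp.tfrac = stf[j];
  }
  double fx = 0, fy = 0, tq = 0;
  adhesion_cell(c, w, P, fx, fy, tq, nullptr, nullptr);
  int nact = 0;
  for (int i = 0; i < 3; ++i) if (c.spr[i].active) ++nact;
  IntegerVector owall(nact);
  NumericVector oax(nact), oay(nact), orest(nact), otf(nact);
  int j = 0;
  for (int i = 0; i < 3; ++i) {
    if (!c.spr[i].active) continue;
    owall[j] = i; oax[j] = c.spr[i].ax; oay[j] = c.spr[i].ay;
    orest[j] = c.spr[i].rest; otf[j] = c.spr[i].tfrac; ++j;
  }
  return List::create(
      _["force"] = NumericVector::create(fx, fy), _["torque"] = tq,
      _["springs"] = DataFrame::create(
          _["wall"] = owall, _["anchor_x"] = oax, _["anchor_y"] = oay,
          _["rest_length"] = orest, _["attach_frac"] = otf));
}

// ---------------------------------------------------------------------------
// state <-> R conversion

static std::vector<Cell> cells_from_list(const List& st) {
  DataFrame cd = as<DataFrame>(st["cells"]);
  IntegerVector id = cd["id"], founder = cd["founder_id"],
                genotype = cd["genotype"], strain = cd["strain_i"];
  NumericVector x = cd["x"], y = cd["y"], ang = cd["angle"], len = cd["length"],
                r = cd["radius"], gm = cd["growth_multiplier"];
  int n = id.size();
  std::vector<Cell> cells((size_t)n);
  for (int i = 0; i < n; ++i) {
    Cell& c = cells[i];
    c.x = x[i]; c.y = y[i]; c.ang = ang[i]; c.len = len[i]; c.r = r[i];
    c.gmult = gm[i]; c.id = id[i]; c.founder = founder[i];
    c.genotype = genotype[i]; c.strain = strain[i];
    for (int w = 0; w < 3; ++w) c.spr[w].active = false;
  }
  DataFrame sd = as<DataFrame>(st["springs"]);
  IntegerVector scell = sd["cell_id"], swall = sd["wall"];
  NumericVector sax = sd["anchor_x"], say = sd["anchor_y"],
                srest = sd["rest_length"], stf = sd["attach_frac"];
  if (scell.size() > 0) {
    std::map<int, int> idx;
    for (int i = 0; i < n; ++i) idx[cells[i].id] = i;
    for (int j = 0; j < scell.size(); ++j) {
      auto it = idx.find(scell[j]);
      if (it == idx.end()) continue;
      Spring& sp = cells[it->second].spr[swall[j]];
      sp.active = true; sp.ax = sax[j]; sp.ay = say[j];
      sp.rest = srest[j]; sp.tfrac = stf[j];
    }
  }
  return cells;
}

static List cells_to_list(const std::vector<Cell>& cells) {
  int n = (int)cells.size();
  IntegerVector id(n), founder(n), genotype(n), strain(n);
  NumericVector x(n), y(n), ang(n), len(n), r(n), gm(n);
  int nspr = 0;
  for (const Cell& c : cells)
    for (int w = 0; w < 3; ++w) if (c.spr[w].active) ++nspr;
  IntegerVector scell(nspr), swall(nspr);
  NumericVector sax(nspr), say(nspr), srest(nspr), stf(nspr);
  int j = 0;
  for (int i = 0; i < n; ++i) {
    const Cell& c = cells[i];
    id[i] = c.id; founder[i] = c.founder; genotype[i] = c.genotype;
    strain[i] = c.strain; x[i] = c.x; y[i] = c.y; ang[i] = c.ang;
    len[i] = c.len; r[i] = c.r; gm[i] = c.gmult;
    for (int w = 0; w < 3; ++w) {
      if (!c.spr[w].active) continue;
      scell[j] = c.id; swall[j] = w; sax[j] = c.spr[w].ax; say[j] = c.spr[w].ay;
      srest[j] = c.spr[w].rest; stf[j] = c.spr[w].tfrac; ++j;
    }
  }
  DataFrame cd = DataFrame::create(
      _["id"] = id, _["founder_id"] = founder, _["genotype"] = genotype,
      _["strain_i"] = strain, _["x"] = x, _["y"] = y, _["angle"] = ang,
      _["length"] = len, _["radius"] = r, _["growth_multiplier"] = gm);
  DataFrame sd = DataFrame::create(
      _["cell_id"] = scell, _["wall"] = swall, _["anchor_x"] = sax,
      _["anchor_y"] = say, _["rest_length"] = srest, _["attach_frac"] = stf);
  return List::create(_["cells"] = cd, _["springs"] = sd);
}

// ---------------------------------------------------------------------------
// broad phase: uniform grid with bin size >= max cell extent

struct Grid {
  double bin, invbin;
  int nx, ny;
  std::vector<int> head, nxt;
  void build(const std::vector<Cell>& cells, double width, double height,
             double bin_size) {
    bin = bin_size; invbin = 1.0 / bin;
    nx = std::max(1, (int)std::ceil(width / bin));
    ny = std::max(1, (int)std::ceil((height + bin) / bin));
    head.assign((size_t)nx * ny, -1);
    nxt.assign(cells.size(), -1);
    for (int i = 0; i < (int)cells.size(); ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)(cells[i].x * invbin)));
      int cy = std::min(ny - 1, std::max(0, (int)(cells[i].y * invbin)));
      int b = cy * nx + cx;
      nxt[i] = head[b]; head[b] = i;
    }
  }
};

// force assembly over all cells; returns max wall penetration seen
struct Workspace {
  std::vector<double> e1x, e1y, e2x, e2y;  // precomputed cap centers
  std::vector<StiffAcc> stiff;             // wall/adhesion stiffness blocks
  // Verlet neighbor structures, rebuilt when accumulated motion can close
  // the skin or when the cell vector changes (division/removal)
  std::vector<int> plist;                  // flattened (i, j) pairs
  std::vector<char> near_wall;
  std::vector<int> deep_pairs;             // pairs overlapping > DEEP_O
  bool valid = false;
  double motion_accum = 0.0;
};

// overlap beyond which the position-based anti-tunneling projection kicks
// in (the stabilized explicit force alone cannot win against clipped
// squeezing once contacts get this deep)
static const double DEEP_O = 0.35;
static const double DEEP_PUSH = 0.02;  // um per step and cell

static void build_neighbors(const std::vector<Cell>& cells, const Well& w,
                            const Params& P, Grid& grid, Workspace& W) {
  int n = (int)cells.size();
  W.plist.clear();
  W.near_wall.assign(n, 0);
  double bin_size = P.l_div + 2.0 * P.radius + P.verlet_skin + 0.1;
  grid.build(cells, w.width, w.height, bin_size);
  for (int i = 0; i < n; ++i) {
    const Cell& ci = cells[i];
    int cx = std::min(grid.nx - 1, std::max(0, (int)(ci.x * grid.invbin)));
    int cy = std::min(grid.ny - 1, std::max(0, (int)(ci.y * grid.invbin)));
    double reach_i = 0.5 * ci.len + ci.r + P.verlet_skin;
    for (int gy = std::max(0, cy - 1); gy <= std::min(grid.ny - 1, cy + 1); ++gy)
      for (int gx = std::max(0, cx - 1); gx <= std::min(grid.nx - 1, cx + 1); ++gx)
        for (int j = grid.head[gy * grid.nx + gx]; j >= 0; j = grid.nxt[j]) {
          if (j <= i) continue;
          const Cell& cj = cells[j];
          double ddx = ci.x - cj.x, ddy = ci.y - cj.y;
          double reach = reach_i + 0.5 * cj.len + cj.r;
          if (ddx * ddx + ddy * ddy > reach * reach) continue;
          W.plist.push_back(i);
          W.plist.push_back(j);
        }
    // wall proximity with the same skin
    double ylo = ci.y - 0.5 * ci.len - ci.r - P.verlet_skin;
    double xlo = ci.x - 0.5 * ci.len - ci.r - P.verlet_skin;
    double xhi = ci.x + 0.5 * ci.len + ci.r + P.verlet_skin;
    if (ylo < w.A || xlo < 0.0 || xhi > w.width) W.near_wall[i] = 1;
  }
  W.valid = true;
  W.motion_accum = 0.0;
}

static void assemble_forces(std::vector<Cell>& cells, const Well& w,
                            const Params& P, double dt, Grid& grid,
                            Workspace& W,
                            std::vector<double>& fx, std::vector<double>& fy,
                            std::vector<double>& tq, double* max_pen,
                            double* energy) {
  int n = (int)cells.size();
  fx.assign(n, 0.0); fy.assign(n, 0.0); tq.assign(n, 0.0);
  W.stiff.assign(n, StiffAcc());
  W.deep_pairs.clear();
  W.e1x.resize(n); W.e1y.resize(n); W.e2x.resize(n); W.e2y.resize(n);
  for (int i = 0; i < n; ++i)
    endpoints(cells[i], W.e1x[i], W.e1y[i], W.e2x[i], W.e2y[i]);
  if (!W.valid || 2.0 * W.motion_accum > 0.9 * P.verlet_skin)
    build_neighbors(cells, w, P, grid, W);
  for (size_t q = 0; q < W.plist.size(); q += 2) {
    int i = W.plist[q], j = W.plist[q + 1];
    Cell& ci = cells[i];
    Cell& cj = cells[j];
    double ddx = ci.x - cj.x, ddy = ci.y - cj.y;
    double reach = 0.5 * (ci.len + cj.len) + ci.r + cj.r;
    if (ddx * ddx + ddy * ddy > reach * reach) continue;
    double s, t;
    double d2 = contact_params(W.e1x[i], W.e1y[i], W.e2x[i], W.e2y[i],
                               W.e1x[j], W.e1y[j], W.e2x[j], W.e2y[j],
                               s, t);
    double rsum = ci.r + cj.r;
    if (d2 >= rsum * rsum) continue;
    double d = std::sqrt(d2);
    double o = rsum - d;
    double pAx = W.e1x[i] + (W.e2x[i] - W.e1x[i]) * s;
    double pAy = W.e1y[i] + (W.e2y[i] - W.e1y[i]) * s;
    double pBx = W.e1x[j] + (W.e2x[j] - W.e1x[j]) * t;
    double pBy = W.e1y[j] + (W.e2y[j] - W.e1y[j]) * t;
    double nx2, ny2;
    if (d > 1e-9) { nx2 = (pAx - pBx) / d; ny2 = (pAy - pBy) / d; }
    else {
      uint64_t hsh = (uint64_t)(ci.id * 2654435761u) ^
                     (uint64_t)(cj.id * 40503u);
      double sgn = (hsh & 1u) ? 1.0 : -1.0;
      nx2 = -std::sin(ci.ang) * sgn; ny2 = std::cos(ci.ang) * sgn;
    }
    double so = std::sqrt(o);
    double F = P.k_cell * o * so;
    if (dt > 0.0) {
      double lA = std::max(ci.len, 0.5), lB = std::max(cj.len, 0.5);
      double mu = dt * 4.5 * P.k_cell * so *
                  (1.0 / (P.gamma * lA) + 1.0 / (P.gamma * lB));
      F *= stab(mu);
    }
    if (energy) *energy += 0.4 * P.k_cell * o * o * so;
    if (o > DEEP_O && dt > 0.0) {
      W.deep_pairs.push_back(i);
      W.deep_pairs.push_back(j);
    }
    double pfx = F * nx2, pfy = F * ny2;
    fx[i] += pfx; fy[i] += pfy;
    tq[i] += (pAx - ci.x) * pfy - (pAy - ci.y) * pfx;
    fx[j] -= pfx; fy[j] -= pfy;
    tq[j] -= (pBx - cj.x) * pfy - (pBy - cj.y) * pfx;
  }
  for (int i = 0; i < n; ++i) {
    if (!W.near_wall[i]) continue;
    StiffAcc* acc = (dt > 0.0) ? &W.stiff[i] : nullptr;
    wall_force_cell(cells[i], w, P.k_wall, fx[i], fy[i], tq[i], energy,
                    max_pen, acc);
    if (P.adhesion_on)
      adhesion_cell(cells[i], w, P, fx[i], fy[i], tq[i], energy, acc);
  }
}

// [[Rcpp::export]]
double cpp_total_energy(List state, List spec, List params) {
  Well w = well_from_list(spec);
  Params P = params_from_list(params);
  std::vector<Cell> cells = cells_from_list(state);
  Grid grid;
  Workspace ws;
  std::vector<double> fx, fy, tq;
  double energy = 0.0;
  // adhesion creation would mutate springs; copy is local so harmless
  assemble_forces(cells, w, P, -1.0, grid, ws, fx, fy, tq, nullptr, &energy);
  return energy;
}

// [[Rcpp::export]]
List cpp_net_forces(List state, List spec, List params) {
  Well w = well_from_list(spec);
  Params P = params_from_list(params);
  std::vector<Cell> cells = cells_from_list(state);
  Grid grid;
  Workspace ws;
  std::vector<double> fx, fy, tq;
  assemble_forces(cells, w, P, -1.0, grid, ws, fx, fy, tq, nullptr, nullptr);
  return List::create(_["fx"] = wrap(fx), _["fy"] = wrap(fy),
                      _["torque"] = wrap(tq));
}

// per-cell pairwise interaction forces (Newton's third law bookkeeping):
// returns the n x 2 matrix of summed cell-cell forces, so callers can check
// that columns sum to zero.
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces_all(List state, List params) {
  Params P = params_from_list(params);
  std::vector<Cell> cells = cells_from_list(state);
  int n = (int)cells.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double pfx, pfy, tA, tB;
      if (pair_force(cells[i], cells[j], P.k_cell, -1.0, P.gamma,
                     pfx, pfy, tA, tB, nullptr)) {
        out(i, 0) += pfx; out(i, 1) += pfy;
        out(j, 0) -= pfx; out(j, 1) -= pfy;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// main driver: advance state to t_target with snapshoting handled in R

// [[Rcpp::export]]
List cpp_advance(List state, List spec, List params, double t_target,
                 NumericVector phase_times, NumericMatrix phase_mult,
                 double retag_at, bool adaptive) {
  Well w = well_from_list(spec);
  Params P = params_from_list(params);
  std::vector<Cell> cells = cells_from_list(state);
  double time = as<double>(state["time"]);
  int removed = as<int>(state["removed_count"]);
  double removed_area = as<double>(state["removed_area"]);
  int next_id = as<int>(state["next_id"]);
  uint64_t rs = ((uint64_t)(uint32_t)as<int>(state["rng_hi"]) << 32) |
                (uint64_t)(uint32_t)as<int>(state["rng_lo"]);
  SplitMix rng(rs);
  bool retagged = as<bool>(state["retagged"]);

  Grid grid;
  Workspace ws;
  std::vector<double> fx, fy, tq;
  double max_pen = 0.0, max_disp = 0.0;
  const double disp_cap = 0.05 * P.radius;
  // with implicit walls and stabilized pair forces the sub-step cap guards
  // only collective modes; the default fraction balances robustness
  // against sub-step churn from persistently loaded contacts
  const double sub_cap = P.sub_cap_frac * P.radius;
  long n_force_evals = 0;

  while (time < t_target - 1e-12) {
    // founder re-tagging for survival statistics
    if (!retagged && retag_at >= 0.0 && time >= retag_at - 1e-12) {
      for (Cell& c : cells) c.founder = c.id;
      retagged = true;
    }
    // growth multipliers from the active protocol phase; exp() factors
    // hoisted out of the per-cell growth loop
    int ph = 0;
    for (int k = 0; k < phase_times.size(); ++k)
      if (time >= phase_times[k] - 1e-12) ph = k;
    double gmul[8], gfac[8];
    int nstr = std::min(8, (int)phase_mult.ncol());
    for (int si = 0; si < nstr; ++si) {
      gmul[si] = phase_mult(ph, si);
      gfac[si] = std::exp(gmul[si] * P.elongation_rate * P.dt);
    }
    for (Cell& c : cells) {
      int si = c.strain - 1;
      c.gmult = (si >= 0 && si < nstr) ? gmul[si] : 1.0;
    }

    double dt = std::min(P.dt, t_target - time);

    // One mechanics step over dt: stiff wall/adhesion springs are
    // integrated implicitly per cell (backward Euler on the accumulated
    // stiffness blocks), soft Hertzian pair forces explicitly with the
    // stabilization factor. Per-cell displacements are clipped at the
    // trust-region cap (`sub_cap_frac * radius`): a rare transient spike
    // (e.g. right after a division) relaxes over a few steps at the capped
    // speed instead of forcing global sub-stepping. With `adaptive =
    // FALSE` an over-cap displacement aborts instead.
    {
      assemble_forces(cells, w, P, P.dt, grid, ws, fx, fy, tq, &max_pen,
                      nullptr);
      ++n_force_evals;
      int nn = (int)cells.size();
      double md = 0.0;
      for (int i = 0; i < nn; ++i) {
        Cell& c = cells[i];
        double li = std::max(c.len, 0.5);
        double a = P.gamma * li / dt;
        const StiffAcc& K = ws.stiff[i];
        double m11 = a + K.kxx, m12 = K.kxy, m22 = a + K.kyy;
        double det = m11 * m22 - m12 * m12;
        double dx = (m22 * fx[i] - m12 * fy[i]) / det;
        double dy = (m11 * fy[i] - m12 * fx[i]) / det;
        double dth = tq[i] * dt / (P.gamma_rot * li * li * li + dt * K.krot);
        double disp = std::sqrt(dx * dx + dy * dy) +
                      std::fabs(dth) * (0.5 * li + c.r);
        if (disp > sub_cap) {
          if (!adaptive && disp > disp_cap)
            stop("integration unstable: per-step displacement %f um exceeds "
                 "0.05*radius at t=%f; reduce dt or soften stiffnesses",
                 disp, time);
          double sc = sub_cap / disp;
          dx *= sc; dy *= sc; dth *= sc;
          disp = sub_cap;
        }
        c.x += dx; c.y += dy; c.ang += dth;
        if (c.ang > M_PI) c.ang -= PI2;
        if (c.ang < -M_PI) c.ang += PI2;
        if (disp > md) md = disp;
        double dlin = std::sqrt(dx * dx + dy * dy);
        if (dlin > max_disp) max_disp = dlin;
      }
      ws.motion_accum += md;
      // anti-tunneling projection: separate deeply overlapping pairs by a
      // bounded amount so clipped force chains cannot squeeze cells
      // through each other
      for (size_t q = 0; q < ws.deep_pairs.size(); q += 2) {
        int i = ws.deep_pairs[q], j = ws.deep_pairs[q + 1];
        Cell& ci = cells[i];
        Cell& cj = cells[j];
        double a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y, s, t;
        endpoints(ci, a1x, a1y, b1x, b1y);
        endpoints(cj, a2x, a2y, b2x, b2y);
        double d = closest_segments(a1x, a1y, b1x, b1y,
                                    a2x, a2y, b2x, b2y, s, t);
        double o = ci.r + cj.r - d;
        if (o <= DEEP_O) continue;
        double pAx = a1x + (b1x - a1x) * s, pAy = a1y + (b1y - a1y) * s;
        double pBx = a2x + (b2x - a2x) * t, pBy = a2y + (b2y - a2y) * t;
        double nx2, ny2;
        if (d > 1e-9) { nx2 = (pAx - pBx) / d; ny2 = (pAy - pBy) / d; }
        else { nx2 = -std::sin(ci.ang); ny2 = std::cos(ci.ang); }
        double push = std::min(0.5 * (o - DEEP_O), DEEP_PUSH);
        // never shove a cell *toward* a nearby wall: zero the offending
        // component so the projection cannot defeat the implicit wall
        // springs (the pair still separates along the remaining component)
        double pix = push * nx2, piy = push * ny2;
        double pjx = -push * nx2, pjy = -push * ny2;
        auto wall_clamp = [&](const Cell& c, double& qx, double& qy) {
          if (c.y - 0.5 * c.len - c.r < w.A + 0.5 && qy < 0.0) qy = 0.0;
          if (c.x - 0.5 * c.len - c.r < 0.5 && qx < 0.0) qx = 0.0;
          if (c.x + 0.5 * c.len + c.r > w.width - 0.5 && qx > 0.0) qx = 0.0;
        };
        wall_clamp(ci, pix, piy);
        wall_clamp(cj, pjx, pjy);
        ci.x += pix; ci.y += piy;
        cj.x += pjx; cj.y += pjy;
      }
      if (!ws.deep_pairs.empty()) ws.motion_accum += DEEP_PUSH;
    }

    // growth and division
    ws.motion_accum += 0.5 * P.l_div * P.elongation_rate * dt * 2.0;
    bool changed = false;
    int n0 = (int)cells.size();
    for (int i = 0; i < n0; ++i) {
      Cell& c = cells[i];
      int si = c.strain - 1;
      if (dt == P.dt && si >= 0 && si < nstr)
        c.len *= gfac[si];
      else
        c.len *= std::exp(c.gmult * P.elongation_rate * dt);
      if (c.len >= P.l_div) {
        double ux = std::cos(c.ang), uy = std::sin(c.ang);
        double l2 = 0.5 * c.len;
        Cell d1 = c, d2 = c;
        d1.len = l2; d2.len = l2;
        d1.x = c.x - 0.25 * c.len * ux; d1.y = c.y - 0.25 * c.len * uy;
        d2.x = c.x + 0.25 * c.len * ux; d2.y = c.y + 0.25 * c.len * uy;
        double no = P.division_angle_noise;
        d1.ang = c.ang + no * (2.0 * rng.unif() - 1.0);
        d2.ang = c.ang + no * (2.0 * rng.unif() - 1.0);
        d1.id = next_id++; d2.id = next_id++;
        for (int s = 0; s < 3; ++s) { d1.spr[s].active = false; d2.spr[s].active = false; }
        cells[i] = d1;
        cells.push_back(d2);
        changed = true;
      }
    }

    // open-top removal
    {
      size_t kept = 0;
      for (size_t i = 0; i < cells.size(); ++i) {
        if (cells[i].y > w.height) {
          ++removed;
          removed_area += 2.0 * cells[i].r * cells[i].len +
                          M_PI * cells[i].r * cells[i].r;
        } else {
          cells[kept++] = cells[i];
        }
      }
      if (kept < cells.size()) changed = true;
      cells.resize(kept);
    }
    if (changed) ws.valid = false;

    time += dt;
    if ((n_force_evals & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  if (!retagged && retag_at >= 0.0 && time >= retag_at - 1e-12) {
    for (Cell& c : cells) c.founder = c.id;
    retagged = true;
  }

  List packed = cells_to_list(cells);
  uint64_t snew = rng.s;
  return List::create(
      _["cells"] = packed["cells"], _["springs"] = packed["springs"],
      _["time"] = time, _["removed_count"] = removed,
      _["removed_area"] = removed_area, _["next_id"] = next_id,
      _["rng_hi"] = (int)(uint32_t)(snew >> 32),
      _["rng_lo"] = (int)(uint32_t)(snew & 0xffffffffULL),
      _["retagged"] = retagged,
      _["max_wall_penetration"] = max_pen, _["max_step_displacement"] = max_disp,
      _["pen_info"] = NumericVector::create(pen_info[0], pen_info[1],
                                            pen_info[2], pen_info[3]),
      _["n_force_evals"] = (double)n_force_evals);
}

// ---------------------------------------------------------------------------
// helper for initialization: does candidate overlap any placed cell?

// [[Rcpp::export]]
bool cpp_overlaps_any(NumericVector cand, DataFrame placed, double pad) {
  NumericVector x = placed["x"], y = placed["y"], ang = placed["angle"],
                len = placed["length"], r = placed["radius"];
  Cell A{};
  A.x = cand[0]; A.y = cand[1]; A.ang = cand[2]; A.len = cand[3]; A.r = cand[4];
  double a1x, a1y, b1x, b1y;
  endpoints(A, a1x, a1y, b1x, b1y);
  for (int i = 0; i < x.size(); ++i) {
    Cell B{};
    B.x = x[i]; B.y = y[i]; B.ang = ang[i]; B.len = len[i]; B.r = r[i];
    double a2x, a2y, b2x, b2y, s, t;
    endpoints(B, a2x, a2y, b2x, b2y);
    double d = closest_segments(a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y, s, t);
    if (d < A.r + B.r + pad) return true;
  }
  return false;
}

// minimum pairwise (surface-surface) separation, for init tests
// [[Rcpp::export]]
double cpp_min_separation(List state) {
  std::vector<Cell> cells = cells_from_list(state);
  double best = R_PosInf;
  for (size_t i = 0; i < cells.size(); ++i)
    for (size_t j = i + 1; j < cells.size(); ++j) {
      double a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y, s, t;
      endpoints(cells[i], a1x, a1y, b1x, b1y);
      endpoints(cells[j], a2x, a2y, b2x, b2y);
      double d = closest_segments(a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y, s, t)
                 - cells[i].r - cells[j].r;
      if (d < best) best = d;
    }
  return best;
}
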