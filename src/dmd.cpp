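// Event-driven discontinuous molecular dynamics over the four-bead
// square-well peptide model: exact ballistic propagation between discrete
// events (hard-core collisions, square-well capture/escape/bounce, bond
// walls, directional NH-CO hydrogen bonding, Andersen ghost collisions),
// periodic cubic box, cell lists, binary-heap event queue with per-bead
// epoch staleness counters.
//
// Reduced units: length Angstrom, mass amu, energy = hydrogen-bond well
// depth (epsilon_HB), time tau = sqrt(amu A^2 / epsilon_HB).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
using namespace Rcpp;

enum EvType { EV_CORE = 0, EV_WELL_IN = 1, EV_WELL_OUT = 2, EV_BOND_LO = 3,
              EV_BOND_HI = 4, EV_HB_IN = 5, EV_HB_OUT = 6, EV_CELL = 7,
              EV_GHOST = 8, EV_SAMPLE = 9 };

struct Ev {
  double t;
  int type;
  int i, j;       // bead indices (j = -1 for single-bead / global events)
  int ei, ej;     // epoch stamps at scheduling time
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;       // min-heap on time
    if (a.type != b.type) return a.type > b.type;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {            // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double normal() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int integer(int n) { return (int)(unif() * n) % n; }
};

struct Engine {
  int n;
  std::vector<double> px, py, pz, vx, vy, vz, mass, sigma, tlast;
  std::vector<int> peptide, residue, kind, rcode;   // kind: 0 NH 1 CA 2 CO 3 R
  std::vector<int> nbr_ca, nbr_prev_co, nbr_next_nh;
  std::vector<int> partner;                         // H-bond registry, -1 none
  std::vector<int> epoch, cellof;
  double box;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> blo, bhi;
  std::vector<std::vector<int>> bonds_of;           // bond indices per bead
  std::vector<std::vector<int>> bonded_nbr;         // bonded partners per bead
  // sidechain wells (by residue-code pair)
  std::vector<double> wlam, weps;                   // 20x20 flattened
  int ncode;
  double hb_range, hb_eps;
  double aux_min[4];
  // cells (linked lists: head per cell, next/prev per bead)
  int ncell;
  double cellsize;
  std::vector<int> cellhead, cellnxt, cellprv;
  std::vector<std::vector<int>> cellnbrs;
  // queue and clock
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  double t;
  Rng rng;
  double t_star, ghost_rate;
  // counters
  double n_core = 0, n_capture = 0, n_escape = 0, n_bounce = 0, n_bondwall = 0,
         n_hb_make = 0, n_hb_break = 0, n_hb_reject = 0, n_ghost = 0,
         n_cell = 0;

  Engine(uint64_t seed) : rng(seed), t(0.0) {}

  inline double mind(double d) const { return d - box * std::round(d / box); }

  inline void posat(int i, double tt, double* out) const {
    double dt = tt - tlast[i];
    out[0] = px[i] + vx[i] * dt;
    out[1] = py[i] + vy[i] * dt;
    out[2] = pz[i] + vz[i] * dt;
  }

  inline void advance(int i, double tt) {
    double dt = tt - tlast[i];
    px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
    tlast[i] = tt;
  }

  inline int bond_index(int i, int j) const {
    const std::vector<int>& nb = bonded_nbr[i];
    for (size_t k = 0; k < nb.size(); ++k) {
      if (nb[k] == j) return bonds_of[i][k];
    }
    return -1;
  }

  inline bool excluded(int i, int j) const {
    return peptide[i] == peptide[j] && std::abs(residue[i] - residue[j]) <= 1;
  }

  inline bool hb_candidate(int i, int j) const {
    if (!((kind[i] == 0 && kind[j] == 2) || (kind[i] == 2 && kind[j] == 0)))
      return false;
    if (peptide[i] == peptide[j] && std::abs(residue[i] - residue[j]) < 4)
      return false;
    return true;
  }

  inline void well_of(int i, int j, double& lam, double& eps) const {
    lam = -1.0; eps = 0.0;
    if (kind[i] == 3 && kind[j] == 3 &&
        (peptide[i] != peptide[j] || std::abs(residue[i] - residue[j]) >= 3)) {
      int a = rcode[i], b = rcode[j];
      if (a >= 0 && b >= 0) {
        double e = weps[a * ncode + b];
        if (e != 0.0) { lam = wlam[a * ncode + b]; eps = e; }
      }
    }
  }

  // earliest future event for pair (i, j), predicted from time tq
  bool predict_pair(int i, int j, double tq, Ev& ev) {
    double xi[3];
    posat(i, tq, xi);
    return predict_pair_from(i, xi, j, tq, ev);
  }

  bool predict_pair_from(int i, const double* xi, int j, double tq, Ev& ev) {
    double xj[3];
    posat(j, tq, xj);
    double dx = mind(xj[0] - xi[0]), dy = mind(xj[1] - xi[1]),
           dz = mind(xj[2] - xi[2]);
    double dvx = vx[j] - vx[i], dvy = vy[j] - vy[i], dvz = vz[j] - vz[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double b = dx * dvx + dy * dvy + dz * dvz;
    double v2 = dvx * dvx + dvy * dvy + dvz * dvz;
    if (v2 <= 0.0) return false;

    int bidx = bond_index(i, j);
    if (bidx >= 0) {
      double lo2 = blo[bidx] * blo[bidx], hi2 = bhi[bidx] * bhi[bidx];
      if (b < 0.0 && r2 > lo2) {
        double disc = b * b - v2 * (r2 - lo2);
        if (disc > 0.0) {
          ev = { tq + (r2 - lo2) / (-b + std::sqrt(disc)), EV_BOND_LO, i, j,
                 epoch[i], epoch[j] };
          return true;
        }
      }
      // outward wall (also recovers pairs marginally outside hi)
      double disc = b * b - v2 * (r2 - hi2);
      if (disc < 0.0) disc = 0.0;
      double dt = (-b + std::sqrt(disc)) / v2;
      if (dt < 0.0) dt = 0.0;
      ev = { tq + dt, EV_BOND_HI, i, j, epoch[i], epoch[j] };
      return true;
    }
    if (excluded(i, j)) return false;

    double sg = 0.5 * (sigma[i] + sigma[j]);
    double s2 = sg * sg;
    double lam, eps;
    well_of(i, j, lam, eps);
    bool hb = hb_candidate(i, j);
    bool registered = hb && partner[i] == j;
    double wl = registered ? hb_range : lam;   // active binding boundary
    bool has_well = registered || lam > 0.0;

    if (has_well) {
      double wl2 = wl * wl;
      double c = r2 - wl2;
      bool outside = c > 1e-9 * wl2 || (std::abs(c) <= 1e-9 * wl2 && b > 0.0);
      if (outside) {
        if (b < 0.0) {
          double disc = b * b - v2 * c;
          if (disc > 0.0) {
            ev = { tq + c / (-b + std::sqrt(disc)), EV_WELL_IN, i, j,
                   epoch[i], epoch[j] };
            return true;
          }
        }
        return false;
      }
      // inside the well: hard core, else outward boundary
      if (b < 0.0 && r2 > s2) {
        double disc = b * b - v2 * (r2 - s2);
        if (disc > 0.0) {
          ev = { tq + (r2 - s2) / (-b + std::sqrt(disc)), EV_CORE, i, j,
                 epoch[i], epoch[j] };
          return true;
        }
      }
      double disc = b * b - v2 * c;   // c <= 0 so disc >= b^2
      if (disc < 0.0) disc = 0.0;
      double dt = (-b + std::sqrt(disc)) / v2;
      if (dt < 0.0) dt = 0.0;
      ev = { tq + dt, registered ? EV_HB_OUT : EV_WELL_OUT, i, j,
             epoch[i], epoch[j] };
      return true;
    }

    if (hb && !registered) {
      double rg2 = hb_range * hb_range;
      double c = r2 - rg2;
      bool outside = c > 1e-9 * rg2 || (std::abs(c) <= 1e-9 * rg2 && b > 0.0);
      if (outside) {
        if (b < 0.0) {
          double disc = b * b - v2 * c;
          if (disc > 0.0) {
            ev = { tq + c / (-b + std::sqrt(disc)), EV_HB_IN, i, j,
                   epoch[i], epoch[j] };
            return true;
          }
        }
        return false;
      }
      // inside range but unpaired: hard core only
    }

    if (b < 0.0 && r2 > s2) {
      double disc = b * b - v2 * (r2 - s2);
      if (disc > 0.0) {
        ev = { tq + (r2 - s2) / (-b + std::sqrt(disc)), EV_CORE, i, j,
               epoch[i], epoch[j] };
        return true;
      }
    }
    return false;
  }

  void schedule_pair(int i, int j, double tq) {
    Ev ev;
    if (predict_pair(i, j, tq, ev)) q.push(ev);
  }

  // ---- cells -------------------------------------------------------------
  inline int cell_index(double x, double y, double z) const {
    int cx = (int)std::floor(x / cellsize), cy = (int)std::floor(y / cellsize),
        cz = (int)std::floor(z / cellsize);
    cx = ((cx % ncell) + ncell) % ncell;
    cy = ((cy % ncell) + ncell) % ncell;
    cz = ((cz % ncell) + ncell) % ncell;
    return (cx * ncell + cy) * ncell + cz;
  }

  void build_cells(double range) {
    // cells of about half the interaction range with a +-2 neighbour shell
    // scan substantially less volume than range-sized cells with a +-1
    // shell; fall back to range-sized cells for small boxes
    ncell = (int)std::floor(box / (range / 2.0));
    int shell = 2;
    if (ncell < 5) {
      ncell = std::max(1, (int)std::floor(box / range));
      shell = 1;
    }
    cellsize = box / ncell;
    // guard: shell * cellsize must cover the interaction range
    while (shell * cellsize < range) ++shell;
    int nc = ncell * ncell * ncell;
    cellnbrs.assign(nc, {});
    for (int cx = 0; cx < ncell; ++cx)
      for (int cy = 0; cy < ncell; ++cy)
        for (int cz = 0; cz < ncell; ++cz) {
          int c = (cx * ncell + cy) * ncell + cz;
          std::vector<int> nb;
          for (int ox = -shell; ox <= shell; ++ox)
            for (int oy = -shell; oy <= shell; ++oy)
              for (int oz = -shell; oz <= shell; ++oz) {
                int nx = ((cx + ox) % ncell + ncell) % ncell;
                int ny = ((cy + oy) % ncell + ncell) % ncell;
                int nz = ((cz + oz) % ncell + ncell) % ncell;
                int cc = (nx * ncell + ny) * ncell + nz;
                if (std::find(nb.begin(), nb.end(), cc) == nb.end())
                  nb.push_back(cc);
              }
          std::sort(nb.begin(), nb.end());
          cellnbrs[c] = nb;
        }
    cellof.assign(n, 0);
    cellhead.assign(nc, -1);
    cellnxt.assign(n, -1);
    cellprv.assign(n, -1);
    for (int i = n - 1; i >= 0; --i) {   // reverse so lists run ascending
      int c = cell_index(px[i], py[i], pz[i]);
      cellof[i] = c;
      cellnxt[i] = cellhead[c];
      if (cellhead[c] >= 0) cellprv[cellhead[c]] = i;
      cellprv[i] = -1;
      cellhead[c] = i;
    }
  }

  void move_cell(int i, int newc) {
    int c = cellof[i];
    if (cellprv[i] >= 0) cellnxt[cellprv[i]] = cellnxt[i];
    else cellhead[c] = cellnxt[i];
    if (cellnxt[i] >= 0) cellprv[cellnxt[i]] = cellprv[i];
    cellof[i] = newc;
    cellnxt[i] = cellhead[newc];
    if (cellhead[newc] >= 0) cellprv[cellhead[newc]] = i;
    cellprv[i] = -1;
    cellhead[newc] = i;
  }

  double next_cell_cross(int i, double tq, Ev& out) {
    schedule_cell_event(i, tq, &out);
    return out.type == EV_CELL ? out.t : R_PosInf;
  }

  void schedule_cell_event(int i, double tq, Ev* out = nullptr) {
    // time until the bead leaves its current cell along any axis; the
    // crossing axis and direction are stored in the event (field j) so the
    // cell step at processing time is exact, never inferred from floats
    double xi[3];
    posat(i, tq, xi);
    double vv[3] = { vx[i], vy[i], vz[i] };
    int c = cellof[i];
    int cz = c % ncell, cy = (c / ncell) % ncell, cx = c / (ncell * ncell);
    int cc[3] = { cx, cy, cz };
    double best = R_PosInf;
    int which = -1;
    for (int a = 0; a < 3; ++a) {
      if (vv[a] == 0.0) continue;
      double lo = cc[a] * cellsize, hi = (cc[a] + 1) * cellsize;
      // position may be wrapped arbitrarily; shift near the cell's frame
      double x = xi[a] - box * std::floor((xi[a] - lo) / box);
      if (x - lo > 1.5 * cellsize) x -= box;   // wrapped just past the top
      double dist = vv[a] > 0.0 ? hi - x : x - lo;
      if (dist < 0.0) dist = 0.0;
      // single-cell boxes: a bead at (or within round-off of) the wrap
      // boundary must traverse the full box, not fire zero-time wraps
      if (ncell == 1 && dist < 1e-9) dist += cellsize;
      double dt = dist / std::abs(vv[a]);
      if (dt < best) { best = dt; which = a * 2 + (vv[a] > 0.0 ? 1 : 0); }
    }
    Ev ev { tq + best, EV_CELL, i, which, epoch[i], 0 };
    if (out != nullptr) {
      if (R_finite(best)) *out = ev; else out->type = -1;
    } else if (R_finite(best)) {
      q.push(ev);
    }
  }

  void step_cell(int i, int which) {
    int axis = which / 2, dir = (which % 2) ? 1 : -1;
    int c = cellof[i];
    int cc[3] = { c / (ncell * ncell), (c / ncell) % ncell, c % ncell };
    cc[axis] = ((cc[axis] + dir) % ncell + ncell) % ncell;
    int newc = (cc[0] * ncell + cc[1]) * ncell + cc[2];
    if (newc != cellof[i]) move_cell(i, newc);
  }

  // Schedule only the bead's earliest candidate event (pair or cell cross).
  // Every processed or stale-popped event reschedules its still-valid
  // members, so later candidates are rediscovered when they can matter.
  void reschedule(int i, double tq, int skip) {
    Ev best; best.t = R_PosInf; best.type = -1;
    Ev ev;
    double xi[3];
    posat(i, tq, xi);
    for (int j : bonded_nbr[i]) {
      if (j == skip) continue;
      if (predict_pair_from(i, xi, j, tq, ev) && ev.t < best.t) best = ev;
    }
    for (int c : cellnbrs[cellof[i]]) {
      for (int j = cellhead[c]; j >= 0; j = cellnxt[j]) {
        if (j == i || j == skip) continue;
        if (bond_index(i, j) >= 0) continue;   // handled above
        if (predict_pair_from(i, xi, j, tq, ev) && ev.t < best.t) best = ev;
      }
    }
    double tcell = next_cell_cross(i, tq, ev);
    if (R_finite(tcell) && ev.t < best.t) best = ev;
    if (best.type >= 0) {
      if (best.type < EV_CELL && best.i > best.j) {   // canonical pair order
        std::swap(best.i, best.j);
        std::swap(best.ei, best.ej);
      }
      q.push(best);
    }
  }

  bool aux_ok(int d, int a, double tt) {
    // d = NH donor bead, a = CO acceptor bead
    int nb[4] = { nbr_ca[d], nbr_prev_co[d], nbr_ca[a], nbr_next_nh[a] };
    int other[4] = { a, a, d, d };
    for (int k = 0; k < 4; ++k) {
      if (nb[k] < 0) continue;
      double p1[3], p2[3];
      posat(nb[k], tt, p1); posat(other[k], tt, p2);
      double dx = mind(p2[0] - p1[0]), dy = mind(p2[1] - p1[1]),
             dz = mind(p2[2] - p1[2]);
      if (dx * dx + dy * dy + dz * dz < aux_min[k] * aux_min[k]) return false;
    }
    return true;
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return ke;
  }

  double potential(double tt) {
    double pe = 0.0;
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 0 && partner[i] >= 0) pe -= hb_eps;
      if (kind[i] != 3) continue;
      double xi[3];
      posat(i, tt, xi);
      for (int j = i + 1; j < n; ++j) {
        if (kind[j] != 3) continue;
        double lam, eps;
        well_of(i, j, lam, eps);
        if (eps == 0.0) continue;
        double xj[3];
        posat(j, tt, xj);
        double dx = mind(xj[0] - xi[0]), dy = mind(xj[1] - xi[1]),
               dz = mind(xj[2] - xi[2]);
        if (dx * dx + dy * dy + dz * dz < lam * lam) pe += eps;
      }
    }
    return pe;
  }

  void validate_initial() {
    for (size_t k = 0; k < bi.size(); ++k) {
      double dx = mind(px[bj[k]] - px[bi[k]]), dy = mind(py[bj[k]] - py[bi[k]]),
             dz = mind(pz[bj[k]] - pz[bi[k]]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < blo[k] * (1 - 1e-7) || r > bhi[k] * (1 + 1e-7))
        stop("initial bond wall violation: beads %d-%d at %f not in [%f, %f]",
             bi[k] + 1, bj[k] + 1, r, blo[k], bhi[k]);
    }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (bond_index(i, j) >= 0 || excluded(i, j)) continue;
        double dx = mind(px[j] - px[i]), dy = mind(py[j] - py[i]),
               dz = mind(pz[j] - pz[i]);
        double r2 = dx * dx + dy * dy + dz * dz;
        double sg = 0.5 * (sigma[i] + sigma[j]);
        if (r2 < sg * sg * (1 - 1e-7))
          stop("initial core overlap: beads %d-%d at %f < sigma %f",
               i + 1, j + 1, std::sqrt(r2), sg);
      }
    for (int i = 0; i < n; ++i) {
      if (partner[i] >= 0 && partner[partner[i]] != i)
        stop("hydrogen-bond registry is not a matching at bead %d", i + 1);
    }
  }
};

// [[Rcpp::export]]
List run_dmd_cpp(NumericMatrix pos, NumericMatrix vel,
                 NumericVector mass, NumericVector sigma,
                 IntegerVector peptide, IntegerVector residue,
                 IntegerVector kind, IntegerVector rcode,
                 IntegerMatrix bonds, NumericVector bond_lo, NumericVector bond_hi,
                 NumericMatrix well_lambda, NumericMatrix well_eps,
                 double hb_range, double hb_eps, NumericVector aux_min,
                 IntegerVector nbr_ca, IntegerVector nbr_prev_co,
                 IntegerVector nbr_next_nh,
                 IntegerVector hb_partner0,
                 double box, double t_star, double ghost_rate,
                 double max_time, double max_events, double sample_every,
                 double cell_range, int seed, bool validate, bool use_cells) {
  int n = pos.nrow();
  Engine e((uint64_t)seed * 2654435761u + 1u);
  e.n = n; e.box = box; e.t_star = t_star; e.ghost_rate = ghost_rate;
  e.px.resize(n); e.py.resize(n); e.pz.resize(n);
  e.vx.resize(n); e.vy.resize(n); e.vz.resize(n);
  for (int i = 0; i < n; ++i) {
    e.px[i] = pos(i, 0); e.py[i] = pos(i, 1); e.pz[i] = pos(i, 2);
    e.vx[i] = vel(i, 0); e.vy[i] = vel(i, 1); e.vz[i] = vel(i, 2);
  }
  e.mass = as<std::vector<double>>(mass);
  e.sigma = as<std::vector<double>>(sigma);
  e.tlast.assign(n, 0.0);
  e.peptide = as<std::vector<int>>(peptide);
  e.residue = as<std::vector<int>>(residue);
  e.kind = as<std::vector<int>>(kind);
  e.rcode = as<std::vector<int>>(rcode);
  e.nbr_ca = as<std::vector<int>>(nbr_ca);
  e.nbr_prev_co = as<std::vector<int>>(nbr_prev_co);
  e.nbr_next_nh = as<std::vector<int>>(nbr_next_nh);
  e.partner = as<std::vector<int>>(hb_partner0);
  e.epoch.assign(n, 0);
  int nb = bonds.nrow();
  e.bi.resize(nb); e.bj.resize(nb);
  e.blo = as<std::vector<double>>(bond_lo);
  e.bhi = as<std::vector<double>>(bond_hi);
  e.bonds_of.assign(n, {});
  e.bonded_nbr.assign(n, {});
  for (int k = 0; k < nb; ++k) {
    int a = bonds(k, 0), b = bonds(k, 1);
    e.bi[k] = a; e.bj[k] = b;
    e.bonds_of[a].push_back(k);
    e.bonds_of[b].push_back(k);
    e.bonded_nbr[a].push_back(b);
    e.bonded_nbr[b].push_back(a);
  }
  e.ncode = well_lambda.nrow();
  e.wlam.assign(e.ncode * e.ncode, 0.0);
  e.weps.assign(e.ncode * e.ncode, 0.0);
  for (int a = 0; a < e.ncode; ++a)
    for (int b = 0; b < e.ncode; ++b) {
      e.wlam[a * e.ncode + b] = well_lambda(a, b);
      e.weps[a * e.ncode + b] = well_eps(a, b);
    }
  e.hb_range = hb_range; e.hb_eps = hb_eps;
  for (int k = 0; k < 4; ++k) e.aux_min[k] = aux_min[k];
  if (box <= 0) stop("a positive cubic box length is required");
  if (2 * cell_range > box)
    stop("box too small for the interaction range (minimum image)");
  if (validate) e.validate_initial();
  e.build_cells(use_cells ? cell_range : box);   // single cell when disabled

  // initial schedule: each bead's earliest event
  for (int i = 0; i < n; ++i) e.reschedule(i, 0.0, -1);
  double ghost_gap = (ghost_rate > 0) ?
    -std::log(e.rng.unif()) / (ghost_rate * n) : R_PosInf;
  if (R_finite(ghost_gap)) e.q.push({ ghost_gap, EV_GHOST, -1, -1, 0, 0 });
  if (sample_every > 0) e.q.push({ 0.0, EV_SAMPLE, -1, -1, 0, 0 });

  std::vector<NumericMatrix> frames;
  std::vector<double> frame_times;
  std::vector<IntegerVector> frame_partners;
  std::vector<double> s_t, s_ke, s_pe, s_tstar, s_nhb, s_nev;
  double processed = 0;
  auto take_sample = [&](double tt) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) {
      double xi[3];
      e.posat(i, tt, xi);
      for (int a = 0; a < 3; ++a)
        fr(i, a) = xi[a] - box * std::floor(xi[a] / box);
    }
    frames.push_back(fr);
    frame_times.push_back(tt);
    IntegerVector pv(n);
    for (int i = 0; i < n; ++i) pv[i] = e.partner[i] + 1;   // 1-based, 0 = none
    frame_partners.push_back(pv);
    double ke = e.kinetic(), pe = e.potential(tt);
    int nhb = 0;
    for (int i = 0; i < n; ++i) if (e.kind[i] == 0 && e.partner[i] >= 0) ++nhb;
    s_t.push_back(tt); s_ke.push_back(ke); s_pe.push_back(pe);
    s_tstar.push_back(2.0 * ke / (3.0 * n));
    s_nhb.push_back(nhb); s_nev.push_back(processed);
  };

  double t_end = max_time;
  bool stopped = false;
  double pops = 0;
  const char* dbg = std::getenv("CATCHDMD_DEBUG_QUEUE");
  while (!e.q.empty() && !stopped) {
    Ev ev = e.q.top(); e.q.pop();
    if (((++pops) - std::floor(pops / 100000.0) * 100000.0) == 0.0) {
      Rcpp::checkUserInterrupt();
      if (dbg) Rcout << "pops " << pops << " processed " << processed
                     << " queue " << e.q.size() << " t " << e.t << "\n";
    }
    if (ev.t > max_time) { e.t = max_time; break; }
    if (ev.type == EV_SAMPLE) {
      take_sample(ev.t);
      e.q.push({ ev.t + sample_every, EV_SAMPLE, -1, -1, 0, 0 });
      continue;
    }
    if (ev.type == EV_GHOST) {
      e.t = ev.t;
      int b = e.rng.integer(n);
      e.advance(b, ev.t);
      for (int a = 0; a < 3; ++a) {
        double nv = e.rng.normal() * std::sqrt(t_star / e.mass[b]);
        if (a == 0) e.vx[b] = nv; else if (a == 1) e.vy[b] = nv; else e.vz[b] = nv;
      }
      e.epoch[b]++;
      e.reschedule(b, ev.t, -1);
      e.n_ghost++; processed++;
      double gap = -std::log(e.rng.unif()) / (ghost_rate * n);
      e.q.push({ ev.t + gap, EV_GHOST, -1, -1, 0, 0 });
      if (processed >= max_events) { e.t = ev.t; stopped = true; }
      continue;
    }
    if (ev.type == EV_CELL) {
      if (ev.ei != e.epoch[ev.i]) continue;
      e.t = ev.t;
      int i = ev.i;
      e.advance(i, ev.t);
      e.px[i] -= box * std::floor(e.px[i] / box);
      e.py[i] -= box * std::floor(e.py[i] / box);
      e.pz[i] -= box * std::floor(e.pz[i] / box);
      e.step_cell(i, ev.j);
      e.epoch[i]++;
      e.reschedule(i, ev.t, -1);
      e.n_cell++;
      continue;
    }
    // two-body event; on a stale pop, members that are still valid lost
    // their only scheduled event, so give them a fresh one
    if (ev.ei != e.epoch[ev.i] || ev.ej != e.epoch[ev.j]) {
      if (ev.ei == e.epoch[ev.i]) e.reschedule(ev.i, e.t, -1);
      if (ev.ej == e.epoch[ev.j]) e.reschedule(ev.j, e.t, -1);
      continue;
    }
    e.t = ev.t;
    int i = ev.i, j = ev.j;
    e.advance(i, ev.t); e.advance(j, ev.t);
    double dx = e.mind(e.px[j] - e.px[i]), dy = e.mind(e.py[j] - e.py[i]),
           dz = e.mind(e.pz[j] - e.pz[i]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double rx = dx / r, ry = dy / r, rz = dz / r;
    double vr = (e.vx[j] - e.vx[i]) * rx + (e.vy[j] - e.vy[i]) * ry +
                (e.vz[j] - e.vz[i]) * rz;
    double mu = e.mass[i] * e.mass[j] / (e.mass[i] + e.mass[j]);
    double newvr = vr;
    bool changed = true;
    switch (ev.type) {
      case EV_CORE: newvr = -vr; e.n_core++; break;
      case EV_BOND_LO: case EV_BOND_HI: newvr = -vr; e.n_bondwall++; break;
      case EV_WELL_IN: {
        // for a registered NH-CO pair found marginally outside its range
        // (numerical edge) well_of gives eps = 0: re-entry is then free
        double lam, eps;
        e.well_of(i, j, lam, eps);
        double qv = vr * vr - 2.0 * eps / mu;
        if (qv <= 0.0) { newvr = -vr; e.n_bounce++; }
        else { newvr = -std::sqrt(qv); e.n_capture++; }
        break;
      }
      case EV_WELL_OUT: {
        double lam, eps;
        e.well_of(i, j, lam, eps);
        double qv = vr * vr + 2.0 * eps / mu;
        if (qv <= 0.0) { newvr = -vr; e.n_bounce++; }
        else { newvr = std::sqrt(qv); e.n_escape++; }
        break;
      }
      case EV_HB_IN: {
        int d = e.kind[i] == 0 ? i : j;
        int a = d == i ? j : i;
        if (e.partner[d] < 0 && e.partner[a] < 0 && e.aux_ok(d, a, ev.t)) {
          double qv = vr * vr + 2.0 * e.hb_eps / mu;
          newvr = -std::sqrt(qv);
          e.partner[d] = a; e.partner[a] = d;
          e.n_hb_make++;
        } else {
          changed = false;   // pass through the association range
          e.n_hb_reject++;
        }
        break;
      }
      case EV_HB_OUT: {
        double qv = vr * vr - 2.0 * e.hb_eps / mu;
        if (qv <= 0.0) { newvr = -vr; e.n_bounce++; }
        else {
          newvr = std::sqrt(qv);
          e.partner[i] = -1; e.partner[j] = -1;
          e.n_hb_break++;
        }
        break;
      }
      default: changed = false;
    }
    if (changed) {
      double P = mu * (newvr - vr);
      e.vx[i] -= P / e.mass[i] * rx; e.vy[i] -= P / e.mass[i] * ry;
      e.vz[i] -= P / e.mass[i] * rz;
      e.vx[j] += P / e.mass[j] * rx; e.vy[j] += P / e.mass[j] * ry;
      e.vz[j] += P / e.mass[j] * rz;
    }
    e.epoch[i]++; e.epoch[j]++;
    e.reschedule(i, ev.t, -1);
    e.reschedule(j, ev.t, i);
    processed++;
    if (processed >= max_events) stopped = true;
  }
  if (!stopped && e.q.empty()) t_end = e.t;
  else t_end = e.t;

  // final sync
  for (int i = 0; i < n; ++i) {
    e.advance(i, t_end);
    e.px[i] -= box * std::floor(e.px[i] / box);
    e.py[i] -= box * std::floor(e.py[i] / box);
    e.pz[i] -= box * std::floor(e.pz[i] / box);
  }
  take_sample(t_end);

  NumericMatrix fpos(n, 3), fvel(n, 3);
  IntegerVector fpartner(n);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = e.px[i]; fpos(i, 1) = e.py[i]; fpos(i, 2) = e.pz[i];
    fvel(i, 0) = e.vx[i]; fvel(i, 1) = e.vy[i]; fvel(i, 2) = e.vz[i];
    fpartner[i] = e.partner[i] + 1;
  }
  NumericMatrix samples(s_t.size(), 6);
  colnames(samples) = CharacterVector::create("time", "kinetic", "potential",
                                              "t_star", "n_hbonds", "events");
  for (size_t k = 0; k < s_t.size(); ++k) {
    samples(k, 0) = s_t[k]; samples(k, 1) = s_ke[k]; samples(k, 2) = s_pe[k];
    samples(k, 3) = s_tstar[k]; samples(k, 4) = s_nhb[k]; samples(k, 5) = s_nev[k];
  }
  return List::create(
    _["frames"] = wrap(frames),
    _["frame_times"] = wrap(frame_times),
    _["frame_partners"] = wrap(frame_partners),
    _["samples"] = samples,
    _["counts"] = NumericVector::create(
      _["core"] = e.n_core, _["capture"] = e.n_capture,
      _["escape"] = e.n_escape, _["bounce"] = e.n_bounce,
      _["bond_wall"] = e.n_bondwall, _["hbond_make"] = e.n_hb_make,
      _["hbond_break"] = e.n_hb_break, _["hbond_reject"] = e.n_hb_reject,
      _["ghost"] = e.n_ghost, _["cell_cross"] = e.n_cell),
    _["events"] = processed,
    _["final_pos"] = fpos, _["final_vel"] = fvel,
    _["final_partner"] = fpartner, _["final_time"] = t_end);
}

// Pure-geometry single-pair event prediction, exposed for oracle tests.
// Returns the earliest discontinuity crossing for a pair with relative
// position dx and relative velocity dv (no periodic box).
// [[Rcpp::export]]
List predict_pair_event_cpp(NumericVector dxv, NumericVector dvv,
                            double sg, double lam, double eps,
                            bool bonded, double lo, double hi,
                            int hb_mode, double range) {
  double dx = dxv[0], dy = dxv[1], dz = dxv[2];
  double dvx = dvv[0], dvy = dvv[1], dvz = dvv[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double b = dx * dvx + dy * dvy + dz * dvz;
  double v2 = dvx * dvx + dvy * dvy + dvz * dvz;
  auto none = []() {
    return List::create(_["time"] = R_PosInf, _["kind"] = "none");
  };
  if (v2 <= 0.0) return none();
  if (r2 < (bonded ? lo * lo : sg * sg) * (1 - 1e-9))
    stop("overlapping pair: distance %f inside inner boundary", std::sqrt(r2));
  if (bonded) {
    if (b < 0.0 && r2 > lo * lo) {
      double disc = b * b - v2 * (r2 - lo * lo);
      if (disc > 0.0)
        return List::create(_["time"] = (r2 - lo * lo) / (-b + std::sqrt(disc)),
                            _["kind"] = "bond_wall_inner");
    }
    double disc = b * b - v2 * (r2 - hi * hi);
    if (disc < 0.0) disc = 0.0;
    return List::create(_["time"] = std::max(0.0, (-b + std::sqrt(disc)) / v2),
                        _["kind"] = "bond_wall_outer");
  }
  bool registered = hb_mode == 2;
  double wl = registered ? range : lam;
  bool has_well = registered || (lam > 0 && eps != 0.0);
  if (has_well) {
    double wl2 = wl * wl;
    double c = r2 - wl2;
    bool outside = c > 1e-9 * wl2 || (std::abs(c) <= 1e-9 * wl2 && b > 0.0);
    if (outside) {
      if (b < 0.0) {
        double disc = b * b - v2 * c;
        if (disc > 0.0)
          return List::create(_["time"] = c / (-b + std::sqrt(disc)),
                              _["kind"] = "capture");
      }
      return none();
    }
    if (b < 0.0 && r2 > sg * sg) {
      double disc = b * b - v2 * (r2 - sg * sg);
      if (disc > 0.0)
        return List::create(_["time"] = (r2 - sg * sg) / (-b + std::sqrt(disc)),
                            _["kind"] = "core");
    }
    double disc = b * b - v2 * c;
    if (disc < 0.0) disc = 0.0;
    return List::create(_["time"] = std::max(0.0, (-b + std::sqrt(disc)) / v2),
                        _["kind"] = registered ? "hbond_boundary" : "well_boundary");
  }
  if (hb_mode == 1) {
    double rg2 = range * range;
    double c = r2 - rg2;
    bool outside = c > 1e-9 * rg2 || (std::abs(c) <= 1e-9 * rg2 && b > 0.0);
    if (outside) {
      if (b < 0.0) {
        double disc = b * b - v2 * c;
        if (disc > 0.0)
          return List::create(_["time"] = c / (-b + std::sqrt(disc)),
                              _["kind"] = "hbond_attempt");
      }
      return none();
    }
  }
  if (b < 0.0 && r2 > sg * sg) {
    double disc = b * b - v2 * (r2 - sg * sg);
    if (disc > 0.0)
      return List::create(_["time"] = (r2 - sg * sg) / (-b + std::sqrt(disc)),
                          _["kind"] = "core");
  }
  return none();
}

// Two-body velocity update, exposed for unit tests.  kind_code:
// 0 bounce (core/bond wall), 1 enter well of depth eps, 2 attempt escape
// across well of depth eps.  Returns new velocities and what happened.
// [[Rcpp::export]]
List resolve_two_body_cpp(NumericVector xi, NumericVector xj,
                          NumericVector viv, NumericVector vjv,
                          double mi, double mj, int kind_code, double eps) {
  double dx = xj[0] - xi[0], dy = xj[1] - xi[1], dz = xj[2] - xi[2];
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  double rx = dx / r, ry = dy / r, rz = dz / r;
  double vr = (vjv[0] - viv[0]) * rx + (vjv[1] - viv[1]) * ry +
              (vjv[2] - viv[2]) * rz;
  double mu = mi * mj / (mi + mj);
  double newvr = -vr;
  std::string what = "bounce";
  if (kind_code == 1) {
    double qv = vr * vr - 2.0 * eps / mu;
    if (qv > 0.0) { newvr = -std::sqrt(qv); what = "capture"; }
  } else if (kind_code == 2) {
    double qv = vr * vr + 2.0 * eps / mu;
    if (qv > 0.0) { newvr = std::sqrt(qv); what = "escape"; }
  }
  double P = mu * (newvr - vr);
  NumericVector vi2 = clone(viv), vj2 = clone(vjv);
  vi2[0] -= P / mi * rx; vi2[1] -= P / mi * ry; vi2[2] -= P / mi * rz;
  vj2[0] += P / mj * rx; vj2[1] += P / mj * ry; vj2[2] += P / mj * rz;
  return List::create(_["vi"] = vi2, _["vj"] = vj2, _["what"] = what);
}
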