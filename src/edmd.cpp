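// Event-driven molecular dynamics of polydisperse hard spheres in a cubic
// periodic box: cell lists, a binary event heap with lazy invalidation,
// Lubachevsky-Stillinger diameter growth, Andersen (ghost-collision)
// thermostatting, and structure-analysis kernels (g(r) histograms, direct
// lattice S(k), pair-gap audit, random non-overlapping placement).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <random>
#include <limits>
#include <complex>

using namespace Rcpp;

static const double INFTY = std::numeric_limits<double>::infinity();

// Deterministic RNG (mt19937_64 + Box-Muller): identical streams on every
// platform for a given seed, unlike std::normal_distribution.
struct Rng {
  std::mt19937_64 eng;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : eng(seed), have_spare(false), spare(0.0) {}
  double unif() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

enum EvKind { EV_PAIR = 0, EV_CROSS = 1, EV_THERMO = 2, EV_SAMPLE = 3,
              EV_STOPGROW = 4, EV_END = 5 };

struct Event {
  double t;
  int kind;
  int i, j;          // j: partner (EV_PAIR) or axis*2+dir (EV_CROSS)
  uint64_t ci, cj;   // event counters at scheduling time
};
struct EventLater {
  bool operator()(const Event& a, const Event& b) const { return a.t > b.t; }
};

struct Engine {
  int n;
  double L;
  std::vector<double> px, py, pz, vx, vy, vz, tlast;
  std::vector<double> dnom, mass;      // nominal (final) diameters
  std::vector<uint64_t> cnt;
  // growth: diameters are dnom * lam(t), lam(t) = lam0 + G*t until lam=1
  double lam0, G, t_stopgrow;
  double e_rest, nu, Tset;
  double tnow;
  // cells
  int nc;
  double cw;
  bool allpairs;
  std::vector<int> cellx, celly, cellz;
  std::vector<int> scanr;                 // per-particle neighbour radius
  std::vector<std::vector<int> > cellof;  // cell id -> particle list
  std::priority_queue<Event, std::vector<Event>, EventLater> heap;
  Rng rng;
  // accounting
  long long ncoll, nevents;
  long long npop_pair, npop_cross, npop_stale, npush;
  mutable long long ncand;
  double virial_sum;     // sum of J * sigma_contact over collisions
  double virial_t0;      // window start for the virial accumulation
  bool record;
  std::vector<double> ev_t;
  std::vector<int> ev_i, ev_j;

  Engine(uint64_t seed) : rng(seed), ncoll(0), nevents(0),
                          npop_pair(0), npop_cross(0), npop_stale(0), npush(0), ncand(0),
                          virial_sum(0.0), virial_t0(0.0), record(false) {}

  double lam(double t) const {
    if (G <= 0.0) return lam0;
    double l = lam0 + G * t;
    return l > 1.0 ? 1.0 : l;
  }
  double growth_now(double t) const {
    return (G > 0.0 && lam0 + G * t < 1.0) ? G : 0.0;
  }

  int cellid(int cx, int cy, int cz) const { return (cz * nc + cy) * nc + cx; }

  void build_cells() {
    cellof.assign(allpairs ? 1 : nc * nc * nc, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      if (allpairs) {
        cellx[i] = celly[i] = cellz[i] = 0;
        cellof[0].push_back(i);
      } else {
        int cx = (int)std::floor(px[i] / cw); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
        int cy = (int)std::floor(py[i] / cw); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
        int cz = (int)std::floor(pz[i] / cw); if (cz >= nc) cz = nc - 1; if (cz < 0) cz = 0;
        cellx[i] = cx; celly[i] = cy; cellz[i] = cz;
        cellof[cellid(cx, cy, cz)].push_back(i);
      }
    }
  }

  void cell_remove(int i) {
    std::vector<int>& v = cellof[allpairs ? 0 : cellid(cellx[i], celly[i], cellz[i])];
    for (size_t k = 0; k < v.size(); ++k) {
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    }
  }

  inline double pos_at(int i, double t, int axis) const {
    double p;
    if (axis == 0)      p = px[i] + vx[i] * (t - tlast[i]);
    else if (axis == 1) p = py[i] + vy[i] * (t - tlast[i]);
    else                p = pz[i] + vz[i] * (t - tlast[i]);
    return p;
  }

  void advance(int i, double t) {
    double dt = t - tlast[i];
    px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
    px[i] -= L * std::floor(px[i] / L);
    py[i] -= L * std::floor(py[i] / L);
    pz[i] -= L * std::floor(pz[i] / L);
    tlast[i] = t;
  }
  void sync_all(double t) { for (int i = 0; i < n; ++i) advance(i, t); }

  inline double mindiff(double d) const {
    d -= L * std::round(d / L);
    return d;
  }

  // earliest contact time offset from `now` for pair (i, j) through the
  // periodic image displaced by (sx, sy, sz), INFTY if none.  The image is
  // chosen by the caller from the cell-neighbour relationship: with few
  // cells the minimum image at prediction time is not necessarily the
  // image through which the pair actually meets.
  // extrapolated position folded to be consistent with the particle's cell
  // bookkeeping (fp jitter at boundaries is clamped onto the boundary); in
  // all-pairs mode a plain box wrap suffices since every image is scanned
  inline double wpos_at(int i, double t, int axis) const {
    double p = pos_at(i, t, axis);
    if (allpairs) {
      p -= L * std::floor(p / L);
      return p;
    }
    int cell = (axis == 0) ? cellx[i] : (axis == 1 ? celly[i] : cellz[i]);
    double xr = p - cell * cw;
    xr -= L * std::floor(xr / L);
    if (xr > L - 0.5 * cw) xr = 0.0;
    else if (xr > cw) xr = cw;
    return cell * cw + xr;
  }

  double pair_time(int i, int j, double now,
                   double sx, double sy, double sz) const {
    return pair_time_from(wpos_at(i, now, 0), wpos_at(i, now, 1),
                          wpos_at(i, now, 2), vx[i], vy[i], vz[i],
                          dnom[i], j, now, sx, sy, sz);
  }

  double pair_time_from(double xi, double yi, double zi,
                        double vxi, double vyi, double vzi, double di,
                        int j, double now,
                        double sx, double sy, double sz) const {
    ncand++;
    double rx = xi - wpos_at(j, now, 0) + sx;
    double ry = yi - wpos_at(j, now, 1) + sy;
    double rz = zi - wpos_at(j, now, 2) + sz;
    double dvx = vxi - vx[j], dvy = vyi - vy[j], dvz = vzi - vz[j];
    double signom = 0.5 * (di + dnom[j]);
    double sig = signom * lam(now);
    double a = signom * growth_now(now);
    double A = dvx * dvx + dvy * dvy + dvz * dvz - a * a;
    double B = rx * dvx + ry * dvy + rz * dvz - sig * a;
    double C = rx * rx + ry * ry + rz * rz - sig * sig;
    if (C <= 0.0) {
      if (C < -1e-6 * sig * sig)
        stop("corrupted state: overlapping pair (j=%d) gap^2 %g at t %g",
             j, C, now);
      return (B < 0.0) ? 0.0 : INFTY;
    }
    if (B >= 0.0 && A >= 0.0) return INFTY;
    double disc = B * B - A * C;
    if (disc < 0.0) return INFTY;
    double sq = std::sqrt(disc);
    double tau;
    if (A == 0.0) {
      tau = (B < 0.0) ? -C / (2.0 * B) : INFTY;
    } else if (B < 0.0) {
      tau = C / (-B + sq);           // stable form of (-B - sq)/A
    } else {                          // A < 0, growth overtakes recession
      tau = (-B - sq) / A;
    }
    return (tau >= 0.0) ? tau : INFTY;
  }

  // next cell-boundary crossing for particle i from time `now`
  void predict_cross(int i, double now, double& dt_min, int& code) {
    dt_min = INFTY; code = -1;
    if (allpairs) return;
    double pos[3] = { pos_at(i, now, 0), pos_at(i, now, 1), pos_at(i, now, 2) };
    double vel[3] = { vx[i], vy[i], vz[i] };
    int cell[3] = { cellx[i], celly[i], cellz[i] };
    for (int ax = 0; ax < 3; ++ax) {
      if (vel[ax] == 0.0) continue;
      // offset within the cell, wrapped periodically; genuine values lie in
      // [0, cw], seam/fp noise is folded onto the nearest boundary
      double xr = pos[ax] - cell[ax] * cw;
      xr -= L * std::floor(xr / L);
      if (xr > L - 0.5 * cw) xr = 0.0;
      else if (xr > cw) xr = cw;
      double dt;
      if (vel[ax] > 0.0) dt = (cw - xr) / vel[ax];
      else dt = xr / (-vel[ax]);
      if (dt < 0.0) dt = 0.0;
      if (dt < dt_min) { dt_min = dt; code = ax * 2 + (vel[ax] > 0.0 ? 1 : 0); }
    }
  }

  void predict_for(int i, double now) {
    double dt_cross; int code;
    predict_cross(i, now, dt_cross, code);
    if (code >= 0) {
      Event e; e.t = now + dt_cross; e.kind = EV_CROSS; e.i = i; e.j = code;
      e.ci = cnt[i]; e.cj = 0;
      heap.push(e);
    }
    double horizon = (code >= 0) ? dt_cross : INFTY;
    // scan neighbourhood
    if (allpairs) {
      // tiny box: every periodic image may matter
      double xi = wpos_at(i, now, 0), yi = wpos_at(i, now, 1),
             zi = wpos_at(i, now, 2);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        for (int iz = -1; iz <= 1; ++iz)
          for (int iy = -1; iy <= 1; ++iy)
            for (int ix = -1; ix <= 1; ++ix) {
              double tau = pair_time_from(xi, yi, zi, vx[i], vy[i], vz[i],
                                          dnom[i], j, now,
                                          ix * L, iy * L, iz * L);
              if (tau <= horizon) {
                Event e; e.t = now + tau; e.kind = EV_PAIR; e.i = i; e.j = j;
                e.ci = cnt[i]; e.cj = cnt[j];
                heap.push(e);
              }
            }
      }
    } else {
      int R = scanr[i];
      double xi = wpos_at(i, now, 0), yi = wpos_at(i, now, 1),
             zi = wpos_at(i, now, 2);
      for (int dz = -R; dz <= R; ++dz)
        for (int dy = -R; dy <= R; ++dy)
          for (int dx = -R; dx <= R; ++dx) {
            int rawx = cellx[i] + dx, rawy = celly[i] + dy, rawz = cellz[i] + dz;
            // image shift implied by the wrap of this neighbour cell
            double sx = (rawx < 0) ? L : (rawx >= nc ? -L : 0.0);
            double sy = (rawy < 0) ? L : (rawy >= nc ? -L : 0.0);
            double sz = (rawz < 0) ? L : (rawz >= nc ? -L : 0.0);
            int cx = (rawx + nc) % nc, cy = (rawy + nc) % nc, cz = (rawz + nc) % nc;
            const std::vector<int>& lst = cellof[cellid(cx, cy, cz)];
            for (size_t k = 0; k < lst.size(); ++k) {
              int j = lst[k];
              if (j == i) continue;
              double tau = pair_time_from(xi, yi, zi, vx[i], vy[i], vz[i],
                                          dnom[i], j, now, sx, sy, sz);
              if (tau <= horizon) {
                Event e; e.t = now + tau; e.kind = EV_PAIR; e.i = i; e.j = j;
                e.ci = cnt[i]; e.cj = cnt[j];
                heap.push(e);
              }
            }
          }
    }
  }

  void repredict_all() {
    for (int i = 0; i < n; ++i) cnt[i]++;
    for (int i = 0; i < n; ++i) predict_for(i, tnow);
  }

  void resolve_pair(int i, int j) {
    advance(i, tnow); advance(j, tnow);
    double rx = mindiff(px[i] - px[j]);
    double ry = mindiff(py[i] - py[j]);
    double rz = mindiff(pz[i] - pz[j]);
    double r = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (r <= 0.0) stop("coincident particles at collision");
    double nx = rx / r, ny = ry / r, nz = rz / r;
    double signom = 0.5 * (dnom[i] + dnom[j]);
    double a = signom * growth_now(tnow);
    double vn = (vx[i] - vx[j]) * nx + (vy[i] - vy[j]) * ny + (vz[i] - vz[j]) * nz;
    if (vn - a >= 0.0) {
      // receding already (stale geometry); re-predict without impulse
      cnt[i]++; cnt[j]++;
      predict_for(i, tnow); predict_for(j, tnow);
      return;
    }
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double dvn = (1.0 + e_rest) * (a - vn);   // change of normal rel. velocity
    double Ji = mu * dvn;
    vx[i] += Ji / mass[i] * nx; vy[i] += Ji / mass[i] * ny; vz[i] += Ji / mass[i] * nz;
    vx[j] -= Ji / mass[j] * nx; vy[j] -= Ji / mass[j] * ny; vz[j] -= Ji / mass[j] * nz;
    ncoll++;
    virial_sum += Ji * r;
    if (record) { ev_t.push_back(tnow); ev_i.push_back(i); ev_j.push_back(j); }
    cnt[i]++; cnt[j]++;
    predict_for(i, tnow); predict_for(j, tnow);
  }

  void prune_heap() {
    std::vector<Event> keep;
    keep.reserve(heap.size() / 4 + 16);
    while (!heap.empty()) {
      const Event& e = heap.top();
      bool ok = true;
      if (e.kind == EV_PAIR) ok = (cnt[e.i] == e.ci && cnt[e.j] == e.cj);
      else if (e.kind == EV_CROSS) ok = (cnt[e.i] == e.ci);
      if (ok) keep.push_back(e);
      heap.pop();
    }
    for (size_t k = 0; k < keep.size(); ++k) heap.push(keep[k]);
  }
};

// [[Rcpp::export]]
List cpp_edmd(NumericMatrix pos, NumericMatrix vel, NumericVector dnom,
              NumericVector mass, double L, double e_rest, double nu,
              double Tset, double growth_rate, double lam0,
              double max_collisions, double t_end, double sample_interval,
              int max_samples, double jam_limit, int seed,
              bool record_events) {
  int n = pos.nrow();
  Engine eng((uint64_t)seed * 2654435761u + 1u);
  eng.n = n; eng.L = L;
  eng.e_rest = e_rest; eng.nu = nu; eng.Tset = Tset;
  eng.G = growth_rate; eng.lam0 = lam0;
  eng.record = record_events;
  eng.px.resize(n); eng.py.resize(n); eng.pz.resize(n);
  eng.vx.resize(n); eng.vy.resize(n); eng.vz.resize(n);
  eng.tlast.assign(n, 0.0);
  eng.dnom.resize(n); eng.mass.resize(n);
  eng.cnt.assign(n, 0);
  eng.cellx.resize(n); eng.celly.resize(n); eng.cellz.resize(n);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    eng.px[i] = pos(i, 0); eng.py[i] = pos(i, 1); eng.pz[i] = pos(i, 2);
    eng.vx[i] = vel(i, 0); eng.vy[i] = vel(i, 1); eng.vz[i] = vel(i, 2);
    eng.dnom[i] = dnom[i]; eng.mass[i] = mass[i];
    if (dnom[i] > dmax) dmax = dnom[i];
  }
  // Cell sizing: for strongly size-disparate mixtures a single cell width
  // equal to the largest diameter makes every neighbourhood scan touch
  // hundreds of small particles.  Instead pick the sub-division k of the
  // largest diameter that minimizes a scan-cost model, and give every
  // particle its own neighbour radius covering its largest possible
  // contact distance (R_i = floor(sigma_max_i / cw) + 1 cells).
  {
    int best_nc = 0;
    double best_cost = INFTY;
    int nc_hi = (int)std::floor(6.0 * L / dmax);
    for (int nck = 3; nck <= nc_hi; ++nck) {
      double cwk = L / nck;
      double dens = (double)n * (cwk / L) * (cwk / L) * (cwk / L);
      double cost = 0.0;
      for (int i = 0; i < n; ++i) {
        int R = (int)std::floor(0.5 * (dnom[i] + dmax) / cwk) + 1;
        if (R > nck) R = nck;
        double cube = (2.0 * R + 1) * (2.0 * R + 1) * (2.0 * R + 1);
        double vbar = std::sqrt(8.0 * Tset / (M_PI * mass[i]));
        cost += (3.0 * vbar / cwk + 4.0) * cube * dens;
      }
      if (cost < best_cost) { best_cost = cost; best_nc = nck; }
    }
    if (best_nc == 0) {
      eng.allpairs = true;
      eng.nc = 1;
    } else {
      eng.allpairs = false;
      eng.nc = best_nc;
    }
    eng.cw = L / eng.nc;
    eng.scanr.resize(n);
    for (int i = 0; i < n; ++i) {
      int R = (int)std::floor(0.5 * (dnom[i] + dmax) / eng.cw) + 1;
      if (R > eng.nc) R = eng.nc;
      eng.scanr[i] = R;
    }
  }
  eng.build_cells();
  eng.tnow = 0.0;

  bool growing = (growth_rate > 0.0 && lam0 < 1.0);
  if (!growing) { eng.G = 0.0; }
  double t_stopgrow = growing ? (1.0 - lam0) / growth_rate : INFTY;

  for (int i = 0; i < n; ++i) eng.predict_for(i, 0.0);
  if (growing) {
    Event e; e.t = t_stopgrow; e.kind = EV_STOPGROW; e.i = -1; e.j = -1;
    e.ci = e.cj = 0; eng.heap.push(e);
  }
  double next_thermo = INFTY;
  if (nu > 0.0) {
    next_thermo = -std::log(eng.rng.unif()) / (nu * n);
    Event e; e.t = next_thermo; e.kind = EV_THERMO; e.i = -1; e.j = -1;
    e.ci = e.cj = 0; eng.heap.push(e);
  }
  double next_sample = INFTY;
  int nsamples = 0;
  std::vector<NumericMatrix> sam_pos, sam_vel;
  std::vector<double> sam_t;
  if (sample_interval > 0.0 && max_samples > 0) {
    next_sample = sample_interval;
    Event e; e.t = next_sample; e.kind = EV_SAMPLE; e.i = -1; e.j = -1;
    e.ci = e.cj = 0; eng.heap.push(e);
  }
  if (R_finite(t_end)) {
    Event e; e.t = t_end; e.kind = EV_END; e.i = -1; e.j = -1;
    e.ci = e.cj = 0; eng.heap.push(e);
  }

  bool jammed = false;
  long long check_counter = 0;
  while (!eng.heap.empty()) {
    Event e = eng.heap.top(); eng.heap.pop();
    if (e.t < eng.tnow - 1e-9) stop("event time went backwards");
    if (e.kind == EV_PAIR) {
      if (eng.cnt[e.i] != e.ci || eng.cnt[e.j] != e.cj) { eng.npop_stale++; continue; }
      eng.npop_pair++;
      eng.tnow = e.t;
      eng.resolve_pair(e.i, e.j);
      if ((double)eng.ncoll >= max_collisions) break;
      if (eng.G > 0.0 && (double)eng.ncoll >= jam_limit) { jammed = true; break; }
    } else if (e.kind == EV_CROSS) {
      if (eng.cnt[e.i] != e.ci) { eng.npop_stale++; continue; }
      eng.npop_cross++;
      eng.tnow = e.t;
      int i = e.i, ax = e.j / 2, dir = (e.j % 2) ? 1 : -1;
      eng.advance(i, e.t);
      eng.cell_remove(i);
      if (ax == 0) eng.cellx[i] = (eng.cellx[i] + dir + eng.nc) % eng.nc;
      else if (ax == 1) eng.celly[i] = (eng.celly[i] + dir + eng.nc) % eng.nc;
      else eng.cellz[i] = (eng.cellz[i] + dir + eng.nc) % eng.nc;
      eng.cellof[eng.cellid(eng.cellx[i], eng.celly[i], eng.cellz[i])].push_back(i);
      eng.cnt[i]++;
      eng.predict_for(i, e.t);
    } else if (e.kind == EV_THERMO) {
      eng.tnow = e.t;
      int i = (int)(eng.rng.unif() * n); if (i >= n) i = n - 1;
      eng.advance(i, e.t);
      double s = std::sqrt(Tset / eng.mass[i]);
      eng.vx[i] = s * eng.rng.norm();
      eng.vy[i] = s * eng.rng.norm();
      eng.vz[i] = s * eng.rng.norm();
      eng.cnt[i]++;
      eng.predict_for(i, e.t);
      next_thermo = e.t - std::log(eng.rng.unif()) / (nu * n);
      Event ne; ne.t = next_thermo; ne.kind = EV_THERMO; ne.i = -1; ne.j = -1;
      ne.ci = ne.cj = 0; eng.heap.push(ne);
    } else if (e.kind == EV_SAMPLE) {
      eng.tnow = e.t;
      eng.sync_all(e.t);
      NumericMatrix P(n, 3), V(n, 3);
      for (int i = 0; i < n; ++i) {
        P(i, 0) = eng.px[i]; P(i, 1) = eng.py[i]; P(i, 2) = eng.pz[i];
        V(i, 0) = eng.vx[i]; V(i, 1) = eng.vy[i]; V(i, 2) = eng.vz[i];
      }
      sam_pos.push_back(P); sam_vel.push_back(V); sam_t.push_back(e.t);
      nsamples++;
      if (nsamples < max_samples) {
        Event ne; ne.t = e.t + sample_interval; ne.kind = EV_SAMPLE;
        ne.i = -1; ne.j = -1; ne.ci = ne.cj = 0; eng.heap.push(ne);
      } else if (!R_finite(t_end) && !R_finite(max_collisions)) {
        break;  // samples were the only stop criterion
      }
    } else if (e.kind == EV_STOPGROW) {
      // target packing fraction reached: freeze growth and stop (growth
      // runs are exactly the compression phase)
      eng.tnow = e.t;
      eng.sync_all(e.t);
      eng.lam0 = 1.0; eng.G = 0.0;
      break;
    } else if (e.kind == EV_END) {
      eng.tnow = e.t;
      break;
    }
    if (++check_counter % 8192 == 0) {
      Rcpp::checkUserInterrupt();
      if (eng.heap.size() > 6000000) eng.prune_heap();
    }
  }
  eng.sync_all(eng.tnow);

  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = eng.px[i]; P(i, 1) = eng.py[i]; P(i, 2) = eng.pz[i];
    V(i, 0) = eng.vx[i]; V(i, 1) = eng.vy[i]; V(i, 2) = eng.vz[i];
  }
  List samples(sam_pos.size());
  List samples_v(sam_vel.size());
  for (size_t k = 0; k < sam_pos.size(); ++k) {
    samples[k] = sam_pos[k];
    samples_v[k] = sam_vel[k];
  }
  List events = R_NilValue;
  if (record_events) {
    events = List::create(_["t"] = wrap(eng.ev_t), _["i"] = wrap(eng.ev_i),
                          _["j"] = wrap(eng.ev_j));
  }
  double lam_final = eng.lam(eng.tnow);
  return List::create(
    _["positions"] = P, _["velocities"] = V,
    _["time"] = eng.tnow, _["lambda"] = lam_final,
    _["n_collisions"] = (double)eng.ncoll,
    _["virial_sum"] = eng.virial_sum,
    _["samples"] = samples, _["sample_velocities"] = samples_v,
    _["sample_times"] = wrap(sam_t),
    _["jammed"] = jammed,
    _["diag"] = NumericVector::create((double)eng.npop_pair, (double)eng.npop_cross,
                                      (double)eng.npop_stale, (double)eng.heap.size(),
                                      (double)eng.ncand, (double)eng.nc),
    _["events"] = events);
}

// Random sequential insertion of non-overlapping spheres (largest first
// is the caller's responsibility via ordering of `diam`).
// [[Rcpp::export]]
NumericMatrix cpp_place_random(NumericVector diam, double L, int seed,
                               int max_attempts) {
  int n = diam.size();
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ull + 7u);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) if (diam[i] > dmax) dmax = diam[i];
  int nc = std::max(1, (int)std::floor(L / dmax));
  bool usecells = nc >= 3;
  double cw = L / nc;
  std::vector<std::vector<int> > grid(usecells ? nc * nc * nc : 1);
  NumericMatrix P(n, 3);
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts && !placed; ++att) {
      double x = rng.unif() * L, y = rng.unif() * L, z = rng.unif() * L;
      bool ok = true;
      if (usecells) {
        int cx = std::min(nc - 1, (int)(x / cw));
        int cy = std::min(nc - 1, (int)(y / cw));
        int cz = std::min(nc - 1, (int)(z / cw));
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              int id = (((cz + dz + nc) % nc) * nc + ((cy + dy + nc) % nc)) * nc
                       + ((cx + dx + nc) % nc);
              const std::vector<int>& lst = grid[id];
              for (size_t k = 0; k < lst.size() && ok; ++k) {
                int j = lst[k];
                double rx = x - P(j, 0); rx -= L * std::round(rx / L);
                double ry = y - P(j, 1); ry -= L * std::round(ry / L);
                double rz = z - P(j, 2); rz -= L * std::round(rz / L);
                double sig = 0.5 * (diam[i] + diam[j]);
                if (rx * rx + ry * ry + rz * rz < sig * sig) ok = false;
              }
            }
      } else {
        for (int j = 0; j < i && ok; ++j) {
          double rx = x - P(j, 0); rx -= L * std::round(rx / L);
          double ry = y - P(j, 1); ry -= L * std::round(ry / L);
          double rz = z - P(j, 2); rz -= L * std::round(rz / L);
          double sig = 0.5 * (diam[i] + diam[j]);
          if (rx * rx + ry * ry + rz * rz < sig * sig) ok = false;
        }
      }
      if (ok) {
        P(i, 0) = x; P(i, 1) = y; P(i, 2) = z;
        if (usecells) {
          int cx = std::min(nc - 1, (int)(x / cw));
          int cy = std::min(nc - 1, (int)(y / cw));
          int cz = std::min(nc - 1, (int)(z / cw));
          grid[(cz * nc + cy) * nc + cx].push_back(i);
        }
        placed = true;
      }
    }
    if (!placed)
      stop("random placement failed: packing too dense for insertion");
  }
  return P;
}

// Minimum pair gap |r_ij| - (d_i+d_j)/2 over all pairs (O(n^2) audit).
// [[Rcpp::export]]
double cpp_min_gap(NumericMatrix pos, NumericVector diam, double L) {
  int n = pos.nrow();
  double gmin = INFTY;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double rx = pos(i, 0) - pos(j, 0); rx -= L * std::round(rx / L);
      double ry = pos(i, 1) - pos(j, 1); ry -= L * std::round(ry / L);
      double rz = pos(i, 2) - pos(j, 2); rz -= L * std::round(rz / L);
      double g = std::sqrt(rx * rx + ry * ry + rz * rz)
                 - 0.5 * (diam[i] + diam[j]);
      if (g < gmin) gmin = g;
    }
  return gmin;
}

// Pair-distance histogram for g(r): counts ordered pairs a->b (or
// unordered doubled for same-species) per bin, accumulated over frames.
// [[Rcpp::export]]
NumericVector cpp_rdf_hist(List frames, IntegerVector idx_a,
                           IntegerVector idx_b, bool same, double L,
                           double bin_width, double r_max) {
  int nbins = (int)std::ceil(r_max / bin_width);
  NumericVector hist(nbins);
  int na = idx_a.size(), nb = idx_b.size();
  for (int f = 0; f < frames.size(); ++f) {
    NumericMatrix P = frames[f];
    if (same) {
      for (int ii = 0; ii < na; ++ii)
        for (int jj = ii + 1; jj < na; ++jj) {
          int i = idx_a[ii], j = idx_a[jj];
          double rx = P(i, 0) - P(j, 0); rx -= L * std::round(rx / L);
          double ry = P(i, 1) - P(j, 1); ry -= L * std::round(ry / L);
          double rz = P(i, 2) - P(j, 2); rz -= L * std::round(rz / L);
          double r = std::sqrt(rx * rx + ry * ry + rz * rz);
          if (r < r_max) hist[(int)(r / bin_width)] += 2.0;  // ordered pairs
        }
    } else {
      for (int ii = 0; ii < na; ++ii)
        for (int jj = 0; jj < nb; ++jj) {
          int i = idx_a[ii], j = idx_b[jj];
          double rx = P(i, 0) - P(j, 0); rx -= L * std::round(rx / L);
          double ry = P(i, 1) - P(j, 1); ry -= L * std::round(ry / L);
          double rz = P(i, 2) - P(j, 2); rz -= L * std::round(rz / L);
          double r = std::sqrt(rx * rx + ry * ry + rz * rz);
          if (r < r_max) hist[(int)(r / bin_width)] += 1.0;
        }
    }
  }
  return hist;
}

// Partial static structure factor on the periodic-box wavevector lattice
// k = (2*pi/L) * (nx, ny, nz), accumulated into exact integer shells
// m = nx^2+ny^2+nz^2.  Returns sum of Re[rho_a(k) conj(rho_b(k))] and the
// vector count per shell; normalization 1/sqrt(Na*Nb) applied here.
// [[Rcpp::export]]
List cpp_sk_shells(List frames, IntegerVector idx_a, IntegerVector idx_b,
                   bool same, double L, double k_max) {
  typedef std::complex<double> cplx;
  int nmax = (int)std::floor(k_max / (2.0 * M_PI / L));
  if (nmax < 1) stop("k_max below the smallest lattice wavevector 2*pi/L");
  int mmax = nmax * nmax;
  std::vector<double> ssum(mmax + 1, 0.0);
  std::vector<double> scount(mmax + 1, 0.0);
  int na = idx_a.size(), nb = idx_b.size();
  double norm = 1.0 / std::sqrt((double)na * (double)nb);

  // merged particle list (a then, if different, b)
  std::vector<int> all(idx_a.begin(), idx_a.end());
  if (!same) all.insert(all.end(), idx_b.begin(), idx_b.end());
  int ntot = all.size();

  int nframes = frames.size();
  std::vector<cplx> ph(ntot * 3 * (nmax + 1));
  std::vector<cplx> rho_a, rho_b;
  for (int f = 0; f < nframes; ++f) {
    NumericMatrix P = frames[f];
    double fac = 2.0 * M_PI / L;
    for (int q = 0; q < ntot; ++q) {
      int i = all[q];
      for (int ax = 0; ax < 3; ++ax) {
        cplx base(std::cos(fac * P(i, ax)), std::sin(fac * P(i, ax)));
        cplx cur(1.0, 0.0);
        for (int m = 0; m <= nmax; ++m) {
          ph[(q * 3 + ax) * (nmax + 1) + m] = cur;
          cur *= base;
        }
      }
    }
    // half-space lattice enumeration (k and -k give the same Re part)
    for (int nx = 0; nx <= nmax; ++nx) {
      int nymin = (nx > 0) ? -nmax : 0;
      for (int ny = nymin; ny <= nmax; ++ny) {
        int m2xy = nx * nx + ny * ny;
        if (m2xy > mmax) continue;
        int nzmin = (nx > 0 || ny > 0) ? -nmax : 1;
        for (int nz = nzmin; nz <= nmax; ++nz) {
          int m = m2xy + nz * nz;
          if (m > mmax || m == 0) continue;
          cplx ra(0.0, 0.0), rb(0.0, 0.0);
          for (int q = 0; q < (same ? na : ntot); ++q) {
            const cplx* pq = &ph[q * 3 * (nmax + 1)];
            cplx ex = pq[nx];
            cplx ey = (ny >= 0) ? pq[(nmax + 1) + ny]
                                : std::conj(pq[(nmax + 1) - ny]);
            cplx ez = (nz >= 0) ? pq[2 * (nmax + 1) + nz]
                                : std::conj(pq[2 * (nmax + 1) - nz]);
            cplx val = ex * ey * ez;
            if (same) { ra += val; }
            else if (q < na) { ra += val; }
            else { rb += val; }
          }
          if (same) rb = ra;
          ssum[m] += (ra * std::conj(rb)).real() * norm;
          scount[m] += 1.0;
        }
      }
    }
  }
  std::vector<double> kout, sout, cout_;
  for (int m = 1; m <= mmax; ++m) {
    if (scount[m] > 0) {
      kout.push_back(2.0 * M_PI / L * std::sqrt((double)m));
      sout.push_back(ssum[m] / scount[m]);
      cout_.push_back(scount[m] / nframes);
    }
  }
  return List::create(_["k"] = wrap(kout), _["s"] = wrap(sout),
                      _["n_vectors"] = wrap(cout_));
}
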