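// Hybrid Brownian-dynamics / Gillespie engine.
//
// Positions are stored UNWRAPPED; all pair geometry uses the minimum-image
// convention, so coordinates may drift arbitrarily far from the primary box.
// Site states live on strand-end beads: -2 = not a site, -1 = inactive site,
// 0 = free, 1 = crosslinked, 2 = bound.  Bond changes are only allowed while
// the two disks overlap (s_ij < 0), which keeps the total energy continuous
// across every stochastic bond flip (the two branches of the pair potential
// coincide for s_ij <= 0).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64; deterministic given the run seed.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    init_ziggurat();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so log() is safe
  inline double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
  // standard normal via the Marsaglia-Tsang ziggurat (128 layers)
  uint32_t kn[128];
  double wn[128], fn[128];
  void init_ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double rnorm() {
    const double rtail = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)next32();
      int iz = hz & 127;
      uint32_t uhz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (uhz < kn[iz]) return hz * wn[iz];
      if (iz == 0) { // tail
        double x, y;
        do {
          x = -std::log(runif()) / rtail;
          y = -std::log(runif());
        } while (y + y < x * x);
        return hz > 0 ? rtail + x : -(rtail + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + runif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// site state codes
enum { S_NONE = -2, S_INACTIVE = -1, S_FREE = 0, S_CROSS = 1, S_BOUND = 2 };
// transition type codes (order matches the rate vector from R)
enum { T_FC = 0, T_CF = 1, T_CB = 2, T_BC = 3, T_BF = 4, T_FB = 5 };

struct Event {
  int i;      // the site undergoing the transition (fc: lower-index site)
  int j;      // partner: complementary end or particle bead
  int type;
  double rate;
};

struct Engine {
  int n, d;
  std::vector<double> ux;       // n*d, unwrapped
  std::vector<double> radius;
  std::vector<int> role;        // 0 core, 1 arm, 2 end, 3 particle
  std::vector<int> binding;     // particles only
  std::vector<int> mobile;
  std::vector<int> state;       // site state codes
  std::vector<int> partner;     // 0-based bead index or -1
  std::vector<int> species;     // -1 self-complementary, 0 = G, 1 = G'
  std::vector<int> bound_count; // particles: number of concurrent GP bonds
  std::vector<std::pair<int,int>> perm;   // permanent bonds
  std::vector<std::vector<int>> perm_adj; // adjacency for exclusion checks
  std::vector<std::array<int,3>> triples; // bending (h, i, j), vertex i
  std::vector<int> particles;   // indices of binding particles
  std::vector<double> L;        // box lengths
  double dt, kH, kBB, eta, kT;
  int capacity;                 // max concurrent GP bonds per particle
  double rates[6];

  // neighbour list
  std::vector<int> nbr_i, nbr_j;          // all close pairs (one-sided cands)
  std::vector<int> knbr_i, knbr_j;        // kinetics-relevant close pairs
  std::vector<double> ref;                // positions at last rebuild
  double skin = 0.7;
  double max_pair_cut;
  std::vector<int> cell_head, cell_next;  // persistent cell-list buffers
  std::vector<Event> ev_buf;              // reusable event buffer

  Xoshiro rng;

  Engine(uint64_t seed) : rng(seed) {}

  inline double mind(double dx, int k) const {
    double Lk = L[k];
    return dx - Lk * std::round(dx / Lk);
  }
  inline double dist2(int i, int j) const {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = mind(ux[i * d + k] - ux[j * d + k], k);
      s += dx * dx;
    }
    return s;
  }
  inline double gap(int i, int j) const {
    return std::sqrt(dist2(i, j)) - (radius[i] + radius[j]);
  }
  inline bool overlapping(int i, int j) const {
    double c = radius[i] + radius[j];
    return dist2(i, j) < c * c;
  }

  // complementarity of two binding sites (self-complementary if untyped)
  inline bool complementary(int i, int j) const {
    if (species[i] < 0 && species[j] < 0) return true;
    return species[i] >= 0 && species[j] >= 0 && species[i] != species[j];
  }
  // particles bind the G sites only (untyped sites bind as G)
  inline bool particle_bindable(int i) const { return species[i] != 1; }

  bool perm_bonded(int i, int j) const {
    const std::vector<int> &a = perm_adj[i];
    return std::find(a.begin(), a.end(), j) != a.end();
  }
  inline bool dyn_bonded(int i, int j) const {
    return (state[i] >= S_CROSS && partner[i] == j) ||
           (state[j] >= S_CROSS && partner[j] == i);
  }

  // ---------------- neighbour list ----------------
  void build_neighbours() {
    nbr_i.clear(); nbr_j.clear();
    knbr_i.clear(); knbr_j.clear();
    ref = ux;
    // cell binning on wrapped coordinates; all-pairs fallback for small boxes
    double cell_min = max_pair_cut + skin;
    std::vector<int> nc(d);
    bool cells_ok = true;
    for (int k = 0; k < d; ++k) {
      nc[k] = std::max(1, (int)std::floor(L[k] / cell_min));
      if (nc[k] < 4) cells_ok = false;
    }
    if (!cells_ok) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) consider_pair(i, j);
      return;
    }
    int ncell = 1;
    for (int k = 0; k < d; ++k) ncell *= nc[k];
    cell_head.assign(ncell, -1);
    cell_next.resize(n);
    for (int i = 0; i < n; ++i) {
      int idx = 0;
      for (int k = 0; k < d; ++k) {
        double x = ux[i * d + k];
        double w = x - L[k] * std::floor(x / L[k]);
        int c = std::min(nc[k] - 1, (int)(w / L[k] * nc[k]));
        idx = idx * nc[k] + c;
      }
      cell_next[i] = cell_head[idx];
      cell_head[idx] = i;
    }
    // half stencil over neighbouring cells (periodic)
    static const int st2[5][3] = {{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0}};
    static const int st3[14][3] = {{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
                 {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},
                 {1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
    const int (*stencil)[3] = (d == 2) ? st2 : st3;
    int nst = (d == 2) ? 5 : 14;
    int cc[3];
    for (int idx = 0; idx < ncell; ++idx) {
      if (cell_head[idx] < 0) continue;
      int rem = idx;
      for (int k = d - 1; k >= 0; --k) { cc[k] = rem % nc[k]; rem /= nc[k]; }
      for (int q = 0; q < nst; ++q) {
        int jdx = 0;
        for (int k = 0; k < d; ++k) {
          int c = (cc[k] + stencil[q][k] + nc[k]) % nc[k];
          jdx = jdx * nc[k] + c;
        }
        if (jdx == idx) {
          for (int i = cell_head[idx]; i >= 0; i = cell_next[i])
            for (int j = cell_next[i]; j >= 0; j = cell_next[j])
              consider_pair(i, j);
        } else {
          for (int i = cell_head[idx]; i >= 0; i = cell_next[i])
            for (int j = cell_head[jdx]; j >= 0; j = cell_next[j])
              consider_pair(i, j);
        }
      }
    }
  }

  inline void consider_pair(int i, int j) {
    double cut = radius[i] + radius[j] + skin;
    if (dist2(i, j) < cut * cut) {
      nbr_i.push_back(i); nbr_j.push_back(j);
      bool ei = (state[i] != S_NONE), ej = (state[j] != S_NONE);
      bool pi = (role[i] == 3 && binding[i]), pj = (role[j] == 3 && binding[j]);
      if ((ei && ej) || (ei && pj) || (ej && pi)) {
        knbr_i.push_back(i); knbr_j.push_back(j);
      }
    }
  }

  bool needs_rebuild() const {
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double dx = ux[i * d + k] - ref[i * d + k];
        s += dx * dx;
      }
      if (s > lim) return true;
    }
    return false;
  }

  // ---------------- forces and energy ----------------
  // adds the pair interaction; 'bonded' selects the two-sided branch
  inline void pair_force(int i, int j, bool bonded,
                         std::vector<double> &F, double &E) {
    double dx[3];
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) {
      dx[k] = mind(ux[i * d + k] - ux[j * d + k], k);
      r2 += dx[k] * dx[k];
    }
    double c = radius[i] + radius[j];
    if (!bonded && r2 >= c * c) return;
    double r = std::sqrt(r2);
    if (r < 1e-12) return; // coincident centres exert no well-defined force
    double s = r - c;
    E += 0.5 * kH * s * s;
    double fmag = -kH * s / r;
    for (int k = 0; k < d; ++k) {
      F[i * d + k] += fmag * dx[k];
      F[j * d + k] -= fmag * dx[k];
    }
  }

  inline void bend_force(int h, int i, int j,
                         std::vector<double> &F, double &E) {
    double a[3], b[3];
    double la2 = 0.0, lb2 = 0.0, ab = 0.0;
    for (int k = 0; k < d; ++k) {
      a[k] = mind(ux[h * d + k] - ux[i * d + k], k);
      b[k] = mind(ux[j * d + k] - ux[i * d + k], k);
      la2 += a[k] * a[k]; lb2 += b[k] * b[k]; ab += a[k] * b[k];
    }
    double la = std::sqrt(la2), lb = std::sqrt(lb2);
    if (la < 1e-12 || lb < 1e-12) stop("bond-bending: coincident monomers");
    double c = ab / (la * lb);
    E += 0.5 * kBB * (c - 1.0);
    double pref = -0.5 * kBB;
    for (int k = 0; k < d; ++k) {
      double ga = b[k] / (la * lb) - c * a[k] / la2;
      double gb = a[k] / (la * lb) - c * b[k] / lb2;
      F[h * d + k] += pref * ga;
      F[j * d + k] += pref * gb;
      F[i * d + k] -= pref * (ga + gb);
    }
  }

  double compute_forces(std::vector<double> &F) {
    std::fill(F.begin(), F.end(), 0.0);
    double E = 0.0;
    for (const auto &b : perm) pair_force(b.first, b.second, true, F, E);
    for (int i = 0; i < n; ++i) {
      if (state[i] == S_CROSS && i < partner[i])
        pair_force(i, partner[i], true, F, E);
      else if (state[i] == S_BOUND)
        pair_force(i, partner[i], true, F, E);
    }
    for (size_t p = 0; p < nbr_i.size(); ++p) {
      int i = nbr_i[p], j = nbr_j[p];
      if (perm_bonded(i, j) || dyn_bonded(i, j)) continue;
      pair_force(i, j, false, F, E);
    }
    for (const auto &t : triples) bend_force(t[0], t[1], t[2], F, E);
    return E;
  }

  // ---------------- kinetics ----------------
  inline bool particle_has_capacity(int p) const {
    return bound_count[p] < capacity;
  }

  void enumerate_events(std::vector<Event> &ev) const {
    ev.clear();
    // pairwise channels gated on current overlap
    for (size_t p = 0; p < knbr_i.size(); ++p) {
      int i = knbr_i[p], j = knbr_j[p];
      if (!overlapping(i, j)) continue;
      bool ei = (state[i] >= S_FREE), ej = (state[j] >= S_FREE);
      if (ei && ej) {
        if (!complementary(i, j)) continue;
        // end-end channels
        if (state[i] == S_FREE && state[j] == S_FREE && rates[T_FC] > 0.0)
          ev.push_back({std::min(i, j), std::max(i, j), T_FC, rates[T_FC]});
        // bound + free -> direct exchange back to a crosslink
        if (state[i] == S_BOUND && state[j] == S_FREE && rates[T_BC] > 0.0) {
          if (overlapping(i, partner[i]))
            ev.push_back({i, j, T_BC, rates[T_BC]});
        }
        if (state[j] == S_BOUND && state[i] == S_FREE && rates[T_BC] > 0.0) {
          if (overlapping(j, partner[j]))
            ev.push_back({j, i, T_BC, rates[T_BC]});
        }
      } else {
        // end-particle channels (non-binding particles never appear here)
        int site = ei ? i : j, part = ei ? j : i;
        if (role[part] != 3 || !binding[part] || state[site] < S_FREE) continue;
        if (!particle_bindable(site)) continue;
        if (state[site] == S_FREE && particle_has_capacity(part) &&
            rates[T_FB] > 0.0)
          ev.push_back({site, part, T_FB, rates[T_FB]});
        if (state[site] == S_CROSS && particle_has_capacity(part) &&
            rates[T_CB] > 0.0) {
          // direct exchange: the broken crosslink must itself be overlapping
          if (overlapping(site, partner[site]))
            ev.push_back({site, part, T_CB, rates[T_CB]});
        }
      }
    }
    // unimolecular exits of existing bonds
    for (int i = 0; i < n; ++i) {
      if (state[i] == S_CROSS && i < partner[i] && rates[T_CF] > 0.0) {
        if (overlapping(i, partner[i]))
          ev.push_back({i, partner[i], T_CF, rates[T_CF]});
      } else if (state[i] == S_BOUND && rates[T_BF] > 0.0) {
        if (overlapping(i, partner[i]))
          ev.push_back({i, partner[i], T_BF, rates[T_BF]});
      }
    }
  }

  void execute(const Event &e) {
    switch (e.type) {
    case T_FC:
      state[e.i] = S_CROSS; state[e.j] = S_CROSS;
      partner[e.i] = e.j;   partner[e.j] = e.i;
      break;
    case T_CF:
      state[e.i] = S_FREE; state[e.j] = S_FREE;
      partner[e.i] = -1;   partner[e.j] = -1;
      break;
    case T_FB:
      state[e.i] = S_BOUND; partner[e.i] = e.j;
      bound_count[e.j]++;
      break;
    case T_BF:
      state[e.i] = S_FREE; partner[e.i] = -1;
      bound_count[e.j]--;
      break;
    case T_CB: { // atomic crosslink -> particle-bond exchange
      int gp = partner[e.i];
      state[gp] = S_FREE; partner[gp] = -1;
      state[e.i] = S_BOUND; partner[e.i] = e.j;
      bound_count[e.j]++;
      break;
    }
    case T_BC: { // atomic particle-bond -> crosslink exchange
      int p = partner[e.i];
      bound_count[p]--;
      state[e.i] = S_CROSS; partner[e.i] = e.j;
      state[e.j] = S_CROSS; partner[e.j] = e.i;
      break;
    }
    }
    audit_event(e);
  }

  void audit_event(const Event &e) const {
    // competitive-binding invariant: a site is exactly one of free /
    // crosslinked / bound, and partnerships are mutual
    int ids[2] = {e.i, e.j};
    for (int id : ids) {
      if (state[id] == S_CROSS &&
          (partner[id] < 0 || partner[partner[id]] != id ||
           state[partner[id]] != S_CROSS))
        stop("bond table corrupted: crosslink partnership not mutual");
      if (state[id] == S_BOUND &&
          (partner[id] < 0 || role[partner[id]] != 3))
        stop("bond table corrupted: bound site without a particle partner");
    }
    for (int p : particles)
      if (bound_count[p] < 0 || bound_count[p] > capacity)
        stop("competitive binding violated: particle capacity out of range");
  }

  double near_particle(int i) const {
    double best = R_PosInf;
    for (int p : particles) {
      if (p == i) continue;
      double r = std::sqrt(dist2(i, p));
      if (r < best) best = r;
    }
    return best;
  }

  // Gillespie loop over one frozen-position interval; returns events fired
  int gillespie(double interval, double t_abs,
                std::vector<double> &ev_t, std::vector<int> &ev_type,
                std::vector<int> &ev_site, std::vector<int> &ev_part,
                std::vector<double> &ev_near, bool record,
                std::vector<long long> &counts) {
    double t_loc = 0.0;
    int fired = 0;
    std::vector<Event> &ev = ev_buf;
    for (;;) {
      enumerate_events(ev);
      double R = 0.0;
      for (const auto &e : ev) R += e.rate;
      if (R <= 0.0) break;
      t_loc += -std::log(rng.runif()) / R;
      if (t_loc > interval) break;
      double u = rng.runif() * R, acc = 0.0;
      size_t pick = ev.size() - 1;
      for (size_t q = 0; q < ev.size(); ++q) {
        acc += ev[q].rate;
        if (u <= acc) { pick = q; break; }
      }
      const Event &e = ev[pick];
      execute(e);
      counts[e.type]++;
      fired++;
      if (record) {
        ev_t.push_back(t_abs + t_loc);
        ev_type.push_back(e.type);
        ev_site.push_back(e.i);
        ev_part.push_back(e.j);
        ev_near.push_back(near_particle(e.i));
      }
    }
    return fired;
  }
};

// build an Engine from the R-side state description
static Engine *make_engine(NumericMatrix ux, NumericVector radius,
                           IntegerVector role, IntegerVector binding,
                           IntegerVector mobile, IntegerVector site_state,
                           IntegerVector partner, IntegerVector species,
                           IntegerMatrix perm_bonds,
                           IntegerMatrix triples, NumericVector box,
                           List params, NumericVector rates, double seed) {
  Engine *E = new Engine((uint64_t)seed);
  E->n = ux.nrow();
  E->d = ux.ncol();
  E->ux.resize(E->n * E->d);
  for (int i = 0; i < E->n; ++i)
    for (int k = 0; k < E->d; ++k) E->ux[i * E->d + k] = ux(i, k);
  E->radius = as<std::vector<double>>(radius);
  E->role = as<std::vector<int>>(role);
  E->binding = as<std::vector<int>>(binding);
  E->mobile = as<std::vector<int>>(mobile);
  E->state = as<std::vector<int>>(site_state);
  E->partner = as<std::vector<int>>(partner);
  E->species = as<std::vector<int>>(species);
  E->L = as<std::vector<double>>(box);
  E->dt = as<double>(params["dt"]);
  E->kH = as<double>(params["k_H"]);
  E->kBB = as<double>(params["k_BB"]);
  E->eta = as<double>(params["eta"]);
  E->kT = as<double>(params["kT"]);
  E->capacity = as<int>(params["capacity"]);
  for (int k = 0; k < 6; ++k) E->rates[k] = rates[k];
  E->perm.resize(perm_bonds.nrow());
  E->perm_adj.assign(E->n, {});
  for (int b = 0; b < perm_bonds.nrow(); ++b) {
    int i = perm_bonds(b, 0), j = perm_bonds(b, 1);
    E->perm[b] = {i, j};
    E->perm_adj[i].push_back(j);
    E->perm_adj[j].push_back(i);
  }
  E->triples.resize(triples.nrow());
  for (int t = 0; t < triples.nrow(); ++t)
    E->triples[t] = {triples(t, 0), triples(t, 1), triples(t, 2)};
  E->bound_count.assign(E->n, 0);
  for (int i = 0; i < E->n; ++i) {
    if (E->role[i] == 3 && E->binding[i]) E->particles.push_back(i);
    if (E->state[i] == S_BOUND) E->bound_count[E->partner[i]]++;
  }
  // largest + second-largest radius bounds every pair cutoff
  double r1 = 0.0, r2 = 0.0;
  for (double r : E->radius) {
    if (r > r1) { r2 = r1; r1 = r; }
    else if (r > r2) r2 = r;
  }
  E->max_pair_cut = r1 + (E->n > 1 ? r2 : r1);
  E->build_neighbours();
  return E;
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix ux, NumericVector radius, IntegerVector role,
             IntegerVector binding, IntegerVector mobile,
             IntegerVector site_state, IntegerVector partner,
             IntegerVector species,
             IntegerMatrix perm_bonds, IntegerMatrix triples,
             NumericVector box, List params, NumericVector rates,
             double steps, double sample_every, double seed,
             bool do_bd, bool do_gillespie, bool noise, double interval,
             IntegerVector track, Nullable<NumericMatrix> ext_force,
             bool record_events, double t0, double max_step_disp) {
  Engine *E = make_engine(ux, radius, role, binding, mobile, site_state,
                          partner, species, perm_bonds, triples, box, params,
                          rates, seed);
  int n = E->n, d = E->d;
  long long nsteps = (long long)steps;
  long long sev = std::max(1LL, (long long)sample_every);
  std::vector<double> F(n * d, 0.0);
  bool have_ext = ext_force.isNotNull();
  NumericMatrix Fext;
  if (have_ext) Fext = NumericMatrix(ext_force);

  std::vector<int> trk = as<std::vector<int>>(track); // 0-based
  long long nframes = nsteps / sev + 1;
  NumericMatrix traj(nframes, (int)(trk.size() * d));
  NumericMatrix comtraj(nframes, d); // gel COM displacement since t0
  NumericVector times(nframes);
  long long frame = 0;
  // gel beads (everything that is not a particle) define the network COM;
  // subtracting its drift from tracer positions removes the free diffusion
  // of the whole periodic network, which is not negligible in small gels
  int n_gel = 0;
  for (int i = 0; i < n; ++i) if (E->role[i] != 3) n_gel++;
  std::vector<double> comdisp(d, 0.0);
  auto record_frame = [&](double t) {
    if (frame >= nframes) return;
    times[frame] = t;
    for (size_t q = 0; q < trk.size(); ++q)
      for (int k = 0; k < d; ++k)
        traj(frame, q * d + k) = E->ux[trk[q] * d + k];
    for (int k = 0; k < d; ++k) comtraj(frame, k) = comdisp[k];
    frame++;
  };

  std::vector<double> ev_t, ev_near;
  std::vector<int> ev_type, ev_site, ev_part;
  std::vector<long long> counts(6, 0);

  // precompute per-bead mobility prefactors
  std::vector<double> invg(n), amp(n);
  for (int i = 0; i < n; ++i) {
    double g = 2.0 * d * M_PI * E->eta * E->radius[i];
    invg[i] = E->dt / g;
    amp[i] = std::sqrt(2.0 * E->kT * E->dt / g);
  }

  double step_time = do_bd ? E->dt : interval;
  record_frame(t0);
  for (long long step = 1; step <= nsteps; ++step) {
    if (do_bd) {
      double Ecur = E->compute_forces(F);
      (void)Ecur;
      for (int i = 0; i < n; ++i) {
        if (!E->mobile[i]) continue;
        bool is_gel = (E->role[i] != 3);
        for (int k = 0; k < d; ++k) {
          double f = F[i * d + k];
          if (have_ext) f += Fext(i, k);
          double disp = f * invg[i];
          if (noise) disp += amp[i] * E->rng.rnorm();
          if (std::fabs(disp) > max_step_disp)
            stop("integration unstable: per-step displacement %.3g exceeds "
                 "bound %.3g (reduce dt or k_H)", std::fabs(disp),
                 max_step_disp);
          E->ux[i * d + k] += disp;
          if (is_gel && n_gel > 0) comdisp[k] += disp / n_gel;
        }
      }
      if (E->needs_rebuild()) E->build_neighbours();
    }
    if (do_gillespie) {
      double t_abs = t0 + (step - 1) * step_time;
      E->gillespie(do_bd ? E->dt : interval, t_abs, ev_t, ev_type, ev_site,
                   ev_part, ev_near, record_events, counts);
    }
    if (step % sev == 0) record_frame(t0 + step * step_time);
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix ux_out(n, d);
  IntegerVector st_out(n), pt_out(n), bc_out(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) ux_out(i, k) = E->ux[i * d + k];
    st_out[i] = E->state[i];
    pt_out[i] = E->partner[i];
    bc_out[i] = E->bound_count[i];
  }
  List events = List::create(
      _["time"] = wrap(ev_t), _["type"] = wrap(ev_type),
      _["site"] = wrap(ev_site), _["partner"] = wrap(ev_part),
      _["near"] = wrap(ev_near));
  NumericVector cnt(6);
  for (int k = 0; k < 6; ++k) cnt[k] = (double)counts[k];
  delete E;
  return List::create(_["ux"] = ux_out, _["site_state"] = st_out,
                      _["partner"] = pt_out, _["bound_count"] = bc_out,
                      _["times"] = times, _["traj"] = traj,
                      _["com"] = comtraj,
                      _["events"] = events, _["event_counts"] = cnt,
                      _["t_end"] = t0 + nsteps * step_time);
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix ux, NumericVector radius, IntegerVector role,
                IntegerVector binding, IntegerVector mobile,
                IntegerVector site_state, IntegerVector partner,
                IntegerVector species,
                IntegerMatrix perm_bonds, IntegerMatrix triples,
                NumericVector box, List params, NumericVector rates) {
  Engine *E = make_engine(ux, radius, role, binding, mobile, site_state,
                          partner, species, perm_bonds, triples, box, params,
                          rates, 1.0);
  std::vector<double> F(E->n * E->d, 0.0);
  double energy = E->compute_forces(F);
  NumericMatrix Fout(E->n, E->d);
  for (int i = 0; i < E->n; ++i)
    for (int k = 0; k < E->d; ++k) Fout(i, k) = F[i * E->d + k];
  delete E;
  return List::create(_["forces"] = Fout, _["energy"] = energy);
}

// [[Rcpp::export]]
DataFrame cpp_enumerate(NumericMatrix ux, NumericVector radius,
                        IntegerVector role, IntegerVector binding,
                        IntegerVector mobile, IntegerVector site_state,
                        IntegerVector partner, IntegerVector species,
                        IntegerMatrix perm_bonds,
                        IntegerMatrix triples, NumericVector box,
                        List params, NumericVector rates) {
  Engine *E = make_engine(ux, radius, role, binding, mobile, site_state,
                          partner, species, perm_bonds, triples, box, params,
                          rates, 1.0);
  std::vector<Event> ev;
  E->enumerate_events(ev);
  IntegerVector site(ev.size()), part(ev.size()), type(ev.size());
  NumericVector rate(ev.size());
  for (size_t q = 0; q < ev.size(); ++q) {
    site[q] = ev[q].i; part[q] = ev[q].j;
    type[q] = ev[q].type; rate[q] = ev[q].rate;
  }
  delete E;
  return DataFrame::create(_["site"] = site, _["partner"] = part,
                           _["type"] = type, _["rate"] = rate);
}
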