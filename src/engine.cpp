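// Simulation core: honeybee colony central-place foraging with waggle-dance
// recruitment (SI) or disoriented dances (NI).
//
// The hot loop runs n_agents x t_day x n_days state-machine updates, so the
// whole engine lives here; the R surface wraps these entry points.  A private
// xoshiro256++ stream (seeded via splitmix64) keeps runs reproducible and
// independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  bool have_norm;
  double cached_norm;

  explicit Xoshiro(uint64_t seed) : have_norm(false), cached_norm(0.0) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1), 53-bit resolution
  inline double unif() {
    return (double)(next() >> 11) * 1.1102230246251565e-16;
  }

  // standard normal (polar Box-Muller, cached pair)
  inline double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached_norm = v * f;
    have_norm = true;
    return u * f;
  }

  // integer in [0, n), n small
  inline int below(int n) { return (int)(unif() * n); }
};

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------

struct Pars {
  int n_scouts, n_recruits;
  int t_day, t_init;
  double p_exit, p_rs;
  double d_patch;
  int a_max;
  double y_patch;
  double t_patch_mean, t_patch_sd;
  int t_nest;
  double q_mean, q_sd;
  double v;
  double mu_levy;
  double c_rest, c_move_factor;
  double m;
  double e_mol;
  double c_recruit;
  int n_dance;
  double p_dance;
  double load_volume_ul;
  double p_detect;
  double dance_midpoint, dance_slope, return_shift;
  int influx_window;
  double influx_floor;
  int grid_half_extent;
  double cell_width_m;
  bool stationary_births;
  bool persistent_recruits;
  int forage_open, forage_close;

  // derived
  double c_move;           // J per airborne/on-patch step
  double load_j_per_q;     // J delivered per (mol/l) of quality
  double handling_cost_j;  // feeding + unloading cost used in trip valuation
  double flight_cost_per_m;
};

static double getd(const List& p, const char* nm) {
  return as<double>(p[nm]);
}
static int geti(const List& p, const char* nm) {
  return as<int>(p[nm]);
}
static bool getb(const List& p, const char* nm) {
  return as<bool>(p[nm]);
}

static Pars parse_pars(const List& p) {
  Pars q;
  q.n_scouts = geti(p, "n_scouts");
  q.n_recruits = geti(p, "n_recruits");
  q.t_day = geti(p, "t_day");
  q.t_init = geti(p, "t_init");
  q.p_exit = getd(p, "p_exit");
  q.p_rs = getd(p, "p_rs");
  q.d_patch = getd(p, "d_patch");
  q.a_max = geti(p, "a_max");
  q.y_patch = getd(p, "y_patch");
  q.t_patch_mean = getd(p, "t_patch_mean");
  q.t_patch_sd = getd(p, "t_patch_sd");
  q.t_nest = geti(p, "t_nest");
  q.q_mean = getd(p, "q_mean");
  q.q_sd = getd(p, "q_sd");
  q.v = getd(p, "v");
  q.mu_levy = getd(p, "mu_levy");
  q.c_rest = getd(p, "c_rest");
  q.c_move_factor = getd(p, "c_move_factor");
  q.m = getd(p, "m");
  q.e_mol = getd(p, "e_mol");
  q.c_recruit = getd(p, "c_recruit");
  q.n_dance = geti(p, "n_dance");
  q.p_dance = getd(p, "p_dance");
  q.load_volume_ul = getd(p, "load_volume_ul");
  q.p_detect = getd(p, "p_detect");
  q.dance_midpoint = getd(p, "dance_midpoint");
  q.dance_slope = getd(p, "dance_slope");
  q.return_shift = getd(p, "return_shift");
  q.influx_window = geti(p, "influx_window");
  q.influx_floor = getd(p, "influx_floor");
  q.grid_half_extent = geti(p, "grid_half_extent");
  q.cell_width_m = getd(p, "cell_width_m");
  q.stationary_births =
      as<std::string>(p["patch_birth_mode"]) == "stationary";
  q.persistent_recruits = getb(p, "persistent_recruits");
  q.forage_open = geti(p, "forage_open");
  q.forage_close = geti(p, "forage_close");

  q.c_move = q.c_rest * q.c_move_factor;
  q.load_j_per_q = q.load_volume_ul * 1e-6 * q.e_mol;
  q.handling_cost_j = q.t_patch_mean * q.c_move + q.t_nest * q.c_rest;
  q.flight_cost_per_m = q.c_move / (q.v * q.cell_width_m);
  return q;
}

// ---------------------------------------------------------------------------
// Shared submodel formulas (the R surface mirrors these; a test cross-checks)
// ---------------------------------------------------------------------------

static inline double trip_value_j(double quality, const Pars& P) {
  return P.load_j_per_q * quality;
}

static inline double effective_value_j(double quality, double dist_m,
                                       const Pars& P) {
  return trip_value_j(quality, P) - 2.0 * dist_m * P.flight_cost_per_m -
         P.handling_cost_j;
}

static inline double dance_prob(double quality, double dist_m, const Pars& P) {
  const double z =
      (effective_value_j(quality, dist_m, P) - P.dance_midpoint) /
      P.dance_slope;
  return 1.0 / (1.0 + std::exp(-z));
}

static inline double return_prob(double quality, double dist_m,
                                 const Pars& P) {
  const double p = dance_prob(quality, dist_m, P) + P.return_shift;
  return p > 1.0 ? 1.0 : p;
}

// dance suppression by forager influx: linear down to influx_floor at 20
// returnees, flat beyond (Fig S2 shape)
static inline double influx_factor_c(int n_recent, const Pars& P) {
  const double k = n_recent > 20 ? 20.0 : (double)n_recent;
  return 1.0 - (1.0 - P.influx_floor) * k / 20.0;
}

static inline double levy_len(Xoshiro& rng, double mu) {
  // inverse-CDF power law, minimum leg 1 cell-width
  const double a = rng.unif();
  return std::pow(1.0 - a, 1.0 / (1.0 - mu));
}

// [[Rcpp::export]]
double cpp_dance_probability(double quality, double dist_m, List params) {
  Pars P = parse_pars(params);
  return dance_prob(quality, dist_m, P);
}

// [[Rcpp::export]]
NumericVector cpp_levy_lengths(int n, double mu, int seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = levy_len(rng, mu);
  return out;
}

// ---------------------------------------------------------------------------
// World
// ---------------------------------------------------------------------------

struct World {
  int H, side;
  std::vector<uint8_t> forage;
  std::vector<double> quality;
  std::vector<int> age;

  inline int idx(int cx, int cy) const {
    return (cx + H) + side * (cy + H);
  }
  inline int nest() const { return idx(0, 0); }
};

static inline int cell_coord(double z) {
  // squares centred on integer coordinates, half-open on the upper edge
  return (int)std::floor(z + 0.5);
}

static inline double draw_quality(Xoshiro& rng, const Pars& P) {
  // truncated-normal by redraw; floor keeps concentrations physical
  double q;
  do {
    q = P.q_mean + P.q_sd * rng.norm();
  } while (q <= 0.05);
  return q;
}

static void init_world_impl(World& W, const Pars& P, Xoshiro& rng) {
  W.H = P.grid_half_extent;
  W.side = 2 * W.H + 1;
  const int n = W.side * W.side;
  W.forage.assign(n, 0);
  W.quality.assign(n, 0.0);
  W.age.assign(n, 0);
  const int nest = W.nest();
  for (int i = 0; i < n; ++i) {
    if (i == nest) continue;
    if (rng.unif() < P.d_patch) {
      W.forage[i] = 1;
      W.quality[i] = draw_quality(rng, P);
      W.age[i] = 1 + rng.below(P.a_max);
    }
  }
}

static void turnover_impl(World& W, const Pars& P, Xoshiro& rng) {
  const int n = W.side * W.side;
  const int nest = W.nest();
  const double birth =
      P.stationary_births
          ? P.d_patch / ((double)P.a_max * (1.0 - P.d_patch))
          : P.d_patch;
  for (int i = 0; i < n; ++i) {
    if (i == nest) continue;
    if (W.forage[i]) {
      if (++W.age[i] > P.a_max) {
        W.forage[i] = 0;
        W.quality[i] = 0.0;
        W.age[i] = 0;
      }
    } else if (rng.unif() < birth) {
      W.forage[i] = 1;
      W.quality[i] = draw_quality(rng, P);
      W.age[i] = 1;
    }
  }
}

static List world_to_list(const World& W) {
  const int n = W.side * W.side;
  LogicalMatrix f(W.side, W.side);
  NumericMatrix q(W.side, W.side);
  IntegerMatrix a(W.side, W.side);
  for (int i = 0; i < n; ++i) {
    f[i] = (bool)W.forage[i];
    q[i] = W.quality[i];
    a[i] = W.age[i];
  }
  return List::create(_["is_forage"] = f, _["quality"] = q, _["age"] = a,
                      _["half_extent"] = W.H);
}

static World world_from_list(const List& wl) {
  World W;
  W.H = as<int>(wl["half_extent"]);
  W.side = 2 * W.H + 1;
  LogicalMatrix f = wl["is_forage"];
  NumericMatrix q = wl["quality"];
  IntegerMatrix a = wl["age"];
  const int n = W.side * W.side;
  W.forage.resize(n);
  W.quality.resize(n);
  W.age.resize(n);
  for (int i = 0; i < n; ++i) {
    W.forage[i] = f[i] ? 1 : 0;
    W.quality[i] = q[i];
    W.age[i] = a[i];
  }
  return W;
}

// [[Rcpp::export]]
List cpp_init_world(List params, int seed) {
  Pars P = parse_pars(params);
  Xoshiro rng((uint64_t)seed);
  World W;
  init_world_impl(W, P, rng);
  return world_to_list(W);
}

// [[Rcpp::export]]
List cpp_daily_turnover(List world, List params, int seed) {
  Pars P = parse_pars(params);
  Xoshiro rng((uint64_t)seed);
  World W = world_from_list(world);
  turnover_impl(W, P, rng);
  return world_to_list(W);
}

// ---------------------------------------------------------------------------
// Agents
// ---------------------------------------------------------------------------

enum AgState {
  IDLE = 0,     // in nest: idle scout / waiting or site-holding recruit
  SCOUT = 1,    // Levy search
  TOSITE = 2,   // recruit flying straight to its known site
  FEED = 3,
  RETFULL = 4,  // homing with a load
  RETEMPTY = 5, // homing without a load
  UNLOAD = 6    // in nest, unloading + dance decisions
};

struct Agent {
  uint8_t role;       // 0 scout, 1 recruit
  uint8_t state;
  bool penalty_pending;
  bool visited_today;
  double x, y;
  double hx, hy;      // unit heading
  double leg;         // remaining Levy leg
  int timer;          // feeding / unloading steps remaining
  int site_cell;      // -1 = none
  double site_q;      // mol/l at last visit
  double site_d;      // nest-to-site distance, metres
  int spell_cell;     // tenure bookkeeping
  int spell_days;
};

static void reset_agent(Agent& a, uint8_t role) {
  a.role = role;
  a.state = IDLE;
  a.penalty_pending = false;
  a.visited_today = false;
  a.x = a.y = 0.0;
  a.hx = 1.0; a.hy = 0.0;
  a.leg = 0.0;
  a.timer = 0;
  a.site_cell = -1;
  a.site_q = 0.0;
  a.site_d = 0.0;
  a.spell_cell = -1;
  a.spell_days = 0;
}

// ---------------------------------------------------------------------------
// Simulation run
// ---------------------------------------------------------------------------

struct DayAcc {
  double deliv_scout, deliv_recruit;
  double cost_scout, cost_recruit;
  double penalties;
  int trips_scout, trips_recruit;
  int deaths;
  std::vector<double> trip_d;
  void reset() {
    deliv_scout = deliv_recruit = 0.0;
    cost_scout = cost_recruit = 0.0;
    penalties = 0.0;
    trips_scout = trips_recruit = 0;
    deaths = 0;
    trip_d.clear();
  }
};

struct Sim {
  Pars P;
  World W;
  Xoshiro rng;
  std::vector<Agent> ag;
  std::vector<int> order;
  // influx ring buffer of completed returns
  std::vector<int> ring;
  int ring_pos, ring_sum;
  // mortality: Bernoulli(m) stream over agent-steps, geometric skipping
  long long death_skip;
  DayAcc day;
  std::vector<int> tenures;

  Sim(const Pars& p, uint64_t seed) : P(p), rng(seed) {}

  int n_agents() const { return P.n_scouts + P.n_recruits; }

  long long draw_death_skip() {
    if (P.m <= 0.0) return -1;          // never
    if (P.m >= 1.0) return 0;           // every trial
    double u = rng.unif();
    if (u <= 0.0) u = 1e-300;
    return (long long)std::floor(std::log(u) / std::log1p(-P.m));
  }

  void end_spell(Agent& a) {
    if (a.role == 1 && a.spell_days >= 1) tenures.push_back(a.spell_days);
    a.spell_cell = -1;
    a.spell_days = 0;
  }

  void drop_site(Agent& a) {
    end_spell(a);
    a.site_cell = -1;
    a.site_q = 0.0;
    a.site_d = 0.0;
    a.penalty_pending = false;
  }

  void init() {
    init_world_impl(W, P, rng);
    const int n = n_agents();
    ag.resize(n);
    order.resize(n);
    for (int i = 0; i < n; ++i) {
      reset_agent(ag[i], i < P.n_scouts ? 0 : 1);
      order[i] = i;
    }
    ring.assign(P.influx_window, 0);
    ring_pos = 0;
    ring_sum = 0;
    death_skip = draw_death_skip();
  }

  inline bool window_open(int step) const {
    return step >= P.forage_open && step <= P.forage_close;
  }

  void begin_scouting(Agent& a) {
    a.state = SCOUT;
    a.x = a.y = 0.0;
    new_levy_leg(a);
  }

  void new_levy_leg(Agent& a) {
    const double th = 2.0 * M_PI * rng.unif();
    a.hx = std::cos(th);
    a.hy = std::sin(th);
    a.leg = levy_len(rng, P.mu_levy);
  }

  void head_home(Agent& a, bool loaded) {
    a.state = loaded ? RETFULL : RETEMPTY;
  }

  void start_feeding(Agent& a, int cell, int cx, int cy) {
    a.state = FEED;
    int t = (int)std::lround(P.t_patch_mean + P.t_patch_sd * rng.norm());
    a.timer = t < 1 ? 1 : t;
    a.site_cell = cell;
    a.site_q = W.quality[cell];
    a.site_d = std::sqrt((double)cx * cx + (double)cy * cy) * P.cell_width_m;
    if (a.role == 1) {
      if (a.spell_cell != cell) {
        end_spell(a);
        a.spell_cell = cell;
        a.visited_today = false;
      }
      if (!a.visited_today) {
        a.spell_days += 1;
        a.visited_today = true;
      }
    }
  }

  // reflecting boundary at +/- (H + 0.5)
  inline void reflect(Agent& a) {
    const double lim = (double)W.H + 0.5;
    if (a.x > lim)  { a.x = 2.0 * lim - a.x; a.hx = -a.hx; }
    if (a.x < -lim) { a.x = -2.0 * lim - a.x; a.hx = -a.hx; }
    if (a.y > lim)  { a.y = 2.0 * lim - a.y; a.hy = -a.hy; }
    if (a.y < -lim) { a.y = -2.0 * lim - a.y; a.hy = -a.hy; }
  }

  // one dance performance by `dancer` under condition si
  void dance_once(Agent& dancer, bool si) {
    for (int k = 0; k < P.n_dance; ++k) {
      // uniform pick among waiting recruits (single reservoir pass)
      int pick = -1, seen = 0;
      const int n = n_agents();
      for (int j = 0; j < n; ++j) {
        Agent& b = ag[j];
        if (b.role == 1 && b.state == IDLE && b.site_cell < 0) {
          ++seen;
          if (rng.unif() * seen < 1.0) pick = j;
        }
      }
      if (pick < 0) continue;  // dance happens, nobody follows
      Agent& f = ag[pick];
      if (si) {
        if (rng.unif() < P.p_dance) {
          f.site_cell = dancer.site_cell;
          f.site_q = dancer.site_q;
          f.site_d = dancer.site_d;
          f.penalty_pending = true;
        }
      } else {
        // disoriented dance: activates one recruit to scout, no location
        begin_scouting(f);
      }
    }
  }

  void arrive_nest_full(Agent& a, int step) {
    a.x = a.y = 0.0;
    const double val = trip_value_j(a.site_q, P);
    if (a.role == 0) {
      day.deliv_scout += val;
      day.trips_scout += 1;
    } else {
      day.deliv_recruit += val;
      day.trips_recruit += 1;
    }
    day.trip_d.push_back(a.site_d);
    // record the completed return for influx modulation
    ring[ring_pos] += 1;
    ring_sum += 1;
    a.state = UNLOAD;
    a.timer = P.t_nest;
    (void)step;
  }

  void update_agent(int i, int step, bool si) {
    Agent& a = ag[i];
    switch (a.state) {
      case IDLE: {
        if (window_open(step)) {
          if (a.role == 0) {
            if (rng.unif() < P.p_exit) begin_scouting(a);
          } else if (a.site_cell >= 0) {
            if (rng.unif() < P.p_exit) {
              a.state = TOSITE;
              a.x = a.y = 0.0;
            }
          } else {
            if (rng.unif() < P.p_rs) begin_scouting(a);
          }
        }
        break;
      }
      case SCOUT: {
        if (step > P.forage_close) { head_home(a, false); break; }
        if (a.leg <= 0.0) new_levy_leg(a);
        a.x += P.v * a.hx;
        a.y += P.v * a.hy;
        a.leg -= P.v;
        reflect(a);
        // saltatory search: the searcher cruises along a leg and scans for
        // forage when the leg completes (at the reorientation point)
        if (a.leg <= 0.0) {
          const int cx = cell_coord(a.x), cy = cell_coord(a.y);
          if (cx != 0 || cy != 0) {
            const int cell = W.idx(cx, cy);
            if (W.forage[cell] && rng.unif() < P.p_detect)
              start_feeding(a, cell, cx, cy);
          }
        }
        break;
      }
      case TOSITE: {
        if (step > P.forage_close) { head_home(a, false); break; }
        const int cell = a.site_cell;
        const int cy = cell / W.side - W.H;
        const int cx = cell % W.side - W.H;
        const double dx = (double)cx - a.x, dy = (double)cy - a.y;
        const double dist = std::sqrt(dx * dx + dy * dy);
        if (dist <= P.v) {
          a.x = cx; a.y = cy;
          if (a.penalty_pending) {
            // search penalty for locating a danced-for site in the field
            day.penalties += P.c_recruit;
            a.penalty_pending = false;
          }
          if (W.forage[cell]) {
            start_feeding(a, cell, cx, cy);
          } else {
            drop_site(a);  // patch gone: give up on the site
            head_home(a, false);
          }
        } else {
          a.x += P.v * dx / dist;
          a.y += P.v * dy / dist;
        }
        break;
      }
      case FEED: {
        if (step > P.forage_close) { head_home(a, false); break; }
        if (--a.timer <= 0) head_home(a, true);
        break;
      }
      case RETFULL:
      case RETEMPTY: {
        const double dist = std::sqrt(a.x * a.x + a.y * a.y);
        if (dist <= P.v) {
          if (a.state == RETFULL) {
            arrive_nest_full(a, step);
          } else {
            a.x = a.y = 0.0;
            a.state = IDLE;
          }
        } else {
          a.x -= P.v * a.x / dist;
          a.y -= P.v * a.y / dist;
        }
        break;
      }
      case UNLOAD: {
        if (a.timer > 0) {
          if (step <= P.forage_close) {
            const double pd = dance_prob(a.site_q, a.site_d, P) *
                              influx_factor_c(ring_sum, P);
            if (rng.unif() < pd) dance_once(a, si);
          }
          if (--a.timer <= 0) {
            a.state = IDLE;
            if (a.role == 0) a.site_cell = -1;  // scouts start fresh
          }
        } else {
          a.state = IDLE;
          if (a.role == 0) a.site_cell = -1;
        }
        break;
      }
    }
    // step cost by occupied state (post-transition)
    const uint8_t st = a.state;
    const double cost =
        (st == IDLE || st == UNLOAD) ? P.c_rest : P.c_move;
    if (a.role == 0) day.cost_scout += cost;
    else day.cost_recruit += cost;
  }

  // mortality stream: n trials this step (one Bernoulli(m) per agent, in
  // index order); killed agents are replaced by naive nestmates of the role
  void apply_mortality_trials(long long trials) {
    if (P.m <= 0.0) return;
    long long pos = 0;
    const int n = n_agents();
    while (death_skip >= 0 && pos + death_skip < trials) {
      pos += death_skip;
      const int who = (int)(pos % (long long)n);
      Agent& a = ag[who];
      end_spell(a);
      reset_agent(a, a.role);
      day.deaths += 1;
      pos += 1;
      death_skip = draw_death_skip();
    }
    if (death_skip >= 0) death_skip -= trials - pos;
  }

  void morning_reset() {
    const int n = n_agents();
    for (int i = 0; i < n; ++i) {
      Agent& a = ag[i];
      // everyone overnights in the nest
      if (a.state != IDLE) {
        a.state = IDLE;
        a.x = a.y = 0.0;
        a.timer = 0;
      }
      a.visited_today = false;
      if (a.role == 0) {
        a.site_cell = -1;  // scouts search anew every day
      } else if (a.site_cell >= 0) {
        if (!P.persistent_recruits) {
          drop_site(a);
        } else if (rng.unif() >= return_prob(a.site_q, a.site_d, P)) {
          drop_site(a);  // abandon
        }
      }
    }
  }

  bool all_idle() const {
    const int n = n_agents();
    for (int i = 0; i < n; ++i)
      if (ag[i].state != IDLE) return false;
    return true;
  }

  void run_day(bool si, bool first_day) {
    if (!first_day) turnover_impl(W, P, rng);
    morning_reset();
    day.reset();
    const int n = n_agents();
    for (int step = 0; step < P.t_day; ++step) {
      // quiet phases (before opening, after everyone is home) are pure
      // resting: batch costs and mortality instead of stepping agents
      if ((step < P.forage_open || step > P.forage_close) && all_idle()) {
        int quiet_end =
            step < P.forage_open ? P.forage_open : P.t_day;
        const long long nsteps = quiet_end - step;
        const double c = P.c_rest * (double)nsteps;
        day.cost_scout += c * P.n_scouts;
        day.cost_recruit += c * P.n_recruits;
        apply_mortality_trials(nsteps * (long long)n);
        // influx buffer decays to empty across the gap
        std::fill(ring.begin(), ring.end(), 0);
        ring_sum = 0;
        step = quiet_end - 1;
        continue;
      }
      // slide the influx window
      ring_pos = (ring_pos + 1) % P.influx_window;
      ring_sum -= ring[ring_pos];
      ring[ring_pos] = 0;
      // random update order each step
      for (int k = n - 1; k > 0; --k) {
        const int j = rng.below(k + 1);
        std::swap(order[k], order[j]);
      }
      for (int k = 0; k < n; ++k) update_agent(order[k], step, si);
      apply_mortality_trials(n);
    }
  }
};

// [[Rcpp::export]]
List cpp_run_simulation(List params, IntegerVector schedule, double seed) {
  Pars P = parse_pars(params);
  const int n_days = schedule.size();
  Sim sim(P, (uint64_t)(int64_t)seed);
  sim.init();

  IntegerVector day_out(n_days), cond_out(n_days), trips_s(n_days),
      trips_r(n_days), deaths(n_days), sites_dawn(n_days),
      forage_cells(n_days);
  NumericVector net(n_days), med_d(n_days), dl_s(n_days), dl_r(n_days),
      cost_s(n_days), cost_r(n_days), pen(n_days);

  const int ncell = (2 * P.grid_half_extent + 1) *
                    (2 * P.grid_half_extent + 1);

  for (int d = 0; d < n_days; ++d) {
    const bool si = schedule[d] == 1;
    sim.run_day(si, d == 0);

    day_out[d] = d + 1;
    cond_out[d] = si ? 1 : 0;
    dl_s[d] = sim.day.deliv_scout;
    dl_r[d] = sim.day.deliv_recruit;
    cost_s[d] = sim.day.cost_scout;
    cost_r[d] = sim.day.cost_recruit;
    pen[d] = sim.day.penalties;
    trips_s[d] = sim.day.trips_scout;
    trips_r[d] = sim.day.trips_recruit;
    deaths[d] = sim.day.deaths;
    net[d] = sim.day.deliv_scout + sim.day.deliv_recruit -
             sim.day.cost_scout - sim.day.cost_recruit -
             sim.day.penalties;
    // median completed-trip distance (m); NaN when no trips
    std::vector<double>& td = sim.day.trip_d;
    if (td.empty()) {
      med_d[d] = NA_REAL;
    } else {
      const size_t mid = td.size() / 2;
      std::nth_element(td.begin(), td.begin() + mid, td.end());
      double mval = td[mid];
      if (td.size() % 2 == 0) {
        double lo = *std::max_element(td.begin(), td.begin() + mid);
        mval = 0.5 * (mval + lo);
      }
      med_d[d] = mval;
    }
    int nsites = 0;
    for (size_t i = 0; i < sim.ag.size(); ++i)
      if (sim.ag[i].role == 1 && sim.ag[i].site_cell >= 0) ++nsites;
    sites_dawn[d] = nsites;  // site holders at day end
    int nf = 0;
    for (int i = 0; i < ncell; ++i) nf += sim.W.forage[i];
    forage_cells[d] = nf;
  }

  // close open tenures at run end
  for (size_t i = 0; i < sim.ag.size(); ++i) sim.end_spell(sim.ag[i]);

  DataFrame days = DataFrame::create(
      _["day"] = day_out, _["condition"] = cond_out, _["net_gain"] = net,
      _["median_trip_m"] = med_d, _["trips_scout"] = trips_s,
      _["trips_recruit"] = trips_r, _["deliv_scout"] = dl_s,
      _["deliv_recruit"] = dl_r, _["cost_scout"] = cost_s,
      _["cost_recruit"] = cost_r, _["penalties"] = pen,
      _["deaths"] = deaths, _["recruits_with_site"] = sites_dawn,
      _["forage_cells"] = forage_cells);

  return List::create(_["days"] = days,
                      _["tenures"] = wrap(sim.tenures),
                      _["n_agents"] = sim.n_agents());
}
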