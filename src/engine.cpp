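// Discrete-time lattice engine for the EAE agent simulation.
//
// Five 2-D compartments (CNS, cervical lymph node, circulation, spleen,
// secondary lymphoid organ) carry cells and three scalar fields (type-1
// cytokine, type-2 cytokine, demyelinating agent). Cells are explicit agents
// with population-specific state machines; probabilistic receptor bindings
// between co-located or adjacent cells drive differentiation, killing and
// antigen presentation. All randomness is drawn from R's RNG, so a run is
// fully reproduced by set.seed() before stepping.
//
// Fixed within-step order (determinism contract):
//   1 immunization insertions        5 movement (random walk)
//   2 homeostatic recruitment        6 inter-compartment migration
//   3 per-cell timers/transitions    7 secretion, field diffusion + decay
//   4 binding resolution (shuffled)  8 neuronal death check (evaluated last)
//   9 recording
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

enum Comp { CNS = 0, CLNC = 1, CIRC = 2, SPLEEN = 3, SLO = 4, NCOMP = 5 };
enum Pop  { NEURON = 0, MICROGLIA = 1, DCPOP = 2, TH = 3, TH1 = 4, TH2 = 5,
            TREG4 = 6, TREG8 = 7, NPOP = 8 };
enum TState { NAIVE = 0, PROLIF = 1, EFFECTOR = 2, APOPTOTIC = 3 };
// microglia reuse state: 0 resting, 1 activated

static inline double urand() { return R::unif_rand(); }
static inline double clampnorm(double m, double s) {
  double v = m + s * R::norm_rand();
  return v > 0 ? v : 0;
}
// per-step probability of an event with hazard `rate` per hour
static inline double hz(double rate, double dt) {
  return 1.0 - std::exp(-rate * dt);
}

struct Cell {
  short pop, state, comp;
  short x, y;
  short gens;
  bool mbp;        // DC: presents MHC-II:MBP
  bool tcrpep;     // DC: presents TCR-derived peptide (after phagocytosis)
  bool licensed;   // DC: licensed by effector CD4Treg help
  bool type1pol;   // DC: type-1 polarized (secretes type-1 cytokine)
  bool alive;
  double next_div, qa1_end, life_end, removal_end, state_end;
  Cell() : pop(0), state(0), comp(0), x(0), y(0), gens(0), mbp(false),
           tcrpep(false), licensed(false), type1pol(false), alive(true),
           next_div(-1), qa1_end(-1), life_end(-1), removal_end(-1),
           state_end(-1) {}
};

// forward-Euler 4-neighbour Laplacian; closed (no-flux) walls or toroidal
// wrap; exponential decay applied first. Stability requires D*dt <= 0.25.
static double diffuse_decay_field(std::vector<double>& f, int w, int h,
                                  double D, double lam, double dt, bool tor,
                                  std::vector<double>& buf) {
  double tot = 0.0;
  if (lam > 0) {
    double k = std::exp(-lam * dt);
    for (size_t i = 0; i < f.size(); ++i) f[i] *= k;
  }
  if (D <= 0) {
    for (size_t i = 0; i < f.size(); ++i) tot += f[i];
    return tot;
  }
  buf.assign(f.begin(), f.end());
  double a = D * dt;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int i = y * w + x;
      double c = buf[i], s = 0.0;
      if (tor) {
        s += buf[y * w + (x + 1) % w] - c;
        s += buf[y * w + (x + w - 1) % w] - c;
        s += buf[((y + 1) % h) * w + x] - c;
        s += buf[((y + h - 1) % h) * w + x] - c;
      } else {
        if (x + 1 < w) s += buf[i + 1] - c;
        if (x > 0)     s += buf[i - 1] - c;
        if (y + 1 < h) s += buf[i + w] - c;
        if (y > 0)     s += buf[i - w] - c;
      }
      f[i] = c + a * s;
      tot += f[i];
    }
  }
  return tot;
}

struct Pending { double due; short x, y; };

class World {
public:
  // --- configuration (cached from the R-side config list) ---
  double dt, horizon_h;
  long n_steps, rec_every;
  int W[NCOMP], H[NCOMP];
  bool toroidal_circ, splenectomy, demyel_direct, acd3_blocks_qa1;
  double motility;
  double D_cyt, D_dem, lam1, lam2, lamd;
  double dc_life_mean, dc_life_sd;
  double n_neurons, kill_thresh, kill_rate, neuron_delay;
  double n_microglia, mg_active_h, dem_secrete;
  double n_cns_dc, cns_dc_mig, cns_dc_delay, n_spleen_dc, n_cln_dc;
  double ag_dc_life;
  double th_target, t4_target, t8_target, recruit_rate;
  double p_th_prime, div_h, th_div, t4_div, t8_div;
  double aicd_mean, aicd_sd, removal_h;
  double qa1_mean, qa1_sd, p_qa1_bind, reg_eff;
  double p_t4_prime, p_t8_prime, p_license, p_phago, p_mg_bind;
  double pol_thresh, s_th1, s_th2, s_dc1, s_bas2;
  double naive_exit, eff_exit, to_spleen, to_cln, to_slo, cns_entry, treg_cns;
  double bbb_base, bbb_half, treg_ly_fac;
  double acd3_eff, acd3_admin_h;
  std::vector<double> ins_t;   // immunization insertion times (h)
  std::vector<int> ins_n;      //   and counts

  // --- state ---
  double t;
  long step_idx;
  std::vector<Cell> cells;
  std::vector<double> fld[NCOMP][3];
  std::vector<Pending> neuron_queue, cnsdc_queue;
  size_t ins_ptr;

  // --- instrumentation / outputs ---
  std::vector<double> death_times;
  double prim4[NCOMP], prim8[NCOMP];
  long kills_cd8, kills_expired_qa1;
  long kills_comp[NCOMP];
  long th1_minted;
  double kill_age_sum;
  long tcr_attempts, tcr_success, tcr_attempts_post, tcr_success_post;
  long births, removals, migrations;
  long max_spleen_occ;
  std::vector<double> rec_t;
  std::vector<int> rec_counts;       // n_rec * (NCOMP*NPOP), row-major
  std::vector<double> rec_mass;      // n_rec * (NCOMP*3)

  // scratch
  std::vector<std::vector<int> > occ[NCOMP];
  std::vector<double> buf;
  int cnt[NCOMP][NPOP][4];
  int n_mbp_dc[NCOMP], n_tcrpep_dc[NCOMP], n_lic_dc[NCOMP],
      n_qa1_th1[NCOMP], n_apop_th1[NCOMP], n_plain_dc[NCOMP];
  int naive_global[NPOP];
  bool field_active[NCOMP][3];

  World(List cfg) { init(cfg); }

  double need(List& cfg, const char* k) {
    if (!cfg.containsElementNamed(k)) stop("engine config missing '%s'", k);
    return as<double>(cfg[k]);
  }

  void init(List cfg) {
    dt = need(cfg, "dt_min") / 60.0;
    horizon_h = need(cfg, "horizon_d") * 24.0;
    n_steps = (long)std::lround(horizon_h / dt);
    rec_every = std::max(1L, (long)std::lround(need(cfg, "record_interval_h") / dt));
    int g[5] = {(int)need(cfg, "cns_grid"), (int)need(cfg, "cln_grid"),
                (int)need(cfg, "circ_grid"), (int)need(cfg, "spleen_grid"),
                (int)need(cfg, "slo_grid")};
    for (int c = 0; c < NCOMP; ++c) { W[c] = g[c]; H[c] = g[c]; }
    toroidal_circ = need(cfg, "toroidal_circulation") > 0.5;
    motility = need(cfg, "cell_motility");
    D_cyt = need(cfg, "cytokine_diffusion_grid2_h");
    D_dem = need(cfg, "demyel_diffusion_grid2_h");
    lam1 = need(cfg, "type1_decay_per_h");
    lam2 = need(cfg, "type2_decay_per_h");
    lamd = need(cfg, "demyel_decay_per_h");
    if (D_cyt * dt > 0.25 || D_dem * dt > 0.25)
      stop("diffusion scheme unstable: D*dt must be <= 0.25");
    dc_life_mean = need(cfg, "dc_lifespan_mean_h");
    dc_life_sd = need(cfg, "dc_lifespan_sd_h");
    n_neurons = need(cfg, "n_neurons");
    kill_thresh = need(cfg, "neuron_kill_threshold");
    kill_rate = need(cfg, "neuron_kill_per_h");
    neuron_delay = need(cfg, "neuron_replace_delay_h");
    n_microglia = need(cfg, "n_microglia");
    mg_active_h = need(cfg, "microglia_active_h");
    dem_secrete = need(cfg, "demyel_secretion_per_h");
    n_cns_dc = need(cfg, "n_cns_dc");
    ag_dc_life = need(cfg, "antigen_dc_lifespan_h");
    cns_dc_mig = need(cfg, "cns_dc_migration_per_h");
    cns_dc_delay = need(cfg, "cns_dc_replace_delay_h");
    n_spleen_dc = need(cfg, "n_splenic_dc");
    n_cln_dc = need(cfg, "n_cln_dc");
    th_target = need(cfg, "th_naive_target");
    t4_target = need(cfg, "treg4_naive_target");
    t8_target = need(cfg, "treg8_naive_target");
    recruit_rate = need(cfg, "recruit_per_h");
    p_th_prime = need(cfg, "th_prime_per_h");
    div_h = need(cfg, "division_interval_h");
    th_div = need(cfg, "th_divisions");
    t4_div = need(cfg, "treg4_divisions");
    t8_div = need(cfg, "treg8_divisions");
    aicd_mean = need(cfg, "tcell_aicd_mean_h");
    aicd_sd = need(cfg, "tcell_aicd_sd_h");
    removal_h = need(cfg, "apoptotic_removal_h");
    qa1_mean = need(cfg, "qa1_duration_mean_h");
    qa1_sd = need(cfg, "qa1_duration_sd_h");
    p_qa1_bind = need(cfg, "qa1_bind_per_h");
    reg_eff = need(cfg, "regulatory_efficacy");
    p_t4_prime = need(cfg, "treg4_prime_per_h");
    p_t8_prime = need(cfg, "treg8_prime_per_h");
    p_license = need(cfg, "license_per_h");
    p_phago = need(cfg, "phagocytosis_per_h");
    p_mg_bind = need(cfg, "th1_microglia_bind_per_h");
    pol_thresh = need(cfg, "polarization_ratio_threshold");
    s_th1 = need(cfg, "type1_secretion_per_h");
    s_th2 = need(cfg, "type2_secretion_per_h");
    s_dc1 = need(cfg, "dc_type1_secretion_per_h");
    s_bas2 = need(cfg, "basal_type2_per_h");
    demyel_direct = need(cfg, "demyel_source_direct") > 0.5;
    naive_exit = need(cfg, "naive_exit_per_h");
    eff_exit = need(cfg, "effector_exit_per_h");
    to_spleen = need(cfg, "circ_to_spleen_per_h");
    to_cln = need(cfg, "circ_to_cln_per_h");
    to_slo = need(cfg, "circ_to_slo_per_h");
    cns_entry = need(cfg, "effector_cns_entry_per_h");
    treg_cns = need(cfg, "treg_cns_entry_per_h");
    bbb_base = need(cfg, "bbb_base_frac");
    bbb_half = need(cfg, "bbb_halfmax_microglia");
    treg_ly_fac = need(cfg, "treg_lymphoid_entry_factor");
    splenectomy = need(cfg, "splenectomy") > 0.5;
    acd3_eff = need(cfg, "anti_cd3_efficacy");
    double ad = need(cfg, "anti_cd3_admin_d");
    acd3_admin_h = ad < 0 ? -1.0 : ad * 24.0;
    acd3_blocks_qa1 = need(cfg, "anti_cd3_blocks_qa1") > 0.5;
    ins_t = as<std::vector<double> >(cfg["imm_insertion_t_h"]);
    {
      std::vector<double> nn = as<std::vector<double> >(cfg["imm_insertion_count"]);
      ins_n.assign(nn.begin(), nn.end());
    }

    t = 0.0;
    step_idx = 0;
    ins_ptr = 0;
    for (int c = 0; c < NCOMP; ++c) {
      for (int k = 0; k < 3; ++k) fld[c][k].assign((size_t)W[c] * H[c], 0.0);
      occ[c].assign((size_t)W[c] * H[c], std::vector<int>());
      prim4[c] = prim8[c] = 0;
    }
    kills_cd8 = kills_expired_qa1 = 0;
    for (int c = 0; c < NCOMP; ++c) kills_comp[c] = 0;
    th1_minted = 0; kill_age_sum = 0;
    tcr_attempts = tcr_success = tcr_attempts_post = tcr_success_post = 0;
    births = removals = migrations = 0;
    max_spleen_occ = 0;
    for (int c = 0; c < NCOMP; ++c)
      for (int k = 0; k < 3; ++k) field_active[c][k] = false;

    seed_residents();
  }

  int rint(int n) { // uniform integer in [0, n)
    int v = (int)(urand() * n);
    return v >= n ? n - 1 : v;
  }

  Cell& add_cell(int pop, int state, int comp) {
    cells.push_back(Cell());
    Cell& c = cells.back();
    c.pop = pop; c.state = state; c.comp = comp;
    // prefer a free grid-space; fall back to any
    for (int tries = 0; tries < 8; ++tries) {
      c.x = rint(W[comp]); c.y = rint(H[comp]);
      if (occ[comp][c.y * W[comp] + c.x].empty()) break;
    }
    ++births;
    return c;
  }

  void seed_residents() {
    for (int i = 0; i < (int)n_neurons; ++i) add_cell(NEURON, 0, CNS);
    for (int i = 0; i < (int)n_microglia; ++i) add_cell(MICROGLIA, 0, CNS);
    for (int i = 0; i < (int)n_cns_dc; ++i) new_dc(CNS, false, false);
    if (!splenectomy)
      for (int i = 0; i < (int)n_spleen_dc; ++i) new_dc(SPLEEN, false, false);
    for (int i = 0; i < (int)n_cln_dc; ++i) new_dc(CLNC, false, false);
    int lymph[3] = {CLNC, SPLEEN, SLO};
    for (int k = 0; k < 3; ++k) {
      int c = lymph[k];
      if (splenectomy && c == SPLEEN) continue;
      for (int i = 0; i < (int)th_target; ++i) add_cell(TH, NAIVE, c);
      for (int i = 0; i < (int)t4_target; ++i) add_cell(TREG4, NAIVE, c);
      for (int i = 0; i < (int)t8_target; ++i) add_cell(TREG8, NAIVE, c);
    }
    births = 0;  // initial residents are the t=0 state, not births
  }

  void new_dc(int comp, bool immunization, bool type1) {
    Cell& d = add_cell(DCPOP, 0, comp);
    d.mbp = immunization;
    d.type1pol = type1;
    d.life_end = t + clampnorm(dc_life_mean, dc_life_sd);
  }

  // anti-CD3 multiplicative factor on all T-cell TCR binding probabilities
  double acd3_factor() {
    if (acd3_admin_h >= 0 && t >= acd3_admin_h) return 1.0 - acd3_eff;
    return 1.0;
  }

  // --- step phases -------------------------------------------------------

  void phase_insertions() {
    while (ins_ptr < ins_t.size() && ins_t[ins_ptr] <= t + 1e-9) {
      for (int i = 0; i < ins_n[ins_ptr]; ++i) new_dc(SLO, true, true);
      ++ins_ptr;
    }
  }

  void rebuild_occupancy() {
    for (int c = 0; c < NCOMP; ++c)
      for (size_t i = 0; i < occ[c].size(); ++i) occ[c][i].clear();
    std::memset(cnt, 0, sizeof(cnt));
    for (int c = 0; c < NCOMP; ++c)
      n_mbp_dc[c] = n_tcrpep_dc[c] = n_lic_dc[c] = n_qa1_th1[c] =
        n_apop_th1[c] = n_plain_dc[c] = 0;
    for (int p = 0; p < NPOP; ++p) naive_global[p] = 0;
    for (int i = 0; i < (int)cells.size(); ++i) {
      Cell& c = cells[i];
      if (!c.alive) continue;
      occ[c.comp][c.y * W[c.comp] + c.x].push_back(i);
      cnt[c.comp][c.pop][c.state]++;
      if (c.state == NAIVE && c.pop >= TH) naive_global[c.pop]++;
      if (c.pop == DCPOP) {
        if (c.mbp) n_mbp_dc[c.comp]++; else n_plain_dc[c.comp]++;
        if (c.tcrpep) n_tcrpep_dc[c.comp]++;
        if (c.tcrpep && c.licensed) n_lic_dc[c.comp]++;
      } else if (c.pop == TH1) {
        if (c.state == EFFECTOR && c.qa1_end > t) n_qa1_th1[c.comp]++;
        if (c.state == APOPTOTIC) n_apop_th1[c.comp]++;
      }
    }
  }

  void phase_recruitment() {
    // homeostasis of the whole recirculating naive pool: targets are
    // per-organ, the census is global (an organ does not re-recruit for
    // residents that are merely transiting the circulation)
    int lymph[3] = {CLNC, SPLEEN, SLO};
    int n_org = splenectomy ? 2 : 3;
    for (int k = 0; k < 3; ++k) {
      int c = lymph[k];
      if (splenectomy && c == SPLEEN) continue;
      refill(TH, c, n_org * th_target);
      refill(TREG4, c, n_org * t4_target);
      refill(TREG8, c, n_org * t8_target);
    }
    // resident DC homeostasis (plain, non-presenting DCs only)
    refill_dc(CLNC, n_cln_dc);
    refill_dc(CNS, n_cns_dc);
    if (!splenectomy) refill_dc(SPLEEN, n_spleen_dc);
    // due neuron / CNS-DC replacements
    flush_queue(neuron_queue, NEURON);
    flush_queue(cnsdc_queue, DCPOP);
  }

  void refill(int pop, int comp, double global_target) {
    int deficit = (int)global_target - naive_global[pop];
    if (deficit <= 0) return;
    int n = (int)R::rpois(recruit_rate * dt);
    if (n > deficit) n = deficit;
    for (int i = 0; i < n; ++i) {
      add_cell(pop, NAIVE, comp);
      naive_global[pop] += 1;
    }
  }

  void refill_dc(int comp, double target) {
    int deficit = (int)target - n_plain_dc[comp];
    if (deficit <= 0) return;
    int n = (int)R::rpois(recruit_rate * dt);
    if (n > deficit) n = deficit;
    for (int i = 0; i < n; ++i) new_dc(comp, false, false);
  }

  void flush_queue(std::vector<Pending>& q, int pop) {
    for (size_t i = 0; i < q.size();) {
      if (q[i].due <= t) {
        if (pop == NEURON) {
          Cell& c = add_cell(NEURON, 0, CNS);
          c.x = q[i].x; c.y = q[i].y;
        } else {
          new_dc(CNS, false, false);
        }
        q[i] = q.back();
        q.pop_back();
      } else {
        ++i;
      }
    }
  }

  void become_effector(Cell& c) {
    c.state = EFFECTOR;
    c.life_end = t + clampnorm(aicd_mean, aicd_sd);
    if (c.pop == TH1) {
      c.qa1_end = t + clampnorm(qa1_mean, qa1_sd);
      if (c.qa1_end > t) n_qa1_th1[c.comp]++;
      ++th1_minted;
      c.state_end = t;   // records differentiation time for instrumentation
    }
  }

  void phase_timers() {
    int n0 = (int)cells.size();  // daughters appended this step divide later
    for (int i = 0; i < n0; ++i) {
      Cell& c = cells[i];
      if (!c.alive) continue;
      switch (c.pop) {
      case MICROGLIA:
        if (c.state == 1 && t >= c.state_end) c.state = 0;
        break;
      case DCPOP:
        if (c.life_end >= 0 && t >= c.life_end) kill(c);
        break;
      case TH1: case TH2: case TREG4: case TREG8:
        if (c.state == PROLIF && t >= c.next_div) {
          if (c.gens > 0) {
            cells.push_back(cells[i]);       // may invalidate reference
            Cell& p = cells[i];
            Cell& d = cells.back();
            ++births;
            p.gens--; d.gens--;
            p.next_div = d.next_div = t + div_h;
            if (p.gens <= 0) { become_effector(p); become_effector(d); }
          } else {
            become_effector(cells[i]);
          }
        } else if (c.state == EFFECTOR && t >= c.life_end) {
          c.state = APOPTOTIC;               // activation-induced cell death
          c.removal_end = t + removal_h;
          if (c.pop == TH1) n_apop_th1[c.comp]++;
        } else if (c.state == APOPTOTIC && t >= c.removal_end) {
          kill(c);
        }
        break;
      default: break;
      }
    }
  }

  void kill(Cell& c) {
    if (!c.alive) return;
    c.alive = false;
    ++removals;
  }

  // iterate partners in the Moore neighbourhood (same or adjacent grid-space)
  template <class F>
  void for_neighbours(const Cell& a, F f) {
    int comp = a.comp, w = W[comp], h = H[comp];
    bool tor = toroidal_circ && comp == CIRC;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int x = a.x + dx, y = a.y + dy;
        if (tor) { x = (x + w) % w; y = (y + h) % h; }
        else if (x < 0 || x >= w || y < 0 || y >= h) continue;
        std::vector<int>& v = occ[comp][y * w + x];
        for (size_t k = 0; k < v.size(); ++k)
          if (!f(v[k])) return;
      }
    }
  }

  bool tcr_attempt(double prob) {
    double f = acd3_factor();
    bool post = acd3_admin_h >= 0 && t >= acd3_admin_h;
    ++tcr_attempts;
    if (post) ++tcr_attempts_post;
    bool ok = urand() < prob * f;
    if (ok) { ++tcr_success; if (post) ++tcr_success_post; }
    return ok;
  }

  void phase_binding() {
    // shuffled iteration order, drawn from the run's RNG stream
    std::vector<int> order(cells.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = rint(i + 1);
      std::swap(order[i], order[j]);
    }
    double p_prime = hz(p_th_prime, dt), p_t4 = hz(p_t4_prime, dt),
           p_t8 = hz(p_t8_prime, dt), p_lic = hz(p_license, dt),
           p_qa1 = hz(p_qa1_bind, dt), p_ph = hz(p_phago, dt),
           p_mg = hz(p_mg_bind, dt);
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      Cell& a = cells[i];
      if (!a.alive) continue;
      int comp = a.comp;
      if (a.pop == TH && a.state == NAIVE && n_mbp_dc[comp] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == DCPOP && d.mbp && tcr_attempt(p_prime)) {
            // polarization by local type-1 : type-2 ratio at the DC site
            size_t s = (size_t)d.y * W[comp] + d.x;
            double c1 = fld[comp][0][s], c2 = fld[comp][1][s];
            a.pop = (c1 >= pol_thresh * c2) ? TH1 : TH2;  // ties favour Th1
            a.state = PROLIF;
            a.gens = (short)th_div;
            a.next_div = t + div_h;
            if (a.gens <= 0) become_effector(a);
            return false;
          }
          return true;
        });
      } else if (a.pop == TREG4 && a.state == NAIVE && n_tcrpep_dc[comp] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == DCPOP && d.tcrpep && tcr_attempt(p_t4)) {
            a.state = PROLIF; a.gens = (short)t4_div; a.next_div = t + div_h;
            if (a.gens <= 0) become_effector(a);
            prim4[comp] += 1;
            return false;
          }
          return true;
        });
      } else if (a.pop == TREG4 && a.state == EFFECTOR &&
                 n_tcrpep_dc[comp] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == DCPOP && d.tcrpep && !d.licensed &&
              tcr_attempt(p_lic)) {
            d.licensed = true;
            n_lic_dc[comp]++;
            return false;
          }
          return true;
        });
      } else if (a.pop == TREG8 && a.state == NAIVE && n_lic_dc[comp] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == DCPOP && d.tcrpep && d.licensed &&
              tcr_attempt(p_t8)) {
            a.state = PROLIF; a.gens = (short)t8_div; a.next_div = t + div_h;
            if (a.gens <= 0) become_effector(a);
            prim8[comp] += 1;
            return false;
          }
          return true;
        });
      } else if (a.pop == TREG8 && a.state == EFFECTOR &&
                 n_qa1_th1[comp] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == TH1 && d.state == EFFECTOR &&
              d.qa1_end > t) {
            bool bound = acd3_blocks_qa1 ? tcr_attempt(p_qa1)
                                         : (urand() < p_qa1);
            if (bound) {
              if (d.qa1_end <= t) ++kills_expired_qa1;  // contract guard
              if (urand() < reg_eff) {
                d.state = APOPTOTIC;
                d.removal_end = t + removal_h;
                n_qa1_th1[comp]--;
                n_apop_th1[comp]++;
                ++kills_cd8;
                kills_comp[comp]++;
                kill_age_sum += t - d.state_end;
              }
              return false;
            }
          }
          return true;
        });
      } else if (a.pop == TH1 && a.state == EFFECTOR && comp == CNS &&
                 !demyel_direct && cnt[CNS][MICROGLIA][0] > 0) {
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == MICROGLIA && d.state == 0 &&
              tcr_attempt(p_mg)) {
            d.state = 1;
            d.state_end = t + mg_active_h;
            cnt[CNS][MICROGLIA][0]--;
            return false;
          }
          return true;
        });
      } else if (a.pop == DCPOP && n_apop_th1[comp] > 0 && !a.tcrpep &&
                 !a.mbp) {  // committed MBP-presenting DCs do not re-present
        for_neighbours(a, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == TH1 && d.state == APOPTOTIC &&
              urand() < p_ph) {   // phagocytosis is not a TCR binding
            kill(d);
            n_apop_th1[comp]--;
            a.tcrpep = true;
            if (a.licensed) n_lic_dc[comp]++;
            n_tcrpep_dc[comp]++;
            return false;
          }
          return true;
        });
      }
    }
  }

  void phase_movement() {
    static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    for (size_t i = 0; i < cells.size(); ++i) {
      Cell& c = cells[i];
      if (!c.alive) continue;
      if (c.pop == NEURON || c.pop == MICROGLIA) continue;  // immobile
      if (c.state == APOPTOTIC) continue;
      if (motility < 1.0 && urand() >= motility) continue;
      int k = rint(8);
      int w = W[c.comp], h = H[c.comp];
      int x = c.x + DX[k], y = c.y + DY[k];
      if (toroidal_circ && c.comp == CIRC) {
        x = (x + w) % w; y = (y + h) % h;
      } else if (x < 0 || x >= w || y < 0 || y >= h) {
        continue;  // closed wall: stay
      }
      c.x = (short)x; c.y = (short)y;
    }
  }

  void place(Cell& c, int comp) {
    c.comp = (short)comp;
    c.x = (short)rint(W[comp]);
    c.y = (short)rint(H[comp]);
    ++migrations;
  }

  void phase_migration() {
    double pe_naive = hz(naive_exit, dt), pe_eff = hz(eff_exit, dt);
    double p_sp = hz(to_spleen, dt), p_cl = hz(to_cln, dt), p_sl = hz(to_slo, dt);
    // blood-brain barrier permeability ramps with CNS inflammation
    // (activated microglia); naive barrier admits only a basal fraction
    double act = (double)cnt[CNS][MICROGLIA][1];
    double gate = bbb_base + (1.0 - bbb_base) * act / (act + bbb_half);
    double p_cns_eff = hz(cns_entry, dt) * gate;
    double p_cns_treg = hz(treg_cns, dt) * gate;
    double p_dcmig = hz(cns_dc_mig, dt);
    for (size_t i = 0; i < cells.size(); ++i) {
      Cell& c = cells[i];
      if (!c.alive || c.pop == NEURON || c.pop == MICROGLIA) continue;
      if (c.state == PROLIF || c.state == APOPTOTIC) continue;
      if (c.pop == DCPOP) {
        // antigen-bearing CNS DCs drain to the cervical lymph node
        if (c.comp == CNS && c.mbp && urand() < p_dcmig) {
          place(c, CLNC);
          cnsdc_queue.push_back(Pending{t + cns_dc_delay, 0, 0});
        }
        continue;  // other DCs are sessile residents
      }
      // T cells
      if (c.comp == CIRC) {
        double u = urand();
        bool eff = c.state == EFFECTOR;
        // effector Tregs patrol the blood and spleen; they re-enter lymph
        // nodes only rarely, so their quarry meets them in transit
        bool treg_eff = eff && (c.pop == TREG4 || c.pop == TREG8);
        double fac = treg_eff ? treg_ly_fac : 1.0;
        double acc = p_sp;
        if (u < acc) { enter(c, SPLEEN); continue; }
        acc += p_cl * fac;
        if (u < acc) { enter(c, CLNC); continue; }
        acc += p_sl * fac;
        if (u < acc) { enter(c, SLO); continue; }
        if (eff) {
          double pc = (c.pop == TH1 || c.pop == TH2) ? p_cns_eff : p_cns_treg;
          acc += pc;
          if (u < acc) { enter(c, CNS); continue; }
        }
      } else {
        double pe = (c.state == EFFECTOR) ? pe_eff : pe_naive;
        if (urand() < pe) place(c, CIRC);
      }
    }
  }

  void enter(Cell& c, int comp) {
    // zero-capacity splenectomy-spleen: entrants forward straight back to
    // the circulation within the same step
    if (comp == SPLEEN && splenectomy) { place(c, CIRC); return; }
    if (comp == CNS && c.pop != TH1 && c.pop != TH2 && c.pop != TREG4 &&
        c.pop != TREG8) return;
    place(c, comp);
  }

  void phase_fields() {
    // secretion
    for (size_t i = 0; i < cells.size(); ++i) {
      Cell& c = cells[i];
      if (!c.alive) continue;
      size_t s = (size_t)c.y * W[c.comp] + c.x;
      if (c.pop == TH1 && c.state == EFFECTOR) {
        fld[c.comp][0][s] += s_th1 * dt;
        field_active[c.comp][0] = true;
        if (demyel_direct && c.comp == CNS) {
          fld[CNS][2][s] += dem_secrete * dt;
          field_active[CNS][2] = true;
        }
      } else if (c.pop == TH2 && c.state == EFFECTOR) {
        fld[c.comp][1][s] += s_th2 * dt;
        field_active[c.comp][1] = true;
      } else if (c.pop == DCPOP && c.type1pol) {
        fld[c.comp][0][s] += s_dc1 * dt;
        field_active[c.comp][0] = true;
      } else if (c.pop == MICROGLIA && c.state == 1 && !demyel_direct) {
        fld[CNS][2][s] += dem_secrete * dt;
        field_active[CNS][2] = true;
      }
    }
    // basal type-2 tone in lymphoid organs
    if (s_bas2 > 0) {
      int lymph[3] = {CLNC, SPLEEN, SLO};
      double inc = s_bas2 * dt;
      for (int k = 0; k < 3; ++k) {
        std::vector<double>& f = fld[lymph[k]][1];
        for (size_t i = 0; i < f.size(); ++i) f[i] += inc;
        field_active[lymph[k]][1] = true;
      }
    }
    // diffusion + decay; untouched all-zero fields are skipped
    double lam[3] = {lam1, lam2, lamd};
    for (int c = 0; c < NCOMP; ++c) {
      bool tor = toroidal_circ && c == CIRC;
      for (int k = 0; k < 3; ++k) {
        if (!field_active[c][k]) continue;
        double D = (k == 2) ? D_dem : D_cyt;
        double tot = diffuse_decay_field(fld[c][k], W[c], H[c], D, lam[k],
                                         dt, tor, buf);
        if (tot < 1e-12) {
          std::fill(fld[c][k].begin(), fld[c][k].end(), 0.0);
          field_active[c][k] = false;
        }
      }
    }
  }

  void phase_neurons() {
    std::vector<double>& dem = fld[CNS][2];
    double p_kill = hz(kill_rate, dt);
    for (size_t i = 0; i < cells.size(); ++i) {
      Cell& c = cells[i];
      if (!c.alive || c.pop != NEURON) continue;
      size_t s = (size_t)c.y * W[CNS] + c.x;
      // above-threshold concentrations are lethal with a finite hazard
      if (dem[s] >= kill_thresh && urand() < p_kill) {
        death_times.push_back(t);
        // replacement delay is jittered to avoid synchronized regrowth
        neuron_queue.push_back(
          Pending{t + clampnorm(neuron_delay, neuron_delay / 3.0), c.x, c.y});
        // myelin antigen uptake by nearby resident CNS dendritic cells
        for_neighbours(c, [&](int j) {
          Cell& d = cells[j];
          if (d.alive && d.pop == DCPOP && !d.mbp) {
            d.mbp = true;
            d.type1pol = true;   // inflammatory context: type-1 polarizing
            // activated antigen-bearing DCs are short-lived
            double le = t + clampnorm(ag_dc_life, ag_dc_life / 4.0);
            if (d.life_end < 0 || le < d.life_end) d.life_end = le;
          }
          return true;
        });
        kill(c);
      }
    }
  }

  void compact_and_tally() {
    size_t w = 0;
    long spleen_occ = 0;
    for (size_t i = 0; i < cells.size(); ++i) {
      if (cells[i].alive) {
        if (cells[i].comp == SPLEEN) ++spleen_occ;
        if (w != i) cells[w] = cells[i];
        ++w;
      }
    }
    cells.resize(w);
    if (spleen_occ > max_spleen_occ) max_spleen_occ = spleen_occ;
  }

  void record() {
    rec_t.push_back(t);
    int counts[NCOMP][NPOP];
    std::memset(counts, 0, sizeof(counts));
    for (size_t i = 0; i < cells.size(); ++i) {
      Cell& c = cells[i];
      if (c.alive) counts[c.comp][c.pop]++;
    }
    for (int c = 0; c < NCOMP; ++c)
      for (int p = 0; p < NPOP; ++p) rec_counts.push_back(counts[c][p]);
    for (int c = 0; c < NCOMP; ++c)
      for (int k = 0; k < 3; ++k) {
        double m = 0;
        for (size_t i = 0; i < fld[c][k].size(); ++i) m += fld[c][k][i];
        rec_mass.push_back(m);
      }
  }

  void step() {
    if (step_idx >= n_steps)
      stop("run terminated: stepping past the configured horizon");
    phase_insertions();
    rebuild_occupancy();
    phase_recruitment();
    phase_timers();
    phase_binding();   // occupancy from this step's rebuild
    phase_movement();
    phase_migration();
    phase_fields();
    phase_neurons();
    compact_and_tally();
    ++step_idx;
    t = step_idx * dt;
    if (step_idx % rec_every == 0 || step_idx == n_steps) record();
  }

  List results() {
    int n_rec = (int)rec_t.size();
    IntegerMatrix counts(n_rec, NCOMP * NPOP);
    for (int r = 0; r < n_rec; ++r)
      for (int j = 0; j < NCOMP * NPOP; ++j)
        counts(r, j) = rec_counts[(size_t)r * NCOMP * NPOP + j];
    NumericMatrix mass(n_rec, NCOMP * 3);
    for (int r = 0; r < n_rec; ++r)
      for (int j = 0; j < NCOMP * 3; ++j)
        mass(r, j) = rec_mass[(size_t)r * NCOMP * 3 + j];
    NumericMatrix prim(2, NCOMP);
    for (int c = 0; c < NCOMP; ++c) { prim(0, c) = prim4[c]; prim(1, c) = prim8[c]; }
    return List::create(
      _["t_h"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["counts"] = counts,
      _["field_mass"] = mass,
      _["death_times_h"] = NumericVector(death_times.begin(), death_times.end()),
      _["priming"] = prim,
      _["counters"] = List::create(
        _["kills_cd8"] = (double)kills_cd8,
        _["kills_expired_qa1"] = (double)kills_expired_qa1,
        _["tcr_attempts"] = (double)tcr_attempts,
        _["tcr_success"] = (double)tcr_success,
        _["tcr_attempts_post_admin"] = (double)tcr_attempts_post,
        _["tcr_success_post_admin"] = (double)tcr_success_post,
        _["births"] = (double)births,
        _["removals"] = (double)removals,
        _["migrations"] = (double)migrations,
        _["max_spleen_occupancy"] = (double)max_spleen_occ,
        _["th1_minted"] = (double)th1_minted,
        _["mean_kill_age_h"] = kills_cd8 ? kill_age_sum / kills_cd8 : NA_REAL,
        _["kills_by_comp"] = NumericVector::create(
          (double)kills_comp[0], (double)kills_comp[1], (double)kills_comp[2],
          (double)kills_comp[3], (double)kills_comp[4])));
  }
};

// [[Rcpp::export]]
SEXP cpp_world_create(List cfg) {
  XPtr<World> p(new World(cfg), true);
  return p;
}

// [[Rcpp::export]]
void cpp_world_step(SEXP wp, int n = 1) {
  XPtr<World> w(wp);
  for (int i = 0; i < n; ++i) w->step();
}

// [[Rcpp::export]]
List cpp_world_time(SEXP wp) {
  XPtr<World> w(wp);
  return List::create(_["step_index"] = (double)w->step_idx,
                      _["t_h"] = w->t, _["dt_h"] = w->dt,
                      _["n_steps"] = (double)w->n_steps);
}

// [[Rcpp::export]]
DataFrame cpp_world_cells(SEXP wp) {
  XPtr<World> w(wp);
  int n = (int)w->cells.size();
  IntegerVector pop(n), state(n), comp(n), x(n), y(n), gens(n);
  LogicalVector mbp(n), tcrpep(n), licensed(n), qa1(n);
  for (int i = 0; i < n; ++i) {
    Cell& c = w->cells[i];
    pop[i] = c.pop; state[i] = c.state; comp[i] = c.comp;
    x[i] = c.x; y[i] = c.y; gens[i] = c.gens;
    mbp[i] = c.mbp; tcrpep[i] = c.tcrpep; licensed[i] = c.licensed;
    qa1[i] = c.pop == TH1 && c.state == EFFECTOR && c.qa1_end > w->t;
  }
  return DataFrame::create(_["pop"] = pop, _["state"] = state,
                           _["comp"] = comp, _["x"] = x, _["y"] = y,
                           _["gens"] = gens, _["mbp"] = mbp,
                           _["tcrpep"] = tcrpep, _["licensed"] = licensed,
                           _["qa1_active"] = qa1);
}

// [[Rcpp::export]]
NumericMatrix cpp_world_field(SEXP wp, int comp, int field) {
  XPtr<World> w(wp);
  if (comp < 0 || comp >= NCOMP || field < 0 || field > 2)
    stop("invalid compartment or field index");
  NumericMatrix out(w->H[comp], w->W[comp]);
  for (int y = 0; y < w->H[comp]; ++y)
    for (int x = 0; x < w->W[comp]; ++x)
      out(y, x) = w->fld[comp][field][(size_t)y * w->W[comp] + x];
  return out;
}

// [[Rcpp::export]]
List cpp_world_results(SEXP wp) {
  XPtr<World> w(wp);
  return w->results();
}

// [[Rcpp::export]]
List cpp_world_run(List cfg) {
  World w(cfg);
  w.record();  // t = 0 snapshot
  while (w.step_idx < w.n_steps) w.step();
  return w.results();
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_decay(NumericMatrix field, double D, double lambda,
                                double dt, bool toroidal = false) {
  if (lambda < 0) stop("decay rate must be >= 0");
  int h = field.nrow(), w = field.ncol();
  std::vector<double> f((size_t)w * h), buf;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double v = field(y, x);
      if (v < 0 || !R_finite(v)) stop("field values must be finite and >= 0");
      f[(size_t)y * w + x] = v;
    }
  if (D * dt > 0.25) stop("diffusion scheme unstable: D*dt must be <= 0.25");
  diffuse_decay_field(f, w, h, D, lambda, dt, toroidal, buf);
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) out(y, x) = f[(size_t)y * w + x];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_draw_duration(int n, double mean_h, double sd_h) {
  if (sd_h < 0) stop("sd must be >= 0");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = clampnorm(mean_h, sd_h);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_attempt_binding(int n, double p, NumericVector modifiers) {
  double prob = p;
  for (int i = 0; i < modifiers.size(); ++i) prob *= modifiers[i];
  if (prob < 0 || prob > 1)
    stop("binding probability product outside [0, 1]");
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = urand() < prob;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_random_walk_step(int x, int y, int w, int h, bool toroidal) {
  static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int k = (int)(urand() * 8); if (k > 7) k = 7;
  int nx = x + DX[k], ny = y + DY[k];
  if (toroidal) { nx = (nx + w) % w; ny = (ny + h) % h; }
  else if (nx < 0 || nx >= w || ny < 0 || ny >= h) { nx = x; ny = y; }
  return IntegerVector::create(nx, ny);
}
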