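#include "energetics.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete-event individual-based simulation of a beaked whale population.
//
// Continuous dynamics (shared prey density R and per-whale reserve mass F)
// are integrated with fixed-step RK4 on a grid of `dt` days; discrete events
// (movement between areas, sonar-event onsets and the disturbance allocation
// they trigger, conception, birth, weaning, death) are resolved at grid
// boundaries in time order. All randomness uses R's RNG stream, so results
// are reproducible under set.seed().

namespace {

// reproductive / life states
enum State { CALF = 0, MALE = 1, RESTING = 2, WAITING = 3, PREGNANT = 4,
             LACTATING = 5 };

struct Whale {
  bool alive = true;
  int sex = 0;           // 0 female, 1 male
  int state = RESTING;
  int area = 0;
  int mother = -1, calf = -1;
  double born_t = 0.0;   // birth time on the simulation clock (may be < 0)
  double F = 0.0;        // reserve mass (kg)
  double preg_clock = 0.0;
  double disturbed_until = -1.0;
  double next_move = R_PosInf;
  double budget = 0.0;   // Exp(1) survival budget
  double cumhaz = 0.0;
  bool born_in_sim = false;
  int pending_dest = -1;  // destination of the scheduled move at next_move
  // female life-history accounting
  int calves_born = 0, calves_weaned = 0;
  double age_recep = -1.0, age_repro = -1.0, age_wean = -1.0;
  double cond_sum = 0.0; int cond_n = 0;
  bool death_starved = false; double death_t = NA_REAL;
};

struct Engine {
  EBParams p;
  // areas
  int n_areas;
  std::vector<double> phi;
  std::vector<int> on_range;     // 0/1
  std::vector<int> disp_target;  // -1 if none
  std::vector<double> p_stable;  // expected distribution for displacement rule
  NumericMatrix Qmove;
  // prey
  double R_max, delta, kappa, R;
  // sonar
  std::vector<double> onset;     // onset times within one series cycle (days)
  NumericMatrix zmat;            // one z column per area (1 = no effect)
  double loop_days, sonar_start, sonar_end;
  int scenario;                  // 0 none, 1 cessation, 2 displacement, 3 both
  int erlang_k; double erlang_mu;
  int rounding;                  // 0 stochastic, 1 nearest
  // control
  double dt, tick_days, total_days;
  double t = 0.0;

  std::vector<Whale> w;
  std::vector<int> alive;        // indices of living whales

  // outputs
  std::vector<double> traj;      // flattened rows
  int traj_cols = 11;
  std::vector<double> vit;       // year bins x 4
  int n_years = 0;
  std::vector<double> lh;        // life-history rows (10 cols)

  double erlang_draw() {
    double s = 0.0;
    for (int i = 0; i < erlang_k; ++i) s += R::rexp(erlang_mu);
    return s;
  }

  int round_count(double x) {
    if (x <= 0.0) return 0;
    if (rounding == 1) return (int)std::floor(x + 0.5);
    double fl = std::floor(x);
    return (int)fl + (unif_rand() < (x - fl) ? 1 : 0);
  }

  // competing-exponentials draw from the current area's row of Qmove
  void sample_move(int i) {
    Whale& wh = w[i];
    double best = R_PosInf; int dest = wh.area;
    for (int j = 0; j < n_areas; ++j) {
      if (j == wh.area) continue;
      double q = Qmove(wh.area, j);
      if (q <= 0.0) continue;
      double tj = R::rexp(1.0 / q);
      if (tj < best) { best = tj; dest = j; }
    }
    wh.next_move = (dest == wh.area) ? R_PosInf : t + best;
    wh.pending_dest = dest;
  }

  void move_whale(int i, int dest) {
    w[i].area = dest;
    if (w[i].calf >= 0 && w[w[i].calf].alive) w[w[i].calf].area = dest;
  }

  double age(const Whale& wh) const { return t - wh.born_t; }

  // ---- continuous dynamics -------------------------------------------------
  // state vector: y[0] = R, y[1..] = F of whales in `alive` order
  void deriv(double ts, const std::vector<double>& y, std::vector<double>& dy,
             const std::vector<int>& idx) {
    int n = (int)idx.size();
    double Rst = std::max(y[0], 0.0);
    std::vector<double> rho(n), milk(n, 0.0);
    std::vector<int> pos(w.size(), -1);
    for (int a = 0; a < n; ++a) pos[idx[a]] = a;
    for (int a = 0; a < n; ++a) {
      const Whale& wh = w[idx[a]];
      double ag = ts - wh.born_t;
      double S = eb::smass(eb::length(ag, p), p);
      rho[a] = eb::condition(std::max(y[1 + a], 0.0), S);
    }
    // calf milk (needs mother's condition)
    for (int a = 0; a < n; ++a) {
      const Whale& wh = w[idx[a]];
      if (wh.state != CALF || wh.mother < 0) continue;
      int mp = pos[wh.mother];
      if (mp < 0) continue;
      double ag = ts - wh.born_t;
      milk[a] = eb::milk_intake(rho[a], eb::length(ag, p), ag, rho[mp], p);
    }
    double depletion = 0.0;
    for (int a = 0; a < n; ++a) {
      const Whale& wh = w[idx[a]];
      double ag = ts - wh.born_t;
      double L = eb::length(ag, p);
      double S = eb::smass(L, p);
      double F = std::max(y[1 + a], 0.0);
      double in = milk[a];
      if (ts >= wh.disturbed_until) {
        double ing = eb::ingestion(rho[a], L, ag, Rst, phi[wh.area], p);
        in += p.assim * ing;
        depletion += kappa * ing;
      }
      double S_fet = 0.0, gest = 0.0;
      if (wh.state == PREGNANT) {
        double af = std::min(wh.preg_clock + (ts - t), p.Tg) - p.Tg;
        S_fet = eb::smass(eb::length(af, p), p);
        gest = p.sigma_G * eb::smass_growth(af, p);
      }
      double lact = 0.0;
      if (wh.state == LACTATING && wh.calf >= 0 && pos[wh.calf] >= 0)
        lact = milk[pos[wh.calf]] / p.sigma_L;
      double out = eb::fmr(S, F, S_fet, p) + p.sigma_G * eb::smass_growth(ag, p)
                   + gest + lact;
      dy[1 + a] = eb::reserves_rate(in - out, p);
    }
    dy[0] = delta * (R_max - Rst) - depletion;
  }

  void rk4_step() {
    int n = (int)alive.size();
    std::vector<double> y(n + 1), k1(n + 1), k2(n + 1), k3(n + 1), k4(n + 1),
        tmp(n + 1);
    y[0] = R;
    for (int a = 0; a < n; ++a) y[1 + a] = w[alive[a]].F;
    double h = dt;
    deriv(t, y, k1, alive);
    for (int i = 0; i <= n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    deriv(t + 0.5 * h, tmp, k2, alive);
    for (int i = 0; i <= n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    deriv(t + 0.5 * h, tmp, k3, alive);
    for (int i = 0; i <= n; ++i) tmp[i] = y[i] + h * k3[i];
    deriv(t + h, tmp, k4, alive);
    for (int i = 0; i <= n; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    R = std::max(y[0], 0.0);
    for (int a = 0; a < n; ++a) {
      Whale& wh = w[alive[a]];
      wh.F = std::max(y[1 + a], 0.0);
      if (wh.state == PREGNANT) wh.preg_clock += h;
    }
  }

  void accumulate_hazard() {
    for (int i : alive) {
      Whale& wh = w[i];
      double ag = age(wh);
      double S = eb::smass(eb::length(ag, p), p);
      double rho = eb::condition(wh.F, S);
      double hz = eb::background_hazard(ag, wh.sex == 1, wh.state != CALF, p) +
                  eb::starvation_hazard(rho, p);
      wh.cumhaz += hz * dt;
    }
  }

  void rebuild_alive() {
    alive.clear();
    for (int i = 0; i < (int)w.size(); ++i) if (w[i].alive) alive.push_back(i);
  }

  int year_bin() const {
    int y = (int)std::floor(t / 365.25);
    return std::min(std::max(y, 0), n_years - 1);
  }

  void record_death(int i, bool orphaned) {
    Whale& wh = w[i];
    wh.alive = false;
    wh.death_t = t;
    double S = eb::smass(eb::length(age(wh), p), p);
    double rho = eb::condition(wh.F, S);
    wh.death_starved = orphaned || rho < p.rho_s;
    int yb = year_bin();
    vit[yb * 4 + 1] += 1;  // deaths
    if (wh.sex == 0) {
      vit[yb * 4 + 2] += 1;
      if (wh.death_starved) vit[yb * 4 + 3] += 1;
      double mc = wh.cond_n > 0 ? wh.cond_sum / wh.cond_n : NA_REAL;
      double lhrow[10] = {wh.born_t, t, (double)wh.born_in_sim,
                          (double)wh.calves_born, (double)wh.calves_weaned,
                          wh.age_recep, wh.age_repro, wh.age_wean,
                          (double)wh.death_starved, mc};
      lh.insert(lh.end(), lhrow, lhrow + 10);
    }
    // dependent calf cannot survive without milk; mother freed if a calf dies
    if (wh.calf >= 0 && w[wh.calf].alive) record_death(wh.calf, true);
    if (wh.state == CALF && wh.mother >= 0 && w[wh.mother].alive) {
      w[wh.mother].state = RESTING;
      w[wh.mother].calf = -1;
    }
  }

  void process_deaths() {
    bool any = false;
    for (int i : alive) {
      if (w[i].alive && w[i].cumhaz > w[i].budget) { record_death(i, false); any = true; }
    }
    if (any) rebuild_alive();
  }

  void process_births() {
    std::vector<int> mothers;
    for (int i : alive)
      if (w[i].state == PREGNANT && w[i].preg_clock >= p.Tg) mothers.push_back(i);
    for (int m : mothers) {
      Whale c;
      c.sex = unif_rand() < 0.5 ? 1 : 0;
      c.state = CALF;
      c.area = w[m].area;
      c.mother = m;
      c.born_t = t;
      c.born_in_sim = true;
      double S0 = eb::smass(p.L0, p);
      c.F = p.rho_birth / (1.0 - p.rho_birth) * S0;
      c.budget = R::rexp(1.0);
      c.next_move = R_PosInf;
      w[m].F = std::max(w[m].F - c.F, 0.0);
      w[m].state = LACTATING;
      w[m].preg_clock = 0.0;
      w[m].calves_born += 1;
      if (w[m].age_repro < 0) w[m].age_repro = age(w[m]);
      w[m].calf = (int)w.size();
      w.push_back(c);
      alive.push_back((int)w.size() - 1);
      vit[year_bin() * 4 + 0] += 1;  // births
    }
  }

  void process_weanings() {
    for (int i : alive) {
      Whale& wh = w[i];
      if (wh.state != LACTATING || wh.calf < 0) continue;
      Whale& c = w[wh.calf];
      if (!c.alive || age(c) < p.Tw) continue;
      c.state = c.sex == 1 ? MALE : RESTING;
      c.mother = -1;
      sample_move(wh.calf);
      wh.calves_weaned += 1;
      if (wh.age_wean < 0) wh.age_wean = age(wh);
      wh.calf = -1;
      wh.state = RESTING;
    }
  }

  void process_reproduction() {
    double pc = 1.0 - std::exp(-p.nu_conception * dt);
    for (int i : alive) {
      Whale& wh = w[i];
      if (wh.sex != 0) continue;
      if (wh.state == RESTING && wh.F > p.F_preg) {
        wh.state = WAITING;
        if (wh.age_recep < 0) wh.age_recep = age(wh);
      } else if (wh.state == WAITING && wh.F <= p.F_preg) {
        wh.state = RESTING;
      }
      if (wh.state == WAITING && unif_rand() < pc) {
        wh.state = PREGNANT;
        wh.preg_clock = 0.0;
      }
    }
  }

  void process_moves() {
    for (int i : alive) {
      while (w[i].alive && w[i].next_move <= t) {
        move_whale(i, w[i].pending_dest);
        sample_move(i);
      }
    }
  }

  // pick `need` distinct entries of pool uniformly at random (partial
  // Fisher-Yates)
  std::vector<int> pick(std::vector<int>& pool, int need) {
    std::vector<int> out;
    int n = (int)pool.size();
    need = std::min(need, n);
    for (int i = 0; i < need; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      out.push_back(pool[i]);
    }
    return out;
  }

  void apply_sonar(const double* z) {
    if (scenario == 0) return;
    // weaned whales only: the dose-response describes foraging dive starts
    int N_tot = 0;
    for (int i : alive) if (w[i].state != CALF) ++N_tot;
    for (int a = 0; a < n_areas; ++a) {
      if (!on_range[a] || z[a] >= 1.0) continue;
      std::vector<int> members;
      for (int i : alive)
        if (w[i].state != CALF && w[i].area == a) members.push_back(i);
      int N = (int)members.size();
      if (N == 0) continue;
      if (scenario == 1) {
        int target = round_count((1.0 - z[a]) * N);
        std::vector<int> undisturbed;
        int cur = 0;
        for (int i : members) {
          if (w[i].disturbed_until > t) ++cur; else undisturbed.push_back(i);
        }
        int need = std::max(0, target - cur);
        for (int i : pick(undisturbed, need))
          w[i].disturbed_until = t + erlang_draw();
      } else {
        double M = p_stable[a] * N_tot;
        int target = round_count(std::max((double)N - M * z[a], 0.0));
        std::vector<int> sel = pick(members, target);
        for (int i : sel) {
          move_whale(i, disp_target[a]);
          sample_move(i);
          if (scenario == 3)
            w[i].disturbed_until = std::max(w[i].disturbed_until,
                                            t + erlang_draw());
        }
      }
    }
  }

  void record_tick() {
    int counts[6] = {0, 0, 0, 0, 0, 0};
    int dist = 0, onr = 0;
    for (int i : alive) {
      Whale& wh = w[i];
      counts[wh.state] += 1;
      if (wh.disturbed_until > t) ++dist;
      if (on_range[wh.area]) ++onr;
      if (wh.sex == 0 && wh.state >= RESTING) {
        double S = eb::smass(eb::length(age(wh), p), p);
        wh.cond_sum += eb::condition(wh.F, S);
        wh.cond_n += 1;
      }
    }
    double row[11] = {t, (double)alive.size(), R, (double)counts[CALF],
                      (double)counts[MALE], (double)counts[RESTING],
                      (double)counts[WAITING], (double)counts[PREGNANT],
                      (double)counts[LACTATING], (double)dist, (double)onr};
    traj.insert(traj.end(), row, row + 11);
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List cfg) {
  Engine e;
  e.p = eb_params_from_list(cfg["params"]);
  List ar = cfg["areas"];
  e.phi = as<std::vector<double>>(ar["phi"]);
  e.on_range = as<std::vector<int>>(ar["on_range"]);
  e.disp_target = as<std::vector<int>>(ar["disp_target"]);
  e.n_areas = (int)e.phi.size();
  e.p_stable = as<std::vector<double>>(cfg["p_stable"]);
  e.Qmove = as<NumericMatrix>(cfg["Q"]);
  List prey = cfg["prey"];
  e.R_max = prey["R_max"]; e.delta = prey["delta"]; e.kappa = prey["kappa"];
  e.R = prey["R0"];
  List sn = cfg["sonar"];
  e.onset = as<std::vector<double>>(sn["onset"]);
  e.zmat = as<NumericMatrix>(sn["z"]);
  e.loop_days = sn["loop_days"]; e.sonar_start = sn["start"];
  e.sonar_end = sn["end"];
  e.scenario = sn["scenario"];
  e.erlang_k = sn["erlang_k"]; e.erlang_mu = sn["erlang_mu"];
  e.rounding = sn["rounding"];
  List ctl = cfg["control"];
  e.dt = ctl["dt"]; e.tick_days = ctl["tick_days"];
  e.total_days = ctl["total_days"];
  e.n_years = (int)std::ceil(e.total_days / 365.25) + 1;
  e.vit.assign(e.n_years * 4, 0.0);

  // initial population
  DataFrame init = as<DataFrame>(cfg["init"]);
  NumericVector i_age = init["age"];
  IntegerVector i_sex = init["sex"], i_area = init["area"];
  NumericVector i_F = init["F"];
  for (int i = 0; i < i_age.size(); ++i) {
    Whale wh;
    wh.sex = i_sex[i];
    wh.state = wh.sex == 1 ? MALE : RESTING;
    wh.area = i_area[i];
    wh.born_t = -i_age[i];
    wh.F = i_F[i];
    wh.budget = R::rexp(1.0);
    wh.born_in_sim = false;
    e.w.push_back(wh);
  }
  e.rebuild_alive();
  for (int i : e.alive) e.sample_move(i);

  int sonar_idx = 0, sonar_cycle = 0;
  bool have_sonar = e.scenario != 0 && e.onset.size() > 0;
  double next_tick = 0.0;
  e.record_tick();
  next_tick += e.tick_days;

  int n_steps = (int)std::ceil(e.total_days / e.dt);
  for (int s = 0; s < n_steps; ++s) {
    if (e.alive.empty()) {  // extinction: advance clock, keep recording zeros
      e.t += e.dt;
      e.R += e.dt * e.delta * (e.R_max - e.R);
    } else {
      e.rk4_step();
      e.t += e.dt;
      e.accumulate_hazard();
      e.process_deaths();
      if (!e.alive.empty()) {
        e.process_births();
        e.process_weanings();
        e.process_reproduction();
        e.process_moves();
      }
    }
    if (have_sonar) {
      while (true) {
        double onset_t = e.sonar_start + sonar_cycle * e.loop_days +
                         e.onset[sonar_idx];
        if (onset_t > e.t || onset_t > e.sonar_end) break;
        if (!e.alive.empty()) {
          std::vector<double> z(e.n_areas);
          for (int a = 0; a < e.n_areas; ++a) z[a] = e.zmat(sonar_idx, a);
          e.apply_sonar(z.data());
        }
        if (++sonar_idx >= (int)e.onset.size()) { sonar_idx = 0; ++sonar_cycle; }
      }
    }
    if (e.t + 1e-9 >= next_tick) {
      e.record_tick();
      next_tick += e.tick_days;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  int n_ticks = (int)e.traj.size() / e.traj_cols;
  NumericMatrix traj(n_ticks, e.traj_cols);
  for (int r = 0; r < n_ticks; ++r)
    for (int c = 0; c < e.traj_cols; ++c) traj(r, c) = e.traj[r * e.traj_cols + c];
  colnames(traj) = CharacterVector::create(
      "t", "N", "R", "calves", "males", "resting", "waiting", "pregnant",
      "lactating", "disturbed", "on_range");

  NumericMatrix vit(e.n_years, 4);
  for (int r = 0; r < e.n_years; ++r)
    for (int c = 0; c < 4; ++c) vit(r, c) = e.vit[r * 4 + c];
  colnames(vit) = CharacterVector::create("births", "deaths", "female_deaths",
                                          "female_starvation_deaths");

  int n_lh = (int)e.lh.size() / 10;
  NumericMatrix lh(n_lh, 10);
  for (int r = 0; r < n_lh; ++r)
    for (int c = 0; c < 10; ++c) lh(r, c) = e.lh[r * 10 + c];
  colnames(lh) = CharacterVector::create(
      "born_t", "death_t", "born_in_sim", "calves_born", "calves_weaned",
      "age_first_receptive", "age_first_reproduction", "age_first_weaning",
      "starved", "mean_adult_condition");

  return List::create(_["trajectory"] = traj, _["vitals"] = vit,
                      _["lifehistory"] = lh, _["final_N"] = (int)e.alive.size(),
                      _["final_R"] = e.R);
}
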