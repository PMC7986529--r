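// Core stepping engine for the three-column integrate-and-fire network.
//
// Unit potentials follow twin leaky integrators V = Vs - Vf with shared
// synaptic input, forward-Euler decay factors (1 - h/tau), strict threshold
// crossing and reset-to-zero on the step after a spike.  Plasticity uses
// per-unit strengthening traces S_j (driven by delayed presynaptic arrivals)
// and weakening traces T_i (driven by postsynaptic spikes), applied
// multiplicatively with the training factor r and weakening factor c at
// spike/arrival events, then hard-clipped.
//
// All randomness is drawn from R's RNG stream so set.seed() in R makes runs
// exactly reproducible.  Everything is single-threaded.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Filter {
  // direct-form II transposed IIR, arbitrary order (a[0] == 1 assumed)
  std::vector<double> b, a, z;
  bool active = false;
  void init(const NumericVector& bb, const NumericVector& aa) {
    b.assign(bb.begin(), bb.end());
    a.assign(aa.begin(), aa.end());
    z.assign(std::max(b.size(), a.size()) - 1, 0.0);
    active = true;
  }
  void reset() { std::fill(z.begin(), z.end(), 0.0); }
  double step(double x) {
    const size_t nz = z.size();
    double y = b[0] * x + (nz ? z[0] : 0.0);
    for (size_t i = 0; i < nz; ++i) {
      double bi = (i + 1 < b.size()) ? b[i + 1] : 0.0;
      double ai = (i + 1 < a.size()) ? a[i + 1] : 0.0;
      z[i] = bi * x + (i + 1 < nz ? z[i + 1] : 0.0) - ai * y;
    }
    return y;
  }
};

struct Protocol {
  int variant = 0;        // 0 none, 1 spike, 2 emg, 3 cycle, 4 gamma
  int trigger_unit = -1;  // for spike-triggered
  int source_col = 0;     // LFP column (cycle/gamma) or EMG pool (emg)
  int target_col = 1;
  int delay_steps = 0;    // trigger -> first stimulus
  double amp_uv = 2000.0; // signed stimulus amplitude (uV)
  int train_n = 1;
  int train_interval_steps = 330;
  long long lockout_steps = 0;
  double threshold = 0.0; // crossing level (emg/gamma)
  int edge = 1;           // +1 rising, -1 falling (emg/gamma)
  double level = 0.0;     // episode arming level (cycle)
  int cross_type = 0;     // 0 rising zero-crossing, 1 falling (cycle)
  int phase_steps = 0;    // extra delay after the chosen crossing (cycle)
  Filter filt;
  // runtime trigger state
  long long last_trigger = LLONG_MIN / 2;
  double prev_y = 0.0;
  bool armed = false;
};

struct Engine {
  // ---- fixed parameters ----
  double h;                // ms
  double ds, dfct;         // potential decay factors (1 - h/tau)
  int d_cort, d_mot;       // delays in steps
  double r, c, wmin, wmax;
  double das, daf, dbs, dbf; // trace decay factors
  double block_s;          // block length (s), for the envelope clock

  // ---- units ----
  int n, ncort;
  std::vector<int> column;       // 0..2
  std::vector<uint8_t> is_moto;
  std::vector<double> thr;       // uV
  std::vector<double> muap_w;    // EMG kernel weight for motoneurons, else 0
  std::vector<std::vector<int>> col_cort;  // cortical units per column
  std::vector<std::vector<int>> col_moto;  // motoneurons per pool

  // ---- connectivity ----
  int ne;
  std::vector<double> w;          // per edge, signed weight units
  std::vector<uint8_t> plastic;
  std::vector<int8_t> sgn;
  // CSR by source, split by target kind (delay class)
  std::vector<int> oc_ptr, oc_dst, oc_eid;  // -> cortical (delay d_cort)
  std::vector<int> om_ptr, om_dst, om_eid;  // -> motoneuron (delay d_mot)
  // CSC over plastic edges by target (for potentiation on post spike)
  std::vector<int> in_ptr, in_src, in_eid;

  // ---- bias input ----
  // per column: correlated column-event prob/step, uncorrelated per-unit
  // prob/step, amplitude (weight units), jitter SD in steps
  double p_corr[3] = {0, 0, 0}, p_unc[3] = {0, 0, 0};
  double bias_amp[3] = {0, 0, 0};
  double jit_steps[3] = {0, 0, 0};
  int corr_look[3] = {1, 1, 1};   // scheduling lookahead (4 SD), steps
  double moto_p = 0.0, moto_amp = 0.0;
  // oscillatory envelope on one column's bias probabilities
  int env_col = -1;
  double env_depth = 0.0, env_freq = 0.0, env_dur_s = 0.0;
  std::vector<double> env_onsets_s;
  // next-event schedule (geometric skipping; thinned where modulated)
  std::vector<long long> next_unc;     // per cortical unit + motoneurons
  long long next_corr[3] = {0, 0, 0};

  // ---- dynamic state ----
  long long t = 0;  // global step counter
  std::vector<double> vs, vf;
  std::vector<double> Ss, Sf, Ts, Tf;
  std::vector<std::vector<int>> spike_ring;  // depth d_mot + 1
  int ring_depth;
  // delivery ring: bias events (enter A); stimulus ring: direct Vs steps
  static const int DRING = 4096;
  std::vector<std::vector<std::pair<int, double>>> deliv_ring;    // unit, amp
  std::vector<std::vector<std::pair<int, double>>> stim_ring;     // col, amp_uv
  double lfps[3] = {0, 0, 0}, lfpf[3] = {0, 0, 0};
  double emgs[3] = {0, 0, 0}, emgf[3] = {0, 0, 0};
  long long truncated = 0;

  // scratch
  std::vector<double> A;
  std::vector<int> spiking, arrivals_c;

  double env_at(long long step) const {
    if (env_col < 0 || env_depth <= 0) return 1.0;
    double ts = step * h / 1000.0;
    double tb = ts - std::floor(ts / block_s) * block_s;
    for (double on : env_onsets_s) {
      if (tb >= on && tb < on + env_dur_s) {
        double m = 1.0 + env_depth *
          std::sin(2.0 * M_PI * env_freq * (tb - on));
        return m > 0 ? m : 0.0;
      }
    }
    return 1.0;
  }

  // geometric gap >= 1 for Bernoulli(p) per step
  static long long geom_gap(double p) {
    if (p <= 0) return LLONG_MAX / 4;
    if (p >= 1) return 1;
    double u = unif_rand();
    while (u <= 0) u = unif_rand();
    return 1 + (long long)std::floor(std::log(u) / std::log1p(-p));
  }
};

Engine* get_engine(SEXP xp) {
  Rcpp::XPtr<Engine> p(xp);
  return p.get();
}

}  // namespace

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List cfg) {
  Engine* E = new Engine();
  E->h = as<double>(cfg["h"]);
  double tau_s = as<double>(cfg["tau_s"]), tau_f = as<double>(cfg["tau_f"]);
  if (E->h >= tau_f) {
    delete E;
    stop("time step h must be smaller than tau_f for Euler stability");
  }
  E->ds = 1.0 - E->h / tau_s;
  E->dfct = 1.0 - E->h / tau_f;
  E->d_cort = as<int>(cfg["d_cort_steps"]);
  E->d_mot = as<int>(cfg["d_mot_steps"]);
  E->r = as<double>(cfg["r"]);
  E->c = as<double>(cfg["c"]);
  E->wmin = as<double>(cfg["w_min"]);
  E->wmax = as<double>(cfg["w_max"]);
  E->das = 1.0 - E->h / as<double>(cfg["a_s"]);
  E->daf = 1.0 - E->h / as<double>(cfg["a_f"]);
  E->dbs = 1.0 - E->h / as<double>(cfg["b_s"]);
  E->dbf = 1.0 - E->h / as<double>(cfg["b_f"]);
  E->block_s = as<double>(cfg["block_s"]);

  IntegerVector column = cfg["column"];
  LogicalVector ismoto = cfg["is_moto"];
  NumericVector thr = cfg["threshold"];
  NumericVector muap = cfg["muap_w"];
  E->n = column.size();
  E->column.resize(E->n);
  E->is_moto.resize(E->n);
  E->thr.assign(thr.begin(), thr.end());
  E->muap_w.assign(muap.begin(), muap.end());
  E->col_cort.assign(3, {});
  E->col_moto.assign(3, {});
  E->ncort = 0;
  for (int i = 0; i < E->n; ++i) {
    E->column[i] = column[i] - 1;
    E->is_moto[i] = ismoto[i] ? 1 : 0;
    if (ismoto[i]) E->col_moto[E->column[i]].push_back(i);
    else { E->col_cort[E->column[i]].push_back(i); ++E->ncort; }
  }
  for (int i = 0; i < E->n; ++i)
    if (!E->is_moto[i] && i >= E->ncort) {
      delete E;
      stop("units must be ordered cortical first, then motoneurons");
    }

  IntegerVector esrc = cfg["edge_src"], edst = cfg["edge_dst"];
  NumericVector ew = cfg["edge_w"];
  LogicalVector epl = cfg["edge_plastic"];
  E->ne = esrc.size();
  E->w.assign(ew.begin(), ew.end());
  E->plastic.resize(E->ne);
  E->sgn.resize(E->ne);
  for (int e = 0; e < E->ne; ++e) {
    if (ew[e] == 0) stop("edge weights must be non-zero");
    E->plastic[e] = epl[e] ? 1 : 0;
    E->sgn[e] = ew[e] > 0 ? 1 : -1;
  }
  // CSR by source, split by target kind
  std::vector<int> cnt_c(E->n + 1, 0), cnt_m(E->n + 1, 0), cnt_in(E->n + 1, 0);
  for (int e = 0; e < E->ne; ++e) {
    int s = esrc[e] - 1, d = edst[e] - 1;
    if (s == d) stop("self-connections are not allowed");
    if (E->is_moto[d]) cnt_m[s + 1]++; else cnt_c[s + 1]++;
    if (epl[e] && !E->is_moto[d]) cnt_in[d + 1]++;
  }
  for (int i = 0; i < E->n; ++i) {
    cnt_c[i + 1] += cnt_c[i];
    cnt_m[i + 1] += cnt_m[i];
    cnt_in[i + 1] += cnt_in[i];
  }
  E->oc_ptr = cnt_c; E->om_ptr = cnt_m; E->in_ptr = cnt_in;
  E->oc_dst.resize(E->oc_ptr[E->n]); E->oc_eid.resize(E->oc_ptr[E->n]);
  E->om_dst.resize(E->om_ptr[E->n]); E->om_eid.resize(E->om_ptr[E->n]);
  E->in_src.resize(E->in_ptr[E->n]); E->in_eid.resize(E->in_ptr[E->n]);
  {
    std::vector<int> pc = E->oc_ptr, pm = E->om_ptr, pi = E->in_ptr;
    for (int e = 0; e < E->ne; ++e) {
      int s = esrc[e] - 1, d = edst[e] - 1;
      if (E->is_moto[d]) { E->om_dst[pm[s]] = d; E->om_eid[pm[s]++] = e; }
      else { E->oc_dst[pc[s]] = d; E->oc_eid[pc[s]++] = e; }
      if (E->plastic[e] && !E->is_moto[d]) {
        E->in_src[pi[d]] = s; E->in_eid[pi[d]++] = e;
      }
    }
  }

  // bias configuration
  NumericVector cr = cfg["bias_corr_rate"], ur = cfg["bias_uncorr_rate"];
  NumericVector ba = cfg["bias_amp_w"], js = cfg["bias_jitter_ms"];
  for (int k = 0; k < 3; ++k) {
    E->p_corr[k] = cr[k] * E->h / 1000.0;
    E->p_unc[k] = ur[k] * E->h / 1000.0;
    if (E->p_corr[k] > 1 || E->p_unc[k] > 1)
      stop("bias event probability per step exceeds 1; reduce rate or h");
    E->bias_amp[k] = ba[k];
    E->jit_steps[k] = js[k] / E->h;
    E->corr_look[k] = (int)std::ceil(4.0 * E->jit_steps[k]) + 1;
  }
  E->moto_p = as<double>(cfg["moto_rate"]) * E->h / 1000.0;
  E->moto_amp = as<double>(cfg["moto_amp_w"]);

  E->env_col = as<int>(cfg["env_col"]) - 1;  // 0 from R means none -> -1
  if (E->env_col >= 0) {
    E->env_depth = as<double>(cfg["env_depth"]);
    E->env_freq = as<double>(cfg["env_freq"]);
    double cycles = as<double>(cfg["env_cycles"]);
    int neps = as<int>(cfg["env_episodes_per_block"]);
    E->env_dur_s = cycles / E->env_freq;
    for (int k = 1; k <= neps; ++k)
      E->env_onsets_s.push_back(E->block_s * (2.0 * k - 1) / (2.0 * neps));
  }

  // dynamic state
  E->vs.assign(E->n, 0.0); E->vf.assign(E->n, 0.0);
  E->Ss.assign(E->n, 0.0); E->Sf.assign(E->n, 0.0);
  E->Ts.assign(E->n, 0.0); E->Tf.assign(E->n, 0.0);
  E->ring_depth = E->d_mot + 1;
  E->spike_ring.assign(E->ring_depth, {});
  E->deliv_ring.assign(Engine::DRING, {});
  E->stim_ring.assign(Engine::DRING, {});
  E->A.assign(E->n, 0.0);

  // initialize next-event schedules (relative to t = 0)
  GetRNGstate();
  E->next_unc.assign(E->n, LLONG_MAX / 4);
  for (int i = 0; i < E->n; ++i) {
    double p;
    if (E->is_moto[i]) p = E->moto_p;
    else {
      int k = E->column[i];
      p = E->p_unc[k] * (k == E->env_col ? 1.0 + E->env_depth : 1.0);
    }
    if (p > 0) E->next_unc[i] = Engine::geom_gap(p) - 1;
  }
  for (int k = 0; k < 3; ++k) {
    double p = E->p_corr[k] * (k == E->env_col ? 1.0 + E->env_depth : 1.0);
    E->next_corr[k] = p > 0 ? Engine::geom_gap(p) - 1 : LLONG_MAX / 4;
  }
  PutRNGstate();

  Rcpp::XPtr<Engine> xp(E, true);
  return xp;
}

// [[Rcpp::export(name = ".net_run")]]
List net_run(SEXP xp, int n_steps, List opts) {
  Engine* E = get_engine(xp);
  const bool plast_on = as<bool>(opts["plasticity"]);
  const bool rec_lfp = as<bool>(opts["record_lfp"]);
  const bool rec_emg = as<bool>(opts["record_emg"]);
  const bool rec_spk = as<bool>(opts["record_spikes"]);
  const bool rec_filt = as<bool>(opts["record_filt"]);
  const int rec_v = as<int>(opts["record_v_unit"]);  // 1-based, 0 = none

  // open-loop stimulus schedule (column-level, local 0-based steps, sorted)
  IntegerVector sstep = opts["stim_step"], scol = opts["stim_col"];
  NumericVector samp = opts["stim_amp"];
  int sched_i = 0, sched_n = sstep.size();

  // forced spikes (testing facility): local step -> unit list
  IntegerVector fstep = opts["forced_step"], funit = opts["forced_unit"];
  int forced_i = 0, forced_n = fstep.size();

  Protocol P;
  if (opts.containsElementNamed("protocol") &&
      !Rf_isNull(opts["protocol"])) {
    List pl = opts["protocol"];
    P.variant = as<int>(pl["variant"]);
    P.trigger_unit = as<int>(pl["trigger_unit"]) - 1;
    P.source_col = as<int>(pl["source_col"]) - 1;
    P.target_col = as<int>(pl["target_col"]) - 1;
    P.delay_steps = as<int>(pl["delay_steps"]);
    P.amp_uv = as<double>(pl["amp_uv"]);
    P.train_n = as<int>(pl["train_n"]);
    P.train_interval_steps = as<int>(pl["train_interval_steps"]);
    P.lockout_steps = as<int>(pl["lockout_steps"]);
    P.threshold = as<double>(pl["threshold"]);
    P.edge = as<int>(pl["edge"]);
    P.level = as<double>(pl["level"]);
    P.cross_type = as<int>(pl["cross_type"]);
    P.phase_steps = as<int>(pl["phase_steps"]);
    if (P.variant >= 2) {
      P.filt.init(pl["filt_b"], pl["filt_a"]);
    }
  }

  std::vector<int> out_spk_unit, out_spk_step;
  NumericMatrix out_lfp(rec_lfp ? n_steps : 0, 3);
  NumericMatrix out_emg(rec_emg ? n_steps : 0, 3);
  NumericVector out_v(rec_v > 0 ? n_steps : 0);
  NumericVector out_filt(rec_filt ? n_steps : 0);
  std::vector<double> trig_steps;
  std::vector<int> log_step, log_col; std::vector<double> log_amp;

  GetRNGstate();
  for (int tl = 0; tl < n_steps; ++tl) {
    const long long t = E->t;
    const int dslot = (int)(t % Engine::DRING);

    // ---- (1) accumulate input A(t) ----
    std::fill(E->A.begin(), E->A.end(), 0.0);
    double colA[3] = {0, 0, 0};  // synaptic + bias input per column (LFP)

    // uncorrelated bias events due now (geometric skipping, thinned under
    // envelope modulation)
    for (int i = 0; i < E->n; ++i) {
      while (E->next_unc[i] <= t) {
        double amp, pmax; int k = E->column[i];
        bool accept = true;
        if (E->is_moto[i]) { amp = E->moto_amp; pmax = E->moto_p; }
        else {
          amp = E->bias_amp[k];
          pmax = E->p_unc[k];
          if (k == E->env_col) {
            pmax *= (1.0 + E->env_depth);
            accept = unif_rand() < E->env_at(t) / (1.0 + E->env_depth);
          }
        }
        if (accept) {
          E->A[i] += amp;
          if (!E->is_moto[i]) colA[k] += amp;
        }
        E->next_unc[i] = t + Engine::geom_gap(pmax);
      }
    }
    // correlated column events: decided `look` steps ahead of delivery center
    for (int k = 0; k < 3; ++k) {
      while (E->next_corr[k] <= t) {
        double pmax = E->p_corr[k];
        bool accept = true;
        long long center = t + E->corr_look[k];
        if (k == E->env_col) {
          pmax *= (1.0 + E->env_depth);
          accept = unif_rand() < E->env_at(center) / (1.0 + E->env_depth);
        }
        if (accept) {
          double maxjit = 4.0 * E->jit_steps[k];
          for (int u : E->col_cort[k]) {
            double j = norm_rand() * E->jit_steps[k];
            if (j > maxjit) j = maxjit; else if (j < -maxjit) j = -maxjit;
            long long at = center + (long long)std::llround(j);
            if (at <= t) at = t + 1;
            E->deliv_ring[at % Engine::DRING].push_back({u, E->bias_amp[k]});
          }
        }
        E->next_corr[k] = t + Engine::geom_gap(pmax);
      }
    }
    // scheduled bias deliveries for this step
    {
      auto& dv = E->deliv_ring[dslot];
      for (auto& pr : dv) {
        E->A[pr.first] += pr.second;
        colA[E->column[pr.first]] += pr.second;
      }
      dv.clear();
    }
    // delayed spikes
    E->arrivals_c.clear();
    if (t >= E->d_cort) {
      for (int j : E->spike_ring[(t - E->d_cort) % E->ring_depth]) {
        if (!E->is_moto[j]) {
          E->arrivals_c.push_back(j);
          for (int q = E->oc_ptr[j]; q < E->oc_ptr[j + 1]; ++q) {
            double wq = E->w[E->oc_eid[q]];
            E->A[E->oc_dst[q]] += wq;
            colA[E->column[E->oc_dst[q]]] += wq;
          }
        }
      }
    }
    if (t >= E->d_mot) {
      for (int j : E->spike_ring[(t - E->d_mot) % E->ring_depth]) {
        if (!E->is_moto[j])
          for (int q = E->om_ptr[j]; q < E->om_ptr[j + 1]; ++q)
            E->A[E->om_dst[q]] += E->w[E->om_eid[q]];
      }
    }

    // ---- (2) evaluate spikes U(t) from current V(t) ----
    E->spiking.clear();
    for (int i = 0; i < E->n; ++i)
      if (E->vs[i] - E->vf[i] > E->thr[i]) E->spiking.push_back(i);
    while (forced_i < forced_n && fstep[forced_i] == tl) {
      int u = funit[forced_i] - 1;
      bool already = false;
      for (int i2 : E->spiking) if (i2 == u) { already = true; break; }
      if (!already) E->spiking.push_back(u);
      ++forced_i;
    }
    {
      auto& slot = E->spike_ring[t % E->ring_depth];
      slot.clear();
      for (int i : E->spiking) slot.push_back(i);
    }
    if (rec_spk)
      for (int i : E->spiking) {
        out_spk_unit.push_back(i + 1);
        out_spk_step.push_back(tl);
      }

    // ---- (3) plasticity, with traces as of time t ----
    if (plast_on) {
      for (int i : E->spiking) {
        if (E->is_moto[i]) continue;
        for (int q = E->in_ptr[i]; q < E->in_ptr[i + 1]; ++q) {
          int j = E->in_src[q], e = E->in_eid[q];
          double Sj = E->Ss[j] - E->Sf[j];
          double nw = E->w[e] + E->r * E->sgn[e] * Sj;
          if (E->sgn[e] > 0) {
            if (nw < E->wmin) nw = E->wmin;
            else if (nw > E->wmax) nw = E->wmax;
          } else {
            if (nw > -E->wmin) nw = -E->wmin;
            else if (nw < -E->wmax) nw = -E->wmax;
          }
          E->w[e] = nw;
        }
      }
      for (int j : E->arrivals_c) {
        for (int q = E->oc_ptr[j]; q < E->oc_ptr[j + 1]; ++q) {
          int e = E->oc_eid[q];
          if (!E->plastic[e]) continue;
          int i = E->oc_dst[q];
          double Ti = E->Ts[i] - E->Tf[i];
          double nw = E->w[e] - E->r * E->c * E->sgn[e] * Ti;
          if (E->sgn[e] > 0) {
            if (nw < E->wmin) nw = E->wmin;
            else if (nw > E->wmax) nw = E->wmax;
          } else {
            if (nw > -E->wmin) nw = -E->wmin;
            else if (nw < -E->wmax) nw = -E->wmax;
          }
          E->w[e] = nw;
        }
      }
    }

    // ---- (4) advance traces (no reset; cortical only) ----
    for (int i = 0; i < E->ncort; ++i) {
      // cortical units are constructed first (indices 0..ncort-1)
      E->Ss[i] *= E->das; E->Sf[i] *= E->daf;
      E->Ts[i] *= E->dbs; E->Tf[i] *= E->dbf;
    }
    for (int j : E->arrivals_c) { E->Ss[j] += 1.0; E->Sf[j] += 1.0; }
    for (int i : E->spiking)
      if (!E->is_moto[i]) { E->Ts[i] += 1.0; E->Tf[i] += 1.0; }

    // ---- (5) advance potentials; reset wins over input ----
    for (int i = 0; i < E->n; ++i) {
      E->vs[i] = E->ds * E->vs[i] + E->A[i];
      E->vf[i] = E->dfct * E->vf[i] + E->A[i];
    }
    for (int i : E->spiking) { E->vs[i] = 0.0; E->vf[i] = 0.0; }

    // ---- (6) stimulus steps (after reset/update: reset never swallows) ----
    {
      auto& sv = E->stim_ring[dslot];
      for (auto& pr : sv) {
        for (int u : E->col_cort[pr.first]) E->vs[u] += pr.second;
        log_step.push_back(tl); log_col.push_back(pr.first + 1);
        log_amp.push_back(pr.second);
      }
      sv.clear();
    }
    while (sched_i < sched_n && sstep[sched_i] == tl) {
      int k = scol[sched_i] - 1;
      for (int u : E->col_cort[k]) E->vs[u] += samp[sched_i];
      log_step.push_back(tl); log_col.push_back(k + 1);
      log_amp.push_back(samp[sched_i]);
      ++sched_i;
    }

    // ---- (7) LFP / EMG accumulators ----
    for (int k = 0; k < 3; ++k) {
      E->lfps[k] = E->ds * E->lfps[k] + colA[k];
      E->lfpf[k] = E->dfct * E->lfpf[k] + colA[k];
      if (rec_lfp) out_lfp(tl, k) = E->lfps[k] - E->lfpf[k];
    }
    {
      double minp[3] = {0, 0, 0};
      for (int i : E->spiking)
        if (E->is_moto[i]) minp[E->column[i]] += E->muap_w[i];
      for (int k = 0; k < 3; ++k) {
        E->emgs[k] = E->ds * E->emgs[k] + minp[k];
        E->emgf[k] = E->dfct * E->emgf[k] + minp[k];
        if (rec_emg) out_emg(tl, k) = E->emgs[k] - E->emgf[k];
      }
    }
    if (rec_v > 0) out_v[tl] = E->vs[rec_v - 1] - E->vf[rec_v - 1];

    // ---- (8) closed-loop trigger detection ----
    if (P.variant > 0) {
      bool fire = false;
      if (P.variant == 1) {
        for (int i : E->spiking) if (i == P.trigger_unit) { fire = true; break; }
      } else {
        double x;
        if (P.variant == 2) x = E->emgs[P.source_col] - E->emgf[P.source_col];
        else x = E->lfps[P.source_col] - E->lfpf[P.source_col];
        double y = P.filt.step(x);
        if (rec_filt) out_filt[tl] = y;
        if (P.variant == 3) {  // cycle-triggered
          if (y > P.level) P.armed = true;
          bool crossed = P.cross_type == 0 ?
            (P.prev_y <= 0 && y > 0) : (P.prev_y >= 0 && y < 0);
          if (P.armed && crossed) { fire = true; P.armed = false; }
        } else {  // emg / gamma threshold crossing
          bool crossed = P.edge > 0 ?
            (P.prev_y <= P.threshold && y > P.threshold) :
            (P.prev_y >= P.threshold && y < P.threshold);
          if (crossed) fire = true;
        }
        P.prev_y = y;
      }
      if (fire && t - P.last_trigger >= P.lockout_steps) {
        P.last_trigger = t;
        trig_steps.push_back((double)tl);
        int base = P.variant == 3 ? P.phase_steps : P.delay_steps;
        for (int p = 0; p < P.train_n; ++p) {
          long long at = t + base + (long long)p * P.train_interval_steps;
          if (at <= t) at = t + 1;
          if (at - t >= Engine::DRING) { ++E->truncated; continue; }
          E->stim_ring[at % Engine::DRING].push_back(
            {P.target_col, P.amp_uv});
        }
      }
    }

    ++E->t;
  }
  PutRNGstate();

  return List::create(
    _["spike_unit"] = wrap(out_spk_unit),
    _["spike_step"] = wrap(out_spk_step),
    _["lfp"] = out_lfp,
    _["emg"] = out_emg,
    _["v"] = out_v,
    _["filt"] = out_filt,
    _["trigger_step"] = wrap(trig_steps),
    _["stim_step"] = wrap(log_step),
    _["stim_col"] = wrap(log_col),
    _["stim_amp"] = wrap(log_amp),
    _["truncated"] = (double)E->truncated);
}

// [[Rcpp::export(name = ".net_get_weights")]]
NumericVector net_get_weights(SEXP xp) {
  Engine* E = get_engine(xp);
  return NumericVector(E->w.begin(), E->w.end());
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP xp, NumericVector w) {
  Engine* E = get_engine(xp);
  if ((int)w.size() != E->ne) stop("weight vector has wrong length");
  std::copy(w.begin(), w.end(), E->w.begin());
  for (int e = 0; e < E->ne; ++e)
    if ((E->sgn[e] > 0) != (w[e] > 0)) stop("weight sign flip not allowed");
}

// [[Rcpp::export(name = ".net_state")]]
List net_state(SEXP xp) {
  Engine* E = get_engine(xp);
  return List::create(
    _["t"] = (double)E->t,
    _["vs"] = wrap(E->vs), _["vf"] = wrap(E->vf),
    _["Ss"] = wrap(E->Ss), _["Sf"] = wrap(E->Sf),
    _["Ts"] = wrap(E->Ts), _["Tf"] = wrap(E->Tf));
}
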