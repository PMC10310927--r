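// Clock-driven simulation engine: conductance-based LIF columns with
// reward-gated eligibility-trace plasticity.
//
// The engine advances a whole phase (n_trials x trial_ms) in one call so the
// per-step loop never crosses the R boundary.  All model content (populations,
// connection classes, plasticity constants, reward windows, stimulus events)
// is assembled on the R side; this file only integrates it.
//
// Units: ms, mV, nS, pF, pA throughout.  dt is the integration step (0.1 ms);
// plasticity (rate filter, traces, reward accumulation) runs on a coarser
// sub-grid (1 ms) since its time constants are two to four orders of
// magnitude slower than the membrane.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (xoshiro256++), independent of R's RNG so that a phase is
// reproducible from a single integer seed regardless of the calling context.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia polar method with cached spare
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

struct OutSyn {        // one synapse in the fan-out table of a neuron
  int target;
  int channel;         // 0 exc (slow), 1 inh, 2 exc input
  int cls;             // connection-class index
  int widx;            // index into the class weight vector
};

struct TraceSet {      // plasticity constants for one synapse family
  double tau_p, tau_d, eta_p, eta_d, Tmax_p, Tmax_d, r_th;
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_phase(List net, NumericMatrix input_events,
                   NumericMatrix reward_windows, int n_trials,
                   double trial_ms, bool plastic, double seed, List opts) {
  // ---- unpack model ------------------------------------------------------
  const int n_neurons = as<int>(net["n_neurons"]);
  IntegerVector pop_offset = net["pop_offset"];  // 0-based start index
  IntegerVector pop_size   = net["pop_size"];
  const int n_pops = pop_offset.size();

  List neu = net["neuron"];                      // per-population vectors
  NumericVector P_Cm = neu["C_m"],   P_gL = neu["g_L"],  P_Vrest = neu["V_rest"];
  NumericVector P_Vth = neu["V_th"], P_Vreset = neu["V_reset"], P_tref = neu["t_ref"];
  NumericVector P_Ee = neu["E_exc"], P_Ei = neu["E_inh"], P_sigma = neu["sigma_pA"];

  List syn = net["syn"];
  NumericVector tau_ch  = syn["tau"];            // length 3
  NumericVector gsat_ch = syn["g_sat"];          // length 3
  const double dt        = as<double>(syn["dt"]);
  const double delay_ms  = as<double>(syn["delay"]);
  const int delay_steps  = std::max(1, (int)std::lround(delay_ms / dt));

  List classes = net["classes"];
  const int n_classes = classes.size();
  std::vector<std::vector<int>>    cls_pre(n_classes), cls_post(n_classes);
  std::vector<std::vector<double>> cls_w(n_classes);
  std::vector<int>    cls_channel(n_classes), cls_traceset(n_classes);
  std::vector<double> cls_eta(n_classes);
  for (int c = 0; c < n_classes; ++c) {
    List cl = classes[c];
    IntegerVector pre = cl["pre"], post = cl["post"];
    NumericVector w = cl["w"];
    cls_pre[c]  = std::vector<int>(pre.begin(), pre.end());
    cls_post[c] = std::vector<int>(post.begin(), post.end());
    cls_w[c]    = std::vector<double>(w.begin(), w.end());
    cls_channel[c]  = as<int>(cl["channel"]);
    cls_traceset[c] = as<int>(cl["trace_set"]);  // -1 static, 0 recurrent, 1 ff
    cls_eta[c]      = as<double>(cl["eta_lr"]);
  }

  List plast = net["plast"];
  const double tau_r    = as<double>(plast["tau_r"]);
  const double tau_hebb = plast.containsElementNamed("tau_r_hebb")
    ? as<double>(plast["tau_r_hebb"]) : tau_r;
  const double pdt      = as<double>(plast["plast_dt"]);
  const int hebb_mode   = as<int>(plast["hebbian_mode"]);  // 0 rates, 1 product
  const double trace_refract = as<double>(plast["trace_refractory"]);
  const double rate_unit = 1e-6;  // Hz^2 -> (spk/ms)^2 inside the trace ODE
  TraceSet tset[2];
  {
    const char* nm[2] = {"rec", "ff"};
    for (int k = 0; k < 2; ++k) {
      List ts = plast[nm[k]];
      tset[k].tau_p = as<double>(ts["tau_p"]);   tset[k].tau_d = as<double>(ts["tau_d"]);
      tset[k].eta_p = as<double>(ts["eta_p"]);   tset[k].eta_d = as<double>(ts["eta_d"]);
      tset[k].Tmax_p = as<double>(ts["Tmax_p"]); tset[k].Tmax_d = as<double>(ts["Tmax_d"]);
      tset[k].r_th = as<double>(ts["r_th"]);
    }
  }
  // optional per-trial randomized learning parameters (columns:
  // tau_p, tau_d, eta_p, eta_d for rec then ff), absolute values
  NumericMatrix lp_trials;
  bool has_lp = false;
  if (opts.containsElementNamed("learning_params") &&
      !Rf_isNull(opts["learning_params"])) {
    lp_trials = as<NumericMatrix>(opts["learning_params"]);
    has_lp = true;
    if (lp_trials.nrow() != n_trials || lp_trials.ncol() != 8)
      stop("learning_params must be n_trials x 8");
  }

  // per-neuron external constant current (pA), optional
  std::vector<double> I_const(n_neurons, 0.0);
  if (opts.containsElementNamed("I_const") && !Rf_isNull(opts["I_const"])) {
    NumericVector ic = opts["I_const"];
    if (ic.size() == 1) std::fill(I_const.begin(), I_const.end(), ic[0]);
    else {
      if ((int)ic.size() != n_neurons) stop("I_const length mismatch");
      std::copy(ic.begin(), ic.end(), I_const.begin());
    }
  }
  const double noise_dt = opts.containsElementNamed("noise_dt")
    ? as<double>(opts["noise_dt"]) : 1.0;
  const int noise_steps = std::max(1, (int)std::lround(noise_dt / dt));
  const double runaway_limit = opts.containsElementNamed("runaway_limit")
    ? as<double>(opts["runaway_limit"]) : 500.0;

  // recording selections (1-based trial indices)
  std::vector<bool> rec_spk(n_trials, false), rec_rate(n_trials, false),
                    rec_log(n_trials, false);
  auto mark = [&](const char* key, std::vector<bool>& flag) {
    if (opts.containsElementNamed(key) && !Rf_isNull(opts[key])) {
      IntegerVector iv = opts[key];
      for (int i = 0; i < iv.size(); ++i)
        if (iv[i] >= 1 && iv[i] <= n_trials) flag[iv[i] - 1] = true;
    }
  };
  mark("record_spikes", rec_spk);
  mark("record_rates", rec_rate);
  mark("log_trials", rec_log);
  IntegerMatrix log_edges;  // k x 2: (class, edge), 1-based
  int n_log = 0;
  // optional single-neuron probe: V and conductances at every step (trial 1)
  int probe = -1;
  if (opts.containsElementNamed("probe_neuron") &&
      !Rf_isNull(opts["probe_neuron"]))
    probe = as<int>(opts["probe_neuron"]) - 1;
  if (opts.containsElementNamed("log_edges") && !Rf_isNull(opts["log_edges"])) {
    log_edges = as<IntegerMatrix>(opts["log_edges"]);
    n_log = log_edges.nrow();
  }

  // ---- derived structures ------------------------------------------------
  const int S = (int)std::lround(trial_ms / dt);
  if (std::fabs(S * dt - trial_ms) > 1e-9 * std::max(1.0, trial_ms))
    stop("trial duration must be a multiple of dt");
  const int sub = std::max(1, (int)std::lround(pdt / dt));
  const int n_bins = S / sub;

  // neuron -> population lookup
  std::vector<int> pop_of(n_neurons);
  for (int p = 0; p < n_pops; ++p)
    for (int i = 0; i < pop_size[p]; ++i) pop_of[pop_offset[p] + i] = p;

  // CSR fan-out table over all classes
  std::vector<int> out_ptr(n_neurons + 1, 0);
  {
    std::vector<int> deg(n_neurons, 0);
    for (int c = 0; c < n_classes; ++c)
      for (size_t e = 0; e < cls_pre[c].size(); ++e) deg[cls_pre[c][e]]++;
    for (int n = 0; n < n_neurons; ++n) out_ptr[n + 1] = out_ptr[n] + deg[n];
  }
  std::vector<OutSyn> out_syn(out_ptr[n_neurons]);
  {
    std::vector<int> cur(out_ptr.begin(), out_ptr.end() - 1);
    for (int c = 0; c < n_classes; ++c)
      for (size_t e = 0; e < cls_pre[c].size(); ++e) {
        int pre = cls_pre[c][e];
        out_syn[cur[pre]++] = OutSyn{cls_post[c][e], cls_channel[c], c, (int)e};
      }
  }

  // plastic-edge bookkeeping
  std::vector<int> plastic_classes;
  for (int c = 0; c < n_classes; ++c)
    if (cls_traceset[c] >= 0) plastic_classes.push_back(c);
  std::vector<std::vector<double>> Tp(n_classes), Td(n_classes), pend(n_classes);
  for (int c : plastic_classes) {
    size_t m = cls_pre[c].size();
    Tp[c].assign(m, 0.0); Td[c].assign(m, 0.0); pend[c].assign(m, 0.0);
  }

  // input events: sort by (trial, step)
  const int n_ev = input_events.nrow();
  std::vector<int> ev_order(n_ev);
  for (int i = 0; i < n_ev; ++i) ev_order[i] = i;
  std::sort(ev_order.begin(), ev_order.end(), [&](int a, int b) {
    if (input_events(a, 0) != input_events(b, 0))
      return input_events(a, 0) < input_events(b, 0);
    return input_events(a, 2) < input_events(b, 2);
  });

  // reward windows (per trial, trial-relative times), sorted, non-overlapping
  const int n_rw = reward_windows.nrow();
  {
    for (int i = 1; i < n_rw; ++i)
      if (reward_windows(i, 0) < reward_windows(i - 1, 1))
        stop("reward windows overlap");
  }

  // ---- state -------------------------------------------------------------
  std::vector<double> V(n_neurons), g0(n_neurons), g1(n_neurons), g2(n_neurons);
  std::vector<double> ref_until(n_neurons), xi(n_neurons, 0.0);
  std::vector<double> rate(n_neurons, 0.0);   // Hebbian-side per-neuron filter
  std::vector<double> pop_rate(n_pops, 0.0);  // recorded population filter
  std::vector<int> spk_cnt(n_neurons, 0);
  std::vector<unsigned char> above_rec(n_neurons), above_ff(n_neurons);
  const double dec0 = std::exp(-dt / tau_ch[0]), dec1 = std::exp(-dt / tau_ch[1]),
               dec2 = std::exp(-dt / tau_ch[2]);
  const double rate_dec = std::exp(-pdt / tau_hebb);
  const double rate_jump = 1000.0 / tau_hebb;   // spk/s added per spike
  const double prate_dec = std::exp(-pdt / tau_r);
  const double prate_jump = 1000.0 / tau_r;

  const int ring_sz = delay_steps + 2;
  std::vector<std::vector<int>> ring(ring_sz);

  Xoshiro rng((uint64_t)std::llround(seed));

  // ---- outputs -----------------------------------------------------------
  List out_spikes(n_trials), out_rates(n_trials), out_logs(n_trials);
  NumericMatrix probe_mat;
  if (probe >= 0) probe_mat = NumericMatrix((int)std::lround(trial_ms / dt), 4);
  NumericMatrix class_w_mean(n_trials, n_classes);
  NumericMatrix pop_spike_count(n_trials, n_pops);
  NumericMatrix trial_dw(n_trials, n_classes);  // mean committed dw per class

  // ---- run ---------------------------------------------------------------
  for (int trial = 0; trial < n_trials; ++trial) {
    // per-trial learning parameters
    TraceSet ts_trial[2] = {tset[0], tset[1]};
    if (has_lp) {
      for (int k = 0; k < 2; ++k) {
        ts_trial[k].tau_p = lp_trials(trial, 4 * k + 0);
        ts_trial[k].tau_d = lp_trials(trial, 4 * k + 1);
        ts_trial[k].eta_p = lp_trials(trial, 4 * k + 2);
        ts_trial[k].eta_d = lp_trials(trial, 4 * k + 3);
      }
    }
    // reset state at trial start
    for (int n = 0; n < n_neurons; ++n) {
      V[n] = P_Vrest[pop_of[n]];
      g0[n] = g1[n] = g2[n] = 0.0;
      ref_until[n] = -1.0;
      rate[n] = 0.0; spk_cnt[n] = 0; xi[n] = 0.0;
    }
    std::fill(pop_rate.begin(), pop_rate.end(), 0.0);
    for (auto& r : ring) r.clear();
    for (int c : plastic_classes) {
      std::fill(Tp[c].begin(), Tp[c].end(), 0.0);
      std::fill(Td[c].begin(), Td[c].end(), 0.0);
      std::fill(pend[c].begin(), pend[c].end(), 0.0);
    }
    double trace_ref_until = -1.0;
    int rw_idx = 0;

    // event window for this trial
    int ev_lo = 0;
    while (ev_lo < n_ev && input_events(ev_order[ev_lo], 0) < trial + 1) ++ev_lo;
    int ev_hi = ev_lo;
    while (ev_hi < n_ev && input_events(ev_order[ev_hi], 0) == trial + 1) ++ev_hi;
    int ev_cur = ev_lo;

    // recording buffers
    std::vector<int> spk_id;  std::vector<double> spk_t;
    NumericMatrix rates_mat;
    if (rec_rate[trial]) rates_mat = NumericMatrix(n_bins, n_pops);
    std::vector<NumericMatrix> logm;
    if (rec_log[trial] && n_log > 0)
      for (int k = 0; k < n_log; ++k) logm.push_back(NumericMatrix(n_bins, 4));
    std::vector<double> pop_cnt(n_pops, 0.0);
    int runaway_run = 0;

    for (int step = 0; step < S; ++step) {
      const double t = step * dt;

      // 1) deliver delayed network spikes
      {
        std::vector<int>& slot = ring[step % ring_sz];
        for (int pre : slot) {
          for (int si = out_ptr[pre]; si < out_ptr[pre + 1]; ++si) {
            const OutSyn& o = out_syn[si];
            double w = cls_w[o.cls][o.widx];
            switch (o.channel) {
              case 0: { double g = g0[o.target];
                        g += w * (1.0 - g / gsat_ch[0]);
                        g0[o.target] = g > gsat_ch[0] ? gsat_ch[0] : g; break; }
              case 1: { double g = g1[o.target];
                        g += w * (1.0 - g / gsat_ch[1]);
                        g1[o.target] = g > gsat_ch[1] ? gsat_ch[1] : g; break; }
              default:{ double g = g2[o.target];
                        g += w * (1.0 - g / gsat_ch[2]);
                        g2[o.target] = g > gsat_ch[2] ? gsat_ch[2] : g; break; }
            }
          }
        }
        slot.clear();
      }
      // 2) deliver external input events due at this step
      while (ev_cur < ev_hi) {
        int e = ev_order[ev_cur];
        int es = (int)std::lround(input_events(e, 2) / dt);
        if (es > step) break;
        int tgt = (int)input_events(e, 1) - 1;
        double w = input_events(e, 3);
        int ch = (int)input_events(e, 4);
        double* g = (ch == 0) ? g0.data() : (ch == 1) ? g1.data() : g2.data();
        double gv = g[tgt] + w * (1.0 - g[tgt] / gsat_ch[ch]);
        g[tgt] = gv > gsat_ch[ch] ? gsat_ch[ch] : gv;
        ++ev_cur;
      }
      // 3) refresh piecewise-constant noise
      if (step % noise_steps == 0) {
        for (int p = 0; p < n_pops; ++p) {
          double s = P_sigma[p];
          if (s > 0.0)
            for (int i = pop_offset[p]; i < pop_offset[p] + pop_size[p]; ++i)
              xi[i] = s * rng.norm();
        }
      }
      // 4) membrane update + threshold detection + conductance decay (fused;
      //    conductances are flushed to zero below 1e-12 nS to avoid denormals)
      for (int p = 0; p < n_pops; ++p) {
        const double alpha = dt / P_Cm[p];
        const double gL = P_gL[p], Vrest = P_Vrest[p], Vth = P_Vth[p];
        const double Vreset = P_Vreset[p], tref = P_tref[p];
        const double Ee = P_Ee[p], Ei = P_Ei[p];
        const int lo = pop_offset[p], hi = lo + pop_size[p];
        for (int n = lo; n < hi; ++n) {
          const double ge = g0[n], gi = g1[n], gin = g2[n];
          if (t >= ref_until[n]) {
            double v = V[n];
            v += alpha * (gL * (Vrest - v) + (ge + gin) * (Ee - v) +
                          gi * (Ei - v) + I_const[n] + xi[n]);
            if (v >= Vth) {
              // crossing registered one step later
              const double t_spk = t + dt;
              if (t_spk < trial_ms) {
                if (rec_spk[trial]) { spk_id.push_back(n + 1); spk_t.push_back(t_spk); }
                ring[(step + 1 + delay_steps) % ring_sz].push_back(n);
                spk_cnt[n]++; pop_cnt[p] += 1.0;
              }
              V[n] = Vreset;
              ref_until[n] = t_spk + tref;
            } else {
              if (!std::isfinite(v)) stop("non-finite membrane potential");
              V[n] = v;
            }
          }
          g0[n] = ge > 1e-12 ? ge * dec0 : 0.0;
          g1[n] = gi > 1e-12 ? gi * dec1 : 0.0;
          g2[n] = gin > 1e-12 ? gin * dec2 : 0.0;
        }
      }

      if (probe >= 0 && trial == 0) {
        probe_mat(step, 0) = V[probe];
        probe_mat(step, 1) = g0[probe];
        probe_mat(step, 2) = g1[probe];
        probe_mat(step, 3) = g2[probe];
      }
      // 6) plasticity / analysis sub-grid
      if ((step + 1) % sub == 0) {
        const int bin = (step + 1) / sub - 1;
        const double tb = (step + 1) * dt;  // end of this bin
        // per-neuron (Hebbian-side) and per-population (recorded) rate filters
        double maxm = 0.0;
        for (int p = 0; p < n_pops; ++p) {
          int cnt = 0;
          for (int i = pop_offset[p]; i < pop_offset[p] + pop_size[p]; ++i) {
            rate[i] = rate[i] * rate_dec + spk_cnt[i] * rate_jump;
            cnt += spk_cnt[i];
            spk_cnt[i] = 0;
          }
          pop_rate[p] = pop_rate[p] * prate_dec +
                        (prate_jump * cnt) / pop_size[p];
          if (rec_rate[trial]) rates_mat(bin, p) = pop_rate[p];
          if (pop_rate[p] > maxm) maxm = pop_rate[p];
        }
        if (runaway_limit > 0) {
          runaway_run = (maxm > runaway_limit) ? runaway_run + 1 : 0;
          if (runaway_run > 50)
            stop("runaway excitation: population rate above limit");
        }

        if (plastic) {
          // reward window bookkeeping (windows are trial-relative)
          if (rw_idx < n_rw && tb >= reward_windows(rw_idx, 1)) {
            // window just ended: consume traces, start trace refractory
            for (int c : plastic_classes) {
              std::fill(Tp[c].begin(), Tp[c].end(), 0.0);
              std::fill(Td[c].begin(), Td[c].end(), 0.0);
            }
            trace_ref_until = reward_windows(rw_idx, 1) + trace_refract;
            rw_idx++;
          }
          const bool in_refract = tb < trace_ref_until;
          bool in_reward = false;
          if (rw_idx < n_rw && tb > reward_windows(rw_idx, 0) &&
              tb <= reward_windows(rw_idx, 1))
            in_reward = true;

          if (!in_refract) {
            // per-neuron threshold flags
            for (int n = 0; n < n_neurons; ++n) {
              above_rec[n] = rate[n] > tset[0].r_th;
              above_ff[n]  = rate[n] > tset[1].r_th;
            }
            for (int c : plastic_classes) {
              const int k = cls_traceset[c];
              const TraceSet& T = ts_trial[k];
              const unsigned char* above = (k == 0) ? above_rec.data() : above_ff.data();
              const double r_th = T.r_th;
              std::vector<double>& tp = Tp[c];
              std::vector<double>& td = Td[c];
              std::vector<double>& pd = pend[c];
              const std::vector<int>& pre = cls_pre[c];
              const std::vector<int>& post = cls_post[c];
              const double ap = pdt / T.tau_p, ad = pdt / T.tau_d;
              const double eta_lr = cls_eta[c];
              const size_t m = pre.size();
              for (size_t e = 0; e < m; ++e) {
                double H = 0.0;
                const int i = pre[e], j = post[e];
                if (hebb_mode == 0) {
                  if (above[i] && above[j]) H = rate[i] * rate[j] * rate_unit;
                } else {
                  double pr = rate[i] * rate[j];
                  if (pr > r_th) H = pr * rate_unit;
                }
                double x = tp[e], y = td[e];
                if (H > 0.0 || x > 1e-12 || y > 1e-12) {
                  x += ap * (-x + T.eta_p * H * (T.Tmax_p - x));
                  y += ad * (-y + T.eta_d * H * (T.Tmax_d - y));
                  tp[e] = x < 0.0 ? 0.0 : (x > T.Tmax_p ? T.Tmax_p : x);
                  td[e] = y < 0.0 ? 0.0 : (y > T.Tmax_d ? T.Tmax_d : y);
                }
                if (in_reward) pd[e] += eta_lr * (tp[e] - td[e]) * pdt;
              }
            }
          } else if (in_reward) {
            // traces are frozen at zero; nothing accumulates
          }
        }

        // trace/rate logging for designated edges
        if (rec_log[trial] && n_log > 0) {
          for (int k = 0; k < n_log; ++k) {
            int c = log_edges(k, 0) - 1, e = log_edges(k, 1) - 1;
            logm[k](bin, 0) = rate[cls_pre[c][e]];
            logm[k](bin, 1) = rate[cls_post[c][e]];
            logm[k](bin, 2) = cls_traceset[c] >= 0 ? Tp[c][e] : NA_REAL;
            logm[k](bin, 3) = cls_traceset[c] >= 0 ? Td[c][e] : NA_REAL;
          }
        }
      }
    }  // step loop

    // ---- end of trial: commit, record ------------------------------------
    if (plastic) {
      for (int c : plastic_classes) {
        double dsum = 0.0;
        std::vector<double>& w = cls_w[c];
        std::vector<double>& pd = pend[c];
        for (size_t e = 0; e < w.size(); ++e) {
          dsum += pd[e];
          double nw = w[e] + pd[e];
          w[e] = nw < 0.0 ? 0.0 : nw;
          pd[e] = 0.0;
        }
        trial_dw(trial, c) = w.empty() ? 0.0 : dsum / w.size();
      }
    }
    for (int c = 0; c < n_classes; ++c) {
      double s = 0.0;
      for (double w : cls_w[c]) s += w;
      class_w_mean(trial, c) = cls_w[c].empty() ? 0.0 : s / cls_w[c].size();
    }
    for (int p = 0; p < n_pops; ++p) pop_spike_count(trial, p) = pop_cnt[p];
    if (rec_spk[trial]) {
      NumericMatrix sm(spk_id.size(), 2);
      for (size_t i = 0; i < spk_id.size(); ++i) {
        sm(i, 0) = spk_id[i]; sm(i, 1) = spk_t[i];
      }
      out_spikes[trial] = sm;
    }
    if (rec_rate[trial]) out_rates[trial] = rates_mat;
    if (rec_log[trial] && n_log > 0) {
      List lg(n_log);
      for (int k = 0; k < n_log; ++k) lg[k] = logm[k];
      out_logs[trial] = lg;
    }
    Rcpp::checkUserInterrupt();
  }  // trial loop

  List final_w(n_classes);
  for (int c = 0; c < n_classes; ++c)
    final_w[c] = NumericVector(cls_w[c].begin(), cls_w[c].end());

  NumericVector rate_times(n_bins);
  for (int b = 0; b < n_bins; ++b) rate_times[b] = (b + 1) * pdt;

  return List::create(
    _["spikes"] = out_spikes,
    _["rates"] = out_rates,
    _["rate_times"] = rate_times,
    _["class_w_mean"] = class_w_mean,
    _["trial_dw"] = trial_dw,
    _["pop_spike_count"] = pop_spike_count,
    _["final_weights"] = final_w,
    _["trace_logs"] = out_logs,
    _["probe"] = probe >= 0 ? (SEXP)probe_mat : R_NilValue);
}
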