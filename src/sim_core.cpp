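#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment lung coupled to a pressure-support ventilator state
// machine, integrated with explicit Euler on a fixed grid.
//
// Lung:  flow = (Paw - V/C + Pmus) / R      [L/s; V in L above relaxed FRC]
// Ventilator: first-order relaxation of Paw toward a state-dependent target
//   EXHALE : EPAP_eff                         (tau = fall_tau)
//   DELAY  : EPAP_eff - drop_gain * Pmus(t)   (tau = fall_tau)  [pre-trigger dip]
//   INHALE : IPAP_eff - comp_deficit(t)       (tau = rise_tau)
// comp_deficit models imperfect leak compensation: after a leak step of
// delta L/min at t0 the inspiratory target is depressed by
// comp_gain * delta * exp(-(t - t0)/leak_comp_tau).
//
// Cycling: inspiration ends when lung flow falls below cycle_fraction of the
// breath's peak inspiratory flow (after min_insp), or at max_insp.
// Backup: a machine breath is delivered when no inspiration has started for
// backup_interval seconds (<= 0 disables backup).

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n, double dt,
              NumericVector pmus,
              NumericVector effort_onsets,
              double ipap, double epap,
              double trigger_delay,
              double rise_tau, double fall_tau,
              double trigger_drop_gain,
              double cycle_fraction,
              double min_insp, double max_insp,
              double backup_interval, double backup_start_lag,
              double C, double Rres,
              NumericVector leak_times, NumericVector leak_deltas,
              double comp_gain, double leak_comp_tau) {
  NumericVector paw(n), flow(n), vol(n);
  std::vector<double> trig_t, cyc_t, machine_t, missed_t;

  const int EXH = 0, DELAY = 1, INH = 2;
  int state = EXH;
  double delay_end = -1.0;

  paw[0] = epap;
  vol[0] = C * epap;

  double last_insp_start = (backup_interval > 0.0)
    ? backup_start_lag - backup_interval : -1e18;
  double insp_start_t = -1e18, peak_flow = 0.0;
  int onset_ptr = 0, n_onsets = effort_onsets.size();
  int n_leaks = leak_times.size();

  for (int i = 0; i < n; ++i) {
    double t = i * dt;

    // patient effort onset
    while (onset_ptr < n_onsets && effort_onsets[onset_ptr] <= t) {
      if (state == EXH) {
        if (trigger_delay > 0.0) {
          state = DELAY;
          delay_end = effort_onsets[onset_ptr] + trigger_delay;
        } else {
          state = INH;
          insp_start_t = t;
          last_insp_start = t;
          peak_flow = 0.0;
          trig_t.push_back(t);
        }
      } else {
        missed_t.push_back(effort_onsets[onset_ptr]);
      }
      ++onset_ptr;
    }
    if (state == DELAY && t >= delay_end) {
      state = INH;
      insp_start_t = t;
      last_insp_start = t;
      peak_flow = 0.0;
      trig_t.push_back(t);
    }
    // backup (timed) breath
    if (state == EXH && backup_interval > 0.0 &&
        t - last_insp_start >= backup_interval) {
      state = INH;
      insp_start_t = t;
      last_insp_start = t;
      peak_flow = 0.0;
      machine_t.push_back(t);
    }

    // leak-compensation deficit (applied to the inspiratory target)
    double deficit = 0.0;
    for (int j = 0; j < n_leaks; ++j) {
      if (t >= leak_times[j])
        deficit += comp_gain * leak_deltas[j] *
          std::exp(-(t - leak_times[j]) / leak_comp_tau);
    }

    double q = (paw[i] - vol[i] / C + pmus[i]) / Rres;
    flow[i] = q;

    if (state == INH) {
      if (q > peak_flow) peak_flow = q;
      double insp_len = t - insp_start_t;
      if ((insp_len >= min_insp && peak_flow > 0.0 &&
           q < cycle_fraction * peak_flow) ||
          insp_len >= max_insp) {
        state = EXH;
        cyc_t.push_back(t);
      }
    }

    double target, tau;
    if (state == INH) {
      target = ipap - deficit;
      tau = rise_tau;
    } else if (state == DELAY) {
      target = epap - trigger_drop_gain * pmus[i];
      tau = fall_tau;
    } else {
      target = epap;
      tau = fall_tau;
    }

    if (i + 1 < n) {
      paw[i + 1] = paw[i] + dt * (target - paw[i]) / tau;
      vol[i + 1] = vol[i] + dt * q;
    }
  }

  return List::create(
    _["paw"] = paw, _["flow"] = flow, _["vol"] = vol,
    _["trigger_completions"] = wrap(trig_t),
    _["cycle_times"] = wrap(cyc_t),
    _["machine_breaths"] = wrap(machine_t),
    _["missed_efforts"] = wrap(missed_t));
}
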