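# Synthetic waveform builders used across the suite. All fixtures are built
# in code; nothing is read from disk.

# Square-wave flow: amp_in L/s for t_in seconds, amp_ex for t_ex seconds.
square_flow_recording <- function(duration = 60, amp_in = 0.5, t_in = 1,
                                  amp_ex = -0.25, t_ex = 5, sr = 512,
                                  paw_level = 4,
                                  cond = test_condition("LC", 10, 4)) {
  n <- round(duration * sr)
  t <- (seq_len(n) - 1) / sr
  phase <- t %% (t_in + t_ex)
  flow <- ifelse(phase < t_in, amp_in, amp_ex)
  recording(paw = rep(paw_level, n), flow = flow, sample_rate = sr,
            condition = cond)
}

# One breath with analytic exponential pressurization and release:
#   baseline epap for t_base, rise toward ipap with rise_tau for t_rise,
#   decay from the reached peak toward epap with fall_tau afterwards.
# Returns the recording, a hand-built segment and the condition.
exp_breath_fixture <- function(epap = 4, ipap = 10, rise_tau = 0.1,
                               fall_tau = 0.05, t_base = 0.5, t_rise = 2,
                               t_fall = 2, sr = 512,
                               phenotype = "LC") {
  dt <- 1 / sr
  n_base <- round(t_base * sr); n_rise <- round(t_rise * sr)
  n_fall <- round(t_fall * sr)
  tr <- (seq_len(n_rise) - 1) * dt
  rise <- ipap - (ipap - epap) * exp(-tr / rise_tau)
  ppeak <- rise[n_rise]
  tf <- seq_len(n_fall) * dt
  fall <- epap + (ppeak - epap) * exp(-tf / fall_tau)
  paw <- c(rep(epap, n_base), rise, fall)
  flow <- c(rep(0, n_base), rep(0.5, n_rise), rep(-0.2, n_fall))
  rec <- recording(paw = paw, flow = flow, sample_rate = sr,
                   condition = test_condition(phenotype, ipap, epap))
  seg <- data.frame(effort_onset_idx = n_base + 1L,
                    insp_start_idx = n_base + 1L,
                    insp_end_idx = n_base + n_rise,
                    exp_end_idx = n_base + n_rise + n_fall)
  list(rec = rec, seg = seg, cond = rec$condition, ppeak = ppeak,
       dt = dt)
}

# Trigger-time fixture at 500 Hz: baseline, a square dip of given depth that
# returns to baseline exactly `return_ms` after the effort onset, then a
# pressure rise so the breath looks ordinary.
trigger_dip_fixture <- function(baseline = 4, dip = 0.5, return_ms = 80,
                                sr = 500) {
  dt <- 1 / sr
  n_base <- round(0.5 * sr)
  n_dip <- round(return_ms / 1000 * sr)
  n_rise <- round(0.5 * sr)
  paw <- c(rep(baseline, n_base), rep(baseline - dip, n_dip),
           rep(10, n_rise), rep(baseline, n_base))
  flow <- c(rep(0, n_base), rep(0.4, n_dip + n_rise), rep(-0.2, n_base))
  rec <- recording(paw = paw, flow = flow, sample_rate = sr,
                   condition = test_condition("LC", 10, 4))
  seg <- data.frame(effort_onset_idx = n_base + 1L,
                    insp_start_idx = n_base + 1L,
                    insp_end_idx = n_base + n_dip + n_rise,
                    exp_end_idx = 2L * n_base + n_dip + n_rise)
  list(rec = rec, seg = seg, cond = rec$condition)
}
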