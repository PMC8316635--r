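#' Lung-model phenotype presets
#'
#' Returns the single-compartment mechanics and scripted-effort parameters of
#' the four simulated COVID-19 phenotypes:
#' * `LC` — low compliance, 20 ml/cmH2O;
#' * `IR` — increased airway resistance, 10 cmH2O/L/s;
#' * `LCIE` — low compliance with increased effort: rate 40/min, effort
#'   10 cmH2O;
#' * `HC` — high compliance, 50 ml/cmH2O.
#'
#' Fields the protocol leaves open take documented defaults (assumptions, not
#' measurements): resistance 5 cmH2O/L/s where not the phenotype's defining
#' feature, compliance 40 ml/cmH2O for IR, effort rate 15/min and amplitude
#' 10 cmH2O for LC/IR/HC, effort duration 0.8 s (0.6 s for LCIE's short
#' breaths).
#'
#' @param name Phenotype code.
#' @return An object of class `phenotype_model`: list with `compliance`
#'   (ml/cmH2O), `resistance` (cmH2O/L/s), `effort_rate` (breaths/min),
#'   `effort_amplitude` (cmH2O), `effort_duration` (s).
#' @examples
#' phenotype_preset("LCIE")
#' @export
phenotype_preset <- function(name = c("LC", "IR", "LCIE", "HC")) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("configuration error: unknown phenotype '",
                          paste(name, collapse = ","), "'", call. = FALSE))
  p <- switch(name,
    LC   = list(compliance = 20, resistance = 5, effort_rate = 15,
                effort_amplitude = 10, effort_duration = 0.8),
    IR   = list(compliance = 40, resistance = 10, effort_rate = 15,
                effort_amplitude = 10, effort_duration = 0.8),
    LCIE = list(compliance = 20, resistance = 5, effort_rate = 40,
                effort_amplitude = 10, effort_duration = 0.6),
    HC   = list(compliance = 50, resistance = 5, effort_rate = 15,
                effort_amplitude = 10, effort_duration = 0.8))
  p$name <- name
  stopifnot(p$effort_duration < 60 / p$effort_rate)
  class(p) <- "phenotype_model"
  p
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf(
    "<phenotype_model> %s: C %g ml/cmH2O, R %g cmH2O/L/s, effort %g cmH2O @ %g/min (%g s)\n",
    x$name, x$compliance, x$resistance, x$effort_amplitude, x$effort_rate,
    x$effort_duration))
  invisible(x)
}

#' Ventilator imperfection profile
#'
#' The knobs of the simulated pressure-support ventilator. Defaults describe a
#' competent but imperfect device; [ideal_profile()] describes a perfect one.
#'
#' @param trigger_delay Delay from effort onset to pressurization start, ms.
#' @param rise_tau,fall_tau Pressurization / release time constants, ms (a
#'   first-order device reaches T90 at `tau * ln 10`).
#' @param ipap_bias,epap_bias Systematic pressure delivery errors, cmH2O.
#' @param trigger_drop_gain Depth of the pre-trigger airway-pressure dip per
#'   unit muscle pressure (dimensionless).
#' @param cycle_fraction Fraction of peak inspiratory flow at which the device
#'   cycles to exhalation, in (0, 1).
#' @param leak_comp_tau Leak-compensation time constant, s: the
#'   pressure-support deficit after a leak step decays with this constant.
#' @param leak_comp_gain Inspiratory-pressure deficit per L/min of leak step,
#'   cmH2O/(L/min).
#' @param fio2_bias_60,fio2_bias_100 Oxygen under-delivery at the 60% / 100%
#'   settings, percentage points.
#' @param fio2_leak_dilution Additional oxygen loss per L/min of leak, as a
#'   fraction of the above-ambient concentration, per L/min.
#' @param noise_sd Gaussian pressure-sensor noise SD, cmH2O.
#' @param seed Integer seed for the noise stream (`NULL` = use current RNG).
#' @return An object of class `ventilator_profile`.
#' @export
ventilator_profile <- function(trigger_delay = 60, rise_tau = 80,
                               fall_tau = 60, ipap_bias = 0.3,
                               epap_bias = 0.2, trigger_drop_gain = 0.15,
                               cycle_fraction = 0.25, leak_comp_tau = 2,
                               leak_comp_gain = 0.04, fio2_bias_60 = 2,
                               fio2_bias_100 = 1, fio2_leak_dilution = 5e-4,
                               noise_sd = 0.05, seed = 1L) {
  stopifnot(rise_tau > 0, fall_tau > 0, leak_comp_tau > 0,
            cycle_fraction > 0, cycle_fraction < 1,
            noise_sd >= 0, trigger_delay >= 0)
  structure(list(trigger_delay = trigger_delay, rise_tau = rise_tau,
                 fall_tau = fall_tau, ipap_bias = ipap_bias,
                 epap_bias = epap_bias,
                 trigger_drop_gain = trigger_drop_gain,
                 cycle_fraction = cycle_fraction,
                 leak_comp_tau = leak_comp_tau,
                 leak_comp_gain = leak_comp_gain,
                 fio2_bias_60 = fio2_bias_60, fio2_bias_100 = fio2_bias_100,
                 fio2_leak_dilution = fio2_leak_dilution,
                 noise_sd = noise_sd, seed = seed),
            class = "ventilator_profile")
}

#' Perfect ventilator profile
#'
#' Zero trigger delay, fast pressurization (40 ms time constants, so T90 is
#' ~92 ms), exact pressures and oxygen, no pre-trigger dip, near-instant leak
#' compensation, late cycling (10% of peak flow, letting the device deliver
#' the full demanded volume), no noise.
#'
#' @param ... Overrides passed to [ventilator_profile()].
#' @return A `ventilator_profile`.
#' @export
ideal_profile <- function(...) {
  args <- modifyList(
    list(trigger_delay = 0, rise_tau = 40, fall_tau = 40, ipap_bias = 0,
         epap_bias = 0, trigger_drop_gain = 0, cycle_fraction = 0.1,
         leak_comp_tau = 0.05, leak_comp_gain = 0.04, fio2_bias_60 = 0,
         fio2_bias_100 = 0, fio2_leak_dilution = 0, noise_sd = 0, seed = 1L),
    list(...))
  do.call(ventilator_profile, args)
}

#' Simulate a bench recording
#'
#' Integrates a single-compartment lung (`flow = (Paw - V/C + Pmus)/R`)
#' against a pressure-support ventilator state machine with explicit Euler
#' steps on the acquisition grid (default 512 Hz), so simulated and analyzed
#' grids coincide. Patient effort is a train of half-sine muscle-pressure
#' pulses; the ventilator holds EPAP, dips during the trigger delay in
#' proportion to the effort, pressurizes toward IPAP with its rise time
#' constant, and cycles to exhalation at a fraction of peak inspiratory flow.
#' A backup machine breath is delivered at `backup_rate` when no effort
#' triggers (spontaneous-timed behaviour). Circuit leak follows an orifice law
#' `Q_leak = c * sqrt(Paw)` with `c` calibrated to deliver the scheduled
#' L/min at the mean applied pressure; because the ventilator is a pressure
#' source on the patient side, the leak enters the patient signals through
#' the leak-compensation deficit, which decays with `leak_comp_tau` after
#' each scheduled step.
#'
#' @param phen A [phenotype_preset()] (or phenotype name).
#' @param prof A [ventilator_profile()].
#' @param cond A [test_condition()]; its `leak_level` is the initial leak.
#' @param duration Recording length, s (>= 10).
#' @param leak_schedule Optional data.frame/matrix with columns `time`,
#'   `level` (L/min): leak steps during the trial.
#' @param backup_rate Backup breath rate, breaths/min (default 10).
#' @param sample_rate Acquisition rate, Hz (default 512).
#' @return An object of class `sim_output`: list with `recording` (pmus
#'   channel included), `event_log` (effort onsets, trigger completions,
#'   cycling times, machine breaths, missed efforts, leak changes) and
#'   `ground_truth` (configured parameter values and realized mean leak).
#' @examples
#' so <- simulate_recording("LCIE", ideal_profile(),
#'                          test_condition("LCIE", 20, 8), duration = 15)
#' nrow(segment_breaths(so$recording))
#' @export
simulate_recording <- function(phen, prof, cond, duration = 60,
                               leak_schedule = NULL, backup_rate = 10,
                               sample_rate = 512) {
  if (is.character(phen)) phen <- phenotype_preset(phen)
  stopifnot(inherits(phen, "phenotype_model"),
            inherits(prof, "ventilator_profile"),
            inherits(cond, "test_condition"))
  if (duration < 10) stop("duration must be >= 10 s", call. = FALSE)
  dt <- 1 / sample_rate
  C <- phen$compliance / 1000            # L/cmH2O
  Rres <- phen$resistance
  if (Rres * C < 4 * dt)
    stop("configuration error: unstable integration step (R*C < 4*dt); ",
         "increase resistance/compliance or the sample rate", call. = FALSE)
  for (tau in c(prof$rise_tau, prof$fall_tau) / 1000)
    if (tau < 2 * dt)
      stop("configuration error: pressure time constants must be >= 2 samples",
           call. = FALSE)
  n <- as.integer(round(duration * sample_rate))
  tgrid <- (seq_len(n) - 1) * dt

  # scripted effort: half-sine pulses starting 0.4 s into the trial
  onsets <- numeric(0)
  if (phen$effort_amplitude > 0) {
    period <- 60 / phen$effort_rate
    onsets <- seq(0.4, duration - dt, by = period)
  }
  pmus <- numeric(n)
  for (t0 in onsets) {
    idx <- which(tgrid >= t0 & tgrid < t0 + phen$effort_duration)
    pmus[idx] <- pmus[idx] +
      phen$effort_amplitude * sin(pi * (tgrid[idx] - t0) / phen$effort_duration)
  }

  # leak schedule -> compensation-deficit events (deltas in L/min)
  lev0 <- cond$leak_level
  lk_t <- numeric(0); lk_delta <- numeric(0); lk_level <- numeric(0)
  if (!is.null(leak_schedule)) {
    ls <- as.data.frame(leak_schedule)
    stopifnot(all(c("time", "level") %in% names(ls)))
    ls <- ls[order(ls$time), , drop = FALSE]
    prev <- lev0
    for (r in seq_len(nrow(ls))) {
      lk_t <- c(lk_t, ls$time[r])
      lk_delta <- c(lk_delta, ls$level[r] - prev)
      lk_level <- c(lk_level, ls$level[r])
      prev <- ls$level[r]
    }
  }

  max_insp <- if (length(onsets))
    min(3, 0.8 * 60 / phen$effort_rate) else 3
  res <- .sim_core(
    n = n, dt = dt, pmus = pmus, effort_onsets = onsets,
    ipap = cond$ipap_set + prof$ipap_bias,
    epap = cond$epap_set + prof$epap_bias,
    trigger_delay = prof$trigger_delay / 1000,
    rise_tau = prof$rise_tau / 1000, fall_tau = prof$fall_tau / 1000,
    trigger_drop_gain = prof$trigger_drop_gain,
    cycle_fraction = prof$cycle_fraction,
    min_insp = 0.1, max_insp = max_insp,
    backup_interval = if (backup_rate > 0) 60 / backup_rate else 0,
    backup_start_lag = 0.5,
    C = C, Rres = Rres,
    leak_times = lk_t, leak_deltas = lk_delta,
    comp_gain = prof$leak_comp_gain, leak_comp_tau = prof$leak_comp_tau)

  paw <- res$paw
  if (prof$noise_sd > 0)
    paw <- paw + with_local_seed(prof$seed, rnorm(n, 0, prof$noise_sd))

  rec <- recording(paw = paw, flow = res$flow,
                   volume = (res$vol - res$vol[1]) * 1000,
                   pmus = pmus, sample_rate = sample_rate,
                   condition = cond)

  # orifice-law leak bookkeeping: c calibrated at the mean applied pressure
  pmean <- (cond$ipap_set + cond$epap_set) / 2
  leak_coef <- if (lev0 > 0) (lev0 / 60) / sqrt(pmean) else 0
  realized_leak <- mean(leak_coef * sqrt(pmax(res$paw, 0))) * 60

  structure(list(
    recording = rec,
    event_log = list(effort_onsets = onsets,
                     trigger_completions = res$trigger_completions,
                     cycle_times = res$cycle_times,
                     machine_breaths = res$machine_breaths,
                     missed_efforts = res$missed_efforts,
                     leak_changes = if (length(lk_t))
                       data.frame(time = lk_t, level = lk_level,
                                  delta = lk_delta)
                     else NULL),
    ground_truth = list(phenotype = phen, profile = prof, condition = cond,
                        duration = duration, sample_rate = sample_rate,
                        initial_leak_lpm = lev0,
                        realized_mean_leak_lpm = realized_leak)),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %s, %g s, %d efforts, %d triggered, %d machine breaths\n",
              x$ground_truth$phenotype$name, x$ground_truth$duration,
              length(x$event_log$effort_onsets),
              length(x$event_log$trigger_completions),
              length(x$event_log$machine_breaths)))
  invisible(x)
}

#' Simulated delivered oxygen concentration
#'
#' Deterministic scalar oxygen model: the delivered fraction is the setting
#' minus the profile's setting-specific bias (linearly interpolated between
#' the 60% and 100% calibration points) minus a leak dilution proportional to
#' the leak level and the above-ambient concentration,
#' `dilution = fio2_leak_dilution * leak_level * (set - 0.21)`, clipped to
#' `[0.21, 1]`.
#'
#' @param fio2_set Set fraction in (0.21, 1].
#' @param prof A [ventilator_profile()].
#' @param cond A [test_condition()] (supplies the leak level).
#' @return Delivered oxygen fraction.
#' @export
simulate_oxygen_delivery <- function(fio2_set, prof, cond) {
  stopifnot(inherits(prof, "ventilator_profile"),
            inherits(cond, "test_condition"))
  if (fio2_set <= 0.21 || fio2_set > 1)
    stop("fio2_set must lie in (0.21, 1]", call. = FALSE)
  bias_pts <- approx(x = c(0.60, 1.00),
                     y = c(prof$fio2_bias_60, prof$fio2_bias_100),
                     xout = min(max(fio2_set, 0.60), 1.00), rule = 2)$y
  dilution <- prof$fio2_leak_dilution * cond$leak_level * (fio2_set - 0.21)
  min(1, max(0.21, fio2_set - bias_pts / 100 - dilution))
}

#' Leak levels of the default protocol
#'
#' @param circuit `"single"` (intentional-leak NIV circuits: 50/70/90 L/min)
#'   or `"double"` (ICU ventilators in NIV mode: 14/19/25 L/min).
#' @return Numeric vector of three leak levels, L/min.
#' @export
protocol_leak_levels <- function(circuit = c("single", "double")) {
  switch(match.arg(circuit), single = c(50, 70, 90), double = c(14, 19, 25))
}

protocol_presets <- function() list(c(10, 4), c(20, 8), c(30, 12))

#' Run the full bench protocol on the simulator
#'
#' Generates the default test matrix: for each phenotype and each IPAP/EPAP
#' preset (10/4, 20/8, 30/12 cmH2O), one steady trial at baseline and at each
#' of the three circuit leak levels (4 phenotypes x 3 presets x 4 levels = 48
#' steady recordings), plus two dedicated leak-step trials per preset (one
#' upward step from baseline to the middle leak level, one downward step
#' back) for settle-time analysis. Deterministic under a fixed seed: each
#' trial's noise stream is seeded from `seed` plus a trial counter.
#'
#' @param phenotypes Phenotype names to include.
#' @param prof A [ventilator_profile()].
#' @param circuit `"single"` or `"double"`.
#' @param duration Steady-trial length, s.
#' @param step_duration,step_time Leak-step trial length and step time, s.
#' @param seed Base seed for the per-trial noise streams (default: the
#'   profile's seed).
#' @return A list of `sim_output` objects; each carries a `trial` attribute
#'   with `type` (`"steady"`, `"step_increase"`, `"step_decrease"`),
#'   `phenotype`, `preset` and `leak_level`.
#' @export
run_protocol <- function(phenotypes = c("LC", "IR", "LCIE", "HC"),
                         prof = ventilator_profile(),
                         circuit = c("single", "double"),
                         duration = 60, step_duration = 90, step_time = 30,
                         seed = prof$seed) {
  circuit <- match.arg(circuit)
  levels <- protocol_leak_levels(circuit)
  out <- list()
  counter <- 0L
  for (ph in phenotypes) {
    phen <- phenotype_preset(ph)
    for (pp in protocol_presets()) {
      for (lv in c(0, levels)) {
        counter <- counter + 1L
        p <- prof
        if (!is.null(seed)) p$seed <- seed + counter
        cond <- test_condition(ph, pp[1], pp[2], leak_level = lv,
                               circuit = circuit)
        so <- simulate_recording(phen, p, cond, duration = duration)
        attr(so, "trial") <- list(type = "steady", phenotype = ph,
                                  preset = preset_key(pp[1], pp[2]),
                                  leak_level = lv)
        out[[length(out) + 1L]] <- so
      }
      mid <- levels[2]
      for (dir in c("increase", "decrease")) {
        counter <- counter + 1L
        p <- prof
        if (!is.null(seed)) p$seed <- seed + counter
        start_lv <- if (dir == "increase") 0 else mid
        end_lv <- if (dir == "increase") mid else 0
        cond <- test_condition(ph, pp[1], pp[2], leak_level = start_lv,
                               circuit = circuit)
        so <- simulate_recording(
          phen, p, cond, duration = step_duration,
          leak_schedule = data.frame(time = step_time, level = end_lv))
        attr(so, "trial") <- list(type = paste0("step_", dir),
                                  phenotype = ph,
                                  preset = preset_key(pp[1], pp[2]),
                                  leak_level = end_lv,
                                  step_time = step_time)
        out[[length(out) + 1L]] <- so
      }
    }
  }
  out
}
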