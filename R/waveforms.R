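#' Segment a recording into breaths
#'
#' Breath boundaries are detected on the flow channel: inspiration starts at an
#' upward crossing of the threshold `theta` that is sustained for at least
#' `min_phase` seconds (hysteresis debounce), and ends at the following
#' downward crossing. Expiration runs until the next inspiration start (or the
#' end of the record). The effort onset is taken from the muscle-pressure
#' channel when present (first sample of the contiguous run, above 2% of the
#' breath's `pmus` maximum, containing that maximum); otherwise from the start
#' of the airway-pressure deflection below baseline that precedes triggering.
#'
#' Indices are 1-based sample indices into the recording, with
#' `effort_onset_idx <= insp_start_idx < insp_end_idx < exp_end_idx`.
#'
#' @param rec A [recording()].
#' @param theta Flow threshold for phase detection, L/s (default 0.033, i.e.
#'   2 L/min, debouncing sensor noise without missing short high-rate breaths).
#' @param min_phase Minimum duration flow must stay above `theta` for a valid
#'   inspiration, seconds.
#' @return A data.frame with one row per breath and columns
#'   `effort_onset_idx`, `insp_start_idx`, `insp_end_idx`, `exp_end_idx`.
#'   Zero rows when no breath is detected.
#' @export
segment_breaths <- function(rec, theta = 0.033, min_phase = 0.1) {
  stopifnot(inherits(rec, "vent_recording"))
  flow <- rec$flow
  n <- length(flow)
  n_min <- max(1L, as.integer(round(min_phase * rec$sample_rate)))
  above <- flow > theta

  rises <- which(above & !c(FALSE, above[-n]))
  starts <- ends <- integer(0)
  for (s in rises) {
    # sustained-above requirement (hysteresis)
    run_end <- s
    while (run_end < n && above[run_end + 1L]) run_end <- run_end + 1L
    if (run_end - s + 1L < n_min) next
    starts <- c(starts, s)
    ends <- c(ends, run_end)          # last sample with flow > theta
  }
  if (!length(starts))
    return(data.frame(effort_onset_idx = integer(0),
                      insp_start_idx = integer(0),
                      insp_end_idx = integer(0),
                      exp_end_idx = integer(0)))

  exp_end <- c(starts[-1L] - 1L, n)
  keep <- ends < exp_end              # need a non-empty expiratory phase
  starts <- starts[keep]; ends <- ends[keep]; exp_end <- exp_end[keep]
  if (!length(starts))
    return(data.frame(effort_onset_idx = integer(0),
                      insp_start_idx = integer(0),
                      insp_end_idx = integer(0),
                      exp_end_idx = integer(0)))

  prev_end <- c(1L, ends[-length(ends)])
  onset <- integer(length(starts))
  for (k in seq_along(starts)) {
    onset[k] <- min(starts[k],
                    detect_effort_onset(rec, prev_end[k], starts[k], ends[k]))
  }
  data.frame(effort_onset_idx = onset, insp_start_idx = starts,
             insp_end_idx = ends, exp_end_idx = exp_end)
}

detect_effort_onset <- function(rec, window_start, insp_start, insp_end) {
  if (!is.null(rec$pmus)) {
    w <- window_start:insp_end
    pm <- rec$pmus[w]
    pk <- max(pm)
    if (pk > 0) {
      im <- w[which.max(pm)]
      thr <- 0.02 * pk
      j <- im
      while (j > window_start && rec$pmus[j - 1L] > thr) j <- j - 1L
      return(j)
    }
  }
  # fall back on the airway-pressure downward deflection: provisional baseline
  # from the pre-inspiratory window, robust to the dip itself via the median
  sr <- rec$sample_rate
  w0 <- max(window_start, insp_start - as.integer(round(0.5 * sr)))
  if (w0 >= insp_start) return(insp_start)
  base <- median(rec$paw[w0:(insp_start - 1L)])
  j <- insp_start
  while (j > w0 && rec$paw[j - 1L] < base - 0.05) j <- j - 1L
  if (j == insp_start && rec$paw[insp_start] >= base - 0.05) insp_start else j
}

# Baseline EPAP estimate: median airway pressure over the final 100 ms before
# the effort onset.
baseline_epap <- function(rec, onset_idx) {
  n100 <- max(1L, as.integer(round(0.1 * rec$sample_rate)))
  lo <- max(1L, onset_idx - n100)
  hi <- max(1L, onset_idx - 1L)
  if (hi < lo) return(rec$paw[onset_idx])
  median(rec$paw[lo:hi])
}

check_segment <- function(rec, seg) {
  n <- length(rec$paw)
  with(seg, {
    if (!(effort_onset_idx <= insp_start_idx &&
          insp_start_idx < insp_end_idx && insp_end_idx < exp_end_idx &&
          effort_onset_idx >= 1 && exp_end_idx <= n))
      stop("invalid breath segment", call. = FALSE)
  })
  invisible(TRUE)
}

#' Per-breath timing features
#'
#' Computes the three reaction-timing parameters of one breath, all in
#' milliseconds and quantized to the sample grid:
#' * `trigger_time` — from the effort onset until airway pressure has returned
#'   to baseline (within 0.05 cmH2O) after its downward deflection;
#' * `insp_t90` — from the upward baseline crossing until pressure reaches 90%
#'   of the rise from set EPAP to set IPAP;
#' * `exp_t90` — from the inspiratory pressure peak until 90% of the drop from
#'   that peak toward set EPAP is accomplished.
#'
#' A feature whose threshold is never reached within the breath is returned as
#' `NA` with a warning, and is excluded from scoring means downstream.
#'
#' @param rec A [recording()].
#' @param seg One row of [segment_breaths()] output (list or 1-row data.frame).
#' @param cond A [test_condition()] supplying set IPAP/EPAP.
#' @return Named list with `trigger_time`, `insp_t90`, `exp_t90` (ms) and the
#'   `baseline` pressure estimate (cmH2O).
#' @export
compute_timing_features <- function(rec, seg, cond) {
  check_segment(rec, seg)
  paw <- rec$paw; tm <- rec$time
  onset <- seg$effort_onset_idx
  base <- baseline_epap(rec, onset)

  # minimum of the trigger deflection, then first return to baseline
  dip_rng <- onset:seg$insp_end_idx
  imin <- dip_rng[which.min(paw[dip_rng])]
  ret_rng <- imin:seg$exp_end_idx
  iret <- ret_rng[which(paw[ret_rng] >= base - 0.05)[1L]]
  trigger_time <- if (is.na(iret)) NA_real_ else (tm[iret] - tm[onset]) * 1000

  thr90 <- cond$epap_set + 0.9 * (cond$ipap_set - cond$epap_set)
  insp_t90 <- NA_real_
  if (!is.na(iret)) {
    rng <- iret:seg$exp_end_idx
    i90 <- rng[which(paw[rng] >= thr90)[1L]]
    if (!is.na(i90)) insp_t90 <- (tm[i90] - tm[iret]) * 1000
  }

  ins <- seg$insp_start_idx:seg$insp_end_idx
  ipk <- ins[which.max(paw[ins])]
  ppeak <- paw[ipk]
  thr_fall <- ppeak - 0.9 * (ppeak - cond$epap_set)
  rng <- ipk:seg$exp_end_idx
  i10 <- rng[which(paw[rng] <= thr_fall)[1L]]
  exp_t90 <- if (is.na(i10)) NA_real_ else (tm[i10] - tm[ipk]) * 1000

  if (anyNA(c(trigger_time, insp_t90, exp_t90)))
    warning("timing threshold not reached within breath; feature(s) flagged missing",
            call. = FALSE)
  list(trigger_time = trigger_time, insp_t90 = insp_t90,
       exp_t90 = exp_t90, baseline = base)
}

#' Per-breath pressure-stability features
#'
#' * `max_pressure_drop` — depth of the airway-pressure dip below the baseline
#'   EPAP between the effort onset and the trigger window (default 300 ms past
#'   inspiration start), cmH2O, floored at 0;
#' * `ipap_error` — absolute difference between the inspiratory pressure peak
#'   and the set IPAP;
#' * `epap_error` — absolute difference between the end-expiratory pressure
#'   (mean over the final 50 ms of expiration) and the set EPAP.
#'
#' @inheritParams compute_timing_features
#' @param trigger_window Length of the post-inspiration-start window searched
#'   for the trigger dip, seconds.
#' @return Named list with `max_pressure_drop`, `ipap_error`, `epap_error`
#'   (all cmH2O, >= 0).
#' @export
compute_pressure_features <- function(rec, seg, cond, trigger_window = 0.3) {
  check_segment(rec, seg)
  paw <- rec$paw
  onset <- seg$effort_onset_idx
  base <- baseline_epap(rec, onset)

  hi <- min(seg$insp_end_idx,
            seg$insp_start_idx + as.integer(round(trigger_window * rec$sample_rate)))
  drop <- max(0, base - min(paw[onset:hi]))

  ins <- seg$insp_start_idx:seg$insp_end_idx
  ipap_error <- abs(max(paw[ins]) - cond$ipap_set)

  n50 <- max(1L, as.integer(round(0.05 * rec$sample_rate)))
  lo <- max(seg$insp_end_idx + 1L, seg$exp_end_idx - n50 + 1L)
  epap_error <- abs(mean(paw[lo:seg$exp_end_idx]) - cond$epap_set)

  list(max_pressure_drop = drop, ipap_error = ipap_error,
       epap_error = epap_error)
}

#' Per-breath volume features
#'
#' Tidal volume is the trapezoidal integral of positive patient-side flow over
#' the inspiratory phase (ml); leak flow never enters it because the recording
#' holds lung-side flow. The peak-flow rising ratio is the peak inspiratory
#' flow (L/s) divided by `insp_t90` (s), an index of pressurization
#' aggressiveness.
#'
#' @inheritParams compute_timing_features
#' @param insp_t90 The breath's `insp_t90` in ms (from
#'   [compute_timing_features()]); `NA` flags the ratio as missing.
#' @return Named list with `tidal_volume` (ml) and `peak_flow_rising_ratio`
#'   (L/s^2, `NA` when `insp_t90` is missing or zero).
#' @export
compute_volume_features <- function(rec, seg, insp_t90) {
  check_segment(rec, seg)
  idx <- seg$insp_start_idx:seg$insp_end_idx
  f <- pmax(rec$flow[idx], 0)
  tm <- rec$time[idx]
  tv <- sum(diff(tm) * (f[-1] + f[-length(f)]) / 2) * 1000
  ratio <- if (is.null(insp_t90) || is.na(insp_t90) || insp_t90 <= 0)
    NA_real_ else max(f) / (insp_t90 / 1000)
  list(tidal_volume = tv, peak_flow_rising_ratio = ratio)
}

#' Interquartile-range outlier filter
#'
#' Drops values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, preserving order.
#' Quartiles use linear interpolation between order statistics (quantile
#' type 7), so results are reproducible. Inputs shorter than 4 are returned
#' unchanged (quartiles are not meaningful there).
#'
#' @param values Numeric vector; must be finite.
#' @return The filtered vector (order preserved).
#' @examples
#' remove_outliers(c(480, 500, 510, 505, 495, 900))
#' @export
remove_outliers <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (length(values) < 4) return(values)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

#' Select equilibrium breaths
#'
#' Picks `k` consecutive non-outlier breaths for analysis: tidal-volume
#' outliers (1.5 IQR rule) are removed first, then the window of `k`
#' consecutive remaining breaths with the smallest coefficient of variation of
#' tidal volume is returned; ties break toward the latest window, so a steady
#' recording yields its final `k` breaths.
#'
#' @param features A data.frame of per-breath features containing a
#'   `tidal_volume` column (e.g. from [analyze_recording()]).
#' @param k Number of breaths to select (default 5).
#' @return `k` rows of `features`, in time order.
#' @export
select_equilibrium_breaths <- function(features, k = 5) {
  stopifnot(is.data.frame(features), "tidal_volume" %in% names(features))
  tv <- features$tidal_volume
  kept_tv <- remove_outliers(tv)
  # map back to rows: drop, in order, the rows whose TV was filtered out
  keep_idx <- seq_along(tv)
  if (length(kept_tv) < length(tv)) {
    q <- quantile(tv, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep_idx <- which(tv >= q[1] - 1.5 * iqr & tv <= q[2] + 1.5 * iqr)
  }
  if (length(keep_idx) < k)
    stop(sprintf("insufficient data: %d usable breaths, need %d",
                 length(keep_idx), k), call. = FALSE)
  best <- NULL; best_cv <- Inf
  for (s in seq_len(length(keep_idx) - k + 1L)) {
    w <- keep_idx[s:(s + k - 1L)]
    v <- tv[w]
    cv <- sd(v) / mean(v)
    if (cv <= best_cv + 1e-12) { best <- w; best_cv <- min(best_cv, cv) }
  }
  features[best, , drop = FALSE]
}

#' Extract all per-breath features from a recording
#'
#' Convenience wrapper: segments the recording and computes the eight
#' per-breath performance parameters for every breath.
#'
#' @param rec A [recording()] whose `condition` is set (or pass `cond`).
#' @param cond Optional [test_condition()] overriding `rec$condition`.
#' @param ... Passed to [segment_breaths()].
#' @return A data.frame with one row per breath: the segment indices,
#'   `onset_time`/`insp_start_time` (s) and the eight features
#'   (`tidal_volume`, `peak_flow_rising_ratio`, `trigger_time`,
#'   `max_pressure_drop`, `insp_t90`, `exp_t90`, `ipap_error`, `epap_error`).
#' @export
analyze_recording <- function(rec, cond = NULL, ...) {
  stopifnot(inherits(rec, "vent_recording"))
  if (is.null(cond)) cond <- rec$condition
  if (is.null(cond))
    stop("no test_condition available for this recording", call. = FALSE)
  segs <- segment_breaths(rec, ...)
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    seg <- segs[k, ]
    timing <- withCallingHandlers(
      compute_timing_features(rec, seg, cond),
      warning = function(w) invokeRestart("muffleWarning"))
    pres <- compute_pressure_features(rec, seg, cond)
    vol <- compute_volume_features(rec, seg, timing$insp_t90)
    out[[k]] <- data.frame(
      seg,
      onset_time = rec$time[seg$effort_onset_idx],
      insp_start_time = rec$time[seg$insp_start_idx],
      tidal_volume = vol$tidal_volume,
      peak_flow_rising_ratio = vol$peak_flow_rising_ratio,
      trigger_time = timing$trigger_time,
      max_pressure_drop = pres$max_pressure_drop,
      insp_t90 = timing$insp_t90,
      exp_t90 = timing$exp_t90,
      ipap_error = pres$ipap_error,
      epap_error = pres$epap_error)
  }
  if (!length(out)) {
    return(data.frame(effort_onset_idx = integer(0), insp_start_idx = integer(0),
                      insp_end_idx = integer(0), exp_end_idx = integer(0),
                      onset_time = numeric(0), insp_start_time = numeric(0),
                      tidal_volume = numeric(0), peak_flow_rising_ratio = numeric(0),
                      trigger_time = numeric(0), max_pressure_drop = numeric(0),
                      insp_t90 = numeric(0), exp_t90 = numeric(0),
                      ipap_error = numeric(0), epap_error = numeric(0)))
  }
  do.call(rbind, out)
}
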