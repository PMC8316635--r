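test_that("square-wave flow yields one segment per period, silence yields none", {
  rec <- square_flow_recording(duration = 60, t_in = 1, t_ex = 5)
  segs <- segment_breaths(rec)
  expect_equal(nrow(segs), 10)
  # ordered, non-overlapping, valid index chains
  expect_true(all(diff(segs$insp_start_idx) > 0))
  expect_true(all(segs$effort_onset_idx <= segs$insp_start_idx))
  expect_true(all(segs$insp_start_idx < segs$insp_end_idx))
  expect_true(all(segs$insp_end_idx < segs$exp_end_idx))
  expect_true(all(segs$insp_start_idx[-1] > head(segs$exp_end_idx, -1)))

  silent <- recording(paw = rep(4, 512 * 60), flow = rep(0, 512 * 60))
  expect_equal(nrow(segment_breaths(silent)), 0)
})

test_that("sub-threshold and too-short flow excursions are debounced", {
  n <- 512 * 10
  flow <- rep(0, n)
  flow[1000:1010] <- 0.5            # ~21 ms burst, shorter than min_phase
  flow[3000:3300] <- 0.02           # below the 2 L/min threshold
  rec <- recording(paw = rep(4, n), flow = flow)
  expect_equal(nrow(segment_breaths(rec)), 0)
})

test_that("T90 timing features match the analytic exponential solution", {
  fx <- exp_breath_fixture(epap = 4, ipap = 10, rise_tau = 0.1,
                           fall_tau = 0.05)
  tf <- compute_timing_features(fx$rec, fx$seg, fx$cond)
  tol_ms <- 1000 / 512           # one sample
  expect_lt(abs(tf$insp_t90 - 100 * log(10)), tol_ms + 1e-9)
  expect_lt(abs(tf$exp_t90 - 50 * log(10)), tol_ms + 1e-9)
  # timing features sit on the sample grid
  expect_equal(tf$insp_t90 %% (1000 / 512), 0, tolerance = 1e-6)

  # second fixture at the scale of a pressure-support release from 20 to 8
  fx2 <- exp_breath_fixture(epap = 8, ipap = 20, rise_tau = 0.1,
                            fall_tau = 0.05)
  tf2 <- compute_timing_features(fx2$rec, fx2$seg, fx2$cond)
  expect_lt(abs(tf2$exp_t90 - 50 * log(10)), tol_ms + 1e-9)
})

test_that("trigger time is the return of pressure to baseline after the dip", {
  fx <- trigger_dip_fixture(baseline = 4, dip = 0.5, return_ms = 80, sr = 500)
  tf <- compute_timing_features(fx$rec, fx$seg, fx$cond)
  expect_equal(tf$trigger_time, 80)
  expect_equal(tf$baseline, 4)
})

test_that("timing thresholds never reached are flagged missing with a warning", {
  fx <- exp_breath_fixture(epap = 4, ipap = 10, rise_tau = 0.1, t_rise = 0.1)
  # truncate the rise long before 90% is reached
  expect_warning(tf <- compute_timing_features(fx$rec, fx$seg, fx$cond),
                 "missing")
  expect_true(is.na(tf$insp_t90))
})

test_that("pressure features recover drop, IPAP error and EPAP error", {
  sr <- 512
  n_base <- round(0.5 * sr)
  paw <- c(rep(4, n_base),                 # baseline
           rep(2.5, 20),                   # trigger dip to 2.5
           rep(19.2, 400),                 # inspiratory plateau (Ppeak)
           rep(4.6, 300))                  # expiration, ends at 4.6
  flow <- c(rep(0, n_base), rep(0.5, 420), rep(-0.2, 300))
  rec <- recording(paw = paw, flow = flow,
                   condition = test_condition("LC", 20, 4))
  seg <- data.frame(effort_onset_idx = n_base + 1L,
                    insp_start_idx = n_base + 1L,
                    insp_end_idx = n_base + 420L,
                    exp_end_idx = n_base + 720L)
  pf <- compute_pressure_features(rec, seg, rec$condition)
  expect_equal(pf$max_pressure_drop, 1.5)
  expect_equal(pf$ipap_error, 0.8)
  expect_equal(pf$epap_error, 0.6)
})

test_that("tidal volume matches closed-form integrals of standard flow shapes", {
  sr <- 512
  # constant 0.5 L/s for 1 s -> 500 ml
  fx <- list()
  n_base <- sr %/% 2
  flow <- c(rep(0, n_base), rep(0.5, sr), rep(-0.25, 2 * sr))
  rec <- recording(paw = rep(4, length(flow)), flow = flow,
                   condition = test_condition("LC", 10, 4))
  seg <- segment_breaths(rec)[1, ]
  vf <- compute_volume_features(rec, seg, insp_t90 = 200)
  expect_equal(vf$tidal_volume, 500, tolerance = 2.5 / 500)
  expect_equal(vf$peak_flow_rising_ratio, 0.5 / 0.2)

  # triangular, peak 1 L/s over 1 s -> 500 ml within 0.5%
  tri <- c(seq(0, 1, length.out = sr %/% 2), seq(1, 0, length.out = sr %/% 2))
  flow2 <- c(rep(0, n_base), tri, rep(-0.25, 2 * sr))
  rec2 <- recording(paw = rep(4, length(flow2)), flow = flow2,
                    condition = test_condition("LC", 10, 4))
  seg2 <- segment_breaths(rec2)[1, ]
  vf2 <- compute_volume_features(rec2, seg2, insp_t90 = 200)
  expect_equal(vf2$tidal_volume, 500, tolerance = 0.005)

  # sinusoidal half-wave, peak 1 L/s over 1 s -> 2000/pi ml within 0.5%
  sine <- sin(pi * seq(0, 1, length.out = sr))
  flow3 <- c(rep(0, n_base), sine, rep(-0.25, 2 * sr))
  rec3 <- recording(paw = rep(4, length(flow3)), flow = flow3,
                    condition = test_condition("LC", 10, 4))
  seg3 <- segment_breaths(rec3)[1, ]
  vf3 <- compute_volume_features(rec3, seg3, insp_t90 = 200)
  expect_equal(vf3$tidal_volume, 2000 / pi, tolerance = 0.005)

  # missing insp_t90 flags the ratio
  expect_true(is.na(compute_volume_features(rec, seg, NA)$peak_flow_rising_ratio))
})

test_that("IQR outlier filter follows the interpolated-quartile rule", {
  x <- c(480, 500, 510, 505, 495, 900)
  # independent oracle: quartiles by linear interpolation of order statistics
  s <- sort(x)
  q1 <- s[2] + 0.25 * (s[3] - s[2])   # h = (6-1)*0.25 = 1.25
  q3 <- s[4] + 0.75 * (s[5] - s[4])   # h = 3.75
  iqr <- q3 - q1
  expected <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
  expect_equal(expected, c(480, 500, 510, 505, 495))  # oracle sanity
  expect_equal(remove_outliers(x), expected)

  expect_equal(remove_outliers(rep(500, 5)), rep(500, 5))  # IQR = 0
  expect_equal(remove_outliers(c(1, 2, 3)), c(1, 2, 3))    # length < 4
  expect_error(remove_outliers(c(1, NA, 3)), "finite")
})

test_that("outlier removal keeps an ordered subset and stabilizes on clean bulks", {
  set.seed(42)
  for (i in 1:25) {
    # bulk of plausible tidal volumes plus occasional spikes
    x <- c(runif(sample(6:40, 1), 480, 520),
           sample(c(900, 50), sample(0:2, 1)))
    once <- remove_outliers(x)
    # always an order-preserving subset that drops the spikes
    expect_true(all(once %in% x))
    expect_identical(once, x[x %in% once])
    expect_false(any(c(900, 50) %in% once))
  }
  expect_identical(
    remove_outliers(remove_outliers(c(480, 500, 510, 505, 495, 900))),
    c(480, 500, 510, 505, 495))
})

test_that("equilibrium selection returns k consecutive low-variability breaths", {
  steady <- data.frame(tidal_volume = rep(500, 12), id = 1:12)
  sel <- select_equilibrium_breaths(steady)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$id, 8:12)          # tie-break toward the latest window

  ramp <- data.frame(
    tidal_volume = c(300, 350, 400, 450, 500, 500, 500, 500, 500, 500),
    id = 1:10)
  # independent oracle: exhaustive CV over all 5-windows
  tv <- ramp$tidal_volume
  cv <- vapply(1:6, function(s) {
    w <- tv[s:(s + 4)]; sd(w) / mean(w)
  }, numeric(1))
  best <- max(which(cv <= min(cv) + 1e-12))
  sel2 <- select_equilibrium_breaths(ramp)
  expect_equal(sel2$id, best:(best + 4))
  expect_true(all(sel2$tidal_volume == 500))

  expect_error(select_equilibrium_breaths(data.frame(tidal_volume = rep(500, 4))),
               "insufficient")
})

test_that("recording construction enforces the uniform-grid invariants", {
  expect_error(recording(paw = 1, flow = 1), "at least 2")
  expect_error(recording(paw = 1:10, flow = 1:9), "equal length")
  t_bad <- c(0:8, 10) / 512
  expect_error(recording(paw = 1:10, flow = 1:10, time = t_bad),
               "constant step")
  r <- recording(paw = rep(4, 100), flow = rep(0, 100))
  expect_equal(r$sample_rate, 512)
  # volume reconstruction integrates flow
  r2 <- recording(paw = rep(4, 512), flow = rep(0.5, 512))
  expect_equal(tail(r2$volume, 1), 0.5 * (511 / 512) * 1000, tolerance = 1e-9)
})
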