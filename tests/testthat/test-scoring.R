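test_that("range mapping reproduces the published boundary rule", {
  rt <- default_ranges()
  # at/beyond the better bound -> 1; at/beyond the worse bound -> 0
  expect_equal(map_score(0, lookup_range(rt, "max_pressure_drop", "LC")), 1)
  expect_equal(map_score(400, lookup_range(rt, "trigger_time", "LC")), 0)
  expect_equal(map_score(270, lookup_range(rt, "tidal_volume", "LC", "4-10")), 1)
  expect_equal(map_score(25, lookup_range(rt, "settle_increase")), 0)
  # linear in between, both orientations
  expect_equal(map_score(1.775, lookup_range(rt, "max_pressure_drop", "LC")), 0.5)
  expect_equal(map_score(230, lookup_range(rt, "trigger_time", "LC")), 0.5)
  # clamping beyond the bounds
  expect_equal(map_score(1e6, lookup_range(rt, "trigger_time", "LC")), 0)
  expect_equal(map_score(0, lookup_range(rt, "trigger_time", "LC")), 1)
  # absolute-deviation ranges score |value|
  r <- lookup_range(rt, "epap_error", preset = "8-20")
  expect_equal(map_score(-2, r), 0.5)
  expect_equal(map_score(2, r), 0.5)
  # step option
  expect_equal(map_score(100, lookup_range(rt, "trigger_time", "LC"),
                         method = "step"), 1)
  expect_equal(map_score(350, lookup_range(rt, "trigger_time", "LC"),
                         method = "step"), 0)
  expect_error(map_score(NA, r), "finite")
})

test_that("score mapping is monotone toward the better bound and bounded", {
  set.seed(7)
  for (i in 1:50) {
    wb <- runif(1, -10, 10); bb <- runif(1, -10, 10)
    if (abs(wb - bb) < 0.1) next
    rng <- list(worse_bound = wb, better_bound = bb,
                absolute_deviation = FALSE)
    v <- sort(runif(20, min(wb, bb) - 5, max(wb, bb) + 5))
    s <- vapply(v, map_score, numeric(1), range = rng)
    expect_true(all(s >= 0 & s <= 1))
    ds <- diff(s) * sign(bb - wb)
    expect_true(all(ds >= -1e-12))   # monotone toward the better bound
  }
})

test_that("oxygen scoring follows the two published setting ranges", {
  rt <- default_ranges()
  expect_equal(score_oxygen(0.60, 0.70, rt), 0)     # +10 points off at 60%
  expect_equal(score_oxygen(1.00, 0.98, rt), 1)     # 98% delivered at 100%
  expect_equal(score_oxygen(0.60, 0.65, rt), 0.5)   # midpoint
  expect_equal(score_oxygen(1.00, 0.80, rt), 0)
  expect_equal(score_oxygen(1.00, 0.89, rt), 0.5)
  expect_error(score_oxygen(0.40, 0.40, rt), "configuration")
})

test_that("node scores average the mapped values over tested levels", {
  rt <- default_ranges()
  expect_equal(score_node(c(60, 230, 400), "trigger_time", rt,
                          phenotype = "LC"), mean(c(1, 0.5, 0)))
  expect_equal(score_node(data.frame(value = c(270, 120),
                                     phenotype = "LC",
                                     preset = "4-10"),
                          "tidal_volume", rt), 0.5)
  expect_equal(score_node(42, "trigger_time", rt, phenotype = "LC"), 1)
  # missing measurements are excluded from the mean
  expect_equal(score_node(c(NA, 60), "trigger_time", rt, phenotype = "LC"), 1)
  expect_error(score_node(c(NA_real_, NA_real_), "trigger_time", rt,
                          phenotype = "LC"), "insufficient")
})

test_that("default range table reproduces every published cell family", {
  rt <- default_ranges()
  r <- lookup_range(rt, "tidal_volume", "HC", "12-30")
  expect_equal(c(r$worse_bound, r$better_bound), c(450, 1200))
  r <- lookup_range(rt, "insp_t90", "HC", "8-20")   # preset-independent
  expect_equal(c(r$worse_bound, r$better_bound), c(1400, 300))
  r <- lookup_range(rt, "epap_error", "LCIE", "8-20")  # phenotype-independent
  expect_true(r$absolute_deviation)
  expect_equal(r$worse_bound, 4)
  r <- lookup_range(rt, "ipap_error", preset = "12-30")
  expect_equal(r$worse_bound, 15)
  r <- lookup_range(rt, "settle_decrease")
  expect_equal(c(r$worse_bound, r$better_bound), c(12, 0))
  r <- lookup_range(rt, "peak_flow_rising_ratio", "HC")
  expect_equal(c(r$worse_bound, r$better_bound), c(0, 3))
  # every one of the 10 parameters resolves for every phenotype/preset
  params <- c("tidal_volume", "peak_flow_rising_ratio", "trigger_time",
              "max_pressure_drop", "insp_t90", "exp_t90", "ipap_error",
              "epap_error", "settle_increase", "settle_decrease")
  for (p in params)
    for (ph in c("LC", "IR", "LCIE", "HC"))
      for (pr in c("4-10", "8-20", "12-30"))
        expect_silent(lookup_range(rt, p, ph, pr))
  expect_error(lookup_range(rt, "no_such_parameter"), "configuration")
})

test_that("range tables round-trip through YAML and JSON configs", {
  doc <- list(
    list(parameter = "trigger_time", phenotype = "LC",
         worse_bound = 400, better_bound = 60),
    list(parameter = "ipap_error", preset = "4-10", worse_bound = 5,
         better_bound = 0, absolute_deviation = TRUE))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, yml)
  rt <- load_ranges(yml)
  expect_equal(lookup_range(rt, "trigger_time", "LC")$worse_bound, 400)
  expect_true(lookup_range(rt, "ipap_error", preset = "4-10")$absolute_deviation)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, jsn, auto_unbox = TRUE)
  rt2 <- load_ranges(jsn)
  expect_equal(as.data.frame(rt), as.data.frame(rt2))
  # schema violations name the offending entry
  bad <- list(list(parameter = "x", worse_bound = 1))
  yaml::write_yaml(bad, yml)
  expect_error(load_ranges(yml), "entry 1.*better_bound")
})

test_that("default weights reproduce the published hierarchy", {
  w <- load_weights()
  expect_equal(unname(w$first_raw),
               c(0.223, 0.229, 0.160, 0.242, 0.146))
  expect_equal(w$second_raw$reaction[["trigger_time"]], 0.498)
  expect_equal(sum(w$second_raw$reaction), 0.999)     # printed rounding
  # renormalized levels sum to exactly 1
  expect_equal(sum(w$first_level), 1)
  for (cr in names(w$second_level))
    expect_equal(sum(w$second_level[[cr]]), 1)
  gw <- global_weights(w)
  expect_equal(sum(gw), 1)
  expect_equal(gw[["trigger_time"]], 0.242 * 0.498 / 0.999, tolerance = 1e-12)
  expect_error(weight_hierarchy(c(a = 1, b = -1), list(a = c(x = 1),
                                                       b = c(y = 1))),
               "configuration")
})

test_that("scorecard aggregation is the weighted sum of the hierarchy", {
  w <- load_weights()
  leaves <- unlist(lapply(w$second_level, names))
  ones <- setNames(rep(1, length(leaves)), leaves)
  expect_equal(aggregate_scorecard(ones, w)$overall, 1)
  zeros <- setNames(rep(0, length(leaves)), leaves)
  expect_equal(aggregate_scorecard(zeros, w)$overall, 0)

  press <- zeros
  press[c("max_pressure_drop", "ipap_error")] <- 1
  card <- aggregate_scorecard(press, w)
  expect_equal(card$criteria[["pressurization"]], 0.337 + 0.385)
  expect_equal(card$overall, 0.223 * (0.337 + 0.385), tolerance = 1e-12)

  # permutation invariance in measurement order
  card2 <- aggregate_scorecard(press[sample(names(press))], w)
  expect_equal(card2$overall, card$overall)

  expect_error(aggregate_scorecard(c(ones, bad = 1.2), w), "\\[0, 1\\]")
})

test_that("missing nodes renormalize their criterion and are flagged", {
  w <- load_weights()
  partial <- c(max_pressure_drop = 1, ipap_error = 1, settle_increase = 0.5,
               settle_decrease = 0.5, peak_flow_rising_ratio = 1,
               tidal_volume = 1, insp_t90 = 1, exp_t90 = 1,
               trigger_time = 1, oxygen = 1)  # epap_error missing
  card <- aggregate_scorecard(partial, w)
  expect_equal(card$criteria[["pressurization"]], 1)  # renormalized over present
  expect_true("pressurization" %in% card$flags$renormalized_criteria)
  expect_true("epap_error" %in% card$flags$missing_nodes)

  # whole criterion missing -> dropped from a renormalized overall
  no_ox <- partial[names(partial) != "oxygen"]
  card2 <- aggregate_scorecard(no_ox, w)
  expect_true("oxygen" %in% card2$flags$dropped_criteria)
  fw <- w$first_level[names(w$first_level) != "oxygen"]
  manual <- sum(fw / sum(fw) * card2$criteria[names(fw)])
  expect_equal(card2$overall, manual)
})

test_that("radar axes are the five criteria in fixed plotting order", {
  w <- load_weights()
  leaves <- unlist(lapply(w$second_level, names))
  ones <- setNames(rep(1, length(leaves)), leaves)
  expect_equal(radar_summary(aggregate_scorecard(ones, w)),
               c(pressure = 1, leak = 1, volume = 1, reaction = 1,
                 oxygen = 1))
  zeros <- setNames(rep(0, length(leaves)), leaves)
  expect_equal(unname(radar_summary(aggregate_scorecard(zeros, w))),
               rep(0, 5))
  press <- zeros
  press[c("max_pressure_drop", "ipap_error")] <- 1
  ax <- radar_summary(aggregate_scorecard(press, w))
  expect_equal(ax[["pressure"]], 0.722, tolerance = 1e-9)
  expect_equal(names(ax), c("pressure", "leak", "volume", "reaction",
                            "oxygen"))
})

test_that("scorecards serialize to JSON and back", {
  w <- load_weights()
  leaves <- unlist(lapply(w$second_level, names))
  scores <- setNames(seq(0.1, 1, length.out = length(leaves)), leaves)
  card <- aggregate_scorecard(scores, w, phenotype = "LC")
  p <- tempfile(fileext = ".json")
  write_scorecard_json(card, p)
  back <- read_scorecard_json(p)
  expect_equal(back$overall, card$overall)
  expect_equal(back$phenotype, "LC")
  expect_equal(unlist(back$criteria), unlist(as.list(card$criteria)),
               tolerance = 1e-12)
})
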