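# Parameters measured on every steady trial, in scorecard-node order.
waveform_parameters <- c(
  "tidal_volume", "peak_flow_rising_ratio", "trigger_time",
  "max_pressure_drop", "insp_t90", "exp_t90", "ipap_error", "epap_error")

#' Wrap an analyzed recording as a bench trial
#'
#' Lets recordings loaded from CSV flow through [score_protocol()] alongside
#' simulator output: attaches the trial type and (for leak-step trials) the
#' step time.
#'
#' @param rec A [recording()] whose `condition` is set.
#' @param type `"steady"`, `"step_increase"` or `"step_decrease"`.
#' @param step_time Leak-change time, s (step trials only).
#' @return A `sim_output`-compatible trial object.
#' @export
bench_trial <- function(rec,
                        type = c("steady", "step_increase", "step_decrease"),
                        step_time = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(rec, "vent_recording"))
  if (is.null(rec$condition))
    stop("recording has no test_condition attached", call. = FALSE)
  if (type != "steady" && is.null(step_time))
    stop("step trials need step_time", call. = FALSE)
  out <- structure(list(recording = rec, event_log = NULL,
                        ground_truth = list(condition = rec$condition)),
                   class = "sim_output")
  cond <- rec$condition
  attr(out, "trial") <- list(type = type, phenotype = cond$phenotype,
                             preset = preset_key(cond$ipap_set, cond$epap_set),
                             leak_level = cond$leak_level,
                             step_time = step_time)
  out
}

trial_info <- function(x) {
  tr <- attr(x, "trial")
  if (is.null(tr)) stop("trial metadata missing on bench input", call. = FALSE)
  tr
}

trial_label <- function(tr)
  sprintf("(%s, preset %s, leak %g)", tr$phenotype, tr$preset, tr$leak_level)

#' Score a set of bench trials into per-phenotype scorecards
#'
#' Runs the full analysis pipeline on each trial — breath segmentation,
#' per-breath features, tidal-volume outlier removal, equilibrium-breath
#' selection, per-trial parameter values — then scores every node over all
#' tested levels and aggregates with the weight hierarchy. Steady trials feed
#' the eight waveform parameters; leak-step trials feed the two settle-time
#' nodes (unsettled trials score 0); the oxygen node is evaluated from the
#' deterministic oxygen model at the tested settings and leak levels.
#'
#' @param trials List of `sim_output` objects ([run_protocol()],
#'   [simulate_recording()] with a `trial` attribute, or [bench_trial()]).
#' @param ranges A `range_table` (default [default_ranges()]).
#' @param weights A [weight_hierarchy()] (default [load_weights()]).
#' @param prof Profile used for the oxygen model; defaults to the profile
#'   recorded in the first trial's ground truth. When unavailable the oxygen
#'   node is marked missing.
#' @param fio2_settings Oxygen settings tested (default 0.60 and 1.00).
#' @param k Equilibrium breaths per trial (default 5).
#' @param method Score interpolation passed to [map_score()].
#' @return Named list of [aggregate_scorecard()] results, one per phenotype.
#' @export
score_protocol <- function(trials, ranges = default_ranges(),
                           weights = load_weights(), prof = NULL,
                           fio2_settings = c(0.60, 1.00), k = 5,
                           method = "linear") {
  if (!length(trials)) stop("usage error: empty input set", call. = FALSE)
  infos <- lapply(trials, trial_info)
  phens <- unique(vapply(infos, `[[`, character(1), "phenotype"))
  if (is.null(prof)) prof <- trials[[1]]$ground_truth$profile

  cards <- list()
  for (ph in phens) {
    sel <- which(vapply(infos, function(i) i$phenotype == ph, logical(1)))
    meas <- list()   # per-parameter data.frames of (value, phenotype, preset)
    settle_scores <- list(settle_increase = numeric(0),
                          settle_decrease = numeric(0))
    leak_levels <- 0
    for (j in sel) {
      tr <- infos[[j]]
      rec <- trials[[j]]$recording
      feats <- tryCatch(analyze_recording(rec),
                        error = function(e)
                          stop("analysis failed for trial ", trial_label(tr),
                               ": ", conditionMessage(e), call. = FALSE))
      if (tr$type == "steady") {
        leak_levels <- unique(c(leak_levels, tr$leak_level))
        eq <- tryCatch(select_equilibrium_breaths(feats, k = k),
                       error = function(e)
                         stop("equilibrium selection failed for trial ",
                              trial_label(tr), ": ", conditionMessage(e),
                              call. = FALSE))
        for (p in waveform_parameters) {
          v <- eq[[p]]
          v <- v[!is.na(v)]
          meas[[p]] <- rbind(meas[[p]], data.frame(
            value = if (length(v)) mean(v) else NA_real_,
            phenotype = ph, preset = tr$preset))
        }
      } else {
        direction <- sub("step_", "", tr$type)
        vs <- tryCatch(
          volume_series(feats$insp_start_time, feats$tidal_volume,
                        leak_change_time = tr$step_time,
                        direction = direction),
          error = function(e)
            stop("settle analysis failed for trial ", trial_label(tr), ": ",
                 conditionMessage(e), call. = FALSE))
        st <- time_to_settle(vs)
        key <- paste0("settle_", direction)
        settle_scores[[key]] <- c(
          settle_scores[[key]],
          if (st$settled)
            map_score(st$settle_time,
                      lookup_range(ranges, key, ph, tr$preset),
                      method = method)
          else 0)
      }
    }

    nodes <- setNames(rep(NA_real_, length(waveform_parameters)),
                      waveform_parameters)
    for (p in waveform_parameters) {
      if (is.null(meas[[p]]) || all(is.na(meas[[p]]$value))) next
      nodes[p] <- score_node(meas[[p]], p, ranges, method = method)
    }
    for (key in names(settle_scores))
      if (length(settle_scores[[key]]))
        nodes[key] <- mean(settle_scores[[key]])

    if (!is.null(prof)) {
      ox <- numeric(0)
      for (fs in fio2_settings) for (lv in leak_levels) {
        cond <- test_condition(ph, 20, 8, leak_level = lv, fio2_set = fs)
        ox <- c(ox, score_oxygen(fs, simulate_oxygen_delivery(fs, prof, cond),
                                 ranges))
      }
      nodes["oxygen"] <- mean(ox)
    }

    cards[[ph]] <- aggregate_scorecard(nodes, weights, phenotype = ph)
  }
  cards
}

#' Run the simulated bench end to end
#'
#' Convenience orchestration: simulates the full protocol for the given
#' device profile, scores it, and (optionally) writes per-phenotype scorecard
#' JSONs plus a run log with configuration checksums. Deterministic for a
#' fixed seed: rerunning with identical inputs reproduces the scorecards
#' bit-for-bit.
#'
#' @param profile A [ventilator_profile()] describing the device under test.
#' @param circuit `"single"` or `"double"`.
#' @param phenotypes Phenotypes to test.
#' @param ranges,weights `"default"`, a path (passed to [load_ranges()] /
#'   [load_weights()]), or the loaded objects.
#' @param output_dir Optional directory for scorecard JSONs and the run log.
#' @param seed Base seed for per-trial noise streams.
#' @param ... Passed to [run_protocol()] (e.g. `duration`, `step_time`).
#' @return Named list of scorecards (invisibly when writing to
#'   `output_dir`).
#' @export
run_bench <- function(profile = ventilator_profile(),
                      circuit = c("single", "double"),
                      phenotypes = c("LC", "IR", "LCIE", "HC"),
                      ranges = "default", weights = "default",
                      output_dir = NULL, seed = profile$seed, ...) {
  circuit <- match.arg(circuit)
  if (!length(phenotypes)) stop("usage error: empty input set", call. = FALSE)
  if (is.character(ranges)) ranges <- load_ranges(ranges)
  if (is.character(weights)) weights <- load_weights(weights)
  trials <- run_protocol(phenotypes = phenotypes, prof = profile,
                         circuit = circuit, seed = seed, ...)
  cards <- score_protocol(trials, ranges = ranges, weights = weights,
                          prof = profile)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(output_dir, "config.json")
    jsonlite::write_json(
      list(profile = unclass(profile), circuit = circuit,
           phenotypes = phenotypes, seed = seed),
      cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- character(0)
    for (ph in names(cards)) {
      p <- file.path(output_dir, sprintf("scorecard_%s.json", ph))
      write_scorecard_json(cards[[ph]], p)
      paths <- c(paths, p)
    }
    log_lines <- c(
      sprintf("ventscore bench run, seed %s", format(seed)),
      sprintf("config %s md5 %s", basename(cfg_path),
              unname(tools::md5sum(cfg_path))),
      sprintf("scorecard %s md5 %s", basename(paths),
              unname(tools::md5sum(paths))),
      vapply(names(cards), function(ph)
        sprintf("%s overall %.6f", ph, cards[[ph]]$overall), character(1)))
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
    return(invisible(cards))
  }
  cards
}
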