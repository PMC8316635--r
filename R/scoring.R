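#' Default score-range table
#'
#' The published per-parameter performance ranges used to map measured values
#' onto `[0, 1]` scores: each row gives the bound that scores 0
#' (`worse_bound`) and the bound that scores 1 (`better_bound`) for one
#' parameter under one phenotype and/or preset (with `"any"` as wildcard).
#' Rows flagged `absolute_deviation` describe symmetric "+/- x" ranges: the
#' absolute value of the measurement is scored, the better bound is 0.
#'
#' Parameters with a single range per phenotype (trigger time, the T90s,
#' maximum pressure drop, peak-flow rising ratio) apply to all presets of that
#' phenotype; IPAP/EPAP error ranges apply per preset across phenotypes;
#' settle times and oxygen ranges are global.
#'
#' @return A data.frame of class `range_table` with columns `parameter`,
#'   `phenotype`, `preset`, `worse_bound`, `better_bound`,
#'   `absolute_deviation`.
#' @seealso [load_ranges()], [map_score()]
#' @export
default_ranges <- function() {
  row <- function(parameter, phenotype, preset, worse, better, absdev = FALSE)
    data.frame(parameter = parameter, phenotype = phenotype, preset = preset,
               worse_bound = worse, better_bound = better,
               absolute_deviation = absdev)
  tv <- list(
    LC   = list(c(120, 270), c(200, 400), c(250, 540)),
    IR   = list(c(190, 490), c(350, 780), c(480, 1025)),
    LCIE = list(c(180, 416), c(184, 561), c(229, 572)),
    HC   = list(c(300, 600), c(400, 900), c(450, 1200)))
  presets <- c("4-10", "8-20", "12-30")
  out <- list()
  for (ph in names(tv))
    for (j in seq_along(presets))
      out[[length(out) + 1L]] <-
        row("tidal_volume", ph, presets[j], tv[[ph]][[j]][1], tv[[ph]][[j]][2])

  per_phen <- function(parameter, vals) # vals: list(LC=, IR=, LCIE=, HC=) of c(worse, better)
    for (ph in names(vals))
      out[[length(out) + 1L]] <<-
        row(parameter, ph, "any", vals[[ph]][1], vals[[ph]][2])
  per_phen("peak_flow_rising_ratio",
           list(LC = c(0, 10), IR = c(0, 6), LCIE = c(0, 15), HC = c(0, 3)))
  per_phen("trigger_time",
           list(LC = c(400, 60), IR = c(600, 90), LCIE = c(400, 60),
                HC = c(600, 60)))
  per_phen("max_pressure_drop",
           list(LC = c(3.55, 0), IR = c(2.55, 0), LCIE = c(7, 0),
                HC = c(2.55, 0)))
  per_phen("exp_t90",
           list(LC = c(600, 100), IR = c(1000, 150), LCIE = c(600, 100),
                HC = c(1400, 100)))
  per_phen("insp_t90",
           list(LC = c(900, 100), IR = c(1200, 150), LCIE = c(900, 100),
                HC = c(1400, 300)))

  err <- list(ipap_error = c(5, 10, 15), epap_error = c(2, 4, 6))
  for (p in names(err))
    for (j in seq_along(presets))
      out[[length(out) + 1L]] <-
        row(p, "any", presets[j], err[[p]][j], 0, absdev = TRUE)

  out[[length(out) + 1L]] <- row("settle_increase", "any", "any", 20, 0)
  out[[length(out) + 1L]] <- row("settle_decrease", "any", "any", 12, 0)
  out[[length(out) + 1L]] <- row("oxygen_60", "any", "any", 10, 0,
                                 absdev = TRUE)
  out[[length(out) + 1L]] <- row("oxygen_100", "any", "any", 80, 98)

  rt <- do.call(rbind, out)
  class(rt) <- c("range_table", "data.frame")
  rt
}

#' Load a score-range table
#'
#' `"default"` returns [default_ranges()]. Otherwise `source` is a YAML or
#' JSON document (picked by file extension) containing a list of entries with
#' fields `parameter`, `worse_bound`, `better_bound` and optional `phenotype`,
#' `preset` (both default `"any"`) and `absolute_deviation` (default `FALSE`).
#'
#' @param source `"default"`, or a path to a YAML/JSON range document.
#' @return A `range_table` data.frame.
#' @export
load_ranges <- function(source = "default") {
  if (identical(source, "default")) return(default_ranges())
  doc <- read_config_doc(source)
  if (!length(doc)) stop("configuration error: empty range document",
                         call. = FALSE)
  rows <- lapply(seq_along(doc), function(i) {
    e <- doc[[i]]
    for (f in c("parameter", "worse_bound", "better_bound"))
      if (is.null(e[[f]]))
        stop(sprintf("configuration error at entry %d: missing field '%s'",
                     i, f), call. = FALSE)
    absdev <- isTRUE(e$absolute_deviation)
    wb <- as.numeric(e$worse_bound); bb <- as.numeric(e$better_bound)
    if (wb == bb)
      stop(sprintf("configuration error at entry %d: worse_bound == better_bound",
                   i), call. = FALSE)
    if (absdev && !(bb == 0 && wb > 0))
      stop(sprintf(
        "configuration error at entry %d: absolute_deviation needs better_bound 0, worse_bound > 0",
        i), call. = FALSE)
    data.frame(parameter = e$parameter,
               phenotype = if (is.null(e$phenotype)) "any" else e$phenotype,
               preset = if (is.null(e$preset)) "any" else e$preset,
               worse_bound = wb, better_bound = bb,
               absolute_deviation = absdev)
  })
  rt <- do.call(rbind, rows)
  class(rt) <- c("range_table", "data.frame")
  rt
}

read_config_doc <- function(source) {
  if (!is.character(source) || !file.exists(source))
    stop("configuration error: no such file: ", source, call. = FALSE)
  if (grepl("\\.ya?ml$", source, ignore.case = TRUE))
    yaml::read_yaml(source)
  else
    jsonlite::read_json(source, simplifyVector = FALSE)
}

#' Look up the score range for a parameter
#'
#' Resolves the most specific matching row: exact phenotype + exact preset,
#' then exact phenotype + `"any"`, then `"any"` + exact preset, then fully
#' generic.
#'
#' @param ranges A `range_table` (see [load_ranges()]).
#' @param parameter Parameter name (e.g. `"tidal_volume"`).
#' @param phenotype Phenotype code or `"any"`.
#' @param preset Preset key `"epap-ipap"` (e.g. `"4-10"`) or `"any"`.
#' @return A one-row `score range` list with fields `parameter`,
#'   `worse_bound`, `better_bound`, `absolute_deviation`.
#' @export
lookup_range <- function(ranges, parameter, phenotype = "any",
                         preset = "any") {
  stopifnot(inherits(ranges, "data.frame"))
  cand <- ranges[ranges$parameter == parameter, , drop = FALSE]
  if (!nrow(cand))
    stop(sprintf("configuration error: no range for parameter '%s'",
                 parameter), call. = FALSE)
  ph_ok <- cand$phenotype == phenotype | cand$phenotype == "any"
  pr_ok <- cand$preset == preset | cand$preset == "any"
  cand <- cand[ph_ok & pr_ok, , drop = FALSE]
  if (!nrow(cand))
    stop(sprintf(
      "configuration error: no range for parameter '%s' (phenotype %s, preset %s)",
      parameter, phenotype, preset), call. = FALSE)
  specificity <- (cand$phenotype != "any") * 2L + (cand$preset != "any")
  cand <- cand[specificity == max(specificity), , drop = FALSE]
  if (nrow(cand) > 1L)
    stop(sprintf(
      "configuration error: ambiguous range for parameter '%s' (phenotype %s, preset %s)",
      parameter, phenotype, preset), call. = FALSE)
  as.list(cand[1L, ])
}

#' Map a measured value to a unit-interval score
#'
#' Values at or beyond the better-performance bound score 1, values at or
#' beyond the worse-performance bound score 0. Within the range the default is
#' linear interpolation (the simplest monotone map consistent with both
#' endpoints); `method = "step"` instead scores 1 for the better half of the
#' range and 0 for the worse half. Ranges flagged `absolute_deviation` score
#' the absolute value of the measurement.
#'
#' @param value Measured value (finite).
#' @param range A range as returned by [lookup_range()].
#' @param method `"linear"` (default) or `"step"`.
#' @return A score in `[0, 1]`.
#' @examples
#' rt <- default_ranges()
#' map_score(0, lookup_range(rt, "max_pressure_drop", "LC"))    # 1
#' map_score(400, lookup_range(rt, "trigger_time", "LC"))       # 0
#' @export
map_score <- function(value, range, method = c("linear", "step")) {
  method <- match.arg(method)
  if (!is.finite(value)) stop("value must be finite", call. = FALSE)
  if (isTRUE(range$absolute_deviation)) value <- abs(value)
  s <- (value - range$worse_bound) / (range$better_bound - range$worse_bound)
  s <- min(1, max(0, s))
  if (method == "step") s <- as.numeric(s >= 0.5)
  s
}

#' Score oxygen-delivery accuracy at one setting
#'
#' At the 60% setting the deviation of delivered from set concentration is
#' scored against a symmetric "+/- 10 points" range; at the 100% setting the
#' delivered concentration itself is scored between 80% (score 0) and 98%
#' (score 1, values above 98% also score 1). Other settings require a range
#' named `oxygen_<setting>` in the table.
#'
#' @param fio2_set Set oxygen fraction (e.g. `0.60`, `1.00`).
#' @param fio2_measured Delivered oxygen fraction.
#' @param ranges A `range_table`.
#' @return A score in `[0, 1]`.
#' @export
score_oxygen <- function(fio2_set, fio2_measured, ranges = default_ranges()) {
  key <- sprintf("oxygen_%d", as.integer(round(fio2_set * 100)))
  rng <- lookup_range(ranges, key)
  value <- if (isTRUE(rng$absolute_deviation))
    (fio2_measured - fio2_set) * 100 else fio2_measured * 100
  map_score(value, rng)
}

#' Score a node from measurements over multiple test levels
#'
#' Maps each measurement through its (phenotype, preset)-specific range, then
#' averages over all tested levels (presets x leak levels). Missing
#' measurements (`NA`) are excluded from the mean — a breath whose feature
#' could not be measured is an analysis gap, not device behaviour.
#'
#' @param measurements A data.frame with columns `value` and optionally
#'   `phenotype`, `preset` (defaults `"any"`), or a bare numeric vector.
#' @param parameter Parameter name (range-table key).
#' @param ranges A `range_table`.
#' @param phenotype,preset Defaults applied when `measurements` lacks the
#'   columns.
#' @param method Interpolation method passed to [map_score()].
#' @return The node score: arithmetic mean of the per-level scores.
#' @export
score_node <- function(measurements, parameter, ranges = default_ranges(),
                       phenotype = "any", preset = "any",
                       method = "linear") {
  if (is.numeric(measurements))
    measurements <- data.frame(value = measurements)
  stopifnot(is.data.frame(measurements), "value" %in% names(measurements))
  if (!"phenotype" %in% names(measurements))
    measurements$phenotype <- phenotype
  if (!"preset" %in% names(measurements)) measurements$preset <- preset
  measurements <- measurements[!is.na(measurements$value), , drop = FALSE]
  if (!nrow(measurements))
    stop("insufficient data: all measurements missing for node '",
         parameter, "'", call. = FALSE)
  scores <- mapply(function(v, ph, pr)
    map_score(v, lookup_range(ranges, parameter, ph, pr), method = method),
    measurements$value, measurements$phenotype, measurements$preset)
  mean(scores)
}

#' Two-level AHP weight hierarchy
#'
#' Five first-level criteria, each carrying leaf-node weights (the oxygen
#' criterion is a singleton leaf). Each level is renormalized at construction
#' to sum to exactly 1 — the published reaction-level weights total 0.999 from
#' rounding — with the raw (as-supplied) weights retained.
#'
#' @param first_level Named positive numeric vector of criterion weights.
#' @param second_level Named list (same names) of named positive leaf-weight
#'   vectors.
#' @return An object of class `weight_hierarchy` with elements `first_level`,
#'   `second_level` (renormalized), `first_raw`, `second_raw`.
#' @export
weight_hierarchy <- function(first_level, second_level) {
  if (is.null(names(first_level)) || any(!nzchar(names(first_level))))
    stop("configuration error: first-level weights must be named",
         call. = FALSE)
  if (!setequal(names(second_level), names(first_level)))
    stop("configuration error: criterion mismatch between levels",
         call. = FALSE)
  if (any(first_level <= 0) ||
      any(vapply(second_level, function(w) any(w <= 0), logical(1))))
    stop("configuration error: weights must be > 0", call. = FALSE)
  second_level <- second_level[names(first_level)]
  structure(list(
    first_level = first_level / sum(first_level),
    second_level = lapply(second_level, function(w) w / sum(w)),
    first_raw = first_level,
    second_raw = second_level), class = "weight_hierarchy")
}

#' @export
print.weight_hierarchy <- function(x, ...) {
  cat("<weight_hierarchy>\n")
  for (cr in names(x$first_level)) {
    cat(sprintf("  %-16s %.3f\n", cr, x$first_level[[cr]]))
    w <- x$second_level[[cr]]
    for (lf in names(w))
      cat(sprintf("    %-22s %.3f\n", lf, w[[lf]]))
  }
  invisible(x)
}

#' Global (criterion x leaf) weights of a hierarchy
#'
#' @param weights A [weight_hierarchy()].
#' @return Named numeric vector over all leaves, summing to 1.
#' @export
global_weights <- function(weights) {
  stopifnot(inherits(weights, "weight_hierarchy"))
  out <- unlist(lapply(names(weights$first_level), function(cr)
    weights$first_level[[cr]] * weights$second_level[[cr]]))
  names(out) <- unlist(lapply(weights$second_level, names))
  out
}

#' Load a weight hierarchy
#'
#' `"default"` reproduces the published weights: first level 0.223
#' (pressurization) / 0.229 (leak) / 0.160 (volume) / 0.242 (reaction) /
#' 0.146 (oxygen), with the printed leaf weights beneath each criterion; each
#' level is then renormalized to sum to 1. Otherwise `source` is a YAML/JSON
#' document with fields `first_level` (named map) and `second_level` (map of
#' named maps).
#'
#' @param source `"default"` or a YAML/JSON path.
#' @return A [weight_hierarchy()].
#' @export
load_weights <- function(source = "default") {
  if (identical(source, "default")) {
    return(weight_hierarchy(
      first_level = c(pressurization = 0.223, leak = 0.229, volume = 0.160,
                      reaction = 0.242, oxygen = 0.146),
      second_level = list(
        pressurization = c(max_pressure_drop = 0.337, epap_error = 0.278,
                           ipap_error = 0.385),
        leak = c(settle_increase = 0.622, settle_decrease = 0.378),
        volume = c(peak_flow_rising_ratio = 0.385, tidal_volume = 0.615),
        reaction = c(insp_t90 = 0.341, exp_t90 = 0.160, trigger_time = 0.498),
        oxygen = c(oxygen = 1))))
  }
  doc <- read_config_doc(source)
  if (is.null(doc$first_level) || is.null(doc$second_level))
    stop("configuration error: weight document needs 'first_level' and 'second_level'",
         call. = FALSE)
  weight_hierarchy(unlist(doc$first_level),
                   lapply(doc$second_level, unlist))
}

#' Aggregate node scores into a scorecard
#'
#' Criterion score = weighted sum of its leaf scores; overall score = weighted
#' sum of criterion scores. Leaves absent from `node_scores` (or `NA`) are
#' treated as missing: their criterion's remaining leaf weights are
#' renormalized and the criterion is flagged; a criterion with all leaves
#' missing is dropped from a renormalized overall (also flagged) rather than
#' silently scoring 0.
#'
#' @param node_scores Named numeric vector of leaf scores in `[0, 1]` (leaf
#'   names as in the hierarchy; the oxygen leaf is `"oxygen"`).
#' @param weights A [weight_hierarchy()] (default [load_weights()]).
#' @param phenotype Optional phenotype label carried on the card.
#' @return An object of class `scorecard`: list with `nodes`, `criteria`,
#'   `overall`, `flags` (missing nodes / renormalized criteria) and
#'   `phenotype`.
#' @export
aggregate_scorecard <- function(node_scores, weights = load_weights(),
                                phenotype = NULL) {
  stopifnot(inherits(weights, "weight_hierarchy"))
  vals <- node_scores[!is.na(node_scores)]
  if (length(vals) && (any(vals < 0) || any(vals > 1)))
    stop("invalid input: node scores must lie in [0, 1]", call. = FALSE)
  criteria <- setNames(numeric(0), character(0))
  missing_nodes <- character(0)
  renormalized <- character(0)
  for (cr in names(weights$first_level)) {
    w <- weights$second_level[[cr]]
    have <- names(w)[names(w) %in% names(vals)]
    absent <- setdiff(names(w), have)
    missing_nodes <- c(missing_nodes, absent)
    if (!length(have)) {
      criteria[cr] <- NA_real_
      next
    }
    if (length(absent)) renormalized <- c(renormalized, cr)
    ww <- w[have] / sum(w[have])
    criteria[cr] <- sum(ww * vals[have])
  }
  present <- !is.na(criteria)
  fw <- weights$first_level[present] / sum(weights$first_level[present])
  overall <- sum(fw * criteria[present])
  structure(list(
    nodes = node_scores,
    criteria = criteria,
    overall = overall,
    flags = list(missing_nodes = missing_nodes,
                 renormalized_criteria = unique(renormalized),
                 dropped_criteria = names(criteria)[!present]),
    phenotype = phenotype), class = "scorecard")
}

#' @export
print.scorecard <- function(x, digits = 3, ...) {
  cat(sprintf("<scorecard>%s overall %.3f\n",
              if (is.null(x$phenotype)) "" else paste0(" ", x$phenotype),
              x$overall))
  for (cr in names(x$criteria))
    cat(sprintf("  %-16s %s\n", cr,
                if (is.na(x$criteria[[cr]])) "missing"
                else formatC(x$criteria[[cr]], digits = digits,
                             format = "f")))
  if (length(x$flags$missing_nodes))
    cat("  missing nodes:", paste(x$flags$missing_nodes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Radar-chart axis values of a scorecard
#'
#' Returns the five criterion scores in the fixed clockwise plotting order
#' pressure, leak, volume, reaction, oxygen. Missing criteria are `NA`.
#'
#' @param card A [aggregate_scorecard()] result.
#' @return Named numeric vector of length 5.
#' @export
radar_summary <- function(card) {
  stopifnot(inherits(card, "scorecard"))
  axes <- c(pressure = "pressurization", leak = "leak", volume = "volume",
            reaction = "reaction", oxygen = "oxygen")
  out <- vapply(axes, function(cr)
    if (cr %in% names(card$criteria)) card$criteria[[cr]] else NA_real_,
    numeric(1))
  names(out) <- names(axes)
  out
}

#' Serialize / read a scorecard as JSON
#'
#' @param card A `scorecard`.
#' @param path Output path.
#' @return `write_scorecard_json()` returns `path` invisibly;
#'   `read_scorecard_json()` returns the parsed list.
#' @export
write_scorecard_json <- function(card, path) {
  stopifnot(inherits(card, "scorecard"))
  jsonlite::write_json(
    list(phenotype = card$phenotype,
         nodes = as.list(card$nodes),
         criteria = as.list(card$criteria),
         overall = card$overall,
         flags = card$flags),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_scorecard_json
#' @export
read_scorecard_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
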