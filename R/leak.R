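#' Breath-by-breath tidal-volume series around a leak step
#'
#' Holds the per-breath tidal volumes of a leak-step trial together with the
#' time of the leak change and its direction. Breath times are the inspiration
#' start times, which keeps settle times deterministic and sample-grid
#' aligned.
#'
#' @param breath_times Inspiration start time of each breath, seconds,
#'   strictly increasing.
#' @param tidal_volumes Tidal volume of each breath, ml.
#' @param leak_change_time Time of the leak step, seconds.
#' @param direction `"increase"` or `"decrease"`; labels which range bound
#'   applies when scoring (the settle detector itself is direction-agnostic).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(breath_times, tidal_volumes, leak_change_time,
                          direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(length(breath_times) == length(tidal_volumes))
  if (any(diff(breath_times) <= 0))
    stop("breath_times must be strictly increasing", call. = FALSE)
  n_pre <- sum(breath_times <= leak_change_time)
  n_post <- sum(breath_times > leak_change_time)
  if (n_pre < 3 || n_post < 3)
    stop(sprintf(
      "insufficient data: need >= 3 breaths before and after the leak change (have %d / %d)",
      n_pre, n_post), call. = FALSE)
  structure(list(breath_times = as.numeric(breath_times),
                 tidal_volumes = as.numeric(tidal_volumes),
                 leak_change_time = leak_change_time,
                 direction = direction),
            class = "volume_series")
}

#' Build a volume series from a two-column CSV
#'
#' Reads `breath_time_s,tidal_volume_ml` rows (for re-analysis of external
#' breath tables) and attaches the change time and direction.
#'
#' @param path CSV path with header `breath_time_s,tidal_volume_ml`.
#' @inheritParams volume_series
#' @return A [volume_series()].
#' @export
read_volume_series_csv <- function(path, leak_change_time,
                                   direction = c("increase", "decrease")) {
  df <- read.csv(path)
  need <- c("breath_time_s", "tidal_volume_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("volume-series CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  volume_series(df$breath_time_s, df$tidal_volume_ml, leak_change_time,
                direction)
}

#' Time to settle after a leak change
#'
#' Measures how long the device needs, after a leak step, until tidal volume
#' has recovered into the band `mean +/- 2 SD` of the settled tidal volume for
#' the new leak level. The band is estimated from the final `n_ref`
#' post-change breaths (the settled tail characterises the level). The settle
#' time is the inspiration-start time, relative to the leak change, of the
#' first post-change breath that lies in the band and is followed by
#' `m_sustain - 1` further consecutive in-band breaths — a single transient
#' band crossing during recovery does not count as settled. If no such breath
#' exists the trial is flagged unsettled (and scores 0 downstream).
#'
#' @param series A [volume_series()].
#' @param n_ref Number of final post-change breaths defining the settled
#'   reference band (default 10; all post-change breaths are used when fewer
#'   exist, minimum 3).
#' @param m_sustain Number of consecutive in-band breaths required (default 3).
#' @param band_floor Lower limit on the band half-width, ml (default 1, about
#'   the volume resolution of a bench measurement). Without it a noise-free
#'   reference tail has SD 0 and the band degenerates to bit-exact equality.
#' @return An object of class `settle_result`: list with `settle_time` (s, or
#'   `NA` when unsettled), `settled` flag, `band_mean`, `band_sd` (ml) and
#'   `direction`.
#' @export
time_to_settle <- function(series, n_ref = 10, m_sustain = 3,
                           band_floor = 1) {
  stopifnot(inherits(series, "volume_series"))
  post <- series$breath_times > series$leak_change_time
  tv <- series$tidal_volumes[post]
  tt <- series$breath_times[post]
  ref <- tail(tv, n_ref)
  mu <- mean(ref)
  sig <- sd(ref)
  in_band <- abs(tv - mu) <= max(2 * sig, band_floor)
  settle_time <- NA_real_
  if (length(tv) >= m_sustain) {
    for (i in seq_len(length(tv) - m_sustain + 1L)) {
      if (all(in_band[i:(i + m_sustain - 1L)])) {
        settle_time <- tt[i] - series$leak_change_time
        break
      }
    }
  }
  structure(list(settle_time = settle_time,
                 settled = !is.na(settle_time),
                 band_mean = mu, band_sd = sig,
                 direction = series$direction),
            class = "settle_result")
}

#' @export
print.settle_result <- function(x, ...) {
  cat(sprintf("<settle_result> leak %s: %s (band %.0f +/- %.0f ml)\n",
              x$direction,
              if (x$settled) sprintf("settled after %.2f s", x$settle_time)
              else "unsettled",
              x$band_mean, 2 * x$band_sd))
  invisible(x)
}
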