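#' Test condition metadata for a bench trial
#'
#' Describes the lung-model phenotype and ventilator settings under which a
#' recording was (or is to be) acquired: which simulated COVID-19 respiratory
#' phenotype is loaded on the lung model, the IPAP/EPAP preset, the applied
#' circuit leak, the circuit topology and (optionally) the oxygen setting.
#'
#' @param phenotype One of `"LC"` (low compliance), `"IR"` (increased
#'   resistance), `"LCIE"` (low compliance, increased effort), `"HC"` (high
#'   compliance).
#' @param ipap_set,epap_set Set inspiratory / expiratory positive airway
#'   pressures, cmH2O. Must satisfy `ipap_set > epap_set >= 0`.
#' @param leak_level Intentional circuit leak in L/min (`0` = baseline).
#' @param circuit Circuit topology, `"single"` or `"double"`; determines which
#'   leak levels the default protocol uses.
#' @param fio2_set Optional oxygen setting as a fraction (e.g. `0.60`, `1.00`).
#' @return An object of class `test_condition`.
#' @examples
#' test_condition("LC", ipap_set = 20, epap_set = 8)
#' @export
test_condition <- function(phenotype = c("LC", "IR", "LCIE", "HC"),
                           ipap_set, epap_set, leak_level = 0,
                           circuit = c("single", "double"), fio2_set = NULL) {
  phenotype <- match.arg(phenotype)
  circuit <- match.arg(circuit)
  stopifnot(is.numeric(ipap_set), is.numeric(epap_set),
            length(ipap_set) == 1, length(epap_set) == 1)
  if (!(ipap_set > epap_set && epap_set >= 0))
    stop("invalid preset: need ipap_set > epap_set >= 0", call. = FALSE)
  if (leak_level < 0) stop("leak_level must be >= 0", call. = FALSE)
  if (!is.null(fio2_set) &&
      (fio2_set <= 0.21 || fio2_set > 1))
    stop("fio2_set must lie in (0.21, 1]", call. = FALSE)
  structure(
    list(phenotype = phenotype, ipap_set = ipap_set, epap_set = epap_set,
         leak_level = leak_level, circuit = circuit, fio2_set = fio2_set),
    class = "test_condition")
}

#' @export
print.test_condition <- function(x, ...) {
  cat(sprintf("<test_condition> %s  IPAP/EPAP %g/%g cmH2O  leak %g L/min (%s)\n",
              x$phenotype, x$ipap_set, x$epap_set, x$leak_level, x$circuit))
  if (!is.null(x$fio2_set)) cat(sprintf("  FiO2 setting %.2f\n", x$fio2_set))
  invisible(x)
}

# Preset key used by the range tables: "epap-ipap", e.g. "4-10".
preset_key <- function(ipap_set, epap_set) {
  sprintf("%g-%g", epap_set, ipap_set)
}

#' Multichannel ventilation recording
#'
#' Container for a uniformly sampled bench recording of airway pressure,
#' patient-side flow, volume and (optionally) muscle pressure. Flow is stored
#' internally in L/s (file interfaces use L/min, the bench convention). The
#' volume channel is reconstructed by trapezoidal integration of flow when not
#' supplied.
#'
#' @param paw Airway pressure, cmH2O.
#' @param flow Patient-side (lung) flow, L/s; positive = inspiratory.
#' @param volume Optional volume channel, ml above the starting volume.
#' @param pmus Optional muscle (effort) pressure, cmH2O; ground truth on the
#'   simulator, usually absent on hardware benches.
#' @param sample_rate Sampling rate in Hz (default 512, the acquisition rate
#'   of the bench protocol).
#' @param time Optional explicit time vector, seconds; must be a uniform grid
#'   with step `1/sample_rate` (tolerance 1e-9 s). Built automatically when
#'   omitted.
#' @param condition Optional [test_condition()].
#' @return An object of class `vent_recording`.
#' @examples
#' r <- recording(paw = rep(4, 1024), flow = rep(0, 1024))
#' r
#' @export
recording <- function(paw, flow, volume = NULL, pmus = NULL,
                      sample_rate = 512, time = NULL, condition = NULL) {
  n <- length(paw)
  if (n < 2) stop("recording needs at least 2 samples", call. = FALSE)
  if (length(flow) != n)
    stop("all channels must have equal length", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  dt <- 1 / sample_rate
  if (is.null(time)) {
    time <- (seq_len(n) - 1) * dt
  } else {
    if (length(time) != n)
      stop("all channels must have equal length", call. = FALSE)
    steps <- diff(time)
    if (any(steps <= 0) || any(abs(steps - dt) > 1e-9))
      stop("time must be strictly increasing with constant step 1/sample_rate",
           call. = FALSE)
  }
  if (!is.null(volume) && length(volume) != n)
    stop("all channels must have equal length", call. = FALSE)
  if (!is.null(pmus) && length(pmus) != n)
    stop("all channels must have equal length", call. = FALSE)
  if (anyNA(paw) || anyNA(flow))
    stop("paw/flow channels must be free of missing values", call. = FALSE)
  if (is.null(volume)) {
    # trapezoidal running integral of flow, ml
    mid <- (flow[-1] + flow[-n]) / 2 * dt * 1000
    volume <- c(0, cumsum(mid))
  }
  if (!is.null(condition) && !inherits(condition, "test_condition"))
    stop("condition must be a test_condition", call. = FALSE)
  structure(
    list(time = as.numeric(time), paw = as.numeric(paw),
         flow = as.numeric(flow), volume = as.numeric(volume),
         pmus = if (is.null(pmus)) NULL else as.numeric(pmus),
         sample_rate = sample_rate, condition = condition),
    class = "vent_recording")
}

#' @export
print.vent_recording <- function(x, ...) {
  cat(sprintf("<vent_recording> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$paw), x$sample_rate,
              length(x$paw) / x$sample_rate,
              if (is.null(x$pmus)) "" else ", pmus present"))
  if (!is.null(x$condition)) print(x$condition)
  invisible(x)
}

#' Read / write the waveform CSV dialect
#'
#' The on-disk dialect is a plain UTF-8 CSV with header
#' `time_s,paw_cmh2o,flow_lpm,volume_ml[,pmus_cmh2o]`, one row per sample and
#' `.` as decimal separator. Flow is in L/min on disk and converted to L/s in
#' memory. Condition metadata travels in a JSON sidecar (same path with a
#' `.json` extension) or can be passed explicitly.
#'
#' @param path CSV file path.
#' @param condition Optional [test_condition()]; if `NULL`, the sidecar JSON is
#'   read when present.
#' @return `read_waveform_csv()` returns a [recording()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_s", "paw_cmh2o", "flow_lpm", "volume_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("waveform CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tm <- df$time_s
  if (length(tm) < 2) stop("recording needs at least 2 samples", call. = FALSE)
  steps <- diff(tm)
  if (any(steps <= 0) || max(steps) - min(steps) > 1e-9)
    stop("non-uniform time grid in ", path, call. = FALSE)
  sr <- 1 / median(steps)
  if (is.null(condition)) {
    sidecar <- sidecar_path(path)
    if (file.exists(sidecar)) condition <- read_condition_json(sidecar)
  }
  recording(paw = df$paw_cmh2o, flow = df$flow_lpm / 60,
            volume = df$volume_ml,
            pmus = if ("pmus_cmh2o" %in% names(df)) df$pmus_cmh2o else NULL,
            sample_rate = sr, time = tm - tm[1], condition = condition)
}

#' @param rec A [recording()].
#' @param write_sidecar Write the condition sidecar JSON next to the CSV?
#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(rec, path, write_sidecar = TRUE) {
  stopifnot(inherits(rec, "vent_recording"))
  df <- data.frame(time_s = rec$time, paw_cmh2o = rec$paw,
                   flow_lpm = rec$flow * 60, volume_ml = rec$volume)
  if (!is.null(rec$pmus)) df$pmus_cmh2o <- rec$pmus
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (write_sidecar && !is.null(rec$condition)) {
    cond <- rec$condition
    jsonlite::write_json(
      cond[!vapply(cond, is.null, logical(1))],
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

read_condition_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  test_condition(phenotype = x$phenotype, ipap_set = x$ipap_set,
                 epap_set = x$epap_set,
                 leak_level = if (is.null(x$leak_level)) 0 else x$leak_level,
                 circuit = if (is.null(x$circuit)) "single" else x$circuit,
                 fio2_set = x$fio2_set)
}
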