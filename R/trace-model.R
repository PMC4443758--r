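#' Construct a single-channel trace
#'
#' A `trace` is a uniformly sampled single-channel time series: the common
#' container for membrane potential sweeps (mV, current clamp), membrane
#' current sweeps (nA, two-electrode voltage clamp) and fluorescence records
#' (arbitrary units). Time is in seconds throughout the package; amplitudes
#' derived from traces are always reported as magnitudes.
#'
#' @param samples Numeric vector of sample values in channel units.
#' @param dt Sampling interval in seconds (`> 0`).
#' @param t0 Time of the first sample in seconds.
#' @param channel One of `"voltage_mV"`, `"current_nA"`, `"fluorescence_au"`.
#' @param label Free-text label.
#' @return An object of class `trace`.
#' @export
trace <- function(samples, dt, t0 = 0, channel = c("voltage_mV", "current_nA",
                                                   "fluorescence_au"),
                  label = "") {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("all trace samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  structure(
    list(samples = samples, dt = dt, t0 = as.numeric(t0),
         channel = channel, label = as.character(label)),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %.6g s (%.4g s), channel %s%s\n",
              length(x$samples), x$dt, length(x$samples) * x$dt, x$channel,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Sample timestamps of a trace
#'
#' @param x A `trace`.
#' @return Numeric vector of times (seconds), `t0 + (0:(n-1)) * dt`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' Construct a stimulus-aligned sweep set
#'
#' Bundles sweeps sharing a sampling grid and channel with their per-sweep
#' stimulus-onset times. Stimulus alignment is always explicit: downstream
#' analyses read `stimulus_times`, never infer onsets from the signal.
#'
#' @param sweeps List of `trace` objects sharing `dt`, length and channel.
#' @param stimulus_times Numeric vector of stimulus onsets (seconds), shared
#'   by all sweeps, strictly increasing.
#' @param protocol One of `"single_AP"`, `"train_60Hz_30"`, `"paired_pulse"`,
#'   `"arch_spot"`, `"ca_linescan"`.
#' @param meta Optional [recording_meta()] (or plain list) carried along.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, stimulus_times,
                      protocol = c("single_AP", "train_60Hz_30",
                                   "paired_pulse", "arch_spot", "ca_linescan"),
                      meta = NULL) {
  protocol <- match.arg(protocol)
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "trace")))
    stop("sweeps must be a non-empty list of trace objects")
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  lens <- vapply(sweeps, function(s) length(s$samples), integer(1))
  chans <- vapply(sweeps, `[[`, character(1), "channel")
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L ||
      length(unique(chans)) != 1L)
    stop("all sweeps must share dt, length and channel")
  stimulus_times <- as.numeric(stimulus_times)
  if (length(stimulus_times) && any(diff(stimulus_times) <= 0))
    stop("stimulus_times must be strictly increasing")
  if (protocol == "train_60Hz_30") {
    if (length(stimulus_times) != 30L)
      stop("train_60Hz_30 requires exactly 30 stimulus times")
    isi <- diff(stimulus_times)
    if (any(abs(isi - 1 / 60) > 1e-3))
      stop("train_60Hz_30 requires ~16.67 ms inter-stimulus spacing")
  }
  structure(list(sweeps = sweeps, stimulus_times = stimulus_times,
                 protocol = protocol, meta = meta),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps, protocol %s, %d stimuli\n",
              length(x$sweeps), x$protocol, length(x$stimulus_times)))
  invisible(x)
}

#' Recording metadata
#'
#' @param genotype Genotype label.
#' @param ca_external_mM Extracellular calcium concentration, mM, in (0, 10].
#' @param vm_rest_mV Resting membrane potential, mV.
#' @param clamp_mode `"current_clamp"` or `"TEVC"`.
#' @param temperature_note Free text.
#' @return A list of class `recording_meta`.
#' @export
recording_meta <- function(genotype = "wt", ca_external_mM = 0.3,
                           vm_rest_mV = NA_real_,
                           clamp_mode = c("current_clamp", "TEVC"),
                           temperature_note = "") {
  clamp_mode <- match.arg(clamp_mode)
  if (!is.na(ca_external_mM) && (ca_external_mM <= 0 || ca_external_mM > 10))
    stop("ca_external_mM must lie in (0, 10]")
  structure(list(genotype = genotype, ca_external_mM = ca_external_mM,
                 vm_rest_mV = vm_rest_mV, clamp_mode = clamp_mode,
                 temperature_note = temperature_note),
            class = "recording_meta")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a trace to delimited text
#'
#' Emits a two-column CSV (`time_s,value`, values at 12 significant digits)
#' plus a JSON sidecar `<name>.json` holding channel, label, dt and optional
#' recording metadata. [read_trace()] reads this dialect back losslessly.
#'
#' @param x A `trace`.
#' @param path Output CSV path.
#' @param meta Optional `recording_meta` written into the sidecar.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "trace"))
  tt <- trace_times(x)
  lines <- c("time_s,value",
             paste(sprintf("%.12g", tt), sprintf("%.12g", x$samples),
                   sep = ","))
  writeLines(lines, path)
  side <- list(channel = x$channel, label = x$label, dt = x$dt, t0 = x$t0)
  if (!is.null(meta)) {
    side$genotype <- meta$genotype
    side$ca_external_mM <- meta$ca_external_mM
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Expects the dialect written by [write_trace()]: a CSV with header
#' `time_s,value` and a JSON sidecar giving at least `channel` and `label`.
#' The sampling interval is inferred as the median time step; a time grid
#' that is non-uniform beyond 1e-6 s, or non-monotonic, is rejected.
#'
#' @param path CSV path.
#' @return A `trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for trace file: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$channel)) stop("sidecar lacks required field 'channel'")
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace file must have columns time_s,value")
  tt <- df$time_s
  if (length(tt) < 1L) stop("trace file contains no samples")
  if (length(tt) > 1L) {
    steps <- diff(tt)
    if (any(steps <= 0)) stop("non-monotonic time column in ", path)
    dt <- stats::median(steps)
    if (any(abs(steps - dt) > 1e-6))
      stop("non-uniform time grid (beyond 1e-6 s) in ", path)
  } else {
    dt <- if (!is.null(side$dt)) side$dt else stop("single-sample trace needs dt in sidecar")
  }
  trace(df$value, dt = dt, t0 = tt[1], channel = side$channel,
        label = if (is.null(side$label)) "" else side$label)
}

#' Write a sweep set to a directory
#'
#' Writes each sweep as a trace CSV (+ sidecar) and a `manifest.json` listing
#' member files, protocol and stimulus times.
#'
#' @param x A `sweep_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for member traces.
#' @return Invisibly, the manifest path.
#' @export
write_sweep_set <- function(x, dir, prefix = "sweep") {
  stopifnot(inherits(x, "sweep_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(x$sweeps))
  for (i in seq_along(x$sweeps)) {
    files[i] <- sprintf("%s_%03d.csv", prefix, i)
    write_trace(x$sweeps[[i]], file.path(dir, files[i]), meta = x$meta)
  }
  man <- list(protocol = x$protocol, stimulus_times = x$stimulus_times,
              traces = files)
  if (!is.null(x$meta))
    man$meta <- list(genotype = x$meta$genotype,
                     ca_external_mM = x$meta$ca_external_mM,
                     vm_rest_mV = x$meta$vm_rest_mV,
                     clamp_mode = x$meta$clamp_mode)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a sweep set from a manifest
#'
#' @param manifest Path to a `manifest.json` written by [write_sweep_set()].
#' @return A `sweep_set`.
#' @export
read_sweep_set <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  sweeps <- lapply(file.path(dir, man$traces), read_trace)
  meta <- NULL
  if (!is.null(man$meta))
    meta <- recording_meta(genotype = man$meta$genotype,
                           ca_external_mM = man$meta$ca_external_mM,
                           vm_rest_mV = if (is.null(man$meta$vm_rest_mV))
                             NA_real_ else man$meta$vm_rest_mV,
                           clamp_mode = man$meta$clamp_mode)
  sweep_set(sweeps, man$stimulus_times, protocol = man$protocol, meta = meta)
}

#' Zero-phase low-pass filter
#'
#' 4-pole zero-phase Butterworth low-pass (2nd-order filter run forward and
#' backward). Signal edges are padded by odd reflection before filtering so
#' that DC gain is exactly 1 and edge transients do not leak into the trace.
#'
#' @param x A `trace`.
#' @param cutoff_hz Cutoff frequency in Hz, below Nyquist.
#' @return A filtered `trace` of identical length.
#' @export
lowpass <- function(x, cutoff_hz) {
  stopifnot(inherits(x, "trace"))
  fs <- 1 / x$dt
  if (cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency ", fs / 2, " Hz")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  n <- length(x$samples)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  mu <- mean(x$samples)
  y <- x$samples - mu
  # odd-reflection padding (as scipy's filtfilt does) to suppress transients
  pad <- min(n - 1L, max(12L, ceiling(3 * fs / cutoff_hz)))
  if (pad > 0L) {
    left <- 2 * y[1] - y[(pad + 1):2]
    right <- 2 * y[n] - y[(n - 1):(n - pad)]
    yp <- c(left, y, right)
  } else yp <- y
  f1 <- signal::filter(bf, yp)
  f2 <- rev(signal::filter(bf, rev(as.numeric(f1))))
  out <- f2[(pad + 1):(pad + n)] + mu
  trace(out, dt = x$dt, t0 = x$t0, channel = x$channel, label = x$label)
}

window_idx <- function(x, window) {
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be c(t_start, t_end) with t_start < t_end")
  tt <- trace_times(x)
  idx <- which(tt >= window[1] - 1e-12 & tt < window[2] - 1e-12)
  idx
}

#' Mean of a trace over a time window
#'
#' Arithmetic mean of samples whose timestamps fall in `[t_start, t_end)`.
#' This is the estimator used for pre-stimulus baselines, e.g. the mean
#' fluorescence over the 300 ms preceding a stimulus.
#'
#' @param x A `trace`.
#' @param window `c(t_start, t_end)` in seconds, within the trace extent.
#' @return The mean (channel units).
#' @export
baseline_mean <- function(x, window) {
  stopifnot(inherits(x, "trace"))
  idx <- window_idx(x, window)
  if (!length(idx)) stop("baseline window contains no samples")
  mean(x$samples[idx])
}

#' Peak amplitude relative to a pre-event baseline
#'
#' Returns `|extremum - baseline|`: the magnitude of the deflection in the
#' search window relative to the baseline-window mean. EPSPs deflect upward
#' in current clamp (`polarity = "up"`), EPSCs downward in voltage clamp
#' (`polarity = "down"`); the reported amplitude is non-negative either way.
#'
#' @param x A `trace`.
#' @param search_window `c(t_start, t_end)`, seconds.
#' @param baseline_window `c(t_start, t_end)`, seconds.
#' @param polarity `"up"` (maximum) or `"down"` (minimum).
#' @return Non-negative amplitude in channel units.
#' @export
peak_amplitude <- function(x, search_window, baseline_window,
                           polarity = c("up", "down")) {
  polarity <- match.arg(polarity)
  b <- baseline_mean(x, baseline_window)
  idx <- window_idx(x, search_window)
  if (!length(idx)) stop("search window contains no samples")
  ext <- if (polarity == "up") max(x$samples[idx]) else min(x$samples[idx])
  abs(ext - b)
}
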