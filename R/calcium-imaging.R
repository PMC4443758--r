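#' Fractional fluorescence change (dF/F) of a line-scan pair
#'
#' `dF/F = (F(t) - Fbaseline) / (Fbaseline - Fbackground)`, where
#' `Fbaseline` is the mean ROI fluorescence over the 300 ms preceding the
#' stimulus and `Fbackground` the mean of the adjacent indicator-free
#' background ROI over the same window.
#'
#' @param roi ROI `trace` (fluorescence, a.u.).
#' @param background Background `trace` on the same time grid.
#' @param stim_time_s Stimulus time, s; must be >= 0.3 so the 300 ms
#'   baseline window exists.
#' @param baseline_s Baseline window length, s.
#' @return A unitless dF/F `trace`.
#' @export
dff <- function(roi, background, stim_time_s, baseline_s = 0.3) {
  stopifnot(inherits(roi, "trace"), inherits(background, "trace"))
  if (abs(roi$dt - background$dt) > 1e-12 ||
      length(roi$samples) != length(background$samples))
    stop("roi and background must share the same time grid")
  if (stim_time_s - roi$t0 < baseline_s)
    stop("stimulus must be at least ", baseline_s,
         " s after the start of the record")
  win <- c(stim_time_s - baseline_s, stim_time_s)
  f_base <- baseline_mean(roi, win)
  f_bg <- baseline_mean(background, win)
  if (f_base <= f_bg)
    stop("degenerate dF/F denominator: Fbaseline <= Fbackground")
  trace((roi$samples - f_base) / (f_base - f_bg), dt = roi$dt, t0 = roi$t0,
        channel = "fluorescence_au",
        label = paste0("dff:", roi$label))
}

#' Imaging exclusion rules for a calcium line scan
#'
#' A record is excluded when its resting fluorescence decreased by more than
#' 15% (bleaching drift) and/or when its baseline fluorescence exceeds
#' 650 a.u. Drift is estimated as the fractional decrease of the resting ROI
#' fluorescence between the first and last second of the record, with the
#' stimulus-transient window masked; both thresholds are strict (values
#' exactly at the threshold are kept).
#'
#' @param roi ROI `trace`.
#' @param stim_time_s Stimulus time, s.
#' @param baseline_max Baseline exclusion threshold, a.u.
#' @param drift_max Fractional drift exclusion threshold.
#' @param transient_mask_s Length of the post-stimulus window masked from
#'   the drift estimate, s.
#' @return A list with `excluded` (logical), `reason` (one of
#'   `"drift_gt_15pct"`, `"baseline_gt_650"`, `"none"`), and the measured
#'   `drift` and `f_baseline`.
#' @export
imaging_qc <- function(roi, stim_time_s, baseline_max = 650,
                       drift_max = 0.15, transient_mask_s = 0.6) {
  stopifnot(inherits(roi, "trace"))
  tt <- trace_times(roi)
  t_end <- tt[length(tt)]
  f_baseline <- baseline_mean(roi, c(max(roi$t0, stim_time_s - 0.3),
                                     stim_time_s))
  resting <- !(tt >= stim_time_s & tt < stim_time_s + transient_mask_s)
  first <- resting & tt < roi$t0 + 1
  last <- resting & tt >= t_end - 1
  drift <- NA_real_
  if (any(first) && any(last)) {
    m1 <- mean(roi$samples[first])
    m2 <- mean(roi$samples[last])
    drift <- (m1 - m2) / m1
  }
  if (!is.na(drift) && drift > drift_max)
    list(excluded = TRUE, reason = "drift_gt_15pct", drift = drift,
         f_baseline = f_baseline)
  else if (f_baseline > baseline_max)
    list(excluded = TRUE, reason = "baseline_gt_650", drift = drift,
         f_baseline = f_baseline)
  else
    list(excluded = FALSE, reason = "none", drift = drift,
         f_baseline = f_baseline)
}

#' Average single-bouton calcium transients
#'
#' Pointwise mean of 8-12 dF/F line-scan traces from one bouton; the peak is
#' the maximum after the stimulus. Fewer than 8 traces is flagged but still
#' computed.
#'
#' @param transients List of dF/F `trace` objects on a common grid (none
#'   excluded).
#' @param stim_time_s Stimulus time, s.
#' @return A list of class `calcium_transient` with `dff_trace`, `peak_dff`,
#'   `n_scans_averaged` and `flag`.
#' @export
average_transients <- function(transients, stim_time_s) {
  if (!length(transients) ||
      !all(vapply(transients, inherits, TRUE, "trace")))
    stop("transients must be a non-empty list of trace objects")
  dts <- vapply(transients, `[[`, numeric(1), "dt")
  lens <- vapply(transients, function(s) length(s$samples), integer(1))
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L)
    stop("transients must share the same time grid")
  m <- rowMeans(vapply(transients, `[[`, numeric(lens[1]), "samples"))
  avg <- trace(m, dt = dts[1], t0 = transients[[1]]$t0,
               channel = "fluorescence_au", label = "bouton-average dff")
  tt <- trace_times(avg)
  post <- which(tt >= stim_time_s)
  if (!length(post)) stop("no samples after the stimulus")
  structure(list(dff_trace = avg, peak_dff = max(m[post]),
                 n_scans_averaged = length(transients),
                 flag = if (length(transients) < 8) "fewer_than_8_scans"
                        else "none"),
            class = "calcium_transient")
}

#' Amplitude-normalized transient shape
#'
#' Divides a bouton-average dF/F trace by its peak so shapes can be compared
#' across conditions independent of amplitude (peak of the output is exactly
#' 1).
#'
#' @param x A `calcium_transient` from [average_transients()].
#' @return A unitless `trace` with peak 1.
#' @export
normalize_shape <- function(x) {
  stopifnot(inherits(x, "calcium_transient"))
  if (!is.finite(x$peak_dff) || x$peak_dff <= 0)
    stop("cannot normalize a transient with non-positive peak")
  tr <- x$dff_trace
  trace(tr$samples / x$peak_dff, dt = tr$dt, t0 = tr$t0,
        channel = "fluorescence_au", label = "normalized dff")
}
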