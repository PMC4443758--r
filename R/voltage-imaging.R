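#' Fit and subtract the photobleach/tissue-fluorescence baseline
#'
#' Fits a single exponential `a * exp(-t / tau) + c` to the window from
#' 10 ms after the start of imaging (excluding the initial Arch photocycle
#' brightening) to 5 ms before stimulus onset, extrapolates it over the full
#' time base and subtracts it, isolating the voltage-dependent fluorescence.
#' The fit uses a log-spaced grid search over tau (linear least squares for
#' `a`, `c` at each tau) refined by Levenberg-Marquardt.
#'
#' @param sweep A fluorescence `trace`.
#' @param stim_time_s Stimulus time, s (>= 15 ms so the fit window exists).
#' @param fit_start_s Offset of the fit-window start from the beginning of
#'   the sweep, s.
#' @param fit_stop_before_s Gap between the fit-window end and the stimulus, s.
#' @return The residual `trace` (sweep minus extrapolated fit), with the fit
#'   coefficients attached as attribute `"bleach_fit"`.
#' @export
subtract_photobleach <- function(sweep, stim_time_s, fit_start_s = 0.010,
                                 fit_stop_before_s = 0.005) {
  stopifnot(inherits(sweep, "trace"))
  if (stim_time_s - sweep$t0 < fit_start_s + fit_stop_before_s)
    stop("stimulus too early: no photobleach fit window")
  tt <- trace_times(sweep)
  win <- tt >= sweep$t0 + fit_start_s & tt <= stim_time_s - fit_stop_before_s
  if (sum(win) < 20)
    stop("photobleach fit window contains fewer than 20 samples")
  tw <- tt[win]; yw <- sweep$samples[win]
  span <- max(tw) - min(tw)
  best <- NULL
  for (tau in exp(seq(log(span / 20), log(span * 50), length.out = 40))) {
    X <- cbind(exp(-tw / tau), 1)
    cf <- tryCatch(stats::lsfit(X, yw, intercept = FALSE)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf)) next
    rss <- sum((yw - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = cf[1], c = cf[2], tau = tau, rss = rss)
  }
  if (is.null(best)) stop("photobleach fit failed on the baseline window")
  fit <- tryCatch(
    minpack.lm::nlsLM(yw ~ a * exp(-tw / tau) + c,
                      start = list(a = best$a, tau = best$tau, c = best$c),
                      lower = c(-Inf, span / 1000, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) as.list(stats::coef(fit))
        else list(a = best$a, tau = best$tau, c = best$c)
  pred <- cf$a * exp(-tt / cf$tau) + cf$c
  res <- trace(sweep$samples - pred, dt = sweep$dt, t0 = sweep$t0,
               channel = "fluorescence_au",
               label = paste0("residual:", sweep$label))
  attr(res, "bleach_fit") <- cf
  res
}

#' Reject sweeps containing extra action potentials
#'
#' A residual sweep is rejected when a second suprathreshold deflection
#' (>= `threshold_frac` of the stimulus-locked peak) occurs outside the
#' expected AP window (stimulus +/- `window_ms`). The first 10 ms of the
#' sweep (photocycle, outside the baseline fit) is ignored.
#'
#' @param sweeps List of residual `trace` objects from
#'   [subtract_photobleach()].
#' @param stim_time_s Stimulus time, s.
#' @param threshold_frac Rejection threshold as a fraction of the
#'   stimulus-locked peak.
#' @param window_ms Half-width of the accepted AP window around the
#'   stimulus, ms.
#' @return A list with `accepted` (the accepted subset), `rejected_idx`,
#'   and `n_rejected`.
#' @export
reject_extra_ap <- function(sweeps, stim_time_s, threshold_frac = 0.5,
                            window_ms = 5) {
  stopifnot(length(sweeps) >= 1,
            all(vapply(sweeps, inherits, TRUE, "trace")))
  w <- window_ms / 1000
  rejected <- vapply(sweeps, function(s) {
    tt <- trace_times(s)
    searchable <- tt >= s$t0 + 0.010
    in_ap <- tt >= stim_time_s - w & tt <= stim_time_s + w
    main <- max(s$samples[in_ap & searchable])
    if (!is.finite(main) || main <= 0) return(FALSE)
    out <- searchable & !in_ap
    any(s$samples[out] >= threshold_frac * main)
  }, logical(1))
  list(accepted = sweeps[!rejected], rejected_idx = which(rejected),
       n_rejected = sum(rejected))
}

#' Average accepted Arch sweeps into an AP waveform
#'
#' Low-pass filters each accepted residual sweep at `filter_hz` (2 kHz
#' standard), averages pointwise, and measures the waveform's full width and
#' width at half maximum with sub-sample linear interpolation
#' ([waveform_widths()]). Optical amplitude is not reported in physical
#' units; widths are the readout.
#'
#' @param accepted List of residual `trace` objects (>= 1).
#' @param filter_hz Zero-phase low-pass cutoff, Hz (`NULL` to skip).
#' @return A list of class `ap_waveform` with `waveform` (`trace`),
#'   `peak_time_s`, `full_width_ms`, `whm_ms`, `n_sweeps`, `normalized`.
#' @export
average_ap <- function(accepted, filter_hz = 2000) {
  if (!length(accepted)) stop("no accepted sweeps")
  stopifnot(all(vapply(accepted, inherits, TRUE, "trace")))
  lens <- vapply(accepted, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L) stop("sweeps must share the time grid")
  # at 4 kHz sampling a 2 kHz cutoff sits at Nyquist and the filter is an
  # identity; skip it rather than reject it
  if (!is.null(filter_hz) && filter_hz < 0.5 / accepted[[1]]$dt)
    accepted <- lapply(accepted, lowpass, cutoff_hz = filter_hz)
  m <- rowMeans(vapply(accepted, `[[`, numeric(lens[1]), "samples"))
  wf <- trace(m, dt = accepted[[1]]$dt, t0 = accepted[[1]]$t0,
              channel = "fluorescence_au", label = "average AP waveform")
  wd <- waveform_widths(wf)
  structure(list(waveform = wf, peak_time_s = wd$peak_time_s,
                 full_width_ms = wd$full_width_ms, whm_ms = wd$whm_ms,
                 n_sweeps = length(accepted), normalized = FALSE),
            class = "ap_waveform")
}

# first crossing of `level` on each flank of the peak, sub-sample by linear
# interpolation between the bracketing samples
flank_crossings <- function(tt, y, ipk, level) {
  left <- NA_real_
  for (i in ipk:2) {
    if (y[i - 1] < level && y[i] >= level) {
      frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
      left <- tt[i - 1] + frac * (tt[i] - tt[i - 1])
      break
    }
  }
  right <- NA_real_
  n <- length(y)
  if (ipk < n) for (i in ipk:(n - 1)) {
    if (y[i] >= level && y[i + 1] < level) {
      frac <- (y[i] - level) / (y[i] - y[i + 1])
      right <- tt[i] + frac * (tt[i + 1] - tt[i])
      break
    }
  }
  c(left = left, right = right)
}

#' Waveform width and width at half maximum
#'
#' Measures the full width (at `full_frac` of the peak, 10% by default —
#' the full-width threshold is a package convention, exposed as config) and
#' the width at half maximum of a single-peaked waveform on a 0 baseline,
#' using linear interpolation between the bracketing samples for sub-sample
#' precision. The peak time is refined by parabolic interpolation.
#'
#' @param waveform A `trace` with a single dominant positive peak.
#' @param full_frac Threshold fraction defining the full width.
#' @return A list with `full_width_ms`, `whm_ms`, `peak_time_s`,
#'   `peak_value`.
#' @export
waveform_widths <- function(waveform, full_frac = 0.1) {
  stopifnot(inherits(waveform, "trace"))
  y <- waveform$samples
  tt <- trace_times(waveform)
  ipk <- which.max(y)
  pk <- y[ipk]
  if (pk <= 0) stop("waveform has no positive peak above baseline")
  # parabolic refinement of the peak position
  peak_time <- tt[ipk]
  if (ipk > 1 && ipk < length(y)) {
    denom <- y[ipk - 1] - 2 * y[ipk] + y[ipk + 1]
    if (denom < 0)
      peak_time <- tt[ipk] + 0.5 * (y[ipk - 1] - y[ipk + 1]) / denom *
        waveform$dt
  }
  half <- flank_crossings(tt, y, ipk, pk / 2)
  full <- flank_crossings(tt, y, ipk, pk * full_frac)
  if (any(is.na(half)))
    stop("no half-maximum crossing found on one flank")
  if (any(is.na(full)))
    stop("no ", full_frac * 100, "% crossing found on one flank")
  list(full_width_ms = unname(full["right"] - full["left"]) * 1000,
       whm_ms = unname(half["right"] - half["left"]) * 1000,
       peak_time_s = peak_time, peak_value = pk)
}

#' Peak-aligned, normalized group-average AP waveform
#'
#' Normalizes each bouton-average waveform to peak 1, time-shifts it so that
#' all (parabolically interpolated) peaks coincide, resamples onto the first
#' waveform's peak-relative grid, and averages pointwise.
#'
#' @param waveforms List of `ap_waveform` objects (>= 1) sharing `dt`.
#' @return An `ap_waveform` with `normalized = TRUE`; widths are remeasured
#'   on the group average.
#' @export
group_average <- function(waveforms) {
  if (!length(waveforms)) stop("no waveforms to average")
  stopifnot(all(vapply(waveforms, inherits, TRUE, "ap_waveform")))
  dts <- vapply(waveforms, function(w) w$waveform$dt, numeric(1))
  if (any(abs(dts - dts[1]) > 1e-12))
    stop("waveforms must share the sampling interval")
  ref <- waveforms[[1]]
  rel <- trace_times(ref$waveform) - ref$peak_time_s
  acc <- matrix(NA_real_, length(rel), length(waveforms))
  for (j in seq_along(waveforms)) {
    w <- waveforms[[j]]
    pk <- max(w$waveform$samples)
    acc[, j] <- stats::approx(trace_times(w$waveform) - w$peak_time_s,
                              w$waveform$samples / pk,
                              xout = rel, rule = 2)$y
  }
  m <- rowMeans(acc)
  wf <- trace(m, dt = ref$waveform$dt, t0 = rel[1] + ref$peak_time_s,
              channel = "fluorescence_au", label = "group-average AP")
  wd <- waveform_widths(wf)
  structure(list(waveform = wf, peak_time_s = wd$peak_time_s,
                 full_width_ms = wd$full_width_ms, whm_ms = wd$whm_ms,
                 n_sweeps = length(waveforms), normalized = TRUE),
            class = "ap_waveform")
}
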