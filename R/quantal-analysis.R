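#' Detect miniature synaptic events in a spontaneous record
#'
#' Threshold-on-smoothed-derivative detection: the trace is low-pass
#' smoothed, candidate onsets are rising-slope excursions of the derivative,
#' each candidate's peak is located and its amplitude measured as peak minus
#' a local pre-onset baseline. Candidates closer together than
#' `min_interval_ms` are merged, keeping the larger. The default amplitude
#' threshold is 4x a robust (MAD-based) estimate of the baseline noise SD.
#'
#' @param x A `trace` (spontaneous record, no stimulus).
#' @param threshold Minimum amplitude above local baseline (channel units);
#'   `NULL` for the 4x robust-noise default.
#' @param min_interval_ms Merge window, ms.
#' @param smooth_hz Smoothing cutoff used before differentiation, Hz.
#' @return A data.frame of detected events with columns `t_peak`,
#'   `amplitude`, `rise_ms` (20-80% rise time) and `decay_ms` (time to 1/e),
#'   possibly empty.
#' @export
detect_minis <- function(x, threshold = NULL, min_interval_ms = 10,
                         smooth_hz = 500) {
  stopifnot(inherits(x, "trace"))
  n <- length(x$samples)
  empty <- data.frame(t_peak = numeric(0), amplitude = numeric(0),
                      rise_ms = numeric(0), decay_ms = numeric(0))
  if (n < 10) return(empty)
  sm <- lowpass(x, min(smooth_hz, 0.45 / x$dt))$samples
  dv <- c(0, diff(sm)) / x$dt
  noise_sd <- stats::mad(diff(x$samples)) / sqrt(2)
  if (is.null(threshold)) threshold <- 4 * noise_sd
  dthr <- stats::mad(dv)
  cand <- dv > max(3 * dthr, 1e-12)
  if (!any(cand)) return(empty)
  # group contiguous suprathreshold derivative runs into candidate onsets
  starts <- which(cand & !c(FALSE, cand[-n]))
  w_pk <- max(1L, round(0.008 / x$dt))     # peak search: 8 ms after onset
  w_bl <- max(1L, round(0.003 / x$dt))     # baseline: 3 ms before onset
  ev <- lapply(starts, function(i0) {
    hi <- min(n, i0 + w_pk)
    ipk <- i0 - 1L + which.max(sm[i0:hi])
    lo <- max(1L, i0 - w_bl)
    bl <- mean(sm[lo:max(lo, i0 - 1L)])
    amp <- sm[ipk] - bl
    c(ipk = ipk, amp = amp, bl = bl)
  })
  ev <- do.call(rbind, ev)
  ev <- ev[ev[, "amp"] >= threshold, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  # merge events closer than min_interval_ms, keeping the larger
  ord <- order(ev[, "ipk"])
  ev <- ev[ord, , drop = FALSE]
  min_gap <- min_interval_ms / 1000 / x$dt
  keep <- rep(TRUE, nrow(ev))
  i <- 1L
  while (i < nrow(ev)) {
    j <- i + 1L
    while (j <= nrow(ev) && ev[j, "ipk"] - ev[i, "ipk"] < min_gap) {
      if (ev[j, "amp"] > ev[i, "amp"]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
      j <- j + 1L
    }
    i <- j
  }
  ev <- ev[keep, , drop = FALSE]
  tt <- trace_times(x)
  rise <- numeric(nrow(ev)); decay <- numeric(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    ipk <- ev[k, "ipk"]; bl <- ev[k, "bl"]; amp <- ev[k, "amp"]
    seg <- sm - bl
    # 20-80% rise time on the rising flank
    i20 <- ipk; while (i20 > 1 && seg[i20] > 0.2 * amp) i20 <- i20 - 1L
    i80 <- ipk; while (i80 > 1 && seg[i80] > 0.8 * amp) i80 <- i80 - 1L
    rise[k] <- (i80 - i20) * x$dt * 1000
    ie <- ipk
    while (ie < n && seg[ie] > amp / exp(1)) ie <- ie + 1L
    decay[k] <- if (ie < n) (ie - ipk) * x$dt * 1000 else NA_real_
  }
  data.frame(t_peak = tt[ev[, "ipk"]], amplitude = ev[, "amp"],
             rise_ms = rise, decay_ms = decay)
}

#' Summary statistics of miniature events
#'
#' @param events A data.frame as returned by [detect_minis()] (needs an
#'   `amplitude` column).
#' @param duration_s Record duration, s, > 0.
#' @return A list with `mean_amplitude`, `sem`, `n`, `frequency_hz` and
#'   `cumulative`, a data.frame (`amplitude`, `fraction`) giving the
#'   right-continuous empirical cumulative amplitude distribution (reaching
#'   1 at the maximum amplitude). With no events the mean is `NA` and
#'   `flag = "no_events"`; with one event the SEM is `NA` and
#'   `flag = "single_event"`.
#' @export
mini_stats <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- nrow(events)
  if (n == 0)
    return(list(mean_amplitude = NA_real_, sem = NA_real_, n = 0L,
                frequency_hz = 0,
                cumulative = data.frame(amplitude = numeric(0),
                                        fraction = numeric(0)),
                flag = "no_events"))
  a <- sort(events$amplitude)
  cum <- data.frame(amplitude = a, fraction = seq_len(n) / n)
  list(mean_amplitude = mean(a),
       sem = if (n > 1) stats::sd(a) / sqrt(n) else NA_real_,
       n = n, frequency_hz = n / duration_s, cumulative = cum,
       flag = if (n == 1) "single_event" else "none")
}

#' Quantal content of a recording
#'
#' The ratio of the mean evoked amplitude to the mean miniature amplitude of
#' the *same* recording. Genotype-level quantal content is the mean of
#' per-recording ratios (see [genotype_quantal_content()]), never the ratio
#' of genotype means.
#'
#' @param epsp_mean Mean evoked amplitude (mV or nA), > 0.
#' @param mepsp_mean Mean miniature amplitude (same units), > 0.
#' @return Quantal content (dimensionless).
#' @export
quantal_content <- function(epsp_mean, mepsp_mean) {
  if (!is.finite(epsp_mean) || epsp_mean <= 0)
    stop("epsp_mean must be positive")
  if (!is.finite(mepsp_mean) || mepsp_mean <= 0)
    stop("mepsp_mean must be positive")
  epsp_mean / mepsp_mean
}

#' Genotype-level quantal content
#'
#' Mean (with SEM) of per-recording quantal contents across NMJs of a
#' genotype — the mean-of-ratios convention.
#'
#' @param recordings A data.frame with columns `epsp_mean` and `mepsp_mean`
#'   (one row per recording), or a numeric vector of per-recording quantal
#'   contents.
#' @return A list with `qc_mean`, `qc_sem`, `n`.
#' @export
genotype_quantal_content <- function(recordings) {
  qc <- if (is.data.frame(recordings))
    mapply(quantal_content, recordings$epsp_mean, recordings$mepsp_mean)
  else as.numeric(recordings)
  list(qc_mean = mean(qc),
       qc_sem = if (length(qc) > 1) stats::sd(qc) / sqrt(length(qc))
                else NA_real_,
       n = length(qc))
}

#' Muscle recording acceptance rule
#'
#' Muscles are recorded at their resting potential when `vm <= -60` mV,
#' clamped to -65 mV when the resting potential is more positive than -60 mV
#' (but not beyond -55 mV), and discarded when more depolarized than -55 mV.
#' Boundary values are read strictly: exactly -60 records at Vm, exactly
#' -55 clamps.
#'
#' @param vm_rest_mV Resting membrane potential, mV.
#' @return A list with `action` (one of `"record_at_vm"`, `"clamp_to"`,
#'   `"discard"`), `clamp_target_mV` (-65 when clamping, else `NA`) and
#'   `accepted` (logical).
#' @export
recording_qc <- function(vm_rest_mV) {
  stopifnot(is.finite(vm_rest_mV))
  if (vm_rest_mV <= -60)
    list(action = "record_at_vm", clamp_target_mV = NA_real_,
         accepted = TRUE)
  else if (vm_rest_mV <= -55)
    list(action = "clamp_to", clamp_target_mV = -65, accepted = TRUE)
  else
    list(action = "discard", clamp_target_mV = NA_real_, accepted = FALSE)
}
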