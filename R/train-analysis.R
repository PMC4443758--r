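#' Per-stimulus EPSC amplitudes of a train sweep
#'
#' For stimulus i, the baseline is the mean over the 2 ms preceding the
#' onset and the peak is the extremum between that onset and the next (or
#' onset + the median inter-stimulus interval for the last stimulus); the
#' amplitude is the magnitude of peak minus baseline. EPSCs recorded under
#' voltage clamp deflect downward, so the extremum is the minimum for
#' `current_nA` sweeps and the maximum for voltage sweeps.
#'
#' @param sweep A `trace`.
#' @param stimulus_times Stimulus onsets, seconds, strictly increasing.
#' @param baseline_ms Pre-onset baseline window length, ms.
#' @return Numeric vector of non-negative amplitudes, one per stimulus.
#' @export
train_amplitudes <- function(sweep, stimulus_times, baseline_ms = 2) {
  stopifnot(inherits(sweep, "trace"))
  st <- as.numeric(stimulus_times)
  if (length(st) < 1 || any(diff(st) <= 0))
    stop("stimulus_times must be strictly increasing")
  bl_s <- baseline_ms / 1000
  if (length(st) > 1 && bl_s >= min(diff(st)))
    stop("baseline window overlaps the preceding stimulus interval")
  isi <- if (length(st) > 1) stats::median(diff(st)) else 0.015
  ends <- c(st[-1], st[length(st)] + isi)
  polarity <- if (sweep$channel == "current_nA") "down" else "up"
  vapply(seq_along(st), function(i) {
    peak_amplitude(sweep,
                   search_window = c(st[i], ends[i]),
                   baseline_window = c(st[i] - bl_s, st[i]),
                   polarity = polarity)
  }, numeric(1))
}

#' RRP estimate by cumulative-EPSC back-extrapolation
#'
#' The cumulative EPSC amplitude is fitted by ordinary least squares over
#' its last `n_fit` points (stimulus-index axis) and back-extrapolated to
#' index 0 ("time 0"); the intercept, divided by the quantal size (the mean
#' mEPSC amplitude of the same cell), is the readily-releasable pool in
#' quanta. The steady-state slope absorbs replenishment.
#'
#' @param amplitudes Per-stimulus EPSC amplitudes (nA, magnitudes).
#' @param quantal_size Mean mEPSC amplitude of the same cell (nA), > 0.
#' @param n_fit Number of final cumulative points fitted (default the last
#'   10 of a 30-stimulus train).
#' @return A list with `cumulative`, `fit_slope` (nA per stimulus),
#'   `fit_intercept_nA`, `rrp_quanta`, and `flag`
#'   (`"negative_intercept"` when the back-extrapolation falls below 0).
#' @export
estimate_rrp <- function(amplitudes, quantal_size, n_fit = 10) {
  amplitudes <- as.numeric(amplitudes)
  n <- length(amplitudes)
  if (!is.finite(quantal_size) || quantal_size <= 0)
    stop("quantal_size must be positive")
  if (n_fit < 2 || n_fit > n)
    stop("n_fit must lie in [2, length(amplitudes)]")
  cum <- cumsum(amplitudes)
  idx <- seq_len(n)
  sel <- (n - n_fit + 1):n
  fit <- stats::lm(cum[sel] ~ idx[sel])
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  list(cumulative = cum, fit_slope = slope, fit_intercept_nA = intercept,
       rrp_quanta = intercept / quantal_size,
       flag = if (intercept < 0) "negative_intercept" else "none")
}

#' P_train: fraction of the RRP released by the first stimulus
#'
#' @param amplitudes Per-stimulus EPSC amplitudes (magnitudes).
#' @param fit_intercept_nA Back-extrapolated cumulative EPSC at time 0, from
#'   [estimate_rrp()].
#' @return A list with `p_train` (first amplitude / intercept, reported
#'   clipped to 1 when it exceeds 1) and `flag` (`"gt_one"` when clipped,
#'   `"undefined"` with `p_train = NA` when the intercept is <= 0).
#' @export
p_train <- function(amplitudes, fit_intercept_nA) {
  a1 <- as.numeric(amplitudes)[1]
  if (!is.finite(fit_intercept_nA) || fit_intercept_nA <= 0)
    return(list(p_train = NA_real_, flag = "undefined"))
  p <- a1 / fit_intercept_nA
  if (p > 1) list(p_train = 1, flag = "gt_one")
  else list(p_train = p, flag = "none")
}

#' Single-phase decay fit to train depression
#'
#' Fits `a(i) = plateau + span * exp(-(i - 2) / tau)` to stimuli 2..10
#' (1-based) of a train's amplitudes by nonlinear least squares and returns
#' the decay constant in stimulus units. Depletion without replenishment
#' predicts geometric decay with `tau = -1 / log(1 - p)`.
#'
#' @param amplitudes Per-stimulus amplitudes, at least 10 values.
#' @return A list with `tau` (stimuli), `plateau`, `span` and `flag`
#'   (`"no_decay"` when the fitted span is not positive or the data do not
#'   decay; `"non_convergence"` when the fit fails).
#' @export
depression_decay_fit <- function(amplitudes) {
  a <- as.numeric(amplitudes)
  if (length(a) < 10) stop("need at least 10 amplitudes (points 2-10 fitted)")
  i <- 2:10
  y <- a[i]
  plateau0 <- mean(y[7:9])
  span0 <- y[1] - plateau0
  if (!is.finite(span0) || span0 <= 0 ||
      stats::sd(y) < 1e-12 * max(abs(y), 1e-300))
    return(list(tau = NA_real_, plateau = mean(y), span = 0,
                flag = "no_decay"))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau + span * exp(-(i - 2) / tau),
                      start = list(plateau = plateau0, span = span0,
                                   tau = 3),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, plateau = NA_real_, span = NA_real_,
                flag = "non_convergence"))
  cf <- stats::coef(fit)
  if (cf[["span"]] <= 0)
    return(list(tau = NA_real_, plateau = cf[["plateau"]],
                span = cf[["span"]], flag = "no_decay"))
  list(tau = cf[["tau"]], plateau = cf[["plateau"]], span = cf[["span"]],
       flag = "none")
}

#' Paired-pulse ratio
#'
#' Amplitude of the second response divided by the first, both measured with
#' the train measurement rules ([train_amplitudes()]).
#'
#' @param sweep A `trace` containing two evoked responses.
#' @param stimulus_times Exactly two stimulus onsets, seconds.
#' @return A list with `ppr` and `flag` (`"undefined"` with `ppr = NA` when
#'   the first amplitude is 0).
#' @export
paired_pulse_ratio <- function(sweep, stimulus_times) {
  if (length(stimulus_times) != 2)
    stop("paired-pulse analysis requires exactly two stimulus times")
  amps <- train_amplitudes(sweep, stimulus_times)
  if (amps[1] == 0) return(list(ppr = NA_real_, flag = "undefined"))
  list(ppr = amps[2] / amps[1], flag = "none")
}

#' Full train analysis of a sweep set
#'
#' Measures per-stimulus amplitudes on every sweep, averages them across
#' sweeps (at least five trains per synapse under the standard protocol),
#' and derives the cumulative-EPSC RRP estimate, P_train and the depression
#' decay constant from the averaged train. Per-sweep amplitude matrices are
#' returned alongside.
#'
#' @param sweeps A `sweep_set` with a train protocol.
#' @param quantal_size Mean mEPSC amplitude of the same cell (nA).
#' @param n_fit Cumulative points used in the back-extrapolation.
#' @return A list of class `train_result` with fields `amplitudes` (sweep
#'   average), `per_sweep` (matrix), `cumulative`, `fit_slope`,
#'   `fit_intercept_nA`, `rrp_quanta`, `p_train`, `decay` (the
#'   [depression_decay_fit()] result) and `flags`.
#' @export
analyze_train <- function(sweeps, quantal_size, n_fit = 10) {
  stopifnot(inherits(sweeps, "sweep_set"))
  per_sweep <- t(vapply(sweeps$sweeps, train_amplitudes,
                        numeric(length(sweeps$stimulus_times)),
                        stimulus_times = sweeps$stimulus_times))
  avg <- colMeans(per_sweep)
  rrp <- estimate_rrp(avg, quantal_size, n_fit = n_fit)
  pt <- p_train(avg, rrp$fit_intercept_nA)
  dec <- depression_decay_fit(avg)
  structure(list(amplitudes = avg, per_sweep = per_sweep,
                 cumulative = rrp$cumulative, fit_slope = rrp$fit_slope,
                 fit_intercept_nA = rrp$fit_intercept_nA,
                 rrp_quanta = rrp$rrp_quanta, p_train = pt$p_train,
                 decay = dec,
                 flags = c(rrp = rrp$flag, p_train = pt$flag,
                           decay = dec$flag)),
            class = "train_result")
}
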