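#' Parameters of the binomial vesicle-depletion release model
#'
#' The classical quantal release model: a pool of `n_pool` vesicles, each
#' released on a given stimulus with probability `p_r`, quantal amplitudes
#' lognormal with mean `q_mean` and coefficient of variation `q_cv`, and
#' continuous-rate replenishment between stimuli capped at the pool ceiling.
#' Release probability couples to external calcium as a power law:
#' `p_eff = p_r * (ca / ca_ref_mM)^ca_exponent`, with exponent ~3 as
#' established for this synapse.
#'
#' @param n_pool Integer > 0, vesicles in the readily-releasable pool.
#' @param p_r Per-stimulus release probability at `ca_ref_mM`, in (0, 1].
#' @param q_mean Mean quantal amplitude (mV or nA) > 0.
#' @param q_cv Lognormal CV of quantal size, >= 0.
#' @param replenish_rate Vesicles per second returned to the pool, >= 0.
#' @param ca_exponent Power-law exponent coupling `p_r` to calcium, > 0.
#' @param ca_ref_mM Calcium concentration (mM) at which `p_r` applies.
#' @return A list of class `release_model_params`.
#' @export
release_model_params <- function(n_pool = 500L, p_r = 0.25, q_mean = 0.8,
                                 q_cv = 0.3, replenish_rate = 0,
                                 ca_exponent = 3, ca_ref_mM = 3) {
  stopifnot(n_pool >= 1, p_r > 0, p_r <= 1, q_mean > 0, q_cv >= 0,
            replenish_rate >= 0, ca_exponent > 0, ca_ref_mM > 0)
  structure(list(n_pool = as.integer(n_pool), p_r = p_r, q_mean = q_mean,
                 q_cv = q_cv, replenish_rate = replenish_rate,
                 ca_exponent = ca_exponent, ca_ref_mM = ca_ref_mM),
            class = "release_model_params")
}

#' Parameters of the miniature-event train generator
#'
#' Spontaneous single-vesicle fusion events: Poisson timing, lognormal
#' amplitudes, double-exponential kinetics. `vglut_scale` multiplies the mean
#' amplitude only (vesicular-transporter overexpression enlarges quanta, ~1.55x,
#' without changing event rate).
#'
#' @param rate_hz Mean event rate, Hz.
#' @param amp_mean Mean amplitude (mV), before `vglut_scale`.
#' @param amp_cv Lognormal CV of amplitudes.
#' @param vglut_scale Quantal-size multiplier (1 for wild type).
#' @param rise_s,decay_s Kinetic time constants, seconds.
#' @param noise_sd Additive Gaussian noise SD (mV).
#' @return A list of class `mini_train_params`.
#' @export
mini_train_params <- function(rate_hz = 2, amp_mean = 0.9, amp_cv = 0.3,
                              vglut_scale = 1, rise_s = 0.002,
                              decay_s = 0.015, noise_sd = 0.05) {
  stopifnot(rate_hz > 0, amp_mean > 0, amp_cv >= 0, vglut_scale > 0,
            rise_s > 0, decay_s > rise_s, noise_sd >= 0)
  structure(list(rate_hz = rate_hz, amp_mean = amp_mean, amp_cv = amp_cv,
                 vglut_scale = vglut_scale, rise_s = rise_s,
                 decay_s = decay_s, noise_sd = noise_sd),
            class = "mini_train_params")
}

#' Parameters of the Arch voltage-imaging trace generator
#'
#' Each simulated sweep is the sum of a tissue-fluorescence exponential
#' decay, a saturating Arch photocycle brightening confined to the first
#' `photocycle_rise_ms`, an AP-shaped voltage transient after the stimulus,
#' and Gaussian noise. The AP transient is a generalized Gaussian
#' `exp(-|t/alpha|^beta)` whose full width (at 10% of peak) and width at half
#' maximum are *both* free parameters, so analytic ground truth exists for
#' the width pipeline.
#'
#' @param tissue_amp,tissue_tau_s Photobleach exponential amplitude (a.u.)
#'   and time constant (s).
#' @param offset Constant fluorescence floor (a.u.).
#' @param photocycle_rise_ms Duration of the initial Arch brightening (ms).
#' @param photocycle_amp Amplitude of the photocycle plateau (a.u.).
#' @param ap_peak AP transient amplitude (a.u.); depolarization brightens.
#' @param ap_width_ms Generator-true full width at 10% of peak (ms).
#' @param ap_whm_ms Generator-true width at half maximum (ms); must be
#'   smaller than `ap_width_ms`.
#' @param ap_latency_s Delay from stimulus onset to AP peak (s).
#' @param stim_time_s Stimulus time (s); imaging starts with 60 ms baseline.
#' @param fs_hz Sampling rate, Hz (spot imaging at 4 kHz).
#' @param duration_s Sweep duration, s.
#' @param extra_ap_prob Probability that a sweep carries a second,
#'   off-schedule AP (for rejection-rule testing), in [0, 1].
#' @param noise_sd Gaussian noise SD (a.u.).
#' @return A list of class `arch_trace_params`.
#' @export
arch_trace_params <- function(tissue_amp = 200, tissue_tau_s = 0.3,
                              offset = 100, photocycle_rise_ms = 10,
                              photocycle_amp = 20, ap_peak = 30,
                              ap_width_ms = 2.4, ap_whm_ms = 1.2,
                              ap_latency_s = 0.002, stim_time_s = 0.060,
                              fs_hz = 4000, duration_s = 0.15,
                              extra_ap_prob = 0, noise_sd = 1) {
  stopifnot(tissue_amp >= 0, tissue_tau_s > 0, photocycle_rise_ms > 0,
            ap_peak >= 0, ap_width_ms > ap_whm_ms, ap_whm_ms > 0,
            stim_time_s > 0.015, fs_hz > 0, duration_s > stim_time_s,
            extra_ap_prob >= 0, extra_ap_prob < 1 + 1e-12, noise_sd >= 0)
  structure(list(tissue_amp = tissue_amp, tissue_tau_s = tissue_tau_s,
                 offset = offset, photocycle_rise_ms = photocycle_rise_ms,
                 photocycle_amp = photocycle_amp, ap_peak = ap_peak,
                 ap_width_ms = ap_width_ms, ap_whm_ms = ap_whm_ms,
                 ap_latency_s = ap_latency_s, stim_time_s = stim_time_s,
                 fs_hz = fs_hz, duration_s = duration_s,
                 extra_ap_prob = extra_ap_prob, noise_sd = noise_sd),
            class = "arch_trace_params")
}

#' Parameters of the calcium line-scan generator
#'
#' Simulates ROI/background trace pairs from line scans across a single
#' bouton: the ROI obeys
#' `F(t) = f_background + (f_baseline - f_background) * (1 + dff(t))`
#' with `dff(t)` a single-AP calcium transient of true peak `dff_peak`,
#' multiplicative bleaching drift, and Gaussian noise. `drift_frac` is the
#' fractional change in resting fluorescence between the first and last
#' second of the record (negative = bleaching).
#'
#' @param f_baseline Resting ROI fluorescence (a.u.), > 0.
#' @param f_background Background fluorescence (a.u.), >= 0.
#' @param dff_peak True peak dF/F of the transient, >= 0.
#' @param decay_tau_s Transient decay time constant (s).
#' @param drift_frac Fractional resting-fluorescence change over the record.
#' @param fs_hz Line-scan rate, Hz (313 Hz standard).
#' @param n_scans Scans per bouton (8-12 standard).
#' @param stim_time_s Stimulus time, s (>= 0.3 so the baseline window exists).
#' @param duration_s Record duration, s.
#' @param noise_sd Gaussian noise SD (a.u.).
#' @return A list of class `ca_linescan_params`.
#' @export
ca_linescan_params <- function(f_baseline = 400, f_background = 80,
                               dff_peak = 0.35, decay_tau_s = 0.12,
                               drift_frac = 0, fs_hz = 313, n_scans = 10L,
                               stim_time_s = 0.5, duration_s = 3,
                               noise_sd = 2) {
  stopifnot(f_baseline > 0, f_background >= 0, f_background < f_baseline,
            dff_peak >= 0, decay_tau_s > 0, fs_hz > 0, n_scans >= 1,
            stim_time_s >= 0.3, duration_s > stim_time_s + 0.5, noise_sd >= 0)
  structure(list(f_baseline = f_baseline, f_background = f_background,
                 dff_peak = dff_peak, decay_tau_s = decay_tau_s,
                 drift_frac = drift_frac, fs_hz = fs_hz,
                 n_scans = as.integer(n_scans), stim_time_s = stim_time_s,
                 duration_s = duration_s, noise_sd = noise_sd),
            class = "ca_linescan_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# unit-mean lognormal multipliers with coefficient of variation cv
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n) * sdlog - sdlog^2 / 2)
}

# compact-support EPSC kernel: beta-shaped pulse on [0, support_s], exactly
# zero at and beyond support_s, normalized so its sampled maximum is 1
epsc_kernel <- function(support_s, dt, a = 1.5, b = 8) {
  k <- floor(support_s / dt)
  tt <- (seq_len(k) - 1) * dt
  u <- tt / support_s
  y <- u^a * (1 - u)^b
  y / max(y)
}

#' Simulate evoked EPSC sweeps from the depletion model
#'
#' Per stimulus, the released count is Binomial(current pool, effective
#' release probability); the pool is decremented by the released count and
#' replenished at `replenish_rate` between stimuli (capped at `n_pool`).
#' The EPSC amplitude is the sum of that stimulus's lognormal quantal sizes;
#' sweeps are rendered as downward current deflections on a 0 nA baseline
#' with compact-support kinetics that return exactly to baseline before the
#' next stimulus. Release probability is scaled by
#' `(ca_mM / ca_ref_mM)^ca_exponent`; a scaled probability above 1 is an
#' error unless `clip = TRUE`.
#'
#' @param params A [release_model_params()].
#' @param protocol `"train_60Hz_30"` (30 stimuli at 60 Hz),
#'   `"paired_pulse"` or `"single_AP"`.
#' @param ca_mM External calcium, mM.
#' @param n_sweeps Number of sweeps (trains) to simulate.
#' @param seed Integer seed fixing all randomness.
#' @param pp_interval_s Paired-pulse inter-stimulus interval, s.
#' @param fs_hz Sampling rate of the rendered sweeps, Hz.
#' @param noise_sd Additive Gaussian trace noise SD, nA.
#' @param clip If `TRUE`, silently clip effective p to 1.
#' @param t_first Time of the first stimulus, s.
#' @return A list with `sweeps` (a [sweep_set()], channel `current_nA`) and
#'   `ground_truth`: matrices `released` and `amplitudes`
#'   (`n_sweeps x n_stimuli`, magnitudes in nA), `pool_after` trajectory,
#'   and the effective release probability `p_eff`.
#' @export
simulate_evoked_train <- function(params,
                                  protocol = c("train_60Hz_30",
                                               "paired_pulse", "single_AP"),
                                  ca_mM = params$ca_ref_mM, n_sweeps = 5L,
                                  seed = 1L, pp_interval_s = 0.03,
                                  fs_hz = 10000, noise_sd = 0, clip = FALSE,
                                  t_first = 0.05) {
  stopifnot(inherits(params, "release_model_params"))
  protocol <- match.arg(protocol)
  stopifnot(n_sweeps >= 1, ca_mM > 0)
  p_eff <- params$p_r * (ca_mM / params$ca_ref_mM)^params$ca_exponent
  if (p_eff > 1) {
    if (!clip)
      stop(sprintf(paste0("effective release probability %.3f exceeds 1 ",
                          "after calcium scaling; pass clip = TRUE to clip"),
                   p_eff))
    p_eff <- 1
  }
  dt <- 1 / fs_hz
  stim_rel <- switch(protocol,
                     train_60Hz_30 = (0:29) / 60,
                     paired_pulse = c(0, pp_interval_s),
                     single_AP = 0)
  # snap stimuli to the sample grid so kernel samples align across stimuli
  stim_times <- round((t_first + stim_rel) / dt) * dt
  n_stim <- length(stim_times)
  isi <- if (n_stim > 1) diff(stim_times) else numeric(0)
  # kernel must return to zero before the next stimulus' 2 ms baseline
  # window so measured amplitudes match ground truth exactly
  support <- min(0.014, if (n_stim > 1) min(isi) - 0.0021 else Inf)
  if (support <= 2 * dt) stop("inter-stimulus interval too short for kernel")
  kern <- -epsc_kernel(support, dt)  # downward EPSC, sampled peak = -1
  duration <- stim_times[n_stim] + 0.05
  n_samp <- ceiling(duration / dt)

  released <- matrix(0L, n_sweeps, n_stim)
  amplitudes <- matrix(0, n_sweeps, n_stim)
  pool_after <- matrix(0, n_sweeps, n_stim)
  sweeps <- vector("list", n_sweeps)

  with_seed(seed, {
    for (s in seq_len(n_sweeps)) {
      pool <- as.numeric(params$n_pool)
      y <- numeric(n_samp)
      for (i in seq_len(n_stim)) {
        avail <- floor(pool + 1e-9)
        r <- if (avail > 0) stats::rbinom(1L, avail, p_eff) else 0L
        amp <- if (r > 0)
          params$q_mean * sum(rlnorm_unit(r, params$q_cv)) else 0
        pool <- pool - r
        if (i < n_stim)
          pool <- min(params$n_pool, pool + params$replenish_rate * isi[i])
        released[s, i] <- r
        amplitudes[s, i] <- amp
        pool_after[s, i] <- pool
        i0 <- round(stim_times[i] / dt) + 1L
        idx <- i0:(i0 + length(kern) - 1L)
        keep <- idx <= n_samp
        y[idx[keep]] <- y[idx[keep]] + amp * kern[keep]
      }
      if (noise_sd > 0) y <- y + stats::rnorm(n_samp, sd = noise_sd)
      sweeps[[s]] <- trace(y, dt = dt, t0 = 0, channel = "current_nA",
                           label = sprintf("evoked_%s_sweep%d", protocol, s))
    }
  })
  ss <- sweep_set(sweeps, stim_times, protocol =
                    if (protocol == "single_AP") "single_AP"
                    else if (protocol == "paired_pulse") "paired_pulse"
                    else "train_60Hz_30",
                  meta = recording_meta(ca_external_mM = ca_mM,
                                        clamp_mode = "TEVC"))
  list(sweeps = ss,
       ground_truth = list(released = released, amplitudes = amplitudes,
                           pool_after = pool_after, p_eff = p_eff,
                           stim_times = stim_times))
}

#' Simulate a spontaneous miniature-event record
#'
#' Event times form a Poisson process; amplitudes are lognormal with mean
#' `amp_mean * vglut_scale`; each event is a double-exponential deflection
#' normalized so the (continuous-time) peak equals the drawn amplitude.
#' Identical seeds with different `vglut_scale` yield identical event times
#' and amplitudes scaled exactly by the ratio of scales.
#'
#' @param params A [mini_train_params()].
#' @param duration_s Record duration, s.
#' @param seed Integer seed.
#' @param fs_hz Sampling rate, Hz.
#' @return A list with `trace` (voltage_mV) and `events`, a data.frame of
#'   ground-truth `t_onset`, `t_peak` and `amplitude` (mV).
#' @export
simulate_mini_record <- function(params, duration_s, seed = 1L,
                                 fs_hz = 10000) {
  stopifnot(inherits(params, "mini_train_params"), duration_s > 0)
  dt <- 1 / fs_hz
  n_samp <- ceiling(duration_s / dt)
  tr <- params$rise_s; td <- params$decay_s
  t_pk <- tr * td / (td - tr) * log(td / tr)
  h_max <- exp(-t_pk / td) - exp(-t_pk / tr)
  klen <- min(n_samp, ceiling(8 * td / dt))
  kt <- (seq_len(klen) - 1) * dt
  kern <- (exp(-kt / td) - exp(-kt / tr)) / h_max

  out <- with_seed(seed, {
    n_ev <- stats::rpois(1L, params$rate_hz * duration_s)
    t_on <- sort(stats::runif(n_ev, 0, max(0, duration_s - 10 * tr)))
    amps <- params$amp_mean * params$vglut_scale *
      rlnorm_unit(n_ev, params$amp_cv)
    y <- numeric(n_samp)
    for (i in seq_len(n_ev)) {
      i0 <- floor(t_on[i] / dt) + 1L
      idx <- i0:min(n_samp, i0 + klen - 1L)
      y[idx] <- y[idx] + amps[i] * kern[seq_along(idx)]
    }
    if (params$noise_sd > 0) y <- y + stats::rnorm(n_samp, sd = params$noise_sd)
    list(y = y, t_on = t_on, amps = amps)
  })
  ev <- data.frame(t_onset = out$t_on, t_peak = out$t_on + t_pk,
                   amplitude = out$amps)
  list(trace = trace(out$y, dt = dt, t0 = 0, channel = "voltage_mV",
                     label = "synthetic mini record"),
       events = ev)
}

#' Simulate calcium line-scan ROI/background trace pairs
#'
#' @param params A [ca_linescan_params()].
#' @param seed Integer seed.
#' @return A list with `scans` (a list of `n_scans` elements, each holding
#'   `roi` and `background` traces) and `ground_truth` (`dff_peak`, the
#'   noiseless dF/F trace, stimulus time).
#' @export
simulate_ca_linescan <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ca_linescan_params"))
  dt <- 1 / params$fs_hz
  n_samp <- ceiling(params$duration_s / dt)
  tt <- (seq_len(n_samp) - 1) * dt
  t_stim <- round(params$stim_time_s / dt) * dt
  dff_true <- ifelse(tt >= t_stim,
                     params$dff_peak * exp(-(tt - t_stim) / params$decay_tau_s),
                     0)
  roi_clean <- params$f_background +
    (params$f_baseline - params$f_background) * (1 + dff_true)
  # bleach factor: resting fluorescence changes by drift_frac between the
  # centers of the first and last second of the record
  bleach <- 1 + params$drift_frac * (tt - 0.5) /
    max(params$duration_s - 1, 1e-9)
  roi_clean <- roi_clean * bleach

  scans <- with_seed(seed, {
    lapply(seq_len(params$n_scans), function(i) {
      roi <- roi_clean +
        if (params$noise_sd > 0) stats::rnorm(n_samp, sd = params$noise_sd)
        else 0
      bg <- rep(params$f_background, n_samp) +
        if (params$noise_sd > 0) stats::rnorm(n_samp, sd = params$noise_sd)
        else 0
      list(roi = trace(roi, dt = dt, t0 = 0, channel = "fluorescence_au",
                       label = sprintf("roi_scan%02d", i)),
           background = trace(bg, dt = dt, t0 = 0,
                              channel = "fluorescence_au",
                              label = sprintf("bg_scan%02d", i)))
    })
  })
  list(scans = scans,
       ground_truth = list(
         dff_peak = params$dff_peak,
         dff_trace = trace(dff_true, dt = dt, t0 = 0,
                           channel = "fluorescence_au", label = "true dff"),
         stim_time_s = t_stim))
}

# generalized-Gaussian pulse with prescribed full width (at frac_full of
# peak) and width at half maximum; returns function of time offset from peak
gen_gaussian_pulse <- function(width_s, whm_s, frac_full = 0.1) {
  ratio <- width_s / whm_s
  beta <- log(log(1 / frac_full) / log(2)) / log(ratio)
  alpha <- (whm_s / 2) / log(2)^(1 / beta)
  function(dt_s) exp(-abs(dt_s / alpha)^beta)
}

#' Simulate Arch voltage-imaging sweeps
#'
#' Each sweep is tissue photobleach decay + photocycle brightening (confined
#' to the first `photocycle_rise_ms`) + an AP-shaped fluorescence transient
#' after the stimulus + noise. With probability `extra_ap_prob` a sweep
#' carries a second AP at a uniform random offset >= 20 ms after the
#' stimulus, to exercise the artifact-rejection rule.
#'
#' @param params An [arch_trace_params()].
#' @param n_events Number of sweeps (events collected per bouton).
#' @param seed Integer seed.
#' @return A list with `sweeps` (a [sweep_set()], protocol `arch_spot`) and
#'   `ground_truth`: the noiseless AP waveform (a `trace` of the transient
#'   alone), analytic `ap_width_ms`/`ap_whm_ms`, and the per-sweep
#'   `has_extra_ap` flags.
#' @export
simulate_arch_record <- function(params, n_events = 40L, seed = 1L) {
  stopifnot(inherits(params, "arch_trace_params"), n_events >= 1)
  dt <- 1 / params$fs_hz
  n_samp <- ceiling(params$duration_s / dt)
  tt <- (seq_len(n_samp) - 1) * dt
  t_stim <- round(params$stim_time_s / dt) * dt
  t_ap <- t_stim + params$ap_latency_s
  pulse <- gen_gaussian_pulse(params$ap_width_ms / 1000,
                              params$ap_whm_ms / 1000)
  ap <- params$ap_peak * pulse(tt - t_ap)
  pc_rise_s <- params$photocycle_rise_ms / 1000
  base <- params$offset + params$tissue_amp * exp(-tt / params$tissue_tau_s) +
    params$photocycle_amp * pmin(tt / pc_rise_s, 1)

  out <- with_seed(seed, {
    extra <- stats::runif(n_events) < params$extra_ap_prob
    sweeps <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      y <- base + ap
      if (extra[i]) {
        off <- stats::runif(1, 0.020,
                            max(0.021, params$duration_s - t_stim - 0.01))
        y <- y + 0.9 * params$ap_peak * pulse(tt - (t_stim + off))
      }
      if (params$noise_sd > 0)
        y <- y + stats::rnorm(n_samp, sd = params$noise_sd)
      sweeps[[i]] <- trace(y, dt = dt, t0 = 0, channel = "fluorescence_au",
                           label = sprintf("arch_sweep%03d", i))
    }
    list(sweeps = sweeps, extra = extra)
  })
  ss <- sweep_set(out$sweeps, t_stim, protocol = "arch_spot")
  list(sweeps = ss,
       ground_truth = list(
         ap_waveform = trace(ap, dt = dt, t0 = 0,
                             channel = "fluorescence_au",
                             label = "true AP waveform"),
         ap_width_ms = params$ap_width_ms, ap_whm_ms = params$ap_whm_ms,
         ap_peak = params$ap_peak, stim_time_s = t_stim,
         has_extra_ap = out$extra))
}

#' Simulate a calcium-cooperativity dataset
#'
#' Runs single-AP depletion-model simulations at each calcium level and
#' tabulates mean quantal content (ground-truth EPSC amplitude divided by
#' the mean quantal size) with SEM. With the power-law calcium coupling of
#' [release_model_params()], expected quantal content is proportional to
#' `ca^ca_exponent` wherever the scaled release probability stays below 1.
#'
#' @param params A [release_model_params()].
#' @param ca_levels_mM Numeric vector of >= 3 calcium levels, mM.
#' @param sweeps_per_level Sweeps simulated per level, >= 1.
#' @param seed Integer seed.
#' @return A data.frame with columns `ca_mM`, `qc_mean`, `qc_sem`, `n`.
#' @export
simulate_cooperativity_dataset <- function(params, ca_levels_mM,
                                           sweeps_per_level, seed = 1L) {
  stopifnot(inherits(params, "release_model_params"))
  if (length(ca_levels_mM) < 3)
    stop("at least 3 calcium levels are required")
  if (sweeps_per_level < 1) stop("sweeps_per_level must be >= 1")
  rows <- lapply(seq_along(ca_levels_mM), function(i) {
    sim <- simulate_evoked_train(params, protocol = "single_AP",
                                 ca_mM = ca_levels_mM[i],
                                 n_sweeps = sweeps_per_level,
                                 seed = seed + i)
    qc <- sim$ground_truth$amplitudes[, 1] / params$q_mean
    data.frame(ca_mM = ca_levels_mM[i], qc_mean = mean(qc),
               qc_sem = stats::sd(qc) / sqrt(length(qc)),
               n = length(qc))
  })
  do.call(rbind, rows)
}

#' Simulate a homeostatic set-point population
#'
#' For each miniature amplitude `m`, emits a synthetic recording whose
#' quantal content is `setpoint_epsp_mV / m` perturbed by unit-mean
#' multiplicative lognormal noise — the population a perfect homeostat
#' produces, used as ground truth for the homeostasis curve fit.
#'
#' @param setpoint_epsp_mV The EPSP set-point, mV, > 0.
#' @param mepsp_values_mV Vector of miniature amplitudes, mV, all > 0.
#' @param noise_cv CV of the multiplicative noise on quantal content.
#' @param seed Integer seed.
#' @return A data.frame with columns `mepsp_mean`, `quantal_content`,
#'   `epsp_mean`.
#' @export
simulate_homeostasis_population <- function(setpoint_epsp_mV,
                                            mepsp_values_mV, noise_cv = 0,
                                            seed = 1L) {
  if (!length(mepsp_values_mV)) stop("mepsp_values_mV must be non-empty")
  stopifnot(setpoint_epsp_mV > 0, all(mepsp_values_mV > 0), noise_cv >= 0)
  qc <- with_seed(seed, {
    setpoint_epsp_mV / mepsp_values_mV *
      rlnorm_unit(length(mepsp_values_mV), noise_cv)
  })
  data.frame(mepsp_mean = mepsp_values_mV, quantal_content = qc,
             epsp_mean = qc * mepsp_values_mV)
}
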