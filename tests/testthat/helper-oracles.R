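# shared fixtures and small independent oracles used across test files

# match detected events to ground-truth peaks within a time tolerance;
# returns recall and precision
match_events <- function(detected_t, truth_t, tol_s = 0.005) {
  if (!length(truth_t))
    return(c(recall = NA_real_, precision = NA_real_))
  recall <- mean(vapply(truth_t, function(tp)
    any(abs(detected_t - tp) < tol_s), logical(1)))
  precision <- if (length(detected_t))
    mean(vapply(detected_t, function(tp)
      any(abs(truth_t - tp) < tol_s), logical(1))) else 0
  c(recall = recall, precision = precision)
}

# closed-form expected train amplitudes of the depletion model without
# replenishment: E[a_i] = q * p * N * (1-p)^(i-1)
depletion_expected_amplitudes <- function(n_pool, p, q, n_stim = 30) {
  q * p * n_pool * (1 - p)^(seq_len(n_stim) - 1)
}

# pooled-variance two-sample t statistic, written out from the formula
pooled_t_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# default noiseless arch generator settings reused across tests; any
# explicit argument overrides the noiseless defaults
arch_noiseless <- function(...) {
  args <- list(...)
  if (is.null(args$noise_sd)) args$noise_sd <- 0
  if (is.null(args$extra_ap_prob)) args$extra_ap_prob <- 0
  do.call(arch_trace_params, args)
}

# delta-method standard error of mean(y)/mean(x) from paired samples
ratio_of_means_se <- function(y, x) {
  n <- length(x)
  r <- mean(y) / mean(x)
  v <- (stats::var(y) + r^2 * stats::var(x) -
          2 * r * stats::cov(x, y)) / (n * mean(x)^2)
  sqrt(max(v, 0))
}
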