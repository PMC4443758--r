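#!/usr/bin/env Rscript
# Simulate the full two-genotype study the downstream analyses consume:
# a wild-type condition and a vGlut-overexpression-like condition in which
# quantal size is scaled by 1.55 and release probability is scaled down by
# the same factor (presynaptic homeostatic depression holding the evoked
# response at its set-point). Trace data (CSV + manifests) go to
# scratch/simdata/; ground truth to scratch/simdata/ground_truth.json.

suppressPackageStartupMessages(library(nmjquant))

seed <- 20260930
root <- file.path("scratch", "simdata")
unlink(root, recursive = TRUE)

genotypes <- list(
  wt = list(q = 0.8, p_r = 0.30, mepsp = 0.9, vglut = 1.00, dff = 0.35),
  vglut_oe = list(q = 0.8 * 1.55, p_r = 0.30 / 1.55, mepsp = 0.9,
                  vglut = 1.55, dff = 0.18)
)

truth <- list()
i <- 0
for (g in names(genotypes)) {
  gp <- genotypes[[g]]
  i <- i + 1
  rel <- release_model_params(n_pool = 300, p_r = gp$p_r, q_mean = gp$q,
                              q_cv = 0.3, replenish_rate = 300)

  tr <- simulate_evoked_train(rel, "train_60Hz_30", n_sweeps = 5,
                              seed = seed + i * 10)
  write_sweep_set(tr$sweeps, file.path(root, paste0(g, "_train")))

  pp <- simulate_evoked_train(rel, "paired_pulse", n_sweeps = 8,
                              seed = seed + i * 10 + 1)
  write_sweep_set(pp$sweeps, file.path(root, paste0(g, "_ppr")))

  sa <- simulate_evoked_train(rel, "single_AP", n_sweeps = 10,
                              seed = seed + i * 10 + 2)
  write_sweep_set(sa$sweeps, file.path(root, paste0(g, "_single")))

  mini <- simulate_mini_record(
    mini_train_params(rate_hz = 2, amp_mean = gp$mepsp, amp_cv = 0.3,
                      vglut_scale = gp$vglut, noise_sd = 0.05),
    duration_s = 60, seed = seed + i * 10 + 3)
  write_trace(mini$trace, file.path(root, paste0(g, "_minis.csv")))

  ca <- simulate_ca_linescan(
    ca_linescan_params(dff_peak = gp$dff, n_scans = 10, noise_sd = 2,
                       drift_frac = -0.05),
    seed = seed + i * 10 + 4)
  write_ca_scans(ca$scans, file.path(root, paste0(g, "_ca")),
                 ca$ground_truth$stim_time_s)

  ar <- simulate_arch_record(
    arch_trace_params(noise_sd = 1, extra_ap_prob = 0.1),
    n_events = 30, seed = seed + i * 10 + 5)
  write_sweep_set(ar$sweeps, file.path(root, paste0(g, "_arch")))

  truth[[g]] <- list(n_pool = 300, p_r = gp$p_r, q_mean = gp$q,
                     mepsp_mean = gp$mepsp * gp$vglut, dff_peak = gp$dff,
                     ap_whm_ms = 1.2, ap_width_ms = 2.4,
                     mini_truth_n = nrow(mini$events))
}
jsonlite::write_json(truth, file.path(root, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat("simulated study written to", root, "\n")
cat("genotypes:", paste(names(genotypes), collapse = ", "), "\n")
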