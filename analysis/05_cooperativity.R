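#!/usr/bin/env Rscript
# Calcium cooperativity of release: simulate single-AP quantal content
# across external calcium levels, fit the log-log power law, and evaluate
# the release decrease the power law predicts for a halved calcium signal.
# Writes results/cooperativity.csv and results/cooperativity_fit.json.

suppressPackageStartupMessages(library(nmjquant))

dir.create("results", showWarnings = FALSE)

params <- release_model_params(n_pool = 500, p_r = 0.3, q_mean = 1,
                               q_cv = 0.3, ca_ref_mM = 1.5, ca_exponent = 3)
levels <- c(0.3, 0.5, 0.75, 1.0, 1.5)
d <- simulate_cooperativity_dataset(params, levels, sweeps_per_level = 50,
                                    seed = 99)
write.csv(d, file.path("results", "cooperativity.csv"), row.names = FALSE)
print(d, row.names = FALSE)

fit <- cooperativity_fit(data.frame(ca_mM = d$ca_mM, qc = d$qc_mean))
cat(sprintf("\nlog-log cooperativity slope: %.3f (generator exponent: 3), r^2 = %.4f\n",
            fit$exponent, fit$r_squared))

pred <- predicted_release_change(0.5, 3)
cat(sprintf("release decrease predicted for a 50%% calcium drop (exponent 3): %.1f%%\n",
            pred))
cat("-> far larger than a ~30% release decrease; a halved spatially averaged\n")
cat("   calcium signal cannot by itself account for modest release changes\n")

jsonlite::write_json(
  list(exponent = fit$exponent, log_k = fit$log_k,
       r_squared = fit$r_squared,
       predicted_release_decrease_pct_at_half_ca = pred),
  file.path("results", "cooperativity_fit.json"), auto_unbox = TRUE,
  digits = NA)
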