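#!/usr/bin/env Rscript

# Step 1: simulate the two urgent tasks with the calibrated race model and
# save the trial tables and tachometric curves used by the later steps.
#
# Outputs (results/):
#   trials_cas.csv, trials_cps.csv         simulated sessions (50k trials)
#   curve_cas.csv, curve_cps.csv           tachometric curves
#   curve_cas_low.csv, curve_cps_low.csv   low-luminance variants
#   fit_landmarks.csv                      fitted timing landmarks

suppressPackageStartupMessages(library(tachorace))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
n_trials <- 50000

params_hi <- race_params()
params_lo <- race_params(luminance = "low")

message("Simulating high-luminance sessions (", n_trials, " trials/task)...")
cas <- filter_urgent(simulate_session(params_hi, "anti", n_trials, seed = 101))
cps <- filter_urgent(simulate_session(params_hi, "pro", n_trials, seed = 102))
write_trials(cas, file.path(out_dir, "trials_cas.csv"))
write_trials(cps, file.path(out_dir, "trials_cps.csv"))

curve_cas <- tachometric(cas, min_bin_n = 300, task = "anti")
curve_cps <- tachometric(cps, min_bin_n = 300, task = "pro")
write_curve(curve_cas, file.path(out_dir, "curve_cas.csv"))
write_curve(curve_cps, file.path(out_dir, "curve_cps.csv"))

message("Simulating low-luminance sessions...")
cas_lo <- filter_urgent(simulate_session(params_lo, "anti", n_trials,
                                         seed = 103))
cps_lo <- filter_urgent(simulate_session(params_lo, "pro", n_trials,
                                         seed = 104))
write_curve(tachometric(cas_lo, min_bin_n = 300, task = "anti"),
            file.path(out_dir, "curve_cas_low.csv"))
write_curve(tachometric(cps_lo, min_bin_n = 300, task = "pro"),
            file.path(out_dir, "curve_cps_low.csv"))

message("Fitting timing landmarks...")
fit_cas <- fit_anti(curve_cas)
fit_cps <- fit_pro(curve_cps)
print(fit_cas)
print(fit_cps)
landmarks <- data.frame(
  task = c("anti", "pro"),
  drop_point_ms = c(drop_point(fit_cas), NA),
  rise_point_ms = c(rise_point(fit_cas), rise_point(fit_cps)),
  mae = c(fit_cas$mae, fit_cps$mae))
write.csv(landmarks, file.path(out_dir, "fit_landmarks.csv"),
          row.names = FALSE)
message("Done: ", out_dir, "/")
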