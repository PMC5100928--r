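#!/usr/bin/env Rscript
# Stage 2: single-channel idealization and conductance estimation.
#
# Reads the recordings from stage 1; leak-subtracts, detects events (3 pA
# threshold, 0.5 ms minimum duration), fits amplitude histograms per
# condition, builds averaged open-channel I-V curves from the ramp
# ensembles, and estimates branch slope conductances.
#
# Writes results/amplitude_fits.tsv and results/slope_conductances.tsv.

suppressPackageStartupMessages(library(trpa1pore))

rec <- file.path("results", "recordings")
if (!dir.exists(rec)) stop("run analysis/01_simulate_recordings.R first")

## amplitude histograms at -60 mV --------------------------------------------
conds <- c("WT-150", "WT-500", "WT-150-Ba100", "E920A-150")
amp_rows <- lapply(conds, function(cond) {
  ss <- read_sweepset(file.path(rec, cond, "manifest.tsv"))
  pts <- unlist(lapply(seq_along(ss$sweeps), function(k) {
    corr <- subtract_leak(ss$sweeps[[k]], ss$controls[[k]])
    open_point_amplitudes(corr, detect_events(corr, threshold_pA = 3))
  }), use.names = FALSE)
  f <- fit_amplitude_states(pts, at_voltage_mV = -60)
  message(sprintf(
    "%-13s %d open levels: large %.0f pS%s",
    cond, f$n_components, f$conductances_pS[1],
    if (f$n_components == 2) {
      sprintf(", small %.0f pS (ratio %.2f)", f$conductances_pS[2],
              f$ratio_small_large)
    } else ""))
  data.frame(condition = cond, n_points = f$n_events,
             gamma_large_pS = f$conductances_pS[1],
             gamma_small_pS = if (f$n_components == 2) f$conductances_pS[2] else NA,
             ratio_small_large = f$ratio_small_large)
})
amp <- do.call(rbind, amp_rows)
message(sprintf("mean small/large conductance ratio across conditions: %.0f%%",
                100 * mean(amp$ratio_small_large)))

## branch slope conductances from ramps ---------------------------------------
iv_for <- function(cond) {
  ss <- read_sweepset(file.path(rec, paste0(cond, "-ramp"), "manifest.tsv"))
  average_open_iv(ss$sweeps, ss$controls, threshold_pA = 3)
}
iv_wt <- iv_for("WT-150")
iv_mut <- iv_for("E920A-150")
# the fit window must clear the noise-censoring band of the smallest level
gmin <- fixture_registry("E920A-150")$branch_conductances[["negative"]]
vmin <- gap_clear_voltage(gmin, threshold_pA = 3, noise_sd_pA = sqrt(2))
s_wt <- slope_conductance(iv_wt, v_min_mV = vmin)
s_mut <- slope_conductance(iv_mut, v_min_mV = vmin)
slopes <- data.frame(
  condition = rep(c("WT-150", "E920A-150"), each = 2),
  branch = rep(c("negative", "positive"), 2),
  conductance_pS = c(s_wt$negative$conductance_pS, s_wt$positive$conductance_pS,
                     s_mut$negative$conductance_pS, s_mut$positive$conductance_pS),
  se_pS = c(s_wt$negative$se_pS, s_wt$positive$se_pS,
            s_mut$negative$se_pS, s_mut$positive$se_pS))
message(sprintf(
  "E920A negative-branch conductance is %.0f%% of wild type (fit window |V| > %.0f mV)",
  100 * s_mut$negative$conductance_pS / s_wt$negative$conductance_pS, vmin))

write.table(amp, file.path("results", "amplitude_fits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(slopes, file.path("results", "slope_conductances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/amplitude_fits.tsv and results/slope_conductances.tsv")
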