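#!/usr/bin/env Rscript
# Stage 1: generate the synthetic recordings all later stages analyze.
#
# Writes, under results/recordings/: per-condition sweep ensembles (TSV +
# sidecar metadata + manifest) for the four -60 mV histogram conditions and
# ramp ensembles for the wild-type vs E920A branch-conductance comparison.

suppressPackageStartupMessages(library(trpa1pore))

seed <- 1L
out <- file.path("results", "recordings")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hold <- hold_protocol(-60, duration_s = 0.3)
ramp <- ramp_protocol()

hist_conditions <- c("WT-150", "WT-500", "WT-150-Ba100", "E920A-150")
message("simulating -60 mV hold ensembles (40 sweeps each, for event/",
        "histogram analysis): ", paste(hist_conditions, collapse = ", "))
for (j in seq_along(hist_conditions)) {
  write_sweepset(hist_conditions[j], hold, n_sweeps = 40,
                 seed = seed + 20000L * j,
                 dir = file.path(out, hist_conditions[j]))
}

message("simulating ramp ensembles (60 sweeps, large open level, for I-V ",
        "analysis): WT-150, E920A-150")
for (j in seq_along(c("WT-150", "E920A-150"))) {
  cond <- c("WT-150", "E920A-150")[j]
  fx <- only_large_openings(fixture_registry(cond))
  write_sweepset(fx, ramp, n_sweeps = 60, seed = seed + 910000L * j,
                 dir = file.path(out, paste0(cond, "-ramp")))
}

n_files <- length(list.files(out, recursive = TRUE, pattern = "[.]tsv$"))
message(sprintf("wrote %d TSV files under %s", n_files, out))
message("each manifest pairs every sweep with its nearest no-opening control")
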