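#!/usr/bin/env Rscript
# Step 4: report figures.
#
# Re-runs a lighter analysis pass (B = 1000) to hold the ensemble in
# memory, then renders the correlation heatmap (non-significant cells
# crossed out), the per-group bootstrap density panels, the box-plot
# panels, and the synoptic trend table under results/figures/.

library(barotrend)

cohort <- read_cohort_csv("results/cohort.csv")
cfg <- analysis_config(gamma = 0.1, B = 1000, n_perm = 1000, seed = 11)
bundle <- run_analysis(cohort, cfg)
files <- render_reports(bundle, "results/figures")
cat("Wrote:\n")
cat(paste(" ", files), sep = "\n")
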