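#!/usr/bin/env Rscript
# Group statistics on the track metrics: one-tailed Welch t-tests on
# velocity and persistence (mutant < wild type), chi-square on the pooled
# deviation-angle distributions, and Fisher's exact test on the
# marker-contribution table.

suppressPackageStartupMessages(library(pouchtrack))
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

metrics <- read.csv("results/metrics/track_metrics.csv")
angles <- read.csv("results/metrics/deviation_angles.csv")

mut <- metrics[metrics$group == "fgf8a_mut", ]
wt <- metrics[metrics$group == "wild_type", ]

tests <- list(
  velocity = welch_t_one_tailed(mut$velocity_um_per_min,
                                wt$velocity_um_per_min, "one_tailed_less"),
  persistence = welch_t_one_tailed(na.omit(mut$persistence),
                                   na.omit(wt$persistence), "one_tailed_less"),
  angle_distribution = compare_angle_distributions(
    bin_angles(angles$angle_deg[angles$group == "fgf8a_mut"], 8, "fgf8a_mut"),
    bin_angles(angles$angle_deg[angles$group == "wild_type"], 8, "wild_type"))
)
for (nm in names(tests)) { cat(nm, ": "); print(tests[[nm]]) }

contrib <- as.matrix(read.csv("results/data/contribution_table.csv",
                              row.names = 1))
fisher <- fisher_exact(contrib, "two_tailed")
cat("contribution: ")
print(fisher)

jsonlite::write_json(
  c(lapply(tests, unclass), list(contribution_fisher = unclass(fisher))),
  file.path(out, "comparisons.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat(sprintf("wrote %s\n", file.path(out, "comparisons.json")))
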