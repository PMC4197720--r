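#!/usr/bin/env Rscript
# Score the phenotype records on the pouch (0/1) and ceratobranchial
# (0/0.5/1/1.5-per-fusion) rubrics, summarize per genotype with the embryo
# as the unit, and compare genotypes with Tukey-Kramer.

suppressPackageStartupMessages(library(pouchtrack))
out <- "results/scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

phenos <- read_phenotypes("results/data/phenotypes.csv")
scores <- score_phenotypes(phenos)
write.csv(scores, file.path(out, "phenotype_scores.csv"), row.names = FALSE,
          quote = FALSE)

summary <- summarize_scores(phenos, unit = "embryo")
write.csv(summary, file.path(out, "score_summary.csv"), row.names = FALSE,
          quote = FALSE)
print(summary)

per_embryo <- aggregate(cbind(pouch_score, cb_score) ~ embryo_id + genotype,
                        data = scores, FUN = mean)
for (metric in c("pouch_score", "cb_score")) {
  cat("\nTukey-Kramer on", metric, "\n")
  tk <- tukey_kramer(split(per_embryo[[metric]], per_embryo$genotype))
  print(as.data.frame(tk), digits = 4)
  write.csv(as.data.frame(tk),
            file.path(out, sprintf("tukey_%s.csv", metric)),
            row.names = FALSE, quote = FALSE)
}
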