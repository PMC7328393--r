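#!/usr/bin/env Rscript
# Stage 3: rank the 36 descriptor x filter candidates against the manual
# distress-call counts: Spearman correlation and random forest permutation
# importance, plus the paired comparison of correlation strength between
# filter regimes.
#
# Reads results/corpus/, writes results/rank_table.csv.

suppressPackageStartupMessages(library(chickcall))

features <- read.csv("results/corpus/features.csv")
counts <- read.csv("results/corpus/counts.csv")
wide <- make_validation_matrix(features, counts)
message("counted minutes: ", nrow(wide))

tab <- rank_candidates(wide, seed = 1)
write.csv(tab, "results/rank_table.csv", row.names = FALSE)
top <- tab[1L, ]
message(sprintf("top candidate: %s (%s), rho = %.3f, importance = %.1f%%",
                top$parameter, top$band, top$spearman_rho,
                top$rf_importance))

for (b in c("highpass", "callregion")) {
  cmp <- compare_filter_rhos(tab, b, "unfiltered")
  message(sprintf("|rho| %s vs unfiltered: t = %.2f, df = %d, p = %.3g",
                  b, cmp$t, cmp$df, cmp$p))
}
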