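#!/usr/bin/env Rscript
# Stage 4: calibrate spectral entropy to distress-call count with a linear
# mixed model (flock random intercept, ML), testing whether the slope is
# age-dependent via a likelihood ratio test on the entropy x day
# interaction; then invert the line to predict counts from entropy.
#
# Reads results/corpus/, writes results/calibration.json.

suppressPackageStartupMessages(library(chickcall))

features <- read.csv("results/corpus/features.csv")
counts <- read.csv("results/corpus/counts.csv")
wide <- make_validation_matrix(features, counts)

cal <- fit_count_calibration(wide)
print(cal$fit)
message(sprintf("interaction LRT: chisq = %.2f, df = %d, p = %.3g -> %s",
                cal$interaction_lrt$chisq, cal$interaction_lrt$df,
                cal$interaction_lrt$p,
                if (cal$interaction_retained) "slope is age-dependent"
                else "slope age-independent; single line applies"))

for (e in c(0.95, 0.85, 0.75))
  message(sprintf("entropy %.2f -> %.0f predicted distress calls/min", e,
                  estimate_count_from_entropy(e, cal$fit)))

jsonlite::write_json(list(fit = unclass(cal$fit),
                          interaction_lrt = cal$interaction_lrt),
                     "results/calibration.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "columns")
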