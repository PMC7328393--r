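#!/usr/bin/env Rscript
# Stage 5: behaviour correlates and welfare forecasting. Fits the day-1 and
# day-2/3 behaviour models (backward stepwise, protected chick-count
# terms), then the next-day weight/mortality mixed models and the day-32
# endpoint regressions on daily median entropy.
#
# Reads results/corpus/, writes results/welfare_models.json and
# results/report.txt.

suppressPackageStartupMessages(library(chickcall))

features <- read.csv("results/corpus/features.csv")
counts <- read.csv("results/corpus/counts.csv")
behaviour <- read.csv("results/corpus/behaviour.csv")
farm <- read.csv("results/corpus/farm.csv")

res <- run_analyse(features, counts, behaviour, farm)

message("day-1 behaviour model:")
print(res$behaviour_fits$day1)
message("next-day log-mortality model:")
print(res$next_day_fits$mortality)
message("day-32 endpoint models (terms retained by selection):")
print(res$day32_fits$weight)
print(res$day32_fits$mortality)

export_results_json(res, "results/welfare_models.json")
writeLines(render_report(res), "results/report.txt")
message("report written to results/report.txt")
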