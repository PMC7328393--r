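#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study corpus.
#
# Emulates the field campaign (12 flocks, days 1-4 of placement): per-flock
# daily distress-call trajectories driven by a latent welfare factor, with
# the four pipeline tables written under results/corpus/. A small all-audio
# corpus (waveforms through the real extractor) is written separately under
# results/corpus_audio/ for the end-to-end checks.

suppressPackageStartupMessages(library(chickcall))

seed <- 1L
message("simulating 12-flock study (stats mode), seed ", seed)
st <- run_simulate("results/corpus", flocks = 12, days = 4,
                   welfare_effect = 1, seed = seed)
message("  minutes: ", nrow(st$truth), "; counted minutes: ", nrow(st$counts),
        "; behaviour videos: ", nrow(st$behaviour))

message("simulating 4-flock audio corpus (waveforms + real extractor)")
sta <- run_simulate("results/corpus_audio", flocks = 4, days = 2,
                    welfare_effect = 1, seed = seed, mode = "audio",
                    minutes_per_day = 3)
message("  audio minutes extracted: ", length(unique(sta$features$file_id)))
message("done; tables under results/corpus{,_audio}/")
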