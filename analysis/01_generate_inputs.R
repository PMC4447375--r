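#!/usr/bin/env Rscript
# Generates the synthetic inputs the two network models consume — a
# calibrated hypnogram, a state-conditioned spike raster, and the
# two-memory alternating input — and writes them under results/inputs/
# together with their summary statistics.

suppressPackageStartupMessages(library(sleepsyn))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

## Sleep architecture: 1000 cycles to check calibration, a short excerpt
## for the model runs.
hyp_long <- gen_hypnogram(1000, seed = seed)
sws <- hyp_long[hyp_long$state == "SWS", ]
message(sprintf("mean SWS episode: %.1f s (target ~87 s)",
                mean(sws$end_s - sws$start_s)))
message(sprintf("REM-to-REM intervals < 30 min: %.1f%% (target 91.6%%)",
                100 * rem_interval_fraction(hyp_long)))
write_hypnogram(hyp_long, "results/inputs/hypnogram_1000cycles.csv")

hyp <- gen_hypnogram(4, seed = seed + 1L)
write_hypnogram(hyp, "results/inputs/hypnogram_run.csv")

## State-conditioned raster over the short hypnogram (40 units).
ras <- gen_state_raster(hyp, n = 40, seed = seed + 2L)
write_raster(ras, "results/inputs/state_raster.csv")
for (st in c("WK", "SWS", "REM")) {
  rows <- hyp[hyp$state == st, ]
  len <- sum(rows$end_s - rows$start_s)
  cnt <- sum(vapply(ras$spikes, function(s) {
    sum(vapply(seq_len(nrow(rows)), function(k) {
      sum(s >= rows$start_s[k] & s < rows$end_s[k])
    }, numeric(1)))
  }, numeric(1)))
  message(sprintf("%s: %.2f Hz over %.0f s", st, cnt / (40 * len), len))
}

## Two-memory alternating input (200 units, 125 ms windows, sleep interval
## with halved rates), as consumed by the hippocampo-cortical model.
inp <- gen_two_memory_input(two_memory_config(t_sleep = 315, t_wake = 585),
                            duration = 900, seed = seed + 3L)
write_raster(inp$raster, "results/inputs/two_memory_raster.csv")
write.csv(data.frame(window = seq_along(inp$labels), memory = inp$labels),
          "results/inputs/two_memory_labels.csv", row.names = FALSE)
message(sprintf("two-memory input: %d windows, %.2f Hz mean unit rate",
                length(inp$labels), mean(raster_rates(inp$raster))))
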