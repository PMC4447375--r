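#!/usr/bin/env Rscript
# Aggregates the tables written by the preceding drivers into a single
# machine-readable summary (results/summary.json) and prints a digest.

suppressPackageStartupMessages(library(sleepsyn))
report("results")
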