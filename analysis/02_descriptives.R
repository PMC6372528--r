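#!/usr/bin/env Rscript
# Stage 2: sequence descriptives of the cohort -- the choice distribution
# over the seven levels, the most frequent complete sequences per goal
# condition, mean manifest up/down transition counts, pooled correlations
# among level, correctness and confidence, and the average residual
# autocorrelation after two-way (participant + item) demeaning.
#
# Reads:  results/cohort.csv
# Writes: results/summary.json, results/frequent_sequences.csv

suppressPackageStartupMessages({
  library(optparse)
  library(sathmm)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results")
)))

ds <- load_dataset(file.path(opts$outdir, "cohort.csv"))
summ <- sequence_summary(ds, k = 10, max_lag = 5)
print(summ)

write_summary(summ, file.path(opts$outdir, "summary.json"))
write.csv(summ$frequent_sequences,
          file.path(opts$outdir, "frequent_sequences.csv"), row.names = FALSE)
message("descriptives written to ", opts$outdir)
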