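#!/usr/bin/env Rscript
# Stage 3: fit the six-model comparison ladder (A, B, B1, B2a, B2b, B3)
# by EM and assemble the comparison table with AIC, BIC and the
# likelihood-ratio chain. The covariate rungs take a few minutes each on
# one core at the full cohort size; pass --models to fit a subset.
#
# Reads:  results/cohort.csv
# Writes: results/ladder.csv, results/ladder.json, results/fit_<model>.json

suppressPackageStartupMessages({
  library(optparse)
  library(sathmm)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20190206L),
  make_option("--outdir", type = "character", default = "results"),
  make_option("--models", type = "character", default = "A,B,B1,B2a,B2b,B3"),
  make_option("--restarts", type = "integer", default = 1L)
)))

ds <- load_dataset(file.path(opts$outdir, "cohort.csv"))
models <- strsplit(opts$models, ",")[[1]]
ctl <- em_control(tol = 1e-8, max_iter = 500,
                  n_restarts = opts$restarts, seed = opts$seed)

lad <- fit_ladder(ds, ctl, models = models)
print(lad)

write_comparison(lad$table,
                 csv = file.path(opts$outdir, "ladder.csv"),
                 json = file.path(opts$outdir, "ladder.json"))
for (nm in names(lad$fits)) {
  if (!inherits(lad$fits[[nm]], "error")) {
    write_hmm_json(lad$fits[[nm]],
                   file.path(opts$outdir, paste0("fit_", nm, ".json")))
  }
}
message("ladder written to ", opts$outdir)
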