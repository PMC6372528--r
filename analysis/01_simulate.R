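#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort that stands in for the
# (non-deposited) study data: 583 participants x 40 items, two goal
# conditions, truncated-normal pre-test scores, three sticky latent
# difficulty-preference states, and correctness/confidence channels
# calibrated to the reported marginal structure.
#
# Writes: results/cohort.csv, results/true_states.csv, results/sim_config.json

suppressPackageStartupMessages({
  library(optparse)
  library(sathmm)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20190206L),
  make_option("--outdir", type = "character", default = "results")
)))
dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = opts$seed)
sim <- simulate_dataset(cfg)
print(sim)

write_simulation(sim,
                 data_csv = file.path(opts$outdir, "cohort.csv"),
                 states_csv = file.path(opts$outdir, "true_states.csv"),
                 config_json = file.path(opts$outdir, "sim_config.json"))
message("cohort written to ", file.path(opts$outdir, "cohort.csv"))
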