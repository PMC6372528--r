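#!/usr/bin/env Rscript
# Stage 4: expected-probability effect surfaces. Two sets are produced:
#   (a) from the published coefficient blocks embedded in the package
#       (initial-state bars over condition x pre-test; transition
#       quadrants at the extremes of accumulated confidence/correctness),
#   (b) from this pipeline's own fitted models where stage 3 wrote them.
#
# Reads:  results/fit_<model>.json (optional)
# Writes: results/effects_*.csv

suppressPackageStartupMessages({
  library(optparse)
  library(sathmm)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results")
)))

ref <- reference_estimates()
init_grid <- covariate_grid(d = c(0, 1), p = c(0, 0.25, 0.5, 0.75, 1))
quad <- covariate_grid(f = c(0, 1), r = c(0, 1))
quad_d <- covariate_grid(d = c(0, 1), f = c(0, 1), r = c(0, 1))

write_effects(expected_initial(ref$B1$params, init_grid),
              file.path(opts$outdir, "effects_initial_published.csv"))
write_effects(expected_transitions(ref$B2b$params, quad),
              file.path(opts$outdir, "effects_transitions_published_B2b.csv"))
write_effects(expected_transitions(ref$B3$params, quad_d),
              file.path(opts$outdir, "effects_transitions_published_B3.csv"))

eff <- expected_transitions(ref$B2b$params, quad)
up_L <- eff[eff$f == 1 & eff$r == 0 & eff$from == "L", "up"][1]
message(sprintf("published B2b block, f=1, r=0: upward mass from L = %.1f%%",
                100 * up_L))

for (nm in c("B1", "B2b", "B3")) {
  path <- file.path(opts$outdir, paste0("fit_", nm, ".json"))
  if (!file.exists(path)) next
  params <- relabel_states(read_hmm_json(path)$params)$params
  grid <- if (nm == "B1") init_grid else if (nm == "B2b") quad else quad_d
  tab <- if (nm == "B1") expected_initial(params, grid)
         else expected_transitions(params, grid)
  write_effects(tab, file.path(opts$outdir, paste0("effects_fitted_", nm, ".csv")))
  message("fitted effect table written for ", nm)
}
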