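#!/usr/bin/env Rscript
# Generate a synthetic registry and write its file set.
#   Rscript scripts/simulate.R --preset single_cluster --seed 1 --out dir/
# Presets: null, single_cluster, paper_like, small_test.

suppressPackageStartupMessages(library(scanmap))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) {
    if (is.null(default)) stop("missing argument: ", flag)
    return(default)
  }
  args[i + 1]
}
preset <- get_arg("--preset", "null")
seed <- as.integer(get_arg("--seed", "20100"))
out <- get_arg("--out")

sim <- sim_registry(sim_scenario_preset(preset, seed = seed))
write_registry(sim, out)
cat(sprintf("wrote %s: %d cases, %d tracts, %d years\n", out,
  sum(sim$cases$cases), length(sim$geometry$ids),
  length(unique(sim$pop$year))))
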