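#!/usr/bin/env Rscript
# Generate the default synthetic paired cohort (45 subjects with BB/IS/OW
# triplets, nasal brushes for 27) and write it, plus the ground-truth
# sidecar, under results/bundle/. Later scripts load this bundle; none of
# them reads the sidecar.

suppressMessages(library(airwaybiogeo))

seed <- 104729L
sim <- simulate_cohort(sim_params(seed = seed, include_controls = TRUE))
paths <- write_dataset(sim$bundle, "results/bundle",
  ground_truth = sim$ground_truth
)

meta <- sim$bundle$sample_meta
cat(sprintf(
  "cohort: %d samples (%d subjects), %d taxa; NB subset n = %d\n",
  nrow(sim$bundle$counts), length(unique(meta$subject_id[!meta$is_control])),
  ncol(sim$bundle$counts), sum(meta$site == "NB")
))
cat("written:\n")
for (p in paths) cat(" ", p, "\n")
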