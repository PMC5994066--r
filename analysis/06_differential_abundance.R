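#!/usr/bin/env Rscript
# Per-OTU differential abundance between AA and HC nasal communities under
# the three-model framework (Poisson / negative binomial / zero-inflated
# negative binomial, AIC-selected), BH-corrected at q < 0.10.

source("analysis/00_config.R")
ch <- load_cohort()

sel <- ch$meta$site == "NB" & ch$meta$group %in% c("AA", "HC")
res <- da_scan(
  ch$canonical[sel, , drop = FALSE],
  factor(ch$meta$group[sel], levels = c("HC", "AA")),
  config
)
write_tsv(res, "results/da/nb_aa_vs_hc.tsv")

flagged <- res[res$flagged, ]
cat(sprintf(
  "%d of %d tested OTUs differ between AA and HC nasal communities (q < %.2f)\n",
  nrow(flagged), sum(!is.na(res$p)), config$fdr_q_da
))
print(as.data.frame(
  flagged[order(flagged$q), c("taxon", "family", "beta", "q", "direction")]
), digits = 3)
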