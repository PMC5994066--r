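#!/usr/bin/env Rscript
# Dominant-genus structure and clinical associations: per-sample dominance
# calls, Prevotella-dominance contingencies across sample types, the
# cytokine half-LOD preprocessing, the Spearman association scan in AA
# subjects, and the Corynebacterium-dominance subgroup comparison.

source("analysis/00_config.R")
ch <- load_cohort()

rel <- relative_abundance(collapse_to_genus(ch$canonical, ch$bundle$taxonomy))
calls <- dominant_genus_calls(rel, ch$meta)
freq <- dominance_frequency(calls, by = "site_group")

contingencies <- do.call(rbind, lapply(c("IS", "OW", "NB"), function(s) {
  res <- dominance_contingency(calls, "Prevotella", c("BB", s))
  res$comparison <- paste("BB vs", s)
  res
}))

clin <- cytokine_preprocess(ch$bundle$clinical, config)
assoc <- clinical_associations(
  rel, ch$meta, clin,
  group = "AA",
  threshold = config$prevalence_genus_threshold, config = config
)
subgroup <- dominance_subgroup_compare(calls, clin)

write_tsv(calls, "results/dominance/calls.tsv")
write_tsv(freq, "results/dominance/frequency.tsv")
write_tsv(contingencies, "results/dominance/prevotella_contingencies.tsv")
write_tsv(assoc, "results/dominance/clinical_associations.tsv")
write_tsv(subgroup, "results/dominance/corynebacterium_subgroup.tsv")

dom <- tapply(calls$dominant_genus == "Prevotella", calls$site, sum)
tot <- table(calls$site)
cat("Prevotella-dominated samples per site:\n")
for (s in c("BB", "IS", "OW", "NB")) cat(sprintf("  %s: %d/%d\n", s, dom[[s]], tot[[s]]))
cat("flagged AA associations (BH q <=", config$fdr_q_assoc, "):\n")
print(as.data.frame(
  assoc[assoc$flagged, c("genus_label", "site", "variable", "rho", "q")]
), digits = 2)
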