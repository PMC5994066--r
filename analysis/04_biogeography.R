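#!/usr/bin/env Rscript
# Shared-taxon biogeography: per-subject Venn partitions of detected OTUs
# across sampled sites, shared richness/PD fractions of the bronchial
# community, exclusive IS+BB genus frequencies, per-subject genus-profile
# correlations, prevalent-genus paired tests, and the Mantel comparison of
# the nasal and oral phylogenetic contributions to BB.

source("analysis/00_config.R")
ch <- load_cohort()

part <- shared_partition(ch$canonical, ch$meta)
regions <- region_size_summary(part)
sf <- shared_pd_fraction(ch$canonical, ch$meta, ch$bundle$tree)
freq <- shared_genus_frequency(
  part, ch$bundle$taxonomy, c("BB", "IS"),
  exclusive = TRUE, threshold = config$shared_subject_frequency_threshold
)
rel <- relative_abundance(collapse_to_genus(ch$canonical, ch$bundle$taxonomy))
cors <- do.call(rbind, lapply(c("IS", "OW", "NB"), function(s) {
  genus_profile_correlation(rel, ch$meta, "BB", s)$summary
}))
prev <- prevalent_genus_tests(
  rel, ch$meta,
  threshold = config$prevalence_genus_threshold,
  q_threshold = config$fdr_q_assoc
)
dm_nb <- shared_taxa_unifrac(part, ch$bundle$tree, "NB")
dm_ow <- shared_taxa_unifrac(part, ch$bundle$tree, "OW")
common <- intersect(rownames(dm_nb), rownames(dm_ow))
mant <- mantel_test(
  dm_nb[common, common], dm_ow[common, common],
  n_perm = config$mantel_permutations,
  seed = config$seed
)

write_tsv(part$region_sizes, "results/biogeo/region_sizes.tsv")
write_tsv(regions, "results/biogeo/region_summary.tsv")
write_tsv(sf, "results/biogeo/shared_fractions.tsv")
write_tsv(freq$frequencies, "results/biogeo/isbb_genus_frequencies.tsv")
write_tsv(cors, "results/biogeo/genus_profile_correlations.tsv")
write_tsv(prev, "results/biogeo/prevalent_genus_tests.tsv")
write_tsv(mant, "results/biogeo/mantel_shared_taxa.tsv")

cat("median fraction of BB richness shared, by site:\n")
print(round(100 * tapply(sf$richness_fraction, sf$site, median), 1))
cat("median genus-profile Pearson r to BB:\n")
print(cors[, c("pair", "median")])
cat(sprintf(
  "Mantel (NB-shared vs OW-shared inter-subject UniFrac): r = %.3f, p = %.2f\n",
  mant$estimate, mant$p_value
))
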