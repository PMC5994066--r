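# airwaybiogeo

Bacterial biogeography of paired adult airway samples in atopic asthma.

`airwaybiogeo` is an R package plus analysis workflow for 16S rRNA
amplicon studies in which several airway sites are sampled from the same
subjects — protected bronchial brush (BB), induced sputum (IS), oral wash
(OW), and nasal brush (NB) — across asthmatic (AA), atopic non-asthmatic
(ANA), and healthy control (HC) groups. The central scientific questions
it addresses: which minimally invasive sample type best reflects the
bronchial microbiota, which taxa the bronchial community shares with the
oral and nasal compartments, and whether nasal community structure
(*Corynebacterium* vs *Moraxella*) tracks markers of allergic
inflammation.

## What it computes

Given an OTU table, a rooted phylogeny, a Greengenes-style taxonomy, and
sample/clinical metadata, the pipeline produces:

- **Alpha diversity** over a multiple-rarefaction ensemble at a common
  depth *D* (default 26,185 reads): richness *S*, Shannon
  *H = −Σ pᵢ log₂ pᵢ*, Faith phylogenetic diversity (root-inclusive sum
  of branch lengths spanning the detected taxa), and Pielou evenness
  *J = H / log₂ S*; Wilcoxon matched-pairs tests between sites and
  Mann-Whitney tests between groups.
- **Beta diversity**: unweighted UniFrac
  *d(A,B) = Σ_unique bₑ / Σ_either bₑ* over tree edges, and normalized
  weighted UniFrac *Σ bₑ |p_A(e) − p_B(e)| / Σ_j d_j (p_Aj + p_Bj)*, both
  averaged over the rarefaction ensemble; classical-scaling PCoA;
  intra-subject paired distances to BB with Wilcoxon / paired-*t* /
  Welch-*t* contrasts; a likelihood-ratio test of sample type on PC1
  under a random-subject-intercept linear mixed model; and a permutation
  Mantel test comparing the phylogenetic contribution of the nasal and
  oral compartments to BB.
- **Shared-taxon partitioning**: per-subject Venn regions of detected
  OTUs across sampled sites, shared richness and PD fractions of the
  bronchial community, genus frequency distributions of sharing regions
  (retained at ≥20% of a group's subjects), per-subject genus-profile
  Pearson correlations, and ≥3%-prevalent-genus paired tests.
- **Dominance and clinical associations**: argmax dominant-genus calls
  with Fisher/chi-square contingency tests, half-LOD cytokine imputation
  with a 20%-detection filter, a Spearman scan of prevalent genera
  against clinical/inflammatory variables (BH-corrected, flagged at
  q ≤ 0.2), and dominance-subgroup comparisons.
- **Differential abundance** by the three-model count framework: per-OTU
  Poisson, negative binomial, and zero-inflated negative binomial fits
  with a log-depth offset, AIC model selection, Wald tests on the group
  log fold-change, and BH flags at q < 0.10.

Because the study's raw sequence data are not deposited, the package
ships a Dirichlet-multinomial **synthetic cohort generator**
(`simulate_cohort()`) that reproduces the design — 22 AA / 12 ANA / 11 HC
subjects with BB+IS+OW triplets and NB for a 27-subject subset — with
planted source-mixing structure (BB = 0.62·oral + 0.05·nasal + 0.33·lung;
IS = 0.35·OW + 0.65·BB), nasal dominance patterns, and clinical covariate
links, plus a ground-truth sidecar used only by parameter-recovery tests.

## Worked example

```r
library(airwaybiogeo)

sim    <- simulate_cohort(sim_params(seed = 42))
config <- pipeline_config(n_rarefactions = 3, seed = 7)
report <- run_all(sim$bundle, config)

pd <- report$paired_distances_unweighted
round(tapply(pd$distance, pd$pair, mean)[c("BB-IS", "BB-OW", "BB-NB")], 2)
#> BB-IS BB-OW BB-NB
#>  0.10  0.36  0.77

round(100 * tapply(report$shared_pd_fractions$richness_fraction,
                   report$shared_pd_fractions$site, median), 0)
#> IS NB OW
#> 88 21 62

subset(report$clinical_associations,
       genus == "Moraxella" & site == "NB" & variable == "bal_eos_frac",
       c(rho, q, flagged))
#>     rho      q flagged
#>   0.723 0.0461    TRUE
```

Reading: induced sputum sits far closer to the bronchial community than
oral wash does, and the nasal community is the most distinct; the oral
compartment accounts for ~62% of bronchial richness against ~21% for the
nose; and nasal *Moraxella* abundance tracks BAL eosinophilia in the
asthmatic group (flagged at BH q ≤ 0.2).

The full workflow over a written dataset is in `analysis/01_simulate.R`
… `analysis/06_differential_abundance.R`; each script prints what it
found and writes its tables under `results/`.

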