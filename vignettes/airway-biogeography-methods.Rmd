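---
title: "Methods: paired airway microbiome biogeography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired airway microbiome biogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design choices
behind `airwaybiogeo`, the way one would document any multi-site
microbiome pipeline whose conclusions depend on a chain of small
methodological decisions.

## The study design the package encodes

The pipeline targets paired-sample 16S data: each subject contributes a
protected bronchial brush (BB), induced sputum (IS), and oral wash (OW),
and a subset additionally a nasal brush (NB). Subjects belong to one of
three groups: atopic asthmatic (AA), atopic non-asthmatic (ANA), or
non-atopic healthy control (HC). The default design is 22 AA / 12 ANA /
11 HC with NB in 18 / 3 / 6 of them. All comparisons respect pairing:
between-site tests are within-subject (Wilcoxon signed rank, paired t),
between-group tests are unpaired (Mann-Whitney, Welch t), contingency
comparisons use Fisher's exact test (2 categories) or Pearson chi-square
without continuity correction.

## Rarefaction

Sequencing effort differs across samples, and presence/absence
statistics (unweighted UniFrac, shared-OTU partitions, richness) are
strongly depth-dependent, so every diversity computation runs on tables
rarefied without replacement to a common depth `D` (default 26,185
reads). Samples under `D` are dropped, never rescaled. "Multiply
rarefied" is implemented as an ensemble of `R` independent rarefactions
(default `R = 10`); alpha metrics and distance matrices are averaged
over the ensemble, which removes most of the subsampling noise (the test
suite checks that doubling `R` moves per-sample metrics by less than the
across-iteration standard error). Operations that need a single
presence/absence table — the shared-OTU partition and the dominance
calls — use the first ensemble member as the canonical table, so they
are deterministic given the master seed; a raw-count presence rule would
conflate detection effort with biology across samples of very different
depth.

Every stochastic step draws its seed from the master seed through a
fixed stream-splitting hash (`derive_seed`), so a bundle, a
configuration, and a seed reproduce every number bit-for-bit.

## Diversity metrics

Shannon diversity is computed in log base 2 (bits), the convention of
the QIIME-1 lineage of pipelines this analysis style descends from;
Pielou evenness divides by `log2(S)` so it is base-invariant. Faith PD
uses the root-inclusive convention: the PD of a set of tips is the sum
of branch lengths of the minimal subtree connecting the tips *and the
root*. Root handling changes values (a single-tip community has PD equal
to its root path, not zero), so the convention is stated and tested.

UniFrac is computed from an edge-incidence decomposition of the rooted
tree: for each edge, the set of descendant tips. Unweighted UniFrac is
unique branch length over total branch length across the two samples;
weighted UniFrac uses the normalized variant (denominator
`sum_j d_j (p_Aj + p_Bj)` over tips at root distance `d_j`) so values
stay in [0, 1] and are comparable across pairs. The implementation is
validated against a brute-force per-edge oracle on hundreds of random
trees at 1e-12, and unweighted UniFrac is property-tested as a metric
(symmetry, identity, triangle inequality).

PCoA is classical scaling: double-center `-D²/2`, eigendecompose, scale
eigenvectors by the square root of the eigenvalue. Axes with negative
eigenvalues (UniFrac matrices are generally non-Euclidean) are dropped
but the eigenvalues reported; each axis sign is fixed by making its
largest-magnitude loading positive, so ordinations are reproducible.

The effect of sample type on community composition is tested on PC1
with a linear mixed model, `PC1 ~ site + (1 | subject)`, fitted by ML;
inference is a likelihood-ratio test against the
intercept-plus-random-intercept null. LRT was chosen over
Satterthwaite-type approximations because it is self-contained and
asymptotically equivalent for this balanced design; a singular fit
(zero between-subject variance) falls back to one-way OLS ANOVA with a
warning. Whether PC1 should come from a pooled four-site ordination or
per-comparison ordinations is genuinely open; the package uses the
pooled ordination, which matches the way the ordination figure is
drawn, and exposes `lme_pc1` on any PC1 vector for the other reading.

## Shared-taxon partitioning and the Mantel construction

For each subject, every OTU detected in at least one of the subject's
sites is assigned to exactly one region of the presence/absence Venn
partition of those sites. "Exclusively shared between IS and BB" means
present in exactly {IS, BB} among the sites that subject has. Shared
richness/PD fractions of BB use the plain pairwise intersection
(present in both BB and the other site, regardless of third sites),
which is the quantity the "proportion of BB richness shared" summaries
describe.

The comparison of the nasal and oral phylogenetic contributions to the
bronchial community is a Mantel test between two inter-subject distance
matrices: matrix A is the unweighted UniFrac between subjects computed
on each subject's BB∩NB taxon set, matrix B the same on BB∩OW. This
construction is one reading of an ambiguous description ("based on OTUs
shared between paired samples"); it is isolated in
`shared_taxa_unifrac()` so an alternative construction can be swapped
in. Subjects with an empty shared set have no defined profile and are
dropped from both matrices. The Mantel statistic is the Pearson
correlation of off-diagonal entries; p is two-sided on |r| by joint
row/column permutation, `p = (1 + #{|r_perm| ≥ |r_obs|}) / (1 + n_perm)`.

## Dominance and clinical associations

"Dominated by genus g" is defined as g being the argmax of genus
relative abundance, with no minimum-share threshold; this is the
weakest definition consistent with the dominance frequencies the
analysis reproduces (21/27 BB, 23/27 IS, 12/27 OW, 0/27 NB for
*Prevotella*), and ties — possible only in degenerate data — break
lexicographically and are flagged. Two-sided Fisher p values use the
"probability ≤ observed" convention (the base-R convention); this is
stated because at least three two-sided conventions exist and they
disagree in the third decimal on these tables.

Cytokine panels carry left-censoring: below-LOD measurements are
imputed as one half of the analyte's lowest detected value, and
analytes detected in fewer than 20% of subjects are dropped before any
correlation is attempted. The association scan is Spearman correlation
of each ≥3%-prevalent genus (prevalence assessed per site within the
scanned group) against each numeric clinical variable,
Benjamini-Hochberg corrected across the entire scan, flagged at
q ≤ 0.2 — the permissive threshold appropriate for a hypothesis-
generating scan of a small cohort.

## The three-model differential-abundance framework

Each OTU passing a 10% prevalence filter is fitted under three count
models with log link and log-library-size offset: Poisson, negative
binomial (ML dispersion), and zero-inflated negative binomial with a
constant logit-linked zero-inflation probability, fitted by direct
numerical ML started from the negative-binomial solution. The
lowest-AIC converged fit is selected (ties to the simpler family), the
group effect is tested by Wald z on the log fold-change, and BH flags
are set at q < 0.10.

Two deliberate substitutions, made because the cited methodology names
mixed-effect versions without printing a specification: the fits are
fixed-effect GLMs, since each subject contributes exactly one sample to
any site-stratified scan and a random subject intercept would be
unidentifiable; and model selection is by AIC because no selection rule
is printed anywhere. Both are documented at the function level.

A known limitation, demonstrated in the calibration tests: with a
log-total-count offset, a strongly one-sided planted signal (e.g. 5% of
taxa enriched four-fold in one group) shifts the library sizes of that
group and biases the null taxa slightly toward "depleted", inflating
the realized false-discovery proportion even though sensitivity is
high and the global-null calibration is exact. Compositional
normalization (median-of-ratios, TMM) would mitigate this but is out of
scope for this framework; the null-calibration and sensitivity
properties are what the test suite asserts.

## The synthetic cohort: what it emulates, and what it does not

No sequence data are deposited for the study this pipeline reproduces,
so the package generates cohorts with the statistical structure the
analysis assumes:

- **Taxa and tree.** 120 OTUs in 16 genus-level clades (oral:
  *Prevotella*, *Streptococcus*, *Veillonella*, *Neisseria*,
  *Haemophilus*, *Fusobacterium*, *Porphyromonas*, *Actinomyces*,
  *Leptotrichia*, plus an unassigned-genus Neisseriaceae clade; nasal:
  *Corynebacterium*, *Staphylococcus*, *Moraxella*, *Alloiococcus*;
  lung-enriched: *Pseudomonas*, *Lactobacillus*). Each clade is a random
  coalescent subtree grafted onto a coalescent backbone, so genera are
  monophyletic and the genus-level collapse of synthetic data is
  meaningful. Within-genus abundances decay geometrically (ratio 0.55).
- **Source mixing.** Subject-level oral, nasal, and lung pools are
  Dirichlet draws (concentration 50) around base pools; the bronchial
  composition is `0.62·oral + 0.05·nasal + 0.33·lung`, encoding oral
  microaspiration as the dominant source of bronchial microbiota with a
  small nasal contribution; induced sputum is `0.35·OW + 0.65·BB`
  (salivary carry-over). These weights were chosen so that the oral
  compartment accounts for roughly 60% of bronchial richness and the
  nasal compartment for far less, and so that IS sits closer to BB than
  OW does — the qualitative pattern the pipeline must recover, not a
  fit to any particular printed number.
- **Nasal structure.** Each subject's nasal community is
  Corynebacterium-dominated with group-specific probability (1.0 HC,
  0.7 ANA, 0.5 AA); nasal *Moraxella* relative abundance is logit-normal
  with mean −3 (sd 1.5) in AA and effectively zero (mean −9) otherwise,
  so Moraxella-dominated noses occur only in asthmatics and *Moraxella*
  is never shared with BB in controls. The AA lung pool additionally
  carries *Haemophilus* and *Neisseria* OTUs whose within-genus order is
  reversed relative to the oral pool, producing asthma-specific
  exclusively-IS∩BB-shared OTUs.
- **Counts.** Dirichlet-multinomial (concentration 200) at log-normal
  depths floored at 27,000 reads — above the rarefaction depth, so no
  sample is lost. Plain multinomial sampling was rejected because real
  amplicon replicates are overdispersed.
- **Clinical covariates.** Group-structured distributions emulating the
  published cohort table (IgE, PC20 with censoring at 32 mg/mL,
  eosinophil fractions, eleven BAL cytokines with analyte-specific
  LODs, plus two sparse analytes that the 20%-detection rule must
  drop). Planted links in AA only: BAL eosinophil fraction is logistic
  in logit nasal *Moraxella* abundance (slope 0.8, noise sd 0.4), blood
  eosinophils and TNF follow weaker positive links, and IL-6/IL-7/IL-21
  decrease log-linearly in logit nasal *Corynebacterium* abundance
  (slope −0.7). One *Staphylococcus* OTU is enriched six-fold in AA
  nasal pools as the differential-abundance target; six-fold (rather
  than a smaller effect) keeps the single-cohort OTU-level confirmation
  well-powered at the n = 18 vs 6 nasal design.
- **Ground truth.** Everything planted — true compositions, pool
  memberships, dominance indicators, Moraxella logits, link slopes, the
  enriched OTU — is returned as a sidecar that the pipeline never
  reads; recovery tests compare pipeline output against it.

What the generator does **not** emulate: contaminant removal ambiguity
(controls carry clean blank-only taxa), PCR/chimera artifacts, the
empirical richness ordering between BB and OW/IS (the mixture
construction makes bronchial samples at least as taxon-rich as oral
wash, so the suite asserts only the robust claim that nasal communities
are far sparser than all lower-airway types), and any particular
printed cohort-level median. Passing recovery tests therefore
demonstrates that the pipeline detects structure of the planted kind at
realistic effect sizes — not that real airway data contain that
structure.

## Numerical conventions and degenerate inputs

- Wilcoxon signed-rank with all zero differences reports p = 1 with a
  warning (zero differences are dropped, the simplest convention).
- Mann-Whitney is exact for combined n ≤ 20 without ties, otherwise
  tie-corrected normal; Spearman is exact for n ≤ 9.
- Correlations on zero-variance vectors are flagged undefined (NA),
  never reported as 0.
- Genus labels are `"Family (Genus)"`, or the deepest assigned rank for
  genus-unassigned lineages, or `"Unclassified"`; Greengenes empty rank
  payloads (`g__`) are unassigned.
- Control-OTU removal takes an explicit taxon list; the convenience
  mode derives it as all taxa with nonzero counts in blank controls.
  Whether abundance-conditioned removal was intended in the original
  pipeline is unknowable from the text; the explicit list sidesteps it.
- All-zero or sub-prevalence taxa in the DA scan are recorded as
  skipped rather than dropped silently; non-converged fits exclude a
  family from selection, and a taxon with no converged fit is skipped.

## Problem sizes used by the test and acceptance runs

The replicate-based properties run at the study's own scale (45-subject
cohorts, depth 26,185) with small ensembles: parameter recovery uses 20
replicate cohorts with one rarefaction each, the DA calibration uses
1000-taxon simulations at 30 samples per group (8 null replicates plus
one 50-signal power run), and null calibrations of the mixed-model and
Mantel tests use 150 and 100 replicates. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bounds while keeping a
full run of the suite in the minutes range.
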