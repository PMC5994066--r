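#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline in one validated
#' object. Defaults follow the study design the package reproduces: samples
#' are multiply rarefied to 26,185 reads; "prevalent" genera are those
#' reaching at least 3% relative abundance in at least one sample;
#' shared-taxon genus frequency distributions keep genera found in at least
#' 20% of a group's subjects; induced-sputum samples with more than 80%
#' squamous epithelial cells are discarded; cytokines detectable in fewer
#' than 20% of subjects are dropped; differential abundance is flagged at
#' BH q < 0.10 and clinical association scans at BH q <= 0.20.
#'
#' @param rarefaction_depth Common read depth `D` for rarefaction (reads).
#' @param n_rarefactions Number of rarefied tables `R` in the ensemble.
#' @param seed Master seed for every stochastic step of the pipeline.
#' @param prevalence_genus_threshold Minimum relative abundance (fraction)
#'   a genus must reach in at least one sample to count as prevalent.
#' @param shared_subject_frequency_threshold Minimum fraction of subjects in
#'   which a genus must occupy a sharing region to be retained.
#' @param squamous_max Maximum tolerated squamous epithelial cell fraction
#'   for induced sputum samples.
#' @param detection_subject_fraction Minimum fraction of subjects with a
#'   detectable (above limit of detection) value for a cytokine analyte.
#' @param fdr_q_da BH q threshold for differential-abundance flags.
#' @param fdr_q_assoc BH q threshold for clinical-association flags.
#' @param mantel_permutations Number of permutations for the Mantel test.
#' @return A list of class `"airway_config"`.
#' @export
pipeline_config <- function(rarefaction_depth = 26185,
                            n_rarefactions = 10,
                            seed = 1L,
                            prevalence_genus_threshold = 0.03,
                            shared_subject_frequency_threshold = 0.20,
                            squamous_max = 0.80,
                            detection_subject_fraction = 0.20,
                            fdr_q_da = 0.10,
                            fdr_q_assoc = 0.20,
                            mantel_permutations = 999L) {
  stopifnot(
    rarefaction_depth >= 1,
    n_rarefactions >= 1,
    is.numeric(seed), length(seed) == 1
  )
  thr <- c(
    prevalence_genus_threshold, shared_subject_frequency_threshold,
    squamous_max, detection_subject_fraction, fdr_q_da, fdr_q_assoc
  )
  if (any(thr <= 0 | thr > 1)) {
    stop("all threshold parameters must lie in (0, 1]")
  }
  if (mantel_permutations < 99) stop("mantel_permutations must be >= 99")
  structure(
    list(
      rarefaction_depth = as.integer(rarefaction_depth),
      n_rarefactions = as.integer(n_rarefactions),
      seed = as.integer(seed),
      prevalence_genus_threshold = prevalence_genus_threshold,
      shared_subject_frequency_threshold = shared_subject_frequency_threshold,
      squamous_max = squamous_max,
      detection_subject_fraction = detection_subject_fraction,
      fdr_q_da = fdr_q_da,
      fdr_q_assoc = fdr_q_assoc,
      mantel_permutations = as.integer(mantel_permutations)
    ),
    class = "airway_config"
  )
}

#' @export
print.airway_config <- function(x, ...) {
  cat("airway biogeography pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-36s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a bounded child seed from a master seed and a stream label.
# Keeps every derived seed strictly below 2^31 so it is a valid R integer.
derive_seed <- function(seed, stream, i = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + i * 7919) %% 2147483647)
}

SITES <- c("BB", "IS", "OW", "NB")
GROUPS <- c("AA", "ANA", "HC")
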