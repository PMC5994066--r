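# Shared setup sourced by the analysis scripts: loads the bundle written
# by 01_simulate.R, applies QC, and builds the rarefaction ensemble.

suppressMessages(library(airwaybiogeo))

config <- pipeline_config(n_rarefactions = 10, seed = 104729L)

load_cohort <- function(dir = "results/bundle") {
  bundle <- load_dataset(
    file.path(dir, "counts.tsv"), file.path(dir, "taxonomy.tsv"),
    file.path(dir, "tree.nwk"), file.path(dir, "sample_metadata.tsv"),
    file.path(dir, "clinical.tsv")
  )
  qc <- apply_qc_filters(bundle, config)
  ensemble <- rarefy_ensemble(qc$counts, config)
  canonical <- ensemble$tables[[1]]
  list(
    bundle = qc, ensemble = ensemble, canonical = canonical,
    meta = qc$sample_meta[match(rownames(canonical), qc$sample_meta$sample_id), ]
  )
}

write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  message("wrote ", path)
}
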