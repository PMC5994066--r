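test_that("write/load round trip is the identity for TSV and BIOM encodings", {
  b <- toy_bundle()
  for (fmt in c("tsv", "biom")) {
    dir <- withr::local_tempdir()
    paths <- write_dataset(b, dir, format = fmt)
    b2 <- load_dataset(
      paths[["counts"]], paths[["taxonomy"]], paths[["tree"]],
      paths[["metadata"]], paths[["clinical"]]
    )
    expect_identical(b2$counts, b$counts)
    expect_equal(b2$sample_meta$subject_id, b$sample_meta$subject_id)
    expect_equal(b2$taxonomy$genus, b$taxonomy$genus)
    expect_equal(
      ape::write.tree(b2$tree), ape::write.tree(b$tree)
    )
    expect_equal(b2$clinical$ige, b$clinical$ige)
  }
})

test_that("BIOM-JSON and TSV encodings of one source load identically", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  p_tsv <- write_dataset(b, file.path(dir, "t"), format = "tsv")
  p_biom <- write_dataset(b, file.path(dir, "b"), format = "biom")
  b_tsv <- load_dataset(
    p_tsv[["counts"]], p_tsv[["taxonomy"]], p_tsv[["tree"]],
    p_tsv[["metadata"]], p_tsv[["clinical"]]
  )
  b_biom <- load_dataset(
    p_biom[["counts"]], p_biom[["taxonomy"]], p_biom[["tree"]],
    p_biom[["metadata"]], p_biom[["clinical"]]
  )
  expect_identical(b_tsv$counts, b_biom$counts)
})

test_that("validation errors name the offending taxon or pair", {
  b <- toy_bundle()
  counts <- cbind(b$counts, E = c(1L, 0L, 0L, 0L))
  tax <- rbind(
    b$taxonomy,
    parse_gg_lineage("E", "k__Bacteria; p__; c__; o__; f__; g__; s__")
  )
  expect_error(
    airway_bundle(counts, b$sample_meta, tax, b$tree, b$clinical),
    "missing from tree: E"
  )
  expect_error(
    airway_bundle(b$counts, b$sample_meta, b$taxonomy[-1, ], b$tree),
    "missing from taxonomy: A"
  )
  meta <- b$sample_meta
  meta$subject_id <- "S1"
  meta$site <- c("BB", "OW", "BB", "OW")
  expect_error(
    airway_bundle(b$counts, meta, b$taxonomy, b$tree),
    "duplicate \\(subject, site\\)"
  )
})

test_that("samples and taxa are canonicalized lexicographically at load", {
  b <- toy_bundle()
  shuffled <- b$counts[c(3, 1, 4, 2), c(4, 2, 1, 3)]
  b2 <- airway_bundle(shuffled, b$sample_meta, b$taxonomy, b$tree, b$clinical)
  expect_identical(b2$counts, b$counts)
})

test_that("QC removes control taxa and samples, leaving survivors unchanged", {
  b <- toy_bundle()
  cfg <- pipeline_config()
  # explicit control-taxon list
  filt <- suppressMessages(apply_qc_filters(b, cfg, control_taxa = c("C", "D")))
  expect_setequal(colnames(filt$counts), c("A", "B"))
  expect_identical(filt$counts[, c("A", "B")], b$counts[, c("A", "B")])
  expect_equal(nrow(attr(filt, "qc_log")), 2)
  # derived from flagged control samples
  meta <- b$sample_meta
  meta$is_control[meta$sample_id == "S2_OW"] <- TRUE
  b2 <- airway_bundle(b$counts, meta, b$taxonomy, b$tree, b$clinical)
  filt2 <- suppressMessages(apply_qc_filters(b2, cfg))
  expect_false("S2_OW" %in% rownames(filt2$counts))
  # all four taxa are nonzero in S2_OW, so everything is removed
  expect_equal(ncol(filt2$counts), 0)
  expect_error(
    suppressMessages(apply_qc_filters(b, cfg, control_taxa = "Z")),
    "not in table"
  )
})

test_that("high-squamous IS samples are excluded and QC is idempotent", {
  b <- toy_bundle()
  meta <- b$sample_meta
  meta$site <- c("BB", "IS", "BB", "IS")
  meta$sample_id <- paste0(meta$subject_id, "_", meta$site)
  meta$squamous_pct <- c(NA, 0.85, NA, 0.40)
  counts <- b$counts
  rownames(counts) <- meta$sample_id
  b2 <- airway_bundle(counts, meta, b$taxonomy, b$tree, b$clinical)
  cfg <- pipeline_config()
  filt <- suppressMessages(apply_qc_filters(b2, cfg))
  expect_false("S1_IS" %in% rownames(filt$counts))
  expect_true("S2_IS" %in% rownames(filt$counts))
  twice <- suppressMessages(apply_qc_filters(filt, cfg))
  expect_identical(twice$counts, filt$counts)
  # no QC flags, no control taxa: identity
  clean <- suppressMessages(apply_qc_filters(toy_bundle(), cfg, control_taxa = character(0)))
  expect_identical(clean$counts, toy_bundle()$counts)
})

test_that("genus collapse labels, aggregates, and conserves totals", {
  b <- toy_bundle()
  g <- collapse_to_genus(b$counts, b$taxonomy)
  # two Prevotella OTUs summed into one labeled column
  expect_true("Prevotellaceae (Prevotella)" %in% colnames(g))
  expect_equal(
    unname(g[, "Prevotellaceae (Prevotella)"]),
    unname(b$counts[, "A"] + b$counts[, "B"])
  )
  # genus-unassigned OTU labeled at family level
  expect_true("Neisseriaceae" %in% colnames(g))
  expect_equal(attr(g, "genus")[colnames(g) == "Neisseriaceae"], NA_character_)
  # conservation
  expect_equal(rowSums(g), rowSums(b$counts))
  # fully unassigned lineage goes to Unclassified
  tax <- b$taxonomy
  tax[tax$taxon == "D", c("kingdom", "phylum", "class", "order", "family", "genus")] <- NA
  g2 <- collapse_to_genus(b$counts, tax)
  expect_true("Unclassified" %in% colnames(g2))
  expect_equal(rowSums(g2), rowSums(b$counts))
})

test_that("Greengenes lineages parse with empty payloads as unassigned", {
  tx <- parse_gg_lineage(
    c("x", "y"),
    c(
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__; f__; g__; s__",
      "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Pseudomonadales; f__Moraxellaceae; g__Moraxella; s__"
    )
  )
  expect_equal(tx$class[1], "Bacilli")
  expect_true(is.na(tx$order[1]))
  expect_equal(tx$genus[2], "Moraxella")
})
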