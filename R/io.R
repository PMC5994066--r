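#' Assemble and validate a cohort bundle
#'
#' A bundle binds together the four inputs every downstream analysis
#' consumes: an OTU count matrix (samples x taxa), per-sample metadata,
#' a Greengenes-style taxonomy, a rooted phylogeny over the taxa, and a
#' subject-level clinical table. Samples and taxa are canonicalized to
#' lexicographic order at construction so every downstream computation is
#' deterministic regardless of input file ordering.
#'
#' Sample identifiers are `subject_id + "_" + site`, which guarantees
#' uniqueness of the (subject, site) pairs and joins directly to the
#' clinical table.
#'
#' @param counts Nonnegative integer matrix, samples in rows, taxa in
#'   columns, with dimnames.
#' @param sample_meta Data frame with columns `sample_id`, `subject_id`,
#'   `site` (one of BB, IS, OW, NB), `group` (AA, ANA, HC), and optionally
#'   `squamous_pct` (fraction, induced sputum only) and `is_control`.
#' @param taxonomy Data frame with columns `taxon` and the ranks
#'   `kingdom` ... `species` (character, `NA` = unassigned).
#' @param tree Rooted `ape::phylo` whose tips cover all count-table taxa.
#' @param clinical Data frame keyed by `subject_id`; cytokine analyte
#'   columns are prefixed `cyt_` and carry `NA` where the measurement fell
#'   below the limit of detection.
#' @return A list of class `"airway_bundle"`.
#' @export
airway_bundle <- function(counts, sample_meta, taxonomy, tree, clinical = NULL) {
  sample_meta <- tibble::as_tibble(sample_meta)
  taxonomy <- tibble::as_tibble(taxonomy)
  if (!is.null(clinical)) clinical <- tibble::as_tibble(clinical)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample rownames and taxon colnames")
  }
  counts <- counts[order(rownames(counts)), order(colnames(counts)), drop = FALSE]
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ]
  bundle <- structure(
    list(
      counts = counts, sample_meta = sample_meta,
      taxonomy = taxonomy, tree = tree, clinical = clinical
    ),
    class = "airway_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Validate a cohort bundle
#'
#' Checks the structural invariants: nonnegative integral counts, unique
#' taxa, unique (subject, site) pairs, taxonomy and tree coverage of every
#' taxon, and agreement between count-table subjects and the clinical table.
#' Errors name the offending taxon or sample.
#'
#' @param bundle An `airway_bundle`.
#' @return The bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  counts <- bundle$counts
  meta <- bundle$sample_meta
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon identifiers")
  if (any(is.na(meta$sample_id)) || !setequal(meta$sample_id, rownames(counts))) {
    stop("sample_meta does not match count-table samples")
  }
  key <- paste(meta$subject_id, meta$site)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicate (subject, site) pair: ", dup[[1]])
  bad_site <- setdiff(unique(meta$site), SITES)
  if (length(bad_site)) stop("unknown site label: ", bad_site[[1]])
  taxa <- colnames(counts)
  miss_tax <- setdiff(taxa, bundle$taxonomy$taxon)
  if (length(miss_tax)) stop("taxon missing from taxonomy: ", miss_tax[[1]])
  miss_tip <- setdiff(taxa, bundle$tree$tip.label)
  if (length(miss_tip)) stop("taxon missing from tree: ", miss_tip[[1]])
  if (!ape::is.rooted(bundle$tree)) stop("tree must be rooted")
  if (!is.null(bundle$tree$edge.length) && any(bundle$tree$edge.length < 0)) {
    stop("tree has negative branch lengths")
  }
  if (!is.null(bundle$clinical)) {
    ctrl <- if (!is.null(meta$is_control)) meta$is_control else FALSE
    subj <- unique(meta$subject_id[!ctrl])
    miss_sub <- setdiff(subj, bundle$clinical$subject_id)
    if (length(miss_sub)) stop("subject missing from clinical table: ", miss_sub[[1]])
  }
  invisible(bundle)
}

#' @export
print.airway_bundle <- function(x, ...) {
  cat(sprintf(
    "airway_bundle: %d samples x %d taxa (%d subjects)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$sample_meta$subject_id))
  ))
  print(table(x$sample_meta$site))
  invisible(x)
}

# ---- readers / writers -----------------------------------------------------

#' Read a count table
#'
#' Accepts the two interchange encodings: tab-separated text with taxa in
#' rows and samples in columns (header row of sample identifiers), or
#' BIOM-JSON v1.0. Returns a samples x taxa integer matrix.
#'
#' @param path File path; `.biom` extension selects the BIOM reader.
#' @return Integer matrix, samples in rows.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path)) {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    mat <- t(m)
  } else {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    mat <- t(as.matrix(df))
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count table
#'
#' @param counts Samples x taxa matrix.
#' @param path Output path; `.biom` extension selects BIOM-JSON v1.0.
#' @export
write_count_table <- function(counts, path) {
  if (grepl("\\.biom$", path)) {
    b <- biomformat::make_biom(t(counts)) # stored taxa x samples
    biomformat::write_biom(b, path)
  } else {
    df <- as.data.frame(t(counts)) # taxa rows x sample columns
    utils::write.table(cbind(taxon = rownames(df), df), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Parse Greengenes lineage strings
#'
#' Splits `k__...;p__...;c__...;o__...;f__...;g__...;s__...` lineages into
#' rank columns. Empty payloads (for example `g__`) are unassigned (`NA`).
#'
#' @param taxon Character vector of taxon identifiers.
#' @param lineage Character vector of lineage strings.
#' @return Tibble with columns `taxon`, `kingdom` ... `species`, `lineage`.
#' @export
parse_gg_lineage <- function(taxon, lineage) {
  ranks <- c(
    k = "kingdom", p = "phylum", c = "class", o = "order",
    f = "family", g = "genus", s = "species"
  )
  out <- matrix(NA_character_, length(lineage), length(ranks),
    dimnames = list(NULL, unname(ranks))
  )
  pieces <- strsplit(lineage, ";")
  for (i in seq_along(pieces)) {
    for (piece in trimws(pieces[[i]])) {
      m <- regmatches(piece, regexec("^([kpcofgs])__(.*)$", piece))[[1]]
      if (length(m) == 3 && nzchar(m[[3]])) out[i, ranks[[m[[2]]]]] <- m[[3]]
    }
  }
  tibble::as_tibble(cbind(
    tibble::tibble(taxon = taxon), as.data.frame(out),
    tibble::tibble(lineage = lineage)
  ))
}

format_gg_lineage <- function(taxonomy) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  pre <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(as.matrix(taxonomy[ranks]), 1, function(r) {
    paste0(pre, ifelse(is.na(r), "", r), collapse = "; ")
  })
}

#' Load a cohort bundle from files
#'
#' Reads the counts (TSV or BIOM-JSON), taxonomy (TSV, `taxon` + `lineage`
#' columns), rooted newick tree, sample metadata (TSV), and optional
#' clinical table (TSV), then cross-validates and canonicalizes them into
#' an [airway_bundle()].
#'
#' @param counts_path,taxonomy_path,tree_path,metadata_path,clinical_path
#'   File paths; `clinical_path` may be `NULL`.
#' @return An `airway_bundle`.
#' @export
load_dataset <- function(counts_path, taxonomy_path, tree_path, metadata_path,
                         clinical_path = NULL) {
  counts <- read_count_table(counts_path)
  tax_raw <- utils::read.delim(taxonomy_path, check.names = FALSE)
  taxonomy <- parse_gg_lineage(tax_raw$taxon, tax_raw$lineage)
  tree <- ape::read.tree(tree_path)
  meta <- tibble::as_tibble(utils::read.delim(metadata_path))
  if (!is.null(meta$is_control)) meta$is_control <- as.logical(meta$is_control)
  clinical <- NULL
  if (!is.null(clinical_path)) {
    clinical <- tibble::as_tibble(utils::read.delim(clinical_path))
  }
  airway_bundle(counts, meta, taxonomy, tree, clinical)
}

#' Write a cohort bundle (and optional ground truth) to a directory
#'
#' Emits exactly the formats [load_dataset()] reads, so that
#' `load_dataset(write_dataset(x)) == x`. The ground-truth sidecar, when
#' given, is serialized as JSON alongside the bundle; it is never read by
#' the analysis pipeline.
#'
#' @param bundle An `airway_bundle`.
#' @param out_dir Output directory (created if missing).
#' @param format `"tsv"` or `"biom"` for the count table.
#' @param ground_truth Optional simulation ground-truth list.
#' @return Named vector of written file paths, invisibly.
#' @export
write_dataset <- function(bundle, out_dir, format = c("tsv", "biom"),
                          ground_truth = NULL) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(out_dir, paste0("counts.", if (format == "biom") "biom" else "tsv")),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    metadata = file.path(out_dir, "sample_metadata.tsv"),
    clinical = file.path(out_dir, "clinical.tsv")
  )
  write_count_table(bundle$counts, paths[["counts"]])
  utils::write.table(
    data.frame(
      taxon = bundle$taxonomy$taxon,
      lineage = if (!is.null(bundle$taxonomy$lineage)) {
        bundle$taxonomy$lineage
      } else {
        format_gg_lineage(bundle$taxonomy)
      }
    ),
    paths[["taxonomy"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ape::write.tree(bundle$tree, paths[["tree"]])
  utils::write.table(bundle$sample_meta, paths[["metadata"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(bundle$clinical)) {
    utils::write.table(bundle$clinical, paths[["clinical"]],
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    paths <- paths[names(paths) != "clinical"]
  }
  if (!is.null(ground_truth)) {
    gt_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, gt_path,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}

# ---- QC --------------------------------------------------------------------

#' Apply cohort quality-control filters
#'
#' Removes (1) taxa detected in negative-control samples (or an explicit
#' control-taxon list), (2) the control samples themselves, and (3) induced
#' sputum samples whose squamous epithelial cell fraction exceeds
#' `config$squamous_max`. Counts of surviving samples and taxa are
#' unchanged, so the filter is idempotent. Every removal is logged via
#' `message()` and recorded in the `qc_log` attribute of the result.
#'
#' @param bundle An `airway_bundle`.
#' @param config An [pipeline_config()].
#' @param control_taxa Explicit character vector of taxa to remove;
#'   `NULL` derives the list as all taxa with nonzero counts in samples
#'   flagged `is_control`.
#' @return Filtered `airway_bundle` with a `qc_log` attribute.
#' @export
apply_qc_filters <- function(bundle, config = pipeline_config(),
                             control_taxa = NULL) {
  meta <- bundle$sample_meta
  counts <- bundle$counts
  log <- list()
  is_ctrl <- if (!is.null(meta$is_control)) {
    !is.na(meta$is_control) & meta$is_control
  } else {
    rep(FALSE, nrow(meta))
  }
  if (is.null(control_taxa)) {
    control_taxa <- colnames(counts)[colSums(counts[is_ctrl, , drop = FALSE]) > 0]
  } else {
    extra <- setdiff(control_taxa, colnames(counts))
    if (length(extra)) stop("control taxon not in table: ", extra[[1]])
  }
  squam <- if (!is.null(meta$squamous_pct)) meta$squamous_pct else NA_real_
  drop_squam <- meta$site == "IS" & !is.na(squam) & squam > config$squamous_max
  drop_sample <- is_ctrl | drop_squam
  for (s in meta$sample_id[is_ctrl]) {
    log[[length(log) + 1]] <- c("sample", s, "negative control")
  }
  for (s in meta$sample_id[drop_squam]) {
    log[[length(log) + 1]] <- c("sample", s, sprintf(
      "IS squamous fraction > %g", config$squamous_max
    ))
  }
  for (t in control_taxa) {
    log[[length(log) + 1]] <- c("taxon", t, "detected in negative controls")
  }
  keep_tax <- setdiff(colnames(counts), control_taxa)
  counts <- counts[!drop_sample, keep_tax, drop = FALSE]
  meta <- meta[!drop_sample, ]
  if (nrow(counts) == 0) warning("all samples removed by QC filters")
  qc_log <- if (length(log)) {
    tibble::tibble(
      what = vapply(log, `[[`, "", 1),
      id = vapply(log, `[[`, "", 2),
      reason = vapply(log, `[[`, "", 3)
    )
  } else {
    tibble::tibble(what = character(), id = character(), reason = character())
  }
  for (i in seq_len(nrow(qc_log))) {
    message(sprintf(
      "QC: removed %s %s (%s)", qc_log$what[i], qc_log$id[i], qc_log$reason[i]
    ))
  }
  taxonomy <- bundle$taxonomy[bundle$taxonomy$taxon %in% keep_tax, ]
  out <- bundle
  out$counts <- counts
  out$sample_meta <- meta
  out$taxonomy <- taxonomy
  attr(out, "qc_log") <- qc_log
  out
}

# ---- genus collapse --------------------------------------------------------

#' Collapse a count table to the genus level
#'
#' Sums counts over OTUs sharing the deepest assigned rank at or above
#' genus. Columns are labeled `"Family (Genus)"` when the genus is
#' assigned, otherwise by the deepest assigned rank name; OTUs with no
#' assigned rank at all fall into `"Unclassified"`. Per-sample totals are
#' conserved exactly. The returned matrix carries a `genus` attribute
#' (character, `NA` where the label is above genus level) aligned with its
#' columns, used by downstream genus-keyed operations.
#'
#' @param counts Samples x taxa matrix.
#' @param taxonomy Taxonomy tibble covering all columns of `counts`.
#' @return Samples x genus-label matrix with `genus` and `label_rank`
#'   attributes.
#' @export
collapse_to_genus <- function(counts, taxonomy) {
  tx <- taxonomy[match(colnames(counts), taxonomy$taxon), ]
  if (any(is.na(tx$taxon))) {
    stop("taxonomy does not cover taxon: ",
         colnames(counts)[is.na(tx$taxon)][[1]])
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  rank_mat <- as.matrix(tx[ranks])
  label <- character(nrow(tx))
  genus <- rep(NA_character_, nrow(tx))
  level <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    assigned <- which(!is.na(rank_mat[i, ]))
    if (!length(assigned)) {
      label[i] <- "Unclassified"
      level[i] <- "none"
    } else {
      deepest <- max(assigned)
      if (ranks[deepest] == "genus") {
        fam <- rank_mat[i, "family"]
        label[i] <- sprintf("%s (%s)", fam, rank_mat[i, "genus"])
        genus[i] <- rank_mat[i, "genus"]
        level[i] <- "genus"
      } else {
        label[i] <- rank_mat[i, deepest]
        level[i] <- ranks[deepest]
      }
    }
  }
  labs <- sort(unique(label))
  out <- matrix(0L, nrow(counts), length(labs),
    dimnames = list(rownames(counts), labs)
  )
  for (j in seq_along(label)) {
    out[, label[j]] <- out[, label[j]] + counts[, j]
  }
  attr(out, "genus") <- genus[match(labs, label)]
  attr(out, "label_rank") <- level[match(labs, label)]
  out
}

#' Convert counts to relative abundances
#'
#' @param counts Samples x taxa matrix with positive row sums.
#' @return Matrix of row-wise proportions; attributes of `counts` other
#'   than dimensions are preserved.
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("sample with zero total: ", rownames(counts)[tot == 0][[1]])
  out <- counts / tot
  for (a in setdiff(names(attributes(counts)), c("dim", "dimnames"))) {
    attr(out, a) <- attr(counts, a)
  }
  out
}
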