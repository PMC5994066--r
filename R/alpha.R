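#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total falls below `depth` are dropped with a
#' warning (rarefaction semantics: no rescaling). Deterministic given
#' `seed`.
#'
#' @param counts Samples x taxa integer matrix.
#' @param depth Target depth `D` (reads).
#' @param seed Integer seed.
#' @return Samples x taxa integer matrix whose row sums all equal `depth`.
#' @export
rarefy_table <- function(counts, depth, seed) {
  stopifnot(depth >= 1)
  tot <- rowSums(counts)
  low <- tot < depth
  if (all(low)) stop("all samples have fewer than ", depth, " reads")
  if (any(low)) {
    warning(
      "dropping ", sum(low), " sample(s) below rarefaction depth: ",
      paste(rownames(counts)[low], collapse = ", ")
    )
    counts <- counts[!low, , drop = FALSE]
  }
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # "not raw counts"); harmless here, where inputs are validated upstream
  out <- withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  storage.mode(out) <- "integer"
  out
}

#' Build a multiple-rarefaction ensemble
#'
#' Draws `R` independent rarefactions of the same table at common depth
#' `D`, each from a seed derived from the master seed by a fixed
#' stream-splitting rule, so the ensemble is bit-reproducible.
#'
#' @param counts Samples x taxa integer matrix.
#' @param config A [pipeline_config()] supplying `rarefaction_depth`,
#'   `n_rarefactions`, and the master `seed`.
#' @return List of class `"rarefied_ensemble"`: `tables` (list of rarefied
#'   matrices), `depth`, and `provenance` (tibble of iteration seeds).
#' @export
rarefy_ensemble <- function(counts, config = pipeline_config()) {
  seeds <- vapply(
    seq_len(config$n_rarefactions),
    function(i) derive_seed(config$seed, "rarefaction", i), integer(1)
  )
  tables <- lapply(seeds, function(s) {
    rarefy_table(counts, config$rarefaction_depth, s)
  })
  structure(
    list(
      tables = tables, depth = config$rarefaction_depth,
      provenance = tibble::tibble(iteration = seq_along(seeds), seed = seeds)
    ),
    class = "rarefied_ensemble"
  )
}

alpha_metrics_single <- function(counts, em) {
  if (any(rowSums(counts) == 0)) stop("empty sample in rarefied table")
  p <- counts / rowSums(counts)
  S <- rowSums(counts > 0)
  H <- apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log2(pi))
  })
  J <- ifelse(S >= 2, H / log2(S), NA_real_)
  PD <- apply(counts > 0, 1, function(pres) {
    faith_pd(colnames(counts)[pres], em)
  })
  tibble::tibble(
    sample_id = rownames(counts), richness = as.numeric(S),
    shannon = unname(H), faith_pd = unname(PD), pielou = unname(J)
  )
}

#' Per-sample alpha diversity over a rarefaction ensemble
#'
#' Computes observed richness S, Shannon diversity H (bits, base-2 log),
#' Faith phylogenetic diversity (root-inclusive), and Pielou evenness
#' J = H / log2(S) for every sample of every rarefied table, then averages
#' each metric over the ensemble. J is undefined (NA) for single-taxon
#' samples.
#'
#' @param ensemble A [rarefy_ensemble()] result.
#' @param tree Rooted `ape::phylo` covering the taxa.
#' @return Tibble: `sample_id`, `richness`, `shannon`, `faith_pd`,
#'   `pielou` (ensemble means).
#' @export
alpha_metrics <- function(ensemble, tree) {
  stopifnot(length(ensemble$tables) >= 1)
  em <- tree_edge_matrix(tree)
  per <- lapply(ensemble$tables, alpha_metrics_single, em = em)
  ids <- per[[1]]$sample_id
  avg <- function(col) {
    rowMeans(vapply(per, function(d) d[[col]][match(ids, d$sample_id)],
      numeric(length(ids))
    ))
  }
  tibble::tibble(
    sample_id = ids,
    richness = avg("richness"), shannon = avg("shannon"),
    faith_pd = avg("faith_pd"), pielou = avg("pielou")
  )
}

#' Compare alpha diversity across sites and groups
#'
#' Within-subject comparisons between sites use the Wilcoxon matched-pairs
#' signed-rank test (restricted to subjects with both sites); between-group
#' comparisons within a site use the Mann-Whitney test.
#'
#' @param alpha Tibble from [alpha_metrics()].
#' @param meta Sample metadata (`sample_id`, `subject_id`, `site`, `group`).
#' @return Tibble of test results, one row per (metric, comparison).
#' @export
alpha_comparisons <- function(alpha, meta) {
  d <- merge(alpha, meta, by = "sample_id")
  metrics <- c("richness", "shannon", "faith_pd", "pielou")
  rows <- list()
  sites <- intersect(SITES, unique(d$site))
  for (m in metrics) {
    wide <- stats::reshape(
      d[, c("subject_id", "site", m)],
      idvar = "subject_id", timevar = "site", direction = "wide"
    )
    names(wide) <- sub(paste0("^", m, "\\."), "", names(wide))
    if (length(sites) >= 2) {
      for (i in seq_len(length(sites) - 1)) {
        for (j in seq(i + 1, length(sites))) {
          a <- sites[i]
          b <- sites[j]
          keep <- stats::complete.cases(wide[[a]], wide[[b]])
          if (sum(keep) < 3) next
          res <- suppressWarnings(two_sample_test(
            wide[[a]][keep], wide[[b]][keep],
            mode = "wilcoxon_signed_rank"
          ))
          res$metric <- m
          res$comparison <- paste(a, "vs", b)
          rows[[length(rows) + 1]] <- res
        }
      }
    }
    for (s in sites) {
      ds <- d[d$site == s, ]
      grp <- intersect(GROUPS, unique(ds$group))
      if (length(grp) < 2) next
      for (i in seq_len(length(grp) - 1)) {
        for (j in seq(i + 1, length(grp))) {
          x <- ds[[m]][ds$group == grp[i]]
          y <- ds[[m]][ds$group == grp[j]]
          if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
          res <- two_sample_test(x, y, mode = "mann_whitney")
          res$metric <- m
          res$comparison <- paste0(s, ": ", grp[i], " vs ", grp[j])
          rows[[length(rows) + 1]] <- res
        }
      }
    }
  }
  do.call(rbind, rows)
}
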