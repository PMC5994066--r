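#' Per-subject shared/exclusive taxon partition across sites
#'
#' For each subject, assigns every taxon detected in at least one of the
#' subject's sampled sites to exactly one region of the presence/absence
#' Venn partition over those sites (e.g. `"BB+IS"` = present in BB and IS
#' and absent from every other site the subject has). Presence is defined
#' as a nonzero count in the supplied table; pass a single canonical
#' rarefied table (fixed seed) to equalize detection effort across
#' samples, or the raw table to count every observed read.
#'
#' @param counts Samples x taxa matrix defining presence.
#' @param meta Sample metadata for the rows of `counts`.
#' @return List of class `"shared_partition"`: `assignments` (tibble
#'   `subject_id`, `group`, `taxon`, `region`) and `region_sizes` (tibble
#'   `subject_id`, `group`, `region`, `n`, `n_sites`). Region labels join
#'   the member sites with `"+"` in BB, IS, OW, NB order.
#' @export
shared_partition <- function(counts, meta) {
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  assignments <- list()
  sizes <- list()
  for (subj in unique(meta$subject_id)) {
    idx <- which(meta$subject_id == subj)
    if (length(idx) < 2) next
    sites <- meta$site[idx]
    ord <- order(match(sites, SITES))
    idx <- idx[ord]
    sites <- sites[ord]
    pres <- counts[idx, , drop = FALSE] > 0
    detected <- which(colSums(pres) > 0)
    region <- apply(pres[, detected, drop = FALSE], 2, function(col) {
      paste(sites[col], collapse = "+")
    })
    assignments[[length(assignments) + 1]] <- tibble::tibble(
      subject_id = subj, group = meta$group[idx[1]],
      taxon = colnames(counts)[detected], region = unname(region)
    )
    tab <- table(region)
    sizes[[length(sizes) + 1]] <- tibble::tibble(
      subject_id = subj, group = meta$group[idx[1]],
      region = names(tab), n = as.integer(tab), n_sites = length(sites)
    )
  }
  structure(
    list(
      assignments = do.call(rbind, assignments),
      region_sizes = do.call(rbind, sizes)
    ),
    class = "shared_partition"
  )
}

#' Group summaries of shared-region sizes
#'
#' @param partition A [shared_partition()] result.
#' @return Tibble of median and interquartile range of each region's size
#'   per group.
#' @export
region_size_summary <- function(partition) {
  rs <- partition$region_sizes
  out <- list()
  for (g in unique(rs$group)) {
    for (r in unique(rs$region[rs$group == g])) {
      # subjects lacking the region contribute 0
      subj <- unique(rs$subject_id[rs$group == g])
      n <- rs$n[rs$group == g & rs$region == r]
      n <- c(n, rep(0L, length(subj) - length(n)))
      q <- stats::quantile(n, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        group = g, region = r, n_subjects = length(subj),
        q25 = q[1], median = q[2], q75 = q[3]
      )
    }
  }
  do.call(rbind, out)
}

#' Shared richness and phylogenetic-diversity fractions of a focal site
#'
#' For each subject and each non-focal site `s`, computes the fraction of
#' the focal site's detected richness that is shared with `s`
#' (`|BB \\u2229 s| / |BB|`) and the corresponding Faith PD fraction
#' (`PD(BB \\u2229 s) / PD(BB)`), both in `[0, 1]`. "Shared" is the
#' pairwise intersection (present in both sites), regardless of other
#' sites.
#'
#' @param counts Presence-defining samples x taxa matrix (canonical
#'   rarefied table).
#' @param meta Sample metadata.
#' @param tree Rooted `ape::phylo`.
#' @param focal_site Focal site, default `"BB"`.
#' @return Tibble: `subject_id`, `group`, `site`, `n_shared`, `n_focal`,
#'   `richness_fraction`, `pd_shared`, `pd_focal`, `pd_fraction`.
#' @export
shared_pd_fraction <- function(counts, meta, tree, focal_site = "BB") {
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  em <- tree_edge_matrix(tree)
  rows <- list()
  for (subj in unique(meta$subject_id)) {
    idx <- which(meta$subject_id == subj)
    if (!(focal_site %in% meta$site[idx])) next
    fidx <- idx[meta$site[idx] == focal_site]
    focal_taxa <- colnames(counts)[counts[fidx, ] > 0]
    if (length(focal_taxa) == 0) {
      stop("empty focal-site sample for subject ", subj)
    }
    pd_focal <- faith_pd(focal_taxa, em)
    for (oidx in idx[meta$site[idx] != focal_site]) {
      s <- meta$site[oidx]
      shared <- intersect(focal_taxa, colnames(counts)[counts[oidx, ] > 0])
      pd_sh <- if (length(shared)) faith_pd(shared, em) else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = subj, group = meta$group[fidx], site = s,
        n_shared = length(shared), n_focal = length(focal_taxa),
        richness_fraction = length(shared) / length(focal_taxa),
        pd_shared = pd_sh, pd_focal = pd_focal,
        pd_fraction = pd_sh / pd_focal
      )
    }
  }
  do.call(rbind, rows)
}

region_matches <- function(region, sites, exclusive) {
  vapply(strsplit(region, "+", fixed = TRUE), function(r) {
    if (exclusive) setequal(r, sites) else all(sites %in% r)
  }, logical(1))
}

#' Genus frequency distribution of a sharing region
#'
#' For each genus, the fraction of a group's subjects in which at least
#' one OTU of that genus occupies the given sharing region; genera below
#' `threshold` in every group are dropped. Cross-group comparisons: a
#' chi-square test on the retained genus-by-group subject-count
#' distribution, and per-genus Fisher exact tests between pairs of groups.
#'
#' @param partition A [shared_partition()] result.
#' @param taxonomy Taxonomy tibble (genus assignment per taxon).
#' @param sites Character vector of sites defining the region, e.g.
#'   `c("BB", "IS")`.
#' @param exclusive If `TRUE`, the region is "present in exactly these
#'   sites among the subject's sampled sites"; if `FALSE`, "present in at
#'   least these sites".
#' @param threshold Minimum subject fraction for retention.
#' @return List: `frequencies` (tibble `group`, `genus`, `n_subjects`,
#'   `n_with`, `fraction`, `retained`), `chi_square` (test-result tibble
#'   or NULL), `fisher_by_genus` (tibble or NULL).
#' @export
shared_genus_frequency <- function(partition, taxonomy, sites,
                                   exclusive = TRUE, threshold = 0.20) {
  ass <- partition$assignments
  hit <- ass[region_matches(ass$region, sites, exclusive), ]
  hit$genus <- taxonomy$genus[match(hit$taxon, taxonomy$taxon)]
  hit <- hit[!is.na(hit$genus), ]
  groups <- sort(unique(ass$group))
  n_subj <- vapply(groups, function(g) {
    length(unique(ass$subject_id[ass$group == g]))
  }, integer(1))
  genera <- sort(unique(hit$genus))
  freq <- list()
  for (g in groups) {
    for (gen in genera) {
      nw <- length(unique(hit$subject_id[hit$group == g & hit$genus == gen]))
      freq[[length(freq) + 1]] <- tibble::tibble(
        group = g, genus = gen, n_subjects = n_subj[[g]], n_with = nw,
        fraction = nw / n_subj[[g]]
      )
    }
  }
  freq <- do.call(rbind, freq)
  if (is.null(freq)) {
    return(list(
      frequencies = tibble::tibble(), chi_square = NULL,
      fisher_by_genus = NULL
    ))
  }
  keep_gen <- unique(freq$genus[freq$fraction >= threshold])
  freq$retained <- freq$genus %in% keep_gen
  chi <- NULL
  fisher <- NULL
  if (length(keep_gen) >= 2 && length(groups) >= 2) {
    tab <- matrix(0L, length(keep_gen), length(groups),
      dimnames = list(keep_gen, groups)
    )
    for (i in seq_len(nrow(freq))) {
      if (freq$genus[i] %in% keep_gen) {
        tab[freq$genus[i], freq$group[i]] <- freq$n_with[i]
      }
    }
    ok <- rowSums(tab) > 0 & is.finite(rowSums(tab))
    tab <- tab[ok, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2 && ncol(tab) >= 2) chi <- chi_square_rxc(tab)
    frows <- list()
    for (gen in keep_gen) {
      for (i in seq_len(length(groups) - 1)) {
        for (j in seq(i + 1, length(groups))) {
          a <- freq[freq$genus == gen & freq$group == groups[i], ]
          b <- freq[freq$genus == gen & freq$group == groups[j], ]
          if (!nrow(a) || !nrow(b)) next
          res <- fisher_exact_2x2(
            a$n_with, a$n_subjects - a$n_with,
            b$n_with, b$n_subjects - b$n_with
          )
          res$genus <- gen
          res$comparison <- paste(groups[i], "vs", groups[j])
          frows[[length(frows) + 1]] <- res
        }
      }
    }
    fisher <- do.call(rbind, frows)
  }
  list(frequencies = freq, chi_square = chi, fisher_by_genus = fisher)
}

#' Per-subject genus-profile correlations between two sites
#'
#' Pearson correlation of the untransformed genus relative-abundance
#' vectors of a subject's two samples, over the union of genera detected
#' in either (absent = 0). Subjects with fewer than 3 genera in the union
#' are flagged as undefined. The cohort summary is the median and IQR of
#' r per site pair.
#'
#' @param genus_rel Samples x genus relative-abundance matrix (from
#'   [collapse_to_genus()] + [relative_abundance()]).
#' @param meta Sample metadata.
#' @param site_a,site_b The ordered site pair.
#' @return List: `per_subject` (tibble `subject_id`, `group`, `r`,
#'   `n_genera`, `note`), `summary` (tibble with median and IQR).
#' @export
genus_profile_correlation <- function(genus_rel, meta, site_a, site_b) {
  meta <- meta[match(rownames(genus_rel), meta$sample_id), ]
  rows <- list()
  for (subj in unique(meta$subject_id)) {
    ia <- which(meta$subject_id == subj & meta$site == site_a)
    ib <- which(meta$subject_id == subj & meta$site == site_b)
    if (!length(ia) || !length(ib)) next
    a <- genus_rel[ia, ]
    b <- genus_rel[ib, ]
    union_g <- which(a > 0 | b > 0)
    if (length(union_g) < 3) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = subj, group = meta$group[ia], r = NA_real_,
        n_genera = length(union_g), note = "undefined: < 3 genera in union"
      )
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = subj, group = meta$group[ia],
      r = stats::cor(a[union_g], b[union_g]),
      n_genera = length(union_g), note = NA_character_
    )
  }
  per <- do.call(rbind, rows)
  r <- per$r[!is.na(per$r)]
  q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  list(
    per_subject = per,
    summary = tibble::tibble(
      pair = paste(site_a, site_b, sep = "-"), n = length(r),
      q25 = q[1], median = q[2], q75 = q[3]
    )
  )
}

#' Paired tests and correlations for prevalent genera
#'
#' Retains genera whose relative abundance reaches `threshold` in at least
#' one sample, then for every site pair and every retained genus runs a
#' Wilcoxon matched-pairs signed-rank test on relative abundance across
#' subjects with both sites, and a Spearman correlation across the same
#' subjects. BH q values are computed within each test family.
#'
#' @param genus_rel Samples x genus relative-abundance matrix.
#' @param meta Sample metadata.
#' @param threshold Prevalence threshold (fraction), default 3%.
#' @param q_threshold BH significance threshold for the flags.
#' @return Tibble with one row per (site pair, genus, test).
#' @export
prevalent_genus_tests <- function(genus_rel, meta, threshold = 0.03,
                                  q_threshold = 0.20) {
  meta <- meta[match(rownames(genus_rel), meta$sample_id), ]
  prevalent <- colnames(genus_rel)[apply(genus_rel, 2, max) >= threshold]
  sites <- intersect(SITES, unique(meta$site))
  rows <- list()
  for (i in seq_len(length(sites) - 1)) {
    for (j in seq(i + 1, length(sites))) {
      sa <- sites[i]
      sb <- sites[j]
      subj_a <- meta$subject_id[meta$site == sa]
      subj_b <- meta$subject_id[meta$site == sb]
      common <- intersect(subj_a, subj_b)
      if (length(common) < 4) next
      ia <- match(paste0(common, "_", sa), rownames(genus_rel))
      ib <- match(paste0(common, "_", sb), rownames(genus_rel))
      for (gen in prevalent) {
        x <- genus_rel[ia, gen]
        y <- genus_rel[ib, gen]
        w <- suppressWarnings(
          two_sample_test(x, y, mode = "wilcoxon_signed_rank")
        )
        ct <- tryCatch(correlation(x, y, mode = "spearman"),
          error = function(e) NULL
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          pair = paste(sa, sb, sep = "-"), genus_label = gen,
          n = length(common),
          wilcoxon_p = w$p_value,
          spearman_rho = if (is.null(ct)) NA_real_ else ct$estimate,
          spearman_p = if (is.null(ct)) NA_real_ else ct$p_value
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(tibble::tibble())
  }
  out$wilcoxon_q <- bh_fdr(out$wilcoxon_p, q_threshold)$q
  out$spearman_q <- stats::p.adjust(out$spearman_p, method = "BH")
  out
}
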