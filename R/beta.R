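#' UniFrac distances for a single count table
#'
#' Unweighted UniFrac between two samples is the fraction of branch length
#' unique to either sample: the summed length of edges whose descendant
#' tips occur in exactly one of the two samples, divided by the summed
#' length of edges whose descendant tips occur in either. Weighted
#' (normalized) UniFrac is `sum_e b_e |p_A(e) - p_B(e)|` over edges, where
#' `p(e)` is the summed relative abundance of tips below edge `e`,
#' normalized by `sum_j d_j (p_Aj + p_Bj)` over tips `j` at root distance
#' `d_j`, which bounds the distance in `[0, 1]`.
#'
#' @param counts Samples x taxa matrix with positive row sums.
#' @param tree Rooted `ape::phylo` covering the taxa (or a precomputed
#'   [tree_edge_matrix()]).
#' @param mode `"unweighted"` or `"weighted_normalized"`.
#' @return Symmetric distance matrix with a `metric` attribute.
#' @export
unifrac_matrix <- function(counts, tree,
                           mode = c("unweighted", "weighted_normalized")) {
  mode <- match.arg(mode)
  em <- if (inherits(tree, "phylo")) tree_edge_matrix(tree) else tree
  unknown <- setdiff(colnames(counts), colnames(em$incidence))
  if (length(unknown)) stop("taxon not in tree: ", unknown[[1]])
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("sample with zero total: ", rownames(counts)[tot == 0][[1]])
  }
  inc <- em$incidence[, colnames(counts), drop = FALSE] # edges x taxa
  b <- em$lengths
  n <- nrow(counts)
  if (mode == "unweighted") {
    # edge occupancy per sample, then shared / unique branch length by
    # cross products
    H <- (inc %*% t(counts > 0)) > 0 # edges x samples
    Hb <- H * b
    shared <- t(Hb) %*% H # S_ij = branch length on edges hit by both
    tot_len <- colSums(Hb)
    uni <- outer(tot_len, tot_len, "+") - 2 * shared
    denom <- outer(tot_len, tot_len, "+") - shared
    d <- ifelse(denom > 0, uni / denom, 0)
  } else {
    p <- counts / tot
    Q <- inc %*% t(p) # edges x samples: abundance below each edge
    s <- as.numeric(em$tip_depth[colnames(counts)] %*% t(p)) # depth-weighted totals
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      diffs <- abs(Q[, (i + 1):n, drop = FALSE] - Q[, i])
      num <- colSums(diffs * b)
      den <- s[(i + 1):n] + s[i]
      d[i, (i + 1):n] <- ifelse(den > 0, num / den, 0)
    }
    d <- d + t(d)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  attr(d, "metric") <- if (mode == "unweighted") {
    "unweighted_unifrac"
  } else {
    "weighted_unifrac"
  }
  d
}

#' UniFrac distances averaged over a rarefaction ensemble
#'
#' Computes the distance matrix on each rarefied table and returns the
#' elementwise mean; the result is invariant to the order of the tables.
#'
#' @param ensemble A [rarefy_ensemble()] result.
#' @param tree Rooted `ape::phylo`.
#' @param mode `"unweighted"` or `"weighted_normalized"`.
#' @return Symmetric distance matrix with a `metric` attribute.
#' @export
unifrac <- function(ensemble, tree,
                    mode = c("unweighted", "weighted_normalized")) {
  mode <- match.arg(mode)
  em <- tree_edge_matrix(tree)
  mats <- lapply(ensemble$tables, unifrac_matrix, tree = em, mode = mode)
  out <- Reduce(`+`, mats) / length(mats)
  attr(out, "metric") <- attr(mats[[1]], "metric")
  out
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square root of their (positive) eigenvalues. Axes with negative
#' eigenvalues are dropped; the negative eigenvalues themselves are
#' reported. The sign of each axis is fixed by making its
#' largest-magnitude coordinate positive.
#'
#' @param dm Symmetric distance matrix.
#' @return List of class `"pcoa_result"`: `coords` (samples x axes),
#'   `eigenvalues` (descending, all of them), `prop_explained`
#'   (over positive eigenvalues).
#' @export
pcoa_ordination <- function(dm) {
  dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  cs <- stats::cmdscale(dm, k = n - 1, eig = TRUE)
  eig <- cs$eig
  pos <- which(eig > max(eig) * 1e-9 & eig > 0)
  coords <- cs$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(dm), "PC1"))
  } else {
    for (j in seq_len(ncol(coords))) {
      k <- which.max(abs(coords[, j]))
      if (coords[k, j] < 0) coords[, j] <- -coords[, j]
    }
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  }
  rownames(coords) <- rownames(dm)
  structure(
    list(
      coords = coords,
      eigenvalues = sort(eig, decreasing = TRUE),
      prop_explained = if (length(pos)) {
        eig[pos] / sum(eig[pos])
      } else {
        numeric(0)
      }
    ),
    class = "pcoa_result"
  )
}

#' Intra-subject paired distances to each site pair
#'
#' Extracts, for every subject and every pair of sites that subject has,
#' the (ensemble-averaged) distance between the two samples.
#'
#' @param dm Distance matrix whose labels are `subject_id _ site` sample
#'   identifiers present in `meta`.
#' @param meta Sample metadata.
#' @return Tibble: `subject_id`, `group`, `pair` (e.g. `"BB-IS"`),
#'   `distance`.
#' @export
paired_site_distances <- function(dm, meta) {
  meta <- meta[match(rownames(dm), meta$sample_id), ]
  rows <- list()
  for (subj in unique(meta$subject_id)) {
    idx <- which(meta$subject_id == subj)
    if (length(idx) < 2) next
    sites <- meta$site[idx]
    ord <- order(match(sites, SITES))
    idx <- idx[ord]
    sites <- sites[ord]
    for (i in seq_len(length(idx) - 1)) {
      for (j in seq(i + 1, length(idx))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = subj, group = meta$group[idx[i]],
          pair = paste(sites[i], sites[j], sep = "-"),
          distance = dm[idx[i], idx[j]]
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Contrasts on intra-subject paired distances
#'
#' Reproduces the three families of paired-distance comparisons:
#' within-subject Wilcoxon signed-rank between site pairs sharing a focal
#' site, paired t between two site pairs within each group, and Welch t on
#' one site pair between groups.
#'
#' @param pd Tibble from [paired_site_distances()].
#' @return Tibble of test results with `comparison` and `scope` columns.
#' @export
paired_distance_contrasts <- function(pd) {
  rows <- list()
  pairs <- unique(pd$pair)
  wide <- stats::reshape(as.data.frame(pd[, c("subject_id", "pair", "distance")]),
    idvar = "subject_id", timevar = "pair", direction = "wide"
  )
  names(wide) <- sub("^distance\\.", "", names(wide))
  grp <- pd[!duplicated(pd$subject_id), c("subject_id", "group")]
  wide <- merge(wide, grp, by = "subject_id")
  if (length(pairs) >= 2) {
    for (i in seq_len(length(pairs) - 1)) {
      for (j in seq(i + 1, length(pairs))) {
        a <- pairs[i]
        b <- pairs[j]
        keep <- stats::complete.cases(wide[[a]], wide[[b]])
        if (sum(keep) >= 3) {
          res <- suppressWarnings(
            two_sample_test(wide[[a]][keep], wide[[b]][keep],
              mode = "wilcoxon_signed_rank"
            )
          )
          res$comparison <- paste(a, "vs", b)
          res$scope <- "all subjects (Wilcoxon)"
          rows[[length(rows) + 1]] <- res
        }
        for (g in intersect(GROUPS, unique(wide$group))) {
          kg <- keep & wide$group == g
          if (sum(kg) >= 3) {
            res <- suppressWarnings(
              two_sample_test(wide[[a]][kg], wide[[b]][kg], mode = "paired_t")
            )
            res$comparison <- paste(a, "vs", b)
            res$scope <- paste0(g, " (paired t)")
            rows[[length(rows) + 1]] <- res
          }
        }
      }
    }
  }
  grps <- intersect(GROUPS, unique(wide$group))
  if (length(grps) >= 2) {
    for (a in pairs) {
      for (i in seq_len(length(grps) - 1)) {
        for (j in seq(i + 1, length(grps))) {
          x <- wide[[a]][wide$group == grps[i]]
          y <- wide[[a]][wide$group == grps[j]]
          x <- x[!is.na(x)]
          y <- y[!is.na(y)]
          if (length(x) >= 3 && length(y) >= 3) {
            res <- two_sample_test(x, y, mode = "welch_t")
            res$comparison <- a
            res$scope <- paste0(grps[i], " vs ", grps[j], " (Welch t)")
            rows[[length(rows) + 1]] <- res
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Mixed-effects test of sample type on the first principal coordinate
#'
#' Fits `PC1 ~ site + (1 | subject)` by maximum likelihood and tests the
#' site effect by likelihood-ratio against the intercept-plus-random-
#' intercept null. A singular fit (zero between-subject variance) falls
#' back to one-way OLS ANOVA with a warning.
#'
#' @param pcoa A [pcoa_ordination()] result (or a numeric PC1 vector named
#'   by sample).
#' @param meta Sample metadata.
#' @return One-row test-result tibble; the lme4 fit is attached as the
#'   `fit` attribute.
#' @export
lme_pc1 <- function(pcoa, meta) {
  pc1 <- if (inherits(pcoa, "pcoa_result")) pcoa$coords[, 1] else pcoa
  d <- data.frame(
    pc1 = pc1,
    site = factor(meta$site[match(names(pc1), meta$sample_id)]),
    subject = factor(meta$subject_id[match(names(pc1), meta$sample_id)])
  )
  stopifnot(nlevels(d$site) >= 2, nlevels(d$subject) >= 2)
  full <- tryCatch(
    suppressMessages(
      lme4::lmer(pc1 ~ site + (1 | subject), data = d, REML = FALSE)
    ),
    error = function(e) NULL
  )
  if (is.null(full) || lme4::isSingular(full, tol = 1e-5)) {
    warning("degenerate or singular random-intercept fit; falling back to OLS ANOVA")
    an <- stats::anova(stats::lm(pc1 ~ site, data = d))
    res <- test_result(an[["F value"]][1], an[["Pr(>F)"]][1],
      method = "ols_anova_pc1", n = nrow(d), note = "singular LME fallback"
    )
    attr(res, "fit") <- NULL
    return(res)
  }
  null <- suppressMessages(
    lme4::lmer(pc1 ~ 1 + (1 | subject), data = d, REML = FALSE)
  )
  lrt <- stats::anova(null, full)
  res <- test_result(lrt$Chisq[2], lrt$`Pr(>Chisq)`[2],
    method = "lme_lrt_pc1", n = nrow(d)
  )
  attr(res, "fit") <- full
  res
}

#' Mantel test between two distance matrices
#'
#' Statistic is the Pearson correlation of the off-diagonal entries;
#' significance is by joint row/column permutation of one matrix,
#' two-sided on `|r|`: `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param dm_a,dm_b Symmetric distance matrices with identical labels in
#'   identical order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return One-row test-result tibble with an `estimate` column (r).
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 999, seed = 1L) {
  dm_a <- as.matrix(dm_a)
  dm_b <- as.matrix(dm_b)
  if (!identical(rownames(dm_a), rownames(dm_b))) {
    stop("distance matrices must have identical labels in identical order")
  }
  stopifnot(n_perm >= 99)
  n <- nrow(dm_a)
  lower <- lower.tri(dm_a)
  r_obs <- stats::cor(dm_a[lower], dm_b[lower])
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_perm <- stats::cor(dm_a[lower], dm_b[perm, perm][lower])
    if (abs(r_perm) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
  }
  res <- test_result(r_obs, (1 + exceed) / (1 + n_perm),
    method = "mantel", n = n
  )
  res$estimate <- r_obs
  res
}

#' Inter-subject UniFrac on taxa shared between a focal site and another
#'
#' For each subject, forms the presence profile of taxa detected in both
#' the focal site (default BB) and `site`, then computes unweighted
#' UniFrac between subjects on those shared-taxon profiles. Subjects whose
#' shared set is empty are dropped (distance undefined). This is the
#' construction used to compare the phylogenetic contribution of the
#' nasal and oral compartments to the bronchial community via the Mantel
#' test.
#'
#' @param partition A [shared_partition()] result.
#' @param tree Rooted `ape::phylo`.
#' @param site Comparison site (e.g. `"NB"` or `"OW"`).
#' @param focal_site Focal site (default `"BB"`).
#' @return Subjects x subjects unweighted UniFrac matrix.
#' @export
shared_taxa_unifrac <- function(partition, tree, site, focal_site = "BB") {
  ass <- partition$assignments
  subjects <- sort(unique(ass$subject_id))
  sets <- lapply(subjects, function(s) {
    sub <- ass[ass$subject_id == s, ]
    sub$taxon[vapply(
      strsplit(sub$region, "+", fixed = TRUE),
      function(r) all(c(focal_site, site) %in% r), logical(1)
    )]
  })
  names(sets) <- subjects
  keep <- vapply(sets, length, integer(1)) > 0
  sets <- sets[keep]
  if (length(sets) < 3) stop("fewer than 3 subjects with nonempty shared sets")
  taxa <- sort(unique(unlist(sets)))
  pres <- matrix(0L, length(sets), length(taxa),
    dimnames = list(names(sets), taxa)
  )
  for (s in names(sets)) pres[s, sets[[s]]] <- 1L
  unifrac_matrix(pres, tree, mode = "unweighted")
}
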