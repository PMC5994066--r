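make_partition_fixture <- function() {
  # BB={o1,o2,o3}, IS={o2,o3,o4}, OW={o3}
  counts <- rbind(
    S1_BB = c(o1 = 1L, o2 = 1L, o3 = 1L, o4 = 0L),
    S1_IS = c(o1 = 0L, o2 = 1L, o3 = 1L, o4 = 1L),
    S1_OW = c(o1 = 0L, o2 = 0L, o3 = 1L, o4 = 0L)
  )
  meta <- tibble::tibble(
    sample_id = rownames(counts), subject_id = "S1",
    site = c("BB", "IS", "OW"), group = "AA"
  )
  list(counts = counts, meta = meta)
}

test_that("shared partition implements the Venn set algebra", {
  f <- make_partition_fixture()
  part <- shared_partition(f$counts, f$meta)
  ass <- part$assignments
  get <- function(o) ass$region[ass$taxon == o]
  expect_equal(get("o1"), "BB")
  expect_equal(get("o2"), "BB+IS")
  expect_equal(get("o3"), "BB+IS+OW")
  expect_equal(get("o4"), "IS")
  expect_equal(sum(part$region_sizes$n), 4)
  # identical presence across sites: everything in the all-sites region
  same <- f$counts
  same[2, ] <- same[1, ]
  same[3, ] <- same[1, ]
  part2 <- shared_partition(same, f$meta)
  expect_true(all(part2$assignments$region == "BB+IS+OW"))
})

test_that("region sizes sum to per-subject detected richness", {
  sim <- simulate_cohort(small_sim_params(seed = 14))
  can <- rarefy_table(sim$bundle$counts, 2000, seed = 1)
  meta <- sim$bundle$sample_meta[
    match(rownames(can), sim$bundle$sample_meta$sample_id),
  ]
  part <- shared_partition(can, meta)
  for (s in unique(part$region_sizes$subject_id)) {
    idx <- which(meta$subject_id == s)
    detected <- sum(colSums(can[idx, , drop = FALSE] > 0) > 0)
    expect_equal(sum(part$region_sizes$n[part$region_sizes$subject_id == s]), detected)
  }
})

test_that("shared PD fractions match edge-enumeration values on the toy tree", {
  tr <- toy_tree()
  counts <- rbind(
    S1_BB = c(A = 1L, B = 1L, C = 1L, D = 0L),
    S1_OW = c(A = 1L, B = 1L, C = 0L, D = 0L),
    S1_NB = c(A = 0L, B = 0L, C = 1L, D = 1L)
  )
  meta <- tibble::tibble(
    sample_id = rownames(counts), subject_id = "S1",
    site = c("BB", "OW", "NB"), group = "AA"
  )
  sf <- shared_pd_fraction(counts, meta, tr)
  ow <- sf[sf$site == "OW", ]
  expect_equal(ow$richness_fraction, 2 / 3)
  expect_equal(ow$pd_fraction, 3 / 5) # PD(A,B)=3, PD(A,B,C)=5
  nb <- sf[sf$site == "NB", ]
  expect_equal(nb$richness_fraction, 1 / 3) # C shared with {A,B,C}
  expect_equal(nb$pd_fraction, 2 / 5) # PD(C)=2, PD(A,B,C)=5
  # full overlap gives fraction 1; disjoint gives 0
  counts2 <- counts
  counts2["S1_OW", ] <- counts["S1_BB", ]
  sf2 <- shared_pd_fraction(counts2, meta, tr)
  expect_equal(sf2$richness_fraction[sf2$site == "OW"], 1)
  expect_equal(sf2$pd_fraction[sf2$site == "OW"], 1)
  counts3 <- counts
  counts3["S1_NB", ] <- c(0L, 0L, 0L, 1L)
  counts3["S1_BB", ] <- c(1L, 1L, 0L, 0L)
  sf3 <- shared_pd_fraction(counts3, meta, tr)
  expect_equal(sf3$richness_fraction[sf3$site == "NB"], 0)
  expect_equal(sf3$pd_fraction[sf3$site == "NB"], 0)
})

test_that("genus frequency retention follows the subject-fraction threshold", {
  # 22 AA subjects, genus present in the region for 5 of them (5/22 > 20%);
  # 11 HC subjects with 1 carrier (excluded)
  mk <- function(n, g, carriers, genus_taxon) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      taxa <- if (i <= carriers) c(genus_taxon, "other_1") else "other_1"
      tibble::tibble(
        subject_id = sprintf("%s%02d", g, i), group = g,
        taxon = taxa, region = "BB+IS"
      )
    }))
  }
  part <- structure(list(
    assignments = rbind(
      mk(22, "AA", 5, "Haemophilus_01"),
      mk(11, "HC", 1, "Haemophilus_01")
    ),
    region_sizes = NULL
  ), class = "shared_partition")
  tax <- tibble::tibble(
    taxon = c("Haemophilus_01", "other_1"),
    genus = c("Haemophilus", "Prevotella")
  )
  res <- shared_genus_frequency(part, tax, c("BB", "IS"),
    exclusive = TRUE, threshold = 0.20
  )
  fr <- res$frequencies
  expect_true(fr$retained[fr$group == "AA" & fr$genus == "Haemophilus"])
  expect_equal(fr$fraction[fr$group == "AA" & fr$genus == "Haemophilus"], 5 / 22)
  expect_lt(fr$fraction[fr$group == "HC" & fr$genus == "Haemophilus"], 0.20)
  expect_equal(nrow(res$fisher_by_genus), 2)
})

test_that("asthma-planted taxa are shared IS+BB in AA but not HC cohorts", {
  hits <- vapply(1:5, function(r) {
    sim <- simulate_cohort(sim_params(seed = 400 + r))
    can <- rarefy_table(sim$bundle$counts, 26185, seed = r)
    meta <- sim$bundle$sample_meta[
      match(rownames(can), sim$bundle$sample_meta$sample_id),
    ]
    part <- shared_partition(can, meta)
    res <- shared_genus_frequency(
      part, sim$bundle$taxonomy, c("BB", "IS"),
      exclusive = TRUE, threshold = 0.20
    )
    fr <- res$frequencies
    aa <- fr[fr$group == "AA" & fr$genus == "Haemophilus", ]
    hc <- fr[fr$group == "HC" & fr$genus == "Haemophilus", ]
    aa_frac <- if (nrow(aa)) aa$fraction else 0
    hc_frac <- if (nrow(hc)) hc$fraction else 0
    (aa_frac >= 0.20) && (aa_frac > hc_frac)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("genus profile correlations match closed forms and flag degeneracy", {
  mk_rel <- function(bb, ow) {
    m <- rbind(S1_BB = bb, S1_OW = ow)
    colnames(m) <- paste0("g", seq_along(bb))
    m
  }
  meta <- tibble::tibble(
    sample_id = c("S1_BB", "S1_OW"), subject_id = "S1",
    site = c("BB", "OW"), group = "AA"
  )
  ident <- genus_profile_correlation(
    mk_rel(c(.5, .3, .2, 0), c(.5, .3, .2, 0)), meta, "BB", "OW"
  )
  expect_equal(ident$per_subject$r, 1)
  disj <- genus_profile_correlation(
    mk_rel(c(.5, .5, 0, 0), c(0, 0, .5, .5)), meta, "BB", "OW"
  )
  expect_equal(disj$per_subject$r, -1)
  few <- genus_profile_correlation(
    mk_rel(c(.5, .5, 0, 0), c(.4, .6, 0, 0)), meta, "BB", "OW"
  )
  expect_true(is.na(few$per_subject$r))
  expect_match(few$per_subject$note, "3 genera")
})

test_that("oral profiles track bronchial profiles far better than nasal ones", {
  sim <- simulate_cohort(sim_params(seed = 19))
  can <- rarefy_table(sim$bundle$counts, 26185, seed = 1)
  meta <- sim$bundle$sample_meta[
    match(rownames(can), sim$bundle$sample_meta$sample_id),
  ]
  rel <- relative_abundance(collapse_to_genus(can, sim$bundle$taxonomy))
  r_is <- genus_profile_correlation(rel, meta, "BB", "IS")$summary$median
  r_ow <- genus_profile_correlation(rel, meta, "BB", "OW")$summary$median
  r_nb <- genus_profile_correlation(rel, meta, "BB", "NB")$summary$median
  expect_gt(r_is, r_ow)
  expect_gt(r_ow, r_nb)
})

test_that("prevalent-genus tests filter at 3% and handle identical profiles", {
  rel <- rbind(
    S1_BB = c(big = 0.96, rare = 0.01, mid = 0.03),
    S1_IS = c(big = 0.96, rare = 0.01, mid = 0.03),
    S2_BB = c(big = 0.94, rare = 0.01, mid = 0.05),
    S2_IS = c(big = 0.94, rare = 0.01, mid = 0.05),
    S3_BB = c(big = 0.92, rare = 0.005, mid = 0.075),
    S3_IS = c(big = 0.92, rare = 0.005, mid = 0.075),
    S4_BB = c(big = 0.9, rare = 0.0, mid = 0.1),
    S4_IS = c(big = 0.9, rare = 0.0, mid = 0.1)
  )
  meta <- tibble::tibble(
    sample_id = rownames(rel),
    subject_id = rep(paste0("S", 1:4), each = 2),
    site = rep(c("BB", "IS"), 4), group = "AA"
  )
  res <- suppressWarnings(prevalent_genus_tests(rel, meta, threshold = 0.03))
  expect_false("rare" %in% res$genus_label)
  mid <- res[res$genus_label == "mid", ]
  expect_equal(mid$wilcoxon_p, 1) # degenerate: identical in BB and IS
  expect_equal(mid$spearman_rho, 1)
})

test_that("partition operations are invariant to taxon ordering", {
  f <- make_partition_fixture()
  perm <- c(3, 1, 4, 2)
  p1 <- shared_partition(f$counts, f$meta)
  p2 <- shared_partition(f$counts[, perm], f$meta)
  o1 <- p1$assignments[order(p1$assignments$taxon), ]
  o2 <- p2$assignments[order(p2$assignments$taxon), ]
  expect_equal(o1$region, o2$region)
})
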