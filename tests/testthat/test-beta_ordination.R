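test_that("UniFrac matches closed-form values on the toy tree", {
  tr <- toy_tree()
  cm <- rbind(
    ab = c(A = 1L, B = 1L, C = 0L, D = 0L),
    a = c(A = 1L, B = 0L, C = 0L, D = 0L),
    cd = c(A = 0L, B = 0L, C = 1L, D = 1L),
    ab2 = c(A = 3L, B = 2L, C = 0L, D = 0L)
  )
  du <- unifrac_matrix(cm, tr, "unweighted")
  expect_equal(du["ab", "ab2"], 0) # identical membership
  expect_equal(du["ab", "cd"], 1) # disjoint clades
  expect_equal(du["ab", "a"], 1 / 3)
  dw <- unifrac_matrix(
    rbind(a = c(A = 10L, B = 0L, C = 0L, D = 0L),
          b = c(A = 0L, B = 10L, C = 0L, D = 0L)),
    tr, "weighted_normalized"
  )
  expect_equal(dw["a", "b"], 0.5)
  same <- unifrac_matrix(cm[c(1, 1), ], tr, "weighted_normalized")
  expect_equal(max(abs(same)), 0)
  bad <- rbind(z = c(A = 0L, B = 0L, C = 0L, D = 0L), a = cm["a", ])
  expect_error(unifrac_matrix(bad, tr), "zero total")
})

test_that("UniFrac agrees with brute-force edge enumeration on random trees", {
  set.seed(42)
  for (rep in 1:25) {
    ntip <- sample(4:16, 1)
    rt <- ape::rtree(ntip)
    cm <- matrix(
      stats::rpois(3 * ntip, 2.5) * stats::rbinom(3 * ntip, 1, 0.6),
      nrow = 3, dimnames = list(c("s1", "s2", "s3"), rt$tip.label)
    )
    storage.mode(cm) <- "integer"
    cm[rowSums(cm) == 0, 1] <- 1L
    for (mode in c("unweighted", "weighted_normalized")) {
      expect_equal(
        c(unifrac_matrix(cm, rt, mode)),
        c(unifrac_oracle(cm, rt, mode)),
        tolerance = 1e-12
      )
    }
  }
})

test_that("unweighted UniFrac is a metric on presence profiles", {
  set.seed(13)
  rt <- ape::rtree(12)
  cm <- matrix(stats::rbinom(8 * 12, 1, 0.5), nrow = 8,
    dimnames = list(paste0("s", 1:8), rt$tip.label)
  )
  storage.mode(cm) <- "integer"
  cm[rowSums(cm) == 0, 1] <- 1L
  d <- unifrac_matrix(cm, rt, "unweighted")
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  for (i in 1:8) {
    for (j in 1:8) {
      for (k in 1:8) {
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      }
    }
  }
})

test_that("ensemble-averaged distances are invariant to table order", {
  sim <- simulate_cohort(small_sim_params(seed = 2))
  cfg <- pipeline_config(rarefaction_depth = 2000, n_rarefactions = 3, seed = 5)
  ens <- rarefy_ensemble(sim$bundle$counts, cfg)
  d1 <- unifrac(ens, sim$bundle$tree)
  ens_rev <- ens
  ens_rev$tables <- rev(ens$tables)
  d2 <- unifrac(ens_rev, sim$bundle$tree)
  expect_equal(d1, d2)
})

test_that("PCoA recovers known geometry", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  o <- pcoa_ordination(d)
  expect_equal(unname(o$coords[, 1]), c(-1, 0, 1), tolerance = 1e-8)
  expect_equal(o$eigenvalues[1], 2, tolerance = 1e-8)
  # all-zero distances: all coordinates zero
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  expect_equal(max(abs(suppressWarnings(pcoa_ordination(z))$coords)), 0)
  # Euclidean input: inter-point distances reproduced
  set.seed(4)
  pts <- matrix(stats::rnorm(10 * 2), 10)
  de <- as.matrix(stats::dist(pts))
  dimnames(de) <- list(paste0("p", 1:10), paste0("p", 1:10))
  rec <- pcoa_ordination(de)$coords[, 1:2]
  expect_equal(unname(as.matrix(stats::dist(rec))), unname(de), tolerance = 1e-8)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("paired site distances honor each subject's available sites", {
  sim <- simulate_cohort(small_sim_params(seed = 21))
  meta <- sim$bundle$sample_meta
  n <- nrow(meta)
  dm <- matrix(0.5, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  diag(dm) <- 0
  pd <- paired_site_distances(dm, meta)
  no_nb <- setdiff(
    unique(meta$subject_id),
    meta$subject_id[meta$site == "NB"]
  )
  expect_false(any(pd$subject_id %in% no_nb & grepl("NB", pd$pair)))
  # identical BB and IS samples give zero BB-IS distance
  for (s in meta$subject_id[meta$site == "BB"]) {
    i <- match(paste0(s, "_BB"), rownames(dm))
    j <- match(paste0(s, "_IS"), rownames(dm))
    dm[i, j] <- dm[j, i] <- 0
  }
  pd0 <- paired_site_distances(dm, meta)
  expect_true(all(pd0$distance[pd0$pair == "BB-IS"] == 0))
})

test_that("LME on PC1 detects planted site shifts and degrades to OLS", {
  set.seed(17)
  n_subj <- 27
  shift <- c(BB = 0, IS = 0.3, OW = 0.6, NB = 0.9)
  subj <- sprintf("S%02d", seq_len(n_subj))
  meta <- tibble::tibble(
    sample_id = as.vector(outer(subj, names(shift), paste, sep = "_")),
    subject_id = rep(subj, 4),
    site = rep(names(shift), each = n_subj),
    group = "AA"
  )
  b_subj <- stats::rnorm(n_subj, 0, 0.2)
  pc1 <- stats::setNames(
    shift[meta$site] + b_subj[match(meta$subject_id, subj)] +
      stats::rnorm(nrow(meta), 0, 0.1),
    meta$sample_id
  )
  res <- lme_pc1(pc1, meta)
  expect_equal(res$method, "lme_lrt_pc1")
  expect_lt(res$p_value, 1e-6)
  # one observation per subject: random intercept is unidentifiable,
  # estimates collapse to OLS
  meta1 <- meta[meta$site %in% c("BB", "IS"), ]
  meta1$subject_id <- meta1$sample_id
  pc1_1 <- pc1[meta1$sample_id]
  expect_warning(res1 <- lme_pc1(pc1_1, meta1), "singular|OLS")
  an <- stats::anova(stats::lm(pc1_1 ~ factor(meta1$site)))
  expect_equal(res1$p_value, an[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("Mantel statistic and permutation p behave as declared", {
  set.seed(9)
  pts <- matrix(stats::rnorm(15 * 2), 15)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  res <- mantel_test(d, d, n_perm = 199, seed = 3)
  expect_equal(res$estimate, 1)
  expect_equal(res$p_value, 1 / 200)
  aff <- 0.3 + 2 * d
  diag(aff) <- 0
  expect_equal(mantel_test(d, aff, n_perm = 99, seed = 1)$estimate, 1)
  d2 <- d
  rownames(d2) <- rev(rownames(d2))
  expect_error(mantel_test(d, d2, n_perm = 99), "identical labels")
  # agreement with the vegan implementation of the statistic
  d3 <- as.matrix(stats::dist(matrix(stats::rnorm(15 * 2), 15)))
  dimnames(d3) <- dimnames(d)
  expect_equal(
    mantel_test(d, d3, n_perm = 99, seed = 1)$estimate,
    unname(vegan::mantel(d, d3, permutations = 2)$statistic),
    tolerance = 1e-10
  )
})
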