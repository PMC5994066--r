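mk_calls <- function(site, n_dom, n_tot, genus = "Prevotella") {
  tibble::tibble(
    sample_id = sprintf("S%02d_%s", seq_len(n_tot), site),
    subject_id = sprintf("S%02d", seq_len(n_tot)),
    site = site, group = "AA",
    dominant_label = c(rep(genus, n_dom), rep("Other", n_tot - n_dom)),
    dominant_genus = c(rep(genus, n_dom), rep("Other", n_tot - n_dom)),
    abundance = 0.5, tie = FALSE
  )
}

test_that("dominance is the argmax with lexicographic flagged ties", {
  rel <- rbind(
    s1 = c(0.4, 0.3, 0.3),
    s2 = c(0.5, 0.5, 0.0),
    s3 = c(0.2, 0.3, 0.5)
  )
  colnames(rel) <- c("Prevotella", "Streptococcus", "Veillonella")
  meta <- tibble::tibble(
    sample_id = rownames(rel), subject_id = paste0("P", 1:3),
    site = "BB", group = "AA"
  )
  calls <- dominant_genus_calls(rel, meta)
  expect_equal(calls$dominant_genus, c("Prevotella", "Prevotella", "Veillonella"))
  expect_equal(calls$tie, c(FALSE, TRUE, FALSE))
  # calls depend only on relative abundance: rescaling changes nothing
  calls2 <- dominant_genus_calls(rel * 1000, meta)
  expect_equal(calls2$dominant_genus, calls$dominant_genus)
  expect_error(dominant_genus_calls(rbind(rel, s4 = c(0, 0, 0)), meta), "empty sample")
})

test_that("dominance contingencies reproduce the printed bronchial pattern", {
  calls <- rbind(
    mk_calls("BB", 21, 27), mk_calls("IS", 23, 27),
    mk_calls("OW", 12, 27), mk_calls("NB", 0, 27)
  )
  p_is <- dominance_contingency(calls, "Prevotella", c("BB", "IS"))
  p_ow <- dominance_contingency(calls, "Prevotella", c("BB", "OW"))
  p_nb <- dominance_contingency(calls, "Prevotella", c("BB", "NB"))
  expect_equal(round(p_is$p_value, 2), 0.73)
  expect_equal(round(p_ow$p_value, 3), 0.024)
  expect_lt(p_nb$p_value, 0.0001)
  cnt <- attr(p_is, "counts")
  expect_equal(unname(colSums(cnt)), c(27, 27))
  # three or more categories route to chi-square
  p3 <- dominance_contingency(calls, "Prevotella", c("BB", "IS", "OW"))
  expect_equal(p3$method, "chi_square")
})

test_that("half-LOD imputation and detection filtering follow the rules", {
  cfg <- pipeline_config()
  cl <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    cyt_rare = c(0.9, rep(NA, 19)), # 1/20 detected
    cyt_mid = c(seq(0.5, 2.5, length.out = 5), rep(NA, 15)), # 5/20
    cyt_full = seq(0.6, 2.5, length.out = 20) # 20/20
  )
  out <- suppressWarnings(cytokine_preprocess(cl, cfg))
  expect_setequal(
    grep("^cyt_", names(out), value = TRUE), c("cyt_mid", "cyt_full")
  )
  expect_equal(out$cyt_mid[6], 0.25) # half the minimum detected (0.5)
  expect_equal(out$cyt_full, cl$cyt_full) # untouched
  # below-LOD entry with analyte minimum detected 0.6 imputes 0.3
  cl2 <- tibble::tibble(
    subject_id = paste0("S", 1:5), cyt_x = c(0.6, 1, 2, NA, 3)
  )
  expect_equal(cytokine_preprocess(cl2, cfg)$cyt_x[4], 0.3)
  # no LOD flags anywhere: identity
  expect_identical(cytokine_preprocess(cl2[1:3, ], cfg), cl2[1:3, ])
  expect_warning(
    cytokine_preprocess(
      tibble::tibble(subject_id = "a", cyt_none = NA_real_), cfg
    ),
    "zero detections"
  )
})

test_that("association scan skips degenerate variables and flags planted links", {
  sim <- simulate_cohort(sim_params(seed = 23))
  b <- sim$bundle
  can <- rarefy_table(b$counts, 26185, seed = 2)
  meta <- b$sample_meta[match(rownames(can), b$sample_meta$sample_id), ]
  rel <- relative_abundance(collapse_to_genus(can, b$taxonomy))
  cl <- suppressWarnings(cytokine_preprocess(b$clinical, pipeline_config()))
  cl$constant <- 1
  expect_warning(
    assoc <- clinical_associations(rel, meta, cl, group = "AA"),
    "zero variance"
  )
  expect_false("constant" %in% assoc$variable)
  hit <- assoc[!is.na(assoc$genus) & assoc$genus == "Moraxella" &
    assoc$site == "NB" & assoc$variable == "bal_eos_frac", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$rho, 0)
  expect_true(hit$flagged)
})

test_that("dominance subgroup comparison detects planted shifts with sign", {
  set.seed(33)
  n <- 18
  calls <- mk_calls("NB", 9, n, genus = "Corynebacterium")
  cl <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    # planted: much lower IL-6 in the dominated subgroup
    cyt_il6 = exp(stats::rnorm(n, ifelse(seq_len(n) <= 9, log(20), log(200)), 0.3)),
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
  res <- dominance_subgroup_compare(calls, cl)
  il6 <- res[res$variable == "cyt_il6", ]
  expect_lt(il6$p_value, 0.01)
  expect_equal(il6$direction, "lower_in_dominated")
  expect_equal(res$method[res$variable == "sex"], "fisher_exact")
  all_dom <- mk_calls("NB", n, n, genus = "Corynebacterium")
  expect_error(dominance_subgroup_compare(all_dom, cl), "empty")
})

test_that("subgroup comparison is calibrated when nothing is planted", {
  set.seed(91)
  ps <- replicate(60, {
    n <- 18
    calls <- mk_calls("NB", 9, n, genus = "Corynebacterium")
    cl <- tibble::tibble(
      subject_id = sprintf("S%02d", 1:n),
      v = stats::rnorm(n)
    )
    dominance_subgroup_compare(calls, cl, variables = "v")$p_value
  })
  expect_lt(abs(mean(ps < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 60) + 0.02)
})
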