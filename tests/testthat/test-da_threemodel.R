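sim_nb_data <- function(n_per_group, mu0, beta, size = Inf, pi0 = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  g <- rep(0:1, each = n_per_group)
  depth <- round(stats::rlnorm(n, log(30000), 0.15))
  mu <- mu0 * exp(beta * g) * depth
  y <- if (is.infinite(size)) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = size, mu = mu)
  }
  if (pi0 > 0) y[stats::runif(n) < pi0] <- 0L
  list(y = as.integer(y), depth = depth, g = g)
}

test_that("Poisson fit recovers a planted log fold-change", {
  d <- sim_nb_data(250, mu0 = 2e-4, beta = log(2), seed = 5)
  fit <- fit_count_model(d$y, d$depth, d$g, "poisson")
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["beta"]] - log(2)), 3 * fit$se_beta)
  # Wald 95% CI coverage over replicates is near nominal
  cover <- vapply(1:60, function(r) {
    di <- sim_nb_data(100, mu0 = 2e-4, beta = log(2), seed = 100 + r)
    f <- fit_count_model(di$y, di$depth, di$g, "poisson")
    abs(f$coef[["beta"]] - log(2)) < 1.96 * f$se_beta
  }, logical(1))
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 60))
})

test_that("model nesting holds numerically", {
  d <- sim_nb_data(60, mu0 = 5e-4, beta = 0.5, size = 1.5, seed = 9)
  nb <- fit_count_model(d$y, d$depth, d$g, "negbin")
  zi <- fit_count_model(d$y, d$depth, d$g, "zinb")
  # zinb contains negbin: its likelihood cannot be meaningfully worse
  expect_gte(zi$logLik, nb$logLik - 0.05)
  # on data without zero inflation the zinb pi collapses
  expect_lt(zi$pi, 0.1)
  expect_lt(abs(zi$coef[["beta"]] - nb$coef[["beta"]]), 0.1)
  # negbin on Poisson data approaches the Poisson likelihood (theta large)
  dp <- sim_nb_data(100, mu0 = 5e-4, beta = 0, seed = 11)
  po <- fit_count_model(dp$y, dp$depth, dp$g, "poisson")
  nbp <- fit_count_model(dp$y, dp$depth, dp$g, "negbin")
  if (nbp$converged) expect_lt(abs(nbp$logLik - po$logLik), 1)
  # constant counts across groups give beta near zero
  dc <- list(y = rep(10L, 20), depth = rep(1000, 20), g = rep(0:1, each = 10))
  fc <- fit_count_model(dc$y, dc$depth, dc$g, "poisson")
  expect_lt(abs(fc$coef[["beta"]]), 1e-8)
})

test_that("AIC selection prefers the generating family", {
  pick <- function(d) {
    fits <- lapply(c("poisson", "negbin", "zinb"), function(f) {
      fit_count_model(d$y, d$depth, d$g, f)
    })
    select_model(fits)$family
  }
  set.seed(2)
  pois_picks <- vapply(1:15, function(r) {
    pick(sim_nb_data(40, 5e-4, 0.3, seed = 200 + r))
  }, character(1))
  expect_gt(mean(pois_picks == "poisson"), 0.5)
  zinb_picks <- vapply(1:15, function(r) {
    pick(sim_nb_data(40, 2e-3, 0.3, size = 2, pi0 = 0.5, seed = 300 + r))
  }, character(1))
  expect_gt(mean(zinb_picks == "zinb"), 0.5)
  one <- fit_count_model(
    sim_nb_data(20, 5e-4, 0, seed = 4)$y,
    sim_nb_data(20, 5e-4, 0, seed = 4)$depth,
    sim_nb_data(20, 5e-4, 0, seed = 4)$g, "poisson"
  )
  expect_equal(select_model(list(one))$family, "poisson")
})

test_that("da_scan records skips and is order-invariant", {
  set.seed(6)
  n <- 24
  counts <- cbind(
    zero = rep(0L, n),
    sparse = c(rep(0L, n - 1), 5L),
    common = stats::rpois(n, 50) + 1L,
    shifted = as.integer(stats::rpois(n, 30) * rep(c(1, 3), each = n / 2)) + 1L
  )
  rownames(counts) <- paste0("s", seq_len(n))
  grp <- factor(rep(c("a", "b"), each = n / 2))
  cfg <- pipeline_config()
  res <- da_scan(counts, grp, cfg)
  expect_match(res$note[res$taxon == "zero"], "all zero")
  expect_match(res$note[res$taxon == "sparse"], "prevalence")
  expect_true(res$flagged[res$taxon == "shifted"])
  expect_equal(res$direction[res$taxon == "shifted"], "enriched")
  perm_s <- sample(n)
  perm_t <- c(3, 1, 4, 2)
  res2 <- da_scan(counts[perm_s, perm_t], grp[perm_s], cfg)
  res2 <- res2[match(res$taxon, res2$taxon), ]
  expect_equal(res$beta, res2$beta, tolerance = 1e-6)
  expect_equal(res$q, res2$q, tolerance = 1e-6)
})

test_that("the planted nasal Staphylococcus enrichment is confirmed at OTU level", {
  sim <- simulate_cohort(sim_params(seed = 512))
  b <- sim$bundle
  can <- rarefy_table(b$counts, 26185, seed = 3)
  meta <- b$sample_meta[match(rownames(can), b$sample_meta$sample_id), ]
  sel <- meta$site == "NB" & meta$group %in% c("AA", "HC")
  res <- da_scan(
    can[sel, , drop = FALSE],
    factor(meta$group[sel], levels = c("HC", "AA")),
    pipeline_config()
  )
  planted <- res[res$taxon == sim$ground_truth$da_taxa$taxon, ]
  expect_gt(planted$beta, 0)
  expect_true(planted$flagged)
})
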