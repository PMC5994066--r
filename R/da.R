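#' Fit one count model for a single taxon
#'
#' Maximum-likelihood fit of taxon counts on a binary group covariate with
#' a log link and a fixed log-depth offset, under one of three families:
#' Poisson, negative binomial (dispersion estimated by ML), or
#' zero-inflated negative binomial (constant zero-inflation probability on
#' the logit scale, fitted by direct optimization started from the
#' negative-binomial solution).
#'
#' @param y Nonnegative integer counts per sample.
#' @param depth Per-sample library sizes (> 0).
#' @param group Binary covariate (logical, 0/1, or 2-level factor); the
#'   reported `beta` is the log fold-change of the second level relative
#'   to the first.
#' @param family `"poisson"`, `"negbin"`, or `"zinb"`.
#' @return List of class `"count_model_fit"`: `family`, `coef`
#'   (intercept, beta), `se_beta`, `dispersion` (theta; NA for Poisson),
#'   `pi` (zero-inflation probability; NA unless zinb), `logLik`, `aic`
#'   (2k - 2 logL), `converged`, `p_wald`.
#' @export
fit_count_model <- function(y, depth, group,
                            family = c("poisson", "negbin", "zinb")) {
  family <- match.arg(family)
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.logical(group))
  stopifnot(length(y) == length(depth), length(y) == length(g), all(depth > 0))
  if (min(table(g)) < 3) stop("need at least 3 samples per group")
  off <- log(depth)
  out <- list(
    family = family, coef = c(intercept = NA_real_, beta = NA_real_),
    se_beta = NA_real_, dispersion = NA_real_, pi = NA_real_,
    logLik = NA_real_, aic = NA_real_, converged = FALSE, p_wald = NA_real_
  )
  class(out) <- "count_model_fit"
  if (family == "poisson") {
    fit <- tryCatch(
      stats::glm(y ~ g + offset(off), family = stats::poisson()),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(y ~ g + offset(off), family = stats::poisson()))
      }
    )
    if (is.null(fit) || !fit$converged) {
      return(out)
    }
    sm <- summary(fit)$coefficients
    out$coef <- c(intercept = sm[1, 1], beta = sm[2, 1])
    out$se_beta <- sm[2, 2]
    out$logLik <- as.numeric(stats::logLik(fit))
    out$aic <- 2 * 2 - 2 * out$logLik
    out$converged <- TRUE
    out$p_wald <- sm[2, 4]
    return(out)
  }
  nb <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ g + offset(off))),
    error = function(e) NULL
  )
  if (family == "negbin") {
    if (is.null(nb) || !nb$converged) {
      return(out)
    }
    sm <- summary(nb)$coefficients
    out$coef <- c(intercept = sm[1, 1], beta = sm[2, 1])
    out$se_beta <- sm[2, 2]
    out$dispersion <- nb$theta
    out$logLik <- as.numeric(stats::logLik(nb))
    out$aic <- 2 * 3 - 2 * out$logLik
    out$converged <- TRUE
    out$p_wald <- sm[2, 4]
    return(out)
  }
  # zinb: direct ML over (intercept, beta, log theta, logit pi)
  nll <- function(par) {
    mu <- exp(par[1] + par[2] * g + off)
    theta <- exp(par[3])
    pi <- stats::plogis(par[4])
    f <- suppressWarnings(stats::dnbinom(y, size = theta, mu = mu))
    ll <- ifelse(y == 0, log(pi + (1 - pi) * f), log1p(-pi) + log(f))
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }
  start <- if (!is.null(nb) && nb$converged) {
    c(unname(stats::coef(nb)), log(max(nb$theta, 1e-3)), stats::qlogis(0.05))
  } else {
    mu0 <- max(mean(y / depth), 1e-8)
    c(log(mu0), 0, 0, stats::qlogis(max(0.05, mean(y == 0) / 2)))
  }
  opt <- tryCatch(
    suppressWarnings(stats::optim(start, nll,
      method = "BFGS", hessian = TRUE,
      control = list(maxit = 500)
    )),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0) {
    return(out)
  }
  se <- tryCatch(
    {
      v <- diag(solve(opt$hessian))[2]
      if (is.na(v) || v <= 0) NA_real_ else sqrt(v)
    },
    error = function(e) NA_real_
  )
  out$coef <- c(intercept = opt$par[1], beta = opt$par[2])
  out$se_beta <- se
  out$dispersion <- exp(opt$par[3])
  out$pi <- stats::plogis(opt$par[4])
  out$logLik <- -opt$value
  out$aic <- 2 * 4 - 2 * out$logLik
  out$converged <- is.finite(se)
  out$p_wald <- if (is.finite(se)) {
    2 * stats::pnorm(-abs(opt$par[2] / se))
  } else {
    NA_real_
  }
  out
}

#' Select among the three count-model fits
#'
#' Lowest AIC among converged fits; exact ties go to the simpler family
#' (poisson < negbin < zinb). Returns `NULL` when no fit converged (the
#' taxon is then skipped by [da_scan()]).
#'
#' @param fits List of [fit_count_model()] results.
#' @return The selected fit, or `NULL`.
#' @export
select_model <- function(fits) {
  order_simple <- c(poisson = 1, negbin = 2, zinb = 3)
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (!length(fits)) {
    return(NULL)
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  simp <- order_simple[vapply(fits, `[[`, character(1), "family")]
  fits[[order(aic, simp)[1]]]
}

#' Three-model differential-abundance scan
#'
#' Per-taxon differential abundance between two groups: each taxon passing
#' a 10% prevalence pre-filter is fitted under Poisson, negative binomial,
#' and zero-inflated negative binomial models (log-depth offset), the
#' lowest-AIC converged fit is selected, the group effect is tested by
#' Wald z on beta, and p values are BH-corrected across taxa with flags at
#' `q < config$fdr_q_da`.
#'
#' @param counts Samples x taxa integer matrix.
#' @param group Binary covariate over samples (2-level factor, logical, or
#'   0/1); `beta > 0` means enriched in the second level.
#' @param config A [pipeline_config()].
#' @param min_prevalence Minimum fraction of samples with a nonzero count.
#' @return Tibble: `taxon`, `family`, `beta`, `se`, `p`, `q`, `direction`,
#'   `flagged`, `note` (skips recorded, not dropped).
#' @export
da_scan <- function(counts, group, config = pipeline_config(),
                    min_prevalence = 0.10) {
  depth <- rowSums(counts)
  taxa <- colnames(counts)
  rows <- vector("list", length(taxa))
  for (k in seq_along(taxa)) {
    y <- counts[, k]
    note <- NA_character_
    if (all(y == 0)) {
      note <- "skipped: all zero"
    } else if (mean(y > 0) < min_prevalence) {
      note <- "skipped: below prevalence filter"
    }
    if (!is.na(note)) {
      rows[[k]] <- tibble::tibble(
        taxon = taxa[k], family = NA_character_, beta = NA_real_,
        se = NA_real_, p = NA_real_, note = note
      )
      next
    }
    fits <- lapply(c("poisson", "negbin", "zinb"), function(fam) {
      fit_count_model(y, depth, group, family = fam)
    })
    best <- select_model(fits)
    if (is.null(best)) {
      rows[[k]] <- tibble::tibble(
        taxon = taxa[k], family = NA_character_, beta = NA_real_,
        se = NA_real_, p = NA_real_, note = "skipped: no converged fit"
      )
      next
    }
    rows[[k]] <- tibble::tibble(
      taxon = taxa[k], family = best$family, beta = unname(best$coef["beta"]),
      se = best$se_beta, p = best$p_wald, note = NA_character_
    )
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, config$fdr_q_da)
  out$q <- fdr$q
  out$direction <- ifelse(is.na(out$beta), NA_character_,
    ifelse(out$beta > 0, "enriched", "depleted")
  )
  out$flagged <- !is.na(out$q) & out$q < config$fdr_q_da
  out
}

#' Simulate a two-group count matrix for differential-abundance calibration
#'
#' Draws per-taxon negative-binomial counts at log-normal library depths,
#' with a chosen number of taxa enriched by a common fold-change in the
#' second group. Used to calibrate the FDR and sensitivity of
#' [da_scan()].
#'
#' @param n_per_group Samples per group.
#' @param n_taxa Total number of taxa.
#' @param n_da Number of enriched taxa (the first `n_da` columns).
#' @param fold Fold-change of enriched taxa in group 2.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters.
#' @param size Negative-binomial size (inverse overdispersion).
#' @param seed Integer seed.
#' @return List: `counts` (samples x taxa), `group` (factor), `da_taxa`
#'   (character vector of enriched taxon names).
#' @export
simulate_da_counts <- function(n_per_group = 30, n_taxa = 1000, n_da = 0,
                               fold = 4, depth_meanlog = log(30000),
                               depth_sdlog = 0.2, size = 2, seed = 1L) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- factor(rep(c("g1", "g2"), each = n_per_group))
  depth <- round(stats::rlnorm(n, depth_meanlog, depth_sdlog))
  base <- stats::rlnorm(n_taxa, log(1 / n_taxa), 1)
  base <- base / sum(base)
  taxa <- sprintf("taxon_%04d", seq_len(n_taxa))
  counts <- matrix(0L, n, n_taxa, dimnames = list(
    paste0("s", seq_len(n)), taxa
  ))
  eff <- rep(1, n_taxa)
  if (n_da > 0) eff[seq_len(n_da)] <- fold
  for (i in seq_len(n)) {
    mu <- base * ifelse(rep(group[i] == "g2", n_taxa), eff, 1) * depth[i]
    counts[i, ] <- stats::rnbinom(n_taxa, size = size, mu = mu)
  }
  list(counts = counts, group = group, da_taxa = taxa[seq_len(n_da)])
}
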