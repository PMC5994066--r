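#' Dominant-genus call per sample
#'
#' The dominant genus of a sample is the argmax of genus relative
#' abundance (no minimum-share requirement). Exact ties are broken
#' lexicographically on the column label and flagged.
#'
#' @param genus_rel Samples x genus relative-abundance matrix carrying the
#'   `genus` attribute from [collapse_to_genus()].
#' @param meta Sample metadata.
#' @return Tibble: `sample_id`, `subject_id`, `site`, `group`,
#'   `dominant_label`, `dominant_genus`, `abundance`, `tie`.
#' @export
dominant_genus_calls <- function(genus_rel, meta) {
  if (any(rowSums(genus_rel) == 0)) {
    stop("empty sample: ", rownames(genus_rel)[rowSums(genus_rel) == 0][[1]])
  }
  meta <- meta[match(rownames(genus_rel), meta$sample_id), ]
  genus_attr <- attr(genus_rel, "genus")
  labs <- colnames(genus_rel) # lexicographic column order = tie-break order
  winner <- apply(genus_rel, 1, which.max) # first max = lexicographic winner
  top <- genus_rel[cbind(seq_len(nrow(genus_rel)), winner)]
  tie <- vapply(seq_len(nrow(genus_rel)), function(i) {
    sum(genus_rel[i, ] == top[i]) > 1
  }, logical(1))
  tibble::tibble(
    sample_id = rownames(genus_rel),
    subject_id = meta$subject_id, site = meta$site, group = meta$group,
    dominant_label = labs[winner],
    dominant_genus = if (is.null(genus_attr)) labs[winner] else genus_attr[winner],
    abundance = as.numeric(top), tie = tie
  )
}

#' Frequency table of dominant genera
#'
#' @param calls Tibble from [dominant_genus_calls()].
#' @param by `"site"` or `"site_group"`.
#' @return Tibble of counts of each dominant genus per stratum.
#' @export
dominance_frequency <- function(calls, by = c("site", "site_group")) {
  by <- match.arg(by)
  key <- if (by == "site") calls$site else paste(calls$site, calls$group)
  tab <- table(key, calls$dominant_label)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("stratum", "dominant_label", "n")
  tibble::as_tibble(out[out$n > 0, ])
}

#' Contingency test on dominance of a focal genus
#'
#' Builds the dominated / not-dominated counts of `focal_genus` across the
#' categories defined by `grouping` (a named list of sample subsets, e.g.
#' two sites or two subject groups at one site) and applies Fisher's exact
#' test for 2 categories or the chi-square test otherwise.
#'
#' @param calls Tibble from [dominant_genus_calls()].
#' @param focal_genus Genus name (matched against `dominant_genus`).
#' @param grouping Named list of logical vectors over the rows of `calls`,
#'   or a character vector of sites (each site becomes a category).
#' @return One-row test-result tibble; the counts are attached as the
#'   `counts` attribute.
#' @export
dominance_contingency <- function(calls, focal_genus, grouping) {
  if (is.character(grouping)) {
    grouping <- stats::setNames(
      lapply(grouping, function(s) calls$site == s), grouping
    )
  }
  stopifnot(length(grouping) >= 2)
  dom <- calls$dominant_genus == focal_genus
  counts <- vapply(grouping, function(sel) {
    c(dominated = sum(dom[sel]), other = sum(!dom[sel]))
  }, integer(2))
  res <- if (length(grouping) == 2) {
    fisher_exact_2x2(
      counts["dominated", 1], counts["other", 1],
      counts["dominated", 2], counts["other", 2]
    )
  } else {
    chi_square_rxc(t(counts))
  }
  attr(res, "counts") <- counts
  res
}

#' Cytokine limit-of-detection preprocessing
#'
#' Applies the half-LOD rule to cytokine analyte columns (prefixed
#' `cyt_`): below-LOD measurements (stored as `NA`) are assigned one half
#' of the lowest detected value for that analyte. Analytes detected in
#' fewer than `config$detection_subject_fraction` of subjects are dropped
#' with a warning, as is any analyte with zero detections. A table with no
#' below-LOD entries is returned unchanged.
#'
#' @param clinical Subject-level clinical tibble.
#' @param config A [pipeline_config()].
#' @return Clinical tibble with imputed and filtered analyte columns.
#' @export
cytokine_preprocess <- function(clinical, config = pipeline_config()) {
  analytes <- grep("^cyt_", names(clinical), value = TRUE)
  drop <- character(0)
  for (a in analytes) {
    v <- clinical[[a]]
    detected <- sum(!is.na(v))
    if (detected == 0) {
      warning("analyte ", a, " has zero detections; dropped")
      drop <- c(drop, a)
      next
    }
    if (detected / length(v) < config$detection_subject_fraction) {
      warning(
        "analyte ", a, " detected in ", detected, "/", length(v),
        " subjects (< ", config$detection_subject_fraction, "); dropped"
      )
      drop <- c(drop, a)
      next
    }
    if (anyNA(v)) clinical[[a]][is.na(v)] <- min(v, na.rm = TRUE) / 2
  }
  clinical[setdiff(names(clinical), drop)]
}

#' Clinical/inflammatory association scan
#'
#' Spearman correlation between the relative abundance of each prevalent
#' genus at each site and each numeric clinical variable, within one
#' subject group (default AA). Prevalence (>= `threshold` in at least one
#' sample) is assessed per site within the group. p values are BH-adjusted
#' across the whole scan and records are flagged at
#' `q <= config$fdr_q_assoc`. Zero-variance variables are skipped with a
#' warning.
#'
#' @param genus_rel Samples x genus relative-abundance matrix.
#' @param meta Sample metadata.
#' @param clinical Preprocessed clinical tibble (see
#'   [cytokine_preprocess()]).
#' @param group Subject group to scan.
#' @param variables Clinical columns to scan; default all numeric,
#'   non-identifier columns.
#' @param threshold Genus prevalence threshold.
#' @param config A [pipeline_config()] (supplies `fdr_q_assoc`).
#' @return Tibble: `genus_label`, `genus`, `site`, `variable`, `rho`, `p`,
#'   `q`, `n`, `flagged`.
#' @export
clinical_associations <- function(genus_rel, meta, clinical, group = "AA",
                                  variables = NULL, threshold = 0.03,
                                  config = pipeline_config()) {
  meta <- meta[match(rownames(genus_rel), meta$sample_id), ]
  genus_attr <- attr(genus_rel, "genus")
  if (is.null(variables)) {
    num <- vapply(clinical, is.numeric, logical(1))
    variables <- setdiff(names(clinical)[num], "subject_id")
  }
  rows <- list()
  warned <- character(0)
  for (s in intersect(SITES, unique(meta$site))) {
    sel <- which(meta$site == s & meta$group == group)
    if (length(sel) < 4) next
    sub <- genus_rel[sel, , drop = FALSE]
    prevalent <- which(apply(sub, 2, max) >= threshold)
    subj <- meta$subject_id[sel]
    cl <- clinical[match(subj, clinical$subject_id), ]
    usable <- vapply(variables, function(v) {
      sv <- stats::sd(cl[[v]], na.rm = TRUE)
      ok <- !is.na(sv) && sv > 0
      if (!ok && !(v %in% warned)) {
        warning("variable ", v, " has zero variance in ", group,
          "; skipped", call. = FALSE)
        warned <<- c(warned, v)
      }
      ok
    }, logical(1))
    for (gi in prevalent) {
      for (v in variables[usable]) {
        y <- cl[[v]]
        if (sum(stats::complete.cases(sub[, gi], y)) < 4) next
        ct <- correlation(sub[, gi], y, mode = "spearman")
        rows[[length(rows) + 1]] <- tibble::tibble(
          genus_label = colnames(genus_rel)[gi],
          genus = if (is.null(genus_attr)) {
            colnames(genus_rel)[gi]
          } else {
            genus_attr[gi]
          },
          site = s, variable = v,
          rho = ct$estimate, p = ct$p_value,
          n = as.integer(ct$n)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(tibble::tibble())
  }
  fdr <- bh_fdr(out$p, config$fdr_q_assoc)
  out$q <- fdr$q
  out$flagged <- fdr$significant
  out
}

#' Compare clinical variables between dominance-defined subgroups
#'
#' Splits the subjects of one group by whether their sample at `site` is
#' dominated by `focal_genus`, then compares each numeric clinical
#' variable between the two subgroups by the Mann-Whitney test and each
#' two-level categorical variable by Fisher's exact test.
#'
#' @param calls Tibble from [dominant_genus_calls()].
#' @param clinical Preprocessed clinical tibble.
#' @param focal_genus Genus defining the split (default Corynebacterium).
#' @param site Site whose dominance defines the split (default NB).
#' @param group Subject group (default AA).
#' @param variables Clinical columns to compare; default all except
#'   `subject_id` and `group`.
#' @return Tibble of test results, one row per variable.
#' @export
dominance_subgroup_compare <- function(calls, clinical,
                                       focal_genus = "Corynebacterium",
                                       site = "NB", group = "AA",
                                       variables = NULL) {
  sel <- calls[calls$site == site & calls$group == group, ]
  if (!nrow(sel)) stop("no calls for site ", site, " in group ", group)
  dom_subj <- sel$subject_id[sel$dominant_genus == focal_genus]
  other_subj <- setdiff(sel$subject_id, dom_subj)
  if (!length(dom_subj) || !length(other_subj)) {
    stop("degenerate split: one dominance subgroup is empty")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(clinical), c("subject_id", "group"))
  }
  cl_dom <- clinical[match(dom_subj, clinical$subject_id), ]
  cl_oth <- clinical[match(other_subj, clinical$subject_id), ]
  rows <- list()
  for (v in variables) {
    x <- cl_dom[[v]]
    y <- cl_oth[[v]]
    if (is.numeric(x)) {
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
      res <- two_sample_test(x, y, mode = "mann_whitney")
      res$direction <- ifelse(
        stats::median(x, na.rm = TRUE) > stats::median(y, na.rm = TRUE),
        "higher_in_dominated", "lower_in_dominated"
      )
    } else {
      lev <- stats::na.omit(unique(c(x, y)))
      if (length(lev) != 2) next
      res <- fisher_exact_2x2(
        sum(x == lev[1], na.rm = TRUE), sum(x == lev[2], na.rm = TRUE),
        sum(y == lev[1], na.rm = TRUE), sum(y == lev[2], na.rm = TRUE)
      )
      res$direction <- NA_character_
    }
    res$variable <- v
    res$n_dominated <- length(dom_subj)
    res$n_other <- length(other_subj)
    rows[[length(rows) + 1]] <- res
  }
  do.call(rbind, rows)
}
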