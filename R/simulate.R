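#' Default genus roster for the synthetic cohort
#'
#' Defines the taxon pool of the simulator: airway genera organized as
#' monophyletic clades, each with a Greengenes-style lineage and a niche
#' pool assignment (oral, nasal, lung). One Neisseriaceae clade carries no
#' genus assignment, exercising family-level labels in the genus collapse.
#'
#' @return Tibble: `clade` (tip-label prefix), `genus` (NA = unassigned),
#'   `family`, `order`, `class`, `phylum`, `n_otus`, `oral`, `nasal`,
#'   `lung` (pool base weights; 0 = absent from pool).
#' @export
default_genus_roster <- function() {
  tibble::tribble(
    ~clade, ~genus, ~family, ~order, ~class, ~phylum, ~n_otus, ~oral, ~nasal, ~lung,
    "Prevotella", "Prevotella", "Prevotellaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes", 15L, 0.24, 0, 0.46,
    "Streptococcus", "Streptococcus", "Streptococcaceae", "Lactobacillales", "Bacilli", "Firmicutes", 13L, 0.20, 0.15, 0,
    "Veillonella", "Veillonella", "Veillonellaceae", "Clostridiales", "Clostridia", "Firmicutes", 8L, 0.12, 0, 0.18,
    "Neisseria", "Neisseria", "Neisseriaceae", "Neisseriales", "Betaproteobacteria", "Proteobacteria", 8L, 0.07, 0, 0,
    "Neisseriaceae", NA, "Neisseriaceae", "Neisseriales", "Betaproteobacteria", "Proteobacteria", 2L, 0.02, 0, 0,
    "Haemophilus", "Haemophilus", "Pasteurellaceae", "Pasteurellales", "Gammaproteobacteria", "Proteobacteria", 8L, 0.08, 0, 0,
    "Fusobacterium", "Fusobacterium", "Fusobacteriaceae", "Fusobacteriales", "Fusobacteriia", "Fusobacteria", 7L, 0.08, 0, 0.10,
    "Porphyromonas", "Porphyromonas", "Porphyromonadaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes", 7L, 0.07, 0, 0.10,
    "Actinomyces", "Actinomyces", "Actinomycetaceae", "Actinomycetales", "Actinobacteria", "Actinobacteria", 8L, 0.07, 0, 0.04,
    "Leptotrichia", "Leptotrichia", "Leptotrichiaceae", "Fusobacteriales", "Fusobacteriia", "Fusobacteria", 6L, 0.05, 0, 0,
    "Corynebacterium", "Corynebacterium", "Corynebacteriaceae", "Actinomycetales", "Actinobacteria", "Actinobacteria", 10L, 0, 0.45, 0,
    "Staphylococcus", "Staphylococcus", "Staphylococcaceae", "Bacillales", "Bacilli", "Firmicutes", 8L, 0, 0.22, 0,
    "Moraxella", "Moraxella", "Moraxellaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria", 6L, 0, 0, 0,
    "Alloiococcus", "Alloiococcus", "Carnobacteriaceae", "Lactobacillales", "Bacilli", "Firmicutes", 4L, 0, 0.18, 0,
    "Pseudomonas", "Pseudomonas", "Pseudomonadaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria", 5L, 0, 0, 0.06,
    "Lactobacillus", "Lactobacillus", "Lactobacillaceae", "Lactobacillales", "Bacilli", "Firmicutes", 5L, 0, 0, 0.06
  )
}

#' Simulation parameters for the synthetic paired cohort
#'
#' Defaults emulate the study design the pipeline reproduces: 22 atopic
#' asthmatic (AA), 12 atopic non-asthmatic (ANA), and 11 healthy control
#' (HC) subjects, each with a BB/IS/OW sample triplet, and nasal brushes
#' for a 27-subject subset (18 AA, 3 ANA, 6 HC). Site compositions are
#' mixtures of subject-level oral, nasal, and lung source pools:
#' `BB = f_oral * oral + f_nasal * nasal + f_lung * lung` and
#' `IS = f_sal * OW + (1 - f_sal) * BB` (salivary carry-over). Nasal
#' communities are Corynebacterium-dominated with group-specific
#' probability, and Moraxella relative abundance in the nose follows a
#' group-specific logit-normal that is near zero outside asthma. Clinical
#' covariates are generated with planted monotone links (e.g. BAL
#' eosinophil fraction = logistic in logit nasal Moraxella abundance).
#'
#' @param n_subjects Named subjects per group.
#' @param nb_subset Named size of the nasal-brush subset per group.
#' @param n_taxa Number of OTUs (allocated over the roster's clades).
#' @param roster Genus roster, see [default_genus_roster()].
#' @param f_oral,f_nasal,f_lung Bronchial source mixing weights (sum 1).
#' @param f_sal Salivary fraction of induced sputum.
#' @param pool_conc Dirichlet concentration of subject pools around the
#'   base pools (smaller = more between-subject variation).
#' @param dm_conc Dirichlet-multinomial concentration of a sample around
#'   its true composition (sequencing overdispersion).
#' @param cory_dom_prob Named per-group probability that a subject's nasal
#'   community is Corynebacterium-dominated.
#' @param cory_boost,cory_deflate Multipliers on the Corynebacterium pool
#'   weight for dominated / non-dominated subjects.
#' @param mor_logit_mean,mor_logit_sd Named per-group parameters of the
#'   logit-normal nasal Moraxella relative abundance.
#' @param lung_asthma_extra Named vector of extra lung-pool genus weights
#'   present only in AA subjects (asthma-associated lower-airway taxa).
#' @param da_fold Enrichment fold of the planted differentially abundant
#'   Staphylococcus OTU in AA nasal pools.
#' @param eos_slope,eos_noise_sd Planted BAL-eosinophil link: slope on the
#'   logit scale against logit nasal Moraxella abundance, and Gaussian
#'   noise sd.
#' @param cyt_slope,cyt_noise_sd Planted log-cytokine link against logit
#'   nasal Corynebacterium abundance (negative slope = lower cytokines
#'   when Corynebacterium-dominated).
#' @param depth_meanlog,depth_sdlog,depth_floor Log-normal sequencing
#'   depth; the floor keeps every sample at or above the rarefaction
#'   depth.
#' @param geom_ratio Within-genus geometric abundance decay.
#' @param include_controls Add a negative-control sample carrying two
#'   contaminant (Ralstonia) OTUs.
#' @param seed Master seed; all randomness derives from it via fixed
#'   stream labels.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(n_subjects = c(AA = 22L, ANA = 12L, HC = 11L),
                       nb_subset = c(AA = 18L, ANA = 3L, HC = 6L),
                       n_taxa = 120L,
                       roster = default_genus_roster(),
                       f_oral = 0.62, f_nasal = 0.05, f_lung = 0.33,
                       f_sal = 0.35,
                       pool_conc = 50, dm_conc = 200,
                       cory_dom_prob = c(AA = 0.5, ANA = 0.7, HC = 1.0),
                       cory_boost = 6, cory_deflate = 0.5,
                       mor_logit_mean = c(AA = -3, ANA = -9, HC = -9),
                       mor_logit_sd = c(AA = 1.5, ANA = 0.7, HC = 0.7),
                       lung_asthma_extra = c(Haemophilus = 0.06, Neisseria = 0.04),
                       da_fold = 6,
                       eos_slope = 0.8, eos_noise_sd = 0.4,
                       cyt_slope = -0.7, cyt_noise_sd = 0.45,
                       depth_meanlog = log(45000), depth_sdlog = 0.25,
                       depth_floor = 27000L,
                       geom_ratio = 0.55,
                       include_controls = FALSE,
                       seed = 104729L) {
  stopifnot(
    all(nb_subset <= n_subjects),
    abs(f_oral + f_nasal + f_lung - 1) < 1e-9,
    f_oral >= 0, f_nasal >= 0, f_lung >= 0,
    f_sal >= 0, f_sal <= 1,
    all(cory_dom_prob >= 0 & cory_dom_prob <= 1)
  )
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (all(g == 0)) g[which.max(alpha[pos])] <- 1
  x[pos] <- g / sum(g)
  x
}

allocate_otus <- function(roster, n_taxa) {
  g <- nrow(roster)
  if (n_taxa < g) {
    roster <- roster[seq_len(n_taxa), ]
    roster$n_otus <- 1L
    return(roster)
  }
  w <- roster$n_otus / sum(roster$n_otus)
  alloc <- pmax(1L, floor(w * n_taxa))
  while (sum(alloc) < n_taxa) {
    i <- which.max(w * n_taxa - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_taxa) {
    ok <- alloc > 1L
    i <- which(ok)[which.min((w * n_taxa - alloc)[ok])]
    alloc[i] <- alloc[i] - 1L
  }
  roster$n_otus <- alloc
  roster
}

otu_table_from_roster <- function(roster) {
  do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    r <- roster[i, ]
    tibble::tibble(
      taxon = sprintf("%s_%02d", r$clade, seq_len(r$n_otus)),
      clade = r$clade, genus = r$genus, family = r$family,
      order = r$order, class = r$class, phylum = r$phylum,
      rank = seq_len(r$n_otus)
    )
  }))
}

#' Simulate a genus-structured rooted phylogeny
#'
#' Builds a random coalescent backbone over the roster's clades and grafts
#' a random coalescent subtree onto each backbone tip, so that every genus
#' is monophyletic and the genus-level collapse of simulated data is
#' meaningful. Branch lengths are coalescent waiting times (exponential);
#' tips are labeled `<clade>_<nn>` so the taxonomy map is derivable from
#' tip labels via [taxonomy_from_tips()].
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed (same seed, same newick string).
#' @param roster Genus roster.
#' @return Rooted binary `ape::phylo` with positive branch lengths.
#' @export
simulate_phylogeny <- function(n_taxa, seed, roster = default_genus_roster()) {
  stopifnot(n_taxa >= 2)
  set.seed(derive_seed(seed, "tree"))
  roster <- allocate_otus(roster, n_taxa)
  otus <- otu_table_from_roster(roster)
  clades <- roster$clade
  backbone <- if (length(clades) >= 2) {
    ape::rcoal(length(clades), tip.label = clades)
  } else {
    NULL
  }
  subtrees <- lapply(seq_len(nrow(roster)), function(i) {
    labs <- otus$taxon[otus$clade == clades[i]]
    if (length(labs) == 1) {
      return(labs)
    }
    tr <- ape::rcoal(length(labs), tip.label = labs)
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  })
  if (is.null(backbone)) {
    tree <- subtrees[[1]]
  } else {
    backbone$edge.length <- pmax(backbone$edge.length, 1e-6)
    tree <- backbone
    for (i in seq_along(clades)) {
      st <- subtrees[[i]]
      if (is.character(st)) {
        tree$tip.label[tree$tip.label == clades[i]] <- st
      } else {
        tree <- ape::bind.tree(tree, st,
          where = which(tree$tip.label == clades[i])
        )
      }
    }
  }
  tree
}

#' Derive a taxonomy map from genus-structured tip labels
#'
#' @param tip_labels Tip labels of a [simulate_phylogeny()] tree.
#' @param roster Genus roster used to build the tree.
#' @return Taxonomy tibble (as produced by [parse_gg_lineage()]).
#' @export
taxonomy_from_tips <- function(tip_labels, roster = default_genus_roster()) {
  clade <- sub("_[0-9]+$", "", tip_labels)
  r <- roster[match(clade, roster$clade), ]
  tx <- tibble::tibble(
    taxon = tip_labels, kingdom = "Bacteria", phylum = r$phylum,
    class = r$class, order = r$order, family = r$family,
    genus = r$genus, species = NA_character_
  )
  tx$lineage <- format_gg_lineage(tx)
  tx
}

geom_weights <- function(n, ratio) {
  w <- ratio^(seq_len(n) - 1)
  w / sum(w)
}

pool_base <- function(otus, roster, pool, geom_ratio, reversed = character(0)) {
  base <- numeric(nrow(otus))
  for (i in seq_len(nrow(roster))) {
    w <- roster[[pool]][i]
    if (w <= 0) next
    idx <- which(otus$clade == roster$clade[i])
    gw <- geom_weights(length(idx), geom_ratio)
    if (roster$clade[i] %in% reversed) gw <- rev(gw)
    base[idx] <- w * gw
  }
  base
}

#' Simulate a paired multi-site airway cohort
#'
#' Generates one sample per (subject, site) according to the paired design
#' (BB, IS, OW for every subject; NB for the nasal subset), with counts
#' drawn Dirichlet-multinomially at a log-normal depth around planted true
#' compositions, a clinical table with planted monotone covariate links,
#' and a ground-truth sidecar recording everything planted.
#'
#' @param params A [sim_params()] object.
#' @return List: `bundle` (an [airway_bundle()]) and `ground_truth` (list:
#'   mixing weights, per-sample true compositions, pool memberships,
#'   per-subject nasal dominance and Moraxella logits, planted slopes,
#'   planted differentially abundant taxa).
#' @export
simulate_cohort <- function(params = sim_params()) {
  p <- params
  roster <- allocate_otus(p$roster, p$n_taxa)
  if (p$include_controls) {
    roster <- rbind(roster, tibble::tibble(
      clade = "Ralstonia", genus = "Ralstonia", family = "Burkholderiaceae",
      order = "Burkholderiales", class = "Betaproteobacteria",
      phylum = "Proteobacteria", n_otus = 2L, oral = 0, nasal = 0, lung = 0
    ))
  }
  otus <- otu_table_from_roster(roster)
  tree <- simulate_phylogeny(sum(roster$n_otus), p$seed, roster = roster)
  taxonomy <- taxonomy_from_tips(otus$taxon, roster = roster)
  ntax <- nrow(otus)

  groups <- rep(names(p$n_subjects), p$n_subjects)
  subj_id <- unlist(lapply(names(p$n_subjects), function(g) {
    sprintf("%s%02d", g, seq_len(p$n_subjects[[g]]))
  }))
  has_nb <- unlist(lapply(names(p$n_subjects), function(g) {
    seq_len(p$n_subjects[[g]]) <= p$nb_subset[[g]]
  }))
  nsub <- length(subj_id)

  oral_base <- pool_base(otus, roster, "oral", p$geom_ratio)
  nasal_base <- pool_base(otus, roster, "nasal", p$geom_ratio)
  lung_base_common <- pool_base(otus, roster, "lung", p$geom_ratio)
  # asthma-associated lower-airway taxa enter the AA lung pool, with
  # within-genus order reversed relative to the oral pool so the shared
  # IS+BB OTUs are not the ones the oral wash already detects
  extra <- roster
  extra$lung <- 0
  for (g in names(p$lung_asthma_extra)) {
    extra$lung[extra$clade == g] <- p$lung_asthma_extra[[g]]
  }
  lung_extra <- pool_base(otus, extra, "lung", p$geom_ratio,
    reversed = names(p$lung_asthma_extra)
  )
  staph_idx <- which(otus$taxon == "Staphylococcus_01")

  set.seed(derive_seed(p$seed, "pools"))
  cory_idx <- otus$clade == "Corynebacterium"
  mor_idx <- otus$clade == "Moraxella"
  mor_within <- geom_weights(sum(mor_idx), p$geom_ratio)
  comp <- list() # per sample true compositions
  meta <- list()
  cory_dom <- stats::setNames(logical(nsub), subj_id)
  mor_logit <- stats::setNames(numeric(nsub), subj_id)
  cory_logit <- stats::setNames(numeric(nsub), subj_id)
  for (si in seq_len(nsub)) {
    g <- groups[si]
    oral_s <- rdirichlet1(p$pool_conc * oral_base)
    lung_vec <- lung_base_common
    if (g == "AA") {
      lung_vec <- lung_vec * (1 - sum(p$lung_asthma_extra)) + lung_extra
    }
    lung_s <- rdirichlet1(p$pool_conc * lung_vec)
    # nasal pool: dominance + Moraxella structure
    dom <- stats::runif(1) < p$cory_dom_prob[[g]]
    cory_dom[si] <- dom
    nb_alpha <- nasal_base
    nb_alpha[cory_idx] <- nb_alpha[cory_idx] *
      (if (dom) p$cory_boost else p$cory_deflate)
    if (g == "AA") nb_alpha[staph_idx] <- nb_alpha[staph_idx] * p$da_fold
    m <- stats::rnorm(1, p$mor_logit_mean[[g]], p$mor_logit_sd[[g]])
    q_m <- stats::plogis(m)
    nb_alpha <- nb_alpha / sum(nb_alpha) * (1 - q_m)
    nb_alpha[mor_idx] <- q_m * mor_within
    nasal_s <- rdirichlet1(p$pool_conc * nb_alpha)
    mor_logit[si] <- stats::qlogis(max(sum(nasal_s[mor_idx]), 1e-6))
    cory_logit[si] <- stats::qlogis(max(sum(nasal_s[cory_idx]), 1e-6))

    bb <- p$f_oral * oral_s + p$f_nasal * nasal_s + p$f_lung * lung_s
    ow <- oral_s
    is_ <- p$f_sal * ow + (1 - p$f_sal) * bb
    site_comp <- list(BB = bb, IS = is_, OW = ow)
    if (has_nb[si]) site_comp$NB <- nasal_s
    for (s in names(site_comp)) {
      id <- paste0(subj_id[si], "_", s)
      comp[[id]] <- site_comp[[s]]
      meta[[id]] <- tibble::tibble(
        sample_id = id, subject_id = subj_id[si], site = s, group = g,
        squamous_pct = if (s == "IS") stats::runif(1, 0, 0.5) else NA_real_,
        is_control = FALSE
      )
    }
  }

  if (p$include_controls) {
    ctrl <- numeric(ntax)
    ctrl[otus$clade == "Ralstonia"] <- c(0.7, 0.3)
    comp[["CTRL1_OW"]] <- ctrl
    meta[["CTRL1_OW"]] <- tibble::tibble(
      sample_id = "CTRL1_OW", subject_id = "CTRL1", site = "OW",
      group = "HC", squamous_pct = NA_real_, is_control = TRUE
    )
  }

  set.seed(derive_seed(p$seed, "counts"))
  ids <- names(comp)
  counts <- matrix(0L, length(ids), ntax, dimnames = list(ids, otus$taxon))
  true_comp <- matrix(0, length(ids), ntax, dimnames = list(ids, otus$taxon))
  for (i in seq_along(ids)) {
    depth <- if (p$include_controls && meta[[ids[i]]]$is_control) {
      5000L
    } else {
      max(p$depth_floor, round(stats::rlnorm(1, p$depth_meanlog, p$depth_sdlog)))
    }
    pr <- rdirichlet1(p$dm_conc * comp[[ids[i]]])
    counts[i, ] <- stats::rmultinom(1, depth, pr)[, 1]
    true_comp[i, ] <- comp[[ids[i]]]
  }

  clinical <- simulate_clinical(
    subj_id, groups, mor_logit, cory_logit, p,
    seed = derive_seed(p$seed, "clinical")
  )

  bundle <- airway_bundle(
    counts, do.call(rbind, meta), taxonomy, tree, clinical
  )
  gt <- list(
    mixing = list(
      f_oral = p$f_oral, f_nasal = p$f_nasal, f_lung = p$f_lung,
      f_sal = p$f_sal
    ),
    pool_membership = tibble::tibble(
      taxon = otus$taxon, clade = otus$clade,
      oral = oral_base > 0, nasal = nasal_base > 0 | otus$clade == "Moraxella",
      lung = lung_base_common > 0
    ),
    cory_dominated = cory_dom,
    moraxella_logit = mor_logit,
    corynebacterium_logit = cory_logit,
    planted_slopes = tibble::tibble(
      variable = c("bal_eos_frac", "blood_eos_abs", "cyt_tnf",
                   "cyt_il6", "cyt_il7", "cyt_il21"),
      predictor = c(rep("logit nasal Moraxella", 3),
                    rep("logit nasal Corynebacterium", 3)),
      group = "AA",
      slope = c(p$eos_slope, p$eos_slope / 2, p$eos_slope / 2,
                rep(p$cyt_slope, 3)),
      noise_sd = c(p$eos_noise_sd, p$eos_noise_sd * 1.5, p$cyt_noise_sd,
                   rep(p$cyt_noise_sd, 3))
    ),
    da_taxa = tibble::tibble(
      taxon = "Staphylococcus_01", site = "NB", fold = p$da_fold,
      enriched_in = "AA"
    ),
    true_compositions = true_comp,
    seed = p$seed
  )
  list(bundle = bundle, ground_truth = gt)
}

simulate_clinical <- function(subj_id, groups, mor_logit, cory_logit, p, seed) {
  set.seed(seed)
  n <- length(subj_id)
  g <- groups
  aa <- g == "AA"
  zx <- (mor_logit - p$mor_logit_mean["AA"]) / p$mor_logit_sd["AA"]
  zc <- cory_logit - stats::median(cory_logit[aa])
  lnorm_by_group <- function(med, sdlog) {
    exp(stats::rnorm(n, log(med[g]), sdlog))
  }
  # planted links act in AA only; other groups draw independent noise
  link <- function(base_log, slope, z, sd) {
    ifelse(aa,
      exp(base_log + slope * z + stats::rnorm(n, 0, sd)),
      exp(base_log + stats::rnorm(n, 0, sqrt(slope^2 + sd^2)))
    )
  }
  pc20 <- ifelse(aa, pmin(exp(stats::rnorm(n, log(1.1), 0.8)), 32), 32)
  cl <- tibble::tibble(
    subject_id = subj_id, group = g,
    age = round(stats::runif(n, 24, 50)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    bmi = round(exp(stats::rnorm(n, log(26), 0.12)), 1),
    acq = ifelse(aa, round(stats::runif(n, 0.2, 1.2), 1), NA_real_),
    fev1_pre = round(stats::rnorm(n, c(AA = 86, ANA = 98, HC = 104)[g], 8)),
    fev1_post = NA_real_,
    fev1_change = round(ifelse(aa, stats::runif(n, 5, 16), stats::runif(n, 0, 6)), 1),
    pc20 = round(pc20, 2),
    pc20_censored = !aa | pc20 >= 32,
    ige = round(lnorm_by_group(c(AA = 169.5, ANA = 88.5, HC = 14), 0.8), 1),
    rhinitis = stats::rbinom(n, 1, c(AA = 0.55, ANA = 0.25, HC = 0)[g]),
    blood_neut_frac = stats::plogis(stats::rnorm(n, stats::qlogis(0.55), 0.2)),
    blood_eos_frac = stats::plogis(stats::rnorm(
      n, stats::qlogis(c(AA = 0.037, ANA = 0.02, HC = 0.018)[g]), 0.4
    )),
    blood_eos_abs = link(log(220), p$eos_slope / 2, zx, p$eos_noise_sd * 1.5),
    sputum_neut_frac = stats::plogis(stats::rnorm(n, stats::qlogis(0.45), 0.4)),
    sputum_eos_frac = stats::plogis(stats::rnorm(
      n, stats::qlogis(c(AA = 0.005, ANA = 0.001, HC = 0.001)[g]), 0.8
    )),
    bal_neut_frac = stats::plogis(stats::rnorm(n, stats::qlogis(0.03), 0.5)),
    bal_eos_frac = stats::plogis(ifelse(
      aa,
      stats::qlogis(0.02) + p$eos_slope * zx + stats::rnorm(n, 0, p$eos_noise_sd),
      stats::qlogis(0.02) +
        stats::rnorm(n, 0, sqrt(p$eos_slope^2 + p$eos_noise_sd^2))
    )),
    cyt_gmcsf = lnorm_by_group(c(AA = 349, ANA = 476, HC = 154), 0.6),
    cyt_il6 = link(log(100), p$cyt_slope, zc, p$cyt_noise_sd),
    cyt_il7 = link(log(0.9), p$cyt_slope, zc, p$cyt_noise_sd),
    cyt_il8 = lnorm_by_group(c(AA = 1407, ANA = 1311, HC = 953), 0.6),
    cyt_cxcl11 = link(log(400), p$eos_slope / 3, zx, p$cyt_noise_sd),
    cyt_mip1a = link(log(90), p$cyt_slope / 2, zc, p$cyt_noise_sd),
    cyt_mip1b = lnorm_by_group(c(AA = 317, ANA = 275, HC = 128), 0.6),
    cyt_mip3a = lnorm_by_group(c(AA = 390, ANA = 411, HC = 264), 0.8),
    cyt_tnf = link(log(65), p$eos_slope / 2, zx, p$cyt_noise_sd),
    cyt_il1b = exp(stats::rnorm(n, log(0.08), 1.5)),
    cyt_il21 = link(log(1.5), p$cyt_slope, zc, p$cyt_noise_sd * 1.2),
    cyt_il13 = exp(stats::rnorm(n, log(0.02), 1)),
    cyt_il17 = exp(stats::rnorm(n, log(0.015), 1))
  )
  cl$fev1_post <- cl$fev1_pre + cl$fev1_change
  # censor below the per-analyte limit of detection (below-LOD = NA)
  lod <- c(
    cyt_il7 = 0.3, cyt_il1b = 0.04, cyt_il21 = 0.04,
    cyt_il13 = 0.05, cyt_il17 = 0.05
  )
  for (a in names(lod)) cl[[a]][cl[[a]] < lod[[a]]] <- NA_real_
  for (a in grep("^cyt_", names(cl), value = TRUE)) {
    cl[[a]] <- round(cl[[a]], 3)
  }
  cl
}
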