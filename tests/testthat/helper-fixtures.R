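# Shared fixtures and independent oracles. Oracles deliberately use
# different machinery (phangorn descendant enumeration, ape node depths,
# direct hypergeometric sums) than the implementation they check.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Brute-force UniFrac by explicit per-edge descendant-set enumeration.
unifrac_oracle <- function(counts, tree, mode = "unweighted") {
  n <- nrow(counts)
  edge_tips <- lapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
    tree$tip.label[tips]
  })
  b <- tree$edge.length
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depth) <- tree$tip.label
  prop <- counts / rowSums(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (mode == "unweighted") {
        num <- 0
        den <- 0
        for (e in seq_along(edge_tips)) {
          labs <- intersect(edge_tips[[e]], colnames(counts))
          inA <- any(counts[i, labs] > 0)
          inB <- any(counts[j, labs] > 0)
          if (inA || inB) den <- den + b[e]
          if (xor(inA, inB)) num <- num + b[e]
        }
        d[i, j] <- if (den > 0) num / den else 0
      } else {
        num <- 0
        for (e in seq_along(edge_tips)) {
          labs <- intersect(edge_tips[[e]], colnames(counts))
          num <- num + b[e] * abs(sum(prop[i, labs]) - sum(prop[j, labs]))
        }
        den <- sum(depth[colnames(counts)] * (prop[i, ] + prop[j, ]))
        d[i, j] <- if (den > 0) num / den else 0
      }
    }
  }
  d
}

# Exact two-sided Fisher p by direct enumeration of all tables with the
# observed margins ("probability <= observed" rule).
fisher_oracle_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  c2 <- b + d
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(ks, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A tiny hand-built 4-sample bundle over the toy tree.
toy_bundle <- function() {
  counts <- rbind(
    S1_BB = c(A = 5L, B = 3L, C = 0L, D = 2L),
    S1_OW = c(A = 1L, B = 0L, C = 6L, D = 3L),
    S2_BB = c(A = 0L, B = 7L, C = 1L, D = 2L),
    S2_OW = c(A = 2L, B = 2L, C = 2L, D = 4L)
  )
  meta <- tibble::tibble(
    sample_id = rownames(counts),
    subject_id = rep(c("S1", "S2"), each = 2),
    site = rep(c("BB", "OW"), 2),
    group = rep(c("AA", "HC"), each = 2),
    squamous_pct = NA_real_, is_control = FALSE
  )
  taxonomy <- parse_gg_lineage(
    c("A", "B", "C", "D"),
    c(
      "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Prevotellaceae; g__Prevotella; s__",
      "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Prevotellaceae; g__Prevotella; s__",
      "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Neisseriales; f__Neisseriaceae; g__; s__",
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus; s__"
    )
  )
  clinical <- tibble::tibble(
    subject_id = c("S1", "S2"), group = c("AA", "HC"),
    age = c(30, 40), ige = c(150, 20)
  )
  airway_bundle(counts, meta, taxonomy, toy_tree(), clinical)
}

small_sim_params <- function(...) {
  # scaled-down cohort for fast structural tests
  args <- utils::modifyList(
    list(
      n_subjects = c(AA = 6L, ANA = 3L, HC = 3L),
      nb_subset = c(AA = 4L, ANA = 1L, HC = 2L),
      depth_meanlog = log(3000), depth_sdlog = 0.2, depth_floor = 2000L
    ),
    list(...)
  )
  do.call(sim_params, args)
}
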