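#' Default species tree for simulations
#'
#' An eight-taxon tree shaped like the fly phylogenies used for comparative
#' ORF analysis: a six-species ingroup clade (reference `dmel` plus five
#' relatives at increasing divergence) and two successively branching
#' outgroup lineages (`mdom`, `agam`). Having two *independently* branching
#' outgroups matters: de novo calls require support from at least two
#' distinct outgroup lineages. Branch lengths are in expected substitutions
#' per site.
#'
#' @return An `ape` phylo object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((((dmel:0.05,dsim:0.05):0.04,dyak:0.09):0.08,dana:0.17):0.08,",
    "dpse:0.25):0.15,dvir:0.40):0.35,mdom:0.60):0.25,agam:0.85);"))
}

.bases <- c("A", "C", "G", "T")

.random_nt <- function(n) sample(.bases, n, replace = TRUE)

# Random stop-free coding region of len_aa codons starting with ATG.
.random_orf_nt <- function(len_aa) {
  codons <- character(len_aa)
  codons[1] <- "ATG"
  i <- 2L
  while (i <= len_aa) {
    cd <- paste(sample(.bases, 3, replace = TRUE), collapse = "")
    if (!cd %in% .stop_codons) {
      codons[i] <- cd
      i <- i + 1L
    }
  }
  codons
}

.shuffle_codons <- function(codons) {
  if (length(codons) < 2L) return(codons)
  sample(codons)
}

# Substitutions + deletions along one branch, on a gapped character vector.
# orf_cols: columns of the coding span; when protect is TRUE the span is
# under purifying selection: its substitution rate is scaled down by
# coding_factor, substitutions creating stop codons are reverted, and
# deletions avoid the span (no frameshifts).
.evolve_branch <- function(chars, bl, sub_rate, del_rate, del_geom_p,
                           orf_cols, protect, coding_factor = 0.2) {
  n <- length(chars)
  live <- which(chars != "-")
  p_sub <- rep(0.75 * (1 - exp(-4 / 3 * bl * sub_rate)), length(live))
  if (protect && length(orf_cols)) {
    p_sub[live %in% orf_cols] <- 0.75 *
      (1 - exp(-4 / 3 * bl * sub_rate * coding_factor))
  }
  hit <- live[stats::runif(length(live)) < p_sub]
  for (i in hit) {
    chars[i] <- sample(setdiff(.bases, chars[i]), 1)
  }
  if (protect && length(orf_cols)) {
    # revert any stop codon created inside the protected span
    for (k in seq_len(length(orf_cols) %/% 3L)) {
      cols <- orf_cols[(3L * k - 2L):(3L * k)]
      if (any(chars[cols] == "-")) next
      if (paste(chars[cols], collapse = "") %in% .stop_codons) {
        chars[cols[3]] <- sample(setdiff(.bases, c(chars[cols[3]], "A", "G")), 1)
      }
    }
  }
  p_del <- bl * del_rate
  starts <- live[stats::runif(length(live)) < p_del]
  for (s in starts) {
    len <- 1L + stats::rgeom(1, del_geom_p)
    span <- s:min(n, s + len - 1L)
    if (protect && length(intersect(span, orf_cols))) next
    chars[span] <- "-"
  }
  chars
}

#' Simulate alignment blocks with planted evolutionary truth
#'
#' Generates, for each locus, a reference sequence carrying a planted ORF
#' (flanked by neutral sequence and a stop codon) and evolves it along the
#' species tree with per-branch substitutions (Jukes-Cantor-like) and
#' geometric-length deletions. Three per-locus scenarios are supported:
#'
#' * `conserved` - the ORF exists at the root and is protected (no nonsense
#'   substitutions or deletions in the coding span) in every lineage.
#' * `denovo` - the root carries a codon-shuffled, noncoding version of the
#'   ORF (alignable, same composition, no protein similarity); the coding
#'   version is born on the branch entering the origin clade and protected
#'   only within it. Outgroup lineages retain genomic homology without
#'   protein similarity - the signature of de novo birth.
#' * `loss` - as `conserved`, but on the terminal branches of
#'   `n_lost_leaves` randomly chosen non-reference ingroup species the
#'   coding span is codon-shuffled and two nonsense codons are planted
#'   (death by divergence).
#'
#' Deletions are the only indels, so alignment columns are stable and every
#' simulated block is a valid single-block alignment per locus.
#'
#' @param n_loci Number of loci (default 50).
#' @param tree Species tree (default [default_species_tree()]).
#' @param reference Reference species tip (default `"dmel"`).
#' @param scenarios Per-locus scenario vector, or a single scenario recycled,
#'   drawn from `c("conserved", "denovo", "loss")` (default `"conserved"`).
#' @param origin_clade Tips defining the clade where de novo loci are born
#'   (default the six-species ingroup).
#' @param orf_len_range Range of planted ORF lengths in residues
#'   (default 30-80).
#' @param flank_nt Neutral flanking sequence on each side (default 30).
#' @param sub_rate Substitution rate multiplier (default 1).
#' @param del_rate Per-site deletion initiation rate per unit branch length
#'   (default 0.02).
#' @param del_geom_p Geometric parameter for deletion lengths (default 0.5).
#' @param coding_factor Rate scaling of protected coding spans relative to
#'   the neutral rate (default 0.2), emulating purifying selection.
#' @param n_lost_leaves Leaves lost per `loss` locus (default 2).
#' @param seed Optional integer seed.
#' @return List with `blocks` (MAF-style block list, one per locus; the
#'   reference chromosome is the locus id), `tree`, `truth` (data frame:
#'   `locus`, `scenario`, `orf_start`, `orf_end`, `length_aa`,
#'   `lost_leaves`, `ref_aa`), and `reference`.
#' @export
simulate_msa_loci <- function(n_loci = 50L, tree = default_species_tree(),
                              reference = "dmel",
                              scenarios = "conserved",
                              origin_clade = c("dmel", "dsim", "dyak",
                                               "dana", "dpse", "dvir"),
                              orf_len_range = c(30L, 80L), flank_nt = 30L,
                              sub_rate = 1, del_rate = 0.02,
                              del_geom_p = 0.5, coding_factor = 0.2,
                              n_lost_leaves = 2L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), reference %in% tree$tip.label,
            all(origin_clade %in% tree$tip.label),
            reference %in% origin_clade)
  if (!is.null(seed)) set.seed(seed)
  scenarios <- rep_len(scenarios, n_loci)
  stopifnot(all(scenarios %in% c("conserved", "denovo", "loss")))
  origin_node <- .mrca_of(tree, origin_clade)
  in_clade_nodes <- {
    ntip <- length(tree$tip.label)
    nodes <- origin_node
    stack <- origin_node
    while (length(stack)) {
      kids <- .tree_children(tree, stack[[1]])
      stack <- c(stack[-1], kids[kids > ntip])
      nodes <- c(nodes, kids)
    }
    nodes
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  blocks <- list()
  truth <- list()
  for (lc in seq_len(n_loci)) {
    locus_id <- sprintf("locus%03d", lc)
    scen <- scenarios[lc]
    len_aa <- sample(orf_len_range[1]:orf_len_range[2], 1)
    coding <- .random_orf_nt(len_aa)
    orf_cols <- (flank_nt + 1L):(flank_nt + 3L * len_aa)
    root_codons <- if (scen == "denovo") .shuffle_codons(coding) else coding
    root_seq <- c(.random_nt(flank_nt), unlist(strsplit(root_codons, "")),
                  unlist(strsplit("TAA", "")), .random_nt(flank_nt))
    lost <- character(0)
    if (scen == "loss") {
      pool <- setdiff(origin_clade, reference)
      lost <- sample(pool, min(n_lost_leaves, length(pool)))
    }
    rows <- list()
    walk <- function(node, chars) {
      for (child in .tree_children(tree, node)) {
        bl <- tree$edge.length[which(tree$edge[, 2] == child)]
        child_chars <- chars
        born_here <- scen == "denovo" && child == origin_node
        if (born_here) {
          child_chars[orf_cols] <- unlist(strsplit(coding, ""))
        }
        protect <- switch(scen,
          conserved = TRUE,
          denovo = child %in% in_clade_nodes,
          loss = TRUE)
        is_lost_tip <- child <= ntip && tree$tip.label[child] %in% lost
        child_chars <- .evolve_branch(child_chars, bl, sub_rate, del_rate,
                                      del_geom_p, orf_cols,
                                      protect && !is_lost_tip, coding_factor)
        if (is_lost_tip) {
          live <- child_chars[orf_cols]
          gap <- live == "-"
          cd <- live[!gap]
          n_cd <- length(cd) %/% 3L
          if (n_cd >= 2L) {
            m <- matrix(cd[seq_len(3L * n_cd)], nrow = 3L)
            m <- m[, sample(n_cd), drop = FALSE]
            kill <- sample(n_cd, min(2L, n_cd))
            for (kk in kill) m[, kk] <- c("T", "A", "A")
            cd[seq_len(3L * n_cd)] <- as.vector(m)
          }
          live[!gap] <- cd
          child_chars[orf_cols] <- live
        }
        if (child <= ntip) {
          rows[[tree$tip.label[child]]] <<- child_chars
        } else {
          walk(child, child_chars)
        }
      }
    }
    walk(root, root_seq)
    species <- tree$tip.label
    texts <- vapply(species, function(sp) paste(rows[[sp]], collapse = ""),
                    character(1))
    sizes <- vapply(species, function(sp) sum(rows[[sp]] != "-"), integer(1))
    blocks[[lc]] <- list(score = 0, rows = data.frame(
      species = species,
      chrom = ifelse(species == reference, locus_id, "scaf"),
      start = 0L, size = sizes, strand = "+", src_size = sizes,
      text = texts, stringsAsFactors = FALSE))
    ref_chars <- rows[[reference]][orf_cols]
    ref_aa <- translate_frame(paste(ref_chars[ref_chars != "-"],
                                    collapse = ""), 0)
    truth[[lc]] <- data.frame(
      locus = locus_id, scenario = scen, orf_start = flank_nt,
      orf_end = flank_nt + 3L * len_aa, length_aa = len_aa,
      lost_leaves = paste(lost, collapse = ","), ref_aa = ref_aa,
      stringsAsFactors = FALSE)
  }
  list(blocks = blocks, tree = tree, truth = do.call(rbind, truth),
       reference = reference)
}

#' Simulate a peptide-spectrum match score table with planted labels
#'
#' True-target scores come from a shifted normal distribution; false-target
#' and decoy scores come from the same null normal, in equal numbers by
#' default so the decoys model the incorrect targets one-for-one (the
#' assumption behind target-decoy FDR estimation).
#'
#' @param n_true,n_false,n_decoy PSM counts (defaults 500/500/500).
#' @param true_mean Mean score of true targets (default 3.5).
#' @param null_mean,score_sd Null mean and common SD (defaults 0 and 1).
#' @param group_prefix Prefix for candidate group ids.
#' @param seed Optional integer seed.
#' @return List with `psms` (data frame: `peptide`, `score`, `is_decoy`,
#'   `parent_group`) and `truth` (logical per row: planted-true PSM).
#' @export
simulate_psm_table <- function(n_true = 500L, n_false = 500L,
                               n_decoy = 500L, true_mean = 3.5,
                               null_mean = 0, score_sd = 1,
                               group_prefix = "cand", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_true + n_false + n_decoy
  psms <- data.frame(
    peptide = sprintf("PEP%06d", seq_len(n)),
    score = c(stats::rnorm(n_true, true_mean, score_sd),
              stats::rnorm(n_false, null_mean, score_sd),
              stats::rnorm(n_decoy, null_mean, score_sd)),
    is_decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoy)),
    parent_group = c(sprintf("%s_t%05d", group_prefix, seq_len(n_true)),
                     sprintf("%s_f%05d", group_prefix, seq_len(n_false)),
                     sprintf("decoy%05d", seq_len(n_decoy))),
    stringsAsFactors = FALSE)
  list(psms = psms,
       truth = rep(c(TRUE, FALSE, FALSE), c(n_true, n_false, n_decoy)))
}

#' Default generating parameters for synthetic latent-class tables
#'
#' Builds a well-separated K-class parameter set over `J` three-level
#' indicators: class `k` concentrates indicator `j` on level
#' `1 + (k + j) mod 3` with probability `sep`, the rest spread evenly.
#'
#' @param K Number of classes.
#' @param J Number of indicators (default 5).
#' @param sep Concentration of the favored level (default 0.7).
#' @param pi Mixing proportions (default uniform).
#' @return List with `K`, `pi`, `rho` (list of K x 3 matrices).
#' @export
default_lca_params <- function(K, J = 5L, sep = 0.7, pi = rep(1 / K, K)) {
  stopifnot(K >= 1L, abs(sum(pi) - 1) < 1e-8, length(pi) == K)
  rho <- lapply(seq_len(J), function(j) {
    m <- matrix((1 - sep) / 2, K, 3)
    for (k in seq_len(K)) m[k, 1L + (k + j) %% 3L] <- sep
    m
  })
  list(K = K, pi = pi, rho = rho)
}

#' Simulate a categorical table from a latent class model
#'
#' @param n Number of rows.
#' @param params Generating parameters (`K`, `pi`, `rho`), e.g. from
#'   [default_lca_params()].
#' @param seed Optional integer seed.
#' @return List with `table` (data frame of factors) and `classes` (integer
#'   vector of true class labels).
#' @export
simulate_lca_table <- function(n, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  z <- sample.int(K, n, replace = TRUE, prob = params$pi)
  cols <- lapply(seq_along(params$rho), function(j) {
    m <- params$rho[[j]]
    L <- ncol(m)
    lev <- paste0("l", seq_len(L))
    vapply(z, function(k) sample(lev, 1, prob = m[k, ]), character(1))
  })
  names(cols) <- paste0("ind", seq_along(cols))
  tab <- as.data.frame(lapply(cols, factor), stringsAsFactors = TRUE)
  list(table = tab, classes = z)
}

#' Simulate an expression matrix with planted specificity
#'
#' Loci are planted as `onehot` (expressed in a single sample, tau = 1),
#' `uniform` (equal expression, tau = 0) or `noisy` (random profile with a
#' recorded realized tau).
#'
#' @param n_loci Number of loci (default 300).
#' @param n_samples Number of samples (default 10).
#' @param type_probs Probabilities of the three profile types, in the order
#'   onehot / uniform / noisy (default 0.3/0.3/0.4).
#' @param base_tpm Expression level of expressed samples (default 10).
#' @param seed Optional integer seed.
#' @return List with `mat` (TPM matrix with sample column names) and `truth`
#'   (data frame: `type`, `true_tau`).
#' @export
simulate_expression <- function(n_loci = 300L, n_samples = 10L,
                                type_probs = c(0.3, 0.3, 0.4),
                                base_tpm = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- sample(c("onehot", "uniform", "noisy"), n_loci, replace = TRUE,
                  prob = type_probs)
  mat <- matrix(0, n_loci, n_samples,
                dimnames = list(sprintf("locus%03d", seq_len(n_loci)),
                                sprintf("sample%02d", seq_len(n_samples))))
  for (i in seq_len(n_loci)) {
    mat[i, ] <- switch(types[i],
      onehot = {
        v <- numeric(n_samples)
        v[sample(n_samples, 1)] <- base_tpm
        v
      },
      uniform = rep(base_tpm, n_samples),
      noisy = stats::rexp(n_samples, 1 / base_tpm))
  }
  true_tau <- apply(mat, 1, tau)
  list(mat = mat, truth = data.frame(type = types, true_tau = true_tau,
                                     stringsAsFactors = FALSE))
}

#' Simulate ribosome footprint frame counts with planted bias
#'
#' Each locus receives a Poisson number of footprints (pooled across
#' replicates and read lengths); each footprint falls in the locus frame
#' with probability `p` and otherwise uniformly in the other two frames.
#'
#' @param n_loci Number of loci (default 1000).
#' @param p Probability of the locus frame (1/3 = no framing, the null).
#' @param depth_mean Mean footprint count per locus (default 100).
#' @param seed Optional integer seed.
#' @return List with `counts` (data frame `n0`, `n1`, `n2`, `n_unique`) and
#'   `p`.
#' @export
simulate_footprints <- function(n_loci = 1000L, p = 1 / 3,
                                depth_mean = 100, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(n_loci, depth_mean)
  n0 <- stats::rbinom(n_loci, n, p)
  n1 <- stats::rbinom(n_loci, n - n0, 0.5)
  counts <- data.frame(n0 = n0, n1 = n1, n2 = n - n0 - n1, n_unique = n)
  list(counts = counts, p = p)
}
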