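# Tree helpers (ape "phylo" objects). Node numbering follows ape: tips are
# 1..Ntip, the root is Ntip + 1.

.tree_parents <- function(tree) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

.tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

# All ancestors of a node (including the node itself), tip-to-root.
.ancestors_inclusive <- function(tree, node) {
  parent <- .tree_parents(tree)
  root <- length(tree$tip.label) + 1L
  path <- node
  while (node != root) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

.tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    kids <- .tree_children(tree, v)
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[tips]
}

.mrca_of <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(unique(idx)) == 1L) return(idx[1])
  ape::getMRCA(tree, unique(idx))
}

#' Infer the phylostratigraphic age of a locus
#'
#' The inferred origin of a locus is the last common ancestor of the
#' reference species and the most distantly related species with a
#' significant protein similarity score (score strictly greater than
#' `threshold`). When no species other than the reference is significant the
#' origin is the reference-specific stratum (the reference tip itself).
#'
#' @param profile Data frame with columns `species`, `score` and
#'   `homology_flag` (`NA` allowed for missing data).
#' @param tree Rooted `phylo` species tree.
#' @param reference Reference species (a tip label).
#' @param threshold Significance threshold in score points (default 2.5).
#' @return List of class `age_call`: `reference`, `origin_node` (ape node
#'   id; equals the reference tip for reference-specific loci),
#'   `stratum_rank` (0 = reference-specific, increasing toward the root),
#'   `most_distant_significant`, `significant_species`.
#' @export
infer_age <- function(profile, tree, reference, threshold = 2.5) {
  stopifnot(reference %in% tree$tip.label,
            all(c("species", "score") %in% names(profile)))
  if (!reference %in% profile$species ||
      is.na(profile$score[profile$species == reference])) {
    stop("reference species must have a defined score")
  }
  if (all(is.na(profile$score))) stop("no scores defined")
  sig <- profile$species[!is.na(profile$score) & profile$score > threshold]
  sig <- union(intersect(sig, tree$tip.label), reference)
  ref_tip <- match(reference, tree$tip.label)
  ref_path <- .ancestors_inclusive(tree, ref_tip)
  if (length(sig) == 1L) {
    out <- list(reference = reference, origin_node = ref_tip,
                stratum_rank = 0L,
                most_distant_significant = reference,
                significant_species = sig)
    class(out) <- "age_call"
    return(out)
  }
  origin <- .mrca_of(tree, sig)
  # deepest-diverging significant species: the one whose LCA with the
  # reference sits farthest up the reference's root path
  others <- setdiff(sig, reference)
  ranks <- vapply(others, function(sp) {
    match(.mrca_of(tree, c(reference, sp)), ref_path) - 1L
  }, integer(1))
  out <- list(reference = reference, origin_node = origin,
              stratum_rank = match(origin, ref_path) - 1L,
              most_distant_significant = others[which.max(ranks)],
              significant_species = sig)
  class(out) <- "age_call"
  out
}

#' Test whether significant species form a monophyletic group
#'
#' TRUE iff the significant species are exactly the data-bearing tips of the
#' subtree rooted at their last common ancestor. Tips without data cannot
#' break monophyly.
#'
#' @param significant_leaves Character vector of tip labels (must include the
#'   reference species, and be nonempty).
#' @param tree Rooted `phylo` tree.
#' @param data_bearing Tips with observed data (default: all tips).
#' @return Logical.
#' @export
is_monophyletic <- function(significant_leaves, tree,
                            data_bearing = tree$tip.label) {
  if (length(significant_leaves) == 0L) stop("empty significant set")
  if (length(significant_leaves) == 1L) return(TRUE)
  node <- .mrca_of(tree, significant_leaves)
  under <- intersect(.tip_descendants(tree, node), data_bearing)
  setequal(under, significant_leaves)
}

#' Call potential de novo origin for a locus
#'
#' A locus is called potentially de novo when enough outgroup species
#' (relative to the inferred origin clade) carry genomic homology at the
#' locus yet score below the protein similarity threshold: the ancestral
#' sequence existed but was not coding for a similar protein. Requiring
#' supporting outgroups from several independently branching outgroup
#' lineages guards against a single homology-detection failure.
#'
#' @param profile Data frame with `species`, `score`, `homology_flag`.
#' @param age An `age_call` from [infer_age()] (same threshold).
#' @param tree Rooted `phylo` tree.
#' @param threshold Similarity threshold (default 2.5).
#' @param min_outgroups Minimum number of supporting outgroup species
#'   (default 2).
#' @param min_clades Minimum number of distinct first-branching outgroup
#'   lineages the supporters must span (default 2).
#' @return List of class `de_novo_call`: `is_de_novo`,
#'   `supporting_outgroups`, `n_supporting`, `n_distinct_clades`.
#' @export
call_de_novo <- function(profile, age, tree, threshold = 2.5,
                         min_outgroups = 2L, min_clades = 2L) {
  stopifnot(inherits(age, "age_call"))
  in_clade <- .tip_descendants(tree, age$origin_node)
  outgroups <- setdiff(tree$tip.label, in_clade)
  p <- profile[match(outgroups, profile$species), , drop = FALSE]
  supp <- outgroups[!is.na(p$homology_flag) & p$homology_flag &
                      !is.na(p$score) & p$score < threshold]
  ref_tip <- match(age$reference, tree$tip.label)
  ref_path <- .ancestors_inclusive(tree, ref_tip)
  lineage <- vapply(supp, function(sp) {
    # walk up from the supporting tip until the reference root-path is hit;
    # the node just below the junction identifies the outgroup lineage
    v <- match(sp, tree$tip.label)
    parent <- .tree_parents(tree)
    while (!parent[v] %in% ref_path) v <- parent[v]
    v
  }, integer(1))
  n_clades <- length(unique(lineage))
  out <- list(is_de_novo = length(supp) >= min_outgroups &&
                n_clades >= min_clades,
              supporting_outgroups = supp,
              n_supporting = length(supp),
              n_distinct_clades = n_clades)
  class(out) <- "de_novo_call"
  out
}

#' Count inferred losses after origin (Dollo parsimony)
#'
#' Among species descended from the origin stratum (excluding the reference),
#' a species is *lost* when it has genomic homology but a similarity score
#' below the threshold, *present* when its score exceeds the threshold, and
#' *unknown* otherwise (missing data never forces an event). Under Dollo
#' parsimony (single origin, losses only) the minimum number of loss events
#' equals the number of maximal subtrees whose data-bearing leaves are all
#' lost.
#'
#' @param profile Data frame with `species`, `score`, `homology_flag`.
#' @param origin_node Origin node (from [infer_age()]).
#' @param tree Rooted `phylo` tree.
#' @param reference Reference species.
#' @param threshold Similarity threshold (default 2.5).
#' @return List of class `loss_count`: `n_losses`, `lost_leaf_sets` (list of
#'   character vectors, disjoint, union = all lost leaves), `status` (named
#'   character vector over considered species).
#' @export
count_losses <- function(profile, origin_node, tree, reference,
                         threshold = 2.5) {
  ref_tip <- match(reference, tree$tip.label)
  if (is.na(ref_tip)) stop("reference not in tree")
  if (!origin_node %in% .ancestors_inclusive(tree, ref_tip)) {
    stop("origin_node is not an ancestor of the reference")
  }
  leaves <- setdiff(.tip_descendants(tree, origin_node), reference)
  status <- vapply(leaves, function(sp) {
    i <- match(sp, profile$species)
    if (is.na(i)) return("unknown")
    sc <- profile$score[i]
    hm <- profile$homology_flag[i]
    if (!is.na(sc) && sc > threshold) return("present")
    if (!is.na(sc) && !is.na(hm) && hm && sc < threshold) return("lost")
    "unknown"
  }, character(1))
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      if (lab == reference) return(list(state = "present", sets = list()))
      st <- status[[lab]]
      if (identical(st, "lost")) {
        return(list(state = "lost", sets = list(lab)))
      }
      return(list(state = if (identical(st, "present")) "present" else "vacuous",
                  sets = list()))
    }
    kids <- lapply(.tree_children(tree, node), rec)
    states <- vapply(kids, `[[`, character(1), "state")
    if (all(states == "vacuous")) return(list(state = "vacuous", sets = list()))
    if (all(states %in% c("lost", "vacuous"))) {
      merged <- unlist(lapply(kids[states == "lost"], function(k) unlist(k$sets)))
      return(list(state = "lost", sets = list(merged)))
    }
    sets <- list()
    for (k in kids) {
      if (k$state == "lost") {
        sets <- c(sets, list(unlist(k$sets)))   # a maximal lost subtree
      } else {
        sets <- c(sets, k$sets)                 # already-finalized events
      }
    }
    list(state = "mixed", sets = sets)
  }
  top <- rec(origin_node)
  sets <- if (top$state == "lost") list(unlist(top$sets)) else top$sets
  out <- list(n_losses = length(sets), lost_leaf_sets = sets, status = status)
  class(out) <- "loss_count"
  out
}

#' Length-matched empirical percentiles with Fisher combination
#'
#' For each locus, draws `n_draws` control loci of identical or similar
#' length without replacement and computes the midrank empirical percentile
#' of the locus metric among the drawn controls (floored at
#' `1 / (n_draws + 1)`, the add-one estimator, so that extreme loci get a
#' finite p-value). Per-locus p-values are combined with Fisher's method:
#' \eqn{-2 \sum \ln p} compared to a chi-square with `2k` degrees of freedom.
#' When a length bin holds fewer than `n_draws` controls the tolerance is
#' widened over the schedule 0, 1, 2, 5, 10, 20, 50 length units before
#' failing.
#'
#' @param values Numeric per-locus metric.
#' @param value_lengths Integer lengths of the loci.
#' @param control_values Numeric metric over the control pool.
#' @param control_lengths Integer lengths of the control pool.
#' @param n_draws Controls drawn per locus (default 250).
#' @param seed Optional integer seed.
#' @return List with `per_locus_p`, `statistic`, `df`, `combined_p`.
#' @export
empirical_percentile_fisher <- function(values, value_lengths,
                                        control_values, control_lengths,
                                        n_draws = 250L, seed = NULL) {
  stopifnot(length(values) == length(value_lengths),
            length(control_values) == length(control_lengths))
  if (!is.null(seed)) set.seed(seed)
  schedule <- c(0L, 1L, 2L, 5L, 10L, 20L, 50L)
  per_p <- vapply(seq_along(values), function(i) {
    pool <- integer(0)
    for (tol in schedule) {
      pool <- which(abs(control_lengths - value_lengths[i]) <= tol)
      if (length(pool) >= n_draws) break
    }
    if (length(pool) < n_draws) {
      stop("insufficient length-matched controls for locus ", i)
    }
    draws <- control_values[sample(pool, n_draws)]
    p <- (sum(draws < values[i]) + 0.5 * sum(draws == values[i])) / n_draws
    max(p, 1 / (n_draws + 1))
  }, numeric(1))
  stat <- -2 * sum(log(per_p))
  df <- 2L * length(per_p)
  list(per_locus_p = per_p, statistic = stat, df = df,
       combined_p = stats::pchisq(stat, df, lower.tail = FALSE))
}
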