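# Eight-leaf test tree matching the simulator's default topology.
test_tree <- function() default_species_tree()

profile_from <- function(tree, sig, hom = tree$tip.label, missing = NULL) {
  sp <- tree$tip.label
  data.frame(species = sp,
             score = ifelse(sp %in% missing, NA_real_,
                            ifelse(sp %in% sig, 4, 1)),
             homology_flag = ifelse(sp %in% missing, NA, sp %in% hom),
             stringsAsFactors = FALSE)
}

test_that("age inference walks to the deepest significant divergence", {
  tree <- test_tree()
  # reference-only significance: reference-specific stratum
  p0 <- profile_from(tree, "dmel")
  a0 <- infer_age(p0, tree, "dmel")
  expect_equal(a0$stratum_rank, 0L)
  expect_equal(a0$most_distant_significant, "dmel")
  # significance everywhere: root stratum
  pall <- profile_from(tree, tree$tip.label)
  aall <- infer_age(pall, tree, "dmel")
  expect_equal(aall$origin_node, length(tree$tip.label) + 1L)
  # reference plus one distant leaf: LCA oracle via ape
  p1 <- profile_from(tree, c("dmel", "mdom"))
  a1 <- infer_age(p1, tree, "dmel")
  expect_equal(a1$origin_node, ape::getMRCA(tree, c("dmel", "mdom")))
  expect_equal(a1$most_distant_significant, "mdom")
  expect_error(infer_age(profile_from(tree, "x", missing = tree$tip.label),
                         tree, "dmel"), "defined score")
})

test_that("age is monotone in the significant set and threshold-robust", {
  tree <- test_tree()
  sets <- list(c("dmel"), c("dmel", "dsim"), c("dmel", "dsim", "dana"),
               c("dmel", "dsim", "dana", "agam"))
  ranks <- vapply(sets, function(s) {
    infer_age(profile_from(tree, s), tree, "dmel")$stratum_rank
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
  # thresholds that do not cross any species score leave the call unchanged
  p <- profile_from(tree, c("dmel", "dana"))
  for (thr in c(1.5, 2.5, 3.5)) {
    expect_equal(infer_age(p, tree, "dmel", threshold = thr)$origin_node,
                 infer_age(p, tree, "dmel", threshold = 2.5)$origin_node)
  }
})

test_that("monophyly compares against data-bearing subtree leaves", {
  tree <- test_tree()
  expect_true(is_monophyletic("dmel", tree))
  expect_true(is_monophyletic(tree$tip.label, tree))
  expect_true(is_monophyletic(c("dmel", "dsim"), tree))
  # skipping an intermediate data-bearing leaf breaks monophyly
  expect_false(is_monophyletic(c("dmel", "dyak"), tree))
  # ... but not if that leaf carries no data
  expect_true(is_monophyletic(c("dmel", "dyak"), tree,
                              data_bearing = setdiff(tree$tip.label, "dsim")))
  expect_error(is_monophyletic(character(0), tree), "empty")
})

test_that("de novo calls require homologous nonsignificant outgroups in two lineages", {
  tree <- test_tree()
  # ingroup clade = dmel..dvir; outgroups mdom (lineage 1), agam (lineage 2)
  sig <- c("dmel", "dsim", "dyak", "dana", "dpse", "dvir")
  p <- profile_from(tree, sig)
  age <- infer_age(p, tree, "dmel")
  dn <- call_de_novo(p, age, tree)
  expect_true(dn$is_de_novo)
  expect_equal(dn$n_supporting, 2L)
  expect_equal(dn$n_distinct_clades, 2L)
  # outgroups without genomic homology cannot support the call
  p_nohom <- profile_from(tree, sig, hom = sig)
  expect_false(call_de_novo(p_nohom, age, tree)$is_de_novo)
  # significant outgroups argue against de novo origin
  p_sig <- profile_from(tree, tree$tip.label)
  age_all <- infer_age(p_sig, tree, "dmel")
  dn_all <- call_de_novo(p_sig, age_all, tree)
  expect_false(dn_all$is_de_novo)
  expect_equal(dn_all$n_supporting, 0L)
  # one supporting outgroup is not enough
  p_one <- profile_from(tree, sig, hom = c(sig, "mdom"))
  expect_false(call_de_novo(p_one, age, tree)$is_de_novo)
})

test_that("loss counting matches exhaustive subtree-cover search", {
  tree <- test_tree()
  root <- length(tree$tip.label) + 1L
  # all descendants significant: no losses
  pall <- profile_from(tree, tree$tip.label)
  expect_equal(count_losses(pall, root, tree, "dmel")$n_losses, 0L)
  # exactly one lost leaf
  p1 <- profile_from(tree, setdiff(tree$tip.label, "dyak"))
  l1 <- count_losses(p1, root, tree, "dmel")
  expect_equal(l1$n_losses, 1L)
  expect_equal(l1$lost_leaf_sets[[1]], "dyak")
  # two lost sister leaves merge into a single Dollo event
  p2 <- profile_from(tree, setdiff(tree$tip.label, c("mdom", "agam")))
  # mdom and agam are successive outgroups, not sisters: two events
  expect_equal(count_losses(p2, root, tree, "dmel")$n_losses, 2L)
  expect_error(count_losses(pall, match("agam", tree$tip.label) , tree,
                            "dmel"), "ancestor")
  # randomized equivalence against the exhaustive cover oracle
  set.seed(330)
  non_ref <- setdiff(tree$tip.label, "dmel")
  for (i in 1:200) {
    status <- setNames(sample(c("lost", "present", "unknown"),
                              length(non_ref), replace = TRUE), non_ref)
    prof <- data.frame(
      species = c("dmel", non_ref),
      score = c(4, ifelse(status == "present", 4,
                          ifelse(status == "lost", 1, NA))),
      homology_flag = c(TRUE, ifelse(status == "unknown", NA, TRUE)),
      stringsAsFactors = FALSE)
    got <- count_losses(prof, root, tree, "dmel")$n_losses
    want <- oracle_min_losses(tree, root, "dmel", status)
    expect_equal(got, want, info = paste(status, collapse = ","))
  }
})

test_that("length-matched empirical percentiles follow the midrank convention", {
  # locus equal to all controls: midrank 0.5
  r <- empirical_percentile_fisher(5, 30, rep(5, 300), rep(30, 300),
                                   n_draws = 250, seed = 1)
  expect_equal(r$per_locus_p, 0.5)
  # locus below every control: add-one floor
  r2 <- empirical_percentile_fisher(0, 30, rep(5, 300), rep(30, 300),
                                    n_draws = 250, seed = 1)
  expect_equal(r2$per_locus_p, 1 / 251)
  # Fisher combination of two p = 0.5
  r3 <- empirical_percentile_fisher(c(5, 5), c(30, 30),
                                    rep(5, 600), rep(30, 600),
                                    n_draws = 250, seed = 1)
  expect_equal(r3$statistic, -2 * log(0.25), tolerance = 1e-10)
  expect_equal(r3$combined_p, exp(-r3$statistic / 2) * (1 + r3$statistic / 2),
               tolerance = 1e-10)
  expect_equal(round(r3$combined_p, 3), 0.597)
  # insufficient controls even after widening
  expect_error(empirical_percentile_fisher(5, 30, rep(5, 10), rep(30, 10)),
               "insufficient")
})
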