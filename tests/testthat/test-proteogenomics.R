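test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_setequal(tryptic_digest("MKR", max_missed = 0, min_len = 1)$peptide,
                  c("MK", "R"))
  expect_equal(tryptic_digest("MKPR", max_missed = 0, min_len = 1)$peptide,
               "MKPR")
  expect_error(tryptic_digest("MKB"), "invalid residue")
})

test_that("digestion equals brute-force enumeration over cleavage subsets", {
  set.seed(310)
  prot <- random_protein(50)
  got <- tryptic_digest(prot, max_missed = 2, min_len = 7)
  # oracle: locate cleavage sites, then enumerate all consecutive runs of
  # 1..3 fragments directly from the site list
  res <- strsplit(prot, "")[[1]]
  n <- length(res)
  sites <- which(res %in% c("K", "R") & c(res[-1], "") != "P" & seq_len(n) < n)
  bounds <- c(0, sites, n)
  want <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(i + 2, length(bounds) - 1)) {
      pep <- substr(prot, bounds[i] + 1, bounds[j + 1])
      if (nchar(pep) >= 7) want <- c(want, pep)
    }
  }
  expect_setequal(got$peptide, want)
  # missed-cleavage supersets
  p1 <- tryptic_digest(prot, max_missed = 1, min_len = 7)$peptide
  p2 <- tryptic_digest(prot, max_missed = 2, min_len = 7)$peptide
  expect_true(all(p1 %in% p2))
})

test_that("trie queries match linear-scan distance oracles", {
  tr <- build_trie("PEPTIDE")
  expect_equal(min_distance("PEPTIDE", tr, "levenshtein", 2), 0L)
  expect_equal(min_distance("AAAC", build_trie("AAAA"), "hamming", 2), 1L)
  expect_equal(min_distance("AAA", build_trie("AAAA"), "levenshtein", 2), 1L)
  expect_identical(min_distance("AAA", build_trie(character(0)),
                                "levenshtein", 2), Inf)
  set.seed(311)
  members <- vapply(1:200, function(i) random_protein(sample(7:12, 1)),
                    character(1))
  idx <- build_trie(members)
  expect_equal(idx$size, length(unique(members)))
  for (q in vapply(1:50, function(i) random_protein(sample(7:12, 1)),
                   character(1))) {
    expect_equal(min_distance(q, idx, "levenshtein", 3),
                 oracle_levenshtein_min(q, members, 3))
    expect_equal(min_distance(q, idx, "hamming", 3),
                 oracle_hamming_min(q, members, 3))
  }
  # membership iff distance zero
  expect_equal(min_distance(members[5], idx, "levenshtein", 3), 0L)
})

test_that("target-decoy FDR matches hand enumeration and threshold sweep", {
  ps <- data.frame(score = c(10, 9, 8, 7, 8.5, 6),
                   is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  r <- estimate_fdr(ps, alpha = 0.5)
  expect_equal(r$psms$fdr[r$psms$score == 8], 1 / 3)
  # no decoys -> all q-values zero
  clean <- estimate_fdr(data.frame(score = 1:5, is_decoy = FALSE))
  expect_true(all(clean$psms$qvalue == 0))
  expect_error(estimate_fdr(data.frame(score = 1, is_decoy = TRUE)),
               "no target")
  set.seed(312)
  big <- data.frame(score = round(rnorm(300), 2),
                    is_decoy = sample(c(TRUE, FALSE), 300, TRUE))
  rb <- estimate_fdr(big)
  expect_equal(rb$psms$qvalue,
               oracle_qvalues(big$score, big$is_decoy))
  # q-values monotone non-increasing in score
  ord <- order(big$score)
  expect_true(all(diff(rb$psms$qvalue[ord]) <= 1e-12))
  # nested acceptance across alpha
  a1 <- estimate_fdr(big, alpha = 0.1)$accepted
  a2 <- estimate_fdr(big, alpha = 0.3)$accepted
  expect_true(all(which(a1) %in% which(a2)))
})

test_that("two-round selection handles clean and degenerate inputs", {
  # no decoys anywhere: every candidate passes
  r1 <- data.frame(peptide = paste0("P", 1:4), score = c(5, 6, 7, 8),
                   is_decoy = FALSE,
                   parent_group = c("candA", "candB", "ann1", "candC"))
  cands <- c("candA", "candB", "candC")
  got <- two_round_select(r1, cands, r1, fdr1 = 0.2, fdr2 = 0.01)
  expect_setequal(got$accepted, cands)
  # empty round-1 survivors: decoys dominate -> empty final set
  bad1 <- data.frame(peptide = "P", score = c(1, 9, 9.5),
                     is_decoy = c(FALSE, TRUE, TRUE),
                     parent_group = c("candA", "d1", "d2"))
  r2 <- bad1[bad1$is_decoy, ]
  expect_length(two_round_select(bad1, "candA", r2,
                                 fdr1 = 0.2, fdr2 = 0.01)$accepted, 0)
  # round 2 referencing a non-survivor is a consistency error
  ref_bad <- data.frame(peptide = "P", score = 9, is_decoy = FALSE,
                        parent_group = "candZ")
  expect_error(two_round_select(r1, c(cands, "candZ"), ref_bad),
               "non-survivor")
  expect_error(two_round_select(r1, cands, r1, fdr1 = 0.01, fdr2 = 0.2),
               "must not exceed")
})

test_that("single-round FDR is calibrated on planted mixtures", {
  realized <- vapply(1:20, function(s) {
    sim <- simulate_psm_table(n_true = 800, n_false = 800, n_decoy = 800,
                              seed = 4000 + s)
    r <- estimate_fdr(sim$psms, alpha = 0.01)
    acc <- which(r$accepted)
    c(mean(!sim$truth[acc]), length(acc))
  }, numeric(2))
  mean_fdr <- mean(realized[1, ])
  n_per_seed <- mean(realized[2, ])
  ci <- stats::qbinom(c(0.025, 0.975), round(n_per_seed), 0.01) /
    round(n_per_seed)
  expect_gte(mean_fdr, ci[1])
  expect_lte(mean_fdr, ci[2])
})

test_that("curation drops short and homologous candidates, keeps longest per group", {
  cands <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    length_aa = c(13, 50, 20, 30, 40),
    homology_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    protein_group = c("g1", "g2", "g3", "g3", "g4"))
  kept <- curate(cands)
  expect_setequal(kept$id, c("d", "e"))   # a: short, b: homologous, c < d
  expect_equal(kept$length_aa[kept$protein_group == "g3"], 30)
})

test_that("retention-time support uses the annotated 95th percentile", {
  set.seed(313)
  ann <- data.frame(observed_rt = runif(200, 0, 100))
  ann$predicted_rt <- ann$observed_rt + rnorm(200, 0, 2)
  ut <- data.frame(peptide = c("P1", "P2", "P3"),
                   observed_rt = c(50, 50, 50),
                   predicted_rt = c(50, 49, -50))
  r <- rt_support(ann, ut)
  deltas <- abs(ann$observed_rt - ann$predicted_rt)
  expect_equal(r$threshold, unname(quantile(deltas, 0.95, type = 7)))
  expect_true("P1" %in% r$supported)            # delta 0
  expect_false("P3" %in% r$supported)           # larger than every annotated
  expect_error(rt_support(ann[0, ], ut), "no annotated")
})
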