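test_that("length and start rules filter spans", {
  expect_equal(nrow(enumerate_potential_orfs(c(r = "ACGACG"))), 0L)
  o <- enumerate_potential_orfs(c(r = "ATGTAAATG"), min_len = 1,
                                min_len_no_start = 1)
  plus1 <- o[o$frame == 1L, ]
  expect_equal(plus1$aa_sequence, c("M", "M"))
  expect_equal(plus1$start, c(0L, 6L))
  # a 19-residue start-less span is dropped, a 20-residue one kept
  no_m <- paste(rep("GCT", 20), collapse = "")          # 20 alanines
  o20 <- enumerate_potential_orfs(setNames(c(no_m), "r"))
  expect_true(any(o20$frame == 1L & o20$length_aa == 20L))
  o19 <- enumerate_potential_orfs(c(r = paste(rep("GCT", 19), collapse = "")))
  expect_false(any(o19$frame == 1L))
})

test_that("enumeration matches a brute-force frame-scan oracle", {
  set.seed(300)
  for (rep in 1:3) {
    seq <- random_dna(300)
    got <- enumerate_potential_orfs(c(chr = seq), min_len = 3,
                                    min_len_no_start = 5)
    want <- oracle_orfs(seq, min_len = 3, min_len_no_start = 5)
    key <- function(d) sort(paste(d$aa_sequence, d$frame, d$start, d$end))
    expect_equal(key(got), key(want))
  }
})

test_that("masked and ambiguous codons break spans", {
  # lowercase base inside an otherwise clean run splits it
  s <- paste0(paste(rep("GCT", 10), collapse = ""), "gct",
              paste(rep("GCT", 10), collapse = ""))
  o <- enumerate_potential_orfs(c(r = s), min_len = 1, min_len_no_start = 1)
  f1 <- o[o$frame == 1L, ]
  expect_equal(sort(f1$length_aa), c(10L, 10L))
  sN <- paste0(paste(rep("GCT", 10), collapse = ""), "GNT",
               paste(rep("GCT", 10), collapse = ""))
  oN <- enumerate_potential_orfs(c(r = sN), min_len = 1, min_len_no_start = 1)
  expect_equal(sort(oN[oN$frame == 1L, "length_aa"]), c(10L, 10L))
  expect_error(enumerate_potential_orfs(c(r = "ACGU")), "invalid nucleotide")
})

test_that("reported ORFs re-translate from their intervals (round trip)", {
  set.seed(301)
  seq <- random_dna(400)
  o <- enumerate_potential_orfs(c(chr = seq), min_len = 2,
                                min_len_no_start = 4)
  expect_gt(nrow(o), 0)
  for (i in seq_len(nrow(o))) {
    nt <- substr(seq, o$start[i] + 1L, o$end[i])
    if (o$strand[i] == "-") {
      nt <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             no.init.codon = TRUE))
    expect_identical(aa, o$aa_sequence[i])
    expect_equal(o$end[i] - o$start[i], 3L * o$length_aa[i])
  }
  expect_false(any(grepl("\\*", o$aa_sequence)))
})

test_that("catalogue is symmetric under reverse complement", {
  set.seed(302)
  seq <- random_dna(300)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  a <- enumerate_potential_orfs(c(chr = seq), min_len = 2, min_len_no_start = 4)
  b <- enumerate_potential_orfs(c(chr = rc), min_len = 2, min_len_no_start = 4)
  expect_equal(sort(a$aa_sequence), sort(b$aa_sequence))
  # frames map +k <-> -k
  expect_equal(sort(a$frame), sort(-b$frame))
})

test_that("deduplication preserves occurrences and counts unique sequences", {
  empty <- deduplicate(enumerate_potential_orfs(c(r = "ACGACG")))
  expect_equal(empty$n_unique, 0L)
  set.seed(303)
  seq1 <- random_dna(200)
  o <- enumerate_potential_orfs(c(a = seq1, b = seq1), min_len = 2,
                                min_len_no_start = 4)
  cat <- deduplicate(o)
  expect_equal(cat$n_unique, length(unique(o$aa_sequence)))
  expect_equal(sum(vapply(cat$entries, nrow, integer(1))), nrow(o))
  # every duplicated sequence appears under one key with >= 2 occurrences
  dup <- names(which(table(o$aa_sequence) > 1))[1]
  expect_gte(nrow(cat$entries[[dup]]), 2L)
})

test_that("gc_content counts G and C, excluding N", {
  expect_equal(gc_content("ATATAT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCNNAT"), 0.5)
  expect_error(gc_content("ACGT", 2, 2), "start < end")
  set.seed(304)
  s <- random_dna(100)
  b <- strsplit(s, "")[[1]]
  expect_equal(gc_content(s), mean(b %in% c("G", "C")))
  expect_equal(gc_content(s, 10, 40),
               mean(b[11:40] %in% c("G", "C")))
})

test_that("aa_composition returns pooled frequencies summing to one", {
  f <- aa_composition("AAAA")
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)
  expect_error(aa_composition(character(0)))
  set.seed(305)
  seqs <- c(random_protein(30), random_protein(50))
  f2 <- aa_composition(seqs)
  ch <- unlist(strsplit(paste(seqs, collapse = ""), ""))
  expect_equal(unname(f2["L"]), mean(ch == "L"))
})

test_that("location classification follows the sense/antisense/intergenic rule", {
  iv <- data.frame(chrom = "2L", start = 100, end = 200, strand = "+")
  none <- classify_location(iv, iv[0, ])
  expect_true(none$intergenic)
  genes <- data.frame(chrom = c("2L", "2L"), start = c(50, 150),
                      end = c(250, 400), strand = c("+", "-"))
  both <- classify_location(iv, genes)
  expect_true(both$sense && both$antisense && !both$intergenic)
  expect_equal(both$location, "sense+antisense")
  nested <- classify_location(iv, genes[1, , drop = FALSE])
  expect_true(nested$sense && !nested$antisense)
  # oracle: pairwise overlap check on random intervals
  set.seed(306)
  ivs <- data.frame(chrom = "c", start = sample(0:900, 30),
                    strand = sample(c("+", "-"), 30, TRUE))
  ivs$end <- ivs$start + sample(10:80, 30, TRUE)
  ann <- data.frame(chrom = "c", start = sample(0:900, 10),
                    strand = sample(c("+", "-"), 10, TRUE))
  ann$end <- ann$start + sample(20:150, 10, TRUE)
  got <- classify_location(ivs, ann)
  for (i in seq_len(nrow(ivs))) {
    ov <- ivs$start[i] < ann$end & ann$start < ivs$end[i]
    expect_equal(got$sense[i], any(ov & ann$strand == ivs$strand[i]))
    expect_equal(got$antisense[i], any(ov & ann$strand != ivs$strand[i]))
  }
})

test_that("track_mean averages defined positions only", {
  tr <- data.frame(pos = 0:2, score = c(0, 0.5, 1))
  expect_equal(track_mean(tr, 0, 3), 0.5)
  expect_equal(track_mean(data.frame(pos = 0:9, score = rep(0.5, 10)), 0, 10),
               0.5)
  expect_warning(v <- track_mean(tr, 10, 20), "no defined")
  expect_true(is.na(v))
  set.seed(307)
  tr2 <- data.frame(pos = sample(0:99, 60), score = runif(60))
  sel <- tr2$pos >= 20 & tr2$pos < 70
  expect_equal(track_mean(tr2, 20, 70), mean(tr2$score[sel]))
})
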