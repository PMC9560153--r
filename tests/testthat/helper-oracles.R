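# Independent brute-force oracles used across the suite. Each reimplements
# the operation it checks from first principles, sharing no code with the
# package internals.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# Plain six-frame scan: walk codons one by one, split on stops and on codons
# containing N or lowercase, apply the length/start rules.
oracle_orfs <- function(seq, min_len = 8L, min_len_no_start = 20L) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  revcomp <- function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      span_aa <- character(0)
      span_start <- NA_integer_
      pos <- f
      flush <- function(endpos) {
        len <- length(span_aa)
        if (len == 0L) return(invisible(NULL))
        has_m <- "M" %in% span_aa
        if (len >= min_len && (has_m || len >= min_len_no_start)) {
          if (strand == "+") {
            gs <- span_start; ge <- endpos
          } else {
            gs <- n - endpos; ge <- n - span_start
          }
          out[[length(out) + 1L]] <<- data.frame(
            aa_sequence = paste(span_aa, collapse = ""), frame =
              if (strand == "+") f + 1L else -(f + 1L),
            start = gs, end = ge, strand = strand, stringsAsFactors = FALSE)
        }
        invisible(NULL)
      }
      while (pos + 3L <= n) {
        cod <- substr(w, pos + 1L, pos + 3L)
        ok <- !grepl("[acgtnN]", cod)
        aa <- if (ok) unname(gc[cod]) else NA_character_
        if (!ok || aa == "*") {
          flush(pos)
          span_aa <- character(0)
          span_start <- NA_integer_
        } else {
          if (length(span_aa) == 0L) span_start <- pos
          span_aa <- c(span_aa, aa)
        }
        pos <- pos + 3L
      }
      flush(pos)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(aa_sequence = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

# Exhaustive enumeration over monotone residue pairings: with zero gap cost
# the optimal local alignment is the best-scoring chain of matched pairs.
oracle_pairing_score <- function(a, b, mat) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) return(0)
  memo <- matrix(NA_real_, n + 1L, m + 1L)
  f <- function(i, j) {
    if (i > n || j > m) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0
    for (i2 in i:n) for (j2 in j:m) {
      v <- mat[av[i2], bv[j2]] + f(i2 + 1L, j2 + 1L)
      if (v > best) best <- v
    }
    memo[i, j] <<- best
    best
  }
  f(1L, 1L)
}

oracle_hamming_min <- function(query, members, cap) {
  q <- strsplit(query, "")[[1]]
  best <- Inf
  for (p in members) {
    if (nchar(p) != length(q)) next
    d <- sum(strsplit(p, "")[[1]] != q)
    if (d < best) best <- d
  }
  if (best <= cap) best else Inf
}

oracle_levenshtein_min <- function(query, members, cap) {
  d <- min(utils::adist(query, members))
  if (d <= cap) d else Inf
}

# FDR recomputation by sweeping every distinct score as a threshold.
oracle_qvalues <- function(score, is_decoy) {
  fdr_at <- vapply(score, function(t) {
    d <- sum(is_decoy & score >= t)
    tt <- sum(!is_decoy & score >= t)
    if (tt == 0) Inf else d / tt
  }, numeric(1))
  vapply(score, function(t) {
    min(1, min(fdr_at[score <= t]))
  }, numeric(1))
}

# Minimum subtree cover of the lost leaves by exhaustive search. status is a
# named vector over non-reference leaves: "lost", "present", "unknown".
oracle_min_losses <- function(tree, origin, reference, status) {
  ntip <- length(tree$tip.label)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  tips_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids(v), tips_under))
  }
  all_nodes_under <- function(v) {
    if (v <= ntip) return(v)
    c(v, unlist(lapply(kids(v), all_nodes_under)))
  }
  leaves <- setdiff(tips_under(origin), reference)
  lost <- names(status)[status == "lost"]
  lost <- intersect(lost, leaves)
  if (length(lost) == 0L) return(0L)
  nodes <- all_nodes_under(origin)
  cands <- Filter(function(v) {
    tl <- setdiff(tips_under(v), character(0))
    if (reference %in% tl) return(FALSE)
    db <- tl[tl %in% names(status) & status[tl] %in% c("lost", "present")]
    length(db) > 0L && all(status[db] == "lost")
  }, nodes)
  if (length(cands) == 0L) return(Inf)
  cover <- lapply(cands, function(v) intersect(tips_under(v), lost))
  for (k in seq_len(length(lost))) {
    combs <- utils::combn(length(cands), k, simplify = FALSE)
    for (cc in combs) {
      if (setequal(unlist(cover[cc]), lost)) return(k)
    }
  }
  length(lost)
}

oracle_binom_tail <- function(k, n, p = 1 / 3) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# Direct mixture log-likelihood of a categorical latent class model.
oracle_lca_loglik <- function(table, pi, rho) {
  n <- nrow(table)
  K <- length(pi)
  ll <- 0
  for (i in seq_len(n)) {
    per_class <- vapply(seq_len(K), function(k) {
      prod(vapply(seq_along(rho), function(j) {
        rho[[j]][k, as.character(table[i, j])]
      }, numeric(1)))
    }, numeric(1))
    ll <- ll + log(sum(pi * per_class))
  }
  ll
}

# Best label-permutation agreement between two class-label vectors.
label_agreement <- function(est, truth, K) {
  perms <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    sub <- perms(k - 1L)
    res <- NULL
    for (r in seq_len(nrow(sub))) {
      for (pos in seq_len(k)) {
        res <- rbind(res, append(sub[r, ], k, after = pos - 1L))
      }
    }
    res
  }
  pm <- perms(K)
  max(vapply(seq_len(nrow(pm)), function(r) mean(pm[r, ][est] == truth),
             numeric(1)))
}
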