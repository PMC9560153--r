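.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal to every K or R not followed by P, and
#' enumerates all peptides with up to `max_missed` missed cleavage sites,
#' keeping those of at least `min_len` residues.
#'
#' @param protein Amino-acid string (20 standard residues).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param min_len Minimum peptide length (default 7).
#' @return Data frame with columns `peptide`, `n_missed`, `start` (0-based
#'   offset of the peptide in the protein).
#' @export
tryptic_digest <- function(protein, max_missed = 2L, min_len = 7L) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  res <- strsplit(toupper(protein), "")[[1]]
  bad <- setdiff(unique(res), .aa20)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  n <- length(res)
  # cleavage after position i when res[i] in {K,R} and res[i+1] != P
  cut_after <- which(res %in% c("K", "R") & c(res[-1], "") != "P" &
                       seq_len(n) < n)
  bounds <- c(0L, cut_after, n)          # fragment boundaries (0-based ends)
  n_frag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      if (e - s + 1L < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[s:e], collapse = ""),
        n_missed = m, start = s - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peptide = character(0), n_missed = integer(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a prefix-tree index of peptides
#'
#' The trie supports bounded minimum-distance queries (Hamming and
#' Levenshtein) against every indexed peptide while sharing prefixes, which
#' prunes the vast majority of comparisons relative to a linear scan.
#'
#' @param peptides Character vector of amino-acid strings.
#' @return An object of class `peptide_trie` with `size` = number of unique
#'   peptides indexed.
#' @export
build_trie <- function(peptides) {
  peptides <- unique(as.character(peptides))
  root <- new.env(parent = emptyenv())
  root$children <- list()
  root$terminal <- FALSE
  for (p in peptides) {
    node <- root
    for (ch in strsplit(p, "")[[1]]) {
      nxt <- node$children[[ch]]
      if (is.null(nxt)) {
        nxt <- new.env(parent = emptyenv())
        nxt$children <- list()
        nxt$terminal <- FALSE
        node$children[[ch]] <- nxt
      }
      node <- nxt
    }
    node$terminal <- TRUE
  }
  out <- list(root = root, size = length(peptides))
  class(out) <- "peptide_trie"
  out
}

#' @export
print.peptide_trie <- function(x, ...) {
  cat(sprintf("Peptide trie: %d unique peptides\n", x$size))
  invisible(x)
}

#' Minimum distance from a query peptide to an indexed set
#'
#' Depth-first search over the trie with branch-and-bound pruning at `cap`.
#' Hamming distance (substitutions only) is defined only between equal-length
#' strings; Levenshtein distance counts substitutions and indels.
#'
#' @param query Amino-acid string.
#' @param index A `peptide_trie` from [build_trie()].
#' @param metric `"hamming"` or `"levenshtein"`.
#' @param cap Maximum distance of interest (>= 0).
#' @return Integer minimum distance, or `Inf` when every indexed peptide is
#'   farther than `cap` (or, for Hamming, of different length).
#' @export
min_distance <- function(query, index, metric = c("hamming", "levenshtein"),
                         cap = 2L) {
  metric <- match.arg(metric)
  stopifnot(inherits(index, "peptide_trie"), cap >= 0)
  q <- strsplit(query, "")[[1]]
  nq <- length(q)
  best <- Inf
  if (metric == "hamming") {
    walk <- function(node, depth, cost) {
      if (cost > cap || cost >= best) return(invisible(NULL))
      if (depth == nq) {
        if (node$terminal && cost < best) best <<- cost
        return(invisible(NULL))
      }
      for (ch in names(node$children)) {
        walk(node$children[[ch]], depth + 1L,
             cost + as.integer(ch != q[depth + 1L]))
      }
    }
    walk(index$root, 0L, 0L)
  } else {
    # classic trie walk carrying one DP row of the edit-distance table
    walk <- function(node, row) {
      if (node$terminal && row[nq + 1L] <= cap && row[nq + 1L] < best) {
        best <<- row[nq + 1L]
      }
      if (min(row) > cap || min(row) >= best) return(invisible(NULL))
      for (ch in names(node$children)) {
        new_row <- numeric(nq + 1L)
        new_row[1L] <- row[1L] + 1L
        for (j in seq_len(nq)) {
          new_row[j + 1L] <- min(row[j] + as.integer(ch != q[j]),
                                 row[j + 1L] + 1L, new_row[j] + 1L)
        }
        walk(node$children[[ch]], new_row)
      }
    }
    walk(index$root, as.numeric(0:nq))
  }
  if (is.finite(best)) as.integer(best) else Inf
}

#' Target-decoy false discovery rate estimation
#'
#' At every score threshold `s`, `FDR(s) = #decoys >= s / #targets >= s`;
#' the q-value of a PSM is the running minimum of FDR from the worst score to
#' its own (the smallest FDR of any threshold that accepts it). Ties at a
#' threshold count decoys in before targets, which is the conservative
#' convention.
#'
#' @param psms Data frame with at least `score` (finite, higher is better)
#'   and `is_decoy` (logical).
#' @param alpha Acceptance level (default 0.01).
#' @return List of class `fdr_result`: `psms` (input plus `fdr` and `qvalue`
#'   columns), `accepted` (logical over rows: target with q-value <= alpha),
#'   `cutoff` (smallest accepted score, `NA` if none), `alpha`.
#' @export
estimate_fdr <- function(psms, alpha = 0.01) {
  stopifnot(all(c("score", "is_decoy") %in% names(psms)),
            all(is.finite(psms$score)))
  if (!any(!psms$is_decoy)) stop("no target PSMs")
  s <- psms$score
  # counts at threshold 'score >= s' for each PSM's own score
  us <- sort(unique(s), decreasing = TRUE)
  idx_all <- match(s, us)
  d_cum <- cumsum(tabulate(idx_all[psms$is_decoy], nbins = length(us)))
  t_cum <- cumsum(tabulate(idx_all[!psms$is_decoy], nbins = length(us)))
  fdr_u <- ifelse(t_cum == 0, Inf, d_cum / t_cum)
  # running min from worst (last) to best (first): q[i] = min(fdr_u[i:end])
  q_u <- rev(cummin(rev(fdr_u)))
  psms$fdr <- fdr_u[idx_all]
  psms$qvalue <- pmin(q_u[idx_all], 1)
  accepted <- !psms$is_decoy & psms$qvalue <= alpha
  out <- list(psms = psms, accepted = accepted,
              cutoff = if (any(accepted)) min(s[accepted]) else NA_real_,
              alpha = alpha)
  class(out) <- "fdr_result"
  out
}

# Best-PSM-per-group table for group-level FDR.
best_psm_per_group <- function(psms) {
  stopifnot("parent_group" %in% names(psms))
  ord <- order(psms$parent_group, -psms$score)
  p <- psms[ord, ]
  p[!duplicated(p$parent_group), ]
}

#' Two-round discovery/verification selection
#'
#' Round 1 ("discovery") screens PSMs against the full candidate database at
#' a permissive FDR, retaining the candidate identifiers with any accepted
#' support. Round 2 ("verification") re-scores against the reduced database
#' (round-1 survivors plus annotated proteins) at a stringent FDR, applied at
#' both the peptide level and the protein-group level (best PSM per group).
#'
#' @param round1 PSM data frame (`peptide`, `score`, `is_decoy`,
#'   `parent_group`).
#' @param full_db_ids Character vector of all candidate (unannotated)
#'   identifiers searchable in round 1; groups not listed are treated as
#'   annotated.
#' @param round2 PSM data frame for the verification round; its target
#'   candidate groups must be round-1 survivors.
#' @param fdr1,fdr2 FDR levels for the two rounds (defaults 0.2 and 0.01).
#' @param group_scope `"joint"` (default) computes the round-2 group-level
#'   FDR over candidate and annotated groups together; `"candidates"`
#'   restricts it to candidate groups.
#' @return List with `survivors` (round-1 candidate ids), `accepted`
#'   (final candidate ids), and the two `fdr_result` objects.
#' @export
two_round_select <- function(round1, full_db_ids, round2,
                             fdr1 = 0.2, fdr2 = 0.01,
                             group_scope = c("joint", "candidates")) {
  group_scope <- match.arg(group_scope)
  if (fdr2 > fdr1) {
    stop("verification FDR (fdr2) must not exceed discovery FDR (fdr1)")
  }
  r1 <- estimate_fdr(round1, alpha = fdr1)
  acc1 <- r1$psms[r1$accepted, , drop = FALSE]
  survivors <- intersect(unique(acc1$parent_group), full_db_ids)
  bad <- setdiff(intersect(unique(round2$parent_group[!round2$is_decoy]),
                           full_db_ids), survivors)
  if (length(bad)) {
    stop("round-2 PSMs reference non-survivor candidates: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(survivors) == 0L) {
    return(list(survivors = character(0), accepted = character(0),
                round1 = r1, round2 = NULL))
  }
  r2_pep <- estimate_fdr(round2, alpha = fdr2)
  grp_tab <- best_psm_per_group(round2)
  if (group_scope == "candidates") {
    grp_tab <- grp_tab[grp_tab$is_decoy | grp_tab$parent_group %in% survivors, ]
  }
  r2_grp <- estimate_fdr(grp_tab, alpha = fdr2)
  ok_groups <- r2_grp$psms$parent_group[r2_grp$accepted]
  acc_pep <- r2_pep$psms[r2_pep$accepted, , drop = FALSE]
  accepted <- intersect(unique(acc_pep$parent_group[
    acc_pep$parent_group %in% ok_groups]), survivors)
  list(survivors = survivors, accepted = accepted,
       round1 = r1, round2 = r2_pep, round2_group = r2_grp)
}

#' Curate verified candidates
#'
#' Applies the post-verification filters: drop candidates shorter than
#' `min_len` residues, drop candidates flagged as homologous to annotated
#' proteins, and within each protein group keep only the longest candidate
#' (first on ties).
#'
#' @param candidates Data frame with columns `id`, `length_aa`,
#'   `homology_flag`, `protein_group`.
#' @param min_len Minimum retained length in residues (default 14).
#' @return The retained subset of `candidates`.
#' @export
curate <- function(candidates, min_len = 14L) {
  req <- c("id", "length_aa", "homology_flag", "protein_group")
  stopifnot(all(req %in% names(candidates)))
  keep <- candidates[candidates$length_aa >= min_len &
                       !candidates$homology_flag, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  ord <- order(keep$protein_group, -keep$length_aa)
  keep <- keep[ord, ]
  keep <- keep[!duplicated(keep$protein_group), ]
  rownames(keep) <- NULL
  keep
}

#' Retention-time support filter
#'
#' The support threshold is the 95th percentile (linear interpolation between
#' order statistics, R quantile type 7) of the absolute differences between
#' observed and predicted retention times over PSMs supporting annotated
#' proteins. A candidate peptide is supported when at least one of its PSMs
#' has an absolute delta at or below the threshold.
#'
#' @param annotated_psms PSM data frame with `observed_rt` and `predicted_rt`
#'   (minutes) for annotated proteins.
#' @param utorf_psms PSM data frame for candidate peptides, with a `peptide`
#'   column and the same RT columns.
#' @param prob Quantile for the threshold (default 0.95).
#' @return List with `threshold` (minutes), `supported` (character vector of
#'   supported peptides), and `deltas` (per-PSM table with `delta` and
#'   `supported` columns).
#' @export
rt_support <- function(annotated_psms, utorf_psms, prob = 0.95) {
  req <- c("observed_rt", "predicted_rt")
  stopifnot(all(req %in% names(annotated_psms)),
            all(c("peptide", req) %in% names(utorf_psms)))
  ann_delta <- abs(annotated_psms$observed_rt - annotated_psms$predicted_rt)
  ann_delta <- ann_delta[!is.na(ann_delta)]
  if (length(ann_delta) == 0L) stop("no annotated PSMs with retention times")
  thr <- unname(stats::quantile(ann_delta, prob, type = 7))
  d <- abs(utorf_psms$observed_rt - utorf_psms$predicted_rt)
  utorf_psms$delta <- d
  utorf_psms$supported <- !is.na(d) & d <= thr
  supported <- unique(utorf_psms$peptide[utorf_psms$supported])
  list(threshold = thr, supported = supported, deltas = utorf_psms)
}
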