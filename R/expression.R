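#' Tissue/stage specificity index tau
#'
#' \eqn{\tau = \sum_i (1 - x_i / \max x) / (N - 1)}: 0 for uniform
#' expression, 1 for expression confined to a single sample. Computed on the
#' linear scale by default; `log_transform = TRUE` applies
#' `log10(x + pseudocount)` shifted to be nonnegative first.
#'
#' @param x Nonnegative expression vector (length >= 2).
#' @param log_transform Apply a log transform before computing tau.
#' @param pseudocount Pseudocount for the log variant (default 0.01).
#' @return Tau in `[0, 1]`, or `NA` (with a warning) for an all-zero vector.
#' @export
tau <- function(x, log_transform = FALSE, pseudocount = 0.01) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(x >= 0))
  if (max(x) == 0) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  if (log_transform) {
    x <- log10(x + pseudocount)
    x <- x - min(x)
    if (max(x) == 0) return(0)
  }
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Binomial framing test for ribosome footprints
#'
#' Tests whether footprints concentrate in the locus reading frame: with
#' `n = n0 + n1 + n2` pooled footprints the one-sided upper-tail probability
#' is `P(X >= n0)` for `X ~ Binomial(n, 1/3)`. Loci with fewer than
#' `min_unique` unique footprints are marked not testable.
#'
#' @param counts Data frame with columns `n0`, `n1`, `n2` and optionally
#'   `n_unique` (defaults to `n0 + n1 + n2`).
#' @param min_unique Minimum unique footprints for testability (default 3,
#'   i.e. strictly more than 2).
#' @param alternative `"greater"` (default, one-sided toward the locus
#'   frame) or `"two.sided"` (doubled one-sided tail, capped at 1).
#' @return `counts` with added columns `testable` and `pvalue` (`NA` where
#'   not testable).
#' @export
framing_pvalue <- function(counts, min_unique = 3L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("n0", "n1", "n2") %in% names(counts)),
            all(counts$n0 >= 0, counts$n1 >= 0, counts$n2 >= 0))
  n_unique <- if ("n_unique" %in% names(counts)) counts$n_unique else
    counts$n0 + counts$n1 + counts$n2
  n <- counts$n0 + counts$n1 + counts$n2
  testable <- n_unique >= min_unique & n > 0
  p <- stats::pbinom(counts$n0 - 1L, n, 1 / 3, lower.tail = FALSE)
  if (alternative == "two.sided") {
    lower <- stats::pbinom(counts$n0, n, 1 / 3, lower.tail = TRUE)
    p <- pmin(1, 2 * pmin(p, lower))
  }
  counts$testable <- testable
  counts$pvalue <- ifelse(testable, p, NA_real_)
  counts
}

#' Transcription support call from expression matrices
#'
#' A locus is supported when its maximum TPM across all samples strictly
#' exceeds the threshold.
#'
#' @param mat Numeric matrix of TPM values (loci x samples).
#' @param threshold Support threshold (default 0.2).
#' @return Logical vector per locus.
#' @export
tpm_support <- function(mat, threshold = 0.2) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  apply(mat, 1, max) > threshold
}

#' Maximum per-sample expression
#'
#' @param mat Numeric TPM matrix (loci x samples) with column names.
#' @return Data frame with `max_tpm` and `argmax_sample` (ties broken by
#'   first sample in column order).
#' @export
max_expression <- function(mat) {
  stopifnot(is.matrix(mat))
  idx <- apply(mat, 1, which.max)
  data.frame(max_tpm = mat[cbind(seq_len(nrow(mat)), idx)],
             argmax_sample = colnames(mat)[idx],
             stringsAsFactors = FALSE)
}

#' Log-ratio expression contrast between two samples
#'
#' Per-locus `log10(TPM_b + c) - log10(TPM_a + c)` with pseudocount `c`.
#'
#' @param mat TPM matrix with column names.
#' @param sample_a,sample_b Column names to contrast (delta is b minus a).
#' @param pseudocount Pseudocount (default 0.01).
#' @return Numeric vector of deltas.
#' @export
expression_contrast <- function(mat, sample_a, sample_b, pseudocount = 0.01) {
  if (!all(c(sample_a, sample_b) %in% colnames(mat))) {
    stop("sample not present in matrix")
  }
  log10(mat[, sample_b] + pseudocount) - log10(mat[, sample_a] + pseudocount)
}

#' Rank-averaged prioritization of loci
#'
#' Ranks loci within each factor (midranks for ties, best = rank 1 in the
#' factor's declared better-direction) and averages ranks per locus;
#' ascending mean rank is the priority order.
#'
#' @param factors Data frame of numeric factor values (one row per locus).
#' @param directions Named character vector over the factor columns:
#'   `"higher"` or `"lower"` is better.
#' @return Data frame of per-factor ranks (`rank_<factor>`), `mean_rank`,
#'   and `priority` (1 = highest priority), in the input row order.
#' @export
priority_ranking <- function(factors, directions) {
  stopifnot(ncol(factors) >= 1L,
            setequal(names(directions), names(factors)),
            all(directions %in% c("higher", "lower")))
  ranks <- vapply(names(factors), function(nm) {
    x <- factors[[nm]]
    if (directions[[nm]] == "higher") x <- -x
    rank(x, ties.method = "average")
  }, numeric(nrow(factors)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(factors))
  colnames(ranks) <- paste0("rank_", names(factors))
  mean_rank <- rowMeans(ranks)
  out <- data.frame(ranks, mean_rank = mean_rank,
                    priority = rank(mean_rank, ties.method = "average"))
  rownames(out) <- rownames(factors)
  out
}
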