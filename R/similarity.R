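#' @useDynLib orfevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Scoring alphabet shared by the C++ kernel and all encoders. '*' (stop) is a
# first-class symbol: it scores -4 against everything so that recent nonsense
# mutations penalize but do not terminate a local alignment.
.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")

.scoring_matrix_cache <- new.env(parent = emptyenv())

#' BLOSUM62 scoring matrix used for protein similarity
#'
#' Returns the BLOSUM62 substitution matrix restricted to the package's
#' scoring alphabet, with the stop symbol `*` rescored to -4 against every
#' symbol (including itself). Stops therefore reduce, but never truncate, a
#' local alignment, which lets the scorer tolerate recently acquired nonsense
#' or frameshift mutations in the non-reference species.
#'
#' @return A numeric matrix with identical row and column names.
#' @export
similarity_matrix <- function() {
  if (!is.null(.scoring_matrix_cache$m)) return(.scoring_matrix_cache$m)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[.aa_alphabet, .aa_alphabet]
  m["*", ] <- -4
  m[, "*"] <- -4
  storage.mode(m) <- "double"
  .scoring_matrix_cache$m <- m
  m
}

# Encode an amino-acid string as 0-based indices into the scoring alphabet.
encode_aa <- function(x) {
  idx <- match(strsplit(toupper(x), "")[[1]], .aa_alphabet)
  if (anyNA(idx)) {
    bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), .aa_alphabet)
    stop("invalid amino-acid symbol(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' Raw zero-gap local alignment score between two amino-acid strings
#'
#' The maximum local-alignment score (in points, not length-normalized)
#' under BLOSUM62 substitution scores with free gaps. This is the kernel
#' behind [similarity_score()] and [calibrate_null()].
#'
#' @param a,b Amino-acid strings (the scoring alphabet includes `*` and `X`).
#' @param mat Substitution matrix; defaults to [similarity_matrix()].
#' @return Nonnegative numeric score; empty input scores 0.
#' @export
score_pair_raw <- function(a, b, mat = similarity_matrix()) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  sw_zero_gap_max(encode_aa(a), encode_aa(b), mat)
}

# Translate a nucleotide string (gaps already removed) in one forward frame,
# keeping stops as '*' and ambiguous codons as 'X'.
translate_frame <- function(nt, frame) {
  stopifnot(frame %in% 0:2)
  nt <- toupper(nt)
  usable <- nchar(nt) - frame
  n_codon <- usable %/% 3L
  if (n_codon < 1L) return("")
  sub <- substr(nt, frame + 1L, frame + 3L * n_codon)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)
  as.character(aa)
}

#' Synteny-anchored protein similarity score
#'
#' Scores a reference protein against the orthologous (syntenic) nucleotide
#' sequence of another species. The nucleotide sequence is translated in all
#' three forward frames (stops kept as `*`), each translation is aligned to
#' the reference with a Smith-Waterman local alignment using BLOSUM62
#' substitution scores and zero gap open/extension penalties, the raw maximum
#' cell score is divided by the reference protein length, and the best frame
#' is kept. Free gaps make the score robust to small indels, and the
#' three-frame maximum makes it robust to frameshifts.
#'
#' @param reference_aa Reference amino-acid sequence (no stop symbol).
#' @param other_nt Nucleotide sequence from the other species; alignment gap
#'   characters (`-`) are removed before translation. May be `NA` or empty,
#'   in which case the score is 0 and `best_frame` is `NA`.
#' @param mat Substitution matrix; defaults to [similarity_matrix()].
#' @return A list with `score` (points per reference residue), `best_frame`
#'   (0, 1 or 2, or `NA`), and `reference_length_aa`.
#' @examples
#' similarity_score("MKVL", "ATGAAGGTGCTG")$score  # self-match
#' @export
similarity_score <- function(reference_aa, other_nt, mat = similarity_matrix()) {
  stopifnot(is.character(reference_aa), length(reference_aa) == 1L,
            nchar(reference_aa) > 0L)
  len <- nchar(reference_aa)
  if (length(other_nt) != 1L || is.na(other_nt)) other_nt <- ""
  nt <- gsub("-", "", other_nt, fixed = TRUE)
  if (nchar(nt) == 0L) {
    return(list(score = 0, best_frame = NA_integer_, reference_length_aa = len))
  }
  ref_enc <- encode_aa(reference_aa)
  best <- 0
  best_frame <- NA_integer_
  for (f in 0:2) {
    aa <- translate_frame(nt, f)
    if (nchar(aa) == 0L) next
    sc <- sw_zero_gap_max(ref_enc, encode_aa(aa), mat) / len
    if (is.na(best_frame) || sc > best) {
      best <- sc
      best_frame <- f
    }
  }
  list(score = best, best_frame = best_frame, reference_length_aa = len)
}

#' Amino-acid frequencies of the annotated D. melanogaster proteome
#'
#' Approximate residue frequencies of the annotated fruit-fly proteome, used
#' as the default composition for the random-sequence null model. Values are
#' documented constants; any 20-vector of frequencies summing to 1 (named by
#' one-letter residue code) can be supplied instead.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
proteome_aa_frequencies <- function() {
  f <- c(A = 7.5, R = 5.5, N = 4.9, D = 5.3, C = 1.9, Q = 5.2, E = 6.4,
         G = 6.3, H = 2.7, I = 4.9, L = 9.0, K = 5.7, M = 2.3, F = 3.5,
         P = 5.4, S = 8.1, T = 5.6, W = 1.0, Y = 2.9, V = 5.9)
  f / sum(f)
}

#' Calibrate the random-sequence null model of the similarity score
#'
#' Draws `n_pairs` independent pairs of random amino-acid sequences (lengths
#' uniform integers in `length_range`, residues i.i.d. from
#' `aa_frequencies`), scores each pair with the zero-gap local alignment
#' normalized by the *first* sequence's length, and summarizes the score
#' distribution. The significance threshold is a fixed input, not a product
#' of the simulation; the returned object records how far it sits above the
#' simulated mean.
#'
#' @param n_pairs Number of simulated pairs (default 10000).
#' @param length_range Integer range of sequence lengths, default `c(20, 150)`.
#' @param aa_frequencies Residue frequencies; default
#'   [proteome_aa_frequencies()].
#' @param threshold Significance threshold in score points (default 2.5).
#' @param seed Optional integer seed for reproducibility.
#' @param keep_scores Keep the per-pair scores in the result (default TRUE).
#' @param pair_lengths `"equal"` (default) draws one length per pair and uses
#'   it for both members, so the score distribution can be summarized as a
#'   function of sequence length; `"independent"` draws the two lengths
#'   independently. The normalizing (first) member's length dominates the
#'   score scale, so independent lengths mix short-reference pairs with
#'   inflated normalized scores into the pooled summary.
#' @return An object of class `orfevo_null`: list with `n_pairs`,
#'   `length_range`, `aa_frequencies`, `mean`, `sd`, `threshold`, `seed`, and
#'   optionally `scores` and the per-pair `lengths`.
#' @export
calibrate_null <- function(n_pairs = 10000, length_range = c(20L, 150L),
                           aa_frequencies = proteome_aa_frequencies(),
                           threshold = 2.5, seed = NULL, keep_scores = TRUE,
                           pair_lengths = c("equal", "independent")) {
  pair_lengths <- match.arg(pair_lengths)
  stopifnot(n_pairs >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (abs(sum(aa_frequencies) - 1) > 1e-6) {
    stop("aa_frequencies must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  residues <- names(aa_frequencies)
  if (is.null(residues)) stop("aa_frequencies must be named by residue")
  code <- match(residues, .aa_alphabet) - 1L
  if (anyNA(code)) stop("unknown residue in aa_frequencies")
  mat <- similarity_matrix()
  lens1 <- sample(length_range[1]:length_range[2], n_pairs, replace = TRUE)
  lens2 <- if (pair_lengths == "equal") lens1 else {
    sample(length_range[1]:length_range[2], n_pairs, replace = TRUE)
  }
  scores <- vapply(seq_len(n_pairs), function(i) {
    a <- sample(code, lens1[i], replace = TRUE, prob = aa_frequencies)
    b <- sample(code, lens2[i], replace = TRUE, prob = aa_frequencies)
    sw_zero_gap_max(a, b, mat) / lens1[i]
  }, numeric(1))
  out <- list(n_pairs = n_pairs, length_range = as.integer(length_range),
              aa_frequencies = aa_frequencies,
              mean = mean(scores), sd = stats::sd(scores),
              threshold = threshold, seed = seed,
              pair_lengths = pair_lengths)
  if (keep_scores) {
    out$scores <- scores
    out$lengths <- lens1
  }
  class(out) <- "orfevo_null"
  out
}

#' @export
print.orfevo_null <- function(x, ...) {
  cat(sprintf(
    "Similarity-score null model: %d pairs, lengths %d-%d\n  mean %.3f, sd %.3f, mean + 2 sd = %.3f (threshold %.2f)\n",
    x$n_pairs, x$length_range[1], x$length_range[2],
    x$mean, x$sd, x$mean + 2 * x$sd, x$threshold))
  invisible(x)
}
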