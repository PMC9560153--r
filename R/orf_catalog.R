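#' @importFrom stats setNames
NULL

.stop_codons <- c("TAA", "TAG", "TGA")

# Reverse complement preserving case (soft-masking travels with the base).
revcomp_keep_case <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

validate_nucleotides <- function(x, id = "<sequence>") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop("record '", id, "': sequence must be a nonempty string")
  }
  if (grepl("[^ACGTNacgtn]", x)) {
    stop("record '", id, "': invalid nucleotide symbol")
  }
  invisible(TRUE)
}

# Split a working-strand sequence into codons for a 0-based frame offset,
# translate, and mark codons broken by N or soft-masked (lowercase) bases.
frame_codons <- function(w, f) {
  n <- nchar(w)
  n_codon <- (n - f) %/% 3L
  if (n_codon < 1L) {
    return(list(aa = character(0), bad = logical(0), n_codon = 0L))
  }
  starts <- f + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(w, starts, starts + 2L)
  bad <- grepl("[acgtnN]", codons)
  aa <- rep(NA_character_, n_codon)
  gc <- Biostrings::GENETIC_CODE
  aa[!bad] <- unname(gc[codons[!bad]])
  list(aa = aa, bad = bad, n_codon = n_codon)
}

#' Enumerate potential ORFs from nucleotide records
#'
#' Scans every record in all six reading frames for maximal stop-free codon
#' spans ("potential ORFs"). Spans are broken at stop codons (TAA/TAG/TGA,
#' standard nuclear code) and at any codon containing `N` or a soft-masked
#' (lowercase) base. A span is retained when it is at least `min_len`
#' residues long and, if it contains no in-frame ATG-encoded methionine, at
#' least `min_len_no_start` residues. Potential ORFs need not begin with a
#' start codon: a six-frame translation cannot associate the exons of a gene,
#' and the set of stop-free codon spans is a superset of all coding exons.
#'
#' @param records Named character vector of nucleotide sequences (uppercase
#'   A/C/G/T plus N; lowercase marks soft-masked bases).
#' @param min_len Minimum length in residues (default 8).
#' @param min_len_no_start Minimum length for spans without a canonical start
#'   (default 20).
#' @return A data frame with one row per retained ORF: `id`, `source_id`,
#'   `frame` (+1/+2/+3/-1/-2/-3), `start`, `end` (0-based half-open,
#'   forward-strand), `strand`, `aa_sequence`, `length_aa`,
#'   `contains_canonical_start`, `first_start_offset` (0-based residue offset
#'   of the first ATG-encoded M, `NA` when absent).
#' @export
enumerate_potential_orfs <- function(records, min_len = 8L,
                                     min_len_no_start = 20L) {
  stopifnot(min_len >= 1L, min_len <= min_len_no_start)
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("records must be a named character vector")
  }
  out <- vector("list", 0L)
  for (rid in names(records)) {
    s <- records[[rid]]
    validate_nucleotides(s, rid)
    n <- nchar(s)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") s else revcomp_keep_case(s)
      for (f in 0:2) {
        fc <- frame_codons(w, f)
        if (fc$n_codon == 0L) next
        keep <- !fc$bad & !(fc$aa %in% "*")
        if (!any(keep)) next
        r <- rle(keep)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          c0 <- starts[k]
          len <- r$lengths[k]
          if (len < min_len) next
          aa_vec <- fc$aa[c0:(c0 + len - 1L)]
          m_idx <- which(aa_vec == "M")
          has_start <- length(m_idx) > 0L
          if (!has_start && len < min_len_no_start) next
          w_start <- f + 3L * (c0 - 1L)        # 0-based on working strand
          w_end <- w_start + 3L * len
          if (strand == "+") {
            g_start <- w_start; g_end <- w_end
          } else {
            g_start <- n - w_end; g_end <- n - w_start
          }
          frame_lab <- if (strand == "+") f + 1L else -(f + 1L)
          out[[length(out) + 1L]] <- data.frame(
            source_id = rid,
            frame = frame_lab,
            start = g_start,
            end = g_end,
            strand = strand,
            aa_sequence = paste(aa_vec, collapse = ""),
            length_aa = len,
            contains_canonical_start = has_start,
            first_start_offset = if (has_start) m_idx[1L] - 1L else NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(0), source_id = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), aa_sequence = character(0),
                      length_aa = integer(0),
                      contains_canonical_start = logical(0),
                      first_start_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- cbind(id = sprintf("orf%06d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Deduplicate potential ORFs into a catalogue
#'
#' Groups potential ORFs by exact amino-acid sequence equality; every genomic
#' occurrence of a sequence is preserved under a single catalogue key.
#'
#' @param orfs Data frame from [enumerate_potential_orfs()].
#' @return An object of class `orf_catalog`: list with `entries` (named list
#'   of occurrence data frames, one element per unique sequence) and
#'   `n_unique`.
#' @export
deduplicate <- function(orfs) {
  if (nrow(orfs) == 0L) {
    out <- list(entries = setNames(list(), character(0)), n_unique = 0L)
    class(out) <- "orf_catalog"
    return(out)
  }
  entries <- split(orfs, orfs$aa_sequence)
  out <- list(entries = entries, n_unique = length(entries))
  class(out) <- "orf_catalog"
  out
}

#' @export
print.orf_catalog <- function(x, ...) {
  n_occ <- sum(vapply(x$entries, nrow, integer(1)))
  cat(sprintf("ORF catalogue: %d unique sequences, %d occurrences\n",
              x$n_unique, n_occ))
  invisible(x)
}

#' GC content of a sequence interval
#'
#' Fraction of G/C bases, case-insensitive; `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param x Nucleotide string.
#' @param start,end Optional 0-based half-open interval within `x`; defaults
#'   to the whole sequence.
#' @return Fraction in `[0, 1]` (`NaN` if the interval is all `N`).
#' @export
gc_content <- function(x, start = NULL, end = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!is.null(start) || !is.null(end)) {
    stopifnot(!is.null(start), !is.null(end),
              start >= 0, end <= nchar(x), start < end)
    x <- substr(x, start + 1L, end)
  }
  if (nchar(x) == 0L) stop("empty interval")
  b <- strsplit(toupper(x), "")[[1]]
  b <- b[b != "N"]
  sum(b %in% c("G", "C")) / length(b)
}

#' Amino-acid composition of a set of sequences
#'
#' Pooled residue frequencies over the 20 standard amino acids.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @return Named numeric 20-vector of frequencies summing to 1.
#' @export
aa_composition <- function(sequences) {
  if (length(sequences) == 0L || sum(nchar(sequences)) == 0L) {
    stop("no sequence content")
  }
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
  bad <- setdiff(unique(ch), aa20)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(ch, levels = aa20))
  setNames(as.numeric(tab) / length(ch), aa20)
}

#' Classify genomic locations against an annotation
#'
#' A location is *sense* if any part overlaps an annotated gene on the same
#' strand, *antisense* if any part overlaps a gene on the opposite strand
#' (both can hold at once), and *intergenic* if and only if it is neither.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param annotation Data frame of gene intervals with the same columns (may
#'   have zero rows).
#' @return `intervals` with added logical columns `sense`, `antisense`,
#'   `intergenic` and a character column `location` collapsing the categories
#'   (e.g. `"sense+antisense"`).
#' @export
classify_location <- function(intervals, annotation) {
  req <- c("chrom", "start", "end", "strand")
  stopifnot(all(req %in% names(intervals)), all(req %in% names(annotation)))
  n <- nrow(intervals)
  sense <- antisense <- rep(FALSE, n)
  if (nrow(annotation) > 0L && n > 0L) {
    q <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(intervals$start + 1L, intervals$end),
      strand = intervals$strand)
    s <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(annotation$start + 1L, annotation$end),
      strand = annotation$strand)
    hits_same <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
    sense[unique(S4Vectors::queryHits(hits_same))] <- TRUE
    hits_any <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    opp <- S4Vectors::queryHits(hits_any)[
      as.character(GenomicRanges::strand(q))[S4Vectors::queryHits(hits_any)] !=
        as.character(GenomicRanges::strand(s))[S4Vectors::subjectHits(hits_any)]]
    antisense[unique(opp)] <- TRUE
  }
  intervals$sense <- sense
  intervals$antisense <- antisense
  intervals$intergenic <- !sense & !antisense
  intervals$location <- ifelse(intervals$intergenic, "intergenic",
    paste0(ifelse(sense, "sense", ""),
           ifelse(sense & antisense, "+", ""),
           ifelse(antisense, "antisense", "")))
  intervals
}

#' Mean of a per-base score track over an interval
#'
#' Arithmetic mean of the defined per-base scores within a 0-based half-open
#' interval. Positions absent from the track are ignored; if no position in
#' the interval is defined the result is `NA` with a warning.
#'
#' @param track Data frame with columns `pos` (0-based) and `score`.
#' @param start,end Interval bounds (0-based half-open).
#' @return Mean score, or `NA_real_` when no scores are defined.
#' @export
track_mean <- function(track, start, end) {
  stopifnot(all(c("pos", "score") %in% names(track)), start < end)
  v <- track$score[track$pos >= start & track$pos < end]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("no defined track positions in [", start, ", ", end, ")")
    return(NA_real_)
  }
  mean(v)
}
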