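#' Read a multiple alignment format (MAF) file
#'
#' Minimal MAF parser for alignment blocks of the form `a score=...` followed
#' by `s <src>.<chrom> <start> <size> <strand> <srcSize> <text>` rows. The
#' part of the source name before the first dot is taken as the species.
#'
#' @param path Path to a MAF file.
#' @return List of blocks; each block is a list with `score` and `rows` (data
#'   frame: `species`, `chrom`, `start`, `size`, `strand`, `src_size`,
#'   `text`).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur$rows) > 0L) blocks[[length(blocks) + 1L]] <<- cur
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      score <- NA_real_
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2L) score <- as.numeric(m[2])
      cur <- list(score = score,
                  rows = data.frame(species = character(0), chrom = character(0),
                                    start = integer(0), size = integer(0),
                                    strand = character(0), src_size = integer(0),
                                    text = character(0), stringsAsFactors = FALSE))
    } else if (startsWith(ln, "s") && !is.null(cur)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      cur$rows <- rbind(cur$rows, data.frame(
        species = src[1],
        chrom = if (length(src) > 1) paste(src[-1], collapse = ".") else NA_character_,
        start = as.integer(f[3]), size = as.integer(f[4]), strand = f[5],
        src_size = as.integer(f[6]), text = f[7], stringsAsFactors = FALSE))
    }
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks Block list in the layout produced by [read_maf()].
#' @param path Output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(sprintf("a score=%s",
                       ifelse(is.na(b$score), "0", format(b$score))), con)
    r <- b$rows
    writeLines(sprintf("s %s.%s %d %d %s %d %s", r$species, r$chrom, r$start,
                       r$size, r$strand, r$src_size, r$text), con)
    writeLines("", con)
  }
}

# Map reference genomic positions to alignment columns within one block.
# Returns the column indices covering [start, end) on the reference row.
.block_columns <- function(ref_row, start, end) {
  chars <- strsplit(ref_row$text, "")[[1]]
  non_gap <- chars != "-"
  pos <- ref_row$start + cumsum(non_gap) - 1L   # genomic pos per non-gap col
  pos[!non_gap] <- NA_integer_
  which(!is.na(pos) & pos >= start & pos < end)
}

#' Extract the aligned slice covering a reference locus
#'
#' Finds the alignment blocks whose reference rows cover the requested
#' interval plus `flank` bases on each side, slices each block to the columns
#' whose reference positions fall inside the flanked interval, and stitches
#' the slices in reference order. Species present in some but not all
#' covering blocks are gap-filled over the blocks they miss; species absent
#' from every covering block are marked missing (`NA`).
#'
#' @param msa Block list from [read_maf()].
#' @param chrom Reference chromosome.
#' @param start,end Reference interval (0-based half-open).
#' @param reference_species Species id of the reference rows.
#' @param flank Flanking bases added on each side (default 9).
#' @return List of class `msa_block`: `chrom`, `interval` (flanked, clipped
#'   to available columns), `flank`, `reference_species`, and `rows` (named
#'   character vector of aligned strings; `NA` = species missing).
#' @export
extract_locus_alignment <- function(msa, chrom, start, end, reference_species,
                                    flank = 9L) {
  stopifnot(start < end, flank >= 0L)
  want_start <- max(0L, start - flank)
  want_end <- end + flank
  covering <- Filter(function(b) {
    r <- b$rows[b$rows$species == reference_species &
                  b$rows$chrom == chrom, , drop = FALSE]
    nrow(r) == 1L && r$start < want_end && (r$start + r$size) > want_start
  }, msa)
  if (length(covering) == 0L) {
    stop("interval ", chrom, ":", start, "-", end,
         " not covered by the alignment")
  }
  ref_starts <- vapply(covering, function(b) {
    b$rows$start[b$rows$species == reference_species & b$rows$chrom == chrom]
  }, integer(1))
  covering <- covering[order(ref_starts)]
  # the species universe is the whole alignment's: a species absent from
  # every covering block is reported as missing, not silently dropped
  species <- unique(unlist(lapply(msa, function(b) b$rows$species)))
  pieces <- lapply(covering, function(b) {
    ref_row <- b$rows[b$rows$species == reference_species &
                        b$rows$chrom == chrom, , drop = FALSE]
    cols <- .block_columns(ref_row, want_start, want_end)
    if (length(cols) == 0L) return(NULL)
    vapply(species, function(sp) {
      r <- b$rows[b$rows$species == sp, , drop = FALSE]
      if (nrow(r) == 0L) {
        strrep("-", length(cols))
      } else {
        paste(strsplit(r$text[1], "")[[1]][cols], collapse = "")
      }
    }, character(1))
  })
  pieces <- Filter(Negate(is.null), pieces)
  rows <- vapply(species, function(sp) {
    paste(vapply(pieces, `[[`, character(1), sp), collapse = "")
  }, character(1))
  # species never seen in any covering block are structurally missing
  present <- vapply(species, function(sp) {
    any(vapply(covering, function(b) sp %in% b$rows$species, logical(1)))
  }, logical(1))
  rows[!present] <- NA_character_
  out <- list(chrom = chrom, interval = c(want_start, want_end), flank = flank,
              reference_species = reference_species, rows = rows)
  class(out) <- "msa_block"
  out
}

#' Genomic identity and coverage of a species against the reference
#'
#' Identity is the fraction of matching columns among columns where both the
#' reference and the species rows are non-gap (case-insensitive). Coverage is
#' the fraction of the reference's non-gap columns where the species row is
#' also non-gap. The homology flag calls the species genomically homologous
#' when coverage reaches `min_coverage`.
#'
#' @param block An `msa_block` from [extract_locus_alignment()].
#' @param species Species id.
#' @param min_coverage Coverage required to flag homology (default 0.5).
#' @return List with `identity`, `coverage`, `homology_flag`, `n_shared`
#'   (shared non-gap columns); all `NA` when the species is missing.
#' @export
genomic_identity <- function(block, species, min_coverage = 0.5) {
  stopifnot(inherits(block, "msa_block"))
  ref <- block$rows[[block$reference_species]]
  if (!species %in% names(block$rows) || is.na(block$rows[[species]])) {
    return(list(identity = NA_real_, coverage = NA_real_,
                homology_flag = NA, n_shared = NA_integer_))
  }
  a <- toupper(strsplit(ref, "")[[1]])
  b <- toupper(strsplit(block$rows[[species]], "")[[1]])
  ref_ng <- a != "-"
  both <- ref_ng & b != "-"
  n_ref <- sum(ref_ng)
  n_shared <- sum(both)
  coverage <- if (n_ref == 0L) 0 else n_shared / n_ref
  identity <- if (n_shared == 0L) 0 else sum(a[both] == b[both]) / n_shared
  list(identity = identity, coverage = coverage,
       homology_flag = coverage >= min_coverage, n_shared = n_shared)
}

#' Score every species in an alignment block against a reference protein
#'
#' Convenience wrapper combining [genomic_identity()] and
#' [similarity_score()] for each non-reference species of a block. The
#' species' gapped row (including the flanks) is degapped, translated in
#' three frames and scored against the reference amino-acid sequence.
#'
#' @param block An `msa_block`.
#' @param reference_aa Reference protein sequence.
#' @param min_coverage Coverage required for the homology flag.
#' @return Data frame with one row per species: `species`, `score`,
#'   `best_frame`, `identity`, `coverage`, `homology_flag`.
#' @export
score_block <- function(block, reference_aa, min_coverage = 0.5) {
  sp_all <- setdiff(names(block$rows), block$reference_species)
  rows <- lapply(sp_all, function(sp) {
    gi <- genomic_identity(block, sp, min_coverage)
    row <- block$rows[[sp]]
    if (is.na(row)) {
      return(data.frame(species = sp, score = NA_real_,
                        best_frame = NA_integer_, identity = gi$identity,
                        coverage = gi$coverage, homology_flag = gi$homology_flag,
                        stringsAsFactors = FALSE))
    }
    ss <- similarity_score(reference_aa, row)
    data.frame(species = sp, score = ss$score, best_frame = ss$best_frame,
               identity = gi$identity, coverage = gi$coverage,
               homology_flag = gi$homology_flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
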