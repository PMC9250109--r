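#' Segment a TE-derived locus into homology blocks
#'
#' Aligns a locus against a reference (TE consensus or homologous locus),
#' slides a window of per-column identity along the alignment, thresholds it
#' into high- and low-identity states, cleans up short runs, and reports the
#' resulting contiguous blocks labelled A, B, C, ... from 5' to 3'. This is
#' the segmentation that, applied to a TE-derived exon, recovers the familiar
#' high-low-high identity pattern of an exonized region flanked by
#' better-conserved TE sequence. Per-block identity is recomputed exactly
#' from the alignment columns of the block, not from window averages.
#'
#' @param locus,reference Nucleotide strings. They are aligned globally
#'   end-to-end (Needleman-Wunsch via Biostrings); supply pre-trimmed
#'   homologous regions.
#' @param window Sliding-window width in alignment columns (step 1).
#' @param min_block Runs shorter than this are absorbed into their
#'   neighbourhood.
#' @param low_id_threshold Window identity at or above this is "high".
#' @param merge_gap Opposite-state interruptions of at most this many columns
#'   between same-state runs are merged.
#' @return A tibble with one row per block: `label`, `state` (`high`/`low`),
#'   `locus_start`, `locus_end`, `ref_start`, `ref_end` (1-based inclusive),
#'   `length` (locus bp), `identity` (exact, gap columns excluded).
#' @export
segment_blocks <- function(locus, reference, window = 30L, min_block = 50L,
                           low_id_threshold = 0.65, merge_gap = 30L) {
  check_dna(locus, arg = "locus"); check_dna(reference, arg = "reference")
  if (nchar(locus) < window) abort("`locus` is shorter than `window`")
  aln <- global_align(locus, reference)
  x <- seq_chars(aln$a); y <- seq_chars(aln$b)
  ncol <- length(x)
  if (ncol < window) abort("alignment shorter than `window`")
  m <- as.numeric(x == y & x != "-")           # gap columns count as mismatch
  wmean <- stats::filter(m, rep(1 / window, window), sides = 2)
  # pad the half-window ends with the nearest defined value
  wmean <- zoo_fill(as.numeric(wmean))
  state <- wmean >= low_id_threshold

  state <- clean_runs(state, min_block, merge_gap)

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  locus_pos <- cumsum(x != "-")
  ref_pos <- cumsum(y != "-")
  blocks <- purrr::map_dfr(seq_along(r$values), function(i) {
    cols <- starts[i]:ends[i]
    keep <- x[cols] != "-" & y[cols] != "-"
    tibble(
      state = if (r$values[i]) "high" else "low",
      locus_start = if (any(x[cols] != "-")) min(locus_pos[cols][x[cols] != "-"]) else NA_integer_,
      locus_end = if (any(x[cols] != "-")) max(locus_pos[cols]) else NA_integer_,
      ref_start = if (any(y[cols] != "-")) min(ref_pos[cols][y[cols] != "-"]) else NA_integer_,
      ref_end = if (any(y[cols] != "-")) max(ref_pos[cols]) else NA_integer_,
      identity = if (any(keep)) mean(x[cols][keep] == y[cols][keep]) else NA_real_
    )
  })
  blocks <- filter(blocks, !is.na(.data$locus_start))
  blocks$label <- LETTERS[seq_len(nrow(blocks))]
  blocks$length <- blocks$locus_end - blocks$locus_start + 1L
  select(blocks, "label", "state", "locus_start", "locus_end", "ref_start",
         "ref_end", "length", "identity")
}

# forward/backward fill of leading/trailing NAs from stats::filter
zoo_fill <- function(v) {
  ok <- which(!is.na(v))
  v[seq_len(ok[1] - 1)] <- v[ok[1]]
  n <- length(v)
  last <- ok[length(ok)]
  if (last < n) v[(last + 1):n] <- v[last]
  v
}

# merge short interruptions, then absorb any residual run below min_block
clean_runs <- function(state, min_block, merge_gap) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1) break
    # interior opposite-state runs no longer than merge_gap get flipped
    interior <- which(r$lengths <= merge_gap)
    interior <- interior[interior > 1 & interior < length(r$lengths)]
    if (length(interior) == 0) break
    i <- interior[which.min(r$lengths[interior])]
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
    state[starts[i]:ends[i]] <- !r$values[i]
  }
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1) break
    small <- which(r$lengths < min_block)
    if (length(small) == 0) break
    i <- small[which.min(r$lengths[small])]
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
    state[starts[i]:ends[i]] <- !r$values[i]
  }
  state
}

# end-to-end global alignment via Biostrings (match 2 / mismatch -3,
# gap open -5 / extend -2 in this package's gap convention)
global_align <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Detect terminal inverted repeats
#'
#' Finds the longest length `L` in `[min_len, max_len]` such that the first
#' `L` bases of the element equal the reverse complement of its last `L`
#' bases with at most `max_mismatch` mismatches — the TIR structure
#' characteristic of DNA transposons such as the hAT superfamily.
#'
#' @param element Nucleotide string.
#' @param min_len,max_len Candidate TIR length range in bp.
#' @param max_mismatch Maximum tolerated mismatches between the 5' TIR and
#'   the reverse complement of the 3' TIR.
#' @return A list of class `tir_result` (`length`, `five_prime`,
#'   `three_prime` 1-based intervals, `mismatches`), or `NULL` if no length
#'   in range qualifies.
#' @examples
#' te <- generate_te_consensus(400, tir_length = 14, seed = 1)
#' find_tir(te$sequence)$length
#' @export
find_tir <- function(element, min_len = 10L, max_len = 30L, max_mismatch = 0L) {
  check_dna(element, arg = "element")
  if (min_len > max_len) abort("`min_len` must be <= `max_len`")
  n <- nchar(element)
  if (n < 2 * min_len) abort("element shorter than 2 * min_len")
  for (L in seq(min(max_len, n %/% 2), min_len)) {
    p5 <- substr(element, 1, L)
    p3 <- revcomp(substr(element, n - L + 1L, n))
    mm <- sum(seq_chars(p5) != seq_chars(p3))
    if (mm <= max_mismatch) {
      return(structure(list(length = L,
                            five_prime = c(start = 1L, end = L),
                            three_prime = c(start = n - L + 1L, end = n),
                            mismatches = mm),
                       class = "tir_result"))
    }
  }
  NULL
}

#' @export
print.tir_result <- function(x, ...) {
  cat(sprintf("<tir_result> %d bp TIR (%d mismatch%s), 5' %d-%d / 3' %d-%d\n",
              x$length, x$mismatches, if (x$mismatches == 1) "" else "es",
              x$five_prime["start"], x$five_prime["end"],
              x$three_prime["start"], x$three_prime["end"]))
  invisible(x)
}
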