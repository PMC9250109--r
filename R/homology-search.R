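#' Alignment scoring scheme
#'
#' Scores for the local aligner. A gap of length `k` costs
#' `gap_open + k * gap_extend`: the opening penalty is charged on top of the
#' per-base extension for the first gapped base. Defaults approximate BLASTN
#' megablast-style scoring; the raw-score minimum in [scan_genome()] plays the
#' role an E-value cutoff plays in database searches, but is deterministic and
#' independent of database size.
#'
#' @param match Match score (> 0).
#' @param mismatch,gap_open,gap_extend Penalties (< 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  if (match <= 0) abort("`match` must be > 0")
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    abort("`mismatch`, `gap_open` and `gap_extend` must be < 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Returns the maximal-scoring local alignment of two nucleotide sequences
#' under affine gap costs (see [scoring_scheme()] for the gap convention).
#' `N` scores as a mismatch against everything.
#'
#' @param a,b Nucleotide strings over A, C, G, T, N.
#' @param scoring A [scoring_scheme()].
#' @return A list: `score`, `a_start`, `a_end`, `b_start`, `b_end` (1-based
#'   inclusive endpoints of the aligned regions), `a_gapped`, `b_gapped`
#'   (aligned strings with `-`), `identity` (matching fraction of non-gap
#'   columns) and `n_columns`.
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT")$score
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme()) {
  check_dna(a, arg = "a"); check_dna(b, arg = "b")
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  res <- .sw_align_cpp(a, b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  res$identity <- alignment_identity(res$a_gapped, res$b_gapped)
  res$n_columns <- nchar(res$a_gapped)
  res
}

# fraction of non-gap columns that match (gap columns excluded from the
# denominator, the usual BLAST "identities" convention)
alignment_identity <- function(ag, bg) {
  if (nchar(ag) == 0) return(NA_real_)
  x <- seq_chars(ag); y <- seq_chars(bg)
  keep <- x != "-" & y != "-"
  if (!any(keep)) return(NA_real_)
  mean(x[keep] == y[keep] & x[keep] != "N")
}

#' Scan a genome for TE-consensus-derived fragments
#'
#' Finds local matches of each consensus in a consensus library against each
#' genome contig, on both strands. Candidate regions are located by exact
#' k-mer seeding (shared `seed_kmer`-mers clustered by position), then aligned
#' in full with [smith_waterman()]; hits below `min_score` are dropped.
#'
#' @param genome Named character vector of contig sequences.
#' @param library A `te_consensus`, a list of them, or a named character
#'   vector of consensus sequences.
#' @param scoring A [scoring_scheme()].
#' @param min_score Minimum retained raw alignment score.
#' @param both_strands Also scan with the reverse-complemented query.
#' @param seed_kmer Exact-seed length for the prefilter.
#' @return A tibble of hits, sorted by contig then start: `query`, `contig`,
#'   `start`, `end` (1-based inclusive on the contig), `strand`, `score`,
#'   `identity`, `coverage` (aligned query fraction), `length`, and the
#'   aligned strings `qalign`/`talign` (query given 5'->3' on the hit strand).
#' @export
scan_genome <- function(genome, library, scoring = scoring_scheme(),
                        min_score = 60, both_strands = TRUE, seed_kmer = 11L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  lib <- as_te_library(library)
  if (length(lib) == 0) abort("consensus library is empty")
  rows <- list()
  for (contig in names(genome)) {
    gseq <- toupper(genome[[contig]])
    for (qname in names(lib)) {
      for (strand in if (both_strands) c("+", "-") else "+") {
        q <- if (strand == "-") revcomp(lib[[qname]]) else lib[[qname]]
        hits <- scan_one(q, gseq, scoring, min_score, seed_kmer)
        if (nrow(hits) > 0) {
          hits$query <- qname
          hits$contig <- contig
          hits$strand <- strand
          rows[[length(rows) + 1]] <- hits
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  out <- bind_rows(rows)
  out <- out[!duplicated(out[c("query", "contig", "start", "end", "strand")]), ]
  out <- cull_contained(out)
  out <- select(out, "query", "contig", "start", "end", "strand", "score",
                "identity", "coverage", "length", "qstart", "qend", "qlen",
                "qalign", "talign")
  arrange(out, .data$contig, .data$start, .data$end)
}

empty_hits <- function() {
  tibble(query = character(), contig = character(), start = integer(),
         end = integer(), strand = character(), score = numeric(),
         identity = numeric(), coverage = numeric(), length = integer(),
         qstart = integer(), qend = integer(), qlen = integer(),
         qalign = character(), talign = character())
}

# overlapping seed bands can rediscover parts of a copy already covered by a
# stronger alignment; drop any hit more than half-covered by a higher-scoring
# kept hit on the same contig (HSP culling)
cull_contained <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- arrange(hits, desc(.data$score), .data$start)
  keep <- logical(nrow(hits))
  for (ct in unique(hits$contig)) {
    idx <- which(hits$contig == ct)
    kept <- integer(0)
    for (i in idx) {
      ov <- if (length(kept) == 0) 0 else max(
        pmin(hits$end[kept], hits$end[i]) - pmax(hits$start[kept], hits$start[i]) + 1L)
      if (ov <= 0.5 * (hits$end[i] - hits$start[i] + 1L)) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  hits[keep, ]
}

as_te_library <- function(library) {
  if (inherits(library, "te_consensus")) {
    return(setNames(library$sequence, library$name))
  }
  if (is.list(library)) {
    return(setNames(
      vapply(library, te_sequence, character(1)),
      vapply(library, function(x) if (inherits(x, "te_consensus")) x$name else "query",
             character(1))))
  }
  stopifnot(is.character(library), !is.null(names(library)))
  library
}

# seed-and-extend for one (query, contig) pair; returns a tibble in contig
# coordinates (no query/contig/strand columns yet)
scan_one <- function(q, gseq, scoring, min_score, k) {
  qlen <- nchar(q); glen <- nchar(gseq)
  scan_cols <- c("start", "end", "score", "identity", "coverage", "length",
                 "qstart", "qend", "qlen", "qalign", "talign")
  if (glen < k || qlen < k) return(empty_hits()[0, scan_cols])
  qk <- substring(q, 1:(qlen - k + 1), k:qlen)
  gpos_all <- 1:(glen - k + 1)
  gkmers <- substring(gseq, gpos_all, gpos_all + k - 1)
  hit_idx <- which(gkmers %in% qk)
  if (length(hit_idx) == 0) return(empty_hits()[0, scan_cols])
  seed_pos <- gpos_all[hit_idx]
  # implied copy start for each seed (first query position of its k-mer);
  # seeds of a genuine copy pile up on nearly the same implied start, while
  # chance k-mer matches scatter
  qpos_first <- match(gkmers[hit_idx], qk)
  diag_start <- seed_pos - qpos_first + 1L
  slack <- max(50L, qlen %/% 10L)
  band_width <- 30L
  # a genuine copy of a long query yields hundreds of exact seeds (a 3 kb
  # query at ~5% divergence gives ~0.57 seeds/site); demanding ~1 seed per
  # 100 query bp rejects chance matches and the self-complementary TIR
  # echoes on the opposite strand, while staying permissive for short
  # queries. Detection fades beyond roughly 25-30% divergence.
  min_seeds <- if (qlen < 200) 1L else max(2L, (qlen - k + 1L) %/% 100L)
  ord <- order(diag_start, seed_pos)
  diag_o <- diag_start[ord]
  pos_o <- seed_pos[ord]
  brk <- c(0, which(diff(diag_o) > band_width | abs(diff(pos_o)) > qlen + slack),
           length(diag_o))
  # candidate windows from qualifying bands, merged where they overlap (a
  # copy whose k-mers recur in the query spawns several bands)
  wins <- list()
  for (ci in seq_len(length(brk) - 1)) {
    sel <- (brk[ci] + 1):brk[ci + 1]
    if (length(sel) < min_seeds) next
    wins[[length(wins) + 1]] <- c(max(1L, min(diag_o[sel]) - slack),
                                  min(glen, max(diag_o[sel]) + qlen - 1L + slack))
  }
  if (length(wins) == 0) return(empty_hits()[0, scan_cols])
  wins <- wins[order(vapply(wins, `[`, numeric(1), 1))]
  merged <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- merged[[length(merged)]]
    ov <- last[2] - w[1] + 1L
    # merge near-duplicate windows of one copy, but keep neighbouring
    # copies' windows apart so DP problems stay small
    if (ov >= 0.5 * min(w[2] - w[1] + 1L, last[2] - last[1] + 1L)) {
      merged[[length(merged)]] <- c(last[1], max(last[2], w[2]))
    } else {
      merged[[length(merged) + 1]] <- w
    }
  }
  rows <- list()
  for (win0 in merged) {
    # a window can hold several tandem copies: align, then recurse into the
    # unaligned flanks
    segments <- list(win0)
    while (length(segments) > 0) {
      seg <- segments[[1]]
      segments <- segments[-1]
      if (seg[2] - seg[1] + 1L < k) next
      aln <- smith_waterman(q, substr(gseq, seg[1], seg[2]), scoring)
      if (aln$score < min_score) next
      rows[[length(rows) + 1]] <- tibble(
        start = seg[1] + aln$b_start - 1L, end = seg[1] + aln$b_end - 1L,
        score = aln$score, identity = aln$identity,
        coverage = (aln$a_end - aln$a_start + 1) / qlen,
        length = aln$b_end - aln$b_start + 1L,
        qstart = aln$a_start, qend = aln$a_end, qlen = qlen,
        qalign = aln$a_gapped, talign = aln$b_gapped)
      segments <- c(segments,
                    list(c(seg[1], seg[1] + aln$b_start - 2L),
                         c(seg[1] + aln$b_end, seg[2])))
    }
  }
  if (length(rows) == 0) return(empty_hits()[0, scan_cols])
  bind_rows(rows)
}

#' Census TE copies under identity, coverage and deduplication thresholds
#'
#' Applies the copy-counting scheme used for TE copy-number estimates:
#' filter hits by minimum identity, then by minimum query coverage, then
#' greedily keep the best-scoring hit and discard any other hit on the same
#' contig whose start lies within `dedup_window` bp of a kept hit's start
#' (distance `<= dedup_window` is a duplicate). Ties on score are broken
#' toward the leftmost start. The operation is idempotent: censusing the
#' retained hits returns them unchanged.
#'
#' @param hits A hits tibble from [scan_genome()].
#' @param min_identity,min_coverage Retained hits have identity and coverage
#'   `>=` these fractions.
#' @param dedup_window Duplicate-removal window in bp on hit starts
#'   (0 disables deduplication of distinct starts).
#' @return The retained hits tibble, sorted by contig then start; the census
#'   count is its row count.
#' @examples
#' hits <- tibble::tibble(query = "te", contig = "chr", start = c(1, 130),
#'   end = c(100, 230), strand = "+", score = c(50, 40),
#'   identity = c(0.9, 0.8), coverage = c(0.9, 0.9))
#' nrow(census(hits, dedup_window = 150))  # 1: starts 129 bp apart
#' @export
census <- function(hits, min_identity = 0.65, min_coverage = 0.60,
                   dedup_window = 0L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1, dedup_window >= 0)
  keep <- filter(hits, .data$identity >= min_identity,
                 .data$coverage >= min_coverage)
  if (nrow(keep) <= 1 || dedup_window == 0) {
    return(arrange(keep, .data$contig, .data$start))
  }
  keep <- arrange(keep, desc(.data$score), .data$contig, .data$start)
  retained <- logical(nrow(keep))
  for (ct in unique(keep$contig)) {
    idx <- which(keep$contig == ct)
    kept_starts <- numeric(0)
    for (i in idx) {
      if (length(kept_starts) == 0 ||
          all(abs(keep$start[i] - kept_starts) > dedup_window)) {
        retained[i] <- TRUE
        kept_starts <- c(kept_starts, keep$start[i])
      }
    }
  }
  arrange(keep[retained, ], .data$contig, .data$start)
}
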