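#' Multiple alignments as named character vectors
#'
#' The package represents a multiple alignment as a named character vector of
#' equal-length gapped strings (`-` the only gap character). `msa_matrix()`
#' converts one to a character matrix (rows = members, columns = alignment
#' columns); `as_msa()` validates and normalises input (accepting a
#' `DNAStringSet`-like object, a list, or a named character vector).
#'
#' @param x Alignment input.
#' @return `as_msa()` returns a named character vector; `msa_matrix()` a
#'   character matrix.
#' @export
as_msa <- function(x) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (is.list(x)) x <- unlist(x)
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  x <- toupper(x)
  if (length(unique(nchar(x))) != 1) {
    abort("all aligned sequences must have equal gapped length")
  }
  if (!all(grepl("^[ACGTN-]*$", x))) {
    abort("aligned sequences must be over A,C,G,T,N,-")
  }
  x
}

#' @rdname as_msa
#' @export
msa_matrix <- function(x) {
  x <- as_msa(x)
  t(vapply(x, function(s) seq_chars(s), character(nchar(x[1]))))
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column, the most frequent base among A, C, G, T wins; ties are broken
#' alphabetically. Columns in which gaps are the strict majority are omitted
#' from the consensus. For a decayed TE family this approximates the
#' ancestral active element.
#'
#' @param msa A multiple alignment (see [as_msa()]); at least 2 members.
#' @return The consensus as a single string.
#' @export
majority_consensus <- function(msa) {
  m <- msa_matrix(msa)
  if (nrow(m) < 2) abort("need at least 2 aligned members")
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (sum(col == "-") > length(col) / 2) return("")
    counts <- table(factor(col[col %in% c("A", "C", "G", "T")],
                           levels = c("A", "C", "G", "T")))
    if (sum(counts) == 0) return("")
    names(counts)[which.max(counts)]  # which.max takes the first: A < C < G < T
  }, character(1))
  paste(cols, collapse = "")
}

#' p-distance with pairwise gap deletion
#'
#' The proportion of differing sites between two aligned sequences, after
#' excluding every column with a gap (or N) in either sequence.
#'
#' @param a_gapped,b_gapped Gapped strings of equal length.
#' @return A list: `p` and `sites_compared`. Zero comparable sites gives
#'   `p = NA` with `sites_compared = 0`.
#' @examples
#' p_distance("AC-T", "ACGT")  # 3 sites, p = 0
#' @export
p_distance <- function(a_gapped, b_gapped) {
  if (nchar(a_gapped) != nchar(b_gapped)) {
    abort("gapped sequences must have equal length")
  }
  x <- seq_chars(toupper(a_gapped)); y <- seq_chars(toupper(b_gapped))
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0) return(list(p = NA_real_, sites_compared = 0L))
  list(p = sum(x[keep] != y[keep]) / n, sites_compared = n)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) ln(1 - (4/3) p)`, correcting the observed proportion of
#' differing sites for multiple substitutions under equal exchange rates.
#' Saturated input (`p >= 0.75`) yields `NA` (an undefined distance); such
#' records are excluded from medians and counted separately downstream.
#'
#' @param p Observed proportion of differing sites.
#' @return The corrected distance (substitutions/site), or `NA` if saturated.
#' @examples
#' jc_distance(0.0521)  # ~0.054
#' @export
jc_distance <- function(p) {
  stopifnot(all(p >= 0 | is.na(p)))
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Kimura two-parameter distance
#'
#' `d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)` where `P` and `Q` are the
#' observed transition and transversion fractions. Inadmissible input
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) yields `NA`.
#'
#' @param P Transition fraction.
#' @param Q Transversion fraction.
#' @return The corrected distance, or `NA` if saturated.
#' @export
k2p_distance <- function(P, Q) {
  stopifnot(all(P >= 0 | is.na(P)), all(Q >= 0 | is.na(Q)))
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ifelse(is.na(w1) | w1 <= 0 | w2 <= 0, NA_real_,
         -0.5 * log(w1) - 0.25 * log(w2))
}

# observed transition / transversion fractions with pairwise deletion
pq_fractions <- function(a_gapped, b_gapped) {
  x <- seq_chars(toupper(a_gapped)); y <- seq_chars(toupper(b_gapped))
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0) return(list(P = NA_real_, Q = NA_real_, sites_compared = 0L))
  x <- x[keep]; y <- y[keep]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  list(P = sum(transition) / n, Q = sum(diff & !transition) / n,
       sites_compared = n)
}

#' Per-copy divergence to a consensus
#'
#' Computes, for each member of an alignment (or for each unaligned copy,
#' which is then globally aligned to the consensus), the observed p-distance
#' to the consensus and the model-corrected distance.
#'
#' @param copies Named character vector of copy sequences. If `aligned = TRUE`
#'   they must be gapped to the same length as `consensus`; otherwise each is
#'   aligned to the consensus pairwise (end-to-end).
#' @param consensus Consensus string (gapped to match if `aligned = TRUE`).
#' @param model `"JC"` or `"K2P"`.
#' @param aligned Are `copies` already aligned to `consensus`?
#' @return A tibble: `copy_name`, `p`, `d`, `model`, `sites_compared`.
#'   Saturated copies have `d = NA`.
#' @export
divergence_to_consensus <- function(copies, consensus, model = c("JC", "K2P"),
                                    aligned = FALSE) {
  model <- match.arg(model)
  stopifnot(is.character(copies), length(copies) >= 1)
  if (is.null(names(copies))) names(copies) <- paste0("copy_", seq_along(copies))
  purrr::map_dfr(names(copies), function(nm) {
    if (aligned) {
      ag <- copies[[nm]]; bg <- consensus
    } else {
      al <- global_align(copies[[nm]], consensus)
      ag <- al$a; bg <- al$b
    }
    pd <- p_distance(ag, bg)
    d <- if (model == "JC") {
      jc_distance(pd$p)
    } else {
      pq <- pq_fractions(ag, bg)
      k2p_distance(pq$P, pq$Q)
    }
    tibble(copy_name = nm, p = pd$p, d = d, model = model,
           sites_compared = pd$sites_compared)
  })
}

#' Bin per-copy divergences into a repeat landscape
#'
#' A repeat landscape is a histogram of the genome fraction annotated to each
#' TE family, binned by the copies' corrected divergence from the family
#' consensus — a proxy for the family's activity through time. Each copy
#' contributes `length / genome_size` to the bin containing its `d`;
#' saturated copies (`d = NA`) are excluded and counted.
#'
#' @param records Divergence tibble from [divergence_to_consensus()],
#'   optionally with a `family` column.
#' @param copy_lengths Copy lengths in bp (recycled if length 1).
#' @param genome_size Genome size in bp.
#' @param bin_width Bin width on the divergence axis.
#' @return A `te_landscape`: a tibble with `bin_low`, `bin_high`, `family`,
#'   `fraction`, carrying attributes `n_saturated` and `bin_width`.
#' @export
landscape <- function(records, copy_lengths, genome_size, bin_width = 0.01) {
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  if (genome_size <= 0) abort("`genome_size` must be > 0")
  stopifnot(length(copy_lengths) %in% c(1L, nrow(records)))
  rec <- mutate(records,
                length = rep_len(copy_lengths, nrow(records)),
                family = if ("family" %in% names(records)) .data$family else "TE")
  n_sat <- sum(is.na(rec$d))
  rec <- filter(rec, !is.na(.data$d))
  rec <- mutate(rec, bin = floor(.data$d / bin_width))
  out <- summarise(group_by(rec, .data$family, .data$bin),
                   fraction = sum(.data$length) / genome_size,
                   .groups = "drop")
  out <- mutate(out, bin_low = .data$bin * bin_width,
                bin_high = (.data$bin + 1) * bin_width)
  out <- select(arrange(out, .data$family, .data$bin_low),
                "bin_low", "bin_high", "family", "fraction")
  structure(out, n_saturated = n_sat, bin_width = bin_width,
            class = c("te_landscape", class(out)))
}

#' Insertion age from divergence to consensus
#'
#' Converts a median divergence-to-consensus into an insertion-age interval
#' via `T = d / r`: copies decay independently from the ancestral
#' (consensus-like) state, so divergence to consensus maps directly onto time
#' at the neutral substitution rate (no factor of two). For *Xenopus* the
#' rate is 3.0e-9 to 3.2e-9 substitutions/site/year, so a median divergence
#' of 0.054 corresponds to 17-18 Ma.
#'
#' @param d_median Median corrected divergence to consensus.
#' @param rate_low,rate_high Substitution-rate bounds, per site per year.
#' @return An `age_estimate` list: `d_median`, `rate_low`, `rate_high`,
#'   `age_low_ma` (`= d / rate_high / 1e6`), `age_high_ma`
#'   (`= d / rate_low / 1e6`). Rounding is left to the report layer.
#' @examples
#' estimate_age(0.054, 3.0e-9, 3.2e-9)
#' @export
estimate_age <- function(d_median, rate_low = 3.0e-9, rate_high = 3.2e-9) {
  if (d_median < 0) abort("`d_median` must be >= 0")
  if (rate_low <= 0 || rate_high <= 0) abort("rates must be > 0")
  if (rate_low > rate_high) abort("`rate_low` must be <= `rate_high`")
  structure(list(d_median = d_median, rate_low = rate_low,
                 rate_high = rate_high,
                 age_low_ma = d_median / rate_high / 1e6,
                 age_high_ma = d_median / rate_low / 1e6),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("<age_estimate> d = %.4g -> %.1f-%.1f Ma (r = %.2g-%.2g /site/yr)\n",
              x$d_median, x$age_low_ma, x$age_high_ma, x$rate_low, x$rate_high))
  invisible(x)
}

#' @rdname estimate_age
#' @param x An `age_estimate`.
#' @param ... Unused.
#' @export
glance.age_estimate <- function(x, ...) {
  tibble(d_median = x$d_median, rate_low = x$rate_low, rate_high = x$rate_high,
         age_low_ma = x$age_low_ma, age_high_ma = x$age_high_ma)
}

#' @rdname estimate_age
#' @export
tidy.age_estimate <- function(x, ...) glance.age_estimate(x)

#' Center-star multiple alignment
#'
#' A simple progressive aligner for small sequence sets: the center is the
#' sequence maximizing summed pairwise alignment scores; every other sequence
#' is aligned to it pairwise and gaps are propagated into the growing
#' alignment ("once a gap, always a gap"). Intended for the handfuls of TE
#' copies or exon homologs this package works with; larger sets should be
#' aligned externally and supplied as aligned FASTA.
#'
#' @param seqs Named character vector of 2-50 unaligned sequences.
#' @return A multiple alignment (named character vector of gapped strings,
#'   in input order); degapping any member recovers its input exactly.
#' @export
center_star_align <- function(seqs) {
  stopifnot(is.character(seqs))
  n <- length(seqs)
  if (n < 2) abort("need at least 2 sequences")
  if (n > 50) {
    abort("center_star_align handles at most 50 sequences; align externally and pass aligned FASTA")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_len(n))
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- global_align(seqs[[i]], seqs[[j]])$score
      scores[i, j] <- scores[j, i] <- s
    }
  }
  center <- which.max(rowSums(scores))
  # master = gapped center; rows = gapped members in master coordinates
  master <- seq_chars(seqs[[center]])
  rows <- list()
  rows[[center]] <- master
  for (i in setdiff(seq_len(n), center)) {
    al <- global_align(paste(master[master != "-"], collapse = ""), seqs[[i]])
    ac <- seq_chars(al$a); bc <- seq_chars(al$b)
    # map the new pairwise alignment onto the master, inserting any new gaps
    # into all existing rows
    new_master <- character(0)
    new_rows <- lapply(rows, function(r) character(0))
    new_row_i <- character(0)
    mi <- 1L  # next master column carrying a center base or an old gap
    take_master_gaps <- function() {
      while (mi <= length(master) && master[mi] == "-") {
        new_master <<- c(new_master, "-")
        for (k in seq_along(new_rows)) {
          if (!is.null(rows[[k]])) new_rows[[k]] <<- c(new_rows[[k]], rows[[k]][mi])
        }
        new_row_i <<- c(new_row_i, "-")
        mi <<- mi + 1L
      }
    }
    for (col in seq_along(ac)) {
      if (ac[col] != "-") take_master_gaps()
      if (ac[col] == "-") {
        # brand-new column: gap in center and in all existing rows
        new_master <- c(new_master, "-")
        for (k in seq_along(new_rows)) {
          if (!is.null(rows[[k]])) new_rows[[k]] <- c(new_rows[[k]], "-")
        }
        new_row_i <- c(new_row_i, bc[col])
      } else {
        new_master <- c(new_master, master[mi])
        for (k in seq_along(new_rows)) {
          if (!is.null(rows[[k]])) new_rows[[k]] <- c(new_rows[[k]], rows[[k]][mi])
        }
        new_row_i <- c(new_row_i, bc[col])
        mi <- mi + 1L
      }
    }
    take_master_gaps()
    master <- new_master
    for (k in seq_along(new_rows)) if (!is.null(rows[[k]])) rows[[k]] <- new_rows[[k]]
    rows[[i]] <- new_row_i
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  setNames(out, names(seqs))
}
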