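# Independent oracles and small fixture builders used across the suite.

# Local alignment score by plain dynamic programming WITHOUT the affine E/F
# shortcut: gap runs are scored by explicit enumeration over run lengths,
# gap(k) = gap_open + k * gap_extend. Only feasible for short sequences.
sw_oracle_score <- function(a, b, scoring = scoring_scheme()) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  gap <- function(k) scoring$gap_open + k * scoring$gap_extend
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (x[i] == y[j] && x[i] != "N") scoring$match else scoring$mismatch
      cand <- c(0, H[i, j] + s)
      for (k in 1:j) cand <- c(cand, H[i + 1, j + 1 - k] + gap(k))
      for (k in 1:i) cand <- c(cand, H[i + 1 - k, j + 1] + gap(k))
      H[i + 1, j + 1] <- max(cand)
    }
  }
  max(H)
}

# exhaustive TIR search over all (L, mismatch-count) pairs
tir_oracle <- function(element, min_len, max_len, max_mismatch) {
  n <- nchar(element)
  best <- NULL
  for (L in min_len:min(max_len, n %/% 2)) {
    p5 <- strsplit(substr(element, 1, L), "")[[1]]
    p3 <- strsplit(revcomp(substr(element, n - L + 1, n)), "")[[1]]
    mm <- sum(p5 != p3)
    if (mm <= max_mismatch) best <- list(length = L, mismatches = mm)
  }
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# global alignment of two sequences as gapped strings (independent of the
# package's internal aligner wrapper)
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# random additive tree on n taxa: returns list(phylo, D) with D the
# path-length matrix (an independent construction via ape's cophenetic)
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# default chimeric-locus fixture shared by exonization tests
chimeric_fixture <- function(variant = "default", seed = 101, n_homologs = 4,
                             homolog_d = 0.02) {
  g <- withr::with_seed(seed, setNames(rand_seq(4000), "chr_sim"))
  te <- generate_te_consensus(1000, 14, seed = seed)
  chim <- implant_chimeric_locus(g, te, script = exonization_script(variant),
                                 seed = seed + 1)
  hom <- simulate_homologs(chim$truth$ancestral_fragment, n = n_homologs,
                           d = homolog_d, seed = seed + 2)
  list(chim = chim, homologs = hom)
}
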