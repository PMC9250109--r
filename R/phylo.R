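#' Pairwise corrected distance matrix from an alignment
#'
#' Computes all pairwise distances between alignment members under the
#' Jukes-Cantor or Kimura two-parameter model, with pairwise gap deletion
#' (each pair uses exactly its mutually ungapped columns).
#'
#' @param msa A multiple alignment (see [as_msa()]) with >= 3 members.
#' @param model `"JC"` or `"K2P"`.
#' @return A symmetric numeric matrix with zero diagonal and the member
#'   names as dimnames, with attribute `model`.
#' @export
distance_matrix <- function(msa, model = c("JC", "K2P")) {
  model <- match.arg(model)
  msa <- as_msa(msa)
  n <- length(msa)
  if (n < 3) abort("need at least 3 aligned members")
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (model == "JC") {
        jc_distance(p_distance(msa[[i]], msa[[j]])$p)
      } else {
        pq <- pq_fractions(msa[[i]], msa[[j]])
        k2p_distance(pq$P, pq$Q)
      }
      if (is.na(d)) {
        abort(sprintf("saturated pair: %s vs %s", names(msa)[i], names(msa)[j]))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion agglomeration, here via
#' `ape::nj()`). An additive distance matrix is recovered exactly (topology
#' and branch lengths). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with a message.
#'
#' @param D Symmetric distance matrix with >= 3 taxa (or a `dist`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D))
  if (nrow(D) < 3) abort("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative NJ branch length(s) to 0", sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

# the non-trivial bipartitions (as sorted tip-label character keys of the
# smaller side, ties by alphabetical first element) induced by the internal
# edges of an unrooted tree; names are the edge indices
tree_bipartitions <- function(tr) {
  ntip <- length(tr$tip.label)
  internal <- which(tr$edge[, 2] > ntip)
  if (length(internal) == 0) return(character(0))
  keys <- vapply(internal, function(e) {
    node <- tr$edge[e, 2]
    tips <- unlist(tip_descendants(tr, node))
    side <- sort(tr$tip.label[tips])
    other <- sort(setdiff(tr$tip.label, side))
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    canon <- if (length(side) < length(other) ||
                 (length(side) == length(other) && a < b)) a else b
    canon
  }, character(1))
  setNames(keys, internal)
}

# tip descendants of a node (own recursion on the edge table)
tip_descendants <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_descendants, tr = tr))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Nonparametric bootstrap: alignment columns are resampled with replacement
#' `n_reps` times, the distance matrix and NJ tree are rebuilt per replicate,
#' and each internal edge of the full-data tree receives the percentage of
#' replicates whose tree contains the same bipartition. Replicates in which
#' any pair saturates are dropped and counted; the support denominator is
#' the number of successful replicates.
#'
#' @param msa Multiple alignment with >= 4 members (3-taxon trees have no
#'   internal edge).
#' @param n_reps Number of bootstrap replicates.
#' @param model Distance model, as in [distance_matrix()].
#' @param seed Optional integer seed (fixed seed: identical supports).
#' @return A list of class `nj_bootstrap`: `tree` (the full-data NJ `phylo`
#'   with `node.label` set to the supports), `supports` (tibble: `edge`,
#'   `bipartition`, `support` in 0-100), `n_reps`, `n_dropped`.
#' @export
bootstrap_nj <- function(msa, n_reps = 1000L, model = "JC", seed = NULL) {
  stopifnot(n_reps >= 1)
  msa <- as_msa(msa)
  m <- msa_matrix(msa)
  full <- neighbor_joining(distance_matrix(msa, model))
  bip <- tree_bipartitions(full)
  counts <- setNames(numeric(length(bip)), names(bip))
  n_dropped <- 0L
  with_seed_(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      tr <- tryCatch(
        suppressMessages(neighbor_joining(distance_matrix(rep_msa, model))),
        error = function(e) NULL)
      if (is.null(tr)) {
        n_dropped <- n_dropped + 1L
        next
      }
      rep_bip <- tree_bipartitions(tr)
      hit <- bip %in% rep_bip
      counts[hit] <- counts[hit] + 1
    }
  })
  n_ok <- n_reps - n_dropped
  if (n_ok == 0) abort("all bootstrap replicates saturated")
  support <- 100 * counts / n_ok
  # node labels: supports attached to the child node of each internal edge
  ntip <- length(full$tip.label)
  labs <- rep(NA_character_, full$Nnode)
  for (k in seq_along(bip)) {
    node <- full$edge[as.integer(names(bip)[k]), 2]
    labs[node - ntip] <- sprintf("%.0f", support[k])
  }
  full$node.label <- labs
  structure(list(tree = full,
                 supports = tibble(edge = as.integer(names(bip)),
                                   bipartition = unname(bip),
                                   support = unname(support)),
                 n_reps = n_reps, n_dropped = n_dropped),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat(sprintf("<nj_bootstrap> %d tips, %d replicates (%d dropped)\n",
              length(x$tree$tip.label), x$n_reps, x$n_dropped))
  print(x$supports)
  invisible(x)
}

#' Write a support-labelled tree to Newick
#'
#' @param x An `nj_bootstrap` or `phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(x, path) {
  tr <- if (inherits(x, "nj_bootstrap")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}
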