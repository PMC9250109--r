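#' Read an exon's coding segment from a splice-defined frame
#'
#' Reads codons from `frame_offset` bases into the exon (the exon is assumed
#' to begin immediately after the splice-acceptor AG) up to and including the
#' first in-frame stop. This models a C-terminal coding continuation: the
#' reading frame comes in from the upstream exon, so no ATG is sought.
#'
#' @param exon_seq Exon nucleotide string (A, C, G, T only).
#' @param frame_offset 0, 1 or 2: bases to skip before the first codon.
#' @return `NULL` if no in-frame stop exists; otherwise a list with
#'   `cds_start`, `cds_end` (1-based on the exon, including the stop codon),
#'   `peptide` (string), `peptide_length` (residues, excluding the stop) and
#'   `stop_codon`.
#' @examples
#' exon_cds("ATGTAA")$peptide_length  # 1
#' @export
exon_cds <- function(exon_seq, frame_offset = 0L) {
  check_dna(exon_seq, allow_n = FALSE, arg = "exon_seq")
  stopifnot(frame_offset %in% 0:2)
  s <- substr(exon_seq, frame_offset + 1L, nchar(exon_seq))
  aa <- translate_nt(s)
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) return(NULL)
  k <- stop_at[1]
  list(
    cds_start = frame_offset + 1L,
    cds_end = frame_offset + 3L * k,
    peptide = paste(aa[seq_len(k - 1)], collapse = ""),
    peptide_length = k - 1L,
    stop_codon = substr(s, 3L * k - 2L, 3L * k)
  )
}

#' Differences between two aligned sequences as typed mutation events
#'
#' Walks a pairwise alignment of an ancestral-like homolog against a
#' candidate sequence and emits one event per substitution column and one
#' per maximal gap run (a run of gaps in the candidate is a deletion; in the
#' homolog, an insertion). Positions are reported in alignment columns with
#' projections onto both sequences.
#'
#' @param ancestral_gapped,candidate_gapped Gapped strings of equal length.
#' @return A tibble: `column` (first alignment column of the event), `type`
#'   (`substitution`/`deletion`/`insertion`, relative to ancestral ->
#'   candidate), `ancestral`, `derived` (event texts; `""` for the absent
#'   side), `anc_pos`, `cand_pos` (1-based positions on each ungapped
#'   sequence: the substituted base; for a deletion, the first deleted
#'   ancestral base and the candidate position where the text would be
#'   re-inserted; for an insertion, vice versa).
#' @examples
#' diff_events("ACGTA", "AC-TA")
#' @export
diff_events <- function(ancestral_gapped, candidate_gapped) {
  if (nchar(ancestral_gapped) != nchar(candidate_gapped)) {
    abort("gapped sequences must have equal length")
  }
  x <- seq_chars(toupper(ancestral_gapped))
  y <- seq_chars(toupper(candidate_gapped))
  if (any(x == "-" & y == "-")) abort("all-gap columns are not allowed")
  apos <- cumsum(x != "-")
  cpos <- cumsum(y != "-")
  kind <- ifelse(x == "-", "ins", ifelse(y == "-", "del",
                 ifelse(x != y, "sub", "same")))
  rows <- list()
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (kind[i] == "same") { i <- i + 1L; next }
    if (kind[i] == "sub") {
      rows[[length(rows) + 1]] <- tibble(
        column = i, type = "substitution", ancestral = x[i], derived = y[i],
        anc_pos = apos[i], cand_pos = cpos[i])
      i <- i + 1L
    } else {
      j <- i
      while (j < n && kind[j + 1L] == kind[i]) j <- j + 1L
      if (kind[i] == "del") {
        rows[[length(rows) + 1]] <- tibble(
          column = i, type = "deletion",
          ancestral = paste(x[i:j], collapse = ""), derived = "",
          anc_pos = apos[i], cand_pos = cpos[i] + 1L)
      } else {
        rows[[length(rows) + 1]] <- tibble(
          column = i, type = "insertion", ancestral = "",
          derived = paste(y[i:j], collapse = ""),
          anc_pos = apos[i] + 1L, cand_pos = cpos[i])
      }
      i <- j + 1L
    }
  }
  if (length(rows) == 0) return(empty_events())
  bind_rows(rows)
}

empty_events <- function() {
  tibble(column = integer(), type = character(), ancestral = character(),
         derived = character(), anc_pos = integer(), cand_pos = integer())
}

# apply ancestral->candidate events (in ancestral coordinates) to a sequence;
# events must be non-overlapping. Used to revert/replay mutation paths.
apply_events <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  ev <- arrange(events, desc(.data$anc_pos))
  for (k in seq_len(nrow(ev))) {
    p <- ev$anc_pos[k]
    seq <- switch(ev$type[k],
      substitution = paste0(substr(seq, 1, p - 1L), ev$derived[k],
                            substr(seq, p + nchar(ev$ancestral[k]), nchar(seq))),
      deletion = paste0(substr(seq, 1, p - 1L),
                        substr(seq, p + nchar(ev$ancestral[k]), nchar(seq))),
      insertion = paste0(substr(seq, 1, p - 1L), ev$derived[k],
                         substr(seq, p, nchar(seq))))
  }
  seq
}

#' Classify the coding effects of mutation events
#'
#' Annotates ancestral -> candidate events with their effect on the
#' candidate's reading frame and stop-codon structure. Indels whose length is
#' not a multiple of 3 are frameshifts; a frameshift is `frameshift_remove`
#' when reverting it on the candidate destroys the observed open reading
#' frame (i.e. the event was needed to bring the downstream stop into frame)
#' and `frameshift_introduce` otherwise. A substitution that creates the
#' in-frame stop terminating the CDS is `stop_gain`; one creating an in-frame
#' stop strictly inside the CDS is `premature_stop`; a substitution in a
#' codon whose amino acid changes is `missense`, otherwise `silent`.
#'
#' @param events Event tibble from [diff_events()].
#' @param candidate Candidate exon sequence (ungapped).
#' @param frame_offset Reading-frame offset of the candidate exon.
#' @return `events` with an `effect` column added.
#' @export
classify_effects <- function(events, candidate, frame_offset = 0L) {
  if (nrow(events) == 0) return(mutate(events, effect = character(0)))
  if (any(events$cand_pos > nchar(candidate) + 1L)) {
    abort("events fall outside the candidate exon")
  }
  cds <- exon_cds(candidate, frame_offset)
  effect <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    type <- events$type[k]
    if (type %in% c("deletion", "insertion")) {
      len <- nchar(if (type == "deletion") events$ancestral[k] else events$derived[k])
      if (len %% 3L != 0L) {
        # reverting the event on the candidate tells its direction: if the
        # observed ORF is destroyed, the event was needed to bring the stop
        # into frame
        reverted <- revert_event_on_candidate(candidate, events[k, ])
        rcds <- exon_cds(reverted, frame_offset)
        effect[k] <- if (is.null(rcds)) "frameshift_remove" else "frameshift_introduce"
      } else {
        effect[k] <- "inframe_indel"
      }
    } else {
      effect[k] <- classify_substitution(events[k, ], candidate, frame_offset, cds)
    }
  }
  # among stop-creating substitutions, the downstream-most terminates the
  # reading; any other is premature relative to it
  stops <- which(effect == "stop_gain")
  if (length(stops) > 1) {
    keep <- stops[which.max(events$cand_pos[stops])]
    effect[setdiff(stops, keep)] <- "premature_stop"
  }
  mutate(events, effect = effect)
}

# revert one ancestral->candidate event in candidate coordinates
revert_event_on_candidate <- function(candidate, ev) {
  p <- ev$cand_pos
  switch(ev$type,
    substitution = paste0(substr(candidate, 1, p - 1L), ev$ancestral,
                          substr(candidate, p + nchar(ev$derived), nchar(candidate))),
    deletion = paste0(substr(candidate, 1, p - 1L), ev$ancestral,
                      substr(candidate, p, nchar(candidate))),
    insertion = paste0(substr(candidate, 1, p - 1L),
                       substr(candidate, p + nchar(ev$derived), nchar(candidate))))
}

classify_substitution <- function(ev, candidate, frame_offset, cds) {
  p <- ev$cand_pos
  rel <- p - frame_offset
  if (rel < 1) return("noncoding")
  codon_i <- (rel - 1L) %/% 3L
  c0 <- frame_offset + 3L * codon_i + 1L
  cand_codon <- substr(candidate, c0, c0 + 2L)
  if (nchar(cand_codon) < 3L) return("noncoding")
  anc_codon <- cand_codon
  substr(anc_codon, p - c0 + 1L, p - c0 + 1L) <- ev$ancestral
  cand_stop <- cand_codon %in% STOP_CODONS
  anc_stop <- anc_codon %in% STOP_CODONS
  if (cand_stop && !anc_stop) return("stop_gain")
  if (!cand_stop && anc_stop) return("stop_loss")
  if (!is.null(cds) && c0 > cds$cds_end) return("noncoding")
  aa1 <- translate_nt(anc_codon); aa2 <- translate_nt(cand_codon)
  if (identical(aa1, aa2)) "silent" else "missense"
}

#' Reconstruct the mutation path that opened an exon's reading frame
#'
#' Given a candidate exon and a set of homologs representing the ancestral
#' (non-coding) state, polarizes the differences between candidate and
#' homologs, classifies their coding effects, and searches for the minimal
#' subset of polarized events that jointly open the observed reading frame:
#' applying that subset to the ancestral reconstruction must reproduce the
#' candidate's peptide length exactly.
#'
#' An event is polarized (called ancestral -> derived) when the candidate
#' differs while a strict majority of homologs agree among themselves on the
#' ancestral state; sites where the homologs disagree are reported as
#' `unpolarizable` and excluded from the minimal set. With a single homolog
#' every event is reported unpolarized, with a warning.
#'
#' @param candidate Candidate exon sequence.
#' @param homologs Named character vector of >= 1 homolog sequences.
#' @param frame_offset Reading-frame offset of the candidate.
#' @return An `exonization_report` list: `peptide_length`, `stop_codon`,
#'   `cds` (the [exon_cds()] result), `events` (polarized, classified),
#'   `unpolarizable` (tibble), `minimal_set` (tibble; the minimal
#'   ORF-enabling events), `homolog_names`, and `no_signal` (`TRUE` when the
#'   candidate matches the homolog consensus).
#' @export
reconstruct_path <- function(candidate, homologs, frame_offset = 0L) {
  check_dna(candidate, allow_n = FALSE, arg = "candidate")
  stopifnot(is.character(homologs), length(homologs) >= 1)
  if (is.null(names(homologs))) names(homologs) <- paste0("homolog_", seq_along(homologs))
  single <- length(homologs) == 1
  if (single) {
    warn("single homolog: events reported unpolarized")
  }
  per_hom <- purrr::map(homologs, function(h) {
    al <- global_align(h, candidate)
    diff_events(al$a, al$b)
  })
  all_ev <- bind_rows(per_hom, .id = "homolog")
  if (nrow(all_ev) == 0) {
    cds <- exon_cds(candidate, frame_offset)
    return(new_exonization_report(candidate, cds, empty_events_eff(),
                                  empty_events_eff(), empty_events_eff(),
                                  names(homologs), no_signal = TRUE))
  }
  # an event is a candidate-vs-ancestor difference when seen against a strict
  # majority of homologs. For substitutions the homologs must agree on the
  # ancestral base; for indels presence/length is the character and the
  # ancestral text is read from the modal homolog (homolog-private noise
  # inside a deleted tract must not break polarization).
  need <- if (single) 1L else floor(length(homologs) / 2) + 1L
  grp <- dplyr::count(all_ev, .data$type, .data$cand_pos, .data$derived,
                      .data$ancestral, name = "n_anc")
  by_site <- group_by(grp, .data$type, .data$cand_pos, .data$derived)
  best <- ungroup(summarise(
    by_site,
    n_support = sum(.data$n_anc),
    n_modal = max(.data$n_anc),
    ancestral = .data$ancestral[which.max(.data$n_anc)],
    .groups = "drop"))
  is_sub <- best$type == "substitution"
  ok <- ifelse(is_sub, best$n_modal >= need, best$n_support >= need)
  polarized <- best[ok, ]
  unpol <- best[!ok, ]
  polarized <- select(polarized, "type", "ancestral", "derived", "cand_pos",
                      "n_support")
  unpol <- select(unpol, "type", "ancestral", "derived", "cand_pos",
                  "n_support")
  polarized <- classify_effects(add_anc_pos(polarized, candidate),
                                candidate, frame_offset)
  unpol <- if (nrow(unpol)) {
    classify_effects(add_anc_pos(unpol, candidate), candidate, frame_offset)
  } else {
    empty_events_eff()
  }
  cds <- exon_cds(candidate, frame_offset)
  minimal <- find_minimal_set(candidate, polarized, frame_offset, cds)
  new_exonization_report(candidate, cds, polarized, unpol, minimal,
                         names(homologs),
                         no_signal = nrow(polarized) == 0)
}

empty_events_eff <- function() mutate(empty_events(), effect = character(0))

# ancestral-reconstruction coordinates for events expressed on the candidate:
# revert all events (descending cand_pos) and track each event's position on
# the reconstructed ancestor.
add_anc_pos <- function(ev, candidate) {
  ev <- arrange(ev, .data$cand_pos, .data$type)
  shift <- 0L
  anc_pos <- integer(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    anc_pos[k] <- ev$cand_pos[k] + shift
    shift <- shift + nchar(ev$ancestral[k]) - nchar(ev$derived[k])
  }
  mutate(ev, anc_pos = anc_pos, column = anc_pos)
}

# exhaustive subset search (size <= max_size) over polarized events, smallest
# first; falls back to greedy beyond that. The target is reproducing the
# candidate's observed peptide length from the ancestral reconstruction.
find_minimal_set <- function(candidate, polarized, frame_offset, cds,
                             max_size = 6L) {
  if (is.null(cds) || nrow(polarized) == 0) return(polarized[0, ])
  ancestor <- candidate
  for (k in order(polarized$cand_pos, decreasing = TRUE)) {
    ancestor <- revert_event_on_candidate(ancestor, polarized[k, ])
  }
  target <- cds$peptide_length
  ok <- function(idx) {
    trial <- apply_events(ancestor, polarized[idx, ])
    tc <- exon_cds(trial, frame_offset)
    !is.null(tc) && tc$peptide_length == target
  }
  a0 <- exon_cds(ancestor, frame_offset)
  if (!is.null(a0) && a0$peptide_length == target) return(polarized[0, ])
  n <- nrow(polarized)
  for (size in seq_len(min(n, max_size))) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      if (ok(idx)) return(polarized[idx, ])
    }
  }
  # greedy fallback for pathological event counts
  idx <- integer(0)
  for (k in order(-abs(nchar(polarized$ancestral) - nchar(polarized$derived)))) {
    idx <- c(idx, k)
    if (ok(idx)) return(polarized[sort(idx), ])  # nocov
  }
  polarized  # nocov
}

new_exonization_report <- function(candidate, cds, events, unpolarizable,
                                   minimal_set, homolog_names, no_signal) {
  structure(list(
    candidate = candidate,
    peptide_length = if (is.null(cds)) NA_integer_ else cds$peptide_length,
    stop_codon = if (is.null(cds)) NA_character_ else cds$stop_codon,
    cds = cds,
    events = events,
    unpolarizable = unpolarizable,
    minimal_set = minimal_set,
    homolog_names = homolog_names,
    no_signal = no_signal
  ), class = "exonization_report")
}

#' @export
print.exonization_report <- function(x, ...) {
  cat("<exonization_report>\n")
  if (x$no_signal) cat("  no exonization signal\n")
  cat(sprintf("  peptide: %s residues, stop %s\n",
              x$peptide_length, x$stop_codon))
  cat(sprintf("  events: %d polarized (%d unpolarizable), minimal ORF-enabling set: %d\n",
              nrow(x$events), nrow(x$unpolarizable), nrow(x$minimal_set)))
  if (nrow(x$minimal_set) > 0) print(x$minimal_set)
  invisible(x)
}

#' @rdname reconstruct_path
#' @param x An `exonization_report`.
#' @param ... Unused.
#' @export
tidy.exonization_report <- function(x, ...) {
  mutate(x$events, in_minimal_set = paste(.data$type, .data$cand_pos) %in%
           paste(x$minimal_set$type, x$minimal_set$cand_pos))
}

#' @rdname reconstruct_path
#' @export
glance.exonization_report <- function(x, ...) {
  tibble(peptide_length = x$peptide_length, stop_codon = x$stop_codon,
         n_events = nrow(x$events), n_unpolarizable = nrow(x$unpolarizable),
         n_minimal = nrow(x$minimal_set), no_signal = x$no_signal)
}

#' Compare exonization reports across species
#'
#' @param reports Named list of `exonization_report`s (one per species or
#'   variant).
#' @return A tibble sorted by name: `name`, `peptide_length`, `stop_codon`,
#'   `n_events`, `n_minimal`, `distinguishing` (comma-separated effects of
#'   events not shared by every report).
#' @export
variant_table <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1)
  if (is.null(names(reports))) names(reports) <- paste0("report_", seq_along(reports))
  keys <- purrr::map(reports, function(r) {
    paste(r$events$type, r$events$cand_pos, r$events$derived)
  })
  shared <- Reduce(intersect, keys)
  out <- purrr::map_dfr(names(reports), function(nm) {
    r <- reports[[nm]]
    own <- !(keys[[nm]] %in% shared)
    tibble(name = nm,
           peptide_length = r$peptide_length,
           stop_codon = r$stop_codon,
           n_events = nrow(r$events),
           n_minimal = nrow(r$minimal_set),
           distinguishing = paste(r$events$effect[own], collapse = ","))
  })
  arrange(out, .data$name)
}
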