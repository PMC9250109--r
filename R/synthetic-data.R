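#' Generate a TE consensus with terminal inverted repeats
#'
#' Builds a random consensus sequence for a DNA-transposon family in the hAT
#' style: the first `tir_length` bases are the reverse complement of the last
#' `tir_length` bases (terminal inverted repeats, TIRs), with random interior.
#'
#' @param length Total element length in bp.
#' @param tir_length TIR length in bp (0 for no TIR constraint). hAT-family
#'   elements carry short TIRs, typically around 14 bp.
#' @param gc_fraction GC content of the random draw, in `[0, 1]`.
#' @param seed Optional integer seed; fixed seed gives an identical element.
#' @param name,family Element identifiers carried through annotations.
#' @return An object of class `te_consensus`: a list with `name`, `family`,
#'   `sequence` and `tir_length`.
#' @examples
#' te <- generate_te_consensus(1000, tir_length = 14, seed = 1)
#' substr(te$sequence, 1, 14) == revcomp(substr(te$sequence, 987, 1000))
#' @export
generate_te_consensus <- function(length, tir_length = 14L, gc_fraction = 0.4,
                                  seed = NULL, name = "hAT-10-like-1",
                                  family = "hAT-10-like") {
  if (tir_length < 0) abort("`tir_length` must be >= 0")
  if (length < 2 * tir_length + 1) {
    abort("`length` must be at least 2 * tir_length + 1")
  }
  seqn <- with_seed_(seed, {
    core <- random_dna(length - 2 * tir_length, gc_fraction)
    # the implanted TIR length is exact truth: keep the inverted repeat from
    # extending by chance into the interior
    if (tir_length > 0 && nchar(core) >= 2) {
      first <- substr(core, 1, 1)
      while (substr(core, 1, 1) == revcomp(substr(core, nchar(core), nchar(core)))) {
        substr(core, 1, 1) <- sample(setdiff(c("A", "C", "G", "T"), first), 1)
      }
    }
    tir <- if (tir_length > 0) random_dna(tir_length, gc_fraction) else ""
    paste0(tir, core, if (tir_length > 0) revcomp(tir) else "")
  })
  structure(list(name = name, family = family, sequence = seqn,
                 tir_length = as.integer(tir_length)),
            class = "te_consensus")
}

#' @export
print.te_consensus <- function(x, ...) {
  cat(sprintf("<te_consensus> %s (%s): %d bp, %d bp TIRs\n",
              x$name, x$family, nchar(x$sequence), x$tir_length))
  invisible(x)
}

te_sequence <- function(x) {
  if (inherits(x, "te_consensus")) x$sequence else check_dna(x, arg = "consensus")
}

#' Convert between Jukes-Cantor distance and substitution probability
#'
#' Under the Jukes-Cantor model the per-site probability that a site differs
#' after divergence `d` is `p = (3/4) (1 - exp(-4 d / 3))`; `jc_distance()`
#' is its inverse.
#'
#' @param d Jukes-Cantor distance (substitutions/site).
#' @return Substitution probability in `[0, 0.75)`.
#' @seealso [jc_distance()]
#' @export
jc_p_from_d <- function(d) {
  stopifnot(all(d >= 0))
  0.75 * (1 - exp(-4 * d / 3))
}

#' Evolve a TE copy to a target divergence
#'
#' Decays a consensus to a copy of known age under the Jukes-Cantor model:
#' every site is substituted independently with probability
#' `p = (3/4)(1 - exp(-4 d/3))` to a uniformly chosen different base.
#' Optionally, indels are laid down at a per-site rate with geometric lengths
#' (mean 2); insertions and deletions are equally likely.
#'
#' @param consensus A `te_consensus` or a plain nucleotide string.
#' @param target_d Target Jukes-Cantor divergence (substitutions/site).
#' @param indel_rate Per-site indel rate (default 0: substitutions only).
#' @param seed Optional integer seed.
#' @return A list with `sequence` (the evolved copy), `d_true` (the target
#'   divergence, the copy's truth value), `n_sub` (substitutions drawn) and
#'   `n_indel`.
#' @export
evolve_copy <- function(consensus, target_d, indel_rate = 0, seed = NULL) {
  s <- te_sequence(consensus)
  if (target_d < 0) abort("`target_d` must be >= 0")
  p <- jc_p_from_d(target_d)
  if (p >= 0.75) abort("`target_d` implies substitution probability >= 0.75")
  with_seed_(seed, {
    bases <- seq_chars(s)
    n <- length(bases)
    hit <- which(runif(n) < p)
    if (length(hit) > 0) {
      # uniform choice among the three other bases, as a cyclic offset
      alphabet <- c("A", "C", "G", "T")
      old <- match(bases[hit], alphabet) - 1L
      if (anyNA(old)) old[is.na(old)] <- sample.int(4L, sum(is.na(old)), replace = TRUE) - 1L
      offset <- sample.int(3L, length(hit), replace = TRUE)
      bases[hit] <- alphabet[(old + offset) %% 4L + 1L]
    }
    n_indel <- 0L
    if (indel_rate > 0) {
      # geometric lengths with mean 2 (p = 0.5, support 1, 2, ...)
      sites <- which(runif(n) < indel_rate)
      for (i in rev(sites)) {
        len <- stats::rgeom(1, 0.5) + 1L
        if (runif(1) < 0.5) {
          bases <- append(bases, seq_chars(random_dna(len, 0.5)), after = i)
        } else {
          drop <- i:min(i + len - 1L, length(bases))
          bases <- bases[-drop]
        }
        n_indel <- n_indel + 1L
      }
    }
    list(sequence = paste(bases, collapse = ""), d_true = target_d,
         n_sub = length(hit), n_indel = n_indel)
  })
}

#' Implant TE copies of known age into a genome
#'
#' Inserts independently decayed copies of a consensus at collision-free
#' random positions. Each copy's truth divergence is `d = r * T` with `T` its
#' age in years (`age_ma * 1e6`) and `r` the per-site yearly substitution
#' rate, so downstream divergence-to-consensus dating can be checked against
#' the simulated ages.
#'
#' @param genome Named character vector of length 1 (contig name -> sequence).
#' @param consensus A `te_consensus`.
#' @param ages_ma Numeric vector of insertion ages in Ma, one per copy.
#' @param rate Substitution rate per site per year (default 3.1e-9, mid-range
#'   for *Xenopus*).
#' @param indel_rate Per-site indel rate passed to [evolve_copy()].
#' @param min_spacing Minimum bp between implanted copies.
#' @param seed Optional integer seed; fixed seed gives a byte-identical genome.
#' @return A list with `genome` (the modified sequence) and `truth`, a tibble
#'   with one row per copy: `contig`, `start`, `end`, `strand`, `d_true`,
#'   `age_ma`, `n_sub` (1-based inclusive coordinates on the output genome).
#' @export
implant_copies <- function(genome, consensus, ages_ma, rate = 3.1e-9,
                           indel_rate = 0, min_spacing = 100L, seed = NULL) {
  stopifnot(is.character(genome), length(genome) == 1, !is.null(names(genome)))
  contig <- names(genome)
  gseq <- unname(genome)
  n_copies <- length(ages_ma)
  if (n_copies == 0) {
    return(list(genome = genome, truth = empty_copy_truth()))
  }
  clen <- nchar(te_sequence(consensus))
  glen <- nchar(gseq)
  if (glen < n_copies * (min_spacing + 1L)) {
    abort("genome too short for the requested number of copies")
  }
  with_seed_(seed, {
    # insertion points on the original genome, pairwise >= min_spacing apart
    pos <- integer(0)
    tries <- 0L
    while (length(pos) < n_copies) {
      cand <- sample.int(glen - 1L, 1L) + 1L
      if (all(abs(cand - pos) >= min_spacing)) pos <- c(pos, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_copies) {
        abort("genome too short for the requested number of copies")
      }
    }
    ord <- order(pos)
    pos <- pos[ord]
    ages <- ages_ma[ord]
    copies <- lapply(ages, function(a) {
      evolve_copy(consensus, target_d = rate * a * 1e6, indel_rate = indel_rate)
    })
    strands <- sample(c("+", "-"), n_copies, replace = TRUE)
    ins <- vapply(seq_len(n_copies), function(i) {
      if (strands[i] == "-") revcomp(copies[[i]]$sequence) else copies[[i]]$sequence
    }, character(1))
    lens <- nchar(ins)
    # final coordinates account for upstream insertions
    shift <- c(0, cumsum(lens))[seq_len(n_copies)]
    starts <- pos + shift
    pieces <- character(2 * n_copies + 1)
    prev <- 1L
    for (i in seq_len(n_copies)) {
      pieces[2 * i - 1] <- substr(gseq, prev, pos[i] - 1L)
      pieces[2 * i] <- ins[i]
      prev <- pos[i]
    }
    pieces[2 * n_copies + 1] <- substr(gseq, prev, glen)
    out <- setNames(paste(pieces, collapse = ""), contig)
    truth <- tibble(
      contig = contig, start = starts, end = starts + lens - 1L,
      strand = strands, d_true = vapply(copies, `[[`, numeric(1), "d_true"),
      age_ma = ages,
      n_sub = vapply(copies, `[[`, integer(1), "n_sub")
    )
    list(genome = out, truth = truth)
  })
}

empty_copy_truth <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         strand = character(), d_true = numeric(), age_ma = numeric(),
         n_sub = integer())
}

#' Mutation scripts for the chimeric-locus simulator
#'
#' An exonization script is an ordered list of edits applied sequentially to
#' the ancestral TE fragment to produce the derived exon region; each entry
#' has `position` (1-based, on the sequence as it stands when the entry is
#' applied), `type` (`deletion`, `insertion`, or `substitution`) and
#' `payload` (deletion length, or replacement/inserted text).
#'
#' The built-in variants mirror the mutational histories observed among
#' *Xenopus* dm-W exon-4 homologs:
#' \describe{
#'   \item{`default`}{one 1-nt deletion removing an ancestral frameshift plus
#'     one substitution creating a TAG stop: a 71-residue ORF.}
#'   \item{`premature_stop`}{default plus an upstream C-to-T substitution
#'     creating a premature TAG: a 43-residue ORF.}
#'   \item{`frameshift16`}{default plus a 16-nt deletion near the ORF end
#'     (16 mod 3 = 1, a frameshift): a 67-residue ORF.}
#' }
#'
#' @param variant Script variant name.
#' @return A tibble with columns `position`, `type`, `payload`.
#' @export
exonization_script <- function(variant = c("default", "premature_stop",
                                           "frameshift16")) {
  variant <- match.arg(variant)
  base <- tibble(
    position = c(ANC_INS_POS, STOP_SUB_POS),
    type = c("deletion", "substitution"),
    payload = list(1L, "T")
  )
  switch(variant,
    default = base,
    premature_stop = bind_rows(base, tibble(position = PREM_SUB_POS,
                                            type = "substitution",
                                            payload = list("T"))),
    frameshift16 = bind_rows(base, tibble(position = FS16_DEL_POS,
                                          type = "deletion",
                                          payload = list(16L)))
  )
}

# Fragment geometry (1-based on the derived fragment):
#   coding codons 1..71 at 1..213, stop TAG at 214..216, then a tail whose
#   first base is G followed by a hidden TAG so the 16-nt deletion variant
#   terminates at codon 68. The ancestral fragment carries one extra base at
#   ANC_INS_POS and C instead of T at the stop position.
N_CODONS <- 71L
CODING_LEN <- 3L * N_CODONS            # 213
ANC_INS_POS <- 52L                     # 1-nt ancestral insertion
STOP_SUB_POS <- 214L                   # post-deletion coordinate of stop T
PREM_SUB_POS <- 130L                   # first base of codon 44 (CAG -> TAG)
FS16_DEL_POS <- 202L                   # 16-nt deletion start (variant)
TAIL_LEN <- 120L
FRAG_LEN_DERIVED <- CODING_LEN + 3L + TAIL_LEN   # 336
FRAG_LEN_ANC <- FRAG_LEN_DERIVED + 1L            # 337

#' Apply a mutation script to a sequence
#'
#' Entries are applied in list order; positions refer to the sequence as it
#' stands when the entry is applied. Deletion payloads are lengths;
#' substitution payloads replace `nchar(payload)` bases in place; insertion
#' payloads are inserted starting at `position`.
#'
#' @param x A nucleotide string.
#' @param script A script tibble as from [exonization_script()].
#' @return The edited string.
#' @export
apply_mutation_script <- function(x, script) {
  check_dna(x)
  for (k in seq_len(nrow(script))) {
    pos <- script$position[k]
    type <- script$type[k]
    payload <- script$payload[[k]]
    if (pos < 1 || pos > nchar(x)) {
      abort(sprintf("script position %d outside sequence (1..%d)", pos, nchar(x)))
    }
    x <- switch(type,
      deletion = {
        len <- if (is.character(payload)) nchar(payload) else as.integer(payload)
        if (pos + len - 1L > nchar(x)) abort("deletion runs past sequence end")
        paste0(substr(x, 1, pos - 1L), substr(x, pos + len, nchar(x)))
      },
      insertion = paste0(substr(x, 1, pos - 1L), payload,
                         substr(x, pos, nchar(x))),
      substitution = {
        len <- nchar(payload)
        if (pos + len - 1L > nchar(x)) abort("substitution runs past sequence end")
        paste0(substr(x, 1, pos - 1L), payload, substr(x, pos + len, nchar(x)))
      },
      abort(sprintf("unknown mutation type '%s'", type))
    )
  }
  x
}

# Draw a derived exon-4 source fragment and its ancestral (pre-exonization)
# state. The derived fragment has a clean 71-codon ORF; the ancestral one has
# a 1-nt insertion (frameshift) and C in place of the stop-forming T, and no
# in-frame stop anywhere, so only the scripted deletion + substitution open
# the ORF. Rejection-samples until the ancestral frame is stop-free.
exonizable_fragment <- function(gc_fraction = 0.4, max_tries = 2000L) {
  non_stop_codons <- function(n) {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        cod <- random_dna(3L, gc_fraction)
        if (!cod %in% STOP_CODONS) break
      }
      out[i] <- cod
    }
    out
  }
  for (try in seq_len(max_tries)) {
    codons <- non_stop_codons(N_CODONS)
    codons[44L] <- "CAG"  # premature-stop variant target
    tail <- paste0("G", "TAG", random_dna(TAIL_LEN - 4L, gc_fraction))
    derived <- paste0(paste(codons, collapse = ""), "TAG", tail)
    stopifnot(nchar(derived) == FRAG_LEN_DERIVED)
    # ancestral: insert one base at ANC_INS_POS, revert stop T -> C
    ins_base <- sample(c("A", "C", "G", "T"), 1)
    anc <- paste0(substr(derived, 1, ANC_INS_POS - 1L), ins_base,
                  substr(derived, ANC_INS_POS, FRAG_LEN_DERIVED))
    substr(anc, STOP_SUB_POS + 1L, STOP_SUB_POS + 1L) <- "C"
    # ancestral must have no in-frame stop over the whole fragment
    aa <- translate_nt(anc)
    if (!any(aa == "*")) {
      return(list(ancestral = anc, derived = apply_mutation_script(
        anc, exonization_script("default"))))
    }
  }
  abort("could not draw a stop-free ancestral fragment")  # nocov
}

#' Host an exonizable fragment inside a TE consensus
#'
#' Replaces part of the consensus interior (3'-biased, clear of the TIRs)
#' with an engineered ancestral exon-source fragment and forces a splice
#' acceptor AG immediately upstream, yielding the family consensus in its
#' pre-exonization state. [implant_chimeric_locus()] consumes the result;
#' copies implanted from it carry the fragment like the paralogous copies a
#' real genome would hold.
#'
#' @param te A `te_consensus` with interior of at least the fragment length
#'   plus margins (about 450 bp beyond the TIRs).
#' @param seed Optional integer seed.
#' @return The `te_consensus` with `sequence` modified and two extra fields:
#'   `fragment_interval` (1-based span of the ancestral fragment on the
#'   consensus) and `ancestral_fragment`.
#' @export
host_exon_fragment <- function(te, seed = NULL) {
  stopifnot(inherits(te, "te_consensus"))
  te_len <- nchar(te$sequence)
  if (te_len < FRAG_LEN_ANC + 2 * te$tir_length + 100L) {
    abort("TE consensus too short to host the exonizable fragment")
  }
  with_seed_(seed, {
    frag <- exonizable_fragment()
    s0 <- te_len - te$tir_length - FRAG_LEN_ANC - 60L
    te$sequence <- paste0(substr(te$sequence, 1, s0 - 3L), "AG",
                          frag$ancestral,
                          substr(te$sequence, s0 + FRAG_LEN_ANC, te_len))
    stopifnot(nchar(te$sequence) == te_len)
    te$fragment_interval <- c(start = s0, end = s0 + FRAG_LEN_ANC - 1L)
    te$ancestral_fragment <- frag$ancestral
    te
  })
}

#' Implant a chimeric four-exon gene with a TE-derived last exon
#'
#' Builds a gene in the architecture of *Xenopus laevis* dm-W: three ordinary
#' coding exons, then a last exon whose sequence derives from the non-coding
#' interior of a DNA transposon. The TE copy spans intron 3, exon 4 and the
#' 3' flank. In the ancestral (pre-exonization) state the TE fragment carries
#' a 1-nt insertion relative to the gene's reading frame and no in-frame stop;
#' the mutation `script` (by default one 1-nt deletion plus one TAG-creating
#' substitution) converts it into an open reading frame. An AG splice-acceptor
#' dinucleotide immediately precedes exon 4.
#'
#' @param genome Named character vector of length 1.
#' @param te A `te_consensus`, ideally already carrying the exon-source
#'   fragment (see [host_exon_fragment()]); a plain consensus is hosted
#'   internally first.
#' @param script Mutation script (see [exonization_script()]).
#' @param insert_at 1-based position in the genome before which the gene is
#'   inserted; default is the midpoint.
#' @param seed Optional integer seed.
#' @return A list with `genome` and `truth`. `truth` is a list with `exons`
#'   (tibble of 1-based intervals on the output genome), `acceptor_pos`
#'   (position of the G of the acceptor AG), `cds4` (exon-4 CDS interval
#'   including the stop), `frame_offset`, `peptide_length`, `script`,
#'   `te_interval` (span of the TE copy), `ancestral_fragment` and
#'   `exon4_region` sequences.
#' @export
implant_chimeric_locus <- function(genome, te, script = exonization_script(),
                                   insert_at = NULL, seed = NULL) {
  stopifnot(is.character(genome), length(genome) == 1, !is.null(names(genome)))
  stopifnot(inherits(te, "te_consensus"))
  if (any(script$position < 1 | script$position > FRAG_LEN_ANC)) {
    abort("script positions outside the TE fragment")
  }
  with_seed_(seed, {
    if (is.null(te$fragment_interval)) te <- host_exon_fragment(te)
    te_mod <- te$sequence
    te_len <- nchar(te_mod)
    s0 <- unname(te$fragment_interval["start"])
    derived_frag <- apply_mutation_script(te$ancestral_fragment, script)

    non_stop <- function(n_cod) {
      paste(vapply(seq_len(n_cod), function(i) {
        repeat {
          cod <- random_dna(3L, 0.45)
          if (!cod %in% STOP_CODONS) return(cod)
        }
      }, character(1)), collapse = "")
    }
    exon1 <- paste0("ATG", non_stop(39L))            # 120 nt
    exon2 <- non_stop(50L)                           # 150 nt
    exon3 <- non_stop(57L)                           # 171 nt -> frame 0 at ex4
    intron1 <- paste0("GT", random_dna(146L, 0.4), "AG")
    intron2 <- paste0("GT", random_dna(136L, 0.4), "AG")
    # intron 3: splice donor + linker + TE 5' portion ending in the acceptor AG
    intron3 <- paste0("GT", random_dna(60L, 0.4), substr(te_mod, 1, s0 - 1L))
    exon4_len <- CODING_LEN + 3L + 60L  # CDS + stop + 60 nt of 3' UTR
    te_derived_part <- paste0(derived_frag,
                              substr(te_mod, s0 + FRAG_LEN_ANC, te_len))
    exon4 <- substr(te_derived_part, 1, exon4_len)
    flank3 <- substr(te_derived_part, exon4_len + 1L, nchar(te_derived_part))

    gene <- paste0(exon1, intron1, exon2, intron2, exon3, intron3, exon4, flank3)
    glen0 <- nchar(unname(genome))
    at <- if (is.null(insert_at)) glen0 %/% 2L + 1L else as.integer(insert_at)
    stopifnot(at >= 1, at <= glen0 + 1L)
    out_seq <- paste0(substr(unname(genome), 1, at - 1L), gene,
                      substr(unname(genome), at, glen0))
    contig <- names(genome)

    off <- at - 1L
    lens <- nchar(c(exon1, intron1, exon2, intron2, exon3, intron3, exon4))
    cum <- cumsum(lens)
    exon_starts <- off + c(1L, cum[2] + 1L, cum[4] + 1L, cum[6] + 1L)
    exon_ends <- off + c(cum[1], cum[3], cum[5], cum[7])
    exons <- tibble(contig = contig, exon = 1:4,
                    start = exon_starts, end = exon_ends)

    cds <- exon_cds(exon4, frame_offset = 0L)
    if (is.null(cds)) abort("scripted exon 4 has no in-frame stop")  # nocov
    truth <- list(
      exons = exons,
      acceptor_pos = exon_starts[4] - 1L,
      cds4 = c(start = exon_starts[4] + cds$cds_start - 1L,
               end = exon_starts[4] + cds$cds_end - 1L),
      frame_offset = 0L,
      peptide_length = cds$peptide_length,
      stop_codon = cds$stop_codon,
      script = script,
      te_interval = c(start = off + cum[5] + 63L,
                      end = off + cum[5] + 62L + (s0 - 1L) +
                        nchar(te_derived_part)),
      ancestral_fragment = te$ancestral_fragment,
      exon4_region = exon4,
      # family consensus carrying the (ancestral) exon source region, the
      # state of the element before exonization; downstream scanning and
      # dating should use this as the library sequence
      te_consensus_used = te_mod
    )
    list(genome = setNames(out_seq, contig), truth = truth)
  })
}

#' Simulate homologs of the ancestral exon-4 source fragment
#'
#' Evolves the ancestral (pre-exonization) TE fragment into a set of lightly
#' diverged homologs, emulating the paralogous TE copies against which the
#' candidate exon is polarized.
#'
#' @param ancestral The ancestral fragment string (from the chimeric-locus
#'   truth).
#' @param n Number of homologs.
#' @param d Jukes-Cantor divergence of each homolog from the ancestor.
#' @param seed Optional integer seed.
#' @return Named character vector of homolog sequences.
#' @export
simulate_homologs <- function(ancestral, n = 4L, d = 0.02, seed = NULL) {
  with_seed_(seed, {
    setNames(
      vapply(seq_len(n), function(i) evolve_copy(ancestral, d)$sequence,
             character(1)),
      paste0("homolog_", seq_len(n))
    )
  })
}

#' Write and read a simulation fixture
#'
#' `write_fixture()` serialises a simulated genome and its truth to plain-text
#' files: `genome.fa` (FASTA, 60 columns), `truth.gff3` (1-based inclusive
#' intervals, source `exaptscan-sim`) and `truth.json`. `read_fixture()`
#' round-trips them.
#'
#' @param genome Named character vector.
#' @param truth Truth object: a tibble of copies, or a list with elements
#'   `copies` (tibble) and/or `chimeric` (list, as produced by
#'   [implant_chimeric_locus()]), and optionally `seed`.
#' @param dir Output directory (created if needed).
#' @return `write_fixture()` invisibly returns `dir`; `read_fixture()` returns
#'   `list(genome, truth)`.
#' @export
write_fixture <- function(genome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (tibble::is_tibble(truth)) truth <- list(copies = truth)
  write_fasta(genome, file.path(dir, "genome.fa"))

  gff <- c("##gff-version 3")
  if (!is.null(truth$copies) && nrow(truth$copies) > 0) {
    cp <- truth$copies
    gff <- c(gff, sprintf(
      "%s\texaptscan-sim\tte_copy\t%d\t%d\t.\t%s\t.\tID=copy%d;d_true=%.6g;age_ma=%.6g",
      cp$contig, cp$start, cp$end, cp$strand, seq_len(nrow(cp)),
      cp$d_true, cp$age_ma))
  }
  if (!is.null(truth$chimeric)) {
    ex <- truth$chimeric$exons
    gff <- c(gff, sprintf(
      "%s\texaptscan-sim\texon\t%d\t%d\t.\t+\t.\tID=exon%d",
      ex$contig, ex$start, ex$end, ex$exon))
  }
  writeLines(gff, file.path(dir, "truth.gff3"))

  json_truth <- truth
  if (!is.null(json_truth$chimeric)) {
    json_truth$chimeric$script <- script_to_json(json_truth$chimeric$script)
  }
  jsonlite::write_json(json_truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

script_to_json <- function(script) {
  lapply(seq_len(nrow(script)), function(k) {
    list(position = script$position[k], type = script$type[k],
         payload = script$payload[[k]])
  })
}

script_from_json <- function(x) {
  tibble(
    position = vapply(x, function(e) as.integer(e$position), integer(1)),
    type = vapply(x, function(e) e$type, character(1)),
    payload = lapply(x, function(e) {
      if (e$type == "deletion" && !is.character(e$payload)) {
        as.integer(e$payload)
      } else {
        e$payload
      }
    })
  )
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE, simplifyDataFrame = TRUE)
  truth <- list()
  if (!is.null(tr$copies) && length(tr$copies)) {
    truth$copies <- as_tibble(tr$copies)
  } else {
    truth$copies <- empty_copy_truth()
  }
  if (!is.null(tr$chimeric)) {
    ch <- tr$chimeric
    ch$exons <- as_tibble(ch$exons)
    ch$script <- script_from_json(jsonlite::read_json(
      file.path(dir, "truth.json"))$chimeric$script)
    ch$cds4 <- unlist(ch$cds4)
    ch$te_interval <- unlist(ch$te_interval)
    truth$chimeric <- ch
  }
  if (!is.null(tr$seed)) truth$seed <- tr$seed
  list(genome = genome, truth = truth)
}
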