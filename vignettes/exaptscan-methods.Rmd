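---
title: "Methods: detecting, dating and reconstructing TE exonization"
author: "exaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, dating and reconstructing TE exonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exaptscan)
```

## The scientific problem

DNA transposons occasionally donate sequence to genes. The motivating case
is the *Xenopus laevis* female-determining gene *dm-W*, a chimeric gene
whose last exon (exon 4) derives from the non-coding interior of a
*hAT-10*-family DNA transposon. Establishing such an origin requires several
coordinated analyses, and this package implements each of them on plain
sequence input, together with a simulator that produces genomes where the
right answer is known:

1. **Homology detection** — find TE-consensus-derived fragments in and
   around the candidate locus, and count family copies under explicit
   identity/coverage/deduplication rules.
2. **Region segmentation** — partition the locus into contiguous blocks of
   high and low identity against the consensus (the high–low–high pattern
   where an exonized region has drifted while its flanks stayed
   recognizable), and detect the terminal inverted repeats (TIRs)
   diagnostic of DNA transposons.
3. **Insertion dating** — convert each copy's corrected divergence from the
   family consensus into time through a neutral substitution rate.
4. **Exonization reconstruction** — polarize the differences between the
   candidate exon and its paralogous TE copies, classify their coding
   effects, and find the minimal mutation set that opened the observed
   reading frame.
5. **Genealogy** — neighbor-joining trees of copies or exon homologs with
   nonparametric bootstrap supports.

## Coordinates and containers

All coordinates are 1-based inclusive, the convention shared by Biostrings,
GenomicRanges and the GFF3 files the simulator writes, so intervals move
between the package and interchange formats without arithmetic. Sequences
are plain named character vectors; tabular results (hits, blocks,
divergence records, landscapes, mutation events) are tibbles so they
compose with dplyr pipelines; fitted-object-like results (`age_estimate`,
`exonization_report`, `nj_bootstrap`) are small S3 objects with `tidy()`
and `glance()` methods.

## The simulator and what it emulates

`generate_te_consensus()` draws a random element with exact terminal
inverted repeats (default 14 bp, the length reported for the *hAT-10*-like
elements of this system; the base just inside each TIR is constrained so
the repeat cannot extend by chance, keeping the implanted length exact
truth). `evolve_copy()` decays a copy under the Jukes-Cantor model: a
target divergence $d$ is converted to the per-site substitution probability

$$p = \tfrac{3}{4}\left(1 - e^{-4d/3}\right),$$

each site is substituted independently with probability $p$ to a uniformly
chosen different base, and (optionally) indels are laid down at a per-site
rate with geometric lengths of mean 2. Indels are off by default: the
downstream dating arithmetic is about substitutions, and no indel model is
calibrated for this system. `implant_copies()` gives every copy the truth
divergence $d = rT$ for its age $T$ (default $r = 3.1\times10^{-9}$
substitutions/site/year, the midpoint of the *Xenopus* range; default ages
17.5 Ma, inside the reported 17–18 Ma activity peak).

`implant_chimeric_locus()` builds a four-exon gene over a TE copy, the
architecture of *dm-W*: the TE spans intron 3, exon 4 and the 3′ flank. A
fragment of the consensus interior is engineered (`host_exon_fragment()`)
so that its *ancestral* state carries a 1-nt insertion relative to the
gene's reading frame and no in-frame stop anywhere, and its *derived* state
— after an ordered mutation script of one 1-nt deletion plus one C→T
substitution creating TAG — encodes exactly 71 residues ending in TAG. A
splice-acceptor AG immediately precedes the exon. Script variants add an
upstream TAG-creating substitution at codon 44 (43-residue product) or a
16-nt deletion near the ORF end (16 mod 3 = 1, a frameshift that runs into
a planted downstream stop after 67 codons), mirroring the three peptide
lengths observed across species. Truth (copy intervals, ages, exon
structure, CDS, script, expected peptide length) is emitted as GFF3 + JSON
and round-trips through `read_fixture()`.

What the simulator does *not* emulate — and therefore what green tests do
not show about real data: allotetraploid subgenome structure, selection,
rate heterogeneity across sites or lineages, nested/fragmented insertions,
and real splice-site context beyond the acceptor AG. Copies decay as
independent draws from one consensus (a star genealogy), which is the
idealization under which divergence-to-consensus dating is exact.

## Homology search

`smith_waterman()` is an affine-gap local aligner (Rcpp). A gap of length
$k$ costs `gap_open + k * gap_extend`; default scores (match 2, mismatch
−3, open −5, extend −2) approximate BLASTN defaults. The E-value cutoff of
a database search cannot be reproduced without database-size statistics, so
retention is by a raw-score minimum (default 60), which is deterministic.
`scan_genome()` seeds candidate windows with exact 11-mers grouped by their
implied copy start (diagonal), requiring roughly one seed per 100 query bp
for long queries — a genuine copy at ~5% divergence yields ~0.57 seeds per
site, while chance matches and the self-complementary TIR echoes on the
opposite strand scatter — then aligns each window in full, recursing into
unaligned flanks so tandem copies are all found. Sensitivity fades beyond
roughly 25–30% divergence, which is far below the census identity cutoff.
Identity is reported over non-gap columns (the usual BLAST "identities"
convention); coverage is the aligned fraction of the query.

`census()` applies the copy-counting scheme: identity ≥ 0.65, coverage ≥
0.60 (the thresholds used for this system's copy counts), then greedy
deduplication keeping the best-scoring hit and discarding any hit whose
*start* lies within the window (10 kb, 1 kb or 150 bp depending on query
class in the original analysis; distance ≤ window is a duplicate). Keying
duplicates on hit starts, with ties broken toward the leftmost, is a
documented choice — the published rule does not specify the anchor.

## Region segmentation and TIRs

`segment_blocks()` aligns locus and reference end-to-end, slides a 30-bp
window (step 1) of per-column identity, thresholds at 0.65 (kept equal to
the census identity cutoff) into high/low states, merges interruptions of
at most 30 columns, absorbs runs under 50 bp, and labels the surviving
blocks A, B, C… 5′→3′. Per-block identity is then recomputed exactly from
the block's alignment columns. The published region identities were
produced by an unstated alignment protocol, so exact reproduction on real
sequences is not claimed — the target is the high–low–high pattern with
identities in the right order. `find_tir()` returns the longest terminal
length in a range whose 5′ prefix matches the reverse complement of the 3′
suffix within a mismatch budget; it is checked against exhaustive search.

## Dating

With pairwise gap deletion, $p$ is the fraction of differing compared
sites, corrected by Jukes-Cantor, $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$,
or Kimura two-parameter, $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$.
Saturated comparisons ($p \ge 0.75$, or inadmissible $P,Q$) yield an
undefined distance: they are excluded from medians and counted, since a
median over finite values is robust but silent exclusion would not be.
Gamma rate heterogeneity is deliberately out of scope.

Divergence to the (majority-rule) consensus is used directly as age,
$T = d/r$, with **no factor of two**: copies decay independently from the
ancestral, consensus-like state, so the divergence of a copy to the
consensus spans one lineage, not two. This reproduces the arithmetic
0.054 → 16.9–18.0 Ma at $r = 3.0$–$3.2\times10^{-9}$. The median is
unweighted by default (a length-weighted variant is a flag away in the
landscape, where copies contribute genome fraction); whether the original
median was length-weighted is unstated. Landscapes bin each copy's
genome-fraction contribution by $d$ with bin width 0.01 — the published
figure's granularity is unstated, and 0.01 resolves a 0.05 peak without
emptying bins at realistic copy counts.

`majority_consensus()` takes the most frequent base per column, ties
broken alphabetically (a deterministic, documented rule); columns with a
strict gap majority are dropped. `center_star_align()` provides alignments
for the small sets this package handles (≤ 50 sequences): the center
maximizes summed pairwise scores and gaps propagate ("once a gap, always a
gap"); larger sets should be aligned externally and read back as aligned
FASTA.

## Exonization reconstruction

`exon_cds()` translates from a frame offset carried in from the upstream
exon — the exon-4 peptide is a C-terminal continuation, not an independent
ORF, so no ATG is sought; the frame offset is a required input because the
exon-3/exon-4 junction phase is annotation, not something to infer.
`diff_events()` collapses gap runs into single indel events.
`reconstruct_path()` polarizes candidate-vs-homolog differences by
majority: a substitution needs a strict majority of homologs agreeing on
the ancestral base; for indels, presence and length are the character and
the ancestral text is read from the modal homolog (homolog-private noise
inside a deleted tract must not break polarization). Sites failing the
majority rule are reported as unpolarizable and excluded. With one homolog
nothing can be polarized; events are reported unpolarized with a warning.

The minimal ORF-enabling set is found by exhaustive search over event
subsets in increasing size (up to 6, then greedily): a subset qualifies if
applying it to the ancestral reconstruction reproduces the candidate's
peptide length exactly. Event counts at a single exon are small in
practice, so the exhaustive bound is not limiting. Frameshift direction is
decided by reversion: if undoing the event on the candidate destroys the
observed ORF, it was needed to bring the stop into frame
(`frameshift_remove`); otherwise it introduced a shift relative to the
ancestral coding state. Among stop-creating substitutions, the
downstream-most is the `stop_gain` that terminates the reading; any other
is `premature_stop` relative to it.

## Trees

`distance_matrix()` uses the package's own pairwise distances (JC or plain
K2P) with pairwise gap deletion; any saturated pair is an error naming the
pair, because a silent infinite distance would corrupt the join.
`neighbor_joining()` delegates the agglomeration to `ape::nj()` — standard
machinery, not this package's contribution — and clamps the negative branch
lengths NJ can produce on non-additive input to zero with a message.
`bootstrap_nj()` resamples alignment columns with replacement, rebuilds the
tree per replicate with the same pipeline, and scores each internal edge of
the full-data tree by the percentage of replicates containing the same
bipartition (canonical sorted-tip-label keys, so taxon order is
irrelevant). Replicates with a saturated pair are dropped and counted, and
the support denominator is the number of successful replicates.

## The pipeline and problem sizes

`run_pipeline()` chains simulate → scan/census → blocks/TIR → date →
exonize → tree, writing every stage's table plus `summary.json` and a log;
one seed fans out per stage (seed + stage index) so stages are
independently reproducible and reruns are bit-identical. Defaults simulate
a 20 kb background genome, a 3 kb element (a realistic size for a
hAT-family element whose transposase alone needs > 3 kb of coding
sequence), 30 copies at 17.5 Ma, and 100 bootstrap replicates on a tree of
up to 8 copies — sizes chosen so a full run completes in about a minute
while the census, dating and reconstruction results are stable. The test
suite exercises the same pipeline at reduced sizes (8 kb genome, 2 kb
element, 12 copies) and checks the full-size statistical properties where
they matter: age recovery uses 200 copies of 5 kb over 100 replicates,
aligner correctness uses a brute-force oracle, and NJ correctness uses 100
random additive matrices.

## Known limitations

* The aligner is for loci and small genomes, not chromosome-scale scans;
  its seed filter trades sensitivity beyond ~25–30% divergence for speed.
* Dating assumes star-like decay from the consensus and a constant rate;
  lineage-specific or CpG-aware calibration is out of scope.
* Event polarization assumes the homolog set brackets the ancestral state;
  with deep homolog divergence, alignment ambiguity around indels can move
  event anchors.
* ML tree inference and model selection are deliberately not implemented;
  the distance-based half of the genealogy is.
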