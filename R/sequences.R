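#' Sequence utilities
#'
#' Small helpers for plain-character nucleotide sequences. Sequences are
#' ordinary R strings over A, C, G, T (optionally N); coordinates throughout
#' the package are 1-based inclusive, the convention shared by Biostrings,
#' GenomicRanges and GFF3.
#'
#' @param x A character vector of nucleotide sequences.
#' @return `revcomp()` returns the reverse complement of each element.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Draw n random bases at a given GC fraction.
random_dna <- function(n, gc_fraction = 0.4) {
  if (n == 0) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL runs in the ambient stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), code)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

check_dna <- function(s, allow_n = TRUE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!is.character(s) || length(s) != 1 || !grepl(pat, s)) {
    abort(sprintf("`%s` must be a single string over %s", arg,
                  if (allow_n) "A,C,G,T,N" else "A,C,G,T"))
  }
  invisible(s)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings that move between named character vectors
#' (the package's working representation) and FASTA files wrapped at 60
#' columns. Gapped (aligned) FASTA round-trips too: `-` is preserved.
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 60L)
  invisible(path)
}

# Translate a nucleotide string; returns a character vector of amino acids
# ("*" for stop, "X" for codons with N). Trailing partial codon is dropped.
# Codon lookup against the standard genetic code (Biostrings' table).
translate_nt <- function(s) {
  n_cod <- nchar(s) %/% 3
  if (n_cod == 0) return(character(0))
  starts <- 3 * (seq_len(n_cod) - 1) + 1
  codons <- substring(s, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
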