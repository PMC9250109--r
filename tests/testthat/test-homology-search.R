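test_that("smith_waterman handles identity and forced-mismatch cases", {
  r <- smith_waterman("ACGTACGT", "ACGTACGT")
  expect_equal(r$score, 16)
  expect_equal(r$identity, 1.0)
  expect_equal(r$a_start, 1); expect_equal(r$a_end, 8)
  r2 <- smith_waterman("ACGT", "TTTT", scoring_scheme(match = 1, mismatch = -3))
  expect_equal(r2$score, 1)   # only a single-base match can score
  expect_error(smith_waterman("", "ACGT"), "non-empty")
  expect_error(smith_waterman("ACGT", "ACXT"), "must be")
})

test_that("aligner matches a brute-force DP oracle on random pairs", {
  schemes <- list(scoring_scheme(),
                  scoring_scheme(match = 1, mismatch = -1,
                                 gap_open = -2, gap_extend = -1))
  withr::with_seed(21, {
    for (i in 1:30) {
      a <- rand_seq(12); b <- rand_seq(12)
      for (sc in schemes) {
        expect_equal(smith_waterman(a, b, sc)$score, sw_oracle_score(a, b, sc))
      }
    }
  })
})

test_that("aligner agrees with an independent local-alignment implementation", {
  withr::with_seed(22, {
    for (i in 1:5) {
      a <- rand_seq(200)
      b <- evolve_copy(a, 0.1)$sequence
      mine <- smith_waterman(a, b)$score
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -3),
        gapOpening = 5, gapExtension = 2))
      expect_equal(mine, ref)
    }
  })
})

test_that("scan_genome finds the consensus in itself and respects strand", {
  te <- generate_te_consensus(500, 14, seed = 31)
  g <- setNames(te$sequence, "self")
  hits <- scan_genome(g, te)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 1); expect_equal(plus$end, 500)
  expect_equal(plus$identity, 1.0); expect_equal(plus$coverage, 1.0)
  # a reverse-complemented copy is reported on "-" with the same identity
  g2 <- withr::with_seed(99, setNames(paste0(rand_seq(300), revcomp(te$sequence),
                                             rand_seq(300)), "rc"))
  h2 <- scan_genome(g2, te)
  minus <- h2[h2$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$identity, 1.0)
  expect_equal(c(minus$start, minus$end), c(301, 800))
})

test_that("scan recall on implanted copies exceeds 48/50", {
  te <- generate_te_consensus(1000, 14, seed = 32)
  g <- withr::with_seed(33, setNames(rand_seq(60000), "chr1"))
  imp <- implant_copies(g, te, rep(17.5, 50), rate = 3.1e-9, seed = 34)
  hits <- scan_genome(imp$genome, te)
  recovered <- vapply(seq_len(50), function(i) {
    tlen <- imp$truth$end[i] - imp$truth$start[i] + 1
    any(pmin(hits$end, imp$truth$end[i]) - pmax(hits$start, imp$truth$start[i]) + 1 >=
          0.9 * tlen & hits$length <= 1.2 * tlen)
  }, logical(1))
  expect_gte(sum(recovered), 48)
  # strand invariance: the reverse-complemented genome gives the same
  # multiset of (identity, length)
  grc <- setNames(revcomp(imp$genome), names(imp$genome))
  hits_rc <- scan_genome(grc, te)
  key <- function(h) sort(paste(round(h$identity, 6), h$length))
  expect_equal(key(hits_rc), key(hits))
})

test_that("census applies identity, coverage and dedup rules", {
  mk <- function(start, score = 100, identity = 0.9, coverage = 0.9,
                 contig = "c1") {
    tibble::tibble(query = "te", contig = contig, start = start,
                   end = start + 99, strand = "+", score = score,
                   identity = identity, coverage = coverage)
  }
  h <- dplyr::bind_rows(mk(1, identity = 0.60), mk(500, identity = 0.70),
                        mk(1000, identity = 0.80))
  expect_equal(nrow(census(h, min_identity = 0.65, min_coverage = 0)), 2)
  # window boundary: 120 bp apart dedups at 150 but not at 100
  h2 <- dplyr::bind_rows(mk(100, score = 90), mk(220, score = 80))
  expect_equal(nrow(census(h2, dedup_window = 150)), 1)
  expect_equal(nrow(census(h2, dedup_window = 100)), 2)
  # the higher-scoring hit is the one kept
  kept <- census(h2, dedup_window = 150)
  expect_equal(kept$start, 100)
})

test_that("census is monotone in its thresholds and idempotent", {
  withr::with_seed(35, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      h <- tibble::tibble(
        query = "te", contig = sample(c("c1", "c2"), n, replace = TRUE),
        start = sample.int(5000, n), strand = "+",
        score = runif(n, 50, 200), identity = runif(n, 0.4, 1),
        coverage = runif(n, 0.3, 1))
      h$end <- h$start + 99
      w <- sample(c(0, 50, 150, 500), 1)
      thr <- sort(runif(2, 0.4, 1))
      expect_lte(nrow(census(h, thr[2], 0.5, w)), nrow(census(h, thr[1], 0.5, w)))
      expect_lte(nrow(census(h, 0.5, thr[2], w)), nrow(census(h, 0.5, thr[1], w)))
      ret <- census(h, 0.6, 0.5, w)
      expect_equal(census(ret, 0.6, 0.5, w), ret)
    }
  })
})

test_that("the short-query census configuration counts nine implanted copies", {
  # nine non-overlapping copies of a ~220 bp query, censused at the
  # Ex4-CDS-like configuration (identity > 0.65, coverage > 0.60, 150 bp
  # dedup window)
  te <- generate_te_consensus(220, 0, seed = 36)
  g <- withr::with_seed(37, setNames(rand_seq(12000), "chr1"))
  imp <- implant_copies(g, te, rep(10, 9), rate = 3.1e-9, min_spacing = 500,
                        seed = 38)
  hits <- scan_genome(imp$genome, te)
  ret <- census(hits, min_identity = 0.65, min_coverage = 0.60,
                dedup_window = 150)
  expect_equal(nrow(ret), 9)
})
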