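test_that("generated consensus carries exact terminal inverted repeats", {
  te <- generate_te_consensus(1000, tir_length = 14, seed = 1)
  expect_equal(nchar(te$sequence), 1000)
  expect_equal(substr(te$sequence, 1, 14),
               revcomp(substr(te$sequence, 987, 1000)))
  # determinism
  te2 <- generate_te_consensus(1000, tir_length = 14, seed = 1)
  expect_identical(te$sequence, te2$sequence)
  # tir_length = 0 is unconstrained
  te0 <- generate_te_consensus(100, tir_length = 0, seed = 3)
  expect_equal(nchar(te0$sequence), 100)
  expect_error(generate_te_consensus(20, tir_length = 14), "length")
  expect_error(generate_te_consensus(100, tir_length = -1), "tir_length")
})

test_that("evolve_copy hits its target divergence", {
  te <- generate_te_consensus(10000, 14, seed = 2)
  # d = 0: untouched
  expect_identical(evolve_copy(te, 0, seed = 1)$sequence, te$sequence)
  # substitution count equals Hamming distance when indels are off
  cp <- evolve_copy(te, 0.054, seed = 5)
  x <- strsplit(te$sequence, "")[[1]]; y <- strsplit(cp$sequence, "")[[1]]
  hamming <- sum(x != y)
  expect_equal(hamming, cp$n_sub)
  # measured p within 3 binomial SDs of the Jukes-Cantor inversion 0.0521
  p_target <- jc_p_from_d(0.054)
  expect_equal(p_target, 0.0521, tolerance = 1e-3)
  sd3 <- 3 * sqrt(p_target * (1 - p_target) / 10000)
  expect_lt(abs(hamming / 10000 - p_target), sd3)
  expect_error(evolve_copy(te, Inf), "0.75|finite")
})

test_that("re-estimated JC distance over many copies recovers the target median", {
  te <- generate_te_consensus(2000, 14, seed = 3)
  d_hat <- withr::with_seed(42, replicate(200, {
    cp <- evolve_copy(te, 0.054)
    jc_distance(p_distance(cp$sequence, te$sequence)$p)
  }))
  expect_lt(abs(median(d_hat) - 0.054), 0.004)
})

test_that("divergence estimates tighten with copy length (d = rT consistency)", {
  err <- withr::with_seed(7, vapply(c(1000, 10000), function(len) {
    te <- generate_te_consensus(len, 14)
    mean(abs(replicate(20, {
      cp <- evolve_copy(te, 0.05425)
      jc_distance(p_distance(cp$sequence, te$sequence)$p)
    }) - 0.05425))
  }, numeric(1)))
  expect_lt(err[2], err[1])
})

test_that("implant_copies records exact d = rT truth and is deterministic", {
  te <- generate_te_consensus(500, 14, seed = 4)
  g <- withr::with_seed(8, setNames(rand_seq(20000), "chr1"))
  imp <- implant_copies(g, te, ages_ma = rep(17.5, 10), rate = 3.1e-9, seed = 9)
  expect_equal(nrow(imp$truth), 10)
  expect_true(all(imp$truth$d_true == 3.1e-9 * 17.5 * 1e6))
  expect_equal(imp$truth$d_true[1], 0.05425)
  # every truth interval extracts a copy-length sequence resembling the
  # consensus at the implanted divergence
  for (i in seq_len(10)) {
    s <- substr(imp$genome, imp$truth$start[i], imp$truth$end[i])
    if (imp$truth$strand[i] == "-") s <- revcomp(s)
    expect_equal(unname(nchar(s)), 500)
    p <- p_distance(s, te$sequence)$p
    expect_lt(p, 0.12)
  }
  # determinism and the empty case
  imp2 <- implant_copies(g, te, ages_ma = rep(17.5, 10), rate = 3.1e-9, seed = 9)
  expect_identical(imp$genome, imp2$genome)
  imp0 <- implant_copies(g, te, ages_ma = numeric(0))
  expect_identical(imp0$genome, g)
  expect_equal(nrow(imp0$truth), 0)
  gs <- setNames(rand_seq(300), "tiny")
  expect_error(implant_copies(gs, te, rep(1, 50)), "too short")
})

test_that("chimeric locus truth encodes the scripted open reading frame", {
  fx <- chimeric_fixture("default")
  tr <- fx$chim$truth
  expect_equal(tr$peptide_length, 71L)
  expect_equal(tr$stop_codon, "TAG")
  # acceptor AG immediately precedes exon 4
  expect_equal(unname(substr(fx$chim$genome, tr$acceptor_pos - 1, tr$acceptor_pos)), "AG")
  # translating the truth CDS interval yields a clean ORF of scripted length
  cds_seq <- substr(fx$chim$genome, tr$cds4["start"], tr$cds4["end"])
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq))), "")[[1]]
  expect_equal(length(aa), 72)          # 71 residues + stop
  expect_equal(aa[72], "*")
  expect_false(any(aa[1:71] == "*"))
  # exon intervals are ordered and within the genome
  expect_true(all(diff(tr$exons$start) > 0))
  expect_true(max(tr$exons$end) <= nchar(fx$chim$genome))
})

test_that("script variants give the expected peptide lengths", {
  lens <- vapply(c(default = "default", premature_stop = "premature_stop",
                   frameshift16 = "frameshift16"), function(v) {
    chimeric_fixture(v)$chim$truth$peptide_length
  }, integer(1))
  expect_equal(unname(lens), c(71L, 43L, 67L))
})

test_that("mutation scripts are validated and applied sequentially", {
  s <- "ACGTACGTACGT"
  script <- tibble::tibble(position = c(3L, 5L),
                           type = c("deletion", "substitution"),
                           payload = list(2L, "TT"))
  expect_equal(apply_mutation_script(s, script), "ACACTTACGT")
  bad <- tibble::tibble(position = 999L, type = "substitution",
                        payload = list("A"))
  te <- generate_te_consensus(1000, 14, seed = 1)
  g <- setNames(rand_seq(2000), "c")
  expect_error(implant_chimeric_locus(g, te, script = bad), "outside")
})

test_that("fixtures round-trip through FASTA/GFF3/JSON", {
  dir <- withr::local_tempdir()
  te <- generate_te_consensus(600, 14, seed = 6)
  g <- withr::with_seed(10, setNames(rand_seq(8000), "chrZ"))
  imp <- implant_copies(g, te, rep(10, 4), seed = 11)
  chim <- implant_chimeric_locus(imp$genome, te, seed = 12)
  truth <- list(copies = imp$truth, chimeric = chim$truth, seed = 11L)
  write_fixture(chim$genome, truth, dir)
  back <- read_fixture(dir)
  expect_identical(back$genome, chim$genome)
  expect_equal(as.data.frame(back$truth$copies), as.data.frame(imp$truth))
  expect_equal(back$truth$chimeric$peptide_length, chim$truth$peptide_length)
  expect_equal(as.data.frame(back$truth$chimeric$script),
               as.data.frame(chim$truth$script))
  # GFF3 is version-3, 1-based inclusive, matching the truth tibble
  gff <- readLines(file.path(dir, "truth.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  f <- strsplit(gff[2], "\t")[[1]]
  expect_equal(as.integer(f[4]), imp$truth$start[1])
  expect_equal(as.integer(f[5]), imp$truth$end[1])
  # empty truth still writes valid files
  dir2 <- withr::local_tempdir()
  write_fixture(g, list(copies = imp$truth[0, ]), dir2)
  expect_equal(readLines(file.path(dir2, "truth.gff3")), "##gff-version 3")
})
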