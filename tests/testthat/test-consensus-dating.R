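test_that("majority consensus follows the documented column rules", {
  m <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_equal(majority_consensus(m), "ACGT")
  # tie broken alphabetically; strict gap majority drops the column
  m2 <- c(a = "AA-A", b = "CA-C", c = "AC--")
  # col1 {A,C,A} -> A; col2 {A,A,C} -> A; col3 all gaps -> dropped;
  # col4 {A,C,-} -> tie A/C -> A
  expect_equal(majority_consensus(m2), "AAA")
  expect_error(majority_consensus(c(x = "ACGT")), "at least 2")
})

test_that("majority vote recovers a simulated ancestral consensus", {
  anc <- withr::with_seed(51, rand_seq(1000))
  copies <- withr::with_seed(52, vapply(1:100, function(i) {
    evolve_copy(anc, 0.054)$sequence
  }, character(1)))
  names(copies) <- paste0("c", 1:100)
  cons <- majority_consensus(copies)
  expect_lt(p_distance(cons, anc)$p, 0.01)
})

test_that("p_distance uses pairwise gap deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), list(p = 0, sites_compared = 4L))
  expect_equal(p_distance("ACGT", "ACGA"), list(p = 0.25, sites_compared = 4L))
  expect_equal(p_distance("AC-T", "ACGT"), list(p = 0, sites_compared = 3L))
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  und <- p_distance("----", "AAAA")
  expect_true(is.na(und$p)); expect_equal(und$sites_compared, 0L)
})

test_that("Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.0521), 0.054, tolerance = 1e-4 / 0.054)
  expect_gt(jc_distance(0.74999), 5)
  expect_true(is.na(jc_distance(0.75)))
  # d >= p, approaching p as p -> 0
  p <- c(1e-4, 0.01, 0.1, 0.3, 0.5)
  expect_true(all(jc_distance(p) >= p))
  expect_equal(jc_distance(1e-4), 1e-4, tolerance = 1e-4)
})

test_that("K2P distance matches its closed form", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05), -0.5 * log(0.75) - 0.25 * log(0.9))
  expect_equal(k2p_distance(0.1, 0.05), 0.17017, tolerance = 1e-4)
  expect_true(is.na(k2p_distance(0.5, 0.1)))
  expect_identical(k2p_distance(0.1, 0.05), k2p_distance(0.1, 0.05))
})

test_that("landscapes conserve annotated genome fraction", {
  rec1 <- tibble::tibble(copy_name = "c1", p = 0.05, d = 0.054, model = "JC",
                         sites_compared = 1000L)
  ls1 <- landscape(rec1, copy_lengths = 5000, genome_size = 5000)
  expect_equal(ls1$fraction, 1.0)
  expect_equal(nrow(ls1), 1)
  # simulated copies: modal bin contains the simulated divergence and the
  # fractions sum to the implanted TE fraction
  te <- generate_te_consensus(800, 14, seed = 53)
  g <- withr::with_seed(54, setNames(rand_seq(30000), "chr1"))
  imp <- implant_copies(g, te, rep(17.5, 15), rate = 3.1e-9, seed = 55)
  seqs <- vapply(seq_len(15), function(i) {
    s <- substr(imp$genome, imp$truth$start[i], imp$truth$end[i])
    if (imp$truth$strand[i] == "-") revcomp(s) else s
  }, character(1))
  names(seqs) <- paste0("c", 1:15)
  div <- divergence_to_consensus(seqs, te$sequence)
  ls <- landscape(div, copy_lengths = 800, genome_size = nchar(imp$genome))
  expect_equal(sum(ls$fraction), 15 * 800 / unname(nchar(imp$genome)))
  modal <- ls[which.max(ls$fraction), ]
  expect_true(modal$bin_low <= 0.05425 && 0.05425 < modal$bin_high)
  # saturated copies are excluded but counted
  div2 <- dplyr::bind_rows(div, tibble::tibble(
    copy_name = "sat", p = 0.76, d = NA_real_, model = "JC",
    sites_compared = 800L))
  ls2 <- landscape(div2, copy_lengths = 800, genome_size = nchar(imp$genome))
  expect_equal(sum(ls2$fraction), sum(ls$fraction))
  expect_equal(attr(ls2, "n_saturated"), 1L)
  expect_error(landscape(rec1, 100, 0), "genome_size")
  expect_error(landscape(rec1, 100, 100, bin_width = 0), "bin_width")
})

test_that("estimate_age converts divergence to the published age interval", {
  a <- estimate_age(0.054, 3.0e-9, 3.2e-9)
  expect_equal(a$age_high_ma, 18.0)
  expect_equal(a$age_low_ma, 16.875)
  expect_equal(round(a$age_low_ma), 17)
  expect_equal(round(a$age_high_ma), 18)
  expect_equal(estimate_age(0, 3.0e-9, 3.2e-9)$age_high_ma, 0)
  expect_error(estimate_age(-1), "d_median")
  expect_error(estimate_age(0.05, 0, 1e-9), "rates|rate")
  expect_error(estimate_age(0.05, 2e-9, 1e-9), "rate_low")
  g <- glance(a)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$age_high_ma, 18.0)
})

test_that("center-star alignment preserves members and aligns small sets", {
  # identical sequences: gapless
  s <- withr::with_seed(56, rand_seq(50))
  al <- center_star_align(setNames(rep(s, 3), c("a", "b", "c")))
  expect_false(any(grepl("-", al, fixed = TRUE)))
  # documented 5-column example
  al2 <- center_star_align(c(a = "ACGT", b = "ACGGT", c = "ACT"))
  expect_equal(unique(nchar(al2)), 5L)
  degap <- function(x) gsub("-", "", x, fixed = TRUE)
  expect_equal(degap(al2), c(a = "ACGT", b = "ACGGT", c = "ACT"))
  # round-trip on indel-mutated copies
  withr::with_seed(57, {
    anc <- rand_seq(300)
    seqs <- setNames(vapply(1:5, function(i) {
      evolve_copy(anc, 0.05, indel_rate = 0.005)$sequence
    }, character(1)), paste0("s", 1:5))
    al3 <- center_star_align(seqs)
    expect_equal(length(unique(nchar(al3))), 1L)
    expect_equal(degap(al3), seqs)
  })
  expect_error(center_star_align("ACGT"), "at least 2")
  many <- setNames(rep("ACGT", 51), paste0("x", 1:51))
  expect_error(center_star_align(many), "at most 50")
})
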