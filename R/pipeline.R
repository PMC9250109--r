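#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. The defaults
#' describe the simulated study system: a 20 kb genome; a 3 kb hAT-like
#' consensus with 14-bp TIRs; 30 implanted copies aged 17.5 Ma decayed at
#' 3.1e-9 substitutions/site/year; a chimeric four-exon gene whose last exon
#' derives from the TE via a 1-nt deletion plus a TAG-creating substitution;
#' census thresholds of 65% identity over 60% query coverage with a 150-bp
#' deduplication window; dating rates 3.0e-9 to 3.2e-9; 100 bootstrap
#' replicates on a tree of up to 8 copies.
#'
#' @param ... Named overrides, e.g. `run_config(seed = 7)` or
#'   `run_config(thresholds = list(dedup_window = 1000))` (partial lists are
#'   merged into the defaults).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = tempfile("exaptscan_run_"),
    simulate = list(genome_length = 20000L, te_length = 3000L,
                    tir_length = 14L, gc_fraction = 0.4, n_copies = 30L,
                    age_ma = 17.5, rate = 3.1e-9, n_homologs = 4L,
                    homolog_d = 0.02, script_variant = "default"),
    thresholds = list(min_identity = 0.65, min_coverage = 0.60,
                      dedup_window = 150L, min_score = 60),
    rates = list(rate_low = 3.0e-9, rate_high = 3.2e-9),
    bin_width = 0.01,
    bootstrap_reps = 100L,
    tree_max_copies = 8L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read and write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_config()` returns a validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(th$min_identity)) abort("min_identity must be in [0, 1]")
  if (!in01(th$min_coverage)) abort("min_coverage must be in [0, 1]")
  if (th$dedup_window < 0) abort("dedup_window must be >= 0")
  if (cfg$rates$rate_low <= 0 || cfg$rates$rate_high < cfg$rates$rate_low) {
    abort("rates must satisfy 0 < rate_low <= rate_high")
  }
  if (cfg$bin_width <= 0) abort("bin_width must be > 0")
  if (cfg$bootstrap_reps < 1) abort("bootstrap_reps must be >= 1")
  invisible(cfg)
}

#' Run the full simulate-scan-date-exonize-tree pipeline
#'
#' Executes every stage on a simulated genome with known truth: simulate
#' (genome + TE copies + chimeric locus), scan (homology search + census),
#' blocks + TIR on the TE-derived locus, consensus dating (per-copy
#' divergence, landscape, age interval), exonization reconstruction, and a
#' bootstrapped NJ tree of the recovered copies. All stage outputs are
#' written under `cfg$out_dir` along with `summary.json` and `run.log`;
#' a single seed fans out per stage (`seed + stage index`), so reruns with
#' the same configuration are bit-identical.
#'
#' @param cfg A `run_config` (see [run_config()], [read_config()]).
#' @return Invisibly, the summary list (also written as JSON): census count,
#'   block table, TIR, age interval, exonization minimal set, tree path,
#'   config hash.
#' @export
run_pipeline <- function(cfg = run_config()) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # the hash covers the scientific configuration, not where results land
  cfg_hash <- rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(stage, event, ...) {
    line <- sprintf("[%s] %s %s", stage, event, paste(..., collapse = " "))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  logline("init", "config", "hash:", cfg_hash)
  sim <- cfg$simulate

  # stage 1: simulate. Copies go in first, the chimeric gene last into a
  # copy-free spot, so every truth interval is in final coordinates.
  s1 <- cfg$seed + 1L
  te <- generate_te_consensus(sim$te_length, sim$tir_length, sim$gc_fraction,
                              seed = s1)
  te_lib <- host_exon_fragment(te, seed = s1)
  genome0 <- withr::with_seed(s1, setNames(
    random_dna(sim$genome_length, sim$gc_fraction), "contig_1"))
  imp <- implant_copies(genome0, te_lib, rep(sim$age_ma, sim$n_copies),
                        rate = sim$rate, seed = s1 + 2L)
  at <- copy_free_position(nchar(imp$genome), imp$truth)
  chim <- implant_chimeric_locus(imp$genome, te_lib,
                                 script = exonization_script(sim$script_variant),
                                 insert_at = at, seed = s1 + 1L)
  genome <- chim$genome
  gene_len <- nchar(genome) - nchar(imp$genome)
  copies <- mutate(imp$truth,
                   start = ifelse(.data$start >= at, .data$start + gene_len,
                                  .data$start),
                   end = ifelse(.data$end >= at, .data$end + gene_len,
                                .data$end))
  truth <- list(copies = copies, chimeric = chim$truth, seed = cfg$seed)
  write_fixture(genome, truth, cfg$out_dir)
  logline("simulate", "done", "genome:", nchar(genome), "bp,",
          nrow(imp$truth), "copies")

  # stage 2: scan + census
  hits <- scan_genome(genome, te_lib, min_score = cfg$thresholds$min_score)
  retained <- census(hits, cfg$thresholds$min_identity,
                     cfg$thresholds$min_coverage, cfg$thresholds$dedup_window)
  utils::write.table(select(hits, -"qalign", -"talign"),
                     file.path(cfg$out_dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(select(retained, -"qalign", -"talign"),
                     file.path(cfg$out_dir, "census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("scan", "done", nrow(hits), "hits,", nrow(retained), "after census")

  # stage 3: blocks + TIR on the TE-spanning locus
  te_iv <- chim$truth$te_interval
  locus <- substr(genome, te_iv["start"], te_iv["end"])
  blocks <- segment_blocks(locus, te_lib$sequence)
  utils::write.table(blocks, file.path(cfg$out_dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tir <- find_tir(te$sequence, max_mismatch = 0L)
  jsonlite::write_json(
    if (is.null(tir)) list(found = FALSE) else c(list(found = TRUE), unclass(tir)),
    file.path(cfg$out_dir, "tir.json"), auto_unbox = TRUE, digits = NA)
  logline("blocks", "done", nrow(blocks), "blocks; TIR:",
          if (is.null(tir)) "none" else tir$length)

  # stage 4: dating
  copy_seqs <- census_sequences(retained, genome)
  div <- divergence_to_consensus(copy_seqs, te_lib$sequence)
  utils::write.table(div, file.path(cfg$out_dir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ls <- landscape(div, copy_lengths = retained$length,
                  genome_size = nchar(genome), bin_width = cfg$bin_width)
  utils::write.table(as_tibble(ls), file.path(cfg$out_dir, "landscape.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d_med <- median(div$d, na.rm = TRUE)
  age <- estimate_age(d_med, cfg$rates$rate_low, cfg$rates$rate_high)
  jsonlite::write_json(unclass(age), file.path(cfg$out_dir, "age.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("date", "done", "median d:", signif(d_med, 4), "-> age",
          signif(age$age_low_ma, 4), "-", signif(age$age_high_ma, 4), "Ma")

  # stage 5: exonization
  s5 <- cfg$seed + 5L
  homologs <- simulate_homologs(chim$truth$ancestral_fragment,
                                n = sim$n_homologs, d = sim$homolog_d,
                                seed = s5)
  report <- reconstruct_path(chim$truth$exon4_region, homologs,
                             frame_offset = chim$truth$frame_offset)
  jsonlite::write_json(
    list(peptide_length = report$peptide_length,
         stop_codon = report$stop_codon,
         minimal_set = report$minimal_set,
         events = report$events,
         no_signal = report$no_signal),
    file.path(cfg$out_dir, "exonization.json"), auto_unbox = TRUE, digits = NA)
  logline("exonize", "done", "peptide:", report$peptide_length,
          "aa; minimal set:", nrow(report$minimal_set))

  # stage 6: tree of recovered copies
  s6 <- cfg$seed + 6L
  n_tree <- min(cfg$tree_max_copies, length(copy_seqs))
  tree_path <- file.path(cfg$out_dir, "tree.nwk")
  boot <- NULL
  if (n_tree >= 4) {
    msa <- center_star_align(copy_seqs[seq_len(n_tree)])
    boot <- bootstrap_nj(msa, n_reps = cfg$bootstrap_reps, seed = s6)
    write_tree(boot, tree_path)
    logline("tree", "done", n_tree, "tips,", cfg$bootstrap_reps, "replicates")
  } else {
    logline("tree", "skipped", "fewer than 4 copies")  # nocov
  }

  summary <- list(
    config_hash = cfg_hash,
    seed = cfg$seed,
    census_count = nrow(retained),
    n_hits = nrow(hits),
    blocks = blocks,
    tir_length = if (is.null(tir)) NA else tir$length,
    d_median = d_med,
    age_low_ma = age$age_low_ma,
    age_high_ma = age$age_high_ma,
    peptide_length = report$peptide_length,
    minimal_set_size = nrow(report$minimal_set),
    minimal_set_effects = report$minimal_set$effect,
    tree_file = if (is.null(boot)) NA else basename(tree_path),
    truth_age_ma = sim$age_ma
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("summary", "written", file.path(cfg$out_dir, "summary.json"))
  invisible(summary)
}

# midpoint-ish insertion position not inside any implanted copy
copy_free_position <- function(glen, copies) {
  at <- glen %/% 2L + 1L
  if (nrow(copies) == 0) return(at)
  repeat {
    inside <- copies$start <= at & at <= copies$end + 1L
    if (!any(inside)) return(at)
    at <- max(copies$end[inside]) + 2L
    if (at > glen + 1L) return(glen + 1L)  # nocov
  }
}

# extract retained census hit sequences from the genome (5'->3' on the hit
# strand), named copy_1..n in census order. With pad = TRUE the local-hit
# interval is widened to the full query span so that divergence estimates are
# not biased by the aligner's trimming of mismatching copy ends.
census_sequences <- function(retained, genome, pad = TRUE) {
  if (nrow(retained) == 0) return(setNames(character(0), character(0)))
  seqs <- vapply(seq_len(nrow(retained)), function(i) {
    s0 <- retained$start[i]; e0 <- retained$end[i]
    if (pad && all(c("qstart", "qend", "qlen") %in% names(retained))) {
      s0 <- max(1L, s0 - (retained$qstart[i] - 1L))
      e0 <- min(nchar(genome[[retained$contig[i]]]),
                e0 + (retained$qlen[i] - retained$qend[i]))
    }
    s <- substr(genome[[retained$contig[i]]], s0, e0)
    if (retained$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(seqs, paste0("copy_", seq_len(nrow(retained))))
}
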