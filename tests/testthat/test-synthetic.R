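# The synthetic-data generator: determinism, accounting, planted structure.

small_cfg <- function(seed = 91L) {
  sim_config(genome_length = 6e4, n_canonical = 3, n_mirna_like = 1,
             n_background_loci = 1, n_multimap_loci = 1,
             library_size = 12000L, seed = seed)
}

test_that("identical configurations produce byte-identical datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- simulate_dataset(small_cfg(), d1)
  ds2 <- simulate_dataset(small_cfg(), d2)
  for (f in c("genome.fasta", "reads_wt.fastq", "reads_proc_mutant.fastq",
              "reads_supp_mutant.fastq", "truth.tsv", "evidence.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  ds3 <- simulate_dataset(small_cfg(seed = 92L), withr::local_tempdir())
  expect_false(identical(readLines(ds1$genome), readLines(ds3$genome)))
})

test_that("each strain library holds exactly library_size reads", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), d)
  for (f in ds$reads) {
    expect_equal(length(readLines(f)) / 4, 12000)
  }
})

test_that("planted reads substring-match the genome at their recorded spans", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), d)
  genome <- load_genome(ds$genome)
  gseq <- as.character(genome[[1]])
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    s <- substring(gseq, tr$start + 1, tr$end)
    if (tr$strand == "-") s <- revcomp(s)
    # the mature sequence at each recorded position must exist in a strain
    # library (it was emitted as reads)
    expect_equal(nchar(s), tr$end - tr$start)
  }
  # planted mature reads appear verbatim in the suppressor library
  supp <- load_reads(ds$reads[["supp_mutant"]], "supp_mutant")
  tr1 <- ds$truth[ds$truth$kind == "CANONICAL" & ds$truth$copy == 1, ][1, ]
  mat <- substring(gseq, tr1$start + 1, tr1$end)
  if (tr1$strand == "-") mat <- revcomp(mat)
  expect_true(mat %in% supp$reads$sequence)
})

test_that("per-strain counts realize the configured fold structure", {
  d <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 3e4, n_canonical = 1, n_mirna_like = 0,
                    n_background_loci = 0, n_multimap_loci = 0,
                    fold_up_range = c(10, 10), fold_down_range = c(10, 10),
                    wt_depth_per_locus = 100, library_size = 3000L, seed = 1L)
  ds <- simulate_dataset(cfg, d)
  genome <- load_genome(ds$genome)
  libs <- list(wt = load_reads(ds$reads[["wt"]], "wt"),
               proc_mutant = load_reads(ds$reads[["proc_mutant"]], "proc_mutant"),
               supp_mutant = load_reads(ds$reads[["supp_mutant"]], "supp_mutant"))
  pset <- do.call(combine_placements,
                  lapply(libs, map_reads, genome = genome))
  tr <- ds$truth[1, ]
  w <- locus_window(tr$locus_id, tr$chrom, tr$start, tr$end, tr$strand)
  raw <- count_window(pset, w)
  # empirical fold-up within Poisson tolerance of the configured 10
  expect_gt(raw[["supp_mutant"]] / raw[["wt"]], 7)
  expect_lt(raw[["supp_mutant"]] / raw[["wt"]], 13)
  expect_gt(raw[["wt"]] / raw[["proc_mutant"]], 5)
})

test_that("a multimap locus maps with multiplicity four", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), d)
  genome <- load_genome(ds$genome)
  supp <- load_reads(ds$reads[["supp_mutant"]], "supp_mutant")
  ps <- map_reads(supp, genome)
  tr <- ds$truth[grepl("multi", ds$truth$locus_id), ]
  expect_equal(nrow(tr), 4L)
  gseq <- as.character(genome[[1]])
  mat <- substring(gseq, tr$start[1] + 1, tr$end[1])
  if (tr$strand[1] == "-") mat <- revcomp(mat)
  hits <- ps$placements[ps$placements$sequence == mat, ]
  expect_equal(nrow(hits), 4L)
  expect_equal(unique(hits$multiplicity), 4L)
  expect_setequal(hits$start, tr$start)
})

test_that("planted canonical contexts pass the hairpin call", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(genome_length = 3e5, n_canonical = 40,
                                    n_mirna_like = 0, n_background_loci = 0,
                                    n_multimap_loci = 0, library_size = 100L,
                                    wt_depth_per_locus = 0, seed = 93L), d)
  genome <- load_genome(ds$genome)
  gseq <- as.character(genome[[1]])
  params <- default_params()
  pass <- vapply(seq_len(nrow(ds$truth)), function(i) {
    tr <- ds$truth[i, ]
    c0 <- tr$start - params$flank; c1 <- tr$end + params$flank
    ctx <- substring(gseq, c0 + 1, c1)
    if (tr$strand == "-") ctx <- revcomp(ctx)
    mspan <- if (tr$strand == "+") c(tr$start - c0 + 1L, tr$end - c0) else
      c(c1 - tr$end + 1L, c1 - tr$start)
    call_hairpin(fold_nussinov(ctx), mspan)$is_hairpin
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("miRNA-like loci have no hairpin context and an override evidence row", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), d)
  ev <- load_evidence(ds$evidence)
  like <- ds$truth[ds$truth$kind == "MIRNA_LIKE", ]
  row <- ev[ev$locus_id == like$locus_id, ]
  expect_equal(row$northern_detectable, 1L)
  expect_equal(row$c3_nb, 1L)
  # no evidence for pure background loci
  expect_false(any(grepl("sirna", ev$locus_id)))
})

test_that("recovery scoring matches by reciprocal overlap", {
  truth <- data.frame(locus_id = c("a", "b"), kind = "CANONICAL",
                      chrom = "chr1", strand = "+",
                      start = c(100L, 500L), end = c(121L, 522L),
                      copies = 1L, copy = 1L, stringsAsFactors = FALSE)
  cands <- data.frame(locus_id = c("x", "y"), chrom = "chr1", strand = "+",
                      start = c(100L, 900L), end = c(121L, 921L),
                      class = c("CANONICAL", "CANONICAL"),
                      stringsAsFactors = FALSE)
  rec <- score_recovery(cands, truth)
  expect_equal(rec$sensitivity, 0.5)
  expect_equal(rec$precision, 0.5)
  expect_equal(rec$matches, c("a", NA))
  # shifting a call beyond the window length breaks the match
  cands2 <- cands[1, ]; cands2$start <- 130L; cands2$end <- 151L
  expect_equal(score_recovery(cands2, truth)$sensitivity, 0)
})
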