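# Criteria evaluation, classification, cluster seeding and the replay mode.

expr_of <- function(wt, proc, supp) {
  expression_criteria(data.frame(arm = "5p", wt = wt, proc_mutant = proc,
                                 supp_mutant = supp))
}

test_that("criteria vectors and classes reproduce the published worked loci", {
  # a fully supported known miRNA: all six criteria, canonical
  ec <- expr_of(16, 3.30, 1341.16)
  ev <- data.frame(locus_id = "x", northern_detectable = 1L,
                   c2_nb = 0L, c3_nb = 0L)
  cv <- evaluate_criteria(c1 = TRUE, ec, c4 = TRUE, c5 = TRUE, ev)
  expect_equal(cv$n_met, 6L)
  expect_equal(criteria_string(cv), "1,2,3,4,5,6")
  expect_equal(classify_candidate(cv), "CANONICAL")

  # the miRNA-like pattern: expression criteria fail from sequencing
  # (2.06-fold up; down in neither), granted on Northern evidence; no
  # hairpin, no star; 4 criteria -> validated but non-canonical
  ec2 <- expr_of(12.00, 754.68, 24.72)
  expect_false(ec2$c2); expect_false(ec2$c3)
  ev2 <- data.frame(locus_id = "d4", northern_detectable = 1L,
                    c2_nb = 1L, c3_nb = 1L)
  cv2 <- evaluate_criteria(TRUE, ec2, c4 = FALSE, c5 = FALSE, ev2)
  expect_equal(cv2$n_met, 4L)
  expect_equal(cv2$c2_source, "NB_OVERRIDE")
  expect_equal(criteria_set(cv2), c(1L, 2L, 3L, 6L))
  expect_match(criteria_string(cv2), "3 \\(based on NB\\)")
  expect_equal(classify_candidate(cv2), "MIRNA_LIKE")

  # three criteria only: rejected
  cv3 <- evaluate_criteria(TRUE, expr_of(10, 1, 100), FALSE, FALSE, NULL)
  expect_equal(cv3$n_met, 3L)
  expect_equal(classify_candidate(cv3), "REJECTED")

  # all false
  cv4 <- evaluate_criteria(FALSE, expr_of(5, 5, 5), FALSE, FALSE, NULL)
  expect_equal(cv4$n_met, 0L)
})

test_that("the classifier is monotone in the criteria", {
  rank <- c(REJECTED = 0, MIRNA_LIKE = 1, CANONICAL = 2)
  set.seed(51)
  for (i in 1:50) {
    flags <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    mk <- function(f) {
      ec <- expr_of(10, if (f[3]) 1 else 10, if (f[2]) 100 else 10)
      evaluate_criteria(f[1], ec, f[4], f[5],
                        data.frame(locus_id = "z",
                                   northern_detectable = as.integer(f[6]),
                                   c2_nb = 0L, c3_nb = 0L))
    }
    base <- classify_candidate(mk(flags))
    off <- which(!flags)
    if (length(off)) {
      j <- sample(off, 1)
      flags2 <- flags; flags2[j] <- TRUE
      expect_gte(rank[classify_candidate(mk(flags2))], rank[base])
    }
  }
})

test_that("cluster seeding finds planted loci and ignores sparse background", {
  mk_pset <- function(placements) {
    structure(list(placements = placements,
                   totals = c(wt = 1000L, proc_mutant = 1000L,
                              supp_mutant = 1000L),
                   seqlengths = c(chr1 = 10000L)),
              class = "placement_set")
  }
  pl <- function(strain, start, len, count, strand = "+", seq = NULL) {
    data.frame(strain = strain,
               sequence = if (is.null(seq)) strrep("A", len) else seq,
               chrom = "chr1", start = start, end = start + len,
               strand = strand, count = count, multiplicity = 1L,
               stringsAsFactors = FALSE)
  }
  # one planted miRNA with 50 suppressor reads seeds exactly one window
  ps <- mk_pset(rbind(pl("supp_mutant", 500, 21, 50, seq = "M"),
                      pl("wt", 500, 21, 5, seq = "M")))
  seeds <- seed_candidates(ps)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$start, 500L)
  expect_equal(seeds$end, 521L)

  # sparse background below min_reads seeds nothing
  bg <- do.call(rbind, lapply(seq(100, 4000, by = 100), function(s) {
    pl("supp_mutant", s, 22, 1, seq = rand_dna(22))
  }))
  expect_equal(nrow(seed_candidates(mk_pset(bg))), 0L)

  # two loci 1 kb apart are never merged at the default cluster gap
  two <- rbind(pl("supp_mutant", 1000, 21, 40, seq = "M1"),
               pl("supp_mutant", 2000, 21, 40, seq = "M2"))
  seeds2 <- seed_candidates(mk_pset(two))
  expect_equal(seeds2$start, c(1000L, 2000L))

  # a modal read outside the 20-24 nt window does not seed
  ps3 <- mk_pset(pl("supp_mutant", 700, 30, 50, seq = strrep("G", 30)))
  expect_equal(nrow(seed_candidates(ps3)), 0L)
})

test_that("replay reproduces the printed criteria column for all seven loci", {
  ev <- load_evidence(published_evidence_path())
  res <- replay_expression_table(published_table_path(), evidence = ev)
  expect_equal(nrow(res), 7L)
  sets <- lapply(seq_len(nrow(res)), function(i) {
    as.integer(strsplit(gsub(" \\(based on NB\\)", "", res$criteria[i]),
                        ",")[[1]])
  })
  names(sets) <- res$locus_id
  for (lid in c("ddi-miR-1176", "ddi-miR-1177", "miRNA_can_D1",
                "miRNA_can_D2", "ddi-mir-7097", "miRNA_can_D3")) {
    expect_equal(sets[[lid]], 1:6, info = lid)
    expect_equal(res$class[res$locus_id == lid], "CANONICAL", info = lid)
  }
  expect_equal(sets[["miRNA-like_D4"]], c(1L, 2L, 3L, 6L))
  expect_equal(res$class[res$locus_id == "miRNA-like_D4"], "MIRNA_LIKE")

  # permutation of input rows leaves every classification unchanged
  tab <- read_expression_table(published_table_path())
  set.seed(52)
  tab2 <- tab[sample(nrow(tab)), ]
  res2 <- replay_expression_table(tab2, evidence = ev)
  expect_equal(res2$class[match(res$locus_id, res2$locus_id)], res$class)
  expect_equal(res2$n_met[match(res$locus_id, res2$locus_id)], res$n_met)
})

test_that("discovery runs end to end on a constructed mini-locus", {
  set.seed(53)
  mature <- rand_dna(21, gc = 0.3)
  loop <- rand_dna(8, gc = 0.3)
  hairpin <- paste0(mature, loop, revcomp(mature))
  gseq <- paste0(rand_dna(300, gc = 0.3), hairpin, rand_dna(300, gc = 0.3))
  genome <- Biostrings::DNAStringSet(c(chr1 = gseq))
  star <- substring(gseq, 300 + 21 + 8 + 2 + 1, 300 + 21 + 8 + 2 + 21)
  # a shared mapped background keeps the per-strain RPM denominators
  # comparable, as in a real library
  bg <- vapply(seq(1, 250), function(s) substring(gseq, s, s + 21), character(1))
  libs <- libs_from_seqs(
    wt = c(rep(mature, 10), rep(star, 2), bg),
    proc = c(rep(mature, 1), bg),
    supp = c(rep(mature, 80), rep(star, 8), bg)
  )
  cands <- discover_mirnas(genome, libs)
  expect_gte(nrow(cands), 1L)
  main <- cands[cands$start == 300L, ]
  expect_equal(nrow(main), 1L)
  expect_true(main$c1); expect_true(main$c2); expect_true(main$c3)
  expect_true(main$c4); expect_true(main$c5); expect_false(main$c6)
  expect_equal(main$class, "CANONICAL")
  expect_equal(main$arm, "5p")
  expect_equal(dna_to_rna(mature), main$sequence)

  # empty libraries give an empty candidate table
  empty <- libs_from_seqs(character(0), character(0), character(0))
  expect_equal(nrow(discover_mirnas(genome, empty)), 0L)

  # a missing strain is a configuration error
  expect_error(discover_mirnas(genome, libs[c("wt", "supp_mutant")]),
               "configuration error")
})
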