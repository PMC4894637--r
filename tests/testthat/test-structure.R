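# Folding, the hairpin criterion, star geometry and star-read detection.

test_that("maximum-pairing fold handles canonical examples", {
  f0 <- fold_nussinov("AAAAAA")
  expect_equal(f0$score, 0L)
  expect_equal(f0$dotbracket, "......")

  f1 <- fold_nussinov("GGGGAAAACCCC", min_loop = 3)
  expect_equal(f1$score, 4L)
  expect_equal(f1$dotbracket, "((((....))))")

  # perfect-complement construction around a published 21-mer mature
  M <- rna_to_dna("CCAAUUUUUAUCAAGGAAAGC")
  ctx <- paste0(M, "GAAA", revcomp(M))
  f2 <- fold_nussinov(ctx)
  expect_equal(f2$score, 21L)
  expect_true(all(!is.na(f2$ptable[1:21])))
})

test_that("fold score equals exhaustive enumeration on short sequences", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    s <- rand_dna(n, gc = runif(1, 0.2, 0.8))
    expect_equal(fold_nussinov(s)$score, brute_max_pairs(s),
                 info = paste("seq:", s))
  }
})

test_that("fold structures are valid and the score is strand-symmetric", {
  set.seed(42)
  for (i in 1:25) {
    s <- rand_dna(sample(10:60, 1), gc = 0.3)
    f <- fold_nussinov(s)
    # pairs are nested, non-crossing, respect the loop constraint
    if (nrow(f$pairs)) {
      expect_true(all(f$pairs[, 2] - f$pairs[, 1] > 3))
      for (a in seq_len(nrow(f$pairs))) {
        i1 <- f$pairs[a, 1]; j1 <- f$pairs[a, 2]
        crossing <- f$pairs[, 1] < i1 & f$pairs[, 2] > i1 & f$pairs[, 2] < j1
        expect_false(any(crossing))
      }
      # every pair is AU, GC or GU
      ch <- strsplit(f$sequence, "")[[1]]
      kinds <- paste0(ch[f$pairs[, 1]], ch[f$pairs[, 2]])
      expect_true(all(kinds %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
    }
    # folding score is invariant under sequence reversal: reversal maps a
    # nested pair set onto a nested pair set with the same base pairs
    # (reverse COMPLEMENT is not a symmetry here: it maps the wobble pair
    # G:U onto the non-pair A:C)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(fold_nussinov(rev_s)$score, f$score)
  }
})

test_that("hairpin calls separate true hairpins from complement-free contexts", {
  set.seed(43)
  M <- rand_dna(21, gc = 0.3)
  ctx <- perfect_hairpin_context(M, flank = 10)
  mspan <- c(11L, 31L)
  hp <- call_hairpin(fold_nussinov(ctx), mspan)
  expect_true(hp$is_hairpin)
  expect_equal(hp$paired_fraction, 1)
  expect_equal(hp$loop_length, 4L)
  expect_equal(hp$mature_arm, "5p")

  # a mature of A/C embedded in A/C flanks cannot pair at all
  ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
  ctx2 <- paste0(ac(40), ac(21), ac(40))
  hp2 <- call_hairpin(fold_nussinov(ctx2), c(41L, 61L))
  expect_false(hp2$is_hairpin)
  expect_lt(hp2$paired_fraction, 0.6)

  expect_error(call_hairpin(fold_nussinov(ctx), c(90, 130)), "outside")
})

test_that("dinucleotide-shuffled hairpin contexts are rejected", {
  set.seed(44)
  M <- rand_dna(21, gc = 0.23)
  ctx <- paste0(rand_dna(50, 0.23), M, "GAAAGAAA", revcomp(M),
                rand_dna(50, 0.23))
  mspan <- c(51L, 71L)
  expect_true(call_hairpin(fold_nussinov(ctx), mspan)$is_hairpin)
  calls <- vapply(1:100, function(i) {
    shuf <- shuffle_dinucleotide(ctx)
    call_hairpin(fold_nussinov(shuf), mspan)$is_hairpin
  }, logical(1))
  expect_gte(mean(!calls), 0.95)
})

test_that("raising the pairing threshold never creates a hairpin", {
  set.seed(45)
  for (i in 1:15) {
    ctx <- rand_dna(120, gc = 0.25)
    f <- fold_nussinov(ctx)
    calls <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
      call_hairpin(f, c(50L, 70L), theta_pair = th)$is_hairpin
    }, logical(1))
    # once FALSE at a lower threshold, never TRUE at a higher one
    expect_true(all(diff(as.integer(calls)) <= 0))
  }
})

test_that("star prediction applies 2-nt 3' overhang duplex geometry", {
  set.seed(46)
  M <- rand_dna(21, gc = 0.4)
  ctx <- perfect_hairpin_context(M, flank = 10)
  hp <- call_hairpin(fold_nussinov(ctx), c(11L, 31L))
  st <- predict_star(hp)
  # opposite-arm window (partners of the mature) shifted by the overhang
  opp <- hp$opposite_span
  expect_equal(st$star_span, opp + 2L)
  expect_equal(diff(st$star_span), diff(c(11L, 31L)))
  expect_equal(st$star_arm, "3p")

  # involution on a perfect stem: the star of the star is the mature
  hp_star <- call_hairpin(fold_nussinov(ctx), st$star_span)
  expect_equal(hp_star$mature_arm, "3p")
  st2 <- predict_star(hp_star)
  expect_equal(st2$star_span, c(11L, 31L))
  expect_equal(st2$star_arm, "5p")

  expect_error(predict_star(call_hairpin(fold_nussinov("ACACACACACAC"),
                                         c(1, 4))),
               "requires a positive hairpin call")
})

test_that("a bulge on the star side widens the predicted star span", {
  set.seed(47)
  M <- rand_dna(21, gc = 0.5)
  arm <- revcomp(M)
  bulged <- paste0(substring(arm, 1, 10), "GG", substring(arm, 11, 21))
  ctx <- paste0(M, "GAAA", bulged, "AAAA")
  f <- fold_nussinov(ctx)
  hp <- call_hairpin(f, c(1L, 21L))
  expect_true(hp$is_hairpin)
  st <- predict_star(hp)
  expect_equal(diff(st$star_span) - diff(c(1L, 21L)), 2L)
})

test_that("star support detection respects the positional tolerance", {
  gseq <- rand_dna(300)
  genome <- Biostrings::DNAStringSet(c(chr1 = gseq))
  star_win <- data.frame(chrom = "chr1", start = 100L, end = 121L,
                         strand = "+")
  star <- structure(list(star_span = c(101L, 121L), overhang = 2L,
                         star_arm = "3p", supported = NA,
                         supporting_reads = 0L),
                    class = "star_prediction")
  mk <- function(s, e, strand = "+", count = 1L) {
    structure(list(placements = data.frame(
      strain = "wt", sequence = "x", chrom = "chr1", start = s, end = e,
      strand = strand, count = count, multiplicity = 1L,
      stringsAsFactors = FALSE),
      totals = c(wt = 1L), seqlengths = c(chr1 = 300L)),
      class = "placement_set")
  }
  # shifted by exactly the tolerance: supported
  got <- detect_star_reads(mk(98L, 119L), star, star_win, tolerance = 2L)
  expect_true(got$supported)
  # shifted by tolerance + 1: not supported
  got2 <- detect_star_reads(mk(97L, 118L), star, star_win, tolerance = 2L)
  expect_false(got2$supported)
  # opposite strand never supports
  got3 <- detect_star_reads(mk(100L, 121L, strand = "-"), star, star_win)
  expect_false(got3$supported)
  # supporting reads sum collapsed counts
  got4 <- detect_star_reads(mk(100L, 121L, count = 7L), star, star_win)
  expect_equal(got4$supporting_reads, 7L)
})
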