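# End-to-end discovery: map -> seed -> quantify -> fold -> star -> criteria
# -> classify, plus the replay mode that re-classifies loci from a published
# relative-expression table.

# genomic (0-based half-open) -> context sequence on the locus strand
extract_context <- function(genome, chrom, start0, end0, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start = start0 + 1L, end = end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

reciprocal_overlap <- function(a1, a2, b1, b2, frac = 0.5) {
  inter <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  inter >= frac * (a2 - a1) & inter >= frac * (b2 - b1)
}

match_evidence <- function(evidence, window) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(NULL)
  if (all(c("chrom", "start", "end") %in% names(evidence))) {
    hit <- evidence$chrom == window$chrom &
      reciprocal_overlap(evidence$start, evidence$end, window$start, window$end)
    if (!is.null(evidence$strand)) hit <- hit & evidence$strand == window$strand
    if (any(hit)) return(evidence[which(hit)[1], , drop = FALSE])
    return(NULL)
  }
  hit <- evidence$locus_id == window$locus_id
  if (any(hit)) evidence[which(hit)[1], , drop = FALSE] else NULL
}

#' Discover miRNA loci from three strain libraries
#'
#' Runs the full pipeline: exact mapping of all three libraries, cluster
#' seeding on the suppressor strain, windowed quantification, folding of the
#' +/- `flank` nt genomic context, hairpin and star-arm calls, evaluation of
#' the six criteria and classification. The result is deterministic and
#' independent of read input order.
#'
#' @param genome named [Biostrings::DNAStringSet] (see [load_genome()]).
#' @param libraries named list with elements `wt`, `proc_mutant` and
#'   `supp_mutant`, each a `strain_library`.
#' @param evidence optional `evidence_table` (see [load_evidence()]). Rows
#'   carrying `chrom`/`start`/`end` are matched to candidates by >= 50%
#'   reciprocal overlap of the mature windows; rows without coordinates by
#'   `locus_id`.
#' @param params pipeline parameters, see [default_params()].
#' @param windows optional data.frame of candidate mature windows (columns
#'   `locus_id`, `chrom`, `start`, `end` (0-based half-open), `strand`). When
#'   given, cluster seeding is skipped and these windows are evaluated
#'   directly.
#' @return data.frame of class `mirna_candidates`, one row per locus, sorted
#'   by chromosome and start, with mature/star coordinates (0-based
#'   half-open), per-strain raw counts and RPM, fold changes, criteria flags
#'   `c1`..`c6`, `n_met`, the criteria string, and `class`
#'   (`CANONICAL`/`MIRNA_LIKE`/`REJECTED`). Per-arm expression rows are
#'   attached as `attr(, "arms")`.
#' @export
discover_mirnas <- function(genome, libraries, evidence = NULL,
                            params = default_params(), windows = NULL) {
  need <- STRAINS
  if (!all(need %in% names(libraries))) {
    stop("configuration error: libraries must be a named list with strains ",
         paste(need, collapse = ", "))
  }
  psets <- lapply(need, function(s) {
    lib <- libraries[[s]]
    stopifnot(inherits(lib, "strain_library"))
    if (lib$strain != s) stop("library at position '", s, "' is labelled '",
                              lib$strain, "'")
    map_reads(lib, genome, k = params$k)
  })
  pset <- do.call(combine_placements, psets)
  if (is.null(windows)) {
    seeds <- seed_candidates(pset,
                             min_reads = params$seed_min_reads,
                             max_cluster_gap = params$max_cluster_gap,
                             len_min = params$len_min, len_max = params$len_max)
  } else {
    stopifnot(all(c("locus_id", "chrom", "start", "end", "strand") %in%
                    names(windows)))
    seeds <- data.frame(
      locus_id = windows$locus_id, chrom = windows$chrom,
      start = as.integer(windows$start), end = as.integer(windows$end),
      strand = windows$strand,
      modal_sequence = vapply(seq_len(nrow(windows)), function(i) {
        extract_context(genome, windows$chrom[i], windows$start[i],
                        windows$end[i], windows$strand[i])
      }, character(1)),
      multiplicity = NA_integer_, stringsAsFactors = FALSE
    )
  }
  rows <- list(); arm_rows <- list()
  for (i in seq_len(nrow(seeds))) {
    sd <- seeds[i, , drop = FALSE]
    cand <- build_candidate(sd, pset, genome, evidence, params)
    rows[[length(rows) + 1L]] <- cand$row
    arm_rows[[length(arm_rows) + 1L]] <- cand$arms
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  arms <- if (length(arm_rows)) do.call(rbind, arm_rows) else NULL
  # collapse candidates whose hairpin footprints overlap (e.g. a star arm
  # seeded as its own cluster): keep the most abundant mature per group
  if (nrow(res) > 1L) {
    keep <- dedup_candidates(res)
    res <- res[keep, , drop = FALSE]
    if (!is.null(arms)) arms <- arms[arms$locus_id %in% res$locus_id, , drop = FALSE]
  }
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "arms") <- arms
  class(res) <- c("mirna_candidates", "data.frame")
  res
}

empty_candidates <- function() {
  data.frame(
    locus_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), arm = character(0),
    sequence = character(0), length = integer(0), multiplicity = integer(0),
    raw_wt = numeric(0), raw_proc = numeric(0), raw_supp = numeric(0),
    rpm_wt = numeric(0), rpm_proc = numeric(0), rpm_supp = numeric(0),
    fold_up = numeric(0), fold_down = numeric(0),
    c1 = logical(0), c2 = logical(0), c3 = logical(0), c4 = logical(0),
    c5 = logical(0), c6 = logical(0), n_met = integer(0),
    criteria = character(0), class = character(0),
    paired_fraction = numeric(0), loop_length = integer(0),
    star_start = integer(0), star_end = integer(0), star_reads = integer(0),
    star_sequence = character(0),
    stringsAsFactors = FALSE
  )
}

build_candidate <- function(sd, pset, genome, evidence, params) {
  chrlen <- pset$seqlengths[[sd$chrom]]
  cstart0 <- max(sd$start - params$flank, 0L)
  cend0 <- min(sd$end + params$flank, chrlen)
  ctx <- extract_context(genome, sd$chrom, cstart0, cend0, sd$strand)
  ctx_len <- nchar(ctx)
  if (sd$strand == "+") {
    mspan <- c(sd$start - cstart0 + 1L, sd$end - cstart0)
  } else {
    mspan <- c(cend0 - sd$end + 1L, cend0 - sd$start)
  }
  fold <- fold_nussinov(ctx, min_loop = params$min_loop)
  hp <- call_hairpin(fold, mspan, theta_pair = params$theta_pair,
                     max_loop = params$max_loop, max_bulge = params$max_bulge,
                     theta_register = params$theta_register)
  star <- NULL; star_win <- NULL; star_seq <- NA_character_
  if (hp$is_hairpin) {
    star <- predict_star(hp, overhang = params$overhang)
    sg <- context_to_genomic(star$star_span, cstart0, ctx_len, sd$strand)
    star_win <- locus_window(paste0(sd$locus_id, "_star"), sd$chrom,
                             sg[1], sg[2], sd$strand, arm = star$star_arm)
    star <- detect_star_reads(pset, star, star_win,
                              tolerance = params$star_tolerance,
                              min_star_reads = params$min_star_reads)
    star_seq <- dna_to_rna(extract_context(genome, sd$chrom, sg[1], sg[2],
                                           sd$strand))
  }
  mature_arm <- if (!is.na(hp$mature_arm)) hp$mature_arm else NA_character_
  mwin <- locus_window(sd$locus_id, sd$chrom, sd$start, sd$end, sd$strand,
                       arm = mature_arm)
  raw_m <- count_window(pset, mwin, margin = params$margin)
  prof_m <- normalize_counts(raw_m, pset$totals)
  arm_expr <- data.frame(
    arm = mature_arm,
    wt = prof_m$rpm[prof_m$strain == "wt"],
    proc_mutant = prof_m$rpm[prof_m$strain == "proc_mutant"],
    supp_mutant = prof_m$rpm[prof_m$strain == "supp_mutant"],
    stringsAsFactors = FALSE
  )
  if (!is.null(star_win)) {
    raw_s <- count_window(pset, star_win, margin = params$margin)
    prof_s <- normalize_counts(raw_s, pset$totals)
    arm_expr <- rbind(arm_expr, data.frame(
      arm = star$star_arm,
      wt = prof_s$rpm[prof_s$strain == "wt"],
      proc_mutant = prof_s$rpm[prof_s$strain == "proc_mutant"],
      supp_mutant = prof_s$rpm[prof_s$strain == "supp_mutant"],
      stringsAsFactors = FALSE
    ))
  }
  expr <- expression_criteria(arm_expr, f_up = params$f_up, f_down = params$f_down)
  mature_len <- sd$end - sd$start
  c1 <- mature_len >= params$len_min && mature_len <= params$len_max
  ev_row <- match_evidence(evidence, mwin)
  cv <- evaluate_criteria(c1, expr, hp$is_hairpin, isTRUE(star$supported), ev_row)
  cls <- classify_candidate(cv, validated_min = params$validated_min)
  row <- data.frame(
    locus_id = sd$locus_id, chrom = sd$chrom, start = sd$start, end = sd$end,
    strand = sd$strand, arm = mature_arm,
    sequence = dna_to_rna(sd$modal_sequence), length = mature_len,
    multiplicity = sd$multiplicity,
    raw_wt = raw_m[["wt"]], raw_proc = raw_m[["proc_mutant"]],
    raw_supp = raw_m[["supp_mutant"]],
    rpm_wt = arm_expr$wt[1], rpm_proc = arm_expr$proc_mutant[1],
    rpm_supp = arm_expr$supp_mutant[1],
    fold_up = cv$fold_up, fold_down = cv$fold_down,
    c1 = cv$c1, c2 = cv$c2, c3 = cv$c3, c4 = cv$c4, c5 = cv$c5, c6 = cv$c6,
    n_met = cv$n_met, criteria = criteria_string(cv), class = cls,
    paired_fraction = hp$paired_fraction, loop_length = hp$loop_length,
    star_start = if (is.null(star_win)) NA_integer_ else star_win$start,
    star_end = if (is.null(star_win)) NA_integer_ else star_win$end,
    star_reads = if (is.null(star)) 0L else star$supporting_reads,
    star_sequence = star_seq,
    stringsAsFactors = FALSE
  )
  arms <- data.frame(
    locus_id = sd$locus_id, arm = arm_expr$arm,
    wt = arm_expr$wt, proc_mutant = arm_expr$proc_mutant,
    supp_mutant = arm_expr$supp_mutant,
    fold_up = expr$per_arm$fold_up, fold_down = expr$per_arm$fold_down,
    stringsAsFactors = FALSE
  )
  list(row = row, arms = arms)
}

# Indices of candidates kept after collapsing overlapping hairpin
# footprints. Strand is ignored: on a near-perfect inverted repeat every arm
# read also maps to the sister arm's position on the opposite strand, so the
# same hairpin is seen from both strands and must be reported once. The
# best-supported view (most criteria met, then most suppressor reads) wins.
dedup_candidates <- function(res) {
  fp_start <- pmin(res$start, ifelse(is.na(res$star_start), res$start, res$star_start))
  fp_end <- pmax(res$end, ifelse(is.na(res$star_end), res$end, res$star_end))
  gr <- GenomicRanges::GRanges(res$chrom,
                               IRanges::IRanges(fp_start + 1L, fp_end))
  groups <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, groups)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  keep <- logical(nrow(res))
  for (g in unique(grp)) {
    members <- which(grp == g)
    best <- members[order(-res$n_met[members], -res$raw_supp[members],
                          res$start[members])][1]
    keep[best] <- TRUE
  }
  which(keep)
}

#' @export
print.mirna_candidates <- function(x, ...) {
  cat("mirna_candidates:", nrow(x), "locus/loci\n")
  if (nrow(x)) print(table(x$class))
  invisible(x)
}

#' Re-classify loci from a published relative-expression table (replay mode)
#'
#' Feeds printed per-arm relative-expression values, together with per-locus
#' hairpin/star flags and Northern blot evidence, through the same criteria
#' engine used for discovery. Because fold ratios are invariant to a common
#' per-row scale, relative expression can stand in for RPM directly. The
#' mature arm of each locus is taken as the arm with the highest suppressor
#' expression; criterion 1 tests its sequence length.
#'
#' @param expr path to a replay TSV (see [read_expression_table()]) or an
#'   equivalent data.frame.
#' @param evidence optional `evidence_table` matched by `locus_id`.
#' @param params pipeline parameters, see [default_params()].
#' @return data.frame of class `mirna_candidates` with one row per locus:
#'   criteria flags, `n_met`, criteria string, `class`, locus-level folds,
#'   mature sequence (RNA alphabet) and `is_new` (negation of the `known`
#'   flag; NA when absent). Per-arm folds are attached as `attr(, "arms")`.
#' @export
replay_expression_table <- function(expr, evidence = NULL,
                                    params = default_params()) {
  if (is.character(expr)) expr <- read_expression_table(expr)
  rows <- list(); arm_rows <- list()
  for (lid in unique(expr$locus_id)) {
    sub <- expr[expr$locus_id == lid, , drop = FALSE]
    ec <- expression_criteria(sub[, c("arm", "wt", "proc_mutant", "supp_mutant")],
                              f_up = params$f_up, f_down = params$f_down)
    mature <- sub[order(-sub$supp_mutant), ][1, ]
    mature_len <- nchar(mature$sequence)
    c1 <- mature_len >= params$len_min && mature_len <= params$len_max
    c4 <- isTRUE(max(sub$hairpin, na.rm = TRUE) == 1)
    c5 <- isTRUE(max(sub$star, na.rm = TRUE) == 1)
    ev_row <- if (!is.null(evidence)) {
      hit <- evidence$locus_id == lid
      if (any(hit)) evidence[which(hit)[1], , drop = FALSE] else NULL
    }
    cv <- evaluate_criteria(c1, ec, c4, c5, ev_row)
    cls <- classify_candidate(cv, validated_min = params$validated_min)
    known <- if (is.null(sub$known)) NA else max(sub$known, na.rm = TRUE) == 1
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lid, arm = mature$arm, sequence = dna_to_rna(mature$sequence),
      length = mature_len, fold_up = cv$fold_up, fold_down = cv$fold_down,
      c1 = cv$c1, c2 = cv$c2, c3 = cv$c3, c4 = cv$c4, c5 = cv$c5, c6 = cv$c6,
      n_met = cv$n_met, criteria = criteria_string(cv), class = cls,
      is_new = !known, stringsAsFactors = FALSE
    )
    arm_rows[[length(arm_rows) + 1L]] <-
      cbind(locus_id = lid, ec$per_arm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "arms") <- do.call(rbind, arm_rows)
  class(res) <- c("mirna_candidates", "data.frame")
  res
}
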