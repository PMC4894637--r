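# The six identification criteria and the locus classifier.
#
#   c1: mature length 20-24 nt
#   c2: >= f_up-fold higher in the suppressor mutant than in WT
#   c3: >= f_down-fold lower in the processing mutant than in WT
#   c4: mature resides in a hairpin-like structure
#   c5: a corresponding star arm (miRNA-5p/-3p partner) is detectable
#   c6: detectable by Northern blot (experimental evidence, never computed)
#
# A locus is validated when >= validated_min (default 4) criteria are met.
# Validated loci with both c4 and c5 are canonical miRNAs; validated loci
# lacking hairpin context or star support are non-canonical miRNA-like RNAs.
# Northern blot evidence may override c2/c3 ("based on NB"), mirroring how a
# published miRNA-like locus was credited with the processing-mutant
# criterion against its sequencing numbers.

#' Assemble a criteria vector for one locus
#'
#' @param c1,c4,c5 logicals for the length, hairpin and star criteria.
#' @param expr result of [expression_criteria()] (provides c2/c3 and folds).
#' @param evidence_row one-row data.frame from an evidence table matched to
#'   this locus, or `NULL`. `northern_detectable == 1` sets c6; `c2_nb`/
#'   `c3_nb == 1` override c2/c3 to TRUE with source `"NB_OVERRIDE"`.
#' @return List of class `criteria_vector`: logicals `c1`..`c6`, `n_met`,
#'   `c2_source`/`c3_source` (`"SEQ"` or `"NB_OVERRIDE"`), `fold_up`,
#'   `fold_down`.
#' @export
evaluate_criteria <- function(c1, expr, c4, c5, evidence_row = NULL) {
  c2 <- isTRUE(expr$c2); c3 <- isTRUE(expr$c3)
  c2_source <- "SEQ"; c3_source <- "SEQ"
  c6 <- FALSE
  if (!is.null(evidence_row)) {
    c6 <- isTRUE(evidence_row$northern_detectable == 1)
    if (!c2 && isTRUE(evidence_row$c2_nb == 1)) { c2 <- TRUE; c2_source <- "NB_OVERRIDE" }
    if (!c3 && isTRUE(evidence_row$c3_nb == 1)) { c3 <- TRUE; c3_source <- "NB_OVERRIDE" }
  }
  v <- c(c1 = isTRUE(c1), c2 = c2, c3 = c3, c4 = isTRUE(c4),
         c5 = isTRUE(c5), c6 = c6)
  structure(
    list(c1 = v[["c1"]], c2 = v[["c2"]], c3 = v[["c3"]], c4 = v[["c4"]],
         c5 = v[["c5"]], c6 = v[["c6"]], n_met = sum(v),
         c2_source = c2_source, c3_source = c3_source,
         fold_up = expr$fold_up, fold_down = expr$fold_down),
    class = "criteria_vector"
  )
}

#' Classify a locus from its criteria vector
#'
#' Validated (>= `validated_min` criteria met) loci with both hairpin context
#' (c4) and star support (c5) are `"CANONICAL"`; validated loci without that
#' structural pair are `"MIRNA_LIKE"`; all others are `"REJECTED"`. The
#' at-least-four rule alone cannot separate canonical from miRNA-like loci,
#' which is exactly the distinction the structural criteria carry.
#'
#' @param criteria a `criteria_vector`.
#' @param validated_min criteria required for validation (default 4).
#' @return `"CANONICAL"`, `"MIRNA_LIKE"` or `"REJECTED"`.
#' @export
classify_candidate <- function(criteria, validated_min = 4L) {
  stopifnot(inherits(criteria, "criteria_vector"))
  if (criteria$n_met < validated_min) return("REJECTED")
  if (criteria$c4 && criteria$c5) "CANONICAL" else "MIRNA_LIKE"
}

#' Criteria met, as the integer set \{1..6\}
#'
#' @param criteria a `criteria_vector`.
#' @return Integer vector of met criterion numbers.
#' @export
criteria_set <- function(criteria) {
  unname(which(unlist(criteria[c("c1", "c2", "c3", "c4", "c5", "c6")])))
}

#' Human-readable criteria string
#'
#' Met criteria joined by commas; criteria granted on Northern blot evidence
#' are annotated, e.g. `"1,2,3 (based on NB),6"`.
#'
#' @param criteria a `criteria_vector`.
#' @return character scalar.
#' @export
criteria_string <- function(criteria) {
  met <- criteria_set(criteria)
  lab <- as.character(met)
  if (criteria$c2_source == "NB_OVERRIDE") lab[met == 2] <- "2 (based on NB)"
  if (criteria$c3_source == "NB_OVERRIDE") lab[met == 3] <- "3 (based on NB)"
  paste(lab, collapse = ",")
}

#' Seed candidate mature windows from read clusters
#'
#' Same-strand placements separated by at most `max_cluster_gap` nt are
#' merged into maximal clusters. Within each cluster the modal read — highest
#' suppressor-strain count, ties broken by total count, then leftmost start,
#' then sequence — defines the putative mature window. Clusters are kept when
#' the modal read itself carries at least `min_reads` suppressor-strain reads
#' (a putative mature must be expressed; diffuse clusters of scattered
#' singleton reads do not qualify) and the modal read length lies within
#' `[len_min, len_max]`.
#'
#' @param pset a `placement_set` holding all three strains.
#' @param min_reads minimum suppressor-strain read count (default 5).
#' @param max_cluster_gap maximum intra-cluster gap in nt (default 30).
#' @param len_min,len_max modal-read length window (default 20, 24).
#' @return data.frame of windows: `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open, the modal read span), `strand`, `cluster_start`,
#'   `cluster_end`, `supp_reads`, `modal_sequence`, `multiplicity`.
#' @export
seed_candidates <- function(pset, min_reads = 5L, max_cluster_gap = 30L,
                            len_min = 20L, len_max = 24L) {
  pl <- pset$placements
  empty <- data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), cluster_start = integer(0),
                      cluster_end = integer(0), supp_reads = integer(0),
                      modal_sequence = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pl) == 0L) return(empty)
  gr <- placements_granges(pset)
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = max_cluster_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, clusters)
  cl_of <- setNames(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  pl$cluster <- as.integer(cl_of[as.character(seq_len(nrow(pl)))])
  # suppressor read count per cluster, vectorized; only qualifying clusters
  # are inspected further
  supp_counts <- ifelse(pl$strain == "supp_mutant", pl$count, 0L)
  supp_by_cluster <- rep(0L, length(clusters))
  agg <- tapply(supp_counts, pl$cluster, sum)
  supp_by_cluster[as.integer(names(agg))] <- as.integer(agg)
  rows_by_cluster <- split(seq_len(nrow(pl)), pl$cluster)
  out <- list()
  for (ci in which(supp_by_cluster >= min_reads)) {
    sub <- pl[rows_by_cluster[[as.character(ci)]], , drop = FALSE]
    supp_n <- supp_by_cluster[ci]
    # modal read species within the cluster
    key <- paste(sub$sequence, sub$start, sub$end)
    supp_cnt <- tapply(ifelse(sub$strain == "supp_mutant", sub$count, 0L), key, sum)
    tot_cnt <- tapply(sub$count, key, sum)
    first <- !duplicated(key)
    species <- data.frame(
      sequence = sub$sequence[first], start = sub$start[first],
      end = sub$end[first], stringsAsFactors = FALSE
    )
    k <- key[first]
    species$supp <- as.integer(supp_cnt[k])
    species$total <- as.integer(tot_cnt[k])
    ord <- order(-species$supp, -species$total, species$start, species$sequence)
    modal <- species[ord[1], ]
    if (modal$supp < min_reads) next
    if (modal$end - modal$start < len_min || modal$end - modal$start > len_max) next
    mult <- sub$multiplicity[sub$sequence == modal$sequence][1]
    chrom <- as.character(GenomicRanges::seqnames(clusters)[ci])
    strand <- as.character(GenomicRanges::strand(clusters)[ci])
    out[[length(out) + 1L]] <- data.frame(
      locus_id = sprintf("locus_%s_%d_%s", chrom, modal$start,
                         if (strand == "+") "fwd" else "rev"),
      chrom = chrom, start = modal$start, end = modal$end, strand = strand,
      cluster_start = GenomicRanges::start(clusters)[ci] - 1L,
      cluster_end = GenomicRanges::end(clusters)[ci],
      supp_reads = supp_n, modal_sequence = modal$sequence,
      multiplicity = as.integer(mult), stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
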