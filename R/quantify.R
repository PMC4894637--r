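# Windowed quantification and the two fold-change criteria.
#
# Reads are counted in the mature-arm window extended by `margin` nt on each
# side (a read is counted iff fully contained, strand-matched). Raw counts
# are converted to reads per million aligned (RPM) and expressed relative to
# the wild type. Fold changes use the zero-denominator convention
# x/0 = +Inf for x > 0 and 0/0 = 0, with no pseudocounts, so that complete
# loss in the processing mutant passes the 3-fold-down criterion.

#' Construct a locus window
#'
#' @param locus_id locus identifier.
#' @param chrom chromosome id.
#' @param start,end 0-based half-open span of the mature arm.
#' @param strand `"+"` or `"-"`.
#' @param arm `"5p"`, `"3p"` or `NA` if not yet assigned.
#' @return A one-row data.frame of class `locus_window`.
#' @export
locus_window <- function(locus_id, chrom, start, end, strand, arm = NA_character_) {
  stopifnot(start >= 0, end > start, strand %in% c("+", "-"))
  structure(
    data.frame(locus_id = locus_id, chrom = chrom,
               start = as.integer(start), end = as.integer(end),
               strand = strand, arm = arm, stringsAsFactors = FALSE),
    class = c("locus_window", "data.frame")
  )
}

#' Count reads in a margin-extended locus window
#'
#' A placement is counted, with its full collapsed count at every placement,
#' iff its strand matches and it lies entirely within
#' `[start - margin, end + margin)`. The extended window is clipped to the
#' chromosome (with a message) if it would overhang an end.
#'
#' @param pset a `placement_set` covering one or more strains.
#' @param window a `locus_window` (one row).
#' @param margin nt added on each side of the window (default 5).
#' @return Named integer vector of raw counts, one per strain in `pset`.
#' @export
count_window <- function(pset, window, margin = 5L) {
  stopifnot(inherits(pset, "placement_set"), nrow(window) == 1L)
  if (!window$chrom %in% names(pset$seqlengths)) {
    stop("window on unknown chromosome: ", window$chrom)
  }
  lo <- window$start - margin
  hi <- window$end + margin
  clip_lo <- max(lo, 0L)
  clip_hi <- min(hi, pset$seqlengths[[window$chrom]])
  if (clip_lo != lo || clip_hi != hi) {
    message("window ", window$locus_id,
            " extends beyond chromosome; clipped to [",
            clip_lo, ",", clip_hi, ")")
  }
  pl <- pset$placements
  inside <- pl$chrom == window$chrom & pl$strand == window$strand &
    pl$start >= clip_lo & pl$end <= clip_hi
  counts <- setNames(integer(length(pset$totals)), names(pset$totals))
  if (any(inside)) {
    agg <- tapply(pl$count[inside], pl$strain[inside], sum)
    counts[names(agg)] <- as.integer(agg)
  }
  counts
}

#' Normalize raw window counts to RPM and WT-relative expression
#'
#' @param raw named vector of raw counts per strain.
#' @param totals named vector of aligned-read totals per strain (the RPM
#'   denominator).
#' @return data.frame with columns `strain`, `raw`, `rpm`
#'   (`1e6 * raw / total`) and `rel_to_wt` (`rpm / rpm_wt`; `NA` when the WT
#'   RPM is zero, the distinguished undefined value).
#' @export
normalize_counts <- function(raw, totals) {
  stopifnot(all(names(raw) %in% names(totals)))
  totals <- totals[names(raw)]
  bad <- raw > 0 & totals == 0
  if (any(bad)) {
    stop("internal consistency error: raw count > 0 with total_aligned = 0 for ",
         paste(names(raw)[bad], collapse = ", "))
  }
  rpm <- ifelse(totals > 0, 1e6 * raw / totals, 0)
  wt_rpm <- if ("wt" %in% names(raw)) rpm[["wt"]] else NA_real_
  rel <- if (!is.na(wt_rpm) && wt_rpm > 0) rpm / wt_rpm else rep(NA_real_, length(rpm))
  data.frame(strain = names(raw), raw = as.numeric(raw), rpm = as.numeric(rpm),
             rel_to_wt = as.numeric(rel), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fold-change ratio with the zero-denominator convention
#'
#' `x/y` for `y > 0`; `+Inf` for `x > 0, y = 0`; `0` for `0/0`.
#'
#' @param num,den non-negative numerics.
#' @return numeric vector of ratios.
#' @export
fold_ratio <- function(num, den) {
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Evaluate the two expression criteria for one locus
#'
#' Per arm, `fold_up = supp/wt` and `fold_down = wt/proc` (on RPM or on any
#' commonly scaled relative-expression values: fold ratios are invariant to a
#' per-row scale, so a published relative-expression table can be fed in
#' directly). Locus-level folds are the maximum over arms: a locus meets a
#' criterion if any of its arms does.
#'
#' @param arm_expr data.frame with columns `arm`, `wt`, `proc_mutant`,
#'   `supp_mutant` (one row per arm; RPM or relative expression).
#' @param f_up,f_down fold thresholds for criteria 2 and 3 (default 3).
#' @return List with `fold_up`, `fold_down` (locus-level, max over arms),
#'   logical `c2`, `c3`, and `per_arm` (the input with per-arm fold columns).
#' @export
expression_criteria <- function(arm_expr, f_up = 3, f_down = 3) {
  stopifnot(nrow(arm_expr) >= 1L,
            all(c("wt", "proc_mutant", "supp_mutant") %in% names(arm_expr)))
  arm_expr$fold_up <- fold_ratio(arm_expr$supp_mutant, arm_expr$wt)
  arm_expr$fold_down <- fold_ratio(arm_expr$wt, arm_expr$proc_mutant)
  fu <- max(arm_expr$fold_up)
  fd <- max(arm_expr$fold_down)
  list(fold_up = fu, fold_down = fd,
       c2 = fu >= f_up, c3 = fd >= f_down,
       per_arm = arm_expr)
}

#' Read a relative-expression table in replay format
#'
#' Tab-separated with header; columns `locus_id`, `arm`, `sequence` (RNA or
#' DNA alphabet), `wt`, `proc_mutant`, `supp_mutant`, and per-locus structure
#' flags `hairpin` and `star` (1/0). An optional `known` column (1/0) marks
#' loci attributed to prior reports. Decimal commas (e.g. `915,13`) are
#' parsed as decimal points, matching the typography of published tables.
#'
#' @param path path to the TSV file.
#' @return data.frame with numeric expression columns.
#' @export
read_expression_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, dec = ",",
                  colClasses = "character")
  req <- c("locus_id", "arm", "sequence", "wt", "proc_mutant", "supp_mutant")
  if (!all(req %in% names(x))) {
    stop("expression table must have columns: ", paste(req, collapse = ", "))
  }
  for (col in c("wt", "proc_mutant", "supp_mutant")) {
    x[[col]] <- as.numeric(chartr(",", ".", x[[col]]))
    if (anyNA(x[[col]])) stop("non-numeric value in column ", col)
  }
  for (col in c("hairpin", "star", "known")) {
    if (!is.null(x[[col]])) x[[col]] <- as.integer(x[[col]])
  }
  x$sequence <- normalize_seq(x$sequence)
  x
}
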