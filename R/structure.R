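# Secondary structure: maximum base-pairing (Nussinov) folding, the hairpin
# criterion, and star-arm prediction with 2-nt 3' overhang duplex geometry.
#
# The folding objective is the maximum number of nested AU/GC/GU pairs
# subject to a minimum loop length. This replaces visual inspection of
# minimum-free-energy folds: for the hairpin/no-hairpin dichotomy the
# pipeline needs, maximum pairing plus the quantitative hairpin-shape test in
# call_hairpin() is sufficient and has a clean exhaustive-enumeration oracle.
# Indices in pair tables and spans are 1-based inclusive (R convention).

PAIRABLE <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)

can_pair_matrix <- function(chars) {
  n <- length(chars)
  keys <- outer(chars, chars, paste0)
  matrix(!is.na(PAIRABLE[keys]), n, n)
}

#' Fold a sequence by maximum base pairing
#'
#' Nussinov dynamic program over nested \{AU, GC, GU\} pairs with a minimum
#' loop length. Traceback is deterministic: where several structures attain
#' the optimum, pairing a base is preferred over leaving it unpaired, and the
#' 3'-most base of a subproblem pairs with its outermost (smallest-index)
#' optimal partner.
#'
#' @param sequence character scalar (DNA or RNA alphabet; folded as RNA).
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return An object of class `fold_result`: list with `sequence` (RNA,
#'   uppercase), `score` (number of pairs), `pairs` (two-column matrix of
#'   1-based index pairs, i < j), `ptable` (integer vector, partner index or
#'   NA) and `dotbracket`.
#' @export
#' @examples
#' fold_nussinov("GGGGAAAACCCC")$dotbracket
fold_nussinov <- function(sequence, min_loop = 3L) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  rna <- dna_to_rna(toupper(sequence))
  chars <- strsplit(rna, "")[[1]]
  n <- length(chars)
  cp <- can_pair_matrix(chars)
  N <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1L:(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        ks <- ks[cp[ks, j]]
        if (length(ks)) {
          left <- integer(length(ks))
          inner <- ks > i
          if (any(inner)) left[inner] <- N[i, ks[inner] - 1L]
          right <- N[cbind(ks + 1L, j - 1L)]
          best <- max(best, max(left + right + 1L))
        }
        N[i, j] <- best
      }
    }
  }
  # deterministic traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    target <- N[i, j]
    if (target == 0L) next
    ks <- i:(j - min_loop - 1L)
    ks <- ks[cp[ks, j]]
    hit <- NA_integer_
    for (k in ks) {
      left <- if (k > i) N[i, k - 1L] else 0L
      if (left + N[k + 1L, j - 1L] + 1L == target) { hit <- k; break }
    }
    if (!is.na(hit)) {
      pairs <- rbind(pairs, c(hit, j))
      if (hit > i) stack[[length(stack) + 1L]] <- c(i, hit - 1L)
      stack[[length(stack) + 1L]] <- c(hit + 1L, j - 1L)
    } else {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    }
  }
  ptable <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    ptable[pairs[, 1]] <- pairs[, 2]
    ptable[pairs[, 2]] <- pairs[, 1]
  }
  db <- rep(".", n)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  structure(
    list(sequence = rna, score = nrow(pairs), pairs = pairs,
         ptable = ptable, dotbracket = paste(db, collapse = ""),
         min_loop = as.integer(min_loop)),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  # Vienna-style plain-text output: sequence line, then structure line.
  cat(x$sequence, "\n", sep = "")
  cat(x$dotbracket, sprintf(" (%d pairs)\n", x$score), sep = "")
  invisible(x)
}

# Direct duplex fit of the mature against either flank: antiparallel
# registers with at most one internal bulge of up to max_bulge nt on the
# opposite strand. For each admissible placement (loop within
# [min_loop, max_loop]) the number of complementary positions is counted;
# the best fit by gap-penalized score (pairs - bulge width; ties to the
# smaller bulge, then the smaller loop) is returned, or NULL. Wider bulge
# allowances blur the fit into a pair of independent registers, which is
# why the cap is small.
scan_registers <- function(chars, m1, m2, min_loop, max_loop, max_bulge = 3L) {
  n <- length(chars)
  L <- m2 - m1 + 1L
  pairable <- function(a, b) !is.na(PAIRABLE[paste0(a, b)])
  best <- NULL
  t <- 0:(L - 1L)

  # bulges are penalized like alignment gaps: score = matches - bulge width,
  # so a bulge must be supported by more pairing than it costs
  consider <- function(n_match, span, loop, bulge) {
    if (loop < min_loop || loop > max_loop) return(invisible())
    score <- n_match - bulge
    if (is.null(best) || score > best$score ||
        (score == best$score && bulge < best$bulge) ||
        (score == best$score && bulge == best$bulge && loop < best$loop)) {
      best <<- list(n_match = n_match, score = score, window = span,
                    loop = loop, bulge = bulge)
    }
  }

  scan_side <- function(downstream) {
    # hit[t] at register r: does mature base t pair with its register
    # partner? downstream: partner(m1+t) = r - t; upstream: partner(m2-t)
    # = r + t (r = outermost partner position)
    hit_at <- function(r) {
      if (downstream) {
        pos <- r - t
      } else {
        pos <- r + t
      }
      ok <- pos >= 1L & pos <= n & (pos < m1 | pos > m2)
      h <- logical(L)
      mat <- if (downstream) chars[m1 + t] else chars[m2 - t]
      h[ok] <- pairable(mat[ok], chars[pos[ok]])
      h
    }
    r_range <- if (downstream) {
      (m2 + min_loop + L):min(m2 + max_loop + L + max_bulge, n)
    } else {
      max(m1 - max_loop - L - max_bulge, 1L):(m1 - min_loop - L)
    }
    if (length(r_range) == 0L || r_range[1] > r_range[length(r_range)]) {
      return(invisible())
    }
    H <- vapply(r_range, hit_at, logical(L))   # L x length(r_range)
    pre <- apply(H, 2, cumsum)                 # prefix match counts
    tot <- pre[L, ]
    for (ri in seq_along(r_range)) {
      r <- r_range[ri]
      for (b in 0:max_bulge) {
        # suffix register shifted by the bulge: away from the mature for a
        # bulge on the opposite strand
        r2i <- if (downstream) ri - b else ri + b
        if (b > 0L && (r2i < 1L || r2i > length(r_range))) next
        if (b == 0L) {
          n_match <- tot[ri]
          split <- L
        } else {
          gains <- pre[, ri] + c(tot[r2i] - pre[, r2i])
          split <- which.max(gains)
          n_match <- gains[split]
        }
        r2 <- r_range[if (b == 0L) ri else r2i]
        if (downstream) {
          span <- c(min(r, r2) - L + 1L, max(r, r2))
          loop <- span[1] - m2 - 1L
        } else {
          span <- c(min(r, r2), max(r, r2) + L - 1L)
          loop <- m1 - span[2] - 1L
        }
        span <- c(max(span[1], 1L), min(span[2], n))
        consider(n_match, span, loop, b)
      }
    }
  }
  scan_side(TRUE)
  scan_side(FALSE)
  best
}

#' Decide the hairpin criterion for a mature arm within a folded context
#'
#' The decisive test is a direct duplex fit: an antiparallel placement of
#' the mature against either flank, allowing at most one internal bulge of
#' up to `max_bulge` nt, must pair at least `max(theta_pair,
#' theta_register)` of the mature bases, with the unpaired gap between
#' mature and opposite arm — the loop — within `[min_loop, max_loop]`. The
#' global maximum-pairing structure is not used for the decision because its
#' single optimum frequently redistributes the pairing of a genuine
#' near-perfect arm across competing helices (and, conversely, pairs well
#' over half of any AT-rich window); it does, however, provide the reported
#' diagnostic `paired_fraction`/`opposite_span` when no duplex passes: the
#' densest run of structure partners on the majority side of the mature,
#' within a window of `mature width + max_bulge` nt.
#'
#' @param fold a `fold_result`.
#' @param mature_span length-2 integer vector, 1-based inclusive span of the
#'   mature arm within `fold$sequence`.
#' @param theta_pair minimum fraction of mature bases paired to the opposite
#'   arm (default 0.6); the effective duplex threshold is
#'   `max(theta_pair, theta_register)`, so raising `theta_pair` beyond
#'   `theta_register` tightens the call.
#' @param max_loop maximum loop length in nt (default 50).
#' @param max_bulge maximum bulge width in the duplex fit, and the width
#'   slack of the reported opposite arm (default 8).
#' @param theta_register baseline paired fraction of the duplex fit
#'   (default 0.8).
#' @return An object of class `hairpin_call`: list with `is_hairpin`,
#'   `paired_fraction`, `opposite_span` (1-based inclusive or NULL),
#'   `loop_length` (NA if no opposite arm), `mature_span`, `mature_arm`
#'   (`"5p"` if the mature precedes the opposite arm in the context, else
#'   `"3p"`), `ptable` and `n` (context length).
#' @export
call_hairpin <- function(fold, mature_span, theta_pair = 0.6, max_loop = 50L,
                         max_bulge = 8L, theta_register = 0.8) {
  stopifnot(inherits(fold, "fold_result"), length(mature_span) == 2L)
  n <- length(fold$ptable)
  m1 <- as.integer(mature_span[1]); m2 <- as.integer(mature_span[2])
  if (m1 < 1L || m2 > n || m1 > m2) {
    stop("mature_span [", m1, ",", m2, "] outside folded context of length ", n)
  }
  mlen <- m2 - m1 + 1L
  res <- list(is_hairpin = FALSE, paired_fraction = 0,
              opposite_span = NULL, loop_length = NA_integer_,
              mature_span = c(m1, m2), mature_arm = NA_character_,
              ptable = fold$ptable, n = n, min_loop = fold$min_loop)
  class(res) <- "hairpin_call"

  # structure route: partners in the maximum-pairing structure
  partners <- fold$ptable[m1:m2]
  partners <- partners[!is.na(partners)]
  partners <- partners[partners < m1 | partners > m2]  # ignore self-pairing
  up <- partners[partners < m1]
  down <- partners[partners > m2]
  side <- if (length(down) >= length(up)) down else up
  struct <- NULL
  if (length(side)) {
    side <- sort(side)
    # densest run of partners within a window of mlen + max_bulge nt
    win <- mlen + max_bulge
    best <- c(1L, 1L); best_n <- 1L
    lo <- 1L
    for (hi in seq_along(side)) {
      while (side[hi] - side[lo] + 1L > win) lo <- lo + 1L
      if (hi - lo + 1L > best_n) { best_n <- hi - lo + 1L; best <- c(lo, hi) }
    }
    run <- side[best[1]:best[2]]
    opp <- c(min(run), max(run))
    loop <- if (opp[1] > m2) opp[1] - m2 - 1L else m1 - opp[2] - 1L
    # duplex anchor: partners of the outermost mature bases paired into the
    # run, extrapolated outward so unpaired mature ends still project onto
    # the opposite arm (antiparallel => partner index decreases along the
    # mature)
    pt <- fold$ptable
    m_idx <- (m1:m2)[!is.na(pt[m1:m2]) & pt[m1:m2] %in% run]
    i1 <- min(m_idx); i2 <- max(m_idx)
    ext_high <- pt[i1] + (i1 - m1)
    ext_low <- pt[i2] - (m2 - i2)
    struct <- list(frac = length(run) / mlen, opp = opp,
                   loop = as.integer(loop),
                   anchor = c(max(ext_low, 1L), min(ext_high, n)))
  }

  # duplex route: direct antiparallel complementarity against a flank,
  # at most one bulge; this is the decisive test
  chars <- strsplit(fold$sequence, "")[[1]]
  reg <- scan_registers(chars, m1, m2, fold$min_loop, max_loop,
                        max_bulge = min(max_bulge, 3L))
  if (!is.null(reg)) {
    reg <- list(frac = reg$n_match / mlen, opp = reg$window,
                loop = as.integer(reg$loop), anchor = reg$window,
                pass = reg$score / mlen >= max(theta_pair, theta_register))
  }
  # a passing duplex defines the call; otherwise report the
  # better-supported diagnostic of the two views
  pick <- if (!is.null(reg) && reg$pass) {
    reg
  } else if (!is.null(struct) && (is.null(reg) || struct$frac >= reg$frac)) {
    struct
  } else {
    reg
  }
  if (is.null(pick)) return(res)
  res$paired_fraction <- pick$frac
  res$opposite_span <- pick$opp
  res$loop_length <- pick$loop
  res$star_anchor <- pick$anchor
  res$mature_arm <- if (pick$opp[1] > m2) "5p" else "3p"
  res$is_hairpin <- !is.null(reg) && isTRUE(reg$pass)
  res
}

#' @export
print.hairpin_call <- function(x, ...) {
  cat(sprintf("hairpin_call: %s (paired fraction %.2f, loop %s nt, mature arm %s)\n",
              if (x$is_hairpin) "hairpin" else "no hairpin",
              x$paired_fraction,
              ifelse(is.na(x$loop_length), "NA", x$loop_length),
              ifelse(is.na(x$mature_arm), "?", x$mature_arm)))
  invisible(x)
}

#' Predict the star arm of a hairpin
#'
#' The miRNA duplex is assumed to carry `overhang`-nt 3' overhangs on both
#' strands (the canonical RNase III product). The duplex footprint on the
#' opposite arm is anchored at the partners of the mature's outermost paired
#' bases, extrapolated across unpaired mature ends; in context coordinates
#' (5' to 3') the star span is that footprint shifted downstream by
#' `overhang`, clipped to the context.
#'
#' @param hairpin a `hairpin_call` with `is_hairpin = TRUE`.
#' @param overhang 3' overhang in nt (default 2).
#' @return List of class `star_prediction` with `star_span` (1-based
#'   inclusive, context coordinates), `overhang`, `supported = NA` and
#'   `supporting_reads = 0` (filled by [detect_star_reads()]).
#' @export
predict_star <- function(hairpin, overhang = 2L) {
  stopifnot(inherits(hairpin, "hairpin_call"))
  if (!isTRUE(hairpin$is_hairpin)) {
    stop("predict_star() requires a positive hairpin call")
  }
  opp <- if (!is.null(hairpin$star_anchor)) hairpin$star_anchor else
    hairpin$opposite_span
  span <- pmin(pmax(opp + as.integer(overhang), 1L), hairpin$n)
  structure(
    list(star_span = span, overhang = as.integer(overhang),
         star_arm = if (identical(hairpin$mature_arm, "5p")) "3p" else "5p",
         supported = NA, supporting_reads = 0L),
    class = "star_prediction"
  )
}

# Map a 1-based inclusive context span to genomic 0-based half-open
# coordinates. ctx_start0 is the genomic 0-based start of the context; for
# minus-strand loci context position t corresponds to genomic base
# ctx_end0 - t (the context is the reverse complement of the genomic slice).
context_to_genomic <- function(span, ctx_start0, ctx_len, strand) {
  if (strand == "+") {
    c(ctx_start0 + span[1] - 1L, ctx_start0 + span[2])
  } else {
    end0 <- ctx_start0 + ctx_len
    c(end0 - span[2], end0 - span[1] + 1L)
  }
}

#' Check a predicted star arm for supporting reads
#'
#' The star arm is supported when at least `min_star_reads` reads (collapsed
#' counts summed over all strains) lie fully within the genomic star span
#' extended by `tolerance` nt on each side, on the same strand.
#'
#' @param pset a `placement_set`.
#' @param star a `star_prediction`.
#' @param star_window one-row data.frame/list with the genomic star
#'   coordinates: `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @param tolerance positional tolerance in nt (default 2).
#' @param min_star_reads minimum supporting read count (default 1).
#' @return The `star_prediction` with `supported` and `supporting_reads` set.
#' @export
detect_star_reads <- function(pset, star, star_window, tolerance = 2L,
                              min_star_reads = 1L) {
  stopifnot(inherits(star, "star_prediction"))
  pl <- pset$placements
  inside <- pl$chrom == star_window$chrom &
    pl$strand == star_window$strand &
    pl$start >= star_window$start - tolerance &
    pl$end <= star_window$end + tolerance
  star$supporting_reads <- if (any(inside)) sum(pl$count[inside]) else 0L
  star$supported <- star$supporting_reads >= min_star_reads
  star
}
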