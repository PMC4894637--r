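# Exact placement of collapsed reads on the genome.
#
# Matching is full-length, ungapped and mismatch-free on both strands; every
# occurrence is reported, so multi-mapping loci (e.g. a species present at
# four genomic positions) are fully represented. Multi-mapped reads carry
# their full collapsed count at every placement; no fractional allocation.
# Coordinates are 0-based half-open throughout the placement tables.

empty_placements <- function() {
  data.frame(strain = character(0), sequence = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), count = integer(0),
             multiplicity = integer(0), stringsAsFactors = FALSE)
}

#' Map a strain library onto a genome by exact matching
#'
#' Every exact, full-length, ungapped occurrence of each collapsed read on
#' either strand of the genome is reported. For minus-strand placements the
#' read equals the reverse complement of the genomic slice. `multiplicity`
#' is the total number of genomic occurrences of the read; `total_aligned`
#' counts each aligned read's collapsed count once, regardless of how many
#' places it maps to, and is the library-size denominator for RPM.
#'
#' @param library a `strain_library` (see [load_reads()]).
#' @param genome a named [Biostrings::DNAStringSet] (see [load_genome()]).
#' @param k seed length of the matcher. Matching is exact and full-length; the
#'   value only has to satisfy the configuration constraint that it does not
#'   exceed the shortest read.
#' @return A `placement_set`: list with `placements` (data.frame with columns
#'   `strain`, `sequence`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `count`, `multiplicity`), `totals` (named vector, aligned reads
#'   per strain) and `seqlengths` (named chromosome lengths).
#' @export
map_reads <- function(library, genome, k = 12L) {
  stopifnot(inherits(library, "strain_library"))
  if (length(genome) == 0L) stop("genome is empty")
  reads <- library$reads
  if (nrow(reads) > 0L && k > min(reads$length)) {
    stop("configuration error: seed length k = ", k,
         " exceeds shortest read (", min(reads$length), " nt)")
  }
  hits <- list()
  if (nrow(reads) > 0L) {
    fwd <- Biostrings::DNAStringSet(reads$sequence)
    rev <- Biostrings::reverseComplement(fwd)
    tb <- min(reads$length)
    for (dir in c("+", "-")) {
      pats <- if (dir == "+") fwd else rev
      # variable-width exact dictionary: trusted band over the first tb
      # bases, full-length verification by matchPDict
      pd <- Biostrings::PDict(pats, tb.start = 1L, tb.end = tb)
      for (ci in seq_along(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[ci]])
        st <- Biostrings::startIndex(m)
        nhit <- lengths(st)
        if (sum(nhit) == 0L) next
        keep <- nhit > 0L
        ri <- rep(seq_len(nrow(reads))[keep], nhit[keep])
        s1 <- unlist(st[keep], use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          read_i = ri,
          chrom = names(genome)[ci],
          start = s1 - 1L,
          end = s1 - 1L + reads$length[ri],
          strand = dir,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits)) {
    pl <- do.call(rbind, hits)
    mult <- table(pl$read_i)
    pl$multiplicity <- as.integer(mult[as.character(pl$read_i)])
    pl <- data.frame(
      strain = library$strain,
      sequence = reads$sequence[pl$read_i],
      chrom = pl$chrom, start = pl$start, end = pl$end, strand = pl$strand,
      count = reads$count[pl$read_i], multiplicity = pl$multiplicity,
      stringsAsFactors = FALSE
    )
    pl <- pl[order(pl$chrom, pl$start, pl$end, pl$strand, pl$sequence), ,
             drop = FALSE]
    rownames(pl) <- NULL
    aligned <- sum(reads$count[unique(as.integer(names(mult)))])
  } else {
    pl <- empty_placements()
    aligned <- 0L
  }
  totals <- setNames(as.integer(aligned), library$strain)
  structure(
    list(placements = pl, totals = totals,
         seqlengths = setNames(Biostrings::width(genome), names(genome))),
    class = "placement_set"
  )
}

#' Combine per-strain placement sets
#'
#' @param ... `placement_set` objects for distinct strains, mapped against the
#'   same genome.
#' @return A single `placement_set` holding all strains.
#' @export
combine_placements <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "placement_set")))
  strains <- unlist(lapply(sets, function(s) names(s$totals)))
  if (anyDuplicated(strains)) stop("duplicate strain in placement sets")
  sl <- sets[[1]]$seqlengths
  for (s in sets[-1]) {
    if (!identical(s$seqlengths, sl)) {
      stop("placement sets were mapped against different genomes")
    }
  }
  structure(
    list(
      placements = do.call(rbind, lapply(sets, `[[`, "placements")),
      totals = unlist(lapply(sets, `[[`, "totals")),
      seqlengths = sl
    ),
    class = "placement_set"
  )
}

#' @export
print.placement_set <- function(x, ...) {
  cat("placement_set:", nrow(x$placements), "placements,",
      length(x$totals), "strain(s)\n")
  for (s in names(x$totals)) {
    cat(sprintf("  %s: %d aligned reads\n", s, x$totals[[s]]))
  }
  invisible(x)
}

# GRanges view of the placements (1-based internally for overlap machinery).
placements_granges <- function(pset) {
  pl <- pset$placements
  GenomicRanges::GRanges(
    seqnames = pl$chrom,
    ranges = IRanges::IRanges(start = pl$start + 1L, end = pl$end),
    strand = pl$strand
  )
}

#' Export placements as BED6
#'
#' 0-based half-open intervals; `name` is the read sequence and `score` the
#' collapsed read count (capped at 1000 per the BED specification).
#'
#' @param pset a `placement_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
placements_to_bed <- function(pset, path) {
  pl <- pset$placements
  gr <- placements_granges(pset)
  S4Vectors::mcols(gr)$name <- pl$sequence
  S4Vectors::mcols(gr)$score <- pmin(pl$count, 1000L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
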