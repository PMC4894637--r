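# Input/output of genomes, small-RNA libraries and evidence tables.
#
# Internal sequence alphabet is DNA (T); user-facing mature sequences are
# reported in the RNA alphabet (U). U is converted to T on input.

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `dna_to_rna()` replaces T with U; `rna_to_dna()` replaces U with T.
#'   Case is preserved.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Uppercase, U->T. Returns the normalized character vector.
normalize_seq <- function(x) rna_to_dna(toupper(x))

has_non_acgt <- function(x) grepl("[^ACGT]", x)

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased and U is converted to T. Any remaining character
#' outside A/C/G/T (including IUPAC ambiguity codes such as N) is an error:
#' the exact mapper cannot place reads across ambiguous reference bases.
#' Records are keyed by the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per chromosome.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty genome FASTA: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome id(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- normalize_seq(as.character(x))
  bad <- has_non_acgt(seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGT]", "", seqs[bad]), "")))
    stop("genome contains non-A/C/G/T character(s) (",
         paste(ch, collapse = ", "), ") in: ", paste(nm[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Construct a small-RNA strain library from sequences
#'
#' Identical sequences are collapsed into one record with summed count.
#'
#' @param sequences character vector of read sequences (DNA or RNA alphabet;
#'   normalized to uppercase DNA).
#' @param strain one of `"wt"`, `"proc_mutant"`, `"supp_mutant"`.
#' @param counts optional integer vector of per-sequence multiplicities
#'   (default 1 each).
#' @return An object of class `strain_library`: a list with elements `strain`,
#'   `reads` (data.frame with columns `sequence`, `length`, `count`),
#'   `n_input`, `n_dropped_alphabet`, `n_dropped_length` and `total_aligned`
#'   (`NA` until the library has been mapped).
#' @export
strain_library <- function(sequences, strain, counts = NULL) {
  strain <- match.arg(strain, STRAINS)
  if (is.null(counts)) counts <- rep.int(1L, length(sequences))
  stopifnot(length(counts) == length(sequences), all(counts >= 1))
  seqs <- normalize_seq(sequences)
  if (length(seqs)) {
    tab <- tapply(as.integer(counts), seqs, sum)
    reads <- data.frame(
      sequence = names(tab),
      length = nchar(names(tab)),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
  } else {
    reads <- data.frame(sequence = character(0), length = integer(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  structure(
    list(strain = strain, reads = reads,
         n_input = sum(as.integer(counts)),
         n_dropped_alphabet = 0L, n_dropped_length = 0L,
         total_aligned = NA_integer_),
    class = "strain_library"
  )
}

#' @export
print.strain_library <- function(x, ...) {
  cat(sprintf("strain_library [%s]: %d distinct sequences, %d reads\n",
              x$strain, nrow(x$reads), sum(x$reads$count)))
  cat(sprintf("  dropped at load: %d non-ACGT, %d outside length prefilter\n",
              x$n_dropped_alphabet, x$n_dropped_length))
  invisible(x)
}

# Parse a 4-line-record FASTQ. Biostrings' FASTQ reader silently tolerates
# records whose quality string is shorter than the sequence, so record
# structure is validated here before the sequences are used.
parse_fastq <- function(path) {
  ln <- readLines(path)
  last <- if (any(nzchar(ln))) max(which(nzchar(ln))) else 0L
  ln <- ln[seq_len(last)]
  if (length(ln) == 0L) return(character(0))
  if (length(ln) %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): line count not a multiple of 4")
  }
  hdr <- ln[seq(1L, length(ln), by = 4L)]
  seq <- ln[seq(2L, length(ln), by = 4L)]
  sep <- ln[seq(3L, length(ln), by = 4L)]
  qual <- ln[seq(4L, length(ln), by = 4L)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(sep, "+"))) {
    stop("malformed FASTQ (", path, "): record markers out of register")
  }
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch in ",
         sum(bad), " record(s), first at record ", which(bad)[1])
  }
  seq
}

#' Load a small-RNA read library (FASTA or FASTQ)
#'
#' The format is auto-detected from the first non-blank character (`>` FASTA,
#' `@` FASTQ). Sequences are uppercased, U is converted to T, identical
#' sequences are collapsed with summed counts, and quality strings are
#' ignored. Reads containing characters outside A/C/G/T (e.g. N) are dropped,
#' as are reads outside the load-time length prefilter; both drop counts are
#' reported via [message()] and kept on the returned object. The prefilter is
#' deliberately wider than the 20-24 nt mature-length criterion so that
#' background reads reach the classifier. Inputs are assumed adapter-trimmed.
#'
#' @param path path to a FASTA or FASTQ file.
#' @inheritParams strain_library
#' @param prefilter length-2 numeric, minimum and maximum read length kept at
#'   load time (default `c(15, 40)`).
#' @return A `strain_library` (see [strain_library()]).
#' @export
load_reads <- function(path, strain, prefilter = c(15L, 40L)) {
  strain <- match.arg(strain, STRAINS)
  if (!file.exists(path)) stop("read file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    seqs <- character(0)
  } else if (startsWith(first, ">")) {
    seqs <- as.character(Biostrings::readBStringSet(path))
  } else if (startsWith(first, "@")) {
    seqs <- parse_fastq(path)
  } else {
    stop("cannot auto-detect read format of ", path,
         " (expected FASTA '>' or FASTQ '@')")
  }
  seqs <- normalize_seq(seqs)
  n_input <- length(seqs)
  bad_alpha <- has_non_acgt(seqs)
  seqs <- seqs[!bad_alpha]
  len <- nchar(seqs)
  bad_len <- len < prefilter[1] | len > prefilter[2]
  seqs <- seqs[!bad_len]
  if (any(bad_alpha) || any(bad_len)) {
    message(sprintf("%s: dropped %d read(s) with non-ACGT characters, %d outside [%d,%d] nt",
                    basename(path), sum(bad_alpha), sum(bad_len),
                    prefilter[1], prefilter[2]))
  }
  lib <- strain_library(seqs, strain)
  lib$n_input <- n_input
  lib$n_dropped_alphabet <- sum(bad_alpha)
  lib$n_dropped_length <- sum(bad_len)
  lib
}

#' Write a strain library to FASTA
#'
#' Each collapsed read is emitted once per unit of count so that a
#' write/load round trip restores identical counts.
#'
#' @param library a `strain_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(library, path) {
  stopifnot(inherits(library, "strain_library"))
  seqs <- rep(library$reads$sequence, library$reads$count)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read_%06d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Load a locus evidence table
#'
#' Tab-separated with header. Required columns: `locus_id` and
#' `northern_detectable` (values 1, 0 or NA; criterion 6). Optional columns:
#' `c2_nb`, `c3_nb` (1 grants the expression criterion on Northern blot
#' evidence, overriding the sequencing-derived flag) and `chrom`, `start`,
#' `end`, `strand` (0-based half-open mature coordinates used to match
#' evidence rows to discovered loci by reciprocal overlap; without them
#' matching falls back on `locus_id`).
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `evidence_table`.
#' @export
load_evidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("locus_id", "northern_detectable")
  if (!all(req %in% names(ev))) {
    stop("evidence table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ev$locus_id)) stop("duplicate locus_id in evidence table")
  ok <- ev$northern_detectable %in% c(0, 1) | is.na(ev$northern_detectable)
  if (!all(ok)) stop("northern_detectable must be 1, 0 or NA")
  for (col in c("c2_nb", "c3_nb")) if (is.null(ev[[col]])) ev[[col]] <- 0L
  class(ev) <- c("evidence_table", "data.frame")
  ev
}
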