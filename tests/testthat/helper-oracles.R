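# Independent oracles and fixture builders shared across tests.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5) {
  paste(sample(DNA, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# --- naive mapping oracle: sliding-window substring comparison -------------

naive_map <- function(read_seqs, genome_seqs) {
  read_seqs <- unique(read_seqs)
  rc_seqs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read_seqs)))
  out <- list()
  for (chrom in names(genome_seqs)) {
    g <- genome_seqs[[chrom]]
    n <- nchar(g)
    for (L in sort(unique(nchar(read_seqs)))) {
      if (L > n) next
      # every window of the genome, compared against the read set
      subs <- substring(g, 1:(n - L + 1), L:n)
      idx <- which(nchar(read_seqs) == L)
      for (dir in c("+", "-")) {
        targets <- if (dir == "+") read_seqs[idx] else rc_seqs[idx]
        hit <- match(subs, targets)
        pos <- which(!is.na(hit))
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = read_seqs[idx][hit[pos]], chrom = chrom,
            start = pos - 1L, end = pos - 1L + L, strand = dir,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$sequence, res$chrom, res$start, res$strand), , drop = FALSE]
}

# --- exhaustive folding oracle ---------------------------------------------

# maximum number of nested {AU,GC,GU} pairs by direct recursion over all
# structures (no memoization, independent of the DP implementation)
brute_max_pairs <- function(seq, min_loop = 3L) {
  chars <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pairable <- function(i, j) paste0(chars[i], chars[j]) %in% ok
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i, j - 1L)  # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (pairable(k, j)) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
      }
    }
    best
  }
  if (length(chars) < 2L) return(0L)
  rec(1L, length(chars))
}

# --- dinucleotide shuffle (Altschul-Erickson) ------------------------------

# Random sequence with the same dinucleotide composition: random Eulerian
# trail through the dinucleotide transition graph (random last-edge
# arborescence toward the final letter, remaining edges in random order).
shuffle_dinucleotide <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  letters_used <- unique(ch)
  edges <- split(ch[-1], ch[-n])  # successors per vertex
  last <- ch[n]
  verts <- names(edges)
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last && length(edges[[v]]) == 0L) return(NA_character_)
      sample(edges[[v]], 1)
    }, character(1))
    # check: following last edges from every vertex must reach `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
        if (!cur %in% verts) { ok <- cur == last; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  order_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      e <- e[-match(last_edge[[v]], e)]
      c(sample(e), last_edge[[v]])
    } else {
      sample(e)
    }
  })
  names(order_edges) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- order_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# --- fixture builders -------------------------------------------------------

# perfect hairpin context: mature + loop + perfect complement, embedded in
# flanks that are themselves complementary extensions (a "perfect stem")
perfect_hairpin_context <- function(mature, loop = "GAAA", flank = 10L,
                                    gc = 0.5) {
  left <- rand_dna(flank, gc)
  stem5 <- paste0(left, mature)
  paste0(stem5, loop, revcomp(stem5))
}

write_fasta <- function(seqs, path, names = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- if (is.null(names)) sprintf("seq%d", seq_along(x)) else names
  Biostrings::writeXStringSet(x, path)
  path
}

write_fastq <- function(seqs, path) {
  if (length(seqs)) {
    ids <- sprintf("r%04d", seq_along(seqs))
    writeLines(c(rbind(paste0("@", ids), seqs, rep("+", length(seqs)),
                       strrep("I", nchar(seqs)))), path)
  } else {
    writeLines(character(0), path)
  }
  path
}

# three-strain library set from sequence vectors
libs_from_seqs <- function(wt, proc, supp) {
  list(wt = strain_library(wt, "wt"),
       proc_mutant = strain_library(proc, "proc_mutant"),
       supp_mutant = strain_library(supp, "supp_mutant"))
}

published_table_path <- function() {
  system.file("extdata", "published_mirna_table.tsv", package = "mirdisco",
              mustWork = TRUE)
}

published_evidence_path <- function() {
  system.file("extdata", "published_mirna_evidence.tsv", package = "mirdisco",
              mustWork = TRUE)
}
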