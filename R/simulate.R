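# Synthetic three-strain small RNA-seq datasets with ground truth.
#
# The generator emulates the statistical structure the identification
# criteria assume: hairpin loci whose 20-24 nt mature arm is several-fold up
# in the suppressor mutant and several-fold down in the processing mutant,
# star reads from the opposite arm with 2-nt 3' overhang placement,
# miRNA-like loci (miRNA expression pattern, no hairpin, no star reads),
# suppressor-responsive siRNA-like decoy loci, one species planted at four
# genomic copies, and a diffuse degradation background of 15-35 nt reads at
# equal abundance across strains. Counts are Poisson (optionally negative
# binomial); the genome is AT-rich by default, as in the social amoeba whose
# small RNA biology this models.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' @param genome_length chromosome length in nt (default 1e6).
#' @param gc_content genomic GC fraction (default 0.23, an AT-rich genome).
#' @param n_canonical planted canonical miRNA loci (default 20).
#' @param n_mirna_like planted miRNA-like loci: miRNA expression pattern but
#'   no hairpin context and no star reads (default 3).
#' @param n_background_loci planted siRNA-like decoy loci: up in the
#'   suppressor, unchanged in the processing mutant, no hairpin (default 5).
#' @param n_multimap_loci hairpin loci planted at 4 identical genomic copies
#'   (default 1).
#' @param fold_up_range,fold_down_range per-locus fold ranges (uniform) for
#'   suppressor-up and processing-mutant-down (defaults `c(5, 80)` and
#'   `c(5, 50)`, the magnitudes seen in published relative-expression
#'   tables).
#' @param wt_depth_per_locus mean WT reads per locus (default 20).
#' @param library_size total reads emitted per strain; locus reads are topped
#'   up with background reads to exactly this number (default 50000).
#' @param star_to_mature_ratio star-read abundance relative to mature
#'   (default 0.1).
#' @param jitter_rate fraction of mature reads whose 5' end is shifted by up
#'   to 2 nt (default 0.1).
#' @param arm_identity_range identity of the opposite arm to the perfect
#'   reverse complement of the mature (default `c(0.85, 1)`).
#' @param dispersion `NULL` for Poisson counts, or a numeric dispersion for a
#'   negative-binomial alternative (`size = 1/dispersion`).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc_content = 0.23,
                       n_canonical = 20L, n_mirna_like = 3L,
                       n_background_loci = 5L, n_multimap_loci = 1L,
                       fold_up_range = c(5, 80), fold_down_range = c(5, 50),
                       wt_depth_per_locus = 20, library_size = 50000L,
                       star_to_mature_ratio = 0.1, jitter_rate = 0.1,
                       arm_identity_range = c(0.85, 1),
                       dispersion = NULL, seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(gc_content > 0, gc_content < 1,
            n_canonical >= 0, n_mirna_like >= 0, n_background_loci >= 0,
            n_multimap_loci >= 0,
            fold_up_range[1] <= fold_up_range[2],
            fold_down_range[1] <= fold_down_range[2],
            library_size >= 0, wt_depth_per_locus >= 0)
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, p) paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

mutate_seq <- function(s, n_mut) {
  if (n_mut == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

draw_count <- function(mu, dispersion) {
  if (is.null(dispersion)) rpois(1, mu) else rnbinom(1, mu = mu, size = 1 / dispersion)
}

# transcript span (1-based) -> genomic 0-based half-open, for a transcript of
# length L planted at genomic 0-based position s0 on `strand`
transcript_to_genomic <- function(t1, t2, s0, L, strand) {
  if (strand == "+") c(s0 + t1 - 1L, s0 + t2) else c(s0 + L - t2, s0 + L - t1 + 1L)
}

#' Generate a synthetic three-strain dataset with ground truth
#'
#' Writes a genome FASTA, one FASTQ per strain (dummy qualities), a truth
#' table (GFF3 and TSV) and an evidence TSV (Northern detectability for all
#' planted miRNA loci; c3 granted "based on NB" for miRNA-like loci, whose
#' processing-mutant expression is deliberately unchanged). Outputs are
#' byte-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List of class `simulated_dataset` with file paths (`genome`,
#'   `reads` (named per strain), `truth_gff3`, `truth_tsv`, `evidence`), the
#'   `truth` data.frame (0-based half-open mature/star coordinates) and the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  gc <- config$gc_content
  p_base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  glen <- as.integer(config$genome_length)
  chars <- sample(BASES, glen, replace = TRUE, prob = p_base)

  bin_w <- 500L
  n_slots <- config$n_canonical + config$n_mirna_like +
    config$n_background_loci + 4L * config$n_multimap_loci
  n_bins <- (glen - 300L) %/% bin_w
  if (n_slots > n_bins) {
    stop("cannot place ", n_slots, " loci without overlap in a ", glen,
         " nt genome; increase genome_length")
  }
  slot_starts <- (sample(n_bins, n_slots) - 1L) * bin_w + 150L

  kinds <- c(rep("CANONICAL", config$n_canonical),
             rep("MIRNA_LIKE", config$n_mirna_like),
             rep("SIRNA_BACKGROUND", config$n_background_loci))
  loci <- list()
  slot_i <- 0L
  flank <- 60L

  make_hairpin <- function() {
    mlen <- sample(20:24, 1, prob = c(0.15, 0.35, 0.3, 0.15, 0.05))
    mature <- rand_seq(mlen, p_base)
    loop_len <- sample(4:15, 1)
    loop <- rand_seq(loop_len, p_base)
    identity <- runif(1, config$arm_identity_range[1], config$arm_identity_range[2])
    arm <- mutate_seq(revcomp_chr(mature), round((1 - identity) * mlen))
    mature_first <- sample(c(TRUE, FALSE), 1)
    transcript <- if (mature_first) paste0(mature, loop, arm) else paste0(arm, loop, mature)
    L <- nchar(transcript)
    if (mature_first) {
      mt <- c(1L, mlen); at <- c(mlen + loop_len + 1L, L)
    } else {
      mt <- c(mlen + loop_len + 1L, L); at <- c(1L, mlen)
    }
    st <- at + 2L  # star: opposite arm shifted for the 2-nt 3' overhangs
    list(transcript = transcript, L = L, mt = mt, st = st,
         mature = mature, mlen = mlen)
  }

  plant <- function(insert, s0, strand) {
    seq_in <- if (strand == "-") revcomp_chr(insert) else insert
    chars[(s0 + 1L):(s0 + nchar(seq_in))] <<- strsplit(seq_in, "")[[1]]
  }

  # canonical + (appended later) multimap hairpins
  for (kind in kinds) {
    slot_i <- slot_i + 1L
    s0 <- slot_starts[slot_i]
    strand <- sample(c("+", "-"), 1)
    fu <- runif(1, config$fold_up_range[1], config$fold_up_range[2])
    fd <- runif(1, config$fold_down_range[1], config$fold_down_range[2])
    if (kind == "CANONICAL") {
      hp <- make_hairpin()
      plant(hp$transcript, s0, strand)
      mg <- transcript_to_genomic(hp$mt[1], hp$mt[2], s0, hp$L, strand)
      sg <- transcript_to_genomic(hp$st[1], hp$st[2], s0, hp$L, strand)
      sg <- sort(sg)  # minus strand flips the order
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("sim_can_%02d", sum(kinds[seq_len(slot_i)] == "CANONICAL")),
        kind = kind, chrom = "chr1", strand = strand,
        start = mg[1], end = mg[2], star_start = sg[1], star_end = sg[2],
        fold_up = fu, fold_down = fd, copies = 1L, copy = 1L,
        stringsAsFactors = FALSE
      )
    } else {
      mlen <- sample(20:24, 1, prob = c(0.15, 0.35, 0.3, 0.15, 0.05))
      mg <- c(s0, s0 + mlen)
      id_prefix <- if (kind == "MIRNA_LIKE") "sim_like" else "sim_sirna"
      n_before <- sum(vapply(loci, function(l) startsWith(l$locus_id, id_prefix), logical(1)))
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("%s_%02d", id_prefix, n_before + 1L),
        kind = kind, chrom = "chr1", strand = strand,
        start = mg[1], end = mg[2], star_start = NA_integer_,
        star_end = NA_integer_,
        fold_up = fu, fold_down = if (kind == "CANONICAL") fd else 1,
        copies = 1L, copy = 1L, stringsAsFactors = FALSE
      )
    }
  }

  # multimap loci: one hairpin copied verbatim to four slots
  for (mi in seq_len(config$n_multimap_loci)) {
    hp <- make_hairpin()
    fu <- runif(1, config$fold_up_range[1], config$fold_up_range[2])
    fd <- runif(1, config$fold_down_range[1], config$fold_down_range[2])
    for (cp in 1:4) {
      slot_i <- slot_i + 1L
      s0 <- slot_starts[slot_i]
      strand <- sample(c("+", "-"), 1)
      plant(hp$transcript, s0, strand)
      mg <- transcript_to_genomic(hp$mt[1], hp$mt[2], s0, hp$L, strand)
      sg <- sort(transcript_to_genomic(hp$st[1], hp$st[2], s0, hp$L, strand))
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("sim_multi_%02d_copy%d", mi, cp),
        kind = "CANONICAL", chrom = "chr1", strand = strand,
        start = mg[1], end = mg[2], star_start = sg[1], star_end = sg[2],
        fold_up = fu, fold_down = fd, copies = 4L, copy = cp,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, loci)
  genome_str <- paste(chars, collapse = "")

  get_seq <- function(s0, e0, strand) {
    s <- substring(genome_str, s0 + 1L, e0)
    if (strand == "-") revcomp_chr(s) else s
  }

  # miRNA-like loci must not sit in fortuitous hairpin context: re-randomize
  # their flanks until the hairpin call is negative
  params <- default_params()
  for (i in which(truth$kind == "MIRNA_LIKE")) {
    for (try in 1:25) {
      c0 <- max(truth$start[i] - flank, 0L)
      c1 <- min(truth$end[i] + flank, glen)
      ctx <- get_seq(c0, c1, truth$strand[i])
      mspan <- if (truth$strand[i] == "+") {
        c(truth$start[i] - c0 + 1L, truth$end[i] - c0)
      } else {
        c(c1 - truth$end[i] + 1L, c1 - truth$start[i])
      }
      hp <- call_hairpin(fold_nussinov(ctx, params$min_loop), mspan,
                         params$theta_pair, params$max_loop, params$max_bulge,
                         params$theta_register)
      if (!hp$is_hairpin) break
      if (try == 25) stop("could not generate a hairpin-free miRNA-like context")
      redo <- setdiff(seq(c0 + 1L, c1), seq(truth$start[i] + 1L, truth$end[i]))
      chars[redo] <- sample(BASES, length(redo), replace = TRUE, prob = p_base)
      genome_str <- paste(chars, collapse = "")
    }
  }

  # per-strain read generation
  strain_mu <- function(kind, fu, fd, strain) {
    d <- config$wt_depth_per_locus
    switch(strain, wt = d, supp_mutant = d * fu,
           proc_mutant = if (kind == "CANONICAL") d / fd else d)
  }
  jitter_span <- function(s0, e0, sh) c(s0 + sh, e0 + sh)
  read_files <- setNames(file.path(dir, paste0("reads_", STRAINS, ".fastq")), STRAINS)
  emit_truth <- truth[truth$copy == 1L, , drop = FALSE]  # reads once per species

  for (strain in STRAINS) {
    seqs <- character(0)
    for (i in seq_len(nrow(emit_truth))) {
      tr <- emit_truth[i, ]
      mu <- strain_mu(tr$kind, tr$fold_up, tr$fold_down, strain)
      n <- draw_count(mu, config$dispersion)
      if (n > 0) {
        sh <- ifelse(runif(n) < config$jitter_rate,
                     sample(c(-2L, -1L, 1L, 2L), n, replace = TRUE), 0L)
        tab <- table(sh)
        for (sv in as.integer(names(tab))) {
          sp <- jitter_span(tr$start, tr$end, sv)
          seqs <- c(seqs, rep(get_seq(sp[1], sp[2], tr$strand), tab[[as.character(sv)]]))
        }
      }
      if (tr$kind == "CANONICAL") {
        ns <- draw_count(mu * config$star_to_mature_ratio, config$dispersion)
        if (ns > 0) {
          seqs <- c(seqs, rep(get_seq(tr$star_start, tr$star_end, tr$strand), ns))
        }
      }
    }
    n_bg <- config$library_size - length(seqs)
    if (n_bg < 0) {
      stop("library_size ", config$library_size, " too small for the planted ",
           "locus reads (", length(seqs), "); increase library_size")
    }
    if (n_bg > 0) {
      lens <- sample(15:35, n_bg, replace = TRUE)
      starts <- as.integer(floor(runif(n_bg) * (glen - lens + 1L)))
      bg <- substring(genome_str, starts + 1L, starts + lens)
      neg <- runif(n_bg) < 0.5
      if (any(neg)) {
        bg[neg] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(bg[neg])))
      }
      seqs <- c(seqs, bg)
    }
    if (length(seqs)) {
      ids <- sprintf("read_%06d", seq_along(seqs))
      lines <- c(rbind(paste0("@", ids), seqs, rep("+", length(seqs)),
                       strrep("I", nchar(seqs))))
    } else {
      lines <- character(0)
    }
    writeLines(lines, read_files[[strain]])
  }

  genome_path <- file.path(dir, "genome.fasta")
  gset <- Biostrings::DNAStringSet(genome_str)
  names(gset) <- "chr1"
  Biostrings::writeXStringSet(gset, genome_path)

  truth_tsv <- file.path(dir, "truth.tsv")
  write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_gff3 <- file.path(dir, "truth.gff3")
  gr <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1L, truth$end),
                               strand = truth$strand)
  S4Vectors::mcols(gr)$type <- truth$kind
  S4Vectors::mcols(gr)$ID <- truth$locus_id
  S4Vectors::mcols(gr)$copies <- truth$copies
  rtracklayer::export(gr, truth_gff3, format = "GFF3")

  ev <- truth[truth$kind != "SIRNA_BACKGROUND", , drop = FALSE]
  evidence <- data.frame(
    locus_id = ev$locus_id, northern_detectable = 1L,
    c2_nb = 0L, c3_nb = as.integer(ev$kind == "MIRNA_LIKE"),
    chrom = ev$chrom, start = ev$start, end = ev$end, strand = ev$strand,
    stringsAsFactors = FALSE
  )
  evidence_path <- file.path(dir, "evidence.tsv")
  write.table(evidence, evidence_path, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(
    list(genome = genome_path, reads = read_files, truth_gff3 = truth_gff3,
         truth_tsv = truth_tsv, evidence = evidence_path,
         truth = truth, config = config),
    class = "simulated_dataset"
  )
}

#' Score recovery of planted loci
#'
#' A candidate matches a planted locus (or one of its genomic copies) when
#' the mature windows overlap reciprocally by at least 50% on the same
#' chromosome and strand.
#'
#' @param candidates a `mirna_candidates` data.frame from [discover_mirnas()].
#' @param truth the truth data.frame from [simulate_dataset()].
#' @return List with `sensitivity` (planted canonical species recovered as
#'   CANONICAL), `precision` (CANONICAL calls matching a planted canonical
#'   copy), `confusion` (planted kind x called class, "NONE" for unmatched
#'   candidates) and `matches` (per-candidate matched locus id or NA).
#' @export
score_recovery <- function(candidates, truth) {
  species <- function(id) sub("_copy[0-9]+$", "", id)
  matched <- rep(NA_character_, nrow(candidates))
  matched_kind <- rep("NONE", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    hit <- truth$chrom == candidates$chrom[i] &
      truth$strand == candidates$strand[i] &
      reciprocal_overlap(truth$start, truth$end,
                         candidates$start[i], candidates$end[i])
    if (any(hit)) {
      j <- which(hit)[1]
      matched[i] <- species(truth$locus_id[j])
      matched_kind[i] <- truth$kind[j]
    }
  }
  can_truth <- unique(species(truth$locus_id[truth$kind == "CANONICAL"]))
  recovered <- unique(matched[candidates$class == "CANONICAL"])
  sens <- if (length(can_truth)) {
    mean(can_truth %in% recovered)
  } else NA_real_
  is_can_call <- candidates$class == "CANONICAL"
  prec <- if (any(is_can_call)) {
    mean(matched_kind[is_can_call] == "CANONICAL")
  } else NA_real_
  conf <- table(planted = matched_kind, called = candidates$class)
  list(sensitivity = sens, precision = prec, confusion = conf,
       matches = matched)
}
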