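# File-in/file-out pipeline: configuration, standardized outputs, logging.
#
# Outputs are deterministic given the configuration and inputs: GFF3
# (1-based closed) and BED6 (0-based half-open) candidate tracks, a
# table-shaped TSV report with per-arm expression in the RNA alphabet, and a
# plain-text log (no timestamps, so reruns are byte-identical).

fmt_num <- function(x) {
  ifelse(is.infinite(x), "Inf", as.character(round(x, 4)))
}

write_candidates_gff3 <- function(cands, path) {
  val <- cands[cands$class != "REJECTED", , drop = FALSE]
  if (nrow(val) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(val$chrom,
                               IRanges::IRanges(val$start + 1L, val$end),
                               strand = val$strand)
  S4Vectors::mcols(gr)$source <- "mirdisco"
  S4Vectors::mcols(gr)$type <- ifelse(val$class == "CANONICAL", "miRNA",
                                      "miRNA_like")
  S4Vectors::mcols(gr)$ID <- val$locus_id
  S4Vectors::mcols(gr)$class <- val$class
  S4Vectors::mcols(gr)$criteria <- val$criteria
  S4Vectors::mcols(gr)$fold_up <- fmt_num(val$fold_up)
  S4Vectors::mcols(gr)$fold_down <- fmt_num(val$fold_down)
  S4Vectors::mcols(gr)$multiplicity <- val$multiplicity
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

write_candidates_bed <- function(cands, path) {
  val <- cands[cands$class != "REJECTED", , drop = FALSE]
  if (nrow(val) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(val$chrom,
                               IRanges::IRanges(val$start + 1L, val$end),
                               strand = val$strand)
  S4Vectors::mcols(gr)$name <- val$locus_id
  S4Vectors::mcols(gr)$score <- pmin(round(val$raw_supp), 1000)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Table-shaped report: one row per arm of each validated locus, mature
# sequences in the RNA alphabet, per-strain expression, criteria and class.
write_report <- function(cands, path) {
  val <- cands[cands$class != "REJECTED", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(val))) {
    r <- val[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = r$locus_id, arm = ifelse(is.na(r$arm), "", r$arm),
      sequence = r$sequence,
      wt = fmt_num(r$rpm_wt), proc_mutant = fmt_num(r$rpm_proc),
      supp_mutant = fmt_num(r$rpm_supp),
      criteria = r$criteria, class = r$class,
      stringsAsFactors = FALSE
    )
    if (!is.null(r$star_sequence) && !is.na(r$star_sequence)) {
      arms <- attr(cands, "arms")
      srow <- NULL
      if (!is.null(arms)) {
        srow <- arms[arms$locus_id == r$locus_id & arms$arm != r$arm, ,
                     drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = r$locus_id,
        arm = if (identical(r$arm, "5p")) "3p" else "5p",
        sequence = r$star_sequence,
        wt = if (nrow(srow)) fmt_num(srow$wt[1]) else "",
        proc_mutant = if (nrow(srow)) fmt_num(srow$proc_mutant[1]) else "",
        supp_mutant = if (nrow(srow)) fmt_num(srow$supp_mutant[1]) else "",
        criteria = "", class = "",
        stringsAsFactors = FALSE
      )
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), arm = character(0),
               sequence = character(0), wt = character(0),
               proc_mutant = character(0), supp_mutant = character(0),
               criteria = character(0), class = character(0))
  write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the discovery pipeline on files
#'
#' Reads a genome and three strain libraries, optionally candidate windows
#' (BED or GFF3) and an evidence table, runs [discover_mirnas()], and writes
#' `candidates.gff3` (1-based closed, types `miRNA`/`miRNA_like`, attributes
#' carrying class, criteria string, folds and multiplicity),
#' `candidates.bed` (0-based half-open), `report.tsv` (one row per arm:
#' sequences in the RNA alphabet, per-strain RPM, criteria, class) and
#' `run.log`. Outputs are deterministic: rerunning an identical
#' configuration yields byte-identical files.
#'
#' @param config named list or path to a YAML file with entries: `genome`,
#'   `reads_wt`, `reads_proc_mutant`, `reads_supp_mutant`, `out_dir`, and
#'   optionally `windows` (BED/GFF3 path), `evidence` (TSV path) and
#'   `params` (named overrides of [default_params()]).
#' @return Invisibly, a list with the output `paths` and the `candidates`
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("genome", "reads_wt", "reads_proc_mutant", "reads_supp_mutant",
           "out_dir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys)) {
    stop("pipeline config is missing: ", paste(missing_keys, collapse = ", "))
  }
  known <- c(req, "windows", "evidence", "params", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  params <- do.call(default_params, as.list(config$params))
  genome <- load_genome(config$genome)
  libs <- list(
    wt = load_reads(config$reads_wt, "wt",
                    prefilter = c(params$prefilter_min, params$prefilter_max)),
    proc_mutant = load_reads(config$reads_proc_mutant, "proc_mutant",
                             prefilter = c(params$prefilter_min, params$prefilter_max)),
    supp_mutant = load_reads(config$reads_supp_mutant, "supp_mutant",
                             prefilter = c(params$prefilter_min, params$prefilter_max))
  )
  evidence <- if (!is.null(config$evidence)) load_evidence(config$evidence)
  windows <- NULL
  if (!is.null(config$windows)) {
    gr <- rtracklayer::import(config$windows)
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
    if (is.null(nm)) nm <- sprintf("window_%03d", seq_along(gr))
    windows <- data.frame(
      locus_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  }
  cands <- discover_mirnas(genome, libs, evidence = evidence,
                           params = params, windows = windows)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- list(
    gff3 = file.path(out, "candidates.gff3"),
    bed = file.path(out, "candidates.bed"),
    report = file.path(out, "report.tsv"),
    log = file.path(out, "run.log")
  )
  write_candidates_gff3(cands, paths$gff3)
  write_candidates_bed(cands, paths$bed)
  write_report(cands, paths$report)
  log_lines <- c(
    sprintf("mirdisco %s on R %s.%s", as.character(packageVersion("mirdisco")),
            R.version$major, R.version$minor),
    "config:",
    paste0("  ", names(config), ": ",
           vapply(config, function(x) paste(deparse(x), collapse = " "),
                  character(1))),
    "parameters:",
    paste0("  ", names(params), " = ",
           vapply(params, function(x) as.character(x), character(1))),
    "libraries:",
    vapply(names(libs), function(s) {
      l <- libs[[s]]
      sprintf("  %s: %d reads in, %d dropped (alphabet), %d dropped (length)",
              s, l$n_input, l$n_dropped_alphabet, l$n_dropped_length)
    }, character(1)),
    sprintf("candidates: %d total (%d CANONICAL, %d MIRNA_LIKE, %d REJECTED)",
            nrow(cands), sum(cands$class == "CANONICAL"),
            sum(cands$class == "MIRNA_LIKE"), sum(cands$class == "REJECTED"))
  )
  writeLines(log_lines, paths$log)
  invisible(list(paths = paths, candidates = cands))
}
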