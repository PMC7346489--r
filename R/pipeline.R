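#' Run the candidate-gene pipeline from files on disk
#'
#' File-level front end to [screen_candidates()]: reads the
#' differential-expression tables (one or more, any mix of the three
#' comparisons), the gene features, the QTL and SNP catalogues and an
#' optional genetic map; runs the screen; and writes the candidate report
#' (`candidates.tsv`), the evidence tables (`qtl_matches.tsv`,
#' `snp_matches.tsv`) and a run log (`run_log.txt`) recording thresholds,
#' input digests and stage counts. Outputs are deterministic: two runs on
#' identical inputs produce byte-identical files. If any stage fails,
#' partial outputs are removed before the error propagates.
#'
#' @param deg_paths Character vector of DEG table paths.
#' @param gene_path Gene feature file (BED or GFF3).
#' @param qtl_path QTL catalogue TSV.
#' @param snp_path SNP catalogue TSV.
#' @param map_path Optional genetic map TSV.
#' @param out_dir Output directory (created if needed).
#' @param control Thresholds, a [screen_control()].
#' @param deg_dialect Dialect of the DEG tables (see [read_deg_table()]).
#' @param gene_format `"bed"` or `"gff3"`; defaults from the file
#'   extension.
#' @param keep Optional keep-list (see [integrate_evidence()]).
#' @return The `candidate_screen`, invisibly.
#' @export
run_pipeline <- function(deg_paths, gene_path, qtl_path, snp_path,
                         map_path = NULL, out_dir = ".",
                         control = screen_control(),
                         deg_dialect = c("cuffdiff", "simple"),
                         gene_format = NULL, keep = NULL) {
  deg_dialect <- match.arg(deg_dialect)
  if (is.null(gene_format)) {
    gene_format <- if (grepl("\\.bed$", gene_path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  deg <- stage("read_deg", do.call(rbind, lapply(deg_paths, read_deg_table,
                                                 dialect = deg_dialect)))
  genes <- stage("read_genes", read_gene_features(gene_path, gene_format))
  qtls <- stage("read_qtl", read_qtl_table(qtl_path))
  snps <- stage("read_snp", read_snp_table(snp_path))
  map <- if (!is.null(map_path)) stage("read_map", read_genetic_map(map_path))
  scr <- stage("screen", screen_candidates(deg, genes, qtls, snps, map = map,
                                           control = control, keep = keep))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("candidates.tsv", "qtl_matches.tsv",
                                  "snp_matches.tsv", "run_log.txt"))
  tryCatch({
    write_candidate_report(scr, outputs[1], format = "tsv")
    write_tsv_raw(scr$qtl_matches, outputs[2])
    write_tsv_raw(scr$snp_matches, outputs[3])
    inputs <- c(deg_paths, gene_path, qtl_path, snp_path, map_path)
    digests <- tools::md5sum(inputs)
    op <- if (control$strict) "<" else "<="
    log <- c("candgene pipeline run",
             sprintf("threshold q < %g", control$q_max),
             sprintf("threshold expression_quantile = %g",
                     control$expression_quantile),
             sprintf("threshold qtl_window %s %g cM", op, control$max_cm),
             sprintf("threshold snp_window %s %g bp", op, control$max_bp),
             sprintf("input %s md5=%s", names(digests), digests),
             sprintf("count %s = %d", names(scr$counts), scr$counts),
             sprintf("candidates: %s",
                     paste(candidate_genes(scr), collapse = ", ")))
    writeLines(log, outputs[4])
  }, error = function(e) {
    unlink(outputs)
    stop(sprintf("[write] %s", conditionMessage(e)), call. = FALSE)
  })
  invisible(scr)
}

#' Recompute every published distance from positions
#'
#' Recomputes each gene-to-QTL-peak linkage distance and each gene-to-SNP
#' physical distance in the packaged evidence tables from the printed
#' positions alone, and compares against the printed value at its printed
#' precision (linkage distances at 1 decimal cM; physical distances at
#' the printed label's own unit and decimals, rounding half away from
#' zero). Rows carrying a documented discrepancy (the three LMNA linkage
#' rows, whose printed values are not |gene cM - peak cM|) are reported as
#' `EXPECTED_MISMATCH` rather than `FAIL`.
#'
#' @param fixture_dir Directory with the fixture TSVs (default: the
#'   packaged evidence).
#' @return `data.frame` with one row per table cell: `table`
#'   (`"QTL"`/`"SNP"`), `gene`, `evidence_id`, `printed`, `computed`,
#'   `status` (`PASS`, `FAIL` or `EXPECTED_MISMATCH`).
#' @export
#' @examples
#' rep <- reproduce_tables()
#' table(rep$status)
reproduce_tables <- function(fixture_dir = NULL) {
  ev <- load_printed_evidence(fixture_dir)
  genes <- ev$genes

  qd <- ev$qtl_distances
  qtl_rows <- NULL
  if (nrow(qd)) {
    gi <- match(qd$gene, genes$gene)
    qi <- match(qd$qtl_id, ev$qtls$qtl_id)
    check_that(!anyNA(gi) && !anyNA(qi),
               "distance table references unknown gene or QTL")
    comp <- round_half_away(
      cm_distance(genes$linkage_cm[gi], ev$qtls$peak_cm[qi]), 1)
    match_ok <- abs(comp - qd$printed_distance_cm) < 1e-9
    status <- ifelse(match_ok, "PASS",
                     ifelse(qd$known_discrepancy == 1L,
                            "EXPECTED_MISMATCH", "FAIL"))
    qtl_rows <- data.frame(table = "QTL", gene = qd$gene,
                           evidence_id = as.character(qd$qtl_id),
                           printed = formatC(qd$printed_distance_cm,
                                             format = "f", digits = 1),
                           computed = formatC(comp, format = "f", digits = 1),
                           status = status, stringsAsFactors = FALSE)
  }

  sd <- ev$snp_distances
  snp_rows <- NULL
  if (nrow(sd)) {
    gi <- match(sd$gene, genes$gene)
    si <- match(sd$snp_name, ev$snps$snp_name)
    check_that(!anyNA(gi) && !anyNA(si),
               "distance table references unknown gene or SNP")
    bp <- gene_snp_distance(genes$start_bp[gi], genes$end_bp[gi],
                            ev$snps$pos_bp[si])
    parsed <- regmatches(sd$printed_label,
                         regexec("^([0-9]+)(?:\\.([0-9]+))? (Kb|Mb)$",
                                 sd$printed_label))
    comp <- character(nrow(sd))
    ok <- logical(nrow(sd))
    for (i in seq_len(nrow(sd))) {
      p <- parsed[[i]]
      check_that(length(p) == 4,
                 paste0("unparseable distance label: ", sd$printed_label[i]))
      dec <- nchar(p[3])
      unit <- if (p[4] == "Kb") 1e3 else 1e6
      # integer-safe half-away rounding at the printed precision
      val <- floor(bp[i] / (unit / 10^dec) + 0.5) / 10^dec
      comp[i] <- paste0(formatC(val, format = "f", digits = dec), " ", p[4])
      ok[i] <- comp[i] == sd$printed_label[i]
    }
    snp_rows <- data.frame(table = "SNP", gene = sd$gene,
                           evidence_id = sd$snp_name,
                           printed = sd$printed_label, computed = comp,
                           status = ifelse(ok, "PASS", "FAIL"),
                           stringsAsFactors = FALSE)
  }
  out <- rbind(qtl_rows, snp_rows)
  if (is.null(out)) {
    out <- data.frame(table = character(), gene = character(),
                      evidence_id = character(), printed = character(),
                      computed = character(), status = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
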