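#' @importFrom utils read.delim write.table
NULL

COMPARISONS <- c("EARLY_VS_DRY", "PEAK_VS_DRY", "PEAK_VS_EARLY")

# Exact double -> text so every TSV writer/reader pair is a lossless round
# trip; infinite fold changes use the Cuffdiff "inf"/"-inf" tokens.
num2str <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.na(x)] <- "NA"
  trimws(out)
}

parse_num <- function(x, what, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x) & !(toupper(trimws(x)) %in% c("NA", ""))
  if (any(bad)) {
    stop(sprintf("unparseable %s value '%s' at line %d", what,
                 x[which(bad)[1]], lines[which(bad)[1]]), call. = FALSE)
  }
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

read_tsv_raw <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, colClasses = "character",
             comment.char = "#", quote = "")
}

write_tsv_raw <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
}

#' Construct a validated gene feature table
#'
#' Gene features carry a physical interval (1-based, inclusive at both ends)
#' and an optional linkage position in centimorgans. Physical positions from
#' BED input are converted to this convention at the boundary
#' (`start + 1`).
#'
#' @param gene Character vector of unique gene names.
#' @param chrom Chromosome labels (normalized with [normalize_chrom()]).
#' @param start_bp,end_bp Integer-valued interval endpoints, 1-based
#'   inclusive, `1 <= start_bp <= end_bp`.
#' @param linkage_cm Optional known linkage positions (cM, `NA` when the
#'   position must be interpolated from a genetic map).
#' @return A `data.frame` with columns `gene`, `chrom`, `start_bp`,
#'   `end_bp`, `linkage_cm`.
#' @export
#' @examples
#' gene_features("APOC2", "Chr18", 53057717, 53059957, 67.9)
gene_features <- function(gene, chrom, start_bp, end_bp,
                          linkage_cm = NA_real_) {
  df <- data.frame(gene = as.character(gene),
                   chrom = normalize_chrom(chrom),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   linkage_cm = rep_len(as.numeric(linkage_cm), length(gene)),
                   stringsAsFactors = FALSE)
  check_that(!anyDuplicated(df$gene), "gene names must be unique")
  check_that(all(df$start_bp >= 1), "start_bp must be >= 1")
  if (any(df$end_bp < df$start_bp)) {
    bad <- df$gene[which(df$end_bp < df$start_bp)[1]]
    stop(sprintf("gene '%s': end_bp < start_bp after normalization", bad),
         call. = FALSE)
  }
  check_that(all(is.na(df$linkage_cm) | df$linkage_cm >= 0),
             "linkage_cm must be non-negative")
  df
}

#' Read gene features from BED or GFF3
#'
#' Parsing is delegated to \pkg{rtracklayer}; BED's 0-based half-open
#' coordinates are thereby converted to the package's 1-based inclusive
#' convention, so the same features encoded as BED and GFF3 parse to
#' identical tables. For GFF3 only rows of type `gene` are kept (all rows if
#' no type column is present); the gene name is taken from the `Name`
#' attribute, falling back to `ID`.
#'
#' @param path Path to the feature file.
#' @param format `"bed"` or `"gff3"`.
#' @return A gene feature `data.frame` (see [gene_features()]);
#'   `linkage_cm` is `NA` and can be resolved later against a genetic map.
#' @seealso [write_gene_features()], [gene_linkage_position()]
#' @export
read_gene_features <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  check_that(file.exists(path), paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(df)) {
    df <- df[as.character(df$type) == "gene", , drop = FALSE]
  }
  name <- if ("name" %in% names(df)) {
    df$name
  } else if ("Name" %in% names(df) && !all(is.na(df$Name))) {
    df$Name
  } else if ("ID" %in% names(df)) {
    df$ID
  } else {
    stop("feature file carries no gene name column", call. = FALSE)
  }
  gene_features(gene = as.character(name),
                chrom = as.character(df$seqnames),
                start_bp = df$start, end_bp = df$end)
}

#' Write gene features to BED or GFF3
#'
#' Inverse of [read_gene_features()]; the known `linkage_cm` column, which
#' neither format can carry, is dropped.
#'
#' @param genes Gene feature table from [gene_features()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_gene_features <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start_bp, end = genes$end_bp))
  if (format == "bed") {
    gr$name <- genes$gene
  } else {
    gr$type <- "gene"
    gr$ID <- genes$gene
    gr$Name <- genes$gene
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

comparison_code <- function(sample_1, sample_2) {
  code <- paste0(toupper(sample_2), "_VS_", toupper(sample_1))
  bad <- !code %in% COMPARISONS
  if (any(bad)) {
    stop(sprintf("unrecognized sample pair '%s'/'%s'; conditions must be DRY, EARLY or PEAK",
                 sample_1[bad][1], sample_2[bad][1]), call. = FALSE)
  }
  code
}

validate_deg <- function(df) {
  check_that(all(df$fpkm_a >= 0) && all(df$fpkm_b >= 0),
             "FPKM values must be non-negative")
  check_that(all(df$p_value >= 0 & df$p_value <= 1),
             "p_value must lie in [0, 1]")
  check_that(all(df$q_value >= 0 & df$q_value <= 1),
             "q_value must lie in [0, 1]")
  check_that(all(df$comparison %in% COMPARISONS),
             paste("comparison must be one of:",
                   paste(COMPARISONS, collapse = ", ")))
  pinf <- is.infinite(df$log2fc) & df$log2fc > 0
  ninf <- is.infinite(df$log2fc) & df$log2fc < 0
  check_that(all(df$fpkm_a[pinf] == 0 & df$fpkm_b[pinf] > 0),
             "log2fc = +inf requires fpkm_a = 0 and fpkm_b > 0")
  check_that(all(df$fpkm_b[ninf] == 0 & df$fpkm_a[ninf] > 0),
             "log2fc = -inf requires fpkm_b = 0 and fpkm_a > 0")
  df
}

CUFFDIFF_COLS <- c("test_id", "gene", "locus", "sample_1", "sample_2",
                   "status", "value_1", "value_2", "log2(fold_change)",
                   "test_stat", "p_value", "q_value", "significant")

SIMPLE_DEG_COLS <- c("gene", "comparison", "chrom", "start_bp", "end_bp",
                     "fpkm_a", "fpkm_b", "log2fc", "p_value", "q_value")

#' Read a differential-expression table
#'
#' Two dialects are supported: `"cuffdiff"`, the tab-separated
#' `gene_exp.diff` layout emitted by Cuffdiff (literal `inf`/`-inf` tokens
#' in the fold-change column are carried as +/-infinity, and the `locus`
#' string `chrom:start-end` is parsed into interval columns), and
#' `"simple"`, this package's plain TSV layout written by
#' [write_deg_table()]. `fpkm_a` is the first (baseline) condition of the
#' comparison and `fpkm_b` the second, so `log2fc = log2(fpkm_b/fpkm_a)`.
#'
#' @param path Path to the table.
#' @param dialect `"cuffdiff"` or `"simple"`.
#' @return A `data.frame` with columns `gene`, `comparison`, `chrom`,
#'   `start_bp`, `end_bp`, `fpkm_a`, `fpkm_b`, `log2fc`, `p_value`,
#'   `q_value`. One row per input row; an input with only a header yields
#'   zero rows.
#' @export
read_deg_table <- function(path, dialect = c("cuffdiff", "simple")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_raw(path)
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (dialect == "cuffdiff") {
    require_columns(raw, CUFFDIFF_COLS, "cuffdiff table")
    if (nrow(raw) == 0) {
      return(validate_deg(empty_deg_table()))
    }
    locus <- regmatches(raw$locus,
                        regexec("^([^:]+):([0-9]+)-([0-9]+)$", raw$locus))
    bad <- vapply(locus, length, 1L) != 4L
    if (any(bad)) {
      stop(sprintf("unparseable locus '%s' at line %d",
                   raw$locus[which(bad)[1]], lines[which(bad)[1]]),
           call. = FALSE)
    }
    df <- data.frame(
      gene = raw$gene,
      comparison = comparison_code(raw$sample_1, raw$sample_2),
      chrom = normalize_chrom(vapply(locus, `[`, "", 2L)),
      start_bp = as.numeric(vapply(locus, `[`, "", 3L)),
      end_bp = as.numeric(vapply(locus, `[`, "", 4L)),
      fpkm_a = parse_num(raw$value_1, "value_1", lines),
      fpkm_b = parse_num(raw$value_2, "value_2", lines),
      log2fc = parse_num(raw$`log2(fold_change)`, "log2(fold_change)", lines),
      p_value = parse_num(raw$p_value, "p_value", lines),
      q_value = parse_num(raw$q_value, "q_value", lines),
      stringsAsFactors = FALSE)
  } else {
    require_columns(raw, SIMPLE_DEG_COLS, "DEG table")
    if (nrow(raw) == 0) {
      return(validate_deg(empty_deg_table()))
    }
    chrom <- rep(NA_character_, nrow(raw))
    known <- !is.na(raw$chrom) & raw$chrom != "NA"
    chrom[known] <- normalize_chrom(raw$chrom[known])
    df <- data.frame(
      gene = raw$gene,
      comparison = raw$comparison,
      chrom = chrom,
      start_bp = parse_num(raw$start_bp, "start_bp", lines),
      end_bp = parse_num(raw$end_bp, "end_bp", lines),
      fpkm_a = parse_num(raw$fpkm_a, "fpkm_a", lines),
      fpkm_b = parse_num(raw$fpkm_b, "fpkm_b", lines),
      log2fc = parse_num(raw$log2fc, "log2fc", lines),
      p_value = parse_num(raw$p_value, "p_value", lines),
      q_value = parse_num(raw$q_value, "q_value", lines),
      stringsAsFactors = FALSE)
  }
  validate_deg(df)
}

empty_deg_table <- function() {
  data.frame(gene = character(), comparison = character(),
             chrom = character(), start_bp = numeric(), end_bp = numeric(),
             fpkm_a = numeric(), fpkm_b = numeric(), log2fc = numeric(),
             p_value = numeric(), q_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a differential-expression table
#'
#' @param deg DEG table in the layout returned by [read_deg_table()].
#' @param path Output path.
#' @param dialect `"simple"` (the package TSV, lossless round trip) or
#'   `"cuffdiff"` (the 14-column `gene_exp.diff` layout, used by the
#'   synthetic-data generator). Infinite fold changes are written as
#'   `inf`/`-inf`.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg, path, dialect = c("simple", "cuffdiff")) {
  dialect <- match.arg(dialect)
  validate_deg(deg)
  if (nrow(deg) == 0) {
    cols <- if (dialect == "simple") SIMPLE_DEG_COLS else
      c("test_id", "gene_id", CUFFDIFF_COLS[-1])
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  if (dialect == "simple") {
    out <- data.frame(gene = deg$gene, comparison = deg$comparison,
                      chrom = ifelse(is.na(deg$chrom), "NA", deg$chrom),
                      start_bp = num2str(deg$start_bp),
                      end_bp = num2str(deg$end_bp),
                      fpkm_a = num2str(deg$fpkm_a),
                      fpkm_b = num2str(deg$fpkm_b),
                      log2fc = num2str(deg$log2fc),
                      p_value = num2str(deg$p_value),
                      q_value = num2str(deg$q_value),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(deg$comparison, "_VS_")
    out <- data.frame(
      test_id = deg$gene, gene_id = deg$gene, gene = deg$gene,
      locus = paste0(deg$chrom, ":", num2str(deg$start_bp), "-",
                     num2str(deg$end_bp)),
      sample_1 = tolower(vapply(parts, `[`, "", 2L)),
      sample_2 = tolower(vapply(parts, `[`, "", 1L)),
      status = rep("OK", nrow(deg)),
      value_1 = num2str(deg$fpkm_a), value_2 = num2str(deg$fpkm_b),
      `log2(fold_change)` = num2str(deg$log2fc),
      test_stat = rep("0", nrow(deg)),
      p_value = num2str(deg$p_value), q_value = num2str(deg$q_value),
      significant = ifelse(deg$q_value < 0.05, "yes", "no"),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  write_tsv_raw(out, path)
  invisible(path)
}

parse_traits <- function(x) {
  sets <- strsplit(x, ",[[:space:]]*")
  ok <- vapply(sets, function(s) length(s) > 0 && all(s %in% trait_codes()),
               TRUE)
  if (!all(ok)) {
    stop(sprintf("unknown trait code in '%s'; allowed codes: %s",
                 x[!ok][1], paste(trait_codes(), collapse = ", ")),
         call. = FALSE)
  }
  sets
}

#' Read a QTL catalogue
#'
#' Tab-separated with header `qtl_id`, `trait`, `chrom`, `ci_lo_cm`,
#' `ci_hi_cm`, `peak_cm`: one trait QTL per row with its linkage confidence
#' interval and peak (cM). A peak lying outside its own confidence interval
#' occurs in published catalogues and is accepted with a warning rather
#' than rejected.
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame` with those six columns (chromosomes
#'   normalized, traits checked against [trait_codes()]).
#' @export
read_qtl_table <- function(path) {
  raw <- read_tsv_raw(path)
  require_columns(raw, c("qtl_id", "trait", "chrom", "ci_lo_cm", "ci_hi_cm",
                         "peak_cm"), "QTL table")
  lines <- seq_len(nrow(raw)) + 1L
  df <- data.frame(qtl_id = raw$qtl_id,
                   trait = trimws(raw$trait),
                   chrom = if (nrow(raw)) normalize_chrom(raw$chrom) else character(),
                   ci_lo_cm = parse_num(raw$ci_lo_cm, "ci_lo_cm", lines),
                   ci_hi_cm = parse_num(raw$ci_hi_cm, "ci_hi_cm", lines),
                   peak_cm = parse_num(raw$peak_cm, "peak_cm", lines),
                   stringsAsFactors = FALSE)
  bad <- !df$trait %in% trait_codes()
  if (any(bad)) {
    stop(sprintf("unknown trait code '%s'; allowed codes: %s",
                 df$trait[bad][1], paste(trait_codes(), collapse = ", ")),
         call. = FALSE)
  }
  check_that(all(df$ci_lo_cm <= df$ci_hi_cm), "ci_lo_cm must be <= ci_hi_cm")
  outside <- df$peak_cm < df$ci_lo_cm | df$peak_cm > df$ci_hi_cm
  if (any(outside)) {
    warning(sprintf("QTL %s: peak %s lies outside its CI [%s, %s]; kept as given",
                    df$qtl_id[outside][1], df$peak_cm[outside][1],
                    df$ci_lo_cm[outside][1], df$ci_hi_cm[outside][1]),
            call. = FALSE)
  }
  df
}

#' Write a QTL catalogue
#' @param qtls QTL table as returned by [read_qtl_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qtl_table <- function(qtls, path) {
  out <- data.frame(qtl_id = qtls$qtl_id, trait = qtls$trait,
                    chrom = qtls$chrom,
                    ci_lo_cm = num2str(qtls$ci_lo_cm),
                    ci_hi_cm = num2str(qtls$ci_hi_cm),
                    peak_cm = num2str(qtls$peak_cm),
                    stringsAsFactors = FALSE)
  write_tsv_raw(out, path)
  invisible(path)
}

#' Read a GWAS SNP catalogue
#'
#' Tab-separated with header `snp_name`, `chrom`, `pos_bp`, `traits`,
#' `p_min`, `p_max`. The `traits` field is a comma-separated set of trait
#' codes; `p_min`/`p_max` record the printed raw p-value range of the
#' association and are carried as annotation only — the screen never
#' filters on them.
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame` with those six columns.
#' @export
read_snp_table <- function(path) {
  raw <- read_tsv_raw(path)
  require_columns(raw, c("snp_name", "chrom", "pos_bp", "traits", "p_min",
                         "p_max"), "SNP table")
  lines <- seq_len(nrow(raw)) + 1L
  df <- data.frame(snp_name = raw$snp_name,
                   chrom = if (nrow(raw)) normalize_chrom(raw$chrom) else character(),
                   pos_bp = parse_num(raw$pos_bp, "pos_bp", lines),
                   traits = vapply(parse_traits(raw$traits), paste,
                                   "", collapse = ","),
                   p_min = parse_num(raw$p_min, "p_min", lines),
                   p_max = parse_num(raw$p_max, "p_max", lines),
                   stringsAsFactors = FALSE)
  check_that(all(df$pos_bp >= 1), "pos_bp must be >= 1")
  check_that(all(df$p_min > 0 & df$p_min <= 1) &&
             all(df$p_max > 0 & df$p_max <= 1),
             "p_min and p_max must lie in (0, 1]")
  check_that(all(df$p_min <= df$p_max), "p_min must be <= p_max")
  df
}

#' Write a GWAS SNP catalogue
#' @param snps SNP table as returned by [read_snp_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.frame(snp_name = snps$snp_name, chrom = snps$chrom,
                    pos_bp = num2str(snps$pos_bp), traits = snps$traits,
                    p_min = num2str(snps$p_min), p_max = num2str(snps$p_max),
                    stringsAsFactors = FALSE)
  write_tsv_raw(out, path)
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-separated with header `chrom`, `bp`, `cm`: marker physical position
#' and linkage position per row. Within each chromosome the rows must have
#' strictly increasing `bp` and non-decreasing `cm`; a violation is a
#' format error naming the offending marker.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `genetic_map` with columns `chrom`,
#'   `bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  raw <- read_tsv_raw(path)
  require_columns(raw, c("chrom", "bp", "cm"), "genetic map")
  lines <- seq_len(nrow(raw)) + 1L
  df <- data.frame(chrom = if (nrow(raw)) normalize_chrom(raw$chrom) else character(),
                   bp = parse_num(raw$bp, "bp", lines),
                   cm = parse_num(raw$cm, "cm", lines),
                   stringsAsFactors = FALSE)
  genetic_map(df)
}

#' Construct and validate a genetic map
#'
#' @param df `data.frame` with columns `chrom`, `bp` (positive integer
#'   marker positions) and `cm` (non-negative linkage positions), ordered
#'   within chromosome.
#' @return The validated map, classed `genetic_map`.
#' @export
genetic_map <- function(df) {
  require_columns(df, c("chrom", "bp", "cm"), "genetic map")
  check_that(all(df$bp >= 1), "marker bp must be >= 1")
  check_that(all(df$cm >= 0), "marker cm must be non-negative")
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (any(diff(sub$bp) <= 0)) {
      i <- which(diff(sub$bp) <= 0)[1] + 1L
      stop(sprintf("genetic map not monotone on chromosome %s: marker at bp %s out of order",
                   ch, format(sub$bp[i], scientific = FALSE)), call. = FALSE)
    }
    if (any(diff(sub$cm) < 0)) {
      i <- which(diff(sub$cm) < 0)[1] + 1L
      stop(sprintf("genetic map not monotone on chromosome %s: cM decreases at marker bp %s",
                   ch, format(sub$bp[i], scientific = FALSE)), call. = FALSE)
    }
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Write a genetic map
#' @param map A `genetic_map` (see [read_genetic_map()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom, bp = num2str(map$bp),
                    cm = num2str(map$cm), stringsAsFactors = FALSE)
  write_tsv_raw(out, path)
  invisible(path)
}
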