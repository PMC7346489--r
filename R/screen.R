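#' Screening thresholds
#'
#' Bundles every tunable threshold of the candidate screen. Defaults are
#' the published rule set: FDR q < 0.05 with a top-half expression filter
#' for differential expression, a strict 5 cM linkage window around QTL
#' peaks, and a strict 5 Mb physical window around GWAS SNPs.
#'
#' @param q_max Strict q-value threshold for DEG selection, in (0, 1].
#' @param expression_quantile Expression-rank cutoff in \[0, 1\] (0.5 =
#'   keep top-half expressed genes; 0 disables the filter).
#' @param max_cm Linkage window around QTL peaks, cM.
#' @param max_bp Physical window around GWAS SNPs, bp.
#' @param strict Logical; `TRUE` applies both windows strictly (`<`),
#'   `FALSE` inclusively (`<=`).
#' @return Object of class `screen_control`.
#' @export
#' @examples
#' screen_control(max_cm = 2.5)
screen_control <- function(q_max = 0.05, expression_quantile = 0.5,
                           max_cm = 5, max_bp = 5e6, strict = TRUE) {
  check_that(q_max > 0 && q_max <= 1, "q_max must lie in (0, 1]")
  check_that(expression_quantile >= 0 && expression_quantile <= 1,
             "expression_quantile must lie in [0, 1]")
  check_that(max_cm > 0, "max_cm must be positive")
  check_that(max_bp > 0, "max_bp must be positive")
  structure(list(q_max = q_max, expression_quantile = expression_quantile,
                 max_cm = max_cm, max_bp = max_bp, strict = isTRUE(strict)),
            class = "screen_control")
}

#' @export
print.screen_control <- function(x, ...) {
  op <- if (x$strict) "<" else "<="
  cat(sprintf("screen control: q %s %g, expression quantile %g, QTL window %s %g cM, SNP window %s %g Mb\n",
              "<", x$q_max, x$expression_quantile, op, x$max_cm, op,
              x$max_bp / 1e6))
  invisible(x)
}

#' Intersect DEG, QTL and SNP evidence into candidate genes
#'
#' A gene is a candidate if and only if it carries differential-expression
#' evidence in at least one comparison AND at least one QTL match AND at
#' least one SNP match. The three inputs must already be thresholded
#' consistently; a match naming a gene that carries no DEG evidence is a
#' consistency error.
#'
#' @param evidence `data.frame` of DEG evidence with columns `gene`,
#'   `comparison`, `direction` (`"UP"`/`"DOWN"`), one row per gene and
#'   comparison in which it was selected.
#' @param qtl_matches Output of [match_qtls()].
#' @param snp_matches Output of [match_snps()].
#' @param keep Optional character vector: a user-supplied keep-list
#'   representing a downstream biological-function judgement. Applied
#'   after positional integration; candidates outside it are dropped and
#'   recorded in the result's `dropped_by_keep` field.
#' @return Named list of candidate records, sorted by gene name. Each
#'   record has fields `gene`, `deg` (evidence rows), `qtl` and `snp`
#'   (match rows) and `traits` (trait-code union, see
#'   [summarize_traits()]).
#' @export
integrate_evidence <- function(evidence, qtl_matches, snp_matches,
                               keep = NULL) {
  require_columns(evidence, c("gene", "comparison", "direction"),
                  "DEG evidence")
  stray <- setdiff(unique(c(qtl_matches$gene, snp_matches$gene)),
                   evidence$gene)
  if (length(stray)) {
    stop("match list references gene(s) absent from every DEG selection: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  cand <- sort(intersect(intersect(unique(evidence$gene),
                                   unique(qtl_matches$gene)),
                         unique(snp_matches$gene)))
  dropped <- character()
  if (!is.null(keep)) {
    dropped <- setdiff(cand, keep)
    cand <- intersect(cand, keep)
  }
  records <- lapply(cand, function(g) {
    rec <- list(gene = g,
                deg = evidence[evidence$gene == g, , drop = FALSE],
                qtl = qtl_matches[qtl_matches$gene == g, , drop = FALSE],
                snp = snp_matches[snp_matches$gene == g, , drop = FALSE])
    rec$traits <- summarize_traits(rec)
    rec
  })
  names(records) <- cand
  attr(records, "dropped_by_keep") <- dropped
  records
}

#' Trait-code union over a candidate's evidence
#'
#' @param candidate One candidate record from [integrate_evidence()] (or
#'   any list with `qtl$trait` and `snp$traits` components).
#' @return Sorted character vector: the union of the QTL traits and the
#'   SNP trait sets, in the order of [trait_codes()].
#' @export
summarize_traits <- function(candidate) {
  tr <- unique(c(candidate$qtl$trait,
                 unlist(strsplit(candidate$snp$traits, ",[[:space:]]*"))))
  trait_codes()[trait_codes() %in% tr]
}

#' Screen genes for simultaneous DEG, QTL and SNP support
#'
#' The package's front door: applies the full prioritization to one set of
#' inputs and returns a classed result. Stages, in order: per-comparison
#' DEG selection ([select_degs()]), linkage-position resolution for the
#' selected genes ([gene_linkage_position()]), QTL-peak matching in
#' linkage space ([match_qtls()]), GWAS-SNP matching in physical space
#' ([match_snps()]), and evidence integration ([integrate_evidence()]).
#' Proximity is computed for DEG-selected genes only.
#'
#' Genes whose linkage position is neither supplied nor interpolatable
#' (no genetic map) take part in SNP matching but cannot match QTLs; they
#' are counted in the result's `n_unplaced_cm`.
#'
#' @param deg Differential-expression input: either a DEG table in the
#'   [read_deg_table()] layout (may mix the three comparisons; selection
#'   runs per comparison), or a pre-computed evidence `data.frame` with
#'   columns `gene`, `comparison`, `direction` for the case where only
#'   selection outcomes are known (e.g. transcribed published evidence).
#' @param genes Gene feature table ([gene_features()]).
#' @param qtls QTL catalogue ([read_qtl_table()]).
#' @param snps SNP catalogue ([read_snp_table()]).
#' @param map Optional `genetic_map` for genes without a supplied
#'   `linkage_cm`.
#' @param control Thresholds, a [screen_control()].
#' @param keep Optional keep-list applied after positional integration
#'   (see [integrate_evidence()]).
#' @return Object of class `candidate_screen` with components
#'   `candidates` (per-gene evidence records), `evidence`, `qtl_matches`,
#'   `snp_matches`, `selections`, `counts`, `control`, `call`. Supports
#'   `print()`, `summary()`, `as.data.frame()` and `plot()`.
#' @export
#' @examples
#' ev <- load_printed_evidence()
#' scr <- screen_candidates(ev$deg_evidence, ev$genes, ev$qtls, ev$snps)
#' scr
screen_candidates <- function(deg, genes, qtls, snps, map = NULL,
                              control = screen_control(), keep = NULL) {
  stopifnot(inherits(control, "screen_control"))
  if (all(c("q_value", "log2fc") %in% names(deg))) {
    selections <- lapply(split(deg, deg$comparison), select_degs,
                         q_max = control$q_max,
                         expression_quantile = control$expression_quantile)
    evidence <- do.call(rbind, lapply(selections, function(s) {
      if (nrow(s$table) == 0) return(NULL)
      data.frame(gene = s$table$gene, comparison = s$comparison,
                 direction = s$table$direction, stringsAsFactors = FALSE)
    }))
    if (is.null(evidence)) {
      evidence <- data.frame(gene = character(), comparison = character(),
                             direction = character(), stringsAsFactors = FALSE)
    }
    rownames(evidence) <- NULL
  } else {
    require_columns(deg, c("gene", "comparison", "direction"), "DEG evidence")
    selections <- NULL
    evidence <- deg
  }

  sel_genes <- genes[genes$gene %in% evidence$gene, , drop = FALSE]
  missing <- setdiff(unique(evidence$gene), genes$gene)
  if (length(missing)) {
    stop("DEG-selected gene(s) absent from the gene feature table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(map)) {
    sel_genes <- gene_linkage_position(sel_genes, map)
  }
  placed <- !is.na(sel_genes$linkage_cm)
  qtl_matches <- match_qtls(sel_genes[placed, , drop = FALSE], qtls,
                            max_cm = control$max_cm, strict = control$strict)
  snp_matches <- match_snps(sel_genes, snps, max_bp = control$max_bp,
                            strict = control$strict)
  candidates <- integrate_evidence(evidence, qtl_matches, snp_matches,
                                   keep = keep)
  counts <- c(n_genes = nrow(genes),
              n_deg = length(unique(evidence$gene)),
              n_qtl_matched = length(unique(qtl_matches$gene)),
              n_snp_matched = length(unique(snp_matches$gene)),
              n_candidates = length(candidates),
              n_unplaced_cm = sum(!placed))
  structure(list(candidates = candidates, evidence = evidence,
                 qtl_matches = qtl_matches, snp_matches = snp_matches,
                 selections = selections, genes = sel_genes,
                 counts = counts, control = control,
                 dropped_by_keep = attr(candidates, "dropped_by_keep"),
                 call = match.call()),
            class = "candidate_screen")
}

#' Candidate gene names of a screen
#' @param screen A `candidate_screen`.
#' @return Character vector, sorted.
#' @export
candidate_genes <- function(screen) {
  names(screen$candidates)
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat("Positional candidate-gene screen\n")
  print(x$control)
  cat(sprintf("  DEG-selected genes: %d   QTL-matched: %d   SNP-matched: %d\n",
              x$counts["n_deg"], x$counts["n_qtl_matched"],
              x$counts["n_snp_matched"]))
  cat(sprintf("  candidates (all three lines of evidence): %d\n",
              x$counts["n_candidates"]))
  if (length(x$candidates)) {
    cat("  ", paste(candidate_genes(x), collapse = ", "), "\n", sep = "")
  }
  if (length(x$dropped_by_keep)) {
    cat("  dropped by keep-list:",
        paste(x$dropped_by_keep, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.candidate_screen <- function(object, ...) {
  rows <- lapply(object$candidates, function(rec) {
    data.frame(gene = rec$gene,
               comparisons = paste0(rec$deg$comparison, ":",
                                    substr(rec$deg$direction, 1, 1),
                                    collapse = ";"),
               n_qtl = nrow(rec$qtl), n_snp = nrow(rec$snp),
               min_qtl_cm = round_half_away(min(rec$qtl$distance_cm), 1),
               nearest_snp = rec$snp$snp_name[1],
               nearest_snp_dist = rec$snp$distance_label[1],
               traits = paste(rec$traits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene = character(), comparisons = character(),
                      n_qtl = integer(), n_snp = integer(),
                      min_qtl_cm = numeric(), nearest_snp = character(),
                      nearest_snp_dist = character(), traits = character())
  }
  rownames(tab) <- NULL
  structure(list(table = tab, counts = object$counts,
                 control = object$control),
            class = "summary.candidate_screen")
}

#' @export
print.summary.candidate_screen <- function(x, ...) {
  cat("Candidate-gene screen summary\n")
  print(x$control)
  cat(sprintf("  stage counts: %s\n",
              paste(names(x$counts), x$counts, sep = "=", collapse = "  ")))
  if (nrow(x$table)) print(x$table, row.names = FALSE) else cat("  no candidates\n")
  invisible(x)
}

#' Flatten a screen to one row per evidence item
#'
#' One row per (candidate gene, QTL match) and per (candidate gene, SNP
#' match); the layout written by [write_candidate_report()].
#'
#' @param x A `candidate_screen`.
#' @param row.names,optional Ignored (standard generic arguments).
#' @param ... Ignored.
#' @return `data.frame` with columns `gene`, `deg_evidence`, `traits`,
#'   `evidence_type` (`"QTL"`/`"SNP"`), `evidence_id`, `evidence_trait`,
#'   `distance_cm`, `within_ci`, `peak_cm`, `ci_lo_cm`, `ci_hi_cm`,
#'   `distance_bp`, `distance_label`, `pos_bp`, `p_min`, `p_max`.
#' @export
as.data.frame.candidate_screen <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  rows <- lapply(x$candidates, function(rec) {
    ev <- paste0(rec$deg$comparison, ":", rec$deg$direction, collapse = ";")
    tr <- paste(rec$traits, collapse = ",")
    q <- rec$qtl
    s <- rec$snp
    rbind(
      data.frame(gene = rec$gene, deg_evidence = ev, traits = tr,
                 evidence_type = "QTL", evidence_id = as.character(q$qtl_id),
                 evidence_trait = q$trait, distance_cm = q$distance_cm,
                 within_ci = q$within_ci, peak_cm = q$peak_cm,
                 ci_lo_cm = q$ci_lo_cm, ci_hi_cm = q$ci_hi_cm,
                 distance_bp = NA_real_, distance_label = NA_character_,
                 pos_bp = NA_real_, p_min = NA_real_, p_max = NA_real_,
                 stringsAsFactors = FALSE),
      data.frame(gene = rec$gene, deg_evidence = ev, traits = tr,
                 evidence_type = "SNP", evidence_id = s$snp_name,
                 evidence_trait = s$traits, distance_cm = NA_real_,
                 within_ci = NA, peak_cm = NA_real_, ci_lo_cm = NA_real_,
                 ci_hi_cm = NA_real_, distance_bp = s$distance_bp,
                 distance_label = s$distance_label, pos_bp = s$pos_bp,
                 p_min = s$p_min, p_max = s$p_max, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), deg_evidence = character(),
                      traits = character(), evidence_type = character(),
                      evidence_id = character(), evidence_trait = character(),
                      distance_cm = numeric(), within_ci = logical(),
                      peak_cm = numeric(), ci_lo_cm = numeric(),
                      ci_hi_cm = numeric(), distance_bp = numeric(),
                      distance_label = character(), pos_bp = numeric(),
                      p_min = numeric(), p_max = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- row.names
  out
}

#' Plot a candidate screen
#'
#' Dot chart of each candidate's closest evidence on both axes of the
#' screen: nearest QTL-peak distance (cM, left panel) and nearest SNP
#' distance (Mb, right panel), with the screening windows drawn as dashed
#' lines.
#'
#' @param x A `candidate_screen`.
#' @param ... Passed to [graphics::dotchart()].
#' @return Invisibly, `x`.
#' @export
plot.candidate_screen <- function(x, ...) {
  if (!length(x$candidates)) {
    warning("no candidates to plot")
    return(invisible(x))
  }
  qd <- vapply(x$candidates, function(r) min(r$qtl$distance_cm), 0)
  sd <- vapply(x$candidates, function(r) min(r$snp$distance_bp), 0) / 1e6
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::dotchart(rev(qd), labels = rev(names(qd)),
                     xlab = "nearest QTL peak (cM)",
                     xlim = c(0, max(x$control$max_cm, qd)), ...)
  graphics::abline(v = x$control$max_cm, lty = 2)
  graphics::dotchart(rev(sd), labels = rev(names(sd)),
                     xlab = "nearest GWAS SNP (Mb)",
                     xlim = c(0, max(x$control$max_bp / 1e6, sd)), ...)
  graphics::abline(v = x$control$max_bp / 1e6, lty = 2)
  invisible(x)
}
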