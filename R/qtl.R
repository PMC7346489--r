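#' Linkage distance between a gene and a QTL peak
#'
#' Absolute centimorgan distance `|gene_cm - peak_cm|`. Reported tables
#' round it to one decimal (half away from zero); the value returned here
#' is unrounded.
#'
#' @param gene_cm,peak_cm Finite linkage positions (cM), vectorized.
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' cm_distance(67.9, 66)  # 1.9
cm_distance <- function(gene_cm, peak_cm) {
  check_that(all(is.finite(gene_cm)) && all(is.finite(peak_cm)),
             "linkage positions must be finite")
  abs(gene_cm - peak_cm)
}

#' Is a linkage position inside a QTL confidence interval?
#'
#' Inclusive at both ends: `ci_lo_cm <= gene_cm <= ci_hi_cm`.
#'
#' @param gene_cm Linkage position(s) in cM.
#' @param qtl One-row QTL record (or vectors recycled against `gene_cm`).
#' @return Logical vector.
#' @export
flag_within_ci <- function(gene_cm, qtl) {
  qtl$ci_lo_cm <= gene_cm & gene_cm <= qtl$ci_hi_cm
}

#' Match genes to nearby QTL peaks
#'
#' For each gene, finds the QTLs on the same (normalized) chromosome whose
#' peak lies within `max_cm` of the gene's linkage position — strictly
#' closer by default, mirroring a "less than 5 cM" rule; set
#' `strict = FALSE` for a closed threshold. Every qualifying QTL row is
#' retained (a gene may match several), sorted by ascending distance with
#' ties broken by `qtl_id`.
#'
#' @param genes Gene feature table with `linkage_cm` resolved for every
#'   gene (see [gene_linkage_position()]).
#' @param qtls QTL catalogue ([read_qtl_table()]).
#' @param max_cm Linkage window in cM.
#' @param strict Logical; strict (`<`) or closed (`<=`) comparison.
#' @return `data.frame` with one row per (gene, QTL) match: `gene`,
#'   `qtl_id`, `trait`, `chrom`, `gene_cm`, `peak_cm`, `distance_cm`,
#'   `within_ci`, `ci_lo_cm`, `ci_hi_cm`.
#' @export
match_qtls <- function(genes, qtls, max_cm = 5, strict = TRUE) {
  if (any(is.na(genes$linkage_cm))) {
    stop("unresolved linkage_cm for gene(s): ",
         paste(genes$gene[is.na(genes$linkage_cm)], collapse = ", "),
         "; resolve with gene_linkage_position()", call. = FALSE)
  }
  check_that(max_cm > 0, "max_cm must be positive")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    q <- qtls[qtls$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(q) == 0) next
    d <- cm_distance(genes$linkage_cm[i], q$peak_cm)
    keep <- if (strict) d < max_cm else d <= max_cm
    if (!any(keep)) next
    q <- q[keep, , drop = FALSE]
    d <- d[keep]
    ord <- order(d, q$qtl_id)
    out[[i]] <- data.frame(gene = genes$gene[i], qtl_id = q$qtl_id[ord],
                           trait = q$trait[ord], chrom = q$chrom[ord],
                           gene_cm = genes$linkage_cm[i],
                           peak_cm = q$peak_cm[ord],
                           distance_cm = d[ord],
                           within_ci = flag_within_ci(genes$linkage_cm[i],
                                                      q[ord, , drop = FALSE]),
                           ci_lo_cm = q$ci_lo_cm[ord],
                           ci_hi_cm = q$ci_hi_cm[ord],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- empty_qtl_matches()
  rownames(out) <- NULL
  out
}

empty_qtl_matches <- function() {
  data.frame(gene = character(), qtl_id = character(), trait = character(),
             chrom = character(), gene_cm = numeric(), peak_cm = numeric(),
             distance_cm = numeric(), within_ci = logical(),
             ci_lo_cm = numeric(), ci_hi_cm = numeric(),
             stringsAsFactors = FALSE)
}
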