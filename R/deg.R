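#' Expression level of a gene in a two-condition comparison
#'
#' The measure used by the top-half expression-rank filter: the arithmetic
#' mean of the two condition FPKMs. It is symmetric in the two conditions;
#' a gene expressed in only one condition (infinite fold change) ranks by
#' half its single nonzero FPKM.
#'
#' @param fpkm_a,fpkm_b Non-negative FPKM values for the two conditions
#'   (vectorized).
#' @return Numeric vector of mean FPKMs.
#' @export
#' @examples
#' expression_level(2, 4)
expression_level <- function(fpkm_a, fpkm_b) {
  check_that(all(fpkm_a >= 0) && all(fpkm_b >= 0),
             "FPKM values must be non-negative")
  (fpkm_a + fpkm_b) / 2
}

#' Select differentially expressed genes in one comparison
#'
#' A gene is selected when its FDR q-value is strictly below `q_max` and
#' its expression level ([expression_level()]) is at or above the
#' `expression_quantile` quantile of all tested genes in the comparison
#' (the default 0.5 keeps the top-half expressed genes; ties at the cut
#' are kept). Selected genes are classified `UP` when `log2fc > 0` and
#' `DOWN` when `log2fc < 0`; infinite fold changes classify by the sign of
#' the infinity. A significant gene with `log2fc == 0` has no direction
#' and is excluded with a message.
#'
#' @param deg DEG table ([read_deg_table()] layout); all rows must belong
#'   to one comparison.
#' @param q_max Strict q-value threshold in (0, 1].
#' @param expression_quantile Expression-rank cutoff in \[0, 1\]; 0
#'   disables the expression filter.
#' @return An object of class `deg_selection`: list with `comparison`,
#'   `table` (the selected rows plus a `direction` column), `n_up`,
#'   `n_down`, `q_max`, `expression_quantile`, `expression_cutoff`.
#' @export
select_degs <- function(deg, q_max = 0.05, expression_quantile = 0.5) {
  check_that(q_max > 0 && q_max <= 1, "q_max must lie in (0, 1]")
  check_that(expression_quantile >= 0 && expression_quantile <= 1,
             "expression_quantile must lie in [0, 1]")
  comp <- unique(deg$comparison)
  if (length(comp) > 1) {
    stop("records mix comparisons: ", paste(comp, collapse = ", "),
         "; select per comparison", call. = FALSE)
  }
  if (nrow(deg) == 0) {
    sel <- cbind(deg, direction = character(0))
    return(structure(list(comparison = NA_character_, table = sel,
                          n_up = 0L, n_down = 0L, q_max = q_max,
                          expression_quantile = expression_quantile,
                          expression_cutoff = NA_real_),
                     class = "deg_selection"))
  }
  expr <- expression_level(deg$fpkm_a, deg$fpkm_b)
  cutoff <- if (expression_quantile > 0) {
    stats::quantile(expr, probs = expression_quantile, names = FALSE)
  } else {
    -Inf
  }
  keep <- deg$q_value < q_max & expr >= cutoff
  flat <- keep & deg$log2fc == 0
  if (any(flat)) {
    message(sum(flat), " significant gene(s) with log2fc = 0 excluded (no direction)")
    keep <- keep & deg$log2fc != 0
  }
  sel <- deg[keep, , drop = FALSE]
  sel$expression <- expr[keep]
  sel$direction <- ifelse(sel$log2fc > 0, "UP", "DOWN")
  rownames(sel) <- NULL
  structure(list(comparison = comp, table = sel,
                 n_up = sum(sel$direction == "UP"),
                 n_down = sum(sel$direction == "DOWN"),
                 q_max = q_max, expression_quantile = expression_quantile,
                 expression_cutoff = cutoff),
            class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat("DEG selection -", x$comparison, "\n")
  cat(sprintf("  %d selected (%d up-regulated, %d down-regulated)\n",
              nrow(x$table), x$n_up, x$n_down))
  cat(sprintf("  thresholds: q < %g, expression quantile %g (cutoff %.4g FPKM)\n",
              x$q_max, x$expression_quantile, x$expression_cutoff))
  invisible(x)
}

#' Replicate-correlation quality control
#'
#' Pairwise Pearson correlation between replicate expression profiles,
#' computed on `log2(FPKM + 1)`. A stage passes when every off-diagonal
#' pair exceeds `min_r`. A zero-variance replicate leaves its pairs
#' undefined (`NA`), which is reported as a failed pair.
#'
#' @param fpkm_matrix Numeric genes-by-replicates matrix of non-negative
#'   FPKMs for one stage (at least 3 genes, at least 2 replicates).
#' @param min_r Pass threshold on the pairwise correlation.
#' @return An object of class `qc_report`: list with the correlation
#'   matrix `r`, logical `pass`, the failing pairs, and `min_r`.
#' @export
qc_replicate_correlation <- function(fpkm_matrix, min_r = 0.935) {
  fpkm_matrix <- as.matrix(fpkm_matrix)
  check_that(ncol(fpkm_matrix) >= 2, "need at least 2 replicates")
  check_that(nrow(fpkm_matrix) >= 3, "need at least 3 genes")
  check_that(all(fpkm_matrix >= 0), "FPKM values must be non-negative")
  lg <- log2(fpkm_matrix + 1)
  r <- suppressWarnings(stats::cor(lg, method = "pearson"))
  diag(r) <- 1
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  bad <- is.na(r[pairs]) | r[pairs] <= min_r
  failed <- data.frame(rep_a = pairs[bad, 1], rep_b = pairs[bad, 2],
                       r = r[pairs][bad])
  structure(list(r = r, pass = nrow(failed) == 0, failed_pairs = failed,
                 min_r = min_r),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Replicate QC:", if (x$pass) "PASS" else "FAIL",
      sprintf("(all pairwise Pearson r on log2(FPKM+1) > %g required)\n",
              x$min_r))
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  %d replicate pairs, min r = %.4f\n", length(off),
              suppressWarnings(min(off, na.rm = FALSE))))
  if (!x$pass) {
    cat("  failing pairs:\n")
    print(x$failed_pairs)
  }
  invisible(x)
}
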