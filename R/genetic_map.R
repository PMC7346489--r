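#' Interpolate a linkage position from a genetic map
#'
#' Piecewise-linear interpolation of centimorgan position between the two
#' markers flanking `bp` on the given chromosome. A query at a marker's
#' exact physical position returns exactly that marker's cM. Queries
#' before the first or after the last marker clamp to the terminal
#' marker's cM with a warning (extrapolation could produce negative or
#' runaway linkage positions); a single-marker chromosome therefore maps
#' every position to that marker's cM.
#'
#' @param map A `genetic_map` (see [genetic_map()]).
#' @param chrom Chromosome label (normalized internally).
#' @param bp Positive integer physical position(s) to convert.
#' @return Numeric vector of linkage positions (cM).
#' @export
#' @examples
#' m <- genetic_map(data.frame(chrom = "1", bp = c(10000, 20000), cm = c(0, 10)))
#' interpolate_cm(m, "1", 15000)
interpolate_cm <- function(map, chrom, bp) {
  chrom <- normalize_chrom(chrom)
  check_that(length(chrom) == 1, "one chromosome per call")
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("chromosome '%s' absent from genetic map", chrom),
         call. = FALSE)
  }
  check_that(all(bp >= 1), "bp must be >= 1")
  outside <- bp < sub$bp[1] | bp > sub$bp[nrow(sub)]
  if (any(outside)) {
    warning(sprintf("%d position(s) outside the mapped range on chromosome %s; clamped to terminal marker cM",
                    sum(outside), chrom), call. = FALSE)
  }
  if (nrow(sub) == 1) {
    return(rep(sub$cm, length(bp)))
  }
  stats::approx(x = sub$bp, y = sub$cm, xout = bp, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Resolve the linkage position of gene features
#'
#' Returns the supplied `linkage_cm` where present; otherwise interpolates
#' the gene's interval midpoint, `floor((start_bp + end_bp)/2)`, against
#' the genetic map (the midpoint is strand-neutral, and strand plays no
#' role in the screen).
#'
#' @param genes Gene feature table ([gene_features()]).
#' @param map A `genetic_map`, required when any gene lacks a supplied
#'   `linkage_cm`.
#' @return The gene table with `linkage_cm` filled in for every gene.
#' @export
gene_linkage_position <- function(genes, map = NULL) {
  todo <- is.na(genes$linkage_cm)
  if (!any(todo)) {
    return(genes)
  }
  check_that(!is.null(map),
             "genes without a supplied linkage_cm require a genetic map")
  mid <- floor((genes$start_bp + genes$end_bp) / 2)
  for (ch in unique(genes$chrom[todo])) {
    idx <- which(todo & genes$chrom == ch)
    genes$linkage_cm[idx] <- interpolate_cm(map, ch, mid[idx])
  }
  genes
}
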