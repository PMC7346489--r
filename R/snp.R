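#' Physical distance from a gene interval to a SNP
#'
#' Nearest-boundary convention: zero when the SNP lies inside the interval
#' (inclusive at both ends), otherwise the distance to the closer
#' endpoint, `min(|pos - start|, |pos - end|)`. This is the convention
#' under which published nearest-SNP tables for the bovine milk-trait
#' candidates reproduce exactly. Note it differs by one from a gap count
#' (an adjacent SNP is at distance 1, not 0).
#'
#' @param start_bp,end_bp Gene interval, 1-based inclusive (vectorized).
#' @param pos_bp SNP position(s).
#' @return Non-negative numeric vector of base-pair distances.
#' @export
#' @examples
#' gene_snp_distance(53057717, 53059957, 53948569)  # 888612
gene_snp_distance <- function(start_bp, end_bp, pos_bp) {
  check_that(all(start_bp >= 1) && all(end_bp >= start_bp),
             "invalid interval: need 1 <= start_bp <= end_bp")
  check_that(all(pos_bp >= 1), "pos_bp must be >= 1")
  inside <- pos_bp >= start_bp & pos_bp <= end_bp
  ifelse(inside, 0, pmin(abs(pos_bp - start_bp), abs(pos_bp - end_bp)))
}

#' Match genes to nearby GWAS SNPs
#'
#' For each gene, finds the SNPs on the same (normalized) chromosome whose
#' nearest-boundary distance ([gene_snp_distance()]) is within `max_bp` —
#' strictly closer by default, mirroring a "less than 5 Mb" rule. SNP
#' positions are indexed per chromosome in sorted order and the candidate
#' window `[start - max_bp, end + max_bp]` is located by binary search
#' ([findInterval()]), so only SNPs that can qualify are scored. Matches
#' are sorted by ascending distance, ties broken by `snp_name`.
#'
#' @param genes Gene feature table ([gene_features()]).
#' @param snps SNP catalogue ([read_snp_table()]).
#' @param max_bp Physical window in bp (default 5 Mb).
#' @param strict Logical; strict (`<`) or closed (`<=`) comparison.
#' @return `data.frame` with one row per (gene, SNP) match: `gene`,
#'   `snp_name`, `chrom`, `pos_bp`, `traits`, `p_min`, `p_max`,
#'   `distance_bp`, `distance_label`.
#' @export
match_snps <- function(genes, snps, max_bp = 5e6, strict = TRUE) {
  check_that(max_bp > 0, "max_bp must be positive")
  index <- split(seq_len(nrow(snps)), snps$chrom)
  index <- lapply(index, function(i) i[order(snps$pos_bp[i], snps$snp_name[i])])
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    idx <- index[[genes$chrom[i]]]
    if (is.null(idx)) next
    pos <- snps$pos_bp[idx]
    # window of SNP positions that could possibly lie within max_bp
    lo <- findInterval(genes$start_bp[i] - max_bp, pos) + 1L
    hi <- findInterval(genes$end_bp[i] + max_bp, pos)
    if (lo > hi) next
    idx <- idx[lo:hi]
    d <- gene_snp_distance(genes$start_bp[i], genes$end_bp[i],
                           snps$pos_bp[idx])
    keep <- if (strict) d < max_bp else d <= max_bp
    if (!any(keep)) next
    idx <- idx[keep]
    d <- d[keep]
    ord <- order(d, snps$snp_name[idx])
    out[[i]] <- data.frame(gene = genes$gene[i],
                           snp_name = snps$snp_name[idx][ord],
                           chrom = snps$chrom[idx][ord],
                           pos_bp = snps$pos_bp[idx][ord],
                           traits = snps$traits[idx][ord],
                           p_min = snps$p_min[idx][ord],
                           p_max = snps$p_max[idx][ord],
                           distance_bp = d[ord],
                           distance_label = format_bp(d[ord]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- empty_snp_matches()
  rownames(out) <- NULL
  out
}

empty_snp_matches <- function() {
  data.frame(gene = character(), snp_name = character(), chrom = character(),
             pos_bp = numeric(), traits = character(), p_min = numeric(),
             p_max = numeric(), distance_bp = numeric(),
             distance_label = character(), stringsAsFactors = FALSE)
}

#' Format a base-pair distance for reporting
#'
#' Canonical rendering: `"0 bp"` for zero, kilobases with two decimals
#' below 1 Mb, megabases with two decimals from 1 Mb, rounding half away
#' from zero. The rounding is performed on the integer bp value scaled by
#' a power of ten, so exact half-way cases (e.g. 230,585 bp -> 230.59 Kb)
#' are not at the mercy of binary floating point.
#'
#' @param distance_bp Non-negative integer distance(s) in bp.
#' @return Character vector of labels.
#' @export
#' @examples
#' format_bp(c(0, 2379, 888612, 2677519))
format_bp <- function(distance_bp) {
  check_that(all(distance_bp >= 0), "distance_bp must be non-negative")
  kb <- floor(distance_bp / 10 + 0.5) / 100
  mb <- floor(distance_bp / 1e4 + 0.5) / 100
  ifelse(distance_bp == 0, "0 bp",
         ifelse(distance_bp < 1e6,
                paste0(formatC(kb, format = "f", digits = 2), " Kb"),
                paste0(formatC(mb, format = "f", digits = 2), " Mb")))
}
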