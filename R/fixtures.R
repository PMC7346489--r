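#' Load the packaged bovine milk-trait evidence
#'
#' Reads the plain-text evidence tables shipped with the package: the 23
#' screened liver genes (11 with published linkage positions), their
#' differential-expression evidence across the three lactation-stage
#' comparisons, the 15 reported milk-trait QTLs, the 76 distinct
#' significant GWAS SNPs, and the published gene-to-QTL and gene-to-SNP distance tables
#' used by [reproduce_tables()]. Running [screen_candidates()] on these
#' inputs recovers the published ten-gene candidate set.
#'
#' @param dir Directory holding the fixture TSVs; defaults to the
#'   package's `extdata`.
#' @return List with elements `genes`, `deg_evidence`, `qtls`, `snps`,
#'   `qtl_distances`, `snp_distances`, `top_degs`.
#' @export
#' @examples
#' ev <- load_printed_evidence()
#' nrow(ev$snps)
load_printed_evidence <- function(dir = NULL) {
  path <- function(f) {
    if (is.null(dir)) candgene_fixture(f) else file.path(dir, f)
  }
  genes_raw <- read_tsv_raw(path("milk_trait_genes.tsv"))
  genes <- gene_features(gene = genes_raw$gene, chrom = genes_raw$chrom,
                         start_bp = as.numeric(genes_raw$start_bp),
                         end_bp = as.numeric(genes_raw$end_bp),
                         linkage_cm = suppressWarnings(
                           as.numeric(genes_raw$linkage_cm)))
  deg_evidence <- read_tsv_raw(path("milk_trait_deg_evidence.tsv"))
  qtls <- suppressWarnings(read_qtl_table(path("milk_trait_qtls.tsv")))
  snps <- read_snp_table(path("milk_trait_snps.tsv"))
  qd <- read_tsv_raw(path("table_qtl_distances.tsv"))
  qd$printed_distance_cm <- as.numeric(qd$printed_distance_cm)
  qd$known_discrepancy <- as.integer(qd$known_discrepancy)
  sd <- read_tsv_raw(path("table_snp_distances.tsv"))
  td <- read_tsv_raw(path("top_degs.tsv"))
  td$q_value <- as.numeric(td$q_value)
  td$log2fc <- as.numeric(td$log2fc)
  list(genes = genes, deg_evidence = deg_evidence, qtls = qtls,
       snps = snps, qtl_distances = qd, snp_distances = sd, top_degs = td)
}
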