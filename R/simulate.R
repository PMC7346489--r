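#' Simulate a genome: gene features and a genetic map
#'
#' Non-overlapping gene intervals placed uniformly along each chromosome,
#' and a monotone genetic map with one marker per ~1 Mb whose cM
#' increments are drawn positive (~0.5-1.5 cM/Mb, i.e. about 1 cM per Mb
#' as in cattle-scale maps). Placement that cannot fit the requested
#' genes on the requested chromosomes is a parameter error.
#'
#' @param seed Integer seed; the same seed reproduces identical output.
#' @param n_chrom Number of chromosomes (default 10).
#' @param chrom_len_bp Chromosome length in bp (all chromosomes equal).
#' @param n_genes Total number of genes.
#' @param gene_len_range Range of gene lengths in bp.
#' @return List with `genes` (a [gene_features()] table, `linkage_cm`
#'   unset), `map` (a `genetic_map`) and `params`.
#' @export
simulate_genome <- function(seed, n_chrom = 10, chrom_len_bp = 80e6,
                            n_genes = 150, gene_len_range = c(2e3, 5e4)) {
  check_that(n_genes >= 1, "n_genes must be >= 1")
  check_that(chrom_len_bp >= 1e4, "chrom_len_bp must be >= 10,000")
  with_seed(split_seed(seed, 1L), {
    chrom_of <- sort(sample.int(n_chrom, n_genes, replace = TRUE))
    gene <- sprintf("G%04d", seq_len(n_genes))
    start <- end <- numeric(n_genes)
    for (ch in seq_len(n_chrom)) {
      idx <- which(chrom_of == ch)
      k <- length(idx)
      if (k == 0) next
      len <- floor(stats::runif(k, gene_len_range[1], gene_len_range[2]))
      free <- chrom_len_bp - sum(len)
      if (free <= k) {
        stop("infeasible packing: genes exceed chromosome capacity",
             call. = FALSE)
      }
      anchors <- sort(sample.int(free, k))
      start[idx] <- anchors + cumsum(c(0, len[-k]))
      end[idx] <- start[idx] + len - 1
    }
    markers <- lapply(seq_len(n_chrom), function(ch) {
      bp <- unique(c(seq(1, chrom_len_bp, by = 1e6), chrom_len_bp))
      data.frame(chrom = as.character(ch), bp = bp,
                 cm = c(0, cumsum(stats::runif(length(bp) - 1, 0.5, 1.5))),
                 stringsAsFactors = FALSE)
    })
    list(genes = gene_features(gene, as.character(chrom_of), start, end),
         map = genetic_map(do.call(rbind, markers)),
         params = list(seed = seed, n_chrom = n_chrom,
                       chrom_len_bp = chrom_len_bp, n_genes = n_genes,
                       gene_len_range = gene_len_range))
  })
}

#' Simulate expression and differential-expression tables
#'
#' Emulates a 3-stage x 3-replicate liver RNA-seq design. Baseline FPKM
#' is lognormal; a pool of genes shared across the three stage
#' comparisons is planted as differentially expressed with multiplicative
#' shifts of |log2FC| in `lfc_range`, a fraction `frac_inf` of them
#' expressed in only one condition (infinite fold change). q-values are
#' emitted directly, consistent with the planted truth (below 0.05 for
#' planted genes, at or above it for nulls): the differential test itself
#' is upstream of this package's contract, which consumes its output
#' dialect. Planted genes are given high baseline expression (at least
#' four times the null median) so that they survive the top-half
#' expression filter by construction. The replicate matrix applies
#' multiplicative lognormal noise (`sigma` on the log scale) around each
#' gene's baseline.
#'
#' @param genome Output of [simulate_genome()].
#' @param seed Integer seed.
#' @param n_de_per_comparison Planted DE genes per comparison, drawn from
#'   the shared pool.
#' @param de_pool_size Size of the shared DE pool.
#' @param lfc_range Range of |log2 fold change| for planted genes.
#' @param frac_inf Fraction of planted genes set to one-condition-zero.
#' @param sigma Replicate noise (sdlog) for the FPKM matrix.
#' @return List with `deg` (all comparisons stacked, [read_deg_table()]
#'   layout), `tables` (per-comparison DEG tables), `fpkm` (genes x 9
#'   replicate matrix, columns `<STAGE>_<rep>`), `truth` (`data.frame`
#'   gene/comparison/sign) and `params`.
#' @export
simulate_expression <- function(genome, seed, n_de_per_comparison = 12,
                                de_pool_size = 16, lfc_range = c(1, 6),
                                frac_inf = 0.1, sigma = 0.2) {
  genes <- genome$genes
  n <- nrow(genes)
  check_that(de_pool_size <= n, "de_pool_size exceeds number of genes")
  check_that(n_de_per_comparison <= de_pool_size,
             "n_de_per_comparison exceeds de_pool_size")
  with_seed(split_seed(seed, 2L), {
    baseline <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
    pool <- sample(genes$gene, de_pool_size)
    pool_idx <- match(pool, genes$gene)
    baseline[pool_idx] <- pmax(stats::rlnorm(de_pool_size, 4, 0.5),
                               4 * stats::median(baseline))
    truth <- NULL
    tables <- list()
    for (comp in COMPARISONS) {
      de <- if (n_de_per_comparison > 0) {
        sample(pool, n_de_per_comparison)
      } else {
        character()
      }
      is_de <- genes$gene %in% de
      sign <- ifelse(stats::runif(n) < 0.5, 1, -1)
      lfc <- stats::runif(n, lfc_range[1], lfc_range[2]) * sign
      inf_case <- is_de & stats::runif(n) < frac_inf
      fpkm_a <- baseline
      fpkm_b <- baseline
      fpkm_b[is_de] <- baseline[is_de] * 2^lfc[is_de]
      log2fc <- rep(0, n)
      log2fc[is_de] <- lfc[is_de]
      up_inf <- inf_case & sign > 0
      dn_inf <- inf_case & sign < 0
      fpkm_a[up_inf] <- 0
      fpkm_b[up_inf] <- baseline[up_inf]
      log2fc[up_inf] <- Inf
      fpkm_b[dn_inf] <- 0
      fpkm_a[dn_inf] <- baseline[dn_inf]
      log2fc[dn_inf] <- -Inf
      q <- ifelse(is_de, stats::runif(n, 1e-6, 0.049),
                  stats::runif(n, 0.05, 1))
      tab <- data.frame(gene = genes$gene, comparison = comp,
                        chrom = genes$chrom, start_bp = genes$start_bp,
                        end_bp = genes$end_bp, fpkm_a = fpkm_a,
                        fpkm_b = fpkm_b, log2fc = log2fc,
                        p_value = q * stats::runif(n, 0.01, 1),
                        q_value = q, stringsAsFactors = FALSE)
      tables[[comp]] <- validate_deg(tab)
      if (any(is_de)) {
        truth <- rbind(truth, data.frame(gene = genes$gene[is_de],
                                         comparison = comp,
                                         sign = sign[is_de],
                                         stringsAsFactors = FALSE))
      }
    }
    stages <- c("DRY", "EARLY", "PEAK")
    fpkm <- matrix(baseline, nrow = n, ncol = 9) *
      matrix(stats::rlnorm(n * 9, 0, sigma), nrow = n)
    dimnames(fpkm) <- list(genes$gene,
                           paste(rep(stages, each = 3), 1:3, sep = "_"))
    if (is.null(truth)) {
      truth <- data.frame(gene = character(), comparison = character(),
                          sign = numeric(), stringsAsFactors = FALSE)
    }
    list(deg = do.call(rbind, c(tables, list(make.row.names = FALSE))),
         tables = tables, fpkm = fpkm, truth = truth,
         params = list(seed = seed,
                       n_de_per_comparison = n_de_per_comparison,
                       de_pool_size = de_pool_size, lfc_range = lfc_range,
                       frac_inf = frac_inf, sigma = sigma))
  })
}

# Complement of the union of [lo_i, hi_i] windows inside [1, len]:
# data.frame of allowed intervals.
allowed_intervals <- function(lo, hi, len) {
  lo <- pmax(lo, 1)
  hi <- pmin(hi, len)
  keep <- lo <= hi
  lo <- lo[keep]
  hi <- hi[keep]
  if (!length(lo)) {
    return(data.frame(lo = 1, hi = len))
  }
  ord <- order(lo)
  lo <- lo[ord]
  hi <- hi[ord]
  merged_lo <- lo[1]
  merged_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= merged_hi[length(merged_hi)]) {
      merged_hi[length(merged_hi)] <- max(merged_hi[length(merged_hi)], hi[i])
    } else {
      merged_lo <- c(merged_lo, lo[i])
      merged_hi <- c(merged_hi, hi[i])
    }
  }
  gaps_lo <- c(1, merged_hi + 1)
  gaps_hi <- c(merged_lo - 1, len)
  keep <- gaps_lo <= gaps_hi
  data.frame(lo = gaps_lo[keep], hi = gaps_hi[keep])
}

sample_from_intervals <- function(iv, k) {
  w <- iv$hi - iv$lo + 1
  pick <- sample.int(nrow(iv), k, replace = TRUE, prob = w)
  iv$lo[pick] + floor(stats::runif(k) * w[pick])
}

#' Simulate QTL and SNP catalogues with planted candidates
#'
#' Designates `n_candidate_target` of the differentially expressed genes
#' as ground-truth candidates and plants, for each, one QTL whose peak
#' lies within `near_cm` of the gene's linkage position and one SNP
#' within `near_bp` of an interval edge. Decoy QTLs and SNPs are placed
#' at least twice the screening threshold away from every DE gene, by
#' exact sampling from the complement of the exclusion windows. Candidate
#' genes are chosen as whole spatial clusters of DE genes (genes closer
#' than the threshold plus planting margin are taken or left together),
#' so no non-candidate DE gene can fall inside both evidence windows of a
#' planted gene; if no cluster combination reaches the target, or a decoy
#' has nowhere to go, placement errors rather than degrading.
#'
#' @param genome Output of [simulate_genome()].
#' @param truth DE truth from [simulate_expression()] (`$truth`).
#' @param seed Integer seed.
#' @param n_candidate_target Number of planted candidate genes.
#' @param near_cm,near_bp Planting margins for QTL peaks (cM) and SNPs
#'   (bp).
#' @param n_decoys Decoy QTLs and decoy SNPs (each).
#' @param max_cm,max_bp The screening windows the plant must respect.
#' @return List with `qtls`, `snps` (catalogue `data.frame`s),
#'   `planted_candidates` (character) and `params`.
#' @export
simulate_catalogues <- function(genome, truth, seed, n_candidate_target = 8,
                                near_cm = 1, near_bp = 1e5, n_decoys = 30,
                                max_cm = 5, max_bp = 5e6) {
  genes <- gene_linkage_position(genome$genes, genome$map)
  de_genes <- unique(truth$gene)
  check_that(n_candidate_target <= length(de_genes),
             "n_candidate_target exceeds the number of distinct DE genes")
  chrom_len <- genome$params$chrom_len_bp
  with_seed(split_seed(seed, 3L), {
    de <- genes[genes$gene %in% de_genes, , drop = FALSE]
    de$mid <- floor((de$start_bp + de$end_bp) / 2)

    # spatial clusters of DE genes: chain genes whose evidence windows
    # could interact (bp or cM)
    link_bp <- max_bp + 2 * near_bp + 4e5
    link_cm <- max_cm + 2 * near_cm + 1
    de <- de[order(de$chrom, de$mid), , drop = FALSE]
    cluster <- integer(nrow(de))
    cid <- 0L
    for (i in seq_len(nrow(de))) {
      if (i == 1 || de$chrom[i] != de$chrom[i - 1] ||
          (de$mid[i] - de$mid[i - 1] >= link_bp &&
           de$linkage_cm[i] - de$linkage_cm[i - 1] >= link_cm)) {
        cid <- cid + 1L
      }
      cluster[i] <- cid
    }
    # exact subset-sum over cluster sizes: clusters are taken whole, so a
    # combination must hit the target exactly
    sizes <- table(cluster)
    ids <- as.integer(names(sizes))
    reach <- vector("list", n_candidate_target + 1L)  # sum k -> cluster ids
    reach[[1]] <- integer(0)
    for (j in seq_along(ids)) {
      sz <- as.integer(sizes[j])
      for (s in rev(seq_len(n_candidate_target + 1L))) {
        ns <- s + sz
        if (!is.null(reach[[s]]) && ns <= n_candidate_target + 1L &&
            is.null(reach[[ns]])) {
          reach[[ns]] <- c(reach[[s]], ids[j])
        }
      }
    }
    chosen <- reach[[n_candidate_target + 1L]]
    if (n_candidate_target > 0 && is.null(chosen)) {
      stop("cannot place ", n_candidate_target,
           " separated candidate genes; reduce the target or enlarge the genome",
           call. = FALSE)
    }
    cand <- de[cluster %in% chosen, , drop = FALSE]

    qtls <- data.frame(
      qtl_id = sprintf("SIMQ%03d", seq_len(nrow(cand))),
      trait = sample(trait_codes(), nrow(cand), replace = TRUE),
      chrom = cand$chrom,
      ci_lo_cm = rep(NA_real_, nrow(cand)),
      ci_hi_cm = rep(NA_real_, nrow(cand)),
      peak_cm = pmax(cand$linkage_cm +
                       stats::runif(nrow(cand), -near_cm, near_cm), 0),
      stringsAsFactors = FALSE)
    half <- stats::runif(nrow(cand), 2, 10)
    qtls$ci_lo_cm <- pmax(qtls$peak_cm - half, 0)
    qtls$ci_hi_cm <- qtls$peak_cm + half

    edge <- ifelse(stats::runif(nrow(cand)) < 0.5, cand$start_bp,
                   cand$end_bp)
    off <- sample.int(near_bp, nrow(cand), replace = TRUE) *
      ifelse(stats::runif(nrow(cand)) < 0.5, -1, 1)
    snps <- data.frame(
      snp_name = sprintf("SIMS%03d", seq_len(nrow(cand))),
      chrom = cand$chrom,
      pos_bp = pmin(pmax(edge + off, 1), chrom_len),
      traits = vapply(seq_len(nrow(cand)), function(i)
        paste(sample(trait_codes(), sample.int(3, 1)), collapse = ","), ""),
      p_min = rep(NA_real_, nrow(cand)),
      p_max = rep(NA_real_, nrow(cand)), stringsAsFactors = FALSE)
    pm <- 10^stats::runif(nrow(cand), -20, -8)
    snps$p_min <- pm
    snps$p_max <- pmin(pm * 10^stats::runif(nrow(cand), 0, 6), 1)

    # decoys: exact sampling outside 2x-threshold windows around DE genes
    for (d in seq_len(n_decoys)) {
      ch <- as.character(sample.int(genome$params$n_chrom, 2, replace = TRUE))
      sub <- de[de$chrom == ch[1], , drop = FALSE]
      iv <- allowed_intervals(sub$start_bp - 2 * max_bp,
                              sub$end_bp + 2 * max_bp, chrom_len)
      if (nrow(iv) == 0) {
        stop("no room for a decoy SNP outside 2x the screening window",
             call. = FALSE)
      }
      pos <- sample_from_intervals(iv, 1)
      pmn <- 10^stats::runif(1, -12, -8)
      snps <- rbind(snps, data.frame(
        snp_name = sprintf("DECS%03d", d), chrom = ch[1], pos_bp = pos,
        traits = paste(sample(trait_codes(), sample.int(3, 1)),
                       collapse = ","),
        p_min = pmn, p_max = pmin(pmn * 10, 1), stringsAsFactors = FALSE))

      sub <- de[de$chrom == ch[2], , drop = FALSE]
      map_sub <- genome$map[genome$map$chrom == ch[2], , drop = FALSE]
      cm_max <- max(map_sub$cm)
      # work on a 0.001 cM integer grid for exact interval arithmetic
      grid <- 1000
      iv <- allowed_intervals(floor((sub$linkage_cm - 2 * max_cm) * grid),
                              ceiling((sub$linkage_cm + 2 * max_cm) * grid),
                              floor(cm_max * grid))
      if (nrow(iv) == 0) {
        stop("no room for a decoy QTL outside 2x the screening window",
             call. = FALSE)
      }
      peak <- sample_from_intervals(iv, 1) / grid
      half <- stats::runif(1, 2, 10)
      qtls <- rbind(qtls, data.frame(
        qtl_id = sprintf("DECQ%03d", d),
        trait = sample(trait_codes(), 1), chrom = ch[2],
        ci_lo_cm = max(peak - half, 0), ci_hi_cm = peak + half,
        peak_cm = peak, stringsAsFactors = FALSE))
    }
    rownames(qtls) <- rownames(snps) <- NULL
    list(qtls = qtls, snps = snps,
         planted_candidates = sort(cand$gene),
         params = list(seed = seed, n_candidate_target = n_candidate_target,
                       near_cm = near_cm, near_bp = near_bp,
                       n_decoys = n_decoys, max_cm = max_cm,
                       max_bp = max_bp))
  })
}

#' Simulate a complete ground-truthed study
#'
#' One call producing every input the screen consumes — genome, genetic
#' map, per-comparison differential-expression tables, replicate FPKM
#' matrix, QTL and SNP catalogues — together with the planted truth. A
#' single master seed drives all three stages through a fixed splitting
#' scheme, so each stage is individually reproducible. With `out_dir`
#' set, all inputs are also written in their file dialects (Cuffdiff
#' tables, BED genes, map/QTL/SNP TSVs) along with a `manifest.txt` of
#' parameters and the planted truth.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional directory to write the file dialects to.
#' @param ... Parameters forwarded to [simulate_genome()]
#'   (`n_chrom`, `chrom_len_bp`, `n_genes`, `gene_len_range`),
#'   [simulate_expression()] (`n_de_per_comparison`, `de_pool_size`,
#'   `lfc_range`, `frac_inf`, `sigma`) and [simulate_catalogues()]
#'   (`n_candidate_target`, `near_cm`, `near_bp`, `n_decoys`, `max_cm`,
#'   `max_bp`).
#' @return List with `genome`, `expression`, `catalogues`,
#'   `planted_candidates` and `files` (paths, when written).
#' @export
#' @examples
#' study <- simulate_study(seed = 7, n_genes = 60, n_candidate_target = 4,
#'                         n_decoys = 5)
#' study$planted_candidates
simulate_study <- function(seed, out_dir = NULL, ...) {
  dots <- list(...)
  pick <- function(fn) dots[names(dots) %in% names(formals(fn))]
  genome <- do.call(simulate_genome,
                    c(list(seed = seed), pick(simulate_genome)))
  expr <- do.call(simulate_expression,
                  c(list(genome = genome, seed = seed),
                    pick(simulate_expression)))
  cats <- do.call(simulate_catalogues,
                  c(list(genome = genome, truth = expr$truth, seed = seed),
                    pick(simulate_catalogues)))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(genes = file.path(out_dir, "genes.bed"),
               map = file.path(out_dir, "genetic_map.tsv"),
               qtls = file.path(out_dir, "qtls.tsv"),
               snps = file.path(out_dir, "snps.tsv"),
               manifest = file.path(out_dir, "manifest.txt"))
    write_gene_features(genome$genes, files["genes"], "bed")
    write_genetic_map(genome$map, files["map"])
    write_qtl_table(cats$qtls, files["qtls"])
    write_snp_table(cats$snps, files["snps"])
    for (comp in names(expr$tables)) {
      f <- file.path(out_dir, paste0("deg_", tolower(comp), ".diff"))
      write_deg_table(expr$tables[[comp]], f, dialect = "cuffdiff")
      files[paste0("deg_", comp)] <- f
    }
    params <- c(genome$params, expr$params[-1], cats$params[-1])
    manifest <- c(
      "candgene synthetic study manifest",
      sprintf("param %s = %s", names(params),
              vapply(params, function(p) paste(p, collapse = ","), "")),
      sprintf("planted_candidate %s", cats$planted_candidates),
      sprintf("planted_de %s %s %+d", expr$truth$gene,
              expr$truth$comparison, expr$truth$sign))
    writeLines(manifest, files["manifest"])
  }
  list(genome = genome, expression = expr, catalogues = cats,
       planted_candidates = cats$planted_candidates, files = files)
}
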