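test_that("the generator is deterministic in its seed", {
  a <- small_study(41)
  b <- small_study(41)
  expect_identical(a$genome, b$genome)
  expect_identical(a$expression, b$expression)
  expect_identical(a$catalogues, b$catalogues)
  c <- small_study(42)
  expect_false(identical(a$genome$genes, c$genome$genes))
})

test_that("simulated genomes respect every feature invariant", {
  g <- simulate_genome(seed = 5, n_chrom = 5, chrom_len_bp = 2e7,
                       n_genes = 100)
  expect_equal(nrow(g$genes), 100)
  expect_true(all(g$genes$start_bp >= 1))
  expect_true(all(g$genes$end_bp >= g$genes$start_bp))
  expect_true(all(g$genes$end_bp <= 2e7))
  # non-overlap within chromosome
  for (ch in unique(g$genes$chrom)) {
    sub <- g$genes[g$genes$chrom == ch, ]
    sub <- sub[order(sub$start_bp), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start_bp[-1] > sub$end_bp[-nrow(sub)]))
    }
  }
  expect_error(simulate_genome(seed = 1, n_chrom = 1, chrom_len_bp = 1e4,
                               n_genes = 50),
               "infeasible packing")
})

test_that("simulated maps are monotone across many seeds", {
  for (seed in 1:200) {
    g <- simulate_genome(seed = seed, n_chrom = 2, chrom_len_bp = 5e6,
                         n_genes = 2)
    for (ch in unique(g$map$chrom)) {
      sub <- g$map[g$map$chrom == ch, ]
      expect_true(all(diff(sub$bp) > 0) && all(diff(sub$cm) >= 0),
                  label = paste("seed", seed))
    }
  }
})

test_that("planted DE genes are exactly recovered without the rank filter", {
  study <- small_study(43)
  for (comp in names(study$expression$tables)) {
    tab <- study$expression$tables[[comp]]
    sel <- select_degs(tab, expression_quantile = 0)
    truth <- study$expression$truth
    expect_setequal(sel$table$gene,
                    truth$gene[truth$comparison == comp])
    # and with the default top-half filter too, by construction
    sel2 <- select_degs(tab)
    expect_setequal(sel2$table$gene, truth$gene[truth$comparison == comp])
    # planted signs match directions
    dir <- ifelse(truth$sign[truth$comparison == comp] > 0, "UP", "DOWN")
    expect_equal(sel2$table$direction[match(truth$gene[truth$comparison == comp],
                                            sel2$table$gene)], dir)
  }
})

test_that("zero planted DE genes yield empty selections", {
  g <- simulate_genome(seed = 3, n_chrom = 3, chrom_len_bp = 2e7,
                       n_genes = 40)
  e <- simulate_expression(g, seed = 3, n_de_per_comparison = 0,
                           de_pool_size = 5)
  sel <- select_degs(e$tables[[1]], expression_quantile = 0)
  expect_equal(nrow(sel$table), 0)
})

test_that("decoys never enter any match list (post-hoc brute force)", {
  study <- small_study(44)
  genes <- suppressWarnings(
    gene_linkage_position(study$genome$genes, study$genome$map))
  de_genes <- genes[genes$gene %in% unique(study$expression$truth$gene), ]
  qtls <- study$catalogues$qtls
  snps <- study$catalogues$snps
  dq <- qtls[grepl("^DECQ", qtls$qtl_id), ]
  ds <- snps[grepl("^DECS", snps$snp_name), ]
  expect_gt(nrow(dq), 0)
  for (i in seq_len(nrow(de_genes))) {
    same_q <- dq[dq$chrom == de_genes$chrom[i], ]
    if (nrow(same_q)) {
      expect_true(all(abs(de_genes$linkage_cm[i] - same_q$peak_cm) >= 10))
    }
    same_s <- ds[ds$chrom == de_genes$chrom[i], ]
    if (nrow(same_s)) {
      d <- gene_snp_distance(de_genes$start_bp[i], de_genes$end_bp[i],
                             same_s$pos_bp)
      expect_true(all(d >= 1e7))
    }
  }
})

test_that("the pipeline recovers planted candidates exactly at study scale", {
  for (seed in 101:130) {
    study <- simulate_study(seed = seed)
    scr <- suppressWarnings(screen_candidates(
      study$expression$deg, study$genome$genes, study$catalogues$qtls,
      study$catalogues$snps, map = study$genome$map))
    expect_identical(candidate_genes(scr), study$planted_candidates,
                     label = paste("seed", seed))
  }
})

test_that("generated files pass their own readers' validation", {
  dir <- withr::local_tempdir()
  study <- simulate_study(seed = 45, out_dir = dir, n_chrom = 6,
                          chrom_len_bp = 80e6, n_genes = 80,
                          n_de_per_comparison = 6, de_pool_size = 8,
                          n_candidate_target = 4, n_decoys = 10)
  genes <- read_gene_features(study$files[["genes"]], "bed")
  genes <- genes[order(genes$gene), c("gene", "chrom", "start_bp", "end_bp")]
  rownames(genes) <- NULL
  expect_identical(genes,
                   study$genome$genes[c("gene", "chrom", "start_bp", "end_bp")])
  expect_identical(read_genetic_map(study$files[["map"]]), study$genome$map)
  expect_identical(read_qtl_table(study$files[["qtls"]]),
                   study$catalogues$qtls)
  expect_identical(read_snp_table(study$files[["snps"]]),
                   study$catalogues$snps)
  deg <- read_deg_table(study$files[["deg_EARLY_VS_DRY"]], "cuffdiff")
  expect_identical(deg, study$expression$tables[["EARLY_VS_DRY"]])
  expect_true(file.exists(study$files[["manifest"]]))
})
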