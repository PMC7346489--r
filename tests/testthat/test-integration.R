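printed <- load_printed_evidence()

test_that("the printed evidence yields exactly the ten published candidates", {
  scr <- screen_candidates(printed$deg_evidence, printed$genes,
                           printed$qtls, printed$snps)
  expect_equal(candidate_genes(scr),
               sort(c("APOC2", "PPP1R3B", "PKLR", "ODC1", "DUSP1", "LMNA",
                      "GALE", "ANGPTL4", "LPIN1", "CDKN1A")))
  # ACADVL has QTL but no SNP support and must not be a candidate
  expect_true("ACADVL" %in% scr$qtl_matches$gene)
  expect_false("ACADVL" %in% candidate_genes(scr))
  # evidence channel sizes mirror the published tables
  expect_equal(unname(scr$counts["n_qtl_matched"]), 11)
  expect_equal(unname(scr$counts["n_snp_matched"]), 22)
})

test_that("trait summaries are the union over both evidence channels", {
  scr <- screen_candidates(printed$deg_evidence, printed$genes,
                           printed$qtls, printed$snps)
  apoc2 <- scr$candidates[["APOC2"]]
  expect_setequal(summarize_traits(apoc2), c("MY", "PY", "FY", "PP", "FP"))
  # brute-force union oracle on every candidate
  for (rec in scr$candidates) {
    manual <- unique(c(rec$qtl$trait,
                       unlist(strsplit(rec$snp$traits, ","))))
    expect_setequal(rec$traits, manual)
  }
  # synthetic single-trait candidate
  one <- list(qtl = data.frame(trait = "FY"),
              snp = data.frame(traits = character(0)))
  expect_equal(summarize_traits(one), "FY")
})

test_that("candidates are exactly the three-way intersection", {
  study <- small_study(31)
  scr <- suppressWarnings(screen_candidates(
    study$expression$deg, study$genome$genes, study$catalogues$qtls,
    study$catalogues$snps, map = study$genome$map))
  cand <- candidate_genes(scr)
  manual <- intersect(intersect(unique(scr$evidence$gene),
                                unique(scr$qtl_matches$gene)),
                      unique(scr$snp_matches$gene))
  expect_setequal(cand, manual)
  expect_true(all(cand %in% scr$evidence$gene))
})

test_that("removing either evidence channel removes the candidate", {
  study <- small_study(32)
  scr <- suppressWarnings(screen_candidates(
    study$expression$deg, study$genome$genes, study$catalogues$qtls,
    study$catalogues$snps, map = study$genome$map))
  expect_gt(length(scr$candidates), 0)
  g <- candidate_genes(scr)[1]
  no_qtl <- integrate_evidence(scr$evidence,
                               scr$qtl_matches[scr$qtl_matches$gene != g, ],
                               scr$snp_matches)
  no_snp <- integrate_evidence(scr$evidence, scr$qtl_matches,
                               scr$snp_matches[scr$snp_matches$gene != g, ])
  expect_false(g %in% names(no_qtl))
  expect_false(g %in% names(no_snp))
})

test_that("matches for unselected genes are a consistency error", {
  ev <- data.frame(gene = "a", comparison = "EARLY_VS_DRY", direction = "UP")
  qm <- empty <- screen_candidates(ev,
    gene_features("a", "1", 1, 2, 5),
    printed$qtls[0, ], printed$snps[0, ])  # no matches at all: fine
  expect_length(empty$candidates, 0)
  stray_qtl <- data.frame(gene = "ghost", qtl_id = "1", trait = "MY",
                          chrom = "1", gene_cm = 1, peak_cm = 1,
                          distance_cm = 0, within_ci = TRUE, ci_lo_cm = 0,
                          ci_hi_cm = 2, stringsAsFactors = FALSE)
  expect_error(integrate_evidence(ev, stray_qtl, printed$snps[0, ]),
               "absent from every DEG selection")
})

test_that("empty selections give an empty candidate list", {
  ev <- data.frame(gene = character(), comparison = character(),
                   direction = character(), stringsAsFactors = FALSE)
  scr <- screen_candidates(ev, printed$genes, printed$qtls, printed$snps)
  expect_length(scr$candidates, 0)
})

test_that("integration is monotone in every threshold", {
  study <- small_study(33)
  base <- screen_control()
  run <- function(ctl) suppressWarnings(candidate_genes(
    screen_candidates(study$expression$deg, study$genome$genes,
                      study$catalogues$qtls, study$catalogues$snps,
                      map = study$genome$map, control = ctl)))
  full <- run(base)
  tighter <- list(screen_control(q_max = 0.01),
                  screen_control(expression_quantile = 0.9),
                  screen_control(max_cm = 0.5),
                  screen_control(max_bp = 5e4))
  for (ctl in tighter) {
    expect_true(all(run(ctl) %in% full))
  }
  looser <- list(screen_control(q_max = 0.5),
                 screen_control(expression_quantile = 0),
                 screen_control(max_cm = 20),
                 screen_control(max_bp = 2e7))
  for (ctl in looser) {
    expect_true(all(full %in% run(ctl)))
  }
})

test_that("the keep-list prunes after positional integration, visibly", {
  scr <- screen_candidates(printed$deg_evidence, printed$genes,
                           printed$qtls, printed$snps,
                           keep = c("APOC2", "ODC1"))
  expect_equal(candidate_genes(scr), c("APOC2", "ODC1"))
  expect_length(scr$dropped_by_keep, 8)
})

test_that("screen methods print, summarize and flatten coherently", {
  scr <- screen_candidates(printed$deg_evidence, printed$genes,
                           printed$qtls, printed$snps)
  expect_output(print(scr), "candidates \\(all three lines of evidence\\): 10")
  sm <- summary(scr)
  expect_equal(nrow(sm$table), 10)
  expect_output(print(sm), "APOC2")
  flat <- as.data.frame(scr)
  # the report carries matches for candidate genes only
  expect_equal(sum(flat$evidence_type == "QTL"),
               sum(scr$qtl_matches$gene %in% candidate_genes(scr)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(scr))
})
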