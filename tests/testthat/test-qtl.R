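test_that("cM distance matches the published worked values", {
  expect_equal(cm_distance(67.9, 66), 1.9)
  expect_equal(round_trip <- cm_distance(95.0, 94.9), 0.1, tolerance = 1e-12)
  expect_equal(cm_distance(47.1, 43.1), 4.0)
  expect_equal(cm_distance(12.3, 12.3), 0)
  expect_error(cm_distance(Inf, 1), "finite")
})

test_that("cM distance is a metric: symmetric, triangle inequality", {
  set.seed(5)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100); z <- runif(60, 0, 100)
  expect_equal(cm_distance(x, y), cm_distance(y, x))
  expect_true(all(cm_distance(x, z) <= cm_distance(x, y) + cm_distance(y, z) + 1e-12))
  expect_true(all(cm_distance(x, y) >= 0))
})

test_that("CI membership is inclusive at both endpoints", {
  qtl <- data.frame(ci_lo_cm = 54.713, ci_hi_cm = 76.57)
  expect_true(flag_within_ci(67.9, qtl))
  expect_true(flag_within_ci(76.57, qtl))
  expect_true(flag_within_ci(54.713, qtl))
  expect_false(flag_within_ci(67.9, data.frame(ci_lo_cm = 70, ci_hi_cm = 80)))
})

test_that("QTL matching applies the strict window on the same chromosome", {
  genes <- gene_features(c("ACADVL", "FAR"), c("19", "19"),
                         c(100, 200), c(200, 300),
                         linkage_cm = c(47.1, 5.0))
  qtls <- data.frame(qtl_id = c("10443", "Q2", "Q3"), trait = "FY",
                     chrom = c("19", "19", "2"),
                     ci_lo_cm = c(14.1, 0, 0), ci_hi_cm = c(60.4, 50, 50),
                     peak_cm = c(43.1, 10.0, 47.1), stringsAsFactors = FALSE)
  m <- match_qtls(genes, qtls)
  acadvl <- m[m$gene == "ACADVL", ]
  expect_equal(nrow(acadvl), 1)  # Q3 is on another chromosome
  expect_equal(acadvl$distance_cm, 4.0)
  expect_true(acadvl$within_ci)
  # exactly at the window: excluded strictly, included with strict = FALSE
  far <- m[m$gene == "FAR", ]
  expect_equal(nrow(far), 0)
  m2 <- match_qtls(genes, qtls, strict = FALSE)
  expect_equal(m2$qtl_id[m2$gene == "FAR"], "Q2")
  expect_error(match_qtls(gene_features("u", "1", 1, 2), qtls),
               "unresolved linkage_cm")
})

test_that("matching equals a brute-force all-pairs scan on random instances", {
  set.seed(99)
  n_genes <- 40; n_qtls <- 200
  genes <- gene_features(sprintf("g%02d", 1:n_genes),
                         sample(as.character(1:5), n_genes, replace = TRUE),
                         1:n_genes * 10, 1:n_genes * 10 + 5,
                         linkage_cm = runif(n_genes, 0, 100))
  qtls <- data.frame(qtl_id = sprintf("q%03d", 1:n_qtls),
                     trait = sample(trait_codes(), n_qtls, replace = TRUE),
                     chrom = sample(as.character(1:5), n_qtls, replace = TRUE),
                     peak_cm = runif(n_qtls, 0, 100),
                     stringsAsFactors = FALSE)
  qtls$ci_lo_cm <- qtls$peak_cm - runif(n_qtls, 1, 10)
  qtls$ci_hi_cm <- qtls$peak_cm + runif(n_qtls, 1, 10)
  m <- match_qtls(genes, qtls, max_cm = 5)
  brute <- expand.grid(g = seq_len(n_genes), q = seq_len(n_qtls))
  brute$same <- genes$chrom[brute$g] == qtls$chrom[brute$q]
  brute$d <- abs(genes$linkage_cm[brute$g] - qtls$peak_cm[brute$q])
  brute <- brute[brute$same & brute$d < 5, ]
  expect_equal(nrow(m), nrow(brute))
  expect_setequal(paste(m$gene, m$qtl_id),
                  paste(genes$gene[brute$g], qtls$qtl_id[brute$q]))
  expect_true(all(m$distance_cm < 5))
  # within_ci agrees with the direct inclusion check
  expect_equal(m$within_ci, m$ci_lo_cm <= m$gene_cm & m$gene_cm <= m$ci_hi_cm)
  # sorted ascending by distance within gene
  expect_true(all(tapply(m$distance_cm, m$gene, function(d) all(diff(d) >= 0))))
})

test_that("matching is monotone in the window size", {
  set.seed(100)
  genes <- gene_features("g", "1", 10, 20, linkage_cm = 50)
  qtls <- data.frame(qtl_id = as.character(1:50), trait = "MY", chrom = "1",
                     peak_cm = runif(50, 0, 100), stringsAsFactors = FALSE)
  qtls$ci_lo_cm <- qtls$peak_cm - 1
  qtls$ci_hi_cm <- qtls$peak_cm + 1
  prev <- character()
  for (w in c(1, 2, 5, 20, 60)) {
    got <- match_qtls(genes, qtls, max_cm = w)$qtl_id
    expect_true(all(prev %in% got))
    prev <- got
  }
})
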