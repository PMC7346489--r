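test_that("expression level is the arithmetic mean of condition FPKMs", {
  expect_equal(expression_level(0, 0), 0)
  expect_equal(expression_level(2, 4), 3)
  set.seed(42)
  a <- rlnorm(100); b <- rlnorm(100)
  # ranking matches an independently computed mean
  expect_equal(order(expression_level(a, b)),
               order(vapply(seq_along(a), function(i) mean(c(a[i], b[i])), 0)))
  expect_error(expression_level(-1, 0), "non-negative")
})

test_that("selection applies strict q and the expression-rank filter", {
  deg <- random_deg_table(n = 200, n_sig = 40, seed = 7)
  deg$q_value[1] <- 0.05  # exactly at the threshold: must be excluded
  sel <- select_degs(deg, q_max = 0.05, expression_quantile = 0.5)
  expect_false(deg$gene[1] %in% sel$table$gene)
  # brute-force oracle: explicit loop over rows
  expr <- (deg$fpkm_a + deg$fpkm_b) / 2
  med <- sort(expr)[c(100, 101)]  # type-7 median of 200 values
  cutoff <- mean(med)
  manual <- deg$gene[deg$q_value < 0.05 & expr >= cutoff & deg$log2fc != 0]
  expect_setequal(sel$table$gene, manual)
  # direction by sign of log2fc
  expect_equal(sel$table$direction, ifelse(sel$table$log2fc > 0, "UP", "DOWN"))
})

test_that("high-expression significant genes select as UP", {
  deg <- random_deg_table(n = 20, n_sig = 0, seed = 8)
  deg$q_value[1] <- 0.004690
  deg$fpkm_a[1] <- 1.5; deg$fpkm_b[1] <- 71.2
  deg$log2fc[1] <- 5.57
  sel <- select_degs(deg)
  expect_true("T001" %in% sel$table$gene)
  expect_equal(unname(sel$table$direction[sel$table$gene == "T001"]), "UP")
})

test_that("selection is monotone in q_max and conserves counts", {
  deg <- random_deg_table(n = 300, n_sig = 60, seed = 9)
  deg$q_value <- runif(300)  # spread thresholds
  prev <- character()
  for (qm in c(0.01, 0.05, 0.2, 0.8)) {
    sel <- select_degs(deg, q_max = qm)
    expect_true(all(prev %in% sel$table$gene))
    expect_equal(sel$n_up + sel$n_down, nrow(sel$table))
    prev <- sel$table$gene
  }
})

test_that("quantile zero reduces selection to the pure q filter", {
  deg <- random_deg_table(n = 150, n_sig = 30, seed = 10)
  sel <- select_degs(deg, expression_quantile = 0)
  expect_setequal(sel$table$gene, deg$gene[deg$q_value < 0.05])
})

test_that("infinite fold changes are kept and classified by sign", {
  deg <- random_deg_table(n = 50, n_sig = 10, seed = 11)
  deg$fpkm_a[1] <- 0; deg$fpkm_b[1] <- 500; deg$log2fc[1] <- Inf
  deg$q_value[1] <- 0.001
  deg$fpkm_b[2] <- 0; deg$fpkm_a[2] <- 400; deg$log2fc[2] <- -Inf
  deg$q_value[2] <- 0.001
  sel <- select_degs(deg)
  dir <- sel$table$direction[match(c("T001", "T002"), sel$table$gene)]
  expect_equal(dir, c("UP", "DOWN"))
})

test_that("a significant gene with zero fold change is excluded, not an error", {
  deg <- random_deg_table(n = 30, n_sig = 5, seed = 12)
  deg$log2fc[1] <- 0; deg$q_value[1] <- 0.001
  deg$fpkm_b[1] <- deg$fpkm_a[1] <- max(deg$fpkm_a)
  expect_message(sel <- select_degs(deg), "log2fc = 0")
  expect_false("T001" %in% sel$table$gene)
})

test_that("mixed comparisons are a precondition error", {
  deg <- rbind(random_deg_table(10, "EARLY_VS_DRY", seed = 1),
               random_deg_table(10, "PEAK_VS_DRY", seed = 2))
  expect_error(select_degs(deg), "mix")
})

test_that("replicate QC flags perfect and broken correlation", {
  m <- matrix(rlnorm(300, 2, 1), ncol = 3)
  m[, 2] <- m[, 1]
  qc <- qc_replicate_correlation(m)
  expect_equal(qc$r[1, 2], 1.0)
  # anticorrelated after log transform: reverse the profile
  m2 <- cbind(m[, 1], rev(m[, 1]))
  qc2 <- qc_replicate_correlation(m2, min_r = 0.935)
  expect_false(qc2$pass)
  # zero-variance replicate is a failed pair, not an error
  m3 <- cbind(m[, 1], rep(1, 100))
  qc3 <- qc_replicate_correlation(m3)
  expect_false(qc3$pass)
  expect_true(is.na(qc3$r[1, 2]))
})

test_that("lognormal replicates at sigma 0.2 pass the published QC bar", {
  study <- small_study(21)
  fpkm <- study$expression$fpkm
  for (stage in c("DRY", "EARLY", "PEAK")) {
    qc <- qc_replicate_correlation(fpkm[, grep(stage, colnames(fpkm))])
    expect_true(qc$pass, label = stage)
    expect_true(all(qc$r[upper.tri(qc$r)] > 0.9))
  }
})
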