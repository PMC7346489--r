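# Shared builders for randomized fixtures (all under explicit seeds).

# A small random DEG table for one comparison, with planted significant genes.
random_deg_table <- function(n = 50, comparison = "EARLY_VS_DRY",
                             n_sig = 10, seed = 1) {
  set.seed(seed)
  fpkm_a <- rlnorm(n, 2, 1)
  fpkm_b <- fpkm_a * 2^runif(n, -3, 3)
  q <- c(runif(n_sig, 0, 0.049), runif(n - n_sig, 0.05, 1))
  data.frame(gene = sprintf("T%03d", seq_len(n)), comparison = comparison,
             chrom = sample(as.character(1:3), n, replace = TRUE),
             start_bp = s <- sort(sample.int(1e6, n)),
             end_bp = s + sample.int(1e4, n),
             fpkm_a = fpkm_a, fpkm_b = fpkm_b,
             log2fc = log2(fpkm_b / fpkm_a),
             p_value = q * runif(n, 0.01, 1), q_value = q,
             stringsAsFactors = FALSE)
}

# A random monotone genetic map over `n_chrom` chromosomes.
random_map <- function(n_chrom = 3, n_markers = 20, len = 1e7, seed = 1) {
  set.seed(seed)
  genetic_map(do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(chrom = as.character(ch),
               bp = sort(sample.int(len, n_markers)),
               cm = cumsum(runif(n_markers, 0, 2)),
               stringsAsFactors = FALSE)
  })))
}

# A compact synthetic study for end-to-end tests (fast, guaranteed feasible).
small_study <- function(seed) {
  simulate_study(seed = seed, n_chrom = 6, chrom_len_bp = 80e6,
                 n_genes = 80, n_de_per_comparison = 6, de_pool_size = 8,
                 n_candidate_target = 4, n_decoys = 10)
}
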