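# Shared fixtures, built in code at test time.

# small map + LD for unit tests
small_sim <- function(seed = 42, n_snps = 600, block = 5, r2 = 0.8) {
  sim_config(seed = seed, n_snps = n_snps, ld_block_size = block,
             ld_r2 = r2, n_genes = 30, n_traits = 4,
             n_instruments_per_trait = 12, n_reverse_hits = 15,
             n_contexts = 5, context_size = 50, n_query = 20)
}

# deterministic harmonised instrument table with a known causal slope
make_instruments <- function(n = 50, slope = 0.3, seed = 7,
                             se_exp = 0.02, se_out = 0.01,
                             pleio_sd = 0) {
  set.seed(seed)
  beta_exp_true <- runif(n, 0.1, 0.3) * sample(c(-1, 1), n, TRUE)
  beta_exp <- beta_exp_true + rnorm(n, 0, se_exp)
  alpha <- if (pleio_sd > 0) rnorm(n, 0, pleio_sd) else 0
  beta_out <- slope * beta_exp_true + alpha + rnorm(n, 0, se_out)
  data.frame(snp = sprintf("snp%03d", seq_len(n)),
             beta_exp = beta_exp, se_exp = se_exp,
             eaf_exp = runif(n, 0.1, 0.9),
             beta_out = beta_out, se_out = se_out,
             eaf_out = runif(n, 0.1, 0.9),
             f_stat = (beta_exp / se_exp)^2,
             stringsAsFactors = FALSE)
}

# the published blood-eQTL SMR table shipped with the package
published_smr <- function() {
  path <- system.file("extdata", "blood_smr_published.tsv",
                      package = "gibaxis")
  read.delim(path, stringsAsFactors = FALSE)
}

# tolerance of one unit in the last printed significant digit
printed_tol <- function(x, sig = 5) 10^(floor(log10(abs(x))) - sig + 1)

# brute-force clumping audit: greedy over ascending p, pairwise rule
# checked exhaustively (independent of the package implementation)
brute_clump <- function(records, ld, r2_threshold, window_kb, p_threshold) {
  cand <- records[records$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos, cand$snp), , drop = FALSE]
  r2_of <- function(a, b) {
    hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
    if (any(hit)) ld$r2[which(hit)[1]] else 0
  }
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      same <- cand$chrom[i] == cand$chrom[j]
      near <- abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      cor2 <- r2_of(cand$snp[i], cand$snp[j]) >= r2_threshold
      if (same && near && cor2) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(cand$snp[kept])
}

# exhaustive hypergeometric upper tail by enumerating all draws
enum_hyper_tail <- function(m, n, r, k) {
  if (k == 0) return(1)
  items <- c(rep(1, m), rep(0, n))
  draws <- combn(m + n, r)
  mean(colSums(matrix(items[draws], nrow = r)) >= k)
}

# hand step-up BH, independent of stats::p.adjust
hand_bh <- function(p) {
  M <- length(p)
  ord <- order(p)
  adj <- rev(cummin(rev(M * p[ord] / seq_len(M))))
  pmin(adj, 1)[order(ord)]
}
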