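test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(10, 100, 5, 0), 1)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 2), 1 / 6)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 1), 5 / 6)

  # full lattice sweep for m + n <= 12 against the enumeration oracle
  for (m in 0:6) for (n in 0:6) for (r in 0:(m + n)) for (k in 0:min(m, r)) {
    expect_equal(hypergeom_upper_tail(m, n, r, k),
                 enum_hyper_tail(m, n, r, k), tolerance = 1e-12,
                 info = sprintf("m=%d n=%d r=%d k=%d", m, n, r, k))
  }
  expect_error(hypergeom_upper_tail(2, 2, 2, 3), "exceed")
  # stable for genome-scale backgrounds
  p <- hypergeom_upper_tail(47, 1e7 - 47, 5e5, 30)
  expect_true(is.finite(p) && p > 0 && p < 1)
})

test_that("BH adjustment matches the hand step-up and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "0,1")

  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), hand_bh(p), tolerance = 1e-12)
    # order invariance
    ord <- sample(length(p))
    expect_equal(bh_adjust(p[ord]), bh_adjust(p)[ord], tolerance = 1e-12)
    # monotonicity: raising one raw p never lowers any adjusted p
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- min(1, p2[j] + runif(1, 0, 1 - p2[j]))
    expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  }
})

test_that("BH over the published SMR p-values reproduces the printed FDR column", {
  tab <- published_smr()
  tab <- tab[!duplicated(tab$probeID), ]      # 25 unique probes
  expect_equal(nrow(tab), 25L)
  adj <- bh_adjust(tab$p_SMR)
  # every cell agrees to the shown significant figures, allowing the
  # source's own last-digit rounding (2 units in the last printed digit)
  expect_true(all(abs(adj - tab$FDR_BH) <= 2 * printed_tol(tab$FDR_BH)))
  # the rank-1/2 pair and the shared rank-6 group agree to the last digit
  key <- adj[tab$FDR_BH %in% c(9.4858e-08, 1.9033e-07, 8.82e-05)]
  key_fdr <- tab$FDR_BH[tab$FDR_BH %in% c(9.4858e-08, 1.9033e-07, 8.82e-05)]
  expect_true(all(abs(key - key_fdr) <= printed_tol(key_fdr)))
  # the two smallest share the printed adjusted value 9.4858e-08
  expect_equal(sort(adj)[1:2], rep(25 * 7.5886e-09 / 2, 2),
               tolerance = 1e-10)
})

test_that("context enrichment counts overlaps and flags the planted context", {
  q <- paste0("q", 1:47)
  bg <- 1e5
  ctx <- list(hit = c(q[1:6], paste0("x", 1:294)),
              miss = paste0("y", 1:300),
              weak = c(q[1], paste0("z", 1:299)))
  res <- enrich_contexts(q, ctx, bg)
  expect_equal(res$k, c(6, 0, 1))
  expect_equal(res$p[res$context == "miss"], 1)
  expect_equal(res$p[res$context == "hit"],
               hypergeom_upper_tail(47, bg - 47, 300, 6))
  expect_equal(which.min(res$p), which(res$context == "hit"))
  expect_true(all(res$p_adj >= res$p))
  ef <- res$enrichment_factor[res$context == "hit"]
  expect_equal(ef, 6 / (300 * 47 / bg))
  expect_error(enrich_contexts(q, ctx, 100), "smaller")

  # planted synthetic layout: the forced-overlap context attains min p
  cfg <- small_sim(seed = 17, n_snps = 5000, block = 1)
  sc <- sim_contexts_and_genesets(cfg)
  res2 <- enrich_contexts(sc$query, sc$contexts, 1e7)
  expect_equal(res2$k, sc$planted_overlaps)
  expect_equal(res2$context[which.min(res2$p)], "context01")
})

test_that("context p-values are super-uniform under random query sets", {
  set.seed(41)
  universe <- sprintf("u%05d", 1:2000)
  ctx <- list(c1 = sample(universe, 200))
  n_rep <- 3000
  pv <- replicate(n_rep, {
    q <- sample(universe, 40)
    k <- length(intersect(q, ctx$c1))
    hypergeom_upper_tail(40, 1960, 200, k)
  })
  ecdf05 <- mean(pv <= 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(ecdf05, 0.05 + 2 * mc_se)
})

test_that("GMT over-representation mirrors the context statistic on genes", {
  # query entirely inside a 10-gene set of a 50-gene universe
  gl <- paste0("GENE", 1:5)
  sets <- list(inside = paste0("GENE", 1:10),
               outside = paste0("GENE", 40:49))
  res <- ora_gmt(gl, sets, universe_size = 50)
  # direct-sum oracle: P(all 5 query genes land in the 10-gene set)
  direct <- sum(choose(10, 5) * choose(40, 0)) / choose(50, 5)
  expect_equal(res$p[res$set == "inside"], direct, tolerance = 1e-12)
  expect_equal(res$k[res$set == "outside"], 0)
  expect_equal(res$p[res$set == "outside"], 1)

  # set equal to the whole universe draws everything: certain event
  all50 <- paste0("GENE", 1:50)
  expect_equal(ora_gmt(gl, list(all = all50), 50)$p, 1)
  # empty query: all p = 1
  expect_true(all(ora_gmt(character(0), sets, 50)$p == 1))
  expect_error(ora_gmt(gl, sets, 0), "universe")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("G1", "G2", "G3"))
  expect_equal(sets$setB, "G9")
})
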