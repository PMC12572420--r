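test_that("fixed-effects pooling matches hand arithmetic and identities", {
  fe <- fixed_effects(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(fe$beta, 0.2)
  expect_equal(fe$se, 0.1 / sqrt(2))

  one <- fixed_effects(0.05, 0.02)
  expect_equal(one$beta, 0.05)
  expect_equal(one$se, 0.02)

  const <- fixed_effects(c(0.2, 0.2, 0.2), c(0.05, 0.2, 0.01))
  expect_equal(const$beta, 0.2)

  expect_error(fixed_effects(numeric(0), numeric(0)), "no studies")
})

test_that("heterogeneity statistics match hand evaluation", {
  h <- heterogeneity(c(0.1, 0.3), c(0.1, 0.1), 0.2)
  expect_equal(h$q_stat, 2)
  expect_equal(h$i2, 50)
  expect_equal(h$q_p, pchisq(2, 1, lower.tail = FALSE))

  h0 <- heterogeneity(c(0.2, 0.2), c(0.1, 0.1), 0.2)
  expect_equal(h0$q_stat, 0)
  expect_equal(h0$i2, 0)

  h8 <- heterogeneity(c(0, 0.4), c(0.1, 0.1), 0.2)
  expect_equal(h8$q_stat, 8)
  expect_equal(h8$i2, 87.5)

  h1 <- heterogeneity(0.1, 0.1, 0.1)
  expect_true(is.na(h1$q_stat))
  expect_equal(h1$i2, 0)
})

test_that("DerSimonian-Laird pooling matches hand evaluation and truncates at 0", {
  re <- random_effects_dl(c(0, 0.4), c(0.1, 0.1))
  expect_equal(re$tau2, 0.07)
  expect_equal(re$beta, 0.2)
  expect_equal(re$se, 0.2)

  # homogeneous: tau2 truncates to zero and equals the fixed-effects fit
  re0 <- random_effects_dl(c(0.2, 0.21), c(0.1, 0.1))
  fe0 <- fixed_effects(c(0.2, 0.21), c(0.1, 0.1))
  expect_equal(re0$tau2, 0)
  expect_equal(re0$beta, fe0$beta)
  expect_equal(re0$se, fe0$se)

  sym <- random_effects_dl(c(-0.3, 0.3), c(0.05, 0.05))
  expect_equal(sym$beta, 0)

  expect_error(random_effects_dl(0.1, 0.1), "at least 2")
})

test_that("fixed and DL pooling agree with metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k, 0.1, 0.2)
    s <- runif(k, 0.02, 0.3)
    fe <- fixed_effects(b, s)
    rma_fe <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(fe$beta, as.numeric(rma_fe$beta), tolerance = 1e-10)
    expect_equal(fe$se, rma_fe$se, tolerance = 1e-10)
    re <- random_effects_dl(b, s)
    rma_dl <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(re$beta, as.numeric(rma_dl$beta), tolerance = 1e-10)
    expect_equal(re$se, rma_dl$se, tolerance = 1e-10)
    expect_equal(re$tau2, rma_dl$tau2, tolerance = 1e-10)
  }
})

test_that("the fallback trigger requires both conditions jointly and strictly", {
  mk <- function(betas, ses) {
    studies <- lapply(seq_along(betas), function(i)
      data.frame(snp = "rs1", chrom = "chr1", pos = 100, ea = "A", oa = "G",
                 eaf = 0.4, beta = betas[i], se = ses[i],
                 p = 0.5, weight = 1000, z = betas[i] / ses[i]))
    meta_pipeline(studies)
  }
  # Q = 2: q_p ~ 0.157 >= 0.1 and I2 = 50 not > 50 -> fixed retained
  m1 <- mk(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m1$model, "fixed")
  expect_equal(m1$beta, 0.2)
  expect_equal(m1$se, 0.1 / sqrt(2))
  expect_equal(m1$i2, 50)
  expect_equal(m1$tau2, 0)

  # Q = 8: q_p ~ 0.0047 < 0.1 and I2 = 87.5 > 50 -> random effects
  m2 <- mk(c(0, 0.4), c(0.1, 0.1))
  expect_equal(m2$model, "random")
  expect_equal(m2$q_p, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.2)
  expect_equal(m2$tau2, 0.07)

  # single-study SNP: fixed, equals the input, Q missing
  m3 <- mk(0.05, 0.02)
  expect_equal(m3$model, "fixed")
  expect_equal(m3$beta, 0.05)
  expect_true(is.na(m3$q_p))
})

test_that("meta pipeline pools subsets, applies the eAF filter and keeps invariants", {
  cfg <- small_sim(seed = 5, n_snps = 400, block = 1)
  gw <- sim_multistudy_gwas(cfg)
  studies <- gw$studies
  # plant a cross-study frequency clash on one SNP
  studies[[1]]$eaf[1] <- 0.05
  studies[[2]]$eaf[1] <- 0.50
  # drop one SNP from one study: pooled over the remaining studies
  studies[[3]] <- studies[[3]][-2, ]
  res <- meta_pipeline(studies)
  expect_false(gw$map$snp[1] %in% res$snp)
  expect_equal(res$k[res$snp == gw$map$snp[2]], length(studies) - 1L)

  # invariants: pooled SE <= min per-study SE (fixed rows); estimate
  # inside the per-study range; random-effects SE >= fixed-effects SE
  B <- sapply(studies, function(s) s$beta[match(res$snp, s$snp)])
  S <- sapply(studies, function(s) s$se[match(res$snp, s$snp)])
  fixed <- res$model == "fixed"
  expect_true(all(res$se[fixed] <= apply(S[fixed, ], 1, min, na.rm = TRUE) + 1e-12))
  expect_true(all(res$beta >= apply(B, 1, min, na.rm = TRUE) - 1e-12))
  expect_true(all(res$beta <= apply(B, 1, max, na.rm = TRUE) + 1e-12))
  rnd <- which(res$model == "random")
  for (i in rnd) {
    b <- B[i, !is.na(B[i, ])]; s <- S[i, !is.na(S[i, ])]
    expect_gte(random_effects_dl(b, s)$se, fixed_effects(b, s)$se)
  }
})

test_that("under homogeneity the random-effects fallback fires at about its nominal rate", {
  # tau2 = 0: the joint trigger (q_p < 0.1 AND I2 > 50) fires in a fraction
  # given by the null chi-square; with k = 4 the I2 > 50 condition implies
  # Q > 6, and q_p < 0.1 implies Q > 6.251: the binding constraint is
  # Q > qchisq(0.9, 3), so the nominal rate is 10%.
  cfg <- sim_config(seed = 9, n_snps = 10000, ld_block_size = 1,
                    prop_causal = 0, tau2 = 0)
  gw <- sim_multistudy_gwas(cfg)
  res <- meta_pipeline(gw$studies, eaf_max_diff = NULL)
  k <- 4
  q_crit <- max(qchisq(0.9, k - 1), 2 * (k - 1))  # joint strict rule
  nominal <- pchisq(q_crit, k - 1, lower.tail = FALSE)
  observed <- mean(res$model == "random")
  expect_lt(abs(observed - nominal), 0.02)
})

test_that("pooled estimates recover true effects within Monte Carlo error", {
  cfg <- sim_config(seed = 13, n_snps = 8000, ld_block_size = 1,
                    prop_causal = 0.2, effect_sd = 0.05, tau2 = 0)
  gw <- sim_multistudy_gwas(cfg)
  res <- meta_pipeline(gw$studies, eaf_max_diff = NULL)
  truth <- gw$truth[match(res$snp, gw$truth$snp), ]
  err <- res$beta - truth$beta_true
  # mean error within 2 MC-SEs of zero, in the null bin and in each
  # quartile bin of the non-zero true effects
  null_sel <- !truth$causal
  expect_lt(abs(mean(err[null_sel])),
            2 * sd(err[null_sel]) / sqrt(sum(null_sel)))
  causal <- which(truth$causal)
  bins <- cut(truth$beta_true[causal],
              breaks = quantile(truth$beta_true[causal], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- causal[bins == b]
    mc_se <- sd(err[sel]) / sqrt(length(sel))
    expect_lt(abs(mean(err[sel])), 2 * mc_se)
  }
})
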