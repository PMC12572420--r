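test_that("instrument selection applies the strict F > 10 floor and exclusions", {
  rec <- data.frame(snp = c("s1", "s2", "s3"), chrom = "chr1",
                    pos = c(1e6, 5e6, 9e6), ea = "A", oa = "G", eaf = 0.3,
                    beta = c(0.1, 0.03, 0.08), se = c(0.02, 0.01, 0.02),
                    p = c(1e-7, 1e-7, 1e-7), stringsAsFactors = FALSE)
  got <- select_instruments(rec, NULL, "forward")
  expect_setequal(got$snp, c("s1", "s3"))          # F = 25, 9 (dropped), 16
  expect_equal(got$f_stat[got$snp == "s1"], 25)

  rev <- select_instruments(rec, NULL, "reverse", exclude = "s1")
  expect_false("s1" %in% rev$snp)
})

test_that("harmonisation aligns, flips and drops palindromic ambiguity", {
  exp <- data.frame(snp = c("m", "s", "p1", "p2", "gone"),
                    ea = c("A", "A", "A", "A", "A"),
                    oa = c("G", "G", "T", "T", "G"),
                    eaf = c(0.3, 0.3, 0.5, 0.2, 0.3),
                    beta = 0.1, se = 0.02, p = 1e-7,
                    stringsAsFactors = FALSE)
  out <- data.frame(snp = c("m", "s", "p1", "p2"),
                    ea = c("A", "G", "A", "T"),
                    oa = c("G", "A", "T", "A"),
                    eaf = c(0.31, 0.69, 0.5, 0.85),
                    beta = c(0.05, 0.05, 0.02, 0.02), se = 0.01,
                    stringsAsFactors = FALSE)
  h <- harmonize(exp, out)
  expect_setequal(h$snp, c("m", "s", "p2"))
  expect_equal(h$beta_out[h$snp == "m"], 0.05)     # matched: unchanged
  expect_equal(h$beta_out[h$snp == "s"], -0.05)    # swapped: negated
  # palindromic at eaf 0.5: dropped; at 0.2 vs 0.85: flipped by frequency
  expect_equal(attr(h, "n_palindromic_dropped"), 1L)
  expect_equal(h$beta_out[h$snp == "p2"], -0.02)
  expect_equal(attr(h, "n_missing_outcome"), 1L)
})

test_that("IVW matches ratio identities and equals the mean under equal SEs", {
  d1 <- data.frame(snp = "a", beta_exp = 0.2, se_exp = 0.01,
                   beta_out = 0.1, se_out = 0.01)
  expect_equal(ivw(d1)$beta, 0.5)

  d2 <- data.frame(snp = c("a", "b"), beta_exp = c(0.2, 0.4),
                   se_exp = 0.01, beta_out = c(0.1, 0.2), se_out = 0.01)
  e2 <- ivw(d2)
  expect_equal(e2$beta, 0.5)
  expect_equal(attr(e2, "q_stat"), 0)

  # equal ratio SEs: IVW equals the unweighted mean of ratios
  d3 <- data.frame(snp = letters[1:4], beta_exp = c(0.2, -0.2, 0.2, -0.2),
                   se_exp = 0.01, beta_out = c(0.05, -0.02, 0.08, -0.04),
                   se_out = 0.015)
  r <- d3$beta_out / d3$beta_exp
  expect_equal(ivw(d3)$beta, mean(r), tolerance = 1e-12)

  # a zero exposure effect is excluded with a warning
  d4 <- rbind(d2, data.frame(snp = "z", beta_exp = 0, se_exp = 0.01,
                             beta_out = 1, se_out = 0.01))
  expect_warning(e4 <- ivw(d4), "excluded")
  expect_equal(e4$beta, 0.5)
  expect_equal(e4$or_, exp(e4$beta))
  expect_equal(e4$ci_low, exp(e4$beta - qnorm(0.975) * e4$se))
})

test_that("IVW recovers a planted causal effect within Monte Carlo error", {
  dat <- make_instruments(n = 50, slope = 0.3, seed = 77)
  est <- ivw(dat)
  r <- dat$beta_out / dat$beta_exp
  mc_se <- sd(r) / sqrt(length(r))
  expect_lt(abs(est$beta - 0.3), 2 * mc_se)
})

test_that("Egger regression solves the exact weighted least-squares fixture", {
  set.seed(61)
  x <- runif(10, 0.1, 0.5)
  d <- data.frame(snp = paste0("s", 1:10), beta_exp = x, se_exp = 0.01,
                  beta_out = 0.02 + 0.4 * x, se_out = 0.01)
  e <- egger(d)
  expect_equal(e$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(e$intercept, 0.02, tolerance = 1e-10)
  expect_equal(e$slope$se, 0, tolerance = 1e-6)    # residual-free fit

  d0 <- transform(d, beta_out = 0.4 * x)
  expect_equal(egger(d0)$intercept, 0, tolerance = 1e-12)
  expect_error(egger(d[1:2, ]), "at least 3")

  # orientation invariance: flipping an exposure sign leaves the fit alone
  d5 <- d
  d5$beta_exp[1] <- -d5$beta_exp[1]
  d5$beta_out[1] <- -d5$beta_out[1]
  expect_equal(egger(d5)$slope$beta, e$slope$beta, tolerance = 1e-10)
})

test_that("Egger intercept test holds its size under balanced pleiotropy", {
  set.seed(62)
  n_rep <- 500
  rej <- replicate(n_rep, {
    d <- make_instruments(n = 30, slope = 0.2,
                          seed = sample.int(1e6, 1),
                          se_out = 0.02, pleio_sd = 0.02)
    egger(d)$intercept_p < 0.05
  })
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc_se)
})

test_that("the weighted median resists outlier contamination", {
  d <- data.frame(snp = paste0("s", 1:3), beta_exp = c(0.2, 0.2, 0.2),
                  se_exp = 0.01, beta_out = c(0.02, 0.1, 0.18),
                  se_out = 0.01)
  wm <- weighted_median(d, n_boot = 200, seed = 3)
  expect_equal(wm$beta, 0.5, tolerance = 1e-9)     # median of 0.1/0.5/0.9

  same <- data.frame(snp = paste0("s", 1:5), beta_exp = 0.2, se_exp = 0.01,
                     beta_out = 0.06, se_out = 0.01)
  expect_equal(weighted_median(same, n_boot = 100, seed = 1)$beta, 0.3,
               tolerance = 1e-9)

  # 30% contamination at ratio 5: median stays near 0.3, IVW is pulled up
  dat <- make_instruments(n = 40, slope = 0.3, seed = 99, se_out = 0.005)
  bad <- 1:12
  dat$beta_out[bad] <- 5 * dat$beta_exp[bad] + rnorm(12, 0, 0.005)
  wm2 <- weighted_median(dat, n_boot = 500, seed = 5)
  expect_lt(abs(wm2$beta - 0.3), 0.05)
  expect_gt(ivw(dat)$beta, wm2$beta + 0.5)
})

test_that("Cochran's Q over instruments matches the pooling arithmetic", {
  d <- data.frame(snp = c("a", "b"), beta_exp = 1, se_exp = 0.01,
                  beta_out = c(0.1, 0.3), se_out = 0.1)
  q <- cochran_q(d)
  expect_equal(q$q_stat, 2)
  expect_equal(q$q_p, pchisq(2, 1, lower.tail = FALSE))
  same <- transform(d, beta_out = 0.2)
  expect_equal(cochran_q(same)$q_stat, 0)

  # under homogeneity Q/df is near 1 on average
  set.seed(63)
  qdf <- replicate(300, {
    dd <- make_instruments(n = 20, slope = 0.2, seed = sample.int(1e6, 1),
                           se_exp = 1e-6)
    q <- cochran_q(dd)
    q$q_stat / q$df
  })
  expect_lt(abs(mean(qdf) - 1), 3 * sd(qdf) / sqrt(300))
})

test_that("leave-one-out equals the complementary ratios at n = 2 and flags outliers", {
  d <- data.frame(snp = c("a", "b"), beta_exp = c(0.2, 0.4), se_exp = 0.01,
                  beta_out = c(0.1, 0.1), se_out = 0.01)
  loo <- leave_one_out(d)
  expect_equal(loo$beta[loo$snp_excluded == "a"], 0.1 / 0.4)
  expect_equal(loo$beta[loo$snp_excluded == "b"], 0.1 / 0.2)

  same <- data.frame(snp = paste0("s", 1:4), beta_exp = 0.2, se_exp = 0.01,
                     beta_out = 0.06, se_out = 0.01)
  loos <- leave_one_out(same)
  expect_true(all(abs(loos$beta - 0.3) < 1e-12))
  expect_true(attr(loos, "pass"))

  # removing a planted outlier moves the estimate toward the truth
  dat <- make_instruments(n = 15, slope = 0.3, seed = 101, se_out = 0.005)
  dat$beta_out[1] <- dat$beta_out[1] + 0.5
  full <- ivw(dat)$beta
  lo <- leave_one_out(dat)
  drop1 <- lo$beta[lo$snp_excluded == dat$snp[1]]
  expect_lt(abs(drop1 - 0.3), abs(full - 0.3))
})

test_that("the PRESSO global test is seeded, sized and powered", {
  dat <- make_instruments(n = 20, slope = 0.3, seed = 55, se_out = 0.01)
  a <- presso_global(dat, n_sim = 400, seed = 9)
  b <- presso_global(dat, n_sim = 400, seed = 9)
  expect_identical(a$global_p, b$global_p)        # bit-reproducible
  expect_error(presso_global(dat[1:3, ]), "at least 4")

  # a 10-sigma outcome outlier is detected
  out <- dat
  out$beta_out[1] <- out$beta_out[1] + 10 * out$se_out[1]
  expect_lte(presso_global(out, n_sim = 400, seed = 9)$global_p, 0.01)

  # type-I error near nominal under no pleiotropy
  set.seed(64)
  n_rep <- 200
  rej <- replicate(n_rep, {
    d <- make_instruments(n = 12, slope = 0.2, seed = sample.int(1e6, 1),
                          se_exp = 1e-6)
    presso_global(d, n_sim = 200, seed = 1)$global_p < 0.05
  })
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc_se)
})

test_that("bidirectional MR flags the planted causal traits and keeps directions disjoint", {
  cfg <- sim_config(seed = 71, n_snps = 8000, ld_block_size = 5,
                    n_traits = 10, n_instruments_per_trait = 25,
                    n_reverse_hits = 40,
                    causal_trait_effects = c(trait01 = 0.15,
                                             trait02 = -0.15))
  mb <- sim_microbiome_panel(cfg)
  res <- run_bidirectional(mb$panel, mb$outcome, NULL,
                           n_sim_presso = 200, seed = 2, modes = FALSE)
  sig <- res$significance
  fwd <- sig[sig$direction == "forward", ]
  expect_equal(nrow(fwd), 10L)
  # the two causal traits get the smallest adjusted IVW p
  top2 <- fwd$trait[order(fwd$mr_p_adj)][1:2]
  expect_setequal(top2, c("trait01", "trait02"))
  expect_true(all(fwd$significant[fwd$trait %in% top2]))
  # estimated effects near the planted +-0.15
  expect_equal(fwd$ivw_beta[fwd$trait == "trait01"], 0.15, tolerance = 0.07)
  expect_equal(fwd$ivw_beta[fwd$trait == "trait02"], -0.15, tolerance = 0.07)
  # forward and reverse instrument sets are disjoint by construction
  expect_length(intersect(res$forward_instruments,
                          res$reverse_instruments), 0)
  expect_true(all(sig$or_[!is.na(sig$or_)] > 0))

  # empty panel gives an empty result
  empty <- run_bidirectional(list(), mb$outcome, NULL)
  expect_length(empty$forward, 0)
})

test_that("a trait whose instruments are all weak is skipped with a report entry", {
  weak <- data.frame(snp = c("w1", "w2"), chrom = "chr1",
                     pos = c(1e6, 8e6), ea = "A", oa = "G", eaf = 0.3,
                     beta = 0.003, se = 0.001, p = 1e-6,
                     stringsAsFactors = FALSE)  # p passes, F = 9 fails
  out <- data.frame(snp = c("w1", "w2"), chrom = "chr1",
                    pos = c(1e6, 8e6), ea = "A", oa = "G", eaf = 0.3,
                    beta = 0, se = 0.004, p = 0.5, stringsAsFactors = FALSE)
  res <- run_bidirectional(list(weak_trait = weak), out, NULL)
  row <- res$significance[res$significance$direction == "forward", ]
  expect_equal(row$status, "no instruments pass selection")
  expect_equal(row$n_snp, 0L)
})
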