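# Bidirectional two-sample Mendelian randomization between a panel of
# exposure GWAS (microbiota taxon abundances) and an outcome GWAS (the ASD
# meta-analysis), with the instrument-selection rules, estimators and
# sensitivity battery used for the gut-brain axis analysis:
#   forward:  exposure p < 1e-5, clump r2 = 0.1 within 500 kb, F > 10
#   reverse:  exposure p < 5e-6, clump r2 < 0.001 within 10,000 kb, F > 10,
#             forward instruments excluded
# Estimators: IVW (multiplicative random-effects SE inflation when
# Q > n-1), MR-Egger with intercept test, weighted median (bootstrap SE),
# simple/weighted mode (presumptive extras), Cochran's Q, leave-one-out,
# and the MR-PRESSO global test.

.mr_direction_defaults <- list(
  forward = list(p_threshold = 1e-5, r2_threshold = 0.1, window_kb = 500),
  reverse = list(p_threshold = 5e-6, r2_threshold = 0.001, window_kb = 10000)
)

#' Select instrument candidates on the exposure side
#'
#' Applies the direction's significance threshold, greedy LD clumping, the
#' weak-instrument filter F = (beta/se)^2 strictly greater than
#' \code{f_min}, and (reverse direction) an exclusion set of SNPs already
#' used as forward instruments.
#'
#' @param exposure exposure summary statistics (canonical columns).
#' @param ld pairwise r-squared table as in [ld_clump()].
#' @param direction \code{"forward"} or \code{"reverse"}; fixes the
#'   clumping thresholds above.
#' @param exclude character vector of SNP ids to drop regardless of
#'   strength (the forward-instrument exclusion for the reverse run).
#' @param f_min weak-instrument floor (default 10, strict).
#' @return data.frame of exposure records for the retained instruments
#'   with an added \code{f_stat} column; zero rows when nothing survives.
#' @export
select_instruments <- function(exposure, ld = NULL,
                               direction = c("forward", "reverse"),
                               exclude = NULL, f_min = 10) {
  direction <- match.arg(direction)
  th <- .mr_direction_defaults[[direction]]
  idx <- ld_clump(exposure, ld,
                  clump_params(r2_threshold = th$r2_threshold,
                               window_kb = th$window_kb,
                               p_threshold = th$p_threshold))
  out <- exposure[exposure$snp %in% idx$snp, , drop = FALSE]
  if (!is.null(exclude)) out <- out[!out$snp %in% exclude, , drop = FALSE]
  out$f_stat <- (out$beta / out$se)^2
  out <- out[out$f_stat > f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonise exposure instruments with outcome effects
#'
#' Joins instruments to the outcome on SNP id and aligns the outcome
#' effect to the exposure's effect allele: matching alleles are kept,
#' swapped alleles flip the outcome beta and frequency, strand-complement
#' matches are rescued for non-palindromic pairs.  Palindromic (A/T, C/G)
#' SNPs with effect-allele frequency inside \[0.42, 0.58\] on either side
#' are dropped as unresolvable; outside that window they are oriented by
#' frequency concordance (flipped when the exposure and outcome
#' frequencies sit on opposite sides of 0.5).  SNPs missing from the
#' outcome are dropped and counted.
#'
#' @param instruments exposure-side instrument table from
#'   [select_instruments()].
#' @param outcome outcome summary statistics (canonical columns).
#' @param palindromic_window frequency window inside which palindromic
#'   SNPs are dropped (default \code{c(0.42, 0.58)}).
#' @return data.frame with \code{snp}, \code{beta_exp}, \code{se_exp},
#'   \code{eaf_exp}, \code{beta_out}, \code{se_out}, \code{eaf_out},
#'   \code{f_stat}; counts of dropped SNPs in attributes
#'   \code{"n_missing_outcome"} and \code{"n_palindromic_dropped"}.
#' @export
harmonize <- function(instruments, outcome,
                      palindromic_window = c(0.42, 0.58)) {
  oi <- match(instruments$snp, outcome$snp)
  n_missing <- sum(is.na(oi))
  keep <- !is.na(oi)
  exp <- instruments[keep, , drop = FALSE]
  out <- outcome[oi[keep], , drop = FALSE]
  n_pal <- 0L
  if (nrow(exp)) {
    aligned <- align_to_reference(out, exp$ea, exp$oa)
    pal <- .is_palindromic(exp$ea, exp$oa)
    status <- aligned$align_status
    # palindromic pairs always look like match or swap; decide them here
    freq_bad <- pal & ((exp$eaf >= palindromic_window[1] &
                          exp$eaf <= palindromic_window[2]) |
                         (aligned$eaf >= palindromic_window[1] &
                            aligned$eaf <= palindromic_window[2]))
    freq_bad[is.na(freq_bad)] <- TRUE   # palindromic without eaf: drop
    drop_pal <- pal & freq_bad
    # palindromic outside the window: orient by frequency concordance
    flip_pal <- pal & !freq_bad &
      (sign(exp$eaf - 0.5) != sign(aligned$eaf - 0.5))
    flip_pal[is.na(flip_pal)] <- FALSE
    aligned$beta[flip_pal] <- -aligned$beta[flip_pal]
    aligned$eaf[flip_pal] <- 1 - aligned$eaf[flip_pal]
    ok <- status != "exclude" & !drop_pal
    n_pal <- sum(drop_pal, na.rm = TRUE)
    exp <- exp[ok, , drop = FALSE]
    aligned <- aligned[ok, , drop = FALSE]
  } else aligned <- out
  nr <- nrow(exp)
  res <- data.frame(snp = exp$snp,
                    beta_exp = exp$beta, se_exp = exp$se,
                    eaf_exp = exp$eaf %||% rep(NA_real_, nr),
                    beta_out = aligned$beta, se_out = aligned$se,
                    eaf_out = aligned$eaf %||% rep(NA_real_, nr),
                    f_stat = if ("f_stat" %in% names(exp)) exp$f_stat
                             else (exp$beta / exp$se)^2,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_missing_outcome") <- n_missing
  attr(res, "n_palindromic_dropped") <- n_pal
  res
}

.mr_estimate <- function(method, beta, se, p, n_snp) {
  data.frame(method = method, beta = beta, se = se, p = p,
             or_ = exp(beta),
             ci_low = exp(beta - qnorm(0.975) * se),
             ci_high = exp(beta + qnorm(0.975) * se),
             n_snp = n_snp, stringsAsFactors = FALSE)
}

.ratios <- function(dat) {
  ok <- dat$beta_exp != 0
  if (any(!ok)) warning(sum(!ok), " instrument(s) with beta_exp = 0 excluded")
  dat <- dat[ok, , drop = FALSE]
  list(b = dat$beta_out / dat$beta_exp,
       se = dat$se_out / abs(dat$beta_exp), dat = dat)
}

#' Inverse-variance-weighted MR estimate
#'
#' Per-SNP ratio estimates \eqn{\beta_j = \beta_{out,j}/\beta_{exp,j}} with
#' first-order SEs \eqn{se_j = se_{out,j}/|\beta_{exp,j}|}, pooled by
#' inverse variance.  When Cochran's Q exceeds its degrees of freedom the
#' SE is inflated multiplicatively by \eqn{\sqrt{Q/(n-1)}} (multiplicative
#' random-effects model).
#'
#' @param dat harmonised instrument table from [harmonize()].
#' @return single-row data.frame (method, beta, se, p, or_, ci_low,
#'   ci_high, n_snp) with \code{q_stat}/\code{q_p} attributes.
#' @export
ivw <- function(dat) {
  r <- .ratios(dat)
  if (length(r$b) == 0L) stop("no usable instruments", call. = FALSE)
  w <- 1 / r$se^2
  beta <- sum(w * r$b) / sum(w)
  se <- 1 / sqrt(sum(w))
  n <- length(r$b)
  q <- sum(w * (r$b - beta)^2)
  if (n >= 2L && q / (n - 1) > 1) se <- se * sqrt(q / (n - 1))
  est <- .mr_estimate("ivw", beta, se, p_from_z(beta / se), n)
  attr(est, "q_stat") <- q
  attr(est, "q_p") <- if (n >= 2L) pchisq(q, n - 1, lower.tail = FALSE) else NA_real_
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept (weights \eqn{1/se_{out}^2}), after orienting all
#' exposure effects non-negative by joint sign flips.  A non-zero
#' intercept indicates directional pleiotropy; its two-sided p uses the t
#' distribution on n-2 df.
#'
#' @param dat harmonised instrument table (>= 3 instruments).
#' @return list with \code{slope} (an estimate row as in [ivw()]),
#'   \code{intercept}, \code{intercept_se}, \code{intercept_p}.
#' @export
egger <- function(dat) {
  if (nrow(dat) < 3L) stop("MR-Egger needs at least 3 instruments",
                           call. = FALSE)
  flip <- sign(dat$beta_exp)
  flip[flip == 0] <- 1
  x <- dat$beta_exp * flip
  y <- dat$beta_out * flip
  fit <- lm(y ~ x, weights = 1 / dat$se_out^2)
  co <- summary(fit)$coefficients
  n <- nrow(dat)
  slope <- .mr_estimate("egger", co["x", 1], co["x", 2],
                        2 * pt(abs(co["x", 1] / co["x", 2]), n - 2,
                               lower.tail = FALSE), n)
  list(slope = slope,
       intercept = co["(Intercept)", 1],
       intercept_se = co["(Intercept)", 2],
       intercept_p = 2 * pt(abs(co["(Intercept)", 1] / co["(Intercept)", 2]),
                            n - 2, lower.tail = FALSE))
}

.weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  cs <- cumsum(w) - 0.5 * w        # interpolated weighted quantile
  cs <- cs / sum(w)
  if (all(cs >= 0.5)) return(b[1])
  below <- max(which(cs < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted-median MR estimate
#'
#' Weighted median of the per-SNP ratio estimates with inverse-variance
#' weights; consistent when at least half the weight comes from valid
#' instruments.  The SE comes from a seeded parametric bootstrap.
#'
#' @param dat harmonised instrument table (>= 3 instruments).
#' @param n_boot bootstrap draws for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return single-row estimate data.frame as in [ivw()].
#' @export
weighted_median <- function(dat, n_boot = 1000, seed = 1) {
  if (nrow(dat) < 3L) stop("weighted median needs at least 3 instruments",
                           call. = FALSE)
  r <- .ratios(dat)
  w <- 1 / r$se^2
  beta <- .weighted_median_point(r$b, w)
  d <- r$dat
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      be <- rnorm(nrow(d), d$beta_exp, d$se_exp)
      bo <- rnorm(nrow(d), d$beta_out, d$se_out)
      ok <- be != 0
      bb <- bo[ok] / be[ok]
      ww <- (abs(be[ok]) / d$se_out[ok])^2
      .weighted_median_point(bb, ww)
    }, numeric(1))
  })
  se <- sd(boot)
  .mr_estimate("weighted_median", beta, se, p_from_z(beta / se), nrow(d))
}

# run code under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

.mode_point <- function(b, w, bw_factor = 1) {
  # kernel-density mode of ratio estimates (normal kernel, mad-based
  # bandwidth as in the conventional mode-based estimator)
  s <- 0.9 * min(sd(b), mad(b)) / length(b)^(1 / 5)
  if (!is.finite(s) || s <= 0) s <- sd(b) / length(b)^(1 / 5)
  if (!is.finite(s) || s <= 0) return(median(b))
  h <- bw_factor * s
  d <- density(b, weights = w / sum(w), bw = h)
  d$x[which.max(d$y)]
}

#' Mode-based MR estimates (presumptive extras)
#'
#' Simple mode (equal weights) and weighted mode (inverse-variance
#' weights) of the ratio estimates, with seeded parametric-bootstrap SEs.
#' These round out the conventional five-method battery alongside IVW,
#' MR-Egger and the weighted median; they are clearly secondary and the
#' significance callout never depends on them.
#'
#' @param dat harmonised instrument table (>= 3 instruments).
#' @param weighted use inverse-variance weights (\code{TRUE}) or equal
#'   weights (\code{FALSE}).
#' @param n_boot,seed bootstrap settings as in [weighted_median()].
#' @return single-row estimate data.frame as in [ivw()].
#' @export
mode_estimate <- function(dat, weighted = TRUE, n_boot = 1000, seed = 1) {
  if (nrow(dat) < 3L) stop("mode estimators need at least 3 instruments",
                           call. = FALSE)
  r <- .ratios(dat)
  w <- if (weighted) 1 / r$se^2 else rep(1, length(r$b))
  beta <- .mode_point(r$b, w)
  d <- r$dat
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      be <- rnorm(nrow(d), d$beta_exp, d$se_exp)
      bo <- rnorm(nrow(d), d$beta_out, d$se_out)
      ok <- be != 0
      bb <- bo[ok] / be[ok]
      ww <- if (weighted) (abs(be[ok]) / d$se_out[ok])^2 else rep(1, sum(ok))
      .mode_point(bb, ww)
    }, numeric(1))
  })
  se <- sd(boot)
  .mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
               beta, se, p_from_z(beta / se), nrow(d))
}

#' Cochran's Q over instruments
#'
#' \eqn{Q = \sum_j w_j (\beta_j - \hat\beta_{IVW})^2} on the ratio scale,
#' p from the chi-square on n-1 df.
#'
#' @param dat harmonised instrument table (>= 2 instruments).
#' @param ivw_beta the IVW point estimate (recomputed when missing).
#' @return list with \code{q_stat}, \code{q_p}, \code{df}.
#' @export
cochran_q <- function(dat, ivw_beta = NULL) {
  r <- .ratios(dat)
  n <- length(r$b)
  if (n < 2L) return(list(q_stat = NA_real_, q_p = NA_real_, df = n - 1L))
  w <- 1 / r$se^2
  if (is.null(ivw_beta)) ivw_beta <- sum(w * r$b) / sum(w)
  q <- sum(w * (r$b - ivw_beta)^2)
  list(q_stat = q, q_p = pchisq(q, n - 1, lower.tail = FALSE), df = n - 1L)
}

#' Leave-one-out IVW estimates
#'
#' Recomputes the IVW estimate excluding each instrument in turn.  The
#' analysis "passes" when every leave-one-out confidence interval overlaps
#' the sign of the full-sample estimate (no single SNP drives the
#' direction).
#'
#' @param dat harmonised instrument table (>= 2 instruments).
#' @return data.frame (\code{snp_excluded}, \code{beta}, \code{se},
#'   \code{p}, \code{ci_low_beta}, \code{ci_high_beta}) with a
#'   \code{"pass"} attribute.
#' @export
leave_one_out <- function(dat) {
  r <- .ratios(dat)
  d <- r$dat
  n <- nrow(d)
  if (n < 2L) stop("leave-one-out needs at least 2 instruments",
                   call. = FALSE)
  full <- ivw(d)
  rows <- lapply(seq_len(n), function(j) {
    e <- ivw(d[-j, , drop = FALSE])
    data.frame(snp_excluded = d$snp[j], beta = e$beta, se = e$se, p = e$p,
               ci_low_beta = e$beta - qnorm(0.975) * e$se,
               ci_high_beta = e$beta + qnorm(0.975) * e$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pass <- if (full$beta >= 0) all(out$ci_high_beta > 0)
          else all(out$ci_low_beta < 0)
  attr(out, "pass") <- pass
  attr(out, "full_beta") <- full$beta
  out
}

#' MR-PRESSO global pleiotropy test
#'
#' Observed residual sum of squares
#' \eqn{RSS = \sum_j w_j (\beta_{out,j} - \hat\beta_{-j} \beta_{exp,j})^2}
#' with \eqn{w_j = 1/se_{out,j}^2} and \eqn{\hat\beta_{-j}} the
#' leave-one-out IVW slope, compared against a parametric null in which
#' \eqn{\beta_{out,j} \sim N(\hat\beta_{-j}\beta_{exp,j}, se_{out,j})} and
#' the leave-one-out slopes are recomputed inside every replicate.
#' \eqn{p = (1 + \#\{RSS_{sim} \ge RSS_{obs}\}) / (n_{sim} + 1)}.
#'
#' @param dat harmonised instrument table (>= 4 instruments).
#' @param n_sim simulated null replicates (default 1000).
#' @param seed RNG seed (default 1); identical data and seed give an
#'   identical p.
#' @return list with \code{global_p}, \code{rss_obs}, \code{n_sim}.
#' @export
presso_global <- function(dat, n_sim = 1000, seed = 1) {
  if (nrow(dat) < 4L) stop("MR-PRESSO global test needs at least 4 instruments",
                           call. = FALSE)
  d <- .ratios(dat)$dat
  x <- d$beta_exp; y <- d$beta_out; w <- 1 / d$se_out^2
  # leave-one-out IVW slope on the outcome scale (regression through the
  # origin of y on x with weights w): (Sxy - x_j y_j w_j)/(Sxx - x_j^2 w_j)
  loo_slope <- function(yv) {
    sxy <- sum(w * x * yv); sxx <- sum(w * x^2)
    (sxy - w * x * yv) / (sxx - w * x^2)
  }
  bhat <- loo_slope(y)
  rss_obs <- sum(w * (y - bhat * x)^2)
  sims <- withr_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      ysim <- rnorm(length(y), bhat * x, d$se_out)
      bsim <- loo_slope(ysim)
      sum(w * (ysim - bsim * x)^2)
    }, numeric(1))
  })
  list(global_p = (1 + sum(sims >= rss_obs)) / (n_sim + 1),
       rss_obs = rss_obs, n_sim = n_sim)
}

#' Full MR report for one exposure-outcome pair
#'
#' Runs the estimator battery (IVW always; MR-Egger, weighted median and
#' the mode estimators when enough instruments survive), Cochran's Q, the
#' Egger intercept test, the MR-PRESSO global test and leave-one-out
#' validation on a harmonised instrument table.
#'
#' @param dat harmonised instrument table from [harmonize()].
#' @param exposure,outcome labels carried into the report.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param n_sim_presso PRESSO null replicates (default 1000).
#' @param seed RNG seed for the stochastic components.
#' @param modes also run the presumptive simple/weighted mode estimators
#'   (default TRUE).
#' @return an object of class \code{mr_report}.
#' @export
mr_report <- function(dat, exposure = "exposure", outcome = "outcome",
                      direction = "forward", n_sim_presso = 1000,
                      seed = 1, modes = TRUE) {
  n <- nrow(dat)
  if (n < 1L) stop("no instruments", call. = FALSE)
  est <- list(ivw(dat))
  q <- cochran_q(dat, est[[1]]$beta)
  eg <- NULL
  if (n >= 3L) {
    eg <- egger(dat)
    est <- c(est, list(eg$slope),
             list(weighted_median(dat, seed = seed)))
    if (modes)
      est <- c(est, list(mode_estimate(dat, weighted = FALSE, seed = seed)),
               list(mode_estimate(dat, weighted = TRUE, seed = seed)))
  }
  presso <- if (n >= 4L) presso_global(dat, n_sim = n_sim_presso,
                                       seed = seed) else NULL
  loo <- if (n >= 2L) leave_one_out(dat) else NULL
  structure(list(
    exposure = exposure, outcome = outcome, direction = direction,
    n_snps = n, estimates = do.call(rbind, est),
    q_stat = q$q_stat, q_p = q$q_p,
    egger_intercept = if (!is.null(eg)) eg$intercept else NA_real_,
    egger_intercept_p = if (!is.null(eg)) eg$intercept_p else NA_real_,
    presso_global_p = if (!is.null(presso)) presso$global_p else NA_real_,
    loo = loo, instruments = dat), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR (", x$direction, "): ", x$exposure, " -> ", x$outcome,
      "  [", x$n_snps, " instruments]\n", sep = "")
  print(x$estimates, row.names = FALSE, digits = 4)
  cat(sprintf("Cochran Q = %.3f (p = %.3g); Egger intercept = %.4g (p = %.3g); PRESSO global p = %.3g\n",
              x$q_stat, x$q_p, x$egger_intercept, x$egger_intercept_p,
              x$presso_global_p))
  if (!is.null(x$loo))
    cat("Leave-one-out:", if (attr(x$loo, "pass")) "pass" else "FAIL", "\n")
  invisible(x)
}

#' Bidirectional MR across an exposure panel
#'
#' Forward: every panel trait as exposure against the outcome GWAS, with
#' the forward instrument rules; BH adjustment of the IVW p across traits.
#' Reverse: the outcome GWAS as exposure against every trait, with the
#' reverse rules and the union of forward instruments excluded.  Per-trait
#' failures (no instruments, no harmonisable SNPs) are isolated and logged
#' in the significance table; the pipeline continues.
#'
#' @param panel named list of exposure summary-statistics data.frames.
#' @param outcome outcome summary statistics (e.g. the ASD meta-analysis).
#' @param ld pairwise r-squared table for clumping.
#' @param n_sim_presso,seed,modes passed to [mr_report()].
#' @param bh_alpha significance callout threshold on the BH-adjusted IVW p
#'   (default 0.05).
#' @return list with \code{forward} and \code{reverse} (lists of
#'   \code{mr_report}), \code{forward_instruments} /
#'   \code{reverse_instruments} (post-harmonisation SNP sets), and
#'   \code{significance} (flat per-trait table: trait, direction, status,
#'   n_snp, ivw_beta, or_, ci_low, ci_high, mr_p, mr_p_adj, significant,
#'   q_stat, q_p, egger_intercept_p, presso_p, loo_pass).
#' @export
run_bidirectional <- function(panel, outcome, ld = NULL,
                              n_sim_presso = 1000, seed = 1, modes = TRUE,
                              bh_alpha = 0.05) {
  stopifnot(is.list(panel))
  if (is.null(names(panel)) && length(panel))
    names(panel) <- paste0("trait", seq_along(panel))
  run_side <- function(direction, exposures, outcomes, exclude,
                       shared_exposure = FALSE) {
    reports <- list(); inst <- character(0); rows <- list()
    shared_cand <- if (shared_exposure && length(exposures))
      select_instruments(exposures[[1]], ld, direction, exclude = exclude)
    else NULL
    for (nm in names(exposures)) {
      trait <- nm
      res <- tryCatch({
        exp_ss <- exposures[[nm]]
        out_ss <- outcomes[[nm]]
        cand <- if (!is.null(shared_cand)) shared_cand
        else select_instruments(exp_ss, ld, direction, exclude = exclude)
        if (nrow(cand) == 0L) stop("no instruments pass selection")
        dat <- harmonize(cand, out_ss)
        if (nrow(dat) == 0L) stop("no instruments harmonisable with outcome")
        mr_report(dat, exposure = if (direction == "forward") trait else "outcome_gwas",
                  outcome = if (direction == "forward") "outcome_gwas" else trait,
                  direction = direction, n_sim_presso = n_sim_presso,
                  seed = seed, modes = modes)
      }, error = function(e) conditionMessage(e))
      if (inherits(res, "mr_report")) {
        reports[[trait]] <- res
        inst <- union(inst, res$instruments$snp)
        e <- res$estimates[res$estimates$method == "ivw", ]
        rows[[trait]] <- data.frame(
          trait = trait, direction = direction, status = "ok",
          n_snp = res$n_snps, ivw_beta = e$beta, or_ = e$or_,
          ci_low = e$ci_low, ci_high = e$ci_high, mr_p = e$p,
          q_stat = res$q_stat, q_p = res$q_p,
          egger_intercept_p = res$egger_intercept_p,
          presso_p = res$presso_global_p,
          loo_pass = if (!is.null(res$loo)) attr(res$loo, "pass") else NA,
          stringsAsFactors = FALSE)
      } else {
        rows[[trait]] <- data.frame(
          trait = trait, direction = direction, status = res,
          n_snp = 0L, ivw_beta = NA_real_, or_ = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, mr_p = NA_real_,
          q_stat = NA_real_, q_p = NA_real_,
          egger_intercept_p = NA_real_, presso_p = NA_real_,
          loo_pass = NA, stringsAsFactors = FALSE)
      }
    }
    list(reports = reports, instruments = inst,
         table = do.call(rbind, rows))
  }
  out_per_trait <- setNames(rep(list(outcome), length(panel)), names(panel))
  fwd <- run_side("forward", panel, out_per_trait, exclude = NULL)
  rev_exposures <- setNames(rep(list(outcome), length(panel)), names(panel))
  rev <- run_side("reverse", rev_exposures, panel,
                  exclude = fwd$instruments, shared_exposure = TRUE)
  sig <- rbind(fwd$table, rev$table)
  if (!is.null(sig)) {
    sig$mr_p_adj <- NA_real_
    for (dir in c("forward", "reverse")) {
      sel <- sig$direction == dir & !is.na(sig$mr_p)
      if (any(sel)) sig$mr_p_adj[sel] <- bh_adjust(sig$mr_p[sel])
    }
    sig$significant <- !is.na(sig$mr_p_adj) & sig$mr_p_adj < bh_alpha
    rownames(sig) <- NULL
  }
  stopifnot(length(intersect(fwd$instruments, rev$instruments)) == 0L)
  list(forward = fwd$reports, reverse = rev$reports,
       forward_instruments = fwd$instruments,
       reverse_instruments = rev$instruments,
       significance = sig)
}
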