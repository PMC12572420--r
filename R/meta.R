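# Multi-study pooling of per-SNP effects: inverse-variance fixed effects,
# Cochran's Q / I-squared heterogeneity, and a DerSimonian-Laird
# random-effects fallback triggered by Q-test P < 0.1 AND I2 > 50%.

#' Inverse-variance fixed-effects pooling
#'
#' Pools per-study effects with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i}, \eqn{SE = 1/\sqrt{\sum w_i}};
#' the two-sided p comes from the standard normal (log-space in the far
#' tail).
#'
#' @param betas,ses numeric vectors of per-study effects and standard
#'   errors (all \code{ses > 0}, equal length, at least one study).
#' @return list with \code{beta}, \code{se}, \code{z}, \code{p}.
#' @examples
#' fixed_effects(c(0.1, 0.3), c(0.1, 0.1))
#' @export
fixed_effects <- function(betas, ses) {
  if (length(betas) == 0L) stop("no studies to pool", call. = FALSE)
  stopifnot(length(betas) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = p_from_z(z))
}

#' Cochran's Q and I-squared heterogeneity
#'
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} with \eqn{w_i = 1/se_i^2}, p
#' from the chi-square on k-1 df, and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100} (0 when Q = 0).  With a
#' single study Q is undefined: \code{q_stat}/\code{q_p} are \code{NA} and
#' \code{i2 = 0}.
#'
#' @param betas,ses per-study effects and standard errors.
#' @param beta_pooled the fixed-effects pooled estimate.
#' @return list with \code{q_stat}, \code{q_p}, \code{i2}, \code{df}.
#' @export
heterogeneity <- function(betas, ses, beta_pooled) {
  k <- length(betas)
  if (k < 2L) return(list(q_stat = NA_real_, q_p = NA_real_, i2 = 0, df = k - 1L))
  w <- 1 / ses^2
  q <- sum(w * (betas - beta_pooled)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q_stat = q, q_p = pchisq(q, df, lower.tail = FALSE), i2 = i2, df = df)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))}, then
#' inverse-variance pooling with restated weights
#' \eqn{w^*_i = 1/(se_i^2 + \tau^2)}.
#'
#' @param betas,ses per-study effects and standard errors (k >= 2).
#' @return list with \code{beta}, \code{se}, \code{tau2}, \code{z}, \code{p}.
#' @examples
#' random_effects_dl(c(0, 0.4), c(0.1, 0.1))
#' @export
random_effects_dl <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("random-effects pooling needs at least 2 studies",
                   call. = FALSE)
  w <- 1 / ses^2
  fe <- fixed_effects(betas, ses)
  q <- sum(w * (betas - fe$beta)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * betas) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- beta / se
  list(beta = beta, se = se, tau2 = tau2, z = z, p = p_from_z(z))
}

#' Per-SNP meta-analysis across studies with heterogeneity fallback
#'
#' Pools every SNP across the supplied studies with inverse-variance fixed
#' effects; where the heterogeneity trigger fires (Q-test p strictly below
#' \code{fallback_q_p} AND I-squared strictly above \code{fallback_i2}, both
#' conditions required jointly) the DerSimonian-Laird random-effects result
#' is reported instead with \code{model = "random"}.  SNPs present in only a
#' subset of studies are pooled over the available studies (no minimum-study
#' filter unless \code{min_k} is raised).  Records must already share a
#' reference allele orientation; the cross-study eAF filter is applied here
#' (SNPs failing it are dropped and reported in the \code{"eaf_filter"}
#' attribute).
#'
#' @param studies named list of summary-statistics data.frames (canonical
#'   columns; \code{beta} and \code{se} required, \code{eaf}/\code{weight}
#'   used when present).
#' @param fallback_q_p,fallback_i2 heterogeneity trigger thresholds
#'   (defaults 0.1 and 50).
#' @param eaf_max_diff cross-study eAF range filter (default 0.2;
#'   \code{NULL} disables).
#' @param min_k minimum number of contributing studies (default 1).
#' @return a \code{meta_result}: data.frame with columns \code{snp},
#'   \code{chrom}, \code{pos}, \code{ea}, \code{oa}, \code{eaf_pooled},
#'   \code{beta}, \code{se}, \code{z}, \code{p}, \code{k}, \code{q_stat},
#'   \code{q_p}, \code{i2}, \code{tau2}, \code{model}.
#' @export
meta_pipeline <- function(studies, fallback_q_p = 0.1, fallback_i2 = 50,
                          eaf_max_diff = 0.2, min_k = 1L) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  snps <- unique(unlist(lapply(studies, `[[`, "snp"), use.names = FALSE))
  n <- length(snps)
  K <- length(studies)
  mat <- function() matrix(NA_real_, n, K, dimnames = list(snps, names(studies)))
  B <- mat(); S <- mat(); F <- mat(); W <- mat()
  map_info <- NULL
  for (j in seq_len(K)) {
    st <- studies[[j]]
    idx <- match(st$snp, snps)
    B[idx, j] <- st$beta
    S[idx, j] <- st$se
    if ("eaf" %in% names(st)) F[idx, j] <- st$eaf
    if ("weight" %in% names(st)) W[idx, j] <- st$weight
    keepcols <- intersect(c("snp", "chrom", "pos", "ea", "oa"), names(st))
    info <- st[, keepcols, drop = FALSE]
    map_info <- if (is.null(map_info)) info else
      rbind(map_info, info[!info$snp %in% map_info$snp, , drop = FALSE])
  }
  usable <- !is.na(B) & !is.na(S) & S > 0
  B[!usable] <- NA_real_; S[!usable] <- NA_real_

  eaf_report <- NULL
  if (!is.null(eaf_max_diff)) {
    eaf_report <- filter_eaf_consistency(F, max_diff = eaf_max_diff)
    drop <- !eaf_report$keep
    if (any(drop)) {
      B[drop, ] <- NA_real_
      S[drop, ] <- NA_real_
    }
  }

  w <- 1 / S^2
  sw <- rowSums(w, na.rm = TRUE)
  k <- rowSums(!is.na(w))
  swb <- rowSums(w * B, na.rm = TRUE)
  beta_fe <- swb / sw
  se_fe <- 1 / sqrt(sw)
  q <- rowSums(w * (B - beta_fe)^2, na.rm = TRUE)
  df <- pmax(k - 1L, 0L)
  q_p <- ifelse(k >= 2L, pchisq(q, df, lower.tail = FALSE), NA_real_)
  i2 <- ifelse(k >= 2L & q > 0, pmax(0, (q - df) / q) * 100, 0)
  sw2 <- rowSums(w^2, na.rm = TRUE)
  denom <- sw - sw2 / sw
  tau2 <- ifelse(k >= 2L & denom > 0, pmax(0, (q - df) / denom), 0)

  use_re <- k >= 2L & !is.na(q_p) & q_p < fallback_q_p & i2 > fallback_i2
  ws <- 1 / (S^2 + tau2)         # recycled per column over rows
  sws <- rowSums(ws * !is.na(w), na.rm = TRUE)
  beta_re <- rowSums(ws * B, na.rm = TRUE) / sws
  se_re <- 1 / sqrt(sws)

  beta <- ifelse(use_re, beta_re, beta_fe)
  se <- ifelse(use_re, se_re, se_fe)
  z <- beta / se
  # pooled eAF: weight-weighted when weights exist, else plain mean
  wf <- ifelse(is.na(W), 1, W)
  wf[is.na(F)] <- NA_real_
  eaf_pooled <- rowSums(wf * F, na.rm = TRUE) / rowSums(wf, na.rm = TRUE)
  eaf_pooled[!is.finite(eaf_pooled)] <- NA_real_

  out <- data.frame(snp = snps, stringsAsFactors = FALSE)
  info <- map_info[match(snps, map_info$snp), , drop = FALSE]
  out$chrom <- if ("chrom" %in% names(info)) info$chrom else NA_character_
  out$pos <- if ("pos" %in% names(info)) info$pos else NA_real_
  out$ea <- if ("ea" %in% names(info)) info$ea else NA_character_
  out$oa <- if ("oa" %in% names(info)) info$oa else NA_character_
  out$eaf_pooled <- eaf_pooled
  out$beta <- beta
  out$se <- se
  out$z <- z
  out$p <- p_from_z(z)
  out$k <- k
  out$q_stat <- ifelse(k >= 2L, q, NA_real_)
  out$q_p <- q_p
  out$i2 <- i2
  out$tau2 <- ifelse(use_re, tau2, 0)
  out$model <- ifelse(use_re, "random", "fixed")
  keep <- k >= max(1L, min_k)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eaf_filter") <- eaf_report
  class(out) <- c("meta_result", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Meta-analysis of", nrow(x), "SNPs:",
      sum(x$model == "random"), "pooled under random effects,",
      sum(x$model == "fixed"), "under fixed effects\n")
  rej <- attr(x, "eaf_filter")
  if (!is.null(rej) && any(!rej$keep))
    cat(sum(!rej$keep), "SNP(s) removed by the cross-study eAF filter\n")
  print(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write a meta-analysis result table
#'
#' @param meta a \code{meta_result}.
#' @param path output path for tab-delimited text.
#' @return \code{path}, invisibly.
#' @export
write_meta <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}
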