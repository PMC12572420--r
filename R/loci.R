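# Known-locus database construction and distance-based novelty screening.
# LD is consumed as a precomputed pairwise r-squared table; clumping is the
# classic greedy pass over ascending p-values.

#' Clumping parameters
#'
#' @param r2_threshold LD r-squared at or above which two nearby SNPs are
#'   considered dependent (set 0 for pure-distance exclusion).
#' @param window_kb window in kilobases within which the r-squared rule
#'   applies.
#' @param p_threshold only SNPs with p strictly below this enter clumping.
#' @return list of class \code{clump_params}.
#' @export
clump_params <- function(r2_threshold = 0.001, window_kb = 10000,
                         p_threshold = 5e-6) {
  stopifnot(r2_threshold >= 0, r2_threshold < 1, window_kb > 0,
            p_threshold > 0)
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p_threshold = p_threshold), class = "clump_params")
}

# Build a fast pair -> r2 lookup from a long (snp_a, snp_b, r2) table.
.ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L)
    return(function(a, b) 0)
  key <- c(paste(ld$snp_a, ld$snp_b, sep = "\r"),
           paste(ld$snp_b, ld$snp_a, sep = "\r"))
  val <- c(ld$r2, ld$r2)
  env <- new.env(hash = TRUE, size = length(key))
  for (i in seq_along(key)) assign(key[i], val[i], envir = env)
  function(a, b) {
    v <- get0(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)
    v
  }
}

#' Greedy LD clumping
#'
#' Sorts candidate SNPs by ascending p-value (ties by chromosome, position,
#' then id, for determinism) and accepts a SNP iff no already-accepted SNP
#' on the same chromosome lies within \code{window_kb} AND has r-squared at
#' or above \code{r2_threshold} with it.  A SNP is excluded only when it is
#' both near and correlated; pairs absent from the LD table count as
#' r-squared 0.  Only records with \code{p < p_threshold} enter.
#'
#' @param records data.frame with \code{snp}, \code{chrom}, \code{pos},
#'   \code{p}.
#' @param ld data.frame with \code{snp_a}, \code{snp_b}, \code{r2} (or
#'   \code{NULL} for no LD).
#' @param params a [clump_params()] object.
#' @return data.frame of index variants (\code{snp}, \code{chrom},
#'   \code{pos}, \code{p}) in acceptance order.
#' @export
ld_clump <- function(records, ld = NULL, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"))
  cand <- records[!is.na(records$p) & records$p < params$p_threshold, ,
                  drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(snp = character(), chrom = character(),
                      pos = numeric(), p = numeric()))
  cand <- cand[order(cand$p, cand$chrom, cand$pos, cand$snp), , drop = FALSE]
  if (!is.null(ld) && nrow(ld))   # only pairs among candidates matter
    ld <- ld[ld$snp_a %in% cand$snp & ld$snp_b %in% cand$snp, , drop = FALSE]
  r2 <- .ld_lookup(ld)
  win <- params$window_kb * 1000
  acc_snp <- character(0); acc_chr <- character(0); acc_pos <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$snp[i]; ch <- cand$chrom[i]; ps <- cand$pos[i]
    near <- which(acc_chr == ch & abs(acc_pos - ps) <= win)
    blocked <- FALSE
    for (j in near) {
      if (r2(s, acc_snp[j]) >= params$r2_threshold) { blocked <- TRUE; break }
    }
    if (!blocked) {
      acc_snp <- c(acc_snp, s); acc_chr <- c(acc_chr, ch)
      acc_pos <- c(acc_pos, ps)
    }
  }
  out <- cand[match(acc_snp, cand$snp), c("snp", "chrom", "pos", "p"),
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a known-locus database from per-study suggestive hits
#'
#' Clumps each study independently at the suggestive threshold (default
#' p < 5e-6, r-squared < 0.001 within 10,000 kb) and takes the union of the
#' resulting index variants, sorted per chromosome with duplicate positions
#' collapsed.
#'
#' @param per_study_records named list of per-study summary-statistics
#'   data.frames (need \code{snp}, \code{chrom}, \code{pos}, \code{p}).
#' @param ld pairwise r-squared table as in [ld_clump()].
#' @param params a [clump_params()]; default mirrors the suggestive
#'   known-locus settings.
#' @return data.frame (\code{chrom}, \code{pos}, \code{snp},
#'   \code{source_study}) sorted by chromosome then position.
#' @export
build_known_db <- function(per_study_records, ld = NULL,
                           params = clump_params()) {
  if (is.null(names(per_study_records)))
    names(per_study_records) <- paste0("study", seq_along(per_study_records))
  pieces <- lapply(names(per_study_records), function(nm) {
    idx <- ld_clump(per_study_records[[nm]], ld, params)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(chrom = idx$chrom, pos = idx$pos, snp = idx$snp,
               source_study = nm, stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, pieces)
  if (is.null(db))
    return(data.frame(chrom = character(), pos = numeric(),
                      snp = character(), source_study = character()))
  db <- db[!duplicated(db[, c("chrom", "pos")]), , drop = FALSE]
  db <- db[order(db$chrom, db$pos), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Screen meta-analysis hits for novelty by distance to known loci
#'
#' A significant hit is novel iff, on its chromosome, the nearest
#' known-locus position is at distance >= \code{min_dist_kb} kilobases
#' (a distance of exactly \code{min_dist_kb} counts as novel), or the
#' chromosome is absent from the database.
#'
#' @param meta_hits data.frame with \code{snp}, \code{chrom}, \code{pos},
#'   \code{p} (typically a \code{meta_result}).
#' @param db known-locus database from [build_known_db()].
#' @param min_dist_kb minimum distance to any known locus (default 500).
#' @param p_threshold significance filter applied before screening
#'   (default genome-wide 5e-8).
#' @return data.frame of novel hits with an added
#'   \code{dist_nearest_known} column (\code{Inf} when the chromosome has
#'   no known locus).
#' @export
screen_novel <- function(meta_hits, db, min_dist_kb = 500,
                         p_threshold = 5e-8) {
  hits <- meta_hits[!is.na(meta_hits$p) & meta_hits$p < p_threshold, ,
                    drop = FALSE]
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0L) {
    hits$dist_nearest_known <- numeric(0)
    return(hits)
  }
  dist <- rep(Inf, nrow(hits))
  for (ch in unique(hits$chrom)) {
    kp <- sort(db$pos[db$chrom == ch])
    if (length(kp) == 0L) next
    sel <- which(hits$chrom == ch)
    idx <- findInterval(hits$pos[sel], kp)
    lo <- ifelse(idx >= 1L, hits$pos[sel] - kp[pmax(idx, 1L)], Inf)
    hi <- ifelse(idx < length(kp), kp[pmin(idx + 1L, length(kp))] - hits$pos[sel], Inf)
    dist[sel] <- pmin(abs(lo), abs(hi))
  }
  novel <- dist >= min_dist_kb * 1000
  out <- hits[novel, , drop = FALSE]
  out$dist_nearest_known <- dist[novel]
  rownames(out) <- NULL
  out
}

#' Read / write helpers for LD tables and known-locus databases
#'
#' @param path delimited text path.
#' @return data.frame.
#' @export
read_ld_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(dt)))
  dt
}

#' @rdname read_ld_table
#' @param db known-locus database data.frame.
#' @export
write_known_db <- function(db, path) {
  data.table::fwrite(db, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname read_ld_table
#' @export
read_known_db <- function(path) {
  data.table::fread(path, header = TRUE, data.table = FALSE,
                    colClasses = list(character = "chrom"))
}
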