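#' @importFrom stats pnorm pchisq qnorm pt lm phyper p.adjust density mad
#'   median sd setNames rnorm runif rbinom
#' @importFrom utils head combn modifyList packageVersion
NULL

# Canonical column order for a summary-statistics table.
.SUMSTAT_COLS <- c("snp", "chrom", "pos", "ea", "oa", "eaf",
                   "beta", "se", "p", "weight", "z")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- (or otherwise-) delimited summary-statistics file with a
#' header, maps its columns onto the canonical names used throughout the
#' package, validates every row, and returns the valid records together with
#' a validation report of rejected rows.  Gzip-compressed files are read
#' transparently.
#'
#' Required columns are the SNP identifier, chromosome, position and the two
#' alleles; in addition at least one of the effect parameterisations
#' \code{beta+se}, \code{z+weight+eaf} or \code{p+beta} must be resolvable.
#' Rows violating the record invariants (non-positive SE, frequency outside
#' \[0,1\], identical alleles, p outside (0,1\], unparseable numerics) are
#' rejected, counted and reported -- never silently dropped.
#'
#' @param path file path to delimited text (optionally .gz).
#' @param column_map named character vector mapping canonical names
#'   (\code{snp}, \code{chrom}, \code{pos}, \code{ea}, \code{oa},
#'   \code{eaf}, \code{beta}, \code{se}, \code{p}, \code{weight}, \code{z})
#'   to the column names present in the file.  Canonical names already
#'   present in the file need not be mapped.
#' @param sep field separator passed to the reader (default tab).
#' @return a \code{data.frame} of valid records with canonical columns; the
#'   rejected rows (with a \code{reason} and 1-based data \code{line}) are
#'   attached as attribute \code{"rejected"}, and \code{n_rejected} gives
#'   their count.
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "\t") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, showProgress = FALSE,
                          colClasses = list(character = 1L))
  # apply column map (canonical -> file name)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(dt))
        stop("column '", src, "' (mapped to '", canon,
             "') not found in ", path, call. = FALSE)
      names(dt)[names(dt) == src] <- canon
    }
  }
  required <- c("snp", "chrom", "pos", "ea", "oa")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has <- function(...) all(c(...) %in% names(dt))
  if (!(has("beta", "se") || has("z", "weight", "eaf") || has("p", "beta")))
    stop("need one of beta+se, z+weight+eaf or p+beta column sets",
         call. = FALSE)
  for (col in setdiff(.SUMSTAT_COLS, names(dt))) dt[[col]] <- NA_real_
  dt$snp <- as.character(dt$snp)
  dt$chrom <- as.character(dt$chrom)
  dt$ea <- toupper(as.character(dt$ea))
  dt$oa <- toupper(as.character(dt$oa))
  num_cols <- c("pos", "eaf", "beta", "se", "p", "weight", "z")
  reasons <- character(nrow(dt))
  for (col in num_cols) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(parsed)
      reasons[bad & reasons == ""] <- paste0("unparseable numeric in '", col, "'")
      dt[[col]] <- parsed
    }
  }
  fail <- function(cond, why) reasons[cond & reasons == ""] <<- why
  fail(is.na(dt$snp) | dt$snp == "", "missing snp id")
  fail(dt$ea == dt$oa, "identical alleles")
  fail(!is.na(dt$se) & dt$se <= 0, "non-positive se")
  fail(!is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1), "eaf outside [0,1]")
  fail(!is.na(dt$p) & (dt$p <= 0 | dt$p > 1), "p outside (0,1]")
  fail(!is.na(dt$weight) & dt$weight < 0, "negative weight")
  zchk <- !is.na(dt$beta) & !is.na(dt$se) & !is.na(dt$z) & dt$se > 0
  fail(zchk & abs(dt$z - dt$beta / dt$se) >
         1e-6 * pmax(1, abs(dt$z)), "z inconsistent with beta/se")
  ok <- reasons == ""
  out <- dt[ok, .SUMSTAT_COLS, drop = FALSE]
  rownames(out) <- NULL
  rejected <- data.frame(line = which(!ok), reason = reasons[!ok],
                         snp = dt$snp[!ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  attr(out, "n_rejected") <- nrow(rejected)
  out
}

#' Write summary statistics to delimited text
#'
#' @param records data.frame of canonical summary-statistics records.
#' @param path output path (\code{.gz} writes compressed).
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cols <- intersect(.SUMSTAT_COLS, names(records))
  data.table::fwrite(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a validation report of rejected rows
#'
#' @param records value returned by [read_sumstats()].
#' @param path output path for a tab-delimited report (line, reason, snp).
#' @return \code{path}, invisibly.
#' @export
write_validation_report <- function(records, path) {
  rej <- attr(records, "rejected")
  if (is.null(rej)) rej <- data.frame(line = integer(), reason = character(),
                                      snp = character())
  data.table::fwrite(rej, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Recover beta and SE from Z-score, frequency and effective sample size
#'
#' Converts a sample-size-scheme association back to the beta/SE scale with
#' \deqn{SE = 1 / \sqrt{2 f (1-f) (w + Z^2)}, \qquad \beta = SE \cdot Z,}
#' where \eqn{f} is the effect-allele frequency and \eqn{w} the effective
#' sample-size weight.  Vectorised over all arguments.
#'
#' @param z signed Z-score.
#' @param eaf effect-allele frequency, strictly inside (0,1).
#' @param weight effective sample size, > 0.
#' @return list with components \code{beta} and \code{se}.
#' @examples
#' recover_beta_se(z = 1, eaf = 0.5, weight = 9999)
#' @export
recover_beta_se <- function(z, eaf, weight) {
  if (any(eaf <= 0 | eaf >= 1))
    stop("degenerate effect-allele frequency (must be strictly inside (0,1))",
         call. = FALSE)
  if (any(weight <= 0)) stop("weight must be > 0", call. = FALSE)
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * (weight + z^2))
  list(beta = se * z, se = se)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(allele) {
  vapply(strsplit(allele, "", fixed = TRUE), function(ch) {
    paste(rev(unname(.COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & .revcomp(ea) == oa
}

#' Align records to a reference allele orientation
#'
#' Brings each record onto the orientation of a reference effect/other
#' allele pair.  Identical orientation is kept; swapped alleles negate beta
#' and z and replace eaf by 1-eaf; otherwise a reverse-complement rescue is
#' attempted for non-palindromic pairs (palindromic A/T, C/G mismatches are
#' excluded -- frequency-based resolution belongs to the MR harmoniser).
#' Records matching neither orientation are flagged for exclusion.
#'
#' Applying the swap twice (against swapped references) is an involution.
#'
#' @param records data.frame of summary-statistics records.
#' @param ref_ea,ref_oa reference alleles, recycled to \code{nrow(records)}.
#' @return \code{records} with adjusted \code{beta}, \code{z}, \code{eaf},
#'   \code{ea}, \code{oa} and an added \code{align_status} column, one of
#'   \code{"match"}, \code{"swap"}, \code{"strand"}, \code{"strand_swap"},
#'   \code{"exclude"}.  Excluded rows are returned unchanged apart from the
#'   status flag.
#' @export
align_to_reference <- function(records, ref_ea, ref_oa) {
  n <- nrow(records)
  ref_ea <- rep_len(toupper(ref_ea), n)
  ref_oa <- rep_len(toupper(ref_oa), n)
  ea <- toupper(records$ea); oa <- toupper(records$oa)
  status <- rep("exclude", n)
  status[ea == ref_ea & oa == ref_oa] <- "match"
  status[ea == ref_oa & oa == ref_ea] <- "swap"
  unresolved <- status == "exclude"
  if (any(unresolved)) {
    pal <- .is_palindromic(ea[unresolved], oa[unresolved])
    rc_ea <- .revcomp(ea[unresolved]); rc_oa <- .revcomp(oa[unresolved])
    st <- rep("exclude", sum(unresolved))
    st[!pal & rc_ea == ref_ea[unresolved] & rc_oa == ref_oa[unresolved]] <- "strand"
    st[!pal & rc_ea == ref_oa[unresolved] & rc_oa == ref_ea[unresolved]] <- "strand_swap"
    status[unresolved] <- st
  }
  flip <- status %in% c("swap", "strand_swap")
  keepdir <- status %in% c("match", "strand")
  out <- records
  if (any(flip)) {
    if ("beta" %in% names(out)) out$beta[flip] <- -out$beta[flip]
    if ("z" %in% names(out)) out$z[flip] <- -out$z[flip]
    if ("eaf" %in% names(out)) out$eaf[flip] <- 1 - out$eaf[flip]
  }
  fixed <- flip | keepdir
  out$ea[fixed] <- ref_ea[fixed]
  out$oa[fixed] <- ref_oa[fixed]
  out$align_status <- status
  out
}

#' Cross-study effect-allele frequency consistency filter
#'
#' Flags SNPs whose effect-allele frequency range across studies exceeds
#' \code{max_diff} (drop iff \code{max(eaf) - min(eaf) > max_diff}, strict;
#' a range of exactly \code{max_diff} is kept).  Single-study SNPs are kept
#' and flagged unchecked.  Mirrors the AVERAGEFREQ/MINMAXFREQ bookkeeping of
#' standard meta-analysis tooling.
#'
#' @param eaf_by_study numeric matrix (SNP x study) of effect-allele
#'   frequencies, \code{NA} where a study lacks the SNP; row names are SNP
#'   ids.
#' @param max_diff maximum tolerated frequency range (default 0.2).
#' @return data.frame with \code{snp}, \code{eaf_min}, \code{eaf_max},
#'   \code{n_studies}, \code{checked}, \code{keep}.
#' @export
filter_eaf_consistency <- function(eaf_by_study, max_diff = 0.2) {
  eaf_by_study <- as.matrix(eaf_by_study)
  k <- rowSums(!is.na(eaf_by_study))
  mn <- suppressWarnings(apply(eaf_by_study, 1, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(eaf_by_study, 1, max, na.rm = TRUE))
  mn[k == 0] <- NA_real_; mx[k == 0] <- NA_real_
  checked <- k >= 2
  keep <- !checked | (mx - mn) <= max_diff
  data.frame(snp = rownames(eaf_by_study) %||% as.character(seq_along(k)),
             eaf_min = mn, eaf_max = mx, n_studies = k,
             checked = checked, keep = keep,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p from z, safe far into the tail (log-space beyond the
# double-precision underflow point).
p_from_z <- function(z, log10p = FALSE) {
  lp <- pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  if (log10p) lp / log(10) else exp(lp)
}
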