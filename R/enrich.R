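# Hypergeometric over-representation of SNP sets in eQTL contexts and of
# gene lists in GMT gene sets, with Benjamini-Hochberg FDR control.

#' Upper-tail hypergeometric probability
#'
#' \deqn{P(X \ge k) = 1 - \sum_{i=0}^{k-1}
#'   \binom{m}{i}\binom{n}{r-i} / \binom{m+n}{r}}
#' where \code{m} is the number of query (GWAS) SNPs, \code{n} the number
#' of non-query background SNPs, \code{r} the number of context (eQTL)
#' SNPs drawn and \code{k} the observed overlap.  Computed via
#' \code{stats::phyper}, which evaluates the tail in log-space and is
#' stable for backgrounds up to 1e7 and beyond.
#'
#' @param m,n,r,k hypergeometric counts (all >= 0, \code{k <= min(m, r)},
#'   \code{r <= m + n}); vectorised.
#' @return upper-tail probability in \[0,1\] (1 when \code{k = 0}).
#' @examples
#' hypergeom_upper_tail(m = 2, n = 2, r = 2, k = 2)  # 1/6
#' @export
hypergeom_upper_tail <- function(m, n, r, k) {
  if (any(m < 0 | n < 0 | r < 0 | k < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(k > pmin(m, r)))
    stop("overlap k cannot exceed min(m, r)", call. = FALSE)
  if (any(r > m + n))
    stop("draw r cannot exceed the background m + n", call. = FALSE)
  phyper(k - 1, m, n, r, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up (adjusted_i = min over j with rank >= rank(i) of
#' M * p_(j) / j, clamped at 1), returned in the input order.  Delegates to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals numeric p-values in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' SNP-set enrichment across eQTL contexts
#'
#' For each context (brain region, cell type, ...) computes the overlap of
#' the query SNP set with the context's eQTL SNP set, the upper-tail
#' hypergeometric p against a genome-wide background, BH adjustment across
#' the supplied contexts (one family per call), and the enrichment factor
#' \eqn{k / (r m / (m+n))} (observed over expected overlap).
#'
#' @param query_snps character vector of query SNP ids (e.g. novel loci).
#' @param contexts named list of character vectors, one eQTL SNP set per
#'   context label.
#' @param genome_background total number of SNPs in the background
#'   universe; must be at least the size of the union of all sets.
#' @return data.frame (\code{context}, \code{m}, \code{n}, \code{r},
#'   \code{k}, \code{p}, \code{p_adj}, \code{enrichment_factor}) ordered as
#'   supplied.
#' @export
enrich_contexts <- function(query_snps, contexts, genome_background) {
  query_snps <- unique(query_snps)
  m <- length(query_snps)
  if (genome_background < length(unique(c(query_snps,
                                          unlist(contexts, use.names = FALSE)))))
    stop("genome_background smaller than the union of the supplied sets",
         call. = FALSE)
  n <- genome_background - m
  rows <- lapply(names(contexts), function(lab) {
    set <- unique(contexts[[lab]])
    r <- length(set)
    k <- length(intersect(query_snps, set))
    expected <- r * m / (m + n)
    data.frame(context = lab, m = m, n = n, r = r, k = k,
               p = hypergeom_upper_tail(m, n, r, k),
               enrichment_factor = if (expected > 0) k / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("context", "m", "n", "r", "k", "p", "p_adj", "enrichment_factor")]
}

#' Over-representation analysis of a gene list against GMT gene sets
#'
#' The same hypergeometric statistic as [enrich_contexts()] with genes as
#' elements: per set, m = query genes, r = set size, k = overlap, against a
#' fixed gene universe.  Symbols are upper-cased before matching.  The
#' per-set overlap gene count is reported for bubble plots.
#'
#' @param gene_list character vector of query gene symbols.
#' @param gmt_sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe_size number of genes in the universe (> 0).
#' @return data.frame (\code{set}, \code{m}, \code{n}, \code{r}, \code{k},
#'   \code{p}, \code{p_adj}, \code{enrichment_factor}, \code{genes}).
#' @export
ora_gmt <- function(gene_list, gmt_sets, universe_size) {
  if (universe_size <= 0) stop("empty gene universe", call. = FALSE)
  gene_list <- unique(toupper(gene_list))
  gmt_sets <- lapply(gmt_sets, function(s) unique(toupper(s)))
  m <- length(gene_list)
  n <- universe_size - m
  rows <- lapply(names(gmt_sets), function(lab) {
    set <- gmt_sets[[lab]]
    r <- length(set)
    hit <- intersect(gene_list, set)
    k <- length(hit)
    expected <- r * m / (m + n)
    data.frame(set = lab, m = m, n = n, r = r, k = k,
               p = hypergeom_upper_tail(m, n, r, k),
               enrichment_factor = if (expected > 0) k / expected else NA_real_,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("set", "m", "n", "r", "k", "p", "p_adj", "enrichment_factor",
          "genes")]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read SNP-set contexts from a long two-column table
#'
#' @param path delimited text with columns \code{context}, \code{snp}.
#' @return named list of SNP id vectors.
#' @export
read_contexts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("context", "snp") %in% names(dt)))
  split(as.character(dt$snp), dt$context)
}
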