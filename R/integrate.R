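# Cross-dimension intersection and joint reporting: which SNPs recur
# across novelty screening, MR instrument sets, SMR top SNPs and
# enrichment contexts — the candidates for pleiotropic hub status.

#' Intersect MR instrument sets with the novel-SNP set
#'
#' @param instrument_sets named list of per-direction SNP id sets (e.g.
#'   \code{list(forward = ..., reverse = ...)}).
#' @param novel character vector of novel SNP ids.
#' @return named list of per-direction intersections.
#' @export
common_snps <- function(instrument_sets, novel) {
  lapply(instrument_sets, function(s) intersect(s, novel))
}

#' Top SNPs shared by every SMR scan version
#'
#' Intersects the \code{topSNP} columns of two or more SMR scans,
#' restricted to significant rows (FDR_BH below \code{fdr_max}) within
#' each version.
#'
#' @param smr_tables named list of \code{smr_scan} tables (>= 2).
#' @param fdr_max per-version significance cutoff (default 0.05).
#' @return character vector of SNP ids appearing as a significant top SNP
#'   in every version.
#' @export
cross_version_top_overlap <- function(smr_tables, fdr_max = 0.05) {
  if (length(smr_tables) < 2L)
    stop("need at least 2 SMR scan versions to intersect", call. = FALSE)
  sets <- lapply(smr_tables, function(tab)
    unique(tab$topSNP[!is.na(tab$FDR_BH) & tab$FDR_BH < fdr_max]))
  Reduce(intersect, sets)
}

#' Joint cross-dimension report
#'
#' Builds one row per SNP appearing in at least one analysis dimension
#' (novel locus, forward/reverse MR instrument, significant SMR top SNP
#' per version, significantly enriched contexts containing the SNP) and
#' ranks SNPs by the number of satisfied dimensions (descending), ties by
#' SNP id — the top rows are the pleiotropic hub candidates.  The report
#' is idempotent and independent of input row order.
#'
#' @param novel annotated novel-locus table (needs \code{snp}; uses
#'   \code{nearest_gene}/\code{pops_gene} when present).
#' @param instrument_sets named list of per-direction instrument SNP sets.
#' @param smr_tables named list of \code{smr_scan} tables (may be empty).
#' @param contexts named list of context SNP sets (optional).
#' @param significant_contexts labels of contexts that passed enrichment
#'   (subset of \code{names(contexts)}).
#' @param fdr_max SMR significance cutoff (default 0.05).
#' @return data.frame with \code{snp}, \code{n_dimensions},
#'   \code{in_novel}, one logical column per MR direction, per SMR
#'   version, \code{enriched_contexts} (comma-joined labels),
#'   \code{nearest_gene}, \code{pops_gene}.
#' @export
joint_report <- function(novel, instrument_sets = list(),
                         smr_tables = list(), contexts = list(),
                         significant_contexts = character(0),
                         fdr_max = 0.05) {
  novel_snps <- unique(novel$snp)
  smr_sets <- lapply(smr_tables, function(tab)
    unique(tab$topSNP[!is.na(tab$FDR_BH) & tab$FDR_BH < fdr_max]))
  ctx_sets <- contexts[names(contexts) %in% significant_contexts]
  all_snps <- sort(unique(c(novel_snps,
                            unlist(instrument_sets, use.names = FALSE),
                            unlist(smr_sets, use.names = FALSE))))
  if (length(all_snps) == 0L)
    return(data.frame(snp = character(), n_dimensions = integer(),
                      in_novel = logical(), stringsAsFactors = FALSE))
  out <- data.frame(snp = all_snps, stringsAsFactors = FALSE)
  out$in_novel <- out$snp %in% novel_snps
  dims <- as.integer(out$in_novel)
  for (dir in names(instrument_sets)) {
    col <- paste0("in_mr_", dir)
    out[[col]] <- out$snp %in% instrument_sets[[dir]]
    dims <- dims + as.integer(out[[col]])
  }
  for (ver in names(smr_sets)) {
    col <- paste0("smr_top_", ver)
    out[[col]] <- out$snp %in% smr_sets[[ver]]
    dims <- dims + as.integer(out[[col]])
  }
  enr <- vapply(out$snp, function(s) {
    labs <- names(ctx_sets)[vapply(ctx_sets, function(set) s %in% set,
                                   logical(1))]
    paste(labs, collapse = ",")
  }, character(1))
  out$enriched_contexts <- enr
  dims <- dims + as.integer(enr != "")
  out$n_dimensions <- dims
  idx <- match(out$snp, novel$snp)
  out$nearest_gene <- if ("nearest_gene" %in% names(novel))
    novel$nearest_gene[idx] else NA_character_
  out$pops_gene <- if ("pops_gene" %in% names(novel))
    novel$pops_gene[idx] else NA_character_
  out <- out[order(-out$n_dimensions, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  front <- c("snp", "n_dimensions", "in_novel")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}
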