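# Gene-window annotation of novel SNPs: window genes, nearest gene and
# distance, and the best PoPS (polygenic priority score) gene per SNP.

#' Read a gene annotation table
#'
#' Accepts BED (0-based half-open, converted to 1-based inclusive on read)
#' or a delimited table already carrying 1-based \code{start}/\code{end}.
#' Columns: chrom, start, end, gene_id, symbol (header optional for BED).
#'
#' @param path file path.
#' @param format \code{"bed"} (0-based half-open, no header required) or
#'   \code{"table"} (1-based, header required).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}, \code{symbol}; 1-based inclusive coordinates.
#' @export
read_gene_table <- function(path, format = c("table", "bed")) {
  format <- match.arg(format)
  header <- format == "table"
  dt <- data.table::fread(path, header = header, data.table = FALSE)
  if (!header) {
    names(dt)[1:5] <- c("chrom", "start", "end", "gene_id", "symbol")
    dt$start <- dt$start + 1L            # BED 0-based half-open -> 1-based
  }
  stopifnot(all(c("chrom", "start", "end", "gene_id", "symbol") %in% names(dt)))
  dt$chrom <- as.character(dt$chrom)
  stopifnot(all(dt$start <= dt$end))
  dt
}

#' Genes within a window of a SNP
#'
#' Returns every gene on the SNP's chromosome whose body intersects
#' \code{[pos - window, pos + window]}, the nearest gene and its distance.
#' Distance to a gene is 0 when the SNP lies inside the gene body,
#' otherwise \code{min(|pos - start|, |pos - end|)}; distances are
#' independent of strand and of gene ordering.
#'
#' @param chrom,pos SNP chromosome and 1-based position.
#' @param genes gene table from [read_gene_table()].
#' @param window_kb half-window in kilobases (default 500).
#' @return list with \code{all_genes} (symbols, ordered by distance then
#'   symbol), \code{nearest_gene} (\code{NA} when the window is empty),
#'   \code{distance}, and \code{distances} (named by symbol).
#' @export
genes_in_window <- function(chrom, pos, genes, window_kb = 500) {
  win <- window_kb * 1000
  g <- genes[genes$chrom == chrom & genes$end >= pos - win &
               genes$start <= pos + win, , drop = FALSE]
  if (nrow(g) == 0L)
    return(list(all_genes = character(0), nearest_gene = NA_character_,
                distance = NA_real_, distances = numeric(0)))
  d <- ifelse(pos >= g$start & pos <= g$end, 0,
              pmin(abs(pos - g$start), abs(pos - g$end)))
  ord <- order(d, g$symbol)
  d <- d[ord]; g <- g[ord, , drop = FALSE]
  list(all_genes = g$symbol, nearest_gene = g$symbol[1], distance = d[1],
       distances = setNames(d, g$symbol))
}

#' Best PoPS gene among a SNP's window genes
#'
#' Among window genes that have a PoPS score, returns the maximum-score
#' gene.  Negative scores are legitimate maxima (no sign filtering).  Ties
#' at the maximum score break to the gene nearest the SNP, then
#' lexicographically by symbol.  When no window gene is scored both fields
#' are \code{NA}.
#'
#' @param all_genes character vector of window gene symbols.
#' @param pops_table named numeric vector (symbol -> score) or two-column
#'   data.frame (\code{symbol}, \code{score}).
#' @param distances optional named distances (symbol -> bp) for tie-breaks.
#' @return list with \code{pops_gene} and \code{pops_score}.
#' @export
match_pops <- function(all_genes, pops_table, distances = NULL) {
  if (is.data.frame(pops_table))
    pops_table <- setNames(pops_table[[2]], pops_table[[1]])
  scored <- all_genes[all_genes %in% names(pops_table)]
  if (length(scored) == 0L)
    return(list(pops_gene = NA_character_, pops_score = NA_real_))
  sc <- pops_table[scored]
  top <- scored[sc == max(sc)]
  if (length(top) > 1L) {
    if (!is.null(distances) && all(top %in% names(distances)))
      top <- top[order(distances[top], top)]
    else top <- sort(top)
  }
  list(pops_gene = top[1], pops_score = unname(pops_table[top[1]]))
}

#' Read a two-column PoPS score table
#'
#' @param path delimited text with gene symbol and score columns.
#' @return named numeric vector (symbol -> score).
#' @export
read_pops_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Annotate novel loci with window genes and PoPS scores
#'
#' @param novel data.frame of novel hits (\code{snp}, \code{chrom},
#'   \code{pos}, \code{ea}, \code{oa}, \code{beta}, \code{se}, \code{p}).
#' @param genes gene table from [read_gene_table()].
#' @param pops_table named score vector as in [match_pops()].
#' @param window_kb half-window in kilobases (default 500).
#' @return data.frame of annotated loci, one row per SNP, with
#'   \code{nearest_gene}, \code{distance}, \code{all_genes}
#'   (comma-separated), \code{pops_gene}, \code{pops_score}.
#' @export
annotate_loci <- function(novel, genes, pops_table = NULL, window_kb = 500) {
  rows <- lapply(seq_len(nrow(novel)), function(i) {
    w <- genes_in_window(novel$chrom[i], novel$pos[i], genes, window_kb)
    pp <- if (is.null(pops_table))
      list(pops_gene = NA_character_, pops_score = NA_real_)
    else match_pops(w$all_genes, pops_table, w$distances)
    data.frame(snp = novel$snp[i], chrom = novel$chrom[i],
               pos = novel$pos[i],
               ea = novel$ea[i] %||% NA_character_,
               oa = novel$oa[i] %||% NA_character_,
               beta = novel$beta[i] %||% NA_real_,
               se = novel$se[i] %||% NA_real_,
               p = novel$p[i] %||% NA_real_,
               nearest_gene = w$nearest_gene,
               distance = w$distance,
               all_genes = paste(w$all_genes, collapse = ","),
               pops_gene = pp$pops_gene, pops_score = pp$pops_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp = character(), chrom = character(),
                      pos = numeric(), ea = character(), oa = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      nearest_gene = character(), distance = numeric(),
                      all_genes = character(), pops_gene = character(),
                      pops_score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.TABLE1_COLS <- c("SNP", "CHR", "BP", "EA", "OA", "beta", "se", "P",
                  "Nearest_Gene", "Distance", "ALL_genes", "PoPS_gene",
                  "PoPS_score")

#' Write / read the annotated-locus table
#'
#' Serialises annotated loci with the exact 13-column schema
#' \code{SNP, CHR, BP, EA, OA, beta, se, P, Nearest_Gene, Distance,
#' ALL_genes, PoPS_gene, PoPS_score}.
#'
#' @param annotated data.frame from [annotate_loci()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_loci <- function(annotated, path) {
  out <- data.frame(SNP = annotated$snp, CHR = annotated$chrom,
                    BP = annotated$pos, EA = annotated$ea,
                    OA = annotated$oa, beta = annotated$beta,
                    se = annotated$se, P = annotated$p,
                    Nearest_Gene = annotated$nearest_gene,
                    Distance = annotated$distance,
                    ALL_genes = annotated$all_genes,
                    PoPS_gene = annotated$pops_gene,
                    PoPS_score = annotated$pops_score,
                    stringsAsFactors = FALSE)
  stopifnot(identical(names(out), .TABLE1_COLS))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_annotated_loci
#' @export
read_annotated_loci <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("CHR")))
  stopifnot(identical(names(dt), .TABLE1_COLS))
  data.frame(snp = as.character(dt$SNP), chrom = as.character(dt$CHR),
             pos = dt$BP, ea = as.character(dt$EA),
             oa = as.character(dt$OA),
             beta = dt$beta, se = dt$se, p = dt$P,
             nearest_gene = as.character(dt$Nearest_Gene),
             distance = dt$Distance,
             all_genes = as.character(dt$ALL_genes),
             pops_gene = as.character(dt$PoPS_gene),
             pops_score = dt$PoPS_score, stringsAsFactors = FALSE)
}
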