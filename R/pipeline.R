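# Config-driven end-to-end runner: meta -> loci -> annotate ->
# enrich / smr / mr -> integrate, with a provenance manifest.  The
# function interface is the entry point; a config can be an R list or a
# YAML file.

#' Default pipeline configuration
#'
#' Thresholds mirror the pipeline's published defaults: suggestive
#' known-locus clumping at p < 5e-6 (r-squared < 0.001, 10,000 kb),
#' genome-wide significance 5e-8, 500 kb novelty distance and gene
#' window, heterogeneity fallback at Q-test p < 0.1 and I-squared > 50%,
#' forward MR at p < 1e-5 (r-squared 0.1, 500 kb), reverse MR at p < 5e-6
#' (r-squared < 0.001, 10,000 kb), F > 10, BH alpha 0.05, PRESSO 1000
#' simulations.
#'
#' @return named list of defaults; override entries via the \code{config}
#'   argument of [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(fallback_q_p = 0.1, fallback_i2 = 50, eaf_max_diff = 0.2,
       known_p = 5e-6, known_r2 = 0.001, known_kb = 10000,
       sig_p = 5e-8, novel_dist_kb = 500, window_kb = 500,
       p_eqtl_max = 5e-8, genome_background = 1e7,
       bh_alpha = 0.05, presso_n_sim = 1000, fdr_max = 0.05)
}

.validate_config <- function(config) {
  num <- c("fallback_q_p", "fallback_i2", "eaf_max_diff", "known_p",
           "known_r2", "known_kb", "sig_p", "novel_dist_kb", "window_kb",
           "p_eqtl_max", "genome_background", "bh_alpha", "presso_n_sim",
           "fdr_max")
  for (k in num) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid config value for '", k, "'", call. = FALSE)
  }
  invisible(config)
}

#' Run the integration pipeline end to end
#'
#' Stages run in dependency order; \code{stages} selects a subset (their
#' prerequisites must be included or already present in \code{inputs}).
#' All stochastic stages derive their streams from \code{seed}, so a rerun
#' with identical inputs and seed reproduces identical outputs.
#'
#' @param inputs named list of stage inputs: \code{studies} (named list
#'   of summary-statistics data.frames), \code{ld}, optional
#'   \code{genes}, \code{pops}, \code{contexts}, \code{gmt},
#'   \code{eqtl_versions} (named list of eQTL tables), \code{panel}
#'   (microbiota exposure list).  Any missing optional input skips the
#'   stages that need it.
#' @param config named list overriding [pipeline_defaults()], or a path
#'   to a YAML file of overrides.
#' @param stages character vector of stage names among \code{"meta"},
#'   \code{"loci"}, \code{"annotate"}, \code{"enrich"}, \code{"smr"},
#'   \code{"mr"}, \code{"integrate"}, or \code{"all"}.
#' @param seed integer seed for the stochastic stages.
#' @param out_dir optional directory; when given, every stage's table is
#'   written there as tab-delimited text along with a JSON run manifest.
#' @return named list of stage outputs (\code{meta}, \code{known_db},
#'   \code{novel}, \code{annotated}, \code{enrichment}, \code{ora},
#'   \code{smr}, \code{mr}, \code{joint}, \code{manifest}).
#' @export
run_pipeline <- function(inputs, config = list(), stages = "all",
                         seed = 1, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  .validate_config(cfg)
  all_stages <- c("meta", "loci", "annotate", "enrich", "smr", "mr",
                  "integrate")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "), call. = FALSE)
  out <- list()
  counts <- list()

  if ("meta" %in% stages) {
    stopifnot(!is.null(inputs$studies))
    out$meta <- meta_pipeline(inputs$studies,
                              fallback_q_p = cfg$fallback_q_p,
                              fallback_i2 = cfg$fallback_i2,
                              eaf_max_diff = cfg$eaf_max_diff)
    counts$meta <- nrow(out$meta)
  }
  if ("loci" %in% stages) {
    meta <- out$meta %||% inputs$meta
    stopifnot(!is.null(meta), !is.null(inputs$studies))
    out$known_db <- build_known_db(inputs$studies, inputs$ld,
                                   clump_params(cfg$known_r2, cfg$known_kb,
                                                cfg$known_p))
    out$novel <- screen_novel(meta, out$known_db,
                              min_dist_kb = cfg$novel_dist_kb,
                              p_threshold = cfg$sig_p)
    counts$known_db <- nrow(out$known_db)
    counts$novel <- nrow(out$novel)
  }
  if ("annotate" %in% stages && !is.null(inputs$genes)) {
    novel <- out$novel %||% inputs$novel
    stopifnot(!is.null(novel))
    out$annotated <- annotate_loci(novel, inputs$genes, inputs$pops,
                                   window_kb = cfg$window_kb)
    counts$annotated <- nrow(out$annotated)
  }
  if ("enrich" %in% stages && !is.null(inputs$contexts)) {
    novel <- out$novel %||% inputs$novel
    stopifnot(!is.null(novel))
    out$enrichment <- enrich_contexts(novel$snp, inputs$contexts,
                                      cfg$genome_background)
    counts$enrichment <- nrow(out$enrichment)
    ann <- out$annotated %||% inputs$annotated
    if (!is.null(inputs$gmt) && !is.null(ann)) {
      genes <- unique(ann$pops_gene[!is.na(ann$pops_gene)])
      if (length(genes))
        out$ora <- ora_gmt(genes, inputs$gmt,
                           universe_size = length(inputs$universe_genes %||%
                                                    unique(inputs$genes$symbol)))
    }
  }
  if ("smr" %in% stages && !is.null(inputs$eqtl_versions)) {
    gwas <- out$meta %||% inputs$meta %||% inputs$gwas
    stopifnot(!is.null(gwas))
    out$smr <- lapply(inputs$eqtl_versions, function(eq)
      smr_scan(gwas, eq, p_eqtl_max = cfg$p_eqtl_max,
               snp_subset = inputs$snp_subset))
    counts$smr <- vapply(out$smr, nrow, integer(1))
  }
  if ("mr" %in% stages && !is.null(inputs$panel)) {
    outcome <- out$meta %||% inputs$meta %||% inputs$outcome
    stopifnot(!is.null(outcome))
    out$mr <- run_bidirectional(inputs$panel, outcome, inputs$ld,
                                n_sim_presso = cfg$presso_n_sim,
                                seed = seed, bh_alpha = cfg$bh_alpha)
    counts$mr_forward_sig <- sum(out$mr$significance$significant &
                                   out$mr$significance$direction == "forward")
    counts$mr_reverse_sig <- sum(out$mr$significance$significant &
                                   out$mr$significance$direction == "reverse")
  }
  if ("integrate" %in% stages) {
    novel <- out$annotated %||% out$novel %||% inputs$novel
    stopifnot(!is.null(novel))
    inst <- if (!is.null(out$mr))
      list(forward = out$mr$forward_instruments,
           reverse = out$mr$reverse_instruments)
    else list()
    sig_ctx <- if (!is.null(out$enrichment))
      out$enrichment$context[out$enrichment$p_adj < cfg$bh_alpha]
    else character(0)
    out$common <- common_snps(inst, unique(novel$snp))
    out$joint <- joint_report(novel, inst, out$smr %||% list(),
                              inputs$contexts %||% list(), sig_ctx,
                              fdr_max = cfg$fdr_max)
    counts$joint <- nrow(out$joint)
  }
  out$manifest <- list(stages = stages, seed = seed, config = cfg,
                       row_counts = counts,
                       package_version = as.character(utils::packageVersion("gibaxis")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) if (!is.null(x) && is.data.frame(x))
      data.table::fwrite(as.data.frame(x), file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, na = "NA")
    wr(out$meta, "meta"); wr(out$known_db, "known_db")
    wr(out$novel, "novel"); wr(out$annotated, "annotated")
    wr(out$enrichment, "enrichment"); wr(out$ora, "ora")
    if (!is.null(out$smr))
      for (nm in names(out$smr)) wr(out$smr[[nm]], paste0("smr_", nm))
    if (!is.null(out$mr)) wr(out$mr$significance, "mr_significance")
    wr(out$joint, "joint")
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
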