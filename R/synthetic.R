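# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth, so all stages are testable without any download.  Summary
# statistics are simulated directly (no individual-level genotypes); LD
# enters only through the pairwise r-squared table that clumping consumes.
# Every generator is a pure function of its config: the same config gives
# byte-identical output on every call.

# effective per-study sample size for a case/control design
.effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' four case/control studies with the source studies' sample sizes, a
#' microbiota-abundance panel measured in 5,959 individuals scaled to 20
#' traits with two causal taxa at effects +/-0.15, 50,000 SNPs in LD
#' blocks, 200 genes, and a point-normal effect distribution (1% causal,
#' sd 0.05) on the log-odds scale.
#'
#' @param seed integer RNG seed; every generator derives its stream from
#'   it.
#' @param n_snps number of SNPs on the map.
#' @param n_studies number of GWAS studies.
#' @param maf_range uniform range for the base minor-allele frequency.
#' @param ld_block_size SNPs per LD block (1 gives identity LD).
#' @param ld_r2 within-block r-squared.
#' @param prop_causal proportion of SNPs with a non-zero true effect.
#' @param effect_sd sd of non-zero true effects (log-odds scale).
#' @param tau2 between-study effect variance (0 = homogeneous).
#' @param case_control list of \code{c(cases, controls)} per study.
#' @param n_genes genes in the eQTL panel.
#' @param eqtl_effect_range absolute-effect range for planted eQTL betas.
#' @param smr_effect planted mediation effect (b_SMR truth).
#' @param prop_mediated proportion of genes whose expression truly
#'   mediates the GWAS signal.
#' @param n_traits microbiota panel size.
#' @param n_instruments_per_trait planted instruments per trait.
#' @param microbiome_n sample size of the microbiota GWAS.
#' @param causal_trait_effects named vector of true causal effects of
#'   traits on the outcome (names must be trait labels).
#' @param n_reverse_hits planted genome-wide hits usable as reverse-MR
#'   instruments.
#' @param n_contexts,context_size eQTL-context layout for enrichment.
#' @param n_query planted query (novel-locus) set size for enrichment.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_snps = 50000,
                       n_studies = 4,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_r2 = 0.8,
                       prop_causal = 0.01,
                       effect_sd = 0.05,
                       tau2 = 0,
                       case_control = list(c(18382, 27969),
                                           c(18235, 36741),
                                           c(888, 362304),
                                           c(22916, 32504)),
                       n_genes = 200,
                       eqtl_effect_range = c(0.3, 0.8),
                       smr_effect = 0.5,
                       prop_mediated = 0.1,
                       n_traits = 20,
                       n_instruments_per_trait = 30,
                       microbiome_n = 5959,
                       causal_trait_effects = c(trait01 = 0.15,
                                                trait02 = -0.15),
                       n_reverse_hits = 60,
                       n_contexts = 13,
                       context_size = 300,
                       n_query = 47) {
  stopifnot(n_snps > 0, n_studies > 0, ld_block_size >= 1,
            ld_r2 >= 0, ld_r2 <= 1, prop_causal >= 0, prop_causal <= 1,
            tau2 >= 0, length(case_control) >= n_studies)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the SNP map and block-diagonal LD
#'
#' SNPs are laid out in LD blocks assigned round-robin to 22 autosomes
#' (so any map with at least two blocks spans at least two chromosomes);
#' within a chromosome consecutive blocks start 1 Mb apart and SNPs within
#' a block sit 5 kb apart — geometry that exercises both the 500 kb and the
#' 10,000 kb clumping windows.  All intra-block pairs share the configured
#' r-squared; inter-block r-squared is 0 (absent from the table).
#'
#' @param config a [sim_config()].
#' @return list with \code{map} (data.frame \code{snp}, \code{chrom},
#'   \code{pos}, \code{block}) and \code{ld} (data.frame \code{snp_a},
#'   \code{snp_b}, \code{r2}).
#' @export
sim_ld_and_map <- function(config) {
  n <- config$n_snps
  bs <- config$ld_block_size
  block <- (seq_len(n) - 1L) %/% bs + 1L
  within <- (seq_len(n) - 1L) %% bs
  n_chr <- 22L
  chrom_i <- (block - 1L) %% n_chr + 1L
  block_on_chrom <- (block - 1L) %/% n_chr
  pos <- 1e6 * block_on_chrom + 5e3 * within + 1e4
  map <- data.frame(snp = sprintf("rs%07d", seq_len(n)),
                    chrom = paste0("chr", chrom_i),
                    pos = pos, block = block, stringsAsFactors = FALSE)
  ld <- NULL
  if (bs > 1L && config$ld_r2 > 0) {
    pairs <- utils::combn(bs, 2)
    blocks <- unique(block)
    ia <- unlist(lapply(blocks, function(b) {
      off <- (b - 1L) * bs
      idx <- off + pairs[1, ]
      idx[idx <= n & off + pairs[2, ] <= n]
    }))
    ib <- unlist(lapply(blocks, function(b) {
      off <- (b - 1L) * bs
      idx2 <- off + pairs[2, ]
      idx2[off + pairs[1, ] <= n & idx2 <= n]
    }))
    ld <- data.frame(snp_a = map$snp[ia], snp_b = map$snp[ib],
                     r2 = config$ld_r2, stringsAsFactors = FALSE)
  } else {
    ld <- data.frame(snp_a = character(), snp_b = character(),
                     r2 = numeric())
  }
  list(map = map, ld = ld)
}

#' Simulate a multi-study GWAS with shared true effects
#'
#' Per-SNP true effects are point-normal (a \code{prop_causal} fraction
#' draws from N(0, \code{effect_sd}^2), the rest are exactly 0).  Each
#' study observes \eqn{\beta_{true} + N(0, \tau^2) + N(0, se^2)} with
#' \eqn{se = 1/\sqrt{2 f (1-f) w}} at the study's effective sample-size
#' weight and its (slightly perturbed) effect-allele frequency.  All
#' records share the A/G orientation, so studies are pre-aligned.
#'
#' @param config a [sim_config()].
#' @param mapld output of [sim_ld_and_map()] (regenerated when missing).
#' @return list with \code{studies} (named list of summary-statistics
#'   data.frames), \code{truth} (\code{snp}, \code{causal},
#'   \code{beta_true}), \code{map}, \code{ld}.
#' @export
sim_multistudy_gwas <- function(config, mapld = sim_ld_and_map(config)) {
  map <- mapld$map
  n <- nrow(map)
  out <- withr_seed(config$seed, {
    maf <- runif(n, config$maf_range[1], config$maf_range[2])
    causal <- rbinom(n, 1, config$prop_causal) == 1
    beta_true <- ifelse(causal, rnorm(n, 0, config$effect_sd), 0)
    studies <- list()
    for (s in seq_len(config$n_studies)) {
      cc <- config$case_control[[s]]
      w <- .effective_n(cc[1], cc[2])
      f <- pmin(pmax(maf + rnorm(n, 0, 0.005), 0.01), 0.99)
      se <- 1 / sqrt(2 * f * (1 - f) * w)
      beta <- beta_true + rnorm(n, 0, sqrt(config$tau2)) + rnorm(n, 0, se)
      z <- beta / se
      studies[[sprintf("study%02d", s)]] <-
        data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                   ea = "A", oa = "G", eaf = f, beta = beta, se = se,
                   p = p_from_z(z), weight = w, z = z,
                   stringsAsFactors = FALSE)
    }
    list(studies = studies,
         truth = data.frame(snp = map$snp, causal = causal,
                            beta_true = beta_true,
                            stringsAsFactors = FALSE))
  })
  c(out, list(map = map, ld = mapld$ld))
}

#' Simulate a two-version eQTL panel with planted mediation
#'
#' Picks \code{n_genes} probes, each with three cis associations from one
#' LD block (the planted top SNP strongest).  A \code{prop_mediated}
#' fraction of genes is wired so that the GWAS effect at the top SNP is
#' \code{smr_effect * beta_eqtl} (plus sampling noise): for those genes
#' the SMR ratio recovers \code{smr_effect}; the remaining genes carry a
#' null GWAS effect, so their SMR p-values are uniform.  The second
#' version re-draws the eQTL sampling noise with a shifted stream, giving
#' an independent replicate with the same planted truth.
#'
#' @param config a [sim_config()].
#' @param mapld output of [sim_ld_and_map()].
#' @return list with \code{v1}, \code{v2} (eQTL tables), \code{gwas}
#'   (summary statistics covering the panel's SNPs), \code{genes} (gene
#'   table), \code{truth} (\code{probe_id}, \code{gene}, \code{top_snp},
#'   \code{beta_eqtl}, \code{mediated}, \code{b_smr_true}).
#' @export
sim_eqtl_panel <- function(config, mapld = sim_ld_and_map(config)) {
  map <- mapld$map
  bs <- config$ld_block_size
  n_blocks <- max(map$block)
  ng <- min(config$n_genes, n_blocks)
  need_cis <- min(3L, bs)
  w_meta <- sum(vapply(config$case_control[seq_len(config$n_studies)],
                       function(cc) .effective_n(cc[1], cc[2]), numeric(1)))
  withr_seed(config$seed + 1L, {
    gene_blocks <- sort(sample.int(n_blocks, ng))
    mediated <- rep(FALSE, ng)
    mediated[sample.int(ng, max(1L, round(config$prop_mediated * ng)))] <- TRUE
    probe <- sprintf("PROBE%04d", seq_len(ng))
    sym <- sprintf("GENE%04d", seq_len(ng))
    make_version <- function(version_seed) {
      withr_seed(config$seed + version_seed, {
        rows <- lapply(seq_len(ng), function(i) {
          idx <- which(map$block == gene_blocks[i])[seq_len(need_cis)]
          f <- runif(length(idx), 0.1, 0.5)
          b_top <- sample(c(-1, 1), 1) *
            runif(1, config$eqtl_effect_range[1], config$eqtl_effect_range[2])
          zmag <- c(runif(1, 10, 15), runif(length(idx) - 1, 3, 6))
          beta <- b_top * c(1, runif(length(idx) - 1, 0.3, 0.7))
          se <- abs(beta) / zmag
          data.frame(probe_id = probe[i], gene = sym[i],
                     probe_chrom = map$chrom[idx[1]],
                     probe_bp = map$pos[idx[1]] + 500,
                     snp = map$snp[idx], snp_chrom = map$chrom[idx],
                     snp_bp = map$pos[idx], freq = f, beta = beta,
                     se = se, p = p_from_z(beta / se),
                     ea = "A", oa = "G", stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
      })
    }
    v1 <- make_version(101L)
    v2 <- make_version(102L)
    top1 <- v1[!duplicated(v1$probe_id), , drop = FALSE]
    # GWAS side: mediated genes inherit smr_effect * beta_eqtl at the top
    # SNP; null genes draw from the null
    se_g <- 1 / sqrt(2 * top1$freq * (1 - top1$freq) * w_meta)
    b_g <- ifelse(mediated, config$smr_effect * top1$beta, 0) +
      rnorm(ng, 0, se_g)
    gwas <- data.frame(snp = top1$snp, chrom = top1$snp_chrom,
                       pos = top1$snp_bp, ea = "A", oa = "G",
                       eaf = top1$freq, beta = b_g, se = se_g,
                       p = p_from_z(b_g / se_g), weight = w_meta,
                       z = b_g / se_g, stringsAsFactors = FALSE)
    genes <- data.frame(chrom = top1$snp_chrom,
                        start = pmax(1, top1$snp_bp - 1000),
                        end = top1$snp_bp + 1000,
                        gene_id = probe, symbol = sym,
                        stringsAsFactors = FALSE)
    list(v1 = v1, v2 = v2, gwas = gwas, genes = genes,
         truth = data.frame(probe_id = probe, gene = sym,
                            top_snp = top1$snp, beta_eqtl = top1$beta,
                            mediated = mediated,
                            b_smr_true = ifelse(mediated, config$smr_effect, 0),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a microbiota exposure panel with known causal traits
#'
#' Each trait receives \code{n_instruments_per_trait} instruments drawn
#' from LD blocks disjoint across traits, with exposure effects sized so
#' the F statistic exceeds 10 at the microbiota GWAS sample size.  Causal
#' traits transmit \code{causal_trait_effects[trait] * beta_exp} to the
#' outcome at their instruments; null traits transmit nothing.  A further
#' set of planted outcome hits (in blocks no trait uses) provides
#' reverse-direction instruments; by default the reverse effects on every
#' trait are null.
#'
#' @param config a [sim_config()].
#' @param mapld output of [sim_ld_and_map()].
#' @return list with \code{panel} (named list of exposure
#'   summary-statistics tables), \code{outcome} (outcome summary
#'   statistics covering all panel instruments and the reverse hits),
#'   \code{truth} (per-trait causal effect), \code{reverse_hits} (SNP
#'   ids).
#' @export
sim_microbiome_panel <- function(config, mapld = sim_ld_and_map(config)) {
  map <- mapld$map
  n_blocks <- max(map$block)
  nt <- config$n_traits
  m <- config$n_instruments_per_trait
  need <- nt * m + config$n_reverse_hits
  if (need > n_blocks)
    stop("map too small: need ", need, " LD blocks, have ", n_blocks,
         call. = FALSE)
  w_exp <- config$microbiome_n
  w_out <- sum(vapply(config$case_control[seq_len(config$n_studies)],
                      function(cc) .effective_n(cc[1], cc[2]), numeric(1)))
  withr_seed(config$seed + 2L, {
    blocks <- sample.int(n_blocks, need)
    trait_names <- sprintf("trait%02d", seq_len(nt))
    causal <- setNames(rep(0, nt), trait_names)
    ce <- config$causal_trait_effects
    causal[names(ce)[names(ce) %in% trait_names]] <-
      ce[names(ce) %in% trait_names]
    panel <- list()
    out_rows <- list()
    for (t in seq_len(nt)) {
      bl <- blocks[((t - 1) * m + 1):(t * m)]
      idx <- match(bl, map$block)          # first SNP of each block
      f <- runif(m, 0.1, 0.5)
      se_e <- 1 / sqrt(2 * f * (1 - f) * w_exp)
      beta_e <- sample(c(-1, 1), m, replace = TRUE) * runif(m, 0.09, 0.16)
      z_e <- beta_e / se_e
      panel[[trait_names[t]]] <-
        data.frame(snp = map$snp[idx], chrom = map$chrom[idx],
                   pos = map$pos[idx], ea = "A", oa = "G", eaf = f,
                   beta = beta_e, se = se_e, p = p_from_z(z_e),
                   weight = w_exp, z = z_e, stringsAsFactors = FALSE)
      se_o <- 1 / sqrt(2 * f * (1 - f) * w_out)
      beta_o <- causal[t] * beta_e + rnorm(m, 0, se_o)
      out_rows[[t]] <-
        data.frame(snp = map$snp[idx], chrom = map$chrom[idx],
                   pos = map$pos[idx], ea = "A", oa = "G", eaf = f,
                   beta = beta_o, se = se_o, p = p_from_z(beta_o / se_o),
                   weight = w_out, z = beta_o / se_o,
                   stringsAsFactors = FALSE)
    }
    # planted outcome hits for the reverse direction
    rb <- blocks[(nt * m + 1):need]
    idx <- match(rb, map$block)
    f <- runif(length(idx), 0.1, 0.5)
    se_o <- 1 / sqrt(2 * f * (1 - f) * w_out)
    beta_o <- sample(c(-1, 1), length(idx), replace = TRUE) *
      runif(length(idx), 8, 12) * se_o      # |z| in 8-12: p << 5e-6, F > 10
    out_rows[[nt + 1L]] <-
      data.frame(snp = map$snp[idx], chrom = map$chrom[idx],
                 pos = map$pos[idx], ea = "A", oa = "G", eaf = f,
                 beta = beta_o, se = se_o, p = p_from_z(beta_o / se_o),
                 weight = w_out, z = beta_o / se_o,
                 stringsAsFactors = FALSE)
    outcome <- do.call(rbind, out_rows)
    rownames(outcome) <- NULL
    reverse_hits <- map$snp[idx]
    # every trait also carries (null) effects at the reverse hits so the
    # reverse direction has an outcome to harmonise against
    for (t in seq_len(nt)) {
      f_r <- outcome$eaf[match(reverse_hits, outcome$snp)]
      se_r <- 1 / sqrt(2 * f_r * (1 - f_r) * w_exp)
      beta_r <- rnorm(length(reverse_hits), 0, se_r)
      panel[[trait_names[t]]] <- rbind(
        panel[[trait_names[t]]],
        data.frame(snp = reverse_hits,
                   chrom = outcome$chrom[match(reverse_hits, outcome$snp)],
                   pos = outcome$pos[match(reverse_hits, outcome$snp)],
                   ea = "A", oa = "G", eaf = f_r, beta = beta_r,
                   se = se_r, p = p_from_z(beta_r / se_r), weight = w_exp,
                   z = beta_r / se_r, stringsAsFactors = FALSE))
    }
    list(panel = panel, outcome = outcome,
         truth = data.frame(trait = trait_names, causal_beta = unname(causal),
                            stringsAsFactors = FALSE),
         reverse_hits = reverse_hits)
  })
}

#' Simulate enrichment contexts, gene sets, PoPS scores and a gene table
#'
#' Builds a designated query SNP set, \code{n_contexts} eQTL contexts with
#' planted overlap counts against it (the first context gets the largest
#' overlap), a GMT collection with one planted enriched set, a PoPS score
#' table with a known per-window maximum, and a matching gene table.
#'
#' @param config a [sim_config()].
#' @param mapld output of [sim_ld_and_map()].
#' @param planted_overlaps integer vector (recycled to \code{n_contexts})
#'   of query/context overlap counts; default plants 6 in the first
#'   context and 1 elsewhere.
#' @return list with \code{query}, \code{contexts}, \code{gmt},
#'   \code{pops}, \code{genes}, \code{universe_genes},
#'   \code{planted_overlaps}.
#' @export
sim_contexts_and_genesets <- function(config,
                                      mapld = sim_ld_and_map(config),
                                      planted_overlaps = NULL) {
  map <- mapld$map
  nq <- min(config$n_query, nrow(map))
  nc <- config$n_contexts
  if (is.null(planted_overlaps))
    planted_overlaps <- c(6L, rep(1L, nc - 1L))
  planted_overlaps <- rep_len(pmin(planted_overlaps, nq), nc)
  withr_seed(config$seed + 3L, {
    query <- sample(map$snp, nq)
    rest <- setdiff(map$snp, query)
    contexts <- list()
    for (j in seq_len(nc)) {
      k <- planted_overlaps[j]
      size <- min(config$context_size, k + length(rest))
      contexts[[sprintf("context%02d", j)]] <-
        c(sample(query, k), sample(rest, size - k))
    }
    n_universe <- 50L
    universe <- sprintf("GENE%04d", seq_len(n_universe))
    enriched_set <- universe[1:10]
    gmt <- list(planted_set = enriched_set,
                null_set_a = sample(universe, 10),
                null_set_b = sample(universe, 15))
    pops <- setNames(round(rnorm(n_universe, 0.3, 0.25), 6), universe)
    gi <- sample.int(nrow(map), n_universe)
    genes <- data.frame(chrom = map$chrom[gi],
                        start = pmax(1, map$pos[gi] - 1000),
                        end = map$pos[gi] + 1000,
                        gene_id = universe, symbol = universe,
                        stringsAsFactors = FALSE)
    list(query = query, contexts = contexts, gmt = gmt, pops = pops,
         genes = genes, universe_genes = universe,
         planted_overlaps = planted_overlaps)
  })
}
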