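# gibaxis

Cross-tissue integration of GWAS summary statistics along the gut
microbiota–immunity–brain axis.

Complex neurodevelopmental phenotypes such as autism spectrum disorder are
increasingly treated as systemic conditions: genetic risk acts not only in
the brain but also through peripheral systems — the gut microbiome and the
blood immune compartment. `gibaxis` is an R toolkit for the summary-
statistics side of that research programme. It takes per-SNP association
tables from several case/control GWAS, pools them, screens for novel risk
loci, and then interrogates those loci across tissues: which genes they
sit near and which the polygenic priority score (PoPS) nominates, whether
they are over-represented among brain-region- and cell-type-specific
eQTLs, whether their trait associations look mediated by gene expression
or methylation (SMR), and whether they connect causally to microbial taxon
abundances in either direction (bidirectional two-sample Mendelian
randomization). A final intersection step ranks SNPs by how many of those
dimensions they satisfy, nominating pleiotropic hub variants.

Everything operates on plain delimited text; no individual-level genotype
data is needed. A first-class synthetic-data module simulates every input
with known ground truth, so the full pipeline is testable offline.

## The statistics at the core

**Meta-analysis with heterogeneity fallback.** Per SNP, inverse-variance
fixed effects: with weights \(w_i = 1/se_i^2\),

\[\hat\beta = \frac{\sum_i w_i \beta_i}{\sum_i w_i},\qquad
SE = \Big(\sum_i w_i\Big)^{-1/2}.\]

Sample-size-scheme results are first converted back to the beta/SE scale
via \(SE = 1/\sqrt{2f(1-f)(w + Z^2)}\), \(\beta = SE \cdot Z\), with
\(f\) the effect-allele frequency and \(w\) the effective sample size.
Heterogeneity is measured by Cochran's \(Q = \sum_i w_i(\beta_i -
\hat\beta)^2\) and \(I^2 = \max(0, (Q - df)/Q)\cdot 100\). When the Q-test
p falls below 0.1 **and** \(I^2\) exceeds 50%, the SNP is re-pooled with
DerSimonian–Laird random effects
(\(\tau^2 = \max(0,(Q-df)/(\sum w - \sum w^2/\sum w))\)).

**Novel-locus screening.** Each contributing study is LD-clumped
(p < 5e-6, r² < 0.001 within 10,000 kb) to build a known-locus database; a
genome-wide-significant pooled SNP (p < 5e-8) is *novel* iff it lies
≥ 500 kb from every known index variant on its chromosome.

**Enrichment.** Overlaps of the novel-SNP set with eQTL contexts (and of
gene lists with GMT gene sets) are tested with the upper-tail
hypergeometric probability
\(P(X \ge k) = 1 - \sum_{i<k} \binom{m}{i}\binom{n}{r-i}/\binom{m+n}{r}\),
Benjamini–Hochberg-adjusted within each context family, with enrichment
factor \(k/(rm/(m+n))\).

**SMR.** At a probe's top cis-SNP, \(b_{SMR} = b_{GWAS}/b_{eQTL}\) and
\(T_{SMR} = z_G^2 z_E^2/(z_G^2+z_E^2) \sim \chi^2_1\); BH-FDR across the
scan's probes.

**Bidirectional MR.** Forward (taxon → outcome): instruments at p < 1e-5,
clump r² = 0.1 / 500 kb, F = (β/se)² > 10. Reverse (outcome → taxon):
p < 5e-6, r² < 0.001 / 10,000 kb, F > 10, forward instruments excluded.
Estimators: IVW on ratio estimates (multiplicative random-effects SE
inflation under overdispersion), MR-Egger with its intercept test,
weighted median, and mode estimators; sensitivity via Cochran's Q,
leave-one-out, and the simulation-based MR-PRESSO global test. Effects are
reported as OR = exp(β) with 95% CI.

## Worked example

Simulate four case/control studies sharing true effects, pool them, and
run bidirectional MR against a simulated microbiota panel in which
trait01 (+0.15) and trait02 (−0.15) are truly causal:

```r
library(gibaxis)
cfg <- sim_config(seed = 42, n_snps = 5000, ld_block_size = 5,
                  n_traits = 6, n_instruments_per_trait = 20,
                  n_reverse_hits = 30)
gw   <- sim_multistudy_gwas(cfg)
meta <- meta_pipeline(gw$studies)
print(meta)
#> Meta-analysis of 5000 SNPs: 500 pooled under random effects, 4500 under fixed effects
#> ...

mb <- sim_microbiome_panel(cfg, list(map = gw$map, ld = gw$ld))
mr <- run_bidirectional(mb$panel, mb$outcome, gw$ld,
                        n_sim_presso = 500, seed = 42)
print(mr$forward$trait01)
#> Two-sample MR (forward): trait01 -> outcome_gwas  [19 instruments]
#>           method   beta       se          p   or_ ci_low ci_high n_snp
#>              ivw 0.1596 0.007252 2.681e-107 1.173  1.156   1.190    19
#>            egger 0.1471 0.051255  1.060e-02 1.159  1.048   1.281    19
#>  weighted_median 0.1631 0.012258  2.243e-40 1.177  1.149   1.206    19
#>      simple_mode 0.1693 0.020327  8.144e-17 1.184  1.138   1.233    19
#>    weighted_mode 0.1679 0.018449  9.126e-20 1.183  1.141   1.226    19
#> Cochran Q = 18.155 (p = 0.445); Egger intercept = 0.00161 (p = 0.809); PRESSO global p = 0.489
#> Leave-one-out: pass

sig <- mr$significance
sig[sig$direction == "forward",
    c("trait", "n_snp", "ivw_beta", "or_", "mr_p_adj", "significant")]
#>     trait n_snp     ivw_beta       or_      mr_p_adj significant
#> 1 trait01    19  0.159577711 1.1730154 1.608684e-106        TRUE
#> 2 trait02    18 -0.154642126 0.8567217  7.986113e-89        TRUE
#> 3 trait03    13  0.004133075 1.0041416  8.026407e-01       FALSE
#> 4 trait04    17 -0.002367930 0.9976349  8.026407e-01       FALSE
#> 5 trait05    15 -0.002665800 0.9973378  8.026407e-01       FALSE
#> 6 trait06    17  0.006682064 1.0067044  7.090286e-01       FALSE
```

The IVW estimate for trait01 (β ≈ 0.160, OR ≈ 1.17) recovers the planted
+0.15 within sampling error; trait02 recovers −0.15; the four null traits
stay non-significant after BH adjustment. The Egger intercept p (0.81) and
the PRESSO global p (0.49) show no evidence of directional pleiotropy, as
expected from a generator that plants none.

For the end-to-end pipeline (`meta → loci → annotate → enrich / smr / mr →
integrate`) see `?run_pipeline` and the methods vignette in `vignettes/`.

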