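---
title: "Cross-tissue integration of GWAS summary statistics: methods and design"
author: "gibaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue integration of GWAS summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibaxis)
```

`gibaxis` implements a multi-stage integration of GWAS summary statistics
across tissues: multi-study meta-analysis, novel-locus screening, gene and
PoPS annotation, eQTL-context enrichment, summary-data Mendelian
randomization (SMR), bidirectional two-sample Mendelian randomization
against a microbiota-abundance panel, and a cross-dimension intersection.
This vignette documents the models, their assumptions, the tunable
parameters, the synthetic-data generator, and the numerical and design
choices made where the methodology left room.

## Meta-analysis

Per-SNP effects $\beta_i$ with standard errors $se_i$ from $K$ studies are
pooled by inverse variance ($w_i = 1/se_i^2$). The model assumes
independent studies measuring a common underlying effect on the same
scale, with approximately normal estimates — the usual large-sample GWAS
regime. Studies reported on the sample-size scale are first converted via

$$SE = \frac{1}{\sqrt{2f(1-f)\,(w + Z^2)}},\qquad \beta = SE \cdot Z,$$

where $f$ is the effect-allele frequency and $w$ the effective sample
size $4/(1/n_{cases} + 1/n_{controls})$. The symbol conventionally printed
as "P" in this conversion is the effect-allele frequency: reading it as a
p-value would make the expression dimensionally incoherent, so the
frequency interpretation is used throughout.

Heterogeneity is quantified by Cochran's $Q$ (chi-square on $K-1$ df) and
$I^2 = \max(0, (Q-df)/Q)\cdot100$. The random-effects fallback uses the
DerSimonian–Laird moment estimator of $\tau^2$ and fires only when
*both* conditions hold strictly: Q-test $p < 0.1$ **and** $I^2 > 50$.
Under homogeneity and $K=4$ the joint rule is binding at
$Q > \max(\chi^2_{3,0.9},\, 2\cdot 3)$, i.e. a ~10% null trigger rate —
a property the test suite checks empirically.

Further choices:

* SNPs present in only a subset of studies are pooled over the available
  studies; no minimum-study filter is imposed by default (`min_k`).
* Cross-study effect-allele-frequency ranges above 0.2 (strictly) drop
  the SNP; the decision record carries the observed min/max.
* Two-sided p-values come from the standard normal computed in log-space
  (`pnorm(..., log.p = TRUE)`), so they do not underflow below 1e-300.
* With a single study, $Q$ and its p are reported as missing rather
  than 1, and $I^2 = 0$.
* Pooled frequency is the weight-weighted mean of per-study frequencies.

**Interval calibration.** With $\tau^2 = 0$ the fallback still fires on
~10% of SNPs by chance and widens exactly those intervals, so overall
empirical coverage sits slightly above 95%. Calibration is therefore
assessed on the fixed-effects rows: under normality $Q$ is independent of
the pooled estimate, so conditioning on the trigger does not bias the
coverage of the fixed-effects interval. The suite verifies 95% ± 2 MC-SE
on those rows at 10,000 simulated SNPs.

## Novel-locus screening

Greedy LD clumping sorts candidates by ascending p (ties broken by
chromosome, position, then id, so results are deterministic) and accepts
a SNP iff no previously accepted SNP on the same chromosome is *both*
within the window *and* correlated at $r^2 \ge$ the threshold. A SNP is
excluded only when near **and** correlated; setting `r2_threshold = 0`
recovers pure-distance exclusion. Pairs absent from the LD table count as
$r^2 = 0$.

The known-locus database is the per-chromosome, deduplicated union of
per-study index variants clumped at the suggestive threshold (p < 5e-6,
$r^2 < 0.001$, 10,000 kb). A pooled hit (default genome-wide p < 5e-8 —
the pooled significance level is configurable because the upstream
workflow leaves it implicit) is novel iff its distance to every known
position on its chromosome is at least 500 kb; a distance of exactly
500,000 bp counts as novel, which makes the "≥ 500 kb apart" and "within
± 500 kb excluded" phrasings coincide at the boundary.

## Annotation

Window genes are all genes whose *body* intersects ± 500 kb of the SNP;
distance is 0 inside the body, otherwise the distance to the nearer gene
edge. Gene-body edges (not TSS) are used because the windowing rule is
stated in terms of genes, not transcription starts. BED input is
converted from 0-based half-open to the 1-based inclusive convention used
everywhere else. The PoPS match keeps the maximum-scoring window gene;
negative scores are legitimate maxima (no sign filtering); ties break to
the gene nearest the SNP, then lexicographically.

## Enrichment

The upper-tail hypergeometric probability is computed with
`stats::phyper`, which works in log-space and is stable for genome-scale
backgrounds (1e7 and beyond); the denominator's draw count is $r$, the
standard normalization. BH adjustment is applied *within* each context
family (brain regions and cell types are separate families), matching
FDR control per analysis. The genome-wide background SNP count is a
configuration value (default 1e7) because no principled universal
denominator exists for overlap-count enrichment; conclusions that depend
on it should be read comparatively across contexts, not absolutely.

## SMR

At each probe the top cis-SNP is the minimum-p association passing
`p_eqtl_max` (ties: larger $|z|$, then smaller position). The SMR
statistic

$$b_{SMR} = b_{GWAS}/b_{eQTL}, \qquad
T = \frac{z_G^2 z_E^2}{z_G^2 + z_E^2} \sim \chi^2_1$$

is valid when the eQTL instrument is strong ($z_E^2 \gg 1$); the reported
$se_{SMR} = |b_{SMR}|\sqrt{1/z_G^2 + 1/z_E^2}$ is the first-order delta
approximation. Duplicate probe rows are collapsed before BH so the FDR
family size equals the number of distinct probes, and the adjustment is
per scan (per eQTL version). The HEIDI linkage test is deliberately out
of scope: with heavily LD-pruned loci too few cis SNPs remain to compute
it, and the upstream pruning is itself the pleiotropy guard. Allele
alignment uses the eQTL orientation as reference when the eQTL table
carries allele columns; otherwise effects are assumed pre-aligned.

## Bidirectional MR

Instrument rules are direction-specific: forward (exposure = taxon
abundance) p < 1e-5, clump $r^2 = 0.1$ within 500 kb; reverse (exposure =
the pooled outcome GWAS) p < 5e-6, $r^2 < 0.001$ within 10,000 kb, with
every SNP already used as a forward instrument excluded, keeping the two
instrument sets disjoint by construction (asserted at run time). Both
directions require $F = (\beta/se)^2 > 10$ strictly.

Harmonisation joins on SNP id and aligns outcome effects to the
exposure's effect allele. Palindromic (A/T, C/G) pairs with effect-allele
frequency in [0.42, 0.58] on either side are dropped as unresolvable —
the conventional two-sample MR window; outside it they are oriented by
frequency concordance.

Estimators operate on the ratio scale $\beta_j = \beta_{out,j} /
\beta_{exp,j}$ with first-order SEs $se_j = se_{out,j}/|\beta_{exp,j}|$
(the second-order term in $se_{exp}$ is omitted; with $F > 10$ it
contributes < 10% of the variance):

* **IVW** — inverse-variance pooling; when $Q/(n-1) > 1$ the SE is
  inflated by $\sqrt{Q/(n-1)}$ (multiplicative random-effects model), a
  guard against overdispersed instrument sets.
* **MR-Egger** — weighted least squares of outcome on exposure effects
  with a free intercept (weights $1/se_{out}^2$), all exposure effects
  oriented non-negative first; intercept and slope inference on the t
  distribution with $n-2$ df.
* **Weighted median** — interpolated weighted quantile at 0.5; SE by a
  seeded parametric bootstrap (default 1,000 draws).
* **Simple/weighted mode** — kernel-density modes of the ratios. The
  methodology names five conventional estimators without listing them
  all; IVW, Egger and the weighted median are explicit, and the two mode
  estimators are included as clearly-labelled presumptive extras. The
  significance callout never depends on them.

Sensitivity battery: Cochran's Q on the ratios; the Egger intercept test;
leave-one-out IVW (a pair "passes" when every leave-one-out CI overlaps
the sign of the full estimate); and the MR-PRESSO *global* test — observed
$RSS = \sum_j w_j(\beta_{out,j} - \hat\beta_{-j}\beta_{exp,j})^2$ with
outcome-precision weights $w_j = 1/se_{out,j}^2$ and leave-one-out IVW
slopes $\hat\beta_{-j}$, compared against a parametric null in which the
outcome effects are redrawn and the leave-one-out slopes recomputed in
every replicate; $p = (1 + \#\{RSS_{sim} \ge RSS_{obs}\})/(n_{sim}+1)$.
PRESSO's outlier-removal and distortion stages are not implemented — only
the global test is reported. All stochastic components run under a local
seeded RNG stream, so identical inputs and seeds give bit-identical
output without disturbing the caller's RNG.

Across the trait panel, the significance callout is BH-adjusted IVW
p < 0.05 per direction. Per-trait failures (no instruments surviving
selection or harmonisation) are isolated: the pipeline records the reason
and continues.

## Cross-dimension integration

`joint_report()` builds one row per SNP appearing in any dimension —
novel locus, per-direction MR instrument, significant SMR top SNP per
eQTL version (FDR_BH < 0.05 within each version), membership in a
significantly enriched context — and ranks by the count of satisfied
dimensions (descending, ties by id). Instrument sets are taken
post-harmonisation: those are the SNPs that actually informed an MR
estimate. The report is idempotent and independent of input row order.

## The synthetic-data generator

The generator emulates the full input suite with known truth, as a pure
function of its configuration (same config ⇒ byte-identical output):

* **Map/LD** — SNPs in LD blocks assigned round-robin to 22 autosomes;
  5 kb within-block spacing, 1 Mb between block starts, so both the
  500 kb and 10,000 kb clumping windows are exercised. LD is
  block-diagonal at a single configured $r^2$ (default 0.8).
* **Multi-study GWAS** — point-normal true effects (default 1% causal,
  sd 0.05 on the log-odds scale); per-study noise
  $N(0, \tau^2) + N(0, se^2)$ with $se = 1/\sqrt{2f(1-f)w}$ at the
  study's effective sample size. The four default study sizes are
  18,382/27,969, 18,235/36,741, 888/362,304 and 22,916/32,504
  cases/controls. The $Z^2$ term of the SE conversion is dropped at
  simulation time (it is unknown before the noise is drawn and is
  $O(Z^2/w) \approx 10^{-4}$ relative at these sizes).
* **eQTL panel** — per gene, three cis associations from one block with
  the planted top SNP strongest; a 10% mediated subset wires
  $b_{GWAS} = 0.5 \cdot b_{eQTL}$ at the top SNP so SMR recovers 0.5;
  the second version redraws the sampling noise with the same truth.
* **Microbiota panel** — default 20 traits at GWAS sample size 5,959,
  30 instruments each in trait-disjoint blocks, effects sized so
  $F > 10$; causal traits (defaults +0.15 and −0.15) transmit
  effect × $\beta_{exp}$ to the outcome; separate strong outcome hits
  provide reverse-direction instruments.
* **Contexts/gene sets** — eQTL contexts with planted overlap counts
  against a designated query set, one planted enriched GMT set, a PoPS
  table with a known per-window maximum.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic LD decay and cross-block correlation,
allele-frequency spectra and strand ambiguity in the wild, population
stratification, sample overlap between exposure and outcome GWAS,
compositional structure of microbiome abundances, and winner's-curse
effects in instrument selection. Tests demonstrate algorithmic
correctness and statistical calibration under the stated model, not
robustness to those artefacts.

## Problem sizes and runtime choices

The suite runs the meta-analysis calibration at 10,000 SNPs, the
type-I-error experiments for the Egger intercept and PRESSO global tests
at 500 replicates (PRESSO at 1,000 null simulations each), IVW recovery
at 50 instruments, SMR recovery at 200 probes, and the end-to-end smoke
run at 4 studies × 50,000 SNPs with 20 microbiota traits, 200 genes and
10 contexts — sizes chosen to make Monte-Carlo error small relative to
the tested tolerances while keeping a full check-out on a laptop in a few
minutes. The smoke run plants one hub SNP that is simultaneously a novel
locus, a reverse-MR instrument, the significant SMR top SNP in both eQTL
versions and a member of one enriched context, and asserts it ranks first
in the joint report.

## Known limitations

* Genome-build liftover is out of scope; all inputs must share one build.
* eQTL summaries are consumed as text; binary BESD stores are not read.
* PoPS scores are consumed, never trained; gene-set enrichment runs
  against user-supplied GMT files, not live pathway databases.
* The MR battery omits MR-PRESSO outlier correction, multivariable MR,
  Steiger filtering and related estimators.
* LD is consumed as a precomputed pairwise $r^2$ table; the package does
  not estimate LD from reference panels.
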