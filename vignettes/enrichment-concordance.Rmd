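---
title: "Measuring the concordance of enrichment results across platforms and sites"
author: "enrichConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the concordance of enrichment results across platforms and sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichConcord)
```

## The question this package addresses

Gene set (GO term) enrichment is the standard second step after selecting
differentially expressed genes (DEGs) from a two-condition expression
study. DEG lists themselves are known to be fairly reproducible across
laboratories and array platforms when genes are ranked by fold change with
a non-stringent p-value filter — but what a biologist ultimately interprets
is the enriched term list, not the gene list. This package measures how
reproducible the *enrichment* results are when DEGs are selected by three
common criteria:

* **FC** — fold-change ranking after a non-stringent Student-t p filter,
  requiring `|log2FC| > 1`;
* **SAM** — the moderated d statistic with a permutation p-value;
* **TTEST** — the plain pooled-variance Student t p-value, used without
  multiple-testing correction.

Two enrichment engines are provided. The GSEA-style engine walks a ranked
gene list accumulating a weighted Kolmogorov–Smirnov running sum per gene
set (hit increment $|s|^w/\sum_{hits}|s|^w$, miss decrement $1/(N-N_h)$),
takes the signed maximal deviation as the enrichment score (ES), normalizes
it by the same-sign mean of a gene-set permutation null (NES), and
estimates FDR by the pooled-null ratio
$q = \Pr_{null}(NES^* \ge z)/\Pr_{obs}(NES \ge z)$, clipped to $[0,1]$ and
made monotone in $|NES|$ within each sign. The LRpath-style engine fits,
per gene set, a logistic regression of set membership on a per-gene
evidence scale and tests the slope with a two-sided Wald test, adjusting
across sets by Benjamini–Hochberg.

Concordance between two FDR-ranked significant-term lists (cutoff
`q < 0.25`, strict) is the **percentage of overlapping terms**
$POG_i = 100\,O_i/T_i$, where $O_i$ is the size of the intersection of the
two top-$i$ blocks and $T_i = i$, after both lists are truncated to the
shorter length. For the directional GSEA engine, the "pos" and "neg" lists
are truncated per direction to the direction-wise minimum and concatenated
(pos block first); the block order affects intermediate depths only, never
the terminal value. An empty significant list yields `NA`, not 0% —
absence of evidence is not disagreement.

## The synthetic study generator

Because the package is exercised at desk scale, a generator emulates the
reference multi-platform design: platforms measuring overlapping gene
subsets, several independent test sites per platform, two RNA conditions
(A and B) with five replicates each per site. The model is additive
Gaussian on the log2 scale:

$$x_{gqsck} = \alpha_g + \lambda_{gq} + \nu_{gqs} + \delta_g\,1[c=A] + \varepsilon_{gqsck}$$

with baseline $\alpha_g \sim N(8, 2^2)$, platform offsets
$\lambda \sim N(0, platformSd^2)$, site offsets $\nu \sim N(0, siteSd^2)$
and per-gene noise $\varepsilon \sim N(0, \sigma_g^2)$,
$\sigma_g \sim U(geneSdRange)$. Defaults (see `studyDesign()`): 2000
genes, three platforms covering 85% of the transcriptome each (their
intersection, about 61% of genes, plays the role of the cross-platform
"common genes" to which all analysis is restricted), three sites, five
replicates, 150 gene sets of 15–80 members, 10 of them planted as
enriched.

Design choices worth making explicit:

* **DE fraction and planted enrichment.** A gene is differentially
  expressed with probability `deFraction = 0.2`, multiplied by
  `plantedDeEnrichment = 5` (capped at one) inside planted sets — so a
  planted set's members are all DE while the background rate is 20%. The
  reference-material contrast this emulates is far stronger still (a
  plain t-test selects 69–84% of common genes there), so 0.2 is a
  conservative desk-scale choice that leaves the planted/background
  contrast meaningful under the capped product.
* **Coherent planted directions.** A DE gene's absolute effect is
  $|\delta| \sim N(1, 0.5^2)$ truncated at zero. Background DE genes get
  independent fair-coin signs, but each *planted* set draws one direction
  (a fair coin per set) inherited by the DE members it recruits. This is
  deliberate: "enriched" in the gene-set sense means coordinated
  regulation, and a set whose members move in random directions is
  undetectable in principle by a signed running-sum statistic — its hits
  split across both extremes of any signed ranking. Undirected engines
  (the logistic model) do not need the coherence but are unharmed by it.
* **Set sizes.** Set sizes are uniform on 15–80 *before* the common-gene
  restriction; after it, planted sets retain roughly 9–49 effective
  members. Sets much smaller than ~10 effective members are below the
  reliable-detection envelope of gene-set statistics (the original GSEA
  software excludes sets under 15 members by default), so the lower bound
  is chosen to keep the planted benchmark well-powered rather than
  borderline.
* **Site effects are additive.** $\nu_{gqs}$ is shared by both conditions
  at a site, so it cancels exactly in within-site A-vs-B contrasts;
  inter-site discordance in this model is driven by replicate noise.
  Real inter-laboratory variation also perturbs condition contrasts
  (hybridization batches interacting with sample), which this generator
  does not model — passing concordance tests here shows the pipeline's
  statistics behave correctly, not that real cross-site reproducibility
  equals the synthetic one.
* **Substreamed randomness.** One seed expands into per-component
  substreams (baseline, noise, sets, coverage, effects, ...), so changing
  one design field never reshuffles unrelated draws, and repeated calls
  are byte-identical.

What the generator does **not** emulate: dye or probe-sequence effects,
intensity-dependent variance on the raw scale, probe-to-gene mapping
ambiguity, or correlated expression within pathways beyond the planted
effects.

## Statistical components and their numerical choices

**Student t.** Pooled-variance two-sided t with $df = n_A + n_B - 2$,
vectorized over genes. Zero pooled variance degenerates to $t = 0, p = 1$
(equal means) or $p = 0$ with an infinite-magnitude statistic flagged
(unequal means).

**SAM.** $d = (\bar{x}_A - \bar{x}_B)/(s + s_0)$ with $s$ the pooled
standard error of the t statistic. The fudge factor $s_0$ is selected by
the coefficient-of-variation rule: candidates are zero and the 5th–95th
percentiles of $s$ in steps of 5; genes are split into 100 windows by
quantiles of $s$; the candidate minimizing the CV of the per-window median
absolute deviation of $d$ is chosen, deterministically. Significance is a
label-permutation p-value with $s_0$ held fixed: for the balanced
five-vs-five design all $\binom{10}{5} = 252$ assignments are enumerated
and the p-value is exact (counting the identity, so $p \ge 1/252$); larger
designs fall back to sampled permutations with add-one smoothing.

**DEG selection and ranking.** FC filters on `t_p < cutoff` and
`|log2fc| > 1` and orders by `|log2fc|` descending; SAM filters on
`sam_p` and orders by `|sam_d|`; TTEST orders by `t_p` ascending. All
ties break lexicographically by gene id so every list is reproducible.
The GSEA ranking metric is criterion-native and signed: `log2fc`, `sam_d`,
or $sign(log2fc)(-\log_{10} t\_p)$; signal-to-noise is available as an
alternative.

**GSEA input scope.** The concordance pipeline feeds each criterion's DEG
list to the pre-ranked engine (which is why gene-set permutation, not
sample-label permutation, supplies the null — a truncated list has no
sample labels left). For *recovery* analyses against the generator's
ground truth, the engine is invoked on the full common-gene universe
(`degList = NULL`): within an already-selected DEG list every gene is
extreme by construction, so member positions carry no enrichment signal
and truncated-list recovery is structurally uninformative, while the
full-universe ranking is the standard pre-ranked usage.

**Permutation null sharing.** Null enrichment scores depend on the ranked
list and the set size only, so sets of equal effective size share one null
sample of `nPerm` scores; this is an exact identity, not an approximation.
The running-sum extremum is evaluated in $O(k)$ from the hit positions
(extrema can only occur immediately before or after a hit), which the test
suite verifies against the full $O(N)$ walk to $10^{-12}$.

**LRpath evidence coupling.** Each criterion supplies the per-gene
evidence it ranks by: $-\log(t\_p)$ for TTEST, $-\log(sam\_p)$ for SAM,
and $|log2FC|$ for FC, always over the full common-gene universe. Two
alternatives were considered and rejected after implementation: (i) using
`t_p` for both FC and TTEST makes those two runs literally identical,
forcing their concordance to 100% and erasing the study's central
contrast; (ii) restricting the regression universe to the DEG list leaves
no significance gradient between members and non-members (every retained
gene is already significant), and the engine returns empty term lists at
desk scale. A `restrict` argument still exposes the restricted variant.
Complete separation is detected (non-convergence or degenerate standard
errors) and flagged rather than ranked. Exact-zero p-values are floored
at $10^{-15}$ with a warning before the log transform.

**Minimum set size.** `minSize = 5` (not the original software's 15)
because desk-scale collections restricted to common genes would otherwise
lose a large fraction of sets; the size filter is applied to members
*present in the analysed universe*, not nominal set size.

## Problem sizes used by tests and scripts

The test suite and the acceptance script run the full pipeline at reduced
scale — 300–2000 genes, 1–3 platforms, 20–150 sets, 200–1000 permutations
— so a complete run finishes in minutes on one core. The intra-site
criterion contrast uses ten seeds of a deliberately heteroscedastic
two-platform, two-site study ($\sigma_g \sim U(0.05, 1)$, site SD 0.3):
heteroscedasticity is the mechanism that separates the variance-sensitive
t-test from the effect-driven FC and variance-moderated SAM criteria, and
therefore the setting in which the reproducibility contrast between
criteria is expected to appear.

## A worked run

```{r, eval = FALSE}
run <- runStudy(list(
  design = list(nGenes = 1000, platforms = c("AFX", "AG1"),
                sitesPerPlatform = 2, nSets = 60),
  criteria = list(methods = c("FC", "SAM", "TTEST"), pCutoffs = 0.05),
  gsea = list(nPerm = 500),
  seed = 7))

run$degCounts          # DEG counts per criterion x platform/site
head(run$concordance)  # POG for every planned pairwise comparison
```

## Known limitations

* The generator's additive site effect cancels in within-site contrasts;
  it stresses the bookkeeping of multi-site designs more than their
  statistics.
* Gene sets are sampled independently, so set overlap is random; real GO
  terms are nested, which inflates between-term correlation and makes
  real term lists more internally redundant than synthetic ones.
* The hierarchical structure of the GO graph is ignored: two non-identical
  but semantically close terms count as a mismatch.
* The engines are compared only against themselves across inputs
  (intra-engine concordance); comparing GSEA with the logistic engine as
  methods is out of scope.
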