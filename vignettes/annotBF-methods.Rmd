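---
title: "Methods: empirical annotation Bayes Factors for GWAS prioritisation"
author: "annotBF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical annotation Bayes Factors for GWAS prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotBF)
```

# The model

A GWAS produces, for each SNP, an effect estimate $\hat\beta$ (log-odds
scale) with standard error $\sqrt{V}$ and a p-value. Only a handful of SNPs
clear genome-wide significance; the long tail of "near hits" mixes true and
false associations. annotBF ranks SNPs by the posterior odds of true
association,

$$O_{\text{post}} = O_{\text{prior}} \times BF_{\text{annot}} \times
BF_{\text{assoc}},$$

assuming annotation and association data are independent given causality.
$O_{\text{prior}}$ is the analyst's prior odds that a SNP is causal
(conventionally $10^{-5}$); when only the relative ranking matters it
cancels and can be omitted ([posteriorTable()] then reports ranks without
absolute odds).

## The association Bayes Factor

$BF_{\text{assoc}}$ uses the Wakefield asymptotic approximation: with a
$N(0, W)$ prior on the true effect, the marginal likelihood ratio of
association to no association at an observed $\hat\beta$ is

$$BF_{\text{assoc}} = \sqrt{\frac{V}{V+W}}
\exp\!\left(\frac{z^2}{2}\,\frac{W}{V+W}\right), \qquad
z = \hat\beta/\sqrt{V},$$

which is exactly the ratio of the $N(0, V+W)$ to the $N(0, V)$ density at
$\hat\beta$ — no integration required. `wakefieldAbf()` implements this
closed form (tested against the density-ratio identity at relative
tolerance $10^{-12}$) and offers a log-scale variant for extreme $z$, where
the ratio overflows double precision around $z^2 W/(V+W) \approx 1400$.

The default prior variance is $W = (\ln 1.5 / 1.96)^2 \approx 0.0428$,
i.e. a 95% prior interval of $(1/1.5,\, 1.5)$ for the odds ratio — a
standard effect-size prior for common variants. It is a tunable parameter
of every function that needs it (`wakefieldPriorW()` builds $W$ from any
odds-ratio interval).

## The annotation Bayes Factor

$BF_{\text{annot}}$ is estimated *empirically* rather than set
subjectively: it is the proportion of a given annotation category among
published GWAS hit SNPs divided by the proportion among the SNPs of the
genotyping panels those GWAS used. Because hits are a vanishing fraction of
panel SNPs, the unselected panel serves as the non-hit background; the few
hits it contains shrink the estimate towards 1, a conservative bias.
`estimateBfAnnot()` returns the ratio together with the delta-method
standard error of its logarithm,

$$\mathrm{SE}[\ln \widehat{BF}] = \sqrt{\tfrac{1}{k_h} - \tfrac{1}{n_h} +
\tfrac{1}{k_p} - \tfrac{1}{n_p}},$$

undefined when no hit is annotated (an optional Haldane-style +0.5
correction is available but off by default: the raw ratio is the canonical
estimator). This uncertainty is reported but not propagated into
$O_{\text{post}}$.

From the packaged counts of two curated hit databases against the combined
Affy500+Illu550 panel (`makeTable1Fixture()`), the supported ranges are
3.1–4.7 for cis eQTLs in open chromatin, 2.9–3.5 for non-synonymous SNPs,
1.8–2.5 for promoter SNPs, and 0.93 for SNPs with no annotation.
`recommendedBfTable()` exposes the midpoints by default and the endpoints
via `weight = "low"` / `"high"` — the low end limits the influence of
annotation, the high end strengthens it.

When a SNP carries several annotations, `assignBfAnnot()` applies the
category with the **largest** Bayes Factor. The data are too sparse to
estimate joint-category factors; using the maximum is conservative under
the assumption that a second annotation can raise but never lower the
evidence.

# Annotation assignment

Categories arrive in two shapes: id sets (nsSNP lists, eQTL selections) and
genomic intervals (promoters, open chromatin; BED). Coordinates follow each
format's native convention — SNP positions are 1-based, BED is 0-based
half-open — and conversion happens once, inside `readBedIntervals()`; a SNP
at position $p$ is inside a BED interval $[s, e)$ iff $s < p \le e$.
Chromosome labels `"chr6"` and `"6"` are treated as equal everywhere.

**LD proxies.** Genotyping panels tag rather than type most causal
variants, so annotation is transferred across linkage disequilibrium:
`propagateLdProxies()` adds a category to any SNP lacking it that has
$r^2 \ge 0.8$ (inclusive, configurable) with a directly annotated SNP.
Propagation is single-hop — proxy-acquired annotations never seed further
transfer, which keeps LD chains bounded and makes the operation idempotent.
Direct provenance always wins over proxy provenance when both apply, and
the recorded `proxy_source` is the highest-$r^2$ qualifying neighbour (ties
broken by id, for determinism). eQTL categories are still extended via LD
proxy even though eQTL discovery itself has LD "built in", because the
discovery panel is typically smaller than the GWAS panels.

**eQTLs.** `selectEqtls()` defines the category from a ranked
SNP–transcript table: keep records whose expression-regression p-value rank
is within a cutoff (20,000 for a stringent set, 100,000 for a lenient one),
optionally restrict to *cis* — same chromosome and within 200 kb
(inclusive) of the transcript — and optionally intersect with open
chromatin. The table supplies one representative coordinate per transcript;
whether that is the start, end or probe midpoint is the data provider's
choice, and the 200 kb rule is applied to whatever coordinate is given.

**Independence subset.** `uniqueAnnotationSubset()` removes every SNP
assigned (by any provenance) to more than one category, allowing
enrichment of each category to be checked free of overlap with the others.

# Enrichment testing

`enrichmentTest()` compares annotation proportions between hits and panel.
The panel counts are so large that their sampling error is negligible, so
the panel is treated as fixed and the null standard error uses the panel
proportion with the hit-set size:

$$z = \frac{\hat p_{\text{hit}} - \hat p_{\text{panel}}}
{\sqrt{\hat p_{\text{panel}}(1-\hat p_{\text{panel}})/n_{\text{hit}}}},$$

with a two-sided normal p-value (sidedness is a convention; two-sided is
the conservative choice, and tests confirm direction and order-of-magnitude
agreement with the exact binomial tail at small $n$). Error bars for
plotting use the hit proportion's own binomial SE. Significance tiers are
Bonferroni-corrected: the most stringent of $\{0.001, 0.01, 0.05\}$ whose
per-test threshold (level divided by the declared family size; 36 in the
packaged example, giving $2.8\times10^{-5}$, $2.8\times10^{-4}$,
$1.4\times10^{-3}$) the p-value beats. The family size defaults to the
number of comparisons actually run.

Supporting sensitivity analyses: `stratifyByMaf()` splits at MAF 0.1
(the cutoff itself falling in the high stratum; missing MAF reported
separately), `thresholdSweep()` re-estimates Bayes Factors as the
hit-defining p-value threshold tightens (strict `<`), and
`restrictToPanel()` implements both the union (shared SNPs counted once)
and summation (once per panel) conventions for combining overlapping
panels. Hit tables are filtered through `filterMhc()`, which removes the
extended MHC region chr6:25,809,985–33,486,934 (closed bounds, as printed)
— gene-dense, with long-range LD, and unrepresentative of the genome. The
filter applies to whatever SNP tables it is given; LD tables are inputs and
are not themselves filtered.

# Re-ranking evaluation

`rankChange()` compares ranks under $BF_{\text{assoc}}$ alone and under the
product $BF_{\text{assoc}} \times BF_{\text{annot}}$. Rank 1 is the best
(largest) score and ties take the average of the spanned ranks, so total
rank change over all SNPs is exactly zero and per-SNP changes are
interpretable as positions gained. `randomSetBaseline()` draws equally
sized random SNP sets for the null distribution of mean rank change; the
target SNPs are excluded from the sampling frame by default (configurable)
so the null is not contaminated by the very signal under test. All sampling
is seeded and the seed is recorded in the report.

# The synthetic generator

`generatePanel()` / `simulateGwas()` emulate the study conditions so every
estimator can be validated against known truth without external data. The
defaults mirror the combined-panel background: category base rates 0.8%,
3.9% and 3.2% (cis eQTL in open chromatin, nsSNP, promoter), causal
enrichments 4.0 / 3.5 / 2.5, panel size $10^5$, 2000 causal SNPs, constant
standard error 0.05 with causal $|\beta| = 0.3$ (so causal $|z| \approx 6$,
typical of a well-powered hit). Categories are assigned independently at
their base rates; MAF is uniform on $[0.01, 0.5]$; LD is block-structured —
consecutive SNPs in blocks of 4 with constant within-block $r^2$ — which is
enough to exercise the proxy-threshold logic but deliberately ignores
real LD decay.

**Calibrated causal selection.** Causal SNPs are drawn with multiplicative
per-category weights

$$g_c = \frac{\rho_c\,(1-r_c)}{1-\rho_c r_c},$$

where $r_c$ is the base rate and $\rho_c$ the target enrichment. Under
independent category assignment this makes the *expected hit-vs-panel
proportion ratio exactly $\rho_c$ for every category, even when categories
overlap* — a naive "weight by $\rho$" scheme inflates the normalising
constant and recovers $\rho_c$ only up to a common bias factor, which at
these rates is larger than the estimator's standard error. Because effects
are drawn independently of annotation, thresholding hits by p-value
subsamples the causal set at random and leaves the calibration unbiased.
Parameter-recovery tests check $|\ln\widehat{BF} - \ln\rho| <
3\,\mathrm{SE}[\ln\widehat{BF}]$ at these conditions.

**True/false mixtures.** For threshold-sweep behaviour the generator adds
an optional second tier: `nFalse` SNPs with a weak effect
(`falseEffectMean`) and *no* annotation preference — stand-ins for spurious
or inflated signals that pass lenient thresholds but thin out under
stringent ones. The packaged sweep check uses 3000 strong causal SNPs
($|z|\approx 8$) against 15,000 weak ones ($|z|\approx 4$) on a $10^5$
panel: across thresholds $10^{-5} \to 10^{-7}$ the causal fraction of the
hit set rises from roughly a third to two thirds, so each category's Bayes
Factor climbs by several times its sampling noise — the monotonicity is a
property of the design, not of a lucky seed. The re-ranking check instead
uses weak causal effects ($|\beta| = 0.07$, mid-pack $z$) so that annotated
causal targets sit among the bulk of null SNPs, where an annotation
weighting of 2–4 moves them past many competitors, as in a real
suggestive-signal tier.

**What the generator does not emulate:** realistic LD decay and
recombination maps, MAF-dependent power, genotype-level data,
phenotype-specific annotation effects, and panel ascertainment bias.
Passing tests therefore demonstrate correctness of the estimators and the
internal consistency of the pipeline under the stated sampling model — not
robustness to those real-data complications.

# Numerical and interface conventions

* Problem sizes in the test-suite simulations ($10^4$–$10^5$ SNPs, 1–5
  replicates) are chosen so each stochastic check has at least a
  $3\sigma$ margin under the design calculations above while remaining
  quick to run.
* Seeds: every stochastic function takes an explicit seed (or config seed)
  and restores the RNG state afterwards; derived seeds stay within 32-bit
  integer range.
* Degenerate inputs: empty hit sets in a sweep yield `NA` Bayes Factors,
  not errors; a panel proportion of 0 or 1 is a degenerate null and errors;
  `k_hit = 0` yields $BF = 0$ with undefined SE.
* Rounding for presentation follows the source conventions (one decimal
  for category Bayes Factors, two for the no-annotation factor);
  computation is never rounded internally.
* The command-line layer (`exec/annotbf`, `annotbfCLI()`) contains no
  analysis logic; it parses flags, calls the API, and writes tab-delimited
  tables whose first line records package version, subcommand and seed.
  Exit codes: 0 success, 1 runtime error, 2 usage/input error.

# Worked example

```{r example}
f <- makeTable1Fixture()
est <- estimateBfAnnot(f$hits$hindorff$nsSNP, f$hits$hindorff$total,
                       f$panel$nsSNP, f$panel$total, "nsSNP")
est
enrichmentTestCounts(f$hits$hindorff$nsSNP, f$hits$hindorff$total,
                     f$panel$nsSNP, f$panel$total, "nsSNP",
                     nTests = f$n_tests)[, c("p_hit", "p_panel", "z", "tier")]
```

# Known limitations

* $BF_{\text{annot}}$ is estimated from hits pooled across phenotypes; a
  phenotype-specific factor could differ.
* The estimator's uncertainty (`logBfSE`) is reported but not propagated
  into posterior odds.
* The panel background includes the hit SNPs themselves (they are a
  negligible fraction; the effect is a slight shrinkage towards 1).
* Exact empirical Bayes Factors depend on the hit database, the reference
  panel, the LD-proxy threshold and the hit-defining p-value cutoff; hence
  ranges, not point values, are recommended.
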