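---
title: "Methods: druggable-genome MR, colocalization and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: druggable-genome MR, colocalization and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The model

`targetmr` treats gene expression as an exposure and disease liability as
an outcome in the two-sample summary-statistics MR framework. For a
variant $i$ instrumenting a gene, the exposure study supplies
$(\hat\beta_{x,i}, \mathrm{SE}_{x,i})$ (SD of expression per effect
allele) and the outcome study $(\hat\beta_{y,i}, \mathrm{SE}_{y,i})$
(log-odds per effect allele). Under the instrumental-variable assumptions
(relevance, independence from confounders, no direct path to the outcome),
every valid instrument identifies the same causal effect
$\theta = \beta_{y,i}/\beta_{x,i}$, the log odds ratio of disease per SD
of expression.

- One instrument: the Wald ratio
  $\hat\theta = \hat\beta_y/\hat\beta_x$ with first-order delta-method
  standard error $\mathrm{SE}_y/|\hat\beta_x|$. The first-order form
  ignores exposure-side noise; because instruments must pass $F > 10$
  (and in practice $F$ is in the hundreds), that term is second order. A
  `second_order = TRUE` flag adds it for sensitivity analyses.
- $k \ge 2$ instruments: the IVW estimate, the inverse-variance-weighted
  mean of per-SNP ratios. Fixed-effect SE is $(\sum w_i)^{-1/2}$ with
  $w_i = 1/\mathrm{SE}(r_i)^2$; the default multiplicative-random-effects
  mode inflates it by $\sqrt{\max(1, Q/(k-1))}$, so heterogeneous
  instrument sets get honestly wider intervals while the SE never drops
  below the fixed-effect value.

P-values are two-sided normal throughout: this is the summary-data,
large-$n$ regime and no small-sample $t$ correction is applied. All
confidence intervals use the 1.959964 normal quantile, and reported odds
ratios are rounded to three decimals in the TSV reports only — the tibbles
keep full precision.

## Instrument selection

The cascade is: genome-wide significance ($p < 5\times10^{-8}$) →
minor-allele frequency $\min(\mathrm{EAF}, 1-\mathrm{EAF}) > 0.01$ →
greedy LD clumping ($r^2 < 0.001$ within 10{,}000 kb) → strength
$F > 10$. The first two are per-variant predicates, so their order cannot
change the result; clumping then scans by p-value priority with ties
broken by position and then variant id, making the retained set
deterministic. Per-variant variance explained uses
$R^2 = \beta^2/(\beta^2 + N\,\mathrm{SE}^2)$ — the conventional
$2\,\mathrm{EAF}(1-\mathrm{EAF})$ factor multiplies numerator and
denominator alike and cancels — and $F = R^2(N-2)/(1-R^2)$. $N$ is the
per-variant sample size, not a study constant, because eQTL meta-analyses
genotype different variants in different subsets.

LD is an explicit input (a per-gene $r^2$ matrix with unit diagonal): the
package never fetches a reference panel, and the simulator supplies
matrices consistent with its own generative correlation structure.
Instruments farther than the cis window (default ±1 Mb of the TSS) or on
another chromosome are flagged `is_trans`; trans-instrumented genes skip
colocalization, since a cis coloc region is undefined for them, and are
carried through prioritization on the remaining evidence.

## Harmonization

Outcome rows are aligned to the exposure's effect allele: swapped alleles
negate $\beta$ and reflect EAF; strand-complemented alleles are mapped
back first. Palindromic variants (A/T, G/C) cannot be strand-resolved
from alleles alone, so those with exposure EAF inside the configurable
ambiguity band (default the open interval 0.42–0.58) are rejected, and
the rest are aligned by frequency side. Palindromic variants lacking an
outcome EAF are rejected; non-palindromic ones proceed. Harmonization is
idempotent and the double allele swap is an involution — both are tested
properties. Every action is logged per variant
(`kept` / `flipped` / `complemented` / `rejected:<reason>`).

## Directionality: Steiger filtering and reverse MR

A valid instrument must explain more variance in the exposure than in the
outcome. The outcome-side $r^2$ is the observed-scale approximation
$z^2/(z^2+N)$ (one algebraic identity with the exposure-side formula, and
computed through the same code path so the strict comparison is exact at
the boundary). For binary outcomes this observed-scale $r^2$ understates
liability-scale variance by roughly the factor
$\mathrm{cf}(1-\mathrm{cf})$; the package makes no liability correction
because the case fraction of the outcome study is not always known, and
the comparison is used as a filter rather than an estimate. The Steiger
p-value compares the two Fisher-transformed correlations across the two
(independent) studies.

Reverse MR re-runs the whole selection cascade with the disease as
exposure against the gene's eQTL associations as outcome, restricted to
the gene's region. One design choice matters here: when a gene truly
affects disease, the disease-side association at the gene's eQTL is the
forward path seen from the other side, and naive reverse MR would flag
every strong forward signal as "bidirectional". The package therefore
applies the Steiger guard in the reverse direction too — a disease
instrument must explain more disease variance than expression variance.
With that guard, forward-only genes come out reverse-not-testable,
disease-driven regions with no reverse path give calibrated null reverse
p-values, and genuinely bidirectional genes keep their power (all three
behaviors are under test).

## Colocalization

Per variant and trait, the Wakefield log approximate Bayes factor is
$\tfrac12[\log(1-r) + r z^2]$ with shrinkage $r = w/(\mathrm{SE}^2+w)$.
Under the single-causal-variant assumption the five hypothesis weights
are sums over causal configurations: $H_0$: 1; $H_1$: $p_1\sum_i A_{1i}$;
$H_2$: $p_2\sum_j A_{2j}$; $H_3$:
$p_1 p_2(\sum_i A_{1i}\sum_j A_{2j} - \sum_i A_{1i}A_{2i})$; $H_4$:
$p_{12}\sum_i A_{1i}A_{2i}$. All accumulation is in log space with
log-sum-exp (a $z$ of 60 would overflow naive exponentiation), and the
implementation is checked against an exhaustive configuration-enumeration
oracle on small regions to $10^{-9}$.

Priors default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; prior effect
SDs to 0.15 for quantitative traits and 0.2 for binary traits on the
log-odds scale. These are the conventional defaults of the approach, are
fully configurable, and should not be read as any particular study's
settings. The coloc region is the harmonized intersection of variants in
the gene's cis window (default ±1 Mb). The decision rule
$\mathrm{PPH3}+\mathrm{PPH4} \ge 0.8$ is inclusive at the threshold.

## The prioritization cascade

A gene is *prioritized* when its discovery p-value beats
$0.05/m$ (with $m$ the number of genes that had at least one instrument,
recomputed per run, never a hard-coded constant), it survives Steiger
filtering, and — where colocalization was performed — the coloc decision
is true. After Steiger removal the estimate is recomputed and reported
alongside the original; the original remains the headline discovery
estimate, the post-filter one documents robustness.

Replication uses two declared strategies: *same-variant* (look the
discovery instruments up in the validation outcome) and
*significant-variant* (re-select instruments from scratch, then
estimate). The family-wise threshold divides 0.05 by the number of genes
tested in the disease family — for example 13 genes give 0.0038, 10 give
0.005. A validation estimate whose direction disagrees with discovery is
reported non-replicated regardless of p-value (configurable via
`require_directional_consistency`); the manifest records the rule. The
biomarker scan is deliberately unadjusted (p < 0.05 per test), with an
optional Bonferroni flag.

One caveat on monotonicity: loosening the post-estimation decision
thresholds (discovery alpha, coloc threshold) can only enlarge the
prioritized set, and this is property-tested. Loosening selection-stage
thresholds ($p_{\max}$, $F_{\min}$, MAF) changes which instruments enter
the estimator and can therefore move estimates themselves, so no
monotonicity is claimed or enforced there.

## The synthetic study

The generator works entirely in z-score space: for a region of $m$
variants with AR(1) genotype correlation $\Sigma_{ij} = \rho^{|i-j|}$ and
sparse causal standardized effects $b$, marginal effects are
$\lambda = \Sigma b$, expected z-scores $\sqrt{N_{\mathrm{eff}}}\lambda$,
and observed z-scores add MVN$(0, \Sigma)$ noise. No individual-level
genotypes are simulated — the pipeline only ever sees summary data, and
this keeps generation desk-scale. Binary outcomes live on the log-odds
scale with $N_{\mathrm{eff}} = N\,\mathrm{cf}(1-\mathrm{cf})$. The
emitted LD matrix is $\Sigma^2$ (positive definite for $\rho < 1$ by the
Schur product theorem). One RNG stream per (gene, purpose) derived from
the seed makes per-gene output reproducible independently of iteration
order, and a fixed seed yields byte-identical bundles.

Default conditions emulate the scale of the intended application: a
blood cis-eQTL meta-analysis of $n = 31{,}684$ (with per-variant sizes
varying within 95–100% of it) as exposure, and a large type-2-diabetes
case-control meta-analysis of 62,892 cases / 596,424 controls as the
binary outcome. Where the application defines no value the defaults are
chosen once as field-realistic: 50 variants per region, AR(1) $\rho =
0.5$, MAF uniform on (0.05, 0.5), two causal cis-eQTL variants per gene
placed far enough apart to survive clumping as independent instruments,
causal standardized eQTL effect 0.07 (a strong cis-eQTL, $F \approx
150$), and a causal effect $\theta = 0.4$ (odds ratio $\approx 1.5$ per
SD of expression, the scale of the stronger reported drug-target
associations). Outcome rows are emitted with randomly scrambled allele
orientation (swaps and strand complements) so harmonization is exercised
end to end; this can be disabled.

Scenarios: `causal` (outcome effects are $\theta\lambda$), `null`,
`reverse` (the outcome has its own causal variant of standardized effect
0.25 and expression is downstream with effect $\theta_{\mathrm{rev}} =
0.2$), `shared_variant` / `distinct_variant` (both traits scaled to an
expected causal-variant $z$ of 8, for colocalization testing; distinct
causal variants sit 20 positions apart, far enough to be effectively
uncorrelated at $\rho = 0.5$), and `pleiotropic` (direct outcome effects
at instrument positions). For the reverse scenario the balanced
case-fraction of 0.5 is used in tests: with a rare-disease case fraction
the observed-scale $r^2$ shrinkage deliberately weakens the Steiger
contrast, which is a real limitation of observed-scale filtering rather
than a bug, and the balanced design isolates the directionality behavior
being tested.

What the simulator does *not* emulate: realistic human LD maps,
population stratification, sample overlap between studies, allele-
frequency mismatch between cohorts, or multi-causal-variant coloc
regions. Passing tests therefore demonstrate correctness of the
estimators and decision logic under the stated generative model, not
robustness to those real-data complications.

## Problem sizes and numerical choices

The validation suite uses: 2,000 null replicates for type-I error
(accepting [0.03, 0.07] at $\alpha = 0.05$), 500 replicates per true
effect for parameter recovery (mean within 2 Monte-Carlo SEs), 200
replicates per colocalization scenario (shared: PPH4 > 0.8 in ≥ 90%;
distinct: PPH3 > PPH4 in ≥ 90%), 500 reverse-causation replicates
(> 95% instrument removal), and a 100-gene end-to-end study with 10
causal genes (≥ 8 causal prioritized, ≤ 1 null prioritized, ≥ 80%
replication). For recovery, instruments are made stronger (standardized
eQTL effect 0.2, $F > 1000$) and the outcome study smaller
($10^5$, balanced): the Wald ratio has a finite-sample bias of order
$\theta/F$, and these conditions keep that bias well below the
Monte-Carlo resolution the test asserts, which is the point of a
recovery test at 500 replicates.

Degenerate inputs are defined, not patched: empty instrument sets
propagate as empty results (a gene is skipped, never an error); a single
instrument routes to the Wald ratio and `ivw()` refuses it; fewer than
three instruments make the Egger intercept not-computable (flagged, not
fatal); a zero exposure effect is a domain error naming the variant;
p-values from extreme z-scores are floored at 10⁻³²⁰ to stay inside
(0, 1]. Clump ties, coloc ties and ordering are all deterministic, and
`run_study()` is byte-reproducible under a fixed seed.

## Known limitations

- Single-causal-variant colocalization only; no SuSiE-style multi-signal
  decomposition or conditional analysis.
- No MR-PRESSO-style outlier removal and no weighted-median/mode
  estimators; the pleiotropy battery is the Egger intercept plus
  Cochran's Q.
- Observed-scale Steiger for binary outcomes (see above).
- Variant identity is matched on `variant_id` alone, which assumes
  consistently keyed (e.g. rsID) inputs; no chromosome-position fallback
  or proxy-SNP lookup.
- No reference-panel clumping against genotype data: LD must be supplied
  (or simulated).
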