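---
title: "Germline and somatic analysis of a two-allele VNTR locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline and somatic analysis of a two-allele VNTR locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrtools)
```

## The scientific setting

A coding-region variable number tandem repeat (VNTR) with two alleles — 4 or
5 copies of a 54-nucleotide motif — yields three genotypes, `4/4`, `4/5` and
`5/5`. In a cancer case-control setting such a locus is interrogated at four
levels, and `vntrtools` implements the statistics for all four:

1. **Germline association.** Do cases carry the long (5-repeat) allele more
   often than controls, per cohort and pooled over published studies?
2. **Somatic allelic imbalance.** In patients with matched blood and tumor
   genotypes, does loss of heterozygosity (LOH) preferentially retain one
   allele?
3. **Co-expression of the gene harbouring the VNTR.** Which genes track its
   expression in healthy tissue, and where does that coupling break down in
   tumors?
4. **Survival.** Is low expression of the gene (or of a signature of its
   partners) associated with shorter relapse-free survival?

A seeded synthetic-data generator module produces inputs with the exact
statistical structure each stage assumes, so the whole pipeline is testable
against planted ground truth without any external download.

## Germline association

Within a cohort, each group's genotype counts $(n_{44}, n_{45}, n_{55})$ are
tested for Hardy-Weinberg equilibrium by the 1-df chi-square goodness of fit
against $(p^2, 2pq, q^2)$ at the observed allele frequency
$q = (2 n_{55} + n_{45}) / 2n$. The goodness-of-fit form (rather than an
exact test) is the package's deliberate choice: it is the classical
large-cohort test and is exact enough at the cohort sizes involved
(hundreds to thousands), as its null calibration test verifies on 10,000
simulated cohorts.

Association is summarized by unadjusted odds ratios for three contrasts
named by their genotype composition — `HOM` (5/5 vs 4/4), `HET` (4/5 vs
4/4) and `COMBINED` (4/5 plus 5/5 vs 4/4) — with Woolf confidence
intervals, $\exp(\log OR \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d})$.
No continuity correction is applied while all cells are positive; a zero
cell triggers the standard 0.5 correction on all four cells with a warning.
Composition-based names are used because model words like "dominant" are
used inconsistently across the literature this package serves; the numbers
are unambiguous, the labels are not.

```{r assoc}
cases <- genotypeCounts(761, 666, 148)
controls <- genotypeCounts(816, 679, 145)
hweTest(controls)
contrastOR(cases, controls, "HOM")
```

## Meta-analysis

Study effects are log odds ratios with variance $1/a + 1/b + 1/c + 1/d$.
Fixed-effect pooling is inverse-variance weighting; the random-effects model
uses the DerSimonian-Laird moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum
w_i)\big)$, chosen because it is closed-form and deterministic, and because
whenever $Q \le df$ (no excess heterogeneity) it collapses exactly onto the
fixed-effect answer — the property the pooled VNTR analyses exhibit.
Heterogeneity is reported as Cochran's $Q$ with its chi-square p-value and
$I^2 = \max(0, (Q - df)/Q) \cdot 100$, floored at zero. Studies missing the
cells a contrast needs (one published study reports only the combined
carrier row) are dropped from that contrast only, never imputed.

```{r meta}
effects <- studyEffects(studyCounts(), "HOM")
poolFixed(effects)
```

## Somatic allelic imbalance

Matched blood-tumor pairs are classified by transition: a blood heterozygote
becoming tumor-homozygous is an LOH event retaining the surviving allele; a
blood homozygote whose tumor shows the other allele cannot arise by allele
loss and is flagged inconsistent but retained, since silently dropping
discordant calls would hide genotyping problems. Retention direction is
tested with both one-sided exact binomial tails at success probability 1/2
(`p_toward5` $= P(X \ge n_5)$ and symmetrically for the 4-allele), reported
at full precision. The Wilson score interval for the retention fraction
supports parameter-recovery checks. Only genotype change is modelled; no
copy-number input is used, so LOH, mitotic recombination and
non-disjunction are indistinguishable here by design.

```{r loh}
pairs <- readMatchedPairs(vntrExample("matched_pairs_synthetic.tsv"))
s <- classifyTransitions(pairs)
s
retentionBiasTest(s$n_loh_retain4, s$n_loh_retain5)
```

## Co-expression profiling

`anchorProfile()` computes the Spearman correlation (average ranks on ties,
pairwise deletion of missing values) between one anchor gene and every other
gene over the samples of a group; rank correlation makes the profile
invariant under any strictly monotone per-gene transform, which matters when
combining array datasets on different intensity scales. The cross-dataset
robust-partner filter keeps genes with $|\rho| >$ threshold (strictly;
default 0.4) in *both* datasets. When the two datasets come from different
species, uppercase symbol equality stands in for orthology mapping by
default — adequate for the mouse/human case where most orthologs share
symbols — and a user-supplied two-column ortholog table overrides it.
Set over-representation uses the inclusive upper hypergeometric tail
$P(X \ge k)$, the standard enrichment convention (the exclusive tail would
assign p = 0 to a complete overlap rather than its actual probability).
Ranked `.rnk` exports (descending correlation, ties alphabetical) feed
external preranked enrichment tools.

## Differential co-expression

For each gene, the anchor correlations $r_1, r_2$ in two groups are Fisher
z-transformed, $Z = \tfrac12 \log\frac{1+r}{1-r}$, and compared with

$$z = \frac{Z_1 - Z_2}{\sqrt{1/(N_1 - 3) + 1/(N_2 - 3)}},$$

referred to the standard normal with two-sided p-values, then
Benjamini-Hochberg adjusted over all tested genes. Three choices deserve
note. First, the correlations fed in are Spearman's, while the $1/(N-3)$
variance is the classical Pearson-based form; this mixed convention is
retained deliberately as the method's canonical form, and the asymptotic
Spearman variance $1.06/(N-3)$ is available via `spearman_var = TRUE`
(default off) for users who want the better-calibrated version. The
package's own calibration test therefore checks the type-I error with
Pearson inputs, where the stated variance is the correct one. Second,
two-sided p-values are used: correlation loss and gain are both of
interest, and two-sided is the conservative default. Third, genes constant
in either group are skipped with a reported count, not imputed.

## Survival analysis

Expression scores are trichotomized by rank: with the sample size not
divisible by three, the top and bottom groups each take exactly
$\lfloor n/3 \rfloor$ samples and the remainder goes to the discarded
middle, keeping the compared groups equal-sized. Boundary ties are broken
by stable sample-id order with a warning. The top (high-expression) tertile
is compared with the bottom by the standard 1-df logrank test; the hazard
ratio is the logrank $\;(O_h/E_h)/(O_l/E_l)\;$ estimator with interval
$\exp(\log HR \pm z\sqrt{1/E_h + 1/E_l})$ — closed-form, deterministic and
on the same footing as the test itself, rather than a proportional-hazards
fit. The convention is HR $<$ 1 $\Rightarrow$ high expression protective.
`rfsScreen()` runs the split-and-test per gene; genes significant in that
univariate screen feed `averageSignature()`, the unweighted per-sample mean
used as a combined score.

## The synthetic-data generators

Every generator takes an explicit seed and is a pure function of its
arguments (the caller's RNG stream is saved and restored), so outputs are
bit-reproducible.

* `simulateCohort()` draws controls from Hardy-Weinberg probabilities at a
  given 5-allele frequency and cases from those probabilities reweighted by
  per-genotype odds ratios $(1, OR_{het}, OR_{hom})$ — the rare-disease
  genotype-OR model, chosen over a liability model because the planted ORs
  are then directly recoverable in closed form by `contrastOR()`.
* `simulateMatchedTumors()` applies LOH to each heterozygote with
  probability `loh_rate`, retaining the 5-allele with probability
  `retention5_bias`. Its defaults in tests mirror the observed study
  conditions: 138 heterozygotes, rate 36/138, bias 24/36.
* `simulateExpression()` builds each group from a latent factor: the anchor
  *is* the standard-normal factor $L$ and gene $i$ is
  $a_i L + \sqrt{1 - a_i^2}\,\varepsilon_i$, so the population Pearson
  correlation with the anchor is exactly $a_i$; $a_i$ is chosen by
  inverting the bivariate-normal identity
  $\rho_s = (6/\pi)\arcsin(a/2)$ so the *Spearman* target is met, exactly
  under Gaussianity. Giving the anchor no private noise is deliberate: with
  anchor noise the stated inversion would undershoot every target.
* `simulateSurvival()` draws exponential event times with rate
  $\lambda_0 e^{\beta \cdot score}$ and independent exponential censoring.

What the generators emulate is the *statistical* structure each stage
assumes — HWE genotype draws, a Bernoulli LOH process, jointly Gaussian
expression with prescribed anchor correlations, proportional hazards. What
they do not emulate: probe-level array artifacts, batch effects, non-Gaussian
expression marginals, subtype label noise, or linkage between the genotype
and expression layers. Passing recovery tests therefore demonstrates the
correctness and calibration of the estimators under their stated models,
not robustness to the messiness of real array data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than left to propagate:
empty count tables error; monomorphic samples give HWE p = 1 with a
warning; all-zero 2x2 tables error while single zero cells get the 0.5
correction; $|r| \ge 1$ errors in the Fisher transform; a tertile group
with zero events reports the test p but an `NA` hazard ratio. BH q-values
are checked for monotonicity in p-rank order. Exact tail identities
(binomial complement, retention symmetry) hold to 1e-12; the logrank
statistic matches a brute-force risk-set oracle to 1e-10; pooling matches
the `metafor` reference implementation to 1e-10.

The validation suite uses problem sizes chosen to make Monte-Carlo error
small relative to the tolerance bands while keeping a full run around half
a minute: 10,000 cohorts of n = 500 for HWE calibration, 2,000 null genes
at n = 100/group for the differential-correlation type-I rate, 500 genes at
n = 200/dataset for robust-partner recovery, 200 replicates of 300 + 300
subjects for hazard-ratio recovery, and 200 cohorts of 5,000 + 5,000 for
genotype-OR coverage.

## Known limitations

* The Fisher-z variance choice described above means Spearman-based
  transcriptome screens are very slightly anti-conservative at the default
  setting; use `spearman_var = TRUE` when calibration matters more than
  convention.
* The O/E hazard-ratio estimator is biased toward the null relative to a
  Cox fit for strong effects; it is reported because it shares the logrank
  test's construction. No covariate adjustment is offered anywhere — the
  association layer reports unadjusted odds ratios by design.
* Cross-species symbol matching by case-folding is a heuristic; supply an
  ortholog table for anything beyond exploratory use.
* Array preprocessing (normalization, probe collapsing, batch removal) and
  enrichment scoring (GSEA, network module detection) are out of scope;
  the package reads pre-collapsed matrices and writes the interchange
  formats (`.rnk`, GMT, plain gene lists) those external tools consume.
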