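---
title: "Methods: synergistic genotype-combination analysis of xenobiotic-metabolism polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergistic genotype-combination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmsynergy)
```

## The scientific problem

Cytochromes P450 (CYPs), esterases and glutathione S-transferases (GSTs)
metabolize xenobiotics such as pesticides, which are long-standing
suspects in sporadic Parkinson's disease (PD) risk. Because enzymes
within a class can compensate for one another, single-variant tests may
miss class-level genetic effects that only emerge when several
genotypes co-occur. This package re-implements, as tested reusable
code, a candidate-gene case-control analysis of 13 polymorphisms (11
SNPs and the GSTM1/GSTT1 gene deletions) across those three enzyme
classes in a cohort of 527 PD cases and 499 controls: Hardy-Weinberg
screening, single-locus association under several genetic models,
genotype dichotomization, within-class genotype-combination scans, and
a backward-elimination search for minimal "core" synergistic patterns.

The individual-level study data are deposited in an external
repository and are not required here: a synthetic-cohort generator
emulates the published design closely enough that every analysis stage
is exercised end to end.

## Statistical model

All association tests are logistic regressions of case status
$y_i \in \{0, 1\}$ on an exposure coding $x_i$ with age (years) and sex
(0 = male, 1 = female) as covariates:

$$\operatorname{logit} \Pr(y_i = 1) = \beta_0 + \beta_1 x_i +
\beta_2 \,\mathrm{age}_i + \beta_3 \,\mathrm{sex}_i,$$

with $\mathrm{OR} = e^{\beta_1}$, Wald 95% CI
$e^{\beta_1 \pm 1.96\,\mathrm{SE}}$ and two-sided Wald P. Exposure
codings per SNP (effect allele = second allele of the metadata pair):

* **dominant** — hom_ref vs het + hom_alt;
* **recessive** — hom_ref + het vs hom_alt;
* **additive** — effect-allele dose 0/1/2 as a single log-additive term;
* **genotypic** — two indicator terms with a 2-df likelihood-ratio P
  (the test behind "genotype frequencies differ" is not named in the
  source study; the LRT is the standard covariate-adjusted choice);
* **allelic** — alleles are not independent subjects, so a
  covariate-adjusted allele-level model is ill-defined. We report both
  the raw allele-count 2×2 cross-product OR and the adjusted
  allele-dose (additive) OR, and document the distinction; the two
  bracket published adjusted allele ORs (e.g. 0.882 raw vs 0.876
  printed for the CYP1A1 promoter SNP).

Deletion loci (present/null) support only the 2-level coding.
Hardy-Weinberg equilibrium is tested in controls by the 1-df Pearson
chi-square against $(p^2, 2pq, q^2)\,n$ with no continuity correction;
loci failing at $P < 0.05$ are removed, deletion loci are untestable and
kept. No continuity corrections are used anywhere (including the sex
chi-square and the tie-corrected normal-approximation Mann-Whitney
test), matching the conventions of the SPSS/SNPStats tool chain such
studies use.

## Dichotomization and the combination machinery

For the combination analysis each locus is reduced to two genotype
groups (`derive_grouping()`):

1. deletion loci keep present vs null;
2. if the pooled (cases + controls) hom_alt frequency is below 0.05,
   the rare homozygote is merged into its heterozygote (hom_ref vs
   het + hom_alt). This merge takes **precedence** over rule 3 — the
   published groupings force this ordering: the PON2 SNP has a smaller
   recessive P yet is grouped by the merged split;
3. otherwise the dominant or recessive split with the smaller model P
   is adopted; ties go to dominant.

The pooled-cohort frequency (rather than control-only) is used in rule
2 for symmetry; on the published counts the two choices never disagree,
and the threshold is a documented argument.

`scan_class()` enumerates all $2^k$ fully-constrained patterns over the
$k$ loci of one enzyme class (32/8/32 for CYP/esterase/GST); a subject
carries a pattern iff their genotype lies in the named group at every
constrained locus, and each carrier indicator is tested with the
adjusted logistic model. `backward_eliminate()` then relaxes the
scan winner greedily: each step evaluates every pattern formed by
wildcarding exactly one constrained locus and moves to the smallest P
(ties: larger |log OR|, then lower locus index), stopping at two
constrained loci — single-locus effects belong to the single-locus
stage, and the published interaction table reports no 1-locus rows.
The **core** pattern is the minimum-P pattern on the path (ties: fewer
constrained loci). The full path is always reported so alternative
cores remain visible; the cited prior literature does not pin the step
selection down, so the deterministic greedy rule is this package's own
choice. Sex-stratified rows refit each path pattern within males and
females with age as the only covariate (sex is constant in a stratum);
the unstratified rows carry the age + sex adjustment.

## Multiple testing

Bonferroni thresholds follow the published conventions: $0.05/13 =
0.0038$ for the 13-locus frequency analysis and $0.05/11 = 0.0045$ for
the 11-SNP genetic-model analysis, with $m$ tracking the number of loci
actually kept by the screen. For the combination scan the published
analysis reuses the per-locus threshold 0.0038 even though 72 patterns
are tested; `scan_class(m =)` keeps that display convention as the
default but the family it controls is then *per locus*, not per
pattern. Under a null simulation the scan's smallest P falls below
0.0038 in roughly a quarter of replicates, so family-wise type-I
control over the scan itself requires $m$ = number of patterns tested
(72 for the full panel); that is the definition our type-I calibration
test uses, and the `m` argument makes either family explicit.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions:

* **Genotypes** are drawn independently per locus under HWE from the
  published control frequencies (e.g. effect-allele frequency 0.481 for
  the CYP1A1 promoter SNP; null frequency 0.483 for GSTT1) — the
  control stratum of a case-control study is the best available stand-in
  for the base population.
* **Demographics**: sex from the design-weighted average of the
  published per-group female fractions (257/527 and 229/499); age from
  a normal distribution centred at the design-weighted mean of the
  published group medians (66 and 58 years), with spread set from the
  published IQRs via $\sigma = \mathrm{IQR}/1.349$ and truncated to
  [30, 95] years.
* **Disease model**: a prospective logistic model with defaults
  $\beta_{\mathrm{age}} = 0.05$/year (so the sampled cases end up older
  than controls by roughly the observed 8-year median gap) and
  $\beta_{\mathrm{female}} = 0$, plus any planted carrier effects
  (`planted`: a genotype set per locus and an odds ratio). The
  intercept is calibrated by bisection on a 20,000-subject calibration
  sample so the expected case fraction matches 527/1026; exact group
  sizes are then reached by rejection (case-control) sampling. Planted
  odds ratios are collapsible here because covariates and genotypes are
  independent in the base population, so the adjusted carrier OR
  targets the planted value directly.
* **Determinism**: one random stream per run, seeded; the same seed
  yields a byte-identical cohort file. Replicated experiments derive
  per-replicate seeds as seed + replicate index.

What the generator deliberately does **not** emulate: linkage
disequilibrium between loci (the study treats loci as independent),
genotyping error and missingness, population stratification, and —
most importantly — the true joint distribution of age, sex and genotype
in the real cohort, which is unknowable from the published summaries.
Passing tests therefore demonstrate that the machinery recovers
*planted* parameters under the study's design, not that the published
covariate-adjusted odds ratios are reproduced; those depend on the
deposited individual-level data, and the package checks them only as
direction/magnitude properties (e.g. the unadjusted core-pattern
cross-product 0.406 vs the printed adjusted 0.393).

## Numerical choices

* Logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`, binomial family) with convergence tolerance 1e-8
  and at most 100 iterations; Wald inference from the Fisher
  information at the optimum.
* Complete or quasi-complete separation is flagged when any
  non-intercept |coefficient| exceeds 15 on the logit scale (an OR
  beyond $e^{15}$ is meaningless at $n \approx 1000$) or the
  information matrix is singular; flagged fits report no OR rather
  than a silent number.
* The 2×2 oracle applies the Haldane-Anscombe +0.5 correction only
  when a cell is zero, and flags it; the regression path never
  corrects, it flags.
* Missing genotypes are handled by per-analysis complete-case
  exclusion (the source study is silent on missingness).
* Elimination tie-breaks (P, then |log OR|, then locus index) are
  exact comparisons; patterns whose fit is flagged sort last.
* Rendered tables round frequencies and ORs/CIs to 3 decimals and
  P-values to 2 significant figures, matching the published display.

## Problem sizes used by the test suite

Property tests run at sizes chosen to make their Monte-Carlo error
small relative to the asserted margins while keeping the default suite
in the low minutes: 1,000 random 2×2 tables for the regression/closed-form
equivalence (log-OR agreement ≤ 1e-6), 400 replicates for Wald CI
coverage, 200 study-scale replicates for recovery of a planted carrier
OR of 0.35 (mean within ±0.10), and 100 null study-scale replicates for
family-wise type-I control of the scan (≥95% of replicates with no
sub-threshold pattern at the scan-level Bonferroni family).

## Known limitations

* The backward-elimination step rule is deterministic but not unique;
  other tie-breaks could visit different paths on near-ties. The full
  path is reported for that reason.
* Sex-stratified and adjusted results on synthetic cohorts inherit the
  generator's simplifications listed above.
* No exact (Fisher/mid-P) tests, no Firth penalization for separated
  fits, no cross-class combinations, and no formal product-term
  interaction models: the implemented "synergy" is joint-carrier
  association, as in the source analysis.
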