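---
title: "Methods: two-cohort extreme-phenotype association with xassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort extreme-phenotype association with xassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xassoc)
```

## The design this package implements

Extreme-phenotype sampling contrasts individuals at opposite tails of a
risk distribution — here the motivating setting is germline exome data
from heavy smokers who either developed lung adenocarcinoma unusually
early (extreme cases) or stayed cancer-free to advanced age (extreme
controls). Alleles that modulate susceptibility should be enriched in one
tail and depleted in the other, so modest cohorts can carry detectable
signal. The package operationalizes that design as a fixed funnel, run
identically on a discovery cohort and an independent validation cohort
sharing one variant panel:

1. site-level QC and functional prioritization of the annotated panel;
2. a PCA check for population substructure (advisory, never a hard stop);
3. a per-variant exact allelic test of case versus control allele
   frequencies;
4. a gene-level burden scan over all subsets of each gene's significant
   variants, with separate case-enriched and control-enriched signals;
5. cross-cohort validation of variants and genes by direction-coherent
   replication, combined with the intersection–union test;
6. hypergeometric gene-set enrichment of the validated genes;
7. genotype classifiers trained on the discovery cohort and evaluated on
   the validation cohort.

Every stage is a plain function over data frames and `cohort` objects;
`run_pipeline()` wires them together behind one configuration.

## The exact allelic test

For one biallelic site, each called genotype contributes two alleles;
no-calls contribute nothing (they are dropped, not imputed — the `0`
no-call code exists only in the classifier encoding). The data reduce to
a 2×2 table of alt/ref allele counts in cases and controls. Conditional
on both margins the case alt count is hypergeometric, and we report the
two-sided exact p-value under the point-probability rule: the total
probability of all tables whose point probability does not exceed the
observed one (with the customary `1 + 1e-7` relative tolerance so that
floating-point noise cannot drop an exactly tied table). Any zero margin
gives p = 1, and the enrichment direction is the sign of
`af_case − af_ctrl`.

This is a deliberate convention choice. The upstream description of the
allelic test we mirror says only that it is "fast, unbiased and exact";
whether it is the conditional test or an unconditional variant is not
recoverable. We adopt the conditional point-probability convention —
the same convention as `fisher.test()` on the allele table, which the
test suite uses as an independent cross-check — and we isolate it behind
`exact_allelic_test()` so a different convention is a one-function swap.
Correctness is defined by a brute-force enumeration oracle: the suite
recomputes every table with per-group allele totals up to 40 (≈7×10⁵
tables) from log-binomial coefficients and requires agreement to 1e-12.

Screening uses raw p-values (`p < 0.05` by default), not FDR-adjusted
ones, because the downstream validation step is itself the replication
filter; `bh_adjust()` is provided for reporting.

## The subset burden scan

A gene enters the burden stage when it harbours ≥ 2 significant variants.
The scan is a transparent surrogate for subset-based rare-variant burden
testing, not a re-implementation of any published package's internals:

* every non-empty subset of the gene's `k` significant variants is
  enumerated (`2^k − 1` subsets);
* a subset's allele counts are pooled by summation — burden on the allele
  scale, consistent with the marginal test — and re-tested exactly;
* `meta_p` is the minimum subset p multiplied by the number of subsets
  (Bonferroni over the scan), capped at 1;
* `subset_case_meta_p` repeats the scan restricted to the case-enriched
  variants, `subset_control_meta_p` to the control-enriched ones (a
  direction with no variants scores 1 with an empty best subset);
* the two directional signals are combined by Fisher's method,
  `X = −2(ln p_case + ln p_ctrl)` against χ²₄.

Two open parameters were fixed here. The degrees of freedom of the
combination are 4 because Fisher's method on two p-values has 4 df; the
source text says only "a chi-square test". The subset multiplicity
correction is a plain Bonferroni because it is exactly checkable against
a literal enumerate-and-retest oracle (the suite requires 1e-12 agreement
on 200 seeded genes). Both choices sit behind `combine_subset_meta()` and
the Bonferroni step in `subset_burden()` and can be swapped without
touching anything else. `k_max = 12` guards the `2^k` cost; larger genes
are reported unprocessed rather than silently truncated.

One statistical caveat is worth stating plainly: genes reach the burden
stage *because* they already have two marginal rejections, so among
eligible genes the subset meta-p-values are conditionally enriched — a
null simulation that conditions on eligibility will show many
`subset_meta_p < 0.05`. The scan itself is conservative: on unselected
null genes the rejection rate stays at or below nominal, which is what
the test suite asserts. Interpretation of burden p-values should always
be joint with the validation step, never in isolation.

## Cross-cohort validation

A variant validates when it is significant in both cohorts with the same
direction; significant-but-discordant variants are excluded and reported
separately. "Significant in both" is an intersection–union hypothesis, so
the combined p-value is `max(p_disc, p_val)` — it is below α exactly when
both components are.

A gene validates when each cohort contributes at least one significant
variant in it (the same or different physical variants), all significant
variants across both cohorts share one direction, and each cohort's
evidence passes α: the matching directional subset meta-p where that
cohort has ≥ 2 significant variants in the gene, the single variant's own
allelic p where it has exactly one. Genes with exactly one significant
variant per cohort are therefore admissible — replication of a gene does
not require replication of a specific allele. The coherence rule is
applied to significant variants only; non-significant variants of
opposite direction do not disqualify a gene.

Variant identity across cohorts is the `chrom:pos:ref:alt` key, which
survives annotation-version drift; identifier collisions with conflicting
alleles are an input error, and multi-allelic records must be split
upstream (the reader rejects them rather than guessing).

Enrichment of the validated gene set uses the one-sided hypergeometric
tail against user-supplied GMT collections. The universe defaults to all
genes carrying at least one tested variant: the urn should be the
assayable space, not the whole genome.

## The classifier stage

Genotypes become ordinal allelic doses — 0 no-call, 1 absent, 2
heterozygous, 3 homozygous alternate — with extreme cases as the positive
class; a per-gene variant-count encoding is available as an alternative
input. Four model families are supported: ridge-penalized logistic
regression (via glmnet), a squared-hinge kernel SVC (linear and RBF), a
random forest, and gradient-boosted trees. No tree or SVM package exists
in the supported dependency set, so the last three are implemented inside
the package as deliberately plain, deterministic small-data learners; the
SVC exposes its decision function as the ROC score, the tree ensembles
their class fractions/probabilities.

Hyperparameters are selected by stratified K-fold cross-validated grid
search on the discovery cohort, maximizing mean left-out accuracy, with
ties broken by grid order; the winner is retrained on the full discovery
cohort and evaluated once on the validation cohort (accuracy, precision,
recall and F1 on the case class, and ROC-AUC — equal to the normalized
Mann–Whitney statistic, with tied scores receiving half credit). K is not
specified by the motivating study; the default is K = 5. The default
grids are modest stand-ins (the study's appendix grids are unavailable)
and are exposed through `ml_design()`. Dose codes are standardized for
LR/SVC using training-fold statistics only, to avoid leakage; tree models
see raw codes. One leakage subtlety recurs in any replication exercise:
feature selection must not see the labels being evaluated — in the
package's pipeline the classifier features are the validated variants,
selected from the association stage, and permutation checks in the test
suite fix the feature set before permuting labels for exactly this
reason.

## The synthetic world

The generator emulates the structure of the motivating study, not its
(non-deposited) data:

* cohort sizes 50/50 (discovery) and 66/83 (validation) by default;
* one shared panel of independent biallelic variants (default 5000 in 500
  genes, null MAF uniform on 0.01–0.30 — no allele-frequency spectrum is
  reported upstream, so a flat spectrum over the plausibly testable range
  was chosen once);
* planted signal with a per-allele odds ratio of 4 at baseline allele
  frequency 0.15: 16 coherent singleton variants (8 risk, 8 protective)
  plus 3 variant-rich genes of 4 same-direction variants each, echoing
  the validated counts of the motivating study; the enriched-group
  frequency is solved from `af' = OR·af / (1 + af(OR − 1))`, so the
  generating odds ratio is exact by construction in both cohorts;
* genotypes drawn per individual under Hardy–Weinberg equilibrium from
  the group allele frequency, then no-calls applied independently at 2%
  (a typical exome-panel missingness; the study reports none);
* ages and pack-years drawn uniformly inside the eligibility windows
  (cases 35–56 years, controls 74–87, both ≥ 15 pack-years) and carried
  as metadata only. The upstream text prints a case pack-year range
  starting at 5 despite the ≥ 15 inclusion criterion; the generator
  follows the criterion.

The default `planted_or = 4` is a testing convenience, not an estimate —
the true effect-size spectrum of validated variants is unknown. What the
simulator deliberately omits: linkage disequilibrium, relatedness,
population substructure (the motivating cohorts showed none; a separate
two-subpopulation generator exists solely to exercise the PCA check),
genotyping error beyond missingness, and any realistic gene length or
allele-frequency architecture. A green recovery test therefore
establishes that the machinery finds what it is specified to find under
its own stated world — it is not evidence about real exomes.

## Numerical conventions

* Exact-test ties: point probabilities compare with relative tolerance
  `1 + 1e-7`; if the whole support qualifies the p-value is exactly 1.
* Burden best subsets: argmin ties resolve to the lexicographically
  smallest sorted variant list.
* `combine_subset_meta(0, ·)` clamps to the smallest positive double with
  a warning rather than returning NaN.
* Association results sort by p then `variant_id`, so outputs are
  byte-stable; the whole pipeline is a deterministic function of the
  configuration and seed, which the suite checks by hashing artifacts.
* QC boundaries are retained (exclusion rules are strict inequalities:
  DP < 20, FS > 60, SOR > 40 remove); only the three named rules are
  implemented, each individually toggleable, because the upstream filter
  list is open-ended ("among others").
* Degenerate inputs fail loudly: both-empty allele tables, constant
  genotype matrices, folds missing a class, multi-variant genes without a
  burden record.

## Limitations

The burden scan is a documented surrogate, not a reproduction of the
referenced burden package. No covariate adjustment, mixed models or
genomic control are provided — the extreme-phenotype design argues for,
but does not guarantee, confounder-free contrasts. The classifier grids
are stand-ins. Allele-level pooling double-counts individuals carrying
several of a gene's variants, which is the intended burden reading but
differs from carrier-indicator collapsing. All p-values are exact but
conditional; no attempt is made to de-bias the winner's-curse effect on
validated effect-size estimates.
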