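# xassoc — extreme-phenotype case-control germline association

`xassoc` implements a two-cohort extreme-phenotype association pipeline
for germline case-control genotype data. The design it targets contrasts
individuals at opposite tails of a risk distribution (the motivating
setting: heavy smokers with very early lung adenocarcinoma versus heavy
smokers cancer-free at advanced age), genotyped over one shared variant
panel in an independent discovery and validation cohort. It is intended
for statistical geneticists and bioinformaticians who want the whole
funnel — per-variant testing, gene-level burden, cross-cohort
replication, enrichment, and genotype classifiers — as tested, reusable,
deterministic functions rather than a one-off analysis script.

## What it computes

**Exact allelic test.** For each biallelic site, the 2×2 table of
alt/ref allele counts in cases and controls (two alleles per called
genotype; no-calls dropped). Conditional on the margins the case alt
count *x* is hypergeometric, and the two-sided exact p-value sums the
point probabilities of all tables as or less probable than the observed
one:

    p = Σ { P(X = k) : P(X = k) ≤ P(X = x) }

with direction from the sign of af_case − af_ctrl. The test suite proves
agreement with a brute-force enumeration oracle to 1e-12 over every
table with per-group allele totals ≤ 40.

**Subset burden.** For a gene with k ≥ 2 significant variants, every
non-empty subset's allele counts are pooled and re-tested; the reported
`meta_p` is the Bonferroni-adjusted minimum over all 2^k − 1 subsets,
with separate case-enriched and control-enriched scans
(`subset_case_meta_p`, `subset_control_meta_p`) combined by Fisher's
method, X = −2(ln p_case + ln p_ctrl) ~ χ²₄.

**Cross-cohort validation.** A variant validates when significant in
both cohorts with the same direction; the combined p-value is the
intersection–union test, max(p_disc, p_val). A gene validates when both
cohorts contribute coherent significant variants (the same or different
ones) and each cohort's evidence — directional subset meta-p for ≥ 2
variants, the individual allelic p for exactly 1 — passes the threshold.
Validated genes feed a one-sided hypergeometric gene-set enrichment over
user-supplied GMT collections.

**Classifiers.** Genotypes become allelic doses (0 no-call, 1 absent,
2 het, 3 hom-alt); LR, SVC, RF and gradient-boosted trees are tuned by
stratified K-fold CV grid search on discovery and evaluated once on
validation (accuracy, precision, recall, F1, ROC-AUC).

**Synthetic worlds.** `simulate_cohort_pair()` generates paired cohorts
(default 50/50 and 66/83) with planted coherent risk/protective variants
at an exact per-allele odds ratio, variant-rich genes, Hardy–Weinberg
genotypes, no-calls, and a ground-truth table, so every downstream stage
is testable offline.

## Worked example

```r
library(xassoc)

cfg  <- simulation_config(n_variants = 2000, n_genes = 220, seed = 42)
pair <- simulate_cohort_pair(cfg)
pair$discovery
#> <cohort> 100 samples (50 cases / 50 controls), 2000 variants, 220 genes
#>   no-call rate: 0.0199

assoc_disc <- run_association(pair$discovery)
assoc_val  <- run_association(pair$validation)
head(assoc_disc$significant[, c("variant_id", "gene", "af_case", "af_ctrl",
                                "p", "direction")], 5)
#>    variant_id   gene    af_case   af_ctrl            p direction
#> 1 1:26000:T:C GP0014 0.09000000 0.4375000 3.026431e-08   control
#> 2 1:16000:A:C GP0004 0.44897959 0.1020408 6.071557e-08      case
#> 3 1:24000:A:C GP0012 0.09782609 0.4387755 9.775346e-08   control
#> 4  1:9000:A:C  GR003 0.46000000 0.1170213 1.188167e-07      case
#> 5  1:5000:C:T  GR002 0.15306122 0.5000000 1.843257e-07   control
```

Variants significant at p < 0.05 in *both* cohorts with a coherent
direction validate; variant-rich genes replicate through their
directional burden signal:

```r
vv <- validate_variants(assoc_disc$all, assoc_val$all)
nrow(vv$validated)
#> [1] 29

vg <- validate_genes(assoc_disc$all, assoc_val$all,
                     run_burden(assoc_disc$all), run_burden(assoc_val$all))
head(vg, 5)
#>     gene direction n_var_disc n_var_val       p_disc        p_val
#> 1  GR002   control          4         4 1.178807e-18 7.699178e-25
#> 2  GR003      case          4         4 8.100464e-15 3.750260e-22
#> 3  GR001      case          4         4 2.277028e-12 4.478145e-25
#> 4 GP0004      case          1         1 6.071557e-08 1.140854e-08
#> 5 GP0015   control          1         1 3.638093e-07 2.294292e-08
```

The three planted variant-rich genes (`GR001`–`GR003`) head the table
with the planted directions, each supported by 4 variants per cohort;
`p_disc`/`p_val` are the directional subset meta-p-values (or the single
variant's allelic p for one-variant sides). The validated variants then
drive the classifier stage:

```r
ml <- run_ml(pair$discovery, pair$validation, vv$validated$variant_id, seed = 1)
ml
#> <ml_report> 29 features (variant mode)
#>   family cv_accuracy cv_auc accuracy precision recall    f1   auc
#> 1     LR        0.97  0.993    0.987     0.985  0.985 0.985 0.999
#> 2    SVC        0.96  0.990    0.980     0.985  0.970 0.977 0.998
#> 3     RF        0.97  0.995    0.960     0.941  0.970 0.955 0.994
#> 4   GbRF        0.91  0.963    0.879     0.864  0.864 0.864 0.969
```

`cv_accuracy`/`cv_auc` are discovery-cohort cross-validation metrics for
the selected hyperparameters; the remaining columns are held-out
validation-cohort performance (case = positive class). On this planted
world the signal is strong and every family separates the tails almost
perfectly; real exomes are far harder.

The same funnel runs end to end from one config —
`run_pipeline(pipeline_config(...))` — writing per-stage TSV/JSON
artifacts plus a manifest, byte-identically across reruns of one seed.
A thin CLI wrapper lives in `inst/scripts/xassoc.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the default simulated world
under the given seed (simulation → QC → association on both cohorts →
burden → validation → classifiers), prints the stage funnel, and writes
the JSON report to `--out`.
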