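---
title: "Detecting transcriptional patterns of driver-gene alterations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional patterns of driver-gene alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivertx)
```

## The question the package answers

When a cancer driver gene loses wild-type activity — through a nonsense or
missense mutation, a frameshift, a splice-site change, a deep deletion or a
high-level amplification — does the tumour's transcriptome change in a way
that is specific to that gene? `drivertx` operationalises this question as a
supervised classification problem: for each driver gene, samples are labelled
*mutant* or *wild-type* from their DNA alteration calls, and a random-forest
classifier is trained on genome-wide expression (TPM) profiles. If the
classifier separates the classes well beyond chance, and the separation is
carried by a reproducible set of transcripts, the gene has a detectable
transcriptional pattern; the structure of where the classifier succeeds
(everywhere, or in particular tumour types) categorises the pattern.

The pipeline runs these stages per gene:

1. **Labelling** (`build_labels`). Variant consequence terms are mapped to
   *impactful* (nonsense, missense, frameshift, splice, inframe indels,
   stop/start loss) or *non-impactful* (synonymous, UTR, intronic,
   up/downstream, intergenic). Samples with at least one qualifying
   alteration are mutant; samples with no record for the gene are wild-type;
   samples carrying only non-impactful variants are *excluded* from training
   and revisited at the end. Under a setting that includes copy-number data,
   high-level events (copy number 0 or ≥ 4 against a diploid baseline, both
   configurable) also make a sample mutant.
2. **Alteration-setting choice** (`choose_alteration_setting`). Cross-
   validated F1 with and without CNA mutants is compared; CNAs are adopted
   only when they improve F1 by more than ε (default 0.01 absolute). SV
   settings can be evaluated the same way but are off by default: SV calls
   are sparse and their functional impact on a given gene is hard to
   confirm, so they tend to add label noise for little F1.
3. **Mode selection** (`compare_modes`). Four analysis modes are scored as
   mean ± SD of F1 over repeated 5-fold CV: all samples; samples of selected
   tumour types; class-balanced sets of all types; balanced sets of the
   selected types. Types are selected by a Gaussian z-threshold
   (`derive_threshold`, upper tail, α = 0.1) on per-type F1, falling back to
   the single best type. A narrower mode is adopted only when it improves
   mean F1 by more than 5% (relative). Under-performing types are then pruned
   iteratively (`prune_types`) while a type's F1 trails the pooled score by
   more than δ = 0.05.
4. **Final fit and confound screening** (`fit_final`,
   `proximity_filter`). The forest is refit on the chosen mode's samples;
   reported F1 is always cross-validated, never resubstitution. Because a
   copy-number event drags the expression of its chromosomal neighbours with
   it (cis dosage), top-ranked features clustering near the driver's locus
   are treated as confounds: the contiguous gene block containing any cluster
   of ≥ 3 top-15 features within 10 Mb of the locus (pairwise gaps ≤ 1 Mb) is
   excised and the model refit, iterating until the top ranks are clean.
5. **Feature significance and direction** (`gini_null`,
   `signed_attribution`). Gini importances are compared rank-for-rank against
   an empirical null built by refitting on label permutations; features are
   counted significant from rank 1 down until the first rank that fails its
   null quantile. Each top feature gets a direction — higher expression
   pushing predictions toward wild-type (tumour-suppressor-like network loss)
   or toward mutant (oncogene-like activation) — from decision-path
   attributions.
6. **Categorisation** (`categorize_pattern`). Across genes, a lower
   z-threshold (α = 0.1) on final F1 and a lower 25th-percentile threshold on
   top Gini separate `pan_cancer` and `tumour_specific` patterns from
   `no_or_weak` ones; high F1 with a sub-threshold top Gini on a balanced set
   of ≤ 2 tumour types is flagged `potential_overfit`, the signature of a
   model that memorised a small cohort.
7. **Re-examining "silent" samples** (`predict_excluded`). The final model
   predicts the excluded group; consequence terms whose carriers are
   predominantly predicted mutant (> 50%, n ≥ 5) are flagged — in practice
   intronic variants causing intron retention behave this way.

## The random forest

No random-forest implementation is available in the deployment environment,
so the package ships its own (`src/forest.cpp`): CART trees on bootstrap
resamples, Gini split criterion, `mtry` random candidate features per node
(default ⌊√p⌋), grown to purity by default, 1000 trees by default. Feature
importance is the mean decrease in Gini impurity, normalised per tree to sum
to one and averaged. Class probabilities are mean leaf class fractions.

Two implementation choices deserve a note:

* **Histogram splitting.** Split search uses per-feature quantile binning
  (≤ 256 bins, cut points kept on the original expression scale), so a node
  costs one pass over its samples instead of a sort. Thresholds are placed
  mid-way across empty-value gaps, as a sort-based CART would place them;
  without this, held-out samples falling inside a gap are systematically
  routed to the right child. A "bin once, refit many" path serves the
  cross-validation and permutation loops.
* **Determinism.** Tree growth uses a self-contained splitmix64 RNG seeded
  from the user seed, so fitted forests are bit-reproducible across platforms
  and independent of R's RNG state; fold assignment and down-sampling draw
  from R's RNG under explicitly set seeds.

Direction of association is computed by decision-path attribution: along each
tree path the change in wild-type probability at a split is credited to the
split feature, and the per-sample credits are rank-correlated with the
feature's expression. This is the Saabas decomposition — the quantity TreeSHAP
refines with exact Shapley weighting — and for sign purposes the two agree;
an independent fallback (rank correlation of expression with predicted
wild-type probability) is reported per feature, and the two signs agree for
essentially all genuinely informative features.

F1 is computed with **wild-type as the positive class** throughout
(configurable). Note the consequence: with mutants rare, the trivial
all-wild-type classifier already earns a high F1 (for a 30% mutant fraction,
about 0.82), so F1 values must always be read against that baseline — which
is exactly why categorisation also requires significant features and a
competitive top Gini.

## The synthetic world

All tests and acceptance runs use cohorts from `generate_cohort`, which emits
expression, metadata, variant/CNA/SV tables and a ground-truth record.
Expression is additive on the log2(TPM + 1) scale:

> x = baseline + tumour-type offset + driver shift + cis dosage + noise,
> TPM = 2^x − 1 clipped at 0

with per-transcript baselines ~ U(3, 8), per-type offsets ~ N(0, 1),
Gaussian noise SD 1, and driver shifts of ±`effect_size` applied to the
signature transcripts of mutant (and cryptic) samples — in every tumour type
for a pan-cancer driver, only in `affected_types` for a tumour-specific one,
never for a null driver. Copy-number carriers additionally shift every
transcript within `cis_window_mb` of the driver locus by
`cis_dosage_coef` × (copy number − 2): the confound the proximity filter
exists to remove. Signature transcripts are drawn from coding genes on
driver-free chromosomes, so signal and confound are separable by
construction and "the filter spared the signature" is a meaningful check.

The simulated genome is 22 chromosomes × 14 Mb with one transcript per
~150 kb — a real genome's gene density, scaled down — so Mb-scale proximity
rules behave realistically. Defaults (600 samples, 2000 transcripts, 4 equal
tumour types, 30% mutants, 10% silent carriers, effect size 1.5, noise SD 1)
are the stated world of the acceptance criteria; effect size 1.5 at noise 1
makes each signature gene a d = 1.5 marker, individually strong but far from
deterministic, so recovery results are informative rather than trivial.

One deliberate refinement: the *world* — genome layout, baselines,
tumour-type offsets, signature assignments — is a deterministic function of
the config and does **not** vary with the seed. Different seeds draw new
patients from the same biology. Without this, "validate on an external cohort
from the same world" would silently mean "validate across a fresh batch
effect", and the PCA merging audit could never be clean.

What a green test does *not* establish: the generator has no tumour purity or
stromal signal, no read-level noise, no correlated co-expression modules
beyond the type offsets, no mutation co-occurrence structure, and its
"cryptic" samples carry the full mutant shift rather than a partial one. It
validates the machinery — labelling logic, CV bookkeeping, threshold rules,
filter behaviour, calibration of the permutation null — not biological effect
sizes, which on real cohorts are whatever they are.

## Numerical and procedural choices

* **Hyperparameters.** Defaults are 1000 trees, ⌊√p⌋ features per split, no depth
  limit, no class weighting (imbalance is handled structurally, by setting
  choice and down-sampling). A small holdout grid helper (`tune_rf`) is
  provided. Tests use 40–100 trees: at these data sizes the F1 estimate is
  stable to ~0.01 by 50 trees, and where a comparison rides on margins of
  that order (the ε rule) tests use 100.
* **"Improved by more than 5%"** is interpreted as a relative gain;
  absolute-points mode is available via `relative = FALSE`.
* **Permutation counts.** Mode comparison defaults to 30 permutations and the
  Gini null to 50; the test suite runs 3–5 and 10–20 respectively, which
  widens Monte-Carlo error but leaves every decision rule and calibration
  property intact.
* **z-thresholds are always recomputed** from the run's own score
  populations and never hardcoded: any particular threshold value is a
  property of the cohort it was derived from. The pipeline
  derives the type-selection threshold from the current gene's per-type F1
  values; pooled derivation across genes is available by calling
  `derive_threshold` on the pooled population directly.
* **Ties and degenerate cases.** Feature-importance ties break
  lexicographically by transcript id; type-selection ties break by sample
  count then name; a zero-variance threshold population returns its mean
  flagged `degenerate`; per-type F1 with a single class present is missing,
  never 0; F1 with no positive predictions is 0 with a warning; an excision
  pass that would remove more than 5% of features aborts with a warning.
* **Samples whose only alteration a setting ignores** (e.g. a CNA-only
  sample under `snv`) are excluded rather than wild-type: the wild-type class
  stays clean across settings, at the cost of a slightly smaller cohort.
* **Cut-off for calling an excluded sample mutant** is the class vote (0.5),
  there being no stated probability threshold to match.

## Known limitations

* The forest is binary; multi-class alteration states (e.g. separating
  deletion from amplification) are out of scope.
* `gini_null` refits the forest per permutation; at 1000 trees and 50
  permutations this is the pipeline's most expensive stage by far.
* The overfit flag requires the balanced-small-cohort condition and so cannot
  fire for a pan-cancer analysis, mirroring its rationale.
* Cross-cohort prediction retrains on shared features when coverage is
  partial; it does not attempt batch correction.

## A worked miniature

```{r example, eval = FALSE}
cfg <- cohort_config(
  n_samples = 300, n_genes = 500, n_coding = 200, seed = 11,
  drivers = list(
    driver_spec("PANX", "pan_cancer", effect_size = 1.5, cna_fraction = 0.4,
                cis_dosage_coef = 0.5, cryptic_fraction = 0.3),
    driver_spec("SPEC", "tumour_specific", affected_types = "TTB"),
    driver_spec("NULLG", "null", effect_size = 0)))
cohort <- generate_cohort(cfg)
res <- run_pipeline(cohort, n_perm_modes = 5, n_perm_gini = 10,
                    n_trees = 50, seed = 5)
res$categories[, c("gene", "category")]
#>    gene        category
#>    PANX      pan_cancer
#>    SPEC tumour_specific
#>   NULLG      no_or_weak
```

The null driver's F1 (~0.80) sits at the majority baseline, its top Gini at
the cohort floor, and it has zero significant features — all three routes to
`no_or_weak`.
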