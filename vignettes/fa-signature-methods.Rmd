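---
title: "Methods: fatty-acid signature analysis of arthritic joint tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatty-acid signature analysis of arthritic joint tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analytical problem

Gas-chromatographic profiling of a tissue sample yields the relative
abundance of each fatty-acid (FA) chain as a percentage of all measured
lipid side chains (mol-%). In inflammatory joint disease, the question is
whether the synovial-membrane FA signature differs between rheumatoid
arthritis (RA) and osteoarthritis (OA), which individual FAs or FA
families carry that difference, and whether the elongation/desaturation
machinery that interconverts FAs behaves differently in the two diseases.
The cohorts involved are small — on the order of eight patients per
diagnosis — so every method in this package is chosen for honest behavior
at small n: exact tests, resampling, and explicit regularization.

`fasig` implements the full chain: derived-variable computation, Z-score
normalization, per-variable two-group statistics, correlation-based FA
grouping, a group-sampling data-enrichment scheme feeding repeated
random-forest classification, linear discriminant analysis (LDA), and a
reaction-network pathway analysis.

## Data model

A profile table is a tibble with one row per sample: `sample_id`,
`diagnosis` (RA/OA), optional `tissue`, then one numeric column per
variable. Raw FA columns are recognized by their chain label
(`"20:4n-6"`, `"DMA 18:0"`, ...); everything else is a derived sum,
ratio or index. Raw mol-% columns must be non-negative and sum to 100
per sample within a tolerance of ±0.5 (published tables round to two
decimals); `validate_profiles()` warns on violations and can
renormalize.

Derived variables are defined by declarative recipes
(`fa_recipe()`): class sums (SFA, MUFA, PUFA, n-3/n-6 PUFA, DMA,
C20–24 SFA), the n-3/n-6 ratio, product/precursor ratios
(C20–22 products of a series over its C18 precursor), the double bond
index $\sum_i \text{mol\%}_i \cdot \text{nDB}_i / 100$ and the average
chain length $\sum_i \text{mol\%}_i \cdot \text{nC}_i / 100$. The exact
composition of such indices varies between laboratories, so the recipe
set is data (serializable to YAML), not code, and every part of it can
be overridden. DMA chains are included in the double-bond index and the
average chain length: they are measured carbon chains like any other.
If a recipe references an FA absent from the table the call fails,
listing the missing labels, unless `missing_as_zero = TRUE`.

## Normalization and univariate statistics

Each variable is standardized across samples,
$Z_i = (x_i - \langle x \rangle_\text{samples}) / \sigma_\text{samples}$,
with the *population* standard deviation (denominator n). The choice of
denominator is a convention; it is configurable (`ddof`), and the
population form makes each variable exactly mean 0, SD 1 over the
standardization set. Zero-variance variables are rejected by name
rather than silently becoming `NaN`.

Between-diagnosis comparisons use the Mann–Whitney U test: for
tie-free data with both groups of at most 12 samples the two-sided
p-value is exact (the study-sized 8 + 8 design always lands in this
branch); larger or tied data use the normal approximation with
continuity and tie correction. No multiple-testing correction is applied
to the significance flags — per-FA testing in this field is
conventionally reported unadjusted — but a Benjamini–Hochberg column is
emitted alongside for the reader. Sex-ratio style 2×2 tables use
Fisher's exact test.

## FA grouping

Variables are clustered with the distance $d = 1 - r$ (Pearson
correlation across samples) and Ward linkage on *unsquared* distances
(`hclust` method `"ward.D"`), the combination used by the ClustVis
service for its "correlation" distance. We use $1 - r$, not
$1 - |r|$: anticorrelated variables are distant. The clustering is
deterministic given the input column order. Group membership is
obtained either by cutting the tree into `k` groups (default `k = 5`)
or by a manual mapping table, which always overrides the cut — a
published grouping is typically fixed by visual assessment of the
heatmap, and the package does not pretend to automate that judgement.

## Data enrichment and random forests

Within a correlated FA group the variables carry largely redundant
information, so a sample can be represented by *any one* member of each
group. `enrich()` exploits this: at each of B iterations one variable
per group is drawn uniformly (with replacement across iterations), and
all n samples are emitted with the K drawn Z-values and copied
diagnosis labels, giving a B × n-row, K-feature dataset (16,000 rows
for B = 1000, n = 16, K = 5).

`train_rf()` then repeatedly (default 100 times) draws a stratified
80/20 train/test split, fits a 100-tree random forest (depth cap 16,
minimum node size 1, five candidate features per split, bootstrap
resampling with replacement at full sample size), and records the test
accuracy and the impurity-based feature importances, normalized to sum
to one and estimated from training data only. The package uses the Gini
impurity as split criterion; for binary classification Gini and entropy
produce near-identical split orderings, and the choice is recorded in
the run's parameter object. The split fraction is stated but
stratification is this package's choice: it avoids degenerate test sets
and is standard practice. `mtry = 5` is kept also for full-variable
runs so the enriched and full configurations differ only in their
features. A single seed fans out to per-repeat sub-seeds, so runs are
bit-reproducible while repeats stay independent.

Two properties of this design deserve emphasis. First, enriched rows
derived from the same source sample appear on both sides of the
train/test split; the reported "enriched accuracy" therefore measures
how well partial group profiles identify the inflammatory state of
*known* samples, not generalization to unseen patients — that is
exactly what the enrichment procedure is designed to quantify, and why
it far exceeds the no-enrichment accuracy. Second, impurity-based
importance is diluted by correlated features and by the
sample-memorization effect above: with a moderate (≈1.5 SD) planted
group effect at n = 8 + 8, the effect-carrying group wins the
importance ranking only ~60% of the time, whereas a group that
separates the classes outright (≈3 SD) wins essentially always. Tests
of ranking stability therefore use the strong-effect configuration.

## Discriminant analysis

`fit_lda()` performs canonical discriminant analysis with equal priors
and the pooled within-groups covariance W: discriminant directions are
eigenvectors of $W^{-1}B$, solved via Cholesky whitening, scaled so
each function has unit pooled within-class variance, and oriented so
the alphabetically first class has a negative mean score. With g
classes and p variables there are min(g − 1, p) functions; their
eigenvalue shares are the reported "% of between-group variance", so a
two-class analysis always has exactly one function carrying 100%.
Classification is nearest-centroid in the discriminant space, which
under these conventions equals the minimal-Mahalanobis rule with equal
priors. With 40+ variables on 16 samples W is singular, so a ridge
$\lambda = 10^{-6}\,\mathrm{tr}(W)/p$ is added by default; the
regularization is explicit, reported in the fitted object, and can be
disabled (in which case singularity is an error naming the most
collinear variables). `loo_accuracy()` refits without each sample in
turn — the honest counterpart of resubstitution accuracy, which at
p ≫ n is always 1.

## Pathway analysis

The reaction network covers the mammalian elongation (+2 C),
chain-shortening (−2 C) and desaturation (+1 double bond) reactions
over the measured chains, with double-bond positions (n-series)
distinguished throughout — the n-3 and n-6 families are not
interconvertible and must not be merged. The default table encodes the
SFA ladder (14:0 → ... → 24:0), the Δ9 branches into the n-7 and n-9
MUFA series, and the n-6 and n-3 PUFA chains including the C24
intermediates and peroxisomal shortening steps that produce 22:5n-6
and 22:6n-3. The table ships as an editable TSV; it is a best-effort
literature reconstruction and should be reviewed before being applied
to other designs. Where a chain passes through unmeasured
intermediates, the maximal unmeasured stretch is contracted into a
single *effective* edge carrying the summed deltas — e.g. with the C24
n-3 intermediates unmeasured, 22:5n-3 → 22:6n-3 appears as one
effective edge.

Each FA gets a level-change score
$(\langle\text{FA}\rangle_\text{RA} - \langle\text{FA}\rangle_\text{OA})
/ \langle\text{FA}\rangle_\text{OA}$ (OA as reference). Each edge gets
the Pearson correlation between substrate and product mol-% computed
*within each diagnosis separately*, and a four-way class from the two
p-values at α = 0.05: `sig_both`, `sig_OA_only`, `sig_RA_only`,
`sig_neither`. Within-group Pearson r is location/scale invariant, so
computing it on mol-% or Z-scores is equivalent; mol-% is used as the
more direct reading. Edge direction comes exclusively from reaction
chemistry — correlation is symmetric and never flips an edge; a
significant within-diagnosis correlation is interpreted as the
reaction being a candidate dominant biosynthesis route in that
diagnosis, no more. No multiplicity correction is applied over edges,
mirroring the per-edge α convention of this analysis style. DMA
variables and derived sums/ratios are excluded from the network (the
network describes acyl-chain interconversion).

## Synthetic data

`generate_profiles()` draws, per sample and group g, a latent factor
$f \sim N(0,1)$ and sets each member variable to
$x = \delta_g\,c + \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ with
class indicator c, so variables have unit variance, intra-group
correlation ρ and a between-class shift of $\delta_g$ SD units. A
single factor per group is the simplest model that reproduces the
block-correlation structure seen in real FA profiles. Defaults emulate
the study conditions: 8 + 8 samples, 5 groups of 8 variables,
ρ = 0.8 (realized intra-group correlations ≈ 0.7–0.85 at n = 16), and
effect vector (0, 0, 0, 1.5, 0) placing a moderate diagnosis signal in
group 4. Optional planted edge effects overwrite a product variable
within one diagnosis as $r\,\tilde s + \sqrt{1-r^2}\,\varepsilon$
(standardized substrate $\tilde s$), for pathway power studies.

mol-% mode applies a logistic-normal closure:
$100\,e^{\sigma x_j + \mu_j} / \sum_k e^{\sigma x_k + \mu_k}$ with
σ = 0.4 and base log-abundances $\mu_j$ spread over ≈0.2–8 mol-%,
assigned round-robin across groups so abundance is not confounded with
group identity. This keeps values positive, sums each sample to
exactly 100, and preserves the within-sample rank order of the latent
magnitudes. Closure redistributes mass: a strong shift in one group
leaks a compensating (anti-correlated) signal into all other
variables, exactly as real compositional data behave. Z-mode
(`closure = FALSE`) bypasses the map for tests that operate on the
Z-score pipeline directly.

What the generator does *not* emulate: chromatographic measurement
noise, lipid-class structure, patient covariates, or the specific mean
profile of any real tissue. Passing tests on synthetic data
demonstrate that the algorithms recover planted structure under the
stated statistical model, not that any biological conclusion holds.

`study_shaped_fixture()` freezes the default configuration with real
chain labels into a deterministic 16 × 40 mol-% table used as the
stand-in for the clinical dataset in all integration tests — it is
synthetic and labelled as such.

## Numerical choices and problem sizes

- Mann–Whitney exact branch: both n ≤ 12 and tie-free; verified against
  full enumeration of label assignments for all group sizes up to
  8 + 8.
- Correlation p-values: two-sided t on n − 2 df; |r| = 1 maps to p = 0.
- LDA ridge: $10^{-6}\,\mathrm{tr}(W)/p$; eigen-solve via Cholesky
  whitening with symmetrization; spectrum checked against an
  independent implementation on a well-conditioned reference dataset.
- Agglomeration ties: resolved by `hclust`'s deterministic rule, so
  results are stable across platforms for a fixed column order.
- Forest runs use one computation thread and per-repeat seeds for
  bit-reproducibility.
- Test-suite problem sizes: the integration checks run the enrichment
  at the study scale (B = 1000, 100 forests) once; ranking-stability
  and calibration checks use 20 seeded runs at B = 200 and 500/100
  simulation replicates respectively — sizes chosen to make the checked
  proportions statistically meaningful while keeping the default suite
  quick to run.

## Known limitations

- Impurity importances are biased under correlated features; a
  permutation-based alternative is a reasonable extension, and the
  per-group aggregation partly mitigates the issue by construction.
- The enriched accuracy is a redundancy measure, not an estimate of
  out-of-sample diagnostic performance; the no-enrichment forest and
  the LDA leave-one-out accuracy are the honest generalization
  numbers, and at n = 16 they are noisy.
- The reaction table is a literature reconstruction; effective-edge
  contraction assumes the interior of a chain is genuinely unmeasured
  rather than measured under another name.
- The XLSX reader accepts the spreadsheet layout described in
  `read_profile_table()` but the canonical interchange format is TSV.
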