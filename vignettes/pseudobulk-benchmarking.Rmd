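---
title: "Simulating and scoring pseudobulk mixtures for tumour deconvolution benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring pseudobulk mixtures for tumour deconvolution benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomix)
```

## The problem

Bulk RNA-seq of a tumour biopsy measures a mixture: malignant epithelial
cells, immune infiltrate, fibroblasts, endothelium and more contribute to
every gene's read count in unknown proportions. Deconvolution methods
estimate those per-cell-type proportions from the bulk profile, usually
with help from an annotated scRNA-seq reference. Benchmarking such
methods requires mixtures whose composition is *known*, which real bulk
samples never offer. The standard device is the artificial (pseudo-)bulk
mixture: sum the expression of a known set of annotated single cells and
treat the realized cell counts as ground truth.

`pseudomix` implements that benchmarking loop end to end: a synthetic
corpus generator shaped like annotated breast-tumour scRNA-seq cohorts,
per-patient SMOTE balancing of minority cell types, three mixture-design
simulators (sparse training, fixed-tumour-purity titration,
lineage-granular), reference/signature construction, a non-negative
least-squares (NNLS) baseline deconvolver plus an adapter contract for
external tools, and a compositional scoring suite.

## Mixture simulation model

Every mixture contains exactly `total_cells` (default 500) single cells
from **one** donor, preserving inter-patient heterogeneity. For one
mixture over the donor's available types:

1. The number of included types `k` is drawn uniformly between 5 and the
   number of available types (degenerating to all types when fewer than
   5 are available, which is logged).
2. One included type is the *free-range* type: its fraction is drawn
   `U(0, 1)` (scaled into `1 - purity` when a tumour-purity constraint
   is active). Without this device, normalizing i.i.d. uniforms
   concentrates every fraction near `1/k`; the free-range draw gives the
   trained and tested methods mixtures spanning nearly the whole simplex.
3. The remaining included types split what is left proportionally to
   i.i.d. `U(0, 1)` draws, so fractions sum to exactly 1.
4. Fractions are converted to integer cell counts summing exactly to the
   mixture size by largest-remainder rounding (ties to the earliest
   position — the paper-scale design never depends on the tie, but
   determinism does).
5. Cells are sampled without replacement within the mixture from the
   donor's pool and their CP10K vectors are summed.

Ground truth is defined from the realized integer counts, not the
continuous fractions: the 500 sampled cells are the physical content of
the pseudobulk, and on the default 5–95% purity grid `purity * 500` is
integral so the cancer-epithelial truth equals the grid value exactly.
Both the continuous fractions and the realized counts are recorded on
every `MixtureSpec`, so either convention can be audited.

The three shipped designs mirror a full benchmarking campaign: 5,000
sparse mixtures per training donor (18 donors gives 90,000); a test
purity titration of 19 levels (5%, 10%, ..., 95%) with 250 mixtures per
donor per level (8 donors gives 38,000); and lineage-granular sets of
250 mixtures per test donor (2,000 in total) in which chosen major
lineages are replaced by their minor or subset children, optionally at a
fixed 50% tumour purity, optionally excluding a lineage's children
entirely. `assemble = FALSE` produces specs and truth without expression
sums, which is how the design arithmetic is verified quickly.

## SMOTE balancing

Cell-type abundance in a real patient spans orders of magnitude, which
starves the sampler for rare types. Before simulation, each patient's
retained types are brought up to that patient's most abundant type by
SMOTE interpolation: a synthesized cell is
`x_new = (1 - lambda) * x_i + lambda * x_j` with both parents original
cells of the same patient and type and `lambda ~ U[0, 1]`. Types with
fewer than 10 cells in a patient are discarded first, so interpolation
always has a reasonable pool. Balancing is strictly per patient: a type
absent in a patient stays absent. Every synthesized cell stores its two
parent ids and `lambda`, and `replay_synthesized()` reproduces it
bit-exactly — the augmentation is fully auditable. The interpolation
partner is drawn uniformly over the patient's other same-type cells; we
deliberately do not restrict to nearest neighbours, as the minimal
random-interpolation rule is sufficient for balanced sampling and has no
tuning parameter.

Deconvolution references are built from **original cells only**
(`build_reference()` drops flagged cells), so methods never see
synthesized data; oversampling only serves mixture diversity.

## The synthetic corpus generator

The generator emulates the structural features of annotated
breast-tumour scRNA-seq cohorts that the pipeline actually depends on:
multiple patients carrying molecular subtype labels (ER+, HER2+, TNBC),
a three-level cell-type hierarchy (major / minor / subset), per-patient
abundances from absent through rare to thousands of cells, and
type-specific marker genes. Expression is negative binomial: gene `g` in
a cell of leaf type `t` from patient `p` has mean
`baseline_mean * marker_fold^[g is a marker of t] * e_pg`, with `e_pg` a
log-normal per-(patient, gene) factor (sd `patient_effect_sd`) modelling
donor heterogeneity, and NB dispersion `phi` (variance
`mu + phi mu^2`).

Defaults: `baseline_mean = 0.2` and `dispersion = 0.5` give the sparse,
overdispersed counts typical of droplet data (most entries zero, CV > 1);
`marker_fold = 8` puts marker genes around an 8-fold enrichment, the
magnitude of a strong lineage marker; `patient_effect_sd = 0.15` yields
±30–40% donor-to-donor expression shifts; `markers_per_type = 10`
disjoint markers per leaf type keeps signature matrices well
conditioned. The demo configuration (`demo_config()`) mirrors the
published corpus shape at desk scale: 6 patients (2 per subtype), 9
major types with 2–3 minor children, 2,000 genes, skewed abundances
between 0 and 1,500 with ~15% of (patient, type) pairs absent —
exercising the rare-type filter and absent-type paths.

What the generator does **not** emulate: batch effects, doublets,
ambient RNA, gene–gene correlation beyond type membership, or realistic
transcriptome-wide mean–variance structure. Passing tests on this corpus
show the bookkeeping, balancing, simulation and scoring machinery is
correct and that signal recovery behaves sensibly; they do not certify
any method's accuracy on real tumours.

## Evaluation metrics

All metrics operate on the percent scale (rows sum to 100); because
mixture size is fixed, count-based and percentage-based definitions
coincide.

- **Bray-Curtis dissimilarity** `1 - 2 * sum(min(p, t)) / (sum(p) + sum(t))`
  — overall composition error in [0, 1]; methods are ranked by their
  median.
- **Aitchison distance** — Euclidean distance between centred log-ratio
  (CLR) transforms; the natural compositional metric, used to compare
  lineage granularities, including an immune-only subcomposition variant
  with re-closure.
- **RMSE and Pearson's r per cell type**, computed within configurable
  strata (e.g. donor × purity level) with the median across strata
  reported. The stratification is explicit and configurable because
  "median across all mixtures" admits several readings; zero-variance
  strata yield undefined r and are excluded from medians with a count.
- **Raw error** `pred - truth` is kept signed and only ever summarized
  as a distribution, never summed — signed errors cancel.
- **Relative Proportion Error** `|pred - truth| / truth`, defined only
  where truth > 0: a 5-point miss on a 2% population (RPE 2.5) is far
  worse than on a 30% one (RPE 0.17).
- **FP/FN analysis** at a 0.1% presence threshold: truth < 0.1% makes a
  component an actual negative; predictions are binned into
  [0.1, 1), [1, 10), [10, Inf) percent severity bins;
  rates are `FP/(FP+TN)` and `FN/(FN+TP)`. Bins are half-open and
  lower-inclusive, and the negative test is strictly `< 0.1%`, fixing
  behaviour exactly at the boundaries. The fixed-purity cancer label is
  excluded from FP counting since its presence is forced by design.

### Numerical choices

CLR requires strict positivity but both truths and predictions
legitimately contain zeros; the default policy closes the composition to
the unit simplex, adds `delta = 1e-6` to zero parts and re-closes.
`delta` is configurable; at 1e-6 a single zero in a 9-part composition
shifts the Aitchison distance of typical vectors by far less than the
differences between methods.

The NNLS baseline solves `min ||S w - b||^2, w >= 0` per mixture with
Lawson-Hanson (via `pracma`), on the gene intersection of bulk and
signature in linear CP10K space (no log transform), matching the space
mixtures are summed in. Because signature columns are per-cell means on
a common CP10K scale, weights carry cell-count semantics and
`w / sum(w)` is the proportion estimate. A tiny Tikhonov augmentation
(`1e-6 * ||S||_2` identity rows) keeps the active-set solver stable when
the bulk is an exact non-negative combination of signature columns; the
induced bias is O(1e-12), far below reporting precision. An all-zero
solution falls back to uniform proportions with a warning rather than an
undefined composition.

External methods are reached only through `run_adapter()`: inputs are
materialized in the adapter's declared dialect (linear CP10K or
`log2(x + 1)` for methods that assume log-space input), the tool runs
out of process, and its output is forced through the simplex contract —
negatives and NaNs clipped to zero (logged), missing type columns
zero-filled (warned), rows renormalized to 100.

## Degenerate inputs and edge behaviour

- A donor with fewer than 5 available types: `k` degenerates to all
  available types, flagged on the draw.
- A fixed-purity draw always includes the cancer label and at least one
  other type (the free-range fraction must live somewhere).
- A fraction rounding to 0 cells records the type as absent (truth 0),
  consistent with the 0.1% presence threshold: 1 cell in 500 is 0.2%.
- Cell pools are sampled without replacement; a shortfall (mixture needs
  more cells of a type than the donor's pool holds) is an error naming
  donor, type, need and have — the fix is more SMOTE balancing or a
  smaller mixture.
- `cp10k_normalize` rejects all-zero cells by id; `filter_rare_celltypes`
  may empty a patient, which downstream stages then reject.
- Patient splits are validated so every major type and molecular subtype
  appears on both sides (override available, logged).

## Choices made where the design was open

- **Free-range and residual draws** are continuous `U(0, 1)` variates;
  the normalization semantics force this reading and it is the simplest
  distribution satisfying them.
- **Largest-remainder rounding** with earliest-position ties: sum-exact
  and deterministic; any sum-preserving rule would do, this one is
  auditable by hand.
- **Ground truth from realized counts** rather than continuous
  fractions (see above); both are stored.
- **SMOTE partner selection** uniform among same-type cells (no
  k-NN restriction), as the neighbourhood rule adds a tuning parameter
  without changing what the balancing is for.
- **Mean-expression signature** for the baseline rather than a
  differential-expression-selected one: the baseline's job is to
  exercise the framework with a well-conditioned matrix, not to compete
  with published methods.
- **Stratified medians** for RMSE/Pearson with the stratification
  exposed as `group_by`, since the aggregation convention materially
  changes reported numbers and should be visible in reports.
- **Sub-seeds** for patients and mixtures are derived deterministically
  from the top-level seed and the entity id (kept below 2^31), so
  results are reproducible and independent of iteration order.

## Problem sizes used in the shipped checks

Design arithmetic runs at the published scale (18 × 5,000 training
mixtures, 8 × 19 × 250 purity mixtures, 8 × 250 lineage mixtures,
2,000 × 9 confusion components) in specs-only mode on a 26-patient
synthetic corpus with 30 genes, since those counts are invariant to
corpus content. Expression-level checks (SMOTE contract, NNLS recovery,
end-to-end pipeline) run on corpora of 1–3 patients, 30–120 genes and a
few hundred to a few thousand cells, with 100 assembled 500-cell
mixtures in the pipeline run — sizes chosen so the full suite completes
in about a minute while still exercising every code path.

## Known limitations

- The NNLS baseline is a convenience reference point; published methods
  model cross-subject variance, batch effects and marker selection and
  are reached only through adapters.
- The corpus generator's independence assumptions (genes conditionally
  independent given type and patient) make deconvolution easier than on
  real data; recovery results here are upper bounds on realism.
- No read-level simulation: mixtures are sums of normalized counts, so
  library-size and sampling-depth effects of real bulk RNA-seq are out
  of scope.
- Significance testing between methods is out of scope; reports provide
  distributions and rankings only.

## A worked example

```{r example, eval = FALSE}
cfg <- demo_config(n_genes = 500, seed = 42)
corpus <- generate_corpus(cfg)
corpus <- filter_rare_celltypes(cp10k_normalize(corpus), "major")
aug <- oversample_cohort(corpus, seed = 1, level = "major")$corpus

donors <- c("P5", "P6")
pbs <- simulate_purity_series(aug, donors,
                              purity_grid = seq(0.1, 0.9, by = 0.2),
                              per_donor_per_level = 10, seed = 2,
                              total_cells = 200)
sig <- build_signature(build_reference(aug, level = "major"))
pred <- nnls_deconvolve(pbs, sig)
evaluate_predictions(list(nnls = pred), pbs$truth,
                     exclude_types = "cancer_epithelial",
                     out_dir = "report")
```
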