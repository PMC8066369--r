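---
title: "The slice-ensemble method: model, design choices, and what the phantom tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The slice-ensemble method: model, design choices, and what the phantom tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`sliceforest` classifies co-registered 3D gray-value volumes and
localizes the region driving the classification. The underlying
assumption is that the patient class differs from controls in one or a
few *compact* regions — locally, not globally — so that:

1. a 2D slice through an affected region carries class signal, while a
   slice that misses it does not;
2. affected slices are *consecutive* along any axis that crosses the
   region, whereas classifier errors on unaffected slices are scattered;
3. the region is recoverable as the 3D intersection of the affected
   slice ranges found independently along three orthogonal axes.

Concretely, a volume of shape `(D1, D2, D3)` is decomposed into
`D1 + D2 + D3` slices (axis 0 ↔ direction 1, cross-sectional; axis 1 ↔
direction 2, sagittal; axis 2 ↔ direction 3, coronal). For each
direction `d` and position `m` a random forest is trained on the design
matrix of all training subjects' flattened `(d, m)` slices. Slice labels
are *weak*: every slice of a patient inherits the label 1, including
slices through normal tissue. This is deliberate — the lesion location
is unknown at training time — and it means a substantial fraction of
positive labels at non-lesion positions is noise. Two mechanisms absorb
that noise:

* the **run-length filter**: per direction, only runs of ≥ `k`
  consecutive positive slice decisions survive (`run_filter()`);
* the **orthogonal intersection**: the subject-level diagnosis requires
  surviving runs in *all three* directions simultaneously
  (`diagnose()`), and the lesion mask is their separable outer product
  (`intersect_mask()`).

Both are monotone in `k`: masks shrink and diagnoses can only switch
from positive to negative as `k` grows, which the test suite checks as
an invariant.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 700 | trees per forest; the bank's per-position ensemble size |
| `max_depth` | 100 | maximum tree depth (effectively unlimited at these sample sizes) |
| `min_samples_split` | 2 | smallest node still eligible for splitting (mapped to a minimal terminal-node size of 1 in `ranger`) |
| `features_per_split` | `"sqrt"` | features drawn per split; the standard random-forest rule |
| `k` | 3 | minimum run length of consecutive positive slices (unitless slice count); selected by cross-validated accuracy over `{2, 3, 4, 5}` via `select_k()` |
| `vote` | `"oob"` | slice-vote aggregation (below) |

The forest settings are the method's reference operating point and there
is rarely a reason to change them; `k` is the scientifically meaningful
dial. `k = 1` disables run filtering and is allowed for ablation only.
Class weights and a multiplicative lesion model are exposed but off by
default. Intensities are passed through unnormalized — co-registered
inputs are assumed comparable — and no intensity normalization is
applied anywhere.

## Why the out-of-bag vote rule

The conventional forest prediction (each tree votes its in-bag leaf
majority; argmax wins) behaves badly under weak labels at *no-signal*
positions. There, patient and control slices are identically
distributed while labels are balanced 0/1, so fully grown trees memorize
in-bag noise and the forest's vote fraction fluctuates symmetrically
around 1/2: roughly half of all no-signal positions are flagged, in a
balanced cohort, no matter how many trees are used. Scattered false
positives are what the `k`-filter is for, but at that rate spurious runs
of length ≥ `k` appear in every direction and both stages of the
decision rule drown.

The package therefore aggregates votes conservatively:

* each tree votes the majority label of the **out-of-bag** training
  samples that fall in the test point's leaf;
* a leaf with no out-of-bag samples, or an exactly tied one, votes 0
  (normal);
* the slice is flagged iff a **strict majority** of trees vote 1, with
  the forest-level tie also resolving to 0.

Out-of-bag leaf evidence is unbiased at no-signal positions (it was not
used to grow the tree), and the asymmetric tie policy prices a false
"disorder" slice higher than a false "normal" one — the natural choice
given that the decision rule needs agreement across three directions
anyway. At positions with real signal the out-of-bag samples land in
the correct leaves, so sensitivity is preserved as long as a handful of
out-of-bag subjects reaches each leaf; with very small training folds
(≲ 10 subjects) the rule is noticeably conservative, which is why the
package's own test fixtures use at least 12 training subjects per fold.
`vote = "inbag"` restores the conventional per-tree majority (with the
same forest-level tie-to-0) for comparison.

Relatedly, features that are constant across a training design matrix
are dropped before fitting: they admit no split, and keeping them would
make the per-split feature draw miss the informative voxels entirely in
small slices (the reference splitter in common Python implementations
skips constant candidates for the same reason). A position whose slices
are constant across the whole training set carries no class information
and receives a degenerate always-normal classifier.

## Decision-stage conventions

* The `k`-filter is applied per direction *before* intersection, making
  the diagnosis equivalent to "at least one run of length ≥ `k` in
  every direction".
* All surviving runs are kept; the mask is the union of all run-product
  boxes, so multiple disjoint candidate regions are representable.
* One scalar `k` applies to all three directions.
* Ties in `select_k()` resolve to the smallest `k`; accuracy is pooled
  over folds (micro-averaged). Banks are trained once per fold and the
  `k`-sweep is pure post-processing, since slice votes do not depend on
  `k`.
* All indices are 0-based with half-open intervals, in the file's native
  axis order; slice flattening is row-major over the remaining axes in
  ascending axis order. Any fixed order would do — train and test share
  one code path, which the round-trip tests (`reconstruct_volume()`)
  pin down, including degenerate shapes like `(1, 5, 7)`.
* Reproducibility: each `(direction, position)` model is seeded
  deterministically from `(seed, direction, position)` and trained
  single-threaded, so banks are bit-reproducible regardless of training
  order; folds are dealt round-robin per class after a seeded shuffle
  (stratified, sizes differing by at most 1); phantom generation
  restores the caller's RNG state.

## What the phantom emulates — and what it does not

`generate_cohort()` builds each subject as

    baseline + smooth per-subject jitter + i.i.d. voxel noise
      (+ effect on lesion voxels, patients only)

* **Baseline**: a soft centered ellipsoid (intensity 100 inside, fading
  to 0 over a sigmoidal shell) giving slices brain-like nonstationary
  structure, or `"flat"` for analytic checks.
* **Lesion**: one or two axis-aligned boxes; the effect is an additive
  mean shift (default) — the simplest proxy for a local volume/intensity
  change. A multiplicative variant is available.
* **Defaults**, chosen once as a realistic, fully recoverable testbed: a
  `24 × 28 × 24` grid with 20 controls + 20 patients (small enough that
  the full cross-validated pipeline runs in seconds), a single
  `4 × 5 × 4` box at `[10,14) × [12,17) × [10,14)`, effect 10
  intensity units against voxel noise SD 2 (effect/noise = 5), and
  jitter 0 — volumes are assumed co-registered; the jitter field
  (a low-resolution Gaussian field, trilinearly upsampled and
  standardized to unit SD) is available to emulate residual anatomical
  variability.

The phantom deliberately omits MRI physics: no bias fields, partial
volume, motion, registration error, or morphological (deformation-based)
lesions, and its lesion is a sharp axis-aligned box rather than an
anatomically shaped region. Passing the recovery tests therefore shows
that the *pipeline* — slicing, weakly labeled per-position forests,
run filtering, orthogonal intersection — correctly recovers a planted
localized effect at a given signal-to-noise ratio and is correctly
calibrated on null data. It does not show that real ADHD-scale effect
sizes are detectable, nor that real anatomy satisfies the compactness
assumption; accuracies on real cohorts depend on the dataset and are
out of scope here.

## Problem sizes used by the tests

The acceptance-style tests run the standard phantom (40 subjects,
`24 × 28 × 24`) with 50-tree banks under 5-fold cross-validation —
380 forests per run, a few seconds each on one core — at noise 0 and
noise 2, plus a null phantom (effect 0) and a `k`-sweep on a lesion
exactly 3 slices deep per direction at noise 0.5. Unit tests use
smaller cohorts (`8 × 9 × 8` to `10 × 11 × 10`, 10–16 subjects).
Full-study-scale volumes (`121 × 145 × 121`, hundreds of subjects, 700-tree
banks) are supported by the same code paths — banks are trained one
design matrix at a time, so memory stays bounded — but are not exercised
in the default test run.

## Known limitations

* Lesion masks are unions of axis-aligned boxes by construction; the
  method cannot outline oblique or curved region boundaries, only
  bracket them.
* The subject-level decision is binary with no confidence measure; vote
  fractions are not calibrated probabilities and are not exposed.
* Weak labels mean the per-slice classifiers are trained against
  substantial label noise; with very small cohorts or very low
  effect-to-noise ratios the conservative vote rule fails toward
  non-diagnosis (sensitivity loss, not false alarms).
* Co-registration is assumed, not checked; volumes in different spaces
  will silently produce meaningless slice correspondences (only shape
  consistency is enforced).
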