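---
title: "Pixel-level analysis of template pain drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-level analysis of template pain drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paindraw)
```

## The problem

Pain drawings are pen-and-paper instruments: a patient shades the painful
areas of their body on a printed sheet carrying a gray human body outline
(HBO) and, in our setting, three black fiducial markers. Digitized, each
drawing becomes a binary raster `marks[row, col]` on a common template
domain, and a group of drawings becomes a *pain profile*: for every pixel,
the proportion of drawings in the group that marked it, a value in $[0, 1]$.

The scientific question this package is built around is whether two groups
of patients mark pain *differently* — for example, endometriosis patients
drawing on a female versus a sex-neutral body outline. Everything in the
package serves that comparison: ingestion of scans into rasters, profile
construction, a similarity statistic, a permutation test, and supporting
descriptive and questionnaire statistics.

## The statistic: Ružička similarity

For nonnegative vectors $x, y$ the Ružička similarity index is

$$RZI(x, y) \;=\; \frac{\sum_i \min(x_i, y_i)}{\sum_i \max(x_i, y_i)} \in [0, 1].$$

On binary rasters it reduces to the Jaccard index
$|x \cap y| / |x \cup y|$; on pain profiles it is the natural weighted
generalization. Its key property for sparse body maps is that pixels marked
by neither side contribute nothing — the comparison concentrates on marked
territory instead of rewarding agreement on the vast unmarked background.

Edge case: two all-zero inputs. We define $RZI = 1$ (two empty drawings are
identical) and emit a warning. This keeps the permutation test total on
degenerate cohorts; any convention only matters when entire groups are
empty, which real cohorts never are.

## The permutation test

`rzi_permutation_test()` compares two groups A and B of sizes
$(n_A, n_B)$:

1. the *origin similarity* is $RZI$ between the two group profiles;
2. the pooled drawings are randomly relabelled into groups of the original
   sizes, the profile-level $RZI$ recomputed; this is repeated $B$ times
   (default 1000), each replicate an independent uniform draw of a
   partition (repeats possible — the replicates are i.i.d. samples from the
   permutation null);
3. the p-value locates the origin in the null sample.

Three tail conventions are implemented, because the direction deserves
care. Under a genuine group difference the true-label profiles are
unusually **dissimilar** — the origin RZI falls in the *left* tail of the
null. The default is therefore `tail = "lower"` with the add-one estimate
$p = (1 + \#\{RZI_b \le \text{origin}\})/(B + 1)$, which is the coherent
difference test and guarantees $p > 0$. The convention used by the software
our pipeline emulates — the count of null values strictly *greater* than
the origin divided by the number of permutations — is preserved verbatim as
`tail = "paper_literal"`: it is small when the groups are unusually
*similar*, can be exactly zero, and is kept as a fidelity mode rather than
a default. `tail = "upper"` completes the set for similarity-seeking
questions. We do not guess which reading the original analysis intended;
both are available and reported explicitly.

For pooled cohorts with $\binom{n_A+n_B}{n_A} \le 200{,}000$,
`exhaustive_rzi_test()` enumerates every assignment once (the observed one
included, so the exact p is never zero) and serves as the exact reference;
the test suite checks that Monte-Carlo p-values converge to it within
binomial error.

Implementation note: each replicate needs only the per-pixel mark *counts*
of one pseudo-group, so the test precomputes a pixels × drawings 0/1 matrix
restricted to the union support (pixels marked by at least one drawing —
all other pixels contribute zero to both sums) and obtains counts as a
matrix–vector product. Counts are exact small integers, and the union
pixels are kept in raster order, so the fast path is *bit-identical* to
naive per-replicate profile construction; the suite asserts `identical()`.

## Groups on two templates

The study design this package emulates gives the two groups two different
(female / sexless) outlines printed on same-size sheets. Group-level
machinery therefore requires a shared raster geometry, not a shared
template id: profiles are built per group on one template, while
cross-group similarity and the permutation test operate on the common pixel
grid. The two synthetic outline variants are built with an identical
torso geometry from waist to hip, so the abdomen/hip band — where
endometriosis pain concentrates — offers equal drawable canvas to both
groups (the suite checks the band areas differ by under 1%).

## Ingestion: from scan to raster

A scanned sheet is turned into a drawing in three steps.

* **Fiducial detection.** Dark 8-connected components whose area lies in
  $[0.5, 2] \times$ the expected marker area are candidates; the triple
  whose pairwise-distance pattern best matches the template triad is
  selected and ordered canonically. Centroids are darkness-weighted over
  the component plus a one-pixel ring: the anti-aliased marker edge carries
  the subpixel position, giving localization errors well below a pixel.
  Ties between plausible triples raise an error rather than a guess.
* **Registration.** Three non-collinear correspondences determine the
  scan-to-template affine map exactly; the residual on the fiducials is
  zero by construction and is checked against a 2 px tolerance downstream
  (a violated tolerance indicates detection failure, and extraction
  refuses to proceed).
* **Mark extraction.** Every drawable template pixel is resampled from the
  scan by nearest neighbour at 5 sub-pixel sample points. The default
  decision rule estimates ink *coverage* linearly between the blank-paper
  level (250) and the solid-ink level (25) and marks the pixel at coverage
  ≥ 1/2, which places the recovered boundary at the 50% ink line and is
  unbiased under the sub-pixel blur that printing and scanning introduce;
  a `strict` majority-vote rule against the classic threshold of 80 (black
  pen < 40 captured, gray outline ≈ 160 untouched) is available for
  hard-binarized input. Pixels outside the body outline are dropped (the
  clipping contract), discs of 1.5 × the marker radius around the
  fiducials are never markable, and isolated single marked pixels are
  removed as scanner speckle.

Drawing-rule enforcement (no crosses, arrows, unfilled outlines) is *not*
attempted: those rules are instructions to patients, not properties a
binarizer can verify; ingestion takes any filled pixels.

## The synthetic cohort generator

No clinical drawings ship with the package, so the generator produces the
study conditions end to end and retains ground truth.

* **Templates** (`make_template()`): a deterministic parametric silhouette
  (head, neck, piecewise-linear torso, arm strips, tapering legs), frontal
  and dorsal views side by side on one sheet, approximating A4 at 150 dpi
  (1240 × 1754). Sex variants differ in shoulder/chest width and leg gap
  only; corner fiducial discs sit in a margin wide enough that a few
  degrees of page rotation cannot push them off the captured area.
* **Drawings** (`sample_cohort()`): per subject, a total marked area is
  drawn lognormally on the log10 scale (mean 3.3, sd 0.35, truncated to
  [500, 20000] px). These parameters mirror the log10 pixel-count
  summaries observed in the cohort this package emulates; the floor
  reflects the smallest blotch a 1 mm fiber pen plausibly leaves at
  150 dpi. The area is split over 1–4 blobs (capped so no blob falls below
  ~150 px), each seeded in a named anatomical region drawn from region
  weights — by default concentrated on the abdomen and lower back, the
  characteristic endometriosis pattern — and grown by Eden-style random
  boundary dilation inside the outline. Raw Eden growth is then
  regularized at pen scale (morphological closing/opening, radius 2 px ≈
  0.3 mm — a fiber pen cannot produce single-pixel raggedness), after
  which the sampled area is restored *exactly* by random boundary
  growth or smoothness-preserving peeling; area conservation therefore
  holds to the pixel whenever the region is not exhausted.
* **Group effects**: `none` (calibration), `area_shift` (group B areas
  multiplied), `region_shift` (group B placed by different region
  weights); disjoint region weights drive the origin RZI to ~0 and are the
  power scenario.
* **Scan renders** (`render_scan()`): white page, gray (160) two-pixel
  outline contour, black fiducials (20) and pen marks (25), placed under a
  uniform rotation (±3°), translation (±10 px) and scale jitter (±2%),
  then corrupted with 1% pen dropout, Gaussian intensity noise (sd 8) and
  0.1% salt-and-pepper. The page is sampled at a 2 × 2 sub-pixel grid per
  scan pixel — a scanner sensor integrates over its footprint, and this
  anti-aliasing is what makes subpixel fiducial localization physically
  possible. The exact applied transform is returned as ground truth.

What the generator does *not* emulate: anatomically realistic pain-shape
statistics, correlated multi-region syndromes, pen-pressure variation,
paper texture, or perspective distortion (flatbed assumption). Passing
tests therefore demonstrate the pipeline's correctness and robustness
under a benign-scan model with compact blob-like pain areas — not
performance on adversarial scans or clinical generalization.

## Supporting statistics

* **Pixel counts** (`pixel_count_comparison()`): per-drawing marked-pixel
  counts, log10-transformed, compared with a two-sided two-sample Wilcoxon
  rank-sum test (midranks, normal approximation with continuity
  correction) and a Welch t-test. The source analysis names a "signed-rank"
  test for two independent unequal groups — a design impossibility; the
  reported statistic is consistent with the rank-sum form, which is what we
  implement, with the naming discrepancy documented here. Drawings with
  zero marks are excluded from the log10 analyses (log10(0) undefined)
  with a warning, but remain in raw counts and profiles.
* **Questionnaires** (`questionnaire_summary()`): 2 × K response tables;
  Fisher's exact test on 2 × 2 tables via the conditional-MLE odds ratio
  with exact CI (both row orientations reported — the orientation of a
  published odds ratio is ambiguous unless labelled, so we always label);
  chi-squared (no continuity correction, zero columns dropped, low
  expected-count warning) for wider tables; "no opinion" columns dropped
  before testing, as non-responses carry no information about association;
  optional Welch t comparisons of ages between response groups. The shipped
  example dataset reproduces published questionnaire counts; its fifth
  table is flagged as internally inconsistent with the odds ratio
  originally published for it and is excluded from reproduction checks.

## Numerical choices and degenerate inputs

* All rasters are 1-based R matrices internally, origin top-left; on-disk
  JSON uses 0-based coordinates and a per-row run-length encoding with
  sorted keys and fixed formatting, so serialization is byte-deterministic
  and write→read is the identity (property-tested).
* Empty drawings are legal, flagged, and participate in profiles and pixel
  counts with count 0 — whether blank sheets were excluded in the source
  analysis is unknown, so we keep them and let the caller filter.
* Summary SDs are sample SDs ($n-1$). Heatmaps display
  $\log_{10}(\max(RZI, 10^{-3}))$ — zero similarities exist in real
  cohorts, and the floor keeps them renderable.
* Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and derives stage seeds from one root seed in the pipeline;
  reruns are bit-identical, which the suite checks on serialized outputs.

## Simulation scales used by the test and acceptance suites

Statistical properties that are resolution-free — type-I calibration (200
no-effect cohorts of 10 + 10, B = 200), power against disjoint regions
(100 cohorts), Monte-Carlo vs exhaustive agreement — are simulated on a
reduced template (20% linear scale, ~30 dpi) with areas and pen radius
scaled accordingly; this is a deliberate design choice, as the permutation
test operates on counts and proportions whose distribution does not depend
on raster resolution. Scan-ingestion recovery (50 noisy renders, Dice ≥
0.95) and the full study-scale replica (24 + 26 drawings, B = 1000) run at
the full 150 dpi default.

## Known limitations

* Three-point registration is exact but unredundant: a misdetected
  fiducial cannot be caught by a residual on the fiducials themselves,
  only by the area/distance-pattern filters and the downstream tolerance.
* The coverage extraction rule assumes roughly bimodal ink/paper
  intensities; heavily faded pens or colored scans are out of scope.
* The permutation test assumes exchangeability of drawings under the null;
  systematic template differences between groups are part of the tested
  hypothesis, not removed by design.
* Only two-group designs are supported; multi-group permutation schemes
  and covariate adjustment are out of scope.
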