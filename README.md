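# paindraw

Pixel-level analysis of pen-and-paper **template pain drawings** (body
maps). Patients shade their painful areas on a printed sheet carrying a
gray human body outline and three black fiducial markers; `paindraw`
digitizes such sheets into binary rasters, builds group **pain profiles**
(per-pixel marking proportions), and tests whether two groups — for
example, patients drawing on a *female* versus a *sex-neutral* body
outline — mark pain differently.

## The statistic and the test

The core comparison uses the **Ružička similarity index**, the extension
of the Jaccard index to nonnegative rasters:

    RZI(x, y) = Σᵢ min(xᵢ, yᵢ) / Σᵢ max(xᵢ, yᵢ)  ∈ [0, 1]

On binary drawings it is exactly Jaccard `|x∩y| / |x∪y|`; on profiles it
compares only marked territory, ignoring the vast unmarked background.
Significance is assessed with a **label-permutation test**: the RZI
between the two group profiles ("origin similarity") is located in the
null distribution obtained by reshuffling group labels (preserving group
sizes) and recomputing the statistic, `B = 1000` times by default, or
exhaustively over all label assignments for small cohorts. Under a true
group difference the origin RZI is unusually *small*, so the default
p-value is the lower tail with add-one correction,
`p = (1 + #{RZI_b ≤ origin}) / (B + 1)`; the literal
"greater-than" convention of the original pain-drawing software is kept
as mode `paper_literal`.

Around that core: scan ingestion (subpixel fiducial detection, exact
3-point affine registration, coverage-based mark binarization, clipping
to the outline), pairwise-similarity heatmaps and boxplots, marked-pixel
count comparisons (rank-sum and Welch t on log10 counts), a questionnaire
suite (Fisher's exact test with conditional-MLE odds ratio and exact CI,
chi-squared, Welch t), and a synthetic generator for templates, cohorts
with controllable group effects, and noisy scan renders with ground
truth.

## Worked example

Simulate a study-scale cohort (24 drawings on a sexless outline, 26 on a
female one, half resolution for speed) and test for a group difference:

```r
library(paindraw)

tpl_s <- make_template("sexless", 620, 877)
tpl_f <- make_template("female",  620, 877)
coh   <- sample_cohort(tpl_s, tpl_f,
                       cohort_config(n_a = 24, n_b = 26,
                                     area_scale = 0.25, seed = 42))

res <- rzi_permutation_test(coh$drawings[1:24], coh$drawings[25:50],
                            B = 1000, seed = 42)
summary(res)
#> Monte-Carlo RZI permutation test (n = 24 + 26)
#>   origin RZI = 0.2525; permutations = 1000; tail = lower
#>   p = 0.9181 (alpha = 0.05); seed = 42
#>   null RZI: min 0.1257, Q1 0.1946, median 0.2157, Q3 0.2339, max 0.2990
#>   reject at alpha = 0.05: no
```

Both groups come from the same generator (no effect), and the test agrees:
the origin similarity 0.25 sits in the *upper* part of the null
distribution — the true-label profiles are, if anything, more similar
than random relabellings — so the lower-tail p of 0.92 gives no evidence
of a group difference. `plot(res)` draws the null histogram with the
origin marker, p and alpha.

Marked-pixel counts per drawing, compared on the log10 scale:

```r
pixel_count_comparison(coh$drawings[1:24], coh$drawings[25:50],
                       labels = c("sexless", "female"))
#> Marked-pixel counts (log10 scale):
#>    group  n   min   max  mean median    sd
#>  sexless 24 2.097 3.419 2.741  2.792 0.314
#>   female 26 2.097 3.328 2.685  2.603 0.356
#>   rank-sum: W = 335, p = 0.6621
#>   Welch t: t = 0.600, df = 47.91, p = 0.5516
```

The package also ships the questionnaire contingency tables from a
published endometriosis body-outline survey as a worked dataset:

```r
fisher_exact_2x2(endometriosis_questionnaire()$q1_suitability)
#> Fisher exact, conditional-MLE odds ratio
#>   p = 1; OR = 1.421; 95% CI 0.147-18.613
#>   orientation: odds(sexless)/odds(female), yes vs no
```

The odds ratio is the conditional MLE under the noncentral hypergeometric
likelihood with its exact 95% interval — suitability ratings do not differ
between the two outlines.

`run_pipeline(run_config(...))` chains the whole analysis (simulate /
JSON / scans input modes) into a run directory with profiles, the
permutation result and histogram, similarity matrix with heatmap and
boxplots, pixel-count reports, and a manifest embedding the seed and a
configuration hash; reruns are bit-identical.

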