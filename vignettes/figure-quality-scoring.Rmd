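---
title: "Consensus scoring of figure quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring of figure quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medvis)
```

## The problem and the model

Whether a scientific figure communicates well is usually judged
qualitatively. `medvis` operationalizes that judgment for raster figures of
biomedical papers with four measurable criteria, then classifies each figure
*good* or *not good* by consensus over three low-dimensional embeddings of
the metric space. The method is deliberately **relative**: every score,
threshold and label is computed against the rest of the corpus, so a figure
cannot be judged in isolation. The package enforces a minimum corpus size of
8 everywhere.

### The four metrics

For an \(H \times W\) image with 8-bit channels \(R, G, B\) and caption
text \(c\):

* **White-space fraction** \(\in [0,1]\): the fraction of pixels whose
  three channels all reach the whiteness threshold \(\tau\) (default
  \(\tau = 250\)). Using 250 rather than 255 tolerates the near-white
  ringing JPEG compression introduces around line art; the boolean mask is
  exposed (`white_mask()`, `white_overlay()`) so the decision can be
  audited visually.
* **Color score** \(\in [0,170]\), in intensity units: the per-pixel mean
  of \(|R-G|, |G-B|, |R-B|\), averaged over pixels. Achromatic images score
  exactly 0; a saturated primary scores \((255+0+255)/3 = 170\), the
  maximum. We chose this direct channel-difference reading over a
  distinct-color count, which is fragile under quantization and
  anti-aliasing. Higher is treated as favorable by default (more color
  differentiation); the direction is configurable.
* **Complexity score** (components per megapixel): luminance
  \(0.299R + 0.587G + 0.114B\) is filtered with \(3\times 3\) Sobel
  kernels, the gradient magnitude is binarized at a fraction (default
  0.10) of the maximum attainable magnitude \(4\sqrt{2}\cdot 255\), and
  connected components of the edge mask are counted (8-neighbor
  connectivity by default; 4 available). Each visually distinct element
  contributes roughly one edge ring, so the score tracks how many separate
  things a reader must parse. Normalizing per megapixel makes the score
  invariant to uniform rescaling of equally busy content.
* **Visualization count** \(\geq 1\): the number of *distinct* case-folded
  parenthesized letters "(a)"/"(B)" in the caption, the convention for
  labeling subpanels. Numerals and roman numerals are deliberately not
  matched — "(1)" and "(iv)" are as often citations or equation references
  as panel labels. A caption without identifiers yields a fallback count of
  1 and is flagged `count_source = "fallback"` rather than dropped, since
  malformatted captions are the dominant failure mode in practice and
  dropping the figure would silently skew the corpus statistics.

### Consensus classification

The \(n \times 4\) metric matrix is standardized column-wise (sample
standard deviation; constant columns map to zeros) because the four metrics
live on incommensurate scales. The standardized matrix is embedded into 2-D
three ways — PCA, t-SNE and UMAP — and each embedding is clustered with
k-means, \(k = 2\), 25 restarts, under a seed derived deterministically
from the user's single seed. Per embedding, the cluster whose members have
the higher mean *badness composite*

\[ b = z_{\text{whitespace}} + z_{\text{complexity}} + z_{\text{count}} - z_{\text{color}} \]

casts a "bad" vote (ties label the first-indexed cluster good). The three
binary votes are summed into a consensus level 0–3 and binarized: levels 0
and 1 are **good**, 2 and 3 **not good**. Two clusters per embedding with
additive votes across the three methods is exactly what yields those four
consensus levels; `k` is nonetheless configurable.

Small corpora need clamped hyperparameters: t-SNE perplexity
\(\min(30, \lfloor (n-1)/3 \rfloor)\) and UMAP neighbors
\(\min(15, n-1)\), so the pipeline runs from \(n = 8\) upward. t-SNE uses
the exact (theta = 0) algorithm and UMAP a single thread, making the whole
pipeline bit-reproducible under a fixed seed; PCA is deterministic by
construction, with each component's sign fixed so its largest-magnitude
loading is positive.

### Quartile thresholds and advice

Feedback is per metric, against a corpus quantile computed by linear
interpolation of order statistics (position \(p(n-1)\), zero-based — the
`type = 7` convention; quartile definitions differ enough across software
that we state it explicitly). Defaults: visualization count is compared to
its first quartile and flagged **above** it (the printed convention for
excessive visual content); white space and complexity are flagged above
their third quartiles; color is flagged below its first quartile. A value
exactly at its threshold passes — flags are strict inequalities, matching
the "more than" phrasing of the count rule. All four (quantile, direction)
pairs are configurable because the upstream convention is internally
ambiguous: the count example pairs a lower-is-better metric with Q1, which
the general rule as stated would not produce; we follow the printed example
and leave the rest to configuration rather than guess further.

Each flagged metric contributes one fixed advice string (reduce white
space, improve color differentiation, simplify layout, drop subpanels);
advice is a pure function of the flag pattern. Gauge charts — one dial per
figure and metric, needle at the value, red mark at the threshold, dial
spanning the corpus range — render these comparisons; with identical inputs
they render identical pixels.

### Weight sensitivity

The composite desirability \(d = -w_{cx} z_{cx} + w_{col} z_{col} -
w_{ws} z_{ws} - w_{ct} z_{ct}\) (favorable directions signed; weights
normalized to sum 1) supports a stability analysis: each of the four
weights is varied over multipliers \(\{1-\delta, 1, 1+\delta\}\) (default
\(\delta = 0.10\)) in a **full factorial**, giving \(3^4 = 81\)
configurations with the baseline as a grid point. One-at-a-time variation
would give 9, which is why the factorial is the default; `levels` must be
odd so the baseline stays on the grid. Per configuration we report rank
divergence \(1 - \rho_s\) (Spearman, average ranks for ties — the only
correlation consistent with a *ranking* divergence), mean absolute rank
shift, and classification flips. Flips are counted against a quantile
split of the composite score (default: median, good iff
\(d \geq\) median) rather than a re-run of the embedding ensemble — the
weights do not enter the embeddings, so re-embedding could not respond to
them; the choice is recorded in the manifest.

### Validation utilities

Two checks compare the algorithm to people. Count agreement uses a
chi-squared **goodness-of-fit** of the algorithm's count-category
frequencies against the human count distribution (categories are the union
of observed counts; zero-expectation categories are pooled into the nearest
category). A count-vs-count independence table would be too sparse to test
at realistic corpus sizes, which is why the goodness-of-fit variant was
chosen; since it compares marginal distributions, the per-figure exact-match
rate is always reported alongside. Label agreement takes per-rater
Good/Bad votes, forms the majority consensus with proportion
\(\geq 0.5 \Rightarrow\) Good (ties count Good), and reports the confusion
matrix, accuracy, per-class precision/recall and the per-figure
vote-proportion table.

## The synthetic corpus generator

Real figure corpora with quality annotations are not redistributable, so
the package ships a generator whose figures have *known* metric ground
truth, and every claim the test suite makes is a parameter-recovery claim
against that truth.

A generated figure is a white canvas tiled into `panel_count` panels, each
holding `shape_density` filled shapes (axis-aligned rectangles and
ellipse "discs"), colored either with saturated hues (chromatic) or grays
(achromatic, which scores exactly 0 on color by construction). The caption
is auto-written with "(a)", "(b)", … identifiers, so the parsed count
equals the panel count. Two properties are engineered, not hoped for:

* **Disjointness.** Shapes sit on a per-panel sub-grid (rows × columns
  chosen to waste as few cells as possible while keeping cells nearly
  square) with a 6-pixel gap, so shapes — and their Sobel edge rings —
  never touch. Each added shape therefore adds at least one edge component,
  making the complexity score strictly increasing in `shape_density`.
* **White-fraction control.** All ink is non-white, so the white fraction
  is one minus the ink coverage, which is monotone in a global shape-scale
  parameter. The scale is set by bisection (at most 20 rounds) to land
  within 0.02 of `white_target`; per-shape random rounding phases keep the
  coverage curve smooth in the scale, so the bisection can actually land
  inside the window on small canvases. Unreachable targets raise an error
  rather than silently missing: disjointness bounds the maximum ink
  coverage (roughly 0.5–0.6 at low densities), so very low white targets
  are infeasible by design and the default "good" stratum uses a white
  target of 0.55.

The default study conditions (`default_strata()`) are a 50/50 two-stratum
corpus: *good* — 2 chromatic panels, 3 shapes each, white target 0.55;
*bad* — 6 achromatic panels, 12 shapes each, white target 0.85, with a
±0.02 per-figure jitter on the white target. On all four metrics the strata
are separated far beyond 3 pooled standard deviations, which is the regime
in which the consensus pipeline is expected to recover the strata with zero
misclassifications and the 81-configuration sensitivity grid to produce
zero flips. The tests and the acceptance script run these conditions at
\(n = 20\) figures on 240 × 360 canvases — sizes chosen so a full
end-to-end run takes seconds on a laptop while every pixel-level metric
still has thousands of pixels to average over.

What the generator does **not** emulate: rendered text and axis labels,
anti-aliased strokes, photographic or gradient content, overlapping panel
insets, and legends. Passing the recovery tests therefore shows the
pipeline is correct and stable on figures whose metric structure is known;
it does not show that the four metrics capture everything that makes real
figures good, nor how the classifier behaves when strata overlap. On real
corpora the separation is smaller and labels near the cluster boundary
should be read as uncertain.

## Numerical and interface choices

* Images are H × W × 3 arrays of 0–255 intensities. Grayscale inputs are
  replicated across channels; alpha is composited over white (figures are
  presumed to sit on a white page), so transparent margins count as white
  space. Rasters above 2048 px on a side are block-averaged down before
  scoring (recorded in the manifest); the metrics are area-normalized, so
  this only bounds runtime.
* Missing captions warn and fall back (`count_source = "fallback"`)
  instead of dropping the figure; corpus order is lexicographic by
  `figure_id`, never filesystem enumeration order.
* One user-visible seed drives everything; per-method sub-seeds are derived
  from it deterministically, and re-running with the same seed reproduces
  `scores.csv`, `labels.csv` and `embeddings.csv` byte-identically.
* Degenerate inputs are defined, not accidental: a constant metric column
  standardizes to zeros; an all-identical embedding votes all figures good
  with a warning; an all-equal metric flags nobody (strict inequality at
  the threshold); a single-category count comparison reports statistic 0,
  df 0, p = 1 with a warning.

## A worked run

```{r, fig.width = 7, fig.height = 2.8}
corpus <- generate_corpus(12, seed = 42)
fit <- medvis(corpus$figures, seed = 42)
fit
plot(fit)
```

```{r}
sens <- stability_summary(fit$z, weight_config())
sens
```

```{r}
table(truth = corpus$truth$stratum, label = labels(fit))
```

## Known limitations

The four metrics are proxies: they cannot see mislabeled axes, misleading
scales, or color-blindness hostility, and "complexity" counts edges, not
conceptual difficulty. Counting relies entirely on caption convention; a
single-panel figure captioned with "(a)" in running text will be
over-counted. The classification is relative, so the same figure can be
good in one corpus and not good in another — that is a feature of the
design, but it means labels are not portable across corpora. Finally,
weight optimization against human labels is out of scope here; the
sensitivity machinery quantifies robustness to the weights, not their
correctness.
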