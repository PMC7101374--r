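---
title: "Photoreceptor layer quantification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoreceptor layer quantification: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlquant)
```

## The problem

In diabetic macular edema (DME) and retinal vein occlusion (RVO), fluid
accumulation damages the central photoreceptors. On OCT, the photoreceptor
layer appears as a thin, bright, near-horizontal band in each B-scan —
roughly 2% of a B-scan's pixels in a Spectralis-like protocol of 49 B-scans
x 496 (depth) x 512 (A-scans) over a 6 x 6 mm macular field. Clinically
relevant alterations are focal *disruptions* (the band vanishes over a run
of A-scans; thickness is 0 by definition there) and abnormal *thinning or
thickening*. Manual delineation is slow and has substantial inter-grader
variability, which motivates both an automated segmentation and an explicit
map of where automated readers disagree.

## The model

`prlquant` segments each B-scan with an **ensemble of four U-shaped fully
convolutional networks** — a standard U-Net, an all-dropout variant
(dropout after every convolution block, favouring precision via stronger
regularization), a residual-bottleneck variant (BRU-style), and a cascaded
two-stage U (U2-style) in which a second U refines the concatenation of the
input with the first stage's score map. Member score maps $s_m(i,j) \in
[0,1]$ are fused pixel-wise:

$$\bar{s}(i,j) = \frac{1}{M}\sum_{m=1}^{M} s_m(i,j), \qquad
\sigma(i,j) = \sqrt{\frac{1}{M}\sum_{m=1}^{M}\left(s_m(i,j) -
\bar{s}(i,j)\right)^2}.$$

The mean map is the consensus; the **population** standard deviation is the
disagreement map (population rather than sample so that $\sigma \le 0.5$
for scores in $[0,1]$, a convenient display bound). The consensus map is
binarized with **Otsu's method** on a 256-bin histogram, computed *per
B-scan* (the single-scan processing flow makes the per-scan choice natural;
a per-volume threshold is a trivial variant). Binarization uses
`score >= threshold`, with ties in the between-class variance broken toward
the lowest maximizing threshold, and a constant map is flagged degenerate
with an empty mask rather than an arbitrary split.

### En-face reconstruction

Per B-scan, the topmost/bottommost foreground row of each A-scan column
gives raw upper/lower interfaces. A **cubic smoothing spline** per interface
(degrees of freedom proportional to the number of supported columns,
default `n/6`) produces continuous edges that deliberately bridge
disruptions and holes. Thickness per column is the inclusive pixel extent
`lower - upper + 1` — a one-pixel band has thickness 1, not 0 — except on
*disrupted* columns (no raw foreground), where it is exactly 0. The
disruption decision always comes from the raw mask, never from the spline,
because the spline's job is precisely to interpolate across gaps. Stacking
the 49 per-B-scan profiles gives the en-face thickness map (row = B-scan,
column = A-scan); multiplying by the axial pixel pitch `dz_um` converts to
micrometres. The disagreement map is sampled at the nearest-integer row of
the medial axis `(upper + lower)/2` of each column, so it reflects
*interior* model conflict (pathology, shadows) rather than the ubiquitous
edge ambiguity.

### Evaluation and statistics

Pixel metrics are precision, recall and Dice
($2\,\mathrm{TP}/(2\,\mathrm{TP}+\mathrm{FP}+\mathrm{FN}) \equiv
2PR/(P+R)$), pooled per volume, and precision-recall curves over a fixed
grid of 101 thresholds with trapezoidal AUC over recall, anchored at recall
0 with the precision of the strictest non-empty threshold (PR curves suit
the ~2% class prevalence far better than ROC). Regions follow the ETDRS
grid in the en-face plane — central subfield (1 mm disk), 3 central mm
(3 mm disk) and the 3–1 mm ring — with membership by Euclidean distance of
cell centres from the fovea and applied to whole A-scan columns. The fovea
defaults to the grid centre (fovea-centred acquisition; no detection
algorithm is in scope). Dice over a region with empty truth *and* empty
prediction is NaN and excluded, not 1, so healthy empty regions cannot
inflate averages.

Paired comparisons use a Wilcoxon signed-rank test whose p-value is exact
(full $2^n$ sign enumeration via dynamic programming, midranks for ties,
zeros dropped) for $n \le 15$ and a tie-corrected normal approximation with
continuity correction above. The thickness-bias protocol screens the paired
differences with an Anderson-Darling composite-normality test and the two
samples with a variance-ratio F-test (both at 0.05); if both pass, a paired
two-sided t-test at $\alpha = 0.01$ is used, otherwise the Wilcoxon test.
Applying an F-test to *paired* samples ignores the pairing and is
statistically unusual; it is implemented as stated in the protocol for
fidelity and the output carries an explicit warning field.

## The synthetic phantom

No clinical data ships with the package, so a phantom generator states the
world the pipeline is validated in:

* geometry 49 x 496 x 512 over 6 x 6 mm (defaults; any size works);
* a bright band of baseline thickness 10 px — about 2% of a B-scan's
  pixels, matching the stated prevalence of the real layer, and consistent
  with a 30–40 µm layer at a ~3.9 µm axial pitch;
* smooth thickness (±2.5 px) and curvature (±18 px) modulation from a
  low-frequency cosine mixture with seeded random phases — cheap, smooth
  and analytically bounded, unlike a Gaussian-process draw;
* focal disruptions as en-face ellipses where the mask is carved to zero
  thickness (an unambiguous ground truth for the thickness-0 rule);
* columnar shadows (intensity attenuation only — the mask is never
  modified), dark cyst ellipsoids above the band, a darker outer-nuclear
  band and a persistent RPE-like band beneath;
* clipped multiplicative log-normal speckle (σ = 0.15 by default); no
  published noise model exists for this protocol, so the choice is
  qualitative.

Ground truth is exact by construction: the mask is the rasterized band
support after disruption carving, and the true thickness is defined as the
per-column foreground run length (tested against a brute-force oracle).
What the phantom does **not** emulate: real RVO/DME texture, A-scan point
spread, eye motion, vendor-specific noise. A green test on phantoms
establishes that the machinery (training, fusion, Otsu, spline
reconstruction, region accounting) recovers a known world — not clinical
performance.

## Numerical choices and degenerate inputs

* **Networks.** No deep-learning framework is available in the target
  environment, so the four architectures run on a small in-package
  reverse-mode engine (im2col GEMM convolutions, 2x2 max-pool, nearest
  upsampling) verified against numerical differentiation to ~1e-8. Loss is
  soft-Dice + binary cross-entropy on the logits; optimizer is Adam.
  Default scale (depth 3, base 8 channels, 64-px foreground-biased crops)
  trains each model in about a minute per handful of epochs on one CPU;
  full scale is a configuration change, not a code change.
* **Determinism.** Every stochastic stage takes a seed; the pipeline
  expands one global seed into fixed per-stage seeds so stages can be rerun
  independently. Training, prediction, phantom and split are
  bit-reproducible on a fixed machine.
* **Splines.** `stats::smooth.spline` with df = max(4, n/6); fewer than 5
  support columns fall back to linear interpolation with constant
  extrapolation, one column to a constant. The fitted lower edge is clamped
  to stay at or below the upper edge.
* **Otsu.** Histogram (256 bins) rather than exact-value search; the
  returned threshold is the lower edge of the first foreground bin, so it
  is strictly interior for separated modes.
* **Degenerate inputs** are flagged, not fatal: constant score maps (empty
  mask + flag), fully empty segmentations (all-disrupted interface set,
  zero thickness row, zero std row + coverage flag), all-zero paired
  differences (p = 1), constant maps under display normalization (zeros +
  flag).
* **Thickness convention.** "Distance between the two edges" is read as
  the inclusive pixel extent (+1); the exclusive reading would assign a
  1-px band thickness 0, indistinguishable from a disruption.

## Known limitations

* The four architectures are re-creations from their cited lineages, not
  replicas of the original layer-by-layer definitions; the ensemble
  mechanism, not the exact layer counts, is what the package implements.
* Columns whose foreground splits into several blobs take the topmost and
  bottommost extents (erring thick; visible in the disagreement map).
* The axial pixel pitch is configuration (`dz_um`, default 1 = pixels); no
  device calibration is bundled.
* The B-scan sampling protocol's 3–6 mm band is empty for a centred fovea
  on a 6 mm scan (maximum reachable distance 2.94 mm); the sampler raises
  a named error, and the full three-band protocol requires an off-centre
  fovea or a longer slow axis.
* Statistical helpers implement the stated protocol including its paired
  F-test quirk; they are not a general-purpose testing library.
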