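---
title: "Detection and outline error decomposition of segmentation agreement"
author: "doee package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and outline error decomposition of segmentation agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doee)
```

## The problem

When two raters (or a rater and an algorithm) outline lesions on medical
image slices, the standard agreement score is the Similarity Index
(SI, the Dice coefficient),

$$\mathrm{SI} = \frac{2\,|R_1 \cap R_2|}{|R_1| + |R_2|},$$

where $|R_i|$ is the total area of rater $i$'s regions of interest
(ROIs). SI mixes two very different kinds of disagreement: whether a
lesion was *detected* at all, and where the boundary of a jointly
detected lesion was *outlined*. Worse, SI is strongly confounded by
lesion burden: scans with large, unambiguous lesions yield high SI
almost regardless of rater skill, so SI comparisons across test sets
with different burdens say more about the patients than about the
raters.

This package decomposes the disagreement. Per slice, the union of the
two raters' binary masks is split into connected regions, and each
region is classified:

* **CR1** — formed only by rater 1's ROIs,
* **CR2** — only by rater 2's,
* **CR12** — by both raters.

Writing $|cr|$ for a region's union area and $R_i(cr)$ for rater $i$'s
pixels inside it,

$$\mathrm{DE} = \sum_{cr \in \mathrm{CR1} \cup \mathrm{CR2}} |cr|, \qquad
  \mathrm{OE} = \sum_{cr \in \mathrm{CR12}} \bigl(|cr| - |R_1(cr) \cap R_2(cr)|\bigr).$$

A region contributes to exactly one of the two sums — its class routes
it. With the mean total area $\mathrm{MTA} = \tfrac12(|R_1|+|R_2|)$ and
the outline error rate $\mathrm{OER} = \mathrm{OE}/\mathrm{MTA}$, the
Dice index decomposes *exactly*:

$$\mathrm{SI} = 1 - \tfrac12\,\mathrm{OER} - \tfrac12\,\frac{\mathrm{DE}}{\mathrm{MTA}}.$$

The identity is algebraic (both sides equal
$|R_1 \cap R_2|/\mathrm{MTA}$), and `scanAgreement()` verifies it to
1e-12 relative tolerance on every call. Treating the pair's mean DE and
mean OER as burden-independent constants turns the identity into a
two-parameter prediction of SI at any burden,

$$\widehat{\mathrm{SI}}(\mathrm{MTA}) = 1 - \tfrac12\,\overline{\mathrm{OER}}
  - \tfrac12\,\frac{\overline{\mathrm{DE}}}{\mathrm{MTA}},$$

which explains why SI climbs with lesion burden: the detection term
$\overline{\mathrm{DE}}/\mathrm{MTA}$ vanishes as burden grows, and SI
approaches $1 - \overline{\mathrm{OER}}/2$. The prediction can be
negative below $\mathrm{MTA} = \overline{\mathrm{DE}}/(2 -
\overline{\mathrm{OER}})$; the numeric API returns the negative value
unchanged (the model is honest about its domain) and only plotting
clamps to $[0, 1]$.

SI relates to the Jaccard index by $\mathrm{SI} = 2\,\mathrm{JI}/(1 +
\mathrm{JI})$ and is the limit of Cohen's kappa as the count of pixels
marked by neither rater grows; `kappaOnFrame()` exposes the finite-frame
kappa so the convergence can be checked rather than assumed.

## Analysis conventions

**Two-dimensional analysis.** Regions are formed per slice and never
merged across slices, reflecting how an operator views and marks
images. Only in-plane pixel dimensions enter any area.

**Connectivity.** Within a slice, connected components use
8-connectivity by default (4-connectivity is available via the
`connectivity` argument). A thin diagonal stroke of a hand-drawn
outline should not split one lesion into several regions; 8-connectivity
guarantees that. Labeling is done over an explicit pixel-adjacency graph
(`igraph` components) and is tested against a brute-force flood fill
and, for the 4-connected case, against `EBImage::bwlabel`.

**Adjacent, non-overlapping ROIs.** A union component touched by both
raters with empty pixel overlap is still CR12 — it was formed by both
raters — and its whole area enters OE. This follows the region
definitions literally and keeps the SI decomposition exact.

**Rasterization.** Polygon contours (0-based pixel coordinates,
x = column, y = row, vertex-on-pixel-center) are rasterized at
`factor = 5` times the native resolution in x and y before any region
logic, so a closed path with a sub-pixel neck cannot fragment, and all
downstream areas divide pixel counts by `factor^2`. A fine pixel is set
when its center lies inside a polygon under the even-odd crossing rule
with the *half-open* boundary convention of scanline rasterizers: a
sample exactly on an edge counts as inside only where the interior lies
to its $+x$ side (with a 1e-9-pixel tie-break against floating-point
jitter). We chose half-open over "boundary always inside" deliberately:
with vertices on pixel centers, an all-inclusive rule inflates a
10 mm × 10 mm square to 104.04 mm² and a right triangle of 50 mm² to
53.04 mm² (6% bias), while the half-open rule gives 100.0 mm² exactly
and 51.0 mm² (2%), and converges to the shoelace area as the factor
grows. Self-intersecting polygons are accepted, resolved by the
even-odd rule, with a warning.

**Degenerate inputs.** A scan where both raters' masks are empty has no
defined MTA and raises a named error rather than returning NaNs. Empty
region tables give DE = OE = 0. Non-binary masks are rejected at
construction.

**Reporting precision.** TSV exports round areas to 0.1 mm² and
dimensionless indices to 3 decimals; all in-memory values keep full
precision.

## Model comparison

`fitStudy()` compares four models of SI as a function of MTA across the
scans of a study:

| model     | form                                   | k |
|-----------|----------------------------------------|---|
| mean      | constant                               | 1 |
| linear    | $a + b\,\mathrm{MTA}$                  | 2 |
| quadratic | $a + b\,\mathrm{MTA} + c\,\mathrm{MTA}^2$ | 3 |
| doee      | $1 - \tfrac12\overline{\mathrm{OER}} - \tfrac12\overline{\mathrm{DE}}/\mathrm{MTA}$ | 2 |

Parameter counts are the minimal free quantities per model; a shared
error-variance parameter would add one to every row and cancel in
comparisons. Models are ranked by the Gaussian-residual AICc,

$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

comparable only within one scan set, with relative likelihoods
$\exp((\mathrm{AICc}_{\min} - \mathrm{AICc}_i)/2)$. A perfect fit
(RSS = 0) yields a $-\infty$ sentinel with a warning rather than a
fabricated finite value.

Two fitting routes exist for the decomposition model, and they are not
the same thing:

* With full per-scan records (DE and OER available),
  $\overline{\mathrm{DE}}$ and $\overline{\mathrm{OER}}$ are plain
  arithmetic means — *not* least-squares optimized. This keeps the
  parameters interpretable as the pair's average error profile and makes
  the reported RSS conservative relative to an optimized two-parameter
  fit.
* On a bare (MTA, SI) table there are no per-scan errors to average, so
  the model is fit by least squares in the $1/\mathrm{MTA}$ basis,
  where it is linear with the same two degrees of freedom. With
  noise-free data generated from the model this recovers the generating
  constants exactly.

`StudyFit` records which route was used (`doeeFitMethod`).

The correlation battery uses Spearman rank correlation for MTA against
DE, OE, OER and SI — the SI–MTA relation is explicitly non-linear, so a
linear coefficient would be misspecified — and Pearson correlation for
observed SI against predicted SI and for the residual against MTA.
Spearman p-values use the exact permutation distribution below n = 10
and the t approximation from there on; ties get average ranks; a
constant column yields NA with a warning rather than a spurious
coefficient.

## Diagnostic graphs

The **Cumulative Detection Error** curve answers: how many regions did
exactly one rater mark, among regions with area strictly greater than a
threshold? "Greater than" is strict, so the curve is right-continuous
and non-increasing, and the per-rater curves sum to the total at every
threshold — asymmetry between them shows one rater marking small
lesions more liberally. The size of a single-rater region is its union
area (the only area such a region has). With
`normalized = TRUE`, counts become per-scan averages.

The **Outline Error Distribution** is the histogram over CR12 regions
of $(|R_2| - |R_1|)/|R_1 \cup R_2|$, always in $[-1, 1]$; negative
values mean rater 1 drew the larger outline, and an ideal pair gives a
thin peak at 0. The default bin width 0.1 (not prescribed by the
method; configurable) spans $[-1, 1]$ with half-open bins $[lo, hi)$
and the last bin closed. Because 0 and every multiple of the bin width
is a bin *edge*, an exact count-level mirror under rater swap is not
attainable for statistics that land exactly on an edge (a region with
identical outlines has statistic 0, which must live in one of the two
adjacent bins); the statistic-level mirror
$s(\text{swap}) = -s(\text{original})$ is exact and is what the tests
assert in general, with count-level mirroring checked on fixtures free
of edge values.

## The synthetic generator

`generateStudy()` produces paired rater masks with known ground truth
so every metric, fit and graph can be validated without patient data.
Its defaults are the package's reference study conditions: 17 scans of
20 slices at 128 × 128 pixels of 0.94 × 0.94 mm, per-scan target MTA
log-uniform over 848–17996 mm².

Each scan combines two lesion populations, reflecting the structure
that motivates the decomposition:

* a **burden pool** of larger lesions — lognormal areas
  (meanlog log 250, sdlog 0.7 mm²) drawn until their total covers
  whatever part of the scan's target MTA the small pool is not
  expected to realize, then rescaled to hit it exactly;
* an **ambiguous pool** of small lesions — count Poisson(120) per scan
  *independent of burden*, areas lognormal (meanlog log 12, sdlog
  0.5 mm²) — carrying the detection-miss risk.

Lesions are random rotated ellipses (aspect ratio uniform on
[0.4, 1]) placed largest-first on random slices with *disjoint*
footprints — distinct lesions are distinct structures, and letting a
small lesion land inside a large one would silently convert detection
disagreement into outline disagreement on high-burden scans; a lesion
that cannot be placed after 100 attempts raises an error. Each rater
independently omits each lesion with probability
$\mathrm{plogis}(a - b \ln A)$, defaults $a = 10.43$, $b = 3.5$: an
85% miss chance at 12 mm², falling below 4% by 30 mm² and to
essentially zero for burden-pool sizes. These defaults put the
study's expected detection error around 500 mm² and ~30 single-rater
regions per scan — the magnitudes at which detection error is a
substantial share of a low-burden scan and SI visibly climbs with
burden. Keeping the ambiguous pool's rate fixed while only the burden
pool scales is what makes the realized DE statistically independent of
MTA while OE grows proportionally — the structure the decomposition is
designed around. A single lognormal population cannot do both: scaling
its count with burden makes DE grow with MTA, scaling its sizes
removes small lesions from high-burden scans entirely.

Outline disagreement is a per-lesion, per-rater radial perturbation:
the drawn ellipse's semi-axes are the truth's times $e^\varepsilon$,
$\varepsilon \sim N(-\sigma^2, \sigma^2)$, so the expected drawn area
equals the truth area. For concentric scaling the expected per-lesion
union-minus-intersection over mean area is $\approx (4/\sqrt{\pi})\,
\sigma$ to first order, but pixel quantization on small lesions
perturbs that, so the mapping from the requested mean OER
(`jitterStrength`, default 0.4) to $\sigma$ is fixed by the included
calibration routine `calibrateJitter()` iterated at the default
configuration ($\sigma = \mathrm{jitterStrength}/2.07$);
independent-seed checks realize mean OER 0.394 and 0.387 at target
0.4.

What the generator does **not** emulate: image intensities or scanner
noise (masks only), irregular or confluent lesion morphology (ellipses
suffice to exercise every code path, but real lesion boundaries are
rougher, so absolute OER values for human raters need not transfer),
spatially correlated misses, or any rater asymmetry (both raters share
one miss model and one jitter scale; biases are exactly what the
diagnostic graphs are for detecting in real data). Passing tests on
this generator therefore validate the *computations* and the *stated
statistical structure*, not rater behavior on clinical images.

A note on sampling noise: with 17 scans, a Spearman correlation from an
exactly independent DE has null standard deviation ≈ 0.25, so about one
replicate study in ten shows $|\rho(\mathrm{MTA}, \mathrm{DE})| > 0.4$
by chance. Structural checks are therefore framed as nonsignificance
rates (p > .05 in at least 90% of replicates) rather than hard bounds
on a single draw.

`generateSiMtaTable()` is the lightweight forward model used for model
selection studies: MTA log-uniform, SI from the decomposition plus
Gaussian noise (sd 0.05 in the reference conditions), clamped to
[0, 1].

## Problem sizes used by the test suite

The suite validates the algebraic identities on 1,000 random mask pairs
(20–24 pixels square), the labeler against brute-force flood fill on
masks up to 32 × 32, kappa convergence on fixed fixtures out to
3000 × the union area, the generator's structure on 20 full 17-scan
replicate studies at the default conditions, and AICc model selection
on 200 forward-simulated 17-scan tables. These sizes were chosen as the
smallest that give the property checks stable statistics.

## Known limitations

* The analysis is strictly two-dimensional; a lesion spanning slices is
  counted per slice, and no volumetric connectivity is offered.
* The decomposition measures *difference*, not *error against truth*:
  DE and OE are symmetric in the raters and make no false-positive /
  false-negative distinction. Comparing a rater to a gold standard works
  (the gold standard is just "rater 2"), but probabilistic truth
  estimation is out of scope.
* The proprietary JIM ROI file format is not parsed; contours come in
  through the documented JSON dialect (whose coordinate convention is
  vertex-on-pixel-center, chosen and documented here because the
  source format leaves it unspecified), NIfTI or PNG masks.
* meanDE is an extensive quantity (mm²): it transfers between studies
  only under comparable slice coverage and acquisition.
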