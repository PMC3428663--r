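# doee — detection and outline error decomposition of segmentation agreement

`doee` measures how well two raters (or a rater and an algorithm, or a
rater and a gold standard) agree when outlining lesions on medical image
slices — and, unlike the Similarity Index alone, it says *why* they
disagree.

The Similarity Index (SI, the Dice coefficient)

SI = 2 |R1 ∩ R2| / (|R1| + |R2|)

is the standard agreement score for lesion segmentations, but it
conflates two different failure modes and is strongly confounded by
lesion burden: scans full of large, obvious lesions produce high SI for
any competent rater, so SI comparisons across test sets mostly reflect
the patients, not the raters. `doee` splits the union of the two
raters' masks, slice by slice, into connected regions classified as
CR1 (rater 1 only), CR2 (rater 2 only) or CR12 (both), and computes

* **DE** (Detection Error) — total area of CR1/CR2 regions:
  disagreement about whether a lesion exists;
* **OE** (Outline Error) — union-minus-intersection area summed over
  CR12 regions: disagreement about a detected lesion's boundary;
* **MTA** (mean total area) = (|R1| + |R2|)/2, the lesion-burden proxy,
  and **OER** = OE/MTA.

These decompose the Dice index exactly:

SI = 1 − OER/2 − (DE/MTA)/2,

so a pair's mean DE and mean OER — which, unlike SI, are approximately
burden-independent — predict SI at any burden and explain its
dependence on lesion load. The package fits this prediction against
mean/linear/quadratic alternatives with finite-sample-corrected AICc,
computes the Spearman/Pearson correlation battery, relates SI to the
Jaccard index and Cohen's kappa, and draws two diagnostics: the
Cumulative Detection Error curve (how many single-rater regions exceed
an area threshold) and the Outline Error Distribution (signed relative
outline differences of jointly detected regions).

Inputs are NIfTI or PNG mask volumes, or per-slice closed-polygon
contours in a documented JSON dialect (rasterized at 5× resolution so a
narrow-necked outline cannot fragment). A calibrated synthetic
generator produces paired rater masks with known ground truth, so the
whole pipeline is testable without patient data.

## Worked example

Generate a synthetic 17-scan two-rater study at the default conditions
(burden spanning 848–17996 mm², target mean OER 0.4), score every scan,
and compare the four SI-versus-burden models:

```r
library(doee)

study <- generateStudy(syntheticConfig(seed = 42))
agreements <- lapply(study$pairs,
                     function(p) scanAgreement(partitionRegions(p)))
agreements[[1]]
#> ScanAgreement 'synth01'
#>   MTA = 13969.3 mm^2, DE = 660.9 mm^2, OE = 6873.5 mm^2
#>   OER = 0.492, SI = 0.730, JI = 0.575
#>   regions: 24 CR1, 17 CR2, 55 CR12

fit <- fitStudy(agreements)
fit
#> StudyFit: 17 scans
#>   meanDE = 533.6 mm^2, meanOER = 0.423 (means)
#>   mean      k=1  RSS=0.1076  AICc=-83.80  relLik=0.211
#>   linear    k=2  RSS=0.0852  AICc=-85.17  relLik=0.42
#>   quadratic k=3  RSS=0.07801  AICc=-83.68  relLik=0.199
#>   doee      k=2  RSS=0.07693  AICc=-86.91  relLik=1
#>   correlations:
#>     MTA vs DE          rho = 0.056 (p = 0.83)
#>     MTA vs OE          rho = 0.956 (p = 2.21e-09)
#>     MTA vs OER         rho = 0.627 (p = 0.00701)
#>     MTA vs SI          rho = 0.564 (p = 0.0184)
#>     SI vs SI_estimate  r = 0.677 (p = 0.00281)
#>     residual vs MTA    r = -0.461 (p = 0.0628)
```

Reading the output: this rater pair's disagreement is dominated by
outlining (OE ≈ 10× DE on the high-burden scan), detection error is
statistically unrelated to burden (rho = .056, p = .83) while outline
error tracks it almost perfectly (rho = .956), and the two-parameter
decomposition model — despite *not* being least-squares fitted — beats
the mean, linear and quadratic fits of SI on both RSS and AICc
(relative likelihoods ≤ 0.42). The first scan's SI of 0.73 is what the
pair's (meanDE, meanOER) profile predicts at that burden; on a
low-burden scan the same pair would score far lower without being any
worse at the task.

The diagnostics:

```r
regions <- do.call(rbind, lapply(study$pairs, partitionRegions))
renderGraphs(cumulativeDetectionCurve(regions, normalized = TRUE,
                                      nScans = 17L), "cde.png")
renderGraphs(outlineErrorDistribution(regions), "oed.png")
```

A shell front end wrapping the same functions ships at
`inst/cli/doee` (subcommands `score`, `synth`, `graphs`; exit codes
0 = success, 1 = partial failure, 2 = usage error).

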