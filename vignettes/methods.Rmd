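---
title: "Methods: image synthesis, statistical image properties, and rating models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image synthesis, statistical image properties, and rating models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipstats)
```

This vignette documents the models, conventions and numerical choices
behind `sipstats`, in the order of the analysis chain.

## Random-phase synthesis

A random-phase image is defined entirely in the Fourier domain: the
amplitude spectrum is set deterministically to $|A(f)| = f^{\alpha/2}$
over radial frequency $f$ (cycles/image), so that power falls as
$f^\alpha$; phases are i.i.d. uniform on $[0, 2\pi)$ under Hermitian
symmetry so the inverse transform is real. The DC component is zeroed
(the $f = 0$ power law is undefined) and the result is rescaled linearly
to $[0, 1]$, which leaves the measured slope untouched because the power
spectrum away from DC is invariant under affine intensity maps.

The phase field is drawn as a full $N \times N$ uniform matrix from one
seed and then symmetrized: each cell keeps its phase if its (0-based,
column-major) linear index precedes its conjugate partner's, takes the
negated partner phase otherwise, and the self-conjugate cells (DC and the
Nyquist combinations) are forced to zero phase. This convention makes the
output reproducible bit-for-bit from `(size, slope, seed)` and lets a
naive double-loop construction serve as a pixel-identical oracle in the
tests.

Colored stimuli place three independent grayscale syntheses of the same
slope in the R, G and B channels; channel sub-seeds are the master seed
plus fixed offsets ($1000003 \cdot (c-1)$). Channels are uncorrelated in
expectation. For steep slopes ($\alpha \le -3$) the image variance is
carried by a handful of low-frequency modes, so the *realized*
channel correlation of a single image scatters widely — the test suite
therefore checks a tight bound only for white noise and a zero mean of
signed correlations across seeds at $\alpha = -2$.

**Slope measurement.** RGB is converted to Rec. 709 luminance, the 2-D
power spectrum is averaged within 30 log-spaced radial bins, and a least
squares line is fit to log mean power versus mean log frequency. The
default fit range is $(10, N/4)$ cycles/image: the lower cut avoids DC
leakage, the upper cut avoids the anisotropic spectrum corners. Neither
the binning nor the range is prescribed by convention elsewhere, so both
are configurable.

## Statistical image properties

All SIPs are computed after bilinear resampling to a fixed internal
resolution (default $800 \times 800$; the tests use 64–128 px), which
makes them invariant to prior resizing and lossless re-encoding.

* **Complexity** — mean gradient magnitude: central differences with
  replicate borders on the three CIELab channels mapped to a 0–255
  convention ($L \cdot 2.55$, $a, b + 128$), pixelwise maximum across
  channels. Zero exactly for constant images.
* **PHOG self-similarity** — magnitude-weighted orientation histograms
  (16 bins, unsigned mod 180°) over a spatial pyramid; the median, over
  the 64 level-3 cells, of the histogram-intersection similarity between
  the L1-normalized cell histogram and the global histogram. A grid-aligned
  seamless tiling scores exactly 1. Cells without gradient energy have no
  defined orientation structure; they contribute similarity 0 and are
  excluded from the anisotropy average.
* **PHOG anisotropy** — standard deviation of the mean level-3 histogram,
  scaled by $\sqrt{\text{bins}}$ so a one-orientation image scores 1 and a
  flat orientation profile 0.
* **Mirror symmetry (lr/ud)** — mean per-cell histogram intersection on a
  4 × 4 grid between one half and the flipped other half; recomputing the
  gradient field on the flipped half reflects orientations automatically.
  The combined value averages the left/right and up/down components.
* **Edge-orientation entropies** — derivative-of-Gaussian filters
  ($\sigma = 1.5$ px) at 24 orientations on luminance; the 10000 strongest
  edge pixels after greedy non-maximum suppression (Chebyshev radius 3,
  ties broken toward lower pixel index) with a filter-radius margin
  excluded, because circular convolution wraps there. First-order entropy
  is the normalized Shannon entropy of the strength-weighted orientation
  histogram. Second-order entropy bins edge pairs into 20 log-spaced
  distance bins and averages the normalized entropies of the
  strength-product-weighted histograms of absolute circular orientation
  differences. Beyond $10^6$ pairs a seeded uniform subsample (with
  replacement) is used; the tests confirm full-enumeration agreement
  within 0.01 at realistic edge densities.
* **Filter variances $P_a(k)$, $P_f(k)$** — rectified responses of a
  deterministic 50-filter bank (Gabor even/odd pairs at 8 orientations ×
  3 scales on luminance, two center-surround color-opponent filters),
  max-pooled onto a $k \times k$ grid, $k \in \{2, 4, 8, 16, 30\}$.
  $P_a$ is the variance over all pooled entries, $P_f$ the median over
  filters of per-filter variances. Every kernel is zero-mean and
  L2-normalized, so constant images respond exactly zero. The bank is a
  built-in stand-in for trained first-layer convolution weights — the
  variance measures only require a fixed bank spanning orientation, scale
  and opponency — and external weights can be loaded from a documented
  CSV dump (`import_filter_bank()`).
* **Color statistics** — CIELab (D65, standard scales) and HSV channel
  means and 256-bin histogram entropies in bits. The hue mean is circular
  (reported in degrees); the hue histogram partition tiles the circle.

Degenerate inputs are handled explicitly: gradient- and spectrum-based
SIPs of a constant image are undefined and returned as `NA` by
`compute_sip_vector()`, while the standalone operations raise classed
errors.

## Feature selection

Best-subset search ranks predictor subsets within each size by adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-s-1)$, retaining the 10 best per size.
Subset RSS comes from a Cholesky solve on the centered cross-product
matrix; rank-deficient candidates are skipped with a warning. When the
number of candidate models of a size exceeds $2 \times 10^6$, a
depth-first branch-and-bound takes over, pruning any partial subset whose
full completion already has a larger RSS than the current tenth-best
model — RSS never increases when predictors are added, so the bound is
admissible and the retained lists are identical to exhaustive
enumeration (verified against an `lm()`-per-subset oracle on randomized
instances).

"Robustness" of a variable — in the original workflow a visual read of
the selection plots — is operationalized as the total appearance count
across all retained models of all sizes and response dimensions, with
ties broken by the best single-model adjusted $R^2$, then alphabetically.
Collinearity pruning repeatedly inspects the pair with the largest
$|\rho| > 0.6$ (Spearman) and drops the member with the lower robustness
count (tie: weaker response correlation, then the alphabetically later
name), guaranteeing the survivors are mutually below threshold. The
PCA reference model (leading components of the standardized full SIP set,
default 8) provides the information ceiling that a reduced SIP model is
compared against.

## Rating models

Regressions are fit on per-image mean ratings (participants see disjoint
random-phase subsets, so per-image means over available raters are the
natural unit; no imputation). Response and predictors are z-scored, so
coefficients are standardized ($\beta^*$) and banded: weak $< 0.2 \le$
moderate $< 0.5 \le$ strong, boundaries inclusive on the upper band. Each
p-value is the partial t-test in the full model. A condition number above
$10^4$ triggers a collinearity warning with variance-inflation factors.

Group comparisons use the tie-corrected Kruskal–Wallis test with Dunn's
post-test; the multiplicity adjustment is Holm by default (Bonferroni
available) since the original analysis tool does not name its method and
Holm dominates Bonferroni. Stars follow the four-level convention
(0.05 / 0.01 / 0.001 / 0.0001). Slope-preference curves fit a quadratic
to per-image mean ratings per dimension; an inverted-U preference
appears as a negative quadratic coefficient with vertex at intermediate
slopes.

## Distance to a reference corpus

The reference distribution uses the coordinatewise median as center —
distances are taken to the reference median — while the covariance is
the ordinary sample covariance about the mean. Genuinely redundant
variable pairs ($|\rho| \approx 1$) raise a singularity error naming the
offenders; merely ill-conditioned covariances are ridge-regularized by
$10^{-8}$ of the mean diagonal. SIPs are not standardized before the
distance: the quadratic form is invariant under coordinatewise affine
maps (the median commutes with monotone per-coordinate transforms, the
covariance absorbs the scale), so raw scales are used. Full rotational
affine invariance holds for the quadratic form itself but not for the
median center, which is why the tests exercise coordinatewise maps.
Automatic subspace selection keeps the SIPs whose reference-vs-test
Kruskal–Wallis comparison is significant, capped at the number the
reference sample can support.

## Participant clustering

Feature vectors are either the three within-participant Spearman
correlations between rating dimensions or the z-scored per-slope mean
rating profile (z-scoring prevents scale dominance; whether the original
analysis scaled features is not stated, so this is flagged as a package
convention). K-means uses Lloyd iterations from k-means++ starts (25
restarts, best WSS kept). Three cluster-count diagnostics are always
reported — elbow (largest second difference of WSS), mean silhouette
width, and the gap statistic against 50 seeded uniform bounding-box
references — but the chooser prioritizes the elbow, demoted to the
largest k whose best solution leaves every cluster with more than three
members.

## The synthetic study generator

The generator emulates the study design: 40 raters; six slope conditions
(−5 … 0) with 25 colored random-phase images each; a balanced assignment
in which every rater sees 5 images per slope (30 of 150) and every image
is rated by exactly 8 raters; a 150-image textured "pseudo-painting" set
rated by everyone; three rating dimensions. Pseudo-paintings are collages
of soft-edged elliptical color patches on a tinted canvas with fine grain
and a smoothing pass tied to the patch scale, so the generator parameters
sweep the eight model SIPs over a wide range (patch scale drives the
spectral slope monotonically, hue spread the hue entropy, and so on).
They stand in for externally produced artistic stimuli only in the sense
of spanning SIP space; no artistic validity is claimed.

Ratings follow the simplest structure consistent with the downstream
linear analysis: base 0.5, plus $0.12 \times$ a linear predictor on
z-scored SIPs (planted loadings in the weak-to-moderate band, signs
following the qualitative pattern the analysis is meant to detect), plus
an archetype-specific slope-preference term (amplitude 0.15; u-shaped
peak at −2.5), a rater offset (sd 0.05), and trial noise (sd 0.08),
clipped to $[0, 1]$. These values were fixed once as realistic for a
continuous click scale — mean-rating signal and noise of comparable
magnitude, clipping negligible — and define the study conditions for all
tests. Rater archetypes (u-shaped, increasing, decreasing, and an
anticorrelated Harmonious/Interesting type that negates the Harmonious
loadings for Interesting) plant the cluster structure. The recorded
ground truth contains the archetype labels, the planted loading matrix,
and per category/dimension the projection of the noiseless expected
per-image means onto the within-category z-scored SIPs — the exact
estimand of the standardized regression — together with the adjusted
$R^2$ implied once averaging noise is added back.

What the generator does **not** emulate: figurative content, saliency,
response times, fatigue or order effects, and any nonlinear
SIP–preference relationship. Passing recovery tests therefore show the
pipeline is correct and well-calibrated under its own model assumptions,
not that those assumptions hold for human raters.

## Problem sizes and runtime choices

The package's own test and example runs use desk-scale sizes chosen for
a single CPU: synthesis at 512 px for the slope-recovery batches and 64
to 256 px elsewhere; SIP computation at 64 to 128 px internal resolution
(the study convention of 800 px remains the default); 200 replicates for
coefficient recovery; 2000 replicates for the test-size simulation; 100
seeds for cluster recovery. Full-scale settings (1024 px stimuli, 800 px
SIPs) are available through the same configuration objects.

## Interfaces

This is an analysis package, not a shell tool: the stages are exposed as
composable functions (`synthesize_*`, `compute_sips`,
`best_subset_search`/`prune_collinear`, `standardized_regression`,
`build_reference`/`distance_rating_correlation`,
`kmeans_with_diagnostics`, `simulate_study`, `run_pipeline`), which keeps
them scriptable from `Rscript` one-liners without a bespoke CLI binary.
`run_pipeline()` writes CSV/JSON stage artifacts, each carrying the
configuration hash so bundles from different configurations cannot be
mixed unnoticed.

## Known limitations

* The built-in filter bank is a deterministic stand-in; pooled variance
  *values* depend on the bank and are comparable only within one bank.
* The second-order entropy estimator subsamples pairs uniformly; very
  sparse distance bins are noisy at toy edge counts.
* Robustness counting is a reproducible surrogate for a judgment the
  original workflow made visually; the 12-variable cut is a convention.
* With per-coordinate medians as centers, Mahalanobis distances are not
  exactly invariant under rotational affine maps of SIP space.
* Best-subset search beyond ~30 predictors is computationally hostile
  even with branch-and-bound; the package targets SIP-sized problems.
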