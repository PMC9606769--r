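# sipstats

Statistical image properties (SIPs) are scalar, objective descriptors of an
image's formal structure — complexity, self-similarity, edge-orientation
entropy, filter-response variance, color statistics. In experimental
aesthetics they are used to ask how much of a beholder's judgment of an
abstract image ("pleasing", "harmonious", "interesting") is carried by
perceptual structure alone. `sipstats` implements that analysis chain as a
tested, reusable R package:

- **Stimulus synthesis** — grayscale and colored random-phase images with a
  prescribed Fourier spectral slope α (power ∝ f^α over radial spatial
  frequency f), plus slope estimation for arbitrary images. Natural scenes
  and most paintings sit near α ≈ −2.
- **SIP computation** — gradient complexity (HOG), PHOG self-similarity and
  anisotropy, first/second-order edge-orientation entropy, pooled
  filter-bank variances P_a(k) and P_f(k), CIELab/HSV color statistics,
  combined mirror symmetry, Fourier slope; all at a fixed internal
  resolution so re-encoded or pre-resized images score identically.
- **Feature selection** — exhaustive (or branch-and-bound) best-subset
  regression ranked by adjusted R², robustness counting across the retained
  models, and iterative pruning of collinear SIPs (|ρ| > 0.6).
- **Rating analysis** — standardized-coefficient (β\*) regression with
  effect bands (weak < 0.2 ≤ moderate < 0.5 ≤ strong), Kruskal–Wallis +
  Dunn group tests, quadratic slope-preference curves, inter-rating
  correlations.
- **Distance analysis** — squared Mahalanobis distance
  D² = (x − m)ᵀ Σ⁻¹ (x − m) of each image to a reference corpus
  ("sweet spot") in SIP space, and its correlation with ratings.
- **Participant clustering** — k-means (k-means++ restarts) on
  inter-rating-correlation vectors or slope-preference profiles, with
  elbow/silhouette/gap diagnostics and a minimum-cluster-size rule.
- **Synthetic studies** — a generator that emulates the full study design
  (40 raters, 6 slope conditions × 25 images, balanced 30-of-150
  assignment, planted rater archetypes and SIP loadings) so every stage is
  verifiable against known ground truth.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Synthesize a colored random-phase image at set slope −3 and verify the
measured spectrum:

```r
library(sipstats)
spec <- random_phase_spec(size_px = 256, set_slope = -3, seed = 7)
img  <- synthesize_colored_random_phase(spec)
measure_fourier_slope(img)
#> # A tibble: 1 × 6
#>   slope intercept r_squared f_min f_max n_bins_used
#>   <dbl>     <dbl>     <dbl> <dbl> <dbl>       <int>
#> 1 -3.01      15.8     0.999    10    64          30
```

The measured log-log slope (−3.01) recovers the set slope; `r_squared`
confirms the spectrum is an almost exact power law over the fitted
frequency range (10 to 64 cycles/image here).

Simulate a small study and regress mean Pleasing ratings on the eight
model SIPs:

```r
cfg <- synthetic_study_config(n_participants = 20, images_per_slope = 5,
                              rated_per_slope = 1, n_pseudo_paintings = 40,
                              image_size = 64, seed = 7)
study <- simulate_study(cfg, sip_resolution = 64)
means <- aggregate_ratings(
  subset(study$ratings, category == "style_transferred"), "image")
d   <- merge(means[means$dimension == "Pleasing", ], study$sips,
             by = "image_id")
fit <- standardized_regression(d, "mean_rating", eight_model_sips())
fit
#> <std_regression> mean_rating ~ 8 SIPs, n = 40, adj R^2 = 0.944
#>                  term beta_star  p_value stars effect_band
#>            complexity   -0.2182 1.00e-02     *    moderate
#>       self_similarity    0.1883 3.06e-02     *        weak
#>  entropy_second_order    0.0734 1.81e-01              weak
#>         variance_Pa_2   -0.1305 1.18e-01              weak
#>        variance_Pf_30    0.3998 8.25e-05  ****    moderate
#>            lab_b_mean   -0.3659 3.13e-10  ****    moderate
#>            hsv_S_mean   -0.4459 6.01e-09  ****    moderate
#>         entropy_hsv_H    0.3896 2.62e-09  ****    moderate
```

Each β\* is the standardized influence of one SIP on the mean rating with
the others controlled for; stars mark partial significance, and the bands
classify effect size. With this generator seed the planted loadings (e.g.
negative complexity and saturation effects, positive P_f(30)) are
recovered with the planted signs, and the model explains 94% of the
variance in the noiseless-by-construction mean ratings. `glance(fit)`
returns the model-level summary, `autoplot(fit)` the coefficient plot.

`run_pipeline()` chains every stage (SIPs → subset selection → pruning →
β\* models → reference distances → clustering) on one seeded synthetic
study and writes the five stage artifacts plus a provenance record.

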