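# rcpquant

Quantification of fluorescence microscopy images of rolling circle
amplification products (RCPs) — the spot-like readout of padlock-probe and
proximity ligation assays. The package measures the three image-level
properties that determine how reliably one RCP is counted as one signal:

* **Signal-to-noise**: per-spot peak intensity against local background
  variation, SNR = 20·log₁₀(r) dB, where r is the maximum intensity in an
  inner disk (radius 3 px) around the spot divided by the SD of the
  surrounding annulus (outer radius 7 px), after excluding spots whose
  measurement neighborhoods overlap.
* **Signal integrity**: the fraction of signals whose Euclidean nearest
  neighbor (across both color channels) has the same color. A
  disintegrated RCP renders as a tight same-color cluster and inflates
  this fraction above the random-placement null, which is simulated by
  Monte Carlo with fixed per-color counts and cross-checked against the
  closed form [n₁(n₁−1) + n₂(n₂−1)] / [(n₁+n₂)(n₁+n₂−1)].
* **Co-localization**: pixel-level intersection-over-union of the two
  binarized channels on slides, and object-level dual-color classification
  (intensity ≥ 35 PMT units, area 2–30 px) for solution-phase line scans,
  with one-way ANOVA + Fisher's LSD across conditions.

Upstream of the statistics sit the standard preparation steps: max/min
z-projection with background correction, automatic "twice the histogram
mode" thresholding, 8-connected spot segmentation with a 40 px / 0.5
circularity cluster filter, and Gaussian-smoothing + median-subtraction
local-maxima detection. A synthetic scene generator renders compact or
dispersed RCPs as Gaussian spots in two-channel z-stacks with exact ground
truth, so the whole pipeline is testable without microscope data.

## Worked example

```r
library(rcpquant)

# a field whose RCPs disintegrate into sub-foci
scene <- generate_scene(scene_config(mode = "dispersed", seed = 1))
proj  <- lapply(list(scene$channel1, scene$channel2), project_stack)
thr   <- lapply(proj, function(p) mode_threshold(p$corrected))
maxima <- lapply(1:2, function(ch)
  detect_maxima(proj[[ch]]$corrected, min_prominence = thr[[ch]]$threshold))
pts  <- as_colored_points(maxima[[1]], maxima[[2]])

obs  <- same_color_frequency(pts)
null <- monte_carlo_null(c(nrow(maxima[[1]]), nrow(maxima[[2]])),
                         dim(proj[[1]]$corrected), seed = 2)
obs$frequency
#> [1] 0.7448071
glance(null)
#> # A tibble: 1 × 5
#>   mean_frequency sd_frequency n_replicates    n1    n2
#>            <dbl>        <dbl>        <int> <int> <int>
#> 1          0.514       0.0296           10   167   170
tidy(integrity_test(obs$frequency, null))
#> # A tibble: 1 × 8
#>   replicate observed null_mean null_sd  p_value within_2sd relative_diff method
#>       <int>    <dbl>     <dbl>   <dbl>    <dbl> <lgl>              <dbl> <chr>
#> 1         1    0.745     0.514  0.0296  1.39e-9 FALSE              0.450 one-sample two-tailed t-test
```

337 signals were detected where only 240 RCPs were simulated — the extra
~97 are disintegration fragments. 74.5% of signals have a same-color
nearest neighbor, far above the 51.4% expected under random placement of
the same color counts (p ≈ 10⁻⁹): the field fails the integrity check, as
a dispersed field should. Rerunning with `mode = "compact"` detects
exactly 240 signals — no fragments — and their same-color frequency shows
no excess over the null (41.7% observed vs 49.2% ± 3.7% expected).

The full flow (simulate → project → detect → SNR / integrity /
co-localization, with every intermediate table on disk plus a run
manifest) is one call:

```r
run_pipeline(run_config(scene = scene_config(mode = "compact"),
                        seed = 1, out_dir = "run1"))
```

or, from a shell, `Rscript inst/scripts/rcp_pipeline.R all --out run1
--seed 1`.

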