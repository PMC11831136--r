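# slicewise

Spatial proteomics of serial tissue cryosections: from a wide DIA
protein-group matrix to normalized, imputed, replicate-aligned spatial
protein profiles and a directed **distance-delay network**.

`slicewise` is for labs that section a tissue with an asymmetric axis —
skeletal muscle running into its tendon is the motivating case — into
consecutive thin sections (e.g. 175 × 20 µm for a 3.5 mm soleus), measure
each section by LC-MS/MS, and want per-protein abundance profiles along
that axis plus a network of which proteins' spatial domains precede
which. The input is tabular (proteins × sections, with replicate and
slice encoded in the column names, as DIA-NN post-processing emits);
every user-facing function takes a data frame and returns a tibble.

## The method in brief

For protein *i* with intensities *x<sub>ij</sub>* in sections
*j = 1…n* per replicate:

1. **Floor & normalize** — censor *x < 10⁴*; per-sample robust scale
   calibration (trimmed fit on log₂ ratios to a geometric-mean
   reference) followed by the arsinh-type generalized log
   *h(z) = log₂((z + √(z² + c²))/2)*; subtract log₂ of the per-section
   total intensity so profiles are relative to per-slice protein input
   (section area shrinks ~8-fold toward the tendon).
2. **Filter** — slide an 11-section window along each replicate; keep
   proteins whose mean (over replicates) *minimum* window
   missing-fraction is ≤ 0.3 (one ~200 µm stretch with a 70 % data
   rate suffices).
3. **Impute** — per missing section, least-squares line on the
   observed points within ±10 sections (needs > 3 points; predictions
   below the replicate-block minimum are rejected); leftovers drawn
   from the sample's low-intensity tail (downshifted normal).
4. **Score trends** — SAM-style quantitative statistic per replicate,
   *d = slope/(se + s₀)* with the fudge factor *s₀* chosen by the
   CV-of-MAD percentile scan, plus a seeded permutation null; markers
   are proteins with |mean d across replicates| > 5.
5. **Align replicates** — smooth marker profiles onto a 5000-point
   grid (loess), scan lags in both directions, apply the median
   fractional shift per pair to the non-reference replicate
   (`perc2`); finalize as per-replicate z-scores and a [0, 1]-ranged
   variant.
6. **Network** — delay cross-correlation (Spearman) for every protein
   pair with a minimum-overlap guard (`delayt = 0.45·n`); best delay
   per pair; strict |delay| < 20 cut; directed edges with delay ≥ 0;
   data-processing-inequality pruning (tolerance 0.1) removes edges
   explained by a two-step path with no more delay and comparable
   correlation; export as Cytoscape-ready CSV with
   `delay_inv = 1/(delay+1)`.

A synthetic generator (`simulate_sections()`) produces raw matrices
with known archetypes (junction sigmoids, bumps, ramps, flat),
log-normal abundances over ~4 orders of magnitude, per-slice loading
decay, MNAR + MCAR missingness and replicate axis offsets, so every
stage is testable against ground truth. Protocol-planning helpers
compute section counts and iRT peptide m/z.

## Worked example

```r
library(slicewise)

sim <- simulate_sections(n_proteins = 30, n_slices = c(80, 80, 80), seed = 7)
cfg <- slicewise_config(sam_nperms = 200, seed = 7)
run <- run_pipeline(sim$quant, sim$annotation, cfg)
run
#> <slicewise_run> stages done: preprocess, filter, impute, markers, align, network
#>   proteins selected: 29 of 30
#>   alignment markers: 10
#>   network edges: 400 -> 400 after DPI pruning

tidy(run$alignment)
#> # A tibble: 6 × 5
#>   rep_a rep_b direction  shift  corr
#>   <chr> <chr> <chr>      <dbl> <dbl>
#> 1 R1    R2    lo        0      0.998
#> 2 R1    R2    up        0.0450 0.999
#> 3 R1    R3    lo        0.120  0.998
#> 4 R1    R3    up        0      0.995
#> 5 R2    R3    lo        0.173  0.998
#> 6 R2    R3    up        0.167  0.992

glance(run$pruned)
#> # A tibble: 1 × 6
#>   n_nodes n_edges n_pruned dpi_tolerance mean_delay mean_corr
#>     <int>   <int>    <int>         <dbl>      <dbl>     <dbl>
#> 1      29     400        0           0.1      0.325     0.740
```

One protein was dropped by the sliding-window filter; ten survived the
|mean d| > 5 marker cut. The generator planted axis offsets of +0.05
(R2) and −0.08 (R3): the R1–R2 scan recovers 0.045 in the "up"
direction (R2's features come early, so its axis is pushed forward) and
the R1–R3 scan 0.120 in the "lo" direction — the right direction, with
the magnitude overshooting at the default loess span; the methods
vignette discusses the span/sharpness trade-off and shows that clean
junction markers are recovered to within 0.01. The finalized network
here has 400 directed edges; most best delays are 0–1 sections, so the
DPI pass finds nothing to prune at this scale.

```r
section_count(3.5, 20)    # 175 sections from a 3.5 mm muscle at 20 um
irt_mz("LGGNEQVTR", 2)    # 487.2567
```

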