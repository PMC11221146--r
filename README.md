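# ciliaPCP

Quantitative analysis of multiciliated ependymal epithelium: planar cell
polarity (PCP), ciliary beat kinetics, and transcriptomic signature
similarity.

Ependymal cells line the brain ventricles and propel cerebrospinal fluid
with coordinated ciliary beating. Whether that coordination develops
correctly is read out through three quantitative assays, all of which this
package implements together with a synthetic-data generator that makes
every stage testable end to end:

- **Translational PCP** — the basal-body patch of each cell is displaced
  from the centre of its apical surface. For each cell the package builds
  the vector from the area-weighted centroid of the cell outline to the
  basal-body patch centroid, and summarises the angular distribution of
  those vectors around their circular mean (polar histograms, the fraction
  of cells within 45° of the mean, apical-area statistics).
- **Rotational PCP** — each motile cilium's central microtubule pair
  defines a beat direction. Per image, the package computes the circular
  mean orientation and each cilium's absolute wrapped deviation from it,
  pooled into a grand mean ± s.e.m. across cilia.
- **Circular statistics** — a kernel with circular means and resultants,
  wrapped differences on directional (360°) and axial (180°) data, von
  Mises sampling/fitting, and the two-sample Watson *U²* homogeneity test.
  The statistic is computed from the two empirical CDFs on the combined
  ordered sample,

  *U²* = (n₁n₂/N²) Σₖ (dₖ − d̄)²,

  with mid-rank handling of ties, and its significance is assessed by
  random-relabelling permutation (default 9999 permutations,
  p = (1 + #{U²ₚₑᵣₘ ≥ U²ₒᵦₛ}) / (1 + B)).
- **Beat kinetics** — kymographs extracted along line ROIs of a time-lapse
  stack (60 frames/s recordings); beat frequency by counting intensity
  peaks (each peak one beat) with an independent FFT-based spectral
  estimator as cross-check.
- **Signature similarity** — microglial (or any) populations described by
  per-gene differential-expression attributes are compared as vectors in
  gene space with the Euclidean distance
  d(i,j) = √Σₖ(vₖⁱ − vₖʲ)² and the absolute-cosine correlation
  C(i,j) = |v⃗ⁱ·v⃗ʲ|/(‖v⃗ⁱ‖‖v⃗ʲ‖) ∈ [0,1], then ordered by average-linkage
  clustering on the distance matrix.

Everything is tidyverse-native: tabular inputs, tibbles out, `tidy()` /
`glance()` methods on every result object, and `autoplot()` figures.

## Worked example

```r
library(ciliaPCP)

# translational PCP on a synthetic apical map (100 cells, von Mises
# displacement directions with concentration kappa = 4)
sim <- sim_apical_map(n_cells = 100, mu = 0, kappa = 4,
                      displacement_frac = 0.4, pixel_size = 0.2, seed = 42)
summarize_translational(translational_vectors(sim$map))
#> Translational PCP summary
#>   100 cells in 1 image(s); 0 degenerate vector(s) excluded
#>   fraction within 45 deg of the per image mean: 0.920
#>   apical area: 120.00 +/- 1.67 um^2 (mean +/- sem)
```

92% of basal-body vectors lie within 45° of the image mean — a tightly
organised epithelium. A disorganised condition (lower concentration) is
distinguishable with the Watson *U²* test:

```r
wt <- translational_vectors(sim_apical_map(100, kappa = 4, seed = 1)$map)
ko <- translational_vectors(sim_apical_map(100, kappa = 1, seed = 2)$map)
watson_u2(wt$angle_deg, ko$angle_deg, n_permutations = 999, seed = 3)
#> Watson two-sample U2 test (permutation null)
#>   U2 = 0.91461, p (permutation, B = 999) = 0.001
#>   p (asymptotic) = 2.887e-08; n1 = 100, n2 = 100; period = 360 deg
```

Rotational PCP, beat frequency and signature similarity follow the same
pattern:

```r
rot <- sim_orientation_field(n_images = 10, cilia_per_image = 12,
                             kappa = 21.3, seed = 7)
summarize_rotational(rot$angles)
#> Rotational PCP summary
#>   120 cilia in 10 image(s), periodicity directional_360
#>   mean deviation from image mean: 9.33 +/- 0.65 deg (mean +/- sem, cilia pooling)

rec <- sim_beat_recording(freq_hz = 9, fps = 60, duration_s = 2,
                          noise_sd = 0.2, seed = 4)
estimate_beat(extract_kymograph(rec$stack, rec$truth$truths$roi))
#> # A tibble: 1 × 6
#>   roi_id freq_peaks freq_spectral n_peaks low_snr disagreement
#>   <chr>       <dbl>         <dbl>   <int> <lgl>   <lgl>
#> 1 roi             9             9      18 FALSE   FALSE

prof <- sim_population_profiles(
  list(developmental = c("PAM", "ATM", "CD11c"),
       disease = c("DAM1", "DAM2")),
  n_genes = 500, block_size = 50, seed = 5)
similarity_matrix(prof$profiles)
#> Signature similarity over 5 populations, 500 shared genes
#>   cluster order: DAM1 | DAM2 | CD11c | PAM | ATM
#>   correlation matrix (|cos theta|):
#>         PAM   ATM CD11c  DAM1  DAM2
#> PAM   1.000 0.724 0.703 0.053 0.003
#> ATM   0.724 1.000 0.710 0.048 0.003
#> CD11c 0.703 0.710 1.000 0.028 0.039
#> DAM1  0.053 0.048 0.028 1.000 0.737
#> DAM2  0.003 0.003 0.039 0.737 1.000
```

The 18 peaks over a 2 s trace give 9 Hz, matching the designed frequency
exactly; in the similarity matrix the two designed signature blocks
(developmental vs disease-associated populations) separate cleanly and
cluster-order adjacently.

`run_pipeline(pipeline_config(seed = 1))` chains all four stages —
simulate, write to disk, read back through the package's own file formats,
analyse — and returns a reproducible run report (per-stage summaries,
config hash, collected warnings).

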