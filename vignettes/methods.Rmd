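---
title: "Methods: PCP quantification, beat kinetics, and signature similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCP quantification, beat kinetics, and signature similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaPCP)
```

# Scope and model

Multiciliated ependymal cells acquire two forms of planar cell polarity
(PCP) during postnatal maturation: *translational* polarity, the coherent
displacement of each cell's basal-body patch away from the centre of its
apical surface, and *rotational* polarity, the uniform orientation of the
individual cilia read from the axis of their central microtubule pair.
Functional output is the ciliary beat, visible in time-lapse recordings as
periodic intensity fluctuations. This package quantifies all three, plus a
vector-space comparison of transcriptomic population signatures, and ships
a synthetic-data generator whose ground truth closes the loop on every
estimator.

# Translational polarity

Input is a per-image cell map: one outline polygon per cell (pixel
coordinates, image convention with the origin top-left and y growing
downwards) plus the centroid of its basal-body patch. The pipeline starts
from outlines and centroids; segmentation of the underlying micrographs is
out of scope, as in practice cells are outlined manually.

**Cell centre.** We define the cell centre as the area-weighted (shoelace)
centroid of the outline polygon. This is a deliberate choice from several
defensible options (vertex mean, bounding-box centre, intensity-weighted
centre): it is parameter-free, reproducible, and insensitive to vertex
density along the outline.

**Vector and angle convention.** The polarity vector runs from the cell
centre to the basal-body centroid. Angles are reported in mathematical
convention — counter-clockwise from +x — *after* flipping the y axis, so
that an angle of 90° means "up" on the screen. The convention is fixed and
documented rather than configurable; mixing conventions is the classic
source of silent sign errors in polarity work.

**Deviations and the 45° fraction.** Per image, each vector angle is
compared to the circular mean of the image's angles (a fixed external
reference is available as an option, e.g. the ventricular-flow axis when
known). The deviation is the absolute wrapped difference in [0°, 180°],
and the headline statistic is the fraction of cells within 45° of the
mean. Under a von Mises displacement-direction model with concentration
$\kappa$ this fraction has the closed form
$P(|\Delta| \le 45^\circ) = \int_{-\pi/4}^{\pi/4}
\frac{e^{\kappa\cos x}}{2\pi I_0(\kappa)}\,dx$,
implemented in `vm_prob_within()` by numerical integration; the uniform
limit ($\kappa = 0$) is exactly $45/180 = 0.25$. The test suite checks the
empirical fraction against this integral across
$\kappa \in \{0, 1, 2, 4, 8\}$.

**Degeneracy.** Vectors shorter than $\varepsilon = 0.1\,\mu m$ (about
half a pixel at typical confocal calibration; configurable) are flagged
degenerate and excluded from angular summaries but counted, since an
angle computed from a near-zero displacement is noise.

**Counts.** Summaries warn below 30 cells per image, the customary
minimum for this assay; histograms default to 24 bins of 15°, a bin width
chosen to keep one cell from dominating a bin at typical n.

# Rotational polarity

Input is a table of per-image central-pair orientation angles.
Orientations default to the *directional* 360° period, because the
central-pair axis defines a directed beat vector; an *axial* 180° mode
(angle-doubling for all statistics) is available for data digitised
without polarity. Per image, each cilium's deviation is the absolute
wrapped difference to the image's circular mean; deviations are pooled
over images and reported as mean ± s.e.m. across cilia (at least 10
images and 100 cilia per animal is the customary reporting scale;
image-first aggregation is an option). The circular mean was chosen over
the arithmetic mean of angles because the latter is not rotation
invariant; the package's rotation-invariance property tests would fail
for it.

The expected absolute deviation under a von Mises model,
$E|\Delta|(\kappa)$, is computed by numerical integration in
`vm_expected_absdev()` (with the half-normal asymptote
$\sqrt{2/(\pi\kappa)}$ above $\kappa = 10^4$, where the Bessel-ratio
computation loses precision), and inverted by `vm_kappa_for_absdev()`.
This gives the calibration used throughout testing: a field tuned to
$E|\Delta| = 10^\circ$ ($\kappa \approx 21.3$) must be recovered by the
pipeline within 5% (averaged over 20 simulated animals of 10 × 100
cilia).

Note one subtlety the tests encode: deviations computed under the axial
and directional conventions agree only to second order in the angular
spread, because the angle-doubled circular mean is not exactly the
directional mean; exact agreement holds in the concentrated limit.

# Circular-statistics kernel

`circ_mean_resultant()` returns the mean direction and resultant length
$R$; samples with $R < 10^{-8}$ (e.g. perfectly balanced configurations)
are flagged and the mean reported as `NA` rather than an arbitrary
number. `vonmises_fit()` estimates $\mu$ as the circular mean and
$\kappa$ by inverting $A_1(\kappa) = I_1(\kappa)/I_0(\kappa) = R$ with
`uniroot`; $R$ so close to 1 that $\kappa$ would exceed $10^6$ is capped
and flagged. Sampling uses the Best–Fisher rejection algorithm, validated
in the tests against an independent inverse-CDF sampler.

**Watson two-sample U².** The homogeneity statistic is computed from the
empirical CDF difference $d_k$ over the combined ordered sample,
$U^2 = \frac{n_1 n_2}{N^2}\sum_k t_k (d_k - \bar d)^2$ with
multiplicities $t_k$ at distinct values (mid-rank treatment of ties; the
tie count is reported in the result). The statistic is invariant under
common rotation of both samples and under exchanging them — both
properties are tested. Significance uses a random-relabelling permutation
null with $p = (1 + \#\{U^2_{perm} \ge U^2_{obs}\})/(1 + B)$, default
$B = 9999$; the permutation approach was chosen over asymptotic
critical-value tables because it is exact at any sample size, handles
ties naturally, and is reproducible given a seed. The classical
asymptotic tail probability is reported alongside as a secondary value.
Calibration is checked head-on: under the null (two von Mises samples of
50 with identical parameters) the rejection rate at $\alpha = 0.05$ over
2000 replicates must be 0.05 ± 0.01 and the p-values must pass a
Kolmogorov–Smirnov uniformity check; the calibration run uses $B = 199$,
which a permutation test's exactness permits without bias.

# Beat kinetics

A kymograph is the space × time matrix obtained by sampling each frame
along a line ROI (bilinear interpolation by default, nearest-pixel
optional), averaged over a 3-px band perpendicular to the line to reduce
noise. The per-frame mean of the kymograph is the intensity trace.

Two estimators are computed on every trace. *Peak counting*: local maxima
with topographic prominence of at least 20% of the trace range (the
fraction mirrors what one accepts by eye on published traces;
configurable), each peak one beat, frequency = peaks / duration. An
optional minimum peak separation of $0.3/f_{max}$ seconds suppresses
double-counting when a maximum physiological frequency is supplied.
*Spectral*: the dominant non-zero bin of the mean-detrended FFT — no
windowing, since the traces are short and the estimator only needs the
dominant bin. Disagreement beyond 0.5 Hz sets a quality flag, as does a
flat (zero-range) trace. Both estimators are invariant to affine
intensity rescaling and to doubling the frame rate of the same physical
signal, and both must recover generated 5–15 Hz recordings at
amplitude/noise = 3 within ±0.5 Hz; whether a "beat" should count full
cycles or half-strokes is a digitisation convention, which is why the
peak definition is configurable and recorded in the output.

Aggregation is hierarchical — ROI → image → animal — matching how such
recordings are reported (3–5 ROIs per area, about 5 images per animal),
with the s.e.m. across animal means.

# Signature similarity

Populations are vectors in gene-attribute space; values are differential
expression levels (conventionally log2 fold change versus a homeostatic
baseline — the scale is the user's responsibility and should be uniform
across columns). Genes are matched by intersection: only genes finite in
every population are kept, because zero-filling missing genes biases the
cosine toward zero; the dropped-gene count is reported. No internal gene
filtering or standardisation is applied by default (a z-scoring switch
exists), since which genes constitute a signature is a scientific choice
that belongs upstream.

Similarity is measured two ways: the Euclidean distance
$d_{i,j} = \sqrt{\sum_k (v_k^i - v_k^j)^2}$ and the absolute-cosine
correlation $C_{i,j} = |v^i \cdot v^j| / (\|v^i\|\|v^j\|) \in [0,1]$,
where 0 means orthogonal (independent) and 1 linearly dependent
(equivalent) populations. Population ordering comes from average-linkage
agglomerative clustering on the distance matrix; average linkage is a
robust default when no linkage is dictated by the data, and the linkage
is configurable. Zero vectors have no direction, so such populations are
excluded with a warning rather than given an arbitrary correlation.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth, and its defaults are the study conditions used throughout
the tests:

- **Apical maps**: a jitter-perturbed rectangular grid — interior vertices
  displaced, boundary fixed — so the polygons tile the region exactly and
  the total-area conservation oracle is exact. Mean apical area defaults
  to 120 µm² at 0.2 µm/px, representative of maturing ependyma at typical
  confocal calibration; the vertex jitter maps a requested area CV
  (default 0.15) through the first-order shoelace sensitivity
  ($j \approx \sqrt{3/2}\,\mathrm{CV}\,L$, capped at $0.3L$ to keep the
  quads simple). The basal-body centroid sits at `displacement_frac`
  (default 0.4) of the effective radius $\sqrt{A/\pi}$ — a
  shape-independent scale — along a von Mises direction; the drawn angles
  are stored so recovery is checked exactly, not statistically.
- **Orientation fields**: default 10 images × 12 cilia (clusters of 10–15
  cilia per section image, ≥ 10 images per animal). Each image gets its
  own uniform-random mean direction — sections are cut at unrelated
  orientations — with a deterministic per-image sub-seed.
- **Beat recordings**: a 3-px horizontal band oscillating sinusoidally at
  the designed frequency over a constant background, Gaussian noise
  everywhere, 60 frames/s by default. Frequencies at or above Nyquist
  (fps/2) are refused at generation time. Additive Gaussian noise on a
  sinusoid is the simplest model with a controllable SNR; non-sinusoidal
  waveforms, resonance-scanner line jitter, photobleaching and drift are
  deliberately *not* modelled.
- **Profile sets**: disjoint gene blocks of `block_size` genes; every
  population in a block carries `effect` on its block's genes plus
  Gaussian noise everywhere. Assigning one population to two blocks is
  rejected as a misspecification. With effect/noise = 5 and 50 signature
  genes out of 500, within-block cosines are ≈ 0.7 and between-block
  cosines ≈ 0 — comfortably separable, which is the point: the generator
  tests the machinery, not the biology.

What passing tests on these data do *not* show: correctness on real
micrographs with segmentation errors, non-convex cells, intensity-graded
basal-body patches, non-stationary beating, or batch effects across
expression studies. The generator omits all of these by design; the
package's claims are about the estimators, conditional on their inputs.

# Numerical choices and degenerate inputs

- Angles are degrees at every user-facing surface and in every file;
  trigonometry is done in radians internally. Wrapped differences live in
  $(-\text{period}/2, \text{period}/2]$.
- Polygons with zero shoelace area, self-intersecting outlines, empty
  maps, all-degenerate vector sets, flat traces, zero expression vectors
  and missing frame-rate metadata are all hard errors or flagged
  results — never silently defaulted.
- The circular mean is snapped to 0 when it lands within $10^{-9}$ degrees
  of the period seam, so symmetric samples report 0 rather than 360.
- 16-bit TIFF storage quantises intensities to ~1/65535 of the range;
  the affine scale/offset recorded in the JSON sidecar restores absolute
  units on read.
- All simulation entry points require an explicit seed; helper RNG use
  saves and restores the caller's `.Random.seed`.

# Problem sizes used in the validation suite

The shipped tests run the Watson calibration at 2000 replicates × 199
permutations (n = 50 + 50), translational closed-form checks on
5000-cell maps across five concentrations, rotational recovery on 20
fields of 10 × 100 cilia, beat recovery on 100 recordings of 4 s at 60
fps, and clustering recovery on 100 profile sets of 6 populations × 500
genes — sizes at which the Monte-Carlo bands in the assertions are
three-sigma statements. The full suite runs in under a minute on one
core.

# Known limitations

- The tessellation is a perturbed grid, not a Voronoi mosaic; cell shapes
  are quads. The analysis only consumes centroids and areas, so this does
  not limit the estimators, but the maps are not visually realistic.
- The Watson test's asymptotic p-value is reported for reference and is
  anti-conservative for very small samples; the permutation p is the
  primary output.
- Kymograph extraction assumes a straight ROI; curved cilia paths need
  piecewise ROIs.
- `summarize_recording()` propagates no uncertainty from the per-ROI
  estimators into the animal-level s.e.m.; it reproduces the field's
  standard mean-of-means reporting.
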