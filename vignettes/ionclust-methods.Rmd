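---
title: "ionclust: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionclust: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionclust)
```

# The model

Mass spectrometry imaging acquires one spectrum per pixel of a tissue
section. For each mass bin, plotting the per-pixel intensity gives an ion
image; a dataset is a stack of thousands of such images over one pixel
grid. Molecules from the same anatomical compartment share a spatial
distribution, so clustering ion images by spatial pattern surfaces the
tissue's chemical organization without annotation.

`ionclust` implements four pipelines over one shared preprocessing block:

1. **regular U-D** — flattened ion images, UMAP to 3-D (cosine), DBSCAN;
2. **neural U-D** — patch-embedding vectors, UMAP to 3-D (cosine), DBSCAN;
3. **regular k-means** — flattened ion images, k-means (Euclidean);
4. **neural k-means** — patch-embedding vectors, k-means (Euclidean).

The *neural ion image* of an ion image is built in three steps: split the
image into overlapping square patches of a target physical size; embed each
patch with a pluggable deterministic embedder; max-pool the patch vectors
elementwise. Max-pooling is chosen over averaging deliberately: coordinate
$k$ of the result records whether feature $k$ fired in *any* patch, which
preserves sensitivity to localized structure that global similarity
measures average away.

# Shared preprocessing

**Spectral stage.** Each pixel spectrum is normalized to unit total ion
current (TIC), removing per-pixel acquisition variance. A running-median
baseline correction (`median_baseline_correct()`, replicate edge padding,
floor at zero) is available for profile-mode axes; it is off by default
because subtracting a running median across a centroided axis would eat
real peaks. The window (`baseline_window`, default 51 bins, odd) should
exceed the widest peak footprint.

**Image stage.** Each ion image is *winsorized above* its 95th percentile
(`winsor_quantile = 0.95`): intensities beyond the quantile of the acquired
pixels are clipped to it, suppressing the hot-pixel outliers endemic to MSI
detectors. The lower tail is never clipped — intensities are already
bounded at zero. The image is then affinely scaled to $[0, 1]$.

Pinned numerical choices:

* quantiles use linear interpolation between order statistics (type 7, the
  common numeric-library default), and are computed over acquired (masked)
  pixels only — unacquired zeros would bias them;
* a constant image scales to all zeros rather than erroring, so blank
  channels flow through the pipeline and end up in some cluster instead of
  aborting a run.

# Patch generation

The patch side in pixels starts from physics, not the detector:
`side0 = round(target_mm * 1000 / pixel_size_um)`. A 1–2 mm side captures
an anatomically meaningful context; the default `target_mm = 1.5`
(configurable in 0.5–3 mm) gives 150 px at 10 μm pitch. If `side0` falls
below the embedder's minimum input side (`min_side`, 71 px for the
convolutional backbone), the image is first upsampled by
`ceil(min_side / side0)` — bilinear, half-pixel centers — which refines
the pitch while preserving the physical patch extent exactly:
`side_px * effective_pitch_um == side0 * pixel_size_um`. At 50 μm pitch and
a 1.85 mm target this yields a factor-2 upsample and 74 px patches.

The stride is `ceil(side_px * (1 - overlap_target))` with
`overlap_target = 0.5`, so the realized overlap between neighboring patches
always lies in the 40–50% band (for sides ≥ 4; a 3-px patch would realize
1/3, a case no shipped embedder can produce since both have
`min_side ≥ 8`). Overlap avoids edge artifacts — structure falling on a
patch boundary still appears whole in a neighbor. Start offsets run at
stride multiples and the final start is clamped so the last patch abuts the
border: the edge gets extra overlap rather than fabricated padding. Only
when the whole upsampled image is smaller than one patch is it
reflect-padded to a single patch, with a warning. The bilinear convention
(half-pixel centers, clamped) is pinned by a test against an independent
loop-based resampler, because resampling conventions differ silently
between libraries.

# Embedders

An embedder is a contract: deterministic, fixed output length `dim`,
minimum input side `min_side`. Two are shipped.

**`reference_embedder()`** (dim 101, min side 8) is the default: the patch
is resized to 32 × 32 and described by block means over 1×1, 2×2, 4×4 and
8×8 partitions (an 85-value multiscale intensity pyramid) plus 4×4 block
means of the central-difference gradient magnitude (16 values of local
texture). It is fast, dependency-free and bit-reproducible, and it is what
the test suite exercises end to end.

**`backbone_embedder()`** (dim 2048, min side 71) is the adapter slot for a
pretrained convolutional feature extractor: grayscale is replicated to
three channels, intensities are mapped $[0,1] \to [-1,1]$, and the final
2048-channel feature map is globally average-pooled. No deep-learning
runtime ships with this package, so `weights = "pretrained"` raises a
capability error pointing at the reference embedder, and
`weights = "random"` instantiates the same architecture with deterministic
He-initialized random weights (fixed internal seed). The random-weight
instance is a **synthetic stand-in**: it honors every interface contract
(2048 dims, 71-px minimum, bit-identical outputs) and random convolutional
features are a serviceable, if weaker, patch descriptor — but it is not the
pretrained extractor, and results from it should be labelled accordingly.

# Clustering

**UMAP → DBSCAN.** Vectors (flattened images or neural ion images) are
reduced to three dimensions with cosine distance (`n_neighbors = 15`,
`min_dist = 0.1`), a space low-dimensional enough for density estimation
and directly plottable; DBSCAN then runs on the 3-D coordinates with
Euclidean distance. DBSCAN's `eps` / `min_samples` have no universal
defaults — density in the embedded space depends on the dataset — so they
are exposed in the configuration (defaults 0.5 / 5) and should be tuned per
run. Points in low-density regions go to the reserved noise cluster,
label `-1`. The DBSCAN implementation is in-package, exact (full distance
matrix), and checked against a literal density-reachability oracle; with
hundreds to thousands of ion images the O(n²) cost is irrelevant.

**k-means.** Lloyd iterations from k-means++ seeding, best of
`n_init = 10` seeded restarts by total within-cluster sum of squares,
Euclidean distance, labels `0..k-1` (never `-1`). `k` must be chosen by the
user; counting *meaningful* clusters (non-noise, ≥ 2 members,
`count_meaningful_clusters()`) across a few values of `k` is the intended
selection aid.

Determinism: UMAP runs single-threaded under an explicit seed; k-means and
every bootstrap draw run under seeds derived from one master seed by a
fixed per-stage offset scheme recorded in the run manifest, so a run
directory is bit-reproducible from its manifest.

# Relative Isotope Ratio

Isotope companions (+1.003 Da, the carbon isotope spacing) of one molecule
must co-localize, which makes them free ground truth for clustering
quality. Channels $i < j$ form a pair iff
$|mz_j - mz_i - 1.003| \le \delta$ and the Pearson correlation of their
standardized ion images is ≥ 0.85 (constant images have undefined
correlation and fail the threshold). δ defaults to 0.01 Da for centroided
high-accuracy axes; 0.1 Da suits profile data.

Choices pinned here, since "fraction of isotopes grouped" admits several
readings:

* the counting unit is the **unordered pair** — the detection criteria are
  defined pairwise, so pairs are what the null model can permute cleanly;
* a pair with any member in the noise cluster counts as **not grouped**
  (noise is explicitly "unassigned", not a cluster);
* the random baseline permutes the entire label vector uniformly, i.e. a
  random clustering with **the same cluster sizes**, the noise block
  included as one more size-fixed group — the baseline answers "what if
  these same cluster sizes were filled at random?";
* `B = 1000` bootstrap replicates by default; the exhaustive permutation
  mean is the test oracle at small n.

$R = F_{clust}/F_{random}$; edge cases: a single all-covering cluster gives
$F = F_{random} = 1$, $R = 1$ (chance-level, as it should); $F_{random}=0$
with $F>0$ yields `Inf` with a warning; $0/0$ is an error, not a number.

# Ranking benchmark

Given expert similarity scores (0 = identical … 10 = nothing alike) for
candidate images against target images, for each score cutoff $c$: the
truth set is the candidates scored ≤ $c$ (size $N$), the ranked set is the
$N$ candidates most similar under the metric being evaluated, and the
segment score is $|truth \cap ranked| / N$, pooled (sums of hits and of
$N$) across target sets; sets empty at a cutoff are skipped. Ties in
similarity break deterministically by ascending candidate index. The
statistic depends on similarity only through its ranking, so it is
invariant to monotone transforms — a property the tests assert.

# The synthetic world

`generate_msi_dataset()` builds the world the test suite measures: a
64 × 64 grid at 50 μm pitch; 4 spatial patterns (Gaussian blob, ring,
half-plane, stripe band at seeded random placements, pairwise correlation
≤ 0.5); 10 base channels per pattern with amplitudes uniform in
[0.5, 1.5]; half the base channels carry an isotope companion at *exactly*
+1.003 Da with 0.4× amplitude, the same pattern and independent noise;
8 pure-noise channels; additive Gaussian noise (sd 0.02) clipped at zero
everywhere; base and noise channels on a jittered 2.4 Da grid in
620–1200 Da so no unintended mass gap falls near 1.003 Da. The companion
spacing is exact (not sampled) so that δ-tolerance behavior is exercised by
explicit perturbation tests rather than by generator luck. With these
defaults every engineered pair passes detection (correlations stay above
0.85 at this noise level) and no spurious pair arises.

What the generator does **not** emulate — and therefore what a green test
does not establish:

* **no per-pixel sensitivity variation.** Real spectra carry
  multiplicative acquisition variance that TIC normalization removes. Here
  total signal is pattern-driven, so the TIC ratio transform *saturates*
  patterns (signal/total tends to a constant inside a pattern) and degrades
  the engineered pair correlations; synthetic evaluations therefore run on
  standardized channel images without TIC, while TIC stays on by default
  for real data;
* no profile-mode peak shapes, no mass-accuracy drift, no isotope
  envelopes beyond the +1 companion, no matrix/ionization physics;
* pattern boundaries are smooth and patterns are few; real anatomies are
  not.

# Why k = number-of-patterns cannot fully recover this world

The reference embedding separates *five* classes on the default world: the
four patterns and the pure-noise channels, whose high-frequency
full-range texture lands them in a tight class far from everything
(between-centroid distances ≈ 4.5–5.2 versus 1.0–1.5 between pattern
classes, within-class spread < 0.08). Lloyd's objective then always spends
one of four centroids on the distant noise class and merges the two closest
pattern classes; any such merge yields ARI 0.7372 against the full
ground-truth labels — the bit-reproducible observed value and the
structural ceiling. One extra centroid resolves it exactly: k = 5 attains
ARI = 1.0, which the test suite asserts. The practical guidance follows:
choose k above the expected pattern count so that noise channels can
sequester themselves, then read the meaningful-cluster count.

# Known limitations

* The imzML writer emits the minimal continuous/processed structures this
  package reads back; exotic vendor extensions are out of scope.
* Load-time binning of processed data (greedy gap rule, bin center = mean)
  is a stand-in for instrument-side binning; with sloppy tolerances,
  distinct species can share a bin.
* The pretrained backbone is an adapter without shipped weights; published
  results with a pretrained extractor are not reproduced by the
  random-weight stand-in.
* DBSCAN parameters are dataset-specific by nature; no automatic `eps`
  selection is attempted.
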