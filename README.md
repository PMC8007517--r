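# ionclust

Spatially aware clustering of mass spectrometry imaging (MSI) ion images.

## The problem

An MSI experiment produces one mass spectrum per spatial pixel of a tissue
section — a data cube over (x, y, m/z). Slicing the cube at one mass bin
gives an *ion image*: the spatial distribution of one molecular species.
A single dataset yields thousands of ion images, and molecules that share a
biological source share a spatial distribution, so grouping ion images by
spatial pattern is a primary exploratory step. Plain pixel-wise distances
(cosine, correlation) are global and miss localized structure; `ionclust`
instead converts every ion image into a fixed-length embedding vector — a
*neural ion image* — by splitting the image into overlapping patches of a
target physical size (1–2 mm works well), embedding each patch, and
max-pooling the patch embeddings elementwise, so a feature fires if it is
detected in *any* patch. Regular (flattened) or neural ion images are then
clustered either with UMAP (cosine metric, 3 components) followed by
DBSCAN, or with k-means.

## The evaluation statistic

Clusterings are scored with the **Relative Isotope Ratio**. Two channels
form an isotope pair iff their mass difference is 1.003 Da (± δ) and the
Pearson correlation of their ion images is ≥ 0.85 — heavy-isotope
companions of one molecule, which must co-localize. With F_clust the
fraction of isotope pairs whose members share a (non-noise) cluster and
F_random the expected fraction under a cluster-size-preserving random
relabeling (estimated by bootstrap),

    R = F_clust / F_random ∈ [0, ∞),

where R ≫ 1 means the clustering groups chemistry far better than chance
and R ≈ 1 means no better than chance.

A segment-wise ranking benchmark against expert similarity scores
(`ranking_benchmark()`) and a seeded synthetic MSI generator with
ground-truth pattern labels and isotope pairs (`generate_msi_dataset()`)
round out the toolkit.

## Worked example

```r
library(ionclust)

sim  <- generate_msi_dataset(synthetic_config())   # seeded, deterministic
sim$dataset
#> <msi_dataset> 4096 pixels, 68 m/z channels [625.9969..1197.2236 Da], 50 um pitch

imgs <- lapply(channel_images(sim$dataset), standardize_image)
nii  <- embed_dataset(imgs, reference_embedder(), preprocessed = TRUE)
labels <- cluster_kmeans(nii$vectors, 5, seed = 11)
count_meaningful_clusters(labels)
#> [1] 5

rir_evaluate(sim$dataset$mz_axis, imgs, labels, B = 1000, seed = 11)
#> <rir_result> F_clust 1.000 / F_random 0.199 (sd 0.090, B=1000) -> R = 5.04 over 20 pairs

adjusted_rand_index(labels, sim$truth$pattern_label)
#> [1] 1
```

All 20 engineered isotope pairs land in the same cluster (F_clust = 1)
while a size-matched random relabeling would co-cluster about 20% of them,
so the clustering beats chance five-fold (R = 5.04); the five recovered
clusters are exactly the four spatial patterns plus the pure-noise channel
group (ARI = 1).

The same workflow is available from the shell via the installed CLI:

```sh
Rscript inst/scripts/ionclust simulate --out simdir --seed 7
Rscript inst/scripts/ionclust run --in simdir/synthetic.imzML \
    --pipeline neural-kmeans --out rundir --k 5 --seed 1
```

which writes `assignments.csv`, `vectors.h5`, `rir.csv`, mean-cluster and
mean-spectrum PNGs, and a JSON run manifest into `rundir/`.

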