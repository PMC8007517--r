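# End-to-end pipelines: shared preprocessing, optional neural embedding,
# clustering (UMAP-DBSCAN or k-means), RIR evaluation, and report artifacts
# under one user-named run directory.

#' Pipeline configuration
#'
#' @param input path to an `.imzML` file, or an [msi_dataset()] directly.
#' @param pipeline one of `"regular-ud"`, `"neural-ud"`,
#'   `"regular-kmeans"`, `"neural-kmeans"`.
#' @param out_dir run directory (created; contents are overwritten).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   and recorded in the manifest.
#' @param preprocess a [preprocess_config()].
#' @param target_mm,overlap_target patch planning parameters (neural
#'   pipelines).
#' @param embedder_name `"reference"` or `"backbone"`.
#' @param k k-means cluster count.
#' @param eps,min_samples DBSCAN parameters.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param criteria an [isotope_criteria()] for the RIR report.
#' @param rir_B bootstrap replicates for the RIR baseline.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, pipeline = c("neural-kmeans", "regular-ud",
                                                "neural-ud", "regular-kmeans"),
                            out_dir = "ionclust-run", seed = 1L,
                            preprocess = preprocess_config(),
                            target_mm = 1.5, overlap_target = 0.5,
                            embedder_name = c("reference", "backbone"),
                            k = 20L, eps = 0.5, min_samples = 5L,
                            n_neighbors = 15L, min_dist = 0.1,
                            criteria = isotope_criteria(), rir_B = 1000L) {
  pipeline <- match.arg(pipeline)
  embedder_name <- match.arg(embedder_name)
  structure(list(input = input, pipeline = pipeline, out_dir = out_dir,
                 seed = as.integer(seed), preprocess = preprocess,
                 target_mm = target_mm, overlap_target = overlap_target,
                 embedder_name = embedder_name, k = as.integer(k),
                 eps = eps, min_samples = as.integer(min_samples),
                 n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 criteria = criteria, rir_B = as.integer(rir_B)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[%s stage] %s", name, conditionMessage(e))
  })
}

#' Run one clustering pipeline end to end
#'
#' Reads (or accepts) the dataset, applies shared preprocessing, builds the
#' per-channel vectors (flattened regular images or neural ion images),
#' clusters them, evaluates the Relative Isotope Ratio, and writes the run
#' artifacts: `assignments.csv`, `vectors.h5` (neural), `embedding3d.csv`
#' (UMAP pipelines), `rir.csv`, `mean_cluster_<id>.png`,
#' `mean_spectrum.png`, and `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path, invisibly; the manifest lists artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  neural <- grepl("^neural", config$pipeline)
  ud <- grepl("ud$", config$pipeline)

  ds <- stage("input", {
    if (inherits(config$input, "msi_dataset")) config$input
    else read_imzml(config$input)
  })
  ds <- stage("preprocess", suppressWarnings(
    preprocess_spectra(ds, config$preprocess)))
  images <- stage("preprocess", channel_images(ds))
  std_images <- stage("preprocess", lapply(
    images, standardize_image, q = config$preprocess$winsor_quantile))

  if (neural) {
    emb <- if (config$embedder_name == "reference") reference_embedder()
           else backbone_embedder()
    bundle <- stage("embedding", embed_dataset(
      std_images, emb, target_mm = config$target_mm,
      overlap_target = config$overlap_target, preprocessed = TRUE))
    vec_path <- file.path(config$out_dir, "vectors.h5")
    write_vectors(bundle, vec_path)
    artifacts <- c(artifacts, "vectors.h5")
    vectors <- bundle$vectors
  } else {
    # regular ion images: flatten row-major to vectors
    vectors <- do.call(rbind, lapply(std_images, function(im) {
      as.numeric(t(im$pixels))
    }))
  }

  result <- if (ud) {
    stage("clustering", cluster_umap_dbscan(
      vectors, eps = config$eps, min_samples = config$min_samples,
      n_neighbors = config$n_neighbors, min_dist = config$min_dist,
      seed = stage_seed(config$seed, "umap")))
  } else {
    stage("clustering", clustering_result(
      cluster_kmeans(vectors, config$k,
                     seed = stage_seed(config$seed, "kmeans")),
      "kmeans", params = list(k = config$k)))
  }

  write_assignments(result, ds$mz_axis,
                    file.path(config$out_dir, "assignments.csv"))
  artifacts <- c(artifacts, "assignments.csv")

  if (ud) {
    emb3 <- data.frame(mz = ds$mz_axis, u1 = result$embedding3d[, 1],
                       u2 = result$embedding3d[, 2],
                       u3 = result$embedding3d[, 3],
                       cluster = result$labels)
    utils::write.csv(emb3, file.path(config$out_dir, "embedding3d.csv"),
                     row.names = FALSE, quote = FALSE)
    artifacts <- c(artifacts, "embedding3d.csv")
  }

  rir <- stage("evaluation", tryCatch(
    rir_evaluate(ds$mz_axis, std_images, result,
                 criteria = config$criteria, B = config$rir_B,
                 seed = stage_seed(config$seed, "rir")),
    error = function(e) e))
  if (inherits(rir, "rir_result")) {
    write_rir_report(rir, file.path(config$out_dir, "rir.csv"))
    artifacts <- c(artifacts, "rir.csv")
  }

  ids <- sort(setdiff(unique(result$labels), -1L))
  for (id in ids) {
    mimg <- mean_cluster_image(images, result$labels, id,
                               winsor_quantile = config$preprocess$winsor_quantile)
    f <- sprintf("mean_cluster_%d.png", id)
    write_image_png(mimg, file.path(config$out_dir, f))
    artifacts <- c(artifacts, f)
  }

  spec_path <- file.path(config$out_dir, "mean_spectrum.png")
  stage("report", report_mean_spectrum(ds, result, spec_path))
  artifacts <- c(artifacts, "mean_spectrum.png")

  manifest <- list(
    pipeline = config$pipeline, seed = config$seed,
    stage_seeds = list(umap = stage_seed(config$seed, "umap"),
                       kmeans = stage_seed(config$seed, "kmeans"),
                       rir = stage_seed(config$seed, "rir")),
    params = list(target_mm = config$target_mm,
                  overlap_target = config$overlap_target,
                  embedder = if (neural) config$embedder_name else NULL,
                  k = if (!ud) config$k else NULL,
                  eps = if (ud) config$eps else NULL,
                  min_samples = if (ud) config$min_samples else NULL,
                  n_neighbors = if (ud) config$n_neighbors else NULL,
                  winsor_quantile = config$preprocess$winsor_quantile,
                  mass_shift = config$criteria$mass_shift,
                  delta = config$criteria$delta,
                  min_corr = config$criteria$min_corr,
                  rir_B = config$rir_B),
    versions = list(ionclust = as.character(utils::packageVersion("ionclust")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    n_images = length(ds$mz_axis),
    n_meaningful_clusters = count_meaningful_clusters(result),
    rir = if (inherits(rir, "rir_result")) {
      list(F_clust = rir$F_clust, F_random_mean = rir$F_random_mean,
           R = rir$R, n_pairs = rir$n_pairs)
    } else list(error = conditionMessage(rir)),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(config$out_dir)
}

#' Write an ion image as a grayscale PNG
#'
#' Pixel values are unit-scaled before export; masked-out pixels are black.
#'
#' @param image an [ion_image_new()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "ion_image"))
  px <- scale_unit(image)$pixels
  png::writePNG(px, path)
  invisible(path)
}

#' Cluster-colored mean spectrum plot
#'
#' Renders the mean intensity per m/z channel (over all pixels) as vertical
#' stems colored by cluster assignment; the DBSCAN noise cluster is gray.
#'
#' @param dataset an [msi_dataset()].
#' @param result a [clustering_result()] aligned with the dataset channels.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
report_mean_spectrum <- function(dataset, result, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  labels <- if (inherits(result, "clustering_result")) result$labels else
    as.integer(result)
  if (length(labels) != length(dataset$mz_axis)) {
    stopf("labels not aligned with dataset channels")
  }
  means <- colMeans(dataset$intensities)
  ids <- sort(setdiff(unique(labels), -1L))
  palette <- grDevices::hcl.colors(max(length(ids), 2L), "Dark 3")
  col <- rep("gray60", length(labels))
  for (i in seq_along(ids)) col[labels == ids[i]] <- palette[i]
  grDevices::png(path, width = 900, height = 420, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NULL, xlim = range(dataset$mz_axis),
                 ylim = c(0, max(means) * 1.05), xlab = "m/z (Da)",
                 ylab = "mean intensity",
                 main = "Mean spectrum with cluster assignment")
  graphics::segments(dataset$mz_axis, 0, dataset$mz_axis, means, col = col,
                     lwd = 2)
  invisible(path)
}
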