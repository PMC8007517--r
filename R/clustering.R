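# Clustering of regular or neural ion image vectors: UMAP to 3-D (cosine
# distance) followed by DBSCAN, or k-means (Euclidean, k-means++ restarts).

#' Clustering result container
#'
#' @param labels integer vector, one label per ion image; cluster ids start
#'   at 0, DBSCAN noise is `-1`. k-means results never contain `-1`.
#' @param method `"umap_dbscan"` or `"kmeans"`.
#' @param params named list of the parameters used.
#' @param embedding3d optional n x 3 matrix of UMAP coordinates.
#' @return object of class `clustering_result`.
#' @export
clustering_result <- function(labels, method = c("umap_dbscan", "kmeans"),
                              params = list(), embedding3d = NULL) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (any(labels < -1L)) stopf("labels must be >= -1")
  if (method == "kmeans" && any(labels == -1L)) {
    stopf("k-means results cannot contain the noise label -1")
  }
  if (!is.null(embedding3d)) {
    embedding3d <- as.matrix(embedding3d)
    if (nrow(embedding3d) != length(labels) || ncol(embedding3d) != 3L) {
      stopf("embedding3d must be n x 3")
    }
  }
  structure(list(labels = labels, method = method, params = params,
                 embedding3d = embedding3d),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s: %d images, %d clusters, %d noise\n",
              x$method, length(x$labels),
              length(setdiff(unique(x$labels), -1L)), sum(x$labels == -1L)))
  invisible(x)
}

#' UMAP reduction to three dimensions
#'
#' Reduces ion-image vectors (regular images flattened row-major, or neural
#' ion images) to 3-D with cosine distance, the configuration used upstream
#' of DBSCAN. Single-threaded and seeded, so identical inputs and seed give
#' identical coordinates.
#'
#' @param vectors n x D numeric matrix.
#' @param n_components embedding dimension (default 3).
#' @param metric distance in the input space (default `"cosine"`).
#' @param n_neighbors local neighborhood size (default 15); must be `< n`.
#' @param min_dist UMAP packing parameter (default 0.1).
#' @param seed integer RNG seed.
#' @return n x `n_components` numeric matrix.
#' @export
reduce_umap <- function(vectors, n_components = 3L, metric = "cosine",
                        n_neighbors = 15L, min_dist = 0.1, seed = 42L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) <= n_neighbors) {
    stopf("UMAP stage: need more than n_neighbors = %d points, got %d",
          n_neighbors, nrow(vectors))
  }
  out <- uwot::umap(vectors, n_neighbors = n_neighbors,
                    n_components = n_components, metric = metric,
                    min_dist = min_dist, seed = as.integer(seed),
                    n_threads = 1, n_sgd_threads = 0, batch = FALSE,
                    verbose = FALSE)
  unname(as.matrix(out))
}

#' DBSCAN clustering
#'
#' Exact density-based clustering: a point is a core point when at least
#' `min_samples` points (itself included) lie within distance `eps`;
#' clusters are the connected components of core points under
#' eps-reachability, plus border points attached to the first core cluster
#' that reaches them; everything else goes to the noise cluster (`-1`).
#' Brute force over the full distance matrix, which is exact and fast for
#' the few hundred to few thousand ion images typical here.
#'
#' @param points n x d numeric matrix (here: 3-D UMAP coordinates,
#'   Euclidean distance).
#' @param eps neighborhood radius.
#' @param min_samples minimum neighborhood size for a core point.
#' @return integer labels in `{-1, 0, 1, ...}`.
#' @export
cluster_dbscan <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stopf("empty input")
  if (eps <= 0) stopf("eps must be > 0")
  if (!is_count(min_samples) || min_samples < 1) {
    stopf("min_samples must be >= 1")
  }
  d <- as.matrix(stats::dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      if (!core[p]) next
      reach <- which(nb[p, ])
      new <- reach[labels[reach] == -1L]
      labels[new] <- cl
      queue <- c(queue, new[core[new]])
    }
  }
  labels
}

# k-means++ initial centers (indices), standard D^2 sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = prob)
      nd <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

#' k-means clustering
#'
#' Lloyd iterations (Euclidean distance) from k-means++ seeding, best of
#' `n_init` seeded restarts by total within-cluster sum of squares.
#'
#' @param vectors n x D numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @param n_init number of restarts (default 10).
#' @return integer labels in `{0, ..., k-1}`.
#' @export
cluster_kmeans <- function(vectors, k, seed = 42L, n_init = 10L) {
  x <- as.matrix(vectors)
  n <- nrow(x)
  if (!is_count(k) || k < 1 || k > n) {
    stopf("k must satisfy 1 <= k <= n = %d", n)
  }
  if (k == 1L) return(rep(0L, n))
  with_seed(seed, {
    best <- NULL
    for (rep_i in seq_len(n_init)) {
      init <- x[kmeanspp_centers(x, k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       algorithm = "Lloyd", iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stopf("k-means failed on all restarts")
    as.integer(best$cluster) - 1L
  })
}

#' Full UMAP-DBSCAN pipeline over a vector matrix
#'
#' @param vectors n x D matrix.
#' @param eps,min_samples DBSCAN parameters (on the 3-D coordinates,
#'   Euclidean).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer RNG seed.
#' @return a [clustering_result()] with `embedding3d` filled in.
#' @export
cluster_umap_dbscan <- function(vectors, eps = 0.5, min_samples = 5L,
                                n_neighbors = 15L, min_dist = 0.1,
                                seed = 42L) {
  emb <- reduce_umap(vectors, n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed)
  labels <- cluster_dbscan(emb, eps = eps, min_samples = min_samples)
  clustering_result(labels, "umap_dbscan",
                    params = list(eps = eps, min_samples = min_samples,
                                  n_neighbors = n_neighbors,
                                  min_dist = min_dist, seed = seed),
                    embedding3d = emb)
}

#' Count meaningful clusters
#'
#' Meaningful clusters exclude the DBSCAN noise cluster and clusters that
#' contain a single image.
#'
#' @param result a [clustering_result()] or bare label vector.
#' @return integer count.
#' @export
count_meaningful_clusters <- function(result) {
  labels <- if (inherits(result, "clustering_result")) result$labels else
    as.integer(result)
  tab <- table(labels[labels != -1L])
  sum(tab >= 2L)
}

#' Mean ion image of one cluster
#'
#' Pixelwise arithmetic mean of the cluster's member images after
#' winsorizing and unit-scaling each member (stratified averaging of
#' standardized images).
#'
#' @param images list of [ion_image_new()] aligned with `labels`.
#' @param labels integer labels.
#' @param cluster_id cluster to average; must be present in `labels`.
#' @param winsor_quantile winsorization quantile.
#' @return an `ion_image` (mz `NA`).
#' @export
mean_cluster_image <- function(images, labels, cluster_id,
                               winsor_quantile = 0.95) {
  members <- which(labels == cluster_id)
  if (length(members) == 0L) stopf("cluster %s is empty", cluster_id)
  std <- lapply(images[members], standardize_image, q = winsor_quantile)
  acc <- Reduce(`+`, lapply(std, `[[`, "pixels")) / length(std)
  mask <- std[[1]]$mask
  acc[!mask] <- 0
  ion_image_new(acc, mz = NA_real_,
                pixel_size_um = std[[1]]$pixel_size_um, mask = mask)
}

#' Adjusted Rand Index between two labelings
#'
#' @param a,b equal-length label vectors (any label coding).
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
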