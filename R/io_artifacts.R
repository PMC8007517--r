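# Tabular and HDF5 artifacts of the pipeline: cluster assignments (CSV) and
# neural-ion-image vector bundles (HDF5 keyed arrays).

#' Write cluster assignments to CSV
#'
#' One row per ion image, header `mz,cluster`; the DBSCAN noise cluster is
#' written as the literal `-1`.
#'
#' @param result a [clustering_result()] or a bare integer label vector.
#' @param mzs m/z values aligned with the labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(result, mzs, path) {
  labels <- if (inherits(result, "clustering_result")) result$labels else
    as.integer(result)
  if (length(labels) != length(mzs)) stopf("mzs/labels length mismatch")
  utils::write.csv(data.frame(mz = mzs, cluster = labels), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cluster assignments written by [write_assignments()]
#'
#' @param path CSV path with header `mz,cluster`.
#' @return list with `mzs` (numeric) and `labels` (integer, noise = -1).
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(colnames(df), c("mz", "cluster"))) {
    stopf("assignments format error: header must be 'mz,cluster'")
  }
  if (anyDuplicated(df$mz)) stopf("assignments format error: duplicate m/z rows")
  list(mzs = as.numeric(df$mz), labels = as.integer(df$cluster))
}

#' Neural ion image
#'
#' A fixed-length embedding vector standing in for one ion image, together
#' with its m/z and the embedder / patch-grid provenance.
#'
#' @param vector finite numeric vector (length = embedder dim).
#' @param mz m/z of the source channel (Da).
#' @param provenance character string describing embedder and patch grid.
#' @return object of class `neural_ion_image`.
#' @export
neural_ion_image <- function(vector, mz = NA_real_, provenance = "") {
  vector <- as.numeric(vector)
  if (length(vector) == 0L || any(!is.finite(vector))) {
    stopf("embedding vector must be non-empty and finite")
  }
  structure(list(vector = vector, mz = as.numeric(mz),
                 provenance = as.character(provenance)),
            class = "neural_ion_image")
}

#' Write neural ion image vectors to an HDF5 bundle
#'
#' Stores the keyed arrays `vectors` (n_images x D), `mz` (length n_images),
#' and `provenance` (strings). Round-trips are bit exact (float64 storage).
#'
#' @param nii list of [neural_ion_image()] objects, or a bundle as returned
#'   by [read_vectors()].
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_vectors <- function(nii, path) {
  if (inherits(nii, "nii_bundle")) {
    mat <- nii$vectors; mz <- nii$mz; prov <- nii$provenance
  } else {
    if (length(nii) == 0L) stopf("no vectors to write")
    lens <- vapply(nii, function(v) length(v$vector), integer(1))
    if (length(unique(lens)) != 1L) stopf("ragged vectors")
    mat <- do.call(rbind, lapply(nii, `[[`, "vector"))
    mz <- vapply(nii, `[[`, numeric(1), "mz")
    prov <- unique(vapply(nii, `[[`, character(1), "provenance"))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(mat, path, "vectors")
  rhdf5::h5write(mz, path, "mz")
  rhdf5::h5write(as.character(prov), path, "provenance")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a vectors bundle written by [write_vectors()]
#'
#' @param path `.h5` path.
#' @return object of class `nii_bundle`: list with `vectors` (n x D matrix),
#'   `mz`, `provenance`.
#' @export
read_vectors <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  keys <- rhdf5::h5ls(path)$name
  for (k in c("vectors", "mz")) {
    if (!k %in% keys) stopf("vectors bundle format error: missing '%s'", k)
  }
  out <- structure(
    list(vectors = as.matrix(rhdf5::h5read(path, "vectors")),
         mz = as.numeric(rhdf5::h5read(path, "mz")),
         provenance = if ("provenance" %in% keys)
           as.character(rhdf5::h5read(path, "provenance")) else character(0)),
    class = "nii_bundle")
  rhdf5::h5closeAll()
  if (nrow(out$vectors) != length(out$mz)) {
    stopf("vectors bundle format error: mz length != vector rows")
  }
  out
}

#' Write a Relative Isotope Ratio report to CSV
#'
#' @param rir an `rir_result` from [rir_evaluate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rir_report <- function(rir, path) {
  stopifnot(inherits(rir, "rir_result"))
  utils::write.csv(
    data.frame(F_clust = rir$F_clust, F_random_mean = rir$F_random_mean,
               F_random_sd = rir$F_random_sd, B = rir$B, R = rir$R,
               n_pairs = rir$n_pairs),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
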