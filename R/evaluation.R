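# Clustering evaluation: isotope-pair detection (+1.003 Da, spatially
# correlated), isotope fraction F, bootstrap random baseline, Relative
# Isotope Ratio R = F_clust / F_random, and the expert-score ranking
# benchmark.

#' Isotope detection criteria
#'
#' Two m/z channels form an isotope pair iff their mass difference is
#' `mass_shift` within `delta`, and the Pearson correlation of their ion
#' images is at least `min_corr`.
#'
#' @param mass_shift expected spacing in Da; 1.003 targets carbon isotopes.
#' @param delta mass tolerance in Da; use about 0.01 for centroided
#'   high-mass-accuracy data and 0.1 for profile data.
#' @param min_corr minimum Pearson correlation between the two ion images.
#' @return object of class `isotope_criteria`.
#' @export
isotope_criteria <- function(mass_shift = 1.003, delta = 0.01,
                             min_corr = 0.85) {
  if (delta < 0) stopf("delta must be >= 0")
  if (min_corr < -1 || min_corr > 1) stopf("min_corr must be in [-1,1]")
  structure(list(mass_shift = mass_shift, delta = delta,
                 min_corr = min_corr),
            class = "isotope_criteria")
}

#' Pearson correlation of two ion images
#'
#' Computed over the jointly acquired (masked-in) pixels. If either image is
#' constant over that region the correlation is undefined and `NA` is
#' returned (treated downstream as failing any correlation threshold).
#'
#' @param a,b [ion_image_new()] objects with identical shape and mask.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_corr <- function(a, b) {
  stopifnot(inherits(a, "ion_image"), inherits(b, "ion_image"))
  if (!identical(dim(a$pixels), dim(b$pixels))) stopf("shape mismatch")
  m <- a$mask & b$mask
  x <- a$pixels[m]; y <- b$pixels[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Detect isotope pairs among the channels of a dataset
#'
#' All unordered channel pairs (i, j), i < j, with
#' `|mz_j - mz_i - mass_shift| <= delta` and image correlation
#' `>= min_corr`.
#'
#' @param mzs sorted ascending m/z vector.
#' @param images list of [ion_image_new()] aligned with `mzs`.
#' @param criteria an [isotope_criteria()].
#' @return data frame with columns `i`, `j` (1-based channel indices),
#'   `mz_i`, `mz_j`, `corr`.
#' @export
find_isotope_pairs <- function(mzs, images, criteria = isotope_criteria()) {
  if (length(mzs) != length(images)) stopf("mzs/images length mismatch")
  if (is.unsorted(mzs, strictly = FALSE)) stopf("mzs must be sorted ascending")
  out <- list()
  for (i in seq_along(mzs)) {
    lo <- mzs[i] + criteria$mass_shift - criteria$delta
    hi <- mzs[i] + criteria$mass_shift + criteria$delta
    js <- which(mzs >= lo & mzs <= hi)
    js <- js[js > i]
    for (j in js) {
      r <- pearson_corr(images[[i]], images[[j]])
      if (!is.na(r) && r >= criteria$min_corr) {
        out[[length(out) + 1L]] <-
          data.frame(i = i, j = j, mz_i = mzs[i], mz_j = mzs[j], corr = r)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), mz_i = numeric(0),
                      mz_j = numeric(0), corr = numeric(0)))
  }
  do.call(rbind, out)
}

#' Fraction of isotope pairs grouped by a clustering
#'
#' A pair counts as grouped when both members carry the same label and that
#' label is not the noise cluster (`-1`).
#'
#' @param pairs data frame with columns `i`, `j` ([find_isotope_pairs()]).
#' @param labels integer labels aligned with the channel indices.
#' @return fraction F in `[0, 1]`.
#' @export
isotope_fraction <- function(pairs, labels) {
  if (nrow(pairs) == 0L) stopf("isotope fraction undefined: zero pairs")
  li <- labels[pairs$i]; lj <- labels[pairs$j]
  mean(li == lj & li != -1L)
}

#' Bootstrap baseline isotope fraction under random relabeling
#'
#' Simulates the isotope fraction of a random clustering with the same
#' cluster sizes: each replicate is a uniform random permutation of the
#' label vector (the noise block is preserved as one more size-fixed group).
#'
#' @param labels integer label vector (noise = -1).
#' @param pairs isotope pair data frame.
#' @param B number of bootstrap replicates, `>= 1`.
#' @param seed integer RNG seed.
#' @return list with `mean`, `sd`, and the per-replicate `fractions`.
#' @export
random_baseline_fraction <- function(labels, pairs, B = 1000L, seed = 42L) {
  if (!is_count(B) || B < 1) stopf("B must be >= 1")
  if (nrow(pairs) == 0L) stopf("zero isotope pairs")
  fr <- with_seed(seed, vapply(seq_len(B), function(b) {
    isotope_fraction(pairs, sample(labels))
  }, numeric(1)))
  list(mean = mean(fr), sd = stats::sd(fr), fractions = fr)
}

#' Relative Isotope Ratio
#'
#' `R = F_clust / F_random`; values well above 1 indicate the clustering
#' groups isotope pairs far better than a size-matched random relabeling.
#'
#' @param F_clust observed isotope fraction.
#' @param F_random_mean bootstrap mean baseline fraction.
#' @return R `>= 0`; `Inf` (with a warning) when the baseline is 0 but the
#'   clustering fraction is positive; an error for the undefined 0/0 case.
#' @export
relative_isotope_ratio <- function(F_clust, F_random_mean) {
  if (F_random_mean < 0) stopf("F_random_mean must be >= 0")
  if (F_random_mean == 0) {
    if (F_clust == 0) stopf("relative isotope ratio undefined (0/0)")
    warning("zero random baseline; relative isotope ratio is infinite")
    return(Inf)
  }
  F_clust / F_random_mean
}

#' Full Relative Isotope Ratio evaluation of a clustering
#'
#' @param mzs sorted m/z vector.
#' @param images aligned preprocessed ion images (used for pair detection).
#' @param labels clustering labels aligned with `mzs`, or a
#'   [clustering_result()].
#' @param criteria an [isotope_criteria()].
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param pairs optional precomputed pair table (skips detection).
#' @return object of class `rir_result`: `F_clust`, `F_random_mean`,
#'   `F_random_sd`, `B`, `R`, `n_pairs`, `pairs`.
#' @export
rir_evaluate <- function(mzs, images, labels,
                         criteria = isotope_criteria(), B = 1000L,
                         seed = 42L, pairs = NULL) {
  if (inherits(labels, "clustering_result")) labels <- labels$labels
  if (is.null(pairs)) pairs <- find_isotope_pairs(mzs, images, criteria)
  if (nrow(pairs) == 0L) stopf("no isotope pairs detected; RIR undefined")
  F_clust <- isotope_fraction(pairs, labels)
  base <- random_baseline_fraction(labels, pairs, B = B, seed = seed)
  R <- relative_isotope_ratio(F_clust, base$mean)
  structure(list(F_clust = F_clust, F_random_mean = base$mean,
                 F_random_sd = base$sd, B = as.integer(B), R = R,
                 n_pairs = nrow(pairs), pairs = pairs),
            class = "rir_result")
}

#' @export
print.rir_result <- function(x, ...) {
  cat(sprintf(
    "<rir_result> F_clust %.3f / F_random %.3f (sd %.3f, B=%d) -> R = %.2f over %d pairs\n",
    x$F_clust, x$F_random_mean, x$F_random_sd, x$B, x$R, x$n_pairs))
  invisible(x)
}

#' Cosine similarity of two vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `dot(u, v) / (|u| |v|)` in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Segment-wise expert-score ranking benchmark
#'
#' For each target set and expert-score cutoff c: the ground-truth set
#' S_truth contains the candidates with expert score <= c (N = |S_truth|);
#' S_rank contains the N candidates with the highest similarity (ties broken
#' by ascending candidate index); hits = |S_truth intersect S_rank|. Hits
#' and N are pooled across target sets per cutoff; sets with N = 0 at a
#' cutoff are skipped.
#'
#' @param sets list of target sets; each element is a list with numeric
#'   `similarity` and `expert` vectors aligned over that set's candidates.
#' @param cutoffs numeric vector of expert-score cutoffs.
#' @return data frame with columns `cutoff`, `N`, `hits`, `fraction`; a
#'   cutoff at which every set is empty yields an `NA` fraction.
#' @export
ranking_benchmark <- function(sets, cutoffs) {
  for (s in sets) {
    if (length(s$similarity) != length(s$expert)) {
      stopf("similarity/expert length mismatch in a target set")
    }
  }
  rows <- lapply(cutoffs, function(cc) {
    tot_n <- 0L; tot_hits <- 0L
    for (s in sets) {
      truth <- which(s$expert <= cc)
      n <- length(truth)
      if (n == 0L) next
      top <- order(-s$similarity, seq_along(s$similarity))[seq_len(n)]
      tot_n <- tot_n + n
      tot_hits <- tot_hits + length(intersect(truth, top))
    }
    data.frame(cutoff = cc, N = tot_n, hits = tot_hits,
               fraction = if (tot_n > 0) tot_hits / tot_n else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read an expert similarity score table
#'
#' Delimited text with header `set_id,candidate_mz,score`: one row per
#' (target set, candidate) pair, score 0 (identical) to 10 (nothing alike).
#'
#' @param path CSV path.
#' @return data frame with those three columns.
#' @export
read_expert_scores <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("set_id", "candidate_mz", "score")
  if (!all(need %in% colnames(df))) {
    stopf("expert score table must have columns %s",
          paste(need, collapse = ","))
  }
  df[need]
}
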