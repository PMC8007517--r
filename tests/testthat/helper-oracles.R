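# Independent oracles: deliberately naive implementations, kept separate
# from the code paths they check.

# running median with replicate edge padding, by direct window enumeration
oracle_running_median <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) median(padded[i:(i + w - 1)]), numeric(1))
}

# linear-interpolation quantile from first principles (sorted order stats)
oracle_quantile <- function(v, q) {
  s <- sort(v)
  h <- (length(s) - 1) * q
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# DBSCAN by literal density reachability: core points, eps-graph components
# among cores, then border attachment. Returns -1 for noise, clusters 0..
oracle_dbscan <- function(points, eps, minpts) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  core <- sapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= minpts)
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == -1L &
                      apply(d[, comp, drop = FALSE] <= eps, 1, any))
      grow <- setdiff(grow, comp)
      if (length(grow) == 0L) break
      labels[grow] <- cl
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  for (i in which(!core & labels == -1L)) {
    cores_near <- which(core & d[i, ] <= eps)
    if (length(cores_near) > 0L) labels[i] <- labels[min(cores_near)]
  }
  labels
}

# exhaustive best 2-partition by within-cluster sum of squares (n <= 12);
# point 1 is fixed in group 0 to halve the enumeration
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    ss <- 0
    for (grp in 0:1) {
      sub <- x[g == grp, , drop = FALSE]
      ctr <- colMeans(sub)
      ss <- ss + sum(sweep(sub, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- g }
  }
  list(labels = best, ss = best_ss)
}

# silhouette of a labeling from the standard formula
oracle_silhouette <- function(points, labels) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (length(own) == 0) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exact expected isotope fraction over all uniform label permutations
oracle_exact_perm_mean_F <- function(labels, pairs) {
  perms <- all_perms(length(labels))
  mean(apply(perms, 1, function(p) {
    l <- labels[p]
    mean(l[pairs$i] == l[pairs$j] & l[pairs$i] != -1L)
  }))
}

# independent bilinear resampler, half-pixel centers, explicit loops
oracle_bilinear <- function(x, out_r, out_c) {
  in_r <- nrow(x); in_c <- ncol(x)
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      sy <- min(max((i - 0.5) * in_r / out_r - 0.5, 0), in_r - 1)
      sx <- min(max((j - 0.5) * in_c / out_c - 0.5, 0), in_c - 1)
      y0 <- min(floor(sy), in_r - 1); y1 <- min(y0 + 1, in_r - 1)
      x0 <- min(floor(sx), in_c - 1); x1 <- min(x0 + 1, in_c - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * x[y0 + 1, x0 + 1] +
                                 fx * x[y0 + 1, x1 + 1]) +
                   fy * ((1 - fx) * x[y1 + 1, x0 + 1] +
                           fx * x[y1 + 1, x1 + 1])
    }
  }
  out
}

# pair-counting adjusted Rand index from its definitional form
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  idx <- n11
  exp_idx <- (n11 + n10) * (n11 + n01) / choose(n, 2)
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)  # degenerate: both partitions trivial
  (idx - exp_idx) / (max_idx - exp_idx)
}
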