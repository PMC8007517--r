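test_that("pearson_corr over masked pixels matches the covariance formula", {
  a <- img(matrix(c(1, 2, 3, 4), 2, 2))
  b <- img(matrix(c(1, 2, 3, 5), 2, 2))
  expect_equal(pearson_corr(a, b), 0.9827, tolerance = 1e-4)
  set.seed(2)
  x <- img(matrix(runif(16), 4, 4))
  expect_equal(pearson_corr(x, x), 1)
  neg <- img(matrix(max(x$pixels) - x$pixels, 4, 4))
  expect_equal(pearson_corr(x, neg), -1)
  expect_true(is.na(pearson_corr(x, img(matrix(3, 4, 4)))))
  expect_error(pearson_corr(x, img(matrix(1, 2, 2))), "shape")
})

test_that("find_isotope_pairs applies the mass-shift and correlation criteria", {
  set.seed(6)
  base <- img(matrix(runif(64), 8, 8))
  crit <- isotope_criteria(delta = 0.01)
  # exact +1.003 shift, identical images -> one pair
  p1 <- find_isotope_pairs(c(700.000, 701.003), list(base, base), crit)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$corr, 1)
  # shift outside tolerance -> none
  expect_equal(nrow(find_isotope_pairs(c(700.000, 701.050),
                                       list(base, base), crit)), 0L)
  # chain: (1,2) and (2,3) qualify, (1,3) differs by 2.006
  p3 <- find_isotope_pairs(c(700.000, 701.003, 702.006),
                           list(base, base, base), crit)
  expect_equal(nrow(p3), 2L)
  expect_equal(p3$i, c(1L, 2L)); expect_equal(p3$j, c(2L, 3L))
  # low-correlation companion rejected
  other <- img(matrix(runif(64), 8, 8))
  expect_equal(nrow(find_isotope_pairs(c(700.000, 701.003),
                                       list(base, other), crit)), 0L)
  expect_error(find_isotope_pairs(c(1, 2), list(base), crit), "length")
})

test_that("isotope_fraction counts co-clustered pairs, noise never groups", {
  pairs <- data.frame(i = c(1L, 3L), j = c(2L, 4L))
  expect_equal(isotope_fraction(pairs, c(0L, 0L, 0L, 0L)), 1)
  expect_equal(isotope_fraction(pairs, c(0L, 0L, 1L, 2L)), 0.5)
  expect_equal(isotope_fraction(pairs, c(-1L, -1L, 1L, 1L)), 0.5)
  expect_error(isotope_fraction(pairs[0, ], c(0L, 0L)), "zero pairs")
})

test_that("bootstrap baseline matches the exhaustive permutation oracle", {
  pairs <- data.frame(i = 1L, j = 2L)
  labels <- c(0L, 0L, 1L, 1L)
  exact <- oracle_exact_perm_mean_F(labels, pairs)
  expect_equal(exact, 1 / 3)
  bs <- random_baseline_fraction(labels, pairs, B = 10000, seed = 5)
  expect_lt(abs(bs$mean - exact), 0.02)
  # a single all-covering cluster keeps every pair together
  one <- random_baseline_fraction(rep(0L, 4), pairs, B = 50, seed = 1)
  expect_equal(one$mean, 1); expect_equal(one$sd, 0)
  expect_error(random_baseline_fraction(labels, pairs, B = 0), "B must be")
  # richer instance with noise block, against the oracle
  labels2 <- c(0L, 0L, 1L, 1L, 1L, -1L, -1L)
  pairs2 <- data.frame(i = c(1L, 3L, 6L), j = c(2L, 4L, 7L))
  exact2 <- oracle_exact_perm_mean_F(labels2, pairs2)
  bs2 <- random_baseline_fraction(labels2, pairs2, B = 10000, seed = 5)
  expect_lt(abs(bs2$mean - exact2), 0.02)
})

test_that("relative_isotope_ratio handles the stated edge cases", {
  expect_equal(relative_isotope_ratio(1, 1), 1)
  expect_equal(relative_isotope_ratio(1, 1 / 3), 3)
  expect_equal(relative_isotope_ratio(0, 0.4), 0)
  expect_warning(r <- relative_isotope_ratio(0.5, 0), "infinite")
  expect_equal(r, Inf)
  expect_error(relative_isotope_ratio(0, 0), "undefined")
})

test_that("rir_evaluate composes F, baseline and R on the sizes-[2,2] instance", {
  set.seed(10)
  im <- img(matrix(runif(36), 6, 6))
  imgs <- list(im, im, img(matrix(runif(36), 6, 6)),
               img(matrix(runif(36), 6, 6)))
  mzs <- c(700, 701.003, 705, 706.5)
  r <- rir_evaluate(mzs, imgs, c(0L, 0L, 1L, 1L), B = 10000, seed = 3)
  expect_equal(r$n_pairs, 1L)
  expect_equal(r$F_clust, 1)
  expect_equal(r$F_random_mean, 1 / 3, tolerance = 0.06)
  expect_equal(r$R, 3, tolerance = 0.2)
})

test_that("cosine_similarity basics", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("ranking_benchmark pools hits across sets with deterministic ties", {
  # perfect proxy: similarity = -score -> fraction 1 at every cutoff
  sets <- list(list(similarity = -c(0.5, 2, 4, 7), expert = c(0.5, 2, 4, 7)),
               list(similarity = -c(1, 3, 9), expert = c(1, 3, 9)))
  res <- ranking_benchmark(sets, c(1, 3, 5, 10))
  expect_equal(res$fraction, rep(1, 4))
  # hand-enumerated case: truth {1,2}, top-2 by similarity {2,4} -> 1 hit
  s2 <- list(list(similarity = c(5, 9, 1, 8, 2),
                  expert = c(0.5, 0.9, 1.5, 3, 4)))
  r2 <- ranking_benchmark(s2, 1.0)
  expect_equal(r2$N, 2L); expect_equal(r2$hits, 1L)
  expect_equal(r2$fraction, 0.5)
  # cutoff below all scores: segment skipped (NA fraction, N 0)
  r3 <- ranking_benchmark(s2, 0.1)
  expect_equal(r3$N, 0L); expect_true(is.na(r3$fraction))
  # invariance under strictly monotone transforms of similarity
  mono <- function(x) exp(3 * x) + 5
  s3 <- list(list(similarity = mono(c(5, 9, 1, 8, 2)),
                  expert = c(0.5, 0.9, 1.5, 3, 4)))
  expect_equal(ranking_benchmark(s3, c(1, 3, 4))$fraction,
               ranking_benchmark(s2, c(1, 3, 4))$fraction)
  expect_error(ranking_benchmark(list(list(similarity = 1:2, expert = 1:3)),
                                 1), "length mismatch")
})

test_that("expert score tables read back with required columns", {
  d <- withr::local_tempdir()
  p <- file.path(d, "scores.csv")
  writeLines(c("set_id,candidate_mz,score", "s1,700.1,2.5", "s1,701.2,0.5"), p)
  df <- read_expert_scores(p)
  expect_equal(nrow(df), 2L)
  expect_equal(df$score, c(2.5, 0.5))
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_expert_scores(p), "columns")
})
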