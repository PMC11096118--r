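test_that("the cluster-forming threshold comes from the t quantile", {
  expect_equal(t_threshold(0.05, 12), qt(0.975, 12))
  expect_equal(t_threshold(0.05, 12, truncate = TRUE), 2.17)
  # normal limit at huge df
  expect_equal(t_threshold(0.05, 1e6), 1.96, tolerance = 1e-3)
  # independent check: invert the t CDF by bisection
  bisect <- function(alpha, df) {
    lo <- 0; hi <- 100
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pt(mid, df) < 1 - alpha / 2) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(t_threshold(0.05, 5), bisect(0.05, 5), tolerance = 1e-9)
  expect_error(t_threshold(1.5, 10), "alpha")
  expect_error(t_threshold(0.05, 0), "df")
})

test_that("all-zero contrasts produce no clusters", {
  maps <- replicate(6, rep(0, 40), simplify = FALSE)
  res <- one_sample_cluster_perm(maps, n_perm = 64, seed = 1L)
  expect_identical(nrow(res$clusters), 0L)
})

test_that("a constant strong offset yields one spanning cluster at min p", {
  set.seed(2)
  maps <- lapply(1:8, function(i) rnorm(30, mean = 0) + 10)
  res <- one_sample_cluster_perm(maps, n_perm = 1024, seed = 3L)
  expect_true(res$exact)           # 2^8 = 256 <= 1024
  expect_identical(nrow(res$clusters), 1L)
  expect_identical(res$clusters$n_cells, 30L)
  expect_identical(res$clusters$sign, "positive")
  # smallest attainable p under the +1 convention with 256 patterns:
  # only the two all-equal sign patterns reach the observed max mass
  expect_lte(res$clusters$p, (1 + 2) / (1 + 256))
})

test_that("exact one-sample p-values equal the enumeration oracle", {
  set.seed(5)
  maps <- lapply(1:8, function(i) rnorm(25) + 0.9)
  thr <- t_threshold(0.05, 7)
  res <- one_sample_cluster_perm(maps, threshold = thr, n_perm = 256,
                                 seed = 1L)
  oracle <- oracle_one_sample_cluster(maps, thr)
  expect_identical(nrow(res$clusters), length(oracle))
  o_mass <- sort(vapply(oracle, `[[`, numeric(1), "mass"))
  o_p <- vapply(oracle, `[[`, numeric(1), "p")[
    order(vapply(oracle, `[[`, numeric(1), "mass"))]
  ord <- order(res$clusters$mass)
  expect_equal(res$clusters$mass[ord], o_mass, tolerance = 1e-10)
  expect_equal(res$clusters$p[ord], o_p, tolerance = 1e-12)
})

test_that("random sign flips approximate the exact p-values", {
  set.seed(6)
  maps <- lapply(1:8, function(i) rnorm(25) + 0.75)
  thr <- t_threshold(0.05, 7)
  exact <- one_sample_cluster_perm(maps, threshold = thr, n_perm = 256,
                                   seed = 1L)
  rand <- one_sample_cluster_perm(maps, threshold = thr, n_perm = 10000,
                                  seed = 2L, enumerate = FALSE)
  expect_false(rand$exact)
  expect_identical(nrow(rand$clusters), nrow(exact$clusters))
  expect_lt(max(abs(rand$clusters$p - exact$clusters$p)), 0.02)
})

test_that("identical groups give no two-sample clusters", {
  set.seed(8)
  shared <- lapply(1:5, function(i) rnorm(40))
  res <- two_sample_cluster_perm(shared, shared, n_perm = 128, seed = 1L)
  expect_true(all(abs(res$t_map) < 1e-9))
  expect_identical(nrow(res$clusters), 0L)
})

test_that("two-sample p-values match the exhaustive partition oracle", {
  set.seed(9)
  maps_a <- lapply(1:4, function(i) rnorm(20) + 1.6)
  maps_b <- lapply(1:4, function(i) rnorm(20))
  thr <- t_threshold(0.05, 3)
  res <- two_sample_cluster_perm(maps_a, maps_b, threshold = thr,
                                 n_perm = 128, seed = 1L)
  expect_true(res$exact)           # C(8,4) = 70 <= 128
  oracle <- oracle_two_sample_cluster(maps_a, maps_b, thr)
  expect_identical(nrow(res$clusters), length(oracle))
  ord <- order(res$clusters$mass)
  o_ord <- order(vapply(oracle, `[[`, numeric(1), "mass"))
  expect_equal(res$clusters$mass[ord],
               vapply(oracle, `[[`, numeric(1), "mass")[o_ord],
               tolerance = 1e-10)
  expect_equal(res$clusters$p[ord],
               vapply(oracle, `[[`, numeric(1), "p")[o_ord],
               tolerance = 1e-12)
  # random label shuffles approximate the exact answer
  rand <- two_sample_cluster_perm(maps_a, maps_b, threshold = thr,
                                  n_perm = 8000, seed = 4L,
                                  enumerate = FALSE)
  expect_lt(max(abs(rand$clusters$p - res$clusters$p)), 0.02)
})

test_that("exact p-values are invariant to participant order and seed", {
  set.seed(10)
  maps <- lapply(1:7, function(i) rnorm(30) + 0.8)
  r1 <- one_sample_cluster_perm(maps, n_perm = 256, seed = 1L)
  r2 <- one_sample_cluster_perm(maps[sample(7)], n_perm = 256, seed = 99L)
  expect_equal(r1$clusters$p, r2$clusters$p)
  expect_equal(r1$clusters$mass, r2$clusters$mass, tolerance = 1e-10)
})

test_that("p-values are always positive and effects only sharpen them", {
  set.seed(11)
  base <- lapply(1:6, function(i) rnorm(30))
  thr <- 1.5
  p_min <- function(shift) {
    maps <- lapply(base, function(m) m + shift)
    res <- one_sample_cluster_perm(maps, threshold = thr, n_perm = 64,
                                   seed = 1L)
    if (nrow(res$clusters) == 0) 1 else min(res$clusters$p)
  }
  ps <- vapply(c(0, 0.5, 1, 2, 4), p_min, numeric(1))
  expect_true(all(ps > 0))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("2-D clusters follow 4-connectivity", {
  # two blobs touching only diagonally must remain separate clusters
  pattern <- matrix(0, 5, 8)
  pattern[1:2, 1:2] <- 1
  pattern[3:4, 3:4] <- 1   # touches the first blob at a corner only
  set.seed(12)
  # identical blob effect with small per-participant gain; cells outside
  # the blobs are exactly zero so only the blobs go suprathreshold
  maps <- lapply(1:6, function(i) pattern * (5 + rnorm(1, sd = 0.2)))
  res <- one_sample_cluster_perm(maps, threshold = 3, n_perm = 64, seed = 1L)
  expect_identical(nrow(res$clusters), 2L)
  expect_setequal(res$clusters$n_cells, c(4L, 4L))
  got <- lapply(res$cells, sort)
  want <- list(sort(which(as.vector(pattern[, ] == 1) &
                            rep(1:8, each = 5) <= 2)),
               sort(which(as.vector(pattern) == 1 &
                            rep(1:8, each = 5) >= 3)))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("excluded cells never enter clusters", {
  set.seed(13)
  maps <- lapply(1:6, function(i) rnorm(20) + 3)
  excl <- rep(FALSE, 20); excl[1:5] <- TRUE
  res <- one_sample_cluster_perm(maps, threshold = 2, n_perm = 64,
                                 seed = 1L, exclude = excl)
  expect_true(all(unlist(res$cells) > 5))
})

test_that("domain mismatches are rejected", {
  maps <- lapply(1:4, function(i) rnorm(10))
  bad <- c(maps, list(rnorm(11)))
  expect_error(one_sample_cluster_perm(bad), "same domain")
  expect_error(two_sample_cluster_perm(maps, lapply(1:4, function(i)
    rnorm(12))), "share the domain")
})
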