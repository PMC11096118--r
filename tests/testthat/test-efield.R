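test_that("evoked averaging matches a naive loop", {
  set.seed(42)
  arr <- array(rnorm(50 * 5 * 30), dim = c(50, 5, 30))
  ep <- make_epochs(arr)
  ev <- evoked(ep)
  manual <- matrix(0, 5, 30)
  for (tr in 1:50) manual <- manual + arr[tr, , ]
  manual <- manual / 50
  expect_lt(max(abs(ev$data - manual)), 1e-12)

  # single trial: identity
  one <- make_epochs(arr[1, , , drop = FALSE])
  expect_equal(evoked(one)$data, arr[1, , ])
  # two opposite trials cancel
  two <- make_epochs(array(c(arr[1, , ], -arr[1, , ]), dim = c(2, 5, 30)))
  arr2 <- array(0, dim = c(2, 5, 30)); arr2[1, , ] <- arr[1, , ]
  arr2[2, , ] <- -arr[1, , ]
  expect_lt(max(abs(evoked(make_epochs(arr2))$data)), 1e-12)
})

test_that("paired contrasts subtract elementwise with shape checks", {
  set.seed(7)
  a <- make_evoked(matrix(rnorm(5 * 20), 5, 20))
  b <- make_evoked(matrix(rnorm(5 * 20), 5, 20))
  d <- paired_contrast(a, b)
  expect_equal(d$data, a$data - b$data)
  zero <- paired_contrast(a, a)
  expect_true(all(zero$data == 0))
  null_map <- make_evoked(matrix(0, 5, 20))
  expect_equal(paired_contrast(a, null_map)$data, a$data)
  short <- make_evoked(matrix(rnorm(5 * 10), 5, 10))
  expect_error(paired_contrast(a, short), "share")
})

test_that("GFP equals the naive per-sample standard deviation", {
  set.seed(3)
  mat <- matrix(rnorm(62 * 40), 62, 40)
  g <- gfp(make_evoked(mat))
  expect_lt(max(abs(g$gfp - oracle_gfp(mat))), 1e-12)
  # spatially uniform map: zero field power
  expect_true(all(gfp(make_evoked(matrix(3, 10, 5)))$gfp == 0))
  # homogeneity
  g2 <- gfp(make_evoked(-2.5 * mat))
  expect_equal(g2$gfp, 2.5 * g$gfp)
  expect_error(gfp(make_evoked(matrix(1, 1, 5))), "two channels")
})

test_that("GFP of the contrast of identical evokeds is identically zero", {
  set.seed(8)
  a <- make_evoked(matrix(rnorm(12 * 25), 12, 25))
  expect_true(all(gfp(paired_contrast(a, a))$gfp == 0))
})

test_that("GMD matches its formula and analytic extremes", {
  set.seed(9)
  a_mat <- matrix(rnorm(62 * 30), 62, 30)
  b_mat <- matrix(rnorm(62 * 30), 62, 30)
  a <- make_evoked(a_mat); b <- make_evoked(b_mat)
  g <- gmd(a, b)
  expect_lt(max(abs(g$gmd - oracle_gmd(a_mat, b_mat))), 1e-12)
  # proportional maps are identical after strength normalization
  prop <- gmd(a, make_evoked(3.7 * a_mat))
  expect_lt(max(prop$gmd), 1e-12)
  # antipodal maps reach the analytic maximum of 2
  anti <- gmd(a, make_evoked(-a_mat))
  expect_equal(anti$gmd, rep(2, 30))
  # symmetry
  expect_equal(gmd(a, b)$gmd, gmd(b, a)$gmd)
  # scale invariance in either argument
  expect_equal(gmd(make_evoked(0.2 * a_mat), b)$gmd, g$gmd)
})

test_that("zero-GFP samples are flagged as undefined, not zero", {
  a_mat <- matrix(rnorm(6 * 4), 6, 4)
  a_mat[, 2] <- 5  # uniform column: zero GFP after average reference
  b_mat <- matrix(rnorm(6 * 4), 6, 4)
  expect_warning(g <- gmd(make_evoked(a_mat), make_evoked(b_mat)),
                 "zero GFP")
  expect_true(is.na(g$gmd[2]))
  expect_false(anyNA(g$gmd[-2]))
})

test_that("Morlet amplitude is linear in signal amplitude", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  base <- sin(2 * pi * 10 * t)
  amps <- c(1, 2, 5)
  peak <- vapply(amps, function(A) {
    ev <- make_evoked(rbind(A * base, A * base), fs = fs)
    tf <- morlet_tfr(ev, freqs = 10, n_cycles = 1.5)
    interior <- !tf$edge[1, ]
    mean(tf$data[1, interior])
  }, numeric(1))
  ratios <- peak / amps
  expect_lt(max(abs(ratios / ratios[1] - 1)), 0.01)
  # zero signal gives zero amplitude
  zero <- morlet_tfr(make_evoked(matrix(0, 2, length(t)), fs = fs))
  expect_true(all(zero$data == 0))
})

test_that("Morlet amplitudes match an independent convolution oracle", {
  fs <- 120
  t <- seq(0, 1.5, by = 1 / fs)
  sig <- sin(2 * pi * 10 * t) + 0.3 * sin(2 * pi * 8.5 * t + 1)
  ev <- make_evoked(rbind(sig, sig), fs = fs)
  tf <- morlet_tfr(ev, freqs = 8:13, n_cycles = 1.5)
  for (k in c(1, 3, 6)) {
    want <- oracle_morlet_amplitude(sig, fs, (8:13)[k], 1.5)
    rel <- abs(tf$data[k, ] - want) / max(want)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("orthogonal-frequency components stay separated in the TFR", {
  # the separation property needs wavelets narrow enough in frequency that
  # the two components do not leak into each other's band (spectral width
  # ~ f / n_cycles); 7 cycles gives ~1.1-1.9 Hz widths for a 5 Hz gap
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  s1 <- sin(2 * pi * 8 * t)
  s2 <- sin(2 * pi * 13 * t)
  cycles <- 7
  tf_sum <- morlet_tfr(make_evoked(rbind(s1 + s2, s1 + s2), fs = fs),
                       freqs = c(8, 13), n_cycles = cycles)
  tf_1 <- morlet_tfr(make_evoked(rbind(s1, s1), fs = fs),
                     freqs = c(8, 13), n_cycles = cycles)
  tf_2 <- morlet_tfr(make_evoked(rbind(s2, s2), fs = fs),
                     freqs = c(8, 13), n_cycles = cycles)
  interior <- !tf_sum$edge[1, ] & !tf_sum$edge[2, ]
  for (k in 1:2) {
    own <- pmax(tf_1$data[k, interior], tf_2$data[k, interior])
    cross <- abs(tf_sum$data[k, interior] - own)
    expect_lt(mean(cross) / mean(own), 0.05)
  }
})

test_that("induced and evoked TFR modes agree for a single trial", {
  set.seed(14)
  arr <- array(rnorm(1 * 4 * 300), dim = c(1, 4, 300))
  ep <- make_epochs(arr, fs = 150)
  a <- morlet_tfr(ep, mode = "induced")
  b <- morlet_tfr(ep, mode = "evoked")
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("a too-short window is rejected", {
  ev <- make_evoked(matrix(rnorm(2 * 20), 2, 20), fs = 100)
  expect_error(morlet_tfr(ev, freqs = 8), "shorter")
})
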