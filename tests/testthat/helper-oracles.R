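# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / different algorithms than the
# implementation under test.

# Monte-Carlo oracle for the triangle decision rule: written as an explicit
# per-trial loop, independent of simulate_response().
oracle_triangle_pc <- function(f_odd, f_pair, sigma, n_trials, seed) {
  set.seed(seed)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    odd_pos <- sample.int(3L, 1L)
    f <- rep(f_pair, 3)
    f[odd_pos] <- f_odd
    x <- rnorm(3, mean = f, sd = sigma)
    d <- numeric(3)
    for (k in 1:3) d[k] <- abs(x[k] - mean(x[-k]))
    correct[i] <- which.max(d) == odd_pos
  }
  mean(correct)
}

# Naive per-sample GFP (population sd across channels, after average
# reference), looped.
oracle_gfp <- function(mat) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j] - mean(mat[, j])
    out[j] <- sqrt(sum(v^2) / length(v))
  }
  out
}

# Naive per-sample GMD, looped.
oracle_gmd <- function(a, b) {
  out <- numeric(ncol(a))
  for (j in seq_len(ncol(a))) {
    va <- a[, j] - mean(a[, j])
    vb <- b[, j] - mean(b[, j])
    ga <- sqrt(mean(va^2))
    gb <- sqrt(mean(vb^2))
    out[j] <- sqrt(mean((va / ga - vb / gb)^2))
  }
  out
}

# Independent Morlet amplitude: direct time-domain convolution sums (no
# FFT), same wavelet definition (unit energy, 5 sd support).
oracle_morlet_amplitude <- function(signal, fs, freq, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(5 * sigma_t * fs)
  tt <- seq(-half, half) / fs
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  n <- length(signal)
  out <- complex(n)
  for (i in seq_len(n)) {
    acc <- 0 + 0i
    for (k in seq_along(w)) {
      j <- i - (k - half - 1L)
      if (j >= 1 && j <= n) acc <- acc + signal[j] * w[k]
    }
    out[i] <- acc
  }
  Mod(out)
}

# Exhaustive sign-flip enumeration oracle for the one-sample cluster test
# on 1-D maps: own t computation and own rle-based clustering, including
# the two-tailed max-statistic null and the (1+k)/(1+N) p convention.
oracle_one_sample_cluster <- function(maps, threshold) {
  X <- do.call(rbind, maps)
  n <- nrow(X)
  tstat <- function(M) {
    m <- colMeans(M)
    s <- apply(M, 2, sd)
    tv <- m / (s / sqrt(n))
    tv[!is.finite(tv)] <- 0
    tv
  }
  clusters_of <- function(tv, sgn) {
    mask <- if (sgn > 0) tv > threshold else tv < -threshold
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(which(r$values), function(k) seq(starts[k], ends[k]))
  }
  max_abs_mass <- function(tv) {
    masses <- c(vapply(clusters_of(tv, 1), function(i) sum(tv[i]),
                       numeric(1)),
                vapply(clusters_of(tv, -1), function(i) -sum(tv[i]),
                       numeric(1)))
    if (length(masses) == 0) 0 else max(masses)
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(signs, 1, function(s) max_abs_mass(tstat(X * s)))
  tv <- tstat(X)
  obs <- list()
  for (sgn in c(1, -1)) {
    for (cl in clusters_of(tv, sgn)) {
      mass <- sum(tv[cl])
      obs[[length(obs) + 1L]] <- c(mass = mass,
                                   p = (1 + sum(null >= abs(mass))) /
                                     (1 + nrow(signs)))
    }
  }
  obs
}

# Exhaustive label-partition enumeration oracle for the two-sample cluster
# test on 1-D maps (pooled-variance t).
oracle_two_sample_cluster <- function(maps_a, maps_b, threshold) {
  X <- rbind(do.call(rbind, maps_a), do.call(rbind, maps_b))
  na <- length(maps_a); nb <- length(maps_b); n <- na + nb
  tstat <- function(ia) {
    A <- X[ia, , drop = FALSE]
    B <- X[-ia, , drop = FALSE]
    ma <- colMeans(A); mb <- colMeans(B)
    sp2 <- (colSums(sweep(A, 2, ma)^2) + colSums(sweep(B, 2, mb)^2)) /
      (n - 2)
    tv <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    tv[!is.finite(tv)] <- 0
    tv
  }
  clusters_of <- function(tv, sgn) {
    mask <- if (sgn > 0) tv > threshold else tv < -threshold
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(which(r$values), function(k) seq(starts[k], ends[k]))
  }
  max_abs_mass <- function(tv) {
    masses <- c(vapply(clusters_of(tv, 1), function(i) sum(tv[i]),
                       numeric(1)),
                vapply(clusters_of(tv, -1), function(i) -sum(tv[i]),
                       numeric(1)))
    if (length(masses) == 0) 0 else max(masses)
  }
  parts <- utils::combn(n, na, simplify = FALSE)
  null <- vapply(parts, function(ia) max_abs_mass(tstat(ia)), numeric(1))
  tv <- tstat(seq_len(na))
  obs <- list()
  for (sgn in c(1, -1)) {
    for (cl in clusters_of(tv, sgn)) {
      mass <- sum(tv[cl])
      obs[[length(obs) + 1L]] <- c(mass = mass,
                                   p = (1 + sum(null >= abs(mass))) /
                                     (1 + length(parts)))
    }
  }
  obs
}

# Small evoked-map fixture builder.
make_evoked <- function(mat, fs = 100, label = "fixture") {
  sestrain:::new_evoked(mat, fs = fs,
                        times = seq(0, by = 1 / fs,
                                    length.out = ncol(mat)),
                        channels = paste0("ch", seq_len(nrow(mat))),
                        trigger = "start", label = label)
}

# Tiny epoch-set fixture with known content: trials x channels x time.
make_epochs <- function(arr, fs = 100) {
  structure(
    list(data = arr, fs = fs,
         times = seq(0, by = 1 / fs, length.out = dim(arr)[3]),
         channels = paste0("ch", seq_len(dim(arr)[2])),
         trigger = "start", participant_id = "P01", group = "Sham",
         phase = "pre"),
    class = "ses_epochs"
  )
}
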