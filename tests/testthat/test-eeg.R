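test_that("synthetic EEG has the right shape and is fully reproducible", {
  ds <- simulate_eeg(6, channels = 16, n_background = 6, seed = 3)
  expect_identical(dim(ds$data), c(16L, 1500L))   # 6 s at 250 Hz
  ds2 <- simulate_eeg(6, channels = 16, n_background = 6, seed = 3)
  expect_identical(ds$data, ds2$data)
  expect_identical(ds$artifact_source_indices, c(1L, 2L))
  expect_identical(dim(ds$mixing), c(16L, 8L))
})

test_that("the mixture model reconstructs exactly up to the stored noise", {
  ds <- simulate_eeg(6, channels = 8, n_background = 4, seed = 5,
                     store_noise = TRUE)
  resid <- ds$data - ds$mixing %*% ds$sources
  expect_equal(resid, ds$noise, tolerance = 1e-12)
})

test_that("blink sources are heavy-tailed relative to background", {
  kurt <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 - 3
  for (seed in 1:3) {
    ds <- simulate_eeg(12, channels = 16, n_background = 6, seed = seed)
    blink_k <- apply(ds$sources[1:2, ], 1, kurt)
    bg_k <- apply(ds$sources[-(1:2), ], 1, kurt)
    expect_gt(min(blink_k), 3)
    expect_gt(min(blink_k), max(bg_k))
    # heavy tails persist in every 6-s window
    n6 <- 6 * ds$fs
    for (start in seq(1, ncol(ds$sources) - n6 + 1, by = n6)) {
      expect_gt(min(apply(ds$sources[1:2, start:(start + n6 - 1)], 1, kurt)),
                3)
    }
  }
})

test_that("PCA reduction explains monotone variance and is lossless at full k", {
  ds <- simulate_eeg(6, channels = 16, n_background = 6, seed = 7)
  ev <- vapply(c(2, 4, 8, 16), function(k) pca_reduce(ds, k)$explained,
               numeric(1))
  expect_true(all(diff(ev) > 0))
  red <- pca_reduce(ds, 16)
  back <- tcrossprod(red$scores, red$loadings) +
    matrix(red$center, ncol(ds$data), nrow(ds$data), byrow = TRUE)
  expect_lt(max(abs(back - t(ds$data))), 1e-8)
  expect_warning(pca_reduce(matrix(rnorm(30), 10, 3), k = 10), "rank")
})

test_that("the default generator concentrates variance in few components", {
  ds <- simulate_eeg(6, seed = 11)    # default 249 channels
  expect_gt(pca_reduce(ds, 50)$explained, 0.99)
})

test_that("a noiseless single-blink-source toy is recovered almost exactly", {
  # 8 channels, one blink source plus Gaussian backgrounds, no sensor noise
  set.seed(13)
  fs <- 250
  n <- 60 * fs
  blink <- numeric(n)
  for (t0 in seq(1, n - 80, by = 1000)) {
    u <- (0:75 - 38) / 76
    blink[t0 + 0:75] <- cos(pi * u)^2
  }
  blink <- blink / sqrt(mean(blink^2)) * 10
  sources <- rbind(blink, matrix(rnorm(3 * n), 3, n))
  mixing <- qr.Q(qr(matrix(rnorm(32), 8, 4)))   # orthonormal topographies
  toy <- structure(
    list(data = mixing %*% sources, fs = fs, channels = 8L,
         mixing = mixing, sources = sources,
         artifact_source_indices = 1L, seed = 13),
    class = "eeg_dataset")
  red <- pca_reduce(toy, 4)
  for (m in c("j15", "fastica_I", "fastica_III")) {
    rec <- extract_and_match(red, toy, contrast = m, n_components = 2,
                             restarts = 5, seed = 17)
    expect_lt(rec$error_deg[1], 1, label = m)
  }
})

test_that("channel relabeling leaves recovery errors unchanged", {
  ds <- simulate_eeg(6, channels = 12, n_background = 5, seed = 19)
  red <- pca_reduce(ds, 7)
  rec <- extract_and_match(red, ds, contrast = "fastica_III",
                           n_components = 4, restarts = 4, seed = 23)
  perm <- sample(12)
  dsp <- ds
  dsp$data <- ds$data[perm, ]
  dsp$mixing <- ds$mixing[perm, ]
  redp <- pca_reduce(dsp, 7)
  recp <- extract_and_match(redp, dsp, contrast = "fastica_III",
                            n_components = 4, restarts = 4, seed = 23)
  # errors agree up to the optimizer's direction tolerance (~0.006 deg)
  expect_equal(sort(rec$error_deg), sort(recp$error_deg), tolerance = 1e-2)
})

test_that("without artifacts no component resembles a blink topography", {
  ds <- simulate_eeg(10, channels = 16, n_background = 6, blink_snr = 0,
                     seed = 29)
  red <- pca_reduce(ds, 8)
  rec <- extract_and_match(red, ds, contrast = "fastica_I",
                           n_components = 6, restarts = 4, seed = 31)
  expect_lt(max(rec$match_cos), 0.5)
})
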