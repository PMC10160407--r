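test_that("whitening yields identity covariance and invertible transforms", {
  set.seed(11)
  X <- matrix(rnorm(4000), 1000, 4) %*% matrix(rnorm(16), 4, 4)
  w <- whiten(X)
  expect_lt(max(abs(crossprod(w$Z) / nrow(w$Z) - diag(4))), 1e-8)
  expect_lt(max(abs(w$backward %*% w$forward - diag(4))), 1e-10)
  u <- c(1, 0, 0, 0)
  expect_equal(sum(to_whitened_direction(w, u)^2), 1, tolerance = 1e-12)
  # rank-deficient input: reduced with a warning, or an error if forbidden
  Xd <- cbind(X, X[, 1] + X[, 2])
  expect_warning(wd <- whiten(Xd), "near-null")
  expect_identical(wd$rank, 4L)
  expect_error(whiten(Xd, reduce = FALSE), "rank deficient")
})

test_that("error angles respect the ICA sign ambiguity", {
  u <- c(1, 0, 0)
  expect_equal(error_angle(u, u), 0)
  expect_equal(error_angle(u, -u), 0)
  expect_equal(error_angle(u, c(0, 1, 0)), 90)
  expect_error(error_angle(u, c(1, 0)), "dimension")
})

test_that("angular variance follows the sign-aligned mean-vector definition", {
  u <- c(1, 0)
  expect_equal(angular_variance(rbind(u, u, u), u), 0)
  expect_equal(angular_variance(rbind(u, -u), u), 0)
  expect_equal(angular_variance(rbind(c(1, 0), c(0, 1)), c(1, 0)),
               1 - sqrt(2) / 2)
  expect_error(angular_variance(rbind(u, c(0, 0)), u), "zero vector")
})

test_that("projection scoring peaks along the non-Gaussian axis", {
  wins <- vapply(1:5, function(s) {
    ds <- make_product_dataset(dist_mixture(0.5), d = 2, N = 1e4, seed = s)
    project_and_score(ds$data, c(1, 0)) > project_and_score(ds$data, c(0, 1))
  }, logical(1))
  expect_true(all(wins))
  # sign invariance
  ds <- make_product_dataset(dist_gev(0), d = 2, N = 5000, seed = 9)
  expect_equal(project_and_score(ds$data, c(1, 0)),
               project_and_score(ds$data, c(-1, 0)), tolerance = 1e-12)
})

test_that("isotropic Gaussian data show no preferred direction", {
  set.seed(13)
  X <- matrix(rnorm(2e4), ncol = 2)
  ang <- seq(0, 175, by = 5) * pi / 180
  sc <- vapply(ang, function(a) {
    project_and_score(X, c(cos(a), sin(a)))
  }, numeric(1))
  for (i in seq_along(sc)) {
    expect_lt(sc[i], mean(sc[-i]) + 4 * sd(sc[-i]))
  }
})

test_that("exhaustive 2-D search recovers the true axis and is equivariant", {
  ds <- make_product_dataset(dist_mixture(0.5), d = 2, N = 1e4, seed = 17)
  res <- exhaustive_search_2d(ds$data, "j15")
  err <- min(res$angle, 180 - res$angle)
  expect_lte(err, 1)
  expect_equal(sum(res$estimate$direction^2), 1, tolerance = 1e-10)
  # rotating the data by 30 degrees shifts the peak by 30 degrees
  rot <- 30 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  res30 <- exhaustive_search_2d(ds$data %*% t(R), "j15")
  shift <- (res30$angle - res$angle) %% 180
  expect_lt(min(abs(shift - 30), abs(shift - 150)), 0.1 + 1e-9)
  # fine grid resolution is 0.1 degrees
  off <- res$angle %% 0.1
  expect_lt(min(off, 0.1 - off), 1e-6)
})

test_that("the analytic J gradient matches central finite differences", {
  for (s in 1:3) {
    ds <- make_product_dataset(dist_gnormal(1), d = 4, N = 1500,
                               rotate = TRUE, seed = 20 + s)
    w <- whiten(ds$data)
    set.seed(40 + s)
    u <- rnorm(4)
    u <- u / sqrt(sum(u^2))
    g <- hfica:::j_gradient(w$Z, u)$gradient
    fd <- vapply(1:4, function(i) {
      e <- rep(0, 4); e[i] <- 1e-5
      (hfica:::j_gradient(w$Z, u + e)$value -
         hfica:::j_gradient(w$Z, u - e)$value) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("deflation extracts orthogonal components and finds the source", {
  ds <- make_product_dataset(dist_gnormal(1), d = 4, N = 1e4, rotate = TRUE,
                             seed = 23)
  w <- whiten(ds$data)
  ests <- deflation_search(w$Z, "j15", n_components = 3, restarts = 5,
                           seed = 2)
  dirs <- do.call(rbind, lapply(ests, `[[`, "direction"))
  expect_lt(max(abs(tcrossprod(dirs) - diag(3))), 1e-8)
  # contrast value is reproducible from the stored direction
  for (e in ests) {
    expect_equal(e$contrast_value,
                 project_and_score(w$Z, e$direction, "j15"),
                 tolerance = 1e-12)
  }
  tw <- to_whitened_direction(w, ds$true_direction)
  expect_lt(error_angle(ests[[1]]$direction, tw), 5)
})

test_that("fixed-point deflation recovers the source for FastICA contrasts", {
  ds <- make_product_dataset(dist_mixture(0.5), d = 4, N = 1e4,
                             rotate = TRUE, seed = 29)
  w <- whiten(ds$data)
  tw <- to_whitened_direction(w, ds$true_direction)
  for (m in c("fastica_I", "fastica_II", "fastica_III")) {
    est <- deflation_search(w$Z, m, n_components = 1, restarts = 5,
                            seed = 3)[[1]]
    expect_lt(error_angle(est$direction, tw), 5, label = m)
  }
})

test_that("cross-contrast selection returns the argmax candidate", {
  ds <- make_product_dataset(dist_gnormal(1), d = 3, N = 5000,
                             rotate = TRUE, seed = 31)
  w <- whiten(ds$data)
  good <- deflation_search(w$Z, "j15", n_components = 1, restarts = 4,
                           seed = 5)[[1]]
  bad <- hfica:::new_unmixing_estimate(c(0, 1, 0), "fastica_I", 0)
  # single candidate: returned unchanged
  one <- cross_contrast_select(w$Z, list(good), "j15")
  expect_equal(one$direction, good$direction)
  # argmax over the candidate set, value re-evaluated under the contrast
  sel <- cross_contrast_select(w$Z, list(bad, good), "j15")
  expect_equal(sel$direction, good$direction)
  expect_gte(sel$contrast_value, good$contrast_value - 1e-12)
})

test_that("profile precision is the 2-SD band separation half-width", {
  ang <- seq(-10, 10, by = 0.5)
  prof <- data.frame(angle = ang, mean = exp(-ang^2 / 8), sd = 0.001)
  pr <- precision_from_profile(prof)
  expect_equal(pr$peak_angle, 0)
  expect_false(pr$flagged)
  expect_lt(pr$half_width, 5)
  # shrinking the SD cannot widen the reported band
  prof_small <- transform(prof, sd = sd / 10)
  expect_lte(precision_from_profile(prof_small)$half_width, pr$half_width)
  # flat profile: flagged, half-range returned
  flat <- data.frame(angle = ang, mean = 1, sd = 0.1)
  prf <- precision_from_profile(flat)
  expect_true(prf$flagged)
  expect_equal(prf$half_width, 10)
})

test_that("hfica returns a full model object with working methods", {
  ds <- make_product_dataset(dist_mixture(0.5), d = 3, N = 5000,
                             rotate = TRUE, seed = 37)
  fit <- hfica(ds$data, n.comp = 2, restarts = 4, seed = 1)
  expect_s3_class(fit, "hfica")
  expect_identical(dim(coef(fit)), c(2L, 3L))
  expect_equal(predict(fit, ds$data), fit$S, tolerance = 1e-10)
  expect_output(print(fit), "Hermite-function ICA")
  s <- summary(fit)
  expect_identical(nrow(s$table), 2L)
  tw <- to_whitened_direction(fit$whitening, ds$true_direction)
  expect_lt(error_angle(fit$directions[1, ], tw), 5)
})
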