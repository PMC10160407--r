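test_that("analytic coefficients of the standard normal put all power in a_0", {
  co <- analytic_coefficients(dist_normal(), 15)
  expect_equal(co$values[1], pi^(1 / 4) / sqrt(2 * pi), tolerance = 1e-8)
  expect_lt(max(abs(co$values[-1])), 1e-8)
  expect_identical(co$source, "analytic")
})

test_that("odd-order analytic coefficients vanish for symmetric densities", {
  co <- analytic_coefficients(dist_gnormal(1), 15, standardize = TRUE)
  odd <- co$values[co$orders %% 2 == 1]
  expect_lt(max(abs(odd)), 1e-8)
})

test_that("a degenerate mixture reproduces the standard-normal coefficients", {
  co_mix <- analytic_coefficients(dist_mixture(1, 0, 1, 5, 2), 10)
  co_norm <- analytic_coefficients(dist_normal(), 10)
  expect_equal(co_mix$values, co_norm$values, tolerance = 1e-9)
})

test_that("sample coefficients are the mean of H_i over the data", {
  co <- estimate_coefficients(rep(0, 10), 3, standardize = FALSE)
  expect_equal(co$values, hermite_basis(0, 3)[1, ])
  expect_equal(co$values[2], 0)   # odd parity at 0
  expect_equal(co$values[4], 0)
  expect_identical(co$sample_size, 10L)
  expect_error(estimate_coefficients(rep(2, 10), 3), "zero variance")
})

test_that("sample coefficients converge to the analytic values (Monte Carlo)", {
  set.seed(401)
  N <- 1e5
  co <- estimate_coefficients(rnorm(N), 15)
  # each H_i is bounded by ~0.8, so SE <= 1/sqrt(N); allow 4 SEs
  expect_lt(max(abs(co$values[-1])), 4 / sqrt(N))
  expect_equal(co$values[1], 0.53114, tolerance = 4 / sqrt(N) / 0.53)
})

test_that("J arithmetic follows the power-ratio definition", {
  co <- hfica:::new_hermite_coefs(0:3, c(0.7, 0, 0, 0), "analytic")
  expect_equal(j_measure(co)$value, 0)
  co2 <- hfica:::new_hermite_coefs(0:3, c(1, 1, 0, 0), "analytic")
  expect_equal(j_measure(co2)$value, 0.5)
  co3 <- hfica:::new_hermite_coefs(0:3, c(1e-200, 0.5, 0, 0), "analytic")
  expect_gt(j_measure(co3)$value, 1 - 1e-8)
  co0 <- hfica:::new_hermite_coefs(0:3, rep(0, 4), "analytic")
  expect_error(j_measure(co0), "undefined")
})

test_that("order subsets keep order 0 and drop the complementary orders", {
  co <- hfica:::new_hermite_coefs(0:4, c(1, 2, 3, 4, 5), "analytic")
  expect_equal(j_measure(co, "even")$value, 1 - 1 / (1 + 9 + 25))
  expect_equal(j_measure(co, "odd")$value, 1 - 1 / (1 + 4 + 16))
})

test_that("J_0 of any sample is zero and J grows with non-Gaussianity", {
  set.seed(77)
  expect_equal(j_statistic(rnorm(500), n = 0)$value, 0)
  # paired replicates: mixture samples always score above Gaussian samples
  spec <- dist_mixture(0.5)
  wins <- vapply(1:20, function(i) {
    jm <- j_statistic(rdist(spec, 1e4, seed = 1000 + i))$value
    jg <- j_statistic(rnorm(1e4))$value
    jm > jg
  }, logical(1))
  expect_true(all(wins))
})

test_that("mean J_15 of Gaussian samples decreases with sample size", {
  sizes <- c(1e2, 1e3, 1e4, 1e5)
  set.seed(55)
  means <- vapply(sizes, function(N) {
    mean(vapply(1:20, function(i) j_statistic(rnorm(N))$value, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("analytic J_15 is zero at the Gaussian member and grows away from it", {
  grid <- seq(0.5, 10, by = 0.5)
  jv <- vapply(grid, function(b) {
    j_measure(analytic_coefficients(dist_gnormal(b), 15,
                                    standardize = TRUE))$value
  }, numeric(1))
  expect_lt(jv[grid == 2], 1e-8)
  expect_true(all(diff(jv[grid >= 2]) > 0))
  expect_true(all(diff(jv[grid <= 2]) < 0))
})

test_that("analytic mixture J_15 peaks at equal weights and vanishes at the ends", {
  alphas <- c(0, 0.25, 0.5, 0.75, 1)
  jv <- vapply(alphas, function(a) {
    j_measure(analytic_coefficients(dist_mixture(a), 15,
                                    standardize = TRUE))$value
  }, numeric(1))
  expect_equal(which.max(jv), 3L)
  expect_lt(jv[1], 1e-8)
  expect_lt(jv[5], 1e-8)
})

test_that("even-variant matches all-variant for symmetric densities; odd is ~0", {
  co <- analytic_coefficients(dist_gnormal(1), 15, standardize = TRUE)
  expect_equal(j_measure(co, "even")$value, j_measure(co, "all")$value,
               tolerance = 1e-8)
  expect_lt(j_measure(co, "odd")$value, 1e-8)
})
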