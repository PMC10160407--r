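specs_unit <- list(
  mixture = dist_mixture(0.7, -2, 1, 2, 0.4),
  gnormal = dist_gnormal(1),
  gev_neg = dist_gev(-0.2),
  gev_pos = dist_gev(0.5),
  gumbel = dist_gev(0)
)

test_that("densities integrate to one over their support", {
  for (nm in names(specs_unit)) {
    spec <- specs_unit[[nm]]
    total <- integrate(function(x) ddist(spec, x), spec$support[1],
                       spec$support[2], rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8, label = nm)
  }
})

test_that("mixture density closed-form values", {
  x <- seq(-3, 3, 0.7)
  expect_equal(ddist(dist_mixture(1, 0, 1, 5, 2), x), dnorm(x))
  expect_equal(ddist(dist_mixture(0.5, -2, 1, 2, 1), 0), dnorm(2))
  expect_error(dist_mixture(1.4), "alpha")
  expect_error(dist_mixture(0.5, sigma1 = -1), "sigma")
})

test_that("generalized normal is Gaussian at beta = 2 and normalizes correctly", {
  expect_equal(ddist(dist_gnormal(2), c(0, 1, 2)), dnorm(c(0, 1, 2)))
  expect_equal(hfica:::gnormal_const(2), 1 / sqrt(2 * pi))
  expect_error(dist_gnormal(0), "beta")
  # Laplace-type member: excess kurtosis ~ 3 by quadrature
  spec <- dist_gnormal(1)
  mom <- hfica:::density_moments(function(x) ddist(spec, x), spec$support)
  m4 <- integrate(function(x) x^4 * ddist(spec, x), -Inf, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m4 / mom$var^2 - 3, 3, tolerance = 1e-6)
})

test_that("GEV density has the Gumbel limit and bounded support", {
  expect_equal(ddist(dist_gev(0), 0), exp(-1))
  expect_equal(dist_gev(0.5)$support[1], -2)
  expect_equal(ddist(dist_gev(0.5), -3), 0)   # outside support: density 0
})

test_that("samplers are seeded, reproducible and respect supports", {
  for (nm in names(specs_unit)) {
    spec <- specs_unit[[nm]]
    a <- rdist(spec, 100, seed = 5)
    b <- rdist(spec, 100, seed = 5)
    expect_identical(a, b, label = nm)
  }
  x <- rdist(dist_normal(), 1e5, seed = 9)
  expect_lt(abs(mean(x)), 4 / sqrt(1e5))
  expect_gt(min(rdist(dist_gev(0.5), 1e5, seed = 2)), -2)
})

test_that("empirical CDFs match the analytic CDFs", {
  for (nm in names(specs_unit)) {
    spec <- specs_unit[[nm]]
    x <- sort(rdist(spec, 1e5, seed = 31))
    dev <- max(abs(pdist(spec, x) - seq_along(x) / length(x)))
    expect_lt(dev, 0.01, label = nm)
  }
})

test_that("family shape indices behave as designed", {
  # GEV skewness: negative well below the transition, positive at and above 0
  expect_lt(dist_skewness(dist_gev(-0.45)), 0)
  expect_gt(dist_skewness(dist_gev(0)), 0)
  expect_gt(dist_skewness(dist_gev(0.2)), 0)
  # generalized normal excess kurtosis changes sign at beta = 2
  kurt <- function(b) {
    spec <- dist_gnormal(b)
    v <- dist_moments(spec)$var
    m4 <- integrate(function(x) x^4 * ddist(spec, x), -Inf, Inf,
                    rel.tol = 1e-10)$value
    m4 / v^2 - 3
  }
  expect_gt(kurt(1.2), 0)
  expect_lt(kurt(4), 0)
  # mixture skewness: zero when symmetric, nonzero when modes differ
  expect_equal(dist_skewness(dist_mixture(0.5, -2, 1, 2, 1)), 0,
               tolerance = 1e-8)
  expect_gt(abs(dist_skewness(dist_mixture(0.7, -2, 1, 2, 0.4))), 0.1)
})

test_that("closed-form moments agree with quadrature", {
  for (spec in list(dist_mixture(0.3, -1, 2, 3, 0.5), dist_gnormal(1.5),
                    dist_gev(-0.2), dist_gev(0))) {
    mom <- dist_moments(spec)
    q <- hfica:::density_moments(function(x) ddist(spec, x), spec$support)
    expect_equal(mom$mean, q$mean, tolerance = 1e-6)
    expect_equal(mom$var, q$var, tolerance = 1e-6)
  }
})

test_that("product datasets carry a standardized non-Gaussian first axis", {
  ds <- make_product_dataset(dist_gnormal(1), d = 3, N = 2e4, seed = 12)
  expect_equal(ds$true_direction, c(1, 0, 0))
  expect_true(all(abs(apply(ds$data, 2, var) - 1) < 5 / sqrt(2e4) * 3))
  # rotated: orthogonal mixing, near-identity covariance, recorded truth
  dsr <- make_product_dataset(dist_mixture(0.5), d = 5, N = 2e4,
                              rotate = TRUE, seed = 13)
  expect_lt(max(abs(crossprod(dsr$mixing) - diag(5))), 1e-10)
  expect_equal(sqrt(sum(dsr$true_direction^2)), 1, tolerance = 1e-10)
  expect_lt(max(abs(cov(dsr$data) - diag(5))), 0.05)
  # determinism
  ds2 <- make_product_dataset(dist_mixture(0.5), d = 5, N = 100,
                              rotate = TRUE, seed = 13)
  ds3 <- make_product_dataset(dist_mixture(0.5), d = 5, N = 100,
                              rotate = TRUE, seed = 13)
  expect_identical(ds2$data, ds3$data)
})
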