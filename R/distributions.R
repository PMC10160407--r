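#' Parametric distribution families for non-Gaussianity benchmarks
#'
#' Constructors for the 1-D families used throughout the benchmarks, each
#' deviating from normality in a distinct way:
#' \describe{
#'   \item{`dist_normal()`}{the standard normal reference.}
#'   \item{`dist_mixture()`}{a two-component Gaussian mixture
#'     \eqn{\alpha N(\mu_1,\sigma_1) + (1-\alpha) N(\mu_2,\sigma_2)};
#'     bimodal for intermediate \eqn{\alpha}, Gaussian at \eqn{\alpha = 0, 1}.}
#'   \item{`dist_gnormal()`}{the symmetric generalized normal
#'     \eqn{C(\beta) e^{-|x|^\beta/2}}; Gaussian at \eqn{\beta = 2},
#'     heavy-tailed below, light-tailed above.}
#'   \item{`dist_gev()`}{the generalized extreme value family
#'     \eqn{e^{-(1+\kappa x)^{-1/\kappa}} (1+\kappa x)^{-1-1/\kappa}} on
#'     \eqn{1+\kappa x > 0}; skewness changes sign near \eqn{\kappa = -0.3};
#'     \eqn{\kappa = 0} is the Gumbel limit.}
#' }
#'
#' @param alpha,mu1,sigma1,mu2,sigma2 Mixture weight, means and SDs.
#' @param beta Generalized-normal shape (> 0).
#' @param kappa GEV shape parameter.
#' @return A `dist_spec` object with fields `family`, `params`, `support`.
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_normal <- function() {
  new_dist_spec("normal", list(), c(-Inf, Inf))
}

#' @rdname dist_spec
#' @export
dist_mixture <- function(alpha, mu1 = -2, sigma1 = 1, mu2 = 2, sigma2 = 1) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be > 0", call. = FALSE)
  new_dist_spec("gaussian_mixture",
                list(alpha = alpha, mu1 = mu1, sigma1 = sigma1,
                     mu2 = mu2, sigma2 = sigma2),
                c(-Inf, Inf))
}

#' @rdname dist_spec
#' @export
dist_gnormal <- function(beta) {
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  new_dist_spec("generalized_normal", list(beta = beta), c(-Inf, Inf))
}

#' @rdname dist_spec
#' @export
dist_gev <- function(kappa) {
  stopifnot(is.numeric(kappa), is.finite(kappa))
  support <- if (abs(kappa) < 1e-12) c(-Inf, Inf)
  else if (kappa > 0) c(-1 / kappa, Inf)
  else c(-Inf, -1 / kappa)
  new_dist_spec("gev", list(kappa = kappa), support)
}

new_dist_spec <- function(family, params, support) {
  structure(list(family = family, params = params, support = support),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  } else "standard"
  cat(sprintf("dist_spec: %s (%s)\n", x$family, ps))
  invisible(x)
}

# normalizing constant of the generalized normal, from the
# integral of exp(-|x|^beta / 2): C(beta) = beta / (2^(1 + 1/beta) Gamma(1/beta))
gnormal_const <- function(beta) beta / (2^(1 + 1 / beta) * gamma(1 / beta))

#' Density of a `dist_spec`
#'
#' @param spec A [dist_spec] object.
#' @param x Numeric vector.  Points outside the support return density 0.
#' @return Density values.
#' @export
ddist <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    normal = stats::dnorm(x),
    gaussian_mixture =
      p$alpha * stats::dnorm(x, p$mu1, p$sigma1) +
      (1 - p$alpha) * stats::dnorm(x, p$mu2, p$sigma2),
    generalized_normal = gnormal_const(p$beta) * exp(-abs(x)^p$beta / 2),
    gev = {
      k <- p$kappa
      out <- numeric(length(x))
      if (abs(k) < 1e-12) {
        out <- exp(-x - exp(-x))
      } else {
        t <- 1 + k * x
        ok <- t > 0
        out[ok] <- exp(-t[ok]^(-1 / k)) * t[ok]^(-1 - 1 / k)
      }
      out
    },
    stop("unknown family", call. = FALSE)
  )
}

#' Cumulative distribution function of a `dist_spec`
#'
#' @inheritParams ddist
#' @return CDF values.
#' @export
pdist <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    normal = stats::pnorm(x),
    gaussian_mixture =
      p$alpha * stats::pnorm(x, p$mu1, p$sigma1) +
      (1 - p$alpha) * stats::pnorm(x, p$mu2, p$sigma2),
    generalized_normal = {
      g <- stats::pgamma(abs(x)^p$beta / 2, shape = 1 / p$beta)
      ifelse(x >= 0, 0.5 + g / 2, 0.5 - g / 2)
    },
    gev = {
      k <- p$kappa
      if (abs(k) < 1e-12) {
        exp(-exp(-x))
      } else {
        t <- pmax(1 + k * x, 0)
        out <- exp(-t^(-1 / k))
        # below/above the support boundary the CDF saturates
        if (k > 0) out[t == 0] <- 0 else out[t == 0] <- 1
        out
      }
    },
    stop("unknown family", call. = FALSE)
  )
}

#' Seeded sampling from a `dist_spec`
#'
#' Mixtures are drawn via a component indicator, the generalized normal via
#' the gamma transform \eqn{X = s\,(2G)^{1/\beta}} with
#' \eqn{G \sim \Gamma(1/\beta, 1)} and a random sign, and the GEV by
#' inversion of its closed-form CDF.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Numeric vector of length `n`.
#' @export
rdist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  with_seed(seed, {
    p <- spec$params
    switch(spec$family,
      normal = stats::rnorm(n),
      gaussian_mixture = {
        comp1 <- stats::runif(n) < p$alpha
        mu <- ifelse(comp1, p$mu1, p$mu2)
        sg <- ifelse(comp1, p$sigma1, p$sigma2)
        stats::rnorm(n, mu, sg)
      },
      generalized_normal = {
        g <- stats::rgamma(n, shape = 1 / p$beta)
        sgn <- sample(c(-1, 1), n, replace = TRUE)
        sgn * (2 * g)^(1 / p$beta)
      },
      gev = {
        u <- stats::runif(n)
        k <- p$kappa
        if (abs(k) < 1e-12) -log(-log(u))
        else ((-log(u))^(-k) - 1) / k
      },
      stop("unknown family", call. = FALSE)
    )
  })
}

#' Moments of a `dist_spec`
#'
#' Mean and variance, by closed form where available (mixture, generalized
#' normal, GEV with \eqn{\kappa < 1/2}) and by quadrature otherwise.
#'
#' @param spec A [dist_spec].
#' @return List with `mean` and `var`.
#' @export
dist_moments <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = list(mean = 0, var = 1),
    gaussian_mixture = {
      m <- p$alpha * p$mu1 + (1 - p$alpha) * p$mu2
      m2 <- p$alpha * (p$sigma1^2 + p$mu1^2) +
        (1 - p$alpha) * (p$sigma2^2 + p$mu2^2)
      list(mean = m, var = m2 - m^2)
    },
    generalized_normal = list(
      mean = 0,
      var = 2^(2 / p$beta) * gamma(3 / p$beta) / gamma(1 / p$beta)
    ),
    gev = {
      k <- p$kappa
      if (abs(k) < 1e-12) {
        list(mean = -digamma(1), var = pi^2 / 6)
      } else if (k < 0.5) {
        g1 <- gamma(1 - k)
        g2 <- gamma(1 - 2 * k)
        list(mean = (g1 - 1) / k, var = (g2 - g1^2) / k^2)
      } else {
        stop("GEV variance is infinite for kappa >= 0.5", call. = FALSE)
      }
    }
  )
}

#' Skewness of a density by quadrature
#'
#' Third standardized central moment computed by adaptive quadrature over
#' the support.  Used to locate the shape parameter at which the GEV
#' family's skewness changes sign.
#'
#' @param spec A [dist_spec] (for the GEV, requires `kappa < 1/3`).
#' @return Skewness (numeric scalar).
#' @export
dist_skewness <- function(spec) {
  dens <- function(x) ddist(spec, x)
  mom <- density_moments(dens, spec$support)
  m3 <- quad_integrate(function(x) (x - mom$mean)^3 * dens(x),
                       spec$support[1], spec$support[2],
                       what = "third central moment")
  m3 / mom$var^1.5
}

#' Locate the GEV shape at which skewness changes sign
#'
#' Root-finds the third standardized moment of the GEV family (computed by
#' quadrature) over an interval of the shape parameter.  The family has a
#' heavier left tail (negative skew) for shapes well below the root and a
#' heavier right tail above it.
#'
#' @param lower,upper Bracketing interval for the shape parameter.
#' @param tol Root-finding tolerance.
#' @return The shape parameter at the sign change (about -0.28).
#' @export
gev_skewness_zero <- function(lower = -0.5, upper = 0, tol = 1e-6) {
  f <- function(k) dist_skewness(dist_gev(k))
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Multivariate product-distribution datasets for ICA benchmarks
#'
#' Samples `N` observations of a `d`-dimensional product distribution whose
#' first axis carries a standardized non-Gaussian component and whose
#' remaining axes are independent standard normal.  Optionally applies a
#' seeded Haar-random orthogonal mixing matrix; the ground-truth unmixing
#' direction (the column of the mixing matrix carrying the non-Gaussian
#' axis) is recorded either way.
#'
#' @param spec A [dist_spec] for the non-Gaussian component.
#' @param d Dimension (>= 2).
#' @param N Number of observations.
#' @param rotate Apply a random orthogonal mixing matrix.
#' @param seed Integer seed (draws and rotation).
#' @return A `product_dataset`: list with `data` (N x d), `true_direction`
#'   (unit d-vector), `mixing` (d x d orthogonal), `spec`, `seed`.
#' @export
make_product_dataset <- function(spec, d = 2, N = 1e4, rotate = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), d >= 2, N >= 2)
  with_seed(seed, {
    mom <- dist_moments(spec)
    x1 <- (rdist(spec, N) - mom$mean) / sqrt(mom$var)
    data <- cbind(x1, matrix(stats::rnorm(N * (d - 1)), N, d - 1))
    colnames(data) <- NULL
    mixing <- diag(d)
    if (rotate) mixing <- random_orthogonal(d)
    data <- data %*% t(mixing)
    structure(
      list(data = data, true_direction = mixing[, 1], mixing = mixing,
           spec = spec, seed = seed),
      class = "product_dataset"
    )
  })
}

# Haar-uniform random orthogonal matrix (QR with positive-diagonal sign fix)
random_orthogonal <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d)
}

#' The five benchmark component distributions
#'
#' Named list of the non-Gaussian component distributions used in the 2-D
#' and 5-D unmixing benchmarks: bimodal symmetric (mixture, alpha = 0.5),
#' bimodal asymmetric (alpha = 0.7, second mode narrow), heavy-tailed
#' (generalized normal beta = 1), light-tailed (beta = 10), and unimodal
#' asymmetric (Gumbel, GEV shape 0).
#'
#' @return Named list of [dist_spec] objects.
#' @export
benchmark_specs <- function() {
  list(
    bimodal_symmetric = dist_mixture(0.5, -2, 1, 2, 1),
    bimodal_asymmetric = dist_mixture(0.7, -2, 1, 2, 0.4),
    heavy_tailed = dist_gnormal(1),
    light_tailed = dist_gnormal(10),
    unimodal_asymmetric = dist_gev(0)
  )
}
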