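#' FastICA contrast functionals
#'
#' Sample means of the three classical FastICA contrast integrands on a
#' standardized sample: the kurtosis-based `fastica_I`
#' \eqn{\frac{1}{4}E[X^4]}, and the two negentropy approximations
#' `fastica_II` \eqn{E[\log\cosh X]} and `fastica_III`
#' \eqn{E[-e^{-X^2/2}]}.
#'
#' @param name One of `"fastica_I"`, `"fastica_II"`, `"fastica_III"`.
#' @param x Standardized numeric sample (mean 0, SD 1).
#' @return Numeric scalar, the sample mean of the functional.
#' @export
fastica_contrast <- function(name = c("fastica_I", "fastica_II", "fastica_III"),
                             x) {
  name <- match.arg(name)
  stopifnot(is.numeric(x), length(x) >= 1L)
  switch(name,
    fastica_I = mean(x^4) / 4,
    fastica_II = mean(log(cosh(x))),
    fastica_III = mean(-exp(-x^2 / 2))
  )
}

# cache for Gaussian expectations of the contrast integrands
.contrast_cache <- new.env(parent = emptyenv())

#' Gaussian expectation of a FastICA contrast integrand
#'
#' The expectation of the contrast functional under the standard normal,
#' used to turn the raw functionals into deviation-from-Gaussian scores.
#' `fastica_I` has the closed form 3/4 (Gaussian fourth moment); the other
#' two are computed once by high-precision quadrature and cached.
#'
#' @inheritParams fastica_contrast
#' @return Numeric scalar.
#' @export
gaussian_reference <- function(name = c("fastica_I", "fastica_II",
                                        "fastica_III")) {
  name <- match.arg(name)
  if (name == "fastica_I") return(0.75)
  if (is.null(.contrast_cache[[name]])) {
    g <- switch(name,
      # log(cosh(x)) written stably as |x| + log1p(e^(-2|x|)) - log(2)
      fastica_II = function(x)
        (abs(x) + log1p(exp(-2 * abs(x))) - log(2)) * stats::dnorm(x),
      fastica_III = function(x) -exp(-x^2 / 2) * stats::dnorm(x)
    )
    .contrast_cache[[name]] <- quad_integrate(g, -Inf, Inf,
                                              what = paste("reference", name))
  }
  .contrast_cache[[name]]
}

#' Non-Gaussianity score of a standardized sample under a named contrast
#'
#' For `"j15"` (or any `j_n`) the score is the \eqn{J_n} statistic itself.
#' For the FastICA contrasts the score is the absolute deviation of the
#' sample functional from its standard-normal expectation, since those
#' functionals are non-monotone around the Gaussian value.
#'
#' @param x Numeric sample (standardized internally).
#' @param contrast Contrast name: `"j15"`, `"fastica_I"`, `"fastica_II"`,
#'   `"fastica_III"`.
#' @param n,variant Truncation order and order subset when the contrast is
#'   the Hermite measure.
#' @return Numeric scalar; larger means more non-Gaussian.
#' @export
contrast_score <- function(x, contrast, n = 15, variant = "all") {
  s <- pop_sd(x)
  if (s == 0) stop("zero-variance sample", call. = FALSE)
  z <- (x - mean(x)) / s
  if (contrast %in% c("j15", "j_n", "J")) {
    j_statistic(z, n = n, variant = variant, standardize = FALSE)$value
  } else {
    abs(fastica_contrast(contrast, z) - gaussian_reference(contrast))
  }
}

#' Standard normality-test statistics
#'
#' Runs five classical normality tests and reports each statistic oriented
#' so that larger values indicate stronger deviation from normality:
#' Kolmogorov-Smirnov \eqn{D} (against the normal fitted by sample mean and
#' SD), Anderson-Darling \eqn{A^2}, Jarque-Bera \eqn{JB}, D'Agostino
#' \eqn{K^2} and Shapiro-Wilk reported as \eqn{1 - W}.  Statistics (not
#' p-values) are the comparison quantity.
#'
#' Shapiro-Wilk is limited to 5000 observations; larger samples are
#' deterministically thinned to 5000 evenly spaced points (with a warning).
#' A test that fails on degenerate input yields `NA` with a warning.
#'
#' @param x Numeric sample, at least 20 observations.
#' @return A data.frame with columns `method` and `statistic`.
#' @export
normality_suite <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 20L) {
    stop("normality_suite needs at least 20 observations", call. = FALSE)
  }
  run <- function(f) {
    tryCatch(f(), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  ks <- run(function() {
    z <- (x - mean(x)) / stats::sd(x)
    unname(suppressWarnings(stats::ks.test(z, "pnorm"))$statistic)
  })
  ad <- run(function() unname(nortest::ad.test(x)$statistic))
  jb <- run(function() jarque_bera_stat(x))
  k2 <- run(function() dagostino_k2_stat(x))
  sw <- run(function() {
    y <- x
    if (length(y) > 5000L) {
      warning("Shapiro-Wilk limited to 5000 observations; using an evenly ",
              "spaced subsample", call. = FALSE)
      y <- y[round(seq(1, length(y), length.out = 5000L))]
    }
    1 - unname(stats::shapiro.test(y)$statistic)
  })
  data.frame(
    method = c("ks", "ad", "jb", "dagostino", "sw"),
    statistic = c(ks, ad, jb, k2, sw),
    stringsAsFactors = FALSE
  )
}

# Jarque-Bera statistic N/6 (g1^2 + (g2 - 3)^2 / 4) from the moment-based
# sample skewness g1 and kurtosis g2.
jarque_bera_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  n / 6 * (g1^2 + (g2 - 3)^2 / 4)
}

# D'Agostino K^2 omnibus statistic: sum of squared normalized transforms of
# sample skewness and kurtosis (D'Agostino-Belanger-D'Agostino).
dagostino_k2_stat <- function(x) {
  n <- length(x)
  if (n < 20) stop("D'Agostino K^2 requires n >= 20", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  z1^2 + z2^2
}

#' Normalize benchmark curves so the maximal mean is 1
#'
#' Within each method (and any further grouping columns supplied), all
#' replicate values are divided by the maximum over parameter values of the
#' per-parameter replicate mean, so that the maximum of the normalized mean
#' curve is exactly 1.  This puts methods with incommensurate raw scales on
#' a common ordinate for comparison plots.
#'
#' @param table Long-format data.frame with at least columns `param`,
#'   `method`, `value`.
#' @param by Character vector of grouping columns (default `"method"`; add
#'   e.g. `"family"` or `"N"` to normalize per panel).
#' @return The table with `value` replaced by its normalized version.
#' @export
normalize_curves <- function(table, by = "method") {
  stopifnot(all(c("param", "value", by) %in% names(table)))
  key <- interaction(table[by], drop = TRUE)
  for (g in levels(key)) {
    idx <- key == g
    means <- tapply(table$value[idx], table$param[idx], mean)
    mx <- max(means)
    if (!is.finite(mx) || mx == 0) {
      warning(sprintf("group '%s' has non-positive maximal mean; left ",
                      "unnormalized", g), call. = FALSE)
      next
    }
    table$value[idx] <- table$value[idx] / mx
  }
  table
}
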