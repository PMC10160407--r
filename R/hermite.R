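#' Physicists' Hermite polynomials
#'
#' Evaluates the Hermite polynomial \eqn{h_n(x)} in the physicists'
#' convention, i.e. orthogonal with respect to the weight \eqn{e^{-x^2}},
#' with \eqn{h_0 = 1}, \eqn{h_1(x) = 2x} and
#' \eqn{h_{n+1}(x) = 2 x h_n(x) - 2 n h_{n-1}(x)}.
#'
#' @param order Non-negative integer order.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of \eqn{h_{order}(x)}.
#' @examples
#' hermite_polynomial(2, 1)   # 4 x^2 - 2 = 2
#' @export
hermite_polynomial <- function(order, x) {
  check_order(order)
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (order == 0L) return(rep(1, length(x)))
  hkm1 <- rep(1, length(x))
  hk <- 2 * x
  if (order == 1L) return(hk)
  for (k in 1:(order - 1)) {
    hkp1 <- 2 * x * hk - 2 * k * hkm1
    hkm1 <- hk
    hk <- hkp1
  }
  hk
}

#' Orthonormal Hermite functions
#'
#' Evaluates the Hermite function
#' \eqn{H_n(x) = (2^n n! \sqrt{\pi})^{-1/2} e^{-x^2/2} h_n(x)},
#' an orthonormal basis of \eqn{L^2(\mathbb{R})} whose order-0 member is a
#' Gaussian.  Evaluation uses the stable normalized three-term recurrence
#' \eqn{H_{k+1}(x) = x\sqrt{2/(k+1)}\,H_k(x) - \sqrt{k/(k+1)}\,H_{k-1}(x)},
#' which avoids the factorial overflow of the direct formula at high order.
#'
#' @param order Non-negative integer order.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of \eqn{H_{order}(x)}.
#' @examples
#' hermite_function(0, 0)  # pi^(-1/4)
#' @export
hermite_function <- function(order, x) {
  check_order(order)
  hermite_basis(x, order)[, order + 1L]
}

#' Hermite-function basis matrix
#'
#' Evaluates all Hermite functions \eqn{H_0 \ldots H_{max\_order}} at each
#' point of `x` by the stable normalized recurrence.
#'
#' @param x Numeric vector of evaluation points.
#' @param max_order Highest order to evaluate.
#' @return A `length(x)` by `max_order + 1` matrix; column `k` holds
#'   \eqn{H_{k-1}(x)}.
#' @export
hermite_basis <- function(x, max_order) {
  check_order(max_order)
  stopifnot(is.numeric(x), all(is.finite(x)))
  hermite_basis_cpp(as.numeric(x), as.integer(max_order))
}

# Derivative matrix dH_k/dx for k = 0..max_order, via
# H_k' = sqrt(k/2) H_{k-1} - sqrt((k+1)/2) H_{k+1}.
hermite_basis_deriv <- function(x, max_order) {
  H <- hermite_basis(x, max_order + 1L)
  D <- matrix(0, length(x), max_order + 1L)
  for (k in 0:max_order) {
    lower <- if (k >= 1L) sqrt(k / 2) * H[, k] else 0
    D[, k + 1L] <- lower - sqrt((k + 1) / 2) * H[, k + 2L]
  }
  D
}

# Direct-formula evaluation of H_n (Gaussian envelope times polynomial over
# sqrt(2^n n! sqrt(pi))).  Overflow-prone for n beyond ~60; retained as an
# independent oracle for the recurrence.
hermite_function_direct <- function(order, x) {
  check_order(order)
  norm <- sqrt(2^order * factorial(order) * sqrt(pi))
  exp(-x^2 / 2) * hermite_polynomial(order, x) / norm
}

check_order <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order < 0 || order != floor(order)) {
    stop("'order' must be a single non-negative integer", call. = FALSE)
  }
  invisible(TRUE)
}
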