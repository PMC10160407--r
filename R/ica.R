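#' Whiten a data matrix
#'
#' Centers the data and applies the PCA whitening transform so the output
#' has identity covariance.  The forward (`k x d`) and backward (`d x k`)
#' transforms are recorded so directions and components can be mapped
#' between the whitened and original spaces.  Eigenvalues below
#' `tol * max(eigenvalue)` are dropped (dimension reduction) with a warning.
#'
#' @param X Numeric matrix, rows are observations.
#' @param tol Relative eigenvalue tolerance for rank detection.
#' @param reduce Drop near-null directions instead of failing.
#' @return A `whitening` object: `Z` (whitened data), `forward`, `backward`,
#'   `center`, `rank`.
#' @export
whiten <- function(X, tol = 1e-10, reduce = TRUE) {
  X <- as.matrix(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  covm <- crossprod(Xc) / nrow(Xc)
  eig <- eigen(covm, symmetric = TRUE)
  keep <- eig$values > tol * max(eig$values)
  if (!all(keep)) {
    if (!reduce) stop("covariance is rank deficient", call. = FALSE)
    warning(sprintf("dropping %d near-null dimension(s) during whitening",
                    sum(!keep)), call. = FALSE)
  }
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  forward <- diag(1 / sqrt(vals), length(vals)) %*% t(vecs)
  backward <- vecs %*% diag(sqrt(vals), length(vals))
  structure(
    list(Z = Xc %*% t(forward), forward = forward, backward = backward,
         center = center, rank = sum(keep)),
    class = "whitening"
  )
}

#' Map a direction from the original space into the whitened space
#'
#' Applies the forward whitening transform to a direction and renormalizes
#' it to unit length, so ground-truth mixing columns can be compared with
#' whitened-space unmixing estimates.
#'
#' @param w A [whiten()] result.
#' @param direction Numeric vector in the original space.
#' @return Unit vector in the whitened space.
#' @export
to_whitened_direction <- function(w, direction) {
  v <- drop(w$forward %*% direction)
  v / sqrt(sum(v^2))
}

#' Angle between two unmixing directions
#'
#' The angle \eqn{\arccos(|u \cdot v|)} in degrees.  The absolute value
#' reflects the sign ambiguity of ICA components: `u` and `-u` describe the
#' same component, so the error of a flipped estimate is 0, and the maximum
#' possible error is 90 degrees.
#'
#' @param u,v Unit vectors of equal length.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
error_angle <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  d <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, d)) * 180 / pi
}

#' Angular variance of a set of estimated directions
#'
#' Computes \eqn{1 - R} where \eqn{R} is the length of the mean of the unit
#' direction vectors, after aligning each member's sign with a reference
#' direction (members with negative dot product against the reference are
#' flipped, reflecting the ICA sign ambiguity).  0 for identical
#' directions; approaches 1 for directions scattered over the sphere.
#'
#' @param members Matrix whose rows are unit d-vectors (or a single vector).
#' @param reference Unit d-vector used for sign alignment.
#' @return Angular variance in `[0, 1]`.
#' @export
angular_variance <- function(members, reference) {
  if (is.null(dim(members))) members <- matrix(members, nrow = 1)
  norms <- sqrt(rowSums(members^2))
  if (any(norms == 0)) stop("zero vector among members", call. = FALSE)
  members <- members / norms
  signs <- sign(drop(members %*% reference))
  signs[signs == 0] <- 1
  aligned <- members * signs
  1 - sqrt(sum(colMeans(aligned)^2))
}

#' Project data on a direction and score its non-Gaussianity
#'
#' Projects rows of `data` onto a unit direction, standardizes the
#' projection, and evaluates the chosen contrast ([contrast_score()]:
#' \eqn{J_n} directly, FastICA functionals as deviation from their Gaussian
#' expectation).
#'
#' @param data Numeric matrix (rows = observations).
#' @param direction Unit vector of length `ncol(data)`.
#' @param contrast Contrast name (see [contrast_score()]).
#' @param n,variant Hermite truncation order and order subset.
#' @return Numeric score; larger = more non-Gaussian.
#' @export
project_and_score <- function(data, direction, contrast = "j15", n = 15,
                              variant = "all") {
  y <- drop(as.matrix(data) %*% direction)
  contrast_score(y, contrast, n = n, variant = variant)
}

new_unmixing_estimate <- function(direction, contrast_name, contrast_value,
                                  restarts_used = 1L, converged = TRUE,
                                  iterations = 0L) {
  structure(
    list(direction = direction / sqrt(sum(direction^2)),
         contrast_name = contrast_name, contrast_value = contrast_value,
         restarts_used = restarts_used, converged = converged,
         iterations = iterations),
    class = "unmixing_estimate"
  )
}

#' @export
print.unmixing_estimate <- function(x, ...) {
  cat(sprintf("unmixing estimate (%s = %.5g, %s, %d iteration(s))\n",
              x$contrast_name, x$contrast_value,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("direction:", format(round(x$direction, 4)), "\n")
  invisible(x)
}

#' Exhaustive angular search for the most non-Gaussian 2-D projection
#'
#' Scores projections of a 2-D dataset over angles 0-179 degrees at a
#' coarse step, then refines around the best angle at a fine step (adaptive
#' step size from `coarse_step` down to `fine_step`).  The coarse score
#' profile is retained for precision analysis (peak width).
#'
#' @param data N x 2 matrix.
#' @param contrast Contrast name.
#' @param coarse_step,fine_step Step sizes in degrees.
#' @param n,variant Hermite options when `contrast` is `"j15"`.
#' @return List with `estimate` (an `unmixing_estimate`), `angle` (best
#'   angle, degrees), and `profile` (data.frame `angle`, `score` on the
#'   coarse grid).
#' @export
exhaustive_search_2d <- function(data, contrast = "j15", coarse_step = 1,
                                 fine_step = 0.1, n = 15, variant = "all") {
  data <- as.matrix(data)
  if (ncol(data) != 2L) stop("exhaustive_search_2d needs 2-D data",
                             call. = FALSE)
  score_at <- function(theta) {
    rad <- theta * pi / 180
    project_and_score(data, c(cos(rad), sin(rad)), contrast, n, variant)
  }
  coarse <- seq(0, 180 - coarse_step, by = coarse_step)
  cs <- vapply(coarse, score_at, numeric(1))
  best <- coarse[which.max(cs)]
  fine <- seq(best - coarse_step, best + coarse_step, by = fine_step)
  fs <- vapply(fine, score_at, numeric(1))
  theta <- fine[which.max(fs)]
  rad <- theta * pi / 180
  est <- new_unmixing_estimate(c(cos(rad), sin(rad)), contrast, max(fs))
  list(estimate = est, angle = theta %% 180,
       profile = data.frame(angle = coarse, score = cs))
}

#' Angular error of J_n variants over truncation orders
#'
#' For a 2-D dataset whose true non-Gaussian axis is known, searches a
#' fine grid around the true axis (0.1-degree steps within 2 degrees,
#' 0.5-degree steps out to 10 degrees) augmented by a 1-degree coarse grid
#' over the remaining half-circle (so an uninformative variant is free to
#' land anywhere, not just inside the fine window), and records, for every
#' truncation order and order-subset variant, the signed angular error of
#' the best direction.  All scores for one angle reuse a single
#' coefficient-vector evaluation, so the full order sweep costs little more
#' than a single \eqn{J_n} search.
#'
#' @param data N x 2 matrix.
#' @param true_angle Angle (degrees) of the true non-Gaussian axis.
#' @param n_values Integer vector of truncation orders.
#' @param variants Subset variants to evaluate.
#' @return data.frame with columns `n`, `variant`, `error_deg` (signed),
#'   `best_angle`.
#' @export
order_study_search <- function(data, true_angle, n_values = 2:50,
                               variants = c("all", "even", "odd")) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == 2L)
  offsets <- c(seq(-10, -2.5, by = 0.5), seq(-2, 2, by = 0.1),
               seq(2.5, 10, by = 0.5),
               seq(-89, -11, by = 1), seq(11, 90, by = 1))
  angles <- true_angle + offsets
  nmax <- max(n_values)
  coef_mat <- t(vapply(angles, function(theta) {
    rad <- theta * pi / 180
    y <- drop(data %*% c(cos(rad), sin(rad)))
    s <- pop_sd(y)
    if (s == 0) return(rep(NA_real_, nmax + 1L))
    hermite_coef_means_cpp((y - mean(y)) / s, nmax)
  }, numeric(nmax + 1L)))
  orders <- 0:nmax
  out <- expand.grid(n = n_values, variant = variants,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(n, variant) {
    keep <- switch(variant,
      all = orders <= n,
      even = orders <= n & orders %% 2L == 0L,
      odd = orders <= n & (orders %% 2L == 1L | orders == 0L)
    )
    denom <- rowSums(coef_mat[, keep, drop = FALSE]^2)
    j <- 1 - coef_mat[, 1]^2 / denom
    offsets[which.max(j)]
  }, out$n, out$variant)
  out$error_deg <- res
  out$best_angle <- true_angle + res
  out
}

# Gradient of J_n with respect to the projection direction w, including the
# standardization of the projection.  X rows are observations.
j_gradient <- function(X, w, n = 15, variant = "all") {
  z <- drop(X %*% w)
  m <- mean(z)
  s <- pop_sd(z)
  if (s == 0) stop("zero-variance projection", call. = FALSE)
  y <- (z - m) / s
  H <- hermite_basis(y, n + 1L)
  a <- colMeans(H[, 1:(n + 1L), drop = FALSE])
  orders <- 0:n
  keep <- switch(variant,
    all = rep(TRUE, n + 1L),
    even = orders %% 2L == 0L,
    odd = orders %% 2L == 1L | orders == 0L
  )
  S <- sum(a[keep]^2)
  a0 <- a[1]
  # dJ/da_i over the kept subset
  wts <- numeric(n + 1L)
  wts[keep] <- 2 * a0^2 * a[keep] / S^2
  wts[1] <- 2 * a0^3 / S^2 - 2 * a0 / S
  # dH_k/dx = sqrt(k/2) H_{k-1} - sqrt((k+1)/2) H_{k+1}: fold the
  # coefficient weights into one vector over basis columns 0..n+1
  v <- numeric(n + 2L)
  for (k in orders[keep]) {
    if (k >= 1L) v[k] <- v[k] + wts[k + 1L] * sqrt(k / 2)
    v[k + 2L] <- v[k + 2L] - wts[k + 1L] * sqrt((k + 1) / 2)
  }
  cvec <- drop(H %*% v)
  N <- nrow(X)
  xbar <- colMeans(X)
  ds <- drop(crossprod(X, y)) / N
  grad <- (drop(crossprod(X, cvec)) / N - mean(cvec) * xbar -
             mean(cvec * y) * ds) / s
  list(value = 1 - a0^2 / S, gradient = grad)
}

# Project a vector onto the orthogonal complement of the columns of B and
# renormalize; B may be NULL.
orth_project <- function(v, B) {
  if (!is.null(B) && ncol(B) > 0) v <- v - B %*% crossprod(B, v)
  v <- drop(v)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NULL)
  v / nv
}

# One-unit J_n search by projected gradient ascent on the unit sphere with a
# time-based learning schedule eta_t = eta0 / (1 + t / tau).
j_one_unit <- function(Z, w0, B, n, variant, schedule) {
  w <- orth_project(w0, B)
  iter <- 0L
  converged <- FALSE
  val_prev <- -Inf
  stall <- 0L
  while (iter < schedule$max_iter) {
    iter <- iter + 1L
    jg <- j_gradient(Z, w, n = n, variant = variant)
    g <- jg$gradient
    g <- g - sum(g * w) * w                       # tangent to the sphere
    if (!is.null(B) && ncol(B) > 0) g <- g - drop(B %*% crossprod(B, g))
    eta <- schedule$eta0 / (1 + iter / schedule$tau)
    w_new <- orth_project(w + eta * g, B)
    if (is.null(w_new)) break
    delta <- acos(min(1, abs(sum(w_new * w))))
    w <- w_new
    if (delta < schedule$tol) {
      converged <- TRUE
      break
    }
    # the decaying step can leave the direction oscillating around a sharp
    # maximum; treat a stalled contrast value as convergence as well
    stall <- if (abs(jg$value - val_prev) < schedule$val_tol) stall + 1L
    else 0L
    val_prev <- jg$value
    if (stall >= 3L) {
      converged <- TRUE
      break
    }
  }
  list(w = w, converged = converged, iterations = iter)
}

# FastICA one-unit fixed-point iteration with deflationary orthogonalization
# against the columns of B.  g is the derivative of the contrast integrand.
fastica_one_unit <- function(Z, w0, B, contrast, max_iter = 200, tol = 1e-6) {
  gfun <- switch(contrast,
    fastica_I = list(g = function(y) y^3, dg = function(y) 3 * y^2),
    fastica_II = list(g = function(y) tanh(y),
                      dg = function(y) 1 - tanh(y)^2),
    fastica_III = list(g = function(y) y * exp(-y^2 / 2),
                       dg = function(y) (1 - y^2) * exp(-y^2 / 2))
  )
  w <- orth_project(w0, B)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    y <- drop(Z %*% w)
    w_new <- drop(crossprod(Z, gfun$g(y))) / nrow(Z) - mean(gfun$dg(y)) * w
    w_new <- orth_project(w_new, B)
    if (is.null(w_new)) break
    delta <- 1 - abs(sum(w_new * w))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, converged = converged, iterations = iter)
}

#' Deflationary search for maximally non-Gaussian components
#'
#' Extracts `n_components` one-dimensional components from whitened data,
#' one at a time, each constrained to the orthogonal complement of the
#' components already found (deflation).  The Hermite contrast \eqn{J_n} is
#' maximized by projected gradient ascent on the unit sphere with a
#' time-based learning schedule \eqn{\eta_t = \eta_0/(1 + t/\tau)}; the
#' FastICA contrasts use the standard one-unit fixed-point iteration.  Each
#' component is restarted from `restarts` seeded random unit vectors and
#' the restart with the largest contrast score is kept (ties broken by
#' restart order).
#'
#' @param Z Whitened data matrix (rows = observations, identity
#'   covariance); see [whiten()].
#' @param contrast `"j15"`, `"fastica_I"`, `"fastica_II"` or
#'   `"fastica_III"`.
#' @param n_components Number of components to extract.
#' @param restarts Random restarts per component.
#' @param schedule List of gradient-ascent controls: `eta0` (initial step),
#'   `tau` (decay time), `max_iter`, `tol` (radians of direction change),
#'   `val_tol` (contrast-value stall tolerance).
#' @param seed Integer seed for the random starts.
#' @param n,variant Hermite options for the `"j15"` contrast.
#' @return List of `unmixing_estimate` objects (directions in whitened
#'   space, mutually orthogonal).
#' @export
deflation_search <- function(Z, contrast = "j15", n_components = 1,
                             restarts = 25,
                             schedule = list(eta0 = 0.5, tau = 50,
                                             max_iter = 500, tol = 1e-4,
                                             val_tol = 1e-9),
                             seed = NULL, n = 15, variant = "all") {
  Z <- as.matrix(Z)
  d <- ncol(Z)
  stopifnot(n_components >= 1, n_components <= d)
  schedule <- utils::modifyList(
    list(eta0 = 0.5, tau = 50, max_iter = 500, tol = 1e-4, val_tol = 1e-9),
    schedule)
  B <- NULL
  out <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    best <- NULL
    any_converged <- FALSE
    for (r in seq_len(restarts)) {
      w0 <- with_seed(
        if (is.null(seed)) NULL else child_seed(seed, comp, r),
        stats::rnorm(d)
      )
      fit <- if (contrast == "j15") {
        j_one_unit(Z, w0, B, n, variant, schedule)
      } else {
        fastica_one_unit(Z, w0, B, contrast)
      }
      if (is.null(fit$w)) next
      val <- project_and_score(Z, fit$w, contrast, n, variant)
      any_converged <- any_converged || fit$converged
      if (is.null(best) || val > best$val) {
        best <- list(w = fit$w, val = val, converged = fit$converged,
                     iterations = fit$iterations, restart = r)
      }
    }
    if (is.null(best)) stop("all restarts failed", call. = FALSE)
    if (!best$converged) {
      warning(sprintf("component %d: best restart did not converge", comp),
              call. = FALSE)
    }
    out[[comp]] <- new_unmixing_estimate(
      best$w, contrast, best$val, restarts_used = restarts,
      converged = best$converged, iterations = best$iterations)
    B <- cbind(B, out[[comp]]$direction)
  }
  out
}

#' Select the best direction for a contrast across candidate sets
#'
#' Evaluates a contrast at every candidate direction -- typically the best
#' directions found by extremizing each of several contrast functions -- and
#' returns the candidate at which this contrast attains its maximum.  This
#' guards each contrast against convergence failures of its own search: a
#' direction found by another contrast is adopted whenever it scores
#' higher.
#'
#' @param data Data matrix the candidates refer to (whitened space).
#' @param candidates List of `unmixing_estimate` objects (any contrasts).
#' @param contrast The contrast to maximize.
#' @param n,variant Hermite options.
#' @return The winning candidate, re-labelled with this contrast and its
#'   re-evaluated score.
#' @export
cross_contrast_select <- function(data, candidates, contrast = "j15",
                                  n = 15, variant = "all") {
  stopifnot(length(candidates) >= 1)
  vals <- vapply(candidates, function(cd) {
    project_and_score(data, cd$direction, contrast, n, variant)
  }, numeric(1))
  best <- which.max(vals)
  win <- candidates[[best]]
  new_unmixing_estimate(win$direction, contrast, vals[best],
                        restarts_used = win$restarts_used,
                        converged = win$converged,
                        iterations = win$iterations)
}

#' Precision (peak half-width) from a replicate score profile
#'
#' Given per-angle means and SDs of a non-Gaussianity profile over
#' replicates, returns the smallest angular deviation from the peak at
#' which the score band first reliably separates from the peak band:
#' mean(theta) + 2 SD(theta) < mean(peak) - 2 SD(peak).  A flat profile
#' whose bands never separate returns the half-range with `flagged = TRUE`.
#'
#' @param profile data.frame with columns `angle`, `mean`, `sd`.
#' @return List: `half_width` (degrees), `peak_angle`, `flagged`.
#' @export
precision_from_profile <- function(profile) {
  stopifnot(all(c("angle", "mean", "sd") %in% names(profile)))
  i0 <- which.max(profile$mean)
  peak_lo <- profile$mean[i0] - 2 * profile$sd[i0]
  sep <- profile$mean + 2 * profile$sd < peak_lo
  dtheta <- abs(profile$angle - profile$angle[i0])
  if (!any(sep)) {
    half_range <- (max(profile$angle) - min(profile$angle)) / 2
    return(list(half_width = half_range, peak_angle = profile$angle[i0],
                flagged = TRUE))
  }
  list(half_width = min(dtheta[sep]), peak_angle = profile$angle[i0],
       flagged = FALSE)
}
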