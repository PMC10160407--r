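#' Hermite-function independent component analysis
#'
#' Fits a deflationary ICA model by maximizing the Hermite-function
#' non-Gaussianity measure \eqn{J_n} (or one of the classical FastICA
#' contrasts) over one-dimensional projections of the whitened data.
#' Components are extracted sequentially, each orthogonal (in whitened
#' space) to those already found.
#'
#' The model is the usual noiseless linear ICA model \eqn{x = A s}: the
#' observed rows of `X` are linear mixtures of independent sources, at most
#' one of which may be Gaussian.  Each source is recovered by the unit
#' direction in whitened space whose projection is maximally non-Gaussian
#' under the chosen contrast.
#'
#' @param X Numeric matrix (rows = observations, columns = channels).
#' @param n.comp Number of components to extract (default: all).
#' @param contrast `"j15"` (Hermite measure, the default), `"fastica_I"`
#'   (kurtosis), `"fastica_II"` (log-cosh) or `"fastica_III"` (Gaussian).
#' @param n,variant Truncation order and order subset of the Hermite
#'   measure.
#' @param restarts Random restarts per component.
#' @param schedule Gradient-ascent schedule for the Hermite contrast; see
#'   [deflation_search()].
#' @param seed Integer seed for the random restarts.
#' @return An object of class `"hfica"` with elements `W` (n.comp x d
#'   unmixing matrix in the original space), `directions` (whitened-space
#'   unit vectors, one row per component), `S` (recovered sources, N x
#'   n.comp), `A` (d x n.comp estimated mixing columns), `scores`
#'   (per-component contrast values), `whitening`, and the call.
#' @examples
#' set.seed(7)
#' ds <- make_product_dataset(dist_gnormal(1), d = 3, N = 2000,
#'                            rotate = TRUE, seed = 7)
#' fit <- hfica(ds$data, n.comp = 1, restarts = 4, seed = 1)
#' error_angle(fit$directions[1, ],
#'             to_whitened_direction(fit$whitening, ds$true_direction))
#' @export
hfica <- function(X, n.comp = NULL, contrast = c("j15", "fastica_I",
                                                 "fastica_II", "fastica_III"),
                  n = 15, variant = "all", restarts = 25,
                  schedule = list(), seed = NULL) {
  contrast <- match.arg(contrast)
  X <- as.matrix(X)
  w <- whiten(X)
  d <- w$rank
  if (is.null(n.comp)) n.comp <- d
  stopifnot(n.comp >= 1, n.comp <= d)
  ests <- deflation_search(w$Z, contrast = contrast, n_components = n.comp,
                           restarts = restarts, schedule = schedule,
                           seed = seed, n = n, variant = variant)
  dirs <- do.call(rbind, lapply(ests, `[[`, "direction"))
  W <- dirs %*% w$forward                 # unmixing rows in original space
  S <- w$Z %*% t(dirs)
  A <- w$backward %*% t(dirs)             # estimated mixing columns
  structure(
    list(W = W, directions = dirs, S = S, A = A,
         scores = vapply(ests, `[[`, numeric(1), "contrast_value"),
         converged = vapply(ests, `[[`, logical(1), "converged"),
         iterations = vapply(ests, `[[`, integer(1), "iterations"),
         contrast = contrast, n = n, variant = variant,
         whitening = w, estimates = ests, call = match.call()),
    class = "hfica"
  )
}

#' @export
print.hfica <- function(x, ...) {
  cat("Hermite-function ICA fit\n")
  cat(sprintf("  contrast: %s%s\n", x$contrast,
              if (x$contrast == "j15")
                sprintf(" (n = %d, %s orders)", x$n, x$variant) else ""))
  cat(sprintf("  components: %d of %d whitened dimension(s)\n",
              nrow(x$W), x$whitening$rank))
  cat("  contrast values:", format(signif(x$scores, 4)), "\n")
  if (!all(x$converged)) {
    cat("  warning:", sum(!x$converged), "component(s) did not converge\n")
  }
  invisible(x)
}

#' @export
summary.hfica <- function(object, ...) {
  df <- data.frame(
    component = seq_along(object$scores),
    contrast_value = object$scores,
    kurtosis = apply(object$S, 2, function(s) mean(s^4) / mean(s^2)^2 - 3),
    converged = object$converged,
    iterations = object$iterations
  )
  structure(list(table = df, contrast = object$contrast), class = "summary.hfica")
}

#' @export
print.summary.hfica <- function(x, ...) {
  cat(sprintf("hfica components (contrast %s):\n", x$contrast))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.hfica <- function(object, ...) object$W

#' Recover sources from new observations
#'
#' Applies the fitted unmixing transform (centering from the training data,
#' then the unmixing matrix) to new rows.
#'
#' @param object A fitted `hfica` model.
#' @param newdata Matrix with the same number of columns as the training
#'   data; defaults to the training sources.
#' @param ... Unused.
#' @return Matrix of recovered source signals.
#' @export
predict.hfica <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$S)
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$whitening$center) %*% t(object$W)
}

#' Plot recovered sources
#'
#' One panel per extracted component, drawn as a time/index trace.
#'
#' @param x A fitted `hfica` model.
#' @param max_points Thin traces to at most this many points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hfica <- function(x, max_points = 2000, ...) {
  k <- ncol(x$S)
  old <- graphics::par(mfrow = c(k, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  idx <- if (nrow(x$S) > max_points) {
    round(seq(1, nrow(x$S), length.out = max_points))
  } else seq_len(nrow(x$S))
  for (j in seq_len(k)) {
    graphics::plot(idx, x$S[idx, j], type = "l",
                   ylab = sprintf("IC %d", j), xlab = "", ...)
  }
  invisible(x)
}
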