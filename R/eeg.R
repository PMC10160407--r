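#' Simulate multichannel EEG with ground-truth ocular artifacts
#'
#' Generates a synthetic channels x samples EEG recording as a linear
#' mixture of sources plus white sensor noise, with full ground truth
#' recorded.  Two ocular-artifact sources (one per eye) are quasi-periodic
#' trains of stereotyped ~300 ms raised-cosine-squared blink pulses with
#' large amplitude and frontal, laterally offset scalp topographies; the
#' heavy-tailed (high-kurtosis) blink time courses are what a
#' non-Gaussianity-seeking ICA exploits.  Background sources are
#' band-limited Gaussian processes mixed through smooth random
#' topographies on a virtual scalp grid.
#'
#' This generator is a deliberately simplified surrogate for a
#' volume-conduction head-model simulator: it reproduces the statistical
#' features the artifact-extraction method relies on (spatially fixed
#' topographies, heavy-tailed artifact sources, Gaussian-like background)
#' but not the biophysics of a realistic head model.
#'
#' @param duration_s Recording length in seconds (>= 6).
#' @param fs Sampling rate in Hz (default 250).
#' @param channels Number of electrodes (default 249; >= 8).
#' @param n_background Number of background sources.
#' @param blink_rate_hz Mean blink rate per eye (default 0.25 Hz, i.e. one
#'   blink roughly every 4 s, jittered).
#' @param blink_snr Root-mean-square amplitude of each blink source
#'   relative to a background source (default 10).
#' @param noise_sd Sensor-noise SD relative to background source RMS.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param store_noise Keep the sensor-noise realization in the object
#'   (memory-heavy for long recordings; useful for reconstruction checks).
#' @return An `eeg_dataset`: `data` (channels x samples), `fs`, `mixing`
#'   (channels x sources, blink columns first), `sources` (sources x
#'   samples), `artifact_source_indices = c(1, 2)`, `seed`.
#' @export
simulate_eeg <- function(duration_s, fs = 250, channels = 249,
                         n_background = 20, blink_rate_hz = 0.25,
                         blink_snr = 10, noise_sd = 0.05, seed = NULL,
                         store_noise = FALSE) {
  stopifnot(duration_s >= 6, channels >= 8, n_background >= 1)
  n <- round(duration_s * fs)
  with_seed(seed, {
    # virtual scalp: channels on a roughly square grid in [0,1]^2,
    # y = 1 is the front of the head
    ng <- ceiling(sqrt(channels))
    gx <- (seq_len(channels) - 1) %% ng / max(1, ng - 1)
    gy <- (seq_len(channels) - 1) %/% ng / max(1, ng - 1)

    blob <- function(cx, cy, width) {
      v <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * width^2))
      v / sqrt(sum(v^2))
    }

    # frontal, laterally offset blink topographies (left / right eye):
    # steep dipolar pattern (strong positive lobe at the front edge, weaker
    # negative return just behind), the characteristic ocular signature
    # that distinguishes eye artifacts from broad cortical topographies
    blink_topo <- function(cx) {
      v <- blob(cx, 1, 0.15) - 0.5 * blob(cx, 0.55, 0.25)
      v / sqrt(sum(v^2))
    }
    topo_blink <- cbind(blink_topo(0.35), blink_topo(0.65))

    # smooth random background topographies: sums of random Gaussian
    # blobs, projected onto the orthogonal complement of the ocular
    # topographies so that the artifact subspace is identifiable and the
    # specificity of artifact matching can be assessed against ground truth
    topo_bg <- vapply(seq_len(n_background), function(i) {
      v <- rowSums(vapply(1:3, function(b) {
        stats::rnorm(1) * blob(stats::runif(1), stats::runif(1),
                               stats::runif(1, 0.15, 0.4)) * sqrt(channels)
      }, numeric(channels)))
      v <- v - topo_blink %*% solve(crossprod(topo_blink),
                                    crossprod(topo_blink, v))
      v / sqrt(sum(v^2))
    }, numeric(channels))

    blink_train <- function() {
      src <- numeric(n)
      width <- round(0.3 * fs)               # ~300 ms blink
      half <- width / 2
      t0 <- stats::runif(1, 0, 1 / blink_rate_hz)
      while (t0 < duration_s) {
        center <- round(t0 * fs)
        idx <- max(1, center - half):min(n, center + half)
        u <- (idx - center) / width          # in [-0.5, 0.5]
        amp <- stats::runif(1, 0.8, 1.2)
        src[idx] <- src[idx] + amp * cos(pi * u)^2
        t0 <- t0 + stats::runif(1, 0.6, 1.4) / blink_rate_hz
      }
      if (blink_snr == 0) return(numeric(n))   # artifact-free control
      src / sqrt(mean(src^2)) * blink_snr
    }
    s_blink <- rbind(blink_train(), blink_train())

    # band-limited Gaussian background: moving-average-smoothed white noise
    win <- max(3L, round(fs / 10))
    kern <- rep(1 / win, win)
    s_bg <- t(vapply(seq_len(n_background), function(i) {
      v <- stats::filter(stats::rnorm(n + win), kern, sides = 2)
      v <- as.numeric(v[!is.na(v)])[1:n]
      v / sqrt(mean(v^2))
    }, numeric(n)))

    sources <- rbind(s_blink, s_bg)
    mixing <- cbind(topo_blink, topo_bg)
    noise <- matrix(stats::rnorm(channels * n, sd = noise_sd), channels, n)
    data <- mixing %*% sources + noise
    structure(
      list(data = data, fs = fs, channels = channels, mixing = mixing,
           sources = sources, artifact_source_indices = c(1L, 2L),
           seed = seed, noise_sd = noise_sd,
           noise = if (store_noise) noise else NULL),
      class = "eeg_dataset"
    )
  })
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("synthetic EEG: %d channels x %d samples (%.1f s at %g Hz), ",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat(sprintf("%d sources (2 ocular)\n", nrow(x$sources)))
  invisible(x)
}

#' PCA dimensionality reduction of an EEG dataset
#'
#' Projects the channel dimension onto the top `k` principal components
#' (the standard pre-ICA reduction step), recording the loading matrix,
#' the explained-variance fraction and the channel means for
#' back-projection.
#'
#' @param dataset An [simulate_eeg()] result, or a channels x samples
#'   matrix.
#' @param k Number of components to keep.
#' @return List: `scores` (samples x k), `loadings` (channels x k,
#'   orthonormal columns), `center`, `explained` (fraction of variance),
#'   `k`.
#' @export
pca_reduce <- function(dataset, k = 50) {
  data <- if (inherits(dataset, "eeg_dataset")) dataset$data else dataset
  X <- t(data)                               # samples x channels
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; reduced", k, rank),
            call. = FALSE)
    k <- rank
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  list(scores = Xc %*% loadings, loadings = loadings, center = center,
       explained = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2), k = k)
}

#' Extract ICA components and match them to ocular-artifact ground truth
#'
#' Whitens the PCA-reduced data and runs [deflation_search()] for
#' `n_components` components.  Each extracted component's estimated
#' topography (its unmixing direction mapped back through the whitening
#' transform, i.e. its mixing column in the reduced space) is compared with
#' the true blink topography projected into the reduced space; for each
#' eye the component with maximal absolute cosine is matched, and the
#' error is the angle between the matched and true directions in the
#' reduced space.  Automated ground-truth matching replaces the visual
#' inspection a human analyst would perform on real data.
#'
#' @param red A [pca_reduce()] result.
#' @param truth The generating [simulate_eeg()] dataset.
#' @param contrast Contrast name for the component search.
#' @param n_components Number of components to extract (default 20).
#' @param restarts,schedule,seed,n,variant Passed to [deflation_search()].
#' @return An `artifact_recovery` data.frame: one row per eye with
#'   `matched_component`, `error_deg` and `match_cos`.
#' @export
extract_and_match <- function(red, truth, contrast = "j15",
                              n_components = 20, restarts = 25,
                              schedule = list(), seed = NULL, n = 15,
                              variant = "all") {
  stopifnot(inherits(truth, "eeg_dataset"))
  if (n_components < 2) stop("need at least 2 components", call. = FALSE)
  n_components <- min(n_components, red$k)
  w <- whiten(red$scores)
  ests <- deflation_search(w$Z, contrast = contrast,
                           n_components = n_components, restarts = restarts,
                           schedule = schedule, seed = seed, n = n,
                           variant = variant)
  dirs <- do.call(rbind, lapply(ests, `[[`, "direction"))
  # estimated mixing columns (topographies) in the reduced space
  topo <- w$backward %*% t(dirs)
  topo <- sweep(topo, 2, sqrt(colSums(topo^2)), "/")
  out <- do.call(rbind, lapply(seq_along(truth$artifact_source_indices),
    function(e) {
      src <- truth$artifact_source_indices[e]
      v <- drop(crossprod(red$loadings, truth$mixing[, src]))
      v <- v / sqrt(sum(v^2))
      cosines <- abs(drop(crossprod(topo, v)))
      best <- which.max(cosines)
      data.frame(eye = e, matched_component = best,
                 error_deg = error_angle(topo[, best], v),
                 match_cos = cosines[best])
    }))
  class(out) <- c("artifact_recovery", class(out))
  attr(out, "contrast") <- contrast
  out
}
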