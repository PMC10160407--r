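#' Build a parametric family grid for the 1-D benchmark
#'
#' @param family `"mixture"` (bimodal, symmetric modes at -2 and 2),
#'   `"gnormal"` or `"gev"`.
#' @param params Numeric vector of family parameter values
#'   (alpha, beta or kappa).
#' @return Named list of [dist_spec] objects keyed by parameter value.
#' @export
family_grid <- function(family = c("mixture", "gnormal", "gev"), params) {
  family <- match.arg(family)
  make <- switch(family,
    mixture = function(a) dist_mixture(a, -2, 1, 2, 1),
    gnormal = dist_gnormal,
    gev = dist_gev
  )
  stats::setNames(lapply(params, make), params)
}

.default_methods <- c("j15", "ks", "ad", "jb", "dagostino", "sw",
                      "fastica_I", "fastica_II", "fastica_III")

# score one sample under one named method
score_method <- function(x, method) {
  if (method %in% c("j15", "fastica_I", "fastica_II", "fastica_III")) {
    contrast_score(x, method)
  } else {
    suppressWarnings({
      tab <- normality_suite(x)
      tab$statistic[tab$method == method]
    })
  }
}

#' 1-D sensitivity benchmark over a distribution family
#'
#' For each family parameter, sample size and replicate, draws a sample and
#' scores it with the Hermite measure, the standard normality tests and the
#' FastICA contrast deviations.  The resulting long table can be normalized
#' per method with [normalize_curves()] so the maximal mean of each curve
#' is 1, the convention used for sensitivity comparison plots.
#'
#' @param family Family name for [family_grid()].
#' @param params Parameter grid.
#' @param sizes Sample sizes.
#' @param n_runs Replicates per cell.
#' @param methods Method names (subset of the nine defaults).
#' @param seed Base seed; each cell uses a derived child seed.
#' @return Long-format data.frame `{family, param, N, method, replicate,
#'   value}`.
#' @export
run_1d_benchmark <- function(family = "mixture", params = seq(0, 1, 0.1),
                             sizes = 1000, n_runs = 100,
                             methods = .default_methods, seed = 1) {
  specs <- family_grid(family, params)
  rows <- vector("list", length(params) * length(sizes) * n_runs)
  i <- 0L
  for (pi in seq_along(params)) {
    for (N in sizes) {
      for (rep in seq_len(n_runs)) {
        x <- rdist(specs[[pi]], N, seed = child_seed(seed, pi, N, rep))
        vals <- vapply(methods, function(m) score_method(x, m), numeric(1))
        i <- i + 1L
        rows[[i]] <- data.frame(
          family = family, param = params[pi], N = N, method = methods,
          replicate = rep, value = unname(vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# wrap an angle difference into (-90, 90]
wrap_angle <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

#' 2-D unmixing benchmark: accuracy and precision by exhaustive search
#'
#' For each replicate, samples a 2-D product dataset (non-Gaussian along
#' the first axis) and finds each method's most non-Gaussian projection by
#' [exhaustive_search_2d()].  Accuracy is the peak's angular deviation from
#' the true axis; precision is the half-width at which the replicate-level
#' mean +/- 2 SD score band separates from the peak band
#' ([precision_from_profile()]).
#'
#' @param spec Non-Gaussian component [dist_spec].
#' @param N Samples per dataset.
#' @param n_seeds Replicates.
#' @param methods Contrast names.
#' @param seed Base seed.
#' @return List: `peaks` (data.frame `method`, `seed`, `peak_deg` with the
#'   wrapped peak angle), `precision` (data.frame `method`, `half_width`,
#'   `flagged`), `profiles` (per-method data.frame `angle`, `mean`, `sd`).
#' @export
run_2d_benchmark <- function(spec, N = 1e4, n_seeds = 10,
                             methods = c("j15", "fastica_I", "fastica_II",
                                         "fastica_III"),
                             seed = 1) {
  peaks <- list()
  prof_scores <- stats::setNames(vector("list", length(methods)), methods)
  for (s in seq_len(n_seeds)) {
    ds <- make_product_dataset(spec, d = 2, N = N, rotate = FALSE,
                               seed = child_seed(seed, s))
    for (m in methods) {
      res <- exhaustive_search_2d(ds$data, contrast = m)
      peaks[[length(peaks) + 1L]] <- data.frame(
        method = m, seed = s, peak_deg = wrap_angle(res$angle),
        stringsAsFactors = FALSE)
      prof_scores[[m]][[s]] <- res$profile$score
    }
  }
  angles <- wrap_angle(seq(0, 179, by = 1))
  profiles <- lapply(prof_scores, function(lst) {
    mat <- do.call(cbind, lst)
    df <- data.frame(angle = angles, mean = rowMeans(mat),
                     sd = apply(mat, 1, stats::sd))
    df[order(df$angle), ]
  })
  precision <- do.call(rbind, lapply(methods, function(m) {
    pr <- precision_from_profile(profiles[[m]])
    data.frame(method = m, half_width = pr$half_width,
               flagged = pr$flagged, stringsAsFactors = FALSE)
  }))
  list(peaks = do.call(rbind, peaks), precision = precision,
       profiles = profiles)
}

#' Truncation-order study of the Hermite contrast
#'
#' For each benchmark distribution, sample size and replicate, runs
#' [order_study_search()] on a fresh 2-D product dataset and aggregates,
#' per truncation order and variant, the axial circular variance of the
#' estimated directions (angles doubled, since a direction and its
#' negative are the same axis) with bootstrap confidence limits.
#'
#' @param specs Named list of non-Gaussian [dist_spec]s.
#' @param sizes Sample sizes.
#' @param n_reps Replicates per cell.
#' @param n_values Truncation orders.
#' @param n_boot Bootstrap resamples for the confidence limits.
#' @param seed Base seed.
#' @return data.frame `{family, N, n, variant, circ_var, ci_lo, ci_hi,
#'   mean_abs_error}`.
#' @export
run_order_study <- function(specs = benchmark_specs(), sizes = c(1e3, 1e4),
                            n_reps = 50, n_values = 2:50, n_boot = 1000,
                            seed = 1) {
  out <- list()
  for (f in seq_along(specs)) {
    for (N in sizes) {
      errs <- vector("list", n_reps)
      for (rep in seq_len(n_reps)) {
        ds <- make_product_dataset(specs[[f]], d = 2, N = N, rotate = FALSE,
                                   seed = child_seed(seed, f, N, rep))
        errs[[rep]] <- order_study_search(ds$data, true_angle = 0,
                                          n_values = n_values)
      }
      key <- errs[[1]][c("n", "variant")]
      err_mat <- vapply(errs, function(e) e$error_deg,
                        numeric(nrow(key)))  # (n x variant) x reps
      # axial circular variance: direction estimates from a 180-degree
      # search carry no sign, so angles are doubled (standard treatment of
      # axial data); identical estimates give 0, uninformative estimates
      # scattered over the half-circle give ~1
      cv_of <- function(deg) {
        rad <- 2 * deg * pi / 180
        1 - sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
      }
      # one shared set of bootstrap resamples for all (n, variant) rows
      boot_idx <- with_seed(child_seed(seed, f, N, 999999),
        matrix(sample.int(n_reps, n_reps * n_boot, replace = TRUE),
               n_reps, n_boot))
      rows <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
        rad <- 2 * err_mat[i, ] * pi / 180
        cb <- matrix(cos(rad)[boot_idx], n_reps)
        sb <- matrix(sin(rad)[boot_idx], n_reps)
        cvs <- 1 - sqrt(colMeans(cb)^2 + colMeans(sb)^2)
        ci <- stats::quantile(cvs, c(0.025, 0.975), names = FALSE)
        data.frame(family = names(specs)[f], N = N, n = key$n[i],
                   variant = key$variant[i],
                   circ_var = cv_of(err_mat[i, ]),
                   ci_lo = ci[1], ci_hi = ci[2],
                   mean_abs_error = mean(abs(err_mat[i, ])),
                   stringsAsFactors = FALSE)
      }))
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

#' 5-D deflationary ICA benchmark with cross-contrast selection
#'
#' For each benchmark distribution, sample size and replicate, mixes one
#' non-Gaussian component with four Gaussian components through a random
#' orthogonal matrix, extracts one component per contrast by
#' [deflation_search()], applies [cross_contrast_select()] (each contrast
#' may adopt a direction found by another if it scores higher there), and
#' records the angular error against the true unmixing direction.  The
#' error table is analyzed by a three-way ANOVA (distribution x sample
#' size x contrast) and by paired two-tailed t-tests of the Hermite
#' contrast against each FastICA contrast and against the per-dataset best
#' FastICA contrast, with Benjamini-Hochberg correction.
#'
#' @param specs Named list of non-Gaussian [dist_spec]s.
#' @param sizes Sample sizes.
#' @param n_seeds Replicates per cell.
#' @param restarts Random restarts per component.
#' @param contrasts Contrast names (first is the comparison baseline).
#' @param seed Base seed.
#' @return List: `table` (long error table), `anova` (the `aov` summary),
#'   `t_tests` (data.frame of paired comparisons with raw and
#'   BH-adjusted p-values).
#' @export
run_5d_benchmark <- function(specs = benchmark_specs(),
                             sizes = c(1e3, 1e4), n_seeds = 10,
                             restarts = 25,
                             contrasts = c("j15", "fastica_I", "fastica_II",
                                           "fastica_III"),
                             seed = 1) {
  rows <- list()
  for (f in seq_along(specs)) {
    for (N in sizes) {
      for (s in seq_len(n_seeds)) {
        ds <- make_product_dataset(specs[[f]], d = 5, N = N, rotate = TRUE,
                                   seed = child_seed(seed, f, N, s))
        w <- whiten(ds$data)
        true_w <- to_whitened_direction(w, ds$true_direction)
        cands <- lapply(seq_along(contrasts), function(ci) {
          deflation_search(w$Z, contrast = contrasts[ci], n_components = 1,
                           restarts = restarts,
                           seed = child_seed(seed, f, N, s, ci))[[1]]
        })
        for (ci in seq_along(contrasts)) {
          final <- cross_contrast_select(w$Z, cands, contrasts[ci])
          rows[[length(rows) + 1L]] <- data.frame(
            family = names(specs)[f], N = N, seed = s,
            contrast = contrasts[ci],
            error_deg = error_angle(final$direction, true_w),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  av <- stats::aov(error_deg ~ factor(family) * factor(N) * factor(contrast),
                   data = table)
  list(table = table, anova = summary(av),
       t_tests = paired_contrast_tests(table, baseline = contrasts[1]))
}

# Paired two-tailed t-tests of a baseline contrast against each other
# contrast and against the per-dataset best of the others, BH-corrected.
paired_contrast_tests <- function(table, baseline = "j15") {
  others <- setdiff(unique(table$contrast), baseline)
  key <- interaction(table$family, table$N, table$seed, drop = TRUE)
  base <- table$error_deg[table$contrast == baseline][
    match(levels(key), key[table$contrast == baseline])]
  res <- lapply(others, function(m) {
    oth <- table$error_deg[table$contrast == m][
      match(levels(key), key[table$contrast == m])]
    tt <- stats::t.test(base, oth, paired = TRUE)
    data.frame(comparison = paste(baseline, "vs", m),
               mean_diff = unname(tt$estimate), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  # per-dataset best of the other contrasts
  best <- vapply(levels(key), function(k) {
    sel <- key == k & table$contrast %in% others
    min(table$error_deg[sel])
  }, numeric(1))
  tt <- stats::t.test(base, best, paired = TRUE)
  res[[length(res) + 1L]] <- data.frame(
    comparison = paste(baseline, "vs best-other"),
    mean_diff = unname(tt$estimate), p = tt$p.value,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, res)
  out$p_adj_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Synthetic-EEG artifact-recovery benchmark
#'
#' For each run length and replicate, simulates an EEG dataset
#' ([simulate_eeg()]), reduces it by PCA, extracts components with each
#' contrast and matches them to the two ground-truth blink directions
#' ([extract_and_match()]).  Per-eye angular errors are recorded and their
#' per-dataset average compared between contrasts by paired t-tests with
#' Benjamini-Hochberg correction.
#'
#' @param durations_s Run lengths in seconds.
#' @param n_seeds Replicates per run length.
#' @param channels,fs,n_background Passed to [simulate_eeg()].
#' @param k PCA components retained.
#' @param n_components ICA components extracted.
#' @param restarts Random restarts per component.
#' @param contrasts Contrast names.
#' @param seed Base seed.
#' @return List: `table` (long table `{duration_s, seed, contrast, eye,
#'   error_deg}`), `t_tests`.
#' @export
run_eeg_benchmark <- function(durations_s = c(6, 15, 30), n_seeds = 5,
                              channels = 16, fs = 250, n_background = 8,
                              k = 10, n_components = 4, restarts = 6,
                              contrasts = c("j15", "fastica_I", "fastica_II",
                                            "fastica_III"),
                              seed = 1) {
  rows <- list()
  for (dur in durations_s) {
    for (s in seq_len(n_seeds)) {
      ds <- simulate_eeg(dur, fs = fs, channels = channels,
                         n_background = n_background,
                         seed = child_seed(seed, round(dur), s))
      red <- pca_reduce(ds, k = k)
      for (ci in seq_along(contrasts)) {
        rec <- extract_and_match(red, ds, contrast = contrasts[ci],
                                 n_components = n_components,
                                 restarts = restarts,
                                 seed = child_seed(seed, round(dur), s, ci))
        rows[[length(rows) + 1L]] <- data.frame(
          duration_s = dur, seed = s, contrast = contrasts[ci],
          eye = rec$eye, error_deg = rec$error_deg,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  # average over eyes, then paired tests between contrasts
  agg <- stats::aggregate(error_deg ~ duration_s + seed + contrast,
                          data = table, FUN = mean)
  agg$family <- "eeg"
  agg$N <- agg$duration_s
  list(table = table,
       t_tests = paired_contrast_tests(agg, baseline = contrasts[1]))
}
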