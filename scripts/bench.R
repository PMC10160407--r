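#!/usr/bin/env Rscript
# Thin command-line wrapper over the hfica benchmark pipelines.
#
#   Rscript scripts/bench.R <subcommand> [options]
#
# Subcommands:
#   score        J_n of a sample read from a text file
#   bench-1d     1-D sensitivity benchmark over a family grid
#   bench-2d     2-D exhaustive-search recovery benchmark
#   order-study  truncation-order study
#   bench-5d     5-D deflation ICA benchmark
#   eeg-sim      write one synthetic EEG dataset
#   bench-eeg    EEG artifact-recovery benchmark

suppressPackageStartupMessages({
  library(optparse)
  library(hfica)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args) >= 1) args[1] else "--help"
rest <- args[-1]

usage <- function() {
  cat("usage: Rscript scripts/bench.R",
      "{score|bench-1d|bench-2d|order-study|bench-5d|eeg-sim|bench-eeg}",
      "[options]\n")
  quit(status = if (cmd %in% c("--help", "-h")) 0 else 1)
}

common <- list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results"),
  make_option("--n-runs", type = "integer", default = 20L, dest = "n_runs"),
  make_option("--sizes", type = "character", default = "1000"),
  make_option("--methods", type = "character",
              default = "j15,fastica_I,fastica_II,fastica_III")
)

parse <- function(extra = list()) {
  parse_args(OptionParser(option_list = c(common, extra)), args = rest)
}

write_out <- function(tab, opts, name) {
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(opts$out, paste0(name, ".csv"))
  utils::write.csv(tab, path, row.names = FALSE)
  cat("wrote", path, "\n")
}

sizes_of <- function(opts) as.numeric(strsplit(opts$sizes, ",")[[1]])
methods_of <- function(opts) strsplit(opts$methods, ",")[[1]]

if (cmd == "score") {
  opts <- parse(list(
    make_option("--input", type = "character"),
    make_option("--n", type = "integer", default = 15L),
    make_option("--variant", type = "character", default = "all")
  ))
  x <- read_samples(opts$input)
  s <- j_statistic(x, n = opts$n, variant = opts$variant)
  print(s)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_scores(s, file.path(opts$out, "score.json"), N = length(x),
               seed = opts$seed)
} else if (cmd == "bench-1d") {
  opts <- parse(list(
    make_option("--family", type = "character", default = "mixture"),
    make_option("--params", type = "character", default = "0,0.25,0.5,0.75,1")
  ))
  tab <- run_1d_benchmark(opts$family,
                          params = as.numeric(strsplit(opts$params, ",")[[1]]),
                          sizes = sizes_of(opts), n_runs = opts$n_runs,
                          seed = opts$seed)
  write_out(normalize_curves(tab, by = c("method", "N")), opts, "bench1d")
} else if (cmd == "bench-2d") {
  opts <- parse()
  out <- lapply(names(benchmark_specs()), function(fam) {
    r <- run_2d_benchmark(benchmark_specs()[[fam]], N = sizes_of(opts)[1],
                          n_seeds = opts$n_runs,
                          methods = methods_of(opts), seed = opts$seed)
    cbind(family = fam, merge(r$peaks, r$precision, by = "method"))
  })
  write_out(do.call(rbind, out), opts, "bench2d")
} else if (cmd == "order-study") {
  opts <- parse()
  tab <- run_order_study(sizes = sizes_of(opts), n_reps = opts$n_runs,
                         seed = opts$seed)
  write_out(tab, opts, "order_study")
} else if (cmd == "bench-5d") {
  opts <- parse(list(
    make_option("--restarts", type = "integer", default = 25L)
  ))
  res <- run_5d_benchmark(sizes = sizes_of(opts), n_seeds = opts$n_runs,
                          restarts = opts$restarts,
                          contrasts = methods_of(opts), seed = opts$seed)
  write_out(res$table, opts, "bench5d")
  write_out(res$t_tests, opts, "bench5d_ttests")
} else if (cmd == "eeg-sim") {
  opts <- parse(list(
    make_option("--duration", type = "double", default = 30),
    make_option("--channels", type = "integer", default = 249L)
  ))
  ds <- simulate_eeg(opts$duration, channels = opts$channels,
                     seed = opts$seed)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$data, file.path(opts$out, "eeg_data.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fs = ds$fs, channels = ds$channels, mixing = ds$mixing,
         artifact_source_indices = ds$artifact_source_indices,
         seed = opts$seed),
    file.path(opts$out, "eeg_meta.json"), digits = NA)
  cat("wrote", file.path(opts$out, "eeg_data.csv"), "\n")
} else if (cmd == "bench-eeg") {
  opts <- parse(list(
    make_option("--durations", type = "character", default = "6,15,30"),
    make_option("--channels", type = "integer", default = 16L)
  ))
  res <- run_eeg_benchmark(
    durations_s = as.numeric(strsplit(opts$durations, ",")[[1]]),
    n_seeds = opts$n_runs, channels = opts$channels,
    contrasts = methods_of(opts), seed = opts$seed)
  write_out(res$table, opts, "bench_eeg")
  write_out(res$t_tests, opts, "bench_eeg_ttests")
} else {
  usage()
}
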