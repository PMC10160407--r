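# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and integer indices,
# staying within the 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 2654435761) %% 2147483647
  as.integer(s)
}

#' Read a numeric sample from a text file
#'
#' Accepts a single column of numbers in CSV, TSV or whitespace-separated
#' text; a header line is detected and skipped.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1L)
  header <- is.na(suppressWarnings(as.numeric(strsplit(
    first, "[,\t ]+")[[1]][1])))
  df <- utils::read.table(path, header = header, sep = "",
                          comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) == 1L) return(as.numeric(df[[1]]))
  # try comma separation if whitespace parsing produced one wide column
  df <- utils::read.table(path, header = header, sep = ",")
  as.numeric(df[[1]])
}

#' Write non-Gaussianity scores as JSON records
#'
#' @param scores A `j_score` or list of `j_score` objects.
#' @param path Output path.
#' @param N,seed Optional sample size and seed recorded with each score.
#' @export
write_scores <- function(scores, path, N = NA, seed = NA) {
  if (inherits(scores, "j_score")) scores <- list(scores)
  recs <- lapply(scores, function(s) {
    list(n = s$n, variant = s$variant, value = s$value, N = N, seed = seed)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
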