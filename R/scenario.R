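#' Scenario configuration for the synthetic-data generators
#'
#' Bundles the knobs shared by every generator: the RNG seed, the
#' multiplicative noise level (as a coefficient of variation), the number of
#' technical replicates, and an optional output directory. A fixed seed makes
#' every generator byte-reproducible: the same configuration always yields
#' identical datasets (and identical files when `output_dir` is set).
#'
#' @param seed integer RNG seed.
#' @param noise_cv coefficient of variation of the noise applied to generated
#'   signals (fraction, e.g. 0.03 for 3%). Must be >= 0. The default 3% is a
#'   typical plate-reader / NMR-integral replicate scatter; it is a
#'   configurable emulation choice, not a measured value.
#' @param replicate_count number of technical replicates per condition.
#' @param output_dir optional directory; when set, generators write their
#'   dataset as TSV plus a JSON ground-truth sidecar there.
#' @return an object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(seed = 1, noise_cv = 0)
#' @export
scenario_config <- function(seed, noise_cv = 0.03, replicate_count = 2,
                            output_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0)
    stop("noise_cv must be a single non-negative number")
  if (replicate_count < 1) stop("replicate_count must be >= 1")
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 replicate_count = as.integer(replicate_count),
                 output_dir = output_dir),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario config: seed", x$seed, "| noise CV", x$noise_cv,
      "| replicates", x$replicate_count, "\n")
  invisible(x)
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Multiplicative Gaussian noise with coefficient of variation cv.
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * (1 + rnorm(length(x), 0, cv))
}

# Write a generated dataset (data frame) + ground-truth JSON sidecar.
write_dataset <- function(df, ground_truth, name, dir) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ground_truth,
                       file.path(dir, paste0(name, ".groundtruth.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tsv)
}
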