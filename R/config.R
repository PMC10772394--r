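# Pipeline configuration: the tunable constants of the harmonization,
# screening and clustering stages, with the study's operative defaults.

#' Pipeline configuration
#'
#' Bundles the constants the analysis stages share. Defaults are the
#' operative values of the analysed study: 5000 balanced subsamples per
#' array, receptor subtype balance 0.384 / 0.368 / 0.158 / 0.09
#' (HR+HER2-, TN, HR+HER2+, HR-HER2+), dendrogram cut height 1.54 on the
#' 1 - Pearson correlation scale, and BH significance threshold 0.05.
#'
#' @param n_subsamples Number of balanced subsamples B drawn per array
#'   during harmonization (default 5000).
#' @param subsample_fraction Fraction of an array's patients drawn (without
#'   replacement) per subsample (default 0.8).
#' @param subtype_proportions Length-4 non-negative vector summing to 1, in
#'   the order of [SUBTYPE_LEVELS].
#' @param cut_height Dendrogram cut height (default 1.54).
#' @param bh_alpha BH-adjusted significance threshold (default 0.05).
#' @param seed Integer RNG seed for every stochastic stage.
#' @param sd_floor Lower guard for per-analyte SD estimates; degenerate
#'   (near-constant) analytes are floored and flagged, never dropped.
#' @param min_coverage Minimum unmasked fraction for an analyte to enter an
#'   association screen (default 0.8).
#' @param min_shared_analytes Minimum number of analytes a patient must
#'   share pairwise with every other patient to enter clustering
#'   (default 30).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_subsamples = 5000L,
                            subsample_fraction = 0.8,
                            subtype_proportions = c(0.384, 0.368, 0.158, 0.09),
                            cut_height = 1.54,
                            bh_alpha = 0.05,
                            seed = 1L,
                            sd_floor = 1e-8,
                            min_coverage = 0.8,
                            min_shared_analytes = 30L) {
  subtype_proportions <- validate_proportions(subtype_proportions)
  stopifnot(n_subsamples >= 1L,
            subsample_fraction > 0, subsample_fraction <= 1,
            cut_height > 0, bh_alpha > 0, bh_alpha < 1, sd_floor > 0)
  structure(list(
    n_subsamples = as.integer(n_subsamples),
    subsample_fraction = subsample_fraction,
    subtype_proportions = subtype_proportions,
    cut_height = cut_height,
    bh_alpha = bh_alpha,
    seed = as.integer(seed),
    sd_floor = sd_floor,
    min_coverage = min_coverage,
    min_shared_analytes = as.integer(min_shared_analytes)
  ), class = "pipeline_config")
}

validate_proportions <- function(p) {
  if (length(p) != length(SUBTYPE_LEVELS)) {
    stop("subtype_proportions must have length ", length(SUBTYPE_LEVELS))
  }
  if (any(p < 0)) stop("subtype_proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("subtype_proportions must sum to 1")
  names(p) <- SUBTYPE_LEVELS
  p
}

#' Read a pipeline configuration from a YAML key/value file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so typos do not pass silently.
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("RPPA pipeline configuration\n")
  cat(sprintf("  subsamples B = %d, fraction = %g, cut height = %g, BH alpha = %g, seed = %d\n",
              x$n_subsamples, x$subsample_fraction, x$cut_height,
              x$bh_alpha, x$seed))
  cat("  subtype balance:",
      paste(sprintf("%s %.3f", names(x$subtype_proportions),
                    x$subtype_proportions), collapse = ", "), "\n")
  invisible(x)
}
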