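# Batch harmonization: per-array standardization by receptor-subtype-
# balanced subsampling. For each array, B subsamples are drawn without
# replacement at a fixed subtype balance; each analyte is then z-scored
# with mu = mean of subsample means and sigma = mean of subsample SDs,
# and the standardized arrays are row-concatenated.

#' Stratified subsample of an array's patients
#'
#' Draws `m` patient indices without replacement, with stratum (subtype)
#' sizes given by largest-remainder rounding of `m * proportions`, each
#' capped at the stratum's population on the array.
#'
#' @param subtypes Character vector of the array patients' subtypes.
#' @param proportions Named length-4 subtype proportions (order of
#'   [SUBTYPE_LEVELS]).
#' @param m Target subsample size.
#' @param array_id Label used in error messages.
#' @return Integer vector of patient indices.
#' @export
stratified_subsample <- function(subtypes, proportions, m,
                                 array_id = "array") {
  proportions <- validate_proportions(proportions)
  sizes <- largest_remainder(m * proportions)
  idx_by <- lapply(SUBTYPE_LEVELS, function(s) which(subtypes == s))
  names(idx_by) <- SUBTYPE_LEVELS
  empty <- proportions > 0 & vapply(idx_by, length, 1L) == 0L
  if (any(empty)) {
    stop("harmonization error on ", array_id, ": no patients of subtype ",
         paste(SUBTYPE_LEVELS[empty], collapse = ", "))
  }
  sizes <- pmin(sizes, vapply(idx_by, length, 1L))
  unlist(lapply(SUBTYPE_LEVELS, function(s) {
    pool <- idx_by[[s]]
    k <- sizes[[s]]
    if (k == 0L) return(integer(0))
    if (k == length(pool)) return(pool)
    sample(pool, k)
  }), use.names = FALSE)
}

# Largest-remainder (Hamilton) rounding of non-negative reals to integers
# preserving the rounded total; ties go to the lower index.
largest_remainder <- function(x) {
  base <- floor(x)
  rem <- x - base
  extra <- round(sum(x)) - sum(base)
  if (extra > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(x))
}

#' Balanced-resampling moments for one array
#'
#' For `b in 1..B` draws a stratified subsample ([stratified_subsample()])
#' and computes each analyte's subsample mean and SD (n-1 denominator);
#' returns `mu` = mean of the subsample means and `sigma` = mean of the
#' subsample SDs per analyte. Near-zero `sigma` values are floored at
#' `sd_floor` with a warning.
#'
#' @param m An endpoint matrix (one array) with patient row names.
#' @param clinical Clinical table covering (at least) the array's patients.
#' @param config A [pipeline_config()] supplying `n_subsamples`,
#'   `subsample_fraction`, `subtype_proportions` and `sd_floor`.
#' @return A list of class `"harmonization_model"` with named vectors `mu`
#'   and `sigma` and the resampling metadata.
#' @export
resample_moments <- function(m, clinical, config = pipeline_config()) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  array_id <- attr(m, "array_id")
  if (is.null(array_id)) array_id <- "array"
  row_cl <- match(rownames(m), clinical$patient_id)
  if (anyNA(row_cl)) {
    stop("patients missing from the clinical table: ",
         paste(rownames(m)[is.na(row_cl)][1:5], collapse = ", "))
  }
  subtypes <- clinical$subtype[row_cl]
  B <- config$n_subsamples
  if (B < 1L) stop("n_subsamples must be >= 1")
  n <- nrow(m)
  msub <- max(1L, round(config$subsample_fraction * n))

  K <- ncol(m)
  sum_mean <- sum_sd <- numeric(K)
  n_mean <- n_sd <- numeric(K)
  has_na <- anyNA(m)
  for (b in seq_len(B)) {
    idx <- stratified_subsample(subtypes, config$subtype_proportions, msub,
                                array_id = array_id)
    x <- m[idx, , drop = FALSE]
    if (has_na) {
      cnt <- colSums(!is.na(x))
      s1 <- colSums(x, na.rm = TRUE)
      s2 <- colSums(x * x, na.rm = TRUE)
    } else {
      cnt <- rep(nrow(x), K)
      s1 <- colSums(x)
      s2 <- colSums(x * x)
    }
    mu_b <- ifelse(cnt > 0, s1 / cnt, NA_real_)
    var_b <- ifelse(cnt > 1, pmax(s2 - cnt * mu_b^2, 0) / (cnt - 1),
                    NA_real_)
    ok_m <- !is.na(mu_b)
    ok_s <- !is.na(var_b)
    sum_mean[ok_m] <- sum_mean[ok_m] + mu_b[ok_m]
    n_mean[ok_m] <- n_mean[ok_m] + 1
    sum_sd[ok_s] <- sum_sd[ok_s] + sqrt(var_b[ok_s])
    n_sd[ok_s] <- n_sd[ok_s] + 1
  }
  mu <- ifelse(n_mean > 0, sum_mean / n_mean, NA_real_)
  sigma <- ifelse(n_sd > 0, sum_sd / n_sd, NA_real_)
  observed <- colSums(!is.na(m)) > 0
  mu[!observed] <- NA_real_
  sigma[!observed] <- NA_real_
  low <- observed & !is.na(sigma) & sigma < config$sd_floor
  if (any(low)) {
    warning("array ", array_id, ": near-constant analyte(s) floored at ",
            "sd_floor: ", paste(colnames(m)[low], collapse = ", "))
    sigma[low] <- config$sd_floor
  }
  structure(list(
    array_id = array_id,
    mu = setNames(mu, colnames(m)),
    sigma = setNames(sigma, colnames(m)),
    n_subsamples = B,
    subsample_fraction = config$subsample_fraction,
    subsample_size = msub,
    subtype_proportions = config$subtype_proportions,
    seed = config$seed
  ), class = "harmonization_model")
}

#' Z-score one array's endpoint matrix with a harmonization model
#'
#' @param m Endpoint matrix for the model's array.
#' @param model A `"harmonization_model"` from [resample_moments()].
#' @return The standardized matrix `(x - mu) / sigma`; masks propagate.
#' @export
zscore_array <- function(m, model) {
  stopifnot(inherits(model, "harmonization_model"))
  missing_model <- setdiff(colnames(m)[colSums(!is.na(m)) > 0],
                           names(model$mu)[!is.na(model$mu)])
  if (length(missing_model)) {
    stop("harmonization model lacks entries for analyte(s): ",
         paste(missing_model, collapse = ", "))
  }
  z <- sweep(sweep(m, 2L, model$mu[colnames(m)], "-"),
             2L, model$sigma[colnames(m)], "/")
  attr(z, "array_id") <- attr(m, "array_id")
  z
}

#' Combine standardized arrays into one matrix
#'
#' Row-concatenates per-array matrices; the analyte set is the union, with
#' array-absent analytes masked (`NA`).
#'
#' @param matrices List of standardized matrices with disjoint patients.
#' @return The combined patient x analyte matrix.
#' @export
combine_arrays <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  all_patients <- unlist(lapply(matrices, rownames), use.names = FALSE)
  dup <- unique(all_patients[duplicated(all_patients)])
  if (length(dup)) {
    stop("patient(s) present on more than one array: ",
         paste(dup, collapse = ", "))
  }
  analytes <- unique(unlist(lapply(matrices, colnames), use.names = FALSE))
  out <- matrix(NA_real_, length(all_patients), length(analytes),
                dimnames = list(all_patients, analytes))
  at <- 0L
  for (m in matrices) {
    out[at + seq_len(nrow(m)), colnames(m)] <- m
    at <- at + nrow(m)
  }
  out
}

#' Harmonize a set of per-array endpoint matrices
#'
#' Runs [resample_moments()] and [zscore_array()] per array (seeding the
#' RNG from the configuration) and combines the standardized arrays.
#'
#' @param matrices Named list of per-array endpoint matrices.
#' @param clinical Clinical table covering all patients.
#' @param config A [pipeline_config()].
#' @return List with `matrix` (combined harmonized matrix) and `models`
#'   (per-array harmonization models).
#' @export
harmonize <- function(matrices, clinical, config = pipeline_config()) {
  set.seed(config$seed)
  models <- lapply(matrices, resample_moments, clinical = clinical,
                   config = config)
  zs <- Map(zscore_array, matrices, models)
  list(matrix = combine_arrays(zs), models = models)
}

#' Serialize harmonization models to JSON (for audit)
#'
#' @param models List of harmonization models.
#' @param path Output path.
#' @export
write_harmonization_models <- function(models, path) {
  payload <- lapply(models, function(mod) {
    list(array_id = mod$array_id,
         mu = as.list(mod$mu), sigma = as.list(mod$sigma),
         n_subsamples = mod$n_subsamples,
         subsample_fraction = mod$subsample_fraction,
         subsample_size = mod$subsample_size,
         subtype_proportions = as.list(mod$subtype_proportions),
         seed = mod$seed)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
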