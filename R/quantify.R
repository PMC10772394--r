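# Spot-level quantification: triplicate averaging, negative-control
# subtraction and total-protein normalization, exactly in that order.

#' Total-protein value for a sample
#'
#' Arithmetic mean of the three replicate total-protein (Sypro) spot
#' intensities.
#'
#' @param sypro_replicates Numeric vector of exactly 3 finite intensities.
#' @return The mean intensity.
#' @export
total_protein <- function(sypro_replicates) {
  if (length(sypro_replicates) != 3L || !all(is.finite(sypro_replicates))) {
    stop("total_protein requires exactly 3 finite replicate intensities")
  }
  mean(sypro_replicates)
}

#' Endpoint signal for one (sample, analyte)
#'
#' Three-step signal computation: (1) subtract the negative-control spot
#' intensity from the paired primary-antibody spot intensity, (2) average
#' the three net replicate intensities, (3) divide by the sample's
#' total-protein value. Negative net signals are retained, not floored:
#' downstream standardization is location-scale based and flooring would
#' bias low-expressing samples.
#'
#' @param primary,negative Numeric vectors of 3 replicate intensities,
#'   paired by replicate index.
#' @param total Total-protein value (> 0).
#' @return The normalized endpoint value.
#' @export
endpoint_signal <- function(primary, negative, total) {
  if (length(primary) != 3L || length(negative) != 3L ||
      !all(is.finite(primary)) || !all(is.finite(negative))) {
    stop("endpoint_signal requires 3 finite primary and 3 negative replicates")
  }
  if (!is.finite(total) || total <= 0) {
    stop("degenerate sample: total protein value must be > 0")
  }
  mean(primary - negative) / total
}

#' Quantify one array's spot table into an endpoint matrix
#'
#' Applies [endpoint_signal()] to every (patient, analyte) present on the
#' array. Analytes present for some but not all patients of the array are
#' kept, with the absent cells masked (`NA`) and a warning.
#'
#' @param spots A validated spot table (may span several arrays).
#' @param array_id The array to quantify.
#' @return A patient x analyte numeric matrix with an `array_id` attribute;
#'   masked cells are `NA`.
#' @export
quantify_array <- function(spots, array_id) {
  sub <- spots[spots$array_id == array_id, , drop = FALSE]
  if (!nrow(sub)) stop("no spots for array: ", array_id)

  tp_rows <- sub[sub$spot_type == "total_protein", , drop = FALSE]
  tp_rows <- tp_rows[order(tp_rows$patient_id, tp_rows$replicate_index), ]
  patients <- unique(tp_rows$patient_id)
  tp_val <- colMeans(matrix(tp_rows$intensity, nrow = 3L))
  names(tp_val) <- patients
  if (any(tp_val <= 0)) {
    stop("degenerate sample: non-positive total protein for patient(s) ",
         paste(patients[tp_val <= 0], collapse = ", "))
  }

  reshape3 <- function(rows) {
    rows <- rows[order(rows$analyte, rows$patient_id, rows$replicate_index), ]
    list(mat = matrix(rows$intensity, nrow = 3L),
         patient = rows$patient_id[seq(1L, nrow(rows), by = 3L)],
         analyte = rows$analyte[seq(1L, nrow(rows), by = 3L)])
  }
  prim <- reshape3(sub[sub$spot_type == "primary", , drop = FALSE])
  neg <- reshape3(sub[sub$spot_type == "negative_control", , drop = FALSE])
  if (!identical(prim$patient, neg$patient) ||
      !identical(prim$analyte, neg$analyte)) {
    stop("primary and negative_control spots do not pair up on array ",
         array_id)
  }
  unknown <- setdiff(prim$patient, patients)
  if (length(unknown)) {
    stop("primary spots without total_protein spots for patient(s) ",
         paste(unknown, collapse = ", "))
  }

  net <- colMeans(prim$mat - neg$mat)
  value <- net / tp_val[prim$patient]

  analytes <- unique(prim$analyte)
  m <- matrix(NA_real_, length(patients), length(analytes),
              dimnames = list(patients, analytes))
  m[cbind(match(prim$patient, patients), match(prim$analyte, analytes))] <-
    value
  if (anyNA(m)) {
    warning("array ", array_id, ": inconsistent analyte sets across ",
            "patients; absent cells are masked")
  }
  attr(m, "array_id") <- array_id
  m
}

#' Quantify every array in a spot table
#'
#' @param spots A validated spot table.
#' @return Named list of endpoint matrices, one per array (sorted by
#'   array label).
#' @export
quantify_all <- function(spots) {
  arrays <- sort(unique(spots$array_id))
  setNames(lapply(arrays, function(a) quantify_array(spots, a)), arrays)
}
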