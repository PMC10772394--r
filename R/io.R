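# Readers/writers for the long spot table and wide endpoint matrices.
# All round-trips are lossless to at least 1e-12 relative tolerance.

SPOT_TYPES <- c("primary", "negative_control", "total_protein")

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Validate a spot table
#'
#' A spot table holds long-format triplicate spot intensities with columns
#' `patient_id`, `array_id`, `analyte`, `spot_type`, `replicate_index`,
#' `intensity`. For every (patient, array, analyte) present there must be
#' exactly 3 `primary` and 3 `negative_control` replicates; every
#' (patient, array) must carry 3 `total_protein` replicates; intensities
#' must be finite and non-negative.
#'
#' @param spots A data.frame of spot records.
#' @return The table, invisibly classed `"spot_table"`.
#' @export
validate_spots <- function(spots) {
  required <- c("patient_id", "array_id", "analyte", "spot_type",
                "replicate_index", "intensity")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols)) {
    stop("spot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(spots$spot_type %in% SPOT_TYPES)) {
    stop("spot_type must be one of: ", paste(SPOT_TYPES, collapse = ", "))
  }
  if (!all(is.finite(spots$intensity))) stop("spot intensities must be finite")
  if (any(spots$intensity < 0)) stop("spot intensities must be non-negative")
  spots$analyte <- normalize_analyte_names(spots$analyte)

  check_triplicate <- function(sub, what, with_analyte = TRUE) {
    key <- if (with_analyte) {
      paste(sub$patient_id, sub$array_id, sub$analyte, sep = "\r")
    } else {
      paste(sub$patient_id, sub$array_id, sep = "\r")
    }
    cnt <- table(key)
    bad <- names(cnt)[cnt != 3L]
    if (length(bad)) {
      stop("expected exactly 3 ", what, " replicates per ",
           if (with_analyte) "(patient, array, analyte)" else "(patient, array)",
           "; offending: ",
           paste(gsub("\r", " / ", utils::head(bad, 5L)), collapse = "; "))
    }
  }
  check_triplicate(spots[spots$spot_type == "primary", ], "primary")
  check_triplicate(spots[spots$spot_type == "negative_control", ],
                   "negative_control")
  check_triplicate(spots[spots$spot_type == "total_protein", ],
                   "total_protein", with_analyte = FALSE)
  class(spots) <- c("spot_table", "data.frame")
  invisible(spots)
}

#' Read a long-format spot TSV
#'
#' @param path Path to a tab-separated spot table (optionally gzipped).
#' @return A validated spot table.
#' @export
read_spots <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spots <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_spots(spots)
}

#' Write a spot table as TSV
#'
#' @param spots A spot table.
#' @param path Output path (gzipped if it ends in `.gz`).
#' @export
write_spots <- function(spots, path) {
  con <- open_out(path)
  on.exit(close(con))
  write.table(as.data.frame(spots), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a wide patient x analyte matrix TSV
#'
#' First column `patient_id`, remaining columns analytes; `NA` encodes
#' masked (unavailable) cells.
#'
#' @param path Path (optionally gzipped).
#' @return Numeric matrix with patient row names and analyte column names.
#'   The `array_id` attribute is restored from a `# array_id:` header
#'   comment when present.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  array_id <- NULL
  skip <- 0L
  if (startsWith(first, "# array_id:")) {
    array_id <- trimws(sub("^# array_id:", "", first))
    skip <- 1L
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   skip = skip)
  if (names(df)[1L] != "patient_id") {
    stop("matrix file must have 'patient_id' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$patient_id)
  colnames(m) <- normalize_analyte_names(colnames(m))
  if (!is.null(array_id)) attr(m, "array_id") <- array_id
  m
}

#' Write a patient x analyte matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path (gzipped if it ends in `.gz`).
#' @param digits Significant digits used for formatting (defaults to 17,
#'   enough for a lossless double round trip).
#' @export
write_matrix <- function(m, path, digits = 17L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- open_out(path)
  on.exit(close(con))
  array_id <- attr(m, "array_id")
  if (!is.null(array_id)) writeLines(paste0("# array_id: ", array_id), con)
  writeLines(paste(c("patient_id", colnames(m)), collapse = "\t"), con)
  fmt <- sprintf("%%.%dg", digits)
  body <- vapply(seq_len(nrow(m)), function(i) {
    s <- sprintf(fmt, m[i, ])
    s[is.na(m[i, ])] <- "NA"
    paste(c(rownames(m)[i], s), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}
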