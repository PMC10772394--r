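# Clinical table: per-patient receptor status, arm, response and survival.

#' Receptor subtype labels
#'
#' The four HR/HER2 receptor subtypes, in the canonical order used for
#' subtype proportion vectors throughout the package.
#'
#' @format Character vector of length 4.
#' @export
SUBTYPE_LEVELS <- c("HR+HER2-", "TN", "HR+HER2+", "HR-HER2+")

#' Default trial arm table
#'
#' The eight treatment arms of the analysed cohort with their HER2
#' eligibility rule and allocation weights proportional to the observed
#' per-arm patient counts (Ctr 194, N 105, VC 63, AMG386 128, MK2206 87,
#' P 43, TDM1/P 49, PD1-inh 67).
#'
#' @return A data.frame with columns `arm`, `eligibility`
#'   (one of `"both"`, `"her2_pos_only"`, `"her2_neg_only"`) and `weight`.
#' @export
default_arms <- function() {
  data.frame(
    arm = c("Ctr", "N", "VC", "AMG386", "MK2206", "P", "TDM1/P", "PD1-inh"),
    eligibility = c("both", "both", "her2_neg_only", "both", "both",
                    "her2_pos_only", "her2_pos_only", "her2_neg_only"),
    weight = c(194, 105, 63, 128, 87, 43, 49, 67),
    stringsAsFactors = FALSE
  )
}

#' Derive the receptor subtype from HR and HER2 status
#'
#' Total deterministic map over the 2x2 of (hr, her2): HR+HER2- , TN
#' (HR-HER2-), HR+HER2+ and HR-HER2+.
#'
#' @param hr,her2 Character vectors with values `"pos"` or `"neg"`.
#' @return Character vector of subtype labels (see [SUBTYPE_LEVELS]).
#' @export
derive_subtype <- function(hr, her2) {
  stopifnot(length(hr) == length(her2))
  bad <- !(hr %in% c("pos", "neg")) | !(her2 %in% c("pos", "neg"))
  if (any(bad)) {
    stop("hr/her2 status must be 'pos' or 'neg' (offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  }
  ifelse(hr == "pos" & her2 == "neg", "HR+HER2-",
  ifelse(hr == "neg" & her2 == "neg", "TN",
  ifelse(hr == "pos" & her2 == "pos", "HR+HER2+", "HR-HER2+")))
}

# GEO exports and figure labels mix dash glyphs in phospho-site names;
# normalize unicode minus / en / em dashes to ASCII hyphen at import.
normalize_analyte_names <- function(x) {
  gsub("[−–—]", "-", x)
}

#' Validate (and finalize) a clinical table
#'
#' Checks the contract of the clinical table: unique patient ids, valid
#' hr/her2/pcr codes, arm values drawn from the declared arm list, paired
#' presence of the DRFS time and event columns, and derives the receptor
#' subtype.
#'
#' @param df A data.frame with columns `patient_id`, `hr`, `her2`, `arm`,
#'   `pcr`, `array_id` and optionally `drfs_time`, `drfs_event`, `mp`, `rps5`.
#' @param arms Character vector of allowed arm labels.
#' @return The validated table with a derived `subtype` column, classed
#'   `"clinical_table"`.
#' @export
validate_clinical <- function(df, arms = default_arms()$arm) {
  required <- c("patient_id", "hr", "her2", "arm", "pcr", "array_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  }
  df$subtype <- derive_subtype(df$hr, df$her2)
  bad_arm <- setdiff(unique(df$arm), arms)
  if (length(bad_arm)) {
    stop("unknown arm value(s): ", paste(bad_arm, collapse = ", "))
  }
  if (!all(df$pcr %in% c(0L, 1L))) stop("pcr must be 0/1")
  has_time <- "drfs_time" %in% names(df)
  has_event <- "drfs_event" %in% names(df)
  if (has_time != has_event) {
    stop("drfs_time and drfs_event must be present together")
  }
  if (has_time) {
    if (any(is.na(df$drfs_time) != is.na(df$drfs_event))) {
      stop("drfs_event must be present exactly where drfs_time is")
    }
    ok <- !is.na(df$drfs_time)
    if (any(df$drfs_time[ok] <= 0)) stop("drfs_time must be > 0")
    if (!all(df$drfs_event[ok] %in% c(0L, 1L))) stop("drfs_event must be 0/1")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical CSV/TSV
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), used to absorb
#'   differing export vocabularies.
#' @param arms Character vector of allowed arm labels.
#' @return A validated [validate_clinical()] clinical table.
#' @export
read_clinical <- function(path, schema = NULL, arms = default_arms()$arm) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (grepl("\\.csv(\\.gz)?$", path)) {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(df))
    if (length(miss)) {
      stop("schema refers to column(s) absent from the file: ",
           paste(miss, collapse = ", "))
    }
    idx <- match(unname(schema), names(df))
    names(df)[idx] <- names(schema)
  }
  validate_clinical(df, arms = arms)
}

#' Write a clinical table to CSV
#'
#' @param clinical A clinical table.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  write.csv(as.data.frame(clinical), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
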