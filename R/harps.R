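# HARPS: HER2 activation response predictive signature. Youden-index cut
# points for phospho-EGFR Y1173 and phospho-ERBB2 Y1248 are derived in a
# derivation cohort (TN patients on neratinib) on the harmonized scale and
# extrapolated to the full TN population; HARPS+ requires co-elevation of
# both markers at or above their cuts.

HARPS_MARKERS <- c("EGFR Y1173", "ERBB2 Y1248")

#' Youden-index optimal cut point
#'
#' Evaluates `J = sensitivity + specificity - 1` (positivity: value >= cut)
#' over candidate thresholds at the midpoints between consecutive distinct
#' sorted values plus the two infinite extremes, and returns the cut
#' maximizing J, ties broken toward the lowest cut.
#'
#' @param values Finite numeric biomarker values.
#' @param labels Binary 0/1 outcome with both classes present.
#' @return List with `cut`, `j`, `sensitivity`, `specificity` at the cut.
#' @export
youden_cutpoint <- function(values, labels) {
  stopifnot(length(values) == length(labels), all(is.finite(values)),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present")
  }
  v <- sort(unique(values))
  cands <- c(-Inf, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(cands, function(cut) sum(labels == 1 & values >= cut),
                 numeric(1L)) / n_pos
  spec <- vapply(cands, function(cut) sum(labels == 0 & values < cut),
                 numeric(1L)) / n_neg
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]   # candidates ascending: first = lowest cut
  list(cut = cands[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Derive a HARPS model in a derivation cohort
#'
#' Computes independent Youden-index cuts for the two marker
#' phosphoproteins against pCR within the derivation filter (by default TN
#' patients on the neratinib arm), on the harmonized scale.
#'
#' @param harmonized Harmonized patient x analyte matrix.
#' @param clinical Clinical table for the same patients.
#' @param derivation_filter List with `subtype` and/or `arm` components
#'   defining the derivation cohort.
#' @param markers The two marker analytes (default EGFR Y1173 and
#'   ERBB2 Y1248).
#' @return A list of class `"harps_model"`: per-marker `cuts`, `j`,
#'   `sensitivity`, `specificity`, the `rule` identifier (`"AND"`), and
#'   `derivation` metadata (filter, n, n_pcr).
#' @export
derive_harps <- function(harmonized, clinical,
                         derivation_filter = list(subtype = "TN", arm = "N"),
                         markers = HARPS_MARKERS) {
  stopifnot(length(markers) == 2L)
  markers <- normalize_analyte_names(markers)
  missing_m <- setdiff(markers, colnames(harmonized))
  if (length(missing_m)) {
    stop("marker analyte(s) absent from the matrix: ",
         paste(missing_m, collapse = ", "))
  }
  clinical <- clinical[match(rownames(harmonized), clinical$patient_id), ,
                       drop = FALSE]
  sel <- rep(TRUE, nrow(clinical))
  if (!is.null(derivation_filter$subtype)) {
    sel <- sel & clinical$subtype == derivation_filter$subtype
  }
  if (!is.null(derivation_filter$arm)) {
    sel <- sel & clinical$arm == derivation_filter$arm
  }
  sel <- sel & !is.na(harmonized[, markers[1L]]) &
    !is.na(harmonized[, markers[2L]])
  if (sum(sel) < 10L) {
    stop("derivation cohort has fewer than 10 usable patients (",
         sum(sel), ")")
  }
  y <- clinical$pcr[sel]
  if (length(unique(y)) < 2L) {
    stop("derivation cohort must contain both pCR classes")
  }
  fits <- lapply(markers, function(mk) {
    youden_cutpoint(harmonized[sel, mk], y)
  })
  names(fits) <- markers
  structure(list(
    markers = markers,
    cuts = setNames(vapply(fits, `[[`, numeric(1L), "cut"), markers),
    j = setNames(vapply(fits, `[[`, numeric(1L), "j"), markers),
    sensitivity = setNames(vapply(fits, `[[`, numeric(1L), "sensitivity"),
                           markers),
    specificity = setNames(vapply(fits, `[[`, numeric(1L), "specificity"),
                           markers),
    rule = "AND",
    derivation = list(filter = derivation_filter, n = sum(sel),
                      n_pcr = sum(y))
  ), class = "harps_model")
}

#' Classify patients by HARPS status
#'
#' HARPS+ iff both marker values are at or above their cuts (the
#' co-activation AND rule, boundary convention >=). Patients with a masked
#' marker get `NA`.
#'
#' @param harmonized Harmonized patient x analyte matrix.
#' @param model A `"harps_model"`.
#' @return Character vector (named by patient) in `{"HARPS+", "HARPS-"}`,
#'   `NA` where a marker is masked.
#' @export
harps_classify <- function(harmonized, model) {
  stopifnot(inherits(model, "harps_model"))
  x1 <- harmonized[, model$markers[1L]]
  x2 <- harmonized[, model$markers[2L]]
  status <- ifelse(x1 >= model$cuts[1L] & x2 >= model$cuts[2L],
                   "HARPS+", "HARPS-")
  names(status) <- rownames(harmonized)
  n_na <- sum(is.na(status))
  if (n_na) {
    message(n_na, " patient(s) with a masked marker left unclassified")
  }
  status
}

#' Response rates by arm and HARPS status
#'
#' @param status Named HARPS status vector from [harps_classify()].
#' @param clinical Clinical table.
#' @param population_filter List restricting the tabulated population
#'   (default TN patients); arms absent from the population are omitted.
#' @return data.frame with `arm`, `status`, `n`, `n_pcr`, `rate`.
#' @export
harps_response_table <- function(status, clinical,
                                 population_filter = list(subtype = "TN")) {
  st <- status[clinical$patient_id]
  sel <- !is.na(st)
  if (!is.null(population_filter$subtype)) {
    sel <- sel & clinical$subtype == population_filter$subtype
  }
  if (!is.null(population_filter$arm)) {
    sel <- sel & clinical$arm == population_filter$arm
  }
  cl <- clinical[sel, , drop = FALSE]
  st <- st[sel]
  out <- do.call(rbind, lapply(unique(cl$arm), function(a) {
    do.call(rbind, lapply(c("HARPS+", "HARPS-"), function(s) {
      pick <- cl$arm == a & st == s
      if (!sum(pick)) return(NULL)
      data.frame(arm = a, status = s, n = sum(pick),
                 n_pcr = sum(cl$pcr[pick]), rate = mean(cl$pcr[pick]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate HARPS status against another label
#'
#' E.g. the distribution of transcriptomic response-predictive subtypes
#' within the HARPS+ and HARPS- cohorts.
#'
#' @param status Named HARPS status vector.
#' @param labels Label vector named by (or aligned with) the same patients.
#' @return data.frame with `status`, `label`, `n` (zero rows retained so
#'   the table covers the full status x label grid).
#' @export
harps_by_label <- function(status, labels) {
  if (!is.null(names(labels)) && !is.null(names(status))) {
    labels <- labels[names(status)]
  }
  stopifnot(length(status) == length(labels))
  keep <- !is.na(status) & !is.na(labels)
  tab <- table(status = status[keep], label = labels[keep])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3L] <- "n"
  out
}

#' @export
print.harps_model <- function(x, ...) {
  cat("HARPS model (rule:", x$rule, ")\n")
  for (mk in x$markers) {
    cat(sprintf("  %s: cut %.4g (J = %.3f, sens %.3f, spec %.3f)\n",
                mk, x$cuts[mk], x$j[mk], x$sensitivity[mk],
                x$specificity[mk]))
  }
  cat(sprintf("  derivation: n = %d, n_pCR = %d\n",
              x$derivation$n, x$derivation$n_pcr))
  invisible(x)
}

#' Serialize / deserialize a HARPS model
#'
#' @param model A `"harps_model"`.
#' @param path JSON path.
#' @export
write_harps_model <- function(model, path) {
  payload <- unclass(model)
  for (f in c("cuts", "j", "sensitivity", "specificity")) {
    payload[[f]] <- as.list(payload[[f]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_harps_model
#' @export
read_harps_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cuts <- unlist(raw$cuts)
  raw$j <- unlist(raw$j)
  raw$sensitivity <- unlist(raw$sensitivity)
  raw$specificity <- unlist(raw$specificity)
  structure(raw, class = "harps_model")
}
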