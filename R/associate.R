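# Per-analyte association screens: adjusted logistic likelihood-ratio
# tests against pCR, Gaussian linear-model LR tests between groups, and
# Benjamini-Hochberg control within each screen's family.

#' Logistic likelihood-ratio test for one biomarker
#'
#' Fits `response ~ biomarker + covariates` and the covariate-only reduced
#' model by maximum likelihood and returns the likelihood-ratio statistic
#' `2 * (ll_full - ll_reduced)` with its chi-squared(1) upper-tail p value.
#' Non-convergence or (quasi-)complete separation is flagged rather than
#' raised: flagged fits carry `NA` p values and are excluded from BH
#' families downstream.
#'
#' @param response Binary 0/1 vector with both classes present.
#' @param biomarker Non-constant numeric vector.
#' @param covariates Optional data.frame of adjustment covariates
#'   (categorical or numeric).
#' @return List with `coefficient`, `lr_stat`, `lr_p` and `flagged`.
#' @export
fit_logistic_lr <- function(response, biomarker, covariates = NULL) {
  stopifnot(length(response) == length(biomarker))
  if (!all(response %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(response)) < 2L) {
    stop("response must contain both classes")
  }
  if (!all(is.finite(biomarker))) stop("biomarker must be finite")
  if (sd(biomarker) == 0) stop("biomarker is constant")
  dat <- data.frame(.y = response, .x = biomarker)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    dat <- cbind(dat, droplevels(as.data.frame(covariates)))
  }
  ctrl <- glm.control(maxit = 50L)
  full <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
                               control = ctrl))
  reduced <- suppressWarnings(glm(.y ~ . - .x, data = dat,
                                  family = binomial(), control = ctrl))
  co <- coef(full)[".x"]
  se <- sqrt(diag(vcov(full)))[".x"]
  flagged <- !full$converged || !reduced$converged ||
    is.na(co) || abs(co) > 15 || is.na(se) || se > 50
  lr_stat <- as.numeric(2 * (logLik(full) - logLik(reduced)))
  list(
    coefficient = unname(co),
    lr_stat = lr_stat,
    lr_p = if (flagged) NA_real_ else pchisq(lr_stat, df = 1L,
                                             lower.tail = FALSE),
    flagged = flagged
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment; `NA` entries are excluded from the
#' family and returned as `NA`.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# Covariate builder: keeps only the requested clinical variables that
# actually vary within the subset ("adjusted ... as appropriate").
build_covariates <- function(clinical, vars) {
  keep <- vars[vapply(vars, function(v) {
    length(unique(clinical[[v]])) >= 2L
  }, logical(1L))]
  if (!length(keep)) return(NULL)
  out <- as.data.frame(clinical)[, keep, drop = FALSE]
  out[] <- lapply(out, factor)
  out
}

scope_subset <- function(clinical, scope) {
  if (identical(scope, "population")) {
    list(rows = seq_len(nrow(clinical)), covars = c("hr", "her2", "arm"))
  } else if (startsWith(scope, "arm:")) {
    a <- sub("^arm:", "", scope)
    list(rows = which(clinical$arm == a), covars = c("hr", "her2"))
  } else if (startsWith(scope, "subtype:")) {
    s <- sub("^subtype:", "", scope)
    list(rows = which(clinical$subtype == s), covars = "arm")
  } else {
    stop("unknown scope: ", scope,
         " (use 'population', 'arm:<name>' or 'subtype:<name>')")
  }
}

#' Screen analytes for association with pCR
#'
#' For every sufficiently covered analyte in the scope, fits the adjusted
#' logistic model (`pCR ~ biomarker + HR + HER2 + arm` in the population;
#' `+ HR + HER2` as appropriate within an arm; `+ arm` within a subtype)
#' and performs the likelihood-ratio test of the biomarker term. BH
#' adjustment is applied within the scope's family (flagged fits are
#' excluded from the family).
#'
#' @param harmonized Harmonized patient x analyte matrix.
#' @param clinical Clinical table (same patients).
#' @param scope `"population"`, `"arm:<name>"` or `"subtype:<name>"`.
#' @param config A [pipeline_config()] (`bh_alpha`, `min_coverage`).
#' @return A data.frame of association records: `analyte`, `scope`, `n`,
#'   `direction`, `coefficient`, `lr_stat`, `lr_p`, `bh_p`, `significant`,
#'   `nominal`, `flagged`. Returns an empty frame (with a warning) when
#'   the scope has fewer than 10 patients or a single-class response.
#' @export
association_screen <- function(harmonized, clinical, scope = "population",
                               config = pipeline_config()) {
  clinical <- clinical[match(rownames(harmonized), clinical$patient_id), ,
                       drop = FALSE]
  if (anyNA(clinical$patient_id)) {
    stop("harmonized matrix contains patients absent from the clinical table")
  }
  sc <- scope_subset(clinical, scope)
  rows <- sc$rows
  empty <- data.frame(analyte = character(0), scope = character(0),
                      n = integer(0), direction = numeric(0),
                      coefficient = numeric(0), lr_stat = numeric(0),
                      lr_p = numeric(0), bh_p = numeric(0),
                      significant = logical(0), nominal = logical(0),
                      flagged = logical(0))
  if (length(rows) < 10L || length(unique(clinical$pcr[rows])) < 2L) {
    warning("scope ", scope, " skipped: fewer than 10 patients or ",
            "single-class response")
    return(empty)
  }
  sub_m <- harmonized[rows, , drop = FALSE]
  sub_cl <- clinical[rows, , drop = FALSE]
  coverage <- colMeans(!is.na(sub_m))
  analytes <- colnames(sub_m)[coverage >= config$min_coverage]
  records <- lapply(analytes, function(a) {
    x <- sub_m[, a]
    keep <- !is.na(x)
    y <- sub_cl$pcr[keep]
    if (length(unique(y)) < 2L || sd(x[keep]) == 0) {
      return(data.frame(analyte = a, scope = scope, n = sum(keep),
                        direction = NA_real_, coefficient = NA_real_,
                        lr_stat = NA_real_, lr_p = NA_real_,
                        bh_p = NA_real_, significant = FALSE,
                        nominal = FALSE, flagged = TRUE))
    }
    cov <- build_covariates(sub_cl[keep, , drop = FALSE], sc$covars)
    fit <- fit_logistic_lr(y, x[keep], cov)
    data.frame(analyte = a, scope = scope, n = sum(keep),
               direction = sign(fit$coefficient),
               coefficient = fit$coefficient,
               lr_stat = fit$lr_stat, lr_p = fit$lr_p,
               bh_p = NA_real_, significant = FALSE, nominal = FALSE,
               flagged = fit$flagged)
  })
  out <- do.call(rbind, c(records, list(empty)))
  out$bh_p <- bh_adjust(out$lr_p)
  out$significant <- !is.na(out$bh_p) & out$bh_p < config$bh_alpha
  out$nominal <- !is.na(out$lr_p) & out$lr_p < 0.05
  rownames(out) <- NULL
  out
}

#' Differential expression screen between groups
#'
#' Per analyte, a Gaussian linear-model likelihood-ratio test of the group
#' term (`value ~ group + covariates` versus `value ~ covariates`), with
#' BH adjustment within the screen.
#'
#' @param harmonized Harmonized patient x analyte matrix.
#' @param groups Grouping vector (>= 2 levels) aligned with the rows.
#' @param covariates Optional data.frame of adjustment covariates.
#' @param bh_alpha Significance threshold on the BH-adjusted p value.
#' @return A data.frame with `analyte`, `n`, `direction` (sign of the
#'   second-level coefficient for binary groupings, `NA` otherwise),
#'   `lr_stat`, `lr_p`, `bh_p`, `significant`, `nominal`.
#' @export
differential_screen <- function(harmonized, groups, covariates = NULL,
                                bh_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("grouping must have at least two levels")
  stopifnot(length(groups) == nrow(harmonized))
  base_cov <- if (!is.null(covariates)) {
    droplevels(as.data.frame(covariates))
  } else NULL
  records <- lapply(colnames(harmonized), function(a) {
    x <- harmonized[, a]
    keep <- !is.na(x) & !is.na(groups)
    g <- droplevels(groups[keep])
    if (nlevels(g) < 2L) {
      return(data.frame(analyte = a, n = sum(keep), direction = NA_real_,
                        lr_stat = NA_real_, lr_p = NA_real_,
                        bh_p = NA_real_, significant = FALSE,
                        nominal = FALSE))
    }
    dat <- data.frame(.v = x[keep], .g = g)
    if (!is.null(base_cov)) {
      dat <- cbind(dat, droplevels(base_cov[keep, , drop = FALSE]))
    }
    full <- lm(.v ~ ., data = dat)
    reduced <- lm(.v ~ . - .g, data = dat)
    lr_stat <- as.numeric(2 * (logLik(full) - logLik(reduced)))
    df <- nlevels(g) - 1L
    direction <- if (nlevels(g) == 2L) {
      unname(sign(coef(full)[paste0(".g", levels(g)[2L])]))
    } else NA_real_
    data.frame(analyte = a, n = sum(keep), direction = direction,
               lr_stat = lr_stat,
               lr_p = pchisq(lr_stat, df = df, lower.tail = FALSE),
               bh_p = NA_real_, significant = FALSE, nominal = FALSE)
  })
  out <- do.call(rbind, records)
  out$bh_p <- bh_adjust(out$lr_p)
  out$significant <- !is.na(out$bh_p) & out$bh_p < bh_alpha
  out$nominal <- !is.na(out$lr_p) & out$lr_p < 0.05
  rownames(out) <- NULL
  out
}

#' Count significant records
#'
#' @param records A screen result data.frame with a `significant` column.
#' @return Integer count.
#' @export
count_significant <- function(records) {
  sum(records$significant, na.rm = TRUE)
}

#' Response rates by group
#'
#' @param labels Grouping vector aligned with the clinical rows.
#' @param clinical Clinical table with a `pcr` column.
#' @return data.frame with `group`, `n`, `n_pcr`, `rate`; empty groups are
#'   excluded with a warning.
#' @export
group_response_rates <- function(labels, clinical) {
  stopifnot(length(labels) == nrow(clinical))
  keep <- !is.na(labels)
  labels <- labels[keep]
  clinical <- clinical[keep, , drop = FALSE]
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts == 0L)) {
    warning("empty group(s) excluded: ",
            paste(names(counts)[counts == 0L], collapse = ", "))
  }
  groups <- names(counts)[counts > 0L]
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- labels == g
    data.frame(group = g, n = sum(sel),
               n_pcr = sum(clinical$pcr[sel]),
               rate = mean(clinical$pcr[sel]))
  }))
  rownames(out) <- NULL
  out
}
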