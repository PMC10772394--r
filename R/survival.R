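# DRFS analysis: Kaplan-Meier curves, Cox hazard ratios for pCR within
# clusters, and per-analyte Cox screens within non-responders.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator over the observed event times.
#'
#' @param times Positive event/censoring times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`
#'   (non-increasing, starting from S(0) = 1).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survfit(Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

# Cox fit wrapper with monotone-likelihood flagging.
#' Cox proportional-hazards fit for one exposure
#'
#' Partial-likelihood fit with Efron tie handling. Non-identifiable fits
#' (monotone likelihood, e.g. no events in one exposure group) are flagged
#' and returned with infinite confidence bounds rather than raised.
#'
#' @param times,events Survival outcome.
#' @param exposure Numeric or binary exposure of interest.
#' @param covariates Optional data.frame of adjustment covariates.
#' @param stratum Label carried into the output row.
#' @return One-row data.frame: `stratum`, `n`, `n_events`, `coefficient`,
#'   `se`, `hazard_ratio`, `ci_low`, `ci_high`, `wald_p`, `lr_p`,
#'   `flagged`.
#' @export
cox_fit <- function(times, events, exposure, covariates = NULL,
                    stratum = "population") {
  stopifnot(length(times) == length(events),
            length(times) == length(exposure))
  if (sum(events) < 1) stop("at least one event is required")
  dat <- data.frame(.t = times, .e = events, .x = exposure)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    dat <- cbind(dat, droplevels(as.data.frame(covariates)))
  }
  monotone <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.t, .e) ~ ., data = dat, ties = "efron",
          control = coxph.control(iter.max = 50L)),
    warning = function(w) {
      if (grepl(paste0("infinite|converged before|beta may be infinite|",
                       "Ran out of iterations|NaN"),
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- coef(fit)[".x"]
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[".x"])
  flagged <- monotone || is.na(co) || is.na(se) || abs(co) > 15 || se > 50
  null_ll <- fit$loglik[1L]
  # LR p for the exposure term: refit without it when covariates present
  lr_stat <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    2 * (fit$loglik[2L] - null_ll)
  } else {
    red <- coxph(Surv(.t, .e) ~ . - .x, data = dat, ties = "efron",
                 control = coxph.control(iter.max = 50L))
    2 * (fit$loglik[2L] - red$loglik[2L])
  }
  zcrit <- qnorm(0.975)
  data.frame(
    stratum = stratum,
    n = nrow(dat),
    n_events = sum(events),
    coefficient = unname(co),
    se = unname(se),
    hazard_ratio = exp(unname(co)),
    ci_low = if (flagged) 0 else exp(co - zcrit * se),
    ci_high = if (flagged) Inf else exp(co + zcrit * se),
    wald_p = if (flagged) NA_real_ else {
      2 * stats::pnorm(abs(co / se), lower.tail = FALSE)
    },
    lr_p = if (flagged) NA_real_ else {
      pchisq(max(lr_stat, 0), df = 1L, lower.tail = FALSE)
    },
    flagged = flagged,
    row.names = NULL
  )
}

#' DRFS hazard ratios for pCR within each cluster
#'
#' One Cox fit (exposure = pCR) per cluster; clusters without events or
#' with single-class pCR are flagged.
#'
#' @param clinical Clinical table with `drfs_time`, `drfs_event`, `pcr`.
#' @param labels Cluster labels (named by patient or aligned with rows).
#' @return Forest-ready data.frame, one row per cluster.
#' @export
drfs_by_cluster <- function(clinical, labels) {
  if (!is.null(names(labels))) labels <- labels[clinical$patient_id]
  stopifnot(length(labels) == nrow(clinical))
  if (!all(c("drfs_time", "drfs_event") %in% names(clinical))) {
    stop("clinical table lacks DRFS columns")
  }
  keep <- !is.na(clinical$drfs_time) & !is.na(labels)
  clinical <- clinical[keep, , drop = FALSE]
  labels <- labels[keep]
  out <- lapply(unique(labels), function(g) {
    sel <- labels == g
    cl <- clinical[sel, , drop = FALSE]
    if (sum(cl$drfs_event) < 1L || length(unique(cl$pcr)) < 2L) {
      return(data.frame(stratum = as.character(g), n = nrow(cl),
                        n_events = sum(cl$drfs_event),
                        coefficient = NA_real_, se = NA_real_,
                        hazard_ratio = NA_real_, ci_low = 0, ci_high = Inf,
                        wald_p = NA_real_, lr_p = NA_real_, flagged = TRUE))
    }
    cox_fit(cl$drfs_time, cl$drfs_event, cl$pcr, stratum = as.character(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-analyte DRFS screen within non-responders, by cluster
#'
#' Within each cluster's non-pCR patients, fits a Cox model per analyte
#' adjusting for HR and HER2 status (when they vary in the subset), with
#' likelihood-ratio p values and BH adjustment within the cluster's family
#' of analytes. Clusters with fewer than `min_n` non-responders or fewer
#' than `min_events` events are skipped with a warning; flagged fits never
#' enter a BH family.
#'
#' @param harmonized Harmonized patient x analyte matrix.
#' @param clinical Clinical table with DRFS columns.
#' @param labels Cluster labels (named by patient or aligned with rows).
#' @param responders If `FALSE` (default) screen non-responders; if `TRUE`
#'   screen responders.
#' @param min_n,min_events Skip thresholds per cluster.
#' @param bh_alpha BH significance threshold.
#' @return data.frame of records: `cluster`, `analyte`, `n`, `n_events`,
#'   `hazard_ratio`, `lr_p`, `wald_p`, `bh_p`, `significant`, `nominal`,
#'   `flagged`.
#' @export
analyte_survival_screen <- function(harmonized, clinical, labels,
                                    responders = FALSE, min_n = 10L,
                                    min_events = 3L, bh_alpha = 0.05) {
  if (!is.null(names(labels))) labels <- labels[clinical$patient_id]
  stopifnot(length(labels) == nrow(clinical))
  harmonized <- harmonized[clinical$patient_id, , drop = FALSE]
  target_pcr <- if (responders) 1L else 0L
  res <- list()
  for (g in unique(labels[!is.na(labels)])) {
    sel <- !is.na(labels) & labels == g & clinical$pcr == target_pcr &
      !is.na(clinical$drfs_time)
    cl <- clinical[sel, , drop = FALSE]
    if (nrow(cl) < min_n || sum(cl$drfs_event) < min_events) {
      warning("cluster ", g, " skipped in survival screen (",
              nrow(cl), " patients, ", sum(cl$drfs_event), " events)")
      next
    }
    cov <- build_covariates(cl, c("hr", "her2"))
    rows <- lapply(colnames(harmonized), function(a) {
      x <- harmonized[sel, a]
      keep <- !is.na(x)
      if (sum(keep) < min_n || sum(cl$drfs_event[keep]) < min_events ||
          sd(x[keep]) == 0) {
        return(NULL)
      }
      fit <- cox_fit(cl$drfs_time[keep], cl$drfs_event[keep], x[keep],
                     covariates = if (is.null(cov)) NULL else
                       cov[keep, , drop = FALSE],
                     stratum = as.character(g))
      data.frame(cluster = as.character(g), analyte = a, n = fit$n,
                 n_events = fit$n_events, hazard_ratio = fit$hazard_ratio,
                 lr_p = fit$lr_p, wald_p = fit$wald_p, bh_p = NA_real_,
                 significant = FALSE, nominal = FALSE,
                 flagged = fit$flagged)
    })
    block <- do.call(rbind, rows)
    if (is.null(block)) next
    block$bh_p <- bh_adjust(ifelse(block$flagged, NA_real_, block$lr_p))
    block$significant <- !is.na(block$bh_p) & block$bh_p < bh_alpha
    block$nominal <- !is.na(block$lr_p) & block$lr_p < 0.05
    res[[as.character(g)]] <- block
  }
  if (!length(res)) {
    return(data.frame(cluster = character(0), analyte = character(0),
                      n = integer(0), n_events = integer(0),
                      hazard_ratio = numeric(0), lr_p = numeric(0),
                      wald_p = numeric(0), bh_p = numeric(0),
                      significant = logical(0), nominal = logical(0),
                      flagged = logical(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
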