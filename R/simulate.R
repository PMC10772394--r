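# Synthetic cohort and spot-level generator with known ground truth.
# The generator emulates the statistical structure the pipeline assumes:
# multinomial receptor subtypes, HER2-eligibility-constrained arm
# allocation, pathway-block-correlated latent signaling values, planted
# logit effects on pCR, per-(array, analyte) additive/multiplicative batch
# effects, triplicate spotting with replicate noise, and exponential DRFS
# hazards depending on pCR.

#' Default analyte name list
#'
#' The first entries carry the field's marker names (including the two
#' HARPS phosphoproteins EGFR Y1173 and ERBB2 Y1248, and the global
#' resistance markers cyclin D1 / ER alpha / AR S650); the remainder are
#' numbered placeholders.
#'
#' @param n Number of analytes.
#' @return Character vector of length `n`.
#' @export
default_analyte_names <- function(n = 139L) {
  named <- c("EGFR Y1173", "ERBB2 Y1248", "Cyclin D1", "ER alpha", "AR S650",
             "STAT1 Y701", "STAT5 Y694", "JAK2 Y1007", "TYK2 Y1054-Y1055",
             "PDL1", "AKT S473", "AKT T308", "TIE2 Y992", "ERK T202-Y204",
             "HLA-DR", "Ki67", "Cyclin B1", "PTEN", "IGF1R", "p53")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("Analyte %03d", seq_len(n - length(named))))
}

#' Simulation configuration
#'
#' Defaults reproduce the structure of the analysed cohort: 736 patients,
#' 139 analytes on 3 arrays, subtype proportions 0.384/0.368/0.158/0.09,
#' the eight arms with HER2-eligibility-respecting allocation, five planted
#' analytes with |beta| = 0.6 on the pCR logit, per-subtype baseline pCR
#' rates (18% HR+HER2-, 40% TN, 38% HR+HER2+, 62% HR-HER2+), batch shift
#' SD 0.5 / scale SD 0.2, and exponential DRFS with pCR hazard ratio 0.25.
#'
#' @param n_patients Cohort size.
#' @param subtype_proportions Length-4 subtype probabilities (order of
#'   [SUBTYPE_LEVELS]).
#' @param arms Arm table as from [default_arms()] (columns `arm`,
#'   `eligibility`, `weight`).
#' @param n_analytes,n_arrays Analyte and array-batch counts.
#' @param analyte_names Analyte name vector (length `n_analytes`).
#' @param batch_shift_sd,batch_scale_sd SDs of the per-(array, analyte)
#'   additive shift and of the log of the multiplicative scale.
#' @param block_size,block_rho Pathway-block structure: analytes are
#'   assigned round-robin to `ceiling(n_analytes / block_size)` blocks with
#'   within-block latent correlation `block_rho`.
#' @param effect_table data.frame (`analyte`, `beta`) of planted global
#'   coefficients on the pCR logit; referenced analytes must exist.
#' @param baseline_pcr_logit Named per-subtype baseline logits.
#' @param subtype_mean_shifts Optional 4 x n_analytes matrix of latent mean
#'   offsets (rows in [SUBTYPE_LEVELS] order); `NULL` installs a default
#'   with HER2-block elevation in HER2+ subtypes, endocrine-block elevation
#'   in HR+ subtypes and immune-block elevation in TN.
#' @param replicate_cv Spot replicate coefficient of variation.
#' @param neg_control_level Background (secondary-antibody-only) level on
#'   the endpoint scale.
#' @param total_protein_sd SD of the log total-protein loading factor.
#' @param latent_scale,intensity_base Latent-to-intensity map: pre-batch
#'   endpoint = `intensity_base * exp(latent_scale * z)` (log-normal,
#'   positive, right-skewed).
#' @param lambda0 Baseline exponential DRFS hazard (events / year) for
#'   non-pCR patients.
#' @param hr_pcr Hazard ratio applied for pCR.
#' @param censor_horizon Administrative censoring time (years).
#' @param masked Named list `array label -> analyte names` absent from that
#'   array (explicit mask, never imputed).
#' @param seed Integer RNG seed; spot generation derives its own stream
#'   deterministically from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 736L,
                       subtype_proportions = c(0.384, 0.368, 0.158, 0.09),
                       arms = default_arms(),
                       n_analytes = 139L,
                       n_arrays = 3L,
                       analyte_names = default_analyte_names(n_analytes),
                       batch_shift_sd = 0.5,
                       batch_scale_sd = 0.2,
                       block_size = 10L,
                       block_rho = 0.5,
                       effect_table = data.frame(
                         analyte = c("ERBB2 Y1248", "EGFR Y1173", "Cyclin D1",
                                     "ER alpha", "AR S650"),
                         beta = c(0.6, 0.6, -0.6, -0.6, -0.6)),
                       baseline_pcr_logit = stats::qlogis(
                         c(`HR+HER2-` = 0.18, TN = 0.40,
                           `HR+HER2+` = 0.38, `HR-HER2+` = 0.62)),
                       subtype_mean_shifts = NULL,
                       replicate_cv = 0.05,
                       neg_control_level = 0.5,
                       total_protein_sd = 0.2,
                       latent_scale = 0.25,
                       intensity_base = 10,
                       lambda0 = 0.05,
                       hr_pcr = 0.25,
                       censor_horizon = 10,
                       masked = list(),
                       seed = 1L) {
  subtype_proportions <- validate_proportions(subtype_proportions)
  stopifnot(n_patients >= 1L, n_analytes >= 1L, n_arrays >= 1L,
            length(analyte_names) == n_analytes,
            !anyDuplicated(analyte_names),
            batch_shift_sd >= 0, batch_scale_sd >= 0,
            block_rho >= 0, block_rho < 1,
            replicate_cv >= 0, total_protein_sd >= 0,
            lambda0 > 0, hr_pcr > 0, censor_horizon > 0)
  stopifnot(all(c("arm", "eligibility", "weight") %in% names(arms)),
            all(arms$eligibility %in% c("both", "her2_pos_only",
                                        "her2_neg_only")),
            all(arms$weight >= 0))
  analyte_names <- normalize_analyte_names(analyte_names)
  if (nrow(effect_table)) {
    effect_table$analyte <- normalize_analyte_names(effect_table$analyte)
    missing_eff <- setdiff(effect_table$analyte, analyte_names)
    if (length(missing_eff)) {
      stop("effect_table refers to unknown analyte(s): ",
           paste(missing_eff, collapse = ", "))
    }
  }
  if (is.null(names(baseline_pcr_logit)) ||
      !setequal(names(baseline_pcr_logit), SUBTYPE_LEVELS)) {
    stop("baseline_pcr_logit must be named by the four subtypes")
  }
  n_blocks <- max(1L, ceiling(n_analytes / block_size))
  block_id <- ((seq_len(n_analytes) - 1L) %% n_blocks) + 1L
  if (is.null(subtype_mean_shifts)) {
    subtype_mean_shifts <- default_subtype_shifts(analyte_names, block_id)
  }
  stopifnot(is.matrix(subtype_mean_shifts),
            nrow(subtype_mean_shifts) == length(SUBTYPE_LEVELS),
            ncol(subtype_mean_shifts) == n_analytes)
  rownames(subtype_mean_shifts) <- SUBTYPE_LEVELS
  colnames(subtype_mean_shifts) <- analyte_names
  for (a in names(masked)) {
    bad <- setdiff(masked[[a]], analyte_names)
    if (length(bad)) stop("masked refers to unknown analyte(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    subtype_proportions = subtype_proportions,
    arms = arms,
    n_analytes = as.integer(n_analytes),
    n_arrays = as.integer(n_arrays),
    analyte_names = analyte_names,
    batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd,
    block_id = block_id,
    block_rho = block_rho,
    effect_table = effect_table,
    baseline_pcr_logit = baseline_pcr_logit[SUBTYPE_LEVELS],
    subtype_mean_shifts = subtype_mean_shifts,
    replicate_cv = replicate_cv,
    neg_control_level = neg_control_level,
    total_protein_sd = total_protein_sd,
    latent_scale = latent_scale,
    intensity_base = intensity_base,
    lambda0 = lambda0,
    hr_pcr = hr_pcr,
    censor_horizon = censor_horizon,
    masked = masked,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Structured latent mean offsets: the block holding ERBB2 Y1248 is elevated
# in HER2+ subtypes, the ER alpha block in HR+ subtypes, the PDL1 (immune)
# block in TN. Magnitudes ~1 latent SD give visibly subtype-linked
# signaling blocks without overwhelming the shared variation.
default_subtype_shifts <- function(analyte_names, block_id) {
  shifts <- matrix(0, nrow = length(SUBTYPE_LEVELS),
                   ncol = length(analyte_names),
                   dimnames = list(SUBTYPE_LEVELS, analyte_names))
  block_of <- function(marker) {
    i <- match(marker, analyte_names)
    if (is.na(i)) return(integer(0))
    which(block_id == block_id[i])
  }
  her2_block <- block_of("ERBB2 Y1248")
  er_block <- block_of("ER alpha")
  imm_block <- block_of("PDL1")
  shifts[c("HR+HER2+", "HR-HER2+"), her2_block] <- 1
  shifts[c("HR+HER2-", "HR+HER2+"), er_block] <-
    shifts[c("HR+HER2-", "HR+HER2+"), er_block] + 1
  shifts["TN", imm_block] <- shifts["TN", imm_block] + 0.8
  shifts
}

#' Simulate a clinical cohort with ground truth
#'
#' Draws subtypes multinomially, assigns arms conditional on HER2
#' eligibility, generates block-correlated latent signaling values z,
#' draws pCR from `Bernoulli(plogis(baseline_subtype + sum(beta_k z_k)))`,
#' and DRFS times from an exponential hazard `lambda0 * hr_pcr^pcr`
#' censored at the horizon. Arrays are assigned by contiguous thirds of the
#' accrual order. Batch shift/scale realizations, total-protein loading
#' factors and the pre-noise batched endpoint values are drawn here so the
#' full ground truth is available before spot noise.
#'
#' @param config A [sim_config()].
#' @return A list with elements `clinical` (a clinical table) and `truth`
#'   (class `"sim_truth"`: `z`, `endpoint_true`, `batch_shift`,
#'   `batch_scale`, `beta`, `pcr_prob`, `hazard`, `tp_factor`, `mask`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  K <- config$n_analytes
  analytes <- config$analyte_names

  subtype <- sample(SUBTYPE_LEVELS, n, replace = TRUE,
                    prob = config$subtype_proportions)
  hr <- ifelse(subtype %in% c("HR+HER2-", "HR+HER2+"), "pos", "neg")
  her2 <- ifelse(subtype %in% c("HR+HER2+", "HR-HER2+"), "pos", "neg")

  arms <- config$arms
  arm <- character(n)
  for (i in seq_len(n)) {
    ok <- arms$eligibility == "both" |
      (her2[i] == "pos" & arms$eligibility == "her2_pos_only") |
      (her2[i] == "neg" & arms$eligibility == "her2_neg_only")
    ok <- ok & arms$weight > 0
    if (!any(ok)) {
      stop("no eligible arm with positive weight for a HER2 ",
           her2[i], " patient")
    }
    arm[i] <- sample(arms$arm[ok], 1L, prob = arms$weight[ok])
  }

  array_labels <- sprintf("array_%d", seq_len(config$n_arrays))
  array_id <- array_labels[ceiling(seq_len(n) / ceiling(n / config$n_arrays))]

  # block-correlated latent values plus subtype mean offsets
  z <- matrix(0, n, K, dimnames = list(NULL, analytes))
  rho <- config$block_rho
  for (b in unique(config$block_id)) {
    cols <- which(config$block_id == b)
    shared <- rnorm(n)
    z[, cols] <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(rnorm(n * length(cols)), n, length(cols))
  }
  z <- z + config$subtype_mean_shifts[subtype, , drop = FALSE]

  beta <- setNames(numeric(K), analytes)
  if (nrow(config$effect_table)) {
    beta[config$effect_table$analyte] <- config$effect_table$beta
  }
  eta <- config$baseline_pcr_logit[subtype] + drop(z %*% beta)
  pcr_prob <- plogis(eta)
  pcr <- rbinom(n, 1L, pcr_prob)

  hazard <- config$lambda0 * config$hr_pcr^pcr
  raw_time <- rexp(n, rate = hazard)
  drfs_event <- as.integer(raw_time <= config$censor_horizon)
  drfs_time <- pmin(raw_time, config$censor_horizon)

  # batch effects and loading factors realized per (array, analyte) / patient
  batch_scale <- matrix(exp(rnorm(config$n_arrays * K, 0,
                                  config$batch_scale_sd)),
                        config$n_arrays, K,
                        dimnames = list(array_labels, analytes))
  batch_shift <- matrix(rnorm(config$n_arrays * K, 0, config$batch_shift_sd),
                        config$n_arrays, K,
                        dimnames = list(array_labels, analytes))
  tp_factor <- rlnorm(n, 0, config$total_protein_sd)

  arr_idx <- match(array_id, array_labels)
  e <- config$intensity_base * exp(config$latent_scale * z)
  endpoint_true <- e * batch_scale[arr_idx, , drop = FALSE] +
    batch_shift[arr_idx, , drop = FALSE]

  mask <- matrix(FALSE, n, K, dimnames = list(NULL, analytes))
  for (a in names(config$masked)) {
    mask[array_id == a, analytes %in% config$masked[[a]]] <- TRUE
  }

  patient_id <- sprintf("P%04d", seq_len(n))
  rownames(z) <- rownames(endpoint_true) <- rownames(mask) <- patient_id

  mp <- sample(c("MP1", "MP2"), n, replace = TRUE, prob = c(0.55, 0.45))
  rps5_levels <- c("HER2-/Immune-/DRD-", "HER2-/Immune+", "HER2-/DRD+",
                   "HER2+/Luminal", "HER2+/Basal")
  rps5 <- ifelse(her2 == "pos",
                 sample(rps5_levels[4:5], n, replace = TRUE),
                 sample(rps5_levels[1:3], n, replace = TRUE,
                        prob = c(0.4, 0.35, 0.25)))

  clinical <- validate_clinical(data.frame(
    patient_id = patient_id, hr = hr, her2 = her2, arm = arm,
    pcr = pcr, drfs_time = drfs_time, drfs_event = drfs_event,
    array_id = array_id, mp = mp, rps5 = rps5,
    stringsAsFactors = FALSE
  ), arms = arms$arm)

  truth <- structure(list(
    z = z, endpoint_true = endpoint_true,
    batch_shift = batch_shift, batch_scale = batch_scale,
    beta = beta, pcr_prob = pcr_prob, hazard = hazard,
    tp_factor = setNames(tp_factor, patient_id), mask = mask
  ), class = "sim_truth")

  list(clinical = clinical, truth = truth)
}

#' Simulate spot-level RPPA data for a generated cohort
#'
#' Emits triplicate `primary`, `negative_control` and `total_protein` spot
#' records. For each (patient, analyte), the noise-free primary level is
#' `(endpoint_true + neg_control_level) * tp_factor`; replicates carry
#' mean-unbiased multiplicative log-normal noise with coefficient of
#' variation `replicate_cv` (with `replicate_cv = 0` the three replicates
#' are identical and quantification recovers `endpoint_true` exactly).
#' Analytes masked on an array are omitted.
#'
#' @param config The [sim_config()] used to generate the cohort.
#' @param clinical Clinical table from [simulate_cohort()].
#' @param truth Ground truth from [simulate_cohort()].
#' @return A validated spot table.
#' @export
simulate_spots <- function(config, clinical, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed((config$seed %% 1000000L) * 2L + 1L)
  n <- nrow(clinical)
  K <- config$n_analytes
  analytes <- config$analyte_names
  cv <- config$replicate_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(m) {
    if (sdlog == 0) rep(1, m) else exp(rnorm(m, -sdlog^2 / 2, sdlog))
  }

  tp <- truth$tp_factor[clinical$patient_id]
  prim_level <- (truth$endpoint_true + config$neg_control_level) * tp
  neg_level <- config$neg_control_level * tp

  keep <- !t(truth$mask)                # analyte-major within patient
  pid <- rep(clinical$patient_id, each = K)[as.vector(keep)]
  aid <- rep(clinical$array_id, each = K)[as.vector(keep)]
  ana <- rep(analytes, times = n)[as.vector(keep)]
  v_prim <- as.vector(t(prim_level))[as.vector(keep)]
  v_neg <- rep(neg_level, each = K)[as.vector(keep)]
  m <- length(pid)

  triplicate <- function(pid, aid, ana, level, type) {
    data.frame(
      patient_id = rep(pid, each = 3L),
      array_id = rep(aid, each = 3L),
      analyte = rep(ana, each = 3L),
      spot_type = type,
      replicate_index = rep(1:3, length(pid)),
      intensity = pmax(rep(level, each = 3L) * noise(3L * length(pid)), 0),
      stringsAsFactors = FALSE
    )
  }
  spots <- rbind(
    triplicate(pid, aid, ana, v_prim, "primary"),
    triplicate(pid, aid, ana, v_neg, "negative_control"),
    triplicate(clinical$patient_id, clinical$array_id, "", tp, "total_protein")
  )
  validate_spots(spots)
}
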