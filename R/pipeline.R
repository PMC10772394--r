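# End-to-end orchestration: simulate (or load) -> quantify -> harmonize ->
# associate -> cluster -> survival -> HARPS, with every stage communicating
# through the documented files and a manifest recording the run.

log_line <- function(con, ...) {
  line <- paste0(...)
  writeLines(line, con)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes each stage's table to `out_dir`:
#' `clinical.csv`, `spots.tsv`, per-array `endpoint_<array>.tsv`,
#' `harmonized.tsv` + `harmonization_model.json`, `associations.tsv`,
#' `clusters.tsv` + `cluster_summary.tsv` + `cluster_flows.tsv`,
#' `survival_clusters.tsv` + `survival_analytes.tsv`, `harps.json` +
#' `harps_status.tsv` + `harps_response.tsv`, and a `manifest.json`
#' recording package version, seed, resolved configuration, per-stage
#' dimensions and an MD5 checksum per output. Stages communicate only via
#' these files, so any stage can be re-run on externally exported
#' matrices. Re-running with the same seed reproduces every output byte
#' for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param simulation A [sim_config()] to generate inputs, or `NULL` to
#'   read existing inputs.
#' @param spots_path,clinical_path Input files used when `simulation` is
#'   `NULL`.
#' @param split Sub-split policy after the dendrogram cut: `"largest"`
#'   splits the largest cluster into its two top subtree branches,
#'   `"none"` skips the split, or a specific cluster id.
#' @param harps_filter Derivation-cohort filter passed to
#'   [derive_harps()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`clinical`, `truth`, `endpoints`, `harmonized`, `models`,
#'   `associations`, `labels`, `cluster_summary`, `survival`,
#'   `survival_screen`, `harps`, `harps_status`, `manifest`).
#' @export
run_pipeline <- function(out_dir,
                         config = pipeline_config(),
                         simulation = sim_config(seed = config$seed),
                         spots_path = NULL, clinical_path = NULL,
                         split = "largest",
                         harps_filter = list(subtype = "TN", arm = "N")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), "wt")
  on.exit(close(log_con), add = TRUE)
  log_line(log_con, "rppasig pipeline, package version ",
           as.character(packageVersion("rppasig")))
  log_line(log_con, "seed: ", config$seed)
  log_line(log_con, "config: ", jsonlite::toJSON(unclass(config),
                                                 auto_unbox = TRUE))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(simulation)) {
    log_line(log_con, "stage simulate: n = ", simulation$n_patients,
             ", analytes = ", simulation$n_analytes,
             ", arrays = ", simulation$n_arrays)
    sim <- stage("simulate", {
      cohort <- simulate_cohort(simulation)
      spots <- simulate_spots(simulation, cohort$clinical, cohort$truth)
      list(clinical = cohort$clinical, truth = cohort$truth, spots = spots)
    })
    clinical <- sim$clinical
    truth <- sim$truth
    spots <- sim$spots
    write_clinical(clinical, file.path(out_dir, "clinical.csv"))
    write_spots(spots, file.path(out_dir, "spots.tsv"))
  } else {
    if (is.null(spots_path) || is.null(clinical_path)) {
      stop("either a simulation config or spots/clinical paths are required")
    }
    clinical <- stage("read", read_clinical(clinical_path))
    spots <- stage("read", read_spots(spots_path))
  }

  log_line(log_con, "stage quantify")
  endpoints <- stage("quantify", quantify_all(spots))
  for (a in names(endpoints)) {
    write_matrix(endpoints[[a]],
                 file.path(out_dir, paste0("endpoint_", a, ".tsv")))
  }

  log_line(log_con, "stage harmonize: B = ", config$n_subsamples,
           ", fraction = ", config$subsample_fraction)
  harm <- stage("harmonize", harmonize(endpoints, clinical, config))
  write_matrix(harm$matrix, file.path(out_dir, "harmonized.tsv"))
  write_harmonization_models(harm$models,
                             file.path(out_dir, "harmonization_model.json"))

  log_line(log_con, "stage associate: population screen")
  assoc <- stage("associate",
                 association_screen(harm$matrix, clinical, "population",
                                    config))
  write_tsv(assoc, file.path(out_dir, "associations.tsv"))

  log_line(log_con, "stage cluster: cut height = ", config$cut_height)
  cluster_out <- stage("cluster", {
    d <- pearson_distance(harm$matrix,
                          min_shared = config$min_shared_analytes)
    tree <- complete_linkage(d)
    labels <- cut_tree(tree, config$cut_height)
    split_id <- if (identical(split, "none")) NULL
      else if (identical(split, "largest")) {
        sizes <- table(labels)
        names(sizes)[which.max(sizes)]
      } else as.character(split)
    final <- if (!is.null(split_id) &&
                 sum(labels == as.integer(split_id)) >= 2L) {
      split_cluster(d, labels, as.integer(split_id), k = 2L)
    } else as.character(labels)
    names(final) <- names(labels)
    list(tree = tree, labels = final)
  })
  labels <- cluster_out$labels
  write_tsv(data.frame(patient_id = names(labels), cluster = labels),
            file.path(out_dir, "clusters.tsv"))
  summ <- stage("cluster", cluster_summary(labels, clinical))
  write_tsv(summ$summary, file.path(out_dir, "cluster_summary.tsv"))
  write_tsv(summ$flows, file.path(out_dir, "cluster_flows.tsv"))

  log_line(log_con, "stage survival")
  surv_clusters <- stage("survival", drfs_by_cluster(clinical, labels))
  write_tsv(surv_clusters, file.path(out_dir, "survival_clusters.tsv"))
  surv_screen <- stage("survival", suppressWarnings(
    analyte_survival_screen(harm$matrix, clinical, labels,
                            bh_alpha = config$bh_alpha)))
  write_tsv(surv_screen, file.path(out_dir, "survival_analytes.tsv"))

  log_line(log_con, "stage harps: derivation filter ",
           paste(unlist(harps_filter), collapse = "/"))
  harps <- stage("harps", derive_harps(harm$matrix, clinical, harps_filter))
  write_harps_model(harps, file.path(out_dir, "harps.json"))
  status <- stage("harps", harps_classify(harm$matrix, harps))
  write_tsv(data.frame(patient_id = names(status), status = status),
            file.path(out_dir, "harps_status.tsv"))
  harps_resp <- stage("harps", harps_response_table(status, clinical))
  write_tsv(harps_resp, file.path(out_dir, "harps_response.tsv"))

  outputs <- list.files(out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, c("manifest.json", "run.log"))
  manifest <- list(
    package = "rppasig",
    version = as.character(packageVersion("rppasig")),
    seed = config$seed,
    config = unclass(config),
    n_patients = nrow(clinical),
    n_analytes = ncol(harm$matrix),
    n_arrays = length(endpoints),
    n_clusters = length(unique(labels)),
    files = lapply(setNames(nm = sort(outputs)), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
           bytes = file.size(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_con, "done: ", nrow(clinical), " patients, ",
           ncol(harm$matrix), " analytes, ", length(endpoints), " arrays, ",
           length(unique(labels)), " clusters")

  invisible(list(
    clinical = clinical, truth = truth, endpoints = endpoints,
    harmonized = harm$matrix, models = harm$models, associations = assoc,
    tree = cluster_out$tree, labels = labels, cluster_summary = summ,
    survival = surv_clusters, survival_screen = surv_screen,
    harps = harps, harps_status = status, harps_response = harps_resp,
    manifest = manifest
  ))
}

write_tsv <- function(df, path) {
  con <- open_out(path)
  on.exit(close(con))
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- "NA"
    s
  })
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
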