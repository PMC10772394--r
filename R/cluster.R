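# Signaling-cluster definition: 1 - Pearson correlation distance between
# patient profiles, complete-linkage agglomeration, fixed-height dendrogram
# cut, and a k-branch sub-split of a chosen cluster.

#' Pearson correlation distance between patient profiles
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation across the
#' analytes the two patients share (pairwise-complete for masked cells),
#' on the `[0, 2]` scale (the scale on which the cut height 1.54 lives).
#'
#' @param m Patient x analyte matrix.
#' @param min_shared Minimum number of shared analytes required between
#'   every pair of retained patients; patients failing the rule against
#'   any other patient are excluded with a warning.
#' @return A symmetric patient x patient distance matrix with zero
#'   diagonal.
#' @export
pearson_distance <- function(m, min_shared = 2L) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  obs <- !is.na(m)
  vars <- apply(m, 1L, function(x) var(x[!is.na(x)]))
  if (any(!is.na(vars) & vars == 0)) {
    stop("zero-variance profile for patient(s): ",
         paste(rownames(m)[!is.na(vars) & vars == 0], collapse = ", "))
  }
  shared <- tcrossprod(obs * 1)
  diag(shared) <- Inf
  # greedily drop the worst offender until every remaining pair shares
  # at least min_shared analytes
  keep <- seq_len(nrow(m))
  repeat {
    sh <- shared[keep, keep, drop = FALSE]
    viol <- rowSums(sh < min_shared)
    if (!any(viol > 0L)) break
    keep <- keep[-which.max(viol)]
  }
  if (length(keep) < nrow(m)) {
    warning("patient(s) excluded from clustering (fewer than ", min_shared,
            " shared analytes with another patient): ",
            paste(rownames(m)[-keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  r <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  if (anyNA(r)) stop("undefined correlation between some patient pair")
  d <- 1 - r
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Complete-linkage agglomeration
#'
#' Agglomerative clustering with inter-cluster distance equal to the
#' maximum pairwise distance; merge heights are non-decreasing.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [pearson_distance()]).
#' @return An `hclust` merge tree.
#' @export
complete_linkage <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  hclust(as.dist(d), method = "complete")
}

#' Cut a merge tree at a height
#'
#' Clusters are the connected components of merges below the threshold.
#' Labels are renumbered by dendrogram order (the leftmost cluster in the
#' dendrogram is 1), so cluster ids are stable under patient-row
#' permutation of the input.
#'
#' @param tree An `hclust` tree.
#' @param h Cut height.
#' @return Integer cluster labels named by the tree's leaf labels.
#' @export
cut_tree <- function(tree, h) {
  raw <- cutree(tree, h = h)
  first_seen <- unique(raw[tree$order])
  out <- match(raw, first_seen)
  names(out) <- names(raw)
  out
}

#' Split one cluster into its top k subtree branches
#'
#' Restricts the clustering to the target cluster's members (for complete
#' linkage the restriction of the agglomeration to a cluster's members
#' reproduces its subtree) and cuts it into its `k` top-level branches.
#' Sub-labels are `"<id>a"`, `"<id>b"`, ... ordered by subtree position.
#'
#' @param d The distance matrix used to build the tree.
#' @param labels Cluster labels from [cut_tree()] (named by patient).
#' @param target_cluster The cluster id to split.
#' @param k Number of branches (default 2).
#' @return Character label vector: unchanged ids for other clusters,
#'   `"<id><letter>"` within the target.
#' @export
split_cluster <- function(d, labels, target_cluster, k = 2L) {
  sel <- labels == target_cluster
  if (sum(sel) < k) {
    stop("cannot split cluster ", target_cluster, " of size ", sum(sel),
         " into ", k, " sub-clusters")
  }
  out <- as.character(labels)
  names(out) <- names(labels)
  members <- names(labels)[sel]
  sub_d <- d[members, members, drop = FALSE]
  sub_tree <- complete_linkage(sub_d)
  sub_raw <- cutree(sub_tree, k = k)
  first_seen <- unique(sub_raw[sub_tree$order])
  sub_lab <- letters[match(sub_raw, first_seen)]
  out[members] <- paste0(target_cluster, sub_lab)
  out
}

#' Per-cluster analyte means
#'
#' @param m Patient x analyte matrix.
#' @param labels Cluster labels aligned with (or named by) the rows.
#' @return cluster x analyte matrix of means (NA-aware).
#' @export
cluster_means <- function(m, labels) {
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  stopifnot(length(labels) == nrow(m))
  groups <- unique(labels)
  out <- t(vapply(groups, function(g) {
    colMeans(m[labels == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(m))))
  rownames(out) <- as.character(groups)
  out
}

#' Cluster summary table
#'
#' Per-cluster size, pCR count and rate, plus a long arm x cluster x pCR
#' flow table ready for Sankey-style display.
#'
#' @param labels Cluster labels (named by patient or aligned with rows).
#' @param clinical Clinical table.
#' @return List with `summary` (cluster, n, n_pcr, rate, and per-subtype
#'   counts) and `flows` (arm, cluster, pcr, n).
#' @export
cluster_summary <- function(labels, clinical) {
  if (!is.null(names(labels))) {
    labels <- labels[clinical$patient_id]
  }
  stopifnot(length(labels) == nrow(clinical))
  summary <- group_response_rates(labels, clinical)
  names(summary)[1L] <- "cluster"
  comp <- as.data.frame.matrix(table(labels, clinical$subtype))
  comp$cluster <- rownames(comp)
  summary <- merge(summary, comp, by = "cluster", sort = FALSE)
  flows <- as.data.frame(table(arm = clinical$arm, cluster = labels,
                               pcr = clinical$pcr))
  names(flows)[4L] <- "n"
  flows <- flows[flows$n > 0L, ]
  rownames(flows) <- NULL
  list(summary = summary, flows = flows)
}
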