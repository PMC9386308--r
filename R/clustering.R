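#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering of spectra with Ward's minimum-variance
#' criterion on squared Euclidean distances, as used for
#' spectral-diversity-driven selection of a reference set. Spectra should
#' be MSC-normalized first; a warning (not an error) is issued when the
#' processing history carries no scatter correction.
#'
#' @param spectra a [spectra_set()].
#' @return a `cluster_tree`: the `hclust` merge history plus the sample
#'   matrix and ids needed for centroid computations.
#' @export
ward_cluster <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  n <- nrow(spectra$absorbance)
  if (n < 2) stop("clustering needs at least 2 spectra")
  if (!any(grepl("^scatter:", spectra$meta$history))) {
    warning("spectra carry no scatter-correction history; ",
            "Ward selection is normally run on MSC-normalized spectra")
  }
  d2 <- stats::dist(spectra$absorbance, method = "euclidean")^2
  hc <- stats::hclust(d2, method = "ward.D")
  structure(list(hclust = hc,
                 absorbance = spectra$absorbance,
                 sample_ids = spectra$sample_ids),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> Ward / squared Euclidean, ",
      length(x$sample_ids), " samples, ", length(x$hclust$height),
      " merges\n", sep = "")
  invisible(x)
}

#' Flat cluster labels at a chosen cut
#' @param tree a `cluster_tree`.
#' @param k number of clusters.
#' @return integer labels named by sample id.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  labels <- stats::cutree(tree$hclust, k = k)
  stats::setNames(as.integer(labels), tree$sample_ids)
}

# center + boundary pick within one cluster (rows of mat).
# Returns local indices: the member nearest the centroid plus the
# `n_boundary` members farthest from it. Ties broken by id order
# (ids are assumed sorted-stable by caller order).
pick_center_boundary <- function(mat, n_boundary) {
  centroid <- colMeans(mat)
  d <- sqrt(rowSums(sweep(mat, 2, centroid)^2))
  center <- which.min(d)
  boundary <- order(d, decreasing = TRUE)[seq_len(min(n_boundary, nrow(mat)))]
  unique(c(center, boundary))
}

#' Select a spectrally diverse representative sample set
#'
#' Implements stratified purposive sampling on the cluster tree: the tree
#' is cut into `k_main` main clusters, each main cluster is re-clustered
#' into up to `k_sub` sub-clusters, and from every cluster and sub-cluster
#' the member nearest the centroid (center) and the `n_boundary` members
#' farthest from it (extreme boundary) are taken. Clusters or sub-clusters
#' with at most `small_cluster_max` members contribute all their members.
#' When `target` is given and the center/boundary picks fall short, the
#' selection is topped up round-robin across sub-clusters with the next
#' most-extreme members until the target size is reached.
#'
#' @param tree a `cluster_tree` from [ward_cluster()].
#' @param k_main number of main clusters.
#' @param k_sub number of sub-clusters per main cluster.
#' @param n_boundary boundary members per (sub-)cluster.
#' @param small_cluster_max clusters at or below this size contribute all
#'   members (default 4).
#' @param target optional target selection size.
#' @return character vector of selected sample ids (duplicate-free, in id
#'   order).
#' @export
select_representatives <- function(tree, k_main = 6, k_sub = 5,
                                   n_boundary = 2, small_cluster_max = 4,
                                   target = NULL) {
  stopifnot(inherits(tree, "cluster_tree"), k_main >= 1, k_sub >= 1)
  n <- length(tree$sample_ids)
  if (k_main > n) stop("k_main (", k_main, ") exceeds sample count (", n, ")")
  labels <- cut_clusters(tree, k_main)
  selected <- character()
  # remaining candidates per sub-cluster, ordered by decreasing extremity,
  # used for target top-up
  pools <- list()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    mat <- tree$absorbance[members, , drop = FALSE]
    ids <- tree$sample_ids[members]
    if (length(members) <= small_cluster_max) {
      selected <- c(selected, ids)
      next
    }
    # main-cluster center and boundary
    selected <- c(selected, ids[pick_center_boundary(mat, n_boundary)])
    # sub-clustering within the main cluster
    k_eff <- min(k_sub, length(members))
    sub_hc <- stats::hclust(stats::dist(mat)^2, method = "ward.D")
    sub_labels <- stats::cutree(sub_hc, k = k_eff)
    for (sub in sort(unique(sub_labels))) {
      sm <- which(sub_labels == sub)
      sub_mat <- mat[sm, , drop = FALSE]
      sub_ids <- ids[sm]
      if (length(sm) <= small_cluster_max) {
        selected <- c(selected, sub_ids)
        next
      }
      picks <- pick_center_boundary(sub_mat, n_boundary)
      selected <- c(selected, sub_ids[picks])
      centroid <- colMeans(sub_mat)
      d <- sqrt(rowSums(sweep(sub_mat, 2, centroid)^2))
      rest <- setdiff(order(d, decreasing = TRUE), picks)
      pools[[length(pools) + 1L]] <- sub_ids[rest]
    }
  }
  selected <- unique(selected)
  if (!is.null(target) && length(selected) < target && length(pools)) {
    repeat {
      added <- FALSE
      for (j in seq_along(pools)) {
        pool <- setdiff(pools[[j]], selected)
        pools[[j]] <- pool
        if (length(pool) && length(selected) < target) {
          selected <- c(selected, pool[1])
          added <- TRUE
        }
      }
      if (!added || length(selected) >= target) break
    }
  }
  sort(unique(selected))
}
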