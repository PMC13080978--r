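#' Validated distance matrix
#'
#' @param values symmetric nonnegative numeric matrix with zero diagonal
#'   (symmetry checked to 1e-9 and then enforced exactly by averaging).
#' @param metric_tag short label for the metric, e.g. `"ermsd"` or
#'   `"pose_min_rmsd"`.
#' @return the matrix, classed `dist_matrix`, with attribute `metric_tag`.
#' @export
dist_matrix <- function(values, metric_tag = "other") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (any(values < 0)) stop("negative distances")
  if (any(abs(values - t(values)) > 1e-9)) stop("asymmetric distance matrix")
  if (any(diag(values) != 0)) stop("nonzero diagonal")
  values <- (values + t(values)) / 2
  structure(values, metric_tag = metric_tag,
            class = c("dist_matrix", "matrix", "array"))
}

#' Quality-Threshold clustering of a distance matrix
#'
#' Repeatedly commits the largest remaining cluster whose diameter (maximum
#' pairwise distance) does not exceed `threshold`, removes its members, and
#' recurses until every item is assigned. The committed cluster is the true
#' maximum such subset, computed exactly: items at distance <= `threshold`
#' form a graph in which a diameter-bounded cluster is precisely a clique,
#' and a deterministic exact maximum-clique search (with a fast path for
#' complete components) is run each round; ties resolve in a fixed
#' ascending-index order. Output clusters are ordered by decreasing size
#' (ties by smallest first member).
#'
#' @param D a [dist_matrix()].
#' @param threshold nonnegative diameter cutoff, in the metric's units.
#' @return object of class `qt_clustering`: list with `clusters` (list of
#'   member-index vectors, sizes non-increasing), `labels` (per-item cluster
#'   id) and `threshold`.
#' @export
qt_cluster <- function(D, threshold) {
  stopifnot(inherits(D, "dist_matrix"))
  if (!is.numeric(threshold) || threshold < 0) stop("threshold must be >= 0")
  lab_raw <- qt_cluster_cpp(unclass(D), threshold)
  clusters <- split(seq_along(lab_raw), lab_raw)
  ord <- order(-lengths(clusters),
               vapply(clusters, min, integer(1)))
  clusters <- unname(clusters[ord])
  labels <- integer(length(lab_raw))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  structure(list(clusters = clusters, labels = labels,
                 threshold = threshold),
            class = "qt_clustering")
}

#' @export
print.qt_clustering <- function(x, ...) {
  cat("<qt_clustering>", length(x$clusters), "clusters at threshold",
      x$threshold, "- sizes:",
      paste(utils::head(lengths(x$clusters), 10), collapse = ", "),
      if (length(x$clusters) > 10) "..." else "", "\n")
  invisible(x)
}

#' Medoid of a cluster
#'
#' The member minimizing the sum of distances to the other members; ties
#' resolve to the lowest index.
#'
#' @param members integer vector of item indices.
#' @param D a [dist_matrix()].
#' @return a single item index.
#' @export
medoid <- function(members, D) {
  if (!length(members)) stop("empty cluster")
  if (length(members) == 1L) return(members)
  sums <- rowSums(D[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' Medoid set of a clustering
#'
#' @param clustering a [qt_cluster()] result.
#' @param D the [dist_matrix()] it was computed on.
#' @return data.frame (class `centroid_set`) with `cluster_id`, `size`,
#'   `medoid` and a `retained` flag (all TRUE until
#'   [select_diverse_centroids()] is applied).
#' @export
cluster_medoids <- function(clustering, D) {
  stopifnot(inherits(clustering, "qt_clustering"))
  out <- data.frame(
    cluster_id = seq_along(clustering$clusters),
    size = lengths(clustering$clusters),
    medoid = vapply(clustering$clusters, medoid, integer(1), D = D),
    retained = TRUE
  )
  class(out) <- c("centroid_set", "data.frame")
  out
}

#' Diversity-based centroid retention
#'
#' Scans centroids in descending parent-cluster size and retains one only
#' if its distance to every already-retained centroid exceeds `cutoff`;
#' the largest cluster's centroid is always retained. This maximizes the
#' structural variability of the retained representative set.
#'
#' @param centroids a `centroid_set` from [cluster_medoids()].
#' @param D the same [dist_matrix()].
#' @param cutoff retention distance cutoff (same units as `D`).
#' @return the centroid set with its `retained` flags updated.
#' @export
select_diverse_centroids <- function(centroids, D, cutoff) {
  stopifnot(inherits(centroids, "centroid_set"))
  ord <- order(-centroids$size, centroids$cluster_id)
  kept <- integer(0)
  retained <- logical(nrow(centroids))
  for (i in ord) {
    m <- centroids$medoid[i]
    if (!length(kept) || all(D[m, kept] > cutoff)) {
      retained[i] <- TRUE
      kept <- c(kept, m)
    }
  }
  centroids$retained <- retained
  centroids
}

#' Most-populated clusters covering a target fraction of items
#'
#' Returns the smallest prefix of the size-ordered clusters whose
#' cumulative member fraction reaches `coverage`.
#'
#' @param clustering a [qt_cluster()] result.
#' @param coverage target fraction in (0, 1].
#' @return integer vector of cluster ids.
#' @export
select_top_clusters <- function(clustering, coverage) {
  stopifnot(inherits(clustering, "qt_clustering"),
            coverage > 0, coverage <= 1)
  sizes <- lengths(clustering$clusters)
  frac <- cumsum(sizes) / sum(sizes)
  seq_len(which(frac >= coverage - 1e-12)[1])
}
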