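#' Clustering of similarity profiles
#'
#' Regions are clustered by their cross-species similarity profiles:
#' mouse regions featurized by their correlations to the other species'
#' targets (rows of the average-latent similarity matrix), and human
#' regions by its columns. The default is agglomerative clustering under
#' Euclidean distance with Ward linkage, evaluated by the within-cluster
#' sum of squared distances (WSS) to the cluster centroids; cluster
#' counts are picked with the elbow rule on the WSS scree curve.
#'
#' @name clustering
NULL

#' Hierarchical clustering of region profiles
#'
#' @param rows regions-by-features numeric matrix
#' @param method linkage method, default `"ward.D2"` (Ward on Euclidean
#'   distances)
#' @param distance distance metric for [stats::dist()]
#' @return An `hclust` object (class `c("linkage_tree", "hclust")`) that
#'   retains the feature matrix for WSS computation.
#' @export
hierarchical_cluster <- function(rows, method = "ward.D2",
                                 distance = "euclidean") {
  stopifnot(is.matrix(rows), nrow(rows) >= 2)
  if (!all(is.finite(rows))) stop("non-finite values in feature matrix")
  tree <- stats::hclust(stats::dist(rows, method = distance),
                        method = method)
  attr(tree, "features") <- rows
  class(tree) <- c("linkage_tree", "hclust")
  tree
}

# within-cluster sum of squared Euclidean distances to centroids
.wss <- function(features, labels) {
  sum(vapply(split(seq_len(nrow(features)), labels), function(idx) {
    x <- features[idx, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x), "-")^2)
  }, 0))
}

#' Cut a linkage tree into k clusters
#'
#' @param tree a `linkage_tree` from [hierarchical_cluster()]
#' @param k number of clusters, between 1 and the leaf count
#' @return An object of class `"cluster_solution"`: `k`, `labels` (named
#'   integer vector) and `wss` on the original features.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  features <- attr(tree, "features")
  n <- nrow(features)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  labels <- stats::cutree(tree, k = k)
  structure(list(k = as.integer(k), labels = labels,
                 wss = .wss(features, labels)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution: k =", x$k, "| WSS =", signif(x$wss, 5), "\n")
  invisible(x)
}

#' Within-cluster sum-of-squares scree curve
#'
#' WSS from nested cuts of a single linkage tree; non-increasing in `k`
#' because cuts refine each other.
#'
#' @param rows regions-by-features matrix
#' @param ks cluster counts to evaluate
#' @param method,distance passed to [hierarchical_cluster()]
#' @return data.frame with columns `k` and `wss`.
#' @export
scree_wss <- function(rows, ks = seq_len(nrow(rows)), method = "ward.D2",
                      distance = "euclidean") {
  tree <- hierarchical_cluster(rows, method = method, distance = distance)
  data.frame(k = as.integer(ks),
             wss = vapply(ks, function(k) cut_tree(tree, k)$wss, 0))
}

#' Elbow selection of the cluster count
#'
#' Picks the `k` maximizing the discrete second difference of the WSS
#' curve (the sharpest kink); ties resolve to the smallest such `k`. An
#' explicit `override` short-circuits the rule.
#'
#' @param curve data.frame with columns `k` and `wss`, as from
#'   [scree_wss()], ordered by `k`
#' @param override optional manual choice, returned as-is
#' @return Selected integer `k`.
#' @export
elbow_select <- function(curve, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(all(c("k", "wss") %in% names(curve)))
  if (nrow(curve) < 3) stop("need at least 3 curve points")
  curve <- curve[order(curve$k), ]
  w <- curve$wss
  second_diff <- w[seq_len(nrow(curve) - 2)] -
    2 * w[seq(2, nrow(curve) - 1)] + w[seq(3, nrow(curve))]
  curve$k[which.max(second_diff) + 1L]
}

#' Export a linkage tree as a JSON merge list
#'
#' The format records, per merge step, the two merged nodes (negative =
#' leaf index, positive = earlier merge index, following `hclust`) and
#' the merge height, plus the leaf labels.
#'
#' @param tree a `linkage_tree`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_linkage_json <- function(tree, path) {
  jsonlite::write_json(
    list(labels = tree$labels,
         merges = lapply(seq_len(nrow(tree$merge)), function(i)
           list(a = tree$merge[i, 1], b = tree$merge[i, 2],
                height = tree$height[i]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
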