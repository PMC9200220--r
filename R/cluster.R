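# Structural grouping of screening hits: agglomerative (average-linkage)
# clustering on Tanimoto distances between circular fingerprints, with
# medoid representatives.

#' Cluster compounds by fingerprint similarity
#'
#' Average-linkage agglomerative clustering (the reciprocal-nearest-
#' neighbor family) on the pairwise Tanimoto distance matrix, with the tree
#' cut to `k` clusters. Duplicate molecules are at distance 0 and always
#' co-cluster.
#'
#' @param fps a [fingerprints()] result.
#' @param k number of clusters (default 6).
#' @return object of class `hit_clustering`: `labels` (named integer vector
#'   in `1..k`), `k`, `linkage`, `merge_heights`.
#' @export
cluster_hits <- function(fps, k = 6L) {
  stopifnot(inherits(fps, "fingerprint_set"), k >= 1L)
  n <- length(fps$ids)
  if (n < k) {
    stop(sprintf("cannot form %d clusters from %d compounds", k, n))
  }
  d <- tanimoto_matrix(fps)
  hc <- hclust(stats::as.dist(d), method = "average")
  labels <- cutree(hc, k = k)
  names(labels) <- fps$ids
  structure(list(labels = labels, k = as.integer(k), linkage = "average",
                 merge_heights = hc$height),
            class = "hit_clustering")
}

#' @export
print.hit_clustering <- function(x, ...) {
  cat(sprintf("<hit_clustering: %d compounds in %d clusters (%s linkage)>\n",
              length(x$labels), x$k, x$linkage))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Pick a representative compound per cluster
#'
#' The representative is the cluster medoid: the member minimizing the
#' summed Tanimoto distance to its co-members, ties broken by id order.
#'
#' @param fps the `fingerprint_set` used for clustering.
#' @param clustering a [cluster_hits()] result over the same ids.
#' @return named character vector: cluster index -> representative id.
#' @export
representatives <- function(fps, clustering) {
  stopifnot(inherits(fps, "fingerprint_set"),
            inherits(clustering, "hit_clustering"),
            setequal(fps$ids, names(clustering$labels)))
  d <- tanimoto_matrix(fps)
  labels <- clustering$labels[fps$ids]
  reps <- character(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    tot <- rowSums(d[members, members, drop = FALSE])
    ids <- fps$ids[members]
    best <- ids[tot == min(tot)]
    reps[as.character(cl)] <- sort(best)[1L]
  }
  reps
}

#' End-to-end hit grouping from SMILES records
#'
#' Fingerprints selected hits, clusters them into `k` groups and marks each
#' group's medoid representative.
#'
#' @param records data frame with `smiles`, `id` of selected hits.
#' @param k number of clusters.
#' @param nbits,radius fingerprint settings (see [fingerprints()]).
#' @return data frame `id`, `cluster`, `is_representative`.
#' @export
cluster_report <- function(records, k = 6L, nbits = 2048L, radius = 2L) {
  fps <- fingerprints(records, nbits = nbits, radius = radius)
  cl <- cluster_hits(fps, k = k)
  reps <- representatives(fps, cl)
  data.frame(id = fps$ids,
             cluster = as.integer(cl$labels[fps$ids]),
             is_representative = fps$ids %in% reps,
             stringsAsFactors = FALSE)
}
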