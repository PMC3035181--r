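#' Euclidean pairwise distances
#'
#' @param x Numeric matrix, one point per row.
#' @return A \code{stats::dist} object (lower-triangle storage) of Euclidean
#'   distances between rows.
#' @export
pairwise_distances <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 points")
  stats::dist(x, method = "euclidean")
}

linkage_method <- function(linkage) {
  switch(linkage,
         average  = "average",
         complete = "complete",
         single   = "single",
         stop("unknown linkage '", linkage, "'"))
}

#' Build an agglomerative dendrogram
#'
#' Standard bottom-up merge tree over a distance matrix under average
#' (UPGMA), complete, or single linkage. The construction is deterministic
#' for a given input. The key property exploited by the FC procedure is that
#' one tree yields the partitions for every k via [cut_dendrogram()].
#'
#' @param d A \code{dist} object or a symmetric distance matrix with zero
#'   diagonal (e.g. from [pairwise_distances()] or
#'   [consensus_to_dissimilarity()]).
#' @param linkage "average", "complete", or "single".
#' @return An object of class \code{hclust}.
#' @export
build_dendrogram <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (!inherits(d, "dist")) stop("d must be a dist object or a square matrix")
  stats::hclust(d, method = linkage_method(linkage))
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last k - 1 merges of the tree. Group ids are renumbered so
#' that id 1 is the group of the smallest member index, id 2 the next
#' unseen group, and so on; for nested cuts of one tree the partitions are
#' nested across k by construction.
#'
#' @param dend An \code{hclust} object.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Integer vector of group ids in \code{1:k}, one per leaf.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) {
    stop("k must lie in [1, ", n, "], got ", k)
  }
  canonical_labels(stats::cutree(dend, k = k))
}

# Renumber group ids by order of first occurrence (smallest member index
# gets id 1). Partition-identical labelings map to the same vector.
canonical_labels <- function(labels) {
  labels <- as.integer(labels)
  map <- integer(max(labels))
  nxt <- 0L
  out <- integer(length(labels))
  for (i in seq_along(labels)) {
    g <- labels[i]
    if (map[g] == 0L) { nxt <- nxt + 1L; map[g] <- nxt }
    out[i] <- map[g]
  }
  out
}

#' Lloyd k-means from a partition
#'
#' One run of Lloyd's iteration under Euclidean distance, started from the
#' centroids of an initial partition: either a supplied labeling (for the
#' hierarchically-initialised engines the cut of the subsample's dendrogram)
#' or a uniform random partition, redrawn until all k labels occur. No
#' restarts. Iteration stops when no label changes or after
#' \code{max_iter} sweeps. If an assignment sweep empties a cluster, the
#' point farthest from its current centroid is reassigned to the empty
#' cluster and iteration continues (deterministic repair).
#'
#' @param x Numeric matrix of points (rows).
#' @param k Number of clusters, \code{k <= nrow(x)}.
#' @param init Optional integer labeling in \code{1:k} of length
#'   \code{nrow(x)}; if NULL a random partition is drawn from R's global
#'   random stream.
#' @param max_iter Maximum number of Lloyd sweeps (default 300).
#' @return Integer labels in \code{1:k} (canonicalised by first occurrence)
#'   with attributes \code{wcss} (final within-cluster sum of squares),
#'   \code{wcss_trace} (per-sweep values), \code{iterations} and
#'   \code{repairs} (number of empty-cluster repairs).
#' @export
kmeans_partition <- function(x, k, init = NULL, max_iter = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) stop("k must lie in [1, ", n, "], got ", k)
  if (is.null(init)) {
    repeat {
      init <- sample.int(k, n, replace = TRUE)
      if (length(unique(init)) == k) break
    }
  } else {
    init <- as.integer(init)
    if (length(init) != n) stop("init labeling length must equal nrow(x)")
    if (!identical(sort(unique(init)), seq_len(k))) {
      stop("init labels must cover 1:k exactly")
    }
  }
  labels <- init
  xsq <- rowSums(x^2)
  trace <- numeric(0)
  repairs <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    counts <- tabulate(labels, nbins = k)
    centers <- rowsum(x, labels) / counts  # labels always cover 1:k here
    # squared point-to-centroid distances via the expansion |x|^2 - 2 x.c + |c|^2
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    d2[d2 < 0] <- 0
    new_labels <- max.col(-d2, ties.method = "first")
    # deterministic empty-cluster repair
    empty <- which(tabulate(new_labels, nbins = k) == 0L)
    for (e in empty) {
      own <- d2[cbind(seq_len(n), new_labels)]
      movable <- tabulate(new_labels, nbins = k)[new_labels] > 1L
      cand <- which(movable)
      far <- cand[which.max(own[cand])]
      new_labels[far] <- e
      repairs <- repairs + 1L
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
    if (all(new_labels == labels)) { labels <- new_labels; break }
    labels <- new_labels
  }
  out <- canonical_labels(labels)
  attr(out, "wcss") <- trace[length(trace)]
  attr(out, "wcss_trace") <- trace
  attr(out, "iterations") <- iter
  attr(out, "repairs") <- repairs
  out
}

# Engine linkage token for the hierarchical component of an algorithm,
# or NULL for kmeans-r (which has none).
engine_linkage <- function(algorithm) {
  switch(algorithm,
         "hier-a" = , "kmeans-a" = "average",
         "hier-c" = , "kmeans-c" = "complete",
         "hier-s" = , "kmeans-s" = "single",
         "kmeans-r" = NULL,
         stop("unknown algorithm '", algorithm, "'"))
}

is_hierarchical <- function(algorithm) {
  algorithm %in% c("hier-a", "hier-c", "hier-s")
}

# Produce a k-cluster labeling of the points `x` for `algorithm`, reusing a
# prebuilt dendrogram `dend` of those points when one is supplied.
engine_labels <- function(x, k, algorithm, dend = NULL) {
  if (algorithm == "kmeans-r") {
    return(kmeans_partition(x, k))
  }
  if (is.null(dend)) {
    dend <- build_dendrogram(pairwise_distances(x), engine_linkage(algorithm))
  }
  cut <- cut_dendrogram(dend, k)
  if (is_hierarchical(algorithm)) cut else kmeans_partition(x, k, init = cut)
}
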