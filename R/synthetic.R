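# Class-mean placement for gaussian_clusters. Pairwise mean distances are
# exactly `separation` on the regular simplex (n_dims >= k); for k > n_dims
# in >= 2 dims, a regular k-gon whose shortest chord (adjacent vertices) is
# `separation`; in 1 dim, equal spacing. Symmetric placement keeps the
# grouping of true classes at coarser k tie-unstable under subsampling,
# mirroring exchangeable cluster geometry.
gaussian_means <- function(k, n_dims, separation) {
  if (n_dims >= k) {
    mu <- diag(k) * separation / sqrt(2)
    cbind(mu, matrix(0, k, n_dims - k))
  } else if (n_dims >= 2L) {
    R <- separation / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    cbind(R * cos(ang), R * sin(ang), matrix(0, k, n_dims - 2L))
  } else {
    matrix(separation * (seq_len(k) - 1L), k, 1L)
  }
}

labeled_dataset <- function(x, labels, true_k) {
  rownames(x) <- paste0("item", seq_len(nrow(x)))
  colnames(x) <- paste0("cond", seq_len(ncol(x)))
  structure(list(data = x, true_labels = as.integer(labels),
                 true_k = as.integer(true_k)),
            class = "labeled_dataset")
}

#' Spherical Gaussian cluster benchmark
#'
#' Draws each class from a spherical Gaussian of unit total within-class
#' spread — RMS radius \code{sqrt(E||x - mu||^2) = 1}, i.e. per-coordinate
#' SD \code{1/sqrt(n_dims)} — with class means placed so that every pair of
#' means is at least \code{separation} apart (see Details). Measuring the
#' separation in units of the total within-class spread makes the
#' difficulty of the recovery problem independent of the dimensionality.
#'
#' Means lie on a regular simplex when \code{n_dims >= k} (all pairwise
#' mean distances exactly equal to \code{separation}), on a regular k-gon
#' in the first two coordinates when \code{2 <= n_dims < k} (adjacent
#' distance equal to \code{separation}), and equally spaced on a line when
#' \code{n_dims = 1}. With \code{separation = 0} all classes share one mean
#' and the labels carry no recoverable structure.
#'
#' Uses R's global random stream (\code{set.seed()} for reproducibility).
#'
#' @param sizes Integer vector of per-class item counts (all >= 1); its
#'   length is the true class count.
#' @param n_dims Number of conditions (columns).
#' @param separation Inter-mean distance in within-class spread units
#'   (>= 0).
#' @return An object of class \code{"labeled_dataset"}: list with
#'   \code{data} (sum(sizes) x n_dims matrix with item/condition ids),
#'   \code{true_labels} and \code{true_k}.
#' @examples
#' set.seed(1)
#' d <- gaussian_clusters(c(20, 20, 20), n_dims = 200, separation = 6)
#' dim(d$data)   # 60 x 200
#' @export
gaussian_clusters <- function(sizes, n_dims, separation) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(is.na(sizes)) || any(sizes < 1L)) {
    stop("all class sizes must be >= 1")
  }
  n_dims <- as.integer(n_dims)
  if (is.na(n_dims) || n_dims < 1L) stop("n_dims must be >= 1")
  if (!is.numeric(separation) || is.na(separation) || separation < 0) {
    stop("separation must be >= 0")
  }
  k <- length(sizes)
  mu <- gaussian_means(k, n_dims, separation)
  sd_coord <- 1 / sqrt(n_dims)
  x <- do.call(rbind, lapply(seq_len(k), function(c) {
    matrix(stats::rnorm(sizes[c] * n_dims, sd = sd_coord),
           sizes[c], n_dims) +
      matrix(mu[c, ], sizes[c], n_dims, byrow = TRUE)
  }))
  labeled_dataset(x, rep(seq_len(k), sizes), k)
}

#' Marker-block expression benchmark
#'
#' Emulates gene-expression data with class-specific up-patterns: a
#' standard-Gaussian background matrix in which each class has a disjoint
#' block of \code{markers_per_class} features shifted upward by
#' \code{effect} (in noise-SD units) for that class's items. With
#' \code{effect = 0} the labels carry no signal.
#'
#' Uses R's global random stream.
#'
#' @param sizes Integer vector of per-class item counts.
#' @param n_features Total feature count; must be at least
#'   \code{length(sizes) * markers_per_class}.
#' @param markers_per_class Number of marker features per class.
#' @param effect Mean shift of a class's markers, in noise-SD units (>= 0).
#' @return A \code{"labeled_dataset"} (see [gaussian_clusters()]).
#' @export
marker_block_dataset <- function(sizes, n_features, markers_per_class,
                                 effect) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(is.na(sizes)) || any(sizes < 1L)) {
    stop("all class sizes must be >= 1")
  }
  n_features <- as.integer(n_features)
  markers_per_class <- as.integer(markers_per_class)
  k <- length(sizes)
  if (is.na(n_features) || is.na(markers_per_class) ||
      markers_per_class < 1L || k * markers_per_class > n_features) {
    stop("block overflow: need true_k * markers_per_class <= n_features")
  }
  if (!is.numeric(effect) || is.na(effect) || effect < 0) {
    stop("effect must be >= 0")
  }
  n <- sum(sizes)
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  row0 <- 0L
  for (c in seq_len(k)) {
    rows <- row0 + seq_len(sizes[c])
    cols <- (c - 1L) * markers_per_class + seq_len(markers_per_class)
    x[rows, cols] <- x[rows, cols] + effect
    row0 <- row0 + sizes[c]
  }
  labeled_dataset(x, rep(seq_len(k), sizes), k)
}

#' Structureless negative control
#'
#' An i.i.d. standard-Gaussian matrix with a single class: no cluster
#' structure for any k. Consensus entries on such data stay away from the
#' 0/1 extremes, in contrast to structured data.
#'
#' @param n Number of items (>= 3).
#' @param n_dims Number of conditions.
#' @return A \code{"labeled_dataset"} with \code{true_k = 1}.
#' @export
null_dataset <- function(n, n_dims) {
  n <- as.integer(n); n_dims <- as.integer(n_dims)
  if (is.na(n) || n < 3L) stop("n must be >= 3")
  if (is.na(n_dims) || n_dims < 1L) stop("n_dims must be >= 1")
  labeled_dataset(matrix(stats::rnorm(n * n_dims), n, n_dims),
                  rep(1L, n), 1L)
}

# Named presets mirroring the artificial benchmark analogs with gold
# k = 3, 5 and 6. These are analogs preserving the gold cluster number and
# the qualitative regime, not reproductions of the original recipes.
synthetic_preset <- function(name) {
  switch(name,
         gaussian3  = gaussian_clusters(c(20L, 20L, 20L), 200L, 6),
         gaussian5  = gaussian_clusters(c(80L, 120L, 100L, 120L, 80L), 2L, 6),
         simulated6 = marker_block_dataset(c(8L, 12L, 10L, 15L, 5L, 10L),
                                           600L, 50L, 2),
         null       = null_dataset(60L, 600L),
         stop("unknown synthetic preset '", name, "'"))
}
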