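#' Create an empty consensus accumulator
#'
#' Holds the two running integer sums behind a consensus matrix: the
#' co-clustering counts (how often a pair of items landed in the same
#' cluster) and the co-sampling counts (how often the pair was drawn into
#' the same subsample). Their elementwise ratio, taken by
#' [finalize_consensus()], is the consensus matrix.
#'
#' @param n Number of items in the full data matrix.
#' @return An object of class \code{"consensus_accumulator"}.
#' @export
consensus_accumulator <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  structure(list(n = n,
                 co_cluster = matrix(0L, n, n),
                 co_sampled = matrix(0L, n, n)),
            class = "consensus_accumulator")
}

#' Fold one clustering solution into an accumulator
#'
#' For every unordered pair of items in the subsample the co-sampling count
#' is incremented; the co-clustering count is incremented only for pairs
#' sharing a cluster label. Pairs involving unsampled items, and the
#' diagonal, are untouched.
#'
#' @param acc A [consensus_accumulator()].
#' @param labels Integer cluster labels, one per subsampled item, in the
#'   order of \code{resample}.
#' @param resample Increasing integer vector of subsampled item indices
#'   (as returned by [subsample()]).
#' @return The updated accumulator.
#' @export
accumulate <- function(acc, labels, resample) {
  stopifnot(inherits(acc, "consensus_accumulator"))
  if (length(labels) != length(resample)) {
    stop("labeling/resample size mismatch: ", length(labels), " labels for ",
         length(resample), " sampled items")
  }
  if (any(resample < 1L) || any(resample > acc$n)) {
    stop("resample indices out of range")
  }
  m <- length(resample)
  inc_s <- matrix(1L, m, m); diag(inc_s) <- 0L
  inc_c <- matrix(as.integer(outer(labels, labels, "==")), m, m)
  diag(inc_c) <- 0L
  acc$co_sampled[resample, resample] <- acc$co_sampled[resample, resample] + inc_s
  acc$co_cluster[resample, resample] <- acc$co_cluster[resample, resample] + inc_c
  acc
}

#' Normalise an accumulator into a consensus matrix
#'
#' Entry (i, j) is the ratio of co-clustering to co-sampling counts: the
#' fraction of subsamples containing both items in which they shared a
#' cluster. Pairs never co-sampled are set to 0 (no evidence of
#' co-clustering) with a warning; the diagonal is fixed at 1 by convention.
#' Symmetry and the [0, 1] range are asserted on the result.
#'
#' @param acc A [consensus_accumulator()] fed by at least one resample.
#' @param k The cluster count the solutions were computed for (carried as
#'   an attribute).
#' @return An n x n numeric matrix with attribute \code{k}.
#' @export
finalize_consensus <- function(acc, k) {
  stopifnot(inherits(acc, "consensus_accumulator"))
  if (all(acc$co_sampled == 0L)) stop("accumulator is empty: no resamples folded in")
  M <- matrix(0, acc$n, acc$n)
  sampled <- acc$co_sampled > 0L
  M[sampled] <- acc$co_cluster[sampled] / acc$co_sampled[sampled]
  miss <- sum(!sampled[upper.tri(sampled)])
  if (miss > 0L) {
    warning(miss, " item pair(s) were never co-sampled; their consensus is set to 0")
  }
  diag(M) <- 1
  stopifnot(isTRUE(all.equal(M, t(M))), all(M >= 0), all(M <= 1))
  attr(M, "k") <- as.integer(k)
  M
}

# Shared driver for the consensus / FC procedures and the naive FC
# reference. `share_resamples` switches between fresh subsamples per k
# (consensus, stream (k, h)) and one subsample for all k (FC, stream
# (0, h)); `reuse_dendrogram` controls whether hierarchical trees are built
# once per resample (FC fast path) or rebuilt for every k (naive path).
run_engine <- function(x, cfg, share_resamples, reuse_dendrogram,
                       verbose = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  validate_config(cfg, nrow(x))
  n <- nrow(x)
  ks <- cfg$k_min:cfg$k_max
  needs_tree <- cfg$algorithm != "kmeans-r"
  accs <- lapply(ks, function(k) consensus_accumulator(n))
  names(accs) <- as.character(ks)

  if (share_resamples) {
    for (h in seq_len(cfg$H)) {
      set.seed(child_seed(cfg$seed, 0L, h))
      idx <- subsample(n, cfg$p)
      xs <- x[idx, , drop = FALSE]
      dend <- if (needs_tree && reuse_dendrogram) {
        build_dendrogram(pairwise_distances(xs), engine_linkage(cfg$algorithm))
      } else NULL
      for (j in seq_along(ks)) {
        labels <- engine_labels(xs, ks[j], cfg$algorithm, dend = dend)
        accs[[j]] <- accumulate(accs[[j]], labels, idx)
      }
      if (verbose && h %% 50L == 0L) {
        message("  resample ", h, "/", cfg$H)
      }
    }
  } else {
    for (j in seq_along(ks)) {
      for (h in seq_len(cfg$H)) {
        set.seed(child_seed(cfg$seed, ks[j], h))
        idx <- subsample(n, cfg$p)
        xs <- x[idx, , drop = FALSE]
        labels <- engine_labels(xs, ks[j], cfg$algorithm, dend = NULL)
        accs[[j]] <- accumulate(accs[[j]], labels, idx)
      }
      if (verbose) message("  k = ", ks[j], " done (", cfg$H, " resamples)")
    }
  }

  matrices <- lapply(seq_along(ks), function(j) {
    M <- finalize_consensus(accs[[j]], ks[j])
    dimnames(M) <- list(rownames(x), rownames(x))
    attr(M, "k") <- ks[j]
    M
  })
  names(matrices) <- as.character(ks)
  structure(list(matrices = matrices, k = ks,
                 method = cfg$method, algorithm = cfg$algorithm,
                 H = cfg$H, p = cfg$p, seed = cfg$seed,
                 n = n, item_ids = rownames(x)),
            class = "consensus_result")
}

#' Run the consensus procedure (k-outer loop)
#'
#' For every candidate k in \code{[cfg$k_min, cfg$k_max]}, draws
#' \code{cfg$H} fresh subsamples, clusters each into k groups with the
#' configured engine, and normalises the accumulated connectivity counts
#' into a consensus matrix. Every (k, h) pair uses its own deterministic
#' child stream of the master seed, so results are exactly reproducible.
#' Total clustering runs: \code{(k_max - k_min + 1) * H}.
#'
#' @param x Numeric item-by-condition matrix (items are rows).
#' @param cfg A [run_config()]; its \code{method} field is set to
#'   "consensus" in the result.
#' @param verbose Log per-k progress via \code{message()}.
#' @return A \code{"consensus_result"}: list with per-k consensus
#'   \code{matrices} (named by k), the k grid, and the run parameters.
#' @seealso [run_fc()] for the fast variant, [consensus_curves()] and
#'   [predict_k()] for the downstream prediction.
#' @export
run_consensus <- function(x, cfg, verbose = FALSE) {
  cfg$method <- "consensus"
  run_engine(x, cfg, share_resamples = FALSE, reuse_dendrogram = FALSE,
             verbose = verbose)
}

#' Run the FC procedure (h-outer loop, dendrogram reuse)
#'
#' The fast variant: the resampling loop is outermost, so one subsample
#' serves every candidate k. For hierarchical engines a single dendrogram
#' is built per resample and cut at every k — H tree constructions in total
#' instead of \code{(k_max - k_min + 1) * H}; the hierarchically-initialised
#' k-means engines likewise reuse the one tree for their initial partitions.
#' The output is bit-identical to re-clustering each subsample from scratch
#' for every k (the property the test suite enforces): only redundant work
#' is skipped, no approximation is introduced.
#'
#' @inheritParams run_consensus
#' @return A \code{"consensus_result"}, as for [run_consensus()].
#' @export
run_fc <- function(x, cfg, verbose = FALSE) {
  cfg$method <- "fc"
  run_engine(x, cfg, share_resamples = TRUE, reuse_dendrogram = TRUE,
             verbose = verbose)
}

# Naive FC reference: same loop order and random streams as run_fc, but the
# subsample is re-clustered from scratch for every k (no dendrogram reuse).
# Kept as the internal oracle for the fast path's exactness.
run_fc_naive <- function(x, cfg, verbose = FALSE) {
  cfg$method <- "fc"
  run_engine(x, cfg, share_resamples = TRUE, reuse_dendrogram = FALSE,
             verbose = verbose)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus matrices (", x$method, ", ", x$algorithm, ")\n", sep = "")
  cat("  items:  ", x$n, "\n")
  cat("  k grid: [", min(x$k), ", ", max(x$k), "]\n", sep = "")
  cat("  H = ", x$H, ", p = ", x$p, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
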