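#' Supported clustering engines
#'
#' Engine tokens accepted throughout the package: three agglomerative
#' hierarchical engines under Euclidean distance (\code{"hier-a"} average
#' linkage, \code{"hier-c"} complete linkage, \code{"hier-s"} single linkage),
#' Lloyd k-means from a random partition (\code{"kmeans-r"}), and Lloyd
#' k-means initialised from the corresponding hierarchical cut
#' (\code{"kmeans-a"}, \code{"kmeans-c"}, \code{"kmeans-s"}).
#'
#' @format A character vector of engine tokens.
#' @export
CLUSTER_ALGORITHMS <- c("hier-a", "hier-c", "hier-s",
                        "kmeans-r", "kmeans-a", "kmeans-c", "kmeans-s")

#' Build a validated run configuration
#'
#' Collects the parameters governing a consensus run: the procedure
#' (\code{"consensus"}, k-outer loop with fresh subsamples per k, or
#' \code{"fc"}, h-outer loop with one subsample shared across k), the
#' clustering engine, the number of resampling steps \code{H}, the
#' subsampling fraction \code{p}, the candidate range \code{[k_min, k_max]},
#' the plateau threshold \code{tau} used by [predict_k()], and the master
#' seed from which all per-resample random streams are derived.
#'
#' Data-dependent constraints (notably \code{k_max <= floor(p * n)}: a
#' k-cluster solution needs at least k sampled items) are checked against a
#' concrete matrix by [validate_config()].
#'
#' @param method "consensus" or "fc".
#' @param algorithm One of [CLUSTER_ALGORITHMS].
#' @param H Positive integer, number of resampling steps. Default 250.
#' @param p Subsampling fraction in (0, 1]; each resample keeps
#'   \code{floor(p * n)} items. Default 0.8.
#' @param k_min,k_max Candidate cluster-number range; \code{k_min >= 2}.
#'   Defaults 2 and 30.
#' @param tau Plateau threshold in (0, 1) for the Delta rule. Default 0.03.
#' @param seed Integer master seed.
#' @param transpose Logical; if TRUE the input matrix is transposed at load
#'   so that items are always rows downstream.
#' @param out_dir Optional output directory (used by the CLI).
#' @return An object of class \code{"run_config"}.
#' @seealso [validate_config()], [run_consensus()], [run_fc()]
#' @export
run_config <- function(method = c("fc", "consensus"),
                       algorithm = "hier-a",
                       H = 250L, p = 0.8,
                       k_min = 2L, k_max = 30L,
                       tau = 0.03, seed = 1L,
                       transpose = FALSE, out_dir = NULL) {
  method <- match.arg(method)
  if (!is.character(algorithm) || length(algorithm) != 1L ||
      !(algorithm %in% CLUSTER_ALGORITHMS)) {
    stop("unknown algorithm '", paste(algorithm, collapse = ","),
         "'; expected one of: ", paste(CLUSTER_ALGORITHMS, collapse = ", "))
  }
  H <- as.integer(H)
  if (is.na(H) || H < 1L) stop("H must be a positive integer")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]")
  }
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 2L) stop("k_min must be an integer >= 2")
  if (is.na(k_max) || k_max < k_min) stop("k_max must be >= k_min")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1) {
    stop("tau must lie in (0, 1)")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(method = method, algorithm = algorithm, H = H, p = p,
                 k_min = k_min, k_max = k_max, tau = tau, seed = seed,
                 transpose = isTRUE(transpose), out_dir = out_dir),
            class = "run_config")
}

#' Check a configuration against a concrete data matrix
#'
#' Enforces the data-dependent invariants: at least 3 items, subsamples of
#' at least 2 items, and \code{k_max <= floor(p * n)} so that every
#' subsample can host a k_max-cluster solution.
#'
#' @param cfg A [run_config()] object.
#' @param n Number of items (rows) in the data matrix.
#' @return \code{cfg}, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg, n) {
  stopifnot(inherits(cfg, "run_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("need at least 3 items to cluster (n = ", n, ")")
  size <- floor(cfg$p * n)
  if (size < 2L) stop("sample too small: floor(p * n) = ", size, " < 2")
  if (cfg$k_max > size) {
    stop("k_max must satisfy k_max <= floor(p * n) = ", size,
         " (got k_max = ", cfg$k_max,
         "); a k-cluster solution needs at least k sampled items")
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Consensus run configuration\n")
  cat("  method:    ", x$method, "\n")
  cat("  algorithm: ", x$algorithm, "\n")
  cat("  H:         ", x$H, "\n")
  cat("  p:         ", x$p, "\n")
  cat("  k range:   [", x$k_min, ", ", x$k_max, "]\n", sep = "")
  cat("  tau:       ", x$tau, "\n")
  cat("  seed:      ", x$seed, "\n")
  invisible(x)
}
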